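#' Biallelic SNP genotype matrix
#'
#' Integer allele-dosage codes 0/1/2 (count of the allele whose homozygote
#' is coded 2), `NA` for missing calls.
#'
#' @param codes integer matrix, animals in rows, SNPs in columns.
#' @param animal_ids,snp_ids identifiers; default to dimnames.
#' @return object of class `"genotype_matrix"` with elements `codes`,
#'   `animal_ids`, `snp_ids`.
#' @export
genotype_matrix <- function(codes, animal_ids = rownames(codes),
                            snp_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  if (is.null(animal_ids)) animal_ids <- paste0("ind", seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  animal_ids <- as.character(animal_ids)
  snp_ids <- as.character(snp_ids)
  if (nrow(codes) != length(animal_ids) || ncol(codes) != length(snp_ids))
    stop("code matrix dimensions inconsistent with id lists")
  if (anyDuplicated(animal_ids)) stop("duplicate animal ids")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  ok <- is.na(codes) | codes %in% c(0L, 1L, 2L)
  if (!all(ok))
    stop("genotype codes must be 0, 1, 2 or NA; first offender at row ",
         which(!ok, arr.ind = TRUE)[1, 1])
  storage.mode(codes) <- "integer"
  dimnames(codes) <- list(animal_ids, snp_ids)
  structure(list(codes = codes, animal_ids = animal_ids, snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs (%.1f%% missing)\n",
              length(x$animal_ids), length(x$snp_ids),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' Read genotypes from CSV or PLINK text files
#'
#' Auto-detects by extension: `.csv` expects animals in rows (first column
#' `animal`), SNP columns coded 0/1/2 with `NA` missing; `.ped` expects the
#' companion `.map` beside it, two allele columns per SNP with `0` missing,
#' dosage counted for the lexicographically larger allele.
#'
#' @param path `.csv` or `.ped` file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] != "animal")
      stop("genotype CSV must have first column 'animal'")
    codes <- as.matrix(df[, -1, drop = FALSE])
    rownames(codes) <- as.character(df$animal)
    return(genotype_matrix(codes))
  }
  if (grepl("\\.ped$", path, ignore.case = TRUE))
    return(.read_plink_ped(path))
  stop("unrecognized genotype file extension: ", path)
}

.read_plink_ped <- function(path) {
  map_path <- sub("\\.ped$", ".map", path, ignore.case = TRUE)
  if (!file.exists(map_path))
    stop("companion .map file not found: ", map_path)
  map <- utils::read.table(map_path, colClasses = "character")
  snp_ids <- map[[2]]
  lines <- utils::read.table(path, colClasses = "character")
  if (ncol(lines) != 6 + 2 * length(snp_ids))
    stop(".ped column count does not match .map SNP count")
  animal_ids <- lines[[2]]
  n <- nrow(lines); L <- length(snp_ids)
  codes <- matrix(NA_integer_, n, L, dimnames = list(animal_ids, snp_ids))
  for (j in seq_len(L)) {
    a1 <- lines[[6 + 2 * j - 1]]
    a2 <- lines[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) > 2)
      stop("SNP ", snp_ids[j], " has more than two alleles")
    ref2 <- alleles[length(alleles)]   # dosage of the larger-sorting allele
    codes[, j] <- (a1 == ref2) + (a2 == ref2)
    codes[miss, j] <- NA_integer_
  }
  genotype_matrix(codes)
}

#' Write genotypes as CSV
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(animal = geno$animal_ids, geno$codes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Allele frequencies of the allele coded 2
#'
#' `p_j = sum(codes) / (2 * n_non_missing)` per SNP.
#'
#' @param geno a [genotype_matrix()].
#' @return named numeric vector of frequencies.
#' @export
allele_frequencies <- function(geno) {
  nn <- colSums(!is.na(geno$codes))
  if (any(nn == 0))
    stop("SNP(s) with no non-missing calls: ",
         paste(geno$snp_ids[nn == 0], collapse = ", "))
  colSums(geno$codes, na.rm = TRUE) / (2 * nn)
}

#' SNP quality control
#'
#' Sequential filters in the order: call rate, Hardy-Weinberg equilibrium
#' (chi-square goodness of fit on genotype counts among non-missing calls),
#' minor allele frequency. Counts are reported per stage, so each SNP is
#' attributed to the first filter that removes it.
#'
#' @param geno a [genotype_matrix()].
#' @param call_rate_min minimum fraction of non-missing calls.
#' @param hwe_p_cutoff SNPs with HWE test P below this are removed.
#' @param maf_min minimum minor allele frequency.
#' @return list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (class `"snp_qc_report"`: counts per filter, surviving
#'   ids, thresholds).
#' @export
qc_snps <- function(geno, call_rate_min = 0.90, hwe_p_cutoff = 1e-15,
                    maf_min = 0.01) {
  n_input <- length(geno$snp_ids)
  codes <- geno$codes
  call_rate <- colMeans(!is.na(codes))
  drop_cr <- call_rate < call_rate_min
  keep <- !drop_cr

  hwe_p <- rep(NA_real_, n_input)
  hwe_p[keep] <- apply(codes[, keep, drop = FALSE], 2, .hwe_chisq_p)
  drop_hwe <- keep & !is.na(hwe_p) & hwe_p < hwe_p_cutoff
  keep <- keep & !drop_hwe

  maf <- rep(NA_real_, n_input)
  if (any(keep)) {
    p <- colSums(codes[, keep, drop = FALSE], na.rm = TRUE) /
      (2 * colSums(!is.na(codes[, keep, drop = FALSE])))
    maf[keep] <- pmin(p, 1 - p)
  }
  drop_maf <- keep & maf < maf_min
  keep <- keep & !drop_maf

  survivors <- geno$snp_ids[keep]
  if (!length(survivors))
    warning("all SNPs removed by quality control: empty panel")
  report <- structure(list(
    n_input = n_input,
    n_removed_callrate = sum(drop_cr),
    n_removed_hwe = sum(drop_hwe),
    n_removed_maf = sum(drop_maf),
    surviving_snp_ids = survivors,
    thresholds = c(call_rate_min = call_rate_min,
                   hwe_p_cutoff = hwe_p_cutoff, maf_min = maf_min)),
    class = "snp_qc_report")
  out <- genotype_matrix(codes[, keep, drop = FALSE],
                         animal_ids = geno$animal_ids,
                         snp_ids = survivors)
  list(genotypes = out, report = report)
}

#' @export
print.snp_qc_report <- function(x, ...) {
  cat(sprintf(paste0("SNP QC: %d in; removed %d (call rate), %d (HWE), ",
                     "%d (MAF); %d remain\n"),
              x$n_input, x$n_removed_callrate, x$n_removed_hwe,
              x$n_removed_maf, length(x$surviving_snp_ids)))
  invisible(x)
}

# chi-square goodness-of-fit to Hardy-Weinberg proportions, 1 df
.hwe_chisq_p <- function(col) {
  col <- col[!is.na(col)]
  n <- length(col)
  if (n == 0) return(NA_real_)
  obs <- c(sum(col == 0L), sum(col == 1L), sum(col == 2L))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)       # monomorphic: trivially in HWE
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((obs - expd)^2 / expd)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Scale genotypes for the genomic relationship matrix
#'
#' `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`. Missing codes are
#' imputed at `2 p_j` (scaled value 0), which preserves zero column means.
#'
#' @param geno a [genotype_matrix()].
#' @param freqs per-SNP frequencies of the allele coded 2; defaults to
#'   [allele_frequencies()] of `geno` itself.
#' @return object of class `"scaled_genotypes"`: `values` (animals x SNPs),
#'   `freqs`, `n_snps`.
#' @export
scale_genotypes <- function(geno, freqs = allele_frequencies(geno)) {
  if (length(freqs) != length(geno$snp_ids))
    stop("freqs length does not match SNP count")
  if (any(freqs <= 0 | freqs >= 1))
    stop("fixed SNP(s) with p in {0,1}: run qc_snps() first (",
         paste(geno$snp_ids[freqs <= 0 | freqs >= 1], collapse = ", "), ")")
  X <- geno$codes
  W <- sweep(X, 2, 2 * freqs, "-")
  W <- sweep(W, 2, sqrt(2 * freqs * (1 - freqs)), "/")
  W[is.na(W)] <- 0                       # impute missing at 2p_j
  structure(list(values = W, freqs = freqs, n_snps = ncol(W),
                 animal_ids = geno$animal_ids, snp_ids = geno$snp_ids),
            class = "scaled_genotypes")
}

#' Genomic relationship matrix
#'
#' VanRaden's second form on scaled genotypes: `G = WW'/N` with `N` the
#' SNP count.
#'
#' @param scaled a [scale_genotypes()] result.
#' @return [relationship_structure()] of kind `"G"` over the genotyped
#'   animals.
#' @export
build_genomic_relationship <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_genotypes"), scaled$n_snps >= 1)
  G <- tcrossprod(scaled$values) / scaled$n_snps
  dimnames(G) <- list(scaled$animal_ids, scaled$animal_ids)
  relationship_structure((G + t(G)) / 2, kind = "G")
}
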