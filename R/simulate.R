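# Synthetic family designs with genetically heterogeneous residual
# variance, emulating a large full-sib aquaculture breeding nucleus:
# hierarchical sire x dam matings, wide family-size variation, a
# genotyped subset of families plus all parents, and phenotypes whose
# residual variance follows an exponential genetic model.

#' Simulation configuration
#'
#' Defaults emulate the reference design: 131 sires mated to 234 dams
#' (1-3 dams per sire), 234 full-sib families with mean size 15.4 (range
#' 4-54, ~3600 fish), 50 genotyped families with 21-38 genotyped sibs
#' each plus all parents (~39% of offspring genotyped), and a SNP panel
#' of 3000 markers. Genetic structure: additive variance 0.3 and
#' common-environment variance 0.1 for weight on the (unit-variance)
#' analysis scale, exponential-scale genetic variance of uniformity 0.23
#' with genetic correlation 0.95 to the mean, common-environment
#' dispersion variance 0.135, and baseline residual variance 0.5 (mean
#' realized residual variance ~0.6, so h2 ~ 0.3 and c2 ~ 0.1). With
#' `scale_effect = TRUE` the same model lives on the log scale with
#' log-scale defaults (additive 0.045, dispersion genetic 0.09,
#' correlation 0), and observed weight is the exponential, giving a
#' mean-variance scale effect on the raw scale.
#'
#' @param n_sires,n_dams parents (each dam mated once; sires serve
#'   `dams_per_sire_range` dams).
#' @param dams_per_sire_range integer range of matings per sire.
#' @param family_size_mean,family_size_range mean and truncation range of
#'   full-sib family sizes (negative-binomial above the lower bound).
#' @param n_snps SNP panel size for gene dropping.
#' @param founder_maf_range founder allele frequencies drawn uniformly
#'   from this range.
#' @param genotyped_families number of families with genotyped offspring.
#' @param genotyped_sibs_range genotyped sibs per genotyped family.
#' @param sigma2_a additive genetic variance of weight (analysis scale).
#' @param sigma2_av_exp exponential-scale genetic variance of uniformity.
#' @param r_g_mean_disp genetic correlation between weight and its
#'   dispersion.
#' @param sigma2_c,sigma2_cv_exp full-sib common-environment variances
#'   (mean and dispersion; their covariance is zero).
#' @param sigma2_e baseline residual variance (per-fish variance is
#'   `sigma2_e * exp(a_v + c_v)`).
#' @param mu intercept on the analysis scale.
#' @param beta_age linear age effect per day.
#' @param age_window days over which family ages spread (one hatching
#'   window).
#' @param age_mean mean age at measurement in days.
#' @param tank_effects,year_class_effects fixed-effect level values.
#' @param weight_mean,weight_sd gram-scale affine mapping of the analysis
#'   scale when `scale_effect = FALSE` (`weight = mean + sd * y`).
#' @param scale_effect simulate on the log scale and exponentiate, so the
#'   raw scale carries a multiplicative mean-variance relation.
#' @param genetic_architecture `"genomic"` (default): breeding-value
#'   pairs are sums of SNP effects over the gene-dropped panel, so
#'   realized genomic relationships carry the trait's Mendelian sampling
#'   and genomic evaluation has information to exploit; `"pedigree"`:
#'   parent-average plus Mendelian-sampling recursion independent of the
#'   markers (the structure used when no genotypes are simulated).
#' @param seed integer seed; every generator call is reproducible from
#'   the config alone.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_sires = 131, n_dams = 234,
                       dams_per_sire_range = c(1L, 3L),
                       family_size_mean = 15.4,
                       family_size_range = c(4L, 54L),
                       n_snps = 3000,
                       founder_maf_range = c(0.05, 0.5),
                       genotyped_families = 50,
                       genotyped_sibs_range = c(21L, 38L),
                       sigma2_a = NULL, sigma2_av_exp = NULL,
                       r_g_mean_disp = NULL,
                       sigma2_c = NULL, sigma2_cv_exp = NULL,
                       sigma2_e = NULL,
                       mu = 0, beta_age = NULL,
                       age_window = 28, age_mean = 480,
                       tank_effects = NULL, year_class_effects = NULL,
                       weight_mean = 500, weight_sd = 150,
                       scale_effect = FALSE,
                       genetic_architecture = c("genomic", "pedigree"),
                       seed = 1L) {
  genetic_architecture <- match.arg(genetic_architecture)
  if (scale_effect) {
    if (is.null(sigma2_a)) sigma2_a <- 0.045
    if (is.null(sigma2_av_exp)) sigma2_av_exp <- 0.09
    if (is.null(r_g_mean_disp)) r_g_mean_disp <- 0
    if (is.null(sigma2_c)) sigma2_c <- 0.013
    if (is.null(sigma2_cv_exp)) sigma2_cv_exp <- 0.01
    if (is.null(sigma2_e)) sigma2_e <- 0.065
    if (is.null(beta_age)) beta_age <- 0.003
    if (is.null(tank_effects)) tank_effects <- c(0, 0.04, -0.04)
    if (is.null(year_class_effects)) year_class_effects <- c(0, 0.05)
  } else {
    if (is.null(sigma2_a)) sigma2_a <- 0.3
    if (is.null(sigma2_av_exp)) sigma2_av_exp <- 0.23
    if (is.null(r_g_mean_disp)) r_g_mean_disp <- 0.95
    if (is.null(sigma2_c)) sigma2_c <- 0.1
    if (is.null(sigma2_cv_exp)) sigma2_cv_exp <- 0.135
    if (is.null(sigma2_e)) sigma2_e <- 0.5
    if (is.null(beta_age)) beta_age <- 0.01
    if (is.null(tank_effects)) tank_effects <- c(0, 0.1, -0.1)
    if (is.null(year_class_effects)) year_class_effects <- c(0, 0.15)
  }
  cfg <- list(n_sires = n_sires, n_dams = n_dams,
              dams_per_sire_range = as.integer(dams_per_sire_range),
              family_size_mean = family_size_mean,
              family_size_range = as.integer(family_size_range),
              n_snps = n_snps, founder_maf_range = founder_maf_range,
              genotyped_families = genotyped_families,
              genotyped_sibs_range = as.integer(genotyped_sibs_range),
              sigma2_a = sigma2_a, sigma2_av_exp = sigma2_av_exp,
              r_g_mean_disp = r_g_mean_disp, sigma2_c = sigma2_c,
              sigma2_cv_exp = sigma2_cv_exp, sigma2_e = sigma2_e,
              mu = mu, beta_age = beta_age, age_window = age_window,
              age_mean = age_mean, tank_effects = tank_effects,
              year_class_effects = year_class_effects,
              weight_mean = weight_mean, weight_sd = weight_sd,
              scale_effect = isTRUE(scale_effect),
              genetic_architecture = genetic_architecture,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  vars <- c("sigma2_a", "sigma2_av_exp", "sigma2_c", "sigma2_cv_exp",
            "sigma2_e")
  for (v in vars) if (cfg[[v]] < 0) stop(v, " must be >= 0")
  if (abs(cfg$r_g_mean_disp) > 1) stop("|r_g_mean_disp| must be <= 1")
  if (cfg$sigma2_av_exp == 0 && cfg$r_g_mean_disp != 0)
    stop("requested genetic covariance implies a non-PSD matrix ",
         "(zero dispersion variance with non-zero correlation)")
  if (cfg$family_size_range[1] < 1) stop("family sizes must be >= 1")
  if (cfg$n_dams < cfg$n_sires * cfg$dams_per_sire_range[1] ||
      cfg$n_dams > cfg$n_sires * cfg$dams_per_sire_range[2])
    stop("infeasible mating design: n_dams incompatible with ",
         "dams_per_sire_range")
  invisible(cfg)
}

#' Simulate a hierarchical mating design pedigree
#'
#' Founder sires and dams, each dam mated to one sire, one full-sib
#' family per dam, family sizes drawn from a truncated negative-binomial
#' matching the configured mean and range.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list: `ped` (a [pedigree()]) and `families` (data.frame
#'   `family`, `sire`, `dam`, `size`).
#' @export
simulate_pedigree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    ns <- config$n_sires; nd <- config$n_dams
    rng <- config$dams_per_sire_range
    d_per_s <- rep(rng[1], ns)
    while (sum(d_per_s) < nd) {
      i <- sample.int(ns, 1)
      if (d_per_s[i] < rng[2]) d_per_s[i] <- d_per_s[i] + 1L
    }
    sire_of_dam <- sample(rep(seq_len(ns), d_per_s))
    sizes <- .family_sizes(nd, config$family_size_mean,
                           config$family_size_range)
    sires <- paste0("S", seq_len(ns))
    dams <- paste0("D", seq_len(nd))
    fam_names <- paste0("F", seq_len(nd))
    off_fam <- rep(seq_len(nd), sizes)
    off_id <- paste0(fam_names[off_fam], "_",
                     unlist(lapply(sizes, seq_len)))
    ped <- pedigree(
      animal = c(sires, dams, off_id),
      sire = c(rep(NA, ns + nd), sires[sire_of_dam][off_fam]),
      dam = c(rep(NA, ns + nd), dams[off_fam]))
    families <- data.frame(family = fam_names,
                           sire = sires[sire_of_dam],
                           dam = dams, size = sizes,
                           stringsAsFactors = FALSE)
    list(ped = ped, families = families)
  })
}

.family_sizes <- function(n, mean_size, range) {
  lo <- range[1]; hi <- range[2]
  mu <- mean_size - lo
  sizes <- lo + stats::rnbinom(n, size = 2.0, mu = mu)
  pmin(sizes, hi)
}

#' Random multi-generation pedigree
#'
#' A deeper pedigree (random mating within generations) used for checking
#' relationship computations against gene-dropping identity-by-descent.
#'
#' @param n_founders founder count (half sires, half dams).
#' @param n_generations generations bred after the founders.
#' @param n_per_generation animals born per generation.
#' @param seed integer seed.
#' @return a [pedigree()].
#' @export
random_pedigree <- function(n_founders = 40, n_generations = 4,
                            n_per_generation = 40, seed = 1) {
  .with_seed(seed, {
    animal <- paste0("G0_", seq_len(n_founders))
    sire <- rep(NA_character_, n_founders)
    dam <- rep(NA_character_, n_founders)
    males <- animal[seq_len(floor(n_founders / 2))]
    females <- setdiff(animal, males)
    for (g in seq_len(n_generations)) {
      ids <- paste0("G", g, "_", seq_len(n_per_generation))
      s <- sample(males, n_per_generation, replace = TRUE)
      d <- sample(females, n_per_generation, replace = TRUE)
      animal <- c(animal, ids)
      sire <- c(sire, s)
      dam <- c(dam, d)
      males <- ids[seq_len(floor(n_per_generation / 2))]
      females <- setdiff(ids, males)
    }
    pedigree(animal, sire, dam)
  })
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions at the given
#' allele frequencies; every descendant inherits one uniformly chosen
#' allele from each parent, independently per locus.
#'
#' @param ped a [pedigree()].
#' @param freqs per-SNP founder frequencies of the allele coded 2 (length
#'   gives the panel size).
#' @param seed integer seed.
#' @return a [genotype_matrix()] over all animals in the pedigree.
#' @export
gene_drop <- function(ped, freqs, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), all(freqs >= 0 & freqs <= 1))
  L <- length(freqs)
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  .with_seed(seed, {
    hap1 <- matrix(0L, n, L)
    hap2 <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      hap1[i, ] <- if (is.na(s))
        as.integer(stats::runif(L) < freqs)
      else {
        si <- pos[s]
        ifelse(stats::runif(L) < 0.5, hap1[si, ], hap2[si, ])
      }
      hap2[i, ] <- if (is.na(d))
        as.integer(stats::runif(L) < freqs)
      else {
        di <- pos[d]
        ifelse(stats::runif(L) < 0.5, hap1[di, ], hap2[di, ])
      }
    }
    genotype_matrix(hap1 + hap2, animal_ids = ped$animal,
                    snp_ids = paste0("snp", seq_len(L)))
  })
}

#' Monte-Carlo identity-by-descent relationship estimate
#'
#' Drops uniquely labeled founder alleles through the pedigree many times
#' and averages allele sharing between every pair of animals; the
#' expectation is the numerator relationship matrix, making this an
#' independent check of the tabular method.
#'
#' @param ped a [pedigree()].
#' @param n_rep replicate gene drops.
#' @param seed integer seed.
#' @return list: `mean` (estimated relationship matrix) and `se` (its
#'   elementwise Monte-Carlo standard errors).
#' @export
ibd_relationship <- function(ped, n_rep = 1e5, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  out <- .with_seed(seed, ibd_genedrop_cpp(si, di, as.integer(n_rep)))
  dimnames(out$mean) <- list(ped$animal, ped$animal)
  dimnames(out$se) <- list(ped$animal, ped$animal)
  out
}

#' Simulate phenotypes with genetically heterogeneous residual variance
#'
#' Breeding-value pairs `(a, a_v)` follow the pedigree (founders from the
#' configured bivariate distribution, descendants as parent average plus
#' Mendelian sampling at half the founder variance); each family carries
#' a common-environment pair `(c, c_v)`; the residual of fish i is drawn
#' with variance `sigma2_e * exp(a_v_i + c_v_i)`. The analysis-scale
#' record is `mu + beta_age * (age - mean age) + tank + year_class + a +
#' c + e`, mapped to grams either affinely or, with `scale_effect`,
#' by exponentiation.
#'
#' @param sim a [simulate_pedigree()] result (pedigree + family table).
#' @param config a [sim_config()].
#' @param genotyped_ids optional character vector marking which animals
#'   carry genotypes (fills the `genotyped` flag).
#' @param genotypes optional [genotype_matrix()] over *all* pedigree
#'   animals (a full [gene_drop()]), used with `founder_freqs` when the
#'   configured genetic architecture is `"genomic"`: per-SNP effect pairs
#'   are drawn with the configured covariance and breeding values are the
#'   centered genotype scores, so marginally `Var(a) = sigma2_a * A` while
#'   realized relationships carry the trait. Without genotypes the
#'   pedigree recursion (parent average + Mendelian sampling at half the
#'   founder variance) is used.
#' @param founder_freqs founder allele frequencies matching `genotypes`.
#' @param seed optional override of `config$seed` (offset internally from
#'   the pedigree stage so the two draws are independent).
#' @return list: `phenotypes` (offspring records: `animal`, `weight`,
#'   `age`, `tank`, `year_class`, `family`, `sire`, `dam`, `genotyped`)
#'   and `truth` (per-animal breeding values, per-family common effects,
#'   per-fish realized residual variance, and the latent analysis-scale
#'   record `y_model`).
#' @export
simulate_phenotypes <- function(sim, config, genotyped_ids = NULL,
                                genotypes = NULL, founder_freqs = NULL,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ped <- sim$ped
  families <- sim$families
  S <- .genetic_cov(config)
  use_genomic <- !is.null(genotypes) &&
    config$genetic_architecture == "genomic"
  if (use_genomic && is.null(founder_freqs))
    stop("genomic architecture needs founder_freqs with the genotypes")
  .with_seed(seed + 1000003L, {
    n <- nrow(ped)
    pos <- seq_len(n)
    names(pos) <- ped$animal
    if (use_genomic) {
      if (!identical(genotypes$animal_ids, ped$animal))
        stop("genomic architecture needs genotypes for every animal ",
             "in pedigree order")
      p <- founder_freqs
      denom <- 2 * sum(p * (1 - p))
      B <- matrix(stats::rnorm(2 * length(p)), ncol = 2) %*%
        .safe_chol(S / denom)
      Xc <- sweep(genotypes$codes, 2, 2 * p, "-")
      bv <- Xc %*% B
    } else {
      bv <- matrix(0, n, 2)
      chol_full <- .safe_chol(S)
      chol_ms <- .safe_chol(S / 2)
      for (i in seq_len(n)) {
        s <- ped$sire[i]; d <- ped$dam[i]
        if (is.na(s) && is.na(d)) {
          bv[i, ] <- stats::rnorm(2) %*% chol_full
        } else {
          pa <- 0.5 * ((if (is.na(s)) c(0, 0) else bv[pos[s], ]) +
                         (if (is.na(d)) c(0, 0) else bv[pos[d], ]))
          bv[i, ] <- pa + stats::rnorm(2) %*% chol_ms
        }
      }
    }
    nf <- nrow(families)
    cm <- stats::rnorm(nf, 0, sqrt(config$sigma2_c))
    cv <- stats::rnorm(nf, 0, sqrt(config$sigma2_cv_exp))
    off <- ped[!is.na(ped$sire) | !is.na(ped$dam), , drop = FALSE]
    fam_of <- match(off$dam, families$dam)
    if (anyNA(fam_of))
      stop("offspring dam not found in family table")
    fam_age <- round(stats::runif(nf, config$age_mean -
                                    config$age_window / 2,
                                  config$age_mean + config$age_window / 2))
    yc_prob <- if (length(config$year_class_effects) == 2)
      c(0.47, 0.53) else NULL
    fam_yc <- sample(seq_along(config$year_class_effects), nf,
                     replace = TRUE, prob = yc_prob)
    n_off <- nrow(off)
    tank <- sample(seq_along(config$tank_effects), n_off, replace = TRUE)
    oi <- pos[off$animal]
    a <- bv[oi, 1]; av <- bv[oi, 2]
    cfam <- cm[fam_of]; cvfam <- cv[fam_of]
    resid_var <- config$sigma2_e * exp(av + cvfam)
    e <- stats::rnorm(n_off, 0, sqrt(resid_var))
    age <- fam_age[fam_of]
    y <- config$mu + config$beta_age * (age - config$age_mean) +
      config$tank_effects[tank] +
      config$year_class_effects[fam_yc[fam_of]] + a + cfam + e
    weight <- if (config$scale_effect)
      exp(y + log(config$weight_mean)) else
        config$weight_mean + config$weight_sd * y
    genotyped <- if (is.null(genotyped_ids)) rep(FALSE, n_off)
                 else off$animal %in% genotyped_ids
    phen <- data.frame(animal = off$animal, weight = weight, age = age,
                       tank = paste0("T", tank),
                       year_class = paste0("YC", fam_yc[fam_of]),
                       family = families$family[fam_of],
                       sire = off$sire, dam = off$dam,
                       genotyped = genotyped,
                       stringsAsFactors = FALSE)
    truth <- list(
      breeding_values = data.frame(animal = ped$animal, a = bv[, 1],
                                   a_v = bv[, 2],
                                   stringsAsFactors = FALSE),
      common_effects = data.frame(family = families$family, c = cm,
                                  c_v = cv, stringsAsFactors = FALSE),
      residual_variance = data.frame(animal = off$animal,
                                     resid_var = resid_var,
                                     y_model = y,
                                     stringsAsFactors = FALSE))
    list(phenotypes = phen, truth = truth)
  })
}

.genetic_cov <- function(config) {
  cov_a <- config$r_g_mean_disp *
    sqrt(config$sigma2_a * config$sigma2_av_exp)
  matrix(c(config$sigma2_a, cov_a, cov_a, config$sigma2_av_exp), 2, 2)
}

.safe_chol <- function(S) {
  d <- diag(S)
  if (all(d == 0)) return(matrix(0, 2, 2))
  if (any(d == 0)) {
    out <- matrix(0, 2, 2)
    out[d > 0, d > 0] <- sqrt(S[d > 0, d > 0])
    return(out)
  }
  chol(S)
}

#' Select the genotyped subset of a simulated design
#'
#' A configurable number of families contributes a window of genotyped
#' sibs; all sires and dams are genotyped, emulating reference designs
#' where parents anchor the genomic relationships.
#'
#' @param sim a [simulate_pedigree()] result.
#' @param config a [sim_config()].
#' @param seed optional override.
#' @return character vector of genotyped animal ids.
#' @export
select_genotyped <- function(sim, config, seed = config$seed) {
  .with_seed(seed + 2000003L, {
    families <- sim$families
    ped <- sim$ped
    ng <- min(config$genotyped_families, nrow(families))
    gf <- sample(families$family, ng)
    rng <- config$genotyped_sibs_range
    chosen <- character(0)
    for (f in gf) {
      dam <- families$dam[families$family == f]
      sibs <- ped$animal[!is.na(ped$dam) & ped$dam == dam]
      k <- min(length(sibs), sample(seq(rng[1], rng[2]), 1))
      chosen <- c(chosen, sample(sibs, k))
    }
    parents <- ped$animal[is.na(ped$sire) & is.na(ped$dam)]
    c(parents, chosen)
  })
}

#' Simulate a complete dataset
#'
#' Pedigree, gene-dropped genotypes restricted to the genotyped subset,
#' phenotypes and ground truth, in one call.
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_dataset"`: `ped`, `families`, `genotypes`
#'   (a [genotype_matrix()] over the genotyped animals), `phenotypes`,
#'   `truth`, `founder_freqs`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_pedigree(config)
  freqs <- .with_seed(config$seed + 3000003L,
                      stats::runif(config$n_snps,
                                   config$founder_maf_range[1],
                                   config$founder_maf_range[2]))
  geno_all <- gene_drop(sim$ped, freqs, seed = config$seed + 4000003L)
  gids <- select_genotyped(sim, config)
  geno <- genotype_matrix(geno_all$codes[gids, , drop = FALSE])
  phe <- simulate_phenotypes(sim, config, genotyped_ids = gids,
                             genotypes = geno_all,
                             founder_freqs = freqs)
  structure(list(ped = sim$ped, families = sim$families,
                 genotypes = geno, phenotypes = phe$phenotypes,
                 truth = phe$truth, founder_freqs = freqs,
                 config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `pedigree.csv`, `genotypes.csv`, `phenotypes.csv`,
#' `truth_breeding_values.csv`, `truth_common_effects.csv`,
#' `truth_residual_variance.csv` and `config.yaml`; byte-stable for a
#' given config.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE))
    stop("cannot create directory ", directory)
  write_pedigree(dataset$ped, file.path(directory, "pedigree.csv"))
  write_genotypes(dataset$genotypes,
                  file.path(directory, "genotypes.csv"))
  utils::write.csv(dataset$phenotypes,
                   file.path(directory, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$truth$breeding_values,
                   file.path(directory, "truth_breeding_values.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$truth$common_effects,
                   file.path(directory, "truth_common_effects.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$truth$residual_variance,
                   file.path(directory, "truth_residual_variance.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(dataset$config),
                   file.path(directory, "config.yaml"))
  invisible(directory)
}

#' Read a fixture directory back
#'
#' @param directory a directory written by [write_fixture()].
#' @return list with `ped`, `genotypes`, `phenotypes`, `truth`, `config`.
#' @export
read_fixture <- function(directory) {
  cfg <- yaml::read_yaml(file.path(directory, "config.yaml"))
  phen <- utils::read.csv(file.path(directory, "phenotypes.csv"),
                          stringsAsFactors = FALSE)
  phen$tank <- as.character(phen$tank)
  phen$year_class <- as.character(phen$year_class)
  list(ped = read_pedigree(file.path(directory, "pedigree.csv"),
                           reorder = FALSE),
       genotypes = read_genotypes(file.path(directory, "genotypes.csv")),
       phenotypes = phen,
       truth = list(
         breeding_values = utils::read.csv(
           file.path(directory, "truth_breeding_values.csv")),
         common_effects = utils::read.csv(
           file.path(directory, "truth_common_effects.csv")),
         residual_variance = utils::read.csv(
           file.path(directory, "truth_residual_variance.csv"))),
       config = do.call(sim_config, cfg))
}
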