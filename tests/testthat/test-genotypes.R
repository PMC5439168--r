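test_that("allele frequencies are the dosage mean over non-missing calls", {
  g <- genotype_matrix(rbind(c(0, 2, 2), c(1, 2, NA), c(2, 2, 0)),
                       animal_ids = c("a", "b", "c"),
                       snp_ids = c("s1", "s2", "s3"))
  p <- allele_frequencies(g)
  expect_equal(unname(p), c(0.5, 1.0, 0.5))
})

test_that("frequencies of a seeded column with missing entries match a hand tally", {
  set.seed(33)
  col <- sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                prob = c(0.3, 0.4, 0.2, 0.1))
  g <- genotype_matrix(matrix(col, ncol = 1))
  tally <- sum(col, na.rm = TRUE) / (2 * sum(!is.na(col)))
  expect_equal(unname(allele_frequencies(g)), tally)
})

test_that("a SNP with no calls is an error naming it", {
  g <- genotype_matrix(matrix(c(1L, 1L, NA, NA), 2),
                       snp_ids = c("ok", "empty"))
  expect_error(allele_frequencies(g), "empty")
})

test_that("QC removes planted violations at the right stage", {
  set.seed(5)
  n <- 200
  clean <- function() rbinom(n, 2, 0.4)
  codes <- cbind(
    good1 = clean(), good2 = clean(),
    lowcall = replace(clean(), sample(n, 0.5 * n), NA), # call rate 50%
    hwe_bad = rep(c(0L, 2L), n / 2),                    # no heterozygotes
    rare = c(1L, rep(0L, n - 1)),                       # MAF = 0.0025
    mono = rep(0L, n))                                  # MAF = 0
  g <- genotype_matrix(codes)
  out <- qc_snps(g)
  expect_equal(out$report$n_removed_callrate, 1)
  expect_equal(out$report$n_removed_hwe, 1)
  expect_equal(out$report$n_removed_maf, 2)
  expect_setequal(out$report$surviving_snp_ids, c("good1", "good2"))
  expect_equal(out$report$n_input,
               out$report$n_removed_callrate + out$report$n_removed_hwe +
                 out$report$n_removed_maf +
                 length(out$report$surviving_snp_ids))
  # idempotence: a second pass removes nothing
  out2 <- qc_snps(out$genotypes)
  expect_equal(out2$report$surviving_snp_ids,
               out$report$surviving_snp_ids)
})

test_that("an all-removed panel warns rather than failing silently", {
  g <- genotype_matrix(matrix(0L, 10, 2))
  expect_warning(qc_snps(g), "empty panel")
})

test_that("genotype scaling follows the VanRaden standardization", {
  g <- genotype_matrix(matrix(c(1L, 2L, 0L), 1), snp_ids = c("a", "b", "c"))
  sc <- scale_genotypes(g, freqs = c(0.5, 0.5, 0.1))
  expect_equal(unname(sc$values[1, ]),
               c(0, 1 / sqrt(0.5), -0.2 / sqrt(0.18)),
               tolerance = 1e-12)
})

test_that("fixed SNPs direct the user to QC", {
  g <- genotype_matrix(matrix(c(0L, 0L), 2))
  expect_error(scale_genotypes(g, freqs = 0), "qc_snps")
})

test_that("scaled columns have mean ~0 and G rows sum to ~0 with own frequencies", {
  ds <- small_dataset(seed = 12, n_snps = 150)
  sc <- scale_genotypes(qc_snps(ds$genotypes)$genotypes)
  expect_lt(max(abs(colMeans(sc$values))), 1e-8)
  G <- build_genomic_relationship(sc)
  expect_lt(max(abs(rowSums(as.matrix(G$values)))), 1e-8)
})

test_that("missing codes are imputed at the column mean (scaled zero)", {
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 4))
  sc <- scale_genotypes(g, freqs = 0.5)
  expect_equal(sc$values[4, 1], 0)
})

test_that("G has mean diagonal near 1 under Hardy-Weinberg sampling", {
  set.seed(99)
  n <- 1000; L <- 2000
  p <- runif(L, 0.1, 0.9)
  codes <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  G <- build_genomic_relationship(scale_genotypes(genotype_matrix(codes)))
  expect_lt(abs(mean(diag(as.matrix(G$values))) - 1), 0.02)
})

test_that("single animal, single heterozygous SNP gives G = 0", {
  g <- genotype_matrix(matrix(1L, 1, 1))
  G <- build_genomic_relationship(scale_genotypes(g, freqs = 0.5))
  expect_equal(as.numeric(G$values), 0)
})

test_that("genotypes round-trip through CSV and PLINK text formats", {
  ds <- small_dataset(seed = 3, n_snps = 20)
  gen <- ds$genotypes
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gen, path)
  back <- read_genotypes(path)
  expect_equal(back$codes, gen$codes)
  # minimal .ped/.map pair
  dir <- withr::local_tempdir()
  map <- file.path(dir, "toy.map")
  pedf <- file.path(dir, "toy.ped")
  writeLines(c("1 s1 0 1", "1 s2 0 2"), map)
  writeLines(c("F1 ind1 0 0 1 -9 A A A G",
               "F1 ind2 0 0 2 -9 A G G G",
               "F1 ind3 0 0 1 -9 0 0 G G"), pedf)
  g <- read_genotypes(pedf)
  expect_equal(unname(g$codes[, "s1"]), c(0L, 1L, NA))
  expect_equal(unname(g$codes[, "s2"]), c(1L, 2L, 2L))
})
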