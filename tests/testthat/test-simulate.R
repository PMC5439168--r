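test_that("the mating design has the configured structure", {
  cfg <- sim_config(n_sires = 2, n_dams = 2,
                    dams_per_sire_range = c(1, 1),
                    family_size_mean = 3, family_size_range = c(3, 3),
                    seed = 1)
  sim <- simulate_pedigree(cfg)
  off <- sim$ped[!is.na(sim$ped$sire), ]
  expect_equal(nrow(off), 6)                      # 2 families x 3
  expect_equal(sort(unique(off$sire)), c("S1", "S2"))
  expect_equal(sort(as.integer(table(off$dam))), c(3L, 3L))
  # determinism
  sim2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(sim$ped), as.data.frame(sim2$ped))
})

test_that("family sizes track the configured mean across seeds", {
  means <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s)
    mean(simulate_pedigree(cfg)$families$size)
  }, numeric(1))
  expect_lt(abs(mean(means) - 15.4) / 15.4, 0.10)
  cfg <- sim_config(seed = 1)
  sizes <- simulate_pedigree(cfg)$families$size
  expect_true(all(sizes >= 4 & sizes <= 54))
})

test_that("infeasible mating ratios are rejected", {
  expect_error(sim_config(n_sires = 10, n_dams = 50,
                          dams_per_sire_range = c(1, 3)),
               "infeasible")
})

test_that("gene dropping is Mendelian-consistent and seed-stable", {
  cfg <- sim_config(n_sires = 6, n_dams = 10, family_size_mean = 6,
                    family_size_range = c(4, 8), seed = 2)
  sim <- simulate_pedigree(cfg)
  freqs <- runif(60, 0.2, 0.8)
  g1 <- gene_drop(sim$ped, freqs, seed = 5)
  g2 <- gene_drop(sim$ped, freqs, seed = 5)
  expect_identical(g1$codes, g2$codes)
  g3 <- gene_drop(sim$ped, freqs, seed = 6)
  expect_false(identical(g1$codes, g3$codes))
  # offspring dosage compatible with parents at every locus:
  # a parent with code 0 cannot transmit the alternative allele, so
  # offspring of two code-0 parents are 0, etc.
  ped <- sim$ped
  pos <- setNames(seq_len(nrow(ped)), ped$animal)
  for (i in which(!is.na(ped$sire))) {
    s <- g1$codes[pos[ped$sire[i]], ]
    d <- g1$codes[pos[ped$dam[i]], ]
    o <- g1$codes[i, ]
    lo <- (s == 2) + (d == 2)
    hi <- 2 - ((s == 0) + (d == 0))
    expect_true(all(o >= lo & o <= hi))
  }
  # all-homozygous founders propagate unchanged
  gfix <- gene_drop(sim$ped, rep(1, 5), seed = 1)
  expect_true(all(gfix$codes == 2L))
})

test_that("gene-dropped genomic relationships track pedigree expectation", {
  cfg <- sim_config(n_sires = 4, n_dams = 8, family_size_mean = 10,
                    family_size_range = c(10, 10), seed = 9)
  sim <- simulate_pedigree(cfg)
  founder_freqs <- runif(5000, 0.2, 0.8)
  g <- gene_drop(sim$ped, founder_freqs, seed = 3)
  A <- relationship_matrix(sim$ped)$values
  # scale with the founder (base-population) frequencies so G estimates
  # identity-by-descent on the same base as A
  W <- scale_genotypes(g, freqs = founder_freqs)
  G <- as.matrix(build_genomic_relationship(W)$values)
  # compare G and A22 over full-sib pairs after removing the panel-mean
  # shift (G is centered on the current set, A on the founders)
  off <- sim$ped$animal[!is.na(sim$ped$sire)]
  fams <- sim$families
  devs <- c()
  for (f in seq_len(nrow(fams))) {
    sibs <- sim$ped$animal[!is.na(sim$ped$dam) &
                             sim$ped$dam == fams$dam[f]]
    prs <- t(combn(sibs, 2))
    devs <- c(devs, G[prs] - A[prs])
  }
  expect_lt(abs(mean(devs)), 0.05)
})

test_that("phenotype simulation honors its variance configuration", {
  cfg <- sim_config(n_sires = 60, n_dams = 110, family_size_mean = 12,
                    family_size_range = c(8, 16), n_snps = 2,
                    genotyped_families = 0, seed = 17)
  sim <- simulate_pedigree(cfg)
  phe <- simulate_phenotypes(sim, cfg)
  tv <- phe$truth$breeding_values
  founders <- sim$ped$animal[is.na(sim$ped$sire)]
  af <- tv$a[match(founders, tv$animal)]
  se <- sqrt(2) * cfg$sigma2_a / sqrt(length(af) - 1)
  expect_lt(abs(var(af) - cfg$sigma2_a), 3 * se)
  # dispersion-null config gives constant residual variance
  cfg0 <- sim_config(n_sires = 6, n_dams = 10, family_size_mean = 6,
                     family_size_range = c(4, 8), sigma2_av_exp = 0,
                     r_g_mean_disp = 0, sigma2_cv_exp = 0, seed = 3)
  sim0 <- simulate_pedigree(cfg0)
  phe0 <- simulate_phenotypes(sim0, cfg0)
  expect_equal(unique(phe0$truth$residual_variance$resid_var),
               cfg0$sigma2_e)
})

test_that("a non-PSD genetic covariance request is rejected", {
  expect_error(sim_config(sigma2_av_exp = 0, r_g_mean_disp = 0.9),
               "non-PSD")
})

test_that("genomic architecture ties breeding values to the markers", {
  cfg <- sim_config(n_sires = 8, n_dams = 14, family_size_mean = 8,
                    family_size_range = c(6, 10), n_snps = 400,
                    genotyped_families = 14,
                    genotyped_sibs_range = c(6, 10), seed = 25)
  ds <- simulate_dataset(cfg)
  tv <- ds$truth$breeding_values
  founders <- ds$ped$animal[is.na(ds$ped$sire)]
  af <- tv$a[match(founders, tv$animal)]
  expect_lt(abs(var(af) - cfg$sigma2_a) / cfg$sigma2_a, 0.6)
  # genotyped animals' BV are an exact linear function of their genotypes,
  # so sibs with more similar genotypes have more similar BV
  expect_true(all(ds$genotypes$animal_ids %in% tv$animal))
})

test_that("fixtures round-trip through plain-text files", {
  ds <- small_dataset(seed = 5, n_snps = 15)
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  back <- read_fixture(dir)
  expect_equal(as.data.frame(back$ped), as.data.frame(ds$ped))
  expect_equal(back$genotypes$codes, ds$genotypes$codes)
  expect_equal(back$phenotypes$weight, ds$phenotypes$weight,
               tolerance = 1e-12)
  expect_equal(back$config$sigma2_av_exp, ds$config$sigma2_av_exp)
  # byte stability for a fixed config
  dir2 <- withr::local_tempdir()
  write_fixture(simulate_dataset(ds$config), dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # a different seed changes the data but not the schema
  cfg2 <- sim_config(n_sires = 12, n_dams = 20, family_size_mean = 10,
                     family_size_range = c(4, 20), n_snps = 15,
                     genotyped_families = 10,
                     genotyped_sibs_range = c(4, 8), seed = 6)
  ds2 <- simulate_dataset(cfg2)
  expect_false(identical(ds2$phenotypes$weight, ds$phenotypes$weight))
  expect_identical(names(ds2$phenotypes), names(ds$phenotypes))
})
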