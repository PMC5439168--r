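test_that("the dispersion working response follows its defining formula", {
  expect_equal(compute_dispersion_response(1, 0, 1), 0)
  expect_equal(compute_dispersion_response(0, 0, 1), -1)
  expect_equal(compute_dispersion_response(2, 0.5, 1), 7)
  expect_error(compute_dispersion_response(1, 1, 1), "leverage")
  expect_error(compute_dispersion_response(1, 0, 0), "positive")
})

test_that("a sire-dam DHGLM fit returns a coherent object", {
  ds <- small_dataset(seed = 7, n_snps = 20)
  ph <- with_std_response(ds)
  spec <- model_spec("sire_dam", "A")
  ev <- evaluation_inverse(ds$ped, spec)
  fit <- fit_dhglm(ph, ds$ped, spec, ev$Kinv,
                   control = dhglm_control(max_iter = 40))
  expect_s3_class(fit, "dhglm_fit")
  expect_true(all(fit$hat >= 0 & fit$hat < 1))
  expect_true(all(fit$fitted_resid_var > 0))
  vc <- fit$varcomps
  expect_gte(vc$sigma2_a, 0)
  expect_gte(vc$sigma2_av_exp, 0)
  expect_lte(abs(vc$sigma_a_av_exp),
             sqrt(vc$sigma2_a * vc$sigma2_av_exp) + 1e-10)
  # scaled residual variances sit near their expectation of 1
  expect_true(all(vc$scaled_eps > 0.8 & vc$scaled_eps < 1.2))
  # adjusted phenotypes reconstruct the response
  adj <- adjusted_phenotypes(fit)
  expect_lt(max(abs(adj$y_star + fit$fitted_fixed_y - ph$y)), 1e-8)
  # and equal the hand-assembled sum of solution vectors
  ns <- asNamespace("ssDHGLM")
  dat <- ns$.assemble_model_data(ph, ds$ped, spec, ev$Kinv)
  Zu <- as.numeric(dat$Zg %*% fit$ebv_mean)
  Qc <- as.numeric(dat$Q %*% fit$common_mean)
  expect_lt(max(abs(adj$y_star - (Zu + Qc + fit$residuals))), 1e-8)
})

test_that("homoscedastic data reduce the DHGLM to the plain REML mean fit", {
  # every sire serves two dams so the sire half-sib covariance separates
  # the genetic variance from the per-family common environment
  cfg <- sim_config(n_sires = 40, n_dams = 80,
                    dams_per_sire_range = c(2, 2),
                    family_size_mean = 12,
                    family_size_range = c(10, 14), n_snps = 2,
                    genotyped_families = 0, sigma2_av_exp = 0,
                    r_g_mean_disp = 0, sigma2_cv_exp = 0, seed = 15)
  sim <- simulate_pedigree(cfg)
  phe <- simulate_phenotypes(sim, cfg)
  ph <- phe$phenotypes
  ph$y <- standardize(ph$weight)$values
  spec <- model_spec("sire_dam", "A")
  ev <- evaluation_inverse(sim$ped, spec)
  uni <- fit_mean_model(ph, sim$ped, spec, ev$Kinv,
                        control = dhglm_control(tol = 1e-10,
                                                comp_tol = 1e-8,
                                                max_iter = 500))
  # seeded at the univariate optimum the reduced bivariate EM must stay
  # there: the mean-model components are a fixed point
  fit <- fit_dhglm(ph, sim$ped, spec, ev$Kinv,
                   control = dhglm_control(max_iter = 60),
                   init = uni, dispersion_random = FALSE)
  expect_lt(abs(fit$varcomps$sigma2_u - uni$sigma2_u) /
              max(uni$sigma2_u, 1e-8), 0.01)
  expect_lt(abs(fit$varcomps$sigma2_c - uni$sigma2_c) /
              max(uni$sigma2_c, 1e-8), 0.01)
  expect_lt(abs(fit$varcomps$sigma2_e - uni$sigma2_e) /
              uni$sigma2_e, 0.01)
})

test_that("an unrelated, unphenotyped animal has EBV 0; twins match; parent average holds", {
  # pedigree: two phenotyped parents, their unphenotyped offspring, and an
  # unrelated singleton; plus a second family providing contrast
  ped <- pedigree(
    c("S1", "D1", "S2", "D2", "loner", "K1", "K2", "O", "P1", "P2"),
    c(NA, NA, NA, NA, NA, "S1", "S1", "S1", "S2", "S2"),
    c(NA, NA, NA, NA, NA, "D1", "D1", "D1", "D2", "D2"))
  set.seed(42)
  phen <- data.frame(
    animal = c("S1", "D1", "S2", "D2", "K1", "K2", "P1", "P2"),
    y = c(1.2, 0.8, -0.5, -0.9, 1.0, 1.4, -0.8, -1.2),
    age = c(100, 104, 98, 96, 101, 101, 99, 102),
    tank = "T1", year_class = "Y1",
    family = c("fS1", "fD1", "fS2", "fD2", "f1", "f1", "f2", "f2"))
  spec <- model_spec("animal", "A", include_common_env = FALSE)
  ev <- evaluation_inverse(ped, spec)
  vc <- structure(list(sigma2_u = 0.075, sigma2_a = 0.3,
                       sigma2_av_exp = 0.1, sigma_a_av_exp = 0,
                       sigma2_c = 0, sigma2_cv_exp = 0,
                       sigma_c_cv_exp = 0, sigma2_e = 0.7,
                       scaled_eps = c(y = 1, psi = 1),
                       genetic_param = "animal"),
                  class = "dhglm_varcomps")
  pred <- predict_breeding_values(phen, ped, spec, ev$Kinv, vc)
  ebv <- setNames(pred$ebv_mean, names(pred$ebv_mean))
  expect_equal(unname(ebv["loner"]), 0)
  # non-phenotyped full sib of phenotyped sibs: parent-average identity
  expect_equal(unname(ebv["O"]),
               unname((ebv["S1"] + ebv["D1"]) / 2), tolerance = 1e-8)
  # identical information: K1 and K2 swapped responses give swapped EBV,
  # and with equal records their EBV would be equal
  phen2 <- phen
  phen2$y[phen2$animal %in% c("K1", "K2")] <- 1.2
  pred2 <- predict_breeding_values(phen2, ped, spec, ev$Kinv, vc)
  expect_equal(unname(pred2$ebv_mean["K1"]),
               unname(pred2$ebv_mean["K2"]), tolerance = 1e-10)
})

test_that("duplicated genotype rows under H give equal GEBV", {
  ds <- small_dataset(seed = 23, n_snps = 120)
  ph <- with_std_response(ds)
  # make two genotyped full sibs marker-identical and mask both
  gen <- ds$genotypes
  fam <- ph$family[ph$genotyped][1]
  sibs <- ph$animal[ph$family == fam & ph$genotyped][1:2]
  gen$codes[sibs[2], ] <- gen$codes[sibs[1], ]
  G <- build_genomic_relationship(scale_genotypes(qc_snps(gen)$genotypes))
  spec <- model_spec("animal", "H")
  ev <- evaluation_inverse(ds$ped, spec, G = G, genotyped_ids = G$ids)
  vc <- structure(list(sigma2_u = 0.075, sigma2_a = 0.3,
                       sigma2_av_exp = 0.15, sigma_a_av_exp = 0.1,
                       sigma2_c = 0.08, sigma2_cv_exp = 0.1,
                       sigma_c_cv_exp = 0, sigma2_e = 0.6,
                       scaled_eps = c(y = 1, psi = 1),
                       genetic_param = "animal"),
                  class = "dhglm_varcomps")
  pred <- predict_breeding_values(ph, ds$ped, spec, ev$Kinv, vc,
                                  mask = sibs)
  expect_lt(abs(pred$ebv_mean[sibs[1]] - pred$ebv_mean[sibs[2]]), 1e-6)
  expect_lt(abs(pred$ebv_disp[sibs[1]] - pred$ebv_disp[sibs[2]]), 1e-6)
})

test_that("sire-dam and animal parameterizations agree on the mean trait", {
  cfg <- sim_config(n_sires = 30, n_dams = 55, family_size_mean = 14,
                    family_size_range = c(10, 18), n_snps = 2,
                    genotyped_families = 0, sigma2_av_exp = 0,
                    r_g_mean_disp = 0, sigma2_cv_exp = 0, seed = 29)
  sim <- simulate_pedigree(cfg)
  phe <- simulate_phenotypes(sim, cfg)
  ph <- phe$phenotypes
  ph$y <- standardize(ph$weight)$values
  ctrl <- dhglm_control(tol = 1e-8, max_iter = 300)
  sd_fit <- fit_mean_model(ph, sim$ped,
                           model_spec("sire_dam", "A"),
                           evaluation_inverse(sim$ped,
                                              model_spec("sire_dam", "A"))$Kinv,
                           control = ctrl)
  an_fit <- fit_mean_model(ph, sim$ped,
                           model_spec("animal", "A"),
                           evaluation_inverse(sim$ped,
                                              model_spec("animal", "A"))$Kinv,
                           control = ctrl)
  s2a_sd <- 4 * sd_fit$sigma2_u
  s2a_an <- an_fit$sigma2_u
  # agreement within a rough 2-SE band for this design (~35% relative)
  expect_lt(abs(s2a_sd - s2a_an) / max(s2a_an, 1e-8), 0.35)
})

test_that("masking a whole fixed-effect level drops it with a warning", {
  ds <- small_dataset(seed = 7, n_snps = 10)
  ph <- with_std_response(ds)
  ph$tank[1:3] <- "Tsolo"
  ph$tank[-(1:3)] <- "T1"
  spec <- model_spec("sire_dam", "A")
  ev <- evaluation_inverse(ds$ped, spec)
  vc <- structure(list(sigma2_u = 0.075, sigma2_a = 0.3,
                       sigma2_av_exp = 0.1, sigma_a_av_exp = 0,
                       sigma2_c = 0.05, sigma2_cv_exp = 0.05,
                       sigma_c_cv_exp = 0, sigma2_e = 0.6,
                       scaled_eps = c(y = 1, psi = 1),
                       genetic_param = "sire_dam"),
                  class = "dhglm_varcomps")
  expect_warning(
    predict_breeding_values(ph, ds$ped, spec, ev$Kinv, vc,
                            mask = ph$animal[2:3]),
    "merged")
})

test_that("adding a phenotyped genotyped full sib never lowers reliability", {
  # prediction-error variance of a candidate's GEBV from the inverted
  # coefficient matrix, with k phenotyped sibs included
  ds <- small_dataset(seed = 31, n_snps = 150)
  ph <- with_std_response(ds)
  gen_fams <- unique(ph$family[ph$genotyped])
  fam <- gen_fams[which.max(tabulate(match(
    ph$family[ph$genotyped], gen_fams)))]
  sibs <- ph$animal[ph$family == fam & ph$genotyped]
  skip_if(length(sibs) < 4)
  candidate <- sibs[1]
  G <- build_genomic_relationship(
    scale_genotypes(qc_snps(ds$genotypes)$genotypes))
  spec <- model_spec("animal", "H")
  ev <- evaluation_inverse(ds$ped, spec, G = G, genotyped_ids = G$ids)
  ns <- asNamespace("ssDHGLM")
  pev_for <- function(mask) {
    keep <- !(ph$animal %in% mask)
    dat <- ns$.assemble_model_data(ph[keep, ], ds$ped, spec, ev$Kinv)
    traits <- list(list(y = dat$y, X = dat$X, w = rep(1, length(dat$y))))
    des <- ns$.mme_design(traits, dat$Zg, dat$Q)
    sol <- ns$.mme_solve(des, traits, dat$Kinv, matrix(0.3, 1, 1),
                         matrix(0.08, 1, 1), 0.6, dense_C = TRUE)
    j <- des$idx$u[[1]][match(candidate, dat$genetic_ids)]
    sol$C[j, j]
  }
  drop_sets <- lapply(0:3, function(k) c(candidate, sibs[-1][seq_len(k)]))
  pev <- vapply(rev(drop_sets), pev_for, numeric(1))
  # rev(): fewest sibs first; PEV must not increase as sibs are added
  expect_true(all(diff(pev) < 1e-10))
})
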