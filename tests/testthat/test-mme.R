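test_that("intercept-only weighted model gives the weighted mean and leverages", {
  set.seed(1)
  y <- rnorm(12)
  w <- runif(12, 0.5, 2)
  fit <- solve_mixed_model(y, X = matrix(1, 12, 1), sigma2_e = 1,
                           weights = w)
  expect_equal(fit$fixed, sum(w * y) / sum(w))
  expect_equal(fit$hat, w / sum(w))
})

test_that("random solutions shrink monotonically as the variance ratio grows", {
  set.seed(2)
  n <- 24; q <- 6
  grp <- rep(1:q, each = n / q)
  Z <- outer(grp, 1:q, "==") * 1
  y <- rnorm(n, rep(rnorm(q), each = n / q))
  norms <- vapply(c(1, 0.3, 0.1, 0.03), function(s2u) {
    fit <- solve_mixed_model(y, matrix(1, n, 1), Zg = Z,
                             Kinv = diag(q), sigma2_u = s2u,
                             sigma2_e = 1)
    sqrt(sum(fit$genetic^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("MME solutions equal dense GLS with genetic and common effects", {
  set.seed(3)
  ds <- small_dataset(seed = 19, n_snps = 10)
  ph <- with_std_response(ds)
  ph <- ph[1:30, ]                     # small instance, dense oracle
  spec <- model_spec("sire_dam", "A")
  ev <- evaluation_inverse(ds$ped, spec)
  ns <- asNamespace("ssDHGLM")
  dat <- ns$.assemble_model_data(ph, ds$ped, spec, ev$Kinv)
  K <- solve(as.matrix(dat$Kinv))
  w <- runif(30, 0.5, 2)
  fit <- solve_mixed_model(dat$y, dat$X, Zg = dat$Zg, Q = dat$Q,
                           Kinv = dat$Kinv, sigma2_u = 0.08,
                           sigma2_c = 0.05, sigma2_e = 0.7,
                           weights = w)
  oracle <- dense_gls(dat$y, dat$X, as.matrix(dat$Zg), K, 0.08,
                      as.matrix(dat$Q), 0.05, 0.7, w)
  expect_equal(fit$fixed, oracle$fixed, tolerance = 1e-8)
  expect_equal(fit$genetic, oracle$genetic, tolerance = 1e-8)
  expect_equal(fit$common, oracle$common, tolerance = 1e-8)
  expect_true(all(fit$hat >= 0 & fit$hat < 1))
})

test_that("confounded fixed effects raise the singularity error", {
  y <- rnorm(10)
  X <- cbind(1, c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  expect_error(solve_mixed_model(y, X), "confounded")
})

test_that("one EM-REML step is a fixed point at the balanced-ANOVA REML optimum", {
  set.seed(11)
  q <- 30; m <- 12
  s_true <- rnorm(q, 0, sqrt(0.4))
  y <- rep(s_true, each = m) + rnorm(q * m, 0, 1)
  grp <- rep(1:q, each = m)
  Z <- outer(grp, 1:q, "==") * 1
  X <- matrix(1, q * m, 1)
  # closed-form REML for the balanced one-way layout
  ybar <- tapply(y, grp, mean)
  msb <- m * sum((ybar - mean(y))^2) / (q - 1)
  msw <- sum((y - ybar[grp])^2) / (q * (m - 1))
  s2e_hat <- msw
  s2u_hat <- (msb - msw) / m
  up <- reml_update(y, X, Zg = Z, Kinv = diag(q),
                    varcomps = list(sigma2_u = s2u_hat,
                                    sigma2_e = s2e_hat))
  expect_lt(abs(up$sigma2_u - s2u_hat) / s2u_hat, 1e-3)
  expect_lt(abs(up$sigma2_e - s2e_hat) / s2e_hat, 1e-3)
})

test_that("iterated EM-REML converges to the balanced sire-model closed form", {
  set.seed(12)
  q <- 50; m <- 20
  s_true <- rnorm(q, 0, sqrt(0.25))
  y <- 3 + rep(s_true, each = m) + rnorm(q * m, 0, 1)
  grp <- rep(1:q, each = m)
  Z <- outer(grp, 1:q, "==") * 1
  X <- matrix(1, q * m, 1)
  ybar <- tapply(y, grp, mean)
  msb <- m * sum((ybar - mean(y))^2) / (q - 1)
  msw <- sum((y - ybar[grp])^2) / (q * (m - 1))
  oracle <- c(u = (msb - msw) / m, e = msw)
  vc <- list(sigma2_u = 0.5, sigma2_e = 0.5)
  ll_prev <- -Inf
  for (i in 1:500) {
    up <- reml_update(y, X, Zg = Z, Kinv = diag(q), varcomps = vc)
    expect_gte(up$loglik, ll_prev - 1e-6)   # monotone within tolerance
    ll_prev <- up$loglik
    done <- abs(up$sigma2_u - vc$sigma2_u) < 1e-10
    vc <- list(sigma2_u = up$sigma2_u, sigma2_e = up$sigma2_e)
    if (done) break
  }
  expect_lt(abs(vc$sigma2_u - oracle["u"]), 1e-4)
  expect_lt(abs(vc$sigma2_e - oracle["e"]), 1e-4)
})

test_that("with a zero-variance truth the estimate tracks the (near-boundary) closed form", {
  set.seed(13)
  q <- 20; m <- 10
  y <- rnorm(q * m)                       # no group effect at all
  grp <- rep(1:q, each = m)
  Z <- outer(grp, 1:q, "==") * 1
  ybar <- tapply(y, grp, mean)
  msb <- m * sum((ybar - mean(y))^2) / (q - 1)
  msw <- sum((y - ybar[grp])^2) / (q * (m - 1))
  closed <- max(0, (msb - msw) / m)       # boundary-truncated REML
  vc <- list(sigma2_u = 0.2, sigma2_e = 1)
  track <- numeric(0)
  for (i in 1:3000) {
    up <- reml_update(y, matrix(1, q * m, 1), Zg = Z, Kinv = diag(q),
                      varcomps = vc)
    vc <- list(sigma2_u = up$sigma2_u, sigma2_e = up$sigma2_e)
    track <- c(track, vc$sigma2_u)
  }
  # EM descends monotonically toward the (sampling-noise-sized) optimum
  expect_true(all(diff(track) <= 1e-12))
  expect_lt(abs(vc$sigma2_u - closed), 1e-3)
  expect_lt(vc$sigma2_u, 0.1)
})
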