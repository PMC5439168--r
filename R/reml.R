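# EM-REML updates on the mixed-model equations.
#
# For random block j,k of the genetic (co)variance matrix Su (priors
# Su (x) K) the expectation step gives
#   Su[j,k] <- (u_j' Kinv u_k + tr(Kinv C_jk)) / q,
# with C_jk the corresponding block of the inverse coefficient matrix;
# common-environment blocks use the identity in place of Kinv. Residual
# scales use the classic form (y'W y - theta'X'Wy-type quadratic) / (n - p).

.tr_prod <- function(Kinv, Cblk) {
  if (methods::is(Kinv, "sparseMatrix")) {
    Ks <- methods::as(methods::as(Kinv, "generalMatrix"), "TsparseMatrix")
    sum(Ks@x * Cblk[cbind(Ks@i + 1L, Ks@j + 1L)])
  } else {
    sum(Kinv * Cblk)
  }
}

.em_step <- function(sol, traits, Kinv, Su, Sc, s2_eps,
                     floor = 1e-8, max_corr = 0.999) {
  des <- sol$des
  m <- des$m
  q <- des$q
  theta <- sol$theta
  C <- sol$C
  Su_new <- matrix(0, m, m)
  for (j in seq_len(m)) for (k in j:m) {
    uj <- theta[des$idx$u[[j]]]
    uk <- theta[des$idx$u[[k]]]
    val <- (sum(uj * as.numeric(Kinv %*% uk)) +
              .tr_prod(Kinv, C[des$idx$u[[j]], des$idx$u[[k]],
                               drop = FALSE])) / q
    Su_new[j, k] <- Su_new[k, j] <- val
  }
  Su_new <- .psd_guard(Su_new, floor, max_corr)
  Sc_new <- NULL
  if (des$f > 0) {
    Sc_new <- matrix(0, m, m)
    for (j in seq_len(m)) for (k in j:m) {
      cj <- theta[des$idx$c[[j]]]
      ck <- theta[des$idx$c[[k]]]
      val <- (sum(cj * ck) +
                sum(diag(C[des$idx$c[[j]], des$idx$c[[k]],
                           drop = FALSE]))) / des$f
      Sc_new[j, k] <- Sc_new[k, j] <- val
    }
    Sc_new <- .psd_guard(Sc_new, floor, max_corr)
  }
  s2_new <- numeric(m)
  for (t in seq_len(m)) {
    tr <- traits[[t]]
    rows <- des$rows[[t]]
    rt <- as.numeric(Matrix::crossprod(des$Td[rows, , drop = FALSE],
                                       tr$w * tr$y))
    s2_new[t] <- max(floor,
                     (sum(tr$w * tr$y^2) - sum(theta * rt)) /
                       (length(tr$y) - des$p[t]))
  }
  list(Su = Su_new, Sc = Sc_new, s2_eps = s2_new)
}

.psd_guard <- function(S, floor = 1e-8, max_corr = 0.999) {
  d <- pmax(diag(S), floor)
  diag(S) <- d
  if (nrow(S) == 2) {
    lim <- max_corr * sqrt(d[1] * d[2])
    S[1, 2] <- S[2, 1] <- sign(S[1, 2]) * min(abs(S[1, 2]), lim)
  }
  S
}

#' Control settings for REML and DHGLM fitting
#'
#' @param tol outer convergence tolerance on the change in REML
#'   log-likelihood. The DHGLM monitors the likelihood of a working
#'   response that itself moves between iterations, so the default is
#'   1e-4; demanding much more asks the criterion to resolve ridge
#'   directions that are flat relative to the sampling error of the
#'   components.
#' @param max_iter maximum outer iterations.
#' @param accelerate use Aitken extrapolation of the EM component track
#'   (proposals that would materially decrease the log-likelihood are
#'   discarded).
#' @param comp_tol secondary stopping rule: relative norm of the
#'   per-iteration EM change of the packed component vector. On
#'   near-boundary ridges the working-response log-likelihood rings while
#'   the components are stationary to far below their standard errors;
#'   this criterion recognizes that state.
#' @param floor lower bound for variance components; a component pinned
#'   here is flagged in the trace.
#' @param psi_tol relative-change tolerance on fitted residual variances
#'   when iterating the dispersion response at fixed components.
#' @param psi_max_iter cap on those weight iterations.
#' @return list of class `"dhglm_control"`.
#' @export
dhglm_control <- function(tol = 1e-4, max_iter = 200, accelerate = TRUE,
                          comp_tol = 1e-4, floor = 1e-8, psi_tol = 1e-5,
                          psi_max_iter = 50) {
  structure(list(tol = tol, max_iter = max_iter, accelerate = accelerate,
                 comp_tol = comp_tol, floor = floor, psi_tol = psi_tol,
                 psi_max_iter = psi_max_iter),
            class = "dhglm_control")
}

.pack_comps <- function(Su, Sc, s2) {
  c(Su[lower.tri(Su, diag = TRUE)],
    if (!is.null(Sc)) Sc[lower.tri(Sc, diag = TRUE)], s2)
}

.unpack_comps <- function(v, m, has_c) {
  nS <- m * (m + 1) / 2
  Su <- matrix(0, m, m)
  Su[lower.tri(Su, diag = TRUE)] <- v[seq_len(nS)]
  Su <- Su + t(Su) - diag(diag(Su), m)
  off <- nS
  Sc <- NULL
  if (has_c) {
    Sc <- matrix(0, m, m)
    Sc[lower.tri(Sc, diag = TRUE)] <- v[off + seq_len(nS)]
    Sc <- Sc + t(Sc) - diag(diag(Sc), m)
    off <- off + nS
  }
  list(Su = Su, Sc = Sc, s2 = v[(off + 1):length(v)])
}

# Aitken extrapolation of the component vector from three EM iterates,
# using the global geometric rate (ratio of successive difference norms);
# elementwise ratios are erratic when components cross zero.
.aitken <- function(v2, v1, v0, cap = 0.98) {
  d1 <- v1 - v0
  d2 <- v2 - v1
  r <- min(sqrt(sum(d2^2)) / max(sqrt(sum(d1^2)), 1e-300), cap)
  v2 + r / (1 - r) * d2
}

#' One EM-REML update of the variance components
#'
#' Runs a single expectation-maximization REML step of the single-trait
#' mixed model (quadratic forms of the current solutions plus the
#' prediction-error trace from the inverted coefficient matrix). Iterating
#' this map to a fixed point gives the REML estimates; the REML
#' log-likelihood is non-decreasing along the path.
#'
#' @inheritParams solve_mixed_model
#' @param varcomps list with `sigma2_u`, `sigma2_c` (or `NULL`),
#'   `sigma2_e`.
#' @return list with updated `sigma2_u`, `sigma2_c`, `sigma2_e`,
#'   `loglik` (REML log-likelihood at the *current* components), and
#'   `at_floor` flags.
#' @export
reml_update <- function(y, X, Zg, Q = NULL, Kinv, varcomps,
                        weights = rep(1, length(y))) {
  X <- as.matrix(X)
  if (inherits(Kinv, "relationship_structure")) Kinv <- Kinv$values
  traits <- list(list(y = y, X = X, w = weights))
  des <- .mme_design(traits, methods::as(Zg, "CsparseMatrix"),
                     if (is.null(Q)) NULL
                     else methods::as(Q, "CsparseMatrix"))
  Su <- matrix(varcomps$sigma2_u, 1, 1)
  Sc <- if (is.null(Q)) NULL else matrix(varcomps$sigma2_c, 1, 1)
  sol <- .mme_solve(des, traits, Kinv, Su, Sc, varcomps$sigma2_e,
                    dense_C = TRUE)
  ll <- .mme_loglik(sol, traits, Kinv, Su, Sc, varcomps$sigma2_e)
  up <- .em_step(sol, traits, Kinv, Su, Sc, varcomps$sigma2_e)
  list(sigma2_u = up$Su[1, 1],
       sigma2_c = if (is.null(Q)) NULL else up$Sc[1, 1],
       sigma2_e = up$s2_eps[1],
       loglik = ll,
       at_floor = c(u = up$Su[1, 1] <= 1e-8,
                    c = !is.null(Q) && up$Sc[1, 1] <= 1e-8))
}

# Generic EM-REML loop over (possibly accelerated) component updates.
# `refresh` lets the DHGLM rebuild its working response and weights from
# the previous iteration's solve before the next solve, so each EM step
# sees a self-consistent system; for a plain REML fit it is NULL.
.reml_loop <- function(traits, des, Kinv, Su, Sc, s2_eps, control,
                       refresh = NULL, logdetK = NULL, pin = NULL) {
  has_c <- !is.null(Sc)
  m <- des$m
  trace <- numeric(0)
  hist <- list()
  prev_ll <- -Inf
  converged <- FALSE
  sol <- NULL
  for (it in seq_len(control$max_iter)) {
    if (!is.null(refresh) && !is.null(sol))
      traits <- refresh(sol, traits, s2_eps)
    sol <- .mme_solve(des, traits, Kinv, Su, Sc, s2_eps, dense_C = TRUE)
    ll <- .mme_loglik(sol, traits, Kinv, Su, Sc, s2_eps, logdetK)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - prev_ll) < control$tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
    v_old <- .pack_comps(Su, Sc, s2_eps)
    up <- .em_step(sol, traits, Kinv, Su, Sc, s2_eps,
                   floor = control$floor)
    Su <- up$Su; Sc <- up$Sc; s2_eps <- up$s2_eps
    if (!is.null(pin)) {
      pinned <- pin(Su, Sc)
      Su <- pinned$Su; Sc <- pinned$Sc
    }
    v_new <- .pack_comps(Su, Sc, s2_eps)
    if (it > 1 &&
        sqrt(sum((v_new - v_old)^2)) <
          control$comp_tol * sqrt(sum(v_new^2) + 1e-12)) {
      converged <- TRUE
      break
    }
    hist <- c(hist, list(v_new))
    nh <- length(hist)
    if (control$accelerate && nh >= 3 && it %% 5 == 0) {
      prop <- .aitken(hist[[nh]], hist[[nh - 1]], hist[[nh - 2]])
      pc <- .unpack_comps(prop, m, has_c)
      pc$Su <- .psd_guard(pc$Su, control$floor)
      if (has_c) pc$Sc <- .psd_guard(pc$Sc, control$floor)
      pc$s2 <- pmax(pc$s2, control$floor)
      sol_try <- .mme_solve(des, traits, Kinv, pc$Su, pc$Sc, pc$s2,
                            dense_C = TRUE)
      ll_try <- .mme_loglik(sol_try, traits, Kinv, pc$Su, pc$Sc, pc$s2,
                            logdetK)
      if (ll_try >= ll - 1e-2) {
        Su <- pc$Su; Sc <- pc$Sc; s2_eps <- pc$s2
        if (!is.null(pin)) {
          pinned <- pin(Su, Sc)
          Su <- pinned$Su; Sc <- pinned$Sc
        }
        hist <- c(hist, list(.pack_comps(Su, Sc, s2_eps)))
      }
    }
  }
  list(sol = sol, traits = traits, Su = Su, Sc = Sc, s2_eps = s2_eps,
       trace = trace, converged = converged, iterations = length(trace))
}

#' Homoscedastic REML fit of the mean model
#'
#' Fits body weight with fixed effects (intercept, age, tank, year class),
#' a genetic random effect (sire-dam or animal parameterization) and an
#' optional full-sib common-environment effect, assuming a homogeneous
#' residual variance. EM-REML with Aitken acceleration; also the
#' initializer of [fit_dhglm()].
#'
#' @param phenotypes data.frame with columns `animal`, `y` (response on
#'   the analysis scale), `age`, `tank`, `year_class`, `family`, `sire`,
#'   `dam`.
#' @param ped a [pedigree()] covering all animals.
#' @param spec a [model_spec()].
#' @param Kinv inverse relationship structure over the genetic ids of the
#'   parameterization (see [evaluation_inverse()]).
#' @param control a [dhglm_control()].
#' @return list of class `"mean_model_fit"`: variance components, fixed
#'   and random solutions, residuals, leverages, log-likelihood trace.
#' @export
fit_mean_model <- function(phenotypes, ped, spec, Kinv,
                           control = dhglm_control()) {
  dat <- .assemble_model_data(phenotypes, ped, spec, Kinv)
  traits <- list(list(y = dat$y, X = dat$X, w = rep(1, length(dat$y))))
  des <- .mme_design(traits, dat$Zg, dat$Q)
  vy <- stats::var(dat$y)
  res <- .reml_loop(traits, des, dat$Kinv,
                    Su = matrix(vy * 0.1, 1, 1),
                    Sc = if (is.null(dat$Q)) NULL
                         else matrix(vy * 0.05, 1, 1),
                    s2_eps = vy * 0.5, control = control,
                    logdetK = dat$logdetK)
  sol <- res$sol
  fitted <- .mme_fitted(sol, res$traits)
  structure(list(
    spec = spec,
    sigma2_u = res$Su[1, 1],
    sigma2_c = if (is.null(res$Sc)) NULL else res$Sc[1, 1],
    sigma2_e = res$s2_eps[1],
    fixed = stats::setNames(sol$theta[des$idx$b[[1]]], colnames(dat$X)),
    genetic = stats::setNames(sol$theta[des$idx$u[[1]]], dat$genetic_ids),
    common = if (is.null(dat$Q)) NULL
             else stats::setNames(sol$theta[des$idx$c[[1]]],
                                  dat$family_ids),
    fitted = fitted,
    residuals = dat$y - fitted,
    hat = .mme_hat(sol, res$traits),
    animal = dat$animal,
    genotyped = dat$genotyped,
    loglik_trace = res$trace,
    converged = res$converged),
    class = "mean_model_fit")
}
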