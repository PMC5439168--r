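# Henderson mixed-model equations for one or two stacked traits.
#
# Coefficient order: fixed effects per trait, then genetic effects per
# trait, then common-environment effects per trait:
#   theta = [b_1, ..., b_m, u_1, ..., u_m, c_1, ..., c_m]
# Priors: [u_1; ...; u_m] ~ N(0, Su (x) K), [c_1; ...] ~ N(0, Sc (x) I_f),
# residuals independent across traits with per-observation variance
# s2_eps[t] / w[t,i].

.mme_design <- function(traits, Zg, Q) {
  m <- length(traits)
  p <- vapply(traits, function(tr) ncol(tr$X), integer(1))
  q <- ncol(Zg)
  f <- if (is.null(Q)) 0L else ncol(Q)
  blocks <- list()
  for (t in seq_len(m)) {
    row <- list()
    for (s in seq_len(m))
      row[[s]] <- if (s == t) Matrix::Matrix(traits[[t]]$X, sparse = TRUE)
                  else Matrix::Matrix(0, nrow(traits[[t]]$X), p[s],
                                      sparse = TRUE)
    for (s in seq_len(m))
      row[[m + s]] <- if (s == t) Zg
                      else Matrix::Matrix(0, nrow(traits[[t]]$X), q,
                                          sparse = TRUE)
    if (f > 0)
      for (s in seq_len(m))
        row[[2 * m + s]] <- if (s == t) Q
                            else Matrix::Matrix(0, nrow(traits[[t]]$X), f,
                                                sparse = TRUE)
    blocks[[t]] <- do.call(cbind, row)
  }
  Td <- do.call(rbind, blocks)
  off <- cumsum(c(0, p, rep(q, m), rep(f, m)))
  idx <- list(
    b = lapply(seq_len(m), function(t) seq.int(off[t] + 1L, off[t + 1L])),
    u = lapply(seq_len(m), function(t)
      seq.int(off[m + t] + 1L, off[m + t + 1L])),
    c = if (f > 0) lapply(seq_len(m), function(t)
      seq.int(off[2 * m + t] + 1L, off[2 * m + t + 1L])) else NULL)
  rows <- split(seq_len(nrow(Td)),
                rep(seq_len(m), vapply(traits, function(tr) length(tr$y),
                                       integer(1))))
  list(Td = Td, idx = idx, rows = rows, m = m, p = p, q = q, f = f)
}

# Solve the MME; optionally return the dense inverse of the coefficient
# matrix (needed by EM-REML trace terms and hat values).
.mme_solve <- function(des, traits, Kinv, Su, Sc, s2_eps,
                       dense_C = FALSE) {
  m <- des$m
  w_all <- unlist(lapply(seq_len(m), function(t)
    traits[[t]]$w / s2_eps[t]))
  y_all <- unlist(lapply(traits, function(tr) tr$y))
  Td <- des$Td
  TtW <- Matrix::t(Td * w_all)
  M <- TtW %*% Td
  rhs <- as.numeric(TtW %*% y_all)
  Su <- as.matrix(Su)
  # penalty blocks are contiguous by construction: [b | u | c]
  pen <- list(Matrix::Matrix(0, sum(des$p), sum(des$p), sparse = TRUE),
              kronecker(solve(Su), Kinv))
  if (des$f > 0) {
    Sc <- as.matrix(Sc)
    pen <- c(pen, list(kronecker(solve(Sc), Matrix::Diagonal(des$f))))
  }
  M <- M + Matrix::bdiag(pen)
  M <- (M + Matrix::t(M)) / 2
  out <- list(M = M, rhs = rhs, des = des, s2_eps = s2_eps)
  if (dense_C) {
    Md <- as.matrix(M)
    ch <- tryCatch(chol(Md), error = function(e) NULL)
    if (is.null(ch))
      stop("singular mixed-model coefficient matrix: ",
           "check for confounded fixed effects")
    C <- chol2inv(ch)
    out$theta <- as.numeric(C %*% rhs)
    out$C <- C
    out$logdetM <- 2 * sum(log(diag(ch)))
  } else {
    ch <- tryCatch(Matrix::Cholesky(methods::as(M, "symmetricMatrix"),
                                    LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch))
      stop("singular mixed-model coefficient matrix: ",
           "check for confounded fixed effects")
    out$theta <- as.numeric(Matrix::solve(ch, rhs))
    out$chol <- ch
    out$logdetM <-
      2 * Matrix::determinant(ch, sqrt = TRUE)$modulus[1]
  }
  out
}

# Leverage (hat) diagonal of trait `t`: h_i = (w_i/s2) * t_i' M^-1 t_i,
# the derivative of the fitted value (fixed + random) w.r.t. the record.
.mme_hat <- function(sol, traits, t = 1L) {
  des <- sol$des
  rows <- des$rows[[t]]
  T1 <- des$Td[rows, , drop = FALSE]
  w <- traits[[t]]$w / sol$s2_eps[t]
  n <- nrow(T1)
  h <- numeric(n)
  chunk <- 512L
  for (lo in seq.int(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    Tc <- T1[lo:hi, , drop = FALSE]
    B <- if (!is.null(sol$C)) as.matrix(Tc %*% sol$C)
         else t(as.matrix(Matrix::solve(sol$chol, Matrix::t(Tc))))
    h[lo:hi] <- rowSums(B * as.matrix(Tc))
  }
  h * w
}

# Fitted values and residuals of trait t.
.mme_fitted <- function(sol, traits, t = 1L) {
  rows <- sol$des$rows[[t]]
  as.numeric(sol$des$Td[rows, , drop = FALSE] %*% sol$theta)
}

# REML log-likelihood of the current linear system (up to a constant).
.mme_loglik <- function(sol, traits, Kinv, Su, Sc, s2_eps, logdetK = NULL) {
  des <- sol$des
  m <- des$m
  Su <- as.matrix(Su)
  if (is.null(logdetK))
    logdetK <- -as.numeric(Matrix::determinant(
      methods::as(Kinv, "generalMatrix"), logarithm = TRUE)$modulus)
  logR <- 0; quad <- 0
  for (t in seq_len(m)) {
    tr <- traits[[t]]
    logR <- logR + sum(log(s2_eps[t] / tr$w))
    quad <- quad + sum(tr$w * tr$y^2) / s2_eps[t]
  }
  logG <- des$q * determinant(Su, logarithm = TRUE)$modulus[1] +
    m * logdetK
  if (des$f > 0)
    logG <- logG +
      des$f * determinant(as.matrix(Sc), logarithm = TRUE)$modulus[1]
  ypy <- quad - sum(sol$theta * sol$rhs)
  -0.5 * (logR + logG + sol$logdetM + ypy)
}

#' Solve Henderson's mixed-model equations at fixed variance components
#'
#' Single-trait convenience wrapper around the engine used by the DHGLM:
#' solves for fixed effects and (optionally correlated) random effects with
#' per-observation residual variance `sigma2_e / weights[i]`, and returns
#' solutions, residuals and leverages.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix.
#' @param Zg design matrix of the genetic random effect (n x q), or `NULL`
#'   for none.
#' @param Q design matrix of the common-environment effect (n x f), or
#'   `NULL`.
#' @param Kinv inverse relationship matrix over the q genetic levels
#'   (matrix, `Matrix`, or [relationship_structure()]).
#' @param sigma2_u,sigma2_c,sigma2_e variance components.
#' @param weights positive per-observation residual weights (variance is
#'   `sigma2_e / weights`).
#' @return list with `fixed`, `genetic`, `common` solution vectors,
#'   `fitted`, `residuals`, and `hat` (leverage in `[0, 1)`).
#' @export
solve_mixed_model <- function(y, X, Zg = NULL, Q = NULL, Kinv = NULL,
                              sigma2_u = NULL, sigma2_c = NULL,
                              sigma2_e = 1, weights = rep(1, length(y))) {
  stopifnot(all(weights > 0), sigma2_e > 0)
  X <- as.matrix(X)
  if (is.null(Zg)) {
    Zg <- Matrix::Matrix(0, length(y), 1, sparse = TRUE)
    Kinv <- Matrix::Diagonal(1)
    sigma2_u <- 1e8                     # effectively absent
  }
  if (inherits(Kinv, "relationship_structure")) Kinv <- Kinv$values
  traits <- list(list(y = y, X = X, w = weights))
  des <- .mme_design(traits, methods::as(Zg, "CsparseMatrix"),
                     if (is.null(Q)) NULL
                     else methods::as(Q, "CsparseMatrix"))
  Sc <- if (is.null(Q)) NULL else matrix(sigma2_c, 1, 1)
  sol <- .mme_solve(des, traits, Kinv, matrix(sigma2_u, 1, 1), Sc,
                    s2_eps = sigma2_e, dense_C = FALSE)
  fitted <- .mme_fitted(sol, traits)
  list(fixed = sol$theta[des$idx$b[[1]]],
       genetic = sol$theta[des$idx$u[[1]]],
       common = if (des$f > 0) sol$theta[des$idx$c[[1]]] else NULL,
       fitted = fitted,
       residuals = y - fitted,
       hat = .mme_hat(sol, traits))
}
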