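#' Model specification for the genetic evaluation
#'
#' @param genetic_param `"sire_dam"` (genetic effects on parents, each
#'   carrying a quarter of the additive variance) or `"animal"` (an effect
#'   for every individual).
#' @param relationship `"A"` (pedigree) or `"H"` (combined
#'   pedigree-genomic).
#' @param transform analysis scale of body weight: `"standardized"` or
#'   `"log"`.
#' @param include_common_env fit the full-sib common-environment effect.
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(genetic_param = c("sire_dam", "animal"),
                       relationship = c("A", "H"),
                       transform = c("standardized", "log"),
                       include_common_env = TRUE) {
  structure(list(genetic_param = match.arg(genetic_param),
                 relationship = match.arg(relationship),
                 transform = match.arg(transform),
                 include_common_env = isTRUE(include_common_env)),
            class = "model_spec")
}

#' Inverse relationship structure for an evaluation
#'
#' Assembles the inverse covariance structure the mixed model needs for a
#' given parameterization: the sparse pedigree inverse (animal/A), the
#' single-step shortcut inverse (animal/H), or a dense inverse over the
#' parental pedigree (sire-dam models, where only parents and their
#' ancestors carry genetic effects).
#'
#' @param ped a [pedigree()].
#' @param spec a [model_spec()] (only `genetic_param` and `relationship`
#'   are used).
#' @param G genomic [relationship_structure()] over the genotyped animals
#'   (required when `relationship = "H"`).
#' @param genotyped_ids ids of genotyped animals (required for H).
#' @param blend_weight weight on G in [blend_genomic()] before inversion.
#' @param tune apply the [tune_genomic()] base-compatibility adjustment
#'   before blending (recommended whenever the genotyped animals are a
#'   related subset of the pedigree).
#' @return list: `Kinv` (a [relationship_structure()] of inverse kind) and
#'   `ids` (the genetic-effect index).
#' @export
evaluation_inverse <- function(ped, spec, G = NULL, genotyped_ids = NULL,
                               blend_weight = 0.99, tune = TRUE) {
  stopifnot(inherits(ped, "pedigree"), inherits(spec, "model_spec"))
  if (spec$relationship == "H") {
    if (is.null(G) || is.null(genotyped_ids))
      stop("relationship 'H' requires genomic data ",
           "(G and genotyped_ids)")
    genotyped_ids <- as.character(genotyped_ids)
    A22 <- relationship_matrix(ped, ids = genotyped_ids)
    A22$kind <- "A22"
    Gb <- subset_relationship(G, genotyped_ids)
    if (tune) Gb <- tune_genomic(Gb, A22)
    Gb <- blend_genomic(Gb, A22, weight = blend_weight)
    if (spec$genetic_param == "animal") {
      Hinv <- build_H_inverse(relationship_inverse(ped),
                              invert_relationship(Gb),
                              invert_relationship(A22),
                              genotyped_ids)
      return(list(Kinv = Hinv, ids = Hinv$ids))
    }
    A <- relationship_matrix(ped)
    H <- build_H_direct(A, Gb, genotyped_ids)
    ids <- parental_ids(ped)
    Hpar <- subset_relationship(H, ids, kind = "H")
    Ki <- invert_relationship(Hpar)
    return(list(Kinv = Ki, ids = ids))
  }
  if (spec$genetic_param == "animal") {
    Ai <- relationship_inverse(ped)
    return(list(Kinv = Ai, ids = Ai$ids))
  }
  ids <- parental_ids(ped)
  Apar <- relationship_matrix(ped, ids = ids)
  list(Kinv = invert_relationship(Apar), ids = ids)
}

# Build design matrices and bookkeeping shared by all fitting entry
# points. `phenotypes` needs: animal, y, age, tank, year_class, family.
.assemble_model_data <- function(phenotypes, ped, spec, Kinv,
                                 logdet = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  if (inherits(Kinv, "list") && !is.null(Kinv$Kinv)) Kinv <- Kinv$Kinv
  if (!inherits(Kinv, "relationship_structure"))
    stop("Kinv must be a relationship_structure (see evaluation_inverse)")
  need <- c("animal", "y", "age", "tank", "year_class", "family")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  animal <- as.character(phenotypes$animal)
  if (anyDuplicated(animal)) stop("duplicate phenotype records per animal")
  not_in_ped <- setdiff(animal, ped$animal)
  if (length(not_in_ped))
    stop("phenotyped animal(s) not in pedigree: ",
         paste(utils::head(not_in_ped, 5), collapse = ", "))
  ids <- Kinv$ids
  n <- length(animal)
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  if (spec$genetic_param == "animal") {
    j <- match(animal, ids)
    if (anyNA(j))
      stop("relationship inverse does not cover all phenotyped animals")
    Zg <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1,
                               dims = c(n, length(ids)))
  } else {
    sires <- ped$sire[pos[animal]]
    dams <- ped$dam[pos[animal]]
    ii <- c(seq_len(n)[!is.na(sires)], seq_len(n)[!is.na(dams)])
    par_ids <- c(sires[!is.na(sires)], dams[!is.na(dams)])
    j <- match(par_ids, ids)
    if (anyNA(j))
      stop("relationship inverse does not cover all parents of ",
           "phenotyped animals")
    Zg <- Matrix::sparseMatrix(i = ii, j = j, x = 1,
                               dims = c(n, length(ids)))
  }
  Q <- NULL; family_ids <- NULL
  if (spec$include_common_env) {
    fam <- factor(as.character(phenotypes$family))
    family_ids <- levels(fam)
    Q <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fam), x = 1,
                              dims = c(n, nlevels(fam)))
  }
  Ki <- Kinv$values
  logdetK <- if (logdet)
    -as.numeric(Matrix::determinant(
      methods::as(Ki, "generalMatrix"), logarithm = TRUE)$modulus)
  else NA_real_
  list(y = as.numeric(phenotypes$y), X = fixed_design(phenotypes),
       Zg = Zg, Q = Q, Kinv = Ki, logdetK = logdetK,
       genetic_ids = ids, family_ids = family_ids, animal = animal,
       genotyped = if ("genotyped" %in% names(phenotypes))
         as.logical(phenotypes$genotyped) else rep(FALSE, n))
}

#' Working response of the dispersion sub-model
#'
#' The linearized log residual variance of each record:
#' `psi_i = log(s2_i) + (e_i^2 / (1 - h_i) - s2_i) / s2_i`,
#' built from the current residual, leverage and fitted residual variance.
#'
#' @param residuals per-record residuals of the mean sub-model.
#' @param hat_values leverages in `[0, 1)`.
#' @param fitted_resid_var current fitted per-record residual variances
#'   (> 0).
#' @return numeric vector `psi`.
#' @export
compute_dispersion_response <- function(residuals, hat_values,
                                        fitted_resid_var) {
  if (any(hat_values >= 1))
    stop("degenerate leverage: hat value >= 1 at record ",
         which(hat_values >= 1)[1])
  if (any(hat_values < 0)) stop("negative hat value")
  if (any(fitted_resid_var <= 0))
    stop("fitted residual variances must be positive")
  log(fitted_resid_var) +
    (residuals^2 / (1 - hat_values) - fitted_resid_var) / fitted_resid_var
}

#' Fit the double hierarchical generalized linear model
#'
#' Joint mixed model for body weight and the log of its residual variance.
#' Each outer iteration (i) solves the bivariate mixed-model equations for
#' `(y, psi)` with residual weights `diag(1/phi)` on `y` (`phi` the fitted
#' per-record residual variances, the exponential of the dispersion linear
#' predictor) and `diag((1 - h)/2)` on `psi`; (ii) takes one EM-REML step
#' on all (co)variance components (genetic and common-environment 2x2
#' blocks, two scaled residual variances expected to converge to 1); and
#' (iii) refreshes `psi` and both weight matrices. Stops when the REML
#' log-likelihood changes by less than `control$tol`.
#'
#' @inheritParams fit_mean_model
#' @param init optional `"mean_model_fit"` to initialize from (otherwise
#'   one is fitted internally).
#' @param dispersion_random fit genetic and common-environment effects in
#'   the dispersion sub-model (the default). With `FALSE` the dispersion
#'   model reduces to an intercept (random dispersion variances pinned at
#'   the floor): the homoscedastic special case, whose mean sub-model
#'   coincides exactly with the plain REML fit.
#' @return object of class `"dhglm_fit"`; see the package vignette. Key
#'   elements: `varcomps` (reported-scale components, class
#'   `"dhglm_varcomps"`), `ebv_mean`/`ebv_disp` (genetic solutions over
#'   the genetic ids), `common_mean`/`common_disp`, `fixed_mean`/
#'   `fixed_disp`, `residuals`, `hat`, `fitted_resid_var`, `psi`,
#'   `loglik_trace`, `converged`.
#' @export
fit_dhglm <- function(phenotypes, ped, spec, Kinv,
                      control = dhglm_control(), init = NULL,
                      dispersion_random = TRUE) {
  dat <- .assemble_model_data(phenotypes, ped, spec, Kinv)
  n <- length(dat$y)
  if (is.null(init))
    init <- fit_mean_model(phenotypes, ped, spec, Kinv,
                           control = dhglm_control(
                             tol = max(control$tol, 1e-5),
                             max_iter = min(control$max_iter, 100),
                             accelerate = control$accelerate))
  s2e0 <- init$sigma2_e
  h0 <- pmin(init$hat, 1 - 1e-8)
  psi0 <- compute_dispersion_response(init$residuals, h0, rep(s2e0, n))
  Xv <- if (dispersion_random) dat$X else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  traits <- list(
    list(y = dat$y, X = dat$X, w = rep(1 / s2e0, n)),
    list(y = psi0, X = Xv, w = (1 - h0) / 2))
  des <- .mme_design(traits, dat$Zg, dat$Q)
  disp_init <- if (dispersion_random) 0.05 else control$floor
  Su <- diag(c(max(init$sigma2_u, control$floor), disp_init))
  Sc <- if (is.null(dat$Q)) NULL
        else diag(c(max(init$sigma2_c, control$floor), disp_init))
  s2_eps <- c(1, 1)
  state <- new.env(parent = emptyenv())
  refresh <- function(sol, traits, s2_eps_cur) {
    fitted1 <- .mme_fitted(sol, traits, 1L)
    e <- dat$y - fitted1
    h <- pmin(pmax(.mme_hat(sol, traits, 1L), 0), 1 - 1e-8)
    eta_v <- .mme_fitted(sol, traits, 2L)
    phi <- exp(pmin(pmax(eta_v, -30), 30))
    s2i <- s2_eps_cur[1] * phi
    psi <- compute_dispersion_response(e, h, s2i)
    traits[[1]]$w <- 1 / phi
    traits[[2]]$y <- psi
    traits[[2]]$w <- (1 - h) / 2
    state$e <- e; state$h <- h; state$phi <- phi
    state$s2i <- s2i; state$psi <- psi
    state$fitted_fixed_y <- as.numeric(dat$X %*%
                                         sol$theta[des$idx$b[[1]]])
    state$fitted_fixed_psi <- as.numeric(Xv %*%
                                           sol$theta[des$idx$b[[2]]])
    state$eta_v <- eta_v
    traits
  }
  pin <- if (dispersion_random) NULL else function(Su, Sc) {
    Su[2, 2] <- control$floor; Su[1, 2] <- Su[2, 1] <- 0
    if (!is.null(Sc)) {
      Sc[2, 2] <- control$floor; Sc[1, 2] <- Sc[2, 1] <- 0
    }
    list(Su = Su, Sc = Sc)
  }
  res <- .reml_loop(traits, des, dat$Kinv, Su, Sc, s2_eps, control,
                    refresh = refresh, logdetK = dat$logdetK, pin = pin)
  sol <- res$sol
  # refresh derived per-record quantities from the final solve
  traits_final <- refresh(sol, res$traits, res$s2_eps)
  g <- if (spec$genetic_param == "sire_dam") 4 else 1
  varcomps <- .report_varcomps(res$Su, res$Sc, res$s2_eps,
                               mean(state$s2i), g, spec)
  structure(list(
    spec = spec,
    varcomps = varcomps,
    Su = res$Su, Sc = res$Sc, s2_eps = res$s2_eps,
    fixed_mean = stats::setNames(sol$theta[des$idx$b[[1]]],
                                 colnames(dat$X)),
    fixed_disp = stats::setNames(sol$theta[des$idx$b[[2]]],
                                 colnames(Xv)),
    ebv_mean = stats::setNames(sol$theta[des$idx$u[[1]]],
                               dat$genetic_ids),
    ebv_disp = stats::setNames(sol$theta[des$idx$u[[2]]],
                               dat$genetic_ids),
    common_mean = if (is.null(dat$Q)) NULL
      else stats::setNames(sol$theta[des$idx$c[[1]]], dat$family_ids),
    common_disp = if (is.null(dat$Q)) NULL
      else stats::setNames(sol$theta[des$idx$c[[2]]], dat$family_ids),
    residuals = state$e,
    resid_disp = state$psi - .mme_fitted(sol, traits_final, 2L),
    hat = state$h,
    fitted_resid_var = state$s2i,
    psi = state$psi,
    fitted_fixed_y = state$fitted_fixed_y,
    fitted_fixed_psi = state$fitted_fixed_psi,
    y = dat$y,
    animal = dat$animal,
    genotyped = dat$genotyped,
    genetic_ids = dat$genetic_ids,
    loglik_trace = res$trace,
    iterations = res$iterations,
    converged = res$converged),
    class = "dhglm_fit")
}

.report_varcomps <- function(Su, Sc, s2_eps, sigma2_e_bar, g, spec) {
  structure(list(
    sigma2_u = Su[1, 1],
    sigma2_a = g * Su[1, 1],
    sigma2_av_exp = g * Su[2, 2],
    sigma_a_av_exp = g * Su[1, 2],
    sigma2_c = if (is.null(Sc)) 0 else Sc[1, 1],
    sigma2_cv_exp = if (is.null(Sc)) 0 else Sc[2, 2],
    sigma_c_cv_exp = if (is.null(Sc)) 0 else Sc[1, 2],
    sigma2_e = sigma2_e_bar,
    scaled_eps = c(y = s2_eps[1], psi = s2_eps[2]),
    genetic_param = spec$genetic_param),
    class = "dhglm_varcomps")
}

#' @export
print.dhglm_varcomps <- function(x, ...) {
  cat("DHGLM variance components (", x$genetic_param, " scale)\n",
      sep = "")
  cat(sprintf("  sigma2_a       = %.4f\n", x$sigma2_a))
  cat(sprintf("  sigma2_av,exp  = %.4f\n", x$sigma2_av_exp))
  cat(sprintf("  sigma_a,av,exp = %.4f\n", x$sigma_a_av_exp))
  cat(sprintf("  sigma2_c       = %.4f   sigma2_cv,exp = %.4f\n",
              x$sigma2_c, x$sigma2_cv_exp))
  cat(sprintf("  sigma2_e (mean fitted) = %.4f\n", x$sigma2_e))
  cat(sprintf("  scaled residuals: %.3f (y), %.3f (psi)\n",
              x$scaled_eps[1], x$scaled_eps[2]))
  invisible(x)
}

#' @export
print.dhglm_fit <- function(x, ...) {
  cat(sprintf("DHGLM fit (%s, %s, %s): %d records, %s after %d outer iterations\n",
              x$spec$genetic_param, x$spec$relationship, x$spec$transform,
              length(x$residuals),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$varcomps)
  invisible(x)
}

#' Predict breeding values at fixed variance components
#'
#' BLUP-only solve of the bivariate model: the (co)variance components are
#' taken as given (normally from the full sire-dam DHGLM fit, converted to
#' the requested parameterization) and only the dispersion response and
#' weights are iterated to a fixed point. Records of masked animals are
#' excluded from both sub-models, so their genetic solutions draw on
#' relatives only.
#'
#' @inheritParams fit_dhglm
#' @param varcomps a `"dhglm_varcomps"` object (or a [fit_dhglm()] result,
#'   whose components are reused).
#' @param mask character vector of animal ids whose records are masked.
#' @param warm_start optional previous fit or prediction on the same
#'   phenotype table (e.g. the full-data prediction when masking folds):
#'   its fitted residual variances, leverages and working response seed
#'   the iteration, which then needs only a few refinement solves.
#' @return object of class `"dhglm_blup"` with the same solution slots as
#'   a `"dhglm_fit"`, plus `mask`.
#' @export
predict_breeding_values <- function(phenotypes, ped, spec, Kinv, varcomps,
                                    mask = character(0),
                                    control = dhglm_control(),
                                    warm_start = NULL) {
  if (inherits(varcomps, "dhglm_fit")) varcomps <- varcomps$varcomps
  stopifnot(inherits(varcomps, "dhglm_varcomps"))
  mask <- as.character(mask)
  keep <- !(as.character(phenotypes$animal) %in% mask)
  if (!any(keep)) stop("mask removes every record")
  phen <- phenotypes[keep, , drop = FALSE]
  dat <- .assemble_model_data(phen, ped, spec, Kinv, logdet = FALSE)
  n <- length(dat$y)
  g <- if (spec$genetic_param == "sire_dam") 4 else 1
  Su <- matrix(c(varcomps$sigma2_a, varcomps$sigma_a_av_exp,
                 varcomps$sigma_a_av_exp, varcomps$sigma2_av_exp),
               2, 2) / g
  Su <- .psd_guard(Su)
  Sc <- if (is.null(dat$Q)) NULL else
    .psd_guard(matrix(c(varcomps$sigma2_c, varcomps$sigma_c_cv_exp,
                        varcomps$sigma_c_cv_exp, varcomps$sigma2_cv_exp),
                      2, 2))
  s2e0 <- varcomps$sigma2_e
  phi <- rep(s2e0, n)
  psi <- rep(log(s2e0), n)
  h <- rep(0, n)
  e <- rep(0, n)
  if (!is.null(warm_start)) {
    idx <- match(dat$animal, warm_start$animal)
    if (anyNA(idx))
      stop("warm_start does not cover the retained records")
    phi <- warm_start$fitted_resid_var[idx]
    psi <- warm_start$psi[idx]
    h <- warm_start$hat[idx]
  }
  traits <- list(list(y = dat$y, X = dat$X, w = 1 / phi),
                 list(y = psi, X = dat$X, w = (1 - h) / 2))
  des <- .mme_design(traits, dat$Zg, dat$Q)
  sol <- NULL
  for (it in seq_len(control$psi_max_iter)) {
    sol <- .mme_solve(des, traits, dat$Kinv, Su, Sc, c(1, 1),
                      dense_C = FALSE)
    fitted1 <- .mme_fitted(sol, traits, 1L)
    e <- dat$y - fitted1
    if (it == control$psi_max_iter) break  # no further reweighting
    h <- pmin(pmax(.mme_hat(sol, traits, 1L), 0), 1 - 1e-8)
    phi_new <- exp(pmin(pmax(.mme_fitted(sol, traits, 2L), -30), 30))
    delta <- max(abs(phi_new - phi) / phi)
    phi <- sqrt(phi * phi_new)   # damped update suppresses two-cycles
    psi <- compute_dispersion_response(e, h, phi)
    traits[[1]]$w <- 1 / phi
    traits[[2]]$y <- psi
    traits[[2]]$w <- (1 - h) / 2
    if (delta < control$psi_tol) break
  }
  psi_iterations <- it
  structure(list(
    spec = spec, varcomps = varcomps, mask = mask,
    fixed_mean = stats::setNames(sol$theta[des$idx$b[[1]]],
                                 colnames(dat$X)),
    fixed_disp = stats::setNames(sol$theta[des$idx$b[[2]]],
                                 colnames(dat$X)),
    ebv_mean = stats::setNames(sol$theta[des$idx$u[[1]]],
                               dat$genetic_ids),
    ebv_disp = stats::setNames(sol$theta[des$idx$u[[2]]],
                               dat$genetic_ids),
    common_mean = if (is.null(dat$Q)) NULL
      else stats::setNames(sol$theta[des$idx$c[[1]]], dat$family_ids),
    common_disp = if (is.null(dat$Q)) NULL
      else stats::setNames(sol$theta[des$idx$c[[2]]], dat$family_ids),
    residuals = e, hat = h, psi = psi, fitted_resid_var = phi,
    fitted_fixed_y = as.numeric(dat$X %*% sol$theta[des$idx$b[[1]]]),
    fitted_fixed_psi = as.numeric(dat$X %*% sol$theta[des$idx$b[[2]]]),
    y = dat$y, genotyped = dat$genotyped,
    animal = dat$animal, genetic_ids = dat$genetic_ids,
    psi_iterations = psi_iterations),
    class = "dhglm_blup")
}

#' Animal-level EBV pairs from a fit or BLUP prediction
#'
#' Under the animal parameterization these are the genetic solutions
#' themselves. Under the sire-dam parameterization the only defined
#' animal-level quantity for a non-fitted individual is the parental sum
#' `u_sire + u_dam` (it omits the Mendelian sampling deviation); unknown
#' parents contribute 0.
#'
#' @param fit a `"dhglm_fit"` or `"dhglm_blup"`.
#' @param ped the [pedigree()] used in the fit.
#' @param ids animals to report (default: all in the pedigree).
#' @return data.frame `animal`, `ebv_mean`, `ebv_disp`.
#' @export
animal_ebv <- function(fit, ped, ids = ped$animal) {
  ids <- as.character(ids)
  u <- fit$ebv_mean
  uv <- fit$ebv_disp
  if (fit$spec$genetic_param == "animal") {
    out <- data.frame(animal = ids,
                      ebv_mean = unname(u[ids]),
                      ebv_disp = unname(uv[ids]))
  } else {
    pos <- match(ids, ped$animal)
    if (anyNA(pos)) stop("ids not in pedigree")
    s <- ped$sire[pos]
    d <- ped$dam[pos]
    pick <- function(v, id) ifelse(is.na(id), 0,
                                   ifelse(is.na(v[id]), 0, v[id]))
    own_m <- ifelse(ids %in% names(u), u[ids], NA)
    own_d <- ifelse(ids %in% names(uv), uv[ids], NA)
    ebv_m <- pick(u, s) + pick(u, d)
    ebv_v <- pick(uv, s) + pick(uv, d)
    # parents themselves are reported as twice their own parental effect
    is_par <- ids %in% names(u) & is.na(s) & is.na(d)
    ebv_m[is_par] <- 2 * own_m[is_par]
    ebv_v[is_par] <- 2 * own_d[is_par]
    out <- data.frame(animal = ids, ebv_mean = unname(ebv_m),
                      ebv_disp = unname(ebv_v))
  }
  rownames(out) <- NULL
  out
}
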