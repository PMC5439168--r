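# Derived genetic parameters of body weight and its uniformity. All pure
# functions of variance components; ratio parameters are clipped to [0, 1]
# with a warning rather than failing, since REML estimates sit near bounds.

#' Phenotypic variance of body weight
#'
#' `sigma2_P = 2 sigma2_u + sigma2_c + sigma2_e` under the sire-dam
#' parameterization (sire plus dam variance is half the additive
#' variance; the Mendelian-sampling half resides in the residual).
#'
#' @param sigma2_u sire-dam (quarter-additive) genetic variance.
#' @param sigma2_c full-sib common-environment variance.
#' @param sigma2_e residual variance of body weight.
#' @return phenotypic variance.
#' @export
phenotypic_variance <- function(sigma2_u, sigma2_c, sigma2_e) {
  .check_nonneg(sigma2_u = sigma2_u, sigma2_c = sigma2_c,
                sigma2_e = sigma2_e)
  2 * sigma2_u + sigma2_c + sigma2_e
}

#' Heritability of body weight
#'
#' `h2 = sigma2_a / sigma2_P`, clipped to `[0, 1]` with a warning.
#'
#' @param sigma2_a additive genetic variance (`4 sigma2_u` under the
#'   sire-dam model).
#' @param sigma2_P phenotypic variance (> 0).
#' @export
heritability_mean <- function(sigma2_a, sigma2_P) {
  if (sigma2_P <= 0) stop("sigma2_P must be > 0")
  .check_nonneg(sigma2_a = sigma2_a)
  .clip01(sigma2_a / sigma2_P, "h2")
}

#' Common-environment ratio of body weight
#' @param sigma2_c common-environment variance.
#' @inheritParams heritability_mean
#' @export
common_env_mean <- function(sigma2_c, sigma2_P) {
  if (sigma2_P <= 0) stop("sigma2_P must be > 0")
  .check_nonneg(sigma2_c = sigma2_c)
  .clip01(sigma2_c / sigma2_P, "c2")
}

#' Heritability of uniformity on the additive scale
#'
#' `h2_v = sigma2_av / (2 sigma2_P^2 + 3 (sigma2_av + sigma2_cv))`.
#' The denominator is the variance of squared phenotypic deviations under
#' normality (twice the squared phenotypic variance) plus the genetic and
#' common-environment variance of the variance itself.
#'
#' @param sigma2_av additive-scale genetic variance of uniformity.
#' @param sigma2_cv additive-scale common-environment variance of
#'   uniformity.
#' @param sigma2_P phenotypic variance of body weight (> 0).
#' @export
heritability_uniformity <- function(sigma2_av, sigma2_cv, sigma2_P) {
  if (sigma2_P <= 0) stop("sigma2_P must be > 0")
  .check_nonneg(sigma2_av = sigma2_av, sigma2_cv = sigma2_cv)
  .clip01(sigma2_av / (2 * sigma2_P^2 + 3 * (sigma2_av + sigma2_cv)),
          "h2_v")
}

#' Common-environment ratio of uniformity
#'
#' Same denominator as [heritability_uniformity()] with `sigma2_cv` in the
#' numerator.
#'
#' @inheritParams heritability_uniformity
#' @export
common_env_uniformity <- function(sigma2_cv, sigma2_av, sigma2_P) {
  if (sigma2_P <= 0) stop("sigma2_P must be > 0")
  .check_nonneg(sigma2_av = sigma2_av, sigma2_cv = sigma2_cv)
  .clip01(sigma2_cv / (2 * sigma2_P^2 + 3 * (sigma2_av + sigma2_cv)),
          "c2_v")
}

#' Genetic coefficient of variation of uniformity
#'
#' `GCV = sqrt(sigma2_av_exp)`: on the exponential scale the genetic
#' standard deviation of the residual variance is already proportional to
#' its mean, so the square root is a scale-free evolvability measure.
#'
#' @param sigma2_av_exp exponential-scale genetic variance of uniformity.
#' @export
gcv_uniformity <- function(sigma2_av_exp) {
  .check_nonneg(sigma2_av_exp = sigma2_av_exp)
  sqrt(sigma2_av_exp)
}

#' Exponential- to additive-scale conversion for uniformity variances
#'
#' First-order linearization of `var(sigma2_E * exp(a_v))` around small
#' `a_v`: the additive-scale variance is the squared mean residual
#' variance times the exponential-scale variance.
#'
#' @param sigma2_e mean fitted residual variance of body weight.
#' @param sigma2_av_exp,sigma2_cv_exp exponential-scale genetic and
#'   common-environment variances of uniformity.
#' @return list with `sigma2_av` and `sigma2_cv`.
#' @export
exp_to_additive <- function(sigma2_e, sigma2_av_exp, sigma2_cv_exp) {
  .check_nonneg(sigma2_e = sigma2_e, sigma2_av_exp = sigma2_av_exp,
                sigma2_cv_exp = sigma2_cv_exp)
  list(sigma2_av = sigma2_e^2 * sigma2_av_exp,
       sigma2_cv = sigma2_e^2 * sigma2_cv_exp)
}

#' Genetic correlation from a covariance and two variances
#'
#' Clipped to `[-1, 1]` with a warning; a zero variance yields `NA` with a
#' warning rather than a silent value.
#'
#' @param cov genetic covariance.
#' @param var1,var2 genetic variances.
#' @export
genetic_correlation <- function(cov, var1, var2) {
  if (var1 <= 0 || var2 <= 0) {
    warning("genetic correlation undefined: zero variance")
    return(NA_real_)
  }
  r <- cov / sqrt(var1 * var2)
  if (abs(r) > 1) {
    warning("genetic correlation clipped from ", format(r))
    r <- sign(r)
  }
  r
}

#' Full parameter set from DHGLM variance components
#'
#' Assembles the reported parameters (phenotypic variance, heritabilities,
#' common-environment ratios, GCV, genetic correlation) from a
#' `"dhglm_varcomps"` object.
#'
#' @param varcomps a `"dhglm_varcomps"` (or `"dhglm_fit"`).
#' @return object of class `"parameter_set"` (named list).
#' @export
genetic_parameters <- function(varcomps) {
  if (inherits(varcomps, "dhglm_fit")) varcomps <- varcomps$varcomps
  vc <- varcomps
  sigma2_P <- phenotypic_variance(vc$sigma2_a / 4, vc$sigma2_c,
                                  vc$sigma2_e)
  addl <- exp_to_additive(vc$sigma2_e, vc$sigma2_av_exp, vc$sigma2_cv_exp)
  structure(list(
    sigma2_P = sigma2_P,
    sigma2_a = vc$sigma2_a,
    sigma2_c = vc$sigma2_c,
    h2 = heritability_mean(vc$sigma2_a, sigma2_P),
    c2 = common_env_mean(vc$sigma2_c, sigma2_P),
    sigma2_av_exp = vc$sigma2_av_exp,
    sigma2_av = addl$sigma2_av,
    sigma2_cv = addl$sigma2_cv,
    h2_v = heritability_uniformity(addl$sigma2_av, addl$sigma2_cv,
                                   sigma2_P),
    c2_v = common_env_uniformity(addl$sigma2_cv, addl$sigma2_av,
                                 sigma2_P),
    gcv = gcv_uniformity(vc$sigma2_av_exp),
    r_g = genetic_correlation(vc$sigma_a_av_exp, vc$sigma2_a,
                              vc$sigma2_av_exp)),
    class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Genetic parameters\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %8.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Write a parameter table across model variants
#'
#' Rows are parameters, columns are model variants, mirroring how such
#' estimates are tabulated in genetic-evaluation reports.
#'
#' @param sets named list of [genetic_parameters()] results.
#' @param path CSV output path.
#' @export
write_parameter_table <- function(sets, path) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  rows <- names(sets[[1]])
  tab <- data.frame(parameter = rows)
  for (nm in names(sets))
    tab[[nm]] <- vapply(rows, function(r) sets[[nm]][[r]], numeric(1))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(vals[[nm]] < 0)) stop(nm, " must be non-negative")
  invisible(NULL)
}

.clip01 <- function(x, what) {
  if (x > 1) {
    warning(what, " clipped from ", format(x), " to 1")
    x <- 1
  }
  x
}
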