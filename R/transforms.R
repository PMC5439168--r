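#' Standardize a phenotype vector
#'
#' Centers to mean 0 and scales to sample variance 1 (divisor `n - 1`).
#' Standardizing body weight before the DHGLM eases convergence; the
#' recorded center and scale allow reporting gains back on the gram scale.
#'
#' @param values numeric vector with at least two distinct values.
#' @return list: `values` (transformed) and `spec` (a `transform_spec`).
#' @export
standardize <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2)
    stop("cannot standardize a constant input")
  center <- mean(values, na.rm = TRUE)
  scale <- stats::sd(values, na.rm = TRUE)
  spec <- transform_spec("standardize", center = center, scale = scale)
  list(values = (values - center) / scale, spec = spec)
}

#' Transform specification
#'
#' @param kind `"standardize"`, `"log"`, or `"boxcox"`.
#' @param lambda Box-Cox exponent (required for `kind = "boxcox"`).
#' @param center,scale affine parameters for `"standardize"`.
#' @return object of class `"transform_spec"`.
#' @export
transform_spec <- function(kind = c("standardize", "log", "boxcox"),
                           lambda = NULL, center = 0, scale = 1) {
  kind <- match.arg(kind)
  if (kind == "boxcox" && is.null(lambda))
    stop("boxcox spec requires lambda")
  if (scale <= 0) stop("scale must be > 0")
  structure(list(kind = kind, lambda = lambda, center = center,
                 scale = scale),
            class = "transform_spec")
}

#' Apply (or invert) a phenotype transform
#'
#' Deterministic elementwise mapping. The Box-Cox branch is
#' `(y^lambda - 1)/lambda`, with the `lambda = 0` limit equal to `log(y)`.
#'
#' @param values numeric vector.
#' @param spec a [transform_spec()].
#' @param inverse if `TRUE`, map transformed values back to the original
#'   scale.
#' @return numeric vector.
#' @export
apply_transform <- function(values, spec, inverse = FALSE) {
  stopifnot(inherits(spec, "transform_spec"))
  if (!inverse && spec$kind %in% c("log", "boxcox") &&
      any(values <= 0, na.rm = TRUE))
    stop(spec$kind, " transform requires strictly positive values")
  switch(spec$kind,
    standardize = if (inverse) values * spec$scale + spec$center
                  else (values - spec$center) / spec$scale,
    log = if (inverse) exp(values) else log(values),
    boxcox = {
      l <- spec$lambda
      if (abs(l) < 1e-12) {
        if (inverse) exp(values) else log(values)
      } else if (inverse) {
        (l * values + 1)^(1 / l)
      } else {
        (values^l - 1) / l
      }
    })
}

#' Box-Cox exponent by profile maximum likelihood
#'
#' Profiles the Box-Cox log-likelihood of the fixed-effects-only mean model
#' (intercept, age covariate, tank, year class) over `lambda`, using a
#' coarse grid followed by golden-section/parabolic refinement
#' ([stats::optimize()]). `lambda` near 0 indicates the log transform.
#'
#' @param phenotypes a phenotype data.frame with columns `weight`, `age`,
#'   `tank`, `year_class` (see [simulate_phenotypes()]), or supply `y` and
#'   `X` directly.
#' @param y optional response overriding `phenotypes$weight`.
#' @param X optional model matrix overriding the default fixed design.
#' @param interval search interval for lambda.
#' @return list: `lambda` (maximizer), `loglik` (profile value at the
#'   maximizer), and `profile(lambda)` the profile log-likelihood function.
#' @export
boxcox_lambda <- function(phenotypes = NULL, y = NULL, X = NULL,
                          interval = c(-2, 2)) {
  if (is.null(y)) {
    stopifnot(!is.null(phenotypes))
    y <- phenotypes$weight
  }
  if (any(y <= 0)) stop("Box-Cox requires strictly positive weights")
  if (is.null(X)) {
    X <- if (!is.null(phenotypes))
      fixed_design(phenotypes)
    else matrix(1, length(y), 1)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("fixed-effect design is rank deficient")
  n <- length(y)
  slog <- sum(log(y))
  profile <- function(lambda) {
    z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
    rss <- sum(qr.resid(qrX, z)^2)
    -n / 2 * log(rss / n) + (lambda - 1) * slog
  }
  grid <- seq(interval[1], interval[2], by = 0.05)
  pl <- vapply(grid, profile, numeric(1))
  i <- which.max(pl)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(profile, c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  list(lambda = opt$maximum, loglik = opt$objective, profile = profile)
}

#' Fixed-effect design matrix of the mean model
#'
#' Intercept, linear age covariate, tank and parental year-class factors
#' (treatment coding). Factor levels holding fewer than two records are
#' merged into the reference level with a warning, which keeps the design
#' identifiable in masked cross-validation subsets.
#'
#' @param phenotypes data.frame with `age`, `tank`, `year_class`.
#' @return numeric model matrix with one row per record.
#' @export
fixed_design <- function(phenotypes) {
  tank <- .merge_rare_levels(factor(phenotypes$tank), "tank")
  yc <- .merge_rare_levels(factor(phenotypes$year_class), "year_class")
  df <- data.frame(age = as.numeric(phenotypes$age), tank = tank,
                   year_class = yc)
  contr <- list()
  if (nlevels(df$tank) > 1) contr$tank <- "contr.treatment"
  if (nlevels(df$year_class) > 1) contr$year_class <- "contr.treatment"
  terms <- c("age",
             if (nlevels(df$tank) > 1) "tank",
             if (nlevels(df$year_class) > 1) "year_class")
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(form, df,
                      contrasts.arg = if (length(contr)) contr else NULL)
}

.merge_rare_levels <- function(f, what) {
  tab <- table(f)
  rare <- names(tab)[tab < 2]
  if (length(rare) && nlevels(f) > 1) {
    ref <- names(tab)[which.max(tab)]
    warning(what, " level(s) with <2 records merged into '", ref, "': ",
            paste(rare, collapse = ", "))
    levels(f)[levels(f) %in% rare] <- ref
  }
  droplevels(f)
}
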