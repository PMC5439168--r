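# Masking cross-validation of (genomic) estimated breeding values.

#' Adjusted phenotypes from a full-data fit
#'
#' Phenotypes with fixed effects removed: `y* = a + c + e` for body weight
#' and `psi* = a_v + c_v + e_v` for its uniformity, using the full-data
#' solutions. Equivalently, response minus fitted fixed effects.
#'
#' @param fit a `"dhglm_fit"` from [fit_dhglm()], or a `"dhglm_blup"`
#'   full-data prediction (empty mask) from [predict_breeding_values()].
#' @return data.frame `animal`, `y_star`, `psi_star`, `genotyped`.
#' @export
adjusted_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "dhglm_fit") || inherits(fit, "dhglm_blup"))
  if (inherits(fit, "dhglm_blup") && length(fit$mask))
    stop("adjusted phenotypes require a full-data fit (no mask)")
  data.frame(animal = fit$animal,
             y_star = fit$y - fit$fitted_fixed_y,
             psi_star = fit$psi - fit$fitted_fixed_psi,
             genotyped = fit$genotyped,
             stringsAsFactors = FALSE)
}

#' Family-stratified fold plan for masking cross-validation
#'
#' Partitions the phenotyped animals into `k` disjoint masks so that each
#' fold holds roughly `1/k` of every family; an animal masked in one fold
#' is never masked again in another.
#'
#' @param phenotypes data.frame with `animal` and `family`.
#' @param k number of folds.
#' @param seed integer seed recorded in the plan.
#' @return object of class `"fold_plan"`: `k`, `seed`, `masks` (list of id
#'   vectors).
#' @export
make_folds <- function(phenotypes, k = 10, seed = 1) {
  stopifnot(k >= 2)
  animal <- as.character(phenotypes$animal)
  fam <- as.character(phenotypes$family)
  if (anyDuplicated(animal)) stop("duplicate animals in phenotype table")
  rng <- .with_seed(seed, {
    fold_of <- integer(length(animal))
    small <- character(0)
    for (f in unique(fam)) {
      members <- which(fam == f)
      if (length(members) < k) small <- c(small, f)
      sh <- sample(members)
      start <- sample.int(k, 1)
      fold_of[sh] <- ((start - 1L + seq_along(sh) - 1L) %% k) + 1L
    }
    list(fold_of = fold_of, small = small)
  })
  if (length(rng$small))
    warning(length(rng$small), " famil(ies) smaller than k spread as ",
            "evenly as possible")
  masks <- lapply(seq_len(k), function(i) animal[rng$fold_of == i])
  structure(list(k = k, seed = seed, masks = masks), class = "fold_plan")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Scaled mean squared error of prediction
#'
#' Mean squared difference between predictions and targets, divided by the
#' sample variance (divisor `n - 1`) of the targets.
#'
#' @param predictions,targets equal-length numeric vectors (n >= 2).
#' @export
msep_scaled <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets),
            length(targets) >= 2)
  v <- stats::var(targets)
  if (v == 0) stop("zero target variance: scaled MSEP undefined")
  mean((predictions - targets)^2) / v
}

#' Rank correlations (Kendall tau-b and Spearman rho)
#'
#' @param x,y numeric vectors of length >= 3.
#' @return named vector `c(kendall = , spearman = )`; `NA` with a warning
#'   for constant input.
#' @export
rank_correlations <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("rank correlation undefined for constant vector")
    return(c(kendall = NA_real_, spearman = NA_real_))
  }
  c(kendall = stats::cor(x, y, method = "kendall"),
    spearman = stats::cor(x, y, method = "spearman"))
}

#' Masking cross-validation of predictive ability
#'
#' For each fold, records of the masked animals are removed, breeding
#' values are re-predicted by BLUP at the supplied (full-fit) variance
#' components, and the per-fold predictive ability is the correlation of
#' the masked, genotyped animals' adjusted phenotypes with their predicted
#' breeding values: `cor(y*, a*)` for weight and `cor(psi*, a_v*)` (also
#' Kendall and Spearman) for uniformity, plus the scaled MSEP of each.
#'
#' @inheritParams predict_breeding_values
#' @param plan a [make_folds()] plan.
#' @param adjusted data.frame from [adjusted_phenotypes()].
#' @param min_masked folds with fewer masked genotyped animals than this
#'   are flagged and excluded from summaries.
#' @param full_fit optional full-data fit or prediction used to warm-start
#'   the per-fold solves (see [predict_breeding_values()]).
#' @return object of class `"crossval_report"`: `per_fold` data.frame and
#'   `summary` (means and standard errors over usable folds).
#' @export
run_crossval <- function(phenotypes, ped, spec, Kinv, varcomps, plan,
                         adjusted, min_masked = 3,
                         control = dhglm_control(), full_fit = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  rows <- list()
  for (fold in seq_len(plan$k)) {
    mask <- plan$masks[[fold]]
    pred <- predict_breeding_values(phenotypes, ped, spec, Kinv, varcomps,
                                    mask = mask, control = control,
                                    warm_start = full_fit)
    ebv <- animal_ebv(pred, ped, ids = mask)
    adj <- adjusted[match(mask, adjusted$animal), , drop = FALSE]
    use <- adj$genotyped & !is.na(adj$y_star)
    n_use <- sum(use)
    if (n_use < min_masked) {
      rows[[fold]] <- data.frame(fold = fold, n_masked_genotyped = n_use,
                                 usable = FALSE,
                                 pearson_weight = NA, msep_weight = NA,
                                 pearson_unif = NA, kendall_unif = NA,
                                 spearman_unif = NA, msep_unif = NA)
      next
    }
    ys <- adj$y_star[use]; ps <- adj$psi_star[use]
    am <- ebv$ebv_mean[use]; av <- ebv$ebv_disp[use]
    rk <- rank_correlations(ps, av)
    rows[[fold]] <- data.frame(
      fold = fold, n_masked_genotyped = n_use, usable = TRUE,
      pearson_weight = stats::cor(ys, am),
      msep_weight = msep_scaled(am, ys),
      pearson_unif = stats::cor(ps, av),
      kendall_unif = rk[["kendall"]],
      spearman_unif = rk[["spearman"]],
      msep_unif = msep_scaled(av, ps))
  }
  per_fold <- do.call(rbind, rows)
  ok <- per_fold$usable
  metrics <- c("pearson_weight", "msep_weight", "pearson_unif",
               "kendall_unif", "spearman_unif", "msep_unif")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]][ok]),
                  numeric(1)),
    se = vapply(metrics, function(m)
      stats::sd(per_fold[[m]][ok]) / sqrt(sum(ok)), numeric(1)))
  structure(list(per_fold = per_fold, summary = summ, k = plan$k,
                 seed = plan$seed, n_usable_folds = sum(ok)),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("%d-fold masking cross-validation (seed %s, %d usable folds)\n",
              x$k, format(x$seed), x$n_usable_folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Confidence interval of a fold-metric difference between two models
#'
#' `d = mean(m1) - mean(m2)` with `SE_d = sqrt((SD1^2 + SD2^2)/k)` and a
#' 95% normal interval; the difference is flagged significant when 0 lies
#' outside the interval.
#'
#' @param metric_folds_model1,metric_folds_model2 per-fold metric vectors
#'   of equal length `k >= 2`.
#' @return list `d`, `lower`, `upper`, `significant`.
#' @export
difference_ci <- function(metric_folds_model1, metric_folds_model2) {
  k <- length(metric_folds_model1)
  if (k < 2 || length(metric_folds_model2) != k)
    stop("need equal fold counts with k >= 2")
  d <- mean(metric_folds_model1) - mean(metric_folds_model2)
  se <- sqrt((stats::sd(metric_folds_model1)^2 +
                stats::sd(metric_folds_model2)^2) / k)
  lower <- d - 1.96 * se
  upper <- d + 1.96 * se
  list(d = d, lower = lower, upper = upper,
       significant = (lower > 0) || (upper < 0))
}

#' Compare residual estimates between two fits
#'
#' Least-squares slope and Pearson correlation of the residuals of one fit
#' against the other, reported separately for genotyped and non-genotyped
#' animals: the scatter that reveals how much genomic relationships
#' re-apportion individual residuals.
#'
#' @param fit_A,fit_H fits (`"dhglm_fit"` or `"mean_model_fit"`) on the
#'   identical records.
#' @return list of class `"residual_comparison"` with `genotyped` and
#'   `non_genotyped` sublists (`slope`, `correlation`, `n`) and a
#'   `scatter` data.frame for plotting.
#' @export
compare_residual_estimates <- function(fit_A, fit_H) {
  if (!identical(fit_A$animal, fit_H$animal))
    stop("fits are not on identical phenotype records")
  df <- data.frame(animal = fit_A$animal,
                   resid_A = fit_A$residuals,
                   resid_H = fit_H$residuals,
                   genotyped = fit_A$genotyped)
  per_group <- function(sub) {
    if (nrow(sub) < 3 || stats::sd(sub$resid_H) == 0)
      return(list(slope = NA_real_, correlation = NA_real_,
                  n = nrow(sub)))
    co <- stats::coef(stats::lm(resid_A ~ resid_H, data = sub))
    list(slope = unname(co[2]),
         correlation = stats::cor(sub$resid_A, sub$resid_H),
         n = nrow(sub))
  }
  structure(list(genotyped = per_group(df[df$genotyped, ]),
                 non_genotyped = per_group(df[!df$genotyped, ]),
                 scatter = df),
            class = "residual_comparison")
}

#' @export
print.residual_comparison <- function(x, ...) {
  cat(sprintf(
    "residuals A vs H: genotyped slope %.3f r %.3f (n=%d); non-genotyped slope %.3f r %.3f (n=%d)\n",
    x$genotyped$slope, x$genotyped$correlation, x$genotyped$n,
    x$non_genotyped$slope, x$non_genotyped$correlation,
    x$non_genotyped$n))
  invisible(x)
}
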