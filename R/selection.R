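# Index selection on (G)EBV pairs and realized genetic gain.

#' Selection index over breeding-value pairs
#'
#' `I = b1 * GEBV_mean - b2 * GEBV_disp`: weight on growth minus weight on
#' variability, so larger `b2` selects harder for uniformity.
#'
#' @param gebv_mean,gebv_disp aligned named numeric vectors of breeding
#'   values for the trait mean and its variability.
#' @param b1,b2 relative index weights (conventionally `b1 + b2 = 1`).
#' @return named numeric vector of index values.
#' @export
compute_index <- function(gebv_mean, gebv_disp, b1 = 0.5, b2 = 0.5) {
  if (length(gebv_mean) != length(gebv_disp))
    stop("GEBV vectors must be aligned and of equal length")
  if (!is.null(names(gebv_mean)) && !is.null(names(gebv_disp)) &&
      !identical(names(gebv_mean), names(gebv_disp)))
    stop("GEBV vectors have misaligned ids")
  out <- b1 * gebv_mean - b2 * gebv_disp
  names(out) <- names(gebv_mean)
  out
}

#' Truncation selection
#'
#' Selects the top `ceiling(proportion * n)` candidates by index value;
#' ties are broken by id order for determinism.
#'
#' @param index named numeric vector of index values.
#' @param proportion selected fraction in `(0, 1]`.
#' @return character vector of selected ids (or integer positions when the
#'   index is unnamed).
#' @export
truncation_select <- function(index, proportion = 0.10) {
  if (!length(index)) stop("empty candidate list")
  stopifnot(proportion > 0, proportion <= 1)
  n_sel <- ceiling(proportion * length(index))
  ids <- if (is.null(names(index))) as.character(seq_along(index))
         else names(index)
  ord <- order(-index, ids)
  ids[ord[seq_len(n_sel)]]
}

#' Realized genetic gain of a selected group
#'
#' Gain per trait is the mean (G)EBV of the selected candidates minus the
#' mean over all candidates (selection differential on the EBV scale); the
#' percent form divides by the phenotypic mean on the observed scale.
#'
#' @param selected ids of the selected candidates.
#' @param gebv data.frame with columns `animal`, `ebv_mean`, `ebv_disp`
#'   (as from [animal_ebv()]).
#' @param trait_mean observed-scale phenotypic mean used for the percent
#'   form (e.g. mean body weight in grams); `NULL` skips it.
#' @return list with `gain_mean`, `gain_disp` and (when `trait_mean` is
#'   given) `gain_mean_pct`, `gain_disp_pct`.
#' @export
genetic_gain <- function(selected, gebv, trait_mean = NULL) {
  if (!length(selected)) stop("empty selection")
  idx <- match(as.character(selected), as.character(gebv$animal))
  if (anyNA(idx)) stop("selected id(s) not in GEBV table")
  gm <- mean(gebv$ebv_mean[idx]) - mean(gebv$ebv_mean)
  gv <- mean(gebv$ebv_disp[idx]) - mean(gebv$ebv_disp)
  out <- list(gain_mean = gm, gain_disp = gv)
  if (!is.null(trait_mean)) {
    if (trait_mean == 0) stop("zero trait mean: percent gain undefined")
    out$gain_mean_pct <- 100 * gm / trait_mean
    out$gain_disp_pct <- 100 * gv / trait_mean
  }
  out
}
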