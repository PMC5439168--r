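#' Construct a pedigree
#'
#' A pedigree is an ordered parent map: every animal appears after both of
#' its parents, unknown parents are the explicit sentinel `NA` (or `"0"` /
#' `""` in files). The numerator relationship matrix, its sparse inverse,
#' and gene-dropping simulations are all built from this object.
#'
#' @param animal character or integer vector of animal identifiers.
#' @param sire,dam parent identifiers aligned with `animal`; `NA`, `"0"` or
#'   `""` mark an unknown parent.
#' @param reorder if `TRUE`, topologically sort the records so parents
#'   precede offspring (an error is raised on cycles). If `FALSE` the given
#'   order must already be valid.
#'
#' @return An object of class `"pedigree"`: a data.frame with columns
#'   `animal`, `sire`, `dam` (character, `NA` for unknown) and an attached
#'   `generation` attribute (0 for founders, 1 + max parental generation
#'   otherwise).
#' @examples
#' ped <- pedigree(c("S", "D", "O1", "O2"),
#'                 c(NA, NA, "S", "S"),
#'                 c(NA, NA, "D", "D"))
#' relationship_matrix(ped)
#' @export
pedigree <- function(animal, sire, dam, reorder = FALSE) {
  animal <- as.character(animal)
  sire <- .clean_parent(sire)
  dam <- .clean_parent(dam)
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  unknown_parents <- setdiff(c(sire, dam), c(animal, NA))
  if (length(unknown_parents))
    stop("parent id(s) not in pedigree: ",
         paste(unknown_parents, collapse = ", "),
         " (add them as founders)")
  if (reorder) ped <- .toposort_pedigree(ped)
  .check_pedigree_order(ped)
  attr(ped, "generation") <- .pedigree_generations(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA")] <- NA_character_
  x
}

.check_pedigree_order <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    bad <- which(!is.na(p) & pos[p] >= pos)
    if (length(bad))
      stop("pedigree not ordered: ", col, " of animal '",
           ped$animal[bad[1]], "' does not precede it (use reorder = TRUE)")
  }
  invisible(ped)
}

.toposort_pedigree <- function(ped) {
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  placed <- logical(n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      s <- ped$sire[i]; d <- ped$dam[i]
      (is.na(s) || placed[pos[s]]) && (is.na(d) || placed[pos[d]])
    }, logical(1))]
    if (!length(ready)) {
      if (length(remaining))
        stop("pedigree contains a cycle involving animal '",
             ped$animal[remaining[1]], "'")
      break
    }
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  ped[order_out, , drop = FALSE]
}

.pedigree_generations <- function(ped) {
  gen <- integer(nrow(ped))
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire[i]; d <- ped$dam[i]
    gs <- if (is.na(s)) -1L else gen[pos[s]]
    gd <- if (is.na(d)) -1L else gen[pos[d]]
    gen[i] <- max(gs, gd) + 1L
  }
  names(gen) <- ped$animal
  gen
}

#' Read a pedigree from CSV
#'
#' Expects a header with columns `animal,sire,dam`; `"0"` or an empty field
#' marks an unknown parent.
#'
#' @param path file path.
#' @param reorder passed to [pedigree()].
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path, reorder = TRUE) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns animal,sire,dam")
  pedigree(df$animal, df$sire, df$dam, reorder = reorder)
}

#' Write a pedigree to CSV
#' @param ped a [pedigree()] object.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix A over all animals
#' in the pedigree. Diagonals are `1 + F_i` where `F_i` is the inbreeding
#' coefficient (half the relationship between the parents); unknown parents
#' contribute no relationship.
#'
#' @param ped a [pedigree()] object.
#' @param ids optional subset of animal ids for which the submatrix is
#'   returned (the full recursion still runs over all ancestors).
#' @return a [relationship_structure()] of kind `"A"` (or the submatrix
#'   over `ids`).
#' @export
relationship_matrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  A <- matrix(0, n, n)
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (si[i] > 0L) A[si[i], j] else 0
      row_d <- if (di[i] > 0L) A[di[i], j] else 0
      aij <- 0.5 * (row_s + row_d)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (si[i] > 0L && di[i] > 0L) 0.5 * A[si[i], di[i]] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, ped$animal)
    if (length(missing_ids))
      stop("ids not in pedigree: ", paste(missing_ids, collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  }
  relationship_structure(A, kind = "A")
}

#' Inbreeding coefficients
#'
#' @param ped a [pedigree()] object.
#' @return named numeric vector of inbreeding coefficients `F_i`.
#' @export
inbreeding <- function(ped) {
  A <- relationship_matrix(ped)$values
  f <- diag(A) - 1
  names(f) <- ped$animal
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with full accounting for inbreeding: the Mendelian
#' sampling variance of animal i is `0.5 - 0.25 (F_s + F_d)` with both
#' parents known, `0.75 - 0.25 F_p` with one, and 1 for founders.
#'
#' @param ped a [pedigree()] object.
#' @return a [relationship_structure()] of kind `"A_inverse"` holding a
#'   sparse symmetric `Matrix`.
#' @export
relationship_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  f <- inbreeding(ped)
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  fs <- ifelse(si > 0L, f[pmax(si, 1L)], 0)
  fd <- ifelse(di > 0L, f[pmax(di, 1L)], 0)
  m <- 1 - 0.25 * (ifelse(si > 0L, 1 + fs, 0) + ifelse(di > 0L, 1 + fd, 0))
  dinv <- 1 / m
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i
    jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, dinv)
  both <- si > 0L & di > 0L
  one_s <- si > 0L
  one_d <- di > 0L
  if (any(one_s)) {
    add(idx[one_s], si[one_s], -0.5 * dinv[one_s])
    add(si[one_s], idx[one_s], -0.5 * dinv[one_s])
    add(si[one_s], si[one_s], 0.25 * dinv[one_s])
  }
  if (any(one_d)) {
    add(idx[one_d], di[one_d], -0.5 * dinv[one_d])
    add(di[one_d], idx[one_d], -0.5 * dinv[one_d])
    add(di[one_d], di[one_d], 0.25 * dinv[one_d])
  }
  if (any(both)) {
    add(si[both], di[both], 0.25 * dinv[both])
    add(di[both], si[both], 0.25 * dinv[both])
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  relationship_structure(Ainv, kind = "A_inverse")
}

#' Parental pedigree restriction
#'
#' Returns the ids of all animals that appear as a sire or dam anywhere in
#' the pedigree, together with their ancestors, in pedigree order. This is
#' the genetic-effect index set of the sire-dam model: individuals that are
#' never parents carry no information about the parental effects and can be
#' dropped from its relationship structure.
#'
#' @param ped a [pedigree()] object.
#' @return character vector of ids in pedigree order.
#' @export
parental_ids <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  keep <- ped$animal %in% c(ped$sire, ped$dam)
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  # ancestors close upward: walk in reverse order marking parents of kept
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (!is.na(s)) keep[pos[s]] <- TRUE
      if (!is.na(d)) keep[pos[d]] <- TRUE
    }
  }
  ped$animal[keep]
}
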