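#' Labeled symmetric relationship structure
#'
#' Container for the relationship matrices the evaluation moves between:
#' pedigree (`A`), its genotyped block (`A22`), genomic (`G`), combined
#' single-step (`H`) and the inverses used in the mixed-model equations.
#'
#' @param values symmetric numeric matrix (base or `Matrix`), with row and
#'   column names giving animal ids (or supply `ids`).
#' @param kind one of `"A"`, `"A_inverse"`, `"A22"`, `"G"`, `"H"`,
#'   `"H_inverse"`, `"G_inverse"`, `"A22_inverse"`.
#' @param ids optional id vector overriding `dimnames(values)`.
#' @param tol symmetry tolerance.
#' @return an object of class `"relationship_structure"` with elements
#'   `ids`, `values`, `kind`.
#' @export
relationship_structure <- function(values, kind, ids = NULL, tol = 1e-10) {
  kinds <- c("A", "A_inverse", "A22", "G", "H", "H_inverse",
             "G_inverse", "A22_inverse")
  kind <- match.arg(kind, kinds)
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) stop("relationship structure needs animal ids")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate ids in relationship structure")
  if (nrow(values) != length(ids) || ncol(values) != length(ids))
    stop("matrix dimensions do not match id list")
  if (length(ids)) {
    asym <- max(abs(values - Matrix::t(values)))
    if (asym > tol)
      stop("matrix is not symmetric (max asymmetry ", format(asym), ")")
  }
  if (!grepl("inverse", kind) && any(Matrix::diag(values) < 0))
    stop("negative diagonal in a relationship matrix of kind ", kind)
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind),
            class = "relationship_structure")
}

#' @export
print.relationship_structure <- function(x, ...) {
  cat(sprintf("relationship_structure kind=%s over %d ids\n",
              x$kind, length(x$ids)))
  invisible(x)
}

#' Extract a labeled submatrix
#' @param rel a [relationship_structure()].
#' @param ids ids to keep.
#' @param kind kind label for the result (default: unchanged).
#' @export
subset_relationship <- function(rel, ids, kind = rel$kind) {
  missing_ids <- setdiff(ids, rel$ids)
  if (length(missing_ids))
    stop("ids not present: ", paste(missing_ids, collapse = ", "))
  relationship_structure(rel$values[ids, ids, drop = FALSE], kind = kind)
}

#' Invert a relationship structure
#'
#' Dense symmetric inversion with an informative failure mode: a singular
#' genomic matrix is the expected outcome of `G = WW'/N` when the SNP count
#' is below the animal count, and the fix is to blend towards the pedigree
#' block first (see [blend_genomic()]).
#'
#' @param rel a [relationship_structure()].
#' @return a [relationship_structure()] of the matching inverse kind.
#' @export
invert_relationship <- function(rel) {
  inv_kind <- switch(rel$kind,
                     A = "A_inverse", G = "G_inverse", A22 = "A22_inverse",
                     H = "H_inverse",
                     stop("no inverse kind defined for ", rel$kind))
  V <- as.matrix(rel$values)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    if (rel$kind == "G")
      stop("G is singular; blend towards A22 first (blend_genomic())")
    stop("relationship matrix of kind ", rel$kind, " is singular")
  }
  Vi <- chol2inv(ch)
  dimnames(Vi) <- dimnames(V)
  relationship_structure((Vi + t(Vi)) / 2, kind = inv_kind)
}

#' Blend a genomic relationship matrix with its pedigree counterpart
#'
#' `G* = w G + (1 - w) A22` restores full rank before inversion; `w = 0.99`
#' is conventional single-step practice.
#'
#' @param G [relationship_structure()] of kind `"G"`.
#' @param A22 [relationship_structure()] of kind `"A22"` (or `"A"` over the
#'   same ids).
#' @param weight blending weight on G.
#' @return blended [relationship_structure()] of kind `"G"`.
#' @export
blend_genomic <- function(G, A22, weight = 0.99) {
  stopifnot(weight > 0, weight <= 1)
  if (!identical(G$ids, A22$ids))
    stop("G and A22 must be indexed by the same ids in the same order")
  relationship_structure(weight * as.matrix(G$values) +
                           (1 - weight) * as.matrix(A22$values),
                         kind = "G")
}

#' Tune a genomic relationship matrix to the pedigree base
#'
#' Genomic relationships computed with allele frequencies from the
#' currently genotyped animals are expressed relative to that group's own
#' mean, while pedigree relationships are relative to the founder
#' population; when the genotyped group is a related subset the two
#' scales disagree and the combined matrix degrades. The standard
#' compatibility adjustment regresses `G* = a + b G` so that the mean
#' diagonal and mean off-diagonal of `G*` match those of `A22`.
#'
#' @param G [relationship_structure()] of kind `"G"`.
#' @param A22 pedigree block over the same ids.
#' @return adjusted [relationship_structure()] of kind `"G"`.
#' @export
tune_genomic <- function(G, A22) {
  if (!identical(G$ids, A22$ids))
    stop("G and A22 must be indexed by the same ids in the same order")
  Gm <- as.matrix(G$values)
  Am <- as.matrix(A22$values)
  dg <- mean(diag(Gm)); da <- mean(diag(Am))
  og <- mean(Gm); oa <- mean(Am)
  if (abs(dg - og) < 1e-12)
    stop("degenerate G: cannot separate diagonal and off-diagonal means")
  b <- (da - oa) / (dg - og)
  a <- oa - b * og
  relationship_structure(a + b * Gm, kind = "G")
}

#' Combined pedigree-genomic relationship matrix (direct block form)
#'
#' Builds the single-step H matrix over all pedigree animals. The
#' non-genotyped block is corrected by propagating the genomic deviation
#' `G - A22` through the pedigree regression `A12 A22^-1`:
#' `H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21`,
#' `H12 = A12 A22^-1 G`, `H22 = G`.
#'
#' @param A [relationship_structure()] of kind `"A"` over all animals.
#' @param G [relationship_structure()] of kind `"G"` over the genotyped
#'   animals (blend first if it is to match [build_H_inverse()]).
#' @param genotyped_ids ids of the genotyped animals; must all be in `A`
#'   and index `G` exactly.
#' @return [relationship_structure()] of kind `"H"` over `A$ids`.
#' @export
build_H_direct <- function(A, G, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  bad <- setdiff(genotyped_ids, A$ids)
  if (length(bad))
    stop("genotyped ids missing from A: ", paste(bad, collapse = ", "))
  if (!setequal(G$ids, genotyped_ids) ||
      !identical(sort(G$ids), sort(genotyped_ids)))
    stop("G must be indexed exactly by genotyped_ids")
  if (!length(genotyped_ids)) return(relationship_structure(A$values, "H"))
  Gm <- as.matrix(G$values)[genotyped_ids, genotyped_ids, drop = FALSE]
  ids1 <- setdiff(A$ids, genotyped_ids)
  Am <- as.matrix(A$values)
  A22 <- Am[genotyped_ids, genotyped_ids, drop = FALSE]
  A22i <- chol2inv(chol(A22))
  H <- matrix(0, length(A$ids), length(A$ids),
              dimnames = list(A$ids, A$ids))
  if (length(ids1)) {
    A11 <- Am[ids1, ids1, drop = FALSE]
    A12 <- Am[ids1, genotyped_ids, drop = FALSE]
    P <- A12 %*% A22i                       # pedigree regression on genotyped
    H11 <- A11 + P %*% (Gm - A22) %*% t(P)
    H12 <- P %*% Gm
    H[ids1, ids1] <- (H11 + t(H11)) / 2
    H[ids1, genotyped_ids] <- H12
    H[genotyped_ids, ids1] <- t(H12)
  }
  H[genotyped_ids, genotyped_ids] <- (Gm + t(Gm)) / 2
  relationship_structure(H, kind = "H")
}

#' Inverse of the combined relationship matrix (single-step shortcut)
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]` on the genotyped block: the whole
#' pedigree inverse plus a dense correction among genotyped animals only,
#' avoiding construction and inversion of the full H.
#'
#' @param A_inverse [relationship_structure()] kind `"A_inverse"` over all
#'   animals.
#' @param G_inverse [relationship_structure()] kind `"G_inverse"` over the
#'   genotyped animals (invert a blended G if singular).
#' @param A22_inverse [relationship_structure()] kind `"A22_inverse"` over
#'   the genotyped animals.
#' @param genotyped_ids genotyped animal ids.
#' @return [relationship_structure()] of kind `"H_inverse"` (sparse except
#'   for the genotyped block).
#' @export
build_H_inverse <- function(A_inverse, G_inverse, A22_inverse,
                            genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  if (!length(genotyped_ids))
    return(relationship_structure(A_inverse$values, "H_inverse"))
  bad <- setdiff(genotyped_ids, A_inverse$ids)
  if (length(bad))
    stop("genotyped ids missing from A_inverse: ",
         paste(bad, collapse = ", "))
  for (obj in list(G_inverse, A22_inverse))
    if (!setequal(obj$ids, genotyped_ids))
      stop("G_inverse and A22_inverse must be indexed by genotyped_ids")
  Ai <- methods::as(methods::as(A_inverse$values, "generalMatrix"),
                    "CsparseMatrix")
  corr <- as.matrix(G_inverse$values)[genotyped_ids, genotyped_ids] -
    as.matrix(A22_inverse$values)[genotyped_ids, genotyped_ids]
  idx <- match(genotyped_ids, A_inverse$ids)
  ng <- length(idx)
  corr_sp <- Matrix::sparseMatrix(
    i = rep(idx, times = ng), j = rep(idx, each = ng),
    x = as.numeric(corr), dims = dim(Ai))
  Hi <- Ai + corr_sp
  Hi <- (Hi + Matrix::t(Hi)) / 2
  dimnames(Hi) <- dimnames(Ai)
  relationship_structure(Hi, kind = "H_inverse")
}

#' Export a relationship structure
#'
#' Dense kinds are written as a labeled CSV; inverse kinds as coordinate
#' triplets (`row_id,col_id,value`, upper triangle included once).
#'
#' @param rel a [relationship_structure()].
#' @param path output file.
#' @export
write_relationship <- function(rel, path) {
  if (grepl("inverse", rel$kind)) {
    M <- methods::as(methods::as(rel$values, "generalMatrix"),
                     "TsparseMatrix")
    keep <- M@i <= M@j
    df <- data.frame(row_id = rel$ids[M@i[keep] + 1L],
                     col_id = rel$ids[M@j[keep] + 1L],
                     value = M@x[keep])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    M <- as.matrix(rel$values)
    utils::write.csv(data.frame(id = rel$ids, M, check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
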