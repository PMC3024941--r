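# Principal coordinates analysis (metric MDS) of a region distance
# matrix.  No correction for negative eigenvalues is applied: axes with
# negative eigenvalues occur at higher orders and are simply discarded
# (correcting was found to distort the configuration).  A deterministic
# sign convention makes the downstream integer codes reproducible across
# runs and platforms.

#' Principal coordinates analysis, positive axes only
#'
#' Gower double-centering `B = -1/2 * J (D o D) J` with
#' `J = I - 11'/n`, symmetric eigendecomposition, axes sorted by
#' descending eigenvalue; axes with eigenvalues at or below
#' `tol * lambda_max` are discarded, and no Lingoes/Cailliez correction
#' is applied.  Axis `j` is scaled by `sqrt(lambda_j)` so that Euclidean
#' distances of the coordinates approximate the input distances.  Each
#' axis is reflected so that its largest-magnitude loading is positive
#' (ties broken by lowest OTU index); tied eigenvalues are ordered by
#' their first differing coordinate.
#'
#' @param D a `"dist_matrix"` (see [region_matrix()]), or a symmetric
#'   numeric matrix with zero diagonal.
#' @param tol relative eigenvalue tolerance for "positive".
#' @return object of class `"pcoa"`: `names`, `eigenvalues` (retained,
#'   decreasing), `coords` (n x m), `all_eigenvalues`.
#' @export
pcoa <- function(D, tol = 1e-8) {
  if (inherits(D, "dist_matrix")) {
    nms <- D$names; D <- D$d
  } else {
    D <- as.matrix(D)
    nms <- rownames(D)
    if (is.null(nms)) nms <- paste0("s", seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (n < 2L) stop("PCoA needs at least two objects")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  A <- -0.5 * D * D
  B <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lmax <- max(e$values, 0)
  keep <- which(e$values > tol * lmax & e$values > 0)
  if (lmax == 0 || length(keep) == 0L) {
    return(structure(list(names = nms, eigenvalues = numeric(0),
                          coords = matrix(0, n, 0,
                                          dimnames = list(nms, NULL)),
                          all_eigenvalues = e$values),
                     class = "pcoa"))
  }
  lambda <- e$values[keep]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lambda),
                                                    length(keep))
  # sign convention: largest-|loading| entry positive, first index on ties
  for (j in seq_len(ncol(coords))) {
    i0 <- which.max(abs(coords[, j]))
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  # deterministic order within tied-eigenvalue groups
  ord <- order_tied_axes(lambda, coords, tol)
  lambda <- lambda[ord]
  coords <- coords[, ord, drop = FALSE]
  dimnames(coords) <- list(nms, paste0("axis", seq_along(lambda)))
  structure(list(names = nms, eigenvalues = lambda, coords = coords,
                 all_eigenvalues = e$values),
            class = "pcoa")
}

order_tied_axes <- function(lambda, coords, tol) {
  ord <- seq_along(lambda)
  if (length(lambda) < 2L) return(ord)
  scale <- max(lambda)
  grp <- cumsum(c(TRUE, diff(lambda) < -tol * scale * 10))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    # lexicographic by coordinate vectors (keys: OTU 1, OTU 2, ...)
    keys <- unname(as.data.frame(t(round(coords[, idx, drop = FALSE], 10))))
    ord[idx] <- idx[do.call(order, c(keys, list(decreasing = TRUE)))]
  }
  ord
}

#' @export
print.pcoa <- function(x, ...) {
  cat("PCoA:", length(x$names), "objects,", length(x$eigenvalues),
      "positive axes retained\n")
  if (length(x$eigenvalues)) {
    cat("eigenvalues:", paste(signif(head(x$eigenvalues, 6), 4),
                              collapse = ", "),
        if (length(x$eigenvalues) > 6) "...\n" else "\n")
  }
  invisible(x)
}

#' Fraction of positive-axis variance explained per retained axis
#'
#' @param ord a [pcoa()] result.
#' @return numeric vector `lambda_j / sum(lambda)`, non-increasing,
#'   summing to 1 over retained axes (empty when no axis is retained).
#' @export
explained_variance <- function(ord) {
  stopifnot(inherits(ord, "pcoa"))
  if (length(ord$eigenvalues) == 0L) return(numeric(0))
  ord$eigenvalues / sum(ord$eigenvalues)
}

#' Write ordination coordinates and eigenvalues
#'
#' Coordinates as a tab-delimited OTU-by-axis table, eigenvalues in a
#' `.eig` sidecar.
#'
#' @param ord a [pcoa()] result.
#' @param prefix output path prefix; writes `<prefix>.coords.tsv` and
#'   `<prefix>.eig.tsv`.
#' @return the two paths, invisibly.
#' @export
write_ordination <- function(ord, prefix) {
  stopifnot(inherits(ord, "pcoa"))
  cpath <- paste0(prefix, ".coords.tsv")
  epath <- paste0(prefix, ".eig.tsv")
  df <- data.frame(otu = ord$names, ord$coords, check.names = FALSE)
  utils::write.table(df, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(axis = seq_along(ord$eigenvalues),
               eigenvalue = ord$eigenvalues,
               explained = explained_variance(ord)),
    epath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cpath, epath))
}
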