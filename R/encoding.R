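# Rescaling of principal coordinates to k-state ordered integer codes.
#
# Per axis, S_Range = S_max - S_min; the maximum range across axes,
# S_Range(max), is the common denominator:
#     S_rescaled = (S_OTU - S_min) / S_Range(max)
# so the widest axis spans exactly [0, 1] and narrower axes are
# compressed towards 0 - the encoding is thereby proportional to the
# spread each axis carries.  Rescaled scores become integers via
#     INT = round(S_rescaled * (k - 0.01) - 0.495)
# which for the default k = 10 is exactly "multiply by 9.99, subtract
# 0.495, round", giving ordered states 0..9 in nearly equal pre-rounding
# intervals of 1.0.

#' Rescale ordination coordinates by the maximum axis range
#'
#' @param coords numeric matrix of principal coordinates (OTUs x axes),
#'   or a [pcoa()] object.
#' @return list with `scores` (matrix of rescaled values in `[0, 1]`),
#'   `s_min`, `s_range` (per axis) and `s_range_max`; `NULL` if every
#'   axis is constant (degenerate region).
#' @export
rescale_scores <- function(coords) {
  if (inherits(coords, "pcoa")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (ncol(coords) == 0L) return(NULL)
  s_min <- apply(coords, 2, min)
  s_max <- apply(coords, 2, max)
  s_range <- s_max - s_min
  s_range_max <- max(s_range)
  if (s_range_max <= 0) return(NULL)
  scores <- sweep(coords, 2, s_min) / s_range_max
  list(scores = scores, s_min = s_min, s_range = s_range,
       s_range_max = s_range_max)
}

# round half away from zero (language-default banker's rounding would
# silently shift codes at exact .5 boundaries)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert rescaled scores to k-state ordered integer codes
#'
#' @param scores numeric vector or matrix of rescaled values in `[0, 1]`.
#' @param k number of states, between 2 and 64 (default 10).
#' @return integer codes in `[0, k - 1]`, same shape as `scores`.
#' @examples
#' to_codes(c(0, 0.55, 1))        # 0 5 9
#' @export
to_codes <- function(scores, k = 10L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 64L) stop("states k must be in [2, 64]")
  s <- as.numeric(scores)
  if (any(s < -1e-9 | s > 1 + 1e-9, na.rm = TRUE))
    stop("rescaled scores must lie in [0, 1]")
  s <- pmin(pmax(s, 0), 1)
  codes <- round_half_away(s * (k - 0.01) - 0.495)
  storage.mode(codes) <- "integer"
  if (is.matrix(scores)) {
    dim(codes) <- dim(scores)
    dimnames(codes) <- dimnames(scores)
  }
  codes
}

new_code_matrix <- function(names, codes, k, axis_weights,
                            region_label = "region") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  rownames(codes) <- names
  structure(list(names = names, codes = codes, k = as.integer(k),
                 axis_weights = axis_weights,
                 region_label = region_label),
            class = "code_matrix")
}

#' @export
print.code_matrix <- function(x, ...) {
  cat(sprintf("PICS-Ord codes for %s: %d OTUs x %d characters (%d states)\n",
              x$region_label, nrow(x$codes), ncol(x$codes), x$k))
  if (ncol(x$codes)) {
    for (i in head(seq_len(nrow(x$codes)), 6L))
      cat(sprintf("  %-12s %s\n", x$names[i],
                  paste(render_codes(x$codes[i, ], x$k), collapse = "")))
    if (nrow(x$codes) > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' Drop invariant code columns
#'
#' Columns in which all OTUs share one state carry no phylogenetic
#' information and are removed, together with their axis weights.
#' Idempotent.
#'
#' @param cm a `"code_matrix"`.
#' @return the filtered `"code_matrix"` (possibly with zero columns).
#' @export
drop_invariant <- function(cm) {
  stopifnot(inherits(cm, "code_matrix"))
  if (ncol(cm$codes) == 0L) return(cm)
  keep <- apply(cm$codes, 2, function(col) length(unique(col)) >= 2L)
  cm$codes <- cm$codes[, keep, drop = FALSE]
  cm$axis_weights <- cm$axis_weights[keep]
  cm
}

#' Encode one ambiguous region as ordered integer characters
#'
#' The full per-region pipeline: [region_matrix()] (pairwise distances)
#' -> [pcoa()] (positive axes only) -> [rescale_scores()] ->
#' [to_codes()] -> [drop_invariant()].  Identical region sequences are
#' guaranteed identical code rows.
#'
#' @inheritParams region_matrix
#' @param k number of code states (default 10).
#' @param tol eigenvalue tolerance passed to [pcoa()].
#' @return a `"code_matrix"`; zero columns when the region is invariant.
#' @export
encode_region <- function(aln, region,
                          engine = c("zeta", "identity", "cost"),
                          model = NULL, k = 10L, tol = 1e-8) {
  engine <- match.arg(engine)
  dm <- region_matrix(aln, region, engine, model)
  ord <- pcoa(dm, tol = tol)
  rs <- rescale_scores(ord)
  if (is.null(rs)) {
    return(new_code_matrix(dm$names,
                           matrix(integer(0), length(dm$names), 0),
                           k, numeric(0), region$label))
  }
  codes <- to_codes(rs$scores, k)
  cm <- new_code_matrix(dm$names, codes, k, explained_variance(ord),
                        region$label)
  drop_invariant(cm)
}

# RAxML multi-state rendering: 0-9 then A-V covers 32 states; the NEXUS
# path extends through lower case and two extra symbols to 64
code_symbols <- c(0:9, LETTERS, letters, "@", "~")

render_codes <- function(codes, k) {
  if (k > 64L) stop("at most 64 states supported")
  code_symbols[codes + 1L]
}
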