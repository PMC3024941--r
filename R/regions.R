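# Automatic delimitation of ambiguous regions.
#
# Mirrors the manual flank rule: slide a 5-column window along the
# alignment; a window is "conserved" if it is gap-free in every OTU and
# the maximum pairwise substitution cost across all OTU pairs (0.5 per
# transition, 1 per transversion) does not exceed a threshold (2.0).
# Maximal spans not covered by any conserved window are candidate
# ambiguous regions; only spans whose ungapped sequence lengths vary
# enough across OTUs are reported.

#' Windowed substitution cost between two ungapped equal-length windows
#'
#' Sums per-position costs: 0 for a match, `ts_cost` for a transition
#' (A/G or C/T), `tv_cost` for any other mismatch.  `N` is a wildcard and
#' scores 0 against anything.
#'
#' @param a,b equal-length ungapped strings.
#' @param ts_cost,tv_cost transition / transversion costs.
#' @return numeric cost.
#' @examples
#' window_distance("ACGTA", "GCGTA")  # one transition -> 0.5
#' @export
window_distance <- function(a, b, ts_cost = 0.5, tv_cost = 1.0) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("windows must have equal length")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop("gap character inside window")
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  sum(pair_sub_cost(ca, cb, ts_cost, tv_cost))
}

# vectorized per-position classification; anything outside ACGT is a
# wildcard for windowing purposes
pair_sub_cost <- function(ca, cb, ts_cost, tv_cost) {
  wild <- !(ca %in% c("A", "C", "G", "T")) | !(cb %in% c("A", "C", "G", "T"))
  match <- ca == cb
  ts <- (ca == "A" & cb == "G") | (ca == "G" & cb == "A") |
        (ca == "C" & cb == "T") | (ca == "T" & cb == "C")
  ifelse(wild | match, 0, ifelse(ts, ts_cost, tv_cost))
}

#' Score all windows of an alignment and flag conserved ones
#'
#' @param aln an [alignment()].
#' @param w window width in columns.
#' @param threshold maximum pairwise window cost for a conserved window.
#' @param ts_cost,tv_cost substitution costs, see [window_distance()].
#' @return data.frame with one row per window start: `start`,
#'   `max_pair_dist` (NA where a gap disqualifies the window), `has_gap`,
#'   `conserved`.
#' @export
conserved_windows <- function(aln, w = 5L, threshold = 2.0,
                              ts_cost = 0.5, tv_cost = 1.0) {
  stopifnot(inherits(aln, "aln"))
  n <- aln_nrow(aln)
  if (aln$ncol < w) {
    return(data.frame(start = integer(0), max_pair_dist = numeric(0),
                      has_gap = logical(0), conserved = logical(0)))
  }
  chars <- as.matrix.aln(aln)                       # n x ncol
  gapcol <- colSums(chars == "-") > 0L
  nw <- aln$ncol - w + 1L
  # per-pair per-column costs, rolled into window sums; max over pairs
  maxd <- rep(0, nw)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cost <- pair_sub_cost(chars[i, ], chars[j, ], ts_cost, tv_cost)
      cs <- c(0, cumsum(cost))
      wsum <- cs[(w + 1L):(aln$ncol + 1L)] - cs[1:nw]
      maxd <- pmax(maxd, wsum)
    }
  }
  gapw <- vapply(seq_len(nw), function(s) any(gapcol[s:(s + w - 1L)]), TRUE)
  data.frame(start = seq_len(nw),
             max_pair_dist = ifelse(gapw, NA_real_, maxd),
             has_gap = gapw,
             conserved = !gapw & maxd <= threshold)
}

#' Delimit ambiguous regions from conserved flanks
#'
#' Columns covered by at least one conserved window are anchored; the
#' maximal uncovered spans are candidate ambiguous regions.  A candidate
#' is reported only if the range of ungapped sequence lengths across OTUs
#' within it is at least `min_len_var` (length variability being the
#' hallmark of alignment ambiguity).  Regions may abut the alignment ends.
#'
#' @inheritParams conserved_windows
#' @param min_len_var minimum range (max - min) of per-OTU ungapped
#'   lengths for a span to be reported.
#' @return list of [region_spec()] objects, sorted by start.
#' @export
delimit_regions <- function(aln, w = 5L, threshold = 2.0, min_len_var = 3L,
                            ts_cost = 0.5, tv_cost = 1.0) {
  stopifnot(inherits(aln, "aln"))
  cw <- conserved_windows(aln, w, threshold, ts_cost, tv_cost)
  covered <- rep(FALSE, aln$ncol)
  for (s in cw$start[cw$conserved]) covered[s:(s + w - 1L)] <- TRUE
  if (all(covered)) return(list())
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    spec <- region_spec(starts[k], ends[k],
                        label = sprintf("r%d", length(out) + 1L))
    lens <- nchar(region_sequences(aln, spec))
    if (diff(range(lens)) >= min_len_var) out[[length(out) + 1L]] <- spec
  }
  # relabel sequentially after filtering
  for (k in seq_along(out)) out[[k]]$label <- sprintf("r%d", k)
  out
}
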