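# Pairwise distance engines for one ambiguous region.
#
# Three engines, matching the original workflow:
#   identity - Clustal-style: globally align each pair under unit costs,
#              identity = matching non-gapped site pairs / shorter raw
#              length, distance = 1 - identity;
#   cost     - explicit substitution costs + log-affine gaps
#              (INAASE-like when ts=tv=gap unit);
#   zeta     - K2P log-odds substitution costs and gap costs from the
#              negative log of a zeta power-law indel length model.
# Gap runs of length k cost C_k = a + b*k + c*log(k).

#' Specify a pairwise alignment cost model
#'
#' @param match_cost,ts_cost,tv_cost per-column substitution costs
#'   (transitions are A/G and C/T).  `N` scores `match_cost` against
#'   anything.
#' @param gap_a,gap_b,gap_c log-affine gap parameters: a maximal gap of
#'   length `k` costs `gap_a + gap_b*k + gap_c*log(k)`.
#' @param free_end_gaps if `TRUE`, leading and trailing gap runs cost 0
#'   (for region ends that need not be homologous, e.g. ITS1/ITS2).
#' @param mode `"cost"` or `"zeta"`; informational tag carried into run
#'   manifests.
#' @return object of class `"cost_model"`.
#' @export
cost_model <- function(match_cost = 0, ts_cost = 1, tv_cost = 1,
                       gap_a = 1, gap_b = 1, gap_c = 0,
                       free_end_gaps = FALSE, mode = "cost") {
  if (gap_a < 0 || gap_b < 0 || gap_c < 0)
    stop("gap parameters must be non-negative")
  if (ts_cost < match_cost || tv_cost < match_cost)
    stop("substitution costs must not be below the match cost")
  if (free_end_gaps && match_cost >= 0)
    warning("free end gaps with a non-negative match cost: the empty ",
            "overlap is always optimal; consider a log-odds model ",
            "(negative match cost) such as zeta_costs()")
  structure(list(match_cost = match_cost, ts_cost = ts_cost,
                 tv_cost = tv_cost, gap_a = gap_a, gap_b = gap_b,
                 gap_c = gap_c, free_end_gaps = free_end_gaps,
                 mode = mode),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf(
    "Cost model (%s): match %.4g, ts %.4g, tv %.4g; C_k = %.4g + %.4g k + %.4g ln k; free ends: %s\n",
    x$mode, x$match_cost, x$ts_cost, x$tv_cost, x$gap_a, x$gap_b, x$gap_c,
    if (isTRUE(x$free_end_gaps)) "yes" else "no"))
  invisible(x)
}

# truncated-at-infinity Riemann zeta, accurate to ~1e-10 for z > 1.1
riemann_zeta <- function(z) {
  k <- 1:20000
  sum(k^(-z)) + 20000^(1 - z) / (z - 1)
}

#' Build the zeta power-law / K2P log-odds cost model
#'
#' Substitution costs are Kimura 2-parameter log-odds at a reference
#' divergence: `cost(x, y) = -log(4 * P_xy(d))` where `P` is the K2P
#' transition probability matrix with transition:transversion event
#' ratio `tstv` and expected `div` substitutions per site.  Matches score
#' negative (a reward), so free-end-gap alignment favours genuine
#' overlap.  Gap costs are the negative log of drawing an indel event
#' (rate `indel_rate` per substitution) with a zeta-distributed length:
#' `C_k = (-log(indel_rate) + log(zeta(z))) + z*log(k)`, i.e. `a + c ln k`
#' with `b = 0`.
#'
#' @param tstv transition:transversion event ratio (default 2).
#' @param div reference divergence in expected substitutions per site.
#' @param indel_rate indel events per substitution.
#' @param z zeta power-law slope; must exceed 1 or the length
#'   distribution cannot be normalized.
#' @param free_end_gaps see [cost_model()]; default `TRUE`, the option
#'   used for the published analyses.
#' @return object of class `"cost_model"` with `mode = "zeta"`.
#' @export
zeta_costs <- function(tstv = 2, div = 0.5, indel_rate = 0.15, z = 1.6,
                       free_end_gaps = TRUE) {
  if (z <= 1) stop("zeta slope z must be > 1 (normalization diverges)")
  if (tstv <= 0 || div <= 0 || indel_rate <= 0 || indel_rate >= 1)
    stop("tstv and div must be positive, indel_rate in (0,1)")
  # K2P with alpha/(2 beta) = tstv, normalized to one substitution per
  # unit branch length: beta = 1/(2 tstv + 2), alpha = tstv/(tstv + 1)
  beta <- 1 / (2 * tstv + 2)
  alpha <- tstv / (tstv + 1)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * div) -
    0.5 * exp(-2 * (alpha + beta) * div)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * div)   # each of the two targets
  p_same <- 1 - p_ts - 2 * p_tv
  m <- cost_model(match_cost = -log(4 * p_same),
                  ts_cost = -log(4 * p_ts),
                  tv_cost = -log(4 * p_tv),
                  gap_a = -log(indel_rate) + log(riemann_zeta(z)),
                  gap_b = 0,
                  gap_c = z,
                  free_end_gaps = free_end_gaps,
                  mode = "zeta")
  m$tstv <- tstv; m$div <- div; m$indel_rate <- indel_rate; m$z <- z
  m
}

# encode a DNA string as 0..4 integers for the C++ kernel
seq_to_int <- function(s) {
  ch <- strsplit(toupper(s), "")[[1L]]
  if (any(ch == "-")) stop("gaps must be stripped before pairwise alignment")
  code <- match(ch, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L           # every non-ACGT symbol behaves as N
  code - 1L
}

int_to_seq <- function(v) {
  paste(c("A", "C", "G", "T", "N", "-")[ifelse(v < 0L, 6L, v + 1L)],
        collapse = "")
}

gap_cost <- function(model, k) {
  ifelse(k == 0, 0, model$gap_a + model$gap_b * k + model$gap_c * log(k))
}

#' Optimal global alignment under log-affine gap costs
#'
#' Minimizes total cost over all global alignments of two ungapped
#' sequences, where each aligned pair costs match/transition/transversion
#' per the model and a maximal gap of length `k` costs
#' `a + b*k + c*log(k)`.  With `model$free_end_gaps`, leading and
#' trailing gap runs cost 0.
#'
#' @param a,b ungapped sequences over A, C, G, T, N.
#' @param model a [cost_model()].
#' @param traceback if `TRUE`, also return one optimal aligned pair.
#' @return list with `cost`, and with `traceback` also `a_aln`/`b_aln`
#'   (gapped strings of equal length).
#' @examples
#' logaffine_align("ACGT", "AGGT", cost_model(ts_cost = 0.5))$cost
#' @export
logaffine_align <- function(a, b, model = cost_model(), traceback = FALSE) {
  stopifnot(inherits(model, "cost_model"))
  a <- gsub("-", "", toupper(a), fixed = TRUE)
  b <- gsub("-", "", toupper(b), fixed = TRUE)
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) {
    out <- list(cost = 0)
    if (traceback) { out$a_aln <- ""; out$b_aln <- "" }
    return(out)
  }
  if (na == 0L || nb == 0L) {
    k <- max(na, nb)
    out <- list(cost = if (model$free_end_gaps) 0 else gap_cost(model, k))
    if (traceback) {
      gaps <- strrep("-", k)
      out$a_aln <- if (na == 0L) gaps else a
      out$b_aln <- if (nb == 0L) gaps else b
    }
    return(out)
  }
  res <- logaffine_align_cpp(seq_to_int(a), seq_to_int(b),
                             model$match_cost, model$ts_cost, model$tv_cost,
                             model$gap_a, model$gap_b, model$gap_c,
                             isTRUE(model$free_end_gaps), traceback)
  out <- list(cost = res$cost)
  if (traceback) {
    out$a_aln <- int_to_seq(res$a)
    out$b_aln <- int_to_seq(res$b)
  }
  out
}

#' Clustal-style identity distance between two sequences
#'
#' The pair is globally aligned under unit costs (match 0, mismatch 1,
#' gap `C_k = 1 + k`), identity is counted as the fraction of aligned
#' non-gapped site pairs with identical residues over the shorter raw
#' sequence length, and the distance is `1 - identity`.
#'
#' @param a,b sequences (gaps are stripped); case-insensitive.
#' @param align if `FALSE`, skip alignment and compare position-wise
#'   (sequences must then have equal length).
#' @return distance in `[0, 1]`.
#' @export
identity_distance <- function(a, b, align = TRUE) {
  a <- gsub("-", "", toupper(a), fixed = TRUE)
  b <- gsub("-", "", toupper(b), fixed = TRUE)
  if (nchar(a) == 0L && nchar(b) == 0L) {
    warning("both sequences empty; identity distance 0")
    return(0)
  }
  if (nchar(a) == 0L || nchar(b) == 0L) {
    warning("empty sequence; identity distance 1")
    return(1)
  }
  if (align) {
    # canonical argument order: tied optimal alignments can differ in
    # match count, and the DP resolves ties by position; ordering the
    # pair makes the distance symmetric in its arguments
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    al <- logaffine_align(a, b, cost_model(match_cost = 0, ts_cost = 1,
                                           tv_cost = 1, gap_a = 1, gap_b = 1,
                                           gap_c = 0),
                          traceback = TRUE)
    ca <- strsplit(al$a_aln, "")[[1L]]
    cb <- strsplit(al$b_aln, "")[[1L]]
  } else {
    if (nchar(a) != nchar(b))
      stop("align = FALSE requires equal-length sequences")
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
  }
  matches <- sum(ca == cb & ca != "-")
  1 - matches / min(nchar(a), nchar(b))
}

#' Pairwise distance matrix for one ambiguous region
#'
#' Extracts each OTU's ungapped residues within the region and scores all
#' pairs under the chosen engine.  Cost engines convert alignment scores
#' to distances by self-normalization
#' `d_ij = c_ij - (c_ii + c_jj)/2` (zero diagonal by construction; tiny
#' negative residue from non-metric scores is clipped to 0).  The matrix
#' is symmetrized by averaging.
#'
#' @param aln an [alignment()].
#' @param region a [region_spec()].
#' @param engine `"identity"`, `"cost"` or `"zeta"`.
#' @param model a [cost_model()]; defaults to [zeta_costs()] for the zeta
#'   engine and to unit costs for `"cost"`.
#' @return object of class `"dist_matrix"`: list with `names` and the
#'   symmetric, zero-diagonal matrix `d`.
#' @export
region_matrix <- function(aln, region,
                          engine = c("zeta", "identity", "cost"),
                          model = NULL) {
  engine <- match.arg(engine)
  seqs <- region_sequences(aln, region)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  if (is.null(model)) {
    model <- if (engine == "zeta") zeta_costs() else
      cost_model(match_cost = 0, ts_cost = 1, tv_cost = 1,
                 gap_a = 1, gap_b = 1, gap_c = 0)
  }
  empty <- !nzchar(seqs)
  if (any(empty))
    message("region ", region$label, ": no residues for OTU(s) ",
            paste(names(seqs)[empty], collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (engine == "identity") {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- if (empty[i] && empty[j]) 0
          else if (empty[i] || empty[j]) 1
          else identity_distance(seqs[i], seqs[j])
        d[i, j] <- d[j, i] <- dij
      }
    }
  } else {
    self <- vapply(seq_len(n), function(i) {
      if (empty[i]) 0 else nchar(seqs[i]) * model$match_cost
    }, 0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- if (empty[i] && empty[j]) 0
          else if (empty[i] || empty[j])   # forced gap, end-discount not applied
            gap_cost(model, nchar(seqs[c(i, j)][!empty[c(i, j)]]))
          else logaffine_align(seqs[i], seqs[j], model)$cost -
            (self[i] + self[j]) / 2
        d[i, j] <- d[j, i] <- max(dij, 0)
      }
    }
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(names = names(seqs), d = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise distance matrix,", length(x$names), "OTUs\n")
  print(round(x$d, digits))
  invisible(x)
}

#' Write a distance matrix in square PHYLIP layout
#'
#' @param dm a `"dist_matrix"` (see [region_matrix()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distmatrix <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  lines <- c(as.character(length(dm$names)),
             vapply(seq_along(dm$names), function(i) {
               paste(c(dm$names[i], formatC(dm$d[i, ], format = "g",
                                            digits = 10)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
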