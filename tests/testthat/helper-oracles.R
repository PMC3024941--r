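# Independent oracles and fixture builders shared across the test files.

DNA4 <- c("A", "C", "G", "T")

random_seq <- function(len, alphabet = DNA4) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_alignment <- function(n, ncol, gap_frac = 0, alphabet = DNA4) {
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, ncol, replace = TRUE)
    if (gap_frac > 0) {
      g <- runif(ncol) < gap_frac
      ch[g] <- "-"
    }
    paste(ch, collapse = "")
  }, "")
  alignment(setNames(seqs, paste0("t", seq_len(n))))
}

# --- exhaustive global-alignment oracle -------------------------------------
# Enumerates every monotone alignment path, charging each maximal gap run
# C(k) = a + b*k + c*log(k) (leading/trailing runs free under free_end),
# and returns the minimum total cost.  Exponential; lengths <= 7 only.
brute_align_cost <- function(a, b, model) {
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  n <- length(ca); m <- length(cb)
  gap_c <- function(k) model$gap_a + model$gap_b * k + model$gap_c * log(k)
  sub_c <- function(x, y) {
    if (x == "N" || y == "N" || x == y) return(model$match_cost)
    ts <- paste0(sort(c(x, y)), collapse = "")
    if (ts %in% c("AG", "CT")) model$ts_cost else model$tv_cost
  }
  free <- isTRUE(model$free_end_gaps)
  # branch-and-bound pruning is only sound when no step can lower the cost
  prune <- model$match_cost >= 0
  best <- Inf
  # state: i,j consumed; run: 0 none, 1 gap-in-b (consumes a), 2 gap-in-a;
  # rlen current run length; rorigin: run started before any column
  rec <- function(i, j, run, rlen, rorigin, cost) {
    if (prune && cost >= best) return(invisible())
    close_run <- function() {
      if (run == 0L) return(0)
      if (free && rorigin) 0 else gap_c(rlen)
    }
    if (i == n && j == m) {
      final <- cost + if (run == 0L) 0 else if (free) 0 else gap_c(rlen)
      if (final < best) best <<- final
      return(invisible())
    }
    if (i < n && j < m) {
      rec(i + 1L, j + 1L, 0L, 0L, FALSE,
          cost + close_run() + sub_c(ca[i + 1L], cb[j + 1L]))
    }
    if (i < n) {                      # gap in b, consume a[i+1]
      if (run == 1L) {
        rec(i + 1L, j, 1L, rlen + 1L, rorigin, cost)
      } else {
        rec(i + 1L, j, 1L, 1L, run == 0L && i == 0L && j == 0L,
            cost + close_run())
      }
    }
    if (j < m) {                      # gap in a, consume b[j+1]
      if (run == 2L) {
        rec(i, j + 1L, 2L, rlen + 1L, rorigin, cost)
      } else {
        rec(i, j + 1L, 2L, 1L, run == 0L && i == 0L && j == 0L,
            cost + close_run())
      }
    }
  }
  if (n == 0L && m == 0L) return(0)
  rec(0L, 0L, 0L, 0L, FALSE, 0)
  best
}

# --- brute bipartition RF oracle --------------------------------------------
# Non-trivial bipartitions of an unrooted tree as sorted tip-name subsets
# (canonical side: the one containing the alphabetically first tip).
brute_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 0L) return(tree$tip.label[node])
    unlist(lapply(kids, desc))
  }
  internal <- tree$edge[, 2][tree$edge[, 2] > ntip]
  parts <- lapply(internal, function(nd) {
    side <- sort(desc(nd))
    if (length(side) <= 1L || length(side) >= ntip - 1L) return(NULL)
    if (!(tips[1L] %in% side)) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  })
  unique(unlist(parts))
}

brute_relative_rf <- function(t1, t2) {
  b1 <- brute_bipartitions(t1)
  b2 <- brute_bipartitions(t2)
  n <- length(t1$tip.label)
  (length(setdiff(b1, b2)) + length(setdiff(b2, b1))) / (2 * (n - 3))
}

# --- substitution classification oracle -------------------------------------
# purine/pyrimidine table, independent of the package's cost code
brute_classify <- function(x, y) {
  pur <- c("A", "G")
  if (x == y) return("match")
  if ((x %in% pur) == (y %in% pur)) "transition" else "transversion"
}

# constructive fixture: conserved flanks around a length-variable insert;
# one OTU has no insert at all so every insert column carries a gap and
# the delimited region is exactly the insert span
flank_insert_alignment <- function(lens, flank = "ACGTA", width = max(lens)) {
  stopifnot(all(lens <= width), any(lens == 0L))
  seqs <- vapply(lens, function(L) {
    paste0(flank,
           paste(c(sample(DNA4, L, replace = TRUE), rep("-", width - L)),
                 collapse = ""),
           flank)
  }, "")
  alignment(setNames(seqs, paste0("t", seq_along(lens))))
}
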