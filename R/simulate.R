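# Sequence evolution simulator with power-law indels.
#
# Emulates the published simulation design: sequences evolve along a
# given phylogeny under a Kimura 2-parameter substitution process; in
# indel-bearing partitions, insertions and deletions occur at fixed
# rates per substitution (default 1 insertion and 2 deletions per 20
# substitutions) with lengths drawn from a truncated discrete power law
# (slope 1.6, maximum 30 or 50 residues).  Site identities are tracked
# so the true alignment is known by construction.  The default
# five-partition layout: root lengths 400/400/100/100/200, substitution
# rate multipliers 1/2/2/3/2, indels only in partitions 3-5, maximum
# indel length 30/30/50.

default_partitions <- function() {
  data.frame(root_length = c(400L, 400L, 100L, 100L, 200L),
             rate = c(1, 2, 2, 3, 2),
             indels = c(FALSE, FALSE, TRUE, TRUE, TRUE),
             max_indel = c(NA, NA, 30L, 30L, 50L))
}

#' Simulation configuration
#'
#' @param tree an `ape` `phylo` object (rooted, with branch lengths in
#'   expected substitutions per site at rate multiplier 1), or a path to
#'   a Newick file.
#' @param partitions data.frame with columns `root_length`, `rate`,
#'   `indels`, `max_indel`; defaults to the five-partition design.
#' @param ins_rate,del_rate insertion / deletion events per substitution
#'   (defaults 1/20 and 2/20).
#' @param indel_slope zeta power-law slope for indel lengths (> 1).
#' @param tstv transition:transversion event ratio of the K2P process.
#' @param seed mandatory integer RNG seed.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(tree, partitions = default_partitions(),
                       ins_rate = 1 / 20, del_rate = 2 / 20,
                       indel_slope = 1.6, tstv = 2, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  partitions <- as.data.frame(partitions)
  stopifnot(all(c("root_length", "rate", "indels", "max_indel") %in%
                  names(partitions)))
  if (any(partitions$root_length < 1L)) stop("root_length must be >= 1")
  if (any(partitions$rate < 0) || ins_rate < 0 || del_rate < 0)
    stop("rates must be non-negative")
  if (indel_slope <= 1) stop("indel_slope must be > 1")
  structure(list(tree = tree, partitions = partitions,
                 ins_rate = ins_rate, del_rate = del_rate,
                 indel_slope = indel_slope, tstv = tstv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw truncated power-law indel lengths
#'
#' `P(k)` proportional to `k^(-z)` for `k` in `1..max_len`.
#'
#' @param n number of draws.
#' @param z power-law slope (> 1).
#' @param max_len maximum length (truncation point).
#' @return integer vector of lengths.
#' @export
sample_indel_length <- function(n, z = 1.6, max_len = 30L) {
  if (z <= 1) stop("z must be > 1")
  max_len <- as.integer(max_len)
  if (max_len < 1L) stop("max_len must be >= 1")
  if (max_len == 1L) return(rep(1L, n))
  sample.int(max_len, n, replace = TRUE,
             prob = (1:max_len)^(-z))
}

# K2P transition probabilities after t expected substitutions per site
k2p_probs <- function(t, tstv) {
  beta <- 1 / (2 * tstv + 2)
  alpha <- tstv / (tstv + 1)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) -
    0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * t)
  c(ts = p_ts, tv = p_tv, same = 1 - p_ts - 2 * p_tv)
}

# bases 1..4 = A C G T; transition partner: A<->G (1<->3), C<->T (2<->4)
TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV_PARTNERS <- matrix(c(2L, 4L,   # A -> C,T
                        1L, 3L,   # C -> A,G
                        2L, 4L,   # G -> C,T
                        1L, 3L),  # T -> A,G
                      nrow = 4L, byrow = TRUE)

#' Evolve sequences along a tree with substitutions and indels
#'
#' Each partition evolves independently from a uniform-random root
#' sequence.  Along each branch, every site substitutes according to the
#' K2P transition probabilities for the branch's expected substitution
#' load; for indel-bearing partitions, insertion and deletion event
#' counts are Poisson with mean `rate_per_substitution * expected
#' substitutions`, positions are uniform, and lengths follow the
#' truncated power law.  Inserted sites receive new identities, so the
#' true alignment is assembled exactly from the recorded site homology.
#'
#' @param cfg a [sim_config()].
#' @return object of class `"sim_result"`: `alignment` (true alignment),
#'   `tree` (the input tree), `partition_table` (data.frame with
#'   `partition`, `start`, `end` columns, 1-based inclusive).
#' @export
evolve <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- ape::reorder.phylo(cfg$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  blocks <- vector("list", nrow(cfg$partitions))
  for (p in seq_len(nrow(cfg$partitions))) {
    par <- cfg$partitions[p, ]
    blocks[[p]] <- evolve_partition(
      tree, root, ntip,
      root_length = par$root_length, rate = par$rate,
      indels = isTRUE(par$indels),
      max_indel = if (is.na(par$max_indel)) 30L else par$max_indel,
      ins_rate = cfg$ins_rate, del_rate = cfg$del_rate,
      z = cfg$indel_slope, tstv = cfg$tstv)
  }
  widths <- vapply(blocks, function(b) nchar(b[1L]), 0L)
  seqs <- do.call(paste0, blocks)
  aln <- alignment(seqs, names = tree$tip.label)
  ends <- cumsum(widths)
  structure(list(alignment = aln, tree = cfg$tree,
                 partition_table = data.frame(
                   partition = seq_along(widths),
                   start = ends - widths + 1L, end = ends)),
            class = "sim_result")
}

# one partition: returns character vector of gapped rows (tip order)
evolve_partition <- function(tree, root, ntip, root_length, rate, indels,
                             max_indel, ins_rate, del_rate, z, tstv) {
  # master column order of all site ids ever created; node sequences are
  # vectors of (id, base)
  master <- seq_len(root_length)
  next_id <- root_length + 1L
  nodeseq <- vector("list", max(tree$edge))
  nodeseq[[root]] <- list(ids = seq_len(root_length),
                          bases = sample.int(4L, root_length, replace = TRUE))
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t <- tree$edge.length[e] * rate
    s <- nodeseq[[parent]]
    ids <- s$ids; bases <- s$bases
    L <- length(ids)
    if (L > 0L && t > 0) {
      # substitutions
      pr <- k2p_probs(t, tstv)
      u <- runif(L)
      is_ts <- u < pr["ts"]
      is_tv <- !is_ts & u < pr["ts"] + 2 * pr["tv"]
      if (any(is_ts)) bases[is_ts] <- TS_PARTNER[bases[is_ts]]
      if (any(is_tv)) {
        which_tv <- which(is_tv)
        pick <- 1L + (runif(length(which_tv)) < 0.5)
        bases[which_tv] <- TV_PARTNERS[cbind(bases[which_tv], pick)]
      }
      if (indels) {
        load <- t * L                      # expected substitutions on branch
        n_ins <- rpois(1L, ins_rate * load)
        n_del <- rpois(1L, del_rate * load)
        for (k in seq_len(n_ins)) {
          len <- sample_indel_length(1L, z, max_indel)
          pos <- sample.int(length(ids) + 1L, 1L) - 1L  # insert after pos
          new_ids <- next_id:(next_id + len - 1L)
          next_id <- next_id + len
          # splice into the master order after the anchoring site
          anchor <- if (pos == 0L) {
            if (length(ids) == 0L) length(master) else
              match(ids[1L], master) - 1L
          } else match(ids[pos], master)
          master <- append(master, new_ids, after = anchor)
          ids <- append(ids, new_ids, after = pos)
          bases <- append(bases, sample.int(4L, len, replace = TRUE),
                          after = pos)
        }
        for (k in seq_len(n_del)) {
          if (length(ids) == 0L) break
          len <- sample_indel_length(1L, z, max_indel)
          start <- sample.int(length(ids), 1L)
          drop <- start:min(length(ids), start + len - 1L)
          ids <- ids[-drop]; bases <- bases[-drop]
        }
      }
    }
    nodeseq[[child]] <- list(ids = ids, bases = bases)
  }
  # assemble rows over master columns present in at least one tip
  BASES <- c("A", "C", "G", "T")
  tipmat <- matrix("-", ntip, length(master))
  for (i in seq_len(ntip)) {
    s <- nodeseq[[i]]
    if (length(s$ids)) {
      tipmat[i, match(s$ids, master)] <- BASES[s$bases]
    }
  }
  keep <- colSums(tipmat != "-") > 0L
  tipmat <- tipmat[, keep, drop = FALSE]
  apply(tipmat, 1L, paste, collapse = "")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated dataset:", length(x$alignment$names), "sequences,",
      x$alignment$ncol, "alignment columns,",
      nrow(x$partition_table), "partitions\n")
  print(x$partition_table)
  invisible(x)
}

#' Relative Robinson-Foulds distance between two trees
#'
#' Symmetric bipartition difference divided by its maximum possible
#' value (`2(n - 3)` for binary trees); 0 for identical unrooted
#' topologies, 1 for trees sharing no non-trivial bipartition.
#'
#' @param t1,t2 `phylo` objects or Newick file paths; same leaf set,
#'   at least 4 leaves.
#' @return fraction in `[0, 1]`.
#' @export
relative_rf <- function(t1, t2) {
  if (is.character(t1)) t1 <- ape::read.tree(t1)
  if (is.character(t2)) t2 <- ape::read.tree(t2)
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (length(t1$tip.label) < 4L) stop("need at least 4 leaves")
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.numeric(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               normalize = TRUE))
}
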