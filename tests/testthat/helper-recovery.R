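# Desk-scale topology-recovery experiment: simulate the five-partition
# design on a fixed tree, then compare neighbor-joining trees built with
# the indel partitions (3-5) either excluded or PICS-Ord encoded.
# Distances are pooled per character: DNA mismatch counts plus L1 code
# differences scaled to [0,1] per column, over the total character count.

recovery_tree <- function(n = 12, depth = 0.25, seed = 2024) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length /
      max(ape::node.depth.edgelength(tr)) * depth
    tr
  })
}

# proportion of mismatching gap-free columns, all pairs
dna_mismatch <- function(rows) {
  ch <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(ch)
  cnt <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cnt[i, j] <- cnt[j, i] <- sum(ch[i, ] != ch[j, ])
    }
  }
  cnt
}

recovery_replicate <- function(tree, seed, encode = TRUE) {
  res <- evolve(sim_config(tree, seed = seed))
  pt <- res$partition_table
  aln <- res$alignment
  dna <- substr(aln$seqs, pt$start[1], pt$end[2])   # partitions 1-2
  mis <- dna_mismatch(dna)
  n_sites <- nchar(dna[1])
  if (encode) {
    l1 <- matrix(0, length(aln$names), length(aln$names))
    n_codes <- 0L
    for (p in 3:5) {
      cm <- suppressMessages(suppressWarnings(
        encode_region(aln, region_spec(pt$start[p], pt$end[p],
                                       paste0("p", p)))))
      if (ncol(cm$codes) == 0L) next
      l1 <- l1 + as.matrix(dist(cm$codes, method = "manhattan")) /
        (cm$k - 1)
      n_codes <- n_codes + ncol(cm$codes)
    }
    D <- (mis + l1) / (n_sites + n_codes)
  } else {
    D <- mis / n_sites
  }
  dimnames(D) <- list(aln$names, aln$names)
  nj <- ape::nj(D)
  relative_rf(nj, res$tree)
}
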