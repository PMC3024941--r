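# Sequence evolution simulator and tree comparison.

fixture_tree <- function(n = 8, depth = 0.25, seed = 101) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length /
      max(ape::node.depth.edgelength(tr)) * depth
    tr
  })
}

test_that("indel lengths follow the truncated power law", {
  expect_equal(sample_indel_length(50, z = 1.6, max_len = 1L), rep(1L, 50))
  withr::local_seed(67)
  draws <- sample_indel_length(2e4, z = 1.6, max_len = 30L)
  expect_true(all(draws >= 1L & draws <= 30L))
  k <- 1:30
  p <- k^(-1.6) / sum(k^(-1.6))
  exact_mean <- sum(k * p)
  se <- sqrt((sum(k^2 * p) - exact_mean^2) / length(draws))
  expect_lt(abs(mean(draws) - exact_mean), 3 * se)
  # steeper slope -> stochastically shorter
  draws3 <- sample_indel_length(2e4, z = 3, max_len = 30L)
  expect_lt(mean(draws3), mean(draws))
  expect_error(sample_indel_length(1, z = 1), "> 1")
})

test_that("no indels means a gap-free alignment of constant length", {
  tr <- fixture_tree()
  parts <- data.frame(root_length = 120L, rate = 1, indels = FALSE,
                      max_indel = NA)
  cfg <- sim_config(tr, parts, seed = 9)
  res <- evolve(cfg)
  expect_equal(res$alignment$ncol, 120L)
  expect_false(any(grepl("-", res$alignment$seqs, fixed = TRUE)))
})

test_that("a doubled substitution rate raises pairwise mismatch", {
  tr <- fixture_tree(n = 6, depth = 0.4)
  parts <- data.frame(root_length = c(400L, 400L), rate = c(1, 2),
                      indels = FALSE, max_indel = NA)
  res <- evolve(sim_config(tr, parts, seed = 21))
  pdist <- function(cols) {
    s <- substr(res$alignment$seqs, cols[1], cols[2])
    ch <- do.call(rbind, strsplit(s, ""))
    n <- nrow(ch)
    tot <- 0; cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + mean(ch[i, ] != ch[j, ]); cnt <- cnt + 1
    }
    tot / cnt
  }
  pt <- res$partition_table
  expect_gt(pdist(c(pt$start[2], pt$end[2])),
            pdist(c(pt$start[1], pt$end[1])))
})

test_that("the five-partition default puts gaps only in partitions 3-5", {
  tr <- fixture_tree(n = 12)
  res <- evolve(sim_config(tr, seed = 33))
  pt <- res$partition_table
  has_gap <- vapply(seq_len(nrow(pt)), function(p) {
    any(grepl("-", substr(res$alignment$seqs, pt$start[p], pt$end[p]),
              fixed = TRUE))
  }, TRUE)
  expect_equal(has_gap, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # partitions tile the alignment
  expect_equal(pt$start[1], 1L)
  expect_equal(pt$end[nrow(pt)], res$alignment$ncol)
  expect_equal(pt$start[-1], head(pt$end, -1) + 1L)
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  tr <- fixture_tree()
  r1 <- evolve(sim_config(tr, seed = 55))
  r2 <- evolve(sim_config(tr, seed = 55))
  expect_identical(r1$alignment, r2$alignment)
  r3 <- evolve(sim_config(tr, seed = 56))
  expect_false(identical(r1$alignment, r3$alignment))
})

test_that("relative RF agrees with brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_equal(relative_rf(t1, t1), 0)

  # all 5-leaf binary shapes against each other
  newicks <- c("((a,b),(c,d),e);", "((a,c),(b,d),e);", "((a,d),(b,c),e);",
               "((a,b),(c,e),d);", "((a,e),(b,c),d);")
  trees <- lapply(newicks, function(s) ape::read.tree(text = s))
  for (i in seq_along(trees)) {
    for (j in seq_along(trees)) {
      expect_equal(relative_rf(trees[[i]], trees[[j]]),
                   brute_relative_rf(trees[[i]], trees[[j]]),
                   label = paste(newicks[i], "vs", newicks[j]))
    }
  }

  # caterpillar vs its relabel-reversed form on 4 leaves: same unrooted tree
  c1 <- ape::read.tree(text = "(((a,b),c),d);")
  c2 <- ape::read.tree(text = "(((d,c),b),a);")
  expect_equal(relative_rf(c1, c2), 0)

  t2 <- ape::read.tree(text = "((a,b),(c,f),e);")
  expect_error(relative_rf(t1, t2), "leaf sets")
  expect_error(relative_rf(ape::read.tree(text = "(a,b,c);"),
                           ape::read.tree(text = "(a,b,c);")),
               "4 leaves")
})

test_that("random trees round-trip through relative_rf with the oracle", {
  withr::local_seed(71)
  for (rep in 1:8) {
    n <- sample(5:9, 1)
    t1 <- ape::rtree(n, tip.label = paste0("t", 1:n))
    t2 <- ape::rtree(n, tip.label = paste0("t", 1:n))
    expect_equal(relative_rf(t1, t2), brute_relative_rf(t1, t2))
  }
})
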