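# Rescaling, integer coding, invariant removal, per-region pipeline.

test_that("rescaling is anchored to the maximum axis range", {
  coords <- cbind(c(-2, 3, 0), c(0, 1, 0.5))
  rs <- rescale_scores(coords)
  expect_equal(rs$s_range_max, 5)
  expect_equal(range(rs$scores[, 1]), c(0, 1))       # widest axis spans [0,1]
  expect_equal(rs$scores[, 2], c(0, 0.2, 0.1))       # compressed axis
  expect_null(rescale_scores(matrix(1, 4, 2)))       # all-constant: degenerate
})

test_that("the coder reproduces the x9.99 - 0.495 rule and its bounds", {
  expect_equal(to_codes(0), 0L)
  expect_equal(to_codes(1), 9L)
  expect_equal(to_codes(0.55), 5L)                   # round(4.9995)
  # general-k formula reduces to the printed constants at k = 10
  s <- seq(0, 1, by = 0.01)
  expect_equal(to_codes(s, 10L),
               as.integer(picsord:::round_half_away(s * 9.99 - 0.495)))
  for (k in c(2L, 4L, 10L, 20L, 32L, 64L)) {
    codes <- to_codes(s, k)
    expect_equal(range(codes), c(0L, k - 1L), label = paste("k =", k))
    expect_true(all(diff(codes) >= 0), label = paste("monotone, k =", k))
  }
  expect_error(to_codes(0.5, 1L), "\\[2, 64\\]")
  expect_error(to_codes(0.5, 65L), "\\[2, 64\\]")
  expect_error(to_codes(1.2), "\\[0, 1\\]")
  # ties round half away from zero, not to even
  expect_equal(picsord:::round_half_away(c(0.5, 1.5, 2.5, -0.5)),
               c(1, 2, 3, -1))
})

test_that("invariant columns are removed idempotently with their weights", {
  cm <- picsord:::new_code_matrix(paste0("t", 1:4),
                                  cbind(c(3, 3, 3, 3), c(0, 0, 0, 1)),
                                  10L, c(0.7, 0.3), "r1")
  d1 <- drop_invariant(cm)
  expect_equal(ncol(d1$codes), 1L)
  expect_equal(d1$axis_weights, 0.3)
  expect_equal(drop_invariant(d1), d1)
})

test_that("identical region sequences always receive identical code rows", {
  withr::local_seed(47)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    aln <- random_alignment(n, 30, gap_frac = 0.2)
    # force a duplicate row
    aln$seqs[n] <- aln$seqs[1]
    cm <- suppressMessages(
      encode_region(aln, region_spec(6, 25), engine = "identity"))
    expect_equal(cm$codes[1, ], cm$codes[n, ],
                 label = sprintf("replicate %d", rep))
  }
})

test_that("codes stay in range on arbitrary random distance matrices", {
  withr::local_seed(53)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    D <- matrix(runif(n * n, 0, 5), n, n); D <- D + t(D); diag(D) <- 0
    rs <- rescale_scores(pcoa(D))
    if (is.null(rs)) next
    k <- sample(c(4L, 10L, 32L), 1)
    codes <- to_codes(rs$scores, k)
    expect_true(all(codes >= 0L & codes <= k - 1L))
  }
})

test_that("codes preserve order along a line and correlate with distances", {
  # colinear points: axis-1 codes must reproduce the point order
  x <- c(0, 1, 3, 6, 10, 15)
  D <- as.matrix(dist(x))
  rs <- rescale_scores(pcoa(D))
  c1 <- to_codes(rs$scores)[, 1]
  expect_true(all(diff(c1) >= 0) || all(diff(c1) <= 0))
  expect_equal(abs(unname(c1[6] - c1[1])), 9L)  # endpoints span the range

  # random planar configurations: L1 code distance tracks input distance
  withr::local_seed(59)
  for (rep in 1:5) {
    pts <- matrix(rnorm(2 * 10), 10, 2)
    D <- as.matrix(dist(pts))
    codes <- to_codes(rescale_scores(pcoa(D))$scores)
    l1 <- as.matrix(dist(codes, method = "manhattan"))
    lower <- lower.tri(D)
    expect_gt(cor(D[lower], l1[lower], method = "spearman"), 0.5)
  }
})

test_that("the region pipeline wires distances to codes in order", {
  # invariant region -> empty code matrix
  aln0 <- alignment(c(a = "TTGGTT", b = "AAGGTT", c = "CCGGTT"))
  cm0 <- encode_region(aln0, region_spec(3, 4))
  expect_equal(ncol(cm0$codes), 0L)

  # printed worked trio: code row of (2) nearer (3) than (1) in L1
  aln <- alignment(c(s1 = "TTGGCCAACCGGTT",
                     s2 = "AACCGGTTGGCCAA",
                     s3 = "AGCCAGCTGGCTAA"))
  cm <- encode_region(aln, region_spec(1, 14), engine = "identity")
  l1 <- function(i, j) sum(abs(cm$codes[i, ] - cm$codes[j, ]))
  expect_lt(l1(2, 3), l1(1, 2))

  # duplicating an OTU: its row duplicates, others' L1 gaps move <= 1/axis
  withr::local_seed(61)
  aln1 <- random_alignment(6, 24, gap_frac = 0.15)
  cmA <- suppressMessages(encode_region(aln1, region_spec(1, 24),
                                        engine = "identity"))
  aln2 <- alignment(setNames(c(aln1$seqs, aln1$seqs[3]),
                             c(aln1$names, "dup")))
  cmB <- suppressMessages(encode_region(aln2, region_spec(1, 24),
                                        engine = "identity"))
  expect_equal(cmB$codes["dup", ], cmB$codes["t3", ], ignore_attr = TRUE)
})
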