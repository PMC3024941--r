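# Pairwise distance engines: identity, explicit cost, zeta.

unit_model <- function(free = FALSE)
  cost_model(match_cost = 0, ts_cost = 1, tv_cost = 1,
             gap_a = 1, gap_b = 1, gap_c = 0, free_end_gaps = free)

test_that("identity distance matches position-wise counting on the printed pair", {
  d <- identity_distance("AACCGGTTGGCCAA", "AGCCAGCTGGCTAA")
  expect_equal(d, 1 - 10 / 14)
  # gap-free position scan of the shifted pair: every site differs
  expect_equal(identity_distance("TTGGCCAACCGGTT", "AACCGGTTGGCCAA",
                                 align = FALSE), 1.0)
  expect_equal(identity_distance("acgt", "ACGT"), 0)   # case-insensitive
  expect_equal(identity_distance("ACGT", "ACGT"), 0)
  expect_warning(d0 <- identity_distance("", "ACGT"), "empty")
  expect_equal(d0, 1.0)
})

test_that("log-affine alignment handles the closed-form cases", {
  m <- cost_model(match_cost = 0, ts_cost = 0.5, tv_cost = 1,
                  gap_a = 1, gap_b = 0.5, gap_c = 1)
  expect_equal(logaffine_align("ACGTT", "ACGTT", m)$cost, 0)
  expect_equal(logaffine_align("ACGT", "", m)$cost, 1 + 2 + log(4))
  expect_equal(logaffine_align("", "", m)$cost, 0)
  # N scores as match
  expect_equal(logaffine_align("ANGT", "AAGT", m)$cost, 0)
  # traceback returns a consistent aligned pair
  al <- logaffine_align("ACGTTTACGT", "ACGTACGT", unit_model(),
                        traceback = TRUE)
  expect_equal(nchar(al$a_aln), nchar(al$b_aln))
  expect_equal(gsub("-", "", al$a_aln), "ACGTTTACGT")
  expect_equal(gsub("-", "", al$b_aln), "ACGTACGT")
})

test_that("DP equals exhaustive enumeration on short pairs", {
  models <- list(
    unit = unit_model(),
    loggap = cost_model(match_cost = 0, ts_cost = 0.5, tv_cost = 1,
                        gap_a = 0.6, gap_b = 0.2, gap_c = 1.3),
    zeta_free = zeta_costs()
  )
  # exhaustive over ALL pairs with both lengths <= 4 over {A,C}
  pool <- unlist(lapply(1:4, function(L) {
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")
  }))
  for (mname in c("unit", "loggap")) {
    m <- models[[mname]]
    for (a in pool) {
      for (b in pool) {
        expect_equal(logaffine_align(a, b, m)$cost,
                     brute_align_cost(a, b, m),
                     label = sprintf("%s: %s vs %s", mname, a, b))
      }
    }
  }
  # seeded random pairs up to length 7, all models incl. free ends
  withr::local_seed(41)
  for (i in 1:10) {
    a <- random_seq(sample(5:7, 1), c("A", "C"))
    b <- random_seq(sample(5:7, 1), c("A", "C"))
    for (mname in names(models)) {
      m <- models[[mname]]
      expect_equal(logaffine_align(a, b, m)$cost,
                   brute_align_cost(a, b, m), tolerance = 1e-10,
                   label = sprintf("%s: %s vs %s", mname, a, b))
    }
  }
})

test_that("alignment cost is symmetric for symmetric substitution costs", {
  withr::local_seed(13)
  for (m in list(unit_model(), zeta_costs(),
                 cost_model(ts_cost = 0.5, gap_c = 0.8))) {
    for (i in 1:10) {
      a <- random_seq(sample(3:12, 1))
      b <- random_seq(sample(3:12, 1))
      expect_equal(logaffine_align(a, b, m)$cost,
                   logaffine_align(b, a, m)$cost, tolerance = 1e-12)
    }
  }
})

test_that("zeta model construction behaves as a power law", {
  expect_error(zeta_costs(z = 1), "z must be > 1")
  m <- zeta_costs()
  expect_lt(m$ts_cost, m$tv_cost)
  expect_lt(m$match_cost, 0)            # log-odds reward for matches
  # gap-length increments shrink (log-concavity of the length term)
  ck <- function(mm, k) mm$gap_a + mm$gap_b * k + mm$gap_c * log(k)
  inc <- diff(vapply(1:10, ck, 0, mm = m))
  expect_true(all(diff(inc) < 0))
  # steeper slope penalizes long gaps more relative to short ones
  m3 <- zeta_costs(z = 3)
  expect_gt(ck(m3, 2) - ck(m3, 1), ck(m, 2) - ck(m, 1))
})

test_that("region matrices satisfy the distance-matrix contract", {
  aln <- alignment(c(a = "AAAA----CCCC", b = "AAAAGG--CCCC",
                     c = "AAAAGGGGCCCC", d = "AAAA--G-CCCC"))
  r <- region_spec(5, 8, "mid")
  for (engine in c("identity", "cost", "zeta")) {
    dm <- suppressMessages(region_matrix(aln, r, engine = engine))
    expect_identical(dm$d, t(dm$d), label = engine)
    expect_true(all(diag(dm$d) == 0), label = engine)
    expect_true(all(dm$d >= 0) && all(is.finite(dm$d)), label = engine)
  }
  # all OTUs identical in the region -> all-zero matrix
  aln0 <- alignment(c(a = "TTGGTT", b = "AAGGTT", c = "CCGGTT"))
  dm0 <- region_matrix(aln0, region_spec(3, 4), engine = "zeta")
  expect_true(all(dm0$d == 0))
})

test_that("the printed sequence trio orders as in the worked example", {
  aln <- alignment(c(s1 = "TTGGCCAACCGGTT",
                     s2 = "AACCGGTTGGCCAA",
                     s3 = "AGCCAGCTGGCTAA"))
  r <- region_spec(1, 14, "all")
  for (engine in c("identity", "zeta")) {
    dm <- region_matrix(aln, r, engine = engine)
    expect_lt(dm$d["s2", "s3"], dm$d["s1", "s2"],
              label = paste(engine, ": (2)-(3) more similar than (1)-(2)"))
  }
})

test_that("distance matrix file writer emits square PHYLIP layout", {
  aln <- alignment(c(a = "ACGTAC", b = "ACTTAC", c = "GCGTAC"))
  dm <- region_matrix(aln, region_spec(1, 6), engine = "identity")
  path <- withr::local_tempfile()
  write_distmatrix(dm, path)
  lines <- readLines(path)
  expect_equal(lines[1], "3")
  row2 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(row2[1], "b")
  expect_equal(as.numeric(row2[-1]), dm$d["b", ], ignore_attr = TRUE,
               tolerance = 1e-9)
})
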