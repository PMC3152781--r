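test_that("explicit alignment scoring leaves the first unit unscored", {
  expect_equal(score_alignment(strrep("A", 13), "A", strrep("M", 13)), 12)
  expect_equal(score_alignment(strrep("AC", 7), "AC", strrep("M", 14)), 12)
  # 14 bp poly-A with one substitution outside the first unit
  region <- paste0(strrep("A", 13), "G")
  expect_equal(score_alignment(region, "A", paste0(strrep("M", 13), "X")),
               12 - 5)
  # indel and N columns
  expect_equal(score_alignment("ACAC", "AC", c("M", "M", "M", "M")), 2)
  expect_equal(score_alignment("ACGAC", "AC", c("M", "M", "I", "M", "M")),
               2 - 5)
  expect_equal(score_alignment("ACNNAC", "AC", strsplit("MMNNMM", "")[[1]]),
               2 + 0)
  # contract violations
  expect_error(score_alignment("ACAC", "AC", c("M", "M", "M")),
               "inconsistent")
  expect_error(score_alignment("ACAC", "AC", c("M", "X", "M", "M")),
               "marked X")
})

test_that("minimum qualifying lengths emerge from the scoring rules", {
  # units 1-3 bp: smallest perfect qualifiers are 13, 14, 15 bp
  for (case in list(list(u = "A", need = 13), list(u = "AC", need = 14),
                    list(u = "ACG", need = 15))) {
    arr <- strrep(case$u, 20)
    for (L in (case$need - 2):(case$need + 1)) {
      h <- find_repeats(substr(arr, 1, L))
      if (L < case$need) {
        expect_equal(nrow(h), 0, label = paste(case$u, L))
      } else {
        expect_equal(nrow(h), 1)
        expect_equal(h$start, 1)
        expect_equal(h$end, L)
        expect_equal(h$score, L - nchar(case$u))
        expect_equal(h$perfection, 100)
      }
    }
  }
  # unit sizes above 12 bp: exactly two perfect units qualify
  set.seed(23)
  for (p in c(13L, 17L, 25L)) {
    u <- rand_seq(p)
    while (primitive_unit(u) != u) u <- rand_seq(p)
    two <- strrep(u, 2)
    h <- find_repeats(two)
    expect_equal(nrow(h), 1)
    expect_equal(h$score, p)
    expect_equal(h$unit_size, p)
    expect_equal(nrow(find_repeats(substr(two, 1, 2 * p - 1))), 0)
  }
})

test_that("extension stops where flanks no longer raise the score", {
  h <- find_repeats(paste0("GGG", strrep("AC", 7), "GGG"))
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end, h$score), c(4, 17, 12))
})

test_that("N runs of at most four are bridged, five split the repeat", {
  h4 <- find_repeats(paste0(strrep("AC", 10), "NNNN", strrep("AC", 10)))
  expect_equal(nrow(h4), 1)
  expect_equal(c(h4$start, h4$end, h4$score, h4$n_ncol), c(1, 44, 38, 4))
  h5 <- find_repeats(paste0(strrep("AC", 10), "NNNNN", strrep("AC", 10)))
  expect_equal(nrow(h5), 2)
  expect_equal(h5$score, c(18, 18))
  expect_equal(h5$length, c(20, 20))
  # reported hits never contain more than four successive Ns
  for (h in list(h4, h5)) expect_false(any(grepl("NNNNN", h$unit)))
})

test_that("alternative unit interpretations are reported with scores", {
  s <- paste0("TGGTTGCGTA", strrep("ACACAT", 4), "CGGTTAGCTT")
  h <- find_repeats(s)
  expect_equal(nrow(h), 1)
  expect_equal(h$unit_size, 6)
  expect_equal(h$score, 18)
  expect_equal(h$alternatives, "6:18;2:-2")
  alt <- alternative_unit_analysis(c(seq1 = s), h)
  expect_equal(alt$unit_size, c(6L, 2L))
  expect_equal(alt$score, c(18L, -2L))

  h <- find_repeats(paste0("TGGTTGCGTA", strrep("AC", 10), "CGGTTAGCTT"))
  expect_equal(h$alternatives, "2:18")
  h <- find_repeats(strrep("A", 13))
  expect_equal(h$alternatives, "1:12")
})

test_that("overlap resolution keeps the best-scoring interpretation", {
  mk <- function(start, end, unit_size, score) {
    data.frame(seq_id = "s", start = start, end = end,
               unit_size = unit_size,
               unit = strrep("A", unit_size), type = "A", motif = "A",
               score = score, length = end - start + 1,
               copy_number = (end - start + 1) / unit_size,
               perfection = 100, n_match = end - start + 1,
               n_mismatch = 0L, n_gap = 0L, n_ncol = 0L,
               alternatives = sprintf("%d:%d", unit_size, score),
               stringsAsFactors = FALSE)
  }
  # identical interval: winner keeps the loser in its alternatives
  r <- resolve_overlaps(rbind(mk(1, 24, 6, 18), mk(1, 24, 2, -2)))
  expect_equal(nrow(r), 1)
  expect_equal(r$unit_size, 6)
  expect_equal(r$alternatives, "6:18;2:-2")
  # disjoint hits pass through
  r <- resolve_overlaps(rbind(mk(1, 20, 2, 18), mk(30, 50, 3, 18)))
  expect_equal(nrow(r), 2)
  # equal score, overlapping: smaller unit size wins
  r <- resolve_overlaps(rbind(mk(1, 20, 4, 16), mk(3, 22, 2, 16)))
  expect_equal(r$unit_size, 2)
})

test_that("detection is deterministic", {
  set.seed(31)
  s <- paste0(rand_seq(50), strrep("ACG", 8), rand_seq(50))
  expect_identical(find_repeats(s), find_repeats(s))
})

test_that("hits mirror onto the reverse complement strand", {
  set.seed(37)
  for (i in 1:12) {
    p <- sample(c(1:6, 10, 17), 1)
    u <- rand_seq(p)
    while (primitive_unit(u) != u) u <- rand_seq(p)
    spec <- plant_spec(u, copies = max(3, ceiling(22 / p) + 1),
                       n_mismatch = if (p >= 2 && i %% 3 == 0) 1L else 0L)
    pl <- planted_seq(spec)
    expect_false(is.null(pl))
    s <- pl$sequence
    n <- nchar(s)
    a <- find_repeats(s)
    b <- find_repeats(reverse_complement(s))
    expect_equal(nrow(a), nrow(b))
    expect_equal(sort(a$score), sort(b$score))
    expect_equal(sort(n - a$end + 1), sort(b$start))
    expect_equal(sort(n - a$start + 1), sort(b$end))
    expect_equal(sort(canonical_type(a$unit)), sort(canonical_type(b$unit)))
  }
})

test_that("seed-and-extend equals the exhaustive oracle on random data", {
  set.seed(41)
  sch <- scoring_scheme(unit_max = 6)
  for (t in 1:60) {
    n <- sample(60:220, 1)
    s <- rand_seq(n)
    if (t %% 2 == 0) {   # salt with a near-threshold, possibly edited array
      p <- sample(1:6, 1)
      u <- rand_seq(p)
      arr <- strrep(u, sample(6:15, 1))
      if (runif(1) < 0.5 && nchar(arr) > 2 * p + 9)
        arr <- substitute_at(arr, sample((p + 2):(nchar(arr) - 7), 1))
      at <- sample(1:(n - nchar(arr) + 1), 1)
      substr(s, at, at + nchar(arr) - 1) <- arr
    }
    expect_same_hits(find_repeats(c(x = s), sch),
                     naive_repeat_oracle(c(x = s), sch))
  }
})

test_that("the oracle refuses inputs beyond its bounds", {
  expect_error(naive_repeat_oracle(strrep("A", 600)), "max_seq_len")
  expect_error(
    naive_repeat_oracle("ACGT", scoring_scheme(unit_max = 4000)),
    "unlimited|unit sizes")
})
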