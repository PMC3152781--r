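test_that("random background is seeded, composed and filterable", {
  a <- random_background(1000, gc = 0.5, seed = 7)
  b <- random_background(1000, gc = 0.5, seed = 7)
  expect_identical(as.character(a), as.character(b))
  expect_false(identical(as.character(random_background(1000, seed = 8)),
                         as.character(a)))
  g <- random_background(500, gc = 1, seed = 7)
  expect_true(grepl("^[CG]+$", as.character(g)))
  f <- random_background(2000, seed = 9, scheme = scoring_scheme())
  expect_true(attr(f, "clean"))
  expect_equal(nrow(find_repeats(as.character(f))), 0)
})

test_that("planted repeats carry exact expected scores", {
  host <- strrep("T", 200)
  r <- plant_repeat(host, plant_spec("AAG", 10, position = 50), seed = 1)
  expect_equal(r$truth$length, 30)
  expect_equal(r$truth$expected_score, 27)    # L - p for a perfect plant
  expect_equal(r$truth$expected_perfection, 100)
  expect_equal(substr(r$sequence, 50, 79), strrep("AAG", 10))

  r <- plant_repeat(host, plant_spec("A", 13, position = 50), seed = 1)
  expect_equal(r$truth$expected_score, 12)    # minimal qualifying mono

  r <- plant_repeat(host, plant_spec("AC", 10, n_mismatch = 1,
                                     position = 50), seed = 1)
  expect_equal(r$truth$expected_score, 12)    # 18 - 6
  expect_lt(r$truth$expected_perfection, 100)

  # refusal: edits that drop the plant below the qualifying score
  expect_error(plant_repeat(host, plant_spec("A", 12, position = 50)),
               "below the qualifying")
  expect_error(plant_repeat(host, plant_spec("AC", 8, n_mismatch = 2,
                                             position = 50)),
               "below the qualifying|spaced edits")
})

test_that("each edit type is recovered at its expected cost", {
  set.seed(73)
  cases <- list(plant_spec("ACGT", 10, n_mismatch = 1),
                plant_spec("AATGC", 8, n_insert = 1),
                plant_spec("ACG", 12, n_delete = 1),
                plant_spec("AC", 14, n_runs = 3L))
  for (spec in cases) {
    pl <- planted_seq(spec)
    expect_false(is.null(pl))
    h <- find_repeats(pl$sequence)
    expect_equal(nrow(h), 1)
    expect_equal(h$start, pl$truth$start)
    expect_equal(h$end, pl$truth$end)
    expect_equal(h$score, pl$truth$expected_score)
    expect_equal(h$perfection, pl$truth$expected_perfection)
    expect_equal(h$n_mismatch, pl$truth$n_mismatch)
    expect_equal(h$n_gap, pl$truth$n_gap)
    expect_equal(h$n_ncol, pl$truth$n_ncol)
  }
})

test_that("fixture genomes are reproducible and fully recovered", {
  cfg <- fixture_config(seq_lengths = c(s1 = 12000L),
                        genes_per_seq = c(s1 = 2L))
  a <- make_fixture_genome(cfg, seed = 5)
  b <- make_fixture_genome(cfg, seed = 5)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$gff, b$gff)
  expect_identical(a$truth, b$truth)
  expect_false(identical(as.character(make_fixture_genome(cfg, 6)$genome),
                         as.character(a$genome)))
  # full pipeline recovery: every truth repeat, exact interval and score
  hits <- find_repeats(a$genome, a$scheme)
  expect_equal(nrow(hits), nrow(a$truth))
  m <- merge(a$truth, hits, by = c("seq_id", "start", "end"))
  expect_equal(nrow(m), nrow(a$truth))
  expect_equal(m$score, m$expected_score)
  expect_equal(m$perfection, m$expected_perfection)
  # statistics on truth equal statistics on hits for the planted set
  expect_equal(sum(m$length.x), sum(m$length.y))
})

test_that("fixture bundles round-trip through the writers", {
  cfg <- fixture_config(seq_lengths = c(s1 = 12000L),
                        genes_per_seq = c(s1 = 2L))
  bundle <- make_fixture_genome(cfg, seed = 5)
  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  write_fixture(bundle, d1)
  write_fixture(make_fixture_genome(cfg, seed = 5), d2)
  for (f in c("genome.fa", "annotation.gff3", "truth.tsv", "config.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  x <- read_fasta(file.path(d1, "genome.fa"))
  expect_identical(as.character(x), as.character(bundle$genome))
  feats <- read_gff(file.path(d1, "annotation.gff3"))
  expect_gt(nrow(feats), 0)
})

test_that("strand-asymmetric CDS plants show up as strandedness", {
  cfg <- fixture_config(seq_lengths = c(s1 = 16000L),
                        genes_per_seq = c(s1 = 3L),
                        plants = data.frame(
                          unit = c("AAG", "AAG", "AC"),
                          copies = c(8, 7, 10),
                          n_mismatch = 0, n_insert = 0, n_delete = 0,
                          nrun = 0,
                          region = c("CDS", "CDS", "intergenic"),
                          strand = "+"))
  fx <- make_fixture_genome(cfg, seed = 9)
  rh <- scan_regions(fx$fragments, fx$scheme)
  eff <- region_effective_bp(fx$fragments)
  st <- strandedness_table(rh, eff)
  cds <- st[st$region == "CDS" & st$motif == "AAG", ]
  expect_equal(nrow(cds), 1)
  expect_gt(cds$density, 0)
  expect_equal(cds$rc_density, 0)   # plants sit on the sense strand only
  expect_equal(cds$label, "a")
})

test_that("empty plant panels give empty truth and statistics", {
  cfg <- fixture_config(seq_lengths = c(s1 = 9000L),
                        genes_per_seq = c(s1 = 1L),
                        plants = fixture_config()$plants[0, ])
  fx <- make_fixture_genome(cfg, seed = 4)
  expect_equal(nrow(fx$truth), 0)
  hits <- find_repeats(fx$genome, fx$scheme)
  expect_equal(nrow(hits), 0)
  tab <- summarize_repeats(hits, effective_bp = 9000)
  expect_equal(nrow(tab), 0)
})

test_that("oversubscribed regions raise a configuration error", {
  cfg <- fixture_config(seq_lengths = c(s1 = 9000L),
                        genes_per_seq = c(s1 = 1L),
                        plants = data.frame(
                          unit = "ACGTACGTTGCAA", copies = 40,
                          n_mismatch = 0, n_insert = 0, n_delete = 0,
                          nrun = 0, region = "five_prime_UTR",
                          strand = "+"))
  expect_error(make_fixture_genome(cfg, seed = 2), "no room")
})
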