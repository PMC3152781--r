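# shared helpers for the trscan test suite; all fixtures are built in code

rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

substitute_at <- function(s, pos, base = NULL) {
  old <- substr(s, pos, pos)
  if (is.null(base)) base <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  substr(s, pos, pos) <- base
  s
}

# a sequence with a planted array inside non-extending random flanks,
# verified so the expected hit interval is exact
planted_seq <- function(spec, flank = 60L, scheme = scoring_scheme()) {
  p <- nchar(spec$unit)
  plen <- round(spec$copies * p) + spec$n_insert - spec$n_delete
  bg <- as.character(random_background(plen + 2L * flank, 0.5,
                                       scheme = scheme))
  plant_verified(bg, spec, at = flank + 1L, scheme = scheme)
}

# columns compared when checking detector output equality
HIT_KEY_COLS <- c("seq_id", "start", "end", "unit_size", "unit", "score",
                  "perfection", "n_match", "n_mismatch", "n_gap", "n_ncol",
                  "alternatives")

expect_same_hits <- function(a, b) {
  expect_equal(a[, HIT_KEY_COLS], b[, HIT_KEY_COLS])
}

# small deterministic gene annotation for region tests
demo_gff_lines <- function() {
  c("scf1\tdemo\tgene\t101\t700\t.\t+\t.\tID=g1",
    "scf1\tdemo\tmRNA\t101\t700\t.\t+\t.\tID=g1.t1;Parent=g1",
    "scf1\tdemo\texon\t101\t300\t.\t+\t.\tParent=g1.t1",
    "scf1\tdemo\texon\t401\t700\t.\t+\t.\tParent=g1.t1",
    "scf1\tdemo\tCDS\t151\t300\t.\t+\t.\tParent=g1.t1",
    "scf1\tdemo\tCDS\t401\t650\t.\t+\t.\tParent=g1.t1",
    "scf1\tdemo\tstart_codon\t151\t153\t.\t+\t.\tParent=g1.t1",
    "scf1\tdemo\tstop_codon\t648\t650\t.\t+\t.\tParent=g1.t1")
}
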