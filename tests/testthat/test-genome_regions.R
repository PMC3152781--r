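write_gff_tmp <- function(lines) {
  f <- tempfile(fileext = ".gff")
  writeLines(lines, f)
  f
}

test_that("GFF parsing keeps 1-based coordinates and flags bad lines", {
  f <- write_gff_tmp("scaf1\t.\texon\t1\t100\t.\t+\t.\tID=e1")
  g <- read_gff(f)
  expect_equal(c(g$start, g$end), c(1L, 100L))
  expect_equal(g$feature_id, "e1")

  f <- write_gff_tmp("scaf1\t.\texon\t1\t100\t.\t+\t.")   # 8 columns
  expect_error(read_gff(f), "line 1.*8 column")
  f <- write_gff_tmp(c("# comment", "scaf1\t.\texon\t200\t100\t.\t+\t.\tx"))
  expect_error(read_gff(f), "line 2.*end")
  f <- write_gff_tmp("scaf1\t.\texon\t1\t100\t.\t*\t.\tx")
  expect_error(read_gff(f), "strand")
})

test_that("GTF-style and bare group fields are parsed permissively", {
  f <- write_gff_tmp(c(
    'scaf1\t.\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1"',
    "scaf1\t.\texon\t201\t300\t.\t+\t.\tt2"))
  g <- read_gff(f)
  expect_equal(g$model_id, c("t1", "t2"))
  models <- gene_models(g)
  expect_equal(sort(vapply(models, `[[`, "", "id")), c("t1", "t2"))
})

test_that("alternative transcripts become separate models at one locus", {
  f <- write_gff_tmp(c(
    "scaf1\t.\texon\t1\t100\t.\t+\t.\tParent=t1",
    "scaf1\t.\texon\t1\t100\t.\t+\t.\tParent=t2",
    "scaf1\t.\texon\t151\t250\t.\t+\t.\tParent=t2"))
  models <- gene_models(read_gff(f))
  expect_equal(length(models), 2)
  # dedup removes the longer of the two overlapping same-strand models
  kept <- dedup_gene_models(models)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$id, "t1")
})

test_that("gene model dedup removes the longer same-strand span only", {
  mk <- function(id, start, end, strand = "+") {
    list(id = id, seqid = "s", strand = strand,
         exons = data.frame(start = start, end = end),
         cds = data.frame(start = integer(), end = integer()),
         start_codon = data.frame(start = integer(), end = integer()),
         stop_codon = data.frame(start = integer(), end = integer()))
  }
  kept <- dedup_gene_models(list(mk("long", 1, 500), mk("short", 101, 400)))
  expect_equal(vapply(kept, `[[`, "", "id"), "short")
  # opposite strands: both kept (nested antisense genes survive)
  kept <- dedup_gene_models(list(mk("a", 1, 500), mk("b", 101, 400, "-")))
  expect_equal(length(kept), 2)
  kept <- dedup_gene_models(list(mk("a", 1, 100), mk("b", 201, 300)))
  expect_equal(length(kept), 2)
  # equal spans: the rightmost is removed
  kept <- dedup_gene_models(list(mk("a", 1, 100), mk("b", 51, 150)))
  expect_equal(vapply(kept, `[[`, "", "id"), "a")
})

test_that("feature dedup removes the longer overlapping feature", {
  m <- list(id = "m", seqid = "s", strand = "+",
            exons = data.frame(start = c(1, 101), end = c(300, 200)),
            cds = data.frame(start = integer(), end = integer()),
            start_codon = data.frame(start = integer(), end = integer()),
            stop_codon = data.frame(start = integer(), end = integer()))
  d <- dedup_features(m)
  expect_equal(d$exons, data.frame(start = 101, end = 200))
  # identical lengths: keep the leftmost
  m$exons <- data.frame(start = c(1, 51), end = c(100, 150))
  expect_equal(dedup_features(m)$exons, data.frame(start = 1, end = 100))
  m$exons <- data.frame(start = c(1, 201), end = c(100, 300))
  expect_equal(dedup_features(m)$exons, m$exons)
})

test_that("introns are the gaps between consecutive exons", {
  m <- list(id = "m", seqid = "s", strand = "+",
            exons = data.frame(start = c(1, 201), end = c(100, 300)),
            cds = data.frame(start = integer(), end = integer()),
            start_codon = data.frame(start = integer(), end = integer()),
            stop_codon = data.frame(start = integer(), end = integer()))
  expect_equal(infer_introns(m), data.frame(start = 101, end = 200))
  m$exons <- data.frame(start = 1, end = 100)
  expect_equal(nrow(infer_introns(m)), 0)
  m$exons <- data.frame(start = c(1, 201, 501), end = c(100, 300, 600))
  expect_equal(infer_introns(m),
               data.frame(start = c(101, 301), end = c(200, 500)))
})

test_that("UTRs are inferred from codon positions, strand-aware", {
  base <- list(id = "m", seqid = "s", strand = "+",
               exons = data.frame(start = 1, end = 300),
               cds = data.frame(start = integer(), end = integer()),
               start_codon = data.frame(start = 101, end = 103),
               stop_codon = data.frame(start = 298, end = 300))
  u <- infer_utrs(base)
  expect_equal(u$five_prime, data.frame(start = 1, end = 100))
  expect_equal(nrow(u$three_prime), 0)
  # minus-strand mirror: 5' UTR sits at the right end
  m <- base
  m$strand <- "-"
  m$start_codon <- data.frame(start = 198, end = 200)
  m$stop_codon <- data.frame(start = 11, end = 13)
  u <- infer_utrs(m)
  expect_equal(u$five_prime, data.frame(start = 201, end = 300))
  expect_equal(u$three_prime, data.frame(start = 1, end = 10))
  # no codon annotation: no UTRs
  m <- base
  m$start_codon <- data.frame(start = integer(), end = integer())
  u <- infer_utrs(m)
  expect_equal(nrow(u$five_prime) + nrow(u$three_prime), 0)
  expect_false(u$flagged)
  # codon outside the exons: flagged, UTRs empty
  m <- base
  m$start_codon <- data.frame(start = 401, end = 403)
  u <- infer_utrs(m)
  expect_true(u$flagged)
  expect_equal(nrow(u$five_prime) + nrow(u$three_prime), 0)
})

test_that("intergenic regions complement the gene spans", {
  mk <- function(start, end) {
    list(id = "m", seqid = "s", strand = "+",
         exons = data.frame(start = start, end = end),
         cds = data.frame(start = integer(), end = integer()),
         start_codon = data.frame(start = integer(), end = integer()),
         stop_codon = data.frame(start = integer(), end = integer()))
  }
  ig <- infer_intergenic(c(s = 1000L), list(mk(101, 200)))
  expect_equal(ig$start, c(1, 201))
  expect_equal(ig$end, c(100, 1000))
  ig <- infer_intergenic(c(s = 1000L), list())
  expect_equal(c(ig$start, ig$end), c(1, 1000))
  ig <- infer_intergenic(c(s = 300L), list(mk(1, 300)))
  expect_equal(nrow(ig), 0)
})

test_that("extracted fragments carry sense-strand sequence and partition", {
  set.seed(61)
  g <- rand_seq(1000)
  lines <- c(demo_gff_lines(),
             "scf1\tdemo\texon\t801\t960\t.\t-\t.\tParent=g2.t1")
  f <- write_gff_tmp(lines)
  models <- dedup_gene_models(gene_models(read_gff(f)))
  fr <- extract_regions(c(scf1 = g), models)
  # minus-strand fragment holds the reverse complement of the slice
  mf <- fr[fr$strand == "-", ][1, ]
  expect_equal(mf$sequence,
               reverse_complement(substr(g, mf$start, mf$end)))
  pf <- fr[fr$kind == "intron", ][1, ]
  expect_equal(pf$sequence, substr(g, pf$start, pf$end))
  # partition: intergenic + gene spans tile the sequence
  span_of <- function(m) {
    iv <- rbind(m$exons, m$cds, m$start_codon, m$stop_codon)
    c(min(iv$start), max(iv$end))
  }
  gene_bp <- sum(vapply(models, function(m) diff(span_of(m)) + 1L,
                        integer(1)))
  ig_bp <- sum(fr$end[fr$kind == "intergenic"] -
                 fr$start[fr$kind == "intergenic"] + 1L)
  expect_equal(gene_bp + ig_bp, 1000L)
  # exon + intron lengths fill each gene span
  for (m in models) {
    sp <- span_of(m)
    ex <- fr[fr$kind %in% c("exon", "intron") &
               fr$start >= sp[1] & fr$end <= sp[2], ]
    expect_equal(sum(ex$end - ex$start + 1L), diff(sp) + 1L)
  }
  # out-of-bounds model is rejected by name
  bad <- models
  bad[[1]]$exons$end[2] <- 2000L
  expect_error(extract_regions(c(scf1 = g), bad), bad[[1]]$id)
})

test_that("region extraction is invariant to GFF record order", {
  set.seed(67)
  g <- rand_seq(1000)
  lines <- demo_gff_lines()
  f1 <- write_gff_tmp(lines)
  f2 <- write_gff_tmp(rev(lines))
  fr1 <- extract_regions(c(scf1 = g), gene_models(read_gff(f1)))
  fr2 <- extract_regions(c(scf1 = g), gene_models(read_gff(f2)))
  expect_equal(fr1, fr2)
})

test_that("strand round trip: mirrored genome and annotation give the same fragments", {
  set.seed(71)
  g <- rand_seq(1000)
  f <- write_gff_tmp(demo_gff_lines())
  feats <- read_gff(f)
  fr <- extract_regions(c(scf1 = g), gene_models(feats))
  # mirror: reverse-complement the genome and flip all coordinates/strands
  n <- nchar(g)
  m <- feats
  m$start <- n - feats$end + 1L
  m$end <- n - feats$start + 1L
  m$strand <- ifelse(feats$strand == "+", "-", "+")
  fr2 <- extract_regions(c(scf1 = reverse_complement(g)), gene_models(m))
  for (kind in c("CDS", "intron", "five_prime_UTR", "three_prime_UTR")) {
    expect_setequal(fr2$sequence[fr2$kind == kind],
                    fr$sequence[fr$kind == kind])
  }
})

test_that("model_key resolution failure names the line", {
  f <- write_gff_tmp("scaf1\t.\texon\t1\t100\t.\t+\t.\tfoo=bar; baz=1")
  expect_error(gene_models(read_gff(f)), "line 1")
})
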