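# Synthetic genomes with planted repeats of known truth.  Everything is
# driven by an explicit seed so fixtures are byte-reproducible.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random background sequence at a given GC content
#'
#' Draws i.i.d. bases at the requested composition from a seeded
#' generator.  With a `scheme`, the background is rejection-filtered: it
#' is regenerated until the detector finds no qualifying repeat in it, so
#' planted repeats are the only signal.  If filtering fails within
#' `max_tries` the last draw is returned with attribute `clean = FALSE`
#' and a warning.
#'
#' @param length Sequence length in bp.
#' @param gc GC content in `[0, 1]`.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param scheme Optional [scoring_scheme()] used for rejection filtering.
#' @param max_tries Bounded retries for the rejection filter.
#' @return A character string with attribute `clean`.
#' @export
random_background <- function(length, gc = 0.5, seed = NULL, scheme = NULL,
                              max_tries = 20L) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    draw <- function() paste(sample(names(probs), length, replace = TRUE,
                                    prob = probs), collapse = "")
    s <- draw()
    clean <- TRUE
    if (!is.null(scheme)) {
      tries <- 1L
      while (nrow(find_repeats(s, scheme)) > 0L && tries < max_tries) {
        s <- draw()
        tries <- tries + 1L
      }
      clean <- nrow(find_repeats(s, scheme)) == 0L
      if (!clean)
        warning("background still contains qualifying repeats after ",
                max_tries, " draws")
    }
    structure(s, clean = clean)
  })
}

#' Specification of one planted repeat
#'
#' @param unit Repeat unit (A/C/G/T).
#' @param copies Copy number; may be fractional, at least 2.
#' @param n_mismatch,n_insert,n_delete Number of substitutions /
#'   insertions / deletions applied at seeded positions outside the first
#'   and last repeat unit.  Insertions and deletions are not supported for
#'   mononucleotide units, where they merely change the array length.
#' @param n_runs Integer vector of N-run lengths to plant (each at most
#'   the detector's N cap to remain detectable).
#' @param position 1-based offset in the target sequence, or `"random"`.
#' @param strand `"+"` or `"-"`: orientation of the unit on the genomic
#'   forward strand relative to the sense strand of the target region.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(unit, copies, n_mismatch = 0L, n_insert = 0L,
                       n_delete = 0L, n_runs = integer(),
                       position = "random", strand = "+") {
  check_unit(unit, allow_n = FALSE)
  if (primitive_unit(unit) != unit)
    stop("unit ", unit, " is not primitive; use ", primitive_unit(unit))
  if (copies < 2) stop("a tandem repeat needs at least 2 copies")
  p <- nchar(unit)
  if (p == 1L && (n_insert > 0L || n_delete > 0L))
    stop("indels in mononucleotide repeats only change the array length")
  if (length(n_runs) && any(n_runs < 1L))
    stop("N-run lengths must be positive")
  stopifnot(strand %in% c("+", "-"))
  structure(list(unit = unit, copies = copies,
                 n_mismatch = as.integer(n_mismatch),
                 n_insert = as.integer(n_insert),
                 n_delete = as.integer(n_delete),
                 n_runs = as.integer(n_runs),
                 position = position, strand = strand),
            class = "plant_spec")
}

# expected alignment bookkeeping for a planted array
plant_truth_counts <- function(p, L0, x, i, d, nruns) {
  nn <- sum(nruns)
  n_match <- L0 - x - d - nn
  cols <- n_match + x + i + d + nn
  score <- (n_match - p) - 5L * (x + i + d)  # with the default scheme
  list(n_match = n_match, n_mismatch = x, n_gap = i + d, n_ncol = nn,
       cols = cols, length = L0 + i - d, score = score,
       perfection = 100 * n_match / cols)
}

#' Plant a tandem repeat into a sequence
#'
#' Writes a perfect array of the unit, then applies the requested
#' substitutions, insertions, deletions and N runs at seeded positions
#' outside the first and last repeat unit (and clear of the array ends),
#' keeping the expected score and perfection bookkeeping exact.  Edits are
#' spaced so their score contributions are independent.  The function
#' refuses edits that would push the plant below the qualifying score.
#'
#' @param seq Target sequence (character scalar).
#' @param spec A [plant_spec()].
#' @param seed Integer seed for edit/position choices (`NULL` = current
#'   RNG).
#' @param scheme [scoring_scheme()] used for the qualifying-score check.
#' @return A list with `sequence` (modified) and `truth` (one-row
#'   data.frame: `start`, `end`, `unit`, `unit_size`, `length`,
#'   `expected_score`, `expected_perfection`, plus expected column
#'   counts).
#' @export
plant_repeat <- function(seq, spec, seed = NULL,
                         scheme = scoring_scheme()) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(seed, {
    u <- spec$unit
    p <- nchar(u)
    L0 <- round(spec$copies * p)
    if (L0 < 2L * p) stop("plant shorter than two units")
    arr <- substr(strrep(u, ceiling(L0 / p) + 1L), 1L, L0)
    tc <- plant_truth_counts(p, L0, spec$n_mismatch, spec$n_insert,
                             spec$n_delete, spec$n_runs)
    exp_score <- (tc$n_match - p) * scheme$match_score +
      tc$n_mismatch * scheme$mismatch_score +
      tc$n_gap * scheme$gap_score + tc$n_ncol * scheme$n_score
    if (exp_score < min_score_rule(scheme, p))
      stop(sprintf(
        "plant (%s)x%g with %d edits scores %d, below the qualifying %d",
        u, spec$copies, spec$n_mismatch + spec$n_insert + spec$n_delete +
          length(spec$n_runs), exp_score, min_score_rule(scheme, p)))
    # event sites: 1-based positions in the array, outside the first unit
    # and clear of the tail, so every edit is followed by enough matches
    # and both terminal units stay perfect (keeps scores strand-symmetric)
    margin <- max(p + 2L, 8L)
    n_events <- spec$n_mismatch + spec$n_insert + spec$n_delete +
      length(spec$n_runs)
    events <- character(0)
    if (n_events > 0L) {
      lo <- p + 2L
      hi <- L0 - margin
      width <- max(spec$n_runs, 1L) + 7L  # min spacing between event sites
      if (hi < lo || (hi - lo) %/% width + 1L < n_events)
        stop("array too short to hold ", n_events, " spaced edits")
      sites <- sort(sample(seq(lo, hi, by = width), n_events))
      events <- sample(c(rep("X", spec$n_mismatch),
                         rep("I", spec$n_insert),
                         rep("D", spec$n_delete),
                         rep("R", length(spec$n_runs))))
      runs <- spec$n_runs
      achars <- strsplit(arr, "")[[1L]]
      edits <- vector("list", n_events)
      for (k in seq_len(n_events)) {
        pos <- sites[k]
        ev <- events[k]
        if (ev == "X") {
          edits[[k]] <- list(op = "X", pos = pos,
                             base = sample(setdiff(c("A", "C", "G", "T"),
                                                   achars[pos]), 1L))
        } else if (ev == "I") {
          edits[[k]] <- list(op = "I", pos = pos,
                             base = sample(setdiff(c("A", "C", "G", "T"),
                                                   achars[pos]), 1L))
        } else if (ev == "D") {
          edits[[k]] <- list(op = "D", pos = pos)
        } else {
          len <- runs[1L]; runs <- runs[-1L]
          edits[[k]] <- list(op = "R", pos = pos, len = len)
        }
      }
      # apply right-to-left so positions stay valid
      for (k in rev(seq_len(n_events))) {
        e <- edits[[k]]
        if (e$op == "X") {
          substr(arr, e$pos, e$pos) <- e$base
        } else if (e$op == "I") {
          arr <- paste0(substr(arr, 1L, e$pos - 1L), e$base,
                        substr(arr, e$pos, nchar(arr)))
        } else if (e$op == "D") {
          arr <- paste0(substr(arr, 1L, e$pos - 1L),
                        substr(arr, e$pos + 1L, nchar(arr)))
        } else {
          substr(arr, e$pos, e$pos + e$len - 1L) <-
            strrep("N", e$len)
        }
      }
    }
    stopifnot(nchar(arr) == tc$length)
    pos <- spec$position
    if (identical(pos, "random")) {
      if (nchar(seq) < nchar(arr)) stop("plant does not fit in sequence")
      pos <- sample.int(nchar(seq) - nchar(arr) + 1L, 1L)
    }
    if (pos < 1L || pos + nchar(arr) - 1L > nchar(seq))
      stop("plant does not fit in sequence at position ", pos)
    out <- seq
    substr(out, pos, pos + nchar(arr) - 1L) <- arr
    truth <- data.frame(start = pos, end = pos + nchar(arr) - 1L,
                        unit = u, unit_size = p, length = tc$length,
                        expected_score = exp_score,
                        expected_perfection = tc$perfection,
                        n_match = tc$n_match, n_mismatch = tc$n_mismatch,
                        n_gap = tc$n_gap, n_ncol = tc$n_ncol,
                        stringsAsFactors = FALSE)
    list(sequence = out, truth = truth)
  })
}

#' Default configuration for a synthetic fixture genome
#'
#' Two scaffolds with gene models on both strands and a panel of plants
#' covering mono- to hexanucleotide microsatellites, a 17 bp minisatellite,
#' larger units, imperfect arrays, an N-bridged array, and strand-biased
#' AAG plants restricted to CDS sense strands.
#'
#' @param seq_lengths Named vector of scaffold lengths.
#' @param gc Background GC content.
#' @param genes_per_seq Genes laid out per scaffold.
#' @param plants A data.frame describing the plants (see the default for
#'   the column set).
#' @param scheme Detection scheme used for background filtering and plant
#'   verification.  Genome-scale fixture scans use a finite maximum score
#'   reduction of 30 so extension dies out quickly in random background.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seq_lengths = c(scf1 = 30000L, scf2 = 20000L),
                           gc = 0.45,
                           genes_per_seq = c(scf1 = 4L, scf2 = 3L),
                           plants = NULL,
                           scheme = scoring_scheme(
                             unit_max = 50L, max_score_reduction = 30)) {
  if (is.null(plants)) {
    plants <- rbind(
      data.frame(unit = "A", copies = 15, n_mismatch = 0, n_insert = 0,
                 n_delete = 0, nrun = 0, region = "intergenic", strand = "+"),
      data.frame(unit = "AC", copies = 10, n_mismatch = 0, n_insert = 0,
                 n_delete = 0, nrun = 0, region = "intergenic", strand = "+"),
      data.frame(unit = "AC", copies = 20, n_mismatch = 0, n_insert = 0,
                 n_delete = 0, nrun = 4, region = "intergenic", strand = "+"),
      data.frame(unit = "AAG", copies = 8, n_mismatch = 0, n_insert = 0,
                 n_delete = 0, nrun = 0, region = "CDS", strand = "+"),
      data.frame(unit = "AAG", copies = 7, n_mismatch = 0, n_insert = 0,
                 n_delete = 0, nrun = 0, region = "CDS", strand = "+"),
      data.frame(unit = "AT", copies = 9, n_mismatch = 0, n_insert = 0,
                 n_delete = 0, nrun = 0, region = "intron", strand = "+"),
      data.frame(unit = "ACGT", copies = 8, n_mismatch = 1, n_insert = 0,
                 n_delete = 0, nrun = 0, region = "intron", strand = "+"),
      data.frame(unit = "AATGC", copies = 7, n_mismatch = 0, n_insert = 1,
                 n_delete = 0, nrun = 0, region = "intergenic", strand = "-"),
      data.frame(unit = "ACACAT", copies = 6, n_mismatch = 0, n_insert = 0,
                 n_delete = 0, nrun = 0, region = "five_prime_UTR",
                 strand = "+"),
      data.frame(unit = "AAAAGTTCAACTTTATG", copies = 4, n_mismatch = 1,
                 n_insert = 0, n_delete = 0, nrun = 0,
                 region = "intergenic", strand = "+"),
      data.frame(unit = "ACGGATTACCGTGGCAATCGATTGG", copies = 3,
                 n_mismatch = 0, n_insert = 0, n_delete = 0, nrun = 0,
                 region = "intergenic", strand = "+"),
      data.frame(unit = "CGT", copies = 8, n_mismatch = 0, n_insert = 0,
                 n_delete = 1, nrun = 0, region = "three_prime_UTR",
                 strand = "+"))
  }
  structure(list(seq_lengths = seq_lengths, gc = gc,
                 genes_per_seq = genes_per_seq, plants = plants,
                 scheme = scheme),
            class = "fixture_config")
}

# lay out evenly spaced three-exon gene models on alternating strands and
# return list(models, gff_rows)
layout_genes <- function(seq_lengths, genes_per_seq) {
  models <- list()
  gff <- list()
  for (sq in names(seq_lengths)) {
    len <- seq_lengths[[sq]]
    ng <- genes_per_seq[[sq]]
    if (ng == 0L) next
    ex_len <- c(500L, 600L, 500L)
    in_len <- 400L
    span <- sum(ex_len) + 2L * in_len          # 2400
    stride <- (len - 1000L) %/% max(ng, 1L)
    if (stride < span + 800L)
      stop("sequence ", sq, " too short for ", ng, " gene models")
    for (g in seq_len(ng)) {
      gs <- 500L + (g - 1L) * stride
      strand <- if (g %% 2L == 1L) "+" else "-"
      e1 <- c(gs, gs + ex_len[1L] - 1L)
      e2 <- c(e1[2L] + in_len + 1L, e1[2L] + in_len + ex_len[2L])
      e3 <- c(e2[2L] + in_len + 1L, e2[2L] + in_len + ex_len[3L])
      exons <- data.frame(start = c(e1[1L], e2[1L], e3[1L]),
                          end = c(e1[2L], e2[2L], e3[2L]))
      if (strand == "+") {
        sc <- c(e1[1L] + 150L, e1[1L] + 152L)
        pc <- c(e3[2L] - 152L, e3[2L] - 150L)
      } else {
        sc <- c(e3[2L] - 152L, e3[2L] - 150L)
        pc <- c(e1[1L] + 150L, e1[1L] + 152L)
      }
      cds_lo <- min(sc[1L], pc[1L])
      cds_hi <- max(sc[2L], pc[2L])
      cds <- df_of(IRanges::intersect(iranges_of(exons),
                                      IRanges::IRanges(cds_lo, cds_hi)))
      id <- sprintf("%s.g%d.t1", sq, g)
      models[[length(models) + 1L]] <- list(
        id = id, seqid = sq, strand = strand, exons = exons, cds = cds,
        start_codon = data.frame(start = sc[1L], end = sc[2L]),
        stop_codon = data.frame(start = pc[1L], end = pc[2L]))
      gene_id <- sprintf("%s.g%d", sq, g)
      row <- function(type, s, e, attrs)
        sprintf("%s\ttrscan_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                sq, type, s, e, strand, attrs)
      gff[[length(gff) + 1L]] <- c(
        row("gene", e1[1L], e3[2L], sprintf("ID=%s", gene_id)),
        row("mRNA", e1[1L], e3[2L],
            sprintf("ID=%s;Parent=%s", id, gene_id)),
        vapply(seq_len(nrow(exons)), function(i)
          row("exon", exons$start[i], exons$end[i],
              sprintf("ID=%s.e%d;Parent=%s", id, i, id)), character(1L)),
        vapply(seq_len(nrow(cds)), function(i)
          row("CDS", cds$start[i], cds$end[i],
              sprintf("ID=%s.c%d;Parent=%s", id, i, id)), character(1L)),
        row("start_codon", sc[1L], sc[2L],
            sprintf("ID=%s.sc;Parent=%s", id, id)),
        row("stop_codon", pc[1L], pc[2L],
            sprintf("ID=%s.pc;Parent=%s", id, id)))
    }
  }
  list(models = models, gff = unlist(gff))
}

#' Generate a synthetic genome with planted repeats and annotations
#'
#' Builds a small multi-scaffold genome: rejection-filtered random
#' background, evenly spaced gene models on both strands (emitted as
#' GFF3), and the configured panel of planted repeats placed inside
#' requested region kinds with at least 60 bp of repeat-free padding, so
#' hits can never merge under the fixture scheme.  Plant flanks are
#' resampled until each plant is recovered exactly (detector-verified
#' construction, like the background filter), so the emitted truth table
#' is correct by construction.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @return A list: `genome` (DNAStringSet), `gff` (character GFF3 lines),
#'   `models`, `fragments`, `truth` (data.frame with genomic coordinates,
#'   expected scores/perfection, region kind, sense-strand unit and
#'   motif), `scheme`, `config`, `seed`.
#' @export
make_fixture_genome <- function(config = fixture_config(), seed = 1L) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(seed, {
    scheme <- config$scheme
    genome <- vapply(names(config$seq_lengths), function(sq) {
      as.character(random_background(config$seq_lengths[[sq]], config$gc,
                                     seed = NULL, scheme = scheme))
    }, character(1L))
    lay <- layout_genes(config$seq_lengths, config$genes_per_seq)
    fragments <- extract_regions(genome, lay$models)
    usable <- fragments[fragments$kind != "exon", , drop = FALSE]
    occupied <- lapply(config$seq_lengths, function(...) {
      data.frame(start = integer(), end = integer())
    })
    pad <- 60L
    truth <- list()
    plants <- config$plants
    for (r in seq_len(nrow(plants))) {
      pl <- plants[r, ]
      spec <- plant_spec(pl$unit, pl$copies, pl$n_mismatch, pl$n_insert,
                         pl$n_delete,
                         n_runs = if (pl$nrun > 0) pl$nrun else integer(),
                         strand = pl$strand)
      built <- plant_repeat(strrep("A", 10000L), spec, seed = NULL,
                            scheme = scheme)
      plen <- built$truth$length
      cand <- usable[usable$kind == pl$region &
                       (nchar(usable$sequence) >= plen + 2L * 10L), ,
                     drop = FALSE]
      placed <- FALSE
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      for (f in seq_len(nrow(cand))) {
        fr <- cand[f, ]
        # offsets are in genomic coordinates within the fragment
        lo <- fr$start + 10L
        hi <- fr$end - 10L - plen + 1L
        if (hi < lo) next
        occ <- occupied[[fr$seq_id]]
        ok_off <- NULL
        for (try in seq_len(50L)) {
          off <- sample.int(hi - lo + 1L, 1L) + lo - 1L
          if (!any(occ$start <= off + plen - 1L + pad &
                     occ$end >= off - pad)) { ok_off <- off; break }
        }
        if (is.null(ok_off)) next
        res <- plant_verified(genome[[fr$seq_id]], spec, ok_off,
                              fr$strand, scheme)
        if (is.null(res)) next
        genome[[fr$seq_id]] <- res$sequence
        tr <- res$truth
        tr$seq_id <- fr$seq_id
        tr$region <- pl$region
        tr$fragment_strand <- fr$strand
        tr$sense_unit <- pl$unit
        tr$sense_motif <- canonical_motif(pl$unit)
        tr$type <- canonical_type(pl$unit)
        truth[[length(truth) + 1L]] <- tr
        occupied[[fr$seq_id]] <- rbind(occ, data.frame(start = tr$start,
                                                       end = tr$end))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("no room for plant (", pl$unit, ")x", pl$copies,
             " in region ", pl$region)
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth))
      truth <- data.frame(start = integer(), end = integer(),
                          unit = character(), unit_size = integer(),
                          length = integer(), expected_score = integer(),
                          expected_perfection = numeric(),
                          n_match = integer(), n_mismatch = integer(),
                          n_gap = integer(), n_ncol = integer(),
                          seq_id = character(), region = character(),
                          fragment_strand = character(),
                          sense_unit = character(),
                          sense_motif = character(), type = character(),
                          stringsAsFactors = FALSE)
    truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    # refresh fragments with the planted genome so sequences match
    fragments <- extract_regions(genome, lay$models)
    list(genome = as_dna(genome), gff = c("##gff-version 3", lay$gff),
         models = lay$models, fragments = fragments, truth = truth,
         scheme = scheme, config = config, seed = seed)
  })
}

#' Plant a repeat at a genomic position with verified flanks
#'
#' Builds the requested array, inserts it (reverse-complemented for
#' minus-strand targets) at the given position, and verifies by local
#' detection that exactly the intended hit is recovered with its expected
#' interval and score.  If background bases adjacent to the plant happen
#' to continue the repeat pattern (which would legitimately extend the
#' hit past the intended interval), the flanking windows are resampled
#' from the current RNG and the check is repeated — the same
#' detector-verified construction used for the background rejection
#' filter.
#'
#' @param seq Target sequence (character scalar).
#' @param spec A [plant_spec()].
#' @param at 1-based insertion position.
#' @param frag_strand `"+"`, `"-"` or `"."`: strand of the surrounding
#'   region fragment; minus inserts the reverse complement.
#' @param scheme [scoring_scheme()] used for verification.
#' @param max_tries Flank resampling attempts before giving up.
#' @return A list with `sequence` and a one-row `truth` data.frame, or
#'   `NULL` if verification keeps failing.
#' @export
plant_verified <- function(seq, spec, at, frag_strand = "+",
                           scheme = scoring_scheme(), max_tries = 30L) {
  p <- nchar(spec$unit)
  for (try in seq_len(max_tries)) {
    built <- plant_repeat(strrep("A", spec$copies * p * 2L + 100L), spec,
                          seed = NULL, scheme = scheme)
    arr <- substr(built$sequence, built$truth$start,
                  built$truth$end)
    if (frag_strand == "-") arr <- reverse_complement(arr)
    s <- seq
    substr(s, at, at + nchar(arr) - 1L) <- arr
    win_lo <- max(1L, at - 40L)
    win_hi <- min(nchar(s), at + nchar(arr) - 1L + 40L)
    hits <- find_repeats(substr(s, win_lo, win_hi), scheme)
    want_start <- at - win_lo + 1L
    want_end <- want_start + nchar(arr) - 1L
    ok <- nrow(hits) == 1L &&
      hits$start == want_start && hits$end == want_end &&
      hits$score == built$truth$expected_score &&
      hits$unit_size == built$truth$unit_size
    if (ok) {
      tr <- built$truth
      tr$start <- at
      tr$end <- at + nchar(arr) - 1L
      return(list(sequence = s, truth = tr))
    }
    # resample the flanking windows and retry
    flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
    lo2 <- max(1L, at - 20L)
    hi2 <- min(nchar(seq), at + nchar(arr) - 1L + 20L)
    substr(seq, lo2, at - 1L) <- flank(at - lo2)
    substr(seq, at + nchar(arr), hi2) <- flank(hi2 - (at + nchar(arr)) + 1L)
  }
  NULL
}

#' Write a fixture bundle to disk
#'
#' Emits `genome.fa` (60-column FASTA), `annotation.gff3`, `truth.tsv`
#' and `config.txt` (flat key = value echo).  Output is byte-identical for
#' identical config and seed.
#'
#' @param bundle A fixture from [make_fixture_genome()].
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "annotation.gff3"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.txt"))
  write_fasta(bundle$genome, paths[["genome"]])
  writeLines(bundle$gff, paths[["gff"]])
  write.table(bundle$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- bundle$config
  writeLines(c(
    sprintf("seed = %d", bundle$seed),
    sprintf("seq.%s = %d", names(cfg$seq_lengths), cfg$seq_lengths),
    sprintf("gc = %g", cfg$gc),
    sprintf("genes.%s = %d", names(cfg$genes_per_seq), cfg$genes_per_seq),
    sprintf("unit_range = %d-%d", cfg$scheme$unit_min, cfg$scheme$unit_max),
    sprintf("max_score_reduction = %s",
            format(cfg$scheme$max_score_reduction))),
    paths[["config"]])
  invisible(paths)
}
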