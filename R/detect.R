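#' Find perfect and imperfect tandem repeats
#'
#' Scans sequences for all tandem repeats in the scheme's unit-size range
#' whose alignment score against a perfect repeat counterpart reaches the
#' minimum score rule.  Every hit is anchored on a perfect first unit
#' (which is not scored) and extended in both directions as far as the
#' score can be raised, allowing mismatches, indels and short N runs.
#' Overlapping interpretations are resolved by score (ties: smaller unit
#' size, then leftmost start), and competing unit-size readings of each hit
#' are reported in its `alternatives` column.
#'
#' @param x Sequences: a [Biostrings::DNAStringSet], `DNAString`, or
#'   (named) character vector.  Residues are normalized to A/C/G/T/N.
#' @param scheme A [scoring_scheme()].
#' @param resolve Resolve overlapping hits (default `TRUE`).  The
#'   unresolved set can be requested for sensitivity analyses.
#' @return A data.frame with one row per hit: `seq_id`, `start`, `end`
#'   (1-based, inclusive), `unit_size`, `unit` (consensus, in phase at the
#'   start), `type`, `motif` (canonical forms; `NA` when the unit contains
#'   N), `score`, `length`, `copy_number`, `perfection` (percent of
#'   alignment columns that match, first unit included), `n_match`,
#'   `n_mismatch`, `n_gap`, `n_ncol`, and `alternatives`
#'   (`"unit_size:score"` pairs, primary first).
#' @examples
#' find_repeats(c(s1 = paste(rep("ACACAT", 4), collapse = "")))
#' @export
find_repeats <- function(x, scheme = scoring_scheme(), resolve = TRUE) {
  x <- as_dna(x)
  stopifnot(inherits(scheme, "tr_scheme"))
  res <- lapply(seq_along(x), function(i) {
    s <- as.character(x[[i]])
    cand <- detect_scan_cpp(s, unclass(scheme))
    assemble_hits(s, names(x)[i], cand, scheme)
  })
  hits <- do.call(rbind, res)
  if (is.null(hits)) hits <- empty_hits()
  if (resolve) hits <- resolve_overlaps(hits)
  hits <- hits[order(hits$seq_id, hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Exhaustive reference detector (test oracle)
#'
#' Enumerates every anchor position and unit size and computes the optimal
#' gapped alignment against the perfect unit tiling by dynamic programming,
#' then applies the same minimum-score filter and overlap resolution as
#' [find_repeats()].  Independent of the seed-and-extend search path; it
#' exists to validate the detector on small instances and refuses inputs
#' beyond its size bounds.
#'
#' @param x Sequences (as in [find_repeats()]).
#' @param scheme A [scoring_scheme()] with unlimited `max_score_reduction`
#'   and `unit_max` at most 12.
#' @param max_seq_len Refuse sequences longer than this (default 500 bp).
#' @return A hits data.frame with the same columns as [find_repeats()].
#' @export
naive_repeat_oracle <- function(x, scheme = scoring_scheme(unit_max = 6L),
                                max_seq_len = 500L) {
  x <- as_dna(x)
  stopifnot(inherits(scheme, "tr_scheme"))
  if (!is.infinite(scheme$max_score_reduction))
    stop("the oracle requires an unlimited max_score_reduction")
  if (scheme$unit_max > 12L)
    stop("the oracle is limited to unit sizes up to 12 bp")
  if (any(Biostrings::width(x) > max_seq_len))
    stop("oracle refused: sequence longer than max_seq_len (", max_seq_len,
         " bp)")
  res <- lapply(seq_along(x), function(i) {
    s <- as.character(x[[i]])
    cand <- oracle_scan_cpp(s, unclass(scheme))
    assemble_hits(s, names(x)[i], cand, scheme)
  })
  hits <- do.call(rbind, res)
  if (is.null(hits)) hits <- empty_hits()
  hits <- resolve_overlaps(hits)
  hits <- hits[order(hits$seq_id, hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             unit_size = integer(), unit = character(), type = character(),
             motif = character(), score = integer(), length = integer(),
             copy_number = numeric(), perfection = numeric(),
             n_match = integer(), n_mismatch = integer(),
             n_gap = integer(), n_ncol = integer(),
             alternatives = character(), stringsAsFactors = FALSE)
}

# Build the user-facing hit table from raw candidate intervals.
assemble_hits <- function(s, seq_id, cand, scheme) {
  if (nrow(cand) == 0L) return(empty_hits())
  key <- paste(cand$unit_size, cand$start0, cand$end0)
  cand <- cand[order(key, -cand$score), , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$unit_size, cand$start0, cand$end0)), ,
               drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    p <- cand$unit_size[r]
    i0 <- cand$start0[r]
    j0 <- cand$end0[r]
    st <- align_stats_cpp(s, i0, j0, p, unclass(scheme))
    alt <- alt_units(s, i0, j0, p, cand$score[r], scheme)
    unit <- st$consensus
    has_n <- grepl("N", unit, fixed = TRUE)
    data.frame(
      seq_id = seq_id, start = i0 + 1L, end = j0,
      unit_size = p, unit = unit,
      type = if (has_n) NA_character_ else canonical_type(unit),
      motif = if (has_n) NA_character_ else canonical_motif(unit),
      score = cand$score[r], length = j0 - i0,
      copy_number = (j0 - i0) / p,
      perfection = 100 * st$n_match / st$cols,
      n_match = st$n_match, n_mismatch = st$n_mismatch,
      n_gap = st$n_gap, n_ncol = st$n_ncol,
      alternatives = format_alts(alt),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Competing unit-size interpretations over a fixed interval: the hit's own
# unit size plus every proper divisor whose anchor unit is primitive and
# whose in-phase gapless rescoring of the interval keeps identity above
# 50% (the natural reinterpretation of the same tiling at a shorter
# period).
alt_units <- function(s, start0, end0, p, score, scheme) {
  qs <- seq_len(p - 1L)
  qs <- qs[p %% qs == 0L & qs >= scheme$unit_min]
  out <- data.frame(unit_size = p, score = score)
  len <- end0 - start0
  chars <- strsplit(substr(s, start0 + 1L, end0), "")[[1L]]
  for (q in qs) {
    uq <- substr(s, start0 + 1L, start0 + q)
    if (grepl("N", uq, fixed = TRUE)) next
    if (primitive_unit(uq) != uq) next
    tiling <- strsplit(strrep(uq, ceiling(len / q)), "")[[1L]][seq_len(len)]
    is_n <- chars == "N"
    is_m <- !is_n & chars == tiling
    if (sum(is_m) / len <= 0.5) next
    scored <- seq_len(len) > q
    qscore <- sum(ifelse(is_m, scheme$match_score,
                         ifelse(is_n, scheme$n_score,
                                scheme$mismatch_score))[scored])
    out <- rbind(out, data.frame(unit_size = q, score = as.integer(qscore)))
  }
  out[order(-out$score, out$unit_size), , drop = FALSE]
}

format_alts <- function(alt) {
  paste(sprintf("%d:%d", alt$unit_size, alt$score), collapse = ";")
}

parse_alts <- function(x) {
  if (!nzchar(x)) return(data.frame(unit_size = integer(), score = integer()))
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(unit_size = as.integer(vapply(parts, `[`, "", 1L)),
             score = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Competing unit-size interpretations of a hit
#'
#' For a detected repeat, reports the best achievable alignment score over
#' the hit's interval for each related unit size (the hit's own, its proper
#' divisors with a primitive anchor unit and over 50% alignment identity,
#' and any overlapping interpretation folded in during overlap resolution).
#' A repeat such as (ACACAT)n can thus be read as a perfect hexanucleotide
#' (the primary, maximum-score interpretation) or an imperfect
#' dinucleotide.
#'
#' @param x The sequences the hit was found in.
#' @param hit A single row of a hits data.frame.
#' @param scheme The [scoring_scheme()] used for detection.
#' @return A data.frame with columns `unit_size` and `score`, best first.
#' @export
alternative_unit_analysis <- function(x, hit, scheme = scoring_scheme()) {
  x <- as_dna(x)
  stopifnot(is.data.frame(hit), nrow(hit) == 1L)
  s <- as.character(x[[match(hit$seq_id, names(x))]])
  out <- alt_units(s, hit$start - 1L, hit$end, hit$unit_size, hit$score,
                   scheme)
  rownames(out) <- NULL
  out
}

#' Resolve overlapping repeat hits
#'
#' Returns a mutually non-overlapping hit set: among overlapping candidates
#' the higher score wins, with ties broken towards the smaller unit size
#' and then the leftmost start.  Interpretations losing to a winner over
#' the identical interval are retained in the winner's `alternatives`.
#'
#' @param hits A hits data.frame (any mixture of sequences).
#' @return The resolved hits data.frame, sorted by sequence and position.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  out <- lapply(split(hits, hits$seq_id), function(h) {
    h <- h[order(-h$score, h$unit_size, h$start), , drop = FALSE]
    keep <- logical(nrow(h))
    winner_of <- integer(nrow(h))   # index of the kept hit covering a loser
    for (r in seq_len(nrow(h))) {
      ov <- which(keep & h$start <= h$end[r] & h$end >= h$start[r])
      if (length(ov) == 0L) {
        keep[r] <- TRUE
      } else {
        same <- ov[h$start[ov] == h$start[r] & h$end[ov] == h$end[r]]
        if (length(same)) winner_of[r] <- same[1L]
      }
    }
    for (r in which(winner_of > 0L)) {
      w <- winner_of[r]
      alt <- parse_alts(h$alternatives[w])
      if (!h$unit_size[r] %in% alt$unit_size) {
        alt <- rbind(alt, data.frame(unit_size = h$unit_size[r],
                                     score = h$score[r]))
        alt <- alt[order(-alt$score, alt$unit_size), , drop = FALSE]
        h$alternatives[w] <- format_alts(alt)
      }
    }
    h[keep, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$seq_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score an explicit repeat alignment
#'
#' Applies the scoring rules to a spelled-out alignment of a region against
#' the perfect tiling of a unit.  Columns are `"M"` (match), `"X"`
#' (mismatch), `"I"` (insertion in the region), `"D"` (deletion / gap in
#' the region) and `"N"` (column consuming an unknown base).  Columns up to
#' and including the first `nchar(unit)` unit-consuming columns — the first
#' repeat unit — are not scored.
#'
#' @param region The repeat region sequence.
#' @param unit The repeat unit.
#' @param alignment Character vector of column codes (or one collapsed
#'   string), covering `region` exactly.
#' @param scheme A [scoring_scheme()].
#' @return The integer alignment score.
#' @examples
#' score_alignment(strrep("A", 13), "A", strrep("M", 13))  # 12
#' @export
score_alignment <- function(region, unit, alignment,
                            scheme = scoring_scheme()) {
  region <- normalize_residues(region)
  check_unit(unit, allow_n = TRUE)
  if (length(alignment) == 1L && nchar(alignment) > 1L)
    alignment <- strsplit(alignment, "")[[1L]]
  if (!all(alignment %in% c("M", "X", "I", "D", "N")))
    stop("alignment columns must be M, X, I, D or N")
  p <- nchar(unit)
  consumes_seq <- alignment %in% c("M", "X", "I", "N")
  consumes_ref <- alignment %in% c("M", "X", "D", "N")
  if (sum(consumes_seq) != nchar(region))
    stop("alignment inconsistent with region length: consumes ",
         sum(consumes_seq), " bases, region has ", nchar(region))
  # verify column codes against the sequence and unit tiling
  seq_chars <- strsplit(region, "")[[1L]]
  unit_chars <- strsplit(unit, "")[[1L]]
  si <- 0L; ri <- 0L
  for (k in seq_along(alignment)) {
    a <- alignment[k]
    cc <- if (a %in% c("M", "X", "I", "N")) seq_chars[si + 1L] else NA
    uc <- if (a %in% c("M", "X", "D", "N")) unit_chars[ri %% p + 1L] else NA
    if (a == "M" && (is.na(cc) || cc != uc))
      stop("column ", k, " marked M but region and unit tiling disagree")
    if (a == "X" && (cc == uc || cc == "N"))
      stop("column ", k, " marked X but is not a mismatch")
    if (a == "N" && cc != "N")
      stop("column ", k, " marked N but the region base is ", cc)
    if (consumes_seq[k]) si <- si + 1L
    if (consumes_ref[k]) ri <- ri + 1L
  }
  colscore <- c(M = scheme$match_score, X = scheme$mismatch_score,
                I = scheme$gap_score, D = scheme$gap_score,
                N = scheme$n_score)
  # a column is scored once the first unit (p reference-consuming
  # columns) is complete before it starts
  scored <- (cumsum(consumes_ref) - consumes_ref) >= p
  sum(colscore[alignment[scored]])
}

#' Write hits to a tab-separated file
#'
#' @param hits A hits data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert hits to GFF3 feature lines
#'
#' @param hits A hits data.frame.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of GFF3 lines (invisibly when `path` is given).
#' @export
hits_to_gff <- function(hits, path = NULL) {
  lines <- c("##gff-version 3",
             if (nrow(hits)) sprintf(
               "%s\ttrscan\ttandem_repeat\t%d\t%d\t%d\t.\t.\t%s",
               hits$seq_id, hits$start, hits$end, hits$score,
               sprintf("ID=TR%06d;unit=%s;unit_size=%d;perfection=%.2f;alternatives=%s",
                       seq_len(nrow(hits)), hits$unit, hits$unit_size,
                       hits$perfection, hits$alternatives)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
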