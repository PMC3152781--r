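#' Read gene features from a GFF file
#'
#' Permissive reader for GFF3 (`ID=...;Parent=...` attributes) and
#' GTF/GFF2-style group fields (`gene_id "x"; transcript_id "y"` or a bare
#' group token), keeping 1-based inclusive coordinates.  Malformed lines
#' (wrong column count, end < start, unknown strand) raise an error naming
#' the offending line number.
#'
#' @param path Path to a GFF file.
#' @return A data.frame of features with columns `seqid`, `source`,
#'   `type`, `start`, `end`, `score`, `strand`, `frame`, `attributes`,
#'   `feature_id`, `model_id` and `line`.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L)
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(),
                      end = integer(), score = character(),
                      strand = character(), frame = character(),
                      attributes = character(), feature_id = character(),
                      model_id = character(), line = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 9L)
  if (length(bad))
    stop(sprintf("malformed GFF (%s, line %d): %d column(s), expected 9",
                 path, keep[bad[1L]], nf[bad[1L]]))
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed GFF (%s, line %d): non-numeric coordinates",
                 path, keep[bad[1L]]))
  bad <- which(end < start)
  if (length(bad))
    stop(sprintf("malformed GFF (%s, line %d): end (%d) < start (%d)",
                 path, keep[bad[1L]], end[bad[1L]], start[bad[1L]]))
  bad <- which(!m[, 7L] %in% c("+", "-", ".", "?"))
  if (length(bad))
    stop(sprintf("malformed GFF (%s, line %d): unknown strand '%s'",
                 path, keep[bad[1L]], m[bad[1L], 7L]))
  attrs <- m[, 9L]
  out <- data.frame(seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
                    start = start, end = end, score = m[, 6L],
                    strand = m[, 7L], frame = m[, 8L], attributes = attrs,
                    feature_id = attr_field(attrs, c("ID", "id")),
                    model_id = model_key(attrs), line = keep,
                    stringsAsFactors = FALSE)
  out
}

# extract the first matching key from GFF3 "k=v" or GTF 'k "v"' syntax
attr_field <- function(attrs, keys) {
  out <- rep(NA_character_, length(attrs))
  for (key in keys) {
    pat1 <- paste0("(^|;)\\s*", key, "\\s*=\\s*([^;]+)")
    pat2 <- paste0("(^|;)\\s*", key, "\\s+\"([^\"]+)\"")
    for (pat in c(pat1, pat2)) {
      mm <- regmatches(attrs, regexec(pat, attrs))
      val <- vapply(mm, function(g) if (length(g) >= 3L) g[3L]
                    else NA_character_, character(1L))
      out[is.na(out)] <- trimws(val[is.na(out)])
    }
  }
  out
}

# grouping key tying a feature to its gene model: Parent (GFF3),
# transcript_id/gene_id (GTF), or a bare single-token group field (GFF2)
model_key <- function(attrs) {
  key <- attr_field(attrs, c("Parent", "parent", "transcript_id",
                             "transcriptId", "gene_id", "name"))
  bare <- is.na(key) & !grepl("[;=\"]", attrs) & nzchar(trimws(attrs))
  key[bare] <- trimws(attrs[bare])
  key
}

#' Assemble gene models from GFF features
#'
#' Groups exon, CDS, start_codon and stop_codon features by their gene
#' model (Parent / transcript id / group token).  Alternative transcripts
#' of one locus become separate models; the overlap deduplication in
#' [dedup_gene_models()] later reduces them to one.
#'
#' @param features A feature data.frame from [read_gff()].
#' @return A list of gene models, each a list with elements `id`, `seqid`,
#'   `strand`, `exons`, `cds`, `start_codon`, `stop_codon` (interval
#'   data.frames with 1-based `start`, `end`).
#' @export
gene_models <- function(features) {
  f <- features[features$type %in% c("exon", "CDS", "cds", "start_codon",
                                     "stop_codon"), , drop = FALSE]
  if (nrow(f) == 0L) return(list())
  if (anyNA(f$model_id))
    stop(sprintf("cannot assign feature to a gene model (line %d)",
                 f$line[which(is.na(f$model_id))[1L]]))
  # GFF3 features may list several parents, comma separated
  reps <- strsplit(f$model_id, ",", fixed = TRUE)
  f <- f[rep(seq_len(nrow(f)), lengths(reps)), , drop = FALSE]
  f$model_id <- unlist(reps)
  models <- lapply(split(f, f$model_id), function(g) {
    if (length(unique(g$seqid)) > 1L || length(unique(g$strand)) > 1L)
      stop("gene model ", g$model_id[1L],
           " spans several sequences or strands")
    iv <- function(types) {
      gg <- g[g$type %in% types, , drop = FALSE]
      gg <- gg[order(gg$start, gg$end), , drop = FALSE]
      data.frame(start = gg$start, end = gg$end)
    }
    list(id = g$model_id[1L], seqid = g$seqid[1L], strand = g$strand[1L],
         exons = iv("exon"), cds = iv(c("CDS", "cds")),
         start_codon = iv("start_codon"), stop_codon = iv("stop_codon"))
  })
  unname(models)
}

model_span <- function(m) {
  iv <- rbind(m$exons, m$cds, m$start_codon, m$stop_codon)
  if (nrow(iv) == 0L) return(c(NA_integer_, NA_integer_))
  as.integer(c(min(iv$start), max(iv$end)))
}

# remove the longer of two overlapping intervals, iterated until stable;
# equal lengths remove the rightmost.  `spans` is a data.frame with
# start/end.  Returns the indices kept.
drop_longer_overlaps <- function(spans) {
  keep <- seq_len(nrow(spans))
  repeat {
    s <- spans[keep, , drop = FALSE]
    o <- order(s$start, s$end)
    s <- s[o, , drop = FALSE]
    victim <- NULL
    for (i in seq_len(nrow(s) - 1L)) {
      j <- i + 1L
      if (s$start[j] <= s$end[i]) {
        li <- s$end[i] - s$start[i]
        lj <- s$end[j] - s$start[j]
        victim <- if (li > lj) i else if (lj > li) j else j  # tie: rightmost
        break
      }
    }
    if (is.null(victim)) return(keep)
    keep <- keep[-o[victim]]
  }
}

#' Remove redundant overlapping gene models
#'
#' When two gene models on the same sequence overlap in the same reading
#' direction, the longer (by genomic span) of the two is removed, iterated
#' until no same-strand overlap remains; equal spans drop the rightmost.
#' Models on opposite strands are never removed, so nested antisense genes
#' are kept.  This avoids over-representing multiply annotated loci.
#'
#' @param models A list of gene models from [gene_models()].
#' @return The deduplicated model list.
#' @export
dedup_gene_models <- function(models) {
  if (length(models) <= 1L) return(models)
  spans <- t(vapply(models, model_span, integer(2L)))
  info <- data.frame(seqid = vapply(models, `[[`, "", "seqid"),
                     strand = vapply(models, `[[`, "", "strand"),
                     start = spans[, 1L], end = spans[, 2L])
  keep_all <- logical(length(models))
  for (grp in split(seq_along(models), list(info$seqid, info$strand),
                    drop = TRUE)) {
    kept <- drop_longer_overlaps(info[grp, c("start", "end"), drop = FALSE])
    keep_all[grp[kept]] <- TRUE
  }
  models[keep_all]
}

#' Remove overlapping same-type features within a gene model
#'
#' If two exons or two CDS features of the same gene overlap, the longer
#' of the two is removed (iterated; equal lengths drop the rightmost).
#'
#' @param model A gene model.
#' @return The model with non-overlapping exons and CDS features.
#' @export
dedup_features <- function(model) {
  for (what in c("exons", "cds")) {
    iv <- model[[what]]
    if (nrow(iv) > 1L) {
      kept <- drop_longer_overlaps(iv)
      iv <- iv[sort(kept), , drop = FALSE]
      rownames(iv) <- NULL
      model[[what]] <- iv
    }
  }
  model
}

#' Infer introns of a gene model
#'
#' Introns are the maximal gaps strictly between consecutive (deduplicated)
#' exons of the same gene model.
#'
#' @param model A gene model (exons should be deduplicated first).
#' @return Interval data.frame of introns (1-based, inclusive).
#' @export
infer_introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) <= 1L) return(data.frame(start = integer(), end = integer()))
  ex <- ex[order(ex$start), , drop = FALSE]
  gs <- ex$end[-nrow(ex)] + 1L
  ge <- ex$start[-1L] - 1L
  ok <- ge >= gs
  data.frame(start = gs[ok], end = ge[ok])
}

#' Infer untranslated regions of a gene model
#'
#' Uses annotated start and stop codon positions within the exons to
#' derive the 5' UTR (exonic positions upstream of the start codon in
#' transcription direction) and 3' UTR (exonic positions downstream of the
#' stop codon), strand-aware.  Models without codon annotations yield empty
#' UTRs; a codon falling outside the exons flags the model and yields
#' empty UTRs.
#'
#' @param model A gene model.
#' @return A list with interval data.frames `five_prime` and `three_prime`
#'   and a logical `flagged`.
#' @export
infer_utrs <- function(model) {
  none <- data.frame(start = integer(), end = integer())
  if (nrow(model$start_codon) == 0L || nrow(model$stop_codon) == 0L)
    return(list(five_prime = none, three_prime = none, flagged = FALSE))
  ex <- iranges_of(model$exons)
  sc <- iranges_of(model$start_codon)
  pc <- iranges_of(model$stop_codon)
  inside <- function(x) {
    cov <- IRanges::intersect(x, ex)
    sum(IRanges::width(cov)) == sum(IRanges::width(x))
  }
  if (!inside(sc) || !inside(pc))
    return(list(five_prime = none, three_prime = none, flagged = TRUE))
  span <- model_span(model)
  if (model$strand == "-") {
    five_win <- IRanges::IRanges(max(IRanges::end(sc)) + 1L, span[2L] + 1L)
    three_win <- IRanges::IRanges(span[1L] - 1L, min(IRanges::start(pc)) - 1L)
  } else {
    five_win <- IRanges::IRanges(span[1L] - 1L, min(IRanges::start(sc)) - 1L)
    three_win <- IRanges::IRanges(max(IRanges::end(pc)) + 1L, span[2L] + 1L)
  }
  clip <- function(win) {
    if (IRanges::width(win) <= 0) return(none)
    df_of(IRanges::intersect(ex, win))
  }
  list(five_prime = clip(five_win), three_prime = clip(three_win),
       flagged = FALSE)
}

iranges_of <- function(df) IRanges::IRanges(start = df$start, end = df$end)
df_of <- function(ir) data.frame(start = IRanges::start(ir),
                                 end = IRanges::end(ir))

#' Infer intergenic intervals
#'
#' The complement of the union of (deduplicated) gene model spans on each
#' sequence.
#'
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param models A list of deduplicated gene models.
#' @return A data.frame with columns `seqid`, `start`, `end`.
#' @export
infer_intergenic <- function(seq_lengths, models) {
  rows <- lapply(names(seq_lengths), function(sq) {
    len <- seq_lengths[[sq]]
    ms <- Filter(function(m) m$seqid == sq, models)
    if (length(ms) == 0L)
      return(data.frame(seqid = sq, start = 1L, end = len))
    spans <- t(vapply(ms, model_span, integer(2L)))
    ir <- IRanges::reduce(IRanges::IRanges(spans[, 1L], spans[, 2L]))
    gaps <- IRanges::gaps(ir, start = 1L, end = len)
    if (length(gaps) == 0L)
      return(data.frame(seqid = character(), start = integer(),
                        end = integer()))
    data.frame(seqid = sq, start = IRanges::start(gaps),
               end = IRanges::end(gaps))
  })
  do.call(rbind, rows)
}

#' Extract region fragments with sense-strand sequence
#'
#' Splits the genome into CDS, intron, 5' UTR, 3' UTR, exon and intergenic
#' fragments.  Stranded kinds (everything except intergenic) carry the
#' sense strand of their gene: fragments of minus-strand genes are
#' reverse-complemented.  Exon fragments are produced but are normally
#' excluded from region reports, since their repeat content is just the
#' combination of CDS and UTRs.
#'
#' @param x Genome sequences (DNAStringSet or named character).
#' @param models Deduplicated gene models; feature-level deduplication is
#'   applied here.
#' @return A data.frame of fragments: `kind`, `seq_id`, `start`, `end`
#'   (1-based genomic), `strand`, `fragment_id`, `sequence` (sense
#'   strand).
#' @export
extract_regions <- function(x, models) {
  x <- as_dna(x)
  seq_lengths <- setNames(Biostrings::width(x), names(x))
  frag <- list()
  add <- function(kind, seqid, iv, strand) {
    if (is.null(iv) || nrow(iv) == 0L) return()
    frag[[length(frag) + 1L]] <<- data.frame(
      kind = kind, seq_id = seqid, start = iv$start, end = iv$end,
      strand = strand, stringsAsFactors = FALSE)
  }
  for (m in models) {
    if (!m$seqid %in% names(x))
      stop("gene model ", m$id, " references unknown sequence ", m$seqid)
    m <- dedup_features(m)
    span <- model_span(m)
    if (!is.na(span[2L]) && (span[1L] < 1L || span[2L] > seq_lengths[m$seqid]))
      stop("gene model ", m$id, " exceeds the bounds of ", m$seqid)
    utr <- infer_utrs(m)
    add("exon", m$seqid, m$exons, m$strand)
    add("CDS", m$seqid, m$cds, m$strand)
    add("intron", m$seqid, infer_introns(m), m$strand)
    add("five_prime_UTR", m$seqid, utr$five_prime, m$strand)
    add("three_prime_UTR", m$seqid, utr$three_prime, m$strand)
  }
  ig <- infer_intergenic(seq_lengths, models)
  if (nrow(ig))
    frag[[length(frag) + 1L]] <- data.frame(
      kind = "intergenic", seq_id = ig$seqid, start = ig$start,
      end = ig$end, strand = ".", stringsAsFactors = FALSE)
  out <- do.call(rbind, frag)
  if (is.null(out))
    return(data.frame(kind = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), fragment_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  seqs <- as.character(Biostrings::subseq(
    x[out$seq_id], start = out$start, end = out$end))
  minus <- out$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  out$fragment_id <- sprintf("%s:%s:%d-%d(%s)", out$kind, out$seq_id,
                             out$start, out$end, out$strand)
  out$sequence <- unname(seqs)
  ord <- order(out$kind, out$seq_id, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Effective (non-N) bp per region kind
#'
#' @param fragments A fragment data.frame from [extract_regions()].
#' @return Named vector of effective bp by region kind.
#' @export
region_effective_bp <- function(fragments) {
  eff <- effective_length(setNames(fragments$sequence,
                                   fragments$fragment_id))
  vapply(split(eff, fragments$kind), sum, numeric(1L))
}

#' Scan region fragments for tandem repeats
#'
#' Runs [find_repeats()] inside every extracted region fragment (so
#' repeats are truncated at region boundaries, matching a region-split
#' genome scan) and annotates hits with their region kind.
#'
#' @param fragments A fragment data.frame from [extract_regions()].
#' @param scheme A [scoring_scheme()].
#' @param include_exons Keep hits in `exon` fragments (default `FALSE`;
#'   exon repeats duplicate the CDS + UTR content).
#' @return A hits data.frame with additional `region` and `fragment_id`
#'   columns; `seq_id`/`start`/`end` refer to the fragment coordinates.
#' @export
scan_regions <- function(fragments, scheme = scoring_scheme(),
                         include_exons = FALSE) {
  fr <- fragments
  if (!include_exons) fr <- fr[fr$kind != "exon", , drop = FALSE]
  if (nrow(fr) == 0L) {
    h <- empty_hits()
    h$region <- character()
    h$fragment_id <- character()
    return(h)
  }
  hits <- find_repeats(setNames(fr$sequence, fr$fragment_id), scheme)
  hits$region <- fr$kind[match(hits$seq_id, fr$fragment_id)]
  hits$fragment_id <- hits$seq_id
  hits
}

#' Write one FASTA file per region kind
#'
#' @param fragments A fragment data.frame from [extract_regions()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_region_fasta <- function(fragments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- unique(fragments$kind)
  paths <- setNames(file.path(dir, paste0(kinds, ".fa")), kinds)
  for (k in kinds) {
    fr <- fragments[fragments$kind == k, , drop = FALSE]
    write_fasta(setNames(fr$sequence, fr$fragment_id), paths[[k]])
  }
  invisible(paths)
}
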