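#' Read sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file and normalizes residues to the
#' five-letter alphabet A, C, G, T, N: lowercase letters are uppercased and
#' IUPAC ambiguity codes other than N are mapped to N, since the analysis
#' only distinguishes known bases from unknown ones.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per record, in file
#'   order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtn", ">s2", "ACRYT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L) stop("empty FASTA file: ", path)
  first <- meaningful[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA (%s, line %d): expected a '>' header",
                 path, first))
  hdr <- which(startsWith(lines, ">"))
  ends <- c(hdr[-1L] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    body <- lines[seq.int(hdr[i] + 1L, length.out = max(0L, ends[i] - hdr[i]))]
    if (sum(nchar(trimws(body))) == 0L)
      stop(sprintf("malformed FASTA (%s, line %d): empty record '%s'",
                   path, hdr[i], sub("^>\\s*", "", lines[hdr[i]])))
  }
  x <- Biostrings::readBStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  seqs <- normalize_residues(as.character(x))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(x)
  out
}

#' Normalize residues to the A/C/G/T/N alphabet
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector with lowercase uppercased and any symbol other
#'   than A, C, G, T mapped to N.
#' @export
normalize_residues <- function(x) {
  gsub("[^ACGTN]", "N", toupper(x))
}

#' Write sequences to FASTA with fixed 60-column wrapping
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- as_dna(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# coerce character / DNAString / DNAStringSet input to a named DNAStringSet
as_dna <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) x <- as.character(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(normalize_residues(x))
    names(out) <- if (!is.null(names(x))) names(x)
      else paste0("seq", seq_along(out))
    return(out)
  }
  stop("cannot interpret input as DNA sequences")
}

#' Effective (non-N) sequence length
#'
#' Number of known bases in each sequence — the sequence length corrected
#' for the number of Ns.  All repeat densities use effective lengths as
#' their denominator.
#'
#' @param x A [Biostrings::DNAStringSet], `DNAString`, or character vector.
#' @return Integer vector of non-N base counts.
#' @examples
#' effective_length(c("ACGT", "ACGTNNNN", "NNNN"))  # 4 4 0
#' @export
effective_length <- function(x) {
  x <- as_dna(x)
  af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  unname(as.integer(rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])))
}

#' Base composition and corrected dinucleotide statistics
#'
#' Computes base counts over known (non-N) positions, the CG content, the
#' A/T and C/G frequency ratios, and observed/expected ("corrected") CpG
#' and CpNpG abundances:
#' `corrected CpG = n(CpG) * L_eff / (n(C) * n(G))` and
#' `corrected CpNpG = n(CpNpG) * L_eff / (n(C) * n(G))`, where CpNpG counts
#' C-any-G trinucleotides and `L_eff` is the effective (non-N) length.
#' Windows containing an N are skipped.  Ratios with an undefined
#' denominator are reported as `NA`, not zero.
#'
#' @param x A single sequence (character scalar, `DNAString`, or length-one
#'   `DNAStringSet`).
#' @return A named list of class `tr_composition`.
#' @examples
#' composition("ACGT")$corrected_cpg  # (1 * 4) / (1 * 1) = 4
#' @export
composition <- function(x) {
  x <- as_dna(x)
  if (length(x) != 1L) stop("`composition()` expects a single sequence")
  s <- x[[1L]]
  af <- Biostrings::alphabetFrequency(s, baseOnly = TRUE)
  counts <- as.integer(af[c("A", "C", "G", "T")])
  names(counts) <- c("A", "C", "G", "T")
  n_n <- length(s) - sum(counts)
  eff <- sum(counts)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  di <- Biostrings::dinucleotideFrequency(s)     # N windows not counted
  tri <- Biostrings::trinucleotideFrequency(s)
  cpg <- unname(di["CG"])
  cpnpg <- sum(tri[c("CAG", "CCG", "CGG", "CTG")])
  out <- list(
    counts = c(counts, N = n_n),
    length = length(s),
    effective_length = eff,
    cg_content = rat(counts["C"] + counts["G"], eff),
    at_ratio = rat(counts["A"], counts["T"]),
    cg_ratio = rat(counts["C"], counts["G"]),
    corrected_cpg = if (eff > 0 && counts["C"] > 0 && counts["G"] > 0)
      cpg * eff / (counts["C"] * counts["G"]) else NA_real_,
    corrected_cpnpg = if (eff > 0 && counts["C"] > 0 && counts["G"] > 0)
      cpnpg * eff / (counts["C"] * counts["G"]) else NA_real_
  )
  out <- lapply(out, function(v) if (is.numeric(v)) unname(v) else v)
  out$counts <- c(counts, N = n_n)
  structure(out, class = "tr_composition")
}

#' @export
print.tr_composition <- function(x, ...) {
  cat("Sequence composition\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = " "), "\n")
  cat(sprintf("  length %d (effective %d)\n", x$length, x$effective_length))
  cat(sprintf("  CG content %.4f | A/T %s | C/G %s\n", x$cg_content,
              format(x$at_ratio, digits = 4), format(x$cg_ratio, digits = 4)))
  cat(sprintf("  corrected CpG %s | corrected CpNpG %s\n",
              format(x$corrected_cpg, digits = 4),
              format(x$corrected_cpnpg, digits = 4)))
  invisible(x)
}
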