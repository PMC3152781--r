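#' Reverse complement of a repeat unit
#'
#' @param u Character vector of units over A, C, G, T, N.
#' @return Reverse-complemented unit(s); N maps to N.
#' @examples
#' reverse_complement("AAG")  # "CTT"
#' @export
reverse_complement <- function(u) {
  check_unit(u, allow_n = TRUE)
  vapply(u, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

check_unit <- function(u, allow_n = TRUE) {
  if (!is.character(u) || any(is.na(u)) || any(!nzchar(u)))
    stop("units must be non-empty strings")
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, u)
  if (any(bad))
    stop("invalid unit symbol in: ", paste(u[bad], collapse = ", "))
  invisible(u)
}

rotations_of <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(s)
  d <- paste0(s, s)
  vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1L))
}

# C-locale lexicographic minimum (A < C < G < N < T)
lex_min <- function(x) sort(x, method = "radix")[1L]

#' Primitive period of a unit
#'
#' Units that are themselves periodic (e.g. `"ACAC"`) are reduced to their
#' shortest repeated prefix (`"AC"`) so the same repeat is never classified
#' under several unit sizes.
#'
#' @param u Character vector of units.
#' @return The primitive unit(s).
#' @export
primitive_unit <- function(u) {
  check_unit(u, allow_n = TRUE)
  vapply(u, function(s) {
    n <- nchar(s)
    for (d in seq_len(n)) {
      if (n %% d != 0L) next
      if (s == strrep(substr(s, 1L, d), n / d)) return(substr(s, 1L, d))
    }
    s
  }, character(1L), USE.NAMES = FALSE)
}

#' Canonical repeat type of a unit
#'
#' The repeat type groups all units that differ only by circular rotation
#' and/or reverse complement; it is represented by the alphabetically first
#' member (plain lexicographic order, A < C < G < N < T).  Units are first
#' reduced to their primitive period.
#'
#' @param u Character vector of units.
#' @return Canonical repeat-type representative(s).
#' @examples
#' canonical_type(c("GAA", "TTC"))  # both "AAG"
#' @export
canonical_type <- function(u) {
  check_unit(u, allow_n = TRUE)
  u <- primitive_unit(u)
  vapply(u, function(s) {
    lex_min(c(rotations_of(s), rotations_of(reverse_complement(s))))
  }, character(1L), USE.NAMES = FALSE)
}

#' Canonical repeat motif of a unit
#'
#' The repeat motif groups units under circular rotation only, keeping the
#' two strands distinct — the level at which strandedness (sense/anti-sense
#' density differences) can be detected.  Units are first reduced to their
#' primitive period.
#'
#' @param u Character vector of units.
#' @return Canonical repeat-motif representative(s).
#' @examples
#' canonical_motif(c("AGA", "TCT"))  # "AAG", "CTT"
#' @export
canonical_motif <- function(u) {
  check_unit(u, allow_n = TRUE)
  u <- primitive_unit(u)
  vapply(u, function(s) lex_min(rotations_of(s)), character(1L),
         USE.NAMES = FALSE)
}

#' Repeat class (unit size) of a unit
#'
#' @param u Character vector of units.
#' @return Integer unit sizes in bp.
#' @export
repeat_class <- function(u) {
  check_unit(u, allow_n = TRUE)
  nchar(u)
}

#' Minimum cyclic mismatch count between a unit and its reverse complement
#'
#' Aligns a unit gaplessly against every cyclic rotation of its own reverse
#' complement and returns the minimum number of mismatching positions.
#' Zero means the unit is rotation-equivalent to its reverse complement
#' (a cyclic palindrome).
#'
#' @param u Character vector of units without Ns (match semantics for N are
#'   undefined, so Ns raise an error).
#' @return Integer vector of minimum mismatch counts.
#' @examples
#' cyclic_rc_mismatches("AT")   # 0
#' cyclic_rc_mismatches("AAG")  # 3
#' @export
cyclic_rc_mismatches <- function(u) {
  check_unit(u, allow_n = FALSE)
  vapply(u, function(s) {
    a <- strsplit(s, "")[[1L]]
    min(vapply(rotations_of(reverse_complement(s)), function(r) {
      sum(a != strsplit(r, "")[[1L]])
    }, numeric(1L)))
  }, numeric(1L), USE.NAMES = FALSE)
}
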