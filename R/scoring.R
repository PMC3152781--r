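#' Detection parameters for the tandem repeat scanner
#'
#' Bundles all scoring and search parameters.  The defaults reproduce the
#' standard configuration: match +1, mismatch -5, gap -5, N 0; the first
#' repeat unit of every TR is not scored; a TR qualifies when its alignment
#' score reaches 12 for unit sizes up to 12 bp, or the unit size itself for
#' larger units.  At most four successive Ns are allowed inside a repeat,
#' and imperfections are explored up to a recursion depth of five
#' consecutive edit columns.  The maximum score reduction (an X-drop style
#' bound on how far the running score may fall below the best score seen in
#' an extension direction) is unlimited for unit ranges up to 50 bp and 30
#' for longer ranges, where it prunes the search at a small accuracy cost.
#'
#' @param unit_min,unit_max Unit size range searched, in bp.
#' @param match_score,mismatch_score,gap_score,n_score Per-column alignment
#'   scores.  `n_score` applies to columns consuming an unknown base (N).
#' @param min_score_floor Minimum qualifying score for unit sizes up to
#'   `min_score_floor` bp; larger units must reach their own unit size.
#' @param max_successive_ns Maximum run of consumed sequence Ns inside a
#'   hit.  Deliberately a run cap on the sequence, so it cannot be
#'   circumvented by interleaving gap columns.
#' @param recursion_depth Maximum number of consecutive edit columns
#'   (mismatch, insertion, deletion) explored before a match or N column
#'   must resume.
#' @param max_score_reduction X-drop bound per extension direction; `Inf`
#'   disables pruning.  Default: `Inf` when `unit_max <= 50`, otherwise 30.
#'
#' @return An object of class `tr_scheme` (a named list).
#' @examples
#' scoring_scheme()                  # short-range preset, units 1-50 bp
#' scoring_scheme(unit_max = 4000)   # long-range preset, score reduction 30
#' @export
scoring_scheme <- function(unit_min = 1L, unit_max = 50L,
                           match_score = 1L, mismatch_score = -5L,
                           gap_score = -5L, n_score = 0L,
                           min_score_floor = 12L,
                           max_successive_ns = 4L,
                           recursion_depth = 5L,
                           max_score_reduction = NULL) {
  unit_min <- as.integer(unit_min)
  unit_max <- as.integer(unit_max)
  if (is.na(unit_min) || unit_min < 1L)
    stop("`unit_min` must be a positive integer")
  if (is.na(unit_max) || unit_max < unit_min)
    stop("`unit_max` must be >= `unit_min`")
  if (match_score <= 0) stop("`match_score` must be positive")
  if (mismatch_score >= 0 || gap_score >= 0)
    stop("`mismatch_score` and `gap_score` must be negative")
  if (n_score < 0 || n_score > match_score)
    stop("`n_score` must lie in [0, match_score]")
  if (recursion_depth < 1L) stop("`recursion_depth` must be >= 1")
  if (max_successive_ns < 0L) stop("`max_successive_ns` must be >= 0")
  if (is.null(max_score_reduction))
    max_score_reduction <- if (unit_max <= 50L) Inf else 30
  if (!is.infinite(max_score_reduction) && max_score_reduction < 0)
    stop("`max_score_reduction` must be nonnegative or Inf")
  structure(list(
    match_score = as.integer(match_score),
    mismatch_score = as.integer(mismatch_score),
    gap_score = as.integer(gap_score),
    n_score = as.integer(n_score),
    min_score_floor = as.integer(min_score_floor),
    max_successive_ns = as.integer(max_successive_ns),
    recursion_depth = as.integer(recursion_depth),
    max_score_reduction = as.numeric(max_score_reduction),
    unit_min = unit_min,
    unit_max = unit_max
  ), class = "tr_scheme")
}

#' Minimum qualifying score for a unit size
#'
#' Score threshold a TR must reach to be reported: `min_score_floor` for
#' unit sizes up to `min_score_floor` bp, the unit size itself beyond.
#' Consequently the smallest qualifying perfect repeats are 13, 14 and
#' 15 bp for unit sizes 1, 2 and 3 bp, and exactly two units for unit
#' sizes above 12 bp.
#'
#' @param scheme A [scoring_scheme()].
#' @param unit_size Unit size(s) in bp.
#' @return Integer vector of minimum scores.
#' @export
min_score_rule <- function(scheme, unit_size) {
  stopifnot(inherits(scheme, "tr_scheme"))
  pmax(scheme$min_score_floor, as.integer(unit_size))
}

#' @export
print.tr_scheme <- function(x, ...) {
  cat("Tandem repeat scoring scheme\n")
  cat(sprintf("  unit size range     : %d-%d bp\n", x$unit_min, x$unit_max))
  cat(sprintf("  match/mismatch/gap/N: %+d/%+d/%+d/%+d (first unit unscored)\n",
              x$match_score, x$mismatch_score, x$gap_score, x$n_score))
  cat(sprintf("  min score           : %d (unit size beyond %d bp)\n",
              x$min_score_floor, x$min_score_floor))
  cat(sprintf("  max successive Ns   : %d\n", x$max_successive_ns))
  cat(sprintf("  recursion depth     : %d\n", x$recursion_depth))
  cat(sprintf("  max score reduction : %s\n",
              if (is.infinite(x$max_score_reduction)) "unlimited"
              else format(x$max_score_reduction)))
  invisible(x)
}
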