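#' Repeat density in base pairs per megabase pair
#'
#' Density is the fraction of base pairs found within repeats, expressed
#' per Mbp of effective (non-N) sequence: `sum(hit lengths) / effective_bp
#' * 1e6`.  It is the coverage of the sequence by the repeat set, not a
#' count per Mbp.
#'
#' @param hits A hits data.frame (assumed non-overlapping).
#' @param effective_bp Effective (non-N) length of the searched sequence.
#' @return Density in bp/Mbp (`NA` when `effective_bp` is zero or missing).
#' @examples
#' h <- data.frame(length = 20L)
#' tr_density(h, 50000)  # 400 bp/Mbp = 0.04%
#' @export
tr_density <- function(hits, effective_bp) {
  if (is.null(effective_bp) || is.na(effective_bp) || effective_bp <= 0)
    return(NA_real_)
  sum(hits$length) / effective_bp * 1e6
}

pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Summary statistics of repeat hits by class, type or motif
#'
#' Aggregates hits into one record per group: count, N-corrected density
#' (bp/Mbp), relative density (percent of the table total), mean, standard
#' deviation (population SD by default) and maximum of hit lengths, and
#' mean (length-unweighted) perfection.  Grouping by repeat class uses the
#' unit size; grouping by type merges units equivalent under rotation and
#' reverse complement (e.g. AAG and CTT hits), while grouping by motif
#' keeps the two strands separate.  Hits whose consensus unit contains an N
#' have no canonical form and are dropped from type/motif tables.
#'
#' @param hits A hits data.frame from [find_repeats()].  If it carries a
#'   `region` column and `by_region = TRUE`, statistics are stratified.
#' @param x Optional sequences the hits were found in, used to compute
#'   `effective_bp`.
#' @param group_by `"class"`, `"type"` or `"motif"`.
#' @param effective_bp Effective (non-N) bp searched; either a single
#'   number or, for stratified tables, a named vector by region.  Required
#'   unless `x` is given.
#' @param by_region Stratify by the `region` column of `hits`.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return A data.frame of density records sorted by unit size, then
#'   canonical string (then region).
#' @export
summarize_repeats <- function(hits, x = NULL,
                              group_by = c("class", "type", "motif"),
                              effective_bp = NULL, by_region = FALSE,
                              sd_type = c("population", "sample")) {
  group_by <- match.arg(group_by)
  sd_type <- match.arg(sd_type)
  if (is.null(effective_bp)) {
    if (is.null(x)) stop("supply either `x` or `effective_bp`")
    effective_bp <- sum(effective_length(x))
  }
  if (by_region && !"region" %in% names(hits))
    stop("`by_region = TRUE` requires a `region` column in `hits`")
  gcol <- switch(group_by, class = "unit_size", type = "type",
                 motif = "motif")
  h <- hits
  if (group_by != "class") h <- h[!is.na(h[[gcol]]), , drop = FALSE]
  keys <- if (by_region) list(group = h[[gcol]], region = h$region)
          else list(group = h[[gcol]])
  if (nrow(h) == 0L) {
    out <- data.frame(group = if (group_by == "class") integer() else character(),
                      count = integer(), total_bp = integer(),
                      density = numeric(), relative_density = numeric(),
                      mean_length = numeric(), sd_length = numeric(),
                      max_length = integer(), mean_perfection = numeric(),
                      stringsAsFactors = FALSE)
    if (by_region) out$region <- character()
    return(out)
  }
  sdf <- if (sd_type == "population") pop_sd else stats::sd
  parts <- split(seq_len(nrow(h)), keys, drop = TRUE)
  rows <- lapply(names(parts), function(k) {
    idx <- parts[[k]]
    lens <- h$length[idx]
    reg <- if (by_region) h$region[idx][1L] else NA_character_
    eff <- if (by_region) {
      if (is.null(names(effective_bp)))
        stop("stratified tables need a named `effective_bp` vector")
      unname(effective_bp[reg])
    } else effective_bp
    data.frame(group = h[[gcol]][idx][1L],
               region = reg,
               count = length(idx),
               total_bp = sum(lens),
               density = tr_density(h[idx, , drop = FALSE], eff),
               mean_length = mean(lens),
               sd_length = if (length(lens) > 1L || sd_type == "population")
                 sdf(lens) else 0,
               max_length = max(lens),
               mean_perfection = mean(h$perfection[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!by_region) out$region <- NULL
  # relative density: percent of the table total (within region if
  # stratified)
  tot <- if (by_region) stats::ave(out$density, out$region, FUN = sum)
         else rep(sum(out$density), nrow(out))
  out$relative_density <- ifelse(tot > 0, 100 * out$density / tot, 0)
  usize <- if (group_by == "class") as.integer(out$group)
           else nchar(out$group)
  ord <- if (by_region) order(out$region, usize, out$group)
         else order(usize, out$group)
  out <- out[ord, , drop = FALSE]
  cols <- c("group", if (by_region) "region", "count", "total_bp",
            "density", "relative_density", "mean_length", "sd_length",
            "max_length", "mean_perfection")
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition class densities into unit-size ranges
#'
#' Sums repeat-class densities over disjoint unit-size ranges (e.g. the
#' short ranges 1-6 bp, 7-10 bp and 11-50 bp) and reports each range's
#' contribution to the total density.
#'
#' @param class_summary A class-level table from
#'   [summarize_repeats()] (`group_by = "class"`).
#' @param ranges List of `c(lo, hi)` unit-size ranges; must be disjoint
#'   and cover every observed class.
#' @return A data.frame with columns `range`, `density` and
#'   `contribution_pct`.
#' @export
unit_range_partition <- function(class_summary,
                                 ranges = list(c(1, 6), c(7, 10), c(11, 50))) {
  lo <- vapply(ranges, `[`, numeric(1L), 1L)
  hi <- vapply(ranges, `[`, numeric(1L), 2L)
  if (any(hi < lo)) stop("each range must be c(lo, hi) with lo <= hi")
  o <- order(lo)
  if (any(lo[o][-1L] <= hi[o][-length(o)]))
    stop("unit-size ranges overlap")
  cls <- as.integer(class_summary$group)
  bin <- vapply(cls, function(p) {
    w <- which(p >= lo & p <= hi)
    if (length(w) == 0L)
      stop("repeat class ", p, " bp falls outside all ranges")
    w
  }, integer(1L))
  dens <- vapply(seq_along(ranges), function(i) {
    sum(class_summary$density[bin == i])
  }, numeric(1L))
  tot <- sum(dens)
  data.frame(range = sprintf("%g-%g", lo, hi),
             density = dens,
             contribution_pct = if (tot > 0) 100 * dens / tot else
               rep(0, length(dens)),
             stringsAsFactors = FALSE)
}

#' Motif strandedness table
#'
#' For hits found on sense-strand region fragments, pairs every repeat
#' motif with its reverse-complement motif and reports both densities per
#' region, revealing strand bias (strandedness) in motif usage.  Pair
#' labels follow the convention: `"-"` palindromic motif (its own reverse
#' complement under rotation), `"A/B"` both motif forms present, `"a"`
#' only the normal form (the alphabetically first, i.e. the repeat-type
#' representative), `"b"` only its reverse complement.
#'
#' @param hits A hits data.frame carrying `motif` and `region` columns
#'   (e.g. from [scan_regions()]).
#' @param effective_bp Named vector of effective bp per region.
#' @return A data.frame with one row per motif pair and region: `region`,
#'   `motif` (normal form), `rc_motif`, `label`, `density` (normal form)
#'   and `rc_density`.
#' @export
strandedness_table <- function(hits, effective_bp) {
  if (!all(c("motif", "region") %in% names(hits)))
    stop("`hits` must carry `motif` and `region` columns")
  h <- hits[!is.na(hits$motif), , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(region = character(), motif = character(),
                      rc_motif = character(), label = character(),
                      density = numeric(), rc_density = numeric(),
                      stringsAsFactors = FALSE))
  h$pair <- canonical_type(h$motif)
  parts <- split(seq_len(nrow(h)), list(pair = h$pair, region = h$region),
                 drop = TRUE)
  rows <- lapply(parts, function(idx) {
    pair <- h$pair[idx][1L]
    region <- h$region[idx][1L]
    rc <- canonical_motif(reverse_complement(pair))
    eff <- unname(effective_bp[region])
    d_a <- tr_density(h[idx, , drop = FALSE][h$motif[idx] == pair, ,
                                             drop = FALSE], eff)
    d_b <- tr_density(h[idx, , drop = FALSE][h$motif[idx] == rc &
                                               rc != pair, , drop = FALSE],
                      eff)
    label <- if (rc == pair) "-"
      else if (d_a > 0 && d_b > 0) "A/B"
      else if (d_a > 0) "a" else "b"
    data.frame(region = region, motif = pair, rc_motif = rc, label = label,
               density = d_a, rc_density = d_b, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region, nchar(out$motif), out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
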