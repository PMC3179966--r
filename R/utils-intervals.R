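# Interval arithmetic helpers. All user-facing tables use 0-based, half-open
# [start, end) coordinates (BED convention); GenomicRanges (1-based, closed)
# is used internally and converted at the boundary.

gr_from_tbl <- function(df, seqlengths = NULL) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges(seqlengths = seqlengths))
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    seqlengths = seqlengths
  )
}

tbl_from_gr <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Union of genomic intervals
#'
#' Collapses a table of `[start, end)` intervals into its union, merging
#' overlapping or abutting intervals per chromosome.
#'
#' @param df A data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return A tibble with the same columns, disjoint and sorted.
#' @export
interval_union <- function(df) {
  if (nrow(df) == 0) return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  tbl_from_gr(GenomicRanges::reduce(gr_from_tbl(df)))
}

#' Intersection of two interval sets
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based, half-open).
#' @return A tibble of the intersected intervals.
#' @export
interval_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  tbl_from_gr(GenomicRanges::intersect(
    GenomicRanges::reduce(gr_from_tbl(a)),
    GenomicRanges::reduce(gr_from_tbl(b))
  ))
}

# Total bp in the union of df, optionally per chromosome.
union_bp <- function(df, by_chrom = FALSE) {
  u <- interval_union(df)
  if (!by_chrom) return(sum(u$end - u$start))
  u |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bp = sum(.data$end - .data$start), .groups = "drop")
}

# bp of overlap between each row of `df` and the union of `track`.
overlap_bp_per_row <- function(df, track) {
  if (nrow(df) == 0) return(integer(0))
  if (nrow(track) == 0) return(rep(0L, nrow(df)))
  q <- gr_from_tbl(df)
  s <- GenomicRanges::reduce(gr_from_tbl(track))
  hits <- GenomicRanges::findOverlaps(q, s)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(q)[S4Vectors::queryHits(hits)],
    IRanges::ranges(s)[S4Vectors::subjectHits(hits)]
  ))
  out <- rep(0L, nrow(df))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Complement of an interval set within chromosome bounds
#'
#' @param df Data frame with `chrom`, `start`, `end`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return Tibble of the uncovered intervals.
#' @export
interval_complement <- function(df, chrom_sizes) {
  sl <- as.integer(chrom_sizes)
  names(sl) <- names(chrom_sizes)
  gr <- gr_from_tbl(df[df$chrom %in% names(sl), , drop = FALSE], seqlengths = sl)
  comp <- GenomicRanges::gaps(GenomicRanges::reduce(gr))
  comp <- comp[GenomicRanges::strand(comp) == "*"]
  tbl_from_gr(comp)
}

# Expand intervals by `pad` on each side, clipped to chromosome bounds.
interval_dilate <- function(df, pad, chrom_sizes) {
  if (nrow(df) == 0 || pad == 0) return(interval_union(df))
  out <- df
  out$start <- pmax(0L, df$start - as.integer(pad))
  out$end <- pmin(as.integer(chrom_sizes[df$chrom]), df$end + as.integer(pad))
  interval_union(out)
}

assert_intervals <- function(df, what = "intervals") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start >= df$end)) {
    stop(sprintf("%s must satisfy start < end", what), call. = FALSE)
  }
  invisible(df)
}

# Stratum of an assembly sequence name: sequences assigned to chromosomes but
# unplaced carry a "_random" suffix; "chrUn"/"Un" holds unassigned contigs.
chrom_stratum <- function(chrom) {
  dplyr::case_when(
    grepl("_random$", chrom) ~ "random",
    chrom %in% c("chrUn", "Un") | grepl("^chrUn", chrom) ~ "unknown",
    TRUE ~ "nonrandom"
  )
}

# Deterministic sub-seed for a named stream, kept below 2^31.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}
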