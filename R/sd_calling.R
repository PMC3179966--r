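# Window classification against calibration thresholds, duplication calling
# by the six-of-seven consecutive-window rule, and genome summary tables.

#' Classify 5-kub windows
#'
#' Labels each window `negative` (depth <= avg + 2 sd), `borderline`
#' (avg + 2 sd < depth < avg + 3 sd) or `positive` (depth >= avg + 3 sd by
#' default; the boundary point is positive, with a switch for the strict
#' convention).
#'
#' @param w5 Window tibble from [sliding_windows()] with depths filled.
#' @param thresholds From [mixture_thresholds()] (list with `borderline_cut`,
#'   `positive_cut`).
#' @param positive_inclusive If `FALSE`, a depth exactly at the positive cut
#'   is borderline rather than positive.
#' @return `w5` with `label` set.
#' @export
classify_windows <- function(w5, thresholds, positive_inclusive = TRUE) {
  if (is.null(thresholds$borderline_cut) || is.null(thresholds$positive_cut)) {
    stop("thresholds must provide borderline_cut and positive_cut", call. = FALSE)
  }
  b <- thresholds$borderline_cut
  p <- thresholds$positive_cut
  stopifnot(b < p)
  pos <- if (positive_inclusive) w5$depth >= p else w5$depth > p
  w5$label <- dplyr::case_when(
    pos ~ "positive",
    w5$depth > b ~ "borderline",
    TRUE ~ "negative"
  )
  w5
}

#' Call duplicated intervals by the m-of-n window rule
#'
#' Every run of `n` consecutive 5-kub windows (consecutive sliding positions
#' within a gap-delimited run) containing at least `m` positive windows marks
#' all `n` as in-duplication; the union of marked window spans, merged when
#' overlapping or abutting, yields the duplicated intervals. Borderline
#' windows neither count toward `m` nor break intervals. Intervals never
#' span an assembly gap because sliding never crosses one.
#'
#' @param w5 Labelled window tibble from [classify_windows()].
#' @param m,n The rule (default 6 of 7).
#' @return Tibble of intervals: `chrom`, `start`, `end`, `n_windows5`
#'   (constituent marked windows), `mean_coverage` (mean depth of the
#'   constituents).
#' @export
call_duplications <- function(w5, m = 6L, n = 7L) {
  stopifnot(m <= n, n >= 1)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_windows5 = integer(),
                          mean_coverage = double())
  if (nrow(w5) == 0) return(empty)
  if (any(w5$label == "unset")) {
    stop("windows must be classified before calling", call. = FALSE)
  }
  marked <- w5 |>
    dplyr::arrange(.data$chrom, .data$first_index) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::group_modify(function(g, key) {
      L <- nrow(g)
      g$marked <- FALSE
      if (L >= n) {
        p <- cumsum(c(0L, g$label == "positive"))
        for (i in seq_len(L - n + 1L)) {
          if (p[i + n] - p[i] >= m) g$marked[i:(i + n - 1L)] <- TRUE
        }
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$marked)
  if (nrow(marked) == 0) return(empty)
  iv <- interval_union(marked[, c("chrom", "start", "end")])
  ov <- GenomicRanges::findOverlaps(gr_from_tbl(marked), gr_from_tbl(iv))
  stats_tbl <- tibble::tibble(
    interval = S4Vectors::subjectHits(ov),
    depth = marked$depth[S4Vectors::queryHits(ov)]
  ) |>
    dplyr::group_by(.data$interval) |>
    dplyr::summarise(n_windows5 = dplyr::n(),
                     mean_coverage = mean(.data$depth), .groups = "drop")
  iv$n_windows5 <- 0L
  iv$mean_coverage <- NA_real_
  iv$n_windows5[stats_tbl$interval] <- stats_tbl$n_windows5
  iv$mean_coverage[stats_tbl$interval] <- stats_tbl$mean_coverage
  iv
}

strata_order <- function(chroms) {
  s <- chrom_stratum(chroms)
  chroms[order(match(s, c("nonrandom", "random", "unknown")), chroms)]
}

#' Per-chromosome duplication summary
#'
#' Reports, per assembly sequence, its size, the union size of duplicated
#' intervals, the duplicated percentage and the interval count, with totals
#' for nonrandom chromosomes, `_random` sequences, all placed sequences, and
#' the whole assembly.
#'
#' @param intervals Called intervals from [call_duplications()].
#' @param mg The `masked_genome` (chromosome names and sizes).
#' @return Tibble with `chr`, `chr_size`, `dup_size`, `perc_dup`,
#'   `n_intervals`; total rows are named `Tot_nonrandom`, `Tot_random`,
#'   `Tot_placed`, `Tot_whole`.
#' @export
summarize_genome <- function(intervals, mg) {
  stopifnot(inherits(mg, "masked_genome"))
  if (nrow(intervals) > 0 &&
      !all(intervals$chrom %in% names(mg$sequences))) {
    stop("interval on unknown chromosome", call. = FALSE)
  }
  sizes <- nchar(mg$sequences)
  per_bp <- union_bp(intervals[, c("chrom", "start", "end"), drop = FALSE],
                     by_chrom = TRUE)
  per_n <- intervals |>
    dplyr::count(.data$chrom, name = "n_intervals")
  base <- tibble::tibble(chr = strata_order(names(sizes)),
                         chr_size = as.numeric(sizes[strata_order(names(sizes))])) |>
    dplyr::left_join(per_bp, by = c(chr = "chrom")) |>
    dplyr::left_join(per_n, by = c(chr = "chrom")) |>
    dplyr::mutate(
      dup_size = dplyr::coalesce(.data$bp, 0L),
      n_intervals = dplyr::coalesce(.data$n_intervals, 0L),
      stratum = chrom_stratum(.data$chr)
    ) |>
    dplyr::select("chr", "chr_size", "dup_size", "n_intervals", "stratum")
  tot <- function(rows, label) {
    tibble::tibble(
      chr = label,
      chr_size = sum(rows$chr_size), dup_size = sum(rows$dup_size),
      n_intervals = sum(rows$n_intervals), stratum = "total"
    )
  }
  nonr <- base[base$stratum == "nonrandom", ]
  rand <- base[base$stratum == "random", ]
  unkn <- base[base$stratum == "unknown", ]
  out <- dplyr::bind_rows(
    nonr, tot(nonr, "Tot_nonrandom"),
    rand, if (nrow(rand)) tot(rand, "Tot_random"),
    if (nrow(rand) || nrow(nonr)) tot(dplyr::bind_rows(nonr, rand), "Tot_placed"),
    unkn, tot(base, "Tot_whole")
  )
  out$perc_dup <- round(100 * out$dup_size / out$chr_size, 2)
  out[, c("chr", "chr_size", "dup_size", "perc_dup", "n_intervals")]
}

#' Window class distribution
#'
#' Percentages of negative / borderline / positive windows, overall and per
#' masked-percentage bin.
#'
#' @param w5 Labelled window tibble.
#' @return Tibble with `bin` (`all` plus the five masked bins), `n` and the
#'   three percentage columns (summing to 100 within rounding).
#' @export
window_class_distribution <- function(w5) {
  stopifnot(all(w5$label != "unset"))
  w5$bin <- as.character(masked_bin(w5$masked_pct))
  dist_of <- function(g, bin) {
    tibble::tibble(
      bin = bin, n = nrow(g),
      negative = 100 * mean(g$label == "negative"),
      borderline = 100 * mean(g$label == "borderline"),
      positive = 100 * mean(g$label == "positive")
    )
  }
  dplyr::bind_rows(
    dist_of(w5, "all"),
    purrr::map_dfr(levels(masked_bin(0)), function(b) {
      g <- w5[w5$bin == b, , drop = FALSE]
      if (nrow(g) == 0) return(NULL)
      dist_of(g, b)
    })
  )
}

#' Interval size distribution
#'
#' Histogram of called interval sizes at a configurable bin width, with the
#' mode (densest bin midpoint) and the maximum size.
#'
#' @param intervals Called intervals.
#' @param binwidth Histogram bin width in bp (default 5000).
#' @return List with `histogram` (tibble `mid`, `count`), `mode_size`,
#'   `max_size`.
#' @export
interval_size_distribution <- function(intervals, binwidth = 5000) {
  sizes <- intervals$end - intervals$start
  if (length(sizes) == 0) {
    return(list(histogram = tibble::tibble(mid = double(), count = integer()),
                mode_size = NA_real_, max_size = NA_real_))
  }
  br <- seq(0, (max(sizes) %/% binwidth + 1) * binwidth, by = binwidth)
  h <- graphics::hist(sizes, breaks = br, plot = FALSE, right = FALSE)
  list(
    histogram = tibble::tibble(mid = h$mids, count = h$counts),
    mode_size = h$mids[which.max(h$counts)],
    max_size = max(sizes)
  )
}

#' Compare called intervals with a truth set
#'
#' Base-level recovery metrics. Sensitivity is the fraction of truth bases
#' covered by calls. Precision is the fraction of called bases falling
#' within the truth dilated by the caller's localisation resolution on each
#' side: the window-of-`n` rule marks whole windows, so a called interval
#' legitimately overhangs a true duplication edge by up to `k` member
#' windows plus the straddling 1-kub window — `(k + 1) * unit` unmasked
#' bases, inflated to genomic span by the masked fraction. Pass a
#' `masked_genome` to have that tolerance derived (`(k + 1) * unit /
#' (1 - masked_fraction / 100)`), or set `boundary_tol` explicitly.
#'
#' @param calls Called interval tibble.
#' @param truth Truth interval tibble (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of chromosome sizes, or a `masked_genome`.
#' @param boundary_tol Edge tolerance in bp applied to the truth when scoring
#'   precision; `NULL` (default) derives it from the window definition
#'   (plain `(k + 1) * unit` when `chrom_sizes` is not a `masked_genome`).
#' @param unit,k Window parameters used for the derived tolerance.
#' @return Tibble with `sensitivity`, `precision`, `boundary_tol`, `tp_bp`,
#'   `called_bp`, `truth_bp`.
#' @export
evaluate_calls <- function(calls, truth, chrom_sizes, boundary_tol = NULL,
                           unit = 1000, k = 5) {
  if (inherits(chrom_sizes, "masked_genome")) {
    mg <- chrom_sizes
    chrom_sizes <- nchar(mg$sequences)
    if (is.null(boundary_tol)) {
      boundary_tol <- (k + 1) * unit / (1 - masked_fraction(mg) / 100)
    }
  }
  if (is.null(boundary_tol)) boundary_tol <- (k + 1) * unit
  called <- interval_union(calls[, c("chrom", "start", "end"), drop = FALSE])
  tru <- interval_union(truth[, c("chrom", "start", "end"), drop = FALSE])
  truth_bp <- sum(tru$end - tru$start)
  called_bp <- sum(called$end - called$start)
  tp <- sum(with(interval_intersect(called, tru), end - start))
  dil <- interval_dilate(tru, boundary_tol, chrom_sizes)
  tp_dil <- sum(with(interval_intersect(called, dil), end - start))
  tibble::tibble(
    sensitivity = if (truth_bp > 0) tp / truth_bp else NA_real_,
    precision = if (called_bp > 0) tp_dil / called_bp else NA_real_,
    boundary_tol = boundary_tol,
    tp_bp = tp, called_bp = called_bp, truth_bp = truth_bp
  )
}

#' Stacked window-class plot per masked bin
#'
#' @param dist Output of [window_class_distribution()].
#' @return A ggplot object.
#' @export
plot_window_classes <- function(dist) {
  long <- tidyr::pivot_longer(dist, c("negative", "borderline", "positive"),
                              names_to = "class", values_to = "pct")
  long$class <- factor(long$class, c("negative", "borderline", "positive"))
  ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$pct, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(negative = "forestgreen",
                                          borderline = "grey55",
                                          positive = "firebrick")) +
    ggplot2::labs(x = "masked sequence percentage bin", y = "% of windows") +
    ggplot2::theme_minimal()
}

#' Histogram plot of interval sizes
#'
#' @param intervals Called intervals.
#' @param binwidth Bin width in bp.
#' @return A ggplot object.
#' @export
plot_interval_sizes <- function(intervals, binwidth = 5000) {
  ggplot2::ggplot(intervals,
                  ggplot2::aes((.data$end - .data$start) / 1000)) +
    ggplot2::geom_histogram(binwidth = binwidth / 1000, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "interval size (kb)", y = "count") +
    ggplot2::theme_minimal()
}
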