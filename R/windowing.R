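# Windowing over unmasked bases. A 1-kub window holds exactly `unit` unmasked
# nucleotides plus any interposed masked ones, so its genomic span varies with
# local repeat content. Assembly gaps discard the partial window in progress
# and restart scanning at the first unmasked base after the gap; masked
# repeats do not.

#' Build 1-kub windows
#'
#' Scans each chromosome left to right, closing a window once it has
#' accumulated exactly `unit` unmasked bases. A window's span runs from the
#' previous window's span end (or, at the start of a gap-delimited run, from
#' the run's first unmasked base) to its last accumulated unmasked base.
#' Partial windows at gaps or at the chromosome end are discarded.
#'
#' @param mg A `masked_genome` from [apply_masking()].
#' @param unit Unmasked bases per window (default 1000; reduce for small
#'   examples).
#' @return Tibble with `chrom`, `run` (gap-delimited run ordinal), `index`
#'   (window ordinal along the chromosome), `start`, `end` (0-based,
#'   half-open span), `unmasked` (= `unit`), `depth1` (NA until
#'   [count_depth()]).
#' @export
kub_windows <- function(mg, unit = 1000L) {
  stopifnot(inherits(mg, "masked_genome"), unit >= 1)
  unit <- as.integer(unit)
  res <- purrr::imap(mg$sequences, function(s, nm) {
    n <- nchar(s)
    if (n == 0) return(NULL)
    masked <- logical(n)
    m <- mg$mask[mg$mask$chrom == nm, , drop = FALSE]
    for (i in seq_len(nrow(m))) masked[(m$start[i] + 1L):m$end[i]] <- TRUE
    gap <- logical(n)
    g <- mg$gaps[mg$gaps$chrom == nm, , drop = FALSE]
    for (i in seq_len(nrow(g))) gap[(g$start[i] + 1L):g$end[i]] <- TRUE

    # gap-delimited segments
    seg <- data.frame(unclass(rle(gap)))
    seg$end <- cumsum(seg$lengths)
    seg$start <- seg$end - seg$lengths
    seg <- seg[!seg$values, , drop = FALSE]

    out <- vector("list", nrow(seg))
    idx0 <- 0L
    for (si in seq_len(nrow(seg))) {
      lo <- seg$start[si]; hi <- seg$end[si]          # 0-based half-open
      u <- which(!masked[(lo + 1L):hi]) + lo          # 1-based positions of unmasked
      nw <- length(u) %/% unit
      if (nw == 0) next
      last_u <- u[seq_len(nw) * unit]                 # 1-based last unmasked base
      ends <- last_u                                   # half-open end == 1-based pos
      starts <- c(u[1] - 1L, ends[-nw])
      out[[si]] <- tibble::tibble(
        chrom = nm, run = si,
        index = idx0 + seq_len(nw),
        start = as.integer(starts), end = as.integer(ends),
        unmasked = unit
      )
      idx0 <- idx0 + nw
    }
    dplyr::bind_rows(out)
  })
  w <- dplyr::bind_rows(res)
  if (nrow(w) == 0) {
    w <- tibble::tibble(chrom = character(), run = integer(), index = integer(),
                        start = integer(), end = integer(), unmasked = integer())
  }
  w$depth1 <- NA_real_
  w
}

#' Build sliding 5-kub windows
#'
#' Merges every run of `k` consecutive 1-kub windows (no gap between members)
#' into one 5-kub window, sliding by one 1-kub window; successive windows
#' share `k - 1` members. Runs shorter than `k` yield no window.
#'
#' @param w1 Output of [kub_windows()], with `depth1` filled by
#'   [count_depth()] (otherwise depths are NA).
#' @param mg The `masked_genome` the windows were built on (for the masked
#'   percentage of each span).
#' @param k Number of 1-kub members (default 5).
#' @return Tibble with `chrom`, `run`, `first_index`, `start`, `end`, `depth`
#'   (sum of member `depth1`), `masked_pct` (percent of the span masked) and
#'   `label` (`"unset"` until [classify_windows()]).
#' @export
sliding_windows <- function(w1, mg, k = 5L) {
  stopifnot(inherits(mg, "masked_genome"), k >= 1)
  k <- as.integer(k)
  if (nrow(w1) == 0) {
    return(tibble::tibble(chrom = character(), run = integer(),
                          first_index = integer(), start = integer(),
                          end = integer(), depth = double(),
                          masked_pct = double(), label = character()))
  }
  cums <- mask_cumsum(mg)
  w1 <- dplyr::arrange(w1, .data$chrom, .data$index)
  out <- w1 |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::group_map(function(g, key) {
      m <- nrow(g)
      if (m < k) return(NULL)
      i <- seq_len(m - k + 1L)
      cd <- c(0, cumsum(g$depth1))
      tibble::tibble(
        chrom = key$chrom, run = key$run,
        first_index = g$index[i],
        start = g$start[i], end = g$end[i + k - 1L],
        depth = cd[i + k] - cd[i]
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), run = integer(),
                          first_index = integer(), start = integer(),
                          end = integer(), depth = double(),
                          masked_pct = double(), label = character()))
  }
  cm <- cums
  out$masked_pct <- purrr::pmap_dbl(
    list(out$chrom, out$start, out$end),
    function(ch, s, e) 100 * (cm[[ch]][e + 1L] - cm[[ch]][s + 1L]) / (e - s)
  )
  out$label <- "unset"
  dplyr::arrange(out, .data$chrom, .data$first_index)
}

#' Masked-percentage bin of a window
#'
#' Bins masked percentages into the five classes used for window-class
#' summaries: `<20` (strictly below 20), `20-40`, `40-60`, `60-80`
#' (closed-open) and `>80` (boundary 80 belongs to `60-80`).
#'
#' @param masked_pct Numeric vector of masked percentages in `[0, 100]`.
#' @return Factor with levels `<20`, `20-40`, `40-60`, `60-80`, `>80`.
#' @export
masked_bin <- function(masked_pct) {
  f <- cut(masked_pct, breaks = c(-Inf, 20, 40, 60, 80, Inf), right = FALSE,
           labels = c("<20", "20-40", "40-60", "60-80", ">80"))
  f[!is.na(masked_pct) & masked_pct == 80] <- "60-80"  # ">80" is strict
  f
}
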