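# Independent brute-force oracles, deliberately written as naive per-base /
# per-position loops, never sharing code with the implementation.

# Percent of non-gap bases masked, by marking every base.
oracle_masked_fraction <- function(seq_len_bp, mask, gaps) {
  masked <- rep(FALSE, seq_len_bp)
  for (i in seq_len(nrow(mask))) {
    masked[(mask$start[i] + 1):mask$end[i]] <- TRUE
  }
  gap <- rep(FALSE, seq_len_bp)
  for (i in seq_len(nrow(gaps))) {
    gap[(gaps$start[i] + 1):gaps$end[i]] <- TRUE
  }
  100 * sum(masked & !gap) / sum(!gap)
}

# Hand-scan of the kub windowing rule over per-base masked/gap indicators.
# Returns a data.frame of spans (0-based half-open).
oracle_windows <- function(masked, gap, unit) {
  n <- length(masked)
  spans <- list()
  i <- 1
  repeat {
    # find the start of the next run: first unmasked non-gap base
    while (i <= n && (gap[i] || masked[i])) i <- i + 1
    if (i > n) break
    run_pos <- i
    acc <- 0
    first <- NA
    span_start <- NA
    j <- i
    while (j <= n && !gap[j]) {
      if (!masked[j]) {
        if (acc == 0 && is.na(span_start)) span_start <- j - 1
        acc <- acc + 1
        if (acc == unit) {
          spans[[length(spans) + 1]] <- c(span_start, j)
          acc <- 0
          span_start <- j  # next window starts right after this span
        }
      }
      j <- j + 1
    }
    i <- j + 1
  }
  if (length(spans) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, spans)
  data.frame(start = m[, 1], end = m[, 2])
}

# Enumerate every window-of-n over a label vector; mark all n when at least
# m are positive. Returns the logical marked vector.
oracle_mark <- function(labels, m = 6, n = 7) {
  L <- length(labels)
  marked <- rep(FALSE, L)
  if (L >= n) {
    for (i in 1:(L - n + 1)) {
      cnt <- 0
      for (j in i:(i + n - 1)) if (labels[j] == "positive") cnt <- cnt + 1
      if (cnt >= m) for (j in i:(i + n - 1)) marked[j] <- TRUE
    }
  }
  marked
}

# Merge a logical marked vector over spans into intervals (overlap/abut).
oracle_intervals <- function(spans_start, spans_end, marked) {
  idx <- which(marked)
  if (length(idx) == 0) return(data.frame(start = integer(), end = integer()))
  iv <- data.frame(start = spans_start[idx], end = spans_end[idx])
  iv <- iv[order(iv$start), ]
  out <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

# Union bp of hit intervals by per-base marking on a single chromosome.
oracle_union_bp <- function(hits, chrom_len) {
  covered <- rep(FALSE, chrom_len)
  for (i in seq_len(nrow(hits))) {
    if (hits$end[i] > hits$start[i]) {
      covered[(hits$start[i] + 1):hits$end[i]] <- TRUE
    }
  }
  sum(covered)
}
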