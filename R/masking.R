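# Repeat masking: three settings compared in the analysis.
#
#   div10_low  tandem repeats plus interspersed repeats with < 10% divergence
#              from their consensus, masked to lowercase
#   nodiv_low  all annotated repeats, masked to lowercase
#   nodiv_N    all annotated repeats, masked to N
#
# Assembly gaps (runs of N in the input assembly) are a separate track: windows
# are discarded at gaps but extend through masked repeats.

MASK_SETTINGS <- c("div10_low", "nodiv_low", "nodiv_N")

#' Detect assembly gaps
#'
#' Finds maximal runs of `N` of length at least `min_gap_run` in each
#' sequence. Shorter N runs are treated as ordinary ambiguous bases, not gaps.
#'
#' @param sequences Named character vector of uppercase assembly sequences.
#' @param min_gap_run Minimum N-run length to call a gap (default 10).
#' @return Tibble with `chrom`, `start`, `end` (0-based, half-open).
#' @export
detect_assembly_gaps <- function(sequences, min_gap_run = 10L) {
  stopifnot(length(sequences) == 0 || !is.null(names(sequences)))
  out <- purrr::imap(sequences, function(s, nm) {
    if (nchar(s) == 0) {
      return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
    }
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "N")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_gap_run
    tibble::tibble(chrom = nm, start = starts[keep], end = ends[keep])
  })
  dplyr::bind_rows(out)
}

#' Read RepeatMasker .out annotations
#'
#' Parses the standard RepeatMasker `.out` column layout (three header lines,
#' divergence in column 2, 1-based inclusive query coordinates) into the
#' 0-based half-open repeat annotation table used throughout the package.
#' Repeats whose class/family is `Simple_repeat`, `Satellite` or
#' `Low_complexity` are classified `tandem`; everything else `interspersed`.
#'
#' @param path Path to a RepeatMasker-style `.out` file.
#' @return Tibble with `chrom`, `start`, `end`, `kind`, `family`, `divergence`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^\\s*(SW|score|perc)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      kind = character(), family = character(), divergence = double()
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  tibble::tibble(
    chrom = purrr::map_chr(fields, 5),
    start = as.integer(purrr::map_chr(fields, 6)) - 1L,
    end = as.integer(purrr::map_chr(fields, 7)),
    kind = dplyr::if_else(
      grepl("Simple_repeat|Satellite|Low_complexity",
            purrr::map_chr(fields, 11)),
      "tandem", "interspersed"
    ),
    family = purrr::map_chr(fields, 10),
    divergence = as.numeric(purrr::map_chr(fields, 2))
  )
}

#' Read repeat annotations from BED
#'
#' BED6+ with `name` carrying the family, column 5 unused, and an optional
#' seventh column holding percent divergence (NA or "." for tandem repeats).
#'
#' @param path Path to the BED file.
#' @param kind Repeat kind to assign when the file does not distinguish:
#'   `"interspersed"` or `"tandem"`.
#' @return Tibble as in [read_repeatmasker_out()].
#' @export
read_repeat_bed <- function(path, kind = "interspersed") {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  tibble::tibble(
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    kind = if (ncol(df) >= 8) as.character(df[[8]]) else kind,
    family = if (ncol(df) >= 4) as.character(df[[4]]) else "repeat",
    divergence = if (ncol(df) >= 7) suppressWarnings(as.numeric(df[[7]])) else NA_real_
  )
}

validate_repeats <- function(repeats, sequences) {
  stopifnot(all(c("chrom", "start", "end", "kind") %in% names(repeats)))
  if (nrow(repeats) == 0) return(invisible(repeats))
  if (!all(repeats$chrom %in% names(sequences))) {
    stop("repeat annotation on unknown chromosome", call. = FALSE)
  }
  if (any(repeats$start < 0) ||
      any(repeats$end > nchar(sequences)[repeats$chrom]) ||
      any(repeats$start >= repeats$end)) {
    stop("repeat annotation out of sequence bounds", call. = FALSE)
  }
  if (any(!is.na(repeats$divergence) & repeats$divergence < 0)) {
    stop("repeat divergence must be non-negative", call. = FALSE)
  }
  invisible(repeats)
}

#' Apply a repeat-masking setting
#'
#' Builds a `masked_genome`: the assembly plus a mask track (union of the
#' repeats selected by `setting`) and an assembly-gap track, kept separate so
#' that windowing can discard gap-crossing windows while extending through
#' masked repeats. Repeats overlapping gaps are clipped to their non-gap
#' portion. Under `div10_low` only tandem repeats and interspersed repeats
#' with divergence strictly below 10% enter the mask; divergence exactly 10
#' is not masked.
#'
#' @param sequences Named character vector of uppercase assembly sequences.
#' @param repeats Repeat annotation tibble (`chrom`, `start`, `end`, `kind`,
#'   `family`, `divergence`), e.g. from [read_repeatmasker_out()].
#' @param setting One of `"div10_low"`, `"nodiv_low"`, `"nodiv_N"`.
#' @param min_gap_run Passed to [detect_assembly_gaps()].
#' @return An object of class `masked_genome`: a list with `sequences`
#'   (original, uppercase), `masked` (policy-applied sequences), `mask` and
#'   `gaps` interval tibbles, `setting`, and `mask_char_policy`
#'   (`"lowercase"` or `"N"`).
#' @export
apply_masking <- function(sequences, repeats, setting = "nodiv_N",
                          min_gap_run = 10L) {
  if (!setting %in% MASK_SETTINGS) {
    stop("unknown masking setting '", setting, "'; expected one of ",
         paste(MASK_SETTINGS, collapse = ", "), call. = FALSE)
  }
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  validate_repeats(repeats, sequences)
  gaps <- detect_assembly_gaps(sequences, min_gap_run)

  selected <- if (setting == "div10_low") {
    dplyr::filter(repeats, .data$kind == "tandem" |
                    (!is.na(.data$divergence) & .data$divergence < 10))
  } else {
    repeats
  }
  mask <- interval_union(selected[, c("chrom", "start", "end")])
  if (nrow(gaps) > 0 && nrow(mask) > 0) {
    # clip mask to its non-gap portion
    nongap <- interval_complement(gaps, setNames(nchar(sequences), names(sequences)))
    mask <- interval_intersect(mask, nongap)
  }
  policy <- if (setting == "nodiv_N") "N" else "lowercase"

  masked <- mask_sequences_chr(sequences, mask, policy)
  structure(
    list(sequences = sequences, masked = masked, mask = mask, gaps = gaps,
         setting = setting, mask_char_policy = policy,
         repeats = tibble::as_tibble(repeats)),
    class = "masked_genome"
  )
}

# Apply the mask character policy to raw sequence strings.
mask_sequences_chr <- function(sequences, mask, policy) {
  out <- sequences
  for (nm in unique(mask$chrom)) {
    m <- mask[mask$chrom == nm, , drop = FALSE]
    r <- charToRaw(sequences[[nm]])
    idx <- unlist(purrr::map2(m$start, m$end, ~ seq.int(.x + 1L, .y)))
    if (policy == "N") {
      r[idx] <- as.raw(0x4E)
    } else {
      b <- r[idx]
      upper <- b >= as.raw(0x41) & b <= as.raw(0x5A)
      b[upper] <- as.raw(as.integer(b[upper]) + 32L)
      r[idx] <- b
    }
    out[[nm]] <- rawToChar(r)
  }
  out
}

#' @export
print.masked_genome <- function(x, ...) {
  cat(sprintf(
    "<masked_genome> %d sequence(s), %s bp; setting %s (%s policy)\n",
    length(x$sequences), format(sum(nchar(x$sequences)), big.mark = ","),
    x$setting, x$mask_char_policy
  ))
  cat(sprintf("  masked: %s bp in %d intervals; gaps: %s bp in %d intervals\n",
              format(sum(x$mask$end - x$mask$start), big.mark = ","),
              nrow(x$mask),
              format(sum(x$gaps$end - x$gaps$start), big.mark = ","),
              nrow(x$gaps)))
  invisible(x)
}

#' Percent of non-gap bases masked
#'
#' `100 * masked bp / (total bp - gap bp)`, with overlapping mask intervals
#' counted once (the mask track is already a union).
#'
#' @param mg A `masked_genome` from [apply_masking()].
#' @return A single numeric percentage.
#' @export
masked_fraction <- function(mg) {
  stopifnot(inherits(mg, "masked_genome"))
  total <- sum(nchar(mg$sequences))
  gap_bp <- sum(mg$gaps$end - mg$gaps$start)
  if (total - gap_bp <= 0) {
    stop("masked fraction undefined: genome consists only of gaps", call. = FALSE)
  }
  100 * union_bp(mg$mask) / (total - gap_bp)
}

#' Policy-applied sequences of a masked genome
#'
#' @param mg A `masked_genome`.
#' @return Named character vector with the mask character policy applied
#'   (lowercase or N at masked positions).
#' @export
masked_sequences <- function(mg) {
  stopifnot(inherits(mg, "masked_genome"))
  mg$masked
}

# Per-chromosome logical masked indicator and its cumulative sum (for O(1)
# masked-bp lookups over arbitrary spans).
mask_cumsum <- function(mg) {
  purrr::imap(mg$sequences, function(s, nm) {
    v <- logical(nchar(s))
    m <- mg$mask[mg$mask$chrom == nm, , drop = FALSE]
    for (i in seq_len(nrow(m))) v[(m$start[i] + 1L):m$end[i]] <- TRUE
    c(0, cumsum(v))
  })
}

#' Write a masked FASTA
#'
#' Writes the policy-applied sequences as FASTA with 60-character lines.
#'
#' @param mg A `masked_genome`.
#' @param path Output path.
#' @export
write_masked_fasta <- function(mg, path) {
  x <- Biostrings::BStringSet(masked_sequences(mg))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any further columns, tab-separated,
#' without header (BED convention, 0-based half-open).
#'
#' @param df Interval table.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED3+ file
#'
#' @param path Path to a BED file.
#' @param extra_names Names for columns beyond the first three, if present.
#' @return Tibble with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names) && ncol(df) >= 3 + length(extra_names)) {
    names(df)[seq(4, 3 + length(extra_names))] <- extra_names
  }
  tibble::as_tibble(df)
}
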