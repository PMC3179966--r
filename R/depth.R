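# Read QC, alignment filtering and match-midpoint depth counting.

#' Clip reads to their high-quality portion
#'
#' Discards reads flagged low-quality/contaminated, reads whose per-trace
#' percent error exceeds 6.00, and reads whose high-quality portion is
#' shorter than 300 bp; survivors are truncated to the high-quality interval.
#' Reads lacking QC metadata pass with defaults (full length, zero error).
#'
#' @param reads Tibble with `id`, `sequence`.
#' @param qc Optional QC sidecar tibble with `id`, `percent_error`,
#'   `hq_start`, `hq_end` (0-based, half-open on the read) and optionally a
#'   logical `flagged` column for low-quality/contamination calls.
#' @param max_percent_error Discard above this per-trace error (default 6).
#' @param min_hq_len Discard below this high-quality length (default 300).
#' @return List with `reads` (tibble `id`, `sequence` clipped) and `counts`
#'   (tibble of reads discarded by each rule).
#' @export
clip_reads <- function(reads, qc = NULL, max_percent_error = 6.0,
                       min_hq_len = 300L) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  df <- tibble::tibble(
    id = reads$id, sequence = reads$sequence,
    percent_error = 0, hq_start = 0L, hq_end = nchar(reads$sequence),
    flagged = FALSE
  )
  if (!is.null(qc)) {
    qc <- tibble::as_tibble(qc)
    if (!"flagged" %in% names(qc)) qc$flagged <- FALSE
    m <- match(df$id, qc$id)
    hit <- !is.na(m)
    df$percent_error[hit] <- qc$percent_error[m[hit]]
    df$hq_start[hit] <- as.integer(qc$hq_start[m[hit]])
    df$hq_end[hit] <- as.integer(qc$hq_end[m[hit]])
    df$flagged[hit] <- dplyr::coalesce(qc$flagged[m[hit]], FALSE)
  }
  stopifnot(all(df$hq_start >= 0), all(df$hq_end <= nchar(df$sequence)))
  hq_len <- df$hq_end - df$hq_start
  drop_flag <- df$flagged
  drop_err <- !drop_flag & df$percent_error > max_percent_error
  drop_len <- !drop_flag & !drop_err & hq_len < min_hq_len
  keep <- !(drop_flag | drop_err | drop_len)
  out <- df[keep, c("id", "sequence", "hq_start", "hq_end")]
  out$sequence <- substr(out$sequence, out$hq_start + 1L, out$hq_end)
  list(
    reads = out[, c("id", "sequence")],
    counts = tibble::tibble(
      total = n,
      flagged = sum(drop_flag),
      percent_error = sum(drop_err),
      short_hq = sum(drop_len),
      retained = sum(keep)
    )
  )
}

#' Map reads with the built-in seed-and-extend aligner
#'
#' A deterministic ungapped local aligner used in place of an external BLAST
#' run: exact seed words indexed over unmasked genome positions, extended in
#' both directions with an X-drop stop and trimmed to the maximum-scoring
#' extent. Extension never crosses an N (so N masking truncates matches);
#' lowercase-masked sequence is extended through and filtered downstream by
#' masked overlap. All qualifying matches are kept — multi-mapping is the
#' read-depth signal for collapsed duplications. Both strands are searched;
#' coordinates are always forward genome coordinates.
#'
#' @param reads Tibble with `id`, `sequence` (clipped reads).
#' @param mg A `masked_genome`.
#' @param seed_len Exact seed length (default 32).
#' @param stride Seed spacing along the read (default 16).
#' @param min_len Minimum reported genomic match length (default 301,
#'   i.e. matches larger than 300 bp).
#' @param min_identity Minimum percent identity (default 93).
#' @param xdrop X-drop extension cutoff (default 20, with +1/-2 scoring).
#' @return Tibble of matches: `read_id`, `chrom`, `start`, `end`, `length`,
#'   `strand`, `identity`, `mismatches`, `masked_overlap`.
#' @export
map_reads <- function(reads, mg, seed_len = 32L, stride = 16L,
                      min_len = 301L, min_identity = 93,
                      xdrop = 20L) {
  stopifnot(inherits(mg, "masked_genome"))
  seqs <- masked_sequences(mg)
  df <- map_reads_cpp(
    as.character(reads$id), as.character(reads$sequence),
    names(seqs), unname(seqs),
    seed_len = as.integer(seed_len), stride = as.integer(stride),
    min_len = as.integer(min_len), min_identity = min_identity,
    xdrop = as.integer(xdrop)
  )
  out <- tibble::as_tibble(df)
  out$masked_overlap <- masked_overlap_bp(out, mg)
  out
}

masked_overlap_bp <- function(matches, mg) {
  if (nrow(matches) == 0) return(integer(0))
  cums <- mask_cumsum(mg)
  purrr::pmap_int(
    list(matches$chrom, matches$start, matches$end),
    function(ch, s, e) as.integer(cums[[ch]][e + 1L] - cums[[ch]][s + 1L])
  )
}

#' Read BLAST tabular (outfmt 6) alignments
#'
#' Columns `qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`; minus-strand hits (`sstart > send`) are normalised
#' to forward 0-based half-open subject coordinates.
#'
#' @param path Path to the tabular file.
#' @param mg Optional `masked_genome` used to fill `masked_overlap`.
#' @return Match tibble as in [map_reads()] (without `mismatches` detail
#'   beyond the BLAST column).
#' @export
read_blast_tabular <- function(path, mg = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                        progress = FALSE)
  minus <- df$sstart > df$send
  s0 <- ifelse(minus, df$send, df$sstart) - 1L
  e0 <- ifelse(minus, df$sstart, df$send)
  out <- tibble::tibble(
    read_id = df$qseqid, chrom = df$sseqid,
    start = as.integer(s0), end = as.integer(e0),
    length = as.integer(e0 - s0),
    strand = ifelse(minus, "-", "+"),
    identity = df$pident,
    mismatches = as.integer(df$mismatch),
    evalue = df$evalue
  )
  out$masked_overlap <- if (is.null(mg)) NA_integer_ else masked_overlap_bp(out, mg)
  out
}

#' Filter alignment matches
#'
#' Keeps matches at least `min_len` bp long on the genome; under lowercase
#' mask policies additionally requires less than `max_masked_overlap` bp of
#' the match to lie within masked sequence. Under the N policy the
#' masked-overlap filter is inapplicable (alignments cannot enter N) and is
#' skipped. Idempotent.
#'
#' @param matches Match tibble from [map_reads()] or [read_blast_tabular()].
#' @param mg The `masked_genome` the matches refer to.
#' @param min_len Minimum genomic match length (default 301).
#' @param max_masked_overlap Exclusive masked-overlap cap under lowercase
#'   policies (default 200).
#' @return List with `matches` (filtered tibble) and `counts` (tibble of
#'   matches removed by each rule).
#' @export
filter_matches <- function(matches, mg, min_len = 301L,
                           max_masked_overlap = 200L) {
  stopifnot(inherits(mg, "masked_genome"))
  if (any(is.na(matches$masked_overlap))) {
    matches$masked_overlap <- masked_overlap_bp(matches, mg)
  }
  short <- matches$length < min_len
  overlap <- if (mg$mask_char_policy == "lowercase") {
    !short & matches$masked_overlap >= max_masked_overlap
  } else {
    rep(FALSE, nrow(matches))
  }
  keep <- !(short | overlap)
  list(
    matches = matches[keep, , drop = FALSE],
    counts = tibble::tibble(
      total = nrow(matches),
      too_short = sum(short),
      masked_overlap = sum(overlap),
      retained = sum(keep)
    )
  )
}

#' Count match-midpoint depth per 1-kub window
#'
#' Assigns each match to the unique window whose span contains the match's
#' middle nucleotide (`start + floor((end - start - 1) / 2)`; for even-length
#' matches the left-of-centre base). Midpoints falling outside any window
#' span (gaps, discarded partial windows, chromosome ends) are dropped;
#' matches on chromosomes without windows raise a warning and are dropped.
#'
#' @param w1 Window tibble from [kub_windows()].
#' @param matches Filtered match tibble.
#' @return `w1` with `depth1` filled (integer counts).
#' @export
count_depth <- function(w1, matches) {
  w1$depth1 <- 0
  if (nrow(matches) == 0) return(w1)
  unknown <- setdiff(unique(matches$chrom), unique(w1$chrom))
  if (length(unknown) > 0) {
    warning("matches on chromosome(s) without windows dropped: ",
            paste(unknown, collapse = ", "))
  }
  mid <- matches$start + (matches$end - matches$start - 1L) %/% 2L
  for (ch in intersect(unique(matches$chrom), unique(w1$chrom))) {
    wi <- which(w1$chrom == ch)
    starts <- w1$start[wi]
    ends <- w1$end[wi]
    m <- mid[matches$chrom == ch]
    pos <- findInterval(m, starts)
    ok <- pos >= 1 & m < ends[pmax(pos, 1L)]
    tab <- tabulate(pos[ok], nbins = length(wi))
    w1$depth1[wi] <- w1$depth1[wi] + tab
  }
  w1
}
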