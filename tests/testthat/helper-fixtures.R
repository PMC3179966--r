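# Shared fixtures, built in code.

no_repeats <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 kind = character(), family = character(),
                 divergence = double())
}

one_repeat <- function(chrom = "chr1", start = 2L, end = 6L,
                       kind = "interspersed", divergence = 12) {
  tibble::tibble(chrom = chrom, start = start, end = end, kind = kind,
                 family = "rep1", divergence = divergence)
}

# masked_genome over a plain sequence with the given repeats
toy_genome <- function(seq, repeats = no_repeats(), setting = "nodiv_low",
                       name = "chr1") {
  seqs <- setNames(seq, name)
  apply_masking(seqs, repeats, setting)
}

# A w5 tibble with the given labels, one gapless run, unit spans of 1 kb
labelled_w5 <- function(labels, chrom = "chr1", depth = NULL) {
  n <- length(labels)
  tibble::tibble(
    chrom = chrom, run = 1L, first_index = seq_len(n),
    start = (seq_len(n) - 1L) * 1000L, end = (seq_len(n) - 1L) * 1000L + 5000L,
    depth = depth %||% ifelse(labels == "positive", 200,
                              ifelse(labels == "borderline", 100, 80)),
    masked_pct = 0, label = labels
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small-scale generator spec for unit tests (fast)
desk_spec <- function(seed = 7, ...) {
  args <- list(...)
  defaults <- list(
    chrom_sizes = c(chr1 = 5e5, chr2 = 2.5e5),
    n_duplications = 4, dup_size_meanlog = log(15000),
    dup_size_sdlog = 0.3, dup_size_range = c(10000, 25000),
    n_gaps = 1, n_calibration = 6, n_genes = 60, n_tandem = 8,
    n_organelle_insertions = 3, seed = seed
  )
  do.call(synth_spec, utils::modifyList(defaults, args))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
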