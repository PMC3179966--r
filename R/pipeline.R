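# Pipeline orchestration: masking -> windowing -> depth -> calibration ->
# calling -> annotation, with per-stage filter bookkeeping and a manifest.

#' Pipeline configuration
#'
#' Collects inputs (in-memory objects or file paths) and parameters for
#' [run_wssd()]. Defaults reproduce the reference analysis: `nodiv_N`
#' masking, 1-kub windows aggregated in fives, matches larger than 300 bp
#' with less than 200 bp of masked overlap, identity at least 93%, and the
#' six-of-seven positive-window rule at `avg + 3 sd`.
#'
#' @param sequences Named character vector of assembly sequences, or a FASTA
#'   path.
#' @param repeats Repeat annotation tibble, or a RepeatMasker `.out` path.
#' @param reads Tibble with `id`, `sequence`, or a FASTA path.
#' @param qc Optional QC sidecar tibble or TSV path (`id`, `percent_error`,
#'   `hq_start`, `hq_end`, `flagged`).
#' @param calibration_regions Interval tibble or BED path of single-copy
#'   loci used to fit the depth mixture.
#' @param genes Optional gene tibble or GFF3 path.
#' @param organelle_hits Optional organelle-hit tibble or TSV.
#' @param setting Masking setting (`div10_low`, `nodiv_low`, `nodiv_N`).
#' @param unit,k Window unit (unmasked bases) and aggregation factor.
#' @param min_len,min_identity,max_masked_overlap Alignment filters.
#' @param seed_len,stride,xdrop Naive mapper parameters.
#' @param m_of_n Integer pair, the positive-window rule (default `c(6, 7)`).
#' @param positive_inclusive Boundary convention at `avg + 3 sd`.
#' @param sqrt_scaling Mixture component SD scaling (see [dmixture()]).
#' @param out_dir Output directory, or `NULL` for in-memory only.
#' @param overwrite Rewrite outputs that already exist (default `TRUE`).
#' @return A list of class `wssd_config`.
#' @export
wssd_config <- function(sequences, repeats, reads, qc = NULL,
                        calibration_regions = NULL, genes = NULL,
                        organelle_hits = NULL,
                        setting = "nodiv_N", unit = 1000L, k = 5L,
                        min_len = 301L, min_identity = 93,
                        max_masked_overlap = 200L,
                        seed_len = 32L, stride = 16L, xdrop = 20L,
                        m_of_n = c(6L, 7L), positive_inclusive = TRUE,
                        sqrt_scaling = TRUE,
                        out_dir = NULL, overwrite = TRUE) {
  if (!setting %in% MASK_SETTINGS) {
    stop("unknown masking setting '", setting, "'", call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "wssd_config")
}

load_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    out <- as.character(s)
    names(out) <- sub("\\s.*", "", names(s))
    return(out)
  }
  x
}

load_tbl <- function(x, reader) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

load_reads <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    return(tibble::tibble(id = sub("\\s.*", "", names(s)),
                          sequence = as.character(s)))
  }
  x
}

#' Run the full read-depth duplication pipeline
#'
#' Executes masking, windowing, read QC, mapping (built-in aligner), match
#' filtering, depth counting, mixture calibration, window classification,
#' interval calling and the summary tables; optionally overlays genes and
#' organelle hits. When `out_dir` is set, writes the masked FASTA, mask/gap
#' BEDs, window BEDs, the fitted-model JSON, interval BED, summary TSVs, a
#' filter-count JSON and a manifest recording parameters and input sizes.
#' Fully deterministic: rerunning a config reproduces every output.
#'
#' @param config A `wssd_config`.
#' @param matches Optional precomputed match tibble (e.g. from
#'   [read_blast_tabular()]) to use instead of the built-in mapper.
#' @return A list of class `wssd_run`: `masked_genome`, `windows1`,
#'   `windows5`, `matches`, `model`, `thresholds`, `intervals`,
#'   `genome_summary`, `class_distribution`, `size_distribution`, `genes`,
#'   `gene_table`, `numt_table`, `filter_counts`.
#' @export
run_wssd <- function(config, matches = NULL) {
  stopifnot(inherits(config, "wssd_config"))
  sequences <- load_sequences(config$sequences)
  repeats <- load_tbl(config$repeats, read_repeatmasker_out)
  reads <- load_reads(config$reads)
  qc <- load_tbl(config$qc, function(p)
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE))
  cal <- load_tbl(config$calibration_regions, read_bed)
  genes <- config$genes
  if (!is.null(genes)) {
    genes <- if (is.character(genes)) read_genes_gff3(genes) else genes
  }
  org <- load_tbl(config$organelle_hits, function(p)
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE))

  filter_counts <- list()

  mg <- apply_masking(sequences, repeats, config$setting)
  w1 <- kub_windows(mg, config$unit)

  clip <- clip_reads(reads, qc)
  filter_counts$reads <- as.list(clip$counts)

  if (is.null(matches)) {
    matches <- map_reads(clip$reads, mg, seed_len = config$seed_len,
                         stride = config$stride, min_len = config$min_len,
                         min_identity = config$min_identity,
                         xdrop = config$xdrop)
  }
  filt <- filter_matches(matches, mg, min_len = config$min_len,
                         max_masked_overlap = config$max_masked_overlap)
  filter_counts$matches <- as.list(filt$counts)

  w1 <- count_depth(w1, filt$matches)
  w5 <- sliding_windows(w1, mg, config$k)

  if (is.null(cal)) stop("calibration_regions are required", call. = FALSE)
  depths <- calibration_depths(w5, cal)
  model <- fit_mixture(depths, sqrt_scaling = config$sqrt_scaling)
  th <- mixture_thresholds(model)

  w5 <- classify_windows(w5, th,
                         positive_inclusive = config$positive_inclusive)
  intervals <- call_duplications(w5, m = config$m_of_n[1],
                                 n = config$m_of_n[2])
  genome_summary <- summarize_genome(intervals, mg)
  class_dist <- window_class_distribution(w5)
  size_dist <- interval_size_distribution(intervals)

  gene_table <- NULL
  if (!is.null(genes)) {
    genes <- classify_genes(genes, intervals)
    gene_table <- gene_density_table(genes, intervals, mg)
  }
  numt_table <- NULL
  if (!is.null(org)) {
    numt_table <- numt_content(org, intervals, mg)
  }

  run <- structure(
    list(masked_genome = mg, windows1 = w1, windows5 = w5,
         matches = filt$matches, model = model, thresholds = th,
         intervals = intervals, genome_summary = genome_summary,
         class_distribution = class_dist, size_distribution = size_dist,
         genes = genes, gene_table = gene_table, numt_table = numt_table,
         filter_counts = filter_counts, config = config),
    class = "wssd_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir,
                                          overwrite = config$overwrite)
  run
}

#' @export
print.wssd_run <- function(x, ...) {
  cat(sprintf(
    "<wssd_run> setting %s: %d intervals, %s bp duplicated (%.2f%% of genome)\n",
    x$config$setting, nrow(x$intervals),
    format(sum(x$intervals$end - x$intervals$start), big.mark = ","),
    100 * sum(x$intervals$end - x$intervals$start) /
      sum(nchar(x$masked_genome$sequences))
  ))
  cat(sprintf("  model: avg %.2f sd %.2f; positive cut %.2f\n",
              x$model$avg, x$model$sd, x$thresholds$positive_cut))
  invisible(x)
}

write_run <- function(run, dir, overwrite = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  emit <- function(f, fun) {
    p <- path(f)
    if (overwrite || !file.exists(p)) fun(p)
    p
  }
  emit("masked.fa", function(p) write_masked_fasta(run$masked_genome, p))
  emit("mask.bed", function(p) write_bed(run$masked_genome$mask, p))
  emit("gaps.bed", function(p) write_bed(run$masked_genome$gaps, p))
  emit("windows1.bed", function(p) write_bed(
    run$windows1[, c("chrom", "start", "end", "index", "unmasked", "depth1")], p))
  emit("windows5.bed", function(p) write_bed(
    run$windows5[, c("chrom", "start", "end", "first_index", "depth",
                     "masked_pct", "label")], p))
  emit("model.json", function(p) jsonlite::write_json(
    list(avg = run$model$avg, sd = run$model$sd, f = run$model$f,
         loglik = run$model$loglik, n_obs = run$model$n_obs),
    p, auto_unbox = TRUE, digits = NA))
  emit("sd_intervals.bed", function(p) write_bed(
    dplyr::mutate(run$intervals,
                  name = sprintf("SD%04d", dplyr::row_number()),
                  score = round(.data$mean_coverage, 2)) |>
      dplyr::select("chrom", "start", "end", "name", "score"), p))
  emit("table1_duplications.tsv", function(p)
    readr::write_tsv(run$genome_summary, p, progress = FALSE))
  emit("window_classes.tsv", function(p)
    readr::write_tsv(run$class_distribution, p, progress = FALSE))
  if (!is.null(run$gene_table)) {
    emit("table3_genes.tsv", function(p)
      readr::write_tsv(run$gene_table, p, progress = FALSE))
  }
  if (!is.null(run$numt_table)) {
    emit("table2_numt.tsv", function(p)
      readr::write_tsv(run$numt_table, p, progress = FALSE))
  }
  emit("filter_counts.json", function(p)
    jsonlite::write_json(run$filter_counts, p, auto_unbox = TRUE))
  emit("manifest.json", function(p) {
    cfg <- run$config
    scalars <- cfg[vapply(cfg, function(v)
      is.atomic(v) && length(v) <= 2 && !is.null(v), TRUE)]
    jsonlite::write_json(list(
      package = "wssdr",
      version = as.character(utils::packageVersion("wssdr")),
      parameters = scalars,
      inputs = list(
        n_sequences = length(run$masked_genome$sequences),
        genome_bp = sum(nchar(run$masked_genome$sequences)),
        n_repeats = nrow(run$masked_genome$repeats)
      )
    ), p, auto_unbox = TRUE)
  })
  invisible(dir)
}

#' Compare the three masking settings
#'
#' Runs the pipeline once per masking setting on the same inputs and returns
#' the window-class distributions side by side.
#'
#' @param sequences,repeats,reads,qc,calibration_regions As in
#'   [wssd_config()].
#' @param settings Settings to compare (default all three).
#' @param ... Further arguments passed to [wssd_config()].
#' @return List with `distributions` (joined tibble with a `setting` column)
#'   and `runs` (named list of `wssd_run`).
#' @export
compare_masking_settings <- function(sequences, repeats, reads, qc = NULL,
                                     calibration_regions = NULL,
                                     settings = MASK_SETTINGS, ...) {
  runs <- purrr::map(settings, function(s) {
    run_wssd(wssd_config(sequences, repeats, reads, qc = qc,
                         calibration_regions = calibration_regions,
                         setting = s, ...))
  })
  names(runs) <- settings
  dist <- purrr::imap_dfr(runs, function(r, s) {
    dplyr::mutate(r$class_distribution, setting = s, .before = 1)
  })
  list(distributions = dist, runs = runs)
}

# ---- report-layer arithmetic -------------------------------------------

#' Read retention and estimated sequence coverage
#'
#' The bookkeeping printed alongside a read-depth analysis: percent of reads
#' retained after QC, and the fold genome coverage estimated from the
#' retained read count and mean clipped length.
#'
#' @param total_reads Total reads before QC.
#' @param discarded_reads Reads discarded by QC.
#' @param mean_read_len Mean clipped read length (bp).
#' @param genome_bp Assembly size (bp).
#' @return Tibble with `retained_reads`, `retention_pct` (one decimal),
#'   `est_coverage` (nearest integer fold).
#' @export
coverage_report <- function(total_reads, discarded_reads, mean_read_len,
                            genome_bp) {
  retained <- total_reads - discarded_reads
  tibble::tibble(
    retained_reads = retained,
    retention_pct = round(100 * retained / total_reads, 1),
    est_coverage = round(retained * mean_read_len / genome_bp)
  )
}

#' Percentage helper used by the summary tables
#'
#' @param x Numerator.
#' @param total Denominator.
#' @param digits Decimal places (default 2).
#' @return `round(100 * x / total, digits)`.
#' @export
as_pct <- function(x, total, digits = 2) {
  stopifnot(total > 0)
  round(100 * x / total, digits)
}
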