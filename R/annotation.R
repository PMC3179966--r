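# Overlays on called duplications: gene content and density, protein-domain
# enrichment, nuclear organelle DNA (NUMT/NUPT) content, interval
# composition.

#' Read gene models from GFF3
#'
#' Imports gene features (1-based inclusive) and converts to the package's
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @return Tibble with `id`, `chrom`, `start`, `end`.
#' @export
read_genes_gff3 <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("gene", seq_along(gr))
  tibble::tibble(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Classify genes by duplication status
#'
#' A gene is `full` when its interval lies entirely within the union of the
#' merged duplicated intervals, `partial` when it properly overlaps the
#' union, `unique` otherwise.
#'
#' @param genes Tibble with `id`, `chrom`, `start`, `end`.
#' @param intervals Called duplication intervals.
#' @return `genes` with a `duplication_status` column.
#' @export
classify_genes <- function(genes, intervals) {
  assert_intervals(genes, "genes")
  u <- interval_union(intervals[, c("chrom", "start", "end"), drop = FALSE])
  ov <- overlap_bp_per_row(genes[, c("chrom", "start", "end")], u)
  width <- genes$end - genes$start
  genes$duplication_status <- dplyr::case_when(
    ov == width ~ "full",
    ov > 0 ~ "partial",
    TRUE ~ "unique"
  )
  genes
}

#' Gene density comparison table
#'
#' Per chromosome: total genes, fully duplicated genes, chromosome gene
#' density, duplicated gene density (both as genes per 100 kb), and their
#' ratio. Densities use the chromosome size and the duplicated union size
#' respectively. Strata totals as in [summarize_genome()].
#'
#' @param genes Classified genes from [classify_genes()].
#' @param intervals Called duplication intervals.
#' @param mg The `masked_genome`.
#' @return Tibble with `chr`, `total_genes`, `full_dup_genes`,
#'   `chr_gene_density`, `full_dup_gene_density`, `ratio_of_densities`.
#' @export
gene_density_table <- function(genes, intervals, mg) {
  stopifnot(inherits(mg, "masked_genome"),
            "duplication_status" %in% names(genes))
  sizes <- nchar(mg$sequences)
  if (any(sizes == 0)) stop("zero-length chromosome", call. = FALSE)
  dup_bp <- union_bp(intervals[, c("chrom", "start", "end"), drop = FALSE],
                     by_chrom = TRUE)
  base <- tibble::tibble(chr = strata_order(names(sizes)),
                         chr_size = as.numeric(sizes[strata_order(names(sizes))])) |>
    dplyr::left_join(
      dplyr::count(genes, .data$chrom, name = "total_genes"),
      by = c(chr = "chrom")
    ) |>
    dplyr::left_join(
      genes |>
        dplyr::filter(.data$duplication_status == "full") |>
        dplyr::count(.data$chrom, name = "full_dup_genes"),
      by = c(chr = "chrom")
    ) |>
    dplyr::left_join(dup_bp, by = c(chr = "chrom")) |>
    dplyr::mutate(
      total_genes = dplyr::coalesce(.data$total_genes, 0L),
      full_dup_genes = dplyr::coalesce(.data$full_dup_genes, 0L),
      dup_size = dplyr::coalesce(.data$bp, 0L),
      stratum = chrom_stratum(.data$chr)
    ) |>
    dplyr::select("chr", "chr_size", "dup_size", "total_genes",
                  "full_dup_genes", "stratum")
  tot <- function(rows, label) {
    tibble::tibble(chr = label, chr_size = sum(rows$chr_size),
                   dup_size = sum(rows$dup_size),
                   total_genes = sum(rows$total_genes),
                   full_dup_genes = sum(rows$full_dup_genes),
                   stratum = "total")
  }
  nonr <- base[base$stratum == "nonrandom", ]
  rand <- base[base$stratum == "random", ]
  unkn <- base[base$stratum == "unknown", ]
  out <- dplyr::bind_rows(
    nonr, tot(nonr, "Tot_nonrandom"),
    rand, if (nrow(rand)) tot(rand, "Tot_random"),
    tot(dplyr::bind_rows(nonr, rand), "Tot_placed"),
    unkn, tot(base, "Tot_whole")
  )
  out |>
    dplyr::mutate(
      chr_gene_density = round(1e5 * .data$total_genes / .data$chr_size, 2),
      full_dup_gene_density = ifelse(
        .data$dup_size > 0,
        round(1e5 * .data$full_dup_genes / .data$dup_size, 2), NA_real_),
      ratio_of_densities = round(
        .data$full_dup_gene_density / .data$chr_gene_density, 2)
    ) |>
    dplyr::select("chr", "total_genes", "full_dup_genes", "chr_gene_density",
                  "full_dup_gene_density", "ratio_of_densities")
}

#' Read InterProScan-style domain assignments
#'
#' Tab-separated with columns `protein_id`, `source_db`, `signature`,
#' `status`, `interpro_id` (header optional; extra columns ignored).
#'
#' @param path Path to the TSV.
#' @return Tibble of assignments.
#' @export
read_interproscan <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("protein_id", first)
  df <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE,
                        progress = FALSE)
  if (!has_header) {
    names(df)[1:5] <- c("protein_id", "source_db", "signature", "status",
                        "interpro_id")
  }
  tibble::as_tibble(df)
}

#' Retain true-positive, InterPro-assigned domain matches
#'
#' Keeps matches with `status == "T"` and a non-null InterPro accession
#' (drops NA, empty and `"NULL"`).
#'
#' @param assignments Tibble from [read_interproscan()].
#' @return Filtered tibble.
#' @export
filter_domains <- function(assignments) {
  dplyr::filter(
    assignments,
    .data$status == "T",
    !is.na(.data$interpro_id),
    .data$interpro_id != "NULL",
    .data$interpro_id != ""
  )
}

#' Domain enrichment factor in duplicated vs unique genes
#'
#' For each InterPro domain, the ratio of its fractional abundance among all
#' retained domain matches of duplicated peptides to its fractional
#' abundance among matches of unique peptides:
#' `EF(d) = (c_dup(d) / sum c_dup) / (c_uniq(d) / sum c_uniq)`.
#' Domains absent from unique peptides are reported with `dup_only = TRUE`
#' and no numeric EF. Counting unit is one retained match (set
#' `per_gene = TRUE` in [domain_counts()] to count gene presence instead).
#'
#' @param counts_dup,counts_unique Tibbles with `interpro_id`, `n` — domain
#'   occurrence counts among duplicated and unique peptides.
#' @return Tibble with `interpro_id`, `n_dup`, `n_unique`, `ef`, `dup_only`,
#'   sorted by EF descending (dup-only domains first by count).
#' @export
enrichment_factor <- function(counts_dup, counts_unique) {
  if (nrow(counts_dup) == 0 || nrow(counts_unique) == 0 ||
      sum(counts_dup$n) == 0 || sum(counts_unique$n) == 0) {
    stop("empty duplicated or unique domain universe", call. = FALSE)
  }
  tot_dup <- sum(counts_dup$n)
  tot_uniq <- sum(counts_unique$n)
  dplyr::full_join(
    dplyr::rename(counts_dup, n_dup = "n"),
    dplyr::rename(counts_unique, n_unique = "n"),
    by = "interpro_id"
  ) |>
    dplyr::mutate(
      n_dup = dplyr::coalesce(.data$n_dup, 0L),
      n_unique = dplyr::coalesce(.data$n_unique, 0L),
      dup_only = .data$n_unique == 0 & .data$n_dup > 0,
      ef = dplyr::if_else(
        .data$n_unique > 0,
        (.data$n_dup / tot_dup) / (.data$n_unique / tot_uniq),
        NA_real_)
    ) |>
    dplyr::arrange(dplyr::desc(.data$dup_only), dplyr::desc(.data$ef),
                   dplyr::desc(.data$n_dup))
}

#' Count retained domain matches by class
#'
#' @param assignments Retained assignments (see [filter_domains()]).
#' @param duplicated_proteins Character vector of protein/gene ids encoded by
#'   fully duplicated genes.
#' @param per_gene Count each (protein, domain) pair once instead of every
#'   match.
#' @return List with `dup` and `unique` count tibbles for
#'   [enrichment_factor()].
#' @export
domain_counts <- function(assignments, duplicated_proteins, per_gene = FALSE) {
  a <- assignments
  if (per_gene) a <- dplyr::distinct(a, .data$protein_id, .data$interpro_id)
  a$dup <- a$protein_id %in% duplicated_proteins
  list(
    dup = dplyr::count(a[a$dup, ], .data$interpro_id, name = "n"),
    unique = dplyr::count(a[!a$dup, ], .data$interpro_id, name = "n")
  )
}

#' Nuclear organelle DNA (NUMT/NUPT) content
#'
#' Quantifies mitochondrial and plastid DNA in the nuclear genome from
#' organelle-vs-nucleus alignment hits: hits at e-value <= `max_evalue` are
#' unioned per organelle class (each nucleotide counted once however many
#' hits cover it), reported per chromosome for the whole chromosome and for
#' its segmentally duplicated fraction, with strata totals. Percentages are
#' relative to the chromosome size and to the duplicated bp respectively.
#'
#' @param hits Tibble with `organelle` (`"mito"`/`"plastid"`), `chrom`,
#'   `start`, `end` and optionally `evalue`.
#' @param intervals Called duplication intervals.
#' @param mg The `masked_genome`.
#' @param max_evalue Hit e-value threshold (default 1e-4).
#' @return Tibble with `chr`, `chr_size`, `sd_size`, and bp/percentage
#'   columns for NUMTs and NUPTs in the whole chromosome and in SDs.
#' @export
numt_content <- function(hits, intervals, mg, max_evalue = 1e-4) {
  stopifnot(inherits(mg, "masked_genome"))
  if ("evalue" %in% names(hits)) {
    hits <- hits[is.na(hits$evalue) | hits$evalue <= max_evalue, , drop = FALSE]
  }
  sizes <- nchar(mg$sequences)
  sd_u <- interval_union(intervals[, c("chrom", "start", "end"), drop = FALSE])
  sd_bp <- union_bp(sd_u, by_chrom = TRUE)
  class_bp <- function(cls) {
    h <- hits[hits$organelle == cls, c("chrom", "start", "end"), drop = FALSE]
    u <- interval_union(h)
    whole <- union_bp(u, by_chrom = TRUE)
    insd <- union_bp(interval_intersect(u, sd_u), by_chrom = TRUE)
    list(whole = whole, insd = insd)
  }
  mt <- class_bp("mito")
  pt <- class_bp("plastid")
  pull_bp <- function(tb, chr) {
    v <- tb$bp[match(chr, tb$chrom)]
    dplyr::coalesce(v, 0L)
  }
  base <- tibble::tibble(
    chr = strata_order(names(sizes)),
    chr_size = as.numeric(sizes[strata_order(names(sizes))])
  ) |>
    dplyr::mutate(
      sd_size = as.numeric(pull_bp(sd_bp, .data$chr)),
      numt_bp = pull_bp(mt$whole, .data$chr),
      nupt_bp = pull_bp(pt$whole, .data$chr),
      numt_sd_bp = pull_bp(mt$insd, .data$chr),
      nupt_sd_bp = pull_bp(pt$insd, .data$chr),
      stratum = chrom_stratum(.data$chr)
    )
  tot <- function(rows, label) {
    dplyr::summarise(
      rows, chr = label,
      dplyr::across(c("chr_size", "sd_size", "numt_bp", "nupt_bp",
                      "numt_sd_bp", "nupt_sd_bp"), sum),
      stratum = "total"
    )
  }
  nonr <- base[base$stratum == "nonrandom", ]
  rand <- base[base$stratum == "random", ]
  unkn <- base[base$stratum == "unknown", ]
  out <- dplyr::bind_rows(
    nonr, tot(nonr, "Tot_nonrandom"),
    rand, if (nrow(rand)) tot(rand, "Tot_random"),
    tot(dplyr::bind_rows(nonr, rand), "Tot_placed"),
    unkn, tot(base, "Tot_whole")
  )
  out |>
    dplyr::mutate(
      numt_pct = round(100 * .data$numt_bp / .data$chr_size, 2),
      nupt_pct = round(100 * .data$nupt_bp / .data$chr_size, 2),
      numt_sd_pct = ifelse(.data$sd_size > 0,
                           round(100 * .data$numt_sd_bp / .data$sd_size, 2),
                           NA_real_),
      nupt_sd_pct = ifelse(.data$sd_size > 0,
                           round(100 * .data$nupt_sd_bp / .data$sd_size, 2),
                           NA_real_)
    ) |>
    dplyr::select("chr", "chr_size", "sd_size", "numt_bp", "numt_pct",
                  "nupt_bp", "nupt_pct", "numt_sd_bp", "numt_sd_pct",
                  "nupt_sd_bp", "nupt_sd_pct")
}

#' Most duplicated genes
#'
#' Ranks fully duplicated genes by the mean 5-kub coverage of their
#' containing merged interval, descending; ties broken by chromosome then
#' start. Optionally flags genes with organelle homologs and attaches their
#' InterPro domains.
#'
#' @param genes Classified genes (from [classify_genes()]).
#' @param intervals Called intervals (with `mean_coverage`).
#' @param n Number of genes to report (default 100); if fewer are eligible,
#'   all are returned with a warning.
#' @param organelle_gene_hits Optional tibble `gene_id`, `organelle` of
#'   gene-vs-organelle alignment hits.
#' @param domains Optional retained domain assignments (`protein_id`,
#'   `interpro_id`).
#' @return Tibble with `rank`, `id`, `chrom`, `start`, `end`,
#'   `mean_coverage`, `organelle_homolog`, `interpro_ids`.
#' @export
top_duplicated_genes <- function(genes, intervals, n = 100L,
                                 organelle_gene_hits = NULL,
                                 domains = NULL) {
  stopifnot("duplication_status" %in% names(genes))
  full <- genes[genes$duplication_status == "full", , drop = FALSE]
  if (nrow(full) == 0) {
    warning("no fully duplicated genes")
    return(tibble::tibble(rank = integer(), id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), mean_coverage = double(),
                          organelle_homolog = character(),
                          interpro_ids = character()))
  }
  u <- interval_union(intervals[, c("chrom", "start", "end"), drop = FALSE])
  ov <- GenomicRanges::findOverlaps(gr_from_tbl(full), gr_from_tbl(u),
                                    type = "within")
  # mean coverage of merged intervals: recompute over the merged union from
  # the (possibly pre-merged) input intervals, weighting by window count
  cov_of <- merged_mean_coverage(intervals, u)
  full$mean_coverage <- NA_real_
  full$mean_coverage[S4Vectors::queryHits(ov)] <-
    cov_of[S4Vectors::subjectHits(ov)]
  out <- full |>
    dplyr::arrange(dplyr::desc(.data$mean_coverage), .data$chrom, .data$start)
  if (nrow(out) < n) {
    warning(sprintf("only %d fully duplicated genes available (requested %d)",
                    nrow(out), n))
  }
  out <- head(out, n)
  out$rank <- seq_len(nrow(out))
  out$organelle_homolog <- ""
  if (!is.null(organelle_gene_hits) && nrow(organelle_gene_hits) > 0) {
    flags <- organelle_gene_hits |>
      dplyr::group_by(gene_id = .data$gene_id) |>
      dplyr::summarise(
        organelle_homolog = paste(sort(unique(.data$organelle)),
                                  collapse = "+"),
        .groups = "drop")
    m <- match(out$id, flags$gene_id)
    out$organelle_homolog[!is.na(m)] <- flags$organelle_homolog[m[!is.na(m)]]
  }
  out$interpro_ids <- ""
  if (!is.null(domains) && nrow(domains) > 0) {
    dd <- domains |>
      dplyr::group_by(protein_id = .data$protein_id) |>
      dplyr::summarise(
        interpro_ids = paste(sort(unique(.data$interpro_id)), collapse = ","),
        .groups = "drop")
    m <- match(out$id, dd$protein_id)
    out$interpro_ids[!is.na(m)] <- dd$interpro_ids[m[!is.na(m)]]
  }
  out[, c("rank", "id", "chrom", "start", "end", "mean_coverage",
          "organelle_homolog", "interpro_ids")]
}

merged_mean_coverage <- function(intervals, merged) {
  if (!"mean_coverage" %in% names(intervals) ||
      !"n_windows5" %in% names(intervals)) {
    intervals$mean_coverage <- intervals$mean_coverage %||% NA_real_
    return(rep(NA_real_, nrow(merged)))
  }
  ov <- GenomicRanges::findOverlaps(gr_from_tbl(intervals), gr_from_tbl(merged))
  tibble::tibble(
    m = S4Vectors::subjectHits(ov),
    w = intervals$n_windows5[S4Vectors::queryHits(ov)],
    cov = intervals$mean_coverage[S4Vectors::queryHits(ov)]
  ) |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(v = sum(.data$w * .data$cov) / sum(.data$w),
                     .groups = "drop") |>
    (function(tb) {
      out <- rep(NA_real_, nrow(merged))
      out[tb$m] <- tb$v
      out
    })()
}

#' GC and repeat composition of duplicated vs whole genome
#'
#' GC percent over non-gap, non-N bases and masked repeat bp per repeat
#' family class, inside the called intervals and genome-wide.
#'
#' @param intervals Called duplication intervals.
#' @param mg The `masked_genome` (carries the repeat annotation used for
#'   masking).
#' @return List with `gc` (tibble `region`, `gc_pct`) and `repeats` (tibble
#'   `family`, `bp_in_sd`, `bp_genome`).
#' @export
interval_composition <- function(intervals, mg) {
  stopifnot(inherits(mg, "masked_genome"))
  u <- interval_union(intervals[, c("chrom", "start", "end"), drop = FALSE])
  gc_of <- function(strings) {
    if (length(strings) == 0 || sum(nchar(strings)) == 0) return(NA_real_)
    x <- Biostrings::DNAStringSet(gsub("[^ACGTacgt]", "", strings))
    fr <- Biostrings::letterFrequency(x, letters = c("C", "G"))
    100 * sum(fr) / sum(Biostrings::width(x))
  }
  sd_seqs <- purrr::pmap_chr(u, function(chrom, start, end)
    substr(mg$sequences[[chrom]], start + 1, end))
  gc <- tibble::tibble(
    region = c("duplicated", "genome"),
    gc_pct = c(gc_of(sd_seqs), gc_of(unname(mg$sequences)))
  )
  reps <- mg$repeats
  if (nrow(reps) > 0) {
    reps$bp_in_sd <- overlap_bp_per_row(reps[, c("chrom", "start", "end")], u)
    rep_tbl <- reps |>
      dplyr::group_by(family = .data$family) |>
      dplyr::summarise(bp_in_sd = sum(.data$bp_in_sd),
                       bp_genome = sum(.data$end - .data$start),
                       .groups = "drop")
  } else {
    rep_tbl <- tibble::tibble(family = character(), bp_in_sd = integer(),
                              bp_genome = integer())
  }
  list(gc = gc, repeats = rep_tbl)
}
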