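# Synthetic genomes, annotations and shotgun reads with the statistical
# structure the pipeline assumes: implanted duplications (copy number 2-4,
# identity 94-100%, >= 10 kb), interspersed repeat families with a range of
# consensus divergences but tight recent subfamilies (so high-divergence
# families still cross-map when left unmasked), tandem repeats, assembly
# gaps, organelle-derived insertions, gene models, and ~12X reads of mean
# length ~735 bp — all recorded in a ground-truth table. Every stage draws
# from a named substream of a single seed.

#' Synthetic genome specification
#'
#' Defaults describe the desk-scale study condition: a 5 Mb assembly in five
#' sequences (three chromosomes, one `_random` contig, one `chrUn`), 20
#' implanted duplications of 10-100 kb (size mode near 20 kb) at copy number
#' 2-4 and identity 94-99.5%, about 15% interspersed repeat content in six
#' families, tandem blocks, three assembly gaps, ten organelle insertions
#' and 500 genes.
#'
#' @param chrom_sizes Named vector of sequence lengths.
#' @param gc GC fraction of the random background.
#' @param n_duplications,dup_size_meanlog,dup_size_sdlog,dup_size_range
#'   Number of duplications and their lognormal size distribution (bp),
#'   clamped to the range.
#' @param dup_copy_prob Probabilities of copy numbers 2, 3, 4.
#' @param dup_identity_range Uniform range of target copy identity (%).
#' @param dup_repeat_frac Fraction of each duplication annotated as
#'   (low-divergence) repeat, mirrored across its copies.
#' @param repeat_frac Target interspersed repeat fraction of the genome.
#' @param repeat_div_means Mean consensus divergence (%) of each repeat
#'   family; families above 10 stay unmasked under the `div10_low` setting.
#' @param repeat_within_div Divergence (%) between recent copies within a
#'   subfamily.
#' @param repeat_consensus_len Range of family consensus lengths (bp).
#' @param n_tandem,tandem_period,tandem_len Tandem repeat blocks.
#' @param n_gaps,gap_len Assembly gaps (runs of N).
#' @param n_calibration,calibration_len Reserved single-copy calibration
#'   regions (no implanted features), emulating FISH-validated single loci.
#' @param organelle_sizes Named sizes of the synthetic `mito` and `plastid`
#'   genomes.
#' @param n_organelle_insertions,organelle_insert_len,organelle_insert_div
#'   Organelle-derived nuclear insertions.
#' @param n_genes,gene_len_meanlog,gene_len_sdlog,gene_len_range Gene models.
#' @param seed Master RNG seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(
    chrom_sizes = c(chr1 = 2e6, chr2 = 1.5e6, chr3 = 1e6,
                    chr1_random = 3e5, chrUn = 2e5),
    gc = 0.35,
    n_duplications = 20,
    dup_size_meanlog = log(28000), dup_size_sdlog = 0.55,
    dup_size_range = c(10000, 100000),
    dup_copy_prob = c(0.60, 0.25, 0.15),
    dup_identity_range = c(94, 99.5),
    dup_repeat_frac = 0.15,
    repeat_frac = 0.15,
    repeat_div_means = c(2, 5, 8, 12, 18, 25),
    repeat_within_div = 2,
    repeat_consensus_len = c(500, 3000),
    n_tandem = 40, tandem_period = c(2, 50), tandem_len = c(200, 2000),
    n_gaps = 3, gap_len = c(5000, 20000),
    n_calibration = 25, calibration_len = 30000,
    organelle_sizes = c(mito = 60000, plastid = 30000),
    n_organelle_insertions = 10,
    organelle_insert_len = c(500, 5000),
    organelle_insert_div = c(0, 4),
    n_genes = 500,
    gene_len_meanlog = log(2500), gene_len_sdlog = 0.6,
    gene_len_range = c(500, 15000),
    seed = 1L) {
  spec <- as.list(environment())
  stopifnot(!is.null(names(chrom_sizes)), gc > 0, gc < 1,
            all(dup_identity_range >= 80), all(dup_identity_range <= 100))
  structure(spec, class = "synth_spec")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

hamming_pct <- function(a, b) {
  100 * mean(charToRaw(a) != charToRaw(b))
}

# Place `sizes` (in the given order) into the free space, non-overlapping.
# `free` is a tibble(chrom, start, end); returns list(placements, free).
place_sizes <- function(sizes, free, what = "feature") {
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    size <- sizes[i]
    w <- pmax(0, (free$end - free$start) - size + 1)
    if (sum(w) == 0) {
      stop(sprintf("cannot place %s of %d bp: no free slot large enough",
                   what, size), call. = FALSE)
    }
    slot <- sample.int(nrow(free), 1, prob = w)
    off <- if (w[slot] == 1) 0L else sample.int(w[slot], 1) - 1L
    s <- free$start[slot] + off
    out[[i]] <- tibble::tibble(chrom = free$chrom[slot], start = s,
                               end = s + size)
    left <- tibble::tibble(chrom = free$chrom[slot],
                           start = free$start[slot], end = s)
    right <- tibble::tibble(chrom = free$chrom[slot],
                            start = s + size, end = free$end[slot])
    free <- dplyr::bind_rows(free[-slot, ], left, right)
    free <- free[free$end - free$start > 0, , drop = FALSE]
  }
  list(placements = dplyr::bind_rows(out), free = free)
}

splice_into <- function(seqs, placements, pieces) {
  for (i in seq_len(nrow(placements))) {
    ch <- placements$chrom[i]
    substr(seqs[[ch]], placements$start[i] + 1L, placements$end[i]) <- pieces[i]
  }
  seqs
}

#' Generate a synthetic genome
#'
#' Builds the assembly, repeat annotations, gene models, organelle sequences
#' and hit truth, single-copy calibration regions, and the feature truth
#' table from a [synth_spec()]. Deterministic given the spec seed.
#'
#' @param spec A `synth_spec`.
#' @return List of class `synth_genome` with `sequences`, `repeats`, `genes`,
#'   `organelles` (named sequences), `organelle_hits`, `calibration_regions`,
#'   `truth`, `spec`.
#' @export
synth_genome <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(sub_seed(spec$seed, "genome"))
  sizes <- spec$chrom_sizes
  seqs <- purrr::map(sizes, ~ random_dna(.x, spec$gc))
  names(seqs) <- names(sizes)

  free <- tibble::tibble(chrom = names(sizes), start = 0L,
                         end = as.integer(sizes))
  truth <- list()
  repeats <- list()

  # --- assembly gaps ---------------------------------------------------
  gap_sizes <- round(runif(spec$n_gaps, spec$gap_len[1], spec$gap_len[2]))
  pl <- place_sizes(gap_sizes, free, "gap")
  free <- pl$free
  gaps <- pl$placements
  seqs <- splice_into(seqs, gaps, strrep("N", gap_sizes))
  truth$gaps <- dplyr::mutate(gaps, type = "gap")

  # --- reserved single-copy calibration regions ------------------------
  # Emulates the FISH-validated single loci used to parameterise the null
  # depth distribution: regions held free of implanted features.
  pl <- place_sizes(rep(spec$calibration_len, spec$n_calibration), free,
                    "calibration region")
  free <- pl$free
  cal <- dplyr::arrange(pl$placements, .data$chrom, .data$start)

  # --- duplications ----------------------------------------------------
  nd <- spec$n_duplications
  dup_sizes <- pmin(pmax(round(rlnorm(nd, spec$dup_size_meanlog,
                                      spec$dup_size_sdlog)),
                         spec$dup_size_range[1]), spec$dup_size_range[2])
  dup_sizes <- sort(dup_sizes, decreasing = TRUE)  # large blocks placed first
  copy_n <- sample(2:4, nd, replace = TRUE, prob = spec$dup_copy_prob)
  dup_ident <- runif(nd, spec$dup_identity_range[1], spec$dup_identity_range[2])
  dup_rows <- list()
  for (d in seq_len(nd)) {
    master <- random_dna(dup_sizes[d], spec$gc)
    pieces <- c(master,
                as.character(mutate_seqs_cpp(
                  rep(master, copy_n[d] - 1L), (100 - dup_ident[d]) / 100)))
    pl <- place_sizes(rep(dup_sizes[d], copy_n[d]), free,
                      sprintf("duplication %d", d))
    free <- pl$free
    plc <- pl$placements
    seqs <- splice_into(seqs, plc, pieces)
    dup_rows[[d]] <- dplyr::mutate(
      plc, type = "duplication", family = sprintf("dup%02d", d),
      copy_number = copy_n[d], identity = dup_ident[d]
    )
    # intra-duplication repeats, mirrored across copies
    if (spec$dup_repeat_frac > 0) {
      rep_bp <- round(spec$dup_repeat_frac * dup_sizes[d])
      n_blocks <- max(1, round(rep_bp / 1500))
      block <- max(200, rep_bp %/% n_blocks)
      offs <- sort(sample.int(max(1, dup_sizes[d] - block),
                              min(n_blocks, max(1, dup_sizes[d] %/% (2 * block)))))
      offs <- offs[c(TRUE, diff(offs) > block)]
      for (o in offs) {
        repeats[[length(repeats) + 1]] <- tibble::tibble(
          chrom = plc$chrom, start = plc$start + o,
          end = pmin(plc$start + o + block, plc$end),
          kind = "interspersed", family = sprintf("dupRep%02d", d),
          divergence = runif(1, 1, 8)
        )
      }
    }
  }
  truth$dups <- dplyr::bind_rows(dup_rows)

  # --- organelle genomes and insertions --------------------------------
  set.seed(sub_seed(spec$seed, "organelle"))
  organelles <- purrr::map(spec$organelle_sizes, ~ random_dna(.x, spec$gc))
  names(organelles) <- names(spec$organelle_sizes)
  n_ins <- spec$n_organelle_insertions
  ins_src <- sample(names(organelles), n_ins, replace = TRUE,
                    prob = c(0.6, 0.4)[seq_along(organelles)])
  ins_len <- round(runif(n_ins, spec$organelle_insert_len[1],
                         spec$organelle_insert_len[2]))
  ins_rows <- list()
  for (i in seq_len(n_ins)) {
    src <- organelles[[ins_src[i]]]
    s0 <- sample.int(nchar(src) - ins_len[i], 1)
    frag <- substr(src, s0, s0 + ins_len[i] - 1L)
    div <- runif(1, spec$organelle_insert_div[1], spec$organelle_insert_div[2])
    frag <- as.character(mutate_seqs_cpp(frag, div / 100))
    pl <- place_sizes(ins_len[i], free, "organelle insertion")
    free <- pl$free
    seqs <- splice_into(seqs, pl$placements, frag)
    ins_rows[[i]] <- dplyr::mutate(
      pl$placements, type = "organelle",
      family = ifelse(ins_src[i] == "mito", "mito", "plastid"),
      identity = 100 - div
    )
  }
  truth$organelle <- dplyr::bind_rows(ins_rows)
  organelle_hits <- truth$organelle |>
    dplyr::transmute(organelle = .data$family, chrom = .data$chrom,
                     start = .data$start, end = .data$end, evalue = 1e-10)

  # --- interspersed repeat families ------------------------------------
  set.seed(sub_seed(spec$seed, "repeats"))
  fam_div <- spec$repeat_div_means
  nf <- length(fam_div)
  fam_len <- round(runif(nf, spec$repeat_consensus_len[1],
                         spec$repeat_consensus_len[2]))
  target_bp <- spec$repeat_frac * sum(sizes)
  fam_copies <- pmax(3, round((target_bp / nf) / fam_len))
  for (f in seq_len(nf)) {
    consensus <- random_dna(fam_len[f], spec$gc)
    n_sub <- max(1, fam_copies[f] %/% 5)
    sub_of <- sample.int(n_sub, fam_copies[f], replace = TRUE)
    sub_var <- as.character(mutate_seqs_cpp(
      rep(consensus, n_sub),
      pmax(0.002, rnorm(n_sub, fam_div[f], 2)) / 100))
    copies <- as.character(mutate_seqs_cpp(
      sub_var[sub_of], spec$repeat_within_div / 200))
    div_obs <- vapply(copies, hamming_pct, 0, b = consensus,
                      USE.NAMES = FALSE)
    pl <- place_sizes(rep(fam_len[f], fam_copies[f]), free,
                      sprintf("repeat family %d", f))
    free <- pl$free
    seqs <- splice_into(seqs, pl$placements, copies)
    repeats[[length(repeats) + 1]] <- dplyr::mutate(
      pl$placements, kind = "interspersed",
      family = sprintf("fam%02d", f), divergence = div_obs
    )
  }

  # --- tandem repeats --------------------------------------------------
  set.seed(sub_seed(spec$seed, "tandem"))
  if (spec$n_tandem > 0) {
    t_len <- round(runif(spec$n_tandem, spec$tandem_len[1], spec$tandem_len[2]))
    t_per <- round(runif(spec$n_tandem, spec$tandem_period[1],
                         spec$tandem_period[2]))
    pieces <- character(spec$n_tandem)
    for (i in seq_len(spec$n_tandem)) {
      unit <- random_dna(t_per[i], spec$gc)
      pieces[i] <- substr(strrep(unit, ceiling(t_len[i] / t_per[i])), 1, t_len[i])
    }
    pl <- place_sizes(t_len, free, "tandem repeat")
    free <- pl$free
    seqs <- splice_into(seqs, pl$placements, pieces)
    repeats[[length(repeats) + 1]] <- dplyr::mutate(
      pl$placements, kind = "tandem", family = "tandem",
      divergence = NA_real_
    )
  }
  repeats <- dplyr::bind_rows(repeats)

  # --- genes (may overlap other features, never gaps) ------------------
  set.seed(sub_seed(spec$seed, "genes"))
  gene_free <- interval_complement(gaps, sizes)
  g_len <- pmin(pmax(round(rlnorm(spec$n_genes, spec$gene_len_meanlog,
                                  spec$gene_len_sdlog)),
                     spec$gene_len_range[1]), spec$gene_len_range[2])
  pl <- place_sizes(g_len, gene_free, "gene")
  genes <- dplyr::mutate(pl$placements,
                         id = sprintf("gene%04d", dplyr::row_number())) |>
    dplyr::select("id", "chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)

  truth_tbl <- dplyr::bind_rows(
    dplyr::mutate(truth$dups[, c("type", "chrom", "start", "end", "family",
                                 "copy_number", "identity")]),
    dplyr::mutate(truth$organelle[, c("type", "chrom", "start", "end",
                                      "family", "identity")]),
    dplyr::mutate(truth$gaps[, c("type", "chrom", "start", "end")])
  )

  structure(
    list(sequences = purrr::map_chr(seqs, identity),
         repeats = repeats, genes = genes,
         organelles = purrr::map_chr(organelles, identity),
         organelle_hits = organelle_hits,
         calibration_regions = cal,
         truth = truth_tbl, spec = spec),
    class = "synth_genome"
  )
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf(
    "<synth_genome> %d sequence(s), %s bp; %d duplications, %d repeat annotations, %d genes\n",
    length(x$sequences), format(sum(nchar(x$sequences)), big.mark = ","),
    sum(x$truth$type == "duplication"), nrow(x$repeats), nrow(x$genes)
  ))
  invisible(x)
}

#' Simulate whole-genome shotgun reads
#'
#' Uniform read starts over non-gap sequence, truncated-normal lengths,
#' independent substitution errors, both strands, and a QC sidecar in which
#' a configurable fraction of reads is marked to fail quality clipping
#' (excess per-trace error, short high-quality portion, or a
#' low-quality/contamination flag).
#'
#' @param x A `synth_genome` or a named character vector of sequences.
#' @param coverage Fold sequence coverage (default 12).
#' @param len_mean,len_sd,len_min,len_max Read length distribution (bp);
#'   defaults 735, 150, 300, 1447.
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param qc_fail_rate Fraction of reads emitted with failing QC metadata
#'   (default 0.0126).
#' @param seed RNG seed.
#' @return List with `reads` (tibble `id`, `sequence`), `qc` (sidecar
#'   tibble) and `origin` (truth tibble `id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
simulate_reads <- function(x, coverage = 12, len_mean = 735, len_sd = 150,
                           len_min = 300, len_max = 1447,
                           error_rate = 0.005, qc_fail_rate = 0.0126,
                           seed = 1L) {
  if (inherits(x, "synth_genome")) x <- x$sequences
  stopifnot(is.character(x), !is.null(names(x)), coverage > 0)
  set.seed(sub_seed(seed, "reads"))
  sizes <- nchar(x)
  n <- round(coverage * sum(sizes) / len_mean)

  draw_len <- function(k) {
    out <- rnorm(k, len_mean, len_sd)
    bad <- out < len_min | out > len_max
    while (any(bad)) {
      out[bad] <- rnorm(sum(bad), len_mean, len_sd)
      bad <- out < len_min | out > len_max
    }
    round(out)
  }

  chroms <- character(0); starts <- integer(0); lens <- integer(0)
  while (length(chroms) < n) {
    k <- ceiling((n - length(chroms)) * 1.15)
    ch <- sample(names(x), k, replace = TRUE, prob = sizes)
    ln <- draw_len(k)
    ok <- ln <= sizes[ch]
    ch <- ch[ok]; ln <- ln[ok]
    st <- floor(runif(length(ch)) * (sizes[ch] - ln)) # 0-based
    frag <- substr(x[ch], st + 1L, st + ln)
    clean <- !grepl("N", frag, fixed = TRUE)
    chroms <- c(chroms, ch[clean])
    starts <- c(starts, as.integer(st[clean]))
    lens <- c(lens, as.integer(ln[clean]))
  }
  chroms <- chroms[seq_len(n)]; starts <- starts[seq_len(n)]
  lens <- lens[seq_len(n)]
  frags <- substr(x[chroms], starts + 1L, starts + lens)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  minus <- strand == "-"
  if (any(minus)) {
    frags[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(frags[minus])))
  }
  set.seed(sub_seed(seed, "errors"))
  if (error_rate > 0) {
    frags <- as.character(mutate_seqs_cpp(frags, error_rate))
  }
  ids <- sprintf("read%07d", seq_len(n))

  set.seed(sub_seed(seed, "qc"))
  fail <- runif(n) < qc_fail_rate
  mode <- sample(1:3, n, replace = TRUE)
  qc <- tibble::tibble(
    id = ids,
    percent_error = round(runif(n, 0, 3), 2),
    hq_start = 0L, hq_end = lens, flagged = FALSE
  )
  f1 <- fail & mode == 1
  qc$percent_error[f1] <- round(runif(sum(f1), 6.5, 12), 2)
  f2 <- fail & mode == 2
  qc$hq_end[f2] <- pmin(qc$hq_end[f2], sample(50:299, sum(f2), replace = TRUE))
  f3 <- fail & mode == 3
  qc$flagged[f3] <- TRUE

  list(
    reads = tibble::tibble(id = ids, sequence = unname(frags)),
    qc = qc,
    origin = tibble::tibble(id = ids, chrom = unname(chroms),
                            start = starts, end = starts + lens,
                            strand = strand)
  )
}

#' Write a synthetic genome to disk
#'
#' Emits the assembly FASTA, organelle FASTA, a RepeatMasker-style `.out`
#' table, gene GFF3, calibration-region BED, organelle-hit TSV and the truth
#' table TSV.
#'
#' @param sg A `synth_genome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_genome <- function(sg, dir) {
  stopifnot(inherits(sg, "synth_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sg$sequences),
                              file.path(dir, "genome.fa"), width = 60L)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sg$organelles),
                              file.path(dir, "organelles.fa"), width = 60L)
  write_repeatmasker_out(sg$repeats, file.path(dir, "repeats.out"))
  write_genes_gff3(sg$genes, file.path(dir, "genes.gff3"))
  write_bed(sg$calibration_regions, file.path(dir, "calibration.bed"))
  readr::write_tsv(sg$organelle_hits, file.path(dir, "organelle_hits.tsv"),
                   progress = FALSE)
  readr::write_tsv(sg$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Write repeat annotations as a RepeatMasker-style .out table
#'
#' @param repeats Repeat annotation tibble.
#' @param path Output path.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query              matching       repeat              position in repeat",
    "score   div. del. ins.  sequence  begin end          (left)     repeat         class/family      begin  end    (left)   ID",
    ""
  )
  lines <- sprintf(
    "  225 %6.1f  0.0  0.0  %s %10d %10d (0) + %-14s %-17s 1 %6d (0) %d",
    ifelse(is.na(repeats$divergence), 0, repeats$divergence),
    repeats$chrom, repeats$start + 1L, repeats$end,
    repeats$family,
    ifelse(repeats$kind == "tandem", "Simple_repeat", "Unknown"),
    repeats$end - repeats$start, seq_len(nrow(repeats))
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}

write_genes_gff3 <- function(genes, path) {
  lines <- sprintf("%s\twssdr\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                   genes$chrom, genes$start + 1L, genes$end, genes$id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
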