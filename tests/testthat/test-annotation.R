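iv100 <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                        n_windows5 = 1L, mean_coverage = 150)

test_that("genes are classified full, partial or unique against the SD union", {
  genes <- tibble::tibble(
    id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(10L, 90L, 300L), end = c(20L, 150L, 400L)
  )
  out <- classify_genes(genes, iv100)
  expect_equal(out$duplication_status, c("full", "partial", "unique"))
  # partition: statuses cover all genes exactly once
  expect_equal(sum(table(out$duplication_status)), nrow(genes))

  # a gene spanning two abutting (hence merged) intervals is full
  iv2 <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                        end = c(100L, 200L), n_windows5 = 1L,
                        mean_coverage = 1)
  g <- tibble::tibble(id = "g", chrom = "chr1", start = 50L, end = 150L)
  expect_equal(classify_genes(g, iv2)$duplication_status, "full")
})

test_that("gene density is genes per 100 kb over the relevant denominator", {
  seqs <- c(chr1 = strrep("A", 100000))
  mg <- apply_masking(seqs, no_repeats(), "nodiv_N")
  genes <- tibble::tibble(id = paste0("g", 1:5), chrom = "chr1",
                          start = seq(0L, 80000L, by = 20000L),
                          end = seq(1000L, 81000L, by = 20000L))
  iv <- tibble::tibble(chrom = "chr1", start = 0L, end = 50000L,
                       n_windows5 = 1L, mean_coverage = 1)
  tb <- gene_density_table(classify_genes(genes, iv), iv, mg)
  row <- tb[tb$chr == "chr1", ]
  expect_equal(row$total_genes, 5L)
  expect_equal(row$chr_gene_density, 5.00)
  expect_equal(row$full_dup_genes, 3L)  # genes at 0, 20k, 40k end <= 50k
  expect_equal(row$full_dup_gene_density, round(1e5 * 3 / 50000, 2))
  expect_equal(row$ratio_of_densities, round(6 / 5, 2))
})

test_that("enrichment factors compare fractional domain abundances", {
  cd <- tibble::tibble(interpro_id = c("IPR1", "IPR2"), n = c(2L, 2L))
  cu <- tibble::tibble(interpro_id = c("IPR1", "IPR2"), n = c(1L, 1L))
  ef <- enrichment_factor(cd, cu)
  expect_equal(ef$ef, c(1, 1))

  cd2 <- tibble::tibble(interpro_id = c("IPR1", "rest"), n = c(10L, 90L))
  cu2 <- tibble::tibble(interpro_id = c("IPR1", "rest"), n = c(4L, 196L))
  ef2 <- enrichment_factor(cd2, cu2)
  expect_equal(ef2$ef[ef2$interpro_id == "IPR1"], (10 / 100) / (4 / 200))

  # dup-only domains get no numeric EF
  cd3 <- tibble::tibble(interpro_id = c("IPRX", "IPR1"), n = c(5L, 5L))
  ef3 <- enrichment_factor(cd3, cu)
  expect_true(ef3$dup_only[ef3$interpro_id == "IPRX"])
  expect_true(is.na(ef3$ef[ef3$interpro_id == "IPRX"]))

  # scale invariance: multiplying one class by a constant leaves EF unchanged
  cu4 <- dplyr::mutate(cu2, n = n * 7L)
  expect_equal(enrichment_factor(cd2, cu4)$ef, ef2$ef)

  expect_error(enrichment_factor(cd[0, ], cu), "empty")
})

test_that("domain retention keeps status T with a real InterPro accession", {
  a <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4"),
    source_db = "PFAM", signature = "S",
    status = c("T", "F", "T", "T"),
    interpro_id = c("IPR1", "IPR2", "NULL", NA)
  )
  expect_equal(filter_domains(a)$protein_id, "p1")
  counts <- domain_counts(filter_domains(a), duplicated_proteins = "p1")
  expect_equal(counts$dup$n, 1L)
  expect_equal(nrow(counts$unique), 0)
})

test_that("organelle DNA content counts union nucleotides per class", {
  seqs <- c(chr1 = strrep("A", 100000))
  mg <- apply_masking(seqs, no_repeats(), "nodiv_N")
  iv <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                       n_windows5 = 1L, mean_coverage = 1)
  hits <- tibble::tibble(
    organelle = c("mito", "mito", "plastid"),
    chrom = "chr1", start = c(0L, 50L, 80L), end = c(100L, 150L, 120L),
    evalue = c(1e-10, 1e-9, 1e-8)
  )
  tb <- numt_content(hits, iv, mg)
  row <- tb[tb$chr == "chr1", ]
  expect_equal(row$numt_bp, 150L)      # union of [0,100) and [50,150)
  expect_equal(row$numt_sd_bp, 50L)    # [100,150) inside SD [100,200)
  expect_equal(row$nupt_sd_bp, 20L)    # [100,120)
  expect_equal(row$numt_pct, round(100 * 150 / 100000, 2))
  expect_equal(row$numt_sd_pct, round(100 * 50 / 100, 2))

  # e-value filter removes weak hits; no hits give zeros
  weak <- dplyr::mutate(hits, evalue = 1)
  tb0 <- numt_content(weak, iv, mg)
  expect_equal(tb0$numt_bp[tb0$chr == "chr1"], 0)
})

test_that("organelle content equals per-base marking on random fixtures", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(20000:100000, 1)
    k <- sample(1:15, 1)
    s <- sample(0:(n - 500), k, replace = TRUE)
    hits <- tibble::tibble(organelle = "mito", chrom = "chr1", start = s,
                           end = pmin(s + sample(50:400, k, TRUE), n),
                           evalue = 1e-9)
    mg <- apply_masking(c(chr1 = strrep("A", n)), no_repeats(), "nodiv_N")
    tb <- numt_content(hits, iv100[0, ], mg)
    expect_equal(tb$numt_bp[tb$chr == "chr1"], oracle_union_bp(hits, n))
  }
})

test_that("per-chromosome organelle bp sums to the whole-genome total", {
  seqs <- c(chr1 = strrep("A", 50000), chr2 = strrep("A", 30000),
            chrUn = strrep("A", 10000))
  mg <- apply_masking(seqs, no_repeats(), "nodiv_N")
  hits <- tibble::tibble(
    organelle = "mito", chrom = c("chr1", "chr2", "chrUn"),
    start = c(0L, 100L, 5L), end = c(400L, 300L, 100L), evalue = 1e-9
  )
  tb <- numt_content(hits, iv100[0, ], mg)
  expect_equal(tb$numt_bp[tb$chr == "Tot_whole"],
               sum(tb$numt_bp[!grepl("^Tot", tb$chr)]))
})

test_that("top duplicated genes rank by containing-interval coverage", {
  iv <- tibble::tibble(chrom = "chr1",
                       start = c(0L, 1000L, 2000L),
                       end = c(500L, 1500L, 2500L),
                       n_windows5 = 1L, mean_coverage = c(300, 200, 100))
  genes <- tibble::tibble(
    id = c("gA", "gB", "gC", "gD"), chrom = "chr1",
    start = c(2100L, 1100L, 100L, 120L), end = c(2200L, 1200L, 200L, 220L)
  )
  genes <- classify_genes(genes, iv)
  top <- top_duplicated_genes(genes, iv, n = 2)
  expect_equal(top$id, c("gC", "gD"))  # both in the 300x interval, tie by start
  expect_equal(top$mean_coverage, c(300, 300))

  expect_warning(all4 <- top_duplicated_genes(genes, iv, n = 10),
                 "only 4")
  expect_equal(all4$id, c("gC", "gD", "gB", "gA"))

  # organelle flags and domains attach by id
  top2 <- suppressWarnings(top_duplicated_genes(
    genes, iv, n = 4,
    organelle_gene_hits = tibble::tibble(gene_id = "gB", organelle = "mito"),
    domains = tibble::tibble(protein_id = "gC", interpro_id = "IPR9")
  ))
  expect_equal(top2$organelle_homolog[top2$id == "gB"], "mito")
  expect_equal(top2$interpro_ids[top2$id == "gC"], "IPR9")
})

test_that("interval composition reports GC and repeat bp inside calls", {
  seqs <- c(chr1 = paste0(strrep("GC", 250), strrep("AT", 250)))
  reps <- one_repeat(start = 400L, end = 600L, divergence = 1)
  mg <- apply_masking(seqs, reps, "nodiv_low")
  iv <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L,
                       n_windows5 = 1L, mean_coverage = 1)
  comp <- interval_composition(iv, mg)
  expect_equal(comp$gc$gc_pct[comp$gc$region == "duplicated"], 100)
  expect_equal(comp$gc$gc_pct[comp$gc$region == "genome"], 50)
  # interval covers half of the repeat
  expect_equal(comp$repeats$bp_in_sd, 100L)
  expect_equal(comp$repeats$bp_genome, 200L)
})

test_that("GFF3 genes import as 0-based half-open intervals", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA"), path)
  g <- read_genes_gff3(path)
  expect_equal(g$id, "geneA")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
})
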