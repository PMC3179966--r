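test_that("read clipping applies the three QC rules and truncates survivors", {
  reads <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    sequence = c(strrep("A", 800), strrep("C", 800), strrep("G", 800),
                 strrep("T", 800))
  )
  qc <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    percent_error = c(7.0, 2.0, 1.0, 1.0),
    hq_start = c(0L, 0L, 100L, 0L),
    hq_end = c(800L, 735L, 450L, 800L),
    flagged = c(FALSE, FALSE, FALSE, TRUE)
  )
  out <- clip_reads(reads, qc)
  expect_equal(out$reads$id, c("b", "c"))
  expect_equal(nchar(out$reads$sequence), c(735, 350))
  expect_equal(out$counts$flagged, 1)
  expect_equal(out$counts$percent_error, 1)
  expect_equal(out$counts$retained, 2)

  # hq length below 300 discarded
  qc2 <- tibble::tibble(id = "a", percent_error = 1, hq_start = 0L,
                        hq_end = 250L)
  expect_equal(clip_reads(reads[1, ], qc2)$counts$short_hq, 1)

  # reads lacking QC metadata pass at full length
  out3 <- clip_reads(reads[2, ])
  expect_equal(nchar(out3$reads$sequence), 800)
})

test_that("the naive mapper finds unique, duplicated and reverse matches", {
  set.seed(11)
  g <- random_seq(6000)
  mg <- toy_genome(g, setting = "nodiv_N")

  # verbatim read from a unique locus: exactly one perfect match
  r1 <- tibble::tibble(id = "u", sequence = substr(g, 1001, 1735))
  m1 <- map_reads(r1, mg)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$start, 1000L)
  expect_equal(m1$end, 1735L)
  expect_equal(m1$identity, 100)

  # two-copy segment at 99% identity: two matches
  seg <- substr(g, 2001, 2800)
  set.seed(12)
  g2 <- paste0(g, random_seq(200),
               as.character(wssdr:::mutate_seqs_cpp(seg, 0.01)))
  mg2 <- toy_genome(g2, setting = "nodiv_N")
  m2 <- map_reads(tibble::tibble(id = "d", sequence = substr(g, 2101, 2600)),
                  mg2)
  expect_equal(nrow(m2), 2)
  expect_true(all(m2$identity >= 93))

  # 10% substitution noise pushes identity below the 93% cutoff: no matches
  set.seed(13)
  noisy <- as.character(wssdr:::mutate_seqs_cpp(substr(g, 1001, 1735), 0.10))
  expect_equal(nrow(map_reads(tibble::tibble(id = "n", sequence = noisy), mg)),
               0)

  # reverse-complement read maps on the minus strand, forward coordinates
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(g, 1001, 1735))))
  m4 <- map_reads(tibble::tibble(id = "r", sequence = rc), mg)
  expect_equal(m4$strand, "-")
  expect_equal(m4$start, 1000L)

  # reads shorter than the seed yield no matches
  expect_equal(nrow(map_reads(tibble::tibble(id = "s", sequence = "ACGTACGT"),
                              mg)), 0)
})

test_that("N masking truncates matches while lowercase extends through", {
  set.seed(21)
  g <- random_seq(3000)
  rep_mid <- one_repeat(start = 1400L, end = 1480L, divergence = 1)
  read <- tibble::tibble(id = "x", sequence = substr(g, 1001, 1900))

  mN <- map_reads(read, toy_genome(g, rep_mid, "nodiv_N"))
  expect_true(all(mN$end <= 1400 | mN$start >= 1480))
  expect_true(all(mN$masked_overlap == 0))

  mL <- map_reads(read, toy_genome(g, rep_mid, "nodiv_low"))
  expect_equal(nrow(mL), 1)
  expect_equal(mL$start, 1000L)
  expect_equal(mL$end, 1900L)
  expect_equal(mL$masked_overlap, 80L)
})

test_that("match filtering enforces length and masked-overlap rules", {
  mg_low <- toy_genome(strrep("A", 1000),
                       one_repeat(start = 0L, end = 500L, divergence = 1),
                       "nodiv_low")
  mk <- function(len, mo) tibble::tibble(
    read_id = "r", chrom = "chr1", start = 0L, end = len, length = len,
    strand = "+", identity = 99, mismatches = 0L, masked_overlap = mo
  )
  # length exactly 300 removed ("larger than 300 bp")
  expect_equal(nrow(filter_matches(mk(300L, 0L), mg_low)$matches), 0)
  expect_equal(nrow(filter_matches(mk(301L, 0L), mg_low)$matches), 1)
  # masked overlap of 250 removed under lowercase policy
  expect_equal(nrow(filter_matches(mk(400L, 250L), mg_low)$matches), 0)
  # same match kept under the N policy (filter inapplicable)
  mg_N <- toy_genome(strrep("A", 1000),
                     one_repeat(start = 0L, end = 500L, divergence = 1),
                     "nodiv_N")
  expect_equal(nrow(filter_matches(mk(400L, 250L), mg_N)$matches), 1)

  # idempotence
  once <- filter_matches(dplyr::bind_rows(mk(300L, 0L), mk(400L, 10L),
                                          mk(500L, 250L)), mg_low)
  twice <- filter_matches(once$matches, mg_low)
  expect_equal(twice$matches, once$matches)
  expect_equal(twice$counts$retained, once$counts$retained)
})

test_that("depth counting assigns each match to its midpoint window once", {
  mg <- toy_genome(strrep("A", 5000))
  w1 <- kub_windows(mg, unit = 1000)
  mt <- function(s, e) tibble::tibble(read_id = "r", chrom = "chr1",
                                      start = s, end = e)
  # midpoint of [2500, 3100) is 2799 -> window 3
  w <- count_depth(w1, mt(2500L, 3100L))
  expect_equal(w$depth1, c(0, 0, 1, 0, 0))
  # match spanning two windows is counted once, in the midpoint window
  w2 <- count_depth(w1, mt(900L, 1500L))  # midpoint 1199 -> window 2
  expect_equal(w2$depth1, c(0, 1, 0, 0, 0))
  # even-length match takes the left-of-centre base
  w3 <- count_depth(w1, mt(0L, 2000L))  # midpoint 999 -> window 1
  expect_equal(w3$depth1, c(1, 0, 0, 0, 0))
  # unknown chromosome: warning, dropped
  expect_warning(
    w4 <- count_depth(w1, tibble::tibble(read_id = "r", chrom = "chrX",
                                         start = 0L, end = 400L)),
    "without windows")
  expect_equal(sum(w4$depth1), 0)
})

test_that("total counted depth never exceeds the number of matches", {
  set.seed(5)
  mg <- toy_genome(strrep("A", 4000))
  w1 <- kub_windows(mg, unit = 1000)
  s <- sample(0:3500, 100, replace = TRUE)
  matches <- tibble::tibble(read_id = "r", chrom = "chr1", start = s,
                            end = s + sample(300:500, 100, TRUE))
  w <- count_depth(w1, matches)
  expect_lte(sum(w$depth1), nrow(matches))
  # midpoints inside [0, 4000) are all counted
  mid <- matches$start + (matches$end - matches$start - 1) %/% 2
  expect_equal(sum(w$depth1), sum(mid < 4000))
})

test_that("BLAST tabular input is normalised to forward half-open intervals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\tchr1\t99.5\t400\t2\t0\t1\t400\t101\t500\t1e-50\t700",
    "r2\tchr1\t98.0\t350\t7\t0\t1\t350\t900\t551\t1e-40\t600"
  ), path)
  b <- read_blast_tabular(path)
  expect_equal(b$start, c(100L, 550L))
  expect_equal(b$end, c(500L, 900L))
  expect_equal(b$strand, c("+", "-"))
  expect_equal(b$identity, c(99.5, 98.0))
})
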