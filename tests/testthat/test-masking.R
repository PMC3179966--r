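test_that("assembly gaps are maximal N runs of at least min_gap_run", {
  expect_equal(nrow(detect_assembly_gaps(c(chr1 = "ACGT"))), 0)

  s <- c(chr1 = paste0("AC", strrep("N", 50), "GT"))
  g <- detect_assembly_gaps(s, min_gap_run = 10)
  expect_equal(g$start, 2)
  expect_equal(g$end, 52)

  s2 <- c(chr1 = paste0("A", strrep("N", 5), "A", strrep("N", 10), "A",
                        strrep("N", 100), "A"))
  g2 <- detect_assembly_gaps(s2, min_gap_run = 10)
  expect_equal(nrow(g2), 2)
  expect_equal(g2$end - g2$start, c(10, 100))

  expect_equal(nrow(detect_assembly_gaps(c(chr1 = ""))), 0)
})

test_that("the three masking settings select and mark repeats as specified", {
  seqs <- c(chr1 = strrep("ACGT", 25))
  rep12 <- one_repeat(divergence = 12)

  m1 <- apply_masking(seqs, rep12, "div10_low")
  expect_equal(nrow(m1$mask), 0)
  expect_equal(m1$mask_char_policy, "lowercase")

  m2 <- apply_masking(seqs, rep12, "nodiv_low")
  expect_equal(m2$mask, tibble::tibble(chrom = "chr1", start = 2L, end = 6L))
  expect_equal(substr(masked_sequences(m2)[[1]], 1, 8), "ACgtacGT")

  m3 <- apply_masking(seqs, rep12, "nodiv_N")
  expect_equal(m3$mask, m2$mask)
  expect_equal(substr(masked_sequences(m3)[[1]], 1, 8), "ACNNNNGT")

  expect_error(apply_masking(seqs, rep12, "div5"), "unknown masking setting")
})

test_that("divergence exactly 10 is not masked under div10_low; tandem always is", {
  seqs <- c(chr1 = strrep("ACGT", 25))
  r <- dplyr::bind_rows(
    one_repeat(start = 0L, end = 4L, divergence = 10),
    one_repeat(start = 10L, end = 14L, divergence = 9.99),
    one_repeat(start = 20L, end = 24L, kind = "tandem", divergence = NA)
  )
  m <- apply_masking(seqs, r, "div10_low")
  expect_equal(m$mask$start, c(10L, 20L))
})

test_that("repeats overlapping assembly gaps are clipped to the non-gap part", {
  seqs <- c(chr1 = paste0(strrep("A", 10), strrep("N", 20), strrep("G", 10)))
  r <- one_repeat(start = 5L, end = 35L, divergence = 1)
  m <- apply_masking(seqs, r, "nodiv_N")
  expect_equal(m$gaps, tibble::tibble(chrom = "chr1", start = 10, end = 30))
  expect_equal(m$mask,
               tibble::tibble(chrom = "chr1", start = c(5L, 30L),
                              end = c(10L, 35L)))
})

test_that("masked_fraction counts overlapping masks once and excludes gaps", {
  seqs <- c(chr1 = strrep("A", 100))
  m <- toy_genome(strrep("A", 100),
                  one_repeat(start = 0L, end = 25L, divergence = 1))
  expect_equal(masked_fraction(m), 25)

  m2 <- toy_genome(strrep("A", 100), dplyr::bind_rows(
    one_repeat(start = 0L, end = 20L, divergence = 1),
    one_repeat(start = 10L, end = 30L, divergence = 1)
  ))
  expect_equal(masked_fraction(m2), 30)

  expect_equal(masked_fraction(toy_genome(strrep("A", 100))), 0)

  all_gap <- apply_masking(c(chr1 = strrep("N", 50)), no_repeats(), "nodiv_N")
  expect_error(masked_fraction(all_gap), "only of gaps")
})

test_that("div10_low mask is contained in the nodiv mask; policies share tracks", {
  set.seed(421)
  for (i in 1:10) {
    n <- 5000
    starts <- sort(sample(0:(n - 60), 15))
    reps <- tibble::tibble(
      chrom = "chr1", start = starts, end = starts + sample(20:50, 15, TRUE),
      kind = sample(c("interspersed", "tandem"), 15, TRUE),
      family = "r", divergence = runif(15, 0, 25)
    )
    seqs <- c(chr1 = random_seq(n))
    d10 <- apply_masking(seqs, reps, "div10_low")
    nlo <- apply_masking(seqs, reps, "nodiv_low")
    nN <- apply_masking(seqs, reps, "nodiv_N")
    expect_equal(nlo$mask, nN$mask)
    # containment: intersection of div10 mask with nodiv mask is div10 mask
    expect_equal(interval_intersect(d10$mask, nlo$mask), d10$mask)
  }
})

test_that("masked_fraction agrees with per-base brute force on random fixtures", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(2000:10000, 1)
    k <- sample(3:20, 1)
    starts <- sample(0:(n - 200), k)
    reps <- tibble::tibble(chrom = "chr1", start = starts,
                           end = pmin(starts + sample(10:150, k, TRUE), n),
                           kind = "interspersed", family = "r",
                           divergence = runif(k, 0, 9))
    seq <- random_seq(n)
    # implant an N gap
    substr(seq, 501, 600) <- strrep("N", 100)
    mg <- apply_masking(c(chr1 = seq), reps, "nodiv_low")
    expect_equal(masked_fraction(mg),
                 oracle_masked_fraction(n, mg$mask, mg$gaps))
  }
})

test_that("RepeatMasker .out tables round-trip through writer and reader", {
  reps <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), start = c(0L, 500L, 10L),
    end = c(120L, 900L, 400L), kind = c("interspersed", "tandem",
                                        "interspersed"),
    family = c("famA", "tandem", "famB"), divergence = c(8.5, NA, 19.2)
  )
  path <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(reps, path)
  back <- read_repeatmasker_out(path)
  expect_equal(back$chrom, reps$chrom)
  expect_equal(back$start, reps$start)
  expect_equal(back$end, reps$end)
  expect_equal(back$kind, reps$kind)
  expect_equal(back$divergence, c(8.5, 0, 19.2))
})
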