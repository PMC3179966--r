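th <- list(borderline_cut = 95.2, positive_cut = 103.2)  # avg 79.2, sd 8

test_that("window classification follows the boundary conventions", {
  w5 <- labelled_w5(rep("unset", 4),
                    depth = c(79.2, 79.2 + 2.5 * 8, 103.2, 95.2))
  lab <- classify_windows(w5, th)$label
  # depth exactly at avg + 2 sd is negative ("less than or equal to two sd")
  expect_equal(lab, c("negative", "borderline", "positive", "negative"))

  # strict convention: boundary depth becomes borderline
  lab2 <- classify_windows(w5, th, positive_inclusive = FALSE)$label
  expect_equal(lab2[3], "borderline")

  expect_error(classify_windows(w5, list(borderline_cut = NULL)),
               "thresholds")
})

test_that("the six-of-seven rule calls and merges intervals as specified", {
  # seven positives: one interval covering all spans
  iv1 <- call_duplications(labelled_w5(rep("positive", 7)))
  expect_equal(nrow(iv1), 1)
  expect_equal(iv1$start, 0L)
  expect_equal(iv1$end, 11000L)
  expect_equal(iv1$n_windows5, 7L)
  expect_equal(iv1$mean_coverage, 200)

  # one negative among seven still qualifies (6/7)
  labs <- c("positive", "positive", "positive", "negative", "positive",
            "positive", "positive")
  iv2 <- call_duplications(labelled_w5(labs))
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$n_windows5, 7L)

  # two negatives do not (max 5/7)
  labs3 <- c("positive", "positive", "negative", "negative", "positive",
             "positive", "positive")
  expect_equal(nrow(call_duplications(labelled_w5(labs3))), 0)

  # borderline windows count as non-positive but do not split intervals
  labs4 <- c(rep("positive", 6), "borderline", rep("positive", 6))
  iv4 <- call_duplications(labelled_w5(labs4))
  expect_equal(nrow(iv4), 1)

  expect_error(call_duplications(labelled_w5(rep("unset", 7))), "classified")
})

test_that("interval calling agrees with window-of-seven enumeration", {
  set.seed(271)
  for (i in 1:200) {
    L <- sample(1:200, 1)
    labels <- sample(c("positive", "negative", "borderline"), L, TRUE,
                     prob = c(0.4, 0.5, 0.1))
    w5 <- labelled_w5(labels)
    got <- call_duplications(w5)
    marked <- oracle_mark(labels)
    want <- oracle_intervals(w5$start, w5$end, marked)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$end, as.integer(want$end))
    }
  }
})

test_that("calling is monotone in labels and in the positive threshold", {
  set.seed(99)
  for (i in 1:20) {
    L <- 60
    labels <- sample(c("positive", "negative"), L, TRUE, prob = c(0.45, 0.55))
    base_iv <- call_duplications(labelled_w5(labels))
    # adding one positive never removes called bases
    j <- sample(which(labels == "negative"), 1)
    labels2 <- labels
    labels2[j] <- "positive"
    more_iv <- call_duplications(labelled_w5(labels2))
    expect_gte(sum(more_iv$end - more_iv$start),
               sum(base_iv$end - base_iv$start))
  }

  # raising the positive cut never increases duplicated bp
  set.seed(100)
  depths <- c(rnorm(30, 80, 8), rnorm(30, 160, 11), rnorm(30, 80, 8))
  w5 <- labelled_w5(rep("unset", 90), depth = depths)
  lo <- call_duplications(classify_windows(w5, list(borderline_cut = 95,
                                                    positive_cut = 103)))
  hi <- call_duplications(classify_windows(w5, list(borderline_cut = 95,
                                                    positive_cut = 130)))
  expect_lte(sum(hi$end - hi$start), sum(lo$end - lo$start))
})

test_that("genome summary stratifies chromosomes and totals correctly", {
  seqs <- c(chr1 = strrep("A", 100000), chr2 = strrep("A", 50000),
            chr1_random = strrep("A", 20000), chrUn = strrep("A", 30000))
  mg <- apply_masking(seqs, no_repeats(), "nodiv_N")
  iv <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1_random", "chrUn"),
    start = c(0L, 20000L, 0L, 1000L),
    end = c(20000L, 30000L, 5000L, 4000L),
    n_windows5 = 1L, mean_coverage = 150
  )
  tb <- summarize_genome(iv, mg)
  expect_equal(tb$perc_dup[tb$chr == "chr1"], 30)
  expect_equal(tb$dup_size[tb$chr == "Tot_nonrandom"], 30000)
  expect_equal(tb$dup_size[tb$chr == "Tot_random"], 5000)
  expect_equal(tb$dup_size[tb$chr == "Tot_placed"], 35000)
  expect_equal(tb$dup_size[tb$chr == "Tot_whole"], 38000)
  expect_equal(tb$n_intervals[tb$chr == "Tot_whole"], 4)
  # whole-genome union equals the per-chromosome sum
  expect_equal(tb$dup_size[tb$chr == "Tot_whole"],
               sum(tb$dup_size[!grepl("^Tot", tb$chr)]))

  # abutting intervals are counted once in the union
  iv2 <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                        end = c(10000L, 20000L), n_windows5 = 1L,
                        mean_coverage = 1)
  expect_equal(summarize_genome(iv2, mg)$dup_size[1], 20000)

  expect_error(summarize_genome(
    tibble::tibble(chrom = "chrX", start = 0L, end = 10L), mg),
    "unknown chromosome")
})

test_that("window class distribution sums to 100 within each bin", {
  w5 <- labelled_w5(c(rep("negative", 75), rep("positive", 25)))
  d <- window_class_distribution(w5)
  expect_equal(d$positive[d$bin == "all"], 25)
  expect_equal(d$negative[d$bin == "all"], 75)
  expect_equal(rowSums(d[, c("negative", "borderline", "positive")]),
               rep(100, nrow(d)))

  all_neg <- window_class_distribution(labelled_w5(rep("negative", 10)))
  expect_equal(unlist(all_neg[1, c("negative", "borderline", "positive")],
                      use.names = FALSE), c(100, 0, 0))
})

test_that("interval size distribution reports mode and maximum", {
  iv <- tibble::tibble(chrom = "chr1", start = c(0L, 50000L, 200000L),
                       end = c(20000L, 70000L, 230000L))
  d <- interval_size_distribution(iv)
  expect_equal(d$mode_size, 22500)  # densest 5-kb bin is [20, 25) kb
  expect_equal(d$max_size, 30000)

  one <- interval_size_distribution(iv[1, ])
  expect_equal(one$max_size, 20000)
  expect_equal(one$mode_size, 22500)

  empty <- interval_size_distribution(iv[0, ])
  expect_true(is.na(empty$mode_size))
})

test_that("call evaluation scores coverage of truth and edge-tolerant precision", {
  calls <- tibble::tibble(chrom = "chr1", start = 8000L, end = 33000L)
  truth <- tibble::tibble(chrom = "chr1", start = 10000L, end = 30000L)
  ev <- evaluate_calls(calls, truth, c(chr1 = 100000L), boundary_tol = 5000)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)  # overhang within tolerance
  ev2 <- evaluate_calls(calls, truth, c(chr1 = 100000L), boundary_tol = 0)
  expect_equal(ev2$precision, 20000 / 25000)
})
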