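test_that("library aggregation sums extensive columns only", {
  t1 <- isoscope_example("pacbio_library_stats")
  agg <- aggregate_library_stats(t1)
  tot <- agg[agg$library == "total", ]
  expect_equal(tot$total_bases, sum(t1$total_bases))
  expect_equal(tot$rois, sum(t1$rois))
  expect_true(is.na(tot$mean_length))
  expect_true(is.na(tot$read_n50))
  # single library: totals equal that row
  one <- aggregate_library_stats(t1[1, ])
  expect_equal(one$total_bases[2], t1$total_bases[1])
  # random tables: sums equal independent summation
  set.seed(2)
  rnd <- tibble::tibble(library = letters[1:5],
                        total_bases = sample(1e6, 5), rois = sample(1e4, 5))
  agg2 <- aggregate_library_stats(rnd)
  expect_equal(agg2$total_bases[6], sum(rnd$total_bases))
  expect_error(aggregate_library_stats(rnd, sum_cols = "nope"), "nope")
})

test_that("category shares round half-up and sum to ~100", {
  kog <- isoscope_example("kog_categories")
  sh <- category_shares(kog)
  expect_equal(sh$share_pct[1], 18.90)      # 202 of 1069
  expect_lt(abs(sum(sh$share_pct) - 100), 0.05 * nrow(sh))
  expect_equal(category_shares(tibble::tibble(c = c("x", "y"),
                                              n = c(0, 10)))$share_pct,
               c(0, 100))
  expect_warning(z <- category_shares(tibble::tibble(c = "x", n = 0)),
                 "zero total")
  expect_equal(nrow(z), 0)
  # shares equal independent computation on a random 26-category table
  set.seed(6)
  rnd <- tibble::tibble(cat = paste0("c", 1:26), n = sample(500, 26))
  sh2 <- category_shares(rnd)
  expect_equal(sh2$share_pct, round_half_up(100 * rnd$n / sum(rnd$n), 2))
  expect_lt(abs(sum(sh2$share_pct) - 100), 0.05 * 26)
})

test_that("locus length bins follow the <1k/1-2k/2-3k/>3k layout", {
  loci <- tibble::tibble(span_length = c(500, 1500, 2500, 3500, 4000))
  b <- length_bin_shares(loci)
  expect_equal(b$bin, c("<1k", "1-2k", "2-3k", ">3k"))
  expect_equal(b$n, c(1L, 1L, 1L, 2L))
  single <- length_bin_shares(tibble::tibble(span_length = 500))
  expect_equal(single$share_pct, c(100, 0, 0, 0))
  # random lengths: counts equal an independent histogram
  set.seed(14)
  lens <- sample(100:6000, 300, replace = TRUE)
  b2 <- length_bin_shares(tibble::tibble(span_length = lens))
  expect_equal(b2$n, c(sum(lens < 1000), sum(lens >= 1000 & lens < 2000),
                       sum(lens >= 2000 & lens < 3000), sum(lens >= 3000)))
})

test_that("differential proportions cross-tabulate within status", {
  tbl <- tibble::tibble(status = c("known", "known", "known", "known"),
                        regulation = c("up", "up", "down", "ns"))
  p <- de_proportions(tbl)
  expect_equal(p$pct[p$status == "known" & p$regulation == "up"], 50)
  expect_error(de_proportions(tibble::tibble(status = "odd", regulation = "up")),
               "odd")
  expect_warning(e <- de_proportions(tbl[0, ]), "empty")
  expect_equal(nrow(e), 0)
  # random labels match an independent cross-tab
  set.seed(21)
  rnd <- tibble::tibble(status = sample(c("known", "novel"), 200, TRUE),
                        regulation = sample(c("up", "down", "ns"), 200, TRUE))
  p2 <- de_proportions(rnd)
  for (i in seq_len(nrow(p2))) {
    n_want <- sum(rnd$status == p2$status[i] & rnd$regulation == p2$regulation[i])
    expect_equal(p2$n[i], n_want)
  }
})

test_that("aggregations are invariant to row order", {
  t1 <- isoscope_example("pacbio_library_stats")
  set.seed(5)
  shuf <- t1[sample(nrow(t1)), ]
  a1 <- aggregate_library_stats(t1)
  a2 <- aggregate_library_stats(shuf)
  expect_equal(a1[a1$library == "total", -1], a2[a2$library == "total", -1])
  kog <- isoscope_example("kog_categories")
  s1 <- category_shares(kog)
  s2 <- category_shares(kog[sample(nrow(kog)), ])
  expect_equal(dplyr::arrange(s1, category), dplyr::arrange(s2, category))
})
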