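test_that("canonical skip and retention patterns are classified", {
  a <- blocks_of(0, 100, 200, 300, 400, 500)
  b <- blocks_of(0, 100, 400, 500)
  ev <- classify_pair(a, b, fuzz = 10)
  expect_equal(ev$type, "SKIP")
  expect_equal(c(ev$region_start, ev$region_end), c(200L, 300L))
  # symmetric call
  expect_equal(event_multiset(classify_pair(b, a, fuzz = 10)),
               event_multiset(ev))

  a2 <- blocks_of(0, 100, 200, 300)
  b2 <- blocks_of(0, 300)
  ev2 <- classify_pair(a2, b2, fuzz = 10)
  expect_equal(ev2$type, "IR")
  expect_equal(c(ev2$region_start, ev2$region_end), c(100L, 200L))

  # multi-exon skipping and multi-intron retention
  a3 <- blocks_of(0, 100, 200, 300, 400, 500, 600, 700, 800, 900)
  b3 <- blocks_of(0, 100, 800, 900)
  expect_equal(classify_pair(a3, b3)$type, "MSKIP")
  b4 <- blocks_of(0, 100, 200, 700, 800, 900)
  expect_equal(classify_pair(a3, b4)$type, "MIR")
})

test_that("approximate boundaries yield X-typed events within fuzz only", {
  a <- blocks_of(0, 100, 200, 300, 400, 500)
  b_shift <- blocks_of(0, 96, 400, 500)      # flanking donor off by 4 bp
  ev <- classify_pair(a, b_shift, fuzz = 10)
  expect_equal(ev$type, "XSKIP")
  # with fuzz = 0 no X-type is ever emitted
  ev0 <- classify_pair(a, b_shift, fuzz = 0)
  expect_false(any(grepl("^X", ev0$type)))
  # beyond fuzz the skip pattern is not matched at all
  b_far <- blocks_of(0, 80, 400, 500)
  expect_false(any(grepl("SKIP", classify_pair(a, b_far, fuzz = 10)$type)))

  # alternative exon end: intron pair sharing one splice site
  b_ae <- blocks_of(0, 124, 200, 300, 400, 500)
  ev_ae <- classify_pair(a, b_ae, fuzz = 10)
  expect_equal(ev_ae$type, "AE")
  b_xae <- blocks_of(0, 124, 203, 300, 400, 500)
  expect_equal(classify_pair(a, b_xae, fuzz = 10)$type, "XAE")
})

test_that("pair classification equals the interval-algebra oracle", {
  sim <- sim_wide()
  iso <- sim$truth$isoforms
  n_pairs <- 0
  for (g in unique(iso$gene_id)) {
    sub <- iso[iso$gene_id == g, ]
    if (nrow(sub) < 2) next
    for (i in 1:(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
      got <- classify_pair(sub$blocks[[i]], sub$blocks[[j]], fuzz = 10)
      want <- oracle_as_events(sub$blocks[[i]], sub$blocks[[j]], fuzz = 10)
      expect_equal(event_multiset(got), event_multiset(want),
                   label = paste(g, i, j))
      n_pairs <- n_pairs + 1
    }
  }
  # plus random structures, including unrelated ones
  set.seed(31)
  for (rep in 1:500) {
    ba <- random_blocks(sample(2:6, 1))
    bb <- if (runif(1) < 0.5) {
      random_blocks(sample(2:6, 1))
    } else {
      # perturbed copy of ba: drop an exon or jitter a boundary
      b <- ba
      if (nrow(b) >= 4 && runif(1) < 0.5) {
        b <- b[-sample(2:(nrow(b) - 1), 1), , drop = FALSE]
      } else {
        k <- sample(nrow(b), 1)
        b[k, sample(2, 1)] <- b[k, sample(2, 1)] + sample(-12:12, 1)
        if (b[k, 2] <= b[k, 1]) b[k, 2] <- b[k, 1] + 5
        b <- b[order(b[, 1]), , drop = FALSE]
        if (any(b[-1, 1] < b[-nrow(b), 2])) next
      }
      b
    }
    got <- classify_pair(ba, bb, fuzz = 10)
    want <- oracle_as_events(ba, bb, fuzz = 10)
    expect_equal(event_multiset(got), event_multiset(want),
                 label = sprintf("random pair %d", rep))
    expect_equal(event_multiset(classify_pair(bb, ba, fuzz = 10)),
                 event_multiset(got), label = sprintf("symmetry %d", rep))
    expect_false(any(grepl("^X", classify_pair(ba, bb, fuzz = 0)$type)))
  }
  expect_gt(n_pairs, 20)
})

test_that("simulated AS ground-truth events are all recovered", {
  sim <- sim_wide()
  iso <- sim$truth$isoforms
  truth <- sim$truth$as_events
  for (i in seq_len(nrow(truth))) {
    m <- iso[iso$isoform_id == truth$iso_master[i], ]
    v <- iso[iso$isoform_id == truth$iso_variant[i], ]
    ev <- classify_pair(m$blocks[[1]], v$blocks[[1]], fuzz = 10)
    expect_true(truth$type[i] %in% ev$type,
                label = paste(truth$iso_variant[i], truth$type[i]))
    expect_equal(ev$n_units[ev$type == truth$type[i]][1], truth$n_units[i])
  }
})

test_that("different loci are rejected and summaries conserve totals", {
  iso <- tibble::tibble(isoform_id = c("a", "b"), locus_id = c("l1", "l2"),
                        blocks = list(blocks_of(0, 100), blocks_of(0, 100)))
  expect_error(classify_pair(iso[1, ], iso[2, ]), "different loci")

  run <- run_basic()
  s <- summarize_as_events(run$as_events)
  expect_equal(sum(s$n), nrow(run$as_events))
  expect_equal(sort(s$type), sort(isoscope:::as_event_types))
  expect_true(all(s$n_dedup <= s$n))
  expect_lt(abs(sum(s$share_pct) - 100), 0.05 * 10 + 1e-9)
  # per-library tallies conserve the pooled total
  sl <- summarize_as_events(run$as_events, by_library = TRUE)
  pooled <- sl[sl$library == "pooled", ]
  expect_equal(sum(pooled$n), nrow(run$as_events))
  # independent tally of one category
  expect_equal(pooled$n[pooled$type == "SKIP"],
               sum(run$as_events$type == "SKIP"))
})
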