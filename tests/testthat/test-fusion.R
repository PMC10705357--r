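# Two toy genes on different chromosomes plus one same-chromosome pair 8 kb
# apart, and reads built as two-segment alignments with chosen coverages.
fusion_fixture <- function() {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    transcript_id = c("gA.t", "gB.t", "gC.t", "gD.t"),
    chrom = c("chr1", "chr2", "chr1", "chr1"),
    strand = "+",
    start = c(1000L, 1000L, 10000L, 60000L),
    end = c(2000L, 2000L, 11000L, 61000L)
  )
  mk_read <- function(id, g1, g2, cov1, cov2) {
    g <- ann[match(c(g1, g2), ann$gene_id), ]
    len <- 1000L
    tibble::tibble(
      read_id = id, segment = 1:2, chrom = g$chrom, strand = "+",
      blocks = list(blocks_of(g$start[1], g$start[1] + round(cov1 * len)),
                    blocks_of(g$start[2], g$start[2] + round(cov2 * len))),
      read_coverage = c(cov1, cov2)
    )
  }
  list(ann = ann, mk_read = mk_read)
}

test_that("the four fusion criteria fire as in the worked examples", {
  fx <- fusion_fixture()
  pe <- tibble::tibble(read_id = c("ok", "near", "lowcov"), pe_count = 3L)
  aln <- dplyr::bind_rows(
    fx$mk_read("ok", "gA", "gB", 0.55, 0.449),      # inter-chromosomal
    fx$mk_read("near", "gC", "gD", 0.55, 0.449),    # 49 kb apart: passes
    fx$mk_read("close", "gA", "gC", 0.55, 0.449),   # 8 kb apart: distance fails
    fx$mk_read("lowcov", "gA", "gB", 0.95, 0.08)    # per-gene coverage fails
  )
  res <- call_fusions(aln, fx$ann, pe_evidence = pe)
  expect_true(res$verdict[res$read_id == "ok"])
  expect_equal(res$failed_criteria[res$read_id == "ok"][[1]], character(0))
  expect_true(res$verdict[res$read_id == "near"])
  expect_false(res$verdict[res$read_id == "close"])
  expect_true("distance" %in% res$failed_criteria[res$read_id == "close"][[1]])
  expect_false(res$verdict[res$read_id == "lowcov"])
  expect_true("segment_coverage" %in%
                res$failed_criteria[res$read_id == "lowcov"][[1]])
  # "close" has no PE row either, so the audit lists both violations
  expect_setequal(res$failed_criteria[res$read_id == "close"][[1]],
                  c("distance", "pe_support"))
  # every rejected read carries a non-empty audit list
  expect_true(all(lengths(res$failed_criteria[!res$verdict]) > 0))
})

test_that("thresholds are monotone: tightening never adds a candidate", {
  fx <- fusion_fixture()
  pe <- tibble::tibble(read_id = "ok", pe_count = 2L)
  aln <- fx$mk_read("ok", "gA", "gB", 0.55, 0.449)
  base <- sum(call_fusions(aln, fx$ann, pe)$verdict)
  expect_lte(sum(call_fusions(aln, fx$ann, pe, min_pe = 3L)$verdict), base)
  expect_lte(sum(call_fusions(aln, fx$ann, pe, min_seg_cov = 0.5)$verdict), base)
  expect_lte(sum(call_fusions(aln, fx$ann, pe, min_total_cov = 0.999)$verdict),
             base)
  expect_lte(sum(call_fusions(aln, fx$ann, pe, min_distance = 1e9)$verdict),
             base)  # different chromosomes still satisfy the distance rule
  expect_equal(sum(call_fusions(aln, fx$ann, pe, min_distance = 1e9)$verdict),
               base)
})

test_that("simulated fusions are recovered perfectly and match the oracle", {
  sim <- sim_basic()
  run <- run_basic()
  truth <- sim$truth$fusions
  got <- run$fusion_candidates
  expect_setequal(got$read_id[got$verdict], truth$read_id)
  # zero false positives among non-fusion reads
  expect_true(all(got$read_id[got$verdict] %in% truth$read_id))
  # independent four-predicate evaluation per candidate
  genes <- sim$genes
  for (i in seq_len(nrow(got))) {
    gs <- got$genes[[i]]
    gi <- genes[match(gs, genes$gene_id), ]
    want <- oracle_fusion_verdict(gi$chrom, gi$start, gi$end,
                                  per_gene_cov = rep(got$min_segment_coverage[i],
                                                     length(gs)),
                                  total_cov = got$total_coverage[i],
                                  pe = got$pe_support[i])
    # min coverage stands in for all per-gene coverages: both sides use the
    # minimum, so the predicate outcome is identical
    expect_equal(got$verdict[i], want, label = got$read_id[i])
  }
})

test_that("fusion summaries tally events, genes and chromosome origin", {
  cand <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    genes = list(c("A", "B"), c("A", "C"), c("D", "E"), c("A", "B")),
    gene_pair = c("A+B", "A+C", "D+E", "A+B"),
    inter_chromosomal = c(TRUE, TRUE, FALSE, TRUE),
    verdict = c(TRUE, TRUE, TRUE, TRUE)
  )
  s <- fusion_gene_summary(cand)
  expect_equal(s$n_fusion_reads, 4L)
  expect_equal(s$n_fusion_gene_events, 3L)
  expect_equal(s$n_distinct_genes, 5L)
  expect_equal(s$inter_chromosomal_fraction, 0.75)
  empty <- fusion_gene_summary(cand[0, ])
  expect_equal(empty$n_fusion_reads, 0L)
})
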