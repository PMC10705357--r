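mk_aln <- function(...) {
  rows <- list(...)
  tibble::tibble(
    read_id = vapply(rows, `[[`, character(1), "id"),
    chrom = vapply(rows, function(r) r$chrom %||% "chr1", character(1)),
    strand = vapply(rows, function(r) r$strand %||% "+", character(1)),
    blocks = lapply(rows, `[[`, "b"),
    identity = vapply(rows, function(r) r$identity %||% 1.0, double(1))
  )
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("junction chains are the gaps between blocks", {
  a <- mk_aln(list(id = "r1", b = blocks_of(100, 200, 300, 400)),
              list(id = "r2", b = blocks_of(100, 400)))
  ch <- build_chain(a)
  expect_equal(ch$chain, c("200-300", ""))
  bad <- tibble::tibble(read_id = "x", chrom = "chr1", strand = "+",
                        blocks = list(blocks_of(100, 300, 200, 400)))
  expect_error(build_chain(bad), "malformed")
})

test_that("collapse groups by exact junction chain and merges mono-exon ends", {
  a <- mk_aln(
    list(id = "r1", b = blocks_of(100, 200, 300, 400)),
    list(id = "r2", b = blocks_of(120, 200, 300, 420)),
    list(id = "r3", b = blocks_of(100, 200, 320, 400)),   # different chain
    list(id = "m1", b = blocks_of(1000, 1500)),
    list(id = "m2", b = blocks_of(1100, 1520)),           # 3' within 50, overlap
    list(id = "m3", b = blocks_of(1100, 1800))            # 3' too far
  )
  iso <- collapse_isoforms(a, mono_end_tol = 50)
  expect_equal(nrow(iso), 4)
  two <- iso[iso$chain == "200-300", ]
  expect_equal(two$support, 2L)
  expect_equal(c(two$start, two$end), c(100L, 420L))
  mono <- iso[iso$chain == "", ]
  expect_equal(sort(mono$support), c(1L, 2L))
  # conservation: total support equals input alignments
  expect_equal(sum(iso$support), nrow(a))
})

test_that("collapse equals brute-force chain grouping on simulated reads", {
  sim <- sim_wide()
  a <- sim$alignments
  a <- a[!duplicated(a$read_id) & a$segment == 1, ]
  single <- names(which(table(sim$alignments$read_id) == 1))
  a <- a[a$read_id %in% single, ]
  expect_gt(nrow(a), 500)
  iso <- collapse_isoforms(a)
  want <- oracle_collapse_keys(a)
  multi <- iso[iso$chain != "", ]
  expect_equal(nrow(multi), want$n_multi)
  expect_equal(sort(as.integer(multi$support)), want$multi_groups)
  expect_equal(sum(iso$support), nrow(a))
})

test_that("collapse is idempotent and order-invariant", {
  sim <- sim_basic()
  a <- sim$alignments
  single <- names(which(table(a$read_id) == 1))
  a <- a[a$read_id %in% single, ]
  iso <- collapse_isoforms(a)
  # expand one read per isoform and re-collapse
  re <- tibble::tibble(read_id = iso$isoform_id, chrom = iso$chrom,
                       strand = iso$strand, blocks = iso$blocks)
  iso2 <- collapse_isoforms(re)
  expect_equal(iso2[, c("chrom", "strand", "chain")],
               iso[, c("chrom", "strand", "chain")])
  # shuffled input, same output
  set.seed(1)
  iso3 <- collapse_isoforms(a[sample(nrow(a)), ])
  expect_equal(iso3[, c("isoform_id", "chrom", "strand", "chain", "support")],
               iso[, c("isoform_id", "chrom", "strand", "chain", "support")])
})

test_that("5'-degraded isoforms are removed by the suffix rule", {
  a <- mk_aln(
    list(id = "r1", b = blocks_of(100, 150, 200, 300, 400, 500)),
    list(id = "r2", b = blocks_of(100, 150, 200, 300, 400, 500)),
    list(id = "d1", b = blocks_of(250, 300, 400, 500)),
    list(id = "u1", b = blocks_of(2200, 2300, 2400, 2500))  # not a suffix source
  )
  iso <- collapse_isoforms(a)
  fd <- filter_degraded(iso)
  expect_equal(nrow(fd$removed), 1)
  expect_equal(fd$removed$chain, "300-400")
  expect_equal(fd$removed$absorbed_by,
               iso$isoform_id[iso$chain == "150-200;300-400"])
  # identical chains collapse, so never self-remove
  expect_true(all(fd$kept$chain != "300-400" | fd$kept$start < 250))
})

test_that("degraded-isoform removal matches the ground truth exactly", {
  cfg <- sim_config(seed = 13, n_genes = 12, frac_degraded_reads = 0.3,
                    frac_fusion_reads = 0, frac_artifact_reads = 0)
  sim <- simulate_isoseq(cfg)
  iso <- collapse_isoforms(sim$alignments)
  fd <- filter_degraded(iso)
  true_chains <- unique(paste(sim$truth$isoforms$chrom,
                              sim$truth$isoforms$strand,
                              sim$truth$isoforms$chain))
  # no removed multi-exon isoform carries a true chain (mono-exon removals
  # are compared by their 5' end, since the empty chain is not distinctive)
  rem_multi <- fd$removed[fd$removed$chain != "", ]
  expect_true(all(!paste(rem_multi$chrom, rem_multi$strand,
                         rem_multi$chain) %in% true_chains))
  truth_mono <- sim$truth$isoforms[sim$truth$isoforms$chain == "", ]
  mono_5p <- ifelse(truth_mono$strand == "+",
                    vapply(truth_mono$blocks, function(b) b[1, 1], integer(1)),
                    vapply(truth_mono$blocks, function(b) b[nrow(b), 2],
                           integer(1)))
  rem_mono <- fd$removed[fd$removed$chain == "", ]
  rem_5p <- ifelse(rem_mono$strand == "+", rem_mono$start, rem_mono$end)
  expect_true(all(!paste(rem_mono$chrom, rem_mono$strand, rem_5p) %in%
                    paste(truth_mono$chrom, truth_mono$strand, mono_5p)))
  # the kept set carries exactly the true chains
  kept_keys <- paste(fd$kept$chrom, fd$kept$strand, fd$kept$chain)
  expect_setequal(kept_keys, true_chains)
})

test_that("the retention rule matches its brute-force evaluation", {
  expect_true(retention_filter(tibble::tibble(
    isoform_id = "a", chain = "10-20", support = 2L,
    best_identity = 0.90))$keep)
  expect_true(retention_filter(tibble::tibble(
    isoform_id = "b", chain = "10-20", support = 1L,
    best_identity = 0.995))$keep)   # single read, identity above 99%
  expect_false(retention_filter(tibble::tibble(
    isoform_id = "c", chain = "10-20;30-40;50-60", support = 1L,
    best_identity = 0.95,
    junction_support = list(c(TRUE, FALSE, TRUE))))$keep)
  set.seed(8)
  for (rep in 1:1000) {
    sup <- sample(1:3, 1)
    idy <- runif(1, 0.9, 1)
    nj <- sample(0:4, 1)
    js <- runif(nj) < 0.7
    iso <- tibble::tibble(
      isoform_id = "x",
      chain = if (nj == 0) "" else
        paste(seq(10, by = 20, length.out = nj),
              seq(20, by = 20, length.out = nj), sep = "-", collapse = ";"),
      support = sup, best_identity = idy, junction_support = list(js))
    expect_equal(retention_filter(iso)$keep,
                 oracle_retention(sup, idy, js),
                 label = sprintf("case %d", rep))
  }
})

test_that("locus assignment follows the 20%-of-shorter-span rule", {
  iso <- tibble::tibble(
    isoform_id = c("a", "b", "c", "d"),
    chrom = "chr1", strand = c("+", "+", "+", "-"),
    start = c(0L, 900L, 700L, 0L), end = c(1000L, 2000L, 1700L, 1000L),
    chain = "", blocks = list(blocks_of(0, 1000), blocks_of(900, 2000),
                              blocks_of(700, 1700), blocks_of(0, 1000))
  )
  got <- assign_loci(iso[c(1, 2, 4), ])
  # 100/1000 = 10% < 20%: separate loci; opposite strand never joins
  expect_equal(length(unique(got$locus_id)), 3)
  got2 <- assign_loci(iso)
  # a-c overlap 300/1000 = 30%, c-b overlap 800/1000: one component
  expect_equal(length(unique(got2$locus_id[got2$strand == "+"])), 1)
})

test_that("loci equal brute-force connected components on simulated isoforms", {
  sim <- sim_wide()
  single <- names(which(table(sim$alignments$read_id) == 1))
  iso <- collapse_isoforms(sim$alignments[sim$alignments$read_id %in% single, ])
  iso <- assign_loci(iso)
  want <- oracle_loci(iso$chrom, iso$strand, iso$start, iso$end)
  # same partition: locus ids are a relabelling of the oracle components
  expect_equal(length(unique(iso$locus_id)), length(unique(want)))
  tab <- table(iso$locus_id, want)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("novelty calling recovers withheld genes as novel loci", {
  sim <- sim_basic()
  run <- run_basic()
  iso <- run$isoforms
  genes <- sim$genes
  withheld <- genes$gene_id[seq_len(nrow(genes)) %% 4 == 0]
  ann <- sim$annotation[!sim$annotation$gene_id %in% withheld, ]
  iso2 <- call_novelty(iso[, setdiff(names(iso),
                                     c("isoform_status", "locus_status"))], ann)
  # map loci to genes by position
  for (i in seq_len(nrow(iso2))) {
    g <- genes[genes$chrom == iso2$chrom[i] & genes$strand == iso2$strand[i] &
                 genes$start < iso2$end[i] & genes$end > iso2$start[i], ]
    expect_equal(iso2$locus_status[i],
                 if (g$gene_id[1] %in% withheld) "novel" else "known",
                 label = iso2$isoform_id[i])
  }
  # exact chain match => known isoform; full annotation => everything known
  iso3 <- call_novelty(iso2[, setdiff(names(iso2),
                                      c("isoform_status", "locus_status"))],
                       sim$annotation)
  expect_true(all(iso3$isoform_status == "known"))
  expect_true(all(iso3$locus_status == "known"))
})

test_that("a reference transcript without strand is skipped with a warning", {
  ann <- tibble::tibble(gene_id = "g", transcript_id = "t", chrom = "chr1",
                        strand = "*", start = 0L, end = 100L)
  expect_warning(res <- isoscope:::annotation_transcripts(ann), "strand")
  expect_equal(nrow(res), 0)
})
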