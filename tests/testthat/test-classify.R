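test_that("poly(A) detection handles pure tails and short reads", {
  s <- paste0(strrep("GATC", 25), strrep("A", 30))
  res <- detect_polya(s, min_len = 20, min_purity = 0.9)
  expect_true(res$has_polya)
  expect_equal(res$tail_start, nchar(s) - 30)   # 0-based leftmost tail base
  expect_false(detect_polya("GATTACA", min_len = 20)$has_polya)
  expect_false(detect_polya(strrep("A", 19), min_len = 20)$has_polya)
})

test_that("poly(A) detection equals the brute-force scanner on noisy tails", {
  set.seed(9)
  n_hit <- 0
  for (rep in 1:500) {
    body <- paste0(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                   collapse = "")
    tail_len <- sample(20:60, 1)
    tail <- sample(c("A"), tail_len, replace = TRUE)
    err <- runif(tail_len) < 0.01
    tail[err] <- sample(c("C", "G", "T"), sum(err), replace = TRUE)
    s <- paste0(body, paste0(tail, collapse = ""))
    got <- detect_polya(s, 20, 0.8)
    want <- oracle_polya(s, 20, 0.8)
    expect_equal(got$has_polya, want$has)
    expect_equal(got$tail_start, want$start0)
    n_hit <- n_hit + got$has_polya
  }
  expect_gt(n_hit, 400)  # detection works on most noisy tails
})

test_that("constructed reads classify by the FL/FLNC rules", {
  p5 <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"
  p3 <- "GTACTCTGCGTTGGTTCCACTAGTCTGCGT"
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  set.seed(4)
  insert <- paste0(sample(c("C", "G", "T", "A"), 400, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), collapse = "")
  full <- paste0(p5, insert, strrep("A", 30), rc(p3))
  reads <- tibble::tibble(
    read_id = c("full", "no_polya", "chimera", "rc_full"),
    sequence = c(full,
                 paste0(p5, insert, rc(p3)),
                 paste0(p5, substr(insert, 1, 200), p5,
                        substr(insert, 201, 400), strrep("A", 30), rc(p3)),
                 rc(full)))
  cls <- classify_reads(reads, p5, p3)
  expect_true(cls$is_flnc[cls$read_id == "full"])
  expect_false(cls$is_fl[cls$read_id == "no_polya"])
  expect_false(cls$is_flnc[cls$read_id == "no_polya"])
  expect_true(cls$is_fl[cls$read_id == "chimera"])
  expect_true(cls$is_chimeric[cls$read_id == "chimera"])
  expect_false(cls$is_flnc[cls$read_id == "chimera"])
  # orientation idempotence: the reverse complement classifies identically
  expect_equal(cls$trimmed_sequence[cls$read_id == "rc_full"],
               cls$trimmed_sequence[cls$read_id == "full"])
  expect_true(cls$is_flnc[cls$read_id == "rc_full"])
})

test_that("error-free simulated reads classify exactly as the ground truth", {
  sim <- sim_basic()
  cls <- classify_reads(sim$reads, sim$config$primer_5p, sim$config$primer_3p)
  truth <- sim$truth$read_class
  m <- merge(cls, truth, by = "read_id")
  expect_true(all(m$is_flnc[m$class %in% c("full_length", "degraded", "fusion")]))
  expect_true(all(!m$is_flnc[m$class == "artifact"]))
  # monotone counts
  expect_true(sum(m$is_flnc) <= sum(m$is_fl))
  expect_true(sum(m$is_fl) <= min(sum(m$has_5p), sum(m$has_3p), sum(m$has_polya)))
})

test_that("library summaries pool by independent summation", {
  sim <- sim_basic()
  cls <- classify_reads(sim$reads, sim$config$primer_5p, sim$config$primer_3p)
  stats <- summarize_libraries(cls)
  pooled <- stats[stats$library == "pooled", ]
  per <- stats[stats$library != "pooled", ]
  for (cc in c("n_ccs", "n_5p", "n_3p", "n_polya", "n_fl", "n_flnc")) {
    expect_equal(pooled[[cc]], sum(per[[cc]]))
  }
  expect_equal(pooled$flnc_pct,
               round_half_up(100 * sum(per$n_flnc) / sum(per$n_ccs), 2))
  # per-library invariants
  expect_true(all(per$n_flnc <= per$n_fl))
  expect_true(all(per$n_fl <= pmin(per$n_5p, per$n_3p, per$n_polya)))
})

test_that("a library with zero reads reports zeros with a warning", {
  cls <- tibble::tibble(read_id = character(0), library = character(0),
                        has_5p = logical(0), has_3p = logical(0),
                        has_polya = logical(0), is_fl = logical(0),
                        is_chimeric = logical(0), is_flnc = logical(0),
                        trimmed_length = integer(0))
  expect_warning(st <- summarize_libraries(cls), "zero CCS")
  expect_equal(st$library, "pooled")
  expect_equal(st$n_ccs, 0L)
  expect_equal(st$flnc_pct, 0)
  cls2 <- tibble::tibble(
    read_id = "r1", library = NA_character_, has_5p = FALSE, has_3p = FALSE,
    has_polya = FALSE, is_fl = FALSE, is_chimeric = FALSE, is_flnc = FALSE,
    trimmed_length = 0L)
  expect_error(summarize_libraries(cls2), "r1")
})
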