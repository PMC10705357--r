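# CCS read classification: 5' primer, 3' primer, poly(A) tail detection,
# orientation, chimera flagging and trimming. A read is full-length (FL) when
# all three signals are present, and FLNC when additionally non-chimeric.

#' Detect a 3'-terminal poly(A) tail
#'
#' A tail is the longest terminal suffix of at least `min_len` bases whose
#' every 5'-anchored prefix has an A-fraction of at least `min_purity` (so the
#' tail starts on an A and impurities are tolerated only once enough As have
#' accumulated). Degenerate inputs simply return no tail.
#'
#' @param sequence Character vector of nucleotide sequences (already oriented
#'   5' to 3').
#' @param min_len Minimum tail length in bases.
#' @param min_purity Minimum A-fraction of every tail prefix.
#' @return Tibble with one row per input: `has_polya`, `tail_start` (0-based
#'   index of the leftmost tail base, `NA` when absent), `tail_length`.
#' @examples
#' detect_polya(paste0(strrep("GATC", 10), strrep("A", 30)))
#' @export
detect_polya <- function(sequence, min_len = 20L, min_purity = 0.8) {
  one <- function(seq) {
    n <- nchar(seq)
    if (n < min_len) return(c(NA_integer_, 0L))
    a <- as.integer(strsplit(seq, "", fixed = TRUE)[[1L]] == "A")
    h <- cumsum(a) - min_purity * seq_len(n)   # h(t) = #A(1..t) - p*t
    h0 <- c(0, h)                              # h(0) = 0
    sufmin <- rev(cummin(rev(h)))
    ok <- sufmin >= h0[seq_len(n)] - 1e-9      # prefix condition for start s
    ok <- ok & (n - seq_len(n) + 1L) >= min_len
    s <- which(ok)
    if (!length(s)) return(c(NA_integer_, 0L))
    c(s[1L] - 1L, n - s[1L] + 1L)
  }
  res <- vapply(sequence, one, integer(2), USE.NAMES = FALSE)
  tibble(has_polya = !is.na(res[1L, ]),
         tail_start = res[1L, ],
         tail_length = ifelse(is.na(res[1L, ]), 0L, res[2L, ]))
}

# Minimal mismatch count of `pattern` placed at any 0-based offset in
# `starts0` within `seq`; offsets that do not fit count as a full-length
# mismatch. Returns c(mismatches, best_offset).
best_primer_hit <- function(seq, pattern, starts0) {
  L <- nchar(pattern)
  pv <- utf8ToInt(pattern)
  n <- nchar(seq)
  starts0 <- starts0[starts0 >= 0L & starts0 + L <= n]
  if (!length(starts0)) return(c(L, NA_integer_))
  mm <- vapply(starts0, function(s0) {
    sum(utf8ToInt(substr(seq, s0 + 1L, s0 + L)) != pv)
  }, integer(1))
  i <- which.min(mm)
  c(mm[i], starts0[i])
}

#' Classify CCS reads by primer and poly(A) signals
#'
#' Reads are oriented so the 5' primer sits upstream (the expected sense
#' layout is `primer_5p + insert + poly(A) + revcomp(primer_3p)`), then
#' classified: `is_fl` requires the 5' primer, the 3' primer and a poly(A)
#' tail; `is_flnc` additionally requires no internal primer hit at least
#' `chimera_margin` bases from both trimmed ends. Primers and the tail are
#' trimmed off. A read whose two orientations score identically is flagged
#' ambiguous and classified non-FL.
#'
#' @param reads Tibble with `read_id` and `sequence` (optionally `library`,
#'   carried through).
#' @param primer_5p,primer_3p Primer sequences (sense orientation).
#' @param max_mismatch Maximum mismatches for an ungapped primer match.
#' @param polya_min_len,polya_min_purity Passed to [detect_polya()].
#' @param chimera_margin Minimum distance (bp) of an internal primer hit from
#'   either trimmed terminus for the read to be called chimeric.
#' @param search_window Number of terminal offsets scanned for each primer.
#' @return Tibble with one row per read: flags `has_5p`, `has_3p`,
#'   `has_polya`, `is_fl`, `is_chimeric`, `is_flnc`, the chosen `orientation`,
#'   `trimmed_sequence` and `trimmed_length`, plus a `note` column
#'   (`"ambiguous_orientation"` where both strands scored equally).
#' @export
classify_reads <- function(reads, primer_5p, primer_3p,
                           max_mismatch = 2L,
                           polya_min_len = 20L, polya_min_purity = 0.8,
                           chimera_margin = 50L, search_window = 8L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (!nzchar(primer_5p) || !nzchar(primer_3p)) {
    abort("primer sequences must be non-empty")
  }
  p5 <- toupper(primer_5p)
  rc3 <- revcomp(toupper(primer_3p))
  L5 <- nchar(p5); L3 <- nchar(rc3)
  n_reads <- nrow(reads)
  out <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    sq <- toupper(reads$sequence[i])
    n <- nchar(sq)
    orient_score <- function(s) {
      m5 <- best_primer_hit(s, p5, 0:search_window)
      m3 <- best_primer_hit(s, rc3, (nchar(s) - L3 - search_window):(nchar(s) - L3))
      list(score = min(m5[1L], L5) + min(m3[1L], L3), m5 = m5, m3 = m3)
    }
    sq_r <- revcomp(sq)
    fwd <- orient_score(sq)
    rev_ <- orient_score(sq_r)
    ambiguous <- fwd$score == rev_$score
    use_rev <- !ambiguous && rev_$score < fwd$score
    o <- if (use_rev) rev_ else fwd
    oriented <- if (use_rev) sq_r else sq
    has_5p <- o$m5[1L] <= max_mismatch
    has_3p <- o$m3[1L] <= max_mismatch
    work <- oriented
    if (has_3p) work <- substr(work, 1L, o$m3[2L])
    pa <- detect_polya(work, polya_min_len, polya_min_purity)
    has_polya <- pa$has_polya[1L]
    if (has_polya) work <- substr(work, 1L, pa$tail_start[1L])
    if (has_5p) work <- substr(work, o$m5[2L] + L5 + 1L, nchar(work))
    out[[i]] <- tibble(
      read_id = reads$read_id[i],
      has_5p = has_5p, has_3p = has_3p, has_polya = has_polya,
      is_fl = has_5p && has_3p && has_polya && !ambiguous,
      orientation = if (ambiguous) NA_character_ else if (use_rev) "-" else "+",
      trimmed_sequence = work,
      note = if (ambiguous) "ambiguous_orientation" else NA_character_
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(read_id = character(0), has_5p = logical(0),
                  has_3p = logical(0), has_polya = logical(0),
                  is_fl = logical(0), orientation = character(0),
                  trimmed_sequence = character(0), note = character(0))
  }
  # internal primer scan on the trimmed inserts (chimera rule)
  chim <- rep(FALSE, nrow(res))
  if (nrow(res)) {
    subj <- Biostrings::DNAStringSet(ifelse(nchar(res$trimmed_sequence) > 0,
                                            res$trimmed_sequence, "N"))
    pats <- unique(c(p5, revcomp(p5), toupper(primer_3p), rc3))
    lens <- nchar(res$trimmed_sequence)
    for (pat in pats) {
      m <- Biostrings::vmatchPattern(pat, subj, max.mismatch = max_mismatch)
      hit <- vapply(seq_along(m), function(j) {
        r <- m[[j]]
        any(IRanges::start(r) - 1L >= chimera_margin &
              IRanges::end(r) <= lens[j] - chimera_margin)
      }, logical(1))
      chim <- chim | hit
    }
  }
  res$is_chimeric <- chim
  res$is_flnc <- res$is_fl & !chim
  res$trimmed_length <- nchar(res$trimmed_sequence)
  if ("library" %in% names(reads)) {
    res <- left_join(res, select(reads, "read_id", "library"), by = "read_id")
  }
  select(res, "read_id", dplyr::any_of("library"), "has_5p", "has_3p",
         "has_polya", "is_fl", "is_chimeric", "is_flnc", "orientation",
         "trimmed_sequence", "trimmed_length", "note")
}

#' Per-library classification statistics
#'
#' Tallies CCS / primer / poly(A) / FL / FLNC counts per sequencing library
#' and appends a pooled row whose FLNC percentage is the pooled
#' FLNC-to-CCS ratio (rounded half-up to 2 decimals).
#'
#' @param classifications Output of [classify_reads()].
#' @param library_map Optional tibble `read_id`, `library`; needed when the
#'   classifications carry no `library` column.
#' @return Tibble with one row per library plus a `"pooled"` row: `library`,
#'   `n_ccs`, `n_5p`, `n_3p`, `n_polya`, `n_fl`, `n_flnc`, `mean_flnc_len`,
#'   `flnc_pct`.
#' @export
summarize_libraries <- function(classifications, library_map = NULL) {
  cls <- classifications
  if (!"library" %in% names(cls)) {
    if (is.null(library_map)) {
      abort("no 'library' column and no 'library_map' supplied")
    }
    cls <- left_join(cls, library_map, by = "read_id")
  }
  if (anyNA(cls$library)) {
    bad <- cls$read_id[which(is.na(cls$library))[1L]]
    abort(sprintf("read '%s' has no library label", bad))
  }
  per <- cls |>
    group_by(.data$library) |>
    summarise(
      n_ccs = n(), n_5p = sum(.data$has_5p), n_3p = sum(.data$has_3p),
      n_polya = sum(.data$has_polya), n_fl = sum(.data$is_fl),
      n_flnc = sum(.data$is_flnc),
      mean_flnc_len = if (any(.data$is_flnc))
        round_half_up(mean(.data$trimmed_length[.data$is_flnc])) else NA_real_,
      .groups = "drop"
    ) |>
    arrange(.data$library)
  pooled <- summarise(
    per, library = "pooled",
    across(all_of(c("n_ccs", "n_5p", "n_3p", "n_polya", "n_fl", "n_flnc")), sum),
    mean_flnc_len = NA_real_
  )
  flnc <- cls$trimmed_length[cls$is_flnc]
  pooled$mean_flnc_len <- if (length(flnc)) round_half_up(mean(flnc)) else NA_real_
  out <- bind_rows(per, pooled)
  out$flnc_pct <- ifelse(out$n_ccs > 0,
                         round_half_up(100 * out$n_flnc / out$n_ccs, 2), 0)
  if (any(out$n_ccs == 0)) {
    warn("library with zero CCS reads: FLNC fraction undefined, reported as 0")
  }
  out
}
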