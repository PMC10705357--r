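# lncRNA candidate screening: no protein-database hit, low coding potential,
# length >= 200 bp; retained candidates are classified positionally against
# the reference annotation (intergenic / intronic / sense / antisense /
# other).

#' Filter lncRNA candidates
#'
#' Retains isoforms with no hit in any protein database, a coding-potential
#' score below `cp_cutoff` (or a `FALSE` `coding_call` when that column is
#' supplied, which bypasses the score) and a transcript length of at least
#' `min_len`. Isoforms without an evidence row are excluded with a warning.
#'
#' @param isoforms Isoform tibble; transcript length is the sum of exon block
#'   widths.
#' @param evidence Tibble with hit flags `hit_nr`, `hit_swissprot`,
#'   `hit_cog`, `hit_kog`, a `cp_score` column and/or a logical
#'   `coding_call`, keyed either by `isoform_id` or by structural identity
#'   (`chrom`, `strand`, `chain`, `five_prime`).
#' @param cp_cutoff Coding-potential cutoff (exclusive; scores `>=` cutoff
#'   are treated as coding).
#' @param min_len Minimum transcript length (bp).
#' @return Tibble of retained candidates with `length` added; an `audit`
#'   attribute records the exclusion reason per isoform
#'   (`"db_hit"`, `"coding_potential"`, `"length"`, `"no_evidence"`).
#' @export
filter_lncrna <- function(isoforms, evidence, cp_cutoff = 0.364,
                          min_len = 200L) {
  iso <- isoforms
  iso$length <- vapply(iso$blocks, blocks_width, double(1))
  if ("isoform_id" %in% names(evidence) &&
      any(evidence$isoform_id %in% iso$isoform_id)) {
    ev <- evidence
    joined <- left_join(iso, ev, by = "isoform_id")
  } else if (all(c("chrom", "strand", "chain", "five_prime") %in% names(evidence))) {
    iso$five_prime <- ifelse(iso$strand == "+", iso$start, iso$end)
    ev <- evidence
    if ("isoform_id" %in% names(ev)) ev <- rename(ev, evidence_id = "isoform_id")
    joined <- left_join(iso, ev,
                        by = c("chrom", "strand", "chain", "five_prime"))
  } else {
    abort("evidence must be keyed by 'isoform_id' or by chrom/strand/chain/five_prime")
  }
  hit_cols <- intersect(c("hit_nr", "hit_swissprot", "hit_cog", "hit_kog"),
                        names(joined))
  if (!length(hit_cols)) abort("evidence has no database hit columns")
  has_ev <- !is.na(joined[[hit_cols[1L]]])
  any_hit <- rep(FALSE, nrow(joined))
  for (hc in hit_cols) any_hit <- any_hit | (joined[[hc]] %in% TRUE)
  coding <- if ("coding_call" %in% names(joined)) {
    joined$coding_call %in% TRUE
  } else if ("cp_score" %in% names(joined)) {
    !is.na(joined$cp_score) & joined$cp_score >= cp_cutoff
  } else {
    abort("evidence must carry 'cp_score' or 'coding_call'")
  }
  reason <- dplyr::case_when(
    !has_ev ~ "no_evidence",
    any_hit ~ "db_hit",
    coding ~ "coding_potential",
    joined$length < min_len ~ "length",
    .default = NA_character_
  )
  if (any(reason %in% "no_evidence")) {
    warn(sprintf("%d isoforms without evidence rows excluded from lncRNA screening",
                 sum(reason %in% "no_evidence")))
  }
  keep <- is.na(reason)
  out <- iso[keep, , drop = FALSE]
  audit <- tibble(isoform_id = iso$isoform_id[!keep], reason = reason[!keep])
  attr(out, "audit") <- audit
  out
}

#' Positionally classify lncRNA candidates against an annotation
#'
#' Classes, tested in order: `intergenic` (no overlap with any gene span on
#' either strand), `intronic` (fully inside an intron of some reference
#' transcript, either strand), `sense` / `antisense` (exonic overlap on the
#' same / opposite strand), and `other` (remaining partial-overlap
#' configurations).
#'
#' @param candidates Tibble with `chrom`, `strand`, `start`, `end` and
#'   optionally `blocks` (exonic overlap then uses the blocks).
#' @param annotation Exon-level reference annotation tibble.
#' @return `candidates` with a `positional_class` column.
#' @export
classify_position <- function(candidates, annotation) {
  if (nrow(candidates) == 0L) {
    return(mutate(candidates, positional_class = character(0)))
  }
  genes <- annotation |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1L], strand = .data$strand[1L],
              start = min(.data$start), end = max(.data$end), .groups = "drop")
  introns <- annotation |>
    group_by(.data$transcript_id) |>
    summarise(chrom = .data$chrom[1L], strand = .data$strand[1L],
              intr = list(blocks_introns(as_blocks(.data$start, .data$end))),
              .groups = "drop")
  cls <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    st <- candidates$start[i]; en <- candidates$end[i]
    ch <- candidates$chrom[i]; sd <- candidates$strand[i]
    cblocks <- if ("blocks" %in% names(candidates)) {
      candidates$blocks[[i]]
    } else {
      as_blocks(st, en)
    }
    g_ov <- genes[genes$chrom == ch & genes$start < en & genes$end > st, ,
                  drop = FALSE]
    if (!nrow(g_ov)) { cls[i] <- "intergenic"; next }
    inside_intron <- FALSE
    for (j in which(introns$chrom == ch)) {
      im <- introns$intr[[j]]
      if (nrow(im) && any(im[, 1L] <= st & im[, 2L] >= en)) {
        inside_intron <- TRUE; break
      }
    }
    if (inside_intron) { cls[i] <- "intronic"; next }
    ex <- annotation[annotation$chrom == ch & annotation$start < en &
                       annotation$end > st, , drop = FALSE]
    ex_hit <- function(strand_sel) {
      e <- ex[ex$strand == strand_sel, , drop = FALSE]
      if (!nrow(e)) return(FALSE)
      for (r in seq_len(nrow(e))) {
        ov <- cblocks[, 1L] < e$end[r] & cblocks[, 2L] > e$start[r]
        if (any(ov)) return(TRUE)
      }
      FALSE
    }
    if (ex_hit(sd)) cls[i] <- "sense"
    else if (ex_hit(setdiff(c("+", "-"), sd))) cls[i] <- "antisense"
    else cls[i] <- "other"
  }
  mutate(candidates, positional_class = cls)
}

#' Mean lncRNA length per library and binned length distribution
#'
#' @param candidates lncRNA candidate tibble with `length` and a `libraries`
#'   list-column or `library` column; candidates count once per library.
#' @param bin_width,max_bin Histogram bins `[0, bin_width)`, ... up to
#'   `max_bin` with a final open-ended bin.
#' @return List-free tibble pair via `type` column is avoided: returns a
#'   tibble of per-library means with attribute `"bins"` holding the binned
#'   distribution (`bin`, `n`, `share_pct`).
#' @export
lncrna_length_summary <- function(candidates, bin_width = 500L,
                                  max_bin = 3500L) {
  if (!"length" %in% names(candidates)) {
    candidates$length <- vapply(candidates$blocks, blocks_width, double(1))
  }
  long <- if ("libraries" %in% names(candidates)) {
    tidyr::unnest_longer(candidates, "libraries", values_to = "library",
                         keep_empty = TRUE)
  } else if ("library" %in% names(candidates)) {
    candidates
  } else {
    mutate(candidates, library = "all")
  }
  means <- long |>
    group_by(.data$library) |>
    summarise(n = n(),
              mean_length = round_half_up(mean(.data$length)),
              .groups = "drop")
  edges <- seq(0L, max_bin, by = bin_width)
  labels <- c(sprintf("%d-%d", head(edges, -1L), edges[-1L]),
              sprintf(">%d", max_bin))
  bin_of <- findInterval(candidates$length, c(edges[-1L], Inf)) + 1L
  bins <- tibble(bin = factor(labels[bin_of], levels = labels)) |>
    dplyr::count(.data$bin, .drop = FALSE) |>
    mutate(bin = as.character(.data$bin))
  bins$share_pct <- if (sum(bins$n) > 0) {
    round_half_up(100 * bins$n / sum(bins$n), 2)
  } else {
    rep(0, nrow(bins))
  }
  attr(means, "bins") <- bins
  means
}
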