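# Candidate fusion transcripts from multi-gene FLNC alignments. A read is a
# candidate fusion when (a) its segments overlap two or more annotated genes,
# all pairs >= `min_distance` apart or on different chromosomes, (b) every
# per-gene alignment covers > `min_seg_cov` of the read, (c) the combined
# coverage exceeds `min_total_cov`, and (d) at least `min_pe` paired-end
# read pairs span the fusion junction.

fusion_criteria <- c("multi_gene", "distance", "segment_coverage",
                     "total_coverage", "pe_support")

#' Call candidate fusion transcripts
#'
#' @param alignments Alignment tibble with (possibly) several segments per
#'   read: `read_id`, `chrom`, `strand`, `blocks`, `read_coverage` (aligned
#'   fraction of the trimmed read). Reads with a single segment are not
#'   candidates and are excluded.
#' @param annotation Exon-level annotation tibble; gene spans are the union
#'   of each gene's exons. Each segment is attributed to the gene with the
#'   largest span overlap (no overlap: unassigned, still counted in total
#'   coverage).
#' @param pe_evidence Optional tibble `read_id`, `pe_count` of paired-end
#'   read pairs spanning the putative junction; missing reads count 0.
#' @param min_distance Minimum genomic distance (bp) between the nearest
#'   boundaries of every gene pair on the same chromosome.
#' @param min_seg_cov Per-gene minimum read coverage (strict `>`).
#' @param min_total_cov Minimum combined read coverage (strict `>`).
#' @param min_pe Minimum paired-end support.
#' @return Tibble with one row per multi-segment read: `read_id`,
#'   `n_segments`, `genes` (list), `n_genes`, `gene_pair` (sorted,
#'   `"+"`-joined), `inter_chromosomal`, `min_gene_distance` (`NA` when all
#'   pairs are inter-chromosomal), `min_segment_coverage`, `total_coverage`,
#'   `pe_support`, `verdict`, `failed_criteria` (list; empty when verdict is
#'   `TRUE`).
#' @export
call_fusions <- function(alignments, annotation, pe_evidence = NULL,
                         min_distance = 10000L, min_seg_cov = 0.10,
                         min_total_cov = 0.99, min_pe = 2L) {
  empty <- tibble(read_id = character(0), n_segments = integer(0),
                  genes = list(), n_genes = integer(0),
                  gene_pair = character(0), inter_chromosomal = logical(0),
                  min_gene_distance = double(0),
                  min_segment_coverage = double(0), total_coverage = double(0),
                  pe_support = integer(0), verdict = logical(0),
                  failed_criteria = list())
  if (nrow(alignments) == 0L) return(empty)
  genes <- annotation |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1L], strand = .data$strand[1L],
              start = min(.data$start), end = max(.data$end), .groups = "drop")
  assign_gene <- function(chrom, start, end) {
    cand <- genes[genes$chrom == chrom & genes$start < end &
                    genes$end > start, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    ov <- pmin(end, cand$end) - pmax(start, cand$start)
    cand$gene_id[which.max(ov)]
  }
  a <- build_chain(alignments)
  rows <- list()
  for (grp in split(a, a$read_id)) {
    if (nrow(grp) < 2L) next
    grp$gene <- vapply(seq_len(nrow(grp)), function(i) {
      assign_gene(grp$chrom[i], grp$start[i], grp$end[i])
    }, character(1))
    # merge segments of one (read, gene) before the per-gene coverage test
    per_gene <- grp |>
      filter(!is.na(.data$gene)) |>
      group_by(.data$gene) |>
      summarise(cov = sum(.data$read_coverage), .groups = "drop")
    gset <- sort(per_gene$gene)
    n_genes <- length(gset)
    total_cov <- sum(grp$read_coverage)
    failed <- character(0)
    inter <- FALSE
    min_dist <- NA_real_
    if (n_genes < 2L) {
      failed <- c(failed, "multi_gene")
    } else {
      gi <- genes[match(gset, genes$gene_id), ]
      dists <- c()
      ok_pairs <- TRUE
      inter <- TRUE
      for (x in seq_len(n_genes - 1L)) {
        for (y in (x + 1L):n_genes) {
          if (gi$chrom[x] != gi$chrom[y]) next
          inter <- FALSE
          d <- max(gi$start[y] - gi$end[x], gi$start[x] - gi$end[y])
          dists <- c(dists, d)
          if (d < min_distance) ok_pairs <- FALSE
        }
      }
      if (length(dists)) min_dist <- min(dists)
      if (!ok_pairs) failed <- c(failed, "distance")
      if (any(per_gene$cov <= min_seg_cov)) {
        failed <- c(failed, "segment_coverage")
      }
    }
    if (total_cov <= min_total_cov) failed <- c(failed, "total_coverage")
    pe <- 0L
    if (!is.null(pe_evidence)) {
      hit <- match(grp$read_id[1L], pe_evidence$read_id)
      if (!is.na(hit)) pe <- as.integer(pe_evidence$pe_count[hit])
    }
    if (pe < min_pe) failed <- c(failed, "pe_support")
    rows[[length(rows) + 1L]] <- tibble(
      read_id = grp$read_id[1L], n_segments = nrow(grp),
      genes = list(gset), n_genes = n_genes,
      gene_pair = paste(gset, collapse = "+"),
      inter_chromosomal = inter, min_gene_distance = min_dist,
      min_segment_coverage = if (nrow(per_gene)) min(per_gene$cov) else NA_real_,
      total_coverage = total_cov, pe_support = pe,
      verdict = length(failed) == 0L, failed_criteria = list(failed)
    )
  }
  if (!length(rows)) return(empty)
  bind_rows(rows) |> arrange(.data$read_id)
}

#' Summarize fusion candidates
#'
#' @param candidates Output of [call_fusions()].
#' @return One-row tibble: `n_fusion_reads` (verdict-true reads),
#'   `n_fusion_gene_events` (distinct unordered gene sets),
#'   `n_distinct_genes`, `inter_chromosomal_fraction` (of verdict-true
#'   reads; `NA` when none).
#' @export
fusion_gene_summary <- function(candidates) {
  hit <- candidates[candidates$verdict %||% logical(0), , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(tibble(n_fusion_reads = 0L, n_fusion_gene_events = 0L,
                  n_distinct_genes = 0L,
                  inter_chromosomal_fraction = NA_real_))
  }
  tibble(
    n_fusion_reads = nrow(hit),
    n_fusion_gene_events = dplyr::n_distinct(hit$gene_pair),
    n_distinct_genes = length(unique(unlist(hit$genes))),
    inter_chromosomal_fraction = mean(hit$inter_chromosomal)
  )
}
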