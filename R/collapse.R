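# Isoform collapse and gene-locus assignment. FLNC alignments with the same
# splicing connections (junction chain) collapse into one isoform model;
# 5'-degraded and unsupported isoforms are filtered; isoforms overlapping by
# at least `min_overlap` of the shorter span on the same strand form a gene
# locus (connected components); loci/isoforms absent from the reference
# annotation are called novel.

#' Add junction chains to spliced alignments
#'
#' The chain of an alignment is the ordered list of intron intervals between
#' consecutive exon blocks, serialized as `"start-end;start-end"`; mono-exonic
#' alignments get the empty chain `""`.
#'
#' @param alignments Tibble with at least `read_id`, `chrom`, `strand` and a
#'   `blocks` list-column of 0-based half-open exon matrices.
#' @return The input with `chain`, `start`, `end` and `n_exons` columns added.
#' @export
build_chain <- function(alignments) {
  stopifnot(is.data.frame(alignments), "blocks" %in% names(alignments))
  for (b in alignments$blocks) check_blocks(b)
  alignments |>
    mutate(
      chain = vapply(.data$blocks, blocks_chain, character(1)),
      start = vapply(.data$blocks, function(b) as.integer(b[1L, 1L]), integer(1)),
      end = vapply(.data$blocks, function(b) as.integer(b[nrow(b), 2L]), integer(1)),
      n_exons = vapply(.data$blocks, nrow, integer(1))
    )
}

three_prime_end0 <- function(start, end, strand) {
  ifelse(strand == "+", end, start)
}

#' Collapse spliced alignments into isoform models
#'
#' Multi-exon alignments sharing `(chrom, strand, chain)` collapse into one
#' isoform whose span is the maximal extent of its reads. Mono-exonic
#' alignments on the same chrom/strand merge (transitively) when their 3'
#' ends lie within `mono_end_tol` bp and their spans overlap; the 5' end is
#' left free, consistent with 5'-degradation handling.
#'
#' @param alignments Alignment tibble; [build_chain()] is applied if needed.
#'   An `identity` column (alignment percent identity as a fraction) and a
#'   `library` column are aggregated when present.
#' @param mono_end_tol Mono-exon 3'-end merge tolerance (bp).
#' @return Isoform tibble: `isoform_id`, `chrom`, `strand`, `start`, `end`,
#'   `n_exons`, `chain`, `blocks`, `support`, `best_identity`, `read_ids`
#'   (list), `libraries` (list). Ids are assigned by sorted genomic position,
#'   so input order never changes the output.
#' @export
collapse_isoforms <- function(alignments, mono_end_tol = 50L) {
  if (nrow(alignments) == 0L) {
    return(tibble(isoform_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  n_exons = integer(0), chain = character(0), blocks = list(),
                  support = integer(0), best_identity = double(0),
                  read_ids = list(), libraries = list()))
  }
  if (!"chain" %in% names(alignments)) alignments <- build_chain(alignments)
  if (!strand_ok(alignments$strand)) abort("strand must be '+' or '-'")
  a <- alignments
  if (!"identity" %in% names(a)) a$identity <- NA_real_
  if (!"library" %in% names(a)) a$library <- NA_character_

  multi <- a[a$chain != "", ]
  mono <- a[a$chain == "", ]

  groups <- list()
  if (nrow(multi)) {
    key <- paste(multi$chrom, multi$strand, multi$chain, sep = "\r")
    groups <- c(groups, split(seq_len(nrow(multi)), key) |>
                  lapply(function(ix) multi[ix, ]))
  }
  if (nrow(mono)) {
    for (grp in split(mono, paste(mono$chrom, mono$strand, sep = "\r"))) {
      e3 <- three_prime_end0(grp$start, grp$end, grp$strand)
      n <- nrow(grp)
      edges <- NULL
      if (n > 1L) {
        pr <- which(outer(e3, e3, function(x, y) abs(x - y) <= mono_end_tol) &
                      outer(grp$start, grp$end, `<`) &
                      outer(grp$end, grp$start, `>`), arr.ind = TRUE)
        pr <- pr[pr[, 1L] < pr[, 2L], , drop = FALSE]
        edges <- t(pr)
      }
      g <- igraph::make_empty_graph(n = n, directed = FALSE)
      if (!is.null(edges) && length(edges)) g <- igraph::add_edges(g, as.vector(edges))
      comp <- igraph::components(g)$membership
      groups <- c(groups, lapply(split(seq_len(n), comp), function(ix) grp[ix, ]))
    }
  }

  rows <- lapply(groups, function(g) {
    start <- min(g$start); end <- max(g$end)
    chain <- g$chain[1L]
    intr <- chain_introns(chain)
    blocks <- if (nrow(intr) == 0L) {
      as_blocks(start, end)
    } else {
      as_blocks(c(start, intr[, 2L]), c(intr[, 1L], end))
    }
    tibble(chrom = g$chrom[1L], strand = g$strand[1L],
           start = start, end = end, n_exons = nrow(blocks), chain = chain,
           blocks = list(blocks), support = nrow(g),
           best_identity = if (all(is.na(g$identity))) NA_real_
           else max(g$identity, na.rm = TRUE),
           read_ids = list(sort(g$read_id)),
           libraries = list(sort(unique(g$library[!is.na(g$library)]))))
  })
  out <- bind_rows(rows) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand, .data$chain)
  out$isoform_id <- new_ids("iso", nrow(out))
  select(out, "isoform_id", dplyr::everything())
}

# TRUE when `chain_v` is a proper 3'-anchored suffix of `chain_b`
# (genomic suffix on "+", genomic prefix on "-").
chain_is_5p_truncation <- function(chain_v, chain_b, strand) {
  iv <- chain_introns(chain_v); ib <- chain_introns(chain_b)
  nv <- nrow(iv); nb <- nrow(ib)
  if (nv >= nb) return(FALSE)
  if (nv == 0L) return(TRUE)  # positional checks are the caller's job
  keep <- if (strand == "+") (nb - nv + 1L):nb else 1L:nv
  identical(unname(iv), unname(ib[keep, , drop = FALSE]))
}

#' Filter 5'-degraded isoforms
#'
#' An isoform is removed when another isoform on the same chrom/strand exists
#' whose junction chain contains the victim's chain as a 3'-anchored suffix
#' and whose span contains the victim's 5' end — the signature of a
#' transcript degraded at the 5' terminal region. A mono-exonic victim (empty
#' chain) must additionally lie within the longer isoform's 3'-terminal exon
#' (extended by `mono_end_tol` bp) to count as a truncation of it.
#'
#' @param isoforms Output of [collapse_isoforms()].
#' @param mono_end_tol Tolerance (bp) for the mono-exonic 3'-terminal-exon
#'   containment check.
#' @return List with `kept` and `removed` tibbles; `removed` gains an
#'   `absorbed_by` column naming the isoform that explains it.
#' @export
filter_degraded <- function(isoforms, mono_end_tol = 50L) {
  if (nrow(isoforms) == 0L) {
    return(list(kept = isoforms,
                removed = mutate(isoforms, absorbed_by = character(0))))
  }
  removed_by <- rep(NA_character_, nrow(isoforms))
  for (grp in split(seq_len(nrow(isoforms)),
                    paste(isoforms$chrom, isoforms$strand, sep = "\r"))) {
    strand <- isoforms$strand[grp[1L]]
    for (v in grp) {
      for (b in grp) {
        if (v == b) next
        if (!chain_is_5p_truncation(isoforms$chain[v], isoforms$chain[b], strand)) next
        fe <- if (strand == "+") isoforms$start[v] else isoforms$end[v]
        if (fe < isoforms$start[b] || fe > isoforms$end[b]) next
        if (isoforms$chain[v] == "") {
          ib <- chain_introns(isoforms$chain[b])
          if (strand == "+") {
            last_acc <- ib[nrow(ib), 2L]
            if (!(isoforms$start[v] >= last_acc &&
                  isoforms$end[v] <= isoforms$end[b] + mono_end_tol)) next
          } else {
            first_don <- ib[1L, 1L]
            if (!(isoforms$end[v] <= first_don &&
                  isoforms$start[v] >= isoforms$start[b] - mono_end_tol)) next
          }
        }
        removed_by[v] <- isoforms$isoform_id[b]
        break
      }
    }
  }
  hit <- !is.na(removed_by)
  list(kept = isoforms[!hit, , drop = FALSE],
       removed = mutate(isoforms[hit, , drop = FALSE],
                        absorbed_by = removed_by[hit]))
}

#' Attach per-junction support evidence
#'
#' A junction is supported when it appears in the short-read junction table
#' or in the reference annotation (logical OR per junction).
#'
#' @param isoforms Isoform tibble.
#' @param junctions Optional tibble of short-read-supported introns: `chrom`,
#'   `start`, `end` (0-based half-open), optionally `strand`.
#' @param annotation Optional exon-level reference annotation tibble (as from
#'   [read_gff3()]).
#' @return `isoforms` with a `junction_support` list-column of per-intron
#'   logical vectors (length 0 for mono-exonic isoforms).
#' @export
add_junction_support <- function(isoforms, junctions = NULL, annotation = NULL) {
  keys <- character(0)
  if (!is.null(junctions) && nrow(junctions)) {
    st <- if ("strand" %in% names(junctions)) junctions$strand else ""
    keys <- c(keys, paste(junctions$chrom, st, junctions$start, junctions$end))
    if (!"strand" %in% names(junctions)) {
      keys <- c(keys, paste(junctions$chrom, "+", junctions$start, junctions$end),
                paste(junctions$chrom, "-", junctions$start, junctions$end))
    }
  }
  if (!is.null(annotation) && nrow(annotation)) {
    ref <- annotation_transcripts(annotation)
    for (i in seq_len(nrow(ref))) {
      intr <- chain_introns(ref$chain[i])
      if (nrow(intr)) {
        keys <- c(keys, paste(ref$chrom[i], ref$strand[i], intr[, 1L], intr[, 2L]))
      }
    }
  }
  keys <- unique(keys)
  isoforms$junction_support <- lapply(seq_len(nrow(isoforms)), function(i) {
    intr <- chain_introns(isoforms$chain[i])
    if (nrow(intr) == 0L) return(logical(0))
    paste(isoforms$chrom[i], isoforms$strand[i], intr[, 1L], intr[, 2L]) %in% keys
  })
  isoforms
}

#' Isoform retention filter
#'
#' Keeps an isoform when it has at least two supporting FLNC reads, or a
#' single read with alignment identity above `pid_cut`, or every junction
#' supported by short-read or annotation evidence (multi-exonic isoforms
#' only; the all-junction rule is not applied vacuously to mono-exonic
#' models).
#'
#' @param isoforms Isoform tibble; a `junction_support` list-column (see
#'   [add_junction_support()]) is required for the evidence rule and treated
#'   as all-unsupported when absent.
#' @param pid_cut Identity threshold (fraction; strict `>`).
#' @return `isoforms` with logical `keep` and character `keep_rule`
#'   (`"multi_read"`, `"high_identity"`, `"junctions_supported"`, `"none"`).
#' @export
retention_filter <- function(isoforms, pid_cut = 0.99) {
  if (!"junction_support" %in% names(isoforms)) {
    isoforms$junction_support <- lapply(
      seq_len(nrow(isoforms)),
      function(i) rep(FALSE, nrow(chain_introns(isoforms$chain[i]))))
  }
  rule <- vapply(seq_len(nrow(isoforms)), function(i) {
    if (isoforms$support[i] >= 2L) return("multi_read")
    idy <- isoforms$best_identity[i]
    if (!is.na(idy) && idy > pid_cut) return("high_identity")
    js <- isoforms$junction_support[[i]]
    if (length(js) > 0L && all(js)) return("junctions_supported")
    "none"
  }, character(1))
  mutate(isoforms, keep = rule != "none", keep_rule = rule)
}

# pairwise locus relation -> connected components, for any span tibble
overlap_components <- function(df, min_overlap) {
  memb <- integer(nrow(df))
  offset <- 0L
  for (grp in split(seq_len(nrow(df)), paste(df$chrom, df$strand, sep = "\r"))) {
    ir <- IRanges::IRanges(start = df$start[grp] + 1L, end = df$end[grp])
    hits <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    keep <- q < s
    q <- q[keep]; s <- s[keep]
    if (length(q)) {
      ov <- IRanges::width(IRanges::pintersect(ir[q], ir[s]))
      frac <- ov / pmin(IRanges::width(ir[q]), IRanges::width(ir[s]))
      sel <- frac >= min_overlap
      q <- q[sel]; s <- s[sel]
    }
    g <- igraph::make_empty_graph(n = length(grp), directed = FALSE)
    if (length(q)) g <- igraph::add_edges(g, rbind(q, s))
    memb[grp] <- igraph::components(g)$membership + offset
    offset <- offset + length(grp)
  }
  memb
}

#' Group isoforms into gene loci
#'
#' Two isoforms belong to the same locus when they share chrom and strand and
#' their spans overlap by at least `min_overlap` of the shorter span; loci
#' are the connected components of this relation. Locus ids are assigned by
#' sorted genomic position.
#'
#' @param isoforms Isoform tibble.
#' @param min_overlap Minimum overlap fraction of the shorter span.
#' @return `isoforms` with a `locus_id` column.
#' @export
assign_loci <- function(isoforms, min_overlap = 0.2) {
  if (nrow(isoforms) == 0L) return(mutate(isoforms, locus_id = character(0)))
  memb <- overlap_components(isoforms, min_overlap)
  span_start <- tapply(isoforms$start, memb, min)
  span_chrom <- tapply(isoforms$chrom, memb, function(x) x[1L])
  ord <- order(span_chrom, span_start)
  lid <- setNames(new_ids("locus", length(ord)), names(span_start)[ord])
  mutate(isoforms, locus_id = unname(lid[as.character(memb)]))
}

#' Summarize gene loci
#'
#' @param isoforms Isoform tibble carrying `locus_id` (see [assign_loci()]).
#' @return One row per locus: span, isoform count and ids, plus `status` when
#'   the isoforms carry a `locus_status` column.
#' @export
summarize_loci <- function(isoforms) {
  stopifnot("locus_id" %in% names(isoforms))
  if (nrow(isoforms) == 0L) {
    return(tibble(locus_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  n_isoforms = integer(0), isoform_ids = list(),
                  status = character(0), span_length = integer(0)))
  }
  isoforms |>
    group_by(.data$locus_id) |>
    summarise(
      chrom = .data$chrom[1L], strand = .data$strand[1L],
      start = min(.data$start), end = max(.data$end),
      n_isoforms = n(), isoform_ids = list(.data$isoform_id),
      status = if ("locus_status" %in% names(isoforms))
        .data$locus_status[1L] else NA_character_,
      .groups = "drop"
    ) |>
    mutate(span_length = .data$end - .data$start) |>
    arrange(.data$locus_id)
}

# reference annotation -> one row per transcript with chain and span
annotation_transcripts <- function(annotation) {
  if (nrow(annotation) == 0L) {
    return(tibble(transcript_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  start = integer(0), end = integer(0), chain = character(0)))
  }
  bad <- !annotation$strand %in% c("+", "-")
  if (any(bad)) {
    warn(sprintf("%d reference exons without strand skipped", sum(bad)))
    annotation <- annotation[!bad, , drop = FALSE]
    if (nrow(annotation) == 0L) return(annotation_transcripts(annotation))
  }
  annotation |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1L], chrom = .data$chrom[1L],
      strand = .data$strand[1L],
      chain = blocks_chain(as_blocks(.data$start, .data$end)),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    )
}

#' Call novel loci and isoforms against a reference annotation
#'
#' A locus is known when some reference locus (connected component of
#' reference transcripts under the same >= `min_overlap` rule) overlaps it by
#' at least `min_overlap` of the shorter span on the same strand. A
#' multi-exonic isoform is known when its junction chain exactly matches a
#' reference transcript on the same chrom/strand; a mono-exonic isoform when
#' a mono-exonic reference transcript on the same strand overlaps it by the
#' locus rule.
#'
#' @param isoforms Isoform tibble with `locus_id` (see [assign_loci()]).
#' @param annotation Exon-level reference annotation tibble.
#' @param min_overlap Overlap fraction, as in [assign_loci()].
#' @return `isoforms` with `isoform_status` and `locus_status` columns
#'   (`"known"`/`"novel"`).
#' @export
call_novelty <- function(isoforms, annotation, min_overlap = 0.2) {
  stopifnot("locus_id" %in% names(isoforms))
  ref <- annotation_transcripts(annotation)
  if (nrow(isoforms) == 0L) {
    return(mutate(isoforms, isoform_status = character(0),
                  locus_status = character(0)))
  }
  # isoform status
  ref_multi_keys <- paste(ref$chrom, ref$strand, ref$chain)[ref$chain != ""]
  iso_known <- logical(nrow(isoforms))
  multi <- isoforms$chain != ""
  iso_known[multi] <- paste(isoforms$chrom, isoforms$strand,
                            isoforms$chain)[multi] %in% ref_multi_keys
  ref_mono <- ref[ref$chain == "", , drop = FALSE]
  if (any(!multi) && nrow(ref_mono)) {
    for (i in which(!multi)) {
      cand <- ref_mono[ref_mono$chrom == isoforms$chrom[i] &
                         ref_mono$strand == isoforms$strand[i], , drop = FALSE]
      if (!nrow(cand)) next
      ov <- pmin(isoforms$end[i], cand$end) - pmax(isoforms$start[i], cand$start)
      frac <- ov / pmin(isoforms$end[i] - isoforms$start[i],
                        cand$end - cand$start)
      iso_known[i] <- any(ov > 0 & frac >= min_overlap)
    }
  }
  # locus status: observed locus span vs reference locus spans
  loci <- isoforms |>
    group_by(.data$locus_id) |>
    summarise(chrom = .data$chrom[1L], strand = .data$strand[1L],
              start = min(.data$start), end = max(.data$end), .groups = "drop")
  locus_known <- setNames(logical(nrow(loci)), loci$locus_id)
  if (nrow(ref)) {
    ref$locus <- overlap_components(ref, min_overlap)
    ref_loci <- ref |>
      group_by(.data$locus) |>
      summarise(chrom = .data$chrom[1L], strand = .data$strand[1L],
                start = min(.data$start), end = max(.data$end),
                .groups = "drop")
    for (i in seq_len(nrow(loci))) {
      cand <- ref_loci[ref_loci$chrom == loci$chrom[i] &
                         ref_loci$strand == loci$strand[i], , drop = FALSE]
      if (!nrow(cand)) next
      ov <- pmin(loci$end[i], cand$end) - pmax(loci$start[i], cand$start)
      frac <- ov / pmin(loci$end[i] - loci$start[i], cand$end - cand$start)
      locus_known[loci$locus_id[i]] <- any(ov > 0 & frac >= min_overlap)
    }
  }
  mutate(isoforms,
         isoform_status = ifelse(iso_known, "known", "novel"),
         locus_status = ifelse(unname(locus_known[.data$locus_id]),
                               "known", "novel"))
}
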