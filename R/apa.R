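# Alternative polyadenylation site detection from clustered FLNC 3' ends:
# ends within `group_window` bp are grouped greedily, clusters need
# `min_support` reads, and an accepted site suppresses further sites within
# `exclusion` bp.

#' Extract per-read 3' ends from spliced alignments
#'
#' The 3' end is the final transcribed base (1-based): the last block end on
#' `+`, the first block start on `-`. Reads are attributed to the locus of
#' the isoform that absorbed them.
#'
#' @param alignments Alignment tibble (single-segment records).
#' @param isoforms Isoform tibble with `locus_id` and `read_ids` (from
#'   [collapse_isoforms()] + [assign_loci()]).
#' @return Tibble `read_id`, `gene_id` (locus), `chrom`, `strand`, `position`.
#' @export
three_prime_ends <- function(alignments, isoforms) {
  stopifnot(all(c("locus_id", "read_ids") %in% names(isoforms)))
  if (nrow(alignments) == 0L || nrow(isoforms) == 0L) {
    return(tibble(read_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  position = integer(0)))
  }
  map <- isoforms |>
    select("locus_id", "read_ids") |>
    tidyr::unnest_longer("read_ids", values_to = "read_id")
  a <- build_chain(alignments)
  a |>
    dplyr::inner_join(map, by = "read_id") |>
    mutate(position = ifelse(.data$strand == "+", .data$end, .data$start + 1L)) |>
    select("read_id", gene_id = "locus_id", "chrom", "strand", "position")
}

# Greedy position clustering for one gene/strand. Scanning ascending
# positions, a new cluster opens when the next end is more than `window` from
# the current cluster's representative; the representative is the modal
# position so far (ties resolved to the most 3'-distal, per strand).
cluster_ends <- function(pos, strand, window) {
  ord <- order(pos)
  cl <- integer(length(pos))
  rep_pos <- NA_integer_
  members <- integer(0)
  k <- 0L
  modal <- function(v) {
    tb <- table(v)
    best <- names(tb)[tb == max(tb)]
    best <- as.integer(best)
    if (strand == "+") max(best) else min(best)
  }
  for (i in ord) {
    if (k == 0L || abs(pos[i] - rep_pos) > window) {
      k <- k + 1L
      members <- pos[i]
    } else {
      members <- c(members, pos[i])
    }
    rep_pos <- modal(members)
    cl[i] <- k
  }
  cl
}

#' Detect alternative polyadenylation sites
#'
#' @param ends Tibble of 3' ends: `gene_id`, `strand`, `position` (1-based
#'   final transcribed base), optionally `chrom` (carried through).
#' @param group_window Maximum distance (bp) of an end from the cluster
#'   representative during greedy grouping.
#' @param min_support Minimum FLNC reads per accepted site.
#' @param exclusion A site within this distance (bp) of an already accepted
#'   site of the same gene is rejected. Acceptance order is descending
#'   support, ties going to the most 3'-distal site.
#' @return Tibble `gene_id`, `chrom` (if given), `strand`, `position`
#'   (cluster representative), `support`, `rank` (acceptance order within
#'   gene). Any two sites of one gene are more than `exclusion` bp apart.
#' @export
detect_apa <- function(ends, group_window = 5L, min_support = 2L,
                       exclusion = 15L) {
  empty <- tibble(gene_id = character(0), chrom = character(0),
                  strand = character(0), position = integer(0),
                  support = integer(0), rank = integer(0))
  if (nrow(ends) == 0L) return(empty)
  if (!strand_ok(ends$strand)) abort("strand must be '+' or '-'")
  has_chrom <- "chrom" %in% names(ends)
  out <- list()
  for (grp in split(ends, paste(ends$gene_id, ends$strand, sep = "\r"))) {
    strand <- grp$strand[1L]
    cl <- cluster_ends(grp$position, strand, group_window)
    sites <- lapply(split(grp$position, cl), function(v) {
      tb <- table(v)
      best <- as.integer(names(tb)[tb == max(tb)])
      rep_pos <- if (strand == "+") max(best) else min(best)
      c(rep_pos, length(v))
    })
    sm <- do.call(rbind, sites)
    sm <- sm[sm[, 2L] >= min_support, , drop = FALSE]
    if (!nrow(sm)) next
    # acceptance: descending support, ties most 3'-distal first
    distal <- if (strand == "+") -sm[, 1L] else sm[, 1L]
    sm <- sm[order(-sm[, 2L], distal), , drop = FALSE]
    accepted <- matrix(integer(0), ncol = 2L)
    for (r in seq_len(nrow(sm))) {
      if (nrow(accepted) &&
          any(abs(accepted[, 1L] - sm[r, 1L]) <= exclusion)) next
      accepted <- rbind(accepted, sm[r, , drop = FALSE])
    }
    out[[length(out) + 1L]] <- tibble(
      gene_id = grp$gene_id[1L],
      chrom = if (has_chrom) grp$chrom[1L] else NA_character_,
      strand = strand,
      position = as.integer(accepted[, 1L]),
      support = as.integer(accepted[, 2L]),
      rank = seq_len(nrow(accepted))
    )
  }
  if (!length(out)) return(empty)
  res <- bind_rows(out) |> arrange(.data$gene_id, .data$rank)
  if (!has_chrom) res$chrom <- NULL
  res
}

#' Per-gene APA statistics
#'
#' @param sites Output of [detect_apa()].
#' @return Tibble `gene_id`, `n_sites`, `multi_apa` (more than one site).
#' @export
apa_gene_stats <- function(sites) {
  if (nrow(sites) == 0L) {
    return(tibble(gene_id = character(0), n_sites = integer(0),
                  multi_apa = logical(0)))
  }
  sites |>
    dplyr::count(.data$gene_id, name = "n_sites") |>
    mutate(multi_apa = .data$n_sites > 1L)
}
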