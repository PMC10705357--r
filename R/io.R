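# Format readers and writers shared by all stages. File formats follow their
# standards (GFF3/BED/SAM coordinate conventions); tibbles inside the package
# stay 0-based half-open.

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences (or a `DNAStringSet`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(unlist(x))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector; names are truncated at the first space.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a transcript annotation as GFF3
#'
#' Emits gene / transcript / exon features with `ID`/`Parent` links.
#' Coordinates are converted from the package-internal 0-based half-open
#' convention to the 1-based inclusive GFF3 convention.
#'
#' @param annotation Exon-level tibble with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end` (0-based half-open)
#'   and optionally `biotype`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(annotation)))
  if (nrow(annotation) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  genes <- annotation |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1L], strand = .data$strand[1L],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  txs <- annotation |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(chrom = .data$chrom[1L], strand = .data$strand[1L],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  mk <- function(df, type, id, parent) {
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = df$strand
    )
    S4Vectors::mcols(gr)$source <- "isoscope"
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
      if (is.null(parent)) rep(list(character(0)), nrow(df)) else as.list(parent)
    )
    gr
  }
  gr <- c(
    mk(genes, "gene", genes$gene_id, NULL),
    mk(txs, "transcript", txs$transcript_id, txs$gene_id),
    mk(annotation, "exon", NA_character_, annotation$transcript_id)
  )
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation into an exon-level tibble
#'
#' @param path GFF3 path.
#' @return Tibble with one row per exon: `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open).
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  empty <- tibble(gene_id = character(0), transcript_id = character(0),
                  chrom = character(0), strand = character(0),
                  start = integer(0), end = integer(0))
  if (length(g) == 0L) return(empty)
  type <- as.character(g$type)
  first_parent <- function(p) {
    vapply(as.list(p), function(v) if (length(v)) v[[1L]] else NA_character_,
           character(1))
  }
  tx_parent <- setNames(first_parent(g$Parent), as.character(g$ID))
  ex <- g[type == "exon"]
  if (length(ex) == 0L) return(empty)
  tx_id <- first_parent(ex$Parent)
  gene_id <- unname(tx_parent[tx_id])
  gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]
  tibble(
    gene_id = gene_id,
    transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex)
  ) |> arrange(.data$transcript_id, .data$start)
}

#' Write spliced alignments as SAM
#'
#' One record per alignment segment; exon blocks become `M` runs separated by
#' `N` gaps, unaligned read ends become soft clips. Percent identity and
#' read-fraction coverage travel in the `XI`/`XC` tags.
#'
#' @param alignments Alignment tibble (see [simulate_isoseq()]): `read_id`,
#'   `segment`, `chrom`, `strand`, `blocks`, `query_start`, `query_end`,
#'   `read_len`, `identity`, `read_coverage`.
#' @param seqlens Named integer vector of chromosome lengths.
#' @param path Output path.
#' @param reads Optional named character vector of trimmed read sequences in
#'   transcript (sense) orientation; used to fill the SEQ column.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, seqlens, path, reads = NULL) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens)),
    "@PG\tID:isoscope\tPN:isoscope"
  )
  recs <- character(nrow(alignments))
  if (nrow(alignments)) {
    for (i in seq_len(nrow(alignments))) {
      a <- alignments[i, ]
      b <- a$blocks[[1L]]
      widths <- b[, 2L] - b[, 1L]
      gaps <- if (nrow(b) > 1L) b[-1L, 1L] - b[-nrow(b), 2L] else integer(0)
      gap_ops <- c(if (length(gaps)) paste0(gaps, "N") else character(0), "")
      body <- paste0(widths, "M", gap_ops[seq_along(widths)], collapse = "")
      rl <- a$read_len
      if (a$strand == "+") {
        clip5 <- a$query_start
        clip3 <- rl - a$query_end
      } else {
        clip5 <- rl - a$query_end
        clip3 <- a$query_start
      }
      cigar <- paste0(if (clip5 > 0) paste0(clip5, "S") else "", body,
                      if (clip3 > 0) paste0(clip3, "S") else "")
      flag <- (if (a$strand == "-") 16L else 0L) +
        (if (a$segment > 1L) 2048L else 0L)
      seq <- "*"
      if (!is.null(reads) && a$read_id %in% names(reads)) {
        seq <- reads[[a$read_id]]
        if (a$strand == "-") seq <- revcomp(seq)
      }
      recs[i] <- paste(
        a$read_id, flag, a$chrom, b[1L, 1L] + 1L, 60L, cigar, "*", 0L, 0L,
        seq, "*",
        sprintf("XI:f:%.6f", a$identity),
        sprintf("XC:f:%.6f", a$read_coverage),
        sep = "\t"
      )
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read spliced alignments from SAM/BAM
#'
#' Requires the suggested packages Rsamtools and GenomicAlignments. `N` cigar
#' gaps delimit exon blocks; `XI`/`XC` tags (if present) populate identity and
#' read coverage.
#'
#' @param path SAM or BAM path.
#' @return Alignment tibble with `read_id`, `segment`, `chrom`, `strand`,
#'   `blocks` (list of 0-based half-open matrices), `identity`,
#'   `read_coverage`.
#' @export
read_sam <- function(path) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("package '%s' is required to read SAM/BAM", pkg))
    }
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = c("XI", "XC"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  if (length(gal) == 0L) {
    return(tibble(read_id = character(0), segment = integer(0),
                  chrom = character(0), strand = character(0),
                  blocks = list(), identity = double(0),
                  read_coverage = double(0)))
  }
  grl <- GenomicAlignments::grglist(gal)
  blocks <- lapply(seq_along(grl), function(i) {
    r <- IRanges::ranges(grl[[i]])
    as_blocks(IRanges::start(r) - 1L, IRanges::end(r))
  })
  meta <- S4Vectors::mcols(gal)
  xi <- meta$XI %||% rep(NA_real_, length(gal))
  xc <- meta$XC %||% rep(NA_real_, length(gal))
  out <- tibble(
    read_id = meta$qname,
    supplementary = bitwAnd(meta$flag, 2048L) > 0L,
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    strand = as.character(GenomicAlignments::strand(gal)),
    blocks = blocks,
    identity = as.double(xi),
    read_coverage = as.double(xc)
  )
  out |>
    group_by(.data$read_id) |>
    mutate(segment = order(order(.data$supplementary,
                                 vapply(.data$blocks, function(b) b[1L, 1L],
                                        double(1))))) |>
    ungroup() |>
    select(-"supplementary") |>
    select("read_id", "segment", dplyr::everything())
}

#' Write a tibble as TSV with a commented header
#'
#' Every table written by the pipeline declares its coordinate convention in
#' `#`-prefixed comment lines that [read_isoscope_tsv()] skips.
#'
#' @param x Tibble to write. List-columns named `blocks` are serialized as
#'   `start-end,start-end` strings.
#' @param path Output path.
#' @param comment Character vector of comment lines (without the leading `#`).
#' @return Invisibly, `path`.
#' @export
write_isoscope_tsv <- function(x, path, comment = character(0)) {
  if ("blocks" %in% names(x) && is.list(x$blocks)) {
    x$blocks <- vapply(x$blocks, format_blocks, character(1))
  }
  for (nm in names(x)) {
    if (is.list(x[[nm]])) {
      x[[nm]] <- vapply(x[[nm]], function(v) paste(v, collapse = ","),
                        character(1))
    }
  }
  writeLines(paste0("# ", c("isoscope TSV; coordinates 0-based half-open",
                            comment)), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_isoscope_tsv()]
#'
#' @param path TSV path.
#' @return A tibble; a serialized `blocks` column is restored to a list of
#'   matrices.
#' @export
read_isoscope_tsv <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if ("blocks" %in% names(x) && is.character(x$blocks)) {
    x$blocks <- parse_blocks(x$blocks)
  }
  x
}

#' Write genomic features as BED6
#'
#' @param x Tibble with `chrom`, `start`, `end` (0-based half-open), `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   x$name, as.integer(x$score), x$strand)
  writeLines(lines, path)
  invisible(path)
}
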