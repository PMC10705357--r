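# Shared helpers. All genomic intervals inside the package are 0-based
# half-open [start, end); conversion to 1-based inclusive happens only in the
# format writers/readers (GFF3, SAM, BED).

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed tables in sequencing reports
#' conventionally round half up, so shares computed here use this variant.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic child seed for a pipeline stage, so adding a stage never
# perturbs the random draws of earlier stages.
child_seed <- function(root_seed, stage) {
  as.integer((as.double(root_seed) * 7919 + stage * 104729) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- exon-block helpers -----------------------------------------------------

# blocks: integer matrix, columns start/end, 0-based half-open, sorted.
as_blocks <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1L]), , drop = FALSE]
}

check_blocks <- function(blocks) {
  if (!is.matrix(blocks) || ncol(blocks) != 2L || nrow(blocks) < 1L) {
    abort("malformed alignment: blocks must be a two-column matrix")
  }
  if (any(blocks[, 2L] <= blocks[, 1L])) {
    abort("malformed alignment: block end must exceed block start")
  }
  if (nrow(blocks) > 1L) {
    if (is.unsorted(blocks[, 1L], strictly = TRUE) ||
        any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L])) {
      abort("malformed alignment: blocks must be sorted and non-overlapping")
    }
  }
  invisible(blocks)
}

blocks_width <- function(blocks) sum(blocks[, 2L] - blocks[, 1L])

# Introns between consecutive blocks, as a matrix of 0-based half-open
# [start, end) genomic intervals. Zero rows for mono-exonic structures.
blocks_introns <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = blocks[-n, 2L], end = blocks[-1L, 1L])
}

# Canonical string key of a junction chain; "" for mono-exonic.
blocks_chain <- function(blocks) {
  intr <- blocks_introns(blocks)
  if (nrow(intr) == 0L) return("")
  paste(intr[, 1L], intr[, 2L], sep = "-", collapse = ";")
}

chain_introns <- function(chain) {
  if (is.na(chain) || !nzchar(chain)) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  parts <- strsplit(strsplit(chain, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

format_blocks <- function(blocks) {
  paste(blocks[, 1L], blocks[, 2L], sep = "-", collapse = ",")
}

parse_blocks <- function(x) {
  lapply(x, function(s) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, as.integer))
    colnames(m) <- c("start", "end")
    m
  })
}

# Genomic sub-blocks covering the transcript-coordinate interval [from, to)
# (0-based, in 5'->3' transcript orientation; strand-aware).
blocks_subset <- function(blocks, strand, from, to) {
  n <- nrow(blocks)
  lens <- blocks[, 2L] - blocks[, 1L]
  ord <- if (strand == "-") rev(seq_len(n)) else seq_len(n)
  cum <- cumsum(lens[ord])
  t_start <- c(0L, head(cum, -1L))
  out <- list()
  for (i in seq_len(n)) {
    a <- max(from, t_start[i])
    b <- min(to, cum[i])
    if (b <= a) next
    la <- a - t_start[i]
    lb <- b - t_start[i]
    j <- ord[i]
    if (strand == "-") {
      out[[length(out) + 1L]] <- c(blocks[j, 2L] - lb, blocks[j, 2L] - la)
    } else {
      out[[length(out) + 1L]] <- c(blocks[j, 1L] + la, blocks[j, 1L] + lb)
    }
  }
  if (!length(out)) return(cbind(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m[order(m[, 1L]), , drop = FALSE]
}

# Spliced transcript sequence (5'->3') for exon blocks on `chrom`.
transcript_seq <- function(genome, chrom, strand, blocks) {
  seqs <- substring(genome[[chrom]], blocks[, 1L] + 1L, blocks[, 2L])
  s <- paste0(seqs, collapse = "")
  if (strand == "-") revcomp(s) else s
}

strand_ok <- function(x) all(x %in% c("+", "-"))

new_ids <- function(prefix, n) {
  if (n == 0L) return(character(0))
  sprintf("%s_%06d", prefix, seq_len(n))
}
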