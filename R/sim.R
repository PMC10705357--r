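# Seeded generator of a toy genome, annotation, full-length reads, spliced
# alignments and ground truth. The generator's job is structural realism:
# multi-exon gene models whose isoform variants produce known AS events,
# reads carrying 5'/3' primers and poly(A) tails, 5'-degraded copies, 3'-end
# scatter around true poly(A) sites, inter-chromosomal fusion chimeras,
# noncoding transcripts and configurable per-base substitution error.

#' Simulation configuration
#'
#' Validates and returns the configuration for [simulate_isoseq()]. Ranges
#' are length-2 integer vectors `c(min, max)` sampled uniformly.
#'
#' @param seed Integer root seed. Per-stage child seeds are derived from it so
#'   adding a stage never perturbs the draws of earlier stages.
#' @param n_chroms,chrom_len Number and length (bp) of toy chromosomes.
#' @param n_genes Number of gene loci.
#' @param isoforms_per_gene Range of isoforms per gene; genes whose master
#'   model has fewer than five exons stay single-isoform.
#' @param exons_per_isoform Range of exons in a gene's master isoform.
#' @param frac_degraded_reads Fraction of reads emitted as 5'-degraded copies
#'   (multi-exon sources only; the cut always removes at least one junction).
#' @param frac_fusion_reads Fraction of reads emitted as two-gene chimeras.
#' @param frac_artifact_reads Fraction of reads with a missing primer/poly(A)
#'   or an internal primer (classification artifacts).
#' @param frac_same_chrom_fusion Of fusion reads, fraction whose partner gene
#'   sits on the same chromosome at >= 12 kb (exercises the distance rule);
#'   the rest are inter-chromosomal.
#' @param apa_sites_per_gene Range of poly(A) sites per gene, spaced 60 bp.
#' @param end_scatter_sd SD (bp) of the per-read 3'-end scatter around the
#'   chosen poly(A) site.
#' @param per_base_error Per-base substitution probability applied to the
#'   transcript insert (primers and poly(A) tails are kept error-free).
#' @param polya_len Range of appended poly(A) tail lengths.
#' @param primer_5p,primer_3p Primer sequences. The sense read layout is
#'   `primer_5p + insert + poly(A) + revcomp(primer_3p)`.
#' @param reads_per_isoform Range of reads per isoform.
#' @param frac_noncoding_genes Fraction of genes that are noncoding (no
#'   protein-database hits, low coding-potential score, exons >= 220 bp).
#' @param n_lnc_candidates Number of placed lncRNA candidate intervals
#'   (intergenic/intronic/sense/antisense by construction) emitted in the
#'   ground truth for positional-classification tests; these carry no reads.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_len = 500000L,
                       n_genes = 20L,
                       isoforms_per_gene = c(2L, 4L),
                       exons_per_isoform = c(1L, 8L),
                       frac_degraded_reads = 0.15,
                       frac_fusion_reads = 0.02,
                       frac_artifact_reads = 0.05,
                       frac_same_chrom_fusion = 0.2,
                       apa_sites_per_gene = c(1L, 3L),
                       end_scatter_sd = 2,
                       per_base_error = 0,
                       polya_len = c(20L, 60L),
                       primer_5p = "AAGCAGTGGTATCAACGCAGAGTACATGGG",
                       primer_3p = "GTACTCTGCGTTGGTTCCACTAGTCTGCGT",
                       reads_per_isoform = c(2L, 5L),
                       frac_noncoding_genes = 0.2,
                       n_lnc_candidates = 20L) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    exons_per_isoform = as.integer(exons_per_isoform),
    frac_degraded_reads = frac_degraded_reads,
    frac_fusion_reads = frac_fusion_reads,
    frac_artifact_reads = frac_artifact_reads,
    frac_same_chrom_fusion = frac_same_chrom_fusion,
    apa_sites_per_gene = as.integer(apa_sites_per_gene),
    end_scatter_sd = end_scatter_sd,
    per_base_error = per_base_error,
    polya_len = as.integer(polya_len),
    primer_5p = toupper(primer_5p), primer_3p = toupper(primer_3p),
    reads_per_isoform = as.integer(reads_per_isoform),
    frac_noncoding_genes = frac_noncoding_genes,
    n_lnc_candidates = as.integer(n_lnc_candidates)
  )
  fracs <- c("frac_degraded_reads", "frac_fusion_reads",
             "frac_artifact_reads", "frac_same_chrom_fusion",
             "per_base_error", "frac_noncoding_genes")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("invalid configuration: '%s' must be a fraction in [0, 1]", f))
    }
  }
  ranges <- c("isoforms_per_gene", "exons_per_isoform", "apa_sites_per_gene",
              "polya_len", "reads_per_isoform")
  for (f in ranges) {
    v <- cfg[[f]]
    if (length(v) != 2L || anyNA(v) || v[1L] > v[2L] || v[1L] < 1L) {
      abort(sprintf(
        "invalid configuration: '%s' must be an integer range c(min, max) with 1 <= min <= max", f))
    }
  }
  for (f in c("seed", "n_chroms", "chrom_len", "n_genes", "n_lnc_candidates")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L) {
      abort(sprintf("invalid configuration: '%s' must be a non-negative integer", f))
    }
  }
  for (f in c("primer_5p", "primer_3p")) {
    if (!nzchar(cfg[[f]]) || grepl("[^ACGT]", cfg[[f]])) {
      abort(sprintf("invalid configuration: '%s' must be a non-empty ACGT string", f))
    }
  }
  structure(cfg, class = "sim_config")
}

sample1 <- function(range) {
  if (range[1L] == range[2L]) range[1L] else sample(range[1L]:range[2L], 1L)
}

sim_libraries <- c("F0-2k", "F2k+", "M0-2k", "M2k+")

as_event_cycle <- c("SKIP", "IR", "AE", "MSKIP", "MIR",
                    "XSKIP", "XIR", "XAE", "XMSKIP", "XMIR")

# Build a variant isoform's blocks from the master blocks. Anchors are chosen
# in genomic exon order; only internal splice sites are perturbed so variant
# chains are never 3'-anchored suffixes of another isoform's chain (those are
# reserved for implanted degradation).
variant_blocks <- function(blocks, type, anchor) {
  n <- nrow(blocks)
  b <- blocks
  drop_exons <- function(b, idx) b[-idx, , drop = FALSE]
  merge_exons <- function(b, from, to) {
    b[from, 2L] <- b[to, 2L]
    b[-((from + 1L):to), , drop = FALSE]
  }
  switch(type,
    SKIP = {
      j <- min(max(anchor, 2L), n - 1L)
      drop_exons(b, j)
    },
    MSKIP = {
      j <- min(max(anchor, 2L), n - 2L)
      drop_exons(b, c(j, j + 1L))
    },
    IR = {
      # keep both terminal introns intact so the variant chain is never a
      # 3'-anchored suffix of the master (reserved for degradation)
      i <- min(max(anchor, 2L), n - 2L)
      merge_exons(b, i, i + 1L)
    },
    MIR = {
      i <- min(max(anchor, 2L), n - 3L)
      merge_exons(b, i, i + 2L)
    },
    AE = {
      k <- min(max(anchor, 2L), n - 1L)
      b[k, 2L] <- b[k, 2L] + 24L
      b
    },
    XSKIP = {
      j <- min(max(anchor, 2L), n - 1L)
      b <- drop_exons(b, j)
      b[j - 1L, 2L] <- b[j - 1L, 2L] - 3L
      b
    },
    XMSKIP = {
      j <- min(max(anchor, 2L), n - 2L)
      b <- drop_exons(b, c(j, j + 1L))
      b[j - 1L, 2L] <- b[j - 1L, 2L] - 3L
      b
    },
    XIR = {
      i <- min(max(anchor, 2L), n - 2L)
      b <- merge_exons(b, i, i + 1L)
      b[i, 1L] <- b[i, 1L] + 3L
      b
    },
    XMIR = {
      i <- min(max(anchor, 2L), n - 3L)
      b <- merge_exons(b, i, i + 2L)
      b[i, 1L] <- b[i, 1L] + 3L
      b
    },
    XAE = {
      k <- min(max(anchor, 2L), n - 1L)
      b[k, 2L] <- b[k, 2L] + 24L
      b[k + 1L, 1L] <- b[k + 1L, 1L] + 3L
      b
    },
    abort(sprintf("unknown variant type '%s'", type))
  )
}

variant_units <- function(type) {
  switch(type, SKIP = 1L, XSKIP = 1L, IR = 1L, XIR = 1L, AE = 1L, XAE = 1L,
         MSKIP = 2L, XMSKIP = 2L, MIR = 2L, XMIR = 2L)
}

#' Implant 5'-terminal degradation into an exon-block structure
#'
#' Removes `trim` transcript bases from the 5' end, preserving the 3'-anchored
#' junction structure: the result's junction chain is always a (possibly
#' improper) 3'-anchored suffix of the source chain.
#'
#' @param blocks Exon-block matrix (0-based half-open, sorted).
#' @param strand `"+"` or `"-"`.
#' @param trim Number of transcript bases to remove from the 5' end;
#'   `trim = 0` returns the input unchanged.
#' @return The trimmed block matrix, or `NULL` (with a warning) when fewer
#'   than 20 bases would remain.
#' @export
implant_degradation <- function(blocks, strand, trim) {
  check_blocks(blocks)
  stopifnot(strand %in% c("+", "-"), trim >= 0)
  len <- blocks_width(blocks)
  if (trim == 0L) return(blocks)
  if (len - trim < 20L) {
    warn(sprintf("degradation skipped: %d bp trim leaves fewer than 20 bases", trim))
    return(NULL)
  }
  blocks_subset(blocks, strand, trim, len)
}

sim_genome <- function(cfg) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  setNames(vapply(chroms, function(ch) {
    paste0(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE,
                  prob = c(0.22, 0.28, 0.28, 0.22)), collapse = "")
  }, character(1)), chroms)
}

empty_gene_tables <- function() {
  list(
    genes = tibble(gene_id = character(0), chrom = character(0),
                   strand = character(0), start = integer(0),
                   end = integer(0), n_exons = integer(0),
                   noncoding = logical(0)),
    isoforms = tibble(gene_id = character(0), isoform_id = character(0),
                      chrom = character(0), strand = character(0),
                      blocks = list(), chain = character(0),
                      variant_type = character(0), biotype = character(0)),
    apa = tibble(gene_id = character(0), strand = character(0),
                 chrom = character(0), site_rank = integer(0),
                 position = integer(0), coord0 = integer(0)),
    as_truth = tibble(gene_id = character(0), iso_master = character(0),
                      iso_variant = character(0), type = character(0),
                      n_units = integer(0))
  )
}

sim_genes <- function(cfg) {
  if (cfg$n_genes == 0L) return(empty_gene_tables())
  nc_ids <- sort(sample(cfg$n_genes, round(cfg$frac_noncoding_genes * cfg$n_genes)))
  cursor <- setNames(rep(2000L, cfg$n_chroms), sprintf("chr%d", seq_len(cfg$n_chroms)))
  cycle_pos <- 0L
  genes <- list(); isoforms <- list(); apa <- list(); as_truth <- list()
  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("gene_%03d", g)
    chrom <- sprintf("chr%d", (g - 1L) %% cfg$n_chroms + 1L)
    noncoding <- g %in% nc_ids
    n_ex <- sample1(cfg$exons_per_isoform)
    ex_min <- if (noncoding) 220L else 120L
    ex_lens <- sample(ex_min:400L, n_ex, replace = TRUE)
    in_lens <- if (n_ex > 1L) sample(300L:1500L, n_ex - 1L, replace = TRUE) else integer(0)
    strand <- sample(c("+", "-"), 1L)
    k_apa <- sample1(cfg$apa_sites_per_gene)
    gap <- sample(3000L:8000L, 1L)
    left_ext <- if (strand == "-") 60L * k_apa + 60L else 0L
    start <- cursor[[chrom]] + gap + left_ext
    starts <- start + c(0L, cumsum(ex_lens[-n_ex] + in_lens))
    blocks <- as_blocks(starts, starts + ex_lens)
    gene_end <- blocks[n_ex, 2L]
    right_ext <- if (strand == "+") 60L * k_apa + 60L else 0L
    if (gene_end + right_ext + 1000L > cfg$chrom_len) {
      abort("invalid configuration: 'chrom_len' too small for 'n_genes' gene models")
    }
    cursor[[chrom]] <- gene_end + right_ext
    n_iso <- if (n_ex >= 5L) sample1(cfg$isoforms_per_gene) else 1L
    # poly(A) sites walk 3'-ward from the master transcript end
    apa_pos <- if (strand == "+") {
      blocks[n_ex, 2L] + 60L * (seq_len(k_apa) - 1L)
    } else {
      blocks[1L, 1L] - 60L * (seq_len(k_apa) - 1L)
    }
    apa_pos1 <- if (strand == "+") apa_pos else apa_pos + 1L
    apa[[g]] <- tibble(gene_id = gene_id, strand = strand, chrom = chrom,
                       site_rank = seq_len(k_apa),
                       position = apa_pos1, coord0 = apa_pos)
    master_chain <- blocks_chain(blocks)
    iso_rows <- list(tibble(
      gene_id = gene_id, isoform_id = paste0(gene_id, ".t1"), chrom = chrom,
      strand = strand, blocks = list(blocks), chain = master_chain,
      variant_type = "master", biotype = if (noncoding) "lncRNA" else "protein_coding"
    ))
    if (n_iso > 1L) {
      for (v in seq_len(n_iso - 1L)) {
        cycle_pos <- cycle_pos + 1L
        type <- as_event_cycle[(cycle_pos - 1L) %% length(as_event_cycle) + 1L]
        vb <- variant_blocks(blocks, type, anchor = 1L + v)
        iso_id <- sprintf("%s.t%d", gene_id, v + 1L)
        vchain <- blocks_chain(vb)
        iso_rows[[v + 1L]] <- tibble(
          gene_id = gene_id, isoform_id = iso_id, chrom = chrom,
          strand = strand, blocks = list(vb), chain = vchain,
          variant_type = type,
          biotype = if (noncoding) "lncRNA" else "protein_coding"
        )
        as_truth[[length(as_truth) + 1L]] <- tibble(
          gene_id = gene_id, iso_master = paste0(gene_id, ".t1"),
          iso_variant = iso_id, type = type, n_units = variant_units(type)
        )
      }
    }
    isoforms[[g]] <- bind_rows(iso_rows)
    genes[[g]] <- tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = blocks[1L, 1L], end = gene_end,
                         n_exons = n_ex, noncoding = noncoding)
  }
  list(genes = bind_rows(genes), isoforms = bind_rows(isoforms),
       apa = bind_rows(apa), as_truth = bind_rows(as_truth))
}

# Apply the per-read poly(A) site + 3' scatter to an isoform's blocks.
apply_three_prime_end <- function(blocks, strand, site0, delta) {
  n <- nrow(blocks)
  if (strand == "+") {
    new_end <- max(site0 + delta, blocks[n, 1L] + 20L)
    blocks[n, 2L] <- new_end
  } else {
    new_start <- min(site0 + delta, blocks[1L, 2L] - 20L)
    blocks[1L, 1L] <- new_start
  }
  blocks
}

mutate_seq <- function(seq, n_err) {
  if (n_err == 0L) return(list(seq = seq, pos = integer(0)))
  len <- nchar(seq)
  pos <- sort(sample(len, n_err))
  chars <- strsplit(seq, "")[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  list(seq = paste0(chars, collapse = ""), pos = pos)
}

sim_lnc_candidates <- function(cfg, genes, isoforms) {
  if (cfg$n_lnc_candidates == 0L || nrow(genes) == 0L) {
    return(tibble(candidate_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  placement_class = character(0)))
  }
  classes <- rep(c("intergenic", "intronic", "sense", "antisense"),
                 length.out = cfg$n_lnc_candidates)
  multi <- genes$gene_id[genes$n_exons >= 2L]
  rows <- list()
  for (i in seq_len(cfg$n_lnc_candidates)) {
    cls <- classes[i]
    if (cls %in% c("intronic") && length(multi) == 0L) cls <- "intergenic"
    if (cls == "intergenic") {
      # middle of the gap downstream of a gene
      g <- genes[sample(nrow(genes), 1L), ]
      same <- genes[genes$chrom == g$chrom & genes$start > g$end, ]
      gap_end <- if (nrow(same)) min(same$start) else g$end + 3000L
      mid <- g$end + (gap_end - g$end) %/% 2L
      len <- sample(300L:800L, 1L)
      st <- mid - len %/% 2L
      rows[[i]] <- tibble(chrom = g$chrom, strand = sample(c("+", "-"), 1L),
                          start = st, end = st + len, placement_class = cls)
    } else if (cls == "intronic") {
      gid <- sample(multi, 1L)
      iso <- isoforms[isoforms$gene_id == gid & isoforms$variant_type == "master", ]
      b <- iso$blocks[[1L]]
      intr <- blocks_introns(b)
      wide <- which(intr[, 2L] - intr[, 1L] >= 400L)
      if (!length(wide)) {
        rows[[i]] <- NULL; next
      }
      j <- wide[sample(length(wide), 1L)]
      st <- intr[j, 1L] + 50L
      en <- intr[j, 2L] - 50L
      if (en - st > 800L) en <- st + 800L
      rows[[i]] <- tibble(chrom = iso$chrom, strand = sample(c("+", "-"), 1L),
                          start = st, end = en, placement_class = cls)
    } else {
      g <- genes[sample(nrow(genes), 1L), ]
      iso <- isoforms[isoforms$gene_id == g$gene_id &
                        isoforms$variant_type == "master", ]
      b <- iso$blocks[[1L]]
      # anchor on the first genomic exon: AS variants never remove it, so the
      # candidate is never fully inside a variant's intron (which would win
      # the intronic precedence over sense/antisense)
      st <- max(0L, b[1L, 1L] - 150L)
      en <- b[1L, 1L] + min(200L, b[1L, 2L] - b[1L, 1L])
      strand <- if (cls == "sense") g$strand else setdiff(c("+", "-"), g$strand)
      rows[[i]] <- tibble(chrom = g$chrom, strand = strand,
                          start = st, end = en, placement_class = cls)
    }
  }
  out <- bind_rows(rows)
  out$candidate_id <- sprintf("lnc_cand_%03d", seq_len(nrow(out)))
  select(out, "candidate_id", dplyr::everything())
}

#' Simulate an Iso-Seq-style dataset with ground truth
#'
#' Generates a toy genome, a transcript annotation, full-length reads (5'
#' primer + insert + poly(A) + reverse-complemented 3' primer), spliced
#' alignments of the trimmed reads, and ground-truth tables for every
#' downstream stage. Identical `config` (including seed) yields byte-identical
#' outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `reads.fa`, `alignments.sam`, `pe_support.tsv`,
#'   `evidence.tsv`, `config.json` and `truth_*.tsv` there.
#' @return A list with elements `genome` (named character), `annotation`
#'   (exon tibble), `reads`, `alignments`, `pe_support`, `evidence`, `truth`
#'   (list of tibbles: `read_class`, `isoforms`, `apa`, `fusions`,
#'   `noncoding_genes`, `as_events`, `lnc_candidates`), `files`, `config`.
#' @export
simulate_isoseq <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genome <- with_seed(child_seed(cfg$seed, 1L), sim_genome(cfg))
  gs <- with_seed(child_seed(cfg$seed, 2L), sim_genes(cfg))
  lnc <- with_seed(child_seed(cfg$seed, 4L),
                   sim_lnc_candidates(cfg, gs$genes, gs$isoforms))
  rd <- with_seed(child_seed(cfg$seed, 3L),
                  sim_reads(cfg, genome, gs))
  annotation <- if (nrow(gs$isoforms) == 0L) {
    tibble(gene_id = character(0), transcript_id = character(0),
           chrom = character(0), strand = character(0),
           start = integer(0), end = integer(0), exon_rank = integer(0),
           biotype = character(0))
  } else {
    gs$isoforms |>
      mutate(exons = purrr::map(.data$blocks, function(b) {
        tibble(start = b[, 1L], end = b[, 2L])
      })) |>
      select("gene_id", transcript_id = "isoform_id", "chrom", "strand",
             "biotype", "exons") |>
      tidyr::unnest("exons") |>
      group_by(.data$transcript_id) |>
      mutate(exon_rank = if (.data$strand[1L] == "+") row_number()
             else rev(row_number())) |>
      ungroup()
  }
  truth_iso <- gs$isoforms
  truth_iso$blocks_str <- vapply(truth_iso$blocks, format_blocks, character(1))
  truth <- list(
    read_class = rd$read_class,
    isoforms = truth_iso,
    apa = gs$apa,
    fusions = rd$fusions,
    noncoding_genes = tibble(
      gene_id = if (nrow(gs$genes)) gs$genes$gene_id[gs$genes$noncoding]
      else character(0)),
    as_events = gs$as_truth,
    lnc_candidates = lnc
  )
  files <- NULL
  result <- list(genome = genome, annotation = annotation, reads = rd$reads,
                 alignments = rd$alignments, pe_support = rd$pe_support,
                 evidence = rd$evidence, truth = truth, genes = gs$genes,
                 config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(genome, p("genome.fa"))
    write_gff3(annotation, p("annotation.gff3"))
    write_fasta(setNames(rd$reads$sequence, rd$reads$read_id), p("reads.fa"))
    trimmed <- setNames(rd$reads$insert, rd$reads$read_id)
    write_sam(rd$alignments, vapply(genome, nchar, integer(1)),
              p("alignments.sam"), reads = trimmed)
    write_isoscope_tsv(rd$pe_support, p("pe_support.tsv"),
                       "paired-end support per read across the fusion junction")
    write_isoscope_tsv(rd$evidence, p("evidence.tsv"),
                       "database hits and coding-potential scores per true isoform")
    write_isoscope_tsv(rd$read_class, p("truth_read_class.tsv"))
    write_isoscope_tsv(select(truth$isoforms, -"blocks"), p("truth_isoforms.tsv"))
    write_isoscope_tsv(gs$apa, p("truth_apa.tsv"))
    write_isoscope_tsv(rd$fusions, p("truth_fusions.tsv"))
    write_isoscope_tsv(truth$noncoding_genes, p("truth_noncoding_genes.tsv"))
    write_isoscope_tsv(gs$as_truth, p("truth_as_events.tsv"))
    write_isoscope_tsv(lnc, p("truth_lnc_candidates.tsv"))
    jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- vapply(c("genome.fa", "annotation.gff3", "reads.fa",
                      "alignments.sam", "pe_support.tsv", "evidence.tsv",
                      "truth_read_class.tsv", "truth_isoforms.tsv",
                      "truth_apa.tsv", "truth_fusions.tsv",
                      "truth_noncoding_genes.tsv", "truth_as_events.tsv",
                      "truth_lnc_candidates.tsv", "config.json"), p,
                    character(1))
    result$files <- files
  }
  result
}

# Read/alignment synthesis; one pass over read "slots" (gene x isoform x n).
sim_reads <- function(cfg, genome, gs) {
  empty <- list(
    reads = tibble(read_id = character(0), sequence = character(0),
                   insert = character(0), library = character(0),
                   n_passes = integer(0)),
    alignments = tibble(read_id = character(0), segment = integer(0),
                        chrom = character(0), strand = character(0),
                        blocks = list(), query_start = integer(0),
                        query_end = integer(0), read_len = integer(0),
                        identity = double(0), read_coverage = double(0)),
    read_class = tibble(read_id = character(0), class = character(0),
                        library = character(0), gene_id = character(0),
                        isoform_id = character(0),
                        partner_gene_id = character(0), chain = character(0)),
    fusions = tibble(read_id = character(0), gene_a = character(0),
                     gene_b = character(0), same_chrom = logical(0)),
    pe_support = tibble(read_id = character(0), pe_count = integer(0)),
    evidence = tibble(chrom = character(0), strand = character(0),
                      chain = character(0), five_prime = integer(0),
                      isoform_id = character(0), hit_nr = logical(0),
                      hit_swissprot = logical(0), hit_cog = logical(0),
                      hit_kog = logical(0), cp_score = double(0))
  )
  iso <- gs$isoforms
  if (is.null(iso) || nrow(iso) == 0L) return(empty)
  genes <- gs$genes
  apa_by_gene <- split(gs$apa, gs$apa$gene_id)
  rcp3 <- revcomp(cfg$primer_3p)

  # fusion partners: master isoforms of other genes, inter-chromosomal or
  # same-chromosome with a >= 12 kb gap
  masters <- iso[iso$variant_type == "master", ]
  master_len <- vapply(masters$blocks, blocks_width, double(1))

  slots <- tidyr::uncount(
    mutate(iso, n_reads = vapply(seq_len(nrow(iso)),
                                 function(i) sample1(cfg$reads_per_isoform),
                                 integer(1))),
    .data$n_reads
  )
  n_slots <- nrow(slots)

  # pre-draw read classes, then guarantee every isoform at least one
  # full-length read so its junction chain is observable
  u <- runif(n_slots)
  cls0 <- rep("full_length", n_slots)
  cls0[u < cfg$frac_fusion_reads + cfg$frac_artifact_reads +
         cfg$frac_degraded_reads] <- "degraded"
  cls0[u < cfg$frac_fusion_reads + cfg$frac_artifact_reads] <- "artifact"
  cls0[u < cfg$frac_fusion_reads] <- "fusion"
  mono <- vapply(slots$blocks, nrow, integer(1)) < 2L
  cls0[mono & cls0 == "degraded"] <- "full_length"
  for (id in unique(slots$isoform_id)) {
    idx <- which(slots$isoform_id == id)
    if (!any(cls0[idx] == "full_length")) {
      cand <- idx[cls0[idx] != "fusion"]
      cls0[if (length(cand)) cand[1L] else idx[1L]] <- "full_length"
    }
  }
  # round-robin poly(A) site assignment per gene keeps per-site support even
  apa_ord <- stats::ave(seq_len(n_slots), slots$gene_id,
                        FUN = seq_along)
  reads <- vector("list", n_slots)
  alns <- vector("list", n_slots)
  rclass <- vector("list", n_slots)
  fus <- list()
  pe <- list()
  artifact_kind <- c("missing_5p", "missing_3p", "missing_polya", "internal_primer")
  art_i <- 0L

  for (i in seq_len(n_slots)) {
    s <- slots[i, ]
    read_id <- sprintf("read_%06d", i)
    library <- sample(sim_libraries, 1L)
    gene <- genes[genes$gene_id == s$gene_id, ]
    apa <- apa_by_gene[[s$gene_id]]
    class <- cls0[i]

    site <- apa[(apa_ord[i] - 1L) %% nrow(apa) + 1L, ]
    delta <- as.integer(round(rnorm(1L, 0, cfg$end_scatter_sd)))
    blocks <- apply_three_prime_end(s$blocks[[1L]], s$strand, site$coord0, delta)
    partner_gene <- NA_character_
    segs <- NULL  # list of (chrom, strand, blocks, q0, q1)

    if (class == "degraded" && nrow(blocks) >= 2L) {
      lens <- blocks[, 2L] - blocks[, 1L]
      ord <- if (s$strand == "-") rev(seq_len(nrow(blocks))) else seq_len(nrow(blocks))
      cum <- cumsum(lens[ord])
      c_ex <- sample(2L:nrow(blocks), 1L)
      ex_len <- lens[ord][c_ex]
      off <- sample(5L:max(5L, ex_len - 30L), 1L)
      t_cut <- cum[c_ex - 1L] + off
      blocks <- blocks_subset(blocks, s$strand, t_cut, sum(lens))
    } else if (class == "degraded") {
      class <- "full_length"
    }

    if (class == "fusion") {
      cand_inter <- which(masters$chrom != s$chrom & master_len >= 400)
      g_here <- gene
      same_ok <- vapply(seq_len(nrow(masters)), function(k) {
        if (masters$chrom[k] != s$chrom || masters$gene_id[k] == s$gene_id) return(FALSE)
        pg <- genes[genes$gene_id == masters$gene_id[k], ]
        gap <- max(pg$start - g_here$end, g_here$start - pg$end)
        gap >= 12000L && master_len[k] >= 400
      }, logical(1))
      cand_same <- which(same_ok)
      use_same <- runif(1L) < cfg$frac_same_chrom_fusion && length(cand_same) > 0L
      cand <- if (use_same) cand_same else cand_inter
      if (length(cand) == 0L || blocks_width(blocks) < 400L) {
        class <- "full_length"
      } else {
        k <- cand[sample(length(cand), 1L)]
        pb <- masters$blocks[[k]]
        p_apa <- apa_by_gene[[masters$gene_id[k]]]
        p_site <- p_apa[sample(nrow(p_apa), 1L), ]
        p_delta <- as.integer(round(rnorm(1L, 0, cfg$end_scatter_sd)))
        pb <- apply_three_prime_end(pb, masters$strand[k], p_site$coord0, p_delta)
        lenA <- blocks_width(blocks); lenB <- blocks_width(pb)
        hA <- max(150L, min(lenA - 150L, lenA %/% 2L))
        hB <- max(150L, min(lenB - 150L, lenB %/% 2L))
        bA <- blocks_subset(blocks, s$strand, 0L, hA)
        bB <- blocks_subset(pb, masters$strand[k], lenB - hB, lenB)
        segs <- list(
          list(chrom = s$chrom, strand = s$strand, blocks = bA,
               q0 = 0L, q1 = hA),
          list(chrom = masters$chrom[k], strand = masters$strand[k],
               blocks = bB, q0 = hA, q1 = hA + hB)
        )
        partner_gene <- masters$gene_id[k]
        fus[[length(fus) + 1L]] <- tibble(
          read_id = read_id, gene_a = s$gene_id, gene_b = partner_gene,
          same_chrom = masters$chrom[k] == s$chrom
        )
        pe[[length(pe) + 1L]] <- tibble(read_id = read_id,
                                        pe_count = sample(2L:6L, 1L))
      }
    }

    if (is.null(segs)) {
      segs <- list(list(chrom = s$chrom, strand = s$strand, blocks = blocks,
                        q0 = 0L, q1 = blocks_width(blocks)))
    }
    insert <- paste0(vapply(segs, function(sg) {
      transcript_seq(genome, sg$chrom, sg$strand, sg$blocks)
    }, character(1)), collapse = "")
    ins_len <- nchar(insert)
    n_err <- if (cfg$per_base_error > 0) rbinom(1L, ins_len, cfg$per_base_error) else 0L
    mut <- mutate_seq(insert, n_err)
    insert <- mut$seq

    polya <- strrep("A", sample1(cfg$polya_len))
    p5 <- cfg$primer_5p; p3tail <- rcp3
    art <- NA_character_
    if (class == "artifact") {
      art_i <- art_i + 1L
      art <- artifact_kind[(art_i - 1L) %% 4L + 1L]
      if (art == "missing_5p") p5 <- ""
      if (art == "missing_3p") p3tail <- ""
      if (art == "missing_polya") polya <- ""
      if (art == "internal_primer") {
        mid <- ins_len %/% 2L
        insert_art <- paste0(substr(insert, 1L, mid), cfg$primer_5p,
                             substr(insert, mid + 1L, ins_len))
        insert <- insert_art
        ins_len <- nchar(insert)
      }
    }
    seq <- paste0(p5, insert, polya, p3tail)
    if (runif(1L) < 0.5) seq <- revcomp(seq)

    reads[[i]] <- tibble(read_id = read_id, sequence = seq, insert = insert,
                         library = library, n_passes = sample(7L:14L, 1L))
    rclass[[i]] <- tibble(
      read_id = read_id,
      class = if (class == "artifact") "artifact" else class,
      library = library, gene_id = s$gene_id, isoform_id = s$isoform_id,
      partner_gene_id = partner_gene,
      chain = if (class %in% c("full_length", "degraded"))
        blocks_chain(segs[[1L]]$blocks) else NA_character_,
      artifact_kind = art
    )
    if (class != "artifact") {
      seg_rows <- lapply(seq_along(segs), function(j) {
        sg <- segs[[j]]
        w <- blocks_width(sg$blocks)
        n_seg_err <- sum(mut$pos > sg$q0 & mut$pos <= sg$q1)
        tibble(read_id = read_id, segment = j, chrom = sg$chrom,
               strand = sg$strand, blocks = list(sg$blocks),
               query_start = sg$q0, query_end = sg$q1, read_len = ins_len,
               identity = 1 - n_seg_err / w, read_coverage = w / ins_len)
      })
      alns[[i]] <- bind_rows(seg_rows)
    }
  }

  # evidence table keyed by structural identity (chrom/strand/chain/5' end)
  evidence <- iso |>
    mutate(
      five_prime = vapply(seq_len(nrow(iso)), function(i) {
        b <- iso$blocks[[i]]
        if (iso$strand[i] == "+") b[1L, 1L] else b[nrow(b), 2L]
      }, integer(1)),
      noncoding = .data$biotype == "lncRNA",
      hit_nr = !.data$noncoding,
      hit_swissprot = !.data$noncoding & runif(nrow(iso)) < 0.8,
      hit_cog = !.data$noncoding & runif(nrow(iso)) < 0.5,
      hit_kog = !.data$noncoding & runif(nrow(iso)) < 0.5,
      cp_score = ifelse(.data$noncoding, runif(nrow(iso), 0, 0.25),
                        runif(nrow(iso), 0.5, 0.99))
    ) |>
    select("chrom", "strand", "chain", "five_prime", "isoform_id",
           "hit_nr", "hit_swissprot", "hit_cog", "hit_kog", "cp_score")

  list(
    reads = bind_rows(reads),
    alignments = if (length(alns)) bind_rows(alns) else empty$alignments,
    read_class = bind_rows(rclass),
    fusions = if (length(fus)) bind_rows(fus) else empty$fusions,
    pe_support = if (length(pe)) bind_rows(pe) else empty$pe_support,
    evidence = evidence
  )
}
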