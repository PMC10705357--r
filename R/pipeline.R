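# End-to-end orchestration: classify -> collapse -> degradation filter ->
# retention -> loci/novelty -> AS -> APA -> fusion -> lncRNA -> report.

#' Pipeline parameters
#'
#' All stage parameters with their defaults; unknown names are rejected.
#'
#' @param ... Name-value overrides of the defaults listed below.
#' @return A named list of class `isoscope_params`.
#' @export
isoscope_params <- function(...) {
  p <- list(
    primer_5p = "AAGCAGTGGTATCAACGCAGAGTACATGGG",
    primer_3p = "GTACTCTGCGTTGGTTCCACTAGTCTGCGT",
    max_mismatch = 2L, polya_min_len = 20L, polya_min_purity = 0.8,
    chimera_margin = 50L,
    mono_end_tol = 50L, pid_cut = 0.99, min_overlap = 0.2,
    fuzz = 10L,
    apa_group_window = 5L, apa_min_support = 2L, apa_exclusion = 15L,
    fusion_min_distance = 10000L, fusion_min_seg_cov = 0.10,
    fusion_min_total_cov = 0.99, fusion_min_pe = 2L,
    cp_cutoff = 0.364, lnc_min_len = 200L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) {
    abort(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")))
  }
  p[names(ov)] <- ov
  structure(p, class = "isoscope_params")
}

#' Run the full structural-annotation pipeline
#'
#' @param reads Read tibble (`read_id`, `sequence`, optional `library`).
#' @param alignments Spliced-alignment tibble for the trimmed reads (as from
#'   [simulate_isoseq()] or [read_sam()]). Reads classified non-FLNC are
#'   dropped; reads with several alignment segments go to fusion calling,
#'   single-segment reads to isoform collapse.
#' @param annotation Exon-level reference annotation tibble (as from
#'   [read_gff3()]).
#' @param pe_evidence Optional paired-end fusion-junction support tibble.
#' @param evidence Optional lncRNA evidence table (see [filter_lncrna()]);
#'   when absent the lncRNA stage is skipped.
#' @param junctions Optional short-read junction tibble for
#'   [add_junction_support()].
#' @param params [isoscope_params()].
#' @return An `isoscope_run` list: `classifications`, `library_stats`,
#'   `isoforms` (retained, with locus and novelty status), `removed_degraded`,
#'   `dropped_unsupported`, `loci`, `as_events`, `as_summary`, `apa_sites`,
#'   `apa_stats`, `fusion_candidates`, `fusion_summary`, `lncrna`,
#'   `lncrna_lengths`, `locus_length_bins`, `manifest`, `params`.
#' @export
run_pipeline <- function(reads, alignments, annotation,
                         pe_evidence = NULL, evidence = NULL,
                         junctions = NULL, params = isoscope_params()) {
  stopifnot(inherits(params, "isoscope_params"))
  cls <- classify_reads(reads, params$primer_5p, params$primer_3p,
                        max_mismatch = params$max_mismatch,
                        polya_min_len = params$polya_min_len,
                        polya_min_purity = params$polya_min_purity,
                        chimera_margin = params$chimera_margin)
  lib_stats <- if (nrow(cls) && "library" %in% names(cls)) {
    summarize_libraries(cls)
  } else {
    NULL
  }
  flnc_ids <- cls$read_id[cls$is_flnc]
  aln <- alignments[alignments$read_id %in% flnc_ids, , drop = FALSE]
  seg_counts <- table(aln$read_id)
  multi_ids <- names(seg_counts)[seg_counts > 1L]
  aln_collapse <- aln[!aln$read_id %in% multi_ids, , drop = FALSE]
  aln_fusion <- aln[aln$read_id %in% multi_ids, , drop = FALSE]

  iso0 <- collapse_isoforms(aln_collapse, mono_end_tol = params$mono_end_tol)
  deg <- filter_degraded(iso0, mono_end_tol = params$mono_end_tol)
  iso1 <- add_junction_support(deg$kept, junctions = junctions,
                               annotation = annotation)
  iso1 <- retention_filter(iso1, pid_cut = params$pid_cut)
  dropped <- iso1[!iso1$keep, , drop = FALSE]
  iso2 <- iso1[iso1$keep, , drop = FALSE]
  iso2 <- assign_loci(iso2, min_overlap = params$min_overlap)
  iso2 <- call_novelty(iso2, annotation, min_overlap = params$min_overlap)
  loci <- summarize_loci(iso2)

  events <- find_as_events(iso2, fuzz = params$fuzz)
  as_sum <- summarize_as_events(events)

  ends <- three_prime_ends(aln_collapse, iso2)
  apa <- detect_apa(ends, group_window = params$apa_group_window,
                    min_support = params$apa_min_support,
                    exclusion = params$apa_exclusion)
  apa_stats <- apa_gene_stats(apa)

  fus <- call_fusions(aln_fusion, annotation, pe_evidence = pe_evidence,
                      min_distance = params$fusion_min_distance,
                      min_seg_cov = params$fusion_min_seg_cov,
                      min_total_cov = params$fusion_min_total_cov,
                      min_pe = params$fusion_min_pe)
  fus_sum <- fusion_gene_summary(fus)

  lnc <- NULL; lnc_len <- NULL
  if (!is.null(evidence)) {
    lnc <- filter_lncrna(iso2, evidence, cp_cutoff = params$cp_cutoff,
                         min_len = params$lnc_min_len)
    lnc <- classify_position(lnc, annotation)
    lnc_len <- lncrna_length_summary(lnc)
  }

  manifest <- tibble(
    stage = c("reads", "flnc", "alignments", "isoforms_collapsed",
              "isoforms_degraded_removed", "isoforms_dropped_unsupported",
              "isoforms_retained", "loci", "novel_loci", "as_events",
              "apa_sites", "fusion_candidates", "fusion_reads",
              "lncrna_candidates"),
    records = c(nrow(reads), length(flnc_ids), nrow(aln), nrow(iso0),
                nrow(deg$removed), nrow(dropped), nrow(iso2), nrow(loci),
                sum(loci$status %in% "novel"), nrow(events), nrow(apa),
                nrow(fus), fus_sum$n_fusion_reads,
                if (is.null(lnc)) NA_integer_ else nrow(lnc))
  )
  structure(list(
    classifications = cls, library_stats = lib_stats,
    isoforms = iso2, removed_degraded = deg$removed,
    dropped_unsupported = dropped, loci = loci,
    as_events = events, as_summary = as_sum,
    apa_sites = apa, apa_stats = apa_stats,
    fusion_candidates = fus, fusion_summary = fus_sum,
    lncrna = lnc, lncrna_lengths = lnc_len,
    locus_length_bins = length_bin_shares(loci),
    manifest = manifest, params = params
  ), class = "isoscope_run")
}

#' @export
print.isoscope_run <- function(x, ...) {
  cat("<isoscope_run>\n")
  m <- x$manifest
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-28s %s\n", m$stage[i],
                ifelse(is.na(m$records[i]), "-", m$records[i])))
  }
  invisible(x)
}

#' Tidy an isoscope pipeline run
#'
#' @param x An `isoscope_run`.
#' @param ... Unused.
#' @return The per-stage record manifest as a tibble.
#' @exportS3Method generics::tidy
tidy.isoscope_run <- function(x, ...) x$manifest

#' One-row summary of an isoscope pipeline run
#'
#' @param x An `isoscope_run`.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @exportS3Method generics::glance
glance.isoscope_run <- function(x, ...) {
  m <- setNames(as.list(x$manifest$records), x$manifest$stage)
  tibble(
    n_reads = m$reads, n_flnc = m$flnc, n_isoforms = m$isoforms_retained,
    n_loci = m$loci, n_novel_loci = m$novel_loci,
    n_novel_isoforms = sum(x$isoforms$isoform_status %in% "novel"),
    n_as_events = m$as_events, n_apa_sites = m$apa_sites,
    n_fusion_reads = m$fusion_reads,
    n_lncrna = m$lncrna_candidates
  )
}
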