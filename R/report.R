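# Tabular report computations: library sequencing statistics, category
# shares, locus length-bin shares and differential-status proportions. All
# percentages are rounded half-up to 2 decimals (printed-table convention).

#' Aggregate per-library sequencing statistics
#'
#' Appends a `"total"` row whose extensive columns (base and read counts)
#' are column-wise sums; per-library statistics such as means and N50 are
#' not aggregated and stay `NA` in the total row.
#'
#' @param stats Tibble with a `library` column and numeric columns.
#' @param sum_cols Columns to sum. Default: every numeric column whose name
#'   does not look like a mean/median/N50/length/percentage statistic.
#' @return `stats` with the total row appended.
#' @export
aggregate_library_stats <- function(stats, sum_cols = NULL) {
  stopifnot("library" %in% names(stats))
  num <- names(stats)[vapply(stats, is.numeric, logical(1))]
  if (is.null(sum_cols)) {
    sum_cols <- num[!grepl("mean|median|n50|length|pct|share", num,
                           ignore.case = TRUE)]
  } else {
    missing <- setdiff(sum_cols, num)
    if (length(missing)) {
      abort(sprintf("non-numeric or absent column(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  total <- stats[0, ]
  total[1L, "library"] <- "total"
  for (cc in num) {
    total[[cc]] <- if (cc %in% sum_cols) sum(stats[[cc]]) else NA
  }
  bind_rows(stats, total)
}

#' Percentage share per category
#'
#' @param table Tibble with a label column (first non-numeric column) and a
#'   count column `n` (or the first numeric column).
#' @param total Denominator for the shares. Defaults to the sum of the
#'   counts; pass an externally stated total when the table's categories do
#'   not exhaust it (shares then need not sum to 100).
#' @return Tibble `category`, `n`, `share_pct` (half-up, 2 decimals). With
#'   the default total, shares sum to 100 within rounding tolerance. A zero
#'   total returns an empty result with a warning.
#' @export
category_shares <- function(table, total = NULL) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  cnt <- if ("n" %in% num) "n" else num[1L]
  lab <- setdiff(names(table), num)[1L]
  if (any(table[[cnt]] < 0)) abort("category counts must be non-negative")
  if (is.null(total)) total <- sum(table[[cnt]])
  if (total == 0) {
    warn("category table with zero total: empty share table returned")
    return(tibble(category = character(0), n = double(0),
                  share_pct = double(0)))
  }
  tibble(category = as.character(table[[lab]]), n = table[[cnt]],
         share_pct = round_half_up(100 * table[[cnt]] / total, 2))
}

#' Locus length-bin shares
#'
#' Bins locus span lengths at the given edges (default <1 kb, 1-2 kb,
#' 2-3 kb, >3 kb) and reports counts and percentage shares.
#'
#' @param loci Tibble with a `span_length` column (or `start`/`end`, from
#'   which spans are computed).
#' @param edges Increasing bin edges in bp.
#' @return Tibble `bin`, `n`, `share_pct`.
#' @export
length_bin_shares <- function(loci, edges = c(1000L, 2000L, 3000L)) {
  len <- if ("span_length" %in% names(loci)) {
    loci$span_length
  } else {
    loci$end - loci$start
  }
  labels <- c(sprintf("<%dk", edges[1L] / 1000L),
              sprintf("%d-%dk", head(edges, -1L) / 1000L, edges[-1L] / 1000L),
              sprintf(">%dk", edges[length(edges)] / 1000L))
  idx <- findInterval(len, edges) + 1L
  tb <- tibble(bin = factor(labels[idx], levels = labels)) |>
    dplyr::count(.data$bin, .drop = FALSE) |>
    mutate(bin = as.character(.data$bin))
  tb$share_pct <- if (sum(tb$n) > 0) {
    round_half_up(100 * tb$n / sum(tb$n), 2)
  } else {
    0
  }
  tb
}

#' Differential-status proportions by novelty
#'
#' Cross-tabulates `status` (known/novel) against `regulation`
#' (up/down/ns) and reports, within each status, the percentage in each
#' regulation class.
#'
#' @param table Tibble with `status` and `regulation` columns (one row per
#'   gene or isoform).
#' @return Tibble `status`, `regulation`, `n`, `pct` (percent within
#'   status, half-up to 2 decimals). Empty input returns an empty tibble
#'   with a warning.
#' @export
de_proportions <- function(table) {
  if (nrow(table) == 0L) {
    warn("empty differential table")
    return(tibble(status = character(0), regulation = character(0),
                  n = integer(0), pct = double(0)))
  }
  bad <- setdiff(unique(table$status), c("known", "novel"))
  if (length(bad)) abort(sprintf("unknown status label '%s'", bad[1L]))
  bad <- setdiff(unique(table$regulation), c("up", "down", "ns"))
  if (length(bad)) abort(sprintf("unknown regulation label '%s'", bad[1L]))
  table |>
    mutate(regulation = factor(.data$regulation, c("up", "down", "ns"))) |>
    group_by(.data$status) |>
    dplyr::count(.data$regulation, .drop = FALSE) |>
    mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 2)) |>
    ungroup() |>
    mutate(regulation = as.character(.data$regulation))
}

#' Bundled worked-example tables
#'
#' Small plain-text tables shipped with the package for replaying report
#' computations: per-library sequencing statistics
#' (`"pacbio_library_stats"`), per-library CCS classification counts
#' (`"ccs_classification"`), AS event category counts
#' (`"as_event_counts"`), a KOG category table with the four largest named
#' categories and the remainder aggregated (`"kog_categories"`), and locus
#' length-bin counts (`"locus_length_bins"`).
#'
#' @param name Table name (see above).
#' @return A tibble.
#' @export
isoscope_example <- function(name = c("pacbio_library_stats",
                                      "ccs_classification",
                                      "as_event_counts",
                                      "kog_categories",
                                      "locus_length_bins")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "isoscope")
  if (!nzchar(path)) abort(sprintf("example table '%s' not found", name))
  read_isoscope_tsv(path)
}
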