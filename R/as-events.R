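# Alternative-splicing event classification between isoforms of one locus.
# Ten categories: SKIP / MSKIP (one / >=2 consecutive cassette exons skipped),
# IR / MIR (one / >=2 consecutive introns retained), AE (alternative exon
# end at a shared intron), and the X-prefixed approximate-boundary variants
# emitted when the structural pattern matches but corresponding splice-site
# coordinates differ by 1..fuzz bp. Only internal (splice-site) boundaries
# are compared; transcript termini are free, since 3' ends scatter with
# poly(A) site choice and are not splice sites.

as_event_types <- c("SKIP", "MSKIP", "IR", "MIR", "AE",
                    "XSKIP", "XMSKIP", "XIR", "XMIR", "XAE")

#' Classify AS events between two isoforms
#'
#' @param iso_a,iso_b One-row isoform tibbles (as produced by
#'   [collapse_isoforms()]) from the same locus and strand, or bare exon-block
#'   matrices.
#' @param fuzz Maximum splice-site coordinate difference (bp) for a pattern
#'   to be reported as an approximate (`X`) event; with `fuzz = 0` no X-type
#'   event is ever emitted.
#' @return Tibble of events: `type`, `region_start`, `region_end` (0-based
#'   half-open), `n_units` (skipped exons or retained introns).
#' @export
classify_pair <- function(iso_a, iso_b, fuzz = 10L) {
  get_blocks <- function(x) {
    if (is.matrix(x)) return(check_blocks(x))
    stopifnot(is.data.frame(x), nrow(x) == 1L, "blocks" %in% names(x))
    check_blocks(x$blocks[[1L]])
  }
  if (is.data.frame(iso_a) && is.data.frame(iso_b) &&
      "locus_id" %in% names(iso_a) && "locus_id" %in% names(iso_b) &&
      !identical(iso_a$locus_id[1L], iso_b$locus_id[1L])) {
    abort("isoforms belong to different loci")
  }
  ba <- get_blocks(iso_a); bb <- get_blocks(iso_b)
  ia <- blocks_introns(ba); ib <- blocks_introns(bb)
  events <- list()
  claimed <- list()  # list of c(a_intron_idx, b_intron_idx)

  add_event <- function(type, rs, re, k) {
    events[[length(events) + 1L]] <<- tibble(
      type = type, region_start = as.integer(rs), region_end = as.integer(re),
      n_units = as.integer(k))
  }
  claim <- function(ai, bi) {
    claimed[[length(claimed) + 1L]] <<- c(ai, bi)
  }

  # --- SKIP family: exons of `extra` inside an intron of `base` -------------
  scan_skips <- function(extra, base, extra_is_a) {
    ie <- blocks_introns(extra); ibs <- blocks_introns(base)
    for (q in seq_len(nrow(ibs))) {
      d <- ibs[q, 1L]; a <- ibs[q, 2L]
      inner <- which(extra[, 1L] >= d & extra[, 2L] <= a)
      if (!length(inner) || any(diff(inner) != 1L)) next
      f <- inner[1L]; l <- inner[length(inner)]
      if (f <= 1L || l >= nrow(extra)) next
      d1 <- abs(ie[f - 1L, 1L] - d)
      d2 <- abs(ie[l, 2L] - a)
      if (d1 > fuzz || d2 > fuzz) next
      approx <- (d1 + d2) > 0L
      k <- length(inner)
      add_event(if (k == 1L) (if (approx) "XSKIP" else "SKIP")
                else (if (approx) "XMSKIP" else "MSKIP"),
                extra[f, 1L], extra[l, 2L], k)
      if (extra_is_a) { claim(f - 1L, q); claim(l, q) }
      else { claim(q, f - 1L); claim(q, l) }
    }
  }

  # --- IR family: introns of `base` inside an exon of `retainer` ------------
  scan_irs <- function(base, retainer, base_is_a) {
    ibs <- blocks_introns(base); irt <- blocks_introns(retainer)
    for (e in seq_len(nrow(retainer))) {
      s <- retainer[e, 1L]; en <- retainer[e, 2L]
      contained <- which(ibs[, 1L] >= s & ibs[, 2L] <= en)
      if (!length(contained) || any(diff(contained) != 1L)) next
      i1 <- contained[1L]; ik <- contained[length(contained)]
      dl <- 0L; dr <- 0L; pl <- NULL; pr <- NULL
      if (e > 1L && i1 > 1L) {
        dl <- abs(irt[e - 1L, 2L] - ibs[i1 - 1L, 2L])
        pl <- c(i1 - 1L, e - 1L)
      }
      if (e < nrow(retainer) && ik < nrow(ibs)) {
        dr <- abs(irt[e, 1L] - ibs[ik + 1L, 1L])
        pr <- c(ik + 1L, e)
      }
      if (dl > fuzz || dr > fuzz) next
      approx <- (dl + dr) > 0L
      k <- length(contained)
      add_event(if (k == 1L) (if (approx) "XIR" else "IR")
                else (if (approx) "XMIR" else "MIR"),
                ibs[i1, 1L], ibs[ik, 2L], k)
      for (p in list(pl, pr)) {
        if (is.null(p)) next
        if (base_is_a) claim(p[1L], p[2L]) else claim(p[2L], p[1L])
      }
    }
  }

  scan_skips(ba, bb, TRUE)
  scan_skips(bb, ba, FALSE)
  scan_irs(ba, bb, TRUE)
  scan_irs(bb, ba, FALSE)

  # --- AE: overlapping intron pairs sharing one splice site -----------------
  if (nrow(ia) && nrow(ib)) {
    claimed_keys <- vapply(claimed, paste, character(1), collapse = "_")
    cand <- list()
    for (i in seq_len(nrow(ia))) {
      for (j in seq_len(nrow(ib))) {
        if (paste(i, j, sep = "_") %in% claimed_keys) next
        if (ia[i, 1L] >= ib[j, 2L] || ib[j, 1L] >= ia[i, 2L]) next
        dd <- abs(ia[i, 1L] - ib[j, 1L])
        da <- abs(ia[i, 2L] - ib[j, 2L])
        if (dd == 0L && da == 0L) next          # identical intron
        shared <- min(dd, da)
        if (shared == 0L) {
          cand[[length(cand) + 1L]] <- c(i, j, dd + da, 0L)
        } else if (shared <= fuzz) {
          cand[[length(cand) + 1L]] <- c(i, j, dd + da, 1L)
        }
      }
    }
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3L]), , drop = FALSE]
      used_a <- logical(nrow(ia)); used_b <- logical(nrow(ib))
      for (r in seq_len(nrow(cm))) {
        i <- cm[r, 1L]; j <- cm[r, 2L]
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        dd <- abs(ia[i, 1L] - ib[j, 1L]); da <- abs(ia[i, 2L] - ib[j, 2L])
        if (dd >= da) {
          rs <- min(ia[i, 1L], ib[j, 1L]); re <- max(ia[i, 1L], ib[j, 1L])
        } else {
          rs <- min(ia[i, 2L], ib[j, 2L]); re <- max(ia[i, 2L], ib[j, 2L])
        }
        add_event(if (cm[r, 4L] == 1L) "XAE" else "AE", rs, re, 1L)
      }
    }
  }

  if (!length(events)) {
    return(tibble(type = character(0), region_start = integer(0),
                  region_end = integer(0), n_units = integer(0)))
  }
  bind_rows(events) |> arrange(.data$region_start, .data$type)
}

#' Find AS events across all isoform pairs of each locus
#'
#' @param isoforms Isoform tibble with `locus_id` (multi-isoform loci are
#'   compared pairwise; pairs on different strands are skipped).
#' @param fuzz Approximate-boundary tolerance in bp (see [classify_pair()]).
#' @return Event tibble: `locus_id`, `iso_a`, `iso_b`, `type`,
#'   `region_start`, `region_end`, `n_units`, `libraries` (list: libraries
#'   shared by both isoforms, or the union when they share none).
#' @export
find_as_events <- function(isoforms, fuzz = 10L) {
  stopifnot("locus_id" %in% names(isoforms))
  out <- list()
  has_lib <- "libraries" %in% names(isoforms)
  for (grp in split(seq_len(nrow(isoforms)), isoforms$locus_id)) {
    if (length(grp) < 2L) next
    for (x in seq_along(grp)) {
      for (y in seq_along(grp)) {
        if (x >= y) next
        i <- grp[x]; j <- grp[y]
        if (isoforms$strand[i] != isoforms$strand[j]) next
        ev <- classify_pair(isoforms$blocks[[i]], isoforms$blocks[[j]], fuzz)
        if (!nrow(ev)) next
        libs <- if (has_lib) {
          both <- intersect(isoforms$libraries[[i]], isoforms$libraries[[j]])
          if (length(both)) both
          else sort(union(isoforms$libraries[[i]], isoforms$libraries[[j]]))
        } else character(0)
        out[[length(out) + 1L]] <- mutate(
          ev, locus_id = isoforms$locus_id[i],
          iso_a = isoforms$isoform_id[i], iso_b = isoforms$isoform_id[j],
          libraries = rep(list(libs), nrow(ev)))
      }
    }
  }
  if (!length(out)) {
    return(tibble(locus_id = character(0), iso_a = character(0),
                  iso_b = character(0), type = character(0),
                  region_start = integer(0), region_end = integer(0),
                  n_units = integer(0), libraries = list()))
  }
  bind_rows(out) |>
    select("locus_id", "iso_a", "iso_b", "type", "region_start",
           "region_end", "n_units", "libraries") |>
    arrange(.data$locus_id, .data$iso_a, .data$iso_b, .data$region_start)
}

#' Summarize AS events by category
#'
#' Counts events per category, both raw (per isoform pair) and deduplicated
#' per locus by `(type, region)`, with category shares to 2 decimals. With
#' `by_library = TRUE`, counts are additionally tallied per library label
#' (an event counts in every library shared by its isoform pair).
#'
#' @param events Event tibble from [find_as_events()].
#' @param by_library Also return per-library counts?
#' @return Tibble `type`, `n`, `n_dedup`, `share_pct` (shares of the raw
#'   total over all ten categories); when `by_library = TRUE`, a long tibble
#'   `library`, `type`, `n`, `share_pct` with a `"pooled"` library.
#' @export
summarize_as_events <- function(events, by_library = FALSE) {
  base <- tibble(type = factor(as_event_types, levels = as_event_types))
  if (by_library) {
    lib_ev <- events |>
      tidyr::unnest_longer("libraries", values_to = "library",
                          keep_empty = TRUE) |>
      mutate(library = ifelse(is.na(.data$library), "unlabelled", .data$library))
    pooled <- mutate(events, library = "pooled")
    all_ev <- bind_rows(select(lib_ev, "library", "type"),
                        select(pooled, "library", "type"))
    out <- all_ev |>
      mutate(type = factor(.data$type, levels = as_event_types)) |>
      dplyr::count(.data$library, .data$type, .drop = FALSE) |>
      group_by(.data$library) |>
      mutate(share_pct = if (sum(.data$n) > 0)
        round_half_up(100 * .data$n / sum(.data$n), 2) else rep(0, n())) |>
      ungroup() |>
      mutate(type = as.character(.data$type))
    return(out)
  }
  counts <- events |>
    mutate(type = factor(.data$type, levels = as_event_types)) |>
    dplyr::count(.data$type, .drop = FALSE)
  dedup <- events |>
    distinct(.data$locus_id, .data$type, .data$region_start, .data$region_end) |>
    mutate(type = factor(.data$type, levels = as_event_types)) |>
    dplyr::count(.data$type, .drop = FALSE, name = "n_dedup")
  out <- left_join(counts, dedup, by = "type") |>
    mutate(type = as.character(.data$type),
           n_dedup = ifelse(is.na(.data$n_dedup), 0L, .data$n_dedup))
  out$share_pct <- if (sum(out$n) > 0) {
    round_half_up(100 * out$n / sum(out$n), 2)
  } else {
    rep(0, nrow(out))
  }
  out
}
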