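# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (loops, exhaustive enumeration) and share no
# code with the package internals beyond trivial accessors.

blocks_of <- function(...) {
  m <- matrix(c(...), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

introns_of <- function(b) {
  n <- nrow(b)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(b[-n, 2L], b[-1L, 1L])
}

# position-by-position scanner for the documented poly(A) tail rule
oracle_polya <- function(seq, min_len = 20L, min_purity = 0.8) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  for (s in seq_len(max(0L, n - min_len + 1L))) {
    ok <- TRUE
    a <- 0L
    for (t in s:n) {
      a <- a + (ch[t] == "A")
      if (a / (t - s + 1L) < min_purity - 1e-9) { ok <- FALSE; break }
    }
    if (ok) return(list(has = TRUE, start0 = s - 1L))
  }
  list(has = FALSE, start0 = NA_integer_)
}

# exact chain-key grouping of multi-exon alignments (mono-exon handled by
# explicit pairwise predicate + transitive closure)
oracle_collapse_keys <- function(alignments) {
  chains <- vapply(alignments$blocks, function(b) {
    im <- introns_of(b)
    if (nrow(im) == 0L) "" else paste(im[, 1L], im[, 2L], collapse = "|")
  }, character(1))
  multi <- chains != ""
  key <- paste(alignments$chrom, alignments$strand, chains)
  tab <- table(key[multi])
  list(multi_groups = sort(as.integer(tab)),
       n_multi = length(tab),
       mono_idx = which(!multi))
}

# transitive closure of a pairwise relation matrix
closure_components <- function(rel) {
  n <- nrow(rel)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (rel[i, j] && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

oracle_loci <- function(chrom, strand, start, end, min_overlap = 0.2) {
  n <- length(start)
  rel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (chrom[i] != chrom[j] || strand[i] != strand[j]) next
    ov <- min(end[i], end[j]) - max(start[i], start[j])
    if (ov <= 0) next
    if (ov / min(end[i] - start[i], end[j] - start[j]) >= min_overlap) {
      rel[i, j] <- TRUE
    }
  }
  diag(rel) <- TRUE
  closure_components(rel)
}

# direct evaluation of the retention boolean rule
oracle_retention <- function(support, identity, junction_supported, pid_cut = 0.99) {
  support >= 2L ||
    (support == 1L && !is.na(identity) && identity > pid_cut) ||
    (length(junction_supported) > 0L && all(junction_supported))
}

# documented APA greedy rule, written independently
oracle_apa <- function(pos, strand, window = 5L, min_support = 2L,
                       exclusion = 15L) {
  pos <- sort(pos)
  clusters <- list()
  cur <- c()
  rep_of <- function(v) {
    cnt <- sapply(unique(v), function(u) sum(v == u))
    best <- unique(v)[cnt == max(cnt)]
    if (strand == "+") max(best) else min(best)
  }
  for (p in pos) {
    if (length(cur) == 0L || abs(p - rep_of(cur)) <= window) {
      cur <- c(cur, p)
    } else {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- p
    }
  }
  if (length(cur)) clusters[[length(clusters) + 1L]] <- cur
  reps <- sapply(clusters, rep_of)
  sup <- sapply(clusters, length)
  keep <- sup >= min_support
  reps <- reps[keep]; sup <- sup[keep]
  if (!length(reps)) return(data.frame(position = integer(0), support = integer(0)))
  ord <- order(-sup, if (strand == "+") -reps else reps)
  reps <- reps[ord]; sup <- sup[ord]
  acc_p <- integer(0); acc_s <- integer(0)
  for (k in seq_along(reps)) {
    if (length(acc_p) && any(abs(acc_p - reps[k]) <= exclusion)) next
    acc_p <- c(acc_p, reps[k]); acc_s <- c(acc_s, sup[k])
  }
  data.frame(position = acc_p, support = acc_s)
}

# literal four-predicate fusion evaluator
oracle_fusion_verdict <- function(gene_chrom, gene_start, gene_end,
                                  per_gene_cov, total_cov, pe,
                                  min_distance = 10000, min_seg_cov = 0.10,
                                  min_total_cov = 0.99, min_pe = 2L) {
  n <- length(per_gene_cov)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (gene_chrom[i] == gene_chrom[j]) {
      d <- max(gene_start[j] - gene_end[i], gene_start[i] - gene_end[j])
      if (d < min_distance) return(FALSE)
    }
  }
  if (any(per_gene_cov <= min_seg_cov)) return(FALSE)
  if (total_cov <= min_total_cov) return(FALSE)
  pe >= min_pe
}

# exhaustive interval-algebra evaluation of the five AS patterns (and their
# approximate variants); enumerates every candidate exon run / intron run.
oracle_as_events <- function(ba, bb, fuzz = 10L) {
  out <- list()
  add <- function(type, rs, re, k) {
    out[[length(out) + 1L]] <<- data.frame(
      type = type, region_start = rs, region_end = re, n_units = k)
  }
  claimed <- character(0)

  skip_scan <- function(extra, base, extra_is_a) {
    ie <- introns_of(extra); ibs <- introns_of(base)
    if (nrow(ie) == 0L || nrow(ibs) == 0L) return()
    ne <- nrow(extra)
    for (f in 2:(ne - 1L)) for (l in f:(ne - 1L)) {
      if (l < f) next
      for (q in seq_len(nrow(ibs))) {
        d <- ibs[q, 1L]; a <- ibs[q, 2L]
        inside <- all(extra[f:l, 1L] >= d & extra[f:l, 2L] <= a)
        # every exon of the run, and only the run, inside the base intron
        others <- setdiff(seq_len(ne), f:l)
        clean <- all(!(extra[others, 1L] >= d & extra[others, 2L] <= a))
        if (!inside || !clean) next
        d1 <- abs(ie[f - 1L, 1L] - d); d2 <- abs(ie[l, 2L] - a)
        if (d1 > fuzz || d2 > fuzz) next
        k <- l - f + 1L
        approx <- d1 > 0L || d2 > 0L
        add(if (k == 1L) (if (approx) "XSKIP" else "SKIP")
            else (if (approx) "XMSKIP" else "MSKIP"),
            extra[f, 1L], extra[l, 2L], k)
        if (extra_is_a) {
          claimed <<- c(claimed, paste(f - 1L, q), paste(l, q))
        } else {
          claimed <<- c(claimed, paste(q, f - 1L), paste(q, l))
        }
      }
    }
  }

  ir_scan <- function(base, retainer, base_is_a) {
    ibs <- introns_of(base); irt <- introns_of(retainer)
    if (nrow(ibs) == 0L) return()
    for (i1 in seq_len(nrow(ibs))) for (ik in i1:nrow(ibs)) {
      for (e in seq_len(nrow(retainer))) {
        s <- retainer[e, 1L]; en <- retainer[e, 2L]
        run <- i1:ik
        inside <- all(ibs[run, 1L] >= s & ibs[run, 2L] <= en)
        others <- setdiff(seq_len(nrow(ibs)), run)
        clean <- length(others) == 0L ||
          all(!(ibs[others, 1L] >= s & ibs[others, 2L] <= en))
        if (!inside || !clean) next
        dl <- 0L; pl <- NULL
        if (e > 1L && i1 > 1L) {
          dl <- abs(irt[e - 1L, 2L] - ibs[i1 - 1L, 2L]); pl <- c(i1 - 1L, e - 1L)
        }
        dr <- 0L; pr <- NULL
        if (e < nrow(retainer) && ik < nrow(ibs)) {
          dr <- abs(irt[e, 1L] - ibs[ik + 1L, 1L]); pr <- c(ik + 1L, e)
        }
        if (dl > fuzz || dr > fuzz) next
        k <- length(run)
        approx <- dl > 0L || dr > 0L
        add(if (k == 1L) (if (approx) "XIR" else "IR")
            else (if (approx) "XMIR" else "MIR"),
            ibs[i1, 1L], ibs[ik, 2L], k)
        for (p in list(pl, pr)) {
          if (is.null(p)) next
          claimed <<- c(claimed,
                        if (base_is_a) paste(p[1L], p[2L]) else paste(p[2L], p[1L]))
        }
      }
    }
  }

  if (nrow(ba) >= 3L) skip_scan(ba, bb, TRUE)
  if (nrow(bb) >= 3L) skip_scan(bb, ba, FALSE)
  ir_scan(ba, bb, TRUE)
  ir_scan(bb, ba, FALSE)

  ia <- introns_of(ba); ib <- introns_of(bb)
  if (nrow(ia) && nrow(ib)) {
    cand <- list()
    for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
      if (paste(i, j) %in% claimed) next
      if (ia[i, 1L] >= ib[j, 2L] || ib[j, 1L] >= ia[i, 2L]) next
      dd <- abs(ia[i, 1L] - ib[j, 1L]); da <- abs(ia[i, 2L] - ib[j, 2L])
      if (dd == 0L && da == 0L) next
      if (min(dd, da) == 0L) {
        cand[[length(cand) + 1L]] <- c(i, j, dd + da, 0L)
      } else if (min(dd, da) <= fuzz) {
        cand[[length(cand) + 1L]] <- c(i, j, dd + da, 1L)
      }
    }
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3L]), , drop = FALSE]
      ua <- logical(nrow(ia)); ub <- logical(nrow(ib))
      for (r in seq_len(nrow(cm))) {
        i <- cm[r, 1L]; j <- cm[r, 2L]
        if (ua[i] || ub[j]) next
        ua[i] <- TRUE; ub[j] <- TRUE
        dd <- abs(ia[i, 1L] - ib[j, 1L]); da <- abs(ia[i, 2L] - ib[j, 2L])
        if (dd >= da) add(if (cm[r, 4L]) "XAE" else "AE",
                          min(ia[i, 1L], ib[j, 1L]), max(ia[i, 1L], ib[j, 1L]), 1L)
        else add(if (cm[r, 4L]) "XAE" else "AE",
                 min(ia[i, 2L], ib[j, 2L]), max(ia[i, 2L], ib[j, 2L]), 1L)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(0), region_start = integer(0),
                      region_end = integer(0), n_units = integer(0)))
  }
  do.call(rbind, out)
}

event_multiset <- function(ev) {
  sort(paste(ev$type, ev$region_start, ev$region_end, ev$n_units))
}

# random exon-block structure generator for property tests
random_blocks <- function(n_exons, origin = 0L) {
  ex <- sample(30:120, n_exons, replace = TRUE)
  intr <- if (n_exons > 1L) sample(60:300, n_exons - 1L, replace = TRUE) else integer(0)
  starts <- origin + c(0L, cumsum(ex[-n_exons] + intr))
  cbind(start = starts, end = starts + ex)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
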