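#' Tile a target gene into consecutive polynucleotide probes
#'
#' Splits a gene into `k` adjacent, non-overlapping, gap-free probes whose
#' melting temperatures and GC contents are as similar as possible, so that
#' all probes of the set hybridize comparably under one condition. The
#' breakpoint assignment minimizes
#' `objective = tm_spread + weight_gc * gc_spread`, where `tm_spread` is the
#' max-min range of probe Tm (Wetmur model at `design_conditions`, perfect
#' match) and `gc_spread` the range of probe GC percent.
#'
#' The optimization enumerates all feasible breakpoint assignments
#' (vectorized, exact) whenever their number is at most `enum_cap`; larger
#' search spaces are explored on a deterministic stride grid over probe
#' lengths followed by local refinement, which is a heuristic. When the gene
#' is longer than `k * max_len`, the covered window is chosen by the same
#' objective over start offsets on a `offset_step`-bp grid.
#'
#' Probes containing more than `max_n_frac` fraction of N are rejected.
#' Ties are broken deterministically: maximal gene coverage first, then
#' most equal probe lengths, then leftmost breakpoints.
#'
#' @param gene A [gene_target()] or a DNA string.
#' @param k Number of probes (default 5).
#' @param min_len,max_len Allowed probe length window in bp. The default
#'   window 300-500 bp is the typical polynucleotide probe length range;
#'   `preset = "genefish2021"` sets the narrower 442-456 bp window.
#' @param weight_gc Weight of the GC spread in the objective (default 1).
#' @param design_conditions [hyb_conditions()] at which probe Tm is matched
#'   (M = 0).
#' @param preset Optional preset name; `"genefish2021"` sets `k = 5`,
#'   `min_len = 442`, `max_len = 456`.
#' @param offset_step Start-offset grid step for long genes (default 10 bp).
#' @param enum_cap Maximum number of tilings enumerated exhaustively
#'   (default 1e6).
#' @param max_n_frac Maximum tolerated fraction of N per probe (default 0.01).
#'
#' @return An object of class `probe_set`: list with `gene_id`, `probes`
#'   (data.frame probe_id, start, end, length, gc_percent, tm_ref_c,
#'   sequence; 0-based half-open intervals on the gene), `tm_spread_c`,
#'   `gc_spread`, `objective_value`, `window`, `exact` (logical: was the
#'   search exhaustive).
#' @export
#' @examples
#' gene <- gene_target("toy", paste(rep("ACGGTCAT", 40), collapse = ""))
#' tile_gene(gene, k = 3, min_len = 100, max_len = 110)
tile_gene <- function(gene, k = 5L, min_len = 300L, max_len = 500L,
                      weight_gc = 1, design_conditions = hyb_conditions(fa_percent = 35),
                      preset = NULL, offset_step = 10L, enum_cap = 1e6,
                      max_n_frac = 0.01) {
  if (!is.null(preset)) {
    if (preset == "genefish2021") { k <- 5L; min_len <- 442L; max_len <- 456L }
    else stop("unknown preset '", preset, "'", call. = FALSE)
  }
  if (inherits(gene, "gene_target")) {
    gene_id <- gene$id; seq <- gene$sequence
  } else {
    gene_id <- "gene"; seq <- normalize_dna(gene)
  }
  k <- as.integer(k); min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  stopifnot(k >= 1, min_len >= 1, max_len >= min_len)
  L <- nchar(seq)
  if (k * min_len > L)
    stop(sprintf("infeasible: gene length %d < k * min_len = %d * %d = %d",
                 L, k, min_len, k * min_len), call. = FALSE)

  chars <- strsplit(seq, "")[[1]]
  cg <- c(0L, cumsum(chars %in% c("G", "C")))
  cn <- c(0L, cumsum(chars == "N"))
  W <- max_len - min_len + 1L
  n_starts_full <- L - k * min_len + 1L

  # evaluate all length combinations in `len_grids` at every start offset in
  # `starts`; returns the best solution under the tie-break order: minimal
  # objective, then maximal gene coverage, then most equal lengths, then
  # leftmost breakpoints (smallest start, then lexicographic lengths)
  eval_best <- function(starts, len_grids) {
    lensM <- as.matrix(expand.grid(len_grids, KEEP.OUT.ATTRS = FALSE))
    cum <- lensM
    for (i in seq_len(k)[-1]) cum[, i] <- cum[, i - 1] + lensM[, i]
    total <- cum[, k]
    spread <- apply_range(lensM)
    best <- NULL
    for (s in starts) {
      ok <- s + total <= L
      if (!any(ok)) next
      gcp <- matrix(NA_real_, nrow(lensM), k)
      tmv <- matrix(NA_real_, nrow(lensM), k)
      nbad <- rep(FALSE, nrow(lensM))
      for (i in seq_len(k)) {
        a <- if (i == 1) rep.int(s, nrow(lensM)) else s + cum[, i - 1]
        b <- s + cum[, i]
        gcc <- cg[pmin(b, L) + 1L] - cg[pmin(a, L) + 1L]
        ncc <- cn[pmin(b, L) + 1L] - cn[pmin(a, L) + 1L]
        gcp[, i] <- 100 * gcc / lensM[, i]
        tmv[, i] <- 0.41 * gcp[, i] - 500 / lensM[, i]  # probe-dependent Tm terms
        nbad <- nbad | (ncc / lensM[, i] > max_n_frac)
      }
      obj <- apply_range(tmv) + weight_gc * apply_range(gcp)
      obj[!ok | nbad] <- Inf
      o <- min(obj)
      if (!is.finite(o)) next
      tied <- which(obj <= o + 1e-9)
      ord <- do.call(order, c(list(-total[tied], spread[tied]),
                              lapply(seq_len(k), function(j) lensM[tied, j])))
      cand <- list(obj = o, coverage = total[tied[ord[1]]],
                   spread = spread[tied[ord[1]]], s = s,
                   lens = lensM[tied[ord[1]], ])
      if (is.null(best) || tiling_better(cand, best)) best <- cand
    }
    if (is.null(best))
      stop("infeasible: no tiling satisfies the length and N constraints", call. = FALSE)
    best
  }

  full_combos <- as.numeric(W)^k
  exact <- full_combos <= enum_cap && n_starts_full * full_combos <= 50 * enum_cap
  if (exact) {
    len_grids <- replicate(k, seq.int(min_len, max_len), simplify = FALSE)
    sol <- eval_best(seq.int(0L, L - k * min_len), len_grids)
  } else {
    # deterministic coarse-to-fine stride search (heuristic)
    starts <- unique(c(seq.int(0L, L - k * min_len, by = offset_step),
                       L - k * min_len))
    d <- 1L
    while (length(starts) * ceiling(W / d)^k > 5 * enum_cap) d <- d + 1L
    len_grids <- replicate(k, unique(c(seq.int(min_len, max_len, by = d), max_len)),
                           simplify = FALSE)
    sol <- eval_best(starts, len_grids)
    while (d > 1L) {
      prev_d <- d
      d <- max(1L, ceiling(d / 3))
      len_grids <- lapply(seq_len(k), function(i)
        unique(pmin(pmax(seq.int(sol$lens[i] - prev_d, sol$lens[i] + prev_d, by = d),
                         min_len), max_len)))
      sol <- eval_best(sol$s, len_grids)
    }
  }

  s <- sol$s; lens <- as.integer(sol$lens)
  bounds <- s + c(0L, cumsum(lens))
  probes <- data.frame(
    probe_id = paste0(gene_id, "_", seq_len(k)),
    start = bounds[-(k + 1L)], end = bounds[-1L], length = lens,
    stringsAsFactors = FALSE)
  probes$sequence <- substring(seq, probes$start + 1L, probes$end)
  probes$gc_percent <- gc_percent(probes$sequence)
  probes$tm_ref_c <- wetmur_tm(duplex_params(probes$gc_percent, probes$length),
                               design_conditions)
  probes <- probes[, c("probe_id", "start", "end", "length", "gc_percent",
                       "tm_ref_c", "sequence")]
  tm_spread <- diff(range(probes$tm_ref_c))
  gc_spread <- diff(range(probes$gc_percent))
  structure(list(gene_id = gene_id, probes = probes,
                 tm_spread_c = tm_spread, gc_spread = gc_spread,
                 objective_value = tm_spread + weight_gc * gc_spread,
                 window = c(bounds[1L], bounds[k + 1L]),
                 design_conditions = design_conditions, exact = exact),
            class = "probe_set")
}

tiling_better <- function(a, b) {
  if (a$obj < b$obj - 1e-9) return(TRUE)
  if (a$obj > b$obj + 1e-9) return(FALSE)
  if (a$coverage != b$coverage) return(a$coverage > b$coverage)
  if (a$spread != b$spread) return(a$spread < b$spread)
  if (a$s != b$s) return(a$s < b$s)
  for (i in seq_along(a$lens)) if (a$lens[i] != b$lens[i]) return(a$lens[i] < b$lens[i])
  FALSE
}

apply_range <- function(m) {
  lo <- m[, 1]; hi <- m[, 1]
  for (i in seq_len(ncol(m))[-1]) { lo <- pmin(lo, m[, i]); hi <- pmax(hi, m[, i]) }
  hi - lo
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set %s: %d probes covering [%d, %d) of the gene%s\n",
              x$gene_id, nrow(x$probes), x$window[1], x$window[2],
              if (x$exact) "" else " (heuristic search)"))
  cat(sprintf("  Tm spread %.3f C, GC spread %.3f%%, objective %.4f\n",
              x$tm_spread_c, x$gc_spread, x$objective_value))
  print(x$probes[, c("probe_id", "start", "end", "length", "gc_percent", "tm_ref_c")])
  invisible(x)
}

#' Write a probe set to FASTA and a design report TSV
#'
#' FASTA headers are `geneID_probeN interval` with the 0-based half-open
#' interval on the gene.
#'
#' @param ps A `probe_set` from [tile_gene()].
#' @param fasta_path Probe FASTA output path.
#' @param report_path Optional design report TSV path.
#' @return Invisibly, the paths written.
#' @export
write_probe_set <- function(ps, fasta_path, report_path = NULL) {
  stopifnot(inherits(ps, "probe_set"))
  seqs <- setNames(ps$probes$sequence,
                   sprintf("%s %d-%d", ps$probes$probe_id, ps$probes$start, ps$probes$end))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(report_path)) {
    rep <- ps$probes[, c("probe_id", "start", "end", "length", "gc_percent", "tm_ref_c")]
    rep$tm_spread_c <- ps$tm_spread_c
    rep$gc_spread <- ps$gc_spread
    write_tsv_strict(rep, report_path)
  }
  invisible(c(fasta_path, report_path))
}

primer_tm <- function(seq) {
  # simple GC-count formula for amplification primers; documented as
  # replaceable by a nearest-neighbor model if needed
  n <- nchar(seq)
  ngc <- nchar(gsub("[^GC]", "", seq))
  64.9 + 41 * (ngc - 16.4) / n
}

#' Design an amplification primer pair for a probe
#'
#' The forward primer is a prefix of the probe and the reverse primer the
#' reverse complement of a suffix, so the amplicon is exactly the probe.
#' Among all length pairs in `[primer_min, primer_max]` whose GC content
#' lies in `[gc_low, gc_high]` and whose Tm difference is at most
#' `max_tm_diff_c`, the pair with the shortest total length is chosen
#' (ties: smaller Tm difference, then shorter forward primer). If no pair
#' satisfies all constraints, the pair minimizing the Tm difference is
#' returned with `constraints_relaxed = TRUE` and a warning.
#'
#' Primer Tm uses the GC-count formula `64.9 + 41 (nGC - 16.4) / len`.
#'
#' @param probe Probe sequence (string), or one row of a `probe_set`'s
#'   `probes` data.frame.
#' @param primer_min,primer_max Primer length bounds (default 18-27).
#' @param gc_low,gc_high Allowed primer GC percent range (default 40-60).
#' @param max_tm_diff_c Maximum Tm difference between the primers (default 2).
#'
#' @return An object of class `primer_pair`: forward/reverse sequences,
#'   lengths, GC percents, Tm values, `tm_difference_c`, per-primer
#'   `gc_ok` flags and `constraints_relaxed`.
#' @export
design_primers <- function(probe, primer_min = 18L, primer_max = 27L,
                           gc_low = 40, gc_high = 60, max_tm_diff_c = 2) {
  if (is.data.frame(probe)) probe <- probe$sequence[1]
  if (inherits(probe, "gene_target")) probe <- probe$sequence
  probe <- normalize_dna(probe)
  n <- nchar(probe)
  if (n <= 2 * primer_max)
    stop("probe too short for primer design: length ", n,
         " <= 2 * primer_max = ", 2 * primer_max, call. = FALSE)
  lens <- seq.int(primer_min, primer_max)
  fwd_cand <- substring(probe, 1L, lens)
  rev_cand <- revcomp(substring(probe, n - lens + 1L, n))
  grid <- expand.grid(fi = seq_along(lens), ri = seq_along(lens),
                      KEEP.OUT.ATTRS = FALSE)
  fgc <- gc_percent(fwd_cand)[grid$fi]; rgc <- gc_percent(rev_cand)[grid$ri]
  ftm <- primer_tm(fwd_cand)[grid$fi]; rtm <- primer_tm(rev_cand)[grid$ri]
  diff <- abs(ftm - rtm)
  gc_ok <- fgc >= gc_low & fgc <= gc_high & rgc >= gc_low & rgc <= gc_high
  feasible <- gc_ok & diff <= max_tm_diff_c
  relaxed <- !any(feasible)
  if (relaxed) {
    warning("no primer pair satisfies all constraints; returning the pair ",
            "minimizing the Tm difference", call. = FALSE)
    ord <- order(diff, lens[grid$fi] + lens[grid$ri], lens[grid$fi])
  } else {
    ord <- order(!feasible, lens[grid$fi] + lens[grid$ri], diff, lens[grid$fi])
  }
  b <- ord[1]
  structure(list(
    forward = fwd_cand[grid$fi[b]], reverse = rev_cand[grid$ri[b]],
    forward_length = lens[grid$fi[b]], reverse_length = lens[grid$ri[b]],
    forward_gc = fgc[b], reverse_gc = rgc[b],
    forward_tm_c = ftm[b], reverse_tm_c = rtm[b],
    tm_difference_c = diff[b],
    forward_gc_ok = fgc[b] >= gc_low & fgc[b] <= gc_high,
    reverse_gc_ok = rgc[b] >= gc_low & rgc[b] <= gc_high,
    constraints_relaxed = relaxed), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer_pair%s\n  fwd %s (%d bp, GC %.1f%%, Tm %.2f C)\n  rev %s (%d bp, GC %.1f%%, Tm %.2f C)\n  Tm difference %.3f C\n",
              if (x$constraints_relaxed) " [constraints relaxed]" else "",
              x$forward, x$forward_length, x$forward_gc, x$forward_tm_c,
              x$reverse, x$reverse_length, x$reverse_gc, x$reverse_tm_c,
              x$tm_difference_c))
  invisible(x)
}

#' Design primers for every probe of a set
#'
#' @param ps A `probe_set`.
#' @inheritParams design_primers
#' @return data.frame with one row per probe: primer sequences, lengths,
#'   GC, Tm, Tm difference and flags (TSV-writable).
#' @export
design_primer_table <- function(ps, primer_min = 18L, primer_max = 27L,
                                gc_low = 40, gc_high = 60, max_tm_diff_c = 2) {
  stopifnot(inherits(ps, "probe_set"))
  rows <- lapply(seq_len(nrow(ps$probes)), function(i) {
    pp <- design_primers(ps$probes$sequence[i], primer_min, primer_max,
                         gc_low, gc_high, max_tm_diff_c)
    data.frame(probe_id = ps$probes$probe_id[i],
               fwd_seq = pp$forward, rev_seq = pp$reverse,
               fwd_length = pp$forward_length, rev_length = pp$reverse_length,
               fwd_gc = pp$forward_gc, rev_gc = pp$reverse_gc,
               fwd_tm_c = pp$forward_tm_c, rev_tm_c = pp$reverse_tm_c,
               tm_difference_c = pp$tm_difference_c,
               constraints_relaxed = pp$constraints_relaxed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
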