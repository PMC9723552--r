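#' Align a probe against a target sequence
#'
#' Deterministic semi-global pairwise alignment: the probe is aligned
#' end-to-end, the target contributes a consecutive subsequence (free end
#' gaps on the target). Both target strands are evaluated and the
#' better-scoring strand is reported. Affine gap costs: a gap of length L
#' costs `gap_open + L * gap_extend`. N never counts as a match.
#'
#' Percent identity is computed over the alignment columns spanning the
#' aligned probe (including internal gaps) by default; set
#' `denominator = "probe"` to divide by probe length instead. The longest
#' mismatch stretch pools substitutions and gap columns into single runs.
#'
#' @param probe_seq,target_seq DNA strings (normalized on input; characters
#'   other than A, C, G, T, N are rejected after IUPAC-to-N mapping).
#' @param scoring Named list: `match` (default 1), `mismatch` (-2),
#'   `gap_open` (4) and `gap_extend` (1); gap penalties are positive costs.
#' @param denominator `"alignment"` (default) or `"probe"` for the percent
#'   identity denominator.
#' @param probe_id,target_id Optional ids carried into the summary.
#'
#' @return An object of class `alignment_summary`: list with `probe_id`,
#'   `target_id`, `strand`, `score`, `percent_identity`,
#'   `longest_mismatch_stretch_bp`, `alignment_length`, `probe_coverage`,
#'   `target_start`/`target_end` (0-based half-open on the reported strand)
#'   and the column-level `trace` string over `=`, `X` (substitution),
#'   `I` (gap in target) and `D` (gap in probe).
#' @export
#' @examples
#' align_probe("ACGTACGTAC", "TTTACGTACGTACTTT")
align_probe <- function(probe_seq, target_seq,
                        scoring = list(match = 1, mismatch = -2,
                                       gap_open = 4, gap_extend = 1),
                        denominator = c("alignment", "probe"),
                        probe_id = "probe", target_id = "target") {
  denominator <- match.arg(denominator)
  probe_seq <- normalize_dna(probe_seq)
  target_seq <- normalize_dna(target_seq)
  if (!nchar(probe_seq) || !nchar(target_seq))
    stop("empty sequence", call. = FALSE)
  fwd <- .align_core(probe_seq, target_seq, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend, FALSE)
  rev <- .align_core(probe_seq, revcomp(target_seq), scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend, FALSE)
  strand <- if (rev$score > fwd$score) "-" else "+"
  aln <- if (strand == "-") rev else fwd
  summarize_alignment(aln, nchar(probe_seq), strand, denominator,
                      probe_id, target_id)
}

summarize_alignment <- function(aln, probe_len, strand, denominator,
                                probe_id, target_id) {
  ops <- strsplit(aln$trace, "")[[1]]
  n_match <- sum(ops == "=")
  aln_len <- length(ops)
  denom <- if (denominator == "probe") probe_len else aln_len
  structure(list(
    probe_id = probe_id, target_id = target_id, strand = strand,
    score = aln$score,
    percent_identity = 100 * n_match / denom,
    longest_mismatch_stretch_bp = longest_mismatch_stretch(aln$trace),
    alignment_length = aln_len,
    probe_coverage = sum(ops %in% c("=", "X", "I")) / probe_len,
    target_start = aln$target_start, target_end = aln$target_end,
    trace = aln$trace), class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): identity %.2f%%, longest mismatch stretch %d bp, %d columns, score %g\n",
              x$probe_id, x$target_id, x$strand, x$percent_identity,
              x$longest_mismatch_stretch_bp, x$alignment_length, x$score))
  invisible(x)
}

#' Global pairwise nucleotide identity
#'
#' End-to-end alignment of two sequences under the same scoring as
#' [align_probe()]; used for homolog identity links between locus genes.
#'
#' @inheritParams align_probe
#' @param seq_a,seq_b DNA strings.
#' @return Percent identity over alignment columns.
#' @export
global_identity <- function(seq_a, seq_b,
                            scoring = list(match = 1, mismatch = -2,
                                           gap_open = 4, gap_extend = 1)) {
  seq_a <- normalize_dna(seq_a); seq_b <- normalize_dna(seq_b)
  aln <- .align_core(seq_a, seq_b, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend, TRUE)
  ops <- strsplit(aln$trace, "")[[1]]
  100 * sum(ops == "=") / length(ops)
}

#' Longest run of mismatch or gap columns in an alignment trace
#'
#' Substitutions (`X`) and gap columns (`I`, `D`) pool into a single run;
#' match columns (`=` or `M`) break runs.
#'
#' @param trace Alignment trace string over `=`/`M` (match) and `X`, `I`,
#'   `D` (substitution, gap in target, gap in probe).
#' @return Length in bp of the longest mismatch-or-gap run (0 for a perfect
#'   alignment).
#' @export
#' @examples
#' longest_mismatch_stretch("==XX=DD=")  # 2 then 2 -> 2
#' longest_mismatch_stretch("==XXDD==")  # pooled -> 4
longest_mismatch_stretch <- function(trace) {
  ops <- strsplit(trace, "")[[1]]
  if (!length(ops)) return(0L)
  bad <- !(ops %in% c("=", "M"))
  if (!any(bad)) return(0L)
  r <- rle(bad)
  max(r$lengths[r$values])
}

#' Set-level hit call from per-probe identities
#'
#' A probe hits a target when its percent identity is at least
#' `identity_threshold` (and, if summaries carry coverage, its probe
#' coverage is at least `min_coverage`); the probe set hits when at least
#' `min_hits` probes hit. The defaults (at least 4 of 5 probes with >= 80%
#' identity) are the set-level detection rule for polynucleotide probe sets.
#'
#' @param summaries List of `alignment_summary` objects, or a numeric
#'   vector of per-probe percent identities.
#' @param identity_threshold Percent identity threshold (default 80).
#' @param min_hits Minimum number of hitting probes (default 4).
#' @param min_coverage Minimum probe coverage for a probe hit (default 0.5;
#'   only applied when coverage is available).
#' @return List with `n_probe_hits`, `set_hit` and the logical `probe_hits`.
#' @export
#' @examples
#' set_hit(c(85, 83, 92, 79, 80))  # 4 hits -> set hit
set_hit <- function(summaries, identity_threshold = 80, min_hits = 4L,
                    min_coverage = 0.5) {
  if (is.numeric(summaries)) {
    ident <- summaries
    cov <- rep(1, length(ident))
  } else {
    ident <- vapply(summaries, `[[`, numeric(1), "percent_identity")
    cov <- vapply(summaries, `[[`, numeric(1), "probe_coverage")
  }
  if (!length(ident)) stop("no per-probe summaries", call. = FALSE)
  hits <- ident >= identity_threshold & cov >= min_coverage
  list(n_probe_hits = sum(hits), set_hit = sum(hits) >= min_hits,
       probe_hits = hits)
}

#' Screen a probe set against a gene database
#'
#' Aligns every probe of a set against every target of a database
#' (both strands), calls per-probe and set-level hits, and combines the
#' result with the Wetmur stringency model: the implied mismatch percent of
#' a target is `100 - mean identity of its hitting probes` (or the worst
#' hitting probe with `mismatch_mode = "worst"`), and the target is
#' predicted detectable at the given conditions when that mismatch is at
#' most [max_mismatch()] for the mean probe GC/length.
#'
#' @param probe_set A `probe_set` from [tile_gene()], a named character
#'   vector of probe sequences, or a probe FASTA path.
#' @param gene_db Named character vector of target sequences or a
#'   multi-FASTA path; record ids must be unique.
#' @param cond [hyb_conditions()] at which detectability is predicted.
#' @inheritParams set_hit
#' @inheritParams align_probe
#' @param mismatch_mode `"mean"` (default) or `"worst"`: how per-probe
#'   identities of hitting probes aggregate into the implied mismatch.
#'
#' @return An object of class `screen_result`: list with `probe_table`
#'   (per probe x target: strand, identity, longest stretch, coverage,
#'   score) and `set_table` (per target: n_probe_hits, set_hit,
#'   implied_mismatch_percent, max_mismatch_percent,
#'   predicted_detectable_at_fa).
#' @export
screen_probes <- function(probe_set, gene_db, cond = hyb_conditions(fa_percent = 35),
                          identity_threshold = 80, min_hits = 4L,
                          min_coverage = 0.5, mismatch_mode = c("mean", "worst"),
                          scoring = list(match = 1, mismatch = -2,
                                         gap_open = 4, gap_extend = 1)) {
  mismatch_mode <- match.arg(mismatch_mode)
  if (inherits(probe_set, "probe_set")) {
    probes <- setNames(probe_set$probes$sequence, probe_set$probes$probe_id)
  } else if (is.character(probe_set) && length(probe_set) == 1 && file.exists(probe_set)) {
    probes <- read_fasta(probe_set)
  } else probes <- probe_set
  if (is.character(gene_db) && length(gene_db) == 1 && file.exists(gene_db)) {
    db <- read_fasta(gene_db)
  } else db <- gene_db
  if (!length(db)) stop("empty gene database", call. = FALSE)
  if (anyDuplicated(names(db)))
    stop("duplicate target ids in gene database: ",
         paste(unique(names(db)[duplicated(names(db))]), collapse = ", "),
         call. = FALSE)

  probe_rows <- list(); set_rows <- list()
  mean_gc <- mean(gc_percent(unname(probes)))
  mean_len <- mean(nchar(probes))
  mm_allowed <- suppressWarnings(
    as.numeric(max_mismatch(duplex_params(mean_gc, mean_len), cond)))
  for (t in names(db)) {
    sums <- lapply(names(probes), function(p)
      align_probe(probes[[p]], db[[t]], scoring = scoring,
                  probe_id = p, target_id = t))
    hit <- set_hit(sums, identity_threshold, min_hits, min_coverage)
    ident <- vapply(sums, `[[`, numeric(1), "percent_identity")
    hit_ident <- ident[hit$probe_hits]
    implied <- if (!length(hit_ident)) NA_real_ else
      switch(mismatch_mode, mean = 100 - mean(hit_ident), worst = 100 - min(hit_ident))
    probe_rows[[t]] <- data.frame(
      probe_id = names(probes), target_id = t,
      strand = vapply(sums, `[[`, character(1), "strand"),
      percent_identity = ident,
      longest_mismatch_stretch_bp =
        vapply(sums, function(s) as.integer(s$longest_mismatch_stretch_bp), integer(1)),
      alignment_length = vapply(sums, function(s) as.integer(s$alignment_length), integer(1)),
      probe_coverage = vapply(sums, `[[`, numeric(1), "probe_coverage"),
      score = vapply(sums, `[[`, numeric(1), "score"),
      probe_hit = hit$probe_hits, stringsAsFactors = FALSE)
    set_rows[[t]] <- data.frame(
      target_id = t, n_probe_hits = hit$n_probe_hits, set_hit = hit$set_hit,
      implied_mismatch_percent = implied,
      max_mismatch_percent = mm_allowed,
      predicted_detectable_at_fa = isTRUE(implied <= mm_allowed),
      stringsAsFactors = FALSE)
  }
  structure(list(probe_table = do.call(rbind, c(probe_rows, make.row.names = FALSE)),
                 set_table = do.call(rbind, c(set_rows, make.row.names = FALSE)),
                 cond = cond, identity_threshold = identity_threshold,
                 min_hits = min_hits, mismatch_mode = mismatch_mode),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d probes x %d targets at FA %.0f%%; %d set hit(s)\n",
              length(unique(x$probe_table$probe_id)), nrow(x$set_table),
              x$cond$fa_percent, sum(x$set_table$set_hit)))
  print(x$set_table)
  invisible(x)
}

#' Write a screen result to TSV (and optionally JSON)
#'
#' @param sr A `screen_result`.
#' @param probe_path TSV path for the per-probe table.
#' @param set_path TSV path for the set-level table.
#' @param json_path Optional JSON mirror of both tables.
#' @return Invisibly, the paths written.
#' @export
write_screen_result <- function(sr, probe_path, set_path, json_path = NULL) {
  stopifnot(inherits(sr, "screen_result"))
  write_tsv_strict(sr$probe_table, probe_path)
  write_tsv_strict(sr$set_table, set_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(probe_table = sr$probe_table, set_table = sr$set_table,
                              fa_percent = sr$cond$fa_percent,
                              identity_threshold = sr$identity_threshold,
                              min_hits = sr$min_hits),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(probe_path, set_path, json_path))
}
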