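# evaluate code under a temporary RNG state seeded with `seed`;
# NULL seed leaves the RNG untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

random_dna <- function(n, gc_percent = 50) {
  p <- c(gc_percent / 200, gc_percent / 200,
         (100 - gc_percent) / 200, (100 - gc_percent) / 200)
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a homolog gene family at controlled identity levels
#'
#' Generates a random ancestor gene and, for each requested identity
#' target, homologs mutated by per-site substitution at rate
#' `(100 - target) / 100`, so the realized identity matches the target in
#' expectation (substitutions always change the base and never create N).
#' With `stretch_model = "clustered"`, substitutions are placed in
#' geometric blocks of mean length `mean_block`, creating the long
#' mismatch stretches seen between diverged homologs; `"uniform"` scatters
#' them independently. Optional small indels (1-3 bp) can be enabled via
#' `indel_rate`.
#'
#' @param ancestor_length Ancestor gene length in bp (default 2250, five
#'   450 bp probes' worth of sequence).
#' @param gc_percent Ancestor GC content (default 50).
#' @param identity_targets Percent identity targets in (0, 100], one
#'   homolog per element per replicate.
#' @param n_replicates Homologs generated per identity target (default 1).
#' @param stretch_model `"uniform"` (default) or `"clustered"`.
#' @param mean_block Mean substitution block length for the clustered
#'   model (default 12 bp).
#' @param indel_rate Per-site indel rate (default 0, i.e. substitutions
#'   only so identity targets are exact in expectation).
#' @param seed Integer seed; the generator is seed-deterministic.
#'
#' @return List with `ancestor` (string), `homologs` (named character
#'   vector, names `id<target>_r<rep>`), and `info` (data.frame: id,
#'   target_identity, realized_identity).
#' @export
#' @examples
#' fam <- simulate_gene_family(identity_targets = c(95, 80), seed = 1)
#' fam$info
simulate_gene_family <- function(ancestor_length = 2250L, gc_percent = 50,
                                 identity_targets, n_replicates = 1L,
                                 stretch_model = c("uniform", "clustered"),
                                 mean_block = 12, indel_rate = 0, seed = NULL) {
  stretch_model <- match.arg(stretch_model)
  stopifnot(all(identity_targets > 0), all(identity_targets <= 100))
  with_seed(seed, {
    ancestor <- random_dna(ancestor_length, gc_percent)
    anc <- strsplit(ancestor, "")[[1]]
    homologs <- character(0)
    info <- list()
    for (target in identity_targets) {
      rate <- (100 - target) / 100
      for (r in seq_len(n_replicates)) {
        n_sub <- rbinom(1, ancestor_length, rate)
        pos <- if (stretch_model == "uniform") {
          sample.int(ancestor_length, n_sub)
        } else {
          marked <- logical(ancestor_length)
          while (sum(marked) < n_sub) {
            len <- 1L + rgeom(1, 1 / mean_block)
            s <- sample.int(ancestor_length, 1)
            marked[seq(s, min(s + len - 1L, ancestor_length))] <- TRUE
          }
          w <- which(marked)
          w[seq_len(n_sub)]  # trim overshoot so the realized count is exact
        }
        mut <- anc
        if (length(pos))
          mut[pos] <- vapply(mut[pos], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        seqstr <- paste(mut, collapse = "")
        if (indel_rate > 0) {
          n_indel <- rbinom(1, ancestor_length, indel_rate)
          for (j in seq_len(n_indel)) {
            at <- sample.int(nchar(seqstr) - 4L, 1)
            len <- sample(1:3, 1)
            if (runif(1) < 0.5) {
              seqstr <- paste0(substr(seqstr, 1, at),
                               random_dna(len, gc_percent),
                               substr(seqstr, at + 1L, nchar(seqstr)))
            } else {
              seqstr <- paste0(substr(seqstr, 1, at),
                               substr(seqstr, at + len + 1L, nchar(seqstr)))
            }
          }
        }
        id <- sprintf("id%g_r%d", target, r)
        homologs[id] <- seqstr
        info[[length(info) + 1L]] <- data.frame(
          id = id, target_identity = target,
          realized_identity = 100 * (1 - length(pos) / ancestor_length),
          stringsAsFactors = FALSE)
      }
    }
    list(ancestor = ancestor, homologs = homologs, info = do.call(rbind, info))
  })
}

#' Simulate annotated contigs with planted PUL cassettes
#'
#' Generates synthetic per-gene annotation tables with known ground truth
#' for the PUL caller: with probability `pul_density`, a contig carries one
#' planted glucuronomannan-like cassette (susC-like, susD-like, GH92,
#' sulfatase, GH16, on one strand). The background is `other` genes plus
#' occasional isolated PUL-relevant distractor genes, always separated
#' from any other relevant gene by more than `isolation_gap` non-relevant
#' genes so that no locus other than the planted cassettes can satisfy the
#' PUL rule.
#'
#' @param n_contigs Number of contigs (default 100).
#' @param genes_per_contig Integer length-2 range of genes per contig
#'   (default 25-40).
#' @param pul_density Probability that a contig carries a planted cassette
#'   (default 0.3).
#' @param distractor_rate Probability per eligible position of an isolated
#'   relevant distractor gene (default 0.05).
#' @param isolation_gap Minimum number of `other` genes flanking each
#'   distractor (default 5; keep above the caller's
#'   `max_intergenic_genes`).
#' @param seed Integer seed.
#'
#' @return List with `annotations` (data.frame as for [find_puls()]) and
#'   `truth` (data.frame: contig_id, first_gene_index, last_gene_index of
#'   each planted cassette).
#' @export
simulate_contigs <- function(n_contigs = 100L, genes_per_contig = c(25L, 40L),
                             pul_density = 0.3, distractor_rate = 0.05,
                             isolation_gap = 5L, seed = NULL) {
  cassette <- c("susC-like", "susD-like", "GH92", "sulfatase", "GH16")
  distractor_pool <- c("susC-like", "susD-like", "GH92", "GH16", "PL7", "sulfatase")
  with_seed(seed, {
    ann <- list(); truth <- list()
    for (ci in seq_len(n_contigs)) {
      contig <- sprintf("contig_%03d", ci)
      n_genes <- sample(seq(genes_per_contig[1], genes_per_contig[2]), 1)
      labels <- rep("other", n_genes)
      has_pul <- runif(1) < pul_density
      cas_at <- NA_integer_
      if (has_pul && n_genes >= length(cassette) + 2L) {
        cas_at <- sample(seq(2L, n_genes - length(cassette)), 1)
        labels[seq(cas_at, cas_at + length(cassette) - 1L)] <- cassette
      }
      # isolated distractors, kept far from the cassette and each other
      relevant_at <- which(labels != "other")
      for (pos in seq_len(n_genes)) {
        if (labels[pos] != "other") next
        if (length(relevant_at) && min(abs(pos - relevant_at)) <= isolation_gap) next
        if (runif(1) < distractor_rate) {
          labels[pos] <- sample(distractor_pool, 1)
          relevant_at <- c(relevant_at, pos)
        }
      }
      strands <- sample(c("+", "-"), n_genes, replace = TRUE)
      if (!is.na(cas_at))
        strands[seq(cas_at, cas_at + length(cassette) - 1L)] <- "+"
      starts <- (seq_len(n_genes) - 1L) * 1000L
      ann[[ci]] <- data.frame(
        contig_id = contig,
        gene_id = sprintf("%s_g%03d", contig, seq_len(n_genes)),
        start = starts, end = starts + 900L, strand = strands,
        label = labels, stringsAsFactors = FALSE)
      if (!is.na(cas_at))
        truth[[length(truth) + 1L]] <- data.frame(
          contig_id = contig, first_gene_index = cas_at,
          last_gene_index = cas_at + length(cassette) - 1L,
          stringsAsFactors = FALSE)
    }
    list(annotations = do.call(rbind, ann),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(contig_id = character(), first_gene_index = integer(),
                      last_gene_index = integer()))
  })
}

#' Simulate a per-field-of-view count table
#'
#' Cell totals are uniform over `cells_per_fov_range`; gene-positive counts
#' are binomial with the given true positive fraction.
#'
#' @param n_fovs Number of fields of view.
#' @param cells_per_fov_range Integer length-2 range of total cells per FOV.
#' @param true_fraction True per-cell probability of a gene signal (0-1).
#' @param experiment_id Experiment label for the table (default "sim").
#' @param seed Integer seed.
#' @return data.frame with columns `experiment_id`, `fov_id`,
#'   `total_cells`, `positive_cells`.
#' @export
simulate_fov_counts <- function(n_fovs = 20L, cells_per_fov_range = c(150L, 250L),
                                true_fraction = 0.7, experiment_id = "sim",
                                seed = NULL) {
  stopifnot(true_fraction >= 0, true_fraction <= 1, n_fovs >= 1)
  with_seed(seed, {
    totals <- sample(seq(cells_per_fov_range[1], cells_per_fov_range[2]),
                     n_fovs, replace = TRUE)
    data.frame(experiment_id = experiment_id,
               fov_id = sprintf("fov_%03d", seq_len(n_fovs)),
               total_cells = totals,
               positive_cells = rbinom(n_fovs, totals, true_fraction),
               stringsAsFactors = FALSE)
  })
}
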