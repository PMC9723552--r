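is_relevant_label <- function(label) {
  label %in% c("susC-like", "susD-like", "sulfatase") | grepl("^(GH|PL)[0-9]+$", label)
}

is_cazyme_label <- function(label) grepl("^(GH|PL)[0-9]+$", label)

#' Find SusCD-like tandem pairs on a contig
#'
#' SusCD-like tandem pairs - an immediately adjacent susC-like
#' (TonB-dependent transporter) and susD-like (substrate-binding) gene on
#' the same strand - are the hallmark of polysaccharide utilization loci.
#'
#' @param ann Annotation data.frame for one contig (columns `gene_id`,
#'   `start`, `end`, `strand`, `label`), sorted by start.
#' @return data.frame of tandems: `susC_gene`, `susD_gene`, `strand`,
#'   `first_index` (position of the first gene of the pair in the sorted
#'   annotation).
#' @export
find_suscd_tandems <- function(ann) {
  stopifnot(all(c("gene_id", "strand", "label") %in% names(ann)))
  if (is.unsorted(ann$start)) stop("annotations must be sorted by start", call. = FALSE)
  n <- nrow(ann)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      a <- ann$label[i]; b <- ann$label[i + 1]
      if (ann$strand[i] == ann$strand[i + 1] &&
          ((a == "susC-like" && b == "susD-like") ||
           (a == "susD-like" && b == "susC-like"))) {
        cidx <- if (a == "susC-like") i else i + 1L
        out[[length(out) + 1L]] <- data.frame(
          susC_gene = ann$gene_id[cidx], susD_gene = ann$gene_id[setdiff(c(i, i + 1L), cidx)],
          strand = ann$strand[i], first_index = i, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(susC_gene = character(), susD_gene = character(),
                      strand = character(), first_index = integer()))
  do.call(rbind, out)
}

#' Detect candidate polysaccharide utilization loci
#'
#' Groups each contig's PUL-relevant genes (susC-like, susD-like, GH and PL
#' family CAZymes, sulfatases) into maximal runs in which at most
#' `max_intergenic_genes` non-relevant genes separate consecutive relevant
#' genes, then evaluates each candidate locus against the PUL rule: at
#' least one susC- or susD-like gene and at least two degradative CAZymes
#' (GH or PL families). Loci additionally carrying at least one GH92 and at
#' least one sulfatase gene are flagged glucuronomannan-like (the
#' GH92-plus-sulfatase signature of sulfated-mannan-targeting loci).
#'
#' @param ann Annotation data.frame (see [read_annotations()]): columns
#'   `contig_id`, `gene_id`, `start`, `end`, `strand`, `label`, sorted by
#'   contig and start.
#' @param max_intergenic_genes Maximum number of consecutive non-relevant
#'   genes tolerated inside a locus (default 3).
#' @return data.frame of PUL calls: contig, gene index span (1-based
#'   indices into the contig's sorted gene list), first/last gene id, label
#'   class counts, `has_suscd_tandem`, `is_pul`, `glucuronomannan_like`.
#' @export
find_puls <- function(ann, max_intergenic_genes = 3L) {
  stopifnot(all(c("contig_id", "gene_id", "start", "end", "strand", "label") %in% names(ann)))
  calls <- list()
  for (contig in unique(ann$contig_id)) {
    ca <- ann[ann$contig_id == contig, , drop = FALSE]
    if (is.unsorted(ca$start)) stop("annotations must be sorted by start within contig",
                                    call. = FALSE)
    rel <- which(is_relevant_label(ca$label))
    if (!length(rel)) next
    # maximal runs of relevant genes separated by <= max_intergenic_genes others
    grp <- cumsum(c(1L, diff(rel) > max_intergenic_genes + 1L))
    for (g in unique(grp)) {
      idx <- rel[grp == g]
      span <- seq(min(idx), max(idx))
      labels <- ca$label[span]
      n_susC <- sum(labels == "susC-like")
      n_susD <- sum(labels == "susD-like")
      n_caz <- sum(is_cazyme_label(labels))
      n_gh92 <- sum(labels == "GH92")
      n_sulf <- sum(labels == "sulfatase")
      is_pul <- (n_susC + n_susD >= 1) && (n_caz >= 2)
      calls[[length(calls) + 1L]] <- data.frame(
        contig_id = contig, first_gene_index = min(idx), last_gene_index = max(idx),
        first_gene = ca$gene_id[min(idx)], last_gene = ca$gene_id[max(idx)],
        n_genes = length(span), n_susC = n_susC, n_susD = n_susD,
        n_cazymes = n_caz, n_gh92 = n_gh92, n_sulfatase = n_sulf,
        has_suscd_tandem = nrow(find_suscd_tandems(ca[span, , drop = FALSE])) > 0,
        is_pul = is_pul,
        glucuronomannan_like = is_pul && n_gh92 >= 1 && n_sulf >= 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(contig_id = character(), first_gene_index = integer(),
                      last_gene_index = integer(), first_gene = character(),
                      last_gene = character(), n_genes = integer(),
                      n_susC = integer(), n_susD = integer(), n_cazymes = integer(),
                      n_gh92 = integer(), n_sulfatase = integer(),
                      has_suscd_tandem = logical(), is_pul = logical(),
                      glucuronomannan_like = logical()))
  do.call(rbind, calls)
}

#' Homolog nucleotide-identity links between two loci
#'
#' Matches genes of two loci greedily by functional label and order along
#' the locus (the first GH92 of locus A pairs with the first GH92 of locus
#' B, and so on) and scores each matched pair by global pairwise nucleotide
#' identity, as used for synteny plots linking homologous PUL genes.
#'
#' @param locus_a,locus_b Annotation data.frames for the two loci (columns
#'   `gene_id`, `label`), sorted along the locus.
#' @param seqs_a,seqs_b Named character vectors of gene sequences (names are
#'   gene ids). Genes without a sequence are skipped with a warning.
#' @inheritParams align_probe
#' @return data.frame of links: `gene_id_a`, `gene_id_b`, `label`,
#'   `percent_identity`.
#' @export
homolog_links <- function(locus_a, locus_b, seqs_a, seqs_b,
                          scoring = list(match = 1, mismatch = -2,
                                         gap_open = 4, gap_extend = 1)) {
  out <- list()
  for (lab in intersect(unique(locus_a$label), unique(locus_b$label))) {
    ga <- locus_a$gene_id[locus_a$label == lab]
    gb <- locus_b$gene_id[locus_b$label == lab]
    for (i in seq_len(min(length(ga), length(gb)))) {
      a <- ga[i]; b <- gb[i]
      a_missing <- !a %in% names(seqs_a) || is.na(seqs_a[[a]])
      b_missing <- !b %in% names(seqs_b) || is.na(seqs_b[[b]])
      if (a_missing || b_missing) {
        warning("missing sequence for ", if (a_missing) a else b,
                "; link skipped", call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id_a = a, gene_id_b = b, label = lab,
        percent_identity = global_identity(seqs_a[[a]], seqs_b[[b]], scoring),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id_a = character(), gene_id_b = character(),
                      label = character(), percent_identity = numeric()))
  do.call(rbind, out)
}
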