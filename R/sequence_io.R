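#' Normalize a DNA sequence string
#'
#' Uppercases, converts U to T, and maps IUPAC ambiguity codes other than N
#' to N (with a warning). Alignment treats N as never matching.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector over the alphabet A, C, G, T, N.
#' @export
normalize_dna <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning("IUPAC ambiguity codes other than N mapped to N", call. = FALSE)
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A, C, G, T, N).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that normalizes
#' sequences (uppercase, U to T, ambiguity codes to N) and enforces
#' non-empty, unique record ids. Record ids are the first whitespace-
#' delimited token of each header.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped, LF or CRLF).
#' @return Named character vector of sequences; full headers are kept in
#'   attribute `description`.
#' @export
read_fasta <- function(path) {
  # BStringSet: no alphabet filtering on read; normalization handles case,
  # U -> T and ambiguity codes afterwards
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("no records in FASTA file '", path, "'", call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("empty record id in '", path, "'", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate record ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(set@ranges@width == 0))
    stop("empty sequence for record ", ids[set@ranges@width == 0][1],
         " in '", path, "'", call. = FALSE)
  seqs <- normalize_dna(as.character(set))
  names(seqs) <- ids
  attr(seqs, "description") <- headers
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- GenBank flat-file parsing (minimal: LOCUS/FEATURES/ORIGIN) ----------

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file: '", path, "'", call. = FALSE)
  feat_start <- grep("^FEATURES", lines)[1]
  origin <- grep("^ORIGIN", lines)[1]
  if (is.na(origin)) stop("GenBank file has no ORIGIN section", call. = FALSE)
  # sequence
  seq_lines <- lines[seq(origin + 1, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- normalize_dna(paste(gsub("[ 0-9/]", "", seq_lines), collapse = ""))
  # features: gene/CDS with a locus_tag
  feats <- list()
  if (!is.na(feat_start)) {
    block <- lines[seq(feat_start + 1, origin - 1)]
    key_idx <- grep("^ {5}\\S", block)
    for (k in seq_along(key_idx)) {
      first <- block[key_idx[k]]
      last <- if (k < length(key_idx)) key_idx[k + 1] - 1 else length(block)
      body <- paste(trimws(block[seq(key_idx[k], last)]), collapse = " ")
      key <- sub("^\\s*(\\S+).*", "\\1", first)
      loc <- sub("^\\s*\\S+\\s+(\\S+).*", "\\1", first)
      tag <- if (grepl("/locus_tag=\"", body))
        sub('.*?/locus_tag="([^"]+)".*', "\\1", body) else NA_character_
      product <- if (grepl("/product=\"", body))
        sub('.*?/product="([^"]+)".*', "\\1", body) else NA_character_
      strand <- if (grepl("^complement", loc)) "-" else "+"
      span <- regmatches(loc, regexpr("[0-9]+\\.\\.[0-9]+", loc))
      if (!length(span)) next
      se <- as.integer(strsplit(span, "\\.\\.")[[1]])
      feats[[length(feats) + 1L]] <- data.frame(
        key = key, locus_tag = tag, product = product,
        start = se[1], end = se[2], strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(key = character(), locus_tag = character(), product = character(),
               start = integer(), end = integer(), strand = character())
  record_id <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]
  list(id = record_id, sequence = sequence, features = features)
}

#' Extract a gene target from a FASTA or GenBank file
#'
#' For GenBank input, the gene is located by locus tag (gene or CDS
#' feature); for FASTA input, by record id plus an explicit interval.
#' Minus-strand genes are returned reverse-complemented, i.e. in coding
#' orientation. Intervals are 0-based half-open internally; GenBank's
#' 1-based closed coordinates are converted on read.
#'
#' @param path FASTA or GenBank flat file.
#' @param locus_tag Locus tag to extract (GenBank input).
#' @param record_id Record id (FASTA input; defaults to the only record).
#' @param interval Integer length-2 vector, 0-based half-open (FASTA input,
#'   or to override the GenBank feature span).
#' @param strand `"+"` or `"-"` (FASTA input).
#' @return A `gene_target`: list with `id`, `sequence` and `source`
#'   (record id, 0-based half-open interval, strand).
#' @export
extract_gene <- function(path, locus_tag = NULL, record_id = NULL,
                         interval = NULL, strand = "+") {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^LOCUS", first)) {
    gb <- parse_genbank(path)
    if (is.null(locus_tag)) stop("locus_tag required for GenBank input", call. = FALSE)
    hit <- gb$features[!is.na(gb$features$locus_tag) &
                         gb$features$locus_tag == locus_tag, , drop = FALSE]
    if (!nrow(hit)) {
      tags <- unique(stats::na.omit(gb$features$locus_tag))
      near <- tags[agrepl(locus_tag, tags, max.distance = 0.2)]
      stop("locus tag '", locus_tag, "' not found",
           if (length(near)) paste0("; near matches: ", paste(near, collapse = ", ")),
           call. = FALSE)
    }
    hit <- hit[1, ]
    iv <- c(hit$start - 1L, hit$end)  # to 0-based half-open
    seq <- substr(gb$sequence, iv[1] + 1L, iv[2])
    if (hit$strand == "-") seq <- revcomp(seq)
    return(gene_target(locus_tag, seq,
                       source = list(record_id = gb$id, interval = iv,
                                     strand = hit$strand)))
  }
  seqs <- read_fasta(path)
  if (is.null(record_id)) {
    if (length(seqs) != 1)
      stop("record_id required: FASTA has ", length(seqs), " records", call. = FALSE)
    record_id <- names(seqs)[1]
  }
  if (!record_id %in% names(seqs))
    stop("record '", record_id, "' not in '", path, "'", call. = FALSE)
  full <- seqs[[record_id]]
  if (is.null(interval)) interval <- c(0L, nchar(full))
  stopifnot(length(interval) == 2, interval[1] >= 0, interval[2] <= nchar(full),
            interval[1] < interval[2])
  seq <- substr(full, interval[1] + 1L, interval[2])
  if (strand == "-") seq <- revcomp(seq)
  gene_target(if (is.null(locus_tag)) record_id else locus_tag, seq,
              source = list(record_id = record_id, interval = as.integer(interval),
                            strand = strand))
}

#' Construct a gene target
#'
#' @param id Gene identifier.
#' @param sequence DNA sequence (normalized on construction).
#' @param source Optional provenance: list(record_id, interval, strand).
#' @return An object of class `gene_target`.
#' @export
gene_target <- function(id, sequence, source = NULL) {
  sequence <- normalize_dna(sequence)
  stopifnot(nzchar(id), nchar(sequence) > 0)
  structure(list(id = id, sequence = sequence, source = source),
            class = "gene_target")
}

#' @export
print.gene_target <- function(x, ...) {
  cat(sprintf("gene_target %s: %d bp, GC %.1f%%\n", x$id, nchar(x$sequence),
              gc_percent(x$sequence)))
  invisible(x)
}

# ---- annotations ---------------------------------------------------------

#' Default regex mapping from free-text products to controlled labels
#'
#' Used when reading GFF3/GenBank annotations whose functional labels live
#' in free-text `product`/`Name` attributes. First match wins; unmatched
#' genes get label `"other"`.
#'
#' @return Named character vector: regex -> label (a `GH`/`PL` label keeps
#'   its family number via backreference).
#' @export
default_label_map <- function() {
  c("[Ss]us[Cc]"                            = "susC-like",
    "TonB[- ]dependent (receptor|transporter)" = "susC-like",
    "[Ss]us[Dd]"                            = "susD-like",
    "[Ss]ulfatase"                          = "sulfatase",
    "[Gg]lycos(ide|yl) hydrolase family ([0-9]+)" = "GH\\2",
    "\\bGH([0-9]+)\\b"                      = "GH\\1",
    "[Pp]olysaccharide lyase family ([0-9]+)" = "PL\\1",
    "\\bPL([0-9]+)\\b"                      = "PL\\1")
}

#' Map free-text functional annotations to controlled labels
#'
#' @param text Character vector of product/name strings.
#' @param label_map Named regex vector, see [default_label_map()].
#' @return Character vector of controlled labels (`"other"` when nothing
#'   matches).
#' @export
map_label <- function(text, label_map = default_label_map()) {
  vapply(text, function(x) {
    if (is.na(x)) return("other")
    for (pat in names(label_map)) {
      m <- regexpr(pat, x)
      if (m[1] != -1L)  # substitute within the match so backreferences
        return(sub(pat, label_map[[pat]], regmatches(x, m)))  # (family no.) survive
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Read gene annotations for PUL screening
#'
#' Accepts either a plain TSV with columns `contig_id`, `gene_id`, `start`,
#' `end`, `strand`, `label` (start/end 0-based half-open) or a GFF3 file
#' (gene/CDS features; 1-based closed coordinates converted on read; labels
#' derived from `product`/`Name` attributes through `label_map`). Labels use
#' the controlled vocabulary `susC-like`, `susD-like`, `GH<n>`, `PL<n>`,
#' `sulfatase`, or `other`/free text.
#'
#' @param path Annotation file (TSV or GFF3).
#' @param label_map Named regex vector, see [default_label_map()].
#' @return A data.frame of annotations sorted by contig and start.
#' @export
read_annotations <- function(path, label_map = default_label_map()) {
  first <- readLines(path, n = 20L, warn = FALSE)
  if (any(grepl("^##gff-version", first)) || all(grepl("(^#|\t.*\t.*\t[0-9]+\t[0-9]+\t)",
                                                       first[nzchar(first)]))) {
    if (any(grepl("^##gff-version", first))) return(read_annotations_gff3(path, label_map))
  }
  ann <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("contig_id", "gene_id", "start", "end", "strand", "label")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation TSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  validate_annotations(ann[req])
}

read_annotations_gff3 <- function(path, label_map = default_label_map()) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 input requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("gene", "CDS")]
  meta <- as.data.frame(gr)
  text <- if ("product" %in% names(meta)) as.character(meta$product) else
    if ("Name" %in% names(meta)) as.character(meta$Name) else rep(NA_character_, nrow(meta))
  ids <- if ("locus_tag" %in% names(meta)) as.character(meta$locus_tag) else
    if ("ID" %in% names(meta)) as.character(meta$ID) else
      paste0("gene_", seq_len(nrow(meta)))
  ann <- data.frame(contig_id = as.character(meta$seqnames),
                    gene_id = ids,
                    start = meta$start - 1L,   # to 0-based half-open
                    end = meta$end,
                    strand = as.character(meta$strand),
                    label = map_label(text, label_map),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  stopifnot(all(ann$start >= 0), all(ann$end > ann$start),
            all(ann$strand %in% c("+", "-")))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene ids in annotations", call. = FALSE)
  ann <- ann[order(ann$contig_id, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# ---- tabular output ------------------------------------------------------

# TSV with fixed column order and header; deterministic byte output
write_tsv_strict <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read a per-field-of-view count table
#'
#' @param path TSV with columns `experiment_id`, `fov_id`, `total_cells`,
#'   `positive_cells` and optionally `group`.
#' @return data.frame of counts.
#' @export
read_fov_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("fov_id", "total_cells", "positive_cells")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

# GC percent of a sequence; N counts as non-GC (denominator = full length)
gc_percent <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[^GCgc]", "", seq))
  100 * gc / n
}
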