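toy_gbk <- function() system.file("extdata", "toy_contig.gbk", package = "polyprobe")

test_that("FASTA write/read round-trips and normalizes dialects", {
  seqs <- c(geneA = "ACGTACGTACGTAAACCCGGG", geneB = "TTTTGGGGCCCCAAAA")
  path <- tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(as.character(back), unname(seqs))
  expect_equal(names(back), names(seqs))
  # wrapped vs unwrapped and CRLF parse identically
  wrapped <- tempfile(fileext = ".fasta")
  write_fasta(seqs, wrapped, width = 7L)
  expect_equal(as.character(read_fasta(wrapped)), as.character(back))
  crlf <- tempfile(fileext = ".fasta")
  writeLines(gsub("\n", "\r\n", paste(readLines(path), collapse = "\n")), crlf)
  expect_equal(as.character(read_fasta(crlf)), as.character(back))
  # lowercase and U are normalized; other ambiguity codes become N
  lc <- tempfile(fileext = ".fasta")
  writeLines(c(">x desc here", "acgu", ">y", "acgryw"), lc)
  expect_warning(norm <- read_fasta(lc), "mapped to N")
  expect_equal(unname(norm["x"]), "ACGT")
  expect_equal(unname(norm["y"]), "ACGNNN")
})

test_that("duplicate or empty records are rejected", {
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("plus-strand GenBank extraction equals the naive slice", {
  g <- extract_gene(toy_gbk(), locus_tag = "TOY_0001")
  expect_equal(g$sequence, strrep("ACGTACGTAC", 6))
  expect_equal(g$source$interval, c(0L, 60L))
  expect_equal(g$source$strand, "+")
})

test_that("minus-strand GenBank extraction is reverse-complemented", {
  g <- extract_gene(toy_gbk(), locus_tag = "TOY_0002")
  # hand expectation: revcomp of positions 81..140 of the repeated decamer
  expect_equal(g$sequence, strrep("GTACGTACGT", 6))
  expect_equal(g$source$interval, c(80L, 140L))
  expect_equal(g$source$strand, "-")
})

test_that("third toy gene and near-match suggestions work", {
  g <- extract_gene(toy_gbk(), locus_tag = "TOY_0003")
  expect_equal(nchar(g$sequence), 60L)
  expect_error(extract_gene(toy_gbk(), locus_tag = "TOY_003"), "TOY_0001|near")
})

test_that("FASTA extraction honors intervals and strand", {
  path <- tempfile(fileext = ".fasta")
  write_fasta(c(chr = "AAACGTACGTTT"), path)
  plus <- extract_gene(path, record_id = "chr", interval = c(3, 10))
  expect_equal(plus$sequence, "CGTACGT")
  minus <- extract_gene(path, record_id = "chr", interval = c(3, 10), strand = "-")
  expect_equal(minus$sequence, revcomp("CGTACGT"))
})

test_that("annotation TSV reading validates and sorts", {
  path <- tempfile(fileext = ".tsv")
  ann <- data.frame(contig_id = "c1", gene_id = c("g2", "g1"),
                    start = c(1000, 0), end = c(1900, 900),
                    strand = "+", label = c("GH92", "susC-like"))
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_annotations(path)
  expect_equal(back$gene_id, c("g1", "g2"))   # sorted by start
  bad <- ann; bad$gene_id <- c("g1", "g1")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotations(path), "duplicate")
})

test_that("GFF3 annotations convert coordinates and map labels", {
  skip_if_not_installed("rtracklayer")
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("ctg1", "prokka", "CDS", "101", "1000", ".", "+", "0",
          "ID=g1;locus_tag=g1;product=SusC/RagA family TonB-linked outer membrane protein",
          sep = "\t"),
    paste("ctg1", "prokka", "CDS", "1101", "2000", ".", "+", "0",
          "ID=g2;locus_tag=g2;product=glycoside hydrolase family 92", sep = "\t"),
    paste("ctg1", "prokka", "CDS", "2101", "3000", ".", "-", "0",
          "ID=g3;locus_tag=g3;product=hypothetical protein", sep = "\t")), path)
  ann <- read_annotations(path)
  expect_equal(ann$start, c(100L, 1100L, 2100L))  # 1-based closed -> 0-based half-open
  expect_equal(ann$end, c(1000L, 2000L, 3000L))
  expect_equal(ann$label, c("susC-like", "GH92", "other"))
  expect_equal(ann$strand, c("+", "+", "-"))
})

test_that("free-text products map onto the controlled label vocabulary", {
  expect_equal(map_label(c("SusC protein", "TonB-dependent receptor",
                           "SusD family protein", "arylsulfatase",
                           "glycoside hydrolase family 92",
                           "GH16 beta-glucanase",
                           "polysaccharide lyase family 7",
                           "hypothetical protein", NA)),
               c("susC-like", "susC-like", "susD-like", "sulfatase",
                 "GH92", "GH16", "PL7", "other", "other"))
})

test_that("screen JSON output mirrors the tables and is deterministic", {
  fam <- simulate_gene_family(400, identity_targets = 100, seed = 71)
  ps <- tile_gene(gene_target("anc", fam$ancestor), k = 2, min_len = 180,
                  max_len = 210)
  sr <- screen_probes(ps, fam$homologs, min_hits = 2)
  p1 <- tempfile(); s1 <- tempfile(); j1 <- tempfile(fileext = ".json")
  p2 <- tempfile(); s2 <- tempfile(); j2 <- tempfile(fileext = ".json")
  write_screen_result(sr, p1, s1, j1)
  write_screen_result(sr, p2, s2, j2)
  expect_identical(readLines(j1), readLines(j2))
  js <- jsonlite::read_json(j1, simplifyVector = TRUE)
  expect_equal(js$set_table$set_hit, sr$set_table$set_hit)
  expect_equal(js$identity_threshold, 80)
  back <- read.delim(s1)
  expect_equal(back$n_probe_hits, sr$set_table$n_probe_hits)
})
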