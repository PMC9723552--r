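make_ann <- function(labels, strands = rep("+", length(labels)),
                     contig = "c1") {
  n <- length(labels)
  starts <- (seq_len(n) - 1L) * 1000L
  data.frame(contig_id = contig, gene_id = paste0(contig, "_g", seq_len(n)),
             start = starts, end = starts + 900L, strand = strands,
             label = labels, stringsAsFactors = FALSE)
}

test_that("susCD tandem detection requires adjacency and same strand", {
  t1 <- find_suscd_tandems(make_ann(c("susC-like", "susD-like")))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$susC_gene, "c1_g1")
  expect_equal(nrow(find_suscd_tandems(
    make_ann(c("susC-like", "other", "susD-like")))), 0L)
  expect_equal(nrow(find_suscd_tandems(
    make_ann(c("susC-like", "susD-like"), strands = c("+", "-")))), 0L)
  # reversed order still a tandem
  expect_equal(nrow(find_suscd_tandems(make_ann(c("susD-like", "susC-like")))), 1L)
})

test_that("the PUL rule needs a susC/D gene and two degradative CAZymes", {
  full <- find_puls(make_ann(c("susC-like", "susD-like", "GH92", "sulfatase", "GH16")))
  expect_equal(nrow(full), 1L)
  expect_true(full$is_pul)
  expect_true(full$glucuronomannan_like)
  expect_true(full$has_suscd_tandem)
  # only one CAZyme: not a PUL
  one_caz <- find_puls(make_ann(c("susC-like", "susD-like", "GH92")))
  expect_false(one_caz$is_pul)
  expect_false(one_caz$glucuronomannan_like)
  # two CAZymes but no transporter: not a PUL
  no_sus <- find_puls(make_ann(c("GH92", "sulfatase", "GH16")))
  expect_false(no_sus$is_pul)
  # PUL without sulfatase is not glucuronomannan-like
  no_sulf <- find_puls(make_ann(c("susC-like", "susD-like", "GH92", "GH16")))
  expect_true(no_sulf$is_pul)
  expect_false(no_sulf$glucuronomannan_like)
  # PL-family genes count as degradative CAZymes
  pl <- find_puls(make_ann(c("susD-like", "PL7", "GH92")))
  expect_true(pl$is_pul)
})

test_that("intergenic gaps split or join loci as configured", {
  labels <- c("susC-like", "susD-like", rep("other", 3), "GH92", "GH16")
  joined <- find_puls(make_ann(labels), max_intergenic_genes = 3)
  expect_equal(nrow(joined), 1L)
  expect_true(joined$is_pul)
  split <- find_puls(make_ann(labels), max_intergenic_genes = 2)
  expect_equal(nrow(split), 2L)
  expect_false(any(split$is_pul))
})

test_that("PUL calls equal the brute-force rule evaluation on synthetic contigs", {
  sim <- simulate_contigs(n_contigs = 100, seed = 41)
  got <- find_puls(sim$annotations)
  ora <- oracle_puls(sim$annotations)
  cols <- c("contig_id", "first_gene_index", "last_gene_index", "is_pul",
            "glucuronomannan_like")
  expect_equal(got[order(got$contig_id, got$first_gene_index), cols],
               ora[order(ora$contig_id, ora$first_gene_index), cols],
               ignore_attr = TRUE)
  # planted cassettes recovered with precision and recall 1
  called <- got[got$is_pul, ]
  key <- function(df) paste(df$contig_id, df$first_gene_index, df$last_gene_index)
  expect_setequal(key(called), key(sim$truth))
})

test_that("emitted calls satisfy their own invariants", {
  sim <- simulate_contigs(n_contigs = 30, seed = 42)
  calls <- find_puls(sim$annotations)
  expect_true(all(!calls$is_pul | (calls$n_susC + calls$n_susD >= 1 & calls$n_cazymes >= 2)))
  expect_true(all(!calls$glucuronomannan_like |
                    (calls$is_pul & calls$n_gh92 >= 1 & calls$n_sulfatase >= 1)))
})

test_that("calls are invariant to contig orientation", {
  sim <- simulate_contigs(n_contigs = 20, seed = 43)
  ann <- sim$annotations
  # reverse each contig: flip coordinates and strands, reverse order
  L <- vapply(ann$contig_id, function(c) max(ann$end[ann$contig_id == c]), numeric(1))
  flipped <- ann
  flipped$start <- L - ann$end
  flipped$end <- L - ann$start
  flipped$strand <- ifelse(ann$strand == "+", "-", "+")
  flipped <- flipped[order(flipped$contig_id, flipped$start), ]
  a <- find_puls(ann); b <- find_puls(flipped)
  expect_equal(sum(a$is_pul), sum(b$is_pul))
  expect_equal(sum(a$glucuronomannan_like), sum(b$glucuronomannan_like))
  expect_setequal(paste(a$contig_id, a$n_genes), paste(b$contig_id, b$n_genes))
})

test_that("unsorted annotations are rejected", {
  ann <- make_ann(c("susC-like", "susD-like", "GH92", "GH16"))
  expect_error(find_puls(ann[c(3, 1, 2, 4), ]), "sorted")
})

test_that("homolog links pair genes by label and order with known identities", {
  set.seed(44)
  genes <- list(susC = random_seq(300), susD = random_seq(250),
                gh92a = random_seq(400), gh92b = random_seq(400))
  locus_a <- data.frame(gene_id = c("a_susC", "a_gh92_1", "a_gh92_2"),
                        label = c("susC-like", "GH92", "GH92"),
                        stringsAsFactors = FALSE)
  locus_b <- data.frame(gene_id = c("b_susC", "b_gh92_1", "b_gh92_2"),
                        label = c("susC-like", "GH92", "GH92"),
                        stringsAsFactors = FALSE)
  # b's first GH92 mutated at 10% of sites
  mutate10 <- function(s) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), length(v) * 0.1)
    v[idx] <- vapply(v[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  seqs_a <- c(a_susC = genes$susC, a_gh92_1 = genes$gh92a, a_gh92_2 = genes$gh92b)
  seqs_b <- c(b_susC = genes$susC, b_gh92_1 = mutate10(genes$gh92a),
              b_gh92_2 = genes$gh92b)
  links <- homolog_links(locus_a, locus_b, seqs_a, seqs_b)
  expect_equal(nrow(links), 3L)
  expect_equal(links$percent_identity[links$gene_id_a == "a_susC"], 100)
  expect_equal(links$percent_identity[links$gene_id_a == "a_gh92_2"], 100)
  expect_equal(links$percent_identity[links$gene_id_a == "a_gh92_1"], 90,
               tolerance = 0.02)
  # disjoint label sets -> no links
  locus_c <- data.frame(gene_id = "c1", label = "PL7", stringsAsFactors = FALSE)
  expect_equal(nrow(homolog_links(locus_a, locus_c, seqs_a, c(c1 = "ACGT"))), 0L)
  # missing sequence -> warning and skipped link
  expect_warning(l2 <- homolog_links(locus_a, locus_b, seqs_a[-1], seqs_b),
                 "missing sequence")
  expect_equal(nrow(l2), 2L)
})
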