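test_that("identity and strand handling on constructed cases", {
  set.seed(31)
  probe <- random_seq(450)
  s <- align_probe(probe, probe)
  expect_equal(s$percent_identity, 100)
  expect_equal(s$longest_mismatch_stretch_bp, 0L)
  expect_equal(s$probe_coverage, 1)
  # one central substitution
  mut <- probe
  old <- substr(mut, 225, 225)
  substr(mut, 225, 225) <- setdiff(c("A", "C", "G", "T"), old)[1]
  s1 <- align_probe(probe, mut)
  expect_equal(s1$percent_identity, 449 / 450 * 100, tolerance = 1e-9)
  expect_equal(s1$longest_mismatch_stretch_bp, 1L)
  # probe embedded in a longer target, either strand
  target <- paste0(random_seq(200), probe, random_seq(200))
  expect_equal(align_probe(probe, target)$percent_identity, 100)
  sm <- align_probe(probe, revcomp(target))
  expect_equal(sm$percent_identity, 100)
  expect_equal(sm$strand, "-")
})

test_that("alignment matches the independent DP oracle on random pairs", {
  set.seed(32)
  for (i in 1:60) {
    np <- sample(10:60, 1); nt <- sample(np:80, 1)
    probe <- random_seq(np)
    target <- if (runif(1) < 0.5) random_seq(nt) else {
      # partially homologous target to exercise realistic traces
      m <- strsplit(probe, "")[[1]]
      sub <- sample(np, ceiling(np * 0.15))
      m[sub] <- vapply(m[sub], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(c(sample(c("A", "C", "G", "T"), nt - np, replace = TRUE), m), collapse = "")
    }
    got <- align_probe(probe, target)
    ora_f <- oracle_align(probe, target)
    ora_r <- oracle_align(probe, revcomp(target))
    ora <- if (ora_r$score > ora_f$score) ora_r else ora_f
    expect_equal(got$score, ora$score, info = paste("pair", i))
    expect_identical(got$trace, ora$trace, info = paste("pair", i))
    expect_equal(got$percent_identity, ora$identity, tolerance = 1e-9)
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  # third-party cross-check under the same scoring and gap convention
  set.seed(33)
  mat <- matrix(-2, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(mat) <- 1; mat["N", "N"] <- -2
  for (i in 1:20) {
    probe <- random_seq(sample(20:50, 1))
    target <- random_seq(sample(60:120, 1))
    got <- align_probe(probe, target)
    pa_f <- Biostrings::pairwiseAlignment(probe, target, type = "global-local",
                                          substitutionMatrix = mat,
                                          gapOpening = 4, gapExtension = 1)
    pa_r <- Biostrings::pairwiseAlignment(probe, revcomp(target), type = "global-local",
                                          substitutionMatrix = mat,
                                          gapOpening = 4, gapExtension = 1)
    expect_equal(got$score, max(Biostrings::score(pa_f), Biostrings::score(pa_r)),
                 info = paste("pair", i))
  }
})

test_that("longest mismatch stretch pools substitutions and gaps", {
  expect_equal(longest_mismatch_stretch(strrep("M", 12)), 0L)
  expect_equal(longest_mismatch_stretch(paste0(strrep("M", 10), strrep("X", 3),
                                               strrep("M", 5), strrep("D", 4), "M")), 4L)
  expect_equal(longest_mismatch_stretch("MMXXDDXM"), 5L)
  expect_equal(longest_mismatch_stretch("==XX=DD="), 2L)
  expect_equal(longest_mismatch_stretch("XXII"), 4L)
})

test_that("N never counts as a match", {
  s <- align_probe("ACGTN", "ACGTN")
  expect_lt(s$percent_identity, 100)
  expect_equal(s$percent_identity, 80)
})

test_that("set-level hit rule counts probes at the threshold", {
  r <- set_hit(c(85, 83, 92, 79, 80))
  expect_equal(r$n_probe_hits, 4L)
  expect_true(r$set_hit)
  r <- set_hit(rep(79, 5))
  expect_equal(r$n_probe_hits, 0L)
  expect_false(r$set_hit)
  r <- set_hit(c(100, 100, 100, 50))
  expect_false(r$set_hit)
  expect_true(set_hit(c(100, 100, 100, 50), min_hits = 3)$set_hit)
})

test_that("screen finds the probe's own gene and respects the threshold", {
  fam <- simulate_gene_family(ancestor_length = 1000, identity_targets = c(100, 70),
                              seed = 34)
  ps <- tile_gene(gene_target("anc", fam$ancestor), k = 5, min_len = 190,
                  max_len = 210)
  db <- c(self = fam$ancestor, fam$homologs)
  sr <- screen_probes(ps, db, hyb_conditions(fa_percent = 35))
  st <- sr$set_table
  expect_true(st$set_hit[st$target_id == "self"])
  expect_equal(st$implied_mismatch_percent[st$target_id == "self"], 0)
  expect_true(st$predicted_detectable_at_fa[st$target_id == "self"])
  expect_true(st$set_hit[st$target_id == "id100_r1"])
  expect_false(st$set_hit[st$target_id == "id70_r1"])
  # per-probe table has one row per probe x target
  expect_equal(nrow(sr$probe_table), 5 * 3)
})

test_that("screen is invariant to reverse-complementing a target", {
  fam <- simulate_gene_family(ancestor_length = 800, identity_targets = 90, seed = 35)
  ps <- tile_gene(gene_target("anc", fam$ancestor), k = 4, min_len = 190,
                  max_len = 210)
  fwd <- screen_probes(ps, c(t1 = fam$homologs[[1]]))
  rev <- screen_probes(ps, c(t1 = revcomp(fam$homologs[[1]])))
  expect_equal(fwd$probe_table$percent_identity, rev$probe_table$percent_identity)
  expect_equal(fwd$set_table$set_hit, rev$set_table$set_hit)
  expect_equal(fwd$set_table$implied_mismatch_percent,
               rev$set_table$implied_mismatch_percent)
})

test_that("raising the identity threshold never adds set hits", {
  fam <- simulate_gene_family(ancestor_length = 1000,
                              identity_targets = c(95, 85, 78, 70), seed = 36)
  ps <- tile_gene(gene_target("anc", fam$ancestor), k = 5, min_len = 190,
                  max_len = 210)
  hits <- vapply(c(70, 80, 90, 99), function(thr)
    sum(screen_probes(ps, fam$homologs, identity_threshold = thr)$set_table$set_hit),
    numeric(1))
  expect_true(all(diff(hits) <= 0))
})

test_that("detectability is monotone in formamide", {
  fam <- simulate_gene_family(ancestor_length = 1000, identity_targets = 88, seed = 37)
  ps <- tile_gene(gene_target("anc", fam$ancestor), k = 5, min_len = 190,
                  max_len = 210)
  det <- vapply(c(15, 25, 35, 45), function(fa)
    screen_probes(ps, fam$homologs,
                  hyb_conditions(fa_percent = fa))$set_table$predicted_detectable_at_fa,
    logical(1))
  # once undetectable at some FA, detectable only at lower FA
  expect_true(all(diff(as.integer(det)) <= 0))
})

test_that("duplicate database ids are rejected", {
  expect_error(screen_probes(c(p1 = "ACGTACGTACGT"),
                             setNames(c("ACGT", "ACGT"), c("a", "a"))),
               "duplicate")
})

test_that("global identity handles equal-length substitution pairs symmetrically", {
  set.seed(38)
  for (i in 1:10) {
    a <- random_seq(60)
    b <- strsplit(a, "")[[1]]
    idx <- sample(60, 6)
    b[idx] <- vapply(b[idx], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    b <- paste(b, collapse = "")
    expect_equal(global_identity(a, b), global_identity(b, a))
    expect_equal(global_identity(a, b), 90, tolerance = 1e-9)
  }
})
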