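# Independent reference implementations used as oracles. These mirror the
# documented conventions (scoring, gap costs, tie-breaks) but are written
# as plain, slow, matrix-based R so that agreement with the package is a
# meaningful cross-check.

# full-matrix affine-gap DP; probe global, target end gaps free unless
# global = TRUE. Tie-breaks: state preference M > P > Q, smallest target
# end index.
oracle_align <- function(probe, target, match = 1, mismatch = -2,
                         gap_open = 4, gap_extend = 1, global = FALSE) {
  p <- strsplit(probe, "")[[1]]; tg <- strsplit(target, "")[[1]]
  m <- length(p); n <- length(tg)
  oe <- gap_open + gap_extend; e <- gap_extend
  M <- P <- Q <- matrix(-Inf, m + 1, n + 1)
  tbM <- tbP <- tbQ <- matrix(0L, m + 1, n + 1)
  if (global) {
    M[1, 1] <- 0
    for (j in 2:(n + 1)) { Q[1, j] <- -(gap_open + (j - 1) * e); tbQ[1, j] <- if (j == 2) 0L else 2L }
  } else {
    M[1, ] <- 0
  }
  for (i in 2:(m + 1)) { P[i, 1] <- -(gap_open + (i - 1) * e); tbP[i, 1] <- if (i == 2) 0L else 1L }
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (p[i - 1] == tg[j - 1] && p[i - 1] != "N") match else mismatch
      cand <- c(M[i - 1, j - 1], P[i - 1, j - 1], Q[i - 1, j - 1])
      b <- which.max(cand)
      M[i, j] <- cand[b] + s; tbM[i, j] <- b - 1L
      # which.max's first-tie rule implements the M > P > Q preference
      cand_pref <- c(M[i - 1, j] - oe, P[i - 1, j] - e, Q[i - 1, j] - oe)
      b <- which.max(cand_pref)
      P[i, j] <- cand_pref[b]; tbP[i, j] <- b - 1L
      cand_pref <- c(M[i, j - 1] - oe, P[i, j - 1] - oe, Q[i, j - 1] - e)
      b <- which.max(cand_pref)
      Q[i, j] <- cand_pref[b]; tbQ[i, j] <- b - 1L
    }
  }
  if (global) {
    score <- max(M[m + 1, n + 1], P[m + 1, n + 1], Q[m + 1, n + 1])
    end_state <- c(0L, 1L, 2L)[which.max(c(M[m + 1, n + 1], P[m + 1, n + 1], Q[m + 1, n + 1]))]
    end_j <- n
  } else {
    score <- -Inf; end_j <- n; end_state <- 0L
    for (j in 0:n) {
      if (M[m + 1, j + 1] > score) { score <- M[m + 1, j + 1]; end_j <- j; end_state <- 0L }
      if (P[m + 1, j + 1] > score) { score <- P[m + 1, j + 1]; end_j <- j; end_state <- 1L }
    }
  }
  trace <- character(0)
  i <- m; j <- end_j; st <- end_state
  repeat {
    if (!global && i == 0) break
    if (global && i == 0 && j == 0) break
    if (st == 0L) {
      trace <- c(if (p[i] == tg[j] && p[i] != "N") "=" else "X", trace)
      st <- tbM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (st == 1L) {
      trace <- c("I", trace)
      st <- tbP[i + 1, j + 1]; i <- i - 1
    } else {
      trace <- c("D", trace)
      st <- tbQ[i + 1, j + 1]; j <- j - 1
    }
  }
  list(score = score, trace = paste(trace, collapse = ""),
       target_start = j, target_end = end_j,
       identity = 100 * sum(trace == "=") / length(trace))
}

# exhaustive tiling search mirroring tile_gene's objective and tie-breaks:
# minimal tm_spread + w * gc_spread; ties by maximal coverage, most equal
# lengths, leftmost breakpoints
oracle_tile <- function(seq, k, min_len, max_len, weight_gc = 1,
                        cond = hyb_conditions(fa_percent = 35)) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  cum_gc <- c(0, cumsum(chars %in% c("G", "C")))
  gc_of <- function(a, len) 100 * (cum_gc[a + len + 1] - cum_gc[a + 1]) / len
  best <- NULL
  lens <- seq.int(min_len, max_len)
  grids <- rep(list(lens), k)
  combos <- as.matrix(expand.grid(grids))
  starts <- 0:(max(L - k * min_len, 0))
  for (s in starts) {
    for (r in seq_len(nrow(combos))) {
      lv <- combos[r, ]
      if (s + sum(lv) > L) next
      a <- s; gcs <- numeric(k); tms <- numeric(k)
      for (i in seq_len(k)) {
        gcs[i] <- gc_of(a, lv[i])
        tms[i] <- as.numeric(wetmur_tm(duplex_params(gcs[i], lv[i]), cond))
        a <- a + lv[i]
      }
      obj <- diff(range(tms)) + weight_gc * diff(range(gcs))
      key <- list(obj = obj, coverage = sum(lv), spread = diff(range(lv)),
                  s = s, lens = lv)
      if (is.null(best) || better_tiling(key, best)) best <- key
    }
  }
  best
}

better_tiling <- function(a, b) {
  if (a$obj < b$obj - 1e-9) return(TRUE)
  if (a$obj > b$obj + 1e-9) return(FALSE)
  if (a$coverage != b$coverage) return(a$coverage > b$coverage)
  if (a$spread != b$spread) return(a$spread < b$spread)
  if (a$s != b$s) return(a$s < b$s)
  for (i in seq_along(a$lens)) if (a$lens[i] != b$lens[i]) return(a$lens[i] < b$lens[i])
  FALSE
}

# independent evaluation of the PUL rule over a contig's sorted gene list
oracle_puls <- function(ann, max_intergenic = 3L) {
  relevant <- function(lab) lab %in% c("susC-like", "susD-like", "sulfatase") |
    grepl("^(GH|PL)[0-9]+$", lab)
  calls <- list()
  for (contig in unique(ann$contig_id)) {
    ca <- ann[ann$contig_id == contig, , drop = FALSE]
    ca <- ca[order(ca$start), , drop = FALSE]
    rel <- which(relevant(ca$label))
    if (!length(rel)) next
    # split relevant genes wherever more than max_intergenic others intervene
    groups <- list(rel[1])
    for (x in rel[-1]) {
      last <- groups[[length(groups)]]
      if (x - last[length(last)] - 1L > max_intergenic) groups[[length(groups) + 1L]] <- x
      else groups[[length(groups)]] <- c(last, x)
    }
    for (g in groups) {
      labs <- ca$label[min(g):max(g)]
      caz <- sum(grepl("^(GH|PL)[0-9]+$", labs))
      is_pul <- (sum(labs %in% c("susC-like", "susD-like")) >= 1) && caz >= 2
      calls[[length(calls) + 1L]] <- data.frame(
        contig_id = contig, first_gene_index = min(g), last_gene_index = max(g),
        is_pul = is_pul,
        glucuronomannan_like = is_pul && sum(labs == "GH92") >= 1 &&
          sum(labs == "sulfatase") >= 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(data.frame(contig_id = character(),
                                        first_gene_index = integer(),
                                        last_gene_index = integer(),
                                        is_pul = logical(),
                                        glucuronomannan_like = logical()))
  do.call(rbind, calls)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
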