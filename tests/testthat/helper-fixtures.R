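# Small in-code fixtures and independent oracles shared across test files.

# Build a collapsed spectral-count data frame from bait/mock matrices
# (proteins x replicates).
make_counts <- function(bait, mock, mw = NULL, gene = NULL) {
  bait <- as.matrix(bait); mock <- as.matrix(mock)
  n <- nrow(bait)
  if (is.null(mw)) mw <- rep(100, n)
  if (is.null(gene)) gene <- sprintf("G%03d", seq_len(n))
  df <- data.frame(protein_id = sprintf("P%03d", seq_len(n)),
                   gene_symbol = gene, mw_kda = mw,
                   stringsAsFactors = FALSE)
  for (r in seq_len(ncol(bait))) {
    df[[sprintf("rep%d_bait", r)]] <- as.integer(bait[, r])
    df[[sprintf("rep%d_mock", r)]] <- as.integer(mock[, r])
  }
  df
}

# Random collapsed count table for property tests.
random_counts <- function(n, R = 4, seed = 1, max_count = 30) {
  set.seed(seed)
  make_counts(matrix(rpois(n * R, max_count / 3), n, R),
              matrix(rpois(n * R, max_count / 6), n, R),
              mw = round(runif(n, 10, 300), 1),
              gene = sprintf("G%03d", sample.int(max(2L, n %/% 2), n, replace = TRUE)))
}

# Independent straight-line recomputation of the whole AP-MS chain from a
# collapsed count table; plain loops, no package stage functions.
oracle_apms <- function(counts, pseudocount = 1) {
  reps <- sort(as.integer(sub("^rep([0-9]+)_bait$", "\\1",
                              grep("^rep[0-9]+_bait$", names(counts), value = TRUE))))
  n <- nrow(counts)
  S <- numeric(n); sumb <- numeric(n); summ <- numeric(n)
  for (i in seq_len(n)) {
    for (r in reps) {
      b <- counts[[paste0("rep", r, "_bait")]][i]
      m <- counts[[paste0("rep", r, "_mock")]][i]
      S[i] <- S[i] + (b - m); sumb[i] <- sumb[i] + b; summ[i] <- summ[i] + m
    }
  }
  keep1 <- S >= 0
  mean_s <- mean(S[keep1])
  thr <- ceiling(mean_s)
  keep2 <- keep1 & S > thr
  groups <- list()
  for (i in which(keep2)) {
    g <- counts$gene_symbol[i]
    if (is.null(groups[[g]])) groups[[g]] <- list(b = 0, m = 0, best_s = -Inf, mw = NA)
    groups[[g]]$b <- groups[[g]]$b + sumb[i]
    groups[[g]]$m <- groups[[g]]$m + summ[i]
    if (S[i] > groups[[g]]$best_s) {
      groups[[g]]$best_s <- S[i]; groups[[g]]$mw <- counts$mw_kda[i]
    }
  }
  out <- data.frame(gene_symbol = names(groups), stringsAsFactors = FALSE)
  out$sum_bait <- vapply(groups, function(g) g$b, 0)
  out$sum_mock <- vapply(groups, function(g) g$m, 0)
  out$S <- out$sum_bait - out$sum_mock
  out$mw <- vapply(groups, function(g) g$mw, 0)
  out$diff_score <- out$S / out$mw
  out$ratio_score <- out$sum_bait / (out$sum_mock + pseudocount)
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean_s") <- mean_s
  attr(out, "n_after_negative") <- sum(keep1)
  attr(out, "n_after_abundance") <- sum(keep2)
  out
}

# Exhaustive hypergeometric upper tail: enumerate every b-subset of the
# universe and count those overlapping list_a in >= k elements.
enumerate_hyper_tail <- function(U, a, b, k) {
  subsets <- combn(U, b)
  hits <- 0L
  for (j in seq_len(ncol(subsets)))
    if (sum(subsets[, j] <= a) >= k) hits <- hits + 1L
  hits / ncol(subsets)
}
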