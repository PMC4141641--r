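test_that("technical runs are summed and totals conserved", {
  df <- data.frame(protein_id = "P1", gene_symbol = "G1", mw_kda = 50,
                   rep1_bait_t1 = 2L, rep1_bait_t2 = 3L, rep1_bait_t3 = 1L,
                   rep1_mock_t1 = 0L, rep1_mock_t2 = 1L, rep1_mock_t3 = 0L)
  out <- collapse_technical(df)
  expect_equal(out$rep1_bait, 6L)
  expect_equal(out$rep1_mock, 1L)

  # single technical run: identity on the counts
  df1 <- make_counts(matrix(c(4, 2), 2, 1), matrix(c(1, 0), 2, 1))
  expect_equal(collapse_technical(df1)$rep1_bait, c(4L, 2L))

  # conservation on a random matrix with technical structure
  set.seed(8)
  rc <- data.frame(protein_id = sprintf("P%02d", 1:15),
                   gene_symbol = sprintf("G%02d", 1:15), mw_kda = 60)
  for (r in 1:3) for (ch in c("mock", "bait")) for (t in 1:2)
    rc[[sprintf("rep%d_%s_t%d", r, ch, t)]] <- rpois(15, 4)
  out <- collapse_technical(rc)
  expect_equal(sum(as.matrix(out[-(1:3)])), sum(as.matrix(rc[-(1:3)])))
})

test_that("a replicate missing one channel is rejected", {
  df <- data.frame(protein_id = "P1", gene_symbol = "G1", mw_kda = 50,
                   rep1_bait_t1 = 2L, rep1_mock_t1 = 1L, rep2_bait_t1 = 3L)
  expect_error(collapse_technical(df), "replicate 2")
})

test_that("detection sets, Venn regions and >=k tallies are consistent", {
  bait <- rbind(c(0, 0, 0, 0),
                c(3, 0, 1, 0),
                c(1, 1, 1, 1))
  counts <- make_counts(bait, matrix(0L, 3, 4))
  dp <- detection_partition(counts)
  expect_equal(unname(rowSums(dp$detected)), c(0, 2, 4))
  expect_equal(unname(dp$regions[["1,3"]]), 1L)
  expect_equal(unname(dp$regions[["1,2,3,4"]]), 1L)
  expect_equal(sum(dp$regions), 2L)  # undetected protein is in no region
  expect_equal(unname(dp$at_least), c(2L, 2L, 1L, 1L))
  expect_length(dp$regions, 2^4 - 1)

  # without dropout every planted interactor sits in the all-replicates region
  sim <- simulate_apms(apms_sim_config(n_proteins = 60, n_true_interactors = 8,
                                       enrichment_factor = 10, dropout_prob = 0,
                                       background_mean = 2, seed = 5))
  dp2 <- detection_partition(sim$counts)
  truth <- sim$truth$feature[sim$truth$is_true_positive]
  expect_true(all(rowSums(dp2$detected[truth, , drop = FALSE]) == 4))
})

test_that("background subtraction matches per-replicate arithmetic", {
  tab <- subtract_background(make_counts(rbind(c(6, 4)), rbind(c(1, 1))))
  expect_equal(c(tab$d_rep1, tab$d_rep2), c(5, 3))
  expect_equal(tab$S, 8)

  tab2 <- subtract_background(make_counts(rbind(c(0, 1)), rbind(c(3, 0))))
  expect_equal(c(tab2$d_rep1, tab2$d_rep2), c(-3, 1))
  expect_equal(tab2$S, -2)

  # all-zero mock: S equals total bait count
  tab3 <- subtract_background(make_counts(rbind(c(2, 5, 1, 0)), matrix(0L, 1, 4)))
  expect_equal(tab3$S, 8)
  expect_equal(tab3$detection_count, 3L)

  # sum conservation over the whole table
  rc <- random_counts(40, seed = 3)
  tabr <- subtract_background(rc)
  bait_cols <- grep("_bait$", names(rc), value = TRUE)
  mock_cols <- grep("_mock$", names(rc), value = TRUE)
  expect_equal(sum(tabr$S), sum(as.matrix(rc[bait_cols])) - sum(as.matrix(rc[mock_cols])))
})

test_that("negative subtracted sums are dropped, zero retained", {
  tab <- subtract_background(make_counts(rbind(c(0, 1), c(1, 1), c(5, 0)),
                                         rbind(c(3, 0), c(1, 1), c(1, 0))))
  tab <- drop_negative(tab)
  expect_equal(tab$dropped_negative, c(TRUE, FALSE, FALSE))  # S = -2, 0, 4
})

test_that("abundance filter cuts at the ceiling of the mean subtracted sum", {
  tab <- subtract_background(make_counts(matrix(c(12, 10, 8, 2), 4, 1),
                                         matrix(0L, 4, 1)))
  tab <- abundance_filter(drop_negative(tab), threshold = "auto")
  expect_equal(attr(tab, "mean_subtracted"), 8)
  expect_equal(attr(tab, "abundance_threshold"), 8)
  expect_equal(tab$dropped_abundance, c(FALSE, FALSE, TRUE, TRUE))

  # all equal: everything falls at S <= ceiling(mean)
  tab2 <- subtract_background(make_counts(matrix(7L, 3, 1), matrix(0L, 3, 1)))
  tab2 <- abundance_filter(drop_negative(tab2))
  expect_true(all(tab2$dropped_abundance))

  # explicit threshold override
  tab3 <- abundance_filter(drop_negative(tab), threshold = 10)
  expect_equal(tab3$dropped_abundance, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("redundant entries collapse by adding counts in both channels", {
  counts <- make_counts(rbind(c(5, 0), c(3, 0), c(2, 2)),
                        rbind(c(1, 0), c(0, 0), c(0, 1)),
                        mw = c(40, 60, 80),
                        gene = c("A", "A", "B"))
  tab <- abundance_filter(drop_negative(subtract_background(counts)),
                          threshold = 0)
  grp <- collapse_redundant(tab)
  a <- grp[grp$gene_symbol == "A", ]
  expect_equal(a$sum_bait, 8)
  expect_equal(a$sum_mock, 1)
  expect_equal(a$S, 7)
  expect_equal(a$mw_kda, 40)  # member with the largest S (5-1=4 vs 3)
  expect_equal(a$protein_id, "P001;P002")
  # singleton groups pass through unchanged
  b <- grp[grp$gene_symbol == "B", ]
  expect_equal(b$sum_bait, 4)
  expect_equal(b$mw_kda, 80)
})

test_that("scores follow the molecular-weight normalization arithmetic", {
  counts <- make_counts(rbind(c(8, 0)), rbind(c(0, 0)), mw = 80)
  tab <- collapse_redundant(abundance_filter(drop_negative(
    subtract_background(counts)), threshold = 0))
  tab <- normalize_and_score(tab, pseudocount = 1)
  expect_equal(tab$diff_score, 0.1)
  expect_equal(tab$ratio_score, 8)

  # equal bait and mock: zero difference, sub-unity pseudocounted ratio
  counts2 <- make_counts(rbind(c(4, 4)), rbind(c(4, 4)), mw = 50)
  tab2 <- normalize_and_score(collapse_redundant(abundance_filter(
    drop_negative(subtract_background(counts2)), threshold = -1)))
  expect_equal(tab2$diff_score, 0)
  expect_lt(tab2$ratio_score, 1)

  # doubling MW halves the difference score, leaves the ratio unchanged
  tab_half <- tab; tab_half$mw_kda <- 160
  tab_half <- normalize_and_score(tab_half)
  expect_equal(tab_half$diff_score, tab$diff_score / 2)
  expect_equal(tab_half$ratio_score, tab$ratio_score)
})

test_that("double ranking and its intersection match brute force", {
  rc <- random_counts(30, seed = 12)
  res <- run_apms_pipeline(rc, threshold = 0, top_n = 5)
  tab <- res$interactome
  brute_diff <- tab$gene_symbol[order(-tab$diff_score, -tab$ratio_score,
                                      tab$gene_symbol)][1:5]
  brute_ratio <- tab$gene_symbol[order(-tab$ratio_score, -tab$diff_score,
                                       tab$gene_symbol)][1:5]
  expect_equal(res$ranking$top_diff, brute_diff)
  expect_equal(res$ranking$top_ratio, brute_ratio)
  expect_setequal(res$ranking$shared, intersect(brute_diff, brute_ratio))

  # single protein: both lists identical
  one <- make_counts(rbind(c(5, 5)), rbind(c(0, 0)))
  res1 <- run_apms_pipeline(one, threshold = 0)
  expect_equal(res1$ranking$top_diff, res1$ranking$top_ratio)
  expect_equal(res1$ranking$n_shared, 1L)
})

test_that("pipeline equals independent straight-line recomputation", {
  for (s in 1:30) {
    rc <- random_counts(sample(5:20, 1), seed = s)
    orc <- oracle_apms(rc)
    if (nrow(orc) == 0) next
    res <- run_apms_pipeline(rc)
    tab <- as.data.frame(res$interactome)
    tab <- tab[order(tab$gene_symbol), ]
    expect_equal(tab$gene_symbol, orc$gene_symbol)
    expect_equal(tab$sum_bait, orc$sum_bait)
    expect_equal(tab$sum_mock, orc$sum_mock)
    expect_equal(tab$S, orc$S)
    expect_equal(tab$mw_kda, orc$mw)
    expect_equal(tab$diff_score, orc$diff_score)
    expect_equal(tab$ratio_score, orc$ratio_score)
    expect_equal(res$mean_subtracted, attr(orc, "mean_s"))
    expect_equal(res$stage_report$retained[2], attr(orc, "n_after_negative"))
    expect_equal(res$stage_report$retained[3], attr(orc, "n_after_abundance"))
  }
})

test_that("stage report is non-increasing and statuses partition the input", {
  rc <- random_counts(50, seed = 21)
  res <- run_apms_pipeline(rc)
  expect_true(all(diff(res$stage_report$retained[1:3]) <= 0))
  flags <- res$all_proteins
  status <- ifelse(flags$dropped_negative, "neg",
                   ifelse(flags$dropped_abundance, "abund", "kept"))
  expect_equal(length(status), nrow(rc))
  expect_equal(sum(status == "kept"), res$stage_report$retained[3])
})

test_that("scaling all counts by an integer scales S and preserves diff ranks", {
  rc <- random_counts(25, seed = 31)
  cnt_cols <- grep("^rep", names(rc), value = TRUE)
  rc3 <- rc
  for (cl in cnt_cols) rc3[[cl]] <- rc3[[cl]] * 3L
  t1 <- subtract_background(rc)
  t3 <- subtract_background(rc3)
  expect_equal(t3$S, 3 * t1$S)
  s1 <- normalize_and_score(collapse_redundant(abundance_filter(
    drop_negative(t1), threshold = -1)))
  s3 <- normalize_and_score(collapse_redundant(abundance_filter(
    drop_negative(t3), threshold = -1)))
  expect_equal(s3$diff_score, 3 * s1$diff_score)
  expect_equal(order(-s3$diff_score, s3$gene_symbol),
               order(-s1$diff_score, s1$gene_symbol))
})

test_that("planted bait-like interactors dominate the difference ranking", {
  hits <- 0L
  for (s in 1:5) {
    sim <- simulate_apms(apms_sim_config(n_proteins = 150, n_true_interactors = 10,
                                         enrichment_factor = 10, dropout_prob = 0.1,
                                         background_mean = 2, seed = s))
    res <- run_apms_pipeline(sim$counts)
    truth <- sub("P", "GENE", sim$truth$feature[sim$truth$is_true_positive])
    top1 <- res$ranking$top_diff[1]
    if (any(vapply(strsplit(top1, ";")[[1]], function(g) g %in% truth, TRUE)))
      hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})

test_that("empty or degenerate matrices raise errors, not empty reports", {
  expect_error(run_apms_pipeline(data.frame()), "non-empty")
  rc <- make_counts(rbind(c(0, 0)), rbind(c(5, 5)))  # everything negative
  expect_error(run_apms_pipeline(rc), "retained")
})
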