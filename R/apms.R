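#' @name apms
#' @title Spectral-count interactome filtering
#'
#' @description
#' Stage-wise reduction of an AP-MS spectral-count matrix to a
#' high-confidence, doubly-ranked bait interactome:
#' technical-replicate collapsing, mock background subtraction,
#' removal of proteins with negative subtracted sums, abundance
#' filtering at the mean subtracted count, redundancy collapsing of
#' database entries, molecular-weight normalization, and ranking by
#' both background-subtracted abundance and fold enrichment.
NULL

# ---- column dialect -------------------------------------------------------

COUNT_META_COLS <- c("protein_id", "gene_symbol", "mw_kda")

# Parse `rep{i}_{mock|bait}(_t{j})?` count columns into a layout table.
count_layout <- function(counts) {
  cols <- setdiff(names(counts), COUNT_META_COLS)
  m <- regmatches(cols, regexec("^rep([0-9]+)_(mock|bait)(?:_t([0-9]+))?$", cols))
  hit <- lengths(m) == 4L
  cols <- cols[hit]
  if (length(cols) == 0L) stopf("no count columns of the form rep{i}_{mock|bait}[_t{j}] found")
  m <- m[hit]
  data.frame(column = cols,
             replicate = as.integer(vapply(m, `[`, "", 2L)),
             channel = vapply(m, `[`, "", 3L),
             technical = ifelse(vapply(m, `[`, "", 4L) == "", NA_integer_,
                                suppressWarnings(as.integer(vapply(m, `[`, "", 4L)))),
             stringsAsFactors = FALSE)
}

check_counts <- function(counts) {
  miss <- setdiff(COUNT_META_COLS, names(counts))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(counts$protein_id))
    stopf("duplicate protein_id: %s",
          counts$protein_id[duplicated(counts$protein_id)][1L])
  if (any(!is.finite(counts$mw_kda) | counts$mw_kda <= 0))
    stopf("mw_kda must be positive for all proteins")
  lay <- count_layout(counts)
  for (cl in lay$column) {
    v <- counts[[cl]]
    if (any(!is.finite(v) | v < 0 | v != round(v)))
      stopf("column '%s' contains non-integer or negative counts", cl)
  }
  invisible(lay)
}

# ---- stages ---------------------------------------------------------------

#' Sum technical LC-MS/MS runs within each replicate and channel
#'
#' Spectral counts are event tallies, so technical runs of the same
#' sample are combined by summation, which conserves totals and keeps
#' counts integral. A matrix without technical suffixes passes through
#' unchanged.
#'
#' @param counts Spectral-count data frame (`protein_id`, `gene_symbol`,
#'   `mw_kda`, plus `rep{i}_{mock|bait}_t{j}` columns).
#' @return The same data frame with one `rep{i}_{mock|bait}` column per
#'   replicate and channel.
#' @export
collapse_technical <- function(counts) {
  lay <- check_counts(counts)
  out <- counts[COUNT_META_COLS]
  key <- unique(lay[c("replicate", "channel")])
  key <- key[order(key$replicate, key$channel == "mock"), ]
  for (i in seq_len(nrow(key))) {
    r <- key$replicate[i]; ch <- key$channel[i]
    src <- lay$column[lay$replicate == r & lay$channel == ch]
    out[[sprintf("rep%d_%s", r, ch)]] <-
      as.integer(rowSums(counts[, src, drop = FALSE]))
  }
  for (r in unique(key$replicate)) {
    have <- key$channel[key$replicate == r]
    if (!all(c("mock", "bait") %in% have))
      stopf("replicate %d is missing its %s channel", r,
            setdiff(c("mock", "bait"), have))
  }
  out
}

#' Replicate-detection sets and Venn-region tallies
#'
#' A protein counts as detected in a purification when its bait-channel
#' spectral count (after technical collapsing) is greater than zero.
#' Returns the full 2^R - 1 region partition of the R-way Venn diagram
#' over replicates, plus the cumulative detected-in-at-least-k tallies.
#'
#' @param counts Collapsed spectral-count data frame (see
#'   [collapse_technical()]).
#' @return A list of class `detection_partition`: `detected` (logical
#'   proteins x replicates matrix), `regions` (named counts, names like
#'   `"1,3"` for the region exclusive to replicates 1 and 3), and
#'   `at_least` (count of proteins detected in >= k replicates,
#'   k = 1..R).
#' @export
detection_partition <- function(counts) {
  counts <- collapse_technical(counts)
  lay <- count_layout(counts)
  reps <- sort(unique(lay$replicate))
  bait <- sapply(reps, function(r) counts[[sprintf("rep%d_bait", r)]] > 0)
  bait <- matrix(bait, nrow = nrow(counts),
                 dimnames = list(counts$protein_id, paste0("rep", reps)))
  R <- length(reps)
  pattern <- apply(bait, 1L, function(z) paste(reps[z], collapse = ","))
  region_names <- unlist(lapply(seq_len(R), function(k)
    utils::combn(reps, k, paste, collapse = ",")))
  regions <- stats::setNames(integer(length(region_names)), region_names)
  tab <- table(pattern[pattern != ""])
  regions[names(tab)] <- as.integer(tab)
  n_det <- rowSums(bait)
  at_least <- stats::setNames(
    vapply(seq_len(R), function(k) sum(n_det >= k), 0L),
    paste0(">=", seq_len(R)))
  structure(list(detected = bait, regions = regions, at_least = at_least),
            class = "detection_partition")
}

#' @export
print.detection_partition <- function(x, ...) {
  R <- ncol(x$detected)
  cat(sprintf("detection_partition: %d proteins over %d purifications\n",
              nrow(x$detected), R))
  cat("  detected in >=k replicates:",
      paste(sprintf("%s: %d", names(x$at_least), x$at_least), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subtract mock background per replicate and sum
#'
#' For each protein the mock-channel count is subtracted from the
#' bait-channel count within every replicate (d_i, which may be
#' negative), and the differences are summed over replicates into the
#' subtracted sum S.
#'
#' @param counts Spectral-count data frame; technical runs are collapsed
#'   first if present.
#' @return An `interactome_table` data frame: per-replicate `bait_rep{i}`,
#'   `mock_rep{i}` and `d_rep{i}` columns, `sum_bait`, `sum_mock`,
#'   `S = sum_bait - sum_mock`, `detection_count`, and stage flags
#'   `dropped_negative`/`dropped_abundance` (all `FALSE` initially).
#' @export
subtract_background <- function(counts) {
  counts <- collapse_technical(counts)
  lay <- count_layout(counts)
  reps <- sort(unique(lay$replicate))
  tab <- counts[COUNT_META_COLS]
  for (r in reps) {
    b <- counts[[sprintf("rep%d_bait", r)]]
    m <- counts[[sprintf("rep%d_mock", r)]]
    tab[[sprintf("bait_rep%d", r)]] <- b
    tab[[sprintf("mock_rep%d", r)]] <- m
    tab[[sprintf("d_rep%d", r)]] <- b - m
  }
  bait_cols <- sprintf("bait_rep%d", reps)
  mock_cols <- sprintf("mock_rep%d", reps)
  tab$sum_bait <- as.integer(rowSums(tab[bait_cols]))
  tab$sum_mock <- as.integer(rowSums(tab[mock_cols]))
  tab$S <- tab$sum_bait - tab$sum_mock
  tab$detection_count <- as.integer(rowSums(tab[bait_cols] > 0))
  tab$dropped_negative <- FALSE
  tab$dropped_abundance <- FALSE
  class(tab) <- c("interactome_table", "data.frame")
  tab
}

#' Drop proteins with negative subtracted sums
#'
#' A protein consistently more abundant in the mock purifications than
#' with the bait (summed difference S < 0) is flagged as background and
#' excluded from later stages. S = 0 is retained: the rule removes
#' strictly negative sums only, and such proteins fall at the abundance
#' filter regardless.
#'
#' @param table An `interactome_table` from [subtract_background()].
#' @return The table with `dropped_negative` set where `S < 0`.
#' @export
drop_negative <- function(table) {
  stopifnot(inherits(table, "interactome_table"))
  table$dropped_negative <- table$S < 0
  table
}

#' Remove low-abundance proteins at the mean subtracted count
#'
#' Proteins whose subtracted sum S does not exceed the threshold are
#' flagged `dropped_abundance`; they are candidate nonspecific
#' associations too sparse to call. With `threshold = "auto"` the cutoff
#' is `ceiling(mean(S))` over the proteins surviving [drop_negative()],
#' and proteins with `S <= threshold` are removed.
#'
#' @param table An `interactome_table` after [drop_negative()].
#' @param threshold `"auto"` or an explicit integer cutoff.
#' @return The table with `dropped_abundance` set; attributes
#'   `abundance_threshold` and `mean_subtracted` record the cutoff used
#'   and the pre-filter mean of S.
#' @export
abundance_filter <- function(table, threshold = "auto") {
  stopifnot(inherits(table, "interactome_table"))
  retained <- !table$dropped_negative
  if (!any(retained)) stopf("no proteins retained before abundance filtering")
  mean_s <- mean(table$S[retained])
  thr <- if (identical(threshold, "auto")) ceiling(mean_s) else {
    if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
      stopf("'threshold' must be \"auto\" or a single finite number")
    threshold
  }
  table$dropped_abundance <- retained & table$S <= thr
  attr(table, "abundance_threshold") <- thr
  attr(table, "mean_subtracted") <- mean_s
  table
}

#' Collapse redundant database entries into non-redundant groups
#'
#' Multiple accessions of one protein (typically isoforms that the
#' identified peptides cannot distinguish) are merged by adding their
#' bait and mock spectral counts per replicate; the subtracted sums are
#' then recomputed. The group inherits the molecular weight of the
#' member contributing the largest S (a representative-isoform
#' convention) and a `protein_id` concatenating the member accessions.
#'
#' @param table An `interactome_table` after [abundance_filter()]; only
#'   proteins not yet dropped are collapsed.
#' @param grouping Optional named character vector mapping `protein_id`
#'   to a group key; defaults to grouping by `gene_symbol`.
#' @return A new `interactome_table` with one row per group, sorted by
#'   group key.
#' @export
collapse_redundant <- function(table, grouping = NULL) {
  stopifnot(inherits(table, "interactome_table"))
  keep <- !table$dropped_negative & !table$dropped_abundance
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stopf("no proteins retained before collapsing")
  if (is.null(grouping)) {
    key <- tab$gene_symbol
  } else {
    key <- unname(grouping[tab$protein_id])
    if (any(is.na(key)))
      stopf("protein(s) missing from grouping map: %s",
            paste(tab$protein_id[is.na(key)], collapse = ", "))
  }
  reps <- as.integer(sub("^bait_rep", "", grep("^bait_rep", names(tab), value = TRUE)))
  rows <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    g <- tab[idx, , drop = FALSE]
    out <- g[1L, , drop = FALSE]
    out$protein_id <- paste(g$protein_id, collapse = ";")
    for (r in reps) {
      out[[sprintf("bait_rep%d", r)]] <- sum(g[[sprintf("bait_rep%d", r)]])
      out[[sprintf("mock_rep%d", r)]] <- sum(g[[sprintf("mock_rep%d", r)]])
      out[[sprintf("d_rep%d", r)]] <-
        out[[sprintf("bait_rep%d", r)]] - out[[sprintf("mock_rep%d", r)]]
    }
    out$sum_bait <- sum(g$sum_bait); out$sum_mock <- sum(g$sum_mock)
    out$S <- out$sum_bait - out$sum_mock
    out$mw_kda <- g$mw_kda[which.max(g$S)]
    out$detection_count <-
      as.integer(sum(colSums(g[sprintf("bait_rep%d", reps)]) > 0))
    out
  })
  out <- do.call(rbind, rows)
  out$gene_symbol <- names(rows)
  rownames(out) <- NULL
  class(out) <- c("interactome_table", "data.frame")
  out
}

#' Molecular-weight normalized abundance and enrichment scores
#'
#' Spectral counts scale with protein size (larger proteins yield more
#' tryptic peptides), so summed counts are divided by the molecular
#' weight before scoring. Two background corrections are computed:
#' `diff_score`, the normalized bait-minus-mock difference (per kDa),
#' and `ratio_score`, the fold enrichment of bait over mock with a raw
#' pseudocount added to the mock sum so that proteins never seen in the
#' mock purifications obtain a finite ratio.
#'
#' @param table An `interactome_table` after [collapse_redundant()].
#' @param pseudocount Raw mock counts added before normalization for the
#'   ratio (default 1); the difference is computed without it.
#' @return The table with `norm_bait`, `norm_mock`, `diff_score` and
#'   `ratio_score` columns added.
#' @export
normalize_and_score <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "interactome_table"))
  check_nonneg(pseudocount, "pseudocount")
  if (any(table$mw_kda <= 0)) stopf("mw_kda must be positive")
  table$norm_bait <- table$sum_bait / table$mw_kda
  table$norm_mock <- table$sum_mock / table$mw_kda
  table$diff_score <- (table$sum_bait - table$sum_mock) / table$mw_kda
  table$ratio_score <- (table$sum_bait / table$mw_kda) /
    ((table$sum_mock + pseudocount) / table$mw_kda)
  table
}

#' Rank the interactome two ways and intersect the top lists
#'
#' Sorts the scored table by background-subtracted abundance
#' (`diff_score`) and, independently, by fold enrichment
#' (`ratio_score`), both descending. Ties are broken by the other score
#' and then by group key, so output order is platform-independent.
#'
#' @param table A scored `interactome_table` ([normalize_and_score()]).
#' @param n How many top entries per list (default 25).
#' @return A list: `top_diff` and `top_ratio` (character vectors of group
#'   keys), `shared` (their intersection), `n_shared`, and the table with
#'   `rank_diff`/`rank_ratio` columns.
#' @export
rank_and_compare <- function(table, n = 25) {
  stopifnot(inherits(table, "interactome_table"))
  if (!is.numeric(n) || n < 1) stopf("'n' must be >= 1")
  if (is.null(table$diff_score)) stopf("scores missing; run normalize_and_score() first")
  o_diff <- order(-table$diff_score, -table$ratio_score, table$gene_symbol)
  o_ratio <- order(-table$ratio_score, -table$diff_score, table$gene_symbol)
  table$rank_diff <- order(o_diff)
  table$rank_ratio <- order(o_ratio)
  n <- min(n, nrow(table))
  top_diff <- table$gene_symbol[o_diff][seq_len(n)]
  top_ratio <- table$gene_symbol[o_ratio][seq_len(n)]
  shared <- intersect(top_diff, top_ratio)
  list(top_diff = top_diff, top_ratio = top_ratio, shared = shared,
       n_shared = length(shared), table = table)
}

#' Run the full spectral-count interactome pipeline
#'
#' Composes [collapse_technical()], [detection_partition()],
#' [subtract_background()], [drop_negative()], [abundance_filter()],
#' [collapse_redundant()], [normalize_and_score()] and
#' [rank_and_compare()], recording how many proteins survive each stage.
#'
#' @param counts Spectral-count data frame (see [read_counts()] for the
#'   on-disk dialect).
#' @param pseudocount Mock pseudocount for the enrichment ratio.
#' @param threshold `"auto"` (mean subtracted count) or an integer.
#' @param top_n Size of the ranked head-to-head comparison lists.
#' @param grouping Optional `protein_id` to group-key map (default: by
#'   gene symbol).
#' @return An object of class `apms_result`: `interactome` (final scored
#'   table), `all_proteins` (per-protein stage flags before collapsing),
#'   `venn` ([detection_partition()]), `ranking`
#'   ([rank_and_compare()] output), `stage_report` (stage, retained) and
#'   `mean_subtracted`.
#' @examples
#' sim <- simulate_apms(apms_sim_config(n_proteins = 60, seed = 2))
#' res <- run_apms_pipeline(sim$counts)
#' res$stage_report
#' @export
run_apms_pipeline <- function(counts, pseudocount = 1, threshold = "auto",
                              top_n = 25, grouping = NULL) {
  if (!is.data.frame(counts) || nrow(counts) == 0L)
    stopf("'counts' must be a non-empty spectral-count data frame")
  collapsed <- collapse_technical(counts)
  venn <- detection_partition(collapsed)
  tab <- subtract_background(collapsed)
  tab <- drop_negative(tab)
  tab <- abundance_filter(tab, threshold = threshold)
  groups <- collapse_redundant(tab, grouping = grouping)
  groups <- normalize_and_score(groups, pseudocount = pseudocount)
  ranking <- rank_and_compare(groups, n = top_n)
  stage_report <- data.frame(
    stage = c("identified", "background_subtracted", "abundance_filtered",
              "collapsed_nonredundant"),
    retained = c(nrow(tab), sum(!tab$dropped_negative),
                 sum(!tab$dropped_negative & !tab$dropped_abundance),
                 nrow(groups)),
    stringsAsFactors = FALSE)
  structure(list(interactome = ranking$table, all_proteins = tab,
                 venn = venn, ranking = ranking[c("top_diff", "top_ratio",
                                                 "shared", "n_shared")],
                 stage_report = stage_report,
                 mean_subtracted = attr(tab, "mean_subtracted"),
                 params = list(pseudocount = pseudocount,
                               threshold = attr(tab, "abundance_threshold"),
                               top_n = top_n)),
            class = "apms_result")
}

#' @export
print.apms_result <- function(x, ...) {
  cat("AP-MS interactome filtering\n")
  with(x$stage_report,
       cat(paste(sprintf("  %-24s %d", stage, retained), collapse = "\n"), "\n"))
  cat(sprintf("  mean subtracted count after background stage: %.2f\n",
              x$mean_subtracted))
  cat(sprintf("  abundance threshold: S <= %s dropped\n", x$params$threshold))
  cat(sprintf("  top-%d lists share %d proteins\n",
              x$params$top_n, x$ranking$n_shared))
  invisible(x)
}

#' @export
summary.apms_result <- function(object, ...) {
  tab <- object$interactome
  o <- order(-tab$diff_score)
  cat("High-confidence interactome (by background-subtracted score):\n")
  print(utils::head(as.data.frame(tab[o, c("gene_symbol", "sum_bait", "sum_mock",
                                           "S", "diff_score", "ratio_score")]),
                    10L), row.names = FALSE)
  cat("Replicate detection tallies:\n")
  print(object$venn$at_least)
  invisible(object)
}
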