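#' Configuration for a synthetic AP-MS spectral-count experiment
#'
#' Describes a pull-down design of `n_replicates` biological replicates,
#' each purified in a mock (empty-vector) and a bait channel and run
#' `n_technical` times on the instrument. Counts are integer spectral
#' counts; a protein's expected count scales linearly with its molecular
#' weight (larger proteins yield more tryptic peptides), and planted true
#' interactors have their bait-channel mean multiplied by
#' `1 + enrichment_factor`.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_true_interactors Number of planted bait-specific interactors
#'   (the first `n_true_interactors` proteins). Must not exceed
#'   `n_proteins`.
#' @param n_replicates Biological replicates (independent purifications).
#' @param n_technical Technical LC-MS/MS runs per sample.
#' @param background_mean Expected mock spectral count per technical run
#'   for a 100 kDa protein.
#' @param enrichment_factor Multiplier on the bait-channel mean of true
#'   interactors: bait mean = background mean times
#'   `(1 + enrichment_factor)`.
#' @param mw_log_mean,mw_log_sd Meanlog/sdlog of the log-normal molecular
#'   weight distribution (kDa).
#' @param dropout_prob Probability that a true interactor yields zero bait
#'   counts in a given replicate (exercises the replicate-detection Venn
#'   logic).
#' @param dispersion Optional negative-binomial size parameter for
#'   over-dispersed counts; `Inf` (default) gives Poisson counts.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `apms_sim_config`.
#' @seealso [simulate_apms()]
#' @export
apms_sim_config <- function(n_proteins = 300, n_true_interactors = 20,
                            n_replicates = 4, n_technical = 3,
                            background_mean = 2, enrichment_factor = 10,
                            mw_log_mean = log(50), mw_log_sd = 0.5,
                            dropout_prob = 0, dispersion = Inf, seed = 1) {
  check_positive(n_proteins, "n_proteins")
  check_nonneg(n_true_interactors, "n_true_interactors")
  if (n_true_interactors > n_proteins)
    stopf("'n_true_interactors' (%d) exceeds 'n_proteins' (%d)",
          n_true_interactors, n_proteins)
  check_positive(n_replicates, "n_replicates")
  check_positive(n_technical, "n_technical")
  check_positive(background_mean, "background_mean")
  check_nonneg(enrichment_factor, "enrichment_factor")
  check_prob(dropout_prob, "dropout_prob")
  check_positive(dispersion, "dispersion")
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_true_interactors = as.integer(n_true_interactors),
    n_replicates = as.integer(n_replicates),
    n_technical = as.integer(n_technical),
    background_mean = background_mean,
    enrichment_factor = enrichment_factor,
    mw_log_mean = mw_log_mean, mw_log_sd = mw_log_sd,
    dropout_prob = dropout_prob, dispersion = dispersion,
    seed = as.integer(seed)
  ), class = "apms_sim_config")
}

#' Simulate an AP-MS spectral-count matrix with planted interactors
#'
#' Draws integer spectral counts per (protein, replicate, channel,
#' technical run). Mock and bait channels share the same background mean
#' `background_mean * mw / 100`; for the planted true interactors the bait
#' mean is multiplied by `1 + enrichment_factor`, and with probability
#' `dropout_prob` an interactor's bait counts are zeroed in a whole
#' replicate. Counts are Poisson (or negative binomial when `dispersion`
#' is finite).
#'
#' @param config An [apms_sim_config()].
#' @return A list with `counts`, a spectral-count data frame in the
#'   canonical dialect (`protein_id`, `gene_symbol`, `mw_kda`, then one
#'   `rep{i}_{mock|bait}_t{j}` column per run), and `truth`, a truth table
#'   (`feature`, `is_true_positive`, `planted_effect`).
#' @examples
#' sim <- simulate_apms(apms_sim_config(n_proteins = 50, seed = 7))
#' head(sim$counts[, 1:6])
#' @export
simulate_apms <- function(config) {
  if (!inherits(config, "apms_sim_config"))
    stopf("'config' must be an apms_sim_config")
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    genes <- sprintf("GENE%04d", seq_len(n))
    mw <- stats::rlnorm(n, cf$mw_log_mean, cf$mw_log_sd)
    is_true <- seq_len(n) <= cf$n_true_interactors
    mu_mock <- cf$background_mean * mw / 100
    mu_bait <- mu_mock * ifelse(is_true, 1 + cf$enrichment_factor, 1)

    draw <- function(mu) {
      if (is.finite(cf$dispersion)) stats::rnbinom(length(mu), mu = mu, size = cf$dispersion)
      else stats::rpois(length(mu), mu)
    }

    counts <- data.frame(protein_id = ids, gene_symbol = genes,
                         mw_kda = mw, stringsAsFactors = FALSE)
    for (r in seq_len(cf$n_replicates)) {
      drop_r <- is_true & stats::runif(n) < cf$dropout_prob
      for (ch in c("mock", "bait")) {
        mu <- if (ch == "mock") mu_mock else ifelse(drop_r, 0, mu_bait)
        for (t in seq_len(cf$n_technical)) {
          counts[[sprintf("rep%d_%s_t%d", r, ch, t)]] <- draw(mu)
        }
      }
    }
    truth <- data.frame(feature = ids, is_true_positive = is_true,
                        planted_effect = ifelse(is_true, cf$enrichment_factor, 0),
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Configuration for a synthetic two-condition expression-array experiment
#'
#' Emulates a duplicate two-condition (GFP control vs bait-expressing)
#' BeadChip-style experiment at one or more timepoints: linear-scale
#' intensities `2^(baseline + effect + noise)` with per-probe, per-sample
#' detection p-values. The first `n_up` probes are planted upregulated and
#' the next `n_down` downregulated, with linear fold changes cycled from
#' `fold_changes`.
#'
#' @param n_probes Number of probes.
#' @param n_up,n_down Planted up/down probe counts.
#' @param fold_changes Linear fold changes (> 1) recycled over the planted
#'   probes.
#' @param baseline_log2_mean,baseline_log2_sd Per-probe baseline on the
#'   log2 scale.
#' @param noise_sd Replicate noise sd on the log2 scale.
#' @param undetected_frac Probability a probe is below detection; such
#'   probes receive detection p-values in \[0.05, 1\] everywhere and are
#'   removed by the downstream detection filter.
#' @param n_replicates Biological replicates per condition (default 2).
#' @param timepoints Timepoint labels in hours (default `c(7, 10)`).
#' @param seed Integer seed.
#' @return An object of class `array_sim_config`.
#' @seealso [simulate_expression()]
#' @export
array_sim_config <- function(n_probes = 2000, n_up = 50, n_down = 50,
                             fold_changes = 5, baseline_log2_mean = 8,
                             baseline_log2_sd = 1.5, noise_sd = 0.1,
                             undetected_frac = 0, n_replicates = 2,
                             timepoints = c(7, 10), seed = 1) {
  check_positive(n_probes, "n_probes")
  check_nonneg(n_up, "n_up"); check_nonneg(n_down, "n_down")
  if (n_up + n_down > n_probes)
    stopf("'n_up' + 'n_down' (%d) exceeds 'n_probes' (%d)", n_up + n_down, n_probes)
  if (any(fold_changes <= 1)) stopf("'fold_changes' must all be > 1")
  check_nonneg(noise_sd, "noise_sd")
  check_prob(undetected_frac, "undetected_frac")
  check_positive(n_replicates, "n_replicates")
  structure(list(
    n_probes = as.integer(n_probes), n_up = as.integer(n_up),
    n_down = as.integer(n_down), fold_changes = as.numeric(fold_changes),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
    undetected_frac = undetected_frac,
    n_replicates = as.integer(n_replicates),
    timepoints = timepoints, seed = as.integer(seed)
  ), class = "array_sim_config")
}

#' Simulate a detection-flagged expression matrix with planted fold changes
#'
#' @param config An [array_sim_config()].
#' @return A list with `expr`, an [expression_set()], and `truth`, a truth
#'   table whose `planted_effect` carries the signed linear fold change
#'   (+fc for up, -fc for down, 0 for null probes).
#' @examples
#' sim <- simulate_expression(array_sim_config(n_probes = 200, seed = 3))
#' sim$expr
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "array_sim_config"))
    stopf("'config' must be an array_sim_config")
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_probes
    probe_id <- sprintf("ILMN_%05d", seq_len(n))
    gene_symbol <- sprintf("GENE%05d", seq_len(n))
    effect <- numeric(n)
    if (cf$n_up > 0) {
      idx <- seq_len(cf$n_up)
      effect[idx] <- log2(rep_len(cf$fold_changes, cf$n_up))
    }
    if (cf$n_down > 0) {
      idx <- cf$n_up + seq_len(cf$n_down)
      effect[idx] <- -log2(rep_len(cf$fold_changes, cf$n_down))
    }

    samples <- expand.grid(replicate = seq_len(cf$n_replicates),
                           timepoint = cf$timepoints,
                           condition = c("GFP", "NKX3.1"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "timepoint", "replicate")]
    samples$sample <- sprintf("%s_%sh_r%d", samples$condition,
                              samples$timepoint, samples$replicate)

    baseline <- stats::rnorm(n, cf$baseline_log2_mean, cf$baseline_log2_sd)
    ns <- nrow(samples)
    log2int <- matrix(baseline, n, ns)
    bait_cols <- samples$condition == "NKX3.1"
    log2int[, bait_cols] <- log2int[, bait_cols] + effect
    if (cf$noise_sd > 0)
      log2int <- log2int + matrix(stats::rnorm(n * ns, 0, cf$noise_sd), n, ns)

    undetected <- stats::runif(n) < cf$undetected_frac
    detp <- matrix(stats::runif(n * ns, 0, 0.049), n, ns)
    if (any(undetected))
      detp[undetected, ] <- stats::runif(sum(undetected) * ns, 0.05, 1)

    dimnames(log2int) <- dimnames(detp) <- list(probe_id, samples$sample)
    expr <- expression_set(
      probes = data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                          stringsAsFactors = FALSE),
      intensity = 2^log2int, detection_p = detp,
      samples = samples[, c("sample", "condition", "timepoint", "replicate")])
    truth <- data.frame(
      feature = probe_id,
      is_true_positive = effect != 0 & !undetected,
      planted_effect = ifelse(effect == 0, 0, sign(effect) * 2^abs(effect)),
      stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

#' Simulate a qPCR threshold-cycle table with planted log2 ratios
#'
#' Generates long-format ct values for `genes` in two conditions (GFP and
#' NKX3.1) such that, after reference-gene normalization and log2
#' transformation, each gene's expected NKX3.1/GFP log2 ratio equals its
#' planted value: the bait-condition gene ct is lowered by
#' `planted_log2_ratios` cycles relative to the control condition, while
#' the reference gene keeps the same ct in both.
#'
#' @param genes Character vector of gene symbols (must not contain
#'   `ref_gene`).
#' @param planted_log2_ratios Numeric, one per gene.
#' @param ct_ref Reference-gene ct (cycles).
#' @param noise_sd Gaussian noise sd added to every ct value (cycles).
#' @param n_technical Technical replicates per (gene, condition).
#' @param ref_gene Reference gene symbol (default `"GAPDH"`).
#' @param timepoint Timepoint label attached to every row.
#' @param seed Integer seed.
#' @return A long-format data frame (`gene`, `condition`, `timepoint`,
#'   `replicate`, `ct`) including the reference gene in both conditions.
#' @examples
#' simulate_qpcr(c("MYC", "CDKN1A"), c(-1, 2), seed = 5)
#' @export
simulate_qpcr <- function(genes, planted_log2_ratios, ct_ref = 15,
                          noise_sd = 0, n_technical = 2,
                          ref_gene = "GAPDH", timepoint = 7, seed = 1) {
  if (length(genes) != length(planted_log2_ratios))
    stopf("'genes' and 'planted_log2_ratios' lengths differ")
  if (ref_gene %in% genes)
    stopf("'genes' must not contain the reference gene '%s'", ref_gene)
  check_nonneg(noise_sd, "noise_sd")
  check_positive(n_technical, "n_technical")
  with_seed(seed, {
    base_ct <- ct_ref + 5  # arbitrary, cancels in the ratio
    rows <- expand.grid(replicate = seq_len(n_technical),
                        condition = c("GFP", "NKX3.1"),
                        gene = c(ref_gene, genes),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    planted <- c(0, planted_log2_ratios)[match(rows$gene, c(ref_gene, genes))]
    ct0 <- ifelse(rows$gene == ref_gene, ct_ref, base_ct)
    ct0 <- ct0 - ifelse(rows$condition == "NKX3.1" & rows$gene != ref_gene,
                        planted, 0)
    data.frame(gene = rows$gene, condition = rows$condition,
               timepoint = timepoint, replicate = rows$replicate,
               ct = ct0 + stats::rnorm(nrow(rows), 0, noise_sd),
               stringsAsFactors = FALSE)
  })
}
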