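#' Convert a qPCR threshold cycle to a relative starting amount
#'
#' `X0 = E^(-ct)`: with amplification efficiency E (perfect doubling,
#' E = 2, by default), a template that crosses threshold one cycle later
#' started at 1/E the amount, so X0 is linearly related to input
#' template.
#'
#' @param ct Threshold cycle(s).
#' @param E Amplification efficiency per cycle, > 1.
#' @return Positive relative amount(s).
#' @examples
#' ct_to_x0(10)        # 2^-10
#' @export
ct_to_x0 <- function(ct, E = 2) {
  if (!is.numeric(E) || length(E) != 1L || E <= 1) stopf("'E' must be > 1")
  if (any(!is.finite(ct))) stopf("'ct' must be finite")
  E^(-ct)
}

#' Reference-normalized log2 expression ratio from ct values
#'
#' Converts the four ct values to relative amounts, normalizes the gene
#' to the reference within each condition, and returns the log2 ratio of
#' the treatment to the control condition. At E = 2 this equals the
#' familiar negative delta-delta-ct.
#'
#' @param ct_gene_trt,ct_ref_trt Gene and reference-gene ct in the
#'   treatment condition.
#' @param ct_gene_ctl,ct_ref_ctl The same in the control condition.
#' @param E Amplification efficiency, > 1.
#' @return The log2 treatment/control ratio.
#' @examples
#' normalized_ratio(20, 15, 22, 15)  # +2
#' @export
normalized_ratio <- function(ct_gene_trt, ct_ref_trt, ct_gene_ctl,
                             ct_ref_ctl, E = 2) {
  q_trt <- ct_to_x0(ct_gene_trt, E) / ct_to_x0(ct_ref_trt, E)
  q_ctl <- ct_to_x0(ct_gene_ctl, E) / ct_to_x0(ct_ref_ctl, E)
  log2(q_trt / q_ctl)
}

#' Mean and standard deviation over replicate log2 ratios
#'
#' Arithmetic mean and sample (n - 1) standard deviation; a single
#' replicate yields sd 0 with a note, there being no spread to estimate.
#'
#' @param x Numeric vector of log2 ratios (>= 1 value).
#' @return A list with `mean`, `sd` and `n`.
#' @export
summarize_replicates <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stopf("no finite replicate values")
  s <- if (length(x) >= 2L) stats::sd(x) else {
    message("single replicate: standard deviation reported as 0")
    0
  }
  list(mean = mean(x), sd = s, n = length(x))
}

#' Relative quantification of a long-format qPCR table
#'
#' For each gene and timepoint, pairs technical replicates of the
#' treatment and control conditions, normalizes each to the reference
#' gene measured in the same condition and replicate, forms log2
#' treatment/control ratios per replicate, and summarizes them as mean
#' and sample standard deviation.
#'
#' @param table Long-format data frame: `gene`, `condition`,
#'   `timepoint`, `replicate`, `ct`.
#' @param ref_gene Reference gene used for normalization (default
#'   `"GAPDH"`); must be present in both conditions at every timepoint.
#' @param trt_condition,ctl_condition Condition labels (defaults
#'   `"NKX3.1"` and `"GFP"`).
#' @param E Amplification efficiency, > 1.
#' @return An object of class `qpcr_result`: a data frame with `gene`,
#'   `timepoint`, `log2_ratio` (mean), `sd` and `n_replicates`.
#' @examples
#' tab <- simulate_qpcr(c("MYC"), -1.5, seed = 2)
#' run_qpcr_pipeline(tab)
#' @export
run_qpcr_pipeline <- function(table, ref_gene = "GAPDH",
                              trt_condition = "NKX3.1",
                              ctl_condition = "GFP", E = 2) {
  need <- c("gene", "condition", "timepoint", "replicate", "ct")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (!ref_gene %in% table$gene)
    stopf("reference gene '%s' absent from table", ref_gene)

  get_ct <- function(g, cond, tp, rep) {
    v <- table$ct[table$gene == g & table$condition == cond &
                  table$timepoint == tp & table$replicate == rep]
    if (length(v) != 1L)
      stopf("expected one ct for gene %s, condition %s, timepoint %s, replicate %s (found %d)",
            g, cond, tp, rep, length(v))
    v
  }

  genes <- setdiff(unique(table$gene), ref_gene)
  cells <- unique(table[table$gene %in% genes, c("gene", "timepoint")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$gene[i]; tp <- cells$timepoint[i]
    reps <- sort(unique(table$replicate[table$gene == g & table$timepoint == tp]))
    ratios <- vapply(reps, function(r) {
      normalized_ratio(get_ct(g, trt_condition, tp, r),
                       get_ct(ref_gene, trt_condition, tp, r),
                       get_ct(g, ctl_condition, tp, r),
                       get_ct(ref_gene, ctl_condition, tp, r), E = E)
    }, 0)
    sm <- summarize_replicates(ratios)
    data.frame(gene = g, timepoint = tp, log2_ratio = sm$mean, sd = sm$sd,
               n_replicates = sm$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qpcr_result", "data.frame")
  out
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("qPCR relative quantification (log2 treatment/control, reference-normalized)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
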