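#' Construct a signed gene list
#'
#' Gene symbols paired with a regulation sign (+1 up, -1 down). Symbols
#' are upper-cased and whitespace-stripped before matching; duplicates
#' (after normalization) are rejected.
#'
#' @param genes Character vector of symbols.
#' @param sign Integer vector of +1/-1, recycled if length 1.
#' @param name Optional list label.
#' @return An object of class `signed_gene_list` (data frame with `gene`
#'   and `sign`).
#' @export
signed_gene_list <- function(genes, sign = 1L, name = NULL) {
  genes <- normalize_symbols(genes)
  sign <- rep_len(as.integer(sign), length(genes))
  if (!all(sign %in% c(-1L, 1L))) stopf("signs must be +1 or -1")
  if (anyDuplicated(genes))
    stopf("duplicate gene symbol(s): %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(data.frame(gene = genes, sign = sign, stringsAsFactors = FALSE),
            class = c("signed_gene_list", "data.frame"), name = name)
}

as_gene_vector <- function(x) {
  if (inherits(x, "signed_gene_list")) x$gene else normalize_symbols(x)
}

#' Hypergeometric overlap test between two gene lists
#'
#' Given an explicit universe of U genes and two lists drawn from it,
#' computes the overlap k and the upper-tail probability
#' `P(X >= k)` for X hypergeometric(U, a, b) - the chance of an overlap
#' at least this large if list membership were independent. The universe
#' must be supplied: enrichment p-values are meaningless without a
#' defined background.
#'
#' @param universe Character vector of background gene symbols.
#' @param list_a,list_b Gene lists (character vectors or
#'   [signed_gene_list()]s), subsets of the universe.
#' @param outside How to treat list members absent from the universe:
#'   `"error"` (default) or `"drop"` (dropped with a warning).
#' @param alternative `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"` (doubled and capped at 1).
#' @return A list of class `overlap_result`: `U`, `a`, `b`, `k`,
#'   `p_hyper`, `overlap` (the shared symbols).
#' @examples
#' hypergeometric_overlap(sprintf("G%02d", 1:20),
#'                        sprintf("G%02d", 1:5), sprintf("G%02d", 3:6))
#' @export
hypergeometric_overlap <- function(universe, list_a, list_b,
                                   outside = c("error", "drop"),
                                   alternative = c("greater", "two.sided")) {
  outside <- match.arg(outside)
  alternative <- match.arg(alternative)
  universe <- unique(normalize_symbols(universe))
  a <- unique(as_gene_vector(list_a))
  b <- unique(as_gene_vector(list_b))
  for (nm in c("a", "b")) {
    lst <- get(nm)
    out <- setdiff(lst, universe)
    if (length(out)) {
      if (outside == "error")
        stopf("list %s has member(s) outside the universe: %s", nm,
              paste(utils::head(out, 5L), collapse = ", "))
      warning(sprintf("dropping %d list-%s member(s) outside the universe",
                      length(out), nm))
      assign(nm, intersect(lst, universe))
    }
  }
  U <- length(universe)
  k <- length(intersect(a, b))
  # P(X >= k), X ~ Hypergeometric(U, |a|, |b|)
  p <- stats::phyper(k - 1L, length(a), U - length(a), length(b),
                     lower.tail = FALSE)
  if (alternative == "two.sided") p <- min(1, 2 * p)
  structure(list(U = U, a = length(a), b = length(b), k = k, p_hyper = p,
                 overlap = intersect(a, b)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k = %d of lists %d and %d in a universe of %d; p = %.3g\n",
              x$k, x$a, x$b, x$U, x$p_hyper))
  if (!is.null(x$k_same))
    cat(sprintf("  direction: %d of %d %s; binomial p = %.3g\n",
                x$k_same, x$n, x$mode, x$p_binom))
  invisible(x)
}

#' Direction concordance of a signed overlap
#'
#' Among genes shared by two signed lists, counts those regulated in the
#' same (or, for a mirror-image comparison, the opposite) direction and
#' tests the count against a fair coin with a one-sided binomial
#' upper-tail p-value, `P(X >= count)` for X ~ Binomial(n, 1/2).
#'
#' @param list_a,list_b [signed_gene_list()]s with >= 1 shared gene.
#' @param mode `"same"` or `"inverse"`.
#' @return A list of class `overlap_result`: `n` (overlap size),
#'   `k_same` (concordant count under `mode`), `p_binom`, `mode`, and
#'   the concordant `genes`.
#' @examples
#' a <- signed_gene_list(LETTERS[1:10], rep(c(1, -1), 5))
#' b <- signed_gene_list(LETTERS[1:10], 1)
#' direction_concordance(a, b, mode = "same")
#' @export
direction_concordance <- function(list_a, list_b, mode = c("same", "inverse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(list_a, "signed_gene_list"),
            inherits(list_b, "signed_gene_list"))
  shared <- intersect(list_a$gene, list_b$gene)
  n <- length(shared)
  if (n == 0L) stopf("the lists share no genes; concordance undefined")
  sa <- list_a$sign[match(shared, list_a$gene)]
  sb <- list_b$sign[match(shared, list_b$gene)]
  hit <- if (mode == "same") sa == sb else sa != sb
  k <- sum(hit)
  p <- stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  structure(list(n = n, k_same = k, p_binom = p, mode = mode,
                 genes = shared[hit]),
            class = "overlap_result")
}

#' Per-direction inverse (mirror-image) fractions of a signed overlap
#'
#' For genes present in both signed lists, reports - separately for the
#' genes down in list B and the genes up in list B - the fraction
#' regulated in the opposite direction in list A. A perfectly
#' mirror-imaged pair of signatures scores 1.0 in both strata.
#'
#' @param list_a,list_b [signed_gene_list()]s.
#' @return A data frame with one row per stratum (`direction_in_b`,
#'   `n`, `n_inverse_in_a`, `fraction`); a stratum with no genes is
#'   reported with `fraction = NA`.
#' @export
inverse_signature_report <- function(list_a, list_b) {
  stopifnot(inherits(list_a, "signed_gene_list"),
            inherits(list_b, "signed_gene_list"))
  shared <- intersect(list_a$gene, list_b$gene)
  sa <- list_a$sign[match(shared, list_a$gene)]
  sb <- list_b$sign[match(shared, list_b$gene)]
  one <- function(dir_b) {
    idx <- sb == dir_b
    n <- sum(idx)
    inv <- sum(idx & sa == -dir_b)
    data.frame(direction_in_b = if (dir_b > 0) "up" else "down",
               n = n, n_inverse_in_a = inv,
               fraction = if (n > 0) inv / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one(-1L), one(1L))
}

#' Percent proliferating cells from image counts
#'
#' Pools label-positive and total cell counts over the images of one
#' well and reports `100 * sum(positive) / sum(total)` (pooled, not the
#' mean of per-image percentages).
#'
#' @param n_positive,n_total Per-image positive and total cell counts.
#' @return Percent positive for the well.
#' @examples
#' proliferation_percent(c(10, 20, 30, 40), rep(100, 4))  # 25
#' @export
proliferation_percent <- function(n_positive, n_total) {
  if (length(n_positive) != length(n_total))
    stopf("'n_positive' and 'n_total' lengths differ")
  if (any(n_total <= 0)) stopf("'n_total' must be positive")
  if (any(n_positive < 0 | n_positive > n_total))
    stopf("'n_positive' must lie in [0, n_total]")
  100 * sum(n_positive) / sum(n_total)
}
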