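#' Expression matrix with detection p-values and sample metadata
#'
#' A light container pairing a probes-by-samples intensity matrix
#' (linear scale, positive) with per-(probe, sample) detection p-values
#' and a sample sheet describing condition, timepoint and replicate.
#'
#' @param probes Data frame with `probe_id` (unique) and `gene_symbol`.
#' @param intensity Numeric matrix, probes x samples, strictly positive.
#' @param detection_p Numeric matrix in \[0, 1\], same shape.
#' @param samples Data frame with `sample`, `condition`, `timepoint`,
#'   `replicate`; `sample` must match `colnames(intensity)`.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(probes, intensity, detection_p, samples) {
  intensity <- as.matrix(intensity)
  detection_p <- as.matrix(detection_p)
  if (anyDuplicated(probes$probe_id))
    stopf("duplicate probe_id: %s",
          probes$probe_id[duplicated(probes$probe_id)][1L])
  if (!identical(dim(intensity), dim(detection_p)))
    stopf("intensity and detection_p dimensions differ")
  if (nrow(intensity) != nrow(probes))
    stopf("intensity has %d rows but probes has %d", nrow(intensity), nrow(probes))
  if (is.null(colnames(detection_p))) colnames(detection_p) <- colnames(intensity)
  if (!setequal(colnames(intensity), samples$sample) ||
      anyDuplicated(samples$sample))
    stopf("sample sheet does not match intensity columns")
  # align column order to the sample sheet
  intensity <- intensity[, samples$sample, drop = FALSE]
  detection_p <- detection_p[, samples$sample, drop = FALSE]
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stopf("intensities must be positive and finite (linear scale)")
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
    stopf("detection p-values must lie in [0, 1]")
  rownames(intensity) <- rownames(detection_p) <- probes$probe_id
  structure(list(probes = probes, intensity = intensity,
                 detection_p = detection_p, samples = samples),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d probes x %d samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat(sprintf("  conditions: %s\n",
              paste(unique(x$samples$condition), collapse = ", ")))
  cat(sprintf("  timepoints: %s h; replicates per cell: %s\n",
              paste(unique(x$samples$timepoint), collapse = ", "),
              paste(unique(table(x$samples$condition, x$samples$timepoint)),
                    collapse = "/")))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$intensity)

# Subset an expression_set by probe index/logical, keeping all slots aligned.
subset_probes <- function(es, keep) {
  expression_set(es$probes[keep, , drop = FALSE],
                 es$intensity[keep, , drop = FALSE],
                 es$detection_p[keep, , drop = FALSE],
                 es$samples)
}
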