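#' @name io
#' @title Readers and writers for the package's TSV dialects
#'
#' @description
#' Canonical on-disk formats are tab-delimited UTF-8 text with LF line
#' endings (CSV is accepted on read, chosen by file extension).
#' Intensities are stored on the linear scale; log transforms are
#' internal only. All writers emit deterministic column and row order.
NULL

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a spectral-count matrix
#'
#' The counts dialect has columns `protein_id`, `gene_symbol`, `mw_kda`,
#' then one integer column per run named `rep{i}_{mock|bait}_t{j}`
#' (`_t{j}` optional once technical runs are collapsed). Column order is
#' irrelevant on read; unknown extra columns are preserved untouched.
#' Duplicate protein ids, missing molecular weights and non-integer
#' counts are rejected with row context.
#'
#' @param path File path (TSV canonical; `.csv` accepted on read).
#' @param counts For `write_counts`, the data frame to write.
#' @return `read_counts`: the validated data frame. `write_counts`: the
#'   path, invisibly.
#' @export
read_counts <- function(path) {
  counts <- read_delim_auto(path)
  lay <- count_layout(counts)
  for (cl in lay$column) {
    v <- suppressWarnings(as.numeric(counts[[cl]]))
    bad <- !is.finite(v) | v < 0 | v != round(v)
    if (any(bad))
      stopf("%s: column '%s', row %d: count '%s' is not a non-negative integer",
            basename(path), cl, which(bad)[1L], counts[[cl]][which(bad)[1L]])
    counts[[cl]] <- as.integer(v)
  }
  if (!"mw_kda" %in% names(counts)) stopf("%s: missing 'mw_kda' column", basename(path))
  bad_mw <- !is.finite(counts$mw_kda) | counts$mw_kda <= 0
  if (any(bad_mw))
    stopf("%s: row %d: missing or non-positive molecular weight",
          basename(path), which(bad_mw)[1L])
  check_counts(counts)
  counts
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  check_counts(counts)
  write_tsv(counts, path)
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix dialect has `probe_id`, `gene_symbol`, then per sample a
#' `<sample>_intensity` and a `<sample>_detection_p` column. The sample
#' sheet has `sample`, `condition`, `timepoint`, `replicate`. Every
#' sample in the matrix must appear in the sheet.
#'
#' @param matrix_path Path to the expression matrix file.
#' @param samples_path Path to the sample sheet file.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, samples_path) {
  mat <- read_delim_auto(matrix_path)
  samples <- read_samplesheet(samples_path)
  int_cols <- grep("_intensity$", names(mat), value = TRUE)
  if (length(int_cols) == 0L)
    stopf("%s: no '<sample>_intensity' columns found", basename(matrix_path))
  snames <- sub("_intensity$", "", int_cols)
  missing_sheet <- setdiff(snames, samples$sample)
  if (length(missing_sheet))
    stopf("sample(s) in matrix absent from sample sheet: %s",
          paste(missing_sheet, collapse = ", "))
  dp_cols <- paste0(snames, "_detection_p")
  miss <- setdiff(dp_cols, names(mat))
  if (length(miss))
    stopf("%s: missing detection column(s): %s", basename(matrix_path),
          paste(miss, collapse = ", "))
  samples <- samples[samples$sample %in% snames, , drop = FALSE]
  intensity <- as.matrix(mat[int_cols]); colnames(intensity) <- snames
  detp <- as.matrix(mat[dp_cols]); colnames(detp) <- snames
  expression_set(probes = mat[c("probe_id", "gene_symbol")],
                 intensity = intensity, detection_p = detp,
                 samples = samples)
}

#' @rdname read_expression
#' @param es For `write_expression`, the [expression_set()] to write;
#'   the matrix and sample sheet are written to the two paths.
#' @export
write_expression <- function(es, matrix_path, samples_path) {
  stopifnot(inherits(es, "expression_set"))
  out <- es$probes
  for (s in es$samples$sample) {
    out[[paste0(s, "_intensity")]] <- es$intensity[, s]
    out[[paste0(s, "_detection_p")]] <- es$detection_p[, s]
  }
  write_tsv(out, matrix_path)
  write_tsv(es$samples, samples_path)
  invisible(c(matrix_path, samples_path))
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample`, `condition`, `timepoint`,
#'   `replicate`.
#' @return A data frame.
#' @export
read_samplesheet <- function(path) {
  sm <- read_delim_auto(path)
  miss <- setdiff(c("sample", "condition", "timepoint", "replicate"), names(sm))
  if (length(miss))
    stopf("%s: missing column(s): %s", basename(path), paste(miss, collapse = ", "))
  sm
}

#' Read a gene list, plain or signed
#'
#' A plain list has one symbol per line (sign +1 assumed); a signed list
#' is a two-column file of symbol and sign (+1/-1, also accepted as
#' `up`/`down`). Symbols are normalized (upper case, trimmed); repeated
#' symbols are deduplicated with a warning. CRLF line endings are
#' accepted.
#'
#' @param path File path.
#' @param name Optional list label.
#' @return A [signed_gene_list()].
#' @export
read_genelist <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("%s: empty gene list", basename(path))
  parts <- strsplit(lines, "[\t,]")
  genes <- normalize_symbols(vapply(parts, `[`, "", 1L))
  # drop a header line if present
  if (genes[1L] %in% c("GENE", "SYMBOL", "GENE_SYMBOL")) {
    parts <- parts[-1L]; genes <- genes[-1L]
  }
  sgn <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "1", "")
  sgn <- ifelse(tolower(sgn) %in% c("down", "-1", "-"), -1L, 1L)
  if (anyDuplicated(genes)) {
    warning(sprintf("%s: %d duplicated symbol(s) removed", basename(path),
                    sum(duplicated(genes))))
    keep <- !duplicated(genes)
    genes <- genes[keep]; sgn <- sgn[keep]
  }
  signed_gene_list(genes, sgn, name = name)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, all
#' tab-separated. Symbols are normalized; signs are not represented in
#' GMT, so sets come back unsigned.
#'
#' @param path GMT file path.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(p) {
    if (length(p) < 3L) stopf("GMT line with fewer than 3 fields: '%s'", p[1L])
    unique(normalize_symbols(p[-(1:2)]))
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  sets
}

#' Write the tables of an AP-MS pipeline result
#'
#' Emits `interactome.tsv` (one row per non-redundant group with all
#' scores and ranks), `stage_report.tsv`, and `venn_regions.tsv` into
#' `dir`.
#'
#' @param result An `apms_result` from [run_apms_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_apms_tables <- function(result, dir) {
  stopifnot(inherits(result, "apms_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(result$interactome)
  tab <- tab[order(tab$rank_diff), , drop = FALSE]
  p1 <- write_tsv(tab, file.path(dir, "interactome.tsv"))
  p2 <- write_tsv(result$stage_report, file.path(dir, "stage_report.tsv"))
  venn <- data.frame(region = names(result$venn$regions),
                     n_proteins = as.integer(result$venn$regions),
                     stringsAsFactors = FALSE)
  p3 <- write_tsv(venn, file.path(dir, "venn_regions.tsv"))
  invisible(c(p1, p2, p3))
}

#' Write the tables of a differential-expression result
#'
#' Emits per timepoint a full DE table (`de_<tp>.tsv`, volcano columns
#' included), up/down gene lists per fold cutoff
#' (`genes_<tp>_<fc>_{up,down}.txt`, signed two-column format), and the
#' stage report.
#'
#' @param result A `de_result` from [run_de_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_de_tables <- function(result, dir) {
  stopifnot(inherits(result, "de_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tp in names(result$tables)) {
    paths <- c(paths, write_tsv(result$tables[[tp]],
                                file.path(dir, sprintf("de_%s.tsv", tp))))
    for (fc in names(result$lists[[tp]])) {
      sel <- result$lists[[tp]][[fc]]
      for (dirn in c("up", "down")) {
        df <- sel[[dirn]]
        out <- data.frame(gene = df$gene_symbol,
                          sign = if (dirn == "up") 1L else -1L)
        paths <- c(paths, write_tsv(
          out, file.path(dir, sprintf("genes_%s_%s_%s.txt", tp, fc, dirn))))
      }
    }
  }
  paths <- c(paths, write_tsv(result$stage_report,
                              file.path(dir, "stage_report.tsv")))
  invisible(paths)
}
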