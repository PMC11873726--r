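#' Construct and validate a gene-by-sample expression matrix
#'
#' The expression container is a plain numeric matrix with gene identifiers
#' as row names and sample identifiers as column names. Values are assumed to
#' be already normalized (e.g. variance-stabilized counts or TPM); all
#' downstream statistics are normalization-agnostic.
#'
#' @param values numeric matrix (genes x samples) or object coercible to one.
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return validated numeric matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    ce_abort("expression matrix needs gene and sample identifiers",
             class = "clonexpr_format_error")
  }
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique gene and sample identifiers,
#' finite values, dimnames consistent with dimensions.
#'
#' @param x numeric matrix with dimnames.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    ce_abort("expression matrix must be a numeric matrix",
             class = "clonexpr_format_error")
  }
  g <- rownames(x); s <- colnames(x)
  if (is.null(g) || is.null(s)) {
    ce_abort("expression matrix must carry gene row names and sample column names",
             class = "clonexpr_format_error")
  }
  if (anyDuplicated(g)) {
    ce_abort(sprintf("duplicate gene identifier(s): %s",
                     paste(unique(g[duplicated(g)]), collapse = ", ")),
             class = "clonexpr_format_error")
  }
  if (anyDuplicated(s)) {
    ce_abort(sprintf("duplicate sample identifier(s): %s",
                     paste(unique(s[duplicated(s)]), collapse = ", ")),
             class = "clonexpr_format_error")
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    ce_abort(sprintf("non-finite expression value at gene '%s', sample '%s'",
                     g[bad[1L]], s[bad[2L]]),
             class = "clonexpr_format_error")
  }
  x
}

#' Read an expression matrix from disk
#'
#' Two plain-text layouts are supported: a TSV with gene rows, sample columns
#' and a header line, and a MatrixMarket-style whitespace triplet file
#' (row-index, col-index, value) with sidecar `<path>.genes` /
#' `<path>.samples` name files (one identifier per line).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx-triplet"`.
#' @return validated expression matrix.
#' @export
read_expression <- function(path, format = c("tsv", "mtx-triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ce_abort(sprintf("expression file not found: %s", path),
             class = "clonexpr_io_error")
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, colClasses = "character",
                            stringsAsFactors = FALSE, comment.char = "")
    gene_ids <- df[[1L]]
    body <- df[, -1L, drop = FALSE]
    values <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
    if (nrow(body) == 1L) values <- matrix(values, nrow = 1L,
                                           dimnames = list(NULL, colnames(body)))
    if (anyNA(values)) {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      ce_abort(sprintf(
        "non-numeric expression value at row %d (gene '%s'), column '%s'",
        bad[1L], gene_ids[bad[1L]], colnames(body)[bad[2L]]),
        class = "clonexpr_parse_error")
    }
    expression_matrix(values, gene_ids, colnames(body))
  } else {
    gfile <- paste0(path, ".genes"); sfile <- paste0(path, ".samples")
    if (!file.exists(gfile) || !file.exists(sfile)) {
      ce_abort("mtx-triplet input needs '<path>.genes' and '<path>.samples' sidecar files",
               class = "clonexpr_io_error")
    }
    genes <- readLines(gfile); samples <- readLines(sfile)
    trip <- utils::read.table(path, header = FALSE,
                              col.names = c("i", "j", "x"))
    m <- matrix(0, nrow = length(genes), ncol = length(samples))
    if (nrow(trip) > 0) {
      if (any(trip$i < 1 | trip$i > length(genes) |
              trip$j < 1 | trip$j > length(samples))) {
        ce_abort("triplet index out of bounds", class = "clonexpr_parse_error")
      }
      m[cbind(trip$i, trip$j)] <- trip$x
    }
    expression_matrix(m, genes, samples)
  }
}

#' Write an expression matrix to disk
#'
#' @param x expression matrix.
#' @param path output path.
#' @param format see [read_expression()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx-triplet")) {
  format <- match.arg(format)
  x <- validate_expression_matrix(x)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nz <- which(x != 0, arr.ind = TRUE)
    trip <- data.frame(i = nz[, 1L], j = nz[, 2L], x = x[nz])
    trip <- trip[order(trip$i, trip$j), , drop = FALSE]
    utils::write.table(trip, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(rownames(x), paste0(path, ".genes"))
    writeLines(colnames(x), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Filter genes by TPM prevalence
#'
#' Retains genes detected at `min_tpm` or more in at least `min_fraction` of
#' samples (both thresholds inclusive); the canonical cohort filter is
#' 1 TPM in at least 20% of samples. Input gene order is preserved.
#'
#' @param tpm expression matrix of non-negative TPM values.
#' @param min_tpm detection threshold (TPM).
#' @param min_fraction minimum fraction of samples at or above `min_tpm`.
#' @return character vector of retained gene ids.
#' @export
filter_genes_by_tpm <- function(tpm, min_tpm = 1, min_fraction = 0.20) {
  tpm <- validate_expression_matrix(tpm)
  stopifnot_fraction(min_fraction, "min_fraction")
  if (any(tpm < 0)) {
    ce_abort("TPM values must be non-negative", class = "clonexpr_format_error")
  }
  frac <- rowMeans(tpm >= min_tpm)
  rownames(tpm)[frac >= min_fraction]
}

#' log2(CPM + 1) fallback normalizer
#'
#' A simple library-size normalization for raw counts, provided as a clearly
#' labelled non-VST fallback: per-sample counts are scaled to counts per
#' million and log2(x + 1) transformed. The pipeline's statistics do not
#' depend on the choice of normalization.
#'
#' @param counts matrix of non-negative counts (genes x samples).
#' @return expression matrix of log2(CPM + 1) values.
#' @export
normalize_log2cpm <- function(counts) {
  counts <- validate_expression_matrix(counts)
  if (any(counts < 0)) {
    ce_abort("counts must be non-negative", class = "clonexpr_format_error")
  }
  libs <- colSums(counts)
  if (any(libs == 0)) {
    ce_abort("sample with zero library size", class = "clonexpr_format_error")
  }
  expression_matrix(log2(sweep(counts, 2L, libs, "/") * 1e6 + 1),
                    rownames(counts), colnames(counts))
}
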