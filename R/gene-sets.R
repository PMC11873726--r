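#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Empty sets are rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      ce_abort("GMT line with fewer than 3 fields (name, description, >=1 gene)",
               class = "clonexpr_parse_error")
    }
    unique(parts[-(1:2)])
  })
  names(sets) <- vcapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L])
  if (anyDuplicated(names(sets))) {
    ce_abort("duplicate gene-set names in GMT", class = "clonexpr_format_error")
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vcapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Gene coordinate / arm annotation table
#'
#' Coordinates are 1-based inclusive; arm membership is decided by the gene
#' start coordinate and strand is ignored (expression-level analysis).
#'
#' @param gene_id,chromosome,arm character vectors.
#' @param start,end integer coordinates, `start <= end`.
#' @return data.frame with one row per gene.
#' @export
gene_annotation <- function(gene_id, chromosome, arm, start, end) {
  if (any(start > end)) {
    ce_abort("gene annotation with start > end", class = "clonexpr_format_error")
  }
  chrom_of_arm <- sub("[pq]$", "", arm)
  if (any(chrom_of_arm != sub("^chr", "", as.character(chromosome)))) {
    ce_abort("arm label inconsistent with chromosome",
             class = "clonexpr_format_error")
  }
  data.frame(gene_id = as.character(gene_id),
             chromosome = as.character(chromosome), arm = as.character(arm),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' @rdname gene_annotation
#' @param path TSV path with columns gene_id, chromosome, arm, start, end.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_annotation(df$gene_id, df$chromosome, df$arm, df$start, df$end)
}

#' @rdname gene_annotation
#' @param annotation annotation data.frame.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
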