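#' Construct an immune repertoire
#'
#' A repertoire is a per-sample mapping from clonotype key to a strictly
#' positive read/UMI count. The key convention is
#' `<locus>|<V>|<J>|<CDR3aa>` (MiXCR-style clonotype semantics); TCR pools
#' alpha+beta loci and BCR pools kappa+lambda, so the `chain` field carries
#' only TCR/BCR.
#'
#' @param sample_id sample identifier.
#' @param chain `"TCR"` or `"BCR"`.
#' @param counts named numeric vector, names are clonotype keys, values
#'   strictly positive counts.
#' @return object of class `repertoire`.
#' @export
repertoire <- function(sample_id, chain = c("TCR", "BCR"), counts) {
  chain <- match.arg(chain)
  if (length(counts) == 0) {
    ce_abort("repertoire must contain at least one clonotype",
             class = "clonexpr_format_error")
  }
  if (is.null(names(counts)) || anyDuplicated(names(counts))) {
    ce_abort("clonotype keys must be unique and named",
             class = "clonexpr_format_error")
  }
  if (any(counts <= 0)) {
    ce_abort("clonotype counts must be strictly positive",
             class = "clonexpr_format_error")
  }
  structure(list(sample_id = as.character(sample_id), chain = chain,
                 counts = counts),
            class = "repertoire")
}

#' Read clonotype tables (AIRR-style TSV)
#'
#' Expected columns: `sample_id`, `chain` (TCR/BCR), `clonotype_key`,
#' `count`. Rows are grouped into one [repertoire()] per (sample, chain).
#'
#' @param path TSV path.
#' @return named list of repertoires keyed `"<sample_id>.<chain>"`.
#' @export
read_repertoires <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "chain", "clonotype_key", "count")
  if (!all(need %in% names(df))) {
    ce_abort(sprintf("repertoire TSV must have columns: %s",
                     paste(need, collapse = ", ")),
             class = "clonexpr_format_error")
  }
  keys <- paste(df$sample_id, df$chain, sep = ".")
  out <- lapply(split(df, keys), function(d) {
    repertoire(d$sample_id[1L], d$chain[1L],
               stats::setNames(as.numeric(d$count), d$clonotype_key))
  })
  out
}

#' @rdname read_repertoires
#' @param reps list of repertoires.
#' @export
write_repertoires <- function(reps, path) {
  rows <- do.call(rbind, lapply(reps, function(r) {
    data.frame(sample_id = r$sample_id, chain = r$chain,
               clonotype_key = names(r$counts),
               count = unname(r$counts), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
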