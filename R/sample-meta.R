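#' Construct a per-sample metadata table
#'
#' One row per RNA sample. Driver status is stored in logical columns named
#' `driver_<name>` (e.g. `driver_9p_loss`, `driver_SETD2`); the clones
#' detected in a sample live in the list-column `clones` (character vectors,
#' empty for normal samples).
#'
#' @param sample_id,patient_id character vectors.
#' @param sample_type one of `"primary"`, `"metastasis"`, `"thrombus"`,
#'   `"normal"` per sample.
#' @param purity tumor purity in `[0, 1]`; `NA` is replaced by 1 with a
#'   warning (purity only ever enters as a covariate).
#' @param wGII weighted genome instability index in `[0, 1]`.
#' @param wgd logical whole-genome-doubling flag.
#' @param clones list of character vectors of clone ids.
#' @param drivers named list of logical vectors (one per driver), or a
#'   data.frame of logical columns.
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, patient_id, sample_type, purity, wGII,
                        wgd, clones = NULL, drivers = NULL) {
  n <- length(sample_id)
  sample_type <- match.arg(as.character(sample_type),
                           c("primary", "metastasis", "thrombus", "normal"),
                           several.ok = TRUE)
  if (length(sample_type) == 1L) sample_type <- rep(sample_type, n)
  if (anyNA(purity)) {
    ce_warn(sprintf("%d sample(s) with missing purity set to 1.0",
                    sum(is.na(purity))))
    purity[is.na(purity)] <- 1
  }
  if (any(purity < 0 | purity > 1) || any(wGII < 0 | wGII > 1)) {
    ce_abort("purity and wGII must lie in [0, 1]",
             class = "clonexpr_format_error")
  }
  if (anyDuplicated(sample_id)) {
    ce_abort("duplicate sample_id in metadata", class = "clonexpr_format_error")
  }
  clones <- clones %||% rep(list(character(0)), n)
  df <- data.frame(sample_id = as.character(sample_id),
                   patient_id = as.character(patient_id),
                   sample_type = sample_type,
                   purity = as.numeric(purity), wGII = as.numeric(wGII),
                   wgd = as.logical(wgd), stringsAsFactors = FALSE)
  df$clones <- unname(lapply(clones, as.character))
  if (any(df$sample_type == "normal" &
          viapply(df$clones, length) > 0L)) {
    ce_abort("normal samples must have an empty clone set",
             class = "clonexpr_format_error")
  }
  if (!is.null(drivers)) {
    for (d in names(drivers)) df[[paste0("driver_", d)]] <- as.logical(drivers[[d]])
  }
  class(df) <- c("sample_meta", "data.frame")
  df
}

driver_columns <- function(meta) {
  grep("^driver_", names(meta), value = TRUE)
}

#' Per-sample status of one driver
#' @param meta sample_meta table.
#' @param driver driver name without the `driver_` prefix.
#' @return named logical vector keyed by sample id.
#' @export
driver_status <- function(meta, driver) {
  col <- paste0("driver_", driver)
  if (!col %in% names(meta)) {
    ce_abort(sprintf("no driver column '%s' in metadata", col),
             class = "clonexpr_lookup_error")
  }
  stats::setNames(meta[[col]], meta$sample_id)
}

#' Read / write sample metadata (TSV)
#'
#' Clone sets are serialized as semicolon-separated lists; driver columns
#' keep their `driver_` prefix, values TRUE/FALSE.
#'
#' @param path file path.
#' @return a `sample_meta` data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  clones <- strsplit(ifelse(is.na(df$clones) | df$clones == "", "",
                            df$clones), ";", fixed = TRUE)
  drv <- df[, grep("^driver_", names(df)), drop = FALSE]
  sample_meta(df$sample_id, df$patient_id, df$sample_type, df$purity,
              df$wGII, df$wgd, clones = clones,
              drivers = stats::setNames(
                lapply(names(drv), function(n) as.logical(drv[[n]])),
                sub("^driver_", "", names(drv))))
}

#' @rdname read_sample_meta
#' @param meta sample_meta table.
#' @export
write_sample_meta <- function(meta, path) {
  out <- as.data.frame(meta, stringsAsFactors = FALSE)
  out$clones <- vcapply(meta$clones, paste, collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate metadata against clone trees
#'
#' Checks every non-normal sample's clones resolve in the patient's tree;
#' tumor samples with zero detected clones are flagged (they are excluded
#' from clone-aware pair construction with a warning downstream).
#'
#' @param meta sample_meta table.
#' @param trees named list of [clone_tree()] keyed by patient id.
#' @return `meta` invisibly.
#' @export
validate_sample_meta <- function(meta, trees) {
  for (i in seq_len(nrow(meta))) {
    if (meta$sample_type[i] == "normal") next
    tr <- trees[[meta$patient_id[i]]]
    if (is.null(tr)) {
      ce_abort(sprintf("no clone tree for patient %s", meta$patient_id[i]),
               class = "clonexpr_lookup_error")
    }
    check_clones_known(tr, meta$clones[[i]])
  }
  invisible(meta)
}
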