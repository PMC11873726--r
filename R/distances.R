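#' Top variable genes across a cohort
#'
#' Genes are ranked by the variance of their normalized expression across
#' all supplied cohort samples, computed once cohort-wide (not per patient).
#' Ties are broken lexicographically by gene id so results are deterministic.
#'
#' @param expr expression matrix (genes x samples).
#' @param k number of genes to return (`k <= nrow(expr)`).
#' @return character vector of `k` gene ids, by descending variance.
#' @export
top_variable_genes <- function(expr, k) {
  expr <- validate_expression_matrix(expr)
  if (k > nrow(expr)) {
    ce_abort(sprintf("k = %d exceeds the %d genes available", k, nrow(expr)),
             class = "clonexpr_argument_error")
  }
  v <- apply(expr, 1L, stats::var)
  ord <- order(-v, rownames(expr), method = "radix")
  rownames(expr)[ord][seq_len(k)]
}

#' Transcriptional distance between two samples
#'
#' Defined as `d = 1 - r` with `r` the Pearson correlation of the two
#' samples' expression over a fixed gene list (conventionally the cohort's
#' top 500 most variable genes), so `d` lies in `[0, 2]`.
#'
#' @param x,y named expression vectors covering all `genes`.
#' @param genes gene ids to restrict to (>= 3).
#' @return distance in `[0, 2]`.
#' @export
transcriptional_distance <- function(x, y, genes = names(x)) {
  if (length(genes) < 3L) {
    ce_abort("need at least 3 genes for a correlation distance",
             class = "clonexpr_argument_error")
  }
  missing_g <- setdiff(genes, intersect(names(x), names(y)))
  if (length(missing_g)) {
    ce_abort(sprintf("gene(s) absent from a sample vector: %s",
                     paste(utils::head(missing_g, 3L), collapse = ", ")),
             class = "clonexpr_lookup_error")
  }
  xs <- x[genes]; ys <- y[genes]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    ce_abort("correlation undefined: constant expression vector over the gene list",
             class = "clonexpr_degenerate_error")
  }
  1 - stats::cor(xs, ys)
}

#' Microenvironment (TME) distance between two samples
#'
#' `d = 1 - c` with `c` the cosine similarity of the two samples'
#' cell-population abundance vectors; `d` is in `[0, 1]` for non-negative
#' abundances and `[0, 2]` in general.
#'
#' @param u,v numeric abundance vectors of equal length (>= 2).
#' @return distance.
#' @export
tme_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L) {
    ce_abort("abundance vectors must have equal length >= 2",
             class = "clonexpr_argument_error")
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    ce_abort("cosine similarity undefined for a zero abundance vector",
             class = "clonexpr_degenerate_error")
  }
  1 - sum(u * v) / (nu * nv)
}

#' All within-patient pairwise distances
#'
#' Builds the per-pair distance table used by I-TED and the coevolution
#' models. Pairs are within-patient, unordered, canonically ordered by
#' sample id; the metric is `"transcriptional"` (expression rows over
#' `genes`) or `"tme"` (cosine over abundance rows of `tme`).
#'
#' @param expr expression matrix.
#' @param metadata sample_meta table.
#' @param genes gene list for transcriptional distances.
#' @param metric `"transcriptional"` or `"tme"`.
#' @param tme sample x population abundance matrix (for `metric = "tme"`).
#' @param pair_types character vector of `"<typeA>-<typeB>"` combinations to
#'   keep (types sorted alphabetically), e.g. `"primary-primary"`.
#' @return data.frame: patient_id, sample_a, sample_b, pair_type, distance.
#' @export
pairwise_distances <- function(expr, metadata, genes = NULL,
                               metric = c("transcriptional", "tme"),
                               tme = NULL,
                               pair_types = "primary-primary") {
  metric <- match.arg(metric)
  rows <- list()
  for (pat in unique(metadata$patient_id)) {
    sub <- metadata[metadata$patient_id == pat, , drop = FALSE]
    ids <- sort(sub$sample_id)
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- ids[i]; b <- ids[j]
        ta <- sub$sample_type[sub$sample_id == a]
        tb <- sub$sample_type[sub$sample_id == b]
        ptype <- paste(sort(c(ta, tb)), collapse = "-")
        if (!ptype %in% pair_types) next
        d <- if (metric == "transcriptional") {
          transcriptional_distance(expr[, a], expr[, b], genes %||% rownames(expr))
        } else {
          tme_distance(tme[a, ], tme[b, ])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pat, sample_a = a, sample_b = b, pair_type = ptype,
          distance = d, metric = metric, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(0), sample_a = character(0),
                      sample_b = character(0), pair_type = character(0),
                      distance = numeric(0), metric = character(0)))
  }
  do.call(rbind, rows)
}

#' Intratumour expression distance (I-TED)
#'
#' Per patient with >= 2 primary tumor samples: all pairwise
#' transcriptional (or TME) distances between primary-primary pairs,
#' aggregated to one score. The aggregator defaults to the median;
#' `"maximum"` is retained as an option. Patients with fewer than two
#' primary samples are skipped with a message.
#'
#' @inheritParams pairwise_distances
#' @param aggregator `"median"` or `"maximum"`.
#' @return list of class `ited_result_set` with elements `per_patient`
#'   (data.frame patient_id, ited, n_pairs, aggregator) and `per_pair`
#'   (the underlying distances).
#' @export
ited <- function(expr, metadata, genes = NULL,
                 aggregator = c("median", "maximum"),
                 metric = c("transcriptional", "tme"), tme = NULL) {
  aggregator <- match.arg(aggregator)
  metric <- match.arg(metric)
  primaries <- metadata[metadata$sample_type == "primary", , drop = FALSE]
  n_primary <- table(primaries$patient_id)
  skipped <- names(n_primary)[n_primary < 2L]
  if (length(skipped)) {
    message(sprintf("I-TED: skipping %d patient(s) with < 2 primary samples",
                    length(skipped)))
  }
  pairs <- pairwise_distances(expr, primaries, genes = genes, metric = metric,
                              tme = tme, pair_types = "primary-primary")
  agg <- if (aggregator == "median") stats::median else max
  per_patient <- do.call(rbind, lapply(split(pairs, pairs$patient_id),
    function(d) data.frame(patient_id = d$patient_id[1L],
                           ited = agg(d$distance), n_pairs = nrow(d),
                           aggregator = aggregator,
                           stringsAsFactors = FALSE)))
  if (is.null(per_patient)) {
    per_patient <- data.frame(patient_id = character(0), ited = numeric(0),
                              n_pairs = integer(0), aggregator = character(0))
  }
  rownames(per_patient) <- NULL
  structure(list(per_patient = per_patient, per_pair = pairs,
                 aggregator = aggregator, metric = metric),
            class = "ited_result_set")
}

#' Bootstrap ratio of inter- to intratumor heterogeneity
#'
#' The point estimate is `mean(inter) / mean(intra)`. Both pair sets are
#' resampled with replacement `B` times; the 2.5% and 97.5% quantiles of the
#' resampled ratios give the percentile confidence interval.
#'
#' @param intra distances between samples of the same patient.
#' @param inter distances between samples of different patients.
#' @param B bootstrap iterations (>= 100; cohort default 1000).
#' @param seed integer seed for the resampling.
#' @return list: ratio, ci_low, ci_high, B.
#' @export
inter_intra_ratio <- function(intra, inter, B = 1000L, seed = 1L) {
  if (length(intra) == 0 || length(inter) == 0) {
    ce_abort("both distance lists must be non-empty",
             class = "clonexpr_argument_error")
  }
  if (B < 100L) {
    ce_abort("B must be >= 100", class = "clonexpr_config_error")
  }
  if (mean(intra) == 0) {
    ce_abort("mean intratumor distance is zero: ratio undefined",
             class = "clonexpr_degenerate_error")
  }
  set.seed(seed)
  boots <- vnapply(seq_len(B), function(i) {
    mean(sample(inter, replace = TRUE)) / mean(sample(intra, replace = TRUE))
  })
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
  list(ratio = mean(inter) / mean(intra), ci_low = qs[1L], ci_high = qs[2L],
       B = as.integer(B))
}

#' Per-patient pair-type summary
#'
#' For comparisons such as primary-primary vs primary-normal or
#' primary-metastasis: per patient and pair type, distances are summarized
#' by the configured aggregator (Methods use the observed maximum, figure
#' legends the median; both are offered, default median).
#'
#' @param pairs data.frame from [pairwise_distances()] with several pair
#'   types.
#' @param aggregator `"median"` or `"maximum"`.
#' @return data.frame patient_id, pair_type, distance (one row per
#'   patient x pair type).
#' @export
summarize_pair_types <- function(pairs, aggregator = c("median", "maximum")) {
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "median") stats::median else max
  out <- stats::aggregate(distance ~ patient_id + pair_type, data = pairs,
                          FUN = agg)
  out[order(out$patient_id, out$pair_type), , drop = FALSE]
}
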