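#' Analysis configuration
#'
#' Bundles the pipeline's tunable constants with the cohort defaults:
#' top 500 most variable genes for transcriptional distances, 1,000
#' bootstrap iterations for the inter/intra ratio, ssGSEA weighting
#' exponent 0.25, the "1 TPM in at least 20% of samples" expression filter,
#' the 70% detection filter for locus (HERV-like) eQTL features, and the
#' Benjamini-Hochberg FDR procedure throughout.
#'
#' @param top_k_variable_genes genes used for transcriptional distance.
#' @param bootstrap_iterations bootstrap resamples for the inter/intra ratio.
#' @param ssgsea_exponent rank-weighting exponent alpha.
#' @param min_tpm,min_fraction expression filter thresholds (inclusive).
#' @param herv_expressed_fraction minimum fraction of samples a locus
#'   feature must be detected in to enter the eQTL (strictly-below excluded).
#' @param per_patient_aggregator `"median"` or `"maximum"` for I-TED and
#'   pair-type summaries.
#' @param random_seed integer seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(top_k_variable_genes = 500L,
                            bootstrap_iterations = 1000L,
                            ssgsea_exponent = 0.25,
                            min_tpm = 1, min_fraction = 0.20,
                            herv_expressed_fraction = 0.70,
                            per_patient_aggregator = c("median", "maximum"),
                            random_seed = 1L) {
  per_patient_aggregator <- match.arg(per_patient_aggregator)
  if (top_k_variable_genes < 1 || bootstrap_iterations < 1) {
    ce_abort("top_k_variable_genes and bootstrap_iterations must be >= 1",
             class = "clonexpr_config_error")
  }
  if (ssgsea_exponent < 0) {
    ce_abort("ssgsea_exponent must be >= 0", class = "clonexpr_config_error")
  }
  stopifnot_fraction(min_fraction, "min_fraction")
  stopifnot_fraction(herv_expressed_fraction, "herv_expressed_fraction")
  structure(list(top_k_variable_genes = as.integer(top_k_variable_genes),
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 ssgsea_exponent = ssgsea_exponent,
                 min_tpm = min_tpm, min_fraction = min_fraction,
                 herv_expressed_fraction = herv_expressed_fraction,
                 fdr_method = "benjamini-hochberg",
                 per_patient_aggregator = per_patient_aggregator,
                 random_seed = as.integer(random_seed)),
            class = "analysis_config")
}
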