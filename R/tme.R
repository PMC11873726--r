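#' Single-sample gene set enrichment (ssGSEA) score
#'
#' Rank-based running-sum enrichment of one gene set in one sample. Genes
#' are ordered by decreasing expression (ties broken by gene id); with
#' `rank_i = N - position_i + 1`, the score is
#' `sum_j [ P_in(j) - P_out(j) ]` where `P_in(j)` is the rank^alpha-weighted
#' cumulative fraction of set genes up to position `j` and `P_out(j)` the
#' unweighted cumulative fraction of non-set genes. Scores are invariant
#' under strictly monotone transforms of the sample's expression values.
#'
#' @param x named expression vector for one sample (the gene universe).
#' @param gene_set character vector of gene ids.
#' @param alpha rank-weighting exponent (>= 0, default 0.25).
#' @return numeric score.
#' @export
ssgsea_score <- function(x, gene_set, alpha = 0.25) {
  if (alpha < 0) ce_abort("alpha must be >= 0", class = "clonexpr_config_error")
  genes <- names(x)
  if (is.null(genes)) {
    ce_abort("expression vector must be named by gene id",
             class = "clonexpr_argument_error")
  }
  set <- intersect(gene_set, genes)
  N <- length(x)
  if (length(set) == 0 || length(set) == N) {
    ce_abort("gene set must be a non-empty proper subset of the universe",
             class = "clonexpr_definition_error")
  }
  ord <- order(-x, genes, method = "radix")
  in_set <- genes[ord] %in% set
  ranks <- N - seq_len(N) + 1
  w <- ranks^alpha
  p_in <- cumsum(w * in_set) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (N - length(set))
  sum(p_in - p_out)
}

#' ssGSEA scores for a score matrix
#'
#' @param expr expression matrix (genes x samples).
#' @param gene_sets named list of gene-id vectors.
#' @param alpha rank-weighting exponent.
#' @return samples x gene-sets numeric matrix.
#' @export
ssgsea_matrix <- function(expr, gene_sets, alpha = 0.25) {
  expr <- validate_expression_matrix(expr)
  out <- vapply(gene_sets, function(s)
    vnapply(colnames(expr), function(sm) ssgsea_score(expr[, sm], s, alpha)),
    numeric(ncol(expr)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = ncol(expr),
                  dimnames = list(colnames(expr), names(gene_sets)))
  }
  out
}

#' Mean-scaled (Z) scores across a cohort
#'
#' `(x - mean) / sd` with the sample (n - 1) standard deviation, computed
#' across the supplied tumor-sample cohort.
#'
#' @param scores numeric vector (>= 2 values, positive SD).
#' @return Z-values with mean 0, SD 1.
#' @export
zscore <- function(scores) {
  if (length(scores) < 2L) {
    ce_abort("need at least 2 samples to Z-score",
             class = "clonexpr_argument_error")
  }
  s <- stats::sd(scores)
  if (s == 0) {
    ce_abort("zero standard deviation: Z-scores undefined",
             class = "clonexpr_degenerate_error")
  }
  (scores - mean(scores)) / s
}

#' Antitumor vs immunosuppressive TME label
#'
#' A sample is `antitumor` when its myeloid-inflammation Z-score minus its
#' T-effector Z-score is below 0 (higher T effector), and
#' `immunosuppressive` otherwise (ties included).
#'
#' @param z_teff,z_myeloid Z-scored signature values (vectorized).
#' @return character vector of labels.
#' @export
classify_tme <- function(z_teff, z_myeloid) {
  if (any(!is.finite(z_teff)) || any(!is.finite(z_myeloid))) {
    ce_abort("Z-scores must be finite", class = "clonexpr_argument_error")
  }
  ifelse(z_myeloid - z_teff < 0, "antitumor", "immunosuppressive")
}

#' Full TME classification table from ssGSEA scores
#'
#' Z-scores the T-effector and myeloid-inflammation signature columns
#' across all supplied (tumor) samples and applies [classify_tme()].
#'
#' @param scores sample x gene-set score matrix.
#' @param teff,myeloid column names of the two signatures.
#' @return data.frame: sample_id, z_teff, z_myeloid, delta, label.
#' @export
tme_classification <- function(scores, teff = "T_effector_signature",
                               myeloid = "Myeloid_inflammation_signature") {
  z_t <- zscore(scores[, teff])
  z_m <- zscore(scores[, myeloid])
  data.frame(sample_id = rownames(scores), z_teff = z_t, z_myeloid = z_m,
             delta = z_m - z_t, label = classify_tme(z_t, z_m),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally TME transitions over oriented sample pairs
#'
#' Pairs are oriented (earlier to later: nonterminal to terminal clone,
#' wild-type to mutant, 9p-WT to 9p-loss). A pair whose labels move from
#' antitumor to immunosuppressive counts as A->I, the reverse as I->A;
#' concordant pairs count as stable. Pairs with a missing label are skipped
#' with a message.
#'
#' @param label_from,label_to label vectors ("antitumor" /
#'   "immunosuppressive") for the first and second element of each pair.
#' @param context free-text tag ("terminal-vs-nonterminal",
#'   "driver WT->mutant", "all-pairs", ...).
#' @return list of class `transition_table`: counts, context, chi2, p
#'   (chi-squared vs the 0.5 transition null; NA when no transitions).
#' @export
count_transitions <- function(label_from, label_to, context = "all-pairs") {
  ok <- !is.na(label_from) & !is.na(label_to)
  if (any(!ok)) {
    message(sprintf("%d pair(s) with unlabeled sample skipped", sum(!ok)))
    label_from <- label_from[ok]; label_to <- label_to[ok]
  }
  n_AI <- sum(label_from == "antitumor" & label_to == "immunosuppressive")
  n_IA <- sum(label_from == "immunosuppressive" & label_to == "antitumor")
  n_sA <- sum(label_from == "antitumor" & label_to == "antitumor")
  n_sI <- sum(label_from == "immunosuppressive" &
                label_to == "immunosuppressive")
  enr <- if (n_AI + n_IA >= 1L) transition_enrichment(n_AI, n_IA) else {
    message("no transitions observed: enrichment test undefined")
    list(chi2 = NA_real_, p = NA_real_)
  }
  structure(list(n_stable_antitumor = n_sA, n_stable_immunosuppressive = n_sI,
                 n_A_to_I = n_AI, n_I_to_A = n_IA, context = context,
                 chi2 = enr$chi2, p = enr$p),
            class = "transition_table")
}

#' Directional transition enrichment test
#'
#' Goodness-of-fit chi-squared comparing the observed numbers of A->I and
#' I->A transitions to an expected 0.5 probability of each direction:
#' expected counts (T/2, T/2) with T the total transitions, df = 1, no
#' continuity correction. Algebraically `chi2 = (n_AI - n_IA)^2 / T`.
#'
#' @param n_A_to_I,n_I_to_A non-negative transition counts, total >= 1.
#' @return list: chi2, p.
#' @export
transition_enrichment <- function(n_A_to_I, n_I_to_A) {
  T_ <- n_A_to_I + n_I_to_A
  if (T_ < 1L) {
    ce_abort("need at least one transition", class = "clonexpr_argument_error")
  }
  e <- T_ / 2
  chi2 <- (n_A_to_I - e)^2 / e + (n_I_to_A - e)^2 / e
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cluster samples by immune infiltration level
#'
#' Population abundances are scaled per population across samples, samples
#' are clustered hierarchically (complete linkage on Manhattan distances)
#' and the tree is cut into `k = 3` groups, which are named low /
#' intermediate / high by their mean total scaled abundance.
#'
#' @param tme sample x population abundance matrix (>= 3 samples).
#' @param k number of groups (fixed at 3 in the reference analysis).
#' @return named character vector of labels per sample.
#' @export
cluster_infiltration <- function(tme, k = 3L) {
  if (nrow(tme) < k) {
    ce_abort(sprintf("need at least %d samples to cut %d clusters", k, k),
             class = "clonexpr_argument_error")
  }
  scaled <- scale(tme)
  scaled[is.nan(scaled)] <- 0  # constant populations carry no signal
  hc <- stats::hclust(stats::dist(scaled, method = "manhattan"),
                      method = "complete")
  grp <- stats::cutree(hc, k = k)
  level <- vnapply(seq_len(k), function(g)
    mean(rowSums(scaled[grp == g, , drop = FALSE])))
  nm <- if (k == 3L) c("low", "intermediate", "high") else
    paste0("level", seq_len(k))
  labels <- nm[rank(level, ties.method = "first")][grp]
  stats::setNames(labels, rownames(tme))
}
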