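#' Morisita-Horn repertoire overlap
#'
#' Abundance-weighted community similarity over the union of clonotype keys
#' (a clonotype absent from one repertoire contributes 0 there):
#' `MH = 2 sum(x_i y_i) / ((lambda_x + lambda_y) X Y)` with `X = sum(x)`,
#' `lambda_x = sum(x^2) / X^2` (and likewise for y). MH is symmetric,
#' lies in \[0, 1\], equals 1 for proportional count vectors and 0 for
#' disjoint clonotype sets, and is invariant to rescaling either
#' repertoire's counts.
#'
#' @param rep_a,rep_b [repertoire()] objects (non-empty by construction).
#' @return similarity in \[0, 1\].
#' @export
morisita_horn <- function(rep_a, rep_b) {
  if (length(rep_a$counts) == 0 || length(rep_b$counts) == 0) {
    ce_abort("similarity undefined for an empty repertoire",
             class = "clonexpr_degenerate_error")
  }
  keys <- union(names(rep_a$counts), names(rep_b$counts))
  x <- rep_a$counts[keys]; x[is.na(x)] <- 0
  y <- rep_b$counts[keys]; y[is.na(y)] <- 0
  X <- sum(x); Y <- sum(y)
  lx <- sum(x^2) / X^2; ly <- sum(y^2) / Y^2
  2 * sum(x * y) / ((lx + ly) * X * Y)
}

#' Gini coefficient of clonotype counts
#'
#' Inequality of the count distribution via the mean-absolute-difference
#' definition `G = sum_ij |c_i - c_j| / (2 n^2 mean(c))`: 0 for a uniform
#' repertoire, approaching 1 as reads concentrate in one clonotype.
#' Invariant to rescaling all counts.
#'
#' @param rep a [repertoire()] (or bare positive count vector).
#' @return Gini coefficient in [0, 1).
#' @export
gini <- function(rep) {
  counts <- if (inherits(rep, "repertoire")) rep$counts else rep
  if (length(counts) == 0) {
    ce_abort("Gini undefined for an empty repertoire",
             class = "clonexpr_degenerate_error")
  }
  n <- length(counts)
  sum(abs(outer(counts, counts, "-"))) / (2 * n^2 * mean(counts))
}

#' Per-sample repertoire diversity statistics
#'
#' @param rep a [repertoire()].
#' @return data.frame: sample_id, chain, n_clonotypes, gini,
#'   top_clone_fraction.
#' @export
repertoire_diversity <- function(rep) {
  data.frame(sample_id = rep$sample_id, chain = rep$chain,
             n_clonotypes = length(rep$counts), gini = gini(rep),
             top_clone_fraction = max(rep$counts) / sum(rep$counts),
             stringsAsFactors = FALSE)
}

#' Pairwise repertoire overlap table
#'
#' Morisita-Horn similarity, shared clonotype count and a shares-any flag
#' for every combination of the two repertoire lists (same chain assumed).
#'
#' @param reps_a,reps_b lists of [repertoire()] objects.
#' @return data.frame: sample_a, sample_b, chain, morisita_horn, n_shared,
#'   shares_any.
#' @export
repertoire_overlap_table <- function(reps_a, reps_b) {
  rows <- list()
  for (ra in reps_a) {
    for (rb in reps_b) {
      shared <- intersect(names(ra$counts), names(rb$counts))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_a = ra$sample_id, sample_b = rb$sample_id, chain = ra$chain,
        morisita_horn = morisita_horn(ra, rb), n_shared = length(shared),
        shares_any = length(shared) > 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Shared-clonotype report between compartments
#'
#' For each primary-vs-other (metastasis or normal) repertoire pair:
#' whether any clonotype is shared, and for the shared clonotypes their
#' within-sample frequency (count / total) in each compartment — the
#' statistic behind "fraction of metastases containing a clone also found
#' in the primary tumor".
#'
#' @param primary_reps,other_reps lists of [repertoire()] objects.
#' @return list: `pairs` (data.frame with shares_any per pair),
#'   `shared_clonotypes` (long data.frame: sample_primary, sample_other,
#'   clonotype_key, freq_primary, freq_other).
#' @export
shared_clonotype_report <- function(primary_reps, other_reps) {
  pairs <- repertoire_overlap_table(primary_reps, other_reps)
  shared_rows <- list()
  for (ra in primary_reps) {
    for (rb in other_reps) {
      shared <- intersect(names(ra$counts), names(rb$counts))
      if (length(shared) == 0) next
      shared_rows[[length(shared_rows) + 1L]] <- data.frame(
        sample_primary = ra$sample_id, sample_other = rb$sample_id,
        clonotype_key = shared,
        freq_primary = unname(ra$counts[shared] / sum(ra$counts)),
        freq_other = unname(rb$counts[shared] / sum(rb$counts)),
        stringsAsFactors = FALSE)
    }
  }
  list(pairs = pairs,
       shared_clonotypes = do.call(rbind, shared_rows) %||%
         data.frame(sample_primary = character(0),
                    sample_other = character(0),
                    clonotype_key = character(0),
                    freq_primary = numeric(0), freq_other = numeric(0)))
}

#' Repertoire similarity vs clonal distance
#'
#' Mixed-effects association of Morisita-Horn similarity with clonal
#' distance across within-patient pairs (patient random intercept, purity
#' difference covariate); delegates to [lme_association()].
#'
#' @param overlaps data.frame from [repertoire_overlap_table()] restricted
#'   to within-patient pairs.
#' @param clonal_distances numeric vector aligned with `overlaps` rows.
#' @param purity_diffs optional aligned purity differences.
#' @param groups aligned patient ids.
#' @return [lme_association()] result.
#' @export
repertoire_vs_clonal_distance <- function(overlaps, clonal_distances,
                                          purity_diffs = NULL, groups) {
  covs <- if (!is.null(purity_diffs)) data.frame(d_purity = purity_diffs)
  lme_association(overlaps$morisita_horn, clonal_distances,
                  covariates = covs, group = groups)
}
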