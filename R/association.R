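#' Build per-pair, per-gene difference records
#'
#' For every within-patient unordered sample pair of an allowed type, with
#' canonical lexicographic ordering (sample_a < sample_b), computes the
#' second-minus-first differences that feed the gene-specific regression
#' framework: per-gene expression and copy-number differences (copy number
#' masked to NA for genes on chromosome arm 9p, to avoid collinearity with
#' the 9p-loss indicator), and pair-level covariates: purity difference,
#' epigenetic-driver mutation count difference (SETD2, PBRM1, ARID1A,
#' KDM5C, BAP1), 9p-loss difference (+1 loss in second sample only, -1 in
#' first only, 0 same), WGD difference coded the same way, and an optional
#' sample-type contrast. Random binary and continuous baseline covariates
#' are drawn per pair to give the model a background expectation.
#'
#' @param expr expression matrix (genes x samples).
#' @param cn integer copy-number matrix (genes x samples).
#' @param annotation gene annotation table (for the 9p mask).
#' @param metadata sample_meta table with `driver_9p_loss` and epigenetic
#'   driver columns.
#' @param pair_types allowed pair types (alphabetically sorted type pairs).
#' @param type_contrast `"none"`, `"normal"` or `"metastasis"`: the sample
#'   type coded +1/-1 in `d_type`.
#' @param seed seed for the random baseline covariates.
#' @return list of class `sample_pair_diffs`: `pairs` (pair-level
#'   covariates), `d_expr` and `d_cn` (genes x pairs matrices), `genes`.
#' @export
build_pair_diffs <- function(expr, cn, annotation, metadata,
                             pair_types = "primary-primary",
                             type_contrast = c("none", "normal",
                                               "metastasis"),
                             seed = 1L) {
  type_contrast <- match.arg(type_contrast)
  expr <- validate_expression_matrix(expr)
  genes <- rownames(expr)
  missing_cn <- setdiff(genes, rownames(cn))
  if (length(missing_cn)) {
    message(sprintf("%d gene(s) without copy number dropped from d_cn",
                    length(missing_cn)))
  }
  arm_of <- stats::setNames(annotation$arm, annotation$gene_id)
  on_9p <- genes %in% annotation$gene_id[annotation$arm == "9p"]
  epi_cols <- intersect(paste0("driver_", .epi_drivers), names(metadata))
  epi_count <- if (length(epi_cols)) {
    rowSums(as.matrix(metadata[, epi_cols, drop = FALSE]))
  } else rep(0L, nrow(metadata))
  names(epi_count) <- metadata$sample_id
  loss9p <- if ("driver_9p_loss" %in% names(metadata)) {
    stats::setNames(metadata$driver_9p_loss, metadata$sample_id)
  } else stats::setNames(rep(FALSE, nrow(metadata)), metadata$sample_id)

  info <- metadata[metadata$sample_id %in% colnames(expr), , drop = FALSE]
  pair_rows <- list(); d_expr <- list(); d_cn <- list()
  for (pat in unique(info$patient_id)) {
    sub <- info[info$patient_id == pat, , drop = FALSE]
    ids <- sort(sub$sample_id)
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- ids[i]; b <- ids[j]
        ta <- sub$sample_type[sub$sample_id == a]
        tb <- sub$sample_type[sub$sample_id == b]
        ptype <- paste(sort(c(ta, tb)), collapse = "-")
        if (!ptype %in% pair_types) next
        key <- paste(a, b, sep = "|")
        d_expr[[key]] <- expr[, b] - expr[, a]
        dc <- rep(NA_real_, length(genes))
        in_cn <- genes %in% rownames(cn)
        dc[in_cn] <- cn[genes[in_cn], b] - cn[genes[in_cn], a]
        dc[on_9p] <- NA_real_
        d_cn[[key]] <- dc
        wa <- sub$wgd[sub$sample_id == a]; wb <- sub$wgd[sub$sample_id == b]
        pair_rows[[key]] <- data.frame(
          patient_id = pat, sample_a = a, sample_b = b, pair_type = ptype,
          d_purity = sub$purity[sub$sample_id == b] -
            sub$purity[sub$sample_id == a],
          d_epi = as.integer(epi_count[b] - epi_count[a]),
          d_9p = as.integer(loss9p[b]) - as.integer(loss9p[a]),
          d_wgd = as.integer(wb) - as.integer(wa),
          d_type = if (type_contrast == "none") 0L else
            as.integer(tb == type_contrast) - as.integer(ta == type_contrast),
          wgd_group = paste(wa, wb, sep = "/"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pair_rows) == 0) {
    ce_abort("no sample pairs of the requested type(s)",
             class = "clonexpr_argument_error")
  }
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  set.seed(seed)
  pairs$rand_binary <- stats::rbinom(nrow(pairs), 1L, 0.5)
  pairs$rand_continuous <- stats::rnorm(nrow(pairs))
  structure(list(pairs = pairs,
                 d_expr = matrix(unlist(d_expr), nrow = length(genes),
                                 dimnames = list(genes, names(d_expr))),
                 d_cn = matrix(unlist(d_cn), nrow = length(genes),
                               dimnames = list(genes, names(d_cn))),
                 genes = genes),
            class = "sample_pair_diffs")
}

# Shared mixed-model core: y ~ fixed covariates (+ intercept) with random
# intercepts per grouping factor. Wald t with residual df (n - p) gives
# p-values; degenerate/non-converging fits fall back to plain lm with
# converged = FALSE.
fit_lmm <- function(df, response, fixed, groups, reml = TRUE) {
  fixed <- fixed[vnapply(fixed, function(f) stats::sd(df[[f]])) > 0]
  usable_groups <- groups[viapply(groups, function(g)
    length(unique(df[[g]]))) > 1L]
  n <- nrow(df)
  if (length(fixed) == 0) {
    empty <- stats::setNames(numeric(0), character(0))
    return(list(estimate = empty, se = empty, t = empty, p = empty,
                n = n, converged = TRUE, method = "empty"))
  }
  form_fixed <- paste(c("1", fixed), collapse = " + ")
  out_row <- function(coefs, p_fixed, converged, method) {
    est <- stats::setNames(rep(NA_real_, length(fixed)), fixed)
    se <- est; tv <- est; pv <- est
    rows <- intersect(fixed, rownames(coefs))
    est[rows] <- coefs[rows, 1L]
    se[rows] <- coefs[rows, 2L]
    tv[rows] <- coefs[rows, 3L]
    pv[rows] <- 2 * stats::pt(-abs(tv[rows]), df = max(n - p_fixed, 1L))
    list(estimate = est, se = se, t = tv, p = pv, n = n,
         converged = converged, method = method)
  }
  if (length(usable_groups) >= 1L) {
    form <- stats::as.formula(paste(
      response, "~", form_fixed, "+",
      paste(sprintf("(1 | %s)", usable_groups), collapse = " + ")))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = df, REML = reml,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      coefs <- summary(fit)$coefficients
      if (ncol(coefs) == 2L) coefs <- cbind(coefs, coefs[, 1L] / coefs[, 2L])
      return(out_row(coefs, nrow(coefs), TRUE, "lmm"))
    }
  }
  form <- stats::as.formula(paste(response, "~", form_fixed))
  fit <- stats::lm(form, data = df)
  coefs <- summary(fit)$coefficients
  out_row(coefs, nrow(coefs), length(usable_groups) == 0L, "ols")
}

#' Fit the gene-specific mixed-effects framework
#'
#' Per gene, the expression difference across pairs is regressed on the
#' copy-number difference (cis dosage), the epigenetic-driver count
#' difference, the 9p-loss difference, the purity difference, the random
#' binary/continuous baselines, and optionally the sample-type contrast,
#' with random intercepts for patient and for the pair's WGD-status
#' grouping (crossed). Covariates constant across pairs are dropped with a
#' message; fits that fail fall back to fixed-effects-only least squares
#' with `converged = FALSE`. Benjamini-Hochberg FDR is computed per
#' covariate across genes.
#'
#' @param pair_diffs a [build_pair_diffs()] result.
#' @param genes genes to fit (default all).
#' @param use_d_type include the sample-type contrast covariate.
#' @param reml use REML (default) or ML.
#' @return data.frame of class `gene_model_results`: gene_id,
#'   `estimate_*`, `p_*`, `fdr_*` per covariate, n_pairs, converged.
#' @export
fit_gene_models <- function(pair_diffs, genes = NULL, use_d_type = FALSE,
                            reml = TRUE) {
  pd <- pair_diffs
  genes <- genes %||% pd$genes
  pairs <- pd$pairs
  if (length(unique(pairs$patient_id)) < 2L) {
    message("fewer than 2 patients contribute pairs; falling back to fixed effects only")
  }
  covs <- c("d_cn", "d_epi", "d_9p", "d_purity", "rand_binary",
            "rand_continuous", if (use_d_type) "d_type")
  base_df <- pairs[, c("patient_id", "wgd_group", "d_epi", "d_9p",
                       "d_purity", "d_wgd", "d_type", "rand_binary",
                       "rand_continuous")]
  const_pair_covs <- covs[covs != "d_cn"][vnapply(
    covs[covs != "d_cn"], function(f) stats::sd(base_df[[f]])) == 0]
  if (length(const_pair_covs)) {
    message(sprintf("covariate(s) constant across pairs dropped: %s",
                    paste(const_pair_covs, collapse = ", ")))
  }
  res <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    df <- base_df
    df$d_expr <- pd$d_expr[g, ]
    df$d_cn <- pd$d_cn[g, ]
    fixed <- covs
    if (all(is.na(df$d_cn))) {
      fixed <- setdiff(fixed, "d_cn")
      df$d_cn <- NULL
    } else if (anyNA(df$d_cn)) {
      df <- df[!is.na(df$d_cn), , drop = FALSE]
    }
    fit <- fit_lmm(df, "d_expr", fixed, c("patient_id", "wgd_group"),
                   reml = reml)
    row <- list(gene_id = g, n_pairs = fit$n, converged = fit$converged)
    for (cv in covs) {
      row[[paste0("estimate_", cv)]] <- unname(fit$estimate[cv])
      row[[paste0("p_", cv)]] <- unname(fit$p[cv])
    }
    res[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  for (cv in covs) {
    out[[paste0("fdr_", cv)]] <- benjamini_hochberg(out[[paste0("p_", cv)]])
  }
  class(out) <- c("gene_model_results", "data.frame")
  out
}

#' Decompose I-TED variance over clinico-genomic covariates
#'
#' Fits one multivariable linear regression of per-patient I-TED on the
#' covariates in their supplied order, then reads each covariate's variance
#' share off the sequential (type-I) analysis-of-variance table — the share
#' is that term's sum of squares over the total sum of squares. P-values
#' come from the same ANOVA and are BH-adjusted across terms. The canonical
#' covariate set is the nine features: purity ITH, tumor size, number of
#' regions, genetic ITH, copy-number heterogeneity, stage, subclonal
#' epigenetic-driver mutation, subclonal 9p loss, subclonal 14q loss.
#'
#' @param ited_values numeric vector, one I-TED per patient.
#' @param covariates data.frame (same row order), columns in the order
#'   whose sequential attribution is wanted.
#' @return list of class `variance_decomposition`: `table` (covariate,
#'   variance_fraction, p, fdr), `total_explained`, `n`.
#' @export
decompose_ited_variance <- function(ited_values, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(ited_values)
  if (n != nrow(covariates)) {
    ce_abort("ited_values and covariates must align",
             class = "clonexpr_argument_error")
  }
  if (n <= ncol(covariates) + 1L) {
    ce_abort(sprintf("need more patients (%d) than covariates (%d) to fit",
                     n, ncol(covariates)),
             class = "clonexpr_rank_error")
  }
  df <- cbind(.ited = ited_values, covariates)
  fit <- stats::lm(.ited ~ ., data = df)
  an <- stats::anova(fit)
  terms <- setdiff(rownames(an), "Residuals")
  ss_total <- sum(an[, "Sum Sq"])
  tab <- data.frame(covariate = terms,
                    variance_fraction = an[terms, "Sum Sq"] / ss_total,
                    p = an[terms, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  tab$fdr <- benjamini_hochberg(tab$p)
  structure(list(table = tab,
                 total_explained = sum(tab$variance_fraction),
                 r_squared = summary(fit)$r.squared, n = n),
            class = "variance_decomposition")
}

#' Driver-CNA scan for the I-TED variance model
#'
#' Refits the I-TED regression iteratively with exactly one driver
#' copy-number alteration indicator at a time appended to the base
#' covariates (the scan that contextualizes subclonal 9p loss against the
#' 14 recurrent driver CNAs), and reports each driver's sequential variance
#' fraction and p-value.
#'
#' @param ited_values per-patient I-TED.
#' @param base_covariates data.frame of non-CNA covariates.
#' @param driver_table data.frame, one 0/1 column per driver CNA.
#' @return data.frame: driver, variance_fraction, p.
#' @export
ited_driver_scan <- function(ited_values, base_covariates, driver_table) {
  do.call(rbind, lapply(names(driver_table), function(d) {
    dec <- decompose_ited_variance(
      ited_values, cbind(base_covariates,
                         stats::setNames(driver_table[d], d)))
    row <- dec$table[dec$table$covariate == d, , drop = FALSE]
    data.frame(driver = d, variance_fraction = row$variance_fraction,
               p = row$p, stringsAsFactors = FALSE)
  }))
}

#' Generic mixed-effects association
#'
#' Fixed slope of `y` on `x` with optional fixed covariates and a random
#' intercept per group (patient). Used for: distance vs clonal distance,
#' repertoire similarity vs clonal distance, seeding vs nonseeding
#' contrasts, pathway score vs MRCA distance (with purity covariate), and
#' normal-distance vs MRCA depth. With a single group the model downgrades
#' to ordinary least squares with a message.
#'
#' @param y response vector.
#' @param x predictor of interest.
#' @param covariates optional data.frame of additional fixed covariates.
#' @param group grouping vector (patient ids).
#' @param reml use REML (default) or ML.
#' @return list: coefficient, se, t, p, n, method ("lmm"/"ols"),
#'   converged.
#' @export
lme_association <- function(y, x, covariates = NULL, group, reml = TRUE) {
  if (length(y) != length(x) || length(y) != length(group)) {
    ce_abort("y, x and group must align", class = "clonexpr_argument_error")
  }
  if (stats::sd(y) == 0) {
    return(list(coefficient = 0, se = NA_real_, t = NA_real_, p = 1,
                n = length(y), method = "degenerate", converged = TRUE))
  }
  df <- data.frame(.y = y, .x = x, .g = as.character(group),
                   stringsAsFactors = FALSE)
  fixed <- ".x"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    fixed <- c(fixed, names(covariates))
  }
  if (length(unique(df$.g)) < 2L) {
    message("single group: downgrading to ordinary least squares")
  }
  fit <- fit_lmm(df, ".y", fixed, ".g", reml = reml)
  list(coefficient = unname(fit$estimate[".x"]),
       se = unname(fit$se[".x"]), t = unname(fit$t[".x"]),
       p = unname(fit$p[".x"]), n = fit$n, method = fit$method,
       converged = fit$converged)
}

#' Paired within-patient driver vs pathway association
#'
#' For each patient carrying the driver subclonally (at least one wild-type
#' and one mutant tumor sample), the mean pathway score is taken in each
#' group; across patients the paired means are compared with a two-sided
#' Wilcoxon signed-rank test (zero differences dropped, count reported),
#' BH-adjusted across pathways.
#'
#' @param scores sample x pathway score matrix (e.g. ssGSEA).
#' @param driver driver name (matched to `driver_<name>` metadata column).
#' @param metadata sample_meta table; normal samples are excluded.
#' @return data.frame: pathway, wt_mean, mut_mean, n_patients, n_zero_diff,
#'   p, fdr.
#' @export
paired_driver_association <- function(scores, driver, metadata) {
  tumor <- metadata[metadata$sample_type != "normal", , drop = FALSE]
  tumor <- tumor[tumor$sample_id %in% rownames(scores), , drop = FALSE]
  status <- driver_status(tumor, driver)
  eligible <- vapply(split(seq_len(nrow(tumor)), tumor$patient_id),
                     function(idx) {
                       s <- status[tumor$sample_id[idx]]
                       any(s) && any(!s)
                     }, logical(1L))
  pats <- names(eligible)[eligible]
  if (length(pats) < 2L) {
    message("fewer than 2 patients with subclonal driver status; empty result")
    return(data.frame(pathway = character(0), wt_mean = numeric(0),
                      mut_mean = numeric(0), n_patients = integer(0),
                      n_zero_diff = integer(0), p = numeric(0),
                      fdr = numeric(0)))
  }
  pathways <- colnames(scores)
  rows <- lapply(pathways, function(pw) {
    wt <- vnapply(pats, function(p) {
      ids <- tumor$sample_id[tumor$patient_id == p]
      mean(scores[ids[!status[ids]], pw])
    })
    mut <- vnapply(pats, function(p) {
      ids <- tumor$sample_id[tumor$patient_id == p]
      mean(scores[ids[status[ids]], pw])
    })
    d <- mut - wt
    nz <- d != 0
    p <- if (!any(nz)) 1 else
      suppressWarnings(stats::wilcox.test(d[nz], exact = FALSE)$p.value)
    data.frame(pathway = pw, wt_mean = mean(wt), mut_mean = mean(mut),
               n_patients = length(pats), n_zero_diff = sum(!nz), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  out
}

#' Locus-level expression QTL with prevalence filter
#'
#' Features (e.g. HERV/LTR transcripts) expressed (value > 0) in strictly
#' less than `min_expressed_fraction` of tumor samples are excluded. Per
#' retained feature, a mixed model relates expression to the copy number of
#' the feature's locus with purity and a binary status (e.g. VHL altered)
#' as fixed covariates and a patient random intercept; BH-FDR across
#' features.
#'
#' @param feature_expr feature x sample expression matrix.
#' @param locus_cn feature x sample locus copy-number matrix.
#' @param purity per-sample purity (aligned to columns).
#' @param binary_status per-sample 0/1 status covariate.
#' @param group per-sample patient ids.
#' @param min_expressed_fraction detection prevalence threshold (default
#'   0.70; a feature at exactly the threshold is retained).
#' @return data.frame: feature, cn_coef, p, fdr, n_expressed_fraction,
#'   converged.
#' @export
locus_eqtl <- function(feature_expr, locus_cn, purity, binary_status, group,
                       min_expressed_fraction = 0.70) {
  frac <- rowMeans(feature_expr > 0)
  keep <- frac >= min_expressed_fraction
  if (!any(keep)) {
    message("all features below the expression prevalence filter; empty result")
    return(data.frame(feature = character(0), cn_coef = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      expressed_fraction = numeric(0),
                      converged = logical(0)))
  }
  feats <- rownames(feature_expr)[keep]
  rows <- lapply(feats, function(f) {
    df <- data.frame(.y = feature_expr[f, ], cn = locus_cn[f, ],
                     purity = purity, status = binary_status,
                     .g = as.character(group), stringsAsFactors = FALSE)
    if (stats::sd(df$.y) == 0) {
      return(data.frame(feature = f, cn_coef = 0, p = 1,
                        expressed_fraction = frac[f], converged = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- fit_lmm(df, ".y", c("cn", "purity", "status"), ".g")
    data.frame(feature = f, cn_coef = unname(fit$estimate["cn"]),
               p = unname(fit$p["cn"]), expressed_fraction = frac[f],
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  out
}
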