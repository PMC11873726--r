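make_pair_meta <- function() {
  sample_meta(c("a1", "a2", "b1", "b2"), rep(c("PA", "PB"), each = 2),
              "primary", purity = c(0.8, 0.6, 0.7, 0.7),
              wGII = rep(0.1, 4), wgd = c(FALSE, TRUE, FALSE, FALSE),
              clones = list("A", "B", "A", "A"),
              drivers = list(`9p_loss` = c(FALSE, TRUE, FALSE, FALSE),
                             SETD2 = c(FALSE, TRUE, FALSE, FALSE),
                             PBRM1 = c(TRUE, TRUE, FALSE, FALSE)))
}

make_pair_inputs <- function(meta = make_pair_meta()) {
  genes <- c("g9p", "gA", "gB")
  ann <- gene_annotation(genes, c("9", "1", "1"), c("9p", "1q", "1q"),
                         c(1, 1, 2), c(10, 10, 12))
  expr <- expression_matrix(
    rbind(c(5, 4, 5, 5), c(2, 3, 2, 2.5), c(7, 6, 7, 7)),
    genes, meta$sample_id)
  cn <- matrix(2L, 3, 4, dimnames = list(genes, meta$sample_id))
  cn["g9p", "a2"] <- 1L
  cn["gA", "a2"] <- 3L
  list(expr = expr, cn = cn, ann = ann, meta = meta)
}

test_that("build_pair_diffs encodes the second-minus-first contrasts", {
  inp <- make_pair_inputs()
  pd <- build_pair_diffs(inp$expr, inp$cn, inp$ann, inp$meta, seed = 3)
  expect_identical(colnames(pd$d_expr), c("a1|a2", "b1|b2"))
  p <- pd$pairs[pd$pairs$sample_a == "a1", ]
  expect_identical(p$d_9p, 1L)        # loss in second sample only
  expect_identical(p$d_epi, 1L)       # SETD2 gained in a2 (PBRM1 in both)
  expect_identical(p$d_wgd, 1L)
  expect_equal(p$d_purity, -0.2)
  expect_equal(unname(pd$d_expr[, "a1|a2"]), c(-1, 1, -1))
  # 9p gene masked from d_cn; the 1q gene carries its CN difference
  expect_true(is.na(pd$d_cn["g9p", "a1|a2"]))
  expect_equal(unname(pd$d_cn["gA", "a1|a2"]), 1)
  # identical genotypes and purity: all pair-level fields zero
  q <- pd$pairs[pd$pairs$sample_a == "b1", ]
  expect_true(all(c(q$d_purity, q$d_epi, q$d_9p, q$d_wgd, q$d_type) == 0))
})

test_that("swapping sample order negates every d_ field", {
  inp <- make_pair_inputs()
  pd <- build_pair_diffs(inp$expr, inp$cn, inp$ann, inp$meta, seed = 3)
  # rename so the former second sample sorts first
  flip <- c(a1 = "z1", a2 = "a0", b1 = "b1", b2 = "b2")
  meta2 <- inp$meta
  meta2$sample_id <- unname(flip[meta2$sample_id])
  expr2 <- inp$expr; colnames(expr2) <- unname(flip[colnames(inp$expr)])
  cn2 <- inp$cn; colnames(cn2) <- colnames(expr2)
  pd2 <- build_pair_diffs(expr2, cn2, inp$ann, meta2, seed = 3)
  a <- pd$pairs[pd$pairs$sample_a == "a1", ]
  b <- pd2$pairs[pd2$pairs$sample_b == "z1", ]
  expect_equal(b$d_purity, -a$d_purity)
  expect_identical(b$d_9p, -a$d_9p)
  expect_identical(b$d_epi, -a$d_epi)
  expect_identical(b$d_wgd, -a$d_wgd)
  expect_equal(unname(pd2$d_expr[, "a0|z1"]), -unname(pd$d_expr[, "a1|a2"]))
})

test_that("d_type contrasts follow the normal / metastasis coding", {
  meta <- sample_meta(c("m1", "p1", "p2"), "P1",
                      c("metastasis", "primary", "primary"),
                      purity = rep(0.8, 3), wGII = rep(0, 3), wgd = FALSE,
                      clones = list("A", "A", "A"))
  genes <- c("gA", "gB", "gC")
  expr <- expression_matrix(matrix(rnorm(9), 3), genes, meta$sample_id)
  cn <- matrix(2L, 3, 3, dimnames = list(genes, meta$sample_id))
  ann <- gene_annotation(genes, "1", "1q", 1:3, 4:6)
  pd <- build_pair_diffs(expr, cn, ann, meta,
                         pair_types = c("primary-primary",
                                        "metastasis-primary"),
                         type_contrast = "metastasis", seed = 1)
  # pair (m1, p1): first sample is the metastasis -> -1
  expect_identical(pd$pairs$d_type[pd$pairs$sample_a == "m1" &
                                     pd$pairs$sample_b == "p1"], -1L)
  expect_identical(pd$pairs$d_type[pd$pairs$sample_a == "p1"], 0L)
})

test_that("fit_gene_models recovers a known dosage slope and drops constant covariates", {
  set.seed(61)
  n_pairs <- 48
  pats <- rep(sprintf("P%02d", 1:16), each = 3)
  pairs <- data.frame(
    patient_id = pats,
    sample_a = sprintf("s%02da", seq_len(n_pairs)),
    sample_b = sprintf("s%02db", seq_len(n_pairs)),
    pair_type = "primary-primary",
    d_purity = 0,                      # constant -> must be dropped
    d_epi = sample(-1:1, n_pairs, TRUE),
    d_9p = sample(-1:1, n_pairs, TRUE),
    d_wgd = 0L, d_type = 0L,
    wgd_group = "FALSE/FALSE",
    rand_binary = rbinom(n_pairs, 1, 0.5),
    rand_continuous = rnorm(n_pairs), stringsAsFactors = FALSE)
  genes <- sprintf("g%02d", 1:40)
  d_cn <- matrix(sample(-1:1, 40 * n_pairs, TRUE), 40,
                 dimnames = list(genes, paste(pairs$sample_a,
                                              pairs$sample_b, sep = "|")))
  d_expr <- 1.0 * d_cn + matrix(rnorm(40 * n_pairs, 0, 0.1), 40)
  pd <- structure(list(pairs = pairs, d_expr = d_expr, d_cn = d_cn,
                       genes = genes), class = "sample_pair_diffs")
  expect_message(fits <- fit_gene_models(pd), "d_purity")
  expect_true(all(is.na(fits$estimate_d_purity)))
  expect_identical(nrow(fits), 40L)
  expect_gte(mean(abs(fits$estimate_d_cn - 1) <= 0.1), 0.95)
  expect_true(all(fits$fdr_d_cn >= fits$p_d_cn - 1e-12))
  expect_true(all(fits$fdr_d_cn < 0.05))          # strong effect everywhere
  # the random baselines stay mostly null
  expect_lt(mean(fits$p_rand_continuous < 0.05, na.rm = TRUE), 0.2)
})

test_that("decompose_ited_variance reads sequential shares off the ANOVA table", {
  set.seed(7)
  n <- 60
  # one covariate generates all signal; others orthogonal noise
  x1 <- rnorm(n)
  covs <- data.frame(x1 = x1, x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * x1 + rnorm(n, 0, 0.05)
  dec <- decompose_ited_variance(y, covs)
  tab <- dec$table
  expect_gte(tab$variance_fraction[tab$covariate == "x1"], 0.9)
  expect_lt(max(tab$variance_fraction[tab$covariate != "x1"]), 0.05)
  expect_equal(dec$total_explained, dec$r_squared, tolerance = 1e-12)
  expect_true(all(tab$fdr >= tab$p - 1e-12))

  # exactly orthogonal design (incl. the intercept): sequential shares
  # equal marginal R^2
  x <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  covs2 <- data.frame(a = x[, 1], b = x[, 2], c = x[, 3])
  y2 <- 1.5 * x[, 1] - 2 * x[, 2] + 0.5 * x[, 3] + rnorm(n, 0, 0.3)
  dec2 <- decompose_ited_variance(y2, covs2)
  marginal <- sapply(covs2, function(cv) summary(lm(y2 ~ cv))$r.squared)
  expect_equal(dec2$table$variance_fraction, unname(marginal),
               tolerance = 1e-10)

  # affine rescaling of one covariate does not change the decomposition
  covs3 <- covs2; covs3$b <- covs3$b * 100 - 4
  dec3 <- decompose_ited_variance(y2, covs3)
  expect_equal(dec3$table$variance_fraction, dec2$table$variance_fraction,
               tolerance = 1e-10)

  expect_error(decompose_ited_variance(rnorm(4), covs[1:4, ]),
               class = "clonexpr_rank_error")
})

test_that("decompose_ited_variance recovers simulated I-TED determinants", {
  set.seed(15)
  n <- 80
  covs <- data.frame(purity_ith = runif(n), tumor_size = rnorm(n),
                     n_regions = sample(2:6, n, TRUE),
                     genetic_ith = runif(n), cn_het = runif(n),
                     stage = sample(1:4, n, TRUE),
                     subclonal_epi = rbinom(n, 1, 0.4),
                     subclonal_9p = rbinom(n, 1, 0.3),
                     subclonal_14q = rbinom(n, 1, 0.3))
  y <- 0.5 * covs$genetic_ith + 0.4 * covs$cn_het + rnorm(n, 0, 0.08)
  dec <- decompose_ited_variance(y, covs)
  tab <- dec$table
  expect_lt(tab$fdr[tab$covariate == "genetic_ith"], 0.05)
  expect_lt(tab$fdr[tab$covariate == "cn_het"], 0.05)
  # the two true determinants dominate the variance attribution
  top2 <- tab$covariate[order(-tab$variance_fraction)][1:2]
  expect_setequal(top2, c("genetic_ith", "cn_het"))
  fit <- lm(y ~ ., data = cbind(y = y, covs))
  expect_gt(coef(fit)["genetic_ith"], 0)
})

test_that("ited_driver_scan appends one driver CNA at a time", {
  set.seed(19)
  n <- 50
  base <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  drv <- data.frame(cna_strong = rbinom(n, 1, 0.4),
                    cna_null = rbinom(n, 1, 0.4))
  y <- 0.8 * drv$cna_strong + rnorm(n, 0, 0.2)
  scan <- ited_driver_scan(y, base, drv)
  expect_identical(scan$driver, c("cna_strong", "cna_null"))
  expect_gt(scan$variance_fraction[1], scan$variance_fraction[2])
  expect_lt(scan$p[1], 0.05)
})

test_that("lme_association honors its degenerate and fallback contracts", {
  g <- rep(c("P1", "P2", "P3"), each = 5)
  x <- rnorm(15)
  flat <- lme_association(rep(2, 15), x, group = g)
  expect_equal(flat$coefficient, 0)
  expect_equal(flat$p, 1)
  expect_identical(flat$method, "degenerate")

  # single group downgrades to OLS and matches the closed-form slope
  set.seed(4)
  y <- 0.5 * x + rnorm(15, 0, 0.3)
  expect_message(fit <- lme_association(y[1:5], x[1:5], group = rep("P1", 5)),
                 "least squares")
  expect_identical(fit$method, "ols")
  ols <- coef(lm(y[1:5] ~ x[1:5]))[2]
  expect_equal(fit$coefficient, unname(ols), tolerance = 1e-10)

  # plain positive-slope detection with patient structure
  set.seed(10)
  g2 <- rep(sprintf("P%02d", 1:15), each = 4)
  x2 <- rnorm(60)
  y2 <- rnorm(15)[as.integer(factor(g2))] + 0.8 * x2 + rnorm(60, 0, 0.4)
  fit2 <- lme_association(y2, x2, group = g2)
  expect_identical(fit2$method, "lmm")
  expect_gt(fit2$coefficient, 0.5)
  expect_lt(fit2$p, 0.01)
})

test_that("paired_driver_association means per group then pairs across patients", {
  set.seed(30)
  pats <- sprintf("P%02d", 1:20)
  ids <- c(); status <- c(); pat_of <- c()
  for (p in pats) {
    ids <- c(ids, paste0(p, "_wt", 1:3), paste0(p, "_mut", 1:2))
    status <- c(status, rep(FALSE, 3), rep(TRUE, 2))
    pat_of <- c(pat_of, rep(p, 5))
  }
  meta <- sample_meta(ids, pat_of, "primary", purity = rep(0.8, length(ids)),
                      wGII = rep(0, length(ids)), wgd = FALSE,
                      clones = as.list(rep("MRCA", length(ids))),
                      drivers = list(SETD2 = status))
  scores <- cbind(shifted = rnorm(length(ids)) + 1.0 * status,
                  null_pw = rnorm(length(ids)))
  rownames(scores) <- ids
  res <- paired_driver_association(scores, "SETD2", meta)
  expect_lt(res$fdr[res$pathway == "shifted"], 0.05)
  expect_gt(res$p[res$pathway == "null_pw"], 0.05)
  expect_identical(unique(res$n_patients), 20L)
  expect_gt(res$mut_mean[res$pathway == "shifted"],
            res$wt_mean[res$pathway == "shifted"])

  # identical scores in both groups: all differences zero -> p = 1
  scores0 <- cbind(pw = ave(seq_along(ids), pat_of))
  rownames(scores0) <- ids
  res0 <- paired_driver_association(scores0, "SETD2", meta)
  expect_equal(res0$p, 1)
  expect_identical(res0$n_zero_diff, 20L)

  # fewer than 2 eligible patients -> empty result with a notice
  meta1 <- meta[meta$patient_id == "P01", ]
  expect_message(
    empty <- paired_driver_association(scores, "SETD2", meta1),
    "fewer than 2")
  expect_identical(nrow(empty), 0L)
})

test_that("locus_eqtl applies the strict 70% prevalence filter and recovers slopes", {
  set.seed(50)
  n <- 100
  g <- rep(sprintf("P%02d", 1:25), each = 4)
  cn <- sample(1:4, n, TRUE)
  purity <- runif(n, 0.5, 1)
  status <- rbinom(n, 1, 0.5)
  at70 <- rep(c(1, 0), c(70, 30))            # exactly 70% detected
  at69 <- rep(c(1, 0), c(69, 31))
  target <- 0.8 * cn + 0.3 * purity + rnorm(n, 0, 0.2)
  flat <- rep(1, n)
  fe <- rbind(at70 = at70, at69 = at69, target = target, flat = flat)
  colnames(fe) <- sprintf("s%03d", 1:n)
  lc <- matrix(rep(cn, each = 4), 4, byrow = FALSE,
               dimnames = dimnames(fe))
  lc["target", ] <- cn
  res <- locus_eqtl(fe, lc, purity, status, g)
  expect_true("at70" %in% res$feature)
  expect_false("at69" %in% res$feature)
  expect_equal(res$cn_coef[res$feature == "target"], 0.8, tolerance = 0.1)
  expect_lt(res$fdr[res$feature == "target"], 0.05)
  expect_equal(res$p[res$feature == "flat"], 1)

  expect_message(
    none <- locus_eqtl(fe[c("at69", "at69"), ] * 0, lc[1:2, ], purity,
                       status, g),
    "prevalence")
  expect_identical(nrow(none), 0L)
})
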