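test_that("simulate_tree grows valid rooted trees with reproducible seeds", {
  t1 <- simulate_tree(1)
  expect_identical(t1$nodes, "MRCA")
  expect_identical(t1$root, "MRCA")

  a <- simulate_tree(5, seed = 11)
  b <- simulate_tree(5, seed = 11)
  expect_identical(a$edges, b$edges)

  expect_error(simulate_tree(0), class = "clonexpr_config_error")

  set.seed(99)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    tr <- simulate_tree(n)
    expect_identical(nrow(tr$edges), n - 1L)   # edges = nodes - 1 always
    expect_identical(length(tr$nodes), n)
  }
})

test_that("simulate_genotypes inherits events cumulatively along lineages", {
  cfg0 <- simulation_config(p_arm_loss = 0, p_arm_gain = 0, p_driver = 0)
  tr <- simulate_genotypes(simulate_tree(6, seed = 2), cfg0, seed = 5)
  for (cl in tr$nodes) {
    expect_identical(tr$genotypes[[cl]]$driver_mutations, "VHL")
    expect_length(tr$genotypes[[cl]]$arm_events, 0L)
  }

  # chain with certain arm loss: every descendant of the first loss keeps it
  cfg1 <- simulation_config(p_arm_loss = 1, p_arm_gain = 0, p_driver = 0)
  ch <- simulate_genotypes(chain_tree(4), cfg1, seed = 3)
  ev2 <- ch$genotypes[["C2"]]$arm_events
  expect_true(length(ev2) == 1 && ev2[[1]] == "loss")
  expect_true(all(names(ev2) %in% names(ch$genotypes[["C3"]]$arm_events)))
  expect_true(all(names(ch$genotypes[["C3"]]$arm_events) %in%
                    names(ch$genotypes[["C4"]]$arm_events)))
})

test_that("per-edge event frequency matches the configured probability", {
  cfg <- simulation_config(p_arm_loss = 0.3, p_arm_gain = 0, p_driver = 0)
  set.seed(17)
  n_edges <- 0; n_events <- 0
  for (i in 1:400) {
    tr <- simulate_genotypes(simulate_tree(8), cfg)
    parent_of <- setNames(tr$edges$parent, tr$edges$child)
    for (ch in tr$edges$child) {
      n_edges <- n_edges + 1
      if (length(tr$genotypes[[ch]]$arm_events) >
          length(tr$genotypes[[parent_of[ch]]]$arm_events)) {
        n_events <- n_events + 1
      }
    }
  }
  # caveat: an edge can draw "loss" with all loss arms exhausted; with 5
  # loss arms and depth <= 7 this is rare but possible, so allow 3 SD + a
  # small saturation margin
  se <- sqrt(0.3 * 0.7 / n_edges)
  expect_lt(abs(n_events / n_edges - 0.3), 3 * se + 0.01)
})

test_that("the same seed reproduces the cohort and its serialized files byte-identically", {
  cfg <- simulation_config(n_patients = 4, n_genes = 200, seed = 21)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$metadata$clones, c2$metadata$clones)
  expect_identical(c1$repertoires, c2$repertoires)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("adding patients does not perturb earlier patients' draws", {
  small <- simulate_cohort(simulation_config(n_patients = 3, n_genes = 150,
                                             seed = 9))
  big <- simulate_cohort(simulation_config(n_patients = 5, n_genes = 150,
                                           seed = 9))
  shared <- colnames(small$expression)
  expect_identical(big$expression[, shared], small$expression[, shared])
})

test_that("cohort invariants hold: simplex TME rows, clones resolve, purity range", {
  co <- simulate_cohort(simulation_config(n_patients = 12, n_genes = 200,
                                          seed = 4))
  expect_true(all(abs(rowSums(co$tme_fractions) - 1) < 1e-9))
  expect_silent(validate_sample_meta(co$metadata, co$trees))
  tumor <- co$metadata[co$metadata$sample_type != "normal", ]
  rng <- simulation_config()$purity_range
  expect_true(all(tumor$purity >= rng[1] & tumor$purity <= rng[2]))
  mid <- mean(rng)
  se <- diff(rng) / sqrt(12) / sqrt(nrow(tumor))
  expect_lt(abs(mean(tumor$purity) - mid), 2 * se + 0.02)
})

test_that("a degenerate noiseless clone-free world collapses to identical samples and I-TED 0", {
  cfg <- simulation_config(n_patients = 3, regions_per_patient = c(3, 3),
                           clones_per_patient = c(1, 1),
                           polyclonal_fraction = 0, n_genes = 120,
                           p_arm_loss = 0, p_arm_gain = 0, p_driver = 0,
                           drift_sd = 1e-12, noise_sd = 0,
                           purity_range = c(1, 1), immune_gain = 0,
                           metastasis_fraction = 0, add_normals = FALSE,
                           seed = 2)
  co <- simulate_cohort(cfg)
  pats <- split(co$metadata$sample_id, co$metadata$patient_id)
  for (ids in pats) {
    expect_lt(max(abs(co$expression[, ids[1]] - co$expression[, ids[2]])),
              1e-9)
  }
  res <- ited(co$expression, co$metadata,
              genes = top_variable_genes(co$expression, 100))
  expect_true(all(res$per_patient$ited < 1e-6))
})

test_that("dosage arithmetic is exact: one lost copy shifts expression by -beta", {
  cfg <- simulation_config(n_patients = 6, n_genes = 200, drift_sd = 1e-12,
                           p_arm_loss = 1, p_arm_gain = 0, p_driver = 0,
                           seed = 31)
  co <- simulate_cohort(cfg)
  checked <- 0
  for (pat in names(co$trees)) {
    tr <- co$trees[[pat]]
    truth <- co$truth$patients[[pat]]
    for (i in seq_len(nrow(tr$edges))) {
      par <- tr$edges$parent[i]; ch <- tr$edges$child[i]
      newly_lost <- setdiff(names(tr$genotypes[[ch]]$arm_events),
                            names(tr$genotypes[[par]]$arm_events))
      for (arm in newly_lost) {
        g <- setdiff(names(co$truth$gene_arms)[co$truth$gene_arms == arm],
                     co$truth$trans_targets)
        if (length(g) == 0 || arm == "9p") next   # 9p also triggers trans shift elsewhere
        delta <- truth$clone_means[g, ch] - truth$clone_means[g, par]
        expect_true(all(abs(delta - (-cfg$dosage_slope)) < 1e-6))
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 0)
})

test_that("Brownian drift variance accumulates linearly with clonal distance", {
  cfg <- simulation_config(n_genes = 150, drift_sd = 0.5, seed = 13)
  set.seed(13)
  sq <- list()
  for (i in 1:120) {
    tr <- simulate_tree(6)
    drift <- matrix(0, 150, 6, dimnames = list(NULL, tr$nodes))
    for (j in seq_len(nrow(tr$edges))) {
      ch <- tr$edges$child[j]; par <- tr$edges$parent[j]
      drift[, ch] <- drift[, par] + rnorm(150, 0, cfg$drift_sd)
    }
    for (a in tr$nodes) for (b in tr$nodes) {
      if (a >= b) next
      d <- clonal_distance(tr, a, b)
      sq[[length(sq) + 1]] <- c(d, mean((drift[, a] - drift[, b])^2))
    }
  }
  m <- do.call(rbind, sq)
  for (d in 1:4) {
    obs <- mean(m[m[, 1] == d, 2])
    expect_lt(abs(obs - cfg$drift_sd^2 * d) / (cfg$drift_sd^2 * d), 0.15)
  }
})

test_that("write_cohort / read_cohort round-trips the analysis inputs", {
  co <- simulate_cohort(simulation_config(n_patients = 3, n_genes = 150,
                                          seed = 6))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$expression, co$expression)
  expect_equal(back$cn, expression_matrix(co$cn, rownames(co$cn),
                                          colnames(co$cn)))
  expect_identical(back$metadata$clones, co$metadata$clones)
  expect_identical(names(back$trees), names(co$trees))
  expect_identical(back$trees$P01$edges, co$trees$P01$edges)
  expect_equal(back$tme_fractions, co$tme_fractions)
  expect_identical(back$gene_sets$Trans_target_block,
                   co$gene_sets$Trans_target_block)
  expect_equal(back$repertoires[["P01_R1.TCR"]]$counts,
               co$repertoires[["P01_R1.TCR"]]$counts,
               ignore_attr = FALSE)
})
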