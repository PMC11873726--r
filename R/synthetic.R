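#' Simulation configuration for synthetic multiregion cohorts
#'
#' The generator states a world with the statistical structure the pipeline
#' assumes: clones on a random phylogeny; heritable Brownian expression drift
#' accumulating along edges; gene-dosage (copy-number) cis effects; a
#' trans-acting driver effect tied to 9p loss shifting a dedicated gene
#' block; purity admixture of tumor and a shared stromal profile; Dirichlet
#' TME fractions with an immunosuppressive (myeloid up, T-effector down)
#' shift in driver-bearing samples, echoed in signature gene expression; and
#' lineage-coupled TCR repertoires whose overlap decays with clonal distance.
#' Defaults are fixed once and documented in the methods vignette.
#'
#' @param n_patients number of patients.
#' @param regions_per_patient inclusive integer range of primary regions.
#' @param clones_per_patient inclusive integer range of clone counts.
#' @param polyclonal_fraction probability a region hosts 2 clones
#'   (parent/child pairs preferred).
#' @param n_genes genes simulated.
#' @param genes_per_arm genes per chromosome-arm block.
#' @param p_arm_loss,p_arm_gain,p_driver per-edge probabilities of acquiring
#'   an arm loss, an arm gain or an epigenetic driver mutation (mutually
#'   exclusive per edge).
#' @param dosage_slope expression units per unit log2(CN/2).
#' @param drift_sd per-edge SD of heritable Brownian expression drift.
#' @param driver_trans_effect expression shift of the trans target block in
#'   9p-lost clones.
#' @param trans_target_fraction fraction of (non-9p) genes in the trans
#'   target block.
#' @param purity_range uniform sampling range of tumor purity.
#' @param noise_sd per-gene per-sample measurement noise SD.
#' @param baseline_mean,baseline_sd gene baseline expression distribution
#'   (variance-stabilized scale).
#' @param low_expr_fraction fraction of genes given a low baseline so the
#'   TPM prevalence filter has something to remove.
#' @param stroma_sd SD of the cohort stromal profile around the baseline.
#' @param stroma_patient_jitter_sd SD of per-patient stromal jitter.
#' @param tme_concentration named Dirichlet concentration per population.
#' @param immunosuppressive_shift log-scale shift applied to the myeloid
#'   (up) and T-effector (down) concentrations in immunosuppressive samples.
#' @param baseline_suppressive_rate probability a patient's TME is
#'   immunosuppressive independent of driver status (driver-bearing clones
#'   are immunosuppressive on top of this base rate, mirroring the roughly
#'   balanced antitumor/immunosuppressive split seen in real cohorts).
#' @param immune_gain expression units per unit population fraction applied
#'   to that population's signature genes.
#' @param immune_signature_size genes per immune signature.
#' @param repertoire_pool_size patient-level shared clonotype pool size.
#' @param repertoire_private_rate Poisson mean of new private clonotypes per
#'   tree edge.
#' @param metastasis_fraction probability a patient contributes a metastasis
#'   sample (seeded by a designated clone).
#' @param add_normals add one tumor-adjacent normal sample per patient.
#' @param wgd_patient_fraction probability a patient is whole-genome doubled
#'   (flag only; no expression effect).
#' @param min_cn_expr floor applied to CN inside log2(CN/2) (guards CN = 0).
#' @param seed global seed; per-patient streams are derived from it so
#'   adding patients does not perturb earlier patients' draws.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 20L,
                              regions_per_patient = c(2L, 4L),
                              clones_per_patient = c(3L, 6L),
                              polyclonal_fraction = 0.2,
                              n_genes = 1000L,
                              genes_per_arm = 50L,
                              p_arm_loss = 0.25, p_arm_gain = 0.15,
                              p_driver = 0.25,
                              dosage_slope = 1.0,
                              drift_sd = 0.4,
                              driver_trans_effect = 1.0,
                              trans_target_fraction = 0.10,
                              purity_range = c(0.6, 0.95),
                              noise_sd = 0.3,
                              baseline_mean = 6, baseline_sd = 1.5,
                              low_expr_fraction = 0.05,
                              stroma_sd = 1.0,
                              stroma_patient_jitter_sd = 0.1,
                              tme_concentration = c(T_effector = 48,
                                                    Myeloid = 48,
                                                    B_cells = 24, NK = 18,
                                                    Endothelial = 30,
                                                    Fibroblast = 36),
                              immunosuppressive_shift = 1.0,
                              baseline_suppressive_rate = 0.35,
                              immune_gain = 6,
                              immune_signature_size = 30L,
                              repertoire_pool_size = 60L,
                              repertoire_private_rate = 8,
                              metastasis_fraction = 0.3,
                              add_normals = TRUE,
                              wgd_patient_fraction = 0.2,
                              min_cn_expr = 0.25,
                              seed = 1L) {
  stopifnot_fraction(polyclonal_fraction, "polyclonal_fraction")
  stopifnot_fraction(metastasis_fraction, "metastasis_fraction")
  stopifnot_fraction(trans_target_fraction, "trans_target_fraction")
  if (drift_sd < 0 || noise_sd < 0) {
    ce_abort("drift_sd and noise_sd must be >= 0",
             class = "clonexpr_config_error")
  }
  if (p_arm_loss + p_arm_gain + p_driver > 1) {
    ce_abort("per-edge event probabilities must sum to <= 1",
             class = "clonexpr_config_error")
  }
  if (length(purity_range) != 2L || purity_range[1L] > purity_range[2L] ||
      purity_range[1L] < 0 || purity_range[2L] > 1) {
    ce_abort("purity_range must be [low, high] within [0, 1]",
             class = "clonexpr_config_error")
  }
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

.epi_drivers <- c("SETD2", "PBRM1", "BAP1", "ARID1A", "KDM5C")
.loss_arms <- c("9p", "14q", "3p", "6q", "8p")
.gain_arms <- c("1q", "2q", "5q", "7q", "8q", "20q")
# ordered so the driver-relevant arms get genes even in small simulations
.arm_pool <- c("9p", "14q", "3p", "1q", "6q", "5q", "8p", "7q", "2q", "20q",
               "1p", "2p", "3q", "4p", "4q", "5p", "6p", "7p", "8q", "17p")

#' Simulate a random clone phylogeny
#'
#' Grows a rooted tree by uniform random attachment: clone `i` attaches to
#' one of the existing `i - 1` clones chosen uniformly. The root is labelled
#' `MRCA`, remaining clones `C2`, `C3`, ...
#'
#' @param n_clones number of clones (>= 1).
#' @param patient_id patient id to attach.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return a [clone_tree()].
#' @export
simulate_tree <- function(n_clones, patient_id = "sim", seed = NULL) {
  if (!is_scalar_number(n_clones) || n_clones < 1) {
    ce_abort("n_clones must be >= 1", class = "clonexpr_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- c("MRCA", if (n_clones > 1) paste0("C", seq(2L, n_clones)))
  if (n_clones == 1L) {
    return(clone_tree(patient_id, data.frame(parent = character(0),
                                             child = character(0)),
                      nodes = "MRCA"))
  }
  parent <- character(n_clones - 1L)
  for (i in seq(2L, n_clones)) {
    parent[i - 1L] <- labels[sample.int(i - 1L, 1L)]
  }
  clone_tree(patient_id,
             data.frame(parent = parent, child = labels[-1L],
                        stringsAsFactors = FALSE))
}

#' Simulate clone genotypes on a tree
#'
#' The root carries a truncal VHL-like driver. Walking the tree from the
#' root, each edge independently acquires at most one event: an arm loss
#' (CN 2 to 1 on an arm block not already lost), an arm gain (2 to 3), or a
#' mutation in an epigenetic driver not yet mutated on that lineage.
#' Genotypes are inherited cumulatively from the parent.
#'
#' @param tree a [clone_tree()].
#' @param config a [simulation_config()] (event probabilities).
#' @param seed optional seed; NULL uses the current stream.
#' @return the tree with `genotypes` filled.
#' @export
simulate_genotypes <- function(tree, config = simulation_config(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genos <- list()
  genos[[tree$root]] <- list(driver_mutations = "VHL",
                             cn = stats::setNames(integer(0), character(0)),
                             arm_events = stats::setNames(character(0),
                                                          character(0)))
  # BFS so parents are always filled first
  order_nodes <- tree$root
  frontier <- tree$root
  while (length(frontier)) {
    kids <- tree$edges$child[tree$edges$parent %in% frontier]
    order_nodes <- c(order_nodes, kids)
    frontier <- kids
  }
  parent_of <- tree_parent_map(tree)
  for (node in order_nodes[-1L]) {
    g <- genos[[parent_of[[node]]]]
    u <- stats::runif(1L)
    if (u < config$p_arm_loss) {
      cand <- setdiff(.loss_arms, names(g$arm_events))
      if (length(cand)) {
        # 9p and 14q losses are the recurrent events in this tumor type
        w <- c(`9p` = 0.4, `14q` = 0.25, `3p` = 0.15, `6q` = 0.1,
               `8p` = 0.1)[cand]
        arm <- cand[sample.int(length(cand), 1L, prob = w)]
        g$arm_events[arm] <- "loss"
      }
    } else if (u < config$p_arm_loss + config$p_arm_gain) {
      cand <- setdiff(.gain_arms, names(g$arm_events))
      if (length(cand)) {
        arm <- cand[sample.int(length(cand), 1L)]
        g$arm_events[arm] <- "gain"
      }
    } else if (u < config$p_arm_loss + config$p_arm_gain + config$p_driver) {
      cand <- setdiff(.epi_drivers, g$driver_mutations)
      if (length(cand)) {
        g$driver_mutations <- c(g$driver_mutations,
                                cand[sample.int(length(cand), 1L)])
      }
    }
    genos[[node]] <- g
  }
  tree$genotypes <- genos
  tree
}

#' Gene-level integer copy number per clone
#'
#' Derived from the clone arm events over the gene-to-arm assignment:
#' baseline 2, loss 1, gain 3; explicit per-gene `cn` entries in a genotype
#' override the arm-derived value.
#'
#' @param tree clone tree with genotypes.
#' @param gene_arms named character vector gene id -> arm.
#' @return integer matrix genes x clones.
#' @export
clone_cn_matrix <- function(tree, gene_arms) {
  genes <- names(gene_arms)
  cn <- matrix(2L, nrow = length(genes), ncol = length(tree$nodes),
               dimnames = list(genes, tree$nodes))
  for (cl in tree$nodes) {
    g <- tree$genotypes[[cl]]
    if (is.null(g)) next
    for (arm in names(g$arm_events)) {
      val <- if (g$arm_events[[arm]] == "loss") 1L else
        if (g$arm_events[[arm]] == "gain") 3L else 2L
      cn[gene_arms == arm, cl] <- val
    }
    if (length(g$cn)) cn[names(g$cn), cl] <- g$cn
  }
  cn
}

# guard against sample()'s scalar expansion when lo == hi
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

clone_ancestors <- function(tree, clone) {
  parent <- tree_parent_map(tree)
  path <- clone
  while (path[length(path)] != tree$root) {
    path <- c(path, parent[[path[length(path)]]])
  }
  path
}

#' Simulate a full multiregion cohort
#'
#' See [simulation_config()] for the generative model. Each patient draws
#' from an RNG stream derived from the global seed and the patient index, so
#' cohorts are reproducible and extending the cohort does not perturb
#' existing patients. All ground truth needed to recompute expected
#' expression means is recorded in `$truth`.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort`: `expression`, `tpm_like`,
#'   `metadata`, `trees`, `tme_fractions`, `repertoires`, `gene_annotation`,
#'   `cn` (genes x samples), `gene_sets`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  set.seed(config$seed)
  n_genes <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n_genes))
  arms <- rep(rep(.arm_pool, length.out = ceiling(n_genes / config$genes_per_arm)),
              each = config$genes_per_arm)[seq_len(n_genes)]
  gene_arms <- stats::setNames(arms, genes)
  annotation <- gene_annotation(
    genes, chromosome = sub("[pq]$", "", arms), arm = arms,
    start = (seq_len(n_genes) - 1L) %% config$genes_per_arm * 100000L + 1L,
    end = (seq_len(n_genes) - 1L) %% config$genes_per_arm * 100000L + 50000L)

  baseline <- stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  n_low <- floor(config$low_expr_fraction * n_genes)
  low_genes <- if (n_low > 0) sample(genes, n_low) else character(0)
  baseline[match(low_genes, genes)] <- stats::rnorm(n_low, -2, 0.5)
  names(baseline) <- genes
  stroma <- baseline + stats::rnorm(n_genes, 0, config$stroma_sd)
  names(stroma) <- genes

  non9p <- genes[arms != "9p"]
  trans_targets <- sample(non9p, floor(config$trans_target_fraction * n_genes))
  immune_pool <- setdiff(genes[!arms %in% c("9p", "14q")], trans_targets)
  sig_size <- min(config$immune_signature_size, floor(length(immune_pool) / 2))
  if (sig_size < config$immune_signature_size) {
    message(sprintf("immune signatures capped at %d genes by the gene pool",
                    sig_size))
  }
  teff_genes <- sample(immune_pool, sig_size)
  myeloid_genes <- sample(setdiff(immune_pool, teff_genes), sig_size)
  # immune signature genes behave like cell-type markers: low tumor-intrinsic
  # baseline, expression driven by the population fraction in the admixture
  marker_idx <- match(c(teff_genes, myeloid_genes), genes)
  baseline[marker_idx] <- stats::rnorm(length(marker_idx),
                                       config$baseline_mean - 4, 0.5)
  stroma[marker_idx] <- baseline[marker_idx] +
    stats::rnorm(length(marker_idx), 0, config$stroma_sd)
  pops <- names(config$tme_concentration)

  expr_cols <- list(); tpm_cols <- list(); cn_cols <- list()
  meta_rows <- list(); tme_rows <- list(); reps <- list()
  trees <- list(); truth_pat <- list()

  for (i in seq_len(config$n_patients)) {
    set.seed(derive_seed(config$seed, i))
    pat <- sprintf("P%02d", i)
    n_clones <- sample_range(config$clones_per_patient[1L],
                             config$clones_per_patient[2L])
    tree <- simulate_tree(n_clones, patient_id = pat)
    tree <- simulate_genotypes(tree, config)
    trees[[pat]] <- tree
    cn_clone <- clone_cn_matrix(tree, gene_arms)

    # Brownian drift accumulated along root paths
    drift <- matrix(0, nrow = n_genes, ncol = n_clones,
                    dimnames = list(genes, tree$nodes))
    order_nodes <- tree$root
    frontier <- tree$root
    while (length(frontier)) {
      kids <- tree$edges$child[tree$edges$parent %in% frontier]
      order_nodes <- c(order_nodes, kids); frontier <- kids
    }
    parent_of <- tree_parent_map(tree)
    for (node in order_nodes[-1L]) {
      drift[, node] <- drift[, parent_of[[node]]] +
        stats::rnorm(n_genes, 0, config$drift_sd)
    }
    # immune marker transcripts reflect the TME compartment, not the tumor
    # clone: they do not inherit clonal expression drift
    drift[marker_idx, ] <- 0

    clone_means <- matrix(NA_real_, n_genes, n_clones,
                          dimnames = list(genes, tree$nodes))
    has_9p <- vlapply(tree$nodes, function(cl)
      identical(unname(tree$genotypes[[cl]]$arm_events["9p"]), "loss"))
    for (cl in tree$nodes) {
      dose <- config$dosage_slope *
        log2(pmax(cn_clone[, cl], config$min_cn_expr) / 2)
      m <- baseline + dose + drift[, cl]
      if (has_9p[[cl]]) {
        m[trans_targets] <- m[trans_targets] + config$driver_trans_effect
      }
      clone_means[, cl] <- m
    }

    stroma_pat <- stroma + stats::rnorm(n_genes, 0,
                                        config$stroma_patient_jitter_sd)
    wgd <- stats::runif(1L) < config$wgd_patient_fraction
    base_sup <- stats::runif(1L) < config$baseline_suppressive_rate
    n_regions <- sample_range(config$regions_per_patient[1L],
                              config$regions_per_patient[2L])

    region_clones <- vector("list", n_regions)
    for (r in seq_len(n_regions)) {
      poly <- n_clones >= 2L && stats::runif(1L) < config$polyclonal_fraction
      if (poly) {
        child <- tree$edges$child[sample.int(nrow(tree$edges), 1L)]
        region_clones[[r]] <- c(parent_of[[child]], child)
      } else {
        region_clones[[r]] <- tree$nodes[sample.int(n_clones, 1L)]
      }
    }

    # metastasis: seeded by a clone observed in a primary region
    met_clone <- NULL
    if (stats::runif(1L) < config$metastasis_fraction) {
      observed <- unique(unlist(region_clones))
      met_clone <- observed[sample.int(length(observed), 1L)]
    }

    make_sample <- function(id, type, clones_here) {
      purity <- if (type == "normal") 0 else
        stats::runif(1L, config$purity_range[1L], config$purity_range[2L])
      if (type == "normal") {
        tumor_mean <- rep(0, n_genes); cn_s <- rep(2L, n_genes)
      } else {
        tumor_mean <- rowMeans(clone_means[, clones_here, drop = FALSE])
        cn_s <- as.integer(round(rowMeans(cn_clone[, clones_here,
                                                   drop = FALSE])))
      }
      suppressive <- type != "normal" &&
        (base_sup || any(unlist(has_9p[clones_here])))
      alpha <- config$tme_concentration
      if (suppressive) {
        alpha["Myeloid"] <- alpha["Myeloid"] * exp(config$immunosuppressive_shift)
        alpha["T_effector"] <- alpha["T_effector"] *
          exp(-config$immunosuppressive_shift)
      }
      frac <- rdirichlet1(alpha)
      names(frac) <- pops
      e <- purity * tumor_mean + (1 - purity) * stroma_pat +
        stats::rnorm(n_genes, 0, config$noise_sd)
      e[teff_genes] <- e[teff_genes] + config$immune_gain * frac["T_effector"]
      e[myeloid_genes] <- e[myeloid_genes] + config$immune_gain * frac["Myeloid"]
      drivers_here <- if (type == "normal") character(0) else
        unique(unlist(lapply(clones_here, function(cl)
          tree$genotypes[[cl]]$driver_mutations)))
      arm_loss_here <- if (type == "normal") c(FALSE, FALSE) else c(
        any(vlapply(clones_here, function(cl)
          identical(unname(tree$genotypes[[cl]]$arm_events["9p"]), "loss"))),
        any(vlapply(clones_here, function(cl)
          identical(unname(tree$genotypes[[cl]]$arm_events["14q"]), "loss"))))
      list(id = id, type = type, purity = purity, clones = clones_here,
           expr = e, cn = cn_s, frac = frac, suppressive = suppressive,
           drivers = drivers_here, loss9p = arm_loss_here[1L],
           loss14q = arm_loss_here[2L],
           wGII = mean(cn_s != 2L))
    }

    samples <- list()
    for (r in seq_len(n_regions)) {
      samples[[length(samples) + 1L]] <-
        make_sample(sprintf("%s_R%d", pat, r), "primary", region_clones[[r]])
    }
    if (!is.null(met_clone)) {
      samples[[length(samples) + 1L]] <-
        make_sample(sprintf("%s_M1", pat), "metastasis", met_clone)
    }
    if (isTRUE(config$add_normals)) {
      samples[[length(samples) + 1L]] <-
        make_sample(sprintf("%s_N1", pat), "normal", character(0))
    }

    # lineage-coupled TCR repertoires (tumor samples only)
    pool_keys <- sprintf("%s|TRB|V1|J1|S%03d", pat,
                         seq_len(config$repertoire_pool_size))
    base_counts <- stats::setNames(
      stats::rgeom(config$repertoire_pool_size, 0.15) + 1, pool_keys)
    private <- stats::setNames(vector("list", n_clones), tree$nodes)
    for (node in order_nodes[-1L]) {
      k <- stats::rpois(1L, config$repertoire_private_rate)
      if (k > 0) {
        keys <- sprintf("%s|TRB|V1|J1|%s.%02d", pat, node, seq_len(k))
        private[[node]] <- stats::setNames(stats::rgeom(k, 0.15) + 1, keys)
      }
    }
    for (s in samples) {
      if (s$type == "normal") next
      acc <- base_counts
      for (cl in s$clones) {
        for (anc in clone_ancestors(tree, cl)) {
          acc <- c(acc, private[[anc]])
        }
      }
      acc <- acc[!duplicated(names(acc))]
      counts <- stats::rpois(length(acc), lambda = acc)
      keep <- counts > 0
      if (!any(keep)) { counts[1L] <- 1; keep[1L] <- TRUE }
      reps[[paste0(s$id, ".TCR")]] <-
        repertoire(s$id, "TCR", stats::setNames(counts[keep],
                                                names(acc)[keep]))
    }

    for (s in samples) {
      expr_cols[[s$id]] <- s$expr
      cn_cols[[s$id]] <- s$cn
      tme_rows[[s$id]] <- s$frac
      meta_rows[[s$id]] <- list(
        sample_id = s$id, patient_id = pat, sample_type = s$type,
        purity = s$purity, wGII = s$wGII, wgd = wgd, clones = s$clones,
        drivers = s$drivers, loss9p = s$loss9p, loss14q = s$loss14q,
        suppressive = s$suppressive)
    }
    truth_pat[[pat]] <- list(clone_means = clone_means, drift = drift,
                             cn_clone = cn_clone, seeding_clone = met_clone,
                             stroma_patient = stroma_pat,
                             has_9p = unlist(has_9p))
  }

  expression <- expression_matrix(do.call(cbind, expr_cols), genes,
                                  names(expr_cols))
  tpm_like <- expression_matrix(pmax(2^expression - 1, 0), genes,
                                colnames(expression))
  cn <- do.call(cbind, cn_cols)
  dimnames(cn) <- dimnames(expression)
  tme_fractions <- do.call(rbind, tme_rows)
  rownames(tme_fractions) <- names(tme_rows)

  all_drivers <- c("VHL", .epi_drivers)
  drivers_tbl <- stats::setNames(lapply(all_drivers, function(d)
    vlapply(meta_rows, function(m) d %in% m$drivers)), all_drivers)
  drivers_tbl[["9p_loss"]] <- vlapply(meta_rows, `[[`, "loss9p")
  drivers_tbl[["14q_loss"]] <- vlapply(meta_rows, `[[`, "loss14q")
  metadata <- sample_meta(
    sample_id = vcapply(meta_rows, `[[`, "sample_id"),
    patient_id = vcapply(meta_rows, `[[`, "patient_id"),
    sample_type = vcapply(meta_rows, `[[`, "sample_type"),
    purity = vnapply(meta_rows, `[[`, "purity"),
    wGII = vnapply(meta_rows, `[[`, "wGII"),
    wgd = vlapply(meta_rows, `[[`, "wgd"),
    clones = lapply(meta_rows, `[[`, "clones"),
    drivers = drivers_tbl)

  gene_sets <- list(T_effector_signature = teff_genes,
                    Myeloid_inflammation_signature = myeloid_genes,
                    Trans_target_block = trans_targets)

  truth <- list(config = config, gene_arms = gene_arms, baseline = baseline,
                stroma = stroma, trans_targets = trans_targets,
                teff_genes = teff_genes, myeloid_genes = myeloid_genes,
                low_genes = low_genes,
                suppressive = stats::setNames(
                  vlapply(meta_rows, `[[`, "suppressive"), names(meta_rows)),
                patients = truth_pat)

  structure(list(expression = expression, tpm_like = tpm_like,
                 metadata = metadata, trees = trees,
                 tme_fractions = tme_fractions, repertoires = reps,
                 gene_annotation = annotation, cn = cn,
                 gene_sets = gene_sets, truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Serializes every component in the package's plain-text interchange
#' formats plus a `truth.json` with the generative parameters (matrix-sized
#' truth such as per-clone means stays in the in-memory object).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_expression(cohort$tpm_like, file.path(dir, "tpm.tsv"))
  write_sample_meta(cohort$metadata, file.path(dir, "metadata.tsv"))
  for (pat in names(cohort$trees)) {
    write_clone_tree(cohort$trees[[pat]],
                     file.path(dir, "trees", paste0(pat, ".json")))
  }
  utils::write.table(
    data.frame(sample_id = rownames(cohort$tme_fractions),
               cohort$tme_fractions, check.names = FALSE),
    file.path(dir, "tme_fractions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_repertoires(cohort$repertoires, file.path(dir, "repertoires.tsv"))
  write_gene_annotation(cohort$gene_annotation,
                        file.path(dir, "gene_annotation.tsv"))
  write_expression(cohort$cn, file.path(dir, "cn.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  truth$patients <- lapply(truth$patients, function(p)
    p[c("seeding_clone", "has_9p")])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
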