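test_that("expression TSV and triplet formats round-trip bit-identically", {
  m <- expression_matrix(matrix(c(1.5, 0, -2.25, 3, 4.125, 0), nrow = 3),
                         c("gA", "gB", "gC"), c("s1", "s2"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, tsv)
  back <- read_expression(tsv)
  expect_identical(dim(back), c(3L, 2L))
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(back, m)

  trip <- withr::local_tempfile()
  write_expression(m, trip, format = "mtx-triplet")
  back2 <- read_expression(trip, format = "mtx-triplet")
  expect_equal(back2, m)

  # writer output itself is byte-stable
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))
})

test_that("expression reader rejects malformed input with located errors", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), tsv)
  expect_error(read_expression(tsv), "gA", class = "clonexpr_format_error")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops"), tsv)
  err <- tryCatch(read_expression(tsv), error = identity)
  expect_s3_class(err, "clonexpr_parse_error")
  expect_match(conditionMessage(err), "gA")
  expect_match(conditionMessage(err), "s2")

  expect_error(expression_matrix(matrix(c(1, NA), 1), "g", c("a", "b")),
               class = "clonexpr_format_error")
})

test_that("filter_genes_by_tpm applies inclusive thresholds and matches a brute-force count", {
  # gene at exactly 1 TPM in exactly 20% of 10 samples is retained
  tpm <- expression_matrix(
    rbind(edge = c(1, 1, rep(0, 8)), zero = rep(0, 10),
          high = rep(5, 10)),
    c("edge", "zero", "high"), sprintf("s%02d", 1:10))
  kept <- filter_genes_by_tpm(tpm, 1, 0.20)
  expect_true("edge" %in% kept)
  expect_false("zero" %in% kept)
  expect_identical(kept, c("edge", "high"))  # input order preserved

  set.seed(7)
  m <- expression_matrix(matrix(rexp(50 * 20), 50),
                         sprintf("g%02d", 1:50), sprintf("s%02d", 1:20))
  got <- filter_genes_by_tpm(m, 0.5, 0.3)
  keep <- character(0)
  for (g in rownames(m)) {          # independent double loop
    n_ok <- 0
    for (s in colnames(m)) if (m[g, s] >= 0.5) n_ok <- n_ok + 1
    if (n_ok / 20 >= 0.3) keep <- c(keep, g)
  }
  expect_identical(got, keep)

  # invariant to sample column order
  perm <- m[, sample(colnames(m))]
  expect_identical(filter_genes_by_tpm(perm, 0.5, 0.3), got)

  expect_error(filter_genes_by_tpm(m, 1, 1.2),
               class = "clonexpr_config_error")
})

test_that("clone trees parse from newick, round-trip via edge-json, and reject bad structure", {
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((B,C)A)MRCA;", nwk)
  tr <- read_clone_tree(nwk, "newick", patient_id = "P1")
  expect_setequal(tr$nodes, c("MRCA", "A", "B", "C"))
  expect_identical(tr$root, "MRCA")
  expect_identical(nrow(tr$edges), 3L)

  # ape as independent oracle for a proper multi-tip newick
  skip_if_not_installed("ape")
  writeLines("((A,B)N1,(C,D)N2)R;", nwk)
  ours <- read_clone_tree(nwk, "newick")
  ap <- ape::read.tree(nwk)
  labs <- c(ap$tip.label, ap$node.label)
  ape_edges <- data.frame(parent = labs[ap$edge[, 1]],
                          child = labs[ap$edge[, 2]])
  key <- function(e) sort(paste(e$parent, e$child))
  expect_identical(key(ours$edges), key(ape_edges))

  json <- withr::local_tempfile(fileext = ".json")
  tr$genotypes <- list(MRCA = list(driver_mutations = "VHL",
                                   cn = c(g1 = 2L),
                                   arm_events = c(`9p` = "loss")))
  write_clone_tree(tr, json)
  back <- read_clone_tree(json, "edge-json")
  expect_identical(back$nodes, tr$nodes)
  expect_identical(back$edges, tr$edges)
  expect_identical(back$root, tr$root)
  expect_identical(back$genotypes$MRCA$arm_events, c(`9p` = "loss"))

  expect_error(
    clone_tree("P1", data.frame(parent = "A", child = "B"), nodes = "Z"),
    class = "clonexpr_structure_error")  # two parentless nodes
  expect_error(
    clone_tree("P1", data.frame(parent = c("A", "B"), child = c("B", "A"))),
    class = "clonexpr_structure_error")  # cycle
})

test_that("single-clone newick parses to a one-node tree", {
  nwk <- withr::local_tempfile()
  writeLines("MRCA;", nwk)
  tr <- read_clone_tree(nwk, "newick")
  expect_identical(tr$nodes, "MRCA")
  expect_identical(tr$root, "MRCA")
})

test_that("sample metadata round-trips and enforces invariants", {
  meta <- sample_meta(c("s1", "s2", "s3"), c("P1", "P1", "P1"),
                      c("primary", "primary", "normal"),
                      purity = c(0.8, 0.6, 0), wGII = c(0.2, 0.3, 0),
                      wgd = c(FALSE, TRUE, FALSE),
                      clones = list(c("A", "B"), "C", character(0)),
                      drivers = list(`9p_loss` = c(TRUE, FALSE, FALSE),
                                     SETD2 = c(FALSE, TRUE, FALSE)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_meta(meta, path)
  back <- read_sample_meta(path)
  expect_identical(back$sample_id, meta$sample_id)
  expect_identical(back$clones, meta$clones)
  expect_identical(driver_status(back, "9p_loss"),
                   driver_status(meta, "9p_loss"))

  expect_warning(
    sample_meta("s1", "P1", "primary", NA, 0.1, FALSE),
    class = "clonexpr_warning")
  expect_error(
    sample_meta("s1", "P1", "normal", 0, 0, FALSE, clones = list("A")),
    class = "clonexpr_format_error")
})

test_that("GMT and repertoire tables round-trip", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g9"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_identical(read_gmt(gmt), sets)

  reps <- list(rand_repertoire("s1", 1), rand_repertoire("s2", 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_repertoires(reps, tsv)
  back <- read_repertoires(tsv)
  expect_length(back, 2L)
  expect_equal(back[["s1.TCR"]]$counts, reps[[1]]$counts)

  expect_error(repertoire("s", "TCR", setNames(c(1, 0), c("a", "b"))),
               class = "clonexpr_format_error")
})

test_that("analysis_config holds the documented defaults and validates ranges", {
  cfg <- analysis_config()
  expect_identical(cfg$top_k_variable_genes, 500L)
  expect_identical(cfg$bootstrap_iterations, 1000L)
  expect_equal(cfg$ssgsea_exponent, 0.25)
  expect_equal(c(cfg$min_tpm, cfg$min_fraction), c(1, 0.20))
  expect_equal(cfg$herv_expressed_fraction, 0.70)
  expect_identical(cfg$fdr_method, "benjamini-hochberg")
  expect_identical(cfg$per_patient_aggregator, "median")
  expect_error(analysis_config(min_fraction = 2),
               class = "clonexpr_config_error")
})
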