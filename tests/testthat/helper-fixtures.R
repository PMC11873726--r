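# Shared fixture builders; all data is generated in code.

toy_tree <- function(patient_id = "P1") {
  clone_tree(patient_id,
             data.frame(parent = c("MRCA", "A", "A"),
                        child = c("A", "B", "C")))
}

chain_tree <- function(n, patient_id = "P1") {
  labels <- c("MRCA", if (n > 1) paste0("C", seq(2, n)))
  clone_tree(patient_id,
             data.frame(parent = labels[-n], child = labels[-1L]))
}

rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n_genes * n_samples), n_genes),
                    sprintf("g%03d", seq_len(n_genes)),
                    sprintf("s%02d", seq_len(n_samples)))
}

rand_repertoire <- function(sample_id, seed, pool = 40, keep = 15) {
  set.seed(seed)
  keys <- sprintf("TRB|V1|J1|CT%03d", sample(pool, keep))
  repertoire(sample_id, "TCR", setNames(rgeom(keep, 0.2) + 1, keys))
}

# Independent BFS shortest-path oracle over an undirected edge list.
oracle_tree_distance <- function(edges, from, to) {
  nodes <- unique(c(edges$parent, edges$child))
  adj <- setNames(lapply(nodes, function(n)
    c(edges$child[edges$parent == n], edges$parent[edges$child == n])),
    nodes)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  unname(dist[to])
}
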