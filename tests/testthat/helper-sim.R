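# Shared fixtures: downsized simulation configs and hand-built paired
# datasets, all generated in code at test time.

# Smaller cohort than the default config so test runs stay fast; structure
# (markers, blocks, planted classes) unchanged unless overridden.
small_sim <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_genes_per_region = 300, n_ctl = 150, n_ad = 150,
                   n_excluded = 0,
                   planted_edges = default_planted_edges(20, 0.7, n_null = 10),
                   planted_blocks = default_planted_blocks(1, 12,
                                                           start_index = 71),
                   n_de_genes = 10, seed = seed)
  for (nm in names(args)) defaults[nm] <- list(args[[nm]])
  do.call(simulation_config, defaults)
}

# Paired dataset straight from two gene x individual matrices and a named
# group vector (individual -> "CTL"/"AD").
make_paired <- function(m1, m2, groups, regions = c("BR1", "BR2")) {
  ind <- names(groups)
  stopifnot(identical(colnames(m1), ind), identical(colnames(m2), ind))
  build <- function(m, r) {
    colnames(m) <- paste(ind, r, sep = "_")
    region_expression(r, m, data.frame(
      sample_id = colnames(m), individual_id = ind, region = r,
      CERAD = ifelse(groups == "CTL", 1L, 2L), stringsAsFactors = FALSE))
  }
  structure(list(br1 = build(m1, regions[1L]), br2 = build(m2, regions[2L]),
                 group_labels = groups), class = "paired_dataset")
}

# Adjusted Rand index from the contingency table (independent of any
# clustering library; used to score partition recovery).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  expected <- s_a * s_b / choose(n, 2)
  maximum <- (s_a + s_b) / 2
  if (maximum == expected) return(1)
  (s_ij - expected) / (maximum - expected)
}

# Apply estimate_spvs + correct_cell_types to both sides of a paired dataset.
ctc_paired <- function(paired, marker_map, alpha = 0.05) {
  g <- paired$group_labels
  paired$br1 <- correct_cell_types(
    paired$br1, estimate_spvs(paired$br1, marker_map, g, alpha))
  paired$br2 <- correct_cell_types(
    paired$br2, estimate_spvs(paired$br2, marker_map, g, alpha))
  paired
}

edge_key <- function(geneA, geneB) paste(geneA, geneB, sep = "||")

# Brute-force hypergeometric upper tail by enumerating all overlaps.
brute_tail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Planted bipartite stochastic block model over two region sides.
make_block_graph <- function(seed, n_blocks = 4, size = 30, p_in = 0.3,
                             p_out = 0.01) {
  set.seed(seed)
  edges <- list()
  labels <- c()
  for (b in seq_len(n_blocks)) {
    ga <- sprintf("blk%d_a%02d@BR1", b, seq_len(size))
    gb <- sprintf("blk%d_b%02d@BR2", b, seq_len(size))
    labels[ga] <- b
    labels[gb] <- b
  }
  all_a <- names(labels)[endsWith(names(labels), "@BR1")]
  all_b <- names(labels)[endsWith(names(labels), "@BR2")]
  for (a in all_a) for (bb in all_b) {
    p <- if (labels[[a]] == labels[[bb]]) p_in else p_out
    if (runif(1) < p) edges[[length(edges) + 1L]] <- c(a, bb)
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  list(graph = g, labels = labels[igraph::V(g)$name])
}

# Downsized pipeline configuration for end-to-end runs; the planted block is
# strong enough that the module-size filter and ORA stages see real modules.
small_pipe <- function(dir, seed = 1, ...) {
  sim <- small_sim(n_ctl = 80, n_ad = 80, n_excluded = 4,
                   planted_blocks = default_planted_blocks(
                     1, 15, rho_ad = 0.7, start_index = 71))
  pipeline_config(dir, sim = sim, n_perm = 3, seed = seed, ...)
}
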