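# Bipartite module detection on the DC network: Louvain modularity
# maximization (standard Newman modularity on the two-region graph), a
# minimum-size filter, and structure-preserving random modules for the
# enrichment null.

#' Build the bipartite graph of a DC network
#'
#' Nodes are `gene@region` labels, edges the DC pairs (crossing regions by
#' construction). Optionally carries `|z|` edge weights.
#'
#' @param network A `dc_network`.
#' @param weighted Attach `|z|` weights (default unweighted, matching the
#'   usual usage of a general-graph Louvain routine).
#' @return An [igraph::graph] with vertex attributes `gene` and `region`.
#' @export
dc_bipartite_graph <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "dc_network"))
  edges <- network$edges
  r <- network$region_ids
  from <- paste0(edges$geneA, "@", r[1L])
  to <- paste0(edges$geneB, "@", r[2L])
  nodes <- data.frame(
    name = c(unique(from), unique(to)),
    gene = c(unique(edges$geneA), unique(edges$geneB)),
    region = rep(r, c(length(unique(from)), length(unique(to)))),
    stringsAsFactors = FALSE)
  el <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (weighted) el$weight <- abs(edges$z)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
}

# Newman modularity of a partition, recomputed from scratch:
# Q = sum_c [ e_c / m - (d_c / 2m)^2 ] with e_c the within-community edge
# count and d_c the community degree sum. Used both to report Q and as the
# recompute-check against the clustering routine's own value.
newman_modularity <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0L) return(NA_real_)
  el <- igraph::as_edgelist(graph, names = FALSE)
  same <- membership[el[, 1L]] == membership[el[, 2L]]
  e_c <- tapply(rep(1L, nrow(el))[same], membership[el[same, 1L]], sum)
  deg <- igraph::degree(graph)
  d_c <- tapply(deg, membership, sum)
  e_c_full <- setNames(rep(0, length(d_c)), names(d_c))
  e_c_full[names(e_c)] <- e_c
  sum(e_c_full / m - (d_c / (2 * m))^2)
}

#' Partition a (bipartite) DC graph with the Louvain method
#'
#' Runs the Louvain heuristic under a fixed seed and returns the partition
#' with its Newman modularity recomputed from the partition itself. Module
#' ids are deterministic given the seed: relabeled by descending module
#' size, ties broken by the smallest member node name. Isolated/singleton
#' communities are allowed.
#'
#' @param graph An undirected [igraph::graph] (node attribute `region`
#'   expected for two-sided gene-set extraction; absent attributes give
#'   one-sided sets).
#' @param seed Seed for the heuristic's node-order randomness.
#' @return A `module_partition`: `membership` (named node -> module id),
#'   `modularity`, `module_sizes`, and `modules` (per module, gene ids split
#'   by region side).
#' @export
louvain_partition <- function(graph, seed = 1) {
  if (igraph::vcount(graph) == 0L) {
    stop("cannot partition an empty graph", call. = FALSE)
  }
  cl <- with_seed(seed, igraph::cluster_louvain(graph))
  memb <- igraph::membership(cl)
  names(memb) <- igraph::V(graph)$name
  # Deterministic relabeling: by descending size, ties by smallest node name.
  first_node <- tapply(names(memb), memb, min)
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), first_node)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  memb <- setNames(as.integer(relabel[as.character(memb)]), names(memb))
  q <- newman_modularity(graph, memb)

  region <- igraph::vertex_attr(graph, "region") %||%
    rep("all", igraph::vcount(graph))
  gene <- igraph::vertex_attr(graph, "gene") %||% igraph::V(graph)$name
  node_tab <- data.frame(node = igraph::V(graph)$name, gene = gene,
                         region = region,
                         module = unname(memb[igraph::V(graph)$name]),
                         stringsAsFactors = FALSE)
  modules <- lapply(split(node_tab, node_tab$module), function(d) {
    lapply(split(d$gene, d$region), sort)
  })
  structure(list(membership = memb, modularity = q,
                 module_sizes = vapply(modules, function(m) sum(lengths(m)),
                                       integer(1L)),
                 modules = modules, nodes = node_tab),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d nodes, Q = %.4f\n",
              length(x$modules), length(x$membership), x$modularity))
  invisible(x)
}

#' Flag modules passing the minimum-size filter
#'
#' Downstream enrichment only consumes modules with at least `min_genes`
#' genes in total (both sides combined); nothing is re-clustered.
#'
#' @param partition A `module_partition`.
#' @param min_genes Minimum total genes per module.
#' @return The partition with a logical `size_pass` vector per module.
#' @export
filter_modules <- function(partition, min_genes = 20) {
  stopifnot(inherits(partition, "module_partition"))
  partition$size_pass <- partition$module_sizes >= min_genes
  partition$min_genes <- min_genes
  if (!any(partition$size_pass)) {
    warning(sprintf("no module reaches %d genes", min_genes), call. = FALSE)
  }
  partition
}

#' Structure-preserving random modules
#'
#' For the enrichment null: per permutation and per region side, the module
#' id labels of the real partition are re-assigned to genes sampled from the
#' side's background gene list, so the multiset of module sizes per side is
#' exactly preserved while the gene content is random.
#'
#' @param background_genes_per_region Named list, region -> background gene
#'   ids (typically the correlated gene list of that region).
#' @param partition A `module_partition` defining the structure.
#' @param n_perm Number of permutations.
#' @param seed Seed; the whole permutation set is reproducible.
#' @return List of `n_perm` data frames (`gene`, `region`, `module`).
#' @export
random_modules <- function(background_genes_per_region, partition,
                           n_perm = 10, seed = 1) {
  stopifnot(inherits(partition, "module_partition"))
  nodes <- partition$nodes
  by_region <- split(nodes$module, nodes$region)
  for (r in names(by_region)) {
    bg <- background_genes_per_region[[r]]
    if (is.null(bg) || length(bg) < length(by_region[[r]])) {
      stop(sprintf("background for region %s smaller than the %d module slots",
                   r, length(by_region[[r]])), call. = FALSE)
    }
  }
  with_seed(seed, lapply(seq_len(n_perm), function(i) {
    do.call(rbind, lapply(names(by_region), function(r) {
      ids <- by_region[[r]]
      data.frame(gene = sample(background_genes_per_region[[r]], length(ids)),
                 region = r, module = ids, stringsAsFactors = FALSE)
    }))
  }))
}
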