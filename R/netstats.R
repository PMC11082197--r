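# Network-level summaries of a DC network: per-side degrees and hub
# candidates, Jaccard overlap between edge/gene sets, pooled region
# exclusivity across comparisons, and the within-region projection test of
# inter-region DC pairs.

#' Per-node degree table of a DC network
#'
#' Degree is the number of distinct DC partners of a gene on its side of the
#' bipartite network; the sum of degrees on one side equals the edge count.
#' Genes are ranked by descending degree and the top `top_k` per side are
#' flagged as hub candidates. An optional biotype map supports restricting
#' to protein-coding genes before ranking (the usual convention for hub
#' reporting, since high-degree non-coding genes are hard to interpret).
#'
#' @param network A `dc_network`.
#' @param biotype_map Optional named character vector, gene id -> biotype.
#' @param protein_coding_only Drop genes not annotated `protein_coding`
#'   (genes without annotation are excluded with a warning).
#' @param top_k Hub candidates flagged per side.
#' @return Data frame with `gene`, `region`, `degree`, `is_hub_candidate`,
#'   and `biotype` when a map is supplied.
#' @export
node_degrees <- function(network, biotype_map = NULL,
                         protein_coding_only = FALSE, top_k = 20) {
  stopifnot(inherits(network, "dc_network"))
  edges <- network$edges
  one_side <- function(genes, region) {
    if (length(genes) == 0L) {
      return(data.frame(gene = character(), region = character(),
                        degree = integer(), stringsAsFactors = FALSE))
    }
    tab <- table(genes)
    data.frame(gene = names(tab), region = region,
               degree = as.integer(tab), stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(edges$geneA, network$region_ids[1L]),
               one_side(edges$geneB, network$region_ids[2L]))
  if (!is.null(biotype_map)) {
    out$biotype <- unname(biotype_map[out$gene])
    if (protein_coding_only) {
      unknown <- is.na(out$biotype)
      if (any(unknown)) {
        warning(sprintf("%d gene(s) without biotype annotation excluded",
                        sum(unknown)), call. = FALSE)
      }
      out <- out[!unknown & out$biotype == "protein_coding", , drop = FALSE]
    }
  }
  out <- out[order(out$region, -out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out$is_hub_candidate <- stats::ave(
    -out$degree, out$region, FUN = function(d) rank(d, ties.method = "min")
  ) <= top_k
  out
}

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 by convention.
#'
#' @param setA,setB Vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(setA, setB) {
  u <- length(union(setA, setB))
  if (u == 0L) return(0)
  length(intersect(setA, setB)) / u
}

#' Region-exclusivity of DC genes across comparisons
#'
#' Pools the DC genes that one focal region uses across all its
#' inter-region comparisons and reports what fraction of the pooled set
#' recurs in at least two comparisons; the complement is the
#' region-exclusive fraction.
#'
#' @param networks List of >= 2 `dc_network`s, each involving the focal
#'   region on one side.
#' @param focal_region The region whose gene usage is pooled.
#' @return List with `focal_region`, `pooled_genes`, `shared_genes`,
#'   `shared_fraction`, and a logical `membership` matrix
#'   (pooled gene x comparison).
#' @export
region_exclusivity <- function(networks, focal_region) {
  if (length(networks) < 2L) {
    stop("region exclusivity needs >= 2 comparisons", call. = FALSE)
  }
  gene_sets <- lapply(networks, function(nw) {
    if (!focal_region %in% nw$region_ids) {
      stop(sprintf("comparison %s-%s does not involve region %s",
                   nw$region_ids[1L], nw$region_ids[2L], focal_region),
           call. = FALSE)
    }
    nw$dc_genes[[focal_region]]
  })
  names(gene_sets) <- vapply(networks, function(nw) {
    paste(nw$region_ids, collapse = "-")
  }, character(1L))
  pooled <- sort(unique(unlist(gene_sets)))
  membership <- vapply(gene_sets, function(s) pooled %in% s,
                       logical(length(pooled)))
  membership <- matrix(membership, nrow = length(pooled),
                       dimnames = list(pooled, names(gene_sets)))
  shared <- pooled[rowSums(membership) >= 2L]
  list(focal_region = focal_region, pooled_genes = pooled,
       shared_genes = shared,
       shared_fraction =
         if (length(pooled) > 0) length(shared) / length(pooled) else 0,
       membership = membership)
}

#' Project inter-region DC pairs into one region and re-test
#'
#' For each inter-region DC edge involving the focal region, the
#' corresponding within-region gene pair is tested with the same machinery
#' (per-group Spearman + BH + |rho| gate on the projected list, Fisher z on
#' the gated union, BH within the projected universe). Testing only the
#' projected pairs keeps the multiple-testing family small, mirroring how
#' the within-region analysis is restricted to pairs already implicated
#' between regions.
#'
#' @param expr `region_expression` of the focal region (CTL and AD samples).
#' @param groups Group labels per sample/column of `expr`.
#' @param network The inter-region `dc_network` supplying the pairs.
#' @param focal_region Region id; defaults to the network's first side.
#' @param fdr_corr,rho_min,fdr_dc Same gates as the inter-region analysis.
#' @return A `dc_network` over the projected within-region pairs, with an
#'   attribute `n_skipped` counting pairs whose partner gene is not measured
#'   in the focal region (self-pairs are also skipped).
#' @export
intra_dc_projection <- function(expr, groups, network,
                                focal_region = network$region_ids[1L],
                                fdr_corr = 0.01, rho_min = 0.4,
                                fdr_dc = 0.01) {
  stopifnot(inherits(network, "dc_network"))
  m <- if (inherits(expr, "region_expression")) expr$matrix else expr
  groups <- as.character(groups)
  edges <- network$edges
  if (focal_region == network$region_ids[1L]) {
    pairs <- data.frame(g1 = edges$geneA, g2 = edges$geneB)
  } else if (focal_region == network$region_ids[2L]) {
    pairs <- data.frame(g1 = edges$geneB, g2 = edges$geneA)
  } else {
    stop("focal_region is not part of the network", call. = FALSE)
  }
  pairs <- unique(pairs)
  measured <- pairs$g1 %in% rownames(m) & pairs$g2 %in% rownames(m)
  self <- pairs$g1 == pairs$g2
  n_skipped <- sum(!measured | self)
  pairs <- pairs[measured & !self, , drop = FALSE]
  regions <- c(focal_region, focal_region)
  if (nrow(pairs) == 0L) {
    universe <- data.frame(geneA = character(), geneB = character(),
                           rho_ctl = numeric(), rho_ad = numeric(),
                           p_ctl = numeric(), p_ad = numeric(),
                           q_ctl = numeric(), q_ad = numeric(),
                           n_ctl = integer(), n_ad = integer(),
                           correlated_ctl = logical(),
                           correlated_ad = logical())
    attr(universe, "region_ids") <- regions
    out <- call_dc_edges(universe, fdr_dc)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  n_ctl <- sum(groups == "CTL")
  n_ad <- sum(groups == "AD")
  rho_for <- function(g) {
    sub <- m[, groups == g, drop = FALSE]
    vapply(seq_len(nrow(pairs)), function(i) {
      cor(rank(sub[pairs$g1[i], ]), rank(sub[pairs$g2[i], ]))
    }, numeric(1L))
  }
  rho_ctl <- rho_for("CTL")
  rho_ad <- rho_for("AD")
  p_ctl <- spearman_pvalue(rho_ctl, n_ctl)
  p_ad <- spearman_pvalue(rho_ad, n_ad)
  q_ctl <- bh_adjust(p_ctl)
  q_ad <- bh_adjust(p_ad)
  corr_ctl <- q_ctl <= fdr_corr & abs(rho_ctl) >= rho_min
  corr_ad <- q_ad <= fdr_corr & abs(rho_ad) >= rho_min
  keep <- which(corr_ctl | corr_ad)
  universe <- data.frame(
    geneA = pairs$g1[keep], geneB = pairs$g2[keep],
    rho_ctl = rho_ctl[keep], rho_ad = rho_ad[keep],
    p_ctl = p_ctl[keep], p_ad = p_ad[keep],
    q_ctl = q_ctl[keep], q_ad = q_ad[keep],
    n_ctl = rep(n_ctl, length(keep)), n_ad = rep(n_ad, length(keep)),
    correlated_ctl = corr_ctl[keep], correlated_ad = corr_ad[keep],
    stringsAsFactors = FALSE)
  attr(universe, "region_ids") <- regions
  attr(universe, "n_pairs_tested") <- nrow(pairs)
  out <- call_dc_edges(universe, fdr_dc)
  attr(out, "n_skipped") <- n_skipped
  out
}
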