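# Over-representation analysis of module gene sets: one-sided (upper-tail)
# hypergeometric tests against a background of correlated genes, BH FDR per
# collection, and an empirical FDR from structure-preserving random modules.

#' Hypergeometric over-representation test
#'
#' Tests whether a query gene set overlaps a functional gene set more than
#' expected under sampling without replacement from the background:
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)` with background size N,
#' set size K (after intersecting with the background), query size n and
#' overlap k.
#'
#' @param query Query gene ids; must be a subset of `background` (a
#'   violation signals a background-construction bug and is an error).
#' @param gene_set Functional set gene ids.
#' @param background Background gene ids.
#' @return One-row data frame with `N`, `K`, `n`, `k`, `p` and the
#'   overlapping gene ids collapsed into `overlap_genes`.
#' @export
hypergeom_ora <- function(query, gene_set, background) {
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background)) {
    stop("query genes outside the background: check background construction",
         call. = FALSE)
  }
  set_bg <- intersect(unique(gene_set), background)
  hit <- intersect(query, set_bg)
  N <- length(background)
  K <- length(set_bg)
  n <- length(query)
  k <- length(hit)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(N = N, K = K, n = n, k = k, p = p,
             overlap_genes = paste(sort(hit), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' ORA of all passing module sides against a gene-set collection
#'
#' Each size-passing module contributes two query sets, one per region side;
#' the background is the region's correlated gene list. BH correction is
#' applied across all (module side x gene set) tests within the collection.
#'
#' @param partition A `module_partition` passed through [filter_modules()]
#'   (without the filter, all modules are used).
#' @param collection Named list, set name -> gene ids.
#' @param background_genes_per_region Named list, region -> background genes.
#' @param fdr BH FDR threshold for the `significant` flag.
#' @return Data frame with `module`, `region`, `set`, the hypergeometric
#'   fields, `q` and `significant`.
#' @export
run_module_ora <- function(partition, collection,
                           background_genes_per_region, fdr = 0.05) {
  stopifnot(inherits(partition, "module_partition"))
  pass <- partition$size_pass %||%
    setNames(rep(TRUE, length(partition$modules)), names(partition$modules))
  rows <- list()
  for (mod in names(partition$modules)[pass]) {
    for (r in names(partition$modules[[mod]])) {
      query <- partition$modules[[mod]][[r]]
      bg <- background_genes_per_region[[r]]
      for (s in names(collection)) {
        res <- hypergeom_ora(query, collection[[s]], bg)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(module = mod, region = r, set = s,
                           stringsAsFactors = FALSE), res)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(module = character(), region = character(),
                      set = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      overlap_genes = character(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  out
}

# ORA of random-module tables (as produced by random_modules()): same test
# and BH family as run_module_ora, one result table per permutation.
random_module_ora <- function(random_partitions, collection,
                              background_genes_per_region, fdr = 0.05,
                              min_genes = 0) {
  lapply(random_partitions, function(tab) {
    rows <- list()
    for (mod in unique(tab$module)) {
      sub <- tab[tab$module == mod, , drop = FALSE]
      if (nrow(sub) < min_genes) next
      for (r in unique(sub$region)) {
        query <- sub$gene[sub$region == r]
        for (s in names(collection)) {
          res <- hypergeom_ora(query, collection[[s]],
                               background_genes_per_region[[r]])
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(module = as.character(mod), region = r, set = s,
                             stringsAsFactors = FALSE), res)
        }
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    out$q <- bh_adjust(out$p)
    out$significant <- out$q <= fdr
    out
  })
}

#' Empirical FDR of module enrichments from a permutation null
#'
#' The ratio of enrichment calls in structure-preserving random modules to
#' calls in the real modules at the same threshold, averaged over
#' permutations: `mean_perm(#significant_random) / max(1, #significant_real)`.
#'
#' @param real_results ORA table of the real modules ([run_module_ora()]).
#' @param random_results_per_perm List of ORA tables, one per permutation.
#' @param threshold q-value threshold defining a call.
#' @return List with `empirical_fdr`, `n_real` and per-permutation random
#'   call counts.
#' @export
empirical_fdr <- function(real_results, random_results_per_perm,
                          threshold = 0.05) {
  n_real <- sum(real_results$q <= threshold, na.rm = TRUE)
  n_rand <- vapply(random_results_per_perm, function(tab) {
    if (is.null(tab)) 0L else sum(tab$q <= threshold, na.rm = TRUE)
  }, integer(1L))
  list(empirical_fdr = mean(n_rand) / max(1L, n_real),
       n_real = n_real, n_random_per_perm = n_rand)
}
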