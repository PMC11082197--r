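# The core differential-correlation machinery: per-group cross-region
# Spearman correlations, the correlated-pair universe (BH FDR + |rho| gate,
# union over groups), the Fisher r-to-z difference test, edge classification
# into gained/lost categories, the dysregulation percentage, Wilcoxon DE and
# DE-driven-edge accounting.

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are taken (ties allowed) and the Pearson correlation of the
#' ranked vectors is computed; the two-sided p-value uses the large-sample
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom (`|rho| = 1` gives p = 0).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return Named vector `c(rho, p)`; both `NA` (with a warning) if either
#'   input has zero variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) {
    stop("x and y must have equal length >= 4", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance input: Spearman correlation undefined",
            call. = FALSE)
    return(c(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rank(x), rank(y))
  c(rho = rho, p = spearman_pvalue(rho, length(x)))
}

spearman_pvalue <- function(rho, n) {
  p <- ifelse(abs(rho) >= 1, 0,
              2 * pt(abs(rho) * sqrt((n - 2) / (1 - rho^2)), df = n - 2,
                     lower.tail = FALSE))
  pmin(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement, order-preserving with respect to
#' the input index. Thin validating wrapper around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return The BH-adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

# Blocked cross-region correlation of pre-ranked matrices; returns the full
# nA x nB rho matrix. Per-block results are mathematically identical for any
# block size (each block is an independent cor() call), which is the
# block-independence contract; blocking keeps the working matrices at
# O(block^2).
blocked_cross_cor <- function(ra, rb, block_size) {
  out <- matrix(NA_real_, nrow(ra), nrow(rb),
                dimnames = list(rownames(ra), rownames(rb)))
  ia <- split(seq_len(nrow(ra)), ceiling(seq_len(nrow(ra)) / block_size))
  ib <- split(seq_len(nrow(rb)), ceiling(seq_len(nrow(rb)) / block_size))
  for (a in ia) for (b in ib) {
    out[a, b] <- cor(t(ra[a, , drop = FALSE]), t(rb[b, , drop = FALSE]))
  }
  out
}

#' Enumerate the correlated-pair universe of a region pair
#'
#' All cross-region gene pairs are correlated (Spearman) separately in the
#' CTL and AD groups; BH correction is applied within each (group,
#' region-pair) family over the full pair grid; a pair is *correlated* in a
#' group when both `q <= fdr_corr` and `|rho| >= rho_min`. The universe --
#' the only pairs subsequently tested for differential correlation -- is the
#' union of pairs correlated in either group. Genes with zero variance in
#' either group are excluded beforehand (with a message).
#'
#' @param paired A `paired_dataset`.
#' @param fdr_corr BH FDR gate on the per-group correlation p-values.
#' @param rho_min Absolute correlation gate.
#' @param block_size Genes per block in the streamed correlation; results do
#'   not depend on it.
#' @return Data frame of `CorrelationRecord`s (one row per universe pair)
#'   with attributes `n_pairs_tested` (full grid size) and `dropped_genes`.
#' @export
correlated_pair_universe <- function(paired, fdr_corr = 0.01, rho_min = 0.4,
                                     block_size = 200) {
  stopifnot(inherits(paired, "paired_dataset"))
  groups <- paired$group_labels
  n_ctl <- sum(groups == "CTL")
  n_ad <- sum(groups == "AD")
  if (min(n_ctl, n_ad) < 4L) {
    stop("each group needs >= 4 paired individuals", call. = FALSE)
  }
  ma <- paired$br1$matrix
  mb <- paired$br2$matrix

  ok_gene <- function(m) {
    apply(m[, groups == "CTL", drop = FALSE], 1L, sd) > 0 &
      apply(m[, groups == "AD", drop = FALSE], 1L, sd) > 0
  }
  oa <- ok_gene(ma)
  ob <- ok_gene(mb)
  if (any(!oa) || any(!ob)) {
    message(sprintf("excluding %d zero-variance gene(s) (%s: %d, %s: %d)",
                    sum(!oa) + sum(!ob), paired$br1$region_id, sum(!oa),
                    paired$br2$region_id, sum(!ob)))
  }
  ma <- ma[oa, , drop = FALSE]
  mb <- mb[ob, , drop = FALSE]

  rho_of <- function(g) {
    ra <- rank_rows(ma[, groups == g, drop = FALSE])
    rb <- rank_rows(mb[, groups == g, drop = FALSE])
    blocked_cross_cor(ra, rb, block_size)
  }
  rho_ctl <- rho_of("CTL")
  rho_ad <- rho_of("AD")
  p_ctl <- spearman_pvalue(rho_ctl, n_ctl)
  p_ad <- spearman_pvalue(rho_ad, n_ad)
  q_ctl <- array(bh_adjust(as.vector(p_ctl)), dim = dim(p_ctl))
  q_ad <- array(bh_adjust(as.vector(p_ad)), dim = dim(p_ad))

  corr_ctl <- q_ctl <= fdr_corr & abs(rho_ctl) >= rho_min
  corr_ad <- q_ad <= fdr_corr & abs(rho_ad) >= rho_min
  in_univ <- which(corr_ctl | corr_ad, arr.ind = TRUE)
  if (nrow(in_univ) == 0L) {
    warning("empty correlated-pair universe", call. = FALSE)
  }
  universe <- data.frame(
    geneA = rownames(ma)[in_univ[, 1L]],
    geneB = rownames(mb)[in_univ[, 2L]],
    rho_ctl = rho_ctl[in_univ], rho_ad = rho_ad[in_univ],
    p_ctl = p_ctl[in_univ], p_ad = p_ad[in_univ],
    q_ctl = q_ctl[in_univ], q_ad = q_ad[in_univ],
    n_ctl = rep(n_ctl, nrow(in_univ)), n_ad = rep(n_ad, nrow(in_univ)),
    correlated_ctl = corr_ctl[in_univ], correlated_ad = corr_ad[in_univ],
    stringsAsFactors = FALSE)
  universe <- universe[order(universe$geneA, universe$geneB), , drop = FALSE]
  rownames(universe) <- NULL
  attr(universe, "n_pairs_tested") <- length(rho_ctl)
  attr(universe, "dropped_genes") <- c(sum(!oa), sum(!ob))
  attr(universe, "region_ids") <- c(paired$br1$region_id,
                                    paired$br2$region_id)
  universe
}

#' Fisher r-to-z differential-correlation test
#'
#' Both correlations are Fisher z-transformed (`atanh`) and their difference
#' is divided by the standard error `sqrt(1/(n_ad-3) + 1/(n_ctl-3))`; the
#' orientation is AD minus CTL, so a positive z-score means the pair's
#' correlation increased in the disease group. The p-value is the two-sided
#' standard-normal tail.
#'
#' @param rho_ctl,rho_ad Correlation coefficients (vectorized); values with
#'   `|rho| = 1` are clamped to `1 - 1e-12` with a warning.
#' @param n_ctl,n_ad Group sample sizes, both > 3.
#' @return List with components `z` and `p`.
#' @export
fisher_z_dc_test <- function(rho_ctl, n_ctl, rho_ad, n_ad) {
  if (any(c(n_ctl, n_ad) <= 3)) {
    stop("group sizes must exceed 3 for the Fisher z test", call. = FALSE)
  }
  clamp <- function(r) {
    if (any(abs(r) >= 1)) {
      warning("|rho| = 1 clamped to 1 - 1e-12", call. = FALSE)
      r <- sign(r) * pmin(abs(r), 1 - 1e-12)
    }
    r
  }
  z <- (atanh(clamp(rho_ad)) - atanh(clamp(rho_ctl))) /
    sqrt(1 / (n_ad - 3) + 1 / (n_ctl - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Classify a differential-correlation edge
#'
#' The group with the larger `|rho|` is the dominant side: AD-dominant edges
#' *gained* correlation (`PG` if `rho_ad > 0`, else `NG`), CTL-dominant
#' edges *lost* it (`LC_pos` if `rho_ctl > 0`, else `LC_neg`). Categories
#' map onto three classes: `PG`, `NG`, and `LC` (= `LC_pos` + `LC_neg`).
#'
#' @param rho_ctl,rho_ad Correlations per group (vectorized).
#' @return Character vector of categories.
#' @export
classify_dc_edge <- function(rho_ctl, rho_ad) {
  gained <- abs(rho_ad) > abs(rho_ctl)
  ifelse(gained,
         ifelse(rho_ad > 0, "PG", "NG"),
         ifelse(rho_ctl > 0, "LC_pos", "LC_neg"))
}

dc_category_to_class <- function(category) {
  ifelse(category %in% c("LC_pos", "LC_neg"), "LC", category)
}

#' Call significant DC edges over a correlated-pair universe
#'
#' The Fisher z p-values of the universe pairs are BH-corrected within the
#' region pair's universe only; edges with `q_dc <= fdr_dc` are retained,
#' classified, and summarized by the dysregulation percentage
#' `100 * edges / tested pairs`.
#'
#' @param universe Output of [correlated_pair_universe()].
#' @param fdr_dc BH FDR cutoff on the DC p-values.
#' @return A `dc_network`: `edges` (data frame with z, p, q, category,
#'   class), `tested_pair_count`, `dysregulation_percentage`, per-region DC
#'   gene lists, region ids and the parameters used.
#' @export
call_dc_edges <- function(universe, fdr_dc = 0.01) {
  regions <- attr(universe, "region_ids") %||% c("BR1", "BR2")
  if (nrow(universe) == 0L) {
    edges <- cbind(universe[0, ],
                   data.frame(z = numeric(), p_dc = numeric(),
                              q_dc = numeric(), category = character(),
                              class = character()))
  } else {
    dc <- fisher_z_dc_test(universe$rho_ctl, universe$n_ctl,
                           universe$rho_ad, universe$n_ad)
    edges <- universe
    edges$z <- dc$z
    edges$p_dc <- dc$p
    edges$q_dc <- bh_adjust(dc$p)
    edges <- edges[edges$q_dc <= fdr_dc, , drop = FALSE]
    edges$category <- classify_dc_edge(edges$rho_ctl, edges$rho_ad)
    edges$class <- dc_category_to_class(edges$category)
    rownames(edges) <- NULL
  }
  structure(list(
    edges = edges,
    tested_pair_count = nrow(universe),
    dysregulation_percentage =
      if (nrow(universe) > 0) 100 * nrow(edges) / nrow(universe) else 0,
    dc_genes = setNames(list(sort(unique(edges$geneA)),
                             sort(unique(edges$geneB))), regions),
    region_ids = regions,
    params = list(fdr_dc = fdr_dc)), class = "dc_network")
}

#' @export
print.dc_network <- function(x, ...) {
  cat(sprintf("<dc_network> %s-%s: %d DC edges / %d tested pairs (%.2f%% dysregulation)\n",
              x$region_ids[1L], x$region_ids[2L], nrow(x$edges),
              x$tested_pair_count, x$dysregulation_percentage))
  invisible(x)
}

#' Wilcoxon rank-sum differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of AD vs CTL samples with BH
#' correction, flagged at each requested FDR cutoff. Constant genes get
#' p = 1 and a `constant` flag.
#'
#' @param expr A `region_expression` (or gene x sample matrix).
#' @param groups Group labels (`"CTL"`/`"AD"`) per sample/column.
#' @param fdr_cutoffs FDR levels at which DE flags are reported.
#' @return Data frame with `gene`, `statistic` (W for AD vs CTL), `p`, `q`
#'   and one logical `de_<cutoff>` column per cutoff.
#' @export
wilcoxon_de <- function(expr, groups, fdr_cutoffs = c(0.05, 0.1, 0.2)) {
  m <- if (inherits(expr, "region_expression")) expr$matrix else expr
  groups <- as.character(groups)
  if (sum(groups == "CTL") < 3L || sum(groups == "AD") < 3L) {
    stop("both groups need >= 3 samples for the Wilcoxon test", call. = FALSE)
  }
  res <- t(vapply(rownames(m), function(g) {
    x <- m[g, groups == "AD"]
    y <- m[g, groups == "CTL"]
    if (sd(c(x, y)) == 0) return(c(NA_real_, 1))
    wt <- suppressWarnings(wilcox.test(x, y))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2L)))
  out <- data.frame(gene = rownames(m), statistic = res[, 1L], p = res[, 2L],
                    q = bh_adjust(res[, 2L]),
                    constant = is.na(res[, 1L]),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cut in fdr_cutoffs) out[[paste0("de_", cut)]] <- out$q <= cut
  out
}

#' Flag DC edges driven by differential expression
#'
#' An edge is DE-driven when either of its genes is differentially expressed
#' in its own region.
#'
#' @param network A `dc_network`.
#' @param de_genes Named list, region id -> character vector of DE genes.
#' @return The network with a `de_driven` edge column and a
#'   `de_driven_percentage` field.
#' @export
flag_de_driven <- function(network, de_genes) {
  stopifnot(inherits(network, "dc_network"))
  r <- network$region_ids
  deA <- de_genes[[r[1L]]] %||% character()
  deB <- de_genes[[r[2L]]] %||% character()
  network$edges$de_driven <-
    network$edges$geneA %in% deA | network$edges$geneB %in% deB
  network$de_driven_percentage <-
    if (nrow(network$edges) > 0)
      100 * mean(network$edges$de_driven) else 0
  network
}
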