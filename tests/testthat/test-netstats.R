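mk_network <- function(geneA, geneB, regions = c("BR1", "BR2")) {
  n <- length(geneA)
  u <- data.frame(geneA = geneA, geneB = geneB, rho_ctl = rep(0, n),
                  rho_ad = rep(0.9, n), p_ctl = rep(NA_real_, n),
                  p_ad = rep(NA_real_, n), q_ctl = rep(NA_real_, n),
                  q_ad = rep(NA_real_, n), n_ctl = rep(200L, n),
                  n_ad = rep(200L, n), correlated_ctl = rep(FALSE, n),
                  correlated_ad = rep(TRUE, n), stringsAsFactors = FALSE)
  attr(u, "region_ids") <- regions
  call_dc_edges(u)
}

test_that("node degrees count partners and satisfy the bipartite handshake", {
  star <- mk_network(rep("hub", 5), sprintf("leaf%d", 1:5))
  deg <- node_degrees(star)
  expect_equal(deg$degree[deg$gene == "hub"], 5)
  expect_true(all(deg$degree[deg$region == "BR2"] == 1))
  expect_equal(sum(deg$degree[deg$region == "BR1"]), nrow(star$edges))
  expect_equal(sum(deg$degree[deg$region == "BR2"]), nrow(star$edges))

  empty <- mk_network(character(), character())
  expect_equal(nrow(node_degrees(empty)), 0)

  gen <- generate_paired_dataset(small_sim(seed = 40, n_ctl = 80, n_ad = 80))
  nw <- call_dc_edges(correlated_pair_universe(gen$dataset))
  deg2 <- node_degrees(nw)
  for (i in 1:2) {
    expect_equal(sum(deg2$degree[deg2$region == nw$region_ids[i]]),
                 nrow(nw$edges))
  }
})

test_that("biotype filtering excludes unannotated genes before ranking", {
  nw <- mk_network(c("a", "a", "b"), c("x", "y", "x"))
  bt <- c(a = "protein_coding", x = "protein_coding", y = "lncRNA")
  expect_warning(deg <- node_degrees(nw, biotype_map = bt,
                                     protein_coding_only = TRUE),
                 "without biotype")
  expect_setequal(deg$gene, c("a", "x"))
})

test_that("Jaccard index matches set arithmetic", {
  expect_equal(jaccard_index(letters[1:3], letters[1:3]), 1)
  expect_equal(jaccard_index(letters[1:3], letters[4:6]), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(character(), character()), 0)
  expect_equal(jaccard_index(c("a", "b"), c("b", "a")), 1)
})

test_that("region exclusivity pools DC genes across comparisons", {
  nw1 <- mk_network(c("a", "b"), c("p", "q"), regions = c("FP", "STG"))
  nw2 <- mk_network(c("b", "c"), c("r", "s"), regions = c("FP", "PHG"))
  nw3 <- mk_network("d", "t", regions = c("FP", "IFG"))
  rep_fp <- region_exclusivity(list(nw1, nw2, nw3), "FP")
  expect_setequal(rep_fp$pooled_genes, c("a", "b", "c", "d"))
  expect_equal(rep_fp$shared_genes, "b")
  expect_equal(rep_fp$shared_fraction, 0.25)
  # invariant under comparison order
  rep_rev <- region_exclusivity(list(nw3, nw2, nw1), "FP")
  expect_equal(rep_rev$shared_fraction, rep_fp$shared_fraction)

  same <- region_exclusivity(list(nw1, nw1), "FP")
  expect_equal(same$shared_fraction, 1)
  expect_error(region_exclusivity(list(nw1), "FP"), ">= 2")
})

test_that("intra-region projection finds no DC when within-region structure is stable", {
  # planted single edges couple gene i of BR1 with gene i of BR2; within one
  # region those genes are mutually independent, so the projected pairs
  # carry no intra-region correlation change
  pe <- data.frame(geneA = sprintf("g%04d", 1:30),
                   geneB = sprintf("g%04d", 31:60),
                   rho_ctl = 0, rho_ad = 0.7, class = "PG",
                   stringsAsFactors = FALSE)
  gen <- generate_paired_dataset(small_sim(seed = 41, planted_edges = pe,
                                           planted_blocks = NULL,
                                           marker_loading = 0,
                                           confounded_per_type = 0))
  paired <- gen$dataset
  nw <- call_dc_edges(correlated_pair_universe(paired))
  expect_gt(nrow(nw$edges), 20)
  intra <- suppressWarnings(
    intra_dc_projection(paired$br1, paired$group_labels, nw, "BR1"))
  expect_lte(nrow(intra$edges), 1)
})

test_that("intra-region projection detects within-region rewiring", {
  set.seed(42)
  n <- 200
  grp <- setNames(rep(c("CTL", "AD"), each = n / 2),
                  sprintf("i%03d", seq_len(n)))
  ad <- grp == "AD"
  f <- rnorm(n / 2)
  m <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(c("p", "q", "r", "s"), names(grp)))
  # within-region pair (p, q) rewires: correlated only in AD
  a <- sqrt(InterDC:::spearman_to_pearson(0.8))
  m["p", ad] <- a * f + sqrt(1 - a^2) * rnorm(n / 2)
  m["q", ad] <- a * f + sqrt(1 - a^2) * rnorm(n / 2)
  colnames(m) <- paste0(names(grp), "_BR1")
  re <- region_expression("BR1", m, data.frame(
    sample_id = colnames(m), individual_id = names(grp), region = "BR1",
    CERAD = ifelse(grp == "CTL", 1L, 2L), stringsAsFactors = FALSE))
  nw <- mk_network(c("p", "absent"), c("q", "r"))
  intra <- intra_dc_projection(re, grp, nw, "BR1")
  expect_equal(attr(intra, "n_skipped"), 1)  # edge with the unmeasured gene
  expect_equal(nrow(intra$edges), 1)
  expect_equal(intra$edges$geneA, "p")
  expect_equal(intra$edges$class, "PG")

  empty_nw <- mk_network(character(), character())
  intra0 <- intra_dc_projection(re, grp, empty_nw, "BR1")
  expect_equal(nrow(intra0$edges), 0)
})
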