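test_that("Spearman rho matches hand-computed rank arithmetic", {
  expect_equal(unname(spearman_rho(c(1, 2, 3, 4), c(1, 2, 3, 4))["rho"]), 1)
  expect_equal(unname(spearman_rho(c(1, 2, 3, 4), c(4, 3, 2, 1))["rho"]), -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d = (1,-1,1,-1,0): 1 - 24/120
  r <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(unname(r["rho"]), 0.8)
  # t-approximation p recomputed independently
  t_stat <- 0.8 * sqrt((5 - 2) / (1 - 0.8^2))
  expect_equal(unname(r["p"]), 2 * pt(t_stat, df = 3, lower.tail = FALSE))
  expect_equal(unname(spearman_rho(1:4, c(2, 1, 4, 3))["p"]) >= 0, TRUE)
  expect_error(spearman_rho(1:3, 1:3), "length")
  expect_warning(out <- spearman_rho(rep(1, 5), 1:5), "zero-variance")
  expect_true(all(is.na(out)))
})

test_that("BH adjustment reproduces hand-worked step-up values", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  # order-preserving w.r.t. input index
  p <- c(0.04, 0.001, 0.5, 0.01)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher z DC statistic matches the closed form and is antisymmetric", {
  # group sizes of a 372-control / 264-case cohort: z for 0 -> 0.5 is ~6.79
  z <- fisher_z_dc_test(0, 372, 0.5, 264)
  se <- sqrt(1 / (264 - 3) + 1 / (372 - 3))
  expect_equal(z$z, (0.5 * log(1.5 / 0.5) - 0) / se, tolerance = 1e-12)
  expect_equal(z$z, 6.79, tolerance = 0.005)

  expect_equal(fisher_z_dc_test(0.6, 100, 0.6, 50)$z, 0)
  expect_equal(fisher_z_dc_test(0.6, 100, 0.6, 50)$p, 1)
  a <- fisher_z_dc_test(0.3, 80, -0.2, 60)
  b <- fisher_z_dc_test(-0.2, 60, 0.3, 80)
  expect_equal(a$z, -b$z)
  expect_error(fisher_z_dc_test(0.5, 3, 0.5, 100), "exceed 3")
  expect_warning(fisher_z_dc_test(1, 100, 0.5, 100), "clamped")
})

test_that("|z| grows monotonically with the correlation difference", {
  deltas <- seq(0, 0.9, by = 0.1)
  zs <- vapply(deltas, function(d) {
    abs(fisher_z_dc_test(0, 150, d, 150)$z)
  }, numeric(1L))
  expect_true(all(diff(zs) > 0))
})

test_that("edge categories follow the dominant-side rule and pool into classes", {
  expect_equal(classify_dc_edge(0.05, 0.6), "PG")
  expect_equal(classify_dc_edge(0.0, -0.6), "NG")
  expect_equal(classify_dc_edge(0.55, 0.02), "LC_pos")
  expect_equal(classify_dc_edge(-0.55, 0.02), "LC_neg")
  expect_equal(InterDC:::dc_category_to_class(c("PG", "NG", "LC_pos",
                                                "LC_neg")),
               c("PG", "NG", "LC", "LC"))
  # exchanging group labels maps gained-positive onto lost-positive
  expect_equal(classify_dc_edge(0.6, 0.05), "LC_pos")
})

test_that("the correlated-pair universe honors its gates and the union rule", {
  gen <- generate_paired_dataset(small_sim(seed = 30))
  paired <- ctc_paired(gen$dataset, gen$truth$marker_map)
  u <- correlated_pair_universe(paired)
  expect_gt(nrow(u), 0)
  # gate invariant on every record, both groups
  for (g in c("ctl", "ad")) {
    q <- u[[paste0("q_", g)]]
    rho <- u[[paste0("rho_", g)]]
    expect_identical(u[[paste0("correlated_", g)]],
                     q <= 0.01 & abs(rho) >= 0.4)
  }
  expect_true(all(u$correlated_ctl | u$correlated_ad))
  expect_true(all(u$q_ctl >= u$p_ctl & u$q_ad >= u$p_ad))

  # a pair planted only in CTL is in the universe through the CTL side
  pe <- gen$truth$planted_edge_table
  lc <- pe[pe$class == "LC_pos", ][1, ]
  row <- u[u$geneA == lc$geneA & u$geneB == lc$geneB, ]
  expect_equal(nrow(row), 1)
  expect_true(row$correlated_ctl)

  # raising the |rho| gate above the planted strength empties the universe
  suppressWarnings(u_hi <- correlated_pair_universe(paired, rho_min = 0.95))
  expect_equal(nrow(u_hi), 0)
})

test_that("universe enumeration is independent of the block size", {
  gen <- generate_paired_dataset(small_sim(seed = 31, n_ctl = 60, n_ad = 60))
  paired <- gen$dataset
  u50 <- correlated_pair_universe(paired, block_size = 50)
  u500 <- correlated_pair_universe(paired, block_size = 500)
  attributes(u50) <- attributes(u50)[c("names", "class", "row.names")]
  attributes(u500) <- attributes(u500)[c("names", "class", "row.names")]
  expect_identical(u50, u500)
})

test_that("DC calling controls the edge set and the dysregulation index", {
  # hand-built universe: 14 pairs with a huge correlation change, 86 stable
  mk_univ <- function(n_dc, n_stable) {
    data.frame(
      geneA = sprintf("a%03d", seq_len(n_dc + n_stable)),
      geneB = sprintf("b%03d", seq_len(n_dc + n_stable)),
      rho_ctl = c(rep(0, n_dc), rep(0.5, n_stable)),
      rho_ad = c(rep(0.9, n_dc), rep(0.5, n_stable)),
      p_ctl = NA_real_, p_ad = NA_real_, q_ctl = NA_real_, q_ad = NA_real_,
      n_ctl = 200L, n_ad = 200L,
      correlated_ctl = FALSE, correlated_ad = TRUE,
      stringsAsFactors = FALSE)
  }
  nw <- call_dc_edges(mk_univ(14, 86))
  expect_equal(nrow(nw$edges), 14)
  expect_equal(nw$dysregulation_percentage, 14)
  expect_true(all(nw$edges$category == "PG"))

  # identical correlations everywhere: zero edges
  nw0 <- call_dc_edges(mk_univ(0, 50))
  expect_equal(nrow(nw0$edges), 0)
  expect_equal(nw0$dysregulation_percentage, 0)
})

test_that("planted rewiring is recovered with correct classes", {
  gen <- generate_paired_dataset(small_sim(seed = 32))
  paired <- ctc_paired(gen$dataset, gen$truth$marker_map)
  nw <- call_dc_edges(correlated_pair_universe(paired))
  pe <- gen$truth$planted_edge_table
  dc_pe <- pe[pe$class != "NULL", ]
  called <- edge_key(nw$edges$geneA, nw$edges$geneB)
  planted <- edge_key(dc_pe$geneA, dc_pe$geneB)
  expect_gte(mean(planted %in% called), 0.8)
  hit <- match(called, planted)
  ok <- !is.na(hit)
  expect_gte(mean(nw$edges$class[ok] ==
                    sub("_.*", "", dc_pe$class[hit[ok]])), 0.9)
  # null planted pairs (equal correlation both groups) are not called
  nulls <- edge_key(pe$geneA[pe$class == "NULL"], pe$geneB[pe$class == "NULL"])
  expect_lte(mean(nulls %in% called), 0.1)
})

test_that("Wilcoxon DE gives exact small-sample p-values and null calibration", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1,
              dimnames = list("g1", paste0("s", 1:6)))
  de <- wilcoxon_de(m, c(rep("CTL", 3), rep("AD", 3)), fdr_cutoffs = 0.05)
  expect_equal(de$p, 0.1)  # most extreme of C(6,3)=20 rank splits, two-sided

  set.seed(33)
  n <- 100
  null_m <- matrix(rnorm(1000 * 2 * n), 1000, 2 * n,
                   dimnames = list(sprintf("g%04d", 1:1000),
                                   sprintf("s%03d", 1:(2 * n))))
  de_null <- wilcoxon_de(null_m, rep(c("CTL", "AD"), each = n))
  expect_gt(mean(de_null$p < 0.05), 0.03)
  expect_lt(mean(de_null$p < 0.05), 0.07)

  const <- matrix(1, 1, 8, dimnames = list("flat", paste0("s", 1:8)))
  de_const <- wilcoxon_de(const, rep(c("CTL", "AD"), each = 4))
  expect_equal(de_const$p, 1)
  expect_true(de_const$constant)

  expect_error(wilcoxon_de(m, c("CTL", "CTL", "CTL", "CTL", "AD", "AD")),
               ">= 3")
})

test_that("DE-driven flags follow the either-gene rule", {
  nw <- call_dc_edges(data.frame(
    geneA = sprintf("a%02d", 1:10), geneB = sprintf("b%02d", 1:10),
    rho_ctl = 0, rho_ad = 0.9, p_ctl = NA_real_, p_ad = NA_real_,
    q_ctl = NA_real_, q_ad = NA_real_, n_ctl = 200L, n_ad = 200L,
    correlated_ctl = FALSE, correlated_ad = TRUE, stringsAsFactors = FALSE))
  flagged <- flag_de_driven(nw, list(BR1 = c("a01", "a02"), BR2 = "b03"))
  expect_equal(sum(flagged$edges$de_driven), 3)
  expect_equal(flagged$de_driven_percentage, 30)
  none <- flag_de_driven(nw, list(BR1 = character(), BR2 = character()))
  expect_equal(none$de_driven_percentage, 0)
})
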