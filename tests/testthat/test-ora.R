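test_that("hypergeometric ORA matches exact enumeration on hand cases", {
  bg <- sprintf("g%02d", 1:20)
  res <- hypergeom_ora(bg[1:5], bg[1:5], bg)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)

  res0 <- hypergeom_ora(bg[6:10], bg[1:5], bg)
  expect_equal(res0$p, 1)  # k = 0: P[X >= 0]

  bg10 <- sprintf("g%02d", 1:10)
  res1 <- hypergeom_ora(bg10[c(1, 6)], bg10[1:5], bg10)
  expect_equal(res1$p, 7 / 9, tolerance = 1e-12)  # 1 - C(5,2)/C(10,2)

  expect_error(hypergeom_ora(c("g01", "zz"), bg[1:5], bg), "background")
})

test_that("the tail equals brute-force enumeration for all N <= 30", {
  for (N in c(5, 10, 17, 24, 30)) {
    for (K in unique(c(1, N %/% 3, N %/% 2, N - 1))) {
      for (n in unique(c(1, N %/% 4, N %/% 2))) {
        bg <- sprintf("x%02d", seq_len(N))
        outside <- setdiff(bg, bg[seq_len(K)])
        for (k in 0:min(K, n)) {
          if (n - k > length(outside)) next  # overlap k not realizable
          query <- c(bg[seq_len(k)],
                     if (n - k > 0) outside[seq_len(n - k)])
          res <- hypergeom_ora(query, bg[seq_len(K)], bg)
          expect_equal(res$p, brute_tail(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the p-value decreases monotonically in the overlap", {
  ps <- vapply(0:10, function(k) {
    stats::phyper(k - 1, 20, 80, 10, lower.tail = FALSE)
  }, numeric(1L))
  bg <- sprintf("g%03d", 1:100)
  ours <- vapply(0:10, function(k) {
    query <- c(bg[seq_len(k)], bg[20 + seq_len(10 - k)])
    hypergeom_ora(query, bg[1:20], bg)$p
  }, numeric(1L))
  expect_equal(ours, ps)
  expect_true(all(diff(ours) < 0))
})

test_that("module ORA flags an exact gene-set copy and is order-invariant", {
  set.seed(60)
  bg <- sprintf("g%04d", 1:1000)
  set30 <- sample(bg, 30)
  collection <- list(hit_set = set30, decoy = sample(bg, 40))
  part <- structure(list(
    modules = list(`1` = list(BR1 = sort(set30))),
    module_sizes = c(`1` = 30L),
    size_pass = c(`1` = TRUE),
    nodes = data.frame(node = paste0(set30, "@BR1"), gene = set30,
                       region = "BR1", module = 1L)),
    class = "module_partition")
  res <- run_module_ora(part, collection, list(BR1 = bg))
  expect_lt(res$q[res$set == "hit_set"], 1e-6)
  shuffled <- run_module_ora(part, lapply(collection, sample),
                             list(BR1 = sample(bg)))
  expect_equal(res$p, shuffled$p)

  # disjoint module/set: q = 1
  part$modules$`1`$BR1 <- setdiff(bg, c(set30, collection$decoy))[1:30]
  part$nodes$gene <- part$modules$`1`$BR1
  res2 <- run_module_ora(part, collection["hit_set"], list(BR1 = bg))
  expect_equal(res2$q, 1)
})

test_that("uniformly drawn modules are significant at about the nominal rate", {
  set.seed(61)
  bg <- sprintf("g%04d", 1:1000)
  collection <- lapply(setNames(1:20, paste0("set", 1:20)), function(i) {
    bg[(i - 1) * 40 + 1:40]
  })
  ps <- replicate(50, {
    query <- sample(bg, 50)
    vapply(collection, function(s) hypergeom_ora(query, s, bg)$p,
           numeric(1L))
  })
  rate <- mean(ps <= 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.075)
})

test_that("empirical FDR summarizes the permutation null", {
  real <- data.frame(q = c(0.001, 0.02, 0.2))
  none <- replicate(10, data.frame(q = rep(0.9, 3)), simplify = FALSE)
  expect_equal(empirical_fdr(real, none, 0.05)$empirical_fdr, 0)
  same <- replicate(10, data.frame(q = c(0.001, 0.02, 0.2)),
                    simplify = FALSE)
  expect_equal(empirical_fdr(real, same, 0.05)$empirical_fdr, 1)
  expect_equal(empirical_fdr(real, same, 0.05)$n_real, 2)
})

test_that("planted module enrichment is robust against the permutation null", {
  set.seed(62)
  bg <- list(BR1 = sprintf("g%04d", 1:500), BR2 = sprintf("g%04d", 1:500))
  sig_genes <- bg$BR1[1:30]
  collection <- list(planted = sig_genes, decoy = bg$BR1[101:140])
  part <- structure(list(
    modules = list(`1` = list(BR1 = sig_genes)),
    module_sizes = c(`1` = 30L), size_pass = c(`1` = TRUE),
    nodes = data.frame(node = paste0(sig_genes, "@BR1"), gene = sig_genes,
                       region = "BR1", module = 1L)),
    class = "module_partition")
  real <- run_module_ora(part, collection, bg)
  perms <- random_modules(bg, part, n_perm = 10, seed = 63)
  rand <- InterDC:::random_module_ora(perms, collection, bg)
  ef <- empirical_fdr(real, rand, 0.05)
  expect_lt(ef$empirical_fdr, 0.2)
  expect_gte(ef$n_real, 1)
})
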