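test_that("robust-marker filter keeps null markers and removes DE markers", {
  set.seed(20)
  n <- 200
  groups <- rep(c("CTL", "AD"), each = n / 2)
  n_mark <- 500
  m <- matrix(rnorm(n_mark * n), n_mark, n,
              dimnames = list(sprintf("m%03d", seq_len(n_mark)),
                              sprintf("s%03d", seq_len(n))))
  kept <- filter_robust_markers(m, rownames(m), groups, alpha = 0.05)
  # under the null a marker is retained with probability ~ 1 - alpha
  expect_gt(length(kept) / n_mark, 0.92)
  expect_lt(length(kept) / n_mark, 0.98)

  m_de <- m
  m_de[1:20, groups == "AD"] <- m_de[1:20, groups == "AD"] + 2
  kept_de <- filter_robust_markers(m_de, rownames(m_de)[1:20], groups)
  expect_length(kept_de, 0)  # delta = 2 sd at n = 200: power ~ 1

  expect_error(filter_robust_markers(m, rownames(m), rep("CTL", n)),
               "both groups")
})

test_that("SPVs recover true cell proportions on a Dirichlet mixture", {
  gen <- generate_paired_dataset(small_sim(seed = 21, n_ctl = 150,
                                           n_ad = 150))
  ds <- gen$dataset
  model <- estimate_spvs(ds$br1, gen$truth$marker_map, ds$group_labels)
  truth <- gen$truth$true_cell_proportions[, names(ds$group_labels)]
  for (ct in rownames(truth)) {
    expect_gte(abs(cor(model$spvs[ct, ], truth[ct, ], method = "spearman")),
               0.9)
  }
  # unit norm and positive mean marker correlation (sign orientation)
  for (ct in rownames(model$spvs)) {
    expect_equal(sqrt(sum(model$spvs[ct, ]^2)), 1, tolerance = 1e-12)
    mk <- model$robust_markers[[ct]]
    expect_gt(mean(cor(model$spvs[ct, ], t(ds$br1$matrix[mk, ]))), 0)
  }
})

test_that("SPV of rank-1 marker data equals the underlying proportion", {
  set.seed(22)
  n <- 100
  prop <- runif(n)
  groups <- rep(c("CTL", "AD"), each = n / 2)
  m <- matrix(rep(prop, each = 5), 5, n, byrow = FALSE,
              dimnames = list(paste0("mk", 1:5), paste0("s", seq_len(n))))
  m <- m * (1 + 0.2 * (seq_len(5) - 3))  # distinct scales, same direction
  model <- estimate_spvs(m, list(ct = rownames(m)), groups, alpha = 0)
  expect_equal(abs(cor(model$spvs["ct", ], prop)), 1, tolerance = 1e-8)
  expect_equal(unname(model$variance_explained["ct"]), 1, tolerance = 1e-8)
  # orientation contract survives negating all marker rows: the SPV then
  # tracks the negated markers (mean correlation still positive)
  neg <- estimate_spvs(-m, list(ct = rownames(m)), groups, alpha = 0)
  expect_gt(mean(cor(neg$spvs["ct", ], t(-m))), 0)
})

test_that("marker-model selection maximizes truth correlation, ties smaller", {
  set.seed(23)
  n <- 150
  prop <- runif(n, 0.1, 0.9)
  groups <- rep(c("CTL", "AD"), length.out = n)
  informative <- t(vapply(1:20, function(i) 3 * prop + rnorm(n, sd = 0.3),
                          numeric(n)))
  # markers 21-40 track a shared confounding signal unrelated to the truth,
  # so including them degrades the leading singular vector
  confound <- rnorm(n)
  noise <- t(vapply(1:20, function(i) 3 * confound + rnorm(n, sd = 0.3),
                    numeric(n)))
  m <- rbind(informative, noise)
  rownames(m) <- paste0("mk", 1:40)
  colnames(m) <- paste0("s", seq_len(n))
  sel <- select_marker_model(m, list(ct = rownames(m)), groups, prop,
                             cell_type = "ct",
                             candidate_sizes = c(20, 40))
  expect_equal(sel$best_size, 20)

  # noise-free rank-1 data: every size is equivalent, smallest wins
  m1 <- matrix(rep(prop, each = 40), 40, n,
               dimnames = list(paste0("mk", 1:40), paste0("s", seq_len(n))))
  m1 <- m1 + matrix(rnorm(40 * n, sd = 1e-8), 40, n)
  sel1 <- select_marker_model(m1, list(ct = rownames(m1)), groups, prop,
                              cell_type = "ct",
                              candidate_sizes = c(20, 40))
  expect_equal(sel1$best_size, 20)
})

test_that("cell-type correction removes composition signal exactly and is idempotent", {
  gen <- generate_paired_dataset(small_sim(seed = 24, n_ctl = 100,
                                           n_ad = 100))
  ds <- gen$dataset
  model <- estimate_spvs(ds$br1, gen$truth$marker_map, ds$group_labels)

  # a gene that is an exact linear combination of SPVs becomes constant
  re <- ds$br1
  re$matrix["g0100", ] <- 2 * model$spvs[1, ] - model$spvs[3, ] + 5
  corrected <- correct_cell_types(re, model)
  expect_lt(stats::var(corrected$matrix["g0100", ]), 1e-12)
  expect_equal(dim(corrected$matrix), dim(re$matrix))

  twice <- correct_cell_types(corrected, model)
  expect_equal(twice$matrix, corrected$matrix, tolerance = 1e-8)

  # zero SPVs = identity transform
  empty <- structure(list(spvs = model$spvs[0, , drop = FALSE]),
                     class = "spv_model")
  expect_identical(correct_cell_types(re, empty)$matrix, re$matrix)
})

test_that("SPV-truth correlation does not degrade as marker loading grows", {
  cors <- vapply(c(2, 5, 10), function(load) {
    gen <- generate_paired_dataset(small_sim(seed = 25, n_ctl = 100,
                                             n_ad = 100,
                                             marker_loading = load))
    ds <- gen$dataset
    model <- estimate_spvs(ds$br1, gen$truth$marker_map, ds$group_labels)
    truth <- gen$truth$true_cell_proportions[, names(ds$group_labels)]
    mean(vapply(rownames(truth), function(ct) {
      abs(cor(model$spvs[ct, ], truth[ct, ], method = "spearman"))
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(cors) > -0.02))  # monotone up to simulation noise
})
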