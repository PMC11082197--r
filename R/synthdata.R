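# Synthetic paired two-region expression data with planted cross-region
# correlation rewiring, cell-type composition confounding, covariates and
# marker genes. Every downstream stage of the pipeline can be exercised
# against the returned ground truth without any external data.

#' Configuration for the paired-region expression simulator
#'
#' The defaults mirror a two-region post-mortem brain cohort: 372 control and
#' 264 disease individuals profiled in both regions, four major cell types
#' (neurons, oligodendrocytes, astrocytes, microglia) with 20 marker genes
#' each mixed into the bulk signal, continuous covariates, and a set of
#' cross-region gene pairs whose Spearman correlation differs between groups.
#'
#' Planted pairs are induced through a shared latent Gaussian factor per edge;
#' the factor loading is chosen so the latent Pearson correlation
#' `r = 2*sin(pi*rho/6)` maps to the target Spearman `rho` (the exact
#' bivariate-normal relationship `rho_S = (6/pi)*asin(r/2)`), which makes the
#' planted rank correlations analytically controllable.
#'
#' Cell-type proportions are drawn from a Dirichlet whose concentration can
#' differ between groups (`concentration_ctl` vs `concentration_ad`). A lower
#' disease-group concentration inflates compositional variance in that group,
#' so genes loading on the same cell type gain correlation in the disease
#' group purely through composition -- the confound that cell-type correction
#' is meant to remove.
#'
#' @param n_genes_per_region Number of genes simulated in each region.
#' @param n_ctl,n_ad Number of control / disease individuals (CERAD 1 / 2).
#' @param n_excluded Number of extra individuals with CERAD 3 or 4; they are
#'   written to the metadata but excluded by group assignment downstream.
#' @param planted_edges Data frame with columns `geneA`, `geneB`, `rho_ctl`,
#'   `rho_ad`, `class` (one of `"PG"`, `"NG"`, `"LC_pos"`, `"LC_neg"`,
#'   `"NULL"`). `geneA` lives in region 1, `geneB` in region 2.
#' @param planted_blocks List of blocks, each a list with `genesA`, `genesB`
#'   (gene ids on the two sides), `rho_ctl`, `rho_ad`: all cross-region
#'   pairs of a block share one latent factor per group, so whole bipartite
#'   modules gain or lose correlation together (what Louvain should
#'   recover). See [default_planted_blocks()].
#' @param n_cell_types,markers_per_type Cell types and marker genes per type.
#' @param marker_loading Loading of a marker gene on its own cell type's
#'   proportion; markers load on no other type.
#' @param confounded_per_type,confound_loading Number of non-marker genes per
#'   cell type (per region) that weakly load on that type's proportion, and
#'   their loading (kept at no more than `marker_loading / 5` so markers load
#'   predominantly on their own type).
#' @param dirichlet_mean Named mean proportion per cell type (sums to 1).
#' @param concentration_ctl,concentration_ad Dirichlet concentration per group.
#' @param proportion_noise_sd SD of gene-specific noise on the proportion
#'   signal entering each composition-loaded gene.
#' @param covariate_effects Named numeric vector: per covariate, the SD of the
#'   random per-gene slope applied to background genes.
#' @param n_de_genes,de_effect Number of background genes per region shifted
#'   by `de_effect` in the disease group (the planted DE genes).
#' @param noise_sd SD of the independent expression noise of non-planted
#'   genes (planted genes are emitted on a unit-variance latent scale).
#' @param region_ids Character vector of length 2 naming the regions.
#' @param seed Integer seed; fully determines the generated dataset.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes_per_region = 400,
                              n_ctl = 372,
                              n_ad = 264,
                              n_excluded = 20,
                              planted_edges = default_planted_edges(),
                              planted_blocks = default_planted_blocks(),
                              n_cell_types = 4,
                              markers_per_type = 20,
                              marker_loading = 5,
                              confounded_per_type = 5,
                              confound_loading = 1,
                              dirichlet_mean = c(neuron = 0.40,
                                                 oligodendrocyte = 0.30,
                                                 astrocyte = 0.15,
                                                 microglia = 0.15),
                              concentration_ctl = 50,
                              concentration_ad = 10,
                              proportion_noise_sd = 0.01,
                              covariate_effects = c(age = 0.05, RIN = 0.2),
                              n_de_genes = 20,
                              de_effect = 1,
                              noise_sd = 0.5,
                              region_ids = c("BR1", "BR2"),
                              seed = 1) {
  cfg <- list(n_genes_per_region = n_genes_per_region, n_ctl = n_ctl,
              n_ad = n_ad, n_excluded = n_excluded,
              planted_edges = planted_edges,
              planted_blocks = planted_blocks, n_cell_types = n_cell_types,
              markers_per_type = markers_per_type,
              marker_loading = marker_loading,
              confounded_per_type = confounded_per_type,
              confound_loading = confound_loading,
              dirichlet_mean = dirichlet_mean,
              concentration_ctl = concentration_ctl,
              concentration_ad = concentration_ad,
              proportion_noise_sd = proportion_noise_sd,
              covariate_effects = covariate_effects,
              n_de_genes = n_de_genes, de_effect = de_effect,
              noise_sd = noise_sd, region_ids = region_ids, seed = seed)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  for (f in c("n_genes_per_region", "n_ctl", "n_ad")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 1) {
      stop_field(f, "must be a positive count")
    }
  }
  if (cfg$n_excluded < 0) stop_field("n_excluded", "must be non-negative")
  if (cfg$n_cell_types < 1) stop_field("n_cell_types", "must be positive")
  if (cfg$markers_per_type < 1) stop_field("markers_per_type", "must be positive")
  if (cfg$markers_per_type * cfg$n_cell_types > cfg$n_genes_per_region) {
    stop_field("markers_per_type",
               "markers_per_type * n_cell_types exceeds n_genes_per_region")
  }
  if (length(cfg$dirichlet_mean) != cfg$n_cell_types) {
    stop_field("dirichlet_mean", "needs one entry per cell type")
  }
  if (abs(sum(cfg$dirichlet_mean) - 1) > 1e-8) {
    stop_field("dirichlet_mean", "must sum to 1")
  }
  if (cfg$noise_sd <= 0) stop_field("noise_sd", "must be positive")
  if (length(cfg$region_ids) != 2L || anyDuplicated(cfg$region_ids)) {
    stop_field("region_ids", "must be two distinct labels")
  }
  pe <- cfg$planted_edges
  if (!is.null(pe) && nrow(pe) > 0) {
    need <- c("geneA", "geneB", "rho_ctl", "rho_ad", "class")
    if (!all(need %in% names(pe))) {
      stop_field("planted_edges", paste("missing column(s):",
                 paste(setdiff(need, names(pe)), collapse = ", ")))
    }
    if (any(abs(pe$rho_ctl) > 1) || any(abs(pe$rho_ad) > 1)) {
      stop_field("planted_edges", "all |rho| values must lie in [-1, 1]")
    }
    if (anyDuplicated(pe$geneA) || anyDuplicated(pe$geneB)) {
      stop_field("planted_edges",
                 "gene ids must be unique within each region side")
    }
    ok <- mapply(planted_class_consistent, pe$rho_ctl, pe$rho_ad, pe$class)
    if (!all(ok)) {
      stop_field("planted_edges", sprintf(
        "class label inconsistent with rho targets in row(s) %s",
        paste(which(!ok), collapse = ", ")))
    }
  }
  pb <- cfg$planted_blocks
  if (!is.null(pb) && length(pb) > 0) {
    for (b in pb) {
      if (!all(c("genesA", "genesB", "rho_ctl", "rho_ad") %in% names(b))) {
        stop_field("planted_blocks",
                   "each block needs genesA, genesB, rho_ctl, rho_ad")
      }
      if (abs(b$rho_ctl) > 1 || abs(b$rho_ad) > 1) {
        stop_field("planted_blocks", "all |rho| values must lie in [-1, 1]")
      }
    }
    if (anyDuplicated(unlist(lapply(pb, `[[`, "genesA"))) ||
        anyDuplicated(unlist(lapply(pb, `[[`, "genesB")))) {
      stop_field("planted_blocks",
                 "block gene ids must be unique within each region side")
    }
  }
  invisible(cfg)
}

# Class semantics: PG gained positive (rho_ad > 0, |rho_ad| > |rho_ctl|),
# NG gained negative, LC_pos / LC_neg lost a positive / negative correlation,
# "NULL" = no differential-correlation expectation (any rho pair allowed).
planted_class_consistent <- function(rho_ctl, rho_ad, class) {
  switch(class,
         PG = rho_ad > 0 && abs(rho_ad) > abs(rho_ctl),
         NG = rho_ad < 0 && abs(rho_ad) > abs(rho_ctl),
         LC_pos = rho_ctl > 0 && abs(rho_ctl) > abs(rho_ad),
         LC_neg = rho_ctl < 0 && abs(rho_ctl) > abs(rho_ad),
         "NULL" = TRUE,
         FALSE)
}

#' Default planted edge table: 50 edges per DC class plus stable pairs
#'
#' Gained edges move from 0 to +/-`rho`, lost edges from `rho` to 0, and
#' `n_null` pairs are equally correlated in both groups (class `"NULL"`) so
#' the correlated-pair universe also contains pairs without differential
#' correlation. Edge `i` couples gene `i` of region 1 with gene `i` of
#' region 2 (the same gene identifier measured in both regions, as in a
#' real two-region design).
#'
#' @param n_per_class Planted edges per DC class (PG, NG, LC).
#' @param rho Magnitude of the planted Spearman correlation.
#' @param lc_sign Sign of the lost correlation (`LC_pos` or `LC_neg`).
#' @param n_null Stable (non-DC) correlated pairs.
#' @param rho_null Their common correlation in both groups.
#' @return Data frame accepted by [simulation_config()].
#' @export
default_planted_edges <- function(n_per_class = 50, rho = 0.7,
                                  lc_sign = 1, n_null = 50,
                                  rho_null = 0.6) {
  n <- 3L * n_per_class + n_null
  ids <- sprintf("g%04d", seq_len(n))
  cls <- rep(c("PG", "NG", if (lc_sign >= 0) "LC_pos" else "LC_neg", "NULL"),
             c(n_per_class, n_per_class, n_per_class, n_null))
  data.frame(geneA = ids, geneB = ids,
             rho_ctl = ifelse(cls == "NULL", rho_null,
                              ifelse(startsWith(cls, "LC"),
                                     lc_sign * rho, 0)),
             rho_ad = ifelse(cls == "NULL", rho_null,
                             ifelse(cls == "PG", rho,
                                    ifelse(cls == "NG", -rho, 0))),
             class = cls, stringsAsFactors = FALSE)
}

#' Default planted bipartite blocks
#'
#' Two blocks of correlated genes (15 per region side) whose cross-region
#' pairs all gain correlation in the disease group, emulating a bipartite
#' module of co-dysregulated genes. Gene indices start after the default
#' planted single edges.
#'
#' @param n_blocks Number of blocks.
#' @param genes_per_side Genes per region side per block.
#' @param rho_ctl,rho_ad Cross-pair Spearman targets per group.
#' @param start_index First gene index used by the blocks.
#' @return List accepted by [simulation_config()].
#' @export
default_planted_blocks <- function(n_blocks = 2, genes_per_side = 15,
                                   rho_ctl = 0, rho_ad = 0.6,
                                   start_index = 201) {
  idx <- start_index - 1L
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    genesA <- sprintf("g%04d", idx + seq_len(genes_per_side))
    idx <- idx + genes_per_side
    genesB <- sprintf("g%04d", idx + seq_len(genes_per_side))
    idx <- idx + genes_per_side
    blocks[[b]] <- list(genesA = genesA, genesB = genesB,
                        rho_ctl = rho_ctl, rho_ad = rho_ad)
  }
  blocks
}

#' Planted edge table with identical correlation in both groups
#'
#' Convenience for null simulations: `n` pairs correlated at `rho` in both
#' groups (class `"NULL"`), so they enter the correlated-pair universe but
#' carry no differential-correlation signal.
#'
#' @param n Number of pairs.
#' @param rho Common Spearman correlation of both groups.
#' @return Data frame accepted by [simulation_config()].
#' @export
null_planted_edges <- function(n = 100, rho = 0.6) {
  ids <- sprintf("g%04d", seq_len(n))
  data.frame(geneA = ids, geneB = ids, rho_ctl = rho, rho_ad = rho,
             class = "NULL", stringsAsFactors = FALSE)
}

# Latent Pearson correlation reproducing a target Spearman rho under
# bivariate normality: rho_S = (6/pi) * asin(r/2)  <=>  r = 2 sin(pi rho_S/6).
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Generate a paired two-region dataset with known ground truth
#'
#' Bulk expression of each gene is latent cell-intrinsic signal plus
#' `sum(proportion x loading)` over cell types, plus covariate effects, plus
#' Gaussian noise. Planted pairs are generated on a unit-variance latent
#' scale with group-specific correlation; marker genes load on their own cell
#' type with `marker_loading` (at least 5x any other gene's loading).
#'
#' @param config A [simulation_config()].
#' @return A list with components `dataset` (a `paired_dataset` restricted to
#'   CTL/AD individuals, see [pair_regions()]), `truth` (ground-truth tables:
#'   planted edges, true cell proportions, DE genes, marker map) and
#'   `regions` (the two unfiltered `region_expression` objects, including
#'   CERAD 3/4 individuals, as written by [write_simulation()]).
#' @export
generate_paired_dataset <- function(config) {
  validate_simulation_config(config)
  with_seed(config$seed, generate_paired_dataset_impl(config))
}

generate_paired_dataset_impl <- function(cfg) {
  n_genes <- cfg$n_genes_per_region
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  types <- names(cfg$dirichlet_mean) %||%
    paste0("celltype", seq_len(cfg$n_cell_types))

  n_mark <- cfg$n_cell_types * cfg$markers_per_type
  marker_ids <- gene_ids[(n_genes - n_mark + 1L):n_genes]
  marker_map <- split(marker_ids, rep(types, each = cfg$markers_per_type))[types]
  n_conf <- cfg$n_cell_types * cfg$confounded_per_type
  conf_ids <- if (n_conf > 0) {
    gene_ids[(n_genes - n_mark - n_conf + 1L):(n_genes - n_mark)]
  } else character()
  conf_map <- if (n_conf > 0) {
    split(conf_ids, rep(types, each = cfg$confounded_per_type))[types]
  } else setNames(rep(list(character()), length(types)), types)

  pe <- cfg$planted_edges
  pb <- cfg$planted_blocks
  block_ids <- unique(unlist(lapply(pb, function(b) c(b$genesA, b$genesB))))
  planted_ids <- unique(c(pe$geneA, pe$geneB, block_ids))
  if (!all(planted_ids %in% gene_ids)) {
    stop_field("planted_edges", "gene ids outside the simulated gene universe")
  }
  if (length(intersect(planted_ids, c(marker_ids, conf_ids))) > 0) {
    stop_field("planted_edges",
               "planted genes collide with marker/composition gene ids; reduce planted edges or increase n_genes_per_region")
  }

  # Individuals: controls (CERAD 1), disease (CERAD 2), excluded (CERAD 3/4).
  ind <- c(sprintf("C%04d", seq_len(cfg$n_ctl)),
           sprintf("A%04d", seq_len(cfg$n_ad)),
           if (cfg$n_excluded > 0) sprintf("X%04d", seq_len(cfg$n_excluded)))
  grp <- c(rep("CTL", cfg$n_ctl), rep("AD", cfg$n_ad),
           rep("EXC", cfg$n_excluded))
  cerad <- c(rep(1L, cfg$n_ctl), rep(2L, cfg$n_ad),
             if (cfg$n_excluded > 0)
               rep_len(c(3L, 4L), cfg$n_excluded))
  n_ind <- length(ind)

  # Cell-type proportions: shared across the two regions of one individual,
  # group-specific Dirichlet concentration.
  conc <- ifelse(grp == "AD", cfg$concentration_ad, cfg$concentration_ctl)
  props <- matrix(NA_real_, cfg$n_cell_types, n_ind,
                  dimnames = list(types, ind))
  for (i in seq_len(n_ind)) {
    props[, i] <- rdirichlet_cols(1L, cfg$dirichlet_mean * conc[i])
  }

  covs <- data.frame(age = rnorm(n_ind, 80, 8), RIN = rnorm(n_ind, 7, 1))
  rownames(covs) <- ind

  bg_ids <- setdiff(gene_ids, c(planted_ids, conf_ids, marker_ids))
  if (cfg$n_de_genes > length(bg_ids)) {
    stop_field("n_de_genes", "more DE genes requested than background genes")
  }

  regions <- vector("list", 2L)
  de_genes <- setNames(vector("list", 2L), cfg$region_ids)
  for (r in 1:2) {
    m <- matrix(rnorm(n_genes * n_ind, sd = cfg$noise_sd), n_genes, n_ind,
                dimnames = list(gene_ids, paste(ind, cfg$region_ids[r],
                                                sep = "_")))
    for (ct in types) {
      sig <- props[ct, ]
      for (g in marker_map[[ct]]) {
        m[g, ] <- m[g, ] + cfg$marker_loading *
          (sig + rnorm(n_ind, sd = cfg$proportion_noise_sd))
      }
      for (g in conf_map[[ct]]) {
        m[g, ] <- m[g, ] + cfg$confound_loading *
          (sig + rnorm(n_ind, sd = cfg$proportion_noise_sd))
      }
    }
    # Covariate effects on background genes: random per-gene slope whose SD
    # is the configured effect size.
    for (cv in names(cfg$covariate_effects)) {
      slopes <- rnorm(length(bg_ids), sd = cfg$covariate_effects[[cv]])
      m[bg_ids, ] <- m[bg_ids, ] +
        outer(slopes, covs[[cv]] - mean(covs[[cv]]))
    }
    if (cfg$n_de_genes > 0) {
      de <- sample(bg_ids, cfg$n_de_genes)
      m[de, grp == "AD"] <- m[de, grp == "AD"] + cfg$de_effect
      de_genes[[r]] <- sort(de)
    } else de_genes[[r]] <- character()
    regions[[r]] <- m
  }

  # Planted cross-region pairs: per group, one shared latent factor per edge.
  for (e in seq_len(nrow(pe %||% data.frame()))) {
    for (g in c("CTL", "AD", "EXC")) {
      cols <- which(grp == g)
      ng <- length(cols)
      if (ng == 0L) next
      rho <- if (g == "AD") pe$rho_ad[e] else pe$rho_ctl[e]
      r <- if (g == "EXC") 0 else spearman_to_pearson(rho)
      a <- sqrt(abs(r))
      f <- rnorm(ng)
      x <- a * f + sqrt(1 - a^2) * rnorm(ng)
      y <- sign(r + (r == 0)) * a * f + sqrt(1 - a^2) * rnorm(ng)
      regions[[1L]][pe$geneA[e], cols] <- x
      regions[[2L]][pe$geneB[e], cols] <- y
    }
  }

  # Planted blocks: one shared latent factor per block and group, each
  # member gene loading sqrt(|r|) on it, so every cross-region pair of the
  # block attains the target correlation.
  for (b in pb %||% list()) {
    for (g in c("CTL", "AD", "EXC")) {
      cols <- which(grp == g)
      ng <- length(cols)
      if (ng == 0L) next
      rho <- if (g == "AD") b$rho_ad else b$rho_ctl
      r <- if (g == "EXC") 0 else spearman_to_pearson(rho)
      a <- sqrt(abs(r))
      f <- rnorm(ng)
      for (gene in b$genesA) {
        regions[[1L]][gene, cols] <- a * f + sqrt(1 - a^2) * rnorm(ng)
      }
      for (gene in b$genesB) {
        regions[[2L]][gene, cols] <-
          sign(r + (r == 0)) * a * f + sqrt(1 - a^2) * rnorm(ng)
      }
    }
  }

  region_objs <- lapply(1:2, function(r) {
    meta <- data.frame(sample_id = colnames(regions[[r]]),
                       individual_id = ind,
                       region = cfg$region_ids[r],
                       CERAD = cerad,
                       age = covs$age, RIN = covs$RIN,
                       stringsAsFactors = FALSE)
    region_expression(cfg$region_ids[r], regions[[r]], meta)
  })

  block_table <- if (length(pb %||% list()) > 0) {
    do.call(rbind, lapply(seq_along(pb), function(i) {
      b <- pb[[i]]
      data.frame(block = i,
                 gene = c(b$genesA, b$genesB),
                 side = rep(1:2, c(length(b$genesA), length(b$genesB))),
                 rho_ctl = b$rho_ctl, rho_ad = b$rho_ad,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(block = integer(), gene = character(), side = integer(),
                    rho_ctl = numeric(), rho_ad = numeric())

  truth <- structure(list(
    planted_edge_table = pe,
    planted_block_table = block_table,
    true_cell_proportions = props,
    true_de_genes = de_genes,
    marker_map = marker_map,
    confounded_map = conf_map,
    composition_genes = c(conf_ids, marker_ids),
    group = setNames(grp, ind)), class = "interdc_ground_truth")
  stopifnot(max(abs(colSums(props) - 1)) < 1e-9)

  dataset <- pair_regions(region_objs[[1L]], region_objs[[2L]])
  list(dataset = dataset, truth = truth, regions = region_objs)
}

#' Flag a fraction of individuals as missing in one region
#'
#' Emulates cohorts where not every individual has every region sampled: the
#' chosen individuals' samples are dropped from one region, and downstream
#' paired-sample selection ([pair_regions()]) must exclude them.
#'
#' @param regions List of two `region_expression` objects (e.g. the `regions`
#'   component returned by [generate_paired_dataset()]).
#' @param fraction Fraction of individuals to drop, in `[0, 1)`.
#' @param region Which region loses samples (1 or 2).
#' @param seed Seed for the individual draw.
#' @return The list of regions with the chosen samples removed from one side.
#' @export
inject_missing_region <- function(regions, fraction, region = 2L, seed = 1) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop_field("fraction", "must lie in [0, 1)")
  }
  if (fraction == 0) return(regions)
  re <- regions[[region]]
  ind <- unique(re$sample_meta$individual_id)
  k <- round(fraction * length(ind))
  drop <- with_seed(seed, sample(ind, k))
  keep <- !(re$sample_meta$individual_id %in% drop)
  regions[[region]] <- region_expression(
    re$region_id, re$matrix[, keep, drop = FALSE],
    re$sample_meta[keep, , drop = FALSE])
  regions
}
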