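# Stage-per-subcommand orchestration of the full analysis: simulate ->
# preprocess -> ctc -> dcnet -> netstats -> modules -> ora. Every stage
# reads its inputs from, and writes its artifacts into, one output
# directory; the resolved configuration (including the seed) is serialized
# alongside the outputs, and each stage appends deterministic count
# bookkeeping to a plain-text log so re-runs with identical inputs are
# byte-identical.

#' Pipeline configuration with the standard thresholds
#'
#' Defaults are the conventional gates of the analysis: correlation FDR 1%
#' with `|rho| >= 0.4`, DC FDR 1%, ORA FDR 5%, DE flags at FDR 0.05/0.1/0.2,
#' modules of at least 20 genes, and 10 random-module permutations.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [simulation_config()] for the `simulate` stage (its seed is
#'   re-derived from `seed` so one pipeline seed drives everything).
#' @param covariates Metadata columns to residualize out in preprocessing.
#' @param fdr_corr,rho_min,fdr_dc,fdr_ora,de_cutoffs,min_module_genes,n_perm
#'   Analysis thresholds (see module documentation).
#' @param min_group_size Minimum paired individuals per group.
#' @param block_size Gene block size for the streamed pair enumeration.
#' @param spv_alpha Robust-marker filter level.
#' @param seed Master seed for all stage randomness.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(),
                            covariates = c("age", "RIN"),
                            fdr_corr = 0.01, rho_min = 0.4, fdr_dc = 0.01,
                            fdr_ora = 0.05, de_cutoffs = c(0.05, 0.1, 0.2),
                            min_module_genes = 20, n_perm = 10,
                            min_group_size = 10, block_size = 200,
                            spv_alpha = 0.05, seed = 1) {
  sim$seed <- seed
  structure(list(out_dir = out_dir, sim = sim, covariates = covariates,
                 fdr_corr = fdr_corr, rho_min = rho_min, fdr_dc = fdr_dc,
                 fdr_ora = fdr_ora, de_cutoffs = de_cutoffs,
                 min_module_genes = min_module_genes, n_perm = n_perm,
                 min_group_size = min_group_size, block_size = block_size,
                 spv_alpha = spv_alpha, seed = seed),
            class = "pipeline_config")
}

out_path <- function(config, ...) file.path(config$out_dir, ...)

log_stage <- function(config, stage, lines) {
  writeLines(c(sprintf("[%s]", stage), lines),
             out_path(config, paste0("log_", stage, ".txt")))
}

write_config_json <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # implied by location; keeps re-runs byte-comparable
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$planted_edges <- NULL  # full table lives in the truth artifacts
  jsonlite::write_json(cfg, out_path(config, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run pipeline stages
#'
#' Chains the requested stages over one output directory. `"all"` runs
#' simulate through ora. Re-running with the same config and seed
#' reproduces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stage names, or `"all"`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "preprocess", "ctc", "dcnet", "netstats",
                  "modules", "ora")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config_json(config)
  for (s in stages) {
    switch(s,
           simulate = stage_simulate(config),
           preprocess = stage_preprocess(config),
           ctc = stage_ctc(config),
           dcnet = stage_dcnet(config),
           netstats = stage_netstats(config),
           modules = stage_modules(config),
           ora = stage_ora(config))
  }
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config) {
  gen <- generate_paired_dataset(config$sim)
  for (re in gen$regions) {
    write_expression(re$matrix,
                     out_path(config, sprintf("expr_%s.tsv", re$region_id)))
  }
  meta <- do.call(rbind, lapply(gen$regions, `[[`, "sample_meta"))
  write.table(meta, out_path(config, "metadata.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write_gmt(gen$truth$marker_map, out_path(config, "markers.gmt"))
  # Functional collection for the ORA stage, derived from the ground truth:
  # one set per cell type plus one per planted edge class.
  pe <- gen$truth$planted_edge_table
  class_sets <- if (!is.null(pe) && nrow(pe) > 0) {
    lapply(split(pe, pe$class), function(d) sort(unique(c(d$geneA, d$geneB))))
  } else list()
  names(class_sets) <- if (length(class_sets) > 0)
    paste0("planted_", names(class_sets)) else character()
  bt <- gen$truth$planted_block_table
  block_sets <- list()
  if (nrow(bt) > 0) {
    for (b in unique(bt$block)) for (s in 1:2) {
      block_sets[[sprintf("block%d_side%d", b, s)]] <-
        sort(bt$gene[bt$block == b & bt$side == s])
    }
  }
  write_gmt(c(gen$truth$marker_map, class_sets, block_sets),
            out_path(config, "genesets.gmt"))
  write.table(pe, out_path(config, "truth_planted_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bt, out_path(config, "truth_planted_blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  props <- data.frame(cell_type = rownames(gen$truth$true_cell_proportions),
                      gen$truth$true_cell_proportions, check.names = FALSE)
  write.table(props, out_path(config, "truth_proportions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (r in names(gen$truth$true_de_genes)) {
    writeLines(gen$truth$true_de_genes[[r]],
               out_path(config, sprintf("truth_de_%s.tsv", r)))
  }
  log_stage(config, "simulate", c(
    sprintf("genes per region: %d", config$sim$n_genes_per_region),
    sprintf("individuals: %d CTL, %d AD, %d excluded", config$sim$n_ctl,
            config$sim$n_ad, config$sim$n_excluded),
    sprintf("planted edges: %d", nrow(pe %||% data.frame()))))
  invisible(config$out_dir)
}

read_region <- function(config, prefix, region) {
  m <- read_expression(out_path(config, sprintf("%s_%s.tsv", prefix, region)))
  meta <- read_metadata(out_path(config, "metadata.csv"))
  meta <- meta[meta$region == region & meta$sample_id %in% colnames(m), ,
               drop = FALSE]
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  region_expression(region, m, meta)
}

pipeline_regions <- function(config) {
  meta <- read_metadata(out_path(config, "metadata.csv"))
  sort(unique(meta$region))
}

#' @rdname run_pipeline
#' @export
stage_preprocess <- function(config) {
  regions <- pipeline_regions(config)
  res <- lapply(regions, function(r) {
    residualize_covariates(read_region(config, "expr", r), config$covariates)
  })
  paired <- pair_regions(res[[1L]], res[[2L]],
                         min_group_size = config$min_group_size)
  write_expression(paired$br1$matrix,
                   out_path(config, sprintf("paired_%s.tsv", regions[1L])))
  write_expression(paired$br2$matrix,
                   out_path(config, sprintf("paired_%s.tsv", regions[2L])))
  jsonlite::write_json(
    list(regions = regions,
         n_ctl = sum(paired$group_labels == "CTL"),
         n_ad = sum(paired$group_labels == "AD"),
         individuals = names(paired$group_labels),
         group = unname(paired$group_labels)),
    out_path(config, "pairing.json"), auto_unbox = TRUE, pretty = TRUE)
  log_stage(config, "preprocess", c(
    sprintf("paired individuals: %d (%d CTL, %d AD)",
            length(paired$group_labels),
            sum(paired$group_labels == "CTL"),
            sum(paired$group_labels == "AD")),
    sprintf("covariates residualized: %s",
            paste(config$covariates, collapse = ", "))))
  invisible(config$out_dir)
}

read_pairing <- function(config) {
  p <- jsonlite::read_json(out_path(config, "pairing.json"),
                           simplifyVector = TRUE)
  p$group <- setNames(p$group, p$individuals)
  p
}

paired_from_files <- function(config, prefix) {
  pairing <- read_pairing(config)
  regions <- pairing$regions
  build <- function(r) {
    m <- read_expression(out_path(config, sprintf("%s_%s.tsv", prefix, r)))
    meta <- data.frame(sample_id = colnames(m),
                       individual_id = pairing$individuals,
                       region = r,
                       CERAD = ifelse(pairing$group == "CTL", 1L, 2L),
                       stringsAsFactors = FALSE)
    region_expression(r, m, meta)
  }
  structure(list(br1 = build(regions[1L]), br2 = build(regions[2L]),
                 group_labels = pairing$group), class = "paired_dataset")
}

#' @rdname run_pipeline
#' @export
stage_ctc <- function(config) {
  pairing <- read_pairing(config)
  markers <- read_gmt(out_path(config, "markers.gmt"))
  for (r in pairing$regions) {
    m <- read_expression(out_path(config, sprintf("paired_%s.tsv", r)))
    groups <- pairing$group[sub(paste0("_", r, "$"), "", colnames(m))]
    model <- estimate_spvs(m, markers, groups, alpha = config$spv_alpha)
    spv_tab <- data.frame(cell_type = rownames(model$spvs), model$spvs,
                          check.names = FALSE)
    write.table(spv_tab, out_path(config, sprintf("spvs_%s.tsv", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    re <- region_expression(r, m, data.frame(
      sample_id = colnames(m), individual_id = pairing$individuals,
      CERAD = ifelse(groups == "CTL", 1L, 2L), stringsAsFactors = FALSE))
    corrected <- correct_cell_types(re, model)
    write_expression(corrected$matrix,
                     out_path(config, sprintf("ctc_%s.tsv", r)))
    log_stage(config, paste0("ctc_", r), c(
      sprintf("robust markers: %s",
              paste(sprintf("%s=%d", names(model$robust_markers),
                            lengths(model$robust_markers)), collapse = ", "))))
  }
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_dcnet <- function(config) {
  paired <- paired_from_files(config, "ctc")
  universe <- correlated_pair_universe(paired, fdr_corr = config$fdr_corr,
                                       rho_min = config$rho_min,
                                       block_size = config$block_size)
  network <- call_dc_edges(universe, fdr_dc = config$fdr_dc)
  regions <- network$region_ids
  de_genes <- list()
  for (i in 1:2) {
    m <- if (i == 1L) paired$br1$matrix else paired$br2$matrix
    de <- wilcoxon_de(m, paired$group_labels, config$de_cutoffs)
    write.table(de, out_path(config, sprintf("de_%s.tsv", regions[i])),
                sep = "\t", quote = FALSE, row.names = FALSE)
    de_genes[[regions[i]]] <- de$gene[de[[paste0("de_", config$de_cutoffs[1L])]]]
  }
  network <- flag_de_driven(network, de_genes)
  write_dc_edges(network, out_path(config, "dc_edges.tsv"))
  for (i in 1:2) {
    writeLines(sort(unique(if (i == 1L) universe$geneA else universe$geneB)),
               out_path(config, sprintf("correlated_genes_%s.txt",
                                        regions[i])))
  }
  jsonlite::write_json(
    list(regions = regions,
         tested_pair_count = network$tested_pair_count,
         n_edges = nrow(network$edges),
         dysregulation_percentage = network$dysregulation_percentage,
         de_driven_percentage = network$de_driven_percentage,
         params = list(fdr_corr = config$fdr_corr, rho_min = config$rho_min,
                       fdr_dc = config$fdr_dc)),
    out_path(config, "dcnet_summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_graphml(network, out_path(config, "dc_network.graphml"))
  log_stage(config, "dcnet", c(
    sprintf("correlated-pair universe: %d", network$tested_pair_count),
    sprintf("DC edges at FDR %g: %d", config$fdr_dc, nrow(network$edges)),
    sprintf("dysregulation percentage: %.4f",
            network$dysregulation_percentage)))
  invisible(config$out_dir)
}

pipeline_network <- function(config) {
  summ <- jsonlite::read_json(out_path(config, "dcnet_summary.json"),
                              simplifyVector = TRUE)
  read_dc_edges(out_path(config, "dc_edges.tsv"),
                tested_pair_count = summ$tested_pair_count)
}

#' @rdname run_pipeline
#' @export
stage_netstats <- function(config) {
  network <- pipeline_network(config)
  degrees <- node_degrees(network)
  write.table(degrees, out_path(config, "node_degrees.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage(config, "netstats", c(
    sprintf("nodes: %d; max degree: %d", nrow(degrees),
            if (nrow(degrees) > 0) max(degrees$degree) else 0L)))
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_modules <- function(config) {
  network <- pipeline_network(config)
  graph <- dc_bipartite_graph(network)
  partition <- louvain_partition(graph, seed = config$seed)
  partition <- filter_modules(partition, config$min_module_genes)
  nodes <- partition$nodes
  nodes$size_pass <- partition$size_pass[as.character(nodes$module)]
  write.table(nodes[, c("gene", "region", "module", "size_pass")],
              out_path(config, "modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pair_tag <- paste(network$region_ids, collapse = "-")
  sets <- list()
  for (mod in names(partition$modules)[partition$size_pass]) {
    for (r in names(partition$modules[[mod]])) {
      side <- paste0("BR", match(r, network$region_ids))
      sets[[paste0(mod, side, pair_tag)]] <- partition$modules[[mod]][[r]]
    }
  }
  write_gmt(sets, out_path(config, "modules.gmt"))
  jsonlite::write_json(
    list(modularity = partition$modularity,
         n_modules = length(partition$modules),
         n_passing = sum(partition$size_pass)),
    out_path(config, "modules_summary.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  log_stage(config, "modules", c(
    sprintf("modules: %d (%d with >= %d genes); Q = %.6f",
            length(partition$modules), sum(partition$size_pass),
            config$min_module_genes, partition$modularity)))
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_ora <- function(config) {
  network <- pipeline_network(config)
  graph <- dc_bipartite_graph(network)
  partition <- filter_modules(louvain_partition(graph, seed = config$seed),
                              config$min_module_genes)
  collection <- read_gmt(out_path(config, "genesets.gmt"))
  background <- lapply(setNames(network$region_ids, network$region_ids),
                       function(r) readLines(out_path(
                         config, sprintf("correlated_genes_%s.txt", r))))
  real <- run_module_ora(partition, collection, background,
                         fdr = config$fdr_ora)
  write.table(real, out_path(config, "ora.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rand <- random_modules(background, partition, n_perm = config$n_perm,
                         seed = config$seed)
  rand_res <- random_module_ora(rand, collection, background,
                                fdr = config$fdr_ora)
  efdr <- empirical_fdr(real, rand_res, threshold = config$fdr_ora)
  jsonlite::write_json(
    list(n_tests = nrow(real), n_significant = sum(real$significant),
         n_perm = config$n_perm, empirical_fdr = efdr$empirical_fdr,
         n_random_per_perm = efdr$n_random_per_perm),
    out_path(config, "ora_summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  log_stage(config, "ora", c(
    sprintf("tests: %d; significant at FDR %g: %d", nrow(real),
            config$fdr_ora, sum(real$significant)),
    sprintf("empirical FDR (%d permutations): %.4f", config$n_perm,
            efdr$empirical_fdr)))
  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' Thin argument parser behind `inst/cli/interdc.R`: subcommands are the
#' stage names plus `all`; options `--out DIR`, `--seed N` and an optional
#' `--config FILE.json` overriding threshold fields.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success, 2 on usage/config errors).
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: interdc.R <simulate|preprocess|ctc|dcnet|netstats|modules|ora|all>",
    "--out DIR [--seed N] [--config FILE.json]")
  if (length(args) < 1L) { message(usage); return(2L) }
  sub <- args[1L]
  known <- c("simulate", "preprocess", "ctc", "dcnet", "netstats", "modules",
             "ora", "all")
  if (!sub %in% known) {
    message(sprintf("unknown subcommand '%s'\n%s", sub, usage))
    return(2L)
  }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    if (i[1L] + 1L > length(args)) {
      stop(sprintf("missing value for %s", flag), call. = FALSE)
    }
    args[i[1L] + 1L]
  }
  out_dir <- opt("--out")
  if (is.null(out_dir)) { message(sprintf("--out is required\n%s", usage))
    return(2L) }
  seed <- as.integer(opt("--seed", "1"))
  config <- pipeline_config(out_dir, seed = seed)
  cfg_path <- opt("--config")
  if (!is.null(cfg_path)) {
    if (!file.exists(cfg_path)) {
      message(sprintf("config file not found: %s", cfg_path))
      return(2L)
    }
    over <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    bad <- setdiff(names(over), names(unclass(config)))
    if (length(bad) > 0L) {
      message(sprintf("unknown config field(s): %s",
                      paste(bad, collapse = ", ")))
      return(2L)
    }
    for (nm in names(over)) config[[nm]] <- over[[nm]]
  }
  status <- tryCatch({
    run_pipeline(config, stages = if (sub == "all") "all" else sub)
    0L
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    1L
  })
  status
}
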