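# File-format adapters: expression TSV/CSV (genes as rows), sample metadata
# CSV, GMT gene sets, GraphML export, JSON summaries. Writers and readers
# round-trip gene ids, sample ids, values and set memberships.

sep_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read a gene x sample expression table
#'
#' First column = gene id, header = sample ids; TSV by default, CSV when the
#' file ends in `.csv`. Duplicate gene ids are an error reporting the
#' offending line.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, sep = sep_for(path), check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  dup <- which(duplicated(ids))
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate gene id '%s' at line %d", path,
                 ids[dup[1L]], dup[1L] + 1L), call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    stop(sprintf("%s: non-numeric expression values", path), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write a gene x sample expression table
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path (TSV, or CSV if ending in `.csv`).
#' @export
write_expression <- function(m, path) {
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with at least `sample_id`, `individual_id`, `region`, `CERAD`;
#' remaining columns are covariates.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "region", "CERAD")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    stop(sprintf("%s: metadata missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  dup <- which(duplicated(meta$sample_id))
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate sample id at line %d", path, dup[1L] + 1L),
         call. = FALSE)
  }
  meta
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description (often `na`), then gene ids. Lines
#' with fewer than 3 fields raise a parse error with the line number.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("%s: malformed GMT line %d (need name, description, genes)",
                   path, i), call. = FALSE)
    }
    sets[[f[1L]]] <- f[-(1:2)]
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; default `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- descriptions[[nm]] %||% "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Export a DC network as GraphML
#'
#' @param network A `dc_network`.
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  g <- dc_bipartite_graph(network, weighted = nrow(network$edges) > 0)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a DC edge list as TSV
#'
#' Columns: geneA, regionA, geneB, regionB, per-group rho and n, z, p, q,
#' category, class and (when computed) the DE-driven flag.
#'
#' @param network A `dc_network`.
#' @param path Output path.
#' @export
write_dc_edges <- function(network, path) {
  e <- network$edges
  tab <- data.frame(geneA = e$geneA, regionA = network$region_ids[1L],
                    geneB = e$geneB, regionB = network$region_ids[2L],
                    rho_ctl = e$rho_ctl, rho_ad = e$rho_ad,
                    n_ctl = e$n_ctl, n_ad = e$n_ad, z = e$z,
                    p_dc = e$p_dc, q_dc = e$q_dc, category = e$category,
                    class = e$class, stringsAsFactors = FALSE)
  if (!is.null(e$de_driven)) tab$de_driven <- e$de_driven
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DC edge list written by [write_dc_edges()]
#'
#' @param path Edge-list TSV.
#' @param tested_pair_count The universe size (restores the dysregulation
#'   percentage); defaults to the edge count.
#' @return A `dc_network`.
#' @export
read_dc_edges <- function(path, tested_pair_count = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  regions <- c(tab$regionA[1L] %||% "BR1", tab$regionB[1L] %||% "BR2")
  if (nrow(tab) == 0L) regions <- c("BR1", "BR2")
  edges <- tab[, setdiff(names(tab), c("regionA", "regionB")), drop = FALSE]
  tested <- tested_pair_count %||% nrow(edges)
  structure(list(
    edges = edges, tested_pair_count = tested,
    dysregulation_percentage =
      if (tested > 0) 100 * nrow(edges) / tested else 0,
    dc_genes = setNames(list(sort(unique(edges$geneA)),
                             sort(unique(edges$geneB))), regions),
    region_ids = regions, params = list()), class = "dc_network")
}
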