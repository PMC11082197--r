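# Reference-free cell-type correction: per-sample surrogate proportion
# variables (SPVs) are extracted as the leading singular vector of the
# row-standardized expression of each cell type's robust marker genes, and
# bulk expression is then linearly adjusted for all SPVs. Robust markers are
# those not differentially expressed between the disease and control groups
# (one-way F-test), so the SPVs track composition rather than disease state.

#' Filter marker genes to those not associated with the group label
#'
#' A marker whose expression differs between the CTL and AD groups would
#' contaminate the surrogate proportion score with disease signal; the
#' one-way F-test (equivalent to a two-group ANOVA) removes such markers.
#' Markers with an F-test p-value >= `alpha` are retained.
#'
#' @param expr A `region_expression` (or gene x sample matrix).
#' @param markers Character vector of candidate marker gene ids.
#' @param groups Named group labels (`"CTL"`/`"AD"`) per individual or
#'   sample, aligned with the matrix columns.
#' @param alpha Rejection level of the robustness filter.
#' @return Character vector of retained markers.
#' @export
filter_robust_markers <- function(expr, markers, groups, alpha = 0.05) {
  m <- if (inherits(expr, "region_expression")) expr$matrix else expr
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) {
    stop("both groups must be non-empty for the robust-marker filter",
         call. = FALSE)
  }
  present <- markers %in% rownames(m)
  if (!all(present)) {
    warning(sprintf("%d marker(s) absent from the expression matrix dropped",
                    sum(!present)), call. = FALSE)
    markers <- markers[present]
  }
  keep <- vapply(markers, function(g) {
    y <- m[g, ]
    if (sd(y) == 0) return(TRUE)  # no group signal in a flat gene
    p <- stats::anova(stats::lm(y ~ factor(groups)))[["Pr(>F)"]][1L]
    p >= alpha
  }, logical(1L))
  markers[keep]
}

#' Estimate surrogate proportion variables from marker genes
#'
#' Per cell type, candidate markers are passed through the robust-marker
#' filter, the surviving rows are z-scored, and the leading right singular
#' vector of that submatrix is taken as the cell type's SPV (unit Euclidean
#' norm over samples). The sign is oriented so the mean correlation between
#' the SPV and its marker genes is positive, making a larger score mean more
#' of that cell type.
#'
#' @param expr A `region_expression` (or gene x sample matrix).
#' @param marker_sets Named list: cell type -> marker gene ids. Marker lists
#'   must be disjoint across cell types.
#' @param groups Group labels per sample (see [filter_robust_markers()]).
#' @param alpha Robust-marker filter level.
#' @return An object of class `spv_model` with `spvs` (cell type x sample),
#'   `robust_markers` and `variance_explained`.
#' @export
estimate_spvs <- function(expr, marker_sets, groups, alpha = 0.05) {
  m <- if (inherits(expr, "region_expression")) expr$matrix else expr
  if (anyDuplicated(unlist(marker_sets))) {
    stop("marker lists must be disjoint across cell types", call. = FALSE)
  }
  spvs <- matrix(NA_real_, length(marker_sets), ncol(m),
                 dimnames = list(names(marker_sets), colnames(m)))
  robust <- setNames(vector("list", length(marker_sets)), names(marker_sets))
  varexp <- setNames(numeric(length(marker_sets)), names(marker_sets))
  for (ct in names(marker_sets)) {
    mk <- filter_robust_markers(m, marker_sets[[ct]], groups, alpha)
    mk <- mk[apply(m[mk, , drop = FALSE], 1L, sd) > 0]
    if (length(mk) < 3L) {
      stop(sprintf("cell type '%s' has %d usable robust marker(s); need >= 3 (supply a larger marker set)",
                   ct, length(mk)), call. = FALSE)
    }
    z <- scale_rows(m[mk, , drop = FALSE])
    sv <- svd(z, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    orient <- mean(cor(v, t(m[mk, , drop = FALSE])))
    if (orient < 0) v <- -v
    spvs[ct, ] <- v
    robust[[ct]] <- mk
    varexp[ct] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(list(spvs = spvs, robust_markers = robust,
                 variance_explained = varexp), class = "spv_model")
}

#' @export
print.spv_model <- function(x, ...) {
  cat(sprintf("<spv_model> %d cell types x %d samples; robust markers: %s\n",
              nrow(x$spvs), ncol(x$spvs),
              paste(sprintf("%s=%d", names(x$robust_markers),
                            lengths(x$robust_markers)), collapse = ", ")))
  invisible(x)
}

#' Select the marker-set size whose SPV best tracks known proportions
#'
#' For each candidate size k, an SPV model is fit on the top-k markers per
#' cell type (marker lists are assumed ordered by informativeness) and the
#' absolute Spearman correlation between the designated cell type's SPV and
#' its known proportion is recorded; the size with the highest correlation
#' wins, ties going to the smaller size. With no ground truth available the
#' field default is 20 markers per type.
#'
#' @param expr A `region_expression` (or matrix).
#' @param marker_sets Named list of ordered marker gene ids per cell type.
#' @param groups Group labels per sample.
#' @param truth_proportions Numeric vector: the known proportion of
#'   `cell_type` for every sample (same order as columns).
#' @param cell_type Which cell type's recovery drives the selection.
#' @param candidate_sizes Marker counts per type to try.
#' @return List with `best_size` and the per-size `correlations`.
#' @export
select_marker_model <- function(expr, marker_sets, groups, truth_proportions,
                                cell_type = names(marker_sets)[1L],
                                candidate_sizes = c(20, 40, 80, 200, 500, 1000)) {
  m <- if (inherits(expr, "region_expression")) expr$matrix else expr
  if (length(truth_proportions) != ncol(m)) {
    stop("truth proportions must cover the same samples", call. = FALSE)
  }
  sizes <- sort(unique(pmin(candidate_sizes,
                            min(lengths(marker_sets)))))
  cors <- vapply(sizes, function(k) {
    sets_k <- lapply(marker_sets, head, k)
    model <- estimate_spvs(m, sets_k, groups)
    abs(cor(model$spvs[cell_type, ], truth_proportions, method = "spearman"))
  }, numeric(1L))
  # ties (to numerical tolerance) go to the smallest size: which.max takes
  # the first maximum and sizes are sorted ascending
  best <- sizes[which.max(round(cors, 9))]
  list(best_size = best, correlations = setNames(cors, sizes))
}

#' Linearly adjust expression for cell-type surrogate proportions
#'
#' Per gene, the OLS residual on all SPVs plus an intercept, with the gene
#' mean added back, removing the component of expression explained by
#' cell-type composition. The operation is idempotent given the same SPVs,
#' and the identity when the model has no SPVs.
#'
#' @param expr A `region_expression`.
#' @param spv_model An `spv_model` covering all samples of `expr`.
#' @return The corrected `region_expression`.
#' @export
correct_cell_types <- function(expr, spv_model) {
  stopifnot(inherits(expr, "region_expression"))
  spvs <- spv_model$spvs
  if (is.null(spvs) || nrow(spvs) == 0L) return(expr)
  if (!all(colnames(expr$matrix) %in% colnames(spvs))) {
    stop("SPVs must be defined for all samples of the expression matrix",
         call. = FALSE)
  }
  design <- as.data.frame(t(spvs[, colnames(expr$matrix), drop = FALSE]))
  expr$matrix <- residualize_matrix(expr$matrix, design)
  expr
}
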