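# Group assignment from CERAD, paired-sample selection across two regions,
# and generic linear covariate residualization. Inputs are assumed already
# normalized (continuous, log-like scale); no count-level processing here.

#' Construct a single-region expression object
#'
#' @param region_id Region label.
#' @param matrix Numeric gene x sample matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param sample_meta Data frame with one row per sample (same order as the
#'   matrix columns) and at least `sample_id`, `individual_id`, `CERAD`;
#'   further columns are treated as covariates.
#' @return An object of class `region_expression`.
#' @export
region_expression <- function(region_id, matrix, sample_meta) {
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("expression matrix needs unique gene ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("expression matrix needs unique sample ids as colnames", call. = FALSE)
  }
  if (anyNA(matrix)) {
    stop("expression matrix must not contain missing values", call. = FALSE)
  }
  need <- c("sample_id", "individual_id", "CERAD")
  if (!all(need %in% names(sample_meta))) {
    stop(sprintf("sample_meta missing column(s): %s",
                 paste(setdiff(need, names(sample_meta)), collapse = ", ")),
         call. = FALSE)
  }
  if (!identical(as.character(sample_meta$sample_id), colnames(matrix))) {
    stop("sample_meta rows must match the matrix columns in order",
         call. = FALSE)
  }
  structure(list(region_id = region_id, matrix = matrix,
                 gene_ids = rownames(matrix), sample_meta = sample_meta),
            class = "region_expression")
}

#' @export
print.region_expression <- function(x, ...) {
  cat(sprintf("<region_expression> %s: %d genes x %d samples\n",
              x$region_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Assign individuals to CTL / AD groups from CERAD scores
#'
#' CERAD 1 defines controls, CERAD 2 ("definite AD") the disease group;
#' CERAD 3 (probable) and 4 (possible) are excluded from the analysis.
#'
#' @param sample_meta Data frame with `individual_id` and `CERAD` columns.
#' @return Named character vector, individual id -> `"CTL"`, `"AD"` or
#'   `"EXCLUDED"`.
#' @export
assign_groups <- function(sample_meta) {
  cerad <- sample_meta$CERAD
  if (anyNA(cerad) || !all(cerad %in% 1:4)) {
    stop("CERAD scores must all lie in {1, 2, 3, 4}", call. = FALSE)
  }
  per_ind <- tapply(cerad, sample_meta$individual_id, function(v) {
    u <- unique(v)
    if (length(u) > 1L) {
      stop("conflicting CERAD scores for one individual", call. = FALSE)
    }
    u
  })
  out <- c("CTL", "AD", "EXCLUDED", "EXCLUDED")[as.integer(per_ind)]
  setNames(out, names(per_ind))
}

#' Pair two regions on shared CTL/AD individuals
#'
#' Retains only individuals profiled in both regions whose CERAD score puts
#' them in the CTL or AD group, and aligns columns by individual so the two
#' matrices are sample-paired. If an individual has multiple samples in one
#' region, the first by sample id is kept with a warning.
#'
#' @param exprA,exprB `region_expression` objects.
#' @param min_group_size Minimum shared individuals required per group.
#' @return An object of class `paired_dataset` with components `br1`, `br2`
#'   (restricted `region_expression`s with identical individual order) and
#'   `group_labels` (individual -> `"CTL"`/`"AD"`).
#' @export
pair_regions <- function(exprA, exprB, min_group_size = 10) {
  groups <- assign_groups(rbind(
    exprA$sample_meta[, c("individual_id", "CERAD")],
    exprB$sample_meta[, c("individual_id", "CERAD")]))
  keep_one <- function(re) {
    meta <- re$sample_meta[order(re$sample_meta$sample_id), , drop = FALSE]
    dup <- duplicated(meta$individual_id)
    if (any(dup)) {
      warning(sprintf("%s: %d duplicate sample(s) per individual dropped (first by sample id kept)",
                      re$region_id, sum(dup)), call. = FALSE)
      meta <- meta[!dup, , drop = FALSE]
    }
    region_expression(re$region_id,
                      re$matrix[, meta$sample_id, drop = FALSE], meta)
  }
  exprA <- keep_one(exprA)
  exprB <- keep_one(exprB)
  shared <- intersect(exprA$sample_meta$individual_id,
                      exprB$sample_meta$individual_id)
  shared <- shared[groups[shared] %in% c("CTL", "AD")]
  shared <- sort(shared)
  for (g in c("CTL", "AD")) {
    n_g <- sum(groups[shared] == g)
    if (n_g < min_group_size) {
      stop(sprintf("only %d shared individuals in group %s (minimum %d)",
                   n_g, g, min_group_size), call. = FALSE)
    }
  }
  subset_re <- function(re) {
    idx <- match(shared, re$sample_meta$individual_id)
    region_expression(re$region_id,
                      re$matrix[, idx, drop = FALSE],
                      re$sample_meta[idx, , drop = FALSE])
  }
  structure(list(br1 = subset_re(exprA), br2 = subset_re(exprB),
                 group_labels = groups[shared]),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %s-%s: %d paired individuals (%d CTL, %d AD)\n",
              x$br1$region_id, x$br2$region_id, length(x$group_labels),
              sum(x$group_labels == "CTL"), sum(x$group_labels == "AD")))
  invisible(x)
}

# Residualize the rows of a gene x sample matrix on a design built from
# `covariates` (data frame, one row per sample). Numeric covariates are mean
# imputed and centered; categoricals are one-hot encoded (reference level
# dropped) and centered, so the fitted intercept is the gene mean and the
# returned values are residuals + gene mean. Collinear columns are dropped
# with a warning (QR pivoting).
residualize_matrix <- function(m, covariates) {
  if (is.null(covariates) || ncol(covariates) == 0L) return(m)
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cols[[nm]] <- v
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "missing"
      lev <- sort(unique(v))
      if (length(lev) < 2L) {
        stop(sprintf("categorical covariate '%s' has fewer than 2 levels", nm),
             call. = FALSE)
      }
      for (l in lev[-1L]) cols[[paste(nm, l, sep = ".")]] <- as.numeric(v == l)
    }
  }
  x <- vapply(cols, function(v) v - mean(v), numeric(nrow(covariates)))
  x <- cbind(`(Intercept)` = 1, x)
  fit <- lm.fit(x, t(m))
  if (fit$rank < ncol(x)) {
    dropped <- colnames(x)[fit$qr$pivot[(fit$rank + 1L):ncol(x)]]
    warning(sprintf("rank-deficient covariate design; dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  res <- t(fit$residuals)
  res + rowMeans(m)
}

#' Linearly residualize expression on sample covariates
#'
#' Per gene, an ordinary least-squares fit of expression on the named
#' covariates; the returned expression is the residual plus the gene mean
#' (so gene means are preserved). Missing covariate values are imputed with
#' the covariate mean (numeric) or an explicit "missing" level (categorical).
#' The operation is idempotent.
#'
#' @param expr A `region_expression`.
#' @param covariate_names Character vector of `sample_meta` columns; empty ->
#'   identity.
#' @return The adjusted `region_expression`.
#' @export
residualize_covariates <- function(expr, covariate_names) {
  if (length(covariate_names) == 0L) return(expr)
  missing_cov <- setdiff(covariate_names, names(expr$sample_meta))
  if (length(missing_cov) > 0L) {
    stop(sprintf("covariate(s) not in sample_meta: %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  expr$matrix <- residualize_matrix(
    expr$matrix, expr$sample_meta[, covariate_names, drop = FALSE])
  expr
}
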