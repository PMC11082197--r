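#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm.fit p.adjust pnorm pt phyper rnorm rgamma runif
#'   sd wilcox.test setNames
#' @importFrom utils head read.csv read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_field("seed", "must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One Dirichlet draw per column of `alpha` replications: returns K x n matrix
# with columns on the simplex.
rdirichlet_cols <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, n)), nrow = k)
  sweep(g, 2L, colSums(g), "/")
}

# Row-wise average ranks of a numeric matrix (ties get mean rank).
rank_rows <- function(m) {
  t(apply(m, 1L, rank))
}

# Row-wise z-score; zero-variance rows are returned as all-zero.
scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  s[s == 0] <- 1
  (m - mu) / s
}
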