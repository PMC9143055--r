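#' @importFrom rlang abort warn .data
#' @importFrom stats median mad sd prcomp kmeans rnorm runif rexp rbinom
#'   pchisq kruskal.test wilcox.test p.adjust quantile setNames
#' @importFrom utils head tail
NULL

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package funnel
# through this so that a seed given once makes a whole stage reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "msitma_config_error")
  }
  bad <- if (strict_min) x <= min else x < min
  if (bad) {
    abort(sprintf("`%s` must be %s %s (got %g).", name,
                  if (strict_min) ">" else ">=", format(min), x),
          class = "msitma_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name, min = min)
  if (x != round(x)) {
    abort(sprintf("`%s` must be an integer count (got %g).", name, x),
          class = "msitma_config_error")
  }
  invisible(as.integer(x))
}

# ppm distance between two m/z values, relative to their mean
ppm_dist <- function(a, b) 1e6 * abs(a - b) / ((a + b) / 2)

# index of nearest element of sorted vector `ref` for each x (vectorised)
nearest_index <- function(x, ref) {
  i <- findInterval(x, ref)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(ref))
  ifelse(abs(x - ref[lo]) <= abs(ref[hi] - x), lo, hi)
}
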