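#' Moran's I spatial autocorrelation test (permutation)
#'
#' Computes Moran's I with binary contiguity weights taken from the
#' adjacency graph and a two-sided permutation p-value: region values are
#' randomly relabelled `n_permutations` times and the p-value is
#' `(1 + #permutations at least as extreme) / (n_permutations + 1)`,
#' extremity measured as distance from the null mean `-1/(N-1)`.
#'
#' Used as the pre-test motivating spatially structured random effects: a
#' significant I on (log) standardized ratios indicates residual spatial
#' covariance that a non-spatial Poisson model would ignore.
#'
#' @param values numeric vector, one value per region, in `graph$region_ids`
#'   order (or named by region id).
#' @param graph an `adjacency_graph`.
#' @param n_permutations number of random permutations (default 9999).
#' @param seed integer seed (required, for reproducibility).
#' @return object of class `moran_result`: list with `statistic`,
#'   `expected_null`, `p_value`, `n_permutations`, `seed`.
#' @export
morans_i_test <- function(values, graph, n_permutations = 9999, seed) {
  if (missing(seed)) stop("seed is required for the permutation test")
  ids <- graph$region_ids
  if (!is.null(names(values))) values <- values[ids]
  if (length(values) != length(ids)) {
    stop("values must have one entry per region")
  }
  if (anyNA(values)) stop("values contain NA")
  if (stats::var(values) == 0) stop("values are constant: Moran's I undefined")
  n <- length(ids)
  ei <- match(graph$edges[, 1L], ids)
  ej <- match(graph$edges[, 2L], ids)
  if (!length(ei)) stop("graph has no edges")
  s0 <- 2 * length(ei)                      # sum of binary weights
  moran_stat <- function(x) {
    z <- x - mean(x)
    # each unordered edge counted twice in sum_ij w_ij z_i z_j
    (n / s0) * (2 * sum(z[ei] * z[ej])) / sum(z * z)
  }
  i_obs <- moran_stat(values)
  e_null <- -1 / (n - 1)
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  i_perm <- .moran_perm(values, ei - 1L, ej - 1L, as.integer(n_permutations))
  extreme <- sum(abs(i_perm - e_null) >= abs(i_obs - e_null))
  structure(list(statistic = i_obs, expected_null = e_null,
                 p_value = (1 + extreme) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (null mean %.4f), permutation p = %.4g [%d perms]\n",
              x$statistic, x$expected_null, x$p_value, x$n_permutations))
  invisible(x)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
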