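#' Indirectly age-sex-standardized expected counts
#'
#' Applies whole-study-area (provincial) reference stratum rates to each
#' region's stratum populations:
#' \deqn{E_i = \sum_j (Y_j^{(s)} / n_j^{(s)}) \, n_{ij}}
#' with the reference totals \eqn{Y_j^{(s)}, n_j^{(s)}} obtained by summing
#' the cube over regions. With `pool_time = TRUE` counts and populations
#' are pooled over the cube's years (one `E_i` per region, the spatial
#' analysis design); with `pool_time = FALSE` year-specific reference rates
#' give `E_it`.
#'
#' Zero-case strata contribute rate 0 (no continuity correction). A
#' stratum with regional population but zero reference population is an
#' error (cannot happen when the reference is the cube's own total).
#'
#' @param cube a `prevalence_cube`.
#' @param pool_time logical; see Details.
#' @return object of class `expected_counts`: list with `E` (named vector
#'   over regions, or region x year matrix), `reference_rates` (per-stratum
#'   vector or stratum x year matrix), `observed` (same shape as `E`), and
#'   `pool_time`.
#' @export
expected_counts <- function(cube, pool_time = TRUE) {
  if (pool_time) {
    Yj <- apply(cube$Y, 3L, sum)                   # provincial stratum counts
    nj <- apply(cube$n, 3L, sum)
    nij <- apply(cube$n, c(1L, 3L), sum)           # region x stratum population
    if (any(nj == 0 & colSums(nij) > 0)) {
      stop("stratum with regional population but zero reference population")
    }
    rate <- ifelse(nj > 0, Yj / nj, 0)
    E <- drop(nij %*% rate)
    obs <- apply(cube$Y, 1L, sum)
  } else {
    Yjt <- apply(cube$Y, c(3L, 2L), sum)           # stratum x year
    njt <- apply(cube$n, c(3L, 2L), sum)
    rate <- ifelse(njt > 0, Yjt / njt, 0)
    nT <- length(cube$years)
    E <- matrix(0, length(cube$regions), nT,
                dimnames = list(cube$regions, cube$years))
    for (t in seq_len(nT)) {
      nij <- cube$n[, t, , drop = TRUE]
      if (any(njt[, t] == 0 & colSums(nij) > 0)) {
        stop("year ", cube$years[t],
             ": stratum with regional population but zero reference population")
      }
      E[, t] <- nij %*% rate[, t]
    }
    obs <- apply(cube$Y, c(1L, 2L), sum)
  }
  structure(list(E = E, reference_rates = rate, observed = obs,
                 pool_time = pool_time),
            class = "expected_counts")
}

#' @export
print.expected_counts <- function(x, ...) {
  cat("Expected counts (indirect age-sex standardization),",
      if (x$pool_time) "pooled over years\n" else "year-specific\n")
  cat("Sum E =", format(sum(x$E)), "| sum observed =", sum(x$observed), "\n")
  invisible(x)
}

#' Standardized morbidity ratios observed/expected
#'
#' The ratio of observed to expected counts; the relative-risk baseline is
#' the reference (provincial) prevalence, so the population-weighted mean
#' ratio is 1 when the reference is derived from the same cube.
#'
#' @param cube a `prevalence_cube`.
#' @param expected an `expected_counts` built from a matching cube.
#' @return data.frame `(region[, year], observed, expected, ratio)`; cells
#'   with zero expected count get `NA` ratio.
#' @export
standardized_ratio <- function(cube, expected) {
  if (expected$pool_time) {
    stopifnot(identical(names(expected$E), cube$regions))
    obs <- apply(cube$Y, 1L, sum)
    df <- data.frame(region = cube$regions, observed = obs,
                     expected = as.vector(expected$E))
  } else {
    stopifnot(identical(rownames(expected$E), cube$regions))
    obs <- apply(cube$Y, c(1L, 2L), sum)
    df <- data.frame(region = rep(cube$regions, length(cube$years)),
                     year = rep(cube$years, each = length(cube$regions)),
                     observed = as.vector(obs),
                     expected = as.vector(expected$E))
  }
  df$ratio <- ifelse(df$expected > 0, df$observed / df$expected, NA_real_)
  rownames(df) <- NULL
  df
}

#' Write expected counts and ratios as a delimited table
#' @param cube,expected as for [standardized_ratio()].
#' @param path output path.
#' @export
write_expected_counts <- function(cube, expected, path) {
  utils::write.table(standardized_ratio(cube, expected), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
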