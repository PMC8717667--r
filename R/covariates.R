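#' Socio-economic factor-index scores from four census variables
#'
#' One-factor maximum-likelihood factor analysis (regression/Thomson
#' scores) of the four standardized census variables: median household
#' income, proportion of adults without a high-school diploma, unemployment
#' rate, and proportion of lone-parent families. The score's sign is
#' oriented so that it correlates positively with the unemployment rate:
#' larger values indicate greater socio-economic deprivation (income's
#' loading is then expected to be negative). Scores have mean 0 across
#' regions.
#'
#' If the correlation matrix is numerically rank-1 (perfectly collinear
#' inputs), the ML factor model is degenerate and the first principal
#' component — which the one-factor model's scores coincide with in that
#' limit — is returned instead.
#'
#' @param census data.frame with columns `region_id`,
#'   `median_household_income`, `prop_no_highschool`, `unemployment_rate`,
#'   `prop_lone_parent` (an optional `prop_indigenous` column is ignored
#'   here).
#' @param weights optional per-region population weights for the factor
#'   analysis (default `NULL`, unweighted).
#' @return named numeric vector of scores (mean 0), with attributes
#'   `loadings` (named, post-orientation) and `method`.
#' @export
sefi2_scores <- function(census, weights = NULL) {
  vars <- c("median_household_income", "prop_no_highschool",
            "unemployment_rate", "prop_lone_parent")
  stopifnot(all(vars %in% names(census)))
  if (nrow(census) < 5L) stop("need at least 5 regions for factor analysis")
  X <- as.matrix(census[, vars])
  if (any(apply(X, 2L, stats::sd) == 0)) {
    stop("constant census variable: correlation matrix singular; ",
         "jitter or remove the offending column")
  }
  if (!is.null(weights)) {
    w <- weights / sum(weights)
    mu <- colSums(X * w)
    Xc <- sweep(X, 2L, mu)
    sdev <- sqrt(colSums(Xc^2 * w))
    Z <- sweep(Xc, 2L, sdev, "/")
    R <- crossprod(Z * sqrt(w))
  } else {
    Z <- scale(X)
    R <- stats::cor(X)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-8) {
    # rank-1 limit: PC1 == the shared standardized variable
    v <- eigen(R, symmetric = TRUE)$vectors[, 1L]
    scores <- drop(Z %*% v) / sqrt(ev[1L])
    loadings <- stats::setNames(v * sqrt(ev[1L]), vars)
    method <- "pc1-rank1-fallback"
  } else {
    fa <- tryCatch(
      stats::factanal(covmat = R, factors = 1L, n.obs = nrow(X)),
      error = function(e) stop("factor analysis failed (singular or ",
                               "degenerate correlation matrix): ",
                               conditionMessage(e)))
    loadings <- stats::setNames(drop(fa$loadings), vars)
    # regression (Thomson) scores: z R^{-1} Lambda
    scores <- drop(Z %*% solve(R, loadings))
    method <- "ml-factanal-regression"
  }
  if (stats::cor(scores, X[, "unemployment_rate"]) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  scores <- scores - mean(scores)
  names(scores) <- census$region_id
  attr(scores, "loadings") <- loadings
  attr(scores, "method") <- method
  scores
}

#' Assemble the region-level model design table
#'
#' Expresses covariates on their reporting scales: the Indigenous
#' population proportion per 0.1-proportion step (so a coefficient's RR
#' corresponds to an increase of 0.1 in the proportion) and the
#' deprivation factor score per 1 index unit.
#'
#' @param census a census table (see [sefi2_scores()]) including
#'   `prop_indigenous`.
#' @param graph optional `adjacency_graph`; if supplied, region sets must
#'   match and rows are ordered to `graph$region_ids`.
#' @param indigenous_step proportion step per design unit (default 0.1).
#' @param sefi2_step index units per design unit (default 1).
#' @param weights optional factor-analysis weights, passed on.
#' @return object of class `covariate_table`: data.frame
#'   `(region_id, sefi2, indigenous)` on the design scales, with attributes
#'   `scaling` (list), `loadings`, and `cor_sefi2_indigenous`.
#' @export
assemble_covariates <- function(census, graph = NULL, indigenous_step = 0.1,
                                sefi2_step = 1, weights = NULL) {
  stopifnot("prop_indigenous" %in% names(census),
            all(census$prop_indigenous >= 0 & census$prop_indigenous <= 1))
  if (!is.null(graph)) {
    if (!setequal(census$region_id, graph$region_ids)) {
      stop("census regions do not match adjacency graph regions")
    }
    census <- census[match(graph$region_ids, census$region_id), , drop = FALSE]
  }
  scores <- sefi2_scores(census, weights = weights)
  out <- data.frame(region_id = census$region_id,
                    sefi2 = as.vector(scores) / sefi2_step,
                    indigenous = census$prop_indigenous / indigenous_step)
  attr(out, "scaling") <- list(indigenous_step = indigenous_step,
                               sefi2_step = sefi2_step)
  attr(out, "loadings") <- attr(scores, "loadings")
  attr(out, "cor_sefi2_indigenous") <- stats::cor(out$sefi2, census$prop_indigenous)
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Read a census table from delimited text
#' @param path file with header columns `region_id`,
#'   `median_household_income`, `prop_no_highschool`, `unemployment_rate`,
#'   `prop_lone_parent`, `prop_indigenous`.
#' @return data.frame.
#' @export
read_census_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c(region_id = "character"))
  need <- c("region_id", "median_household_income", "prop_no_highschool",
            "unemployment_rate", "prop_lone_parent", "prop_indigenous")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("census table missing column(s): ",
                         paste(miss, collapse = ", "))
  props <- c("prop_no_highschool", "unemployment_rate", "prop_lone_parent",
             "prop_indigenous")
  for (v in props) {
    if (any(df[[v]] < 0 | df[[v]] > 1)) stop(v, " outside [0, 1]")
  }
  if (any(df$median_household_income <= 0)) stop("income must be positive")
  df
}

#' Write a covariate table (and its scaling metadata sidecar)
#' @param covariates a `covariate_table`.
#' @param path output path; scaling metadata goes to `<path>.config.json`.
#' @export
write_covariate_table <- function(covariates, path) {
  utils::write.table(as.data.frame(covariates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(attr(covariates, "scaling"),
            list(loadings = as.list(attr(covariates, "loadings")),
                 cor_sefi2_indigenous = attr(covariates, "cor_sefi2_indigenous")))
  jsonlite::write_json(meta, paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
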