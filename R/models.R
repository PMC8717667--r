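#' Sampler and model configuration
#'
#' @param model_form `"spatial"` (BYM convolution on one time slice),
#'   `"st_main"` (adds iid + RW1 temporal main effects), or
#'   `"st_interaction"` (adds the Kronecker-structured space-time
#'   interaction field).
#' @param hyperprior `"gamma"`: Gamma(1, 0.0005) priors on all random-effect
#'   precisions; `"uniform"`: Uniform(0, `uniform_upper`) on standard
#'   deviations (sensitivity analysis).
#' @param n_iterations,n_burnin,n_chains,thinning MCMC settings. Defaults:
#'   4 chains x 5000 iterations, 2500 burn-in, thin 1.
#' @param seed integer seed (required; chain c uses `seed + c - 1`).
#' @param interaction_type Knorr-Held interaction type `"I"` (iid),
#'   `"II"` (RW1 in time, unstructured in space), `"III"` (ICAR in space,
#'   unstructured in time) or `"IV"` (ICAR x RW1, the default: fully
#'   structured).
#' @param sum_to_zero impose sum-to-zero constraints on u, phi, and both
#'   margins of delta by compensated recentring each iteration (default
#'   TRUE; identifiability of the intrinsic effects).
#' @param prior_only if TRUE the likelihood is ignored and the sampler
#'   draws from the (constrained) priors at the current/fixed variances —
#'   used for sampler-correctness checks.
#' @param fixed_sigma2 named list fixing any of `v, u, gamma, phi, delta`
#'   variances (others sampled), e.g. `list(v = 1e-8)`.
#' @param uniform_upper upper bound for the uniform-on-sd hyperprior.
#' @param beta_prior_var prior variance of the intercept and regression
#'   coefficients (diffuse Normal, default 1000).
#' @return a `model_config` list.
#' @export
model_config <- function(model_form = c("spatial", "st_main", "st_interaction"),
                         hyperprior = c("gamma", "uniform"),
                         n_iterations = 5000, n_burnin = 2500, n_chains = 4,
                         thinning = 1, seed,
                         interaction_type = c("IV", "I", "II", "III"),
                         sum_to_zero = TRUE, prior_only = FALSE,
                         fixed_sigma2 = list(), uniform_upper = 10,
                         beta_prior_var = 1000) {
  if (missing(seed)) stop("seed is required in model_config()")
  stopifnot(n_iterations > n_burnin)
  structure(list(model_form = match.arg(model_form),
                 hyperprior = match.arg(hyperprior),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed),
                 interaction_type = match.arg(interaction_type),
                 sum_to_zero = isTRUE(sum_to_zero),
                 prior_only = isTRUE(prior_only),
                 fixed_sigma2 = fixed_sigma2,
                 uniform_upper = uniform_upper,
                 beta_prior_var = beta_prior_var),
            class = "model_config")
}

#' ICAR full conditional of one region's spatial effect
#'
#' The intrinsic CAR prior specifies
#' \eqn{u_i | u_{-i} \sim N(\frac{1}{N_i}\sum_j a_{ij}u_j, \sigma_u^2/N_i)}.
#'
#' @param u numeric vector of current spatial effects (graph order).
#' @param i region index or id.
#' @param graph an `adjacency_graph`.
#' @param sigma2_u conditional variance scale.
#' @return list with `mean` and `variance`.
#' @export
icar_full_conditional <- function(u, i, graph, sigma2_u) {
  if (is.character(i)) i <- match(i, graph$region_ids)
  id <- graph$region_ids[i]
  nb <- graph$neighbors[[id]]
  if (!length(nb)) stop("region ", id, " is an island: ICAR conditional undefined")
  idx <- match(nb, graph$region_ids)
  list(mean = mean(u[idx]), variance = sigma2_u / length(nb))
}

#' Fit a Bayesian hierarchical Poisson disease-mapping model by MCMC
#'
#' Fits one of three models for standardized counts with offset
#' \eqn{\log E}:
#' \describe{
#'   \item{spatial}{\eqn{\log\lambda_i = \log E_i + \beta_0 + X_i\beta + v_i + u_i}}
#'   \item{st_main}{\eqn{\log\lambda_{it} = \log E_{it} + \beta_0 + v_i + u_i + \gamma_t + \phi_t}}
#'   \item{st_interaction}{st_main \eqn{+ \delta_{it}}}
#' }
#' with `v` iid Normal, `u` intrinsic CAR on the adjacency graph, `gamma`
#' iid Normal, `phi` RW1, and `delta` Gaussian with Kronecker precision
#' structure. Precisions get Gamma(1, 0.0005) priors by default. Inference
#' is adaptive Metropolis-within-Gibbs (see `src/mcmc.cpp`). Covariates are
#' only used in the spatial form.
#'
#' Cells with zero expected count are excluded from the likelihood (a
#' message records how many).
#'
#' @param Y named vector (spatial) or region x year matrix of counts.
#' @param E an `expected_counts` object, or a vector/matrix shaped like `Y`.
#' @param X `covariate_table`, data.frame or matrix of region-level
#'   covariates (spatial form only), or `NULL`.
#' @param graph an `adjacency_graph` (no islands).
#' @param config a [model_config()].
#' @return object of class `bym_fit`: list with `draws` (matrices, rows =
#'   kept iterations across chains), `chain` (chain index per row), `data`,
#'   `config`, `convergence` (split-Rhat / ESS table), `converged` flag.
#' @export
fit_model <- function(Y, E, X = NULL, graph, config) {
  stopifnot(inherits(graph, "adjacency_graph"), inherits(config, "model_config"))
  if (length(graph$islands)) {
    stop("graph contains island region(s): ",
         paste(graph$islands, collapse = ", "))
  }
  if (inherits(E, "expected_counts")) E <- E$E
  spatial <- config$model_form == "spatial"
  if (spatial) {
    Y <- as.matrix(Y); E <- as.matrix(E)
    if (ncol(Y) != 1L) stop("spatial form expects one count per region")
  } else {
    Y <- as.matrix(Y); E <- as.matrix(E)
    if (ncol(Y) < 2L) stop("spatio-temporal forms require T >= 2")
    if (!is.null(X)) stop("covariates are only supported in the spatial form")
  }
  n <- length(graph$region_ids)
  if (nrow(Y) != n) stop("Y rows must match graph regions")
  if (!is.null(rownames(Y)) && !identical(rownames(Y), graph$region_ids)) {
    Y <- Y[graph$region_ids, , drop = FALSE]
    E <- E[graph$region_ids, , drop = FALSE]
  }
  stopifnot(identical(dim(Y), dim(E)))
  Tn <- ncol(Y)

  Xm <- matrix(0, n, 0L)
  xnames <- character(0)
  if (!is.null(X)) {
    if (inherits(X, "covariate_table") || is.data.frame(X)) {
      Xd <- as.data.frame(X)
      if ("region_id" %in% names(Xd)) {
        Xd <- Xd[match(graph$region_ids, Xd$region_id), , drop = FALSE]
        Xd$region_id <- NULL
      }
      Xm <- as.matrix(Xd)
    } else Xm <- as.matrix(X)
    stopifnot(nrow(Xm) == n)
    xnames <- colnames(Xm)
    if (is.null(xnames)) xnames <- paste0("x", seq_len(ncol(Xm)))
  }

  mask <- matrix(1L, n, Tn)
  bad <- !is.finite(E) | E <= 0 | !is.finite(Y)
  if (any(bad)) {
    message("excluding ", sum(bad), " cell(s) with zero/undefined expected count")
    mask[bad] <- 0L
    E[bad] <- 1; Y[bad] <- 0
  }
  if (all(mask == 0L)) stop("no usable cells")

  nbr <- lapply(graph$region_ids,
                function(id) match(graph$neighbors[[id]], graph$region_ids) - 1L)
  icar_rank <- n - n_components(graph)
  int_type <- match(config$interaction_type, c("I", "II", "III", "IV"))
  fixed <- rep(NA_real_, 5)
  names(fixed) <- c("v", "u", "gamma", "phi", "delta")
  for (nm in names(config$fixed_sigma2)) fixed[[nm]] <- config$fixed_sigma2[[nm]]
  init_b0 <- log(sum(Y[mask == 1L]) / sum(E[mask == 1L]))
  if (!is.finite(init_b0)) init_b0 <- 0

  old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- .bym_mcmc(Y, log(E), mask, Xm, nbr, icar_rank,
                             has_temporal = !spatial,
                             has_interaction = config$model_form == "st_interaction",
                             int_type = int_type,
                             n_iter = config$n_iterations,
                             n_burnin = config$n_burnin,
                             thin = config$thinning,
                             prior_type = if (config$hyperprior == "gamma") 0L else 1L,
                             prior_shape = 1, prior_rate = 5e-4,
                             prior_upper = config$uniform_upper,
                             fixed_sigma2 = unname(fixed),
                             prior_only = config$prior_only,
                             sum_to_zero = config$sum_to_zero,
                             beta_prior_var = config$beta_prior_var,
                             init_beta0 = init_b0)
  }
  keep <- length(chains[[1L]]$beta0)
  draws <- list(
    beta0 = do.call(c, lapply(chains, `[[`, "beta0")),
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    v = do.call(rbind, lapply(chains, `[[`, "v")),
    u = do.call(rbind, lapply(chains, `[[`, "u")),
    gamma = do.call(rbind, lapply(chains, `[[`, "gamma")),
    phi = do.call(rbind, lapply(chains, `[[`, "phi")),
    delta = do.call(rbind, lapply(chains, `[[`, "delta")),
    sigma2 = do.call(rbind, lapply(chains, `[[`, "sigma2")))
  colnames(draws$sigma2) <- c("v", "u", "gamma", "phi", "delta")
  if (ncol(draws$beta)) colnames(draws$beta) <- xnames
  colnames(draws$v) <- colnames(draws$u) <- graph$region_ids
  if (!spatial) {
    yrs <- colnames(Y)
    if (is.null(yrs)) yrs <- paste0("t", seq_len(Tn))
    colnames(draws$gamma) <- colnames(draws$phi) <- yrs
    if (ncol(draws$delta)) {
      colnames(draws$delta) <-
        as.vector(t(outer(graph$region_ids, yrs, paste, sep = ":")))
    }
  }
  chain_id <- rep(seq_len(config$n_chains), each = keep)

  fit <- structure(list(draws = draws, chain = chain_id,
                        data = list(Y = Y, E = E, X = Xm, graph = graph,
                                    T = Tn, mask = mask),
                        config = config, n_kept = keep * config$n_chains),
                   class = "bym_fit")
  fit$convergence <- .convergence_table(fit)
  fit$converged <- all(is.na(fit$convergence$rhat) |
                         fit$convergence$rhat < 1.05)
  if (!fit$converged && !config$prior_only) {
    warning("possible non-convergence: max split-Rhat = ",
            round(max(fit$convergence$rhat, na.rm = TRUE), 3))
  }
  fit
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("Bayesian disease-mapping fit (", x$config$model_form, "), ",
      x$n_kept, " kept draws over ", x$config$n_chains, " chain(s)\n", sep = "")
  cat("Posterior median intercept:", round(stats::median(x$draws$beta0), 4), "\n")
  if (ncol(x$draws$beta)) {
    for (k in seq_len(ncol(x$draws$beta))) {
      b <- x$draws$beta[, k]
      cat(sprintf("  beta[%s]: median %.4f (log scale), RR %.4f (%.4f, %.4f)\n",
                  colnames(x$draws$beta)[k], stats::median(b),
                  exp(stats::median(b)),
                  exp(stats::quantile(b, 0.025)), exp(stats::quantile(b, 0.975))))
    }
  }
  if (!is.null(x$convergence)) {
    cat("Max split-Rhat:", round(max(x$convergence$rhat, na.rm = TRUE), 3),
        if (isTRUE(x$converged)) "(converged)\n" else "(check convergence)\n")
  }
  invisible(x)
}

# monitored scalars: intercept, betas, sampled log-variances
.monitored_scalars <- function(fit) {
  out <- list(beta0 = fit$draws$beta0)
  for (k in seq_len(ncol(fit$draws$beta))) {
    out[[paste0("beta_", colnames(fit$draws$beta)[k])]] <- fit$draws$beta[, k]
  }
  active <- c("v", "u")
  if (fit$config$model_form != "spatial") active <- c(active, "gamma", "phi")
  if (fit$config$model_form == "st_interaction") active <- c(active, "delta")
  active <- setdiff(active, names(fit$config$fixed_sigma2))
  if (!fit$config$prior_only) {
    for (nm in active) out[[paste0("log_sigma2_", nm)]] <- log(fit$draws$sigma2[, nm])
  }
  out
}

.convergence_table <- function(fit) {
  mon <- .monitored_scalars(fit)
  data.frame(parameter = names(mon),
             rhat = vapply(mon, split_rhat, numeric(1L), chain = fit$chain),
             ess = vapply(mon, ess_bulk, numeric(1L), chain = fit$chain),
             row.names = NULL)
}

#' Split-chain potential scale reduction factor (split-Rhat)
#' @param x numeric vector of draws (chains stacked).
#' @param chain integer chain index per draw.
#' @return Rhat (NA if fewer than 4 draws per split-chain or zero variance).
#' @export
split_rhat <- function(x, chain) {
  parts <- split(x, chain)
  halves <- unlist(lapply(parts, function(d) {
    h <- length(d) %/% 2L
    list(d[seq_len(h)], d[seq.int(h + 1L, 2L * h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1L]])
  if (nn < 4L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1L))
  vars <- vapply(halves, stats::var, numeric(1L))
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- nn * stats::var(means)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Crude bulk effective sample size (within-chain autocorrelation)
#' @inheritParams split_rhat
#' @return effective sample size estimate.
#' @export
ess_bulk <- function(x, chain) {
  parts <- split(x, chain)
  ess <- vapply(parts, function(d) {
    nn <- length(d)
    if (stats::var(d) == 0) return(NA_real_)
    ac <- stats::acf(d, lag.max = min(100L, nn - 1L), plot = FALSE)$acf[-1L]
    # initial positive sequence
    pos <- which(ac <= 0)
    if (length(pos)) ac <- ac[seq_len(pos[1L] - 1L)]
    nn / (1 + 2 * sum(ac))
  }, numeric(1L))
  sum(ess, na.rm = !all(is.na(ess)))
}

#' Per-draw linear predictor, fitted rates, and relative risks
#'
#' `fitted_linpred` returns the draws of \eqn{\eta - \log E} (the log
#' relative risk); `fitted_lambda` multiplies by E; `fitted_relative_risks`
#' summarises RR draws per region(-year) as posterior median and equal-tailed
#' 95% credible interval.
#'
#' @param fit a `bym_fit`.
#' @return `fitted_linpred`/`fitted_lambda`: draws matrix (rows = draws,
#'   columns = region or region:year cells, region-major). Excluded cells
#'   are `NA`.
#' @export
fitted_linpred <- function(fit) {
  d <- fit$draws
  n <- nrow(fit$data$Y); Tn <- fit$data$T
  S <- fit$n_kept
  spatial <- fit$config$model_form == "spatial"
  Xb <- if (ncol(d$beta)) d$beta %*% t(fit$data$X) else matrix(0, S, n)
  eta_region <- d$beta0 + Xb + d$v + d$u          # S x n
  if (spatial) {
    colnames(eta_region) <- fit$data$graph$region_ids
    eta_region[, fit$data$mask[, 1L] == 0L] <- NA_real_
    return(eta_region)
  }
  eta <- matrix(NA_real_, S, n * Tn)
  for (i in seq_len(n)) {
    for (t in seq_len(Tn)) {
      col <- (i - 1L) * Tn + t
      e <- eta_region[, i] + d$gamma[, t] + d$phi[, t]
      if (ncol(d$delta)) e <- e + d$delta[, col]
      eta[, col] <- e
    }
  }
  yrs <- colnames(fit$data$Y)
  if (is.null(yrs)) yrs <- paste0("t", seq_len(Tn))
  colnames(eta) <- as.vector(t(outer(fit$data$graph$region_ids, yrs,
                                     paste, sep = ":")))
  eta[, as.vector(t(fit$data$mask)) == 0L] <- NA_real_
  eta
}

#' @rdname fitted_linpred
#' @export
fitted_lambda <- function(fit) {
  eta <- fitted_linpred(fit)
  Evec <- if (fit$config$model_form == "spatial") fit$data$E[, 1L]
          else as.vector(t(fit$data$E))
  sweep(exp(eta), 2L, Evec, "*")
}

#' @rdname fitted_linpred
#' @param draws if `TRUE` return the RR draws matrix instead of summaries.
#' @return `fitted_relative_risks`: data.frame `(unit[, region, year],
#'   rr_median, rr_lo, rr_hi)` unless `draws = TRUE`.
#' @export
fitted_relative_risks <- function(fit, draws = FALSE) {
  rr <- exp(fitted_linpred(fit))
  if (draws) return(rr)
  qs <- apply(rr, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              na.rm = FALSE, names = FALSE)
  out <- data.frame(unit = colnames(rr), rr_median = qs[1L, ],
                    rr_lo = qs[2L, ], rr_hi = qs[3L, ])
  if (fit$config$model_form != "spatial") {
    parts <- strsplit(out$unit, ":", fixed = TRUE)
    out$region <- vapply(parts, `[[`, "", 1L)
    out$year <- vapply(parts, `[[`, "", 2L)
  } else {
    out$region <- out$unit
  }
  rownames(out) <- NULL
  out
}

#' Covariate effects on the log and relative-risk scales
#'
#' Reports each regression coefficient both as the posterior log-scale
#' coefficient and as the RR per design-scale step (e.g. per 0.1 increase
#' in a population proportion), with 95% equal-tailed credible intervals.
#'
#' @param fit a `bym_fit` with covariates.
#' @return data.frame `(covariate, log_median, log_lo, log_hi, rr_median,
#'   rr_lo, rr_hi)`.
#' @export
covariate_effects <- function(fit) {
  if (!ncol(fit$draws$beta)) stop("fit has no covariates")
  qs <- apply(fit$draws$beta, 2L, stats::quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  data.frame(covariate = colnames(fit$draws$beta),
             log_median = qs[1L, ], log_lo = qs[2L, ], log_hi = qs[3L, ],
             rr_median = exp(qs[1L, ]), rr_lo = exp(qs[2L, ]),
             rr_hi = exp(qs[3L, ]), row.names = NULL)
}

#' Persist posterior draws and run metadata
#'
#' Draws go to a long-format delimited file `(parameter, chain, iteration,
#' value)`; the configuration (with seed) is echoed to `<path>.meta.json`.
#'
#' @param fit a `bym_fit`.
#' @param path output path for the draws table.
#' @param parameters which draw blocks to write (default scalars +
#'   variances; writing full latent fields can be large).
#' @export
write_fit_draws <- function(fit, path,
                            parameters = c("beta0", "beta", "sigma2")) {
  rows <- list()
  for (nm in parameters) {
    d <- fit$draws[[nm]]
    if (is.null(d)) next
    if (is.null(dim(d))) d <- matrix(d, ncol = 1L, dimnames = list(NULL, nm))
    if (!ncol(d)) next
    cn <- colnames(d)
    if (is.null(cn)) cn <- paste0(nm, seq_len(ncol(d)))
    else if (nm != "beta0") cn <- paste0(nm, "_", cn)
    for (k in seq_len(ncol(d))) {
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = cn[k], chain = fit$chain,
                   iteration = stats::ave(seq_along(fit$chain), fit$chain,
                                          FUN = seq_along),
                   value = d[, k])
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- unclass(fit$config)
  meta$fixed_sigma2 <- as.list(meta$fixed_sigma2)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
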