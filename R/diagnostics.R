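#' Per-draw Poisson log-likelihood matrix
#' @param fit a `bym_fit`.
#' @return S x n_obs matrix of log p(y_obs | lambda_draw) over included
#'   cells only.
#' @keywords internal
loglik_matrix <- function(fit) {
  lam <- fitted_lambda(fit)
  y <- if (fit$config$model_form == "spatial") fit$data$Y[, 1L]
       else as.vector(t(fit$data$Y))
  keep <- !is.na(lam[1L, ])
  lam <- lam[, keep, drop = FALSE]
  y <- y[keep]
  ll <- matrix(0, nrow(lam), ncol(lam), dimnames = dimnames(lam))
  for (j in seq_len(ncol(lam))) ll[, j] <- stats::dpois(y[j], lam[, j], log = TRUE)
  ll
}

#' Deviance information criterion
#'
#' DIC = D-bar + pD with D-bar the posterior mean deviance (deviance =
#' -2 x Poisson log-likelihood) and pD = D-bar - D(theta-bar), the
#' deviance evaluated at the posterior mean of the linear predictor.
#' Lower is better.
#'
#' @param fit a `bym_fit` with at least 100 kept draws.
#' @return list with `dic`, `p_effective`, `mean_deviance`.
#' @export
dic <- function(fit) {
  if (fit$n_kept < 100L) stop("need at least 100 post-burn-in draws for DIC")
  eta <- fitted_linpred(fit)
  keep <- !is.na(eta[1L, ])
  Evec <- if (fit$config$model_form == "spatial") fit$data$E[, 1L]
          else as.vector(t(fit$data$E))
  y <- if (fit$config$model_form == "spatial") fit$data$Y[, 1L]
       else as.vector(t(fit$data$Y))
  lam <- sweep(exp(eta[, keep, drop = FALSE]), 2L, Evec[keep], "*")
  y <- y[keep]
  dev_draw <- numeric(nrow(lam))
  for (s in seq_len(nrow(lam))) {
    dev_draw[s] <- -2 * sum(stats::dpois(y, lam[s, ], log = TRUE))
  }
  dbar <- mean(dev_draw)
  lam_at_mean <- Evec[keep] * exp(colMeans(eta[, keep, drop = FALSE]))
  dhat <- -2 * sum(stats::dpois(y, lam_at_mean, log = TRUE))
  pd <- dbar - dhat
  list(dic = dbar + pd, p_effective = pd, mean_deviance = dbar)
}

#' Conditional predictive ordinates
#'
#' CPO_i approximated by the harmonic-mean identity over posterior draws:
#' \eqn{CPO_i = [S^{-1} \sum_s 1/p(y_i | \theta_s)]^{-1}}, the standard
#' single-run estimate of the leave-one-out predictive density. Summarised
#' as \eqn{\sum_i \log CPO_i} (higher is better). Observations where any
#' draw has vanishing likelihood are flagged as numerically unstable.
#'
#' @param fit a `bym_fit`.
#' @return list with `cpo_i` (named vector), `sum_log_cpo`, `unstable`
#'   (character vector of flagged units).
#' @export
cpo <- function(fit) {
  ll <- loglik_matrix(fit)
  # log CPO_i = -logmeanexp(-ll_i)
  log_cpo <- -apply(-ll, 2L, .log_mean_exp)
  unstable <- colnames(ll)[apply(ll, 2L, min) < -700]
  if (length(unstable)) {
    warning("CPO numerically unstable for: ",
            paste(utils::head(unstable, 5L), collapse = ", "),
            if (length(unstable) > 5L) ", ..." else "")
  }
  list(cpo_i = stats::setNames(exp(log_cpo), colnames(ll)),
       sum_log_cpo = sum(log_cpo), unstable = unstable)
}

.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Probability integral transform for count observations
#'
#' For discrete outcomes the randomized PIT draws
#' \eqn{U_i \sim Uniform(F_i(y_i - 1), F_i(y_i))} with \eqn{F_i} the
#' *leave-one-out* predictive CDF, estimated from a single run by
#' importance weighting each draw with \eqn{1/p(y_i|\theta_s)} (the same
#' identity underlying the CPO): the plain posterior-predictive CDF
#' conditions on \eqn{y_i} itself and is center-biased. Under a
#' well-calibrated model the \eqn{U_i} are approximately iid Uniform(0,1).
#' With `randomize = FALSE` the interval midpoint is returned.
#'
#' @param fit a `bym_fit`.
#' @param randomize logical, default TRUE.
#' @param seed integer seed (required when `randomize`).
#' @return named vector of PIT values in `[0, 1]`.
#' @export
pit <- function(fit, randomize = TRUE, seed) {
  if (randomize && missing(seed)) stop("seed required for randomized PIT")
  lam <- fitted_lambda(fit)
  y <- if (fit$config$model_form == "spatial") fit$data$Y[, 1L]
       else as.vector(t(fit$data$Y))
  keep <- !is.na(lam[1L, ])
  lam <- lam[, keep, drop = FALSE]; y <- y[keep]
  Fhi <- Flo <- numeric(ncol(lam))
  for (j in seq_len(ncol(lam))) {
    lw <- -stats::dpois(y[j], lam[, j], log = TRUE)   # log importance weights
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    Fhi[j] <- sum(w * stats::ppois(y[j], lam[, j]))
    Flo[j] <- if (y[j] > 0) sum(w * stats::ppois(y[j] - 1, lam[, j])) else 0
  }
  if (randomize) {
    old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    u <- stats::runif(length(y), Flo, Fhi)
  } else {
    u <- (Flo + Fhi) / 2
  }
  stats::setNames(u, colnames(lam))
}

#' Variance partitioning across random-effect terms
#'
#' For each random effect present (v, u, gamma, phi, delta) computes the
#' empirical variance, across its own index, of the posterior-mean effect
#' values, and expresses each as a percentage of the total. This is the
#' standard reporting device for intrinsic effects (whose marginal prior
#' variance is improper); shares sum to exactly 100.
#'
#' @param fit a `bym_fit`.
#' @return named numeric vector of percentages.
#' @export
variance_shares <- function(fit) {
  eff <- list(v = colMeans(fit$draws$v), u = colMeans(fit$draws$u))
  if (fit$config$model_form != "spatial") {
    eff$gamma <- colMeans(fit$draws$gamma)
    eff$phi <- colMeans(fit$draws$phi)
  }
  if (fit$config$model_form == "st_interaction") {
    eff$delta <- colMeans(fit$draws$delta)
  }
  vars <- vapply(eff, function(e) stats::var(as.vector(e)), numeric(1L))
  if (sum(vars) == 0) stop("all random-effect variances are zero")
  100 * vars / sum(vars)
}

#' Posterior exceedance probabilities Pr(RR > threshold)
#'
#' Fraction of posterior draws whose fitted relative risk exceeds the
#' threshold, per region(-year); with threshold 1 this is the probability
#' of elevated risk relative to the reference (provincial) rate.
#'
#' @param fit a `bym_fit`.
#' @param threshold RR threshold (default 1).
#' @return named vector of probabilities in `[0, 1]`.
#' @export
exceedance_probabilities <- function(fit, threshold = 1) {
  rr <- fitted_relative_risks(fit, draws = TRUE)
  apply(rr, 2L, function(x) mean(x > threshold))
}

#' Region ranking by fitted RR with credible-interval significance class
#'
#' Units sorted by posterior median RR; classified `"above"`/`"below"`
#' when the equal-tailed 95% interval excludes 1, else `"null"`.
#'
#' @param fit a `bym_fit`.
#' @return data.frame `(unit, rr_median, rr_lo, rr_hi, class)`, sorted.
#' @export
rr_interval_ranking <- function(fit) {
  rr <- fitted_relative_risks(fit)
  rr$class <- ifelse(rr$rr_lo > 1, "above",
                     ifelse(rr$rr_hi < 1, "below", "null"))
  rr <- rr[order(rr$rr_median), ]
  rownames(rr) <- NULL
  rr
}

#' Full diagnostics report for a fitted model
#'
#' @param fit a `bym_fit`.
#' @param seed seed for the randomized PIT.
#' @param exceedance_threshold RR threshold (default 1).
#' @return object of class `diagnostics_report`: list with `dic`,
#'   `p_effective`, `sum_log_cpo`, `cpo_i`, `pit_i`, `pit_ks` (KS statistic
#'   and p-value of PIT vs Uniform), `variance_shares`, `exceedance`,
#'   `rr_summary`.
#' @export
diagnostics_report <- function(fit, seed, exceedance_threshold = 1) {
  d <- dic(fit)
  cp <- cpo(fit)
  pits <- pit(fit, randomize = TRUE, seed = seed)
  ks <- suppressWarnings(stats::ks.test(pits, "punif"))
  structure(list(dic = d$dic, p_effective = d$p_effective,
                 sum_log_cpo = cp$sum_log_cpo, cpo_i = cp$cpo_i,
                 pit_i = pits,
                 pit_ks = list(statistic = unname(ks$statistic),
                               p_value = ks$p.value),
                 variance_shares = variance_shares(fit),
                 exceedance = exceedance_probabilities(fit,
                                                       exceedance_threshold),
                 rr_summary = rr_interval_ranking(fit)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("DIC %.2f (pD %.2f) | sum log CPO %.2f | PIT KS %.3f (p %.3g)\n",
              x$dic, x$p_effective, x$sum_log_cpo, x$pit_ks$statistic,
              x$pit_ks$p_value))
  cat("Variance shares (%):\n")
  print(round(x$variance_shares, 2))
  invisible(x)
}

#' Write a diagnostics report to delimited files
#'
#' `<path>_summary.tsv` holds the scalar criteria and variance shares;
#' `<path>_units.tsv` the per-unit RR/exceedance table.
#'
#' @param report a `diagnostics_report`.
#' @param path output path stem.
#' @export
write_diagnostics_report <- function(report, path) {
  shares <- report$variance_shares
  summ <- data.frame(
    quantity = c("dic", "p_effective", "sum_log_cpo", "pit_ks_statistic",
                 "pit_ks_p_value", paste0("variance_share_", names(shares))),
    value = c(report$dic, report$p_effective, report$sum_log_cpo,
              report$pit_ks$statistic, report$pit_ks$p_value, shares))
  utils::write.table(summ, paste0(path, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  units <- report$rr_summary
  units$exceedance <- report$exceedance[units$unit]
  utils::write.table(units, paste0(path, "_units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join RR/exceedance fields onto a GeoJSON FeatureCollection
#'
#' Adds `rr_median`, `rr_lo`, `rr_hi`, `exceedance`, `class` properties to
#' each feature (matched on the id property) and writes plain GeoJSON,
#' ready for choropleth rendering elsewhere.
#'
#' @param report a `diagnostics_report` from a spatial fit.
#' @param geojson_in,geojson_out input/output GeoJSON paths.
#' @param id_property feature property holding the region id.
#' @export
export_choropleth_geojson <- function(report, geojson_in, geojson_out,
                                      id_property = "region_id") {
  gj <- jsonlite::read_json(geojson_in)
  rr <- report$rr_summary
  rownames(rr) <- rr$unit
  gj$features <- lapply(gj$features, function(f) {
    id <- as.character(f$properties[[id_property]])
    if (id %in% rr$unit) {
      f$properties$rr_median <- rr[id, "rr_median"]
      f$properties$rr_lo <- rr[id, "rr_lo"]
      f$properties$rr_hi <- rr[id, "rr_hi"]
      f$properties$exceedance <- unname(report$exceedance[id])
      f$properties$class <- rr[id, "class"]
    }
    f
  })
  jsonlite::write_json(gj, geojson_out, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(geojson_out)
}
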