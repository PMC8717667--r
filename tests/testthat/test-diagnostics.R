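test_that("DIC collapses to the plug-in deviance at a point-mass posterior", {
  lam <- matrix(rep(c(4, 9, 2, 7), each = 120), 120, 4)
  y <- c(5L, 8L, 2L, 6L)
  fit <- fake_fit(lam, y)
  d <- dic(fit)
  expect_equal(d$p_effective, 0, tolerance = 1e-9)
  expect_equal(d$dic, -2 * sum(dpois(y, c(4, 9, 2, 7), log = TRUE)),
               tolerance = 1e-9)
})

test_that("DIC prefers the saturated mean fit on heterogeneous counts", {
  set.seed(1)
  y <- c(2L, 25L, 7L, 40L, 1L, 18L, 30L, 3L, 12L, 50L)
  S <- 150
  lam_sat <- matrix(rep(pmax(y, 0.5), each = S), S, 10)
  lam_const <- matrix(mean(y), S, 10)
  expect_lt(dic(fake_fit(lam_sat, y))$dic,
            dic(fake_fit(lam_const, y))$dic)
})

test_that("CPO equals the single-draw likelihood and ranks misspecified models", {
  y <- c(3L, 10L)
  one <- matrix(c(4, 8), 1, 2)
  # a single draw: harmonic mean of one value
  fit1 <- fake_fit(one[rep(1, 120), , drop = FALSE], y)
  cp <- cpo(fit1)
  expect_equal(unname(cp$cpo_i), dpois(y, c(4, 8)), tolerance = 1e-12)
  expect_equal(cp$sum_log_cpo, sum(dpois(y, c(4, 8), log = TRUE)),
               tolerance = 1e-12)
  # gross mean shift worsens the predictive score
  set.seed(2)
  y2 <- rpois(30, 10)
  S <- 400
  lam_good <- matrix(exp(rnorm(S * 30, log(10), 0.05)), S, 30)
  lam_bad <- matrix(exp(rnorm(S * 30, log(30), 0.05)), S, 30)
  expect_gt(cpo(fake_fit(lam_good, y2))$sum_log_cpo,
            cpo(fake_fit(lam_bad, y2))$sum_log_cpo)
})

test_that("CPO harmonic mean tracks brute-force leave-one-out on a conjugate toy", {
  # Gamma(a, b) prior on a shared Poisson rate: closed-form LOO predictive
  # p(y_i | y_-i) is negative binomial; compare with the harmonic-mean
  # estimate computed from posterior draws of the full posterior.
  set.seed(3)
  n <- 50
  y <- rpois(n, 5)
  a0 <- 2; b0 <- 0.4
  S <- 40000
  lam_draws <- rgamma(S, a0 + sum(y), b0 + n)
  lam <- matrix(lam_draws, S, n)
  est <- cpo(fake_fit(lam, y))
  loo <- vapply(seq_len(n), function(i) {
    a <- a0 + sum(y[-i]); b <- b0 + (n - 1)
    dnbinom(y[i], size = a, prob = b / (b + 1), log = TRUE)
  }, numeric(1))
  expect_equal(est$sum_log_cpo, sum(loo), tolerance = 0.05)
})

test_that("PIT hits its analytic endpoints and midpoints", {
  # y far above all predictive mass
  fithi <- fake_fit(matrix(1, 150, 1), 30L)
  expect_gt(pit(fithi, seed = 1), 1 - 1e-6)
  # symmetric two-point predictive at its median observation:
  # F(0) = P(y=0), F(1) covers the midpoint 0.5 for lambda = log(2)
  lam0 <- log(2)                     # P(Y=0) = 0.5 under Poisson(log 2)
  fitmid <- fake_fit(matrix(lam0, 200, 1), 0L)
  expect_equal(unname(pit(fitmid, randomize = FALSE)), 0.25)
  fitmid1 <- fake_fit(matrix(lam0, 200, 1), 1L)
  mid1 <- (ppois(0, lam0) + ppois(1, lam0)) / 2
  expect_equal(unname(pit(fitmid1, randomize = FALSE)), mid1)
  # randomized PIT is seed-deterministic and in [F(y-1), F(y)]
  p1 <- pit(fitmid1, seed = 5)
  p2 <- pit(fitmid1, seed = 5)
  expect_identical(p1, p2)
  expect_true(p1 >= ppois(0, lam0) && p1 <= ppois(1, lam0))
})

test_that("variance shares partition to 100 with expected degenerate cases", {
  b <- generate_bundle(seed = 4, n_rows = 3, n_cols = 4, years = 2001:2004,
                       model_form = "st_interaction")
  E <- expected_counts(b$cube, pool_time = FALSE)
  Y <- apply(b$cube$Y, c(1L, 2L), sum)
  fit <- quiet_fit(Y, E, NULL, b$graph,
                   model_config("st_interaction", n_iterations = 500,
                                n_burnin = 250, n_chains = 1, seed = 5))
  vs <- variance_shares(fit)
  expect_equal(sum(vs), 100, tolerance = 1e-9)
  expect_named(vs, c("v", "u", "gamma", "phi", "delta"))
  # hand-built: only u varies
  lam <- matrix(rep(c(1, 2, 3, 4), each = 50), 50, 4)
  f2 <- fake_fit(lam, c(1L, 2L, 3L, 4L))
  vs2 <- variance_shares(f2)
  expect_equal(unname(vs2["u"]), 100)
  expect_equal(unname(vs2["v"]), 0)
})

test_that("exceedance probabilities count draws above the threshold", {
  lam <- matrix(c(0.8, 0.9, 1.1, 1.2), 4, 1)
  fit <- fake_fit(lam, 1L)
  expect_equal(unname(exceedance_probabilities(fit, 1)), 0.5)
  expect_equal(unname(exceedance_probabilities(fit, 0)), 1)
  # monotone non-increasing in the threshold
  th <- seq(0, 2, by = 0.25)
  ex <- vapply(th, function(t) exceedance_probabilities(fit, t), numeric(1))
  expect_true(all(diff(ex) <= 0))
})

test_that("RR ranking classifies intervals against the null", {
  set.seed(6)
  S <- 4000
  lam <- cbind(exp(rnorm(S, 0.075, 0.015)),   # interval clearly above 1
               exp(rnorm(S, 0.05, 0.04)),     # interval straddles 1
               exp(rnorm(S, -0.15, 0.02)))    # interval clearly below 1
  fit <- fake_fit(lam, c(1L, 1L, 1L))
  rk <- rr_interval_ranking(fit)
  cls <- setNames(rk$class, rk$unit)
  expect_identical(unname(cls[c("F01", "F02", "F03")]),
                   c("above", "null", "below"))
  expect_false(is.unsorted(rk$rr_median))
})

test_that("diagnostics report assembles, prints, and writes", {
  b <- generate_bundle(seed = 7, n_rows = 3, n_cols = 4, years = 2001:2003,
                       model_form = "spatial")
  E <- expected_counts(b$cube, pool_time = TRUE)
  Y <- apply(b$cube$Y, 1L, sum)
  fit <- quiet_fit(Y, E, NULL, b$graph,
                   model_config("spatial", n_iterations = 600,
                                n_burnin = 300, n_chains = 1, seed = 8))
  rep <- diagnostics_report(fit, seed = 9)
  expect_s3_class(rep, "diagnostics_report")
  expect_equal(sum(rep$variance_shares), 100, tolerance = 1e-9)
  expect_true(all(rep$exceedance >= 0 & rep$exceedance <= 1))
  expect_true(all(rep$cpo_i > 0))
  expect_output(print(rep), "DIC")
  stem <- withr::local_tempfile()
  write_diagnostics_report(rep, stem)
  summ <- read.delim(paste0(stem, "_summary.tsv"))
  expect_true("dic" %in% summ$quantity)
  units <- read.delim(paste0(stem, "_units.tsv"))
  expect_identical(nrow(units), length(b$graph$region_ids))
})

test_that("choropleth export joins fields onto GeoJSON properties", {
  feats <- grid_polygons(2, 2)
  gj <- list(type = "FeatureCollection", features = lapply(feats, function(f) {
    list(type = "Feature", properties = list(region_id = f$id),
         geometry = list(type = "Polygon",
                         coordinates = list(apply(f$coords, 1L, as.list,
                                                  simplify = FALSE))))
  }))
  gin <- withr::local_tempfile(fileext = ".geojson")
  gout <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, gin, auto_unbox = TRUE)
  g <- build_adjacency_graph(feats)
  set.seed(10)
  E <- setNames(rep(30, 4), g$region_ids)
  Y <- setNames(rpois(4, 30), g$region_ids)
  fit <- quiet_fit(Y, E, NULL, g,
                   model_config("spatial", n_iterations = 400,
                                n_burnin = 200, n_chains = 1, seed = 11))
  rep <- diagnostics_report(fit, seed = 12)
  export_choropleth_geojson(rep, gin, gout)
  out <- jsonlite::read_json(gout)
  expect_true(all(vapply(out$features,
                         function(f) !is.null(f$properties$rr_median),
                         logical(1))))
})
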