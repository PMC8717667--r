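test_that("ICAR full conditional matches the closed form", {
  g <- path_graph()
  fc <- icar_full_conditional(c(1, NA, 3), 2, g, sigma2_u = 2)
  expect_equal(fc$mean, 2)
  expect_equal(fc$variance, 1)
  # all-zero neighbours
  fc0 <- icar_full_conditional(c(0, 5, 0), 2, g, sigma2_u = 1)
  expect_equal(fc0$mean, 0)
  # variance formula: sigma2 / N_i
  g4 <- build_adjacency_graph(data.frame(a = c("X", "X", "X", "X"),
                                         b = c("A", "B", "C", "D")))
  expect_equal(icar_full_conditional(rep(0, 5), "X", g4, 1)$variance, 0.25)
  expect_error(icar_full_conditional(
    rep(0, 3), 3,
    suppressWarnings(build_adjacency_graph(data.frame(a = "A", b = "B"),
                                           region_ids = c("A", "B", "C"))),
    1), "island")
})

test_that("degenerate variances reduce the intercept to the Poisson MLE", {
  g <- generate_lattice(4, 4, 0, seed = 2)
  E <- setNames(rep(10, 16), g$region_ids)
  set.seed(3)
  Y <- setNames(rpois(16, 10), g$region_ids)
  cfg <- model_config("spatial", n_iterations = 2000, n_burnin = 1000,
                      n_chains = 2, seed = 42,
                      fixed_sigma2 = list(v = 1e-8, u = 1e-8))
  fit <- quiet_fit(Y, E, NULL, g, cfg)
  mle <- log(sum(Y) / sum(E))
  mcse <- sd(fit$draws$beta0) / sqrt(ess_bulk(fit$draws$beta0, fit$chain))
  expect_lt(abs(mean(fit$draws$beta0) - mle), 4 * mcse + 1e-3)
})

test_that("null data with tight priors give RR medians near 1", {
  g <- generate_lattice(3, 4, 0, seed = 4)
  E <- setNames(rep(50, 12), g$region_ids)
  Y <- setNames(rep(50L, 12), g$region_ids)
  cfg <- model_config("spatial", n_iterations = 1500, n_burnin = 500,
                      n_chains = 1, seed = 5,
                      fixed_sigma2 = list(v = 1e-4, u = 1e-4))
  fit <- quiet_fit(Y, E, NULL, g, cfg)
  rr <- fitted_relative_risks(fit)
  expect_true(all(rr$rr_median > 0.9 & rr$rr_median < 1.1))
})

test_that("fits are reproducible given the seed", {
  g <- generate_lattice(3, 3, 0, seed = 6)
  E <- setNames(rep(20, 9), g$region_ids)
  set.seed(7)
  Y <- setNames(rpois(9, 25), g$region_ids)
  cfg <- model_config("spatial", n_iterations = 600, n_burnin = 300,
                      n_chains = 2, seed = 8)
  f1 <- quiet_fit(Y, E, NULL, g, cfg)
  f2 <- quiet_fit(Y, E, NULL, g, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- quiet_fit(Y, E, NULL, g,
                  model_config("spatial", n_iterations = 600,
                               n_burnin = 300, n_chains = 2, seed = 9))
  expect_false(identical(f1$draws$beta0, f3$draws$beta0))
})

test_that("region relabeling permutes posterior spatial summaries", {
  g <- generate_lattice(2, 4, 0, seed = 10)
  set.seed(11)
  E <- setNames(rep(30, 8), g$region_ids)
  Y <- setNames(rpois(8, 30 * exp(rnorm(8, 0, 0.3))), g$region_ids)
  cfg <- model_config("spatial", n_iterations = 6000, n_burnin = 2000,
                      n_chains = 1, seed = 12)
  f1 <- quiet_fit(Y, E, NULL, g, cfg)
  m1 <- colMeans(f1$draws$u)
  # pure renaming that preserves positional order: draws are bit-identical
  ren <- setNames(paste0("z_", g$region_ids), g$region_ids)
  edges <- data.frame(a = unname(ren[g$edges[, 1L]]),
                      b = unname(ren[g$edges[, 2L]]))
  gr <- build_adjacency_graph(edges, region_ids = unname(ren[g$region_ids]))
  fr <- quiet_fit(setNames(Y, unname(ren[names(Y)])),
                  setNames(E, unname(ren[names(E)])), NULL, gr, cfg)
  expect_identical(unname(fr$draws$u), unname(f1$draws$u))
  # true permutation changes the update order, so summaries agree up to
  # Monte-Carlo error only
  map <- setNames(rev(g$region_ids), g$region_ids)
  edges2 <- data.frame(a = unname(map[g$edges[, 1L]]),
                       b = unname(map[g$edges[, 2L]]))
  g2 <- build_adjacency_graph(edges2, region_ids = sort(unname(map)))
  Y2 <- setNames(Y, unname(map[names(Y)]))
  E2 <- setNames(E, unname(map[names(E)]))
  f2 <- quiet_fit(Y2[g2$region_ids], E2[g2$region_ids], NULL, g2, cfg)
  m2 <- colMeans(f2$draws$u)
  expect_lt(max(abs(m2[unname(map[names(m1)])] - m1)), 0.05)
})

test_that("constrained effects sum to zero in every draw", {
  b <- generate_bundle(seed = 13, n_rows = 3, n_cols = 4, years = 2001:2004,
                       model_form = "st_interaction")
  E <- expected_counts(b$cube, pool_time = FALSE)
  Y <- apply(b$cube$Y, c(1L, 2L), sum)
  cfg <- model_config("st_interaction", n_iterations = 400, n_burnin = 200,
                      n_chains = 1, seed = 14)
  fit <- quiet_fit(Y, E, NULL, b$graph, cfg)
  expect_lt(max(abs(rowSums(fit$draws$u))), 1e-8)
  expect_lt(max(abs(rowSums(fit$draws$phi))), 1e-8)
  n <- length(b$graph$region_ids); Tn <- 4L
  del <- fit$draws$delta
  for (s in c(1L, nrow(del))) {
    D <- matrix(del[s, ], n, Tn, byrow = TRUE)
    expect_lt(max(abs(rowMeans(D))), 1e-8)
    expect_lt(max(abs(colMeans(D))), 1e-8)
  }
})

test_that("tightening the interaction variance recovers the main-effects model", {
  b <- generate_bundle(seed = 15, n_rows = 3, n_cols = 4, years = 2001:2004,
                       truth = true_params(sigma2 = list(u = 0.05, v = 0.01,
                                                         phi = 0.01),
                                           seed = 16),
                       model_form = "st_main")
  E <- expected_counts(b$cube, pool_time = FALSE)
  Y <- apply(b$cube$Y, c(1L, 2L), sum)
  base <- model_config("st_main", n_iterations = 1500, n_burnin = 700,
                       n_chains = 1, seed = 17)
  f_main <- quiet_fit(Y, E, NULL, b$graph, base)
  tight <- model_config("st_interaction", n_iterations = 1500,
                        n_burnin = 700, n_chains = 1, seed = 17,
                        fixed_sigma2 = list(delta = 1e-10))
  f_tight <- quiet_fit(Y, E, NULL, b$graph, tight)
  expect_lt(abs(dic(f_main)$dic - dic(f_tight)$dic),
            0.05 * abs(dic(f_main)$dic))
})

test_that("covariate RR scaling matches the assembly metadata algebra", {
  # RR per 0.1 proportion step = exp(0.1 * beta_per_unit_proportion)
  beta_raw <- 0.7                      # per unit proportion
  step <- 0.1
  beta_design <- beta_raw * step       # per design unit on the 0.1 scale
  expect_equal(exp(beta_design), exp(step * beta_raw))
  b <- generate_bundle(seed = 18, n_rows = 3, n_cols = 4, years = 2001:2003,
                       model_form = "spatial")
  X <- b$covariates
  expect_equal(X$indigenous * attr(X, "scaling")$indigenous_step,
               b$census$prop_indigenous[match(X$region_id,
                                              b$census$region_id)])
})

test_that("uniform-on-sd hyperprior runs and stays within its bounds", {
  g <- generate_lattice(3, 4, 0, seed = 19)
  set.seed(20)
  E <- setNames(rep(40, 12), g$region_ids)
  Y <- setNames(rpois(12, 40 * exp(rnorm(12, 0, 0.25))), g$region_ids)
  cfg <- model_config("spatial", hyperprior = "uniform", uniform_upper = 5,
                      n_iterations = 1200, n_burnin = 600, n_chains = 1,
                      seed = 21)
  fit <- quiet_fit(Y, E, NULL, g, cfg)
  expect_true(all(sqrt(fit$draws$sigma2[, c("v", "u")]) <= 5 + 1e-9))
  expect_true(all(fit$draws$sigma2 > 0))
})

test_that("draw persistence writes a readable long table with metadata", {
  g <- generate_lattice(3, 3, 0, seed = 22)
  set.seed(23)
  E <- setNames(rep(20, 9), g$region_ids)
  Y <- setNames(rpois(9, 20), g$region_ids)
  fit <- quiet_fit(Y, E, NULL, g,
                   model_config("spatial", n_iterations = 400,
                                n_burnin = 200, n_chains = 2, seed = 24))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fit_draws(fit, path)
  df <- read.delim(path)
  expect_setequal(unique(df$parameter),
                  c("beta0", paste0("sigma2_",
                                    c("v", "u", "gamma", "phi", "delta"))))
  expect_equal(sum(df$parameter == "beta0"), fit$n_kept)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 24)
})
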