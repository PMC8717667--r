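test_that("regular lattice has rook-grid neighbour counts", {
  g <- generate_lattice(12, 8, 0, seed = 1)
  expect_length(g$region_ids, 96)
  expect_true(all(g$n_neighbors %in% 2:4))
  expect_identical(unname(g$n_neighbors[["R01C01"]]), 2L)  # corner cell
  expect_identical(unname(g$n_neighbors[["R05C04"]]), 4L)  # interior cell
})

test_that("irregular lattices stay connected for any seed", {
  for (seed in 1:8) {
    g <- generate_lattice(6, 5, 0.4, seed = seed)
    expect_identical(n_components(g), 1L)
    expect_identical(icar_structure_matrix(g)$rank_deficiency, 1L)
  }
})

test_that("census generator hits the configured factor correlation", {
  g <- generate_lattice(12, 8, 0.2, seed = 2)
  cors <- vapply(1:12, function(s) {
    cen <- generate_census(g, target_correlation = 0.92, seed = 100 + s)
    cor(attr(cen, "latent_factor"), cen$prop_indigenous)
  }, numeric(1))
  expect_true(all(abs(cors - 0.92) < 0.05))
  # null target
  cors0 <- vapply(1:12, function(s) {
    cen <- generate_census(g, target_correlation = 0, seed = 200 + s)
    cor(attr(cen, "latent_factor"), cen$prop_indigenous)
  }, numeric(1))
  expect_gte(mean(abs(cors0) < 0.2), 0.9)
  # proportions clipped to [0, 1]
  cen <- generate_census(g, 0.92, seed = 3)
  props <- cen[c("prop_no_highschool", "unemployment_rate",
                 "prop_lone_parent", "prop_indigenous")]
  expect_true(all(props >= 0 & props <= 1))
  expect_true(all(cen$median_household_income > 0))
})

test_that("indigenous proportion follows the lattice gradient", {
  g <- generate_lattice(12, 8, 0, seed = 4)
  cen <- generate_census(g, 0.92, seed = 5)
  rows <- attr(g, "coords")$row
  expect_gt(cor(qlogis(cen$prop_indigenous), rows), 0.5)
})

test_that("constrained intrinsic field draws sum to zero with K+ covariance", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  K <- icar_structure_matrix(g)
  set.seed(6)
  draws <- t(replicate(30000, sample_intrinsic_field(K, 0.7)))
  expect_lt(max(abs(rowSums(draws))), 1e-10)
  target <- 0.7 * pinv(K$entries)
  err <- norm(cov(draws) - target, "F") / norm(target, "F")
  expect_lt(err, 0.1)
})

test_that("null generative model yields Poisson(E) counts", {
  g <- generate_lattice(12, 8, 0.2, seed = 7)
  pop <- generate_population(g, years = 2001:2002, seed = 8)
  tr <- true_params(sigma2 = list(), seed = 9)
  cube <- simulate_counts(g, pop, NULL, tr, "spatial")
  E <- true_expected_counts(pop, tr)
  ratio <- apply(cube$Y, c(1L, 2L), sum) / E
  se <- sqrt(1 / mean(E)) / sqrt(length(E))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
  expect_equal(attr(cube, "truth")$u, setNames(rep(0, 96), g$region_ids))
})

test_that("doubling the population doubles expected counts at fixed eta", {
  g <- generate_lattice(4, 4, 0, seed = 10)
  pop <- generate_population(g, years = 2001:2003, seed = 11)
  tr <- true_params(sigma2 = list(u = 0.05, v = 0.01), seed = 12)
  c1 <- simulate_counts(g, pop, NULL, tr, "spatial")
  c2 <- simulate_counts(g, pop * 2L, NULL, tr, "spatial")
  # same seed: identical latent eta; Poisson totals scale by 2
  expect_equal(attr(c1, "truth")$eta, attr(c2, "truth")$eta)
  expect_equal(sum(c2$Y) / sum(c1$Y), 2, tolerance = 0.05)
})

test_that("strong spatial signal is detected by the Moran pre-test", {
  g <- generate_lattice(12, 8, 0.2, seed = 13)
  pop <- generate_population(g, years = 2001:2001, seed = 14)
  hits <- 0L
  for (r in 1:5) {
    tr <- true_params(sigma2 = list(u = 0.5), seed = 300 + r)
    cube <- simulate_counts(g, pop, NULL, tr, "spatial")
    E <- expected_counts(cube, pool_time = TRUE)
    vals <- log((apply(cube$Y, 1L, sum) + 0.5) / E$E)
    mi <- morans_i_test(vals, g, 399, seed = 400 + r)
    hits <- hits + (mi$p_value < 0.05)
  }
  expect_gte(hits, 4L)
})

test_that("synthetic bundles are bit-identical under the same seed", {
  b1 <- generate_bundle(seed = 15, n_rows = 3, n_cols = 4, years = 2001:2004)
  b2 <- generate_bundle(seed = 15, n_rows = 3, n_cols = 4, years = 2001:2004)
  expect_identical(b1$cube$Y, b2$cube$Y)
  expect_identical(b1$census, b2$census)
  expect_identical(b1$population, b2$population)
  expect_identical(attr(b1$cube, "truth")$u, attr(b2$cube, "truth")$u)
  b3 <- generate_bundle(seed = 16, n_rows = 3, n_cols = 4, years = 2001:2004)
  expect_false(identical(b1$cube$Y, b3$cube$Y))
})

test_that("person-record generator respects its extreme configurations", {
  g <- generate_lattice(2, 3, 0, seed = 17)
  # zero event intensities: no cases, no noise
  recs <- simulate_person_records(g, n_persons = 80, years = 2001:2005,
                                  case_fraction = 0, noise_fraction = 0,
                                  seed = 18)
  st <- lapply(recs, apply_case_definition)
  cube <- build_prevalence_cube(st, recs, 2001:2005, g$region_ids)
  expect_identical(sum(cube$Y), 0L)
  expect_gt(sum(cube$n), 0L)
  # every person a case: prevalence approaches 1 in the final year
  recs1 <- simulate_person_records(g, n_persons = 150, years = 2001:2005,
                                   case_fraction = 1, censor_fraction = 0,
                                   patterns = "hospital", seed = 19)
  st1 <- lapply(recs1, apply_case_definition)
  cube1 <- build_prevalence_cube(st1, recs1, 2001:2005, g$region_ids)
  cp <- crude_prevalence(cube1)
  final <- cp$rate[cp$region == "PROVINCE" & cp$year == "2005"]
  expect_gt(final, 0.9)
})

test_that("cohort-derived prevalence matches the configured case fraction", {
  g <- generate_lattice(3, 4, 0.2, seed = 20)
  recs <- simulate_person_records(g, n_persons = 2000, years = 2001:2010,
                                  case_fraction = 0.1, seed = 21)
  st <- lapply(recs, apply_case_definition)
  cube <- build_prevalence_cube(st, recs, 2001:2010, g$region_ids)
  cp <- crude_prevalence(cube)
  final <- cp$rate[cp$region == "PROVINCE" & cp$year == "2010"]
  expect_lt(abs(final - 0.1), 0.02)
})

test_that("round trip: intended case years reappear in the cohort cube", {
  g <- generate_lattice(2, 2, 0, seed = 22)
  recs <- simulate_person_records(g, n_persons = 300, years = 2001:2008,
                                  case_fraction = 0.2, censor_fraction = 0,
                                  seed = 23)
  st <- lapply(recs, apply_case_definition)
  intended <- attr(recs, "intended")
  got <- vapply(st, function(s) s$is_case, logical(1))
  # persons whose intended pattern survived generation must be detected;
  # detected cases must carry the intended onset year
  expect_identical(got, intended$is_case)
  onset_years <- vapply(st, function(s) {
    if (s$is_case) as.integer(format(s$onset_date, "%Y")) else NA_integer_
  }, integer(1))
  expect_identical(onset_years, intended$onset_year)
})
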