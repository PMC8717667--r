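#' Ground-truth parameters for synthetic data generation
#'
#' @param beta named numeric vector of covariate coefficients on the design
#'   scales (default none).
#' @param sigma2 named list of random-effect variances `v, u, gamma, phi,
#'   delta` (defaults 0; unused terms ignored by the chosen model form).
#' @param baseline_rates named per-stratum prevalence rates; default a
#'   realistic chronic-disease age-sex profile rising from about 1% at
#'   40-44 to about 25% (men) / 15% (women) at 80-84.
#' @param beta0 log baseline relative risk (default 0: RR centred at 1).
#' @param seed integer seed.
#' @return a `true_params` list.
#' @export
true_params <- function(beta = numeric(0),
                        sigma2 = list(),
                        baseline_rates = NULL, beta0 = 0, seed) {
  if (missing(seed)) stop("seed is required")
  s2 <- list(v = 0, u = 0, gamma = 0, phi = 0, delta = 0)
  for (nm in names(sigma2)) {
    stopifnot(nm %in% names(s2), sigma2[[nm]] >= 0)
    s2[[nm]] <- sigma2[[nm]]
  }
  if (is.null(baseline_rates)) baseline_rates <- default_baseline_rates()
  structure(list(beta = beta, sigma2 = s2, baseline_rates = baseline_rates,
                 beta0 = beta0, seed = as.integer(seed)),
            class = "true_params")
}

#' Default age-sex stratum prevalence profile
#' @param age_min,age_max age window bounds.
#' @return named vector over [age_sex_strata()] labels.
#' @export
default_baseline_rates <- function(age_min = 40, age_max = 85) {
  strata <- age_sex_strata(age_min, age_max)
  parts <- strsplit(strata, "[-:]")
  mid <- vapply(parts, function(p) (as.numeric(p[1L]) + as.numeric(p[2L])) / 2,
                numeric(1L))
  sex <- vapply(parts, `[[`, "", 3L)
  rate <- 0.012 * exp(0.075 * (mid - 42)) * ifelse(sex == "M", 1, 0.6)
  stats::setNames(pmin(rate, 0.5), strata)
}

#' Generate an irregular lattice adjacency graph
#'
#' Starts from an `n_rows x n_cols` rook-contiguity grid (the default
#' 12 x 8 = 96 regions stands in for a health-district map) and perturbs a
#' fraction `irregularity` of potential diagonal links on and rook links
#' off, rejecting any perturbation that disconnects the graph (up to 100
#' retries).
#'
#' @param n_rows,n_cols grid dimensions (`n_rows * n_cols >= 4`).
#' @param irregularity fraction in `[0, 1]` of edges perturbed (default 0.2).
#' @param seed integer seed.
#' @return an `adjacency_graph` with a `coords` attribute (region row/col
#'   centroids, used by [generate_census()] for spatial gradients).
#' @export
generate_lattice <- function(n_rows = 12, n_cols = 8, irregularity = 0.2,
                             seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_rows * n_cols >= 4, irregularity >= 0, irregularity <= 1)
  old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  id <- function(r, c) sprintf("R%02dC%02d", r, c)
  ids <- as.vector(t(outer(seq_len(n_rows), seq_len(n_cols), id)))
  rook <- list(); diagonal <- list()
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      if (c < n_cols) rook[[length(rook) + 1L]] <- c(id(r, c), id(r, c + 1L))
      if (r < n_rows) rook[[length(rook) + 1L]] <- c(id(r, c), id(r + 1L, c))
      if (r < n_rows && c < n_cols) {
        diagonal[[length(diagonal) + 1L]] <- c(id(r, c), id(r + 1L, c + 1L))
        diagonal[[length(diagonal) + 1L]] <- c(id(r, c + 1L), id(r + 1L, c))
      }
    }
  }
  rook <- do.call(rbind, rook)
  diagonal <- do.call(rbind, diagonal)
  build <- function(edges) {
    df <- data.frame(a = edges[, 1L], b = edges[, 2L])
    suppressWarnings(build_adjacency_graph(df, region_ids = ids,
                                           allow_islands = TRUE))
  }
  g <- NULL
  for (attempt in seq_len(100L)) {
    edges <- rook
    if (irregularity > 0) {
      drop <- stats::runif(nrow(rook)) < irregularity / 2
      add <- stats::runif(nrow(diagonal)) < irregularity / 2
      edges <- rbind(rook[!drop, , drop = FALSE],
                     diagonal[add, , drop = FALSE])
    }
    cand <- build(edges)
    if (!length(cand$islands) && n_components(cand) == 1L) { g <- cand; break }
  }
  if (is.null(g)) stop("could not generate a connected lattice in 100 attempts")
  rc <- do.call(rbind, lapply(ids, function(x) {
    c(as.integer(substr(x, 2L, 3L)), as.integer(substr(x, 5L, 6L)))
  }))
  attr(g, "coords") <- data.frame(region_id = ids, row = rc[, 1L],
                                  col = rc[, 2L])
  g
}

#' Generate correlated region-level census covariates
#'
#' The Indigenous population proportion is drawn on the logit scale as a
#' smooth north-south gradient over the lattice plus spatially unstructured
#' noise (mimicking high northern / low southern proportions). A latent
#' deprivation factor is then constructed with the configured correlation
#' to the proportion, and the four socio-economic census inputs are
#' generated from a one-factor model (loadings 0.8, uniquenesses 0.36) on
#' that factor, transformed to their natural scales (income negatively
#' related to deprivation).
#'
#' @param graph an `adjacency_graph`, ideally from [generate_lattice()].
#' @param target_correlation desired correlation between the deprivation
#'   factor and the Indigenous proportion, `|rho| < 1` (default 0.92).
#' @param seed integer seed.
#' @return a census data.frame (see [read_census_table()]) with attribute
#'   `latent_factor` (the true deprivation factor).
#' @export
generate_census <- function(graph, target_correlation = 0.92, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(abs(target_correlation) < 1)
  old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  ids <- graph$region_ids
  n <- length(ids)
  coords <- attr(graph, "coords")
  grad <- if (!is.null(coords)) {
    scale(coords$row[match(ids, coords$region_id)])[, 1L]
  } else scale(seq_len(n))[, 1L]
  logit_ind <- qlogis(0.12) + 1.3 * grad + stats::rnorm(n, 0, 0.5)
  prop_ind <- pmin(pmax(plogis(logit_ind), 1e-4), 1 - 1e-4)
  z <- scale(prop_ind)[, 1L]
  rho <- target_correlation
  f <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  latent <- function() 0.8 * f + 0.6 * stats::rnorm(n)
  census <- data.frame(
    region_id = ids,
    median_household_income = exp(log(65000) - 0.25 * latent()),
    prop_no_highschool = plogis(qlogis(0.15) + 0.5 * latent()),
    unemployment_rate = plogis(qlogis(0.07) + 0.5 * latent()),
    prop_lone_parent = plogis(qlogis(0.16) + 0.4 * latent()),
    prop_indigenous = prop_ind)
  attr(census, "latent_factor") <- f
  census
}

#' Generate a region x year x stratum population table
#'
#' Stratum populations are log-normal around the default age profile, with
#' region-level size multipliers (also log-normal) and a small yearly
#' drift; values are rounded to integers with a floor of 20.
#'
#' @param graph an `adjacency_graph`.
#' @param years integer vector of calendar years (default 18 years
#'   2001-2018).
#' @param mean_stratum_pop average stratum population per region
#'   (default 300).
#' @param seed integer seed.
#' @return integer array `region x year x stratum`.
#' @export
generate_population <- function(graph, years = 2001:2018,
                                mean_stratum_pop = 300, seed) {
  if (missing(seed)) stop("seed is required")
  old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  ids <- graph$region_ids
  strata <- age_sex_strata()
  agewt <- exp(-0.04 * (seq_along(unique(sub(":.*", "", strata))) - 1L))
  agewt <- rep(agewt / mean(agewt), times = 2L)       # fewer people at older ages
  size <- exp(stats::rnorm(length(ids), 0, 0.6))
  base <- outer(size, agewt) * mean_stratum_pop *
    exp(matrix(stats::rnorm(length(ids) * length(strata), 0, 0.2),
               length(ids)))
  drift <- exp(0.005 * (seq_along(years) - 1L))
  pop <- array(0L, c(length(ids), length(years), length(strata)),
               dimnames = list(region = ids, year = as.character(years),
                               stratum = strata))
  for (t in seq_along(years)) {
    pop[, t, ] <- pmax(20L, as.integer(round(base * drift[t])))
  }
  pop
}

#' Sample a sum-to-zero intrinsic Gaussian field
#'
#' Draws from the intrinsic Gaussian density with structure matrix K and
#' scale `sigma2`, constrained to the orthogonal complement of K's null
#' space, via eigendecomposition: the draw has covariance
#' \eqn{\sigma^2 K^+} (Moore-Penrose pseudo-inverse).
#'
#' @param K a `structure_matrix`.
#' @param sigma2 variance scale.
#' @return numeric vector named by `K$labels`.
#' @export
sample_intrinsic_field <- function(K, sigma2) {
  eg <- eigen(K$entries, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  z <- stats::rnorm(sum(pos))
  x <- eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(eg$values[pos]))
  stats::setNames(sqrt(sigma2) * drop(x), K$labels)
}

# Kronecker-structured field as an n x T matrix, region-major consistency
# with interaction_structure_matrix (K_space %x% K_time)
.sample_kronecker_field <- function(Ks, Kt, sigma2) {
  es <- eigen(Ks$entries, symmetric = TRUE)
  et <- eigen(Kt$entries, symmetric = TRUE)
  ps <- es$values > max(es$values) * 1e-9
  pt <- et$values > max(et$values) * 1e-9
  C <- matrix(0, nrow(Ks$entries), nrow(Kt$entries))
  C[ps, pt] <- stats::rnorm(sum(ps) * sum(pt)) /
    sqrt(outer(es$values[ps], et$values[pt]))
  sqrt(sigma2) * es$vectors %*% C %*% t(et$vectors)
}

#' Expected counts under the generator's true baseline rates
#'
#' Applies the true per-stratum rates to the stratum populations, giving
#' the fixed offset \eqn{E} the generative model actually used (as opposed
#' to [expected_counts()], which re-derives reference rates from realized
#' counts and therefore couples E to the data). Used in calibration
#' checks where a correctly specified fixed offset is required.
#'
#' @param population `region x year x stratum` array.
#' @param truth a [true_params()] object.
#' @param pool_time if `TRUE`, sum over years to one E per region.
#' @return region x year matrix (or named region vector).
#' @export
true_expected_counts <- function(population, truth, pool_time = FALSE) {
  rates <- truth$baseline_rates[dimnames(population)[[3L]]]
  stopifnot(!anyNA(rates))
  Tn <- dim(population)[2L]
  E <- vapply(seq_len(Tn),
              function(t) drop(population[, t, , drop = TRUE] %*% rates),
              numeric(dim(population)[1L]))
  dimnames(E) <- dimnames(population)[1:2]
  if (pool_time) rowSums(E) else E
}

#' Simulate a prevalence cube from the generative disease-mapping model
#'
#' Draws the latent fields from their (constrained) priors at the true
#' variances, builds cellwise rates
#' \eqn{\lambda_{itj} = r_j \, n_{itj} \exp(\eta_{it})} with \eqn{r_j} the
#' baseline stratum rates, and samples Poisson counts (capped at the
#' stratum population so the cube stays a valid prevalence cube; at
#' realistic rates the cap essentially never binds).
#'
#' @param graph an `adjacency_graph`.
#' @param population `region x year x stratum` array (see
#'   [generate_population()]).
#' @param covariates a `covariate_table` or `NULL` (spatial form only).
#' @param truth a [true_params()] object.
#' @param model_form `"spatial"`, `"st_main"`, or `"st_interaction"`.
#' @param interaction_type Knorr-Held type for the delta field
#'   (default `"IV"`).
#' @return a `prevalence_cube` with attribute `truth`: list of the latent
#'   fields (`u, v, gamma, phi, delta`), the linear predictor `eta`
#'   (region x year), and the `true_params` used.
#' @export
simulate_counts <- function(graph, population, covariates = NULL, truth,
                            model_form = c("spatial", "st_main",
                                           "st_interaction"),
                            interaction_type = "IV") {
  model_form <- match.arg(model_form)
  stopifnot(inherits(truth, "true_params"))
  old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(truth$seed)
  ids <- graph$region_ids
  n <- length(ids)
  years <- dimnames(population)[[2L]]
  Tn <- length(years)
  strata <- dimnames(population)[[3L]]
  rates <- truth$baseline_rates[strata]
  stopifnot(!anyNA(rates))

  Kspace <- icar_structure_matrix(graph)
  u <- if (truth$sigma2$u > 0) sample_intrinsic_field(Kspace, truth$sigma2$u)
       else stats::setNames(rep(0, n), ids)
  v <- stats::rnorm(n, 0, sqrt(truth$sigma2$v))
  xb <- rep(0, n)
  if (length(truth$beta)) {
    stopifnot(!is.null(covariates))
    Xd <- as.data.frame(covariates)
    Xd <- Xd[match(ids, Xd$region_id), , drop = FALSE]
    for (nm in names(truth$beta)) xb <- xb + truth$beta[[nm]] * Xd[[nm]]
  }
  gam <- phi <- rep(0, Tn)
  delta <- matrix(0, n, Tn)
  if (model_form != "spatial") {
    gam <- stats::rnorm(Tn, 0, sqrt(truth$sigma2$gamma))
    Ktime <- rw1_structure_matrix(Tn, labels = years)
    phi <- if (truth$sigma2$phi > 0)
      sample_intrinsic_field(Ktime, truth$sigma2$phi) else rep(0, Tn)
    if (model_form == "st_interaction" && truth$sigma2$delta > 0) {
      Ks <- switch(interaction_type,
                   I = identity_structure_matrix(ids),
                   II = identity_structure_matrix(ids),
                   III = Kspace, IV = Kspace)
      Kt <- switch(interaction_type,
                   I = identity_structure_matrix(years),
                   II = Ktime, III = identity_structure_matrix(years),
                   IV = Ktime)
      delta <- .sample_kronecker_field(Ks, Kt, truth$sigma2$delta)
    }
  }
  eta <- truth$beta0 + outer(xb + v + u, rep(1, Tn)) +
    outer(rep(1, n), gam + phi) + delta
  dimnames(eta) <- list(ids, years)

  Y <- array(0L, dim(population), dimnames = dimnames(population))
  for (t in seq_len(Tn)) {
    mu <- sweep(population[, t, , drop = TRUE], 2L, rates, "*") * exp(eta[, t])
    Y[, t, ] <- pmin(array(stats::rpois(length(mu), mu), dim(mu)),
                     population[, t, ])
  }
  cube <- prevalence_cube(Y, population)
  attr(cube, "truth") <- list(u = u, v = v, gamma = gam, phi = phi,
                              delta = delta, eta = eta, params = truth)
  cube
}

#' Simulate person-level administrative records
#'
#' Generates a synthetic population of persons with registry coverage
#' spells, region assignments, and dated events, whose induced prevalence
#' (via [apply_case_definition()] and [build_prevalence_cube()])
#' approximates a configured case fraction. Cases receive one of three
#' qualifying evidence patterns (a hospital abstract; two claims within
#' the window; one claim plus two prescriptions within the window)
#' completed in their onset year; non-cases receive sub-threshold noise
#' patterns (single claims, or one claim plus one prescription) that
#' stress the case-definition algorithm. A configurable fraction is
#' censored by death or emigration.
#'
#' @param graph an `adjacency_graph` (regions sampled uniformly).
#' @param n_persons number of persons.
#' @param years study calendar years.
#' @param case_fraction probability a person is a true case (default 0.1).
#' @param censor_fraction probability of death/emigration censoring during
#'   the study (default 0.1).
#' @param noise_fraction probability a non-case carries sub-threshold
#'   events (default 0.3).
#' @param patterns qualifying evidence patterns sampled for cases (any of
#'   `"hospital"`, `"claims"`, `"claim_drug"`; default all three).
#' @param seed integer seed.
#' @return list of `person_records`, with attribute `intended` (data.frame
#'   of each person's true case status and onset year).
#' @export
simulate_person_records <- function(graph, n_persons = 5000,
                                    years = 2001:2018, case_fraction = 0.1,
                                    censor_fraction = 0.1,
                                    noise_fraction = 0.3,
                                    patterns = c("hospital", "claims",
                                                 "claim_drug"), seed) {
  if (missing(seed)) stop("seed is required")
  old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  ids <- graph$region_ids
  y0 <- min(years); y1 <- max(years)
  study_start <- as.Date(paste0(y0, "-01-01"))
  study_end <- as.Date(paste0(y1, "-12-31"))
  out <- vector("list", n_persons)
  intended <- data.frame(person_id = character(n_persons),
                         is_case = logical(n_persons),
                         onset_year = NA_integer_)
  for (k in seq_len(n_persons)) {
    pid <- sprintf("P%06d", k)
    sex <- sample(c("M", "F"), 1L)
    # age 42..80 at study midpoint: inside the window for most of the study
    age_mid <- sample(42:80, 1L)
    mid <- as.Date(paste0((y0 + y1) %/% 2, "-07-01"))
    birth <- mid - round(age_mid * 365.25) - sample(0:364, 1L)
    censored <- stats::runif(1) < censor_fraction
    end <- as.Date(NA); reason <- "none"
    if (censored) {
      end <- study_start + sample.int(as.integer(study_end - study_start), 1L)
      reason <- sample(c("death", "emigration"), 1L)
    }
    spells <- data.frame(start = study_start, end = end,
                         end_reason = reason)
    region <- sample(ids, 1L)
    region_by_year <- stats::setNames(rep(region, length(years)),
                                      as.character(years))
    is_case <- stats::runif(1) < case_fraction
    ev <- data.frame(date = as.Date(character(0)), source = character(0))
    lastdate <- if (censored) end else study_end
    if (is_case) {
      onset_year <- sample(years[-length(years)], 1L)
      onset <- as.Date(paste0(onset_year, "-02-01")) + sample(0:40, 1L)
      if (onset < lastdate) {
        pattern <- sample(patterns, 1L)
        ev <- switch(pattern,
          hospital = data.frame(date = onset, source = "hospital"),
          claims = data.frame(date = c(onset - sample(30:600, 1L), onset),
                              source = c("claim", "claim")),
          claim_drug = data.frame(
            date = c(onset - sample(200:600, 1L),
                     onset - sample(30:180, 1L), onset),
            source = c("claim", "drug", "drug")))
        # clamp supporting events into the study window so the pattern is
        # never truncated (it stays inside the rolling window regardless)
        ev$date <- pmax(ev$date, study_start)
        if (!any(ev$source == "hospital") &&
            sum(ev$source == "claim") < 2L &&
            !(sum(ev$source == "claim") >= 1L && sum(ev$source == "drug") >= 2L)) {
          is_case <- FALSE   # safety: pattern degenerated
        }
      } else is_case <- FALSE
    }
    if (!is_case && stats::runif(1) < noise_fraction) {
      # sub-threshold noise: a lone claim, or claim + one drug
      d1 <- study_start + sample.int(as.integer(lastdate - study_start), 1L)
      ev <- if (stats::runif(1) < 0.5) {
        data.frame(date = d1, source = "claim")
      } else {
        data.frame(date = c(d1, d1 + 30), source = c("claim", "drug"))
      }
      ev <- ev[ev$date <= lastdate, , drop = FALSE]
    }
    ev <- ev[ev$date > birth, , drop = FALSE]
    out[[k]] <- person_records(pid, sex, birth, spells, region_by_year, ev)
    intended$person_id[k] <- pid
    intended$is_case[k] <- is_case
    intended$onset_year[k] <- if (is_case)
      as.integer(format(max(ev$date[ev$source != "drug" | TRUE]), "%Y")) else NA_integer_
  }
  attr(out, "intended") <- intended
  out
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper producing every pipeline input with known ground
#' truth: lattice, census covariates, populations, and a model-generated
#' prevalence cube (optionally person-level records as well). All stage
#' seeds derive deterministically from `seed`.
#'
#' @param seed master integer seed.
#' @param n_rows,n_cols,irregularity lattice settings (default 12 x 8).
#' @param years study years.
#' @param truth a [true_params()] object; default: moderate spatial
#'   variation (`sigma2 u = 0.1, v = 0.01`).
#' @param model_form generative model form.
#' @param target_correlation census factor/Indigenous correlation.
#' @param with_records also simulate person-level records (slower).
#' @param mean_stratum_pop average stratum population per region.
#' @return object of class `synthetic_bundle`: list with `graph`, `census`,
#'   `covariates`, `population`, `cube`, `truth`, and optionally `records`.
#' @export
generate_bundle <- function(seed, n_rows = 12, n_cols = 8,
                            irregularity = 0.2, years = 2001:2018,
                            truth = NULL,
                            model_form = "st_interaction",
                            target_correlation = 0.92,
                            with_records = FALSE,
                            mean_stratum_pop = 300) {
  if (missing(seed)) stop("seed is required")
  if (is.null(truth)) {
    truth <- true_params(sigma2 = list(u = 0.1, v = 0.01, gamma = 0.001,
                                       phi = 0.01, delta = 0.02),
                         seed = seed + 4L)
  }
  graph <- generate_lattice(n_rows, n_cols, irregularity, seed = seed)
  census <- generate_census(graph, target_correlation, seed = seed + 1L)
  covariates <- assemble_covariates(census, graph)
  population <- generate_population(graph, years,
                                    mean_stratum_pop = mean_stratum_pop,
                                    seed = seed + 2L)
  cube <- simulate_counts(graph, population, covariates, truth, model_form)
  out <- list(graph = graph, census = census, covariates = covariates,
              population = population, cube = cube, truth = truth)
  if (with_records) {
    out$records <- simulate_person_records(graph, seed = seed + 3L,
                                           years = years)
  }
  structure(out, class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic bundle:", length(x$graph$region_ids), "regions,",
      length(x$cube$years), "years,", length(x$cube$strata), "strata\n")
  invisible(x)
}
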