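# shared small fixtures, built in code

path_graph <- function(ids = c("A", "B", "C")) {
  if (length(ids) == 1L) {
    return(suppressWarnings(build_adjacency_graph(
      data.frame(a = character(0), b = character(0)),
      region_ids = ids, allow_islands = TRUE)))
  }
  build_adjacency_graph(data.frame(a = ids[-length(ids)], b = ids[-1L]))
}

# unit-square polygon feature list for a grid, queen-contiguous
grid_polygons <- function(n_rows, n_cols) {
  out <- list()
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      xy <- rbind(c(c - 1, r - 1), c(c, r - 1), c(c, r), c(c - 1, r),
                  c(c - 1, r - 1))
      out[[length(out) + 1L]] <- list(id = sprintf("g%d%d", r, c),
                                      coords = xy)
    }
  }
  out
}

# minimal person with one coverage spell over the whole study
simple_person <- function(id = "P1", sex = "F", birth = "1950-06-15",
                          events = data.frame(date = as.Date(character(0)),
                                              source = character(0)),
                          region = "A", years = 2000:2010,
                          end = as.Date(NA), end_reason = "none") {
  person_records(id, sex, as.Date(birth),
                 data.frame(start = as.Date("1995-01-01"), end = end,
                            end_reason = end_reason),
                 setNames(rep(region, length(years)), years), events)
}

# hand-built fit object with fully controlled draws (spatial form),
# for exercising the diagnostics formulas in isolation
fake_fit <- function(lambda_draws, Y, E = rep(1, length(Y))) {
  n <- length(Y)
  S <- nrow(lambda_draws)
  ids <- sprintf("F%02d", seq_len(n))
  g <- path_graph(ids)
  cfg <- model_config("spatial", n_iterations = S + 1, n_burnin = 1,
                      n_chains = 1, seed = 1)
  # encode the target lambda via beta0 = 0 and u = log(lambda/E)
  structure(list(
    draws = list(beta0 = rep(0, S),
                 beta = matrix(0, S, 0),
                 v = matrix(0, S, n, dimnames = list(NULL, ids)),
                 u = log(sweep(lambda_draws, 2L, E, "/")),
                 gamma = matrix(0, S, 0), phi = matrix(0, S, 0),
                 delta = matrix(0, S, 0),
                 sigma2 = matrix(0.1, S, 5,
                                 dimnames = list(NULL,
                                                 c("v", "u", "gamma", "phi",
                                                   "delta")))),
    chain = rep(1L, S),
    data = list(Y = matrix(Y, n, 1, dimnames = list(ids, NULL)),
                E = matrix(E, n, 1, dimnames = list(ids, NULL)),
                X = matrix(0, n, 0), graph = g, T = 1L,
                mask = matrix(1L, n, 1)),
    config = cfg, n_kept = S), class = "bym_fit")
}

quiet_fit <- function(...) suppressWarnings(fit_model(...))
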