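# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the case-definition oracle enumerates event
# pairs/triples combinatorially, the pseudo-inverse is a plain eigen
# computation, and Moran's I is evaluated from the dense weight matrix.

# combinatorial case-definition oracle: any hospital event; any claim pair
# closer than the window; any (claim, drug, drug) triple whose span fits in
# the window. Returns list(is_case, onset_date).
oracle_case_definition <- function(events, window_years = 5) {
  wdays <- round(window_years * 365.25)
  qual <- as.Date(character(0))
  hosp <- events$date[events$source == "hospital"]
  qual <- c(qual, hosp)
  claims <- sort(events$date[events$source == "claim"])
  drugs <- sort(events$date[events$source == "drug"])
  if (length(claims) >= 2L) {
    for (a in seq_len(length(claims) - 1L)) {
      for (b in seq.int(a + 1L, length(claims))) {
        if (as.numeric(claims[b] - claims[a]) < wdays) {
          qual <- c(qual, claims[b])
        }
      }
    }
  }
  if (length(claims) >= 1L && length(drugs) >= 2L) {
    for (a in seq_along(claims)) {
      for (b in seq_len(length(drugs) - 1L)) {
        for (d in seq.int(b + 1L, length(drugs))) {
          trio <- c(claims[a], drugs[b], drugs[d])
          if (as.numeric(max(trio) - min(trio)) < wdays) {
            qual <- c(qual, max(trio))
          }
        }
      }
    }
  }
  if (length(qual)) list(is_case = TRUE, onset_date = min(qual))
  else list(is_case = FALSE, onset_date = as.Date(NA))
}

# random person history with wide coverage (no censoring interference)
random_history <- function(n_events_max = 8L) {
  n_ev <- sample(0:n_events_max, 1L)
  dates <- as.Date("2000-01-01") + sample(0:3200, n_ev, replace = TRUE)
  events <- data.frame(date = dates,
                       source = sample(c("hospital", "claim", "drug"), n_ev,
                                       replace = TRUE,
                                       prob = c(0.1, 0.45, 0.45)))
  events <- events[order(events$date), , drop = FALSE]
  person_records(person_id = "X", sex = "F",
                 birth_date = as.Date("1955-06-15"),
                 coverage_spells = data.frame(start = as.Date("1995-01-01"),
                                              end = as.Date(NA),
                                              end_reason = "none"),
                 region_by_year = setNames(rep("A", 20), 1999:2018),
                 events = events)
}

# Moore-Penrose pseudo-inverse by eigendecomposition
pinv <- function(M, tol = 1e-9) {
  eg <- eigen(M, symmetric = TRUE)
  pos <- abs(eg$values) > max(abs(eg$values)) * tol
  eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
}

# dense-matrix Moran's I
oracle_moran <- function(x, W) {
  z <- x - mean(x)
  (length(x) / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

# numeric matrix rank
num_rank <- function(M, tol = 1e-8) {
  s <- svd(M)$d
  sum(s > max(s) * tol)
}
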