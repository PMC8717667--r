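#' Person-level administrative records
#'
#' Bundles the four administrative record streams for one person: insurance
#' registry coverage spells, region assignment by year, and dated disease
#' events pre-classified by source (`hospital` abstract, physician `claim`,
#' or `drug` prescription).
#'
#' @param person_id opaque identifier.
#' @param sex `"M"` or `"F"`.
#' @param birth_date `Date`.
#' @param coverage_spells data.frame with `Date` columns `start`, `end`
#'   (`NA` end = coverage open at end of study) and character `end_reason`
#'   in `death`, `emigration`, `none`.
#' @param region_by_year named character vector, names = calendar years.
#' @param events data.frame with columns `date` (`Date`) and `source`.
#' @return object of class `person_records`.
#' @export
person_records <- function(person_id, sex, birth_date, coverage_spells,
                           region_by_year, events) {
  sex <- match.arg(sex, c("M", "F"))
  birth_date <- as.Date(birth_date)
  if (nrow(coverage_spells)) {
    sp <- coverage_spells[order(coverage_spells$start), , drop = FALSE]
    if (nrow(sp) > 1L) {
      ends <- sp$end[-nrow(sp)]
      if (anyNA(ends) || any(ends >= sp$start[-1L])) {
        stop("overlapping coverage spells for person ", person_id)
      }
    }
    coverage_spells <- sp
  }
  if (nrow(events) && any(events$date < birth_date)) {
    stop("event predates birth for person ", person_id)
  }
  structure(list(person_id = person_id, sex = sex, birth_date = birth_date,
                 coverage_spells = coverage_spells,
                 region_by_year = region_by_year,
                 events = events[order(events$date), , drop = FALSE]),
            class = "person_records")
}

.covered_on <- function(records, date) {
  sp <- records$coverage_spells
  if (!nrow(sp)) return(FALSE)
  any(sp$start <= date & (is.na(sp$end) | sp$end >= date))
}

#' Apply the chronic-disease case-definition algorithm
#'
#' A person is a prevalent case if they have at least one hospital-abstract
#' event, or, within some rolling window of `window_years` years, at least
#' two physician-claim events, or at least one claim plus two drug
#' prescriptions. The onset date is the earliest date on which a qualifying
#' criterion is first completed (the date of the completing event). A
#' window of length w years ending at event date d contains events with
#' dates in `(d - round(365.25 w) days, d]`.
#'
#' By default the single-hospital-event route is *not* window-constrained
#' (the window applies to the multi-event combinations); set
#' `hospital_windowed = TRUE` for the alternative reading (equivalent here,
#' since one event always lies in its own window, but kept for symmetry
#' and auditability).
#'
#' Censoring: the earliest of death, emigration (from the end reason of the
#' last coverage spell) and the 85th birthday (aging out).
#'
#' @param records a `person_records` object.
#' @param window_years rolling window length in years (default 5).
#' @param hospital_windowed logical; see Details.
#' @param age_max age at which a person ages out (85: strata end at 80-84).
#' @return object of class `case_status`: list with `person_id`, `is_case`,
#'   `onset_date`, `censor_date`, `censor_reason`.
#' @export
apply_case_definition <- function(records, window_years = 5,
                                  hospital_windowed = FALSE,
                                  age_max = 85) {
  stopifnot(window_years >= 1)
  ev <- records$events
  if (nrow(ev)) {
    ok <- vapply(seq_len(nrow(ev)), function(k) .covered_on(records, ev$date[k]),
                 logical(1L))
    if (!all(ok)) {
      warning("ignoring ", sum(!ok), " event(s) outside coverage for person ",
              records$person_id)
      ev <- ev[ok, , drop = FALSE]
    }
  }
  wdays <- round(window_years * 365.25)
  onset <- as.Date(NA)
  if (nrow(ev)) {
    dates <- ev$date
    src <- ev$source
    hosp <- dates[src == "hospital"]
    if (length(hosp)) onset <- min(hosp)
    # rolling windows ending at each claim/drug event (two-pointer scan)
    for (k in seq_along(dates)) {
      d <- dates[k]
      if (!is.na(onset) && d >= onset) break
      inwin <- dates > (d - wdays) & dates <= d
      ncl <- sum(src[inwin] == "claim")
      ndr <- sum(src[inwin] == "drug")
      qual <- ncl >= 2L || (ncl >= 1L && ndr >= 2L)
      if (hospital_windowed) qual <- qual || any(src[inwin] == "hospital")
      if (qual) {
        onset <- if (is.na(onset)) d else min(onset, d)
        break
      }
    }
  }
  cens <- .censor_info(records, age_max)
  if (!is.na(onset) && !is.na(cens$date) && onset > cens$date) {
    # criterion completed only after leaving the cohort: not a prevalent case
    onset <- as.Date(NA)
  }
  structure(list(person_id = records$person_id,
                 is_case = !is.na(onset),
                 onset_date = onset,
                 censor_date = cens$date,
                 censor_reason = cens$reason),
            class = "case_status")
}

.censor_info <- function(records, age_max = 85) {
  cand_date <- as.Date(character(0))
  cand_reason <- character(0)
  sp <- records$coverage_spells
  if (nrow(sp)) {
    last <- sp[nrow(sp), ]
    if (!is.na(last$end) && last$end_reason %in% c("death", "emigration")) {
      cand_date <- c(cand_date, last$end)
      cand_reason <- c(cand_reason, last$end_reason)
    }
  }
  bday85 <- .add_years(records$birth_date, age_max)
  cand_date <- c(cand_date, bday85)
  cand_reason <- c(cand_reason, "aged_out")
  k <- which.min(cand_date)
  list(date = cand_date[k], reason = cand_reason[k])
}

# birthday arithmetic robust to Feb 29 (falls back to Mar 1)
.add_years <- function(date, k) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + k
  as.Date(lt)
}

.age_on <- function(birth_date, date) {
  b <- as.POSIXlt(birth_date); d <- as.POSIXlt(date)
  age <- d$year - b$year
  before <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  age - as.integer(before)
}

#' Age-sex stratum labels (5-year groups, ages 40-84, both sexes)
#' @param age_min,age_max inclusive-exclusive bounds of the age window.
#' @return character vector like `"40-44:F"`, ..., `"80-84:M"`.
#' @export
age_sex_strata <- function(age_min = 40, age_max = 85) {
  lo <- seq(age_min, age_max - 5, by = 5)
  grp <- paste0(lo, "-", lo + 4)
  as.vector(outer(grp, c("F", "M"), paste, sep = ":"))
}

.age_group <- function(age, age_min = 40, age_max = 85) {
  lo <- (age - age_min) %/% 5 * 5 + age_min
  paste0(lo, "-", lo + 4)
}

#' Build the region x year x age-sex prevalence cube
#'
#' Point prevalence at a fixed reference date per year (default the fiscal
#' year start, April 1). For each year, a person contributes to the
#' population denominator `n` if covered by insurance on the reference
#' date, not yet censored, aged in `[age_min, age_max)`, and with a region
#' assignment for that year; they additionally contribute to the case
#' numerator `Y` if their onset date is on or before the reference date.
#'
#' @param statuses list of `case_status` objects.
#' @param records list of matching `person_records` objects.
#' @param years integer vector of contiguous calendar years.
#' @param regions character vector of region ids (the cube index; usually
#'   `graph$region_ids`).
#' @param age_min,age_max age window (default `[40, 85)`).
#' @param reference_md reference month-day within each year, `"MM-DD"`
#'   (default `"04-01"`, fiscal-year start).
#' @return object of class `prevalence_cube`: list with integer arrays `Y`
#'   and `n` of dim `regions x years x strata`.
#' @export
build_prevalence_cube <- function(statuses, records, years, regions,
                                  age_min = 40, age_max = 85,
                                  reference_md = "04-01") {
  stopifnot(length(statuses) == length(records))
  strata <- age_sex_strata(age_min, age_max)
  dims <- c(length(regions), length(years), length(strata))
  dn <- list(region = regions, year = as.character(years), stratum = strata)
  Y <- array(0L, dims, dimnames = dn)
  n <- array(0L, dims, dimnames = dn)
  refdates <- as.Date(paste0(years, "-", reference_md))
  for (k in seq_along(records)) {
    rec <- records[[k]]; st <- statuses[[k]]
    stopifnot(identical(rec$person_id, st$person_id))
    for (ti in seq_along(years)) {
      ref <- refdates[ti]
      if (!is.na(st$censor_date) && ref >= st$censor_date) next
      if (!.covered_on(rec, ref)) next
      age <- .age_on(rec$birth_date, ref)
      if (age < age_min || age >= age_max) next
      reg <- rec$region_by_year[[as.character(years[ti])]]
      if (is.null(reg) || is.na(reg)) {
        stop("person ", rec$person_id, " has no region for year ", years[ti])
      }
      ri <- match(reg, regions)
      if (is.na(ri)) stop("unknown region '", reg, "' for person ", rec$person_id)
      si <- match(paste0(.age_group(age, age_min), ":", rec$sex), strata)
      n[ri, ti, si] <- n[ri, ti, si] + 1L
      if (st$is_case && st$onset_date <= ref) Y[ri, ti, si] <- Y[ri, ti, si] + 1L
    }
  }
  prevalence_cube(Y, n)
}

#' Construct a prevalence cube from count arrays
#' @param Y,n integer arrays `region x year x stratum` with identical
#'   dimnames; `Y <= n` cellwise.
#' @return object of class `prevalence_cube`.
#' @export
prevalence_cube <- function(Y, n) {
  stopifnot(identical(dim(Y), dim(n)), all(Y >= 0), all(n >= 0))
  if (any(Y > n)) stop("case count exceeds population in some cell")
  structure(list(Y = Y, n = n,
                 regions = dimnames(Y)[[1L]],
                 years = dimnames(Y)[[2L]],
                 strata = dimnames(Y)[[3L]]),
            class = "prevalence_cube")
}

#' @export
print.prevalence_cube <- function(x, ...) {
  cat("Prevalence cube:", length(x$regions), "regions x", length(x$years),
      "years x", length(x$strata), "strata\n")
  cat("Total cases", sum(x$Y), "of", sum(x$n), "person-years at reference dates\n")
  invisible(x)
}

#' Crude prevalence by region-year, with provincial aggregate
#'
#' @param cube a `prevalence_cube`.
#' @return data.frame `(region, year, Y, n, rate)`; rows with `region =
#'   "PROVINCE"` pool all regions. Zero-population cells get `NA` rate.
#' @export
crude_prevalence <- function(cube) {
  Yrt <- apply(cube$Y, c(1L, 2L), sum)
  nrt <- apply(cube$n, c(1L, 2L), sum)
  reg <- data.frame(region = rep(rownames(Yrt), ncol(Yrt)),
                    year = rep(colnames(Yrt), each = nrow(Yrt)),
                    Y = as.vector(Yrt), n = as.vector(nrt))
  prov <- data.frame(region = "PROVINCE", year = colnames(Yrt),
                     Y = colSums(Yrt), n = colSums(nrt))
  out <- rbind(reg, prov)
  out$rate <- ifelse(out$n > 0, out$Y / out$n, NA_real_)
  rownames(out) <- NULL
  out
}

#' Read / write a prevalence cube as a long-format delimited table
#'
#' Columns: `region, year, age_group, sex, Y, n` (tab-separated, header).
#' @param cube a `prevalence_cube`.
#' @param path file path.
#' @export
write_prevalence_cube <- function(cube, path) {
  grid <- expand.grid(region = cube$regions, year = cube$years,
                      stratum = cube$strata, stringsAsFactors = FALSE)
  parts <- strsplit(grid$stratum, ":", fixed = TRUE)
  df <- data.frame(region = grid$region, year = grid$year,
                   age_group = vapply(parts, `[[`, "", 1L),
                   sex = vapply(parts, `[[`, "", 2L),
                   Y = as.vector(cube$Y), n = as.vector(cube$n))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prevalence_cube
#' @export
read_prevalence_cube <- function(path) {
  df <- utils::read.delim(path, colClasses = c(region = "character",
                                               year = "character"))
  stratum <- paste0(df$age_group, ":", df$sex)
  regions <- unique(df$region); years <- unique(df$year)
  strata <- unique(stratum)
  dn <- list(region = regions, year = years, stratum = strata)
  Y <- array(0L, unname(lengths(dn)), dimnames = dn)
  n <- array(0L, unname(lengths(dn)), dimnames = dn)
  idx <- cbind(match(df$region, regions), match(df$year, years),
               match(stratum, strata))
  Y[idx] <- df$Y
  n[idx] <- df$n
  prevalence_cube(Y, n)
}
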