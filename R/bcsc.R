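#' Load BCSC-style risk-model coefficients
#'
#' The 5-year absolute-risk projection is driven entirely by configuration:
#' a relative-risk table over the clinical covariates (BI-RADS density,
#' binary first-degree family history, worst prior biopsy pathology, by age
#' band) and per race/ethnicity annual baseline breast cancer hazards and
#' competing (non-breast-cancer death) hazards indexed by single year of
#' age. The package ships a synthetic fixture with plausible values
#' (`system.file("extdata", "bcsc_coefficients_synthetic.yaml",
#' package = "prsscreen")`); the published model's tables can be supplied in
#' the same format without any code change.
#'
#' YAML structure:
#' \preformatted{
#' rr_table:
#'   age_bands:
#'     - ages: [40, 80]        # inclusive
#'       density: {a: 0.6, b: 1.0, c: 1.5, d: 2.1, unknown: 1.0}
#'       fdr:     {no: 1.0, yes: 1.6}
#'       biopsy:  {none: 1.0, ..., unknown: 1.0}
#' hazards:
#'   nh_white:
#'     age_start: 40
#'     baseline:  [0.0012, ...]   # annual incidence, covariate-baseline women
#'     competing: [0.0020, ...]   # annual other-cause mortality
#' }
#' Relative risks multiply across the three covariate components; the
#' reference pattern (density b, no first-degree relative, no biopsy) has
#' relative risk exactly 1.
#'
#' @param path Path to the YAML (or JSON) coefficient file.
#' @return An object of class `bcsc_coefficients`.
#' @export
read_bcsc_coefficients <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$rr_table$age_bands) || is.null(raw$hazards)) {
    stop("coefficient file must contain rr_table$age_bands and hazards")
  }
  bands <- lapply(raw$rr_table$age_bands, function(b) {
    stopifnot(length(b$ages) == 2L)
    list(lo = b$ages[[1]], hi = b$ages[[2]],
         density = unlist(b$density), fdr = unlist(b$fdr),
         biopsy = unlist(b$biopsy))
  })
  hz <- lapply(raw$hazards, function(h) {
    n <- length(h$baseline)
    if (length(h$competing) != n) {
      stop("baseline and competing hazard vectors must have equal length")
    }
    if (any(unlist(h$baseline) < 0) || any(unlist(h$competing) < 0)) {
      stop("hazards must be nonnegative")
    }
    ages <- seq(h$age_start, length.out = n)
    list(ages = ages, baseline = unlist(h$baseline),
         competing = unlist(h$competing))
  })
  bad_rr <- unlist(lapply(bands, function(b) c(b$density, b$fdr, b$biopsy)))
  if (any(!is.finite(bad_rr) | bad_rr <= 0)) {
    stop("all relative risks must be finite and > 0")
  }
  structure(list(rr_bands = bands, hazards = hz),
            class = "bcsc_coefficients")
}

#' @export
print.bcsc_coefficients <- function(x, ...) {
  cat("BCSC-style coefficient set:", length(x$rr_bands), "RR age band(s),",
      length(x$hazards), "hazard stratum(e):",
      paste(names(x$hazards), collapse = ", "), "\n")
  invisible(x)
}

.rr_band_for_age <- function(coeffs, age) {
  for (b in coeffs$rr_bands) if (age >= b$lo && age <= b$hi) return(b)
  stop("no relative-risk age band covers age ", age)
}

.rr_component <- function(tab, key, what) {
  if (!key %in% names(tab)) {
    stop("no relative risk for ", what, " = '", key, "'")
  }
  unname(tab[[key]])
}

#' Clinical relative risk of a participant
#'
#' Multiplies the coefficient table's density, family-history and biopsy
#' components. Family history enters as a binary term — any first-degree
#' relative with breast cancer, regardless of how many; second-degree
#' relatives do not contribute.
#'
#' @param participant Data frame (or single-row list) with columns `age`,
#'   `density` (`"a"`..`"d"` or `"unknown"`), `fdr_bc` (count of affected
#'   first-degree relatives) and `biopsy` (`"none"`, `"nonproliferative"`,
#'   `"proliferative_no_atypia"`, `"atypia"`, `"lcis"`, `"unknown"`).
#' @param coeffs A `bcsc_coefficients` object.
#' @return Numeric vector of relative risks, one per participant row.
#' @export
relative_risk <- function(participant, coeffs) {
  p <- as.data.frame(participant, stringsAsFactors = FALSE)
  vapply(seq_len(nrow(p)), function(i) {
    b <- .rr_band_for_age(coeffs, p$age[i])
    dens <- if (is.na(p$density[i])) "unknown" else as.character(p$density[i])
    biop <- if (is.na(p$biopsy[i])) "unknown" else as.character(p$biopsy[i])
    fdr <- if (!is.na(p$fdr_bc[i]) && p$fdr_bc[i] > 0) "yes" else "no"
    .rr_component(b$density, dens, "density") *
      .rr_component(b$fdr, fdr, "first-degree family history") *
      .rr_component(b$biopsy, biop, "biopsy pathology")
  }, numeric(1))
}

.hazard_lookup <- function(coeffs, group, ages, which = c("baseline", "competing")) {
  which <- match.arg(which)
  h <- coeffs$hazards[[group]]
  if (is.null(h)) stop("no hazard stratum named '", group, "'")
  i <- match(ages, h$ages)
  if (anyNA(i)) {
    stop("hazard years missing for ages ",
         paste(ages[is.na(i)], collapse = ", "), " in stratum ", group)
  }
  h[[which]][i]
}

#' Absolute risk of breast cancer over a projection window
#'
#' Gail-type cause-specific competing-risk projection on annual intervals.
#' With `h1(a)` the baseline breast cancer hazard at age `a`, `h2(a)` the
#' competing mortality hazard, and `rr` the participant's relative risk, the
#' risk over `horizon` years starting at `age` is
#' \deqn{\sum_{t=0}^{T-1} \frac{rr\,h_1(a+t)}{rr\,h_1(a+t)+h_2(a+t)}
#'  \left[1 - e^{-(rr\,h_1(a+t)+h_2(a+t))}\right]
#'  e^{-\sum_{s<t} (rr\,h_1(a+s)+h_2(a+s))}}
#' i.e. the probability of remaining event-free through earlier years and
#' then developing breast cancer (rather than dying first) in year `t`.
#'
#' @param rr Relative risk(s), > 0.
#' @param age Current age(s) in whole years.
#' @param race_eth Hazard-stratum label(s), matching the names in the
#'   coefficient file's `hazards` block.
#' @param coeffs A `bcsc_coefficients` object.
#' @param horizon Projection window in years (default 5).
#' @return Numeric vector of absolute risks in `[0, 1)`.
#' @export
absolute_5yr_risk <- function(rr, age, race_eth, coeffs, horizon = 5L) {
  n <- max(length(rr), length(age), length(race_eth))
  rr <- rep_len(rr, n); age <- rep_len(age, n)
  race_eth <- rep_len(race_eth, n)
  if (any(rr <= 0)) stop("relative risk must be > 0")

  risk <- numeric(n)
  surv <- rep(1, n)
  for (t in 0:(horizon - 1L)) {
    h1 <- h2 <- numeric(n)
    for (g in unique(race_eth)) {
      i <- which(race_eth == g)
      h1[i] <- .hazard_lookup(coeffs, g, age[i] + t, "baseline")
      h2[i] <- .hazard_lookup(coeffs, g, age[i] + t, "competing")
    }
    h1 <- rr * h1
    tot <- h1 + h2
    frac <- ifelse(tot > 0, h1 / tot, 0)
    risk <- risk + frac * (1 - exp(-tot)) * surv
    surv <- surv * exp(-tot)
  }
  risk
}

#' First study year in which the clinical model alone recommends screening
#'
#' Recomputes the clinical (BCSC-only) risk yearly with age incremented and
#' re-applies the screening threshold table, returning the first 1-based
#' study year whose recommendation is more than "no screening", or `NA` if
#' no crossing occurs within the horizon. Used to ask, of women recommended
#' to start screening because of their PRS, how many would have started
#' shortly anyway on clinical risk alone.
#'
#' @param participant One-row data frame with the columns used by
#'   [relative_risk()] plus `race_eth` (hazard stratum) and `density`.
#' @param coeffs A `bcsc_coefficients` object.
#' @param thresholds A `threshold_table`.
#' @param horizon Number of study years to examine (default 3).
#' @return Integer study year of first crossing, or `NA_integer_`.
#' @export
project_start_year <- function(participant, coeffs, thresholds, horizon = 3L) {
  stopifnot(horizon >= 1L)
  p <- as.data.frame(participant, stringsAsFactors = FALSE)
  stopifnot(nrow(p) == 1L)
  rr <- relative_risk(p, coeffs)
  for (y in seq_len(horizon)) {
    age_y <- p$age + (y - 1L)
    risk <- absolute_5yr_risk(rr, age_y, p$race_eth, coeffs)
    rec <- assign_screening(age = age_y, risk = risk, density = p$density,
                            pv = FALSE, thresholds = thresholds)
    if (rec != "none_or_stop") return(y)
  }
  NA_integer_
}
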