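#' Exchange-rate temperature series
#'
#' Exchange rate constants for one transition direction of one residue
#' probe measured at several temperatures.
#'
#' @param residue_label residue identifier (e.g. `"W43e"`, `"T17"`)
#' @param direction `"1->2"` (major to minor) or `"2->1"` (minor to major)
#' @param temperatures temperatures (K), strictly increasing
#' @param k exchange rate constants (s^-1), positive, aligned
#' @param k_stderr optional standard errors on `k`
#' @return an object of class `rate_series`
#' @export
rate_series <- function(residue_label, direction = c("1->2", "2->1"),
                        temperatures, k, k_stderr = NULL) {
  direction <- match.arg(direction)
  if (length(k) != length(temperatures)) stop("k must align with temperatures")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (any(k <= 0)) stop("rates must be positive")
  if (!is.null(k_stderr) && length(k_stderr) != length(k))
    stop("k_stderr must align with k")
  structure(list(residue_label = residue_label, direction = direction,
                 temperatures = as.numeric(temperatures),
                 k = as.numeric(k), k_stderr = k_stderr),
            class = "rate_series")
}

#' Arrhenius fit of a rate-temperature series
#'
#' Least-squares line through (1/T, ln k). The apparent activation energy
#' is -slope * R (R = 1.9872e-3 kcal/(mol K)). A negative value is a
#' diagnostic of non-two-state observed kinetics, not a thermodynamic
#' quantity.
#'
#' @param series a [rate_series] with >= 3 temperatures
#' @param weighted if `TRUE`, weight points by 1/se(ln k)^2 with
#'   se(ln k) = k_stderr/k (requires `k_stderr`)
#' @return an object of class `arrhenius_fit` with `Ea_app` (kcal/mol),
#'   `lnA`, `Ea_stderr`, `r_squared`, `n`
#' @export
fit_arrhenius <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "rate_series"))
  if (length(series$k) < 3)
    stop("at least 3 temperatures are required for an Arrhenius fit")
  x <- 1 / series$temperatures
  y <- log(series$k)
  w <- NULL
  if (weighted) {
    if (is.null(series$k_stderr)) stop("weighted fit requires k_stderr")
    w <- (series$k / series$k_stderr)^2
  }
  if (diff(range(y)) == 0) {
    # temperature-invariant rates: the flat line is exact and the slope is
    # identically zero (avoids spurious epsilon-scale slopes from lm)
    return(structure(list(Ea_app = 0, lnA = y[1], Ea_stderr = 0,
                          r_squared = 1, n = length(y),
                          residue_label = series$residue_label,
                          direction = series$direction),
                     class = "arrhenius_fit"))
  }
  fit <- stats::lm(y ~ x, weights = w)
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(Ea_app = -co["x", "Estimate"] * .R_KCAL,
                 lnA = co["(Intercept)", "Estimate"],
                 Ea_stderr = co["x", "Std. Error"] * .R_KCAL,
                 r_squared = safe_r_squared(fit, y),
                 n = length(y),
                 residue_label = series$residue_label,
                 direction = series$direction),
            class = "arrhenius_fit")
}

# R^2 with the constant-response edge case defined: zero total variation
# with zero residuals is a perfect flat-line fit.
safe_r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  if (ss_tot < .Machine$double.eps * max(1, sum(y^2)))
    return(if (ss_res <= ss_tot) 1 else 0)
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%s, %s): Ea_app = %.3g +/- %.2g kcal/mol (R^2 = %.4f)\n",
              x$residue_label, x$direction, x$Ea_app, x$Ea_stderr, x$r_squared))
  invisible(x)
}

#' Eyring fit of a rate-temperature series
#'
#' Least-squares line through (1/T, ln(k/T)) with transmission coefficient
#' fixed at 1: ln(k/T) = ln(k_B/h) + dS/R - dH/(R T). Activation enthalpy
#' is reported in kcal/mol and activation entropy in cal/(mol K).
#'
#' @param series a [rate_series] with >= 3 temperatures
#' @return an object of class `eyring_fit` with `dH_act`, `dS_act`,
#'   `dH_stderr`, `dS_stderr`, `transmission_coefficient`
#' @export
fit_eyring <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  if (length(series$k) < 3)
    stop("at least 3 temperatures are required for an Eyring fit")
  x <- 1 / series$temperatures
  y <- log(series$k / series$temperatures)
  fit <- stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(dH_act = -co["x", "Estimate"] * .R_KCAL,
                 dS_act = (co["(Intercept)", "Estimate"] - log(.KB_OVER_H)) * .R_CAL,
                 dH_stderr = co["x", "Std. Error"] * .R_KCAL,
                 dS_stderr = co["(Intercept)", "Std. Error"] * .R_CAL,
                 transmission_coefficient = 1,
                 n = length(y),
                 residue_label = series$residue_label,
                 direction = series$direction),
            class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("Eyring fit (%s, %s): dH = %.3g kcal/mol, dS = %.3g cal/(mol K)\n",
              x$residue_label, x$direction, x$dH_act, x$dS_act))
  invisible(x)
}

#' Classify exchange behavior from directional Arrhenius fits
#'
#' Exchange is called "Arrhenius" when the apparent activation energy is
#' strictly positive for both transition directions, and "non-Arrhenius"
#' otherwise (a zero or negative energy in either direction). When fits
#' for a dimer-interface reporter residue are supplied, the probe is also
#' checked for consistency with the reporter: the two activation energies
#' must agree within twice their combined standard error in both
#' directions. A probe that is Arrhenius but inconsistent with the dimer
#' reporter flags a distinct dynamic process.
#'
#' @param fit_fwd,fit_rev [arrhenius_fit] objects for the probe residue,
#'   forward (major-to-minor) and reverse direction
#' @param reporter_fwd,reporter_rev optional [arrhenius_fit] objects for
#'   the dimerization reporter residue
#' @return an object of class `behavior_call` with `behavior`,
#'   `reporter_consistent` (`NA` when no reporter given) and `notes`
#' @export
classify_behavior <- function(fit_fwd, fit_rev,
                              reporter_fwd = NULL, reporter_rev = NULL) {
  stopifnot(inherits(fit_fwd, "arrhenius_fit"),
            inherits(fit_rev, "arrhenius_fit"))
  behavior <- if (fit_fwd$Ea_app > 0 && fit_rev$Ea_app > 0)
    "Arrhenius" else "non-Arrhenius"
  reporter_consistent <- NA
  notes <- ""
  if (!is.null(reporter_fwd) && !is.null(reporter_rev)) {
    agree <- function(a, b) {
      tol <- 2 * sqrt(a$Ea_stderr^2 + b$Ea_stderr^2)
      abs(a$Ea_app - b$Ea_app) <= tol
    }
    reporter_consistent <- agree(fit_fwd, reporter_fwd) &&
      agree(fit_rev, reporter_rev)
    if (behavior == "Arrhenius" && !reporter_consistent)
      notes <- paste("both activation energies positive but inconsistent",
                     "with the dimer-interface reporter; a dynamic process",
                     "other than monomer-dimer exchange is likely sensed")
  }
  structure(list(behavior = behavior,
                 reporter_consistent = reporter_consistent,
                 notes = notes),
            class = "behavior_call")
}

#' @export
print.behavior_call <- function(x, ...) {
  cat(sprintf("Exchange behavior: %s (reporter consistent: %s)\n",
              x$behavior, as.character(x$reporter_consistent)))
  if (nzchar(x$notes)) cat("  note: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Read rate series from TSV
#'
#' Columns: residue, direction, temperature_K (or temperature_C, converted
#' on read), k_per_s and optionally k_stderr. Returns one [rate_series]
#' per residue/direction combination.
#'
#' @param file path to a tab-separated file
#' @return a list of [rate_series]
#' @export
read_rates_tsv <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.delim(file, check.names = FALSE)
  if (!"temperature_K" %in% names(d)) {
    if (!"temperature_C" %in% names(d))
      stop("need a temperature_K or temperature_C column")
    d$temperature_K <- celsius_to_kelvin(d$temperature_C)
  }
  need <- c("residue", "direction", "k_per_s")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- list()
  for (key in unique(paste(d$residue, d$direction))) {
    sub <- d[paste(d$residue, d$direction) == key, ]
    sub <- sub[order(sub$temperature_K), ]
    out[[key]] <- rate_series(
      residue_label = as.character(sub$residue[1]),
      direction = as.character(sub$direction[1]),
      temperatures = sub$temperature_K,
      k = sub$k_per_s,
      k_stderr = if ("k_stderr" %in% names(d)) sub$k_stderr else NULL)
  }
  out
}
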