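#' Denaturation curves
#'
#' `melt_curve` holds a thermal denaturation trace (circular dichroism
#' ellipticity at 208 nm versus temperature); `denat_curve` holds a
#' chemical denaturation trace (response, typically fraction unfolded,
#' versus denaturant concentration).
#'
#' @param temperatures temperatures (degrees C), strictly increasing,
#'   >= 8 points
#' @param ellipticity ellipticity (mdeg), aligned
#' @return an object of class `melt_curve` / `denat_curve`
#' @export
melt_curve <- function(temperatures, ellipticity) {
  if (length(temperatures) < 8) stop("at least 8 points are required")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (length(ellipticity) != length(temperatures))
    stop("ellipticity must align with temperatures")
  structure(list(temperatures = as.numeric(temperatures),
                 ellipticity = as.numeric(ellipticity)),
            class = "melt_curve")
}

#' @rdname melt_curve
#' @param denaturant denaturant concentrations (M), nonnegative, strictly
#'   increasing, >= 6 points
#' @param response observed response (fraction unfolded or raw signal)
#' @export
denat_curve <- function(denaturant, response) {
  if (length(denaturant) < 6) stop("at least 6 points are required")
  if (any(denaturant < 0)) stop("denaturant concentrations must be nonnegative")
  if (is.unsorted(denaturant, strictly = TRUE))
    stop("denaturant concentrations must be strictly increasing")
  if (length(response) != length(denaturant))
    stop("response must align with denaturant")
  structure(list(denaturant = as.numeric(denaturant),
                 response = as.numeric(response)),
            class = "denat_curve")
}

#' Convert fluorescence spectra to fraction unfolded
#'
#' Integrates each emission spectrum over wavelength (trapezoid rule) and
#' normalizes the integrals between linear folded and unfolded baselines
#' fitted to the lowest- and highest-denaturant points:
#' fraction = (S(D) - S_folded(D)) / (S_unfolded(D) - S_folded(D)).
#'
#' @param denaturant denaturant concentrations (M), strictly increasing
#' @param spectra matrix of emission intensities, one row per denaturant
#'   point, one column per wavelength
#' @param wavelengths emission wavelengths (nm), aligned with columns
#' @param n_baseline number of points at each end used to fit the
#'   baselines (default 2; 1 gives a flat baseline)
#' @return a [denat_curve] with `response` = fraction unfolded
#' @export
fluorescence_to_fraction <- function(denaturant, spectra, wavelengths,
                                     n_baseline = 2) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(denaturant))
    stop("one spectrum per denaturant point is required")
  if (ncol(spectra) != length(wavelengths))
    stop("wavelengths must align with spectrum columns")
  if (nrow(spectra) < 2) stop("at least 2 spectra are required")
  # trapezoid integral over wavelength
  dl <- diff(wavelengths)
  S <- as.numeric((spectra[, -ncol(spectra), drop = FALSE] +
                     spectra[, -1, drop = FALSE]) %*% (dl / 2))
  n <- length(S)
  nb <- max(1, min(n_baseline, floor(n / 2)))
  base_fit <- function(idx) {
    if (length(idx) < 2) {
      c(S[idx][1], 0)
    } else {
      co <- stats::coef(stats::lm(S[idx] ~ denaturant[idx]))
      c(co[1], co[2])
    }
  }
  bf <- base_fit(seq_len(nb))
  bu <- base_fit(seq(n - nb + 1, n))
  Sf <- bf[1] + bf[2] * denaturant
  Su <- bu[1] + bu[2] * denaturant
  den <- Su - Sf
  if (any(abs(den) < 1e-12 * max(abs(S), 1)))
    stop("degenerate baselines: folded and unfolded signals coincide")
  denat_curve(denaturant, (S - Sf) / den)
}

# two-state unfolded population for chemical denaturation at temperature T
# (K), linear extrapolation: dG(D) = m (Cm - D), p_U = 1/(1 + exp(dG/RT))
p_unfolded_chem <- function(D, Cm, m, T_K = .T_REF)
  1 / (1 + exp(m * (Cm - D) / (.R_KCAL * T_K)))

# van't Hoff two-state unfolded population for thermal denaturation
p_unfolded_therm <- function(T_K, Tm_K, dH_vH)
  1 / (1 + exp(dH_vH / .R_KCAL * (1 / T_K - 1 / Tm_K)))

# guard against featureless input: error when the response is constant or
# exactly linear in the abscissa (no sigmoidal transition to fit)
check_transition <- function(x, y) {
  if (diff(range(y)) == 0) stop("no transition detected: response is constant")
  res <- stats::residuals(stats::lm(y ~ x))
  if (sqrt(mean(res^2)) < 1e-10 * max(abs(y), 1))
    stop("no transition detected: response is linear in the denaturation axis")
}

# shared nonlinear least-squares machinery for the two-state sigmoid with
# linear folded/unfolded baselines; `pop` maps (x, midpoint, steep) to the
# unfolded population, with the steepness parameter log-transformed.
fit_two_state <- function(x, y, pop, mid0, steep0) {
  model <- function(par) {
    pu <- pop(x, par[1], exp(par[2]))
    (par[3] + par[4] * x) * (1 - pu) + (par[5] + par[6] * x) * pu
  }
  n <- length(x)
  bf0 <- y[1]; bu0 <- y[n]
  par0 <- c(mid0, log(steep0), bf0, 0, bu0, 0)
  fit <- minpack.lm::nls.lm(
    par = par0, fn = function(p) model(p) - y,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  se <- tryCatch(
    sqrt(diag(solve(fit$hessian)) * fit$deviance / max(n - 6, 1)),
    error = function(e) rep(NA_real_, 6))
  cov_mid_steep <- tryCatch({
    V <- solve(fit$hessian) * fit$deviance / max(n - 6, 1)
    V[1, 2]
  }, error = function(e) NA_real_)
  list(par = fit$par, se = se, rss = fit$deviance,
       converged = fit$info %in% 1:4, cov_mid_steep = cov_mid_steep)
}

#' Fit a two-state chemical denaturation curve
#'
#' Fits response(D) = (b_f + s_f D)(1 - p_U) + (b_u + s_u D) p_U with
#' p_U = 1 / (1 + exp(m (Cm - D) / (R T))), the two-state linear
#' extrapolation model at fixed temperature (default 25 C). The free
#' energy of unfolding in water is dG_U = m * Cm.
#'
#' @param curve a [denat_curve] spanning both baselines
#' @param temperature assay temperature (K); default 298.15
#' @return an object of class `stability_fit` with `midpoint` (Cm, M),
#'   `m_value` (kcal/(mol M)), `dG_U` (kcal/mol), `baselines`, `stderr`,
#'   `rss`, `converged`
#' @export
fit_chemical <- function(curve, temperature = .T_REF) {
  stopifnot(inherits(curve, "denat_curve"))
  D <- curve$denaturant
  y <- curve$response
  check_transition(D, y)
  # crude midpoint guess: crossing of the flat-baseline-normalized signal
  ynorm <- (y - y[1]) / (y[length(y)] - y[1])
  mid0 <- stats::approx(ynorm, D, xout = 0.5, ties = "ordered")$y
  if (is.na(mid0)) mid0 <- stats::median(D)
  fit <- fit_two_state(D, y, function(x, mid, m)
    p_unfolded_chem(x, mid, m, temperature), mid0, 2)
  Cm <- fit$par[1]
  m <- exp(fit$par[2])
  if (Cm < min(D) || Cm > max(D))
    stop("fitted midpoint lies outside the measured denaturant range")
  se_Cm <- fit$se[1]
  se_m <- m * fit$se[2]
  # delta-method error on dG = m * Cm
  se_dG <- if (all(is.finite(c(se_Cm, se_m, fit$cov_mid_steep))))
    sqrt((m * se_Cm)^2 + (Cm * se_m)^2 +
           2 * m * Cm * m * fit$cov_mid_steep) else NA_real_
  structure(list(type = "chemical",
                 midpoint = Cm, m_value = m, dG_U = m * Cm,
                 baselines = c(b_f = fit$par[3], s_f = fit$par[4],
                               b_u = fit$par[5], s_u = fit$par[6]),
                 stderr = c(midpoint = se_Cm, m_value = se_m, dG_U = se_dG),
                 rss = fit$rss, converged = fit$converged,
                 temperature = temperature),
            class = "stability_fit")
}

#' Fit a two-state thermal melt
#'
#' Fits the same two-state sigmoid with linear baselines against
#' temperature, with a van't Hoff enthalpy steepness parameter (fitted
#' but reported only as `steepness`; only the midpoint Tm is a headline
#' quantity).
#'
#' @param curve a [melt_curve] spanning both baselines
#' @return an object of class `stability_fit` with `midpoint` (Tm, C),
#'   `steepness` (van't Hoff enthalpy, kcal/mol), `baselines`, `stderr`,
#'   `rss`, `converged`
#' @export
fit_thermal <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  TC <- curve$temperatures
  y <- curve$ellipticity
  check_transition(TC, y)
  ynorm <- (y - y[1]) / (y[length(y)] - y[1])
  mid0 <- stats::approx(ynorm, TC, xout = 0.5, ties = "ordered")$y
  if (is.na(mid0)) mid0 <- stats::median(TC)
  fit <- fit_two_state(TC, y, function(x, mid, dH)
    p_unfolded_therm(celsius_to_kelvin(x), celsius_to_kelvin(mid), dH),
    mid0, 40)
  Tm <- fit$par[1]
  if (Tm < min(TC) || Tm > max(TC))
    stop("fitted midpoint lies outside the measured temperature range")
  structure(list(type = "thermal",
                 midpoint = Tm,
                 steepness = exp(fit$par[2]),
                 baselines = c(b_f = fit$par[3], s_f = fit$par[4],
                               b_u = fit$par[5], s_u = fit$par[6]),
                 stderr = c(midpoint = fit$se[1],
                            steepness = exp(fit$par[2]) * fit$se[2]),
                 rss = fit$rss, converged = fit$converged),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  if (x$type == "chemical")
    cat(sprintf("Chemical denaturation fit: Cm = %.3g M, m = %.3g kcal/(mol M), dG_U = %.3g kcal/mol\n",
                x$midpoint, x$m_value, x$dG_U))
  else
    cat(sprintf("Thermal melt fit: Tm = %.3g C\n", x$midpoint))
  invisible(x)
}

#' Destabilization free energy between two variants
#'
#' @param variant_dG unfolding free energy of the variant (kcal/mol)
#' @param reference_dG unfolding free energy of the reference (kcal/mol)
#' @return `reference_dG - variant_dG` (kcal/mol); positive values mean
#'   the variant is destabilized relative to the reference
#' @export
delta_delta_g <- function(variant_dG, reference_dG) {
  if (!is.finite(variant_dG) || !is.finite(reference_dG))
    stop("free energies must be finite")
  reference_dG - variant_dG
}

#' Read denaturation curves from CSV
#'
#' Thermal files have columns temperature_C, ellipticity_mdeg; chemical
#' files have conc_M and fraction_unfolded.
#'
#' @param file path to a comma-separated file
#' @return a [melt_curve] or [denat_curve] according to the columns found
#' @export
read_denaturation_csv <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.csv(file, check.names = FALSE)
  if (all(c("temperature_C", "ellipticity_mdeg") %in% names(d))) {
    d <- d[order(d$temperature_C), ]
    melt_curve(d$temperature_C, d$ellipticity_mdeg)
  } else if (all(c("conc_M", "fraction_unfolded") %in% names(d))) {
    d <- d[order(d$conc_M), ]
    denat_curve(d$conc_M, d$fraction_unfolded)
  } else {
    stop("unrecognized denaturation file layout: ", file)
  }
}
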