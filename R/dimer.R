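#' Equilibrium monomer fraction for a 2M <-> M2 equilibrium
#'
#' Mass-action solution with Kd = \[M\]^2/\[D\] and total concentration in
#' monomer equivalents (Ctot = \[M\] + 2\[D\]):
#' \[M\] = (-Kd + sqrt(Kd^2 + 8 Kd Ctot)) / 4.
#'
#' @param Ctot total protein concentration (M, monomer equivalents), > 0
#' @param Kd dissociation constant (M), > 0
#' @return fraction of protein in the monomeric state, in (0, 1\]
#' @export
monomer_fraction <- function(Ctot, Kd) {
  if (any(Ctot <= 0)) stop("Ctot must be positive")
  if (any(Kd <= 0)) stop("Kd must be positive")
  M <- (-Kd + sqrt(Kd^2 + 8 * Kd * Ctot)) / 4
  M / Ctot
}

#' Dimerization titration
#'
#' Peak volumes of linked monomer (major) and dimer (minor) state peaks
#' across total protein concentrations.
#'
#' @param concentrations total concentrations (M, monomer equivalents),
#'   positive and strictly increasing
#' @param V_monomer,V_dimer peak volumes (arbitrary units), aligned
#' @return an object of class `dimer_titration`
#' @export
dimer_titration <- function(concentrations, V_monomer, V_dimer) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (length(V_monomer) != length(concentrations) ||
      length(V_dimer) != length(concentrations))
    stop("volumes must align with concentrations")
  if (any(V_monomer < 0) || any(V_dimer < 0)) stop("volumes must be nonnegative")
  if (length(concentrations) < 2) stop("at least 2 concentrations required")
  structure(list(concentrations = as.numeric(concentrations),
                 V_monomer = as.numeric(V_monomer),
                 V_dimer = as.numeric(V_dimer)),
            class = "dimer_titration")
}

#' Fit a dissociation constant to a peak-volume titration
#'
#' The observed monomer fraction at each concentration is
#' f = V_monomer / (V_monomer + V_dimer): the dimer peak volume is taken
#' proportional to 2\[D\] because each dimer contributes two reporter
#' residues. Kd is found by least squares of f against
#' [monomer_fraction()] over log-Kd (bounds 1e-9 to 1e-1 M).
#'
#' @param titration a [dimer_titration]
#' @param response_factor optional relative response factor of the dimer
#'   peak (dimer volume divided by `response_factor` before forming the
#'   fraction); default 1
#' @return an object of class `kd_fit` with `Kd` (M), `Kd_stderr`, `rss`
#'   (fraction scale) and `identifiable`
#' @export
fit_kd <- function(titration, response_factor = 1) {
  stopifnot(inherits(titration, "dimer_titration"))
  Vm <- titration$V_monomer
  Vd <- titration$V_dimer / response_factor
  tot <- Vm + Vd
  if (all(tot == 0)) stop("all volumes are zero; nothing to fit")
  if (any(tot == 0)) stop("zero total volume at some concentrations")
  f_obs <- Vm / tot
  Ct <- titration$concentrations

  identifiable <- !(all(f_obs > 0.98) || all(f_obs < 0.02))
  rss_fun <- function(logKd)
    sum((f_obs - monomer_fraction(Ct, exp(logKd)))^2)
  opt <- stats::optimize(rss_fun, interval = log(c(1e-9, 1e-1)),
                         tol = 1e-12)
  logKd <- opt$minimum
  rss <- opt$objective

  Kd_stderr <- NA_real_
  if (identifiable) {
    h <- 1e-4
    d2 <- (rss_fun(logKd + h) - 2 * rss + rss_fun(logKd - h)) / h^2
    n <- length(f_obs)
    if (is.finite(d2) && d2 > 0 && n > 1) {
      s2 <- rss / (n - 1)
      Kd_stderr <- exp(logKd) * sqrt(2 * s2 / d2)
    }
  }
  structure(list(Kd = exp(logKd), Kd_stderr = Kd_stderr, rss = rss,
                 identifiable = identifiable, n = length(f_obs)),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (x$identifiable)
    cat(sprintf("Dimer Kd = %.4g M (se %.2g M, rss %.3g, n = %d)\n",
                x$Kd, x$Kd_stderr, x$rss, x$n))
  else
    cat("Dimer Kd not identifiable from this titration\n")
  invisible(x)
}

#' Read a dimer titration from TSV
#'
#' Columns: conc_M, V_monomer, V_dimer.
#'
#' @param file path to a tab-separated file
#' @return a [dimer_titration]
#' @export
read_titration_tsv <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.delim(file, check.names = FALSE)
  need <- c("conc_M", "V_monomer", "V_dimer")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- d[order(d$conc_M), ]
  dimer_titration(d$conc_M, d$V_monomer, d$V_dimer)
}
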