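#' Two-site exchange parameters
#'
#' Parameter set for the two-site longitudinal exchange model underlying
#' ZZ-exchange NMR experiments: state 1 (major) and state 2 (minor)
#' interconvert with first-order rate constants while both magnetizations
#' relax longitudinally.
#'
#' @param k_12 major-to-minor exchange rate constant (s^-1), >= 0
#' @param k_21 minor-to-major exchange rate constant (s^-1), >= 0
#' @param R1_1,R1_2 longitudinal relaxation rates of each state (s^-1), > 0
#' @param I0_1,I0_2 initial peak intensities of each state (arbitrary
#'   units), > 0. These absorb instrument and population factors and are
#'   deliberately not tied to the equilibrium constant.
#' @return an object of class `zz_params`
#' @export
zz_params <- function(k_12, k_21, R1_1, R1_2, I0_1, I0_2) {
  vals <- c(k_12 = k_12, k_21 = k_21, R1_1 = R1_1, R1_2 = R1_2,
            I0_1 = I0_1, I0_2 = I0_2)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (k_12 < 0 || k_21 < 0) stop("exchange rates must be nonnegative")
  if (R1_1 <= 0 || R1_2 <= 0) stop("relaxation rates must be positive")
  if (I0_1 <= 0 || I0_2 <= 0) stop("initial intensities must be positive")
  structure(as.list(vals), class = "zz_params")
}

#' @export
print.zz_params <- function(x, ...) {
  cat("Two-site exchange parameters:\n")
  cat(sprintf("  k_12 = %.4g s^-1, k_21 = %.4g s^-1\n", x$k_12, x$k_21))
  cat(sprintf("  R1_1 = %.4g s^-1, R1_2 = %.4g s^-1\n", x$R1_1, x$R1_2))
  cat(sprintf("  I0_1 = %.4g, I0_2 = %.4g\n", x$I0_1, x$I0_2))
  invisible(x)
}

#' ZZ-exchange dataset
#'
#' Mixing-time-resolved intensities of the four peak classes of a
#' ZZ-exchange experiment at one temperature: both auto peaks (AA major,
#' BB minor) and both cross peaks (AB major-to-minor, BA minor-to-major).
#'
#' @param residue_label residue identifier, e.g. `"W43e"` or `"T17"`
#' @param temperature sample temperature (K)
#' @param mixing_times mixing times (s), nonnegative, strictly increasing
#' @param I_AA,I_BB,I_AB,I_BA intensity series aligned with `mixing_times`
#' @param sigma optional per-point intensity uncertainty
#' @return an object of class `zz_dataset`
#' @export
zz_dataset <- function(residue_label, temperature, mixing_times,
                       I_AA, I_BB, I_AB, I_BA, sigma = NULL) {
  n <- length(mixing_times)
  if (n < 1) stop("mixing_times must be non-empty")
  if (any(mixing_times < 0)) stop("mixing times must be nonnegative")
  if (is.unsorted(mixing_times, strictly = TRUE))
    stop("mixing times must be strictly increasing")
  for (nm in c("I_AA", "I_BB", "I_AB", "I_BA")) {
    v <- get(nm)
    if (length(v) != n) stop(sprintf("%s must align with mixing_times", nm))
  }
  if (!is.null(sigma) && length(sigma) != n)
    stop("sigma must align with mixing_times")
  structure(list(residue_label = residue_label,
                 temperature = temperature,
                 mixing_times = as.numeric(mixing_times),
                 I_AA = as.numeric(I_AA), I_BB = as.numeric(I_BB),
                 I_AB = as.numeric(I_AB), I_BA = as.numeric(I_BA),
                 sigma = sigma),
            class = "zz_dataset")
}

#' @export
print.zz_dataset <- function(x, ...) {
  cat(sprintf("ZZ-exchange dataset: %s at %.2f K, %d mixing times (%g-%g s)\n",
              x$residue_label, x$temperature, length(x$mixing_times),
              min(x$mixing_times), max(x$mixing_times)))
  invisible(x)
}

# exp(-K t) for the 2x2 exchange-relaxation matrix, elementwise over t.
# K = [[R1_1 + k_12, -k_21], [-k_12, R1_2 + k_21]].
# Uses the Lagrange (Sylvester) form for a 2x2 matrix function; the nearly
# degenerate eigenvalue case falls back to the first-order expansion about
# the mean eigenvalue.
zz_propagator <- function(params, times) {
  a11 <- params$R1_1 + params$k_12
  a22 <- params$R1_2 + params$k_21
  tr <- a11 + a22
  disc <- sqrt((a11 - a22)^2 + 4 * params$k_12 * params$k_21)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (disc > 1e-10 * max(abs(l1), 1)) {
    e1 <- exp(-l1 * times)
    e2 <- exp(-l2 * times)
    beta <- (e1 - e2) / (l1 - l2)
    alpha <- (l1 * e2 - l2 * e1) / (l1 - l2)
  } else {
    lm <- tr / 2
    el <- exp(-lm * times)
    alpha <- el * (1 + times * lm)
    beta <- -times * el
  }
  list(E11 = alpha + beta * a11,
       E22 = alpha + beta * a22,
       E12 = -beta * params$k_21,
       E21 = -beta * params$k_12)
}

#' Predict ZZ-exchange intensity curves
#'
#' Closed-form solution of the two-site longitudinal exchange model.
#' Magnetization evolves as M(t) = exp(-K t) M(0) with
#' K = \[\[R1_1 + k_12, -k_21\], \[-k_12, R1_2 + k_21\]\]; the auto peaks
#' start from (I0_1, 0) and (0, I0_2) and the cross peaks read the
#' transferred component.
#'
#' @param params a [zz_params] object
#' @param times mixing times (s), nonnegative
#' @return a data.frame with columns `tmix_s`, `I_AA`, `I_BB`, `I_AB`,
#'   `I_BA`
#' @export
predict_zz <- function(params, times) {
  stopifnot(inherits(params, "zz_params"))
  if (any(times < 0)) stop("mixing times must be nonnegative")
  E <- zz_propagator(params, times)
  data.frame(tmix_s = times,
             I_AA = params$I0_1 * E$E11,
             I_BB = params$I0_2 * E$E22,
             I_AB = params$I0_1 * E$E21,
             I_BA = params$I0_2 * E$E12)
}

# residuals of the joint four-curve fit in log-parameter space
zz_residuals <- function(logp, dataset, weights) {
  p <- exp(logp)
  params <- structure(list(k_12 = p[1], k_21 = p[2], R1_1 = p[3],
                           R1_2 = p[4], I0_1 = p[5], I0_2 = p[6]),
                      class = "zz_params")
  pred <- predict_zz(params, dataset$mixing_times)
  res <- c(pred$I_AA - dataset$I_AA, pred$I_BB - dataset$I_BB,
           pred$I_AB - dataset$I_AB, pred$I_BA - dataset$I_BA)
  if (!is.null(weights)) res <- res * rep(weights, 4)
  res
}

#' Fit the two-site exchange model to a ZZ-exchange dataset
#'
#' Jointly fits all four intensity curves (both auto and both cross peaks)
#' by nonlinear least squares. All six parameters are constrained positive
#' through a log transform. Without a user-supplied starting point a
#' deterministic multi-start over a coarse grid of rate and relaxation
#' values is run and the best residual sum of squares wins (ties broken by
#' grid order).
#'
#' @param dataset a [zz_dataset] with at least 6 distinct mixing times
#' @param init optional [zz_params] starting point
#' @param weighted if `TRUE` and `dataset$sigma` is present, residuals are
#'   divided by the per-point uncertainty
#' @return an object of class `zz_fit` with elements `params`
#'   ([zz_params]), `stderr` (named vector, delta-method standard errors on
#'   the natural scale; `NULL` when unavailable), `rss`, `converged`,
#'   `n_points`
#' @export
fit_zz <- function(dataset, init = NULL, weighted = FALSE) {
  stopifnot(inherits(dataset, "zz_dataset"))
  tm <- dataset$mixing_times
  if (length(unique(tm)) < 6)
    stop("at least 6 distinct mixing times are required (6 free parameters)")
  obs <- c(dataset$I_AA, dataset$I_BB, dataset$I_AB, dataset$I_BA)
  if (all(obs == 0)) stop("all intensities are zero; nothing to fit")
  weights <- NULL
  if (weighted) {
    if (is.null(dataset$sigma)) stop("weighted fit requested but sigma absent")
    weights <- 1 / dataset$sigma
  }

  starts <- list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "zz_params"))
    ini <- unlist(init)
    # zero rates cannot be represented in log space; floor them
    ini[1:2] <- pmax(ini[1:2], 1e-6)
    starts[[1]] <- log(ini)
  } else {
    I0_1 <- max(dataset$I_AA, 1e-6)
    I0_2 <- max(dataset$I_BB, 1e-6)
    grid <- expand.grid(k_12 = c(0.1, 1, 10), k_21 = c(0.1, 1, 10),
                        R1_1 = c(0.5, 2), R1_2 = c(0.5, 2),
                        KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(grid)))
      starts[[i]] <- log(c(grid$k_12[i], grid$k_21[i], grid$R1_1[i],
                           grid$R1_2[i], I0_1, I0_2))
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = zz_residuals, dataset = dataset,
                         weights = weights, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("ZZ-exchange fit failed to converge from any start")

  p <- exp(best$par)
  names(p) <- c("k_12", "k_21", "R1_1", "R1_2", "I0_1", "I0_2")
  converged <- best$info %in% 1:4
  stderr <- NULL
  if (converged) {
    se_log <- tryCatch(
      sqrt(diag(solve(best$hessian)) * best$deviance /
             max(length(best$fvec) - 6, 1)),
      error = function(e) NULL)
    if (!is.null(se_log)) stderr <- stats::setNames(p * se_log, names(p))
  }
  structure(list(params = do.call(zz_params, as.list(p)),
                 stderr = stderr,
                 rss = best$deviance,
                 converged = converged,
                 n_points = length(tm),
                 message = best$message),
            class = "zz_fit")
}

#' @export
print.zz_fit <- function(x, ...) {
  cat(sprintf("ZZ-exchange fit (%s, rss = %.4g, %d mixing times)\n",
              if (x$converged) "converged" else "NOT converged",
              x$rss, x$n_points))
  print(x$params)
  invisible(x)
}

#' Read / write ZZ-exchange datasets as TSV
#'
#' Columns: residue, temperature_K, tmix_s, I_AA, I_BB, I_AB, I_BA and
#' optionally sigma. One file may hold one residue/temperature series.
#'
#' @param file path to a tab-separated file
#' @return a [zz_dataset]
#' @export
read_zz_tsv <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.delim(file, check.names = FALSE)
  need <- c("residue", "temperature_K", "tmix_s", "I_AA", "I_BB", "I_AB", "I_BA")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  zz_dataset(residue_label = as.character(d$residue[1]),
             temperature = d$temperature_K[1],
             mixing_times = d$tmix_s,
             I_AA = d$I_AA, I_BB = d$I_BB, I_AB = d$I_AB, I_BA = d$I_BA,
             sigma = if ("sigma" %in% names(d)) d$sigma else NULL)
}

#' @rdname read_zz_tsv
#' @param dataset a [zz_dataset]
#' @export
write_zz_tsv <- function(dataset, file) {
  d <- data.frame(residue = dataset$residue_label,
                  temperature_K = dataset$temperature,
                  tmix_s = dataset$mixing_times,
                  I_AA = dataset$I_AA, I_BB = dataset$I_BB,
                  I_AB = dataset$I_AB, I_BA = dataset$I_BA)
  if (!is.null(dataset$sigma)) d$sigma <- dataset$sigma
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
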