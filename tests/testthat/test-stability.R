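test_that("fluorescence spectra normalize to fraction unfolded", {
  D <- seq(0, 5, length.out = 12)
  wl <- seq(300, 450, by = 2)
  # folded and unfolded reference spectra with different integrals
  folded <- exp(-(wl - 330)^2 / 400)
  unfolded <- 1.8 * exp(-(wl - 355)^2 / 600)
  p_u <- c(0, 0, 0.1, 0.25, 0.5, 0.75, 0.9, 0.97, 1, 1, 1, 1)
  spectra <- t(vapply(p_u, function(p) (1 - p) * folded + p * unfolded,
                      numeric(length(wl))))
  cur <- fluorescence_to_fraction(D, spectra, wl)
  expect_equal(cur$response[1], 0, tolerance = 1e-9)
  expect_equal(cur$response[12], 1, tolerance = 1e-9)
  expect_equal(cur$response[5], 0.5, tolerance = 1e-9)
  expect_true(all(cur$response > -0.05 & cur$response < 1.05))
  # identical folded/unfolded signal is degenerate
  same <- t(vapply(p_u, function(p) folded, numeric(length(wl))))
  expect_error(fluorescence_to_fraction(D, same, wl), "degenerate")
})

test_that("chemical fits recover midpoint, m-value and free energy exactly", {
  cur <- gen_denaturation("chemical", list(Cm = 2.66, m = 1.616), noise_sd = 0)
  fit <- fit_chemical(cur)
  expect_true(fit$converged)
  expect_equal(fit$midpoint, 2.66, tolerance = 1e-6)
  expect_equal(fit$m_value, 1.616, tolerance = 1e-6)
  expect_equal(fit$dG_U, 1.616 * 2.66, tolerance = 1e-6)
  # with sloped baselines
  cur2 <- gen_denaturation("chemical",
                           list(Cm = 1.7, m = 2.0, b_f = 0.05, s_f = 0.01,
                                b_u = 0.95, s_u = -0.01), noise_sd = 0)
  fit2 <- fit_chemical(cur2)
  expect_equal(fit2$midpoint, 1.7, tolerance = 1e-6)
  expect_equal(fit2$m_value, 2.0, tolerance = 1e-6)
})

test_that("featureless denaturation data raise a no-transition error", {
  D <- seq(0, 5, length.out = 12)
  expect_error(fit_chemical(denat_curve(D, rep(0, 12))), "no transition")
  expect_error(fit_chemical(denat_curve(D, 0.1 + 0.05 * D)), "no transition")
  TC <- seq(25, 95, by = 5)
  expect_error(fit_thermal(melt_curve(TC, -10 + 0.02 * TC)), "no transition")
})

test_that("chemical midpoint estimation is accurate at 2% noise", {
  err <- vapply(1:50, function(i) {
    cur <- gen_denaturation("chemical", list(Cm = 2.66, m = 1.616),
                            noise_sd = 0.02, seed = 3000 + i)
    abs(fit_chemical(cur)$midpoint - 2.66)
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("thermal fits recover the melting temperature", {
  mc <- gen_denaturation("thermal", list(Tm = 81, dH_vH = 50), noise_sd = 0)
  fit <- fit_thermal(mc)
  expect_equal(fit$midpoint, 81, tolerance = 1e-6)
  # steeply sloped baselines do not bias the midpoint
  mc2 <- gen_denaturation("thermal",
                          list(Tm = 81, dH_vH = 50, s_f = 0.5, s_u = -0.5),
                          noise_sd = 0)
  expect_lt(abs(fit_thermal(mc2)$midpoint - 81), 0.01)
})

test_that("the fitted midpoint is where the corrected fraction crosses half", {
  cur <- gen_denaturation("chemical",
                          list(Cm = 2.2, m = 1.8, b_f = 0.1, s_f = 0.02,
                               b_u = 0.9, s_u = 0.01), noise_sd = 0)
  fit <- fit_chemical(cur)
  b <- fit$baselines
  # baseline-corrected fraction at the fitted midpoint
  D <- fit$midpoint
  y_mid <- (b["b_f"] + b["s_f"] * D) * 0.5 + (b["b_u"] + b["s_u"] * D) * 0.5
  pu <- confex:::p_unfolded_chem(D, fit$midpoint, fit$m_value)
  expect_equal(pu, 0.5, tolerance = 1e-6)
  model_mid <- (b["b_f"] + b["s_f"] * D) * (1 - pu) +
    (b["b_u"] + b["s_u"] * D) * pu
  expect_equal(unname(model_mid), unname(y_mid), tolerance = 1e-9)
})

test_that("destabilization free energies difference and antisymmetry", {
  expect_equal(delta_delta_g(2.7, 4.3), 1.6, tolerance = 1e-12)
  expect_equal(delta_delta_g(3.3, 3.3), 0)
  expect_equal(delta_delta_g(4.3, 2.7), -delta_delta_g(2.7, 4.3))
  expect_error(delta_delta_g(NA, 1), "finite")
})

test_that("denaturation files round-trip through CSV", {
  cur <- gen_denaturation("chemical", list(Cm = 2, m = 1.5),
                          noise_sd = 0.01, seed = 12)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(conc_M = cur$denaturant,
                       fraction_unfolded = cur$response), f, row.names = FALSE)
  back <- read_denaturation_csv(f)
  expect_s3_class(back, "denat_curve")
  expect_equal(back$response, cur$response, tolerance = 1e-12)
})
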