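test_that("zero-noise ZZ datasets equal the model prediction exactly", {
  tr <- zz_params(2, 1, 1.5, 1.0, 1, 0.5)
  ds <- gen_zz_dataset(tr, noise_sd = 0)
  pred <- predict_zz(tr, ds$mixing_times)
  expect_identical(ds$I_AA, pred$I_AA)
  expect_identical(ds$I_BB, pred$I_BB)
  expect_identical(ds$I_AB, pred$I_AB)
  expect_identical(ds$I_BA, pred$I_BA)
})

test_that("all generators are bit-identical under a fixed seed", {
  tr <- zz_params(2, 1, 1.5, 1.0, 1, 0.5)
  expect_identical(gen_zz_dataset(tr, noise_sd = 0.05, seed = 42),
                   gen_zz_dataset(tr, noise_sd = 0.05, seed = 42))
  expect_identical(
    gen_rate_series("arrhenius", list(k0 = 2, Ea = 9), noise_sd = 0.1, seed = 7),
    gen_rate_series("arrhenius", list(k0 = 2, Ea = 9), noise_sd = 0.1, seed = 7))
  expect_identical(gen_titration(1e-4, noise_sd = 0.05, seed = 3),
                   gen_titration(1e-4, noise_sd = 0.05, seed = 3))
  expect_identical(
    gen_denaturation("chemical", list(Cm = 2.66, m = 1.6), noise_sd = 0.02, seed = 5),
    gen_denaturation("chemical", list(Cm = 2.66, m = 1.6), noise_sd = 0.02, seed = 5))
  expect_identical(gen_rotamer_traj(n_frames = 200, seed = 11),
                   gen_rotamer_traj(n_frames = 200, seed = 11))
  expect_identical(gen_backbone_ensemble(rep(0.3, 3), n_frames = 4, seed = 13),
                   gen_backbone_ensemble(rep(0.3, 3), n_frames = 4, seed = 13))
})

test_that("ZZ intensity noise has the configured standard deviation", {
  tr <- zz_params(2, 1, 1.5, 1.0, 1, 0.5)
  tm <- seq(0, 0.4, length.out = 1000)
  ds <- gen_zz_dataset(tr, mixing_times = tm, noise_sd = 0.02, seed = 8)
  pred <- predict_zz(tr, tm)
  res <- c(ds$I_AA - pred$I_AA, ds$I_BB - pred$I_BB,
           ds$I_AB - pred$I_AB, ds$I_BA - pred$I_BA)
  expect_gte(sd(res), 0.018)
  expect_lte(sd(res), 0.022)
})

test_that("generator input validation rejects bad specifications", {
  tr <- zz_params(2, 1, 1.5, 1.0, 1, 0.5)
  expect_error(gen_zz_dataset(tr, mixing_times = c(0, 0.1, 0.2)), "4 mixing")
  expect_error(gen_zz_dataset(tr, noise_sd = -1), "nonnegative")
  expect_error(gen_rate_series("vogel", list(k0 = 1, Ea = 5)))
  expect_error(gen_titration(1e-4, concentrations = c(-1e-5, 1e-4)), "positive")
  expect_error(gen_denaturation("chemical", list(Cm = 7, m = 1.6)), "inside")
})

test_that("noiseless Arrhenius rate series are exactly log-linear in 1/T", {
  rs <- gen_rate_series("arrhenius", list(k0 = 3, Ea = 11), noise_sd = 0)
  fit <- lm(log(rs$k) ~ I(1 / rs$temperatures))
  expect_lt(sum(residuals(fit)^2), 1e-24)
  expect_equal(fit_arrhenius(rs)$r_squared, 1, tolerance = 1e-12)
})

test_that("the dimer-coupled law yields a negative apparent activation energy", {
  rs <- gen_rate_series("dimer_coupled",
                        list(k0 = 10, Ea_intrinsic = 9, Kd0 = 100e-6,
                             dH_assoc = 30, Ctot = 1e-3),
                        noise_sd = 0)
  expect_lt(fit_arrhenius(rs)$Ea_app, 0)
  f_M <- attr(rs, "f_M")
  expect_true(all(f_M > 0 & f_M <= 1))
})

test_that("dimer coupling with zero association enthalpy is Arrhenius rescaled", {
  temps <- seq(278, 303, by = 5)
  plain <- gen_rate_series("arrhenius", list(k0 = 4, Ea = 9), temps)
  coupled <- gen_rate_series("dimer_coupled",
                             list(k0 = 4, Ea_intrinsic = 9, Kd0 = 1e-4,
                                  dH_assoc = 0, Ctot = 5e-4), temps)
  ratio <- coupled$k / plain$k
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
  expect_equal(fit_arrhenius(coupled)$Ea_app, 9, tolerance = 1e-9)
})

test_that("titration volumes follow the mass-action closed form", {
  Kd <- 1e-4
  # at Ctot = Kd the quadratic gives [M] = Kd/2, i.e. half the protein
  tt <- gen_titration(Kd, concentrations = c(Kd, 2 * Kd), noise_sd = 0)
  f <- tt$V_monomer / (tt$V_monomer + tt$V_dimer)
  expect_equal(f[1], 0.5, tolerance = 1e-12)
  # dilution limit: essentially all monomer
  tt2 <- gen_titration(Kd, concentrations = c(1e-6 * Kd, Kd), noise_sd = 0)
  f2 <- tt2$V_monomer[1] / (tt2$V_monomer[1] + tt2$V_dimer[1])
  expect_gt(f2, 0.999)
})

test_that("chemical generator evaluates to exactly 0.5 at the midpoint", {
  grid <- sort(c(seq(0, 5, length.out = 12), 2.66))
  cur <- gen_denaturation("chemical", list(Cm = 2.66, m = 1.6), grid = grid,
                          noise_sd = 0)
  expect_equal(cur$response[which(grid == 2.66)], 0.5, tolerance = 1e-12)
})

test_that("noiseless thermal melts are strictly monotone between baselines", {
  mc <- gen_denaturation("thermal", list(Tm = 81, dH_vH = 50, s_f = 0, s_u = 0),
                         noise_sd = 0)
  expect_true(all(diff(mc$ellipticity) > 0))
})

test_that("a frozen rotamer chain emits a constant dihedral series", {
  Q0 <- matrix(0, 6, 6)
  rt <- gen_rotamer_traj(Q0, n_frames = 100, angular_noise_sd = 0, seed = 4)
  expect_equal(length(unique(rt$chi1)), 1)
  expect_equal(length(unique(rt$chi2)), 1)
  expect_equal(nrow(attr(rt, "jump_log")), 0)
})

test_that("CTMC dwell times follow the exponential law mean 1/q", {
  # uniform exit rate 1 per ns from every state
  Q <- rotamer_rate_matrix(q_chi1 = 0.6, q_chi2 = 0.4)
  rt <- gen_rotamer_traj(Q, n_frames = 2600, frame_interval = 1,
                         angular_noise_sd = 0, seed = 21)
  jumps <- attr(rt, "jump_log")
  expect_gt(nrow(jumps), 2000)
  dwells <- diff(c(0, jumps$time))
  expect_equal(mean(dwells), 1, tolerance = 0.05)
})

test_that("angular noise has the configured circular spread", {
  rt <- gen_rotamer_traj(rotamer_rate_matrix(0.001, 0.001),
                         n_frames = 1e5, angular_noise_sd = 10, seed = 17)
  tab <- confex:::rotamer_state_table()
  centers <- tab$chi1_center[match(attr(rt, "true_states"), tab$state)]
  dev <- confex:::wrap_angle(rt$chi1 - centers)
  expect_gte(sd(dev), 9)
  expect_lte(sd(dev), 11)
})

test_that("long-run rotamer occupancies match the CTMC stationary law", {
  Q <- rotamer_rate_matrix(q_chi1 = 0.3, q_chi2 = 0.1)
  pi_true <- confex:::ctmc_stationary(Q)
  rt <- gen_rotamer_traj(Q, n_frames = 20000, angular_noise_sd = 0, seed = 31)
  occ <- table(factor(attr(rt, "true_states"), levels = names(pi_true)))
  occ <- as.numeric(occ) / sum(occ)
  # effective sample size ~ number of dwells, not frames
  n_eff <- nrow(attr(rt, "jump_log"))
  se <- sqrt(pi_true * (1 - pi_true) / n_eff)
  expect_true(all(abs(occ - pi_true) <= 3 * se + 1e-3))
})

test_that("a zero-fluctuation ensemble has identical frames", {
  tr <- gen_backbone_ensemble(rep(0, 4), n_frames = 6, seed = 2)
  expect_equal(max(tr$xyz) - min(tr$xyz), max(tr$xyz[1, ]) - min(tr$xyz[1, ]))
  expect_true(all(apply(tr$xyz, 2, function(col) diff(range(col)) == 0)))
})

test_that("ground-truth sidecars serialize generator parameters", {
  tt <- gen_titration(5e-5, noise_sd = 0.02, seed = 9)
  f <- tempfile(fileext = ".json")
  write_truth_json(tt, f)
  expect_equal(jsonlite::read_json(f)[[1]], 5e-5)
  ds <- gen_zz_dataset(zz_params(2, 1, 1.5, 1, 1, 0.5), noise_sd = 0)
  f2 <- tempfile(fileext = ".json")
  write_truth_json(ds, f2)
  expect_equal(jsonlite::read_json(f2)$k_12, 2)
  expect_error(write_truth_json(list(), f2), "no ground-truth")
})
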