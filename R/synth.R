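#' Synthetic ZZ-exchange dataset with known ground truth
#'
#' Evaluates the two-site exchange model ([predict_zz]) on a mixing-time
#' grid and adds i.i.d. Gaussian noise to all four intensity curves.
#' Intensities may go slightly negative under noise, as real peak
#' integrals can.
#'
#' @param truth a [zz_params] object (the ground-truth parameter set)
#' @param mixing_times mixing-time grid (s), >= 4 nonnegative points
#' @param temperature temperature (K) recorded in the dataset
#' @param noise_sd standard deviation of the additive intensity noise
#'   (same arbitrary units as the intensities); 0 gives the exact model
#' @param seed integer seed; a fixed seed makes the output bit-identical
#'   across calls
#' @param residue_label residue identifier stored in the dataset
#' @return a [zz_dataset]; the ground truth is attached as
#'   `attr(, "truth")`
#' @export
gen_zz_dataset <- function(truth, mixing_times = seq(0, 0.4, length.out = 8),
                           temperature = .T_REF, noise_sd = 0.02,
                           seed = NULL, residue_label = "W43e") {
  stopifnot(inherits(truth, "zz_params"))
  if (length(mixing_times) < 4) stop("at least 4 mixing times are required")
  if (any(mixing_times < 0)) stop("mixing times must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  pred <- predict_zz(truth, mixing_times)
  n <- length(mixing_times)
  noise <- with_seed(seed, matrix(stats::rnorm(4 * n, 0, noise_sd), n, 4))
  ds <- zz_dataset(residue_label, temperature, mixing_times,
                   I_AA = pred$I_AA + noise[, 1],
                   I_BB = pred$I_BB + noise[, 2],
                   I_AB = pred$I_AB + noise[, 3],
                   I_BA = pred$I_BA + noise[, 4],
                   sigma = if (noise_sd > 0) rep(noise_sd, n) else NULL)
  attr(ds, "truth") <- truth
  ds
}

#' Arrhenius rate law
#'
#' k(T) = k0 * exp(-Ea/R * (1/T - 1/T0)), with k0 the rate at the
#' reference temperature T0 = 298.15 K.
#'
#' @param temperatures temperatures (K)
#' @param k0 rate at `T0` (s^-1)
#' @param Ea activation energy (kcal/mol)
#' @param T0 reference temperature (K)
#' @return rates (s^-1)
#' @export
arrhenius_rate <- function(temperatures, k0, Ea, T0 = .T_REF)
  k0 * exp(-Ea / .R_KCAL * (1 / temperatures - 1 / T0))

#' Dimer-coupled observed rate law
#'
#' Composes an intrinsic Arrhenius exchange rate with the equilibrium
#' monomer fraction of a temperature-dependent monomer-dimer equilibrium:
#' k_obs(T) = f_M(T) * k_intrinsic(T), with Kd(T) following van't Hoff
#' behavior, Kd(T) = Kd0 * exp(dH_assoc/R * (1/T - 1/T0)). A positive
#' association enthalpy favors the dimer at high temperature; when
#' exchange occurs only in the monomer, the observed rate can then fall
#' with temperature, producing a negative apparent activation energy.
#'
#' @param temperatures temperatures (K)
#' @param k0 intrinsic exchange rate at `T0` (s^-1)
#' @param Ea_intrinsic intrinsic activation energy (kcal/mol)
#' @param Kd0 dissociation constant at `T0` (M)
#' @param dH_assoc van't Hoff association enthalpy (kcal/mol; positive
#'   means dimer favored at high temperature)
#' @param Ctot total protein concentration (M)
#' @param T0 reference temperature (K)
#' @return observed rates (s^-1)
#' @export
dimer_coupled_rate <- function(temperatures, k0, Ea_intrinsic, Kd0,
                               dH_assoc, Ctot, T0 = .T_REF) {
  if (k0 <= 0 || Kd0 <= 0 || Ctot <= 0)
    stop("k0, Kd0 and Ctot must be positive")
  Kd_T <- Kd0 * exp(dH_assoc / .R_KCAL * (1 / temperatures - 1 / T0))
  f_M <- monomer_fraction(Ctot, Kd_T)
  f_M * arrhenius_rate(temperatures, k0, Ea_intrinsic, T0)
}

#' Synthetic exchange-rate temperature series
#'
#' Generates a [rate_series] from either a pure Arrhenius law or the
#' dimer-coupled law of [dimer_coupled_rate], with optional multiplicative
#' lognormal noise (rates are positive observables).
#'
#' @param law `"arrhenius"` or `"dimer_coupled"`
#' @param truth named list of rate-law parameters. For `"arrhenius"`:
#'   `k0`, `Ea`. For `"dimer_coupled"`: `k0`, `Ea_intrinsic`, `Kd0`,
#'   `dH_assoc`, `Ctot`.
#' @param temperatures temperature grid (K), >= 3 points in 273-313 K
#' @param noise_sd standard deviation of the lognormal noise on the log
#'   scale; 0 gives exact model rates
#' @param seed integer seed
#' @param residue_label,direction stored in the series
#' @return a [rate_series] with the truth in `attr(, "truth")` and, for
#'   the dimer-coupled law, the monomer fractions in `attr(, "f_M")`
#' @export
gen_rate_series <- function(law = c("arrhenius", "dimer_coupled"), truth,
                            temperatures = seq(278, 303, by = 5),
                            noise_sd = 0, seed = NULL,
                            residue_label = "W43e", direction = "2->1") {
  law <- match.arg(law)
  if (length(temperatures) < 3) stop("at least 3 temperatures are required")
  if (any(temperatures < 273) || any(temperatures > 313))
    stop("temperatures must lie in 273-313 K")
  if (law == "arrhenius") {
    k <- arrhenius_rate(temperatures, truth$k0, truth$Ea)
    f_M <- NULL
  } else {
    k <- dimer_coupled_rate(temperatures, truth$k0, truth$Ea_intrinsic,
                            truth$Kd0, truth$dH_assoc, truth$Ctot)
    Kd_T <- truth$Kd0 * exp(truth$dH_assoc / .R_KCAL *
                              (1 / temperatures - 1 / .T_REF))
    f_M <- monomer_fraction(truth$Ctot, Kd_T)
  }
  if (noise_sd > 0)
    k <- k * exp(with_seed(seed, stats::rnorm(length(k), 0, noise_sd)))
  rs <- rate_series(residue_label, direction, temperatures, k)
  attr(rs, "truth") <- c(list(law = law), truth)
  if (!is.null(f_M)) attr(rs, "f_M") <- f_M
  rs
}

#' Synthetic dimerization titration
#'
#' Solves the 2M <-> M2 mass-action equilibrium at each total
#' concentration and emits monomer and dimer peak volumes proportional to
#' \[M\] and 2\[D\], multiplied by lognormal noise.
#'
#' @param Kd ground-truth dissociation constant (M)
#' @param concentrations total concentrations (M), >= 2, positive
#' @param noise_sd lognormal noise standard deviation on the log scale
#' @param seed integer seed
#' @param response_scale volume per molar concentration (a.u./M)
#' @return a [dimer_titration] with `attr(, "truth")` = Kd
#' @export
gen_titration <- function(Kd, concentrations = c(20, 100, 500, 1000) * 1e-6,
                          noise_sd = 0, seed = NULL, response_scale = 1e6) {
  if (Kd <= 0) stop("Kd must be positive")
  if (length(concentrations) < 2) stop("at least 2 concentrations required")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  f_M <- monomer_fraction(concentrations, Kd)
  M <- f_M * concentrations
  D2 <- concentrations - M          # 2[D], monomer equivalents in dimer
  Vm <- response_scale * M
  Vd <- response_scale * D2
  if (noise_sd > 0) {
    noise <- with_seed(seed,
                       matrix(stats::rnorm(2 * length(M), 0, noise_sd),
                              ncol = 2))
    Vm <- Vm * exp(noise[, 1])
    Vd <- Vd * exp(noise[, 2])
  }
  tt <- dimer_titration(concentrations, Vm, Vd)
  attr(tt, "truth") <- Kd
  tt
}

#' Synthetic denaturation curves
#'
#' Two-state sigmoid with linear folded/unfolded baselines plus Gaussian
#' noise. The chemical mode follows the linear extrapolation model
#' dG(D) = m (Cm - D) at 298.15 K; the thermal mode uses a van't Hoff
#' sigmoid in temperature.
#'
#' @param mode `"chemical"` or `"thermal"`
#' @param truth named list. Chemical: `Cm` (M), `m` (kcal/(mol M)) and
#'   optional baselines `b_f`, `s_f`, `b_u`, `s_u` (defaults 0, 0, 1, 0:
#'   the curve is a fraction unfolded). Thermal: `Tm` (C), `dH_vH`
#'   (kcal/mol) and baselines in mdeg (defaults -12, -0.01, -3, -0.02).
#' @param grid denaturant grid (M; default 12 points, 0-5 M) or
#'   temperature grid (C; default every 2 C, 25-95 C). The midpoint must
#'   lie inside the grid range.
#' @param noise_sd additive Gaussian noise standard deviation
#' @param seed integer seed
#' @return a [denat_curve] (`chemical`) or [melt_curve] (`thermal`) with
#'   `attr(, "truth")`
#' @export
gen_denaturation <- function(mode = c("chemical", "thermal"), truth,
                             grid = NULL, noise_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (mode == "chemical") {
    grid <- grid %||% seq(0, 5, length.out = 12)
    if (truth$Cm <= min(grid) || truth$Cm >= max(grid))
      stop("midpoint Cm must lie inside the denaturant grid")
    b <- list(b_f = truth$b_f %||% 0, s_f = truth$s_f %||% 0,
              b_u = truth$b_u %||% 1, s_u = truth$s_u %||% 0)
    pu <- p_unfolded_chem(grid, truth$Cm, truth$m)
    y <- (b$b_f + b$s_f * grid) * (1 - pu) + (b$b_u + b$s_u * grid) * pu
    if (noise_sd > 0)
      y <- y + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
    out <- denat_curve(grid, y)
  } else {
    grid <- grid %||% seq(25, 95, by = 2)
    if (truth$Tm <= min(grid) || truth$Tm >= max(grid))
      stop("midpoint Tm must lie inside the temperature grid")
    b <- list(b_f = truth$b_f %||% -12, s_f = truth$s_f %||% -0.01,
              b_u = truth$b_u %||% -3, s_u = truth$s_u %||% -0.02)
    pu <- p_unfolded_therm(celsius_to_kelvin(grid),
                           celsius_to_kelvin(truth$Tm), truth$dH_vH)
    y <- (b$b_f + b$s_f * grid) * (1 - pu) + (b$b_u + b$s_u * grid) * pu
    if (noise_sd > 0)
      y <- y + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
    out <- melt_curve(grid, y)
  }
  attr(out, "truth") <- c(truth, b[setdiff(names(b), names(truth))])
  out
}

# --- rotamer CTMC ----------------------------------------------------------

# the six combined chi1 x chi2 rotamer states and their angle centers
rotamer_state_table <- function() {
  chi1 <- c("g+" = 60, "g-" = -60, "t" = 180)
  chi2 <- c("-90" = -90, "+90" = 90)
  g <- expand.grid(chi1 = names(chi1), chi2 = names(chi2),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(state = paste(g$chi1, g$chi2, sep = "/"),
             chi1 = g$chi1, chi2 = g$chi2,
             chi1_center = unname(chi1[g$chi1]),
             chi2_center = unname(chi2[g$chi2]),
             stringsAsFactors = FALSE)
}

#' Default rotamer-jump rate matrix
#'
#' Generator matrix of a continuous-time Markov chain over the six
#' combined chi1 (g+, g-, t) x chi2 (-90, +90) rotamer states in which a
#' jump changes exactly one dihedral at a time: each chi1 state can jump
#' to either of the other two chi1 states at rate `q_chi1 / 2` each, and
#' chi2 flips at rate `q_chi2`.
#'
#' @param q_chi1 total chi1 exit rate (per ns)
#' @param q_chi2 chi2 flip rate (per ns)
#' @return a 6x6 generator matrix with state names from the combined bins
#' @export
rotamer_rate_matrix <- function(q_chi1 = 0.01, q_chi2 = 0.01) {
  tab <- rotamer_state_table()
  n <- nrow(tab)
  Q <- matrix(0, n, n, dimnames = list(tab$state, tab$state))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    same1 <- tab$chi1[i] == tab$chi1[j]
    same2 <- tab$chi2[i] == tab$chi2[j]
    if (!same1 && same2) Q[i, j] <- q_chi1 / 2
    if (same1 && !same2) Q[i, j] <- q_chi2
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of a CTMC generator (left null vector); a fully
# absorbing (all-zero) generator has no unique stationary law and falls
# back to uniform
ctmc_stationary <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- tryCatch(as.numeric(qr.solve(A, b)),
                     error = function(e) rep(1 / n, n))
  pi_hat <- stats::setNames(pi_hat, rownames(Q))
  pi_hat / sum(pi_hat)
}

#' Synthetic rotamer dihedral trajectory
#'
#' Simulates a continuous-time Markov jump process over the six combined
#' chi1 x chi2 rotamer states (Gillespie algorithm), samples the state at
#' regular frame times, and emits dihedral angles as the state center
#' plus wrapped Gaussian angular noise. The exact jump log and the true
#' per-frame state labels are attached for oracle comparisons.
#'
#' @param Q 6x6 CTMC generator matrix (rows sum to zero, nonnegative
#'   off-diagonals), e.g. from [rotamer_rate_matrix()]
#' @param n_frames number of frames to emit
#' @param frame_interval time between frames (ns), > 0
#' @param angular_noise_sd wrapped Gaussian angular noise (degrees)
#' @param seed integer seed
#' @param residue_label stored in the series
#' @param init_state starting state name; `NULL` draws from the
#'   stationary distribution
#' @return a `dihedral_series` (fields `time_ns`, `chi1`, `chi2`) with
#'   attributes `truth` (Q and noise), `jump_log` (data.frame time, from,
#'   to) and `true_states` (per-frame combined state labels)
#' @export
gen_rotamer_traj <- function(Q = rotamer_rate_matrix(), n_frames = 2000,
                             frame_interval = 1, angular_noise_sd = 10,
                             seed = NULL, residue_label = "W43",
                             init_state = NULL) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  offdiag <- Q; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(Q)) > 1e-8 * max(abs(Q), 1)))
    stop("rows of Q must sum to zero")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  tab <- rotamer_state_table()
  if (is.null(rownames(Q))) rownames(Q) <- colnames(Q) <- tab$state
  states <- rownames(Q)

  sim <- with_seed(seed, {
    s <- if (!is.null(init_state)) match(init_state, states)
    else sample(length(states), 1, prob = pmax(ctmc_stationary(Q), 0))
    if (is.na(s)) stop("unknown init_state")
    t_end <- (n_frames - 1) * frame_interval
    jump_t <- numeric(0); jump_from <- integer(0); jump_to <- integer(0)
    t_now <- 0; cur <- s
    path_t <- 0; path_s <- cur       # piecewise-constant path breakpoints
    repeat {
      q_exit <- -Q[cur, cur]
      if (q_exit <= 0) break
      t_now <- t_now + stats::rexp(1, q_exit)
      if (t_now > t_end) break
      rates <- Q[cur, ]; rates[cur] <- 0
      nxt <- sample(length(states), 1, prob = rates)
      jump_t <- c(jump_t, t_now); jump_from <- c(jump_from, cur)
      jump_to <- c(jump_to, nxt)
      cur <- nxt
      path_t <- c(path_t, t_now); path_s <- c(path_s, cur)
    }
    frame_times <- seq(0, by = frame_interval, length.out = n_frames)
    frame_state <- path_s[findInterval(frame_times, path_t)]
    noise1 <- stats::rnorm(n_frames, 0, angular_noise_sd)
    noise2 <- stats::rnorm(n_frames, 0, angular_noise_sd)
    list(frame_times = frame_times, frame_state = frame_state,
         jumps = data.frame(time = jump_t, from = states[jump_from],
                            to = states[jump_to]),
         noise1 = noise1, noise2 = noise2)
  })

  centers1 <- tab$chi1_center[match(states[sim$frame_state], tab$state)]
  centers2 <- tab$chi2_center[match(states[sim$frame_state], tab$state)]
  out <- dihedral_series(residue_label = residue_label,
                         time_ns = sim$frame_times,
                         chi1 = wrap_angle(centers1 + sim$noise1),
                         chi2 = wrap_angle(centers2 + sim$noise2))
  attr(out, "truth") <- list(Q = Q, angular_noise_sd = angular_noise_sd)
  attr(out, "jump_log") <- sim$jumps
  attr(out, "true_states") <- states[sim$frame_state]
  out
}

# --- backbone coordinate ensemble ------------------------------------------

# simple non-degenerate backbone template: N, CA, C, O per residue laid
# out along x with fixed offsets (geometry is schematic, not stereochemical)
backbone_template <- function(n_residues) {
  offs <- rbind(N = c(-1.2, 0.8, 0.0),
                CA = c(0.0, 0.0, 0.0),
                C = c(1.2, 0.8, 0.2),
                O = c(1.4, 2.0, 0.3))
  xyz <- matrix(0, 4 * n_residues, 3)
  atom <- data.frame(elety = character(4 * n_residues),
                     resno = integer(4 * n_residues),
                     resid = "ALA", stringsAsFactors = FALSE)
  for (i in seq_len(n_residues)) {
    rows <- (i - 1) * 4 + 1:4
    xyz[rows, ] <- sweep(offs, 2, c(3.8 * (i - 1), 0, 0), "+")
    atom$elety[rows] <- rownames(offs)
    atom$resno[rows] <- i
  }
  list(xyz = xyz, atom = atom)
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  R <- R %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Synthetic backbone coordinate ensemble
#'
#' Builds a schematic backbone (N, CA, C, O per residue) and generates
#' frames as the mean structure plus an independent isotropic Gaussian
#' displacement per residue per frame (all four atoms of a residue move
#' together), optionally composed with a random global rotation and
#' translation per frame. After superposition the expected per-residue
#' RMSF is sd * sqrt(3).
#'
#' @param sd_profile per-residue displacement standard deviation (A per
#'   axis); its length sets the number of residues (>= 2)
#' @param n_frames number of frames (>= 2)
#' @param rigid_body if `TRUE`, apply a random global rotation and
#'   translation to every frame
#' @param seed integer seed
#' @param frame_interval time between frames (ns)
#' @return an `md_trajectory` (see [trajectory()]) with
#'   `attr(, "truth")` = the sd profile
#' @export
gen_backbone_ensemble <- function(sd_profile, n_frames = 100,
                                  rigid_body = FALSE, seed = NULL,
                                  frame_interval = 1) {
  n_res <- length(sd_profile)
  if (n_res < 2) stop("at least 2 residues are required")
  if (n_frames < 2) stop("at least 2 frames are required")
  if (any(sd_profile < 0)) stop("sd_profile must be nonnegative")
  tmpl <- backbone_template(n_res)
  if (max(dist(tmpl$xyz[1:4, ])) == 0)
    stop("degenerate mean structure")
  n_atoms <- nrow(tmpl$xyz)
  xyz <- with_seed(seed, {
    out <- matrix(0, n_frames, 3 * n_atoms)
    for (f in seq_len(n_frames)) {
      disp <- matrix(stats::rnorm(3 * n_res, 0, rep(sd_profile, each = 3)),
                     ncol = 3, byrow = TRUE)
      coords <- tmpl$xyz + disp[tmpl$atom$resno, , drop = FALSE]
      if (rigid_body) {
        R <- random_rotation()
        tr <- stats::rnorm(3, 0, 10)
        coords <- coords %*% t(R) + matrix(tr, n_atoms, 3, byrow = TRUE)
      }
      out[f, ] <- as.numeric(t(coords))
    }
    out
  })
  tr <- trajectory(xyz, tmpl$atom, frame_interval = frame_interval)
  attr(tr, "truth") <- sd_profile
  tr
}

#' Write a generator's ground truth as a JSON sidecar
#'
#' Every generator attaches its true parameter set as `attr(x, "truth")`;
#' this helper serializes that attribute next to the data file so that
#' downstream fits can be scored against known values.
#'
#' @param x an object produced by one of the `gen_*` generators
#' @param file output path (conventionally `<data file>.truth.json`)
#' @return the path, invisibly
#' @export
write_truth_json <- function(x, file) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("object carries no ground-truth attribute")
  if (inherits(truth, "zz_params")) truth <- unclass(truth)
  if (is.matrix(truth)) truth <- as.data.frame(truth)
  if (is.list(truth) && !is.null(truth$Q) && is.matrix(truth$Q))
    truth$Q <- as.data.frame(truth$Q)
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
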