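test_that("planar arrangements give the canonical trans and cis angles", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(compute_dihedral(p1, p2, p3, c(1, -1, 0)), -180)  # trans, wrapped
  expect_equal(compute_dihedral(p1, p2, p3, c(1, 1, 0)), 0)      # cis
  expect_error(compute_dihedral(p1, p1, p3, c(1, 1, 0)), "coincide")
  expect_error(compute_dihedral(c(-1, 0, 0), p2, p3, c(2, 1, 0)), "collinear")
})

test_that("dihedrals match a second independent implementation", {
  set.seed(5)
  for (i in 1:100) {
    pts <- matrix(rnorm(12), 4, 3)
    mine <- compute_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    brute <- dihedral_brute(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(mine, brute, tolerance = 1e-9)
  }
})

test_that("dihedrals agree with bio3d and respect rigid-motion invariance", {
  set.seed(6)
  for (i in 1:25) {
    pts <- matrix(rnorm(12), 4, 3)
    mine <- compute_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    b3d <- bio3d::torsion.xyz(as.numeric(t(pts)), atm.inc = 4)
    expect_lt(abs(confex:::wrap_angle(mine - b3d)), 1e-6)
    # global rotation + translation
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    tr <- rnorm(3, 0, 10)
    moved <- pts %*% t(R) + matrix(tr, 4, 3, byrow = TRUE)
    moved_ang <- compute_dihedral(moved[1, ], moved[2, ], moved[3, ], moved[4, ])
    expect_lt(abs(confex:::wrap_angle(mine - moved_ang)), 1e-9)
    # mirror reflection flips the sign
    mir <- pts; mir[, 3] <- -mir[, 3]
    mir_ang <- compute_dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ])
    expect_lt(abs(confex:::wrap_angle(mine + mir_ang)), 1e-9)
  }
})

test_that("rotamer bins assign centers, wrap and boundaries as documented", {
  s <- dihedral_series("W43", 0:5,
                       chi1 = c(-60, 60, 180, 300, 0, -120),
                       chi2 = c(-90, 90, 0, 180, -180, 359))
  st <- assign_rotamer_states(s)
  # -120 belongs to the half-open g- bin [-120, 0)
  expect_equal(st$chi1_state, c("g-", "g+", "t", "g-", "g+", "g-"))
  expect_equal(st$chi2_state, c("-90", "+90", "+90", "-90", "-90", "-90"))
})

test_that("transition counting matches the brute-force oracle on CTMC runs", {
  rt <- gen_rotamer_traj(rotamer_rate_matrix(0.02, 0.02), n_frames = 5000,
                         angular_noise_sd = 5, seed = 23)
  st <- assign_rotamer_states(rt)
  true_labels <- attr(rt, "true_states")
  for (md in c(1L, 3L, 5L)) {
    expect_identical(count_transitions(st, min_dwell = md),
                     count_changes_brute(st$combined, md))
  }
  # at low angular noise the label sequence equals the true state path
  expect_identical(st$combined, true_labels)
  # raw count equals the number of state changes visible on the frame grid
  expect_identical(count_transitions(st),
                   count_changes_brute(true_labels, 1L))
})

test_that("counting is monotone in the dwell filter and handles edge cases", {
  s <- dihedral_series("X", 0:10, chi1 = rep(c(60, -60), length.out = 11),
                       chi2 = rep(90, 11))
  st <- assign_rotamer_states(s)
  expect_identical(count_transitions(st, 1), 10L)
  const <- assign_rotamer_states(dihedral_series("X", 0:9, rep(60, 10),
                                                 rep(90, 10)))
  expect_identical(count_transitions(const), 0L)
  rt <- gen_rotamer_traj(rotamer_rate_matrix(0.05, 0.05), n_frames = 3000,
                         angular_noise_sd = 25, seed = 29)
  st2 <- assign_rotamer_states(rt)
  counts <- vapply(1:8, function(md) count_transitions(st2, md), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the dwell filter suppresses noise-induced chatter", {
  Q <- rotamer_rate_matrix(0.004, 0.004)
  # low noise: raw count tracks the true jump count closely
  rt1 <- gen_rotamer_traj(Q, n_frames = 20000, angular_noise_sd = 15, seed = 41)
  true1 <- count_changes_brute(attr(rt1, "true_states"), 1L)
  raw1 <- count_transitions(assign_rotamer_states(rt1))
  expect_lt(abs(raw1 - true1) / true1, 0.05)
  # heavy noise: raw counting overcounts, dwell filtering recovers
  rt2 <- gen_rotamer_traj(Q, n_frames = 20000, angular_noise_sd = 40, seed = 43)
  true2 <- count_changes_brute(attr(rt2, "true_states"), 1L)
  st2 <- assign_rotamer_states(rt2)
  raw2 <- count_transitions(st2, 1)
  filt2 <- count_transitions(st2, 5)
  expect_gt(raw2 / true2, 1.5)
  expect_lt(abs(filt2 - true2) / true2, 0.15)
})

test_that("concerted-transition statistics behave at the extremes", {
  # B transitions exactly at A's transition frames: minimal p. Irregular
  # dwell lengths so no circular shift can realign the transitions.
  set.seed(14)
  runs <- sample(15:85, 12)
  chi1 <- unlist(mapply(rep, rep(c(60, -60), 6), runs))[1:600]
  a <- assign_rotamer_states(dihedral_series("A", seq_len(600), chi1,
                                             rep(90, 600)))
  b <- assign_rotamer_states(dihedral_series("B", seq_len(600), chi1,
                                             rep(-90, 600)))
  # window 0: only perfect frame alignment counts, so no circular shift
  # of the irregular transition pattern can tie the observed statistic
  res <- detect_concerted(a, b, window = 0, n_permutations = 99, seed = 2)
  expect_lte(res$p_value, 1 / (1 + 99) + 1e-12)
  expect_gt(res$co_transition_count, 0)
  # constant B: zero statistic, p = 1
  bc <- assign_rotamer_states(dihedral_series("B", seq_len(600),
                                              rep(60, 600), rep(90, 600)))
  res0 <- detect_concerted(a, bc, window = 1, n_permutations = 99, seed = 2)
  expect_identical(res0$co_transition_count, 0L)
  expect_equal(res0$p_value, 1)
})

test_that("RMSF vanishes for static ensembles and ignores rigid-body motion", {
  tr0 <- gen_backbone_ensemble(rep(0, 5), n_frames = 6, seed = 3)
  prof0 <- compute_rmsf(tr0, burn_in_fraction = 0)
  expect_true(all(prof0$rmsf < 1e-10))
  # identical internal coordinates, random global rotation/translation
  tr1 <- gen_backbone_ensemble(rep(0, 8), n_frames = 40, rigid_body = TRUE,
                               seed = 19)
  prof1 <- compute_rmsf(tr1, burn_in_fraction = 0)
  expect_true(all(prof1$rmsf < 1e-6))
})

test_that("RMSF is invariant to the input reference frame", {
  tr <- gen_backbone_ensemble(c(0.2, 0.5, 0.8, 0.4, 0.3, 0.6), n_frames = 300,
                              seed = 27)
  prof <- compute_rmsf(tr, burn_in_fraction = 0)
  # rotate + translate every frame identically
  R <- rotation_matrix(c(1, 2, 3), 73)
  n_at <- ncol(tr$xyz) / 3
  xyz2 <- t(apply(tr$xyz, 1, function(fr) {
    m <- matrix(fr, ncol = 3, byrow = TRUE)
    as.numeric(t(m %*% t(R) + matrix(c(5, -3, 11), n_at, 3, byrow = TRUE)))
  }))
  prof2 <- compute_rmsf(trajectory(xyz2, tr$atom), burn_in_fraction = 0)
  expect_equal(prof$rmsf, prof2$rmsf, tolerance = 1e-6)
})

test_that("burn-in removal and selection subsetting are honored", {
  tr <- gen_backbone_ensemble(rep(0.4, 4), n_frames = 30, seed = 33)
  prof <- compute_rmsf(tr, selection = "CA", burn_in_fraction = 1 / 3)
  expect_equal(attr(prof, "n_frames_used"), 20)
  expect_error(compute_rmsf(tr, selection = "XX"), "no atoms")
  expect_error(compute_rmsf(tr, burn_in_fraction = 1), "burn_in_fraction")
})

test_that("chi dihedrals extracted from a constructed side chain match truth", {
  # build a 2-frame, 2-residue system where residue 2 carries CB/CG/CD1
  atom <- data.frame(
    elety = c("N", "CA", "C", "O", "N", "CA", "CB", "CG", "CD1"),
    resno = c(1, 1, 1, 1, 2, 2, 2, 2, 2),
    resid = c(rep("GLY", 4), rep("TRP", 5)), stringsAsFactors = FALSE)
  base <- rbind(c(-2, 1, 0), c(-2, 0, 0), c(-2, -1, 1), c(-2, -2, 1),
                c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1.4, 0),
                c(2.6, -2.1, 0.9))
  frame <- as.numeric(t(base))
  traj <- trajectory(rbind(frame, frame), atom)
  ds <- extract_dihedrals(traj, resno = 2)
  chi1_direct <- compute_dihedral(base[5, ], base[6, ], base[7, ], base[8, ])
  chi2_direct <- compute_dihedral(base[6, ], base[7, ], base[8, ], base[9, ])
  expect_equal(ds$chi1, rep(chi1_direct, 2), tolerance = 1e-9)
  expect_equal(ds$chi2, rep(chi2_direct, 2), tolerance = 1e-9)
})

test_that("trajectories and dihedral tables round-trip through disk", {
  tr <- gen_backbone_ensemble(rep(0.3, 3), n_frames = 4, seed = 15)
  f <- tempfile(fileext = ".pdb")
  write_traj_pdb(tr, f)
  back <- read_traj_pdb(f)
  expect_equal(dim(back$xyz), dim(tr$xyz))
  expect_lt(max(abs(back$xyz - tr$xyz)), 1e-3)  # PDB stores 3 decimals
  rt <- gen_rotamer_traj(n_frames = 50, seed = 8)
  f2 <- tempfile(fileext = ".tsv")
  write_dihedral_tsv(rt, f2)
  back2 <- read_dihedral_tsv(f2)
  expect_equal(back2$chi1, rt$chi1, tolerance = 1e-10)
})
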