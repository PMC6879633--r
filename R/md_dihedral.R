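#' Coordinate trajectory container
#'
#' Frames of per-atom 3-D coordinates in the row-per-frame layout used by
#' bio3d (each row is c(x1, y1, z1, x2, ...)), with atom metadata.
#'
#' @param xyz numeric matrix, one row per frame, 3 columns per atom (A)
#' @param atom data.frame with columns `elety` (atom name), `resno`
#'   (residue number) and `resid` (residue name), one row per atom
#' @param frame_interval time between frames (ns)
#' @return an object of class `md_trajectory`
#' @export
trajectory <- function(xyz, atom, frame_interval = 1) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2) stop("at least 2 frames are required")
  if (ncol(xyz) != 3 * nrow(atom))
    stop("xyz must have 3 columns per atom")
  need <- c("elety", "resno", "resid")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stop("atom metadata missing: ", paste(miss, collapse = ", "))
  structure(list(xyz = xyz, atom = atom, frame_interval = frame_interval),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms (%d residues), dt = %g ns\n",
              nrow(x$xyz), ncol(x$xyz) / 3, length(unique(x$atom$resno)),
              x$frame_interval))
  invisible(x)
}

#' Read / write multi-model PDB trajectories
#'
#' Thin wrappers over [bio3d::read.pdb()] / [bio3d::write.pdb()] mapping
#' MODEL/ENDMDL records to trajectory frames.
#'
#' @param file path to a PDB file
#' @param frame_interval time between models (ns)
#' @return an `md_trajectory`
#' @export
read_traj_pdb <- function(file, frame_interval = 1) {
  if (!file.exists(file)) stop("file not found: ", file)
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  trajectory(xyz,
             data.frame(elety = pdb$atom$elety, resno = pdb$atom$resno,
                        resid = pdb$atom$resid, stringsAsFactors = FALSE),
             frame_interval = frame_interval)
}

#' @rdname read_traj_pdb
#' @param traj an `md_trajectory`
#' @export
write_traj_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "md_trajectory"))
  bio3d::write.pdb(xyz = traj$xyz, elety = traj$atom$elety,
                   resno = traj$atom$resno, resid = traj$atom$resid,
                   file = file)
  invisible(file)
}

#' Per-frame side-chain dihedral series
#'
#' @param residue_label residue identifier
#' @param time_ns frame times (ns)
#' @param chi1,chi2 per-frame dihedrals (degrees), wrapped to \[-180, 180)
#' @return an object of class `dihedral_series`
#' @export
dihedral_series <- function(residue_label, time_ns, chi1, chi2) {
  if (length(chi1) != length(time_ns) || length(chi2) != length(time_ns))
    stop("chi1/chi2 must align with time_ns")
  if (length(time_ns) == 0) stop("series must be non-empty")
  structure(list(residue_label = residue_label,
                 time_ns = as.numeric(time_ns),
                 chi1 = wrap_angle(as.numeric(chi1)),
                 chi2 = wrap_angle(as.numeric(chi2))),
            class = "dihedral_series")
}

#' Signed dihedral angle from four points
#'
#' IUPAC-convention torsion computed via the atan2 of the cross and dot
#' products of the two bond-plane normals. The result is wrapped to
#' \[-180, 180), so an exactly planar trans arrangement returns -180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors
#' @return angle in degrees in \[-180, 180)
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("degenerate geometry: consecutive points coincide")
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-20 * sum(b1^2) * sum(b2^2) ||
      sum(n2^2) < 1e-20 * sum(b2^2) * sum(b3^2))
    stop("degenerate geometry: three consecutive points are collinear")
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# chi1/chi2 atom-name table; the fourth chi1 atom and the chi2 atoms vary
# by residue type. Overridable via the chi_atoms argument of
# extract_dihedrals().
.chi_atom_table <- list(
  default = list(chi1 = c("N", "CA", "CB", "CG"),
                 chi2 = c("CA", "CB", "CG", "CD1")),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"),
             chi2 = c("CA", "CB", "CG1", "CD1")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = NULL),
  SER = list(chi1 = c("N", "CA", "CB", "OG"), chi2 = NULL),
  THR = list(chi1 = c("N", "CA", "CB", "OG1"), chi2 = NULL),
  CYS = list(chi1 = c("N", "CA", "CB", "SG"), chi2 = NULL),
  MET = list(chi1 = c("N", "CA", "CB", "CG"),
             chi2 = c("CA", "CB", "CG", "SD"))
)

#' Extract chi1/chi2 dihedral series for one residue
#'
#' @param traj an `md_trajectory`
#' @param resno residue number to analyze
#' @param chi_atoms optional list with elements `chi1` and `chi2`, each a
#'   character vector of four atom names, overriding the built-in table
#' @return a [dihedral_series]; `chi2` is `NA` when the residue type has
#'   no chi2 definition
#' @export
extract_dihedrals <- function(traj, resno, chi_atoms = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- traj$atom$resno == resno
  if (!any(sel)) stop("residue ", resno, " not found")
  resid <- traj$atom$resid[sel][1]
  if (is.null(chi_atoms))
    chi_atoms <- .chi_atom_table[[resid]] %||% .chi_atom_table$default
  atom_xyz <- function(name, frame) {
    idx <- which(sel & traj$atom$elety == name)
    if (length(idx) != 1) stop("atom ", name, " not found uniquely in residue ", resno)
    traj$xyz[frame, (3 * idx - 2):(3 * idx)]
  }
  n_frames <- nrow(traj$xyz)
  angle_series <- function(names4) {
    if (is.null(names4)) return(rep(NA_real_, n_frames))
    vapply(seq_len(n_frames), function(f)
      compute_dihedral(atom_xyz(names4[1], f), atom_xyz(names4[2], f),
                       atom_xyz(names4[3], f), atom_xyz(names4[4], f)),
      numeric(1))
  }
  dihedral_series(residue_label = paste0(resid, resno),
                  time_ns = (seq_len(n_frames) - 1) * traj$frame_interval,
                  chi1 = angle_series(chi_atoms$chi1),
                  chi2 = angle_series(chi_atoms$chi2))
}

#' Assign chi1/chi2 rotamer states
#'
#' Half-open angular bins centered on the canonical rotamer positions:
#' chi1 in \[0, 120) is g+, \[-120, 0) is g-, the rest is t (centered at
#' 180); chi2 in \[0, 180) is +90, the rest is -90. The half-open
#' convention makes boundary assignment deterministic and is equivalent
#' to nearest-center assignment away from the boundaries.
#'
#' @param series a [dihedral_series]
#' @return an object of class `rotamer_states` with per-frame `chi1_state`,
#'   `chi2_state` and `combined` labels
#' @export
assign_rotamer_states <- function(series) {
  stopifnot(inherits(series, "dihedral_series"))
  a1 <- wrap_angle(series$chi1)
  a2 <- wrap_angle(series$chi2)
  chi1_state <- ifelse(a1 >= 0 & a1 < 120, "g+",
                       ifelse(a1 >= -120 & a1 < 0, "g-", "t"))
  chi2_state <- ifelse(a2 >= 0, "+90", "-90")
  structure(list(residue_label = series$residue_label,
                 time_ns = series$time_ns,
                 chi1_state = chi1_state,
                 chi2_state = chi2_state,
                 combined = paste(chi1_state, chi2_state, sep = "/")),
            class = "rotamer_states")
}

# dwell-filtered count of label changes: runs shorter than min_dwell are
# ignored; a transition is counted when an accepted run's label differs
# from the previously accepted label
count_label_changes <- function(labels, min_dwell) {
  r <- rle(as.character(labels))
  keep <- r$lengths >= min_dwell
  vals <- r$values[keep]
  if (length(vals) < 2) return(0L)
  sum(vals[-1] != vals[-length(vals)])
}

#' Count rotamer transitions
#'
#' Counts changes of the rotamer state label along the trajectory. A
#' change is counted only when the new state persists for at least
#' `min_dwell` frames; with `min_dwell = 1` this is the raw label-change
#' count. The combined chi1 x chi2 state is used by default; `dihedral`
#' selects the chi1-only or chi2-only count instead (the chi1-only count
#' is the conventional definition of a side-chain conformational
#' transition between g+, g- and t).
#'
#' @param states a `rotamer_states` object
#' @param min_dwell minimum persistence (frames), >= 1
#' @param dihedral which label sequence to count: `"combined"`, `"chi1"`
#'   or `"chi2"`
#' @return integer transition count
#' @export
count_transitions <- function(states, min_dwell = 1,
                              dihedral = c("combined", "chi1", "chi2")) {
  stopifnot(inherits(states, "rotamer_states"))
  dihedral <- match.arg(dihedral)
  if (min_dwell < 1) stop("min_dwell must be >= 1")
  labels <- switch(dihedral,
                   combined = states$combined,
                   chi1 = states$chi1_state,
                   chi2 = states$chi2_state)
  count_label_changes(labels, min_dwell)
}

#' Permutation test for concerted transitions between two residues
#'
#' The statistic is the number of transitions in series B that fall
#' within `window` frames of any transition in series A. The null
#' distribution is generated by circularly shifting B's transition
#' indicator by uniformly random offsets, which preserves B's transition
#' count and clustering while destroying its alignment with A. The
#' p-value is (1 + number of null statistics >= observed) /
#' (1 + n_permutations).
#'
#' @param states_a,states_b `rotamer_states` objects of equal length
#' @param window half-width of the coincidence window (frames), >= 0
#' @param n_permutations number of random circular shifts
#' @param seed integer seed for the permutation draws
#' @return an object of class `concerted_result` with
#'   `co_transition_count`, `p_value`, `window`, `n_permutations`
#' @export
detect_concerted <- function(states_a, states_b, window = 2,
                             n_permutations = 199, seed = NULL) {
  stopifnot(inherits(states_a, "rotamer_states"),
            inherits(states_b, "rotamer_states"))
  n <- length(states_a$combined)
  if (length(states_b$combined) != n) stop("series must have equal length")
  if (window < 0) stop("window must be nonnegative")
  trans_ind <- function(labels) {
    x <- as.character(labels)
    c(FALSE, x[-1] != x[-length(x)])
  }
  ia <- trans_ind(states_a$combined)
  ib <- trans_ind(states_b$combined)
  if (!any(ia) || !any(ib)) {
    return(structure(list(co_transition_count = 0L, p_value = 1,
                          window = window, n_permutations = n_permutations),
                     class = "concerted_result"))
  }
  # frames within +/- window of an A transition
  near_a <- rep(FALSE, n)
  for (i in which(ia))
    near_a[max(1, i - window):min(n, i + window)] <- TRUE
  stat <- function(ind_b) sum(ind_b & near_a)
  observed <- stat(ib)
  null_ge <- with_seed(seed, {
    hits <- 0L
    for (p in seq_len(n_permutations)) {
      off <- sample.int(n - 1, 1)
      shifted <- c(ib[(off + 1):n], ib[1:off])
      if (stat(shifted) >= observed) hits <- hits + 1L
    }
    hits
  })
  structure(list(co_transition_count = observed,
                 p_value = (1 + null_ge) / (1 + n_permutations),
                 window = window, n_permutations = n_permutations),
            class = "concerted_result")
}

#' @export
print.concerted_result <- function(x, ...) {
  cat(sprintf("Concerted transitions: %d within +/-%d frames (p = %.4g, %d permutations)\n",
              x$co_transition_count, x$window, x$p_value, x$n_permutations))
  invisible(x)
}

#' Backbone RMSF profile
#'
#' Discards an initial burn-in fraction of frames, iteratively superposes
#' the remaining frames onto their mean structure (two least-squares
#' passes via [bio3d::fit.xyz()]), and reports the per-residue root mean
#' square fluctuation about the mean, averaged over the selected atoms of
#' each residue.
#'
#' @param traj an `md_trajectory`
#' @param selection atom names used for superposition and reporting
#'   (default backbone N, CA, C, O)
#' @param burn_in_fraction fraction of initial frames to discard
#'   (default 1/3)
#' @return an object of class `rmsf_profile`: data.frame with columns
#'   `resno` and `rmsf` (A), with the selection and burn-in recorded as
#'   attributes
#' @export
compute_rmsf <- function(traj, selection = c("N", "CA", "C", "O"),
                         burn_in_fraction = 1 / 3) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(selection) == 0) stop("selection must be non-empty")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  n <- nrow(traj$xyz)
  start <- floor(burn_in_fraction * n) + 1
  if (n - start + 1 < 2) stop("fewer than 2 frames remain after burn-in")
  sel_atoms <- which(traj$atom$elety %in% selection)
  if (length(sel_atoms) == 0) stop("no atoms match the selection")
  cols <- as.numeric(vapply(sel_atoms, function(i) (3 * i - 2):(3 * i),
                            numeric(3)))
  xyz <- traj$xyz[start:n, cols, drop = FALSE]
  inds <- seq_len(ncol(xyz))
  m <- colMeans(xyz)
  for (pass in 1:2) {
    xyz <- bio3d::fit.xyz(fixed = m, mobile = xyz,
                          fixed.inds = inds, mobile.inds = inds)
    m <- colMeans(xyz)
  }
  dev2 <- sweep(xyz, 2, m)^2
  # per-atom mean squared fluctuation summed over x, y, z
  msf_atom <- colMeans(dev2[, seq(1, ncol(xyz), by = 3)] +
                         dev2[, seq(2, ncol(xyz), by = 3)] +
                         dev2[, seq(3, ncol(xyz), by = 3)])
  rmsf_atom <- sqrt(msf_atom)
  resno_sel <- traj$atom$resno[sel_atoms]
  prof <- data.frame(resno = sort(unique(resno_sel)))
  prof$rmsf <- vapply(prof$resno,
                      function(r) mean(rmsf_atom[resno_sel == r]),
                      numeric(1))
  structure(prof, class = c("rmsf_profile", "data.frame"),
            selection = selection, burn_in_fraction = burn_in_fraction,
            n_frames_used = n - start + 1)
}

#' Read a per-frame dihedral table
#'
#' TSV with columns frame, time_ns, chi1_deg, chi2_deg; bypasses
#' coordinate processing.
#'
#' @param file path to a tab-separated file
#' @param residue_label label for the resulting series
#' @return a [dihedral_series]
#' @export
read_dihedral_tsv <- function(file, residue_label = "W43") {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.delim(file, check.names = FALSE)
  need <- c("time_ns", "chi1_deg", "chi2_deg")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dihedral_series(residue_label, d$time_ns, d$chi1_deg, d$chi2_deg)
}

#' @rdname read_dihedral_tsv
#' @param series a [dihedral_series]
#' @export
write_dihedral_tsv <- function(series, file) {
  d <- data.frame(frame = seq_along(series$time_ns),
                  time_ns = series$time_ns,
                  chi1_deg = series$chi1, chi2_deg = series$chi2)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
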