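# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form code paths.

# numerical 2x2 matrix-exponential prediction of the four ZZ curves
zz_oracle <- function(params, times) {
  K <- matrix(c(params$R1_1 + params$k_12, -params$k_12,
                -params$k_21, params$R1_2 + params$k_21), 2, 2)
  out <- matrix(0, length(times), 4,
                dimnames = list(NULL, c("I_AA", "I_BB", "I_AB", "I_BA")))
  for (i in seq_along(times)) {
    E <- as.matrix(Matrix::expm(-K * times[i]))
    out[i, "I_AA"] <- params$I0_1 * E[1, 1]
    out[i, "I_AB"] <- params$I0_1 * E[2, 1]
    out[i, "I_BB"] <- params$I0_2 * E[2, 2]
    out[i, "I_BA"] <- params$I0_2 * E[1, 2]
  }
  out
}

# random physically plausible ZZ parameter draw
random_zz_params <- function() {
  zz_params(k_12 = 10^stats::runif(1, -2, 1.5),
            k_21 = 10^stats::runif(1, -2, 1.5),
            R1_1 = 10^stats::runif(1, -0.5, 0.7),
            R1_2 = 10^stats::runif(1, -0.5, 0.7),
            I0_1 = stats::runif(1, 0.2, 2),
            I0_2 = stats::runif(1, 0.1, 1))
}

# brute-force signed dihedral from the two-plane construction using
# explicit projections (no cross-product normals)
dihedral_brute <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- b2 / sqrt(sum(b2^2))
  # components of the outer bonds perpendicular to the central bond
  v1 <- (p1 - p2) - sum((p1 - p2) * u) * u
  v2 <- (p4 - p3) - sum((p4 - p3) * u) * u
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  cosang <- max(-1, min(1, sum(v1 * v2)))
  # sign from the handedness of (v1, v2, u)
  s <- sign(sum(u * c(v1[2] * v2[3] - v1[3] * v2[2],
                      v1[3] * v2[1] - v1[1] * v2[3],
                      v1[1] * v2[2] - v1[2] * v2[1])))
  ang <- acos(cosang) * 180 / pi * ifelse(s == 0, 1, s)
  ((ang + 180) %% 360) - 180
}

# raw label-change counter with dwell filtering, written independently of
# the package implementation (explicit per-frame loop)
count_changes_brute <- function(labels, min_dwell = 1) {
  n <- length(labels)
  # collapse into runs by scanning
  vals <- character(0); lens <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1] == labels[i]) j <- j + 1
    vals <- c(vals, labels[i]); lens <- c(lens, j - i + 1)
    i <- j + 1
  }
  accepted <- vals[lens >= min_dwell]
  if (length(accepted) < 2) return(0L)
  count <- 0L
  for (k in 2:length(accepted))
    if (accepted[k] != accepted[k - 1]) count <- count + 1L
  count
}

# 3-D rotation about a given axis by angle (degrees)
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  C <- 1 - c_
  matrix(c(c_ + a[1]^2 * C, a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
           a[2] * a[1] * C + a[3] * s_, c_ + a[2]^2 * C, a[2] * a[3] * C - a[1] * s_,
           a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, c_ + a[3]^2 * C),
         3, 3, byrow = TRUE)
}
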