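#' Peak cluster for 2-D Gaussian quantification
#'
#' A rectangular patch of a 2-D spectrum holding one or more overlapping
#' peaks, with ppm axis vectors and initial peak positions.
#'
#' @param grid intensity matrix; rows run along `y`, columns along `x`
#' @param x,y axis coordinate vectors (ppm) for columns / rows of `grid`
#' @param peak_seeds two-column matrix (x, y) of initial peak positions,
#'   each inside the grid
#' @return an object of class `peak_cluster`
#' @export
peak_cluster <- function(grid, x, y, peak_seeds) {
  grid <- as.matrix(grid)
  if (!all(is.finite(grid))) stop("grid must be finite")
  if (length(x) != ncol(grid) || length(y) != nrow(grid))
    stop("axis vectors must match grid dimensions")
  peak_seeds <- matrix(as.numeric(peak_seeds), ncol = 2)
  if (nrow(peak_seeds) < 1) stop("at least one peak seed is required")
  inx <- peak_seeds[, 1] >= min(x) & peak_seeds[, 1] <= max(x)
  iny <- peak_seeds[, 2] >= min(y) & peak_seeds[, 2] <= max(y)
  if (!all(inx & iny)) stop("peak seeds must lie inside the grid")
  structure(list(grid = grid, x = x, y = y, peak_seeds = peak_seeds,
                 fitted = NULL),
            class = "peak_cluster")
}

# model: flat baseline + sum of axis-aligned 2-D Gaussians
peak_model <- function(par, xg, yg, n_peaks) {
  base <- par[1]
  z <- rep(base, length(xg))
  for (k in seq_len(n_peaks)) {
    o <- 1 + (k - 1) * 5
    cx <- par[o + 1]; cy <- par[o + 2]
    sdx <- exp(par[o + 3]); sdy <- exp(par[o + 4]); amp <- exp(par[o + 5])
    z <- z + amp * exp(-((xg - cx)^2 / (2 * sdx^2) +
                           (yg - cy)^2 / (2 * sdy^2)))
  }
  z
}

#' Quantify peaks in a cluster by 2-D Gaussian fitting
#'
#' Fits a sum of axis-aligned 2-D Gaussians plus a flat baseline to the
#' cluster by nonlinear least squares and integrates each component
#' analytically: volume = 2 pi * amplitude * sd_x * sd_y.
#'
#' @param cluster a [peak_cluster]
#' @return the cluster with `$fitted` set to a data.frame with columns
#'   `center_x`, `center_y`, `sd_x`, `sd_y`, `amplitude`, `volume`, and
#'   `$converged` flag
#' @export
quantify_peaks <- function(cluster) {
  stopifnot(inherits(cluster, "peak_cluster"))
  g <- cluster$grid
  xg <- rep(cluster$x, each = nrow(g))
  yg <- rep(cluster$y, times = ncol(g))
  z <- as.numeric(g)
  n_peaks <- nrow(cluster$peak_seeds)

  base0 <- stats::median(z)
  dx <- if (length(cluster$x) > 1) abs(mean(diff(cluster$x))) else 1
  dy <- if (length(cluster$y) > 1) abs(mean(diff(cluster$y))) else 1
  amp0 <- numeric(n_peaks)
  for (k in seq_len(n_peaks)) {
    i <- which.min(abs(cluster$y - cluster$peak_seeds[k, 2]))
    j <- which.min(abs(cluster$x - cluster$peak_seeds[k, 1]))
    amp0[k] <- g[i, j] - base0
  }
  tol <- 1e-8 * max(abs(z), 1e-300)
  if (all(amp0 <= tol)) stop("no peak detected above baseline at any seed")

  par0 <- base0
  for (k in seq_len(n_peaks))
    par0 <- c(par0, cluster$peak_seeds[k, 1], cluster$peak_seeds[k, 2],
              log(2 * dx), log(2 * dy), log(max(amp0[k], tol)))

  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) peak_model(p, xg, yg, n_peaks) - z,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- fit$par
  out <- data.frame(center_x = numeric(n_peaks), center_y = numeric(n_peaks),
                    sd_x = numeric(n_peaks), sd_y = numeric(n_peaks),
                    amplitude = numeric(n_peaks), volume = numeric(n_peaks))
  for (k in seq_len(n_peaks)) {
    o <- 1 + (k - 1) * 5
    out$center_x[k] <- p[o + 1]
    out$center_y[k] <- p[o + 2]
    out$sd_x[k] <- exp(p[o + 3])
    out$sd_y[k] <- exp(p[o + 4])
    out$amplitude[k] <- exp(p[o + 5])
    out$volume[k] <- 2 * pi * out$amplitude[k] * out$sd_x[k] * out$sd_y[k]
  }
  cluster$fitted <- out
  cluster$baseline <- p[1]
  cluster$converged <- fit$info %in% 1:4
  cluster
}

#' Read a peak cluster from a plain-text matrix and JSON seed list
#'
#' The matrix file is tab-separated: the header row holds the x-axis ppm
#' values and the first column of each subsequent row holds the y-axis
#' ppm value for that row. The seeds file is a JSON array of two-element
#' \[x, y\] arrays.
#'
#' @param matrix_file path to the intensity matrix
#' @param seeds_file path to the JSON peak-seed list
#' @return a [peak_cluster]
#' @export
read_peak_cluster <- function(matrix_file, seeds_file) {
  for (f in c(matrix_file, seeds_file))
    if (!file.exists(f)) stop("file not found: ", f)
  lines <- utils::read.delim(matrix_file, header = TRUE,
                             check.names = FALSE)
  y <- as.numeric(lines[[1]])
  x <- as.numeric(names(lines)[-1])
  grid <- as.matrix(lines[, -1, drop = FALSE])
  dimnames(grid) <- NULL
  seeds <- jsonlite::read_json(seeds_file, simplifyVector = TRUE)
  peak_cluster(grid, x, y, matrix(as.numeric(seeds), ncol = 2,
                                  byrow = !is.matrix(seeds)))
}

#' @rdname read_peak_cluster
#' @param cluster a [peak_cluster]
#' @export
write_peak_cluster <- function(cluster, matrix_file, seeds_file) {
  d <- data.frame(y = cluster$y, cluster$grid, check.names = FALSE)
  names(d) <- c("y_ppm", format(cluster$x, trim = TRUE))
  utils::write.table(d, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(lapply(seq_len(nrow(cluster$peak_seeds)),
                              function(i) as.numeric(cluster$peak_seeds[i, ])),
                       seeds_file, digits = NA)
  invisible(matrix_file)
}
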