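#' Instantaneous gaze velocity
#'
#' Computes per-sample gaze velocity with the smoothed two-point
#' central-difference operator used as the default by video eye trackers:
#'
#' \deqn{v(n) = SR \cdot \frac{g(n+4)+g(n+3)+g(n+2)-g(n-2)-g(n-3)-g(n-4)}{18
#'   \cdot PPD}}
#'
#' where `SR` is the sampling rate (Hz), `PPD` the pixels-per-degree
#' resolution and 18 the sum of the index differences
#' `(4-(-4)) + (3-(-3)) + (2-(-2))`. The operator is applied separately to the
#' horizontal and vertical components and returns degrees per second. No
#' further smoothing is applied: the six-sample sum is itself the noise
#' filter.
#'
#' A sample's velocity is *defined* only when all samples in its `n-4 ... n+4`
#' neighbourhood are valid; the first and last four samples, and samples whose
#' neighbourhood touches an invalid sample, are flagged undefined rather than
#' interpolated or zeroed.
#'
#' @param recording a [gaze_recording()] with at least 9 samples.
#' @return A tibble (class `velocity_trace`) with columns `t`, `vx`, `vy`
#'   (deg/s), `magnitude` and `defined`.
#' @export
instantaneous_velocity <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  n <- nrow(s)
  if (n < 9) stop("instantaneous velocity needs at least 9 samples, got ", n)
  sr <- recording$geometry$sampling_rate
  ppd <- recording$geometry$pixels_per_degree

  op <- function(g) {
    v <- rep(NA_real_, n)
    i <- 5:(n - 4)
    v[i] <- sr * (g[i + 4] + g[i + 3] + g[i + 2] -
                    g[i - 2] - g[i - 3] - g[i - 4]) / (18 * ppd)
    v
  }
  vx <- op(s$x)
  vy <- op(s$y)

  ok <- s$valid & !is.na(s$x) & !is.na(s$y)
  # defined iff every sample in n-4..n+4 is valid
  run9 <- stats::filter(as.numeric(ok), rep(1, 9), sides = 2)
  defined <- !is.na(run9) & run9 == 9
  vx[!defined] <- NA_real_
  vy[!defined] <- NA_real_

  out <- tibble::tibble(
    t = s$t, vx = vx, vy = vy,
    magnitude = sqrt(vx^2 + vy^2),
    defined = defined
  )
  class(out) <- c("velocity_trace", class(out))
  attr(out, "geometry") <- recording$geometry
  out
}

#' Velocity magnitude and 2-D velocity distributions
#'
#' Histograms of the instantaneous gaze velocity: a 1-D density of the
#' magnitude and a 2-D density over (horizontal, vertical) velocity, both on a
#' fixed bin width (default 16 deg/s) and normalised to sum to 1.
#'
#' @param trace a velocity trace from [instantaneous_velocity()].
#' @param bin_size bin width in deg/s.
#' @return List with `magnitude_density` (tibble: `bin_lo`, `bin_hi`,
#'   `density`), `xy_density` (matrix with break attributes), and
#'   `median_magnitude`.
#' @export
velocity_distribution <- function(trace, bin_size = 16) {
  d <- trace[trace$defined, , drop = FALSE]
  if (nrow(d) == 0) stop("no defined velocity samples")
  mmax <- max(d$magnitude)
  br <- seq(0, bin_size * (floor(mmax / bin_size) + 1), by = bin_size)
  cnt <- tabulate(findInterval(d$magnitude, br, rightmost.closed = TRUE,
                               all.inside = TRUE),
                  nbins = length(br) - 1)
  mag <- tibble::tibble(bin_lo = br[-length(br)], bin_hi = br[-1],
                        density = cnt / sum(cnt))
  lim <- bin_size * (floor(max(abs(c(d$vx, d$vy))) / bin_size) + 1)
  br2 <- seq(-lim, lim, by = bin_size)
  ix <- findInterval(d$vx, br2, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(d$vy, br2, rightmost.closed = TRUE, all.inside = TRUE)
  m <- matrix(0, nrow = length(br2) - 1, ncol = length(br2) - 1)
  for (k in seq_along(ix)) m[iy[k], ix[k]] <- m[iy[k], ix[k]] + 1
  m <- m / sum(m)
  attr(m, "breaks") <- br2
  list(magnitude_density = mag, xy_density = m,
       median_magnitude = stats::median(d$magnitude))
}

#' Partition defined samples into velocity-magnitude quantile bins
#'
#' Defined samples are split into `n_bins` near-equal-size groups ordered by
#' velocity magnitude; ties are broken by sample order so the partition is
#' deterministic. Undefined samples get `NA`.
#'
#' @param trace a velocity trace.
#' @param n_bins number of quantile bins (default 10).
#' @return Integer vector of bin labels `1..n_bins` per sample (`NA` where
#'   velocity is undefined).
#' @export
velocity_quantile_partition <- function(trace, n_bins = 10) {
  idx <- which(trace$defined)
  nd <- length(idx)
  if (nd < n_bins) {
    stop("need at least ", n_bins, " defined samples, got ", nd)
  }
  r <- rank(trace$magnitude[idx], ties.method = "first")
  lab <- as.integer(ceiling(r * n_bins / nd))
  out <- rep(NA_integer_, nrow(trace))
  out[idx] <- lab
  out
}
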