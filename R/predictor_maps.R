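# Predictor maps: empirical fixation-density maps (with leave-one-out),
# luminance-contrast maps, externally supplied maps, and low-pass image
# variants. All maps are nonnegative per-pixel matrices normalised to sum 1.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # sigma = FWHM * 0.42466

# internal: separable Gaussian convolution with reflect padding (FFT-based)
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- max(1L, ceiling(4 * sigma_px))
  k <- min(k, min(dim(m)) - 1L)  # reflect padding cannot exceed the image
  g <- stats::dnorm(-k:k, sd = sigma_px)
  g <- g / sum(g)
  conv_axis <- function(mat, kern) {
    # convolve each column with kern under reflect padding
    n <- nrow(mat)
    kh <- (length(kern) - 1L) / 2L
    top <- mat[kh:1, , drop = FALSE]
    bot <- mat[n:(n - kh + 1), , drop = FALSE]
    padded <- rbind(top, mat, bot)
    np <- nrow(padded)
    # FFT along columns: zero-pad kernel to np, centre at 1
    kv <- numeric(np)
    kv[1:(2 * kh + 1)] <- kern
    kv <- c(kv[(kh + 1):np], kv[1:kh])  # rotate so kernel centre sits at index 1
    K <- stats::fft(kv)
    out <- Re(stats::mvfft(stats::mvfft(padded) * K, inverse = TRUE)) / np
    out[(kh + 1):(kh + n), , drop = FALSE]
  }
  m1 <- conv_axis(m, g)        # vertical
  t(conv_axis(t(m1), g))       # horizontal
}

new_predictor_map <- function(values, geometry, provenance, fwhm_deg = NA_real_,
                              lowpass_cutoff_deg = NA_real_, flags = character(0)) {
  stopifnot(is.matrix(values))
  if (nrow(values) != geometry$image_size_px[2] ||
      ncol(values) != geometry$image_size_px[1]) {
    stop(sprintf("map is %dx%d but geometry expects %dx%d",
                 ncol(values), nrow(values),
                 geometry$image_size_px[1], geometry$image_size_px[2]))
  }
  if (any(values < 0)) stop("predictor map values must be nonnegative")
  tot <- sum(values)
  if (tot <= 0) stop("predictor map has zero total mass")
  structure(
    list(values = values / tot, geometry = geometry, provenance = provenance,
         fwhm_deg = fwhm_deg, lowpass_cutoff_deg = lowpass_cutoff_deg,
         flags = flags),
    class = "predictor_map"
  )
}

#' @export
print.predictor_map <- function(x, ...) {
  cat(sprintf("<predictor_map> %s, %dx%d px, sum = %g%s\n",
              x$provenance, ncol(x$values), nrow(x$values), sum(x$values),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Empirical gaze-density predictor map
#'
#' Pools the valid gaze samples of the contributing recordings at pixel level,
#' smooths the counts with a unit-sum 2-D Gaussian kernel (default full width
#' at half maximum 2 visual degrees) and normalises to a probability map.
#' When `exclude_participant` is given, that participant's recordings
#' contribute nothing — the leave-one-out variant used when a participant is
#' scored against their own group's map.
#'
#' @param recordings list of [gaze_recording()] of one image (typically the
#'   sighted-control group).
#' @param geometry a [geometry_spec()].
#' @param exclude_participant participant id to leave out, or `NULL`.
#' @param fwhm_deg Gaussian smoothing FWHM in degrees.
#' @return A `predictor_map` (provenance `empirical_loo` or `empirical_full`).
#' @export
empirical_map <- function(recordings, geometry, exclude_participant = NULL,
                          fwhm_deg = 2) {
  contrib <- recordings
  if (!is.null(exclude_participant)) {
    contrib <- Filter(function(r) r$participant_id != exclude_participant,
                      recordings)
  }
  if (length(contrib) == 0) {
    stop("no contributing recordings after exclusion")
  }
  w <- geometry$image_size_px[1]; h <- geometry$image_size_px[2]
  counts <- matrix(0, nrow = h, ncol = w)
  for (r in contrib) {
    s <- r$samples[r$samples$valid, , drop = FALSE]
    if (nrow(s) == 0) next
    px <- pmin(floor(s$x), w - 1) + 1
    py <- pmin(floor(s$y), h - 1) + 1
    idx <- (px - 1) * h + py
    tb <- tabulate(idx, nbins = w * h)
    counts <- counts + matrix(tb, nrow = h, ncol = w)
  }
  if (sum(counts) == 0) stop("contributing recordings have no valid samples")
  sigma <- fwhm_deg * FWHM_TO_SIGMA * geometry$pixels_per_degree
  sm <- gaussian_blur(counts, sigma)
  sm[sm < 0] <- 0  # clip FFT round-off
  new_predictor_map(sm, geometry,
                    if (is.null(exclude_participant)) "empirical_full" else "empirical_loo",
                    fwhm_deg = fwhm_deg)
}

#' Luminance-contrast predictor map
#'
#' Local luminance contrast: the Gaussian-weighted local standard deviation of
#' image intensity (window `window_deg` degrees), smoothed with the same
#' FWHM kernel as the empirical maps and normalised to sum 1. This is a
#' deliberately simple low-level feature map; externally computed feature maps
#' (e.g. deep-network saliency) can be supplied via [load_external_map()].
#'
#' @param image numeric intensity matrix in `[0, 1]`.
#' @param geometry a [geometry_spec()].
#' @param window_deg standard deviation of the local-contrast window, degrees.
#' @param fwhm_deg final smoothing FWHM in degrees.
#' @return A `predictor_map` (provenance `contrast`); a constant image yields
#'   a uniform map flagged `"constant_image"`.
#' @export
contrast_map <- function(image, geometry, window_deg = 1, fwhm_deg = 2) {
  stopifnot(is.matrix(image))
  if (nrow(image) != geometry$image_size_px[2] ||
      ncol(image) != geometry$image_size_px[1]) {
    stop("image does not match geometry")
  }
  sigw <- window_deg * geometry$pixels_per_degree
  mu <- gaussian_blur(image, sigw)
  mu2 <- gaussian_blur(image^2, sigw)
  v <- mu2 - mu^2
  v[v < 0] <- 0
  sd_local <- sqrt(v)
  if (max(sd_local) < 1e-12) {
    u <- matrix(1, nrow = nrow(image), ncol = ncol(image))
    return(new_predictor_map(u, geometry, "contrast",
                             fwhm_deg = fwhm_deg, flags = "constant_image"))
  }
  sigma <- fwhm_deg * FWHM_TO_SIGMA * geometry$pixels_per_degree
  sm <- gaussian_blur(sd_local, sigma)
  sm[sm < 0] <- 0
  new_predictor_map(sm, geometry, "contrast", fwhm_deg = fwhm_deg)
}

#' Load an externally computed predictor map
#'
#' Reads a grayscale image (PNG/PGM) or a plain numeric grid (whitespace-
#' separated text) holding a nonnegative map matching the stimulus size, and
#' normalises it to sum 1. Use this to feed maps produced outside the package
#' (e.g. deep-network saliency models) into the AUC machinery.
#'
#' @param path map file.
#' @param geometry a [geometry_spec()].
#' @return A `predictor_map` (provenance `external`).
#' @export
load_external_map <- function(path, geometry) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("png", "pgm", "pnm")) {
    read_image(path)
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  vals <- unname(vals)
  if (nrow(vals) != geometry$image_size_px[2] ||
      ncol(vals) != geometry$image_size_px[1]) {
    stop(sprintf("external map is %dx%d but geometry expects %dx%d",
                 ncol(vals), nrow(vals),
                 geometry$image_size_px[1], geometry$image_size_px[2]))
  }
  if (any(vals < 0)) stop("external map contains negative values")
  new_predictor_map(vals, geometry, "external")
}

#' Save a predictor map as a plain-text grid
#'
#' Full-precision text output readable by [load_external_map()].
#'
#' @param map a `predictor_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_map <- function(map, path) {
  utils::write.table(format(map$values, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Low-pass filtered image variant
#'
#' Gaussian blur parameterised by the spatial frequency at which the kernel's
#' modulation transfer drops to `reduction` (default 0.67): with cutoff
#' period `cutoff_deg` degrees the attenuation at frequency `1/cutoff_deg`
#' cycles/degree is `reduction`, giving
#' `sigma_deg = cutoff_deg * sqrt(log(1/reduction)) / (pi * sqrt(2))`.
#'
#' @param image numeric intensity matrix in `[0, 1]`.
#' @param geometry a [geometry_spec()].
#' @param cutoff_deg cutoff period in degrees (the study used 0.5, 1, 2).
#' @param reduction modulation transfer at the cutoff frequency.
#' @return Blurred image matrix, clipped to `[0, 1]`.
#' @export
lowpass_image <- function(image, geometry, cutoff_deg, reduction = 0.67) {
  stopifnot(cutoff_deg > 0, reduction > 0, reduction < 1)
  sigma_deg <- cutoff_deg * sqrt(log(1 / reduction)) / (pi * sqrt(2))
  out <- gaussian_blur(image, sigma_deg * geometry$pixels_per_degree)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
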