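# Five-point polynomial calibration.
#
# Raw tracker coordinates (u, v) are mapped to screen coordinates by fitting,
# per output axis, a full quadratic polynomial in (u, v) to the per-target
# medians of experimenter-selected low-velocity gaze windows. Coordinates here
# are screen-centred pixels (0 = screen centre); the five standard targets sit
# at the centre, 15 deg left/right and 8.5 deg above/below.

#' Standard five-point calibration target positions
#'
#' @param geometry a [geometry_spec()].
#' @return Tibble with `target_label`, `x_deg`, `y_deg`, `x_px`, `y_px`
#'   (screen-centred pixels; y positive downward).
#' @export
calibration_targets <- function(geometry = geometry_spec()) {
  ppd <- geometry$pixels_per_degree
  tibble::tibble(
    target_label = c("center", "right", "left", "up", "down"),
    x_deg = c(0, 15, -15, 0, 0),
    y_deg = c(0, 0, 0, -8.5, 8.5),
    x_px = c(0, 15, -15, 0, 0) * ppd,
    y_px = c(0, 0, 0, -8.5, 8.5) * ppd
  )
}

quad_design <- function(u, v) {
  cbind(1, u, v, u * v, u^2, v^2)
}

#' Fit the five-point polynomial calibration
#'
#' Per-target medians of the selected low-velocity windows are computed first;
#' a full quadratic in `(u, v)` (6 coefficients per output axis) is then fit
#' to the target screen positions by minimum-norm least squares (SVD with
#' near-zero singular values dropped), which keeps the underdetermined
#' five-point system solvable. With exactly five non-degenerate targets the
#' fit interpolates the medians, and because the design is centred on the
#' median cross, an affine tracker distortion is recovered exactly everywhere.
#'
#' @param windows data frame with columns `target_label`, `u`, `v`: the
#'   selected low-velocity raw gaze samples, at least 1 window of >= 1 sample
#'   per target.
#' @param geometry a [geometry_spec()].
#' @param targets target table as from [calibration_targets()].
#' @return A `calibration_model`: coefficient matrix (6 x 2), per-target
#'   residuals (px) and the target medians.
#' @export
fit_calibration <- function(windows, geometry = geometry_spec(),
                            targets = calibration_targets(geometry)) {
  stopifnot(all(c("target_label", "u", "v") %in% names(windows)))
  if (!all(targets$target_label %in% windows$target_label)) {
    stop("windows missing for target(s): ",
         paste(setdiff(targets$target_label, windows$target_label),
               collapse = ", "))
  }
  if (any(!is.finite(windows$u)) || any(!is.finite(windows$v))) {
    stop("calibration windows contain non-finite samples")
  }
  med <- do.call(rbind, lapply(targets$target_label, function(lb) {
    sub <- windows[windows$target_label == lb, ]
    c(u = stats::median(sub$u), v = stats::median(sub$v))
  }))
  # centre and scale raw coordinates before building the quadratic design:
  # keeps the normal equations well conditioned, and centring makes the
  # minimum-norm five-point fit coincide with the true map when the
  # distortion is affine (the free cross term vanishes at a centred cross)
  ctr <- colMeans(med)
  scl <- max(stats::sd(med[, "u"]), stats::sd(med[, "v"]), 1e-12)
  un <- (med[, "u"] - ctr["u"]) / scl
  vn <- (med[, "v"] - ctr["v"]) / scl
  X <- quad_design(un, vn)
  Y <- cbind(targets$x_px, targets$y_px)
  # minimum-norm least squares via SVD: with five targets the quadratic is
  # underdetermined; dropping near-zero singular values keeps the fit solvable
  # and makes it interpolate the medians exactly when the geometry allows
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-10
  dinv <- ifelse(keep, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * (t(sv$u) %*% Y))
  fitted <- X %*% coef
  resid <- sqrt(rowSums((fitted - Y)^2))
  if (max(abs(fitted - Y)) > 1) {
    # degenerate geometry (e.g. collinear medians) leaves large residuals
    # at the targets themselves
    stop("singular calibration fit: target medians cannot be interpolated ",
         sprintf("(max residual %.2f px)", max(resid)))
  }
  structure(
    list(coefficients = coef, center = ctr, scale = scl,
         residuals_px = stats::setNames(resid, targets$target_label),
         medians = med, targets = targets, geometry = geometry),
    class = "calibration_model"
  )
}

#' Apply a calibration model to raw coordinates
#'
#' @param model a `calibration_model`.
#' @param u,v raw coordinates.
#' @return Matrix with columns `x`, `y` in screen-centred pixels.
#' @export
predict_calibration <- function(model, u, v) {
  un <- (u - model$center["u"]) / model$scale
  vn <- (v - model$center["v"]) / model$scale
  out <- quad_design(un, vn) %*% model$coefficients
  colnames(out) <- c("x", "y")
  out
}

#' Calibrate a gaze recording
#'
#' Replaces the recording's coordinates (raw tracker units in `x`/`y`; use
#' `space = "raw"` when constructing such recordings) by the calibrated screen
#' position converted to image pixels (the image is centred on the screen),
#' and re-evaluates the validity flags against the image bounds. Incoming
#' flags are kept as the pupil-presence signal.
#'
#' @param model a `calibration_model`.
#' @param recording a [gaze_recording()] holding raw coordinates.
#' @return The calibrated [gaze_recording()] in image space.
#' @export
apply_calibration <- function(model, recording) {
  geo <- recording$geometry
  s <- recording$samples
  xy <- predict_calibration(model, s$x, s$y)
  s$x <- xy[, "x"] + geo$image_size_px[1] / 2
  s$y <- xy[, "y"] + geo$image_size_px[2] / 2
  gaze_recording(recording$participant_id, recording$group,
                 recording$image_id, recording$trial_index, recording$block,
                 s, geo, order = recording$order, check = FALSE,
                 space = "image")
}

#' Central calibration error
#'
#' Euclidean distance, in degrees, between the calibrated median of a
#' validation window recorded while the participant looked at the screen
#' centre, and the true centre.
#'
#' @param model a `calibration_model`.
#' @param validation_window data frame with raw columns `u`, `v`.
#' @param geometry a [geometry_spec()].
#' @return Error in degrees (scalar).
#' @export
central_error <- function(model, validation_window,
                          geometry = geometry_spec()) {
  stopifnot(nrow(validation_window) > 0)
  mu <- stats::median(validation_window$u)
  mv <- stats::median(validation_window$v)
  xy <- predict_calibration(model, mu, mv)
  sqrt(sum(xy^2)) / geometry$pixels_per_degree
}

#' Read calibration windows from the tabular format
#'
#' Columns `target_label`, `t_ms`, `u`, `v`.
#'
#' @param path file path.
#' @param sep delimiter.
#' @return Tibble of windows.
#' @export
read_calibration_windows <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("target_label", "t_ms", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("calibration file missing column(s): ",
                         paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' Serialise a calibration model to JSON
#'
#' @param model a `calibration_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration_model <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = unclass(model$coefficients),
         center = as.list(model$center), scale = model$scale,
         residuals_px = as.list(model$residuals_px),
         targets = model$targets),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
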