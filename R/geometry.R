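#' Screen and stimulus geometry
#'
#' Bundles the acquisition geometry used throughout the pipeline: eye-tracker
#' sampling rate, angular resolution in pixels per degree, the stimulus image
#' extent and the screen size. Defaults correspond to a 500 Hz tracker viewing
#' 800 x 800 px images that subtend 19.6 x 19.6 visual degrees on a
#' 1920 x 1080 screen.
#'
#' Gaze coordinates are 0-based image pixel indices: origin at the top-left
#' image corner, x rightward, y downward. A sample is on-image when
#' `0 <= x < width` and `0 <= y < height`.
#'
#' @param sampling_rate samples per second.
#' @param pixels_per_degree pixels per visual degree.
#' @param image_size_px integer vector `c(width, height)` of the stimulus.
#' @param image_extent_deg numeric vector `c(width, height)` in degrees.
#' @param screen_size_px integer vector `c(width, height)` of the display.
#' @return A `geometry_spec` object (list with the five fields above).
#' @examples
#' geo <- geometry_spec()
#' geo$pixels_per_degree
#' @export
geometry_spec <- function(sampling_rate = 500,
                          pixels_per_degree = 800 / 19.6,
                          image_size_px = c(800L, 800L),
                          image_extent_deg = c(19.6, 19.6),
                          screen_size_px = c(1920L, 1080L)) {
  stopifnot(
    sampling_rate > 0, pixels_per_degree > 0,
    length(image_size_px) == 2, all(image_size_px > 0),
    length(image_extent_deg) == 2, all(image_extent_deg > 0),
    length(screen_size_px) == 2, all(screen_size_px > 0)
  )
  implied <- image_size_px / pixels_per_degree
  if (any(abs(implied - image_extent_deg) / image_extent_deg > 0.05)) {
    stop("image_size_px / pixels_per_degree disagrees with image_extent_deg by more than 5%")
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      pixels_per_degree = pixels_per_degree,
      image_size_px = as.integer(image_size_px),
      image_extent_deg = image_extent_deg,
      screen_size_px = as.integer(screen_size_px)
    ),
    class = "geometry_spec"
  )
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf(
    "<geometry_spec> %g Hz, %.3f px/deg, image %dx%d px (%.1fx%.1f deg), screen %dx%d px\n",
    x$sampling_rate, x$pixels_per_degree,
    x$image_size_px[1], x$image_size_px[2],
    x$image_extent_deg[1], x$image_extent_deg[2],
    x$screen_size_px[1], x$screen_size_px[2]
  ))
  invisible(x)
}

#' Construct a single gaze recording
#'
#' One participant x image exploration: an ordered, regularly sampled gaze
#' stream with per-sample validity flags. Samples that fall off the image (or
#' where the pupil was lost) are retained and flagged invalid rather than
#' dropped, so that missing-data fractions stay computable.
#'
#' @param participant_id character scalar.
#' @param group group label, one of `"CC"`, `"SC"`, `"DC"`, `"NC"`.
#' @param image_id character scalar.
#' @param trial_index integer trial number within the session.
#' @param block block number.
#' @param samples data frame with columns `t` (seconds), `x`, `y` (image px)
#'   and `valid` (logical).
#' @param geometry a [geometry_spec()].
#' @param order presentation order within the trial (1 or 2), if known.
#' @param check validate timestamp regularity and nominal duration
#'   (3.9-4.1 s). Disable only for deliberately truncated fixtures.
#' @param space `"image"` for calibrated image-pixel coordinates (off-image
#'   samples are flagged invalid); `"raw"` for uncalibrated tracker units,
#'   where the validity flag only encodes pupil presence and no bounds apply.
#' @return A `gaze_recording` object.
#' @export
gaze_recording <- function(participant_id, group, image_id, trial_index, block,
                           samples, geometry, order = NA_integer_,
                           check = TRUE, space = c("image", "raw")) {
  space <- match.arg(space)
  stopifnot(is.data.frame(samples),
            all(c("t", "x", "y", "valid") %in% names(samples)))
  samples <- tibble::as_tibble(samples[, c("t", "x", "y", "valid")])
  samples$valid <- as.logical(samples$valid)
  if (space == "image") {
    # off-image coordinates are never valid, whatever the incoming flag says
    w <- geometry$image_size_px[1]; h <- geometry$image_size_px[2]
    on_img <- !is.na(samples$x) & !is.na(samples$y) &
      samples$x >= 0 & samples$x < w & samples$y >= 0 & samples$y < h
    samples$valid <- samples$valid & on_img
  }
  if (check) {
    if (nrow(samples) < 2) stop("recording needs at least 2 samples")
    dt <- diff(samples$t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    step <- 1 / geometry$sampling_rate
    if (any(abs(dt - step) > step * 1e-3)) {
      stop("nonuniform timestamps: expected constant step 1/sampling_rate")
    }
    dur <- nrow(samples) / geometry$sampling_rate
    if (dur < 3.9 || dur > 4.1) {
      stop(sprintf("recording duration %.3f s outside accepted 3.9-4.1 s window", dur))
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         group = as.character(group),
         image_id = as.character(image_id),
         trial_index = as.integer(trial_index),
         block = as.integer(block),
         order = as.integer(order),
         samples = samples,
         geometry = geometry,
         space = space),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> %s [%s] image %s, trial %d, %d samples (%.1f%% valid)\n",
    x$participant_id, x$group, x$image_id, x$trial_index,
    nrow(x$samples), 100 * mean(x$samples$valid)
  ))
  invisible(x)
}

#' Fraction of missing (invalid) samples in a recording
#'
#' @param recording a [gaze_recording()].
#' @return Proportion in `[0, 1]` of samples flagged invalid.
#' @export
missing_fraction <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"), nrow(recording$samples) > 0)
  mean(!recording$samples$valid)
}

#' Keep only sufficiently valid recordings
#'
#' A recording survives when the fraction of valid samples is at least
#' `min_valid_fraction` (default 0.5, i.e. at least 50% of the 4 s exploration
#' must be usable gaze on the image).
#'
#' @param recordings list of [gaze_recording()] objects.
#' @param min_valid_fraction minimum proportion of valid samples to keep.
#' @return List with elements `kept`, `discarded` (both lists of recordings)
#'   and `report`, a tibble of discarded counts per group.
#' @export
validity_filter <- function(recordings, min_valid_fraction = 0.5) {
  stopifnot(length(recordings) > 0)
  vf <- vapply(recordings, function(r) 1 - missing_fraction(r), numeric(1))
  keep <- vf >= min_valid_fraction
  groups <- vapply(recordings, function(r) r$group, character(1))
  report <- tibble::tibble(group = sort(unique(groups)))
  report$n_total <- vapply(report$group, function(g) sum(groups == g),
                           integer(1), USE.NAMES = FALSE)
  report$n_discarded <- vapply(report$group,
                               function(g) sum(groups == g & !keep),
                               integer(1), USE.NAMES = FALSE)
  list(kept = recordings[keep], discarded = recordings[!keep], report = report)
}

# ---- tabular interchange -----------------------------------------------

#' Read a gaze dataset from the tabular interchange format
#'
#' The gaze table is delimiter-separated text (default tab), one sample per
#' row, header required, columns `participant_id, group, block, trial_index,
#' image_id, t_ms, x_px, y_px, valid` (and optionally `order`). Binocular
#' input may instead carry `x_left, y_left, x_right, y_right, valid_left,
#' valid_right`; the reader averages the valid eye(s) per sample. Off-image
#' coordinates are retained and flagged invalid.
#'
#' @param path gaze table file.
#' @param geometry a [geometry_spec()].
#' @param trials_path optional trial table (`pair_type, first_image_id,
#'   second_image_id, named_first_correct, named_second_correct` plus
#'   `participant_id`, `trial_index`).
#' @param sep field delimiter.
#' @return List with `recordings` (list of [gaze_recording()]) and `trials`
#'   (tibble or `NULL`).
#' @export
read_gaze_dataset <- function(path, geometry, trials_path = NULL, sep = "\t") {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) stop("parse error in gaze table '", path, "': ",
                             conditionMessage(e))
  )
  binoc <- all(c("x_left", "y_left", "x_right", "y_right",
                 "valid_left", "valid_right") %in% names(df))
  need <- c("participant_id", "group", "block", "trial_index", "image_id", "t_ms")
  need <- c(need, if (binoc) character(0) else c("x_px", "y_px", "valid"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gaze table '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$t_ms))
  if (length(bad)) stop("malformed t_ms at data line ", bad[1])
  if (binoc) {
    vl <- as.logical(df$valid_left); vr <- as.logical(df$valid_right)
    wsum <- vl + vr
    df$x_px <- ifelse(wsum > 0,
                      (ifelse(vl, df$x_left, 0) + ifelse(vr, df$x_right, 0)) / pmax(wsum, 1),
                      NA_real_)
    df$y_px <- ifelse(wsum > 0,
                      (ifelse(vl, df$y_left, 0) + ifelse(vr, df$y_right, 0)) / pmax(wsum, 1),
                      NA_real_)
    df$valid <- wsum > 0
  }
  has_order <- "order" %in% names(df)
  key <- paste(df$participant_id, df$trial_index,
               if (has_order) df$order else df$image_id, df$image_id, sep = "\r")
  recs <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                 function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$t_ms), , drop = FALSE]
    if (anyDuplicated(sub$t_ms)) stop("duplicate timestamps within a recording")
    gaze_recording(
      participant_id = sub$participant_id[1], group = sub$group[1],
      image_id = sub$image_id[1], trial_index = sub$trial_index[1],
      block = sub$block[1],
      samples = data.frame(t = sub$t_ms / 1000, x = sub$x_px, y = sub$y_px,
                           valid = as.logical(sub$valid)),
      geometry = geometry,
      order = if (has_order) sub$order[1] else NA_integer_
    )
  })
  names(recs) <- NULL
  trials <- NULL
  if (!is.null(trials_path)) trials <- read_trial_table(trials_path, sep = sep)
  list(recordings = recs, trials = trials)
}

#' Read a trial-pair table
#'
#' @param path trial table file.
#' @param sep field delimiter.
#' @return Tibble with one row per trial pair.
#' @export
read_trial_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_index", "pair_type",
            "first_image_id", "second_image_id",
            "named_first_correct", "named_second_correct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  ok <- df$pair_type %in% c("same_image", "same_category", "different_category")
  if (!all(ok)) stop("unknown pair_type at row ", which(!ok)[1])
  same <- df$pair_type == "same_image"
  if (any(same & df$first_image_id != df$second_image_id)) {
    stop("same_image pair with differing image ids")
  }
  if (any(!same & df$first_image_id == df$second_image_id)) {
    stop("non-repeat pair with identical image ids")
  }
  tibble::as_tibble(df)
}

#' Write a gaze dataset to the tabular interchange format
#'
#' Inverse of [read_gaze_dataset()]; `t_ms` is written as an integer.
#'
#' @param recordings list of [gaze_recording()].
#' @param path output file.
#' @param trials optional trial tibble written next to it.
#' @param trials_path where to write `trials` (required if given).
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_gaze_dataset <- function(recordings, path, trials = NULL,
                               trials_path = NULL, sep = "\t") {
  rows <- lapply(recordings, function(r) {
    data.frame(participant_id = r$participant_id, group = r$group,
               block = r$block, trial_index = r$trial_index,
               image_id = r$image_id, order = r$order,
               t_ms = as.integer(round(r$samples$t * 1000)),
               x_px = r$samples$x, y_px = r$samples$y,
               valid = as.integer(r$samples$valid))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(trials)) {
    stopifnot(!is.null(trials_path))
    utils::write.table(as.data.frame(trials), trials_path, sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a grayscale stimulus image
#'
#' Accepts PNG (8/16-bit, via the png package) or plain/raw PGM. Intensities
#' are rescaled to `[0, 1]`; RGB input is averaged to gray.
#'
#' @param path image file.
#' @param geometry optional [geometry_spec()]; if given, the size is checked.
#' @return Numeric matrix (rows = y, cols = x) in `[0, 1]`.
#' @export
read_image <- function(path, geometry = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  } else if (ext %in% c("pgm", "pnm")) {
    img <- read_pgm(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (!is.null(geometry)) {
    if (nrow(img) != geometry$image_size_px[2] || ncol(img) != geometry$image_size_px[1]) {
      stop(sprintf("image is %dx%d px but geometry expects %dx%d",
                   ncol(img), nrow(img),
                   geometry$image_size_px[1], geometry$image_size_px[2]))
    }
  }
  img
}

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  hdr <- integer(0)
  buf <- character(0)
  while (length(hdr) < 3) {
    line <- readLines(con, n = 1)
    line <- sub("#.*$", "", line)
    hdr <- c(hdr, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
    hdr <- hdr[!is.na(hdr)]
  }
  w <- hdr[1]; h <- hdr[2]; maxv <- hdr[3]
  if (magic == "P5") {
    n <- w * h
    vals <- if (maxv < 256) as.integer(readBin(con, "raw", n)) else
      readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a matrix as a plain-text PGM image
#'
#' 16-bit plain (P2) PGM; values are rescaled so that `max(values)` maps to
#' 65535 unless `rescale = FALSE`.
#'
#' @param values numeric matrix in `[0, 1]` (or arbitrary nonnegative if
#'   `rescale = TRUE`).
#' @param path output file.
#' @param rescale divide by the maximum before quantising.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(values, path, rescale = TRUE) {
  stopifnot(is.matrix(values), all(values >= 0))
  v <- values
  if (rescale && max(v) > 0) v <- v / max(v)
  q <- round(v * 65535)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "65535"), con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# internal: deterministic 31-bit subseed from a base seed and context labels
subseed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(paste(p, collapse = ""))) else as.numeric(p)
  })))
  s <- 0
  for (p in parts) s <- (s * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(s + 1)
}
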