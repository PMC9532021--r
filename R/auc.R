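# Bias-controlled AUC classification of gazed vs nongazed locations.
#
# The null ("nongazed") locations are not random pixels: they are locations
# the same participant gazed at on OTHER images. Both classes therefore share
# the participant's spatial bias (notably the center bias of gaze and of
# photographic content), so AUC > 0.5 reflects image-specific prediction and
# not a generic central tendency.

#' Rank-based AUC from gazed and nongazed map values
#'
#' Mann-Whitney U formulation with midranks for ties:
#' `U = R_gazed - n_gazed (n_gazed + 1) / 2` where `R_gazed` is the rank sum
#' of the gazed values in the joint ranking (smallest value gets rank 1), and
#' `AUC = U / (n_gazed * n_nongazed)`. Equals the probability that a random
#' gazed location outranks a random nongazed one (ties counted half).
#'
#' @param gazed,nongazed numeric vectors of predictor-map values (non-empty).
#' @return One-row tibble: `auc`, `U`, `R_gazed`, `n_gazed`, `n_nongazed`.
#' @export
auc_from_values <- function(gazed, nongazed) {
  n_g <- length(gazed); n_n <- length(nongazed)
  stopifnot(n_g > 0, n_n > 0, all(is.finite(gazed)), all(is.finite(nongazed)))
  r <- rank(c(gazed, nongazed), ties.method = "average")
  r_gazed <- sum(r[seq_len(n_g)])
  u <- r_gazed - as.numeric(n_g) * (n_g + 1) / 2
  tibble::tibble(auc = u / (as.numeric(n_g) * n_n), U = u, R_gazed = r_gazed,
                 n_gazed = n_g, n_nongazed = n_n)
}

#' Map values at a recording's valid gaze locations
#'
#' Nearest-pixel lookup of the predictor map at every valid sample, in time
#' order. Invalid samples contribute nothing.
#'
#' @param map a `predictor_map`.
#' @param recording a [gaze_recording()].
#' @param sample_mask optional logical vector (length = samples) restricting
#'   which samples are used, e.g. a time interval or velocity bin.
#' @return Numeric vector of map values.
#' @export
sample_gazed_values <- function(map, recording, sample_mask = NULL) {
  s <- recording$samples
  keep <- s$valid
  if (!is.null(sample_mask)) keep <- keep & sample_mask
  if (!any(keep)) return(numeric(0))
  map_values_at(map, s$x[keep], s$y[keep])
}

# internal: nearest-pixel map lookup for 0-based pixel coordinates
map_values_at <- function(map, x, y) {
  w <- ncol(map$values); h <- nrow(map$values)
  px <- pmin(pmax(floor(x), 0), w - 1) + 1
  py <- pmin(pmax(floor(y), 0), h - 1) + 1
  map$values[cbind(py, px)]
}

#' Draw nongazed locations from a participant's gaze on other images
#'
#' Pools the valid gaze locations of `other_recordings` (the same
#' participant's explorations of images other than the one under analysis),
#' draws `n_target` of them uniformly without replacement (with replacement,
#' flagged, only when the pool is smaller than `n_target`) and evaluates the
#' analysed image's map there. Seed-reproducible.
#'
#' @param map predictor map of the analysed image.
#' @param other_recordings list of [gaze_recording()] on other images.
#' @param n_target number of nongazed locations to draw.
#' @param seed integer seed for this draw.
#' @param sample_mask optional logical mask applied to every other recording's
#'   samples (e.g. the matching time interval).
#' @return Numeric vector of map values with attribute
#'   `with_replacement` (logical).
#' @export
sample_nongazed_values <- function(map, other_recordings, n_target, seed,
                                   sample_mask = NULL) {
  xl <- lapply(other_recordings, function(r) {
    keep <- r$samples$valid
    if (!is.null(sample_mask)) keep <- keep & sample_mask
    cbind(r$samples$x[keep], r$samples$y[keep])
  })
  xy <- do.call(rbind, xl)
  if (is.null(xy) || nrow(xy) == 0) {
    stop("empty nongazed pool: no valid samples on other images")
  }
  pool <- nrow(xy)
  replace <- pool < n_target
  idx <- with_seed(seed, sample.int(pool, n_target, replace = replace))
  out <- map_values_at(map, xy[idx, 1], xy[idx, 2])
  attr(out, "with_replacement") <- replace
  out
}

# ---- internal pooled machinery ------------------------------------------

# group a recording list by participant, keeping input order
split_by_participant <- function(recordings) {
  ids <- vapply(recordings, function(r) r$participant_id, character(1))
  split(recordings, factor(ids, levels = unique(ids)))
}

# flatten a participant's valid samples into parallel vectors
participant_pool <- function(recs) {
  imgs <- vapply(recs, function(r) r$image_id, character(1))
  img_levels <- unique(imgs)
  parts <- lapply(seq_along(recs), function(j) {
    s <- recs[[j]]$samples
    keep <- s$valid
    cbind(s$x[keep], s$y[keep], match(imgs[j], img_levels), s$t[keep])
  })
  m <- do.call(rbind, parts)
  list(x = m[, 1], y = m[, 2], img = m[, 3], t = m[, 4],
       img_levels = img_levels)
}

# seed-reproducible draw of n_target pool rows (indices into `candidates`)
draw_from <- function(candidates, n_target, seed) {
  pool <- length(candidates)
  if (pool == 0) stop("empty nongazed pool")
  replace <- pool < n_target
  idx <- with_seed(seed, sample.int(pool, n_target, replace = replace))
  candidates[idx]
}

# internal: image -> map-id assignment; identity for "actual", seed-controlled
# derangement (no fixed point) for "shuffled"
map_assignment <- function(maps, recordings, seed, condition) {
  imgs <- unique(vapply(recordings, function(r) r$image_id, character(1)))
  missing_maps <- setdiff(imgs, names(maps))
  if (length(missing_maps)) {
    stop("no predictor map for image(s): ", paste(missing_maps, collapse = ", "))
  }
  if (condition == "actual") {
    return(stats::setNames(as.list(imgs), imgs))
  }
  n <- length(imgs)
  if (n < 2) stop("shuffled control needs at least 2 images")
  perm <- with_seed(subseed(seed, "derangement"), {
    p <- sample.int(n)
    while (any(p == seq_len(n))) p <- sample.int(n)
    p
  })
  stats::setNames(as.list(imgs[perm]), imgs)
}

# core per-participant loop shared by the whole-trial variants; returns
# gazed/nongazed value lists per recording
pooled_unit_values <- function(recs, maps, assignment, seed, partition_label) {
  pp <- participant_pool(recs)
  gz <- vector("list", length(recs))
  ngz <- vector("list", length(recs))
  for (j in seq_along(recs)) {
    rec <- recs[[j]]
    map <- maps[[assignment[[rec$image_id]]]]
    g <- sample_gazed_values(map, rec)
    if (length(g) == 0) next
    cand <- which(pp$img != match(rec$image_id, pp$img_levels))
    idx <- draw_from(cand, length(g),
                     subseed(seed, rec$participant_id, rec$image_id,
                             rec$trial_index, partition_label))
    gz[[j]] <- g
    ngz[[j]] <- map_values_at(map, pp$x[idx], pp$y[idx])
  }
  list(gazed = gz, nongazed = ngz)
}

#' Per-participant AUC, pooled across images
#'
#' For every recording, gazed values are read from the analysed image's own
#' map (or a reassigned map under `condition = "shuffled"`) and an equal
#' number of nongazed values is drawn from the participant's gaze on other
#' images, evaluated on the same map. Values are pooled across the
#' participant's images and summarised in a single AUC per participant.
#' Participants with fewer than two distinct images are skipped with a
#' warning (their nongazed pool is undefined).
#'
#' @param maps named list of `predictor_map`, keyed by image id.
#' @param recordings list of [gaze_recording()] (typically after
#'   [validity_filter()]).
#' @param seed integer seed controlling the nongazed draws. Draws are made
#'   once per (participant, image, trial, partition, seed), so reruns with a
#'   different predictor-map family share the identical null sample.
#' @param condition `"actual"` or `"shuffled"`; shuffling applies a
#'   seed-controlled derangement of the image-to-map assignment (no image
#'   keeps its own map).
#' @return Tibble, one row per participant, with the AUC fields of
#'   [auc_from_values()] plus `participant_id`, `group`, `condition`,
#'   `pooling` and `partition`.
#' @export
auc_per_participant <- function(maps, recordings, seed,
                                condition = c("actual", "shuffled")) {
  condition <- match.arg(condition)
  assignment <- map_assignment(maps, recordings, seed, condition)
  by_part <- split_by_participant(recordings)
  rows <- lapply(by_part, function(recs) {
    imgs <- unique(vapply(recs, function(r) r$image_id, character(1)))
    if (length(imgs) < 2) {
      warning("participant ", recs[[1]]$participant_id,
              " has < 2 distinct images; skipped")
      return(NULL)
    }
    uv <- pooled_unit_values(recs, maps, assignment, seed, "whole")
    g <- unlist(uv$gazed); ng <- unlist(uv$nongazed)
    if (length(g) == 0) return(NULL)
    out <- auc_from_values(g, ng)
    out$participant_id <- recs[[1]]$participant_id
    out$group <- recs[[1]]$group
    out
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$condition <- condition
    out$pooling <- "per_participant"
    out$partition <- "whole"
  }
  out
}

#' Per-image AUC, pooled across participants
#'
#' Mirror of [auc_per_participant()] with the pooling axes swapped: for each
#' image, gazed and nongazed values from all participants' explorations of
#' that image are pooled into a single AUC. Nongazed draws are identical to
#' the per-participant analysis (same seeds), only the pooling differs.
#'
#' @inheritParams auc_per_participant
#' @return Tibble, one row per image.
#' @export
auc_per_image <- function(maps, recordings, seed,
                          condition = c("actual", "shuffled")) {
  condition <- match.arg(condition)
  assignment <- map_assignment(maps, recordings, seed, condition)
  by_part <- split_by_participant(recordings)
  acc_g <- list(); acc_n <- list()
  for (recs in by_part) {
    imgs <- unique(vapply(recs, function(r) r$image_id, character(1)))
    if (length(imgs) < 2) {
      warning("participant ", recs[[1]]$participant_id,
              " has < 2 distinct images; skipped")
      next
    }
    uv <- pooled_unit_values(recs, maps, assignment, seed, "whole")
    for (j in seq_along(recs)) {
      if (is.null(uv$gazed[[j]])) next
      img <- recs[[j]]$image_id
      acc_g[[img]] <- c(acc_g[[img]], list(uv$gazed[[j]]))
      acc_n[[img]] <- c(acc_n[[img]], list(uv$nongazed[[j]]))
    }
  }
  rows <- lapply(names(acc_g), function(img) {
    out <- auc_from_values(unlist(acc_g[[img]]), unlist(acc_n[[img]]))
    out$image_id <- img
    out
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$condition <- condition
    out$pooling <- "per_image"
    out$partition <- "whole"
  }
  out
}

#' Shuffled-image control AUC
#'
#' Convenience wrapper: [auc_per_participant()] under a derangement of the
#' image-to-map assignment. With only two images the maps are necessarily
#' swapped. A cohort whose AUC is driven by image-specific prediction drops to
#' chance (0.5) under this control; residual structure indicates a spatial
#' bias the nongazed sampling did not remove.
#'
#' @inheritParams auc_per_participant
#' @return Tibble as [auc_per_participant()], `condition = "shuffled"`.
#' @export
shuffled_control <- function(maps, recordings, seed) {
  auc_per_participant(maps, recordings, seed, condition = "shuffled")
}

#' Time-binned AUC (per participant x 500 ms interval)
#'
#' Splits each 4 s recording into `n_bins` nonoverlapping intervals of
#' `bin_width_ms` (default eight 500 ms intervals). Gazed values are
#' restricted to each interval; the nongazed pool is restricted to the
#' *matching* interval of the participant's other images, so that the strong
#' early center bias (enforced central trial starts) is present in both
#' classes. Intervals with no valid samples yield no row (never a zero).
#'
#' @inheritParams auc_per_participant
#' @param n_bins number of intervals.
#' @param bin_width_ms interval width in milliseconds.
#' @return Tibble, one row per participant x interval; `partition` is
#'   `"interval <k>"` with `interval` also given as an integer column.
#' @export
time_binned_auc <- function(maps, recordings, seed, n_bins = 8,
                            bin_width_ms = 500,
                            condition = c("actual", "shuffled")) {
  condition <- match.arg(condition)
  assignment <- map_assignment(maps, recordings, seed, condition)
  by_part <- split_by_participant(recordings)
  rows <- list()
  for (recs in by_part) {
    imgs <- unique(vapply(recs, function(r) r$image_id, character(1)))
    if (length(imgs) < 2) next
    pp <- participant_pool(recs)
    pool_iv <- pmin(floor(pp$t * 1000 / bin_width_ms) + 1, n_bins)
    rec_iv <- lapply(recs, function(r)
      pmin(floor(r$samples$t * 1000 / bin_width_ms) + 1, n_bins))
    for (k in seq_len(n_bins)) {
      gz <- list(); ngz <- list()
      for (j in seq_along(recs)) {
        rec <- recs[[j]]
        map <- maps[[assignment[[rec$image_id]]]]
        g <- sample_gazed_values(map, rec, rec_iv[[j]] == k)
        if (length(g) == 0) next
        cand <- which(pool_iv == k &
                        pp$img != match(rec$image_id, pp$img_levels))
        if (length(cand) == 0) next
        idx <- draw_from(cand, length(g),
                         subseed(seed, rec$participant_id, rec$image_id,
                                 rec$trial_index, paste0("interval", k)))
        gz[[length(gz) + 1]] <- g
        ngz[[length(ngz) + 1]] <- map_values_at(map, pp$x[idx], pp$y[idx])
      }
      if (length(gz) == 0) next
      out <- auc_from_values(unlist(gz), unlist(ngz))
      out$participant_id <- recs[[1]]$participant_id
      out$group <- recs[[1]]$group
      out$interval <- k
      rows[[length(rows) + 1]] <- out
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$condition <- condition
    out$pooling <- "per_participant"
    out$partition <- paste("interval", out$interval)
  }
  out
}

#' Velocity-binned AUC (per participant x velocity quantile)
#'
#' Pools each participant's defined velocity magnitudes across recordings,
#' forms participant-specific quantile bins (default 10) and computes one AUC
#' per bin from the gazed samples falling in that bin. The nongazed pool is
#' the participant's whole-trial gaze on other images (not velocity-matched).
#' Tests whether map-driven exploration is confined to low-velocity
#' (foveation-like) phases of a nystagmus or spans the whole cycle.
#'
#' @inheritParams auc_per_participant
#' @param n_bins number of velocity quantile bins.
#' @return Tibble, one row per participant x quantile, with `quantile` column.
#' @export
velocity_binned_auc <- function(maps, recordings, seed, n_bins = 10) {
  assignment <- map_assignment(maps, recordings, seed, "actual")
  by_part <- split_by_participant(recordings)
  rows <- list()
  for (recs in by_part) {
    imgs <- unique(vapply(recs, function(r) r$image_id, character(1)))
    if (length(imgs) < 2) next
    pp <- participant_pool(recs)
    traces <- lapply(recs, instantaneous_velocity)
    mags <- unlist(lapply(traces, function(tr) tr$magnitude[tr$defined]))
    if (length(mags) < n_bins) {
      stop("participant ", recs[[1]]$participant_id, " has fewer than ",
           n_bins, " defined velocity samples")
    }
    # participant-level quantile bins; ties broken by pooled sample order
    rk <- rank(mags, ties.method = "first")
    lab_pool <- as.integer(ceiling(rk * n_bins / length(mags)))
    # scatter pooled labels back onto each recording's defined samples
    labs <- vector("list", length(recs))
    pos <- 0
    for (j in seq_along(recs)) {
      nd <- sum(traces[[j]]$defined)
      lj <- rep(NA_integer_, nrow(traces[[j]]))
      lj[traces[[j]]$defined] <- lab_pool[pos + seq_len(nd)]
      labs[[j]] <- lj
      pos <- pos + nd
    }
    for (q in seq_len(n_bins)) {
      gz <- list(); ngz <- list()
      for (j in seq_along(recs)) {
        rec <- recs[[j]]
        map <- maps[[assignment[[rec$image_id]]]]
        mk <- !is.na(labs[[j]]) & labs[[j]] == q
        g <- sample_gazed_values(map, rec, mk)
        if (length(g) == 0) next
        cand <- which(pp$img != match(rec$image_id, pp$img_levels))
        idx <- draw_from(cand, length(g),
                         subseed(seed, rec$participant_id, rec$image_id,
                                 rec$trial_index, paste0("vq", q)))
        gz[[length(gz) + 1]] <- g
        ngz[[length(ngz) + 1]] <- map_values_at(map, pp$x[idx], pp$y[idx])
      }
      if (length(gz) == 0) next
      out <- auc_from_values(unlist(gz), unlist(ngz))
      out$participant_id <- recs[[1]]$participant_id
      out$group <- recs[[1]]$group
      out$quantile <- q
      rows[[length(rows) + 1]] <- out
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$condition <- "actual"
    out$pooling <- "per_participant"
    out$partition <- paste("velocity-quantile", out$quantile)
  }
  out
}
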