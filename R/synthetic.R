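# Synthetic free-viewing cohort generator.
#
# Emulates the statistical structure the analysis assumes: saliency-driven
# target selection (targets drawn from a per-image ground-truth map),
# fixation-saccade kinematics for sighted-like groups, horizontal jerk
# nystagmus (NC-like) and multiplanar irregular nystagmus (CC-like), enforced
# central trial starts, missing-data insertion, and entropy narrowing on
# identical image repetition. Ground truth (maps, targets, parameters) is
# stored with every output so parameter-recovery tests can close the loop.

#' Kinematic/behavioural profile of one synthetic group
#'
#' @param n number of participants.
#' @param profile `"fixation_saccade"`, `"horizontal_jerk"` or
#'   `"multiplanar_irregular"`.
#' @param nystagmus_amplitude_deg beat amplitude (degrees); ignored by the
#'   fixation profile.
#' @param nystagmus_frequency_hz beats per second.
#' @param slow_phase_accel exponential slow-phase velocity growth rate
#'   (0 = constant-velocity sawtooth); larger values concentrate low
#'   velocities at the on-target start of each beat (foveation periods).
#' @param fixation_mean_ms,fixation_sd_ms dwell-duration distribution.
#' @param saccade_ms duration of inter-target transitions.
#' @param jitter_sd_deg stationary SD of the smooth fixational jitter.
#' @param missing_rate expected fraction of invalid (lost/off-image) samples.
#' @param acuity_range logMAR range; per-participant acuity is drawn uniformly
#'   within it.
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(n,
                          profile = c("fixation_saccade", "horizontal_jerk",
                                      "multiplanar_irregular"),
                          nystagmus_amplitude_deg = 3,
                          nystagmus_frequency_hz = 3,
                          slow_phase_accel = 2,
                          fixation_mean_ms = 300,
                          fixation_sd_ms = 60,
                          saccade_ms = 30,
                          jitter_sd_deg = 0.15,
                          missing_rate = 0.05,
                          acuity_range = c(0, 0.2)) {
  profile <- match.arg(profile)
  stopifnot(n >= 1, nystagmus_amplitude_deg > 0, nystagmus_frequency_hz > 0,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "group_profile")
}

#' Cohort specification for the synthetic session generator
#'
#' Defaults give a 12-participant cohort (3 per group) matching the study
#' design: SC and DC with fixation-saccade kinematics, NC with horizontal jerk
#' nystagmus, CC with multiplanar irregular nystagmus and the highest
#' missing-data rate; 500 ms enforced central starts; targets drawn from the
#' image's ground-truth map at fidelity `tau`; identical repeats concentrated
#' by `repeat_concentration`.
#'
#' @param groups named list of [group_profile()] (names = group labels).
#' @param tau map-following fidelity: targets are drawn from
#'   `map^(1/(tau * dispersion))`. `tau -> 0` approaches the map mode;
#'   large `tau` flattens towards uniform exploration.
#' @param dispersion spatial-dispersion multiplier (1 = calibrated); larger
#'   values flatten the target distribution and increase exploration entropy.
#' @param repeat_concentration factor `c >= 1`: on the second presentation of
#'   an identical image, targets are drawn from `map^c` (renormalised),
#'   narrowing exploration.
#' @param central_start_ms initial period anchored at the image centre.
#' @param recognition_coef coefficients `(intercept, acuity, auc)` of the
#'   logistic model generating naming-correct outcomes.
#' @param geometry a [geometry_spec()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(
                          CC = group_profile(3, "multiplanar_irregular",
                                             nystagmus_amplitude_deg = 3,
                                             nystagmus_frequency_hz = 3,
                                             slow_phase_accel = 2.5,
                                             fixation_mean_ms = 600,
                                             missing_rate = 0.10,
                                             acuity_range = c(0.5, 1.4)),
                          SC = group_profile(3, "fixation_saccade",
                                             missing_rate = 0.037,
                                             acuity_range = c(0, 0.2)),
                          DC = group_profile(3, "fixation_saccade",
                                             missing_rate = 0.043,
                                             acuity_range = c(0.2, 0.8)),
                          NC = group_profile(3, "horizontal_jerk",
                                             nystagmus_amplitude_deg = 4,
                                             nystagmus_frequency_hz = 4,
                                             slow_phase_accel = 2.5,
                                             fixation_mean_ms = 600,
                                             missing_rate = 0.10,
                                             acuity_range = c(0.1, 0.6))
                        ),
                        tau = 1,
                        dispersion = 1,
                        repeat_concentration = 2,
                        central_start_ms = 500,
                        recognition_coef = c(intercept = -2, acuity = -3, auc = 6),
                        geometry = geometry_spec()) {
  stopifnot(tau > 0, dispersion > 0, repeat_concentration >= 1,
            central_start_ms >= 0, length(recognition_coef) == 3)
  structure(list(groups = groups, tau = tau, dispersion = dispersion,
                 repeat_concentration = repeat_concentration,
                 central_start_ms = central_start_ms,
                 recognition_coef = recognition_coef,
                 geometry = geometry),
            class = "cohort_spec")
}

IMAGE_CATEGORIES <- c("animals", "chairs", "fruits", "guitars", "houses",
                      "plants", "telephones")

#' Generate synthetic stimulus images and their ground-truth attention maps
#'
#' Each image carries a textured object region close to the image centre on a
#' low-contrast background; its ground-truth map is a mixture of 2-5 isotropic
#' Gaussians over the object's features (sum-normalised). The analytic mixture
#' parameters travel with the map (attribute `"mixture"`) so target sampling
#' and tempering stay exact.
#'
#' @param n number of images; assigned to `categories` round-robin.
#' @param seed integer seed.
#' @param categories category labels.
#' @param geometry a [geometry_spec()].
#' @param render_pixels also render the grayscale pixel matrices (needed for
#'   contrast maps and low-pass variants; skip for gaze-only studies).
#' @return List with `stimuli` (list of `image_stimulus`: `image_id`,
#'   `category`, `pixels` or `NULL`) and `maps` (named list of
#'   `predictor_map`, provenance `"truth"`).
#' @export
generate_images <- function(n, seed, categories = IMAGE_CATEGORIES,
                            geometry = geometry_spec(), render_pixels = TRUE) {
  stopifnot(n >= 1)
  w <- geometry$image_size_px[1]; h <- geometry$image_size_px[2]
  ppd <- geometry$pixels_per_degree
  stimuli <- vector("list", n)
  maps <- vector("list", n)
  ids <- sprintf("img%03d", seq_len(n))
  for (i in seq_len(n)) {
    mix <- with_seed(subseed(seed, "img", i), {
      k <- sample(2:5, 1)
      list(
        mu_x = w / 2 + stats::runif(k, -0.25, 0.25) * w,
        mu_y = h / 2 + stats::runif(k, -0.25, 0.25) * h,
        sigma = stats::runif(k, 0.7, 1.5) * ppd,
        weight = {
          u <- stats::runif(k, 0.5, 1.5); u / sum(u)
        }
      )
    })
    vals <- mixture_matrix(mix, w, h)
    map <- new_predictor_map(vals, geometry, "truth")
    attr(map, "mixture") <- mix
    maps[[i]] <- map
    pixels <- NULL
    if (render_pixels) {
      pixels <- with_seed(subseed(seed, "pix", i), {
        bg <- gaussian_blur(matrix(stats::rnorm(w * h), h, w), 8)
        bg <- 0.04 * bg / stats::sd(bg)
        envelope <- vals / max(vals)
        tex <- gaussian_blur(matrix(stats::rnorm(w * h), h, w), 2)
        tex <- tex / stats::sd(tex)
        px <- 0.5 + bg + 0.3 * tex * envelope
        px[px < 0] <- 0; px[px > 1] <- 1
        px
      })
    }
    stimuli[[i]] <- structure(
      list(image_id = ids[i],
           category = categories[((i - 1) %% length(categories)) + 1],
           pixels = pixels),
      class = "image_stimulus"
    )
  }
  names(maps) <- ids
  names(stimuli) <- ids
  list(stimuli = stimuli, maps = maps)
}

# internal: evaluate a Gaussian mixture on the full pixel grid (separable)
mixture_matrix <- function(mix, w, h) {
  vals <- matrix(0, nrow = h, ncol = w)
  xs <- seq_len(w) - 0.5
  ys <- seq_len(h) - 0.5
  for (k in seq_along(mix$weight)) {
    gx <- stats::dnorm(xs, mix$mu_x[k], mix$sigma[k])
    gy <- stats::dnorm(ys, mix$mu_y[k], mix$sigma[k])
    vals <- vals + mix$weight[k] * (gy %o% gx)
  }
  vals
}

# internal: draw m target locations from map^expo (renormalised), via a
# 100x100 discretisation of the analytic mixture
sample_targets <- function(map, m, expo, geometry) {
  w <- geometry$image_size_px[1]; h <- geometry$image_size_px[2]
  ng <- 100L
  mix <- attr(map, "mixture")
  cx <- (seq_len(ng) - 0.5) * w / ng
  cy <- (seq_len(ng) - 0.5) * h / ng
  if (!is.null(mix)) {
    vals <- matrix(0, nrow = ng, ncol = ng)
    for (k in seq_along(mix$weight)) {
      gx <- stats::dnorm(cx, mix$mu_x[k], mix$sigma[k])
      gy <- stats::dnorm(cy, mix$mu_y[k], mix$sigma[k])
      vals <- vals + mix$weight[k] * (gy %o% gx)
    }
  } else {
    # block-average the stored pixel map
    fx <- floor((seq_len(w) - 1) / (w / ng)) + 1
    fy <- floor((seq_len(h) - 1) / (h / ng)) + 1
    vals <- rowsum(t(rowsum(map$values, fy)), fx)
    vals <- t(vals)
  }
  p <- vals^expo
  p <- p / sum(p)
  cell <- sample.int(ng * ng, m, replace = TRUE, prob = as.vector(p))
  row <- (cell - 1) %% ng + 1   # y cell index (column-major vectorisation)
  col <- (cell - 1) %/% ng + 1  # x cell index
  cbind(x = cx[col] - w / ng / 2 + stats::runif(m) * w / ng,
        y = cy[row] - h / ng / 2 + stats::runif(m) * h / ng)
}

#' Simulate one 4 s exploration of an image
#'
#' Draws a sequence of gaze targets from the tempered ground-truth map and
#' renders it into a 500 Hz gaze stream under the group's kinematic profile:
#' dwell periods with smooth fixational jitter joined by short
#' linearly-interpolated transitions, plus (for nystagmus profiles) a
#' superimposed beat waveform — an accelerating slow-phase drift away from the
#' target followed by a fast corrective reset. The first `central_start_ms`
#' are anchored at the image centre. Invalid samples (pupil loss / off-image
#' gaze) are inserted in runs at the profile's missing rate.
#'
#' @param map ground-truth `predictor_map` of the image.
#' @param profile a [group_profile()].
#' @param spec a [cohort_spec()] (geometry, tau, dispersion, central start).
#' @param seed integer seed.
#' @param participant_id,group,image_id,trial_index,block,order metadata
#'   stamped on the recording.
#' @param concentration extra exponent (`c`) applied to the map for repeated
#'   identical presentations.
#' @param duration_s exploration duration.
#' @return List with `recording` (a [gaze_recording()]) and `truth` (target
#'   sequence and the exponent actually used).
#' @export
simulate_recording <- function(map, profile, spec, seed,
                               participant_id = "p1", group = "SC",
                               image_id = "img001", trial_index = 1L,
                               block = 1L, order = 1L,
                               concentration = 1, duration_s = 4) {
  geo <- spec$geometry
  sr <- geo$sampling_rate
  ppd <- geo$pixels_per_degree
  n <- round(duration_s * sr)
  w <- geo$image_size_px[1]; h <- geo$image_size_px[2]
  expo <- concentration / (spec$tau * spec$dispersion)

  out <- with_seed(seed, {
    # ---- dwell/transition schedule ------------------------------------
    n_central <- min(n, round(spec$central_start_ms / 1000 * sr))
    dwell_n <- function() {
      ms <- max(100, stats::rnorm(1, profile$fixation_mean_ms,
                                  profile$fixation_sd_ms))
      max(1L, round(ms / 1000 * sr))
    }
    sacc_n <- max(1L, round(profile$saccade_ms / 1000 * sr))
    max_targets <- ceiling(n / (sacc_n + 50)) + 2L
    tx <- numeric(0); ty <- numeric(0)
    base_x <- numeric(n); base_y <- numeric(n)
    pos <- 0L
    cur <- c(w / 2, h / 2)
    if (n_central > 0) {
      base_x[1:n_central] <- cur[1]; base_y[1:n_central] <- cur[2]
      pos <- n_central
    }
    targets <- sample_targets(map, max_targets, expo, geo)
    ti <- 0L
    while (pos < n) {
      ti <- ti + 1L
      nxt <- targets[ti, ]
      # transition
      ns <- min(sacc_n, n - pos)
      frac <- seq_len(ns) / sacc_n
      base_x[pos + seq_len(ns)] <- cur[1] + frac * (nxt[1] - cur[1])
      base_y[pos + seq_len(ns)] <- cur[2] + frac * (nxt[2] - cur[2])
      pos <- pos + ns
      cur <- nxt
      tx <- c(tx, nxt[1]); ty <- c(ty, nxt[2])
      if (pos >= n) break
      # dwell
      nd <- min(dwell_n(), n - pos)
      base_x[pos + seq_len(nd)] <- cur[1]
      base_y[pos + seq_len(nd)] <- cur[2]
      pos <- pos + nd
    }

    # ---- smooth fixational jitter (AR(1), stationary SD jitter_sd_deg) --
    rho <- 0.95
    sd_innov <- profile$jitter_sd_deg * ppd * sqrt(1 - rho^2)
    jx <- as.numeric(stats::filter(stats::rnorm(n, 0, sd_innov), rho,
                                   method = "recursive"))
    jy <- as.numeric(stats::filter(stats::rnorm(n, 0, sd_innov), rho,
                                   method = "recursive"))
    gx <- base_x + jx
    gy <- base_y + jy

    # ---- nystagmus beat waveform ---------------------------------------
    if (profile$profile != "fixation_saccade") {
      amp <- profile$nystagmus_amplitude_deg * ppd
      per_n <- max(4L, round(sr / profile$nystagmus_frequency_hz))
      slow_n <- max(2L, round(0.85 * per_n))
      fast_n <- per_n - slow_n
      a <- profile$slow_phase_accel
      u <- seq_len(slow_n) / slow_n
      slow_off <- if (a > 0) (exp(a * u) - 1) / (exp(a) - 1) else u
      cyc <- c(slow_off, rev(seq_len(fast_n)) / (fast_n + 1))  # drift out, snap back
      n_cyc <- ceiling(n / per_n)
      phase <- rep(cyc, n_cyc)[seq_len(n)]
      if (profile$profile == "horizontal_jerk") {
        dir_x <- rep(1, n); dir_y <- rep(0, n)
      } else {
        ang <- stats::runif(n_cyc, 0, 2 * pi)
        dir_x <- rep(cos(ang), each = per_n)[seq_len(n)]
        dir_y <- rep(sin(ang), each = per_n)[seq_len(n)]
      }
      gx <- gx + amp * phase * dir_x
      gy <- gy + amp * phase * dir_y
    }

    # ---- missing-data runs ---------------------------------------------
    valid <- rep(TRUE, n)
    target_missing <- round(profile$missing_rate * n)
    guard <- 0L
    while (sum(!valid) < target_missing && guard < 1000L) {
      guard <- guard + 1L
      len <- max(1L, round(stats::rexp(1, 1 / 50)))
      len <- min(len, target_missing - sum(!valid) + 5L)
      st <- sample.int(n - len + 1L, 1)
      valid[st:(st + len - 1L)] <- FALSE
    }
    gx[!valid] <- -1e4  # tracker junk coordinate: clearly off-image
    gy[!valid] <- -1e4
    list(gx = round(gx, 3), gy = round(gy, 3), valid = valid,
         targets = cbind(x = tx, y = ty))
  })

  samples <- tibble::tibble(
    t = (seq_len(n) - 1) / sr,
    x = out$gx, y = out$gy,
    valid = out$valid
  )
  rec <- gaze_recording(participant_id, group, image_id, trial_index, block,
                        samples, geo, order = order)
  list(recording = rec,
       truth = list(targets = out$targets, exponent = expo,
                    concentration = concentration))
}

#' Simulate a complete experimental session for a synthetic cohort
#'
#' Builds the two-block, 28-trial design (7 same-image, 7 same-category and 14
#' different-category pairs over 49 images, randomised per participant),
#' simulates every exploration, and draws per-presentation naming-correct
#' outcomes from `logistic(intercept + a * acuity + b * auc_truth)` where
#' `auc_truth` is the participant's AUC against the ground-truth maps (so
#' recognition links to map-following ability without circular use of the
#' estimated maps).
#'
#' @param spec a [cohort_spec()].
#' @param images output of [generate_images()] with at least 49 images.
#' @param seed integer seed; the full session is a pure function of
#'   `(spec, images, seed)`.
#' @return List with `recordings`, `trials` (tibble), `participants` (tibble:
#'   id, group, acuity_logmar), `images`, and `truth` (per-recording target
#'   sequences, the recognition coefficients and per-participant truth AUC).
#' @export
simulate_session <- function(spec, images, seed) {
  stimuli <- images$stimuli
  maps <- images$maps
  if (length(stimuli) < 49) stop("session design needs at least 49 images")
  cats <- vapply(stimuli, function(s) s$category, character(1))
  ids <- names(stimuli)
  by_cat <- split(ids, cats)
  if (length(by_cat) < 7 || any(lengths(by_cat) < 7)) {
    stop("session design needs 7 categories with 7 images each")
  }
  by_cat <- lapply(by_cat[seq_len(7)], function(v) v[seq_len(7)])

  participants <- list()
  pid <- 0L
  for (g in names(spec$groups)) {
    prof <- spec$groups[[g]]
    for (j in seq_len(prof$n)) {
      pid <- pid + 1L
      participants[[pid]] <- list(
        participant_id = sprintf("%s%02d", g, j), group = g, profile = prof)
    }
  }

  recordings <- list()
  trial_rows <- list()
  truth_targets <- list()
  part_rows <- list()

  for (p in participants) {
    pseed <- subseed(seed, "participant", p$participant_id)
    acuity <- with_seed(subseed(pseed, "acuity"),
                        stats::runif(1, p$profile$acuity_range[1],
                                     p$profile$acuity_range[2]))
    design <- with_seed(subseed(pseed, "design"), build_trial_design(by_cat))
    for (ti in seq_len(nrow(design))) {
      tr <- design[ti, ]
      for (ord in 1:2) {
        img <- if (ord == 1) tr$first_image_id else tr$second_image_id
        conc <- if (ord == 2 && tr$pair_type == "same_image")
          spec$repeat_concentration else 1
        sim <- simulate_recording(
          maps[[img]], p$profile, spec,
          seed = subseed(pseed, "rec", ti, ord),
          participant_id = p$participant_id, group = p$group,
          image_id = img, trial_index = ti,
          block = if (ti <= nrow(design) / 2) 1L else 2L,
          order = ord, concentration = conc
        )
        recordings[[length(recordings) + 1]] <- sim$recording
        truth_targets[[paste(p$participant_id, ti, ord, sep = "/")]] <-
          sim$truth
      }
      trial_rows[[length(trial_rows) + 1]] <- tibble::tibble(
        participant_id = p$participant_id, group = p$group,
        trial_index = ti, block = if (ti <= nrow(design) / 2) 1L else 2L,
        pair_type = tr$pair_type,
        first_image_id = tr$first_image_id,
        second_image_id = tr$second_image_id
      )
    }
    part_rows[[length(part_rows) + 1]] <- tibble::tibble(
      participant_id = p$participant_id, group = p$group,
      acuity_logmar = acuity)
  }
  trials <- dplyr::bind_rows(trial_rows)
  part_tbl <- dplyr::bind_rows(part_rows)

  # truth-map AUC per participant drives the recognition outcomes
  auc_truth <- auc_per_participant(maps, recordings,
                                   seed = subseed(seed, "auc-truth"))
  part_tbl <- dplyr::left_join(part_tbl,
                               auc_truth[, c("participant_id", "auc")],
                               by = "participant_id")
  names(part_tbl)[names(part_tbl) == "auc"] <- "auc_truth"

  co <- spec$recognition_coef
  lp <- co[1] + co[2] * part_tbl$acuity_logmar + co[3] * part_tbl$auc_truth
  pr <- stats::plogis(lp)
  names(pr) <- part_tbl$participant_id
  trials$named_first_correct <- NA_integer_
  trials$named_second_correct <- NA_integer_
  for (i in seq_len(nrow(trials))) {
    pp <- pr[[trials$participant_id[i]]]
    draws <- with_seed(subseed(seed, "recog", trials$participant_id[i],
                               trials$trial_index[i]),
                       stats::rbinom(2, 1, pp))
    trials$named_first_correct[i] <- draws[1]
    trials$named_second_correct[i] <- draws[2]
  }

  list(recordings = recordings, trials = trials, participants = part_tbl,
       images = images,
       truth = list(targets = truth_targets,
                    recognition_coef = co,
                    auc_truth = stats::setNames(part_tbl$auc_truth,
                                                part_tbl$participant_id)))
}

# internal: one participant's randomised 28-trial design
# 7 same-image pairs (image 1 of each category), 7 same-category pairs
# (images 2+3), 14 different-category pairs (images 4-7, cross-category)
build_trial_design <- function(by_cat) {
  cats <- names(by_cat)
  same_img <- lapply(cats, function(cc) {
    img <- by_cat[[cc]][1]
    tibble::tibble(pair_type = "same_image",
                   first_image_id = img, second_image_id = img)
  })
  same_cat <- lapply(cats, function(cc) {
    pair <- sample(by_cat[[cc]][2:3])
    tibble::tibble(pair_type = "same_category",
                   first_image_id = pair[1], second_image_id = pair[2])
  })
  rest <- unlist(lapply(cats, function(cc) by_cat[[cc]][4:7]))
  rest_cat <- rep(cats, each = 4)
  # pair the 28 remaining images so the two members differ in category:
  # repeatedly shuffle until every adjacent pair is cross-category
  repeat {
    ix <- sample(length(rest))
    a <- ix[seq(1, length(ix), by = 2)]
    b <- ix[seq(2, length(ix), by = 2)]
    if (all(rest_cat[a] != rest_cat[b])) break
  }
  diff_cat <- lapply(seq_along(a), function(k) {
    tibble::tibble(pair_type = "different_category",
                   first_image_id = rest[a[k]], second_image_id = rest[b[k]])
  })
  design <- dplyr::bind_rows(c(same_img, same_cat, diff_cat))
  design[sample(nrow(design)), ]
}
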