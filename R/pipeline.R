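# End-to-end orchestration: validity filter -> velocity -> entropy -> maps ->
# AUC (actual / shuffled / time-binned / velocity-binned) -> repetition ->
# group statistics, with per-stage logging and seed stamping.

#' Pipeline run configuration
#'
#' @param seed integer master seed for all stochastic stages.
#' @param grid_cells entropy grid cells per axis.
#' @param fwhm_deg empirical-map smoothing FWHM (degrees).
#' @param min_valid_fraction validity-filter threshold.
#' @param partitions character subset of
#'   `c("whole", "shuffled", "time", "velocity")`.
#' @param time_bins,velocity_bins partition sizes.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, grid_cells = 20, fwhm_deg = 2,
                       min_valid_fraction = 0.5,
                       partitions = c("whole", "shuffled", "time", "velocity"),
                       time_bins = 8, velocity_bins = 10) {
  stopifnot(all(partitions %in% c("whole", "shuffled", "time", "velocity")))
  structure(list(seed = as.integer(seed), grid_cells = grid_cells,
                 fwhm_deg = fwhm_deg,
                 min_valid_fraction = min_valid_fraction,
                 partitions = partitions, time_bins = time_bins,
                 velocity_bins = velocity_bins),
            class = "run_config")
}

# internal: cheap order-sensitive content hash for reproducibility stamping
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stamp <- function(tbl, config) {
  attr(tbl, "seed") <- config$seed
  attr(tbl, "config_hash") <- config_hash(config)
  tbl
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes every stage in order and returns a report bundle of tidy tables.
#' Stage failures abort with the stage name. The bundle is a pure function of
#' `(dataset, maps, config)`: every table carries the seed and a config hash.
#'
#' @param dataset list with `recordings` (list of [gaze_recording()]),
#'   `trials` (tibble or `NULL`) and optionally `participants` (tibble with
#'   `participant_id`, `acuity_logmar`) — the shape returned by
#'   [simulate_session()] or assembled from [read_gaze_dataset()].
#' @param maps named list of `predictor_map` keyed by image id. If `NULL`,
#'   leave-one-out empirical maps are built from the dataset's SC recordings.
#' @param config a [run_config()].
#' @return List of class `pipeline_report`: `filter_report`, `velocity`
#'   (per-recording median magnitudes), `entropy`, `auc` (one tibble binding
#'   all requested conditions/partitions), `repetition` (per pair type),
#'   `group_contrasts` (entropy and AUC), `recognition`, `log`.
#' @export
run_pipeline <- function(dataset, maps = NULL, config = run_config()) {
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- sprintf("[%s] %s", stage, msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- validity filter ----
  flt <- run_stage("filter",
                   validity_filter(dataset$recordings,
                                   config$min_valid_fraction))
  note("filter", sprintf("%d kept, %d discarded", length(flt$kept),
                         length(flt$discarded)))
  recs <- flt$kept
  if (length(recs) == 0) stop("pipeline stage 'filter' left no recordings")
  geometry <- recs[[1]]$geometry

  # ---- velocity ----
  vel <- run_stage("velocity", {
    rows <- lapply(recs, function(r) {
      tr <- instantaneous_velocity(r)
      tibble::tibble(participant_id = r$participant_id, group = r$group,
                     image_id = r$image_id, trial_index = r$trial_index,
                     median_velocity = stats::median(tr$magnitude[tr$defined]),
                     n_defined = sum(tr$defined))
    })
    dplyr::bind_rows(rows)
  })
  note("velocity", sprintf("%d recordings", nrow(vel)))

  # ---- entropy ----
  ent <- run_stage("entropy", {
    g <- grid_spec(config$grid_cells, config$grid_cells, geometry)
    entropy_table(recs, g)
  })
  note("entropy", sprintf("%d recordings, grid %dx%d", nrow(ent),
                          config$grid_cells, config$grid_cells))

  # ---- maps ----
  if (is.null(maps)) {
    maps <- run_stage("maps", {
      sc <- Filter(function(r) r$group == "SC", recs)
      if (length(sc) == 0) stop("no SC recordings to build empirical maps from")
      by_img <- split(sc, vapply(sc, function(r) r$image_id, character(1)))
      lapply(by_img, function(rr) empirical_map(rr, geometry,
                                                fwhm_deg = config$fwhm_deg))
    })
    note("maps", sprintf("built %d empirical maps", length(maps)))
  } else {
    note("maps", sprintf("using %d supplied maps", length(maps)))
  }

  # ---- AUC ----
  auc_tables <- list()
  if ("whole" %in% config$partitions) {
    auc_tables$actual <- run_stage("auc",
      auc_per_participant(maps, recs, config$seed))
  }
  if ("shuffled" %in% config$partitions) {
    auc_tables$shuffled <- run_stage("auc-shuffled",
      shuffled_control(maps, recs, config$seed))
  }
  if ("time" %in% config$partitions) {
    auc_tables$time <- run_stage("auc-time",
      time_binned_auc(maps, recs, config$seed, n_bins = config$time_bins))
  }
  if ("velocity" %in% config$partitions) {
    auc_tables$velocity <- run_stage("auc-velocity",
      velocity_binned_auc(maps, recs, config$seed,
                          n_bins = config$velocity_bins))
  }
  auc_all <- dplyr::bind_rows(auc_tables)
  note("auc", sprintf("%d AUC rows across %d variants", nrow(auc_all),
                      length(auc_tables)))

  # ---- repetition ----
  repetition <- NULL
  if (!is.null(dataset$trials)) {
    repetition <- run_stage("repetition", {
      tab <- build_repetition_table(ent, dataset$trials)
      out <- list(table = tab)
      for (pt in intersect(c("same_image", "same_category",
                             "different_category"),
                           unique(tab$pair_type))) {
        out[[pt]] <- tryCatch(repetition_contrast(tab, pt),
                              error = function(e) NULL)
      }
      out
    })
    note("repetition", sprintf("%d complete pairs",
                               sum(attr(repetition$table, "pair_counts"))))
  }

  # ---- group statistics ----
  stats_out <- run_stage("stats", {
    out <- list()
    per_part_H <- stats::aggregate(H ~ participant_id + group, data = ent,
                                   FUN = mean)
    if (length(unique(per_part_H$group)) >= 2 &&
        all(table(per_part_H$group) >= 2)) {
      out$entropy_contrasts <- robust_group_contrasts(per_part_H$H,
                                                      per_part_H$group)
    }
    if (!is.null(auc_tables$actual) && nrow(auc_tables$actual) &&
        length(unique(auc_tables$actual$group)) >= 2 &&
        all(table(auc_tables$actual$group) >= 2)) {
      out$auc_contrasts <- robust_group_contrasts(auc_tables$actual$auc,
                                                  auc_tables$actual$group)
      out$auc_vs_chance <- location_tests(auc_tables$actual$auc, 0.5)
    }
    if (!is.null(auc_tables$shuffled) && nrow(auc_tables$shuffled)) {
      out$shuffled_vs_chance <- location_tests(auc_tables$shuffled$auc, 0.5)
    }
    out
  })

  # ---- recognition ----
  recognition <- NULL
  if (!is.null(dataset$trials) && !is.null(dataset$participants) &&
      "named_first_correct" %in% names(dataset$trials) &&
      !is.null(auc_tables$actual) && nrow(auc_tables$actual) > 0) {
    recognition <- run_stage("recognition", {
      tr <- dataset$trials
      long <- rbind(
        data.frame(participant_id = tr$participant_id,
                   correct = tr$named_first_correct),
        data.frame(participant_id = tr$participant_id,
                   correct = tr$named_second_correct)
      )
      pp <- merge(dataset$participants,
                  auc_tables$actual[, c("participant_id", "auc")],
                  by = "participant_id")
      long <- merge(long, pp, by = "participant_id")
      recognition_model(long$correct, long$acuity_logmar, long$auc)
    })
    note("recognition", "3 binomial models fitted")
  }

  out <- list(
    filter_report = stamp(flt$report, config),
    velocity = stamp(vel, config),
    entropy = stamp(ent, config),
    auc = stamp(auc_all, config),
    repetition = repetition,
    group_stats = stats_out,
    recognition = recognition,
    config = config,
    log = unlist(log)
  )
  class(out) <- "pipeline_report"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (l in x$log) cat(" ", l, "\n")
  if (!is.null(x$entropy)) {
    m <- stats::aggregate(H ~ group, data = x$entropy, FUN = mean)
    cat("  mean entropy by group:",
        paste(sprintf("%s=%.2f", m$group, m$H), collapse = ", "), "bits\n")
  }
  if (!is.null(x$auc) && nrow(x$auc)) {
    act <- x$auc[x$auc$condition == "actual" & x$auc$partition == "whole", ]
    if (nrow(act)) cat(sprintf("  mean whole-trial AUC (actual): %.3f\n",
                               mean(act$auc)))
    sh <- x$auc[x$auc$condition == "shuffled", ]
    if (nrow(sh)) cat(sprintf("  mean AUC (shuffled control): %.3f\n",
                              mean(sh$auc)))
  }
  invisible(x)
}
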