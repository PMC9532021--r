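test_that("image generation is deterministic and well-formed", {
  geo <- small_geometry()
  a <- generate_images(5, seed = 81, geometry = geo)
  b <- generate_images(5, seed = 81, geometry = geo)
  expect_identical(a$stimuli[[3]]$pixels, b$stimuli[[3]]$pixels)
  expect_identical(a$maps[[3]]$values, b$maps[[3]]$values)
  for (i in 1:5) {
    px <- a$stimuli[[i]]$pixels
    expect_true(all(px >= 0 & px <= 1))
    expect_equal(sum(a$maps[[i]]$values), 1, tolerance = 1e-9)
    expect_true(all(a$maps[[i]]$values >= 0))
  }
  c_ <- generate_images(5, seed = 82, geometry = geo)
  expect_false(identical(a$stimuli[[1]]$pixels, c_$stimuli[[1]]$pixels))
})

test_that("object regions carry more local contrast than the background", {
  geo <- small_geometry()
  out <- generate_images(3, seed = 83, geometry = geo)
  for (i in 1:3) {
    px <- out$stimuli[[i]]$pixels
    env <- out$maps[[i]]$values / max(out$maps[[i]]$values)
    obj <- env > 0.5; bg <- env < 0.01
    local_sd <- function(mask) {
      sd(px[mask])
    }
    expect_gt(local_sd(obj), 1.5 * local_sd(bg))
  }
})

test_that("recordings are seed-deterministic with valid structure", {
  geo <- small_geometry()
  imgs <- generate_images(2, seed = 84, geometry = geo, render_pixels = FALSE)
  spec <- small_cohort_spec(geo)
  r1 <- simulate_recording(imgs$maps[[1]], spec$groups$NC, spec, seed = 5)
  r2 <- simulate_recording(imgs$maps[[1]], spec$groups$NC, spec, seed = 5)
  expect_identical(r1$recording$samples, r2$recording$samples)
  expect_identical(r1$truth$targets, r2$truth$targets)
  s <- r1$recording$samples
  expect_identical(nrow(s), 2000L)
  expect_equal(diff(s$t), rep(1 / 500, 1999), tolerance = 1e-12)
})

test_that("the missing-data rate lands close to its target around the 50% rule", {
  geo <- small_geometry()
  imgs <- generate_images(2, seed = 85, geometry = geo, render_pixels = FALSE)
  for (rate in c(0.40, 0.49, 0.51)) {
    spec <- small_cohort_spec(geo)
    prof <- group_profile(1, "fixation_saccade", missing_rate = rate)
    fracs <- sapply(1:5, function(s) {
      missing_fraction(simulate_recording(imgs$maps[[1]], prof, spec,
                                          seed = 100 * rate + s)$recording)
    })
    expect_equal(mean(fracs), rate, tolerance = 0.04)
    kept <- validity_filter(lapply(1:5, function(s) {
      simulate_recording(imgs$maps[[1]], prof, spec,
                         seed = 100 * rate + s)$recording
    }))
    if (rate <= 0.49) {
      expect_gte(length(kept$kept), 4)
    } else {
      expect_lte(length(kept$kept), 1)
    }
  }
})

test_that("central starts anchor the first 500 ms at the image centre", {
  geo <- small_geometry()
  imgs <- generate_images(2, seed = 86, geometry = geo, render_pixels = FALSE)
  spec <- small_cohort_spec(geo)
  rec <- simulate_recording(imgs$maps[[1]], spec$groups$SC, spec,
                            seed = 7)$recording
  s <- rec$samples[rec$samples$valid & rec$samples$t < 0.5, ]
  ctr <- geo$image_size_px / 2
  d <- sqrt((s$x - ctr[1])^2 + (s$y - ctr[2])^2) / geo$pixels_per_degree
  expect_lt(median(d), 1)  # within a degree of centre (jitter aside)
})

test_that("smaller tau (higher fidelity) increases truth-map AUC monotonically", {
  geo <- small_geometry()
  imgs <- generate_images(6, seed = 87, geometry = geo, render_pixels = FALSE)
  taus <- c(0.5, 1, 2, 6)
  aucs <- sapply(taus, function(tv) {
    spec <- small_cohort_spec(geo, tau = tv)
    recs <- lapply(1:6, function(i) {
      simulate_recording(imgs$maps[[i]], spec$groups$SC, spec, seed = 200 + i,
                         image_id = names(imgs$maps)[i],
                         trial_index = i)$recording
    })
    auc_per_participant(imgs$maps, recs, seed = 1)$auc
  })
  expect_equal(cor(aucs, taus, method = "spearman"), -1, tolerance = 1e-9)
})

test_that("near-deterministic targeting dwells at the map mode", {
  geo <- small_geometry()
  imgs <- generate_images(1, seed = 88, geometry = geo, render_pixels = FALSE)
  spec <- small_cohort_spec(geo, tau = 0.02, central_start_ms = 0)
  prof <- group_profile(1, "fixation_saccade", jitter_sd_deg = 0.05)
  rec <- simulate_recording(imgs$maps[[1]], prof, spec, seed = 9)$recording
  mode_idx <- which(imgs$maps[[1]]$values == max(imgs$maps[[1]]$values),
                    arr.ind = TRUE)
  s <- rec$samples[rec$samples$valid, ]
  d <- sqrt((s$x - (mode_idx[1, "col"] - 1))^2 +
              (s$y - (mode_idx[1, "row"] - 1))^2) / geo$pixels_per_degree
  # dwell samples concentrate at the mode (transitions excepted)
  expect_lt(median(d), 1)
})

test_that("group kinematic profiles order median velocities as designed", {
  geo <- small_geometry()
  imgs <- generate_images(3, seed = 89, geometry = geo, render_pixels = FALSE)
  spec <- small_cohort_spec(geo)
  med <- sapply(c("SC", "CC", "NC"), function(g) {
    median(sapply(1:3, function(i) {
      rec <- simulate_recording(imgs$maps[[i]], spec$groups[[g]], spec,
                                seed = 300 + i, group = g)$recording
      tr <- instantaneous_velocity(rec)
      median(tr$magnitude[tr$defined])
    }))
  })
  expect_lt(med[["SC"]], med[["CC"]])
  expect_lt(med[["CC"]], med[["NC"]])
})

test_that("sessions have the 7/7/14 pair mix and full determinism", {
  geo <- small_geometry()
  imgs <- generate_images(49, seed = 777, geometry = geo,
                          render_pixels = FALSE)
  spec <- small_cohort_spec(geo, n_per_group = 1)
  s1 <- simulate_session(spec, imgs, seed = 90)
  s2 <- simulate_session(spec, imgs, seed = 90)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$recordings[[17]]$samples, s2$recordings[[17]]$samples)
  per_part <- table(s1$trials$participant_id, s1$trials$pair_type)
  expect_true(all(per_part[, "same_image"] == 7))
  expect_true(all(per_part[, "same_category"] == 7))
  expect_true(all(per_part[, "different_category"] == 14))
  # same-category pairs share a category, different-category pairs do not
  cats <- vapply(imgs$stimuli, function(s) s$category, character(1))
  tr <- s1$trials
  sc <- tr[tr$pair_type == "same_category", ]
  expect_true(all(cats[sc$first_image_id] == cats[sc$second_image_id]))
  dc <- tr[tr$pair_type == "different_category", ]
  expect_true(all(cats[dc$first_image_id] != cats[dc$second_image_id]))
  # two blocks of 14 trials
  expect_true(all(table(tr$block, tr$participant_id) == 14))
  # recognition outcomes present and binary
  expect_true(all(tr$named_first_correct %in% 0:1))
  # written dataset files are byte-identical across reruns
  d1 <- withr::local_tempfile(fileext = ".tsv")
  d2 <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_dataset(s1$recordings, d1)
  write_gaze_dataset(s2$recordings, d2)
  expect_identical(readLines(d1), readLines(d2))
})

test_that("insufficient images abort the session design", {
  geo <- small_geometry()
  imgs <- generate_images(10, seed = 91, geometry = geo,
                          render_pixels = FALSE)
  expect_error(simulate_session(small_cohort_spec(geo), imgs, seed = 1),
               "49 images")
})
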