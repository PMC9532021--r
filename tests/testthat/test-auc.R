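test_that("U-formula AUC equals brute-force pair counting with ties", {
  set.seed(51)
  for (i in 1:200) {
    n_g <- sample(1:60, 1); n_n <- sample(1:60, 1)
    # coarse integer values guarantee plenty of ties
    g <- sample(0:8, n_g, replace = TRUE)
    n <- sample(0:8, n_n, replace = TRUE)
    res <- auc_from_values(g, n)
    expect_equal(res$auc, auc_bruteforce(g, n), tolerance = 1e-12)
    expect_equal(res$auc, res$U / (n_g * n_n), tolerance = 1e-14)
  }
})

test_that("definitional endpoints: perfect separation 1, identical sets 0.5", {
  expect_identical(auc_from_values(c(3, 4, 5), c(1, 2))$auc, 1)
  expect_identical(auc_from_values(c(1, 2), c(3, 4, 5))$auc, 0)
  expect_identical(auc_from_values(c(2, 4), c(1, 3))$auc, 0.75)
  v <- c(0.1, 0.4, 0.4, 2)
  expect_identical(auc_from_values(v, v)$auc, 0.5)
  expect_identical(auc_from_values(rep(1, 5), rep(1, 9))$auc, 0.5)
})

test_that("AUC is invariant under strictly monotone transforms of map values", {
  set.seed(52)
  g <- rexp(40); n <- rexp(55)
  base <- auc_from_values(g, n)$auc
  for (f in list(function(x) 2 * x + 1, sqrt, function(x) x^3,
                 function(x) exp(x / 2))) {
    expect_equal(auc_from_values(f(g), f(n))$auc, base, tolerance = 1e-12)
  }
})

test_that("null AUC over replicates matches the U-statistic mean and variance", {
  set.seed(53)
  n_g <- 30; n_n <- 30
  aucs <- replicate(3000, {
    auc_from_values(rnorm(n_g), rnorm(n_n))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
  var_theory <- (n_g + n_n + 1) / (12 * n_g * n_n)
  expect_lt(abs(var(aucs) - var_theory) / var_theory, 0.10)
})

test_that("gazed sampling reads the map at valid samples only", {
  geo <- small_geometry()
  m <- bump_map(98, 98, 15, geo)
  rec <- make_recording(c(98, 98, -5, 20), c(98, 98, 98, 30), geometry = geo)
  v <- sample_gazed_values(m, rec)
  expect_length(v, 3)                      # invalid sample dropped
  expect_equal(v[1], max(m$values), tolerance = 1e-6)
  u <- uniform_map(geo)
  vu <- sample_gazed_values(u, rec)
  expect_true(all(vu == 1 / (196 * 196)))
})

test_that("nongazed draws are seed-reproducible and unique when possible", {
  geo <- small_geometry()
  set.seed(54)
  # map with almost-surely distinct pixel values, pool at distinct pixels,
  # so distinct drawn locations give distinct values
  m <- freegaze:::new_predictor_map(matrix(runif(196 * 196), 196, 196), geo,
                                    "external")
  other <- make_recording(sample(0:195, 100, replace = FALSE) + 0.5,
                          sample(0:195, 100, replace = TRUE) + 0.5,
                          geometry = geo, image_id = "other")
  v1 <- sample_nongazed_values(m, list(other), 50, seed = 7)
  v2 <- sample_nongazed_values(m, list(other), 50, seed = 7)
  v3 <- sample_nongazed_values(m, list(other), 50, seed = 8)
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
  expect_false(attr(v1, "with_replacement"))
  # pool of 100 distinct locations, 50 draws -> 50 distinct values a.s.
  expect_identical(length(unique(v1)), 50L)
  # larger request than pool -> replacement, flagged
  v4 <- sample_nongazed_values(m, list(other), 150, seed = 7)
  expect_true(attr(v4, "with_replacement"))
  expect_length(v4, 150)
  # single-pixel pool: every value is the map at that pixel
  one <- make_recording(rep(30, 2000), rep(40, 2000), geometry = geo,
                        image_id = "other")
  v5 <- sample_nongazed_values(m, list(one), 10, seed = 9)
  expect_true(all(v5 == m$values[41, 31]))
  none <- make_recording(rep(-5, 10), 10, geometry = geo, image_id = "other")
  expect_error(sample_nongazed_values(m, list(none), 5, seed = 1), "empty")
})

test_that("uniform map gives AUC exactly 0.5 under any pooling", {
  geo <- small_geometry()
  u <- uniform_map(geo)
  set.seed(55)
  recs <- lapply(1:3, function(i) {
    make_recording_4s(runif(200, 0, 195), runif(200, 0, 195), geometry = geo,
                      image_id = paste0("img", i), trial_index = i)
  })
  maps <- stats::setNames(list(u, u, u), paste0("img", 1:3))
  a <- auc_per_participant(maps, recs, seed = 1)
  expect_identical(a$auc, 0.5)
  ai <- auc_per_image(maps, recs, seed = 1)
  expect_true(all(ai$auc == 0.5))
})

test_that("single-participant per-image AUC equals their per-participant pooling axes", {
  geo <- small_geometry()
  set.seed(56)
  imgs <- generate_images(4, seed = 56, geometry = geo, render_pixels = FALSE)
  spec <- small_cohort_spec(geo)
  recs <- lapply(seq_along(imgs$maps), function(i) {
    simulate_recording(imgs$maps[[i]], spec$groups$SC, spec, seed = 60 + i,
                       image_id = names(imgs$maps)[i],
                       trial_index = i)$recording
  })
  per_img <- auc_per_image(imgs$maps, recs, seed = 3)
  expect_identical(nrow(per_img), 4L)
  expect_true(all(per_img$n_gazed == per_img$n_nongazed))
})

test_that("shuffling two images swaps their maps; identical maps change nothing", {
  geo <- small_geometry()
  mA <- bump_map(50, 50, 12, geo)
  mB <- bump_map(150, 150, 12, geo)
  set.seed(57)
  # participant gazes at each image's own bump
  rA <- make_recording_4s(rnorm(2000, 50, 6), rnorm(2000, 50, 6),
                          geometry = geo, image_id = "A")
  rB <- make_recording_4s(rnorm(2000, 150, 6), rnorm(2000, 150, 6),
                          geometry = geo, image_id = "B", trial_index = 2L)
  maps <- list(A = mA, B = mB)
  act <- auc_per_participant(maps, list(rA, rB), seed = 5)
  shuf <- shuffled_control(maps, list(rA, rB), seed = 5)
  expect_gt(act$auc, 0.9)
  expect_lt(shuf$auc, 0.1)  # with 2 images the derangement must swap
  # identical maps for all images: shuffling is a no-op
  maps_id <- list(A = mA, B = mA)
  act2 <- auc_per_participant(maps_id, list(rA, rB), seed = 5)
  shuf2 <- shuffled_control(maps_id, list(rA, rB), seed = 5)
  expect_identical(act2$auc, shuf2$auc)
  expect_error(shuffled_control(list(A = mA), list(rA), seed = 1),
               "at least 2|< 2 distinct")
})

test_that("participants with a single distinct image are skipped with a warning", {
  geo <- small_geometry()
  m <- bump_map(98, 98, 15, geo)
  rec <- make_recording_4s(98, 98, geometry = geo, image_id = "A")
  expect_warning(out <- auc_per_participant(list(A = m), list(rec), seed = 1),
                 "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("time bins tile the trial and conserve gazed sample counts", {
  geo <- small_geometry()
  set.seed(58)
  imgs <- generate_images(3, seed = 58, geometry = geo, render_pixels = FALSE)
  spec <- small_cohort_spec(geo)
  recs <- lapply(1:3, function(i) {
    simulate_recording(imgs$maps[[i]], spec$groups$SC, spec, seed = 70 + i,
                       image_id = names(imgs$maps)[i],
                       trial_index = i)$recording
  })
  whole <- auc_per_participant(imgs$maps, recs, seed = 4)
  binned <- time_binned_auc(imgs$maps, recs, seed = 4)
  expect_identical(sum(binned$n_gazed), whole$n_gazed)
  expect_identical(sort(unique(binned$interval)), 1:8)
})

test_that("velocity-binned AUC decreases with quantile for map-driven nystagmus", {
  geo <- small_geometry()
  imgs <- generate_images(6, seed = 59, geometry = geo, render_pixels = FALSE)
  spec <- small_cohort_spec(geo)
  recs <- lapply(1:6, function(i) {
    simulate_recording(imgs$maps[[i]], spec$groups$NC, spec, seed = 80 + i,
                       group = "NC", participant_id = "n1",
                       image_id = names(imgs$maps)[i],
                       trial_index = i)$recording
  })
  vb <- velocity_binned_auc(imgs$maps, recs, seed = 6)
  expect_identical(nrow(vb), 10L)
  expect_lt(cor(vb$quantile, vb$auc, method = "spearman"), 0)
  # quantile gazed counts are near-equal before validity masking
  expect_lt(max(vb$n_gazed) - min(vb$n_gazed), max(vb$n_gazed) * 0.2)
})
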