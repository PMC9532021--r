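test_that("four groups yield exactly six contrasts at alpha 0.05/6", {
  set.seed(61)
  values <- rnorm(40)
  groups <- rep(c("CC", "SC", "DC", "NC"), each = 10)
  out <- robust_group_contrasts(values, groups)
  expect_identical(nrow(out), 6L)
  expect_true(all(out$corrected_alpha == 0.05 / 6))
  expect_setequal(
    out$contrast,
    c("DC - CC", "NC - CC", "SC - CC", "NC - DC", "SC - DC", "SC - NC")
  )
  expect_error(robust_group_contrasts(c(1, 2, 3), c("a", "a", "b")),
               ">= 2 participants")
})

test_that("robust fit matches OLS on uncontaminated data and resists an outlier", {
  # symmetric within-group residuals: bisquare weights are even in the
  # residual, so the weighted and unweighted group means coincide exactly
  resid <- rep(c(-0.5, -0.2, 0, 0, 0.2, 0.5), 2)
  values <- c(0 + resid, 2 + resid)
  groups <- rep(c("g1", "g2"), each = 12)
  rob <- robust_group_contrasts(values, groups)
  ols <- coef(lm(values ~ factor(groups)))[2]
  expect_equal(rob$estimate, unname(ols), tolerance = 1e-6)
  # a gross outlier barely moves the robust estimate
  values2 <- values; values2[1] <- 50
  rob2 <- robust_group_contrasts(values2, groups)
  expect_lt(abs(rob2$estimate - rob$estimate), 0.15)
  ols2 <- coef(lm(values2 ~ factor(groups)))[2]
  expect_gt(abs(ols2 - ols), 1.5)
})

test_that("a 5-SD group offset is detected in at least 19 of 20 seeds", {
  hits <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    sd0 <- 0.4
    values <- c(rnorm(8, 0, sd0), rnorm(8, 0, sd0),
                rnorm(8, 0, sd0), rnorm(8, 5 * sd0, sd0))
    groups <- rep(c("CC", "SC", "DC", "NC"), each = 8)
    out <- robust_group_contrasts(values, groups)
    nc_rows <- out[grepl("NC", out$contrast), ]
    if (all(nc_rows$significant)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("identical groups are not declared different at the corrected level", {
  ok <- 0
  for (s in 1:20) {
    set.seed(2000 + s)
    values <- rnorm(32)
    groups <- rep(c("CC", "SC", "DC", "NC"), each = 8)
    out <- robust_group_contrasts(values, groups)
    if (!any(out$significant)) ok <- ok + 1
  }
  expect_gte(ok, 18)  # >= 90% of seeds
})

test_that("mixed model recovers per-group slopes {0, -0.02} with Satterthwaite df", {
  sign_ok <- 0
  for (s in 1:20) {
    frame <- make_interaction_frame(3000 + s)
    fit <- mixed_model(frame, "y ~ group * interval")
    co <- fit$coefficients
    inter <- co[co$term == "groupg2:interval", ]
    if (nrow(inter) == 1 && inter$estimate < 0 && inter$p_value < 0.05) {
      sign_ok <- sign_ok + 1
    }
    expect_true(all(co$df > 0))
  }
  expect_gte(sign_ok, 19)
  # the reported estimate is near the planted slope difference
  fit <- mixed_model(make_interaction_frame(123), "y ~ group * interval")
  est <- unname(fit$coefficients$estimate[fit$coefficients$term ==
                                            "groupg2:interval"])
  expect_equal(est, -0.02, tolerance = 0.5)
  expect_identical(fit$df_method, "satterthwaite")
})

test_that("a zero covariate effect is covered by its CI in >= 90% of seeds", {
  cover <- 0
  for (s in 1:20) {
    frame <- make_interaction_frame(4000 + s, slopes = c(g1 = 0, g2 = 0))
    fit <- mixed_model(frame, "y ~ group * interval")
    co <- fit$coefficients
    row <- co[co$term == "groupg2:interval", ]
    ci <- row$estimate + c(-1, 1) * qt(0.975, row$df) * row$se
    if (ci[1] <= 0 && 0 <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 18)
})

test_that("a singular random-effect fit is flagged with an lm fallback", {
  # one row per participant: the random intercept is unidentifiable
  frame <- data.frame(participant_id = paste0("p", 1:12),
                      y = rnorm(12), x = rnorm(12))
  frame <- rbind(frame, frame)  # 2 rows per participant but zero participant
  frame$y <- rnorm(24)          # variance -> singular fit with high probability
  set.seed(65)
  fit <- mixed_model(frame, "y ~ x")
  if (fit$singular) {
    expect_identical(fit$df_method, "residual (singular fallback)")
    expect_identical(fit$random_intercept_var, 0)
  } else {
    succeed("fit happened to be non-singular for this draw")
  }
})

test_that("location tests handle one-sample, paired and degenerate input", {
  out <- location_tests(rep(0.5, 10), 0.5)
  expect_true(out$all_equal)
  expect_true(is.na(out$statistic))
  set.seed(66)
  hits <- sum(sapply(1:20, function(s) {
    set.seed(600 + s)
    location_tests(rnorm(10, 0.55, 0.02), 0.5)$p_value < 0.05
  }))
  expect_gte(hits, 19)
  x <- rnorm(8)
  paired <- location_tests(x, x)
  expect_true(paired$all_equal)
  expect_identical(paired$mean_diff, 0)
  expect_error(location_tests(c(1, 2), 0.5))
})

test_that("correlation tests: perfect correlation, null, and z comparison", {
  x <- 1:10
  out <- correlation_tests(x, x * 2 + 3)
  expect_equal(out$r, 1, tolerance = 1e-12)
  null_ok <- sum(sapply(1:20, function(s) {
    set.seed(700 + s)
    abs(correlation_tests(rnorm(49), rnorm(49))$r) < 0.4
  }))
  expect_gte(null_ok, 18)
  z_ok <- sum(sapply(1:20, function(s) {
    set.seed(800 + s)
    a <- rnorm(40); b <- a + rnorm(40)
    c2 <- rnorm(40); d <- c2 + rnorm(40)
    correlation_tests(a, b, c2, d)$z_p_value > 0.05
  }))
  expect_gte(z_ok, 18)
  expect_error(correlation_tests(rep(1, 10), rnorm(10)), "constant")
})

test_that("recognition model comparison prefers the true two-predictor model", {
  gen <- function(seed) {
    set.seed(seed)
    n_part <- 15; n_img <- 40
    acuity <- runif(n_part, 0, 1.4)
    auc <- runif(n_part, 0.5, 0.9)
    p <- plogis(-2 - 3 * rep(acuity, each = n_img) + 6 * rep(auc, each = n_img))
    list(correct = rbinom(n_part * n_img, 1, p),
         acuity = rep(acuity, each = n_img), auc = rep(auc, each = n_img))
  }
  wins <- 0
  for (s in 1:20) {
    d <- gen(900 + s)
    out <- recognition_model(d$correct, d$acuity, d$auc)
    if (out$model[which.min(out$aic)] == "both") wins <- wins + 1
    expect_true(all(out$tjur_r2 >= -1 & out$tjur_r2 <= 1, na.rm = TRUE))
  }
  expect_gte(wins, 16)
})

test_that("a null AUC effect is not detected in >= 90% of seeds", {
  cover <- 0
  for (s in 1:20) {
    set.seed(1100 + s)
    n_part <- 15; n_img <- 40
    acuity <- runif(n_part, 0, 1.4)
    auc <- runif(n_part, 0.5, 0.9)
    p <- plogis(0.5 - 2 * rep(acuity, each = n_img))  # b = 0
    correct <- rbinom(n_part * n_img, 1, p)
    out <- recognition_model(correct, rep(acuity, each = n_img),
                             rep(auc, each = n_img))
    co <- out$coefficients[[which(out$model == "both")]]
    row <- co[co$term == "auc", ]
    ci <- row$estimate + c(-1, 1) * 1.96 * row$se
    if (ci[1] <= 0 && 0 <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 18)
})

test_that("complete separation is flagged and a penalised fit reported", {
  correct <- c(rep(0, 20), rep(1, 20))
  acuity <- c(rep(1.2, 20), rep(0.1, 20))
  auc <- runif(40, 0.5, 0.9)
  out <- recognition_model(correct, acuity, auc)
  expect_true(out$separation[out$model == "acuity"])
  co <- out$coefficients[[which(out$model == "acuity")]]
  expect_true(all(is.finite(co$estimate)))
  # all outcomes identical: every model flagged, nothing fitted
  out2 <- recognition_model(rep(1, 40), acuity, auc)
  expect_true(all(out2$separation))
})
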