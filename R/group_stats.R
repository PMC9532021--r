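# Group-level statistical models: robust pairwise group contrasts, linear
# mixed models with Satterthwaite degrees of freedom, location and correlation
# tests, and the binomial recognition model.

#' Robust pairwise group contrasts
#'
#' Fits a robust linear model of a per-participant statistic on the group
#' factor by iteratively reweighted least squares with Tukey's bisquare weight
#' function (tuning constant 4.685, 95% Gaussian efficiency) and tests every
#' pairwise group contrast at a Bonferroni-corrected level
#' `alpha / choose(k, 2)` (0.05/6 for four groups).
#'
#' @param values numeric per-participant statistic.
#' @param groups group labels (same length).
#' @param alpha family-wise significance level.
#' @return Tibble, one row per pair: `contrast`, `estimate`, `se`,
#'   `statistic`, `df`, `p_value`, `corrected_alpha`, `significant`.
#' @export
robust_group_contrasts <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("every group needs >= 2 participants; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- MASS::rlm(values ~ groups, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 100)
  lev <- levels(groups)
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  corrected <- alpha / n_pairs
  V <- stats::vcov(fit)
  beta <- stats::coef(fit)
  df <- length(values) - k
  rows <- lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    # model is intercept + indicator coding: mean(g1) = b0 (+ b_g1 if g1 != ref)
    L <- numeric(k)
    if (i1 > 1) L[i1] <- -1
    if (i2 > 1) L[i2] <- 1
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    stat <- est / se
    p <- 2 * stats::pt(-abs(stat), df)
    tibble::tibble(contrast = paste(lev[i2], "-", lev[i1]),
                   estimate = est, se = se, statistic = stat, df = df,
                   p_value = p, corrected_alpha = corrected,
                   significant = p < corrected)
  })
  dplyr::bind_rows(rows)
}

#' Linear mixed model with a participant random intercept
#'
#' Fits the given fixed-effect formula plus `(1 | random_intercept)` by REML
#' and reports fixed-effect estimates with Satterthwaite-approximated
#' denominator degrees of freedom. A singular random-effect fit is flagged and
#' a fixed-effects-only least-squares fallback is reported instead (with
#' residual df).
#'
#' @param frame long-format data frame.
#' @param fixed fixed-effects formula as a string, e.g.
#'   `"auc ~ group * interval"`.
#' @param random_intercept grouping column name (default `"participant_id"`).
#' @return List of class `mixed_model_result`: `coefficients` (tibble:
#'   `term`, `estimate`, `se`, `df`, `statistic`, `p_value`),
#'   `random_intercept_var`, `residual_var`, `singular`, `df_method`,
#'   `formula`, and the fitted object.
#' @export
mixed_model <- function(frame, fixed, random_intercept = "participant_id") {
  stopifnot(is.character(fixed), random_intercept %in% names(frame))
  counts <- table(frame[[random_intercept]])
  if (all(counts < 2)) stop("need >= 2 rows for at least one grouping unit")
  full <- stats::as.formula(paste0(fixed, " + (1 | ", random_intercept, ")"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(full, data = frame, REML = TRUE)
  ))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (!singular) {
    sm <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"], df = sm[, "df"],
      statistic = sm[, "t value"], p_value = sm[, "Pr(>|t|)"]
    )
    res <- list(coefficients = coefs,
                random_intercept_var = as.numeric(vc[[random_intercept]]),
                residual_var = attr(vc, "sc")^2,
                singular = FALSE, df_method = "satterthwaite",
                formula = fixed, fit = fit)
  } else {
    lmfit <- stats::lm(stats::as.formula(fixed), data = frame)
    sm <- summary(lmfit)$coefficients
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"], df = lmfit$df.residual,
      statistic = sm[, "t value"], p_value = sm[, "Pr(>|t|)"]
    )
    res <- list(coefficients = coefs, random_intercept_var = 0,
                residual_var = summary(lmfit)$sigma^2,
                singular = TRUE, df_method = "residual (singular fallback)",
                formula = fixed, fit = lmfit)
  }
  class(res) <- "mixed_model_result"
  res
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> %s  [df: %s%s]\n", x$formula, x$df_method,
              if (x$singular) ", SINGULAR random effect" else ""))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' One-sample and paired location tests
#'
#' One-sample t test of `values` against a scalar `reference` (e.g. the 0.5
#' chance AUC), or a paired t test when `reference` is a vector of partners.
#' Zero-variance input returns an exact-equality report without a test
#' statistic.
#'
#' @param values numeric vector, `n >= 3`.
#' @param reference scalar null value or paired partner vector.
#' @return Tibble: `type`, `mean_diff`, `statistic`, `df`, `p_value`,
#'   `all_equal`.
#' @export
location_tests <- function(values, reference = 0.5) {
  stopifnot(length(values) >= 3)
  if (length(reference) == 1) {
    d <- values - reference
    type <- "one_sample"
  } else {
    stopifnot(length(reference) == length(values))
    d <- values - reference
    type <- "paired"
  }
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    return(tibble::tibble(type = type, mean_diff = mean(d),
                          statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_,
                          all_equal = TRUE))
  }
  tt <- stats::t.test(d)
  tibble::tibble(type = type, mean_diff = mean(d),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, all_equal = FALSE)
}

#' Correlation test and two-correlation comparison
#'
#' Pearson product-moment correlation with its test, and (when a second pair
#' of vectors is supplied) a comparison of the two correlations via the
#' variance-stabilising z transform with the independent-sample standard error
#' `sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param x,y numeric vectors (`n >= 4`).
#' @param x2,y2 optional second sample for the r1-vs-r2 comparison.
#' @return List with `r`, `p_value`, `n` and, if compared, `r2`, `n2`,
#'   `z_stat`, `z_p_value`.
#' @export
correlation_tests <- function(x, y, x2 = NULL, y2 = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
  if (!is.null(x2)) {
    stopifnot(length(x2) == length(y2), length(x2) >= 4)
    if (stats::sd(x2) == 0 || stats::sd(y2) == 0) {
      stop("undefined correlation: constant input")
    }
    r2 <- stats::cor(x2, y2)
    z1 <- atanh(out$r); z2 <- atanh(r2)
    se <- sqrt(1 / (out$n - 3) + 1 / (length(x2) - 3))
    z <- (z1 - z2) / se
    out$r2 <- r2
    out$n2 <- length(x2)
    out$z_stat <- z
    out$z_p_value <- 2 * stats::pnorm(-abs(z))
  }
  out
}

# internal: Tjur's coefficient of discrimination
tjur_r2 <- function(y, fitted) {
  mean(fitted[y == 1]) - mean(fitted[y == 0])
}

#' Binomial recognition models (acuity, AUC, both)
#'
#' Fits three logistic regressions of per-image naming correctness on the
#' participant-level predictors — visual acuity (logMAR) alone, AUC alone, and
#' both — and reports coefficients, AIC and Tjur's discrimination index for
#' model comparison. Complete or quasi-complete separation is flagged and a
#' ridge-penalised fit is reported for the affected model.
#'
#' @param correct 0/1 outcomes, one per image presentation.
#' @param acuity logMAR per presentation (participant-level, repeated).
#' @param auc AUC per presentation (participant-level, repeated).
#' @return Tibble, one row per model: `model`, `aic`, `tjur_r2`, `separation`,
#'   plus a `coefficients` list-column of per-term tibbles.
#' @export
recognition_model <- function(correct, acuity, auc) {
  stopifnot(length(correct) == length(acuity),
            length(correct) == length(auc),
            all(correct %in% c(0, 1)))
  if (length(unique(correct)) < 2) {
    return(tibble::tibble(model = c("acuity", "auc", "both"),
                          aic = NA_real_, tjur_r2 = NA_real_,
                          separation = TRUE,
                          coefficients = list(NULL, NULL, NULL)))
  }
  dat <- data.frame(correct = correct, acuity = acuity, auc = auc)
  specs <- list(acuity = correct ~ acuity, auc = correct ~ auc,
                both = correct ~ acuity + auc)
  rows <- lapply(names(specs), function(nm) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(specs[[nm]], family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    if (sep || any(abs(stats::coef(fit)) > 15)) {
      sep <- TRUE
      fit <- ridge_logistic(specs[[nm]], dat)
    }
    sm <- summary(fit)$coefficients
    coefs <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                            se = sm[, 2], p_value = sm[, 4])
    tibble::tibble(model = nm,
                   aic = stats::AIC(fit),
                   tjur_r2 = tjur_r2(dat$correct, stats::fitted(fit)),
                   separation = sep,
                   coefficients = list(coefs))
  })
  dplyr::bind_rows(rows)
}

# internal: weak L2-penalised logistic fit for separated data, reported as a
# glm-like object (penalty 1e-2 on non-intercept coefficients)
ridge_logistic <- function(formula, data, lambda = 1e-2) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data)
  pen <- rep(lambda, ncol(X)); pen[1] <- 0
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + sum(pen * b^2) / 2
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))
  fitted <- stats::plogis(drop(X %*% opt$par))
  sm <- cbind(opt$par, se, opt$par / se, 2 * stats::pnorm(-abs(opt$par / se)))
  rownames(sm) <- colnames(X)
  structure(
    list(par = opt$par, fitted.values = fitted, y = y,
         aic = 2 * (opt$value - sum(pen * opt$par^2) / 2) + 2 * ncol(X),
         summary_matrix = sm),
    class = "ridge_logistic"
  )
}

#' @export
summary.ridge_logistic <- function(object, ...) {
  list(coefficients = object$summary_matrix)
}

#' @export
fitted.ridge_logistic <- function(object, ...) object$fitted.values

#' @importFrom stats AIC
#' @export
AIC.ridge_logistic <- function(object, ...) object$aic
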