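# small labeled table with one driving feature (A) and two inert ones
abc_table <- function(n = 800, seed = 1, beta = 1.5) {
  set.seed(seed)
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  tibble::tibble(
    A = a, B = b, C = c_,
    sex = sample(c("male", "female"), n, TRUE),
    caller_id = paste0("g", rep(1:20, length.out = n)),
    distress_label = factor(ifelse(rbinom(n, 1, plogis(beta * a)) == 1,
                                   "high", "low"),
                            levels = c("low", "high")))
}

test_that("base learners hit their effective-df targets", {
  tab <- abc_table(400)
  lrn <- boost_learners(tab, c("A", "B"), df = 4)
  for (l in lrn) {
    if (l$lambda == 0) next
    A <- crossprod(l$X)
    M <- A + l$lambda * l$S + diag(1e-7 * mean(diag(A)), ncol(A))
    edf <- sum(diag(solve(M, A)))
    expect_equal(edf, l$df_target, tolerance = 0.1)
  }
  kinds <- vapply(lrn, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "pspline"), 2)
  expect_equal(sum(kinds == "pspline_by_sex"), 2)
  expect_equal(sum(kinds == "ridge_caller"), 1)
})

test_that("an mstop = 0 model predicts the prevalence everywhere", {
  tab <- abc_table(300, seed = 2)
  fit <- fit_boost(tab, features = c("A", "B"), mstop = 0)
  pr <- predict(fit, tab)
  expect_true(all(abs(pr - mean(tab$distress_label == "high")) < 1e-12))
  expect_warning(vi <- variable_importance(fit), "importance")
  expect_equal(nrow(vi), 0)
})

test_that("boosting with unpenalized linear learners matches IRLS", {
  set.seed(5)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 1.3 * x))
  tab <- tibble::tibble(label = y, x = x, sex = "female", caller_id = "A")
  lrn <- list(
    structure(list(name = "intercept", kind = "intercept",
                   X = matrix(1, n, 1), S = matrix(0, 1, 1), lambda = 0,
                   df_target = 1), class = "base_learner"),
    structure(list(name = "x", kind = "linear", feature = "x",
                   X = matrix(x, ncol = 1), S = matrix(0, 1, 1),
                   lambda = 0, df_target = 1, center = 0, scale = 1),
              class = "base_learner"))
  fit <- fit_boost(tab, learners = lrn, nu = 1, mstop = 2000)
  oracle <- stats::glm(y ~ x, family = stats::binomial())
  expect_lt(abs(fit$offset + fit$coef[[1]][1] -
                  coef(oracle)[1]), 1e-4)
  expect_lt(abs(fit$coef[[2]][1] - coef(oracle)[2]), 1e-4)
})

test_that("training risk never increases along the path", {
  fit <- fit_boost(abc_table(600, seed = 3), features = c("A", "B", "C"),
                   mstop = 250)
  expect_true(all(diff(fit$risk_path) <= 1e-12))
})

test_that("a lone informative feature dominates selection and importance", {
  tab <- abc_table(1200, seed = 4, beta = 2)
  fit <- fit_boost(tab, learners = boost_learners(tab, c("A", "B", "C"),
                                                  caller = FALSE),
                   mstop = 200)
  nm <- fit$learner_names[fit$selection_path]
  a_frac <- mean(grepl("s\\(A\\)", nm) | nm == "intercept")
  expect_gte(a_frac, 0.9)
  vi <- variable_importance(fit)
  expect_equal(sum(vi$fraction), 1, tolerance = 1e-12)
  expect_gt(sum(vi$fraction[grepl("A", vi$learner)]), 0.8)
})

test_that("halving nu and doubling mstop barely changes training risk", {
  tab <- abc_table(600, seed = 6)
  r1 <- fit_boost(tab, features = c("A", "B"), nu = 0.1, mstop = 200)
  r2 <- fit_boost(tab, features = c("A", "B"), nu = 0.05, mstop = 400)
  f1 <- r1$risk_path[length(r1$risk_path)]
  f2 <- r2$risk_path[length(r2$risk_path)]
  expect_lt(abs(f1 - f2) / f1, 0.01)
})

test_that("grouped cross-validation picks a sane stopping iteration", {
  # single-value grid short-circuits
  tab <- abc_table(500, seed = 7)
  expect_equal(select_mstop(tab, c("A", "B"), folds = 5,
                            mstop_grid = 80)$mstop, 80)

  # pure-noise labels: minimal boosting wins
  set.seed(8)
  noise <- dplyr::mutate(tab, distress_label = factor(
    sample(c("low", "high"), nrow(tab), TRUE), levels = c("low", "high")))
  mn <- select_mstop(noise, c("A", "B"), folds = 5,
                     mstop_grid = seq(20, 200, by = 20))
  expect_lte(mn$mstop, 40)

  # strong signal: out-of-fold risk falls then flattens; mstop > minimum
  ms <- select_mstop(abc_table(900, seed = 9, beta = 2.5), c("A", "B"),
                     folds = 5, mstop_grid = seq(20, 300, by = 40))
  expect_gt(ms$mstop, 20)
  expect_lt(ms$cv$mean_risk[which(ms$cv$mstop == ms$mstop)],
            ms$cv$mean_risk[1])

  # more folds than callers triggers a reduction warning
  few <- dplyr::filter(tab, caller_id %in% c("g1", "g2", "g3"))
  expect_warning(select_mstop(few, c("A", "B"), folds = 10,
                              mstop_grid = c(20, 40)), "fewer callers")
})

test_that("prediction contract: unseen callers get the population level", {
  tab <- abc_table(500, seed = 10)
  fit <- fit_boost(tab, features = c("A", "B"), mstop = 150)
  new1 <- dplyr::mutate(tab[1:5, ], caller_id = "never-seen")
  p_unseen <- predict(fit, new1)
  fit0 <- fit
  j <- which(vapply(fit$learners, `[[`, character(1), "kind") ==
               "ridge_caller")
  fit0$coef[[j]][] <- 0
  expect_equal(p_unseen, predict(fit0, tab[1:5, ]), tolerance = 1e-12)

  expect_error(predict(fit, dplyr::select(tab, -A)), "missing column")
  expect_true(all(p_unseen > 0 & p_unseen < 1))
})

test_that("Youden threshold maximizes J with brute-force agreement", {
  # perfectly separated toy case
  yt <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yt$j, 1)
  expect_equal(yt$threshold, 0.8)

  # brute force over all cutpoints on random data
  set.seed(11)
  p <- runif(40); y <- rbinom(40, 1, p)
  yt2 <- youden_threshold(p, y)
  brute <- vapply(sort(unique(p)), function(t)
    mean(p[y == 1] >= t) + mean(p[y == 0] < t) - 1, numeric(1))
  expect_equal(yt2$j, max(brute), tolerance = 1e-12)

  # independent labels: J near zero at large n
  set.seed(12)
  p3 <- runif(5000); y3 <- rbinom(5000, 1, 0.4)
  expect_lt(youden_threshold(p3, y3)$j, 0.08)

  # degenerate equal probabilities
  expect_warning(yd <- youden_threshold(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)),
                 "degenerate")
  expect_equal(yd$j, 0)
  expect_equal(yd$threshold, 0.3)

  expect_error(youden_threshold(runif(5), rep(1, 5)), "classes")
})

test_that("AUROC and AUPRC match exhaustive oracles and pROC", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)

  # exhaustive concordant-pair count on small random sets, ties included
  set.seed(13)
  for (r in 1:5) {
    p <- sample(seq(0, 1, 0.25), 10, TRUE)
    y <- rbinom(10, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    brute <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                         ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
    expect_equal(auroc(p, y), brute)
  }

  # cross-check against pROC on continuous scores
  set.seed(14)
  sc <- rnorm(300); yy <- rbinom(300, 1, plogis(sc))
  expect_equal(auroc(sc, yy),
               as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE))),
               tolerance = 1e-12)

  # permutation null
  set.seed(15)
  pn <- runif(1e4); yn <- sample(rep(0:1, 5e3))
  expect_lt(abs(auroc(pn, yn) - 0.5), 0.02)

  expect_equal(auroc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
})

test_that("discrimination report: CIs ordered and contain the point", {
  set.seed(16)
  n <- 400
  p <- runif(n); y <- rbinom(n, 1, p)
  cl <- rep(paste0("c", 1:20), each = 20)
  rep_ <- discrimination(p, y, callers = cl, n_boot = 200, seed = 3)
  expect_true(rep_$auroc_ci[1] <= rep_$auroc &&
                rep_$auroc <= rep_$auroc_ci[2])
  expect_true(rep_$auprc_ci[1] <= rep_$auprc &&
                rep_$auprc <= rep_$auprc_ci[2])
  expect_equal(sum(rep_$confusion$n), n)
  # seeded: identical on rerun
  rep2 <- discrimination(p, y, callers = cl, n_boot = 200, seed = 3)
  expect_identical(rep_$auroc_ci, rep2$auroc_ci)
})

test_that("LOCO folds never train on the held-out caller", {
  set.seed(17)
  n <- 240
  x <- rnorm(n)
  tab <- tibble::tibble(
    A = x, sex = "female",
    caller_id = rep(c("p", "q"), each = n / 2),
    distress_label = factor(ifelse(rbinom(n, 1, plogis(1.5 * x)) == 1,
                                   "high", "low"), levels = c("low", "high")))
  lc <- loco_cv(tab, "A", mstop = 60)
  expect_false(anyNA(lc$prob))
  expect_equal(lc$label, as.numeric(tab$distress_label == "high"))

  # fold contract: q's probabilities equal a manual fit on p only,
  # re-anchored at the pooled prevalence
  fit_p <- fit_boost(tab[tab$caller_id == "p", ], features = "A",
                     mstop = 60)
  eta <- predict(fit_p, tab[tab$caller_id == "q", ], type = "link")
  manual <- plogis(qlogis(mean(lc$label)) + (eta - fit_p$offset))
  expect_equal(lc$prob[tab$caller_id == "q"], manual, tolerance = 1e-12)
})
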