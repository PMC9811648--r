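#' Build the component-wise boosting base-learner set
#'
#' One P-spline learner and one sex-difference P-spline learner per
#' feature (the decomposition makes sex moderation selectable per
#' component), an optional ridge learner over caller intercepts, an
#' intercept learner, and one linear learner per cluster-PC column.
#' Each penalized learner's ridge weight is calibrated so its effective
#' degrees of freedom match `df` at build time.
#'
#' @param table Training frame table (`sex`, `caller_id`, features, and
#'   any `pcs` columns).
#' @param features Feature columns receiving spline learners.
#' @param pcs Names of linear (cluster principal component) columns
#'   present in `table`; missing ones are skipped.
#' @param df Target effective degrees of freedom per penalized learner.
#' @param knots B-spline basis size per spline learner.
#' @param caller Include the caller ridge learner? Default TRUE.
#' @return List of base-learner objects (class `base_learner`).
#' @export
boost_learners <- function(table, features, pcs = c("pc1", "pc2"),
                           df = 4, knots = 9, caller = TRUE) {
  n <- nrow(table)
  sex <- as.character(table$sex)
  learners <- list()
  add <- function(l) learners[[length(learners) + 1L]] <<- l

  add(structure(list(name = "intercept", kind = "intercept",
                     X = matrix(1, n, 1), S = matrix(0, 1, 1),
                     lambda = 0, df_target = 1), class = "base_learner"))

  D2 <- function(k) crossprod(diff(diag(k), differences = 2))

  for (f in features) {
    x <- table[[f]]
    ctr <- mean(x, na.rm = TRUE); scl <- stats::sd(x, na.rm = TRUE)
    if (is.na(scl) || scl == 0) next
    z <- (x - ctr) / scl
    rng <- range(z, na.rm = TRUE) + c(-1, 1) * 1e-8
    n_int <- knots - 4L
    interior <- stats::quantile(z, probs = seq_len(n_int) / (n_int + 1),
                                na.rm = TRUE, names = FALSE)
    kv <- c(rep(rng[1], 4), interior, rep(rng[2], 4))
    B <- splines::splineDesign(kv, pmin(pmax(z, rng[1]), rng[2]), ord = 4)
    cm <- colMeans(B)
    B <- sweep(B, 2, cm)
    S <- D2(knots)

    lam <- calibrate_df(B, S, df)
    add(structure(list(name = paste0("s(", f, ")"), kind = "pspline",
                       feature = f, X = B, S = S, lambda = lam,
                       df_target = df, center = ctr, scale = scl,
                       knots_vec = kv, col_means = cm, range = rng),
                  class = "base_learner"))

    sx <- as.numeric(sex == "male") - mean(sex == "male")
    Bs <- B * sx
    lam_s <- calibrate_df(Bs, S, df)
    add(structure(list(name = paste0("s(", f, "):sex"),
                       kind = "pspline_by_sex", feature = f, X = Bs,
                       S = S, lambda = lam_s, df_target = df,
                       center = ctr, scale = scl, knots_vec = kv,
                       col_means = cm, range = rng,
                       sex_center = mean(sex == "male")),
                  class = "base_learner"))
  }

  if (caller && "caller_id" %in% names(table)) {
    callers <- sort(unique(as.character(table$caller_id)))
    Z <- matrix(0, n, length(callers))
    Z[cbind(seq_len(n), match(as.character(table$caller_id), callers))] <- 1
    dfc <- min(df, length(callers) - 1)
    lam <- calibrate_df(Z, diag(length(callers)), max(dfc, 1))
    add(structure(list(name = "caller", kind = "ridge_caller",
                       X = Z, S = diag(length(callers)), lambda = lam,
                       df_target = dfc, callers = callers),
                  class = "base_learner"))
  }

  for (pc in intersect(pcs, names(table))) {
    x <- table[[pc]]
    ctr <- mean(x); scl <- stats::sd(x)
    if (scl == 0) next
    add(structure(list(name = pc, kind = "linear", feature = pc,
                       X = matrix((x - ctr) / scl, ncol = 1),
                       S = matrix(0, 1, 1), lambda = 0, df_target = 1,
                       center = ctr, scale = scl), class = "base_learner"))
  }
  learners
}

# Ridge weight giving the requested effective df: tr((X'X+lam S)^-1 X'X).
calibrate_df <- function(X, S, df_target) {
  A <- crossprod(X)
  # the centered spline basis shares a null direction (the constant) with
  # the difference penalty; the jitter keeps the system well posed there
  df_at <- function(loglam) {
    M <- A + 10^loglam * S
    M <- M + diag(1e-9 * mean(diag(M)) + 1e-7 * mean(diag(A)), ncol(A))
    sum(diag(solve(M, A))) - df_target
  }
  lo <- -8; hi <- 12
  if (df_at(lo) < 0) return(10^lo)    # even tiny penalty under target
  if (df_at(hi) > 0) return(10^hi)
  10^stats::uniroot(df_at, c(lo, hi), tol = 1e-3)$root
}

# Precompute each learner's penalized least-squares solver.
learner_solvers <- function(learners) {
  lapply(learners, function(l) {
    M <- crossprod(l$X) + l$lambda * l$S
    M <- M + diag(1e-7 * max(mean(diag(M)), 1e-12), ncol(M))
    chol(M)
  })
}

# Evaluate a learner's design matrix on new data.
learner_design <- function(l, table) {
  n <- nrow(table)
  switch(l$kind,
    intercept = matrix(1, n, 1),
    pspline = {
      z <- (table[[l$feature]] - l$center) / l$scale
      B <- splines::splineDesign(l$knots_vec,
                                 pmin(pmax(z, l$range[1]), l$range[2]),
                                 ord = 4)
      sweep(B, 2, l$col_means)
    },
    pspline_by_sex = {
      z <- (table[[l$feature]] - l$center) / l$scale
      B <- splines::splineDesign(l$knots_vec,
                                 pmin(pmax(z, l$range[1]), l$range[2]),
                                 ord = 4)
      B <- sweep(B, 2, l$col_means)
      B * (as.numeric(as.character(table$sex) == "male") - l$sex_center)
    },
    ridge_caller = {
      Z <- matrix(0, n, length(l$callers))
      m <- match(as.character(table$caller_id), l$callers)
      ok <- !is.na(m)
      Z[cbind(which(ok), m[ok])] <- 1   # unseen callers stay all-zero
      Z
    },
    linear = matrix((table[[l$feature]] - l$center) / l$scale, ncol = 1),
    stop("unknown learner kind ", l$kind))
}

binomial_risk <- function(y, eta) {
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  -mean(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Fit a component-wise gradient boosting classifier
#'
#' Functional gradient descent on the binomial deviance: starting from the
#' log-odds of the prevalence, each iteration fits every base learner to
#' the negative gradient by penalized least squares, selects the learner
#' with the smallest residual sum of squares, and adds `nu` times its fit
#' to the additive predictor. The selection path and each learner's
#' cumulative in-sample risk reduction are recorded.
#'
#' @param table Training frame table (must contain `distress_label` or
#'   `label`, plus every column the learners need).
#' @param learners Base learners from [boost_learners()] (built from
#'   `table` if NULL, using `features`).
#' @param features Used only when `learners` is NULL.
#' @param nu Step length (default 0.1).
#' @param mstop Number of boosting iterations.
#' @param track Optional list `list(table =, y =)`: a held-out set whose
#'   risk is evaluated along the path (used by cross-validation).
#' @return A `boost_model`: learners (design matrices dropped), per-learner
#'   coefficient states, `offset`, `nu`, `mstop`, `selection_path`,
#'   `risk_path`, `risk_reduction`, and `track_risk` when tracked.
#' @export
fit_boost <- function(table, learners = NULL, features = NULL, nu = 0.1,
                      mstop = 100, track = NULL, pcs = c("pc1", "pc2")) {
  y <- gamm_labels(table)
  if (length(unique(y)) < 2) stop("both label classes must be present")
  stopifnot(mstop >= 0)
  if (is.null(learners)) {
    if (is.null(features))
      features <- intersect(distress_features(), names(table))
    learners <- boost_learners(table, features, pcs = pcs)
  }
  if (!length(learners)) stop("no base learners")
  solvers <- learner_solvers(learners)
  n <- nrow(table)

  offset <- stats::qlogis(mean(y))
  eta <- rep(offset, n)
  coef_state <- lapply(learners, function(l) rep(0, ncol(l$X)))
  path <- integer(mstop)
  risk_path <- numeric(mstop + 1)
  risk_path[1] <- binomial_risk(y, eta)
  reduction <- numeric(length(learners))

  track_design <- NULL
  track_risk <- NULL
  if (!is.null(track)) {
    track_design <- lapply(learners, learner_design, table = track$table)
    eta_t <- rep(offset, nrow(track$table))
    track_risk <- numeric(mstop + 1)
    track_risk[1] <- binomial_risk(track$y, eta_t)
  }

  for (m in seq_len(mstop)) {
    mu <- stats::plogis(eta)
    u <- y - mu                     # negative gradient of the loss
    if (!all(is.finite(u))) stop("non-finite gradient at iteration ", m)
    best_rss <- Inf; best_j <- 0L; best_c <- NULL; best_fit <- NULL
    for (j in seq_along(learners)) {
      rhs <- crossprod(learners[[j]]$X, u)
      cj <- backsolve(solvers[[j]], forwardsolve(t(solvers[[j]]), rhs))
      fitj <- drop(learners[[j]]$X %*% cj)
      rss <- sum((u - fitj)^2)
      if (rss < best_rss) {
        best_rss <- rss; best_j <- j; best_c <- cj; best_fit <- fitj
      }
    }
    eta <- eta + nu * best_fit
    coef_state[[best_j]] <- coef_state[[best_j]] + nu * drop(best_c)
    path[m] <- best_j
    risk_path[m + 1] <- binomial_risk(y, eta)
    reduction[best_j] <- reduction[best_j] +
      max(0, risk_path[m] - risk_path[m + 1])
    if (!is.null(track)) {
      eta_t <- eta_t + nu * drop(track_design[[best_j]] %*% best_c)
      track_risk[m + 1] <- binomial_risk(track$y, eta_t)
    }
  }

  light <- lapply(learners, function(l) { l$X <- NULL; l })
  structure(list(
    learners = light, coef = coef_state, offset = offset, nu = nu,
    mstop = mstop, selection_path = path, risk_path = risk_path,
    risk_reduction = reduction, track_risk = track_risk,
    learner_names = vapply(learners, `[[`, character(1), "name"),
    prevalence = mean(y)
  ), class = "boost_model")
}

#' @export
print.boost_model <- function(x, ...) {
  cat(sprintf("<boost_model> %d learners, mstop=%d, nu=%g, train risk %.4f\n",
              length(x$learners), x$mstop, x$nu,
              x$risk_path[length(x$risk_path)]))
  invisible(x)
}

#' Predict frame probabilities from a boosting model
#'
#' Inverse-logit of the offset plus every learner's contribution. Unseen
#' callers get a zero caller contribution (population level).
#'
#' @param object A `boost_model`.
#' @param table New frame table (needs the learner feature columns).
#' @param type `"response"` (probabilities) or `"link"` (additive
#'   predictor, including the offset).
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1) (or log-odds for
#'   `type = "link"`).
#' @export
predict.boost_model <- function(object, table,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  needed <- unique(unlist(lapply(object$learners, function(l)
    switch(l$kind, pspline = l$feature, linear = l$feature,
           pspline_by_sex = c(l$feature, "sex"),
           ridge_caller = "caller_id", NULL))))
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("missing column(s) in new data: ", paste(miss, collapse = ", "))
  eta <- rep(object$offset, nrow(table))
  for (j in seq_along(object$learners)) {
    if (all(object$coef[[j]] == 0)) next
    Xj <- learner_design(object$learners[[j]], table)
    eta <- eta + drop(Xj %*% object$coef[[j]])
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' Per-learner variable importance by risk reduction
#'
#' Each learner's summed in-sample risk reduction across the iterations
#' where it was selected, normalized to fractions summing to one.
#'
#' @param model A `boost_model`.
#' @return Tibble: `learner`, `kind`, `selections`, `risk_reduction`,
#'   `fraction`, sorted by decreasing fraction. Empty (with a warning) for
#'   an `mstop = 0` model.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "boost_model"))
  if (model$mstop == 0 || sum(model$risk_reduction) == 0) {
    warning("no boosting iterations: importance undefined")
    return(tibble::tibble(learner = character(0), kind = character(0),
                          selections = integer(0),
                          risk_reduction = numeric(0),
                          fraction = numeric(0)))
  }
  tibble::tibble(
    learner = model$learner_names,
    kind = vapply(model$learners, `[[`, character(1), "kind"),
    selections = vapply(seq_along(model$learners), function(j)
      sum(model$selection_path == j), integer(1)),
    risk_reduction = model$risk_reduction,
    fraction = model$risk_reduction / sum(model$risk_reduction)
  ) |> dplyr::arrange(dplyr::desc(.data$fraction))
}

#' @rdname variable_importance
#' @param x A `boost_model`.
#' @param ... Unused.
#' @method tidy boost_model
#' @export
tidy.boost_model <- function(x, ...) variable_importance(x)

#' @method glance boost_model
#' @export
glance.boost_model <- function(x, ...) {
  tibble::tibble(mstop = x$mstop, nu = x$nu,
                 train_risk = x$risk_path[length(x$risk_path)],
                 offset = x$offset, n_learners = length(x$learners))
}

#' Choose the number of boosting iterations by grouped cross-validation
#'
#' Folds are grouped by caller (no caller spans folds) and balanced on
#' label prevalence; the chosen `mstop` minimizes the mean out-of-fold
#' binomial risk over `mstop_grid`. A one-standard-error alternative is
#' also reported.
#'
#' @param table Training frame table.
#' @param features Feature columns for the learners.
#' @param folds Number of folds (default 10; reduced with a warning when
#'   there are fewer callers).
#' @param mstop_grid Candidate iteration counts (default `seq(10, 200, 10)`).
#' @param nu Step length.
#' @param pcs Linear PC columns to include.
#' @param seed Seed for fold assignment.
#' @return List: `mstop`, `mstop_1se`, `cv` (tibble mstop, mean_risk,
#'   se_risk), `folds`.
#' @export
select_mstop <- function(table, features, folds = 10,
                         mstop_grid = seq(50, 600, by = 50), nu = 0.1,
                         pcs = c("pc1", "pc2"), seed = 1) {
  stopifnot(folds >= 2)
  y <- gamm_labels(table)
  callers <- unique(as.character(table$caller_id))
  if (length(callers) < folds) {
    warning("fewer callers (", length(callers), ") than folds; reducing")
    folds <- max(2L, length(callers))
  }
  if (length(mstop_grid) == 1L)
    return(list(mstop = mstop_grid, mstop_1se = mstop_grid,
                cv = tibble::tibble(mstop = mstop_grid,
                                    mean_risk = NA_real_,
                                    se_risk = NA_real_),
                folds = folds))
  # label-balanced grouped assignment: order callers by prevalence (with a
  # seeded jitter for ties) and deal round-robin
  prev <- vapply(callers, function(cl)
    mean(y[table$caller_id == cl]), numeric(1))
  rng <- seeded_rng(seed)
  ord <- order(prev + 1e-9 * rng(length(prev)))
  fold_of <- integer(length(callers))
  fold_of[ord] <- rep_len(seq_len(folds), length(callers))
  names(fold_of) <- callers

  mmax <- max(mstop_grid)
  risk_mat <- matrix(NA_real_, nrow = folds, ncol = length(mstop_grid))
  for (f in seq_len(folds)) {
    test <- fold_of[as.character(table$caller_id)] == f
    if (length(unique(y[!test])) < 2 || !any(test)) next
    fit <- fit_boost(table[!test, , drop = FALSE], features = features,
                     nu = nu, mstop = mmax, pcs = pcs,
                     track = list(table = table[test, , drop = FALSE],
                                  y = y[test]))
    risk_mat[f, ] <- fit$track_risk[mstop_grid + 1]
  }
  mean_risk <- colMeans(risk_mat, na.rm = TRUE)
  se_risk <- apply(risk_mat, 2, function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  best <- which.min(mean_risk)
  ok_1se <- which(mean_risk <= mean_risk[best] + se_risk[best])
  list(mstop = mstop_grid[best],
       mstop_1se = mstop_grid[min(ok_1se)],
       cv = tibble::tibble(mstop = mstop_grid, mean_risk = mean_risk,
                           se_risk = se_risk),
       folds = folds)
}

#' Youden-J optimal probability threshold
#'
#' Maximizes sensitivity + specificity - 1 over the observed probability
#' cutpoints (prediction rule: high iff prob >= cutpoint); ties are broken
#' toward the cutpoint nearest 0.5.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 (or low/high) true labels.
#' @return List: `threshold`, `j` (the maximized index), `sensitivity`,
#'   `specificity`.
#' @export
youden_threshold <- function(probs, labels) {
  y <- as.numeric(labels %in% c(1, "high", TRUE))
  if (length(unique(y)) < 2) stop("both label classes must be present")
  cand <- sort(unique(probs))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(cand, function(t) sum(probs >= t & y == 1) / n1,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(probs < t & y == 0) / n0,
                 numeric(1))
  j <- sens + spec - 1
  jmax <- max(j)
  if (jmax <= 0 && length(cand) == 1L)
    warning("degenerate probabilities: J = 0")
  ties <- which(j >= jmax - 1e-12)
  pick <- ties[which.min(abs(cand[ties] - 0.5))]
  list(threshold = cand[pick], j = jmax, sensitivity = sens[pick],
       specificity = spec[pick])
}

#' AUROC by the midrank statistic
#'
#' @param probs Predicted probabilities (or any scores).
#' @param labels 0/1 (or low/high) labels.
#' @return Scalar AUROC in `[0, 1]`; ties handled by midranks.
#' @export
auroc <- function(probs, labels) {
  y <- as.numeric(labels %in% c(1, "high", TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUPRC by step-wise precision-recall integration
#'
#' Descending-threshold sweep with tied scores processed as one block;
#' area accumulated as precision times recall increment.
#'
#' @inheritParams auroc
#' @return Scalar AUPRC in `(0, 1]`.
#' @export
auprc <- function(probs, labels) {
  y <- as.numeric(labels %in% c(1, "high", TRUE))
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) stop("both label classes must be present")
  o <- order(probs, decreasing = TRUE)
  ys <- y[o]; ps <- probs[o]
  grp <- cumsum(c(TRUE, diff(ps) != 0))
  tp_g <- tapply(ys, grp, sum)
  n_g <- tapply(ys, grp, length)
  tp <- cumsum(tp_g); nn <- cumsum(n_g)
  prec <- tp / nn
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Discrimination report with caller-bootstrap confidence intervals
#'
#' AUROC (midranks) and AUPRC (step integration) with percentile bootstrap
#' CIs, resampling callers rather than frames so the interval respects the
#' grouped design; plus the Youden threshold and frame-level confusion
#' counts at it.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 (or low/high) true labels.
#' @param callers Caller id per row (bootstrap unit; rows resampled when
#'   NULL).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for resampling.
#' @param conf Confidence level (default 0.95).
#' @return A `discrimination_report`: `auroc`, `auroc_ci`, `auprc`,
#'   `auprc_ci`, `threshold`, `youden_j`, `confusion` (tibble),
#'   `n_boot`, `seed`.
#' @export
discrimination <- function(probs, labels, callers = NULL, n_boot = 2000,
                           seed = 1, conf = 0.95) {
  y <- as.numeric(labels %in% c(1, "high", TRUE))
  roc <- auroc(probs, y)
  pr <- auprc(probs, y)
  yt <- youden_threshold(probs, y)

  rng <- seeded_rng(seed)
  units <- if (is.null(callers)) as.character(seq_along(y))
           else as.character(callers)
  split_idx <- split(seq_along(y), units)
  uq <- names(split_idx)
  boot <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    pick <- uq[floor(rng(length(uq)) * length(uq)) + 1]
    idx <- unlist(split_idx[pick], use.names = FALSE)
    if (length(unique(y[idx])) < 2) next
    boot[b, 1] <- auroc(probs[idx], y[idx])
    boot[b, 2] <- auprc(probs[idx], y[idx])
  }
  a <- (1 - conf) / 2
  qs <- function(v) unname(stats::quantile(v, c(a, 1 - a), na.rm = TRUE))
  pred <- as.numeric(probs >= yt$threshold)
  confusion <- tibble::tibble(
    truth = c("low", "low", "high", "high"),
    predicted = c("low", "high", "low", "high"),
    n = c(sum(y == 0 & pred == 0), sum(y == 0 & pred == 1),
          sum(y == 1 & pred == 0), sum(y == 1 & pred == 1)))

  structure(list(auroc = roc, auroc_ci = qs(boot[, 1]),
                 auprc = pr, auprc_ci = qs(boot[, 2]),
                 threshold = yt$threshold, youden_j = yt$j,
                 confusion = confusion, n_boot = n_boot, seed = seed),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf(paste0("<discrimination_report> AUROC %.4f (%.4f-%.4f), ",
                     "AUPRC %.4f (%.4f-%.4f), tau=%.3f (J=%.3f)\n"),
              x$auroc, x$auroc_ci[1], x$auroc_ci[2], x$auprc,
              x$auprc_ci[1], x$auprc_ci[2], x$threshold, x$youden_j))
  invisible(x)
}

#' Leave-one-caller-out cross-validated probabilities
#'
#' One fold per caller: the model is fitted on all other callers (with
#' `mstop` fixed, or chosen per fold by grouped k-fold cross-validation on
#' the training callers) and the held-out caller is predicted with its
#' random effect at zero (it was never in training). A training fold that
#' lacks a label class skips that caller with a warning.
#'
#' Pooled out-of-fold probabilities are re-anchored to the overall
#' prevalence: each fold's score enters as its deviation from that fold's
#' training base rate. Without this, leaving a high-prevalence caller out
#' lowers its fold's offset, and when the feature signal is weak that
#' nuisance anti-ranks the pooled probabilities (a leave-one-group-out
#' pooling artifact); with strong signal the adjustment is negligible.
#'
#' @param table Frame table.
#' @param features Feature columns for the learners.
#' @param nu Step length.
#' @param mstop Fixed iteration count, or `"cv"` to select per fold.
#' @param cv_folds,mstop_grid Inner-selection controls when
#'   `mstop = "cv"`.
#' @param pcs Linear PC columns.
#' @param seed Seed for inner fold assignment.
#' @return Tibble in the original row order: `caller_id`, `prob`, `label`,
#'   `mstop_used`.
#' @export
loco_cv <- function(table, features, nu = 0.1, mstop = "cv",
                    cv_folds = 10, mstop_grid = seq(50, 600, by = 50),
                    pcs = c("pc1", "pc2"), seed = 1) {
  y <- gamm_labels(table)
  callers <- unique(as.character(table$caller_id))
  if (length(callers) < 2) stop("need at least 2 callers")
  prob <- rep(NA_real_, nrow(table))
  mstop_used <- rep(NA_integer_, nrow(table))
  for (cl in callers) {
    test <- as.character(table$caller_id) == cl
    train <- table[!test, , drop = FALSE]
    if (length(unique(y[!test])) < 2) {
      warning("training fold for caller ", cl, " has one class; skipped")
      next
    }
    m <- if (identical(mstop, "cv")) {
      select_mstop(train, features, folds = cv_folds,
                   mstop_grid = mstop_grid, nu = nu, pcs = pcs,
                   seed = seed)$mstop
    } else as.integer(mstop)
    fit <- fit_boost(train, features = features, nu = nu, mstop = m,
                     pcs = pcs)
    eta <- predict(fit, table[test, , drop = FALSE], type = "link")
    prob[test] <- stats::plogis(stats::qlogis(mean(y)) +
                                  (eta - fit$offset))
    mstop_used[test] <- m
  }
  tibble::tibble(caller_id = as.character(table$caller_id), prob = prob,
                 label = y, mstop_used = mstop_used)
}

#' Plot the boosting risk path
#'
#' @param object A `boost_model`.
#' @param ... Unused.
#' @return A ggplot of in-sample (and tracked, if any) risk by iteration.
#' @method autoplot boost_model
#' @export
autoplot.boost_model <- function(object, ...) {
  d <- tibble::tibble(iteration = seq_along(object$risk_path) - 1,
                      risk = object$risk_path, set = "train")
  if (!is.null(object$track_risk))
    d <- dplyr::bind_rows(d, tibble::tibble(
      iteration = seq_along(object$track_risk) - 1,
      risk = object$track_risk, set = "holdout"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$risk,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "boosting iteration",
                  y = "mean binomial negative log-likelihood") +
    ggplot2::theme_minimal()
}
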