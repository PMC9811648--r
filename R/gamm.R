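#' Build the penalized GAMM design
#'
#' For every predictor and sex a centered cubic B-spline block (knots at
#' within-sex quantiles of the z-scored predictor) with a second-difference
#' penalty plus a small identity shrinkage that removes the penalty null
#' space, so a whole term can be penalized out of the model. Adds a global
#' intercept, a male-vs-female contrast column and (optionally) a ridge
#' -penalized caller-intercept block. Predictors are z-scored internally;
#' the scaling is stored for prediction.
#'
#' @param table Frame table with `sex`, `caller_id` and the predictor
#'   columns.
#' @param features Character vector of predictor columns.
#' @param knots Number of B-spline basis functions per smooth (default 9).
#' @param shrink Relative weight of the null-space shrinkage penalty
#'   (default 1e-3).
#' @param linear Features forced to enter linearly (no spline), mainly for
#'   oracle comparisons.
#' @param random Include the caller random-intercept block? Default TRUE.
#' @return A `gamm_design` list: `X`, `blocks` (per-term metadata incl.
#'   penalty), `scaling`, `callers`, `y` is *not* included.
#' @export
build_design <- function(table, features, knots = 9, shrink = 1e-3,
                         linear = character(0), random = TRUE) {
  stopifnot(knots >= 4, all(features %in% names(table)))
  sex <- as.character(table$sex)
  stopifnot(all(sex %in% c("male", "female")))
  n <- nrow(table)

  center <- vapply(features, function(f) mean(table[[f]], na.rm = TRUE),
                   numeric(1))
  scale_ <- vapply(features, function(f) stats::sd(table[[f]], na.rm = TRUE),
                   numeric(1))
  scale_[scale_ == 0 | is.na(scale_)] <- 1

  cols <- list(`(Intercept)` = rep(1, n),
               sex_male = as.numeric(sex == "male"))
  blocks <- list(list(name = "(Intercept)", type = "parametric",
                      cols = 1L, S = NULL),
                 list(name = "sex_male", type = "parametric",
                      cols = 2L, S = NULL))
  next_col <- 3L

  D2 <- function(k) {
    d <- diff(diag(k), differences = 2)
    crossprod(d)
  }

  for (f in features) {
    z_all <- (table[[f]] - center[f]) / scale_[f]
    for (s in c("male", "female")) {
      rows <- sex == s
      if (!any(rows)) next    # single-sex table: no stratum to model
      zs <- z_all[rows]
      if (stats::sd(zs, na.rm = TRUE) == 0 ||
          is.na(stats::sd(zs, na.rm = TRUE))) {
        warning("predictor ", f, " constant within sex ", s,
                "; term dropped")
        next
      }
      if (f %in% linear) {
        colv <- numeric(n)
        colv[rows] <- zs - mean(zs, na.rm = TRUE)
        colv[is.na(colv)] <- 0
        nm <- paste0("lin(", f, "):", s)
        cols[[nm]] <- colv
        blocks[[length(blocks) + 1L]] <-
          list(name = nm, type = "linear", feature = f, sex = s,
               cols = next_col, S = matrix(0, 1, 1),
               col_center = mean(zs, na.rm = TRUE),
               range = range(zs, na.rm = TRUE))
        next_col <- next_col + 1L
      } else {
        rng <- range(zs, na.rm = TRUE)
        rng <- rng + c(-1, 1) * 1e-8 * max(1, diff(rng))
        n_int <- knots - 4L
        interior <- if (n_int > 0)
          stats::quantile(zs, probs = seq_len(n_int) / (n_int + 1),
                          na.rm = TRUE, names = FALSE) else numeric(0)
        kv <- c(rep(rng[1], 4), interior, rep(rng[2], 4))
        B <- matrix(0, n, knots)
        zc <- pmin(pmax(zs, rng[1]), rng[2])
        B[rows, ] <- splines::splineDesign(kv, zc, ord = 4)
        cmeans <- colSums(B[rows, , drop = FALSE]) / sum(rows)
        B[rows, ] <- sweep(B[rows, , drop = FALSE], 2, cmeans)
        S <- D2(knots)
        S <- S + shrink * mean(diag(S)) * diag(knots)
        idx <- next_col:(next_col + knots - 1L)
        nm <- paste0("s(", f, "):", s)
        for (j in seq_len(knots)) cols[[paste0(nm, ".", j)]] <- B[, j]
        blocks[[length(blocks) + 1L]] <-
          list(name = nm, type = "smooth", feature = f, sex = s,
               cols = idx, S = S, knots_vec = kv, col_means = cmeans,
               range = rng)
        next_col <- next_col + knots
      }
    }
  }

  callers <- NULL
  if (random) {
    callers <- sort(unique(as.character(table$caller_id)))
    Z <- matrix(0, n, length(callers))
    Z[cbind(seq_len(n), match(as.character(table$caller_id), callers))] <- 1
    idx <- next_col:(next_col + length(callers) - 1L)
    for (j in seq_along(callers)) cols[[paste0("caller.", j)]] <- Z[, j]
    blocks[[length(blocks) + 1L]] <-
      list(name = "caller", type = "caller", cols = idx,
           S = diag(length(callers)))
    next_col <- next_col + length(callers)
  }

  X <- do.call(cbind, cols)
  # normalize each penalty so lambda is comparable across blocks
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (!is.null(blk$S) && any(blk$S != 0)) {
      Xb <- X[, blk$cols, drop = FALSE]
      sc <- sum(diag(crossprod(Xb))) / sum(diag(blk$S))
      blocks[[b]]$S <- blk$S * sc
    }
  }
  zvalues <- lapply(features, function(f)
    (table[[f]] - center[f]) / scale_[f])
  names(zvalues) <- features
  structure(list(X = X, blocks = blocks, features = features,
                 scaling = list(center = center, scale = scale_),
                 callers = callers, knots = knots, linear = linear,
                 sex = sex, zvalues = zvalues),
            class = "gamm_design")
}

# Assemble the total penalty matrix for given smoothing parameters.
total_penalty <- function(design, lambda_smooth, lambda_caller) {
  p <- ncol(design$X)
  S <- matrix(0, p, p)
  for (blk in design$blocks) {
    if (is.null(blk$S)) next
    lam <- switch(blk$type,
                  smooth = lambda_smooth, linear = lambda_smooth,
                  caller = lambda_caller, 0)
    S[blk$cols, blk$cols] <- S[blk$cols, blk$cols] + lam * blk$S
  }
  S
}

# One penalized IRLS fit at fixed smoothing parameters.
pirls <- function(X, y, S, beta0 = NULL, tol = 1e-8, maxit = 200) {
  n <- nrow(X); p <- ncol(X)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  eta <- drop(X %*% beta)
  if (is.null(beta0)) eta <- rep(stats::qlogis(mean(c(y, 0.5, 0.5))), n)
  dev_trace <- numeric(0)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    Xw <- X * sw
    A <- crossprod(Xw)
    rhs <- crossprod(X, w * z)
    M <- A + S
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      M <- M + diag(1e-8 * mean(diag(A)), p)
      ch <- chol(M)
    }
    beta <- backsolve(ch, forwardsolve(t(ch), rhs))
    eta <- drop(X %*% beta)
    dev <- -2 * sum(y * log(pmax(stats::plogis(eta), 1e-300)) +
                    (1 - y) * log(pmax(1 - stats::plogis(eta), 1e-300)))
    dev_trace <- c(dev_trace, dev)
    if (is.finite(dev_old) &&
        abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  list(beta = drop(beta), eta = eta, deviance = dev, A = A, M = M,
       chol = ch, dev_trace = dev_trace, converged = converged,
       iterations = it)
}

#' Fit the penalized binomial GAMM
#'
#' Penalized IRLS with per-sex shrinkage smooths and caller ridge
#' intercepts; smoothing parameters chosen by GCV over a log-spaced grid
#' (one shared smoothness multiplier for all smooths, one ridge weight for
#' callers). The model is `logit P(high) = b0 + b_sex * male +
#' sum_f s_f,sex(z(x_f)) + u_caller`.
#'
#' @param table Frame table with `distress_label` (or `label`), `sex`,
#'   `caller_id` and the predictor columns.
#' @param features Predictor columns (default: all of
#'   [distress_features()] present).
#' @param knots Basis functions per smooth.
#' @param lambda_smooth,lambda_caller Smoothing-parameter grids (numeric
#'   vectors; scalars fix the value).
#' @param shrink Null-space shrinkage weight.
#' @param linear Features forced linear.
#' @param random Include caller intercepts?
#' @param lambda_select `"grouped_cv"` (default) chooses the smoothing
#'   parameters by caller-grouped cross-validated deviance, which respects
#'   the clustering of frames within callers; `"gcv"` uses classical
#'   generalized cross-validation (appropriate for independent rows, but
#'   it undersmooths badly when frames are clustered).
#' @param cv_folds Caller-grouped folds for `lambda_select = "grouped_cv"`.
#' @return A `gamm_fit` object; see [term_table()], [tidy.gamm_fit()],
#'   [glance.gamm_fit()], [select_predictors()], [partial_effects()].
#' @export
fit_distress_gamm <- function(table, features = NULL, knots = 9,
                              lambda_smooth = 10^seq(-1, 3, length.out = 5),
                              lambda_caller = c(0.1, 10, 1000),
                              shrink = 1e-3, linear = character(0),
                              random = TRUE,
                              lambda_select = c("grouped_cv", "gcv"),
                              cv_folds = 3) {
  lambda_select <- match.arg(lambda_select)
  if (is.null(features))
    features <- intersect(distress_features(), names(table))
  y <- gamm_labels(table)
  if (length(unique(y)) < 2) stop("both label classes must be present")
  keep <- stats::complete.cases(as.data.frame(table)[features])
  if (!all(keep)) {
    table <- table[keep, , drop = FALSE]
    y <- y[keep]
  }
  design <- build_design(table, features, knots, shrink, linear, random)
  n <- nrow(design$X)
  clusters <- as.character(table$caller_id)

  grid <- expand.grid(ls = lambda_smooth, lc = if (random) lambda_caller
                      else 0)
  single <- nrow(grid) == 1L

  crit_tab <- tibble::tibble(lambda_smooth = grid$ls,
                             lambda_caller = grid$lc,
                             criterion = NA_real_)
  if (!single && lambda_select == "grouped_cv") {
    fold_of <- grouped_folds(clusters, y, cv_folds, seed = 1)
    for (g in seq_len(nrow(grid))) {
      S <- total_penalty(design, grid$ls[g], grid$lc[g])
      heldout <- 0
      for (f in seq_len(cv_folds)) {
        test <- fold_of[clusters] == f
        if (!any(test) || length(unique(y[!test])) < 2) next
        ft <- pirls(design$X[!test, , drop = FALSE], y[!test], S)
        # held-out callers predicted with their random effect at zero
        beta <- ft$beta
        cb <- Find(function(b) b$type == "caller", design$blocks)
        if (!is.null(cb)) beta[cb$cols] <- 0
        eta_t <- drop(design$X[test, , drop = FALSE] %*% beta)
        mu_t <- pmin(pmax(stats::plogis(eta_t), 1e-12), 1 - 1e-12)
        heldout <- heldout -
          2 * sum(y[test] * log(mu_t) + (1 - y[test]) * log(1 - mu_t))
      }
      crit_tab$criterion[g] <- heldout
    }
  }

  # Held-out deviance is nearly flat in the caller ridge weight (held-out
  # callers are predicted with a zero random effect), so break near-ties
  # toward the strongest penalties; otherwise the caller block freely
  # absorbs binomial noise in per-caller label rates.
  chosen_g <- NA_integer_
  if (!single && lambda_select == "grouped_cv") {
    tol <- min(crit_tab$criterion) * 1.002
    cands <- which(crit_tab$criterion <= tol)
    chosen_g <- cands[order(grid$lc[cands], grid$ls[cands],
                            decreasing = TRUE)][1]
  }

  best <- NULL
  beta_warm <- NULL
  for (g in seq_len(nrow(grid))) {
    if (!single && lambda_select == "grouped_cv" && g != chosen_g) next
    S <- total_penalty(design, grid$ls[g], grid$lc[g])
    fit <- pirls(design$X, y, S, beta0 = beta_warm)
    beta_warm <- fit$beta
    Minv_A <- backsolve(fit$chol,
                        forwardsolve(t(fit$chol), fit$A))
    edf <- sum(diag(Minv_A))
    gcv <- n * fit$deviance / (n - edf)^2
    if (lambda_select == "gcv") crit_tab$criterion[g] <- gcv
    if (is.null(best) ||
        (lambda_select == "gcv" && gcv < best$criterion) ||
        (lambda_select == "grouped_cv")) {
      best <- list(fit = fit, criterion = if (lambda_select == "gcv") gcv
                   else crit_tab$criterion[g],
                   edf = edf, lambda_smooth = grid$ls[g],
                   lambda_caller = grid$lc[g], Minv_A = Minv_A)
    }
  }
  fit <- best$fit
  if (!fit$converged)
    rlang::abort("penalized IRLS did not converge",
                 class = "gamm_convergence_error",
                 dev_trace = fit$dev_trace)
  if (max(abs(fit$beta)) > 50)
    warning("very large coefficients: possible complete separation")

  Vb <- chol2inv(fit$chol)
  # Caller-cluster-robust covariance for inference: frames are strongly
  # dependent within segments and callers, so the model-based covariance
  # understates sampling variance. The jackknife-type (CR3) leverage
  # adjustment (I - H_gg)^{-1} per caller is essential here because the
  # ridge-penalized caller intercepts absorb most of each caller's
  # residual, which would otherwise deflate the plain sandwich severely.
  mu_fit <- stats::plogis(fit$eta)
  w_fit <- pmax(mu_fit * (1 - mu_fit), 1e-10)
  G <- length(unique(clusters))
  Minv <- Vb
  meat <- matrix(0, ncol(design$X), ncol(design$X))
  for (cl in unique(clusters)) {
    rows <- which(clusters == cl)
    Ug <- design$X[rows, , drop = FALSE] * sqrt(w_fit[rows])
    IH <- diag(length(rows)) - Ug %*% Minv %*% t(Ug)
    eg <- (y[rows] - mu_fit[rows]) / sqrt(w_fit[rows])
    sg <- crossprod(Ug, solve(IH + diag(1e-8, length(rows)), eg))
    meat <- meat + tcrossprod(sg)
  }
  Vr <- ((G - 1) / G) * Minv %*% meat %*% Minv
  clusters_by_sex <- vapply(c("male", "female"), function(s)
    length(unique(clusters[design$sex == s])), numeric(1))

  edf_cols <- diag(best$Minv_A)
  mu <- stats::plogis(fit$eta)
  p0 <- mean(y)
  null_dev <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  dev_expl <- 1 - fit$deviance / null_dev
  adj_dev_expl <- 1 - ((n - 1) / pmax(n - best$edf, 1)) *
    (fit$deviance / null_dev)

  caller_blk <- Find(function(b) b$type == "caller", design$blocks)
  caller_effects <- if (!is.null(caller_blk)) {
    stats::setNames(fit$beta[caller_blk$cols], design$callers)
  } else NULL

  structure(list(
    design = design, y = y, coefficients = fit$beta, Vb = Vb, Vr = Vr,
    n_clusters = G, clusters = clusters,
    clusters_by_sex = clusters_by_sex,
    fitted = mu, linear_predictor = fit$eta,
    edf_by_col = edf_cols, edf_total = best$edf,
    lambda_smooth = best$lambda_smooth, lambda_caller = best$lambda_caller,
    lambda_select = lambda_select,
    criterion = crit_tab, deviance = fit$deviance, null_deviance = null_dev,
    deviance_explained = dev_expl, adj_deviance_explained = adj_dev_expl,
    caller_effects = caller_effects,
    caller_sd = if (!is.null(caller_effects)) stats::sd(caller_effects)
                else NA_real_,
    n = n, prevalence = p0, converged = fit$converged,
    dev_trace = fit$dev_trace
  ), class = "gamm_fit")
}

# Label-balanced caller-grouped fold assignment: callers ordered by label
# prevalence (seeded jitter for ties) and dealt round-robin.
grouped_folds <- function(clusters, y, folds, seed = 1) {
  uq <- unique(clusters)
  folds <- max(2L, min(folds, length(uq)))
  prev <- vapply(uq, function(cl) mean(y[clusters == cl]), numeric(1))
  rng <- seeded_rng(seed)
  ord <- order(prev + 1e-9 * rng(length(prev)))
  fold_of <- integer(length(uq))
  fold_of[ord] <- rep_len(seq_len(folds), length(uq))
  names(fold_of) <- uq
  fold_of
}

# Accept either distress_label (factor low/high) or a 0/1 label column.
gamm_labels <- function(table) {
  if ("distress_label" %in% names(table)) {
    as.numeric(table$distress_label == "high" |
                 table$distress_label == 1)
  } else if ("label" %in% names(table)) {
    as.numeric(table$label %in% c("high", 1, TRUE))
  } else stop("no distress_label/label column")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat(sprintf(paste0("<gamm_fit> n=%d, edf=%.1f, deviance explained=%.3f",
                     " (adj %.3f), lambda=(%.3g, %.3g)\n"),
              x$n, x$edf_total, x$deviance_explained,
              x$adj_deviance_explained, x$lambda_smooth, x$lambda_caller))
  invisible(x)
}

#' Per-term summary of a fitted GAMM
#'
#' One row per (feature, sex) smooth: the slope of the fitted term's
#' linear projection (`beta`, on the standardized-logit scale) with its
#' standard error and 95% Wald CI, the term's effective degrees of freedom,
#' an approximate F test of the whole smooth and its p value. Standard
#' errors and tests use the caller-cluster-robust covariance with
#' denominator df = callers - 1, since frames are strongly dependent
#' within segments and callers. A final row holds the male-vs-female
#' parametric contrast.
#'
#' @param fit A `gamm_fit`.
#' @return Tibble: `feature`, `sex`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `edf`, `F`, `df_num`, `df_den`, `p`.
#' @export
term_table <- function(fit) {
  stopifnot(inherits(fit, "gamm_fit"))
  design <- fit$design
  rows <- purrr::map_dfr(design$blocks, function(blk) {
    if (!(blk$type %in% c("smooth", "linear"))) return(NULL)
    idx <- blk$cols
    bj <- fit$coefficients[idx]
    Vj <- fit$Vr[idx, idx, drop = FALSE]
    edf_j <- sum(fit$edf_by_col[idx])
    # denominator df from the clusters actually informing this term
    df_den <- max(1, fit$clusters_by_sex[[blk$sex]] - 1)

    srows <- design$sex == blk$sex
    # slope of the fitted term's linear projection on the z-scored predictor
    zx <- term_covariate(design, blk)
    cvec <- drop(crossprod(design$X[srows, idx, drop = FALSE],
                           zx - mean(zx))) / sum((zx - mean(zx))^2)
    beta <- sum(cvec * bj)
    se <- sqrt(drop(t(cvec) %*% Vj %*% cvec))

    # Wald test restricted to the rank-edf leading eigenspace of the
    # robust covariance (the directions the penalized fit actually used)
    r <- max(1L, min(length(idx), round(edf_j)))
    ev <- eigen(Vj, symmetric = TRUE)
    keep_ev <- seq_len(r)
    proj <- drop(crossprod(ev$vectors[, keep_ev, drop = FALSE], bj))
    chi2 <- sum(proj^2 / pmax(ev$values[keep_ev], 1e-300))
    Fstat <- chi2 / r
    pval <- stats::pf(Fstat, r, df_den, lower.tail = FALSE)

    tibble::tibble(feature = blk$feature, sex = blk$sex, beta = beta,
                   se = se, ci_low = beta - 1.96 * se,
                   ci_high = beta + 1.96 * se, edf = edf_j, F = Fstat,
                   df_num = r, df_den = df_den, p = pval)
  })
  # male-vs-female parametric contrast
  sb <- which(vapply(design$blocks, function(b) b$name == "sex_male",
                     logical(1)))
  i <- design$blocks[[sb]]$cols
  beta_s <- fit$coefficients[i]
  se_s <- sqrt(fit$Vr[i, i])
  df_sex <- max(1, fit$n_clusters - 1)
  rows <- dplyr::add_row(rows, feature = "sex", sex = "male_vs_female",
                         beta = beta_s, se = se_s,
                         ci_low = beta_s - 1.96 * se_s,
                         ci_high = beta_s + 1.96 * se_s,
                         edf = 1, F = (beta_s / se_s)^2, df_num = 1,
                         df_den = df_sex,
                         p = stats::pf((beta_s / se_s)^2, 1, df_sex,
                                       lower.tail = FALSE))
  rows
}

# z-scored covariate values over the rows of the block's sex stratum.
term_covariate <- function(design, blk) {
  design$zvalues[[blk$feature]][design$sex == blk$sex]
}

#' @rdname term_table
#' @param x A `gamm_fit`.
#' @param ... Unused.
#' @method tidy gamm_fit
#' @export
tidy.gamm_fit <- function(x, ...) term_table(x)

#' Model-level summary of a fitted GAMM
#'
#' @param x A `gamm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `edf`, `deviance`, `null_deviance`,
#'   `deviance_explained`, `adj_deviance_explained`, `lambda_smooth`,
#'   `lambda_caller`, `caller_sd`, `converged`.
#' @method glance gamm_fit
#' @export
glance.gamm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, edf = x$edf_total, deviance = x$deviance,
                 null_deviance = x$null_deviance,
                 deviance_explained = x$deviance_explained,
                 adj_deviance_explained = x$adj_deviance_explained,
                 lambda_smooth = x$lambda_smooth,
                 lambda_caller = x$lambda_caller,
                 caller_sd = x$caller_sd, converged = x$converged)
}

#' Select significant (feature, sex) predictors
#'
#' @param fit A `gamm_fit`.
#' @param alpha Significance level (default 0.05).
#' @return List with `selected` (tibble of significant feature-sex pairs),
#'   `features` (unique features passed downstream; falls back to the full
#'   set with a warning when nothing is significant) and `alpha`.
#' @export
select_predictors <- function(fit, alpha = 0.05) {
  tt <- term_table(fit)
  tt <- dplyr::filter(tt, .data$feature != "sex")
  sel <- dplyr::filter(tt, .data$p < alpha)
  feats <- unique(sel$feature)
  if (!length(feats)) {
    warning("no predictor significant at alpha = ", alpha,
            "; falling back to the full feature set")
    feats <- unique(tt$feature)
  }
  list(selected = sel, features = feats, alpha = alpha)
}

#' Partial-effect probability curve for one smooth
#'
#' Predicted probability of high distress against one feature, with all
#' other features held at their means (their centered smooths contribute
#' their value at the mean), the caller intercept at 0, and sex fixed.
#'
#' @param fit A `gamm_fit`.
#' @param feature Feature name.
#' @param sex `"male"` or `"female"`.
#' @param grid Feature values (original units); default 50 points over the
#'   within-sex observed range.
#' @return Tibble: `feature`, `sex`, `value`, `z`, `eta`, `prob`.
#' @export
partial_effects <- function(fit, feature, sex, grid = NULL) {
  design <- fit$design
  blk <- Find(function(b) !is.null(b$feature) && b$feature == feature &&
                b$sex == sex, design$blocks)
  if (is.null(blk)) stop("no term for feature ", feature, ", sex ", sex)
  ctr <- design$scaling$center[feature]
  scl <- design$scaling$scale[feature]
  if (is.null(grid)) {
    rng <- blk$range * scl + ctr
    grid <- seq(rng[1], rng[2], length.out = 50)
  }
  z <- (grid - ctr) / scl

  eta0 <- fit$coefficients[1] +
    fit$coefficients[2] * as.numeric(sex == "male")
  # other smooths of this sex evaluated at their mean (z = 0)
  for (b in design$blocks) {
    if (b$type != "smooth" || is.null(b$sex) || b$sex != sex) next
    if (b$feature == feature) next
    eta0 <- eta0 + smooth_eval(b, 0) %*% fit$coefficients[b$cols]
  }
  eta <- drop(eta0) + drop(smooth_eval(blk, z) %*%
                             fit$coefficients[blk$cols])
  tibble::tibble(feature = feature, sex = sex, value = grid, z = z,
                 eta = eta, prob = stats::plogis(eta))
}

# Evaluate a stored centered spline block at new z values (clamped).
smooth_eval <- function(blk, z) {
  if (is.null(blk$knots_vec)) {   # linear term
    return(matrix(z - blk$col_center, ncol = 1))
  }
  zc <- pmin(pmax(z, blk$range[1]), blk$range[2])
  B <- splines::splineDesign(blk$knots_vec, zc, ord = 4)
  sweep(B, 2, blk$col_means)
}

#' Plot partial-effect curves of a fitted GAMM
#'
#' @param object A `gamm_fit`.
#' @param features Features to plot (default: all smooth terms).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gamm_fit
#' @export
autoplot.gamm_fit <- function(object, features = NULL, ...) {
  blks <- Filter(function(b) b$type %in% c("smooth", "linear") &&
                   !is.null(b$feature), object$design$blocks)
  feats <- unique(vapply(blks, `[[`, character(1), "feature"))
  if (!is.null(features)) feats <- intersect(feats, features)
  curves <- purrr::map_dfr(feats, function(f) {
    purrr::map_dfr(c("male", "female"), function(s) {
      tryCatch(partial_effects(object, f, s), error = function(e) NULL)
    })
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$value, y = .data$prob,
                               color = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = "feature value", y = "P(high distress)",
                  color = "sex") +
    ggplot2::theme_minimal()
}
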