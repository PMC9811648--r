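#' k-means clustering of speech frames
#'
#' Lloyd's algorithm from k-means++ starts, best of `n_init` restarts by
#' within-cluster sum of squares. Features are z-scored internally.
#' Cluster labels are renumbered by descending cluster size. The
#' per-iteration objective trace of the winning restart is kept (it is
#' non-increasing by construction and asserted in tests).
#'
#' @param table Data frame with the feature columns.
#' @param features Feature columns to cluster on (default: intersection of
#'   [distress_features()] with `names(table)`).
#' @param k Number of clusters.
#' @param seed Integer seed (restarts are deterministic given it).
#' @param n_init Number of k-means++ restarts (default 25).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return A `cluster_model`: `k`, `centroids` (k x p, z-space),
#'   `assignments`, `explained_variance_fraction`, `objective_trace`,
#'   `scaling`, `features`, `seed`, `n_init`.
#' @export
cluster_frames <- function(table, features = NULL, k = 2, seed = 1,
                           n_init = 25, max_iter = 100) {
  if (is.null(features))
    features <- intersect(distress_features(), names(table))
  if (!length(features)) stop("no feature columns to cluster on")
  X <- as.matrix(as.data.frame(table)[features])
  keep <- stats::complete.cases(X)
  if (!all(keep)) stop("clustering requires complete feature rows")
  n <- nrow(X)
  stopifnot(k >= 1, n >= k)
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (nrow(unique(Z)) < k)
    stop("fewer than k distinct rows: degenerate data for k = ", k)

  tot_ss <- sum(sweep(Z, 2, colMeans(Z))^2)
  rng <- seeded_rng(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    cen <- kmeanspp_init(Z, k, rng)
    res <- lloyd(Z, cen, max_iter)
    if (is.null(best) || res$wss < best$wss) best <- res
  }
  # renumber by descending size
  sizes <- tabulate(best$assign, nbins = k)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  assign <- relabel[best$assign]
  centroids <- best$centroids[ord, , drop = FALSE]
  rownames(centroids) <- NULL

  structure(list(
    k = k, centroids = centroids, assignments = assign,
    explained_variance_fraction =
      if (tot_ss > 0) max(0, 1 - best$wss / tot_ss) else 0,
    objective_trace = best$trace, within_ss = best$wss, total_ss = tot_ss,
    scaling = list(center = ctr, scale = scl),
    features = features, seed = seed, n_init = n_init
  ), class = "cluster_model")
}

# Small explicit linear-congruential RNG so restarts are deterministic and
# independent of the caller's RNG state.
seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state == 0) state <- 1
  function(n = 1) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

kmeanspp_init <- function(Z, k, rng) {
  n <- nrow(Z)
  idx <- integer(k)
  idx[1] <- floor(rng() * n) + 1
  if (k > 1) {
    d2 <- rowSums(sweep(Z, 2, Z[idx[1], ])^2)
    for (j in 2:k) {
      tot <- sum(d2)
      pick <- if (tot <= 0) floor(rng() * n) + 1
              else which(cumsum(d2) >= rng() * tot)[1]
      idx[j] <- pick
      d2 <- pmin(d2, rowSums(sweep(Z, 2, Z[pick, ])^2))
    }
  }
  Z[idx, , drop = FALSE]
}

lloyd <- function(Z, cen, max_iter) {
  n <- nrow(Z); k <- nrow(cen)
  trace <- numeric(0)
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d <- outer(rowSums(Z^2), rep(1, k)) - 2 * Z %*% t(cen) +
      outer(rep(1, n), rowSums(cen^2))
    new_assign <- max.col(-d, ties.method = "first")
    wss <- sum(d[cbind(seq_len(n), new_assign)])
    trace <- c(trace, wss)
    if (it > 1 && all(new_assign == assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      rows <- assign == j
      if (any(rows)) cen[j, ] <- colMeans(Z[rows, , drop = FALSE])
    }
  }
  # final objective at converged centroids
  d <- outer(rowSums(Z^2), rep(1, k)) - 2 * Z %*% t(cen) +
    outer(rep(1, n), rowSums(cen^2))
  assign <- max.col(-d, ties.method = "first")
  wss <- sum(pmax(d[cbind(seq_len(n), assign)], 0))
  list(assign = assign, centroids = cen, wss = wss, trace = trace)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, explained variance %.1f%%, n=%d\n",
              x$k, 100 * x$explained_variance_fraction,
              length(x$assignments)))
  invisible(x)
}

#' Scree of explained variance over k and elbow choice
#'
#' Fits k-means for each k in `k_range` and returns the
#' between-cluster-variance fraction per k. The chosen k is the smallest k
#' whose *next* marginal gain falls below `gain_frac` of the first gain
#' (the k=1 to k=2 gain); when every gain stays comparable the elbow is
#' flagged weak and the largest k is returned, and all-identical rows give
#' k = 1.
#'
#' @inheritParams cluster_frames
#' @param k_range Ascending integer vector of k values (default 1:5).
#' @param gain_frac Elbow sensitivity (default 0.25).
#' @return List: `scree` (tibble k, explained_variance, gain), `k`,
#'   `weak_elbow`, `models` (per-k cluster models).
#' @export
scree_select <- function(table, features = NULL, k_range = 1:5, seed = 1,
                         n_init = 10, gain_frac = 0.25) {
  stopifnot(!is.unsorted(k_range))
  models <- lapply(k_range, function(k)
    tryCatch(cluster_frames(table, features, k = k, seed = seed,
                            n_init = n_init),
             error = function(e) NULL))   # k infeasible (too few distinct)
  feasible <- !vapply(models, is.null, logical(1))
  k_range <- k_range[feasible]
  models <- models[feasible]
  if (!length(models)) stop("no feasible number of clusters in k_range")
  ev <- vapply(models, `[[`, numeric(1), "explained_variance_fraction")
  gains <- c(NA_real_, diff(ev))
  first_gain <- if (length(gains) >= 2) gains[2] else NA_real_

  weak <- FALSE
  if (is.na(first_gain) || first_gain <= 1e-12) {
    k_chosen <- k_range[1]
  } else {
    k_chosen <- NA_integer_
    for (i in 2:length(k_range)) {
      nxt <- if (i < length(k_range)) gains[i + 1] else NA_real_
      if (!is.na(nxt) && nxt < gain_frac * first_gain) {
        k_chosen <- k_range[i]
        break
      }
    }
    if (is.na(k_chosen)) {
      k_chosen <- k_range[length(k_range)]
      weak <- TRUE
    }
  }
  list(scree = tibble::tibble(k = k_range, explained_variance = ev,
                              gain = gains),
       k = k_chosen, weak_elbow = weak, models = models)
}

#' Cramer's V between two categorical vectors
#'
#' `sqrt(chi2 / (n * (min(r, c) - 1)))` from the contingency table, without
#' continuity correction. A vector with a single level gives 0 with a
#' warning (association undefined).
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return Value in `[0, 1]`.
#' @export
cramers_v <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  if (min(dim(tab)) < 2) {
    warning("a variable has a single level; Cramer's V undefined, returning 0")
    return(0)
  }
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expd)^2 / expd)
  sqrt(chi2 / (n * (min(dim(tab)) - 1)))
}

#' Append the first two principal-component scores
#'
#' PCA of the z-scored selected features over all frames; each component's
#' sign is fixed so its highest-loading feature loads positively. The
#' scores are appended as `pc1`, `pc2` (rank-1 data yields a zero `pc2`
#' with a warning).
#'
#' @param table Frame table.
#' @param features Features entering the PCA.
#' @return `table` with `pc1`, `pc2` columns added; the `prcomp` rotation
#'   is attached as attribute `"pca"`.
#' @export
add_cluster_pcs <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(distress_features(), names(table))
  stopifnot(length(features) >= 2)
  X <- as.matrix(as.data.frame(table)[features])
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- function(j) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) -1 else 1
  }
  s1 <- flip(1)
  pc1 <- s1 * pc$x[, 1]
  if (ncol(pc$x) >= 2 && pc$sdev[2] > 1e-10) {
    s2 <- flip(2)
    pc2 <- s2 * pc$x[, 2]
  } else {
    warning("effectively rank-1 data: pc2 set to 0")
    pc2 <- rep(0, nrow(X))
  }
  out <- dplyr::mutate(tibble::as_tibble(table), pc1 = pc1, pc2 = pc2)
  attr(out, "pca") <- pc
  out
}

#' Validate a 2-cluster solution by logistic regression
#'
#' Regresses cluster membership on the selected features (binomial, logit
#' link); reports McFadden pseudo-R-squared as "variance accounted for"
#' and, per feature, which cluster sits higher. Perfect separation
#' triggers a ridge-regularized refit (lambda 1e-6) with a flag.
#'
#' @param table Frame table.
#' @param assignments Cluster labels (two clusters).
#' @param features Features for the regression.
#' @return A `cluster_validation`: `cramers_v_sex` (if `sex` present),
#'   `pseudo_r2`, `directions` (tibble feature, higher_in_cluster),
#'   `regularized`.
#' @export
validate_clusters <- function(table, assignments, features = NULL) {
  if (is.null(features))
    features <- intersect(distress_features(), names(table))
  stopifnot(length(unique(assignments)) == 2)
  y <- as.numeric(assignments == max(assignments))
  X <- scale(as.matrix(as.data.frame(table)[features]))
  X[is.na(X)] <- 0

  regularized <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        regularized <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (regularized || !fit$converged) {
    # ridge-penalized IRLS refit
    S <- diag(c(0, rep(1e-6, ncol(X))))
    rf <- pirls(cbind(1, X), y, S)
    coefs <- rf$beta
    dev <- rf$deviance
    regularized <- TRUE
  } else {
    coefs <- fit$coefficients
    dev <- fit$deviance
  }
  p0 <- mean(y)
  null_dev <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  pseudo_r2 <- min(1, max(0, 1 - dev / null_dev))

  directions <- tibble::tibble(
    feature = features,
    coefficient = coefs[-1],
    higher_in_cluster = ifelse(coefs[-1] > 0, max(assignments),
                               min(assignments)))
  out <- list(pseudo_r2 = pseudo_r2, directions = directions,
              regularized = regularized)
  if ("sex" %in% names(table))
    out$cramers_v_sex <- cramers_v(assignments, table$sex)
  structure(out, class = "cluster_validation")
}

#' @export
print.cluster_validation <- function(x, ...) {
  cat(sprintf("<cluster_validation> pseudo-R2 %.3f%s%s\n", x$pseudo_r2,
              if (!is.null(x$cramers_v_sex))
                sprintf(", Cramer's V vs sex %.3f", x$cramers_v_sex) else "",
              if (x$regularized) " (ridge-regularized)" else ""))
  invisible(x)
}

#' Scree plot of a cluster-number search
#'
#' @param scree The result of [scree_select()].
#' @return A ggplot of explained variance against k.
#' @export
plot_scree <- function(scree) {
  ggplot2::ggplot(scree$scree,
                  ggplot2::aes(x = .data$k, y = .data$explained_variance)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = scree$k, linetype = "dashed") +
    ggplot2::labs(x = "clusters (k)", y = "explained variance fraction") +
    ggplot2::theme_minimal()
}
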