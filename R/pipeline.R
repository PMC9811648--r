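#' Run the full distress-classification pipeline
#'
#' Stages in methods order: ingest or simulate a frame table, screen
#' correlated features, select predictors with the penalized GAMM, cluster
#' frames and append the two principal components, classify frames with
#' component-wise boosting under leave-one-caller-out validation, pick the
#' Youden threshold, and aggregate to segment decisions. A manifest of
#' parameters and seeds is attached so every number in the reports traces
#' to a configuration.
#'
#' @param frames Frame table (e.g. from [extract_features()] or
#'   [simulate_frames()]).
#' @param features Candidate features (default: [distress_features()]
#'   columns present).
#' @param r_threshold Correlation-screening threshold.
#' @param alpha GAMM selection significance level.
#' @param k_range Cluster-number search range.
#' @param nu,mstop Boosting controls (`mstop = "cv"` selects per LOCO fold
#'   by grouped 10-fold CV).
#' @param mstop_grid Candidate iteration counts when `mstop = "cv"`.
#' @param n_boot Bootstrap replicates for the discrimination CIs.
#' @param seed Seed for clustering, fold assignment and the bootstrap.
#' @param gamm_args Extra arguments passed to [fit_distress_gamm()].
#' @return A `distress_pipeline` list: `screening`, `gamm`, `selection`,
#'   `scree`, `clusters`, `cluster_validation`, `loco`, `report`
#'   (discrimination), `threshold`, `segments`, `frame_confusion`,
#'   `segment_confusion`, `misclassification`, `manifest`.
#' @export
run_pipeline <- function(frames, features = NULL, r_threshold = 0.9,
                         alpha = 0.05, k_range = 1:5, nu = 0.1,
                         mstop = "cv", mstop_grid = seq(10, 150, by = 10),
                         n_boot = 500, seed = 1, gamm_args = list()) {
  if (is.null(features))
    features <- intersect(distress_features(), names(frames))

  screening <- prune_correlated(frames, features, r_threshold)
  feats <- screening$kept

  gamm <- do.call(fit_distress_gamm,
                  c(list(table = frames, features = feats), gamm_args))
  selection <- select_predictors(gamm, alpha)
  sel_feats <- selection$features

  scree <- scree_select(frames, sel_feats, k_range = k_range, seed = seed)
  k <- scree$k
  clusters <- scree$models[[match(k, scree$scree$k)]]
  validation <- if (k == 2)
    validate_clusters(frames, clusters$assignments, sel_feats) else NULL
  frames_pc <- add_cluster_pcs(frames, sel_feats)

  loco <- loco_cv(frames_pc, sel_feats, nu = nu, mstop = mstop,
                  mstop_grid = mstop_grid, seed = seed)
  ok <- !is.na(loco$prob)
  report <- discrimination(loco$prob[ok], loco$label[ok],
                           callers = loco$caller_id[ok], n_boot = n_boot,
                           seed = seed)
  tau <- report$threshold

  segments <- aggregate_segments(loco$prob, frames_pc$segment_id,
                                 loco$label, tau)
  frame_conf <- confusion_summary(
    ifelse(loco$prob[ok] >= tau, "high", "low"),
    ifelse(loco$label[ok] == 1, "high", "low"), "frame")
  seg_conf <- confusion_summary(segments$predicted, segments$truth,
                                "segment")
  mis <- misclassification_report(segments)

  structure(list(
    screening = screening, gamm = gamm, selection = selection,
    scree = scree, clusters = clusters, cluster_validation = validation,
    loco = loco, report = report, threshold = tau, segments = segments,
    frame_confusion = frame_conf, segment_confusion = seg_conf,
    misclassification = mis,
    manifest = list(features_in = features, screened = feats,
                    selected = sel_feats, k = k, nu = nu, mstop = mstop,
                    r_threshold = r_threshold, alpha = alpha,
                    seed = seed, n_frames = nrow(frames),
                    n_callers = length(unique(frames$caller_id)),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "distress_pipeline")
}

#' @export
print.distress_pipeline <- function(x, ...) {
  cat("<distress_pipeline>\n")
  cat(sprintf("  frames: %d over %d callers\n", x$manifest$n_frames,
              x$manifest$n_callers))
  cat(sprintf("  screened %d -> %d features; GAMM selected: %s\n",
              length(x$manifest$features_in), length(x$manifest$screened),
              paste(x$manifest$selected, collapse = ", ")))
  cat(sprintf("  clusters: k=%d (Cramer's V vs sex %.3f)\n",
              x$manifest$k,
              if (!is.null(x$cluster_validation))
                x$cluster_validation$cramers_v_sex else NA))
  cat(sprintf("  LOCO AUROC %.4f, AUPRC %.4f, tau %.3f\n",
              x$report$auroc, x$report$auprc, x$threshold))
  fl <- x$frame_confusion
  cat(sprintf("  frames correct: low %.2f%%, high %.2f%%\n",
              fl$pct_correct[fl$class == "low"],
              fl$pct_correct[fl$class == "high"]))
  sl <- x$segment_confusion
  cat(sprintf("  segments correct: low %.1f%%, high %.1f%%\n",
              sl$pct_correct[sl$class == "low"],
              sl$pct_correct[sl$class == "high"]))
  invisible(x)
}
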