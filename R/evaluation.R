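# round-half-up at d decimals (printed percentages use this, not banker's)
round_half_up <- function(x, d = 0) floor(x * 10^d + 0.5) / 10^d

#' Aggregate frame probabilities to segment decisions
#'
#' Each segment's score is the mean predicted probability over its scored
#' (non-silent) frames; the segment is called high iff that mean is at
#' least `tau`. Segments with zero scored frames are excluded with a
#' warning.
#'
#' @param frame_probs Per-frame probabilities.
#' @param segment_ids Segment id per frame.
#' @param truth Per-frame true labels (0/1 or low/high); constant within a
#'   segment.
#' @param tau Probability threshold in (0, 1) (the frame-level Youden
#'   threshold is the conventional choice).
#' @return Tibble of class `segment_result`: `segment_id`, `mean_prob`,
#'   `n_frames`, `predicted`, `truth`, `misclassified`.
#' @export
aggregate_segments <- function(frame_probs, segment_ids, truth, tau = 0.5) {
  stopifnot(tau > 0, tau < 1,
            length(frame_probs) == length(segment_ids),
            length(truth) == length(segment_ids))
  y <- as.numeric(truth %in% c(1, "high", TRUE))
  ok <- !is.na(frame_probs)
  if (!all(ok)) {
    dropped <- setdiff(unique(segment_ids), unique(segment_ids[ok]))
    if (length(dropped))
      warning("segment(s) with zero scored frames excluded: ",
              paste(dropped, collapse = ", "))
  }
  d <- tibble::tibble(segment_id = segment_ids[ok], prob = frame_probs[ok],
                      y = y[ok])
  res <- d |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(mean_prob = mean(.data$prob),
                     n_frames = dplyr::n(),
                     truth_num = .data$y[1], .groups = "drop") |>
    dplyr::mutate(
      predicted = factor(ifelse(.data$mean_prob >= tau, "high", "low"),
                         levels = c("low", "high")),
      truth = factor(ifelse(.data$truth_num == 1, "high", "low"),
                     levels = c("low", "high")),
      misclassified = .data$predicted != .data$truth) |>
    dplyr::select(-"truth_num")
  class(res) <- c("segment_result", class(res))
  res
}

#' Per-class confusion summary with printed-precision percentages
#'
#' Counts correct and incorrect predictions per true class and computes
#' percentage correct/incorrect as `100 * count / total`, rounded half-up
#' to 2 decimals at frame level and 1 decimal at segment level (matching
#' how such results are conventionally reported).
#'
#' @param predicted,truth Equal-length label vectors (low/high or 0/1).
#' @param level `"frame"` or `"segment"` (controls rounding precision).
#' @return Tibble: `level`, `class`, `total`, `correct`, `incorrect`,
#'   `pct_correct`, `pct_incorrect`.
#' @export
confusion_summary <- function(predicted, truth, level = c("frame",
                                                          "segment")) {
  level <- match.arg(level)
  if (!length(truth)) stop("empty input")
  stopifnot(length(predicted) == length(truth))
  p <- ifelse(predicted %in% c(1, "high", TRUE), "high", "low")
  t_ <- ifelse(truth %in% c(1, "high", TRUE), "high", "low")
  dp <- if (level == "frame") 2 else 1
  purrr::map_dfr(c("low", "high"), function(cl) {
    tot <- sum(t_ == cl)
    cor <- sum(t_ == cl & p == cl)
    tibble::tibble(level = level, class = cl, total = tot, correct = cor,
                   incorrect = tot - cor,
                   pct_correct = if (tot > 0)
                     round_half_up(100 * cor / tot, dp) else NA_real_,
                   pct_incorrect = if (tot > 0)
                     round_half_up(100 * (tot - cor) / tot, dp)
                   else NA_real_)
  })
}

#' Misclassified-segment report
#'
#' Lists misclassified segments with the direction of the error and the
#' segment mean probability; free-text notes from the annotations (column
#' `note`, if present) are passed through for qualitative review. Also
#' reports the per-class misclassification percentages (half-up, 1 dp).
#'
#' @param segment_results A `segment_result` tibble from
#'   [aggregate_segments()].
#' @param annotations Optional annotation tibble (joined on `segment_id`).
#' @return List: `misclassified` (tibble, possibly empty), `by_class`
#'   (tibble class, total, misclassified, pct), `overall_pct`.
#' @export
misclassification_report <- function(segment_results, annotations = NULL) {
  mis <- dplyr::filter(tibble::as_tibble(segment_results),
                       .data$misclassified) |>
    dplyr::mutate(direction = ifelse(.data$truth == "high",
                                     "high_called_low", "low_called_high"))
  if (!is.null(annotations) && "note" %in% names(annotations))
    mis <- dplyr::left_join(
      mis, dplyr::select(annotations, "segment_id", "note"),
      by = "segment_id")
  by_class <- tibble::as_tibble(segment_results) |>
    dplyr::group_by(class = as.character(.data$truth)) |>
    dplyr::summarise(total = dplyr::n(),
                     misclassified = sum(.data$misclassified),
                     .groups = "drop") |>
    dplyr::mutate(pct = round_half_up(100 * .data$misclassified /
                                        .data$total, 1))
  list(misclassified = mis, by_class = by_class,
       overall_pct = round_half_up(
         100 * sum(by_class$misclassified) / sum(by_class$total), 1))
}

#' Format a results-paragraph style summary
#'
#' @param frame_summary Frame-level [confusion_summary()].
#' @param segment_summary Segment-level [confusion_summary()].
#' @return A single character string.
#' @export
results_text <- function(frame_summary, segment_summary) {
  g <- function(s, cl) dplyr::filter(s, .data$class == cl)
  fl <- g(frame_summary, "low"); fh <- g(frame_summary, "high")
  sl <- g(segment_summary, "low"); sh <- g(segment_summary, "high")
  sprintf(paste0(
    "%s of %s (%.2f%%) speech frames nested within %s of %s (%.1f%%) ",
    "segments were correctly classified as exhibiting low psychological ",
    "distress. Conversely, %s of %s (%.2f%%) speech frames nested within ",
    "%s of %s (%.1f%%) segments were correctly classified as exhibiting ",
    "high psychological distress."),
    format(fl$correct, big.mark = ","), format(fl$total, big.mark = ","),
    fl$pct_correct, sl$correct, sl$total, sl$pct_correct,
    format(fh$correct, big.mark = ","), format(fh$total, big.mark = ","),
    fh$pct_correct, sh$correct, sh$total, sh$pct_correct)
}
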