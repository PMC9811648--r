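#' Greedy removal of highly correlated features
#'
#' Iteratively removes features until no pair of survivors has
#' `|Pearson r| >= r_threshold`. At each step the pair with the largest
#' `|r|` is found and the member with the larger mean absolute correlation
#' to all remaining features is dropped (the caret-style victim rule);
#' ties are broken alphabetically (the alphabetically later name is
#' dropped). Zero-variance columns are dropped first. Correlations use
#' pairwise-complete observations, so missing-flagged frames are tolerated.
#'
#' @param table Data frame containing the feature columns (other columns
#'   ignored).
#' @param features Character vector of feature columns to screen (default:
#'   the intersection of [distress_features()] with `names(table)`).
#' @param r_threshold Absolute-correlation threshold (default 0.9).
#' @return An object of class `screening_report`: list with `kept`,
#'   `dropped` (tibble: `feature`, `partner`, `abs_r`, `reason`) and
#'   `r_threshold`.
#' @export
prune_correlated <- function(table, features = NULL, r_threshold = 0.9) {
  if (is.null(features))
    features <- intersect(distress_features(), names(table))
  if (length(features) < 2) stop("need at least 2 feature columns")
  x <- as.data.frame(table)[features]
  if (nrow(x) < 3) stop("need at least 3 rows")

  dropped <- tibble::tibble(feature = character(0), partner = character(0),
                            abs_r = numeric(0), reason = character(0))
  sds <- vapply(x, function(col) stats::sd(col, na.rm = TRUE), numeric(1))
  const <- names(x)[is.na(sds) | sds == 0]
  for (f in sort(const)) {
    dropped <- dplyr::add_row(dropped, feature = f, partner = NA_character_,
                              abs_r = NA_real_, reason = "zero variance")
  }
  keep <- setdiff(features, const)

  while (length(keep) >= 2) {
    r <- abs(stats::cor(x[keep], use = "pairwise.complete.obs"))
    diag(r) <- 0
    r[is.na(r)] <- 0
    if (max(r) < r_threshold) break
    # worst pair; ties resolved by alphabetical order of the pair names
    idx <- which(r == max(r), arr.ind = TRUE)
    pair <- sort(c(rownames(r)[idx[1, 1]], colnames(r)[idx[1, 2]]))
    mean_abs <- rowMeans(r)
    victim <- if (mean_abs[pair[1]] > mean_abs[pair[2]]) pair[1]
              else if (mean_abs[pair[2]] > mean_abs[pair[1]]) pair[2]
              else pair[2]   # tie: drop the alphabetically later
    partner <- setdiff(pair, victim)
    dropped <- dplyr::add_row(dropped, feature = victim, partner = partner,
                              abs_r = r[pair[1], pair[2]],
                              reason = "high correlation")
    keep <- setdiff(keep, victim)
  }

  structure(list(kept = keep, dropped = dropped,
                 r_threshold = r_threshold),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> kept %d, dropped %d at |r| >= %g\n",
              length(x$kept), nrow(x$dropped), x$r_threshold))
  if (nrow(x$dropped)) print(x$dropped)
  invisible(x)
}

#' @rdname prune_correlated
#' @param x A `screening_report`.
#' @param ... Unused.
#' @method tidy screening_report
#' @export
tidy.screening_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(feature = x$kept, partner = NA_character_,
                   abs_r = NA_real_, reason = NA_character_,
                   status = "kept"),
    dplyr::mutate(x$dropped, status = "dropped")
  )
}
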