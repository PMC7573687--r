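#' Cleanliness categories and threshold triples
#'
#' The cleanliness evaluation score is a four-category ordinal scale:
#' Poor (1, dense intestinal content impeding evaluation), Fair (2, only
#' partial evaluation possible), Good (3, some content, not impeding
#' evaluation), Excellent (4, no intestinal content). A `threshold_triple`
#' holds the three cut-points on the mean dirty probability that separate
#' the categories, ordered `0 <= t1 < t2 < t3 <= 1` with `t1` between
#' Excellent and Good, `t2` between Good and Fair, `t3` between Fair and
#' Poor.
#'
#' @param t1,t2,t3 cut-points (Excellent/Good, Good/Fair, Fair/Poor).
#' @return a numeric vector of class `threshold_triple`.
#' @export
threshold_triple <- function(t1, t2, t3) {
  t <- c(t1 = t1, t2 = t2, t3 = t3)
  if (any(!is.finite(t)) || t[1] < 0 || t[3] > 1 || t[1] >= t[2] ||
      t[2] >= t[3])
    stop("thresholds must satisfy 0 <= t1 < t2 < t3 <= 1")
  structure(t, class = "threshold_triple")
}

#' Category labels of the cleanliness scale
#' @export
cleanliness_levels <- function() c("Poor", "Fair", "Good", "Excellent")

#' Categorise mean dirty probabilities
#'
#' `p < t1` maps to Excellent, `t1 <= p < t2` to Good, `t2 <= p < t3` to
#' Fair and `p >= t3` to Poor: a mean exactly on a threshold falls in the
#' dirtier-adjacent (less clean) category. Returns an ordered factor
#' `Poor < Fair < Good < Excellent` whose integer codes are the 1..4
#' encoding used in rating tables.
#'
#' @param mean_prob numeric vector in `[0, 1]`.
#' @param thresholds a [threshold_triple()].
#' @return ordered factor of the same length.
#' @export
categorize <- function(mean_prob, thresholds) {
  stopifnot(inherits(thresholds, "threshold_triple"))
  if (any(mean_prob < 0 | mean_prob > 1, na.rm = TRUE))
    stop("mean_prob must lie in [0, 1]")
  code <- categorize_code(mean_prob, thresholds)
  factor(cleanliness_levels()[code], levels = cleanliness_levels(),
         ordered = TRUE)
}

# integer codes 1=Poor .. 4=Excellent; vectorised workhorse
categorize_code <- function(mean_prob, thresholds) {
  4L - findInterval(mean_prob, unclass(thresholds))
}

#' Score a frame end to end
#'
#' Composition of the full per-frame pipeline: FOV detection, patch grid,
#' patch extraction, CNN dirty probabilities, pixel interpolation, FOV mean,
#' categorisation. Deterministic: the same frame with the same model and
#' thresholds always receives the same score (the method's intrarater
#' reliability is exactly 1).
#'
#' @param frame a [ce_frame()].
#' @param model a trained `nn_model`.
#' @param thresholds a [threshold_triple()].
#' @param intensity_threshold FOV detection threshold (default 10).
#' @param mask optional precomputed `fov_mask` (skips detection).
#' @return list of class `cleanliness_score`: `category` (ordered factor),
#'   `code` (1..4), `mean_prob`, `pixel_map`, `frame_id`, `video_id`.
#' @export
score_frame <- function(frame, model, thresholds, intensity_threshold = 10L,
                        mask = NULL) {
  stopifnot(inherits(frame, "ce_frame"), inherits(model, "nn_model"))
  if (is.null(mask)) mask <- detect_fov_mask(frame, intensity_threshold)
  grid <- build_patch_grid(mask)
  patches <- extract_patches(frame, grid)
  probs <- nn_predict(model, patches)[, "dirty"]
  pxm <- interpolate_pixel_probabilities(patch_probability_map(grid, probs),
                                         mask)
  mp <- mean_dirty_probability(pxm)
  cat_f <- categorize(mp, thresholds)
  structure(list(category = cat_f, code = as.integer(cat_f),
                 mean_prob = mp, pixel_map = pxm,
                 frame_id = frame$frame_id, video_id = frame$video_id),
            class = "cleanliness_score")
}

#' @export
print.cleanliness_score <- function(x, ...) {
  cat(sprintf("frame %s (video %s): %s (mean dirty probability %.3f)\n",
              x$frame_id, x$video_id, as.character(x$category), x$mean_prob))
  invisible(x)
}

#' Write per-frame scores to CSV
#'
#' Layout `frame_id,video_id,mean_prob,category`, mirroring per-frame score
#' tables used in clinical validation.
#'
#' @param scores list of `cleanliness_score` objects, or a data.frame with
#'   the four columns.
#' @param path CSV path.
#' @export
write_scores <- function(scores, path) {
  df <- if (is.data.frame(scores)) scores else
    do.call(rbind, lapply(scores, function(s)
      data.frame(frame_id = s$frame_id, video_id = s$video_id,
                 mean_prob = s$mean_prob,
                 category = as.character(s$category))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
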