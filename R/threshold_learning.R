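#' Grouped k-fold assignment of videos
#'
#' Deals whole videos into folds so that all frames of one video (one
#' patient) share a fold — the grouping that prevents leakage between
#' threshold learning and validation frames.
#'
#' @param video_ids character vector of video identifiers (one entry per
#'   video, or per frame — duplicates are collapsed).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return object of class `grouped_folds`: list with `n_folds`,
#'   `video_to_fold` (named integer vector), `seed`.
#' @export
grouped_kfold <- function(video_ids, n_folds = 5L, seed = 1L) {
  vids <- unique(as.character(video_ids))
  if (length(vids) < n_folds)
    stop("fewer videos (", length(vids), ") than folds (", n_folds, ")")
  shuffled <- with_seed(seed, sample(vids))
  fold <- rep_len(seq_len(n_folds), length(vids))
  structure(list(n_folds = as.integer(n_folds),
                 video_to_fold = stats::setNames(fold, shuffled)[vids],
                 seed = seed),
            class = "grouped_folds")
}

#' Fold label of each frame
#'
#' @param folds a `grouped_folds`.
#' @param video_ids per-frame video ids.
#' @return integer vector of fold labels per frame.
#' @export
frame_folds <- function(folds, video_ids) {
  f <- folds$video_to_fold[as.character(video_ids)]
  if (anyNA(f)) stop("video missing from fold assignment: ",
                     video_ids[which(is.na(f))[1]])
  unname(f)
}

#' Threshold search configuration
#'
#' @param resolution grid step on `[0, 1]` (default 0.01).
#' @param objective `"three_rater"` (default): ICC(C,1) over the 3-column
#'   table method + expert 1 + expert 2; `"pairwise_mean"`: mean of the two
#'   2-rater ICC(C,1) values (method, expert).
#' @return list of class `threshold_search_config`.
#' @export
threshold_search_config <- function(resolution = 0.01,
                                    objective = c("three_rater",
                                                  "pairwise_mean")) {
  stopifnot(resolution > 0, resolution < 0.5)
  structure(list(resolution = resolution, objective = match.arg(objective)),
            class = "threshold_search_config")
}

# ICC(C,1) ingredients that depend only on the grand sums of an n x m table:
# returns the ICC given sum, sum of squares, sum of squared row totals and
# sum of squared column totals (vectorised over candidates).
icc_c1_from_sums <- function(S, SSq, R2, C2, n, m) {
  corr <- S^2 / (n * m)
  SST <- SSq - corr
  SSR <- R2 / m - corr
  SSC <- C2 / n - corr
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSE <- SSE / ((n - 1) * (m - 1))
  den <- MSR + (m - 1) * MSE
  ifelse(abs(den) < 1e-12 | SST < 1e-12, NA_real_, (MSR - MSE) / den)
}

#' Learn categorisation thresholds by maximising consistency ICC
#'
#' Exhaustively searches ordered triples `t1 < t2 < t3` on a regular grid.
#' For each triple every frame's mean dirty probability is categorised, the
#' resulting method scores are placed next to the two experts' scores as a
#' third rater, and the single-rater consistency ICC, ICC(C,1), of that
#' table is computed; the argmax triple is returned, ties broken by the
#' lexicographically smallest triple. The search is evaluated through an
#' O(1)-per-triple prefix-sum formulation, so the full 0.01 grid
#' (~1.6e5 triples) takes well under a second for hundreds of frames.
#'
#' @param mean_probs per-frame mean dirty probabilities in `[0, 1]`.
#' @param expert_scores `n x 2` matrix (or `rating_table`) of expert scores
#'   in 1..4 (1 = Poor .. 4 = Excellent), rows aligned with `mean_probs`.
#' @param cfg a [threshold_search_config()].
#' @return a [threshold_triple()] with attributes `icc_c1` (objective at the
#'   optimum) and `objective`.
#' @export
learn_thresholds <- function(mean_probs, expert_scores,
                             cfg = threshold_search_config()) {
  E <- as.matrix(unclass(expert_scores))
  if (ncol(E) < 2L) stop("need scores from two experts")
  E <- E[, 1:2, drop = FALSE]
  n <- length(mean_probs)
  if (nrow(E) != n) stop("expert_scores rows must align with mean_probs")
  if (any(mean_probs < 0 | mean_probs > 1)) stop("mean_probs must lie in [0, 1]")
  if (stats::sd(mean_probs) < 1e-12)
    stop("degenerate input: all frames have identical mean probability")
  grid <- seq(cfg$resolution, 1 - cfg$resolution, by = cfg$resolution)
  grid <- round(grid / cfg$resolution) * cfg$resolution # exact decimals
  ng <- length(grid)
  ord <- order(mean_probs)
  p_sorted <- mean_probs[ord]
  # cuts[g] = number of frames with p < grid[g]
  cuts <- findInterval(grid - 1e-9, p_sorted)
  # all ordered triples (ia < ib < ic index into grid), lexicographic order
  combs <- utils::combn(ng, 3L)
  ia <- combs[1L, ]; ib <- combs[2L, ]; ic <- combs[3L, ]
  a <- cuts[ia]; b <- cuts[ib]; c <- cuts[ic]
  # method scores in sorted-p order: first a frames get 4 (Excellent),
  # then 3, 2, and 1 beyond cut c. Prefix sums give all table sums in O(1).
  m_sum <- n + a + b + c
  m_sq <- n + 7 * a + 5 * b + 3 * c
  if (cfg$objective == "three_rater") {
    Erow <- rowSums(E)[ord]
    PE <- c(0, cumsum(Erow))
    cross <- PE[n + 1L] + PE[a + 1L] + PE[b + 1L] + PE[c + 1L]
    S <- m_sum + sum(Erow)
    SSq <- m_sq + sum(E^2)
    R2 <- m_sq + 2 * cross + sum(Erow^2)
    C2 <- m_sum^2 + sum(colSums(E)^2)
    obj <- icc_c1_from_sums(S, SSq, R2, C2, n, 3L)
  } else {
    obj <- 0
    for (j in 1:2) {
      e <- E[ord, j]
      PEj <- c(0, cumsum(e))
      crossj <- PEj[n + 1L] + PEj[a + 1L] + PEj[b + 1L] + PEj[c + 1L]
      S <- m_sum + sum(e)
      SSq <- m_sq + sum(e^2)
      R2 <- m_sq + 2 * crossj + sum(e^2)
      C2 <- m_sum^2 + sum(e)^2
      obj <- obj + icc_c1_from_sums(S, SSq, R2, C2, n, 2L) / 2
    }
  }
  if (all(is.na(obj))) stop("objective undefined on the entire grid")
  best <- which.max(obj) # first maximum = lexicographically smallest triple
  out <- threshold_triple(grid[ia[best]], grid[ib[best]], grid[ic[best]])
  attr(out, "icc_c1") <- obj[best]
  attr(out, "objective") <- cfg$objective
  out
}

# direct (slow) objective evaluation for one triple; used as an oracle by
# the tests and for the per-fold reporting
threshold_objective <- function(t, mean_probs, expert_scores,
                                objective = "three_rater") {
  E <- as.matrix(unclass(expert_scores))[, 1:2, drop = FALSE]
  s <- categorize_code(mean_probs, t)
  if (objective == "three_rater") {
    r <- icc_single(rating_table(cbind(method = s, E)), "C1")
    r$icc
  } else {
    mean(c(icc_single(rating_table(cbind(s, E[, 1L])), "C1")$icc,
           icc_single(rating_table(cbind(s, E[, 2L])), "C1")$icc))
  }
}

#' Cross-validated threshold learning and out-of-fold scoring
#'
#' For every fold of a grouped assignment, thresholds are learned on the
#' frames of all *other* folds and applied to the held-out frames, so each
#' frame receives exactly one method score from thresholds that never saw
#' it. Returns the out-of-fold scores, the per-fold threshold triples and
#' their mean and standard deviation.
#'
#' @param mean_probs per-frame mean dirty probabilities.
#' @param expert_scores `n x 2` matrix of expert scores aligned with
#'   `mean_probs`.
#' @param video_ids per-frame video identifiers.
#' @param folds a [grouped_kfold()] assignment of those videos.
#' @param cfg a [threshold_search_config()].
#' @return list of class `cv_threshold_result`: `scores` (data.frame
#'   `frame`, `video_id`, `fold`, `mean_prob`, `method_code`,
#'   `method_category`), `fold_thresholds` (data.frame `fold,t1,t2,t3,icc`),
#'   `summary` (mean and SD per threshold).
#' @export
cross_validated_scores <- function(mean_probs, expert_scores, video_ids,
                                   folds, cfg = threshold_search_config()) {
  stopifnot(inherits(folds, "grouped_folds"))
  ff <- frame_folds(folds, video_ids)
  n <- length(mean_probs)
  E <- as.matrix(unclass(expert_scores))
  method_code <- integer(n)
  trip <- list()
  for (f in sort(unique(ff))) {
    hold <- ff == f
    t_f <- learn_thresholds(mean_probs[!hold], E[!hold, , drop = FALSE], cfg)
    method_code[hold] <- categorize_code(mean_probs[hold], t_f)
    trip[[as.character(f)]] <-
      data.frame(fold = f, t1 = t_f[["t1"]], t2 = t_f[["t2"]],
                 t3 = t_f[["t3"]], icc = attr(t_f, "icc_c1"))
  }
  ft <- do.call(rbind, trip)
  summ <- data.frame(
    threshold = c("t1", "t2", "t3"),
    boundary = c("Excellent/Good", "Good/Fair", "Fair/Poor"),
    mean = colMeans(ft[, c("t1", "t2", "t3")]),
    sd = apply(ft[, c("t1", "t2", "t3")], 2L, stats::sd))
  structure(list(
    scores = data.frame(frame = seq_len(n), video_id = as.character(video_ids),
                        fold = ff, mean_prob = mean_probs,
                        method_code = method_code,
                        method_category = cleanliness_levels()[method_code]),
    fold_thresholds = ft, summary = summ),
    class = "cv_threshold_result")
}

#' Persist learned thresholds as JSON
#'
#' @param thresholds a [threshold_triple()] (attributes `icc_c1`, `fold`,
#'   `seed` included when present).
#' @param path JSON path.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(list(t1 = thresholds[["t1"]], t2 = thresholds[["t2"]],
                            t3 = thresholds[["t3"]],
                            icc_c1 = attr(thresholds, "icc_c1"),
                            objective = attr(thresholds, "objective")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- threshold_triple(x$t1, x$t2, x$t3)
  attr(out, "icc_c1") <- x$icc_c1
  attr(out, "objective") <- x$objective
  out
}
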