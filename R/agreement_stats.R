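#' Rating tables
#'
#' A rating table is a complete `frames x raters` matrix of ordinal scores
#' in `1..k` (k = 4 for the cleanliness scale, 1 = Poor .. 4 = Excellent),
#' with frame and video identifiers attached. Missing cells are rejected,
#' not imputed.
#'
#' @param scores integer matrix or data.frame, one column per rater.
#' @param frame_id,video_id identifier vectors (defaults generated).
#' @param k number of categories (default 4).
#' @return object of class `rating_table`: the integer matrix with
#'   attributes `frame_id`, `video_id`, `k`.
#' @export
rating_table <- function(scores, frame_id = NULL, video_id = NULL, k = 4L) {
  m <- as.matrix(scores)
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop("rating table must be complete (no missing cells)")
  if (any(m < 1L | m > k)) stop("ratings must lie in 1..", k)
  if (nrow(m) < 2L) stop("need at least 2 rated frames")
  structure(m,
            frame_id = as.character(frame_id %||% seq_len(nrow(m))),
            video_id = as.character(video_id %||% rep("v1", nrow(m))),
            k = as.integer(k), class = "rating_table")
}

#' Read ratings from CSV
#'
#' Long format has columns `frame_id,video_id,rater,score`; wide format has
#' `frame_id,video_id` followed by one score column per rater. Scores may be
#' integers `1..k` or category names, remapped through `category_levels`
#' (position = integer code).
#'
#' @param path CSV path.
#' @param format `"long"` or `"wide"`.
#' @param k number of categories.
#' @param category_levels character vector mapping names to codes; default
#'   [cleanliness_levels()].
#' @return a [rating_table()].
#' @export
read_ratings <- function(path, format = c("long", "wide"), k = 4L,
                         category_levels = cleanliness_levels()) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  decode <- function(x) {
    if (is.character(x)) {
      code <- match(x, category_levels)
      if (anyNA(code)) stop("unknown category name in ", path)
      code
    } else as.integer(x)
  }
  if (format == "long") {
    need <- c("frame_id", "video_id", "rater", "score")
    if (!all(need %in% names(df))) stop("long format needs columns ",
                                        paste(need, collapse = ","))
    wide <- stats::reshape(df[, need], idvar = c("frame_id", "video_id"),
                           timevar = "rater", direction = "wide")
    scores <- as.matrix(wide[, -(1:2), drop = FALSE])
    colnames(scores) <- sub("^score\\.", "", colnames(scores))
    rating_table(apply(scores, 2L, decode), wide$frame_id, wide$video_id, k)
  } else {
    raters <- setdiff(names(df), c("frame_id", "video_id"))
    scores <- vapply(df[raters], decode, integer(nrow(df)))
    rating_table(scores, df$frame_id, df$video_id, k)
  }
}

# weight matrices for agreement with partial credit
kappa_weights <- function(k, scheme = c("linear", "quadratic", "identity")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(scheme,
    linear = 1 - d / (k - 1),
    quadratic = 1 - (d / (k - 1))^2,
    identity = (d == 0) * 1)
}

#' Cohen's weighted kappa with confidence interval
#'
#' Chance-corrected agreement between two raters on a k-category ordinal
#' scale, with partial credit `w_ij = 1 - |i - j| / (k - 1)` for linear
#' weights (the default; quadratic weights systematically inflate agreement
#' and are provided only for cross-checks). The confidence interval is
#' `kappa +/- z * SE` with the large-sample standard error of Fleiss, Cohen
#' and Everitt.
#'
#' @param a,b integer vectors of ratings in `1..k`, equal length.
#' @param k number of categories (default 4).
#' @param weights weighting scheme.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `weighted_kappa`: list with `kappa`, `se`,
#'   `ci95`, `weights`, `n`, `po`, `pe`. `kappa` is `NA` with a degenerate
#'   flag when chance agreement is 1 (both raters constant on one category).
#' @export
linear_weighted_kappa <- function(a, b, k = 4L,
                                  weights = c("linear", "quadratic",
                                              "identity"),
                                  conf_level = 0.95) {
  if (length(a) != length(b)) stop("rating vectors differ in length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 rated frames")
  a <- as.integer(a); b <- as.integer(b)
  if (any(c(a, b) < 1L | c(a, b) > k)) stop("ratings must lie in 1..", k)
  W <- kappa_weights(k, weights)
  f <- table(factor(a, 1:k), factor(b, 1:k)) / n   # joint proportions
  r <- rowSums(f); c <- colSums(f)
  po <- sum(W * f)
  pe <- sum(W * outer(r, c))
  if (abs(1 - pe) < 1e-12)
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          ci95 = c(NA_real_, NA_real_), weights = W, n = n,
                          po = po, pe = pe, degenerate = TRUE),
                     class = "weighted_kappa"))
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance of the weighted kappa
  wbar_i <- as.numeric(W %*% c)   # row-conditional expected weights
  wbar_j <- as.numeric(r %*% W)
  term <- outer(wbar_i, wbar_j, "+")
  ssq <- sum(f * (W * (1 - pe) - term * (1 - po))^2)
  var_k <- (ssq - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 ci95 = c(max(kappa - z * se, -1), min(kappa + z * se, 1)),
                 weights = W, n = n, po = po, pe = pe, degenerate = FALSE),
            class = "weighted_kappa")
}

#' @export
print.weighted_kappa <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("weighted kappa: undefined (pe = 1)\n")
  else cat(sprintf("weighted kappa %.3f (95%% CI %.3f, %.3f), n = %d\n",
                   x$kappa, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Single-rater intraclass correlation (two-way model)
#'
#' Computes ICC(C,1) (consistency: systematic rater offsets do not count as
#' disagreement) or ICC(A,1) (absolute agreement) from the two-way ANOVA
#' decomposition of a complete `n x m` rating table, following McGraw &
#' Wong's definitions for a two-way mixed model with single-rater
#' reliability, with the corresponding F-based confidence intervals. Ordinal
#' scores are treated as interval numbers.
#'
#' @param table a [rating_table()] or plain numeric `n x m` matrix.
#' @param form `"C1"` (consistency) or `"A1"` (absolute agreement).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: list with `icc`, `ci95`, `form`,
#'   `ms` (named MSR, MSC, MSE), `n`, `m`. Constant tables give a degenerate
#'   `NA` result.
#' @export
icc_single <- function(table, form = c("C1", "A1"), conf_level = 0.95) {
  form <- match.arg(form)
  m0 <- unclass(table)
  attributes(m0) <- list(dim = dim(m0))
  n <- nrow(m0); m <- ncol(m0)
  if (n < 2L || m < 2L) stop("need at least 2 frames and 2 raters")
  if (anyNA(m0)) stop("rating table must be complete")
  x <- m0 * 1.0
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SSR <- m * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (m - 1)
  MSE <- SSE / ((n - 1) * (m - 1))
  ms <- c(MSR = MSR, MSC = MSC, MSE = MSE)
  if (SST < 1e-12)
    return(structure(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                          form = form, ms = ms, n = n, m = m,
                          degenerate = TRUE), class = "icc_result"))
  alpha <- 1 - conf_level
  if (form == "C1") {
    icc <- (MSR - MSE) / (MSR + (m - 1) * MSE)
    Fobs <- MSR / MSE
    df1 <- n - 1; df2 <- (n - 1) * (m - 1)
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((FL - 1) / (FL + m - 1), (FU - 1) / (FU + m - 1))
  } else {
    icc <- (MSR - MSE) /
      (MSR + (m - 1) * MSE + (m / n) * (MSC - MSE))
    # Satterthwaite-approximated interval (McGraw & Wong case 2/3, single)
    a <- (m * icc) / (n * (1 - icc))
    b <- 1 + (m * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (m - 1) + (b * MSE)^2 / ((n - 1) * (m - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (m * MSC + (m * n - m - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (m * MSC + (m * n - m - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci95 = ci, form = form, ms = ms, n = n, m = m,
                 degenerate = FALSE), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  lab <- if (x$form == "C1") "ICC(C,1)" else "ICC(A,1)"
  if (isTRUE(x$degenerate)) cat(lab, ": undefined (no variance)\n")
  else cat(sprintf("%s = %.3f (95%% CI %.3f, %.3f), n = %d frames, %d raters\n",
                   lab, x$icc, x$ci95[1], x$ci95[2], x$n, x$m))
  invisible(x)
}

#' Per-fold and pooled weighted kappa for every rater pair
#'
#' Computes the linearly weighted kappa separately inside each fold of a
#' grouped cross-validation and on the concatenation of all folds, for every
#' pair of raters in the table — the per-video-fold agreement picture used
#' to compare the automatic method against each human specialist.
#'
#' @param table a [rating_table()].
#' @param folds integer vector of fold labels, one per frame (e.g. from
#'   [grouped_kfold()] applied to the table's videos).
#' @param k number of categories.
#' @return data.frame with columns `rater_a`, `rater_b`, `fold` (`"pooled"`
#'   for the concatenation), `kappa`, `ci_lower`, `ci_upper`, `n`.
#' @export
per_fold_kappa_report <- function(table, folds, k = attr(table, "k") %||% 4L) {
  stopifnot(inherits(table, "rating_table"))
  if (length(folds) != nrow(table))
    stop("folds must label every frame of the table")
  raters <- colnames(table) %||% paste0("rater", seq_len(ncol(table)))
  pairs <- utils::combn(seq_len(ncol(table)), 2L)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    for (f in c(sort(unique(folds)), "pooled")) {
      sel <- if (identical(f, "pooled")) rep(TRUE, nrow(table))
             else folds == f
      if (sum(sel) < 2L) stop("fold ", f, " has fewer than 2 frames")
      kp <- linear_weighted_kappa(table[sel, i], table[sel, j], k = k)
      rows[[length(rows) + 1L]] <-
        data.frame(rater_a = raters[i], rater_b = raters[j],
                   fold = as.character(f), kappa = kp$kappa,
                   ci_lower = kp$ci95[1], ci_upper = kp$ci95[2],
                   n = kp$n)
    }
  }
  do.call(rbind, rows)
}

#' Plot a per-fold kappa report
#'
#' Point estimates with 95% CI whiskers per fold and pooled, one panel per
#' rater pair. Requires ggplot2.
#'
#' @param report output of [per_fold_kappa_report()].
#' @return a ggplot object.
#' @export
plot_kappa_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_kappa_report requires ggplot2")
  report$pair <- paste(report$rater_a, "vs", report$rater_b)
  report$fold <- factor(report$fold,
                        c(setdiff(sort(unique(report$fold)), "pooled"),
                          "pooled"))
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$fold, y = .data$kappa,
                               colour = .data$pair, group = .data$pair)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = expression(kappa[1]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
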