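#' Image-level k-fold split
#'
#' Frames (not patches) are shuffled and dealt into `n_folds` folds of equal
#' size (sizes differ by at most one frame), so that the patches of the test
#' fold always originate from different images than the training patches.
#'
#' @param frame_ids character vector of unique frame identifiers.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return object of class `fold_assignment`: list with `n_folds`,
#'   `image_to_fold` (named integer vector, values in `1..n_folds`), `seed`.
#' @export
split_images_into_folds <- function(frame_ids, n_folds = 5L, seed = 1L) {
  frame_ids <- as.character(frame_ids)
  if (anyDuplicated(frame_ids)) stop("frame_ids must be unique")
  n <- length(frame_ids)
  if (n < n_folds) stop("fewer frames (", n, ") than folds (", n_folds, ")")
  shuffled <- with_seed(seed, sample(frame_ids))
  fold <- rep_len(seq_len(n_folds), n) # dealt round-robin: sizes differ <= 1
  image_to_fold <- stats::setNames(fold, shuffled)[frame_ids]
  structure(list(n_folds = as.integer(n_folds),
                 image_to_fold = image_to_fold, seed = seed),
            class = "fold_assignment")
}

#' Frames of the test / training side of one fold
#'
#' @param fa a `fold_assignment`.
#' @param fold fold index in `1..n_folds`.
#' @return character vector of frame ids.
#' @export
fold_test_frames <- function(fa, fold) {
  names(fa$image_to_fold)[fa$image_to_fold == fold]
}

#' @rdname fold_test_frames
#' @export
fold_train_frames <- function(fa, fold) {
  names(fa$image_to_fold)[fa$image_to_fold != fold]
}

#' Cap class imbalance by undersampling the majority class
#'
#' If the majority class holds more than 10% more patches than the minority
#' class, randomly selected majority patches are removed until the majority
#' count equals `floor(1.1 * minority)`; otherwise the input is returned
#' unchanged. The minority class is never touched.
#'
#' @param patches annotation data.frame with a `label` column in
#'   `{"clean", "dirty"}`.
#' @param seed integer seed for the random removal.
#' @param max_excess allowed fractional excess of the majority class
#'   (default 0.1).
#' @return a subset of `patches` (row order of survivors preserved).
#' @export
undersample_to_ten_percent <- function(patches, seed = 1L, max_excess = 0.1) {
  counts <- table(factor(patches$label, levels = c("clean", "dirty")))
  if (any(counts == 0L))
    stop("both classes must be present (got ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(c("clean", "dirty"), minority)
  n_min <- min(counts); n_maj <- max(counts)
  cap <- floor((1 + max_excess) * n_min)
  if (n_maj <= cap) return(patches)
  maj_idx <- which(patches$label == majority)
  drop <- with_seed(seed, sample(maj_idx, n_maj - cap))
  patches[-drop, , drop = FALSE]
}

#' 80-20 train/validation split
#'
#' Splits a patch set into a training part of `round(fraction * n)` patches
#' and a validation part holding the rest, deterministically for a fixed seed.
#'
#' @param patches data.frame (or anything indexable by row) of patches.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with elements `train` and `val`.
#' @export
train_val_split <- function(patches, fraction = 0.8, seed = 1L) {
  n <- if (is.data.frame(patches)) nrow(patches) else length(patches)
  if (n < 2L) stop("need at least 2 patches to split")
  n_train <- round(fraction * n)
  idx <- with_seed(seed, sample(n, n_train))
  take <- function(x, i) if (is.data.frame(x)) x[i, , drop = FALSE] else x[i]
  list(train = take(patches, sort(idx)),
       val = take(patches, sort(setdiff(seq_len(n), idx))))
}

#' Write a fold manifest
#'
#' @param fa a `fold_assignment`.
#' @param video_ids named character vector mapping frame id to video id (or a
#'   single video id recycled).
#' @param path CSV output path, columns `frame_id,video_id,fold`.
#' @export
write_fold_manifest <- function(fa, video_ids, path) {
  ids <- names(fa$image_to_fold)
  vid <- if (length(video_ids) == 1L) rep(video_ids, length(ids))
         else video_ids[ids]
  utils::write.csv(
    data.frame(frame_id = ids, video_id = unname(vid),
               fold = unname(fa$image_to_fold)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
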