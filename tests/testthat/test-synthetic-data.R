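test_that("frame generation is deterministic and honours its geometry", {
  p <- synthetic_frame_params(size = 256L, fov_radius = 120L,
                              dirty_fraction = 0.3, seed = 8)
  g1 <- generate_frame(p)
  g2 <- generate_frame(p)
  expect_identical(g1$frame$pixels, g2$frame$pixels)       # bit-identical
  expect_identical(g1$ground_truth$dirty_mask, g2$ground_truth$dirty_mask)
  g3 <- generate_frame(synthetic_frame_params(size = 256L, fov_radius = 120L,
                                              dirty_fraction = 0.3, seed = 9))
  expect_false(identical(g1$frame$pixels, g3$frame$pixels))
  # black outside the disk, lit inside
  expect_true(all(g1$frame$pixels[!g1$mask] == 0))
  maxc <- pmax(g1$frame$pixels[, , 1], g1$frame$pixels[, , 2],
               g1$frame$pixels[, , 3])
  expect_true(all(maxc[g1$mask] > 10))
  # content stays inside the FOV and hits the target fraction
  expect_true(all(g1$mask[g1$ground_truth$dirty_mask]))
  expect_lt(abs(g1$ground_truth$dirty_fraction - 0.3), 0.05)
})

test_that("saturated and empty content targets behave as limits", {
  clean <- generate_frame(synthetic_frame_params(size = 256L,
                                                 fov_radius = 120L,
                                                 dirty_fraction = 0, seed = 1))
  expect_false(any(clean$ground_truth$dirty_mask))
  grid <- build_patch_grid(clean$mask)
  ann <- derive_patch_labels(clean$ground_truth, grid)
  expect_true(all(ann$label == "clean"))
  expect_equal(nrow(ann), nrow(grid$anchors)) # nothing is mixed

  dirty <- generate_frame(synthetic_frame_params(
    size = 256L, fov_radius = 120L, dirty_fraction = 1,
    content_types = "bile_blob", seed = 1))
  expect_gte(sum(dirty$ground_truth$dirty_mask) / sum(dirty$mask), 0.95)
})

test_that("patch labels agree with a brute-force footprint scan", {
  g <- generate_frame(synthetic_frame_params(size = 256L, fov_radius = 120L,
                                             dirty_fraction = 0.45, seed = 5))
  grid <- build_patch_grid(g$mask)
  ann <- derive_patch_labels(g$ground_truth, grid)
  n_dirty <- n_clean <- n_mixed <- 0L
  for (i in seq_len(nrow(grid$anchors))) {
    r <- grid$anchors[i, 1]; c <- grid$anchors[i, 2]
    block <- g$ground_truth$dirty_mask[(r + 1):(r + 64), (c + 1):(c + 64)]
    if (all(block)) n_dirty <- n_dirty + 1L
    else if (!any(block)) n_clean <- n_clean + 1L
    else n_mixed <- n_mixed + 1L
  }
  expect_equal(sum(ann$label == "dirty"), n_dirty)
  expect_equal(sum(ann$label == "clean"), n_clean)
  expect_equal(nrow(ann) + n_mixed, nrow(grid$anchors))
  expect_gt(n_mixed, 0L) # a 45% coverage frame has transition patches
})

test_that("datasets emulate the video/frame corpus structure", {
  ds <- generate_dataset(n_videos = 4, frames_per_video = 3, seed = 2,
                         size = 224L, fov_radius = 100L)
  expect_length(ds$frames, 12L)
  expect_equal(nrow(ds$manifest), 12L)
  expect_equal(length(unique(ds$manifest$video_id)), 4L)
  # annotation rows reference existing frames and lattice anchors
  expect_true(all(ds$annotations$frame_id %in% ds$manifest$frame_id))
  expect_true(all(ds$annotations$row %% 32 == 0))
  expect_true(all(ds$annotations$label %in% c("clean", "dirty")))
  # manifest supports grouped folds
  gf <- grouped_kfold(ds$manifest$video_id, 4, seed = 1)
  expect_silent(frame_folds(gf, ds$manifest$video_id))
  # on-disk dialect round-trips through the geometry loaders
  dir <- withr::local_tempdir()
  ds2 <- generate_dataset(n_videos = 1, frames_per_video = 1, seed = 3,
                          size = 224L, fov_radius = 100L, dir = dir)
  fid <- ds2$manifest$frame_id[1]
  frame <- read_frame(file.path(dir, paste0(fid, ".png")), video_id = "v")
  expect_identical(frame$pixels, ds2$frames[[fid]]$frame$pixels)
  mask <- read_fov_mask(file.path(dir, paste0(fid, "_mask.png")))
  expect_identical(unclass(mask), unclass(ds2$frames[[fid]]$mask))
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(nrow(ann), nrow(ds2$annotations))
})

test_that("rating studies are deterministic with calibrated rater noise", {
  truth <- threshold_triple(0.42, 0.66, 0.94)
  rs0 <- generate_rating_study(5, 10, truth, flip_prob = 0, seed = 4)
  # zero flips: experts identical, agreement perfect
  expect_identical(rs0$ratings[, 1], rs0$ratings[, 2])
  expect_equal(linear_weighted_kappa(rs0$ratings[, 1],
                                     rs0$ratings[, 2])$kappa, 1)
  expect_identical(unname(rs0$ratings[, 1]), rs0$true_scores)
  rs0b <- generate_rating_study(5, 10, truth, flip_prob = 0, seed = 4)
  expect_identical(rs0$mean_probs, rs0b$mean_probs)

  rs <- generate_rating_study(20, 10, truth, flip_prob = 0.2, seed = 4)
  expect_true(all(unclass(rs$ratings) %in% 1:4))
  # flips move scores by at most one category
  expect_true(all(abs(unclass(rs$ratings) - rs$true_scores) <= 1))
  # realised flip rate is near its target
  rate <- mean(unclass(rs$ratings) != rs$true_scores)
  expect_lt(abs(rate - 0.2), 0.06)
  expect_error(generate_rating_study(2, 5, truth, flip_prob = 0.6),
               "flip_prob")
})
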