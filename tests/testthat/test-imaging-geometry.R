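test_that("FOV detection finds the recording area and rejects black frames", {
  expect_true(all(detect_fov_mask(tiny_gray_frame(128L))))

  g <- generate_frame(synthetic_frame_params(seed = 11, dirty_fraction = 0.3))
  m <- detect_fov_mask(g$frame)
  # any disagreement with the analytic disk stays on the disk boundary
  mismatch <- which(m != g$mask)
  if (length(mismatch)) {
    n <- nrow(m); centre <- (n + 1) / 2
    rr <- (mismatch - 1) %% n + 1; cc <- (mismatch - 1) %/% n + 1
    d <- sqrt((rr - centre)^2 + (cc - centre)^2)
    expect_true(all(abs(d - 280) <= 1.5))
  }
  expect_error(detect_fov_mask(tiny_gray_frame(64L, 0L)), "no recording area")
  # threshold is honoured: a frame entirely below it has no recording area
  expect_error(detect_fov_mask(tiny_gray_frame(64L, 5L), 10), "no recording area")
})

test_that("patch grid anchors tile the FOV with full containment", {
  full <- structure(matrix(TRUE, 576, 576), class = "fov_mask")
  grid <- build_patch_grid(full)
  expect_equal(nrow(grid$anchors), 289L) # 17 x 17
  expect_equal(sort(unique(grid$anchors[, 1L])), seq(0L, 512L, 32L))
  # row-major ordering
  expect_true(all(diff(grid$anchors[, 1L]) >= 0))

  one <- structure(matrix(TRUE, 64, 64), class = "fov_mask")
  g1 <- build_patch_grid(one)
  expect_identical(g1$anchors, matrix(c(0L, 0L), 1L,
                                      dimnames = list(NULL, c("row", "col"))))

  # disk mask: grid equals a brute-force containment scan over all candidates
  n <- 576; centre <- (n + 1) / 2
  d2 <- outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, "+")
  disk <- structure(d2 <= 280^2, class = "fov_mask")
  gd <- build_patch_grid(disk)
  brute <- list()
  for (r in seq(0L, 512L, 32L)) for (c in seq(0L, 512L, 32L))
    if (all(disk[(r + 1):(r + 64), (c + 1):(c + 64)]))
      brute[[length(brute) + 1L]] <- c(r, c)
  brute <- do.call(rbind, brute)
  expect_true(nrow(gd$anchors) > 0 && nrow(gd$anchors) < 289)
  expect_equal(unname(gd$anchors), unname(brute))

  tiny <- structure(matrix(TRUE, 32, 32), class = "fov_mask")
  expect_error(build_patch_grid(tiny), "FOV too small")
})

test_that("patch extraction slices the frame and scales to [0, 1]", {
  px <- array(0L, c(128, 128, 3))
  px[33:96, 65:128, 1] <- 255L            # red block at anchor (32, 64)
  frame <- ce_frame(px, "f", "v")
  mask <- structure(matrix(TRUE, 128, 128), class = "fov_mask")
  grid <- build_patch_grid(mask)
  patches <- extract_patches(frame, grid)
  expect_length(patches, nrow(grid$anchors))
  i <- which(grid$anchors[, 1] == 32 & grid$anchors[, 2] == 64)
  expect_equal(patches[[i]], px[33:96, 65:128, , drop = FALSE] / 255)
  expect_equal(max(patches[[i]]), 1.0)    # 255 -> 1
  zero <- extract_patches(ce_frame(array(0L, c(128, 128, 3)), "z", "v"), grid)
  expect_true(all(vapply(zero, function(p) all(p == 0), TRUE)))
})

test_that("50% overlap covers interior pixels with 2 patches per axis", {
  full <- structure(matrix(TRUE, 576, 576), class = "fov_mask")
  grid <- build_patch_grid(full)
  covers <- function(r, c) # number of anchors whose footprint holds (r, c)
    sum(grid$anchors[, 1] <= r & r < grid$anchors[, 1] + 64 &
          grid$anchors[, 2] <= c & c < grid$anchors[, 2] + 64)
  # patch 64 / stride 32: every interior pixel lies in exactly 2 footprints
  # along each axis, hence 4 in 2-D
  for (p in list(c(200, 300), c(96, 96), c(400, 133)))
    expect_equal(covers(p[1], p[2]), 4L)
  # 1-D coverage along a row: exactly 2 anchors bracket an interior column
  expect_equal(sum(grid$anchors[, 1] == 0 & grid$anchors[, 2] <= 200 &
                     200 < grid$anchors[, 2] + 64), 2L)
})

test_that("annotation IO round-trips and rejects malformed rows", {
  ann <- data.frame(frame_id = rep(c("f1", "f2"), each = 5),
                    video_id = "v1",
                    row = rep(seq(0L, 128L, 32L), 2),
                    col = rep(64L, 10),
                    label = rep(c("clean", "dirty"), 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path), ann)

  bad <- ann; bad$label[3] <- "wet"
  write_annotations(bad, path)
  expect_error(read_annotations(path), "unknown label 'wet' in row 3")

  off <- ann; off$row[2] <- 33L
  write_annotations(off, path)
  expect_error(read_annotations(path), "off grid in row 2")

  dup <- rbind(ann, ann[1, ])
  write_annotations(dup, path)
  expect_error(read_annotations(path), "duplicate")
})

test_that("annotations are checked against the FOV grid on load", {
  n <- 576; centre <- (n + 1) / 2
  d2 <- outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, "+")
  disk <- structure(d2 <= 280^2, class = "fov_mask")
  grid <- build_patch_grid(disk)
  good <- data.frame(frame_id = "f1", video_id = "v1",
                     row = grid$anchors[1, 1], col = grid$anchors[1, 2],
                     label = "clean")
  expect_true(validate_annotations(good, "f1", grid))
  corner <- data.frame(frame_id = "f1", video_id = "v1", row = 0L, col = 0L,
                       label = "clean") # corner patch is outside the disk
  expect_error(validate_annotations(corner, "f1", grid), "outside FOV")
})
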