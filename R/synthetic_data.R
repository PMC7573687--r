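#' Parameters of the synthetic frame generator
#'
#' The generator emulates the geometry and colour statistics that the
#' pipeline depends on — a circular recording area on a black background,
#' low-frequency pinkish mucosa texture, and distinctly coloured intestinal
#' content (bile-like blobs, bubble clusters, brown debris speckle) with an
#' exact ground-truth mask. It does not attempt photo-realism: its purpose
#' is a learnably distinct clean/dirty structure at desk scale.
#'
#' @param size frame side length in pixels (default 576).
#' @param fov_radius radius of the circular field of view (default 280).
#' @param dirty_fraction target fraction of the FOV covered by content.
#' @param content_types subset of `c("bile_blob", "bubble_cluster",
#'   "debris")`.
#' @param texture_scale relative spatial scale of the mucosa texture.
#' @param lumen whether to darken a lumen-hole region.
#' @param seed integer seed; generation is a pure function of the seed.
#' @return list of class `synthetic_frame_params`.
#' @export
synthetic_frame_params <- function(size = 576L, fov_radius = 280L,
                                   dirty_fraction = 0.3,
                                   content_types = "bile_blob",
                                   texture_scale = 1, lumen = FALSE,
                                   seed = 1L) {
  stopifnot(fov_radius < size / 2, dirty_fraction >= 0, dirty_fraction <= 1,
            all(content_types %in% c("bile_blob", "bubble_cluster", "debris")))
  structure(list(size = as.integer(size), fov_radius = as.integer(fov_radius),
                 dirty_fraction = dirty_fraction,
                 content_types = content_types,
                 texture_scale = texture_scale, lumen = lumen,
                 seed = as.integer(seed)),
            class = "synthetic_frame_params")
}

# seeded value noise: sum of bilinearly upsampled random lattices. `periods`
# are the lattice spacings in pixels, weights halve per octave.
value_noise <- function(h, w, periods) {
  out <- matrix(0, h, w)
  wt <- 1
  total <- 0
  for (p in periods) {
    nr <- ceiling(h / p) + 1L
    nc <- ceiling(w / p) + 1L
    lattice <- matrix(stats::runif(nr * nc), nr, nc)
    ry <- lattice_coords((seq_len(h) - 1) / p, seq_len(nr) - 1)
    cx <- lattice_coords((seq_len(w) - 1) / p, seq_len(nc) - 1)
    up <- (ry$w0 %o% cx$w0) * lattice[ry$i0, cx$i0] +
      (ry$w0 %o% cx$w1) * lattice[ry$i0, cx$i1] +
      (ry$w1 %o% cx$w0) * lattice[ry$i1, cx$i0] +
      (ry$w1 %o% cx$w1) * lattice[ry$i1, cx$i1]
    out <- out + wt * up
    total <- total + wt
    wt <- wt / 2
  }
  out / total
}

#' Generate a synthetic capsule-endoscopy-like frame
#'
#' Returns a frame with black background outside a centred disk, textured
#' mucosa inside, and intestinal-content regions painted according to the
#' requested content types until the realised dirty fraction matches the
#' target (the content region is selected by thresholding a smooth random
#' field at the matching quantile, so the realised fraction is within one
#' pixel-quantile of the target). Deterministic for a fixed seed.
#'
#' @param params a [synthetic_frame_params()].
#' @param frame_id,video_id identifiers for the produced frame.
#' @return list with `frame` (a [ce_frame()]), `mask` (the analytic disk
#'   `fov_mask`), `ground_truth` (list `dirty_mask`, `dirty_fraction`).
#' @export
generate_frame <- function(params, frame_id = "synthetic", video_id = "v1") {
  stopifnot(inherits(params, "synthetic_frame_params"))
  with_seed(params$seed, {
    n <- params$size
    centre <- (n + 1) / 2
    d2 <- outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, "+")
    fov <- d2 <= params$fov_radius^2
    ts <- params$texture_scale
    base_lo <- value_noise(n, n, pmax(4, round(c(96, 48) * ts)))
    base_hi <- value_noise(n, n, pmax(2, round(c(12, 6) * ts)))
    # mucosa: pinkish red with fine texture
    R <- 0.62 + 0.22 * base_lo + 0.08 * base_hi
    G <- 0.28 + 0.14 * base_lo + 0.06 * base_hi
    B <- 0.24 + 0.10 * base_lo + 0.05 * base_hi
    # dirty region: threshold a smooth field at the quantile matching the
    # target coverage of the FOV
    dirty <- matrix(FALSE, n, n)
    if (params$dirty_fraction > 0) {
      field <- value_noise(n, n, pmax(8, round(c(128, 64, 32) * ts)))
      fv <- field[fov]
      if (params$dirty_fraction >= 1) thr <- -Inf
      else thr <- stats::quantile(fv, 1 - params$dirty_fraction, names = FALSE)
      dirty <- fov & field > thr
    }
    realized <- sum(dirty) / sum(fov)
    if (params$dirty_fraction > 0 &&
        abs(realized - params$dirty_fraction) > 0.05)
      warning(sprintf("realised dirty fraction %.3f misses target %.3f",
                      realized, params$dirty_fraction))
    if (any(dirty)) {
      types <- params$content_types
      # split the dirty region among the requested content types by a
      # coarse random field
      assign_field <- if (length(types) > 1L)
        value_noise(n, n, c(160, 80)) else matrix(0, n, n)
      cutpoints <- stats::quantile(assign_field[dirty],
                                   probs = seq_len(length(types) - 1L) /
                                     length(types), names = FALSE)
      type_idx <- findInterval(assign_field, c(-Inf, cutpoints))
      hf <- value_noise(n, n, c(4, 2))
      for (ti in seq_along(types)) {
        reg <- dirty & type_idx == ti
        if (!any(reg)) next
        if (types[ti] == "bile_blob") {
          sm <- value_noise(n, n, c(48, 24))
          R[reg] <- 0.55 + 0.20 * sm[reg]
          G[reg] <- 0.62 + 0.22 * sm[reg]
          B[reg] <- 0.10 + 0.08 * sm[reg]
        } else if (types[ti] == "bubble_cluster") {
          R[reg] <- 0.50 + 0.15 * hf[reg]
          G[reg] <- 0.55 + 0.15 * hf[reg]
          B[reg] <- 0.20 + 0.10 * hf[reg]
          rim <- bubble_rims(reg, seed_offset = 17L)
          R[rim] <- pmin(R[rim] + 0.35, 1)
          G[rim] <- pmin(G[rim] + 0.35, 1)
          B[rim] <- pmin(B[rim] + 0.30, 1)
        } else { # debris
          R[reg] <- 0.38 + 0.25 * hf[reg]
          G[reg] <- 0.30 + 0.18 * hf[reg]
          B[reg] <- 0.08 + 0.08 * hf[reg]
        }
      }
    }
    if (params$lumen) {
      lum <- value_noise(n, n, c(192, 96))
      dark <- 0.35 + 0.65 * pmin(lum / stats::quantile(lum[fov], 0.25), 1)
      R <- R * dark; G <- G * dark; B <- B * dark
    }
    px <- array(0, c(n, n, 3))
    px[, , 1][fov] <- pmin(pmax(R[fov], 0.05), 1)
    px[, , 2][fov] <- pmin(pmax(G[fov], 0.05), 1)
    px[, , 3][fov] <- pmin(pmax(B[fov], 0.05), 1)
    list(frame = ce_frame(px, frame_id, video_id),
         mask = structure(fov, class = "fov_mask"),
         ground_truth = list(dirty_mask = dirty, dirty_fraction = realized))
  })
}

# bright circle outlines inside a region (bubble highlights)
bubble_rims <- function(region, seed_offset = 0L) {
  n <- nrow(region)
  rim <- matrix(FALSE, n, n)
  pts <- which(region)
  if (length(pts) == 0L) return(rim)
  n_bub <- max(3L, length(pts) %/% 4000L)
  centres <- sample(pts, min(n_bub, length(pts)))
  rr <- (centres - 1L) %% n + 1L
  cc <- (centres - 1L) %/% n + 1L
  for (i in seq_along(centres)) {
    rad <- stats::runif(1, 6, 14)
    th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * rad * 2))
    pr <- pmin(pmax(round(rr[i] + rad * sin(th)), 1L), n)
    pc <- pmin(pmax(round(cc[i] + rad * cos(th)), 1L), n)
    rim[cbind(pr, pc)] <- TRUE
  }
  rim & region
}

#' Derive pure patch labels from ground truth
#'
#' Mirrors the expert annotation protocol: a grid patch is labelled dirty
#' only when its entire footprint lies in the content mask, clean only when
#' none of it does; mixed patches are omitted (unannotated).
#'
#' @param ground_truth the `ground_truth` element of [generate_frame()].
#' @param grid the frame's [build_patch_grid()].
#' @param frame_id,video_id identifiers for the annotation rows.
#' @return annotation data.frame `frame_id,video_id,row,col,label` (possibly
#'   zero rows).
#' @export
derive_patch_labels <- function(ground_truth, grid, frame_id = "synthetic",
                                video_id = "v1") {
  stopifnot(inherits(grid, "patch_grid"))
  ps <- grid$patch_size
  S <- integral_image(ground_truth$dirty_mask * 1L)
  cover <- window_sum(S, grid$anchors[, 1L], grid$anchors[, 2L], ps, ps)
  label <- ifelse(cover == ps * ps, "dirty",
                  ifelse(cover == 0L, "clean", NA_character_))
  keep <- which(!is.na(label))
  data.frame(frame_id = rep(frame_id, length(keep)),
             video_id = rep(video_id, length(keep)),
             row = grid$anchors[keep, 1L], col = grid$anchors[keep, 2L],
             label = label[keep])
}

#' Generate a multi-video synthetic dataset
#'
#' Videos differ in texture scale, content mix and dirty-fraction range
#' (per-video parameter drift); each frame comes with its FOV mask, ground
#' truth and pure-patch annotations in the CSV dialects the rest of the
#' package reads. With `dir` set, frames and masks are written as PNG and
#' the annotation/manifest tables as CSV.
#'
#' @param n_videos,frames_per_video dataset shape (e.g. 35 videos of ~16
#'   frames emulate a 563-frame training corpus; 30 videos of ~28 frames an
#'   854-frame validation corpus).
#' @param dirty_range range the per-frame dirty fraction is drawn from.
#' @param content_pool content types sampled per video.
#' @param seed integer seed.
#' @param dir optional output directory.
#' @param size,fov_radius frame geometry.
#' @return list with `frames` (list of [generate_frame()] outputs),
#'   `annotations` (combined data.frame), `manifest` (data.frame
#'   `frame_id,video_id,fold`-ready `frame_id,video_id`).
#' @export
generate_dataset <- function(n_videos, frames_per_video,
                             dirty_range = c(0.05, 0.75),
                             content_pool = c("bile_blob", "bubble_cluster",
                                              "debris"),
                             seed = 1L, dir = NULL, size = 576L,
                             fov_radius = 280L) {
  stopifnot(n_videos >= 1L)
  plan <- with_seed(seed, {
    lapply(seq_len(n_videos), function(v) {
      types <- sample(content_pool, sample(seq_along(content_pool), 1L))
      list(types = types,
           texture = stats::runif(1, 0.8, 1.3),
           lumen = stats::runif(1) < 0.3,
           dirty = stats::runif(frames_per_video, dirty_range[1],
                                dirty_range[2]),
           seeds = sample.int(1e6, frames_per_video))
    })
  })
  frames <- list(); ann <- list(); manifest <- list()
  for (v in seq_len(n_videos)) {
    vid <- sprintf("video%03d", v)
    for (f in seq_len(frames_per_video)) {
      fid <- sprintf("%s_frame%03d", vid, f)
      pv <- plan[[v]]
      g <- generate_frame(
        synthetic_frame_params(size = size, fov_radius = fov_radius,
                               dirty_fraction = pv$dirty[f],
                               content_types = pv$types,
                               texture_scale = pv$texture, lumen = pv$lumen,
                               seed = pv$seeds[f]),
        frame_id = fid, video_id = vid)
      grid <- build_patch_grid(g$mask)
      frames[[fid]] <- g
      ann[[fid]] <- derive_patch_labels(g$ground_truth, grid, fid, vid)
      manifest[[fid]] <- data.frame(frame_id = fid, video_id = vid)
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (fid in names(frames)) {
      write_frame(frames[[fid]]$frame, file.path(dir, paste0(fid, ".png")))
      png::writePNG(frames[[fid]]$mask * 1,
                    file.path(dir, paste0(fid, "_mask.png")))
    }
    write_annotations(annotations, file.path(dir, "annotations.csv"))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(frames = frames, annotations = annotations, manifest = manifest)
}

#' Generate a balanced labelled patch set
#'
#' Convenience wrapper for training experiments: draws synthetic frames and
#' collects pure clean/dirty patches until `n_patches` (balanced as closely
#' as possible) are available.
#'
#' @param n_patches total number of patches wanted.
#' @param content_types content palette for the dirty class.
#' @param dirty_fraction per-frame content coverage (default 0.45 gives a
#'   rich supply of both pure classes).
#' @param seed integer seed.
#' @param size,fov_radius frame geometry; the default generates from
#'   full-size frames.
#' @return list with `x` (array `64 x 64 x 3 x n`), `labels`
#'   (`"clean"`/`"dirty"`), `frames_used`.
#' @export
generate_labeled_patches <- function(n_patches, content_types = "bile_blob",
                                     dirty_fraction = 0.45, seed = 1L,
                                     size = 576L, fov_radius = 280L) {
  per_class <- ceiling(n_patches / 2)
  xs <- list(); labs <- character(); used <- 0L
  count <- c(clean = 0L, dirty = 0L)
  fseed <- seed
  while (any(count < per_class) && used < 200L) {
    fseed <- fseed + 1L
    used <- used + 1L
    g <- generate_frame(
      synthetic_frame_params(size = size, fov_radius = fov_radius,
                             dirty_fraction = dirty_fraction,
                             content_types = content_types, seed = fseed))
    grid <- build_patch_grid(g$mask)
    ann <- derive_patch_labels(g$ground_truth, grid)
    if (nrow(ann) == 0L) next
    patches <- extract_patches(g$frame, grid)
    key <- paste(grid$anchors[, 1L], grid$anchors[, 2L])
    for (i in seq_len(nrow(ann))) {
      lab <- ann$label[i]
      if (count[lab] >= per_class) next
      j <- match(paste(ann$row[i], ann$col[i]), key)
      xs[[length(xs) + 1L]] <- patches[[j]]
      labs <- c(labs, lab)
      count[lab] <- count[lab] + 1L
    }
  }
  keep <- seq_len(min(length(labs), n_patches))
  # interleave classes before truncation so both survive
  ord <- order(ave(seq_along(labs), labs, FUN = seq_along))
  xs <- xs[ord][keep]; labs <- labs[ord][keep]
  list(x = patch_list_to_array(xs), labels = labs, frames_used = used)
}

#' Generate a synthetic rating study
#'
#' Draws per-frame mean dirty probabilities uniformly on `[0, 1]`, derives
#' each expert's score by categorising with the true thresholds and then,
#' with probability `flip_prob`, moving the score to an adjacent category
#' (moved inward at the scale ends). Frames are organised into videos so
#' grouped cross-validation can be exercised.
#'
#' @param n_videos,frames_per_video study shape.
#' @param true_thresholds a [threshold_triple()].
#' @param flip_prob adjacent-flip probability per expert (scalar or
#'   length 2), in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list with `mean_probs`, `ratings` (a 2-column [rating_table()]),
#'   `video_ids`, `true_scores` (noise-free codes).
#' @export
generate_rating_study <- function(n_videos, frames_per_video,
                                  true_thresholds, flip_prob = 0.1,
                                  seed = 1L) {
  stopifnot(inherits(true_thresholds, "threshold_triple"),
            all(flip_prob >= 0), all(flip_prob < 0.5))
  flip_prob <- rep_len(flip_prob, 2L)
  n <- n_videos * frames_per_video
  with_seed(seed, {
    mean_probs <- stats::runif(n)
    video_ids <- rep(sprintf("video%03d", seq_len(n_videos)),
                     each = frames_per_video)
    truth <- categorize_code(mean_probs, true_thresholds)
    perturb <- function(code, fp) {
      flip <- stats::runif(n) < fp
      dir <- ifelse(code == 1L, 1L, ifelse(code == 4L, -1L,
                    sample(c(-1L, 1L), n, replace = TRUE)))
      ifelse(flip, code + dir, code)
    }
    ratings <- rating_table(cbind(expert1 = perturb(truth, flip_prob[1]),
                                  expert2 = perturb(truth, flip_prob[2])),
                            frame_id = sprintf("frame%04d", seq_len(n)),
                            video_id = video_ids)
    list(mean_probs = mean_probs, ratings = ratings, video_ids = video_ids,
         true_scores = truth)
  })
}
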