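#' Patch probability map
#'
#' Pairs a patch grid with one dirty-probability per anchor (model output for
#' the patch at that anchor), in grid order.
#'
#' @param grid a `patch_grid`.
#' @param probs numeric vector in `[0, 1]`, one per anchor.
#' @return object of class `patch_prob_map`.
#' @export
patch_probability_map <- function(grid, probs) {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(probs) != nrow(grid$anchors))
    stop("need one probability per anchor (", nrow(grid$anchors), ")")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(grid = grid, probs = as.numeric(probs)),
            class = "patch_prob_map")
}

#' Interpolate patch probabilities to per-pixel probabilities
#'
#' Each patch probability is planted at the patch's central pixel (anchor +
#' half the patch size in both directions). Pixels between four planted
#' centres receive the bilinear combination of those values; field-of-view
#' pixels outside the convex hull of the centres take the value of the
#' nearest centre (clamped extrapolation), and lattice nodes missing because
#' of a ragged FOV edge are filled from the nearest existing centre along
#' their lattice row (then column). The result is defined exactly on the FOV
#' and clipped to `[0, 1]`.
#'
#' @param ppm a [patch_probability_map()].
#' @param mask the frame's `fov_mask`.
#' @return a numeric `h x w` matrix of class `pixel_prob_map`, `NA` outside
#'   the FOV.
#' @export
interpolate_pixel_probabilities <- function(ppm, mask) {
  stopifnot(inherits(ppm, "patch_prob_map"), inherits(mask, "fov_mask"))
  grid <- ppm$grid
  if (nrow(grid$anchors) == 0L) stop("empty patch probability map")
  h <- nrow(mask); w <- ncol(mask)
  half <- grid$patch_size %/% 2L
  # planted centres, 0-based pixel coordinates
  cr <- grid$anchors[, 1L] + half
  cc <- grid$anchors[, 2L] + half
  rows <- sort(unique(cr)); cols <- sort(unique(cc))
  V <- matrix(NA_real_, length(rows), length(cols))
  V[cbind(match(cr, rows), match(cc, cols))] <- ppm$probs
  V <- fill_lattice_na(V, rows, cols)
  # bilinear sample of the complete lattice at every pixel, clamped
  ry <- lattice_coords(seq_len(h) - 1L, rows)
  cx <- lattice_coords(seq_len(w) - 1L, cols)
  vals <- (ry$w0 %o% cx$w0) * V[ry$i0, cx$i0, drop = FALSE] +
    (ry$w0 %o% cx$w1) * V[ry$i0, cx$i1, drop = FALSE] +
    (ry$w1 %o% cx$w0) * V[ry$i1, cx$i0, drop = FALSE] +
    (ry$w1 %o% cx$w1) * V[ry$i1, cx$i1, drop = FALSE]
  vals <- pmin(pmax(vals, 0), 1)
  vals[!mask] <- NA_real_
  structure(vals, class = "pixel_prob_map")
}

# bracketing lattice indices and weights for positions p (0-based pixels)
# against node coordinates `nodes` (sorted); clamped at both ends.
lattice_coords <- function(p, nodes) {
  i0 <- findInterval(p, nodes)        # nodes[i0] <= p < nodes[i0+1]
  i0 <- pmin(pmax(i0, 1L), length(nodes))
  i1 <- pmin(i0 + 1L, length(nodes))
  below <- p < nodes[1L]
  t <- ifelse(i1 > i0, (p - nodes[i0]) / (nodes[i1] - nodes[i0]), 0)
  t[below] <- 0                        # clamp to first node
  t <- pmin(pmax(t, 0), 1)
  list(i0 = i0, i1 = i1, w0 = 1 - t, w1 = t)
}

# nearest-neighbour completion of missing lattice nodes: along rows first,
# then columns (ties resolved towards the lower index).
fill_lattice_na <- function(V, rows, cols) {
  fill_vec <- function(v, pos) {
    ok <- which(!is.na(v))
    if (length(ok) == 0L || length(ok) == length(v)) return(v)
    nearest <- ok[apply(abs(outer(pos, pos[ok], "-")), 1L, which.min)]
    v[is.na(v)] <- v[nearest[is.na(v)]]
    v
  }
  for (i in seq_len(nrow(V))) V[i, ] <- fill_vec(V[i, ], cols)
  for (j in seq_len(ncol(V))) V[, j] <- fill_vec(V[, j], rows)
  if (anyNA(V)) { # rows with no centre at all: fall back to column fill again
    for (i in seq_len(nrow(V))) V[i, ] <- fill_vec(V[i, ], cols)
  }
  V
}

#' Mean dirty probability of a frame
#'
#' Arithmetic mean of the pixel probabilities over the defined (FOV) pixels;
#' this is the scalar that the cleanliness categorisation thresholds act on.
#'
#' @param pxm a `pixel_prob_map`.
#' @return a number in `[0, 1]`.
#' @export
mean_dirty_probability <- function(pxm) {
  stopifnot(inherits(pxm, "pixel_prob_map"))
  v <- pxm[!is.na(pxm)]
  if (length(v) == 0L) stop("no defined pixels")
  mean(v)
}

#' Render a probability heat map over a frame
#'
#' Blends a colour-mapped version of the pixel probabilities onto the frame
#' inside the FOV; pixels outside the FOV are returned untouched.
#'
#' @param frame a [ce_frame()].
#' @param pxm a `pixel_prob_map` of matching dimensions.
#' @param alpha blend weight in `[0, 1]`: 0 returns the frame, 1 pure
#'   colormap.
#' @param palette colour vector interpolated over `[0, 1]` probability.
#' @return numeric `h x w x 3` array in `[0, 1]`.
#' @export
render_heatmap <- function(frame, pxm, alpha = 0.5,
                           palette = c("#00007F", "#0000FF", "#00FFFF",
                                       "#FFFF00", "#FF7F00", "#FF0000")) {
  stopifnot(inherits(frame, "ce_frame"), inherits(pxm, "pixel_prob_map"))
  if (!all(dim(frame$pixels)[1:2] == dim(pxm)))
    stop("frame and probability map dimensions differ")
  ramp <- grDevices::colorRamp(palette)
  out <- frame$pixels / 255
  def <- which(!is.na(pxm))
  if (length(def) && alpha > 0) {
    cols <- ramp(as.numeric(pxm[def])) / 255
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[def] <- (1 - alpha) * plane[def] + alpha * cols[, ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Export a pixel probability map
#'
#' `write_pixel_map_tiff` stores the map as 16-bit grayscale TIFF
#' (`value = round(p * 65535)`, undefined pixels 0); `write_pixel_map_png`
#' stores an 8-bit grayscale PNG preview; `write_pixel_map_csv` stores the
#' raw values (NA outside the FOV) as plain text.
#'
#' @param pxm a `pixel_prob_map`.
#' @param path output path.
#' @export
write_pixel_map_tiff <- function(pxm, path) {
  m <- unclass(pxm); m[is.na(m)] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_pixel_map_tiff
#' @export
write_pixel_map_png <- function(pxm, path) {
  m <- unclass(pxm); m[is.na(m)] <- 0
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_pixel_map_tiff
#' @export
write_pixel_map_csv <- function(pxm, path) {
  utils::write.table(unclass(pxm), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
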