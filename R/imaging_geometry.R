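#' Construct a capsule-endoscopy frame object
#'
#' A frame is an 8-bit RGB image together with the identifiers that tie it to
#' its video (one video per patient). Paper-conformant frames are 576x576 with
#' a circular recording area on a black background, but any size is accepted.
#'
#' @param pixels integer array `h x w x 3` with values in 0..255, or a numeric
#'   array in `[0, 1]` which is rescaled.
#' @param frame_id,video_id character identifiers.
#' @return an object of class `ce_frame` with fields `pixels`, `frame_id`,
#'   `video_id`.
#' @export
ce_frame <- function(pixels, frame_id, video_id) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an h x w x 3 array")
  if (is.double(pixels) && max(pixels) <= 1 + 1e-9 && min(pixels) >= 0) {
    pixels <- round(pixels * 255)
  }
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("channel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, frame_id = as.character(frame_id),
         video_id = as.character(video_id)),
    class = "ce_frame")
}

#' Read a frame image from disk
#'
#' PNG and JPEG (8-bit RGB) are supported. Grayscale images are expanded to
#' three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @param frame_id,video_id identifiers; `frame_id` defaults to the file name
#'   without extension.
#' @return a [ce_frame()].
#' @export
read_frame <- function(path, frame_id = NULL, video_id = "unknown") {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  ce_frame(img, frame_id %||% tools::file_path_sans_ext(basename(path)),
           video_id)
}

#' Write a frame image to PNG
#'
#' @param frame a [ce_frame()].
#' @param path output path.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "ce_frame"))
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' Detect the circular field of view of a frame
#'
#' The recording area of a capsule frame is surrounded by a black border that
#' carries no information and must be ignored in all downstream computations.
#' A pixel is provisionally inside the field of view (FOV) when its brightest
#' channel exceeds `intensity_threshold`; the provisional mask is then reduced
#' to its largest connected component and interior holes (dark lumen, black
#' text overlays) are filled.
#'
#' @param frame a [ce_frame()].
#' @param intensity_threshold intensity in 0..255 above which a pixel counts
#'   as lit; default 10.
#' @return a logical `h x w` matrix of class `fov_mask`, `TRUE` inside the
#'   recording area.
#' @export
detect_fov_mask <- function(frame, intensity_threshold = 10L) {
  stopifnot(inherits(frame, "ce_frame"))
  px <- frame$pixels
  maxc <- pmax(px[, , 1L], px[, , 2L], px[, , 3L])
  raw <- maxc > intensity_threshold
  if (!any(raw)) stop("no recording area: frame is entirely black")
  lab <- EBImage::bwlabel(EBImage::Image(raw * 1))
  lab <- EBImage::imageData(lab)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- lab == keep
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  structure(matrix(filled, nrow(maxc), ncol(maxc)), class = "fov_mask")
}

#' Use a precomputed FOV mask
#'
#' Alternative to [detect_fov_mask()] when masks are shipped alongside the
#' frames: reads a single-channel PNG where nonzero means inside the FOV.
#'
#' @param path path to a grayscale PNG.
#' @return a `fov_mask`.
#' @export
read_fov_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- img > 0
  if (!any(m)) stop("no recording area: mask is empty")
  structure(m, class = "fov_mask")
}

#' Build the overlapping patch grid of a frame
#'
#' The frame is pre-divided into `patch_size x patch_size` patches with a step
#' of `stride` pixels in both directions (50% overlap at the defaults). A
#' candidate anchor enters the grid only when its complete footprint lies
#' inside the field of view, so every patch is free of black border pixels.
#' Anchors are 0-based `(row, col)` top-left coordinates in row-major order,
#' with half-open footprints `[r, r + patch_size) x [c, c + patch_size)`.
#'
#' @param mask a `fov_mask`.
#' @param patch_size patch side length in pixels (default 64).
#' @param stride step between anchors in pixels (default 32).
#' @return an object of class `patch_grid` with fields `patch_size`, `stride`,
#'   `anchors` (n x 2 integer matrix), `dim` (mask dimensions).
#' @export
build_patch_grid <- function(mask, patch_size = 64L, stride = 32L) {
  stopifnot(inherits(mask, "fov_mask"))
  h <- nrow(mask); w <- ncol(mask)
  if (h < patch_size || w < patch_size) stop("FOV too small for one patch")
  rows <- seq(0L, h - patch_size, by = stride)
  cols <- seq(0L, w - patch_size, by = stride)
  cand <- expand.grid(col = cols, row = rows)[, c("row", "col")] # row-major
  S <- integral_image(mask * 1L)
  inside <- window_sum(S, cand$row, cand$col, patch_size, patch_size) ==
    patch_size * patch_size
  if (!any(inside)) stop("FOV too small for one patch")
  anchors <- as.matrix(cand[inside, , drop = FALSE])
  dimnames(anchors) <- list(NULL, c("row", "col"))
  storage.mode(anchors) <- "integer"
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 anchors = anchors, dim = c(h, w)),
            class = "patch_grid")
}

#' Extract normalised patch tensors from a frame
#'
#' Returns one `patch_size x patch_size x 3` array per grid anchor, in grid
#' order, with channel intensities divided by 255 so values lie in `[0, 1]`.
#' No other preprocessing (no mean subtraction, no rescaling) is applied.
#'
#' @param frame a [ce_frame()].
#' @param grid a [build_patch_grid()] result for this frame's dimensions.
#' @return list of numeric arrays.
#' @export
extract_patches <- function(frame, grid) {
  stopifnot(inherits(frame, "ce_frame"), inherits(grid, "patch_grid"))
  if (!all(dim(frame$pixels)[1:2] == grid$dim))
    stop("grid was built for different frame dimensions")
  ps <- grid$patch_size
  px <- frame$pixels
  lapply(seq_len(nrow(grid$anchors)), function(i) {
    r <- grid$anchors[i, 1L]; c <- grid$anchors[i, 2L]
    px[(r + 1L):(r + ps), (c + 1L):(c + ps), , drop = FALSE] / 255
  })
}

#' Read / write patch annotation tables
#'
#' Annotations are CSV files with header `frame_id,video_id,row,col,label`
#' where `(row, col)` is the 0-based anchor of an annotated patch and `label`
#' is `"clean"` or `"dirty"` (a patch is annotated only when it is entirely
#' one or the other). Anchors must lie on the stride lattice.
#'
#' @param path CSV path.
#' @param stride the lattice step annotations must respect (default 32).
#' @return `read_annotations`: a `data.frame` with the five columns above.
#' @export
read_annotations <- function(path, stride = 32L) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "video_id", "row", "col", "label")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns ", paste(need, collapse = ","))
  ann <- ann[, need]
  bad <- which(!ann$label %in% c("clean", "dirty"))
  if (length(bad))
    stop("unknown label '", ann$label[bad[1]], "' in row ", bad[1])
  off <- which(ann$row %% stride != 0L | ann$col %% stride != 0L |
                 ann$row < 0L | ann$col < 0L)
  if (length(off))
    stop("anchor off grid in row ", off[1], ": (",
         ann$row[off[1]], ", ", ann$col[off[1]], ")")
  dup <- duplicated(ann[, c("frame_id", "row", "col")])
  if (any(dup))
    stop("duplicate annotation in row ", which(dup)[1])
  ann
}

#' @rdname read_annotations
#' @param annotations data.frame as returned by `read_annotations`.
#' @export
write_annotations <- function(annotations, path) {
  need <- c("frame_id", "video_id", "row", "col", "label")
  stopifnot(all(need %in% names(annotations)))
  utils::write.csv(annotations[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check annotations against a frame's grid
#'
#' Verifies that every annotation of `frame_id` coincides with an anchor of
#' `grid` (and therefore lies fully inside the field of view).
#'
#' @param annotations annotation data.frame.
#' @param frame_id frame to check.
#' @param grid the frame's `patch_grid`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_annotations <- function(annotations, frame_id, grid) {
  ann <- annotations[annotations$frame_id == frame_id, , drop = FALSE]
  key <- paste(grid$anchors[, 1L], grid$anchors[, 2L])
  bad <- which(!paste(ann$row, ann$col) %in% key)
  if (length(bad))
    stop("annotation outside FOV grid: (", ann$row[bad[1]], ", ",
         ann$col[bad[1]], ") of frame ", frame_id)
  invisible(TRUE)
}
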