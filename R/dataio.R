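#' Two-channel fluorescence image container
#'
#' Channel 1 is the myotube (myosin heavy chain) stain, channel 2 the
#' nuclei (DAPI) stain; pixel values live in `[0, 1]`.
#'
#' @param ch_myotube,ch_nuclei Numeric matrices of identical shape.
#' @param um_per_px Physical pixel size in microns per pixel.
#' @param source Optional provenance string.
#' @return Object of class `fluor_image` with `pixels` of dim `(2, H, W)`.
#' @export
fluor_image <- function(ch_myotube, ch_nuclei, um_per_px = 1.0, source = NA) {
  check_same_shape(ch_myotube, ch_nuclei, "myotube channel", "nuclei channel")
  H <- nrow(ch_myotube); W <- ncol(ch_myotube)
  px <- array(0, dim = c(2L, H, W))
  px[1, , ] <- ch_myotube
  px[2, , ] <- ch_nuclei
  if (min(px) < 0 || max(px) > 1)
    stop("channel values must lie in [0, 1]; use normalize_and_stack() for raw data")
  structure(list(pixels = px, um_per_px = um_per_px, source = source),
            class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("fluor_image: 2 x %d x %d, %.3g um/px, range [%.3f, %.3f]\n",
              d[2], d[3], x$um_per_px, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Normalize two raw channels and stack them into a model input
#'
#' Each channel is min-max normalized to `[0, 1]` independently (per-image
#' normalization, so the result is invariant to acquisition gain); a
#' constant channel maps to all zeros.
#'
#' @param myotube_raw,nuclei_raw Numeric/integer matrices of equal shape
#'   (any dtype/bit depth).
#' @inheritParams fluor_image
#' @return A [fluor_image()].
#' @export
normalize_and_stack <- function(myotube_raw, nuclei_raw, um_per_px = 1.0,
                                source = NA) {
  check_same_shape(myotube_raw, nuclei_raw, "myotube channel", "nuclei channel")
  norm1 <- function(m) {
    m <- as.matrix(m) * 1.0
    rng <- range(m)
    if (rng[2] - rng[1] <= 0) return(m * 0)
    (m - rng[1]) / (rng[2] - rng[1])
  }
  fluor_image(norm1(myotube_raw), norm1(nuclei_raw),
              um_per_px = um_per_px, source = source)
}

#' Crop a two-channel image into non-overlapping square training patches
#'
#' Row-major grid tiling; image dimensions must be divisible by `size` on
#' this (training) path -- use [tile_for_inference()] otherwise.
#'
#' @param image A [fluor_image()].
#' @param size Patch side length in px (default 512).
#' @param labels Optional label triple (list with binary `myotube`,
#'   `nuclei`, `centroid` matrices) cropped identically.
#' @return List of patches: each has `pixels` `(2, size, size)`, `origin`
#'   (0-based row, col of the top-left corner), `rotation` (degrees CCW),
#'   and optionally `labels`.
#' @export
crop_patches <- function(image, size = 512L, labels = NULL) {
  stopifnot(inherits(image, "fluor_image"))
  d <- dim(image$pixels)
  H <- d[2]; W <- d[3]
  if (H %% size != 0 || W %% size != 0)
    stop(sprintf(paste0("image %dx%d is not divisible by patch size %d; ",
                        "use tile_for_inference() for arbitrary sizes"),
                 H, W, size))
  out <- list()
  for (r0 in seq(0L, H - size, by = size)) {
    for (c0 in seq(0L, W - size, by = size)) {
      rows <- (r0 + 1):(r0 + size)
      cols <- (c0 + 1):(c0 + size)
      patch <- list(pixels = image$pixels[, rows, cols, drop = FALSE],
                    origin = c(r0, c0), rotation = 0L)
      if (!is.null(labels))
        patch$labels <- list(myotube = labels$myotube[rows, cols],
                             nuclei = labels$nuclei[rows, cols],
                             centroid = labels$centroid[rows, cols])
      out[[length(out) + 1L]] <- patch
    }
  }
  out
}

rotate_patch <- function(patch, k) {
  s <- dim(patch$pixels)[2]
  px <- array(0, dim = dim(patch$pixels))
  px[1, , ] <- rot_k(patch$pixels[1, , ], k)
  px[2, , ] <- rot_k(patch$pixels[2, , ], k)
  out <- patch
  out$pixels <- px
  out$rotation <- as.integer(90L * k)
  if (!is.null(patch$labels))
    out$labels <- lapply(patch$labels, rot_k, k = k)
  out
}

#' Augment square patches with 90/180/270-degree rotations
#'
#' Returns the originals plus their three counter-clockwise rotations
#' (x4 count); any attached labels are rotated identically. Rotations are
#' exact multiples of 90 degrees, so no interpolation occurs.
#'
#' @param patches List of patches from [crop_patches()].
#' @return List of length `4 * length(patches)`.
#' @export
augment_rotations <- function(patches) {
  out <- list()
  for (p in patches) {
    d <- dim(p$pixels)
    if (d[2] != d[3]) stop("rotation augmentation requires square patches")
    for (k in 0:3) out[[length(out) + 1L]] <- rotate_patch(p, k)
  }
  out
}

#' Build training label triples
#'
#' `make_labels_from_truth` passes the ground-truth masks through (the
#' synthetic stand-in for expert-corrected labels), dilating the
#' single-pixel centroid mask by `centroid_radius` because single-pixel
#' targets make per-pixel BCE training degenerate.
#' `make_labels_from_raw` builds labels from the image itself: Otsu
#' thresholding per channel, with centroids taken as connected-component
#' centers of the nuclei mask (the automated stand-in for manual dotting).
#'
#' @param gt A `ground_truth` object.
#' @param centroid_radius Dilation radius (px) for centroid training
#'   targets; 0 keeps single pixels.
#' @return A label triple: list of binary `myotube`, `nuclei`, `centroid`.
#' @export
make_labels_from_truth <- function(gt, centroid_radius = 2) {
  cen <- gt$centroid_mask
  if (centroid_radius > 0) cen <- dilate_mask(cen, centroid_radius)
  list(myotube = gt$myotube_mask, nuclei = gt$nuclei_mask, centroid = cen)
}

#' @rdname make_labels_from_truth
#' @param image A [fluor_image()].
#' @export
make_labels_from_raw <- function(image, centroid_radius = 2) {
  stopifnot(inherits(image, "fluor_image"))
  myo <- threshold_segment(image$pixels[1, , ], "otsu")
  nuc <- threshold_segment(image$pixels[2, , ], "otsu")
  if (sum(myo) == 0 || sum(nuc) == 0)
    warning("empty foreground after Otsu thresholding; labels are empty")
  cen <- matrix(0L, nrow(nuc), ncol(nuc))
  lab <- label_components(nuc, connectivity = 4L)
  for (l in seq_len(attr(lab, "n"))) {
    idx <- which(lab == l, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    # snap to the component pixel nearest the centroid (concave shapes)
    d <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    best <- idx[which.min(d), ]
    cen[best[1], best[2]] <- 1L
  }
  if (centroid_radius > 0) cen <- dilate_mask(cen, centroid_radius)
  list(myotube = myo, nuclei = nuc, centroid = cen)
}

#' Tile an image for full-frame inference and stitch predictions back
#'
#' `tile_for_inference` covers the image with `size`-square tiles whose
#' origins advance by `size - overlap`, clamping the last tile to the
#' image edge. `stitch_tiles` reassembles single-channel maps by per-pixel
#' averaging over all covering tiles; with `overlap = 0` the round trip is
#' the identity.
#'
#' @param image A [fluor_image()] (or a single-channel matrix).
#' @param size Tile side length.
#' @param overlap Overlap in px between successive tiles (>= 0).
#' @return `tile_for_inference`: list with `tiles` (list of pixel arrays)
#'   and `origins` (n x 2 matrix of 0-based row/col).
#' @export
tile_for_inference <- function(image, size = 512L, overlap = 0L) {
  if (overlap < 0) stop("overlap must be >= 0")
  if (overlap >= size) stop("overlap must be smaller than tile size")
  px <- if (inherits(image, "fluor_image")) image$pixels else image
  two_ch <- length(dim(px)) == 3
  H <- if (two_ch) dim(px)[2] else nrow(px)
  W <- if (two_ch) dim(px)[3] else ncol(px)
  if (H < size || W < size) stop("image smaller than tile size")
  starts <- function(n) {
    if (n == size) return(0L)
    s <- seq(0L, n - size, by = size - overlap)
    if (s[length(s)] != n - size) s <- c(s, n - size)
    s
  }
  org <- as.matrix(expand.grid(row = starts(H), col = starts(W)))
  org <- org[order(org[, 1], org[, 2]), , drop = FALSE]
  tiles <- vector("list", nrow(org))
  for (i in seq_len(nrow(org))) {
    rows <- (org[i, 1] + 1):(org[i, 1] + size)
    cols <- (org[i, 2] + 1):(org[i, 2] + size)
    tiles[[i]] <- if (two_ch) px[, rows, cols, drop = FALSE]
    else px[rows, cols, drop = FALSE]
  }
  list(tiles = tiles, origins = org, size = as.integer(size),
       H = H, W = W)
}

#' @rdname tile_for_inference
#' @param tiles List of single-channel matrices (e.g. probability maps).
#' @param origins n x 2 matrix of 0-based tile origins.
#' @param H,W Output dimensions.
#' @export
stitch_tiles <- function(tiles, origins, H, W) {
  if (length(tiles) != nrow(origins))
    stop(sprintf("length(tiles) = %d but nrow(origins) = %d",
                 length(tiles), nrow(origins)))
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(tiles)) {
    tl <- as.matrix(tiles[[i]])
    rows <- (origins[i, 1] + 1):(origins[i, 1] + nrow(tl))
    cols <- (origins[i, 2] + 1):(origins[i, 2] + ncol(tl))
    acc[rows, cols] <- acc[rows, cols] + tl
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  if (any(cnt == 0)) stop("tiles do not cover the full image")
  acc / cnt
}
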