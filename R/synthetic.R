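#' Specification of a synthetic two-channel fluorescence scene
#'
#' Describes the stated world the generator renders: elongated, smoothly
#' curved (optionally forking) bright tubes on the myotube channel and
#' clustered elliptical nuclei on the nuclei channel, over a dark background
#' with an illumination gradient and additive Gaussian noise.
#'
#' @param height,width Scene size in pixels (>= 64).
#' @param n_tubes Number of myotubes to draw.
#' @param tube_width_range Integer (min, max) stroke width in px; must lie
#'   within `[3, width/4]`.
#' @param tube_curvature Dimensionless bending amplitude (0 = straight);
#'   the perpendicular jitter of path control points as a fraction of the
#'   scene diagonal.
#' @param branch_prob Probability that a tube forks into a side branch.
#' @param n_nuclei Number of nuclei.
#' @param nucleus_radius_range (min, max) nucleus semi-major axis in px.
#' @param overlap_fraction Target fraction of nuclei placed so that their
#'   mask intersects another nucleus, in `[0, 1]`.
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise (intensity units on the [0,1] scale).
#' @param background_gradient Maximum fractional illumination falloff
#'   across the scene (0 = flat field). Both background and foreground are
#'   attenuated, which is what defeats global-threshold baselines.
#' @param um_per_px Physical pixel size recorded with the scene (microns
#'   per pixel); measurement routines scale by it.
#' @param seed RNG seed; identical spec + seed gives a bit-identical scene.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 128L, width = 128L,
                       n_tubes = 3L,
                       tube_width_range = c(5L, 13L),
                       tube_curvature = 0.15,
                       branch_prob = 0.3,
                       n_nuclei = 12L,
                       nucleus_radius_range = c(4L, 7L),
                       overlap_fraction = 0.2,
                       noise_sigma = 0.08,
                       background_gradient = 0.75,
                       um_per_px = 1.0,
                       seed = 1L) {
  if (height < 64 || width < 64) stop("height and width must be >= 64")
  if (tube_width_range[1] < 3 || tube_width_range[2] > width / 4)
    stop("tube_width_range must lie within [3, width/4]")
  if (tube_width_range[1] > tube_width_range[2])
    stop("tube_width_range must be (min, max) with min <= max")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (n_tubes < 0 || n_nuclei < 0) stop("counts must be non-negative")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_tubes = as.integer(n_tubes),
                 tube_width_range = as.integer(tube_width_range),
                 tube_curvature = tube_curvature,
                 branch_prob = branch_prob,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = as.integer(nucleus_radius_range),
                 overlap_fraction = overlap_fraction,
                 noise_sigma = noise_sigma,
                 background_gradient = background_gradient,
                 um_per_px = um_per_px,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: %dx%d px, %d tubes (width %d-%d), %d nuclei, seed %d\n",
              x$height, x$width, x$n_tubes, x$tube_width_range[1],
              x$tube_width_range[2], x$n_nuclei, x$seed))
  invisible(x)
}

# sample a smooth polyline crossing the scene; returns dense (row, col) points
sample_tube_path <- function(H, W, curvature, from = NULL, heading = NULL) {
  diag_len <- sqrt(H^2 + W^2)
  if (is.null(from)) {
    # start on a random border and aim at a random point on the opposite
    # border, so every tube spans the field of view
    side <- sample(4L, 1L)
    from <- switch(side,
                   c(1, runif(1, 1, W)),            # top
                   c(H, runif(1, 1, W)),            # bottom
                   c(runif(1, 1, H), 1),            # left
                   c(runif(1, 1, H), W))            # right
    target <- switch(side,
                     c(H, runif(1, 1, W)),
                     c(1, runif(1, 1, W)),
                     c(runif(1, 1, H), W),
                     c(runif(1, 1, H), 1))
    heading <- atan2(target[1] - from[1], target[2] - from[2])
  }
  n_ctrl <- 5L
  step <- diag_len / (n_ctrl - 1)
  pts <- matrix(0, n_ctrl, 2)
  pts[1, ] <- from
  dir <- c(sin(heading), cos(heading))  # (d_row, d_col) unit-ish
  for (i in 2:n_ctrl) {
    perp <- c(-dir[2], dir[1])
    jitter <- rnorm(1, 0, curvature * diag_len / 4)
    pts[i, ] <- pts[i - 1, ] + dir * step + perp * jitter
  }
  tt <- seq_len(n_ctrl)
  dense_t <- seq(1, n_ctrl, length.out = ceiling(2.5 * diag_len))
  r <- stats::spline(tt, pts[, 1], xout = dense_t)$y
  c_ <- stats::spline(tt, pts[, 2], xout = dense_t)$y
  cbind(r, c_)
}

# rasterize dense float path to unique in-bounds pixels, preserving order
rasterize_path <- function(path, H, W) {
  px <- cbind(round(path[, 1]), round(path[, 2]))
  keep <- px[, 1] >= 1 & px[, 1] <= H & px[, 2] >= 1 & px[, 2] <= W
  px <- px[keep, , drop = FALSE]
  if (nrow(px) == 0) return(px)
  dup <- c(FALSE, px[-1, 1] == px[-nrow(px), 1] & px[-1, 2] == px[-nrow(px), 2])
  px[!dup, , drop = FALSE]
}

# stroke of width w along the continuous path: pixels within w/2 of the
# densely-sampled polyline, i.e. a band of geometric width w at any
# orientation (continuous distance; a pixelated axis would inflate angled
# strokes by up to 1 px)
render_stroke <- function(path, w, H, W) {
  .stroke_mask(path, w / 2, H, W)
}

#' Generate a synthetic fluorescence scene with exact ground truth
#'
#' Renders the two-channel image (myotube channel 1, nuclei channel 2) and
#' its ground truth: binary myotube / nuclei / centroid masks, per-nucleus
#' instance labels, and the tube axes with their stroke widths.
#'
#' Tubes are constant-width strokes along random smooth splines; with
#' probability `branch_prob` a tube forks, giving the skeleton stage
#' nontrivial branch structure. Nuclei are filled ellipses; a target
#' fraction is placed overlapping a previous nucleus, and overlapping
#' regions are attributed to the nearest nucleus centre in the label map.
#' Intensities: background ~0.1, foreground ~U(0.6, 1), both attenuated by
#' a linear illumination ramp of maximal relative depth
#' `background_gradient` in a random direction, then additive Gaussian
#' noise, clipped to [0, 1]. Noise and illumination affect only the image,
#' never the ground truth.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (a [fluor_image()]) and `truth`
#'   (class `ground_truth`: `myotube_mask`, `nuclei_mask`, `centroid_mask`,
#'   `nuclei_labels`, `tube_axes`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  H <- spec$height
  W <- spec$width
  myotube <- matrix(0L, H, W)
  tube_int <- matrix(0, H, W)
  tube_axes <- list()

  for (i in seq_len(spec$n_tubes)) {
    w <- if (spec$tube_width_range[1] == spec$tube_width_range[2])
      spec$tube_width_range[1]
    else sample(spec$tube_width_range[1]:spec$tube_width_range[2], 1L)
    path <- sample_tube_path(H, W, spec$tube_curvature)
    px <- rasterize_path(path, H, W)
    if (nrow(px) < 2) next
    axes_i <- list(px)
    paths_i <- list(path)
    if (runif(1) < spec$branch_prob) {
      kk <- seq(floor(nrow(px) * 0.3), ceiling(nrow(px) * 0.7))
      k <- kk[sample.int(length(kk), 1L)]
      at <- px[k, ]
      base_dir <- px[min(k + 5, nrow(px)), ] - px[max(k - 5, 1), ]
      ang <- atan2(base_dir[1], base_dir[2]) +
        sample(c(-1, 1), 1) * runif(1, pi / 6, pi / 3)
      bp <- sample_tube_path(H, W, spec$tube_curvature, from = at,
                             heading = ang)
      bpx <- rasterize_path(bp, H, W)
      if (nrow(bpx) >= 2) {
        axes_i <- c(axes_i, list(bpx))
        paths_i <- c(paths_i, list(bp))
      }
    }
    stroke <- matrix(0L, H, W)
    for (pp in paths_i) stroke <- pmax(stroke, render_stroke(pp, w, H, W))
    intensity <- runif(1, 0.6, 1.0)
    newpx <- stroke == 1L
    myotube[newpx] <- 1L
    tube_int[newpx] <- pmax(tube_int[newpx], intensity)
    tube_axes[[length(tube_axes) + 1L]] <-
      list(tube = i, width = w, axes = axes_i)
  }

  # nuclei placement
  rmin <- spec$nucleus_radius_range[1]
  rmax <- spec$nucleus_radius_range[2]
  n <- spec$n_nuclei
  n_overlap <- round(spec$overlap_fraction * n)
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  shapes <- list()   # per nucleus: a, b, theta
  tries <- 0L
  max_tries <- 200L * max(n, 1L)
  j <- 0L
  while (j < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(paste0("cannot place %d nuclei of radius %d-%d in a ",
                          "%dx%d scene after %d attempts"),
                   n, rmin, rmax, H, W, max_tries))
    a <- runif(1, rmin, rmax)
    b <- a * runif(1, 0.7, 1)
    theta <- runif(1, 0, pi)
    want_overlap <- j > 0L && (j + 1L) <= n_overlap + 1L &&
      nrow(centers) > 0L
    if (want_overlap) {
      k <- sample(nrow(centers), 1L)
      dist <- (radii[k] + a) * runif(1, 0.5, 0.9)
      ang <- runif(1, 0, 2 * pi)
      ctr <- centers[k, ] + dist * c(sin(ang), cos(ang))
    } else {
      ctr <- c(runif(1, rmax + 1, H - rmax), runif(1, rmax + 1, W - rmax))
    }
    if (ctr[1] < 2 || ctr[1] > H - 1 || ctr[2] < 2 || ctr[2] > W - 1) next
    if (!want_overlap && nrow(centers) > 0) {
      dd <- sqrt(rowSums((centers - matrix(ctr, nrow(centers), 2,
                                           byrow = TRUE))^2))
      if (any(dd < radii + a + 1)) next   # would overlap; resample
    }
    j <- j + 1L
    centers <- rbind(centers, ctr)
    radii <- c(radii, a)
    shapes[[j]] <- list(a = a, b = b, theta = theta)
  }

  nuclei <- matrix(0L, H, W)
  labels <- matrix(0L, H, W)
  centroid <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  nuc_int <- matrix(0, H, W)
  for (j in seq_len(n)) {
    s <- shapes[[j]]
    ctr <- centers[j, ]
    rr <- max(1, floor(ctr[1] - s$a - 1)):min(H, ceiling(ctr[1] + s$a + 1))
    cc <- max(1, floor(ctr[2] - s$a - 1)):min(W, ceiling(ctr[2] + s$a + 1))
    dr <- outer(rr - ctr[1], rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - ctr[2])
    u <- dr * cos(s$theta) + dc * sin(s$theta)
    v <- -dr * sin(s$theta) + dc * cos(s$theta)
    inside <- (u / s$a)^2 + (v / s$b)^2 <= 1
    d2 <- dr^2 + dc^2
    intens <- runif(1, 0.6, 1.0)
    for (ii in seq_along(rr)) for (jj in seq_along(cc)) {
      if (!inside[ii, jj]) next
      r0 <- rr[ii]; c0 <- cc[jj]
      nuclei[r0, c0] <- 1L
      nuc_int[r0, c0] <- max(nuc_int[r0, c0], intens)
      if (d2[ii, jj] < bestd[r0, c0]) {   # nearest-centre attribution
        bestd[r0, c0] <- d2[ii, jj]
        labels[r0, c0] <- j
      }
    }
    centroid[round(ctr[1]), round(ctr[2])] <- 1L
  }

  # illumination ramp along a random direction
  phi <- runif(1, 0, 2 * pi)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  proj <- (rr - 1) / max(H - 1, 1) * sin(phi) + (cc - 1) / max(W - 1, 1) * cos(phi)
  proj <- (proj - min(proj)) / max(max(proj) - min(proj), 1e-12)
  illum <- 1 - spec$background_gradient * proj

  bg <- 0.1
  ch1 <- ifelse(myotube == 1L, tube_int, bg) * illum
  ch2 <- ifelse(nuclei == 1L, nuc_int, bg) * illum
  if (spec$noise_sigma > 0) {
    ch1 <- ch1 + rnorm(H * W, 0, spec$noise_sigma)
    ch2 <- ch2 + rnorm(H * W, 0, spec$noise_sigma)
  }
  ch1 <- pmin(pmax(ch1, 0), 1)
  ch2 <- pmin(pmax(ch2, 0), 1)

  img <- fluor_image(ch1, ch2, um_per_px = spec$um_per_px,
                     source = sprintf("synthetic:seed=%d", spec$seed))
  truth <- structure(list(myotube_mask = myotube,
                          nuclei_mask = nuclei,
                          centroid_mask = centroid,
                          nuclei_labels = labels,
                          tube_axes = tube_axes),
                     class = "ground_truth")
  list(image = img, truth = truth)
}

#' Generate and write a dataset of synthetic scenes
#'
#' Writes, per scene, the two image channels as 16-bit ASCII PGM, the three
#' ground-truth masks and the nucleus label map as PGM, and a manifest CSV
#' that [read_scene()] can consume.
#'
#' @param spec_list List of [scene_spec()] objects.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(spec_list, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (i in seq_along(spec_list)) {
    sc <- generate_scene(spec_list[[i]])
    base <- sprintf("scene_%03d", i)
    p <- function(suffix) file.path(out_dir, paste0(base, suffix))
    write_pgm(sc$image$pixels[1, , ], p("_myotube.pgm"), maxval = 65535L)
    write_pgm(sc$image$pixels[2, , ], p("_nuclei.pgm"), maxval = 65535L)
    write_mask(sc$truth$myotube_mask, p("_mask_myotube.pgm"))
    write_mask(sc$truth$nuclei_mask, p("_mask_nuclei.pgm"))
    write_mask(sc$truth$centroid_mask, p("_mask_centroid.pgm"))
    nlab <- max(sc$truth$nuclei_labels, 1L)
    write_pgm(sc$truth$nuclei_labels / nlab, p("_labels.pgm"),
              maxval = as.integer(nlab))
    rows[[i]] <- data.frame(
      scene = base,
      path_myotube = p("_myotube.pgm"),
      path_nuclei = p("_nuclei.pgm"),
      path_mask_myotube = p("_mask_myotube.pgm"),
      path_mask_nuclei = p("_mask_nuclei.pgm"),
      path_mask_centroid = p("_mask_centroid.pgm"),
      path_labels = p("_labels.pgm"),
      seed = spec_list[[i]]$seed,
      n_tubes = spec_list[[i]]$n_tubes,
      n_nuclei = spec_list[[i]]$n_nuclei,
      um_per_px = spec_list[[i]]$um_per_px,
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scene = character(0), path_myotube = character(0),
               path_nuclei = character(0), path_mask_myotube = character(0),
               path_mask_nuclei = character(0),
               path_mask_centroid = character(0), path_labels = character(0),
               seed = integer(0), n_tubes = integer(0), n_nuclei = integer(0),
               um_per_px = numeric(0), stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
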