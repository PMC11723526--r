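#' Connected-component labelling
#'
#' @param mask Binary matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels `1..n` (0 = background) with attribute
#'   `"n"`; labels follow row-major discovery order.
#' @export
label_components <- function(mask, connectivity = 4L) {
  m <- as_binary(mask)
  .cc_label(m, as.integer(connectivity))
}

#' Exact Euclidean distance transform
#'
#' Distance of every foreground pixel to its nearest background pixel
#' (background maps to 0). Pixels beyond the image border are not treated
#' as background, so objects touching the border keep their full width.
#'
#' @param mask Binary matrix.
#' @return Numeric matrix of distances in px.
#' @export
distance_transform <- function(mask) .edt(as_binary(mask))

#' Binary dilation by a Euclidean disk
#'
#' @param mask Binary matrix.
#' @param radius Disk radius in px.
#' @export
dilate_mask <- function(mask, radius) {
  m <- as_binary(mask)
  if (sum(m) == 0 || radius <= 0) return(m)
  d <- .edt(1L - m)             # distance of every pixel to the mask
  out <- (d <= radius) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Build watershed markers from a nuclei mask and a centroid map
#'
#' Markers encode certainty: label 1 is the background marker (the
#' complement of the nuclei mask dilated by `background_dilation`, so an
#' "unknown" band surrounds each nucleus), labels `2..K+1` are the
#' connected components of the centroid map, and 0 is the unknown region
#' the flood must assign. Centroid components that do not intersect the
#' nuclei mask are dropped with a warning.
#'
#' @param nuclei_mask,centroid_mask Binary matrices of the same shape.
#' @param background_dilation Dilation radius (px) of the nuclei mask that
#'   delimits the certain-background marker (default 3).
#' @return Object of class `marker_map`: list with integer matrix `labels`
#'   and nucleus-marker count `K`.
#' @export
build_markers <- function(nuclei_mask, centroid_mask,
                          background_dilation = 3) {
  nuc <- as_binary(nuclei_mask, "nuclei_mask")
  cen <- as_binary(centroid_mask, "centroid_mask")
  check_same_shape(nuc, cen, "nuclei_mask", "centroid_mask")
  comp <- .cc_label(cen, 8L)
  ncomp <- attr(comp, "n")
  markers <- matrix(0L, nrow(nuc), ncol(nuc))
  markers[dilate_mask(nuc, background_dilation) == 0L] <- 1L
  k <- 0L
  dropped <- 0L
  for (l in seq_len(ncomp)) {
    px <- comp == l
    if (!any(nuc[px] == 1L)) {
      dropped <- dropped + 1L
      next
    }
    k <- k + 1L
    markers[px] <- k + 1L
  }
  if (dropped > 0L)
    warning(sprintf("%d centroid component%s outside the nuclei mask; dropped",
                    dropped, if (dropped > 1L) "s lie" else " lies"))
  structure(list(labels = markers, K = k), class = "marker_map")
}

#' Marker-controlled watershed over the unknown region
#'
#' Floods the unknown region from the markers in non-decreasing relief
#' order (4-connectivity, deterministic FIFO tie-breaking within a relief
#' level). A pixel reached by a single nucleus flood takes its label; a
#' pixel reached by two or more distinct nucleus floods becomes watershed
#' line (-1). The background flood claims what no nucleus reaches first
#' and never forms a line, so an isolated nucleus is labelled without any
#' line around it. The default relief is the negated Euclidean distance
#' transform of the nuclei mask, so water rises from the nucleus centres
#' outwards.
#'
#' @param markers A `marker_map` from [build_markers()].
#' @param nuclei_mask Binary nuclei mask (defines the default relief).
#' @param relief Optional numeric height map (finite values).
#' @return Object of class `label_map`: integer matrix `labels` with 0 =
#'   background, `1..K` = nucleus instances, -1 = watershed line; and `n`,
#'   the instance count.
#' @export
watershed_segment <- function(markers, nuclei_mask, relief = NULL) {
  stopifnot(inherits(markers, "marker_map"))
  nuc <- as_binary(nuclei_mask, "nuclei_mask")
  check_same_shape(markers$labels, nuc, "markers", "nuclei_mask")
  if (is.null(relief)) relief <- -distance_transform(nuc)
  check_same_shape(markers$labels, relief, "markers", "relief")
  if (!all(is.finite(relief))) stop("relief contains non-finite values")
  raw <- .watershed_flood(markers$labels, relief)
  out <- raw
  out[raw == 1L] <- 0L                 # background marker region
  pos <- raw >= 2L
  out[pos] <- raw[pos] - 1L
  structure(list(labels = out, n = markers$K), class = "label_map")
}

# centroid pixel of every positive label, snapped onto the label's pixels
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, length(ids), 2)
  for (i in seq_along(ids)) {
    idx <- which(labels == ids[i], arr.ind = TRUE)
    ctr <- colMeans(idx)
    d <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    out[i, ] <- idx[which.min(d), ]
  }
  rownames(out) <- ids
  out
}

#' Count nucleus instances, optionally within a region of interest
#'
#' With an `roi_mask`, an instance is counted when its centroid pixel
#' (mean of its pixels, snapped to the instance) falls inside the region
#' -- the assignment rule used for nuclei-per-myotube counts.
#'
#' @param labelmap A `label_map` from [watershed_segment()] (or an integer
#'   label matrix).
#' @param roi_mask Optional binary matrix.
#' @return Integer count.
#' @export
count_nuclei <- function(labelmap, roi_mask = NULL) {
  labels <- if (inherits(labelmap, "label_map")) labelmap$labels else labelmap
  ids <- unique(labels[labels > 0])
  if (is.null(roi_mask)) return(length(ids))
  roi <- as_binary(roi_mask, "roi_mask")
  cen <- label_centroids(labels)
  if (nrow(cen) == 0) return(0L)
  sum(roi[cen] == 1L)
}

#' Skeletonize a binary mask by iterative medial-axis thinning
#'
#' Iterative boundary peeling (two-subiteration thinning) that removes
#' simple pixels until the image stabilizes, preserving topology and
#'8-connectivity. The result is idempotent: thinning a skeleton returns
#' it unchanged.
#'
#' @param mask Binary matrix.
#' @return Binary matrix containing the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  m <- as_binary(mask)
  .thin_zs(m)
}

skel_neighbors <- function(skel, r, c) {
  H <- nrow(skel); W <- ncol(skel)
  out <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && skel[rr, cc] == 1L)
      out <- rbind(out, c(rr, cc))
  }
  out
}

#' Decompose a skeleton into branches, junctions and endpoints
#'
#' Junctions are skeleton pixels where three or more distinct arms meet;
#' arms are counted with the crossing number (runs of foreground around
#' the 8-neighbour ring), which equals the neighbour count on ideal
#' one-pixel skeletons but correctly ignores staircase corners, where a
#' diagonal step makes two consecutive ring positions foreground.
#' Endpoints have exactly one neighbour. Branches are the maximal
#' junction-free paths; each is returned as an ordered pixel path
#' including the junction pixels it attaches to (junction pixels are
#' shared between branches). A closed ring with no junctions yields a
#' single cyclic branch.
#'
#' @param skeleton Binary skeleton matrix (from [skeletonize()]).
#' @return List with `branches` (list of ordered n x 2 pixel matrices),
#'   `junctions` and `endpoints` (n x 2 matrices of pixel coordinates).
#' @export
extract_branches <- function(skeleton) {
  skel <- as_binary(skeleton, "skeleton")
  H <- nrow(skel); W <- ncol(skel)
  pts <- which(skel == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0)
    return(list(branches = list(), junctions = matrix(0L, 0, 2),
                endpoints = matrix(0L, 0, 2)))
  # neighbour degree and crossing number via shifted copies
  padded <- matrix(0L, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- skel
  shift <- function(dr, dc) padded[(2 + dr):(H + 1 + dr),
                                   (2 + dc):(W + 1 + dc)]
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),     # N NE E SE
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))   # S SW W NW
  nb <- lapply(ring, function(d) shift(d[1], d[2]))
  deg <- Reduce(`+`, nb)
  cross <- matrix(0L, H, W)                # 0 -> 1 transitions around ring
  for (k in 1:8)
    cross <- cross + (1L - nb[[k]]) * nb[[if (k == 8) 1 else k + 1]]
  deg[skel == 0L] <- 0L
  cross[skel == 0L] <- 0L
  junctions <- which(skel == 1L & cross >= 3L, arr.ind = TRUE)
  endpoints <- which(skel == 1L & deg == 1L, arr.ind = TRUE)

  is_junc <- matrix(FALSE, H, W)
  if (nrow(junctions)) is_junc[junctions] <- TRUE
  body <- skel
  body[is_junc] <- 0L
  comp <- .cc_label(body, 8L)
  branches <- list()
  for (l in seq_len(attr(comp, "n"))) {
    px <- which(comp == l, arr.ind = TRUE)
    # order the component as a path
    cdeg <- apply(px, 1, function(p) {
      nb <- skel_neighbors(body, p[1], p[2])
      if (is.null(nb)) 0L else nrow(nb)
    })
    start_i <- if (any(cdeg <= 1)) which(cdeg <= 1)[1] else 1L
    visited <- matrix(FALSE, H, W)
    path <- matrix(0L, 0, 2)
    cur <- px[start_i, ]
    repeat {
      path <- rbind(path, cur)
      visited[cur[1], cur[2]] <- TRUE
      nb <- skel_neighbors(body, cur[1], cur[2])
      nxt <- NULL
      if (!is.null(nb)) {
        free <- !visited[nb]
        if (any(free)) nxt <- nb[which(free)[1], ]
      }
      if (is.null(nxt)) break
      cur <- nxt
    }
    # attach adjacent junction pixels at both ends (shared nodes)
    attach_junc <- function(p) {
      nb <- skel_neighbors(skel, p[1], p[2])
      if (is.null(nb)) return(NULL)
      jj <- nb[is_junc[nb], , drop = FALSE]
      if (nrow(jj)) jj[1, ] else NULL
    }
    hd <- attach_junc(path[1, ])
    tl <- if (nrow(path) > 1) attach_junc(path[nrow(path), ]) else NULL
    if (!is.null(hd)) path <- rbind(hd, path)
    if (!is.null(tl)) path <- rbind(path, tl)
    rownames(path) <- NULL
    branches[[length(branches) + 1L]] <- path
  }
  list(branches = branches, junctions = junctions, endpoints = endpoints)
}

#' Diameter profile of a myotube branch
#'
#' Local width at each branch pixel is twice the Euclidean distance
#' transform of the myotube mask at that pixel. For a stroke rendered as
#' a continuous band of geometric width w (the generator's tubes, at any
#' orientation) this recovers w to within one pixel; on blocky
#' axis-aligned masks built from whole pixel rows it reads one pixel
#' high, because the nearest background pixel *centre* lies half a pixel
#' beyond the ink boundary on each side. Samples within
#' `junction_buffer` px of a junction are excluded from the profile,
#' since the distance transform inflates where branches meet.
#'
#' @param myotube_mask Binary mask the branch was skeletonized from.
#' @param branch Ordered n x 2 pixel path (rows, cols, 1-based).
#' @param um_per_px Microns per pixel.
#' @param junctions Optional junction pixel matrix (from
#'   [extract_branches()]).
#' @param junction_buffer Exclusion radius around junctions in px.
#' @param min_branch_px Branches shorter than this are flagged
#'   (`flagged = TRUE`) so callers can exclude them from rollups.
#' @return List with `mean_um`, `profile_um`, and `flagged`.
#' @export
measure_diameter <- function(myotube_mask, branch, um_per_px = 1,
                             junctions = NULL, junction_buffer = 2,
                             min_branch_px = 5) {
  mask <- as_binary(myotube_mask, "myotube_mask")
  if (nrow(branch) == 0)
    return(list(mean_um = NA_real_, profile_um = numeric(0), flagged = TRUE))
  if (any(mask[branch] == 0L))
    stop("branch pixels must lie on the myotube mask")
  d <- distance_transform(mask)
  keep <- rep(TRUE, nrow(branch))
  if (!is.null(junctions) && nrow(junctions) > 0) {
    for (i in seq_len(nrow(branch))) {
      dj <- sqrt((junctions[, 1] - branch[i, 1])^2 +
                 (junctions[, 2] - branch[i, 2])^2)
      if (min(dj) <= junction_buffer) keep[i] <- FALSE
    }
  }
  if (!any(keep)) keep <- rep(TRUE, nrow(branch))  # tiny branch: keep all
  prof <- 2 * d[branch[keep, , drop = FALSE]] * um_per_px
  list(mean_um = mean(prof), profile_um = prof,
       flagged = nrow(branch) < min_branch_px)
}

#' Geodesic length of an ordered branch path
#'
#' Sum of per-step distances: 1 px for axis-aligned steps, sqrt(2) px for
#' diagonal steps, scaled by `um_per_px`. The path must be ordered: every
#' consecutive pair must be 8-adjacent.
#'
#' @inheritParams measure_diameter
#' @return Length in microns (0 for single-pixel paths).
#' @export
measure_length <- function(branch, um_per_px = 1) {
  n <- nrow(branch)
  if (n < 2) return(0)
  steps <- abs(branch[-1, , drop = FALSE] - branch[-n, , drop = FALSE])
  if (any(steps > 1) || any(rowSums(steps) == 0))
    stop("branch path is not an ordered 8-connected pixel sequence")
  sum(ifelse(rowSums(steps) == 2, sqrt(2), 1)) * um_per_px
}

#' Full morphometry of one segmented image
#'
#' Binarizes the three probability maps, splits the myotube mask into
#' instances, skeletonizes each and measures per-branch diameter and
#' length; separates nuclei with the marker-controlled watershed and
#' counts, for every myotube, the nucleus instances whose centroid falls
#' inside its mask.
#'
#' @param outputs `seg_outputs` (full-image probability maps) or a list of
#'   three binary masks under the same names.
#' @param um_per_px Microns per pixel.
#' @param binarize_threshold Probability threshold (default 0.5).
#' @param min_object_px Myotube components smaller than this are dropped.
#' @param marker_dilation_px Background-marker dilation, see
#'   [build_markers()].
#' @return List with data frames `branches` (myotube_id, branch_id,
#'   diameter_um, length_um, n_px, flagged) and `myotubes` (myotube_id,
#'   diameter_um, length_um, n_branches, n_nuclei), plus the nuclei
#'   `label_map`.
#' @export
quantify_image <- function(outputs, um_per_px = 1, binarize_threshold = 0.5,
                           min_object_px = 25L, marker_dilation_px = 3) {
  bin <- function(m) (as.matrix(m) >= binarize_threshold) * 1L
  myo <- bin(outputs$p_myotube)
  nuc <- bin(outputs$p_nuclei)
  cen <- bin(outputs$p_centroid)

  branches_df <- data.frame(myotube_id = integer(0), branch_id = integer(0),
                            diameter_um = numeric(0), length_um = numeric(0),
                            n_px = integer(0), flagged = logical(0))
  tubes_df <- data.frame(myotube_id = integer(0), diameter_um = numeric(0),
                         length_um = numeric(0), n_branches = integer(0),
                         n_nuclei = integer(0))

  nuclei_map <- structure(list(labels = matrix(0L, nrow(myo), ncol(myo)),
                               n = 0L), class = "label_map")
  if (sum(nuc) > 0 && sum(cen) > 0) {
    mk <- build_markers(nuc, cen, background_dilation = marker_dilation_px)
    nuclei_map <- watershed_segment(mk, nuc)
  }
  nuc_centroids <- label_centroids(nuclei_map$labels)

  if (sum(myo) == 0) {
    return(list(branches = branches_df, myotubes = tubes_df,
                nuclei = nuclei_map))
  }
  comp <- label_components(myo, connectivity = 8L)
  for (tube_id in seq_len(attr(comp, "n"))) {
    tube_mask <- (comp == tube_id) * 1L
    if (sum(tube_mask) < min_object_px) next
    skel <- skeletonize(tube_mask)
    br <- extract_branches(skel)
    dia_all <- numeric(0)
    len_all <- 0
    wt_all <- numeric(0)
    for (b in seq_along(br$branches)) {
      path <- br$branches[[b]]
      dm <- measure_diameter(tube_mask, path, um_per_px = um_per_px,
                             junctions = br$junctions)
      ln <- measure_length(path, um_per_px = um_per_px)
      branches_df <- rbind(branches_df, data.frame(
        myotube_id = tube_id, branch_id = b, diameter_um = dm$mean_um,
        length_um = ln, n_px = nrow(path), flagged = dm$flagged))
      if (!dm$flagged) {
        dia_all <- c(dia_all, dm$mean_um)
        wt_all <- c(wt_all, nrow(path))
      }
      len_all <- len_all + ln
    }
    n_in <- if (nrow(nuc_centroids))
      sum(tube_mask[nuc_centroids] == 1L) else 0L
    tubes_df <- rbind(tubes_df, data.frame(
      myotube_id = tube_id,
      diameter_um = if (length(dia_all))
        sum(dia_all * wt_all) / sum(wt_all) else NA_real_,
      length_um = len_all,
      n_branches = length(br$branches),
      n_nuclei = n_in))
  }
  list(branches = branches_df, myotubes = tubes_df, nuclei = nuclei_map)
}
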