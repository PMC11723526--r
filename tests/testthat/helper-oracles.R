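# Independent reference implementations used as oracles. These deliberately
# use naive algorithms (explicit loops, linear scans) so that they share no
# code path with the package implementations they check.

# connected components by literal breadth-first flood fill
flood_count <- function(mask, connectivity = 4) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else {
    out <- list()
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) out[[length(out) + 1]] <- c(dr, dc)
    out
  }
  n <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c] == 0 || seen[r, c]) next
    n <- n + 1
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in nb) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] != 0 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  n
}

# naive marker-controlled watershed: same contract as the package flood
# (4-connectivity, non-decreasing relief, FIFO within a level, a pixel
# reached by two distinct nucleus floods becomes the line -1; the
# background flood never forms a line), implemented with a plain frontier
# list and linear minimum scans.
ws_oracle <- function(markers, relief) {
  H <- nrow(markers); W <- ncol(markers)
  lab <- markers
  queued <- matrix(FALSE, H, W)
  fr_r <- integer(0); fr_c <- integer(0); fr_rel <- numeric(0); fr_seq <- integer(0)
  seqc <- 0L
  neigh <- function(r, c) {
    out <- list()
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
        out[[length(out) + 1]] <- c(rr, cc)
    }
    out
  }
  push <- function(r, c) {
    fr_r <<- c(fr_r, r); fr_c <<- c(fr_c, c)
    fr_rel <<- c(fr_rel, relief[r, c]); fr_seq <<- c(fr_seq, seqc)
    seqc <<- seqc + 1L
    queued[r, c] <<- TRUE
  }
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (lab[r, c] != 0) next
    for (n in neigh(r, c)) if (lab[n[1], n[2]] > 0) { push(r, c); break }
  }
  while (length(fr_r)) {
    best <- 1
    for (i in seq_along(fr_r)) {
      if (fr_rel[i] < fr_rel[best] ||
          (fr_rel[i] == fr_rel[best] && fr_seq[i] < fr_seq[best])) best <- i
    }
    r <- fr_r[best]; c <- fr_c[best]
    fr_r <- fr_r[-best]; fr_c <- fr_c[-best]
    fr_rel <- fr_rel[-best]; fr_seq <- fr_seq[-best]
    if (lab[r, c] != 0) next
    nucs <- integer(0); saw_wl <- FALSE; saw_bg <- FALSE
    for (n in neigh(r, c)) {
      l <- lab[n[1], n[2]]
      if (l >= 2) nucs <- union(nucs, l)
      if (l == 1) saw_bg <- TRUE
      if (l == -1) saw_wl <- TRUE
    }
    if (length(nucs) >= 2) lab[r, c] <- -1L
    else if (length(nucs) == 1) lab[r, c] <- nucs
    else if (saw_bg) lab[r, c] <- 1L
    else if (saw_wl) lab[r, c] <- -1L
    else next
    for (n in neigh(r, c))
      if (lab[n[1], n[2]] == 0 && !queued[n[1], n[2]]) push(n[1], n[2])
  }
  lab[lab == 0 & markers == 0] <- -1L
  lab
}

# per-pixel loop implementation of mean binary cross-entropy
bce_loop <- function(pred, target, eps = 1e-7) {
  s <- 0
  n <- 0
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], eps), 1 - eps)
    s <- s - (target[i] * log(p) + (1 - target[i]) * log(1 - p))
    n <- n + 1
  }
  s / n
}

# horizontal constant-width bar: `width` rows centred at `row`
straight_tube_mask <- function(H, W, width, row = round(H / 2),
                               margin = 3) {
  m <- matrix(0L, H, W)
  half <- (width - 1) / 2
  rows <- max(1, round(row - half)):min(H, round(row + half))
  m[rows, (1 + margin):(W - margin)] <- 1L
  m
}

# filled disk
disk_mask <- function(H, W, r0, c0, radius) {
  m <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W))
    if ((r - r0)^2 + (c - c0)^2 <= radius^2) m[r, c] <- 1L
  m
}

# overlapping-nuclei toy scene: random disks + centre dots
random_nuclei_scene <- function(seed, H = 48, W = 48, n = 5) {
  set.seed(seed)
  nuc <- matrix(0L, H, W)
  cen <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    r0 <- sample(8:(H - 8), 1); c0 <- sample(8:(W - 8), 1)
    rad <- sample(4:7, 1)
    nuc <- pmax(nuc, disk_mask(H, W, r0, c0, rad))
    cen[r0, c0] <- 1L
  }
  list(nuclei = nuc, centroid = cen)
}

# scene -> training sample
mk_sample <- function(seed, ...) {
  sc <- generate_scene(scene_spec(seed = seed, ...))
  list(x = sc$image$pixels, labels = make_labels_from_truth(sc$truth),
       truth = sc$truth)
}
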