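# Classical global auto-threshold baselines, computed on a 256-bin
# histogram of the [0,1]-normalized channel. Pixels strictly above the
# returned threshold are foreground.

hist256 <- function(x) {
  v <- pmin(pmax(as.numeric(x), 0), 1)
  bin <- pmin(floor(v * 256) + 1L, 256L)
  tabulate(bin, 256L)
}

bin_centers <- (seq_len(256) - 0.5) / 256
bin_edges <- seq_len(256) / 256   # upper edge of each bin

otsu_threshold <- function(h) {
  n <- sum(h)
  p <- h / n
  omega <- cumsum(p)
  mu <- cumsum(p * bin_centers)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b[-256])
  bin_edges[k]
}

isodata_threshold <- function(h) {
  # fixed point of t = (mean below + mean above) / 2
  t <- sum(h * bin_centers) / sum(h)
  for (i in 1:1000) {
    below <- bin_centers <= t
    m0 <- sum(h[below] * bin_centers[below]) / max(sum(h[below]), 1)
    m1 <- sum(h[!below] * bin_centers[!below]) / max(sum(h[!below]), 1)
    tn <- (m0 + m1) / 2
    if (abs(tn - t) < 1e-7) break
    t <- tn
  }
  t
}

li_threshold <- function(h) {
  # Li & Tam iterative minimum cross-entropy; intensities shifted off zero
  g <- bin_centers + 1 / 512
  t <- sum(h * g) / sum(h)
  for (i in 1:1000) {
    below <- g <= t
    m0 <- sum(h[below] * g[below]) / max(sum(h[below]), 1)
    m1 <- sum(h[!below] * g[!below]) / max(sum(h[!below]), 1)
    if (m0 <= 0 || m1 <= 0) break
    tn <- (m0 - m1) / (log(m0) - log(m1))
    if (!is.finite(tn)) break
    if (abs(tn - t) < 1e-7) break
    t <- tn
  }
  t - 1 / 512
}

mean_threshold <- function(x) mean(as.numeric(x))

minimum_threshold <- function(h) {
  # smooth the histogram with a 3-point running mean until exactly two
  # local maxima remain; threshold = the minimum between them
  s <- as.numeric(h)
  smooth3 <- function(v) {
    n <- length(v)
    (c(v[1], v[-n]) + v + c(v[-1], v[n])) / 3
  }
  n_modes <- function(v) {
    n <- length(v)
    left <- c(-Inf, v[-n])
    right <- c(v[-1], -Inf)
    sum(v > left & v >= right)
  }
  for (i in 1:10000) {
    if (n_modes(s) <= 2) break
    s <- smooth3(s)
  }
  if (n_modes(s) < 2)
    stop("histogram could not be made bimodal (is the image constant?)")
  n <- length(s)
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  peaks <- which(s > left & s >= right)
  p1 <- peaks[1]; p2 <- peaks[length(peaks)]
  valley <- which.min(s[p1:p2]) + p1 - 1L
  bin_edges[valley]
}

yen_threshold <- function(h) {
  p <- h / sum(h)
  P0 <- cumsum(p)
  G0 <- cumsum(p^2)
  G1 <- G0[256] - G0
  crit <- -log(pmax(G0 * G1, 1e-300)) +
    2 * log(pmax(P0 * (1 - P0), 1e-300))
  crit[!is.finite(crit)] <- -Inf
  k <- which.max(crit[-256])
  bin_edges[k]
}

#' Global auto-threshold value of a channel
#'
#' Computes the scalar threshold chosen by one of six classical histogram
#' criteria (IsoData, Li, Mean, Minimum, Otsu, Yen) on a 256-bin histogram
#' of the `[0,1]` channel.
#'
#' @param channel Numeric matrix with values in `[0, 1]`.
#' @param method One of `"isodata"`, `"li"`, `"mean"`, `"minimum"`,
#'   `"otsu"`, `"yen"`.
#' @return Threshold on the intensity scale; pixels strictly above it are
#'   foreground.
#' @export
threshold_value <- function(channel,
                            method = c("isodata", "li", "mean", "minimum",
                                       "otsu", "yen")) {
  method <- match.arg(method)
  x <- as.matrix(channel)
  if (max(x) - min(x) <= 0) {
    warning("constant image; threshold set above the constant (empty foreground)")
    return(max(x))
  }
  h <- hist256(x)
  switch(method,
         isodata = isodata_threshold(h),
         li = li_threshold(h),
         mean = mean_threshold(x),
         minimum = minimum_threshold(h),
         otsu = otsu_threshold(h),
         yen = yen_threshold(h))
}

#' Auto-threshold segmentation baseline
#'
#' @inheritParams threshold_value
#' @return Binary mask (pixels above the threshold).
#' @export
threshold_segment <- function(channel, method = "otsu") {
  t <- threshold_value(channel, method)
  out <- (as.matrix(channel) > t) * 1L
  storage.mode(out) <- "integer"
  out
}
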