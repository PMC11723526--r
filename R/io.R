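#' Write a grayscale image as plain-text (ASCII) PGM
#'
#' Netpbm "P2" portable graymap: a standard, human-readable raster format.
#' Values in `[0, 1]` are quantized to `0..maxval`.
#'
#' @param img Numeric matrix with values in `[0, 1]` (or integers already on
#'   the `0..maxval` scale when `raw = TRUE`).
#' @param path Output file path.
#' @param maxval Maximum gray value (255 or 65535).
#' @param raw If `TRUE`, `img` is written as-is without rescaling.
#' @export
write_pgm <- function(img, path, maxval = 255L, raw = FALSE) {
  m <- as.matrix(img)
  vals <- if (raw) round(m) else round(m * maxval)
  vals[vals < 0] <- 0
  vals[vals > maxval] <- maxval
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)),
               sprintf("%d", maxval)), con)
  # one image row per line
  writeLines(apply(vals, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text (ASCII) PGM image
#'
#' @param path File path of a `P2` PGM.
#' @param rescale If `TRUE` (default) return values divided by the file's
#'   maxval, giving a `[0, 1]` matrix; otherwise raw integers.
#' @return Numeric (or integer) matrix, rows = image rows.
#' @export
read_pgm <- function(path, rescale = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != h * w)
    stop(sprintf("corrupt PGM %s: expected %d values, found %d",
                 path, h * w, length(vals)))
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (rescale) m / maxval else m
}

#' Write / read a binary mask ({0,1} in memory, {0,maxval} on disk)
#' @param mask Binary matrix.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  m <- as_binary(mask)
  write_pgm(m * 255L, path, maxval = 255L, raw = TRUE)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- read_pgm(path, rescale = FALSE)
  out <- (m > 0) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Read one scene (image + ground truth) from a dataset manifest row
#'
#' @param row One row of the manifest written by [generate_dataset()], or a
#'   named list with the same `path_*` fields.
#' @return List with `image` ([fluor_image()]) and `truth` (masks; the
#'   label map is re-read as integers).
#' @export
read_scene <- function(row) {
  ch1 <- read_pgm(row$path_myotube)
  ch2 <- read_pgm(row$path_nuclei)
  img <- fluor_image(ch1, ch2,
                     um_per_px = row$um_per_px %||% 1.0,
                     source = row$path_myotube)
  lab <- NULL
  if (!is.null(row$path_labels) && file.exists(row$path_labels)) {
    lab <- read_pgm(row$path_labels, rescale = FALSE)
    storage.mode(lab) <- "integer"
  }
  truth <- structure(list(
    myotube_mask = read_mask(row$path_mask_myotube),
    nuclei_mask = read_mask(row$path_mask_nuclei),
    centroid_mask = read_mask(row$path_mask_centroid),
    nuclei_labels = lab,
    tube_axes = NULL), class = "ground_truth")
  list(image = img, truth = truth)
}
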