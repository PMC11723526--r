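#' End-to-end pipeline configuration
#'
#' Validated, fully serializable configuration tying the modules together;
#' its JSON snapshot (and a short hash of it) is embedded in every output
#' for provenance.
#'
#' @param manifest Data frame as written by [generate_dataset()] (or a
#'   path to such a CSV), one row per image.
#' @param groups Character vector, one group label per manifest row
#'   (e.g. `"Y-Con"`, `"Y-Dex"`, `"A-Con"`, `"A-Dex"`; labels are free
#'   strings).
#' @param um_per_px Microns per pixel (overrides the manifest when given).
#' @param checkpoint Path to a model checkpoint
#'   ([save_checkpoint()]); required unless `use_truth_masks`.
#' @param use_truth_masks Bypass the model and feed the ground-truth masks
#'   into post-processing (the fully deterministic validation mode).
#' @param binarize_threshold,min_object_px,marker_dilation_px
#'   Post-processing settings, see [quantify_image()].
#' @param tile_size,overlap Inference tiling, see [predict_image()].
#' @param out_dir Optional directory for per-image CSVs and the summary.
#' @param seed RNG seed recorded in the provenance block.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, groups, um_per_px = NULL,
                            checkpoint = NULL, use_truth_masks = FALSE,
                            binarize_threshold = 0.5, min_object_px = 25L,
                            marker_dilation_px = 3, tile_size = NULL,
                            overlap = 0L, out_dir = NULL, seed = 1L) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (nrow(manifest) == 0) stop("manifest is empty")
  if (length(groups) != nrow(manifest))
    stop(sprintf("groups has length %d but the manifest has %d rows",
                 length(groups), nrow(manifest)))
  if (!use_truth_masks && is.null(checkpoint))
    stop("either provide a model checkpoint or set use_truth_masks = TRUE")
  if (!is.null(checkpoint) && !file.exists(checkpoint))
    stop("checkpoint file not found: ", checkpoint)
  for (p in manifest$path_myotube)
    if (!file.exists(p)) stop("missing channel file: ", p)
  structure(list(manifest = manifest, groups = as.character(groups),
                 um_per_px = um_per_px, checkpoint = checkpoint,
                 use_truth_masks = isTRUE(use_truth_masks),
                 binarize_threshold = binarize_threshold,
                 min_object_px = as.integer(min_object_px),
                 marker_dilation_px = marker_dilation_px,
                 tile_size = tile_size, overlap = as.integer(overlap),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  ser <- unclass(cfg)
  ser$manifest <- NULL
  ser$out_dir <- NULL          # run location, not an analysis setting
  ser <- ser[!vapply(ser, is.null, logical(1))]
  fnv1a(as.character(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA)))
}

#' Run the full quantification pipeline
#'
#' For every image: obtain the three maps (model prediction, tiled if
#' configured, or ground-truth masks in `use_truth_masks` mode), run
#' [quantify_image()], and collect per-myotube records; then summarize
#' per experimental group. With `out_dir` set, writes one records CSV per
#' image plus `group_summary.csv`, each stamped with the config hash.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `summary` (from [summarize_groups()]), `per_image`
#'   (data frame of per-image mean diameter and nuclei-per-myotube),
#'   `records` (list of per-image [quantify_image()] results), and
#'   `config_hash`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  model <- if (!cfg$use_truth_masks) load_checkpoint(cfg$checkpoint) else NULL
  hash <- config_hash(cfg)
  n <- nrow(cfg$manifest)
  per_image <- data.frame(scene = character(n), group = character(n),
                          diameter_um = numeric(n), n_nuclei = numeric(n),
                          n_myotubes = integer(n), stringsAsFactors = FALSE)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    row <- cfg$manifest[i, ]
    sc <- read_scene(row)
    um <- cfg$um_per_px %||% sc$image$um_per_px
    maps <- if (cfg$use_truth_masks) {
      list(p_myotube = sc$truth$myotube_mask,
           p_nuclei = sc$truth$nuclei_mask,
           p_centroid = sc$truth$centroid_mask)
    } else {
      predict_image(model, sc$image, tile_size = cfg$tile_size,
                    overlap = cfg$overlap)
    }
    q <- quantify_image(maps, um_per_px = um,
                        binarize_threshold = cfg$binarize_threshold,
                        min_object_px = cfg$min_object_px,
                        marker_dilation_px = cfg$marker_dilation_px)
    records[[i]] <- q
    tubes <- q$myotubes
    per_image$scene[i] <- as.character(row$scene %||% i)
    per_image$group[i] <- cfg$groups[i]
    per_image$diameter_um[i] <- if (nrow(tubes))
      mean(tubes$diameter_um, na.rm = TRUE) else NA_real_
    per_image$n_nuclei[i] <- if (nrow(tubes))
      mean(tubes$n_nuclei) else NA_real_
    per_image$n_myotubes[i] <- nrow(tubes)
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(cfg$out_dir,
                     sprintf("%s_records.csv", per_image$scene[i]))
      con <- file(f, "w")
      writeLines(sprintf("# config_hash: %s", hash), con)
      utils::write.csv(q$branches, con, row.names = FALSE)
      close(con)
    }
  }
  summary <- summarize_groups(per_image)
  if (!is.null(cfg$out_dir)) {
    f <- file.path(cfg$out_dir, "group_summary.csv")
    con <- file(f, "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    utils::write.csv(summary, con, row.names = FALSE)
    close(con)
  }
  list(summary = summary, per_image = per_image, records = records,
       config_hash = hash)
}

#' Per-group summaries of myotube morphometry
#'
#' Mean and sample standard deviation (n-1 denominator) of the per-image
#' mean myotube diameter and nuclei-per-myotube, per experimental group;
#' optionally percent change and Welch t-test p-values against a named
#' reference group (the test is a convenience -- no particular test is
#' canonical for these summaries).
#'
#' @param per_image Data frame with columns `group`, `diameter_um`,
#'   `n_nuclei` (one row per image), e.g. from [run_pipeline()].
#' @param reference Optional reference group label for deltas.
#' @return Data frame with one row per group (group order = first
#'   appearance): `group`, `n_images`, `diameter_mean`, `diameter_sd`,
#'   `nuclei_mean`, `nuclei_sd`, and with a reference also
#'   `diameter_delta_pct`, `nuclei_delta_pct`, `p_diameter`, `p_nuclei`.
#' @export
summarize_groups <- function(per_image, reference = NULL) {
  if (nrow(per_image) == 0) stop("no per-image records to summarize")
  glev <- unique(per_image$group)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  rows <- lapply(glev, function(g) {
    d <- per_image[per_image$group == g, ]
    if (nrow(d) == 0) stop("empty group: ", g)
    data.frame(group = g, n_images = nrow(d),
               diameter_mean = mean(d$diameter_um, na.rm = TRUE),
               diameter_sd = sd0(d$diameter_um[!is.na(d$diameter_um)]),
               nuclei_mean = mean(d$n_nuclei, na.rm = TRUE),
               nuclei_sd = sd0(d$n_nuclei[!is.na(d$n_nuclei)]),
               single_image = nrow(d) < 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    if (!reference %in% glev) stop("unknown reference group: ", reference)
    ref <- per_image[per_image$group == reference, ]
    out$diameter_delta_pct <- 100 * (out$diameter_mean /
      mean(ref$diameter_um, na.rm = TRUE) - 1)
    out$nuclei_delta_pct <- 100 * (out$nuclei_mean /
      mean(ref$n_nuclei, na.rm = TRUE) - 1)
    pvals <- function(col) vapply(glev, function(g) {
      if (g == reference) return(NA_real_)
      a <- per_image[per_image$group == g, col]
      b <- ref[[col]]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      stats::t.test(a, b)$p.value
    }, numeric(1))
    out$p_diameter <- pvals("diameter_um")
    out$p_nuclei <- pvals("n_nuclei")
  }
  rownames(out) <- NULL
  out
}
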