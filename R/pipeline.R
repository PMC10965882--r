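## End-to-end orchestration: screen -> metrics -> image statistics ->
## regression -> rotation, over synthetic or user-supplied inputs.

#' Pipeline configuration
#'
#' Collects every stage parameter plus input/output paths.  With
#' `synth = TRUE` (default) the input bundle is generated by
#' [gen_dataset()] from `synth_cfg`; otherwise `paths$events`,
#' `paths$annotations` and `paths$embeddings` are read with the package
#' readers.
#'
#' @param synth generate inputs synthetically.
#' @param synth_cfg a [synth_config()].
#' @param paths named list of input paths (`events`, `annotations`,
#'   `embeddings`) when `synth = FALSE`.
#' @param out_dir output directory (`NULL` keeps results in memory only).
#' @param px_per_deg,fdm_fwhm_deg,n_segments gaze-metric parameters.
#' @param glcm_mode,glcm_levels,glcm_window texture parameters.
#' @param gabor_px_per_deg pixel scale announced to the Gabor bank.
#' @param rotation run the rotation-invariance stage.
#' @param restrict_correct restrict similarity statistics to correctly
#'   classified images.
#' @param seed master seed (propagated to `synth_cfg` when generating).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = TRUE, synth_cfg = synth_config(),
                            paths = list(), out_dir = NULL, px_per_deg = 40,
                            fdm_fwhm_deg = 0.5, n_segments = 6,
                            glcm_mode = "windowed", glcm_levels = 64,
                            glcm_window = 3, gabor_px_per_deg = 40,
                            rotation = TRUE, restrict_correct = FALSE,
                            seed = 1L) {
  if (synth) synth_cfg$seed <- as.integer(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in fixed order: event screening, per-observer gaze metrics and
#' image/category aggregation, image statistics, luminance-controlled
#' stepwise regressions of the five eye-movement variables on the nine
#' image statistics, and (optionally) the rotation-invariance ANOVA report.
#' All randomness flows from the configuration seed, so identical
#' configurations give identical result bundles.
#'
#' @param cfg a [pipeline_config()].
#' @return List of class `pipeline_result`: `screening` (stage reports),
#'   `metrics` (observer x image records), `metrics_image`,
#'   `metrics_category`, `image_stats`, `regressions_image`,
#'   `regressions_category`, `rotation` (or `NULL`), `manifest`.
#'   When `cfg$out_dir` is set, tables are also written there as CSV/JSON
#'   with a `manifest.json`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$synth) {
    bundle <- gen_dataset(cfg$synth_cfg)
    gaze <- bundle$gaze
    meta <- bundle$meta
    annotations <- bundle$annotations
    embeddings <- bundle$embeddings
    images <- bundle$images
  } else {
    gaze <- load_events(cfg$paths$events)
    annotations <- if (!is.null(cfg$paths$annotations))
      read_annotations(cfg$paths$annotations) else list()
    embeddings <- if (!is.null(cfg$paths$embeddings))
      list(blk5 = read_embeddings(cfg$paths$embeddings)) else list()
    images <- NULL
    meta <- unique(gaze$trials[c("image_id", "category")])
  }
  size <- if (cfg$synth) cfg$synth_cfg$image_size_px else 600

  scr_cfg <- screening_config(image_size_px = size,
                              viewing_ms = if (cfg$synth)
                                cfg$synth_cfg$viewing_ms else 3000)
  scr <- screen_gaze(gaze, scr_cfg)

  metrics <- summarize_gaze(scr$data, image_size_px = size,
                            px_per_deg = cfg$px_per_deg,
                            fwhm_deg = cfg$fdm_fwhm_deg,
                            n_segments = cfg$n_segments)
  categories <- setNames(meta$category, meta$image_id)
  m_img <- aggregate_gaze(metrics, "image", categories)
  m_cat <- aggregate_gaze(metrics, "category", categories)

  emb_stats <- if (length(embeddings))
    embedding_statistics(embeddings,
                         sim_layer = intersect(c("blk5", names(embeddings)),
                                               names(embeddings))[1],
                         restrict_correct = cfg$restrict_correct)
  else NULL
  gcfg <- gabor_config(px_per_deg = cfg$gabor_px_per_deg)
  stats_rows <- lapply(names(images), function(id) {
    es <- if (!is.null(emb_stats)) {
      r <- emb_stats[emb_stats$image_id == id, , drop = FALSE]
      unlist(r[setdiff(names(r), "image_id")])
    } else NULL
    compute_image_stats(images[[id]], id, annotations[[id]], es,
                        gabor_cfg = gcfg, glcm_levels = cfg$glcm_levels,
                        glcm_window = cfg$glcm_window,
                        glcm_mode = cfg$glcm_mode)
  })
  istats <- do.call(rbind, stats_rows)
  istats$category <- unname(categories[istats$image_id])

  responses <- c("mean_fixation_duration_ms", "n_fixations",
                 "fdm_entropy_bits", "mean_saccade_amplitude_dva",
                 "gte_normalized")
  predictors <- c("gabor_low_sf", "gabor_high_sf", "homogeneity",
                  "within_sim", "across_sim", "cos", "blk1_l2", "blk5_l2",
                  "fc2_l2")
  img_tab <- merge(m_img, istats[istats$orientation_deg == 0, ],
                   by = "image_id")
  use_pred <- predictors[colSums(!is.na(img_tab[predictors])) > 0]
  reg_img <- regress_gaze_on_stats(img_tab, responses, use_pred, "image")
  cat_stats <- stats::aggregate(
    istats[istats$orientation_deg == 0, c(use_pred, "luminance")],
    by = list(category = istats$category[istats$orientation_deg == 0]),
    FUN = mean)
  cat_tab <- merge(m_cat, cat_stats, by = "category")
  reg_cat <- if (nrow(cat_tab) > length(use_pred) + 2)
    regress_gaze_on_stats(cat_tab, responses, use_pred, "category")
  else NULL

  rot <- NULL
  if (cfg$rotation && !is.null(images)) {
    rot_rows <- lapply(names(images), function(id)
      rotate_stats(images[[id]], id, annotations[[id]],
                   gabor_cfg = gcfg, glcm_levels = cfg$glcm_levels,
                   glcm_window = cfg$glcm_window, glcm_mode = cfg$glcm_mode))
    rot_tab <- do.call(rbind, rot_rows)
    rot_tab$category <- unname(categories[rot_tab$image_id])
    rot <- rotation_report(rot_tab,
                           statistics = c("gabor_low_sf", "gabor_high_sf",
                                          "homogeneity", "cos"))
  }

  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("scenegaze")),
                   n_images = length(images), n_trials = nrow(gaze$trials),
                   stages = c("screen", "metrics", "imagestats", "regress",
                              if (!is.null(rot)) "rotate"))
  res <- structure(list(screening = scr$report, metrics = metrics,
                        metrics_image = m_img, metrics_category = m_cat,
                        image_stats = istats, regressions_image = reg_img,
                        regressions_category = reg_cat, rotation = rot,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) .write_bundle(res, cfg$out_dir)
  res
}

.write_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$metrics, file.path(dir, "metrics_observer_image.csv"),
            row.names = FALSE)
  write.csv(res$metrics_image, file.path(dir, "metrics_image.csv"),
            row.names = FALSE)
  write.csv(res$metrics_category, file.path(dir, "metrics_category.csv"),
            row.names = FALSE)
  write.csv(res$image_stats, file.path(dir, "image_stats.csv"),
            row.names = FALSE)
  if (!is.null(res$rotation))
    write.csv(res$rotation, file.path(dir, "rotation_report.csv"),
              row.names = FALSE)
  screening_report_json(res$screening, file.path(dir, "screening_report.json"))
  reg_to_list <- function(fits) lapply(fits, function(f)
    list(response = attr(f, "response"), selected = f$selected,
         adj_r_squared = f$adj_r_squared,
         coefficients = f$coefficients))
  regs <- list(image = reg_to_list(res$regressions_image))
  if (!is.null(res$regressions_category))
    regs$category <- reg_to_list(res$regressions_category)
  writeLines(jsonlite::toJSON(regs, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE),
             file.path(dir, "regressions.json"))
  writeLines(jsonlite::toJSON(res$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  trials retained:", x$screening$trials$retained, "/",
      x$screening$trials$n_input, "\n")
  cat("  observer x image records:", nrow(x$metrics), "\n")
  cat("  image statistics rows:", nrow(x$image_stats), "\n")
  cat("  image-level regressions:", length(x$regressions_image), "\n")
  if (!is.null(x$rotation))
    cat("  rotation tests:", nrow(x$rotation), "\n")
  invisible(x)
}

#' Read and write PNG images
#'
#' Thin wrappers for moving sRGB rasters in and out of the pipeline.
#' @param path PNG file.
#' @return `read_image()`: H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) stop("grayscale PNG: a 3-channel image is required")
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @param img H x W x 3 array in `[0, 1]`.
#' @export
write_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
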