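## Rotation-invariance harness: recompute image statistics at the four
## right-angle orientations and test orientation effects per category.

#' Rotate a raster counterclockwise in 90-degree steps
#'
#' Pure index permutation — no resampling, no interpolation noise.  Works on
#' grayscale matrices and H x W x C arrays.  Only square rasters are
#' accepted (right-angle rotation is then closed under the pixel grid;
#' oblique angles would require padding and are out of scope).
#'
#' @param img matrix or 3-d array.
#' @param k number of counterclockwise quarter turns (0-3).
#' @return Rotated raster of the same type.
#' @export
rotate_raster <- function(img, k = 1) {
  k <- as.integer(k) %% 4L
  rot1 <- function(m) t(m[, rev(seq_len(ncol(m))), drop = FALSE])
  apply_k <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (is.matrix(img)) {
    if (nrow(img) != ncol(img)) stop("rotation requires a square raster")
    return(apply_k(img))
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[1] != dim(img)[2]) stop("rotation requires a square raster")
    out <- img
    for (c_ in seq_len(dim(img)[3])) out[, , c_] <- apply_k(img[, , c_])
    return(out)
  }
  stop("img must be a matrix or a 3-d array")
}

#' Rotate annotation vertices with the raster
#'
#' Applies the continuous-coordinate counterpart of [rotate_raster()]:
#' one counterclockwise quarter turn maps `(x, y)` to `(y, S - x)` for a
#' square image of side `S` (origin top-left, y downward).  Area and
#' distance to the image center are preserved exactly.
#'
#' @param ann an [annotation()] or list of annotations.
#' @param image_size_px image side length.
#' @param k counterclockwise quarter turns.
#' @return Rotated annotation(s).
#' @export
rotate_annotations <- function(ann, image_size_px = 600, k = 1) {
  k <- as.integer(k) %% 4L
  rot_one <- function(a) {
    v <- a$vertices_px
    for (i in seq_len(k)) v <- cbind(v[, 2], image_size_px - v[, 1])
    a$vertices_px <- unname(v)
    a
  }
  if (inherits(ann, "annotation")) return(rot_one(ann))
  lapply(ann, rot_one)
}

#' Image statistics at the four right-angle orientations
#'
#' Rotates the image and its annotations to 0/90/180/270 degrees and
#' recomputes every statistic with [compute_image_stats()].  Embedding-based
#' statistics, which come from an external representation of each rotated
#' image, are supplied per orientation.
#'
#' @param img H x W x 3 sRGB array (square).
#' @param image_id image identifier.
#' @param annotations list of [annotation()] objects (may be empty).
#' @param embedding_stats_by_orientation optional named list
#'   (`"0"`, `"90"`, `"180"`, `"270"`) of embedding statistic vectors.
#' @param ... further arguments passed to [compute_image_stats()].
#' @return data.frame of four `ImageStatsRecord` rows.
#' @export
rotate_stats <- function(img, image_id, annotations = list(),
                         embedding_stats_by_orientation = NULL, ...) {
  if (dim(img)[1] != dim(img)[2]) stop("rotation requires a square image")
  size <- dim(img)[1]
  rows <- lapply(0:3, function(k) {
    deg <- 90L * k
    emb <- embedding_stats_by_orientation[[as.character(deg)]]
    compute_image_stats(rotate_raster(img, k), image_id,
                        rotate_annotations(annotations, size, k),
                        embedding_stats = emb, orientation_deg = deg, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way orientation ANOVA for an image statistic
#'
#' Fixed-effects one-way ANOVA of a statistic across image orientations,
#' computed within one scene category (groups of equal size: the category's
#' images at each orientation).  Statistics that are exactly invariant
#' (zero between- and within-group variance, e.g. geometric ones) are
#' flagged `invariant_exact` with an undefined F.
#'
#' @param stats_table data.frame with columns `image_id`, `orientation_deg`,
#'   and the statistic; typically rows of [rotate_stats()] for one
#'   category's images.
#' @param statistic statistic column name.
#' @return One-row data.frame: `statistic`, `F`, `p`, `invariant_exact`,
#'   and the per-orientation group means (`mean_0` ... `mean_270`).
#' @export
rotation_anova <- function(stats_table, statistic) {
  stopifnot(statistic %in% names(stats_table))
  v <- stats_table[[statistic]]
  g <- factor(stats_table$orientation_deg)
  if (nlevels(g) < 2) stop("need at least 2 orientations")
  if (min(table(g)) < 2) stop("need at least 2 images per orientation group")
  means <- tapply(v, g, mean)
  # exact invariance: identical group means (bitwise), as for statistics
  # defined on rotation-preserved geometry
  exact <- all(means == means[1])
  if (exact && var(v) == 0) {
    Fv <- NA_real_; pv <- NA_real_        # no variance at all: F undefined
  } else {
    a <- anova(lm(v ~ g))
    Fv <- a$`F value`[1]; pv <- a$`Pr(>F)`[1]
  }
  out <- data.frame(statistic = statistic, F = Fv, p = pv,
                    invariant_exact = exact, stringsAsFactors = FALSE)
  for (nm in names(means)) out[[paste0("mean_", nm)]] <- unname(means[nm])
  out
}

#' Rotation report over categories and statistics
#'
#' Runs [rotation_anova()] for every (category, statistic) pair.
#'
#' @param stats_table data.frame of `ImageStatsRecord` rows for all images
#'   at all four orientations, with a `category` column.
#' @param statistics statistic columns to test.
#' @return data.frame: one row per category x statistic.
#' @export
rotation_report <- function(stats_table,
                            statistics = c("gabor_low_sf", "gabor_high_sf",
                                           "homogeneity", "within_sim",
                                           "across_sim", "cos", "blk1_l2",
                                           "blk5_l2", "fc2_l2")) {
  stopifnot("category" %in% names(stats_table))
  statistics <- intersect(statistics, names(stats_table))
  rows <- list()
  for (cat_ in unique(stats_table$category)) {
    sub <- stats_table[stats_table$category == cat_, , drop = FALSE]
    for (st in statistics) {
      if (all(is.na(sub[[st]]))) next
      r <- rotation_anova(sub[!is.na(sub[[st]]), , drop = FALSE], st)
      r <- cbind(category = cat_, r, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
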