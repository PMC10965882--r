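## Low-, mid- and object-level image statistics.

#' Mean CIELAB luminance of a true-color image
#'
#' Converts an sRGB image to CIE L*a*b* (D65 white) and returns the pixel
#' mean of the L* channel.  Luminance is the covariate regressed out of the
#' eye-movement data before model selection.
#'
#' @param img H x W x 3 array with values in `[0, 1]` (sRGB, gamma-encoded).
#' @return Mean L* (0 for black, 100 for white).
#' @export
luminance_L <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("luminance_L needs a 3-channel sRGB image")
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  mean(lab[, 1])
}

#' Gabor filter bank configuration
#'
#' The bank spans 12 orientations (0 to 165 degrees in 15-degree steps;
#' quadrature energy makes orientations 180 degrees apart redundant) and 8
#' spatial frequencies logarithmically spaced between 0.35 and 8.56 cycles
#' per degree, giving a 96-dimensional energy vector per image.  Energies
#' are pooled over a grid of Gaussian population-receptive-field (pRF)
#' windows; the default grid is a single uniform full-image window, i.e.
#' plain averaging of the energy map.
#'
#' @param n_orientations,orientations_deg orientation sampling.
#' @param n_frequencies number of frequency bands.
#' @param freq_range_cpd frequency range in cycles per degree (log-spaced).
#' @param px_per_deg pixel scale of the images the bank is applied to.
#' @param bandwidth_octaves approximate frequency bandwidth of each filter.
#' @param prf_grid optional data.frame `x_px`, `y_px`, `sigma_px` of Gaussian
#'   pooling windows; `NULL` means one uniform full-image window.
#' @param full_circle if `TRUE`, use the 0-360 degree orientation variant
#'   (orientations then wrap; redundant under quadrature energy).
#' @return A list of class `gabor_config`.
#' @export
gabor_config <- function(n_orientations = 12, orientations_deg = NULL,
                         n_frequencies = 8, freq_range_cpd = c(0.35, 8.56),
                         px_per_deg = 40, bandwidth_octaves = 1,
                         prf_grid = NULL, full_circle = FALSE) {
  if (is.null(orientations_deg)) {
    span <- if (full_circle) 360 else 180
    orientations_deg <- seq(0, span - span / n_orientations,
                            length.out = n_orientations)
  }
  freqs <- exp(seq(log(freq_range_cpd[1]), log(freq_range_cpd[2]),
                   length.out = n_frequencies))
  structure(list(orientations_deg = orientations_deg,
                 frequencies_cpd = freqs, px_per_deg = px_per_deg,
                 bandwidth_octaves = bandwidth_octaves, prf_grid = prf_grid),
            class = "gabor_config")
}

#' Gabor energy activations
#'
#' Applies the quadrature Gabor bank to a grayscale image and returns one
#' pooled energy per (orientation, frequency) channel.  Filters are built in
#' the frequency domain as single-lobe (analytic) Gaussian transfer
#' functions with the DC term forced to zero, so activations are invariant
#' to adding a constant to the image; the complex modulus of the filtered
#' image is the quadrature-pair energy envelope.  Each energy map is
#' averaged under every pRF Gaussian window and the pRF means are averaged,
#' yielding a vector of length `n_orientations * n_frequencies` (96 for the
#' default bank).
#'
#' @param img grayscale matrix (any square or rectangular size whose pixel
#'   scale matches `cfg$px_per_deg`).
#' @param cfg a [gabor_config()].
#' @return Numeric vector ordered orientation-major (all frequencies of
#'   orientation 1, then orientation 2, ...), with names `"oXX_fY"`.
#' @export
gabor_activations <- function(img, cfg = gabor_config()) {
  stopifnot(is.matrix(img))
  f_px <- cfg$frequencies_cpd / cfg$px_per_deg
  if (any(f_px > 0.5))
    stop("configured frequency exceeds the Nyquist limit for px_per_deg = ",
         cfg$px_per_deg)
  h <- nrow(img); w <- ncol(img)
  F <- stats::fft(img)
  # frequency coordinates (cycles/pixel): u along columns (x), v along rows (y)
  u <- outer(rep(1, h), .fft_freq(w))
  v <- outer(.fft_freq(h), rep(1, w))
  prf <- cfg$prf_grid
  weights <- if (is.null(prf)) list(matrix(1 / (h * w), h, w)) else {
    lapply(seq_len(nrow(prf)), function(i) {
      gx <- exp(-((col(img) - 1 - prf$x_px[i])^2 +
                    (row(img) - 1 - prf$y_px[i])^2) / (2 * prf$sigma_px[i]^2))
      gx / sum(gx)
    })
  }
  sig_fac <- (2^cfg$bandwidth_octaves - 1) / (2^cfg$bandwidth_octaves + 1) /
    sqrt(2 * log(2))
  out <- numeric(0)
  for (th in cfg$orientations_deg) {
    a <- th * pi / 180
    for (k in seq_along(f_px)) {
      f0 <- f_px[k]
      u0 <- f0 * cos(a); v0 <- f0 * sin(a)
      sf <- f0 * sig_fac
      G <- exp(-((u - u0)^2 + (v - v0)^2) / (2 * sf^2))
      G[1, 1] <- 0   # zero DC: invariance to constant offsets
      resp <- stats::fft(F * G, inverse = TRUE) / (h * w)
      energy <- Mod(resp)
      pooled <- vapply(weights, function(wm) sum(wm * energy), numeric(1))
      out <- c(out, mean(pooled))
    }
  }
  names(out) <- as.vector(t(outer(cfg$orientations_deg, seq_along(f_px),
                                  function(o, k) sprintf("o%03d_f%d", o, k))))
  out
}

.fft_freq <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k <= n / 2, k, k - n) / n
}

#' Low- and high-spatial-frequency Gabor statistics
#'
#' Averages the activation vector over the four lowest and the four highest
#' frequency bands (across all orientations), the two low-level image
#' statistics entering the regressions.
#'
#' @param activations output of [gabor_activations()] (orientation-major
#'   ordering, `n_frequencies` per orientation).
#' @param n_frequencies frequency bands per orientation.
#' @return Named numeric vector `c(gabor_low_sf, gabor_high_sf)`.
#' @export
gabor_statistics <- function(activations, n_frequencies = 8) {
  if (length(activations) %% n_frequencies != 0)
    stop("activation vector length is not a multiple of n_frequencies")
  m <- matrix(activations, nrow = n_frequencies)   # rows = frequency bands
  half <- n_frequencies / 2
  c(gabor_low_sf = mean(m[seq_len(half), ]),
    gabor_high_sf = mean(m[seq_len(half) + half, ]))
}

#' Gray-level co-occurrence homogeneity
#'
#' Quantizes the image to `levels` gray levels (linear mapping of the image's
#' `[min, max]` range), tabulates co-occurrences of horizontally adjacent
#' pixels (offset distance 1; optionally averaged over the four distance-1
#' directions) and returns `sum P(i,j) / (1 + |i - j|)`.  In `"windowed"`
#' mode (the default) homogeneity is computed inside every sliding
#' `window` x `window` block and averaged over blocks; `"global"` mode uses
#' one whole-image co-occurrence matrix.  Constant images score exactly 1.
#'
#' @param img grayscale matrix.
#' @param levels number of quantization levels.
#' @param window sliding-window side length (windowed mode).
#' @param mode `"windowed"` or `"global"`.
#' @param directions `"single"` for offset (0, 1) only, `"all4"` to average
#'   the four distance-1 offsets.
#' @return Homogeneity in `(0, 1]`.
#' @export
glcm_homogeneity <- function(img, levels = 64, window = 3,
                             mode = c("windowed", "global"),
                             directions = c("single", "all4")) {
  mode <- match.arg(mode); directions <- match.arg(directions)
  stopifnot(is.matrix(img))
  if (nrow(img) < window || ncol(img) < window)
    stop("image smaller than the processing window")
  q <- .quantize(img, levels)
  offs <- if (directions == "single") list(c(0, 1)) else
    list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (mode == "global") {
    mean(vapply(offs, function(o) .glcm_homog_global(q, o), numeric(1)))
  } else {
    mean(vapply(offs, function(o) .glcm_homog_windowed(q, o, window),
                numeric(1)))
  }
}

.quantize <- function(img, levels) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(img), ncol(img)))
  q <- floor((img - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q > levels - 1] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

## pairwise similarity weights 1/(1+|dq|) for one offset; values at pair sites
.pair_weights <- function(q, off) {
  dr <- off[1]; dc <- off[2]
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  1 / (1 + abs(a - b))
}

.glcm_homog_global <- function(q, off) {
  w <- .pair_weights(q, off)
  mean(w)   # each pair has GLCM mass 1/n_pairs, so homogeneity = mean weight
}

## windowed mode: every window's homogeneity is the mean pair weight inside
## it, so the window average is a box filter over the pair-weight map
.glcm_homog_windowed <- function(q, off, window) {
  wmap <- .pair_weights(q, off)
  hh <- nrow(wmap) - window + 1 + abs(off[1])
  ww <- ncol(wmap) - window + 1 + abs(off[2])
  # windows of the *image* are window x window; pair sites inside a window
  # span (window - |dr|) x (window - |dc|)
  kh <- window - abs(off[1]); kw <- window - abs(off[2])
  sums <- .box_sum(wmap, kh, kw)
  mean(sums / (kh * kw))
}

## sums over all kh x kw blocks via cumulative sums
.box_sum <- function(m, kh, kw) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 1, w + 1)
  pad[-1, -1] <- cs
  i <- seq_len(h - kh + 1); j <- seq_len(w - kw + 1)
  pad[i + kh, j + kw, drop = FALSE] - pad[i, j + kw, drop = FALSE] -
    pad[i + kh, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

#' Polygon or rectangle annotation of a critical object
#'
#' @param image_id image identifier.
#' @param vertices_px matrix or list of (x, y) vertices in image
#'   coordinates; a rectangle may be given as its two opposite corners.
#' @param shape `"polygon"` or `"rectangle"`.
#' @return An `annotation` object (rectangles are stored as their 4-vertex
#'   polygon).
#' @export
annotation <- function(image_id, vertices_px, shape = c("polygon", "rectangle")) {
  shape <- match.arg(shape)
  v <- if (is.list(vertices_px)) do.call(rbind, lapply(vertices_px, unlist))
  else as.matrix(vertices_px)
  if (shape == "rectangle") {
    if (nrow(v) == 2)
      v <- rbind(c(v[1, 1], v[1, 2]), c(v[2, 1], v[1, 2]),
                 c(v[2, 1], v[2, 2]), c(v[1, 1], v[2, 2]))
    if (nrow(v) != 4) stop("rectangle needs 2 corners or 4 vertices")
  }
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices")
  structure(list(image_id = image_id, shape = shape, vertices_px = v),
            class = "annotation")
}

#' Read/write LabelMe-style annotation JSON
#'
#' Records have the layout `{image_id, shape, points: [[x, y], ...]}`.
#' @param path JSON file path.
#' @return `read_annotations()`: named list (by image_id) of lists of
#'   [annotation()] objects; `write_annotations()`: `path` invisibly.
#' @export
read_annotations <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  anns <- lapply(recs, function(r) {
    v <- do.call(rbind, lapply(r$points, function(p) as.numeric(unlist(p))))
    annotation(r$image_id, v, r$shape)
  })
  split(anns, vapply(anns, function(a) as.character(a$image_id), character(1)))
}

#' @rdname read_annotations
#' @param annotations flat list or image-keyed list of [annotation()] objects.
#' @export
write_annotations <- function(annotations, path) {
  if (length(annotations) && inherits(annotations[[1]], "annotation"))
    annotations <- list(annotations)
  flat <- unlist(annotations, recursive = FALSE)
  recs <- lapply(flat, function(a)
    list(image_id = a$image_id, shape = a$shape,
         points = lapply(seq_len(nrow(a$vertices_px)),
                         function(i) as.numeric(a$vertices_px[i, ]))))
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Polygon area and centroid (shoelace formula)
#'
#' Continuous vertex geometry, independent of raster resolution.
#' @param v vertex matrix (x, y), any orientation, not self-intersecting.
#' @return List with `area` (positive) and `centroid` (x, y).
#' @export
polygon_geometry <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a2 <- sum(cross)                      # 2 * signed area
  if (abs(a2) < .Machine$double.eps * 100)
    return(list(area = 0, centroid = c(mean(x), mean(y))))
  cx <- sum((x + xn) * cross) / (3 * a2)
  cy <- sum((y + yn) * cross) / (3 * a2)
  list(area = abs(a2) / 2, centroid = c(cx, cy))
}

#' Critical-object saliency of an image
#'
#' Sums, over annotated critical objects, the product of a compressed size
#' term and a centrality term: `Size = (area / image_area)^0.7` (Stevens'
#' power law for apparent size) and `Location = 1 - d(centroid, center) /
#' d(center, corner)`.  The center is the continuous image center
#' `(W/2, H/2)`; an object covering the whole image scores exactly 1, an
#' image without annotations scores 0.  Degenerate (zero-area) polygons
#' contribute 0 with a warning.
#'
#' @param annotations list of [annotation()] objects for one image (possibly
#'   empty).
#' @param image_size_px image extent (square).
#' @param stevens_exponent exponent of the size compression.
#' @return COS value (>= 0).
#' @export
critical_object_saliency <- function(annotations, image_size_px = 600,
                                     stevens_exponent = 0.7) {
  if (!length(annotations)) return(0)
  h <- image_size_px / 2
  corner_d <- sqrt(h^2 + h^2)
  total <- 0
  for (a in annotations) {
    # shoelace in center-origin coordinates: a quarter-turn rotation then
    # permutes/negates the accumulated terms without re-rounding, so COS is
    # bit-identical across the four orientations (vertices on a dyadic grid)
    vc <- cbind(a$vertices_px[, 1] - h, a$vertices_px[, 2] - h)
    g <- polygon_geometry(vc)
    if (g$area == 0) {
      warning("degenerate zero-area annotation contributes 0")
      next
    }
    size_c <- (g$area / image_size_px^2)^stevens_exponent
    loc_c <- 1 - sqrt(g$centroid[1]^2 + g$centroid[2]^2) / corner_d
    total <- total + size_c * loc_c
  }
  total
}

#' All image statistics for one image at one orientation
#'
#' Computes the luminance covariate and the nine image statistics used as
#' regression predictors: Gabor low/high spatial-frequency energies, GLCM
#' homogeneity, within- and across-category embedding similarity, critical-
#' object saliency, and the PCA-space L2 norms of up to three embedding
#' layers.  Embedding-based statistics are `NA` when the corresponding
#' inputs are not supplied.
#'
#' @param img H x W x 3 sRGB array in `[0, 1]` (grayscale statistics use the
#'   channel mean).
#' @param image_id image identifier.
#' @param annotations list of [annotation()] objects for this image (may be
#'   empty or `NULL`).
#' @param embedding_stats optional named numeric vector with entries among
#'   `within_sim`, `across_sim`, `blk1_l2`, `blk5_l2`, `fc2_l2` (see
#'   [embedding_statistics()]).
#' @param gabor_cfg a [gabor_config()] matched to the image's pixel scale.
#' @param glcm_levels,glcm_window,glcm_mode GLCM parameters.
#' @param orientation_deg orientation label stored in the record.
#' @return One-row data.frame (an `ImageStatsRecord`).
#' @export
compute_image_stats <- function(img, image_id, annotations = NULL,
                                embedding_stats = NULL,
                                gabor_cfg = gabor_config(),
                                glcm_levels = 64, glcm_window = 3,
                                glcm_mode = "windowed",
                                orientation_deg = 0) {
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  act <- gabor_activations(gray, gabor_cfg)
  gs <- gabor_statistics(act, length(gabor_cfg$frequencies_cpd))
  emb <- function(nm) {
    if (!is.null(embedding_stats) && nm %in% names(embedding_stats))
      unname(embedding_stats[[nm]]) else NA_real_
  }
  data.frame(
    image_id = image_id, orientation_deg = orientation_deg,
    gabor_low_sf = unname(gs["gabor_low_sf"]),
    gabor_high_sf = unname(gs["gabor_high_sf"]),
    homogeneity = glcm_homogeneity(gray, glcm_levels, glcm_window, glcm_mode),
    within_sim = emb("within_sim"), across_sim = emb("across_sim"),
    cos = critical_object_saliency(if (is.null(annotations)) list() else
      annotations, nrow(gray)),
    blk1_l2 = emb("blk1_l2"), blk5_l2 = emb("blk5_l2"),
    fc2_l2 = emb("fc2_l2"),
    luminance = luminance_L(img),
    stringsAsFactors = FALSE)
}
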