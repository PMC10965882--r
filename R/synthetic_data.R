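## Seeded synthetic-data generator.  Emulates the experimental design the
## analysis assumes -- 12 scene categories x 20 images x 20 observers, 3-s
## trials, lognormal fixation durations, central fixation bias, attraction
## to annotated critical objects -- and plants, with ground-truth flags,
## violations of every screening rule and linear image-statistic effects,
## so every pipeline stage can be checked exactly.

#' Synthetic experiment configuration
#'
#' Defaults reproduce the study design: 12 categories x 20 images x 20
#' observers, 3000 ms free viewing of 600 x 600 px images at 40 px/dva,
#' lognormal fixation durations with mean 296 ms and SD 139 ms.  The
#' incorrect-trial (2.12%) and too-few-fixations (2.71%) rates equal the
#' protocol's reported exclusion percentages; the remaining invalid-event
#' rates are small laboratory-realistic values.
#'
#' @param n_categories,images_per_category,observers design size.
#' @param viewing_ms stimulus duration.
#' @param px_per_deg,image_size_px display geometry.
#' @param duration_mean_ms,duration_sd_ms target mean/SD of the lognormal
#'   fixation-duration distribution (millisecond scale).
#' @param duration_band optional `c(lo, hi)` ms: truncate valid fixation
#'   durations to this band and force the first fixation to at least 200 ms.
#'   Used for screening-exactness fixtures, where no *unflagged* event may
#'   trip a data-dependent filter; `NULL` (default) leaves the distribution
#'   untruncated.
#' @param center_bias_strength mixture weight of the central Gaussian
#'   fixation component (0-1).
#' @param object_attraction_weight mixture weight of the critical-object
#'   components (used only for images with annotations).
#' @param center_sigma_px spread of the central component.
#' @param base_n_fixations mean fixations per 3-s trial before planted
#'   effects.
#' @param nfix_cos_slope planted log-linear effect of COS on the number of
#'   fixations (negative: salient critical objects need fewer fixations).
#' @param entropy_homog_slope planted effect of texture homogeneity on
#'   fixation spread (positive value shrinks the spread of homogeneous
#'   images, lowering FDM entropy).
#' @param rate_incorrect,rate_fewfix,rate_trackloss trial-level violation
#'   rates (mutually exclusive per trial).
#' @param rate_short_fix,rate_oob_fix,rate_early_saccade per-trial rates of
#'   planted event-level violations.
#' @param rate_blink rate of benign (blink) tracking gaps, which screening
#'   must retain.
#' @param n_objects_by_category integer vector (recycled over categories) of
#'   planted critical objects per image; 0 gives a COS of exactly 0.
#' @param embedding_dim,embedding_within_sd,embedding_between_sd embedding
#'   cluster geometry; smaller within-spread gives a larger WS - AS margin.
#' @param classifier_accuracy probability that the synthetic classifier
#'   labels an image correctly.
#' @param seed integer; fully determines every generated artifact.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_categories = 12, images_per_category = 20,
                         observers = 20, viewing_ms = 3000, px_per_deg = 40,
                         image_size_px = 600, duration_mean_ms = 296,
                         duration_sd_ms = 139, duration_band = NULL,
                         center_bias_strength = 0.5,
                         object_attraction_weight = 0.25,
                         center_sigma_px = image_size_px / 6,
                         base_n_fixations = 8, nfix_cos_slope = -0.6,
                         entropy_homog_slope = 0.8,
                         rate_incorrect = 0.0212, rate_fewfix = 0.0271,
                         rate_trackloss = 0.005, rate_short_fix = 0.02,
                         rate_oob_fix = 0.01, rate_early_saccade = 0.01,
                         rate_blink = 0.02,
                         n_objects_by_category = c(0L, 1L, 2L, 3L),
                         embedding_dim = 32, embedding_within_sd = 0.4,
                         embedding_between_sd = 1,
                         classifier_accuracy = 0.9375, seed = 1L) {
  rates <- c(rate_incorrect, rate_fewfix, rate_trackloss, rate_short_fix,
             rate_oob_fix, rate_early_saccade, rate_blink,
             center_bias_strength, object_attraction_weight)
  stopifnot(all(rates >= 0), all(rates <= 1),
            center_bias_strength + object_attraction_weight <= 1,
            viewing_ms >= 1000, duration_mean_ms > 0, duration_sd_ms > 0)
  cfg <- as.list(environment())
  cfg$rates <- NULL
  # lognormal location/scale from the target moment parameters
  s2 <- log(1 + (duration_sd_ms / duration_mean_ms)^2)
  cfg$dur_sdlog <- sqrt(s2)
  cfg$dur_meanlog <- log(duration_mean_ms) - s2 / 2
  structure(cfg, class = "synth_config")
}

#' Sample fixation durations from the configured lognormal
#'
#' The raw duration sampler of the generator (no truncation, no planted
#' per-image scaling), suitable for distributional checks.
#' @param n samples.
#' @param cfg a [synth_config()].
#' @param seed optional seed (defaults to the config's).
#' @return Durations in ms.
#' @export
gen_fixation_durations <- function(n, cfg = synth_config(), seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  withr::with_seed(seed, rlnorm(n, cfg$dur_meanlog, cfg$dur_sdlog))
}

## truncated lognormal by rejection (band is always well inside the support)
.rlnorm_band <- function(n, meanlog, sdlog, band) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rlnorm(2 * n + 20, meanlog, sdlog)
    out <- c(out, d[d >= band[1] & d <= band[2]])
  }
  out[seq_len(n)]
}

#' Generate synthetic aerial-like images
#'
#' Each category gets a textured background (Gaussian-smoothed noise; the
#' smoothing scale increases over categories, so measured GLCM homogeneity
#' rank-matches the planted ordering) plus 0 or more planted rectangular
#' "critical objects" of controlled area and centroid.  Images are sRGB
#' arrays with a category tint and per-image brightness jitter, so mean
#' luminance varies as in real photographs.
#'
#' @param cfg a [synth_config()].
#' @return List with `images` (named list of H x W x 3 arrays) and `meta`
#'   (data.frame: `image_id`, `category`, `smooth_sigma`, `homog_rank` in
#'   `[0, 1]`, `n_objects`, `cos_true`).
#' @export
gen_images <- function(cfg = synth_config()) {
  withr::with_seed(cfg$seed + 101L, {
    size <- cfg$image_size_px
    cats <- sprintf("cat%02d", seq_len(cfg$n_categories))
    sigmas <- seq(1, max(2, size / 50), length.out = cfg$n_categories)
    n_obj <- rep_len(cfg$n_objects_by_category, cfg$n_categories)
    images <- list(); meta <- list(); objects <- list()
    for (ci in seq_along(cats)) {
      for (ii in seq_len(cfg$images_per_category)) {
        id <- sprintf("%s_img%02d", cats[ci], ii)
        base <- .gauss_smooth(matrix(runif(size^2), size, size), sigmas[ci])
        base <- (base - min(base)) / (max(base) - min(base) + 1e-12)
        obj_list <- list()
        if (n_obj[ci] > 0) {
          for (k in seq_len(n_obj[ci])) {
            # quarter-pixel vertex grid: dyadic coordinates stay exact under
            # the right-angle rotation transform
            side <- round(runif(1, 0.06, 0.22) * size * 4) / 4
            cx <- round(runif(1, side / 2 + 1, size - side / 2 - 1) * 4) / 4
            cy <- round(runif(1, side / 2 + 1, size - side / 2 - 1) * 4) / 4
            v <- rbind(c(cx - side / 2, cy - side / 2),
                       c(cx + side / 2, cy - side / 2),
                       c(cx + side / 2, cy + side / 2),
                       c(cx - side / 2, cy + side / 2))
            obj_list[[k]] <- annotation(id, v, "polygon")
            rows <- pmax(1, floor(cy - side / 2)):pmin(size, ceiling(cy + side / 2))
            cols <- pmax(1, floor(cx - side / 2)):pmin(size, ceiling(cx + side / 2))
            base[rows, cols] <- 0.85 + 0.1 * runif(1)
          }
        }
        tint <- 0.7 + 0.3 * c(ci %% 3, (ci + 1) %% 3, (ci + 2) %% 3) / 2
        bright <- runif(1, 0.75, 1)
        img <- array(0, c(size, size, 3))
        for (ch in 1:3) img[, , ch] <- pmin(1, base * tint[ch] * bright)
        images[[id]] <- img
        objects[[id]] <- obj_list
        meta[[id]] <- data.frame(
          image_id = id, category = cats[ci], smooth_sigma = sigmas[ci],
          homog_rank = (ci - 1) / max(1, cfg$n_categories - 1),
          n_objects = n_obj[ci],
          cos_true = critical_object_saliency(obj_list, size),
          stringsAsFactors = FALSE)
      }
    }
    list(images = images, meta = do.call(rbind, c(meta, make.row.names = FALSE)),
         objects = objects)
  })
}

#' Annotations for the planted critical objects
#'
#' Returns the exact polygons planted by [gen_images()], so the planted COS
#' is computable in closed form from the annotation geometry alone.
#' @param gen output of [gen_images()].
#' @return Named list (by image id) of lists of [annotation()] objects;
#'   images without objects map to empty lists.
#' @export
gen_annotations <- function(gen) gen$objects

#' Generate synthetic scanpaths for every observer x image trial
#'
#' Fixation locations are drawn i.i.d. from a mixture of a central Gaussian
#' (weight `center_bias_strength`), Gaussian kernels over the planted
#' critical objects (weight `object_attraction_weight`), and a uniform
#' exploration component.  Durations are lognormal; the expected number of
#' fixations decreases log-linearly with the image's planted COS, and the
#' spread of the central component shrinks with the planted homogeneity
#' rank, producing the planted negative COS -> n-fixations and homogeneity
#' -> FDM-entropy effects.  Trial- and event-level screening violations are
#' injected at the configured rates, each carrying a ground-truth flag
#' column (`flag_*`), so screening precision and recall are exactly
#' checkable.
#'
#' @param cfg a [synth_config()].
#' @param meta image metadata from [gen_images()] (`$meta`); any data.frame
#'   with `image_id`, `category`, `homog_rank`, `cos_true` works.
#' @param annotations named list of annotation lists ([gen_annotations()]).
#' @return A [gaze_data()] object whose event tables carry the flag columns
#'   `flag_incorrect`, `flag_fewfix`, `flag_trackloss` (trials),
#'   `flag_short`, `flag_oob` (fixations), `flag_early`, `flag_oob_endpoint`
#'   (saccades).
#' @export
gen_scanpaths <- function(cfg = synth_config(), meta, annotations = NULL) {
  min_fix_possible <- floor(cfg$viewing_ms / 150)
  if (min_fix_possible < 3)
    stop("viewing window too short to hold 3 fixations")
  withr::with_seed(cfg$seed + 202L, {
    size <- cfg$image_size_px
    obs <- sprintf("p%02d", seq_len(cfg$observers))
    fix_rows <- list(); sac_rows <- list(); tri_rows <- list(); tl_rows <- list()
    sac_ms <- 30
    for (p in obs) {
      for (r in seq_len(nrow(meta))) {
        img <- meta$image_id[r]
        anns <- annotations[[img]]
        # --- trial-level violation (mutually exclusive) ---
        u <- runif(1)
        viol <- if (u < cfg$rate_incorrect) "incorrect"
        else if (u < cfg$rate_incorrect + cfg$rate_fewfix) "fewfix"
        else if (u < cfg$rate_incorrect + cfg$rate_fewfix + cfg$rate_trackloss)
          "trackloss" else "none"
        # --- planned fixation count (planted COS effect) ---
        lam <- cfg$base_n_fixations * exp(cfg$nfix_cos_slope * meta$cos_true[r])
        n_fix <- max(4, rpois(1, lam))
        if (viol == "fewfix") n_fix <- 3  # first + 2 valid
        # --- durations ---
        band <- cfg$duration_band
        durs <- if (is.null(band))
          rlnorm(n_fix, cfg$dur_meanlog, cfg$dur_sdlog)
        else .rlnorm_band(n_fix, cfg$dur_meanlog, cfg$dur_sdlog, band)
        if (!is.null(band)) durs[1] <- max(durs[1], 200)
        # --- positions (planted homogeneity -> spread effect) ---
        spread <- cfg$center_sigma_px *
          exp(-cfg$entropy_homog_slope * (meta$homog_rank[r] - 0.5))
        w_obj <- if (length(anns)) cfg$object_attraction_weight else 0
        w_ctr <- cfg$center_bias_strength
        comp <- sample(c("c", "o", "u"), n_fix, replace = TRUE,
                       prob = c(w_ctr, w_obj, 1 - w_ctr - w_obj))
        xs <- numeric(n_fix); ys <- numeric(n_fix)
        for (k in seq_len(n_fix)) {
          if (comp[k] == "c") {
            xs[k] <- rnorm(1, size / 2, spread); ys[k] <- rnorm(1, size / 2, spread)
          } else if (comp[k] == "o") {
            a <- anns[[sample.int(length(anns), 1)]]
            g <- polygon_geometry(a$vertices_px)
            s_obj <- max(3, sqrt(g$area) / 2)
            xs[k] <- rnorm(1, g$centroid[1], s_obj)
            ys[k] <- rnorm(1, g$centroid[2], s_obj)
          } else {
            xs[k] <- runif(1, 0, size); ys[k] <- runif(1, 0, size)
          }
        }
        xs <- pmin(pmax(xs, 0.5), size - 0.5)
        ys <- pmin(pmax(ys, 0.5), size - 0.5)
        # --- event-level injections (valid trials only) ---
        f_short <- f_oob <- rep(FALSE, n_fix)
        if (viol == "none" && n_fix >= 6) {
          pool <- 2:n_fix
          if (runif(1) < cfg$rate_short_fix) {
            k <- sample(pool, 1)
            durs[k] <- runif(1, 50, 90); f_short[k] <- TRUE
            pool <- setdiff(pool, k)
          }
          if (length(pool) && runif(1) < cfg$rate_oob_fix) {
            k <- sample(pool, 1)
            if (runif(1) < 0.5) xs[k] <- size + runif(1, 5, 40)
            else ys[k] <- -runif(1, 5, 40)
            f_oob[k] <- TRUE
          }
        }
        # --- timeline ---
        onset <- numeric(n_fix); offset <- numeric(n_fix)
        t0 <- -100 + runif(1, 0, 40)
        keep <- rep(TRUE, n_fix)
        for (k in seq_len(n_fix)) {
          onset[k] <- t0
          offset[k] <- t0 + durs[k]
          if (onset[k] >= cfg$viewing_ms) { keep[k:n_fix] <- FALSE; break }
          if (offset[k] > cfg$viewing_ms) {
            offset[k] <- cfg$viewing_ms
            trunc_dur <- offset[k] - onset[k]
            min_ok <- if (is.null(band)) 1 else band[1]
            if (trunc_dur < min_ok) keep[k] <- FALSE
            keep[seq_len(n_fix) > k] <- FALSE
            break
          }
          t0 <- offset[k] + sac_ms
        }
        idx <- which(keep)
        fix_rows[[length(fix_rows) + 1]] <- data.frame(
          participant_id = p, image_id = img, onset_ms = onset[idx],
          offset_ms = offset[idx], x_px = xs[idx], y_px = ys[idx],
          flag_short = f_short[idx], flag_oob = f_oob[idx],
          stringsAsFactors = FALSE)
        if (length(idx) >= 2) {
          a_i <- idx[-length(idx)]; b_i <- idx[-1]
          amp <- sqrt((xs[b_i] - xs[a_i])^2 + (ys[b_i] - ys[a_i])^2) /
            cfg$px_per_deg
          sac <- data.frame(
            participant_id = p, image_id = img, onset_ms = offset[a_i],
            start_x_px = xs[a_i], start_y_px = ys[a_i],
            end_x_px = xs[b_i], end_y_px = ys[b_i], amplitude_dva = amp,
            flag_early = FALSE,
            flag_oob_endpoint = f_oob[a_i] | f_oob[b_i],
            stringsAsFactors = FALSE)
          if (viol == "none" && runif(1) < cfg$rate_early_saccade) {
            k <- length(idx) %/% 2
            sac <- rbind(sac, data.frame(
              participant_id = p, image_id = img, onset_ms = runif(1, 10, 70),
              start_x_px = xs[idx[k]], start_y_px = ys[idx[k]],
              end_x_px = xs[idx[k + 1]], end_y_px = ys[idx[k + 1]],
              amplitude_dva = amp[1], flag_early = TRUE,
              flag_oob_endpoint = FALSE, stringsAsFactors = FALSE))
          }
          sac_rows[[length(sac_rows) + 1]] <- sac
        }
        if (viol == "trackloss") {
          t_s <- runif(1, 200, cfg$viewing_ms - 400)
          tl_rows[[length(tl_rows) + 1]] <- data.frame(
            participant_id = p, image_id = img, start_ms = t_s,
            end_ms = t_s + runif(1, 120, 300), is_blink = FALSE,
            stringsAsFactors = FALSE)
        } else if (runif(1) < cfg$rate_blink) {
          t_s <- runif(1, 200, cfg$viewing_ms - 400)
          tl_rows[[length(tl_rows) + 1]] <- data.frame(
            participant_id = p, image_id = img, start_ms = t_s,
            end_ms = t_s + runif(1, 110, 200), is_blink = TRUE,
            stringsAsFactors = FALSE)
        }
        tri_rows[[length(tri_rows) + 1]] <- data.frame(
          participant_id = p, image_id = img, category = meta$category[r],
          correct = viol != "incorrect",
          flag_incorrect = viol == "incorrect",
          flag_fewfix = viol == "fewfix",
          flag_trackloss = viol == "trackloss", stringsAsFactors = FALSE)
      }
    }
    gaze_data(do.call(rbind, fix_rows), do.call(rbind, sac_rows),
              do.call(rbind, tri_rows), do.call(rbind, tl_rows))
  })
}

#' Generate synthetic per-image embeddings
#'
#' Per-category Gaussian clusters: category means drawn with spread
#' `embedding_between_sd`, image vectors around their category mean with
#' spread `within_sd`.  Tight clusters with separated means guarantee a
#' positive within-minus-across similarity margin.  A synthetic classifier
#' label (`predicted_category`) is correct with probability
#' `classifier_accuracy`.
#'
#' @param cfg a [synth_config()].
#' @param meta image metadata (`image_id`, `category`).
#' @param layer_tag stored layer label.
#' @param within_sd override of `cfg$embedding_within_sd`.
#' @param seed_offset layers generated with different offsets are
#'   independent.
#' @return An [embedding_set()].
#' @export
gen_embeddings <- function(cfg = synth_config(), meta, layer_tag = "blk5",
                           within_sd = NULL, seed_offset = 303L) {
  if (is.null(within_sd)) within_sd <- cfg$embedding_within_sd
  withr::with_seed(cfg$seed + seed_offset, {
    cats <- unique(meta$category)
    d <- cfg$embedding_dim
    mu <- matrix(rnorm(length(cats) * d, sd = cfg$embedding_between_sd),
                 length(cats), d, dimnames = list(cats, NULL))
    vecs <- t(vapply(seq_len(nrow(meta)), function(i)
      mu[meta$category[i], ] + rnorm(d, sd = within_sd), numeric(d)))
    correct <- runif(nrow(meta)) < cfg$classifier_accuracy
    pred <- meta$category
    wrong <- which(!correct)
    for (i in wrong)
      pred[i] <- sample(setdiff(cats, meta$category[i]), 1)
    embedding_set(vecs, meta$image_id, meta$category, pred, layer_tag)
  })
}

#' Planted-effect image-level regression table
#'
#' Draws the image-level analysis table directly: nine mildly correlated
#' image-statistic columns plus luminance, and responses with planted
#' linear effects (negative COS on the number of fixations, negative
#' homogeneity on FDM entropy) at a signal-to-noise ratio giving a model
#' R-squared near the image-level benchmark (~0.4).  Used for stepwise
#' selection recovery checks at full problem size without rendering images.
#'
#' @param n_images rows.
#' @param b_cos,b_homog planted standardized slopes (negative).
#' @param b_lum luminance nuisance slope (removed by residualization).
#' @param sigma residual noise SD.
#' @param seed RNG seed.
#' @return data.frame with the nine predictor columns, `luminance`,
#'   `n_fixations` and `fdm_entropy_bits`.
#' @export
gen_regression_table <- function(n_images = 240, b_cos = -0.55,
                                 b_homog = -0.5, b_lum = 0.3, sigma = 1,
                                 seed = 1L) {
  withr::with_seed(seed, {
    p <- 9
    nms <- c("gabor_low_sf", "gabor_high_sf", "homogeneity", "within_sim",
             "across_sim", "cos", "blk1_l2", "blk5_l2", "fc2_l2")
    # mild common factor induces realistic inter-statistic correlation (~0.3)
    z <- rnorm(n_images)
    X <- sapply(seq_len(p), function(j) sqrt(0.7) * rnorm(n_images) +
                  sqrt(0.3) * z)
    colnames(X) <- nms
    lum <- rnorm(n_images)
    eps <- rnorm(n_images, sd = sigma)
    nfix <- b_cos * X[, "cos"] + b_homog * X[, "homogeneity"] +
      b_lum * lum + eps
    ent <- b_homog * X[, "homogeneity"] + b_cos * X[, "cos"] / 2 +
      b_lum * lum + rnorm(n_images, sd = sigma)
    cbind(as.data.frame(X), luminance = lum, n_fixations = nfix,
          fdm_entropy_bits = ent)
  })
}

#' Generate the complete synthetic dataset bundle
#'
#' Images, annotations, embeddings for the three layer tags, and scanpaths,
#' all determined by `cfg$seed`.
#' @param cfg a [synth_config()].
#' @return List with `images`, `meta`, `annotations`, `embeddings` (named
#'   list of three [embedding_set()]s), `gaze` (a [gaze_data()]).
#' @export
gen_dataset <- function(cfg = synth_config()) {
  gi <- gen_images(cfg)
  anns <- gen_annotations(gi)
  emb <- list(
    blk1 = gen_embeddings(cfg, gi$meta, "blk1",
                          within_sd = cfg$embedding_within_sd * 2.5,
                          seed_offset = 301L),
    blk5 = gen_embeddings(cfg, gi$meta, "blk5", seed_offset = 303L),
    fc2 = gen_embeddings(cfg, gi$meta, "fc2",
                         within_sd = cfg$embedding_within_sd * 0.6,
                         seed_offset = 305L))
  gaze <- gen_scanpaths(cfg, gi$meta, anns)
  list(images = gi$images, meta = gi$meta, annotations = anns,
       embeddings = emb, gaze = gaze)
}
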