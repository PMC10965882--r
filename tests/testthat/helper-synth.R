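# Shared fixtures: small study configurations and screening ground-truth
# comparison utilities.

# reduced design for fast unit runs
small_cfg <- function(seed = 11, ...) {
  synth_config(n_categories = 4, images_per_category = 3, observers = 5,
               image_size_px = 120, seed = seed, ...)
}

# screening-exactness fixture: valid events cannot trip any filter, every
# violation is planted and flagged
exact_cfg <- function(seed = 11, ...) {
  small_cfg(seed = seed, duration_band = c(110, 300), ...)
}

trial_key <- function(df) paste(df$participant_id, df$image_id, sep = "|")
fix_key <- function(df) paste(trial_key(df), df$onset_ms, sep = "|")
sacc_key <- function(df) paste(trial_key(df), df$onset_ms, df$end_x_px,
                               sep = "|")

# per-rule screening precision/recall against generator flags
screening_confusion <- function(gd, scr) {
  valid_tri <- trial_key(scr$data$trials)
  tri <- gd$trials
  tri_removed <- !(trial_key(tri) %in% valid_tri)
  tri_flagged <- tri$flag_incorrect | tri$flag_fewfix | tri$flag_trackloss

  f <- gd$fixations
  pool <- f[trial_key(f) %in% valid_tri & !f$is_first, , drop = FALSE]
  fix_removed <- !(fix_key(pool) %in% fix_key(scr$data$fixations))
  fix_flagged <- pool$flag_short | pool$flag_oob

  s <- gd$saccades
  spool <- s[trial_key(s) %in% valid_tri, , drop = FALSE]
  sac_removed <- !(sacc_key(spool) %in% sacc_key(scr$data$saccades))
  sac_flagged <- spool$flag_early | spool$flag_oob_endpoint

  list(trials = list(removed = tri_removed, flagged = tri_flagged),
       fixations = list(removed = fix_removed, flagged = fix_flagged),
       saccades = list(removed = sac_removed, flagged = sac_flagged))
}

# tiny hand-built gaze_data: one participant, one image, explicit events
manual_gaze <- function(fix, sac = NULL, correct = TRUE, trackloss = NULL,
                        participant = "p1", image = "i1", category = "c1") {
  fix$participant_id <- participant; fix$image_id <- image
  if (is.null(sac))
    sac <- data.frame(participant_id = character(), image_id = character(),
                      onset_ms = numeric(), start_x_px = numeric(),
                      start_y_px = numeric(), end_x_px = numeric(),
                      end_y_px = numeric(), amplitude_dva = numeric())
  else { sac$participant_id <- participant; sac$image_id <- image }
  if (!is.null(trackloss)) {
    trackloss$participant_id <- participant; trackloss$image_id <- image
  }
  trials <- data.frame(participant_id = participant, image_id = image,
                       category = category, correct = correct,
                       stringsAsFactors = FALSE)
  gaze_data(fix, sac, trials, trackloss)
}

fix_df <- function(onset, dur, x, y) {
  data.frame(onset_ms = onset, offset_ms = onset + dur, x_px = x, y_px = y)
}
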