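## Event containers and the complete screening procedure.

#' Assemble a gaze dataset from event tables
#'
#' Bundles per-trial oculomotor events into a `gaze_data` object, the input
#' container for screening and metric computation.  Events within a trial
#' must be ordered by onset; the first recorded fixation of every trial is
#' flagged (it starts before stimulus onset and is discarded downstream).
#'
#' @param fixations data.frame with columns `participant_id`, `image_id`,
#'   `onset_ms`, `offset_ms`, `x_px`, `y_px`.  `duration_ms` is derived if
#'   absent.  Onsets are relative to stimulus onset; recording starts 100 ms
#'   earlier, so the first fixation typically has a negative onset.
#' @param saccades data.frame with columns `participant_id`, `image_id`,
#'   `onset_ms`, `start_x_px`, `start_y_px`, `end_x_px`, `end_y_px`,
#'   `amplitude_dva`.
#' @param trials data.frame with one row per participant x image:
#'   `participant_id`, `image_id`, `category`, `correct` (logical).
#' @param trackloss optional data.frame of recording gaps: `participant_id`,
#'   `image_id`, `start_ms`, `end_ms`, `is_blink`.
#' @return An object of class `gaze_data`: a list of the four validated
#'   data.frames, with `is_first` set on fixations.
#' @export
gaze_data <- function(fixations, saccades, trials, trackloss = NULL) {
  fix_cols <- c("participant_id", "image_id", "onset_ms", "offset_ms",
                "x_px", "y_px")
  sac_cols <- c("participant_id", "image_id", "onset_ms", "start_x_px",
                "start_y_px", "end_x_px", "end_y_px", "amplitude_dva")
  tri_cols <- c("participant_id", "image_id", "category", "correct")
  .need_cols(fixations, fix_cols, "fixations")
  .need_cols(saccades, sac_cols, "saccades")
  .need_cols(trials, tri_cols, "trials")
  if (is.null(trackloss)) {
    trackloss <- data.frame(participant_id = character(), image_id = character(),
                            start_ms = numeric(), end_ms = numeric(),
                            is_blink = logical())
  }
  .need_cols(trackloss, c("participant_id", "image_id", "start_ms", "end_ms",
                          "is_blink"), "trackloss")

  if (nrow(fixations)) {
    if (is.null(fixations$duration_ms))
      fixations$duration_ms <- fixations$offset_ms - fixations$onset_ms
    if (any(fixations$offset_ms <= fixations$onset_ms))
      stop("fixation offset_ms must exceed onset_ms")
    key <- .trial_key(fixations)
    ord <- order(key, fixations$onset_ms)
    fixations <- fixations[ord, , drop = FALSE]
    fixations$is_first <- !duplicated(.trial_key(fixations))
  } else {
    fixations$duration_ms <- numeric(0)
    fixations$is_first <- logical(0)
  }
  if (nrow(saccades)) {
    if (any(saccades$amplitude_dva < 0)) stop("saccade amplitude_dva must be >= 0")
    saccades <- saccades[order(.trial_key(saccades), saccades$onset_ms), ,
                         drop = FALSE]
  }
  if (anyNA(trials$correct)) stop("every trial needs a correctness flag")
  rownames(fixations) <- rownames(saccades) <- rownames(trials) <- NULL
  structure(list(fixations = fixations, saccades = saccades,
                 trials = trials, trackloss = trackloss),
            class = "gaze_data")
}

#' @export
print.gaze_data <- function(x, ...) {
  cat("<gaze_data> ", nrow(x$trials), " trials, ",
      nrow(x$fixations), " fixations, ", nrow(x$saccades), " saccades, ",
      nrow(x$trackloss), " trackloss segments\n", sep = "")
  invisible(x)
}

.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.trial_key <- function(df) paste(df$participant_id, df$image_id, sep = "\r")

#' Default column mapping for delimited event tables
#'
#' Maps the canonical column names used by [load_events()] to the names in a
#' file.  Override entries to adapt to a vendor export.
#' @return Named character vector `canonical = file_column`.
#' @export
event_dialect <- function() {
  c(participant = "participant", image = "image", category = "category",
    event_type = "event_type", onset_ms = "onset_ms", offset_ms = "offset_ms",
    x_px = "x_px", y_px = "y_px", end_x_px = "end_x_px", end_y_px = "end_y_px",
    amplitude_dva = "amplitude_dva", correct = "correct", blink = "blink")
}

#' Read trials and events from a delimited text file
#'
#' Reads a long-format event table (one row per event; `event_type` is
#' `"fixation"`, `"saccade"` or `"trackloss"`) and assembles a [gaze_data()]
#' object.  Saccade rows use `x_px`/`y_px` as the start position and
#' `end_x_px`/`end_y_px` as the landing position.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect column mapping as produced by [event_dialect()].
#' @param sep field separator (`","` default).
#' @return A `gaze_data` object; an empty file yields empty tables with a
#'   warning.
#' @export
load_events <- function(path, dialect = event_dialect(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    warning("no events in ", path)
    empty <- data.frame()
    return(gaze_data(
      fixations = data.frame(participant_id = character(), image_id = character(),
                             onset_ms = numeric(), offset_ms = numeric(),
                             x_px = numeric(), y_px = numeric()),
      saccades = data.frame(participant_id = character(), image_id = character(),
                            onset_ms = numeric(), start_x_px = numeric(),
                            start_y_px = numeric(), end_x_px = numeric(),
                            end_y_px = numeric(), amplitude_dva = numeric()),
      trials = data.frame(participant_id = character(), image_id = character(),
                          category = character(), correct = logical())))
  }
  need <- c("participant", "image", "category", "event_type", "onset_ms",
            "correct")
  file_cols <- dialect[need]
  miss <- setdiff(unname(file_cols), names(raw))
  if (length(miss))
    stop("event file is missing column(s): ", paste(miss, collapse = ", "))
  col <- function(nm) raw[[dialect[[nm]]]]
  num_col <- function(nm) {
    v <- col(nm)
    if (is.null(v)) return(NULL)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d",
                   dialect[[nm]], bad[1]))
    out
  }
  type <- col("event_type")
  is_fix <- type == "fixation"; is_sac <- type == "saccade"
  is_tl <- type == "trackloss"
  onset <- num_col("onset_ms"); offset <- num_col("offset_ms")
  x <- num_col("x_px"); y <- num_col("y_px")
  fixations <- data.frame(
    participant_id = col("participant")[is_fix], image_id = col("image")[is_fix],
    onset_ms = onset[is_fix], offset_ms = offset[is_fix],
    x_px = x[is_fix], y_px = y[is_fix], stringsAsFactors = FALSE)
  saccades <- data.frame(
    participant_id = col("participant")[is_sac], image_id = col("image")[is_sac],
    onset_ms = onset[is_sac],
    start_x_px = x[is_sac], start_y_px = y[is_sac],
    end_x_px = num_col("end_x_px")[is_sac], end_y_px = num_col("end_y_px")[is_sac],
    amplitude_dva = num_col("amplitude_dva")[is_sac], stringsAsFactors = FALSE)
  blink <- col("blink")
  trackloss <- data.frame(
    participant_id = col("participant")[is_tl], image_id = col("image")[is_tl],
    start_ms = onset[is_tl], end_ms = offset[is_tl],
    is_blink = as.logical(blink[is_tl]), stringsAsFactors = FALSE)
  tri <- !duplicated(paste(col("participant"), col("image"), sep = "\r"))
  trials <- data.frame(
    participant_id = col("participant")[tri], image_id = col("image")[tri],
    category = col("category")[tri], correct = as.logical(col("correct")[tri]),
    stringsAsFactors = FALSE)
  gaze_data(fixations, saccades, trials, trackloss)
}

#' Write a gaze dataset to a delimited text file
#'
#' Inverse of [load_events()]: serializes all events in long format.
#' @param gd a `gaze_data` object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_events <- function(gd, path, sep = ",") {
  stopifnot(inherits(gd, "gaze_data"))
  tri <- gd$trials
  tkey <- .trial_key(tri)
  cat_of <- setNames(as.character(tri$category), tkey)
  cor_of <- setNames(tri$correct, tkey)
  row_block <- function(df, type, onset, offset, x, y, ex, ey, amp, blink) {
    if (!nrow(df)) return(NULL)
    k <- .trial_key(df)
    data.frame(participant = df$participant_id, image = df$image_id,
               category = unname(cat_of[k]), event_type = type,
               onset_ms = onset, offset_ms = offset, x_px = x, y_px = y,
               end_x_px = ex, end_y_px = ey, amplitude_dva = amp,
               correct = unname(cor_of[k]), blink = blink,
               stringsAsFactors = FALSE)
  }
  f <- gd$fixations; s <- gd$saccades; tl <- gd$trackloss
  blocks <- list(
    row_block(f, "fixation", f$onset_ms, f$offset_ms, f$x_px, f$y_px,
              NA_real_, NA_real_, NA_real_, NA),
    row_block(s, "saccade", s$onset_ms, NA_real_, s$start_x_px, s$start_y_px,
              s$end_x_px, s$end_y_px, s$amplitude_dva, NA),
    row_block(tl, "trackloss", tl$start_ms, tl$end_ms, NA_real_, NA_real_,
              NA_real_, NA_real_, NA_real_, tl$is_blink))
  out <- do.call(rbind, Filter(Negate(is.null), blocks))
  # trials with no events still need a carrier row so correctness round-trips
  seen <- unique(c(.trial_key(f), .trial_key(s), .trial_key(tl)))
  orphan <- !(tkey %in% seen)
  if (any(orphan)) {
    o <- tri[orphan, , drop = FALSE]
    out <- rbind(out, data.frame(
      participant = o$participant_id, image = o$image_id,
      category = as.character(o$category), event_type = "trial",
      onset_ms = 0, offset_ms = NA_real_, x_px = NA_real_, y_px = NA_real_,
      end_x_px = NA_real_, end_y_px = NA_real_, amplitude_dva = NA_real_,
      correct = o$correct, blink = NA, stringsAsFactors = FALSE))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Screening configuration
#'
#' Parameters of the event-screening procedure.  Defaults follow the standard
#' protocol for 3-s free viewing of 600 x 600 px stimuli: fixations shorter
#' than 100 ms or more than two standard deviations above the dataset grand
#' mean are discarded, saccades starting within 75 ms of stimulus onset are
#' anticipation errors, non-blink tracking gaps over 100 ms invalidate a
#' trial, and participants lose all data at 25% trackloss or 25% excluded
#' trials.
#'
#' @param image_size_px image extent; the valid region is the half-open
#'   rectangle `[0, size) x [0, size)`, origin top-left, y downward.
#' @param min_fix_ms minimum fixation duration (ms).
#' @param sd_mult multiplier of the grand SD for the long-duration cutoff.
#' @param sd_scale `"ms"` applies mean + sd_mult * SD on the millisecond
#'   scale (the scale on which grand statistics are reported); `"log"`
#'   applies it to log durations.
#' @param sd_after_min if `TRUE` (default) grand statistics are computed
#'   after the minimum-duration removal.
#' @param duration_cutoff_ms optional precomputed upper duration cutoff; when
#'   supplied the data-dependent cutoff is not recomputed (this makes
#'   re-screening a no-op).
#' @param max_gap_ms longest tolerated non-blink tracking gap (ms).
#' @param min_sacc_onset_ms saccades with earlier onsets are anticipation
#'   errors.
#' @param max_trackloss_frac,max_excluded_frac participant-level limits.
#' @param viewing_ms trial viewing duration (ms), the trackloss denominator.
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(image_size_px = 600, min_fix_ms = 100,
                             sd_mult = 2, sd_scale = c("ms", "log"),
                             sd_after_min = TRUE, duration_cutoff_ms = NULL,
                             max_gap_ms = 100, min_sacc_onset_ms = 75,
                             max_trackloss_frac = 0.25,
                             max_excluded_frac = 0.25, viewing_ms = 3000) {
  sd_scale <- match.arg(sd_scale)
  structure(list(image_size_px = image_size_px, min_fix_ms = min_fix_ms,
                 sd_mult = sd_mult, sd_scale = sd_scale,
                 sd_after_min = sd_after_min,
                 duration_cutoff_ms = duration_cutoff_ms,
                 max_gap_ms = max_gap_ms,
                 min_sacc_onset_ms = min_sacc_onset_ms,
                 max_trackloss_frac = max_trackloss_frac,
                 max_excluded_frac = max_excluded_frac,
                 viewing_ms = viewing_ms),
            class = "screening_config")
}

.in_region <- function(x, y, size) {
  x >= 0 & x < size & y >= 0 & y < size
}

## fixation validity from per-event rules only (no dataset statistics);
## used for trial rule 2, where the grand mean/SD are not yet defined
.locally_valid_fix <- function(f, cfg) {
  !f$is_first &
    .in_region(f$x_px, f$y_px, cfg$image_size_px) &
    f$duration_ms >= cfg$min_fix_ms
}

#' Screen trials
#'
#' Applies the four trial-level rules in order: (1) incorrect categorization;
#' (2) two or fewer valid fixations (first recorded fixation excluded, and
#' counting only fixations inside the image region with duration at or above
#' the minimum); (3) any non-blink tracking gap longer than `max_gap_ms`;
#' then (4) removal of participants with more than 25% of viewing time lost
#' or more than 25% of trials excluded.  A trial is attributed to the first
#' rule it violates.
#'
#' @param gd a `gaze_data` object.
#' @param cfg a [screening_config()].
#' @return `list(data, report)`: the dataset restricted to valid trials (all
#'   event tables subset accordingly) and a [screening_report] for the stage.
#' @export
screen_trials <- function(gd, cfg = screening_config()) {
  stopifnot(inherits(gd, "gaze_data"))
  tri <- gd$trials
  if (anyNA(tri$correct)) stop("trial without correctness flag")
  tkey <- .trial_key(tri)
  f <- gd$fixations
  nval <- tapply(.locally_valid_fix(f, cfg), .trial_key(f), sum)
  n_valid_fix <- ifelse(tkey %in% names(nval), nval[tkey], 0L)
  tl <- gd$trackloss
  bad_gap_key <- unique(.trial_key(tl)[!tl$is_blink &
                                         (tl$end_ms - tl$start_ms) > cfg$max_gap_ms])
  rule <- rep(NA_character_, nrow(tri))
  rule[is.na(rule) & !tri$correct] <- "incorrect"
  rule[is.na(rule) & n_valid_fix <= 2] <- "too_few_fixations"
  rule[is.na(rule) & tkey %in% bad_gap_key] <- "trackloss_gap"

  # participant rule: trackloss fraction of viewing time, or excluded-trial share
  tl_time <- tapply(pmin(tl$end_ms, cfg$viewing_ms) - pmax(tl$start_ms, 0),
                    tl$participant_id, sum)
  p_ids <- unique(tri$participant_id)
  n_tri <- tapply(rep(1, nrow(tri)), tri$participant_id, sum)[p_ids]
  lost <- ifelse(p_ids %in% names(tl_time), tl_time[p_ids], 0)
  tl_frac <- lost / (n_tri * cfg$viewing_ms)
  excl_frac <- tapply(!is.na(rule), tri$participant_id, mean)[p_ids]
  bad_p <- p_ids[tl_frac > cfg$max_trackloss_frac |
                   excl_frac > cfg$max_excluded_frac]
  rule[is.na(rule) & tri$participant_id %in% bad_p] <- "participant_excluded"

  keep_key <- tkey[is.na(rule)]
  sub <- function(df) df[.trial_key(df) %in% keep_key, , drop = FALSE]
  out <- gd
  out$trials <- tri[is.na(rule), , drop = FALSE]
  out$fixations <- sub(gd$fixations)
  out$saccades <- sub(gd$saccades)
  out$trackloss <- sub(gd$trackloss)
  counts <- c(incorrect = sum(rule == "incorrect", na.rm = TRUE),
              too_few_fixations = sum(rule == "too_few_fixations", na.rm = TRUE),
              trackloss_gap = sum(rule == "trackloss_gap", na.rm = TRUE),
              participant_excluded = sum(rule == "participant_excluded",
                                         na.rm = TRUE))
  rep_ <- screening_report("trials", n_input = nrow(tri), excluded = counts,
                           extra = list(
                             excluded_participants = as.character(bad_p),
                             participant_trackloss_frac =
                               setNames(as.numeric(tl_frac), p_ids)))
  list(data = out, report = rep_)
}

#' Screen fixations
#'
#' Removes, from an already trial-screened dataset: the first recorded
#' fixation of every trial (uninformative: recording starts before stimulus
#' onset); fixations outside the image region; fixations shorter than
#' `min_fix_ms`; and fixations more than `sd_mult` standard deviations above
#' the dataset grand mean duration.  Percentages are relative to all
#' fixations of valid trials excluding the first fixations.
#'
#' @inheritParams screen_trials
#' @return `list(data, report)`; the report records the duration cutoff used
#'   (`extra$duration_cutoff_ms`).
#' @export
screen_fixations <- function(gd, cfg = screening_config()) {
  stopifnot(inherits(gd, "gaze_data"))
  f <- gd$fixations
  first <- f$is_first
  pool <- f[!first, , drop = FALSE]
  out_region <- !.in_region(pool$x_px, pool$y_px, cfg$image_size_px)
  too_short <- !out_region & pool$duration_ms < cfg$min_fix_ms
  if (is.null(cfg$duration_cutoff_ms)) {
    base <- pool$duration_ms[!out_region]
    if (cfg$sd_after_min) base <- base[base >= cfg$min_fix_ms]
    if (cfg$sd_scale == "ms") {
      cutoff <- mean(base) + cfg$sd_mult * sd(base)
    } else {
      cutoff <- exp(mean(log(base)) + cfg$sd_mult * sd(log(base)))
    }
  } else cutoff <- cfg$duration_cutoff_ms
  if (!length(pool$duration_ms) || !is.finite(cutoff)) cutoff <- Inf
  too_long <- !out_region & !too_short & pool$duration_ms > cutoff
  keep <- !(out_region | too_short | too_long)
  out <- gd
  out$fixations <- pool[keep, , drop = FALSE]
  rep_ <- screening_report("fixations", n_input = nrow(pool),
                           excluded = c(outside_region = sum(out_region),
                                        too_short = sum(too_short),
                                        too_long = sum(too_long)),
                           extra = list(duration_cutoff_ms = cutoff,
                                        n_first_removed = sum(first)))
  list(data = out, report = rep_)
}

#' Screen saccades
#'
#' Removes saccades with onset earlier than `min_sacc_onset_ms` after
#' stimulus onset (anticipation errors; pre-stimulus onsets are negative and
#' never valid) and saccades whose start or landing position lies outside
#' the image region.  The first recorded saccade of a trial is retained.
#'
#' @inheritParams screen_trials
#' @return `list(data, report)`.
#' @export
screen_saccades <- function(gd, cfg = screening_config()) {
  stopifnot(inherits(gd, "gaze_data"))
  s <- gd$saccades
  early <- s$onset_ms < cfg$min_sacc_onset_ms
  outside <- !early &
    !(.in_region(s$start_x_px, s$start_y_px, cfg$image_size_px) &
        .in_region(s$end_x_px, s$end_y_px, cfg$image_size_px))
  out <- gd
  out$saccades <- s[!(early | outside), , drop = FALSE]
  rep_ <- screening_report("saccades", n_input = nrow(s),
                           excluded = c(anticipation = sum(early),
                                        endpoint_outside = sum(outside)))
  list(data = out, report = rep_)
}

#' Run the full screening procedure
#'
#' Trial rules, then fixation filters, then saccade filters, in the fixed
#' order of the protocol.
#'
#' @inheritParams screen_trials
#' @return `list(data, report)` where `report` is a named list of the three
#'   stage reports (classes `screening_report`).
#' @export
screen_gaze <- function(gd, cfg = screening_config()) {
  st <- screen_trials(gd, cfg)
  sf <- screen_fixations(st$data, cfg)
  ss <- screen_saccades(sf$data, cfg)
  list(data = ss$data,
       report = list(trials = st$report, fixations = sf$report,
                     saccades = ss$report))
}

#' Screening report
#'
#' Per-rule exclusion counts and percentages for one screening stage.
#' @param stage stage label.
#' @param n_input events entering the stage.
#' @param excluded named integer vector of per-rule exclusion counts.
#' @param extra optional list of stage-specific diagnostics.
#' @return Object of class `screening_report` with fields `stage`, `n_input`,
#'   `excluded`, `retained`, `pct` (percentages of `n_input`).
#' @export
screening_report <- function(stage, n_input, excluded, extra = list()) {
  excluded <- as.integer(excluded) |> setNames(names(excluded))
  retained <- n_input - sum(excluded)
  pct <- if (n_input > 0) 100 * excluded / n_input else excluded * 0
  structure(list(stage = stage, n_input = n_input, excluded = excluded,
                 retained = retained, pct = pct, extra = extra),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening stage '%s': %d in, %d retained\n", x$stage,
              x$n_input, x$retained))
  for (nm in names(x$excluded))
    cat(sprintf("  %-22s %6d  (%.2f%%)\n", nm, x$excluded[[nm]], x$pct[[nm]]))
  invisible(x)
}

#' Serialize screening reports to JSON
#'
#' @param report a `screening_report` or a named list of them (as produced by
#'   [screen_gaze()]).
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
screening_report_json <- function(report, path = NULL) {
  as_l <- function(r) list(stage = r$stage, n_input = r$n_input,
                           excluded = as.list(r$excluded),
                           retained = r$retained, pct = as.list(r$pct))
  obj <- if (inherits(report, "screening_report")) as_l(report)
  else lapply(report, as_l)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
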