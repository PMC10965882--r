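# Event containers, file round trips, and the screening procedure.

test_that("event tables round-trip through delimited text", {
  cfg <- exact_cfg(seed = 21)
  gi <- gen_images(cfg)
  gd <- gen_scanpaths(cfg, gi$meta, gen_annotations(gi))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(gd, path)
  back <- load_events(path)
  expect_equal(nrow(back$trials), nrow(gd$trials))
  expect_equal(nrow(back$fixations), nrow(gd$fixations))
  expect_equal(nrow(back$saccades), nrow(gd$saccades))
  expect_equal(sum(back$fixations$is_first), nrow(back$trials))
  # content identity on sorted keys
  o1 <- order(fix_key(gd$fixations)); o2 <- order(fix_key(back$fixations))
  expect_equal(back$fixations$x_px[o2], gd$fixations$x_px[o1])
  expect_equal(back$fixations$duration_ms[o2], gd$fixations$duration_ms[o1])
  o1 <- order(sacc_key(gd$saccades)); o2 <- order(sacc_key(back$saccades))
  expect_equal(back$saccades$amplitude_dva[o2], gd$saccades$amplitude_dva[o1])
  expect_equal(sort(trial_key(back$trials[!back$trials$correct, ])),
               sort(trial_key(gd$trials[!gd$trials$correct, ])))
})

test_that("first recorded fixation is flagged and an empty file warns", {
  gd <- manual_gaze(fix_df(c(-80, 200, 600, 950, 1400),
                           c(250, 300, 250, 350, 200),
                           x = rep(300, 5), y = rep(300, 5)))
  expect_identical(gd$fixations$is_first, c(TRUE, rep(FALSE, 4)))
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant,image,category,event_type,onset_ms,correct", empty)
  expect_warning(out <- load_events(empty), "no events")
  expect_s3_class(out, "gaze_data")
  expect_equal(nrow(out$trials), 0)
})

test_that("malformed event files raise informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,image,event_type", "p1,i1,fixation"), p)
  expect_error(load_events(p), "missing column")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,image,category,event_type,onset_ms,offset_ms,x_px,y_px,end_x_px,end_y_px,amplitude_dva,correct,blink",
               "p1,i1,c1,fixation,0,200,abc,5,,,,TRUE,"), p2)
  expect_error(load_events(p2), "non-numeric.*row 1")
})

test_that("trial screening applies the four rules in order", {
  base_fix <- fix_df(c(-80, 200, 600, 950), c(250, 300, 250, 350),
                     x = rep(300, 4), y = rep(300, 4))
  # rule 1: incorrect response
  g1 <- manual_gaze(base_fix, correct = FALSE)
  r1 <- screen_trials(g1)
  expect_equal(nrow(r1$data$trials), 0)
  expect_equal(unname(r1$report$excluded["incorrect"]), 1L)
  # rule 2: exactly 2 valid fixations (after first removal) is too few
  g2 <- manual_gaze(fix_df(c(-80, 200, 600), c(250, 300, 250),
                           x = rep(300, 3), y = rep(300, 3)))
  r2 <- screen_trials(g2)
  expect_equal(unname(r2$report$excluded["too_few_fixations"]), 1L)
  # 3 valid fixations pass
  expect_equal(nrow(screen_trials(manual_gaze(base_fix))$data$trials), 1)
  # rule 3: 150 ms non-blink gap kills the trial, a blink gap does not
  tl_bad <- data.frame(start_ms = 1000, end_ms = 1150, is_blink = FALSE)
  tl_blink <- data.frame(start_ms = 1000, end_ms = 1150, is_blink = TRUE)
  expect_equal(unname(screen_trials(manual_gaze(base_fix, trackloss = tl_bad))$
                        report$excluded["trackloss_gap"]), 1L)
  expect_equal(nrow(screen_trials(manual_gaze(base_fix, trackloss = tl_blink))$
                      data$trials), 1)
  # missing correctness flag is an error
  g4 <- manual_gaze(base_fix)
  g4$trials$correct <- NA
  expect_error(screen_trials(g4), "correctness")
})

test_that("participant rule removes heavy-trackloss observers", {
  fixs <- fix_df(c(-80, 200, 600, 950), c(250, 300, 250, 350),
                 rep(300, 4), rep(300, 4))
  mk <- function(p, img, tl = NULL) {
    f <- fixs; f$participant_id <- p; f$image_id <- img
    list(fix = f,
         tri = data.frame(participant_id = p, image_id = img,
                          category = "c", correct = TRUE),
         tl = if (!is.null(tl)) cbind(tl, participant_id = p, image_id = img))
  }
  # p_bad loses 900 ms of each 3000 ms trial (30%) via blinks (valid trials,
  # but over the participant trackloss budget)
  parts <- list(mk("p_bad", "i1", data.frame(start_ms = 100, end_ms = 1000,
                                             is_blink = TRUE)),
                mk("p_bad", "i2", data.frame(start_ms = 100, end_ms = 1000,
                                             is_blink = TRUE)),
                mk("p_ok", "i1"), mk("p_ok", "i2"))
  gd <- gaze_data(do.call(rbind, lapply(parts, `[[`, "fix")),
                  data.frame(participant_id = character(), image_id = character(),
                             onset_ms = numeric(), start_x_px = numeric(),
                             start_y_px = numeric(), end_x_px = numeric(),
                             end_y_px = numeric(), amplitude_dva = numeric()),
                  do.call(rbind, lapply(parts, `[[`, "tri")),
                  do.call(rbind, Filter(Negate(is.null),
                                        lapply(parts, `[[`, "tl"))))
  r <- screen_trials(gd)
  expect_equal(unname(r$report$excluded["participant_excluded"]), 2L)
  expect_setequal(unique(r$data$trials$participant_id), "p_ok")
})

test_that("fixation filters remove out-of-region, short and long events", {
  durs <- c(250, 157, 296, 435, 90, 580, 200, 300)
  xs <- c(300, 300, 650, 599.5, 300, 300, 300, -1)
  ys <- rep(300, 8)
  gd <- manual_gaze(fix_df(seq(-80, by = 400, length.out = 8), durs, xs, ys))
  r <- screen_fixations(gd)
  pool <- gd$fixations[!gd$fixations$is_first, ]
  # region rule: x = 650 and x = -1 out, boundary 599.5 in
  expect_equal(unname(r$report$excluded["outside_region"]), 2L)
  expect_equal(unname(r$report$excluded["too_short"]), 1L)
  # grand stats from in-region durations >= 100: hand-computed cutoff
  base <- c(157, 435, 580, 200)   # in-region, non-first, >= 100 ms
  cutoff <- mean(base) + 2 * sd(base)
  expect_equal(r$report$extra$duration_cutoff_ms, cutoff)
  expect_equal(unname(r$report$excluded["too_long"]), sum(base > cutoff))
  # counts conservation
  expect_equal(r$report$retained + sum(r$report$excluded), nrow(pool))
})

test_that("the printed-scale duration cutoff matches the M + 2 SD rule", {
  # durations engineered to grand mean 296, SD 139 -> cutoff 574
  base <- c(157, 296, 435)                       # mean 296, sd 139 exactly
  expect_equal(mean(base), 296); expect_equal(sd(base), 139)
  gd <- manual_gaze(fix_df(seq(-80, by = 700, length.out = 5),
                           c(250, base, 580), rep(300, 5), rep(300, 5)))
  r <- screen_fixations(gd, screening_config(duration_cutoff_ms = 574))
  expect_equal(unname(r$report$excluded["too_long"]), 1L)
  expect_false(580 %in% r$data$fixations$duration_ms)
  expect_true(all(base %in% r$data$fixations$duration_ms))
})

test_that("saccade filters remove anticipation and out-of-region endpoints", {
  sac <- data.frame(onset_ms = c(50, 74, 75, 200, 400, -20),
                    start_x_px = c(300, 300, 300, 300, -5, 300),
                    start_y_px = 300,
                    end_x_px = c(300, 300, 300, -5, 300, 300),
                    end_y_px = 300, amplitude_dva = 2)
  fixs <- fix_df(c(-80, 200, 600, 950), c(250, 300, 250, 350),
                 rep(300, 4), rep(300, 4))
  gd <- manual_gaze(fixs, sac)
  r <- screen_saccades(gd)
  expect_equal(unname(r$report$excluded["anticipation"]), 3L)  # 50, 74, -20
  expect_equal(unname(r$report$excluded["endpoint_outside"]), 2L)
  expect_equal(r$data$saccades$onset_ms, 75)
})

test_that("screening is idempotent given the recorded duration cutoff", {
  cfg <- exact_cfg(seed = 31)
  gi <- gen_images(cfg)
  gd <- gen_scanpaths(cfg, gi$meta, gen_annotations(gi))
  s1 <- screen_gaze(gd, screening_config(image_size_px = cfg$image_size_px))
  cut <- s1$report$fixations$extra$duration_cutoff_ms
  s2 <- screen_gaze(s1$data, screening_config(image_size_px = cfg$image_size_px,
                                              duration_cutoff_ms = cut))
  expect_equal(sum(s2$report$trials$excluded), 0L)
  expect_equal(sum(s2$report$fixations$excluded), 0L)
  expect_equal(sum(s2$report$saccades$excluded), 0L)
  expect_equal(nrow(s2$data$fixations), nrow(s1$data$fixations))
})

test_that("report percentages are bounded and counts conserve", {
  cfg <- exact_cfg(seed = 41, rate_incorrect = 0.1, rate_fewfix = 0.1,
                   rate_trackloss = 0.05, rate_short_fix = 0.1,
                   rate_oob_fix = 0.05, rate_early_saccade = 0.05)
  gi <- gen_images(cfg)
  gd <- gen_scanpaths(cfg, gi$meta, gen_annotations(gi))
  scr <- screen_gaze(gd, screening_config(image_size_px = cfg$image_size_px))
  for (rep_ in scr$report) {
    expect_true(all(rep_$pct >= 0 & rep_$pct <= 100))
    expect_equal(rep_$retained + sum(rep_$excluded), rep_$n_input)
  }
})

test_that("planted screening violations are recovered exactly, per rule", {
  cfg <- exact_cfg(seed = 51, rate_incorrect = 0.05, rate_fewfix = 0.05,
                   rate_trackloss = 0.05, rate_short_fix = 0.05,
                   rate_oob_fix = 0.05, rate_early_saccade = 0.05)
  gi <- gen_images(cfg)
  gd <- gen_scanpaths(cfg, gi$meta, gen_annotations(gi))
  scr <- screen_gaze(gd, screening_config(image_size_px = cfg$image_size_px))
  # per-rule counts equal planted counts
  expect_equal(unname(scr$report$trials$excluded["incorrect"]),
               sum(gd$trials$flag_incorrect))
  expect_equal(unname(scr$report$trials$excluded["too_few_fixations"]),
               sum(gd$trials$flag_fewfix))
  expect_equal(unname(scr$report$trials$excluded["trackloss_gap"]),
               sum(gd$trials$flag_trackloss))
  cf <- screening_confusion(gd, scr)
  for (st in cf) expect_identical(st$removed, st$flagged)
  # at least one instance of each rule actually occurred in this fixture
  expect_true(all(scr$report$trials$excluded[1:3] >= 1))
  expect_true(sum(cf$fixations$flagged) >= 1)
  expect_true(sum(cf$saccades$flagged) >= 1)
})

test_that("screening reports serialize to JSON", {
  gd <- manual_gaze(fix_df(c(-80, 200, 600, 950), c(250, 300, 250, 350),
                           rep(300, 4), rep(300, 4)))
  scr <- screen_gaze(gd)
  js <- screening_report_json(scr$report)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$trials$retained, 1)
  expect_named(parsed, c("trials", "fixations", "saccades"))
})
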