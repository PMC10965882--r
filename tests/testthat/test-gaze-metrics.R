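# Fixation density maps, entropies, transitions, center bias, aggregation.

test_that("fixation density maps are unit-mass and geometrically faithful", {
  f <- build_fdm(300, 300, image_size_px = 600)
  expect_equal(sum(f$grid), 1, tolerance = 1e-12)
  expect_equal(which(f$grid == max(f$grid), arr.ind = TRUE)[1, ],
               c(row = 301, col = 301))
  # mirror symmetry for fixations mirrored on the pixel grid
  f2 <- build_fdm(c(200.5, 399.5), c(300, 300), image_size_px = 600)
  expect_equal(f2$grid, f2$grid[, ncol(f2$grid):1], tolerance = 1e-12)
  # kernel truncated at the edge: still unit mass after renormalization
  f3 <- build_fdm(c(1, 3, 598), c(2, 1, 599), image_size_px = 600)
  expect_equal(sum(f3$grid), 1, tolerance = 1e-12)
})

test_that("FDM entropy matches analytic values and validates input", {
  point <- matrix(0, 50, 50); point[10, 10] <- 1
  expect_equal(fdm_entropy(point), 0)
  expect_equal(fdm_entropy(matrix(1 / 2500, 50, 50)), log2(2500))
  three <- matrix(0, 10, 10); three[1, 1] <- 0.5; three[5, 5] <- 0.25
  three[9, 9] <- 0.25
  expect_equal(fdm_entropy(three), 1.5)
  expect_error(fdm_entropy(matrix(1, 10, 10)), "summing to 1")
  # entropy is bounded by the uniform case
  f <- build_fdm(c(100, 300, 500), c(100, 300, 500), image_size_px = 600)
  expect_lt(fdm_entropy(f), log2(600^2))
})

test_that("AOI transitions tabulate occupancy and row-normalized moves", {
  # all fixations in one AOI
  t1 <- build_transitions(rep(50, 5), rep(50, 5), n_segments = 6,
                          image_size_px = 600)
  expect_equal(sum(t1$v), 1)
  expect_equal(max(t1$v), 1)
  aoi <- which(t1$v == 1)
  expect_equal(t1$M[aoi, aoi], 1)
  # alternating two-AOI scanpath: deterministic cross transitions
  xs <- rep(c(50, 550), 4); ys <- rep(50, 8)
  t2 <- build_transitions(xs, ys, n_segments = 6, image_size_px = 600)
  occupied <- which(t2$v > 0)
  expect_equal(unname(t2$v[occupied]), c(0.5, 0.5))
  expect_equal(t2$M[occupied[1], occupied[2]], 1)
  expect_equal(t2$M[occupied[2], occupied[1]], 1)
  # boundary fixation joins the higher-index cell (half-open cells)
  t3 <- build_transitions(c(100, 100), c(0, 0), n_segments = 6,
                          image_size_px = 600)
  expect_equal(which(t3$v > 0), 2L)   # x = 100 is exactly the 100-boundary
  # transitions never cross trials
  t4 <- build_transitions(c(50, 550, 50, 550), rep(50, 4),
                          trial = c(1, 1, 2, 2), n_segments = 6,
                          image_size_px = 600)
  expect_equal(t4$n_transitions, 2L)
  expect_error(build_transitions(1, 1), "at least 2")
})

test_that("large uniform scanpaths give near-stationary transition rows", {
  withr::with_seed(99, {
    xs <- runif(1e5, 0, 600); ys <- runif(1e5, 0, 600)
  })
  tr <- build_transitions(xs, ys, n_segments = 6, image_size_px = 600)
  expect_equal(tr$v, rep(1 / 36, 36), tolerance = 0.05)
  # every row of M approximates the occupancy distribution (iid sampling)
  for (i in c(1, 18, 36))
    expect_equal(unname(tr$M[i, ]), unname(tr$v), tolerance = 0.15)
})

test_that("gaze transition entropy hits its analytic anchors", {
  # deterministic scanpath -> 0
  xs <- rep(c(50, 550), 6)
  expect_equal(gaze_transition_entropy(
    build_transitions(xs, rep(50, 12), n_segments = 6, image_size_px = 600)), 0)
  # uniform v and M over N AOIs -> exactly 1 after normalization
  N <- 36
  t_unif <- structure(list(v = rep(1 / N, N), M = matrix(1 / N, N, N),
                           n_segments = 6, N = N, n_transitions = N),
                      class = "aoi_transitions")
  expect_equal(gaze_transition_entropy(t_unif), 1)
  # 2-AOI chain with stationary occupancy: direct hand evaluation
  M <- matrix(0, N, N)
  M[1, 1] <- 0.9; M[1, 2] <- 0.1; M[2, 1] <- 0.5; M[2, 2] <- 0.5
  v <- c(5 / 6, 1 / 6, rep(0, N - 2))   # stationary for the 2x2 block
  t_chain <- structure(list(v = v, M = M, n_segments = 6, N = N,
                            n_transitions = 100), class = "aoi_transitions")
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  raw_hand <- 5 / 6 * h(c(0.9, 0.1)) + 1 / 6 * h(c(0.5, 0.5))
  expect_equal(gaze_transition_entropy(t_chain, normalize = FALSE), raw_hand)
  expect_equal(gaze_transition_entropy(t_chain), raw_hand / log2(N))
  # raw GTE never exceeds log2(N)
  expect_lte(gaze_transition_entropy(t_unif, normalize = FALSE), log2(N))
})

test_that("GTE is invariant to AOI relabeling", {
  withr::with_seed(7, { xs <- runif(200, 0, 600); ys <- runif(200, 0, 600) })
  g1 <- gaze_transition_entropy(build_transitions(xs, ys, n_segments = 6,
                                                  image_size_px = 600))
  # mirroring coordinates permutes AOI labels but not transition structure
  g2 <- gaze_transition_entropy(build_transitions(600 - xs, ys, n_segments = 6,
                                                  image_size_px = 600))
  g3 <- gaze_transition_entropy(build_transitions(ys, xs, n_segments = 6,
                                                  image_size_px = 600))
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(g1, g3, tolerance = 1e-12)
})

test_that("the uniform baseline distance matches numeric integration", {
  # midpoint quadrature oracle on a fine grid
  n <- 601
  xs <- (seq_len(n) - 0.5) * 600 / n
  d <- sqrt(outer(xs - 300, rep(1, n))^2 + outer(rep(1, n), xs - 300)^2)
  expect_equal(uniform_center_distance(600), mean(d), tolerance = 1e-5)
  expect_equal(uniform_center_distance(1), 0.3825978, tolerance = 1e-6)
})

test_that("center bias anchors: all-center 100, uniform ~ 0, corner negative", {
  cb <- center_bias(rep(300, 100), rep(300, 100), 600, n_bootstrap = 0)
  expect_identical(cb$score, 100)
  withr::with_seed(5, {
    u <- center_bias(runif(2e5, 0, 600), runif(2e5, 0, 600), 600,
                     n_bootstrap = 0)
  })
  expect_equal(u$score, 0, tolerance = 1.5)
  corner <- center_bias(rep(0, 10), rep(0, 10), 600, n_bootstrap = 0)
  expect_equal(corner$mean_dist_px, 300 * sqrt(2))
  expect_equal(corner$score,
               100 * (1 - 300 * sqrt(2) / uniform_center_distance(600)))
  expect_lt(corner$score, 0)
})

test_that("center bias is rotation invariant and bootstrap SE is seeded", {
  withr::with_seed(8, { xs <- runif(50, 0, 600); ys <- runif(50, 0, 600) })
  a <- center_bias(xs, ys, 600, n_bootstrap = 0)
  b <- center_bias(ys, 600 - xs, 600, n_bootstrap = 0)  # 90 deg about center
  expect_equal(a$score, b$score, tolerance = 1e-12)
  s1 <- center_bias(xs, ys, 600, n_bootstrap = 200, seed = 42)
  s2 <- center_bias(xs, ys, 600, n_bootstrap = 200, seed = 42)
  expect_identical(s1$se, s2$se)
  expect_gt(s1$se, 0)
})

test_that("per-trial summaries equal hand computation", {
  gd <- manual_gaze(fix_df(c(-80, 200, 600, 950, 1400, 1800),
                           c(250, rep(200, 5)),
                           x = c(300, 100, 500, 100, 500, 100),
                           y = rep(300, 6)),
                    sac = data.frame(onset_ms = c(150, 500, 900),
                                     start_x_px = 300, start_y_px = 300,
                                     end_x_px = 400, end_y_px = 300,
                                     amplitude_dva = c(2, 3, 4)))
  scr <- screen_gaze(gd)
  rec <- summarize_gaze(scr$data)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mean_fixation_duration_ms, 200)
  expect_equal(rec$n_fixations, 5)
  expect_equal(rec$mean_saccade_amplitude_dva, 3)
  fx <- scr$data$fixations
  expect_equal(rec$fdm_entropy_bits,
               fdm_entropy(build_fdm(fx$x_px, fx$y_px, 600)))
  expect_equal(rec$center_bias,
               center_bias(fx$x_px, fx$y_px, 600, n_bootstrap = 0)$score)
  # identical trials give identical records
  gd2 <- gd
  gd2$fixations$participant_id <- "p2"
  gd2$saccades$participant_id <- "p2"
  gd2$trials$participant_id <- "p2"
  both <- screen_gaze(gaze_data(rbind(gd$fixations, gd2$fixations),
                                rbind(gd$saccades, gd2$saccades),
                                rbind(gd$trials, gd2$trials)))
  rec2 <- summarize_gaze(both$data)
  expect_equal(rec2[1, -1], rec2[2, -1], ignore_attr = TRUE)
})

test_that("aggregation averages observers then images", {
  rec <- data.frame(participant_id = rep(c("p1", "p2"), 3),
                    image_id = rep(c("i1", "i2", "i3"), each = 2),
                    n_fixations = c(8, 10, 6, 8, 4, 6),
                    fdm_entropy_bits = c(10, 12, 9, 11, 8, 10))
  img <- aggregate_gaze(rec, "image")
  expect_equal(img$n_fixations[img$image_id == "i1"], 9)
  expect_equal(img$fdm_entropy_bits[img$image_id == "i3"], 9)
  cats <- c(i1 = "catA", i2 = "catA", i3 = "catB")
  byc <- aggregate_gaze(rec, "category", cats)
  expect_equal(byc$n_fixations[byc$category == "catA"], mean(c(9, 7)))
  expect_equal(byc$n_fixations[byc$category == "catB"], 5)
  # single observer: image value is that observer's value
  one <- aggregate_gaze(rec[rec$participant_id == "p1", ], "image")
  expect_equal(one$n_fixations, c(8, 6, 4))
  # unlabeled image dropped with warning at category level
  expect_warning(aggregate_gaze(rec, "category", cats[-3]), "without a category")
})
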