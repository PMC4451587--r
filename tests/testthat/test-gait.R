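# feet oscillating along x around a moving centroid; inter-feet distance is
# the scripted signal `sep`
feet_stream <- function(t, x, y, sep, present = TRUE, frame_rate = 10) {
  make_stream(t, x, y, posture = "standing", present = present,
              frame_rate = frame_rate,
              lfx = x + sep / 2, lfy = y, rfx = x - sep / 2, rfy = y)
}

test_that("step detection counts peaks of the inter-feet distance signal", {
  t <- seq(0, 9.9, 0.1)
  # standing still: constant separation, no local maxima
  still <- gait_segment(feet_stream(t, 1, 1, 0.1), "mono")
  expect_equal(nrow(detect_steps(still)), 0)

  # sinusoidal separation, period 1 s, peak amplitude 0.3 m -> 10 steps
  sep <- 0.15 + 0.15 * sin(2 * pi * t)
  seg <- gait_segment(feet_stream(t, t * 0.4, 1, sep), "mono")
  steps <- detect_steps(seg)
  expect_equal(nrow(steps), 10)
  # peaks at t = 0.25, 1.25, ... within one frame
  expect_true(all(abs(steps$t - (0:9 + 0.25)) <= 0.1 + 1e-9))
})

test_that("missing foot data triggers the centroid-fallback error", {
  t <- seq(0, 4.9, 0.1)
  st <- make_stream(t, t, 1)  # no feet at all
  seg <- gait_segment(st, "mono")
  expect_error(detect_steps(seg), "centroid")
  expect_silent(detect_steps(seg, method = "centroid"))
})

test_that("gait parameters follow their definitions on a constructed walk", {
  # 4 m in 8 s; 8 steps, consecutive step displacements all 0.5 m
  t <- seq(0, 7.9, 0.1)
  x <- t * 0.5
  sep <- 0.15 + 0.15 * sin(2 * pi * t)  # peaks every 1 s -> 8 steps
  seg <- gait_segment(feet_stream(t, x, 2, sep), "mono")
  steps <- detect_steps(seg)
  expect_equal(nrow(steps), 8)
  gp <- compute_gait_parameters(seg, steps)
  expect_equal(gp$total_duration_s, 8)
  expect_equal(gp$n_steps, 8)
  expect_equal(gp$cadence, 1)
  expect_equal(gp$avg_speed_mps, 0.5, tolerance = 0.02)
  expect_equal(mean(gp$step_lengths_m), 0.5, tolerance = 1e-6)
  expect_equal(gp$stride_length_m, 1.0, tolerance = 1e-6)
  expect_equal(gp$gap_duration_s, 0)
  expect_lt(gp$step_len_sd_m, 0.05)  # frame-grid peak placement jitter
  expect_true(gp$distance_traveled_m >= max(gp$step_lengths_m))

  # dropping frames [3.0, 3.5) creates 0.5 s of gap
  keep <- !(t >= 3.0 & t < 3.5)
  seg2 <- gait_segment(feet_stream(t[keep], x[keep], 2, sep[keep]), "mono")
  gp2 <- compute_gait_parameters(seg2, detect_steps(seg2))
  expect_equal(gp2$gap_duration_s, 0.5)
})

test_that("parameters are scale-equivariant and shift-invariant", {
  t <- seq(0, 9.9, 0.1)
  sep <- 0.16 + 0.14 * sin(2 * pi * t / 0.8)
  base <- feet_stream(t, t * 0.45, 1 + 0.1 * sin(t), sep)
  gp <- compute_gait_parameters(gait_segment(base, "mono"))
  for (k in c(2, 5)) {
    sc <- base
    for (cl in c("x", "y", "lfx", "lfy", "rfx", "rfy")) sc[[cl]] <- k * sc[[cl]]
    sc <- track_stream(as.data.frame(sc), frame_rate = 10)
    gk <- compute_gait_parameters(gait_segment(sc, "mono"))
    expect_equal(gk$n_steps, gp$n_steps)
    expect_equal(gk$total_duration_s, gp$total_duration_s)
    expect_equal(gk$cadence, gp$cadence)
    expect_equal(gk$step_lengths_m, k * gp$step_lengths_m, tolerance = 1e-9)
    expect_equal(gk$stride_length_m, k * gp$stride_length_m, tolerance = 1e-9)
    expect_equal(gk$distance_traveled_m, k * gp$distance_traveled_m,
                 tolerance = 1e-9)
    expect_equal(gk$avg_speed_mps, k * gp$avg_speed_mps, tolerance = 1e-9)
  }
  shifted <- base
  shifted$t <- shifted$t + 137.4
  shifted <- track_stream(as.data.frame(shifted), frame_rate = 10)
  gs <- compute_gait_parameters(gait_segment(shifted, "mono"))
  gp_cmp <- gp; gs_cmp <- gs
  expect_equal(gs_cmp[setdiff(names(gs_cmp), "task_kind")],
               gp_cmp[setdiff(names(gp_cmp), "task_kind")],
               tolerance = 1e-9)
})

test_that("simulator walks are recovered: scripted steps, path length, slowing", {
  cfg <- cohort_config(seed = 5)
  for (s in c(3, 14)) {
    sch <- generate_schedule("intermediate", "MCI", cfg, seed = s)
    r <- render_track_stream(sch, cfg, seed = s + 100)
    ev <- recognize_stream(r$stream, cfg$zones, cfg$models)
    g <- gait_from_events(r$stream, ev)
    truth_mono <- r$gait_truth[[1]]; truth_dual <- r$gait_truth[[2]]
    expect_equal(g$mono$n_steps, truth_mono$n_steps)
    expect_equal(g$dual$n_steps, truth_dual$n_steps)
    # scripted step times recovered within one frame
    steps <- detect_steps(gait_segment(slice_stream(
      r$stream, truth_mono$t_walk_start,
      truth_mono$t_walk_start + truth_mono$duration_s), "mono"))
    expect_equal(nrow(steps), truth_mono$n_steps)
    expect_true(all(abs(steps$t - truth_mono$step_times) <= 0.1 + 1e-9))
    # dual-task slowing encoded in the schedule is recovered
    expect_gt(g$dual$total_duration_s, g$mono$total_duration_s)
    # distance within 2% of the scripted path length (plus corridor tails)
    walk_only <- compute_gait_parameters(gait_segment(slice_stream(
      r$stream, truth_mono$t_walk_start,
      truth_mono$t_walk_start + truth_mono$duration_s), "mono"))
    expect_equal(walk_only$distance_traveled_m, truth_mono$path_length_m,
                 tolerance = 0.02)
  }
})
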