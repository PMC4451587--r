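test_that("schedule draws follow the class calibrations", {
  cfg <- cohort_config()
  # good-class draws land in the good band almost always
  draws <- vapply(1:400, function(i)
    generate_schedule("good", NA, cfg,
                      rng = ecoadl:::new_rng(ecoadl:::derive_seed(3, i))
    )$completed_count, integer(1))
  expect_gte(mean(draws >= 8 & draws <= 13), 0.95)
  # raw (pre-round/clip) mean near the calibration target
  raw <- vapply(1:1000, function(i)
    generate_schedule("good", NA, cfg,
                      rng = ecoadl:::new_rng(ecoadl:::derive_seed(5, i))
    )$completed_raw, numeric(1))
  expect_lt(abs(mean(raw) - 10.04), 3 * 1.4 / sqrt(1000))

  # degenerate noise: counts equal the rounded class means
  cal0 <- default_calibration()
  cal0$completed$sd <- 0; cal0$initiated_extra$sd <- 0
  cal0$walk[c("single_sd", "dual_sd")] <- 0; cal0$age$sd <- 0
  cfg0 <- cohort_config(calibration = cal0)
  s0 <- generate_schedule("intermediate", "MCI", cfg0, seed = 1)
  expect_equal(s0$completed_count, round(5.5))
  expect_equal(s0$age, 77.6)
  expect_equal(s0$walk$single_s, 11.43)

  # dual-task duration is never below the single-task duration
  for (i in 1:25) {
    s <- generate_schedule(sample(c("good", "poor"), 1), "AD", cfg,
                           rng = ecoadl:::new_rng(i))
    expect_gte(s$walk$dual_s, s$walk$single_s)
    expect_gte(s$initiated_count, s$completed_count)
    expect_lte(s$initiated_count, 13)
  }
})

test_that("seeding contract: same seed identical, different seeds differ", {
  cfg <- cohort_config(seed = 21)
  a <- generate_schedule("good", "HC", cfg, seed = 8)
  b <- generate_schedule("good", "HC", cfg, seed = 8)
  d <- generate_schedule("good", "HC", cfg, seed = 9)
  expect_identical(a[names(a) != "participant_id"],
                   b[names(b) != "participant_id"])
  expect_false(isTRUE(all.equal(a$completed_raw, d$completed_raw)))

  c1 <- simulate_cohort(cohort_config(seed = 4,
                                      joint = data.frame(
                                        autonomy = "good", diagnosis = "HC",
                                        n = 2L)))
  c2 <- simulate_cohort(cohort_config(seed = 4,
                                      joint = data.frame(
                                        autonomy = "good", diagnosis = "HC",
                                        n = 2L)))
  expect_identical(as.data.frame(c1$participants[[1]]$stream),
                   as.data.frame(c2$participants[[1]]$stream))
})

test_that("noiseless renders close the loop through the full pipeline", {
  cfg <- cohort_config(seed = 31)
  for (aut in c("good", "poor")) {
    sch <- generate_schedule(aut, NA, cfg, seed = 17)
    r <- render_track_stream(sch, cfg, seed = 18)
    ev <- recognize_stream(r$stream, cfg$zones, cfg$models)
    expect_equal(sort_events(ev),
                 sort_events(r$truth[c("model_name", "t_start", "t_end")]),
                 tolerance = 1e-9)
    g <- gait_from_events(r$stream, ev)
    prof <- build_profile(ev, g, cfg$proto, sch$age,
                          window_start = r$window_start)
    expect_equal(prof$activities_completed, sch$completed_count)
    expect_equal(prof$activities_initiated, sch$initiated_count)
  }
})

test_that("dropout leaves the configured presence rate", {
  cfg <- cohort_config(noise = list(dropout_prob = 0.05,
                                    position_jitter_sd_m = 0.05),
                       seed = 12)
  sch <- generate_schedule("good", "HC", cfg, seed = 2)
  r <- render_track_stream(sch, cfg, seed = 3)
  n <- nrow(r$stream)
  expect_gt(n, 2000)
  expect_lt(abs(mean(r$stream$person_present) - 0.95), 0.01)
})

test_that("profile-level simulation hits its calibration and seeds cleanly", {
  cal <- data.frame(class = rep(c("HC", "AD"), each = 2),
                    feature = rep(c("age", "speed"), 2),
                    mean = c(74.1, 1.1, 82.0, 0.7),
                    sd = c(6.6, 0.2, 8.0, 0.2))
  v0 <- draw_feature_profile("AD", transform(cal, sd = 0), seed = 1)
  expect_equal(unname(v0), c(82.0, 0.7))
  expect_equal(names(v0), c("age", "speed"))
  ages <- vapply(1:1000, function(i)
    draw_feature_profile("AD", cal,
                         rng = ecoadl:::new_rng(ecoadl:::derive_seed(9, i))
    )[["age"]], numeric(1))
  expect_lt(abs(mean(ages) - 82.0), 3 * 8 / sqrt(1000))
  expect_identical(draw_feature_profile("HC", cal, seed = 5),
                   draw_feature_profile("HC", cal, seed = 5))
  expect_false(isTRUE(all.equal(draw_feature_profile("HC", cal, seed = 5),
                                draw_feature_profile("HC", cal, seed = 6))))
  expect_error(draw_feature_profile("MCI", cal), "unknown class")

  d <- simulate_profile_table(c(a = 30, b = 20),
                              list(a = c(f1 = 0), b = c(f1 = 4)), sd = 0.5,
                              seed = 3)
  expect_equal(nrow(d$x), 50)
  expect_lt(abs(mean(d$x$f1[d$y == "b"]) - 4), 3 * 0.5 / sqrt(20))
})

test_that("default cohort composition matches the study population", {
  j <- default_cohort_joint()
  expect_equal(sum(j$n), 49)
  aut <- tapply(j$n, j$autonomy, sum)
  expect_equal(unname(c(aut[c("good", "intermediate", "poor")])),
               c(22, 16, 11))
  dia <- tapply(j$n, j$diagnosis, sum)
  expect_equal(unname(c(dia[c("HC", "MCI", "AD")])), c(14, 23, 12))
})
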