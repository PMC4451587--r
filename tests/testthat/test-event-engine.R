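test_that("point-in-polygon follows the even-odd rule with inclusive boundary", {
  sq <- square_zone("sq", 0, 0, 2)
  expect_true(point_in_polygon(1, 1, sq$polygon))
  expect_false(point_in_polygon(3, 1, sq$polygon))
  # boundary and vertex count as inside
  expect_true(point_in_polygon(0, 1, sq$polygon))
  expect_true(point_in_polygon(2, 2, sq$polygon))
  # concave polygon: notch is outside
  notch <- zone("notch", cbind(c(0, 4, 4, 2, 2, 0), c(0, 0, 3, 3, 1, 1)))
  expect_false(point_in_polygon(1, 2, notch$polygon))
  expect_true(point_in_polygon(3, 2, notch$polygon))
  expect_error(zone("bow", cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))),
               "self-intersecting")
  expect_error(zone("thin", cbind(c(0, 1), c(0, 1))), "vertices")
})

test_that("constant-state and empty streams give trivial primitives", {
  z <- square_zone("Drink", 0, 0, 2)
  st <- make_stream(seq(0, 9.9, 0.1), x = 1, y = 1)
  prim <- detect_primitive_states(st, list(z))
  expect_equal(prim$state_name, c("Person_in_zone_Drink", "Person_standing"))
  expect_equal(prim$t_start, c(0, 0))
  expect_equal(prim$t_end, c(10, 10))

  empty <- track_stream(NULL)
  expect_equal(nrow(detect_primitive_states(empty, list(z))), 0)
  absent <- make_stream(0:5, x = NA, y = NA, posture = NA, present = FALSE)
  expect_equal(nrow(detect_primitive_states(absent, list(z))), 0)
})

test_that("primitive detection matches the brute-force per-frame oracle", {
  zones <- list(square_zone("A", 0, 0, 2), square_zone("B", 1.5, 1.5, 2))
  for (seed in c(11, 23, 37)) {
    set.seed(seed)
    n <- 200
    st <- make_stream(seq(0, by = 0.1, length.out = n),
                      x = runif(n, -0.5, 4), y = runif(n, -0.5, 4),
                      posture = sample(c("standing", "sitting", "bending"),
                                       n, replace = TRUE),
                      present = runif(n) > 0.1)
    got <- detect_primitive_states(st, zones)
    want <- oracle_primitives(st, zones)
    rownames(got) <- NULL
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the drink-preparation example recognizes on [3, 4)", {
  m <- event_model("prepare_drink",
                   c(c1 = "Person_in_zone_Drink", c2 = "Person_bending"),
                   list(list(kind = "overlap", components = c("c1", "c2")),
                        list(kind = "min_duration_before", component = "c1",
                             min_s = 2)))
  prim <- data.frame(
    state_name = c("Person_in_zone_Drink", "Person_bending"),
    t_start = c(0, 3), t_end = c(10, 4))
  ev <- recognize_composite_events(m, prim)
  expect_equal(ev$model_name, "prepare_drink")
  expect_equal(ev$t_start, 3)
  expect_equal(ev$t_end, 4)

  # zone occupancy too short for the 2 s prior-duration constraint
  prim2 <- data.frame(
    state_name = c("Person_in_zone_Drink", "Person_bending"),
    t_start = c(0, 0), t_end = c(1, 1))
  expect_equal(nrow(recognize_composite_events(m, prim2)), 0)
})

test_that("composite recognition matches the instant-wise oracle", {
  states <- c("s1", "s2", "s3", "s4")
  mk_model <- function(i) {
    comps <- setNames(sample(states, 2), c("c1", "c2"))
    event_model(paste0("m", i), comps,
                list(list(kind = "overlap", components = c("c1", "c2")),
                     list(kind = "min_duration_before", component = "c1",
                          min_s = sample(c(0.5, 1, 2), 1))))
  }
  for (seed in 1:8) {
    set.seed(seed)
    prim <- random_primitives(50, states)
    models <- lapply(1:3, mk_model)
    got <- recognize_composite_events(models, prim)
    want <- oracle_composites(models, prim)
    expect_equal(sort_events(got), sort_events(want), tolerance = 1e-9)
  }
})

test_that("recognition is idempotent and stays within component support", {
  set.seed(5)
  prim <- random_primitives(40, c("a", "b"))
  m <- event_model("ev", c(c1 = "a", c2 = "b"),
                   list(list(kind = "overlap", components = c("c1", "c2"))))
  e1 <- recognize_composite_events(m, prim)
  e2 <- recognize_composite_events(m, prim)
  expect_identical(e1, e2)
  # every recognized instant lies inside the union of both components
  covered <- function(tt, state) {
    iv <- prim[prim$state_name == state, ]
    any(tt >= iv$t_start - 1e-9 & tt < iv$t_end - 1e-9)
  }
  for (i in seq_len(nrow(e1))) {
    instants <- seq(e1$t_start[i], e1$t_end[i] - 0.05, by = 0.1)
    expect_true(all(vapply(instants, covered, logical(1), state = "a")))
    expect_true(all(vapply(instants, covered, logical(1), state = "b")))
  }
})

test_that("nested models resolve and cycles are rejected", {
  inner <- event_model("inner", c(c1 = "a"),
                       list(list(kind = "min_duration_before",
                                 component = "c1", min_s = 1)))
  outer <- event_model("outer", c(c1 = "inner", c2 = "b"),
                       list(list(kind = "overlap",
                                 components = c("c1", "c2"))))
  prim <- data.frame(state_name = c("a", "b"),
                     t_start = c(0, 2), t_end = c(10, 6))
  ev <- recognize_composite_events(list(inner, outer), prim)
  out <- ev[ev$model_name == "outer", ]
  expect_equal(out$t_start, 2)  # inner active from t=1, b from t=2
  expect_equal(out$t_end, 6)

  a <- event_model("a_model", c(c1 = "b_model"))
  b <- event_model("b_model", c(c1 = "a_model"))
  expect_error(recognize_composite_events(list(a, b), prim), "cyclic")
  expect_error(
    event_model("bad", c(c1 = "a"),
                list(list(kind = "overlap", components = c("c1", "zz")))),
    "undeclared")
})

test_that("detection evaluation counts greedy one-to-one matches", {
  tr <- data.frame(model_name = "m", t_start = 0, t_end = 10)
  rec <- data.frame(model_name = c("m", "m"),
                    t_start = c(0, 20), t_end = c(9, 25))
  r <- evaluate_detection(rec, tr, threshold = 0.5)
  expect_equal(r$tp, 1); expect_equal(r$fp, 1); expect_equal(r$fn, 0)
  expect_equal(r$precision, 0.5); expect_equal(r$recall, 1)

  # perfect detection
  set.seed(2)
  ev <- random_primitives(10, c("m1", "m2"))
  names(ev)[1] <- "model_name"
  ev <- ev[!duplicated(ev[c("model_name", "t_start")]), ]
  p <- evaluate_detection(ev, ev, 0.8)
  expect_true(all(p$precision == 1) && all(p$recall == 1))

  # nothing recognized
  r0 <- evaluate_detection(ev[0, ], tr, 0.5)
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))
  # no truth for a model: recall undefined, precision still computed
  r1 <- evaluate_detection(rec, tr[0, ], 0.5)
  expect_true(is.na(r1$recall))
  expect_equal(r1$precision, 0)
})

test_that("zone and model JSON files round-trip", {
  zs <- default_scene()
  f <- tempfile(fileext = ".json")
  write_zones(zs, f)
  zs2 <- read_zones(f)
  expect_equal(names(zs2), names(zs))
  expect_equal(zs2$Drink$polygon, zs$Drink$polygon)

  ms <- default_event_models()
  f2 <- tempfile(fileext = ".json")
  write_event_models(ms, f2)
  ms2 <- read_event_models(f2)
  expect_equal(names(ms2), names(ms))
  expect_equal(ms2$preparing_drink$components, ms$preparing_drink$components)
  expect_equal(length(ms2$preparing_drink$constraints),
               length(ms$preparing_drink$constraints))
})
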