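#' Synthetic scene simulation
#'
#' Stand-in for the (unavailable) clinic video recordings: generates cohorts
#' of participants with known ground truth. Per participant, a schedule is
#' drawn from class-calibrated Gaussians (completed-activity counts per
#' autonomy class, walk durations and age per diagnosis group), then
#' rendered into a tracked-person stream: the person walks the corridor
#' twice (single task, then the slower dual task), then performs the
#' scheduled activity units by moving between contextual zones at 1 m/s,
#' adopting each activity's posture inside its zone. Completed units dwell
#' long enough to pass the completion-duration check; initiated-but-not-
#' completed units enter the zone only briefly. Ground-truth event intervals
#' (with the 2 s recognition latency applied) are emitted alongside, and
#' per-frame dropout and position jitter can be layered on top.
#'
#' @name synthetic_scene
NULL

#' Default class calibrations
#'
#' Completed-activity counts per autonomy class (good 10.04 +/- 1.4,
#' intermediate 5.5 +/- 1.2, poor 1.54 +/- 1.4), the initiated-minus-
#' completed surplus (interpolated across classes; only diagnosis-
#' conditioned initiated counts are published), single/dual walk durations
#' and ages per diagnosis group, with cohort-marginal rows (`all`) used when
#' no diagnosis is given.
#'
#' @return A list of calibration data.frames.
#' @export
default_calibration <- function() {
  list(
    completed = data.frame(
      autonomy = c("good", "intermediate", "poor"),
      mean = c(10.04, 5.5, 1.54),
      sd = c(1.4, 1.2, 1.4)),
    initiated_extra = data.frame(
      autonomy = c("good", "intermediate", "poor"),
      mean = c(1.6, 2.8, 2.9),   # interpolated from diagnosis-level counts
      sd = c(0.8, 1.0, 1.2)),
    walk = data.frame(
      diagnosis = c("HC", "MCI", "AD", "all"),
      single_mean = c(10.79, 11.43, 14.36, 11.92),
      single_sd = c(1.31, 2.97, 3.83, 3.1),
      dual_mean = c(14.79, 18.35, 23.25, 18.53),
      dual_sd = c(4.26, 8.78, 8.65, 8.19)),
    age = data.frame(
      diagnosis = c("HC", "MCI", "AD", "all"),
      mean = c(74.1, 77.6, 82.0, 77.7),
      sd = c(6.6, 6.2, 8.0, 7.3)))
}

#' Cohort configuration
#'
#' Defaults reproduce the study population: 49 participants whose joint
#' autonomy x diagnosis composition is good = 13 HC + 9 MCI,
#' intermediate = 1 HC + 10 MCI + 5 AD, poor = 4 MCI + 7 AD (so 14 HC /
#' 23 MCI / 12 AD and 22 / 16 / 11 by autonomy).
#'
#' @param joint data.frame with `autonomy`, `diagnosis`, `n`.
#' @param noise list with `dropout_prob` (per-frame probability the tracker
#'   loses the person) and `position_jitter_sd_m` (Gaussian jitter SD on all
#'   reported coordinates, meters).
#' @param frame_rate Hz. @param seed Integer master seed.
#' @param zones Scene zones. @param models Event-model library.
#' @param proto Activity protocol.
#' @param calibration See [default_calibration()].
#' @return An `ecoadl_cohort_config`.
#' @export
cohort_config <- function(joint = default_cohort_joint(),
                          noise = list(dropout_prob = 0,
                                       position_jitter_sd_m = 0),
                          frame_rate = 10, seed = 1,
                          zones = default_scene(),
                          models = default_event_models(),
                          proto = default_protocol(),
                          calibration = default_calibration()) {
  stopifnot(all(joint$n > 0),
            noise$dropout_prob >= 0, noise$dropout_prob < 1,
            noise$position_jitter_sd_m >= 0)
  structure(list(joint = joint, noise = noise, frame_rate = frame_rate,
                 seed = seed, zones = zones, models = models, proto = proto,
                 calibration = calibration),
            class = "ecoadl_cohort_config")
}

#' @rdname cohort_config
#' @export
default_cohort_joint <- function() {
  data.frame(
    autonomy = c("good", "good", "intermediate", "intermediate",
                 "intermediate", "poor", "poor"),
    diagnosis = c("HC", "MCI", "HC", "MCI", "AD", "MCI", "AD"),
    n = c(13L, 9L, 1L, 10L, 5L, 4L, 7L))
}

# expand protocol units into one slot per expected occurrence
protocol_slots <- function(proto) {
  u <- proto$activity_units
  data.frame(slot = seq_len(sum(u$expected_count)),
             model_name = rep(u$model_name, u$expected_count))
}

cal_row <- function(df, col, key) {
  r <- df[df[[col]] == key, , drop = FALSE]
  if (!nrow(r)) stop("no calibration row for ", col, " = ", key)
  r[1, ]
}

#' Draw one participant's ground-truth schedule
#'
#' The completed-activity count is drawn from the autonomy-class Gaussian
#' (draw, then round, then clip to `[0, 13]`; the raw draw is kept in
#' `completed_raw` for calibration checks). The initiated count adds a
#' class-calibrated surplus. Walk durations come from the diagnosis
#' Gaussians (marginal when no diagnosis), with the dual-task duration
#' resampled until it is at least the single-task duration.
#'
#' @param autonomy `"good"`, `"intermediate"` or `"poor"`.
#' @param diagnosis `"HC"`, `"MCI"`, `"AD"` or `NA` (marginal calibration).
#' @param config An [cohort_config()].
#' @param rng RNG stream (internal); pass `seed` instead from user code.
#' @param seed Used when `rng` is missing.
#' @param participant_id Identifier.
#' @return An `ecoadl_schedule`.
#' @export
generate_schedule <- function(autonomy, diagnosis = NA,
                              config = cohort_config(),
                              rng = NULL, seed = 1,
                              participant_id = "p1") {
  if (is.null(rng)) rng <- new_rng(seed)
  cal <- config$calibration
  cc <- cal_row(cal$completed, "autonomy", autonomy)
  completed_raw <- rng_norm(rng, 1, cc$mean, cc$sd)
  completed <- min(13L, max(0L, as.integer(round(completed_raw))))
  ex <- cal_row(cal$initiated_extra, "autonomy", autonomy)
  extra <- max(0L, as.integer(round(rng_norm(rng, 1, ex$mean, ex$sd))))
  initiated <- min(13L, completed + extra)
  slots <- protocol_slots(config$proto)
  n_slots <- nrow(slots)
  if (completed > n_slots)
    stop("completed count exceeds the number of protocol slots")
  pick <- rng_sample(rng, n_slots, initiated)
  done <- pick[seq_len(completed)]
  slots$status <- "omitted"
  slots$status[pick] <- "initiated"
  slots$status[done] <- "completed"
  wk <- cal_row(cal$walk, "diagnosis",
                if (is.na(diagnosis)) "all" else diagnosis)
  single_s <- max(6, rng_norm(rng, 1, wk$single_mean, wk$single_sd))
  dual_s <- max(6, rng_norm(rng, 1, wk$dual_mean, wk$dual_sd))
  tries <- 0L
  while (dual_s < single_s && tries < 50L) {
    dual_s <- max(6, rng_norm(rng, 1, wk$dual_mean, wk$dual_sd))
    tries <- tries + 1L
  }
  if (dual_s < single_s) dual_s <- single_s + 0.5
  ag <- cal_row(cal$age, "diagnosis",
                if (is.na(diagnosis)) "all" else diagnosis)
  age <- rng_norm(rng, 1, ag$mean, ag$sd)
  active <- which(slots$status != "omitted")
  order_idx <- active[rng_sample(rng, length(active))]
  dwell <- numeric(nrow(slots))
  dwell[slots$status == "completed"] <-
    rng_unif(rng, sum(slots$status == "completed"), 18, 35)
  dwell[slots$status == "initiated"] <-
    rng_unif(rng, sum(slots$status == "initiated"), 4.2, 5.4)
  slots$dwell_s <- dwell
  structure(list(participant_id = participant_id,
                 autonomy = autonomy, diagnosis = diagnosis, age = age,
                 completed_raw = completed_raw,
                 completed_count = completed,
                 initiated_count = initiated,
                 slots = slots, perform_order = order_idx,
                 walk = list(single_s = single_s, dual_s = dual_s)),
            class = "ecoadl_schedule")
}

#' @export
print.ecoadl_schedule <- function(x, ...) {
  cat(sprintf(
    "<schedule %s (%s/%s): %d initiated, %d completed, walks %.1f/%.1f s>\n",
    x$participant_id, x$autonomy, x$diagnosis, x$initiated_count,
    x$completed_count, x$walk$single_s, x$walk$dual_s))
  invisible(x)
}

zone_centroid <- function(z) colMeans(z$polygon)

# staging point just outside a zone, in the free walking band below it
staging_point <- function(z) {
  c0 <- zone_centroid(z)
  ymin <- min(z$polygon[, 2])
  c(c0[1], if (ymin >= 3.5) 3.45 else 1.7)
}

#' Render a schedule into a track stream with ground truth
#'
#' Movement is piecewise linear at 1 m/s between zone staging points and
#' centroids; activity dwells hold the activity posture at the zone
#' centroid; walking tasks traverse the corridor with scripted foot
#' oscillation whose inter-feet-distance peaks mark the scripted steps.
#' Ground-truth event intervals are computed from the scripted (noiseless)
#' trajectory with the recognizer's interval semantics (frame grid, 0.5 s
#' gap merge, 2 s minimum prior zone duration), then jitter and dropout are
#' applied to the emitted stream only.
#'
#' @param schedule An `ecoadl_schedule`.
#' @param config An [cohort_config()].
#' @param rng Internal RNG stream; pass `seed` from user code.
#' @param seed Used when `rng` is missing.
#' @return List: `stream` ([track_stream()]), `truth` (event data.frame with
#'   `model_name`, `t_start`, `t_end`, `slot`, `completed`), `window_start`,
#'   `gait_truth` (per walk: scripted step count/times, corridor occupancy
#'   interval, walk duration, path length).
#' @export
render_track_stream <- function(schedule, config = cohort_config(),
                                rng = NULL, seed = 1) {
  if (is.null(rng)) rng <- new_rng(seed)
  fr <- config$frame_rate; dt <- 1 / fr
  zones <- config$zones
  az <- activity_zones(); ap <- activity_postures()
  quant <- function(s) max(1L, as.integer(round(s * fr)))

  segs <- list()
  add_seg <- function(p0, p1, dur_s, posture, block = NA_character_,
                      walk = FALSE) {
    segs[[length(segs) + 1L]] <<- list(
      p0 = p0, p1 = p1, n = quant(dur_s), posture = posture,
      block = block, walk = walk)
    p1
  }
  transit <- function(p0, p1, block = NA_character_) {
    d <- sqrt(sum((p1 - p0)^2))
    if (d < 1e-9) return(p0)
    add_seg(p0, p1, d / 1.0, "standing", block)   # 1 m/s
  }

  entry <- c(0.5, 1.7)
  w0 <- c(1.05, 0.7); w1 <- c(4.95, 0.7); wx <- c(5.5, 1.5)
  pos <- entry
  add_seg(pos, pos, 2, "standing")
  pos <- transit(pos, w0, block = "walk1")
  pos <- add_seg(pos, w1, schedule$walk$single_s, "standing",
                 block = "walk1", walk = TRUE)
  pos <- transit(pos, wx, block = "walk1")
  add_seg(pos, pos, 2, "standing")
  pos <- transit(pos, w1, block = "walk2")
  pos <- add_seg(pos, w0, schedule$walk$dual_s, "standing",
                 block = "walk2", walk = TRUE)
  pos <- transit(pos, entry, block = "walk2")
  add_seg(pos, pos, 2, "standing")
  n_prefix <- sum(vapply(segs, `[[`, integer(1), "n"))
  window_start <- n_prefix * dt

  for (si in schedule$perform_order) {
    m <- schedule$slots$model_name[si]
    z <- zones[[az[[m]]]]
    if (is.null(z)) stop("no zone for scheduled model '", m, "'")
    blk <- paste0("slot", si)
    s <- staging_point(z); cen <- zone_centroid(z)
    pos <- transit(pos, s, block = blk)
    pos <- transit(pos, cen, block = blk)
    pos <- add_seg(pos, pos, schedule$slots$dwell_s[si], ap[[m]],
                   block = blk)
    pos <- transit(pos, s, block = blk)
    pos <- add_seg(pos, pos, 1.5, "standing", block = blk)
  }
  transit(pos, c(3.0, 1.7))
  add_seg(c(3.0, 1.7), c(3.0, 1.7), 3, "standing")

  # ---- expand segments to frames ----
  n_total <- sum(vapply(segs, `[[`, integer(1), "n"))
  t <- (seq_len(n_total) - 1L) * dt
  x <- numeric(n_total); y <- numeric(n_total)
  posture <- character(n_total); block <- rep(NA_character_, n_total)
  lfx <- numeric(n_total); lfy <- numeric(n_total)
  rfx <- numeric(n_total); rfy <- numeric(n_total)
  gait_truth <- list()
  at <- 0L
  for (sg in segs) {
    idx <- at + seq_len(sg$n)
    frac <- (seq_len(sg$n) - 1L) / sg$n
    x[idx] <- sg$p0[1] + (sg$p1[1] - sg$p0[1]) * frac
    y[idx] <- sg$p0[2] + (sg$p1[2] - sg$p0[2]) * frac
    posture[idx] <- sg$posture
    block[idx] <- sg$block
    if (sg$walk) {
      dur <- sg$n * dt
      dist <- sqrt(sum((sg$p1 - sg$p0)^2))
      n_steps <- max(4L, as.integer(round(dur)))   # ~1 step per second
      amp <- max(MIN_STEP_SEPARATION_M + 0.05, dist / n_steps)
      period <- dur / n_steps
      trel <- frac * dur
      sep <- 0.1 + (amp - 0.1) * abs(sin(pi * trel / period))
      u <- (sg$p1 - sg$p0) / dist
      lfx[idx] <- x[idx] + u[1] * sep / 2; lfy[idx] <- y[idx] + u[2] * sep / 2
      rfx[idx] <- x[idx] - u[1] * sep / 2; rfy[idx] <- y[idx] - u[2] * sep / 2
      gait_truth[[length(gait_truth) + 1L]] <- list(
        block = sg$block, t_walk_start = t[idx[1]], duration_s = dur,
        n_steps = n_steps,
        step_times = t[idx[1]] + (seq_len(n_steps) - 0.5) * period,
        path_length_m = dist)
    } else {
      # feet at rest: constant narrow separation, below the step threshold
      lfx[idx] <- x[idx] + 0.05; lfy[idx] <- y[idx]
      rfx[idx] <- x[idx] - 0.05; rfy[idx] <- y[idx]
    }
    at <- at + sg$n
  }

  # ---- ground truth from the scripted (noiseless) trajectory ----
  truth <- truth_from_script(schedule, t, x, y, posture, block, zones, dt)
  gait_truth <- lapply(gait_truth, function(g) {
    row <- truth[truth$slot == g$block, , drop = FALSE]
    g$event_t_start <- if (nrow(row)) row$t_start[1] else NA_real_
    g$event_t_end <- if (nrow(row)) row$t_end[1] else NA_real_
    g$task_kind <- if (g$block == "walk1") "mono" else "dual"
    g
  })

  # ---- sensor noise ----
  present <- rep(TRUE, n_total)
  if (config$noise$dropout_prob > 0)
    present <- rng_binom(rng, n_total, 1 - config$noise$dropout_prob) == 1L
  js <- config$noise$position_jitter_sd_m
  if (js > 0) {
    x <- x + rng_norm(rng, n_total, 0, js)
    y <- y + rng_norm(rng, n_total, 0, js)
    lfx <- lfx + rng_norm(rng, n_total, 0, js)
    lfy <- lfy + rng_norm(rng, n_total, 0, js)
    rfx <- rfx + rng_norm(rng, n_total, 0, js)
    rfy <- rfy + rng_norm(rng, n_total, 0, js)
  }
  x[!present] <- NA; y[!present] <- NA; posture[!present] <- NA
  lfx[!present] <- NA; lfy[!present] <- NA
  rfx[!present] <- NA; rfy[!present] <- NA
  stream <- track_stream(
    data.frame(t = t, person_present = present, x = x, y = y,
               posture = posture, lfx = lfx, lfy = lfy,
               rfx = rfx, rfy = rfy),
    frame_rate = fr)
  list(stream = stream, truth = truth, window_start = window_start,
       gait_truth = gait_truth)
}

# Expected recognized intervals, computed block-locally on the scripted
# trajectory with the recognizer's semantics (merge dropout gaps, require
# posture overlap and >= 2 s of prior zone occupancy).
truth_from_script <- function(schedule, t, x, y, posture, block, zones, dt) {
  az <- activity_zones(); ap <- activity_postures()
  rows <- list()
  add_truth <- function(model, idx, zone_name, want_posture, slot_id,
                        completed) {
    inz <- point_in_polygon(x[idx], y[idx], zones[[zone_name]]$polygon)
    iv <- merge_close_intervals(runs_to_intervals(t[idx], inz, dt))
    zon <- intervals_active(iv, t[idx])
    ok <- zon & (posture[idx] == want_posture) &
      (streak_seconds(zon, dt) >= 2 - 1e-9)
    ev <- runs_to_intervals(t[idx], ok, dt)
    if (nrow(ev))
      rows[[length(rows) + 1L]] <<- cbind(
        model_name = model, ev, slot = slot_id, completed = completed)
  }
  add_truth("mono_walk", which(block == "walk1"),
            "WalkCorridor", "standing", "walk1", TRUE)
  add_truth("dual_walk", which(block == "walk2"),
            "WalkCorridor", "standing", "walk2", TRUE)
  for (si in schedule$perform_order) {
    m <- schedule$slots$model_name[si]
    blk <- paste0("slot", si)
    add_truth(m, which(block == blk), az[[m]], ap[[m]], blk,
              schedule$slots$status[si] == "completed")
  }
  if (!length(rows))
    return(data.frame(model_name = character(0), t_start = numeric(0),
                      t_end = numeric(0), slot = character(0),
                      completed = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$t_start), ]
}

#' Simulate a full cohort
#'
#' Draws one schedule per participant according to the configured joint
#' autonomy x diagnosis composition and renders each to a track stream.
#' All randomness derives from `config$seed`; the result is bit-reproducible.
#'
#' @param config An [cohort_config()].
#' @return An `ecoadl_cohort`: list of participants (each with `schedule`,
#'   `stream`, `truth`, `window_start`, `gait_truth`) plus a `labels`
#'   data.frame.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  joint <- config$joint
  ids <- character(0); auts <- character(0); diags <- character(0)
  for (i in seq_len(nrow(joint))) {
    auts <- c(auts, rep(joint$autonomy[i], joint$n[i]))
    diags <- c(diags, rep(joint$diagnosis[i], joint$n[i]))
  }
  n <- length(auts)
  ids <- sprintf("p%02d", seq_len(n))
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    rng <- new_rng(derive_seed(config$seed, i))
    sch <- generate_schedule(auts[i], diags[i], config, rng = rng,
                             participant_id = ids[i])
    rend <- render_track_stream(sch, config, rng = rng)
    participants[[i]] <- c(list(participant_id = ids[i], schedule = sch),
                           rend)
  }
  structure(list(participants = participants,
                 labels = data.frame(participant_id = ids,
                                     autonomy = auts, diagnosis = diags),
                 config = config),
            class = "ecoadl_cohort")
}

#' @export
print.ecoadl_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d participants (%s)>\n",
              length(x$participants),
              paste(sprintf("%s %d", names(table(x$labels$autonomy)),
                            table(x$labels$autonomy)), collapse = ", ")))
  invisible(x)
}

#' Draw a profile-level feature vector directly
#'
#' Bypasses rendering for classifier experiments: independent Gaussian
#' draws per feature from the class-conditional calibration.
#'
#' @param class_label Class to draw from.
#' @param calibration data.frame with `class`, `feature`, `mean`, `sd`.
#' @param rng Internal RNG stream; or pass `seed`.
#' @param seed Used when `rng` is missing.
#' @return Named numeric feature vector.
#' @export
draw_feature_profile <- function(class_label, calibration, rng = NULL,
                                 seed = 1) {
  if (is.null(rng)) rng <- new_rng(seed)
  rows <- calibration[calibration$class == class_label, , drop = FALSE]
  if (!nrow(rows)) stop("unknown class '", class_label, "' in calibration")
  v <- rng_norm(rng, nrow(rows), rows$mean, rows$sd)
  names(v) <- rows$feature
  v
}

#' Simulate a labeled profile table for classifier experiments
#'
#' @param n_per_class Named integer vector: class -> row count.
#' @param class_means Named list: class -> numeric vector of feature means
#'   (all classes must share feature names/length).
#' @param sd Common feature SD.
#' @param seed Integer seed.
#' @return List with `x` (feature data.frame) and `y` (labels).
#' @export
simulate_profile_table <- function(n_per_class, class_means, sd = 1,
                                   seed = 1) {
  rng <- new_rng(seed)
  feats <- names(class_means[[1]])
  if (is.null(feats))
    feats <- paste0("f", seq_along(class_means[[1]]))
  xs <- list(); ys <- character(0)
  for (cl in names(n_per_class)) {
    mu <- class_means[[cl]]
    n <- n_per_class[[cl]]
    m <- matrix(rng_norm(rng, n * length(mu), rep(mu, each = n), sd),
                nrow = n)
    colnames(m) <- feats
    xs[[cl]] <- m
    ys <- c(ys, rep(cl, n))
  }
  list(x = as.data.frame(do.call(rbind, xs)), y = ys)
}
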