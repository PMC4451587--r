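#' Gait analysis of walking-task segments
#'
#' The directed physical tasks (single-task walk, and the dual task of
#' walking while counting backwards) are analyzed kinematically from the
#' track-stream slice covered by the recognized walking event: steps are
#' detected from the inter-feet distance signal, and duration, cadence,
#' per-step lengths, stride length, path length, average speed and tracking
#' gaps are derived.
#'
#' @name gait_analysis
NULL

MIN_STEP_SEPARATION_M <- 0.15  # peak height a step must exceed
MIN_STEP_INTERVAL_S <- 0.3     # two steps cannot be closer than this

#' Build a gait segment
#'
#' @param stream_slice [track_stream()] restricted to one walking task.
#' @param task_kind `"mono"` or `"dual"`.
#' @return An `ecoadl_gait_segment`.
#' @export
gait_segment <- function(stream_slice, task_kind = c("mono", "dual")) {
  task_kind <- match.arg(task_kind)
  stopifnot(inherits(stream_slice, "ecoadl_track_stream"))
  if (!nrow(stream_slice)) stop("gait segment is empty")
  structure(list(stream = stream_slice, task_kind = task_kind),
            class = "ecoadl_gait_segment")
}

foot_coverage <- function(stream) {
  pres <- stream$person_present
  if (!any(pres)) return(0)
  has_feet <- !is.na(stream$lfx) & !is.na(stream$lfy) &
    !is.na(stream$rfx) & !is.na(stream$rfy)
  mean(has_feet[pres])
}

#' Detect steps in a walking segment
#'
#' Steps are placed at local maxima of the inter-feet Euclidean distance:
#' at mid-stance the feet are together, at each step completion they are
#' maximally apart. A peak counts as a step when it exceeds
#' `min_step_separation_m`, and two retained steps must be at least
#' `min_step_interval_s` apart (the larger peak wins).
#'
#' When foot positions are missing in more than 20% of present frames the
#' foot signal is unreliable; either request `method = "centroid"` (local
#' minima of centroid speed, the single-camera fallback) or fix the tracker
#' output.
#'
#' @param segment An [gait_segment()].
#' @param method `"feet"` (default) or `"centroid"`.
#' @param min_step_separation_m,min_step_interval_s Detection thresholds.
#' @return data.frame with columns `t`, `x`, `y` (centroid at step instant).
#' @export
detect_steps <- function(segment, method = c("feet", "centroid"),
                         min_step_separation_m = MIN_STEP_SEPARATION_M,
                         min_step_interval_s = MIN_STEP_INTERVAL_S) {
  method <- match.arg(method)
  st <- segment$stream
  pres <- st$person_present
  if (method == "feet") {
    if (foot_coverage(st) < 0.8)
      stop("foot positions missing in > 20% of frames; ",
           "use method = \"centroid\" (centroid-speed fallback) instead")
    sig <- sqrt((st$lfx - st$rfx)^2 + (st$lfy - st$rfy)^2)
    peaks <- local_peaks(st$t, sig, keep = sig > min_step_separation_m)
  } else {
    dt <- diff(st$t)
    spd <- c(NA, sqrt(diff(st$x)^2 + diff(st$y)^2) / dt)
    # step instants at speed minima (foot planted): peaks of -speed
    peaks <- local_peaks(st$t, -spd, keep = !is.na(spd))
  }
  peaks <- peaks[pres[peaks]]
  peaks <- enforce_min_interval(st$t, peaks,
                                if (method == "feet")
                                  sqrt((st$lfx - st$rfx)^2 +
                                         (st$lfy - st$rfy)^2)
                                else rep(1, nrow(st)),
                                min_step_interval_s)
  data.frame(t = st$t[peaks], x = st$x[peaks], y = st$y[peaks])
}

# indices of strict-left / weak-right local maxima satisfying keep
local_peaks <- function(t, sig, keep) {
  n <- length(sig)
  if (n < 3L) return(integer(0))
  sig[is.na(sig)] <- -Inf
  idx <- which(sig[2:(n - 1)] > sig[1:(n - 2)] &
                 sig[2:(n - 1)] >= sig[3:n]) + 1L
  keep[is.na(keep)] <- FALSE
  idx[keep[idx]]
}

enforce_min_interval <- function(t, idx, height, min_s) {
  if (length(idx) < 2L) return(idx)
  ord <- idx[order(-height[idx], t[idx])]  # strongest peaks first
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(t[i] - t[kept]) >= min_s))
      kept <- c(kept, i)
  sort(kept)
}

#' Compute gait parameters for a walking segment
#'
#' @param segment An [gait_segment()].
#' @param steps Step events from [detect_steps()].
#' @return An `ecoadl_gait_parameters` list:
#'   `total_duration_s`, `n_steps`, `cadence` (steps/s), `step_lengths_m`
#'   (centroid displacement between consecutive step instants),
#'   `stride_length_m` (two consecutive steps, i.e. `2 * mean(step length)`),
#'   `distance_traveled_m` (summed centroid path over present frames),
#'   `avg_speed_mps`, `gap_duration_s` (within-task time with no person
#'   detection), and `step_len_sd_m` / `step_len_max_m` / `step_len_min_m`
#'   (0 when fewer than two step lengths).
#' @export
compute_gait_parameters <- function(segment, steps = detect_steps(segment)) {
  st <- segment$stream
  dt <- frame_dt(st)
  span <- (max(st$t) + dt) - min(st$t)
  if (span <= 0) stop("zero-duration gait segment")
  if (nrow(steps) &&
      (min(steps$t) < min(st$t) || max(steps$t) > max(st$t) + 1e-9))
    stop("step events outside segment time bounds")
  pres <- which(st$person_present)
  dist <- if (length(pres) >= 2L)
    sum(sqrt(diff(st$x[pres])^2 + diff(st$y[pres])^2)) else 0
  gap <- span - length(pres) * dt
  n <- nrow(steps)
  step_len <- if (n >= 2L)
    sqrt(diff(steps$x)^2 + diff(steps$y)^2) else numeric(0)
  structure(list(
    task_kind = segment$task_kind,
    total_duration_s = span,
    n_steps = n,
    cadence = n / span,
    step_lengths_m = step_len,
    stride_length_m = if (length(step_len)) 2 * mean(step_len) else 0,
    distance_traveled_m = dist,
    avg_speed_mps = dist / span,
    gap_duration_s = max(0, gap),
    step_len_sd_m = if (length(step_len) >= 2L) stats::sd(step_len) else 0,
    step_len_max_m = if (length(step_len)) max(step_len) else 0,
    step_len_min_m = if (length(step_len)) min(step_len) else 0),
    class = "ecoadl_gait_parameters")
}

#' @export
print.ecoadl_gait_parameters <- function(x, ...) {
  cat(sprintf(
    "<gait %s: %.1f s, %d steps, cadence %.2f /s, speed %.2f m/s, gap %.1f s>\n",
    x$task_kind, x$total_duration_s, x$n_steps, x$cadence, x$avg_speed_mps,
    x$gap_duration_s))
  invisible(x)
}

# flatten to the profile feature columns for one task ("single"/"dual")
gait_feature_row <- function(gp, prefix) {
  v <- c(total_duration = gp$total_duration_s,
         gap_duration = gp$gap_duration_s,
         number_of_steps = gp$n_steps,
         cadence = gp$cadence,
         average_steps = if (length(gp$step_lengths_m))
           mean(gp$step_lengths_m) else 0,
         standard_deviation_steps = gp$step_len_sd_m,
         max_steps = gp$step_len_max_m,
         min_steps = gp$step_len_min_m,
         stride_length = gp$stride_length_m,
         distance_traveled = gp$distance_traveled_m,
         speed_average_from_centroid_information = gp$avg_speed_mps)
  names(v) <- paste0(prefix, "_task_", names(v))
  v
}
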