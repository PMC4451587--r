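#' Behavioral profiles and autonomy staging
#'
#' The behavioral profile is the per-participant feature vector the pipeline
#' hands to the classifiers: per-activity frequency, total duration,
#' omissions and repetitions against the protocol's expected unit counts,
#' the aggregate counts of initiated and completed activity units, the gait
#' parameters of the single and dual walking task, and age.
#'
#' @name behavior_profile
NULL

#' Build one participant's behavioral profile
#'
#' Frequencies are counts of recognized intervals per model (clipped to the
#' protocol window); durations are summed interval lengths. Repetitions and
#' omissions are computed against each model's expected unit count:
#' `repetitions = max(0, frequency - expected)`,
#' `omissions = max(0, expected - frequency)`. An activity *unit* (one
#' expected occurrence) is initiated when a recognized interval exists for
#' it (`initiated = sum over models of min(frequency, expected)`), and
#' completed when the interval additionally lasts at least the model's
#' minimum completion duration — the automated stand-in for the clinician's
#' quality verification.
#'
#' @param events Recognized event data.frame (`model_name,t_start,t_end`).
#' @param gait Named list with elements `mono` and `dual`, each an
#'   `ecoadl_gait_parameters` (or `NULL` when a walk was not recognized).
#' @param proto An `ecoadl_protocol`.
#' @param age Age in years.
#' @param participant_id Identifier.
#' @param window_start Start of the activity window in stream seconds
#'   (events are clipped to `[window_start, window_start + window_s)`).
#' @param diagnosis,autonomy Optional ground-truth labels to carry along.
#' @return An `ecoadl_profile` list; see [profile_feature_row()] for the
#'   flat numeric feature vector.
#' @export
build_profile <- function(events, gait, proto, age,
                          participant_id = "p1", window_start = 0,
                          diagnosis = NA_character_,
                          autonomy = NA_character_) {
  units <- proto$activity_units
  known <- units$model_name
  act_events <- events[events$model_name %in% known, , drop = FALSE]
  extra <- setdiff(unique(events$model_name),
                   c(known, "mono_walk", "dual_walk", "walking_task"))
  if (length(extra))
    warning("events for models outside the protocol ignored: ",
            paste(extra, collapse = ", "))
  w0 <- window_start; w1 <- window_start + proto$window_s
  if (nrow(act_events)) {
    act_events$t_start <- pmax(act_events$t_start, w0)
    act_events$t_end <- pmin(act_events$t_end, w1)
    act_events <- act_events[act_events$t_end > act_events$t_start, ,
                             drop = FALSE]
  }
  per <- lapply(seq_len(nrow(units)), function(i) {
    m <- units$model_name[i]
    exp_n <- units$expected_count[i]
    ev <- act_events[act_events$model_name == m, , drop = FALSE]
    durs <- ev$t_end - ev$t_start
    min_s <- completion_min_for(proto, m)
    qualifying <- sum(durs >= min_s)
    freq <- nrow(ev)
    data.frame(model_name = m, expected = exp_n, frequency = freq,
               duration_s = sum(durs),
               omissions = max(0L, exp_n - freq),
               repetitions = max(0L, freq - exp_n),
               initiated_units = min(freq, exp_n),
               completed_units = min(qualifying, exp_n),
               completed = freq >= exp_n & sum(durs) >= min_s)
  })
  per <- do.call(rbind, per)
  structure(list(
    participant_id = participant_id,
    age = age,
    activities = per,
    activities_initiated = sum(per$initiated_units),
    activities_completed = sum(per$completed_units),
    gait = gait,
    diagnosis = diagnosis,
    autonomy = autonomy),
    class = "ecoadl_profile")
}

#' @export
print.ecoadl_profile <- function(x, ...) {
  cat(sprintf(
    "<profile %s: age %.0f, initiated %d, completed %d (%s autonomy)>\n",
    x$participant_id, x$age, x$activities_initiated, x$activities_completed,
    stage_autonomy(x$activities_completed)))
  invisible(x)
}

#' Stage autonomy from the completed-activity count
#'
#' Cut-offs from the cumulative-frequency staging of completed activities:
#' 8 or more completed units is a good performance, 4 to 7 intermediate,
#' 3 or fewer poor.
#'
#' @param activities_completed Integer count(s) in `[0, 13]`.
#' @return Character vector over `{"good", "intermediate", "poor"}`.
#' @export
stage_autonomy <- function(activities_completed) {
  if (any(activities_completed < 0 | activities_completed > 13, na.rm = TRUE))
    stop("activities_completed must be between 0 and 13")
  ifelse(activities_completed >= 8, "good",
         ifelse(activities_completed >= 4, "intermediate", "poor"))
}

#' Flatten a profile to its numeric feature row
#'
#' Column names match the classifier feature vocabulary, e.g.
#' `single_task_total_duration`, `dual_task_max_steps`,
#' `person_using_pharmacybasket_frequency_of_event`,
#' `person_reading_inchairreadingtable_duration_of_event`.
#'
#' @param profile An `ecoadl_profile`.
#' @return Named numeric vector.
#' @export
profile_feature_row <- function(profile) {
  prefixes <- activity_feature_prefixes()
  act <- profile$activities
  av <- numeric(0)
  for (i in seq_len(nrow(act))) {
    pre <- prefixes[act$model_name[i]]
    if (is.na(pre)) pre <- paste0("person_", act$model_name[i])
    v <- c(act$frequency[i], act$duration_s[i], act$omissions[i],
           act$repetitions[i])
    names(v) <- paste0(pre, c("_frequency_of_event", "_duration_of_event",
                              "_omissions", "_repetitions"))
    av <- c(av, v)
  }
  zero_gait <- structure(list(
    task_kind = "mono", total_duration_s = 0, n_steps = 0L, cadence = 0,
    step_lengths_m = numeric(0), stride_length_m = 0,
    distance_traveled_m = 0, avg_speed_mps = 0, gap_duration_s = 0,
    step_len_sd_m = 0, step_len_max_m = 0, step_len_min_m = 0),
    class = "ecoadl_gait_parameters")
  g_mono <- if (is.null(profile$gait$mono)) zero_gait else profile$gait$mono
  g_dual <- if (is.null(profile$gait$dual)) zero_gait else profile$gait$dual
  c(age = profile$age,
    gait_feature_row(g_mono, "single"),
    gait_feature_row(g_dual, "dual"),
    av,
    activities_initiated = profile$activities_initiated,
    activities_completed = profile$activities_completed)
}

#' Assemble a cohort feature table
#'
#' @param profiles List of `ecoadl_profile` objects.
#' @return data.frame, one row per participant: `participant_id`, all
#'   numeric features, `diagnosis`, `autonomy` (staged from completed count
#'   when not provided).
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    fr <- profile_feature_row(p)
    aut <- if (is.na(p$autonomy)) stage_autonomy(p$activities_completed)
      else p$autonomy
    cbind(data.frame(participant_id = p$participant_id),
          as.data.frame(as.list(fr), check.names = TRUE),
          data.frame(diagnosis = p$diagnosis, autonomy = aut))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write profile tables as CSV
#'
#' Column order is not significant: the header names identify features, so a
#' shuffled file parses to the same table.
#'
#' @param path File path.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  lead <- intersect("participant_id", names(df))
  tail <- intersect(c("diagnosis", "autonomy"), names(df))
  feats <- sort(setdiff(names(df), c(lead, tail)))
  df[c(lead, feats, tail)]
}

#' @param table Profile data.frame.
#' @rdname read_profiles
#' @export
write_profiles <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
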