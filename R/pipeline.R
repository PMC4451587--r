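#' End-to-end pipeline
#'
#' `run_full_pipeline()` chains simulate -> recognize -> gait -> profile ->
#' classify -> evaluate -> stats, writing every artifact under an output
#' directory plus a manifest JSON (seed, version, per-file MD5 hashes).
#' Two runs with the same configuration produce byte-identical payloads.
#'
#' @name cli_io
NULL

#' Recognize events for one participant stream
#'
#' Primitive-state detection, composite recognition, and protocol-order
#' relabeling of the corridor walking tasks.
#'
#' @param stream A [track_stream()].
#' @param zones Scene zones. @param models Event-model library.
#' @return Event data.frame (`model_name`, `t_start`, `t_end`).
#' @export
recognize_stream <- function(stream, zones = default_scene(),
                             models = default_event_models()) {
  prim <- detect_primitive_states(stream, zones)
  ev <- recognize_composite_events(models, prim,
                                   frame_rate = attr(stream, "frame_rate"))
  label_walk_tasks(ev)
}

#' Gait parameters from recognized walking events
#'
#' The recognized walking interval starts after the walking model's 2 s
#' prior-occupancy constraint is met; the analyzed slice is therefore
#' extended 2 s backwards to cover the full corridor occupancy.
#'
#' @param stream A [track_stream()]. @param events Recognized events.
#' @param latency_s Recognition latency to rewind (default 2).
#' @return List with elements `mono` and `dual` (each
#'   `ecoadl_gait_parameters` or `NULL` when that walk was not recognized).
#' @export
gait_from_events <- function(stream, events, latency_s = 2) {
  out <- list(mono = NULL, dual = NULL)
  for (task in c("mono", "dual")) {
    ev <- events[events$model_name == paste0(task, "_walk"), , drop = FALSE]
    if (!nrow(ev)) next
    sl <- slice_stream(stream, ev$t_start[1] - latency_s, ev$t_end[1])
    if (!nrow(sl)) next
    seg <- gait_segment(sl, task)
    out[[task]] <- compute_gait_parameters(seg, detect_steps(seg))
  }
  out
}

#' Process one participant end to end
#'
#' @param stream Track stream. @param age Age in years.
#' @param zones,models,proto Scene, model library, protocol.
#' @param window_start Start of the activity window (seconds).
#' @param participant_id,diagnosis,autonomy Identifiers/labels carried into
#'   the profile.
#' @return List with `events` and `profile`.
#' @export
process_participant <- function(stream, age, zones = default_scene(),
                                models = default_event_models(),
                                proto = default_protocol(),
                                window_start = 0, participant_id = "p1",
                                diagnosis = NA_character_,
                                autonomy = NA_character_) {
  events <- recognize_stream(stream, zones, models)
  gait <- gait_from_events(stream, events)
  prof <- build_profile(events, gait, proto, age,
                        participant_id = participant_id,
                        window_start = window_start,
                        diagnosis = diagnosis, autonomy = autonomy)
  list(events = events, profile = prof)
}

pipeline_log <- function(quiet, stage, msg)
  if (!quiet) message(sprintf("[%s] %s", stage, msg))

run_stage <- function(stage, quiet, expr) {
  pipeline_log(quiet, stage, "start")
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' @param out_dir Output directory (created if needed).
#' @param config An [cohort_config()].
#' @param k Cross-validation folds.
#' @param quiet Suppress progress messages.
#' @return The manifest (invisibly also written to `manifest.json`):
#'   seed, counts, stage outputs, file hashes.
#' @export
run_full_pipeline <- function(out_dir, config = cohort_config(), k = 20,
                              quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)

  cohort <- run_stage("simulate", quiet, simulate_cohort(config))
  run_stage("simulate-io", quiet, {
    dir.create(fp("tracks"), showWarnings = FALSE)
    for (p in cohort$participants)
      write_tracks(p$stream, fp("tracks", paste0(p$participant_id, ".csv")))
    truth_all <- do.call(rbind, lapply(cohort$participants, function(p)
      cbind(participant_id = p$participant_id,
            p$truth[c("model_name", "t_start", "t_end")])))
    utils::write.csv(truth_all, fp("truth_events.csv"), row.names = FALSE)
    utils::write.csv(cohort$labels, fp("labels.csv"), row.names = FALSE)
    write_zones(config$zones, fp("zones.json"))
    write_event_models(config$models, fp("models.json"))
    write_protocol(config$proto, fp("protocol.json"))
  })

  results <- run_stage("recognize", quiet, lapply(
    cohort$participants, function(p)
      process_participant(p$stream, age = p$schedule$age,
                          zones = config$zones, models = config$models,
                          proto = config$proto,
                          window_start = p$window_start,
                          participant_id = p$participant_id,
                          diagnosis = p$schedule$diagnosis)))

  run_stage("recognize-io", quiet, {
    ev_all <- do.call(rbind, lapply(results, function(r)
      cbind(participant_id = r$profile$participant_id,
            r$events[c("model_name", "t_start", "t_end")])))
    utils::write.csv(ev_all, fp("recognized_events.csv"), row.names = FALSE)
  })

  profiles <- run_stage("profile", quiet, {
    tab <- profile_table(lapply(results, `[[`, "profile"))
    write_profiles(tab, fp("profiles.csv"))
    tab
  })

  evaluation <- run_stage("evaluate", quiet, {
    rec <- do.call(rbind, lapply(results, `[[`, "events"))
    tru <- do.call(rbind, lapply(cohort$participants, function(p) p$truth))
    # pool per participant so cross-participant intervals never match
    per <- lapply(seq_along(results), function(i)
      evaluate_detection(results[[i]]$events,
                         cohort$participants[[i]]$truth, threshold = 0.5))
    agg <- do.call(rbind, per)
    agg <- stats::aggregate(cbind(tp, fp, fn) ~ model_name, agg, sum)
    agg$precision <- ifelse(agg$tp + agg$fp > 0,
                            agg$tp / (agg$tp + agg$fp), NA)
    agg$recall <- ifelse(agg$tp + agg$fn > 0,
                         agg$tp / (agg$tp + agg$fn), NA)
    utils::write.csv(agg, fp("detection_evaluation.csv"), row.names = FALSE)
    agg
  })

  classification <- run_stage("classify", quiet, {
    res <- list()
    for (task in c("autonomy", "diagnosis")) {
      feats <- default_feature_set(task)
      y <- if (task == "autonomy")
        stage_autonomy(profiles$activities_completed)
      else cohort$labels$diagnosis
      cv <- cross_validate(profiles, y, features = feats, k = k,
                           seed = config$seed)
      res[[task]] <- list(features = feats, k = cv$k,
                          accuracy = cv$accuracy,
                          n_correct = cv$n_correct,
                          n_incorrect = cv$n_incorrect,
                          confusion = as.data.frame(cv$confusion))
    }
    jsonlite::write_json(res, fp("classification.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  stats_out <- run_stage("stats", quiet, {
    feats <- c("activities_initiated", "activities_completed",
               "single_task_total_duration", "dual_task_total_duration",
               "age")
    gc <- group_comparison_table(profiles, cohort$labels$diagnosis,
                                 features = feats)
    utils::write.csv(cbind(comparison = rownames(gc$formatted),
                           gc$formatted),
                     fp("group_comparisons.csv"), row.names = FALSE)
    ct <- correlation_table(profiles,
                            c("activities_initiated",
                              "activities_completed"),
                            "age")
    utils::write.csv(cbind(feature = rownames(ct$formatted), ct$formatted),
                     fp("correlations.csv"), row.names = FALSE)
    list(comparisons = gc$results, correlations = ct$results)
  })

  manifest <- run_stage("manifest", quiet, {
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.json"))
    man <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("ecoadl")),
      n_participants = length(cohort$participants),
      stages = c("simulate", "recognize", "gait", "profile", "classify",
                 "evaluate", "stats"),
      classification = lapply(classification, function(r)
        r[c("accuracy", "n_correct", "n_incorrect")]),
      files = lapply(files, function(f)
        list(path = f,
             md5 = unname(tools::md5sum(file.path(out_dir, f))))))
    jsonlite::write_json(man, fp("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    man
  })
  invisible(list(manifest = manifest, profiles = profiles,
                 evaluation = evaluation, classification = classification,
                 stats = stats_out, cohort = cohort, results = results))
}

#' Parse-write-parse round trip
#'
#' Reads a file in one of the supported formats, rewrites it, reparses and
#' checks equality of the parsed objects.
#'
#' @param path Input file.
#' @param type One of `"tracks"`, `"zones"`, `"events"`, `"profiles"`,
#'   `"models"`, `"protocol"`.
#' @return The parsed object, invisibly; errors if the round trip is not
#'   faithful.
#' @export
roundtrip <- function(path, type = c("tracks", "zones", "events",
                                     "profiles", "models", "protocol")) {
  type <- match.arg(type)
  io <- switch(type,
    tracks = list(r = read_tracks, w = write_tracks),
    zones = list(r = read_zones, w = write_zones),
    events = list(r = read_events, w = write_events),
    profiles = list(r = read_profiles, w = write_profiles),
    models = list(r = read_event_models, w = write_event_models),
    protocol = list(r = read_protocol, w = write_protocol))
  obj <- io$r(path)
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
  on.exit(unlink(tmp))
  io$w(obj, tmp)
  obj2 <- io$r(tmp)
  if (!isTRUE(all.equal(obj, obj2, check.attributes = FALSE)))
    stop("round trip not faithful for ", path)
  invisible(obj)
}

parse_cli_args <- function(args) {
  opts <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (key %in% c("quiet")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        if (i == length(args)) stop("missing value for --", key)
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      positional <- c(positional, a); i <- i + 1L
    }
  }
  list(opts = opts, positional = positional)
}

cli_config <- function(opts) {
  seed <- as.integer(opts$seed %||% 1L)
  noise <- list(dropout_prob = as.numeric(opts[["dropout"]] %||% 0),
                position_jitter_sd_m = as.numeric(opts[["jitter"]] %||% 0))
  cohort_config(noise = noise, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate`, `recognize`, `evaluate`, `classify`, `stats`,
#' `run-all`, `roundtrip`. Common flags: `--seed`, `--out`, `--quiet`,
#' `--dropout`, `--jitter`; `classify` takes `--task {autonomy|diagnosis}`,
#' `--folds`, `--features {paper|select|all}`. A thin Rscript front-end is
#' installed at `inst/cli/ecoadl.R`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit code, invisibly: 0 success, 1 validation error, 2 stage
#'   failure.
#' @export
ecoadl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: ecoadl <simulate|recognize|evaluate|classify|stats|",
            "run-all|roundtrip> [--seed N] [--out DIR] ...")
    return(invisible(1L))
  }
  cmd <- args[1]
  parsed <- tryCatch(parse_cli_args(args[-1]),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    message("argument error: ", conditionMessage(parsed))
    return(invisible(1L))
  }
  opts <- parsed$opts
  quiet <- isTRUE(opts$quiet)
  code <- tryCatch({
    switch(cmd,
      "run-all" = {
        out <- opts$out %||% "ecoadl_out"
        run_full_pipeline(out, cli_config(opts),
                          k = as.integer(opts$folds %||% 20), quiet = quiet)
        0L
      },
      "simulate" = {
        out <- opts$out %||% "ecoadl_out"
        cohort <- simulate_cohort(cli_config(opts))
        dir.create(file.path(out, "tracks"), recursive = TRUE,
                   showWarnings = FALSE)
        for (p in cohort$participants)
          write_tracks(p$stream, file.path(
            out, "tracks", paste0(p$participant_id, ".csv")))
        truth_all <- do.call(rbind, lapply(cohort$participants, function(p)
          cbind(participant_id = p$participant_id,
                p$truth[c("model_name", "t_start", "t_end")])))
        utils::write.csv(truth_all, file.path(out, "truth_events.csv"),
                         row.names = FALSE)
        utils::write.csv(cohort$labels, file.path(out, "labels.csv"),
                         row.names = FALSE)
        pipeline_log(quiet, "simulate",
                     sprintf("%d participants -> %s",
                             length(cohort$participants), out))
        0L
      },
      "recognize" = {
        stream <- read_tracks(opts$tracks)
        zones <- if (is.null(opts$zones)) default_scene()
          else read_zones(opts$zones)
        models <- if (is.null(opts$models)) default_event_models()
          else read_event_models(opts$models)
        ev <- recognize_stream(stream, zones, models)
        write_events(ev, opts$out %||% "events.csv")
        0L
      },
      "evaluate" = {
        rec <- read_events(opts$recognized)
        tru <- read_events(opts$truth)
        res <- evaluate_detection(rec, tru,
                                  as.numeric(opts$threshold %||% 0.5))
        utils::write.csv(res, opts$out %||% "evaluation.csv",
                         row.names = FALSE)
        0L
      },
      "classify" = {
        tab <- read_profiles(opts$profiles)
        task <- opts$task %||% "autonomy"
        y <- tab[[task]]
        if (is.null(y)) stop("profiles lack a '", task, "' label column")
        mode <- opts$features %||% "paper"
        feats <- switch(mode,
          paper = default_feature_set(task),
          all = setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                        "participant_id"),
          select = NULL,
          stop("unknown --features mode '", mode, "'"))
        k <- as.integer(opts$folds %||% 20)
        seed <- as.integer(opts$seed %||% 1L)
        if (is.null(feats)) {
          sel <- select_features_best_first(
            tab, y, features = setdiff(
              names(tab)[vapply(tab, is.numeric, logical(1))],
              "participant_id"),
            k = k, seed = seed)
          feats <- sel$selected_features
        }
        cv <- cross_validate(tab, y, features = feats, k = k, seed = seed)
        jsonlite::write_json(
          list(task = task, features = feats, k = cv$k, seed = cv$seed,
               accuracy = cv$accuracy, n_correct = cv$n_correct,
               n_incorrect = cv$n_incorrect,
               confusion = as.data.frame(cv$confusion)),
          opts$out %||% "classification.json",
          auto_unbox = TRUE, digits = NA)
        0L
      },
      "stats" = {
        tab <- read_profiles(opts$profiles)
        group_col <- opts$group %||% "diagnosis"
        feats <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                         "participant_id")
        gc <- group_comparison_table(tab, tab[[group_col]],
                                     features = feats)
        utils::write.csv(gc$results, opts$out %||% "stats.csv",
                         row.names = FALSE)
        0L
      },
      "roundtrip" = {
        roundtrip(parsed$positional[1], opts$type %||% "tracks")
        0L
      },
      {
        message("unknown subcommand '", cmd, "'")
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^stage '", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}
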