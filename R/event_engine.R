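#' Constraint-based event recognition
#'
#' Activities are modeled in two layers. *Primitive states* are per-frame
#' predicates computed directly from the track stream: `Person_in_zone_<Z>`
#' (the centroid lies inside zone `Z`) and `Person_<posture>`. *Composite
#' events* combine named components (primitive states or other event models)
#' under temporal constraints; the event is recognized on every maximal time
#' span where all constraints hold simultaneously.
#'
#' All intervals are half-open `[t_start, t_end)` in seconds, and constraint
#' evaluation happens on the discrete frame grid, which makes recognition
#' exactly reproducible by an instant-wise brute-force scan.
#'
#' @name event_engine
NULL

GAP_MERGE_S <- 0.5  # same-state runs closer than this are one tracking run

# Run-length encode a logical vector over frame times into half-open
# intervals; each TRUE frame covers [t, t + dt).
runs_to_intervals <- function(times, active, dt) {
  active[is.na(active)] <- FALSE
  if (!length(active) || !any(active))
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(t_start = times[starts[keep]],
             t_end = times[ends[keep]] + dt)
}

# Merge same-state intervals separated by gaps shorter than gap_merge_s
# (tracking dropout produces 1-2 frame holes that are not real state exits).
merge_close_intervals <- function(iv, gap_merge_s = GAP_MERGE_S) {
  if (nrow(iv) < 2L) return(iv)
  iv <- iv[order(iv$t_start), , drop = FALSE]
  out_s <- iv$t_start[1]; out_e <- iv$t_end[1]
  res_s <- numeric(0); res_e <- numeric(0)
  for (i in 2:nrow(iv)) {
    if (iv$t_start[i] - out_e < gap_merge_s) {
      out_e <- max(out_e, iv$t_end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- iv$t_start[i]; out_e <- iv$t_end[i]
    }
  }
  data.frame(t_start = c(res_s, out_s), t_end = c(res_e, out_e))
}

#' Detect primitive states
#'
#' Scans the stream frame by frame and emits maximal intervals for every
#' zone-occupancy state (`Person_in_zone_<name>`) and every posture state
#' (`Person_standing` etc.). Runs of the same state separated by less than
#' `gap_merge_s` seconds (tracking dropout) are merged.
#'
#' @param stream A [track_stream()].
#' @param zones Named list of [zone()] objects.
#' @param gap_merge_s Merge tolerance in seconds (default 0.5).
#' @return data.frame with columns `state_name`, `t_start`, `t_end`.
#' @export
detect_primitive_states <- function(stream, zones, gap_merge_s = GAP_MERGE_S) {
  stopifnot(inherits(stream, "ecoadl_track_stream"))
  zones <- as_zone_list(zones)
  dt <- frame_dt(stream)
  present <- stream$person_present
  if (!nrow(stream) || !any(present))
    return(data.frame(state_name = character(0),
                      t_start = numeric(0), t_end = numeric(0)))
  pieces <- list()
  for (z in zones) {
    inz <- present & point_in_polygon(stream$x, stream$y, z$polygon)
    iv <- merge_close_intervals(runs_to_intervals(stream$t, inz, dt),
                                gap_merge_s)
    if (nrow(iv))
      pieces[[length(pieces) + 1L]] <-
        cbind(state_name = paste0("Person_in_zone_", z$name), iv)
  }
  for (p in c("standing", "sitting", "bending")) {
    isp <- present & !is.na(stream$posture) & stream$posture == p
    iv <- merge_close_intervals(runs_to_intervals(stream$t, isp, dt),
                                gap_merge_s)
    if (nrow(iv))
      pieces[[length(pieces) + 1L]] <-
        cbind(state_name = paste0("Person_", p), iv)
  }
  if (!length(pieces))
    return(data.frame(state_name = character(0),
                      t_start = numeric(0), t_end = numeric(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$state_name, out$t_start), ]
}

as_zone_list <- function(zones) {
  if (inherits(zones, "ecoadl_zone")) zones <- list(zones)
  lapply(zones, function(z) {
    if (!inherits(z, "ecoadl_zone")) stop("zones must be zone() objects")
    z
  })
}

#' Declare a composite event model
#'
#' @param name Model identifier.
#' @param components Named character vector: alias -> primitive state name or
#'   another model name (nesting allowed up to depth 4).
#' @param constraints List of constraints. Supported kinds:
#'   \describe{
#'     \item{`overlap`}{`list(kind = "overlap", components = c("c1", "c2"))` —
#'       all listed components are active at the same instant.}
#'     \item{`min_duration_before`}{`list(kind = "min_duration_before",
#'       component = "c1", min_s = 2)` — the component has been continuously
#'       active for at least `min_s` seconds at the evaluated instant.}
#'   }
#' @return An `ecoadl_event_model`.
#' @export
event_model <- function(name, components, constraints = list()) {
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("model '", name, "': components must be a named vector")
  if (anyDuplicated(names(components)))
    stop("model '", name, "': duplicated component aliases")
  for (cn in constraints) {
    if (!cn$kind %in% c("overlap", "min_duration_before"))
      stop("model '", name, "': unknown constraint kind '", cn$kind, "'")
    refs <- if (cn$kind == "overlap") cn$components else cn$component
    bad <- setdiff(refs, names(components))
    if (length(bad))
      stop("model '", name, "': constraint references undeclared component(s) ",
           paste(bad, collapse = ", "))
    if (cn$kind == "overlap" && length(cn$components) < 2L)
      stop("model '", name, "': overlap needs >= 2 components")
    if (cn$kind == "min_duration_before" &&
        (!is.numeric(cn$min_s) || cn$min_s < 0))
      stop("model '", name, "': min_duration_before needs min_s >= 0")
  }
  structure(list(name = name, components = components,
                 constraints = constraints),
            class = "ecoadl_event_model")
}

#' @export
print.ecoadl_event_model <- function(x, ...) {
  cat(sprintf("<event model %s: %d components, %d constraints>\n",
              x$name, length(x$components), length(x$constraints)))
  invisible(x)
}

#' Read / write event models as JSON
#'
#' Format: array of `{name, components: {alias: state_or_model},
#' constraints: [{kind, ...}]}`.
#'
#' @param path File path.
#' @return `read_event_models()` returns a named list of models.
#' @export
read_event_models <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ms <- lapply(raw, function(m) {
    comps <- unlist(m$components)
    cons <- lapply(m$constraints, function(cn) {
      cn$components <- unlist(cn$components)
      cn
    })
    event_model(m$name, comps, cons)
  })
  names(ms) <- vapply(ms, function(m) m$name, character(1))
  ms
}

#' @param models Named list of models.
#' @rdname read_event_models
#' @export
write_event_models <- function(models, path) {
  out <- lapply(unname(models), function(m)
    list(name = m$name, components = as.list(m$components),
         constraints = lapply(m$constraints, function(cn) {
           if (!is.null(cn$components)) cn$components <- as.list(cn$components)
           cn
         })))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Active-indicator of an interval set on the frame grid.
intervals_active <- function(iv, grid) {
  act <- rep(FALSE, length(grid))
  if (is.null(iv) || !nrow(iv)) return(act)
  for (i in seq_len(nrow(iv)))
    act <- act | (grid >= iv$t_start[i] - 1e-9 & grid < iv$t_end[i] - 1e-9)
  act
}

# Seconds of continuous activity accumulated at each grid instant
# (0 where inactive; dt at the first active frame of a run counts as the
# elapsed time since run start, i.e. t - run_start).
streak_seconds <- function(active, dt) {
  n <- length(active)
  if (!n) return(numeric(0))
  run_id <- cumsum(c(TRUE, diff(active) != 0))
  pos <- stats::ave(rep(1, n), run_id, FUN = cumsum)
  ifelse(active, (pos - 1) * dt, 0)
}

resolve_component <- function(ref, models, primitives, grid, dt, depth) {
  if (depth > 4L)
    stop("event model nesting exceeds maximum depth 4 (cycle?)")
  if (!is.null(models[[ref]]))
    return(recognize_one(models[[ref]], models, primitives, grid, dt,
                         depth + 1L))
  primitives[primitives$state_name == ref, c("t_start", "t_end"),
             drop = FALSE]
}

recognize_one <- function(model, models, primitives, grid, dt, depth = 1L) {
  comp_iv <- lapply(model$components, resolve_component,
                    models = models, primitives = primitives,
                    grid = grid, dt = dt, depth = depth)
  act <- lapply(comp_iv, intervals_active, grid = grid)
  if (length(model$constraints)) {
    ok <- rep(TRUE, length(grid))
    for (cn in model$constraints) {
      if (cn$kind == "overlap") {
        for (al in cn$components) ok <- ok & act[[al]]
      } else {  # min_duration_before
        ok <- ok & (streak_seconds(act[[cn$component]], dt) >=
                      cn$min_s - 1e-9)
      }
    }
  } else {
    ok <- Reduce(`&`, act, init = rep(TRUE, length(grid)))
  }
  runs_to_intervals(grid, ok, dt)
}

#' Recognize composite events
#'
#' Evaluates every model's constraint conjunction at each instant of the
#' frame grid spanned by the primitive intervals and emits the maximal spans
#' on which all constraints hold. Recognition therefore starts at the first
#' instant every constraint is satisfied (e.g. once a zone occupancy has
#' lasted its minimum prior duration) and ends as soon as any constraint
#' ceases to hold.
#'
#' @param models Named list (or list) of [event_model()] objects.
#' @param primitives data.frame from [detect_primitive_states()].
#' @param frame_rate Frame grid resolution in Hz (must match the stream the
#'   primitives came from for frame-exact results).
#' @return data.frame with columns `model_name`, `t_start`, `t_end`.
#' @export
recognize_composite_events <- function(models, primitives, frame_rate = 10) {
  if (inherits(models, "ecoadl_event_model")) models <- list(models)
  nm <- vapply(models, function(m) m$name, character(1))
  names(models) <- nm
  check_model_acyclic(models)
  empty <- data.frame(model_name = character(0),
                      t_start = numeric(0), t_end = numeric(0))
  if (is.null(primitives) || !nrow(primitives)) return(empty)
  dt <- 1 / frame_rate
  t0 <- min(primitives$t_start)
  t1 <- max(primitives$t_end)
  grid <- seq(t0, t1 - dt / 2, by = dt)
  out <- lapply(models, function(m) {
    iv <- recognize_one(m, models, primitives, grid, dt)
    if (nrow(iv)) cbind(model_name = m$name, iv) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_model_acyclic <- function(models) {
  visit <- function(name, stack) {
    if (name %in% stack)
      stop("cyclic event model reference: ",
           paste(c(stack, name), collapse = " -> "))
    m <- models[[name]]
    if (is.null(m)) return(invisible())
    for (ref in m$components)
      if (!is.null(models[[ref]])) visit(ref, c(stack, name))
  }
  for (nm in names(models)) visit(nm, character(0))
  invisible(TRUE)
}

#' Read / write recognized or ground-truth events as CSV
#'
#' Header `model_name,t_start,t_end`, one interval per row.
#' @param path File path.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("model_name", "t_start", "t_end")
  if (!all(needed %in% names(df)))
    stop("event CSV must have header model_name,t_start,t_end: ", path)
  df[needed]
}

#' @param events Event data.frame.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[c("model_name", "t_start", "t_end")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Evaluate detection against ground truth
#'
#' A recognized interval is a true positive if a same-model ground-truth
#' interval overlaps it by at least `threshold` of the truth interval's
#' length; matching is one-to-one, greedy by decreasing overlap.
#'
#' @param recognized,truth Event data.frames (`model_name,t_start,t_end`).
#' @param threshold Overlap fraction in (0, 1], default 0.5.
#' @return data.frame per model with `tp`, `fp`, `fn`, `precision`, `recall`
#'   (`NA` where undefined, e.g. recall with no truth intervals).
#' @export
evaluate_detection <- function(recognized, truth, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  mods <- sort(unique(c(recognized$model_name, truth$model_name)))
  res <- lapply(mods, function(m) {
    r <- recognized[recognized$model_name == m, , drop = FALSE]
    g <- truth[truth$model_name == m, , drop = FALSE]
    nr <- nrow(r); ng <- nrow(g)
    if (ng == 0L)
      return(data.frame(model_name = m, tp = 0L, fp = nr, fn = 0L,
                        precision = if (nr) 0 else NA_real_,
                        recall = NA_real_))
    ov <- matrix(0, nr, ng)
    if (nr) for (i in seq_len(nr)) for (j in seq_len(ng))
      ov[i, j] <- max(0, min(r$t_end[i], g$t_end[j]) -
                        max(r$t_start[i], g$t_start[j]))
    used_r <- logical(nr); used_g <- logical(ng); tp <- 0L
    repeat {
      if (!nr) break
      ov2 <- ov
      ov2[used_r, ] <- -1; ov2[, used_g] <- -1
      best <- which(ov2 == max(ov2), arr.ind = TRUE)[1, , drop = FALSE]
      i <- best[1]; j <- best[2]
      if (ov2[i, j] <= 0) break
      glen <- g$t_end[j] - g$t_start[j]
      if (ov2[i, j] >= threshold * glen - 1e-9) {
        tp <- tp + 1L; used_r[i] <- TRUE; used_g[j] <- TRUE
      } else {
        ov[i, j] <- 0  # below threshold; try other pairings
      }
      if (all(used_r) || all(used_g)) break
    }
    fp <- nr - tp; fn <- ng - tp
    data.frame(model_name = m, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
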