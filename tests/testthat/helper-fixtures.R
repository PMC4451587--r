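# Shared fixtures and independent oracles.

square_zone <- function(name, x0, y0, side = 1)
  zone(name, cbind(c(x0, x0 + side, x0 + side, x0),
                   c(y0, y0, y0 + side, y0 + side)))

# constant-rate stream from per-frame vectors
make_stream <- function(t, x, y, posture = "standing", present = TRUE,
                        frame_rate = 10, lfx = NA, lfy = NA,
                        rfx = NA, rfy = NA) {
  n <- length(t)
  rec <- function(v) rep_len(v, n)
  track_stream(data.frame(
    t = t, person_present = rec(present), x = rec(x), y = rec(y),
    posture = rec(posture), lfx = rec(lfx), lfy = rec(lfy),
    rfx = rec(rfx), rfy = rec(rfy)), frame_rate = frame_rate)
}

# --- brute-force oracle for primitive-state detection -----------------------
# per-frame point-in-polygon scan + run-length encoding + gap merge,
# written as a plain loop, independent of the package's vectorized path
oracle_primitives <- function(stream, zones, gap_merge_s = 0.5) {
  dt <- 1 / attr(stream, "frame_rate")
  states <- list()
  for (z in zones)
    states[[paste0("Person_in_zone_", z$name)]] <- local({
      zz <- z
      function(i) stream$person_present[i] &&
        point_in_polygon(stream$x[i], stream$y[i], zz$polygon)
    })
  for (p in c("standing", "sitting", "bending"))
    states[[paste0("Person_", p)]] <- local({
      pp <- p
      function(i) stream$person_present[i] && !is.na(stream$posture[i]) &&
        stream$posture[i] == pp
    })
  rows <- list()
  for (nm in names(states)) {
    f <- states[[nm]]
    iv <- list(); cur <- NULL
    for (i in seq_len(nrow(stream))) {
      on <- isTRUE(f(i))
      if (on && is.null(cur)) cur <- c(stream$t[i], stream$t[i] + dt)
      else if (on) cur[2] <- stream$t[i] + dt
      else if (!is.null(cur)) { iv[[length(iv) + 1]] <- cur; cur <- NULL }
    }
    if (!is.null(cur)) iv[[length(iv) + 1]] <- cur
    # merge gaps < gap_merge_s
    merged <- list()
    for (v in iv) {
      k <- length(merged)
      if (k && v[1] - merged[[k]][2] < gap_merge_s)
        merged[[k]][2] <- v[2]
      else merged[[k + 1]] <- v
    }
    for (v in merged)
      rows[[length(rows) + 1]] <-
        data.frame(state_name = nm, t_start = v[1], t_end = v[2])
  }
  if (!length(rows))
    return(data.frame(state_name = character(0), t_start = numeric(0),
                      t_end = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$state_name, out$t_start), ]
  rownames(out) <- NULL
  out
}

# --- instant-wise brute-force oracle for composite recognition --------------
# tests every constraint at every frame instant by direct interval scans
oracle_composites <- function(models, primitives, frame_rate = 10) {
  dt <- 1 / frame_rate
  if (!nrow(primitives))
    return(data.frame(model_name = character(0), t_start = numeric(0),
                      t_end = numeric(0)))
  grid <- seq(min(primitives$t_start),
              max(primitives$t_end) - dt / 2, by = dt)
  in_state <- function(state, tt) {
    iv <- primitives[primitives$state_name == state, , drop = FALSE]
    any(tt >= iv$t_start - 1e-9 & tt < iv$t_end - 1e-9)
  }
  active_since <- function(state, tt) {
    # continuous activity duration ending at tt, walked instant by instant
    dur <- 0
    while (in_state(state, tt - dur - dt) && dur < 1e4) dur <- dur + dt
    dur
  }
  rows <- list()
  for (m in models) {
    ok <- vapply(grid, function(tt) {
      for (cn in m$constraints) {
        if (cn$kind == "overlap") {
          for (al in cn$components)
            if (!in_state(m$components[[al]], tt)) return(FALSE)
        } else {
          st <- m$components[[cn$component]]
          if (!in_state(st, tt)) return(FALSE)
          if (active_since(st, tt) < cn$min_s - 1e-9) return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    r <- rle(ok); e <- cumsum(r$lengths); s <- e - r$lengths + 1
    for (j in which(r$values))
      rows[[length(rows) + 1]] <- data.frame(
        model_name = m$name, t_start = grid[s[j]], t_end = grid[e[j]] + dt)
  }
  if (!length(rows))
    return(data.frame(model_name = character(0), t_start = numeric(0),
                      t_end = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random primitive intervals on a frame grid (no sub-frame offsets so the
# frame-grid semantics are exact)
random_primitives <- function(n, states, t_max = 30, frame_rate = 10) {
  dt <- 1 / frame_rate
  s <- round(runif(n, 0, t_max - 2) / dt) * dt
  len <- round(runif(n, dt, 5) / dt) * dt
  data.frame(state_name = sample(states, n, replace = TRUE),
             t_start = s, t_end = s + pmax(len, dt))
}

# --- naive Bayes density-product oracle -------------------------------------
oracle_nb_posterior <- function(model, xrow) {
  num <- vapply(model$classes, function(cl) {
    s <- model$stats[[cl]]
    s$prior * prod(dnorm(xrow[model$features], s$mean, sqrt(s$var)))
  }, numeric(1))
  num / sum(num)
}

sort_events <- function(ev) {
  ev <- ev[order(ev$model_name, ev$t_start), c("model_name", "t_start", "t_end")]
  rownames(ev) <- NULL
  ev
}
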