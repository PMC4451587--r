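#' Tracked-person streams
#'
#' A track stream is the per-frame output of an upstream person detector and
#' tracker: timestamps, floor-plane position of the person centroid, a
#' categorical posture label and (optionally) left/right foot positions.
#' Frames where the tracker lost the person carry `person_present = FALSE`
#' and no spatial fields.
#'
#' @param frames A data.frame with columns `t`, `person_present`, `x`, `y`,
#'   `posture`, `lfx`, `lfy`, `rfx`, `rfy`. Spatial columns must be `NA` on
#'   absent frames; `posture` is one of `"standing"`, `"sitting"`,
#'   `"bending"`.
#' @param frame_rate Nominal frame rate in Hz.
#' @return An object of class `ecoadl_track_stream` (a data.frame with a
#'   `frame_rate` attribute).
#' @export
track_stream <- function(frames, frame_rate = 10) {
  needed <- c("t", "person_present", "x", "y", "posture",
              "lfx", "lfy", "rfx", "rfy")
  if (is.null(frames) || nrow(frames) == 0L) {
    frames <- as.data.frame(
      setNames(rep(list(numeric(0)), length(needed)), needed))
    frames$person_present <- logical(0)
    frames$posture <- character(0)
  }
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols))
    stop("track stream missing columns: ", paste(missing_cols, collapse = ", "))
  frames <- frames[needed]
  frames$person_present <- as.logical(frames$person_present)
  frames$posture <- as.character(frames$posture)
  if (nrow(frames)) {
    if (any(frames$t < 0)) stop("track stream has negative timestamps")
    if (is.unsorted(frames$t, strictly = TRUE))
      stop("track stream timestamps must be strictly increasing")
    bad_post <- frames$person_present &
      !frames$posture %in% c("standing", "sitting", "bending")
    if (any(bad_post, na.rm = TRUE))
      stop("unknown posture label(s): ",
           paste(unique(frames$posture[bad_post]), collapse = ", "))
    if (any(frames$person_present & (is.na(frames$x) | is.na(frames$y))))
      stop("present frames must carry x/y positions")
  }
  structure(frames, frame_rate = as.numeric(frame_rate),
            class = c("ecoadl_track_stream", "data.frame"))
}

#' @export
print.ecoadl_track_stream <- function(x, ...) {
  cat(sprintf("<track stream: %d frames @ %g Hz, %.1f s, %.0f%% present>\n",
              nrow(x), attr(x, "frame_rate"),
              if (nrow(x)) diff(range(x$t)) else 0,
              if (nrow(x)) 100 * mean(x$person_present) else 0))
  invisible(x)
}

#' @rdname track_stream
#' @param stream A track stream.
#' @export
frame_dt <- function(stream) 1 / attr(stream, "frame_rate")

#' Read / write track streams as CSV
#'
#' CSV dialect: comma separator, `.` decimal, UTF-8, mandatory header
#' `t,person_present,x,y,posture,lfx,lfy,rfx,rfy`, one row per frame.
#'
#' @param path File path.
#' @param frame_rate Frame rate to attach on read (Hz).
#' @return `read_tracks()` returns a [track_stream()].
#' @export
read_tracks <- function(path, frame_rate = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(posture = "character"))
  df$person_present <- as.logical(df$person_present)
  df$posture[is.na(df$posture) | df$posture == ""] <- NA_character_
  track_stream(df, frame_rate = frame_rate)
}

#' @param stream A [track_stream()].
#' @rdname read_tracks
#' @export
write_tracks <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a stream to a time window
#'
#' Keeps frames with `t_start <= t < t_end` (half-open, matching event
#' interval semantics).
#'
#' @param stream A [track_stream()].
#' @param t_start,t_end Window bounds in seconds.
#' @export
slice_stream <- function(stream, t_start, t_end) {
  keep <- stream$t >= t_start & stream$t < t_end
  track_stream(as.data.frame(stream)[keep, , drop = FALSE],
               frame_rate = attr(stream, "frame_rate"))
}
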