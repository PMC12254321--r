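#' Trajectory sets
#'
#' A `trajectory_set` is a data frame of linked particle positions with one
#' row per (track, frame): columns `track_id`, `frame` (0-based integer,
#' strictly increasing within a track), `t_s` (seconds), `x_um`, `y_um` and
#' optionally `population` (ground-truth label for simulated tracks). The
#' frame interval in seconds is carried as an attribute.
#'
#' @param df Data frame with at least `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Frame interval in seconds.
#' @return A `trajectory_set`.
#' @export
as_trajectory_set <- function(df, frame_interval) {
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  dup <- stats::ave(df$frame, df$track_id, FUN = function(f) duplicated(f))
  if (any(dup > 0))
    stop("a frame appears more than once within a track", call. = FALSE)
  if (!"t_s" %in% names(df)) df$t_s <- df$frame * frame_interval
  rownames(df) <- NULL
  structure(df, frame_interval = frame_interval,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  ids <- unique(x$track_id)
  cat(sprintf("Trajectory set: %d tracks, %d points, frame interval %.4g s\n",
              length(ids), nrow(x), attr(x, "frame_interval")))
  lens <- table(x$track_id)
  cat(sprintf("  track length: median %d, range %d-%d frames\n",
              as.integer(median(lens)), min(lens), max(lens)))
  invisible(x)
}

#' @export
`[.trajectory_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "frame_interval") <- attr(x, "frame_interval")
    class(out) <- c("trajectory_set", "data.frame")
  }
  out
}

# Split into per-track data frames (list keyed by id).
split_tracks <- function(set) split(as.data.frame(set), set$track_id)

#' Write / read trajectory CSV
#'
#' Round-trips the trajectory table schema (`track_id, frame, t_s, x_um,
#' y_um[, population]`) with the frame interval recorded in a JSON sidecar
#' when `sidecar = TRUE`.
#'
#' @param set A `trajectory_set`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` holding the frame interval and any
#'   ground-truth attributes.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(set, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(set), path, row.names = FALSE)
  if (sidecar) {
    meta <- list(frame_interval = attr(set, "frame_interval"),
                 ground_truth = attr(set, "ground_truth"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trajectories
#' @param frame_interval Frame interval in seconds; if `NULL`, read from the
#'   JSON sidecar.
#' @export
read_trajectories <- function(path, frame_interval = NULL) {
  df <- utils::read.csv(path)
  if (is.null(frame_interval)) {
    sc <- paste0(path, ".json")
    if (!file.exists(sc))
      stop("no `frame_interval` given and no sidecar found", call. = FALSE)
    frame_interval <- jsonlite::read_json(sc)$frame_interval
  }
  as_trajectory_set(df, frame_interval)
}
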