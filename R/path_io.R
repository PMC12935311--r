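#' Read a path log of timestamped 3D positions
#'
#' A path log is a CSV with columns `participant_id, session_id, t, x, y, z`
#' holding one position sample per second per participant and session. Rows
#' are sorted by time within each (participant, session); duplicated
#' timestamps are rejected.
#'
#' @param file CSV path, or a data frame already in that layout.
#' @return A list of `"tracked_path"` objects, each a list with
#'   `participant_id`, `session_id` and a `samples` data frame
#'   (`t, x, y, z`, time strictly increasing).
#' @export
read_path_log <- function(file) {
  df <- if (is.data.frame(file)) file else utils::read.csv(file)
  need <- c("participant_id", "session_id", "t", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("path log missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  split_paths <- split(df, list(df$participant_id, df$session_id), drop = TRUE)
  out <- lapply(split_paths, function(p) {
    p <- p[order(p$t), , drop = FALSE]
    dup <- duplicated(p$t)
    if (any(dup))
      stop("duplicated timestamps for participant ", p$participant_id[1],
           " session ", p$session_id[1], " at t = ",
           paste(utils::head(p$t[dup], 5), collapse = ", "), call. = FALSE)
    if (nrow(p) < 2)
      stop("tracked path needs at least 2 samples (participant ",
           p$participant_id[1], ")", call. = FALSE)
    structure(list(participant_id = p$participant_id[1],
                   session_id = p$session_id[1],
                   samples = data.frame(t = p$t, x = p$x, y = p$y, z = p$z)),
              class = "tracked_path")
  })
  unname(out)
}

#' Read an event log of object finds and placements
#'
#' Events carry columns `participant_id, session_id, t, kind, object_id, x, y,
#' z` with `kind` one of `session_start`, `object_found`, `object_placed`,
#' `trial_start`, `session_end` (`trial_start` marks teleport-in at the start
#' of a placement trial in the test phase). Times must be non-decreasing
#' within a session, and no object may be found twice in one training session.
#'
#' @param file CSV path, or a data frame already in that layout.
#' @return A list of `"event_log"` objects (`participant_id`, `session_id`,
#'   `events` data frame).
#' @export
read_event_log <- function(file) {
  df <- if (is.data.frame(file)) file else utils::read.csv(file)
  need <- c("participant_id", "session_id", "t", "kind", "object_id",
            "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event log missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  kinds <- c("session_start", "object_found", "object_placed",
             "trial_start", "session_end")
  bad <- setdiff(unique(df$kind), kinds)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, list(df$participant_id, df$session_id), drop = TRUE),
                function(e) {
    e <- e[order(e$t), , drop = FALSE]
    if (is.unsorted(e$t))
      stop("event times must be non-decreasing", call. = FALSE)
    found <- e$object_id[e$kind == "object_found"]
    if (anyDuplicated(found))
      stop("object ", found[duplicated(found)][1], " found more than once in ",
           "session ", e$session_id[1], " of participant ",
           e$participant_id[1], call. = FALSE)
    structure(list(participant_id = e$participant_id[1],
                   session_id = e$session_id[1],
                   events = data.frame(t = e$t, kind = e$kind,
                                       object_id = e$object_id,
                                       x = e$x, y = e$y, z = e$z)),
              class = "event_log")
  })
  unname(out)
}

#' Split a training path into object-to-object segments
#'
#' Each segment runs from one anchoring event (session start or a found
#' object) to the next found object; a participant who finds m objects yields
#' m segments. The sample recorded at an event time closes the earlier
#' segment and anchors the start of the next, so stored segment samples span
#' the closed interval between the two event times while segment interiors
#' are disjoint. Path recorded after the last found object is discarded — a
#' cost-difference curve needs a destination object.
#'
#' @param path A `"tracked_path"` (see [read_path_log()]).
#' @param log A matching `"event_log"` containing a `session_start` event.
#' @param snap_tolerance Warn when the final sample of a segment lies farther
#'   than this (2D Euclidean, in cells) from the found object's logged
#'   position.
#' @return A list of `"segment"` objects: `participant_id`, `session_id`,
#'   `start_label`, `end_label`, `samples` (t, x, y, z with t rebased to 0),
#'   `duration`, `end_position` (from the event log), and flags `is_first`,
#'   `is_last`.
#' @export
segment_training_path <- function(path, log, snap_tolerance = 2) {
  if (!identical(path$participant_id, log$participant_id) ||
      !identical(path$session_id, log$session_id))
    stop("path and event log refer to different participant/session",
         call. = FALSE)
  ev <- log$events
  if (!any(ev$kind == "session_start"))
    stop("event log has no session_start event", call. = FALSE)
  t0 <- ev$t[ev$kind == "session_start"][1]
  finds <- ev[ev$kind == "object_found" & ev$t >= t0, , drop = FALSE]
  if (nrow(finds) == 0) return(list())
  bounds_t <- c(t0, finds$t)
  labels <- c("session_start", as.character(finds$object_id))
  segs <- vector("list", nrow(finds))
  for (k in seq_len(nrow(finds))) {
    ta <- bounds_t[k]; tb <- bounds_t[k + 1]
    rows <- path$samples[path$samples$t >= ta & path$samples$t <= tb, ,
                         drop = FALSE]
    if (nrow(rows) == 0)
      stop("no path samples between events at t = ", ta, " and ", tb,
           call. = FALSE)
    if (min(rows$t) - ta > 1 || tb - max(rows$t) > 1)
      warning("segment boundary samples more than one sampling interval ",
              "from event times (", ta, ", ", tb, ")", call. = FALSE)
    endpos <- c(x = finds$x[k], y = finds$y[k], z = finds$z[k])
    gap <- sqrt((rows$x[nrow(rows)] - endpos["x"])^2 +
                  (rows$y[nrow(rows)] - endpos["y"])^2)
    if (is.finite(gap) && gap > snap_tolerance)
      warning("segment to object ", finds$object_id[k], " ends ",
              round(gap, 2), " cells from the logged object position",
              call. = FALSE)
    samples <- data.frame(t = rows$t - ta, x = rows$x, y = rows$y, z = rows$z)
    segs[[k]] <- structure(
      list(participant_id = path$participant_id,
           session_id = path$session_id,
           start_label = labels[k],
           end_label = as.character(finds$object_id[k]),
           samples = samples,
           duration = tb - ta,
           end_position = endpos,
           is_first = k == 1L,
           is_last = k == nrow(finds)),
      class = "segment")
  }
  segs
}

#' @export
print.segment <- function(x, ...) {
  cat("Segment ", x$start_label, " -> ", x$end_label, " (participant ",
      x$participant_id, ", session ", x$session_id, "): ",
      nrow(x$samples), " samples over ", x$duration, " s\n", sep = "")
  invisible(x)
}
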