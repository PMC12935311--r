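#' Classify a segment as low-cost or high-cost
#'
#' Segments are triaged by the optimal (Dijkstra) start-to-end cost of the
#' segment: those strictly below the cutoff are "low" (typical, direct
#' paths), those at or above it are "high" (long or challenging segments,
#' excluded from a participant's mean curve and counted as removed curves).
#'
#' @param optimal_cost Non-negative finite optimal segment cost(s).
#' @param cutoff Cost threshold, default 70.
#' @return Character vector of `"low"` / `"high"`.
#' @examples
#' classify_segment(c(0, 69.9, 70))  # low, low, high
#' @export
classify_segment <- function(optimal_cost, cutoff = 70) {
  if (any(!is.finite(optimal_cost)) || any(optimal_cost < 0))
    stop("optimal_cost must be finite and non-negative", call. = FALSE)
  ifelse(optimal_cost < cutoff, "low", "high")
}

#' Participant-level features from segment curves
#'
#' Aggregates a cohort's normalised curves to one feature row per
#' participant: the removed-curve count (high-cost segments), the shares of
#' clusters 2..K among ALL of the participant's segments, the average segment
#' time over all segments, and the mean curve — the pointwise average of the
#' normalised curves of low-cost segments only. Participants with no
#' low-cost segment get an all-`NA` mean curve and are reported in
#' `excluded`; they cannot enter the functional regression.
#'
#' @param cm A curve matrix as returned by [curve_matrix()] (`values`,
#'   `grid`, `meta` with `participant_id`, `optimal_start_cost`, `duration`).
#' @param assignments Integer cluster label per curve (from
#'   [cluster_curves()]).
#' @param covariates Optional data frame keyed by `participant_id` to merge
#'   onto the feature table.
#' @param cutoff Low/high-cost cutoff passed to [classify_segment()].
#' @param k Number of clusters (defaults to `max(assignments)`).
#' @return List with `features` (data frame: participant_id,
#'   removed_curve_count, n_segments, cluster_prop_2..k,
#'   average_segment_time, has_mean_curve, plus merged covariates),
#'   `mean_curves` (participants x grid matrix, NA rows for excluded),
#'   `grid`, and `excluded` (participant ids without a low-cost segment).
#' @export
participant_features <- function(cm, assignments, covariates = NULL,
                                 cutoff = 70, k = max(assignments)) {
  meta <- cm$meta
  if (length(assignments) != nrow(meta))
    stop("one cluster assignment per curve is required", call. = FALSE)
  cls <- classify_segment(meta$optimal_start_cost, cutoff)
  ids <- unique(meta$participant_id)
  G <- length(cm$grid)
  feats <- vector("list", length(ids))
  mean_curves <- matrix(NA_real_, length(ids), G,
                        dimnames = list(as.character(ids), NULL))
  for (i in seq_along(ids)) {
    sel <- meta$participant_id == ids[i]
    low <- sel & cls == "low"
    if (any(low))
      mean_curves[i, ] <- colMeans(cm$values[low, , drop = FALSE])
    props <- vapply(2:k, function(cl) mean(assignments[sel] == cl),
                    numeric(1))
    feats[[i]] <- data.frame(
      participant_id = ids[i],
      n_segments = sum(sel),
      removed_curve_count = sum(sel & cls == "high"),
      t(stats::setNames(props, paste0("cluster_prop_", 2:k))),
      average_segment_time = mean(meta$duration[sel]),
      has_mean_curve = any(low))
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  if (!is.null(covariates))
    features <- merge(features, covariates, by = "participant_id",
                      sort = FALSE)
  list(features = features, mean_curves = mean_curves, grid = cm$grid,
       excluded = ids[!features$has_mean_curve[match(ids,
                                                     features$participant_id)]])
}

#' Spatial-memory outcomes from a placement-test log
#'
#' Scores a test session against the true object locations. A placement is
#' correct when its distance to the true location is at most
#' `correct_radius` (10 blocks by default); the distance metric is the
#' directed Dijkstra distance from the placed block to the true block
#' (`metric = "dijkstra"`, matching the distance used for the precision
#' outcome) or 2D Euclidean (`metric = "euclidean"`). The outcomes are
#' `y1` — the number of correctly located objects; `y2` — the mean time from
#' trial start (teleport-in) to placement, over correct trials only; and
#' `y3` — the mean distance from the true location over correct trials.
#' With no correct placement, `y2` and `y3` are `NA`.
#'
#' @param map A [terrain_map()].
#' @param test_log An `"event_log"` containing `trial_start` /
#'   `object_placed` event pairs per object.
#' @param true_locations Data frame `object_id, x, y` of true object cells.
#' @param rules A [movement_rules()].
#' @param correct_radius Correctness radius in blocks (default 10).
#' @param metric `"dijkstra"` (default) or `"euclidean"`.
#' @return List `y1`, `y2`, `y3`, plus a `trials` data frame
#'   (object_id, placement_time, distance, correct).
#' @export
compute_outcomes <- function(map, test_log, true_locations,
                             rules = movement_rules(), correct_radius = 10,
                             metric = c("dijkstra", "euclidean")) {
  metric <- match.arg(metric)
  ev <- test_log$events
  placed <- ev[ev$kind == "object_placed", , drop = FALSE]
  starts <- ev[ev$kind == "trial_start", , drop = FALSE]
  if (nrow(placed) > 12)
    stop("more than 12 placement events in one test log", call. = FALSE)
  trials <- lapply(seq_len(nrow(placed)), function(i) {
    oid <- placed$object_id[i]
    truth <- true_locations[true_locations$object_id == oid, , drop = FALSE]
    if (nrow(truth) != 1)
      stop("no unique true location for object ", oid, call. = FALSE)
    st <- starts[starts$object_id == oid, , drop = FALSE]
    t_start <- if (nrow(st)) st$t[1] else 0
    pb <- snap_to_block(map, placed$x[i], placed$y[i])
    tb <- block(map, truth$x, truth$y)
    dist <- if (metric == "dijkstra")
      dijkstra(map, pb, tb, rules)$distance
    else sqrt((pb$x - tb$x)^2 + (pb$y - tb$y)^2)
    data.frame(object_id = oid, placement_time = placed$t[i] - t_start,
               distance = dist, correct = dist <= correct_radius)
  })
  trials <- do.call(rbind, trials)
  if (is.null(trials))
    trials <- data.frame(object_id = character(), placement_time = numeric(),
                         distance = numeric(), correct = logical())
  y1 <- sum(trials$correct)
  list(y1 = y1,
       y2 = if (y1 >= 1) mean(trials$placement_time[trials$correct]) else NA_real_,
       y3 = if (y1 >= 1) mean(trials$distance[trials$correct]) else NA_real_,
       trials = trials)
}
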