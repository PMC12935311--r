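#' Cost of one observed step between consecutive samples
#'
#' Both positions are snapped to blocks. A stationary second costs 0; a step
#' along a walkable edge costs its [edge_weight()]; any other transition (the
#' player covered more than one cell in a second, or took a move the edge
#' rules exclude) is charged its Dijkstra distance, which keeps the
#' triangle-inequality structure the cost-difference curve invariants rely
#' on. An unreachable transition yields `Inf`.
#'
#' @param map A [terrain_map()].
#' @param p,q Positions: `c(x, y)` continuous coordinates or blocks.
#' @param rules A [movement_rules()].
#' @return Non-negative cost (possibly `Inf`).
#' @export
step_cost <- function(map, p, q, rules = movement_rules()) {
  u <- if (is.list(p)) as_block(map, p) else snap_to_block(map, p[1], p[2])
  v <- if (is.list(q)) as_block(map, q) else snap_to_block(map, q[1], q[2])
  if (u$x == v$x && u$y == v$y) return(0)
  if (is_walkable_edge(map, u, v, rules)) return(edge_weight(map, u, v, rules))
  tg <- terrain_graph(map, rules)
  igraph::distances(tg$graph, v = cell_id(map, u$x, u$y),
                    to = cell_id(map, v$x, v$y), mode = "out")[1, 1]
}

# Vectorised step costs along a snapped block-id sequence.
step_costs_along <- function(map, ids, rules) {
  n <- length(ids)
  if (n < 2) return(numeric(0))
  tg <- terrain_graph(map, rules)
  xy <- id_to_xy(map, ids)
  elev <- as.vector(map$elevation)
  obs <- as.vector(map$obstructed)
  a <- ids[-n]; b <- ids[-1]
  dx <- xy[-1, "x"] - xy[-n, "x"]
  dy <- xy[-1, "y"] - xy[-n, "y"]
  dz <- elev[b] - elev[a]
  cost <- numeric(n - 1)
  same <- a == b
  edge <- !same & abs(dx) <= 1 & abs(dy) <= 1 &
    dz <= rules$max_climb & dz >= -rules$max_fall & !obs[a] & !obs[b]
  if (rules$strict_corners) {
    diag <- edge & dx != 0 & dy != 0
    edge[diag] <- !obs[a[diag] + dx[diag]] & !obs[a[diag] + dy[diag] * map$width]
  }
  cost[edge] <- sqrt(dx[edge]^2 + dy[edge]^2) +
    rules$alpha_up * pmax(dz[edge], 0) + rules$alpha_down * pmax(-dz[edge], 0)
  other <- which(!same & !edge)
  for (k in other)
    cost[k] <- igraph::distances(tg$graph, v = a[k], to = b[k],
                                 mode = "out")[1, 1]
  cost
}

#' Cost-difference curve of a segment
#'
#' For a segment with samples at times `t_0 .. t_N`, the actual cost-to-go
#' `A(t_j)` is the summed step cost of the remaining observed path, and the
#' optimal cost-to-go `O(t_j)` is the Dijkstra distance from the current
#' block to the segment-end block (the last sample's block). Their difference
#' `D(t_j) = A(t_j) - O(t_j)` measures how much avoidable cost is still ahead:
#' it is non-negative, non-increasing in time, and exactly 0 at the segment
#' end. Segments containing an unreachable transition cannot be scored and
#' raise a condition of class `"voxelnav_unreachable_segment"`.
#'
#' @param map A [terrain_map()].
#' @param segment A `"segment"` (see [segment_training_path()]).
#' @param rules A [movement_rules()].
#' @return An object of class `"cost_curve"`: list with `times` (seconds from
#'   segment start), `values` (`D(t)`), `actual`, `optimal`,
#'   `optimal_start_cost` (`O(t_0)`, the segment's optimal start-to-end cost
#'   used by the low/high-cost triage), `duration`, and the segment
#'   identifiers.
#' @export
cost_difference_curve <- function(map, segment, rules = movement_rules()) {
  s <- segment$samples
  bx <- floor(s$x); by <- floor(s$y)
  if (!all(in_bounds(map, bx, by)))
    stop("segment samples fall outside the map", call. = FALSE)
  ids <- cell_id(map, bx, by)
  n <- length(ids)
  end_id <- ids[n]
  end_xy <- id_to_xy(map, end_id)
  field <- distance_field(map, c(end_xy[1, "x"], end_xy[1, "y"]), rules)
  optimal <- as.vector(field)[ids]
  steps <- step_costs_along(map, ids, rules)
  if (any(!is.finite(steps)) || any(!is.finite(optimal)))
    stop(structure(class = c("voxelnav_unreachable_segment", "error",
                             "condition"),
                   list(message = paste0(
                     "segment ", segment$start_label, " -> ",
                     segment$end_label, " contains unreachable transitions"),
                     call = NULL)))
  actual <- rev(cumsum(rev(c(steps, 0))))
  values <- actual - optimal
  values[n] <- 0                       # exact by construction; kill fp dust
  structure(list(participant_id = segment$participant_id,
                 session_id = segment$session_id,
                 start_label = segment$start_label,
                 end_label = segment$end_label,
                 times = s$t,
                 values = values,
                 actual = actual,
                 optimal = optimal,
                 optimal_start_cost = optimal[1],
                 duration = segment$duration,
                 is_first = segment$is_first,
                 is_last = segment$is_last),
            class = "cost_curve")
}

#' @export
print.cost_curve <- function(x, ...) {
  cat("Cost-difference curve ", x$start_label, " -> ", x$end_label, ": D(0) = ",
      format(x$values[1], digits = 6), ", T = ", x$duration,
      " s, optimal start cost ", format(x$optimal_start_cost, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Normalise a cost-difference curve to the unified time grid
#'
#' Rescales time linearly from `[0, T_s]` to `[0, t_unified]` and evaluates
#' the curve by linear interpolation on `grid_size` equally spaced points.
#' Endpoint values are preserved exactly, and linear interpolation of a
#' monotone sequence is monotone, so the curve invariants survive
#' normalisation; applying the operation again on the unified grid is the
#' identity.
#'
#' @param curve A `"cost_curve"` or `"normalized_curve"`.
#' @param t_unified Unified time-scale length (default 100).
#' @param grid_size Number of grid points (default 101).
#' @return An object of class `"normalized_curve"`: `grid`, `values`, and the
#'   source metadata (including original `duration`).
#' @export
normalize_curve <- function(curve, t_unified = 100, grid_size = 101) {
  times <- if (inherits(curve, "normalized_curve")) curve$grid else curve$times
  ts <- max(times) - min(times)
  if (ts <= 0) stop("degenerate segment: zero duration", call. = FALSE)
  if (length(times) < 2) stop("curve needs at least 2 points", call. = FALSE)
  grid <- seq(0, t_unified, length.out = grid_size)
  scaled <- (times - min(times)) / ts * t_unified
  vals <- stats::approx(scaled, curve$values, xout = grid, rule = 2)$y
  vals[1] <- curve$values[1]
  vals[grid_size] <- curve$values[length(curve$values)]
  out <- unclass(curve)
  out$grid <- grid
  out$values <- vals
  out$times <- NULL
  out$actual <- NULL
  out$optimal <- NULL
  structure(out, class = "normalized_curve")
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat("Normalised curve on [0, ", max(x$grid), "] (", length(x$grid),
      " points), D(0) = ", format(x$values[1], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Stack normalised curves into a matrix
#'
#' @param curves List of `"normalized_curve"` objects sharing one grid.
#' @return List with `values` (curves x grid matrix), `grid`, and `meta`
#'   (data frame of per-curve metadata: participant, session, labels,
#'   duration, optimal start cost, first/last flags).
#' @export
curve_matrix <- function(curves) {
  if (!length(curves)) stop("no curves supplied", call. = FALSE)
  grid <- curves[[1]]$grid
  for (cv in curves)
    if (!isTRUE(all.equal(cv$grid, grid)))
      stop("curves are not on a common grid", call. = FALSE)
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  meta <- do.call(rbind, lapply(curves, function(cv) data.frame(
    participant_id = cv$participant_id %||% NA,
    session_id = cv$session_id %||% NA,
    start_label = cv$start_label %||% NA,
    end_label = cv$end_label %||% NA,
    duration = cv$duration %||% NA,
    environment = cv$environment %||% NA,
    optimal_start_cost = cv$optimal_start_cost %||% NA,
    is_first = cv$is_first %||% NA,
    is_last = cv$is_last %||% NA)))
  rownames(meta) <- NULL
  list(values = vals, grid = grid, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
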