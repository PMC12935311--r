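#' Movement rules for voxel-terrain navigation
#'
#' Encodes the kinematic constraints and vertical movement costs used to build
#' the walkability graph. A step between horizontally (8-neighbourhood)
#' adjacent cells is permitted when the ascent is at most `max_climb` blocks
#' and the descent at most `max_fall` blocks. Vertical movement adds cost on
#' top of the 2D Euclidean step length: `alpha_up` per block ascended and
#' `alpha_down` per block descended, with ascending strictly costlier than
#' descending.
#'
#' @param alpha_up Cost per block ascended (dimensionless, > 0).
#' @param alpha_down Cost per block descended (dimensionless, > 0, and
#'   strictly less than `alpha_up`).
#' @param max_climb Maximum permitted ascent per step, in blocks.
#' @param max_fall Maximum permitted descent per step, in blocks.
#' @param strict_corners If `TRUE`, a diagonal step additionally requires both
#'   flanking orthogonal cells to be unobstructed (no corner cutting).
#'   Defaults to `FALSE`: diagonal moves are judged by the end cells alone.
#' @return An object of class `"movement_rules"`.
#' @examples
#' movement_rules()
#' movement_rules(alpha_up = 3, alpha_down = 0.5)
#' @export
movement_rules <- function(alpha_up = 2, alpha_down = 1,
                           max_climb = 2L, max_fall = 3L,
                           strict_corners = FALSE) {
  if (!(alpha_up > alpha_down && alpha_down > 0))
    stop("movement rules require alpha_up > alpha_down > 0", call. = FALSE)
  max_climb <- as.integer(max_climb)
  max_fall <- as.integer(max_fall)
  if (max_climb < 0L || max_fall < 0L)
    stop("max_climb and max_fall must be non-negative integers", call. = FALSE)
  structure(
    list(alpha_up = alpha_up, alpha_down = alpha_down,
         max_climb = max_climb, max_fall = max_fall,
         strict_corners = isTRUE(strict_corners)),
    class = "movement_rules"
  )
}

#' @export
print.movement_rules <- function(x, ...) {
  cat("Movement rules: +", x$alpha_up, "/block up, +", x$alpha_down,
      "/block down; climb <= ", x$max_climb, ", fall <= ", x$max_fall,
      if (x$strict_corners) ", strict corners" else "", "\n", sep = "")
  invisible(x)
}

#' Terrain map of a voxel environment
#'
#' A rectangular integer elevation surface with a same-shape obstruction mask.
#' Each (x, y) cell carries exactly one elevation value (the walkable block's
#' z), so terrain is a height field; obstructed cells (water, trees, fences,
#' cacti, ...) are excluded from the navigation graph. Cell indices are
#' 0-based: x in `0..width-1`, y in `0..depth-1`; `elevation` is stored as a
#' `width x depth` matrix indexed `[x + 1, y + 1]`.
#'
#' @param elevation Integer matrix (`width x depth`) of block elevations.
#' @param obstructed Logical matrix of the same shape (`TRUE` = impassable);
#'   defaults to all-clear.
#' @return An object of class `"terrain_map"` with fields `width`, `depth`,
#'   `elevation`, `obstructed`.
#' @examples
#' flat <- terrain_map(matrix(1L, 5, 5))
#' flat
#' @export
terrain_map <- function(elevation, obstructed = NULL) {
  elevation <- as.matrix(elevation)
  if (any(elevation != round(elevation)))
    stop("elevation values must be integers (block units)", call. = FALSE)
  storage.mode(elevation) <- "integer"
  if (is.null(obstructed))
    obstructed <- matrix(FALSE, nrow(elevation), ncol(elevation))
  obstructed <- as.matrix(obstructed)
  if (!identical(dim(obstructed), dim(elevation)))
    stop("elevation and obstructed must have identical dimensions", call. = FALSE)
  storage.mode(obstructed) <- "logical"
  structure(
    list(width = nrow(elevation), depth = ncol(elevation),
         elevation = elevation, obstructed = obstructed,
         .cache = new.env(parent = emptyenv())),
    class = "terrain_map"
  )
}

#' @export
print.terrain_map <- function(x, ...) {
  cat("Terrain map: ", x$width, " x ", x$depth, " cells, elevation [",
      min(x$elevation), ", ", max(x$elevation), "], ",
      sum(x$obstructed), " obstructed (",
      round(100 * mean(x$obstructed), 1), "%)\n", sep = "")
  invisible(x)
}

cell_id <- function(map, x, y) x + map$width * y + 1L

id_to_xy <- function(map, id) {
  id0 <- id - 1L
  cbind(x = id0 %% map$width, y = id0 %/% map$width)
}

in_bounds <- function(map, x, y) {
  x >= 0 & x < map$width & y >= 0 & y < map$depth
}

#' Blocks: grid cells with their elevation
#'
#' `block()` addresses a cell of the map and returns it together with its
#' elevation; `snap_to_block()` maps continuous player coordinates to the
#' containing cell by flooring (a coordinate on a cell boundary belongs to its
#' own cell).
#'
#' @param map A [terrain_map()].
#' @param x,y Cell indices (for `block`) or continuous coordinates (for
#'   `snap_to_block`).
#' @return A list with integer fields `x`, `y`, `z`.
#' @examples
#' m <- terrain_map(matrix(1:25, 5, 5))
#' block(m, 2, 3)
#' snap_to_block(m, 3.7, 2.1)
#' @export
block <- function(map, x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (!all(in_bounds(map, x, y)))
    stop("block (", x, ", ", y, ") out of map bounds", call. = FALSE)
  list(x = x, y = y, z = map$elevation[x + 1L, y + 1L])
}

#' @rdname block
#' @export
snap_to_block <- function(map, x, y) {
  bx <- floor(x); by <- floor(y)
  if (!all(in_bounds(map, bx, by)))
    stop("coordinate (", x, ", ", y, ") outside map bounds", call. = FALSE)
  block(map, bx, by)
}

as_block <- function(map, b) {
  if (is.list(b) && !is.null(b$x)) block(map, b$x, b$y)
  else if (is.numeric(b) && length(b) >= 2) block(map, b[1], b[2])
  else stop("cannot interpret block specification", call. = FALSE)
}

#' Walkability of a single step
#'
#' An edge from block `from` to block `to` is walkable iff (i) neither cell is
#' obstructed, (ii) the cells are distinct 8-neighbours (|dx| <= 1, |dy| <= 1),
#' and (iii) the elevation change satisfies `-max_fall <= dz <= max_climb`.
#' Because ascent and descent limits differ, walkability is directed:
#' `(u, v)` walkable does not imply `(v, u)` walkable.
#'
#' @param map A [terrain_map()].
#' @param from,to Blocks (`list(x, y)` or `c(x, y)`).
#' @param rules A [movement_rules()].
#' @return Logical scalar.
#' @export
is_walkable_edge <- function(map, from, to, rules = movement_rules()) {
  u <- as_block(map, from); v <- as_block(map, to)
  if (map$obstructed[u$x + 1L, u$y + 1L] || map$obstructed[v$x + 1L, v$y + 1L])
    return(FALSE)
  dx <- v$x - u$x; dy <- v$y - u$y
  if (abs(dx) > 1L || abs(dy) > 1L || (dx == 0L && dy == 0L)) return(FALSE)
  dz <- v$z - u$z
  if (dz > rules$max_climb || dz < -rules$max_fall) return(FALSE)
  if (rules$strict_corners && dx != 0L && dy != 0L) {
    if (map$obstructed[u$x + dx + 1L, u$y + 1L] ||
        map$obstructed[u$x + 1L, u$y + dy + 1L]) return(FALSE)
  }
  TRUE
}

#' Cost of a walkable step
#'
#' The edge weight is the 2D Euclidean distance between the cells plus an
#' asymmetric vertical surcharge: `alpha_up` per block ascended or
#' `alpha_down` per block descended. A flat orthogonal step costs 1, a flat
#' diagonal step `sqrt(2)`.
#'
#' @inheritParams is_walkable_edge
#' @return Positive numeric cost.
#' @examples
#' m <- terrain_map(matrix(1L, 3, 3))
#' edge_weight(m, c(0, 0), c(1, 1))  # sqrt(2)
#' @export
edge_weight <- function(map, from, to, rules = movement_rules()) {
  if (!is_walkable_edge(map, from, to, rules))
    stop("edge is not walkable under the given movement rules", call. = FALSE)
  u <- as_block(map, from); v <- as_block(map, to)
  dz <- v$z - u$z
  sqrt((v$x - u$x)^2 + (v$y - u$y)^2) +
    rules$alpha_up * max(dz, 0) + rules$alpha_down * max(-dz, 0)
}

# Build (and memoise per rules) the directed weighted walkability graph.
# Vertices are all cells (obstructed cells stay isolated); edges follow
# is_walkable_edge with edge_weight weights, constructed vectorised.
terrain_graph <- function(map, rules = movement_rules()) {
  key <- paste(unlist(rules), collapse = "|")
  cached <- map$.cache[[key]]
  if (!is.null(cached)) return(cached)

  w <- map$width; d <- map$depth
  n <- w * d
  xs <- rep(0:(w - 1L), times = d)
  ys <- rep(0:(d - 1L), each = w)
  elev <- as.vector(map$elevation)   # column-major == cell_id order
  obs <- as.vector(map$obstructed)

  offsets <- expand.grid(dx = -1:1, dy = -1:1)
  offsets <- offsets[offsets$dx != 0 | offsets$dy != 0, ]

  eu <- ev <- ew <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    dx <- offsets$dx[i]; dy <- offsets$dy[i]
    ok <- in_bounds(map, xs + dx, ys + dy)
    u <- which(ok)
    v <- u + dx + dy * w
    keep <- !obs[u] & !obs[v]
    if (rules$strict_corners && dx != 0 && dy != 0)
      keep <- keep & !obs[u + dx] & !obs[u + dy * w]
    u <- u[keep]; v <- v[keep]
    dz <- elev[v] - elev[u]
    keep <- dz <= rules$max_climb & dz >= -rules$max_fall
    u <- u[keep]; v <- v[keep]; dz <- dz[keep]
    eu[[i]] <- u; ev[[i]] <- v
    ew[[i]] <- sqrt(dx^2 + dy^2) +
      rules$alpha_up * pmax(dz, 0) + rules$alpha_down * pmax(-dz, 0)
  }
  u <- unlist(eu); v <- unlist(ev); wt <- unlist(ew)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (length(u)) {
    g <- igraph::add_edges(g, rbind(u, v))
    igraph::E(g)$weight <- wt
  }
  out <- list(graph = g, rules = rules)
  map$.cache[[key]] <- out
  out
}

#' Shortest (Dijkstra) path between two blocks
#'
#' Runs Dijkstra's algorithm on the directed walkability graph. Because
#' ascending costs more than descending, the distance is direction-dependent:
#' `d(a, b) != d(b, a)` in general.
#'
#' @inheritParams is_walkable_edge
#' @param from,to Source and target blocks (`list(x, y)` or `c(x, y)`).
#' @return An object of class `"path_result"`: a list with `distance` (total
#'   cost; `Inf` if unreachable), `blocks` (data frame of x, y, z along the
#'   path; empty if unreachable), and `reachable` (logical).
#' @examples
#' m <- terrain_map(matrix(1L, 6, 6))
#' dijkstra(m, c(0, 0), c(3, 5))$distance  # octile distance 5 + 3*(sqrt(2)-1)
#' @export
dijkstra <- function(map, from, to, rules = movement_rules()) {
  u <- as_block(map, from); v <- as_block(map, to)
  tg <- terrain_graph(map, rules)
  uid <- cell_id(map, u$x, u$y); vid <- cell_id(map, v$x, v$y)
  if (uid == vid) {
    return(structure(list(
      distance = 0,
      blocks = data.frame(x = u$x, y = u$y, z = u$z),
      reachable = TRUE), class = "path_result"))
  }
  dist <- igraph::distances(tg$graph, v = uid, to = vid, mode = "out")[1, 1]
  if (!is.finite(dist)) {
    return(structure(list(distance = Inf,
                          blocks = data.frame(x = integer(), y = integer(),
                                              z = integer()),
                          reachable = FALSE), class = "path_result"))
  }
  vp <- igraph::shortest_paths(tg$graph, from = uid, to = vid,
                               mode = "out", output = "vpath")$vpath[[1]]
  ids <- as.integer(vp)
  xy <- id_to_xy(map, ids)
  structure(list(
    distance = dist,
    blocks = data.frame(x = xy[, "x"], y = xy[, "y"],
                        z = map$elevation[cbind(xy[, "x"] + 1L, xy[, "y"] + 1L)]),
    reachable = TRUE), class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (x$reachable)
    cat("Path: ", nrow(x$blocks), " blocks, Dijkstra distance ",
        format(x$distance, digits = 7), "\n", sep = "")
  else cat("Path: target unreachable (distance Inf)\n")
  invisible(x)
}

#' Dijkstra distances from every block to one target
#'
#' Single-source shortest paths on the edge-reversed graph, so that
#' `field[x+1, y+1]` equals the directed Dijkstra distance from block (x, y)
#' TO the target. Reversal matters: edge weights are direction-asymmetric.
#' Unreachable and obstructed cells carry `Inf`.
#'
#' @inheritParams is_walkable_edge
#' @param to Target block.
#' @return A `width x depth` numeric matrix of costs; 0 at the target.
#' @export
distance_field <- function(map, to, rules = movement_rules()) {
  v <- as_block(map, to)
  tg <- terrain_graph(map, rules)
  vid <- cell_id(map, v$x, v$y)
  d <- igraph::distances(tg$graph, v = vid, mode = "in")[1, ]
  matrix(d, nrow = map$width, ncol = map$depth)
}

#' Octile distance on an unobstructed flat grid
#'
#' Closed-form shortest-path length for 8-connected movement with unit
#' orthogonal and `sqrt(2)` diagonal steps:
#' `max(|dx|, |dy|) + (sqrt(2) - 1) * min(|dx|, |dy|)`. On flat obstacle-free
#' terrain this equals the Dijkstra distance.
#'
#' @param from,to Blocks or `c(x, y)` pairs.
#' @return Numeric distance.
#' @export
octile_distance <- function(from, to) {
  fx <- if (is.list(from)) from$x else from[1]
  fy <- if (is.list(from)) from$y else from[2]
  tx <- if (is.list(to)) to$x else to[1]
  ty <- if (is.list(to)) to$y else to[2]
  dx <- abs(tx - fx); dy <- abs(ty - fy)
  pmax(dx, dy) + (sqrt(2) - 1) * pmin(dx, dy)
}

#' Read and write terrain maps
#'
#' Terrain is serialised either as a single JSON object
#' `{width, depth, elevation, obstructed}` with row-major (x fastest) lists,
#' or as a pair of whitespace-delimited text matrices (elevation and a 0/1
#' obstruction mask) whose rows are y-slices.
#'
#' @param path JSON file path (for the JSON form).
#' @param map A [terrain_map()] (for writing).
#' @param elevation_file,obstruction_file Delimited text matrices; the
#'   obstruction file may be omitted for fully walkable terrain.
#' @return A [terrain_map()] (readers) or the input map invisibly (writer).
#' @examples
#' tf <- system.file("extdata", "example_terrain.json", package = "voxelnav")
#' read_terrain(tf)
#' @export
read_terrain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("width", "depth", "elevation"))
    if (is.null(obj[[f]])) stop("terrain JSON missing field '", f, "'", call. = FALSE)
  w <- as.integer(obj$width); d <- as.integer(obj$depth)
  if (length(obj$elevation) != w * d)
    stop("terrain JSON elevation has length ", length(obj$elevation),
         ", expected width * depth = ", w * d, call. = FALSE)
  elev <- matrix(as.integer(obj$elevation), nrow = w, ncol = d)
  obs <- if (is.null(obj$obstructed)) NULL else {
    if (length(obj$obstructed) != w * d)
      stop("terrain JSON obstructed has wrong length", call. = FALSE)
    matrix(as.logical(obj$obstructed), nrow = w, ncol = d)
  }
  terrain_map(elev, obs)
}

#' @rdname read_terrain
#' @export
write_terrain <- function(map, path) {
  jsonlite::write_json(
    list(width = map$width, depth = map$depth,
         elevation = as.vector(map$elevation),
         obstructed = as.integer(as.vector(map$obstructed))),
    path, auto_unbox = TRUE)
  invisible(map)
}

#' @rdname read_terrain
#' @export
read_terrain_matrices <- function(elevation_file, obstruction_file = NULL) {
  elev <- t(as.matrix(utils::read.table(elevation_file)))
  dimnames(elev) <- NULL
  obs <- NULL
  if (!is.null(obstruction_file)) {
    obs <- t(as.matrix(utils::read.table(obstruction_file))) != 0
    dimnames(obs) <- NULL
    if (!identical(dim(obs), dim(elev)))
      stop("elevation and obstruction matrices differ in shape", call. = FALSE)
  }
  terrain_map(elev, obs)
}
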