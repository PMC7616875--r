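#' Build a regular hexagonal analysis grid over a study region
#'
#' Lays a regular hexagonal lattice of analysis locations (offset rows:
#' horizontal pitch `spacing`, vertical pitch `spacing * sqrt(3)/2`, odd
#' rows shifted by half a pitch) over the region and keeps nodes that fall
#' inside the polygon or within half a spacing of its boundary, so that
#' edge areas remain covered. Every node of such a lattice has up to six
#' equidistant neighbours, which is the adjacency used for the spatial
#' weight matrix in map comparisons.
#'
#' Exactly one of `spacing` and `target_n` must be given. With `target_n`,
#' the spacing is solved by bisection so that the clipped node count is
#' within 5% of the target (the analysis resolution is then a property of
#' the region, as when a fixed number of analysis locations is wanted).
#'
#' @param region A [region_polygon()] / [region_rectangle()] object.
#' @param spacing Centre-to-centre distance between neighbouring nodes
#'   (metres).
#' @param target_n Desired number of grid nodes after clipping.
#' @return An `analysis_grid`: list with `nodes` (data.frame `node`, `x`,
#'   `y`), `spacing`, `region`, and `adjacency` (list of integer neighbour
#'   indices per node).
#' @examples
#' g <- build_hex_grid(region_rectangle(0, 0, 5000, 5000), spacing = 1000)
#' nrow(g$nodes)
#' @export
build_hex_grid <- function(region, spacing = NULL, target_n = NULL) {
  stopifnot(inherits(region, "study_region"))
  if (is.null(spacing) == is.null(target_n)) {
    pgsmap_error("give exactly one of `spacing` or `target_n`", "pgsmap_config_error")
  }

  if (!is.null(target_n)) {
    spacing <- .solve_spacing(region, target_n)
  }
  if (!is.finite(spacing) || spacing <= 0) {
    pgsmap_error("grid spacing must be a positive number", "pgsmap_config_error")
  }
  bb <- region$bbox
  if (spacing > max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])) {
    pgsmap_error("grid spacing exceeds the region extent: no nodes placed",
                 "pgsmap_empty_grid")
  }

  nodes <- .hex_lattice_points(region, spacing)
  if (nrow(nodes) == 0) {
    pgsmap_error("grid spacing exceeds the region extent: no nodes placed",
                 "pgsmap_empty_grid")
  }

  grid <- structure(
    list(
      nodes = data.frame(node = seq_len(nrow(nodes)), x = nodes[, 1], y = nodes[, 2]),
      spacing = spacing,
      region = region,
      adjacency = NULL
    ),
    class = "analysis_grid"
  )
  grid$adjacency <- hex_adjacency(grid)
  grid
}

# Internal: candidate lattice over the bbox, then clip. Origin anchored at
# the bbox lower-left corner so translating the region translates nodes.
.hex_lattice_points <- function(region, spacing) {
  bb <- region$bbox
  vstep <- spacing * sqrt(3) / 2
  # one extra ring outside the bbox so the half-spacing boundary band is covered
  rows <- seq(bb["ymin"] - vstep, bb["ymax"] + vstep, by = vstep)
  pts <- vector("list", length(rows))
  for (r in seq_along(rows)) {
    off <- if (r %% 2 == 0) spacing / 2 else 0
    xs <- seq(bb["xmin"] - spacing + off, bb["xmax"] + spacing, by = spacing)
    pts[[r]] <- cbind(xs, rows[r])
  }
  pts <- do.call(rbind, pts)
  keep <- region_contains(region, pts)
  near <- !keep & .dist_to_boundary(region, pts) <= spacing / 2
  unname(pts[keep | near, , drop = FALSE])
}

# Internal: bisection on spacing so the clipped count lands within 5% of
# target_n. Count is (weakly) decreasing in spacing; start from the
# area-density guess n ~ A / (s^2 * sqrt(3)/2).
.solve_spacing <- function(region, target_n, tol = 0.05, max_iter = 60L) {
  if (target_n < 1) pgsmap_error("target_n must be >= 1", "pgsmap_config_error")
  s0 <- sqrt(2 * region$area / (sqrt(3) * target_n))
  lo <- s0 / 8; hi <- s0 * 8
  count_at <- function(s) nrow(.hex_lattice_points(region, s))
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    n <- count_at(mid)
    if (abs(n - target_n) <= tol * target_n) return(mid)
    if (n > target_n) lo <- mid else hi <- mid
  }
  pgsmap_error(
    sprintf("could not reach within %.0f%% of target_n = %d (last count %d)",
            100 * tol, target_n, n),
    "pgsmap_config_error"
  )
}

#' Hexagonal-lattice adjacency
#'
#' Neighbours are node pairs at (essentially) one lattice spacing:
#' distance at most `1.01 * spacing`. The relation is symmetric with no
#' self-loops; interior nodes have six neighbours, clipped boundary nodes
#' fewer.
#'
#' @param grid An `analysis_grid`.
#' @return List of integer vectors, neighbour indices per node.
#' @export
hex_adjacency <- function(grid) {
  stopifnot(inherits(grid, "analysis_grid"))
  xy <- as.matrix(grid$nodes[, c("x", "y")])
  n <- nrow(xy)
  thr <- 1.01 * grid$spacing
  # bucket by rounded row to avoid the full O(n^2) distance matrix for
  # large grids; neighbours can only lie in the same or adjacent rows
  vstep <- grid$spacing * sqrt(3) / 2
  row_id <- round((xy[, 2] - min(xy[, 2])) / vstep)
  ord <- order(row_id, xy[, 1])
  adj <- vector("list", n)
  by_row <- split(seq_len(n), row_id)
  row_keys <- as.integer(names(by_row))
  for (k in seq_along(by_row)) {
    cand <- unlist(by_row[as.character(row_keys[k] + c(-1L, 0L, 1L))], use.names = FALSE)
    for (i in by_row[[k]]) {
      d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
      nb <- cand[d2 <= thr^2 & cand != i]
      adj[[i]] <- sort(nb)
    }
  }
  adj
}

#' @export
print.analysis_grid <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf(
    "<analysis_grid> %d nodes, spacing %.6g m, neighbours: median %d, max %d\n",
    nrow(x$nodes), x$spacing, stats::median(deg), max(deg)
  ))
  invisible(x)
}

#' Write a grid as GeoJSON points
#'
#' Node index is stored as property `node`; adjacency goes to a separate
#' two-column edge list (`from`, `to`, one row per undirected edge) via
#' [write_grid_edges()].
#'
#' @param grid An `analysis_grid`.
#' @param path Output file.
#' @export
write_grid_geojson <- function(grid, path) {
  write_geojson_points(grid$nodes[, c("x", "y", "node")], path)
}

#' @rdname write_grid_geojson
#' @export
write_grid_edges <- function(grid, path) {
  e <- do.call(rbind, lapply(seq_along(grid$adjacency), function(i) {
    nb <- grid$adjacency[[i]]
    nb <- nb[nb > i]
    if (length(nb)) cbind(from = i, to = nb) else NULL
  }))
  write.table(as.data.frame(e), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
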