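#' Study regions
#'
#' A study region is a simple polygon in planar coordinates (metres).
#' `region_rectangle()` and `region_polygon()` construct one;
#' [read_geojson_polygon()] reads one from a GeoJSON file. All analysis
#' geometry in pgsmap is Euclidean: coordinates are assumed already
#' projected (e.g. a national grid), and no geodesic computation is done
#' anywhere.
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds (metres).
#' @param vertices Two-column numeric matrix of polygon vertices in order,
#'   open ring (first vertex not repeated). Must enclose positive area.
#' @return A `study_region` object: list with `vertices` (open ring
#'   matrix), `area`, and `bbox` (`c(xmin, ymin, xmax, ymax)`).
#' @examples
#' r <- region_rectangle(0, 0, 1000, 1000)
#' r$area
#' @export
region_rectangle <- function(xmin, ymin, xmax, ymax) {
  region_polygon(cbind(
    x = c(xmin, xmax, xmax, xmin),
    y = c(ymin, ymin, ymax, ymax)
  ))
}

#' @rdname region_rectangle
#' @export
region_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3 || !is.numeric(vertices)) {
    pgsmap_error("region vertices must be a numeric matrix with >= 3 rows and 2 columns",
                 "pgsmap_invalid_region")
  }
  # drop a repeated closing vertex if present
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  a <- .shoelace_area(vertices)
  if (!is.finite(a) || a <= 0) {
    pgsmap_error("region polygon has zero or undefined area", "pgsmap_invalid_region")
  }
  structure(
    list(
      vertices = unname(vertices),
      area = a,
      bbox = c(
        xmin = min(vertices[, 1]), ymin = min(vertices[, 2]),
        xmax = max(vertices[, 1]), ymax = max(vertices[, 2])
      )
    ),
    class = "study_region"
  )
}

.shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf(
    "<study_region> %d vertices, area %.4g m^2, bbox [%.6g, %.6g] x [%.6g, %.6g]\n",
    nrow(x$vertices), x$area, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]
  ))
  invisible(x)
}

#' Point-in-region test
#'
#' @param region A [region_polygon()] object.
#' @param xy Two-column matrix of point coordinates.
#' @return Logical vector, `TRUE` for points strictly inside the polygon.
#' @export
region_contains <- function(region, xy) {
  stopifnot(inherits(region, "study_region"))
  xy <- rbind(xy)
  # mgcv::in.out expects a closed boundary loop
  bnd <- rbind(region$vertices, region$vertices[1, ])
  mgcv::in.out(bnd, as.matrix(xy))
}

# Internal: Euclidean distance from points to the polygon boundary,
# minimum over edges of the point-to-segment distance.
.dist_to_boundary <- function(region, xy) {
  v <- region$vertices
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  xy <- rbind(xy)
  out <- rep(Inf, nrow(xy))
  for (e in seq_len(n)) {
    dx <- b[e, 1] - a[e, 1]; dy <- b[e, 2] - a[e, 2]
    len2 <- dx * dx + dy * dy
    tt <- ((xy[, 1] - a[e, 1]) * dx + (xy[, 2] - a[e, 2]) * dy) / len2
    tt <- pmin(pmax(tt, 0), 1)
    px <- a[e, 1] + tt * dx; py <- a[e, 2] + tt * dy
    d <- sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
    out <- pmin(out, d)
  }
  out
}

#' Read and write GeoJSON geometries
#'
#' Minimal GeoJSON support for the formats the pipeline exchanges: a
#' single `Polygon` feature (study region) and `Point` feature
#' collections with scalar properties (grid nodes, fitted maps,
#' environmental surfaces). Coordinates are taken verbatim as planar.
#'
#' @param path File path.
#' @return `read_geojson_polygon()`: a `study_region`.
#'   `read_geojson_points()`: a data.frame with `x`, `y` and one column
#'   per property.
#' @export
read_geojson_polygon <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- switch(g$type %||% "",
    FeatureCollection = g$features[[1]]$geometry,
    Feature = g$geometry,
    Polygon = g,
    pgsmap_error("no Polygon geometry found in GeoJSON", "pgsmap_io_error")
  )
  if (!identical(geom$type, "Polygon")) {
    pgsmap_error("GeoJSON geometry is not a Polygon", "pgsmap_io_error")
  }
  ring <- geom$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  region_polygon(m)
}

#' @rdname read_geojson_polygon
#' @param region A `study_region` to write.
#' @export
write_geojson_polygon <- function(region, path) {
  ring <- rbind(region$vertices, region$vertices[1, ])
  obj <- list(
    type = "Feature",
    properties = stats::setNames(list(), character(0)),
    geometry = list(
      type = "Polygon",
      coordinates = list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_geojson_polygon
#' @export
read_geojson_points <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(g$type, "FeatureCollection")) {
    pgsmap_error("expected a GeoJSON FeatureCollection of Points", "pgsmap_io_error")
  }
  rows <- lapply(g$features, function(f) {
    co <- f$geometry$coordinates
    props <- lapply(f$properties, function(p) if (is.null(p)) NA else p)
    c(list(x = co[[1]], y = co[[2]]), props)
  })
  nm <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(
    lapply(nm, function(k) unlist(lapply(rows, function(r) r[[k]] %||% NA))),
    col.names = nm, check.names = FALSE
  )
  df
}

#' @rdname read_geojson_polygon
#' @param df Data frame with `x`, `y` and property columns to write as
#'   GeoJSON Points.
#' @export
write_geojson_points <- function(df, path) {
  stopifnot(all(c("x", "y") %in% names(df)))
  prop_cols <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      properties = as.list(df[i, prop_cols, drop = FALSE]),
      geometry = list(type = "Point",
                      coordinates = c(df$x[i], df$y[i]))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
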