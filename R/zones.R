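#' Contextual zones
#'
#' A zone is a named simple polygon on the floor plane, in meters. Zones give
#' scene semantics to raw positions: being inside the `PharmacyBasket` zone is
#' the spatial cue that medication preparation may be under way.
#'
#' @param name Zone identifier, unique within a scene.
#' @param polygon Numeric matrix (or coercible two-column structure) of
#'   vertices, one `(x, y)` row per vertex, at least three vertices.
#' @return An object of class `ecoadl_zone`.
#' @export
zone <- function(name, polygon) {
  polygon <- as.matrix(polygon)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("zone name must be a single non-empty string")
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop(sprintf("zone '%s': polygon needs >= 3 (x, y) vertices", name))
  storage.mode(polygon) <- "double"
  if (anyNA(polygon))
    stop(sprintf("zone '%s': polygon has missing coordinates", name))
  if (polygon_self_intersects(polygon))
    stop(sprintf("zone '%s': polygon is self-intersecting", name))
  structure(list(name = name, polygon = unname(polygon)),
            class = "ecoadl_zone")
}

#' @export
print.ecoadl_zone <- function(x, ...) {
  cat(sprintf("<zone %s: %d vertices>\n", x$name, nrow(x$polygon)))
  invisible(x)
}

# Segment-intersection test for non-adjacent polygon edges (simple-polygon
# validation). O(n^2), fine for scene zones with a handful of vertices.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Point-in-polygon test (even-odd rule, boundary-inclusive)
#'
#' Vectorized over points. Points lying exactly on a polygon edge count as
#' inside — a deterministic tie-break so that a person standing on a painted
#' zone boundary is attributed to the zone.
#'
#' @param x,y Numeric vectors of point coordinates (meters).
#' @param polygon Two-column vertex matrix.
#' @return Logical vector, `NA` where `x` or `y` is `NA`.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  px <- polygon[, 1]; py <- polygon[, 2]
  qx <- px[c(2:n, 1L)]; qy <- py[c(2:n, 1L)]
  inside <- rep(FALSE, length(x))
  onedge <- rep(FALSE, length(x))
  eps <- 1e-12
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]; x2 <- qx[k]; y2 <- qy[k]
    # edge-crossing parity for a ray to +infinity in x
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # collinear and within the bounding box -> on the edge
    d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- d <= eps * max(1, len2) &
      x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
      y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps
    on[is.na(on)] <- FALSE
    onedge <- onedge | on
  }
  out <- inside | onedge
  out[is.na(x) | is.na(y)] <- NA
  out
}

#' Read / write scene zones as JSON
#'
#' The on-disk format is a JSON array of `{name, polygon: [[x, y], ...]}`
#' objects with coordinates in meters.
#'
#' @param path File path.
#' @return `read_zones()` returns a named list of [zone()] objects.
#' @export
read_zones <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  zones <- lapply(raw, function(z) {
    poly <- do.call(rbind, lapply(z$polygon, function(v) unlist(v)))
    zone(z$name, poly)
  })
  names(zones) <- vapply(zones, function(z) z$name, character(1))
  if (anyDuplicated(names(zones)))
    stop("duplicate zone names in ", path)
  zones
}

#' @param zones Named list of [zone()] objects.
#' @rdname read_zones
#' @export
write_zones <- function(zones, path) {
  out <- lapply(unname(zones), function(z)
    list(name = z$name,
         polygon = lapply(seq_len(nrow(z$polygon)),
                          function(i) as.numeric(z$polygon[i, ]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default scene geometry
#'
#' A rectangular 6 m x 5 m observation room with one contextual zone per
#' protocol activity plus a 4 m walking corridor along the lower wall.
#' Zone names follow the scene vocabulary of the assessment room
#' (`Drink`, `PharmacyBasket`, `ChairReadingTable`, `Plant`, `TV`, `Phone`,
#' `DeskFinance`, `BusMap`, `WalkCorridor`).
#'
#' @return Named list of [zone()] objects.
#' @export
default_scene <- function() {
  rect <- function(x0, y0, w, h)
    cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
  zs <- list(
    zone("Drink",             rect(0.2, 3.8, 1.0, 1.0)),
    zone("PharmacyBasket",    rect(1.7, 3.8, 1.0, 1.0)),
    zone("Plant",             rect(3.2, 3.8, 1.0, 1.0)),
    zone("TV",                rect(4.7, 3.8, 1.0, 1.0)),
    zone("Phone",             rect(0.2, 2.2, 1.0, 1.0)),
    zone("DeskFinance",       rect(1.9, 2.2, 1.2, 1.0)),
    zone("ChairReadingTable", rect(3.5, 2.2, 1.2, 1.0)),
    zone("BusMap",            rect(5.0, 2.2, 0.8, 1.0)),
    zone("WalkCorridor",      rect(1.0, 0.2, 4.0, 1.0))
  )
  names(zs) <- vapply(zs, function(z) z$name, character(1))
  zs
}
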