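# Planar regions in pixel coordinates.
#
# Convention: 0-based pixel indices, origin top-left, y increasing downward;
# polygon vertices lie on pixel corners, so pixel (x, y) is the unit square
# [x, x+1] x [y, y+1] and rasterization is exact. A region's geometry is a
# list of polygons (MultiPolygon); each polygon is a list of rings (first
# ring outer, remaining rings holes); each ring an m x 2 matrix (x, y),
# not closed (the first vertex is not repeated).

shoelace_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area_px <- function(poly) abs(shoelace_signed(poly))

geometry_area_px <- function(geometry) {
  sum(vapply(geometry, function(polygon) {
    outer <- abs(shoelace_signed(polygon[[1]]))
    holes <- if (length(polygon) > 1) {
      sum(vapply(polygon[-1], function(r) abs(shoelace_signed(r)), numeric(1)))
    } else 0
    outer - holes
  }, numeric(1)))
}

segments_properly_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

validate_simple_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2) {
    abort("a polygon must be an n x 2 numeric matrix of (x, y) vertices.")
  }
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) abort("a polygon ring needs at least 3 distinct vertices.")
  seg <- function(i) list(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      a <- seg(i); b <- seg(j)
      if (segments_properly_intersect(a[[1]], a[[2]], b[[1]], b[[2]])) {
        abort("self-intersecting polygon.")
      }
    }
  }
  if (abs(shoelace_signed(poly)) == 0) abort("degenerate polygon (zero area).")
  poly
}

#' Labelled polygon regions with physical areas
#'
#' @param geometries List of region geometries; each geometry is a list of
#'   polygons, each polygon a list of rings (first ring outer, the rest
#'   holes), each ring an m x 2 matrix of pixel-corner coordinates (0-based,
#'   y down). A single ring or a single polygon may be given bare and is
#'   promoted.
#' @param labels Character vector of region labels (recycled default
#'   `"region_i"`).
#' @param pixel_size_um Pixel size (um) used to convert planar areas to um^2.
#' @return A `region_set`: a list with a `regions` tibble (`label`,
#'   `geometry` list-column, `area_um2`) and `pixel_size_um`.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' rs <- region_set(list(sq), labels = "square", pixel_size_um = 1)
#' rs$regions$area_um2
#' @export
region_set <- function(geometries = list(), labels = NULL, pixel_size_um) {
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  geometries <- lapply(geometries, function(g) {
    if (is.matrix(g)) g <- list(list(g))                # bare ring
    else if (is.list(g) && is.matrix(g[[1]])) g <- list(g) # bare polygon
    lapply(g, function(polygon) lapply(polygon, function(r) {
      r <- as.matrix(r)
      n <- nrow(r)
      if (n >= 2 && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
      if (nrow(r) < 3) abort("every ring needs at least 3 vertices.")
      r
    }))
  })
  if (is.null(labels)) labels <- sprintf("region_%d", seq_along(geometries))
  stopifnot(length(labels) == length(geometries))
  areas <- vapply(geometries, geometry_area_px, numeric(1)) * pixel_size_um^2
  structure(
    list(
      regions = tibble(label = as.character(labels),
                       geometry = geometries, area_um2 = areas),
      pixel_size_um = pixel_size_um
    ),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d region(s) @ %.6g um/px, total %.4f um^2\n",
              nrow(x$regions), x$pixel_size_um, sum(x$regions$area_um2)))
  invisible(x)
}

#' @method tidy region_set
#' @export
tidy.region_set <- function(x, ...) {
  dplyr::mutate(
    x$regions[, c("label", "area_um2")],
    n_polygons = vapply(x$regions$geometry, length, integer(1))
  )
}

# ---- boundary tracing ------------------------------------------------------

DIR_VEC <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)) # codes 0..3 (+x,+y,-x,-y)

# Trace pixel-corner boundary rings of a binary mask (one component or any
# mask). Directed edges keep foreground on the right of travel; at corner
# vertices where four boundary edges meet, the successor is the first
# available direction in priority order: left turn first for 8-connectivity
# (diagonally touching foreground stays one ring set, diagonally touching
# background splits), right turn first for 4-connectivity (the dual).
trace_boundaries <- function(mask, connectivity = 8, offset = c(0L, 0L)) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  y <- (idx - 1L) %% nr      # 0-based pixel y (row)
  x <- (idx - 1L) %/% nr     # 0-based pixel x (col)
  at <- function(xx, yy) {
    ok <- xx >= 0L & xx < nc & yy >= 0L & yy < nr
    out <- rep(FALSE, length(xx))
    out[ok] <- mask[yy[ok] + 1L + xx[ok] * nr]
    out
  }
  sx <- integer(0); sy <- integer(0); dir <- integer(0)
  add <- function(cond, vx, vy, d) {
    sx <<- c(sx, vx[cond]); sy <<- c(sy, vy[cond]); dir <<- c(dir, rep(d, sum(cond)))
  }
  add(!at(x, y - 1L), x, y, 0L)                 # top edge, travel +x
  add(!at(x + 1L, y), x + 1L, y, 1L)            # right edge, travel +y
  add(!at(x, y + 1L), x + 1L, y + 1L, 2L)       # bottom edge, travel -x
  add(!at(x - 1L, y), x, y + 1L, 3L)            # left edge, travel -y
  m <- length(sx)
  key <- sy * (nc + 1L) + sx + 1L
  # end vertex of each edge
  ex <- sx + DIR_VEC[dir + 1L, 1L]
  ey <- sy + DIR_VEC[dir + 1L, 2L]
  ekey <- ey * (nc + 1L) + ex + 1L
  out_edges <- split(seq_len(m), key)
  prio <- if (connectivity == 8) c(3L, 0L, 1L) else c(1L, 0L, 3L) # rel. turns
  used <- rep(FALSE, m)
  rings <- list()
  for (e0 in seq_len(m)) {
    if (used[e0]) next
    ring_x <- integer(0); ring_y <- integer(0); ring_d <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_x <- c(ring_x, sx[e]); ring_y <- c(ring_y, sy[e]); ring_d <- c(ring_d, dir[e])
      k <- ekey[e]
      cand <- out_edges[[as.character(k)]]
      if (length(cand) > 1L) {
        want <- (dir[e] + prio) %% 4L
        nxt <- NA_integer_
        for (w in want) {
          hit <- cand[dir[cand] == w]
          if (length(hit)) { nxt <- hit[1L]; break }
        }
      } else {
        nxt <- cand[1L]
      }
      if (nxt == e0) break
      e <- nxt
    }
    # merge collinear runs
    keep <- c(TRUE, ring_d[-1] != ring_d[-length(ring_d)])
    # the first vertex may also be mid-run relative to the last edge
    if (ring_d[length(ring_d)] == ring_d[1]) keep[1] <- length(ring_d) == 1L
    ring <- cbind(ring_x[keep] + offset[1], ring_y[keep] + offset[2])
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

# group traced rings into MultiPolygon nesting: positive signed area = outer
# (y-down, foreground-on-right orientation), negative = hole; each hole is
# attached to the outer ring containing its representative interior point.
nest_rings <- function(rings) {
  signs <- vapply(rings, shoelace_signed, numeric(1))
  outers <- which(signs > 0)
  holes <- which(signs < 0)
  polys <- lapply(outers, function(i) list(rings[[i]]))
  if (length(holes) && length(outers)) {
    for (h in holes) {
      r <- rings[[h]]
      d <- r[2, ] - r[1, ]
      d <- d / max(abs(d))
      left <- c(d[2], -d[1]) # background (hole interior) lies left of travel
      p <- r[1, ] + 0.5 * d + 0.5 * left
      owner <- NULL
      for (k in seq_along(outers)) {
        if (point_in_polygon(p[1], p[2], rings[[outers[k]]])) { owner <- k; break }
      }
      if (is.null(owner)) owner <- 1L
      polys[[owner]] <- c(polys[[owner]], list(r))
    }
  }
  polys
}

#' Polygonize a binary mask into labelled regions
#'
#' One region per connected component of true pixels. Polygons trace the
#' pixel-corner boundary, so each region's planar area equals its component's
#' pixel count exactly; [regions_to_mask()] inverts the operation.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Pixel size (um).
#' @param connectivity 4 or 8 (default 8).
#' @param min_area_um2 Components smaller than this are dropped.
#' @param label_prefix Prefix for generated region labels.
#' @return A [region_set()].
#' @examples
#' m <- matrix(FALSE, 6, 6); m[2:4, 2:5] <- TRUE
#' mask_to_regions(m, pixel_size_um = 2)$regions$area_um2 # 12 px * 4 um^2
#' @export
mask_to_regions <- function(mask, pixel_size_um, connectivity = 8,
                            min_area_um2 = 0, label_prefix = "region") {
  stopifnot(is.matrix(mask), is.logical(mask), nrow(mask) > 0, ncol(mask) > 0)
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  geoms <- list(); labels <- character(0)
  for (i in seq_len(n)) {
    idx <- which(lab == i)
    if (length(idx) * pixel_size_um^2 < min_area_um2) next
    ry <- (idx - 1L) %% nrow(mask)
    rx <- (idx - 1L) %/% nrow(mask)
    x0 <- min(rx); x1 <- max(rx); y0 <- min(ry); y1 <- max(ry)
    sub <- matrix(FALSE, y1 - y0 + 1L, x1 - x0 + 1L)
    sub[cbind(ry - y0 + 1L, rx - x0 + 1L)] <- TRUE
    rings <- trace_boundaries(sub, connectivity, offset = c(x0, y0))
    geoms[[length(geoms) + 1L]] <- nest_rings(rings)
    labels <- c(labels, sprintf("%s_%d", label_prefix, length(labels) + 1L))
  }
  region_set(geoms, labels, pixel_size_um)
}

# even-odd rasterization of a set of rings onto a W x H pixel grid
rasterize_rings <- function(rings, width_px, height_px) {
  mask <- matrix(FALSE, height_px, width_px)
  edges <- do.call(rbind, lapply(rings, function(r) {
    nx <- c(r[-1, 1], r[1, 1]); ny <- c(r[-1, 2], r[1, 2])
    cbind(r[, 1], r[, 2], nx, ny)
  }))
  if (is.null(edges) || nrow(edges) == 0) return(mask)
  ymin <- pmin(edges[, 2], edges[, 4])
  ymax <- pmax(edges[, 2], edges[, 4])
  keep <- ymin != ymax
  edges <- edges[keep, , drop = FALSE]
  ymin <- ymin[keep]; ymax <- ymax[keep]
  if (nrow(edges) == 0) return(mask)
  for (j in 0:(height_px - 1L)) {
    yc <- j + 0.5
    hit <- which(ymin <= yc & yc < ymax)
    if (!length(hit)) next
    xc <- edges[hit, 1] +
      (yc - edges[hit, 2]) * (edges[hit, 3] - edges[hit, 1]) /
      (edges[hit, 4] - edges[hit, 2])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      lo <- floor(xc[k] - 0.5) + 1L
      hi <- ceiling(xc[k + 1L] - 0.5) - 1L
      lo <- max(lo, 0L); hi <- min(hi, width_px - 1L)
      if (lo <= hi) mask[j + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  mask
}

#' Rasterize regions back to a binary mask
#'
#' Even-odd fill at pixel centres; exact inverse of [mask_to_regions()] for
#' pixel-aligned polygons.
#'
#' @param regions A [region_set()], or a bare ring / polygon / geometry as
#'   accepted by [region_set()].
#' @param width_px,height_px Output raster size.
#' @return Logical matrix.
#' @export
regions_to_mask <- function(regions, width_px, height_px) {
  geoms <- if (inherits(regions, "region_set")) {
    regions$regions$geometry
  } else {
    region_set(list(regions), pixel_size_um = 1)$regions$geometry
  }
  mask <- matrix(FALSE, height_px, width_px)
  for (g in geoms) {
    rings <- unlist(g, recursive = FALSE)
    mask <- mask | rasterize_rings(rings, width_px, height_px)
  }
  mask
}

# ---- GeoJSON ---------------------------------------------------------------

ring_coords_closed <- function(r) {
  r <- rbind(r, r[1, ])
  lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
}

#' Write regions as a GeoJSON FeatureCollection
#'
#' Coordinates are written in pixel space (0-based, y down); each region
#' becomes one feature with `label` and `area_um2` properties. The pixel-size
#' calibration is stored as a top-level `pixel_size_um` member.
#'
#' @param regions A [region_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  features <- purrr::pmap(regions$regions, function(label, geometry, area_um2) {
    geom <- if (length(geometry) == 1L) {
      list(type = "Polygon",
           coordinates = lapply(geometry[[1]], ring_coords_closed))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(geometry, function(p) lapply(p, ring_coords_closed)))
    }
    list(
      type = "Feature",
      geometry = geom,
      properties = list(label = label, area_um2 = area_um2)
    )
  })
  doc <- list(
    type = "FeatureCollection",
    pixel_size_um = regions$pixel_size_um,
    features = features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

parse_ring <- function(coords) {
  r <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  n <- nrow(r)
  if (n >= 2 && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
  r
}

#' Read a GeoJSON FeatureCollection of polygon regions
#'
#' Accepts Polygon and MultiPolygon features; the label is taken from the
#' `label` property, falling back to a QuPath-style
#' `classification$name`, then to a generated name.
#'
#' @param path GeoJSON file.
#' @param pixel_size_um Calibration override; required if the file carries no
#'   top-level `pixel_size_um`.
#' @return A [region_set()].
#' @export
read_regions_geojson <- function(path, pixel_size_um = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$type) || doc$type != "FeatureCollection") {
    abort("not a GeoJSON FeatureCollection.")
  }
  ps <- pixel_size_um %||% doc$pixel_size_um
  if (is.null(ps)) {
    abort(paste0(
      "no pixel-size calibration in '", path,
      "'; pass `pixel_size_um` explicitly."
    ))
  }
  feats <- doc$features %||% list()
  geoms <- list(); labels <- character(0)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    if (is.null(g$type) || !g$type %in% c("Polygon", "MultiPolygon")) {
      abort(sprintf("feature %d: non-polygon geometry (%s).", i,
                    g$type %||% "missing"))
    }
    geom <- if (g$type == "Polygon") {
      list(lapply(g$coordinates, parse_ring))
    } else {
      lapply(g$coordinates, function(p) lapply(p, parse_ring))
    }
    lab <- f$properties$label %||% f$properties$classification$name %||%
      sprintf("region_%d", i)
    geoms[[length(geoms) + 1L]] <- geom
    labels <- c(labels, lab)
  }
  region_set(geoms, labels, pixel_size_um = as.numeric(ps))
}
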