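# Planar geometry in a local azimuthal-equidistant frame.
#
# Polygons are stored as "multipolygon" lists: a list of parts, each part a
# list of rings, each ring an un-closed two-column matrix (lon, lat, WGS84
# degrees). The first ring of a part is the outer boundary; any further rings
# are holes. Containment uses even-odd ray casting, so hole rings need no
# particular orientation.

.EARTH_RADIUS_M <- 6371008.8  # mean Earth radius, metres (spherical model)

#' Project lon/lat to a local azimuthal equidistant plane
#'
#' Forward azimuthal-equidistant projection on a sphere, centred at
#' `(lon0, lat0)`. Distances from the centre are preserved exactly; distances
#' between off-centre points are accurate to well under a percent at the
#' scales of a park plus its buffer (tens of kilometres).
#'
#' @param coords two-column matrix of lon/lat degrees.
#' @param lon0,lat0 projection centre in degrees.
#' @return two-column matrix of x/y metres.
#' @export
aeqdForward <- function(coords, lon0, lat0) {
  coords <- matrix(coords, ncol = 2L)
  lam <- coords[, 1L] * pi / 180
  phi <- coords[, 2L] * pi / 180
  lam0 <- lon0 * pi / 180
  phi0 <- lat0 * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c <- acos(cosc)
  k <- ifelse(c < 1e-12, 1, c / sin(c))
  x <- .EARTH_RADIUS_M * k * cos(phi) * sin(lam - lam0)
  y <- .EARTH_RADIUS_M * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x, y)
}

#' Inverse azimuthal equidistant projection
#'
#' @param xy two-column matrix of x/y metres.
#' @param lon0,lat0 projection centre in degrees.
#' @return two-column matrix of lon/lat degrees.
#' @export
aeqdInverse <- function(xy, lon0, lat0) {
  xy <- matrix(xy, ncol = 2L)
  lam0 <- lon0 * pi / 180
  phi0 <- lat0 * pi / 180
  rho <- sqrt(xy[, 1L]^2 + xy[, 2L]^2)
  c <- rho / .EARTH_RADIUS_M
  phi <- ifelse(rho < 1e-9, phi0,
    asin(cos(c) * sin(phi0) + xy[, 2L] * sin(c) * cos(phi0) / pmax(rho, 1e-12)))
  lam <- lam0 + atan2(
    xy[, 1L] * sin(c),
    rho * cos(phi0) * cos(c) - xy[, 2L] * sin(phi0) * sin(c)
  )
  cbind(lam * 180 / pi, phi * 180 / pi)
}

# Even-odd ray casting; pts and ring are two-column matrices in a common
# planar or geographic frame. Returns logical vector, boundary counts inside.
.pointsInRing <- function(pts, ring) {
  n <- nrow(ring)
  xs <- ring[, 1L]; ys <- ring[, 2L]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  px <- pts[, 1L]; py <- pts[, 2L]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
      hit <- which(crosses)[xint > px[crosses]]
      inside[hit] <- !inside[hit]
    }
  }
  inside
}

#' Test points against a multipolygon (even-odd rule)
#'
#' @param pts two-column lon/lat matrix.
#' @param geom multipolygon list (parts of rings).
#' @return logical vector, one entry per point.
#' @export
pointsInPolygon <- function(pts, geom) {
  pts <- matrix(pts, ncol = 2L)
  inside <- rep(FALSE, nrow(pts))
  for (part in geom) {
    for (ring in part) {
      inside <- xor(inside, .pointsInRing(pts, ring))
    }
  }
  inside
}

# Minimum distance (same planar units) from each point to a set of segments.
.ptSegDist <- function(px, py, ax, ay, bx, by) {
  best <- rep(Inf, length(px))
  for (i in seq_along(ax)) {
    dx <- bx[i] - ax[i]; dy <- by[i] - ay[i]
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax[i]) * dx + (py - ay[i]) * dy) / len2))
    d2 <- (px - (ax[i] + t * dx))^2 + (py - (ay[i] + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Distance from points to a multipolygon boundary, in metres
#'
#' Projects the points and every ring of `geom` into an azimuthal-equidistant
#' plane centred on the polygon centroid and measures planar point-to-segment
#' distances. Points inside the polygon still get their (positive) distance to
#' the nearest boundary; use [pointsInPolygon()] to distinguish.
#'
#' @param pts two-column lon/lat matrix.
#' @param geom multipolygon list.
#' @return numeric vector of metres.
#' @export
boundaryDistance <- function(pts, geom) {
  pts <- matrix(pts, ncol = 2L)
  ctr <- geomCentroid(geom)
  p <- aeqdForward(pts, ctr[1L], ctr[2L])
  best <- rep(Inf, nrow(pts))
  for (part in geom) {
    for (ring in part) {
      r <- aeqdForward(ring, ctr[1L], ctr[2L])
      n <- nrow(r)
      nxt <- c(2:n, 1L)
      best <- pmin(best, .ptSegDist(p[, 1L], p[, 2L],
                                    r[, 1L], r[, 2L],
                                    r[nxt, 1L], r[nxt, 2L]))
    }
  }
  best
}

#' Vertex-average centroid of a multipolygon (outer rings only)
#' @keywords internal
geomCentroid <- function(geom) {
  verts <- do.call(rbind, lapply(geom, function(part) part[[1L]]))
  c(mean(verts[, 1L]), mean(verts[, 2L]))
}

#' Bounding box (lon/lat) of a multipolygon
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @keywords internal
geomBBox <- function(geom) {
  verts <- do.call(rbind, unlist(geom, recursive = FALSE))
  c(min(verts[, 1L]), min(verts[, 2L]), max(verts[, 1L]), max(verts[, 2L]))
}

#' Planar area of a multipolygon in square metres
#'
#' Shoelace area in the centroid-centred azimuthal-equidistant plane; holes
#' subtract.
#'
#' @param geom multipolygon list.
#' @return area in m^2.
#' @export
geomArea <- function(geom) {
  ctr <- geomCentroid(geom)
  total <- 0
  for (part in geom) {
    for (k in seq_along(part)) {
      r <- aeqdForward(part[[k]], ctr[1L], ctr[2L])
      n <- nrow(r)
      nxt <- c(2:n, 1L)
      a <- abs(sum(r[, 1L] * r[nxt, 2L] - r[nxt, 1L] * r[, 2L])) / 2
      total <- total + if (k == 1L) a else -a
    }
  }
  total
}

#' Buffer a park polygon by a ground distance in metres
#'
#' Expands the park geometry outward by `buffer_m` metres. The geometry is
#' projected to an azimuthal-equidistant plane centred on the park centroid
#' (so the buffer distance is true ground metres, not degrees, even at high
#' latitudes), offset with round joins, and projected back to WGS84.
#'
#' @param park a single-park [ParkSet] or a multipolygon list.
#' @param buffer_m non-negative buffer distance in metres; `0` returns the
#'   geometry unchanged.
#' @return a multipolygon list in WGS84.
#' @examples
#' ps <- simulateParks(simulationConfig(n_parks = 1, seed = 1))$parks
#' buf <- bufferPark(ps[1], 10000)
#' @export
bufferPark <- function(park, buffer_m) {
  geom <- if (is(park, "ParkSet")) parkGeoms(park)[[1L]] else park
  stopifnot(is.list(geom), length(geom) >= 1L)
  if (buffer_m < 0) stop("buffer_m must be non-negative")
  if (buffer_m == 0) return(geom)
  ctr <- geomCentroid(geom)
  contours <- lapply(unlist(geom, recursive = FALSE), function(ring) {
    xy <- aeqdForward(ring, ctr[1L], ctr[2L])
    list(x = xy[, 1L], y = xy[, 2L])
  })
  # even-odd ring set; polyoffset resolves orientations internally
  off <- polyclip::polyoffset(contours, buffer_m,
                              jointype = "round", arctol = buffer_m / 200)
  if (length(off) == 0L) stop("buffering produced empty geometry")
  lapply(off, function(cc) {
    ring <- aeqdInverse(cbind(cc$x, cc$y), ctr[1L], ctr[2L])
    list(ring)
  })
}
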