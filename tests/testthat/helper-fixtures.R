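# Shared fixture builders and independent oracles.

# Axis-aligned square multipolygon centred at (lon0, lat0), half-width in deg.
squareGeom <- function(lon0, lat0, half_deg) {
  ring <- cbind(lon0 + c(-1, 1, 1, -1) * half_deg,
                lat0 + c(-1, -1, 1, 1) * half_deg)
  list(list(ring))
}

squareParkSet <- function(lons, lats, half_deg, ids = NULL,
                          country = "XX") {
  n <- length(lons)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  half_deg <- rep_len(half_deg, n)
  ParkSet(park_id = ids, country = country,
          geoms = lapply(seq_len(n), function(i)
            squareGeom(lons[i], lats[i], half_deg[i])))
}

# GeoJSON text for square parks (for reader tests).
writeSquareParksGeoJSON <- function(path, lons, lats, half_deg,
                                    ids = sprintf("P%02d", seq_along(lons))) {
  half_deg <- rep_len(half_deg, length(lons))
  feats <- lapply(seq_along(lons), function(i) {
    xs <- lons[i] + c(-1, 1, 1, -1, -1) * half_deg[i]
    ys <- lats[i] + c(-1, -1, 1, 1, -1) * half_deg[i]
    coords <- lapply(seq_along(xs), function(k) c(xs[k], ys[k]))
    list(type = "Feature",
         properties = list(park_id = ids[i], name = ids[i], country = "XX"),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# Minimal posts data.frame (timestamps UTC).
makePosts <- function(user, platform, time_utc, lon, lat) {
  data.frame(user_id = user, platform = platform,
             timestamp = as.POSIXct(time_utc, tz = "UTC"),
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

writePostsCSV <- function(path, lines) {
  writeLines(c("user_id,platform,timestamp,lon,lat", lines), path)
  path
}

# ---- independent oracles -------------------------------------------------

# Brute-force assignment: sp containment + geosphere geodesic distances.
# Returns data.frame(park_id, mode, dist). `skip` marks points whose decision
# is within `tol_frac` of the buffer threshold or of a distance tie (the
# implementation measures planar AEQD distance on a sphere, the oracle
# ellipsoidal geodesics, so near-threshold decisions may differ either way).
oracleAssign <- function(pts, parks, buffer_m, tol_frac = 0.01) {
  ids <- parkIds(parks)
  geoms <- parkGeoms(parks)
  n <- nrow(pts)
  out <- data.frame(park_id = rep(NA_character_, n),
                    mode = rep("unassigned", n), dist = rep(NA_real_, n),
                    skip = rep(FALSE, n), stringsAsFactors = FALSE)
  dmat <- matrix(Inf, n, length(ids))
  inmat <- matrix(FALSE, n, length(ids))
  for (k in seq_along(ids)) {
    for (part in geoms[[k]]) {
      ring <- part[[1L]]
      inmat[, k] <- inmat[, k] |
        sp::point.in.polygon(pts[, 1L], pts[, 2L], ring[, 1L], ring[, 2L]) > 0
      closed <- rbind(ring, ring[1L, ])
      dmat[, k] <- pmin(dmat[, k],
                        geosphere::dist2Line(pts, closed)[, "distance"])
    }
  }
  ord <- order(ids)
  for (i in seq_len(n)) {
    ins <- which(inmat[i, ])
    if (length(ins)) {
      pick <- ins[order(ids[ins])][1L]
      out$park_id[i] <- ids[pick]; out$mode[i] <- "interior"; out$dist[i] <- 0
      next
    }
    d <- dmat[i, ]
    within <- which(d <= buffer_m)
    if (!length(within)) {
      # near-threshold: metric disagreement possible
      if (min(d) <= buffer_m * (1 + tol_frac)) out$skip[i] <- TRUE
      next
    }
    dmin <- min(d[within])
    cand <- within[d[within] <= dmin * (1 + tol_frac)]
    if (length(cand) > 1L || dmin >= buffer_m * (1 - tol_frac)) {
      out$skip[i] <- TRUE
    }
    pick <- within[order(d[within], ids[within])][1L]
    out$park_id[i] <- ids[pick]; out$mode[i] <- "buffer"; out$dist[i] <- dmin
  }
  out
}

# Independent SUD recount: nested tapply over explicit factors.
oracleMonthlyCount <- function(user_days, year) {
  ud <- user_days[format(user_days$date, "%Y") == as.character(year), ]
  key <- interaction(ud$park_id, format(ud$date, "%m"), ud$platform,
                     drop = FALSE)
  table(droplevels(key))
}

# Closed-form Spearman on untied ranks: 1 - 6*sum(d^2) / (n(n^2-1)).
oracleSpearmanUntied <- function(rank_a, rank_b) {
  n <- length(rank_a)
  1 - 6 * sum((rank_a - rank_b)^2) / (n * (n^2 - 1))
}

# Textbook Pearson.
oraclePearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sxy / (sqrt(sum((x - mean(x))^2) / n) * sqrt(sum((y - mean(y))^2) / n))
}

# Sample ACF by the direct estimator r_k = c_k / c_0, c_k = sum/n.
oracleACF <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  c0 <- sum(xc^2) / n
  vapply(0:max_lag, function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / n / c0, numeric(1))
}

# PACF via Yule-Walker solves on the ACF (independent of stats::pacf).
oraclePACF <- function(x, max_lag) {
  r <- oracleACF(x, max_lag)[-1L]
  vapply(seq_len(max_lag), function(k) {
    if (k == 1L) return(r[1L])
    R <- stats::toeplitz(c(1, r[seq_len(k - 1L)]))
    solve(R, r[seq_len(k)])[k]
  }, numeric(1))
}

# Tie-corrected Kruskal-Wallis H from first principles.
oracleKW_H <- function(values, groups) {
  N <- length(values)
  r <- rank(values, ties.method = "average")
  Rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
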