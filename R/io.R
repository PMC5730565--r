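#' Dialect for delimited post files
#'
#' Describes how a delimited text file of geotagged posts maps onto the five
#' canonical fields. Coordinate columns are always named explicitly (never
#' positional) to avoid lon/lat swaps.
#'
#' @param user_id,platform,timestamp,lon,lat header names in the file.
#' @param sep field separator.
#' @param thousands optional thousands-separator character to strip from
#'   numeric fields (e.g. `" "` for `"1 204"`).
#' @return a list of class `"post_dialect"`.
#' @export
postDialect <- function(user_id = "user_id", platform = "platform",
                        timestamp = "timestamp", lon = "lon", lat = "lat",
                        sep = ",", thousands = NULL) {
  structure(list(user_id = user_id, platform = platform,
                 timestamp = timestamp, lon = lon, lat = lat,
                 sep = sep, thousands = thousands),
            class = "post_dialect")
}

.stripThousands <- function(x, thousands) {
  if (is.null(thousands)) return(x)
  gsub(thousands, "", x, fixed = TRUE)
}

#' Parse ISO 8601 timestamps with timezone offsets
#'
#' Accepts `...T12:34:56+02:00`, `...T12:34:56+0200`, a trailing `Z`, or a
#' space instead of `T`. Timestamps lacking an offset are interpreted as UTC;
#' their count is returned in the `"assumed_utc"` attribute so callers can
#' flag them.
#'
#' @param x character vector.
#' @return POSIXct in UTC with attribute `assumed_utc` (integer count);
#'   unparsable entries become `NA`.
#' @export
parseTimestamps <- function(x) {
  x <- trimws(x)
  x <- sub(" ", "T", x, fixed = TRUE)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  has_offset <- grepl("[+-][0-9]{4}$", x)
  x[!has_offset & nzchar(x)] <- paste0(x[!has_offset & nzchar(x)], "+0000")
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  attr(out, "assumed_utc") <- sum(!has_offset & !is.na(out))
  out
}

.reportRejections <- function(what, n_in, n_ok, reasons) {
  n_rej <- n_in - n_ok
  if (n_rej > 0L)
    message(sprintf("%s: rejected %d of %d row(s) [%s]",
                    what, n_rej, n_in,
                    paste(sprintf("%s: %d", names(reasons), reasons),
                          collapse = ", ")))
  invisible(n_rej)
}

#' Read geotagged social-media posts
#'
#' Reads a delimited text file of posts and validates every row: coordinates
#' must lie in the WGS84 domain, timestamps must parse, and user and platform
#' must be non-empty. Failing rows are rejected, counted and reported via a
#' message — never dropped silently. `rows_in = rows_accepted + rows_rejected`
#' always holds.
#'
#' @param path file path.
#' @param dialect a [postDialect()] describing the file layout.
#' @return data.frame with columns `user_id`, `platform`, `timestamp`
#'   (POSIXct, UTC), `lon`, `lat`; attributes `rows_in`, `rows_rejected`,
#'   `rejection_reasons`, `assumed_utc`.
#' @export
readPosts <- function(path, dialect = postDialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- unlist(dialect[c("user_id", "platform", "timestamp", "lon", "lat")])
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("posts file is missing required column(s): ",
         paste(miss, collapse = ", "))
  n_in <- nrow(raw)
  if (n_in == 0L) {
    warning("posts file contains no data rows: ", path)
    out <- data.frame(user_id = character(), platform = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric())
    attr(out, "rows_in") <- 0L
    attr(out, "rows_rejected") <- 0L
    return(out)
  }
  lon <- suppressWarnings(
    as.numeric(.stripThousands(raw[[dialect$lon]], dialect$thousands)))
  lat <- suppressWarnings(
    as.numeric(.stripThousands(raw[[dialect$lat]], dialect$thousands)))
  ts <- parseTimestamps(raw[[dialect$timestamp]])
  user <- trimws(raw[[dialect$user_id]])
  plat <- trimws(raw[[dialect$platform]])

  bad_coord <- is.na(lon) | is.na(lat) | lon < -180 | lon > 180 |
    lat < -90 | lat > 90
  bad_ts <- is.na(ts)
  bad_id <- is.na(user) | user == "" | is.na(plat) | plat == ""
  keep <- !(bad_coord | bad_ts | bad_id)

  out <- data.frame(user_id = user[keep], platform = plat[keep],
                    timestamp = ts[keep], lon = lon[keep], lat = lat[keep],
                    stringsAsFactors = FALSE)
  reasons <- c(coordinate = sum(bad_coord), timestamp = sum(bad_ts & !bad_coord),
               identifier = sum(bad_id & !bad_coord & !bad_ts))
  .reportRejections("readPosts", n_in, nrow(out), reasons[reasons > 0])
  attr(out, "rows_in") <- n_in
  attr(out, "rows_rejected") <- n_in - nrow(out)
  attr(out, "rejection_reasons") <- reasons
  attr(out, "assumed_utc") <- attr(ts, "assumed_utc")
  out
}

# GeoJSON coordinates -> multipolygon list (list of parts of rings).
.geojsonToGeom <- function(geometry) {
  closeOff <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    if (nrow(m) >= 2L && all(m[1L, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    m
  }
  type <- geometry$type
  if (identical(type, "Polygon")) {
    list(lapply(geometry$coordinates, closeOff))
  } else if (identical(type, "MultiPolygon")) {
    lapply(geometry$coordinates, function(part) lapply(part, closeOff))
  } else {
    stop("unsupported geometry type: ", type)
  }
}

#' Read park polygons from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection of Polygon/MultiPolygon features with
#' a `park_id` property (plus optional `name`, `country`) into a
#' [ParkSet-class]. Coordinates must already be WGS84 lon/lat, as RFC 7946
#' requires. Duplicate `park_id` values or unreadable geometries are fatal.
#'
#' @param path GeoJSON file path.
#' @return a [ParkSet-class].
#' @export
readParks <- function(path) {
  stopifnot(file.exists(path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0L) stop("no features in ", path)
  ids <- vapply(feats, function(f) {
    id <- f$properties$park_id
    if (is.null(id) || !nzchar(as.character(id)))
      stop("feature without park_id property")
    as.character(id)
  }, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate park_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nm <- vapply(feats, function(f)
    as.character(f$properties$name %||% f$properties$park_id), character(1L))
  ctry <- vapply(feats, function(f)
    as.character(f$properties$country %||% NA_character_), character(1L))
  geoms <- lapply(feats, function(f) .geojsonToGeom(f$geometry))
  ParkSet(park_id = ids, name = nm, country = ctry, geoms = geoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read exclusion zones from GeoJSON
#'
#' Exclusion zones are polygons whose posts are removed before park
#' assignment. A zone may be restricted to one platform via a `platform`
#' property; zones without that property apply to every platform.
#'
#' @param path GeoJSON file path.
#' @return list of zones, each `list(geom = multipolygon, platform =
#'   character-or-NA)`.
#' @export
readExclusions <- function(path) {
  stopifnot(file.exists(path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    list(geom = .geojsonToGeom(f$geometry),
         platform = as.character(f$properties$platform %||% NA_character_))
  })
}

#' Read official monthly visitor statistics
#'
#' Reads a CSV with columns `park_id`, `year`, `month`, `visitors`. A
#' duplicated (park, year, month) key is fatal; rows with negative or
#' unparsable counts are rejected with a report. A thousands separator (e.g.
#' `"1 204"`) can be stripped via `thousands`.
#'
#' @param path file path.
#' @param thousands optional thousands-separator character.
#' @return data.frame `park_id`, `year`, `month`, `visitors` with attributes
#'   `rows_in`, `rows_rejected`.
#' @export
readVisitorStats <- function(path, thousands = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("park_id", "year", "month", "visitors")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("visitor statistics missing column(s): ", paste(miss, collapse = ", "))
  n_in <- nrow(raw)
  year <- suppressWarnings(as.integer(raw$year))
  month <- suppressWarnings(as.integer(raw$month))
  visitors <- suppressWarnings(
    as.numeric(.stripThousands(raw$visitors, thousands)))
  bad <- is.na(year) | is.na(month) | month < 1L | month > 12L |
    is.na(visitors) | visitors < 0 | raw$park_id == ""
  out <- data.frame(park_id = raw$park_id[!bad], year = year[!bad],
                    month = month[!bad], visitors = visitors[!bad],
                    stringsAsFactors = FALSE)
  key <- paste(out$park_id, out$year, out$month, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (park_id, year, month) in ", path)
  .reportRejections("readVisitorStats", n_in, nrow(out),
                    c(invalid = sum(bad)))
  attr(out, "rows_in") <- n_in
  attr(out, "rows_rejected") <- sum(bad)
  out
}

#' Write posts in the canonical dialect
#'
#' Timestamps are written as ISO 8601 UTC with an explicit `+00:00` offset,
#' so a write/read round trip is lossless.
#'
#' @param posts data.frame as returned by [readPosts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePosts <- function(posts, path) {
  out <- posts
  out$timestamp <- paste0(format(posts$timestamp, "%Y-%m-%dT%H:%M:%S",
                                 tz = "UTC"), "+00:00")
  out$lon <- formatC(posts$lon, format = "g", digits = 15)
  out$lat <- formatC(posts$lat, format = "g", digits = 15)
  utils::write.csv(out[, c("user_id", "platform", "timestamp", "lon", "lat")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a ParkSet as GeoJSON
#'
#' @param parks a [ParkSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeParksGeoJSON <- function(parks, path) {
  m <- parkMeta(parks)
  feats <- lapply(seq_len(length(parks)), function(i) {
    geom <- parkGeoms(parks)[[i]]
    coords <- lapply(geom, function(part)
      lapply(part, function(ring) {
        closed <- rbind(ring, ring[1L, ])
        lapply(seq_len(nrow(closed)), function(k) as.numeric(closed[k, ]))
      }))
    list(type = "Feature",
         properties = list(park_id = m$park_id[i], name = m$name[i],
                           country = m$country[i]),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and re-read a MonthlyMatrix as CSV
#'
#' The on-disk layout is one row per (park_id, year, month) with one column
#' per source, in the matrix's column order. `readMonthlyMatrix()` restores
#' the object to full precision (round-trip safe).
#'
#' @param x a [MonthlyMatrix-class].
#' @param path CSV path.
#' @return `writeMonthlyMatrix`: `path` invisibly; `readMonthlyMatrix`: a
#'   [MonthlyMatrix-class].
#' @export
writeMonthlyMatrix <- function(x, path) {
  cnt <- sudCounts(x)
  full <- as.data.frame(lapply(seq_len(ncol(cnt)), function(j) {
    v <- cnt[, j]
    if (all(v == round(v))) format(v, scientific = FALSE, trim = TRUE)
    else sprintf("%.17g", v)  # full double precision for round-tripping
  }), optional = TRUE)
  df <- cbind(monthKeys(x), full)
  tp <- as.data.frame(SummarizedExperiment::colData(x))$type
  names(df)[-(1:3)] <- colnames(x)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  attr_path <- paste0(path, ".types")
  writeLines(paste(colnames(x), tp, sep = ","), attr_path)
  invisible(path)
}

#' @rdname writeMonthlyMatrix
#' @export
readMonthlyMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cnt <- as.matrix(df[, -(1:3), drop = FALSE])
  type_path <- paste0(path, ".types")
  type <- if (file.exists(type_path)) {
    tt <- utils::read.csv(type_path, header = FALSE)
    tt$V2[match(colnames(cnt), tt$V1)]
  } else {
    ifelse(colnames(cnt) == "official", "official",
           ifelse(colnames(cnt) == "combined", "combined", "platform"))
  }
  MonthlyMatrix(cnt, df$park_id, df$year, df$month, type = type)
}
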