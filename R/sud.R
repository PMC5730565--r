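#' Collapse assigned posts into social-media user-days
#'
#' A user-day is one distinct (user, park, calendar day, platform) tuple: a
#' user posting five times from one park on one day counts once, while one
#' post on each of three consecutive days counts three times — matching how
#' trail counters tally a multi-day visitor once per day. Only posts assigned
#' `interior` or `buffer` contribute; `unassigned` and `excluded` posts are
#' ignored. Calendar days are taken in `tz`, the reporting timezone, after
#' converting each timestamp from its recorded offset; a post at 23:30 UTC
#' rolls to the next day under a UTC+2 reporting timezone.
#'
#' @param assigned data.frame from [assignPosts()].
#' @param tz reporting timezone (Olson name or `"UTC"`). May also be a named
#'   character vector keyed by country code, in which case `parks` must be
#'   given to map each park to its country.
#' @param parks optional [ParkSet-class], needed only for per-country `tz`.
#' @return data.frame `user_id`, `park_id`, `date` (Date), `platform`, one
#'   row per distinct user-day.
#' @examples
#' sim <- simulateDataset(simulationConfig(n_parks = 2, seed = 3))
#' ud <- computeUserDays(assignPosts(sim$posts, sim$parks), tz = "UTC")
#' nrow(ud) <= nrow(sim$posts)
#' @export
computeUserDays <- function(assigned, tz = "UTC", parks = NULL) {
  keep <- assigned$assignment_mode %in% c("interior", "buffer")
  a <- assigned[keep, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(user_id = character(), park_id = character(),
                      date = as.Date(character()), platform = character()))
  if (length(tz) > 1L || !is.null(names(tz))) {
    stopifnot(!is.null(parks))
    m <- parkMeta(parks)
    ctz <- tz[m$country[match(a$park_id, m$park_id)]]
    ctz[is.na(ctz)] <- "UTC"
    date <- as.Date(vapply(seq_len(nrow(a)), function(i)
      format(a$timestamp[i], "%Y-%m-%d", tz = ctz[i]), character(1L)))
  } else {
    date <- as.Date(format(a$timestamp, "%Y-%m-%d", tz = tz))
  }
  key <- paste(a$user_id, a$park_id, date, a$platform, sep = "\r")
  first <- !duplicated(key)
  data.frame(user_id = a$user_id[first], park_id = a$park_id[first],
             date = date[first], platform = a$platform[first],
             stringsAsFactors = FALSE)
}

#' Aggregate user-days to a monthly park-by-source matrix
#'
#' Counts user-days per (park, month, platform) for one calendar year. Every
#' park present in the data — or listed in `park_ids` — carries all 12
#' months, zero-filled, so that series align with monthly official
#' statistics.
#'
#' @param user_days data.frame from [computeUserDays()].
#' @param year calendar year to aggregate.
#' @param park_ids optional character vector of parks that must appear even
#'   with zero activity.
#' @param platforms optional character vector fixing the platform columns.
#' @return a [MonthlyMatrix-class] with one column per platform.
#' @export
monthlySUD <- function(user_days, year, park_ids = NULL, platforms = NULL) {
  year <- as.integer(year)
  ud <- user_days[!is.na(user_days$date) &
                    as.integer(format(user_days$date, "%Y")) == year, ,
                  drop = FALSE]
  parks <- sort(unique(c(park_ids, ud$park_id)))
  plats <- sort(unique(c(platforms, ud$platform)))
  if (length(parks) == 0L) stop("no parks to tabulate")
  if (length(plats) == 0L) stop("no platforms to tabulate")
  keys <- expand.grid(month = 1:12, park_id = parks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys <- keys[, c("park_id", "month")]
  cnt <- matrix(0L, nrow = nrow(keys), ncol = length(plats),
                dimnames = list(NULL, plats))
  if (nrow(ud)) {
    mon <- as.integer(format(ud$date, "%m"))
    ri <- match(paste(ud$park_id, mon), paste(keys$park_id, keys$month))
    ci <- match(ud$platform, plats)
    tab <- table(factor(ri, levels = seq_len(nrow(keys))),
                 factor(ci, levels = seq_along(plats)))
    cnt <- cnt + matrix(as.integer(tab), nrow = nrow(keys),
                        dimnames = dimnames(cnt))
  }
  MonthlyMatrix(cnt, park_id = keys$park_id, year = year, month = keys$month)
}

#' Add the combined (all-platforms) column
#'
#' Appends a `combined` source equal to the elementwise sum of the platform
#' columns. No cross-platform user deduplication is attempted: platforms have
#' disjoint user-id spaces, so the sum is the total user-day volume.
#'
#' @param x a [MonthlyMatrix-class] with at least one platform column.
#' @return the matrix with a `combined` column appended.
#' @export
combinePlatforms <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  plat <- colnames(x)[cd$type == "platform"]
  if (length(plat) == 0L) stop("no platform columns to combine")
  if ("combined" %in% colnames(x)) return(x)
  cnt <- sudCounts(x)
  comb <- rowSums(cnt[, plat, drop = FALSE])
  k <- monthKeys(x)
  MonthlyMatrix(cbind(cnt, combined = comb), k$park_id, k$year, k$month,
                type = c(as.character(cd$type), "combined"))
}

#' Attach official visitor statistics as a source column
#'
#' Joins monthly official counts onto the matrix rows; months missing from
#' the statistics become 0.
#'
#' @param x a [MonthlyMatrix-class].
#' @param visitor_stats data.frame from [readVisitorStats()].
#' @return the matrix with an `official` column appended.
#' @export
attachOfficial <- function(x, visitor_stats) {
  k <- monthKeys(x)
  idx <- match(paste(k$park_id, k$year, k$month),
               paste(visitor_stats$park_id, visitor_stats$year,
                     visitor_stats$month))
  off <- ifelse(is.na(idx), 0, visitor_stats$visitors[idx])
  cd <- SummarizedExperiment::colData(x)
  MonthlyMatrix(cbind(sudCounts(x), official = off),
                k$park_id, k$year, k$month,
                type = c(as.character(cd$type), "official"))
}

#' Annual totals per park and source
#'
#' Sums the 12 monthly cells of each park/source; input to popularity
#' ranking and to log-scale popularity-vs-performance trends.
#'
#' @param x a [MonthlyMatrix-class].
#' @return data.frame `park_id`, `source`, `total` (long format).
#' @export
annualTotals <- function(x) {
  k <- monthKeys(x)
  cnt <- sudCounts(x)
  out <- do.call(rbind, lapply(colnames(cnt), function(s) {
    agg <- rowsum(cnt[, s], k$park_id)
    data.frame(park_id = rownames(agg), source = s, total = agg[, 1L],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out[order(out$source, out$park_id), , drop = FALSE]
}

#' Extract one park/source 12-month series
#'
#' @param x a [MonthlyMatrix-class].
#' @param park park_id.
#' @param source column label.
#' @param year optional year (needed when `x` spans several).
#' @return numeric vector of length 12, ordered January..December.
#' @export
monthlySeries <- function(x, park, source, year = NULL) {
  k <- monthKeys(x)
  sel <- k$park_id == park
  if (!is.null(year)) sel <- sel & k$year == as.integer(year)
  if (sum(sel) != 12L) stop("expected 12 monthly rows for park ", park)
  v <- sudCounts(x)[sel, source]
  v[order(k$month[sel])]
}
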