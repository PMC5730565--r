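#' Configuration for the synthetic visitation simulator
#'
#' Bundles every knob of the coupled ground-truth / social-media generator.
#' Defaults describe a realistic park system at desk scale: annual visitation
#' spanning two orders of magnitude, smooth unimodal seasonal profiles, and
#' per-platform adoption rates derived from observed country-level ratios of
#' social-media user-days to official visitors (about 0.4% of visitor-days
#' overall, split roughly 71/25/4% between the three default platforms).
#'
#' @param n_parks number of parks (>= 1).
#' @param seed integer seed; the whole generator is deterministic given it.
#' @param visitor_range length-2 positive bounds; annual visitors are drawn
#'   log-uniformly between them.
#' @param peak_month park peak month 1..12, or `NULL` to draw one per park.
#' @param concentration seasonal concentration `kappa` (von Mises-style;
#'   0 = uniform months).
#' @param second_peak optional second peak month for bimodal seasonality.
#' @param peak_mix weight of the second peak when bimodal.
#' @param platforms named numeric vector of per-visitor-day adoption
#'   probabilities (probability that a visitor-day yields at least one post
#'   on that platform).
#' @param activity_exponent exponent `alpha` of the discrete power-law
#'   per-user posting intensity (posts per active day `k` with
#'   `P(k) ~ k^-alpha`, `k = 1..50`); models participation inequality —
#'   a small fraction of users produces most posts.
#' @param mean_visit_days mean visit length in days (geometric lengths).
#' @param jitter_m geotag scatter (Gaussian sd, metres).
#' @param noise_frac fraction of posts relocated uniformly over the region,
#'   emulating mis-geotagged content.
#' @param timezone reporting timezone for post timestamps.
#' @param region bounding box `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param park_radius_km length-2 range of park radii, km.
#' @param year simulated calendar year.
#' @return list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(n_parks = 20L, seed = 1L,
                             visitor_range = c(200, 20000),
                             peak_month = NULL, concentration = 1.5,
                             second_peak = NULL, peak_mix = 0.3,
                             platforms = c(instagram = 0.003,
                                           twitter = 0.001,
                                           flickr = 3e-4),
                             activity_exponent = 2.2,
                             mean_visit_days = 2,
                             jitter_m = 50, noise_frac = 0.02,
                             timezone = "UTC",
                             region = c(22, 60, 30, 68),
                             park_radius_km = c(2, 12),
                             year = 2014L) {
  stopifnot(n_parks >= 1L, all(visitor_range > 0), length(visitor_range) == 2L,
            all(platforms >= 0), all(platforms <= 1),
            mean_visit_days >= 1, jitter_m >= 0,
            noise_frac >= 0, noise_frac <= 1, concentration >= 0,
            length(region) == 4L, region[3L] > region[1L],
            region[4L] > region[2L])
  if (is.null(names(platforms)) || any(!nzchar(names(platforms))))
    stop("platforms must be a named vector")
  structure(list(n_parks = as.integer(n_parks), seed = as.integer(seed),
                 visitor_range = visitor_range, peak_month = peak_month,
                 concentration = concentration, second_peak = second_peak,
                 peak_mix = peak_mix, platforms = platforms,
                 activity_exponent = activity_exponent,
                 mean_visit_days = mean_visit_days, jitter_m = jitter_m,
                 noise_frac = noise_frac, timezone = timezone,
                 region = region, park_radius_km = park_radius_km,
                 year = as.integer(year)),
            class = "SimulationConfig")
}

#' Seasonal monthly profile
#'
#' Unimodal circular profile over the 12 months,
#' `p_m` proportional to `exp(kappa * cos(2 pi (m - peak) / 12))`, optionally
#' mixed with a second peak (e.g. a summer-hiking plus winter-sports
#' system). `kappa = 0` gives the uniform 1/12 profile. Proportions sum to 1.
#'
#' @param peak peak month 1..12.
#' @param kappa concentration (>= 0).
#' @param second_peak optional second peak month.
#' @param mix weight of the second peak.
#' @return numeric vector of 12 proportions.
#' @export
seasonalProfile <- function(peak, kappa, second_peak = NULL, mix = 0.3) {
  one <- function(pk) {
    w <- exp(kappa * cos(2 * pi * ((1:12) - pk) / 12))
    w / sum(w)
  }
  p <- one(peak)
  if (!is.null(second_peak)) p <- (1 - mix) * p + mix * one(second_peak)
  p / sum(p)
}

# Sum-preserving largest-remainder apportionment of `total` over `props`.
.apportion <- function(total, props) {
  raw <- total * props
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# Discrete power-law posts-per-active-day, P(k) ~ k^-alpha on 1..kmax.
.rpowerlaw <- function(n, alpha, kmax = 50L) {
  if (n == 0L) return(integer())
  sample.int(kmax, n, replace = TRUE, prob = (seq_len(kmax))^(-alpha))
}

#' Generate disjoint convex park polygons with annual totals
#'
#' Places `n_parks` convex polygons on a jittered grid inside the region (so
#' parks are pairwise disjoint by construction), each built as the convex
#' hull of radial samples around its centroid in a local metric plane. The
#' ground-truth annual visitor totals are drawn log-uniformly between the
#' configured bounds, reproducing a visitation spread over orders of
#' magnitude.
#'
#' @param config a [simulationConfig()].
#' @return list: `parks` (a [ParkSet-class]) and `truth` (data.frame
#'   `park_id`, `annual_visitors`).
#' @export
simulateParks <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_parks
  reg <- config$region
  rmax_km <- config$park_radius_km[2L]
  # grid spacing guaranteeing disjoint parks (jitter capped below spacing/2)
  lat_hi <- max(abs(reg[c(2L, 4L)]))
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(lat_hi * pi / 180)
  cell_deg_lat <- (2.6 * rmax_km) / km_per_deg_lat
  cell_deg_lon <- (2.6 * rmax_km) / km_per_deg_lon
  nx <- floor((reg[3L] - reg[1L]) / cell_deg_lon)
  ny <- floor((reg[4L] - reg[2L]) / cell_deg_lat)
  if (nx * ny < n)
    stop("region too small for ", n, " disjoint parks of radius ",
         rmax_km, " km")
  cells <- sample.int(nx * ny, n)
  cx <- reg[1L] + ((cells - 1L) %% nx + 0.5 +
                     stats::runif(n, -0.15, 0.15)) * cell_deg_lon
  cy <- reg[2L] + ((cells - 1L) %/% nx + 0.5 +
                     stats::runif(n, -0.15, 0.15)) * cell_deg_lat
  radius_km <- stats::runif(n, config$park_radius_km[1L],
                            config$park_radius_km[2L])
  geoms <- lapply(seq_len(n), function(i) {
    m <- 14L
    ang <- sort(stats::runif(m, 0, 2 * pi))
    rad <- radius_km[i] * 1000 * stats::runif(m, 0.6, 1)
    xy <- cbind(rad * cos(ang), rad * sin(ang))
    hull <- grDevices::chull(xy)
    ring <- aeqdInverse(xy[hull, , drop = FALSE], cx[i], cy[i])
    list(list(ring))
  })
  ids <- sprintf("park_%03d", seq_len(n))
  parks <- ParkSet(park_id = ids, name = sprintf("Synthetic Park %d", seq_len(n)),
                   country = "XX", geoms = geoms)
  lr <- log10(config$visitor_range)
  annual <- as.integer(round(10^stats::runif(n, lr[1L], lr[2L])))
  list(parks = parks,
       truth = data.frame(park_id = ids, annual_visitors = annual,
                          stringsAsFactors = FALSE))
}

#' Generate true monthly visitor counts
#'
#' Expands each park's annual total into 12 monthly counts following its
#' seasonal profile (peak month and concentration drawn per park unless
#' fixed in the config), with sum-preserving largest-remainder rounding so
#' the monthly counts add exactly to the annual total.
#'
#' @param truth data.frame from [simulateParks()].
#' @param config a [simulationConfig()].
#' @return data.frame `park_id`, `year`, `month`, `visitors`, with the
#'   per-park expected proportions in attribute `"profiles"`.
#' @export
simulateVisitation <- function(truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  peaks <- if (is.null(config$peak_month)) sample.int(12L, n, replace = TRUE)
           else rep_len(config$peak_month, n)
  profiles <- matrix(NA_real_, n, 12L,
                     dimnames = list(truth$park_id, NULL))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- seasonalProfile(peaks[i], config$concentration,
                          config$second_peak, config$peak_mix)
    profiles[i, ] <- pr
    cnt <- .apportion(truth$annual_visitors[i], pr)
    rows[[i]] <- data.frame(park_id = truth$park_id[i], year = config$year,
                            month = 1:12, visitors = cnt,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  attr(out, "peaks") <- peaks
  out
}

# Uniform points inside a multipolygon, by rejection from the bbox.
.runifInPolygon <- function(n, geom) {
  if (n == 0L) return(matrix(numeric(), ncol = 2L))
  bb <- geomBBox(geom)
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- max(64L, 2L * (n - got))
    cand <- cbind(stats::runif(m, bb[1L], bb[3L]),
                  stats::runif(m, bb[2L], bb[4L]))
    hit <- cand[pointsInPolygon(cand, geom), , drop = FALSE]
    take <- min(nrow(hit), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take), ] <- hit[seq_len(take), ]
      got <- got + take
    }
  }
  out
}

#' Generate geotagged posts from true visitation
#'
#' Instantiates each month's visitors as visits with geometric lengths (mean
#' `mean_visit_days`; a multi-day visitor is active on several calendar
#' days, as SUD expects). Each visitor-day independently yields posts on
#' each platform with probability `platforms[p]`; the number of posts on an
#' active day is the user's heavy-tailed activity level, so participation
#' inequality inflates post counts but never user-days. Post locations are
#' uniform within the park plus Gaussian geotag jitter; a `noise_frac`
#' share is relocated uniformly over the whole region.
#'
#' @param parks a [ParkSet-class] from [simulateParks()].
#' @param visitation data.frame from [simulateVisitation()].
#' @param config a [simulationConfig()].
#' @return list: `posts` (data.frame `user_id`, `platform`, `timestamp`,
#'   `lon`, `lat`) and `truth` (list with `visits` and `user_days`, the
#'   lineage every post traces back to).
#' @export
simulatePosts <- function(parks, visitation, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  geoms <- parkGeoms(parks)
  ids <- parkIds(parks)
  q <- if (config$mean_visit_days <= 1) 1 else 1 / config$mean_visit_days
  plat_names <- names(config$platforms)

  # phase 1 (visit lineage): arrivals, visit lengths and per-day platform
  # adoption. Drawn from its own seed so the user-day structure is invariant
  # to downstream posting-intensity settings.
  set.seed(config$seed + 2L)
  visits_l <- list(); ud_l <- list()
  ucounter <- 0L
  for (k in seq_along(ids)) {
    vis <- visitation[visitation$park_id == ids[k], , drop = FALSE]
    if (nrow(vis) == 0L) next
    V <- sum(vis$visitors)
    if (V == 0L) next
    month0 <- as.Date(sprintf("%d-%02d-01", vis$year, vis$month))
    dim_m <- as.integer(format(month0 + 31 - as.integer(format(month0 + 31, "%d")),
                               "%d"))  # days in month
    arrivals <- rep(month0, vis$visitors) +
      unlist(lapply(seq_len(nrow(vis)), function(i)
        sample.int(dim_m[i], vis$visitors[i], replace = TRUE) - 1L))
    len <- 1L + stats::rgeom(V, q)
    uids <- sprintf("u%08d", ucounter + seq_len(V))
    ucounter <- ucounter + V
    visits_l[[k]] <- data.frame(user_id = uids, park_id = ids[k],
                                arrival = as.Date(arrivals, origin = "1970-01-01"),
                                length_days = len, stringsAsFactors = FALSE)
    day_user <- rep(uids, len)
    day_date <- rep(arrivals, len) + (sequence(len) - 1L)
    nd <- length(day_user)
    for (p in plat_names) {
      act <- stats::runif(nd) < config$platforms[[p]]
      if (!any(act)) next
      ud_l[[length(ud_l) + 1L]] <-
        data.frame(user_id = day_user[act], park_id = ids[k],
                   date = as.Date(day_date[act], origin = "1970-01-01"),
                   platform = p, stringsAsFactors = FALSE)
    }
  }

  # phase 2 (posting): per-user heavy-tailed intensity, geotags and times.
  # Inflates post counts, never user-days (participation inequality).
  set.seed(config$seed + 5L)
  posts_l <- list()
  for (b in ud_l) {
    k <- match(b$park_id[1L], ids)
    au <- b$user_id
    uu <- unique(au)
    intensity <- .rpowerlaw(length(uu), config$activity_exponent)
    nposts <- intensity[match(au, uu)]
    pu <- rep(au, nposts)
    pd <- rep(b$date, nposts)
    np <- length(pu)
    loc <- .runifInPolygon(np, geoms[[k]])
    if (config$jitter_m > 0) {
      ctr <- geomCentroid(geoms[[k]])
      xy <- aeqdForward(loc, ctr[1L], ctr[2L])
      xy <- xy + matrix(stats::rnorm(2L * np, 0, config$jitter_m), ncol = 2L)
      loc <- aeqdInverse(xy, ctr[1L], ctr[2L])
    }
    secs <- round(stats::runif(np, 6 * 3600, 22 * 3600))
    ts <- as.POSIXct(paste(pd, sprintf("%02d:%02d:%02d", secs %/% 3600,
                                       (secs %/% 60) %% 60, secs %% 60)),
                     tz = config$timezone)
    posts_l[[length(posts_l) + 1L]] <-
      data.frame(user_id = pu, platform = b$platform[1L], timestamp = ts,
                 lon = loc[, 1L], lat = loc[, 2L], stringsAsFactors = FALSE)
  }
  posts <- if (length(posts_l)) do.call(rbind, posts_l) else
    data.frame(user_id = character(), platform = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               lon = numeric(), lat = numeric())
  if (nrow(posts) > 0L && config$noise_frac > 0) {
    nn <- round(config$noise_frac * nrow(posts))
    if (nn > 0L) {
      sel <- sample.int(nrow(posts), nn)
      posts$lon[sel] <- stats::runif(nn, config$region[1L], config$region[3L])
      posts$lat[sel] <- stats::runif(nn, config$region[2L], config$region[4L])
    }
  }
  attr(posts, "timezone") <- config$timezone
  list(posts = posts,
       truth = list(visits = do.call(rbind, visits_l),
                    user_days = if (length(ud_l)) unique(do.call(rbind, ud_l))
                                else NULL))
}

#' Draw monthly user-day counts directly (fast path)
#'
#' Analytic shortcut past the post-level machinery: each park-month's SUD on
#' each platform is drawn as `Binomial(visitor_days, adoption)` with
#' `visitor_days = visitors * mean_visit_days`. This matches the full
#' posts-to-SUD path in distribution when geotag noise is off and visits do
#' not straddle month boundaries, and is used for heavily replicated
#' simulation studies where generating every post would dominate runtime.
#'
#' @param visitation data.frame from [simulateVisitation()].
#' @param config a [simulationConfig()].
#' @param seed optional seed override (defaults to `config$seed + 3`).
#' @return a [MonthlyMatrix-class] with one column per platform.
#' @export
simulateUserDays <- function(visitation, config, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(if (is.null(seed)) config$seed + 3L else seed)
  vd <- round(visitation$visitors * config$mean_visit_days)
  cnt <- vapply(names(config$platforms), function(p)
    stats::rbinom(length(vd), vd, config$platforms[[p]]), numeric(length(vd)))
  cnt <- matrix(cnt, nrow = length(vd),
                dimnames = list(NULL, names(config$platforms)))
  MonthlyMatrix(cnt, visitation$park_id, visitation$year, visitation$month)
}

#' Run the whole generator
#'
#' Convenience wrapper: parks and annual totals, monthly visitation, and
#' geotagged posts, all deterministic under `config$seed`. The true monthly
#' counts double as the official visitor statistics of the synthetic world
#' (official counters are treated as exact).
#'
#' @param config a [simulationConfig()].
#' @return list: `parks`, `truth` (annual totals), `official` (monthly
#'   visitor records), `posts`, `lineage` (visits and true user-days).
#' @examples
#' sim <- simulateDataset(simulationConfig(n_parks = 2, seed = 11))
#' head(sim$posts)
#' @export
simulateDataset <- function(config = simulationConfig()) {
  pk <- simulateParks(config)
  vis <- simulateVisitation(pk$truth, config)
  pp <- simulatePosts(pk$parks, vis, config)
  list(parks = pk$parks, truth = pk$truth, official = vis,
       posts = pp$posts, lineage = pp$truth)
}
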