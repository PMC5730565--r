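#' Standardise a 12-month series to proportions
#'
#' Divides each monthly count by the annual sum so the monthly proportions
#' sum to 1.0 and each lies in \[0, 1\], putting parks of very different size
#' on a common scale for visual and correlation comparison. An all-zero
#' series has no defined pattern and returns all `NA` (the park is flagged
#' and skipped downstream), never zeros.
#'
#' @param x numeric vector of 12 non-negative monthly counts.
#' @return numeric vector of 12 proportions, or all `NA` if `sum(x) == 0`.
#' @examples
#' normalizeMonthly(rep(5, 12))  # 1/12 each
#' @export
normalizeMonthly <- function(x) {
  stopifnot(length(x) == 12L)
  if (anyNA(x) || sum(x) <= 0) return(rep(NA_real_, 12L))
  x / sum(x)
}

#' Pearson correlation between two monthly visitation patterns
#'
#' Both series are standardised with [normalizeMonthly()] first; Pearson
#' correlation is invariant to that positive rescaling, so the result equals
#' the correlation of the raw counts whenever both are defined. Returns `NA`
#' (never 0) when either series is all-zero or has zero variance.
#'
#' @param official,sud numeric vectors of 12 monthly counts.
#' @return Pearson r in \[-1, 1\], or `NA` when undefined.
#' @export
pearsonPattern <- function(official, sud) {
  stopifnot(length(official) == 12L, length(sud) == 12L)
  po <- normalizeMonthly(official)
  ps <- normalizeMonthly(sud)
  if (anyNA(po) || anyNA(ps)) return(NA_real_)
  if (stats::sd(po) == 0 || stats::sd(ps) == 0) return(NA_real_)
  stats::cor(po, ps, method = "pearson")
}

#' Popularity ranking agreement between official totals and SUD
#'
#' Ranks parks by annual total on each side — rank 1 is the most visited —
#' and computes Spearman's rank correlation with average-rank tie handling.
#' High agreement means parks popular on the ground are popular on social
#' media.
#'
#' @param official named numeric vector of annual official totals (names =
#'   park_id).
#' @param sud named numeric vector of annual SUD totals over the same parks.
#' @return list of class `"RankingResult"`: `rs`, `n_parks`, and a `ranks`
#'   data.frame (`park_id`, `official_rank`, `social_rank`). `rs` is `NA`
#'   when either side is constant.
#' @examples
#' off <- c(a = 1000, b = 500, c = 100)
#' spearmanRanking(off, c(a = 90, b = 60, c = 5))$rs
#' @export
spearmanRanking <- function(official, sud) {
  stopifnot(!is.null(names(official)), !is.null(names(sud)))
  common <- intersect(names(official), names(sud))
  if (length(common) < 3L) stop("need at least 3 parks with both totals")
  o <- official[common]; s <- sud[common]
  ro <- rank(-o, ties.method = "average")  # 1 = most visited
  rs_rank <- rank(-s, ties.method = "average")
  rs <- if (stats::sd(ro) == 0 || stats::sd(rs_rank) == 0) NA_real_
        else stats::cor(ro, rs_rank, method = "pearson")
  structure(list(rs = rs, n_parks = length(common),
                 ranks = data.frame(park_id = common, official_rank = ro,
                                    social_rank = rs_rank,
                                    row.names = NULL)),
            class = "RankingResult")
}

#' @export
print.RankingResult <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: %.3f over %d parks\n",
              x$rs, x$n_parks))
  invisible(x)
}

#' Screen a 12-month series for temporal autocorrelation
#'
#' Computes the sample ACF and PACF up to `max_lag` lags and marks a lag
#' significant when its coefficient falls outside the white-noise band
#' \eqn{\pm z_{1-\alpha/2}/\sqrt{n}} (n = 12). Under the default policy a
#' series is flagged `autocorrelated` when lag 1 or lag 2 of either function
#' is significant; a Pearson correlation computed on such a series may be
#' inflated, so flagged parks are excluded from group comparisons and trend
#' fits. A zero-variance series is degenerate and flagged for exclusion too.
#'
#' @param x numeric vector of 12 monthly counts.
#' @param max_lag maximum lag (default 11).
#' @param alpha significance level for the band (default 0.05).
#' @param flag_lags lags that trigger the `autocorrelated` flag (default
#'   `1:2`).
#' @return list: `acf` (lags 0..max_lag), `pacf` (lags 1..max_lag),
#'   `sig_band`, `sig_lags_acf`, `sig_lags_pacf`, `autocorrelated`,
#'   `degenerate`.
#' @export
autocorrelationScreen <- function(x, max_lag = 11L, alpha = 0.05,
                                  flag_lags = 1:2) {
  n <- length(x)
  stopifnot(n >= 4L, max_lag < n)
  band <- stats::qnorm(1 - alpha / 2) / sqrt(n)
  if (anyNA(x) || stats::sd(x) == 0) {
    return(list(acf = c(1, rep(NA_real_, max_lag)), pacf = rep(NA_real_, max_lag),
                sig_band = band, sig_lags_acf = integer(), sig_lags_pacf = integer(),
                autocorrelated = TRUE, degenerate = TRUE))
  }
  ac <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  pc <- as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)
  sig_a <- which(abs(ac[-1L]) > band)
  sig_p <- which(abs(pc) > band)
  list(acf = ac, pacf = pc, sig_band = band,
       sig_lags_acf = sig_a, sig_lags_pacf = sig_p,
       autocorrelated = any(flag_lags %in% sig_a) || any(flag_lags %in% sig_p),
       degenerate = FALSE)
}

#' Per-park pattern correlations with autocorrelation screening
#'
#' For every park and every non-official source, computes the Pearson
#' correlation between the monthly official pattern and the source's SUD
#' pattern, and screens the park's series for short-lag temporal
#' autocorrelation. The screen examines both the official series and the SUD
#' series named in `screen_sources` (default: `combined` if present,
#' otherwise every platform); a park flagged on any screened series is
#' excluded from downstream group comparisons and trend fits.
#'
#' @param x a [MonthlyMatrix-class] containing an `official` column.
#' @param year the year to analyse (required when `x` spans several years).
#' @param alpha significance level of the screening band.
#' @param flag_lags lags triggering exclusion (default `1:2`).
#' @param screen_sources SUD sources screened alongside the official series.
#' @return data.frame of class `"ParkCorrelationTable"`: `park_id`, `source`,
#'   `pearson_r`, `n_months`, `autocorrelated`, `excluded`.
#' @export
parkCorrelations <- function(x, year = NULL, alpha = 0.05, flag_lags = 1:2,
                             screen_sources = NULL) {
  cd <- SummarizedExperiment::colData(x)
  if (!"official" %in% colnames(x)) stop("matrix has no 'official' column")
  k <- monthKeys(x)
  if (is.null(year)) {
    year <- unique(k$year)
    if (length(year) > 1L)
      stop("matrix spans several years; pass `year`")
  }
  sud_sources <- colnames(x)[cd$type != "official"]
  if (is.null(screen_sources))
    screen_sources <- if ("combined" %in% sud_sources) "combined" else sud_sources
  parks <- sort(unique(k$park_id))
  rows <- list()
  for (p in parks) {
    off <- monthlySeries(x, p, "official", year)
    flagged <- autocorrelationScreen(off, alpha = alpha,
                                     flag_lags = flag_lags)$autocorrelated
    if (!flagged) {
      for (s in screen_sources) {
        scr <- autocorrelationScreen(monthlySeries(x, p, s, year),
                                     alpha = alpha, flag_lags = flag_lags)
        if (scr$autocorrelated) { flagged <- TRUE; break }
      }
    }
    for (s in sud_sources) {
      r <- pearsonPattern(off, monthlySeries(x, p, s, year))
      rows[[length(rows) + 1L]] <-
        data.frame(park_id = p, source = s, pearson_r = r, n_months = 12L,
                   autocorrelated = flagged, excluded = flagged,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ParkCorrelationTable", class(out))
  out
}

#' Popularity-vs-performance trend
#'
#' Regresses per-park pattern correlations on the log10 of a popularity
#' predictor (annual official visitors or annual SUD) over the non-excluded
#' parks with defined correlations. A positive slope says social media
#' tracks visitation better in more popular parks.
#'
#' @param correlations a `ParkCorrelationTable` from [parkCorrelations()].
#' @param totals data.frame from [annualTotals()].
#' @param source which SUD source's correlations to use (e.g. `"combined"`).
#' @param predictor which annual totals to log-transform: `"official"` or a
#'   SUD source label.
#' @return list of class `"TrendResult"`: `pearson_r`, `slope`, `intercept`,
#'   `n_parks`, `dropped_zero_total`.
#' @export
popularityTrend <- function(correlations, totals, source = "combined",
                            predictor = "official") {
  cc <- correlations[correlations$source == source & !correlations$excluded &
                       !is.na(correlations$pearson_r), , drop = FALSE]
  tt <- totals[totals$source == predictor, , drop = FALSE]
  tot <- tt$total[match(cc$park_id, tt$park_id)]
  usable <- !is.na(tot) & tot > 0  # log undefined at zero
  dropped <- sum(!usable)
  cc <- cc[usable, , drop = FALSE]
  tot <- tot[usable]
  if (nrow(cc) < 3L) stop("fewer than 3 usable parks for the trend fit")
  lx <- log10(tot)
  fit <- stats::lm(cc$pearson_r ~ lx)
  r <- if (stats::sd(lx) == 0 || stats::sd(cc$pearson_r) == 0) NA_real_
       else stats::cor(lx, cc$pearson_r)
  structure(list(pearson_r = r,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_parks = nrow(cc), dropped_zero_total = dropped,
                 source = source, predictor = predictor),
            class = "TrendResult")
}

#' @export
print.TrendResult <- function(x, ...) {
  cat(sprintf(
    "Trend of %s pattern correlation vs log10 %s totals:\n  r = %.3f, slope = %.3f (n = %d parks)\n",
    x$source, x$predictor, x$pearson_r, x$slope, x$n_parks))
  invisible(x)
}
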