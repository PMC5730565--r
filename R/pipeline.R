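#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end run. Defaults follow the
#' reference analysis parameters: a 10 km assignment buffer, one analysed
#' calendar year, and a 95% screening confidence level.
#'
#' @param posts,parks,official,exclusions input paths (exclusions optional).
#' @param buffer_m assignment buffer in metres.
#' @param tz reporting timezone (string, or named-by-country vector).
#' @param year analysed 4-digit year.
#' @param alpha significance level for the autocorrelation screen.
#' @param screen_lags lags triggering exclusion.
#' @param ranking_metric annual totals used for the popularity ranking:
#'   `"sud"` (combined user-days, the default) or `"posts"` (raw post
#'   counts).
#' @param out_dir output directory for the result tables.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(posts, parks, official, exclusions = NULL,
                           buffer_m = 10000, tz = "UTC", year = 2014L,
                           alpha = 0.05, screen_lags = 1:2,
                           ranking_metric = c("sud", "posts"),
                           out_dir = "results") {
  stopifnot(buffer_m >= 0, alpha > 0, alpha < 1,
            year >= 1000L, year <= 9999L)
  structure(list(posts = posts, parks = parks, official = official,
                 exclusions = exclusions, buffer_m = buffer_m, tz = tz,
                 year = as.integer(year), alpha = alpha,
                 screen_lags = screen_lags,
                 ranking_metric = match.arg(ranking_metric),
                 out_dir = out_dir),
            class = "PipelineConfig")
}

.stageFail <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full visitor-monitoring pipeline
#'
#' Executes assignment, SUD aggregation, the per-park statistics and the
#' cross-platform comparison, writing the result tables and a machine-
#' readable run manifest to `config$out_dir`:
#' `monthly.csv`, `park_correlations.csv`, `rankings.csv`, `trend.csv`,
#' `screening.csv`, `comparison.csv`, `summary.csv` and `manifest.json`.
#' Any stage's fatal error aborts with a stage-labelled message. Reruns with
#' an identical configuration are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @return invisible list with every intermediate and result object.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  posts <- .stageFail("read", readPosts(config$posts))
  parks <- .stageFail("read", readParks(config$parks))
  official <- .stageFail("read", readVisitorStats(config$official))
  excl <- if (!is.null(config$exclusions))
    .stageFail("read", readExclusions(config$exclusions)) else NULL

  assigned <- .stageFail("assign",
    assignPosts(posts, parks, buffer_m = config$buffer_m, exclusions = excl))
  amode <- assignmentSummary(assigned)

  ud <- .stageFail("sud", computeUserDays(assigned, tz = config$tz,
                                          parks = parks))
  mm <- .stageFail("sud", monthlySUD(ud, config$year,
                                     park_ids = parkIds(parks),
                                     platforms = unique(posts$platform)))
  mm <- combinePlatforms(mm)
  mm <- attachOfficial(mm, official)
  writeMonthlyMatrix(mm, file.path(config$out_dir, "monthly.csv"))

  corr <- .stageFail("analyze",
    parkCorrelations(mm, year = config$year, alpha = config$alpha,
                     flag_lags = config$screen_lags))
  utils::write.csv(corr, file.path(config$out_dir, "park_correlations.csv"),
                   row.names = FALSE)

  tot <- annualTotals(mm)
  rank_tot <- if (config$ranking_metric == "sud") {
    tot[tot$source == "combined", ]
  } else {
    agg <- rowsum(rep(1L, sum(assigned$assignment_mode %in%
                                c("interior", "buffer"))),
                  assigned$park_id[assigned$assignment_mode %in%
                                     c("interior", "buffer")])
    data.frame(park_id = rownames(agg), source = "posts", total = agg[, 1L])
  }
  off_tot <- tot[tot$source == "official", ]
  ranking <- .stageFail("analyze", spearmanRanking(
    stats::setNames(off_tot$total, off_tot$park_id),
    stats::setNames(rank_tot$total, rank_tot$park_id)))
  rk <- ranking$ranks
  rk$spearman_rs <- ranking$rs
  rk$metric <- config$ranking_metric
  utils::write.csv(rk, file.path(config$out_dir, "rankings.csv"),
                   row.names = FALSE)

  # too few screened-in parks is a data condition, not a hard error
  trend <- tryCatch(
    popularityTrend(corr, tot, source = "combined", predictor = "official"),
    error = function(e) {
      message("trend not estimable: ", conditionMessage(e))
      structure(list(pearson_r = NA_real_, slope = NA_real_,
                     intercept = NA_real_,
                     n_parks = sum(!corr$excluded & corr$source == "combined" &
                                     !is.na(corr$pearson_r)),
                     dropped_zero_total = NA_integer_, source = "combined",
                     predictor = "official"), class = "TrendResult")
    })
  utils::write.csv(
    data.frame(source = trend$source, predictor = trend$predictor,
               pearson_r = trend$pearson_r, slope = trend$slope,
               intercept = trend$intercept, n_parks = trend$n_parks),
    file.path(config$out_dir, "trend.csv"), row.names = FALSE)

  screening <- .stageFail("analyze", {
    parks_scr <- sort(unique(monthKeys(mm)$park_id))
    do.call(rbind, lapply(parks_scr, function(p) {
      s <- autocorrelationScreen(monthlySeries(mm, p, "official", config$year),
                                 alpha = config$alpha,
                                 flag_lags = config$screen_lags)
      data.frame(park_id = p, series = "official",
                 autocorrelated = s$autocorrelated,
                 degenerate = s$degenerate,
                 sig_lags_acf = paste(s$sig_lags_acf, collapse = ";"),
                 sig_lags_pacf = paste(s$sig_lags_pacf, collapse = ";"))
    }))
  })
  utils::write.csv(screening, file.path(config$out_dir, "screening.csv"),
                   row.names = FALSE)

  comparison <- tryCatch(comparePlatforms(corr), error = function(e) {
    message("platform comparison not estimable: ", conditionMessage(e))
    structure(list(kw = list(H = NA_real_, p = NA_real_, df = NA_integer_,
                             n = integer()),
                   pairwise = data.frame(group_i = character(),
                                         group_j = character(), z = numeric(),
                                         p_raw = numeric(),
                                         p_adjusted = numeric()),
                   n_used = 0L, n_excluded = sum(corr$excluded)),
              class = "GroupComparison")
  })
  cmp_df <- comparison$pairwise
  if (nrow(cmp_df) == 0L)
    cmp_df <- data.frame(group_i = NA_character_, group_j = NA_character_,
                         z = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_)
  cmp_df$kw_H <- comparison$kw$H
  cmp_df$kw_p <- comparison$kw$p
  utils::write.csv(cmp_df, file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE)

  summ <- summarizeCorrelations(corr)
  utils::write.csv(summ, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("parkdays")),
    config = unclass(config),
    rows = list(posts_in = attr(posts, "rows_in"),
                posts_rejected = attr(posts, "rows_rejected"),
                posts_accepted = nrow(posts),
                assignment = as.list(amode),
                user_days = nrow(ud),
                official_rows = nrow(official)),
    parks = length(parks),
    exclusion_zones = length(excl %||% list()))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(posts = posts, parks = parks, official = official,
                 assigned = assigned, user_days = ud, monthly = mm,
                 correlations = corr, ranking = ranking, trend = trend,
                 screening = screening, comparison = comparison,
                 summary = summ, manifest = manifest))
}

#' Summarise a park-correlation table
#'
#' Per source: the median Pearson correlation and the share of parks at the
#' conventional reporting thresholds (at or above 0.9 / 0.7 / 0.6, below
#' 0.3, negative), over every park with a defined correlation — the
#' threshold shares describe the whole park system, while the
#' autocorrelation screen (whose exclusion count is reported alongside)
#' only gates the group comparisons and trend fits.
#'
#' @param correlations a `ParkCorrelationTable` from [parkCorrelations()].
#' @return data.frame, one row per source.
#' @export
summarizeCorrelations <- function(correlations) {
  if (is.null(correlations) || nrow(correlations) == 0L)
    stop("empty correlation table")
  out <- lapply(split(correlations, correlations$source), function(d) {
    r <- d$pearson_r[!is.na(d$pearson_r)]
    data.frame(source = d$source[1L],
               n_parks = nrow(d),
               n_excluded = sum(d$excluded),
               n_usable = length(r),
               median_r = if (length(r)) stats::median(r) else NA_real_,
               share_ge_0.9 = if (length(r)) mean(r >= 0.9) else NA_real_,
               share_ge_0.7 = if (length(r)) mean(r >= 0.7) else NA_real_,
               share_ge_0.6 = if (length(r)) mean(r >= 0.6) else NA_real_,
               share_lt_0.3 = if (length(r)) mean(r < 0.3) else NA_real_,
               share_negative = if (length(r)) mean(r < 0) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$source), , drop = FALSE]
}
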