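test_that("monthly normalization yields proportions summing to one", {
  expect_equal(normalizeMonthly(rep(7, 12)), rep(1 / 12, 12))
  expect_equal(normalizeMonthly(c(12, rep(0, 11))), c(1, rep(0, 11)))
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(12, 40)
    if (sum(x) == 0) next
    p <- normalizeMonthly(x)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_true(all(is.na(normalizeMonthly(rep(0, 12)))))
})

test_that("pattern correlation is exact on self, reflections and a textbook
           oracle, and is scale invariant", {
  x <- c(5, 8, 12, 20, 35, 50, 60, 48, 30, 18, 9, 6)
  expect_equal(pearsonPattern(x, x), 1)
  expect_equal(pearsonPattern(x, max(x) - x), -1)
  set.seed(31)
  y <- x + rnorm(12, 0, 10)
  y <- pmax(y, 0.1)
  expect_equal(pearsonPattern(x, y),
               oraclePearson(normalizeMonthly(x), normalizeMonthly(y)))
  # positive rescaling of raw counts changes nothing
  expect_equal(pearsonPattern(x * 937, y), pearsonPattern(x, y))
  # undefined cases propagate as NA, never 0
  expect_true(is.na(pearsonPattern(rep(3, 12), y)))
  expect_true(is.na(pearsonPattern(rep(0, 12), y)))
})

test_that("spearman ranking recovers identical, reversed and hand-computed
           orderings", {
  off <- setNames(c(1000, 800, 600, 400, 200, 150, 90, 50, 30, 10),
                  sprintf("p%02d", 1:10))
  expect_equal(spearmanRanking(off, off)$rs, 1)
  expect_equal(spearmanRanking(off, setNames(rev(unname(off)), names(off)))$rs, -1)

  # 5-park fixture with one adjacent swap: closed-form untied Spearman
  off5 <- setNames(c(500, 400, 300, 200, 100), letters[1:5])
  sud5 <- setNames(c(400, 500, 300, 200, 100), letters[1:5])  # swap a,b
  rk <- spearmanRanking(off5, sud5)
  expect_equal(rk$rs, oracleSpearmanUntied(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5)))
  expect_equal(rk$rs, 0.9)
  expect_equal(rk$ranks$official_rank[rk$ranks$park_id == "a"], 1)  # 1 = most visited
  # invariance under strictly monotone transforms of the totals
  expect_equal(spearmanRanking(off5^3, exp(sud5 / 100))$rs, rk$rs)
  # constant side -> undefined
  expect_true(is.na(spearmanRanking(off5, setNames(rep(5, 5), letters[1:5]))$rs))
})

test_that("acf/pacf match direct estimators and the white-noise band flags
           alternating series", {
  set.seed(13)
  x <- rpois(12, 30)
  s <- autocorrelationScreen(x)
  expect_equal(s$acf, oracleACF(x, 11), tolerance = 1e-10)
  expect_equal(s$pacf, oraclePACF(x, 11), tolerance = 1e-8)
  expect_equal(s$acf[1], 1)                       # lag 0 by definition
  expect_equal(s$sig_band, qnorm(0.975) / sqrt(12))

  alt <- rep(c(40, 10), 6)                        # strictly alternating
  sa <- autocorrelationScreen(alt)
  r1 <- oracleACF(alt, 1)[2]
  expect_lt(r1, 0)                                # negative lag-1
  expect_gt(abs(r1), sa$sig_band)
  expect_true(1 %in% sa$sig_lags_acf)
  expect_true(sa$autocorrelated)

  expect_true(autocorrelationScreen(rep(5, 12))$degenerate)
  # custom flag policy: disabling the trigger lags clears the flag
  expect_false(autocorrelationScreen(alt, flag_lags = integer())$autocorrelated)
})

test_that("popularity trend recovers exact linear structure and a closed-form
           OLS slope", {
  mk <- function(r, total) {
    structure(data.frame(park_id = sprintf("p%d", seq_along(r)),
                         source = "combined", pearson_r = r, n_months = 12L,
                         autocorrelated = FALSE, excluded = FALSE),
              class = c("ParkCorrelationTable", "data.frame")) }
  totals <- data.frame(park_id = sprintf("p%d", 1:6), source = "official",
                       total = 10^seq(2, 4.5, length.out = 6))
  r_lin <- 0.1 + 0.2 * log10(totals$total)
  tr <- popularityTrend(mk(r_lin), totals, predictor = "official")
  expect_equal(tr$pearson_r, 1)
  expect_equal(tr$slope, 0.2)

  r_const <- rep(0.5, 6)
  expect_equal(popularityTrend(mk(r_const), totals)$slope, 0)

  set.seed(4)
  r6 <- runif(6, 0.2, 0.95)
  lx <- log10(totals$total)
  slope_hand <- sum((lx - mean(lx)) * (r6 - mean(r6))) / sum((lx - mean(lx))^2)
  expect_equal(popularityTrend(mk(r6), totals)$slope, slope_hand)

  # zero-total parks are dropped (log undefined); < 3 usable -> error
  totals$total[1:4] <- 0
  expect_error(popularityTrend(mk(r6), totals), "fewer than 3")
})

test_that("parkCorrelations joins official and SUD patterns and applies the
           screen to both series", {
  # park A: official follows a clean seasonal curve, SUD proportional (r = 1)
  prof <- round(200 * seasonalProfile(7, 1.5))
  cnt <- cbind(instagram = prof, official = 5 * prof)
  mm <- MonthlyMatrix(cnt, "A", 2014, 1:12,
                      type = c("platform", "official"))
  cc <- parkCorrelations(mm, 2014, flag_lags = integer())
  expect_equal(cc$pearson_r[cc$source == "instagram"], 1, tolerance = 1e-12)
  expect_false(any(cc$excluded))
  # the default policy flags the same park: smooth seasonality is
  # short-lag autocorrelated
  cc2 <- parkCorrelations(mm, 2014)
  expect_true(all(cc2$excluded))
  expect_equal(cc2$pearson_r, cc$pearson_r)  # r itself is unaffected
})
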