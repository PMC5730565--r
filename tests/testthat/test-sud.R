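mkAssigned <- function(user, park, time_utc, platform = "instagram") {
  data.frame(user_id = user, platform = platform,
             timestamp = as.POSIXct(time_utc, tz = "UTC"),
             lon = 0, lat = 0, park_id = park, assignment_mode = "interior",
             distance_to_boundary_m = 0, stringsAsFactors = FALSE)
}

test_that("five same-day posts collapse to one user-day; three consecutive
           days count three times", {
  a <- mkAssigned(rep("u1", 5), "A",
                  sprintf("2014-07-10 %02d:00:00", 9:13))
  expect_equal(nrow(computeUserDays(a)), 1L)

  b <- mkAssigned(rep("u1", 3), "A",
                  sprintf("2014-07-%02d 12:00:00", 10:12))
  expect_equal(nrow(computeUserDays(b)), 3L)
})

test_that("the same user on the same day in two parks yields two user-days", {
  a <- mkAssigned(c("u1", "u1"), c("A", "B"),
                  rep("2014-07-10 12:00:00", 2))
  ud <- computeUserDays(a)
  expect_equal(nrow(ud), 2L)
  expect_setequal(ud$park_id, c("A", "B"))
})

test_that("platforms separate user-days; unassigned and excluded posts are
           ignored", {
  a <- mkAssigned(rep("u1", 2), "A", rep("2014-07-10 12:00:00", 2))
  a$platform <- c("instagram", "twitter")
  expect_equal(nrow(computeUserDays(a)), 2L)

  b <- mkAssigned(c("u1", "u2"), c("A", NA), rep("2014-07-10 12:00:00", 2))
  b$assignment_mode <- c("buffer", "unassigned")
  expect_equal(nrow(computeUserDays(b)), 1L)  # buffer counts, unassigned not
})

test_that("the reporting timezone bounds the calendar day", {
  a <- mkAssigned("u1", "A", "2014-07-10 23:30:00")
  expect_equal(computeUserDays(a, tz = "UTC")$date, as.Date("2014-07-10"))
  # UTC+2: 23:30 UTC is 01:30 the next day
  expect_equal(computeUserDays(a, tz = "Etc/GMT-2")$date,
               as.Date("2014-07-11"))
})

test_that("SUD is invariant to duplicated posts and never exceeds post
           counts", {
  set.seed(5)
  n <- 120
  a <- mkAssigned(sample(sprintf("u%d", 1:10), n, TRUE),
                  sample(c("A", "B", "C"), n, TRUE),
                  sprintf("2014-%02d-%02d 10:00:00",
                          sample(1:12, n, TRUE), sample(1:28, n, TRUE)),
                  platform = sample(c("instagram", "flickr"), n, TRUE))
  ud <- computeUserDays(a)
  expect_lte(nrow(ud), nrow(a))
  dup <- rbind(a, a[sample(n, 40), ])
  expect_equal(nrow(computeUserDays(dup)), nrow(ud))
  # adding a genuinely new post never decreases any cell
  mm1 <- monthlySUD(ud, 2014)
  extra <- rbind(a, mkAssigned("brand_new", "A", "2014-03-03 10:00:00"))
  mm2 <- monthlySUD(computeUserDays(extra), 2014)
  expect_true(all(sudCounts(mm2) - sudCounts(mm1) >= 0))
})

test_that("monthly aggregation matches an independent recount and zero-fills", {
  set.seed(23)
  n <- 200
  ud <- data.frame(
    user_id = sample(sprintf("u%d", 1:10), n, TRUE),
    park_id = sample(c("A", "B", "C"), n, TRUE),
    date = as.Date("2014-01-01") + sample(0:364, n, TRUE),
    platform = sample(c("instagram", "twitter"), n, TRUE),
    stringsAsFactors = FALSE)
  ud <- unique(ud)
  mm <- monthlySUD(ud, 2014)
  ref <- oracleMonthlyCount(ud, 2014)
  k <- monthKeys(mm)
  cnt <- sudCounts(mm)
  for (nm in names(ref)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    row <- which(k$park_id == parts[1] & k$month == as.integer(parts[2]))
    expect_equal(unname(cnt[row, parts[3]]), unname(as.integer(ref[nm])))
  }
  expect_equal(sum(cnt), nrow(ud))          # conservation
  expect_equal(nrow(k), 3 * 12)             # 12 zero-filled months per park
  # empty input with declared parks/platforms -> all-zero matrix
  mm0 <- monthlySUD(ud[0, ], 2014, park_ids = "A", platforms = "instagram")
  expect_equal(sum(sudCounts(mm0)), 0)
  expect_equal(nrow(monthKeys(mm0)), 12L)
})

test_that("three user-days in July land in July and nowhere else", {
  ud <- data.frame(user_id = c("u1", "u2", "u3"), park_id = "A",
                   date = as.Date(c("2014-07-01", "2014-07-15", "2014-07-31")),
                   platform = "instagram", stringsAsFactors = FALSE)
  mm <- monthlySUD(ud, 2014)
  k <- monthKeys(mm)
  expect_equal(unname(sudCounts(mm)[k$month == 7, "instagram"]), 3L)
  expect_equal(sum(sudCounts(mm)[k$month != 7, ]), 0)
})

test_that("combined column is the elementwise platform sum and annual totals
           match a direct sum", {
  set.seed(8)
  cnt <- matrix(rpois(72, 4), nrow = 24,
                dimnames = list(NULL, c("instagram", "twitter", "flickr")))
  mm <- MonthlyMatrix(cnt, park_id = rep(c("A", "B"), each = 12),
                      year = 2014, month = rep(1:12, 2))
  mc <- combinePlatforms(mm)
  expect_equal(unname(sudCounts(mc)[, "combined"]), unname(rowSums(cnt)))
  expect_true(validObject(mc))
  # single platform: combined equals it
  m1 <- combinePlatforms(MonthlyMatrix(cnt[, 1, drop = FALSE],
                                       rep(c("A", "B"), each = 12),
                                       2014, rep(1:12, 2)))
  expect_equal(unname(sudCounts(m1)[, "combined"]),
               unname(cnt[, 1]))
  tot <- annualTotals(mc)
  expect_equal(tot$total[tot$source == "combined" & tot$park_id == "A"],
               sum(cnt[1:12, ]))
  # all-zero park totals zero; 1-per-month totals 12
  mz <- MonthlyMatrix(matrix(c(rep(0, 12), rep(1, 12)), ncol = 2,
                             dimnames = list(NULL, c("a", "b"))),
                      "A", 2014, 1:12)
  tz <- annualTotals(mz)
  expect_equal(tz$total[tz$source == "a"], 0)
  expect_equal(tz$total[tz$source == "b"], 12)
})

test_that("a corrupted combined column fails validity", {
  cnt <- cbind(instagram = rep(1, 12), combined = rep(2, 12))
  expect_error(
    MonthlyMatrix(cnt, "A", 2014, 1:12, type = c("platform", "combined")),
    "combined")
})
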