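make_ar1 <- function(name, years, phi = 0.5, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(years))
  climate_series(name, years, as.numeric(stats::filter(e, phi,
                                                       method = "recursive")))
}

test_that("common period intersects ranges and honors the clip", {
  enso <- climate_series("ENSO", 1300:2004, rnorm(705))
  pdsi <- climate_series("PDSI", 1240:2006, rnorm(767))
  expect_equal(common_period(list(enso, pdsi), end = 1893), c(1300L, 1893L))
  expect_equal(common_period(enso), c(1300L, 2004L))
  late <- climate_series("PDO", 1950:2000, rnorm(51))
  early <- climate_series("AO", 1300:1400, rnorm(101))
  expect_error(common_period(list(late, early)), "no common period")
})

test_that("extreme-year selection matches a brute-force sort", {
  s <- climate_series("PDO", 1:100, 1:100)
  top <- select_extreme_years(s, "+", k = 5)
  expect_equal(top$event_years, 96:100)
  bot <- select_extreme_years(s, "-", k = 5)
  expect_equal(bot$event_years, 1:5)
  expect_length(intersect(top$event_years, bot$event_years), 0)

  ar <- make_ar1("ENSO", 1300:1999, seed = 11)
  es <- select_extreme_years(ar, "+", k = 50)
  brute <- sort(ar$years[order(-ar$values, ar$years)][1:50])
  expect_equal(es$event_years, brute)
  es_neg <- select_extreme_years(ar, "-", k = 50)
  brute_neg <- sort(ar$years[order(ar$values, ar$years)][1:50])
  expect_equal(es_neg$event_years, brute_neg)
  expect_error(select_extreme_years(ar, "+", k = 1000), "exceeds")
})

test_that("event sets are rank-based, hence invariant to monotone maps", {
  ar <- make_ar1("AO", 1400:1899, seed = 3)
  warped <- climate_series("AO", ar$years, exp(ar$values) + 5)
  expect_equal(select_extreme_years(ar, "+", 50)$event_years,
               select_extreme_years(warped, "+", 50)$event_years)
})

test_that("phase combination reduces to top-k for identical inputs", {
  ar <- make_ar1("ENSO", 1300:1899, seed = 21)
  twin <- climate_series("PDO", ar$years, ar$values)
  comb <- combine_phase_events(list(ar, twin), c("+", "+"), k = 60)
  expect_equal(comb$event_years,
               select_extreme_years(ar, "+", k = 60)$event_years)
})

test_that("rank-sum combination matches a brute-force oracle", {
  s1 <- make_ar1("ENSO", 1300:1899, seed = 31)
  s2 <- make_ar1("PDO", 1300:1899, phi = 0.7, seed = 32)
  s3 <- make_ar1("AO", 1300:1899, phi = 0.3, seed = 33)
  comb <- combine_phase_events(list(s1, s2, s3), c("+", "+", "-"), k = 100)
  # oracle: rank years per series in phase direction, smallest rank sums win
  rk <- function(v, sign, yrs) {
    o <- order(if (sign > 0) -v else v, yrs)
    r <- integer(length(v)); r[o] <- seq_along(v); r
  }
  yrs <- s1$years
  total <- rk(s1$values, 1, yrs) + rk(s2$values, 1, yrs) +
    rk(s3$values, -1, yrs)
  oracle <- sort(yrs[order(total, yrs)][1:100])
  expect_equal(comb$event_years, oracle)
})

test_that("ties are broken toward earlier years, deterministically", {
  x <- make_ar1("ENSO", 1500:1599, seed = 41)
  anti <- climate_series("PDO", x$years, -x$values)
  # constant rank sums: the earliest k years must be chosen
  comb <- combine_phase_events(list(x, anti), c("+", "+"), k = 10)
  expect_equal(comb$event_years, 1500:1509)
})

test_that("fire-year moisture classification thresholds PDSI", {
  pdsi <- climate_series("PDSI", 1800:1810,
                         c(-2, 0, 2, 0, 0, -1, 1, 0, 0, 0, 0))
  out <- classify_fire_year_moisture(pdsi, c(1800, 1801, 1802))
  expect_equal(unname(out$counts), c(1, 1, 1))
  all_avg <- classify_fire_year_moisture(pdsi, c(1801, 1803, 1804))
  expect_equal(unname(all_avg$counts), c(0, 3, 0))
  # boundary values land in the extreme categories
  expect_equal(unname(classify_fire_year_moisture(pdsi, 1805)$counts),
               c(1, 0, 0))
  expect_error(classify_fire_year_moisture(pdsi, 1700), "1700")
})

test_that("fires planted in dry years exceed the dry-year base rate", {
  set.seed(77)
  pdsi <- make_ar1("PDSI", 1300:1899, phi = 0.4, seed = 78)
  dry_years <- pdsi$years[pdsi$values <= -1]
  base_rate <- length(dry_years) / length(pdsi$years)
  fires <- sample(dry_years, 30)
  out <- classify_fire_year_moisture(pdsi, fires)
  expect_gt(out$proportions[["warm_dry"]], base_rate)
})
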