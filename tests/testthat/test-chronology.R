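test_that("the two-tree rule keeps multi-tree scar years only", {
  col <- collection_from_scars(list(
    A = c(1700), B = c(1700), C = c(1700, 1710)))
  ch2 <- detect_fire_events(col, min_trees = 2)
  expect_equal(ch2$events$year, 1700L)
  expect_equal(ch2$events$n_scarred, 3L)
  expect_equal(ch2$events$n_recording, 3L)
  ch1 <- detect_fire_events(col, min_trees = 1)
  expect_equal(ch1$events$year, c(1700L, 1710L))
  expect_error(detect_fire_events(col, min_trees = 0), "positive")
})

test_that("detected events are monotone decreasing in the tree threshold", {
  set.seed(55)
  for (i in 1:5) {
    col <- rand_collection(10)
    yrs <- lapply(1:4, function(m) detect_fire_events(col, m)$events$year)
    for (m in 2:4) expect_true(all(yrs[[m]] %in% yrs[[m - 1]]))
  }
})

test_that("single-scar years are promoted only with a qualifying cohort", {
  col <- collection_from_scars(list(
    A = c(1700), B = c(1700), C = c(1800), D = c(1850)))
  ch <- detect_fire_events(col, 2)
  expect_equal(ch$events$year, 1700L)
  # five establishing trees within the decade after 1800; 1850's cohort too late
  est <- c(1803, 1804, 1805, 1806, 1807, 1865, 1866, 1867, 1868, 1869)
  ch2 <- verify_single_scar_events(col, ch, est, window = 10)
  expect_equal(ch2$events$year, c(1700L, 1800L))
  expect_equal(ch2$events$cohort_verified, c(FALSE, TRUE))
  # a cohort of four is below the default minimum
  ch3 <- verify_single_scar_events(col, ch, c(1803:1806), window = 10)
  expect_equal(ch3$events$year, 1700L)
})

test_that("cohorts in the window of an existing event corroborate it instead", {
  col <- collection_from_scars(list(
    A = c(1700), B = c(1700), C = c(1705)))
  ch <- detect_fire_events(col, 2)
  # establishment 1706-1710 sits in 1700's window, so it cannot verify 1705
  ch2 <- verify_single_scar_events(col, ch, 1706:1710, window = 10)
  expect_equal(ch2$events$year, 1700L)
})

test_that("mean fire interval equals span over n - 1", {
  ch <- detect_fire_events(collection_from_scars(
    list(A = c(1376, 1893), B = c(1376, 1893))), 2)
  expect_equal(mean_fire_interval(ch), 517)
  ch3 <- detect_fire_events(collection_from_scars(
    list(A = c(1400, 1450, 1500), B = c(1400, 1450, 1500))), 2)
  expect_equal(mean_fire_interval(ch3), 50)
  set.seed(9)
  yrs <- sort(sample(1376:1893, 16))
  chr <- detect_fire_events(collection_from_scars(list(A = yrs, B = yrs)), 2)
  expect_equal(mean_fire_interval(chr), sum(diff(yrs)) / 15)
  expect_equal(mean_fire_interval(chr),
               (max(yrs) - min(yrs)) / (length(yrs) - 1))
  one <- detect_fire_events(collection_from_scars(list(A = 1700, B = 1700)), 2)
  expect_error(mean_fire_interval(one), "fewer than 2")
})

test_that("point fire interval pools within-tree scar intervals", {
  col1 <- collection_from_scars(list(A = c(1700, 1800)))
  expect_equal(point_fire_interval(col1), 100)
  col2 <- collection_from_scars(list(A = c(1700, 1750),
                                     B = c(1500, 1600, 1750),
                                     C = c(1820)))
  # intervals 50, 100, 150; the single-scar tree contributes nothing
  expect_equal(point_fire_interval(col2), 100)
  expect_error(point_fire_interval(collection_from_scars(list(A = 1700))),
               "no tree has 2 or more")
})

test_that("severity is mixed only when a burned plot has a post-fire cohort", {
  col <- collection_from_scars(
    list(A = 1700, B = 1700, C = 1800, D = 1800),
    plots = c(A = "P1", B = "P2", C = "P1", D = "P3"))
  ch <- detect_fire_events(col, 2)
  ch <- assign_severity(ch, list(P1 = c(1702, 1703), P9 = 1802))
  expect_equal(ch$events$severity, c("mixed", "low"))
  ch_none <- assign_severity(detect_fire_events(col, 2), list())
  expect_equal(ch_none$events$severity, c("low", "low"))
})
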