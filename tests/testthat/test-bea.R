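test_that("K counts backward pairs with the documented normalization", {
  # single fire at 50, single climate event at 48 on a 100-year domain:
  # the pair enters at lag 2 with full weight
  k <- k_bivariate_1d(50, 48, c(1, 100), 5)
  expect_equal(unname(k), c(0, 0, 100, 100, 100, 100))
  # a climate event in the fire year counts at lag 0
  k0 <- k_bivariate_1d(50, 50, c(1, 100), 2)
  expect_equal(unname(k0), c(100, 100, 100))
  # identical event sets at lag 0: each fire pairs with its own year
  fires <- c(10, 40, 70)
  expect_equal(unname(k_bivariate_1d(fires, fires, c(1, 100), 0)), 100 / 3)
})

test_that("the fast K equals brute-force pair counting", {
  set.seed(202)
  for (i in 1:60) {
    T0 <- sample(30:200, 1)
    domain <- c(1000, 1000 + T0 - 1)
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    fires <- sort(sample(domain[1]:domain[2], n1))
    climate <- sort(sample(domain[1]:domain[2], n2))
    t_max <- sample(0:min(30, T0 - 2), 1)
    expect_equal(unname(k_bivariate_1d(fires, climate, domain, t_max)),
                 k1d_oracle(fires, climate, domain, t_max),
                 tolerance = 1e-12)
    expect_equal(unname(k_bivariate_1d(fires, climate, domain, t_max,
                                       edge_correction = "none")),
                 k1d_oracle(fires, climate, domain, t_max, edge = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("doubling the domain doubles K at interior lags", {
  fires <- c(500, 520, 560)
  climate <- c(498, 515, 555)
  k1 <- k_bivariate_1d(fires, climate, c(1, 1000), 10)
  k2 <- k_bivariate_1d(fires, climate, c(1, 2000), 10)
  expect_equal(unname(k2), 2 * unname(k1))
})

test_that("input contracts are enforced", {
  expect_error(k_bivariate_1d(integer(), 5, c(1, 10), 2), "non-empty")
  expect_error(k_bivariate_1d(5, 5, c(1, 10), 10), "smaller than the domain")
  expect_error(k_bivariate_1d(5, 50, c(1, 10), 2), "outside domain")
  expect_error(bea_envelopes(5, 3, c(1, 10), 2, n_reps = 10), "at least 100")
  expect_error(bea_envelopes(5, 3, c(1, 10), 2, levels = 1.05), "in \\(0, 1\\)")
})

test_that("envelopes are reproducible from the seed and properly nested", {
  set.seed(1)
  fires <- sort(sample(1300:1899, 16))
  climate <- sort(sample(1300:1899, 50))
  r1 <- bea_envelopes(fires, climate, c(1300, 1899), t_max = 15,
                      n_reps = 200, seed = 99)
  r2 <- bea_envelopes(fires, climate, c(1300, 1899), t_max = 15,
                      n_reps = 200, seed = 99)
  expect_identical(r1$envelopes, r2$envelopes)
  expect_equal(r1$null_expectation, 0:15 + 1)
  # the 99% band contains the 95% band pointwise
  expect_true(all(r1$envelopes[["99%"]]$lo <= r1$envelopes[["95%"]]$lo))
  expect_true(all(r1$envelopes[["99%"]]$hi >= r1$envelopes[["95%"]]$hi))
})

test_that("classification yields the documented lag windows", {
  khat <- rep(0.5, 21)
  khat[c(7:10, 14:18)] <- 2 # lags 6-9 and 13-17
  res <- fake_k1d_result(khat, lo = rep(0.2, 21), hi = rep(1, 21))
  cl <- classify_synchrony(res, 0.95)
  sync <- cl$windows[cl$windows$class == "synchronous", ]
  expect_equal(sync$from, c(6, 13))
  expect_equal(sync$to, c(9, 17))
  # all inside the band: one independent window spanning the lag grid
  res2 <- fake_k1d_result(rep(0.5, 21), rep(0.2, 21), rep(1, 21))
  cl2 <- classify_synchrony(res2, 0.95)
  expect_equal(cl2$windows,
               data.frame(class = "independent", from = 0L, to = 20L))
  # below the lower envelope everywhere: asynchronous everywhere
  res3 <- fake_k1d_result(rep(0.1, 21), rep(0.2, 21), rep(1, 21))
  expect_true(all(classify_synchrony(res3, 0.95)$labels == "asynchronous"))
  expect_error(classify_synchrony(res3, 0.99), "no envelope")
})

test_that("a strong planted lag is flagged as synchronous", {
  set.seed(500)
  climate <- sort(sample(1300:1896, 50))
  fires <- climate + 3
  r <- bea_envelopes(fires, climate, c(1300, 1899), t_max = 10,
                     n_reps = 500, levels = 0.95)
  expect_true(all(r$classification[4:11] == "synchronous"))
  expect_true(all(r$classification[1:2] != "synchronous"))
})

test_that("random fire years are independent of structured climate events", {
  set.seed(600)
  climate_sets <- list(pdo = sort(sample(1300:1899, 50)))
  out <- randomization_sanity(climate_sets, c(1300, 1899), n_events = 16,
                              t_max = 10, n_reps = 300, levels = 0.95,
                              seed = 601)
  # pointwise non-independence should stay near the nominal 5% rate
  expect_lt(out$prop_nonindependent[["pdo"]], 0.4)
})
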