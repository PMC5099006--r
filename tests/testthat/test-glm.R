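make_plots <- function(n = 30, beta0 = 1.5, beta_dist = -0.002) {
  d <- data.frame(
    plot_id = sprintf("P%02d", 1:n),
    vegetation_type = sample(c("zonal", "bog_forest", "bog_woodland",
                               "blanket_bog"), n, replace = TRUE),
    elevation_m = runif(n, 0, 150),
    slope_deg = runif(n, 0, 35),
    aspect_deg = runif(n, 0, 360),
    dist_habitation_m = runif(n, 0, 1000),
    dist_shoreline_m = runif(n, 0, 2000))
  d$n_fire_scars <- rpois(n, exp(beta0 + beta_dist * d$dist_habitation_m))
  d$n_fire_events <- rpois(n, exp(beta0 - 0.5 + beta_dist * d$dist_habitation_m))
  d
}

test_that("the IRLS fit matches closed-form Poisson MLEs", {
  set.seed(10)
  y <- rpois(40, 5)
  fit <- fit_poisson(y ~ 1, data.frame(y = y))
  expect_equal(fit$coefficients$estimate, log(mean(y)), tolerance = 1e-8)

  x <- rep(0:1, each = 25)
  y2 <- rpois(50, ifelse(x == 1, 8, 3))
  fit2 <- fit_poisson(y ~ x, data.frame(y = y2, x = x))
  m0 <- mean(y2[x == 0]); m1 <- mean(y2[x == 1])
  expect_equal(fit2$coefficients$estimate, c(log(m0), log(m1 / m0)),
               tolerance = 1e-8)
  expect_lte(fit2$residual_deviance, fit2$null_deviance)
})

test_that("a rank-deficient design is rejected with the aliased term named", {
  set.seed(2)
  d <- data.frame(y = rpois(20, 3), x1 = rnorm(20))
  d$x2 <- 2 * d$x1
  expect_error(fit_poisson(y ~ x1 + x2, d), "x2")
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(-50, 2, 30), 104 + 12 / 27)
  expect_equal(aicc(-50, 0, 30), 100) # no correction without parameters
  expect_equal(aicc(-50, 3, 1e9), -2 * -50 + 6, tolerance = 1e-6)
  expect_error(aicc(-50, 10, 11), "must exceed")
})

test_that("model ranking produces normalized weights and evidence ratios", {
  set.seed(30)
  plots <- make_plots()
  sel <- select_models(plots, "scar_abundance")
  tab <- sel$table
  expect_equal(nrow(tab), 64) # all subsets of six predictor blocks
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$dAICc[1], 0)
  expect_equal(tab$ER[1], 1)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_equal(tab$weight,
               exp(-tab$dAICc / 2) / sum(exp(-tab$dAICc / 2)))
  expect_equal(tab$ER, tab$weight[1] / tab$weight)
  expect_true(all(tab$pseudo_R2 >= 0 & tab$pseudo_R2 <= 1))
})

test_that("two identical candidates split the weight evenly", {
  set.seed(31)
  plots <- make_plots()
  sel <- select_models(plots, "event_frequency",
                       candidates = c("dist_habitation_m",
                                      "dist_habitation_m"))
  expect_equal(sel$table$weight, c(0.5, 0.5))
  expect_equal(sel$table$ER, c(1, 1))
})

test_that("model averaging shrinks absent predictors toward zero", {
  fit1 <- list(coefficients = data.frame(
    term = c("(Intercept)", "dist_habitation_m"), estimate = c(1, -0.002)))
  fit2 <- list(coefficients = data.frame(term = "(Intercept)", estimate = 1))
  fake <- structure(
    list(table = data.frame(model = c("m1", "m2"), K = c(2, 1),
                            pseudo_R2 = c(0.5, 0.1), AICc = c(100, 100),
                            dAICc = c(0, 0), weight = c(0.5, 0.5),
                            ER = c(1, 1)),
         fits = list(fit1, fit2), response = "scar_abundance", n = 30),
    class = "model_selection")
  avg <- model_average(fake, 0.95)
  expect_equal(avg$estimate[avg$term == "dist_habitation_m"], -0.001)
  expect_equal(avg$importance[avg$term == "dist_habitation_m"], 0.5)
  expect_equal(avg$estimate[avg$term == "(Intercept)"], 1)

  # a dominant top model forms a singleton confidence set
  fake$table$weight <- c(0.97, 0.03)
  avg1 <- model_average(fake, 0.95)
  expect_equal(attr(avg1, "confidence_set"), "m1")
  expect_equal(avg1$estimate[avg1$term == "dist_habitation_m"], -0.002)
})

test_that("aspect can enter as northness or raw degrees", {
  set.seed(32)
  plots <- make_plots()
  s1 <- select_models(plots, "scar_abundance",
                      candidates = c("1", "aspect"))
  s2 <- select_models(plots, "scar_abundance",
                      candidates = c("1", "aspect"), aspect = "degrees")
  f1 <- s1$fits[[which(s1$table$model == "aspect")]]
  f2 <- s2$fits[[which(s2$table$model == "aspect")]]
  expect_false(isTRUE(all.equal(f1$coefficients$estimate,
                                f2$coefficients$estimate)))
})
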