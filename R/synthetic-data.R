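#' Configuration for the synthetic fire-history generator
#'
#' Bundles every knob of the synthetic landscape, climate, fire-regime and
#' tree-record generators. The defaults emulate the study system the
#' package targets: a ~300 ha coastal temperate rainforest with 30 sample
#' plots across four vegetation types between sea level and 150 m, three
#' former habitation sites, reconstructed climate indices spanning
#' 1300-2000, an ignition regime that weakens with distance from
#' habitation sites and strengthens after dry (negative-PDSI) years, a
#' cessation of burning after 1893, and a sampling effort that recovers on
#' the order of 45 scarred trees carrying ~100 scars and ~16 composite
#' fire events.
#'
#' @param seed Base RNG seed; all generators derive from it.
#' @param period `c(first, last)` calendar years of the simulated record.
#' @param n_plots Number of sample plots.
#' @param n_habitation Number of former habitation sites.
#' @param extent_m Side of the square landscape (m); the shoreline is the
#'   `x = 0` edge.
#' @param veg_props Named proportions over the four vegetation types.
#' @param climate List: `phi` named AR(1) coefficients per index,
#'   `pdsi_scale` standard deviation of the rescaled PDSI (2 gives the
#'   familiar approx. -6..+6 range), `enso_pdo_rho` innovation correlation
#'   between ENSO and PDO.
#' @param regime List: `beta0` baseline annual ignition log-odds per plot,
#'   `beta_dist` change in log-odds per metre from the nearest habitation
#'   site (negative: burning concentrates near settlements), `gamma_dry`
#'   weight on last year's drought (`-PDSI` at lag 1), `switchoff_year`
#'   last year of human ignition, `post_drop` log-odds subtracted
#'   afterwards.
#' @param recording List: `trees_per_plot` sampled fire-scar trees per
#'   plot, `p_scar` probability a recording tree scars in a plot fire,
#'   `tree_start` range of tree innermost-ring years, `recording_delay`
#'   years after the innermost ring before a tree records fire,
#'   `cohort_prob` probability a plot fire triggers an establishment
#'   pulse, `cohort_size_mean` mean pulse size (Poisson), `cohort_window`
#'   years after fire over which the pulse establishes,
#'   `background_est_rate` background establishment rate (trees per plot
#'   per year).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             period = c(1300L, 2000L),
                             n_plots = 30L,
                             n_habitation = 3L,
                             extent_m = 2000,
                             veg_props = c(zonal = 0.3, bog_forest = 0.3,
                                           bog_woodland = 0.2,
                                           blanket_bog = 0.2),
                             climate = list(),
                             regime = list(),
                             recording = list()) {
  climate <- utils::modifyList(list(
    phi = c(PDSI = 0.4, ENSO = 0.3, PDO = 0.6, AO = 0.4),
    pdsi_scale = 2, enso_pdo_rho = 0.3), climate)
  regime <- utils::modifyList(list(
    beta0 = -8.5, beta_dist = -0.002, gamma_dry = 1.5,
    switchoff_year = 1893L, post_drop = 8), regime)
  recording <- utils::modifyList(list(
    trees_per_plot = 3L, p_scar = 0.6, tree_start = c(1225L, 1325L),
    recording_delay = 25L, cohort_prob = 0.3, cohort_size_mean = 6,
    cohort_window = 10L, background_est_rate = 0.02), recording)
  if (any(abs(climate$phi) >= 1)) stop("AR(1) coefficients must satisfy |phi| < 1")
  stopifnot(recording$p_scar >= 0, recording$p_scar <= 1,
            abs(sum(veg_props) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), period = as.integer(period),
                 n_plots = as.integer(n_plots),
                 n_habitation = as.integer(n_habitation),
                 extent_m = extent_m, veg_props = veg_props,
                 climate = climate, regime = regime, recording = recording),
            class = "synthetic_config")
}

#' Simulate reconstructed climate-index series
#'
#' Draws the four annual indices (PDSI, ENSO, PDO, AO) as stationary AR(1)
#' processes with unit marginal variance (PDSI rescaled to the usual
#' approx. -6..+6 range), with optional cross-correlated innovations
#' between ENSO and PDO.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed (defaults to the config's base seed).
#' @return Named list of four [climate_series].
#' @export
simulate_climate <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  years <- config$period[1]:config$period[2]
  n <- length(years)
  phi <- config$climate$phi
  rho <- config$climate$enso_pdo_rho
  innov <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, c("PDSI", "ENSO", "PDO", "AO")))
  # correlate ENSO and PDO innovations
  if (rho != 0) {
    innov[, "PDO"] <- rho * innov[, "ENSO"] + sqrt(1 - rho^2) * innov[, "PDO"]
  }
  out <- lapply(names(phi), function(nm) {
    p <- phi[[nm]]
    e <- innov[, nm] * sqrt(1 - p^2) # unit stationary variance
    x <- as.numeric(stats::filter(e, p, method = "recursive"))
    if (nm == "PDSI") x <- x * config$climate$pdsi_scale
    climate_series(nm, years, x)
  })
  names(out) <- names(phi)
  out
}

#' Simulate the landscape and the true fire process
#'
#' Places habitation sites and plots uniformly in the landscape, assigns
#' plot attributes, and draws plot-year fires as independent Bernoulli
#' trials with
#' `logit p = beta0 + beta_dist * dist_habitation + gamma_dry * (-PDSI[year - 1])`,
#' with `post_drop` subtracted after the human-ignition switch-off year.
#' Returns the ground truth the downstream recovery tests compare
#' against.
#'
#' @param config A [synthetic_config()].
#' @param climate Output of [simulate_climate()] (at least `$PDSI`).
#' @param seed RNG seed.
#' @return An object of class `fire_ground_truth`: list with `plots` (a
#'   plot-attribute data frame), `fire_years` (list of true fire years per
#'   plot), `params` (the generating regime) and `period`.
#' @export
simulate_fires <- function(config, climate, seed = config$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  np <- config$n_plots
  ext <- config$extent_m
  hab <- cbind(x = runif(config$n_habitation, 0, ext),
               y = runif(config$n_habitation, 0, ext))
  px <- runif(np, 0, ext)
  py <- runif(np, 0, ext)
  dist_hab <- vapply(seq_len(np), function(i) {
    sqrt(min((hab[, "x"] - px[i])^2 + (hab[, "y"] - py[i])^2))
  }, numeric(1))
  plots <- data.frame(
    plot_id = sprintf("P%02d", seq_len(np)),
    vegetation_type = sample(names(config$veg_props), np, replace = TRUE,
                             prob = config$veg_props),
    elevation_m = runif(np, 0, 150),
    slope_deg = runif(np, 0, 35),
    aspect_deg = runif(np, 0, 360),
    dist_habitation_m = dist_hab,
    dist_shoreline_m = px
  )
  reg <- config$regime
  pdsi <- climate$PDSI
  years <- (config$period[1] + 1L):config$period[2]
  dry_lag1 <- -pdsi$values[match(years - 1L, pdsi$years)]
  logit_year <- reg$beta0 + reg$gamma_dry * dry_lag1 -
    reg$post_drop * (years > reg$switchoff_year)
  fire_years <- lapply(seq_len(np), function(i) {
    p <- plogis(logit_year + reg$beta_dist * dist_hab[i])
    years[runif(length(years)) < p]
  })
  names(fire_years) <- plots$plot_id
  structure(list(plots = plots, fire_years = fire_years, params = reg,
                 period = config$period, habitation_xy = hab),
            class = "fire_ground_truth")
}

#' Simulate fire-scarred tree records and establishment dates
#'
#' Converts true plot fires into the observable evidence the field method
#' collects: each sampled tree independently records each plot fire in its
#' recording span as a season-undetermined (`U`) scar with probability
#' `p_scar`, and plot fires trigger post-fire establishment pulses plus a
#' low background establishment rate.
#'
#' @param truth A `fire_ground_truth` from [simulate_fires()].
#' @param config The same [synthetic_config()].
#' @param seed RNG seed.
#' @return List with `collection` (an [fhx_collection] that parses through
#'   the chronology stage unchanged) and `establishment` (named list of
#'   establishment years per plot).
#' @export
simulate_tree_records <- function(truth, config, seed = config$seed + 2L) {
  if (!is.null(seed)) set.seed(seed)
  rec <- config$recording
  last_year <- config$period[2]
  series <- list()
  establishment <- list()
  plot_of_series <- character()
  for (i in seq_len(nrow(truth$plots))) {
    pid <- truth$plots$plot_id[i]
    fires <- truth$fire_years[[pid]]
    for (j in seq_len(rec$trees_per_plot)) {
      sid <- sprintf("%sT%d", pid, j)
      first <- sample(rec$tree_start[1]:rec$tree_start[2], 1L)
      rec_from <- first + rec$recording_delay
      recordable <- fires[fires >= rec_from & fires < last_year]
      scars <- recordable[runif(length(recordable)) < rec$p_scar]
      series[[sid]] <- fhx_series(
        sid, first, last_year,
        scar_years = data.frame(year = scars,
                                code = rep("U", length(scars))),
        recording_years = rec_from:(last_year - 1L),
        pith_at_start = TRUE, bark_at_end = TRUE)
      plot_of_series[sid] <- pid
    }
    est <- integer()
    for (f in fires) {
      if (runif(1) < rec$cohort_prob) {
        size <- rpois(1, rec$cohort_size_mean)
        if (size > 0) {
          est <- c(est, f + sample.int(rec$cohort_window, size,
                                       replace = TRUE))
        }
      }
    }
    n_bg <- rpois(1, rec$background_est_rate *
                    (last_year - config$period[1]))
    est <- c(est, sample(config$period[1]:last_year, n_bg, replace = TRUE))
    establishment[[pid]] <- sort(est[est <= last_year])
  }
  list(collection = fhx_collection(series,
                                   site_name = "synthetic study area",
                                   plot_of_series = plot_of_series),
       establishment = establishment)
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [simulate_climate()], [simulate_fires()]
#' and [simulate_tree_records()], and attaching observed per-plot scar and
#' fire-event counts to the plot table (the input of the spatial GLM
#' stage).
#'
#' @param config A [synthetic_config()].
#' @return List with `climate`, `truth`, `collection`, `establishment` and
#'   `plots` (attributes plus `n_fire_scars` and `n_fire_events` counts).
#' @export
simulate_fire_history <- function(config = synthetic_config()) {
  climate <- simulate_climate(config)
  truth <- simulate_fires(config, climate)
  records <- simulate_tree_records(truth, config)
  plots <- truth$plots
  counts <- plot_fire_counts(records$collection)
  plots$n_fire_scars <- counts$n_fire_scars[match(plots$plot_id,
                                                  counts$plot_id)]
  plots$n_fire_events <- counts$n_fire_events[match(plots$plot_id,
                                                    counts$plot_id)]
  plots$n_fire_scars[is.na(plots$n_fire_scars)] <- 0L
  plots$n_fire_events[is.na(plots$n_fire_events)] <- 0L
  list(climate = climate, truth = truth, collection = records$collection,
       establishment = records$establishment, plots = plots,
       config = config)
}

#' Per-plot scar and fire-event counts
#'
#' @param collection An [fhx_collection] with a `plot_of_series` mapping.
#' @return Data frame with `plot_id`, `n_fire_scars` (total dated scars on
#'   the plot's trees) and `n_fire_events` (distinct scar years in the
#'   plot).
#' @export
plot_fire_counts <- function(collection) {
  scars <- scar_table(collection)
  scars <- scars[!is.na(scars$plot_id), , drop = FALSE]
  if (!nrow(scars)) {
    return(data.frame(plot_id = character(), n_fire_scars = integer(),
                      n_fire_events = integer()))
  }
  per <- split(scars, scars$plot_id)
  data.frame(
    plot_id = names(per),
    n_fire_scars = vapply(per, nrow, integer(1)),
    n_fire_events = vapply(per, function(d) length(unique(d$year)),
                           integer(1)),
    row.names = NULL
  )
}
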