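# Fixture builders and independent oracles shared across the test files.
# All randomness uses the caller's RNG state; tests set their own seeds.

# Random but valid FHX collection: scars strictly inside the series span so
# the canonical writer round-trips exactly.
rand_collection <- function(n_series = 10) {
  series <- lapply(seq_len(n_series), function(j) {
    first <- sample(1300:1500, 1)
    last <- first + sample(80:300, 1)
    rec <- sort(sample((first + 1):(last - 1), sample(10:60, 1)))
    n_scar <- sample(0:4, 1)
    scars <- sort(sample(rec, min(length(rec), n_scar)))
    fhx_series(
      sprintf("S%02d", j), first, last,
      scar_years = data.frame(
        year = scars,
        code = sample(c("U", "D", "E", "L"), length(scars), replace = TRUE)),
      recording_years = rec,
      pith_at_start = runif(1) < 0.5,
      bark_at_end = runif(1) < 0.5)
  })
  fhx_collection(series)
}

# Collection with prescribed scar years: scar_map is a list series_id ->
# integer scar years; every series spans [first, last] and records
# throughout the interior.
collection_from_scars <- function(scar_map, first = 1300, last = 1900,
                                  plots = NULL) {
  series <- lapply(names(scar_map), function(id) {
    yrs <- scar_map[[id]]
    fhx_series(id, first, last,
               scar_years = data.frame(year = yrs,
                                       code = rep("U", length(yrs))),
               recording_years = (first + 1):(last - 1))
  })
  fhx_collection(series, plot_of_series = plots)
}

# Brute-force 1-D bivariate K: explicit pair counting with the edge weight
# obtained by enumerating the window years. Independent of the package's
# findInterval-based implementation.
k1d_oracle <- function(fires, climate, domain, t_max, edge = TRUE) {
  T0 <- domain[2] - domain[1] + 1
  out <- numeric(t_max + 1)
  for (f in fires) {
    for (cl in climate) {
      d <- f - cl
      if (d < 0 || d > t_max) next
      for (t in d:t_max) {
        w <- if (edge) {
          win <- (f - t):f
          sum(win >= domain[1] & win <= domain[2]) / (t + 1)
        } else 1
        out[t + 1] <- out[t + 1] + 1 / w
      }
    }
  }
  out * T0 / (length(fires) * length(climate))
}

# Minimal hand-built k1d_result for classification tests.
fake_k1d_result <- function(khat, lo, hi, level = 0.95) {
  structure(
    list(t_grid = seq_along(khat) - 1L, khat = khat,
         null_expectation = seq_along(khat),
         envelopes = setNames(
           list(list(level = level, lo = lo, hi = hi)),
           sprintf("%g%%", 100 * level)),
         levels = level),
    class = "k1d_result")
}
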