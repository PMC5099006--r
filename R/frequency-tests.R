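#' Build a fire-by-climate-phase contingency table
#'
#' Tabulates fire years by climate-phase category over a period, with
#' expected counts under an equal likelihood of burning in all years:
#' `expected_i = total_fires * category_years_i / total_years`.
#'
#' @param fire_years Integer fire years within `period`.
#' @param phase_assignment Either a function mapping a year vector to
#'   category labels, or a named vector/list indexed by year.
#' @param period `c(start, end)` years of analysis; fire years outside it
#'   are dropped.
#' @return An object of class `phase_contingency` with `categories`,
#'   `observed`, `expected`, `category_years`, `total_fires`,
#'   `total_years`.
#' @export
build_contingency <- function(fire_years, phase_assignment, period) {
  years <- period[1]:period[2]
  fire_years <- fire_years[fire_years >= period[1] & fire_years <= period[2]]
  cat_of <- if (is.function(phase_assignment)) {
    as.character(phase_assignment(years))
  } else {
    as.character(phase_assignment[as.character(years)])
  }
  if (anyNA(cat_of) || length(cat_of) != length(years)) {
    stop("every year in the period must have a phase category")
  }
  fire_cat <- cat_of[match(fire_years, years)]
  if (anyNA(fire_cat)) {
    stop("uncategorized fire years: ",
         paste(fire_years[is.na(fire_cat)], collapse = ", "))
  }
  categories <- unique(cat_of)
  category_years <- vapply(categories, function(k) sum(cat_of == k), numeric(1))
  observed <- vapply(categories, function(k) sum(fire_cat == k), numeric(1))
  total_fires <- length(fire_years)
  total_years <- length(years)
  structure(
    list(categories = categories, observed = observed,
         expected = total_fires * category_years / total_years,
         category_years = category_years, total_fires = total_fires,
         total_years = total_years),
    class = "phase_contingency"
  )
}

#' G-test of goodness of fit
#'
#' Log-likelihood-ratio test of observed category counts against expected
#' counts: `G = 2 * sum(O * ln(O / E))` with the convention
#' `0 * ln(0) = 0`, referred to a chi-square distribution on
#' `length(O) - 1` degrees of freedom. Williams' correction and a Monte
#' Carlo multinomial p-value (useful when expected counts are small) are
#' available as options.
#'
#' @param observed Numeric vector of counts, or a `phase_contingency`.
#' @param expected Expected counts (same length and total as `observed`);
#'   taken from the contingency when one is supplied.
#' @param williams Apply Williams' continuity correction (default `FALSE`).
#' @param simulate_p If `TRUE`, compute the p-value by `n_sim` multinomial
#'   simulations instead of the chi-square approximation.
#' @param n_sim Number of simulations when `simulate_p = TRUE`.
#' @return List with `G`, `df`, `p_value`, `min_expected` and
#'   `approx_suspect` (`TRUE` when any expected count is below 5).
#' @export
g_test <- function(observed, expected = NULL, williams = FALSE,
                   simulate_p = FALSE, n_sim = 10000L) {
  if (inherits(observed, "phase_contingency")) {
    expected <- observed$expected
    observed <- observed$observed
  }
  if (length(observed) != length(expected)) {
    stop("'observed' and 'expected' must have equal length")
  }
  if (any(observed < 0)) stop("negative observed counts")
  if (any(expected <= 0)) stop("all expected counts must be positive")
  if (sum(observed) <= 0) stop("G-test undefined for zero total count")
  terms <- ifelse(observed > 0, observed * log(observed / expected), 0)
  G <- 2 * sum(terms)
  k <- length(observed)
  df <- k - 1L
  if (williams) {
    q <- 1 + (k^2 - 1) / (6 * sum(observed) * df)
    G <- G / q
  }
  p <- if (simulate_p) {
    n <- sum(observed)
    prob <- expected / sum(expected)
    sims <- stats::rmultinom(n_sim, n, prob)
    g_sim <- 2 * colSums(ifelse(sims > 0, sims * log(sims / expected), 0))
    (sum(g_sim >= G - 1e-12) + 1) / (n_sim + 1)
  } else {
    pchisq(G, df, lower.tail = FALSE)
  }
  list(G = G, df = df, p_value = p, min_expected = min(expected),
       approx_suspect = min(expected) < 5)
}

#' G-tests of fire frequency across climate phase combinations
#'
#' For each extreme-event set (single-index or phase-combination), splits
#' the period into event years and non-event years, counts fires in each,
#' and tests the split against equal likelihood of burning in all years.
#'
#' @param fire_years Integer fire years.
#' @param event_sets Named list of `extreme_event_set` objects (or plain
#'   year vectors, in which case `period` must cover them).
#' @param period Default analysis period for plain year vectors; each
#'   `extreme_event_set` is tested over its own period.
#' @param ... Passed on to [g_test()] (e.g. `williams`, `simulate_p`).
#' @return Data frame with one row per set: `combination`, `n_event_years`,
#'   `observed_in`, `expected_in`, `G`, `df`, `p_value`, `approx_suspect`.
#' @export
phase_combination_tests <- function(fire_years, event_sets, period = NULL,
                                    ...) {
  if (!length(event_sets)) stop("no event sets supplied")
  if (is.null(names(event_sets))) {
    names(event_sets) <- paste0("set", seq_along(event_sets))
  }
  rows <- lapply(names(event_sets), function(nm) {
    es <- event_sets[[nm]]
    if (inherits(es, "extreme_event_set")) {
      yrs <- es$event_years
      per <- es$period
      label <- paste0(paste0(es$source_names, es$phase_signs), collapse = "/")
    } else {
      yrs <- es
      per <- period
      label <- nm
    }
    if (is.null(per)) stop("'period' required for plain event-year vectors")
    assign <- function(y) ifelse(y %in% yrs, "event", "other")
    ct <- build_contingency(fire_years, assign, per)
    gt <- g_test(ct, ...)
    data.frame(
      combination = label, period_start = per[1], period_end = per[2],
      n_event_years = sum(ct$category_years[ct$categories == "event"]),
      total_fires = ct$total_fires,
      observed_in = sum(ct$observed[ct$categories == "event"]),
      expected_in = sum(ct$expected[ct$categories == "event"]),
      G = gt$G, df = gt$df, p_value = gt$p_value,
      approx_suspect = gt$approx_suspect
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
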