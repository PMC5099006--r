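#' Detect composite fire events from a fire-scar collection
#'
#' Compiles all dated fire scars in the collection into a study-area
#' composite and keeps as fire events the calendar years in which at least
#' `min_trees` distinct trees carry a fire scar (the standard two-tree event
#' rule). Lowercase injury codes do not count as fire scars.
#'
#' @param collection An [fhx_collection].
#' @param min_trees Minimum number of scarred trees for a year to qualify as
#'   a fire event (default 2).
#' @param by_plot If `TRUE`, apply the rule within each plot and keep years
#'   qualifying in any plot; requires `plot_of_series` on the collection.
#' @return A `composite_chronology`: a list with an `events` data frame
#'   (`year`, `n_scarred`, `n_recording`, `plots` comma-separated,
#'   `cohort_verified`, `severity`) plus `period_start` and `period_end`.
#' @export
detect_fire_events <- function(collection, min_trees = 2L, by_plot = FALSE) {
  if (!is.numeric(min_trees) || min_trees < 1) {
    stop("'min_trees' must be a positive integer")
  }
  min_trees <- as.integer(min_trees)
  scars <- scar_table(collection)
  depth <- recorder_depth(collection)
  if (!nrow(scars)) {
    return(new_chronology(empty_events()))
  }
  per_year <- split(scars, scars$year)
  keep <- if (by_plot) {
    vapply(per_year, function(d) {
      any(tapply(d$series_id, d$plot_id, function(x) length(unique(x))) >= min_trees)
    }, logical(1))
  } else {
    vapply(per_year, function(d) length(unique(d$series_id)) >= min_trees,
           logical(1))
  }
  per_year <- per_year[keep]
  events <- do.call(rbind, lapply(per_year, function(d) {
    yr <- d$year[1]
    data.frame(
      year = yr,
      n_scarred = length(unique(d$series_id)),
      n_recording = depth$depth[match(yr, depth$year)],
      plots = paste(sort(unique(d$plot_id[!is.na(d$plot_id)])), collapse = ","),
      cohort_verified = FALSE,
      severity = NA_character_
    )
  }))
  if (is.null(events)) events <- empty_events()
  new_chronology(events)
}

# Long table of dated fire scars (uppercase codes only) with plot ids.
scar_table <- function(collection) {
  rows <- lapply(collection$series, function(s) {
    sc <- s$scar_years[s$scar_years$code %in% .fhx_scar_codes, , drop = FALSE]
    if (!nrow(sc)) return(NULL)
    pid <- if (!is.null(collection$plot_of_series)) {
      unname(collection$plot_of_series[s$series_id])
    } else NA_character_
    data.frame(series_id = s$series_id, year = sc$year, code = sc$code,
               plot_id = if (is.null(pid) || is.na(pid)) NA_character_ else pid)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(series_id = character(), year = integer(),
                      code = character(), plot_id = character())
  }
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(year = integer(), n_scarred = integer(), n_recording = integer(),
             plots = character(), cohort_verified = logical(),
             severity = character())
}

new_chronology <- function(events) {
  events <- events[order(events$year), , drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(events = events,
         period_start = if (nrow(events)) min(events$year) else NA_integer_,
         period_end = if (nrow(events)) max(events$year) else NA_integer_),
    class = "composite_chronology"
  )
}

#' @export
print.composite_chronology <- function(x, ...) {
  cat(sprintf("Composite fire chronology: %d events", nrow(x$events)))
  if (nrow(x$events)) {
    cat(sprintf(" over %d-%d (%d yr)", x$period_start, x$period_end,
                x$period_end - x$period_start))
  }
  cat("\n")
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Verify single-scar fire years with post-fire cohorts
#'
#' Fire scars give exact fire years but a year recorded by only one tree
#' fails the two-tree event rule. Such years are promoted to fire events
#' when an establishment pulse (a post-fire cohort) of at least `min_cohort`
#' trees dates to the decade after the scar: establishment years in
#' `(scar_year, scar_year + window]`. Cohorts falling in the window of an
#' already-detected event corroborate that event rather than creating a new
#' one.
#'
#' @param collection An [fhx_collection].
#' @param chronology A `composite_chronology` from [detect_fire_events()].
#' @param establishment_years Integer vector of tree establishment (pith)
#'   years pooled over plots, or a list of such vectors per plot.
#' @param window Length of the post-fire establishment window in years
#'   (default 10).
#' @param min_cohort Minimum number of establishing trees that constitutes a
#'   cohort (default 5).
#' @return The chronology with verified single-scar events added
#'   (`cohort_verified = TRUE`).
#' @export
verify_single_scar_events <- function(collection, chronology,
                                      establishment_years, window = 10L,
                                      min_cohort = 5L) {
  if (window < 0) stop("'window' must be nonnegative")
  est <- sort(unlist(establishment_years, use.names = FALSE))
  scars <- scar_table(collection)
  if (!nrow(scars)) return(chronology)
  n_trees <- tapply(scars$series_id, scars$year,
                    function(x) length(unique(x)))
  singles <- as.integer(names(n_trees)[n_trees == 1L])
  singles <- setdiff(singles, chronology$events$year)
  if (!length(singles)) return(chronology)
  # establishment years already claimed by an existing event's window
  claimed <- est[vapply(est, function(e) {
    any(e > chronology$events$year & e <= chronology$events$year + window)
  }, logical(1))]
  free <- setdiff(est, claimed)
  depth <- recorder_depth(collection)
  add <- lapply(singles, function(yr) {
    n_est <- sum(free > yr & free <= yr + window)
    if (n_est < min_cohort) return(NULL)
    d <- scars[scars$year == yr, , drop = FALSE]
    data.frame(
      year = yr, n_scarred = 1L,
      n_recording = depth$depth[match(yr, depth$year)],
      plots = paste(sort(unique(d$plot_id[!is.na(d$plot_id)])), collapse = ","),
      cohort_verified = TRUE, severity = NA_character_
    )
  })
  add <- do.call(rbind, add)
  if (is.null(add)) return(chronology)
  new_chronology(rbind(chronology$events, add))
}

#' Mean fire interval of a composite chronology
#'
#' Arithmetic mean of the successive intervals between composite fire
#' years; for n events spanning S years this equals S / (n - 1).
#'
#' @param chronology A `composite_chronology`.
#' @param period Optional `c(start, end)` clip applied to the event years
#'   before computing intervals.
#' @return Mean fire interval in years.
#' @export
mean_fire_interval <- function(chronology, period = NULL) {
  years <- chronology$events$year
  if (!is.null(period)) years <- years[years >= period[1] & years <= period[2]]
  if (length(years) < 2L) {
    stop("mean fire interval undefined: fewer than 2 fire events")
  }
  mean(diff(sort(years)))
}

#' Point fire interval (tree-scale mean fire interval)
#'
#' Mean interval between successive fire scars on the same tree, pooled
#' across all trees carrying at least two scars. Trees with a single scar
#' contribute no interval.
#'
#' @param collection An [fhx_collection].
#' @return Point fire interval in years.
#' @export
point_fire_interval <- function(collection) {
  intervals <- unlist(lapply(collection$series, function(s) {
    yrs <- sort(unique(s$scar_years$year[s$scar_years$code %in% .fhx_scar_codes]))
    if (length(yrs) < 2L) return(NULL)
    diff(yrs)
  }), use.names = FALSE)
  if (!length(intervals)) {
    stop("point fire interval undefined: no tree has 2 or more scars")
  }
  mean(intervals)
}

#' Classify fire-event severity from post-fire cohorts
#'
#' A fire that killed part of the canopy opens growing space and leaves an
#' establishment pulse; a surface fire that only scarred survivors does
#' not. Events with a post-fire cohort in at least one burned plot are
#' labelled `"mixed"` severity, events recorded by scars alone `"low"`.
#'
#' @param chronology A `composite_chronology`.
#' @param establishment_by_plot Named list of establishment-year vectors per
#'   plot id (may be empty).
#' @param window Post-fire window in years within which establishment counts
#'   as a cohort (default 10).
#' @return The chronology with the `severity` column filled.
#' @export
assign_severity <- function(chronology, establishment_by_plot = list(),
                            window = 10L) {
  ev <- chronology$events
  if (!nrow(ev)) return(chronology)
  ev$severity <- vapply(seq_len(nrow(ev)), function(i) {
    plots <- strsplit(ev$plots[i], ",", fixed = TRUE)[[1]]
    plots <- plots[nzchar(plots)]
    hit <- any(vapply(plots, function(p) {
      est <- establishment_by_plot[[p]]
      !is.null(est) && any(est > ev$year[i] & est <= ev$year[i] + window)
    }, logical(1)))
    if (hit) "mixed" else "low"
  }, character(1))
  new_chronology(ev)
}

#' Summary of scar and sample counts
#'
#' @param collection An [fhx_collection].
#' @return List with `n_trees` (series carrying at least one fire scar),
#'   `n_scars` (total dated fire scars), `scars_per_tree` (mean over scarred
#'   trees) and `max_scars`.
#' @export
scar_summary <- function(collection) {
  per_tree <- vapply(collection$series, function(s) {
    sum(s$scar_years$code %in% .fhx_scar_codes)
  }, integer(1))
  scarred <- per_tree[per_tree > 0L]
  list(
    n_trees = length(scarred),
    n_scars = sum(scarred),
    scars_per_tree = if (length(scarred)) mean(scarred) else NA_real_,
    max_scars = if (length(scarred)) max(scarred) else 0L
  )
}
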