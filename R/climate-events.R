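#' Construct an annual climate-index series
#'
#' Holds one reconstructed annual climate index (PDSI, ENSO, PDO or AO) on
#' a contiguous run of calendar years. By the usual sign convention,
#' negative PDSI values indicate dry years and positive values wet years.
#'
#' @param name Index name, one of `"PDSI"`, `"ENSO"`, `"PDO"`, `"AO"` (other
#'   labels are allowed but unchecked).
#' @param years Contiguous ascending integer years.
#' @param values Numeric index value per year.
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(name, years, values) {
  years <- as.integer(years)
  if (length(years) != length(values)) {
    stop("'years' and 'values' must have equal length")
  }
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop(sprintf("series '%s': years must be contiguous and ascending", name))
  }
  structure(list(name = name, years = years, values = as.numeric(values)),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("Climate series %s: %d-%d (n = %d), range [%.2f, %.2f]\n",
              x$name, min(x$years), max(x$years), length(x$years),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read a year/value climate CSV
#'
#' @param file CSV with columns `year` and `value`; the index name is taken
#'   from `name` or, when `NULL`, from the file name.
#' @param name Optional index name.
#' @return A [climate_series].
#' @export
read_climate_csv <- function(file, name = NULL) {
  d <- utils::read.csv(file)
  if (!all(c("year", "value") %in% names(d))) {
    stop("climate CSV must have columns 'year' and 'value'")
  }
  if (is.null(name)) name <- toupper(sub("\\.csv$", "", basename(file)))
  d <- d[order(d$year), ]
  climate_series(name, d$year, d$value)
}

#' Common period of analysis for a set of series
#'
#' Intersects the year ranges of the given climate series, optionally
#' clipped to an analysis window (analyses tied to a fire record typically
#' clip the end to the last detected fire year).
#'
#' @param series_list List of [climate_series] (a single series may be given
#'   directly).
#' @param start,end Optional clip bounds.
#' @return Integer vector `c(start, end)`.
#' @export
common_period <- function(series_list, start = NULL, end = NULL) {
  if (inherits(series_list, "climate_series")) series_list <- list(series_list)
  if (!length(series_list)) stop("at least one series is required")
  lo <- max(vapply(series_list, function(s) min(s$years), integer(1)))
  hi <- min(vapply(series_list, function(s) max(s$years), integer(1)))
  if (!is.null(start)) lo <- max(lo, as.integer(start))
  if (!is.null(end)) hi <- min(hi, as.integer(end))
  if (lo > hi) stop("series have no common period")
  c(lo, hi)
}

# Rank years of one series in the direction of a phase sign:
# rank 1 = most extreme (largest value for "+", smallest for "-");
# ties broken by earlier year.
phase_ranks <- function(series, sign, period) {
  sign <- match_sign(sign)
  keep <- series$years >= period[1] & series$years <= period[2]
  years <- series$years[keep]
  vals <- series$values[keep]
  ord <- order(if (sign > 0) -vals else vals, years)
  r <- integer(length(years))
  r[ord] <- seq_along(years)
  data.frame(year = years, rank = r)
}

match_sign <- function(sign) {
  if (is.numeric(sign)) return(if (sign >= 0) 1L else -1L)
  switch(as.character(sign),
         "+" = , "positive" = 1L,
         "-" = , "negative" = -1L,
         stop("'sign' must be '+' or '-'"))
}

#' Select extreme climate-event years from one index
#'
#' Defines climate "events" as the `k` most extreme annual values of an
#' index within a period: the k most positive years for the positive phase
#' or the k most negative for the negative phase. The returned set of years
#' feeds the synchrony and frequency analyses.
#'
#' @param series A [climate_series].
#' @param sign `"+"` or `"-"`: which phase of the index.
#' @param k Number of event years (default 50).
#' @param period `c(start, end)`; defaults to the series' own range.
#' @return An object of class `extreme_event_set` with fields
#'   `source_names`, `phase_signs`, `event_years`, `k`, `rank_rule`,
#'   `period`.
#' @export
select_extreme_years <- function(series, sign, k = 50L, period = NULL) {
  if (is.null(period)) period <- common_period(series)
  rk <- phase_ranks(series, sign, period)
  if (k > nrow(rk)) {
    stop(sprintf("k = %d exceeds the %d years of the period %d-%d",
                 k, nrow(rk), period[1], period[2]))
  }
  yrs <- sort(rk$year[rk$rank <= k])
  structure(
    list(source_names = series$name,
         phase_signs = if (match_sign(sign) > 0) "+" else "-",
         event_years = yrs, k = as.integer(k), rank_rule = "single_topk",
         period = period),
    class = "extreme_event_set"
  )
}

#' Combine climate phases into joint extreme-event years
#'
#' For two- and three-way phase interactions each index is ranked within
#' the common period in the direction of its phase (rank 1 = most extreme)
#' and the per-year ranks are combined. The default `"rank_sum"` rule keeps
#' the `k` years with the smallest rank sum, which always yields exactly
#' `k` years; `"union"` and `"intersection"` instead combine the per-index
#' top-`k` sets and may return more or fewer years.
#'
#' @param series_list List of 2-3 [climate_series].
#' @param signs Character vector of `"+"`/`"-"` phases, one per series.
#' @param k Number of event years for the rank-sum rule, and per-index set
#'   size for union/intersection (default 100).
#' @param period Common period; defaults to the intersection of ranges.
#' @param rule One of `"rank_sum"`, `"union"`, `"intersection"`.
#' @return An `extreme_event_set` with `rank_rule = "combined_rank"`.
#' @export
combine_phase_events <- function(series_list, signs, k = 100L, period = NULL,
                                 rule = c("rank_sum", "union", "intersection")) {
  rule <- match.arg(rule)
  if (inherits(series_list, "climate_series")) series_list <- list(series_list)
  if (length(signs) != length(series_list)) {
    stop("'signs' must give one phase per series")
  }
  if (is.null(period)) period <- common_period(series_list)
  if (rule == "rank_sum") {
    ranks <- mapply(function(s, sg) phase_ranks(s, sg, period)$rank,
                    series_list, signs)
    years <- period[1]:period[2]
    if (k > length(years)) stop("k exceeds the common-period length")
    total <- rowSums(as.matrix(ranks))
    ord <- order(total, years)
    yrs <- sort(years[ord[seq_len(k)]])
  } else {
    sets <- mapply(function(s, sg) {
      select_extreme_years(s, sg, k = k, period = period)$event_years
    }, series_list, signs, SIMPLIFY = FALSE)
    yrs <- sort(Reduce(if (rule == "union") union else intersect, sets))
  }
  structure(
    list(source_names = vapply(series_list, `[[`, character(1), "name"),
         phase_signs = vapply(signs, function(sg) {
           if (match_sign(sg) > 0) "+" else "-"
         }, character(1)),
         event_years = yrs, k = as.integer(k), rank_rule = "combined_rank",
         period = period),
    class = "extreme_event_set"
  )
}

#' @export
print.extreme_event_set <- function(x, ...) {
  cat(sprintf("Extreme event set %s (%s): %d years in %d-%d\n",
              paste(x$source_names, collapse = "/"),
              paste(x$phase_signs, collapse = "/"),
              length(x$event_years), x$period[1], x$period[2]))
  invisible(x)
}

#' Classify fire years by moisture status
#'
#' Splits fire years into warm/dry, average and cool/wet categories by
#' thresholding the PDSI in the fire year (negative PDSI = dry).
#'
#' @param pdsi A [climate_series] of PDSI values.
#' @param fire_years Integer fire years, all within the PDSI record.
#' @param dry_threshold Fire-year PDSI at or below this is warm/dry
#'   (default -1).
#' @param wet_threshold Fire-year PDSI at or above this is cool/wet
#'   (default +1).
#' @return List with `counts` and `proportions`, each a named numeric over
#'   `warm_dry`, `average`, `cool_wet`.
#' @export
classify_fire_year_moisture <- function(pdsi, fire_years,
                                        dry_threshold = -1,
                                        wet_threshold = 1) {
  missing <- setdiff(fire_years, pdsi$years)
  if (length(missing)) {
    stop("fire years outside the PDSI record: ",
         paste(missing, collapse = ", "))
  }
  v <- pdsi$values[match(fire_years, pdsi$years)]
  cat3 <- ifelse(v <= dry_threshold, "warm_dry",
                 ifelse(v >= wet_threshold, "cool_wet", "average"))
  counts <- vapply(c("warm_dry", "average", "cool_wet"),
                   function(k) sum(cat3 == k), numeric(1))
  list(counts = counts, proportions = counts / max(1, length(fire_years)))
}
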