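# Cell codes used in the FHX year-by-series matrix.
.fhx_scar_codes <- c("D", "E", "M", "L", "A", "U")
.fhx_injury_codes <- tolower(.fhx_scar_codes)
.fhx_event_codes <- c(.fhx_scar_codes, .fhx_injury_codes)

#' Construct a single fire-scar tree series
#'
#' A tree series is the annual record of one crossdated fire-scarred tree:
#' its year span, whether the innermost ring reaches pith and the outermost
#' reaches bark, the dated fire scars (uppercase season codes, here usually
#' `"U"` for season undetermined) or injuries (lowercase), and the years in
#' which the tree is an active fire recorder.
#'
#' Any scar year not listed among the recording years is promoted to
#' recording status with a warning: a tree that scarred in a year was, by
#' definition, recording fire in that year.
#'
#' @param series_id Short unique label for the tree.
#' @param first_year,last_year Calendar-year span of the series.
#' @param scar_years Data frame with columns `year` (integer) and `code`
#'   (one of `D E M L A U` for scars, lowercase for injuries), or `NULL`.
#' @param recording_years Integer vector of years in which the tree records
#'   fire (the `|` years of an FHX file).
#' @param pith_at_start,bark_at_end Logical; `TRUE` when the series bounds
#'   are true pith/bark dates rather than innermost/outermost ring dates.
#' @return An object of class `fhx_series`.
#' @examples
#' fhx_series("T01", 1400, 1900,
#'   scar_years = data.frame(year = 1700, code = "U"),
#'   recording_years = 1650:1899
#' )
#' @export
fhx_series <- function(series_id, first_year, last_year,
                       scar_years = NULL, recording_years = integer(),
                       pith_at_start = FALSE, bark_at_end = FALSE) {
  first_year <- as.integer(first_year)
  last_year <- as.integer(last_year)
  if (length(series_id) != 1L || !nzchar(series_id)) {
    stop("'series_id' must be a single non-empty string")
  }
  if (first_year > last_year) {
    stop(sprintf("series '%s': first_year (%d) exceeds last_year (%d)",
                 series_id, first_year, last_year))
  }
  if (is.null(scar_years)) {
    scar_years <- data.frame(year = integer(), code = character())
  }
  scar_years$year <- as.integer(scar_years$year)
  scar_years$code <- as.character(scar_years$code)
  bad <- !scar_years$code %in% .fhx_event_codes
  if (any(bad)) {
    stop(sprintf("series '%s': unknown scar codes: %s", series_id,
                 paste(unique(scar_years$code[bad]), collapse = ", ")))
  }
  recording_years <- sort(unique(as.integer(recording_years)))
  out_of_span <- c(
    scar_years$year[scar_years$year < first_year | scar_years$year > last_year],
    recording_years[recording_years < first_year | recording_years > last_year]
  )
  if (length(out_of_span)) {
    stop(sprintf("series '%s': years outside span [%d, %d]: %s", series_id,
                 first_year, last_year,
                 paste(unique(out_of_span), collapse = ", ")))
  }
  orphan <- setdiff(scar_years$year, recording_years)
  if (length(orphan)) {
    warning(sprintf(
      "series '%s': scar years %s fall in non-recording runs; treating them as recording",
      series_id, paste(orphan, collapse = ", ")))
    recording_years <- sort(union(recording_years, orphan))
  }
  scar_years <- scar_years[order(scar_years$year), , drop = FALSE]
  rownames(scar_years) <- NULL
  structure(
    list(series_id = series_id, first_year = first_year,
         last_year = last_year, pith_at_start = isTRUE(pith_at_start),
         bark_at_end = isTRUE(bark_at_end), scar_years = scar_years,
         recording_years = recording_years),
    class = "fhx_series"
  )
}

#' Construct a collection of fire-scar series for one site
#'
#' @param series List of [fhx_series] objects.
#' @param site_name Site label.
#' @param plot_of_series Named character vector mapping `series_id` to a
#'   plot id, or `NULL` when plots are unknown.
#' @return An object of class `fhx_collection`.
#' @export
fhx_collection <- function(series, site_name = "unnamed site",
                           plot_of_series = NULL) {
  stopifnot(is.list(series))
  ids <- vapply(series, function(s) s$series_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate series ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  names(series) <- ids
  if (!is.null(plot_of_series)) {
    plot_of_series <- plot_of_series[ids[ids %in% names(plot_of_series)]]
  }
  structure(
    list(site_name = site_name, series = series,
         plot_of_series = plot_of_series),
    class = "fhx_collection"
  )
}

#' @export
print.fhx_collection <- function(x, ...) {
  sp <- collection_span(x)
  n_scars <- sum(vapply(x$series, function(s) nrow(s$scar_years), integer(1)))
  cat(sprintf("FHX collection '%s': %d series, %d scars", x$site_name,
              length(x$series), n_scars))
  if (length(x$series)) cat(sprintf(", span %d-%d", sp[1], sp[2]))
  cat("\n")
  invisible(x)
}

#' Year span of a collection
#'
#' @param collection An [fhx_collection].
#' @return Integer vector `c(first, last)` over all series.
#' @export
collection_span <- function(collection) {
  if (!length(collection$series)) stop("collection has no series")
  c(min(vapply(collection$series, `[[`, integer(1), "first_year")),
    max(vapply(collection$series, `[[`, integer(1), "last_year")))
}

#' Read a fire-history file in FHX format
#'
#' Parses the standard plain-text Fire History Exchange matrix: a format
#' header (`FHX2 FORMAT` or `FIRE2 FORMAT`), a line giving the first year,
#' number of series and id length, vertically written series ids, and one
#' row per calendar year whose j-th character encodes the state of series j
#' (`[`/`]` pith/bark, `{`/`}` innermost/outermost ring, `|` recording,
#' `.` non-recording, uppercase letters dated fire scars, lowercase letters
#' injuries, space outside the series span).
#'
#' @param file Path to an FHX file, or a character vector of its lines.
#' @return An [fhx_collection].
#' @seealso [write_fhx()]
#' @examples
#' f <- system.file("extdata", "example.fhx", package = "firesync")
#' col <- read_fhx(f)
#' recorder_depth(col)[76:80, ]
#' detect_fire_events(col)$events
#' @export
read_fhx <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (length(file) == 1L && grepl("\n", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(file)
  }
  hdr_i <- grep("^(FHX2|FIRE2) FORMAT", lines)
  if (!length(hdr_i)) {
    stop("FHX parse error at line 1: missing 'FHX2 FORMAT' or 'FIRE2 FORMAT' header")
  }
  hdr_i <- hdr_i[1]
  meta <- suppressWarnings(
    as.integer(strsplit(trimws(lines[hdr_i + 1L]), "\\s+")[[1]])
  )
  if (length(meta) != 3L || anyNA(meta)) {
    stop(sprintf(
      "FHX parse error at line %d: expected 'first_year n_series id_length', got '%s'",
      hdr_i + 1L, lines[hdr_i + 1L]))
  }
  first_year <- meta[1]; n_series <- meta[2]; id_length <- meta[3]
  id_lines <- lines[(hdr_i + 2L):(hdr_i + 1L + id_length)]
  ids <- vapply(seq_len(n_series), function(j) {
    chars <- vapply(id_lines, function(l) {
      if (nchar(l) >= j) substr(l, j, j) else " "
    }, character(1))
    trimws(paste(chars, collapse = ""))
  }, character(1))
  if (anyDuplicated(ids[nzchar(ids)])) {
    stop("FHX parse error: duplicate series ids in header block")
  }
  body <- lines[(hdr_i + 2L + id_length):length(lines)]
  # skip the single blank separator line(s) before the matrix
  while (length(body) && !nzchar(trimws(body[1]))) body <- body[-1]
  while (length(body) && !nzchar(trimws(body[length(body)]))) {
    body <- body[-length(body)]
  }
  n_years <- length(body)
  if (!n_years) stop("FHX parse error: no data rows")
  cells <- matrix(" ", nrow = n_years, ncol = n_series)
  for (i in seq_len(n_years)) {
    row <- body[i]
    year <- first_year + i - 1L
    trailer <- if (nchar(row) > n_series) {
      trimws(substr(row, n_series + 1L, nchar(row)))
    } else ""
    if (nzchar(trailer) && !grepl("^-?[0-9]+$", trailer)) {
      stop(sprintf(
        "FHX parse error at year %d: row wider than %d series ('%s')",
        year, n_series, trailer))
    }
    row <- formatC(substr(row, 1L, n_series), width = n_series, flag = "-")
    cells[i, ] <- strsplit(row, "")[[1]]
  }
  known <- c(.fhx_event_codes, "|", ".", "[", "]", "{", "}", " ")
  series <- vector("list", n_series)
  for (j in seq_len(n_series)) {
    col <- cells[, j]
    bad <- which(!col %in% known)
    if (length(bad)) {
      stop(sprintf("FHX parse error at year %d, series '%s': unknown code '%s'",
                   first_year + bad[1] - 1L, ids[j], col[bad[1]]))
    }
    present <- which(col != " ")
    if (!length(present)) {
      stop(sprintf("FHX parse error: series '%s' has an empty year span", ids[j]))
    }
    yrs <- first_year + present - 1L
    codes <- col[present]
    is_event <- codes %in% .fhx_event_codes
    scar_years <- data.frame(year = yrs[is_event], code = codes[is_event])
    recording <- yrs[codes == "|" | is_event]
    series[[j]] <- fhx_series(
      series_id = ids[j],
      first_year = min(yrs), last_year = max(yrs),
      scar_years = scar_years, recording_years = recording,
      pith_at_start = codes[1] == "[",
      bark_at_end = codes[length(codes)] == "]"
    )
  }
  fhx_collection(series)
}

#' Write a collection to FHX format
#'
#' Emits a canonical FHX2 document that [read_fhx()] parses back to an
#' identical collection. The first and last year of each series are written
#' as boundary markers (`[`/`{` and `]`/`}`) unless a scar falls on them, so
#' generated series should keep scars strictly inside their span for exact
#' round trips.
#'
#' @param collection An [fhx_collection].
#' @param file Optional path; when given the document is also written there.
#' @return The document as a character vector of lines, invisibly when
#'   `file` is given.
#' @export
write_fhx <- function(collection, file = NULL) {
  series <- collection$series
  n_series <- length(series)
  header <- "FHX2 FORMAT"
  if (!n_series) {
    out <- c(header, "0 0 0")
  } else {
    sp <- collection_span(collection)
    years <- sp[1]:sp[2]
    ids <- names(series)
    id_length <- max(nchar(ids))
    id_block <- vapply(seq_len(id_length), function(r) {
      paste(vapply(ids, function(id) {
        if (nchar(id) >= r) substr(id, r, r) else " "
      }, character(1)), collapse = "")
    }, character(1))
    cells <- matrix(" ", nrow = length(years), ncol = n_series)
    for (j in seq_len(n_series)) {
      s <- series[[j]]
      if (s$first_year > s$last_year) stop("series with empty year span")
      idx <- (s$first_year:s$last_year) - sp[1] + 1L
      col <- rep(".", length(idx))
      col[(s$recording_years - s$first_year) + 1L] <- "|"
      if (s$pith_at_start) col[1] <- "[" else if (col[1] == ".") col[1] <- "{"
      n <- length(col)
      if (s$bark_at_end) col[n] <- "]" else if (col[n] == ".") col[n] <- "}"
      if (nrow(s$scar_years)) {
        col[(s$scar_years$year - s$first_year) + 1L] <- s$scar_years$code
      }
      cells[idx, j] <- col
    }
    rows <- vapply(seq_along(years), function(i) {
      paste0(paste(cells[i, ], collapse = ""), " ", years[i])
    }, character(1))
    out <- c(header, paste(sp[1], n_series, id_length), id_block, "", rows)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Sample recorder depth per year
#'
#' The recorder depth of a chronology is, for every calendar year in the
#' collection span, the number of tree series actively recording fire in
#' that year. It is the denominator against which scarred-tree counts are
#' judged.
#'
#' @param collection An [fhx_collection].
#' @return Data frame with columns `year` and `depth`.
#' @export
recorder_depth <- function(collection) {
  sp <- collection_span(collection)
  years <- sp[1]:sp[2]
  depth <- integer(length(years))
  for (s in collection$series) {
    idx <- s$recording_years - sp[1] + 1L
    depth[idx] <- depth[idx] + 1L
  }
  data.frame(year = years, depth = depth)
}
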