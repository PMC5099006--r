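#' Fit a Poisson regression of per-plot fire counts
#'
#' Thin wrapper around [stats::glm()] with a log link, returning the pieces
#' the model-selection stage needs: coefficients with standard errors and
#' Wald z, deviances, log-likelihood and a convergence flag.
#'
#' @param formula Model formula; the response is a per-plot count.
#' @param data Data frame of plot attributes and counts.
#' @return An object of class `fire_glm_fit` with elements `coefficients`
#'   (data frame of `term`, `estimate`, `se`, `z`, `p_value`),
#'   `null_deviance`, `residual_deviance`, `logLik`, `K` (number of
#'   estimated parameters), `n`, `converged`, `formula` and the underlying
#'   `glm` object.
#' @export
fit_poisson <- function(formula, data) {
  fit <- glm(formula, family = poisson(link = "log"), data = data)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  structure(
    list(
      coefficients = data.frame(
        term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
        z = sm[, 3], p_value = sm[, 4], row.names = NULL),
      null_deviance = fit$null.deviance,
      residual_deviance = fit$deviance,
      logLik = as.numeric(logLik(fit)),
      K = length(coef(fit)),
      n = nrow(data),
      converged = fit$converged,
      formula = formula,
      glm = fit),
    class = "fire_glm_fit"
  )
}

#' @export
print.fire_glm_fit <- function(x, ...) {
  cat("Poisson GLM:", deparse(x$formula), "\n")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("null deviance %.2f, residual %.2f, logLik %.2f (K = %d, n = %d)\n",
              x$null_deviance, x$residual_deviance, x$logLik, x$K, x$n))
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`; reduces to AIC as
#' `n` grows.
#'
#' @param logLik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Sample size; must exceed `K + 1`.
#' @return The AICc value.
#' @export
aicc <- function(logLik, K, n) {
  if (n <= K + 1) {
    stop(sprintf("AICc undefined: n (%d) must exceed K + 1 (%d)", n, K + 1))
  }
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# Conceptual predictor blocks: vegetation enters as one block of dummies
# with blanket bog as the reference level.
.glm_blocks <- c("dist_habitation_m", "dist_shoreline_m", "elevation_m",
                 "slope_deg", "aspect", "vegetation_type")

prepare_plot_data <- function(plots, aspect = c("northness", "degrees")) {
  aspect <- match.arg(aspect)
  d <- as.data.frame(plots)
  req <- c("dist_habitation_m", "dist_shoreline_m", "elevation_m",
           "slope_deg", "aspect_deg", "vegetation_type")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("plot data lacks columns: ", paste(miss, collapse = ", "))
  d$aspect <- if (aspect == "northness") {
    cos(d$aspect_deg * pi / 180)
  } else {
    d$aspect_deg
  }
  d$vegetation_type <- stats::relevel(
    factor(d$vegetation_type,
           levels = union("blanket_bog", unique(d$vegetation_type))),
    ref = "blanket_bog")
  d
}

#' All-subsets AICc model selection for per-plot fire counts
#'
#' Fits Poisson GLMs for every subset of the six conceptual predictors
#' (distance to former habitation site, distance to shoreline, elevation,
#' slope, aspect, and vegetation type as one dummy block with blanket bog
#' as reference), ranks them by AICc, and reports Akaike weights, evidence
#' ratios and deviance-based pseudo-R².
#'
#' @param plots Data frame of plot records with the attribute columns
#'   `dist_habitation_m`, `dist_shoreline_m`, `elevation_m`, `slope_deg`,
#'   `aspect_deg`, `vegetation_type` and the count columns `n_fire_scars`
#'   and `n_fire_events`.
#' @param response `"scar_abundance"` (counts from `n_fire_scars`) or
#'   `"event_frequency"` (`n_fire_events`).
#' @param candidates Optional character vector of model formulas (right-hand
#'   sides) replacing the all-subsets default.
#' @param aspect Encoding of the circular aspect variable: `"northness"`
#'   (`cos(aspect)`, default) or raw `"degrees"`.
#' @return An object of class `model_selection`: a list with `table` (one
#'   row per model: `model`, `K`, `pseudo_R2`, `AICc`, `dAICc`, `weight`,
#'   `ER`), `fits` (the `fire_glm_fit`s in table order), `response`, `n`.
#' @export
select_models <- function(plots,
                          response = c("scar_abundance", "event_frequency"),
                          candidates = NULL,
                          aspect = c("northness", "degrees")) {
  response <- match.arg(response)
  d <- prepare_plot_data(plots, aspect)
  ycol <- switch(response, scar_abundance = "n_fire_scars",
                 event_frequency = "n_fire_events")
  if (!ycol %in% names(d)) stop("plot data lacks count column ", ycol)
  if (is.null(candidates)) {
    blocks <- .glm_blocks
    candidates <- unlist(lapply(0:length(blocks), function(m) {
      if (m == 0) return("1")
      apply(utils::combn(blocks, m), 2, paste, collapse = " + ")
    }))
  }
  if (length(candidates) < 2L) stop("at least 2 candidate models required")
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    rhs <- candidates[i]
    f <- stats::as.formula(paste(ycol, "~", rhs))
    fit <- tryCatch(fit_poisson(f, d), error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      warning(sprintf("model '%s' excluded: %s", rhs,
                      if (inherits(fit, "error")) conditionMessage(fit)
                      else "did not converge"))
      next
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      model = rhs, K = fit$K,
      pseudo_R2 = 1 - fit$residual_deviance / fit$null_deviance,
      AICc = aicc(fit$logLik, fit$K, fit$n))
  }
  ok <- !vapply(rows, is.null, logical(1))
  fits <- fits[ok]
  tab <- do.call(rbind, rows[ok])
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$weight <- exp(-tab$dAICc / 2)
  tab$weight <- tab$weight / sum(tab$weight)
  tab$ER <- tab$weight[1] / tab$weight
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, response = response,
                 n = nrow(d)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, digits = 3, ...) {
  cat(sprintf("AICc model selection for %s (%d models, n = %d plots)\n",
              x$response, nrow(x$table), x$n))
  print(head(format(x$table, digits = digits), 10), row.names = FALSE)
  invisible(x)
}

#' Akaike-weight model averaging over a confidence set
#'
#' Averages coefficients across the smallest set of top-ranked models whose
#' cumulative Akaike weight reaches `confidence`, with weights renormalized
#' within the set. Predictors absent from a model contribute a coefficient
#' of zero (shrinkage averaging). Per-predictor relative importance is the
#' summed weight of the confidence-set models containing the predictor.
#'
#' @param selection A `model_selection` from [select_models()].
#' @param confidence Cumulative-weight threshold of the confidence set
#'   (default 0.95).
#' @return An object of class `averaged_coefficients`: data frame of
#'   `term`, `estimate` (shrinkage-averaged, log-link scale) and
#'   `importance`, plus attributes `confidence_set` (model labels) and
#'   `weights`.
#' @export
model_average <- function(selection, confidence = 0.95) {
  tab <- selection$table
  m <- which(cumsum(tab$weight) >= confidence)[1]
  if (is.na(m)) m <- nrow(tab)
  sel <- seq_len(m)
  w <- tab$weight[sel] / sum(tab$weight[sel])
  fits <- selection$fits[sel]
  terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  est <- setNames(numeric(length(terms)), terms)
  imp <- setNames(numeric(length(terms)), terms)
  for (i in seq_along(fits)) {
    co <- fits[[i]]$coefficients
    est[co$term] <- est[co$term] + w[i] * co$estimate
    imp[co$term] <- imp[co$term] + w[i]
  }
  out <- data.frame(term = terms, estimate = unname(est),
                    importance = unname(imp))
  structure(out, class = c("averaged_coefficients", "data.frame"),
            confidence_set = tab$model[sel], weights = w)
}
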