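# Closed-form pooled semi-log OLS. Returns slope of ln(value) on time, its
# standard error, and bookkeeping. With `replicate` supplied, a per-replicate
# intercept variant is obtained by centering both variables within replicate
# (Frisch-Waugh), costing one residual df per extra intercept.
ols_semilog <- function(time, log_value, replicate = NULL,
                        per_replicate_intercept = FALSE) {
  n <- length(time)
  if (per_replicate_intercept && !is.null(replicate)) {
    t_c <- time - ave(time, replicate)
    y_c <- log_value - ave(log_value, replicate)
    df <- n - n_distinct(replicate) - 1L
  } else {
    t_c <- time - mean(time)
    y_c <- log_value - mean(log_value)
    df <- n - 2L
  }
  sxx <- sum(t_c^2)
  if (sxx == 0) abort("all time points identical; slope is undefined")
  slope <- sum(t_c * y_c) / sxx
  rss <- max(sum(y_c^2) - slope^2 * sxx, 0)
  se <- if (df > 0) sqrt(rss / df / sxx) else NA_real_
  list(slope = slope, se = se, n = n, df = df, rss = rss,
       tss = sum(y_c^2))
}

decay_row <- function(fit, cv_threshold) {
  k <- -fit$slope
  cv <- if (k != 0) fit$se / abs(k) else Inf
  reliable <- is.finite(cv) && k > 0 && cv < cv_threshold
  tibble(
    k = k, se_k = fit$se, cv = cv, reliable = reliable,
    half_life = if (k > 0) ln2 / k else NA_real_,
    n_points = fit$n
  )
}

#' Fit degradation rate constants for all transcripts and strains
#'
#' For each (transcript, strain), an ordinary least-squares regression of
#' ln(intensity) on time is fit over all pooled replicate points with a
#' single common intercept. The degradation rate constant k is minus the
#' slope; its coefficient of variation is the slope standard error divided by
#' the slope, and an estimate is flagged reliable only if the CV is below
#' `cv_threshold` (strict inequality). The half-life is ln(2)/k, undefined
#' (NA) when k <= 0; such transcripts are retained, not dropped.
#'
#' @param tm Transcript-level tibble (columns `transcript_id`, `strain`,
#'   `time_min`, `intensity`, optionally `replicate`).
#' @param cv_threshold Reliability cut on the CV of the slope (default 0.30).
#' @param per_replicate_intercept Fit one intercept per replicate instead of
#'   a common intercept (sensitivity analysis; default FALSE).
#' @return Tibble with one row per (transcript, strain): `transcript_id`,
#'   `strain`, `k` (per minute), `se_k`, `cv`, `reliable`, `half_life`
#'   (minutes), `n_points`.
#' @examples
#' tm <- tibble::tibble(transcript_id = "a", strain = "wt",
#'                      time_min = c(1, 2, 4, 8),
#'                      intensity = 100 * exp(-0.231 * c(1, 2, 4, 8)))
#' fit_decay_all(tm)
#' @export
fit_decay_all <- function(tm, cv_threshold = 0.30,
                          per_replicate_intercept = FALSE) {
  tm <- as_tibble(tm)
  if (any(tm$intensity <= 0)) abort("intensities must be positive")
  counts <- count(tm, .data$transcript_id, .data$strain)
  if (any(counts$n < 3)) {
    offenders <- counts$transcript_id[counts$n < 3]
    abort(sprintf("need >= 3 points per (transcript, strain); offending: %s",
                  paste(head(unique(offenders), 5), collapse = ", ")))
  }
  rep_col <- if ("replicate" %in% names(tm)) tm$replicate else NULL
  tm |>
    reframe({
      fit <- ols_semilog(.data$time_min, log(.data$intensity),
                         replicate = if (per_replicate_intercept) .data$replicate,
                         per_replicate_intercept = per_replicate_intercept)
      decay_row(fit, cv_threshold)
    }, .by = c("transcript_id", "strain"))
}

#' Fit the decay rate of one transcript in one strain
#'
#' Pooled semi-log regression for a single (transcript, strain), returning a
#' `decay_fit` object that carries the estimate, the fitted line and the
#' underlying points for plotting; see [fit_decay_all()] for the batch
#' version and the estimator definition.
#'
#' @inheritParams fit_decay_all
#' @param transcript_id Transcript to fit.
#' @param strain Strain to fit.
#' @return An object of class `decay_fit`; use [tidy()] / [glance()] to
#'   extract the estimates as tibbles.
#' @export
fit_decay <- function(tm, transcript_id, strain, cv_threshold = 0.30,
                      per_replicate_intercept = FALSE) {
  sub <- filter(as_tibble(tm), .data$transcript_id == !!transcript_id,
                .data$strain == !!strain)
  if (nrow(sub) == 0) {
    abort(sprintf("no data for transcript '%s' in strain '%s'",
                  transcript_id, strain))
  }
  new_decay_fit(sub$time_min, sub$intensity,
                replicate = if ("replicate" %in% names(sub)) sub$replicate,
                cv_threshold = cv_threshold,
                per_replicate_intercept = per_replicate_intercept,
                label = sprintf("%s (%s)", transcript_id, strain))
}

new_decay_fit <- function(time, value, replicate = NULL, cv_threshold = 0.30,
                          per_replicate_intercept = FALSE, label = "series") {
  if (length(time) < 3) abort("need >= 3 points to fit a decay rate")
  fit <- ols_semilog(time, log(value), replicate = replicate,
                     per_replicate_intercept = per_replicate_intercept)
  est <- decay_row(fit, cv_threshold)
  intercept <- mean(log(value)) - fit$slope * mean(time)
  structure(
    list(estimate = est, slope = fit$slope, intercept = intercept,
         r_squared = if (fit$tss > 0) 1 - fit$rss / fit$tss else NA_real_,
         data = tibble(time_min = time, value = value),
         cv_threshold = cv_threshold, label = label),
    class = "decay_fit"
  )
}

#' Fit an exponential decay to a single measured series
#'
#' Semi-log ordinary least squares of ln(value) on time -- the generic
#' estimator used for slot-blot mRNAs, small-RNA northerns, bulk-decay counts
#' and pulse-chase protein series. Non-positive values inside the fit window
#' are dropped with a message; the fit requires at least 3 remaining points.
#' The estimated rate (and hence the half-life) is invariant to overall
#' scaling of the series.
#'
#' @param series Tibble with columns `time_min` and `value`.
#' @param fit_window Optional numeric `c(min, max)` time range; points outside
#'   are excluded.
#' @param cv_threshold Reliability cut on the slope CV (default 0.30).
#' @return An object of class `decay_fit`.
#' @examples
#' s <- tibble::tibble(time_min = c(0, 2.5, 5, 7.5), value = 8 / 2^(0:3))
#' glance(fit_exponential(s))
#' @export
fit_exponential <- function(series, fit_window = NULL, cv_threshold = 0.30) {
  series <- as_tibble(series)
  stopifnot(all(c("time_min", "value") %in% names(series)))
  if (!is.null(fit_window)) {
    series <- filter(series, .data$time_min >= fit_window[1],
                     .data$time_min <= fit_window[2])
  }
  n_bad <- sum(series$value <= 0)
  if (n_bad > 0) {
    inform(sprintf("dropping %d non-positive value(s) before semi-log fit", n_bad))
    series <- filter(series, .data$value > 0)
  }
  if (nrow(series) < 3) abort("fewer than 3 positive points in the fit window")
  new_decay_fit(series$time_min, series$value, cv_threshold = cv_threshold,
                label = if ("label" %in% names(series))
                  as.character(series$label[[1]]) else "series")
}

#' @export
print.decay_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("Exponential decay fit: %s\n", x$label))
  cat(sprintf("  k = %.4g /min (se %.3g, cv %.3g)  half-life = %.4g min  %s\n",
              e$k, e$se_k, e$cv,
              ifelse(is.na(e$half_life), NA, e$half_life),
              if (e$reliable) "reliable" else "NOT reliable"))
  invisible(x)
}

#' @rdname fit_exponential
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("log_intercept", "k"),
         estimate = c(x$intercept, x$estimate$k),
         std.error = c(NA_real_, x$estimate$se_k))
}

#' @rdname fit_exponential
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  bind_cols(x$estimate, tibble(r.squared = x$r_squared))
}

#' Per-strain half-life distribution summary
#'
#' Restricts to transcripts whose estimates are reliable in every strain
#' present, then summarizes the per-strain half-life distributions (count,
#' median, quartiles).
#'
#' @param estimates Decay-estimate tibble from [fit_decay_all()].
#' @return Tibble with one row per strain: `strain`, `n`, `median`, `q25`,
#'   `q75`.
#' @seealso [filter_reliable_both()] for the underlying filtered table.
#' @export
half_life_table <- function(estimates) {
  hl <- filter_reliable_both(estimates)
  if (nrow(hl) == 0) abort("no transcript is reliable in every strain")
  hl |>
    summarise(n = n(),
              median = median(.data$half_life),
              q25 = quantile(.data$half_life, 0.25, names = FALSE),
              q75 = quantile(.data$half_life, 0.75, names = FALSE),
              .by = "strain")
}

#' Transcripts with reliable estimates in every strain
#'
#' @inheritParams half_life_table
#' @return Long tibble (`transcript_id`, `strain`, `half_life`, ...)
#'   containing only transcripts flagged reliable in all strains; this is the
#'   comparison universe for distribution tests and enrichment backgrounds.
#' @export
filter_reliable_both <- function(estimates) {
  estimates <- as_tibble(estimates)
  n_strains <- n_distinct(estimates$strain)
  keep <- estimates |>
    filter(.data$reliable) |>
    count(.data$transcript_id) |>
    filter(.data$n == n_strains) |>
    pull("transcript_id")
  filter(estimates, .data$transcript_id %in% keep)
}
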