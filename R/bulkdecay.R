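#' Subtract the stable-RNA baseline from a bulk decay series
#'
#' In pulse-labelled total-RNA decay measurements a proportion of the label
#' is in stable species (rRNA, tRNA). The stable level is estimated as the
#' arithmetic mean of the values at the late sampling times (by default 30,
#' 40 and 50 min, when mRNA has essentially fully decayed) and subtracted
#' from the earlier time points. Late points are removed from the returned
#' series (they carry no decay information after subtraction) and
#' non-positive subtracted values are dropped with a message, never imputed.
#'
#' @param series Tibble with columns `time_min`, `value` (and optionally
#'   `replicate`; the baseline is then estimated within each replicate).
#' @param late_times Times whose mean value is the stable baseline; all must
#'   be present in the series.
#' @return Tibble of the earlier time points with baseline-subtracted
#'   `value` and a `baseline` column recording the subtracted constant.
#' @examples
#' s <- tibble::tibble(time_min = c(1, 30, 40, 50),
#'                     value = c(1500, 500, 510, 490))
#' subtract_stable_baseline(s)
#' @export
subtract_stable_baseline <- function(series, late_times = c(30, 40, 50)) {
  series <- as_tibble(series)
  stopifnot(all(c("time_min", "value") %in% names(series)))
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  out <- series |>
    group_by(.data$replicate) |>
    group_modify(function(df, key) {
      missing <- setdiff(late_times, df$time_min)
      if (length(missing) > 0) {
        abort(sprintf("late timepoint(s) missing from series: %s",
                      paste(missing, collapse = ", ")))
      }
      baseline <- mean(df$value[df$time_min %in% late_times])
      early <- filter(df, .data$time_min < min(late_times))
      early <- mutate(early, value = .data$value - baseline,
                      baseline = baseline)
      n_bad <- sum(early$value <= 0)
      if (n_bad > 0) {
        inform(sprintf(
          "dropping %d point(s) at or below the stable baseline", n_bad))
        early <- filter(early, .data$value > 0)
      }
      early
    }) |>
    ungroup()
  relocate(out, "time_min", "value", "baseline", "replicate")
}

#' Chemical half-life of bulk mRNA from labelled-RNA decay counts
#'
#' Applies [subtract_stable_baseline()] and then fits the remaining early
#' points with the semi-log estimator [fit_exponential()]. With a
#' `replicate` column, each replicate series is fit independently and one
#' row per replicate is returned (half-lives are conventionally reported as
#' mean and SD over replicates).
#'
#' @inheritParams subtract_stable_baseline
#' @param cv_threshold Reliability cut on the slope CV (default 0.30).
#' @return Tibble with one row per replicate: the [glance()] columns of the
#'   fit plus `replicate` and `baseline`.
#' @export
chemical_half_life <- function(series, late_times = c(30, 40, 50),
                               cv_threshold = 0.30) {
  sub <- subtract_stable_baseline(series, late_times)
  sub |>
    group_by(.data$replicate) |>
    group_modify(function(df, key) {
      fit <- fit_exponential(df, cv_threshold = cv_threshold)
      mutate(glance(fit), baseline = df$baseline[[1]])
    }) |>
    ungroup() |>
    relocate("replicate")
}

#' Functional half-life of bulk mRNA from protein synthesis rates
#'
#' Protein synthesis rates measured by pulse labelling after transcription
#' shutoff are treated as proportional to the remaining functional mRNA, so
#' their decline is fit directly by semi-log regression; no baseline is
#' subtracted. With a `replicate` column each series is fit independently.
#'
#' @param rates Tibble with columns `time_min`, `value` (synthesis rate) and
#'   optionally `replicate`.
#' @param cv_threshold Reliability cut on the slope CV (default 0.30).
#' @return Tibble with one row per replicate: [glance()] columns of the fit.
#' @export
functional_half_life <- function(rates, cv_threshold = 0.30) {
  rates <- as_tibble(rates)
  if (!"replicate" %in% names(rates)) rates$replicate <- 1L
  rates |>
    group_by(.data$replicate) |>
    group_modify(function(df, key) {
      glance(fit_exponential(df, cv_threshold = cv_threshold))
    }) |>
    ungroup() |>
    relocate("replicate")
}

#' Normalize a target signal to a co-measured reference signal
#'
#' Convenience wrapper for the slot-blot / northern workflow: the target band
#' or slot signal is divided by a stable reference signal (e.g. 23S rRNA)
#' quantified on the same blot, and the ratio series is then fit with
#' [fit_exponential()].
#'
#' @param series Tibble with columns `time_min`, `value` (target signal) and
#'   `reference_value` (reference signal, positive).
#' @return Tibble like `series` with `value` replaced by the target/reference
#'   ratio and `reference_value` dropped.
#' @export
normalized_series <- function(series) {
  series <- as_tibble(series)
  stopifnot(all(c("time_min", "value", "reference_value") %in% names(series)))
  if (any(series$reference_value <= 0)) {
    abort("reference values must be strictly positive")
  }
  series |>
    mutate(value = .data$value / .data$reference_value) |>
    select(-"reference_value")
}
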