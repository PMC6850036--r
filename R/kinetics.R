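#' Cleavage fraction and initial velocity from gel signals
#'
#' The extent of cleavage is the proportion of product signal to total
#' (product + remaining substrate) signal on the gel. Initial-velocity
#' conditions require limiting the extent of cleavage; a warning is issued
#' when the fraction exceeds 20%.
#'
#' @param product_signal,total_signal Numeric vectors of band signals
#'   (fluorescence units); `total_signal > 0` and
#'   `product_signal <= total_signal`.
#' @return Numeric vector of cleavage fractions in `[0, 1]`.
#' @seealso [cleavage_velocity()]
#' @export
cleavage_fraction <- function(product_signal, total_signal) {
  if (any(total_signal <= 0)) abort("total signal must be positive")
  if (any(product_signal < 0)) abort("product signal must be non-negative")
  if (any(product_signal > total_signal)) {
    abort("product signal exceeds total signal")
  }
  frac <- product_signal / total_signal
  if (any(frac > 0.20)) {
    warn(paste("cleavage fraction exceeds 20%: outside the initial-velocity",
               "regime; velocities may be underestimated"))
  }
  frac
}

#' Convert a cleavage fraction to an initial velocity
#'
#' @param fraction Cleavage fraction from [cleavage_fraction()].
#' @param s0_um Initial substrate concentration, uM.
#' @param time_min Reaction time, minutes.
#' @return Velocity in uM per minute: `fraction * s0_um / time_min`.
#' @examples
#' cleavage_velocity(0.2, s0_um = 5, time_min = 10) # 0.1 uM/min
#' @export
cleavage_velocity <- function(fraction, s0_um, time_min) {
  if (any(s0_um <= 0) || any(time_min <= 0)) {
    abort("substrate concentration and time must be positive")
  }
  fraction * s0_um / time_min
}

# Lineweaver-Burk initial guess: E/v = (Km/kcat) (1/S) + 1/kcat, pooling all
# enzyme concentrations (E in uM).
lb_guess <- function(s_um, e_um, v) {
  fit <- lm(I(e_um / v) ~ I(1 / s_um))
  kcat <- 1 / coef(fit)[[1]]
  km <- coef(fit)[[2]] * kcat
  if (!is.finite(km) || !is.finite(kcat) || km <= 0 || kcat <= 0) {
    # fall back to crude moment guesses when the LB line is degenerate
    kcat <- max(v / e_um) * 2
    km <- median(s_um)
  }
  c(km = km, kcat = kcat)
}

#' Fit Michaelis--Menten parameters from initial velocities
#'
#' Nonlinear least squares of `v = kcat * E * S / (Km + S)` jointly over all
#' enzyme concentrations, fit independently within each replicate. Enzyme
#' concentrations are converted from nM to uM internally so that kcat is in
#' min^-1. Starting values come from a pooled Lineweaver--Burk linear fit.
#' Replicate estimates are aggregated as unweighted mean and sample SD.
#'
#' Gel-quantified velocities carry roughly constant relative (not absolute)
#' error, so the default objective is relative least squares: residuals are
#' weighted by `1/v^2`, which keeps the low-substrate points -- the ones
#' that determine Km -- from being swamped by the high-velocity points.
#' `weighting = "none"` gives the plain unweighted fit.
#'
#' @param data Tibble with columns `s_um` (substrate, uM), `e_nm` (enzyme,
#'   nM), `v_um_min` (velocity, uM/min) and optionally `replicate`.
#' @param weighting `"relative"` (default) weights residuals by the inverse
#'   squared observed velocity; `"none"` fits unweighted.
#' @param by_grid Also fit each enzyme concentration separately (diagnostic;
#'   a single grid constrains Km and kcat poorly).
#' @return An object of class `mm_fit` with elements `replicates` (per-
#'   replicate tibble of `km`, `kcat`), `km_mean`, `km_sd`, `kcat_mean`,
#'   `kcat_sd`, and optionally `per_grid`. Use [tidy()] / [glance()].
#' @examples
#' d <- simulate_mm_velocities(4.8, 10, noise_cv = 0, replicates = 1)
#' glance(fit_michaelis_menten(d))
#' @export
fit_michaelis_menten <- function(data, weighting = c("relative", "none"),
                                 by_grid = FALSE) {
  weighting <- match.arg(weighting)
  data <- as_tibble(data)
  stopifnot(all(c("s_um", "e_nm", "v_um_min") %in% names(data)))
  if (any(data$s_um <= 0) || any(data$e_nm <= 0)) {
    abort("substrate and enzyme concentrations must be positive")
  }
  if (any(data$v_um_min < 0)) abort("velocities must be non-negative")
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  if (n_distinct(data$s_um) < 4) {
    abort("need >= 4 distinct substrate concentrations to constrain Km and kcat")
  }
  if (weighting == "relative" && any(data$v_um_min == 0)) {
    warn("zero velocities present; falling back to unweighted least squares")
    weighting <- "none"
  }

  fit_one <- function(df) {
    e_um <- df$e_nm / 1000
    start <- lb_guess(df$s_um, e_um, df$v_um_min)
    if (min(df$s_um) > start[["km"]] || max(df$s_um) < start[["km"]]) {
      warn(sprintf(
        "substrate grid (%.3g-%.3g uM) may not span the Km (initial guess %.3g uM)",
        min(df$s_um), max(df$s_um), start[["km"]]))
    }
    w <- if (weighting == "relative") 1 / df$v_um_min^2 else rep(1, nrow(df))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v_um_min ~ kcat * (e_nm / 1000) * s_um / (km + s_um),
        data = df, start = as.list(start), weights = w,
        lower = c(km = 1e-9, kcat = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        abort(sprintf(
          "Michaelis-Menten fit failed to converge (start km=%.4g, kcat=%.4g): %s",
          start[["km"]], start[["kcat"]], conditionMessage(e)))
      })
    est <- coef(fit)
    # the objective actually minimized (weighted when weighting = "relative")
    tibble(km = est[["km"]], kcat = est[["kcat"]],
           rss = sum(w * (df$v_um_min - stats::fitted(fit))^2), n = nrow(df))
  }

  reps <- data |>
    group_by(.data$replicate) |>
    group_modify(function(df, key) fit_one(df)) |>
    ungroup()

  per_grid <- NULL
  if (by_grid) {
    per_grid <- data |>
      group_by(.data$replicate, .data$e_nm) |>
      group_modify(function(df, key) {
        df$e_nm <- key$e_nm # grouping column is dropped inside group_modify
        if (n_distinct(df$s_um) < 4) return(tibble(km = NA_real_,
                                                   kcat = NA_real_,
                                                   rss = NA_real_,
                                                   n = nrow(df)))
        fit_one(df)
      }) |>
      ungroup()
  }

  structure(
    list(replicates = reps,
         km_mean = mean(reps$km),
         km_sd = if (nrow(reps) > 1) sd(reps$km) else NA_real_,
         kcat_mean = mean(reps$kcat),
         kcat_sd = if (nrow(reps) > 1) sd(reps$kcat) else NA_real_,
         per_grid = per_grid, data = data),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%d replicate%s)\n",
              nrow(x$replicates), if (nrow(x$replicates) > 1) "s" else ""))
  cat(sprintf("  Km   = %.3g +/- %.2g uM\n", x$km_mean, x$km_sd))
  cat(sprintf("  kcat = %.3g +/- %.2g /min\n", x$kcat_mean, x$kcat_sd))
  invisible(x)
}

#' @rdname fit_michaelis_menten
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) x$replicates

#' @rdname fit_michaelis_menten
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(km_mean = x$km_mean, km_sd = x$km_sd,
         kcat_mean = x$kcat_mean, kcat_sd = x$kcat_sd,
         n_replicates = nrow(x$replicates))
}
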