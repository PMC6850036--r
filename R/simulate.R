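#' Time-course design for a rifampicin-chase microarray experiment
#'
#' Describes the sampling layout: sampling times (minutes after transcription
#' shutoff), number of replicate cultures per strain, the strain labels, and
#' the number of array probes targeting each transcript.
#'
#' @param times Numeric vector of sampling times in minutes after rifampicin
#'   addition; strictly increasing and positive. The default covers 0.5 to
#'   11 min with 8 points, the usual window for fast bacterial mRNA decay.
#' @param replicates Number of independent replicate cultures per strain.
#' @param strains Character vector of two strain labels; the first is treated
#'   as the reference (wild-type) strain downstream.
#' @param probes_per_transcript Number of probes targeting each transcript on
#'   every array (default 16).
#' @return A list of class `decay_design`.
#' @examples
#' decay_design(times = c(1, 2, 4, 8), replicates = 2)
#' @export
decay_design <- function(times = c(0.5, 1, 2, 3, 4, 6, 8, 11),
                         replicates = 3,
                         strains = c("wt", "mut"),
                         probes_per_transcript = 16) {
  if (length(times) < 2 || any(times <= 0)) {
    abort(sprintf("`times` must be positive; offending value(s): %s",
                  paste(times[times <= 0], collapse = ", ")))
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing")
  }
  if (replicates < 1) abort("`replicates` must be >= 1")
  if (probes_per_transcript < 1) abort("`probes_per_transcript` must be >= 1")
  if (anyDuplicated(strains)) abort("`strains` labels must be distinct")
  structure(
    list(times = as.numeric(times), replicates = as.integer(replicates),
         strains = as.character(strains),
         probes_per_transcript = as.integer(probes_per_transcript)),
    class = "decay_design"
  )
}

#' Multiplicative noise model for simulated probe intensities
#'
#' Intensity noise is log-normal (multiplicative), matching the log scale on
#' which decay rates are fit; additive noise would generate negative
#' intensities. Each probe additionally carries a fixed multiplicative
#' affinity offset, drawn once and shared across all arrays, mimicking the
#' probe-effect structure that median summarization must cancel.
#'
#' @param log_sd Standard deviation of the per-observation log-normal noise
#'   (natural-log scale; default 0.10).
#' @param probe_affinity_sd Standard deviation of the per-probe fixed affinity
#'   offset (natural-log scale; default 0.25).
#' @param seed Integer seed; identical seeds give byte-identical simulations.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(log_sd = 0.10, probe_affinity_sd = 0.25, seed = 1L) {
  if (log_sd < 0) abort("`log_sd` must be >= 0")
  if (probe_affinity_sd < 0) abort("`probe_affinity_sd` must be >= 0")
  structure(list(log_sd = log_sd, probe_affinity_sd = probe_affinity_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Draw a ground-truth table of per-transcript half-lives and abundances
#'
#' True half-lives are log-normal with a chosen per-strain median; the default
#' log-scale SD of 0.45 yields roughly the 1.5- to 4.5-fold spread seen in
#' genome-wide half-life distributions. Initial abundances are log-normal and
#' shared between strains for each transcript.
#'
#' @param n_transcripts Number of transcripts.
#' @param median_half_life Named numeric vector of per-strain median
#'   half-lives in minutes (names are strain labels), or a single unnamed
#'   value applied to one strain named `"wt"`.
#' @param log_sd_half_life SD of log half-life (default 0.45).
#' @param i0_meanlog,i0_sdlog Log-normal parameters of initial intensity.
#' @param seed Integer seed.
#' @return Tibble with columns `transcript_id`, `strain`, `half_life`, `i0`.
#' @examples
#' simulate_decay_truth(10, c(wt = 2.37, mut = 3.13), seed = 1)
#' @export
simulate_decay_truth <- function(n_transcripts,
                                 median_half_life = c(wt = 2.37, mut = 3.13),
                                 log_sd_half_life = 0.45,
                                 i0_meanlog = log(500), i0_sdlog = 1,
                                 seed = 1L) {
  if (n_transcripts < 1) abort("`n_transcripts` must be >= 1")
  if (any(median_half_life <= 0)) abort("median half-lives must be positive")
  if (is.null(names(median_half_life))) {
    if (length(median_half_life) != 1) {
      abort("`median_half_life` must be named by strain when length > 1")
    }
    names(median_half_life) <- "wt"
  }
  withr::local_seed(seed)
  ids <- sprintf("tx%05d", seq_len(n_transcripts))
  i0 <- rlnorm(n_transcripts, i0_meanlog, i0_sdlog)
  map_dfr(names(median_half_life), function(s) {
    tibble(
      transcript_id = ids,
      strain = s,
      half_life = rlnorm(n_transcripts, log(median_half_life[[s]]),
                         log_sd_half_life),
      i0 = i0
    )
  })
}

#' Simulate probe-level intensities for a rifampicin-chase array time course
#'
#' Each transcript decays exponentially from its true initial abundance:
#' the expected intensity of probe p on the array sampled at time t is
#' `i0 * a_p * exp(-t * ln(2) / half_life)`, with `a_p` the fixed probe
#' affinity. Log-normal noise is applied multiplicatively per observation.
#'
#' @param truth Truth tibble from [simulate_decay_truth()] (columns
#'   `transcript_id`, `strain`, `half_life`, `i0`); must cover every strain in
#'   the design.
#' @param design A [decay_design()].
#' @param noise A [noise_model()].
#' @return Probe-level tibble with columns `probe_id`, `transcript_id`,
#'   `array_id`, `strain`, `replicate`, `time_min`, `intensity`. Array
#'   metadata can be split off with [write_probe_matrix()].
#' @examples
#' truth <- simulate_decay_truth(5, c(wt = 2.4), seed = 1)
#' pm <- simulate_array_timecourse(truth,
#'   decay_design(times = c(1, 2, 4), replicates = 2, strains = "wt",
#'                probes_per_transcript = 4),
#'   noise_model(seed = 1))
#' @export
simulate_array_timecourse <- function(truth, design = decay_design(),
                                      noise = noise_model()) {
  stopifnot(inherits(design, "decay_design"), inherits(noise, "noise_model"))
  truth <- as_tibble(truth)
  missing_strains <- setdiff(design$strains, unique(truth$strain))
  if (length(missing_strains) > 0) {
    abort(sprintf("truth table lacks strain(s): %s",
                  paste(missing_strains, collapse = ", ")))
  }
  bad <- truth$half_life <= 0 | truth$i0 <= 0
  if (any(bad)) {
    abort(sprintf("non-positive half-life or abundance for transcript(s): %s",
                  paste(unique(truth$transcript_id[bad]), collapse = ", ")))
  }

  truth <- filter(truth, .data$strain %in% design$strains)
  txs <- sort(unique(truth$transcript_id))

  arrays <- expand_grid(strain = design$strains,
                        replicate = seq_len(design$replicates),
                        time_min = design$times) |>
    mutate(array_id = sprintf("%s_r%d_t%g", .data$strain, .data$replicate,
                              .data$time_min))

  withr::local_seed(noise$seed)
  probes <- expand_grid(transcript_id = txs,
                        probe = seq_len(design$probes_per_transcript)) |>
    mutate(probe_id = sprintf("%s_p%02d", .data$transcript_id, .data$probe),
           affinity = exp(rnorm(n(), 0, noise$probe_affinity_sd)))

  out <- expand_grid(arrays, probes["probe_id"]) |>
    left_join(probes, by = "probe_id") |>
    left_join(truth, by = c("transcript_id", "strain")) |>
    mutate(
      expected = .data$i0 * .data$affinity *
        exp(-.data$time_min * ln2 / .data$half_life),
      intensity = .data$expected * exp(rnorm(n(), 0, noise$log_sd))
    ) |>
    select("probe_id", "transcript_id", "array_id", "strain", "replicate",
           "time_min", "intensity")
  out
}

#' Simulate a bulk RNA decay series with a stable-RNA fraction
#'
#' Emulates a pulse-labelled total-RNA decay measurement (e.g. loss of
#' 3H-uridine counts after rifampicin): a stable fraction (rRNA/tRNA)
#' persists while the unstable (mRNA) fraction decays exponentially. The
#' expected signal is
#' `total0 * (stable_fraction + (1 - stable_fraction) * exp(-t ln2 / unstable_half_life))`
#' with multiplicative Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param stable_fraction Proportion of signal that never decays, in `[0, 1)`.
#' @param unstable_half_life Half-life of the decaying fraction, minutes.
#' @param times Sampling times in minutes; the default includes late points at
#'   30/40/50 min used for baseline estimation.
#' @param total0 Expected signal at time zero (counts).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise.
#' @param replicates Number of independent replicate series.
#' @param seed Integer seed.
#' @param label Series label.
#' @return Tibble with columns `time_min`, `value`, `replicate`, `label`.
#' @examples
#' simulate_bulk_decay(0.5, 10, times = c(1, 5, 30, 40, 50), noise_cv = 0)
#' @export
simulate_bulk_decay <- function(stable_fraction, unstable_half_life,
                                times = c(0.5, 1, 2, 4, 8, 16, 30, 40, 50),
                                total0 = 1000, noise_cv = 0.05,
                                replicates = 1L, seed = 1L,
                                label = "bulk") {
  if (stable_fraction < 0 || stable_fraction >= 1) {
    abort("`stable_fraction` must be in [0, 1)")
  }
  if (unstable_half_life <= 0) abort("`unstable_half_life` must be positive")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  n_late <- sum(times > 4 * unstable_half_life)
  if (stable_fraction > 0 && n_late < 3) {
    warn(paste("fewer than 3 sampling times beyond ~4 unstable half-lives;",
               "stable-baseline subtraction will be unreliable"))
  }
  withr::local_seed(seed)
  expand_grid(replicate = seq_len(replicates), time_min = as.numeric(times)) |>
    mutate(
      expected = total0 * (stable_fraction + (1 - stable_fraction) *
                             exp(-.data$time_min * ln2 / unstable_half_life)),
      value = .data$expected * (1 + rnorm(n(), 0, noise_cv)),
      label = label
    ) |>
    select("time_min", "value", "replicate", "label")
}

#' Default substrate/enzyme grids for the cleavage-kinetics assay
#'
#' Two initial-velocity grids: substrate 0.5--7.5 uM digested with 10 nM
#' enzyme, and substrate 6--15 uM with 20 nM enzyme. Each grid alone poorly
#' constrains both Michaelis--Menten parameters; they are fit jointly.
#'
#' @return Tibble with columns `s_um` (substrate, uM) and `e_nm` (enzyme, nM).
#' @export
mm_grids <- function() {
  bind_rows(
    tibble(s_um = c(0.5, 1, 2, 3, 4.5, 6, 7.5), e_nm = 10),
    tibble(s_um = c(6, 8, 10, 12, 15), e_nm = 20)
  )
}

#' Simulate Michaelis--Menten initial velocities
#'
#' Velocities follow `v = kcat * E * S / (Km + S)` (enzyme concentration
#' converted from nM to uM internally so velocities are in uM/min) with
#' multiplicative Gaussian noise.
#'
#' @param km Michaelis constant, uM.
#' @param kcat Turnover number, per minute.
#' @param grids Tibble of `(s_um, e_nm)` points; default [mm_grids()].
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param replicates Number of replicate datasets.
#' @param seed Integer seed.
#' @return Tibble with columns `s_um`, `e_nm`, `v_um_min`, `replicate`.
#' @examples
#' simulate_mm_velocities(km = 4.8, kcat = 10, noise_cv = 0)
#' @export
simulate_mm_velocities <- function(km, kcat, grids = mm_grids(),
                                   noise_cv = 0.05, replicates = 3L,
                                   seed = 1L) {
  if (km <= 0 || kcat <= 0) abort("`km` and `kcat` must be positive")
  grids <- as_tibble(grids)
  if (nrow(grids) == 0) abort("`grids` must contain at least one point")
  stopifnot(all(c("s_um", "e_nm") %in% names(grids)))
  withr::local_seed(seed)
  expand_grid(replicate = seq_len(replicates), grids) |>
    mutate(
      v_um_min = kcat * (.data$e_nm / 1000) * .data$s_um / (km + .data$s_um) *
        (1 + rnorm(n(), 0, noise_cv))
    ) |>
    select("s_um", "e_nm", "v_um_min", "replicate")
}
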