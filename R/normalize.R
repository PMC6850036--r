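#' Summarize probe intensities to transcript intensities
#'
#' The intensity of a transcript on an array is the median of its targeting
#' probe intensities on that array (typically 16 probes per transcript).
#' Because the median of scaled values scales, fixed per-probe affinity
#' offsets cancel out of log-intensity slopes.
#'
#' @param probes Probe-level tibble with columns `probe_id`, `transcript_id`,
#'   `array_id`, `strain`, `replicate`, `time_min`, `intensity`.
#' @return Transcript-level tibble with columns `transcript_id`, `array_id`,
#'   `strain`, `replicate`, `time_min`, `intensity`.
#' @examples
#' truth <- simulate_decay_truth(4, c(wt = 2.4), seed = 1)
#' pm <- simulate_array_timecourse(truth,
#'   decay_design(times = c(1, 2, 4), replicates = 1, strains = "wt",
#'                probes_per_transcript = 4))
#' summarize_transcripts(pm)
#' @export
summarize_transcripts <- function(probes) {
  probes <- validate_probe_matrix(probes)
  n_arrays <- n_distinct(probes$array_id)
  tm <- probes |>
    summarise(intensity = median(.data$intensity),
              .by = c("transcript_id", "array_id", "strain", "replicate",
                      "time_min"))
  per_tx <- count(tm, .data$transcript_id)
  incomplete <- per_tx$transcript_id[per_tx$n < n_arrays]
  if (length(incomplete) > 0) {
    abort(sprintf("transcript(s) missing from some arrays: %s",
                  paste(head(incomplete, 5), collapse = ", ")))
  }
  arrange(tm, .data$strain, .data$replicate, .data$time_min,
          .data$transcript_id)
}

validate_probe_matrix <- function(probes) {
  probes <- as_tibble(probes)
  need <- c("probe_id", "transcript_id", "array_id", "strain", "replicate",
            "time_min", "intensity")
  missing <- setdiff(need, names(probes))
  if (length(missing) > 0) {
    abort(sprintf("probe table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(probes$intensity <= 0)) {
    abort("probe intensities must be strictly positive; zeros are rejected rather than floored")
  }
  multi <- probes |>
    distinct(.data$probe_id, .data$transcript_id) |>
    count(.data$probe_id) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(sprintf("probe(s) map to more than one transcript: %s",
                  paste(head(multi$probe_id, 5), collapse = ", ")))
  }
  probes
}

#' Select a rank-invariant background probeset
#'
#' Identifies transcripts usable as a normalization anchor: those whose
#' summarized intensity lies in the background of the reference array (below
#' a quantile of that array's intensities) and whose normalized intensity
#' rank (rank / number of transcripts) is roughly invariant across all
#' arrays. "Roughly invariant" is a single-pass thresholded criterion: the
#' maximum pairwise difference in normalized rank across arrays -- i.e. the
#' range of the normalized ranks -- must be below `rank_tolerance`.
#'
#' @param x Probe-level or transcript-level tibble; probe tables are
#'   summarized first with [summarize_transcripts()].
#' @param rank_tolerance Maximum allowed range of normalized ranks (default
#'   0.05).
#' @param background_quantile Background cut: transcripts at or below this
#'   quantile of the reference array's intensities (default 0.50).
#' @param reference_array Array id used to define the background; default the
#'   first array in metadata order.
#' @return Character vector of invariant transcript ids.
#' @export
select_invariant_probesets <- function(x, rank_tolerance = 0.05,
                                       background_quantile = 0.50,
                                       reference_array = NULL) {
  if (rank_tolerance <= 0 || rank_tolerance >= 1) {
    abort("`rank_tolerance` must be in (0, 1)")
  }
  if (background_quantile <= 0 || background_quantile > 1) {
    abort("`background_quantile` must be in (0, 1]")
  }
  tm <- if ("probe_id" %in% names(x)) summarize_transcripts(x) else as_tibble(x)
  if (n_distinct(tm$array_id) < 2) abort("need at least 2 arrays")

  if (is.null(reference_array)) reference_array <- tm$array_id[[1]]
  ref <- filter(tm, .data$array_id == reference_array)
  if (nrow(ref) == 0) abort(sprintf("reference array '%s' not found", reference_array))
  bg_cut <- quantile(ref$intensity, background_quantile, names = FALSE)
  background <- ref$transcript_id[ref$intensity <= bg_cut]

  rank_range <- tm |>
    mutate(nrank = rank(.data$intensity) / n(), .by = "array_id") |>
    summarise(spread = max(.data$nrank) - min(.data$nrank),
              .by = "transcript_id")

  invariant <- rank_range |>
    filter(.data$spread < rank_tolerance,
           .data$transcript_id %in% background) |>
    pull("transcript_id")

  if (length(invariant) == 0) {
    abort(paste("no rank-invariant background transcripts found;",
                "increase `rank_tolerance` or `background_quantile`"))
  }
  sort(invariant)
}

#' Scale strains to a common level using an invariant probeset
#'
#' The median intensity of the invariant probeset within each strain is used
#' as the strain's scaling factor: every array of a strain is divided by
#' (strain median / reference-strain median over the invariant set), so that
#' after scaling the per-strain medians over the invariant set are equal (to
#' the reference strain's median). Scaling is a per-strain constant, so
#' within-array intensity ratios -- and hence log-intensity decay slopes --
#' are untouched, and the operation is idempotent.
#'
#' @param tm Transcript-level tibble from [summarize_transcripts()].
#' @param invariant Character vector of invariant transcript ids from
#'   [select_invariant_probesets()].
#' @param reference_strain Strain whose invariant median anchors the scale;
#'   default the first strain in order of appearance.
#' @return Transcript-level tibble with rescaled intensities.
#' @export
normalize_between_strains <- function(tm, invariant, reference_strain = NULL) {
  tm <- as_tibble(tm)
  if (length(invariant) == 0) abort("invariant transcript set is empty")
  inv <- filter(tm, .data$transcript_id %in% invariant)
  if (nrow(inv) == 0) abort("no invariant transcripts present in the table")
  if (is.null(reference_strain)) reference_strain <- tm$strain[[1]]
  ref_median <- median(inv$intensity[inv$strain == reference_strain])
  if (!is.finite(ref_median)) {
    abort(sprintf("reference strain '%s' has no invariant intensities",
                  reference_strain))
  }
  factors <- inv |>
    summarise(strain_median = median(.data$intensity), .by = "strain") |>
    mutate(scale = .data$strain_median / ref_median)
  tm |>
    left_join(factors[c("strain", "scale")], by = "strain") |>
    mutate(intensity = .data$intensity / .data$scale) |>
    select(-"scale")
}
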