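#' Pipeline configuration
#'
#' Bundles and validates the tunable thresholds of the analysis chain. The
#' defaults are the conventional operating points of the assay: slope-CV
#' reliability below 30%, differential-stability FDR 10%, enrichment cutoff
#' 5%, stable-RNA baseline from 30/40/50-min samples.
#'
#' @param seed Integer seed controlling every stochastic step.
#' @param cv_threshold Reliability cut on the slope CV, in (0, 1).
#' @param fdr_threshold FDR threshold for differential stability, in (0, 1).
#' @param rank_tolerance Rank-invariance tolerance, in (0, 1).
#' @param background_quantile Background definition quantile, in (0, 1].
#' @param enrichment_cutoff Enrichment p-value cutoff, in (0, 1).
#' @param late_times Increasing vector of late sampling times (minutes) used
#'   for stable-baseline estimation.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, cv_threshold = 0.30, fdr_threshold = 0.10,
                       rank_tolerance = 0.05, background_quantile = 0.50,
                       enrichment_cutoff = 0.05,
                       late_times = c(30, 40, 50)) {
  in01 <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x < 1
  for (nm in c("cv_threshold", "fdr_threshold", "rank_tolerance",
               "enrichment_cutoff")) {
    if (!in01(get(nm))) abort(sprintf("`%s` must lie in (0, 1)", nm))
  }
  if (!(background_quantile > 0 && background_quantile <= 1)) {
    abort("`background_quantile` must lie in (0, 1]")
  }
  if (is.unsorted(late_times, strictly = TRUE)) {
    abort("`late_times` must be strictly increasing")
  }
  structure(
    list(seed = as.integer(seed), cv_threshold = cv_threshold,
         fdr_threshold = fdr_threshold, rank_tolerance = rank_tolerance,
         background_quantile = background_quantile,
         enrichment_cutoff = enrichment_cutoff,
         late_times = as.numeric(late_times)),
    class = "run_config"
  )
}

#' Run the genome-wide decay pipeline end to end
#'
#' Chains summarization, rank-invariant normalization between strains,
#' pooled log-linear decay fitting with the reliability filter, half-life
#' summaries, the differential-stability interaction test with BH FDR, the
#' KS comparison of the two half-life distributions and, when an annotation
#' is supplied, hypergeometric term enrichment of the stabilized set against
#' the reliable-in-both background. Deterministic for a fixed seed: rerunning
#' on the same inputs reproduces every table byte for byte.
#'
#' @param probes Probe-level tibble (see [simulate_array_timecourse()] /
#'   [read_probe_matrix()]); if NULL, a time course is simulated from
#'   `truth` (or a default truth table drawn under `config$seed`).
#' @param config A [run_config()].
#' @param truth Optional truth tibble for simulation when `probes` is NULL.
#' @param annotation Optional term-to-gene tibble for enrichment.
#' @param n_transcripts Number of transcripts for the default simulation.
#' @return List with elements `estimates`, `half_life_summary`, `half_lives`,
#'   `diff`, `volcano`, `ks`, `enrichment` (NULL without annotation) and
#'   `summary` (one-row tibble: strain medians, KS statistic and p, selected
#'   count, seed, config hash, package version).
#' @export
run_pipeline <- function(probes = NULL, config = run_config(), truth = NULL,
                         annotation = NULL, n_transcripts = 200) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(probes)) {
    if (is.null(truth)) {
      truth <- simulate_decay_truth(n_transcripts, seed = config$seed)
    }
    probes <- simulate_array_timecourse(
      truth, decay_design(), noise_model(seed = config$seed))
  }
  # strain order (and hence the reference strain) follows the probe table,
  # not the alphabetical order summarization sorts into
  strains <- unique(probes$strain)
  tm <- summarize_transcripts(probes)
  invariant <- select_invariant_probesets(
    tm, rank_tolerance = config$rank_tolerance,
    background_quantile = config$background_quantile)
  tm <- normalize_between_strains(tm, invariant,
                                  reference_strain = strains[[1]])
  estimates <- fit_decay_all(tm, cv_threshold = config$cv_threshold)
  hl_summary <- half_life_table(estimates)
  hl <- filter_reliable_both(estimates)

  diff <- NULL; volcano <- NULL; ks <- NULL; enrichment <- NULL
  if (length(strains) == 2) {
    diff <- diff_stability(tm, estimates = estimates,
                           fdr = config$fdr_threshold,
                           reference_strain = strains[[1]])
    volcano <- volcano_table(diff, fdr = config$fdr_threshold)
    ks <- ks_compare(hl$half_life[hl$strain == strains[[1]]],
                     hl$half_life[hl$strain == strains[[2]]])
    if (!is.null(annotation)) {
      stabilized <- diff$transcript_id[diff$significant &
                                         diff$fold_change > 1]
      if (length(stabilized) > 0) {
        enrichment <- hypergeom_enrich(
          stabilized, unique(hl$transcript_id), annotation,
          p_cutoff = config$enrichment_cutoff)
      }
    }
  }

  summary <- tibble(
    n_reliable_both = n_distinct(hl$transcript_id),
    n_invariant = length(invariant),
    n_selected = if (is.null(diff)) NA_integer_ else sum(diff$significant),
    ks_statistic = if (is.null(ks)) NA_real_ else ks$statistic,
    ks_p = if (is.null(ks)) NA_real_ else ks$p_value,
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("rifadecay"))
  )
  for (s in strains) {
    summary[[paste0("median_half_life_", s)]] <-
      hl_summary$median[hl_summary$strain == s]
  }

  list(estimates = estimates, half_life_summary = hl_summary,
       half_lives = hl, diff = diff, volcano = volcano, ks = ks,
       enrichment = enrichment, invariant = invariant, summary = summary)
}

# ---- TSV readers/writers -------------------------------------------------

require_columns <- function(tab, need, what, path) {
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("%s '%s' is missing column(s): %s", what, path,
                  paste(missing, collapse = ", ")))
  }
  invisible(tab)
}

#' Write / read a probe matrix as a pair of TSV files
#'
#' The interchange layout is two UTF-8 tab-separated tables: a probe table
#' (`probe_id`, `transcript_id`, `array_id`, `intensity`) and an array
#' metadata table (`array_id`, `strain`, `replicate`, `time_min`).
#'
#' @param probes Probe-level tibble including array metadata columns.
#' @param probe_path,meta_path Output/input file paths.
#' @return `write_probe_matrix()` returns the paths invisibly;
#'   `read_probe_matrix()` returns the joined probe-level tibble.
#' @export
write_probe_matrix <- function(probes, probe_path, meta_path) {
  probes <- validate_probe_matrix(probes)
  readr::write_tsv(probes[c("probe_id", "transcript_id", "array_id",
                            "intensity")], probe_path)
  meta <- distinct(probes, .data$array_id, .data$strain, .data$replicate,
                   .data$time_min)
  readr::write_tsv(meta, meta_path)
  invisible(c(probe_path, meta_path))
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(probe_path, meta_path) {
  probes <- readr::read_tsv(probe_path, show_col_types = FALSE)
  require_columns(probes, c("probe_id", "transcript_id", "array_id",
                            "intensity"), "probe table", probe_path)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  require_columns(meta, c("array_id", "strain", "replicate", "time_min"),
                  "array metadata table", meta_path)
  orphans <- setdiff(unique(probes$array_id), meta$array_id)
  if (length(orphans) > 0) {
    abort(sprintf("array id(s) without metadata: %s",
                  paste(head(orphans, 5), collapse = ", ")))
  }
  validate_probe_matrix(left_join(probes, meta, by = "array_id")) |>
    relocate("probe_id", "transcript_id", "array_id", "strain", "replicate",
             "time_min", "intensity")
}

#' Read / write a measured decay series
#'
#' TSV with header; columns `time_min`, `value`, optional `reference_value`
#' and `replicate`.
#'
#' @param path File path.
#' @param series Series tibble.
#' @return A tibble / the path, invisibly.
#' @export
read_series <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(tab, c("time_min", "value"), "series table", path)
  as_tibble(tab)
}

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  readr::write_tsv(as_tibble(series), path)
  invisible(path)
}

#' Read / write an initial-velocity kinetics table
#'
#' TSV with header; columns `s_um`, `e_nm`, `v_um_min`, optional `replicate`.
#'
#' @param path File path.
#' @param data Kinetics tibble.
#' @return A tibble / the path, invisibly.
#' @export
read_kinetics <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(tab, c("s_um", "e_nm", "v_um_min"), "kinetics table", path)
  as_tibble(tab)
}

#' @rdname read_kinetics
#' @export
write_kinetics <- function(data, path) {
  readr::write_tsv(as_tibble(data), path)
  invisible(path)
}
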