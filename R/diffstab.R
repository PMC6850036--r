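#' Time-by-strain interaction test for one transcript
#'
#' Fits the global linear model `ln(I) = b0 + b1 t + b2 strain + b3 t:strain`
#' with the strain coded 0 for the reference (wild type) and 1 for the other
#' strain. The interaction coefficient b3 is the difference between the two
#' strains' log-linear decay slopes, slope(mut) - slope(wt); since decay
#' slopes are negative, b3 > 0 means a shallower mutant slope, i.e. slower
#' decay and stabilization (equivalently, the difference in rate constants
#' is k_wt - k_mut = b3). Its two-sided t-test p-value is the per-transcript
#' differential-stability p-value.
#'
#' @param tm Transcript-level tibble (see [summarize_transcripts()]).
#' @param transcript_id Transcript to test.
#' @param reference_strain Strain coded 0; default the first strain in the
#'   table's order of appearance.
#' @return One-row tibble: `transcript_id`, `beta_interaction`, `se`,
#'   `statistic`, `p_interaction`.
#' @export
interaction_test <- function(tm, transcript_id, reference_strain = NULL) {
  sub <- filter(as_tibble(tm), .data$transcript_id == !!transcript_id)
  if (nrow(sub) == 0) abort(sprintf("transcript '%s' not found", transcript_id))
  interaction_test_impl(sub, reference_strain)
}

interaction_test_impl <- function(sub, reference_strain = NULL) {
  strains <- unique(sub$strain)
  if (length(strains) != 2) {
    abort("interaction test requires exactly two strains")
  }
  if (is.null(reference_strain)) reference_strain <- strains[[1]]
  n_per <- count(sub, .data$strain)
  if (any(n_per$n < 3)) abort("need >= 3 points per strain")
  sub$strain01 <- as.numeric(sub$strain != reference_strain)
  fit <- lm(log(intensity) ~ time_min * strain01, data = sub)
  cf <- summary(fit)$coefficients
  if (!"time_min:strain01" %in% rownames(cf) || anyNA(coef(fit))) {
    abort("rank-deficient design: interaction coefficient is not estimable")
  }
  row <- cf["time_min:strain01", ]
  tibble(transcript_id = sub$transcript_id[[1]],
         beta_interaction = row[["Estimate"]],
         se = row[["Std. Error"]],
         statistic = row[["t value"]],
         p_interaction = row[["Pr(>|t|)"]])
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, clipped at 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Two-sample Kolmogorov--Smirnov comparison of half-life distributions
#'
#' Two-sided two-sample KS test. The exact small-sample p-value is computed
#' when both samples have at most 25 observations; otherwise the asymptotic
#' formula is used.
#'
#' @param a,b Numeric vectors (e.g. per-strain half-lives); non-empty.
#' @return One-row tibble: `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  exact <- length(a) <= 25 && length(b) <= 25
  kt <- suppressWarnings(ks.test(a, b, exact = exact))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(a), n_b = length(b))
}

#' Compare a transcript subgroup against the remainder, per strain
#'
#' For each strain, the half-life distribution of the member transcripts is
#' compared by a KS test against the complement of the comparison universe
#' (all other transcripts reliable in every strain) -- the control group is
#' the remainder, not the whole universe.
#'
#' @param members Character vector of transcript ids forming the test group.
#' @param estimates Decay-estimate tibble ([fit_decay_all()]); only
#'   transcripts reliable in every strain form the universe.
#' @return Tibble with one row per strain: `strain`, `statistic`, `p_value`,
#'   `n_members`, `n_complement`.
#' @export
subgroup_compare <- function(members, estimates) {
  hl <- filter_reliable_both(estimates)
  universe <- unique(hl$transcript_id)
  stray <- setdiff(members, universe)
  if (length(stray) > 0) {
    abort(sprintf("member transcript(s) not in the reliable universe: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  complement <- setdiff(universe, members)
  if (length(members) == 0 || length(complement) == 0) {
    abort("degenerate partition: both the subgroup and its complement must be non-empty")
  }
  hl |>
    group_by(.data$strain) |>
    group_modify(function(df, key) {
      ks_compare(df$half_life[df$transcript_id %in% members],
                 df$half_life[df$transcript_id %in% complement])
    }) |>
    ungroup() |>
    rename(n_members = "n_a", n_complement = "n_b")
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test with Welch--Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("both samples need at least 2 observations")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Differential-stability table for two strains
#'
#' For every transcript reliable in both strains, computes the per-strain
#' half-lives, the half-life fold change (test strain / reference strain, so
#' FC > 1 means stabilized), the time-by-strain interaction p-value
#' ([interaction_test()]), the BH-adjusted q-value, and a significance flag
#' at the FDR threshold.
#'
#' @param tm Transcript-level tibble covering both strains.
#' @param estimates Optional precomputed [fit_decay_all()] result for `tm`;
#'   computed if missing.
#' @param fdr FDR threshold on adjusted p-values (default 0.10).
#' @param reference_strain Strain treated as wild type (fold-change
#'   denominator, interaction code 0); default first in order of appearance.
#' @param cv_threshold Reliability cut when `estimates` is computed here.
#' @param p_mode `"adjusted"` (default) selects on BH-adjusted q-values;
#'   `"raw"` selects on unadjusted interaction p-values.
#' @return Tibble with one row per transcript: `transcript_id`,
#'   `half_life_wt`, `half_life_mut`, `fold_change`, `p_interaction`, `q_bh`,
#'   `significant`. "wt" is the reference strain, "mut" the other.
#' @export
diff_stability <- function(tm, estimates = NULL, fdr = 0.10,
                           reference_strain = NULL, cv_threshold = 0.30,
                           p_mode = c("adjusted", "raw")) {
  p_mode <- match.arg(p_mode)
  tm <- as_tibble(tm)
  strains <- unique(tm$strain)
  if (length(strains) != 2) abort("diff_stability requires exactly two strains")
  if (is.null(reference_strain)) reference_strain <- strains[[1]]
  if (!reference_strain %in% strains) {
    abort(sprintf("reference strain '%s' not present", reference_strain))
  }
  other_strain <- setdiff(strains, reference_strain)
  if (is.null(estimates)) {
    estimates <- fit_decay_all(tm, cv_threshold = cv_threshold)
  }
  hl <- filter_reliable_both(estimates)
  if (nrow(hl) == 0) abort("no transcript is reliable in both strains")
  wide <- hl |>
    select("transcript_id", "strain", "half_life") |>
    pivot_wider(names_from = "strain", values_from = "half_life")

  pvals <- tm |>
    filter(.data$transcript_id %in% wide$transcript_id) |>
    group_by(.data$transcript_id) |>
    group_modify(function(df, key) {
      res <- interaction_test_impl(
        mutate(df, transcript_id = key$transcript_id[[1]]),
        reference_strain = reference_strain)
      select(res, -"transcript_id")
    }) |>
    ungroup()

  out <- wide |>
    left_join(select(pvals, "transcript_id", "beta_interaction",
                     "p_interaction"),
              by = "transcript_id") |>
    mutate(
      half_life_wt = .data[[reference_strain]],
      half_life_mut = .data[[other_strain]],
      fold_change = .data$half_life_mut / .data$half_life_wt,
      q_bh = bh_adjust(.data$p_interaction),
      significant = if (p_mode == "adjusted") .data$q_bh < fdr
                    else .data$p_interaction < fdr
    ) |>
    select("transcript_id", "half_life_wt", "half_life_mut", "fold_change",
           "beta_interaction", "p_interaction", "q_bh", "significant")
  attr(out, "reference_strain") <- reference_strain
  attr(out, "test_strain") <- other_strain
  out
}

#' Volcano table of half-life fold changes versus adjusted p-values
#'
#' Emits per-transcript log2 fold change and adjusted p-value and flags the
#' selected set at the chosen threshold.
#'
#' @param records Differential-stability tibble from [diff_stability()].
#' @param fdr Selection threshold (default 0.10).
#' @param use `"adjusted"` (default) thresholds `q_bh`; `"raw"` thresholds
#'   the unadjusted interaction p-value.
#' @return Tibble: `transcript_id`, `fold_change`, `log2_fc`, `p_interaction`,
#'   `q_bh`, `selected`.
#' @export
volcano_table <- function(records, fdr = 0.10, use = c("adjusted", "raw")) {
  use <- match.arg(use)
  records |>
    mutate(log2_fc = log2(.data$fold_change),
           selected = if (use == "adjusted") .data$q_bh < fdr
                      else .data$p_interaction < fdr) |>
    select("transcript_id", "fold_change", "log2_fc", "p_interaction",
           "q_bh", "selected")
}
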