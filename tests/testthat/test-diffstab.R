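two_strain_tm <- function(slope_wt, slope_mut, times = c(1, 2, 4, 8),
                          reps = 2, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(strain = c("wt", "mut"), replicate = seq_len(reps),
                       time_min = times) |>
      dplyr::mutate(
        transcript_id = "tx",
        array_id = sprintf("%s_r%d_t%g", strain, replicate, time_min),
        slope = ifelse(strain == "wt", slope_wt, slope_mut),
        intensity = exp(5 + slope * time_min + rnorm(dplyr::n(), 0, noise))
      )
  })
}

test_that("interaction coefficient is the difference of per-strain slopes", {
  # noiseless: slopes -0.20 (wt) and -0.30 (mut) give beta3 = -0.10
  tm <- two_strain_tm(-0.20, -0.30)
  res <- suppressWarnings(interaction_test(tm, "tx", reference_strain = "wt"))
  expect_equal(res$beta_interaction, -0.10, tolerance = 1e-10)

  # identical strains: beta3 = 0
  tm_same <- two_strain_tm(-0.25, -0.25)
  expect_equal(suppressWarnings(interaction_test(tm_same, "tx"))$beta_interaction,
               0, tolerance = 1e-12)

  # on any balanced design, beta3 equals the difference of two separate
  # per-strain OLS slopes, to 1e-10
  withr::with_seed(17, {
    for (i in 1:10) {
      tm_n <- two_strain_tm(-0.2, -0.35, noise = 0.15, seed = sample(1e4, 1))
      res_n <- interaction_test(tm_n, "tx", reference_strain = "wt")
      s_wt <- coef(lm(log(intensity) ~ time_min,
                      data = dplyr::filter(tm_n, strain == "wt")))[[2]]
      s_mut <- coef(lm(log(intensity) ~ time_min,
                       data = dplyr::filter(tm_n, strain == "mut")))[[2]]
      expect_equal(res_n$beta_interaction, s_mut - s_wt, tolerance = 1e-10)
    }
  })

  # rank-deficient design (a strain sampled at one time) is an error
  degenerate <- dplyr::bind_rows(
    dplyr::filter(tm, strain == "wt"),
    dplyr::filter(tm, strain == "mut", time_min == 1))
  expect_error(interaction_test(degenerate, "tx"))
})

test_that("BH adjustment matches the textbook step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  withr::with_seed(42, {
    for (i in 1:1000) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
    # permutation invariance and monotonicity
    p <- runif(25)
    perm <- sample(25)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p))
  })
})

test_that("KS comparison matches the exhaustive ECDF oracle", {
  expect_equal(ks_compare(c(1, 2, 3), c(4, 5, 6))$statistic, 1.0)
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(ks_compare(numeric(0), 1), "non-empty")

  withr::with_seed(8, {
    for (i in 1:50) {
      a <- round(runif(sample(2:6, 1)) * 10, 1)
      b <- round(runif(sample(2:6, 1)) * 10, 1)
      expect_equal(ks_compare(a, b)$statistic, ks_D_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("Welch test is antisymmetric and agrees with a permutation oracle", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), "2 observations")

  withr::with_seed(12, {
    a <- rnorm(8, 1, 1); b <- rnorm(8, 0, 2)
  })
  fwd <- welch_t(a, b); rev <- welch_t(b, a)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)

  # two-sided permutation p-value of the Welch statistic (Monte Carlo)
  withr::with_seed(13, {
    pooled <- c(a, b)
    perm <- replicate(4000, {
      idx <- sample(16, 8)
      abs(welch_t(pooled[idx], pooled[-idx])$statistic)
    })
  })
  p_perm <- mean(perm >= abs(fwd$statistic))
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_perm - fwd$p_value), 0.03 + 3 * mc_se)
})

test_that("volcano table selection equals a brute-force filter", {
  hl_wt <- c(2.37, 2.0, 3.0, 1.5)
  hl_mut <- c(3.13, 2.1, 2.9, 4.5)
  records <- tibble::tibble(
    transcript_id = letters[1:4],
    half_life_wt = hl_wt, half_life_mut = hl_mut,
    fold_change = hl_mut / hl_wt,
    beta_interaction = -0.1,
    p_interaction = c(0.001, 0.5, 0.9, 0.0001),
    q_bh = bh_adjust(c(0.001, 0.5, 0.9, 0.0001)),
    significant = NA)
  # ratio of the two genome-wide median half-lives: 3.13 / 2.37 = 1.32
  expect_equal(round(records$fold_change[1], 2), 1.32)

  v <- volcano_table(records, fdr = 0.1)
  expect_equal(v$selected, v$q_bh < 0.1)
  expect_equal(v$log2_fc, log2(records$fold_change), tolerance = 1e-12)
  v0 <- volcano_table(records, fdr = 0)
  expect_equal(sum(v0$selected), 0)
  v_raw <- volcano_table(records, fdr = 0.1, use = "raw")
  expect_equal(v_raw$selected, records$p_interaction < 0.1)
})

test_that("subgroup comparison is valid under the null and powerful under shift", {
  ids <- sprintf("t%03d", 1:300)
  make_est <- function(hl_a, hl_b = hl_a) dplyr::bind_rows(
    estimates_table(ids, "wt", hl_a),
    estimates_table(ids, "mut", hl_b))

  # degenerate partitions are errors
  est <- make_est(rlnorm(300, log(2.4), 0.45))
  expect_error(subgroup_compare(ids, est), "degenerate")
  expect_error(subgroup_compare(c(ids[1], "zzz"), est), "zzz")

  # null calibration: members drawn from the same distribution; the
  # two-sample KS p is slightly conservative at these sizes, so validity
  # (no excess small p-values) is asserted rather than exact uniformity
  withr::with_seed(77, {
    ps <- replicate(200, {
      e <- make_est(rlnorm(300, log(2.4), 0.45))
      subgroup_compare(sample(ids, 100), e)$p_value[1]
    })
  })
  expect_lte(mean(ps < 0.05), 0.075)
  expect_gte(mean(ps), 0.45)

  # power: members twice as stable as the complement (n = 200 vs 100)
  withr::with_seed(78, {
    hits <- replicate(20, {
      hl <- rlnorm(300, log(2.4), 0.45)
      hl[1:200] <- hl[1:200] * 2
      e <- make_est(hl)
      all(subgroup_compare(ids[1:200], e)$p_value < 0.01)
    })
  })
  expect_true(all(hits))
})

test_that("differential stability controls type I error and detects 2x shifts", {
  # type-I calibration: identical truth for both strains; the fraction of
  # transcripts called at q < 0.1 stays at or below the nominal FDR
  fracs <- vapply(1:3, function(s) {
    truth_wt <- simulate_decay_truth(120, c(wt = 2.37), seed = 100 + s)
    truth <- dplyr::bind_rows(truth_wt,
                              dplyr::mutate(truth_wt, strain = "mut"))
    pm <- simulate_array_timecourse(truth, decay_design(),
                                    noise_model(seed = 200 + s))
    d <- diff_stability(summarize_transcripts(pm), reference_strain = "wt")
    mean(d$significant)
  }, 0)
  expect_lte(mean(fracs), 0.1)

  # power: 12% of transcripts truly stabilized twofold in the mutant
  truth_wt <- simulate_decay_truth(200, c(wt = 2.37), seed = 301)
  stabilized <- unique(truth_wt$transcript_id)[1:24]
  truth <- dplyr::bind_rows(
    truth_wt,
    dplyr::mutate(truth_wt, strain = "mut",
                  half_life = ifelse(transcript_id %in% stabilized,
                                     half_life * 2, half_life)))
  pm <- simulate_array_timecourse(truth, decay_design(),
                                  noise_model(seed = 302))
  d <- diff_stability(summarize_transcripts(pm), reference_strain = "wt")
  recall <- mean(stabilized %in% d$transcript_id[d$significant])
  expect_gte(recall, 0.70)

  # record invariants: positive fold changes, q >= p, BH monotone in p
  expect_true(all(d$fold_change > 0))
  expect_true(all(d$q_bh >= d$p_interaction - 1e-12))
  o <- order(d$p_interaction)
  expect_true(all(diff(d$q_bh[o]) >= -1e-12))
  # sign convention: stabilization (fold change > 1) means the mutant slope
  # is shallower, i.e. the slope-difference coefficient beta3 is positive
  strong <- dplyr::filter(d, significant, fold_change > 1)
  expect_true(all(strong$beta_interaction > 0))
})
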