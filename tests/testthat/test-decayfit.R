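test_that("exact log-linear data recovers rate and half-life identities", {
  t <- c(1, 2, 4, 8)
  tm <- tibble::tibble(transcript_id = "a", strain = "wt", time_min = t,
                       replicate = 1L,
                       intensity = 100 * exp(-0.2310 * t))
  est <- fit_decay_all(tm)
  expect_equal(est$k, 0.2310, tolerance = 1e-10)
  expect_equal(est$half_life, log(2) / 0.2310, tolerance = 1e-10)
  expect_equal(est$half_life, 3.0, tolerance = 1e-2)
  expect_lt(est$cv, 1e-8)
  expect_true(est$reliable)

  # ln2 identity: k = 0.6931 / min gives a 1-minute half-life, and
  # k * half_life = ln2 across a random batch
  tm2 <- dplyr::mutate(tm, intensity = 100 * exp(-log(2) * time_min))
  expect_equal(fit_decay_all(tm2)$half_life, 1.0, tolerance = 1e-12)
  truth <- simulate_decay_truth(10, c(wt = 2.4, mut = 3.1), seed = 6)
  est_b <- fit_decay_all(summarize_transcripts(simulate_array_timecourse(
    truth, decay_design(probes_per_transcript = 2), noise_model(seed = 6))))
  expect_equal(est_b$k * est_b$half_life, rep(log(2), nrow(est_b)),
               tolerance = 1e-12)
})

test_that("reliability uses a strict CV threshold", {
  withr::with_seed(10, {
    t <- rep(c(1, 2, 4, 8), 3)
    tm <- tibble::tibble(transcript_id = "a", strain = "wt", time_min = t,
                         replicate = rep(1:3, each = 4),
                         intensity = 100 * exp(-0.3 * t + rnorm(12, 0, 0.3)))
  })
  est <- fit_decay_all(tm)
  # at a threshold equal to the observed cv the flag is FALSE (strict <)
  expect_false(fit_decay_all(tm, cv_threshold = est$cv)$reliable)
  expect_true(fit_decay_all(tm, cv_threshold = est$cv + 1e-9)$reliable)
})

test_that("slope and SE match lm() and the closed-form sums on random inputs", {
  withr::with_seed(21, {
    for (i in 1:15) {
      n_rep <- sample(2:3, 1)
      t <- rep(sort(runif(5, 0.5, 11)), n_rep)
      rep_id <- rep(seq_len(n_rep), each = 5)
      y <- exp(2 - 0.3 * t + rnorm(length(t), 0, 0.2) +
                 0.3 * rep_id[seq_along(t)])
      tm <- tibble::tibble(transcript_id = "x", strain = "s", time_min = t,
                           replicate = rep_id, intensity = y)
      # common intercept vs lm and vs explicit sum formulas
      est <- fit_decay_all(tm)
      ref <- summary(lm(log(y) ~ t))$coefficients
      expect_equal(est$k, -ref["t", "Estimate"], tolerance = 1e-10)
      expect_equal(est$se_k, ref["t", "Std. Error"], tolerance = 1e-10)
      orc <- ols_oracle(t, log(y))
      expect_equal(est$k, -orc[["slope"]], tolerance = 1e-10)
      expect_equal(est$se_k, orc[["se"]], tolerance = 1e-10)
      # per-replicate intercept variant vs lm with replicate factor
      est_r <- fit_decay_all(tm, per_replicate_intercept = TRUE)
      ref_r <- summary(lm(log(y) ~ t + factor(rep_id)))$coefficients
      expect_equal(est_r$k, -ref_r["t", "Estimate"], tolerance = 1e-10)
      expect_equal(est_r$se_k, ref_r["t", "Std. Error"], tolerance = 1e-10)
    }
  })
})

test_that("rescaling time by c rescales k by 1/c and leaves the CV unchanged", {
  withr::with_seed(31, {
    t <- rep(c(0.5, 1, 2, 4, 8), 2)
    y <- exp(3 - 0.25 * t + rnorm(10, 0, 0.1))
  })
  tm <- tibble::tibble(transcript_id = "a", strain = "wt", time_min = t,
                       replicate = rep(1:2, each = 5), intensity = y)
  est1 <- fit_decay_all(tm)
  est2 <- fit_decay_all(dplyr::mutate(tm, time_min = time_min * 60))
  expect_equal(est2$k, est1$k / 60, tolerance = 1e-12)
  expect_equal(est2$cv, est1$cv, tolerance = 1e-12)
})

test_that("fit_exponential handles constants, scaling and bad points", {
  # signal halving every 2.5 min
  s <- tibble::tibble(time_min = c(0, 2.5, 5, 7.5, 10), value = 64 / 2^(0:4))
  expect_equal(glance(fit_exponential(s))$half_life, 2.5, tolerance = 1e-12)
  # overall scaling leaves k unchanged
  expect_equal(glance(fit_exponential(dplyr::mutate(s, value = value * 37)))$k,
               glance(fit_exponential(s))$k, tolerance = 1e-12)
  # constant series: k = 0, half-life undefined, not reliable
  const <- glance(fit_exponential(tibble::tibble(time_min = 1:5, value = 7)))
  expect_equal(const$k, 0)
  expect_true(is.na(const$half_life))
  expect_false(const$reliable)
  # non-positive values are dropped with a message; too few points error
  s_bad <- dplyr::bind_rows(s, tibble::tibble(time_min = 12, value = -1))
  expect_message(fit_exponential(s_bad), "non-positive")
  expect_error(fit_exponential(s[1:2, ]), "3")
  expect_error(fit_decay_all(tibble::tibble(
    transcript_id = "a", strain = "wt", time_min = 1:2,
    intensity = c(2, 1))), "a")
  # tidy/glance return the broom-style shapes
  fit <- fit_exponential(s)
  expect_named(tidy(fit), c("term", "estimate", "std.error"))
  expect_named(glance(fit), c("k", "se_k", "cv", "reliable", "half_life",
                              "n_points", "r.squared"))
})

test_that("half-life table restricts to transcripts reliable in all strains", {
  est <- dplyr::bind_rows(
    estimates_table(c("a", "b", "c"), "wt", c(2, 3, 4)),
    estimates_table(c("a", "b", "c"), "mut", c(3, 4, 5)))
  tab <- half_life_table(est)
  expect_equal(tab$median[tab$strain == "wt"], 3)
  expect_equal(tab$median[tab$strain == "mut"], 4)

  # a transcript reliable in only one strain is excluded from both lists
  est$reliable[est$transcript_id == "c" & est$strain == "mut"] <- FALSE
  kept <- filter_reliable_both(est)
  both <- intersect(
    est$transcript_id[est$reliable & est$strain == "wt"],
    est$transcript_id[est$reliable & est$strain == "mut"])
  expect_setequal(unique(kept$transcript_id), both)
  expect_false("c" %in% kept$transcript_id)
})

test_that("default-noise simulation recovers short half-lives reliably", {
  # parameter recovery: >= 95% of transcripts with true half-life <= 10 min
  # within 15% relative error and past the reliability filter
  truth <- simulate_decay_truth(150, c(wt = 2.37), seed = 14)
  pm <- simulate_array_timecourse(truth, decay_design(strains = "wt"),
                                  noise_model(seed = 15))
  est <- fit_decay_all(summarize_transcripts(pm))
  joined <- dplyr::inner_join(est, truth, by = c("transcript_id", "strain"),
                              suffix = c("", "_true"))
  short <- dplyr::filter(joined, half_life_true <= 10)
  ok <- short$reliable &
    abs(short$half_life - short$half_life_true) / short$half_life_true < 0.15
  expect_gte(mean(ok), 0.95)
})
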