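# In-code fixtures shared across test files. Everything is generated at test
# time; no data files.

# Noiseless transcript-level time course for given half-lives (named vector),
# one strain, optional replicates.
noiseless_tm <- function(half_lives, strain = "wt",
                         times = c(0.5, 1, 2, 4, 8), replicates = 1,
                         i0 = 100) {
  tidyr::expand_grid(
    transcript_id = names(half_lives),
    replicate = seq_len(replicates),
    time_min = times
  ) |>
    dplyr::mutate(
      strain = strain,
      array_id = sprintf("%s_r%d_t%g", strain, replicate, time_min),
      intensity = i0 * exp(-time_min * log(2) / half_lives[transcript_id])
    )
}

# Transcript-level table from an intensity matrix (transcripts x arrays);
# all arrays get dummy metadata in column order.
tm_from_matrix <- function(mat, strain = "wt") {
  tibble::tibble(
    transcript_id = rep(rownames(mat), times = ncol(mat)),
    array_id = rep(colnames(mat), each = nrow(mat)),
    strain = strain,
    replicate = rep(seq_len(ncol(mat)), each = nrow(mat)),
    time_min = rep(seq_len(ncol(mat)), each = nrow(mat)),
    intensity = as.vector(mat)
  )
}

# Minimal decay-estimate table with chosen half-lives / reliability flags.
estimates_table <- function(transcripts, strains, half_life, reliable = TRUE) {
  tidyr::expand_grid(transcript_id = transcripts, strain = strains) |>
    dplyr::mutate(
      half_life = half_life, k = log(2) / half_life,
      se_k = 0.01, cv = se_k / k, reliable = reliable, n_points = 24L
    )
}

# Exhaustive two-sample KS statistic: max ECDF difference over all points.
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Textbook BH step-up computed directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Upper-tail hypergeometric probability summed term by term in log space
# (independent of stats::phyper).
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  if (length(kk) == 0 || k > min(K, n)) return(0)
  terms <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  sum(exp(terms))
}

# OLS slope and slope SE from the explicit sum formulas.
ols_oracle <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  yhat <- mean(y) + slope * (t - mean(t))
  se <- sqrt(sum((y - yhat)^2) / (n - 2) / sxx)
  c(slope = slope, se = se)
}
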