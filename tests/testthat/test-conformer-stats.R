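test_that("percent north is exact on degenerate series and counts exclusions", {
  s0 <- simulate_pucker_series(two_state_spec(p_N = 0, n_frames = 500,
                                              n_residues = 3, seed = 4))
  expect_equal(percent_N(s0)$aggregate, 0)
  s1 <- simulate_pucker_series(two_state_spec(p_N = 1, n_frames = 500,
                                              n_residues = 2, seed = 4))
  expect_equal(percent_N(s1)$aggregate, 100)
  # 10-mer duplex, one terminal residue excluded per end per chain: 16 of 20
  df <- data.frame(frame = 1, chain = rep(c("A", "B"), each = 10),
                   resid = rep(1:10, 2), P = 150)
  pn <- percent_N(df, exclude_terminal = 1)
  expect_equal(pn$n_residues_aggregated, 16)
  expect_equal(nrow(pn$per_residue), 20)
  expect_error(percent_N(df, exclude_terminal = 5), "no residues")
})

test_that("percent north recovers the planted stationary probability", {
  p <- 0.15
  n <- 2e5
  spec <- two_state_spec(p_N = p, switch_time = 1 / (1 - p), n_frames = n,
                         sigma_P = 12, seed = 21)
  s <- simulate_pucker_series(spec)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(percent_N(s)$aggregate - 100 * p), 100 * 3 * se)
})

test_that("percent north estimator is unbiased over seeds on the two-state generator", {
  p <- 0.3
  n <- 4000
  errs <- vapply(1:100, function(s) {
    series <- simulate_pucker_series(
      two_state_spec(p_N = p, switch_time = 1 / (1 - p), n_frames = n,
                     seed = s))
    percent_N(series)$aggregate - 100 * p
  }, numeric(1))
  se_pct <- 100 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(errs)), 2 * se_pct / sqrt(100))
})

test_that("PMF follows the closed form and ignores overall frame count", {
  # uniform histogram: all PMF values zero
  u <- rep(seq(1.5, 358.5, by = 3), times = 10)
  expect_equal(max(abs(pmf(u)$pmf)), 0)
  # two bins with count ratio e: delta PMF = RT
  x <- c(rep(10, 1000), rep(100, round(1000 / exp(1))))
  prof <- pmf(x, bin = 20)
  v <- prof$pmf[prof$count > 0]
  expect_equal(abs(diff(v)), 1.987204e-3 * 298.15,
               tolerance = 1e-3)  # 0.5925 kcal/mol up to count rounding
  # doubling every count leaves the PMF unchanged
  p1 <- pmf(x, bin = 20)$pmf
  p2 <- pmf(c(x, x), bin = 20)$pmf
  expect_equal(p1, p2, tolerance = 1e-12)
  # empty bins are NA, not infinities
  expect_true(all(is.na(prof$pmf[prof$count == 0])))
  expect_false(any(is.infinite(prof$pmf), na.rm = TRUE))
})

test_that("PMF recovers a planted double-well free-energy difference within its CI", {
  # 100 seeds at a ~93-95% empirical coverage make >= 85 hits a sound bound
  # (false-failure probability < 1%); small seed counts are underpowered.
  means <- c(18, 150); sds <- c(12, 12); w <- c(0.2, 0.8)
  RT <- 1.987204e-3 * 298.15
  # analytic expectation from the planted mixture density, per 3-degree bin
  bin_n <- oracle_mixture_bin_prob(15, 18, means, sds, w)
  bin_s <- oracle_mixture_bin_prob(150, 153, means, sds, w)
  planted_dg <- -RT * log(bin_n / bin_s)
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    n <- 3e4
    comp <- runif(n) < w[1]
    x <- wrap360(ifelse(comp, rnorm(n, means[1], sds[1]),
                        rnorm(n, means[2], sds[2])))
    prof <- pmf(x)
    i_n <- which(prof$center == 16.5)
    i_s <- which(prof$center == 151.5)
    dg <- prof$pmf[i_n] - prof$pmf[i_s]
    half <- sqrt((prof$ci_high[i_n] - prof$ci_low[i_n])^2 +
                   (prof$ci_high[i_s] - prof$ci_low[i_s])^2) / 2
    if (abs(dg - planted_dg) <= half) hits <- hits + 1L
  }
  expect_gte(hits, 85L)
})

test_that("block-averaged count CIs cover the planted bin probability", {
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    set.seed(300 + s)
    x <- runif(3000, 0, 360)
    prof <- pmf(x, bin = 30)
    i <- 6
    planted <- 3000 / 12
    lo <- exp(-prof$ci_high[i] / attr(prof, "RT")) * max(prof$count)
    hi <- exp(-prof$ci_low[i] / attr(prof, "RT")) * max(prof$count)
    if (planted >= lo && planted <= hi) hits <- hits + 1L
  }
  expect_gte(hits, 85L)
})

test_that("epsilon/zeta and alpha/gamma substates classify by the rotamer windows", {
  expect_equal(classify_bi_bii(181, 267), "BI")
  expect_equal(classify_bi_bii(270, 180), "BII")
  expect_equal(classify_bi_bii(60, 60), "other")
  expect_equal(classify_bi_bii(NA, 200), NA_character_)
  expect_equal(classify_alpha_gamma(295, 52), "canonical")
  expect_equal(classify_alpha_gamma(60, 180), "g+/t")
  expect_equal(classify_alpha_gamma(180, 180), "other")
  expect_equal(rotamer_window(c(0, 119.9, 120, 239.9, 240, 359.9)),
               c("g+", "g+", "t", "t", "g-", "g-"))
})

test_that("substate populations sum to 100 and recover planted fractions", {
  spec <- two_state_spec(p_BII = 0.25, p_ag_flip = 0.05, n_frames = 4e4,
                         n_residues = 2, seed = 8)
  s <- simulate_pucker_series(spec)
  pops <- substate_populations(s)
  pr <- pops$per_residue
  expect_equal(pr$BI + pr$BII + pr$other_ez, rep(100, nrow(pr)),
               tolerance = 1e-9)
  expect_equal(pr$canonical + pr$gp_t + pr$other_ag, rep(100, nrow(pr)),
               tolerance = 1e-9)
  se_bii <- 100 * sqrt(0.25 * 0.75 / (4e4 * 2))
  expect_lt(abs(pops$aggregate[["BII"]] - 25), 4 * se_bii)
  se_ag <- 100 * sqrt(0.05 * 0.95 / (4e4 * 2))
  expect_lt(abs(pops$aggregate[["gp_t"]] - 5), 4 * se_ag)
  # all-canonical series
  s2 <- simulate_pucker_series(two_state_spec(p_BII = 0, p_ag_flip = 0,
                                              n_frames = 100, seed = 2))
  pops2 <- substate_populations(s2)
  expect_equal(unname(pops2$aggregate[c("BI", "BII", "other_ez")]),
               c(100, 0, 0))
  # exclusion bookkeeping on a 12-mer duplex, 1 pair per end
  df <- data.frame(frame = 1, chain = rep(c("A", "B"), each = 12),
                   resid = rep(1:12, 2), epsilon = 185, zeta = 265,
                   alpha = 295, gamma = 52)
  expect_equal(substate_populations(df, exclude_terminal = 1)$n_residues_aggregated,
               20)
})
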