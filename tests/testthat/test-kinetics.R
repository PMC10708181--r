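test_that("peptide OLS recovers exact log-linear decay", {
  fr <- noiseless_fractions(0.2)
  fit <- fit_peptide_ols(fr)
  expect_equal(fit$slope, -0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_samples, 7L)
  expect_true(fit$passes_filter)
})

test_that("constant fractions have undefined r-squared and fail the filter", {
  fr <- noiseless_fractions(0)
  fit <- fit_peptide_ols(fr)
  expect_equal(fit$slope, 0)
  expect_true(is.na(fit$r_squared))
  expect_false(fit$passes_filter)
})

test_that("peptide OLS agrees with R's linear-model fitter", {
  set.seed(42)
  for (i in 1:5) {
    times <- rep(c(0, 1, 2, 4, 8, 16, 32), 2)
    kd <- runif(1, 0.05, 0.4)
    frac <- exp(-kd * times + rnorm(length(times), 0, 0.1))
    fr <- data.table::data.table(
      peptide_id = "p", protein_id = "P", organ = "lung", oxygen = "21",
      sample_id = paste0("s", seq_along(times)), time_days = times,
      fraction14N = frac)
    fit <- fit_peptide_ols(fr)
    oracle <- ols_oracle(times, log(frac))
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("retention filter thresholds are strict on both axes", {
  fits <- data.table::data.table(
    peptide_id = paste0("p", 1:4), protein_id = "P", organ = "lung",
    oxygen = "21", slope = -0.1, intercept = 0,
    r_squared = c(0.65, 0.99, 0.66, 0.66),
    n_samples = c(6L, 5L, 6L, 100L))
  fits[, passes_filter := !is.na(r_squared) & r_squared > 0.65 &
         n_samples >= 6L]
  kept <- suppressMessages(filter_peptides(fits))
  ## r2 = 0.65 exactly -> dropped; n = 5 -> dropped; 0.66/6 -> kept
  expect_setequal(kept$peptide_id, c("p3", "p4"))

  ## the same boundaries through the fitting interface
  fr <- noiseless_fractions(0.2, times = c(0, 1, 2, 4, 8))
  fit5 <- fit_peptide_ols(fr)  # r2 = 1 but only 5 samples
  expect_equal(fit5$n_samples, 5L)
  expect_false(fit5$passes_filter)
})

test_that("single-peptide protein fit equals the peptide OLS slope", {
  fr <- noiseless_fractions(0.1)
  rec <- suppressMessages(fit_protein_kd(fr))
  pep <- fit_peptide_ols(fr)
  expect_equal(rec$kd, -pep$slope, tolerance = 1e-14)
  expect_equal(rec$kd, 0.1, tolerance = 1e-12)
  expect_equal(rec$half_life_days, log(2) / 0.1, tolerance = 1e-12)
  expect_equal(rec$fit_method, "ols_fallback")

  ## noisy single peptide: still exactly the OLS slope
  set.seed(3)
  times <- rep(c(0, 1, 2, 4, 8, 16, 32), 3)
  frac <- exp(-0.15 * times + rnorm(length(times), 0, 0.1))
  fr2 <- data.table::data.table(
    peptide_id = "p", protein_id = "P", organ = "lung", oxygen = "21",
    sample_id = paste0("s", seq_along(times)), time_days = times,
    fraction14N = frac)
  rec2 <- suppressMessages(fit_protein_kd(fr2))
  expect_equal(rec2$kd, -ols_oracle(times, log(frac))$slope,
               tolerance = 1e-12)
})

test_that("identical peptides collapse to the single-peptide answer", {
  fr <- noiseless_fractions(0.1, n_peptides = 3)
  rec <- suppressMessages(fit_protein_kd(fr))
  expect_equal(rec$n_peptides_used, 3L)
  expect_equal(rec$kd, 0.1, tolerance = 1e-10)
})

test_that("mixed-model rate matches a brute-force REML profile likelihood", {
  set.seed(7)
  times <- rep(c(0, 1, 2, 4, 8, 16, 32), each = 2)
  kd_true <- 0.12
  rows <- lapply(1:3, function(i) {
    off <- rnorm(1, 0, 0.3)
    data.table::data.table(
      peptide_id = paste0("p", i), protein_id = "P", organ = "lung",
      oxygen = "21", sample_id = paste0("s", seq_along(times), "_", i),
      time_days = times,
      fraction14N = exp(off - kd_true * times + rnorm(length(times), 0, 0.1)))
  })
  fr <- data.table::rbindlist(rows)
  rec <- suppressMessages(fit_protein_kd(fr))
  expect_equal(rec$fit_method, "lmm")
  kd_oracle <- reml_profile_kd(fr$time_days, log(fr$fraction14N),
                               fr$peptide_id)
  expect_equal(rec$kd, kd_oracle, tolerance = 1e-4)
})

test_that("rates with p-values under 0.20 are flagged as reported", {
  set.seed(11)
  times <- rep(c(0, 1, 2, 4, 8, 16, 32), 2)
  ## strong decay -> tiny p; near-flat noise -> large p
  strong <- data.table::data.table(
    peptide_id = "ps", protein_id = "PS", organ = "lung", oxygen = "21",
    sample_id = paste0("a", seq_along(times)), time_days = times,
    fraction14N = exp(-0.2 * times + rnorm(length(times), 0, 0.05)))
  rec <- suppressMessages(fit_protein_kd(strong))
  expect_true(rec$reported)
  expect_lt(rec$p_value, 0.20)
})

test_that("half-life is ln(2) over the rate, and rejects kd <= 0", {
  expect_equal(half_life(0.693147), 1, tolerance = 1e-5)
  expect_equal(half_life(log(2) / 3.9), 3.9, tolerance = 1e-12)
  expect_equal(half_life(log(2) / c(3.9, 7.3, 8.0)), c(3.9, 7.3, 8.0))
  ## involution through ln 2
  x <- c(0.3, 1, 5, 64)
  expect_equal(half_life(log(2) / x), x)
  expect_error(half_life(0), "non-positive")
  expect_error(half_life(c(0.1, -0.2)), "non-positive")
})

test_that("half-life summaries report group medians", {
  rec <- data.table::data.table(
    organ = "lung", oxygen = "21",
    half_life_days = c(1, 2, 3))
  sm <- summarize_half_lives(rec)
  expect_equal(sm$median_half_life, 2)
  expect_equal(sm$n, 3L)

  ## noiseless simulation at a single rate: median is exact
  cfg <- sim_config(n_proteins = 12, organs = "lung", oxygen_levels = "21",
                    median_half_life_days = c(lung = 3.9),
                    half_life_sigma = 0, frac_affected = 0, noise_cv = 0,
                    missing_rate = 0, loading_factor_sigma = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  f <- compute_sample_factors(sim$abundance, sim$design, sim$panel)
  fr <- compute_fractions(normalize_abundance(sim$abundance, f), sim$design)
  kd <- suppressMessages(fit_protein_kd(fr))
  kd <- kd[!protein_id %in% sim$panel]
  sm2 <- summarize_half_lives(kd)
  expect_equal(sm2$median_half_life, 3.9, tolerance = 1e-9)
})

test_that("noiseless pipeline recovery is exact and monotone", {
  cfg <- sim_config(n_proteins = 25, organs = "lung", oxygen_levels = "21",
                    noise_cv = 0, missing_rate = 0, loading_factor_sigma = 0,
                    frac_affected = 0, seed = 17)
  sim <- simulate_dataset(cfg)
  f <- compute_sample_factors(sim$abundance, sim$design, sim$panel)
  fr <- compute_fractions(normalize_abundance(sim$abundance, f), sim$design)
  kd <- suppressMessages(fit_protein_kd(fr))
  m <- merge(kd, sim$truth$proteins, by = c("protein_id", "organ", "oxygen"))
  m <- m[is_longlived == FALSE]
  expect_equal(nrow(m), 25)
  expect_true(all(abs(m$kd - m$true_kd) / m$true_kd < 1e-8))
  ## estimated rates strictly increase with true rates
  data.table::setorder(m, true_kd)
  expect_true(all(diff(m$kd) > 0))
})
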