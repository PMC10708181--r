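test_that("tables round-trip through files with validation", {
  toy <- toy_panel_tables()
  ad <- tempfile(fileext = ".tsv")
  sp <- tempfile(fileext = ".tsv")
  data.table::fwrite(toy$abundance, ad, sep = "\t")
  data.table::fwrite(toy$samples, sp, sep = "\t")
  tabs <- read_tables(ad, sp)
  expect_equal(nrow(tabs$abundance), 9)
  expect_equal(nrow(tabs$samples), 3)

  ## non-positive abundance rows are dropped with a logged count
  bad <- data.table::copy(toy$abundance)
  bad$abundance[1] <- 0
  data.table::fwrite(bad, ad, sep = "\t")
  expect_message(out <- read_abundance_table(ad), "dropped 1 of 9")
  expect_equal(nrow(out), 8)

  ## unknown sample id is a referential error
  bad2 <- data.table::copy(toy$abundance)
  bad2$sample_id[5] <- "sX"
  data.table::fwrite(bad2, ad, sep = "\t")
  expect_error(read_tables(ad, sp), "sX")

  ## missing column named in the error
  data.table::fwrite(toy$abundance[, !"protein_id"], ad, sep = "\t")
  expect_error(read_abundance_table(ad), "protein_id")
})

test_that("panel factors match hand-computed geometric means", {
  toy <- toy_panel_tables()
  factors <- compute_sample_factors(toy$abundance, toy$samples, toy$panel)
  ## per-peptide references across samples: llA -> (100*200*400)^(1/3),
  ## llB -> (10*10*40)^(1/3); per-sample factor = geometric mean of the
  ## two ratios, then rescaled to overall geometric mean 1
  refA <- (100 * 200 * 400)^(1 / 3)
  refB <- (10 * 10 * 40)^(1 / 3)
  raw <- c(sqrt((100 / refA) * (10 / refB)),
           sqrt((200 / refA) * (10 / refB)),
           sqrt((400 / refA) * (40 / refB)))
  expected <- raw / prod(raw)^(1 / 3)
  expect_equal(factors[order(sample_id)]$factor, expected, tolerance = 1e-12)
  expect_equal(exp(mean(log(factors$factor))), 1, tolerance = 1e-12)
})

test_that("identical panel abundances give unit factors; scaling a sample scales its factor", {
  samples <- data.table::data.table(sample_id = c("a", "b", "c"),
                                    organ = "lung", oxygen = "21",
                                    time_days = c(0, 1, 2),
                                    replicate = "r1")
  abund <- data.table::CJ(peptide_id = c("p1", "p2"),
                          sample_id = c("a", "b", "c"))
  abund[, protein_id := "LL1"]
  abund[, abundance := 100]
  f <- compute_sample_factors(abund, samples, "LL1")
  expect_equal(f$factor, rep(1, 3))

  ## one sample 10x brighter: its factor is 10x the others' after
  ## rescaling, so their ratio is exactly 10
  abund2 <- data.table::copy(abund)
  abund2[sample_id == "b", abundance := 1000]
  f2 <- compute_sample_factors(abund2, samples, "LL1")
  expect_equal(f2[sample_id == "b", factor] / f2[sample_id == "a", factor],
               10, tolerance = 1e-12)
  expect_equal(exp(mean(log(f2$factor))), 1, tolerance = 1e-12)

  ## a sample with no panel peptide is an error naming the sample
  abund3 <- abund[!(sample_id == "c")]
  expect_error(compute_sample_factors(abund3, samples, "LL1"), "c")
})

test_that("normalization divides by sample factors", {
  toy <- toy_panel_tables()
  f1 <- data.table::data.table(sample_id = c("s1", "s2", "s3"), factor = 1)
  expect_equal(normalize_abundance(toy$abundance, f1)$abundance,
               toy$abundance$abundance)
  f2 <- data.table::data.table(sample_id = c("s1", "s2", "s3"),
                               factor = c(0.5, 1, 2))
  norm <- normalize_abundance(toy$abundance, f2)
  merged <- merge(norm, toy$abundance, by = c("peptide_id", "sample_id"))
  fac <- c(s1 = 0.5, s2 = 1, s3 = 2)[merged$sample_id]
  expect_equal(merged$abundance.x, merged$abundance.y / unname(fac))
})

test_that("fractions are abundance over day-0 baseline", {
  samples <- data.table::data.table(
    sample_id = c("d0a", "d0b", "d4"), organ = "lung", oxygen = "21",
    time_days = c(0, 0, 4), replicate = c("r1", "r2", "r1"))
  abund <- data.table::data.table(
    peptide_id = "p1", protein_id = "P1",
    sample_id = c("d0a", "d0b", "d4"),
    abundance = c(90, 110, 100 * exp(-0.8)))
  fr <- compute_fractions(abund, samples)
  ## baseline = mean(90, 110) = 100; noiseless e^(-0.2 t) at t = 4
  expect_equal(fr[sample_id == "d0a", fraction14N], 0.9)
  expect_equal(fr[sample_id == "d4", fraction14N], exp(-0.8))
  ## day-0 fractions average exactly 1 per peptide
  expect_equal(fr[time_days == 0, mean(fraction14N)], 1)
})

test_that("baseline scope and missing-baseline handling behave per mode", {
  ## two conditions with different pre-labeling abundance; condition_t0
  ## must not mix them, explicit_t0 pools them
  samples <- data.table::data.table(
    sample_id = c("hx0", "hx4", "nx0", "nx4"), organ = "lung",
    oxygen = c("8", "8", "21", "21"), time_days = c(0, 4, 0, 4),
    replicate = "r1")
  abund <- data.table::data.table(
    peptide_id = "p1", protein_id = "P1",
    sample_id = c("hx0", "hx4", "nx0", "nx4"),
    abundance = c(200, 200 * exp(-0.4), 100, 100 * exp(-0.8)))
  fr <- compute_fractions(abund, samples, baseline_mode = "condition_t0")
  expect_equal(fr[sample_id == "hx4", fraction14N], exp(-0.4))
  expect_equal(fr[sample_id == "nx4", fraction14N], exp(-0.8))
  fr2 <- compute_fractions(abund, samples, baseline_mode = "explicit_t0")
  expect_equal(fr2[sample_id == "hx4", fraction14N],
               200 * exp(-0.4) / 150)

  ## no day-0 samples: explicit modes refuse, fitted_intercept recovers
  ## the baseline from the decay line itself
  samples2 <- data.table::data.table(
    sample_id = c("d1", "d2", "d4"), organ = "lung", oxygen = "21",
    time_days = c(1, 2, 4), replicate = "r1")
  abund2 <- data.table::data.table(
    peptide_id = "p1", protein_id = "P1",
    sample_id = c("d1", "d2", "d4"),
    abundance = 100 * exp(-0.2 * c(1, 2, 4)))
  expect_error(compute_fractions(abund2, samples2), "fitted_intercept")
  fr3 <- compute_fractions(abund2, samples2,
                           baseline_mode = "fitted_intercept")
  expect_equal(fr3$fraction14N, exp(-0.2 * c(1, 2, 4)), tolerance = 1e-10)

  ## a peptide absent from all day-0 samples is dropped, and accounted for
  abund3 <- rbind(abund, data.table::data.table(
    peptide_id = "p2", protein_id = "P1", sample_id = c("hx4", "nx4"),
    abundance = c(5, 5)))
  expect_message(fr4 <- compute_fractions(abund3, samples), "dropped 2 of 6")
  expect_false("p2" %in% fr4$peptide_id)
})

test_that("per-sample rescaling leaves fractions invariant", {
  cfg <- sim_config(n_proteins = 10, organs = "lung", seed = 31,
                    missing_rate = 0)
  sim <- simulate_dataset(cfg)
  run <- function(abund) {
    f <- compute_sample_factors(abund, sim$design, sim$panel)
    compute_fractions(normalize_abundance(abund, f), sim$design)
  }
  fr1 <- run(sim$abundance)
  set.seed(77)
  scale <- data.table::data.table(
    sample_id = sim$design$sample_id,
    c = exp(runif(nrow(sim$design), -1.5, 1.5)))
  scaled <- merge(sim$abundance, scale, by = "sample_id", sort = FALSE)
  scaled[, abundance := abundance * c]
  fr2 <- run(scaled[, .(peptide_id, protein_id, sample_id, abundance)])
  data.table::setkey(fr1, peptide_id, sample_id)
  data.table::setkey(fr2, peptide_id, sample_id)
  expect_equal(fr2$fraction14N, fr1$fraction14N, tolerance = 1e-12)
})
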