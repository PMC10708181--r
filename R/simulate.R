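#' Configure a pulsed-labeling simulation
#'
#' Builds and validates the parameter set for the synthetic pulsed-SILAM
#' generator. The defaults emulate the whole-animal labeling design the
#' estimator is built for: three organs, three inspired-oxygen tensions
#' (8% hypoxia, 21% normoxia, 60% hyperoxia), harvests at 1, 2, 4, 8, 16
#' and 32 days after the diet switch plus explicit day-0 baseline samples,
#' and per-organ median half-lives of 3.9 (lung), 7.3 (heart) and 8.0
#' (brain) days.
#'
#' @param organs character vector of organ labels.
#' @param oxygen_levels character vector of oxygen-tension labels (percent
#'   FiO2). Must contain `normoxia`.
#' @param normoxia the reference oxygen label; proteins are never
#'   oxygen-shifted in this condition.
#' @param timepoints_days non-negative labeling times in days. A day-0
#'   baseline is always added if absent: the fraction of unlabeled protein
#'   is defined relative to abundance at the start of the pulse.
#' @param replicates_per_point animals per organ x oxygen x timepoint.
#' @param n_proteins number of ordinary (non-panel) proteins.
#' @param peptides_per_protein integer range `c(min, max)`; the number of
#'   detectable peptides per protein is drawn uniformly from it. Typical
#'   DIA runs quantify a handful of peptides per protein; the default 2-8
#'   brackets that.
#' @param median_half_life_days median half-life in days, either a single
#'   value or a named vector with one entry per organ.
#' @param half_life_sigma log-scale standard deviation of the lognormal
#'   half-life distribution around the per-organ median.
#' @param frac_affected fraction of proteins whose degradation rate is
#'   shifted away from its normoxic value in non-normoxic conditions.
#' @param effect_fc_range fold-change interval `c(low, high)` with
#'   `low >= 1`; an affected protein's rate is multiplied or divided
#'   (direction random) by a factor drawn uniformly from this interval.
#' @param n_longlived size of the long-lived normalization panel appended
#'   to the proteome (the real analysis uses a 10-protein panel).
#' @param longlived_min_half_life_days half-life floor for panel proteins
#'   (default 60 days, i.e. stable over the 32-day study window).
#' @param longlived_decay if `FALSE` (default), panel peptides are
#'   simulated with a flat light-channel time course: the fixed-abundance
#'   assumption the normalization relies on holds exactly, so recovery
#'   tests are interpretable. If `TRUE`, panel peptides decay at their
#'   drawn rates, which biases every recovered rate down by the panel's
#'   mean rate — the bias the assumption hides on real data.
#' @param peptide_intercept_sigma log-scale SD of per-peptide baseline
#'   offsets (ionization-efficiency differences between peptides).
#' @param peptide_slope_sigma SD of optional per-peptide slope deviations
#'   (per day); 0 disables random slopes.
#' @param noise_cv multiplicative measurement noise, expressed as a
#'   coefficient of variation. Noise is lognormal so intensities stay
#'   positive.
#' @param missing_rate probability that a post-baseline measurement is
#'   dropped.
#' @param intensity_dependent_missing if `TRUE`, drop probability decreases
#'   with intensity rank (mean drop rate still `missing_rate`), mimicking
#'   intensity censoring; default is missing completely at random.
#' @param loading_factor_sigma log-scale SD of per-sample loading factors.
#' @param seed integer seed; mandatory so every run is reproducible.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(organs = c("lung", "heart", "brain"),
                       oxygen_levels = c("8", "21", "60"),
                       normoxia = "21",
                       timepoints_days = c(0, 1, 2, 4, 8, 16, 32),
                       replicates_per_point = 4L,
                       n_proteins = 100L,
                       peptides_per_protein = c(2L, 8L),
                       median_half_life_days = c(lung = 3.9, heart = 7.3,
                                                 brain = 8.0),
                       half_life_sigma = 0.25,
                       frac_affected = 0.1,
                       effect_fc_range = c(1.5, 3),
                       n_longlived = 10L,
                       longlived_min_half_life_days = 60,
                       longlived_decay = FALSE,
                       peptide_intercept_sigma = 0.5,
                       peptide_slope_sigma = 0,
                       noise_cv = 0.1,
                       missing_rate = 0.05,
                       intensity_dependent_missing = FALSE,
                       loading_factor_sigma = 0.1,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  organs <- as.character(organs)
  oxygen_levels <- as.character(oxygen_levels)
  normoxia <- as.character(normoxia)
  if (length(organs) == 0L) stop("at least one organ is required")
  if (length(oxygen_levels) == 0L) stop("at least one oxygen level is required")
  if (!normoxia %in% oxygen_levels) {
    stop(sprintf("normoxia level '%s' must be one of the oxygen levels",
                 normoxia))
  }
  timepoints_days <- sort(unique(as.numeric(timepoints_days)))
  if (length(timepoints_days) == 0L || any(timepoints_days < 0)) {
    stop("timepoints_days must be non-negative")
  }
  if (!0 %in% timepoints_days) timepoints_days <- c(0, timepoints_days)
  replicates_per_point <- as.integer(replicates_per_point)
  if (is.na(replicates_per_point) || replicates_per_point < 1L) {
    stop("replicates_per_point must be a positive integer")
  }
  n_proteins <- as.integer(n_proteins)
  if (n_proteins < 1L) stop("n_proteins must be positive")
  peptides_per_protein <- as.integer(peptides_per_protein)
  if (length(peptides_per_protein) != 2L ||
      any(peptides_per_protein < 1L) ||
      peptides_per_protein[1] > peptides_per_protein[2]) {
    stop("peptides_per_protein must be an increasing positive pair c(min, max)")
  }
  if (length(median_half_life_days) == 1L) {
    median_half_life_days <- setNames(rep(median_half_life_days,
                                          length(organs)), organs)
  }
  if (!all(organs %in% names(median_half_life_days))) {
    stop("median_half_life_days must be named with one entry per organ")
  }
  median_half_life_days <- median_half_life_days[organs]
  if (any(median_half_life_days <= 0)) stop("median half-lives must be positive")
  if (half_life_sigma < 0) stop("half_life_sigma must be non-negative")
  if (frac_affected < 0 || frac_affected > 1) {
    stop("frac_affected must be in [0, 1]")
  }
  if (length(effect_fc_range) != 2L || effect_fc_range[1] < 1 ||
      effect_fc_range[2] < effect_fc_range[1]) {
    stop("effect_fc_range must be c(low, high) with low >= 1")
  }
  n_longlived <- as.integer(n_longlived)
  if (n_longlived < 0L) stop("n_longlived must be >= 0")
  if (longlived_min_half_life_days <= 0) {
    stop("longlived_min_half_life_days must be positive")
  }
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (loading_factor_sigma < 0) stop("loading_factor_sigma must be non-negative")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")

  cfg <- list(
    organs = organs, oxygen_levels = oxygen_levels, normoxia = normoxia,
    timepoints_days = timepoints_days,
    replicates_per_point = replicates_per_point,
    n_proteins = n_proteins, peptides_per_protein = peptides_per_protein,
    median_half_life_days = median_half_life_days,
    half_life_sigma = half_life_sigma, frac_affected = frac_affected,
    effect_fc_range = effect_fc_range, n_longlived = n_longlived,
    longlived_min_half_life_days = longlived_min_half_life_days,
    longlived_decay = isTRUE(longlived_decay),
    peptide_intercept_sigma = peptide_intercept_sigma,
    peptide_slope_sigma = peptide_slope_sigma,
    noise_cv = noise_cv, missing_rate = missing_rate,
    intensity_dependent_missing = isTRUE(intensity_dependent_missing),
    loading_factor_sigma = loading_factor_sigma, seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Lay out the sampling design
#'
#' One sample per organ x oxygen x timepoint x replicate, including the
#' day-0 baseline animals.
#'
#' @param config a [sim_config()] object.
#' @return a `data.table` with columns `sample_id`, `organ`, `oxygen`,
#'   `time_days`, `replicate`.
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- data.table::CJ(organ = config$organs,
                           oxygen = config$oxygen_levels,
                           time_days = config$timepoints_days,
                           replicate = paste0("r", seq_len(config$replicates_per_point)),
                           sorted = FALSE)
  design[, sample_id := sprintf("%s_o%s_d%g_%s", organ, oxygen, time_days,
                                replicate)]
  data.table::setcolorder(design, c("sample_id", "organ", "oxygen",
                                    "time_days", "replicate"))
  design[]
}

#' Draw ground-truth degradation rates
#'
#' Per-organ degradation rates are lognormal around ln(2)/median half-life.
#' A configured fraction of proteins is "oxygen-affected": in each
#' non-normoxic condition their rate is multiplied or divided (coin flip)
#' by a fold change drawn uniformly from `effect_fc_range`. A long-lived
#' panel (half-life at or above the configured floor, identical across
#' conditions, never oxygen-affected) is appended; these are the
#' normalization standards.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `silam_truth`: a list with
#'   `proteins` (protein_id, organ, oxygen, condition, true_kd,
#'   true_half_life, is_longlived, affected, effect_fc) and
#'   `peptides` (peptide_id, protein_id, log_baseline, slope_dev).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$effect_fc_range[1] < 1) {
    stop("effect_fc_range low bound must be >= 1")
  }
  set.seed(config$seed)

  prot_ids <- sprintf("P%05d", seq_len(config$n_proteins))
  ll_ids <- if (config$n_longlived > 0L) {
    sprintf("LLP%02d", seq_len(config$n_longlived))
  } else character(0)

  rows <- list()
  for (org in config$organs) {
    med_hl <- config$median_half_life_days[[org]]
    base_hl <- med_hl * exp(rnorm(config$n_proteins, 0, config$half_life_sigma))
    affected <- runif(config$n_proteins) < config$frac_affected
    for (oxy in config$oxygen_levels) {
      kd <- log(2) / base_hl
      eff <- rep(NA_real_, config$n_proteins)
      if (oxy != config$normoxia && any(affected)) {
        n_aff <- sum(affected)
        fc <- runif(n_aff, config$effect_fc_range[1], config$effect_fc_range[2])
        dir <- sample(c(-1, 1), n_aff, replace = TRUE)
        kd[affected] <- kd[affected] * fc^dir
        eff[affected] <- fc^dir
      }
      rows[[length(rows) + 1L]] <- data.table::data.table(
        protein_id = prot_ids, organ = org, oxygen = oxy,
        true_kd = kd, is_longlived = FALSE,
        affected = affected & oxy != config$normoxia, effect_fc = eff)
    }
  }
  ## long-lived panel: one rate per protein, identical across all conditions
  if (config$n_longlived > 0L) {
    ll_hl <- config$longlived_min_half_life_days *
      exp(abs(rnorm(config$n_longlived, 0, 0.25)))
    ll_kd <- log(2) / ll_hl
    for (org in config$organs) {
      for (oxy in config$oxygen_levels) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          protein_id = ll_ids, organ = org, oxygen = oxy,
          true_kd = ll_kd, is_longlived = TRUE,
          affected = FALSE, effect_fc = NA_real_)
      }
    }
  }
  proteins <- data.table::rbindlist(rows)
  proteins[, condition := paste(organ, oxygen, sep = ":")]
  proteins[, true_half_life := log(2) / true_kd]

  ## peptide-level structure shared across conditions
  all_ids <- c(prot_ids, ll_ids)
  n_pep <- sample(seq(config$peptides_per_protein[1],
                      config$peptides_per_protein[2]),
                  length(all_ids), replace = TRUE)
  prot_log_base <- rnorm(length(all_ids), log(1e6), 1)
  peptides <- data.table::data.table(
    protein_id = rep(all_ids, n_pep),
    pep_index = unlist(lapply(n_pep, seq_len))
  )
  peptides[, peptide_id := sprintf("%s_pep%02d", protein_id, pep_index)]
  peptides[, pep_index := NULL]
  peptides[, log_baseline := rep(prot_log_base, n_pep) +
             rnorm(.N, 0, config$peptide_intercept_sigma)]
  peptides[, slope_dev := if (config$peptide_slope_sigma > 0) {
    rnorm(.N, 0, config$peptide_slope_sigma)
  } else 0]
  data.table::setcolorder(peptides, c("peptide_id", "protein_id",
                                      "log_baseline", "slope_dev"))

  out <- list(proteins = proteins[], peptides = peptides[],
              panel = ll_ids, config = config)
  class(out) <- "silam_truth"
  out
}

#' Simulate peptide light-channel abundances
#'
#' Forward model per peptide and sample:
#' `abundance = exp(log_baseline + log_loading + -(kd + slope_dev) * t + e)`
#' with `e ~ N(0, sigma)` where `sigma` matches the configured
#' multiplicative CV. Post-baseline measurements are dropped at
#' `missing_rate`; day-0 baselines are always retained so the unlabeled
#' fraction is computable for every emitted peptide.
#'
#' @param truth a [simulate_truth()] object.
#' @param design a [simulate_design()] table.
#' @param config the same [sim_config()] used for both.
#' @return a `data.table` with columns `peptide_id`, `protein_id`,
#'   `sample_id`, `abundance`.
#' @export
simulate_abundances <- function(truth, design, config) {
  stopifnot(inherits(truth, "silam_truth"), inherits(config, "sim_config"))
  design <- as_dt(design)
  missing_cond <- design[!truth$proteins,
                         on = c("organ", "oxygen"),
                         unique(paste(organ, oxygen, sep = ":"))]
  if (length(missing_cond) > 0L) {
    stop(sprintf("truth table does not cover design condition(s): %s",
                 paste(missing_cond, collapse = ", ")))
  }
  set.seed(config$seed + 1L)

  loading <- design[, .(sample_id,
                        log_loading = rnorm(.N, 0, config$loading_factor_sigma))]

  pep <- truth$peptides[, .(peptide_id, protein_id, log_baseline, slope_dev)]
  np <- nrow(pep)
  ns <- nrow(design)
  grid <- cbind(
    pep[rep(seq_len(np), each = ns)],
    design[rep(seq_len(ns), times = np), .(sample_id, organ, oxygen, time_days)]
  )
  grid <- merge(grid,
                truth$proteins[, .(protein_id, organ, oxygen, true_kd,
                                   is_longlived)],
                by = c("protein_id", "organ", "oxygen"), sort = FALSE)
  grid <- merge(grid, loading, by = "sample_id", sort = FALSE)
  data.table::setorder(grid, peptide_id, sample_id)

  ## panel standards: light-channel signal held fixed unless the
  ## configuration asks for their (slow) decay explicitly
  grid[, sim_kd := if (config$longlived_decay) true_kd else {
    data.table::fifelse(is_longlived, 0, true_kd)
  }]
  sigma <- sqrt(log(1 + config$noise_cv^2))
  grid[, log_abund := log_baseline + log_loading -
         (sim_kd + slope_dev) * time_days + rnorm(.N, 0, sigma)]
  grid[, abundance := exp(log_abund)]

  ## missingness never touches the day-0 baselines
  u <- runif(nrow(grid))
  if (config$missing_rate > 0) {
    if (config$intensity_dependent_missing) {
      ## rank-based: the dimmest measurement is ~2x as likely to drop as
      ## average, the brightest ~0; mean drop rate stays missing_rate
      p <- config$missing_rate * 2 *
        (1 - (data.table::frank(grid$log_abund) - 0.5) / nrow(grid))
    } else {
      p <- rep(config$missing_rate, nrow(grid))
    }
    keep <- grid$time_days == 0 | u >= p
    grid <- grid[keep]
  }
  grid[, .(peptide_id, protein_id, sample_id, abundance)]
}

#' Simulate a complete pulsed-labeling dataset
#'
#' Convenience wrapper: design + truth + abundances + panel list.
#'
#' @param config a [sim_config()] object.
#' @return list with `design`, `truth`, `abundance`, `panel`.
#' @export
simulate_dataset <- function(config) {
  design <- simulate_design(config)
  truth <- simulate_truth(config)
  abundance <- simulate_abundances(truth, design, config)
  list(design = design, truth = truth, abundance = abundance,
       panel = truth$panel)
}

#' Write a simulated dataset to disk
#'
#' Emits `abundance.tsv`, `samples.tsv`, `truth.tsv`, `peptides.tsv` and
#' `panel.txt` under `dir`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(sim$abundance, file.path(dir, "abundance.tsv"), sep = "\t")
  data.table::fwrite(sim$design, file.path(dir, "samples.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$proteins, file.path(dir, "truth.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$peptides, file.path(dir, "peptides.tsv"), sep = "\t")
  writeLines(sim$panel, file.path(dir, "panel.txt"))
  invisible(dir)
}
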