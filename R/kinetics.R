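## First-order decay kinetics: the unlabeled fraction of a peptide decays
## as exp(-kd * t), so log(fraction) is linear in time with slope -kd.
## Peptides are screened with per-peptide OLS, then each protein's rate is
## estimated by a linear mixed model with per-peptide random intercepts.

#' Per-peptide ordinary least squares decay fits
#'
#' Fits `log(fraction14N) ~ time` separately for every peptide within
#' every organ x oxygen condition, by closed-form least squares. This is
#' the preliminary screen: the slope estimates quality, and `r_squared`
#' and the number of samples feed the retention filter (kept when
#' r-squared exceeds `r2_min` and the peptide is detected in at least
#' `min_samples` samples in that condition).
#'
#' Fractions below `floor` are raised to it before the log transform,
#' with a logged count. The default is a pure underflow guard: fractions
#' are positive by construction, and genuine fast decay can reach very
#' small fractions by day 32, which must not be clipped. Raise the floor
#' (e.g. `1e-6`) to blunt the leverage of extreme low-intensity outliers
#' in real data.
#'
#' @param fractions a FractionTable from [compute_fractions()].
#' @param r2_min minimum r-squared, exclusive (default 0.65).
#' @param min_samples minimum number of samples, inclusive (default 6,
#'   i.e. "detected in more than five samples").
#' @param through_origin if `TRUE`, the regression is forced through
#'   log(fraction) = 0 at t = 0; default is a free intercept, which
#'   absorbs residual baseline mis-normalization.
#' @param floor lower floor applied to fractions before logging.
#' @return a `data.table` of PeptideFit rows: `peptide_id`, `protein_id`,
#'   `organ`, `oxygen`, `slope`, `intercept`, `r_squared`, `n_samples`,
#'   `passes_filter`.
#' @export
fit_peptide_ols <- function(fractions, r2_min = 0.65, min_samples = 6L,
                            through_origin = FALSE, floor = 1e-300) {
  fractions <- as_dt(fractions)
  assert_columns(fractions, c("peptide_id", "protein_id", "organ", "oxygen",
                              "time_days", "fraction14N"), "fraction table")
  n_floored <- sum(fractions$fraction14N < floor)
  if (n_floored > 0L) {
    log_info("fit_peptide_ols: floored %d fraction(s) below %g before log transform",
             n_floored, floor)
  }
  fits <- fractions[, {
    tt <- time_days
    yy <- log(pmax(fraction14N, floor))
    n <- length(tt)
    if (n < 3L || data.table::uniqueN(tt) < 2L) {
      .(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
        n_samples = n)
    } else if (through_origin) {
      b <- sum(tt * yy) / sum(tt * tt)
      ss_res <- sum((yy - b * tt)^2)
      ss_tot <- sum(yy^2)
      .(slope = b, intercept = 0,
        r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
        n_samples = n)
    } else {
      sxx <- sum((tt - mean(tt))^2)
      syy <- sum((yy - mean(yy))^2)
      sxy <- sum((tt - mean(tt)) * (yy - mean(yy)))
      b <- sxy / sxx
      .(slope = b, intercept = mean(yy) - b * mean(tt),
        r_squared = if (syy > 0) sxy^2 / (sxx * syy) else NA_real_,
        n_samples = n)
    }
  }, by = .(peptide_id, protein_id, organ, oxygen)]
  fits[, passes_filter := !is.na(r_squared) & r_squared > r2_min &
         n_samples >= min_samples]
  fits[]
}

#' Retain peptides that pass the quality filter
#'
#' @param fits output of [fit_peptide_ols()].
#' @return the subset of rows with `passes_filter == TRUE`; counts logged.
#' @export
filter_peptides <- function(fits) {
  fits <- as_dt(fits)
  kept <- fits[passes_filter == TRUE]
  log_info("filter_peptides: kept %d of %d peptide-condition fits",
           nrow(kept), nrow(fits))
  kept
}

## Closed-form OLS with inference; x = time, y = log fraction.
ols_inference <- function(tt, yy) {
  n <- length(tt)
  sxx <- sum((tt - mean(tt))^2)
  b <- sum((tt - mean(tt)) * (yy - mean(yy))) / sxx
  a <- mean(yy) - b * mean(tt)
  res <- yy - a - b * tt
  df <- n - 2L
  s2 <- sum(res^2) / max(df, 1L)
  se <- sqrt(s2 / sxx)
  p <- if (df >= 1L && se > 0) 2 * pt(-abs(b / se), df) else NA_real_
  list(slope = b, intercept = a, se = se, p = p, sigma2 = s2, df = df)
}

## One protein x condition mixed-model fit; d has columns peptide_id,
## time_days, y. Returns list(kd, se, p, n_pep, n_obs, method).
fit_protein_one <- function(d, reml = TRUE) {
  n_pep <- data.table::uniqueN(d$peptide_id)
  pooled <- ols_inference(d$time_days, d$y)
  ## single peptide, or an (essentially) exact pooled fit: the mixed model
  ## is degenerate and OLS is the maximum-likelihood answer
  if (n_pep == 1L || pooled$sigma2 < 1e-18) {
    return(list(kd = -pooled$slope, se = pooled$se, p = pooled$p,
                n_pep = n_pep, n_obs = nrow(d), method = "ols_fallback"))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ time_days + (1 | peptide_id), data = d, REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    )),
    error = function(e) NULL)
  if (is.null(fit) && reml) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ time_days + (1 | peptide_id), data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
      )),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    b <- lme4::fixef(fit)[["time_days"]]
    se <- sqrt(as.matrix(stats::vcov(fit))["time_days", "time_days"])
    if (is.finite(b) && is.finite(se) && se > 0) {
      ## Wald z test of the time coefficient
      return(list(kd = -b, se = se, p = 2 * pnorm(-abs(b / se)),
                  n_pep = n_pep, n_obs = nrow(d), method = "lmm"))
    }
  }
  list(kd = -pooled$slope, se = pooled$se, p = pooled$p,
       n_pep = n_pep, n_obs = nrow(d), method = "ols_fallback")
}

#' Per-protein degradation rates from a linear mixed-effects model
#'
#' For each protein within each organ x oxygen condition, fits
#' `log(fraction14N) ~ time + (1 | peptide)` (REML) over the peptides that
#' pass the r-squared / sample-count filter. The degradation rate `kd` is
#' minus the time coefficient; its p-value is the two-sided Wald test of
#' that coefficient; half-life is `ln(2)/kd` for positive rates. Records
#' with `p_value < p_max` carry `reported = TRUE`. With a single kept
#' peptide, or if the mixed model cannot be fitted (REML, then ML
#' retried), the fit falls back to pooled OLS and `fit_method` says so.
#' Non-positive rate estimates are retained, flagged `nonphysical`, with
#' undefined half-life.
#'
#' @param fractions a FractionTable.
#' @param peptide_fits optional precomputed [fit_peptide_ols()] table;
#'   computed from `fractions` if `NULL`.
#' @param r2_min,min_samples,through_origin,floor passed to
#'   [fit_peptide_ols()] when `peptide_fits` is `NULL`.
#' @param p_max reporting threshold on the rate p-value (default 0.20).
#' @return a `data.table` of ProteinKdRecord rows: `protein_id`, `organ`,
#'   `oxygen`, `kd`, `se_kd`, `p_value`, `half_life_days`,
#'   `n_peptides_used`, `n_obs`, `fit_method`, `nonphysical`, `reported`.
#' @export
fit_protein_kd <- function(fractions, peptide_fits = NULL, r2_min = 0.65,
                           min_samples = 6L, p_max = 0.20,
                           through_origin = FALSE, floor = 1e-300) {
  fractions <- as_dt(fractions)
  if (is.null(peptide_fits)) {
    peptide_fits <- fit_peptide_ols(fractions, r2_min = r2_min,
                                    min_samples = min_samples,
                                    through_origin = through_origin,
                                    floor = floor)
  }
  kept <- filter_peptides(peptide_fits)
  n_prot_all <- data.table::uniqueN(fractions[, .(protein_id, organ, oxygen)])
  dat <- merge(fractions,
               kept[, .(peptide_id, organ, oxygen, keep = TRUE)],
               by = c("peptide_id", "organ", "oxygen"), sort = FALSE)
  dat[, y := log(pmax(fraction14N, floor))]

  groups <- split(dat, by = c("protein_id", "organ", "oxygen"), drop = TRUE)
  out <- data.table::rbindlist(lapply(groups, function(d) {
    if (data.table::uniqueN(d$time_days) < 2L) return(NULL)
    f <- fit_protein_one(d)
    data.table::data.table(
      protein_id = d$protein_id[1], organ = d$organ[1], oxygen = d$oxygen[1],
      kd = f$kd, se_kd = f$se, p_value = f$p,
      half_life_days = if (f$kd > 0) log(2) / f$kd else NA_real_,
      n_peptides_used = f$n_pep, n_obs = f$n_obs, fit_method = f$method,
      nonphysical = f$kd <= 0,
      reported = !is.na(f$p) && f$p < p_max)
  }))
  log_info("fit_protein_kd: fitted %d of %d protein-condition groups (others had no kept peptides)",
           nrow(out), n_prot_all)
  data.table::setorder(out, organ, oxygen, protein_id)
  out[]
}

#' Half-life from a first-order degradation rate
#'
#' @param kd degradation rate(s), per day; must be strictly positive.
#' @return `ln(2)/kd`, in days.
#' @export
#' @examples
#' half_life(log(2) / 3.9)  # 3.9 days
half_life <- function(kd) {
  if (!is.numeric(kd) || length(kd) == 0L) stop("kd must be numeric")
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("half-life is undefined for non-positive degradation rates")
  }
  log(2) / kd
}

#' Summarize half-life distributions by group
#'
#' @param records output of [fit_protein_kd()] (rows with undefined
#'   half-life are ignored).
#' @param by grouping columns (default organ and oxygen).
#' @param window plausible half-life range in days given the labeling
#'   window; values outside are counted in `n_outside_window`.
#' @return per-group `data.table`: `n`, `median_half_life`, `q25`, `q75`,
#'   `n_outside_window`.
#' @export
summarize_half_lives <- function(records, by = c("organ", "oxygen"),
                                 window = c(0.5, 64)) {
  records <- as_dt(records)
  ok <- records[!is.na(half_life_days)]
  dropped_groups <- records[is.na(half_life_days),
                            unique(.SD), .SDcols = by][
                              !unique(ok[, .SD, .SDcols = by]), on = by]
  if (nrow(ok) < nrow(records)) {
    log_info("summarize_half_lives: %d record(s) without a defined half-life ignored",
             nrow(records) - nrow(ok))
  }
  if (nrow(dropped_groups) > 0L) {
    warning("group(s) with no defined half-life omitted from the summary")
  }
  out <- ok[, .(n = .N,
                median_half_life = median(half_life_days),
                q25 = quantile(half_life_days, 0.25, names = FALSE),
                q75 = quantile(half_life_days, 0.75, names = FALSE),
                n_outside_window = sum(half_life_days < window[1] |
                                         half_life_days > window[2])),
            by = by]
  data.table::setorderv(out, by)
  out[]
}
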