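## Differential turnover: for each protein, log(fraction) is modeled with
## oxygen, time, and oxygen:time fixed effects plus per-peptide random
## intercepts. The oxygen:time interaction coefficient is the difference
## in decay slopes, i.e. the difference in degradation rates.

## One protein, two conditions; d has peptide_id, oxygen (factor with the
## reference level first), time_days, y.
fit_interaction_one <- function(d) {
  n_pep <- data.table::uniqueN(d$peptide_id)
  use_lm <- n_pep == 1L
  if (!use_lm) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ oxygen * time_days + (1 | peptide_id), data = d,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
      )),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(y ~ oxygen * time_days + (1 | peptide_id), data = d,
                     REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore",
                                                 calc.derivs = FALSE))
        )),
        error = function(e) NULL)
    }
    if (!is.null(fit)) {
      b <- lme4::fixef(fit)
      V <- as.matrix(stats::vcov(fit))
      i_time <- which(names(b) == "time_days")
      i_int <- grep(":time_days$|^time_days:", names(b))
      if (length(i_time) == 1L && length(i_int) == 1L &&
          all(is.finite(b[c(i_time, i_int)]))) {
        se_int <- sqrt(V[i_int, i_int])
        t_stat <- b[[i_int]] / se_int
        return(list(kd_ref = -b[[i_time]], kd_alt = -(b[[i_time]] + b[[i_int]]),
                    t_statistic = t_stat, p = 2 * pnorm(-abs(t_stat)),
                    n_pep = n_pep, method = "lmm"))
      }
    }
    use_lm <- TRUE
  }
  if (use_lm) {
    fit <- stats::lm(y ~ oxygen * time_days, data = d)
    b <- stats::coef(fit)
    sm <- summary(fit)$coefficients
    i_time <- which(names(b) == "time_days")
    i_int <- grep(":time_days$|^time_days:", names(b))
    if (length(i_time) != 1L || length(i_int) != 1L ||
        any(is.na(b[c(i_time, i_int)]))) {
      return(NULL)
    }
    t_stat <- sm[i_int, "t value"]
    return(list(kd_ref = -b[[i_time]], kd_alt = -(b[[i_time]] + b[[i_int]]),
                t_statistic = t_stat, p = sm[i_int, "Pr(>|t|)"],
                n_pep = n_pep, method = "ols_fallback"))
  }
}

#' Differential turnover between oxygen tensions
#'
#' For every organ and every non-reference oxygen level, each protein is
#' tested with `log(fraction14N) ~ oxygen * time + (1 | peptide)`. The
#' oxygen:time interaction p-value asks whether the decay slope — the
#' degradation rate — differs between conditions; `t_statistic` is the
#' interaction Wald statistic used for signed ranking. Rates implied by
#' the single model are `kd_ref = -b_time` and
#' `kd_alt = -(b_time + b_interaction)`; the fold change is their ratio.
#' p-values are Benjamini-Hochberg adjusted within each organ x contrast
#' family, and proteins are classified with [classify_turnover()].
#'
#' @param fractions a FractionTable covering the conditions to compare.
#' @param peptide_fits [fit_peptide_ols()] table (computed if `NULL`).
#' @param ref_oxygen reference oxygen label (default "21", normoxia).
#' @param alt_oxygen oxygen level(s) to contrast against the reference;
#'   default all other levels present.
#' @param peptide_rule `"either"` (default) keeps a peptide that passes
#'   the quality filter in at least one of the two conditions; `"both"`
#'   requires both.
#' @param fc_threshold,fdr_threshold classification thresholds
#'   (default 1.3 and 0.05, both strict).
#' @param r2_min,min_samples,floor filter settings used when
#'   `peptide_fits` is `NULL`.
#' @return a `data.table` of DifferentialRecord rows: `protein_id`,
#'   `organ`, `contrast`, `kd_ref`, `kd_alt`, `log2_fc`, `t_statistic`,
#'   `p_interaction`, `fdr`, `class`, `n_peptides_used`, `fit_method`,
#'   `nonphysical`.
#' @export
fit_differential <- function(fractions, peptide_fits = NULL,
                             ref_oxygen = "21", alt_oxygen = NULL,
                             peptide_rule = c("either", "both"),
                             fc_threshold = 1.3, fdr_threshold = 0.05,
                             r2_min = 0.65, min_samples = 6L, floor = 1e-300) {
  peptide_rule <- match.arg(peptide_rule)
  fractions <- as_dt(fractions)
  ref_oxygen <- as.character(ref_oxygen)
  if (!ref_oxygen %in% fractions$oxygen) {
    stop(sprintf("reference oxygen level '%s' not present in the data",
                 ref_oxygen))
  }
  if (is.null(alt_oxygen)) {
    alt_oxygen <- setdiff(unique(fractions$oxygen), ref_oxygen)
  }
  alt_oxygen <- as.character(alt_oxygen)
  if (length(alt_oxygen) == 0L) stop("no alternative oxygen level to contrast")
  if (is.null(peptide_fits)) {
    peptide_fits <- fit_peptide_ols(fractions, r2_min = r2_min,
                                    min_samples = min_samples, floor = floor)
  } else {
    peptide_fits <- as_dt(peptide_fits)
  }

  res <- list()
  for (alt in alt_oxygen) {
    contrast <- sprintf("%sv%s", alt, ref_oxygen)
    pf <- peptide_fits[oxygen %in% c(ref_oxygen, alt)]
    keep <- if (peptide_rule == "either") {
      pf[, .(keep = any(passes_filter)), by = .(peptide_id, organ)][keep == TRUE]
    } else {
      pf[, .(keep = sum(passes_filter) == 2L), by = .(peptide_id, organ)][keep == TRUE]
    }
    dat <- merge(fractions[oxygen %in% c(ref_oxygen, alt)],
                 keep[, .(peptide_id, organ)],
                 by = c("peptide_id", "organ"), sort = FALSE)
    if (nrow(dat) == 0L) next
    dat[, y := log(pmax(fraction14N, floor))]
    dat[, oxygen := factor(oxygen, levels = c(ref_oxygen, alt))]

    groups <- split(dat, by = c("protein_id", "organ"), drop = TRUE)
    n_skipped <- 0L
    rows <- lapply(groups, function(d) {
      if (data.table::uniqueN(d$oxygen) < 2L) {
        n_skipped <<- n_skipped + 1L
        return(NULL)
      }
      f <- fit_interaction_one(d)
      if (is.null(f)) {
        n_skipped <<- n_skipped + 1L
        return(NULL)
      }
      data.table::data.table(
        protein_id = d$protein_id[1], organ = d$organ[1], contrast = contrast,
        kd_ref = f$kd_ref, kd_alt = f$kd_alt,
        log2_fc = if (f$kd_ref > 0 && f$kd_alt > 0) {
          log2(f$kd_alt / f$kd_ref)
        } else NA_real_,
        t_statistic = f$t_statistic, p_interaction = f$p,
        n_peptides_used = f$n_pep, fit_method = f$method,
        nonphysical = f$kd_ref <= 0 || f$kd_alt <= 0)
    })
    if (n_skipped > 0L) {
      log_info("fit_differential [%s]: skipped %d protein group(s) lacking both conditions or a valid fit",
               contrast, n_skipped)
    }
    res[[contrast]] <- data.table::rbindlist(rows)
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) stop("no protein could be tested in any contrast")
  ## BH family: all proteins within one organ x contrast
  out[, fdr := bh_adjust(p_interaction), by = .(organ, contrast)]
  out[, class := classify_turnover(log2_fc, fdr, fc_threshold = fc_threshold,
                                   fdr_threshold = fdr_threshold)]
  data.table::setorder(out, organ, contrast, protein_id)
  out[]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; values are returned in input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify differential-turnover records
#'
#' `faster` when the rate fold change exceeds `fc_threshold` with
#' `fdr < fdr_threshold` (both strict); `slower` for the reciprocal
#' change; otherwise `ns`. Records with undefined fold change (a
#' non-positive rate estimate) are `ns`.
#'
#' @param log2_fc log2 rate ratio (alternative over reference).
#' @param fdr BH-adjusted interaction p-value.
#' @param fc_threshold fold-change threshold (default 1.3).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return character vector: `"faster"`, `"slower"` or `"ns"`.
#' @export
classify_turnover <- function(log2_fc, fdr, fc_threshold = 1.3,
                              fdr_threshold = 0.05) {
  out <- rep("ns", length(log2_fc))
  sig <- !is.na(log2_fc) & !is.na(fdr) & fdr < fdr_threshold
  out[sig & 2^log2_fc > fc_threshold] <- "faster"
  out[sig & 2^(-log2_fc) > fc_threshold] <- "slower"
  out
}

#' Fraction of proteins with significant turnover changes
#'
#' @param records classified [fit_differential()] output.
#' @param by grouping columns (default organ and contrast).
#' @return per-group `data.table`: `n_tested`, `n_faster`, `n_slower`,
#'   `pct_significant`.
#' @export
summarize_significant <- function(records, by = c("organ", "contrast")) {
  records <- as_dt(records)
  out <- records[, .(n_tested = .N,
                     n_faster = sum(class == "faster"),
                     n_slower = sum(class == "slower"),
                     pct_significant = 100 * mean(class != "ns")),
                 by = by]
  data.table::setorderv(out, by)
  out[]
}
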