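#' Read the peptide abundance and sample metadata tables
#'
#' Both files may be comma- or tab-delimited (sniffed) and gzipped. Rows
#' with non-positive or non-numeric abundance are dropped with a logged
#' count; sample ids appearing in the abundance table but not in the
#' metadata are a referential error.
#'
#' @param abundance_path file with columns `peptide_id`, `protein_id`,
#'   `sample_id`, `abundance`.
#' @param samples_path file with columns `sample_id`, `organ`, `oxygen`,
#'   `time_days`, `replicate`.
#' @return list with `abundance` and `samples` data.tables.
#' @export
read_tables <- function(abundance_path, samples_path) {
  samples <- read_sample_table(samples_path)
  abundance <- read_abundance_table(abundance_path, samples = samples)
  list(abundance = abundance, samples = samples)
}

#' @rdname read_tables
#' @param path file path.
#' @param samples optional sample table for referential validation.
#' @export
read_abundance_table <- function(path, samples = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  abund <- data.table::fread(path)
  assert_columns(abund, c("peptide_id", "protein_id", "sample_id", "abundance"),
                 "abundance table")
  abund <- abund[, .(peptide_id = as.character(peptide_id),
                     protein_id = as.character(protein_id),
                     sample_id = as.character(sample_id),
                     abundance = suppressWarnings(as.numeric(abundance)))]
  n_in <- nrow(abund)
  abund <- abund[is.finite(abundance) & abundance > 0]
  n_dropped <- n_in - nrow(abund)
  if (n_dropped > 0L) {
    log_info("read_abundance_table: dropped %d of %d rows with non-positive or non-numeric abundance",
             n_dropped, n_in)
  }
  if (anyDuplicated(abund, by = c("peptide_id", "sample_id"))) {
    stop("abundance table has duplicated (peptide_id, sample_id) pairs")
  }
  if (!is.null(samples)) {
    unknown <- setdiff(abund$sample_id, samples$sample_id)
    if (length(unknown) > 0L) {
      stop(sprintf("abundance table references sample id(s) absent from metadata: %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")))
    }
  }
  abund[]
}

#' @rdname read_tables
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  samples <- data.table::fread(path)
  assert_columns(samples, c("sample_id", "organ", "oxygen", "time_days",
                            "replicate"), "sample table")
  samples[, `:=`(sample_id = as.character(sample_id),
                 organ = as.character(organ),
                 oxygen = as.character(oxygen),
                 time_days = as.numeric(time_days),
                 replicate = as.character(replicate))]
  if (anyDuplicated(samples$sample_id)) stop("sample_id values must be unique")
  if (any(!is.finite(samples$time_days)) || any(samples$time_days < 0)) {
    stop("time_days must be non-negative")
  }
  samples[]
}

#' Read a long-lived protein panel list
#'
#' @param path text file, one protein id per line (blank lines and lines
#'   starting with `#` ignored).
#' @return character vector of protein ids.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop("panel file contains no protein ids")
  unique(x)
}

#' Per-sample normalization factors from the long-lived panel
#'
#' Long-lived proteins are assumed to have fixed abundance across
#' conditions and labeling times, so any systematic per-sample deviation
#' of their peptides reflects sample loading. For each sample the factor
#' is the geometric mean, over observed panel peptides, of
#' (abundance in this sample) / (that peptide's geometric-mean abundance
#' across samples); factors are then rescaled to have geometric mean 1.
#'
#' @param abund a PeptideAbundanceTable.
#' @param samples a SampleTable (defines the set of samples that must be
#'   covered).
#' @param panel character vector of long-lived protein ids.
#' @return data.table `(sample_id, factor)`, geometric mean of `factor`
#'   equal to 1.
#' @export
compute_sample_factors <- function(abund, samples, panel) {
  abund <- as_dt(abund)
  samples <- as_dt(samples)
  panel <- as.character(panel)
  sub <- abund[protein_id %in% panel]
  if (nrow(sub) == 0L) {
    stop("no peptide of any panel protein is present in the abundance table")
  }
  sub[, ref := geomean(abundance), by = peptide_id]
  sub[, ratio := abundance / ref]
  factors <- sub[, .(factor = geomean(ratio)), by = sample_id]
  uncovered <- setdiff(samples$sample_id, factors$sample_id)
  if (length(uncovered) > 0L) {
    stop(sprintf("sample(s) with no observed panel peptide: %s",
                 paste(uncovered, collapse = ", ")))
  }
  factors[, factor := factor / geomean(factor)]
  data.table::setkeyv(factors, "sample_id")
  factors[]
}

#' Apply per-sample normalization factors
#'
#' @param abund a PeptideAbundanceTable.
#' @param factors output of [compute_sample_factors()].
#' @return the abundance table with `abundance` divided by its sample's
#'   factor.
#' @export
normalize_abundance <- function(abund, factors) {
  abund <- as_dt(abund)
  factors <- as_dt(factors)
  uncovered <- setdiff(abund$sample_id, factors$sample_id)
  if (length(uncovered) > 0L) {
    stop(sprintf("no normalization factor for sample(s): %s",
                 paste(utils::head(uncovered, 5L), collapse = ", ")))
  }
  out <- merge(abund, factors[, .(sample_id, factor)], by = "sample_id",
               sort = FALSE)
  out[, abundance := abundance / factor]
  out[, factor := NULL]
  data.table::setcolorder(out, c("peptide_id", "protein_id", "sample_id",
                                 "abundance"))
  out[]
}

#' Convert normalized abundances to unlabeled-isotope fractions
#'
#' Each normalized abundance is divided by that peptide's baseline: the
#' mean of its day-0 normalized abundances. Under first-order decay the
#' resulting fraction follows `exp(-kd * t)`.
#'
#' `baseline_mode` controls the baseline scope:
#' \describe{
#'   \item{`condition_t0`}{(default) mean of the peptide's day-0 samples
#'     within the same organ x oxygen condition; conditions with different
#'     pre-labeling abundances are not mixed.}
#'   \item{`explicit_t0`}{mean of the peptide's day-0 samples pooled
#'     across all conditions.}
#'   \item{`fitted_intercept`}{per peptide and condition, the baseline is
#'     `exp(intercept)` of an OLS fit of log abundance on time — for
#'     datasets without day-0 samples.}
#' }
#'
#' Fractions above 1 (noise) are retained: truncating them would bias
#' slopes near t = 0. Rows whose baseline cannot be formed are dropped
#' with a logged count.
#'
#' @param norm normalized PeptideAbundanceTable.
#' @param samples a SampleTable.
#' @param baseline_mode one of `"condition_t0"`, `"explicit_t0"`,
#'   `"fitted_intercept"`.
#' @return a FractionTable: `peptide_id`, `protein_id`, `sample_id`,
#'   `organ`, `oxygen`, `time_days`, `fraction14N`.
#' @export
compute_fractions <- function(norm, samples,
                              baseline_mode = c("condition_t0", "explicit_t0",
                                                "fitted_intercept")) {
  baseline_mode <- match.arg(baseline_mode)
  norm <- as_dt(norm)
  samples <- as_dt(samples)
  dt <- merge(norm, samples[, .(sample_id, organ, oxygen, time_days)],
              by = "sample_id", sort = FALSE)
  n_in <- nrow(dt)

  if (baseline_mode %in% c("condition_t0", "explicit_t0") &&
      !any(dt$time_days == 0)) {
    stop("no day-0 samples found; use baseline_mode = 'fitted_intercept'")
  }

  if (baseline_mode == "explicit_t0") {
    base <- dt[time_days == 0, .(baseline = mean(abundance)), by = peptide_id]
    dt <- merge(dt, base, by = "peptide_id", sort = FALSE)
  } else if (baseline_mode == "condition_t0") {
    base <- dt[time_days == 0, .(baseline = mean(abundance)),
               by = .(peptide_id, organ, oxygen)]
    dt <- merge(dt, base, by = c("peptide_id", "organ", "oxygen"), sort = FALSE)
  } else {
    base <- dt[, {
      ok <- length(time_days) >= 3L && data.table::uniqueN(time_days) >= 2L
      if (ok) {
        yy <- log(abundance)
        tt <- time_days
        b <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
        .(baseline = exp(mean(yy) - b * mean(tt)))
      } else .(baseline = NA_real_)
    }, by = .(peptide_id, organ, oxygen)]
    dt <- merge(dt, base[!is.na(baseline)],
                by = c("peptide_id", "organ", "oxygen"), sort = FALSE)
  }

  dt[, fraction14N := abundance / baseline]
  n_dropped <- n_in - nrow(dt)
  if (n_dropped > 0L) {
    log_info("compute_fractions: dropped %d of %d rows with no usable baseline",
             n_dropped, n_in)
  }
  out <- dt[, .(peptide_id, protein_id, sample_id, organ, oxygen, time_days,
                fraction14N)]
  data.table::setorder(out, peptide_id, sample_id)
  out[]
}
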