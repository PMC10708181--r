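## Pipeline orchestration: each stage reads/writes TSVs under out_dir so
## stages are independently runnable and auditable. The resolved
## configuration is written next to the outputs of every stage.

default_run_config <- function() {
  list(
    out_dir = ".",
    seed = 1L,
    baseline_mode = "condition_t0",
    peptide_rule = "either",
    ref_oxygen = "21",
    thresholds = list(
      r2_min = 0.65,
      n_samples_min = 6L,
      kd_p_max = 0.20,
      fc_threshold = 1.3,
      fdr_threshold = 0.05,
      tail_fraction_baseline = 0.05,
      tail_fraction_differential = 0.02,
      min_measured_subunits = 4L
    ),
    paths = list(
      abundance = NULL, samples = NULL, panel = NULL,
      fasta = NULL, feature_table = NULL, complex_table = NULL
    ),
    sim = list()
  )
}

deep_merge <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- deep_merge(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Resolve a pipeline run configuration
#'
#' Merges, in increasing precedence: package defaults, a YAML config
#' file, and explicit overrides. Thresholds default to the analysis'
#' canonical values (r-squared > 0.65, more than five samples, rate
#' p-value < 0.20, fold change > 1.3, FDR < 0.05, 5%/2% tails, at least
#' 4 measured complex subunits).
#'
#' @param config path to a YAML file, a list, or `NULL`.
#' @param ... named overrides (nested lists merged recursively, e.g.
#'   `thresholds = list(r2_min = 0.5)`).
#' @return a `run_config` list.
#' @export
run_config <- function(config = NULL, ...) {
  cfg <- default_run_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    cfg <- deep_merge(cfg, yaml::read_yaml(config))
  } else if (is.list(config)) {
    cfg <- deep_merge(cfg, config)
  } else if (!is.null(config)) {
    stop("config must be a YAML path, a list, or NULL")
  }
  overrides <- list(...)
  if (length(overrides) > 0L) cfg <- deep_merge(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

write_resolved_config <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plain <- unclass(cfg)
  yaml::write_yaml(plain, file.path(out_dir, "resolved_config.yaml"))
}

## tee messages emitted during expr into out_dir/pipeline.log (appended)
with_stage_log <- function(out_dir, stage, expr) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat(sprintf("[%s] stage %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              stage), file = log_path, append = TRUE)
  withCallingHandlers(expr, message = function(m) {
    cat(conditionMessage(m), file = log_path, append = TRUE)
  })
}

stage_input <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing input '%s'; run the '%s' stage (or point the config at an existing file) first",
                 path, producer), call. = FALSE)
  }
  path
}

#' Run the simulation stage
#'
#' Generates a synthetic pulsed-labeling dataset and writes
#' `abundance.tsv`, `samples.tsv`, `truth.tsv`, `peptides.tsv` and
#' `panel.txt` under `out_dir`.
#'
#' @param config a [run_config()] (or YAML path / list); simulation
#'   parameters come from its `sim` entry, the seed from `seed`.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- cfg$out_dir
  with_stage_log(out_dir, "simulate", {
    sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    sim <- simulate_dataset(sc)
    write_dataset(sim, out_dir)
    log_info("run_simulate: %d samples, %d abundance rows, %d proteins (+%d panel)",
             nrow(sim$design), nrow(sim$abundance), sc$n_proteins,
             sc$n_longlived)
    write_resolved_config(cfg, out_dir)
  })
  invisible(out_dir)
}

#' Run the fitting stage
#'
#' Reads abundance/sample/panel inputs (defaulting to the files written
#' by [run_simulate()] in `out_dir`), normalizes to the long-lived
#' panel, computes unlabeled fractions, fits and filters peptides, and
#' fits per-protein degradation rates. Writes `factors.tsv`,
#' `fractions.tsv`, `peptide_fits.tsv` and `protein_kd.tsv`.
#'
#' @inheritParams run_simulate
#' @return the protein-rate table, invisibly.
#' @export
run_fit <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- cfg$out_dir
  th <- cfg$thresholds
  result <- NULL
  with_stage_log(out_dir, "fit", {
    abund_path <- cfg$paths$abundance %||% file.path(out_dir, "abundance.tsv")
    samples_path <- cfg$paths$samples %||% file.path(out_dir, "samples.tsv")
    panel_path <- cfg$paths$panel %||% file.path(out_dir, "panel.txt")
    tabs <- read_tables(stage_input(abund_path, "simulate"),
                        stage_input(samples_path, "simulate"))
    panel <- read_panel(stage_input(panel_path, "simulate"))

    factors <- compute_sample_factors(tabs$abundance, tabs$samples, panel)
    normalized <- normalize_abundance(tabs$abundance, factors)
    fractions <- compute_fractions(normalized, tabs$samples,
                                   baseline_mode = cfg$baseline_mode)
    peptide_fits <- fit_peptide_ols(fractions, r2_min = th$r2_min,
                                    min_samples = th$n_samples_min)
    protein_kd <- fit_protein_kd(fractions, peptide_fits,
                                 p_max = th$kd_p_max)

    data.table::fwrite(factors, file.path(out_dir, "factors.tsv"), sep = "\t")
    data.table::fwrite(fractions, file.path(out_dir, "fractions.tsv"), sep = "\t")
    data.table::fwrite(peptide_fits, file.path(out_dir, "peptide_fits.tsv"),
                       sep = "\t")
    data.table::fwrite(protein_kd, file.path(out_dir, "protein_kd.tsv"),
                       sep = "\t")
    log_info("run_fit: %d protein-condition rate estimates (%d reported at p < %g)",
             nrow(protein_kd), sum(protein_kd$reported), th$kd_p_max)
    write_resolved_config(cfg, out_dir)
    result <- protein_kd
  })
  invisible(result)
}

#' Run the differential-turnover stage
#'
#' Reads `fractions.tsv` and `peptide_fits.tsv` from the fit stage and
#' tests every protein's oxygen:time interaction against the reference
#' oxygen level. Writes `differential.tsv`.
#'
#' @inheritParams run_simulate
#' @return the differential table, invisibly.
#' @export
run_diff <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- cfg$out_dir
  th <- cfg$thresholds
  result <- NULL
  with_stage_log(out_dir, "diff", {
    fractions <- data.table::fread(
      stage_input(file.path(out_dir, "fractions.tsv"), "fit"),
      colClasses = list(character = c("oxygen", "organ")))
    peptide_fits <- data.table::fread(
      stage_input(file.path(out_dir, "peptide_fits.tsv"), "fit"),
      colClasses = list(character = c("oxygen", "organ")))
    diff <- fit_differential(fractions, peptide_fits,
                             ref_oxygen = cfg$ref_oxygen,
                             peptide_rule = cfg$peptide_rule,
                             fc_threshold = th$fc_threshold,
                             fdr_threshold = th$fdr_threshold)
    data.table::fwrite(diff, file.path(out_dir, "differential.tsv"), sep = "\t")
    sm <- summarize_significant(diff)
    for (i in seq_len(nrow(sm))) {
      log_info("run_diff [%s %s]: %d tested, %.1f%% significant",
               sm$organ[i], sm$contrast[i], sm$n_tested[i],
               sm$pct_significant[i])
    }
    write_resolved_config(cfg, out_dir)
    result <- diff
  })
  invisible(result)
}

#' Run the feature-enrichment stage
#'
#' Builds a feature table (from `paths$fasta` and/or a precomputed
#' `paths$feature_table`) and KS-tests percentile tails of two rankings:
#' per-organ degradation rate at the reference oxygen (5% tails) and,
#' when `differential.tsv` exists, the interaction t-statistic (2%
#' tails). Writes `enrichment.tsv`.
#'
#' @inheritParams run_simulate
#' @return the enrichment table, invisibly.
#' @export
run_enrich <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- cfg$out_dir
  th <- cfg$thresholds
  result <- NULL
  with_stage_log(out_dir, "enrich", {
    features <- NULL
    if (!is.null(cfg$paths$fasta)) {
      features <- sequence_features(stage_input(cfg$paths$fasta, "user input"))
    }
    if (!is.null(cfg$paths$feature_table)) {
      extra <- data.table::fread(stage_input(cfg$paths$feature_table,
                                             "user input"))
      features <- if (is.null(features)) extra else {
        merge(features, extra, by = "protein_id", all = TRUE)
      }
    }
    if (is.null(features)) {
      stop("run_enrich needs paths$fasta and/or paths$feature_table")
    }

    kd_tab <- data.table::fread(
      stage_input(file.path(out_dir, "protein_kd.tsv"), "fit"),
      colClasses = list(character = c("oxygen", "organ")))
    rows <- list()
    for (org in unique(kd_tab$organ)) {
      base <- kd_tab[organ == org & oxygen == cfg$ref_oxygen & kd > 0]
      if (nrow(base) == 0L) next
      enr <- feature_enrichment(features, setNames(base$kd, base$protein_id),
                                tail_fraction = th$tail_fraction_baseline)
      enr[, `:=`(ranking = "degradation_rate", organ = org,
                 contrast = NA_character_)]
      rows[[length(rows) + 1L]] <- enr
    }
    diff_path <- file.path(out_dir, "differential.tsv")
    if (file.exists(diff_path)) {
      diff <- data.table::fread(diff_path,
                                colClasses = list(character = "organ"))
      for (grp in split(diff, by = c("organ", "contrast"), drop = TRUE)) {
        enr <- tryCatch(
          feature_enrichment(features,
                             setNames(grp$t_statistic, grp$protein_id),
                             tail_fraction = th$tail_fraction_differential),
          error = function(e) NULL)
        if (is.null(enr)) next
        enr[, `:=`(ranking = "t_statistic", organ = grp$organ[1],
                   contrast = grp$contrast[1])]
        rows[[length(rows) + 1L]] <- enr
      }
    }
    if (length(rows) == 0L) stop("no ranking had enough proteins to enrich")
    out <- data.table::rbindlist(rows)
    data.table::fwrite(out, file.path(out_dir, "enrichment.tsv"), sep = "\t")
    log_info("run_enrich: %d enrichment tests written", nrow(out))
    write_resolved_config(cfg, out_dir)
    result <- out
  })
  invisible(result)
}

#' Run the protein-complex stage
#'
#' Joins the differential table onto a complex membership table
#' (`paths$complex_table`) and writes per-complex subunit counts and
#' fold-change ranges to `complexes.tsv`.
#'
#' @inheritParams run_simulate
#' @return the complex summary table, invisibly.
#' @export
run_complexes <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- cfg$out_dir
  result <- NULL
  with_stage_log(out_dir, "complexes", {
    if (is.null(cfg$paths$complex_table)) {
      stop("run_complexes needs paths$complex_table")
    }
    complexes <- read_complexes(stage_input(cfg$paths$complex_table,
                                            "user input"))
    diff <- data.table::fread(
      stage_input(file.path(out_dir, "differential.tsv"), "diff"),
      colClasses = list(character = "organ"))
    out <- complex_summaries(diff, complexes,
                             min_measured = cfg$thresholds$min_measured_subunits)
    data.table::fwrite(out, file.path(out_dir, "complexes.tsv"), sep = "\t")
    log_info("run_complexes: %d complex summaries written", nrow(out))
    write_resolved_config(cfg, out_dir)
    result <- out
  })
  invisible(result)
}
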