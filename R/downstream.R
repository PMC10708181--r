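#' Kyte-Doolittle hydropathy scale
#'
#' Residue-level hydropathy values for the 20 standard amino acids.
#' @format named numeric vector.
#' @export
kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Sequence-derived biophysical features
#'
#' Computes, per protein: amino-acid length, the fraction of charged
#' residues (H, K, R, D, E), the fractions of negatively (D, E) and
#' positively (H, K, R) charged residues, and mean hydropathy on the
#' Kyte-Doolittle scale rescaled to \[0, 1\] via `(kd + 4.5) / 9`.
#' Non-standard letters are ignored with a warning; an empty sequence is
#' an error. Externally predicted features (disorder, charge patterning)
#' are not computed here — supply them as extra columns of a precomputed
#' feature table.
#'
#' @param sequences a named character vector of amino-acid sequences, an
#'   `AAStringSet`, or the path to a FASTA file (read with Biostrings).
#' @return a `data.table`: `protein_id`, `length`, `fraction_charged`,
#'   `fraction_negative`, `fraction_positive`, `hydropathy`.
#' @export
sequence_features <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package")
    }
    aa <- Biostrings::readAAStringSet(sequences)
    sequences <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  } else if (inherits(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences),
                          sub("\\s.*$", "", names(sequences)))
  }
  if (!is.character(sequences) || is.null(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("sequences must be named (protein ids)")
  }

  standard <- names(kyte_doolittle)
  n_unknown_total <- 0L
  rows <- lapply(seq_along(sequences), function(i) {
    id <- names(sequences)[i]
    aa <- strsplit(toupper(sequences[[i]]), "")[[1]]
    unknown <- !(aa %in% standard)
    n_unknown_total <<- n_unknown_total + sum(unknown)
    aa <- aa[!unknown]
    if (length(aa) == 0L) {
      stop(sprintf("sequence '%s' is empty (or has no standard residues)", id))
    }
    data.table::data.table(
      protein_id = id,
      length = length(aa),
      fraction_charged = mean(aa %in% c("H", "K", "R", "D", "E")),
      fraction_negative = mean(aa %in% c("D", "E")),
      fraction_positive = mean(aa %in% c("H", "K", "R")),
      hydropathy = mean((kyte_doolittle[aa] + 4.5) / 9)
    )
  })
  if (n_unknown_total > 0L) {
    warning(sprintf("ignored %d non-standard residue(s)", n_unknown_total))
  }
  data.table::rbindlist(rows)
}

#' Split a ranked protein list into percentile tails and background
#'
#' Proteins are ranked by `values` (ties broken by protein id, so the
#' split is deterministic). Each tail holds `max(1, floor(tail_fraction *
#' n))` proteins; `background` is everything outside both tails. For an
#' enrichment comparison of one tail against "all other proteins", take
#' the union of `background` and the opposite tail.
#'
#' @param values named numeric vector (e.g. degradation rates for the
#'   baseline analysis, interaction t-statistics for the oxygen analysis).
#' @param tail_fraction fraction in (0, 0.5) per tail; the study uses
#'   0.05 for baseline rates and 0.02 for oxygen effects.
#' @return list with character vectors `top`, `bottom`, `background`.
#' @export
rank_and_tail <- function(values, tail_fraction = 0.05) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by protein id")
  }
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must be in (0, 0.5)")
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < ceiling(1 / tail_fraction)) {
    stop(sprintf("too few proteins (%d) for tail_fraction %g", n, tail_fraction))
  }
  k <- max(1L, as.integer(floor(tail_fraction * n)))
  ord <- order(values, names(values))  # ascending, ties broken by id
  ids <- names(values)[ord]
  bottom <- ids[seq_len(k)]
  top <- names(values)[order(-values, names(values))][seq_len(k)]
  list(top = top, bottom = bottom,
       background = setdiff(ids, c(top, bottom)))
}

#' Two-sample Kolmogorov-Smirnov enrichment
#'
#' Compares the feature distribution of a ranked tail against a
#' background set; the enrichment score is the two-sided KS statistic
#' and `direction` is the sign of the mean difference (tail minus
#' background).
#'
#' @param tail_values numeric feature values of the tail proteins.
#' @param background_values numeric feature values of the background.
#' @return list: `ks_statistic`, `p_value`, `direction`, `n_tail`,
#'   `n_background`.
#' @export
ks_enrichment <- function(tail_values, background_values) {
  tail_values <- tail_values[!is.na(tail_values)]
  background_values <- background_values[!is.na(background_values)]
  if (length(tail_values) == 0L || length(background_values) == 0L) {
    stop("both samples must be non-empty")
  }
  ## ties between samples are expected for discrete features; the exact
  ## p-value warning is irrelevant here
  st <- suppressWarnings(ks.test(tail_values, background_values))
  list(ks_statistic = unname(st$statistic), p_value = st$p.value,
       direction = sign(mean(tail_values) - mean(background_values)),
       n_tail = length(tail_values), n_background = length(background_values))
}

#' Percentile-tail feature enrichment over a protein ranking
#'
#' For each feature column, ranks proteins by `ranking`, takes the top
#' and bottom `tail_fraction`, and KS-tests each tail's feature values
#' against all other proteins (background = everything not in that tail,
#' including the opposite tail).
#'
#' @param features a FeatureTable (column `protein_id` plus numeric
#'   feature columns), e.g. from [sequence_features()] optionally merged
#'   with precomputed predictor columns.
#' @param ranking named numeric vector over proteins (degradation rate or
#'   interaction t-statistic). Proteins absent from `features` are
#'   dropped with a logged count.
#' @param tail_fraction per-tail fraction (default 0.05).
#' @return `data.table`: `feature`, `tail` ("top"/"bottom"),
#'   `tail_fraction`, `n_tail`, `n_background`, `ks_statistic`,
#'   `p_value`, `direction`.
#' @export
feature_enrichment <- function(features, ranking, tail_fraction = 0.05) {
  features <- as_dt(features)
  assert_columns(features, "protein_id", "feature table")
  in_both <- intersect(names(ranking), features$protein_id)
  if (length(in_both) < length(ranking)) {
    log_info("feature_enrichment: %d ranked protein(s) without features dropped",
             length(ranking) - length(in_both))
  }
  ranking <- ranking[in_both]
  tails <- rank_and_tail(ranking, tail_fraction)
  all_ids <- names(ranking)
  feat_cols <- setdiff(names(features), "protein_id")
  if (length(feat_cols) == 0L) stop("feature table has no feature columns")
  fx <- features[match(all_ids, protein_id)]

  rows <- list()
  for (feat in feat_cols) {
    v <- setNames(fx[[feat]], all_ids)
    for (side in c("top", "bottom")) {
      tail_ids <- tails[[side]]
      bg_ids <- setdiff(all_ids, tail_ids)  # "all other proteins"
      ks <- ks_enrichment(v[tail_ids], v[bg_ids])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        feature = feat, tail = side, tail_fraction = tail_fraction,
        n_tail = ks$n_tail, n_background = ks$n_background,
        ks_statistic = ks$ks_statistic, p_value = ks$p_value,
        direction = ks$direction)
    }
  }
  data.table::rbindlist(rows)
}

#' Read a protein-complex membership table
#'
#' A simplified CORUM-style dialect: tab-separated with a header, either
#' two columns (`complex_name`, `subunits`) or three (`complex_id`,
#' `complex_name`, `subunits`), where `subunits` is a
#' semicolon-separated list of protein ids.
#'
#' @param path TSV path.
#' @return `data.table`: `complex_id`, `complex_name`, `subunits`
#'   (list column of character vectors).
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (ncol(raw) == 2L) {
    data.table::setnames(raw, c("complex_name", "subunits"))
    raw[, complex_id := complex_name]
  } else if (ncol(raw) >= 3L) {
    data.table::setnames(raw, 1:3, c("complex_id", "complex_name", "subunits"))
    raw <- raw[, .(complex_id, complex_name, subunits)]
  } else {
    stop("complex table must have at least two columns")
  }
  raw[, subunits := lapply(strsplit(subunits, ";"), trimws)]
  data.table::setcolorder(raw, c("complex_id", "complex_name", "subunits"))
  raw[]
}

#' Complex-level summaries of differential turnover
#'
#' Joins classified differential records onto complex membership and
#' counts measured, significant, faster and slower subunits per complex;
#' `fc_min`/`fc_max` span the magnitude fold changes
#' (`2^|log2_fc|`) of the significant subunits. Complexes with fewer
#' than `min_measured` measured subunits are excluded. Records should be
#' a single organ x contrast slice; if several are present each is
#' summarized separately.
#'
#' @param records classified [fit_differential()] output.
#' @param complexes [read_complexes()] table.
#' @param min_measured minimum measured subunits (default 4).
#' @return `data.table`: one row per complex (and organ x contrast),
#'   with `n_subunits_total`, `n_measured`, `n_significant`, `n_faster`,
#'   `n_slower`, `fc_min`, `fc_max`.
#' @export
complex_summaries <- function(records, complexes, min_measured = 4L) {
  records <- as_dt(records)
  complexes <- as_dt(complexes)
  if (nrow(complexes) == 0L) stop("complex table is empty")
  membership <- complexes[, .(protein_id = unlist(subunits)),
                          by = .(complex_id, complex_name)]
  membership <- merge(membership,
                      complexes[, .(complex_id,
                                    n_subunits_total = lengths(subunits))],
                      by = "complex_id", sort = FALSE)
  joined <- merge(membership, records, by = "protein_id",
                  allow.cartesian = TRUE)
  if (nrow(joined) == 0L) {
    return(data.table::data.table())
  }
  out <- joined[, {
    sig <- class != "ns"
    fc_mag <- 2^abs(log2_fc[sig])
    .(n_subunits_total = n_subunits_total[1],
      n_measured = .N,
      n_significant = sum(sig),
      n_faster = sum(class == "faster"),
      n_slower = sum(class == "slower"),
      fc_min = if (any(sig)) min(fc_mag) else NA_real_,
      fc_max = if (any(sig)) max(fc_mag) else NA_real_)
  }, by = .(complex_id, complex_name, organ, contrast)]
  out <- out[n_measured >= min_measured]
  data.table::setorder(out, organ, contrast, complex_id)
  out[]
}
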