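## Small in-code fixtures shared across test files.

## Noiseless fraction table: one or more peptides decaying at `kd`
## (optionally per peptide) under a single condition.
noiseless_fractions <- function(kd, times = c(0, 1, 2, 4, 8, 16, 32),
                                n_peptides = 1, protein = "P1",
                                organ = "lung", oxygen = "21") {
  kd <- rep(kd, length.out = n_peptides)
  data.table::rbindlist(lapply(seq_len(n_peptides), function(i) {
    data.table::data.table(
      peptide_id = sprintf("%s_pep%d", protein, i), protein_id = protein,
      sample_id = sprintf("s_d%g", times), organ = organ, oxygen = oxygen,
      time_days = times, fraction14N = exp(-kd[i] * times))
  }))
}

## Tiny abundance + sample tables with two panel peptides; abundances are
## powers of 10 so panel factors are hand-checkable.
toy_panel_tables <- function() {
  samples <- data.table::data.table(
    sample_id = c("s1", "s2", "s3"), organ = "lung", oxygen = "21",
    time_days = c(0, 0, 1), replicate = c("r1", "r2", "r1"))
  abundance <- data.table::data.table(
    peptide_id = c("llA_p1", "llA_p1", "llA_p1", "llB_p1", "llB_p1", "llB_p1",
                   "tgt_p1", "tgt_p1", "tgt_p1"),
    protein_id = c(rep("LLA", 3), rep("LLB", 3), rep("TGT", 3)),
    sample_id = rep(c("s1", "s2", "s3"), 3),
    abundance = c(100, 200, 400, 10, 10, 40, 50, 50, 25))
  list(abundance = abundance, samples = samples, panel = c("LLA", "LLB"))
}

## Random amino-acid sequences for a set of protein ids (for enrichment
## plumbing tests; composition is uniform over the 20 standard residues).
random_sequences <- function(ids, min_len = 80, max_len = 400) {
  aa <- names(pulseTurnover::kyte_doolittle)
  setNames(vapply(seq_along(ids), function(i) {
    paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1)), ids)
}

## Write a small complex membership TSV; returns the path.
write_toy_complexes <- function(path, complexes) {
  lines <- c("complex_id\tcomplex_name\tsubunits",
             vapply(names(complexes), function(id) {
               sprintf("%s\t%s complex\t%s", id, id,
                       paste(complexes[[id]], collapse = ";"))
             }, character(1)))
  writeLines(lines, path)
  path
}
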