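aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic toy repertoire: CDR3s CAAAF, CAACF, ... with given reads.
toy_sample <- function(reads, sample_kind = "baseline_bm", locus = "alpha",
                       patient_id = "P1", v_call = NULL) {
  n <- length(reads)
  stopifnot(n <= 400)
  i <- seq_len(n) - 1L
  cdr3 <- if (n <= 20) paste0("CAA", aa_letters[i + 1L], "F") else
    paste0("CAA", aa_letters[i %/% 20 + 1L], aa_letters[i %% 20 + 1L], "F")
  tab <- tibble::tibble(cdr3_aa = cdr3, read_count = reads)
  if (!is.null(v_call)) tab$v_call <- v_call
  repertoire_sample(tab, patient_id, sample_kind, locus)
}

write_minimal_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}

write_airr_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}

# Independent enumeration oracle for the DFR permutation p-value: scales the
# control arm, walks every bitmask split of the pooled counts into a
# stimulated-sized subset, and counts splits whose mean difference reaches
# the observed one. Coded with sums over bitmasks, unlike the package's
# combn-based path.
dfr_oracle <- function(stim, ctrl, multiplier = 1) {
  ctrl <- multiplier * ctrl
  pool <- c(stim, ctrl)
  n <- length(pool)
  n1 <- length(stim)
  obs <- sum(stim) / n1 - sum(ctrl) / (n - n1)
  eps <- 1e-9 * (1 + abs(obs))
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    total <- total + 1L
    d <- sum(pool[bits == 1]) / n1 - sum(pool[bits == 0]) / (n - n1)
    if (d >= obs - eps) hits <- hits + 1L
  }
  hits / total
}
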