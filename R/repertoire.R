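#' @importFrom rlang .data
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

SAMPLE_KINDS <- c("baseline_bm", "end_of_trial_bm", "specific_culture")
LOCI <- c("alpha", "beta")

#' Construct a repertoire sample from a clonotype table
#'
#' A repertoire sample holds the clonotypes of one (patient, sample, chain)
#' combination: bulk bone-marrow T cells at baseline or end of trial, or an
#' antigen-enriched specific T-cell culture. Rows sharing the same identity
#' columns are merged by summing read counts, and within-sample frequencies
#' are computed so that they sum to 1.
#'
#' @param clonotypes A data frame with columns `cdr3_aa` (uppercase
#'   amino-acid CDR3) and `read_count` (integer >= 1), optionally `cdr3_nt`,
#'   `v_call`, `j_call`.
#' @param patient_id Patient identifier.
#' @param sample_kind One of `"baseline_bm"`, `"end_of_trial_bm"`,
#'   `"specific_culture"`.
#' @param locus Chain: `"alpha"` or `"beta"`.
#' @param strict_aa Reject CDR3s containing characters outside the 20
#'   amino-acid alphabet (stops, frameshift marks). Default `TRUE`.
#' @return A `repertoire_sample` object.
#' @export
repertoire_sample <- function(clonotypes, patient_id, sample_kind, locus,
                              strict_aa = TRUE) {
  sample_kind <- match.arg(sample_kind, SAMPLE_KINDS)
  locus <- match.arg(locus, LOCI)
  clonotypes <- tibble::as_tibble(clonotypes)
  required <- c("cdr3_aa", "read_count")
  missing <- setdiff(required, names(clonotypes))
  if (length(missing) > 0) {
    stop("clonotype table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(clonotypes) == 0L) {
    stop("empty sample: no clonotype rows for ", patient_id, " ",
         sample_kind, " ", locus, call. = FALSE)
  }
  for (opt in c("cdr3_nt", "v_call", "j_call")) {
    if (!opt %in% names(clonotypes)) clonotypes[[opt]] <- NA_character_
  }
  clonotypes$read_count <- as.integer(round(clonotypes$read_count))
  if (any(is.na(clonotypes$read_count)) || any(clonotypes$read_count < 1L)) {
    stop("'read_count' must be integer >= 1 for every clonotype",
         call. = FALSE)
  }
  cdr3 <- clonotypes$cdr3_aa
  if (any(is.na(cdr3)) || any(!nzchar(cdr3))) {
    stop("'cdr3_aa' must be non-empty for every clonotype", call. = FALSE)
  }
  if (strict_aa) {
    ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), cdr3)
    if (!all(ok)) {
      stop("non-amino-acid characters in cdr3_aa (e.g. '",
           cdr3[!ok][[1]], "'); set strict_aa = FALSE to allow",
           call. = FALSE)
    }
  }
  merged <- clonotypes |>
    dplyr::group_by(.data$cdr3_aa, .data$cdr3_nt, .data$v_call,
                    .data$j_call) |>
    dplyr::summarise(read_count = sum(.data$read_count), .groups = "drop")
  merged$frequency <- merged$read_count / sum(merged$read_count)
  merged <- dplyr::arrange(merged, dplyr::desc(.data$read_count),
                           .data$cdr3_aa)
  structure(
    list(patient_id = as.character(patient_id),
         sample_kind = sample_kind,
         locus = locus,
         clonotypes = merged,
         total_reads = sum(merged$read_count)),
    class = "repertoire_sample"
  )
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "Repertoire sample: patient %s, %s, %s chain\n  %d clonotypes, %d reads\n",
    x$patient_id, x$sample_kind, x$locus,
    nrow(x$clonotypes), x$total_reads))
  invisible(x)
}

check_sample <- function(x) {
  if (!inherits(x, "repertoire_sample")) {
    stop("expected a 'repertoire_sample' object", call. = FALSE)
  }
  x
}

#' Read a clonotype table into a repertoire sample
#'
#' Supports two plain-TSV dialects: AIRR Rearrangement (columns `locus`,
#' `junction_aa`, `duplicate_count`, optionally `junction`, `v_call`,
#' `j_call`; locus codes `TRA`/`TRB`) and a minimal dialect (columns
#' `cdr3_aa`, `reads`, optionally `cdr3_nt`, `v_call`, `j_call`). For the
#' AIRR dialect, rows of the non-requested chain are dropped with a message.
#'
#' @param path Path to a TSV file.
#' @param dialect `"airr"` or `"minimal"`.
#' @inheritParams repertoire_sample
#' @return A `repertoire_sample`.
#' @export
read_repertoire <- function(path, dialect = c("airr", "minimal"),
                            patient_id, sample_kind, locus,
                            strict_aa = TRUE) {
  dialect <- match.arg(dialect)
  locus <- match.arg(locus, LOCI)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (dialect == "airr") {
    required <- c("locus", "junction_aa", "duplicate_count")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      stop("AIRR file missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    airr_locus <- c(alpha = "TRA", beta = "TRB")[[locus]]
    dropped <- sum(raw$locus != airr_locus, na.rm = TRUE)
    if (dropped > 0) {
      message(dropped, " row(s) of other loci ignored")
    }
    raw <- raw[!is.na(raw$locus) & raw$locus == airr_locus, , drop = FALSE]
    tab <- tibble::tibble(
      cdr3_aa = raw$junction_aa,
      read_count = raw$duplicate_count,
      cdr3_nt = if ("junction" %in% names(raw)) raw$junction else
        NA_character_,
      v_call = if ("v_call" %in% names(raw)) raw$v_call else NA_character_,
      j_call = if ("j_call" %in% names(raw)) raw$j_call else NA_character_
    )
  } else {
    required <- c("cdr3_aa", "reads")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      stop("minimal TSV missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tab <- tibble::tibble(
      cdr3_aa = raw$cdr3_aa,
      read_count = raw$reads,
      cdr3_nt = if ("cdr3_nt" %in% names(raw)) raw$cdr3_nt else
        NA_character_,
      v_call = if ("v_call" %in% names(raw)) raw$v_call else NA_character_,
      j_call = if ("j_call" %in% names(raw)) raw$j_call else NA_character_
    )
  }
  if (nrow(tab) == 0L) {
    stop("empty sample: no usable rows in ", path, call. = FALSE)
  }
  repertoire_sample(tab, patient_id, sample_kind, locus,
                    strict_aa = strict_aa)
}

#' Clonotype identity keys
#'
#' Builds the identity key used to match clonotypes across samples. The
#' default recipe is chain + amino-acid CDR3 + V gene (`"aa_v"`); `"aa"`
#' drops the V gene and `"nt_vj"` uses the nucleotide CDR3 with both gene
#' calls. Coarser recipes can only merge clonotypes, never split them.
#'
#' @param sample A `repertoire_sample`.
#' @param recipe `"aa_v"`, `"aa"` or `"nt_vj"`.
#' @return Character vector of keys, one per clonotype row.
#' @export
clonotype_keys <- function(sample, recipe = c("aa_v", "aa", "nt_vj")) {
  sample <- check_sample(sample)
  recipe <- match.arg(recipe)
  ct <- sample$clonotypes
  blank <- function(x) ifelse(is.na(x), "", x)
  switch(recipe,
    aa_v = paste(sample$locus, ct$cdr3_aa, blank(ct$v_call), sep = "|"),
    aa = paste(sample$locus, ct$cdr3_aa, sep = "|"),
    nt_vj = paste(sample$locus, blank(ct$cdr3_nt), blank(ct$v_call),
                  blank(ct$j_call), sep = "|")
  )
}

#' Remove low-read clonotypes
#'
#' Clonotypes supported by fewer than `min_reads` reads (default 2, i.e.
#' singletons) are excluded. By default frequencies are recomputed over the
#' surviving clonotypes so they again sum to 1; `renormalize = FALSE` keeps
#' the pre-filter denominators.
#'
#' @param sample A `repertoire_sample`.
#' @param min_reads Minimum read count to retain (>= 1).
#' @param renormalize Recompute frequencies over survivors (default `TRUE`).
#' @return A filtered `repertoire_sample`.
#' @export
filter_min_reads <- function(sample, min_reads = 2L, renormalize = TRUE) {
  sample <- check_sample(sample)
  if (!is.numeric(min_reads) || min_reads < 1) {
    stop("'min_reads' must be >= 1", call. = FALSE)
  }
  keep <- sample$clonotypes$read_count >= min_reads
  if (!any(keep)) {
    stop("empty sample: all clonotypes below ", min_reads, " reads",
         call. = FALSE)
  }
  out <- sample
  out$clonotypes <- sample$clonotypes[keep, , drop = FALSE]
  if (renormalize) {
    out$clonotypes$frequency <-
      out$clonotypes$read_count / sum(out$clonotypes$read_count)
  }
  out$total_reads <- sum(out$clonotypes$read_count)
  out
}

#' Call specific clonotypes in a culture sample
#'
#' In an antigen-enriched culture, low-frequency clonotypes are attributed
#' to background (e.g. feeder-cell) T cells; clonotypes at a within-culture
#' frequency below `min_fraction` (default 1%) are excluded, and the
#' remainder are called specific. The boundary is inclusive: a clonotype at
#' exactly 1% is retained.
#'
#' @param culture_sample A `repertoire_sample` with kind
#'   `"specific_culture"`.
#' @param min_fraction Frequency threshold (default 0.01).
#' @param recipe Identity-key recipe, see [clonotype_keys()].
#' @return Character vector of specific identity keys (possibly empty, with
#'   a warning), with a `ranks` attribute (tibble of key, frequency, rank in
#'   the culture) for rank-based flagging of doubtful matches.
#' @export
specific_clonotype_set <- function(culture_sample, min_fraction = 0.01,
                                   recipe = "aa_v") {
  culture_sample <- check_sample(culture_sample)
  if (culture_sample$sample_kind != "specific_culture") {
    stop("specific clonotypes are called from a 'specific_culture' sample",
         call. = FALSE)
  }
  per_key <- tibble::tibble(
    key = clonotype_keys(culture_sample, recipe),
    frequency = culture_sample$clonotypes$frequency
  ) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$key)
  per_key$rank <- seq_len(nrow(per_key))
  keep <- per_key$frequency >= min_fraction
  if (!any(keep)) {
    warning("no clonotype reaches the ", min_fraction * 100,
            "% culture-frequency threshold", call. = FALSE)
  }
  out <- per_key$key[keep]
  attr(out, "ranks") <- per_key[keep, , drop = FALSE]
  out
}

#' Number of unique clonotypes in a sample
#'
#' @param sample A `repertoire_sample`.
#' @param recipe Identity-key recipe, see [clonotype_keys()].
#' @return Integer count of unique identity keys.
#' @export
count_clonotypes <- function(sample, recipe = "aa_v") {
  length(unique(clonotype_keys(check_sample(sample), recipe)))
}

#' The n most frequent clonotypes
#'
#' Ties are broken by read count (descending) then CDR3 amino-acid sequence
#' (lexicographic) so the ordering is deterministic.
#'
#' @param sample A `repertoire_sample`.
#' @param n Number of clonotypes to return (all if fewer exist).
#' @param recipe Identity-key recipe.
#' @return Character vector of up to `n` identity keys, most frequent first.
#' @export
top_n_clonotypes <- function(sample, n = 100L, recipe = "aa_v") {
  sample <- check_sample(sample)
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  ct <- sample$clonotypes
  keys <- clonotype_keys(sample, recipe)
  agg <- tibble::tibble(key = keys, frequency = ct$frequency,
                        read_count = ct$read_count,
                        cdr3_aa = ct$cdr3_aa) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(frequency = sum(.data$frequency),
                     read_count = sum(.data$read_count),
                     cdr3_aa = min(.data$cdr3_aa), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frequency),
                   dplyr::desc(.data$read_count), .data$cdr3_aa)
  utils::head(agg$key, n)
}

#' Track clonotype frequencies across an ordered list of samples
#'
#' Builds the keys-by-samples frequency matrix used for trajectory plots:
#' entry (i, j) is the frequency of key i in sample j, and exactly 0 where
#' the clonotype is absent (no pseudocounts).
#'
#' @param keys Character vector of identity keys (non-empty).
#' @param samples List of `repertoire_sample` objects, same patient and
#'   locus, in display order. Names are used as column labels (defaulting
#'   to sample kinds).
#' @param recipe Identity-key recipe used to build `keys`.
#' @return A `tracking_result`: list with `key_definition`, `clonotype_keys`,
#'   `sample_order` and `frequency_matrix`.
#' @export
track_clonotypes <- function(keys, samples, recipe = "aa_v") {
  if (length(keys) == 0L) stop("'keys' must be non-empty", call. = FALSE)
  if (length(samples) == 0L) stop("'samples' must be non-empty",
                                  call. = FALSE)
  samples <- lapply(samples, check_sample)
  loci <- vapply(samples, function(s) s$locus, character(1))
  if (length(unique(loci)) != 1L) {
    stop("all samples must share one locus; got: ",
         paste(unique(loci), collapse = ", "), call. = FALSE)
  }
  patients <- vapply(samples, function(s) s$patient_id, character(1))
  if (length(unique(patients)) != 1L) {
    stop("all samples must come from one patient", call. = FALSE)
  }
  labels <- names(samples)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(samples, function(s) s$sample_kind, character(1))
    labels <- make.unique(labels)
  }
  keys <- unique(keys)
  mat <- matrix(0, nrow = length(keys), ncol = length(samples),
                dimnames = list(keys, labels))
  for (j in seq_along(samples)) {
    skeys <- clonotype_keys(samples[[j]], recipe)
    freq <- tapply(samples[[j]]$clonotypes$frequency, skeys, sum)
    hit <- intersect(keys, names(freq))
    mat[hit, j] <- freq[hit]
  }
  structure(
    list(key_definition = recipe,
         clonotype_keys = keys,
         sample_order = labels,
         frequency_matrix = mat),
    class = "tracking_result"
  )
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("Clonotype tracking (%s key): %d clonotypes x %d samples\n",
              x$key_definition, length(x$clonotype_keys),
              length(x$sample_order)))
  invisible(x)
}

#' Tidy long-format view of a tracking result
#'
#' @param tracking A `tracking_result` from [track_clonotypes()].
#' @return A tibble with columns `key`, `sample`, `frequency`.
#' @export
as_tibble_tracking <- function(tracking) {
  stopifnot(inherits(tracking, "tracking_result"))
  m <- tracking$frequency_matrix
  tibble::tibble(
    key = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    frequency = as.vector(m)
  )
}

#' Specific-clonotype fraction report for one patient and chain
#'
#' Summarises, for the set of culture-called specific clonotypes, the summed
#' frequency they occupy in the baseline bone-marrow sample, the end-of-trial
#' bone-marrow sample, and the specific culture itself. Clonotypes absent
#' from a sample contribute exactly 0.
#'
#' @param specific_keys Identity keys from [specific_clonotype_set()].
#' @param baseline,end_of_trial,culture `repertoire_sample` objects sharing
#'   patient and locus.
#' @param recipe Identity-key recipe used to build `specific_keys`.
#' @return One-row tibble: `patient_id`, `locus`, `n_specific_clonotypes`,
#'   `fraction_in_baseline`, `fraction_in_end_of_trial`,
#'   `fraction_in_specific_sample` (all fractions in `[0, 1]`).
#' @export
specific_fraction_report <- function(specific_keys, baseline, end_of_trial,
                                     culture, recipe = "aa_v") {
  samples <- list(baseline = check_sample(baseline),
                  end_of_trial = check_sample(end_of_trial),
                  culture = check_sample(culture))
  loci <- vapply(samples, function(s) s$locus, character(1))
  pts <- vapply(samples, function(s) s$patient_id, character(1))
  if (length(unique(loci)) != 1L || length(unique(pts)) != 1L) {
    stop("baseline, end-of-trial and culture samples must share patient ",
         "and locus", call. = FALSE)
  }
  frac_in <- function(s) {
    keys <- clonotype_keys(s, recipe)
    sum(s$clonotypes$frequency[keys %in% specific_keys])
  }
  tibble::tibble(
    patient_id = pts[[1]],
    locus = loci[[1]],
    n_specific_clonotypes = length(unique(specific_keys)),
    fraction_in_baseline = frac_in(samples$baseline),
    fraction_in_end_of_trial = frac_in(samples$end_of_trial),
    fraction_in_specific_sample = frac_in(samples$culture)
  )
}

#' Format a fraction as a percentage string
#'
#' Three decimals with a dot separator, matching the per-patient report
#' style (e.g. `0.00022` becomes `"0.022%"`).
#'
#' @param x Numeric fraction(s) in `[0, 1]`.
#' @param digits Decimal places (default 3).
#' @return Character vector.
#' @export
format_percent <- function(x, digits = 3) {
  paste0(formatC(100 * x, format = "f", digits = digits), "%")
}
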