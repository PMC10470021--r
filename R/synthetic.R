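#' @keywords internal
# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

V_CATALOGUE <- paste0("TRV", 1:12)
J_CATALOGUE <- paste0("TRJ", 1:6)

# Random CDR3 amino-acid strings, unique, uniform length 8-20.
random_cdr3 <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(8:20, need, replace = TRUE)
    new <- vapply(lens, function(l)
      paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

#' Clone-size laws for the synthetic repertoire generator
#'
#' `power_law(exponent)` gives Zipf-type rank weights proportional to
#' `rank^-exponent`; `geometric_law(p)` gives weights `p * (1-p)^(rank-1)`.
#' Bulk T-cell repertoires are heavy-tailed, which the power law emulates.
#'
#' @param exponent Positive Zipf exponent (rank-frequency log-log slope is
#'   `-exponent` by construction).
#' @return A clone-size-law object used by [repertoire_scenario()].
#' @export
power_law <- function(exponent = 1.0) {
  stopifnot(is.numeric(exponent), exponent > 0)
  structure(list(type = "power_law", exponent = exponent),
            class = "clone_size_law")
}

#' @rdname power_law
#' @param p Geometric success probability in (0, 1).
#' @export
geometric_law <- function(p = 0.01) {
  stopifnot(is.numeric(p), p > 0, p < 1)
  structure(list(type = "geometric", p = p), class = "clone_size_law")
}

law_weights <- function(law, n) {
  w <- switch(law$type,
    power_law = seq_len(n)^(-law$exponent),
    geometric = law$p * (1 - law$p)^(seq_len(n) - 1)
  )
  w / sum(w)
}

#' Define a synthetic bulk-repertoire scenario
#'
#' Bundles the ground-truth parameters for one simulated bulk sample:
#' number of background clonotypes, their size law, sequencing depth, and
#' optional spike-in clonotypes injected at exact target frequencies (the
#' synthetic analogue of antigen-specific clones present at trace levels in
#' bone marrow).
#'
#' @param n_clonotypes Number of background clonotypes (>= 1).
#' @param law A [power_law()] or [geometric_law()] object.
#' @param read_depth Total reads drawn per sample (default 1e6, at which a
#'   0.022%-scale spike yields ~220 expected reads).
#' @param spike_ins Optional tibble with columns `cdr3_aa`, `v_call`,
#'   `target_frequency`; frequencies must sum to < 1.
#' @param seed Integer RNG seed; every generated sample is reproducible
#'   given the scenario seed.
#' @return A `repertoire_scenario` object.
#' @export
repertoire_scenario <- function(n_clonotypes = 5000, law = power_law(1.0),
                                read_depth = 1e6, spike_ins = NULL,
                                seed = 1L) {
  stopifnot(is.numeric(n_clonotypes), n_clonotypes >= 1,
            inherits(law, "clone_size_law"),
            is.numeric(read_depth), read_depth >= 1)
  if (!is.null(spike_ins)) {
    spike_ins <- tibble::as_tibble(spike_ins)
    need <- c("cdr3_aa", "target_frequency")
    if (!all(need %in% names(spike_ins))) {
      stop("spike_ins needs columns cdr3_aa and target_frequency",
           call. = FALSE)
    }
    if (!"v_call" %in% names(spike_ins)) {
      spike_ins$v_call <- V_CATALOGUE[[1]]
    }
    if (sum(spike_ins$target_frequency) >= 1) {
      stop("spike-in target frequencies must sum to < 1", call. = FALSE)
    }
  }
  structure(
    list(n_clonotypes = as.integer(n_clonotypes), law = law,
         read_depth = as.integer(read_depth), spike_ins = spike_ins,
         seed = as.integer(seed)),
    class = "repertoire_scenario"
  )
}

# Draw a repertoire_sample from explicit clone table + frequencies.
sample_reads <- function(clones, freqs, depth, patient_id, sample_kind,
                         locus) {
  counts <- as.vector(stats::rmultinom(1, depth, freqs))
  keep <- counts > 0
  repertoire_sample(
    tibble::tibble(
      cdr3_aa = clones$cdr3_aa[keep],
      v_call = clones$v_call[keep],
      j_call = clones$j_call[keep],
      read_count = counts[keep]
    ),
    patient_id = patient_id, sample_kind = sample_kind, locus = locus
  )
}

# Background clone table + normalized frequencies for a scenario,
# with spikes appended at their exact target frequencies.
scenario_pool <- function(scenario) {
  n <- scenario$n_clonotypes
  clones <- tibble::tibble(
    cdr3_aa = random_cdr3(n),
    v_call = sample(V_CATALOGUE, n, replace = TRUE),
    j_call = sample(J_CATALOGUE, n, replace = TRUE)
  )
  freqs <- law_weights(scenario$law, n)
  if (!is.null(scenario$spike_ins)) {
    spike_total <- sum(scenario$spike_ins$target_frequency)
    freqs <- freqs * (1 - spike_total)
    clones <- dplyr::bind_rows(
      clones,
      tibble::tibble(
        cdr3_aa = scenario$spike_ins$cdr3_aa,
        v_call = scenario$spike_ins$v_call,
        j_call = J_CATALOGUE[[1]]
      )
    )
    freqs <- c(freqs, scenario$spike_ins$target_frequency)
  }
  list(clones = clones, freqs = freqs)
}

#' Generate a synthetic bulk repertoire sample
#'
#' Read counts are drawn by multinomial sampling of the scenario's read
#' depth over the clone-size-law weights, with any spike-in clonotypes
#' injected at their exact target frequencies. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [repertoire_scenario()].
#' @param patient_id,sample_kind,locus Sample labels (see
#'   [repertoire_sample()]).
#' @return A `repertoire_sample` with attribute `ground_truth` (the
#'   scenario, including exact spike frequencies).
#' @export
generate_bulk_sample <- function(scenario, patient_id = "sim",
                                 sample_kind = "baseline_bm",
                                 locus = "beta") {
  stopifnot(inherits(scenario, "repertoire_scenario"))
  with_seed(scenario$seed, {
    pool <- scenario_pool(scenario)
    s <- sample_reads(pool$clones, pool$freqs, scenario$read_depth,
                      patient_id, sample_kind, locus)
    attr(s, "ground_truth") <- scenario
    s
  })
}

#' Generate paired baseline / end-of-trial bulk samples
#'
#' Emulates the longitudinal design of a vaccination trial: the end-of-trial
#' repertoire reuses a `retention` fraction of the baseline clonotypes
#' (counts independently resampled) plus novel clonotypes replacing the
#' rest, so baseline and follow-up overlap heavily when retention is high.
#' Scenario spike-ins are injected into the end-of-trial sample only
#' (the synthetic analogue of vaccine-induced clones appearing at trace
#' frequencies after the trial).
#'
#' @param scenario A [repertoire_scenario()].
#' @param retention Fraction of baseline clonotypes retained at end of
#'   trial, in `[0, 1]`.
#' @param patient_id,locus Sample labels.
#' @return List with elements `baseline` and `end_of_trial`
#'   (`repertoire_sample`s) plus `ground_truth` (retained key set, spike
#'   frequencies, retention).
#' @export
generate_paired_timepoints <- function(scenario, retention = 0.9,
                                       patient_id = "sim", locus = "beta") {
  stopifnot(inherits(scenario, "repertoire_scenario"),
            is.numeric(retention), retention >= 0, retention <= 1)
  base_scenario <- scenario
  base_scenario$spike_ins <- NULL
  with_seed(scenario$seed, {
    n <- scenario$n_clonotypes
    base_clones <- tibble::tibble(
      cdr3_aa = random_cdr3(n),
      v_call = sample(V_CATALOGUE, n, replace = TRUE),
      j_call = sample(J_CATALOGUE, n, replace = TRUE)
    )
    base_freqs <- law_weights(scenario$law, n)
    baseline <- sample_reads(base_clones, base_freqs, scenario$read_depth,
                             patient_id, "baseline_bm", locus)

    n_keep <- round(retention * n)
    keep_idx <- if (n_keep > 0) sample.int(n, n_keep) else integer(0)
    n_new <- n - n_keep
    eot_clones <- dplyr::bind_rows(
      base_clones[keep_idx, , drop = FALSE],
      if (n_new > 0) tibble::tibble(
        cdr3_aa = random_cdr3_avoiding(n_new, base_clones$cdr3_aa),
        v_call = sample(V_CATALOGUE, n_new, replace = TRUE),
        j_call = sample(J_CATALOGUE, n_new, replace = TRUE)
      )
    )
    # retained clones keep their baseline rank weights; novel clones draw
    # fresh weights from the same law, then everything renormalizes
    eot_freqs <- c(base_freqs[keep_idx],
                   if (n_new > 0) law_weights(scenario$law, n_new) *
                     (sum(base_freqs) - sum(base_freqs[keep_idx]) + 1e-12))
    eot_freqs <- eot_freqs / sum(eot_freqs)
    if (!is.null(scenario$spike_ins)) {
      spike_total <- sum(scenario$spike_ins$target_frequency)
      eot_freqs <- eot_freqs * (1 - spike_total)
      eot_clones <- dplyr::bind_rows(
        eot_clones,
        tibble::tibble(cdr3_aa = scenario$spike_ins$cdr3_aa,
                       v_call = scenario$spike_ins$v_call,
                       j_call = J_CATALOGUE[[1]])
      )
      eot_freqs <- c(eot_freqs, scenario$spike_ins$target_frequency)
    }
    end_of_trial <- sample_reads(eot_clones, eot_freqs,
                                 scenario$read_depth,
                                 patient_id, "end_of_trial_bm", locus)
    list(
      baseline = baseline,
      end_of_trial = end_of_trial,
      ground_truth = list(
        retention = retention,
        retained_cdr3 = base_clones$cdr3_aa[keep_idx],
        spike_ins = scenario$spike_ins
      )
    )
  })
}

random_cdr3_avoiding <- function(n, avoid) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_cdr3(n - length(out))
    out <- unique(c(out, setdiff(cand, avoid)))
  }
  out[seq_len(n)]
}

#' Generate a near-monoclonal specific-culture sample
#'
#' Emulates an antigen-enriched T-cell culture: a few dominant clonotypes
#' share `dominant_fraction` of the reads (equally), and `background_n`
#' low-frequency clonotypes (feeder-cell background) share the remainder.
#' With enough background clones each background clonotype sits below the
#' 1% culture threshold by construction.
#'
#' @param dominant_clones Tibble with columns `cdr3_aa`, `v_call` for the
#'   specific clonotypes.
#' @param dominant_fraction Total read fraction of the dominant clones, in
#'   `(0, 1]`.
#' @param background_n Number of background clonotypes.
#' @param read_depth Total reads (default 1e5).
#' @param patient_id,locus Sample labels.
#' @param seed Integer RNG seed.
#' @return A `repertoire_sample` of kind `"specific_culture"` with attribute
#'   `ground_truth`.
#' @export
generate_culture_sample <- function(dominant_clones, dominant_fraction,
                                    background_n = 100, read_depth = 1e5,
                                    patient_id = "sim", locus = "beta",
                                    seed = 1L) {
  dominant_clones <- tibble::as_tibble(dominant_clones)
  stopifnot(nrow(dominant_clones) >= 1,
            all(c("cdr3_aa", "v_call") %in% names(dominant_clones)),
            is.numeric(dominant_fraction),
            dominant_fraction > 0, dominant_fraction <= 1)
  if (dominant_fraction < 1 && background_n < 1) {
    stop("background_n must be >= 1 when dominant_fraction < 1",
         call. = FALSE)
  }
  n_dom <- nrow(dominant_clones)
  with_seed(seed, {
    bg_n <- if (dominant_fraction < 1) background_n else 0
    clones <- dplyr::bind_rows(
      tibble::tibble(cdr3_aa = dominant_clones$cdr3_aa,
                     v_call = dominant_clones$v_call,
                     j_call = J_CATALOGUE[[1]]),
      if (bg_n > 0) tibble::tibble(
        cdr3_aa = random_cdr3_avoiding(bg_n, dominant_clones$cdr3_aa),
        v_call = sample(V_CATALOGUE, bg_n, replace = TRUE),
        j_call = sample(J_CATALOGUE, bg_n, replace = TRUE)
      )
    )
    freqs <- c(rep(dominant_fraction / n_dom, n_dom),
               if (bg_n > 0) rep((1 - dominant_fraction) / bg_n, bg_n))
    s <- sample_reads(clones, freqs, read_depth, patient_id,
                      "specific_culture", locus)
    attr(s, "ground_truth") <- list(
      dominant_clones = dominant_clones,
      dominant_fraction = dominant_fraction,
      background_n = bg_n
    )
    s
  })
}

#' Generate a synthetic ELISPOT assay
#'
#' Replicate counts are Poisson: unstimulated (and target-alone, if
#' requested) wells at `rate_background`, stimulated wells at
#' `rate_background + rate_effect`. An effect of zero gives a null assay for
#' type-I-error studies.
#'
#' @param rate_background Background spot rate per well (>= 0).
#' @param rate_effect Additional rate in stimulated wells (>= 0).
#' @param replicates Wells per arm (default 3).
#' @param with_target_alone Also generate target-alone wells at the
#'   background rate (default `FALSE`).
#' @param condition Condition label.
#' @param seed Integer RNG seed.
#' @return An [elispot_assay()] with attribute `ground_truth`.
#' @export
generate_elispot <- function(rate_background, rate_effect, replicates = 3,
                             with_target_alone = FALSE,
                             condition = "sim", seed = 1L) {
  stopifnot(rate_background >= 0, rate_effect >= 0, replicates >= 2)
  with_seed(seed, {
    a <- elispot_assay(
      condition = condition,
      stimulated = stats::rpois(replicates, rate_background + rate_effect),
      unstimulated = stats::rpois(replicates, rate_background),
      target_alone = if (with_target_alone)
        stats::rpois(replicates, rate_background) else NULL
    )
    attr(a, "ground_truth") <- list(rate_background = rate_background,
                                    rate_effect = rate_effect)
    a
  })
}
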