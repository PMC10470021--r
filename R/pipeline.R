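#' Default configuration for a fully synthetic demonstration cohort
#'
#' Four patients, two chains each, at the scales seen in bulk bone-marrow
#' TCR sequencing: thousands of background clonotypes per sample, paired
#' baseline/end-of-trial samples with high repertoire overlap, a
#' near-monoclonal specific culture per patient/chain, and trace spike-ins
#' of culture clonotypes into the end-of-trial sample (order 0.01-0.05%).
#'
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param n_patients Number of simulated patients (default 4).
#' @param read_depth Bulk read depth (default 2e5; deep enough to recover
#'   0.02%-scale spikes with tens of reads).
#' @param n_clonotypes Background clonotypes per bulk sample (default 4000).
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, n_patients = 4, read_depth = 2e5,
                        n_clonotypes = 4000) {
  list(
    seed = as.integer(seed),
    min_reads = 2,
    min_fraction = 0.01,
    key_recipe = "aa_v",
    simulate = list(
      n_patients = n_patients,
      loci = c("alpha", "beta"),
      n_clonotypes = n_clonotypes,
      read_depth = read_depth,
      retention = 0.9,
      n_specific = 5,
      culture_dominant_fraction = 0.9,
      culture_background_n = 120,
      spike_frequency_total = 2.2e-4
    ),
    balance = list(vaf = 0.41, b = 1e-4, tau = "90 minutes"),
    elispot = list(
      conditions = list(
        list(condition = "peptide", rate_background = 5, rate_effect = 45),
        list(condition = "null", rate_background = 5, rate_effect = 0)
      ),
      multiplier = 2, alpha = 0.05, resamples = 10000
    )
  )
}

# Small deterministic integer hash (FNV-ish) of the serialized config,
# used to name immutable run directories; avoids timestamps so identical
# configs map to identical directories and byte-identical outputs.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (xor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> read filter -> specific-clonotype calling ->
#' tracking -> per-patient specific-fraction report -> balance-model sweeps
#' -> ELISPOT positivity calls, writing tidy TSV/CSV reports plus a
#' machine-readable JSON manifest into an immutable run directory.
#'
#' @param config A config list (see [demo_config()]) or path to a YAML file
#'   with the same structure.
#' @param out_dir Parent directory for the run directory.
#' @param overwrite Allow re-use of an existing run directory (default
#'   `FALSE`; runs are immutable).
#' @return Invisibly, a list with the run directory path, the per-patient
#'   report tibble, tracking results, sweep tibbles and ELISPOT call table.
#' @export
run_pipeline <- function(config, out_dir = tempdir(), overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$seed))
  if (config$min_reads < 1) stop("min_reads must be >= 1", call. = FALSE)
  if (config$min_fraction <= 0 || config$min_fraction >= 1) {
    stop("min_fraction must be in (0, 1)", call. = FALSE)
  }
  run_dir <- file.path(out_dir, paste0("run-", config_hash(config)))
  if (dir.exists(run_dir) && !overwrite) {
    stop("run directory already exists (runs are immutable): ", run_dir,
         call. = FALSE)
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- simulate_cohort(config)
  recipe <- config$key_recipe

  reports <- list(); trackings <- list()
  for (pc in cohort) {
    baseline <- filter_min_reads(pc$baseline, config$min_reads)
    eot <- filter_min_reads(pc$end_of_trial, config$min_reads)
    culture <- filter_min_reads(pc$culture, config$min_reads)
    specific <- specific_clonotype_set(culture, config$min_fraction,
                                       recipe = recipe)
    label <- paste(pc$patient_id, pc$locus, sep = "_")
    message(sprintf(
      "[%s] %d/%d/%d clonotypes (baseline/end-of-trial/culture), %d specific",
      label, count_clonotypes(baseline, recipe),
      count_clonotypes(eot, recipe), count_clonotypes(culture, recipe),
      length(specific)))
    reports[[label]] <- specific_fraction_report(
      specific, baseline, eot, culture, recipe = recipe)
    samples <- list(baseline = baseline, end_of_trial = eot,
                    culture = culture)
    top <- top_n_clonotypes(eot, 100, recipe = recipe)
    trackings[[label]] <- list(
      top100 = track_clonotypes(top, samples, recipe = recipe),
      specific = if (length(specific) > 0)
        track_clonotypes(specific, samples, recipe = recipe) else NULL
    )
  }
  report_tbl <- dplyr::bind_rows(reports)
  report_out <- report_tbl
  for (col in grep("^fraction_", names(report_out), value = TRUE)) {
    report_out[[paste0(col, "_pct")]] <- format_percent(report_out[[col]])
  }
  readr::write_tsv(report_out, file.path(run_dir, "specific_fractions.tsv"))

  track_long <- dplyr::bind_rows(lapply(names(trackings), function(lab) {
    t <- trackings[[lab]]
    dplyr::bind_rows(
      dplyr::mutate(as_tibble_tracking(t$top100), set = "top100",
                    sample_id = lab),
      if (!is.null(t$specific))
        dplyr::mutate(as_tibble_tracking(t$specific), set = "specific",
                      sample_id = lab)
    )
  }))
  readr::write_tsv(track_long, file.path(run_dir, "tracking_long.tsv"))

  params <- balance_params(
    vaf = config$balance$vaf, b = config$balance$b,
    tau = parse_duration(config$balance$tau), tau_unit = "days")
  sweeps <- dplyr::bind_rows(
    as_tibble_sweep(balance_sweep(
      params, "kills", "vaf", seq(0, 0.5, by = 0.05),
      "b", 10^(-(1:5)))),
    as_tibble_sweep(balance_sweep(
      params, "total_time", "vaf", seq(0.005, 0.5, by = 0.045),
      "b", 10^(-(1:5)))),
    as_tibble_sweep(balance_sweep(
      params, "max_vaf", "tau",
      to_days(c(30, 60, 90, 240, 720), "minutes"), "b", 10^(-(1:5))))
  )
  readr::write_csv(sweeps, file.path(run_dir, "balance_sweeps.csv"))

  es <- config$elispot
  assays <- lapply(seq_along(es$conditions), function(i) {
    cc <- es$conditions[[i]]
    generate_elispot(cc$rate_background, cc$rate_effect,
                     condition = cc$condition,
                     seed = config$seed + 7000L + i)
  })
  calls <- elispot_call_table(assays, multiplier = es$multiplier,
                              alpha = es$alpha, resamples = es$resamples,
                              seed = config$seed + 7999L)
  readr::write_csv(calls, file.path(run_dir, "elispot_calls.csv"))

  manifest <- list(
    package = "tcrbalance",
    version = as.character(utils::packageVersion("tcrbalance")),
    seed = config$seed,
    key_recipe = recipe,
    min_reads = config$min_reads,
    min_fraction = config$min_fraction,
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(run_dir = run_dir, report = report_tbl,
                 trackings = trackings, sweeps = sweeps,
                 elispot_calls = calls))
}

# Simulate the cohort described by config$simulate: per patient and chain,
# paired bulk timepoints plus a culture whose dominant clones are spiked
# into the end-of-trial sample at trace frequency.
simulate_cohort <- function(config) {
  sim <- config$simulate
  if (is.null(sim)) stop("config$simulate must be specified", call. = FALSE)
  cohort <- list()
  idx <- 0L
  for (p in seq_len(sim$n_patients)) {
    for (locus in sim$loci) {
      idx <- idx + 1L
      seed_i <- config$seed + 100L * idx
      n_spec <- sim$n_specific
      spec_clones <- with_seed(seed_i + 1L, tibble::tibble(
        cdr3_aa = random_cdr3(n_spec),
        v_call = sample(V_CATALOGUE, n_spec, replace = TRUE)
      ))
      spikes <- tibble::tibble(
        cdr3_aa = spec_clones$cdr3_aa,
        v_call = spec_clones$v_call,
        target_frequency = rep(sim$spike_frequency_total / n_spec, n_spec)
      )
      scen <- repertoire_scenario(
        n_clonotypes = sim$n_clonotypes, law = power_law(1.0),
        read_depth = sim$read_depth, spike_ins = spikes,
        seed = seed_i + 2L)
      pair <- generate_paired_timepoints(scen, retention = sim$retention,
                                         patient_id = paste0("P", p),
                                         locus = locus)
      culture <- generate_culture_sample(
        spec_clones, sim$culture_dominant_fraction,
        background_n = sim$culture_background_n,
        patient_id = paste0("P", p), locus = locus, seed = seed_i + 3L)
      cohort[[idx]] <- list(
        patient_id = paste0("P", p), locus = locus,
        baseline = pair$baseline, end_of_trial = pair$end_of_trial,
        culture = culture, ground_truth = pair$ground_truth)
    }
  }
  cohort
}

#' Run the synthetic demonstration cohort end-to-end
#'
#' @param out_dir Parent directory for the run directory.
#' @param seed Integer master seed.
#' @param ... Passed to [demo_config()].
#' @return See [run_pipeline()].
#' @export
run_demo <- function(out_dir = tempdir(), seed = 1L, ...) {
  run_pipeline(demo_config(seed = seed, ...), out_dir = out_dir)
}
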