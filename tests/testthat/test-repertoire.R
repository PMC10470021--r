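test_that("duplicate clonotype rows merge by summing read counts", {
  tab <- tibble::tibble(cdr3_aa = c("CASSF", "CASSF", "CASRF"),
                        read_count = c(5, 3, 2))
  s <- repertoire_sample(tab, "P1", "baseline_bm", "alpha")
  expect_equal(nrow(s$clonotypes), 2)
  expect_equal(s$clonotypes$read_count[s$clonotypes$cdr3_aa == "CASSF"], 8L)
  expect_equal(sum(s$clonotypes$frequency), 1, tolerance = 1e-9)
})

test_that("clonotype validation rejects bad CDR3s and read counts", {
  expect_error(repertoire_sample(
    tibble::tibble(cdr3_aa = "CAS*F", read_count = 3),
    "P1", "baseline_bm", "alpha"), "non-amino-acid")
  expect_no_error(repertoire_sample(
    tibble::tibble(cdr3_aa = "CAS*F", read_count = 3),
    "P1", "baseline_bm", "alpha", strict_aa = FALSE))
  expect_error(repertoire_sample(
    tibble::tibble(cdr3_aa = "CASSF", read_count = 0),
    "P1", "baseline_bm", "alpha"), "read_count")
  expect_error(repertoire_sample(
    tibble::tibble(cdr3_aa = character(0), read_count = integer(0)),
    "P1", "baseline_bm", "alpha"), "empty sample")
})

test_that("AIRR dialect reader selects the requested chain", {
  df <- tibble::tibble(
    locus = rep(c("TRA", "TRB"), each = 10),
    junction_aa = paste0("CA", aa_letters, "F"),
    duplicate_count = 2:21,
    v_call = "TRV1", j_call = "TRJ1"
  )
  path <- write_airr_tsv(df)
  expect_message(
    s <- read_repertoire(path, "airr", "P1", "baseline_bm", "alpha"),
    "ignored")
  expect_equal(nrow(s$clonotypes), 10)
  expect_equal(s$total_reads, sum(2:11))
})

test_that("minimal dialect reader maps cdr3_aa/reads columns", {
  path <- write_minimal_tsv(tibble::tibble(
    cdr3_aa = c("CASSF", "CASSF", "CASRF"), reads = c(5, 3, 2),
    v_call = "TRV2"))
  s <- read_repertoire(path, "minimal", "P1", "end_of_trial_bm", "beta")
  expect_equal(nrow(s$clonotypes), 2)
  expect_equal(s$clonotypes$read_count[s$clonotypes$cdr3_aa == "CASSF"], 8L)
})

test_that("reader errors name missing columns and reject header-only files", {
  path <- write_minimal_tsv(tibble::tibble(cdr3_aa = "CASSF", other = 1))
  expect_error(read_repertoire(path, "minimal", "P1", "baseline_bm",
                               "alpha"), "reads")
  empty <- write_minimal_tsv(tibble::tibble(cdr3_aa = character(0),
                                            reads = numeric(0)))
  expect_error(read_repertoire(empty, "minimal", "P1", "baseline_bm",
                               "alpha"), "empty sample")
  airr_empty <- write_airr_tsv(tibble::tibble(
    locus = "TRB", junction_aa = "CASSF", duplicate_count = 5))
  expect_error(read_repertoire(airr_empty, "airr", "P1", "baseline_bm",
                               "alpha"), "empty sample")
})

test_that("read filter removes singletons and renormalizes frequencies", {
  s <- toy_sample(c(5, 3, 1))
  f <- filter_min_reads(s)
  expect_equal(sort(f$clonotypes$read_count), c(3L, 5L))
  expect_equal(sort(f$clonotypes$frequency), c(3 / 8, 5 / 8))
  expect_equal(sum(f$clonotypes$frequency), 1, tolerance = 1e-9)

  keep_denominator <- filter_min_reads(s, renormalize = FALSE)
  expect_equal(sort(keep_denominator$clonotypes$frequency), c(3 / 9, 5 / 9))

  expect_error(filter_min_reads(toy_sample(c(1, 1, 1))), "empty sample")
  identity <- filter_min_reads(s, min_reads = 1)
  expect_equal(identity$clonotypes, s$clonotypes)
  # boundary: exactly 2 reads is retained
  f2 <- filter_min_reads(toy_sample(c(2, 1)))
  expect_equal(f2$clonotypes$read_count, 2L)
  # idempotence
  expect_equal(filter_min_reads(f)$clonotypes, f$clonotypes)
})

test_that("specific clonotypes are called at the 1% culture threshold", {
  s <- toy_sample(c(950, 30, 5), sample_kind = "specific_culture")
  keys <- specific_clonotype_set(s, 0.01)
  expect_length(keys, 2)
  ranks <- attr(keys, "ranks")
  expect_equal(ranks$rank, c(1, 2))

  # frequency exactly 1% is retained (strictly-below is excluded)
  boundary <- toy_sample(c(99, 1), sample_kind = "specific_culture")
  expect_length(specific_clonotype_set(boundary, 0.01), 2)

  expect_warning(
    none <- specific_clonotype_set(
      toy_sample(rep(1, 200), sample_kind = "specific_culture"), 0.01),
    "threshold")
  expect_length(none, 0)

  expect_error(specific_clonotype_set(toy_sample(c(5, 5)), 0.01),
               "specific_culture")
})

test_that("clonotype counting respects identity-key coarseness", {
  s <- toy_sample(c(4, 3, 2), v_call = c("TRV1", "TRV2", "TRV1"))
  expect_equal(count_clonotypes(s), 3)
  # same CDR3 under different V genes merges under the aa-only key
  tab <- tibble::tibble(cdr3_aa = c("CASSF", "CASSF"),
                        v_call = c("TRV1", "TRV2"), read_count = c(4, 3))
  s2 <- repertoire_sample(tab, "P1", "baseline_bm", "alpha")
  expect_equal(count_clonotypes(s2, "aa_v"), 2)
  expect_equal(count_clonotypes(s2, "aa"), 1)
  expect_lte(count_clonotypes(s2, "aa"), count_clonotypes(s2, "aa_v"))
})

test_that("top-n selection is deterministic under ties", {
  s <- toy_sample(c(5, 3, 2))
  expect_length(top_n_clonotypes(s, 100), 3)
  expect_equal(top_n_clonotypes(s, 1), clonotype_keys(s)[1])
  ties <- toy_sample(c(3, 3, 3))
  expect_equal(top_n_clonotypes(ties, 2),
               sort(clonotype_keys(ties))[1:2])   # lexicographic tie-break
  expect_error(top_n_clonotypes(s, 0), "'n'")
})

test_that("tracking builds a keys-by-samples frequency matrix with 0 for absent", {
  base <- repertoire_sample(
    tibble::tibble(cdr3_aa = c("CAAAF", "CAADF"), read_count = c(2, 98)),
    "P1", "baseline_bm", "alpha")
  eot <- repertoire_sample(
    tibble::tibble(cdr3_aa = c("CAADF", "CAACF"), read_count = c(60, 40)),
    "P1", "end_of_trial_bm", "alpha")
  tr <- track_clonotypes(clonotype_keys(base)[base$clonotypes$cdr3_aa ==
                                                "CAAAF"],
                         list(baseline = base, end_of_trial = eot))
  expect_equal(as.vector(tr$frequency_matrix), c(0.02, 0))

  full <- track_clonotypes(clonotype_keys(base), list(base, eot))
  expect_true(all(colSums(full$frequency_matrix) <= 1 + 1e-9))

  beta <- repertoire_sample(
    tibble::tibble(cdr3_aa = "CAAAF", read_count = 5),
    "P1", "baseline_bm", "beta")
  expect_error(track_clonotypes("k", list(base, beta)), "locus")
  expect_error(track_clonotypes(character(0), list(base)), "non-empty")
})

test_that("specific-fraction report sums frequencies of specific keys", {
  culture <- toy_sample(c(95, 5), sample_kind = "specific_culture")
  base <- toy_sample(c(10, 10, 80))
  eot <- toy_sample(c(20, 30, 50), sample_kind = "end_of_trial_bm")
  keys <- specific_clonotype_set(culture, 0.01)
  rep <- specific_fraction_report(keys, base, eot, culture)
  expect_equal(rep$n_specific_clonotypes, 2)
  expect_equal(rep$fraction_in_specific_sample, 1)   # both retained
  # toy samples share CDR3 prefixes, so the first two keys are present
  expect_equal(rep$fraction_in_baseline, 0.2)
  expect_equal(rep$fraction_in_end_of_trial, 0.5)

  none <- specific_fraction_report(character(0), base, eot, culture)
  expect_equal(none$fraction_in_baseline, 0)
  expect_equal(none$fraction_in_end_of_trial, 0)
  expect_equal(none$fraction_in_specific_sample, 0)

  other <- toy_sample(c(5), patient_id = "P2")
  expect_error(specific_fraction_report(keys, other, eot, culture),
               "share patient")
})

test_that("percent formatting uses three decimals and a dot", {
  expect_equal(format_percent(0.00022), "0.022%")
  expect_equal(format_percent(0.89011), "89.011%")
  expect_equal(format_percent(0), "0.000%")
})
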