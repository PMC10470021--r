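#' Construct an ELISPOT assay
#'
#' Holds replicate spot counts for one condition: wells with stimulated
#' effector T cells, wells with unstimulated effectors (negative control),
#' and — when the stimulus is a target-cell population rather than peptide —
#' wells with the target cells plated alone, whose background cytokine
#' activity is also subtracted.
#'
#' @param condition Condition label (e.g. `"monocytes"`, `"peptide"`).
#' @param stimulated Integer vector of spot counts, typically triplicate.
#' @param unstimulated Integer vector of spot counts.
#' @param target_alone Optional integer vector of spot counts for
#'   target-cells-alone wells.
#' @param cells_per_well Effector cells plated per well (default 1e5).
#' @return An `elispot_assay` object.
#' @export
elispot_assay <- function(condition, stimulated, unstimulated,
                          target_alone = NULL, cells_per_well = 1e5) {
  check_counts <- function(x, arm) {
    if (length(x) == 0L || !is.numeric(x) || any(!is.finite(x)) ||
        any(x < 0)) {
      stop("'", arm, "' must be a non-empty vector of counts >= 0",
           call. = FALSE)
    }
  }
  check_counts(stimulated, "stimulated")
  check_counts(unstimulated, "unstimulated")
  if (!is.null(target_alone)) check_counts(target_alone, "target_alone")
  if (!is.numeric(cells_per_well) || cells_per_well <= 0) {
    stop("'cells_per_well' must be > 0", call. = FALSE)
  }
  structure(
    list(condition = as.character(condition),
         stimulated = as.numeric(stimulated),
         unstimulated = as.numeric(unstimulated),
         target_alone = if (is.null(target_alone)) NULL else
           as.numeric(target_alone),
         cells_per_well = cells_per_well),
    class = "elispot_assay"
  )
}

#' @export
print.elispot_assay <- function(x, ...) {
  cat(sprintf("ELISPOT assay '%s': stim (%s) vs unstim (%s)%s\n",
              x$condition,
              paste(x$stimulated, collapse = ","),
              paste(x$unstimulated, collapse = ","),
              if (is.null(x$target_alone)) "" else
                paste0(" minus targets (",
                       paste(x$target_alone, collapse = ","), ")")))
  invisible(x)
}

check_assay <- function(x) {
  if (!inherits(x, "elispot_assay")) {
    stop("expected an 'elispot_assay' object", call. = FALSE)
  }
  x
}

#' Normalized spot count
#'
#' Mean stimulated count minus mean unstimulated count, additionally minus
#' the mean target-alone count when those wells are present. The raw value
#' can be negative; reports floor it at zero while retaining the raw value
#' for audit.
#'
#' @param assay An [elispot_assay()].
#' @param floor Floor negative values at 0 (default `TRUE`); the unfloored
#'   value is attached as attribute `raw`.
#' @return Normalized count (numeric scalar).
#' @export
normalized_count <- function(assay, floor = TRUE) {
  assay <- check_assay(assay)
  raw <- mean(assay$stimulated) - mean(assay$unstimulated) -
    if (is.null(assay$target_alone)) 0 else mean(assay$target_alone)
  if (!floor) return(raw)
  out <- max(raw, 0)
  attr(out, "raw") <- raw
  out
}

# Permutation engine for the distribution-free resampling test.
# Controls are scaled by `multiplier` (DFR2x scales by 2), the scaled pool
# is re-split into stimulated/control arms in every way (exhaustive) or by
# Monte-Carlo sampling, and the one-sided p-value is the fraction of splits
# whose mean difference reaches the observed one.
dfr_pvalue <- function(stim, ctrl, multiplier, resamples, seed,
                       mode = "auto", exhaustive_limit = 1e6) {
  ctrl <- multiplier * ctrl
  n1 <- length(stim)
  pool <- c(stim, ctrl)
  n <- length(pool)
  obs <- mean(stim) - mean(ctrl)
  eps <- 1e-9 * (1 + abs(obs))
  n_comb <- choose(n, n1)
  use_exhaustive <- switch(mode,
    auto = n_comb <= exhaustive_limit,
    exhaustive = TRUE,
    monte_carlo = FALSE
  )
  if (use_exhaustive) {
    idx <- utils::combn(n, n1)
    stat <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
    p <- mean(stat >= obs - eps)
    list(p = p, method_detail = "exhaustive", n_resamples = n_comb)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    hits <- 0L
    for (r in seq_len(resamples)) {
      i <- sample.int(n, n1)
      if (mean(pool[i]) - mean(pool[-i]) >= obs - eps) hits <- hits + 1L
    }
    p <- (hits + 1) / (resamples + 1)
    list(p = p, method_detail = "monte_carlo", n_resamples = resamples)
  }
}

#' Distribution-free resampling (DFR) positivity test
#'
#' One-sided permutation test of whether antigen-stimulated wells exceed
#' control wells: H0 is that stimulated counts do not exceed `multiplier`
#' times the control level. With `multiplier = 2` this is the conservative
#' DFR2x variant, which demands the stimulated signal beat twice the
#' background. Control counts are scaled by the multiplier, well labels are
#' permuted within the pooled counts, and the p-value is the fraction of
#' label permutations whose stimulated-minus-control mean difference reaches
#' the observed one. For small replicate numbers (permutation space up to
#' 1e6 splits) the full permutation set is enumerated, which is
#' deterministic; larger designs fall back to Monte-Carlo resampling with a
#' recorded seed.
#'
#' @param assay An [elispot_assay()], or `NULL` when `stimulated` and
#'   `control` vectors are given directly.
#' @param multiplier 1 (DFR) or 2 (DFR2x).
#' @param alpha Significance level for the positivity call (default 0.05).
#' @param resamples Monte-Carlo resamples when enumeration is infeasible
#'   (default 10000).
#' @param seed Seed for the Monte-Carlo fallback (default 20211).
#' @param stimulated,control Optional explicit replicate vectors overriding
#'   the assay's arms (e.g. to test normalized rather than raw counts).
#' @param mode `"auto"` (enumerate when the permutation space is at most
#'   1e6 splits, else Monte-Carlo), `"exhaustive"` or `"monte_carlo"`.
#' @param control_arm When taking arms from the assay, which wells serve as
#'   control: `"unstimulated"` (default) or `"target_alone"`.
#' @return A `positivity_call`: list with `condition`, `normalized_count`,
#'   `raw_normalized_count`, `p_value`, `is_response`, `method`
#'   (`"DFR"`/`"DFR2x"`), `method_detail`, `alpha`, `n_resamples`.
#' @examples
#' a <- elispot_assay("peptide", c(100, 110, 90), c(2, 3, 1))
#' dfr_test(a, multiplier = 2)
#' @export
dfr_test <- function(assay = NULL, multiplier = 1, alpha = 0.05,
                     resamples = 10000, seed = 20211,
                     stimulated = NULL, control = NULL,
                     control_arm = c("unstimulated", "target_alone"),
                     mode = c("auto", "exhaustive", "monte_carlo")) {
  mode <- match.arg(mode)
  if (!multiplier %in% c(1, 2)) {
    stop("'multiplier' must be 1 (DFR) or 2 (DFR2x)", call. = FALSE)
  }
  control_arm <- match.arg(control_arm)
  condition <- NA_character_
  norm <- NA_real_
  raw_norm <- NA_real_
  if (is.null(stimulated) || is.null(control)) {
    assay <- check_assay(assay)
    stimulated <- assay$stimulated
    control <- if (control_arm == "unstimulated") assay$unstimulated else {
      if (is.null(assay$target_alone)) {
        stop("assay has no target_alone wells", call. = FALSE)
      }
      assay$target_alone
    }
    condition <- assay$condition
    norm <- normalized_count(assay)
    raw_norm <- attr(norm, "raw")
    norm <- as.numeric(norm)
  }
  if (length(stimulated) < 2L || length(control) < 2L) {
    stop("at least 2 replicates per arm are required", call. = FALSE)
  }
  res <- dfr_pvalue(stimulated, control, multiplier, resamples, seed,
                    mode = mode)
  structure(
    list(condition = condition,
         normalized_count = norm,
         raw_normalized_count = raw_norm,
         p_value = res$p,
         is_response = res$p <= alpha,
         method = if (multiplier == 2) "DFR2x" else "DFR",
         method_detail = res$method_detail,
         alpha = alpha,
         n_resamples = res$n_resamples),
    class = "positivity_call"
  )
}

#' @export
print.positivity_call <- function(x, ...) {
  cat(sprintf("%s (%s): p = %.4g -> %s at alpha = %g\n",
              x$method, x$method_detail, x$p_value,
              if (x$is_response) "response" else "no response", x$alpha))
  invisible(x)
}

#' Read ELISPOT assays from a well-level CSV
#'
#' Expects one row per well with columns `condition`, `arm` (one of
#' `stimulated`, `unstimulated`, `target_alone`), `count`, and optionally
#' `cells_per_well`.
#'
#' @param path Path to a CSV file.
#' @return Named list of [elispot_assay()] objects, one per condition.
#' @export
read_elispot_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("condition", "arm", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("ELISPOT CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conds <- unique(df$condition)
  out <- lapply(conds, function(cond) {
    sub <- df[df$condition == cond, , drop = FALSE]
    grab <- function(arm) sub$count[sub$arm == arm]
    ta <- grab("target_alone")
    elispot_assay(
      condition = cond,
      stimulated = grab("stimulated"),
      unstimulated = grab("unstimulated"),
      target_alone = if (length(ta) > 0) ta else NULL,
      cells_per_well = if ("cells_per_well" %in% names(sub))
        sub$cells_per_well[[1]] else 1e5
    )
  })
  stats::setNames(out, conds)
}

#' Positivity calls for a list of assays, as a tidy table
#'
#' @param assays List of [elispot_assay()] objects.
#' @param multiplier,alpha,resamples,seed Passed to [dfr_test()].
#' @return Tibble with one row per condition: `condition`,
#'   `normalized_count`, `p_value`, `method`, `is_response`.
#' @export
elispot_call_table <- function(assays, multiplier = 2, alpha = 0.05,
                               resamples = 10000, seed = 20211) {
  rows <- lapply(assays, function(a) {
    call <- dfr_test(a, multiplier = multiplier, alpha = alpha,
                     resamples = resamples, seed = seed)
    tibble::tibble(
      condition = call$condition,
      normalized_count = call$normalized_count,
      p_value = call$p_value,
      method = call$method,
      is_response = call$is_response
    )
  })
  dplyr::bind_rows(rows)
}
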