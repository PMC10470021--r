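#' Time-unit conversion to days
#'
#' The balance model works internally in days, but per-kill times are
#' naturally quoted in minutes or hours. `to_days()` converts a duration to
#' days; it is the single conversion point so that 90 minutes, 1.5 hours and
#' 0.0625 days are guaranteed to give identical model outputs.
#'
#' @param x Numeric duration(s), non-negative.
#' @param unit One of `"days"`, `"hours"`, `"minutes"`.
#' @return Numeric duration in days.
#' @examples
#' to_days(90, "minutes")  # 0.0625
#' @export
to_days <- function(x, unit = c("days", "hours", "minutes")) {
  unit <- match.arg(unit)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("duration must be finite and non-negative", call. = FALSE)
  }
  switch(unit,
    days    = x,
    hours   = x / 24,
    minutes = x / (24 * 60)
  )
}

#' Parameters of the effector-target balance model
#'
#' Bundles the cell-count and kinetic constants of the closed-form balance
#' between mutant myeloid cells and neoantigen-specific effector T cells in
#' peripheral blood. Defaults are literature estimates of total-body cell
#' numbers and turnover: `N = 6e11` neutrophils with a 6.6-day lifetime,
#' `M = 1e10` monocytes with a 3.5-day lifetime, and `T = 7e11` T cells.
#'
#' The mutation is heterozygous, so a variant allele fraction `vaf` implies a
#' mutant-cell fraction of `2 * vaf`; `vaf > 0.5` is therefore rejected.
#' `b` is the fraction of the T-cell pool specific for the neoantigen and
#' `tau` the time one effector needs to complete one kill (serial killing
#' with constant per-kill time).
#'
#' @param N Total neutrophil count (cells), > 0.
#' @param M Total monocyte count (cells), > 0.
#' @param T Total T-cell count (cells), > 0.
#' @param neutrophil_lifetime Neutrophil lifetime in days, > 0. This is the
#'   dominant self-renewal time of the transformed compartment and the bound
#'   used by the eradication criterion.
#' @param monocyte_lifetime Monocyte lifetime in days, > 0. Stored for
#'   completeness; the eradication criterion uses the neutrophil lifetime.
#' @param vaf Variant allele fraction in `[0, 0.5]`.
#' @param b Specific fraction of the T-cell pool, in `(0, 1]`.
#' @param tau Per-kill time, > 0, in the unit given by `tau_unit`.
#' @param tau_unit Unit of `tau`; converted to days internally.
#' @return A `balance_params` object (named list, `tau` in days).
#' @examples
#' p <- balance_params(vaf = 0.40, b = 1e-4, tau = 90, tau_unit = "minutes")
#' kills_per_effector(p)
#' @export
balance_params <- function(N = 6e11, M = 1e10, T = 7e11,
                           neutrophil_lifetime = 6.6,
                           monocyte_lifetime = 3.5,
                           vaf = 0.41, b = 1e-4,
                           tau = 90, tau_unit = "minutes") {
  check_pos <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
        value <= 0) {
      stop(sprintf("'%s' must be a single finite number > 0", field),
           call. = FALSE)
    }
  }
  check_pos(N, "N"); check_pos(M, "M"); check_pos(T, "T")
  check_pos(neutrophil_lifetime, "neutrophil_lifetime")
  check_pos(monocyte_lifetime, "monocyte_lifetime")
  if (!is.numeric(vaf) || length(vaf) != 1L || !is.finite(vaf) ||
      vaf < 0 || vaf > 0.5) {
    stop("'vaf' must be in [0, 0.5]: a heterozygous mutation implies ",
         "a mutant-cell fraction of 2*vaf <= 1", call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0 || b > 1) {
    stop("'b' must be in (0, 1]", call. = FALSE)
  }
  check_pos(tau, "tau")
  structure(
    list(
      N = N, M = M, T = T,
      neutrophil_lifetime = neutrophil_lifetime,
      monocyte_lifetime = monocyte_lifetime,
      vaf = vaf, b = b,
      tau = to_days(tau, tau_unit)
    ),
    class = "balance_params"
  )
}

#' @export
print.balance_params <- function(x, ...) {
  cat("Effector-target balance parameters\n")
  cat(sprintf("  N (neutrophils): %.3g cells, lifetime %.3g d\n",
              x$N, x$neutrophil_lifetime))
  cat(sprintf("  M (monocytes):   %.3g cells, lifetime %.3g d\n",
              x$M, x$monocyte_lifetime))
  cat(sprintf("  T (T cells):     %.3g cells\n", x$T))
  cat(sprintf("  vaf = %.3g, b = %.3g, tau = %.4g d\n", x$vaf, x$b, x$tau))
  invisible(x)
}

check_params <- function(params) {
  if (!inherits(params, "balance_params")) {
    stop("'params' must be created by balance_params()", call. = FALSE)
  }
  params
}

#' Total mutant-cell burden in peripheral blood
#'
#' The tumor burden is the mutant fraction of the neutrophil plus monocyte
#' pool. Because the driver mutation is heterozygous, the mutant-cell
#' fraction is twice the variant allele fraction: `2 * (N + M) * vaf`.
#'
#' @param params A [balance_params()] object.
#' @return Mutant cell count.
#' @export
tumor_burden <- function(params) {
  params <- check_params(params)
  2 * (params$N + params$M) * params$vaf
}

#' Neoantigen-specific effector pool
#'
#' The specific effector pool is the fraction `b` of the total T-cell pool:
#' `b * T`.
#'
#' @inheritParams tumor_burden
#' @return Specific T-cell count.
#' @export
effector_pool <- function(params) {
  params <- check_params(params)
  params$b * params$T
}

#' Kills required per specific effector T cell
#'
#' Number of target cells each specific T cell must kill to eliminate the
#' mutant burden: `2 * (N + M) * vaf / (b * T)`. Returned unrounded; at the
#' default pool sizes with `vaf = 0.40` and `b = 1e-4` this is about 6971,
#' i.e. on the order of 7000 kills per effector.
#'
#' @inheritParams tumor_burden
#' @return Kills per effector (dimensionless).
#' @export
kills_per_effector <- function(params) {
  params <- check_params(params)
  tumor_burden(params) / effector_pool(params)
}

#' Total time to eliminate the mutant burden
#'
#' Under serial killing with constant per-kill time `tau`, every effector
#' works through its share of targets sequentially, so the total kill time is
#' `tau * kills_per_effector = 2 * tau * (N + M) * vaf / (b * T)` days.
#'
#' @inheritParams tumor_burden
#' @return Duration in days.
#' @export
total_kill_time <- function(params) {
  params <- check_params(params)
  params$tau * kills_per_effector(params)
}

#' Can the specific T cells eradicate the mutant clone?
#'
#' Transformed neutrophils self-renew with a characteristic lifetime, so the
#' effectors only win if they clear the burden faster than it is replaced:
#' eradication requires `total_kill_time <= neutrophil_lifetime` (6.6 days by
#' default, the dominant self-renewal time of the transformed compartment).
#'
#' @inheritParams tumor_burden
#' @return `TRUE` if the burden can be eradicated before it self-renews.
#' @export
is_eradicable <- function(params) {
  params <- check_params(params)
  total_kill_time(params) <= params$neutrophil_lifetime
}

#' Maximal variant allele fraction controllable by cellular immunity
#'
#' Inverting the eradication criterion for the VAF gives the largest burden
#' the effector pool can keep up with:
#' `vaf <= lifetime * b * T / (2 * tau * (N + M))`.
#' The `vaf` field of `params` is ignored. The value is deliberately not
#' clamped: a result above 0.5 means any biologically possible VAF is
#' controllable (use [clamp_vaf()] for display).
#'
#' @inheritParams tumor_burden
#' @return Maximal controllable VAF (dimensionless, unclamped).
#' @export
max_controllable_vaf <- function(params) {
  params <- check_params(params)
  params$neutrophil_lifetime * params$b * params$T /
    (2 * params$tau * (params$N + params$M))
}

#' Clamp a VAF to the biologically possible range for display
#'
#' @param vaf Numeric VAF value(s), e.g. from [max_controllable_vaf()].
#' @return Values clamped to `[0, 0.5]`, with attribute `clamped` flagging
#'   which entries exceeded the heterozygous bound.
#' @export
clamp_vaf <- function(vaf) {
  clamped <- vaf > 0.5
  out <- pmin(pmax(vaf, 0), 0.5)
  attr(out, "clamped") <- clamped
  out
}

#' Estimate the specific T-cell fraction b from an ex vivo ELISPOT
#'
#' The fraction of the T-cell pool specific for the neoantigen can be
#' estimated directly from an ex vivo ELISPOT as spots per assayed cell. The
#' raw ratio is usually reported to its order of magnitude (e.g. 45 spots in
#' 6e5 cells gives 7.5e-5, quoted as 1e-4).
#'
#' @param spots Spot count (>= 0).
#' @param assayed_cells Number of cells assayed (> 0).
#' @return A list with `raw` (spots/assayed_cells) and `magnitude`
#'   (`10^round(log10(raw))`; `NA` with a warning when `spots == 0`, where
#'   the order of magnitude is undefined).
#' @examples
#' estimate_b_from_elispot(45, 6e5)
#' @export
estimate_b_from_elispot <- function(spots, assayed_cells) {
  if (!is.numeric(assayed_cells) || length(assayed_cells) != 1L ||
      !is.finite(assayed_cells) || assayed_cells <= 0) {
    stop("'assayed_cells' must be a single number > 0", call. = FALSE)
  }
  if (!is.numeric(spots) || length(spots) != 1L || !is.finite(spots) ||
      spots < 0) {
    stop("'spots' must be a single number >= 0", call. = FALSE)
  }
  if (spots > assayed_cells) {
    stop("'spots' cannot exceed 'assayed_cells'", call. = FALSE)
  }
  raw <- spots / assayed_cells
  if (raw == 0) {
    warning("zero spots: order-of-magnitude estimate undefined",
            call. = FALSE)
    magnitude <- NA_real_
  } else {
    magnitude <- 10^round(log10(raw))
  }
  list(raw = raw, magnitude = magnitude)
}

#' Parameter sweep over the balance model
#'
#' Evaluates one model output over a grid: an axis (the quantity varied along
#' columns) crossed with a series (one row per value, e.g. curves for
#' several specific fractions `b`). Every cell is an independent scalar
#' evaluation with the remaining fields taken from `params`.
#'
#' @param params Baseline [balance_params()]; swept fields are substituted.
#' @param output One of `"kills"` ([kills_per_effector()]), `"total_time"`
#'   ([total_kill_time()]), `"max_vaf"` ([max_controllable_vaf()]).
#' @param axis_name Field swept along columns: `"vaf"`, `"tau"` or `"b"`.
#' @param axis_values Strictly increasing numeric vector.
#' @param series_name Field swept across rows, distinct from `axis_name`:
#'   `"b"` or `"tau"`.
#' @param series_values Numeric vector (one row per value).
#' @return A `sweep_grid` object: list with the swept names/values and a
#'   `values` matrix of dimension `length(series_values) x
#'   length(axis_values)`. Use [as_tibble_sweep()] for a tidy long format.
#' @examples
#' p <- balance_params()
#' sw <- balance_sweep(p, "kills", "vaf", c(0, 0.2, 0.4), "b", c(1e-4, 1e-3))
#' as_tibble_sweep(sw)
#' @export
balance_sweep <- function(params, output = c("kills", "total_time", "max_vaf"),
                          axis_name = c("vaf", "tau", "b"), axis_values,
                          series_name = c("b", "tau"), series_values) {
  params <- check_params(params)
  output <- match.arg(output)
  axis_name <- match.arg(axis_name)
  series_name <- match.arg(series_name)
  if (identical(axis_name, series_name)) {
    stop("'axis_name' and 'series_name' must differ", call. = FALSE)
  }
  if (length(axis_values) == 0L || length(series_values) == 0L) {
    stop("axis and series values must be non-empty", call. = FALSE)
  }
  if (any(diff(axis_values) <= 0)) {
    stop("'axis_values' must be strictly increasing", call. = FALSE)
  }
  fn <- switch(output,
    kills      = kills_per_effector,
    total_time = total_kill_time,
    max_vaf    = max_controllable_vaf
  )
  vals <- matrix(NA_real_, nrow = length(series_values),
                 ncol = length(axis_values))
  for (i in seq_along(series_values)) {
    for (j in seq_along(axis_values)) {
      p <- unclass(params)
      p[[series_name]] <- series_values[[i]]
      p[[axis_name]] <- axis_values[[j]]
      # vaf = 0 is a valid sweep point even though balance_params() defaults
      # reject only out-of-range values; revalidate the substituted fields
      if (p$vaf < 0 || p$vaf > 0.5) {
        stop("swept 'vaf' outside [0, 0.5]", call. = FALSE)
      }
      if (p$b <= 0 || p$b > 1 || p$tau <= 0) {
        stop("swept 'b' or 'tau' outside its valid range", call. = FALSE)
      }
      vals[i, j] <- fn(structure(p, class = "balance_params"))
    }
  }
  structure(
    list(output = output,
         axis_name = axis_name, axis_values = axis_values,
         series_name = series_name, series_values = series_values,
         values = vals),
    class = "sweep_grid"
  )
}

#' Tidy long-format view of a sweep grid
#'
#' @param grid A `sweep_grid` from [balance_sweep()].
#' @return A tibble with columns `axis_value`, `series_value`,
#'   `output_value` (plus the swept field names as metadata columns).
#' @export
as_tibble_sweep <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  tibble::tibble(
    output = grid$output,
    axis = grid$axis_name,
    series = grid$series_name,
    axis_value = rep(grid$axis_values, each = length(grid$series_values)),
    series_value = rep(grid$series_values, times = length(grid$axis_values)),
    output_value = as.vector(grid$values)
  )
}

#' Read balance-model parameters from a YAML config
#'
#' Expects a top-level `balance` mapping with fields `N`, `M`, `T`,
#' `neutrophil_lifetime_days`, `monocyte_lifetime_days`, `vaf`, `b`, and
#' `tau` given as a string with unit suffix (`"90 minutes"`, `"4 hours"`,
#' `"0.0625 days"`) or a bare number of days.
#'
#' @param path Path to a YAML file.
#' @return A [balance_params()] object.
#' @export
read_balance_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bal <- cfg$balance
  if (is.null(bal)) stop("config has no 'balance' table", call. = FALSE)
  tau <- parse_duration(bal$tau)
  args <- list(
    vaf = bal$vaf, b = bal$b, tau = tau, tau_unit = "days"
  )
  for (f in c("N", "M", "T")) if (!is.null(bal[[f]])) args[[f]] <- bal[[f]]
  if (!is.null(bal$neutrophil_lifetime_days)) {
    args$neutrophil_lifetime <- bal$neutrophil_lifetime_days
  }
  if (!is.null(bal$monocyte_lifetime_days)) {
    args$monocyte_lifetime <- bal$monocyte_lifetime_days
  }
  do.call(balance_params, args)
}

# "90 minutes" / "4 hours" / "6.6 days" / bare number (days) -> days
parse_duration <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop("duration must be a number (days) or a '<value> <unit>' string",
         call. = FALSE)
  }
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  value <- suppressWarnings(as.numeric(parts[[1]]))
  if (is.na(value)) stop("cannot parse duration: ", x, call. = FALSE)
  if (length(parts) == 1L) return(value)
  unit <- sub("s$", "", tolower(parts[[2]]))
  unit <- switch(unit,
    day = "days", hour = "hours", minute = "minutes", min = "minutes",
    stop("unknown duration unit: ", parts[[2]], call. = FALSE)
  )
  to_days(value, unit)
}
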