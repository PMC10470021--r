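default_p <- function(...) {
  args <- utils::modifyList(
    list(vaf = 0.40, b = 1e-4, tau = 90, tau_unit = "minutes"),
    list(...))
  do.call(balance_params, args)
}

test_that("tumor burden is 2*(N+M)*vaf", {
  expect_equal(tumor_burden(default_p(vaf = 0)), 0)
  expect_equal(tumor_burden(default_p()), 2 * 6.1e11 * 0.40)      # 4.88e11
  expect_equal(tumor_burden(default_p(vaf = 0.41)), 5.002e11)
})

test_that("effector pool is b*T and linear in b", {
  expect_equal(effector_pool(default_p()), 7e7)
  expect_equal(effector_pool(default_p(b = 1)), 7e11)
  expect_equal(effector_pool(default_p(b = 1e-1)), 7e10)
  expect_equal(effector_pool(default_p(b = 2e-4)),
               2 * effector_pool(default_p(b = 1e-4)))
})

test_that("kills per effector matches direct arithmetic", {
  expect_equal(kills_per_effector(default_p()), 4.88e11 / 7e7)   # ~6971.4
  expect_equal(round(kills_per_effector(default_p()) / 1000) * 1000, 7000)
  expect_equal(kills_per_effector(default_p(vaf = 0)), 0)
  expect_equal(kills_per_effector(default_p(b = 1e-1)),
               4.88e11 / 7e10)                                   # ~6.97
})

test_that("total kill time is tau * kills per effector", {
  expect_equal(total_kill_time(default_p()), 0.0625 * 4.88e11 / 7e7,
               tolerance = 1e-12)                                # ~435.7 d
  expect_equal(total_kill_time(default_p(vaf = 0)), 0)
})

test_that("eradication criterion compares total time to neutrophil lifetime", {
  expect_false(is_eradicable(default_p()))                       # 435.7 > 6.6
  expect_true(is_eradicable(default_p(vaf = 0.005)))             # below 0.6%
  expect_true(is_eradicable(default_p(vaf = 0)))
})

test_that("max controllable VAF matches the closed form and is linear in b", {
  expect_equal(max_controllable_vaf(default_p()),
               6.6 * 1e-4 * 7e11 / (2 * 0.0625 * 6.1e11))
  expect_equal(max_controllable_vaf(default_p(b = 2e-4)),
               2 * max_controllable_vaf(default_p(b = 1e-4)))
  # unclamped above the heterozygous bound; clamp_vaf flags it
  big <- max_controllable_vaf(default_p(b = 1, tau = 1, tau_unit = "minutes"))
  expect_gt(big, 0.5)
  clamped <- clamp_vaf(big)
  expect_equal(as.numeric(clamped), 0.5)
  expect_true(attr(clamped, "clamped"))
})

test_that("total kill time at the maximal controllable VAF equals the lifetime", {
  p <- default_p(b = 1e-3, tau = 4, tau_unit = "hours")
  v <- max_controllable_vaf(p)
  p2 <- balance_params(vaf = v, b = 1e-3, tau = 4, tau_unit = "hours")
  expect_equal(total_kill_time(p2), p$neutrophil_lifetime,
               tolerance = 1e-9)
})

test_that("tau unit conversions give identical model outputs", {
  p_min <- default_p()
  p_hr <- balance_params(vaf = 0.40, b = 1e-4, tau = 1.5, tau_unit = "hours")
  p_day <- balance_params(vaf = 0.40, b = 1e-4, tau = 0.0625,
                          tau_unit = "days")
  expect_identical(total_kill_time(p_min), total_kill_time(p_hr))
  expect_identical(total_kill_time(p_min), total_kill_time(p_day))
  expect_identical(max_controllable_vaf(p_min), max_controllable_vaf(p_day))
})

test_that("model outputs are monotone in vaf, b and tau", {
  set.seed(42)
  for (i in 1:50) {
    b <- 10^stats::runif(1, -5, -1)
    vaf <- stats::runif(1, 0.01, 0.45)
    tau <- stats::runif(1, 0.01, 0.5)
    p <- balance_params(vaf = vaf, b = b, tau = tau, tau_unit = "days")
    p_vaf <- balance_params(vaf = min(vaf * 1.1, 0.5), b = b, tau = tau,
                            tau_unit = "days")
    p_b <- balance_params(vaf = vaf, b = b * 1.1, tau = tau,
                          tau_unit = "days")
    p_tau <- balance_params(vaf = vaf, b = b, tau = tau * 1.1,
                            tau_unit = "days")
    expect_gt(kills_per_effector(p_vaf), kills_per_effector(p))
    expect_lt(kills_per_effector(p_b), kills_per_effector(p))
    expect_lt(max_controllable_vaf(p_tau), max_controllable_vaf(p))
    expect_gt(max_controllable_vaf(p_b), max_controllable_vaf(p))
  }
})

test_that("parameter validation names the offending field", {
  expect_error(balance_params(N = -1), "'N'")
  expect_error(balance_params(vaf = 0.6), "vaf")
  expect_error(balance_params(b = 0), "'b'")
  expect_error(balance_params(tau = 0), "'tau'")
  expect_error(to_days(-1, "hours"), "non-negative")
})

test_that("b estimate from ex vivo ELISPOT rounds to its order of magnitude", {
  est <- estimate_b_from_elispot(45, 6e5)
  expect_equal(est$raw, 7.5e-5)
  expect_equal(est$magnitude, 1e-4)
  expect_equal(estimate_b_from_elispot(600, 6e5)$magnitude, 1e-3)
  expect_warning(z <- estimate_b_from_elispot(0, 6e5), "undefined")
  expect_equal(z$raw, 0)
  expect_true(is.na(z$magnitude))
  expect_error(estimate_b_from_elispot(10, 5), "exceed")
})

test_that("sweep grids agree cell-by-cell with scalar evaluation", {
  p <- default_p()
  sw <- balance_sweep(p, "kills", "vaf", c(0, 0.2, 0.4), "b", 1e-4)
  expect_equal(dim(sw$values), c(1, 3))
  expect_equal(sw$values[1, ], c(0, 3.485714285714286e3, 6.971428571428572e3),
               tolerance = 1e-9)
  sw2 <- balance_sweep(p, "max_vaf", "tau", 0.0625, "b", 1e-4)
  expect_equal(sw2$values[1, 1], 0.006059016393442623, tolerance = 1e-12)

  sw3 <- balance_sweep(p, "total_time", "vaf", c(0.1, 0.3),
                       "tau", c(0.05, 0.2))
  for (i in 1:2) for (j in 1:2) {
    pij <- balance_params(vaf = c(0.1, 0.3)[j], b = p$b,
                          tau = c(0.05, 0.2)[i], tau_unit = "days")
    expect_equal(sw3$values[i, j], total_kill_time(pij))
  }
  long <- as_tibble_sweep(sw3)
  expect_equal(nrow(long), 4)
  expect_equal(long$output_value[long$axis_value == 0.3 &
                                   long$series_value == 0.2],
               sw3$values[2, 2])

  expect_error(balance_sweep(p, "kills", "vaf", numeric(0), "b", 1e-4),
               "non-empty")
  expect_error(balance_sweep(p, "kills", "vaf", c(0.2, 0.1), "b", 1e-4),
               "increasing")
  expect_error(balance_sweep(p, "kills", "b", c(1e-4), "b", 1e-4),
               "differ")
})

test_that("balance config round-trips through YAML with unit-tagged tau", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "balance:",
    "  N: 6.0e+11", "  M: 1.0e+10", "  T: 7.0e+11",
    "  neutrophil_lifetime_days: 6.6",
    "  monocyte_lifetime_days: 3.5",
    "  vaf: 0.40", "  b: 1.0e-04",
    "  tau: 90 minutes"), path)
  p <- read_balance_config(path)
  expect_equal(p$tau, 0.0625)
  expect_equal(kills_per_effector(p), 4.88e11 / 7e7)
})
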