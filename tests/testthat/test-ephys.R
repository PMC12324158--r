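make_trace <- function(current, dt = 1e-3, stim_onset = 1,
                       stim_duration = 1, voltage = 0, cell = "c1") {
  time <- seq(0, by = dt, length.out = length(current))
  current_trace(time, current, voltage_mV = voltage, stim_onset = stim_onset,
                stim_duration = stim_duration, cell = cell)
}

test_that("baseline correction removes constant offsets and is idempotent", {
  n <- 5001
  tr <- make_trace(rep(7, n))
  expect_equal(baseline_correct(tr)$current, rep(0, n))
  # already zero-mean baseline -> unchanged
  tr0 <- baseline_correct(tr)
  expect_equal(baseline_correct(tr0)$current, tr0$current)
  # shift invariance: trace + c corrects to the same output
  sig <- c(rep(0, 1000), -50 * exp(-seq(0, 4, 1e-3) / 0.5))
  tr1 <- make_trace(sig)
  tr2 <- make_trace(sig + 12.5)
  expect_equal(baseline_correct(tr1)$current, baseline_correct(tr2)$current)
})

test_that("linear baseline mode removes drift", {
  time <- seq(0, 5, 1e-3)
  tr <- current_trace(time, 3 + 2 * time, stim_onset = 1, stim_duration = 1)
  out <- baseline_correct(tr, "linear")
  expect_equal(max(abs(out$current)), 0, tolerance = 1e-8)
})

test_that("windows outside the trace are rejected", {
  tr <- make_trace(rep(0, 2001))
  expect_error(split_charges(tr, window = c(10, 20)), "outside")
})

test_that("flat traces give zero charges and an undefined ratio", {
  res <- split_charges(make_trace(rep(0, 8001)))
  expect_equal(res$Q_in_pC, 0)
  expect_equal(res$Q_out_pC, 0)
  expect_false(res$ratio_defined)
  expect_true(is.na(res$coupling_ratio))
})

test_that("exponential decay integrates to A*tau within 0.1%", {
  t <- seq(0, 10, 1e-3)
  tr <- make_trace(-100 * exp(-t / 0.5), stim_onset = 0.5)
  res <- split_charges(tr, window = c(0, 10))
  expect_equal(res$Q_in_pC, 50, tolerance = 1e-3)
  expect_equal(res$Q_out_pC, 0)
  expect_equal(res$peak_in_pA, -100)
})

test_that("negating a trace exchanges inward and outward exactly", {
  set.seed(1)
  sig <- cumsum(rnorm(5000))
  a <- split_charges(make_trace(sig), window = c(1, 4))
  b <- split_charges(make_trace(-sig), window = c(1, 4))
  expect_identical(a$Q_in_pC, b$Q_out_pC)
  expect_identical(a$Q_out_pC, b$Q_in_pC)
})

test_that("trapezoidal charge error shrinks at least 3.5x when dt halves", {
  q_for_dt <- function(dt) {
    t <- seq(0, 10, dt)
    split_charges(make_trace(-100 * exp(-t / 0.5), dt = dt, stim_onset = 0.5),
                  window = c(0, 10))$Q_in_pC
  }
  err1 <- abs(q_for_dt(1e-3) - 50)
  err2 <- abs(q_for_dt(5e-4) - 50)
  expect_gte(err1 / err2, 3.5)
})

test_that("charge split recovers simulator ground truth on disjoint sweeps", {
  cfg <- trace_sim_config(dt = 1e-3, duration = 10, stim_onset = 1,
                          stim_duration = 1,
                          inward_amplitude = 800, inward_rise = 0.02,
                          inward_decay = 0.25,
                          outward_amplitude = 150, outward_delay = 2,
                          outward_rise = 0.1, outward_decay = 0.5,
                          noise_sd = 0, seed = 1)
  sim <- simulate_current_trace(cfg)
  res <- analyze_sweep(sim$trace, window = c(1, 9.5))
  expect_equal(res$Q_in_pC, sim$true_Q_in_pC, tolerance = 1e-3)
  expect_equal(res$Q_out_pC, sim$true_Q_out_pC, tolerance = 2e-3)
  expect_equal(res$coupling_ratio, sim$true_Q_out_pC / sim$true_Q_in_pC,
               tolerance = 1e-3)
})

fake_results <- function(values, col) {
  do.call(rbind, lapply(seq_along(values), function(i) {
    v <- values[[i]]
    df <- data.frame(cell = paste0("c", i),
                     voltage_mV = seq(-80, by = 20, length.out = length(v)))
    df$peak_in_pA <- if (col == "peak_in_pA") v else -1
    df$peak_out_pA <- 0
    df$Q_in_pC <- if (col == "Q_in_pC") v else 1
    df$Q_out_pC <- 0
    df$coupling_ratio <- if (col == "coupling_ratio") v else 0
    df$ratio_defined <- TRUE
    df
  }))
}

test_that("I-V normalization uses the per-cell maximum magnitude", {
  cs <- iv_curve(fake_results(list(c(-100, -50)), "peak_in_pA"))
  expect_equal(cs$per_cell$value, c(-1, -0.5))
  # scaling a cell's currents leaves its normalized curve unchanged
  cs3 <- iv_curve(fake_results(list(3 * c(-100, -50)), "peak_in_pA"))
  expect_equal(cs3$per_cell$value, cs$per_cell$value)
  # two identical cells -> SEM 0 everywhere
  cs2 <- iv_curve(fake_results(list(c(-100, -50), c(-100, -50)),
                               "peak_in_pA"))
  expect_equal(cs2$aggregate$sem, c(0, 0))
  expect_equal(cs2$aggregate$n, c(2, 2))
})

test_that("all-zero cells are excluded from I-V with a warning", {
  res <- fake_results(list(c(-100, -50), c(0, 0)), "peak_in_pA")
  expect_warning(cs <- iv_curve(res), "all-zero")
  expect_equal(unique(cs$per_cell$cell), "c1")
})

test_that("Q-V normalization and aggregation follow the I-V rules", {
  cs <- qv_curve(fake_results(list(c(10, 5)), "Q_in_pC"))
  expect_equal(cs$per_cell$value, c(1, 0.5))
  cs2 <- qv_curve(fake_results(list(c(1.0, 0.5), c(1.0, 0.7)), "Q_in_pC"))
  expect_equal(cs2$aggregate$mean, c(1.0, 0.6))
})

test_that("coupling curve aggregates raw ratios and reports dropped sweeps", {
  res <- fake_results(list(c(0.4, 0.4), c(0.4, 0.4)), "coupling_ratio")
  res$ratio_defined[4] <- FALSE
  res$coupling_ratio[4] <- NA
  cs <- coupling_curve(res)
  expect_equal(cs$aggregate$mean, c(0.4, 0.4))
  expect_equal(cs$aggregate$n_undefined, c(0, 1))
  expect_equal(cs$aggregate$n, c(2, 1))
})

test_that("sweep CSV + JSON round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- trace_sim_config(dt = 1e-3, duration = 4, noise_sd = 2, seed = 5)
  sim <- simulate_current_trace(cfg)
  csv <- file.path(dir, "sweep.csv")
  write_current_trace(sim$trace, csv,
                      extra = list(true_Q_in_pC = sim$true_Q_in_pC,
                                   true_Q_out_pC = sim$true_Q_out_pC))
  tr <- read_current_trace(csv)
  expect_equal(tr$current, sim$trace$current, tolerance = 1e-12)
  expect_equal(tr$voltage_mV, sim$trace$voltage_mV)
  expect_equal(attr(tr, "meta")$true_Q_in_pC, sim$true_Q_in_pC)
})
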