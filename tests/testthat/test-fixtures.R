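p_default <- default_parameters()

test_that("noiseless time series collapse exactly onto the simulator", {
  co <- synth_timeseries(p_default, noise_cv = 0, seed = 5)
  tp <- co$generating$timepoints
  # with cv = 0 every replicate equals the recorded model truth exactly
  truth_at <- function(m, t)
    co$summary$truth_mM[co$summary$metabolite == m & co$summary$time_min == t]
  for (m in co$generating$metabolites)
    for (t in tp) {
      v <- co$data$value_mM[co$data$metabolite == m & co$data$time_min == t]
      expect_identical(v, rep(truth_at(m, t), 3))
    }
  expect_true(all(co$summary$se_mM == 0))
  expect_equal(co$summary$mean_mM, co$summary$truth_mM, tolerance = 1e-14)
  # and the recorded truth is the model trajectory (same solver tolerances;
  # output-grid choice perturbs values only at the error-control level)
  tr <- integrate_model(p_default, duration = max(tp), output_step = 1)
  for (m in co$generating$metabolites) {
    ref <- tr$states[match(tp, tr$times), m]
    got <- vapply(tp, function(t) truth_at(m, t), numeric(1))
    # mixed relative/absolute bound, 100x the solver's error control
    expect_true(all(abs(got - ref) <= 1e-6 * abs(ref) + 1e-8))
  }
})

test_that("time-series design arithmetic holds", {
  co <- synth_timeseries(p_default, noise_cv = 0.15, seed = 7)
  # 6 time points x 3 replicates per metabolite
  for (m in co$generating$metabolites)
    expect_identical(sum(co$data$metabolite == m), 18L)
  expect_identical(nrow(co$summary), 18L)
  expect_true(all(co$data$value_mM >= 0))
})

test_that("generators are deterministic under a seed and leave the RNG alone", {
  a <- synth_timeseries(p_default, seed = 123)
  b <- synth_timeseries(p_default, seed = 123)
  expect_identical(a$data, b$data)
  d <- synth_timeseries(p_default, seed = 124)
  expect_false(identical(a$data, d$data))
  # caller's RNG stream is not consumed
  set.seed(99)
  expected <- runif(1)
  set.seed(99)
  invisible(synth_timeseries(p_default, seed = 1))
  expect_identical(runif(1), expected)
})

test_that("replicate means converge to the noiseless trajectory value", {
  co <- synth_timeseries(p_default, timepoints = 60, n_reps = 10000,
                         noise_cv = 0.1, seed = 31)
  s <- co$summary[co$summary$metabolite == "LACT_r", ]
  expect_lt(abs(s$mean_mM - s$truth_mM), 3 * s$se_mM)
})

test_that("generator input validation", {
  expect_error(synth_timeseries(p_default, noise_cv = -0.1), "noise_cv")
  expect_error(synth_timeseries(p_default, timepoints = numeric()),
               "timepoints")
  expect_error(synth_timeseries(p_default, timepoints = -5), "timepoints")
  expect_error(synth_knockout_cohort(p_default, glut1_levels = c(1, 0.5),
                                     group_sizes = c(2, 0)), "group_sizes")
  expect_error(synth_knockout_cohort(p_default, glut1_levels = c(1, 1.5),
                                     group_sizes = c(2, 2)), "glut1_levels")
})

test_that("noiseless knockout cohorts sit exactly on the sweep's relative curve", {
  sw <- cached_default_sweep()
  co <- synth_knockout_cohort(p_default, noise_cv = 0, seed = 9, sweep = sw)
  # control group scales itself to exactly 100
  ctrl <- co$data[co$data$group == 1L, ]
  expect_true(all(ctrl$relative == 100))
  for (k in 2:3) {
    lvl <- co$generating$glut1_levels[k]
    i <- sweep_row(sw, lvl)
    for (m in c("g_r", "LACT_r")) {
      vals <- co$data$relative[co$data$group == k & co$data$metabolite == m]
      expect_equal(vals, rep(unname(sw$relative[i, m]), length(vals)),
                   tolerance = 1e-10)
    }
  }
  # group sizes as requested
  expect_identical(
    as.integer(table(co$data$group[co$data$metabolite == "g_r"])),
    c(6L, 4L, 6L))
})

test_that("knockout cohorts regenerate bit-identically under the same seed", {
  sw <- cached_default_sweep()
  a <- synth_knockout_cohort(p_default, seed = 17, sweep = sw)
  b <- synth_knockout_cohort(p_default, seed = 17, sweep = sw)
  expect_identical(a$data, b$data)
  expect_false(identical(
    a$data, synth_knockout_cohort(p_default, seed = 18, sweep = sw)$data))
})

test_that("control-median scaling is idempotent and guards against a zero control", {
  set.seed(3)
  vals <- rlnorm(20)
  is_ctrl <- rep(c(TRUE, FALSE), 10)
  once <- scale_by_control_median(vals, is_ctrl)
  twice <- scale_by_control_median(once, is_ctrl)
  expect_equal(median(once[is_ctrl]), 100, tolerance = 1e-12)
  expect_equal(twice, once, tolerance = 1e-12)
  expect_error(scale_by_control_median(c(0, 0, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               "control median")
})

test_that("intensity conversion follows the documented dimensional chain", {
  # pmol/ug * (mg protein / ml) -> nmol/ml -> umol/l, /1000 -> mM
  expect_identical(convert_intensity(0), 0)
  expect_identical(convert_intensity(0, protein_conc = 3), 0)
  expect_equal(convert_intensity(50), 1.0, tolerance = 1e-14)
  expect_equal(convert_intensity(50, protein_conc = 40), 2.0,
               tolerance = 1e-14)
  expect_equal(convert_intensity(c(1, 2)), c(0.02, 0.04), tolerance = 1e-14)
  expect_error(convert_intensity(10, protein_conc = 0), "protein_conc")
  expect_error(convert_intensity(-1), "non-negative")
})

test_that("cohort export writes the table plus a regenerating JSON sidecar", {
  sw <- cached_default_sweep()
  co <- synth_knockout_cohort(p_default, seed = 11, sweep = sw)
  f <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(co, f)
  expect_true(file.exists(f))
  side <- jsonlite::read_json(paste0(sub("\\.csv$", "", f), ".json"))
  expect_identical(side$design, "knockout")
  expect_identical(side$seed, 11L)
  expect_identical(side$noise_cv, 0.15)
})
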