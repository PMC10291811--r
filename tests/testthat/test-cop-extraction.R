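# Plate and mat CoP extraction, calibration, resampling, QC.

test_that("the plate relation maps moments to CoP under the stated convention", {
  s <- tibble::tibble(time = 0, fx = 0, fy = 0, fz = 10, mx = 2, my = -3, mz = 0)
  traj <- cop_from_forceplate(s, fz_threshold = 1)
  expect_equal(traj$x_ap, 0.3)
  expect_equal(traj$y_ml, 0.2)
})

test_that("all-unloaded plate samples give an empty-trajectory error", {
  s <- tibble::tibble(time = 0:9 / 100, fx = 0, fy = 0, fz = 0,
                      mx = 0, my = 0, mz = 0)
  expect_error(cop_from_forceplate(s), "empty trajectory")
})

test_that("sub-threshold plate samples are excluded and counted", {
  s <- tibble::tibble(time = 0:3 / 100, fx = 0, fy = 0,
                      fz = c(50, 0.5, 50, 50), mx = 1, my = -1, mz = 0)
  traj <- cop_from_forceplate(s, fz_threshold = 1)
  expect_equal(nrow(traj), 3)
  expect_equal(attr(traj, "n_excluded"), 1)
})

test_that("calibration scale follows mass * g / mean raw load and is idempotent", {
  spec <- device_spec("pressure_mat", grid_dim = c(4, 4))
  frames <- array(rep(c(62, 63), each = 16), dim = c(4, 4, 2))  # totals 992, 1008
  ps <- structure(list(time = c(0, 1 / 60), frames = frames, spec = spec,
                       calibration_scale = 1, unit = "raw_count"),
                  class = "pressure_stream")
  cal <- calibrate_pressure(ps, 50)
  expect_equal(cal$calibration_scale, 50 * 9.81 / 1000)  # 0.4905 N/count
  recal <- calibrate_pressure(cal, 50)
  expect_equal(recal$calibration_scale, 1, tolerance = 1e-12)
  expect_error(calibrate_pressure(ps, 0), "positive mass")
  ps$frames[] <- 0
  expect_error(calibrate_pressure(ps, 50), "zero mean total load")
})

test_that("the mat centroid reproduces midpoint and single-sensel cases", {
  spec <- device_spec("pressure_mat", sensel_pitch = 2, grid_dim = c(3, 3))
  g <- pawsway:::mat_grid(spec)
  mk <- function(m) structure(list(time = 0, frames = array(m, c(3, 3, 1)),
                                   spec = spec, calibration_scale = 1,
                                   unit = "N"), class = "pressure_stream")
  # two equal loads in the same row, columns 2 and 3: midpoint in x
  m <- matrix(0, 3, 3); m[2, 2] <- 5; m[2, 3] <- 5
  traj <- cop_from_pressure(mk(m))
  expect_equal(traj$x_ap, (g$x[2] + g$x[3]) / 2)
  expect_equal(traj$y_ml, g$y[2])
  # one loaded sensel: CoP at its centre
  m <- matrix(0, 3, 3); m[1, 3] <- 7
  traj <- cop_from_pressure(mk(m))
  expect_equal(c(traj$x_ap, traj$y_ml), c(g$x[3], g$y[1]))
})

test_that("under-loaded frames are dropped; an empty stream errors", {
  spec <- device_spec("pressure_mat", grid_dim = c(2, 2))
  frames <- array(0, c(2, 2, 5))
  frames[1, 1, ] <- c(100, 100, 1, 100, 100)   # frame 3 far below the median
  ps <- structure(list(time = 0:4 / 60, frames = frames, spec = spec,
                       calibration_scale = 1, unit = "N"),
                  class = "pressure_stream")
  traj <- cop_from_pressure(ps, load_threshold = 0.1)
  expect_equal(nrow(traj), 4)
  expect_equal(attr(traj, "n_excluded"), 1)
  ps$frames[] <- 0
  expect_error(cop_from_pressure(ps), "empty trajectory")
})

test_that("resampling is the identity on its own grid and on constants", {
  traj <- make_traj(c(1, 1, 1, 1), c(2, 2, 2, 2), rate = 50)
  out <- resample_trajectory(traj, 200)
  expect_true(all(out$x_ap == 1) && all(out$y_ml == 2))
  p <- random_traj(40, rate = 60)
  same <- resample_trajectory(p, 60)
  expect_equal(same$x_ap, p$x_ap, tolerance = 1e-12)
  expect_equal(same$y_ml, p$y_ml, tolerance = 1e-12)
})

test_that("resampling onto a polyline never lengthens the sway path", {
  withr::local_seed(55)
  for (i in 1:50) {
    p <- random_traj(60, rate = 60)
    r <- resample_trajectory(p, 100)
    expect_lte(sway_path(r), sway_path(p) + 1e-12)
  }
})

test_that("resampling moves AP/ML range by at most the largest inter-sample step", {
  withr::local_seed(56)
  for (i in 1:20) {
    p <- random_traj(60, rate = 60)
    r <- resample_trajectory(p, 100)
    bound <- max(sqrt(diff(p$x_ap)^2 + diff(p$y_ml)^2))
    expect_lte(abs(ap_range(p) - ap_range(r)), bound)
    expect_lte(abs(ml_range(p) - ml_range(r)), bound)
    # interpolation stays inside the original envelope
    expect_lte(ap_range(r), ap_range(p) + 1e-12)
    expect_lte(ml_range(r), ml_range(p) + 1e-12)
  }
})

test_that("QC accepts clean trials and names the rule that rejects", {
  rec <- simulate_trial(seed = 61)
  expect_equal(qc_trial(rec)$decision, "accept")
  bad <- inject_artifact(rec, "limb_unload", onset = 3, magnitude = 1, paw = 4)
  expect_equal(qc_trial(bad)$reason, "limb_unload")
  short <- simulate_trial(quick_sway_params(duration = 3), seed = 62)
  expect_equal(qc_trial(short)$reason, "duration")
  drift <- inject_artifact(rec, "body_shift", onset = 2, magnitude = 8)
  expect_equal(qc_trial(drift)$reason, "body_shift")
})
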