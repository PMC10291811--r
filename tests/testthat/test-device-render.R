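# Rendering ground truth as raw device streams, and recovering it.

test_that("noise-free plate rendering round-trips the CoP exactly", {
  p <- simulate_cop_path(sway_model_params(duration = 2, seed = 3))
  fp <- render_force_plate(p, spec = device_spec("force_plate", cop_noise_sd = 0))
  back <- cop_from_forceplate(fp, fz_threshold = 1)
  expect_equal(back$x_ap, p$x_ap, tolerance = 1e-12)
  expect_equal(back$y_ml, p$y_ml, tolerance = 1e-12)
})

test_that("mean vertical force equals body weight times g", {
  p <- simulate_cop_path(sway_model_params(duration = 10, seed = 4))
  fp <- render_force_plate(p, stance_geometry(body_weight = 5.4), seed = 8)
  expect_equal(mean(fp$fz), 5.4 * 9.81, tolerance = 0.01)
})

test_that("CoP recovery error matches the specified device noise", {
  p <- simulate_cop_path(sway_model_params(duration = 100, seed = 5))
  fp <- render_force_plate(p, spec = device_spec("force_plate", cop_noise_sd = 0.05),
                           seed = 6)
  back <- cop_from_forceplate(fp)
  rms <- sqrt(mean((back$x_ap - p$x_ap)^2))
  expect_gt(rms, 0.04)
  expect_lt(rms, 0.06)
})

test_that("a narrow blob centred on a sensel loads only that sensel", {
  spec <- device_spec("pressure_mat", blob_sd = 0.01)
  g <- pawsway:::mat_grid(spec)
  centre <- c(g$x[20], g$y[10])
  # all paw centres sit exactly on sensel centres so the delta-like blobs
  # rasterise onto single sensels
  geom <- stance_geometry(
    paw_centres = rbind(centre, c(g$x[30], g$y[10]),
                        c(g$x[30], g$y[20]), c(g$x[20], g$y[20])),
    nominal_shares = c(1, 0, 0, 0) * 0.97 + 0.0075, body_weight = 5)
  path <- make_traj(rep(centre[1], 10), rep(centre[2], 10), rate = 60)
  # the CoP sits on the loaded paw, so that paw carries everything and the
  # delta-like blob concentrates on its sensel
  ps <- render_pressure_mat(path, geom, spec, quantize = FALSE)
  fr <- ps$frames[, , 1]
  expect_equal(fr[10, 20] / sum(fr), 1, tolerance = 1e-9)
})

test_that("symmetric stance with central CoP gives a centred pressure centroid", {
  geom <- stance_geometry(paw_centres = rbind(c(10, 3), c(10, -3),
                                              c(-10, 3), c(-10, -3)),
                          nominal_shares = rep(0.25, 4), body_weight = 5)
  path <- make_traj(rep(0, 12), rep(0, 12), rate = 60)
  ps <- render_pressure_mat(path, geom, quantize = FALSE)
  traj <- cop_from_pressure(ps)
  expect_lt(max(abs(traj$x_ap)), 1e-6)
  expect_lt(max(abs(traj$y_ml)), 1e-6)
})

test_that("pre-quantization sensel loads conserve the body weight", {
  p <- simulate_cop_path(sway_model_params(duration = 1, seed = 6))
  geom <- stance_geometry(body_weight = 5.4)
  ps <- render_pressure_mat(p, geom, quantize = FALSE)
  totals <- apply(ps$frames, 3, sum)
  expect_equal(totals, rep(5.4 * 9.81, length(totals)), tolerance = 1e-9)
})

test_that("quantization-free mat rendering recovers the CoP to 1e-6 cm", {
  p <- simulate_cop_path(sway_model_params(duration = 2, seed = 7))
  ps <- render_pressure_mat(p, quantize = FALSE)
  traj <- cop_from_pressure(ps)
  xs <- approx(p$time, p$x_ap, xout = traj$time)$y
  ys <- approx(p$time, p$y_ml, xout = traj$time)$y
  expect_lt(max(abs(traj$x_ap - xs)), 1e-6)
  expect_lt(max(abs(traj$y_ml - ys)), 1e-6)
})

test_that("quantized mat CoP error stays below one sensel pitch", {
  errs <- c()
  for (seed in 1:2) {
    p <- simulate_cop_path(sway_model_params(duration = 10, seed = seed))
    ps <- render_pressure_mat(p)  # 600 quantized frames each
    traj <- cop_from_pressure(ps)
    xs <- approx(p$time, p$x_ap, xout = traj$time)$y
    ys <- approx(p$time, p$y_ml, xout = traj$time)$y
    errs <- c(errs, abs(traj$x_ap - xs), abs(traj$y_ml - ys))
  }
  expect_gt(length(errs), 2000)  # > 1000 frames checked
  expect_lt(max(errs), 1 / sqrt(1.4))
})

test_that("a stance too close to the mat edge is a geometry error", {
  geom <- stance_geometry(paw_centres = rbind(c(21, 3.5), c(21, -3.5),
                                              c(-5, 3.5), c(-5, -3.5)),
                          nominal_shares = rep(0.25, 4), body_weight = 5)
  p <- make_traj(rep(8, 5), rep(0, 5), rate = 60)
  expect_error(render_pressure_mat(p, geom), "does not fit")
})
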