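# Bland-Altman, Pearson and ICC machinery.

test_that("a constant difference gives bias with zero-width limits", {
  ba <- bland_altman(a = c(2, 3, 4), b = c(1, 2, 3))
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(1, 1))
  expect_equal(ba$trend_slope, 0)
})

test_that("identical devices give zero bias and swapping devices flips it", {
  withr::local_seed(81)
  a <- rnorm(10, 5); b <- rnorm(10, 4)
  expect_equal(bland_altman(a = a, b = a)$bias, 0)
  ab <- bland_altman(a = a, b = b)
  ba <- bland_altman(a = b, b = a)
  expect_equal(ab$bias, -ba$bias)
  expect_equal(c(ab$loa_low, ab$loa_high), -c(ba$loa_high, ba$loa_low))
})

test_that("the device bias equals the difference of the device means", {
  # normative reference: per-measure device means imply the printed biases
  ref <- normative_reference()
  withr::local_seed(82)
  for (i in seq_len(nrow(ref))) {
    noise <- rnorm(42)
    a <- ref$mean_force_plate[i] + noise  # same within-dog perturbation on
    b <- ref$mean_pressure_mat[i] + noise # both devices: pure location shift
    ba <- bland_altman(a = a, b = b)
    expect_equal(ba$bias, ref$mean_force_plate[i] - ref$mean_pressure_mat[i],
                 tolerance = 1e-12)
  }
})

test_that("the long-format interface matches the vector interface", {
  withr::local_seed(83)
  d <- tibble::tibble(dog = rep(sprintf("d%02d", 1:12), 2),
                      device = rep(c("force_plate", "pressure_mat"), each = 12),
                      v = c(rnorm(12, 3), rnorm(12, 2)))
  ba1 <- bland_altman(d, v, device, dog, device_a = "force_plate")
  wide <- tidyr::pivot_wider(d, names_from = device, values_from = v)
  ba2 <- bland_altman(a = wide$force_plate, b = wide$pressure_mat)
  expect_equal(tidy(ba1), tidy(ba2))
})

test_that("pearson matches the direct covariance formula and handles edge cases", {
  expect_equal(pearson_validity(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_validity(1:5, -3 * (1:5))$r, -1)
  withr::local_seed(84)
  a <- rnorm(5); b <- rnorm(5)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  pv <- pearson_validity(a, b)
  expect_equal(pv$r, direct, tolerance = 1e-12)
  tstat <- direct * sqrt(3 / (1 - direct^2))
  expect_equal(pv$p, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)
  expect_error(pearson_validity(rep(1, 5), rnorm(5)), "zero variance")
  # invariance under positive affine maps of either side
  expect_equal(pearson_validity(10 + 3 * a, b)$r, pv$r, tolerance = 1e-12)
})

test_that("ICC is 1 with zero within-subject variance and near 0 under the null", {
  m <- matrix(rep(c(4, 6, 8, 5), each = 5), nrow = 4, byrow = TRUE)
  r <- icc_a_k(m)
  expect_equal(r$icc, 1)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  withr::local_seed(85)
  null <- suppressWarnings(icc_a_k(matrix(rnorm(200 * 5), 200, 5)))
  expect_lt(abs(null$icc), 0.1)
})

test_that("ICC agrees with an independent reference implementation", {
  # fixture: 6 subjects x 3 trials; expected values frozen from an
  # independent ICC implementation (two-way, absolute agreement, average
  # of k raters) run on the same matrix
  m <- matrix(c(4.289758, 4.392875, 3.637881,
                6.183782, 5.237703, 5.051823,
                2.789819, 3.131155, 1.462294,
                5.962765, 6.958336, 5.887889,
                3.460829, 4.565510, 2.108503,
                4.842603, 5.369585, 5.320101), nrow = 6, byrow = TRUE)
  r <- icc_a_k(m)
  expect_equal(r$icc, 0.9135697343, tolerance = 1e-9)
  expect_equal(round(r$ci_low, 2), 0.61)
  expect_equal(round(r$ci_high, 2), 0.99)
  expect_equal(r$p_value, 8.612360e-05, tolerance = 1e-6)
})

test_that("ICC tracks the closed-form value for a simulated two-way design", {
  withr::local_seed(86)
  n <- 500; k <- 5
  subj <- rnorm(n, 0, 1); trialeff <- rnorm(k, 0, 0.3)
  m <- outer(subj, trialeff, "+") + matrix(rnorm(n * k, 0, 0.5), n, k)
  # mixed model: trials are fixed once drawn, so the averaged-ratings
  # oracle uses the realised trial variance component
  pop <- 1 / (1 + (var(trialeff) + 0.5^2) / k)
  r <- icc_a_k(m)
  expect_equal(r$icc, pop, tolerance = 0.03 / pop)
})

test_that("ICC is invariant to shifting and positive scaling of the matrix", {
  withr::local_seed(87)
  m <- outer(rnorm(30), rep(1, 5)) + matrix(rnorm(150, 0, 0.5), 30, 5)
  r0 <- icc_a_k(m)
  r1 <- icc_a_k(m + 100)
  r2 <- icc_a_k(m * 3.7)
  expect_equal(r1$icc, r0$icc, tolerance = 1e-10)
  expect_equal(r2$icc, r0$icc, tolerance = 1e-10)
  expect_equal(c(r1$ci_low, r1$ci_high), c(r0$ci_low, r0$ci_high),
               tolerance = 1e-8)
})

test_that("negative ICC estimates are reported with a warning, not floored", {
  withr::local_seed(88)
  # strong trial effect, no subject effect: expectation slightly negative
  found <- FALSE
  for (i in 1:20) {
    m <- outer(rep(0, 8), rnorm(4, 0, 2), "+") + matrix(rnorm(32, 0, 0.3), 8, 4)
    r <- suppressWarnings(icc_a_k(m))
    if (r$icc < 0) {
      expect_warning(icc_a_k(m), "negative ICC")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("ICC rejects incomplete matrices and tiny designs", {
  m <- matrix(rnorm(20), 5, 4); m[2, 3] <- NA
  expect_error(icc_a_k(m), "complete")
  expect_error(icc_a_k(matrix(1:4, 1, 4)), "at least 2 subjects")
})

test_that("reliability bands follow the published thresholds", {
  expect_equal(icc_band(0.792), "good")       # published AP-range plate ICC
  expect_equal(icc_band(0.986), "excellent")  # published sway-path plate ICC
  expect_equal(icc_band(0.5), "moderate")     # boundary goes to the upper band
  expect_equal(icc_band(c(0.49, 0.75, 0.9, -0.2)),
               c("poor", "good", "excellent", "poor"))
  expect_error(icc_band(1.2), "exceed 1")
})
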