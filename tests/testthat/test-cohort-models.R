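# Regression families, selection, and one-way ANOVA.

test_that("every family recovers exact generating parameters", {
  x <- seq(0.5, 8, length.out = 40)
  cases <- list(
    list(fam = "linear", y = 3 + 2 * x, coef = c(a = 3, b = 2)),
    list(fam = "logarithmic", y = 1.5 - 0.8 * log(x), coef = c(a = 1.5, b = -0.8)),
    list(fam = "quadratic", y = 10 - 3 * x + 0.5 * x^2, coef = c(a = 10, b = -3, c = 0.5)),
    list(fam = "exponential", y = 2.5 * exp(0.3 * x), coef = c(a = 2.5, b = 0.3)),
    list(fam = "power", y = 2 * x^1.0, coef = c(a = 2, b = 1)))
  for (cs in cases) {
    fit <- fit_family(NULL, x, cs$y, family = cs$fam)
    expect_equal(unname(fit$coefficients), unname(cs$coef), tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("domain violations fail loudly", {
  expect_error(fit_family(NULL, c(-1, 1, 2, 3), c(1, 2, 3, 4), "power"),
               "positive x")
  expect_error(fit_family(NULL, 1:4, c(-1, 2, 3, 4), "exponential"),
               "positive y")
  expect_error(fit_family(NULL, 1:3, 1:3, "quadratic"), "at least 4")
})

test_that("selection prefers fewer coefficients on ties and the truth otherwise", {
  x <- 1:20
  lin <- select_family(NULL, x, 5 + 1.5 * x)
  expect_equal(lin$family, "linear")  # quadratic also reaches R^2 = 1
  quad <- select_family(NULL, x, 2 + 0.5 * x + 0.3 * x^2)
  expect_equal(quad$family, "quadratic")
  expect_named(quad$candidates)
  expect_true(all(c("linear", "quadratic") %in% names(quad$candidates)))
})

test_that("nesting: the quadratic family never fits worse than the linear", {
  withr::local_seed(91)
  for (i in 1:20) {
    x <- runif(30, 1, 9)
    y <- 2 + rnorm(30) + 0.3 * x + 0.2 * x^2 * rbinom(1, 1, 0.5)
    f_lin <- fit_family(NULL, x, y, "linear")
    f_quad <- fit_family(NULL, x, y, "quadratic")
    expect_gte(f_quad$r_squared, f_lin$r_squared - 1e-10)
  }
})

test_that("a noisy quadratic weight-sway relation is recovered within 3 bootstrap SEs", {
  withr::local_seed(92)
  n <- 200
  w <- runif(n, 3, 8)
  y <- 1000 - 80 * w + 4 * w^2 + rnorm(n, 0, 20)
  fit <- fit_family(NULL, w, y, "quadratic")
  # bootstrap oracle for the coefficient SEs
  boots <- t(replicate(400, {
    idx <- sample.int(n, replace = TRUE)
    stats::coef(stats::lm(y[idx] ~ w[idx] + I(w[idx]^2)))
  }))
  se <- apply(boots, 2, sd)
  truth <- c(1000, -80, 4)
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
  expect_gt(fit$r_squared, 0.7)
})

test_that("identical groups give F = 0 and p = 1", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4), y = rep(1:4, 3))
  res <- one_way_anova(d, y, g)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 9L)
})

test_that("with two groups F equals the square of the pooled t statistic", {
  withr::local_seed(93)
  d <- tibble::tibble(g = rep(c("m", "f"), c(12, 18)),
                      y = c(rnorm(12, 5), rnorm(18, 5.8)))
  res <- one_way_anova(d, y, g)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("group summaries and failure modes are right", {
  d <- tibble::tibble(g = c("a", "a", "b"), y = c(1, 2, 3))
  expect_error(one_way_anova(d, y, g), "fewer than 2 values")
  d2 <- tibble::tibble(g = rep("a", 5), y = rnorm(5))
  expect_error(one_way_anova(d2, y, g), "at least 2 groups")
})
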