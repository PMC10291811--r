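# On-disk formats: round trips and rejection of malformed input.

test_that("a hand-written 3-row force file parses to the stated values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# rate_hz: 100",
               "time,fx,fy,fz,mx,my,mz",
               "0,0.1,0.2,52.9,1,2,0",
               "0.01,0.0,0.1,53.1,1.1,1.9,0",
               "0.02,-0.1,0.2,53.0,0.9,2.1,0"), f)
  s <- read_force_csv(f)
  expect_equal(nrow(s), 3)
  expect_equal(s$fz, c(52.9, 53.1, 53.0))
  expect_equal(attr(s, "rate"), 100)
})

test_that("force stream write -> read round-trips exactly", {
  p <- simulate_cop_path(quick_sway_params(seed = 41))
  fp <- render_force_plate(p, seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  write_force_csv(fp, f)
  back <- read_force_csv(f)
  for (col in c("time", "fx", "fy", "fz", "mx", "my", "mz")) {
    expect_equal(back[[col]], fp[[col]], tolerance = 1e-12)
  }
})

test_that("a force file without Fz fails naming the column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,fx,fy,mx,my,mz", "0,0,0,1,2,0"), f)
  expect_error(read_force_csv(f), "fz")
})

test_that("non-monotonic time and non-finite values are rejected with row info", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,fx,fy,fz,mx,my,mz",
               "0,0,0,50,1,2,0", "0.01,0,0,50,1,2,0", "0.005,0,0,50,1,2,0"), f)
  expect_error(read_force_csv(f), "not strictly increasing at row 3")
  writeLines(c("time,fx,fy,fz,mx,my,mz",
               "0,0,0,50,1,2,0", "0.01,0,0,NA,1,2,0"), f)
  expect_error(read_force_csv(f), "non-finite value in data row 2")
})

test_that("a single 2x2 zero frame parses with total load zero", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# rate_hz: 60", "Frame 1, t=0.000000", "0,0", "0,0"), f)
  s <- read_pressure_frames(f)
  expect_equal(dim(s$frames), c(2, 2, 1))
  expect_equal(sum(s$frames), 0)
})

test_that("pressure stream write -> read round-trips raw counts exactly", {
  p <- simulate_cop_path(quick_sway_params(seed = 43, duration = 1))
  ps <- render_pressure_mat(p)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pressure_frames(ps, f)
  back <- read_pressure_frames(f)
  expect_identical(dim(back$frames), dim(ps$frames))
  expect_equal(back$frames, ps$frames, ignore_attr = TRUE)
  expect_equal(back$time, ps$time, tolerance = 1e-9)
  expect_equal(back$calibration_scale, ps$calibration_scale, tolerance = 1e-9)
})

test_that("a mid-file grid-shape change fails with the frame index", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Frame 1, t=0.0", "0,1", "2,3",
               "Frame 2, t=0.1", "0,1,2", "3,4,5"), f)
  expect_error(read_pressure_frames(f), "shape changes at frame 2")
  writeLines(c("Frame 1, t=0.0", "0,1", "2,3,4"), f)
  expect_error(read_pressure_frames(f), "ragged rows in frame 1")
})

test_that("cohort tables validate tokens and the age inclusion rule", {
  f <- withr::local_tempfile(fileext = ".csv")
  hdr <- "dog_id,sex,breed_type,age,weight,height_withers,body_length,bcs"
  writeLines(c(hdr, "d1,female,long,4.5,5.2,19,27,3.5"), f)
  tab <- read_cohort_table(f)
  expect_equal(tab$breed_type, "long")
  expect_equal(tab$length_height_ratio, 27 / 19)

  writeLines(c(hdr, "d1,female,poodle,4.5,5.2,19,27,3.5"), f)
  expect_error(read_cohort_table(f), "unknown breed type 'poodle'")
  writeLines(c(hdr, "d1,spayed,long,4.5,5.2,19,27,3.5"), f)
  expect_error(read_cohort_table(f), "unknown sex token")
  writeLines(c(hdr, "d1,female,long,0.3,5.2,19,27,3.5"), f)
  expect_error(read_cohort_table(f), "inclusion rule")
  writeLines(hdr, f)
  expect_warning(tab <- read_cohort_table(f), "empty")
  expect_equal(nrow(tab), 0)
})

test_that("results tables round-trip through the hash-commented CSV form", {
  f <- withr::local_tempfile(fileext = ".csv")
  x <- tibble::tibble(measure = c("ap_range", "ml_range"), value = c(1.5, 2.5))
  write_results_table(x, f, meta = list(seed = 9, n = 2))
  back <- readr::read_csv(f, comment = "#", show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(x))
  expect_true(any(grepl("seed: 9", readLines(f))))
})
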