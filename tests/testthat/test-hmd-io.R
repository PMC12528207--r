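test_that("a small Mx fixture is echoed into a surface", {
  path <- write_mx_fixture(basic_mx_rows())
  s <- read_hmd_mx(path, column = "Total")
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$period), "1751–1754")
  expect_equal(s$period_start, rep(1751L, 3))
  expect_equal(s$period_end, rep(1754L, 3))
  expect_equal(s$age, 40:42)
  expect_equal(s$rate, c(0.01, 0.011, 0.012))
  expect_false(any(s$open_age))
})

test_that("open age class 110+ and '.' missing markers follow the format rules", {
  rows <- data.frame(
    year = "1900-1904", age = c("109", "110+"),
    female = ".", male = ".", total = c(".", "0.8")
  )
  s <- read_hmd_mx(write_mx_fixture(rows), column = "Total")
  expect_equal(s$age, c(109L, 110L))
  expect_equal(s$open_age, c(FALSE, TRUE))
  expect_true(is.na(s$rate[1]))
  expect_equal(s$rate[2], 0.8)
})

test_that("single years, en-dash ranges, and sex columns all parse", {
  rows <- data.frame(
    year = c("1900", "1901"), age = "40",
    female = c("0.004", "0.005"), male = ".", total = "0.01"
  )
  s <- read_hmd_mx(write_mx_fixture(rows), column = "Female")
  expect_equal(s$period, c("1900", "1901"))
  expect_equal(s$period_start, s$period_end)
  expect_equal(s$rate, c(0.004, 0.005))

  rows2 <- basic_mx_rows()
  rows2$year <- "1751–1754"  # en-dash on input
  s2 <- read_hmd_mx(write_mx_fixture(rows2), column = "Total")
  expect_equal(unique(s2$period), "1751–1754")
})

test_that("surface parsing is insensitive to input row order", {
  rows <- expand.grid(year = c("1900-1904", "1905-1909"),
                      age = as.character(40:44),
                      stringsAsFactors = FALSE)
  rows$female <- "."; rows$male <- "."
  rows$total <- sprintf("%.4f", runif(nrow(rows), 0.01, 0.02))
  shuffled <- rows[sample(nrow(rows)), ]
  s1 <- read_hmd_mx(write_mx_fixture(rows), column = "Total",
                    population = "testland")
  s2 <- read_hmd_mx(write_mx_fixture(shuffled), column = "Total",
                    population = "testland")
  expect_equal(s1, s2)
})

test_that("malformed inputs raise distinct descriptive errors", {
  rows <- basic_mx_rows()
  expect_error(read_hmd_mx(write_mx_fixture(rows), column = "Bogus"),
               class = "smcorr_column_error")

  dup <- rows[c(1, 1, 2), ]
  expect_error(read_hmd_mx(write_mx_fixture(dup), column = "Total"),
               class = "smcorr_duplicate_error")

  bad_age <- rows; bad_age$age[2] <- "forty"
  expect_error(read_hmd_mx(write_mx_fixture(bad_age), column = "Total"),
               "age", class = "smcorr_parse_error")

  bad_year <- rows; bad_year$year <- "long-ago"
  expect_error(read_hmd_mx(write_mx_fixture(bad_year), column = "Total"),
               class = "smcorr_parse_error")

  weird <- rows; weird$total[1] <- "n/a"
  expect_warning(s <- read_hmd_mx(write_mx_fixture(weird), column = "Total"),
                 "missing")
  expect_true(is.na(s$rate[1]))
})

test_that("params table write -> read round-trips full-precision values", {
  fits <- rotation_fits(alphas = c(0.0625731, 0.0619002, 0.0712345))
  fits$r2 <- c(0.98091, 0.98452, 0.99013)
  path <- withr::local_tempfile(fileext = ".csv")
  write_params_table(fits, path = path)
  back <- read_params_table(path, population = "rot")
  expect_identical(back$alpha, fits$alpha)
  expect_identical(back$ln_m0, fits$ln_m0)
  expect_identical(back$r2, fits$r2)
  expect_equal(back$period, fits$period)
})

test_that("params table display columns follow the 4/2/4 rounding and sign codes", {
  fits <- rotation_fits(alphas = c(0.0625, 0.0619))
  fits$ln_m0 <- c(-7.17, -6.93); fits$r2 <- c(0.9809, 0.9845)
  path <- withr::local_tempfile(fileext = ".csv")
  write_params_table(fits, path = path)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(raw)[1:6],
               c("period", "a", "first_diff", "sign", "ln_m0", "r2"))
  expect_equal(raw$a, c(0.0625, 0.0619))
  expect_equal(raw$first_diff, c(NA, -0.0006))
  expect_equal(raw$sign, c("x", "N"))
  expect_equal(raw$ln_m0, c(-7.17, -6.93))
})

test_that("empty and misaligned params tables are handled", {
  fits <- rotation_fits()[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_params_table(fits, diffs = first_differences(rotation_fits())[0, ],
                     path = path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 0)

  good <- rotation_fits(alphas = c(0.06, 0.07, 0.08))
  bad_diffs <- first_differences(good)[1:2, ]
  expect_error(write_params_table(good, bad_diffs, path),
               class = "smcorr_alignment_error")
})

test_that("read_params_table sorts shuffled rows and names missing columns", {
  fits <- rotation_fits(alphas = c(0.06, 0.07, 0.08))
  path <- withr::local_tempfile(fileext = ".csv")
  write_params_table(fits, path = path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(tab[c(3, 1, 2), ], path, na = "")
  back <- read_params_table(path)
  expect_equal(back$period_start, sort(fits$period_start))

  readr::write_csv(tab[, setdiff(names(tab), c("a", "a_full"))], path, na = "")
  expect_error(read_params_table(path), "a",
               class = "smcorr_column_error")
})

test_that("shipped parameter tables load with the published dimensions", {
  sw <- example_params("sweden")
  fr <- example_params("france")
  expect_equal(nrow(sw), 55)
  expect_equal(nrow(fr), 42)
  expect_equal(sw$period[1], "1751–1754")
  expect_equal(sw$period[55], "2020–2023")
  expect_equal(fr$period[1], "1815–1819")
  expect_equal(fr$period[42], "2020–2021")
  expect_equal(sw$alpha[1:2], c(0.0625, 0.0619))
})

test_that("surfaces written in the Mx dialect read back identically", {
  sim <- simulate_surface(simulation_spec(
    alpha_schedule = seq(0.06, 0.08, length.out = 4),
    noise_model = "poisson", seed = 7
  ))
  path <- withr::local_tempfile(fileext = ".txt")
  write_hmd_mx(sim$surface, path)
  back <- read_hmd_mx(path, column = "Total", population = "simulated")
  expect_equal(back, sim$surface)
})
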