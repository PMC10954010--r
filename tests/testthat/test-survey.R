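test_that("survey read/write round-trips values, order and derived columns", {
  sv <- generate(generator_params(n = 50, incomplete_rate = 0), seed = 303)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_survey(sv, f1)
  back <- read_survey(f1)
  expect_equal(back$id, sv$id)
  expect_equal(back$total_spend, sv$total_spend)
  expect_equal(back$days_staples, as.numeric(sv$days_staples))
  expect_equal(as.data.frame(back)[, names(back)],
               as.data.frame(sv)[, names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)

  # idempotence: write(read(write(x))) is byte-identical to write(x)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # derived columns survive the round trip
  scored <- classify_dataset(compute_indicators(complete_cases(sv)))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_survey(scored, f3)
  back3 <- read_survey(f3)
  expect_true(all(c("fcs", "pwfe", "csi_cat", "fsi") %in% names(back3)))
  expect_equal(back3$fsi, scored$fsi)
  expect_equal(back3$fcs_cat, scored$fcs_cat)
  expect_equal(back3$fsi_label, scored$fsi_label)
})

test_that("schema violations are reported by name; malformed cells become NA", {
  sv <- generate(generator_params(n = 5, incomplete_rate = 0), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(sv, f)

  txt <- readLines(f)
  expect_error(
    read_survey(textConnection(sub("total_spend", "totalspend", txt))),
    "total_spend")

  # blank a food_spend cell -> NA -> incomplete, not an error
  fields <- strsplit(txt, ",")
  i_fs <- match("food_spend", fields[[1]])
  fields[[2]][i_fs] <- ""
  broken <- vapply(fields, paste, "", collapse = ",")
  sv2 <- read_survey(textConnection(broken))
  expect_true(is.na(sv2$food_spend[1]))
  cc <- complete_cases(sv2)
  expect_equal(attr(cc, "dropped"), 1)
  expect_equal(nrow(cc), 4)

  # food days outside 0..7 are rejected with the household id
  fields2 <- strsplit(txt, ",")
  i_d <- match("days_staples", fields2[[1]])
  fields2[[3]][i_d] <- "9"
  expect_error(read_survey(textConnection(
    vapply(fields2, paste, "", collapse = ","))), "days_staples.*hh00002")
})

test_that("empty dataset writes a header-only file", {
  sv <- generate(generator_params(n = 3, incomplete_rate = 0), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(sv[0, ], f, config = indicator_config())
  expect_length(readLines(f), 1)
  expect_equal(nrow(read_survey(f)), 0)
})

test_that("complete_cases applies the all-indicator rule and is idempotent", {
  sv <- generate(generator_params(n = 400, incomplete_rate = 0.1), seed = 7)
  cc <- complete_cases(sv)
  expect_equal(attr(cc, "retained") + attr(cc, "dropped"), nrow(sv))
  cc2 <- complete_cases(cc)
  expect_equal(nrow(cc2), nrow(cc))
  expect_equal(attr(cc2, "dropped"), 0)

  # all-complete dataset passes through unchanged
  sv0 <- generate(generator_params(n = 30, incomplete_rate = 0), seed = 8)
  expect_equal(nrow(complete_cases(sv0)), 30)

  # zero or missing total spending makes a household incomplete
  sv0$total_spend[1] <- 0
  sv0$total_spend[2] <- NA
  cc0 <- complete_cases(sv0)
  expect_equal(attr(cc0, "dropped"), 2)
  expect_false(any(cc0$id %in% sv0$id[1:2]))

  # every record missing total_spend -> none retained
  sv0$total_spend <- NA
  expect_equal(nrow(complete_cases(sv0)), 0)
})

test_that("describe reproduces known frequencies and bands", {
  # 1162 female / 879 male heads -> 56.9% / 43.1%
  n <- 1162 + 879
  sv <- generate(generator_params(n = n, incomplete_rate = 0), seed = 5)
  sv$head_sex <- rep(c("female", "male"), c(1162, 879))
  d <- describe(sv)
  sex <- d$frequencies[d$frequencies$variable == "head_sex", ]
  expect_equal(sex$n, c(1162L, 879L))
  expect_equal(sex$pct, c(56.9, 43.1))

  # percentages within a variable total 100 (up to rounding)
  for (v in unique(d$frequencies$variable))
    expect_equal(sum(d$frequencies$pct[d$frequencies$variable == v]), 100,
                 tolerance = 0.2)

  # size bands honour <3 / 3-6 / >6
  sv$hh_size <- c(rep(2, 10), rep(3, 20), rep(6, 5), rep(7, 8),
                  rep(4, n - 43))
  bands <- describe(sv)$frequencies
  bands <- bands[bands$variable == "hh_size_band", ]
  expect_equal(bands$n[bands$category == "<3"], 10L)
  expect_equal(bands$n[bands$category == ">6"], 8L)

  # single household: 100% in each applicable category
  d1 <- describe(sv[1, ])
  expect_true(all(d1$frequencies$pct[d1$frequencies$n > 0] == 100))
})

test_that("describe recovers generator mixtures at large n", {
  sv <- generate(generator_params(n = 5000, incomplete_rate = 0), seed = 21)
  d <- describe(sv)
  f <- d$frequencies
  expect_equal(f$pct[f$variable == "head_sex" & f$category == "female"],
               56.9, tolerance = 2)
  expect_equal(f$pct[f$variable == "civil_status" &
                       f$category == "married_or_couple"],
               50.8, tolerance = 2)
  expect_equal(f$pct[f$variable == "hh_size_band" & f$category == "3-6"],
               59.4, tolerance = 2)
  expect_equal(d$head_age$mean, 48.7, tolerance = 1.5)
})

test_that("indicator config round-trips through YAML", {
  cfg <- indicator_config(alpha = 0.01,
                          fcs_cutoffs = c(poor_max = 21, borderline_max = 35))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$fcs_cutoffs, cfg$fcs_cutoffs)
  expect_equal(back$alpha, 0.01)
  expect_equal(back$food_groups, cfg$food_groups)
  expect_equal(back$four_point_map, cfg$four_point_map)
})
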