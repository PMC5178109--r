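test_that("age strata cover all ages and match the documented boundaries", {
  expect_equal(assign_stratum(10), "NB_2MO")
  expect_equal(assign_stratum(0), "NB_2MO")
  expect_equal(assign_stratum(200), "3_11MO")
  expect_equal(
    assign_stratum(c(90, 91, 364, 365, 1825, 1826, 4748, 4749, 20000)),
    c("NB_2MO", "3_11MO", "3_11MO", "1_4Y", "1_4Y", "5_12Y", "5_12Y",
      "GT_12Y", "GT_12Y"))
  expect_error(assign_stratum(-1), "non-negative")
  # every age maps to exactly one stratum
  tbl <- load_vipe_tables()
  for (a in c(0:5, sample(0:8000, 50))) {
    hits <- sum(a >= tbl$strata$lower_days & a <= tbl$strata$upper_days)
    expect_identical(hits, 1L)
  }
})

test_that("parameter sub-scores follow the band tables", {
  expect_equal(score_parameter(40, "RR", "NB_2MO"), 0L)
  expect_equal(score_parameter(91, "SPO2", "1_4Y"), 2L)
  # printed overlap in the 5-12 y HR row: 50 claimed by '<51' (4) and
  # '50-60' (2); the worst-case rule assigns 4
  expect_equal(score_parameter(50, "HR", "5_12Y"), 4L)
  # rounding half away from zero onto the integer grid
  expect_equal(score_parameter(29.5, "RR", "NB_2MO"), 0L)  # -> 30
  expect_equal(score_parameter(29.4, "RR", "NB_2MO"), 1L)  # -> 29
  expect_equal(score_parameter(90.5, "RR", "NB_2MO"), 4L)  # -> 91
  expect_error(score_parameter(105, "SPO2", "1_4Y"), "<= 100")
  expect_error(score_parameter(40, "XX", "1_4Y"), "unknown parameter")
})

test_that("fever correction applies only with elevated heart rate", {
  expect_equal(temperature_correction(39.0, 3), -2L)
  expect_equal(temperature_correction(39.0, 0), 0L)
  expect_equal(temperature_correction(37.5, 2), -1L)
  expect_equal(temperature_correction(38.5, 4), -1L)  # inclusive upper edge
  expect_equal(temperature_correction(38.6, 2), -2L)
  expect_equal(temperature_correction(37.4, 4), 0L)
  expect_warning(temperature_correction(45, 2), "physiologic range")
  expect_error(temperature_correction(38, 7), "0..4")
})

test_that("vipe_score sums sub-scores, applies correction, clamps and colors", {
  v <- vipe_score(list(rr = 40, hr = 120, spo2 = 97, axtemp = 36.5), 10)
  expect_equal(v$total, 0L)
  expect_equal(v$color, "BLUE")

  v <- vipe_score(list(rr = 65, hr = 155, spo2 = 93, axtemp = 39.0), 730)
  expect_equal(c(v$rr_score, v$hr_score, v$spo2_score), c(3L, 3L, 1L))
  expect_equal(v$temp_correction, -2L)
  expect_equal(v$total, 5L)
  expect_equal(v$color, "YELLOW")

  v <- vipe_score(list(rr = 75, hr = 175, spo2 = 89, axtemp = 36.8), 730)
  expect_equal(v$total, 12L)
  expect_equal(v$color, "RED")

  # clamp at zero: sub-scores 0 + 2 + 0 with correction -2
  v <- vipe_score(list(rr = 40, hr = 160, spo2 = 97, axtemp = 39.0), 10)
  expect_equal(v$temp_correction, -2L)
  expect_equal(v$total, 0L)
  expect_equal(v$color, "BLUE")

  expect_error(vipe_score(list(rr = 40, hr = 120, spo2 = NA, axtemp = 36.5), 10),
               "'spo2'")
  expect_error(vipe_score(list(rr = 40, hr = 120, spo2 = 97), 10), "'axtemp'")
})

test_that("color legend maps totals piecewise", {
  expect_equal(color_from_total(c(0, 1, 2, 3, 5, 6, 9, 10, 12)),
               c("BLUE", "GREEN", "GREEN", "YELLOW", "YELLOW", "ORANGE",
                 "ORANGE", "RED", "RED"))
  expect_error(color_from_total(13), "0..12")
  expect_error(color_from_total(-1), "0..12")
})

test_that("sub-scores are monotone moving away from the zero band", {
  tbl <- load_vipe_tables()
  for (sid in tbl$strata$id) {
    for (par in c("RR", "HR", "SPO2")) {
      cap <- if (par == "SPO2") 100 else 250
      sc <- vapply(0:cap, score_parameter, integer(1), par, sid, tbl)
      expect_true(all(sc %in% 0:4), info = paste(sid, par))
      z <- range(which(sc == 0))
      left <- sc[seq_len(z[1])]
      right <- sc[z[2]:length(sc)]
      expect_false(is.unsorted(rev(left)), info = paste(sid, par, "low side"))
      expect_false(is.unsorted(right), info = paste(sid, par, "high side"))
    }
  }
})

test_that("correction is gated on elevated heart rate (randomized)", {
  set.seed(11)
  tbl <- load_vipe_tables()
  for (i in 1:200) {
    age <- sample(0:6000, 1)
    v <- list(rr = runif(1, 0, 120), hr = runif(1, 30, 230),
              spo2 = runif(1, 70, 100), axtemp = runif(1, 35, 41))
    r <- vipe_score(v, age, tbl)
    if (r$temp_correction != 0L) expect_gte(r$hr_score, 2L)
    expect_gte(r$total, 0L)
    expect_lte(r$total, 12L)
    expect_equal(r$total,
                 max(0L, r$rr_score + r$hr_score + r$spo2_score + r$temp_correction))
  }
})

test_that("table loader rejects malformed configurations", {
  tbl <- jsonlite::fromJSON(system.file("extdata", "vipe_tables.json",
                                        package = "clariped"),
                            simplifyVector = FALSE)
  # coverage gap
  bad <- tbl
  bad$bands$NB_2MO$RR[[4]] <- list(30L, 50L, 0L)  # was 30-60; 51-60 now unclaimed
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f, auto_unbox = TRUE, null = "null", digits = NA)
  expect_error(load_vipe_tables(f), "coverage gap")
  # two zero bands
  bad <- tbl
  bad$bands$NB_2MO$RR[[3]] <- list(20L, 29L, 0L)
  jsonlite::write_json(bad, f, auto_unbox = TRUE, null = "null", digits = NA)
  expect_error(load_vipe_tables(f), "band shape")
  # the bundled table flags its known printed overlap
  expect_warning(
    load_vipe_tables(system.file("extdata", "vipe_tables.json", package = "clariped")),
    "overlapping bands in 5_12Y/HR")
})
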