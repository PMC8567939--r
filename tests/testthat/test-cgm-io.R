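test_that("CGM CSV write then read is the identity for valid traces", {
  f <- withr::local_tempfile(fileext = ".csv")
  tr1 <- glucose_trace("A1", "pre", seq(0, 1440 * 3 - 15, by = 15),
                       rep(c(5.1, 6.25, 4.8), length.out = 288))
  g2 <- rep(5.5, 96); g2[c(10, 40)] <- NA  # gaps survive the round trip
  tr2 <- glucose_trace("A2", "post", seq(0, 1440 - 15, by = 15), g2)
  write_cgm_csv(list(tr1, tr2), f)
  back <- read_cgm_csv(f)
  expect_length(back, 2)
  expect_equal(back[["A1.pre"]]$time, tr1$time)
  expect_equal(back[["A1.pre"]]$glucose, tr1$glucose, tolerance = 1e-9)
  expect_equal(back[["A2.post"]]$glucose, g2, tolerance = 1e-9)
  # a gapless 3-day 15-min file yields 288 samples
  expect_length(back[["A1.pre"]]$glucose, 3 * 24 * 60 / 15)
  rep <- attr(back, "report")
  expect_equal(rep$parsed + rep$missing, rep$rows)
})

test_that("malformed CGM files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  tr <- glucose_trace("A1", "pre", c(0, 15, 30, 45), c(5, 5.2, 5.1, 5.3))
  write_cgm_csv(tr, f)
  lines <- readLines(f)
  writeLines(lines[c(1, 2, 4, 3, 5)], f)  # shuffle one timestamp
  expect_error(read_cgm_csv(f), "non-monotone")
  writeLines(gsub("glucose_mmol_l", "glucose", lines), f)
  expect_error(read_cgm_csv(f), "missing required columns")
  expect_error(read_cgm_csv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("unparseable glucose rows become counted missing samples", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,period,timestamp,glucose_mmol_l",
               "A1,pre,2021-03-01T00:00:00,5.0",
               "A1,pre,2021-03-01T00:15:00,LO",
               "A1,pre,2021-03-01T00:30:00,5.4"), f)
  back <- read_cgm_csv(f)
  expect_equal(back[["A1.pre"]]$glucose, c(5.0, NA, 5.4))
  expect_equal(attr(back, "report")$missing, 1)
})

test_that("diary lines merge into meals within the 15-minute window", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,period,timestamp,item,carbs_g",
               "A1,pre,2021-03-01T08:00:00,porridge,20",
               "A1,pre,2021-03-01T08:05:00,juice,10",
               "A1,pre,2021-03-01T12:30:00,sandwich,35"), f)
  meals <- read_food_diary(f)
  expect_equal(nrow(meals), 2)
  expect_equal(meals$carbs, c(30, 35))
  rep <- attr(meals, "report")
  expect_equal(rep$merged + rep$meals, rep$rows)

  # distinct times stay distinct
  writeLines(c("patient_id,period,timestamp,item,carbs_g",
               "A1,pre,2021-03-01T08:00:00,a,20",
               "A1,pre,2021-03-01T10:00:00,b,10",
               "A1,pre,2021-03-01T12:30:00,c,35"), f)
  expect_equal(nrow(read_food_diary(f)), 3)

  writeLines(c("patient_id,period,timestamp,item,carbs_g",
               "A1,pre,2021-03-01T08:00:00,a,-1"), f)
  expect_error(read_food_diary(f), "carbohydrate")
})

test_that("align_period windows the trace and applies the meal carry-in rule", {
  # 14-day trace; diary on days 3-5
  tr <- glucose_trace("A1", "pre", seq(0, 14 * 1440 - 15, by = 15),
                      rep(5.5, 14 * 96))
  day3 <- 2 * 1440
  meals <- data.frame(patient_id = "A1", period = "pre",
                      time = c(day3 - 60,         # 1 h before: kept
                               day3 - 300,        # 5 h before: dropped
                               day3 + 500, day3 + 2000),
                      carbs = c(30, 40, 50, 60))
  attr(meals, "origin") <- tr$origin
  ds <- align_period(tr, meals, days = 3,
                     window_start = tr$origin + day3 * 60)
  expect_equal(length(ds$times), 3 * 96)
  expect_equal(range(ds$times), c(0, 3 * 1440 - 15))
  expect_equal(sort(ds$meals$carbs), c(30, 50, 60))
  expect_equal(min(ds$meals$time), -60)

  # empty overlap
  tr2 <- glucose_trace("A1", "pre", c(0, 15), c(5, 5),
                       origin = as.POSIXct("2020-01-01", tz = "UTC"))
  expect_error(align_period(tr2, meals, meal_origin = tr$origin), "overlap")
})
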