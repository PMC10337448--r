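test_that("allowed_fraction follows the stepped 3-day blocks", {
  expect_equal(allowed_fraction(1), 0.85)
  expect_equal(allowed_fraction(12), 0.40)
  expect_equal(allowed_fraction(21), 0.10)
  expect_equal(allowed_fraction(1:21),
               rep(c(0.85, 0.70, 0.55, 0.40, 0.30, 0.20, 0.10), each = 3))
  expect_true(all(diff(allowed_fraction(1:21)) <= 0))
  expect_error(allowed_fraction(0), "1\\.\\.21")
  expect_error(allowed_fraction(22), "1\\.\\.21")
  expect_error(allowed_fraction(1.5), "integer")
})

test_that("daily quota rounds half-up, clamps at 3 and freezes at 3-4", {
  p23 <- smoker_profile(23, "07:00", "23:00")
  expect_equal(daily_quota(p23, 1)$quota, 20)   # round(19.55)
  expect_equal(daily_quota(p23, 16)$quota, 5)   # round(4.6)
  d21 <- daily_quota(p23, 21)
  expect_equal(d21$quota, 3)                    # round(2.3) clamped to 3
  expect_true(d21$frozen)
  # once frozen the quota never moves again
  for (cpd in c(10, 12, 15, 23, 40, 57)) {
    q <- vapply(1:21, function(d) {
      daily_quota(smoker_profile(cpd, 420, 1380), d)$quota
    }, 0)
    first_low <- which(q <= 4)[1]
    expect_true(all(q[first_low:21] == q[first_low]), label = paste(cpd))
    expect_true(all(diff(q) <= 0))
    expect_true(all(q >= 3))
  }
})

test_that("intercigarette interval is waking minutes over quota", {
  expect_equal(intercigarette_interval(960, 16), 60)
  expect_equal(intercigarette_interval(960, 7), 960 / 7)
  expect_equal(intercigarette_interval(960, 960), 1)
  expect_error(intercigarette_interval(960, 0), "quota")
  expect_error(intercigarette_interval(0, 5), "waking")
})

test_that("quarter rounding snaps to nearest grid point, ties later", {
  expect_equal(round_to_quarter(547), 540)  # 09:07 -> 09:00
  expect_equal(round_to_quarter(548), 555)  # 09:08 -> 09:15
  expect_equal(round_to_quarter(540), 540)  # fixed point
  expect_equal(round_to_quarter(547.5), 555)  # midpoint rounds up
  expect_true(all(round_to_quarter(runif(500, 0, 1439)) %% 15 == 0))
})

test_that("weekly delay is cumulative from week 1", {
  expect_equal(weekly_delay(1), 15)
  expect_equal(weekly_delay(2), 30)
  expect_equal(weekly_delay(3) - weekly_delay(2), 15)
  expect_error(weekly_delay(0))
  expect_error(weekly_delay(4))
})

test_that("generate_day honours delay, rounding and bedtime truncation", {
  p <- smoker_profile(20, "07:00", "23:00")
  d8 <- generate_day(p, 8)
  expect_equal(d8$prompt_times[1], parse_clock("07:30")) # wake + 30
  d1 <- generate_day(p, 1)
  expect_equal(d1$prompt_times[1], parse_clock("07:15"))
  expect_true(all(d1$prompt_times %% 15 == 0))
  expect_true(all(d1$prompt_times < p$bed_time))
  expect_lte(length(d1$prompt_times), d1$quota)
  expect_true(all(diff(d1$prompt_times) > 0))
})

test_that("a cramped waking window degrades gracefully", {
  expect_warning(p <- smoker_profile(4, 420, 460), "inclusion floor")
  # quota floor of 3 in a 40-minute window: at least one prompt survives
  d <- generate_day(p, 1)
  expect_gte(length(d$prompt_times), 1)
  expect_true(all(d$prompt_times < 460))
})

test_that("full schedules satisfy the printed anchors", {
  s <- generate_schedule(smoker_profile(23, "07:00", "23:00"))
  counts <- vapply(s$days, function(d) length(d$prompt_times), 0L)
  expect_length(s$days, 21)
  expect_lte(counts[21], 4)                       # 3-4 the day before quit
  expect_gte(100 * (23 - counts[16]) / 23, 75)    # >=75% by week 3
  expect_true(s$quotas$quota[21] %in% 3:4)
  expect_true(all(diff(s$quotas$quota) <= 0))
  s10 <- generate_schedule(smoker_profile(10, "06:00", "22:00"))
  expect_true(all(s10$quotas$quota >= 3))
})

test_that("brute-force enumerator reproduces generate_day exactly", {
  set.seed(42)
  for (i in 1:100) {
    p <- random_profile()
    day <- sample(1:21, 1)
    got <- generate_day(p, day)
    want <- oracle_day_times(p$baseline_cpd, p$wake_time, p$bed_time, day)
    expect_identical(got$prompt_times, want,
                     label = sprintf("cpd=%d wake=%d bed=%d day=%d",
                                     p$baseline_cpd, p$wake_time,
                                     p$bed_time, day))
    expect_identical(got$quota, oracle_quotas(p$baseline_cpd)[day])
  }
})

test_that("schedule-wide invariants hold over randomized profiles", {
  set.seed(7)
  for (i in 1:25) {
    p <- random_profile()
    s <- generate_schedule(p)
    times <- unlist(lapply(s$days, `[[`, "prompt_times"))
    expect_true(all(times %% 15 == 0))            # quarter grid
    expect_true(all(times < p$bed_time))          # truncation
    counts <- vapply(s$days, function(d) length(d$prompt_times), 0L)
    expect_true(all(counts <= s$quotas$quota))
    expect_true(s$quotas$quota[21] %in% 3:4)
    # exactly 15 minutes between week-over-week first prompts
    expect_equal(s$days[[8]]$prompt_times[1] - s$days[[7]]$prompt_times[1],
                 15)
    expect_equal(s$days[[15]]$prompt_times[1] -
                   s$days[[14]]$prompt_times[1], 15)
  }
})

test_that("schedule flattening and CSV round-trip keep every prompt", {
  s <- generate_schedule(smoker_profile(23, "07:00", "23:00"))
  df <- as.data.frame(s)
  expect_named(df, c("day", "week", "quota", "ici_minutes",
                     "prompt_index", "prompt_time"))
  expect_equal(nrow(df),
               sum(vapply(s$days, function(d) length(d$prompt_times), 0L)))
  path <- tempfile(fileext = ".csv")
  write_schedule_csv(s, path)
  back <- read.csv(path, colClasses = c(prompt_time = "character"))
  expect_equal(nrow(back), nrow(df))
  expect_equal(parse_clock(back$prompt_time[1]),
               s$days[[1]]$prompt_times[1])
})

test_that("profile validation rejects unusable inputs", {
  expect_error(smoker_profile(20, "23:00", "07:00"), "overnight")
  expect_error(smoker_profile(-3, "07:00", "23:00"), "positive")
  expect_warning(smoker_profile(8, "07:00", "23:00"), "inclusion floor")
  expect_error(parse_clock("25:00"), "invalid|1440")
})
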