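# 21-day gradual-reduction ("scheduled smoking") schedule generator.
#
# The precessation programme spaces a shrinking daily cigarette quota evenly
# over the waking day: the intercigarette interval is waking minutes divided
# by the day's quota, the permitted fraction of baseline steps down every
# three days (15 percentage points per block over days 1-12, then 10 points
# per block over days 13-21), a cumulative 15-minute delay pushes the first
# cigarette later each week, prompts snap to the quarter-hour grid, and
# anything pushed past bedtime is dropped. Once the quota reaches 3-4
# cigarettes it is frozen until the quit date.

#' Smoker profile for schedule generation
#'
#' Bundles the three self-report quantities that drive the reduction
#' schedule: baseline smoking rate and the waking window.
#'
#' @param baseline_cpd baseline cigarettes per day (positive). Values below
#'   10 are outside the population the programme was designed for and
#'   trigger a warning, not an error.
#' @param wake_time,bed_time clock times, either `"HH:MM"` strings or
#'   numeric minutes from midnight. `bed_time` must be later than
#'   `wake_time`; overnight (wrap-around) waking windows are not supported.
#' @return an object of class `smoker_profile` with elements
#'   `baseline_cpd`, `wake_time`, `bed_time` and `waking_minutes`.
#' @examples
#' smoker_profile(23, "07:00", "23:00")
#' @export
smoker_profile <- function(baseline_cpd, wake_time, bed_time) {
  if (!is.numeric(baseline_cpd) || length(baseline_cpd) != 1L ||
      !is.finite(baseline_cpd) || baseline_cpd <= 0) {
    stop("baseline_cpd must be a single positive number")
  }
  if (baseline_cpd < 10) {
    warning("baseline_cpd < 10 is below the intended inclusion floor ",
            "of 10 cigarettes/day")
  }
  wake <- parse_clock(wake_time)
  bed <- parse_clock(bed_time)
  if (length(wake) != 1L || length(bed) != 1L) {
    stop("wake_time and bed_time must be single times")
  }
  if (bed <= wake) {
    stop("bed_time must be after wake_time (overnight waking windows ",
         "are not supported)")
  }
  structure(
    list(baseline_cpd = baseline_cpd, wake_time = wake, bed_time = bed,
         waking_minutes = bed - wake),
    class = "smoker_profile"
  )
}

#' @export
print.smoker_profile <- function(x, ...) {
  cat(sprintf("Smoker profile: %.1f cig/day, awake %s-%s (%d min)\n",
              x$baseline_cpd, format_clock(x$wake_time),
              format_clock(x$bed_time), as.integer(x$waking_minutes)))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Permitted fraction of baseline smoking for a schedule day
#'
#' Days 1-12 step the baseline rate down by 15 percentage points every
#' 3 days and days 13-21 by 10 points every 3 days, so the seven 3-day
#' blocks permit 85, 70, 55, 40, 30, 20 and 10 percent of baseline. The
#' fraction is returned before the 3-4 cigarette floor is applied.
#'
#' @param day integer day of the schedule, 1 to 21 (vectorized).
#' @return permitted proportion of the baseline rate, in (0, 1].
#' @examples
#' allowed_fraction(1)   # 0.85
#' allowed_fraction(21)  # 0.10
#' @export
allowed_fraction <- function(day) {
  if (!is.numeric(day) || any(!is.finite(day)) ||
      any(day != floor(day)) || any(day < 1 | day > 21)) {
    stop("day must be an integer in 1..21")
  }
  block <- (day - 1) %/% 3            # 3-day block index, 0..6
  # Reduction applies from day 1: blocks 0..3 (days 1-12) at 85/70/55/40,
  # blocks 4..6 (days 13-21) at 30/20/10 percentage points of baseline.
  points <- ifelse(block <= 3, 85 - 15 * block, 30 - 10 * (block - 4))
  points / 100
}

#' Schedule week of a day (1-7 -> 1, 8-14 -> 2, 15-21 -> 3)
#' @param day integer day in 1..21.
#' @return integer week 1..3.
#' @export
schedule_week <- function(day) {
  if (any(day < 1 | day > 21)) stop("day must be in 1..21")
  as.integer((day - 1) %/% 7 + 1)
}

#' Cumulative delay to the first cigarette of the day
#'
#' A 15-minute delay to the day's first cigarette is added each week of the
#' schedule, cumulatively and including week 1, so weeks 1-3 delay the
#' first prompt by 15, 30 and 45 minutes relative to wake time.
#'
#' @param week integer week of the schedule, 1..3.
#' @return delay in minutes.
#' @export
weekly_delay <- function(week) {
  if (!is.numeric(week) || any(week != floor(week)) ||
      any(week < 1 | week > 3)) {
    stop("week must be an integer in 1..3")
  }
  15 * week
}

#' Intercigarette interval
#'
#' The waking day divided evenly among the day's scheduled cigarettes.
#'
#' @param waking_minutes minutes awake per day (> 0).
#' @param quota number of cigarettes scheduled for the day (>= 1).
#' @return interval in minutes (real, unrounded).
#' @examples
#' intercigarette_interval(960, 16) # one per hour
#' @export
intercigarette_interval <- function(waking_minutes, quota) {
  if (any(waking_minutes <= 0)) stop("waking_minutes must be positive")
  if (any(quota < 1)) stop("quota must be at least 1")
  waking_minutes / quota
}

#' Snap a clock time to the nearest quarter hour
#'
#' Times are adjusted to the nearest quarter within the hour (…:00, :15,
#' :30, :45). Exact midpoints (7.5 minutes from both neighbours) round to
#' the later quarter.
#'
#' @param t clock time in minutes from midnight (vectorized).
#' @return nearest multiple of 15 minutes.
#' @examples
#' round_to_quarter(547) # 540 (09:07 -> 09:00)
#' round_to_quarter(548) # 555 (09:08 -> 09:15)
#' @export
round_to_quarter <- function(t) {
  if (any(t < 0)) stop("t must be non-negative")
  round_half_up(t / 15) * 15
}

# Quota path for all 21 days: round-half-up of fraction x baseline, clamped
# to >= 3; the first day whose quota lands in the 3-4 floor freezes the
# quota at that value for all remaining days. The final 3-day block is
# additionally capped at 4: the programme's endpoint is 3-4 cigarettes the
# day before quitting, which 10% of a very heavy baseline (> 44/day) would
# otherwise overshoot.
quota_path <- function(baseline_cpd) {
  quota <- integer(21)
  frozen <- logical(21)
  frozen_at <- NA_integer_
  for (d in 1:21) {
    if (!is.na(frozen_at)) {
      quota[d] <- quota[frozen_at]
      frozen[d] <- TRUE
    } else {
      cand <- round_half_up(allowed_fraction(d) * baseline_cpd)
      if (d >= 19) cand <- min(cand, 4)
      q <- as.integer(max(cand, 3))
      quota[d] <- q
      if (q <= 4) {
        frozen_at <- d
        frozen[d] <- TRUE
      }
    }
  }
  data.frame(day = 1:21, allowed_fraction = allowed_fraction(1:21),
             quota = quota, frozen = frozen)
}

#' Daily cigarette quota
#'
#' Applies the permitted fraction to the baseline rate with half-up
#' rounding, clamps to a floor of 3 cigarettes, and freezes the quota once
#' it first reaches the 3-4 cigarette floor (no further reductions until
#' the quit date). The final 3-day block is capped at 4 so that every
#' schedule ends at the programme's stated 3-4 cigarette endpoint, which
#' 10% of a very heavy baseline would otherwise overshoot.
#'
#' @param profile a [smoker_profile()].
#' @param day integer day in 1..21.
#' @return one-row data.frame with `day`, `allowed_fraction`, `quota`,
#'   `frozen`.
#' @examples
#' p <- smoker_profile(23, "07:00", "23:00")
#' daily_quota(p, 16)$quota # 5
#' daily_quota(p, 21)$quota # 3 (floor reached and frozen)
#' @export
daily_quota <- function(profile, day) {
  stopifnot(inherits(profile, "smoker_profile"))
  if (length(day) != 1L || day < 1 || day > 21 || day != floor(day)) {
    stop("day must be an integer in 1..21")
  }
  quota_path(profile$baseline_cpd)[day, , drop = FALSE]
}

#' Generate the prompt times for one schedule day
#'
#' The first (unrounded) prompt falls at wake time plus the week's
#' cumulative delay; subsequent prompts follow at intercigarette-interval
#' increments. Each time in the unrounded arithmetic sequence is snapped to
#' the quarter-hour grid independently (no accumulation of rounding error),
#' and any prompt falling at or past bedtime is dropped.
#'
#' @inheritParams daily_quota
#' @return list with `day`, `week`, `quota`, `ici_minutes` and
#'   `prompt_times` (minutes from midnight, strictly increasing, all on the
#'   quarter grid).
#' @examples
#' p <- smoker_profile(20, "07:00", "23:00")
#' format_clock(generate_day(p, 8)$prompt_times[1]) # "07:30"
#' @export
generate_day <- function(profile, day) {
  q <- daily_quota(profile, day)
  week <- schedule_week(day)
  ici <- intercigarette_interval(profile$waking_minutes, q$quota)
  raw <- profile$wake_time + weekly_delay(week) + (seq_len(q$quota) - 1) * ici
  times <- round_to_quarter(raw)
  times <- unique(times[times < profile$bed_time])
  if (length(times) == 0L) {
    warning(sprintf("day %d: no prompt fits inside the waking window", day))
  }
  list(day = as.integer(day), week = week, quota = q$quota,
       ici_minutes = ici, prompt_times = times)
}

#' Generate the full 21-day reduction schedule
#'
#' @param profile a [smoker_profile()].
#' @return object of class `reduction_schedule`: a list with the `profile`,
#'   `quotas` (21-row data.frame from the quota path) and `days` (list of 21
#'   [generate_day()] results).
#' @examples
#' sched <- generate_schedule(smoker_profile(23, "07:00", "23:00"))
#' length(sched$days[[21]]$prompt_times) # 3 cigarettes the day before quit
#' @export
generate_schedule <- function(profile) {
  stopifnot(inherits(profile, "smoker_profile"))
  structure(
    list(profile = profile,
         quotas = quota_path(profile$baseline_cpd),
         days = lapply(1:21, function(d) generate_day(profile, d))),
    class = "reduction_schedule"
  )
}

#' @export
print.reduction_schedule <- function(x, ...) {
  print(x$profile)
  counts <- vapply(x$days, function(d) length(d$prompt_times), 0L)
  cat("21-day reduction schedule; scheduled cigarettes per day:\n")
  cat(paste(counts, collapse = " "), "\n")
  cat(sprintf("Day 21 first/last prompt: %s / %s\n",
              format_clock(x$days[[21]]$prompt_times[1]),
              format_clock(rev(x$days[[21]]$prompt_times)[1])))
  invisible(x)
}

#' Flatten a reduction schedule to one row per prompt
#'
#' @param x a `reduction_schedule`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return data.frame with columns `day`, `week`, `quota`, `ici_minutes`,
#'   `prompt_index`, `prompt_time` (`"HH:MM"`).
#' @export
as.data.frame.reduction_schedule <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  rows <- lapply(x$days, function(d) {
    n <- length(d$prompt_times)
    if (n == 0L) return(NULL)
    data.frame(day = d$day, week = d$week, quota = d$quota,
               ici_minutes = d$ici_minutes, prompt_index = seq_len(n),
               prompt_time = format_clock(d$prompt_times))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a schedule to CSV
#'
#' One row per prompt with columns `day, week, quota, ici_minutes,
#' prompt_index, prompt_time`.
#'
#' @param schedule a `reduction_schedule`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
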