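# Compliance measures: expired-CO percent reduction with the >=50% cutoff,
# and on-schedule adherence from prompt/event logs.

#' Percent reduction in expired carbon monoxide
#'
#' `100 * (baseline - final) / baseline`. Negative when CO rose. Reduction
#' is scale-free: multiplying both readings by a positive constant leaves
#' it unchanged.
#'
#' @param co_baseline expired CO at baseline, ppm (> 0).
#' @param co_final expired CO at the last precessation visit, ppm (>= 0).
#' @return percent reduction (vectorized).
#' @examples
#' co_percent_reduction(30, 15) # 50
#' @export
co_percent_reduction <- function(co_baseline, co_final) {
  if (any(!is.finite(co_baseline)) || any(co_baseline <= 0)) {
    stop("co_baseline must be positive")
  }
  if (any(!is.finite(co_final)) || any(co_final < 0)) {
    stop("co_final must be non-negative")
  }
  100 * (co_baseline - co_final) / co_baseline
}

#' Classify schedule compliance from CO percent reduction
#'
#' A participant counts as compliant with the reduction schedule when their
#' expired CO fell by at least the threshold (default 50%, inclusive).
#'
#' @param percent_reduction percent CO reduction (vectorized), e.g. from
#'   [co_percent_reduction()].
#' @param threshold compliance cutoff in percent; default 50.
#' @return data.frame with `percent_reduction`, `compliant` (logical),
#'   `threshold`.
#' @examples
#' classify_compliance(c(50, 49.99, -10))$compliant
#' @export
classify_compliance <- function(percent_reduction, threshold = 50) {
  stopifnot(is.numeric(percent_reduction), length(threshold) == 1L,
            is.finite(threshold))
  data.frame(percent_reduction = percent_reduction,
             compliant = percent_reduction >= threshold,
             threshold = threshold)
}

#' Schedule adherence from prompt and smoking-event logs
#'
#' Each smoked cigarette is matched one-to-one to the nearest unmatched
#' scheduled prompt within `window` minutes (symmetric, boundary
#' inclusive), taking the closest pairs first. Matched events are
#' "on schedule"; events with no prompt available inside the window are
#' "off schedule". Missing a scheduled cigarette is permissible, so
#' unmatched prompts are not violations: they only depress the on-schedule
#' proportion, whose denominator is the number of scheduled prompts.
#'
#' @param prompts sorted numeric vector of scheduled prompt times (minutes).
#' @param events sorted numeric vector of smoked-cigarette times (minutes).
#' @param window matching tolerance in minutes (>= 0); default 5.
#' @return list with `n_scheduled`, `n_on_schedule`, `prop_on_schedule`,
#'   `n_off_schedule`, `window_minutes`.
#' @examples
#' schedule_adherence(prompts = c(600, 720), events = c(603, 700))
#' @export
schedule_adherence <- function(prompts, events, window = 5) {
  if (is.unsorted(prompts) || is.unsorted(events)) {
    stop("prompts and events must be sorted in increasing time order")
  }
  if (window < 0) stop("window must be non-negative")
  n_p <- length(prompts)
  n_e <- length(events)
  matched_e <- logical(n_e)
  matched_p <- logical(n_p)
  if (n_p > 0L && n_e > 0L) {
    d <- abs(outer(events, prompts, "-"))
    repeat {
      d[matched_e, ] <- Inf
      d[, matched_p] <- Inf
      if (all(!is.finite(d)) || min(d) > window) break
      idx <- arrayInd(which.min(d), dim(d))
      matched_e[idx[1]] <- TRUE
      matched_p[idx[2]] <- TRUE
    }
  }
  n_on <- sum(matched_e)
  list(n_scheduled = n_p,
       n_on_schedule = n_on,
       prop_on_schedule = if (n_p > 0L) n_on / n_p else NA_real_,
       n_off_schedule = n_e - n_on,
       window_minutes = window)
}
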