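#' Parse a clock time to minutes from midnight
#'
#' Accepts `"HH:MM"` strings or bare numeric minutes. Times must fall within
#' a single day (0--1439 minutes).
#'
#' @param x character `"HH:MM"` vector or numeric minutes from midnight.
#' @return numeric vector of minutes from midnight.
#' @examples
#' parse_clock("07:00")
#' parse_clock(c("07:00", "23:15"))
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    out <- as.numeric(x)
  } else {
    m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", as.character(x)))
    bad <- vapply(m, length, 0L) != 3L
    if (any(bad)) {
      stop("invalid clock time(s): ", paste(x[bad], collapse = ", "))
    }
    out <- vapply(m, function(p) as.numeric(p[2]) * 60 + as.numeric(p[3]), 0)
  }
  if (any(!is.finite(out) | out < 0 | out >= 1440)) {
    stop("clock times must lie in [0, 1440) minutes from midnight")
  }
  out
}

#' Format minutes from midnight as "HH:MM"
#'
#' @param minutes numeric minutes from midnight; values are floored to whole
#'   minutes.
#' @return character vector.
#' @examples
#' format_clock(465)
#' @export
format_clock <- function(minutes) {
  minutes <- floor(minutes) %% 1440
  sprintf("%02d:%02d", minutes %/% 60, minutes %% 60)
}
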