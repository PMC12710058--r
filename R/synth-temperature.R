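# Treatment designs and diurnal temperature profiles.

#' Treatment design
#'
#' @param day_max_c,day_min_c Daily maximum / minimum air temperature (degC).
#' @param duration_days Treatment duration in days (positive integer;
#'   the factorial uses 3, 6, 9).
#' @param label Treatment marker, e.g. "T4D3" or "CK".
#' @param is_control Control-group flag.
#' @return A `treatment_design` list.
#' @export
treatment_design <- function(day_max_c, day_min_c, duration_days, label,
                             is_control = FALSE) {
  if (day_max_c <= day_min_c)
    cp_stop("treatment_design(): day_max_c must exceed day_min_c")
  if (duration_days < 1 || duration_days != round(duration_days))
    cp_stop("treatment_design(): duration_days must be a positive integer")
  structure(list(day_max_c = day_max_c, day_min_c = day_min_c,
                 duration_days = as.integer(duration_days), label = label,
                 is_control = is_control),
            class = "treatment_design")
}

#' The factorial of treatment designs
#'
#' Control 25/15 degC plus four cooling gradients (19/9, 16/6, 13/3,
#' 10/0 degC), each at 3, 6 and 9 days. All designs share a 10 degC
#' diurnal amplitude.
#'
#' @param durations Durations in days (default `c(3, 6, 9)`).
#' @return Named list of `treatment_design` objects (CK_D1..T4D3).
#' @export
factorial_designs <- function(durations = c(3L, 6L, 9L)) {
  temps <- list(CK = c(25, 15), T1 = c(19, 9), T2 = c(16, 6),
                T3 = c(13, 3), T4 = c(10, 0))
  out <- list()
  for (tn in names(temps)) {
    for (di in seq_along(durations)) {
      lab <- if (tn == "CK") sprintf("CKD%d", di) else sprintf("%sD%d", tn, di)
      out[[lab]] <- treatment_design(temps[[tn]][1], temps[[tn]][2],
                                     durations[di], lab, tn == "CK")
    }
  }
  out
}

# Normalized diurnal shape on hours 0..23: 0 at 05:00, 1 at 14:00,
# piecewise cosine between the anchors (rise 05->14 over 9 h, fall
# 14->05 over 15 h).
#' @noRd
diurnal_shape <- function(hours = 0:23) {
  h <- hours %% 24
  phi <- numeric(length(h))
  rise <- h >= 5 & h <= 14
  phi[rise] <- (1 - cos(pi * (h[rise] - 5) / 9)) / 2
  fall <- h > 14
  phi[fall] <- (1 + cos(pi * (h[fall] - 14) / 15)) / 2
  night <- h < 5
  phi[night] <- (1 + cos(pi * (h[night] + 10) / 15)) / 2
  phi
}

#' Hourly temperature profile for a treatment design
#'
#' A smooth diurnal curve per day: minimum at 05:00, maximum at 14:00,
#' piecewise-cosine in between (the standard agro-meteorological
#' interpolant for greenhouse settings). All designs share one normalized
#' shape, so two designs with equal amplitude differ by a constant hourly
#' offset (which makes the accumulated temperature difference analytic).
#'
#' @param design A [treatment_design()].
#' @return A `temperature_profile`: list with `hourly_c` (length
#'   `24 * duration_days`, hour 0 = midnight of day 1) and the design.
#' @export
make_temperature_profile <- function(design) {
  stopifnot(inherits(design, "treatment_design"))
  amp <- design$day_max_c - design$day_min_c
  one_day <- design$day_min_c + amp * diurnal_shape(0:23)
  structure(list(hourly_c = rep(one_day, design$duration_days),
                 design = design),
            class = "temperature_profile")
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf("temperature_profile %s: %d h, min %.2f, max %.2f degC\n",
              x$design$label, length(x$hourly_c), min(x$hourly_c),
              max(x$hourly_c)))
  invisible(x)
}
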