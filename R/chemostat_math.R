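## Continuous-culture (chemostat) arithmetic.
##
## A chemostat with working volume V (litre) fed at flow F (litre/day) has
## dilution rate D = F / V (per day); at steady state D equals the
## community growth rate, so the doubling time is ln(2)/D.  Oxidant pulses
## delivered from a feed (ml/min, mM, minutes) add a dose in mmol that,
## spread over the working volume, sets the peak concentration in mM.  A
## solute that is neither consumed nor produced washes out exponentially at
## rate D.

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(x <= 0)) {
    stop_chemobin(what, " must be > 0", class = "chemobin_invalid_spec")
  }
  invisible(x)
}

#' Dilution rate of a chemostat
#'
#' @param medium_flow Medium supply rate, litre per day.
#' @param working_volume Working (liquid) volume, litre.
#' @return Dilution rate D, per day.
#' @examples
#' dilution_rate(0.17, 0.4)   # 0.425 per day
#' @export
dilution_rate <- function(medium_flow, working_volume) {
  check_positive(medium_flow, "medium_flow")
  check_positive(working_volume, "working_volume")
  medium_flow / working_volume
}

#' Oxidant dose delivered per pulse
#'
#' dose (mmol) = volume delivered (litre) x molarity (mmol/litre), with the
#' delivered volume given by feed flow (ml/min) x duration (min) / 1000.
#'
#' @param feed_flow Feed pump rate, ml per minute.
#' @param feed_concentration Feed concentration, mM.
#' @param duration Pulse duration, minutes.
#' @return Dose in mmol.
#' @examples
#' pulse_dose(1.4, 20, 7)   # 0.196 mmol (~0.2)
#' @export
pulse_dose <- function(feed_flow, feed_concentration, duration) {
  if (any(c(feed_flow, feed_concentration, duration) < 0)) {
    stop_chemobin("pulse parameters must be >= 0",
                  class = "chemobin_invalid_spec")
  }
  (feed_flow * duration / 1000) * feed_concentration
}

#' Peak concentration after a pulse
#'
#' c = dose / working volume.  By default the few millilitres of feed added
#' during the pulse are neglected relative to the working volume; set
#' `feed_volume_ml` for the exact divisor `V + feed volume`.
#'
#' @param dose Dose in mmol (>= 0).
#' @param working_volume Working volume, litre.
#' @param feed_volume_ml Optional feed volume added during the pulse, ml.
#' @return Concentration in mM.
#' @examples
#' post_pulse_concentration(0.2, 0.4)                        # 0.5 mM
#' post_pulse_concentration(0.196, 0.4, feed_volume_ml = 9.8)  # 0.478 mM
#' @export
post_pulse_concentration <- function(dose, working_volume,
                                     feed_volume_ml = 0) {
  if (any(dose < 0)) {
    stop_chemobin("dose must be >= 0", class = "chemobin_invalid_spec")
  }
  check_positive(working_volume, "working_volume")
  dose / (working_volume + feed_volume_ml / 1000)
}

#' Doubling time at a given dilution rate
#'
#' At steady state the growth rate equals D, so t_d = ln(2) / D, converted
#' to hours.
#'
#' @param D Dilution rate, per day (> 0).
#' @return Doubling time in hours.
#' @examples
#' doubling_time(0.4)   # 41.6 h
#' @export
doubling_time <- function(D) {
  check_positive(D, "dilution rate")
  log(2) / D * 24
}

#' Washout of an inert solute
#'
#' A solute that is neither consumed nor produced decays as
#' c(t) = c0 * exp(-D t).  Biological consumption is deliberately not
#' modelled: this is the inert reference trace against which consumption is
#' judged.
#'
#' @param c0 Initial concentration, mM (>= 0).
#' @param D Dilution rate, per day.
#' @param t_hours Time(s) since the pulse, hours.
#' @return Concentration(s) in mM.
#' @examples
#' washout_curve(0.5, 0.425, 24)   # 0.327 mM
#' @export
washout_curve <- function(c0, D, t_hours) {
  if (any(c0 < 0)) {
    stop_chemobin("c0 must be >= 0", class = "chemobin_invalid_spec")
  }
  check_positive(D, "dilution rate")
  c0 * exp(-D * t_hours / 24)
}
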