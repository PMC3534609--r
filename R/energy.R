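#' Resting energy expenditure from oxygen consumption
#'
#' Indirect-calorimetry accounting: oxygen consumption in cc/min is
#' converted to litres/day by the factor `1440 / 1000` (minutes per day over
#' cc per litre) and multiplied by the caloric equivalent of oxygen.
#'
#' @param oxygen_cc_min resting oxygen consumption (cc O2/min), > 0.
#' @param caloric_equivalent kcal per litre of oxygen consumed at rest
#'   (taken from standard indirect-calorimetry tables), > 0.
#' @return resting energy expenditure (kcal/day).
#' @examples
#' resting_ee(139.1, 4.964)  # group value at the last starvation week, ~994
#' @export
resting_ee <- function(oxygen_cc_min, caloric_equivalent) {
  if (any(oxygen_cc_min <= 0)) stop("'oxygen_cc_min' must be positive")
  if (any(caloric_equivalent <= 0)) stop("'caloric_equivalent' must be positive")
  oxygen_cc_min * (1440 / 1000) * caloric_equivalent
}

#' Activity profile for walking energy expenditure
#'
#' Describes a subject's (or group's) walking regimen.  The defaults mirror
#' the starvation-study protocol: 22 miles/week of outdoor walking at
#' 3 mph (3.6 kcal/min for a 54 kg reference man) plus 30 min/week on a
#' treadmill (4.2 kcal/min at reference weight).  Energy costs for other
#' speed/weight combinations must be supplied by the caller; costs scale
#' linearly with body weight relative to the reference.
#'
#' @param body_weight current body weight (kg).
#' @param reference_weight weight at which the costs are tabulated (kg).
#' @param outdoor_miles_per_week weekly outdoor walking distance (miles).
#' @param outdoor_speed_mph walking speed (mph).
#' @param outdoor_cost_kcal_min energy cost at reference weight and speed
#'   (kcal/min).
#' @param treadmill_cost_kcal_min treadmill energy cost at reference weight
#'   (kcal/min).
#' @param treadmill_minutes_per_week weekly treadmill time (min).
#' @return an object of class `"activity_profile"`.
#' @export
activity_profile <- function(body_weight,
                             reference_weight = 54,
                             outdoor_miles_per_week = 22,
                             outdoor_speed_mph = 3,
                             outdoor_cost_kcal_min = 3.6,
                             treadmill_cost_kcal_min = 4.2,
                             treadmill_minutes_per_week = 30) {
  vals <- c(body_weight, reference_weight, outdoor_miles_per_week,
            outdoor_speed_mph, outdoor_cost_kcal_min, treadmill_cost_kcal_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all activity-profile fields except treadmill minutes must be positive")
  if (treadmill_minutes_per_week < 0)
    stop("'treadmill_minutes_per_week' must be non-negative")
  structure(list(body_weight = body_weight,
                 reference_weight = reference_weight,
                 outdoor_miles_per_week = outdoor_miles_per_week,
                 outdoor_speed_mph = outdoor_speed_mph,
                 outdoor_cost_kcal_min = outdoor_cost_kcal_min,
                 treadmill_cost_kcal_min = treadmill_cost_kcal_min,
                 treadmill_minutes_per_week = treadmill_minutes_per_week),
            class = "activity_profile")
}

#' Daily energy expenditure of outdoor walking
#'
#' `(body_weight / reference_weight) * (daily_miles / speed) * cost * 60`,
#' where `daily_miles = miles_per_week / 7` rounded to hundredths of a mile
#' (the precision the published accounting carries: 22 miles/week enters as
#' 3.14 miles/day) and the quotient by speed is daily walking time in hours.
#'
#' @param profile an [activity_profile()].
#' @return kcal/day.
#' @examples
#' walking_ee(activity_profile(body_weight = 52.57))  # ~220.1
#' @export
walking_ee <- function(profile) {
  stopifnot(inherits(profile, "activity_profile"))
  with(profile,
       (body_weight / reference_weight) *
         (round(outdoor_miles_per_week / 7, 2) / outdoor_speed_mph) *
         outdoor_cost_kcal_min * 60)
}

#' Daily energy expenditure of the weekly treadmill walk
#'
#' `(body_weight / reference_weight) * cost * minutes_per_week / 7`.
#'
#' @param profile an [activity_profile()].
#' @return kcal/day.
#' @examples
#' treadmill_ee(activity_profile(body_weight = 52.57))  # ~17.52
#' @export
treadmill_ee <- function(profile) {
  stopifnot(inherits(profile, "activity_profile"))
  with(profile,
       (body_weight / reference_weight) *
         treadmill_cost_kcal_min * treadmill_minutes_per_week / 7)
}

#' Total energy expenditure
#'
#' Sum of resting energy expenditure and any number of activity components.
#'
#' @param ree resting energy expenditure (kcal/day), >= 0.
#' @param aee numeric vector of activity components (kcal/day), >= 0.
#' @return kcal/day.
#' @export
total_ee <- function(ree, aee = numeric()) {
  if (any(c(ree, aee) < 0)) stop("energy expenditures must be non-negative")
  sum(ree, aee)
}

#' Net energy intake
#'
#' Food intake minus total energy expenditure; negative during underfeeding.
#' This is the forcing term `l(t)` of the weight recursion.
#'
#' @param intake food energy intake (kcal/day).
#' @param tee total energy expenditure (kcal/day).
#' @return kcal/day.
#' @export
net_energy_intake <- function(intake, tee) intake - tee
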