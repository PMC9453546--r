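#' Gravimetric substrate water content
#'
#' Computes the gravimetric substrate water content (GWC, %) of a potted
#' plant from the current pot weight and the reference weights of the pot
#' with oven-dry substrate and with substrate at container capacity:
#' `GWC = 100 * (pot - pot_dry) / (pot_wet - pot_dry)`.
#'
#' GWC is affine in `pot`: it is exactly 0 at `pot_dry` and exactly 100 at
#' `pot_wet`. Values slightly above 100 (fresh irrigation, weighing error)
#' are kept and flagged with a warning rather than clipped, because they
#' carry information about measurement noise.
#'
#' @param pot Current weight of pot plus substrate (kg or g; any unit, as
#'   long as all three arguments share it).
#' @param pot_dry Weight of pot plus oven-dried substrate.
#' @param pot_wet Weight of pot plus substrate at container capacity.
#' @return Numeric vector of GWC in percent.
#' @examples
#' compute_gwc(5, 4, 6) # 50
#' @export
compute_gwc <- function(pot, pot_dry, pot_wet) {
  check_number(pot, "pot")
  check_number(pot_dry, "pot_dry")
  check_number(pot_wet, "pot_wet")
  if (any(pot_wet <= pot_dry)) {
    ht_param_error(
      "Invalid pot weight record: `pot_wet` must exceed `pot_dry` (zero or negative water capacity)."
    )
  }
  gwc <- 100 * (pot - pot_dry) / (pot_wet - pot_dry)
  if (any(gwc > 100)) {
    warn(sprintf("%d GWC value(s) exceed 100%%; kept as-is (flagged).",
                 sum(gwc > 100)))
  }
  if (any(gwc < 0)) {
    warn(sprintf("%d GWC value(s) below 0%%: pot lighter than oven-dry reference.",
                 sum(gwc < 0)))
  }
  gwc
}

#' Percentage loss of hydraulic conductivity
#'
#' Computes PLC from a conductance measurement `kh` at an applied pressure
#' and the maximum (flushed) conductance `kmax`:
#' `PLC = 100 * (1 - kh / kmax)`.
#'
#' Values marginally outside \[0, 100\] arise routinely from flow-measurement
#' noise; they are clipped to the valid range with a warning, never treated
#' as errors.
#'
#' @param kh Hydraulic conductance at the applied pressure (any unit shared
#'   with `kmax`).
#' @param kmax Maximum conductance measured after flushing; must be positive.
#' @return Numeric vector of PLC in percent, within \[0, 100\].
#' @examples
#' compute_plc(0.5, 1) # 50
#' @export
compute_plc <- function(kh, kmax) {
  check_number(kh, "kh")
  check_number(kmax, "kmax")
  if (any(kmax <= 0)) {
    ht_param_error("Invalid vulnerability curve: `kmax` must be positive.")
  }
  if (any(kh < 0)) {
    ht_param_error("`kh` must be non-negative.")
  }
  plc <- 100 * (1 - kh / kmax)
  if (any(plc < 0)) {
    warn(sprintf("%d PLC value(s) below 0 (kh > kmax, measurement noise); clipped to 0.",
                 sum(plc < 0)))
    plc <- pmax(plc, 0)
  }
  pmin(plc, 100)
}

#' Instantaneous water-use efficiency
#'
#' Computes iWUE as the per-record ratio of net photosynthesis to
#' transpiration, `a_n / e` (mmol CO2 mol-1 H2O when `a_n` is in umol CO2
#' m-2 s-1 and `e` in mmol H2O m-2 s-1).
#'
#' iWUE must be computed per record and only then averaged: a ratio of
#' treatment means is not the mean of the individual ratios. Records with
#' non-positive transpiration are returned as `NA` (flagged via warning)
#' and should be excluded from downstream summaries.
#'
#' @param a_n Net photosynthesis.
#' @param e Transpiration rate; iWUE is defined only where `e > 0`.
#' @return Numeric vector of per-record iWUE, `NA` where `e <= 0`.
#' @examples
#' compute_iwue(12, 4.8) # 2.5
#' @export
compute_iwue <- function(a_n, e) {
  check_number(a_n, "a_n")
  check_number(e, "e")
  bad <- e <= 0
  if (any(bad)) {
    warn(sprintf("%d record(s) with e <= 0: iWUE undefined, set to NA.", sum(bad)))
  }
  ifelse(bad, NA_real_, a_n / e)
}

#' Relative water content of a dehydrating leaf
#'
#' `RWC = 100 * (fresh_mass - dry_mass) / (sat_mass - dry_mass)`.
#'
#' @param fresh_mass Fresh mass of the leaf during bench drying (g).
#' @param dry_mass Oven-dry mass (g).
#' @param sat_mass Mass at full saturation (g); must exceed `dry_mass`.
#' @return Numeric vector of RWC in percent.
#' @seealso [saturated_water_content()]
#' @examples
#' compute_rwc(0.4, 0.2, 0.6) # 50
#' @export
compute_rwc <- function(fresh_mass, dry_mass, sat_mass) {
  check_number(fresh_mass, "fresh_mass")
  check_number(dry_mass, "dry_mass")
  check_number(sat_mass, "sat_mass")
  if (any(sat_mass <= dry_mass)) {
    ht_param_error("`sat_mass` must exceed `dry_mass`.")
  }
  if (any(fresh_mass < dry_mass)) {
    ht_param_error("Invalid point: `fresh_mass` below `dry_mass`.")
  }
  100 * (fresh_mass - dry_mass) / (sat_mass - dry_mass)
}

#' Saturated water content
#'
#' `SWC = (sat_mass - dry_mass) / dry_mass`, in g water per g dry mass.
#'
#' @inheritParams compute_rwc
#' @return Numeric vector of SWC (g g-1).
#' @examples
#' saturated_water_content(0.2, 0.6) # 2
#' @export
saturated_water_content <- function(dry_mass, sat_mass) {
  check_number(dry_mass, "dry_mass", lower = 1e-12)
  check_number(sat_mass, "sat_mass")
  if (any(sat_mass <= dry_mass)) {
    ht_param_error("`sat_mass` must exceed `dry_mass`.")
  }
  (sat_mass - dry_mass) / dry_mass
}
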