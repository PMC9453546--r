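#' Virtual cultivar presets for the synthetic dry-down generator
#'
#' Three virtual almond-like cultivars spanning the isohydric-anisohydric
#' continuum. Their trait targets (maximum gas exchange, water potential at
#' stomatal closure, turgor loss point, P50, saturated water content) are
#' patterned on published almond cultivar values; the water-balance
#' constants (whole-plant hydraulic conductance, residual cuticular
#' transpiration, effective daily transpiring time) were calibrated once so
#' that a 50-day pot desiccation reproduces the expected predawn-midday
#' water-potential geometry and final substrate water contents. They are
#' simulation presets, not measured data.
#'
#' Fields (units): `gs_max`, `e_max` (mmol m-2 s-1), `a_max`
#' (umol m-2 s-1), `k_stomatal` (MPa-1), `psi_gs90`, `psi_tlp`, `pi_o`,
#' `epsilon`, `p50` (MPa), `weibull_b` (MPa), `weibull_c`, `swc` (g g-1),
#' `retention_a` (MPa), `retention_n`, `plant_conductance`
#' (mmol m-2 s-1 MPa-1), `e_cuticular` (mmol m-2 s-1), `cuticle_decay`
#' (MPa), `relk_min` (residual relative conductance), `capacity_g` (g
#' water at container capacity), `pot_dry_kg`, `canopy_area_m2`,
#' `t_eff_s` (effective transpiring seconds per day), `leaf_area_m2` (PV
#' sample leaf), `dry_mass_g`, `ww_gwc` (%), and per-channel observation
#' noise standard deviations (`noise_*`; gas-exchange channels are
#' relative, water-potential and mass channels absolute).
#'
#' @param label One of `"avijor-like"`, `"isabelona-like"`,
#'   `"soleta-like"`; `cultivar_presets()` returns all three.
#' @return `cultivar_preset()`: a named list; `cultivar_presets()`: a
#'   tibble with one row per preset.
#' @export
cultivar_preset <- function(label = c("avijor-like", "isabelona-like",
                                      "soleta-like")) {
  label <- match.arg(label)
  base <- list(
    retention_a = 1.6, retention_n = 1.0,
    capacity_g = 1400, pot_dry_kg = 2.8, canopy_area_m2 = 0.05,
    cuticle_decay = 3, relk_min = 0.15, weibull_c = 5,
    dry_mass_g = 0.2, ww_gwc = 90,
    noise_psi = 0.02, noise_gs_rel = 0.05, noise_an_rel = 0.05,
    noise_e_rel = 0.05,
    noise_pot_g = 5, noise_kh = 0.05, noise_psi_pv = 0.005,
    noise_mass_pv = 0.001)
  per <- switch(label,
    "avijor-like" = list(
      gs_max = 363.32, e_max = 5.18, a_max = 12.24,
      psi_gs90 = -1.72, pi_o = 1.52, psi_tlp = -2.01, p50 = -2.97,
      swc = 2.43, leaf_area_m2 = 0.0058,
      plant_conductance = 0.6334, e_cuticular = 0.3401, t_eff_s = 45336),
    "isabelona-like" = list(
      gs_max = 517.39, e_max = 6.31, a_max = 11.24,
      psi_gs90 = -2.25, pi_o = 1.62, psi_tlp = -2.31, p50 = -3.80,
      swc = 2.68, leaf_area_m2 = 0.0052,
      plant_conductance = 0.4866, e_cuticular = 0.3809, t_eff_s = 41339),
    "soleta-like" = list(
      gs_max = 623.36, e_max = 6.83, a_max = 13.22,
      psi_gs90 = -2.14, pi_o = 1.97, psi_tlp = -2.87, p50 = -3.73,
      swc = 2.05, leaf_area_m2 = 0.0035,
      plant_conductance = 0.6144, e_cuticular = 0.5064, t_eff_s = 38121))
  p <- c(list(label = label), per, base)
  # derived: kinetic decline rate from the closure target, Weibull scale
  # from P50, elasticity from (pi_o, psi_tlp) under the ideal PV model,
  # saturated mass from SWC
  p$k_stomatal <- log(10) / abs(p$psi_gs90)
  p$weibull_b <- abs(p$p50) / log(2)^(1 / p$weibull_c)
  p$epsilon <- p$pi_o * abs(p$psi_tlp) / (abs(p$psi_tlp) - p$pi_o)
  p$sat_mass_g <- p$dry_mass_g * (1 + p$swc)
  p$pot_wet_kg <- p$pot_dry_kg + p$capacity_g / 1000
  p
}

#' @rdname cultivar_preset
#' @export
cultivar_presets <- function() {
  purrr::map_dfr(c("avijor-like", "isabelona-like", "soleta-like"),
                 function(l) tibble::as_tibble(cultivar_preset(l)))
}

# substrate water retention: predawn potential from gravimetric water
# content (MPa, <= 0)
retention_psi <- function(gwc, a, n) {
  -a * (100 / gwc - 1)^n
}

# Weibull relative conductance with a residual floor (non-vascular pathways
# keep a fraction of conductance even past full cavitation of the measured
# xylem)
relk_weibull <- function(psi, b, c, relk_min = 0) {
  pmax(exp(-(abs(psi) / b)^c), relk_min)
}

# total transpiration (mmol m-2 s-1): stomatal component plus cuticular
# water loss that fades as the leaf dehydrates
transpiration <- function(psi_min, preset) {
  preset$e_max * exp(preset$k_stomatal * psi_min) +
    preset$e_cuticular * exp(psi_min / preset$cuticle_decay)
}

# midday water potential: solves psi = psi_pd - E(psi) / (Kplant * relk(psi))
solve_psi_min <- function(psi_pd, preset, day = NA) {
  h <- function(psi) {
    psi - psi_pd + transpiration(psi, preset) /
      (preset$plant_conductance *
         relk_weibull(psi, preset$weibull_b, preset$weibull_c, preset$relk_min))
  }
  lo <- psi_pd - 12
  while (h(lo) >= 0 && lo > psi_pd - 60) lo <- lo - 12
  if (h(lo) >= 0) {
    ht_fit_error(sprintf(
      "Dry-down simulation: midday water potential has no solution on day %s (runaway cavitation).",
      day))
  }
  uniroot(h, c(lo, psi_pd), tol = 1e-10, maxiter = 50)$root
}

#' Simulate a pot-desiccation dry-down
#'
#' Daily water-balance simulation of a potted plant under either
#' progressive pot desiccation (`"PD"`, irrigation withheld) or a
#' well-watered control (`"WW"`, substrate held near container capacity).
#' Each day: predawn water potential follows the substrate retention curve
#' `psi_pd = -a * (100/GWC - 1)^n`; the midday minimum potential solves
#' the supply-demand balance
#' `psi_min = psi_pd - E(psi_min) / (Kplant * relK(psi_min))`, where the
#' transpiration demand combines the kinetic stomatal decline with a
#' fading cuticular component and `relK` is the Weibull vulnerability
#' curve with a residual floor; the substrate then loses the transpired
#' water mass. Gaussian observation noise is added per channel, with one
#' seed fanning out to independent per-channel substreams.
#'
#' All `n_plants` replicates share the same true trajectory (they are pots
#' of the same preset dried side by side) and differ only in observation
#' noise.
#'
#' @param preset A preset from [cultivar_preset()] (or a compatible list).
#' @param days Number of days (default 50).
#' @param treatment `"PD"` (desiccation) or `"WW"` (well-watered control).
#' @param n_plants Number of replicate plants (default 8).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @return A tibble with one row per plant and day: observed `psi_pd`,
#'   `psi_min`, `gs`, `a_n`, `e`, `ci`, pot weights (`pot`, `pot_dry`,
#'   `pot_wet`, kg) and `gwc`, plus the hidden true state (`*_true`
#'   columns). The attribute `"truth"` carries the per-day true state and
#'   the cumulative transpired mass.
#' @export
simulate_drydown <- function(preset, days = 50, treatment = c("PD", "WW"),
                             n_plants = 8, seed = 1) {
  treatment <- match.arg(treatment)
  stopifnot(days >= 1, n_plants >= 1)
  cap <- preset$capacity_g
  water <- if (treatment == "WW") preset$ww_gwc / 100 * cap else cap
  state <- vector("list", days)
  transpired <- 0
  for (d in seq_len(days)) {
    gwc <- 100 * water / cap
    psi_pd <- retention_psi(gwc, preset$retention_a, preset$retention_n)
    psi_min <- solve_psi_min(psi_pd, preset, day = d)
    gs <- preset$gs_max * exp(preset$k_stomatal * psi_min)
    e_tot <- transpiration(psi_min, preset)
    a_n <- 1.25 * preset$a_max * gs / (gs + preset$gs_max / 4)
    state[[d]] <- c(day = d, gwc = gwc, psi_pd = psi_pd, psi_min = psi_min,
                    gs = gs, e = e_tot, a_n = a_n, water = water)
    if (treatment == "PD") {
      # grams of water transpired during the day
      loss <- e_tot * 1e-3 * preset$canopy_area_m2 * preset$t_eff_s * 18.015
      loss <- min(loss, water - 1)
      transpired <- transpired + loss
      water <- water - loss
    }
  }
  truth <- tibble::as_tibble(do.call(rbind, state))

  seeds <- fan_out_seeds(seed, 6)
  noise <- function(s, sd) {
    withr::with_seed(s, matrix(rnorm(days * n_plants, 0, sd), nrow = days))
  }
  n_psi_pd <- noise(seeds[1], preset$noise_psi)
  n_psi_min <- noise(seeds[2], preset$noise_psi)
  n_gs <- noise(seeds[3], preset$noise_gs_rel)
  n_an <- noise(seeds[4], preset$noise_an_rel)
  n_e <- noise(seeds[5], preset$noise_e_rel)
  n_pot <- noise(seeds[6], preset$noise_pot_g)

  out <- purrr::map_dfr(seq_len(n_plants), function(p) {
    obs_psi_pd <- pmin(truth$psi_pd + n_psi_pd[, p], 0)
    obs_psi_min <- pmin(truth$psi_min + n_psi_min[, p], 0)
    tibble::tibble(
      plant_id = sprintf("%s_%s_p%02d", preset$label, treatment, p),
      cultivar = preset$label,
      treatment = treatment,
      day = truth$day,
      psi_pd = obs_psi_pd,
      psi_min = obs_psi_min,
      gs = pmax(truth$gs * (1 + n_gs[, p]), 0),
      a_n = pmax(truth$a_n * (1 + n_an[, p]), 0),
      e = pmax(truth$e * (1 + n_e[, p]), 0),
      ci = pmin(pmax(400 - 1600 * truth$a_n / pmax(truth$gs, 1), 40), 400),
      pot = preset$pot_dry_kg + truth$water / 1000 + n_pot[, p] / 1000,
      pot_dry = preset$pot_dry_kg,
      pot_wet = preset$pot_wet_kg,
      gwc = truth$gwc,
      psi_pd_true = truth$psi_pd,
      psi_min_true = truth$psi_min,
      gs_true = truth$gs,
      e_true = truth$e)
  })
  attr(out, "truth") <- list(state = truth, transpired_g = transpired,
                             water_end_g = water, preset = preset,
                             treatment = treatment, seed = seed)
  out
}

#' Simulate stem vulnerability curves
#'
#' Draws per-stem maximum conductances and applies the preset's Weibull
#' vulnerability curve with multiplicative measurement noise:
#' `kh = kmax * exp(-(P/b)^c) * (1 + eps)`. A flushed measurement at
#' pressure 0 (the K_max determination) is included for each stem.
#'
#' @param preset A preset from [cultivar_preset()].
#' @param pressure_steps Applied tensions in positive MPa (default the
#'   standard 11-step sequence, [vc_pressure_steps()]).
#' @param n_stems Number of stems (default 3).
#' @param seed Integer seed.
#' @return A tibble in the `vulnerability` schema: `stem_id`,
#'   `pressure_mpa`, `kh`, `cultivar`, with the pressure-0 rows carrying
#'   K_max.
#' @export
simulate_vulnerability <- function(preset, pressure_steps = vc_pressure_steps(),
                                   n_stems = 3, seed = 1) {
  check_number(pressure_steps, "pressure_steps", lower = 0)
  stopifnot(n_stems >= 1)
  seeds <- fan_out_seeds(seed, 2)
  kmaxes <- withr::with_seed(seeds[1], 5 * exp(rnorm(n_stems, 0, 0.1)))
  eps <- withr::with_seed(seeds[2], {
    matrix(rnorm(n_stems * length(pressure_steps), 0, preset$noise_kh),
           nrow = n_stems)
  })
  purrr::map_dfr(seq_len(n_stems), function(s) {
    relk <- exp(-(pressure_steps / preset$weibull_b)^preset$weibull_c)
    kh <- pmax(kmaxes[s] * relk * (1 + eps[s, ]), 0)
    tibble::tibble(
      stem_id = sprintf("%s_s%02d", preset$label, s),
      pressure_mpa = c(0, pressure_steps),
      kh = c(kmaxes[s], kh),
      cultivar = preset$label)
  })
}

#' Simulate pressure-volume bench-drying curves
#'
#' Generates ideal-model PV curves (zero apoplastic water fraction): over
#' a relative water content grid, the osmotic component is
#' `psi_pi = -pi_o * 100 / RWC`, turgor is
#' `psi_p = max(0, pi_o - epsilon * (1 - RWC/100))`, and
#' `psi = psi_pi + psi_p`. Below the turgor loss point `1/psi` is exactly
#' linear in `100 - RWC` by construction. Fresh masses are back-computed
#' from RWC; Gaussian noise is added to potentials and masses.
#'
#' @param preset A preset from [cultivar_preset()]; requires
#'   `pi_o < epsilon` (otherwise the TLP would fall outside any physical
#'   RWC range and the preset is degenerate).
#' @param n_points Points per leaf over RWC in \[60, 100\] (default 41).
#' @param n_leaves Number of replicate leaves (default 4).
#' @param seed Integer seed.
#' @return A tibble in the `pv_curve` schema (`leaf_id`, `psi_mpa`,
#'   `fresh_mass_g`, `dry_mass_g`, `sat_mass_g`, `leaf_area_m2`,
#'   `cultivar`), ordered wettest to driest within each leaf.
#' @export
simulate_pv_curve <- function(preset, n_points = 41, n_leaves = 4, seed = 1) {
  if (preset$pi_o >= preset$epsilon) {
    ht_param_error(
      "Degenerate preset: pi_o >= epsilon places the turgor loss point outside the curve.")
  }
  stopifnot(n_points >= 8, n_leaves >= 1)
  seeds <- fan_out_seeds(seed, 2)
  rwc <- seq(100, 60, length.out = n_points)
  psi_pi <- -preset$pi_o * 100 / rwc
  psi_p <- pmax(0, preset$pi_o - preset$epsilon * (1 - rwc / 100))
  psi <- psi_pi + psi_p
  dry <- preset$dry_mass_g
  sat <- preset$sat_mass_g
  fresh <- dry + rwc / 100 * (sat - dry)
  n_psi <- withr::with_seed(seeds[1], {
    matrix(rnorm(n_points * n_leaves, 0, preset$noise_psi_pv), nrow = n_points)
  })
  n_mass <- withr::with_seed(seeds[2], {
    matrix(rnorm(n_points * n_leaves, 0, preset$noise_mass_pv), nrow = n_points)
  })
  purrr::map_dfr(seq_len(n_leaves), function(l) {
    tibble::tibble(
      leaf_id = sprintf("%s_l%02d", preset$label, l),
      psi_mpa = pmin(psi + n_psi[, l], -1e-4),
      fresh_mass_g = pmax(fresh + n_mass[, l], dry),
      dry_mass_g = dry,
      sat_mass_g = sat,
      leaf_area_m2 = preset$leaf_area_m2,
      cultivar = preset$label)
  })
}

#' Simulate a complete dry-down study
#'
#' Generates every input table the analysis pipeline consumes - the PD and
#' WW water-potential and gas-exchange series, pot weights, stem
#' vulnerability curves and PV curves - for one or more cultivar presets,
#' with known ground truth.
#'
#' @param presets A list of presets (default: all three shipped presets).
#' @param days,n_plants Passed to [simulate_drydown()].
#' @param seed Integer seed; per-preset and per-table seeds are fanned out
#'   deterministically.
#' @param include_ww Also simulate the well-watered control? Default
#'   `TRUE`.
#' @return A list of tibbles `water_potential`, `gas_exchange`,
#'   `pot_weights`, `vulnerability`, `pv_curve`, and `ground_truth` (a
#'   list per preset).
#' @export
simulate_study <- function(presets = NULL, days = 50, n_plants = 8, seed = 1,
                           include_ww = TRUE) {
  if (is.null(presets)) {
    presets <- lapply(c("avijor-like", "isabelona-like", "soleta-like"),
                      cultivar_preset)
  }
  seeds <- fan_out_seeds(seed, 4 * length(presets))
  wp <- ge <- pw <- vc <- pv <- NULL
  truth <- list()
  for (i in seq_along(presets)) {
    p <- presets[[i]]
    s <- seeds[(i - 1) * 4 + 1:4]
    runs <- list(simulate_drydown(p, days = days, treatment = "PD",
                                  n_plants = n_plants, seed = s[1]))
    if (include_ww) {
      runs <- c(runs, list(simulate_drydown(p, days = days, treatment = "WW",
                                            n_plants = n_plants, seed = s[2])))
    }
    for (r in runs) {
      wp <- dplyr::bind_rows(wp, r[c("plant_id", "day", "psi_pd", "psi_min",
                                     "cultivar", "treatment")])
      ge <- dplyr::bind_rows(ge, r[c("plant_id", "day", "a_n", "gs", "e",
                                     "ci", "cultivar", "treatment")])
      pw <- dplyr::bind_rows(pw, r[c("plant_id", "day", "pot", "pot_dry",
                                     "pot_wet", "cultivar", "treatment")])
    }
    vc <- dplyr::bind_rows(vc, simulate_vulnerability(p, seed = s[3]))
    pv <- dplyr::bind_rows(pv, simulate_pv_curve(p, seed = s[4]))
    truth[[p$label]] <- list(preset = p,
                             pd = attr(runs[[1]], "truth"))
  }
  list(water_potential = wp, gas_exchange = ge, pot_weights = pw,
       vulnerability = vc, pv_curve = pv, ground_truth = truth)
}

#' Write a simulated study to CSV files
#'
#' Writes the five input tables of [simulate_study()] into a directory
#' (creating it if needed) under their schema names, plus a
#' `ground_truth.json` with the generating parameters.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("water_potential", "gas_exchange", "pot_weights",
               "vulnerability", "pv_curve")) {
    write_table(sim[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  gt <- lapply(sim$ground_truth, function(t) t$preset)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
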