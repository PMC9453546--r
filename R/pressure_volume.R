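#' Locate the turgor loss point on a pressure-volume curve
#'
#' Beyond the turgor loss point (TLP) the leaf water potential is purely
#' osmotic, so `1/psi` is linear in `100 - RWC`. The TLP is found by
#' growing a candidate linear tail from the three driest points upward and
#' keeping the longest tail whose linear fit of `1/psi` against
#' `100 - RWC` retains R^2 >= 0.99; wet-end points whose residual stands
#' out against the remaining tail (|residual| above three tail RMSEs) are
#' then trimmed so that the boundary is not dragged past the true
#' inflection by the curvature of the turgid phase. The osmotic potential
#' at full turgor is read off the tail line extrapolated to RWC = 100:
#' `pi_o = -1 / intercept` (reported as a positive magnitude).
#'
#' @param psi Leaf water potentials during bench drying (MPa, < 0).
#' @param rwc Relative water contents (percent), same length.
#' @param r2_keep Minimum tail R^2 to accept while growing (default 0.99).
#' @param r2_min If the best tail falls below this R^2 the curve has no
#'   detectable linear (osmotic) region and an error is raised (default
#'   0.98).
#' @return A list with `psi_tlp`, `rwc_tlp`, `pi_o` (positive magnitude,
#'   MPa), `tail_n` (points in the osmotic tail), `r2_tail`, `intercept`
#'   and `slope` of the 1/psi tail line, and `degenerate` (`TRUE` when the
#'   whole series is linear, i.e. no turgid phase was seen).
#' @export
find_tlp <- function(psi, rwc, r2_keep = 0.99, r2_min = 0.98) {
  check_number(psi, "psi", upper = 0)
  check_number(rwc, "rwc", lower = 0)
  if (length(psi) != length(rwc)) {
    ht_param_error("`psi` and `rwc` must have equal length.")
  }
  n <- length(psi)
  if (n < 8) {
    ht_fit_error("Need at least 8 PV points spanning both sides of turgor loss.")
  }
  if (any(psi >= -1e-12)) {
    ht_param_error("All `psi` values must be strictly negative for TLP analysis.")
  }
  ord <- order(rwc)            # driest first
  x <- (100 - rwc)[ord]        # water deficit, increasing toward index 1
  y <- (1 / psi)[ord]

  tail_r2 <- function(m) {
    xi <- x[seq_len(m)]
    yi <- y[seq_len(m)]
    f <- lsq(cbind(1, xi), yi)
    tss <- sum((yi - mean(yi))^2)
    if (tss <= 0) return(-Inf)
    1 - f$rss / tss
  }
  r2s <- vapply(3:n, tail_r2, numeric(1))
  if (max(r2s) < r2_min) {
    ht_fit_error(sprintf(
      "No linear osmotic tail detectable (best tail R^2 = %.3f < %.2f).",
      max(r2s), r2_min))
  }
  ok <- which(r2s >= r2_keep)
  m <- if (length(ok) > 0) max(ok) + 2 else which.max(r2s) + 2

  # trim wet-end points that deviate from the line supported by the rest of
  # the tail: guards against the tail creeping past the inflection
  while (m > 3) {
    xi <- x[seq_len(m - 1)]
    yi <- y[seq_len(m - 1)]
    f <- lsq(cbind(1, xi), yi)
    rmse_rest <- sqrt(f$rss / max(m - 3, 1))
    pred_wet <- f$coef[1] + f$coef[2] * x[m]
    thr <- max(3 * rmse_rest, 1e-10)
    if (abs(y[m] - pred_wet) > thr) m <- m - 1 else break
  }

  xi <- x[seq_len(m)]
  yi <- y[seq_len(m)]
  f <- lsq(cbind(1, xi), yi)
  tss <- sum((yi - mean(yi))^2)
  r2_tail <- if (tss > 0) 1 - f$rss / tss else NA_real_
  intercept <- unname(f$coef[1])
  slope <- unname(f$coef[2])
  if (intercept >= 0) {
    ht_fit_error("Osmotic tail extrapolates to a non-negative 1/psi at full turgor; curve invalid.")
  }
  degenerate <- m >= n
  if (degenerate) {
    warn("Entire 1/psi series is linear: TLP placed at the wettest point, turgid phase empty (degenerate curve).")
  }
  list(psi_tlp = psi[ord][m], rwc_tlp = rwc[ord][m],
       pi_o = -1 / intercept, tail_n = m, r2_tail = r2_tail,
       intercept = intercept, slope = slope, degenerate = degenerate)
}

#' Bulk modulus of elasticity from the turgid phase
#'
#' Turgor pressure is `psi_p = psi - psi_pi`, with the osmotic component
#' modelled under the zero-apoplast convention as
#' `psi_pi = -pi_o * 100 / RWC`. The modulus of elasticity is the
#' least-squares slope of `psi_p` against `RWC/100` over the points
#' between full turgor and the TLP.
#'
#' @inheritParams find_tlp
#' @param pi_o Osmotic potential at full turgor (positive magnitude, MPa).
#' @param rwc_tlp RWC at the turgor loss point (percent).
#' @return A list with `epsilon` (MPa) and `n_supra`, the number of
#'   supra-TLP points used. A (near) zero modulus is flagged nonphysical
#'   with a warning.
#' @export
pv_elasticity <- function(psi, rwc, pi_o, rwc_tlp) {
  check_number(pi_o, "pi_o", lower = 1e-9)
  keep <- rwc >= rwc_tlp - 1e-9
  if (sum(keep) < 3) {
    ht_fit_error(sprintf(
      "Insufficient data: only %d point(s) above the turgor loss point (need 3).",
      sum(keep)))
  }
  psi_pi <- -pi_o * 100 / rwc[keep]
  psi_p <- psi[keep] - psi_pi
  f <- lsq(cbind(1, rwc[keep] / 100), psi_p)
  epsilon <- unname(f$coef[2])
  if (!is.finite(epsilon) || epsilon < 1e-8) {
    warn("Elasticity slope is zero or negative: flat turgor phase, nonphysical modulus.")
  }
  list(epsilon = epsilon, n_supra = sum(keep))
}

#' Leaf capacitance at full turgor
#'
#' Capacitance is the slope of relative water content (as a fraction)
#' against water potential over the supra-TLP points, converted to moles
#' of water per unit leaf area:
#' `C_FT = slope * (sat_mass - dry_mass) / (M_w * leaf_area)` with
#' `M_w = 18.015 g mol-1`.
#'
#' @inheritParams pv_elasticity
#' @param water_mass Saturated water mass `sat_mass - dry_mass` (g).
#' @param leaf_area One-sided leaf area (m^2); if `NA`, only the
#'   mass-normalized value is returned, with a warning.
#' @return A list with `c_ft` (mol m-2 MPa-1; `NA` without `leaf_area`),
#'   `c_ft_mass` (mol MPa-1, before area normalization) and `slope`
#'   (MPa-1).
#' @export
pv_capacitance <- function(psi, rwc, rwc_tlp, water_mass, leaf_area = NA) {
  check_number(water_mass, "water_mass", lower = 1e-12)
  keep <- rwc >= rwc_tlp - 1e-9
  if (sum(keep) < 3) {
    ht_fit_error("Insufficient supra-TLP points for capacitance (need 3).")
  }
  f <- lsq(cbind(1, psi[keep]), rwc[keep] / 100)
  slope <- unname(f$coef[2])
  if (!is.finite(slope) || slope < 1e-10) {
    warn("Capacitance slope is zero: nonphysical (no water release with declining potential).")
    slope <- max(slope, 0)
  }
  m_w <- 18.015
  c_ft_mass <- slope * water_mass / m_w
  if (is.na(leaf_area)) {
    warn("`leaf_area` missing: returning only the unnormalized capacitance (mol MPa-1).")
    return(list(c_ft = NA_real_, c_ft_mass = c_ft_mass, slope = slope))
  }
  check_number(leaf_area, "leaf_area", lower = 1e-12)
  list(c_ft = c_ft_mass / leaf_area, c_ft_mass = c_ft_mass, slope = slope)
}

#' Extract pressure-volume traits from a bench-drying series
#'
#' Full PV-curve analysis of one leaf: relative water contents from the
#' mass series, turgor loss point by linear-tail analysis of the 1/psi
#' transform ([find_tlp()]), osmotic potential at full turgor, modulus of
#' elasticity ([pv_elasticity()]), capacitance at full turgor
#' ([pv_capacitance()]) and saturated water content.
#'
#' @param data A data frame for a single leaf with columns `psi_mpa`
#'   (signed MPa), `fresh_mass_g`, `dry_mass_g`, `sat_mass_g` and
#'   optionally `leaf_area_m2` (see [read_pv_curve()]).
#' @return An object of class `pv_fit`: a list with the traits (`swc`,
#'   `pi_o`, `psi_tlp`, `rwc_tlp`, `epsilon`, `c_ft`) plus diagnostics
#'   (`tail_n`, `r2_tail`, `n`, `degenerate`) and the working series.
#'   `tidy()` and `autoplot()` methods are available.
#' @export
fit_pv_curve <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("psi_mpa", "fresh_mass_g", "dry_mass_g", "sat_mass_g")
  if (!all(req %in% names(data))) {
    ht_schema_error(sprintf("`data` must contain columns %s.",
                            paste(req, collapse = ", ")))
  }
  if ("leaf_id" %in% names(data) && length(unique(data$leaf_id)) > 1) {
    ht_param_error("`fit_pv_curve()` analyzes one leaf; use `pv_traits()` for several.")
  }
  dry <- data$dry_mass_g[1]
  sat <- data$sat_mass_g[1]
  area <- if ("leaf_area_m2" %in% names(data)) data$leaf_area_m2[1] else NA
  d <- data[order(-data$fresh_mass_g), ]
  if (is.unsorted(rev(d$psi_mpa))) {
    # psi should become more negative as the leaf dries
    warn("psi is not monotonically decreasing along the drying series (noise or mis-ordered points).")
  }
  rwc <- compute_rwc(d$fresh_mass_g, dry, sat)
  swc <- saturated_water_content(dry, sat)

  # a first point at (or numerically above) zero potential cannot enter the
  # 1/psi transform; it still contributes to the turgid-phase regressions
  neg <- d$psi_mpa < 0
  tlp <- find_tlp(d$psi_mpa[neg], rwc[neg])
  el <- tryCatch(pv_elasticity(d$psi_mpa, rwc, tlp$pi_o, tlp$rwc_tlp),
                 ht_fit_error = function(e) {
                   warn(conditionMessage(e))
                   list(epsilon = NA_real_, n_supra = NA_integer_)
                 })
  cap <- tryCatch(pv_capacitance(d$psi_mpa, rwc, tlp$rwc_tlp,
                                 water_mass = sat - dry, leaf_area = area),
                  ht_fit_error = function(e) {
                    warn(conditionMessage(e))
                    list(c_ft = NA_real_, c_ft_mass = NA_real_, slope = NA_real_)
                  })

  structure(
    list(leaf_id = if ("leaf_id" %in% names(data)) data$leaf_id[1] else NA,
         swc = swc, pi_o = tlp$pi_o, psi_tlp = tlp$psi_tlp,
         rwc_tlp = tlp$rwc_tlp, epsilon = el$epsilon, c_ft = cap$c_ft,
         c_ft_mass = cap$c_ft_mass,
         tail_n = tlp$tail_n, r2_tail = tlp$r2_tail, n = nrow(d),
         n_supra = el$n_supra, degenerate = tlp$degenerate,
         series = tibble::tibble(psi = d$psi_mpa, rwc = rwc)),
    class = "pv_fit")
}

#' Per-leaf pressure-volume trait table
#'
#' Runs [fit_pv_curve()] on every leaf in a multi-leaf PV table and binds
#' the traits into one tibble.
#'
#' @param data A data frame as in [fit_pv_curve()] with a `leaf_id` column
#'   (and optionally `cultivar`).
#' @return A tibble with one row per leaf: `leaf_id`, optional `cultivar`,
#'   `swc`, `pi_o`, `psi_tlp`, `rwc_tlp`, `epsilon`, `c_ft`, plus
#'   diagnostics.
#' @export
pv_traits <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"leaf_id" %in% names(data)) data$leaf_id <- "leaf1"
  purrr::map_dfr(dplyr::group_split(data, .data$leaf_id), function(d) {
    fit <- fit_pv_curve(d)
    out <- tidy(fit)
    if ("cultivar" %in% names(d)) {
      out <- dplyr::bind_cols(tibble::tibble(cultivar = d$cultivar[1]), out)
    }
    out
  })
}

#' @export
print.pv_fit <- function(x, ...) {
  cat("Pressure-volume curve traits\n")
  cat(sprintf("  pi_o    = %7.3f MPa (magnitude)\n", x$pi_o))
  cat(sprintf("  psi_tlp = %7.3f MPa\n", x$psi_tlp))
  cat(sprintf("  rwc_tlp = %7.2f %%\n", x$rwc_tlp))
  cat(sprintf("  epsilon = %7.3f MPa\n", x$epsilon))
  cat(sprintf("  c_ft    = %7.3f mol m-2 MPa-1\n", x$c_ft))
  cat(sprintf("  swc     = %7.3f g g-1\n", x$swc))
  cat(sprintf("  tail: %d of %d points, R^2 = %.4f%s\n", x$tail_n, x$n,
              x$r2_tail, if (x$degenerate) " (degenerate: no turgid phase)" else ""))
  invisible(x)
}

#' @export
tidy.pv_fit <- function(x, ...) {
  tibble::tibble(
    leaf_id = x$leaf_id, swc = x$swc, pi_o = x$pi_o, psi_tlp = x$psi_tlp,
    rwc_tlp = x$rwc_tlp, epsilon = x$epsilon, c_ft = x$c_ft,
    tail_n = x$tail_n, r2_tail = x$r2_tail, n = x$n,
    degenerate = x$degenerate)
}
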