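# Independent oracles and small generators used across the suite.

# Exhaustive breakpoint search for the 3-segment continuous piecewise model:
# profiles the RSS of the closed-form linear fit over a dense grid of
# breakpoint pairs, with one local refinement pass at `fine` resolution.
# Independent of the package's iterative fitter.
oracle_piecewise_rss <- function(x, y, coarse = 0.01, fine = 0.001,
                                 min_gap = 0.055) {
  rss_at <- function(t1, t2) {
    X <- cbind(1, x, pmin(x - t1, 0), pmin(x - t2, 0))
    sum(lm.fit(X, y)$residuals^2)
  }
  rng <- range(x)
  grid <- seq(rng[1] + 0.05, rng[2] - 0.05, by = coarse)
  pairs <- expand.grid(t1 = grid, t2 = grid)
  pairs <- pairs[pairs$t2 < pairs$t1 - min_gap, ]
  pairs$rss <- mapply(rss_at, pairs$t1, pairs$t2)
  # refine around the best few coarse basins at `fine` resolution; pick
  # candidates greedily with a spacing constraint so several distinct
  # basins are represented, not just neighbours of the single best cell
  ord <- order(pairs$rss)
  top <- pairs[0, ]
  for (idx in ord) {
    if (nrow(top) == 8) break
    cand <- pairs[idx, ]
    if (nrow(top) == 0 ||
        all(pmax(abs(top$t1 - cand$t1), abs(top$t2 - cand$t2)) > 0.04)) {
      top <- rbind(top, cand)
    }
  }
  best <- list(rss = Inf)
  for (i in seq_len(nrow(top))) {
    for (t1 in seq(top$t1[i] - coarse, top$t1[i] + coarse, by = fine)) {
      for (t2 in seq(top$t2[i] - coarse, top$t2[i] + coarse, by = fine)) {
        if (t2 >= t1 - min_gap) next
        r <- rss_at(t1, t2)
        if (r < best$rss) best <- list(rss = r, t1 = t1, t2 = t2)
      }
    }
  }
  # coordinate-descent finish: the profile RSS is smooth between data
  # points, so alternating 1-D minimization reaches the basin floor
  for (round in 1:8) {
    o1 <- optimize(function(t) rss_at(t, best$t2),
                   c(best$t1 - 2 * fine, best$t1 + 2 * fine), tol = 1e-10)
    if (o1$objective < best$rss) {
      best$t1 <- o1$minimum
      best$rss <- o1$objective
    }
    o2 <- optimize(function(t) rss_at(best$t1, t),
                   c(best$t2 - 2 * fine, best$t2 + 2 * fine), tol = 1e-10)
    if (o2$objective < best$rss) {
      best$t2 <- o2$minimum
      best$rss <- o2$objective
    }
  }
  best
}

# Table of published cultivar anchor values used as internal-consistency
# inputs (sigma, hydroscape MPa^2, psi_gs90, psi_tlp, p50).
anchor_cultivars <- function() {
  tibble::tibble(
    cultivar = c("Avijor", "Isabelona", "Soleta"),
    sigma = c(0.922, 0.811, 0.867),
    hydroscape = c(8.74, 8.13, 9.23),
    psi_gs90 = c(-1.72, -2.25, -2.14),
    psi_tlp = c(-2.01, -2.31, -2.87),
    p50 = c(-2.97, -3.80, -3.73))
}

# Published triphasic water-potential-curve parameters (per cultivar:
# theta1, theta2, beta1..3). Intercept -0.037 reproduces the published
# 1:1-line intersection of -6.15 MPa for the first cultivar.
avijor_wp_params <- function() {
  list(intercept = -0.037, beta = c(2.594, 1.015, 0.711),
       theta = c(-0.803, -1.553))
}

# noiseless ideal PV curve from (pi_o, epsilon), zero apoplast
gen_ideal_pv <- function(pi_o, epsilon, rwc = seq(100, 60, length.out = 41),
                         dry = 0.2, sat = 0.6, area = 0.001) {
  psi_pi <- -pi_o * 100 / rwc
  psi_p <- pmax(0, pi_o - epsilon * (1 - rwc / 100))
  tibble::tibble(
    leaf_id = "L1",
    psi_mpa = psi_pi + psi_p,
    fresh_mass_g = dry + rwc / 100 * (sat - dry),
    dry_mass_g = dry, sat_mass_g = sat, leaf_area_m2 = area)
}

# kinetic gs decline data with optional multiplicative noise
gen_kinetic_gs <- function(g0 = 500, k = 1.2, n = 30, psi_range = c(-3, 0),
                           noise = 0, seed = NULL) {
  psi <- seq(psi_range[1], psi_range[2], length.out = n)
  gs <- g0 * exp(k * psi)
  if (noise > 0) {
    gs <- withr::with_seed(seed, gs * (1 + rnorm(n, 0, noise)))
  }
  tibble::tibble(psi_min = psi, gs = pmax(gs, 0))
}

# noiseless Weibull vulnerability table at given pressures
gen_weibull_vc <- function(b, c, pressures = vc_pressure_steps(), kmax = 1,
                           noise = 0, seed = NULL, n_stems = 1) {
  purrr::map_dfr(seq_len(n_stems), function(s) {
    kh <- kmax * exp(-(pressures / b)^c)
    if (noise > 0) {
      kh <- withr::with_seed(seed + s, kh * (1 + rnorm(length(kh), 0, noise)))
    }
    tibble::tibble(stem_id = paste0("s", s), pressure_mpa = pressures,
                   kh = pmax(kh, 0), kmax = kmax)
  })
}
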