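test_that("ideal noiseless curves return the generating traits", {
  d <- gen_ideal_pv(pi_o = 2, epsilon = 10)
  fit <- fit_pv_curve(d)
  # closed forms: psi_tlp = -pi_o*eps/(eps-pi_o), rwc_tlp = 100*(1-pi_o/eps)
  expect_equal(fit$psi_tlp, -2.5, tolerance = 2.5 * 0.005)
  expect_equal(fit$rwc_tlp, 80, tolerance = 80 * 0.005)
  expect_equal(fit$pi_o, 2, tolerance = 2 * 0.005)
  expect_equal(fit$epsilon, 10, tolerance = 10 * 0.005)
  expect_equal(fit$swc, 2, tolerance = 1e-12)
  expect_false(fit$degenerate)
})

test_that("rigid-wall limit pushes the TLP to full turgor", {
  rwc <- c(seq(100, 99, length.out = 11), seq(98.8, 92, length.out = 18))
  d <- gen_ideal_pv(pi_o = 2, epsilon = 1000, rwc = rwc)
  fit <- fit_pv_curve(d)
  expect_equal(fit$psi_tlp, -2, tolerance = 0.02)
  expect_gt(fit$rwc_tlp, 99)
})

test_that("a purely osmotic series is flagged degenerate", {
  rwc <- seq(95, 60, length.out = 12)
  d <- tibble::tibble(
    leaf_id = "L1", psi_mpa = -2 * 100 / rwc,
    fresh_mass_g = 0.2 + rwc / 100 * 0.4,
    dry_mass_g = 0.2, sat_mass_g = 0.6, leaf_area_m2 = 0.001)
  expect_warning(fit <- fit_pv_curve(d), "degenerate")
  expect_true(fit$degenerate)
  expect_equal(fit$rwc_tlp, 95, tolerance = 1e-9)
})

test_that("curves with no linear tail are rejected", {
  set.seed(8)
  rwc <- seq(100, 60, length.out = 15)
  d <- tibble::tibble(
    leaf_id = "L1",
    psi_mpa = -exp(seq(0.1, 2, length.out = 15)) + rnorm(15, 0, 0.4),
    fresh_mass_g = 0.2 + rwc / 100 * 0.4,
    dry_mass_g = 0.2, sat_mass_g = 0.6)
  d$psi_mpa <- pmin(d$psi_mpa, -0.01)
  expect_error(fit_pv_curve(d), class = "ht_fit_error")
})

test_that("elasticity recovery tolerates moderate noise", {
  # scale patterned on a stiff-leaved crop: epsilon 12.91, pi_o 1.5;
  # 0.02 MPa chamber-scale noise on the potentials
  errs <- vapply(1:20, function(i) {
    rwc <- seq(100, 60, length.out = 41)
    d <- gen_ideal_pv(pi_o = 1.5, epsilon = 12.91, rwc = rwc)
    d$psi_mpa <- withr::with_seed(300 + i,
      pmin(d$psi_mpa + rnorm(41, 0, 0.02), -1e-4))
    fit <- tryCatch(suppressWarnings(fit_pv_curve(d)), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$epsilon - 12.91) / 12.91
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("flat turgor (zero elasticity) is flagged nonphysical", {
  rwc <- seq(100, 60, length.out = 21)
  psi <- -2 * 100 / rwc + 2          # psi_p constant at pi_o: epsilon = 0
  expect_warning(
    out <- pv_elasticity(pmin(psi, -1e-6), rwc, pi_o = 2, rwc_tlp = 80),
    "nonphysical")
  expect_lt(abs(out$epsilon), 0.1)
})

test_that("capacitance follows the unit arithmetic and scales with area", {
  # slope 0.05 MPa-1 exactly: rwc/100 = 1 + 0.05 * psi
  psi <- seq(-2, -0.1, length.out = 10)
  rwc <- 100 * (1 + 0.05 * psi)
  out <- pv_capacitance(psi, rwc, rwc_tlp = min(rwc), water_mass = 0.4,
                        leaf_area = 0.001)
  expect_equal(out$c_ft, 0.05 * 0.4 / (18.015 * 0.001), tolerance = 1e-9)
  expect_equal(out$c_ft, 1.110, tolerance = 1e-3)
  out2 <- pv_capacitance(psi, rwc, rwc_tlp = min(rwc), water_mass = 0.4,
                         leaf_area = 0.002)
  expect_equal(out2$c_ft, out$c_ft / 2, tolerance = 1e-12)
  expect_warning(
    out3 <- pv_capacitance(psi, rwc, rwc_tlp = min(rwc), water_mass = 0.4),
    "leaf_area")
  expect_true(is.na(out3$c_ft))
  expect_equal(out3$c_ft_mass, 0.05 * 0.4 / 18.015, tolerance = 1e-9)
})

test_that("turgor loss cannot sit above the full-turgor osmotic potential", {
  for (pars in list(c(1.5, 8), c(2, 10), c(2.5, 6))) {
    d <- gen_ideal_pv(pi_o = pars[1], epsilon = pars[2])
    fit <- fit_pv_curve(d)
    expect_gte(abs(fit$psi_tlp), fit$pi_o - 1e-6)
  }
})

test_that("TLP location is invariant to uniform mass rescaling", {
  d <- gen_ideal_pv(pi_o = 2, epsilon = 10)
  f1 <- fit_pv_curve(d)
  d2 <- d
  d2$fresh_mass_g <- d2$fresh_mass_g * 1000  # g -> mg
  d2$dry_mass_g <- d2$dry_mass_g * 1000
  d2$sat_mass_g <- d2$sat_mass_g * 1000
  f2 <- fit_pv_curve(d2)
  expect_equal(f2$psi_tlp, f1$psi_tlp, tolerance = 1e-12)
  expect_equal(f2$rwc_tlp, f1$rwc_tlp, tolerance = 1e-12)
})

test_that("multi-leaf tables produce one trait row per leaf", {
  d1 <- gen_ideal_pv(pi_o = 2, epsilon = 10)
  d2 <- gen_ideal_pv(pi_o = 1.6, epsilon = 8)
  d2$leaf_id <- "L2"
  out <- pv_traits(dplyr::bind_rows(d1, d2))
  expect_equal(nrow(out), 2)
  expect_equal(out$pi_o, c(2, 1.6), tolerance = 0.01)
})
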