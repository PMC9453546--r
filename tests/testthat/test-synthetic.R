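test_that("well-watered controls hold predawn potential at baseline", {
  pre <- cultivar_preset("avijor-like")
  ww <- simulate_drydown(pre, days = 20, treatment = "WW", n_plants = 2,
                         seed = 3)
  truth <- attr(ww, "truth")$state
  expect_equal(truth$gwc, rep(pre$ww_gwc, 20), tolerance = 1e-12)
  expect_equal(diff(truth$psi_pd), rep(0, 19), tolerance = 1e-12)
})

test_that("dry-down conserves water and closes the psi gap at depth", {
  pre <- cultivar_preset("soleta-like")
  pd <- simulate_drydown(pre, days = 50, seed = 4, n_plants = 1)
  truth <- attr(pd, "truth")
  state <- truth$state
  # conservation: cumulative transpiration equals depleted substrate water
  expect_equal(truth$transpired_g, pre$capacity_g - truth$water_end_g,
               tolerance = 1e-6)
  # monotone drydown of the true state
  expect_true(all(diff(state$gwc) < 0))
  expect_true(all(diff(state$psi_pd) < 0))
  expect_true(all(state$psi_min <= state$psi_pd))
  # stomatal closure limit: the psi_min - psi_pd gap shrinks at low GWC
  gap <- state$psi_pd - state$psi_min
  deep <- retention_psi(20, pre$retention_a, pre$retention_n)
  psi_deep <- hydrotraits:::solve_psi_min(deep, pre)
  expect_lt(deep - psi_deep, 1)
  expect_lt(deep - psi_deep, max(gap))
})

test_that("generator output is byte-identical under a repeated seed", {
  pre <- cultivar_preset("isabelona-like")
  a <- simulate_drydown(pre, days = 15, seed = 77, n_plants = 3)
  b <- simulate_drydown(pre, days = 15, seed = 77, n_plants = 3)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_table(a, f1)
  write_table(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # per-channel substreams: a different seed changes draws
  c2 <- simulate_drydown(pre, days = 15, seed = 78, n_plants = 3)
  expect_false(identical(a$psi_pd, c2$psi_pd))
})

test_that("synthetic vulnerability curves invert to the preset P50", {
  pre <- cultivar_preset("soleta-like")
  pre$noise_kh <- 0
  vc <- simulate_vulnerability(pre, n_stems = 1, seed = 1)
  # PLC at |P50| is exactly 50
  kmax <- vc$kh[vc$pressure_mpa == 0]
  kh_at_p50 <- kmax * exp(-(abs(pre$p50) / pre$weibull_b)^pre$weibull_c)
  expect_equal(compute_plc(kh_at_p50, kmax), 50, tolerance = 1e-9)
  # P = 0 row carries kmax: PLC 0
  expect_equal(compute_plc(vc$kh[vc$pressure_mpa == 0], kmax), 0,
               tolerance = 1e-12)
  # doubling kmax leaves PLC unchanged
  fit1 <- fit_weibull(vc)
  vc2 <- vc
  vc2$kh <- vc2$kh * 2
  fit2 <- fit_weibull(vc2)
  expect_equal(fit2$p50, fit1$p50, tolerance = 1e-9)
  expect_equal(fit1$p50, pre$p50, tolerance = 1e-6)
})

test_that("synthetic PV curves embed the ideal model exactly when noiseless", {
  pre <- cultivar_preset("avijor-like")
  pre$noise_psi_pv <- 0
  pre$noise_mass_pv <- 0
  pv <- simulate_pv_curve(pre, n_leaves = 1, seed = 2)
  # full turgor: psi = 0 (clipped to -1e-4 for storage)
  expect_equal(max(pv$psi_mpa), -1e-4, tolerance = 1e-9)
  # below the TLP, 1/psi is exactly linear in (100 - RWC)
  rwc <- compute_rwc(pv$fresh_mass_g, pv$dry_mass_g[1], pv$sat_mass_g[1])
  rwc_tlp <- 100 * (1 - pre$pi_o / pre$epsilon)
  post <- rwc < rwc_tlp - 1e-9
  f <- lm(I(1 / psi_mpa[post]) ~ I(100 - rwc[post]), data = pv)
  expect_lt(sum(resid(f)^2), 1e-16)
  # analyzed traits match the preset closed forms
  fit <- fit_pv_curve(pv)
  expect_equal(fit$psi_tlp, pre$psi_tlp, tolerance = 0.01)
  expect_equal(fit$pi_o, pre$pi_o, tolerance = 0.01)
  # degenerate preset rejected
  bad <- pre
  bad$pi_o <- 20
  expect_error(simulate_pv_curve(bad), class = "ht_param_error")
})

test_that("every analysis stage recovers its generating parameters (master loop)", {
  pre <- cultivar_preset("isabelona-like")
  pre$noise_kh <- 0
  pre$noise_psi_pv <- 0
  pre$noise_mass_pv <- 0
  vc <- simulate_vulnerability(pre, n_stems = 2, seed = 10)
  expect_equal(fit_weibull(vc)$p50, pre$p50, tolerance = 1e-6)
  pv <- simulate_pv_curve(pre, n_leaves = 1, seed = 10)
  pfit <- fit_pv_curve(pv)
  expect_equal(pfit$epsilon, pre$epsilon, tolerance = pre$epsilon * 0.005)
  expect_equal(pfit$rwc_tlp, 100 * (1 - pre$pi_o / pre$epsilon),
               tolerance = 0.5)
  # kinetic decline from the true dry-down state
  dd <- simulate_drydown(pre, seed = 10, n_plants = 1)
  kin <- fit_gs_kinetic(tibble::tibble(psi_min = dd$psi_min_true,
                                       gs = dd$gs_true))
  expect_equal(kin$k, pre$k_stomatal, tolerance = 1e-6)
  expect_equal(kin$psi_gs90, pre$psi_gs90, tolerance = 1e-6)
})
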