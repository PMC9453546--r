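test_that("GWC is the affine interpolation between dry and wet pot weights", {
  expect_equal(compute_gwc(5, 4, 6), 50)
  expect_equal(compute_gwc(6, 4, 6), 100)   # container capacity
  expect_equal(compute_gwc(4, 4, 6), 0)     # oven dry
  # affine: exact endpoints for arbitrary weights
  for (dw in list(c(2, 3.5), c(0.1, 9), c(4, 4.01))) {
    expect_equal(compute_gwc(dw[1], dw[1], dw[2]), 0)
    expect_equal(compute_gwc(dw[2], dw[1], dw[2]), 100)
  }
  expect_warning(compute_gwc(6.2, 4, 6), "exceed 100")
  expect_error(compute_gwc(5, 4, 4), class = "ht_param_error")
})

test_that("PLC conserves relative conductivity and clips noise", {
  expect_equal(compute_plc(1, 1), 0)
  expect_equal(compute_plc(0.5, 1), 50)
  expect_equal(compute_plc(0, 1), 100)
  # conservation: PLC + 100*kh/kmax = 100 on [0, kmax]
  kh <- seq(0, 2, length.out = 21)
  expect_equal(compute_plc(kh, 2) + 100 * kh / 2, rep(100, 21))
  expect_warning(out <- compute_plc(1.1, 1), "clipped")
  expect_equal(out, 0)
  expect_error(compute_plc(1, 0), class = "ht_param_error")
  expect_error(compute_plc(-0.1, 1), class = "ht_param_error")
})

test_that("iWUE is a per-record ratio, undefined for non-positive E", {
  expect_equal(compute_iwue(10, 5), 2)
  expect_equal(compute_iwue(0, 5), 0)
  expect_equal(compute_iwue(12, 4.8), 2.5)
  expect_warning(out <- compute_iwue(c(10, 10), c(5, 0)), "undefined")
  expect_equal(out, c(2, NA))
})

test_that("RWC and SWC follow their mass definitions", {
  expect_equal(compute_rwc(0.6, 0.2, 0.6), 100)
  expect_equal(compute_rwc(0.4, 0.2, 0.6), 50)
  expect_equal(saturated_water_content(0.2, 0.6), 2)
  expect_error(compute_rwc(0.1, 0.2, 0.6), class = "ht_param_error")
})

test_that("CSV round-trip preserves records bit-exactly", {
  d <- tibble::tibble(
    plant_id = c("p1", "p2", "p3"),
    day = c(1, 9, 50),
    psi_pd = c(-0.123456789, -1.5, -3.00000001),
    psi_min = c(-1.3, -2.25, -3.1),
    cultivar = "cv", treatment = "PD")
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(d, path)
  back <- read_table(path, "water_potential")
  expect_equal(back$psi_pd, d$psi_pd)
  expect_equal(back$psi_min, d$psi_min)
  expect_equal(nrow(back), 3)
  expect_true(all(back$flag == ""))
})

test_that("sign convention: all-positive potentials auto-negate, mixed signs error", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- tibble::tibble(plant_id = "p1", day = 1:3,
                      psi_pd = c(0.5, 1.0, 1.5), psi_min = c(-1, -2, -2.5))
  write_table(d, path)
  expect_message(back <- read_table(path, "water_potential"), "negating")
  expect_equal(back$psi_pd, c(-0.5, -1.0, -1.5))

  d$psi_pd <- c(0.5, -1.0, 1.5)
  write_table(d, path)
  expect_error(read_table(path, "water_potential"), class = "ht_schema_error")
})

test_that("inconsistent records are flagged, never dropped", {
  d <- tibble::tibble(plant_id = "p1", day = 1:3,
                      psi_pd = c(-1, -1, -1), psi_min = c(-0.5, -1.5, -2))
  expect_warning(out <- validate_table(d, "water_potential"), "flagged")
  expect_equal(nrow(out), 3)
  expect_match(out$flag[1], "psi_min_above_psi_pd")
  expect_true(all(out$flag[2:3] == ""))
})

test_that("schema violations are reported with offending locations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("plant_id,day,psi_pd,psi_min,bogus\np1,1,-1,-2,x", path)
  expect_error(read_table(path, "water_potential"), "unknown column",
               class = "ht_schema_error")
  writeLines("plant_id,day,psi_pd,psi_min\np1,1,-1,-2\np2,oops,-1,-2", path)
  expect_error(read_table(path, "water_potential"), "non-numeric",
               class = "ht_schema_error")
  writeLines("plant_id,day,psi_pd,psi_min", path)
  expect_warning(out <- read_table(path, "water_potential"), "empty")
  expect_equal(nrow(out), 0)
})
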