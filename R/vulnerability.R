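#' The standard air-injection pressure sequence
#'
#' Applied tensions (positive MPa) used by default for synthetic
#' vulnerability curves: 0.5 to 4.0 MPa in 0.5 MPa steps, then 5, 6 and
#' 7 MPa (11 steps).
#'
#' @return Numeric vector of 11 pressures (MPa).
#' @export
vc_pressure_steps <- function() {
  c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7)
}

# normalize a vulnerability table: per-stem kmax (explicit column or the
# flushed measurement at pressure 0), relative conductivity, PLC
prepare_vc <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("pressure_mpa", "kh")
  if (!all(req %in% names(data))) {
    ht_schema_error("`data` must contain columns `pressure_mpa` and `kh`.")
  }
  if (!"stem_id" %in% names(data)) data$stem_id <- "stem1"
  if (any(data$pressure_mpa < 0, na.rm = TRUE)) {
    ht_schema_error("Applied pressures must be positive MPa of tension.")
  }

  split <- dplyr::group_split(data, .data$stem_id)
  out <- purrr::map_dfr(split, function(d) {
    d <- d[order(d$pressure_mpa), ]
    if ("kmax" %in% names(d) && any(!is.na(d$kmax))) {
      kmax <- d$kmax[!is.na(d$kmax)][1]
    } else if (any(d$pressure_mpa == 0)) {
      kmax <- mean(d$kh[d$pressure_mpa == 0])
    } else {
      ht_param_error(sprintf(
        "Stem '%s': no `kmax` column and no flushed (pressure 0) measurement; K_max unavailable.",
        d$stem_id[1]))
    }
    if (is.na(kmax) || kmax <= 0) {
      ht_param_error(sprintf("Stem '%s': K_max must be positive.", d$stem_id[1]))
    }
    d <- d[d$pressure_mpa > 0, ]
    if (anyDuplicated(d$pressure_mpa)) {
      warn(sprintf("Stem '%s': duplicated pressure steps retained.", d$stem_id[1]))
    }
    d$kmax <- kmax
    d$relk <- d$kh / kmax
    d$plc <- compute_plc(d$kh, kmax)
    d
  })
  out
}

#' Fit a Weibull xylem vulnerability curve
#'
#' Fits the Weibull vulnerability model to (applied pressure, conductance)
#' measurements by nonlinear least squares on relative conductivity:
#' `K(P) / K_max = exp(-(P / b)^c)` with scale `b > 0` (MPa) and shape
#' `c > 0`. The pressure of x% conductivity loss is
#' `Px = b * (-log(1 - x/100))^(1/c)`; P50 is reported with the package's
#' negative sign convention for water potentials.
#'
#' Fitting is done on relative conductivity (not PLC) to keep the error
#' structure simple; multiple stems are pooled after normalizing each stem
#' by its own K_max. A deterministic multistart grid
#' (`c` in {1, 2, 4, 8} crossed with two data-driven scale guesses) guards
#' against local minima.
#'
#' @param data A data frame with columns `pressure_mpa` (positive MPa of
#'   tension) and `kh`, plus either a `kmax` column or flushed rows at
#'   `pressure_mpa == 0`; optional `stem_id` for multi-stem pooling (see
#'   [read_vulnerability()]).
#' @return An object of class `weibull_fit` with elements `b`, `c`, `p50`
#'   (signed MPa), `rss`, `r2`, `n`, the prepared data, and (after
#'   [bootstrap_p50()]) `ci_p50`, `n_boot`, `seed`. Methods: `tidy()`,
#'   `glance()`, `autoplot()`, and [weibull_px()].
#' @examples
#' p <- vc_pressure_steps()
#' d <- data.frame(pressure_mpa = p, kh = exp(-(p / 4)^3), kmax = 1)
#' fit <- fit_weibull(d)
#' fit$p50 # -3.540 = -4 * log(2)^(1/3)
#' @export
fit_weibull <- function(data) {
  d <- prepare_vc(data)
  if (length(unique(d$pressure_mpa)) < 5) {
    ht_fit_error("Need at least 5 distinct pressure steps to fit a vulnerability curve.")
  }
  max_plc <- max(d$plc)
  if (max_plc < 50) {
    warn(sprintf(
      "Maximum observed PLC is %.1f%% (< 50%%): P50 will be extrapolated beyond the data.",
      max_plc))
  } else if (max_plc < 80 || min(d$plc) > 20) {
    warn("PLC observations do not span 20-80%; parameter estimates may be weakly constrained.")
  }

  # scale guesses: pressure where PLC first exceeds half its maximum, and the
  # median applied pressure
  p_half <- d$pressure_mpa[which(d$plc >= max_plc / 2)[1]]
  starts <- expand.grid(c = c(1, 2, 4, 8),
                        b = unique(c(p_half, median(d$pressure_mpa))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(relk ~ exp(-(pressure_mpa / b)^c), data = d,
                        start = list(b = starts$b[i], c = starts$c[i]),
                        lower = c(b = 1e-6, c = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    ht_fit_error("Weibull fit failed from every multistart point.")
  }
  cf <- coef(best$fit)
  tss <- sum((d$relk - mean(d$relk))^2)
  structure(
    list(b = unname(cf["b"]), c = unname(cf["c"]),
         p50 = -unname(cf["b"]) * log(2)^(1 / unname(cf["c"])),
         rss = best$rss, r2 = if (tss > 0) 1 - best$rss / tss else NA_real_,
         n = nrow(d), n_stems = length(unique(d$stem_id)),
         data = d, extrapolated = max_plc < 50),
    class = "weibull_fit")
}

#' Pressure of x% conductivity loss from a fitted Weibull curve
#'
#' @param fit A `weibull_fit`.
#' @param x Percent loss of conductivity, in (0, 100).
#' @return Water potential (signed MPa) at `x`% loss:
#'   `-b * (-log(1 - x/100))^(1/c)`.
#' @examples
#' # weibull_px(fit, 50) equals fit$p50
#' @export
weibull_px <- function(fit, x) {
  stopifnot(inherits(fit, "weibull_fit"))
  check_number(x, "x", lower = 1e-9, upper = 100 - 1e-9)
  -fit$b * (-log(1 - x / 100))^(1 / fit$c)
}

#' Case-resampling bootstrap confidence interval for P50
#'
#' Resamples the pooled (pressure, conductance) observations with
#' replacement, refits the Weibull curve to each replicate, and returns the
#' percentile interval of P50. Deterministic given `seed`. Replicates whose
#' refit fails are dropped; if more than 20% fail the interval is flagged
#' unstable with a warning.
#'
#' @param fit A `weibull_fit` from [fit_weibull()].
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed controlling the resampling.
#' @param level Confidence level (default 0.95).
#' @return The input fit with elements `ci_p50` (length-2 signed MPa,
#'   most-negative first), `boot_p50` (replicate estimates), `n_boot`,
#'   `seed`, `boot_fail_rate` and `unstable` filled in.
#' @export
bootstrap_p50 <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!is.numeric(n_boot) || n_boot < 100) {
    ht_param_error("`n_boot` must be at least 100.")
  }
  d <- fit$data
  start <- list(b = fit$b, c = fit$c)
  draws <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(nrow(d), nrow(d) * n_boot, replace = TRUE), nrow = n_boot)
  })
  p50s <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    db <- d[draws[i, ], ]
    fb <- tryCatch(
      minpack.lm::nlsLM(relk ~ exp(-(pressure_mpa / b)^c), data = db,
                        start = start, lower = c(b = 1e-6, c = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 60)),
      error = function(e) NULL)
    if (!is.null(fb)) {
      cf <- coef(fb)
      p50s[i] <- -cf["b"] * log(2)^(1 / cf["c"])
    }
  }
  fail_rate <- mean(is.na(p50s))
  if (all(is.na(p50s))) {
    ht_fit_error("All bootstrap replicates failed to fit.")
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(p50s, c(alpha, 1 - alpha), na.rm = TRUE))
  fit$ci_p50 <- sort(ci)  # most negative first
  fit$boot_p50 <- p50s
  fit$n_boot <- n_boot
  fit$seed <- seed
  fit$boot_fail_rate <- fail_rate
  fit$unstable <- fail_rate > 0.2
  if (fit$unstable) {
    warn(sprintf("Bootstrap unstable: %.0f%% of replicates failed to refit.",
                 100 * fail_rate))
  }
  fit
}

#' Hydraulic safety margin
#'
#' `HSM = psi_gs90 - p50`, both in signed MPa. A positive margin means
#' stomata close before half of the stem conductivity is lost - the
#' cavitation-avoidance signature.
#'
#' @param psi_gs90 Water potential at 90% stomatal closure (MPa, <= 0).
#' @param p50 Water potential at 50% loss of conductivity (MPa, <= 0).
#' @return The safety margin in MPa.
#' @examples
#' safety_margin(-1.72, -2.97) # 1.25
#' @export
safety_margin <- function(psi_gs90, p50) {
  check_number(psi_gs90, "psi_gs90", upper = 0)
  check_number(p50, "p50", upper = 0)
  psi_gs90 - p50
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull vulnerability curve: K/Kmax = exp(-(P/b)^c)\n")
  cat(sprintf("  b = %.4f MPa, c = %.4f\n", x$b, x$c))
  cat(sprintf("  P50 = %.4f MPa%s\n", x$p50,
              if (isTRUE(x$extrapolated)) " (extrapolated beyond observed PLC)" else ""))
  if (!is.null(x$ci_p50)) {
    cat(sprintf("  95%% bootstrap CI: [%.4f, %.4f] (n_boot = %d, seed = %s%s)\n",
                x$ci_p50[1], x$ci_p50[2], x$n_boot, x$seed,
                if (isTRUE(x$unstable)) ", UNSTABLE" else ""))
  }
  cat(sprintf("  n = %d observations, %d stem(s), R^2 = %.4f\n",
              x$n, x$n_stems, x$r2))
  invisible(x)
}

#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("b", "c", "p50"),
    estimate = c(x$b, x$c, x$p50))
}

#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(
    b = x$b, c = x$c, p50 = x$p50,
    ci_low = if (is.null(x$ci_p50)) NA_real_ else x$ci_p50[1],
    ci_high = if (is.null(x$ci_p50)) NA_real_ else x$ci_p50[2],
    r.squared = x$r2, nobs = x$n, n_stems = x$n_stems,
    n_boot = x$n_boot %||% NA_integer_)
}
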