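#' First-order kinetic model of stomatal conductance decline
#'
#' Fits the two-parameter exponential decay
#' `gs(psi) = g0 * exp(k * psi)` (`k > 0`, `psi <= 0`) to stomatal
#' conductance against midday water potential by Gauss-Newton nonlinear
#' least squares with numeric derivatives. `g0` is the fitted conductance
#' at `psi = 0` (the operational maximum of the fit) and the water
#' potential at 90% stomatal closure follows in closed form:
#' `psi_gs90 = log(0.1) / k`.
#'
#' An optional three-parameter variant adds an additive conductance floor
#' `g_min` (`gs = g_min + g0 * exp(k * psi)`), useful when residual
#' (cuticular) conductance keeps gs from reaching zero; `psi_gs90` then
#' refers to the decaying component.
#'
#' @param data A data frame with columns `psi_min` (signed MPa) and `gs`.
#' @param floor Fit the three-parameter variant with an additive `g_min`?
#'   Default `FALSE` (the standard first-order form).
#' @return An object of class `gs_kinetic_fit` with elements `g0`, `k`,
#'   `g_min` (0 for the two-parameter form), `psi_gs90`, `r2`, `n`,
#'   `no_response` (flag for k ~ 0). Methods: `tidy()`, `glance()`,
#'   `autoplot()`.
#' @examples
#' d <- data.frame(psi_min = seq(-4, 0, length.out = 8))
#' d$gs <- 500 * exp(1.2 * d$psi_min)
#' fit_gs_kinetic(d)$k # 1.2
#' @export
fit_gs_kinetic <- function(data, floor = FALSE) {
  data <- tibble::as_tibble(data)
  if (!all(c("psi_min", "gs") %in% names(data))) {
    ht_schema_error("`data` must contain columns `psi_min` and `gs`.")
  }
  d <- data[complete.cases(data[c("psi_min", "gs")]), c("psi_min", "gs")]
  if (nrow(d) < 6) {
    ht_fit_error("Need at least 6 (psi_min, gs) pairs.")
  }
  if (sd(d$gs) < 1e-10 * max(1, mean(abs(d$gs)))) {
    warn("Constant gs data: no stomatal response detectable (k = 0).")
    return(structure(
      list(g0 = mean(d$gs), k = 0, g_min = 0, psi_gs90 = NA_real_,
           r2 = NA_real_, n = nrow(d), no_response = TRUE, data = d),
      class = "gs_kinetic_fit"))
  }

  # log-linear start (positive gs only), then Gauss-Newton multistart
  pos <- d$gs > 0
  start_k <- 1
  start_g0 <- max(d$gs)
  if (sum(pos) >= 2 && sd(d$psi_min[pos]) > 0) {
    lf <- lm(log(gs) ~ psi_min, data = d[pos, ])
    start_g0 <- exp(unname(coef(lf)[1]))
    start_k <- max(unname(coef(lf)[2]), 0.01)
  }
  best <- NULL
  for (mult in c(1, 0.5, 2)) {
    st <- if (floor) {
      list(g_min = max(min(d$gs), 1e-3), g0 = start_g0, k = start_k * mult)
    } else {
      list(g0 = start_g0, k = start_k * mult)
    }
    form <- if (floor) gs ~ g_min + g0 * exp(k * psi_min) else gs ~ g0 * exp(k * psi_min)
    fit <- tryCatch(
      stats::nls(form, data = d, start = st,
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = d, start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    ht_fit_error("Kinetic gs model did not converge from any start.")
  }
  cf <- coef(best$fit)
  k <- unname(cf["k"])
  g0 <- unname(cf["g0"])
  g_min <- if (floor) unname(cf["g_min"]) else 0
  no_response <- k < 1e-6
  if (no_response) {
    warn("Fitted k is ~0: no stomatal response to psi_min.")
  }
  tss <- sum((d$gs - mean(d$gs))^2)
  structure(
    list(g0 = g0, k = k, g_min = g_min,
         psi_gs90 = if (no_response) NA_real_ else log(0.1) / k,
         r2 = 1 - best$rss / tss, rss = best$rss, n = nrow(d),
         no_response = no_response, data = d),
    class = "gs_kinetic_fit")
}

#' Water potential at 90% stomatal closure by weighted polynomial fit
#'
#' Fits a polynomial (default degree 2) of stomatal conductance against
#' midday water potential, weighted proportionally to the observed gs so
#' that near-closed stomata do not dominate the fit. The reference
#' conductance `gs_ref` is the fitted value at the least negative observed
#' psi, and `psi_gs90` is the most negative real root of
#' `fitted(psi) = 0.1 * gs_ref` within the observed psi range (a root up
#' to 25% of the range beyond it is returned with an `extrapolated` flag).
#' A case-resampling bootstrap provides a percentile confidence interval.
#'
#' @param data A data frame with columns `psi_min` (signed MPa) and `gs`.
#' @param degree Polynomial degree (default 2).
#' @param n_boot Bootstrap replicates for the CI; 0 (default) skips the
#'   bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @param weights `"gs"` (default; weights proportional to observed gs) or
#'   `"equal"`.
#' @return An object of class `gs_poly_fit` with elements `coefs`,
#'   `gs_ref`, `psi_gs90`, `extrapolated`, `saturated`, `ci_psi_gs90`
#'   (when bootstrapped), `r2`, `n`. Methods: `tidy()`, `glance()`.
#' @export
fit_psi_gs90 <- function(data, degree = 2, n_boot = 0, seed = 1,
                         weights = c("gs", "equal")) {
  weights <- match.arg(weights)
  data <- tibble::as_tibble(data)
  if (!all(c("psi_min", "gs") %in% names(data))) {
    ht_schema_error("`data` must contain columns `psi_min` and `gs`.")
  }
  d <- data[complete.cases(data[c("psi_min", "gs")]), c("psi_min", "gs")]
  if (nrow(d) < degree + 3) {
    ht_fit_error(sprintf("Need at least %d points for a degree-%d fit.",
                         degree + 3, degree))
  }
  if (any(d$gs < 0)) {
    ht_param_error("`gs` must be non-negative.")
  }

  core <- function(d) {
    w <- if (weights == "gs") pmax(d$gs, 0) else rep(1, nrow(d))
    if (all(w == 0)) w <- rep(1, nrow(d))
    fit <- lm(gs ~ poly(psi_min, degree, raw = TRUE), data = d, weights = w)
    coefs <- unname(coef(fit))
    psi_ref <- max(d$psi_min)
    gs_ref <- unname(predict(fit, newdata = data.frame(psi_min = psi_ref)))
    if (gs_ref <= 0) {
      ht_fit_error("Fitted reference conductance is non-positive.")
    }
    target <- 0.1 * gs_ref
    rng <- range(d$psi_min)
    # saturated case: everything already below 10% of the reference
    if (all(d$gs < target)) {
      return(list(coefs = coefs, gs_ref = gs_ref, psi_gs90 = psi_ref,
                  extrapolated = FALSE, saturated = TRUE, fit = fit))
    }
    rts <- polyroot(c(coefs[1] - target, coefs[-1]))
    real <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
    margin <- 0.25 * diff(rng)
    cand <- real[real >= rng[1] - margin & real <= psi_ref + 1e-9]
    if (length(cand) == 0) {
      ht_fit_error("No closure detected: fitted polynomial never falls to 10% of the reference conductance near the observed psi range.")
    }
    psi90 <- min(cand)
    list(coefs = coefs, gs_ref = gs_ref, psi_gs90 = psi90,
         extrapolated = psi90 < rng[1], saturated = FALSE, fit = fit)
  }

  res <- core(d)
  ci <- NULL
  if (n_boot > 0) {
    draws <- withr::with_seed(as.integer(seed), {
      matrix(sample.int(nrow(d), nrow(d) * n_boot, replace = TRUE),
             nrow = n_boot)
    })
    vals <- rep(NA_real_, n_boot)
    for (i in seq_len(n_boot)) {
      vals[i] <- tryCatch(core(d[draws[i, ], ])$psi_gs90,
                          error = function(e) NA_real_)
    }
    if (mean(is.na(vals)) > 0.2) {
      warn("More than 20% of bootstrap replicates failed; CI may be unstable.")
    }
    ci <- unname(quantile(vals, c(0.025, 0.975), na.rm = TRUE))
  }
  if (res$extrapolated) {
    warn(sprintf("psi_gs90 = %.3f MPa lies beyond the observed psi range (extrapolated).",
                 res$psi_gs90))
  }
  if (res$saturated) {
    warn("All gs observations below 10% of the reference: psi_gs90 set to the least negative psi (saturated closure).")
  }
  tss <- sum((d$gs - mean(d$gs))^2)
  structure(
    list(coefs = res$coefs, degree = degree, gs_ref = res$gs_ref,
         psi_gs90 = res$psi_gs90, ci_psi_gs90 = ci,
         extrapolated = res$extrapolated, saturated = res$saturated,
         weights = weights, n = nrow(d), n_boot = n_boot, seed = seed,
         r2 = 1 - sum(resid(res$fit)^2) / tss, data = d),
    class = "gs_poly_fit")
}

#' Extra-sums-of-squares comparison of per-group kinetic models
#'
#' Tests whether separate kinetic gs declines per group (cultivar) explain
#' the data better than one pooled curve, via the extra-sums-of-squares
#' F test: `F = ((RSS_pooled - RSS_full) / (df_pooled - df_full)) /
#' (RSS_full / df_full)`.
#'
#' @param data A data frame with columns `psi_min`, `gs` and a grouping
#'   column.
#' @param group Name of the grouping column (default `"cultivar"`).
#' @param floor Passed to [fit_gs_kinetic()].
#' @return A one-row tibble with `f_statistic`, `df1`, `df2`, `p_value`,
#'   `rss_pooled`, `rss_full`, `n_groups`.
#' @export
compare_gs_models <- function(data, group = "cultivar", floor = FALSE) {
  data <- tibble::as_tibble(data)
  if (!group %in% names(data)) {
    ht_schema_error(sprintf("Grouping column '%s' not found.", group))
  }
  groups <- unique(data[[group]])
  if (length(groups) < 2) {
    ht_param_error("Need at least 2 groups to compare kinetic models.")
  }
  p_per <- if (floor) 3 else 2
  pooled <- fit_gs_kinetic(data, floor = floor)
  fits <- lapply(groups, function(g) {
    fit_gs_kinetic(data[data[[group]] == g, ], floor = floor)
  })
  n <- pooled$n
  rss_pooled <- pooled$rss
  rss_full <- sum(vapply(fits, function(f) f$rss, numeric(1)))
  df_pooled <- n - p_per
  df_full <- n - p_per * length(groups)
  if (df_full <= 0) {
    ht_fit_error("Insufficient data: no residual degrees of freedom for the full model.")
  }
  f_stat <- ((rss_pooled - rss_full) / (df_pooled - df_full)) / (rss_full / df_full)
  tibble::tibble(
    f_statistic = f_stat, df1 = df_pooled - df_full, df2 = df_full,
    p_value = stats::pf(f_stat, df_pooled - df_full, df_full, lower.tail = FALSE),
    rss_pooled = rss_pooled, rss_full = rss_full,
    n_groups = length(groups))
}

#' @export
print.gs_kinetic_fit <- function(x, ...) {
  cat("First-order kinetic gs decline: gs = g0 * exp(k * psi)\n")
  cat(sprintf("  g0 = %.2f, k = %.4f MPa-1%s\n", x$g0, x$k,
              if (x$g_min > 0) sprintf(", g_min = %.2f", x$g_min) else ""))
  cat(sprintf("  psi_gs90 = %s MPa\n",
              if (is.na(x$psi_gs90)) "NA (no response)" else sprintf("%.4f", x$psi_gs90)))
  cat(sprintf("  R^2 = %s, n = %d\n",
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2), x$n))
  invisible(x)
}

#' @export
tidy.gs_kinetic_fit <- function(x, ...) {
  tibble::tibble(term = c("g0", "k", "g_min"),
                 estimate = c(x$g0, x$k, x$g_min))
}

#' @export
glance.gs_kinetic_fit <- function(x, ...) {
  tibble::tibble(g0 = x$g0, k = x$k, psi_gs90 = x$psi_gs90,
                 r.squared = x$r2, nobs = x$n, no_response = x$no_response)
}

#' @export
print.gs_poly_fit <- function(x, ...) {
  cat(sprintf("Weighted degree-%d polynomial gs decline (weights: %s)\n",
              x$degree, x$weights))
  cat(sprintf("  gs_ref = %.2f, psi_gs90 = %.4f MPa%s%s\n", x$gs_ref, x$psi_gs90,
              if (x$extrapolated) " (extrapolated)" else "",
              if (x$saturated) " (saturated)" else ""))
  if (!is.null(x$ci_psi_gs90)) {
    cat(sprintf("  95%% bootstrap CI: [%.4f, %.4f] (n_boot = %d)\n",
                x$ci_psi_gs90[1], x$ci_psi_gs90[2], x$n_boot))
  }
  cat(sprintf("  R^2 = %.4f, n = %d\n", x$r2, x$n))
  invisible(x)
}

#' @export
tidy.gs_poly_fit <- function(x, ...) {
  tibble::tibble(term = paste0("b", seq_along(x$coefs) - 1),
                 estimate = x$coefs)
}

#' @export
glance.gs_poly_fit <- function(x, ...) {
  tibble::tibble(gs_ref = x$gs_ref, psi_gs90 = x$psi_gs90,
                 ci_low = if (is.null(x$ci_psi_gs90)) NA_real_ else x$ci_psi_gs90[1],
                 ci_high = if (is.null(x$ci_psi_gs90)) NA_real_ else x$ci_psi_gs90[2],
                 r.squared = x$r2, nobs = x$n,
                 extrapolated = x$extrapolated, saturated = x$saturated)
}
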