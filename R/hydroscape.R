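#' Fit the predawn-midday water potential relationship and hydroscape
#'
#' Regresses the midday minimum leaf water potential on the predawn water
#' potential by ordinary least squares. The slope is the iso/anisohydry
#' index sigma (0 = perfectly isohydric, 1 = perfectly anisohydric), the
#' intercept `a` is the most negative midday potential expected when the
#' soil is wet, and the fitted line meets the 1:1 line at
#' `b = a / (1 - sigma)`, the limit of stomatal control. The hydroscape is
#' the area of the triangle enclosed between the regression and the 1:1
#' line, `|a * b| / 2` (MPa^2); larger hydroscapes indicate more
#' anisohydric behaviour.
#'
#' Records flagged as physically inconsistent (`psi_min > psi_pd`) are
#' excluded from the fit but reported in the diagnostics. Well-watered
#' control records (`treatment == "WW"`) are excluded by default because
#' the hydroscape is a dry-down metric.
#'
#' @param data A data frame with columns `psi_pd` and `psi_min` (signed
#'   MPa), optionally `treatment` and `flag` (as produced by
#'   [read_water_potential()]).
#' @param include_ww Include well-watered (`treatment == "WW"`) records in
#'   the fit? Default `FALSE`.
#' @return An object of class `hydroscape_fit` with elements `sigma`, `a`,
#'   `b`, `area`, `n`, `n_excluded`, `r2` and the fitted `lm` object.
#'   `tidy()`, `glance()` and `autoplot()` methods are available.
#' @examples
#' d <- data.frame(psi_pd = seq(-3, 0, length.out = 10))
#' d$psi_min <- -1 + 0.5 * d$psi_pd
#' fit <- fit_hydroscape(d)
#' fit$area # 1
#' @export
fit_hydroscape <- function(data, include_ww = FALSE) {
  data <- tibble::as_tibble(data)
  if (!all(c("psi_pd", "psi_min") %in% names(data))) {
    ht_schema_error("`data` must contain columns `psi_pd` and `psi_min`.")
  }
  n_total <- nrow(data)
  keep <- complete.cases(data[c("psi_pd", "psi_min")])
  if ("flag" %in% names(data)) keep <- keep & data$flag == ""
  keep <- keep & data$psi_min <= data$psi_pd
  if (!include_ww && "treatment" %in% names(data)) {
    keep <- keep & data$treatment != "WW"
  }
  use <- data[keep, ]
  if (nrow(use) < 3) {
    ht_fit_error(sprintf(
      "Need at least 3 usable records to fit sigma (%d available).", nrow(use)))
  }
  if (sd(use$psi_pd) < 1e-12) {
    ht_fit_error("Degenerate fit: psi_pd has (near) zero variance.")
  }

  fit <- lm(psi_min ~ psi_pd, data = use)
  sigma <- unname(coef(fit)[2])
  a <- unname(coef(fit)[1])
  geom <- hydroscape_geometry(a, sigma)
  r2 <- summary(fit)$r.squared

  structure(
    list(sigma = sigma, a = a, b = geom$b, area = geom$area,
         n = nrow(use), n_excluded = n_total - nrow(use), r2 = r2,
         lm = fit, data = use),
    class = "hydroscape_fit")
}

# intersection with the 1:1 line and enclosed area; Inf area when the lines
# never meet (sigma >= 1)
hydroscape_geometry <- function(a, sigma) {
  if (sigma >= 1) {
    if (sigma == 1 && a == 0) {
      return(list(b = NA_real_, area = 0))
    }
    warn(sprintf(
      "sigma = %.3f >= 1: regression never meets the 1:1 line; hydroscape is infinite.",
      sigma))
    return(list(b = -Inf, area = Inf))
  }
  b <- a / (1 - sigma)
  list(b = b, area = abs(a * b) / 2)
}

#' Hydroscape area from intercept and slope
#'
#' Closed-form hydroscape area `|a * b| / 2` with `b = a / (1 - sigma)`,
#' i.e. `a^2 / (2 * (1 - sigma))`. Accepts either a `hydroscape_fit` or the
#' raw intercept and slope.
#'
#' @param a Intercept of the psi_min ~ psi_pd regression (MPa), or a
#'   `hydroscape_fit` object.
#' @param sigma Slope of the regression; must be below 1 for the area to be
#'   finite.
#' @return Hydroscape area in MPa^2.
#' @examples
#' hydroscape_area(-1, 0.5) # 1
#' @export
hydroscape_area <- function(a, sigma) {
  if (inherits(a, "hydroscape_fit")) {
    sigma <- a$sigma
    a <- a$a
  }
  check_number(a, "a")
  check_number(sigma, "sigma")
  if (any(sigma >= 1 & !(sigma == 1 & a == 0))) {
    ht_fit_error(
      "sigma >= 1: the regression does not intersect the 1:1 line (infinite hydroscape).")
  }
  ifelse(sigma == 1 & a == 0, 0, a^2 / (2 * (1 - sigma)))
}

#' Per-cultivar hydroscape table
#'
#' Fits [fit_hydroscape()] within each level of a grouping column and
#' returns one row per group.
#'
#' @inheritParams fit_hydroscape
#' @param group Name of the grouping column (default `"cultivar"`).
#' @return A tibble with columns `cultivar` (or the chosen group name),
#'   `sigma`, `a`, `b`, `area`, `n`, `n_excluded`, `r2`.
#' @export
hydroscape_table <- function(data, group = "cultivar", include_ww = FALSE) {
  data <- tibble::as_tibble(data)
  if (!group %in% names(data)) {
    ht_schema_error(sprintf("Grouping column '%s' not found.", group))
  }
  data |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::group_modify(function(d, key) {
      tidy(fit_hydroscape(d, include_ww = include_ww))
    }) |>
    dplyr::ungroup()
}

#' Rank cultivars from isohydric to anisohydric
#'
#' Orders a per-cultivar hydroscape table by ascending hydroscape area
#' (small area = isohydric, large = anisohydric). Ties in area are broken
#' by sigma (a larger slope is more anisohydric), then alphabetically by
#' label; the tie-break is reported with a message.
#'
#' @param results A data frame with one row per cultivar and columns
#'   `cultivar` (or `label`), `area` and optionally `sigma` (as returned by
#'   [hydroscape_table()]).
#' @return The input tibble ordered isohydric to anisohydric, with a `rank`
#'   column prepended.
#' @export
rank_cultivars <- function(results) {
  results <- tibble::as_tibble(results)
  label_col <- intersect(c("cultivar", "label"), names(results))[1]
  if (is.na(label_col) || !"area" %in% names(results)) {
    ht_schema_error("`results` needs a cultivar/label column and an `area` column.")
  }
  if (nrow(results) < 1) {
    ht_schema_error("`results` is empty.")
  }
  sigma <- if ("sigma" %in% names(results)) results$sigma else rep(0, nrow(results))
  ord <- order(results$area, sigma, results[[label_col]])
  if (anyDuplicated(results$area)) {
    inform("Tied hydroscape areas broken by sigma (larger sigma = more anisohydric), then label.")
  }
  out <- results[ord, ]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' @export
print.hydroscape_fit <- function(x, ...) {
  cat("Hydroscape fit (psi_min ~ psi_pd, OLS)\n")
  cat(sprintf("  sigma  = %8.4f MPa MPa-1\n", x$sigma))
  cat(sprintf("  a      = %8.4f MPa (intercept)\n", x$a))
  cat(sprintf("  b      = %8.4f MPa (1:1 intersection)\n", x$b))
  cat(sprintf("  area   = %8.4f MPa^2 (hydroscape)\n", x$area))
  cat(sprintf("  n = %d (excluded: %d), R^2 = %.4f\n", x$n, x$n_excluded, x$r2))
  invisible(x)
}

#' @export
tidy.hydroscape_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, a = x$a, b = x$b, area = x$area,
                 n = x$n, n_excluded = x$n_excluded, r2 = x$r2)
}

#' @export
glance.hydroscape_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n, sigma = x$sigma,
                 area = x$area)
}
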