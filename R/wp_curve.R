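#' Three-segment piecewise-linear water-potential curve
#'
#' Fits a continuous piecewise-linear model of midday minimum water
#' potential against predawn water potential with `n_segments - 1` interior
#' breakpoints. The drydown trajectory is triphasic: a steep initial
#' decline in psi_min (phase I), a gentler intermediate phase (II), and a
#' flat terminal phase (III). The boundaries theta1 (between phases I and
#' II) and theta2 (between II and III) sit on the psi_pd axis, with
#' `theta2 < theta1 < 0`.
#'
#' Estimation profiles the residual sum of squares over the breakpoints:
#' for fixed breakpoints the model is linear in its coefficients, and the
#' breakpoints themselves are refined by iterative relinearization (the
#' gap-term update of segmented regression), started from a deterministic
#' grid of breakpoint pairs spanning the inner 80% of the psi_pd range.
#' The best converged solution by RSS wins; if no start converges the best
#' grid point is returned with a warning. Standard errors for the
#' breakpoints come from the final linearization.
#'
#' @param data A data frame with columns `psi_pd` and `psi_min` (signed
#'   MPa); flagged records (`flag != ""`) and rows with
#'   `psi_min > psi_pd` are excluded from the fit.
#' @param n_segments Number of linear phases (default 3, the standard
#'   triphasic model).
#' @param grid_size Number of candidate positions per breakpoint in the
#'   starting grid (default 10).
#' @param tol Convergence tolerance on the breakpoints (MPa).
#' @param max_iter Maximum relinearization iterations per start.
#' @return An object of class `wp_piecewise_fit` with elements `theta`
#'   (breakpoints, least- to most-negative: theta1, theta2, ...),
#'   `theta_se`, `beta` (per-phase slopes, phase I first), `intercept`
#'   (phase-I intercept at psi_pd = 0), `rmse`, `r2`, `rss`, `n`,
#'   `converged`, and the data range. `predict()`, `tidy()`, `glance()`
#'   and `autoplot()` methods are available.
#' @examples
#' x <- seq(-4, 0, length.out = 60)
#' y <- wp_piecewise_eval(x, intercept = -0.037,
#'                        beta = c(2.594, 1.015, 0.711),
#'                        theta = c(-0.803, -1.553))
#' fit <- fit_wp_piecewise(data.frame(psi_pd = x, psi_min = y))
#' round(fit$theta, 3)
#' @export
fit_wp_piecewise <- function(data, n_segments = 3, grid_size = 10,
                             tol = 1e-8, max_iter = 100) {
  data <- tibble::as_tibble(data)
  if (!all(c("psi_pd", "psi_min") %in% names(data))) {
    ht_schema_error("`data` must contain columns `psi_pd` and `psi_min`.")
  }
  if (n_segments < 2) {
    ht_param_error("`n_segments` must be at least 2.")
  }
  keep <- complete.cases(data[c("psi_pd", "psi_min")])
  if ("flag" %in% names(data)) keep <- keep & data$flag == ""
  use <- data[keep, ]
  x <- use$psi_pd
  y <- use$psi_min
  n <- length(x)
  n_bp <- n_segments - 1
  if (n < max(8, 2 * n_segments + n_bp)) {
    ht_fit_error(sprintf("Need at least %d usable records (%d available).",
                         max(8, 2 * n_segments + n_bp), n))
  }
  rng <- range(x)
  if (diff(rng) < 1e-8) {
    ht_fit_error("Degenerate fit: psi_pd has (near) zero range.")
  }

  # deterministic starting grid over the inner 80% of the psi_pd range
  qs <- seq(0.1, 0.9, length.out = grid_size)
  cand <- rng[1] + qs * diff(rng)
  starts <- utils::combn(cand, n_bp)
  grid_rss <- apply(starts, 2, function(th) profile_rss(x, y, sort(th)))
  ord <- order(grid_rss)

  best <- NULL
  all_res <- list()
  # refine from the most promising grid starts
  for (j in ord[seq_len(min(12, length(ord)))]) {
    res <- muggeo_iterate(x, y, sort(starts[, j]), tol = tol,
                          max_iter = max_iter, rng = rng)
    if (is.null(res)) next
    all_res[[length(all_res) + 1]] <- res
    if (is.null(best) || res$rss < best$rss - 1e-12 ||
        (res$converged && !best$converged && res$rss < best$rss + 1e-9)) {
      best <- res
    }
  }
  if (is.null(best) || !best$converged) {
    # fall back to the best grid point
    th0 <- sort(starts[, ord[1]])
    warn("Breakpoint iteration did not converge; falling back to the best grid start.")
    fb <- refit_at(x, y, th0, rng)
    all_res[[length(all_res) + 1]] <- fb
    if (is.null(best) || fb$rss < best$rss) best <- fb
    best$converged <- FALSE
  }

  # simplex polish of the profile RSS from every basin the multistart
  # visited (plus the best raw grid starts): tightens the optimum on noisy,
  # kinked profiles where the relinearization stalls in a shallow basin
  polish_from <- unique(c(lapply(all_res, function(r) r$theta),
                          lapply(ord[seq_len(min(6, length(ord)))],
                                 function(j) sort(starts[, j])),
                          list(best$theta)))
  th_pol <- best$theta
  rss_pol <- best$rss
  for (th0 in polish_from) {
    tp <- polish_breakpoints(x, y, th0, rng)
    rp <- profile_rss(x, y, tp)
    if (rp < rss_pol - 1e-13) {
      th_pol <- tp
      rss_pol <- rp
    }
  }
  if (rss_pol < best$rss - 1e-12) {
    res <- muggeo_iterate(x, y, th_pol, tol = tol, max_iter = max_iter,
                          rng = rng)
    if (!is.null(res) && res$rss <= rss_pol + 1e-12) {
      res$converged <- best$converged || res$converged
      best <- res
    } else {
      keep_conv <- best$converged
      best <- refit_at(x, y, th_pol, rng)
      best$converged <- keep_conv
    }
    all_res[[length(all_res) + 1]] <- best
  }

  # identifiability-preferring selection: when the global optimum collapses
  # the breakpoints (onto each other or the range edges) but some visited
  # solution with well-separated breakpoints fits essentially as well
  # (within 0.5% RSS), prefer the identifiable one; only a decisively
  # better collapsed optimum is reported as an unidentifiability error
  edge_tol <- 0.05
  identifiable <- function(th) {
    all(th - rng[1] >= edge_tol) && all(rng[2] - th >= edge_tol) &&
      all(diff(th) >= edge_tol)
  }
  if (!identifiable(best$theta) && length(all_res) > 0) {
    idents <- Filter(function(r) identifiable(r$theta), all_res)
    if (length(idents) > 0) {
      rbest <- idents[[which.min(vapply(idents, function(r) r$rss,
                                        numeric(1)))]]
      if (rbest$rss <= best$rss * 1.005 + 1e-12) {
        best <- rbest
      }
    }
  }

  th <- best$theta
  # identifiability: breakpoints must sit strictly inside the data range and
  # apart from each other
  near_lo <- th - rng[1] < edge_tol
  near_hi <- rng[2] - th < edge_tol
  if (any(near_lo | near_hi)) {
    which_bad <- which(near_lo | near_hi)[1]
    ht_fit_error(sprintf(
      "Unidentifiable breakpoint: theta%d = %.3f collapses onto the edge of the psi_pd range [%.3f, %.3f].",
      n_bp + 1 - which_bad, th[which_bad], rng[1], rng[2]),
      boundary = paste0("theta", n_bp + 1 - which_bad))
  }
  if (any(diff(th) < edge_tol)) {
    ht_fit_error(sprintf(
      "Unidentifiable breakpoints: theta estimates %.3f and %.3f are within %.2f MPa of each other.",
      th[which(diff(th) < edge_tol)[1]], th[which(diff(th) < edge_tol)[1] + 1],
      edge_tol), boundary = "theta1/theta2")
  }
  # slope changes of essentially zero mean there is no detectable phase
  # structure (e.g. data on a single line)
  dslope <- diff(best$beta)
  if (any(abs(dslope) < 1e-7 * max(1, abs(best$beta[1])))) {
    ht_fit_error(
      "Unidentifiable breakpoints: adjacent phases have indistinguishable slopes (data may be a single line).",
      boundary = "slopes")
  }

  rss <- best$rss
  p <- 2 * n_segments  # intercept + slopes + breakpoints
  tss <- sum((y - mean(y))^2)
  structure(
    list(theta = unname(rev(th)),  # theta1 (least negative) first
         theta_se = unname(rev(best$theta_se)),
         beta = unname(best$beta), # phase I first
         intercept = unname(best$intercept),
         rss = rss,
         rmse = sqrt(rss / max(n - p, 1)),
         r2 = 1 - rss / tss,
         n = n, n_excluded = nrow(data) - n,
         converged = best$converged,
         range = rng, data = use,
         n_segments = n_segments),
    class = "wp_piecewise_fit")
}

# design matrix for fixed breakpoints th (ascending): continuous piecewise
# line y = c + b1*x + sum_k delta_k * pmin(x - th_k, 0)
piecewise_design <- function(x, th) {
  cbind(1, x, vapply(th, function(t) pmin(x - t, 0), numeric(length(x))))
}

profile_rss <- function(x, y, th) {
  lsq(piecewise_design(x, th), y)$rss
}

# coefficients at fixed breakpoints, mapped to phase slopes
refit_at <- function(x, y, th, rng) {
  fit <- lsq(piecewise_design(x, th), y)
  k <- length(th)
  cf <- unname(fit$coef)
  # phase I slope is cf[2]; moving to more negative x adds the delta of each
  # crossed breakpoint (descending th order)
  deltas <- cf[2 + seq_len(k)]
  beta <- cf[2] + c(0, cumsum(rev(deltas)))
  list(theta = th, theta_se = rep(NA_real_, k), beta = beta,
       intercept = cf[1], rss = fit$rss, converged = FALSE)
}

# deterministic simplex polish of the profile RSS over the breakpoints;
# catches optima the relinearization stalls short of on kinked surfaces
polish_breakpoints <- function(x, y, th, rng) {
  pad <- 0.01 * diff(rng)
  obj <- function(t) {
    t <- sort(pmin(pmax(t, rng[1] + pad), rng[2] - pad))
    profile_rss(x, y, t)
  }
  opt <- tryCatch(
    stats::optim(th, obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt)) return(th)
  sort(pmin(pmax(opt$par, rng[1] + pad), rng[2] - pad))
}

# iterative relinearization for the breakpoints: augment the design with the
# gap covariates V_k = -(x < th_k) and update th_k <- th_k + gamma_k/delta_k
muggeo_iterate <- function(x, y, th, tol, max_iter, rng) {
  k <- length(th)
  pad <- 0.01 * diff(rng)
  clamp <- function(t) pmin(pmax(t, rng[1] + pad), rng[2] - pad)
  rss_old <- profile_rss(x, y, th)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- vapply(th, function(t) pmin(x - t, 0), numeric(length(x)))
    V <- vapply(th, function(t) -(x < t), numeric(length(x)))
    X <- cbind(1, x, U, V)
    fit <- tryCatch(lsq(X, y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coef[2 + seq_len(k)])) return(NULL)
    delta <- fit$coef[2 + seq_len(k)]
    gamma <- fit$coef[2 + k + seq_len(k)]
    gamma[is.na(gamma)] <- 0
    if (any(abs(delta) < 1e-12)) return(NULL)
    step <- gamma / delta
    # damped update: halve the step until the profile RSS stops worsening;
    # if no damping level improves, the current point is a local minimum
    lam <- 1
    improved <- FALSE
    th_new <- th
    while (lam >= 1 / 64) {
      cand <- clamp(sort(th + lam * step))
      rss_cand <- profile_rss(x, y, cand)
      if (rss_cand <= rss_old + 1e-13) {
        th_new <- cand
        rss_old <- rss_cand
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    moved <- max(abs(th_new - th))
    th <- th_new
    if (!improved || moved < tol) {
      converged <- TRUE
      break
    }
  }
  # final linearization for coefficients and breakpoint standard errors
  U <- vapply(th, function(t) pmin(x - t, 0), numeric(length(x)))
  V <- vapply(th, function(t) -(x < t), numeric(length(x)))
  X <- cbind(1, x, U, V)
  qrX <- qr(X)
  cf <- qr.coef(qrX, y)
  res <- y - X %*% ifelse(is.na(cf), 0, cf)
  dfres <- length(y) - qrX$rank
  s2 <- sum(res^2) / max(dfres, 1)
  XtX_inv <- tryCatch(chol2inv(qr.R(qrX)), error = function(e) NULL)
  theta_se <- rep(NA_real_, k)
  delta <- cf[2 + seq_len(k)]
  if (!is.null(XtX_inv) && !anyNA(delta)) {
    se_gamma <- sqrt(pmax(diag(XtX_inv)[2 + k + seq_len(k)], 0) * s2)
    theta_se <- se_gamma / abs(delta)
  }
  out <- refit_at(x, y, th, rng)
  out$theta_se <- theta_se
  out$converged <- converged
  out
}

#' Evaluate a continuous piecewise-linear function
#'
#' Helper used throughout the package and its tests: evaluates the
#' triphasic (or general) continuous piecewise line defined by a phase-I
#' intercept at `x = 0`, per-phase slopes (phase I first) and breakpoints
#' (least-negative first).
#'
#' @param x Points at which to evaluate (MPa, <= 0 in normal use).
#' @param intercept Phase-I intercept at `x = 0`.
#' @param beta Slopes, phase I (nearest zero) first.
#' @param theta Breakpoints, least-negative (theta1) first.
#' @return Numeric vector of fitted values.
#' @export
wp_piecewise_eval <- function(x, intercept, beta, theta) {
  stopifnot(length(beta) == length(theta) + 1)
  if (is.unsorted(rev(theta))) {
    ht_param_error("`theta` must be ordered least- to most-negative.")
  }
  y <- intercept + beta[1] * x
  for (k in seq_along(theta)) {
    y <- y + (beta[k + 1] - beta[k]) * pmin(x - theta[k], 0)
  }
  y
}

#' @export
predict.wp_piecewise_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$psi_pd else {
    if (is.data.frame(newdata)) newdata$psi_pd else newdata
  }
  wp_piecewise_eval(x, object$intercept, object$beta, object$theta)
}

#' Intersection of the fitted water-potential curve with the 1:1 line
#'
#' Solves `f(psi_pd) = psi_pd` for the fitted piecewise model: the water
#' potential at which predawn and midday potentials meet, i.e. the limit of
#' stomatal control. When the crossing lies beyond the most negative
#' observed psi_pd, the terminal-phase line is extended and the result is
#' flagged as extrapolated.
#'
#' @param fit A `wp_piecewise_fit`.
#' @param method `"piecewise"` evaluates the full fitted function
#'   (including the terminal-phase extension); `"terminal"` uses only the
#'   terminal (most negative) phase line, `psi = c3 / (1 - beta3)`.
#' @return A one-row tibble with columns `psi` (MPa), `segment` (phase
#'   index, 1 = phase I) and `extrapolated`.
#' @export
intersect_one_to_one <- function(fit, method = c("piecewise", "terminal")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "wp_piecewise_fit"))
  nseg <- fit$n_segments
  theta_desc <- fit$theta                      # theta1, theta2 (descending)
  # segment k (1 = phase I) spans (lower_k, upper_k] on the psi_pd axis
  uppers <- c(Inf, theta_desc)
  lowers <- c(theta_desc, -Inf)
  eps <- 1e-10

  seg_line <- function(k) {
    # line of segment k: slope beta_k through the fitted value at its upper
    # boundary (or at 0 for phase I)
    xref <- if (k == 1) 0 else theta_desc[k - 1]
    yref <- wp_piecewise_eval(xref, fit$intercept, fit$beta, fit$theta)
    c(intercept = yref - fit$beta[k] * xref, slope = fit$beta[k])
  }

  if (method == "terminal") {
    ln <- seg_line(nseg)
    if (abs(1 - ln["slope"]) < eps) {
      if (abs(ln["intercept"]) < eps) {
        ht_fit_error("Terminal phase coincides with the 1:1 line: intersection undefined.")
      }
      ht_fit_error("Terminal-phase slope is 1 with nonzero offset: no intersection with the 1:1 line.")
    }
    psi <- unname(ln["intercept"] / (1 - ln["slope"]))
    return(tibble::tibble(psi = psi, segment = nseg,
                          extrapolated = psi < fit$range[1]))
  }

  crossings <- NULL
  for (k in seq_len(nseg)) {
    ln <- seg_line(k)
    if (abs(1 - ln["slope"]) < eps) next
    psi <- unname(ln["intercept"] / (1 - ln["slope"]))
    lo <- lowers[k]
    hi <- min(uppers[k], 0)
    # terminal phase extends indefinitely to more negative psi
    ok <- if (k == nseg) psi <= hi + eps else psi > lo - eps && psi <= hi + eps
    if (ok) {
      crossings <- dplyr::bind_rows(crossings, tibble::tibble(
        psi = psi, segment = k, extrapolated = psi < fit$range[1]))
    }
  }
  if (is.null(crossings) || nrow(crossings) == 0) {
    ln <- seg_line(nseg)
    if (abs(1 - ln["slope"]) < eps && abs(ln["intercept"]) >= eps) {
      ht_fit_error("Terminal-phase slope is 1 with nonzero offset: the curve never meets the 1:1 line.")
    }
    ht_fit_error("The fitted piecewise curve does not cross the 1:1 line.")
  }
  # report the least-negative (first reached during drydown) crossing
  crossings[which.max(crossings$psi), ]
}

#' Ordered physiological thresholds along the drydown
#'
#' Collates the piecewise-curve boundaries with the stomatal closure point
#' (psi_gs90), the turgor loss point (psi_tlp) and the xylem P50 into one
#' table ordered from least to most negative, and checks the
#' cavitation-avoidance signature: stomatal closure should precede both
#' turgor loss (`psi_gs90 > psi_tlp`) and half-loss of stem conductivity
#' (`psi_gs90 > p50`).
#'
#' @param fit A `wp_piecewise_fit`, or `NULL` to omit the boundaries.
#' @param psi_gs90,psi_tlp,p50 Thresholds in signed MPa (all <= 0; `p50`
#'   supplied negative).
#' @return A tibble with columns `event`, `psi`, `order` (ties share a
#'   rank and are reported), and attributes `gs90_before_tlp` and
#'   `gs90_before_p50` (strict inequalities; ties give `FALSE`).
#' @export
phase_report <- function(fit = NULL, psi_gs90, psi_tlp, p50) {
  for (v in c(psi_gs90 = psi_gs90, psi_tlp = psi_tlp, p50 = p50)) {
    check_number(v, "threshold", upper = 0)
  }
  events <- tibble::tibble(
    event = c("psi_gs90", "psi_tlp", "p50"),
    psi = c(psi_gs90, psi_tlp, p50))
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "wp_piecewise_fit"))
    events <- dplyr::bind_rows(tibble::tibble(
      event = paste0("theta", seq_along(fit$theta)), psi = fit$theta), events)
  }
  events <- events[order(-events$psi), ]
  events$order <- rank(-events$psi, ties.method = "min")
  if (anyDuplicated(events$order)) {
    inform("Tied thresholds share a rank in the phase report.")
  }
  attr(events, "gs90_before_tlp") <- psi_gs90 > psi_tlp
  attr(events, "gs90_before_p50") <- psi_gs90 > p50
  events
}

#' @export
print.wp_piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise water-potential curve (%d segments)\n", x$n_segments))
  for (k in seq_along(x$theta)) {
    cat(sprintf("  theta%d = %8.4f MPa (se %.4f)\n", k, x$theta[k], x$theta_se[k]))
  }
  cat(sprintf("  slopes = %s\n", paste(sprintf("%.4f", x$beta), collapse = ", ")))
  cat(sprintf("  intercept (phase I) = %.4f MPa\n", x$intercept))
  cat(sprintf("  RMSE = %.4f, R^2 = %.4f, n = %d%s\n", x$rmse, x$r2, x$n,
              if (x$converged) "" else " (not converged; grid fallback)"))
  invisible(x)
}

#' @export
tidy.wp_piecewise_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("theta", seq_along(x$theta)),
             paste0("beta", seq_along(x$beta)), "intercept"),
    estimate = c(x$theta, x$beta, x$intercept),
    std.error = c(x$theta_se, rep(NA_real_, length(x$beta) + 1)))
}

#' @export
glance.wp_piecewise_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, rmse = x$rmse, rss = x$rss, nobs = x$n,
                 n_segments = x$n_segments, converged = x$converged)
}
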