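#' Run the full dry-down trait analysis
#'
#' Orchestrates the complete analysis on the five input tables: per-record
#' measurement summaries, the hydroscape (sigma, area), the three-segment
#' piecewise water-potential curve with its 1:1 intersection, the Weibull
#' vulnerability curve with a bootstrapped P50, the pressure-volume
#' traits, the stomatal decline models (kinetic and weighted polynomial),
#' the hydraulic safety margin, and the ordered threshold (phase) report
#' per cultivar.
#'
#' Inputs may be tibbles or CSV paths; each is validated against its
#' schema. A missing (`NULL`) input skips the stages that need it with a
#' warning; an error inside a stage halts the run naming the stage and
#' cultivar (set `on_error = "continue"` to fill `NA` and keep going).
#'
#' @param water_potential Water-potential table or path (required).
#' @param gas_exchange,vulnerability,pv_curve,pot_weights Optional tables
#'   or paths.
#' @param include_ww Include well-watered records in hydroscape and
#'   piecewise fits? Default `FALSE`.
#' @param degree Polynomial degree for [fit_psi_gs90()].
#' @param segments Segment count for [fit_wp_piecewise()].
#' @param n_boot Bootstrap replicates for P50 and psi_gs90 intervals
#'   (default 200; 0 skips bootstraps).
#' @param seed Integer seed governing all bootstraps.
#' @param on_error `"halt"` (default) or `"continue"`.
#' @return An object of class `drydown_analysis`: a list with
#'   `trait_table` (one row per cultivar), `phase_reports` (named list of
#'   [phase_report()] tables), `fits` (all fitted objects), `log` (tibble
#'   of per-stage diagnostics) and `config`.
#' @export
run_drydown_analysis <- function(water_potential,
                                 gas_exchange = NULL,
                                 vulnerability = NULL,
                                 pv_curve = NULL,
                                 pot_weights = NULL,
                                 include_ww = FALSE,
                                 degree = 2,
                                 segments = 3,
                                 n_boot = 200,
                                 seed = 1,
                                 on_error = c("halt", "continue")) {
  on_error <- match.arg(on_error)
  load_in <- function(x, schema) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) return(read_table(x, schema))
    validate_table(x, schema)
  }
  wp <- load_in(water_potential, "water_potential")
  if (is.null(wp)) ht_param_error("`water_potential` is required.")
  ge <- load_in(gas_exchange, "gas_exchange")
  vc <- load_in(vulnerability, "vulnerability")
  pv <- load_in(pv_curve, "pv_curve")
  pw <- load_in(pot_weights, "pot_weights")
  for (nm in c("gas_exchange", "vulnerability", "pv_curve", "pot_weights")) {
    if (is.null(get(c(gas_exchange = "ge", vulnerability = "vc",
                      pv_curve = "pv", pot_weights = "pw")[[nm]]))) {
      warn(sprintf("Input '%s' not provided: dependent stages skipped.", nm))
    }
  }

  if (!"cultivar" %in% names(wp)) wp$cultivar <- "all"
  cultivars <- sort(unique(wp$cultivar))
  seeds <- fan_out_seeds(seed, 2 * length(cultivars))
  log <- list()
  fits <- list()
  note <- function(stage, cultivar, msg) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, cultivar = cultivar, note = msg)
  }
  run_stage <- function(stage, cultivar, expr) {
    tryCatch(expr, error = function(e) {
      msg <- sprintf("Stage '%s' failed for cultivar '%s': %s",
                     stage, cultivar, conditionMessage(e))
      if (on_error == "halt") {
        ht_abort(msg, "ht_stage_error", stage = stage, cultivar = cultivar)
      }
      warn(msg)
      note(stage, cultivar, paste("FAILED:", conditionMessage(e)))
      NULL
    })
  }

  rows <- list()
  phase_reports <- list()
  for (i in seq_along(cultivars)) {
    cv <- cultivars[i]
    wp_cv <- wp[wp$cultivar == cv, ]
    row <- tibble::tibble(cultivar = cv)

    hs <- run_stage("hydroscape", cv,
                    fit_hydroscape(wp_cv, include_ww = include_ww))
    if (!is.null(hs)) {
      row$sigma <- hs$sigma
      row$hydroscape <- hs$area
      row$sigma_a <- hs$a
      row$sigma_r2 <- hs$r2
      fits[[cv]]$hydroscape <- hs
      note("hydroscape", cv, sprintf("n=%d excluded=%d r2=%.4f",
                                     hs$n, hs$n_excluded, hs$r2))
    }

    # the piecewise curve is advisory for the trait table (its columns are
    # the Table-2-shaped traits): smooth trajectories can make the three-
    # phase breakpoints unidentifiable, which is logged, not fatal
    pwfit <- tryCatch({
      d <- if (include_ww) wp_cv else wp_cv[wp_cv$treatment != "WW" |
                                              is.na(wp_cv$treatment), ]
      suppressWarnings(fit_wp_piecewise(d, n_segments = segments))
    }, error = function(e) {
      warn(sprintf("wp_curve stage for cultivar '%s': %s", cv,
                   conditionMessage(e)))
      note("wp_curve", cv, paste("piecewise fit unavailable:",
                                 conditionMessage(e)))
      NULL
    })
    if (!is.null(pwfit)) {
      row$theta1 <- pwfit$theta[1]
      row$theta2 <- pwfit$theta[length(pwfit$theta)]
      row$wp_rmse <- pwfit$rmse
      row$wp_r2 <- pwfit$r2
      ix <- run_stage("wp_curve", cv, intersect_one_to_one(pwfit))
      if (!is.null(ix)) {
        row$psi_equal <- ix$psi
        row$psi_equal_extrapolated <- ix$extrapolated
      }
      fits[[cv]]$wp_curve <- pwfit
      note("wp_curve", cv, sprintf("theta=%s rmse=%.3f conv=%s",
                                   paste(sprintf("%.3f", pwfit$theta), collapse = ","),
                                   pwfit$rmse, pwfit$converged))
    }

    if (!is.null(ge)) {
      ge_cv <- ge[if ("cultivar" %in% names(ge)) ge$cultivar == cv else TRUE, ]
      merged <- run_stage("stomatal", cv, {
        m <- dplyr::inner_join(
          wp_cv[wp_cv$flag == "", c("plant_id", "day", "psi_min", "treatment")],
          ge_cv[ge_cv$flag == "", c("plant_id", "day", "gs")],
          by = c("plant_id", "day"))
        if (!include_ww) m <- m[m$treatment != "WW" | is.na(m$treatment), ]
        m
      })
      if (!is.null(merged) && nrow(merged) >= 6) {
        kin <- run_stage("stomatal", cv, fit_gs_kinetic(merged))
        if (!is.null(kin)) {
          row$psi_gs90 <- kin$psi_gs90
          row$gs_k <- kin$k
          row$gs_g0 <- kin$g0
          fits[[cv]]$gs_kinetic <- kin
          note("stomatal", cv, sprintf("kinetic g0=%.1f k=%.3f r2=%.3f",
                                       kin$g0, kin$k, kin$r2))
        }
        # the polynomial closure estimate is advisory in the pipeline (the
        # kinetic fit is the trait-table value): a failure is logged, not fatal
        poly <- tryCatch(suppressWarnings(
          fit_psi_gs90(merged, degree = degree, n_boot = n_boot,
                       seed = seeds[2 * i - 1])),
          error = function(e) {
            note("stomatal", cv, paste("polynomial psi_gs90 unavailable:",
                                       conditionMessage(e)))
            NULL
          })
        if (!is.null(poly)) {
          row$psi_gs90_poly <- poly$psi_gs90
          fits[[cv]]$gs_poly <- poly
          note("stomatal", cv, sprintf(
            "poly deg=%d psi_gs90=%.3f seed=%d", degree, poly$psi_gs90,
            seeds[2 * i - 1]))
        }
        # iWUE: always the mean of per-record ratios
        if (all(c("a_n", "e") %in% names(ge_cv))) {
          iw <- suppressWarnings(compute_iwue(ge_cv$a_n, ge_cv$e))
          row$iwue <- mean(iw, na.rm = TRUE)
        }
      }
    }

    if (!is.null(vc)) {
      vc_cv <- vc[if ("cultivar" %in% names(vc)) vc$cultivar == cv else TRUE, ]
      if (nrow(vc_cv) > 0) {
        wfit <- run_stage("vulnerability", cv, {
          f <- fit_weibull(vc_cv)
          if (n_boot > 0) f <- bootstrap_p50(f, n_boot = max(n_boot, 100),
                                            seed = seeds[2 * i])
          f
        })
        if (!is.null(wfit)) {
          row$p50 <- wfit$p50
          row$p50_ci_low <- if (is.null(wfit$ci_p50)) NA_real_ else wfit$ci_p50[1]
          row$p50_ci_high <- if (is.null(wfit$ci_p50)) NA_real_ else wfit$ci_p50[2]
          fits[[cv]]$vulnerability <- wfit
          note("vulnerability", cv, sprintf(
            "b=%.3f c=%.3f p50=%.3f n_boot=%s seed=%d", wfit$b, wfit$c,
            wfit$p50, wfit$n_boot %||% 0, seeds[2 * i]))
        }
      }
    }

    if (!is.null(pv)) {
      pv_cv <- pv[if ("cultivar" %in% names(pv)) pv$cultivar == cv else TRUE, ]
      if (nrow(pv_cv) > 0) {
        tr <- run_stage("pressure_volume", cv, pv_traits(pv_cv))
        if (!is.null(tr)) {
          row$swc <- mean(tr$swc, na.rm = TRUE)
          row$pi_o <- mean(tr$pi_o, na.rm = TRUE)
          row$psi_tlp <- mean(tr$psi_tlp, na.rm = TRUE)
          row$rwc_tlp <- mean(tr$rwc_tlp, na.rm = TRUE)
          row$epsilon <- mean(tr$epsilon, na.rm = TRUE)
          row$c_ft <- mean(tr$c_ft, na.rm = TRUE)
          fits[[cv]]$pv <- tr
          note("pressure_volume", cv, sprintf("%d leaves", nrow(tr)))
        }
      }
    }

    if (!is.null(pw)) {
      pw_cv <- pw[if ("cultivar" %in% names(pw)) pw$cultivar == cv else TRUE, ]
      if ("treatment" %in% names(pw_cv) && !include_ww) {
        pw_cv <- pw_cv[pw_cv$treatment != "WW" | is.na(pw_cv$treatment), ]
      }
      if (nrow(pw_cv) > 0) {
        gwc <- run_stage("measurements", cv, {
          g <- suppressWarnings(
            compute_gwc(pw_cv$pot, pw_cv$pot_dry, pw_cv$pot_wet))
          last <- pw_cv$day == max(pw_cv$day)
          mean(g[last], na.rm = TRUE)
        })
        if (!is.null(gwc)) row$gwc_final <- gwc
      }
    }

    if (!is.null(row$psi_gs90 %||% NULL) && !is.null(row$p50 %||% NULL)) {
      row$hsm <- safety_margin(row$psi_gs90, row$p50)
    }
    if (all(c("psi_gs90", "psi_tlp", "p50") %in% names(row)) &&
        !anyNA(c(row$psi_gs90, row$psi_tlp, row$p50))) {
      phase_reports[[cv]] <- phase_report(pwfit, row$psi_gs90, row$psi_tlp,
                                          row$p50)
    }
    rows[[cv]] <- row
  }

  structure(
    list(trait_table = dplyr::bind_rows(rows),
         phase_reports = phase_reports,
         fits = fits,
         log = dplyr::bind_rows(log),
         config = list(include_ww = include_ww, degree = degree,
                       segments = segments, n_boot = n_boot, seed = seed)),
    class = "drydown_analysis")
}

#' @export
print.drydown_analysis <- function(x, ...) {
  cat("Dry-down trait analysis\n")
  cat(sprintf("  cultivars: %s\n", paste(x$trait_table$cultivar, collapse = ", ")))
  cat(sprintf("  seed = %s, n_boot = %s\n", x$config$seed, x$config$n_boot))
  print(x$trait_table)
  invisible(x)
}

#' Write analysis results to disk
#'
#' Emits the per-cultivar trait table as CSV and JSON, each phase report
#' as CSV, and the stage log.
#'
#' @param x A `drydown_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "drydown_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(x$trait_table, file.path(dir, "trait_table.csv"))
  jsonlite::write_json(x$trait_table, file.path(dir, "trait_table.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (cv in names(x$phase_reports)) {
    pr <- x$phase_reports[[cv]]
    pr$gs90_before_tlp <- attr(pr, "gs90_before_tlp")
    pr$gs90_before_p50 <- attr(pr, "gs90_before_p50")
    write_table(pr, file.path(dir, sprintf("phase_report_%s.csv", cv)))
  }
  if (nrow(x$log) > 0) write_table(x$log, file.path(dir, "stage_log.csv"))
  invisible(dir)
}
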