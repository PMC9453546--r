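# CSV input schemas. All water potentials are stored as signed MPa (<= 0);
# vulnerability-curve applied pressures are positive MPa of tension. That is
# the single unit convention of the package, enforced here at the boundary.

ht_schemas <- list(
  water_potential = list(
    required = c("plant_id", "day", "psi_pd", "psi_min"),
    optional = c("cultivar", "treatment"),
    numeric  = c("day", "psi_pd", "psi_min"),
    negative = c("psi_pd", "psi_min")
  ),
  gas_exchange = list(
    required = c("plant_id", "day", "a_n", "gs", "e"),
    optional = c("ci", "cultivar", "treatment"),
    numeric  = c("day", "a_n", "gs", "e", "ci"),
    negative = character()
  ),
  pot_weights = list(
    required = c("plant_id", "day", "pot", "pot_dry", "pot_wet"),
    optional = c("cultivar", "treatment"),
    numeric  = c("day", "pot", "pot_dry", "pot_wet"),
    negative = character()
  ),
  vulnerability = list(
    required = c("stem_id", "pressure_mpa", "kh"),
    optional = c("cultivar", "kmax"),
    numeric  = c("pressure_mpa", "kh", "kmax"),
    negative = character()
  ),
  pv_curve = list(
    required = c("leaf_id", "psi_mpa", "fresh_mass_g", "dry_mass_g",
                 "sat_mass_g"),
    optional = c("leaf_area_m2", "cultivar"),
    numeric  = c("psi_mpa", "fresh_mass_g", "dry_mass_g", "sat_mass_g",
                 "leaf_area_m2"),
    negative = "psi_mpa"
  )
)

#' Read a measurement table in one of the documented CSV schemas
#'
#' Reads and validates one of the five input tables used by the analysis
#' pipeline. Validation enforces the schema (no unknown columns, numeric
#' cells where required) and the sign convention for water-potential
#' columns: potentials must be negative; if *every* value in a potential
#' column is positive, the column is assumed to have been recorded as a
#' magnitude and is auto-negated with a message; a mixture of signs is a
#' schema error listing the offending rows.
#'
#' Physically inconsistent records (e.g. `psi_min > psi_pd`, or a pot
#' lighter than its oven-dry reference) are never dropped: they are kept
#' with a non-empty `flag` column so downstream fits can exclude them while
#' diagnostics still count them.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema One of `"water_potential"`, `"gas_exchange"`,
#'   `"pot_weights"`, `"vulnerability"`, `"pv_curve"`.
#' @return A tibble with typed columns, a `flag` character column (empty
#'   string when the record is clean) and, for `gas_exchange`, a derived
#'   `iwue` column.
#' @export
read_table <- function(path, schema = names(ht_schemas)) {
  schema <- match.arg(schema)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_table(raw, schema, source = path)
}

#' @rdname read_table
#' @export
read_water_potential <- function(path) read_table(path, "water_potential")

#' @rdname read_table
#' @export
read_gas_exchange <- function(path) read_table(path, "gas_exchange")

#' @rdname read_table
#' @export
read_pot_weights <- function(path) read_table(path, "pot_weights")

#' @rdname read_table
#' @export
read_vulnerability <- function(path) read_table(path, "vulnerability")

#' @rdname read_table
#' @export
read_pv_curve <- function(path) read_table(path, "pv_curve")

#' Validate an in-memory table against a documented schema
#'
#' The same checks as [read_table()], applied to a data frame already in
#' memory (e.g. output of the synthetic generator).
#'
#' @param data A data frame.
#' @inheritParams read_table
#' @param source Label used in error messages.
#' @return A validated tibble (see [read_table()]).
#' @export
validate_table <- function(data, schema = names(ht_schemas), source = "data") {
  schema <- match.arg(schema)
  sch <- ht_schemas[[schema]]
  data <- tibble::as_tibble(data)

  if (nrow(data) == 0) {
    warn(sprintf("'%s': empty %s table.", source, schema))
    out <- tibble::as_tibble(setNames(
      rep(list(character()), length(sch$required)), sch$required))
    out$flag <- character()
    return(out)
  }

  known <- c(sch$required, sch$optional, "flag")
  unknown <- setdiff(names(data), known)
  if (length(unknown) > 0) {
    ht_schema_error(sprintf(
      "'%s': unknown column(s) for schema '%s': %s. Expected: %s.",
      source, schema, paste(unknown, collapse = ", "),
      paste(known, collapse = ", ")))
  }
  missing <- setdiff(sch$required, names(data))
  if (length(missing) > 0) {
    ht_schema_error(sprintf("'%s': missing required column(s): %s.",
                            source, paste(missing, collapse = ", ")))
  }

  for (col in intersect(sch$numeric, names(data))) {
    vals <- data[[col]]
    if (!is.numeric(vals)) {
      conv <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & vals != "" & is.na(conv))
      if (length(bad) > 0) {
        ht_schema_error(sprintf(
          "'%s': non-numeric cell(s) in column '%s' at row(s) %s.",
          source, col, paste(utils::head(bad, 10), collapse = ", ")))
      }
      data[[col]] <- conv
    }
  }

  # sign convention for water potentials
  for (col in intersect(sch$negative, names(data))) {
    v <- data[[col]]
    nz <- v[!is.na(v) & v != 0]
    if (length(nz) == 0) next
    if (all(nz > 0)) {
      inform(sprintf(
        "'%s': column '%s' is entirely positive; interpreting values as magnitudes and negating (sign convention: water potentials are <= 0 MPa).",
        source, col))
      data[[col]] <- -v
    } else if (any(nz > 0)) {
      ht_schema_error(sprintf(
        "'%s': column '%s' mixes positive and negative values at row(s) %s; water potentials must share one sign.",
        source, col, paste(utils::head(which(v > 0), 10), collapse = ", ")))
    }
  }

  data$flag <- flag_records(data, schema)
  n_flag <- sum(data$flag != "")
  if (n_flag > 0) {
    warn(sprintf("'%s': %d record(s) flagged (%s); kept, not dropped.",
                 source, n_flag,
                 paste(unique(data$flag[data$flag != ""]), collapse = "; ")))
  }

  if (schema == "gas_exchange") {
    data$iwue <- suppressWarnings(compute_iwue(data$a_n, data$e))
  }
  data
}

# per-schema physical consistency flags (records kept, never dropped)
flag_records <- function(data, schema) {
  flag <- rep("", nrow(data))
  mark <- function(flag, idx, label) {
    ifelse(seq_along(flag) %in% which(idx), paste0(flag,
      ifelse(flag == "", "", ";"), label), flag)
  }
  if (schema == "water_potential") {
    bad <- !is.na(data$psi_min) & !is.na(data$psi_pd) & data$psi_min > data$psi_pd
    flag <- mark(flag, bad, "psi_min_above_psi_pd")
  }
  if (schema == "pot_weights") {
    if (any(data$pot_dry >= data$pot_wet, na.rm = TRUE)) {
      ht_schema_error("pot_weights: pot_dry must be below pot_wet.")
    }
    bad <- !is.na(data$pot) & data$pot < data$pot_dry
    flag <- mark(flag, bad, "pot_below_dry_weight")
  }
  if (schema == "gas_exchange") {
    flag <- mark(flag, !is.na(data$gs) & data$gs < 0, "negative_gs")
    flag <- mark(flag, !is.na(data$e) & data$e <= 0, "nonpositive_e")
  }
  if (schema == "vulnerability") {
    flag <- mark(flag, !is.na(data$pressure_mpa) & data$pressure_mpa < 0,
                 "negative_pressure")
  }
  if (schema == "pv_curve") {
    bad <- !is.na(data$fresh_mass_g) & !is.na(data$sat_mass_g) &
      data$fresh_mass_g > data$sat_mass_g
    flag <- mark(flag, bad, "fresh_above_saturated")
  }
  flag
}

#' Write a measurement or result table to CSV
#'
#' Plain CSV writer used for all package outputs. Finite numeric values
#' round-trip bit-exactly through [read_table()].
#'
#' @param data A data frame.
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
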