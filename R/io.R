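#' Read and write per-injection peak-area tables
#'
#' An injection table holds one row per measured peak: the sample it came
#' from, the compound, whether the monitored MRM transition is the
#' quantifier or the qualifier, the integrated peak area, the retention
#' time, and (optionally) the signal-to-noise ratio. The CSV schema is
#' `sample_id,compound,transition_role,area,rt,snr` (comma-separated,
#' UTF-8, dot decimal separator, one header row); `snr` may be empty.
#'
#' @param path Path to a CSV file.
#' @param registry Optional compound registry; when supplied, compounds not
#'   present in the registry are rejected (names are matched
#'   case-insensitively after whitespace normalization).
#' @return A tibble of validated injection records.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' inj <- tibble::tibble(
#'   sample_id = "s1", compound = "Atrazine",
#'   transition_role = c("quantifier", "qualifier"),
#'   area = c(1000, 480), rt = 7.1, snr = c(120, 55)
#' )
#' write_injections(inj, tf)
#' read_injections(tf)
#' @export
read_injections <- function(path, registry = NULL) {
  x <- read_schema_csv(
    path,
    cols = readr::cols(
      sample_id = readr::col_character(),
      compound = readr::col_character(),
      transition_role = readr::col_character(),
      area = readr::col_double(),
      rt = readr::col_double(),
      snr = readr::col_double()
    )
  )
  validate_injections(x, registry = registry)
}

#' @rdname read_injections
#' @param injections A tibble of injection records.
#' @export
write_injections <- function(injections, path) {
  validate_injections(injections)
  readr::write_csv(injections, path, na = "")
  invisible(path)
}

validate_injections <- function(x, registry = NULL) {
  x <- as_tibble(x)
  bad_role <- setdiff(unique(x$transition_role), c("quantifier", "qualifier"))
  if (length(bad_role) > 0) {
    abort(paste0("`transition_role` must be 'quantifier' or 'qualifier'; found: ",
                 paste(bad_role, collapse = ", ")),
          class = "residuval_validation_error")
  }
  neg <- which(!is.na(x$area) & x$area < 0)
  if (length(neg) > 0) {
    abort(paste0("Peak areas must be non-negative; offending rows: ",
                 paste(head(neg, 10), collapse = ", ")),
          class = "residuval_validation_error")
  }
  if (any(is.na(x$rt) | x$rt <= 0)) {
    abort("Retention times must be positive (decimal minutes).",
          class = "residuval_validation_error")
  }
  if (any(!is.na(x$snr) & x$snr < 0)) {
    abort("Signal-to-noise ratios must be non-negative when present.",
          class = "residuval_validation_error")
  }
  dup <- x %>%
    count(.data$sample_id, .data$compound, .data$transition_role) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate (sample, compound, transition_role) records, e.g. ",
                 dup$sample_id[1], " / ", dup$compound[1]),
          class = "residuval_validation_error")
  }
  if (!is.null(registry)) {
    unknown <- setdiff(unique(normalize_name(x$compound)),
                       normalize_name(registry$name))
    if (length(unknown) > 0) {
      abort(paste0("Compounds not in the registry: ",
                   paste(unknown, collapse = ", ")),
            class = "residuval_lookup_error")
    }
  }
  x
}

#' Read and write sample metadata tables
#'
#' Sample metadata assigns each injected sample its role in the study
#' design (solvent calibration, matrix-matched calibration, blank,
#' fortified, or monitoring), its soil matrix, the nominal concentration
#' (ng/mL for calibration levels, ng/g for fortification; 0 for blanks),
#' and the day/replicate indices of the precision design. Schema:
#' `sample_id,role,matrix,nominal_conc,day,replicate`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated sample records.
#' @export
read_samples <- function(path) {
  x <- read_schema_csv(
    path,
    cols = readr::cols(
      sample_id = readr::col_character(),
      role = readr::col_character(),
      matrix = readr::col_character(),
      nominal_conc = readr::col_double(),
      day = readr::col_integer(),
      replicate = readr::col_integer()
    )
  )
  validate_samples(x)
}

#' @rdname read_samples
#' @param samples A tibble of sample records.
#' @export
write_samples <- function(samples, path) {
  validate_samples(samples)
  readr::write_csv(samples, path, na = "")
  invisible(path)
}

sample_roles <- c("solvent_cal", "mm_cal", "blank", "fortified", "monitoring")
soil_matrices <- c("solvent", "SR", "RFNo", "RFNc", "XFN", "DC", "sand", "other")

validate_samples <- function(x) {
  x <- as_tibble(x)
  bad_role <- setdiff(unique(x$role), sample_roles)
  if (length(bad_role) > 0) {
    abort(paste0("Unknown sample roles: ", paste(bad_role, collapse = ", ")),
          class = "residuval_validation_error")
  }
  bad_mat <- setdiff(unique(x$matrix), soil_matrices)
  if (length(bad_mat) > 0) {
    abort(paste0("Unknown matrices: ", paste(bad_mat, collapse = ", "),
                 ". Expected one of: ", paste(soil_matrices, collapse = ", ")),
          class = "residuval_validation_error")
  }
  if (any(is.na(x$nominal_conc) | x$nominal_conc < 0)) {
    abort("`nominal_conc` must be non-negative (0 for blanks).",
          class = "residuval_validation_error")
  }
  if (any(x$role == "blank" & x$nominal_conc != 0)) {
    abort("Blank samples must carry nominal_conc 0.",
          class = "residuval_validation_error")
  }
  if (any(x$day < 1) || any(x$replicate < 1)) {
    abort("`day` and `replicate` must be integers >= 1.",
          class = "residuval_validation_error")
  }
  if (anyDuplicated(x$sample_id)) {
    abort("Sample ids must be unique.", class = "residuval_validation_error")
  }
  x
}

#' Read and write compound registries
#'
#' Schema: `name,category,ilis_group,si_ilis,expected_rt`.
#'
#' @param path Path to a CSV file.
#' @return A validated registry tibble.
#' @export
read_compounds <- function(path) {
  x <- read_schema_csv(
    path,
    cols = readr::cols(
      name = readr::col_character(),
      category = readr::col_character(),
      ilis_group = readr::col_integer(),
      si_ilis = readr::col_logical(),
      expected_rt = readr::col_double()
    )
  )
  validate_registry(x)
  x
}

#' @rdname read_compounds
#' @param registry A registry tibble.
#' @export
write_compounds <- function(registry, path) {
  validate_registry(registry)
  readr::write_csv(registry, path, na = "")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration holding the units policy, validation
#' thresholds, and RNG seed, merging it over the package defaults so that a
#' partial file is sufficient.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list with elements `units_policy`, `thresholds`, `seed`.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    extract_volume_per_mass = 1,
    thresholds = unclass(sante_thresholds()),
    seed = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    defaults <- utils::modifyList(defaults, user)
  }
  list(
    units_policy = units_policy(defaults$extract_volume_per_mass),
    thresholds = do.call(sante_thresholds, defaults$thresholds),
    seed = defaults$seed
  )
}

read_schema_csv <- function(path, cols) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "residuval_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(names(cols$cols), header)
  if (length(missing) > 0) {
    abort(paste0("CSV ", path, " is missing required columns: ",
                 paste(missing, collapse = ", ")),
          class = "residuval_schema_error")
  }
  readr::read_csv(path, col_types = cols)
}
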