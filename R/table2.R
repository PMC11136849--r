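#' Published per-compound validation table
#'
#' Loads the packaged validation figures of merit for the 38-analyte soil
#' method, validated in skeletic regosol: repeatability (`rsdr_*`) and
#' within-laboratory reproducibility (`rsdR_*`) RSDs in percent at the
#' three fortification levels (10, 25, 50 ng/g), relative recoveries in
#' percent at the same levels, the limit of quantification in ng/g, and the
#' calibration coefficient of determination. RSD values are stored as
#' percent throughout (the source occasionally quotes them with a ng/g
#' unit; that is not propagated here).
#'
#' @return A tibble with 38 rows and columns `no`, `analyte`, `category`,
#'   `ilis_group`, `si_ilis`, `rsdr_10/25/50`, `rsdR_10/25/50`,
#'   `rel_rec_10/25/50`, `loq_ng_g`, `r_squared`.
#' @examples
#' tab <- load_table2_fixture()
#' mean(tab$rsdr_10)
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_validation.csv", package = "residuval")
  if (path == "") {
    abort("Packaged validation table not found; reinstall the package.",
          class = "residuval_integrity_error")
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      no = readr::col_integer(),
      analyte = readr::col_character(),
      category = readr::col_character(),
      ilis_group = readr::col_integer(),
      si_ilis = readr::col_logical(),
      .default = readr::col_double()
    )
  )
  check_table2_integrity(x)
  x
}

# frozen at packaging time: nrow, numeric-cell checksum
.table2_nrow <- 38L
.table2_checksum <- 13676.489

check_table2_integrity <- function(x) {
  numeric_cols <- c("no", "ilis_group", "rsdr_10", "rsdr_25", "rsdr_50",
                    "rsdR_10", "rsdR_25", "rsdR_50", "rel_rec_10",
                    "rel_rec_25", "rel_rec_50", "loq_ng_g", "r_squared")
  missing <- setdiff(numeric_cols, names(x))
  if (nrow(x) != .table2_nrow || length(missing) > 0) {
    abort("Packaged validation table is corrupted (row/column contract).",
          class = "residuval_integrity_error")
  }
  checksum <- sum(as.matrix(x[numeric_cols]))
  if (!isTRUE(all.equal(checksum, .table2_checksum, tolerance = 1e-9))) {
    abort("Packaged validation table failed its checksum.",
          class = "residuval_integrity_error")
  }
  invisible(x)
}
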