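#' Concentration units policy
#'
#' Links concentrations in the final extract (ng/mL) to concentrations in
#' soil (ng/g dry weight). With the reference QuEChERS protocol (5 g soil
#' extracted into 5 mL acidified acetonitrile) the conversion factor is
#' 1 mL/g, so the two unit systems coincide numerically; other
#' soil-to-solvent ratios are supported through this policy object.
#'
#' @param extract_volume_per_mass Extract volume per soil mass in mL/g.
#'   Default 1 (5 g / 5 mL).
#' @return An object of class `units_policy`.
#' @examples
#' pol <- units_policy()
#' to_ng_per_g(25, pol)
#' @export
units_policy <- function(extract_volume_per_mass = 1) {
  if (!is.numeric(extract_volume_per_mass) || length(extract_volume_per_mass) != 1 ||
      is.na(extract_volume_per_mass) || extract_volume_per_mass <= 0) {
    abort("`extract_volume_per_mass` must be a single positive number (mL/g).",
          class = "residuval_validation_error")
  }
  structure(list(extract_volume_per_mass = extract_volume_per_mass),
            class = "units_policy")
}

#' @rdname units_policy
#' @param x Concentration(s) to convert.
#' @param policy A [units_policy()].
#' @export
to_ng_per_g <- function(x, policy = units_policy()) {
  stopifnot(inherits(policy, "units_policy"))
  x * policy$extract_volume_per_mass
}

#' @rdname units_policy
#' @export
to_ng_per_ml <- function(x, policy = units_policy()) {
  stopifnot(inherits(policy, "units_policy"))
  x / policy$extract_volume_per_mass
}

#' @export
print.units_policy <- function(x, ...) {
  cat("<units_policy> ", x$extract_volume_per_mass,
      " mL extract per g soil (ng/mL extract * factor = ng/g soil)\n", sep = "")
  invisible(x)
}
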