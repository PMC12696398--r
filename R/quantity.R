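# Quantities with bench units and exact conversion. Internal canonical units
# are mol/l, l, g, g/l and g/mol; conversion happens only at I/O boundaries so
# chained computations never accumulate unit drift.

.unit_table <- data.frame(
  unit      = c("g", "mg", "l", "ml", "ul", "mol/l", "mmol/l", "umol/l",
                "g/l", "mg/l", "g/mol", "dimensionless", "%"),
  dimension = c("mass", "mass", "volume", "volume", "volume",
                "molar_conc", "molar_conc", "molar_conc",
                "mass_conc", "mass_conc", "molar_mass", "dimensionless",
                "dimensionless"),
  factor    = c(1, 1e-3, 1, 1e-3, 1e-6, 1, 1e-3, 1e-6, 1, 1e-3, 1, 1, 1),
  stringsAsFactors = FALSE
)

# Accept the Greek-mu spellings used on reagent sheets.
.normalize_unit <- function(unit) {
  u <- gsub("μ|µ", "u", trimws(unit))
  u <- sub("^uM$", "umol/l", u)
  u <- sub("^mM$", "mmol/l", u)
  u <- sub("^M$", "mol/l", u)
  u
}

.unit_info <- function(unit) {
  u <- .normalize_unit(unit)
  i <- match(u, .unit_table$unit)
  if (is.na(i)) {
    stop_mediaforge("mediaforge_unit_error", sprintf("unknown unit '%s'", unit))
  }
  .unit_table[i, ]
}

#' Create a quantity with a unit
#'
#' @param value a finite number; must be non-negative for masses, volumes and
#'   concentrations.
#' @param unit one of `g, mg, l, ml, ul, mol/l, mmol/l, umol/l, g/l, mg/l,
#'   g/mol, dimensionless, %` (Greek-mu spellings accepted).
#' @return A `quantity` object.
#' @examples
#' quantity(0.5, "g")
#' @export
quantity <- function(value, unit) {
  check_scalar_number(value, "value")
  info <- .unit_info(unit)
  if (info$dimension %in% c("mass", "volume", "molar_conc", "mass_conc") &&
      value < 0) {
    stop_mediaforge("mediaforge_domain_error",
                    sprintf("a %s cannot be negative (got %g %s)",
                            info$dimension, value, unit))
  }
  structure(list(value = value, unit = info$unit, dimension = info$dimension),
            class = "quantity")
}

#' @export
print.quantity <- function(x, ...) {
  cat(format(x$value, digits = 12), x$unit, "\n")
  invisible(x)
}

#' Convert a quantity to a compatible unit
#'
#' Pure rescaling between units of the same dimension (mass to mass, volume to
#' volume, ...). Converting a mass concentration to a molar concentration
#' requires a molar mass: see [mass_conc_to_molar()].
#'
#' @param q a [quantity()].
#' @param unit target unit.
#' @return A new `quantity`; the input is untouched.
#' @examples
#' convert_quantity(quantity(0.5, "g"), "mg")  # 500 mg
#' @export
convert_quantity <- function(q, unit) {
  stopifnot(inherits(q, "quantity"))
  info <- .unit_info(unit)
  from <- .unit_info(q$unit)
  if (info$dimension != from$dimension) {
    stop_mediaforge("mediaforge_unit_error",
                    sprintf("cannot convert '%s' (%s) to '%s' (%s)",
                            q$unit, from$dimension, info$unit, info$dimension))
  }
  quantity(q$value * from$factor / info$factor, info$unit)
}

#' Convert a mass concentration to a molar concentration
#'
#' @param c_mass mass concentration in g/l (a number, or a `quantity` with a
#'   mass-concentration unit).
#' @param molar_mass molar mass in g/mol, > 0.
#' @return Molar concentration in mol/l (full precision; display at the bench
#'   is conventionally 2-decimal mM or integer uM).
#' @examples
#' 1e3 * mass_conc_to_molar(0.2, 115.13)  # proline: 1.74 mM
#' @export
mass_conc_to_molar <- function(c_mass, molar_mass) {
  if (inherits(c_mass, "quantity")) {
    c_mass <- convert_quantity(c_mass, "g/l")$value
  }
  check_scalar_number(c_mass, "c_mass", min = 0)
  check_scalar_number(molar_mass, "molar_mass", min = 0, strict = TRUE)
  c_mass / molar_mass
}

#' Molar concentration to mass concentration
#'
#' @param c_molar molar concentration in mol/l.
#' @param molar_mass molar mass in g/mol, > 0.
#' @return Mass concentration in g/l.
#' @export
molar_to_mass_conc <- function(c_molar, molar_mass) {
  check_scalar_number(c_molar, "c_molar", min = 0)
  check_scalar_number(molar_mass, "molar_mass", min = 0, strict = TRUE)
  c_molar * molar_mass
}

#' Weigh-in mass for a stock solution
#'
#' m = M * c * V: the mass to weigh for a target molarity and volume.
#'
#' @param c_molar target concentration in mol/l (>= 0).
#' @param volume_l target volume in l (> 0).
#' @param molar_mass molar mass in g/mol (> 0).
#' @return Mass in g (full precision; report mg at 0.1 mg, the precision of a
#'   calibrated analytical balance).
#' @examples
#' weigh_in_mass(0.201, 0.05, 149.21)  # 1.4996 g Met for a 1000x stock
#' @export
weigh_in_mass <- function(c_molar, volume_l, molar_mass) {
  check_scalar_number(c_molar, "c_molar", min = 0)
  check_scalar_number(volume_l, "volume_l", min = 0, strict = TRUE)
  check_scalar_number(molar_mass, "molar_mass", min = 0, strict = TRUE)
  molar_mass * c_molar * volume_l
}

#' Adjusted dilution volume from the actually weighed mass
#'
#' V = m / (M * c): the solvent volume that preserves the target molarity for
#' whatever mass (m2 - m1 on the balance) actually landed in the tube.
#'
#' @param actual_mass_g actual mass in g (>= 0).
#' @param molar_mass molar mass in g/mol (> 0).
#' @param c_molar target concentration in mol/l (> 0).
#' @return Volume in l (display at 0.01 ml).
#' @examples
#' 1e3 * adjusted_volume(1.6, 149.21, 0.201)  # 53.35 ml
#' @export
adjusted_volume <- function(actual_mass_g, molar_mass, c_molar) {
  check_scalar_number(actual_mass_g, "actual_mass_g", min = 0)
  check_scalar_number(molar_mass, "molar_mass", min = 0, strict = TRUE)
  check_scalar_number(c_molar, "c_molar", min = 0, strict = TRUE)
  actual_mass_g / (molar_mass * c_molar)
}

#' Cells per well from a seeding density
#'
#' @param density_per_ml cells per ml (>= 0).
#' @param volume_ml dispensed volume in ml (>= 0).
#' @return Cell count, rounded to the nearest integer.
#' @examples
#' cells_per_well(2e5, 0.1)  # 20,000 cells per well
#' @export
cells_per_well <- function(density_per_ml, volume_ml) {
  check_scalar_number(density_per_ml, "density_per_ml", min = 0)
  check_scalar_number(volume_ml, "volume_ml", min = 0)
  round(density_per_ml * volume_ml)
}

#' Cost ratio of commercial versus self-made medium
#'
#' @param self_made_cost cost per bottle of the self-made medium (> 0).
#' @param commercial_cost cost per bottle of the commercial equivalent.
#' @return The fold ratio commercial / self-made (display as nearest integer).
#' @examples
#' cost_fold(5.50, 85)  # ~15x
#' @export
cost_fold <- function(self_made_cost, commercial_cost) {
  check_scalar_number(self_made_cost, "self_made_cost", min = 0, strict = TRUE)
  check_scalar_number(commercial_cost, "commercial_cost", min = 0)
  commercial_cost / self_made_cost
}
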