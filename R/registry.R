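# Compound registry: the media component database (names, formulas, molar
# masses, final 1x amounts, stock multipliers, solvents, storage). A built-in
# table ships the DMEM component set; any registry with the same columns can
# be loaded instead.

.registry_columns <- c(
  "name", "category", "formula", "molar_mass_g_per_mol", "final_amount",
  "final_amount_unit", "stock_multiplier", "solvent", "storage",
  "light_sensitive", "notes"
)

.categories <- c("amino_acid", "vitamin", "inorganic_salt", "carbohydrate",
                 "buffer", "additional", "supplement", "label")

# Bench shorthand -> registry name (after normalization).
.compound_aliases <- c(
  gly = "glycine", arg = "arginine hydrochloride",
  his = "histidine hydrochloride monohydrate",
  lys = "lysine monohydrochloride", met = "methionine",
  cystine = "cystine dihydrochloride", ile = "isoleucine", leu = "leucine",
  phe = "phenylalanine", ser = "serine", thr = "threonine",
  trp = "tryptophan", tryptophan = "tryptophan",
  tyr = "tyrosine disodium salt dihydrate", val = "valine",
  nam = "nicotinamide", glucose = "glucose", pro = "proline",
  proline = "proline", aha = "4-azido-l-homoalanine",
  gln = "glutamine", glutamine = "glutamine", pyruvate = "sodium pyruvate",
  methionine = "methionine", arginine = "arginine hydrochloride",
  lysine = "lysine monohydrochloride",
  "pen-strep" = "penicillin-streptomycin",
  "trp-13c11-15n2" = "tryptophan-13c11-15n2",
  "arg-13c6" = "arginine-13c6", "arg-13c6-15n4" = "arginine-13c6-15n4",
  "lys-d4" = "lysine-d4", "lys-13c6-15n2" = "lysine-13c6-15n2"
)

#' Normalize a compound name
#'
#' Lowercases and strips a leading stereochemical prefix (`L-`, `D-`, `DL-`,
#' `i-`) into a separate field, so lookups are robust to how the prefix was
#' typed.
#'
#' @param name character vector of compound names.
#' @return A data frame with columns `normalized` and `stereo_prefix`.
#' @export
normalize_compound_name <- function(name) {
  low <- tolower(trimws(name))
  m <- regmatches(low, regexec("^(l|d|dl|i)-(.*)$", low))
  prefix <- vapply(m, function(x) if (length(x)) x[2] else "", character(1))
  core <- ifelse(nzchar(prefix),
                 vapply(m, function(x) if (length(x)) x[3] else "", character(1)),
                 low)
  data.frame(normalized = core, stereo_prefix = prefix,
             stringsAsFactors = FALSE)
}

# Final concentration in umol/l from a (final_amount, unit, molar mass) row;
# NA where not expressible (percent supplements).
.final_conc_um <- function(amount, unit, molar_mass) {
  u <- .normalize_unit(unit)
  if (is.na(amount)) return(NA_real_)
  switch(u,
    "mg/l"   = if (is.na(molar_mass)) NA_real_ else amount / molar_mass * 1e3,
    "g/l"    = if (is.na(molar_mass)) NA_real_ else amount / molar_mass * 1e6,
    "umol/l" = amount,
    "mmol/l" = amount * 1e3,
    "mol/l"  = amount * 1e6,
    NA_real_
  )
}

#' Load a compound registry
#'
#' Reads and validates a registry CSV (columns: name, category, formula,
#' molar_mass_g_per_mol, final_amount, final_amount_unit, stock_multiplier,
#' solvent, storage, light_sensitive, notes). With `path = NULL` the built-in
#' DMEM registry is loaded: the full high-glucose DMEM component set with the
#' stock-multiplier scheme used at the bench (1000x/100x amino-acid stocks,
#' 1000x/2000x salt and vitamin stocks, 200x inorganic salts, 25x
#' bicarbonate/NaCl, 100x glucose) plus SILAC/tracing label compounds.
#'
#' @param path path to a registry CSV, or `NULL` for the built-in table.
#' @return A `compound_registry` tibble with typed columns plus derived
#'   `normalized_name`, `stereo_prefix`, `final_conc_um` and `stock_conc_um`.
#' @examples
#' reg <- load_registry()
#' compound_molarity(reg, "Trp")  # ~78 uM
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dmem_registry.csv", package = "mediaforge",
                        mustWork = TRUE)
  }
  raw <- utils::read.csv(path, colClasses = "character")
  missing_cols <- setdiff(.registry_columns, names(raw))
  if (length(missing_cols)) {
    stop_mediaforge("mediaforge_validation_error",
                    paste("registry is missing columns:",
                          paste(missing_cols, collapse = ", ")))
  }
  reg <- tibble::as_tibble(raw[, .registry_columns])
  num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  reg$molar_mass_g_per_mol <- num(reg$molar_mass_g_per_mol)
  reg$final_amount <- num(reg$final_amount)
  reg$stock_multiplier <- num(reg$stock_multiplier)
  reg$light_sensitive <- toupper(reg$light_sensitive) == "TRUE"
  norm <- normalize_compound_name(reg$name)
  reg$normalized_name <- norm$normalized
  reg$stereo_prefix <- norm$stereo_prefix
  validate_registry(reg)
  reg$final_conc_um <- mapply(.final_conc_um, reg$final_amount,
                              reg$final_amount_unit, reg$molar_mass_g_per_mol)
  reg$stock_conc_um <- reg$final_conc_um * reg$stock_multiplier
  class(reg) <- c("compound_registry", class(reg))
  reg
}

#' Validate a compound registry
#'
#' Checks name uniqueness (after normalization), positive molar masses
#' (required except for percent-dosed supplements), stock multipliers >= 1,
#' non-negative final amounts and known categories. All offending rows are
#' listed in one error.
#'
#' @param reg a registry tibble.
#' @return The registry, invisibly, if valid.
#' @export
validate_registry <- function(reg) {
  problems <- character(0)
  dup <- reg$normalized_name[duplicated(reg$normalized_name)]
  if (length(dup)) {
    problems <- c(problems, paste("duplicate names:", paste(unique(dup), collapse = ", ")))
  }
  pct <- .normalize_unit(reg$final_amount_unit) == "%"
  bad_mm <- !pct & (is.na(reg$molar_mass_g_per_mol) | reg$molar_mass_g_per_mol <= 0)
  if (any(bad_mm)) {
    problems <- c(problems, paste("missing or non-positive molar mass:",
                                  paste(reg$name[bad_mm], collapse = ", ")))
  }
  bad_cat <- !(reg$category %in% .categories)
  if (any(bad_cat)) {
    problems <- c(problems, paste("unknown category:",
                                  paste(reg$name[bad_cat], collapse = ", ")))
  }
  bad_mult <- is.na(reg$stock_multiplier) | reg$stock_multiplier < 1
  if (any(bad_mult)) {
    problems <- c(problems, paste("stock multiplier must be >= 1:",
                                  paste(reg$name[bad_mult], collapse = ", ")))
  }
  bad_amt <- !is.na(reg$final_amount) & reg$final_amount < 0
  if (any(bad_amt)) {
    problems <- c(problems, paste("negative final amount:",
                                  paste(reg$name[bad_amt], collapse = ", ")))
  }
  if (length(problems)) {
    stop_mediaforge("mediaforge_validation_error",
                    paste("invalid registry:", paste(problems, collapse = "; ")))
  }
  invisible(reg)
}

#' Save a registry to CSV
#'
#' Writes the canonical comma-separated dialect (unquoted fields, so fields
#' must not contain commas), such that `save_registry(load_registry(x))` is
#' byte-stable.
#'
#' @param reg a `compound_registry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(reg, path) {
  out <- reg[, .registry_columns]
  chr <- function(x) {
    if (is.logical(x)) return(ifelse(x, "TRUE", "FALSE"))
    if (is.numeric(x)) return(ifelse(is.na(x), "", as.character(x)))
    ifelse(is.na(x), "", x)
  }
  out <- as.data.frame(lapply(out, chr), stringsAsFactors = FALSE)
  has_comma <- vapply(out, function(x) any(grepl(",", x)), logical(1))
  if (any(has_comma)) {
    stop_mediaforge("mediaforge_validation_error",
                    "canonical registry CSV forbids commas inside fields")
  }
  lines <- c(paste(.registry_columns, collapse = ","),
             do.call(paste, c(unname(out), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Look up a compound by name or bench shorthand
#'
#' Matches the normalized name (stereo prefix stripped, case-insensitive) and
#' common shorthands (`"Met"`, `"Trp"`, `"NAM"`, `"glucose"`, ...).
#'
#' @param reg a `compound_registry`.
#' @param name compound name or alias (length 1).
#' @return The matching one-row tibble.
#' @export
find_compound <- function(reg, name) {
  key <- normalize_compound_name(name)$normalized
  if (key %in% names(.compound_aliases)) key <- .compound_aliases[[key]]
  i <- match(key, reg$normalized_name)
  if (is.na(i)) {
    stop_mediaforge("mediaforge_lookup_error",
                    sprintf("compound '%s' not found in registry", name))
  }
  reg[i, ]
}

#' Final molar concentration of a registry compound in 1x medium
#'
#' @param reg a `compound_registry`.
#' @param name compound name or alias.
#' @return Concentration in umol/l.
#' @examples
#' reg <- load_registry()
#' compound_molarity(reg, "Met")  # ~201 uM
#' @export
compound_molarity <- function(reg, name) {
  row <- find_compound(reg, name)
  if (is.na(row$final_conc_um)) {
    stop_mediaforge("mediaforge_lookup_error",
                    sprintf("'%s' has no molar final concentration", name))
  }
  row$final_conc_um
}
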