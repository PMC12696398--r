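# Stock / master-stock planning and final medium assembly: per-addition
# volumes, automatic water back-fill, variant generation and ordered bench
# checklists. Volume conservation is asserted to 0.001 ml; volumes are
# displayed at 0.01 ml.

.vol_tol_ml <- 1e-3

# The three master stocks and their member compounds (normalized names).
.master_stocks <- list(
  amino_acids = list(
    label = "10x amino acid master stock", multiplier = 10,
    members = c("glycine", "arginine hydrochloride",
                "histidine hydrochloride monohydrate",
                "lysine monohydrochloride", "methionine",
                "cystine dihydrochloride", "isoleucine", "leucine",
                "phenylalanine", "serine", "threonine", "tryptophan",
                "tyrosine disodium salt dihydrate", "valine")),
  salts_vitamins = list(
    label = "100x salts and vitamins master stock", multiplier = 100,
    members = c("choline chloride", "calcium pantothenate", "nicotinamide",
                "pyridoxine hydrochloride", "thiamine hydrochloride",
                "inositol", "iron(iii) nitrate nonahydrate",
                "calcium chloride dihydrate", "potassium chloride")),
  inorganic_salts = list(
    label = "100x inorganic salts master stock", multiplier = 100,
    members = c("magnesium sulfate", "sodium dihydrogen phosphate dihydrate"))
)

.sections <- c("initial water", "inorganic salts", "salts and vitamins",
               "amino acids", "additional components")

.section_of <- function(normalized_name) {
  for (key in c("inorganic_salts", "salts_vitamins", "amino_acids")) {
    if (normalized_name %in% .master_stocks[[key]]$members) {
      return(switch(key, inorganic_salts = "inorganic salts",
                    salts_vitamins = "salts and vitamins",
                    amino_acids = "amino acids"))
    }
  }
  "additional components"
}

#' Plan a combined (master) stock from individual stocks
#'
#' Each component contributes `total_volume * target_multiplier /
#' source_multiplier`; water is back-filled to the total. A source more dilute
#' than the target is an impossible dilution.
#'
#' @param components a data frame with columns `name` and `source_multiplier`
#'   (and optionally `light_sensitive`, `notes`, carried into the
#'   instructions).
#' @param target_multiplier concentration factor of the combined stock.
#' @param total_volume_ml total stock volume in ml (> 0).
#' @return A `stock_plan`: components with volumes, the water back-fill and
#'   ordered instructions.
#' @examples
#' plan_master_stock(
#'   data.frame(name = c("a", "b"), source_multiplier = c(200, 200)),
#'   target_multiplier = 100, total_volume_ml = 10)
#' @export
plan_master_stock <- function(components, target_multiplier, total_volume_ml) {
  check_scalar_number(target_multiplier, "target_multiplier", min = 0, strict = TRUE)
  check_scalar_number(total_volume_ml, "total_volume_ml", min = 0, strict = TRUE)
  stopifnot(is.data.frame(components),
            all(c("name", "source_multiplier") %in% names(components)))
  infeasible <- components$source_multiplier < target_multiplier
  if (any(infeasible)) {
    stop_mediaforge("mediaforge_infeasible_plan",
                    paste("source stock more dilute than the target for:",
                          paste(components$name[infeasible], collapse = ", ")))
  }
  vols <- total_volume_ml * target_multiplier / components$source_multiplier
  water <- total_volume_ml - sum(vols)
  if (water < -.vol_tol_ml) {
    stop_mediaforge("mediaforge_overcommitted_volume",
                    sprintf("component volumes (%.2f ml) exceed the total (%.2f ml)",
                            sum(vols), total_volume_ml))
  }
  water <- max(water, 0)
  steps <- sprintf("Add %s ml of the %gx '%s' stock.", fmt_num(vols),
                   components$source_multiplier, components$name)
  if (!is.null(components$light_sensitive)) {
    ls <- isTRUE(components$light_sensitive) | components$light_sensitive %in% TRUE
    steps[ls] <- paste(steps[ls], "Protect from light.")
  }
  if (!is.null(components$notes)) {
    has_note <- !is.na(components$notes) & nzchar(components$notes)
    steps[has_note] <- paste0(steps[has_note], " Note: ", components$notes[has_note], ".")
  }
  steps <- c(steps, sprintf("Back-fill with %s ml water to reach %s ml.",
                            fmt_num(water), fmt_num(total_volume_ml)))
  structure(
    list(components = tibble::tibble(name = components$name,
                                     source_multiplier = components$source_multiplier,
                                     volume_ml = vols),
         target_multiplier = target_multiplier,
         total_volume_ml = total_volume_ml,
         water_ml = water, instructions = steps),
    class = "stock_plan")
}

#' @export
print.stock_plan <- function(x, ...) {
  cat(sprintf("<stock_plan> %gx combined stock, %s ml (water %s ml)\n",
              x$target_multiplier, fmt_num(x$total_volume_ml), fmt_num(x$water_ml)))
  for (s in x$instructions) cat(" -", s, "\n")
  invisible(x)
}

#' Plan one of the three built-in master stocks
#'
#' @param kind `"amino_acids"` (10x), `"salts_vitamins"` (100x) or
#'   `"inorganic_salts"` (100x).
#' @param total_volume_ml total master-stock volume in ml.
#' @param registry a `compound_registry`.
#' @return A `stock_plan`.
#' @examples
#' master_stock_plan("amino_acids", 100)  # 6 x 1 ml + 8 x 10 ml + 14 ml water
#' @export
master_stock_plan <- function(kind = names(.master_stocks), total_volume_ml,
                              registry = load_registry()) {
  kind <- match.arg(kind)
  def <- .master_stocks[[kind]]
  idx <- match(def$members, registry$normalized_name)
  if (anyNA(idx)) {
    stop_mediaforge("mediaforge_lookup_error",
                    paste("registry lacks master-stock members:",
                          paste(def$members[is.na(idx)], collapse = ", ")))
  }
  comps <- data.frame(name = registry$name[idx],
                      source_multiplier = registry$stock_multiplier[idx],
                      light_sensitive = registry$light_sensitive[idx],
                      notes = registry$notes[idx],
                      stringsAsFactors = FALSE)
  plan_master_stock(comps, def$multiplier, total_volume_ml)
}

# Can this master stock be used as-is for the spec (all members present at
# their registry amounts, none omitted/titrated/replaced)?
.master_usable <- function(spec, registry, key) {
  def <- .master_stocks[[key]]
  comp <- spec$composition
  for (m in def$members) {
    i <- which(comp$normalized_name == m)
    if (length(i) != 1L) return(FALSE)
    j <- match(m, registry$normalized_name)
    ref <- registry$final_conc_um[j]
    if (is.na(comp$final_conc_um[i]) || is.na(ref)) return(FALSE)
    if (abs(comp$final_conc_um[i] - ref) > 1e-9 * max(1, ref)) return(FALSE)
  }
  TRUE
}

#' Assemble a medium: per-addition volumes and water back-fill
#'
#' Resolves a `medium_spec` into an ordered bench checklist. Master stocks are
#' used whenever the spec keeps all their members at standard amounts;
#' otherwise the affected section falls back to individual stocks so single
#' components can be omitted, titrated or replaced. Each addition occupies
#' `final_volume / multiplier` (or `final_volume * target_conc / stock_conc`
#' for retitrated components); water is back-filled so that additions plus
#' water equal the final volume. Post-filtration supplements (FBS, glutamine,
#' pyruvate, antibiotics) are listed on a separate checklist and - like the pH
#' adjustment acid - are excluded from the back-filled volume.
#'
#' @param spec a `medium_spec`.
#' @param final_volume_ml final batch volume in ml (> 0).
#' @param registry a `compound_registry`.
#' @return An `assembly_plan` with `additions` (section, addition, volume_ml),
#'   `water_ml`, `ph_target`, a supplements checklist and notes.
#' @examples
#' plan <- assemble_medium(load_preset("complete_dmem"), 500)
#' plan$water_ml  # 385
#' @export
assemble_medium <- function(spec, final_volume_ml, registry = load_registry()) {
  stopifnot(inherits(spec, "medium_spec"))
  check_scalar_number(final_volume_ml, "final_volume_ml", min = 0, strict = TRUE)
  comp <- spec$composition
  additions <- tibble::tibble(section = character(0), addition = character(0),
                              volume_ml = numeric(0))
  covered <- character(0)
  for (key in c("inorganic_salts", "salts_vitamins", "amino_acids")) {
    def <- .master_stocks[[key]]
    present <- intersect(def$members, comp$normalized_name)
    if (!length(present)) next
    if (.master_usable(spec, registry, key)) {
      additions <- tibble::add_row(
        additions, section = .section_of(def$members[1]),
        addition = def$label, volume_ml = final_volume_ml / def$multiplier)
      covered <- c(covered, def$members)
    }
  }
  rest <- comp[!(comp$normalized_name %in% covered) & !comp$post_filtration, ]
  active <- !is.na(rest$final_amount) & rest$final_amount > 0
  rest <- rest[active, ]
  if (nrow(rest)) {
    j <- match(rest$normalized_name, registry$normalized_name)
    unresolved <- is.na(j)
    if (any(unresolved)) {
      stop_mediaforge("mediaforge_lookup_error",
                      paste("components not in registry:",
                            paste(rest$component[unresolved], collapse = ", ")))
    }
    # Concentration-specified additions scale by target/stock concentration;
    # standard additions by the stock multiplier.
    vol <- ifelse(
      !is.na(rest$final_conc_um) & !is.na(rest$stock_conc_um),
      final_volume_ml * rest$final_conc_um / rest$stock_conc_um,
      final_volume_ml / rest$stock_multiplier)
    additions <- rbind(additions, tibble::tibble(
      section = vapply(rest$normalized_name, .section_of, character(1)),
      addition = sprintf("%gx %s stock", rest$stock_multiplier, rest$component),
      volume_ml = vol))
  }
  additions$section <- factor(additions$section, levels = .sections)
  additions <- additions[order(additions$section), ]
  additions$section <- as.character(additions$section)
  water <- final_volume_ml - sum(additions$volume_ml)
  if (water < -.vol_tol_ml) {
    stop_mediaforge("mediaforge_overcommitted_volume",
                    paste0(sprintf("additions sum to %.2f ml > final volume %.2f ml: ",
                                   sum(additions$volume_ml), final_volume_ml),
                           paste(additions$addition, collapse = ", ")))
  }
  supp <- comp[comp$post_filtration &
                 !is.na(comp$final_amount) & comp$final_amount > 0, ]
  supp_name <- supp$component
  if (isTRUE(spec$dialyzed_fbs)) {
    supp_name[supp$normalized_name == "fbs"] <- "dialyzed FBS"
  }
  supplements <- tibble::tibble(
    name = supp_name,
    final_amount = supp$final_amount,
    final_amount_unit = supp$final_amount_unit,
    volume_ml = final_volume_ml / supp$stock_multiplier)
  acid <- if (max(spec$ph_target) <= 7.5) "HCl (correct with 1 M NaOH if overshot)" else "HCl"
  structure(
    list(spec = spec, final_volume_ml = final_volume_ml,
         additions = additions, water_ml = max(water, 0),
         ph_target = spec$ph_target, acid = acid,
         supplements = supplements,
         control_reminder = isTRUE(spec$control_reminder),
         notes = spec$notes),
    class = "assembly_plan")
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(export_plan(x, "markdown"))
  invisible(x)
}

#' Derive a variant medium by omitting, titrating or replacing components
#'
#' @param spec the parent `medium_spec`.
#' @param omit character vector of components to set to zero.
#' @param titrate named numeric vector of target concentrations in umol/l.
#' @param replace named character vector mapping a component to its (labeled)
#'   counterpart; the molar amount is preserved.
#' @param registry a `compound_registry`.
#' @param name name for the variant (default derived from the parent).
#' @return A new `medium_spec` with control linkage back to the parent.
#' @examples
#' v <- make_variant(load_preset("complete_dmem"), omit = "Trp")
#' nrow(diff_specs(v, load_preset("complete_dmem")))  # 1
#' @export
make_variant <- function(spec, omit = NULL, titrate = NULL, replace = NULL,
                         registry = load_registry(), name = NULL) {
  stopifnot(inherits(spec, "medium_spec"))
  comp <- spec$composition
  resolve <- function(nm) {
    key <- normalize_compound_name(nm)$normalized
    if (key %in% names(.compound_aliases)) key <- .compound_aliases[[key]]
    i <- which(comp$normalized_name == key)
    if (!length(i)) {
      stop_mediaforge("mediaforge_lookup_error",
                      sprintf("component '%s' not in specification", nm))
    }
    i[1]
  }
  for (nm in omit) {
    comp <- .zero_component(comp, comp$normalized_name[resolve(nm)])
  }
  if (!is.null(titrate)) {
    stopifnot(is.numeric(titrate), !is.null(names(titrate)))
    for (nm in names(titrate)) {
      i <- resolve(nm)
      target <- titrate[[nm]]
      check_scalar_number(target, nm, min = 0)
      if (is.na(comp$stock_conc_um[i])) {
        stop_mediaforge("mediaforge_infeasible_plan",
                        sprintf("'%s' has no molar stock to titrate from", nm))
      }
      if (target > comp$stock_conc_um[i]) {
        stop_mediaforge("mediaforge_infeasible_plan",
                        sprintf("target %g umol/l for '%s' exceeds its stock concentration (%g umol/l)",
                                target, nm, comp$stock_conc_um[i]))
      }
      comp$final_conc_um[i] <- target
      comp$final_amount[i] <- target
      comp$final_amount_unit[i] <- "umol/l"
    }
  }
  if (!is.null(replace)) {
    stopifnot(is.character(replace), !is.null(names(replace)))
    for (nm in names(replace)) {
      i <- resolve(nm)
      conc <- comp$final_conc_um[i]
      comp <- .zero_component(comp, comp$normalized_name[i])
      comp <- .add_component(comp, registry, replace[[nm]], conc_um = conc)
    }
  }
  new_medium_spec(
    name = if (is.null(name)) paste0(spec$name, "_variant") else name,
    composition = comp, ph_target = spec$ph_target,
    control_of = spec$name,
    control_reminder = length(omit) > 0,
    dialyzed_fbs = isTRUE(spec$dialyzed_fbs) || length(omit) > 0,
    notes = spec$notes)
}

#' Concentrations of a serial-dilution titration
#'
#' @param start_conc starting concentration (> 0).
#' @param dilution_factor fold dilution per step (> 1).
#' @param n_steps number of dilution steps (>= 1).
#' @param include_zero append a zero (full-depletion) member.
#' @return Numeric vector `start, start/f, ..., start/f^n` (plus 0).
#' @examples
#' titration_concentrations(78, 2, 4)  # 78 ... 4.875, 0
#' @export
titration_concentrations <- function(start_conc, dilution_factor, n_steps,
                                     include_zero = TRUE) {
  check_scalar_number(start_conc, "start_conc", min = 0, strict = TRUE)
  check_scalar_number(dilution_factor, "dilution_factor", min = 1, strict = TRUE)
  if (!is_scalar_number(n_steps) || n_steps < 1 || n_steps != round(n_steps)) {
    stop_mediaforge("mediaforge_domain_error", "`n_steps` must be an integer >= 1")
  }
  conc <- start_conc / dilution_factor^(0:n_steps)
  if (include_zero) conc <- c(conc, 0)
  conc
}

#' Titration series of media over a component
#'
#' One medium variant per concentration of a serial dilution (e.g. Trp from
#' 78 uM in 2-fold steps down to 0 to find a stress-response threshold).
#'
#' @param spec base `medium_spec`.
#' @param component component to titrate (name or alias).
#' @param start_conc_um starting concentration in umol/l.
#' @inheritParams titration_concentrations
#' @param registry a `compound_registry`.
#' @return A list of `medium_spec`s, named by display concentration (2
#'   decimals).
#' @export
titration_series <- function(spec, component, start_conc_um, dilution_factor,
                             n_steps, include_zero = TRUE,
                             registry = load_registry()) {
  conc <- titration_concentrations(start_conc_um, dilution_factor, n_steps,
                                   include_zero)
  lapply(stats::setNames(conc, fmt_num(conc)), function(ci) {
    if (ci == 0) {
      make_variant(spec, omit = component, registry = registry,
                   name = sprintf("%s_%s_0uM", spec$name, component))
    } else {
      make_variant(spec, titrate = stats::setNames(ci, component),
                   registry = registry,
                   name = sprintf("%s_%s_%suM", spec$name, component, fmt_num(ci)))
    }
  })
}

#' Stock volume and weigh-in for a number of medium bottles
#'
#' Sizes a single-compound stock to supply `bottles` bottles of final medium:
#' stock volume = bottles x bottle_volume / multiplier, with the weigh-in mass
#' at the stock concentration.
#'
#' @param component compound name or alias.
#' @param bottles number of bottles (> 0).
#' @param bottle_volume_ml bottle volume in ml (> 0).
#' @param registry a `compound_registry`.
#' @return A tibble with the stock volume, concentration and mass to weigh.
#' @examples
#' bottles_to_supply("sodium chloride", 10, 500)  # 200 ml of 25x stock
#' @export
bottles_to_supply <- function(component, bottles, bottle_volume_ml,
                              registry = load_registry()) {
  check_scalar_number(bottles, "bottles", min = 0, strict = TRUE)
  check_scalar_number(bottle_volume_ml, "bottle_volume_ml", min = 0, strict = TRUE)
  row <- find_compound(registry, component)
  vol_ml <- bottles * bottle_volume_ml / row$stock_multiplier
  conc_mol_l <- if (!is.na(row$stock_conc_um)) row$stock_conc_um * 1e-6 else NA_real_
  mass_g <- if (!is.na(conc_mol_l)) {
    weigh_in_mass(conc_mol_l, vol_ml / 1e3, row$molar_mass_g_per_mol)
  } else NA_real_
  tibble::tibble(component = row$name, stock_multiplier = row$stock_multiplier,
                 stock_volume_ml = vol_ml, stock_conc_mol_l = conc_mol_l,
                 mass_g = mass_g)
}
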