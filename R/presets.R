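# Medium specifications and the preset library: complete DMEM, the Seahorse
# assay medium, nutrient-depletion media, the isotope-tracing medium and the
# six-step SILAC nascent-proteome series.

.preset_names <- c(
  "complete_dmem", "seahorse", "nam_free", "met_free", "trp_free",
  "trp_tracing", "silac_treatment_c", "silac_treatment_t",
  "silac_prelabel_c", "silac_prelabel_t", "silac_label_c", "silac_label_t"
)

# Compounds that are part of 1x complete DMEM (everything in the built-in
# registry except label compounds, the proline guard and the dialyzed-FBS row,
# which belong to specific labeling/depletion workflows).
.complete_excluded <- c("proline", "4-azido-l-homoalanine", "dialyzed fbs")

#' Preset medium names
#'
#' @return Character vector of the built-in preset names.
#' @export
preset_names <- function() .preset_names

new_medium_spec <- function(name, composition, ph_target, control_of = NULL,
                            control_reminder = FALSE, dialyzed_fbs = FALSE,
                            notes = character(0)) {
  structure(
    list(name = name, composition = composition, ph_target = ph_target,
         control_of = control_of, control_reminder = control_reminder,
         dialyzed_fbs = dialyzed_fbs, notes = notes),
    class = "medium_spec"
  )
}

#' @export
print.medium_spec <- function(x, ...) {
  n_active <- sum(x$composition$final_conc_um > 0 |
                    x$composition$final_amount > 0, na.rm = TRUE)
  cat(sprintf("<medium_spec> %s: %d components (%d active), pH target %s\n",
              x$name, nrow(x$composition), n_active,
              paste(format(x$ph_target), collapse = "-")))
  if (!is.null(x$control_of)) {
    cat("  depletion variant of:", x$control_of, "\n")
  }
  if (x$control_reminder) {
    cat("  reminder: prepare control medium with the omitted nutrient included\n")
  }
  invisible(x)
}

# Base composition table for complete DMEM, drawn from the registry.
.base_composition <- function(registry) {
  reg <- registry[!(registry$normalized_name %in% .complete_excluded) &
                    registry$category != "label", ]
  tibble::tibble(
    component = reg$name,
    normalized_name = reg$normalized_name,
    category = reg$category,
    final_amount = reg$final_amount,
    final_amount_unit = reg$final_amount_unit,
    final_conc_um = reg$final_conc_um,
    molar_mass = reg$molar_mass_g_per_mol,
    stock_multiplier = reg$stock_multiplier,
    stock_conc_um = reg$stock_conc_um,
    post_filtration = reg$category == "supplement"
  )
}

# Set a composition row's final amount to zero (component stays listed).
.zero_component <- function(comp, normalized) {
  i <- which(comp$normalized_name == normalized)
  if (!length(i)) {
    stop_mediaforge("mediaforge_lookup_error",
                    sprintf("component '%s' not in specification", normalized))
  }
  comp$final_amount[i] <- 0
  comp$final_conc_um[i] <- ifelse(is.na(comp$final_conc_um[i]), NA, 0)
  comp
}

# Append a registry compound (e.g. a label) at its registry amount, or at an
# explicit molar concentration.
.add_component <- function(comp, registry, name, conc_um = NULL) {
  row <- find_compound(registry, name)
  conc <- if (is.null(conc_um)) row$final_conc_um else conc_um
  amount <- if (is.null(conc_um)) row$final_amount else conc_um
  unit <- if (is.null(conc_um)) row$final_amount_unit else "umol/l"
  tibble::add_row(
    comp,
    component = row$name, normalized_name = row$normalized_name,
    category = row$category, final_amount = amount, final_amount_unit = unit,
    final_conc_um = conc, molar_mass = row$molar_mass_g_per_mol,
    stock_multiplier = row$stock_multiplier, stock_conc_um = row$stock_conc_um,
    post_filtration = FALSE
  )
}

#' Load a preset medium specification
#'
#' The presets mirror the media used around a custom-DMEM workflow:
#' \describe{
#'   \item{complete_dmem}{full high-glucose DMEM, pH target 8.1-8.2 before
#'     filtration; FBS, glutamine, pyruvate and pen-strep as post-filtration
#'     supplements.}
#'   \item{seahorse}{complete DMEM minus glucose, sodium bicarbonate,
#'     glutamine, pyruvate, pen-strep and FBS (they would buffer or feed the
#'     assay); pH target 7.4, with an NaOH-correction note since the medium is
#'     unbuffered.}
#'   \item{nam_free, met_free, trp_free}{depletion media: the nutrient at 0,
#'     dialyzed FBS, and a reminder to prepare the matched control medium.}
#'   \item{trp_tracing}{Trp substituted by Trp-13C11,15N2 at the same molar
#'     concentration.}
#'   \item{silac_treatment_c/t}{all amino acids unlabeled, with (C) or without
#'     (T) Trp.}
#'   \item{silac_prelabel_c/t}{Met, Arg and Lys omitted to deplete the
#'     unlabeled pools, with/without Trp.}
#'   \item{silac_label_c/t}{Met replaced by 100 uM AHA; Arg/Lys replaced by the
#'     intermediate (Arg-13C6, Lys-D4) or heavy (Arg-13C6,15N4, Lys-13C6,15N2)
#'     SILAC pair; proline 0.2 g/l as Arg-to-Pro conversion guard; with (C) or
#'     without (T) Trp.}
#' }
#'
#' @param name one of [preset_names()].
#' @param registry a `compound_registry` (built-in by default).
#' @return A `medium_spec`.
#' @examples
#' spec <- load_preset("trp_free")
#' diff_specs(spec, load_preset("complete_dmem"))
#' @export
load_preset <- function(name, registry = load_registry()) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .preset_names)) {
    stop_mediaforge("mediaforge_lookup_error",
                    paste0("unknown preset '", paste(name, collapse = ","),
                           "'; available: ", paste(.preset_names, collapse = ", ")))
  }
  comp <- .base_composition(registry)
  ph_std <- c(8.1, 8.2)
  spec <- switch(
    name,
    complete_dmem = new_medium_spec("complete_dmem", comp, ph_std),
    seahorse = {
      for (cmp in c("glucose", "sodium bicarbonate", "glutamine",
                    "sodium pyruvate", "penicillin-streptomycin", "fbs")) {
        comp <- .zero_component(comp, cmp)
      }
      new_medium_spec(
        "seahorse", comp, c(7.4, 7.4),
        notes = paste("unbuffered: pH may drift; adjust with HCl and, if",
                      "needed, correct with 1 M NaOH; re-check pH 7.4 at 37 C.",
                      "Supplement glucose, pyruvate and glutamine immediately",
                      "before the assay as the experiment requires."))
    },
    nam_free = new_medium_spec(
      "nam_free", .zero_component(comp, "nicotinamide"), ph_std,
      control_of = "complete_dmem", control_reminder = TRUE,
      dialyzed_fbs = TRUE),
    met_free = new_medium_spec(
      "met_free", .zero_component(comp, "methionine"), ph_std,
      control_of = "complete_dmem", control_reminder = TRUE,
      dialyzed_fbs = TRUE),
    trp_free = new_medium_spec(
      "trp_free", .zero_component(comp, "tryptophan"), ph_std,
      control_of = "complete_dmem", control_reminder = TRUE,
      dialyzed_fbs = TRUE),
    trp_tracing = {
      trp_um <- comp$final_conc_um[comp$normalized_name == "tryptophan"]
      comp <- .zero_component(comp, "tryptophan")
      comp <- .add_component(comp, registry, "Trp-13C11-15N2", conc_um = trp_um)
      new_medium_spec("trp_tracing", comp, ph_std,
                      control_of = "complete_dmem", dialyzed_fbs = TRUE,
                      notes = "labeled Trp may also be added after pH adjustment")
    },
    silac_treatment_c = new_medium_spec(
      "silac_treatment_c", comp, ph_std, dialyzed_fbs = TRUE),
    silac_treatment_t = new_medium_spec(
      "silac_treatment_t", .zero_component(comp, "tryptophan"), ph_std,
      control_of = "silac_treatment_c", control_reminder = TRUE,
      dialyzed_fbs = TRUE),
    silac_prelabel_c = {
      for (cmp in c("methionine", "arginine hydrochloride",
                    "lysine monohydrochloride")) comp <- .zero_component(comp, cmp)
      new_medium_spec("silac_prelabel_c", comp, ph_std, dialyzed_fbs = TRUE)
    },
    silac_prelabel_t = {
      for (cmp in c("methionine", "arginine hydrochloride",
                    "lysine monohydrochloride", "tryptophan")) {
        comp <- .zero_component(comp, cmp)
      }
      new_medium_spec("silac_prelabel_t", comp, ph_std,
                      control_of = "silac_prelabel_c", control_reminder = TRUE,
                      dialyzed_fbs = TRUE)
    },
    silac_label_c = ,
    silac_label_t = {
      heavy <- name == "silac_label_t"
      arg_um <- comp$final_conc_um[comp$normalized_name == "arginine hydrochloride"]
      lys_um <- comp$final_conc_um[comp$normalized_name == "lysine monohydrochloride"]
      for (cmp in c("methionine", "arginine hydrochloride",
                    "lysine monohydrochloride")) comp <- .zero_component(comp, cmp)
      if (heavy) comp <- .zero_component(comp, "tryptophan")
      comp <- .add_component(comp, registry, "AHA")
      comp <- .add_component(comp, registry,
                             if (heavy) "Arg-13C6-15N4" else "Arg-13C6",
                             conc_um = arg_um)
      comp <- .add_component(comp, registry,
                             if (heavy) "Lys-13C6-15N2" else "Lys-D4",
                             conc_um = lys_um)
      comp <- .add_component(comp, registry, "L-proline")
      new_medium_spec(
        name, comp, ph_std,
        control_of = if (heavy) "silac_label_c" else NULL,
        control_reminder = heavy, dialyzed_fbs = TRUE,
        notes = "pulse-labeling medium; AHA is light-sensitive and cytotoxic on prolonged exposure")
    }
  )
  spec
}

# Comparable per-component amount: molar where available, else the raw amount
# (percent supplements compare on their percent value).
.comparable_amount <- function(comp) {
  ifelse(!is.na(comp$final_conc_um), comp$final_conc_um, comp$final_amount)
}

#' Differences between two medium specifications
#'
#' Symmetric difference of (component, final amount) pairs: a row for every
#' component whose final amount differs (absent counts as 0). Empty iff the
#' media are identical - the check the control-medium discipline relies on.
#'
#' @param a,b `medium_spec`s resolved against the same registry.
#' @param tol numeric tolerance on amounts.
#' @return A tibble with columns `component`, `amount_a`, `amount_b`, `unit`.
#' @export
diff_specs <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "medium_spec"), inherits(b, "medium_spec"))
  amt <- function(spec) {
    tibble::tibble(component = spec$composition$component,
                   normalized_name = spec$composition$normalized_name,
                   amount = .comparable_amount(spec$composition),
                   unit = ifelse(!is.na(spec$composition$final_conc_um),
                                 "umol/l", spec$composition$final_amount_unit))
  }
  da <- amt(a)
  db <- amt(b)
  keys <- union(da$normalized_name, db$normalized_name)
  ia <- match(keys, da$normalized_name)
  ib <- match(keys, db$normalized_name)
  amount_a <- ifelse(is.na(ia), 0, da$amount[ia])
  amount_b <- ifelse(is.na(ib), 0, db$amount[ib])
  amount_a[is.na(amount_a)] <- 0
  amount_b[is.na(amount_b)] <- 0
  differs <- abs(amount_a - amount_b) > tol
  tibble::tibble(
    component = ifelse(is.na(ia), db$component[ib], da$component[ia]),
    amount_a = amount_a, amount_b = amount_b,
    unit = ifelse(is.na(ia), db$unit[ib], da$unit[ia])
  )[differs, ]
}
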