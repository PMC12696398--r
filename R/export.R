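# Checklist serialization: Markdown for the bench, JSON for machines, CSV one
# row per addition. Field order is deterministic so machine output is
# hash-stable.

plan_to_list <- function(plan) {
  stopifnot(inherits(plan, "assembly_plan"))
  list(
    medium = plan$spec$name,
    final_volume_ml = plan$final_volume_ml,
    water_ml = plan$water_ml,
    ph_target = plan$ph_target,
    acid = plan$acid,
    additions = lapply(seq_len(nrow(plan$additions)), function(i) {
      list(section = plan$additions$section[i],
           addition = plan$additions$addition[i],
           volume_ml = plan$additions$volume_ml[i])
    }),
    supplements = lapply(seq_len(nrow(plan$supplements)), function(i) {
      list(name = plan$supplements$name[i],
           final_amount = plan$supplements$final_amount[i],
           final_amount_unit = plan$supplements$final_amount_unit[i],
           volume_ml = plan$supplements$volume_ml[i])
    }),
    control_reminder = plan$control_reminder,
    notes = if (length(plan$notes)) paste(plan$notes, collapse = " ") else ""
  )
}

#' Export an assembly plan
#'
#' Markdown renders the checklist in the five fixed sections (initial water,
#' inorganic salts, salts and vitamins, amino acids, additional components)
#' with tick boxes, the pH record and the post-filtration supplement
#' checklist. JSON carries full numeric precision with deterministic field
#' order; CSV has one row per addition plus the water line.
#'
#' @param plan an `assembly_plan` from [assemble_medium()].
#' @param format `"markdown"`, `"json"` or `"csv"`.
#' @param path optional file to write; the serialized text is always returned.
#' @return The serialized document as a character scalar, invisibly when
#'   `path` is given.
#' @export
export_plan <- function(plan, format = c("markdown", "json", "csv"),
                        path = NULL) {
  if (length(format) != 1L && !identical(format, c("markdown", "json", "csv"))) {
    format <- format[1]
  }
  if (!(format[1] %in% c("markdown", "json", "csv"))) {
    stop_mediaforge("mediaforge_usage_error",
                    sprintf("unknown export format '%s'", format[1]))
  }
  format <- match.arg(format)
  out <- switch(format,
    markdown = .plan_markdown(plan),
    json = as.character(jsonlite::toJSON(plan_to_list(plan),
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)),
    csv = .plan_csv(plan))
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

.plan_markdown <- function(plan) {
  lines <- c(
    sprintf("# %s - %s ml", plan$spec$name, fmt_num(plan$final_volume_ml)),
    "",
    "## initial water",
    sprintf("- [ ] %s ml cell culture-grade water", fmt_num(plan$water_ml)))
  for (sec in setdiff(.sections, "initial water")) {
    rows <- plan$additions[plan$additions$section == sec, ]
    lines <- c(lines, "", paste("##", sec))
    if (nrow(rows) == 0) {
      lines <- c(lines, "- (none)")
    } else {
      lines <- c(lines, sprintf("- [ ] %s ml %s", fmt_num(rows$volume_ml),
                                rows$addition))
    }
  }
  ph <- if (plan$ph_target[1] == plan$ph_target[length(plan$ph_target)]) {
    fmt_num(plan$ph_target[1], 1)
  } else {
    paste(fmt_num(plan$ph_target, 1), collapse = "-")
  }
  lines <- c(lines, "", "## pH record",
             sprintf("- start pH: ____  target: %s  adjusted with: %s", ph,
                     plan$acid),
             "- sterile-filter after pH adjustment",
             "", "## post-filtration supplements (immediately before use)")
  if (nrow(plan$supplements) == 0) {
    lines <- c(lines, "- (none)")
  } else {
    lines <- c(lines, sprintf("- [ ] %s ml %s (%g %s final)",
                              fmt_num(plan$supplements$volume_ml),
                              plan$supplements$name,
                              plan$supplements$final_amount,
                              plan$supplements$final_amount_unit))
  }
  if (plan$control_reminder) {
    lines <- c(lines, "",
               "> Reminder: prepare the control medium with the omitted nutrient included (use dialyzed FBS for both).")
  }
  if (length(plan$notes) && any(nzchar(plan$notes))) {
    lines <- c(lines, "", paste(">", plan$notes))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

.plan_csv <- function(plan) {
  df <- data.frame(section = c(plan$additions$section, "initial water"),
                   addition = c(plan$additions$addition, "water"),
                   volume_ml = c(plan$additions$volume_ml, plan$water_ml),
                   stringsAsFactors = FALSE)
  lines <- c("section,addition,volume_ml",
             sprintf("%s,%s,%s", df$section, df$addition,
                     format(df$volume_ml, trim = TRUE, scientific = FALSE)))
  paste0(paste(lines, collapse = "\n"), "\n")
}
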