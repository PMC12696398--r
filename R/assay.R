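# Assay computations used alongside custom media: sulforhodamine-B (SRB)
# doubling analysis and Seahorse mito-stress OCR metrics, plus seeded
# simulators so both are testable without a plate reader or flux analyzer.

#' Build an OD time course for SRB doubling analysis
#'
#' @param days integer day indices per reading (day 0 = baseline, required).
#' @param od optical densities (>= 0), one per reading.
#' @param condition optional condition label.
#' @return An `od_timecourse` tibble with columns `day` and `od`.
#' @export
od_timecourse <- function(days, od, condition = NULL) {
  stopifnot(length(days) == length(od))
  if (any(od < 0, na.rm = TRUE)) {
    stop_mediaforge("mediaforge_domain_error", "OD readings must be >= 0")
  }
  if (!any(days == 0)) {
    stop_mediaforge("mediaforge_input_error",
                    "day 0 (baseline) readings are required")
  }
  tc <- tibble::tibble(day = as.integer(days), od = as.numeric(od))
  attr(tc, "condition") <- condition
  class(tc) <- c("od_timecourse", class(tc))
  tc
}

#' SRB proliferation summary: mean OD, fold change and log2 fold change
#'
#' Per day: the replicate mean OD, its ratio to the day-0 mean (normalized
#' fold change) and the log2 of that ratio; day 0 is 0 on the log2 scale by
#' construction.
#'
#' @param tc an `od_timecourse` (or a data frame with `day` and `od`).
#' @return A tibble with columns `day`, `n`, `mean_od`, `fold_change`,
#'   `log2_fc`.
#' @examples
#' tc <- od_timecourse(c(0, 0, 0, 3, 3, 3), c(0.10, 0.11, 0.09, 0.8, 0.8, 0.8))
#' srb_summary(tc)
#' @export
srb_summary <- function(tc) {
  if (!inherits(tc, "od_timecourse")) {
    tc <- od_timecourse(tc$day, tc$od)
  }
  days <- sort(unique(tc$day))
  mean_od <- vapply(days, function(d) mean(tc$od[tc$day == d]), numeric(1))
  n <- vapply(days, function(d) sum(tc$day == d), integer(1))
  od0 <- mean_od[days == 0]
  if (od0 <= 0) {
    stop_mediaforge("mediaforge_domain_error",
                    "day-0 mean OD must be > 0 to normalize fold changes")
  }
  fold <- mean_od / od0
  tibble::tibble(day = days, n = n, mean_od = mean_od, fold_change = fold,
                 log2_fc = log2(fold))
}

#' Simulate an SRB OD time course with known doubling time
#'
#' Exponential growth `OD = od0 * 2^(day / doubling_time)` with multiplicative
#' log-normal replicate noise, seeded for reproducibility. The ground truth is
#' attached for recovery tests.
#'
#' @param doubling_time_days doubling time in days (> 0).
#' @param days day indices measured (default 0:7, daily reads over a week).
#' @param replicates technical replicates per day (default 3).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param seed integer seed.
#' @param od0 baseline OD (default 0.1).
#' @return An `od_timecourse` with attribute `truth`.
#' @export
simulate_od_timecourse <- function(doubling_time_days, days = 0:7,
                                   replicates = 3, noise_cv = 0.05, seed,
                                   od0 = 0.1) {
  check_scalar_number(doubling_time_days, "doubling_time_days", min = 0,
                      strict = TRUE)
  check_scalar_number(noise_cv, "noise_cv", min = 0)
  set.seed(as.integer(seed))
  day <- rep(days, each = replicates)
  mu <- od0 * 2^(day / doubling_time_days)
  od <- mu * exp(stats::rnorm(length(day), mean = 0, sd = noise_cv))
  tc <- od_timecourse(day, od)
  attr(tc, "truth") <- list(doubling_time_days = doubling_time_days, od0 = od0,
                            noise_cv = noise_cv)
  tc
}

.phases <- c("basal", "oligomycin", "fccp", "rot_aa")

#' Build an OCR trace from long-format data
#'
#' @param data a data frame with columns `well`, `time_min`, `ocr`, `phase`;
#'   phases must appear in the fixed mito-stress order basal, oligomycin,
#'   fccp, rot_aa, non-overlapping in time.
#' @param blank_wells well IDs of the medium-only background wells (default
#'   the four corners A1, A12, H1, H12).
#' @param normalizers optional named numeric vector (per-well protein or cell
#'   count) for normalization.
#' @return An `ocr_trace` tibble.
#' @export
ocr_trace <- function(data, blank_wells = c("A1", "A12", "H1", "H12"),
                      normalizers = NULL) {
  need <- c("well", "time_min", "ocr", "phase")
  if (!all(need %in% names(data))) {
    stop_mediaforge("mediaforge_input_error",
                    paste("trace needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(data$phase %in% .phases)) {
    bad <- setdiff(unique(data$phase), .phases)
    stop_mediaforge("mediaforge_input_error",
                    paste("unknown phase(s):", paste(bad, collapse = ", ")))
  }
  # phases must be ordered and non-overlapping in time
  tp <- unique(data[order(data$time_min), c("time_min", "phase")])
  idx <- match(tp$phase, .phases)
  if (is.unsorted(idx)) {
    stop_mediaforge("mediaforge_input_error",
                    "phases must be non-overlapping and in the order basal -> oligomycin -> fccp -> rot_aa")
  }
  tr <- tibble::as_tibble(data[, need])
  attr(tr, "blank_wells") <- intersect(blank_wells, unique(tr$well))
  attr(tr, "normalizers") <- normalizers
  attr(tr, "corrected") <- FALSE
  class(tr) <- c("ocr_trace", class(tr))
  tr
}

#' Read an OCR trace from a long-format CSV
#'
#' @param path CSV with header `well,time_min,ocr,phase`.
#' @inheritParams ocr_trace
#' @return An `ocr_trace`.
#' @export
read_ocr_csv <- function(path, blank_wells = c("A1", "A12", "H1", "H12"),
                         normalizers = NULL) {
  ocr_trace(utils::read.csv(path, stringsAsFactors = FALSE),
            blank_wells = blank_wells, normalizers = normalizers)
}

#' Subtract the medium-only background from an OCR trace
#'
#' The per-timepoint mean of the blank (no-cell) wells is subtracted from
#' every sample well; blanks are then dropped. Mandatory before metric
#' extraction unless explicitly disabled there.
#'
#' @param trace an `ocr_trace` with blank wells.
#' @return The corrected `ocr_trace` (blanks removed).
#' @export
background_correct <- function(trace) {
  stopifnot(inherits(trace, "ocr_trace"))
  blanks <- attr(trace, "blank_wells")
  if (!length(blanks)) {
    stop_mediaforge("mediaforge_config_error",
                    "no blank wells in trace; background correction requires medium-only wells (default A1, A12, H1, H12)")
  }
  is_blank <- trace$well %in% blanks
  bg <- tapply(trace$ocr[is_blank], trace$time_min[is_blank], mean)
  out <- trace[!is_blank, ]
  out$ocr <- out$ocr - as.numeric(bg[as.character(out$time_min)])
  attr(out, "blank_wells") <- character(0)
  attr(out, "normalizers") <- attr(trace, "normalizers")
  attr(out, "corrected") <- TRUE
  class(out) <- class(trace)
  out
}

#' Mito-stress metrics from an OCR trace
#'
#' Point estimates use the OCR at the final measurement of each phase (when
#' the inhibitor effect has stabilized); `estimator = "phase_mean"` averages
#' within each phase instead. Definitions: basal = end of basal phase;
#' ATP-linked = basal - post-oligomycin; maximal = end of FCCP phase; spare =
#' maximal - basal; non-mitochondrial = end of rotenone/antimycin-A phase;
#' average OCR = mean over all timepoints. Basal is reported without
#' subtracting the non-mitochondrial rate (`correct_basal = TRUE` subtracts
#' it). With per-well normalizers all metrics are divided by them.
#'
#' @param trace a background-corrected `ocr_trace` containing all four phases
#'   (set `require_correction = FALSE` to skip the check for pre-corrected
#'   data).
#' @param estimator `"final"` (default) or `"phase_mean"`.
#' @param correct_basal subtract non-mitochondrial OCR from basal/maximal
#'   (default FALSE).
#' @param require_correction insist the trace went through
#'   [background_correct()] (default TRUE).
#' @return A tibble with one row per well: `basal`, `atp_linked`, `maximal`,
#'   `spare`, `non_mito`, `average_ocr`, and `spare_negative` flagging wells
#'   whose maximal respiration fell below basal.
#' @examples
#' tr <- simulate_ocr(c(100, 40, 180, 10), noise_sd = 0, seed = 1)
#' mito_stress_metrics(background_correct(tr))
#' @export
mito_stress_metrics <- function(trace, estimator = c("final", "phase_mean"),
                                correct_basal = FALSE,
                                require_correction = TRUE) {
  stopifnot(inherits(trace, "ocr_trace"))
  estimator <- match.arg(estimator)
  if (require_correction && !isTRUE(attr(trace, "corrected"))) {
    stop_mediaforge("mediaforge_config_error",
                    "trace is not background-corrected; run background_correct() first or set require_correction = FALSE")
  }
  missing_phases <- setdiff(.phases, unique(trace$phase))
  if (length(missing_phases)) {
    stop_mediaforge("mediaforge_input_error",
                    paste("trace lacks phase(s):",
                          paste(missing_phases, collapse = ", ")))
  }
  normalizers <- attr(trace, "normalizers")
  wells <- unique(trace$well)
  one <- function(w) {
    d <- trace[trace$well == w, ]
    d <- d[order(d$time_min), ]
    est <- vapply(.phases, function(p) {
      v <- d$ocr[d$phase == p]
      if (estimator == "final") v[length(v)] else mean(v)
    }, numeric(1))
    basal <- est[["basal"]]
    non_mito <- est[["rot_aa"]]
    maximal <- est[["fccp"]]
    if (correct_basal) {
      basal <- basal - non_mito
      maximal <- maximal - non_mito
    }
    c(basal = basal,
      atp_linked = est[["basal"]] - est[["oligomycin"]],
      maximal = maximal,
      spare = maximal - basal,
      non_mito = non_mito,
      average_ocr = mean(d$ocr))
  }
  m <- t(vapply(wells, one, numeric(6)))
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, well = wells, .before = 1)
  if (!is.null(normalizers)) {
    nz <- unname(normalizers[out$well])
    if (anyNA(nz) || any(nz == 0)) {
      stop_mediaforge("mediaforge_domain_error",
                      "normalizers must cover every well and be non-zero")
    }
    for (col in c("basal", "atp_linked", "maximal", "spare", "non_mito",
                  "average_ocr")) {
      out[[col]] <- out[[col]] / nz
    }
  }
  out$spare_negative <- out$spare < 0
  if (any(out$spare_negative)) {
    warning("maximal OCR below basal in well(s): ",
            paste(out$well[out$spare_negative], collapse = ", "),
            "; spare respiratory capacity is negative", call. = FALSE)
  }
  out
}

#' Simulate a mito-stress OCR trace with known phase plateaus
#'
#' Generates a reproducible trace with the instrument's cycle structure
#' (mix/wait/measure, one measurement per 15-min cycle, default 3 cycles per
#' phase), per-phase plateau levels with an optional first-order relaxation
#' after each injection, Gaussian noise, and constant-level blank wells. The
#' ground-truth parameters are attached for recovery tests.
#'
#' @param plateaus numeric length 4: basal, post-oligomycin, FCCP (maximal)
#'   and rotenone/antimycin-A plateau OCR levels (>= 0).
#' @param cycles_per_phase measurement cycles per phase (default 3).
#' @param interval_min minutes per mix/wait/measure cycle (default 15).
#' @param noise_sd Gaussian noise SD in OCR units (>= 0).
#' @param seed integer seed.
#' @param n_wells number of sample wells (default 3).
#' @param blank_wells blank well IDs (default A1, A12, H1, H12).
#' @param blank_level constant OCR of blank wells (default 5).
#' @param tau_min first-order relaxation time constant after each injection in
#'   minutes; 0 (default) settles instantly at the first measurement.
#' @return An `ocr_trace` with attribute `truth`.
#' @export
simulate_ocr <- function(plateaus, cycles_per_phase = 3, interval_min = 15,
                         noise_sd = 0, seed, n_wells = 3,
                         blank_wells = c("A1", "A12", "H1", "H12"),
                         blank_level = 5, tau_min = 0) {
  stopifnot(length(plateaus) == 4)
  if (any(plateaus < 0)) {
    stop_mediaforge("mediaforge_domain_error", "plateau levels must be >= 0")
  }
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(tau_min, "tau_min", min = 0)
  set.seed(as.integer(seed))
  n_tp <- 4 * cycles_per_phase
  time_min <- seq_len(n_tp) * interval_min
  phase <- rep(.phases, each = cycles_per_phase)
  # clean per-timepoint profile: plateau, relaxing from the previous one
  profile <- numeric(n_tp)
  prev <- plateaus[1]
  for (p in seq_along(.phases)) {
    idx <- which(phase == .phases[p])
    within <- seq_along(idx) * interval_min
    decay <- if (tau_min > 0) exp(-within / tau_min) else 0
    profile[idx] <- plateaus[p] + (prev - plateaus[p]) * decay
    prev <- profile[idx[length(idx)]]
  }
  sample_wells <- sprintf("B%02d", seq_len(n_wells))
  wells <- c(sample_wells, blank_wells)
  df <- expand.grid(well = wells, i = seq_len(n_tp), stringsAsFactors = FALSE)
  df$time_min <- time_min[df$i]
  df$phase <- phase[df$i]
  is_blank <- df$well %in% blank_wells
  clean <- ifelse(is_blank, blank_level, profile[df$i] + blank_level)
  df$ocr <- clean + stats::rnorm(nrow(df), 0, noise_sd)
  tr <- ocr_trace(df[, c("well", "time_min", "ocr", "phase")],
                  blank_wells = blank_wells)
  attr(tr, "truth") <- list(plateaus = stats::setNames(plateaus, .phases),
                            blank_level = blank_level, noise_sd = noise_sd,
                            tau_min = tau_min)
  tr
}
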