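test_that("SRB summary computes replicate means, fold and log2 fold changes", {
  tc <- od_timecourse(c(0, 0, 0, 3, 3, 3),
                      c(0.10, 0.11, 0.09, 0.80, 0.80, 0.80))
  s <- srb_summary(tc)
  expect_equal(s$mean_od[s$day == 0], 0.10)
  expect_equal(s$fold_change[s$day == 3], 8)
  expect_equal(s$log2_fc[s$day == 3], 3)
  expect_equal(s$log2_fc[s$day == 0], 0)
  # day-0 only: log2 FC is zero by construction
  s0 <- srb_summary(od_timecourse(c(0, 0), c(0.2, 0.2)))
  expect_equal(s0$log2_fc, 0)
  expect_error(od_timecourse(c(1, 2), c(0.1, 0.2)),
               class = "mediaforge_input_error")
  expect_error(srb_summary(od_timecourse(c(0, 3), c(0, 0.5))),
               class = "mediaforge_domain_error")
})

test_that("SRB log2 fold change is invariant to uniform OD scaling", {
  set.seed(12)
  for (i in 1:10) {
    day <- rep(0:5, each = 3)
    od <- stats::runif(length(day), 0.05, 2)
    k <- stats::runif(1, 0.1, 50)
    s1 <- srb_summary(od_timecourse(day, od))
    s2 <- srb_summary(od_timecourse(day, k * od))
    expect_equal(s2$log2_fc, s1$log2_fc)
  }
})

test_that("the OD simulator is seeded and recovers its own doubling time", {
  a <- simulate_od_timecourse(1.5, seed = 99)
  b <- simulate_od_timecourse(1.5, seed = 99)
  expect_identical(a, b)
  # noiseless: log2 FC at day 3 with 1 d doubling is exactly 3
  clean <- simulate_od_timecourse(1, days = c(0, 3), noise_cv = 0, seed = 1)
  expect_equal(srb_summary(clean)$log2_fc[2], 3)
  # 5% CV, 6 replicates: regression slope recovers 1/doubling_time
  sim <- simulate_od_timecourse(1.5, days = 0:6, replicates = 6,
                                noise_cv = 0.05, seed = 7)
  s <- srb_summary(sim)
  fit <- stats::lm(log2_fc ~ day, data = s)
  est <- summary(fit)$coefficients["day", ]
  expect_lt(abs(est["Estimate"] - 1 / 1.5), 2 * est["Std. Error"] + 0.02)
  expect_error(simulate_od_timecourse(0, seed = 1),
               class = "mediaforge_domain_error")
})

test_that("trace construction enforces phase order and column contract", {
  expect_error(ocr_trace(data.frame(well = "B01", time_min = 1, ocr = 1)),
               class = "mediaforge_input_error")
  bad_phase <- data.frame(well = "B01", time_min = 1:2, ocr = c(1, 2),
                          phase = c("basal", "glycolysis"))
  expect_error(ocr_trace(bad_phase), class = "mediaforge_input_error")
  out_of_order <- data.frame(well = "B01", time_min = 1:4, ocr = 1,
                             phase = c("basal", "fccp", "oligomycin", "rot_aa"))
  expect_error(ocr_trace(out_of_order), class = "mediaforge_input_error")
})

test_that("background correction subtracts the blank mean and drops blanks", {
  tr <- simulate_ocr(c(100, 40, 180, 10), noise_sd = 0, seed = 1,
                     blank_level = 5)
  corrected <- background_correct(tr)
  expect_false(any(corrected$well %in% c("A1", "A12", "H1", "H12")))
  # blanks were constant 5: every sample OCR dropped by exactly 5
  raw_sample <- tr[tr$well == "B01", ]
  expect_equal(corrected$ocr[corrected$well == "B01"], raw_sample$ocr - 5)
  # a well identical to the blanks corrects to zero
  df <- as.data.frame(tr)
  df$ocr[df$well == "B01"] <- 5
  zeroed <- background_correct(ocr_trace(df))
  expect_equal(zeroed$ocr[zeroed$well == "B01"], rep(0, 12))
  # no blanks at all: configuration error (correction is mandatory)
  no_blanks <- ocr_trace(df[!(df$well %in% c("A1", "A12", "H1", "H12")), ],
                         blank_wells = character(0))
  expect_error(background_correct(no_blanks),
               class = "mediaforge_config_error")
})

test_that("mito-stress metrics implement the definitional arithmetic", {
  tr <- background_correct(simulate_ocr(c(100, 40, 180, 10), noise_sd = 0,
                                        seed = 1))
  m <- mito_stress_metrics(tr)
  expect_equal(unique(m$basal), 100)
  expect_equal(unique(m$atp_linked), 60)
  expect_equal(unique(m$maximal), 180)
  expect_equal(unique(m$spare), 80)
  expect_equal(unique(m$non_mito), 10)
  expect_equal(unique(m$average_ocr), mean(c(100, 40, 180, 10)))
  # flat trace: spare and ATP-linked are zero
  flat <- background_correct(simulate_ocr(rep(55, 4), noise_sd = 0, seed = 2))
  mf <- mito_stress_metrics(flat)
  expect_equal(unique(mf$spare), 0)
  expect_equal(unique(mf$atp_linked), 0)
  # maximal below basal flags negative spare with a warning
  inverted <- background_correct(simulate_ocr(c(100, 40, 80, 10),
                                              noise_sd = 0, seed = 3))
  expect_warning(mi <- mito_stress_metrics(inverted), "spare")
  expect_true(all(mi$spare_negative))
  # uncorrected traces are refused unless explicitly allowed
  raw <- simulate_ocr(c(100, 40, 180, 10), noise_sd = 0, seed = 4)
  expect_error(mito_stress_metrics(raw), class = "mediaforge_config_error")
  # missing phase is named
  partial <- raw[raw$phase != "fccp", ]
  attr(partial, "corrected") <- TRUE
  class(partial) <- class(raw)
  err <- expect_error(mito_stress_metrics(partial),
                      class = "mediaforge_input_error")
  expect_match(conditionMessage(err), "fccp")
})

test_that("spare and ATP-linked identities hold on random noisy traces", {
  set.seed(13)
  for (i in 1:10) {
    tr <- simulate_ocr(stats::runif(4, 5, 200), noise_sd = stats::runif(1, 0, 10),
                       seed = sample.int(1e6, 1))
    corr <- background_correct(tr)
    m <- suppressWarnings(mito_stress_metrics(corr))
    for (w in unique(m$well)) {
      expect_equal(m$spare[m$well == w],
                   m$maximal[m$well == w] - m$basal[m$well == w])
      dd <- corr[corr$well == w, ]
      dd <- dd[order(dd$time_min), ]
      last <- function(p) { v <- dd$ocr[dd$phase == p]; v[length(v)] }
      expect_equal(m$atp_linked[m$well == w], last("basal") - last("oligomycin"))
      expect_equal(m$basal[m$well == w], last("basal"))
    }
  }
})

test_that("normalization divides every metric and rejects zero normalizers", {
  tr <- background_correct(simulate_ocr(c(100, 40, 180, 10), noise_sd = 0,
                                        seed = 5, n_wells = 2))
  plain <- mito_stress_metrics(tr)
  attr(tr, "normalizers") <- c(B01 = 2, B02 = 4)
  norm <- mito_stress_metrics(tr)
  expect_equal(norm$basal, plain$basal / c(2, 4))
  expect_equal(norm$average_ocr, plain$average_ocr / c(2, 4))
  attr(tr, "normalizers") <- c(B01 = 0, B02 = 4)
  expect_error(mito_stress_metrics(tr), class = "mediaforge_domain_error")
})

test_that("the OCR simulator is deterministic and exactly recoverable at zero noise", {
  a <- simulate_ocr(c(90, 30, 160, 8), noise_sd = 3, seed = 123)
  b <- simulate_ocr(c(90, 30, 160, 8), noise_sd = 3, seed = 123)
  expect_identical(a, b)
  clean <- simulate_ocr(c(90, 30, 160, 8), noise_sd = 0, seed = 1)
  m <- mito_stress_metrics(background_correct(clean))
  expect_equal(unique(m$basal), 90)
  expect_equal(unique(m$maximal), 160)
  expect_equal(unique(m$non_mito), 8)
  expect_error(simulate_ocr(c(90, 30, 160, 8), noise_sd = -1, seed = 1),
               class = "mediaforge_domain_error")
  expect_error(simulate_ocr(c(-5, 30, 160, 8), noise_sd = 0, seed = 1),
               class = "mediaforge_domain_error")
})
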