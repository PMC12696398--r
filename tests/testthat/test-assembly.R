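reg <- load_registry()
complete <- load_preset("complete_dmem", reg)

test_that("master-stock plans compute component volumes and water back-fill", {
  aa <- master_stock_plan("amino_acids", 100, reg)
  expect_equal(sum(aa$components$source_multiplier == 1000), 6)  # well-soluble set
  expect_equal(sum(aa$components$source_multiplier == 100), 8)
  expect_equal(aa$components$volume_ml[aa$components$source_multiplier == 1000],
               rep(1, 6))
  expect_equal(aa$components$volume_ml[aa$components$source_multiplier == 100],
               rep(10, 8))
  expect_equal(aa$water_ml, 14)
  # two 200x salts combined 1:2 into a 100x: half volume each, no water
  for (v in c(10, 37, 250)) {
    inorg <- master_stock_plan("inorganic_salts", v, reg)
    expect_equal(inorg$components$volume_ml, rep(v / 2, 2))
    expect_equal(inorg$water_ml, 0)
  }
})

test_that("impossible dilutions and over-committed volumes are rejected", {
  comps <- data.frame(name = "x", source_multiplier = 100)
  err <- expect_error(plan_master_stock(comps, 1000, 50),
                      class = "mediaforge_infeasible_plan")
  expect_match(conditionMessage(err), "x")
  over <- data.frame(name = c("a", "b", "c"), source_multiplier = c(2, 2, 2))
  expect_error(plan_master_stock(over, 1, 10),
               class = "mediaforge_overcommitted_volume")
})

test_that("complete-DMEM assembly back-fills 385 ml of water per 500 ml", {
  plan <- assemble_medium(complete, 500, reg)
  expect_equal(plan$water_ml, 385)
  expect_equal(assemble_medium(complete, 1000, reg)$water_ml, 770)
  # section order is fixed
  expect_identical(unique(plan$additions$section),
                   c("inorganic salts", "salts and vitamins", "amino acids",
                     "additional components"))
  # masters are used when the composition is standard
  expect_true("10x amino acid master stock" %in% plan$additions$addition)
})

test_that("volume conservation and scaling linearity hold on fuzzed recipes", {
  set.seed(11)
  omittable <- c("Trp", "Met", "NAM", "glycine", "L-valine", "riboflavin",
                 "sodium chloride", "D-glucose", "L-serine", "potassium chloride")
  for (i in 1:15) {
    spec <- make_variant(complete,
                         omit = sample(omittable, sample(0:3, 1)),
                         registry = reg)
    v <- stats::runif(1, 50, 2000)
    plan <- assemble_medium(spec, v, reg)
    expect_equal(sum(plan$additions$volume_ml) + plan$water_ml, v,
                 tolerance = 1e-3 / v)
    k <- stats::runif(1, 0.2, 5)
    plan_k <- assemble_medium(spec, k * v, reg)
    expect_equal(plan_k$additions$volume_ml, k * plan$additions$volume_ml)
    expect_equal(plan_k$water_ml, k * plan$water_ml)
  }
})

test_that("omission variants fall back to individual stocks and diff exactly", {
  trp_free <- make_variant(complete, omit = "Trp", registry = reg)
  d <- diff_specs(trp_free, complete)
  expect_identical(d$component, "L-tryptophan")
  plan <- assemble_medium(trp_free, 500, reg)
  # amino-acid master no longer usable: individual stocks appear instead
  expect_false("10x amino acid master stock" %in% plan$additions$addition)
  expect_true(any(grepl("L-valine", plan$additions$addition)))
  expect_false(any(grepl("L-tryptophan", plan$additions$addition)))
  expect_error(make_variant(complete, omit = "unobtainium", registry = reg),
               class = "mediaforge_lookup_error")
})

test_that("isotopologue replacement preserves molar amounts and volumes", {
  tracing <- make_variant(complete, replace = c(Trp = "Trp-13C11-15N2"),
                          registry = reg)
  d <- diff_specs(tracing, complete)
  expect_setequal(d$component, c("L-tryptophan", "L-tryptophan-13C11-15N2"))
  conc <- tracing$composition$final_conc_um[
    tracing$composition$normalized_name == "tryptophan-13c11-15n2"]
  expect_equal(conc, compound_molarity(reg, "Trp"))
  # against the matching omission plan (both use individual amino-acid
  # stocks), the replacement adds exactly the volume the unlabeled compound
  # would occupy from an individual stock of equal molarity
  trp_free <- make_variant(complete, omit = "Trp", registry = reg)
  p_free <- assemble_medium(trp_free, 500, reg)
  p_trace <- assemble_medium(tracing, 500, reg)
  labeled_row <- grepl("13C11", p_trace$additions$addition)
  expect_equal(p_trace$additions$volume_ml[labeled_row], 500 / 100,
               tolerance = 1e-6)
  expect_equal(p_trace$additions$volume_ml[!labeled_row],
               p_free$additions$volume_ml)
  expect_equal(p_trace$water_ml, p_free$water_ml - 500 / 100, tolerance = 1e-6)
})

test_that("titration above the stock concentration is infeasible", {
  expect_error(make_variant(complete, titrate = c(Trp = 1e7), registry = reg),
               class = "mediaforge_infeasible_plan")
  v <- make_variant(complete, titrate = c(Trp = 39), registry = reg)
  plan <- assemble_medium(v, 500, reg)
  trp_row <- grepl("tryptophan", plan$additions$addition)
  expect_equal(plan$additions$volume_ml[trp_row],
               500 * 39 / (compound_molarity(reg, "Trp") * 100))
})

test_that("titration series spans start to zero with the printed threshold step", {
  conc <- titration_concentrations(78, 2, 4, include_zero = TRUE)
  expect_equal(conc, c(78, 39, 19.5, 9.75, 4.875, 0))
  expect_equal(round_half_even(conc[5], 2), 4.88)
  expect_equal(titration_concentrations(10, 2, 1, include_zero = FALSE),
               c(10, 5))
  expect_error(titration_concentrations(78, 1, 4),
               class = "mediaforge_domain_error")
  expect_error(titration_concentrations(78, 2, 0),
               class = "mediaforge_domain_error")
  series <- titration_series(complete, "Trp", 78, 2, 4, registry = reg)
  expect_length(series, 6)
  d <- diff_specs(series[["4.88"]], complete)
  expect_identical(d$component, "L-tryptophan")
  expect_equal(d$amount_a, 4.875)
})

test_that("bottles-to-supply sizes stocks and weigh-ins", {
  out <- bottles_to_supply("sodium chloride", 10, 500, reg)
  expect_equal(out$stock_volume_ml, 200)  # 10 x 500/25
  expect_equal(out$mass_g, 6.4 * 25 * 0.2)  # 6.4 g/l at 25x in 0.2 l
  one <- bottles_to_supply("sodium chloride", 1, 500, reg)
  expect_equal(one$stock_volume_ml, 20)
  expect_error(bottles_to_supply("sodium chloride", 0, 500, reg),
               class = "mediaforge_domain_error")
})
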