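test_that("plain and isotope-annotated formulas parse to the right composition", {
  f <- parse_formula("C11H12N2O2")
  expect_equal(unclass(f)[c("C", "H", "N", "O")],
               c(C = 11L, H = 12L, N = 2L, O = 2L))
  g <- parse_formula("13C11H12 15N2O2")
  expect_equal(unclass(g)[c("13C", "H", "15N", "O")],
               c("13C" = 11L, H = 12L, "15N" = 2L, O = 2L))
  # typeset markup (sub/superscripts) parses identically
  expect_equal(parse_formula("^13^C_11_H_12_^15^N_2_O_2_"), g)
  # bracketed isotopes are valid anywhere, D aliases 2H
  expect_equal(parse_formula("[13C]11H12[15N]2O2"), g)
  expect_equal(unclass(parse_formula("CD4"))[["2H"]], 4L)
  # repeated tokens sum
  expect_equal(unclass(parse_formula("CH3CH3"))[["C"]], 2L)
})

test_that("parse errors name the offending token and position", {
  err <- expect_error(parse_formula("Xq3"), class = "mediaforge_parse_error")
  expect_match(conditionMessage(err), "Xq")
  expect_match(conditionMessage(err), "position 0")
  expect_error(parse_formula("13"), class = "mediaforge_parse_error")
  expect_error(parse_formula("C0H4"), class = "mediaforge_parse_error")
  expect_error(parse_formula(""), class = "mediaforge_parse_error")
})

test_that("monoisotopic masses match hand-checked values", {
  expect_equal(monoisotopic_mass("H2"), 2.01565, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("C11H12N2O2"), 204.08988, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C6H6N2O"), 122.04801, tolerance = 1e-6)
  expect_error(monoisotopic_mass("U3O8"),
               class = "mediaforge_unsupported_isotope")
})

test_that("protonated m/z reproduces accurate-mass library values", {
  printed <- c("C6H6N2O" = 123.05529,      # nicotinamide
               "C11H12N2O2" = 205.09715,   # tryptophan
               "13C11H12 15N2O2" = 218.12813,
               "C10H12N2O3" = 209.09207,   # kynurenine
               "13C10H12 15N2O3" = 221.11969)
  for (f in names(printed)) {
    expect_equal(mz_protonated(f), printed[[f]], tolerance = 1e-4 / printed[[f]])
  }
})

test_that("m/z minus neutral mass is exactly one proton", {
  set.seed(41)
  for (i in 1:20) {
    f <- parse_formula(random_formula_string())
    expect_equal(mz_protonated(f) - monoisotopic_mass(f),
                 isotope_masses()$proton_mass, tolerance = 1e-12)
  }
})

test_that("isotope table carries the required isotopes and mass differences", {
  tab <- isotope_masses()$entries
  required <- c("1H", "2H", "12C", "13C", "14N", "15N", "16O", "32S", "31P",
                "23Na", "35Cl", "39K")
  expect_true(all(required %in% names(tab)))
  expect_equal(tab[["13C"]] - tab[["12C"]], 1.0033548, tolerance = 1e-6)
  expect_equal(tab[["15N"]] - tab[["14N"]], 0.9970349, tolerance = 1e-6)
})

test_that("label mass shifts match printed m/z differences and identity", {
  expect_equal(label_mass_shift("C11H12N2O2", "13C11H12 15N2O2"),
               218.12813 - 205.09715, tolerance = 1e-4)
  expect_equal(label_mass_shift("C10H12N2O3", "13C10H12 15N2O3"),
               221.11969 - 209.09207, tolerance = 1e-4)
  expect_equal(label_mass_shift("C6H6N2O", "C6H6N2O"), 0)
  expect_error(label_mass_shift("C6H6N2O", "C6H6N2O2"),
               class = "mediaforge_not_isotopologue")
})

test_that("mass shift is additive in the substituted isotope counts", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_isotopologue_pair()
    expected <- p$n13C * 1.0033548 + p$n15N * 0.9970349 + p$nD * 1.0062767
    expect_equal(label_mass_shift(p$unlabeled, p$labeled), expected,
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("render/parse roundtrips are the identity", {
  set.seed(43)
  for (i in 1:50) {
    f <- parse_formula(random_formula_string())
    expect_equal(parse_formula(render_formula(f)), f)
  }
  # canonical rendering is order-stable Hill order
  expect_identical(render_formula(parse_formula("O2N2H12C11")), "C11H12N2O2")
  expect_identical(render_formula(parse_formula("13C11H12 15N2O2")),
                   "[13C]11H12[15N]2O2")
})
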