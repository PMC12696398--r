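# mediaforge

Preparing cell-culture media from individual components — instead of buying
fixed commercial formulations — lets a lab omit, titrate, trace or
isotope-label any single nutrient, at a fraction of the price. The hard part
is the bookkeeping: dozens of compounds with different solubilities live in
stocks at different concentration factors (1000x, 200x, 100x, 25x), combined
into master stocks, and assembled into a final batch whose remaining volume
must be back-filled with water. A single arithmetic slip ruins the batch.

`mediaforge` is a scriptable R toolkit for that bookkeeping and for the
calculations that surround media-based metabolism experiments:

- **Stoichiometry.** All core conversions use `n = c·V` and `m = M·n`: the
  weigh-in mass for a target molarity and volume, and the *adjusted dilution
  volume* `V = m/(M·c)` that preserves the target molarity for whatever mass
  actually landed on the balance (`m2 − m1`).
- **Compound registry.** A validated table of compounds (molar mass, final
  1x amount, stock multiplier, solvent, storage, light sensitivity). The
  built-in registry ships the full high-glucose DMEM set.
- **Presets and assembly.** Complete DMEM, a bicarbonate/glucose/serum-free
  Seahorse medium (pH 7.4), NAM-/Met-/Trp-depletion media, a
  heavy-tryptophan tracing medium, and the six-step SILAC nascent-proteome
  series (treatment, pre-labeling and AHA + Arg/Lys labeling media, each with
  and without Trp). `assemble_medium()` resolves a preset into an ordered
  bench checklist with automatic water back-fill; `make_variant()` and
  `titration_series()` derive depletion and dilution-series media with
  control-medium linkage.
- **Exact masses.** An isotope-aware molecular-formula parser
  (`13C`, `15N`, `2H`/`D`, bracket and typeset notations) with monoisotopic
  mass and protonated `[M+H]+` m/z for identifying labeled tracers such as
  Trp-13C11,15N2 by accurate mass.
- **Assay metrics.** Sulforhodamine-B doubling analysis (replicate mean OD,
  fold change over day 0, log2 fold change) and Seahorse mito-stress metrics
  (basal, ATP-linked, maximal, spare, non-mitochondrial, average OCR) with
  mandatory blank-well background correction — plus seeded simulators so both
  are testable without instruments.

## Worked example

```r
library(mediaforge)
reg  <- load_registry()                       # built-in DMEM registry
plan <- assemble_medium(load_preset("complete_dmem", reg), 500, reg)
cat(export_plan(plan, "markdown"))
```

```
# complete_dmem - 500.00 ml

## initial water
- [ ] 385.00 ml cell culture-grade water

## inorganic salts
- [ ] 5.00 ml 100x inorganic salts master stock

## salts and vitamins
- [ ] 5.00 ml 100x salts and vitamins master stock

## amino acids
- [ ] 50.00 ml 10x amino acid master stock

## additional components
- [ ] 5.00 ml 100x folic acid stock
- [ ] 5.00 ml 100x riboflavin stock
- [ ] 20.00 ml 25x sodium bicarbonate stock
- [ ] 20.00 ml 25x sodium chloride stock
- [ ] 5.00 ml 100x D-glucose stock

## pH record
- start pH: ____  target: 8.1-8.2  adjusted with: HCl
- sterile-filter after pH adjustment

## post-filtration supplements (immediately before use)
- [ ] 50.00 ml FBS (10 % final)
- [ ] 5.00 ml L-glutamine (2 mmol/l final)
- [ ] 5.00 ml sodium pyruvate (1 mmol/l final)
- [ ] 5.00 ml penicillin-streptomycin (1 % final)
```

The 385 ml water line is the automatic back-fill: the eight stock additions
occupy 115 ml of the 500 ml batch. Stock-level arithmetic works the same way:

```r
weigh_in_mass(0.201, 0.05, 149.21)        # Met 1000x stock: 1.4996 g in 50 ml
1e3 * adjusted_volume(1.6, 149.21, 0.201) # weighed 1.6 g instead: use 53.35 ml
mz_protonated("13C11H12 15N2O2")          # heavy Trp [M+H]+: 218.12813
```

A thin command-line wrapper over the same functions ships in
`inst/cli/media.R`:

```sh
Rscript inst/cli/media.R mass --formula "C6H6N2O" --adduct M+H
Rscript inst/cli/media.R assemble --preset seahorse --volume-ml 500
```

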