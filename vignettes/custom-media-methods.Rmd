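---
title: "Designing custom cell-culture media: models, conventions and simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing custom cell-culture media: models, conventions and simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediaforge)
```

# The problem

Defined media such as DMEM are assembled from ~30 compounds whose
solubilities span four orders of magnitude. At the bench this is handled with
a hierarchy of stocks: well-soluble amino acids at 1000x, the poorly soluble
ones at 100x, salts at 200-2000x, and high-salt components (NaCl, NaHCO3) at
25x, combined into three master stocks (10x amino acids, 100x salts and
vitamins, 100x inorganic salts). A batch of medium is then a sum of stock
volumes plus a water back-fill, followed by pH adjustment, sterile filtration
and the unstable supplements (serum, glutamine, pyruvate, antibiotics) added
immediately before use. `mediaforge` models exactly this workflow.

# Stoichiometric model

Everything reduces to `n = c·V` and `m = M·n`:

* weigh-in mass: `m = M·c·V` (reported in g and, at 0.1 mg, the precision of
  a calibrated analytical balance, in mg);
* adjusted dilution volume: `V = m_actual/(M·c)`, recomputed from the mass
  that actually landed in the tube so the stock's molarity is exact even when
  the weigh-in is not;
* per-addition volume in a batch: `V_batch/multiplier` for a standard
  component, or `V_batch · c_target/c_stock` for a retitrated one;
* water back-fill: `V_batch − Σ additions`.

Internal canonical units are mol/l, l, g and g/mol; unit conversion happens
only at I/O boundaries, so chained computations never accumulate rounding.
Display rounding is round-half-even everywhere: masses at 0.1 mg, volumes at
0.01 ml, millimolar values at 2 decimals. Volume conservation is asserted
internally at 0.001 ml. A plan whose additions exceed the batch volume, or a
master stock targeted above a source stock's concentration, is rejected as
infeasible rather than silently truncated.

Two bookkeeping conventions matter and are deliberate:

* The pH-adjustment acid (HCl, and NaOH correction for the unbuffered
  Seahorse medium) is recorded on the checklist but its volume is neither
  computed nor counted in the conservation sum — no titration model is
  attempted, and the back-fill figure refers to the pre-adjustment batch.
* Post-filtration supplements (FBS, glutamine, pyruvate,
  penicillin-streptomycin) are a separate checklist and are likewise outside
  the back-filled volume; they are added to the finished medium at use time.

# The registry and its provenance

The built-in registry carries the standard high-glucose DMEM formulation in
mg/l, with each compound's stock multiplier, solvent and storage. Amounts for
the headline nutrients reproduce the concentrations a practitioner checks
first: Met 30 mg/l = 201 uM, Trp 16 mg/l = 78 uM, nicotinamide 4 mg/l =
33 uM, Arg·HCl 84 mg/l = 399 uM, Lys·HCl 146 mg/l = 799 uM. Remaining rows
are standard DMEM sheet values and are flagged "unverified against supplier
sheet" in their notes: they ship as editable data, not hard-coded truth.
Glucose is modeled as a 100x additional-component stock (450 g/l for the
4.5 g/l medium); this factor is a reconstruction — it is the one under which
the complete-DMEM plan at 500 ml back-fills exactly 385 ml of water, the
bench-validated figure — and is overridable in a user registry. Labeled
compounds (heavy Trp, SILAC Arg/Lys, AHA) carry synthetic average molar
masses derived from the unlabeled compound plus the isotope mass shift, and
final concentrations stored at full precision so that isotopologue
replacement conserves molar amounts and volumes exactly.

Compound names are normalized by lowercasing and splitting the
stereochemical prefix (L-/D-/DL-/i-) into its own field, and common bench
shorthands (Met, Trp, NAM, AHA, glucose, ...) resolve through an explicit
alias table — never by molar-mass guessing.

# Presets and variants

Twelve presets cover the workflows the package targets: complete DMEM
(pH target 8.1-8.2 before filtration), the Seahorse medium (glucose,
bicarbonate, glutamine, pyruvate, antibiotics and serum omitted because they
feed or buffer the extracellular-flux assay; pH 7.4), three depletion media
(NAM-, Met-, Trp-free, with dialyzed FBS and a reminder to prepare the
matched control), a heavy-Trp tracing medium, and the six SILAC
nascent-proteome media: treatment (all amino acids unlabeled), pre-labeling
(Met/Arg/Lys omitted to drain the unlabeled pools) and labeling (100 uM AHA
in place of Met; Arg-13C6 + Lys-D4 as the intermediate channel or
Arg-13C6,15N4 + Lys-13C6,15N2 as the heavy channel; proline at 0.2 g/l =
1.74 mM to suppress Arg-to-Pro conversion), each with and without Trp.

A depletion variant differs from its control only by the omitted or
retitrated components; `diff_specs()` asserts this by symmetric difference of
(component, final amount) pairs, and the dialyzed-versus-regular-serum choice
is metadata on the spec rather than a composition change so the diff names
exactly the intended nutrients. When a variant breaks a master stock's
standard composition (any member omitted, titrated or replaced), assembly
falls back to the member's individual stocks for that section — the same rule
a careful bench worker applies.

# Exact-mass conventions

The formula parser accepts plain formulas, isotope prefixes at token
boundaries (`13C11H12 15N2O2`), bracket notation (`[13C]11`), `D` for 2H,
and typeset sub/superscript markup (`^13^C_11_...`), which is stripped before
parsing. A digit run is read as an isotope prefix only at a token boundary;
after a closing bracket, digits bind as the count unless digits + element
name a known isotope — and the canonical renderer inserts a space in the one
genuinely ambiguous case so render/parse roundtrips are the identity.

Isotope masses are embedded from the standard IUPAC/AME atomic-mass tables
(1H 1.0078250, 2H 2.0141018, 12C 12 exact, 13C 13.0033548, 14N 14.0030740,
15N 15.0001089, 16O 15.9949146, ...). `[M+H]+` adds the proton mass
1.0072765 Da — the hydrogen-atom mass minus the electron mass, since the
protonated ion carries no extra electron. The hydrogen-atom alternative
(1.0078250) would shift every computed m/z by ~5.5e-4, outside the 1e-4
agreement this module maintains against accurate-mass library values, which
settles the convention. Isotope-pattern envelopes, charge states above 1 and
non-protonated adducts are out of scope.

# Assay metrics

**SRB doubling analysis.** Per day, the replicate mean OD; normalized fold
change as the ratio to the day-0 mean (day 0 is read immediately after
seeding, so plating efficiency divides out); and its log2, which is 0 at day
0 by construction and invariant to uniform OD scaling — so gain settings and
dye-batch differences do not move the readout.

**Mito-stress metrics.** Blank-well background correction (default corner
wells A1, A12, H1, H12, overridable) is mandatory: the per-timepoint blank
mean is subtracted from every sample well before metrics are taken. The
point estimate for each phase is the OCR at the final measurement of that
phase, when the inhibitor effect has stabilized; a phase-mean estimator is
available behind a flag. Basal respiration is reported without subtracting
the non-mitochondrial rate, matching the convention of reporting basal and
non-mitochondrial values as separate quantities; a corrected-basal option
exists but is off by default. Phases come from explicit annotations in the
input (injection times are known by design), so no changepoint detection is
attempted. Spare = maximal − basal and ATP-linked = basal − post-oligomycin
are definitional identities and are asserted as such.

# Simulators and what passing tests mean

`simulate_ocr()` emulates the instrument's mix/wait/measure cycling: one
measurement per 15-minute cycle, 3 cycles per phase by default (the cycle
count per phase is not standardized; 3 is a common protocol choice), constant
plateau levels per phase, Gaussian measurement noise, and constant-level
blank wells. The post-injection transition is first-order with time constant
`tau_min`; the default is 0 (the trace settles within the first cycle), which
makes the noiseless simulator exactly recoverable by the metric extractor —
the property the unit tests pin — while a positive `tau_min` produces
realistic curved transitions for visual work. `simulate_od_timecourse()`
grows OD as `od0 · 2^(t/doubling_time)` with multiplicative log-normal noise
(5% CV default, a typical plate-reader replicate spread).

These simulators emulate plateau structure, cycle timing, background offset
and measurement noise. They do not emulate injection failures, edge-well
evaporation, drifting baselines, oxygen-diffusion artifacts, cell-death
during the assay, or saturating growth in the SRB curve. Passing the
recovery tests therefore demonstrates that the *computations* are correct
and stable under realistic noise — not that real instrument data are this
well behaved.

Problem sizes in the shipped tests and the acceptance script are chosen to
make the statistics meaningful at interactive speed: 200 seeded mito-stress
simulations at noise SD = 5% of basal for plateau-recovery error (median
absolute error < 2 noise SD), 3-6 wells per simulated plate, 21-row OD
tables for doubling-time regression, and 15-50 case property loops for the
parser, unit and volume-conservation invariants.

# Known limitations

* Table-level amounts for the minor DMEM components are sheet defaults, not
  re-assayed values; users with a validated in-house sheet should load their
  own registry CSV.
* The printed Lys value 798 uM differs from the 146 mg/l computation
  (799.3 uM) by 1.3 uM — consistent with truncation on the source sheet; the
  registry keeps the mg/l value and comparisons allow the extra margin for
  this compound only.
* No solubility prediction, osmolarity model or pH titration model: solvents
  and pH targets are carried as registry/preset metadata, and acid volumes
  are recorded by the user.
* Costs are plain ratios of user-supplied bottle prices; no catalog
  integration.
* The Seahorse module reads long-format CSV (`well,time_min,ocr,phase`), not
  vendor report files; the average-OCR summary covers all non-blank
  timepoints.
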