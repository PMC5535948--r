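---
title: "Methods: mass models, speciation and synthetic data in snailMT"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass models, speciation and synthetic data in snailMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snailMT)
```

snailMT implements the computational side of a native electrospray
mass-spectrometry (ESI-MS) characterization of two cysteine-rich snail
metallothionein (MT) variants: a wild type (`BgwtMT`, apo mass 12,652.3 Da)
and a single Lys-to-Asn point mutant (`BgKNMT`). This vignette records the
modelling assumptions, the numeric tolerances, and the design of the seeded
synthetic-data generators, so that every constant in the package can be
traced to a decision rather than a magic number.

## 1. The proton-displacement mass model

Average (not monoisotopic) masses are used throughout, because native ESI of
a ~12.7 kDa protein resolves the envelope centroid, not isotopes. The mass
of a metal-loaded species is built from the apo (metal-free) mass by a
proton-displacement rule:

* each **divalent** metal ion (Zn²⁺, Cd²⁺) adds its average atomic mass and
  displaces **two** protons: `+ m(M) − 2·m(H)`;
* each **monovalent** Cu⁺ adds its mass and displaces **one** proton:
  `+ m(Cu) − 1·m(H)`;
* each **acid-labile sulfide** adds one bare average sulfur atom: `+ m(S)`.

The displaced hydrogens are neutral-atom masses (1.00794 Da in the default
table): the thiolate loses H⁺ but the species is observed as the neutral
molecule, so the bookkeeping is done entirely in neutral masses. Example:

```{r}
tab <- mass_table("iupac2005")
species_mass(12652.3, species_composition(n_zn = 10), tab)        # Zn10
species_mass(12652.3, species_composition(n_cd = 14, n_sulfide = 1), tab)
```

Two mass-table vintages ship with the package (`"iupac2005"`, the default,
and `"iupac2021"`), because standard atomic weights of Zn and S were revised
between them by up to 0.03 Da per atom; with 10–14 metals bound this moves a
complex by a few tenths of a dalton. All reference masses reproduce under
both vintages within the 0.5 Da tolerance used everywhere for theoretical
masses (one-decimal reporting plus vintage drift). The K→N apo shift is the
average residue-mass difference Asn − Lys = −14.07 Da, checked at a tighter
0.2 Da because no metal-table uncertainty enters it.

Sequence-derived apo masses use ExPASy average residue masses plus one water;
`protein_record()` prefers a sequence-derived mass and warns if a user-supplied
apo mass disagrees by more than 0.1 Da.

## 2. Spectra: charge inference and deconvolution

Positive-mode ESI relates a neutral mass `M` to its peaks by
`m/z = (M + z·1.00728)/z` with the proton (1.00728 Da) as charge carrier.
For two adjacent charge states at m/z `a < b`, the lower-m/z peak carries one
more charge and `z_b = (a − 1.00728)/(b − a)`; `infer_charges()` derives the
whole ladder from the first adjacent pair and rejects the envelope if the
per-peak neutral masses spread by more than 0.2 % (twice the assignment
tolerance, i.e. a genuinely inconsistent ladder, not instrument jitter).
`neutral_mass_from_envelope()` then returns the intensity-weighted mean of
`z·(m/z − proton)` across the envelope.

When several species overlap in one raw peak list and no charges are given,
`deconvolute()` forms candidate neutral masses from the implied charge of
every peak pair, clusters them within 0.1 %, and scores each cluster by the
longest run of **consecutive** charge states among the peaks it explains. A
genuine envelope occupies adjacent charge states; the k-fold harmonics that
any ladder also satisfies (2M at charges 2z, …) support only scattered,
non-adjacent charges and therefore score low. Ties go to the smaller mass.

## 3. Speciation assignment

`assign_species()` matches each observed neutral mass to the nearest
candidate composition within `max(0.1 % of mass, 0.5 Da)` — the 0.1 % term
is the stated instrument accuracy; the 0.5 Da floor keeps low masses from
getting an unrealistically tight window. Ties prefer fewer sulfides, fewer
distinct metals, then fewer total metals (parsimony). Two chemistry rules
shape the candidate space:

* at **acidic pH** Zn-containing and sulfide-free Cd candidates are excluded
  — those complexes are acid-labile, and only Cu⁺ and sulfide-stabilized Cd
  species survive acidification;
* in **Cu-supplemented** preparations Zn/Cu heteronuclear compositions of a
  given total metal count are near-degenerate in mass (a Zn↔Cu swap moves
  the mass by only 0.86 Da, inside tolerance), so such assignments are
  reported as an ambiguous `M<n>` species carrying the full list of
  admissible (Zn, Cu) splits. `icp_esi_consistency()` resolves the split by
  least squares against an elemental (ICP-style) metal-to-protein readout,
  in which protein concentration comes from total sulfur divided by the
  sulfur atoms per chain.

## 4. Architecture and expression modules

`cys_profile()` counts Cys and classifies motifs by a single left-to-right
non-overlapping scan (CC, then CXC, then CXXC). Capacity heuristics follow
the standard thiolate-cluster stoichiometries: divalent capacity
`floor(nCys/3)` (M(II)Cys₃ equivalents), Cu⁺ capacity per 9-Cys domain of
4–6 Cu. `deviation_report()` aligns a query against a reference Cys scaffold
and labels terminal gaps as truncation/extension and internal runs of ≥3 as
deletions.

Absolute qPCR quantification uses the textbook calibration
`Cq = intercept + slope·log10(copies)` with
`efficiency = 10^(−1/slope) − 1` (a slope of −3.42 is 96 % efficiency).
Group comparison applies a Shapiro–Wilk gate at α = 0.05 per group — Welch's
t-test if both groups look normal, otherwise the Mann–Whitney test with a
normal approximation. A zero-variance group fails the gate by definition,
and a fully tied rank test (undefined p) is treated as p = 1.

## 5. Synthetic-data generators

All generators are pure functions of `(sim_config(), seed)`: they save and
restore the caller's RNG state, so they compose without side effects.
Problem sizes are the package's own choices, picked to keep the whole test
suite under ~10 s while still exercising every code path:

* `make_prep()` draws species abundances and either deconvoluted masses
  (Gaussian jitter, sd 0.35 Da by default) or raw charge-state envelopes
  (charges 5–9, m/z jitter sd 0.05 Th). Species closer than 3× the mass
  noise are flagged `overlapping` in the truth metadata and a warning is
  raised — that is the generator admitting its own resolution limit.
* `make_titration()` implements a deliberately simple Zn→Cd displacement
  toy model: the expected Cd load is `min(equivalents·bias, capacity)` with
  capacity 12 and a geometric-decay window (ratio 0.2) of ±2 species around
  it; Zn fills the remainder from an initial load of 11. It reproduces the
  qualitative shape of a displacement titration — heteronuclear
  intermediates, saturation at 12 equivalents — but makes no thermodynamic
  claim; affinities enter only as a single bias scalar.
* `make_icp()`, `make_qpcr()` and `make_tissue()` add mean-one lognormal,
  Gaussian-Cq (sd 0.15 cycles) and lognormal tissue noise respectively,
  each on an independent sub-seed so modules can be tested in isolation.

The generators' main limitation versus real data is benign peak shape: no
adducts, no baseline, no detector saturation, and intensity weights that are
exact multinomial draws. They are parameter-recovery instruments, not
spectrum simulators.

## 6. Resolved design questions

* **Single-fit S3 idiom.** The pipeline is multi-stage (masses → spectra →
  speciation → cross-checks), so instead of one `fit()` entry point each
  stage returns a classed S3 object (`speciation_table`,
  `qpcr_calibration`, `titration_curve`, …) with `print`/`summary`/`coef`/
  `predict`/`plot` methods where they make sense.
* **Heteronuclear naming.** Mixed Zn/Cu species are reported under the
  all-Cu mass convention (`M13` prints the Cu₁₃ mass) with the split list
  attached, matching how such species are conventionally tabulated.
* **Saturation detection.** `detect_saturation()` returns the smallest
  equivalents value after which every later increment of Cd occupancy is
  below 0.25; a strictly rising curve returns `NA` with a reason attribute
  rather than pretending the last grid point is a plateau.
* **Tolerances are contracts.** 0.1 % (instrument), 0.5 Da (theoretical
  mass reporting + vintage drift), 0.2 Da (residue shift), 0.2 % (envelope
  self-consistency). They are stated once here and asserted in the test
  suite; none were tuned against outcomes.

## 7. Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from the
installed package, the theoretical masses of the landmark species of both
variants and the worst-case deconvolution error over 100 seeded envelopes,
and writes them as JSON. See the README for a worked end-to-end example.
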