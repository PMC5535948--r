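# snailMT

Metal speciation and expression analysis for cysteine-rich snail
metallothioneins (MTs), built around native electrospray mass spectrometry
(ESI-MS) of intact metal–protein complexes.

## The scientific problem

Metallothioneins chelate Zn²⁺, Cd²⁺ and Cu⁺ through metal–thiolate
clusters. Native ESI-MS of an intact MT preparation yields a set of neutral
masses; the analytical task is to decide, for each observed mass, *which*
metal complement the protein carries. snailMT implements that pipeline for
a wild-type snail MT (`BgwtMT`, apo mass 12,652.3 Da) and its single
Lys→Asn point mutant (`BgKNMT`), plus the companion measurements used to
cross-check and contextualize the speciation: elemental (ICP-style)
metal-to-protein ratios, cysteine-architecture capacity predictions, and
absolute qPCR quantification of transcript induction.

## The model

All masses are **average** masses. A holo-species mass is derived from the
apo mass by proton displacement:

```
M(apo + a·Zn + b·Cd + c·Cu + d·S)
  = M(apo) + a·(m_Zn − 2 m_H) + b·(m_Cd − 2 m_H) + c·(m_Cu − 1 m_H) + d·m_S
```

Divalent metals (Zn²⁺, Cd²⁺) displace two protons each, monovalent Cu⁺
displaces one, and acid-labile sulfide adds a bare sulfur atom. Observed
m/z relates to neutral mass by `m/z = (M + z·1.00728)/z`; for adjacent
charge states at m/z `a < b`, `z_b = (a − 1.00728)/(b − a)`, which lets the
whole charge ladder — and hence `M` — be inferred with no prior knowledge.
Assignment accepts the nearest candidate within `max(0.1 % of mass,
0.5 Da)`; at acidic pH, Zn-containing and sulfide-free Cd candidates are
chemically excluded. Near-degenerate Zn/Cu heteronuclear species are
reported as an ambiguity set and resolved against elemental ratios by least
squares. Expression analysis converts qPCR calibration slope to efficiency
(`10^(−1/slope) − 1`) and compares groups through a Shapiro–Wilk gate
(Welch's t-test vs Mann–Whitney).

## Worked example

```r
library(snailMT)

tab <- mass_table("iupac2005")
species_mass(12652.3, species_composition(n_zn = 10), tab)
#> [1] 13286.23

cand <- enumerate_candidates(12652.3, prep_context("Zn"))
st <- assign_species(data.frame(mass = c(12652.4, 13286.1, 13349.7),
                                intensity = c(1, 5, 3)), cand)
st
#> Speciation table (pH neutral, vintage iupac2005, apo 12652.3 Da)
#>   observed_mass intensity label n_zn n_cd n_cu n_sulfide theoretical_mass delta
#> 1       12652.4         1   apo    0    0    0         0          12652.3 -0.10
#> 2       13286.1         5  Zn10   10    0    0         0          13286.2  0.13
#> 3       13349.7         3  Zn11   11    0    0         0          13349.6 -0.08
#>   relative_error assigned ambiguous major
#> 1        7.9e-06     TRUE     FALSE FALSE
#> 2        9.9e-06     TRUE     FALSE  TRUE
#> 3        5.7e-06     TRUE     FALSE FALSE

summary(st)
#> 3 observed, 3 assigned; major species: Zn10
#>   intensity-weighted occupancy: Zn 9.22, Cd 0.00, Cu 0.00
```

Raw (m/z-domain) peak lists are handled the same way after
`deconvolute()`, which infers charges, groups envelopes and returns neutral
masses. Seeded synthetic preparations, titrations, elemental readouts and
qPCR runs come from `sim_config()` + `make_prep()` / `make_titration()` /
`make_icp()` / `make_qpcr()`; a command-line front end is available as
`snailmt_cli()` (or the `inst/cli/snailmt` launcher).

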