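#' Reference speciation of the two snail metallothionein variants
#'
#' The packaged analytical characterization of the recombinant Zn-, Cd- and
#' Cu-supplemented preparations of the wild-type protein (apo 12,652.3 Da)
#' and its Lys-to-Asn allelic variant (apo 12,638.2 Da): one row per
#' detected species with its stoichiometry label, composition counts,
#' experimental and reference theoretical masses at each pH, and whether it
#' was a major species. `M<n>` labels denote heteronuclear Zn/Cu species of
#' unresolved split; their composition columns carry the all-Cu convention
#' under which the reference theoretical masses were tabulated.
#'
#' @return Data frame with columns `protein`, `apo_mass`, `prep`, `ph`,
#'   `label`, `n_zn`, `n_cd`, `n_cu`, `n_s`, `major`, `exp_mm`, `calc_mm`.
#' @export
reference_speciation <- function() {
  utils::read.csv(system.file("extdata", "table1_speciation.csv",
                              package = "snailMT", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference metal-to-peptide ratios of the recombinant preparations
#'
#' Elemental (ICP-AES) metal-to-peptide ratios for the six recombinant
#' preparations (two protein variants, three supplemented metals).
#'
#' @return Data frame with columns `protein`, `prep`, `Zn`, `Cd`, `Cu`.
#' @export
reference_icp_ratios <- function() {
  utils::read.csv(system.file("extdata", "table1_icp.csv",
                              package = "snailMT", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
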