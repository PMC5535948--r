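#' Elemental (ICP-AES style) readout of a protein preparation
#'
#' @param concentrations Named numeric vector of micromolar element
#'   concentrations; must include `S` and may include `Zn`, `Cd`, `Cu`.
#' @param n_sulfur_per_protein Sulfur atoms per protein molecule (Cys + Met),
#'   >= 1. All sulfur in the preparation is assumed to come from the peptide.
#' @return Object of class `element_readout`.
#' @export
element_readout <- function(concentrations, n_sulfur_per_protein) {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)),
            all(concentrations >= 0), n_sulfur_per_protein >= 1)
  structure(list(concentrations = concentrations,
                 n_sulfur_per_protein = n_sulfur_per_protein),
            class = "element_readout")
}

#' Read an elemental readout from CSV
#'
#' Expects columns `element,concentration_uM`.
#' @param path CSV path.
#' @param n_sulfur_per_protein Sulfur atoms per protein molecule.
#' @return An [element_readout()].
#' @export
read_element_readout <- function(path, n_sulfur_per_protein) {
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  if (!all(c("element", "concentration_um") %in% nm)) {
    stop("elemental CSV must have columns element,concentration_uM: ", path)
  }
  element_readout(
    stats::setNames(df[[which(nm == "concentration_um")]],
                    df[[which(nm == "element")]]),
    n_sulfur_per_protein)
}

#' Sulfur-based protein concentration
#'
#' Divides the measured sulfur concentration by the number of sulfur atoms
#' per protein molecule, assuming all sulfur is peptide-borne.
#'
#' @param readout An [element_readout()].
#' @return Protein concentration in micromolar.
#' @export
protein_concentration <- function(readout) {
  cs <- readout$concentrations[["S"]]
  if (is.null(cs) || is.na(cs) || cs <= 0) stop("S concentration must be > 0")
  cs / readout$n_sulfur_per_protein
}

#' Metal-to-peptide ratios from an elemental readout
#'
#' Each metal concentration divided by the sulfur-derived protein
#' concentration: the "9.8 Zn / 0 Cd / 0 Cu"-style numbers reported per
#' preparation.
#'
#' @param readout An [element_readout()].
#' @return Named numeric vector of ratios for every non-S element present.
#' @export
metal_per_protein <- function(readout) {
  p <- protein_concentration(readout)
  met <- readout$concentrations[setdiff(names(readout$concentrations), "S")]
  met / p
}

#' Cross-check ICP ratios against ESI speciation
#'
#' Compares each elemental metal-to-peptide ratio with the intensity-weighted
#' mean stoichiometry of the assigned ESI species. For ambiguous
#' heteronuclear rows (the "M_n" Zn/Cu species) the (n_zn, n_cu) split
#' minimizing the total squared discrepancy against the ICP ratios is
#' selected before the comparison; both the full ambiguity set and the
#' selected split are reported.
#'
#' @param ratios Named numeric vector from [metal_per_protein()].
#' @param table A [assign_species()] output with >= 1 assigned row.
#' @param tolerance Ratio units above which a metal is flagged (default 1.5).
#' @return List of class `icp_esi_report` with `comparison` (data frame:
#'   metal, icp_ratio, esi_mean, discrepancy, consistent), `chosen_splits`,
#'   and `all_consistent`.
#' @export
icp_esi_consistency <- function(ratios, table, tolerance = 1.5) {
  tab <- table[table$assigned, , drop = FALSE]
  if (!nrow(tab)) stop("speciation table has no assigned rows")
  splits_attr <- attr(table, "splits")
  idx_assigned <- which(table$assigned)

  metals <- intersect(c("Zn", "Cd", "Cu"), names(ratios))
  col <- c(Zn = "n_zn", Cd = "n_cd", Cu = "n_cu")

  # resolve ambiguous rows by least-squares discrepancy against ICP ratios
  chosen <- list()
  for (i in seq_len(nrow(tab))) {
    if (isTRUE(tab$ambiguous[i])) {
      sp <- splits_attr[[idx_assigned[i]]]
      if (!is.null(sp) && nrow(sp) > 1) {
        score <- vapply(seq_len(nrow(sp)), function(k) {
          d <- 0
          if ("Zn" %in% metals) d <- d + (sp$n_zn[k] - ratios[["Zn"]])^2
          if ("Cu" %in% metals) d <- d + (sp$n_cu[k] - ratios[["Cu"]])^2
          d
        }, numeric(1))
        k <- which.min(score)
        tab$n_zn[i] <- sp$n_zn[k]
        tab$n_cu[i] <- sp$n_cu[k]
        chosen[[tab$label[i]]] <- c(n_zn = sp$n_zn[k], n_cu = sp$n_cu[k])
      }
    }
  }

  w <- tab$intensity
  esi_mean <- vapply(metals, function(m) sum(w * tab[[col[[m]]]]) / sum(w),
                     numeric(1))
  cmpdf <- data.frame(metal = metals,
                      icp_ratio = as.numeric(ratios[metals]),
                      esi_mean = as.numeric(esi_mean))
  cmpdf$discrepancy <- abs(cmpdf$icp_ratio - cmpdf$esi_mean)
  cmpdf$consistent <- cmpdf$discrepancy <= tolerance
  structure(list(comparison = cmpdf, chosen_splits = chosen,
                 tolerance = tolerance,
                 all_consistent = all(cmpdf$consistent)),
            class = "icp_esi_report")
}

#' @export
print.icp_esi_report <- function(x, ...) {
  cat("ICP vs ESI stoichiometry (tolerance", x$tolerance, "ions/protein)\n")
  print(x$comparison, row.names = FALSE)
  for (nm in names(x$chosen_splits)) {
    sp <- x$chosen_splits[[nm]]
    cat(sprintf("  %s resolved as Zn%d Cu%d (least-squares vs ICP)\n",
                nm, sp[["n_zn"]], sp[["n_cu"]]))
  }
  cat(if (x$all_consistent) "all metals consistent\n" else "INCONSISTENT metals present\n")
  invisible(x)
}
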