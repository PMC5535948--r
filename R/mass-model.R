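#' Theoretical average mass of a protein from its sequence
#'
#' Sums standard average residue masses over a 1-letter amino acid sequence
#' and adds one water for the termini.
#'
#' @param sequence Character scalar; 1-letter codes for the 20 standard
#'   residues (case-insensitive). Must be non-empty.
#' @param table A [mass_table()].
#' @return Average mass in Da.
#' @examples
#' protein_average_mass("G")   # glycine monomer, 75.07 Da
#' @export
protein_average_mass <- function(sequence, table = mass_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(table$residue_masses))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  sum(table$residue_masses[aa]) + table$water_mass
}

#' Mass shift of a single residue substitution
#'
#' Residue mass of `to_residue` minus that of `from_residue`. Adding the
#' shift to any species mass of the original protein yields the mass of the
#' corresponding species of the point mutant (the Lys-to-Asn allelic variant
#' of the snail metallothionein shifts every species by -14.07 Da).
#'
#' @param from_residue,to_residue Single 1-letter residue codes.
#' @inheritParams protein_average_mass
#' @return Mass difference in Da.
#' @examples
#' substitution_shift("K", "N")   # -14.07
#' @export
substitution_shift <- function(from_residue, to_residue, table = mass_table()) {
  rm <- table$residue_masses
  from_residue <- toupper(from_residue); to_residue <- toupper(to_residue)
  if (!from_residue %in% names(rm)) stop("invalid residue: ", from_residue)
  if (!to_residue %in% names(rm)) stop("invalid residue: ", to_residue)
  unname(rm[to_residue] - rm[from_residue])
}

#' Metal/sulfide composition of one species
#'
#' Defines one metal-loaded form by its counts of Zn(II), Cd(II), Cu(I) and
#' acid-labile sulfide. Sulfide is only admitted alongside divalent metals
#' (it is observed in Cd-thiolate clusters).
#'
#' @param n_zn,n_cd,n_cu,n_sulfide Non-negative integer counts.
#' @return An object of class `species_composition`.
#' @examples
#' species_composition(n_zn = 10)
#' @export
species_composition <- function(n_zn = 0L, n_cd = 0L, n_cu = 0L, n_sulfide = 0L) {
  counts <- c(n_zn = n_zn, n_cd = n_cd, n_cu = n_cu, n_sulfide = n_sulfide)
  if (any(counts < 0)) stop("composition counts must be >= 0")
  if (any(counts != round(counts))) stop("composition counts must be integers")
  if (n_sulfide > n_zn + n_cd) {
    stop("sulfide count cannot exceed the divalent metal count")
  }
  counts <- as.integer(counts)
  names(counts) <- c("n_zn", "n_cd", "n_cu", "n_sulfide")
  structure(as.list(counts), class = "species_composition")
}

#' @export
format.species_composition <- function(x, ...) species_label(x)

#' @export
print.species_composition <- function(x, ...) {
  cat(species_label(x), "\n")
  invisible(x)
}

#' Human-readable species label (e.g. "Zn10", "Cd14S", "apo")
#' @param comp A [species_composition()].
#' @return Character scalar.
#' @export
species_label <- function(comp) {
  parts <- character(0)
  if (comp$n_zn > 0) parts <- c(parts, paste0("Zn", comp$n_zn))
  if (comp$n_cd > 0) parts <- c(parts, paste0("Cd", comp$n_cd))
  if (comp$n_cu > 0) parts <- c(parts, paste0("Cu", comp$n_cu))
  if (comp$n_sulfide > 0) {
    parts <- c(parts, if (comp$n_sulfide == 1) "S" else paste0("S", comp$n_sulfide))
  }
  if (!length(parts)) "apo" else paste(parts, collapse = "")
}

#' Theoretical mass of a metal-loaded species
#'
#' Adds to the apo (metal-free) mass the effective mass of each bound ligand
#' under the proton-displacement model: each divalent metal ion (Zn2+, Cd2+)
#' displaces two protons from cysteine thiols, so it contributes its atomic
#' mass minus two hydrogen atoms; each monovalent Cu+ displaces one proton;
#' each acid-labile sulfide adds a bare sulfur atom with no hydrogen
#' adjustment. This is the unique simple rule that reproduces the full set of
#' published holo-minus-apo mass differences for these proteins.
#'
#' @param apo_mass Apo protein mass in Da (> 0).
#' @param comp A [species_composition()].
#' @inheritParams protein_average_mass
#' @return Species mass in Da.
#' @examples
#' species_mass(12652.3, species_composition(n_zn = 10))   # 13286.2
#' @export
species_mass <- function(apo_mass, comp, table = mass_table()) {
  stopifnot(is.numeric(apo_mass), apo_mass > 0)
  if (!inherits(comp, "species_composition")) {
    comp <- do.call(species_composition, as.list(comp))
  }
  em <- table$element_masses
  h <- table$h_atom_mass
  apo_mass +
    comp$n_zn * (em[["Zn"]] - 2 * h) +
    comp$n_cd * (em[["Cd"]] - 2 * h) +
    comp$n_cu * (em[["Cu"]] - 1 * h) +
    comp$n_sulfide * em[["S"]]
}

#' Preparation context for candidate enumeration
#'
#' Declares which ligands are admissible for a given recombinant preparation:
#' the supplemented metal is always admissible, Zn is always admissible as
#' host-cell background, and sulfide is admitted only when divalent metals
#' are (Cd or Zn preparations).
#'
#' @param supplemented One of `"Zn"`, `"Cd"`, `"Cu"`.
#' @param max_metals Per-metal maximum count (default 16) or a named vector
#'   over the admissible metals.
#' @param max_sulfide Maximum sulfide count (default 2 when divalent metals
#'   are admissible, 0 otherwise).
#' @param max_total Bound on the total metal count (default `max(max_metals)`).
#' @return A list of class `prep_context`.
#' @export
prep_context <- function(supplemented = c("Zn", "Cd", "Cu"),
                         max_metals = 16L,
                         max_sulfide = NULL,
                         max_total = NULL) {
  supplemented <- match.arg(supplemented)
  metals <- union(supplemented, "Zn")
  if (length(max_metals) == 1L && is.null(names(max_metals))) {
    max_metals <- stats::setNames(rep(as.integer(max_metals), length(metals)), metals)
  }
  stopifnot(all(metals %in% names(max_metals)), all(is.finite(max_metals)))
  divalent <- any(c("Zn", "Cd") %in% metals)
  if (is.null(max_sulfide)) max_sulfide <- if (supplemented == "Cd") 2L else 0L
  if (!divalent) max_sulfide <- 0L
  if (is.null(max_total)) max_total <- max(max_metals)
  structure(list(supplemented = supplemented, metals = metals,
                 max_metals = max_metals, max_sulfide = as.integer(max_sulfide),
                 max_total = as.integer(max_total)),
            class = "prep_context")
}

#' Enumerate candidate species compositions with theoretical masses
#'
#' Exhaustively lists every admissible composition for a preparation context,
#' with its theoretical mass, sorted by mass (ties broken by Zn, Cd, Cu,
#' sulfide counts so the order is deterministic). This is the search space
#' for species assignment.
#'
#' @inheritParams species_mass
#' @param context A [prep_context()].
#' @return A data frame with columns `n_zn`, `n_cd`, `n_cu`, `n_sulfide`,
#'   `label`, `mass`.
#' @examples
#' head(enumerate_candidates(12652.3, prep_context("Zn")))
#' @export
enumerate_candidates <- function(apo_mass, context, table = mass_table()) {
  stopifnot(inherits(context, "prep_context"))
  mm <- context$max_metals
  zmax <- if ("Zn" %in% names(mm)) mm[["Zn"]] else 0L
  cdmax <- if ("Cd" %in% names(mm)) mm[["Cd"]] else 0L
  cumax <- if ("Cu" %in% names(mm)) mm[["Cu"]] else 0L
  grid <- expand.grid(n_zn = 0:zmax, n_cd = 0:cdmax, n_cu = 0:cumax,
                      n_sulfide = 0:context$max_sulfide)
  keep <- (grid$n_zn + grid$n_cd + grid$n_cu) <= context$max_total &
    grid$n_sulfide <= (grid$n_zn + grid$n_cd)
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) stop("empty admissible set")
  em <- table$element_masses; h <- table$h_atom_mass
  grid$mass <- apo_mass +
    grid$n_zn * (em[["Zn"]] - 2 * h) +
    grid$n_cd * (em[["Cd"]] - 2 * h) +
    grid$n_cu * (em[["Cu"]] - 1 * h) +
    grid$n_sulfide * em[["S"]]
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    species_label(species_composition(grid$n_zn[i], grid$n_cd[i],
                                      grid$n_cu[i], grid$n_sulfide[i]))
  }, character(1))
  ord <- order(grid$mass, grid$n_zn, grid$n_cd, grid$n_cu, grid$n_sulfide)
  grid <- grid[ord, c("n_zn", "n_cd", "n_cu", "n_sulfide", "label", "mass")]
  rownames(grid) <- NULL
  attr(grid, "apo_mass") <- apo_mass
  attr(grid, "vintage") <- table$vintage
  attr(grid, "context") <- context
  grid
}

#' Protein record with optional sequence
#'
#' Bundles an identifier, an optional sequence, the apo mass and the number
#' of sulfur atoms per molecule (Cys + Met, the basis of sulfur-derived
#' protein concentrations). When a sequence is supplied its computed mass is
#' authoritative: a conflicting `apo_mass` more than 0.1 Da away triggers a
#' warning and is replaced.
#'
#' @param identifier Character scalar.
#' @param sequence Optional 1-letter sequence ("" to omit).
#' @param apo_mass Apo mass in Da; required when no sequence is given.
#' @param n_sulfur_atoms Optional sulfur-atom count; computed from the
#'   sequence when present.
#' @inheritParams protein_average_mass
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(identifier, sequence = "", apo_mass = NULL,
                           n_sulfur_atoms = NULL, table = mass_table()) {
  has_seq <- nzchar(sequence)
  if (has_seq) {
    computed <- protein_average_mass(sequence, table)
    if (!is.null(apo_mass) && abs(apo_mass - computed) > 0.1) {
      warning(sprintf(
        "apo_mass %.2f differs from sequence-derived mass %.2f by > 0.1 Da; using the sequence",
        apo_mass, computed))
    }
    apo_mass <- computed
    aa <- strsplit(toupper(sequence), "")[[1]]
    n_s <- sum(aa %in% c("C", "M"))
    if (!is.null(n_sulfur_atoms) && n_sulfur_atoms != n_s) {
      warning("n_sulfur_atoms disagrees with the sequence (Cys + Met); using the sequence")
    }
    n_sulfur_atoms <- n_s
    if (n_sulfur_atoms < sum(aa == "C")) stop("sulfur count below Cys count")
  } else {
    if (is.null(apo_mass)) stop("apo_mass required when no sequence is given")
  }
  structure(list(identifier = identifier, sequence = sequence,
                 apo_mass = apo_mass, n_sulfur_atoms = n_sulfur_atoms),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("Protein:", x$identifier, "\n")
  cat("  apo mass:", sprintf("%.1f Da", x$apo_mass), "\n")
  if (nzchar(x$sequence)) cat("  length:", nchar(x$sequence), "aa\n")
  if (!is.null(x$n_sulfur_atoms)) cat("  S atoms:", x$n_sulfur_atoms, "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a plain (optionally gapped) FASTA file.
#' @return Named character vector of sequences (gaps retained).
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(recs, as.character, character(1))), names(recs))
}
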