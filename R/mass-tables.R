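#' Average-mass tables for protein and metal-adduct arithmetic
#'
#' Returns a mass table holding average element masses for the metals handled
#' by the pipeline (Zn, Cd, Cu) and sulfur, the twenty standard average amino
#' acid residue masses, the mass of water, the proton (the ESI charge carrier)
#' and the hydrogen atom. Two element-mass vintages are shipped as packaged
#' JSON: `"iupac2005"` (the default) and `"iupac2021"`, which differ only in
#' the third decimal of Zn, Cd and S. Every downstream report records which
#' vintage produced its theoretical masses.
#'
#' @param vintage `"iupac2005"`, `"iupac2021"`, or a list with components
#'   `element_masses` (named numeric: Zn, Cd, Cu, S) and optionally
#'   `h_atom_mass` for a custom table (then labelled `"custom"`).
#' @return An object of class `mass_table`: a list with `element_masses`,
#'   `residue_masses`, `water_mass`, `proton_mass`, `h_atom_mass`, `vintage`.
#' @examples
#' tab <- mass_table()
#' tab$element_masses[["Zn"]]
#' @export
mass_table <- function(vintage = "iupac2005") {
  raw <- .mass_table_json()
  if (is.list(vintage)) {
    em <- unlist(vintage$element_masses)
    stopifnot(all(c("Zn", "Cd", "Cu", "S") %in% names(em)), all(em > 0))
    tab <- list(
      element_masses = em,
      residue_masses = unlist(raw$residue_masses),
      water_mass = raw$water_mass,
      proton_mass = raw$proton_mass,
      h_atom_mass = if (!is.null(vintage$h_atom_mass)) vintage$h_atom_mass else 1.00794,
      vintage = "custom"
    )
  } else {
    vintage <- match.arg(vintage, names(raw$vintages))
    v <- raw$vintages[[vintage]]
    tab <- list(
      element_masses = unlist(v$element_masses),
      residue_masses = unlist(raw$residue_masses),
      water_mass = raw$water_mass,
      proton_mass = raw$proton_mass,
      h_atom_mass = v$h_atom_mass,
      vintage = vintage
    )
  }
  stopifnot(all(tab$residue_masses > 0), tab$water_mass > 0)
  class(tab) <- "mass_table"
  tab
}

.mass_table_json <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "mass_tables.json", package = "snailMT",
                          mustWork = TRUE)
      cache <<- jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cache
  }
})

#' @export
print.mass_table <- function(x, ...) {
  cat("Average mass table (vintage:", x$vintage, ")\n")
  cat("  elements:",
      paste(sprintf("%s=%.4g", names(x$element_masses), x$element_masses),
            collapse = ", "), "\n")
  cat("  water", x$water_mass, " proton", x$proton_mass,
      " H atom", x$h_atom_mass, "\n")
  invisible(x)
}
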