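#' Census parameters: radii, thresholds and modes
#'
#' Collects every tunable quantity of the halide census in one validated
#' list. Defaults follow the study conditions the census reproduces: ionic
#' radii of 1.19, 1.67, 1.82 and 2.06 angstrom for F-, Cl-, Br- and I-, a
#' 1.4 angstrom water probe, a 5 angstrom interaction sphere, a 0.5 angstrom
#' RMSD threshold for merging homologous site copies, and a 2.0 angstrom
#' resolution cutoff for entry curation.
#'
#' @param halide_radii Named numeric vector of ionic radii (angstrom) for the
#'   species `F`, `Cl`, `Br`, `I`.
#' @param water_radius Water probe radius in angstrom used both for the
#'   accessible-surface expansion and for the fractional-ASA denominator.
#' @param sphere_radius Radius (angstrom) of the interaction sphere around a
#'   halide inside which atoms are considered.
#' @param rmsd_threshold Superposition RMSD (angstrom) at or below which two
#'   compositionally identical sites within one entry are treated as
#'   crystallographic copies and merged.
#' @param resolution_cutoff Entries with resolution worse (numerically larger)
#'   than this value in angstrom are excluded during curation.
#' @param include_waters If `TRUE`, water oxygens inside the sphere join the
#'   coordinating set (and the coordination number); if `FALSE` they are only
#'   counted as solvation waters.
#' @param halide_residue_codes Named list mapping species to the PDB residue
#'   codes recognised as that halide.
#' @param water_residue_codes Residue codes recognised as water.
#' @param sasa_points Number of deterministic sphere sample points for the
#'   accessible-surface calculation (>= 64).
#' @param protein_atom_radii Named numeric vector of van-der-Waals radii
#'   (angstrom) by element for the occlusion context of the ASA calculation.
#'
#' @return A list of class `census_params`.
#' @examples
#' p <- census_params()
#' p$halide_radii[["Cl"]]
#' @export
census_params <- function(halide_radii = c(F = 1.19, Cl = 1.67, Br = 1.82, I = 2.06),
                          water_radius = 1.4,
                          sphere_radius = 5.0,
                          rmsd_threshold = 0.5,
                          resolution_cutoff = 2.0,
                          include_waters = FALSE,
                          halide_residue_codes = list(
                            F = "F", Cl = "CL", Br = "BR", I = c("IOD", "I")
                          ),
                          water_residue_codes = c("HOH", "DOD", "WAT"),
                          sasa_points = 960L,
                          protein_atom_radii = c(
                            N = 1.55, O = 1.52, S = 1.80, P = 1.80, C = 1.70
                          )) {
  stopifnot(
    is.numeric(halide_radii), all(halide_radii > 0),
    all(c("F", "Cl", "Br", "I") %in% names(halide_radii)),
    is.numeric(water_radius), water_radius > 0,
    is.numeric(sphere_radius), sphere_radius > max(halide_radii),
    is.numeric(rmsd_threshold), rmsd_threshold > 0,
    is.numeric(resolution_cutoff), resolution_cutoff > 0,
    is.logical(include_waters), length(include_waters) == 1L,
    is.list(halide_residue_codes),
    all(c("F", "Cl", "Br", "I") %in% names(halide_residue_codes)),
    is.numeric(sasa_points), sasa_points >= 64,
    is.numeric(protein_atom_radii), all(protein_atom_radii > 0)
  )
  structure(
    list(
      halide_radii = halide_radii,
      water_radius = water_radius,
      sphere_radius = sphere_radius,
      rmsd_threshold = rmsd_threshold,
      resolution_cutoff = resolution_cutoff,
      include_waters = include_waters,
      halide_residue_codes = halide_residue_codes,
      water_residue_codes = water_residue_codes,
      sasa_points = as.integer(sasa_points),
      protein_atom_radii = protein_atom_radii
    ),
    class = "census_params"
  )
}

#' @export
print.census_params <- function(x, ...) {
  cat("<census_params>\n")
  cat("  halide radii (A):",
      paste(sprintf("%s=%.2f", names(x$halide_radii), x$halide_radii), collapse = " "), "\n")
  cat(sprintf("  water probe %.2f A, sphere %.1f A, rmsd threshold %.2f A\n",
              x$water_radius, x$sphere_radius, x$rmsd_threshold))
  cat(sprintf("  resolution cutoff %.2f A, include_waters=%s, sasa points %d\n",
              x$resolution_cutoff, x$include_waters, x$sasa_points))
  invisible(x)
}

# species label ("F","Cl","Br","I") for a halide residue code, or NA
species_for_code <- function(res_name, params) {
  for (sp in names(params$halide_residue_codes)) {
    if (res_name %in% params$halide_residue_codes[[sp]]) return(sp)
  }
  NA_character_
}
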