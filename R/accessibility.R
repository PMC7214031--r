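# Deterministic golden-spiral lattice of n points on the unit sphere.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radius <- function(element, res_name, params) {
  sp <- species_for_code(res_name, params)
  if (!is.na(sp)) return(params$halide_radii[[sp]])
  if (element %in% names(params$halide_radii)) {
    return(params$halide_radii[[element]])
  }
  if (!element %in% names(params$protein_atom_radii)) {
    stop(sprintf("no radius configured for element '%s'", element), call. = FALSE)
  }
  params$protein_atom_radii[[element]]
}

#' Accessible surface area of one atom
#'
#' Numerical solvent-accessible surface area of the target atom's expanded
#' sphere (van-der-Waals or ionic radius plus the water probe radius),
#' computed on a deterministic golden-spiral lattice of `params$sasa_points`
#' sample points: a point is exposed when it lies outside every context
#' atom's expanded sphere, and the area is the exposed fraction times the
#' full sphere area \eqn{4\pi(r + r_w)^2}.
#'
#' @param target A one-row atom tibble (as in `halide_structure$atoms`).
#' @param context Atom tibble of occluding atoms; hydrogens (and, for the
#'   census's burial measure, waters) should already be excluded. The target
#'   itself is ignored if present.
#' @param params A [census_params()] object supplying radii, the probe radius
#'   and the sampling density.
#' @return Area in square angstrom.
#' @examples
#' p <- census_params()
#' cl <- tibble::tibble(element = "Cl", res_name = "CL", x = 0, y = 0, z = 0)
#' atom_asa(cl, cl[0, ], p) # ~ 4 * pi * (1.67 + 1.4)^2
#' @export
atom_asa <- function(target, context, params = census_params()) {
  r_t <- atom_radius(target$element, target$res_name, params) + params$water_radius
  centre <- c(target$x, target$y, target$z)
  pts <- sweep(golden_spiral_points(params$sasa_points) * r_t, 2, centre, "+")

  if (nrow(context) > 0) {
    # drop the target itself and any context atom too far to occlude
    r_c <- vapply(seq_len(nrow(context)), function(j) {
      atom_radius(context$element[j], context$res_name[j], params)
    }, numeric(1)) + params$water_radius
    d2c <- (context$x - centre[1])^2 + (context$y - centre[2])^2 +
      (context$z - centre[3])^2
    near <- d2c > 1e-12 & sqrt(d2c) < r_t + r_c
    context <- context[near, , drop = FALSE]
    r_c <- r_c[near]
    exposed <- rep(TRUE, nrow(pts))
    for (j in seq_along(r_c)) {
      d2 <- (pts[, 1] - context$x[j])^2 + (pts[, 2] - context$y[j])^2 +
        (pts[, 3] - context$z[j])^2
      exposed <- exposed & d2 >= r_c[j]^2
      if (!any(exposed)) break
    }
    frac <- mean(exposed)
  } else {
    frac <- 1
  }
  frac * 4 * pi * r_t^2
}

#' Fractional accessible surface area of a halide
#'
#' Ratio between the halide's accessible surface area inside the structure
#' and the area of the isolated expanded sphere of radius (ionic radius +
#' 1.4 angstrom water probe). 1 means fully solvent-exposed, 0 fully buried.
#' The occlusion context is every non-hydrogen, non-water atom of the
#' structure, so the measure reflects burial by the protein (and any bound
#' ligands), not by ordered solvent.
#'
#' @param halide A one-row atom tibble for the halide.
#' @param structure The `halide_structure` containing it.
#' @param params A [census_params()] object.
#' @return A fraction in \[0, 1\].
#' @export
fractional_asa <- function(halide, structure, params = census_params()) {
  ctx <- structure$atoms
  ctx <- ctx[!(ctx$element %in% c("H", "D")) & ctx$record_class != "water", ,
             drop = FALSE]
  self <- abs(ctx$x - halide$x) < 1e-9 & abs(ctx$y - halide$y) < 1e-9 &
    abs(ctx$z - halide$z) < 1e-9
  ctx <- ctx[!self, , drop = FALSE]
  r_t <- atom_radius(halide$element, halide$res_name, params) + params$water_radius
  asa <- atom_asa(halide, ctx, params)
  min(1, asa / (4 * pi * r_t^2))
}

#' Add fractional ASA to a site tibble
#'
#' @param sites A `halide_sites` tibble.
#' @param structure The `halide_structure` the sites came from.
#' @param params A [census_params()] object.
#' @return `sites` with a `fasa` column.
#' @export
add_fasa <- function(sites, structure, params = census_params()) {
  if (nrow(sites) == 0) {
    sites$fasa <- double()
    return(sites)
  }
  a <- structure$atoms
  sites$fasa <- purrr::map_dbl(seq_len(nrow(sites)), function(i) {
    hit <- which(a$record_class == "halide" & a$chain_id == sites$chain[i] &
                   a$res_seq == sites$res_seq[i] & a$i_code == sites$i_code[i])
    fractional_asa(a[hit[1], ], structure, params)
  })
  sites
}
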