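# Independent oracles and small fixture builders shared across tests.

# Brute-force re-derivation of site extraction: an explicit double loop over
# halide x atom pairs with scalar distance arithmetic, no shared code path
# with extract_sites().
brute_force_sites <- function(structure, params = census_params()) {
  a <- structure$atoms
  halide_idx <- which(a$record_class == "halide")
  out <- list()
  for (h in halide_idx) {
    coord_keys <- character()
    water_res <- character()
    for (j in seq_len(nrow(a))) {
      if (j == h) next
      d <- sqrt((a$x[j] - a$x[h])^2 + (a$y[j] - a$y[h])^2 + (a$z[j] - a$z[h])^2)
      if (d > params$sphere_radius || d <= 0) next
      if (a$record_class[j] == "polymer" && !(a$element[j] %in% c("C", "H", "D"))) {
        coord_keys <- c(coord_keys, sprintf("%s|%s|%s|%d|%s", a$chain_id[j],
                                            a$res_name[j], a$atom_name[j],
                                            a$res_seq[j], a$i_code[j]))
      }
      if (a$record_class[j] == "water" && a$element[j] == "O") {
        water_res <- c(water_res, sprintf("%s|%d|%s", a$chain_id[j],
                                          a$res_seq[j], a$i_code[j]))
        if (params$include_waters) {
          coord_keys <- c(coord_keys, sprintf("%s|%s|%s|%d|%s", a$chain_id[j],
                                              a$res_name[j], a$atom_name[j],
                                              a$res_seq[j], a$i_code[j]))
        }
      }
    }
    out[[length(out) + 1]] <- list(
      chain = a$chain_id[h], res_seq = a$res_seq[h],
      cn = length(coord_keys), n_waters = length(unique(water_res)),
      coord_keys = sort(coord_keys)
    )
  }
  out[order(vapply(out, \(s) sprintf("%s%09d", s$chain, s$res_seq), ""))]
}

site_coord_keys <- function(site_row) {
  co <- site_row$coord[[1]]
  sort(sprintf("%s|%s|%s|%d|%s", co$chain_id, co$res_name, co$atom_name,
               co$res_seq, co$i_code))
}

# Monte-Carlo ASA oracle: uniform random directions, independent of the
# golden-spiral lattice used by atom_asa().
mc_atom_asa <- function(target, context, params, n_points = 100000, seed = 99) {
  r_t <- params$halide_radii[["Cl"]] + params$water_radius
  withr::with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
  })
  pts <- sweep(dirs * r_t, 2, c(target$x, target$y, target$z), "+")
  exposed <- rep(TRUE, n_points)
  for (j in seq_len(nrow(context))) {
    r_c <- params$protein_atom_radii[[context$element[j]]] + params$water_radius
    d2 <- (pts[, 1] - context$x[j])^2 + (pts[, 2] - context$y[j])^2 +
      (pts[, 3] - context$z[j])^2
    exposed <- exposed & d2 >= r_c^2
  }
  mean(exposed) * 4 * pi * r_t^2
}

# random proper rotation matrix
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# minimal hand-built PDB lines
pdb_atom_line <- function(serial, name, res, chain, seq, x, y, z,
                          het = FALSE, occ = 1, b = 10, alt = " ",
                          element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  nm <- if (nchar(element) == 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, alt, res, chain, seq, " ",
          x, y, z, occ, b, toupper(element))
}

entry_tbl <- function(...) {
  tibble::tibble(...)
}
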