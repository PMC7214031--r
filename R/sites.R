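EXCLUDED_COORD_ELEMENTS <- c("C", "H", "D")
BACKBONE_ATOM_NAMES <- c("N", "O", "OXT")

new_sites_tibble <- function(rows) {
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      pdb_id = character(), species = character(), chain = character(),
      res_seq = integer(), i_code = character(),
      hx = double(), hy = double(), hz = double(),
      cn = integer(), n_waters = integer(),
      coord = list(), residues = list()
    )
  }
  class(out) <- c("halide_sites", class(tibble::tibble()))
  out
}

#' Extract halide-binding sites from a structure
#'
#' Builds one candidate site per halide atom. The coordinating set holds the
#' polymer atoms whose element is not carbon, hydrogen or deuterium and whose
#' centre-to-centre distance to the halide is at most the interaction-sphere
#' radius (5 angstrom by default). Water oxygens inside the sphere are counted
#' as solvation waters; with `params$include_waters = TRUE` they additionally
#' join the coordinating set and the coordination number. Other halide atoms
#' are never coordination partners. Distances, nearest-atom vector angles and
#' the coordination number are computed per site.
#'
#' @param structure A `halide_structure`, parsed and altloc-resolved.
#' @param params A [census_params()] object.
#' @return A `halide_sites` tibble, one row per halide atom, with list-columns
#'   `coord` (coordinating atoms with `distance` and `angle`) and `residues`
#'   (unique coordinating polymer residues), plus `cn` and `n_waters`.
#' @export
extract_sites <- function(structure, params = census_params()) {
  a <- structure$atoms
  halides <- a[a$record_class == "halide", , drop = FALSE]
  halides <- dplyr::arrange(halides, .data$chain_id, .data$res_seq, .data$i_code)
  eligible <- a[a$record_class == "polymer" &
                  !(a$element %in% EXCLUDED_COORD_ELEMENTS), , drop = FALSE]
  water_o <- a[a$record_class == "water" & a$element == "O", , drop = FALSE]

  rows <- purrr::map(
    seq_len(nrow(halides)),
    function(i) {
      h <- halides[i, ]
      hpos <- c(h$x, h$y, h$z)
      species <- species_for_code(h$res_name, params)

      dpol <- sqrt((eligible$x - hpos[1])^2 + (eligible$y - hpos[2])^2 +
                     (eligible$z - hpos[3])^2)
      keep <- dpol <= params$sphere_radius & dpol > 0
      coord <- eligible[keep, c("element", "atom_name", "res_name", "chain_id",
                                "res_seq", "i_code", "x", "y", "z",
                                "record_class"), drop = FALSE]
      coord$distance <- dpol[keep]

      dwat <- sqrt((water_o$x - hpos[1])^2 + (water_o$y - hpos[2])^2 +
                     (water_o$z - hpos[3])^2)
      wkeep <- dwat <= params$sphere_radius & dwat > 0
      wat <- water_o[wkeep, c("element", "atom_name", "res_name", "chain_id",
                              "res_seq", "i_code", "x", "y", "z",
                              "record_class"), drop = FALSE]
      n_waters <- nrow(dplyr::distinct(
        wat, .data$chain_id, .data$res_seq, .data$i_code
      ))
      if (params$include_waters && nrow(wat) > 0) {
        wat$distance <- dwat[wkeep]
        coord <- dplyr::bind_rows(coord, wat)
      }

      coord$angle <- if (nrow(coord) >= 2) {
        site_angles(
          hpos, as.matrix(coord[, c("x", "y", "z")]),
          tie_keys = sprintf("%s%09d%s", coord$chain_id, coord$res_seq,
                             coord$atom_name)
        )
      } else if (nrow(coord) == 1) {
        0
      } else {
        double()
      }

      residues <- coord |>
        dplyr::filter(.data$record_class == "polymer") |>
        dplyr::distinct(.data$res_name, .data$chain_id, .data$res_seq, .data$i_code)

      tibble::tibble(
        pdb_id = structure$pdb_id, species = species,
        chain = h$chain_id, res_seq = h$res_seq, i_code = h$i_code,
        hx = hpos[1], hy = hpos[2], hz = hpos[3],
        cn = nrow(coord), n_waters = n_waters,
        coord = list(coord), residues = list(residues)
      )
    }
  )
  new_sites_tibble(rows)
}

#' Drop sites contaminated by ligands or nucleic acids
#'
#' Removes every site that has at least one ligand-class atom — a non-water,
#' non-halide HETATM, or a DNA/RNA nucleotide — inside the interaction sphere,
#' so that only purely protein-coordinated halides remain.
#'
#' @param sites A `halide_sites` tibble.
#' @param structure The `halide_structure` the sites came from.
#' @param params A [census_params()] object.
#' @return The filtered sites tibble.
#' @export
reject_contaminated_sites <- function(sites, structure, params = census_params()) {
  if (nrow(sites) == 0) return(sites)
  lig <- structure$atoms[structure$atoms$record_class == "ligand", , drop = FALSE]
  if (nrow(lig) == 0) return(sites)
  clean <- purrr::map_lgl(seq_len(nrow(sites)), function(i) {
    d2 <- (lig$x - sites$hx[i])^2 + (lig$y - sites$hy[i])^2 + (lig$z - sites$hz[i])^2
    all(d2 > params$sphere_radius^2)
  })
  sites[clean, , drop = FALSE]
}

#' Drop sites coordinated by several chains
#'
#' Removes sites whose coordinating polymer atoms span more than one chain;
#' waters never count toward the chain spread, and sites with an empty
#' coordinating set are kept (zero chains).
#'
#' @param sites A `halide_sites` tibble.
#' @return The filtered sites tibble.
#' @export
reject_multichain_sites <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  keep <- purrr::map_lgl(sites$coord, function(co) {
    chains <- unique(co$chain_id[co$record_class == "polymer"])
    length(chains) <= 1
  })
  sites[keep, , drop = FALSE]
}

# composition key and matched point matrix for homologous-site comparison;
# atoms ordered by (res_name, atom_name), ties by distance-to-halide rank
# (then angle), halide prepended as an extra point. Atoms whose sort key is
# fully tied are genuinely interchangeable; their group ids let the RMSD be
# minimised over within-group permutations.
site_match_key <- function(co) {
  paste(sort(paste(co$res_name, co$atom_name, sep = "|")), collapse = ";")
}

site_match_points <- function(site_row) {
  co <- site_row$coord[[1]]
  rd <- round(co$distance, 3)
  ra <- round(co$angle, 2)
  ord <- order(co$res_name, co$atom_name, rd, ra)
  key <- paste(co$res_name, co$atom_name, rd, ra)[ord]
  list(
    points = rbind(
      c(site_row$hx, site_row$hy, site_row$hz),
      as.matrix(co[ord, c("x", "y", "z")])
    ),
    # group 0 = the halide itself (never permuted)
    groups = c(0L, match(key, unique(key)))
  )
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (k in seq_len(n)) {
    for (p in sub) out[[length(out) + 1L]] <- c(k, ifelse(p >= k, p + 1L, p))
  }
  out
}

# minimal superposition RMSD over the ambiguous within-group pairings
matched_site_rmsd <- function(ref, mov, max_combos = 720) {
  if (nrow(ref$points) <= 1) return(0)
  base <- superpose(ref$points, mov$points)$rmsd
  grp_sizes <- table(mov$groups[mov$groups > 0])
  n_combos <- prod(factorial(grp_sizes))
  if (all(grp_sizes == 1) || n_combos > max_combos || base < 1e-9) return(base)
  tied <- as.integer(names(grp_sizes)[grp_sizes > 1])
  orders <- list(seq_len(nrow(mov$points)))
  for (g in tied) {
    idx <- which(mov$groups == g)
    perms <- permutations_of(length(idx))
    orders <- unlist(lapply(orders, function(o) {
      lapply(perms, function(p) {
        o2 <- o
        o2[idx] <- o[idx][p]
        o2
      })
    }), recursive = FALSE)
  }
  min(vapply(orders, function(o) {
    superpose(ref$points, mov$points[o, , drop = FALSE])$rmsd
  }, numeric(1)))
}

#' Merge homologous site copies within an entry
#'
#' Crystallographic symmetry often repeats the same binding site several
#' times in one entry. Sites of one `pdb_id` and species are clustered
#' greedily in deterministic order (halide chain, residue number): a site is
#' discarded when a previously retained site has the identical composition
#' key — the sorted sequence of (residue name, atom name) of the coordinating
#' set — and the optimal rigid-body superposition RMSD of the matched
#' coordinates (the halide included as an extra point) is at or below the
#' threshold. The first member of each cluster is retained.
#'
#' @param sites A `halide_sites` tibble (any mix of entries/species; grouping
#'   is internal).
#' @param threshold RMSD threshold in angstrom (default 0.5).
#' @return The deduplicated sites tibble.
#' @export
dedup_homologous_sites <- function(sites, threshold = 0.5) {
  if (nrow(sites) <= 1) return(sites)
  sites <- dplyr::arrange(sites, .data$pdb_id, .data$species, .data$chain,
                          .data$res_seq, .data$i_code)
  grp <- paste(sites$pdb_id, sites$species, sep = "\r")
  keep <- rep(TRUE, nrow(sites))
  keys <- purrr::map_chr(sites$coord, site_match_key)
  matched <- purrr::map(seq_len(nrow(sites)), \(i) site_match_points(sites[i, ]))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    retained <- integer()
    for (i in idx) {
      dup <- FALSE
      for (j in retained) {
        if (keys[i] != keys[j]) next
        rmsd <- matched_site_rmsd(matched[[j]], matched[[i]])
        if (rmsd <= threshold) {
          dup <- TRUE
          break
        }
      }
      if (dup) keep[i] <- FALSE else retained <- c(retained, i)
    }
  }
  sites[keep, , drop = FALSE]
}
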