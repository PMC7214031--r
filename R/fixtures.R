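# Unit-vector vertex tables for the nine ideal coordination polyhedra,
# centred at the origin (vertices at unit distance from the central ion).
polyhedron_vertices <- function(geometry) {
  eq3 <- function(z) {
    r <- sqrt(1 - z^2)
    t(vapply(c(0, 2, 4) * pi / 3, \(a) c(r * cos(a), r * sin(a), z), numeric(3)))
  }
  sq4 <- function(z, rot = 0) {
    r <- sqrt(1 - z^2)
    t(vapply(rot + c(0, 0.5, 1, 1.5) * pi, \(a) c(r * cos(a), r * sin(a), z), numeric(3)))
  }
  switch(
    geometry,
    "linear" = rbind(c(0, 0, 1), c(0, 0, -1)),
    "trigonal" = eq3(0),
    "tetrahedral" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3),
    "square-pyramidal" = rbind(sq4(0), c(0, 0, 1)),
    "trigonal-bipyramidal" = rbind(eq3(0), c(0, 0, 1), c(0, 0, -1)),
    "octahedral" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                         c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    "capped-octahedral" = rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
      c(1, 1, 1) / sqrt(3)
    ),
    "square-antiprismatic" = rbind(sq4(0.6), sq4(-0.6, rot = pi / 4)),
    "tricapped-trigonal-prismatic" = rbind(
      eq3(0.6), eq3(-0.6),
      t(vapply(c(1, 3, 5) * pi / 3, \(a) c(cos(a), sin(a), 0), numeric(3)))
    ),
    stop(sprintf("unknown geometry '%s'", geometry), call. = FALSE)
  )
}

GEOMETRY_CN <- c(
  "linear" = 2L, "trigonal" = 3L, "tetrahedral" = 4L,
  "square-pyramidal" = 5L, "trigonal-bipyramidal" = 5L, "octahedral" = 6L,
  "capped-octahedral" = 7L, "square-antiprismatic" = 8L,
  "tricapped-trigonal-prismatic" = 9L
)

DEFAULT_GEOMETRY_FOR_CN <- c(
  "2" = "linear", "3" = "trigonal", "4" = "tetrahedral",
  "5" = "trigonal-bipyramidal", "6" = "octahedral", "7" = "capped-octahedral",
  "8" = "square-antiprismatic", "9" = "tricapped-trigonal-prismatic"
)

HALIDE_HET <- list(
  F = list(res = "F", element = "F"),
  Cl = list(res = "CL", element = "Cl"),
  Br = list(res = "BR", element = "Br"),
  I = list(res = "IOD", element = "I")
)

# coordinating partners a halide plausibly sees in proteins; (residue, atom)
PARTNER_POOL <- list(
  c("ARG", "NH1"), c("ARG", "NH2"), c("ARG", "NE"), c("LYS", "NZ"),
  c("SER", "OG"), c("THR", "OG1"), c("ASN", "ND2"), c("GLN", "NE2"),
  c("HIS", "NE2"), c("TYR", "OH"), c("GLY", "N"), c("ALA", "N"),
  c("SER", "N"), c("ALA", "O")
)

#' Specify one synthetic halide site
#'
#' Describes a synthetic binding site for [make_site_structure()]: the halide
#' species, an ideal coordination polyhedron scaled to a chosen anion-atom
#' distance with optional Gaussian positional noise, the partner residues
#' providing the coordinating atoms, solvation waters, and optional decoy
#' contaminants that are designed to trigger specific pipeline filters.
#'
#' @param species `"F"`, `"Cl"`, `"Br"` or `"I"`.
#' @param cn Coordination number, 2-9.
#' @param geometry One of the nine ideal polyhedra (`"linear"`, `"trigonal"`,
#'   `"tetrahedral"`, `"square-pyramidal"`, `"trigonal-bipyramidal"`,
#'   `"octahedral"`, `"capped-octahedral"`, `"square-antiprismatic"`,
#'   `"tricapped-trigonal-prismatic"`); default chosen from `cn`. Its vertex
#'   count must equal `cn`.
#' @param distance Halide-to-atom distance in angstrom (must be inside the
#'   5 angstrom interaction sphere).
#' @param noise_sigma Std. dev. (angstrom) of isotropic Gaussian noise added
#'   to each coordinating atom; 0 gives exact vertices.
#' @param partner_residues Optional list of `c(res_name, atom_name)` pairs,
#'   recycled over vertices; default: a seeded draw from a pool of plausible
#'   partners (Arg/Lys/His side chains, Ser/Thr hydroxyls, backbone amides).
#' @param n_waters Number of water molecules placed inside the sphere.
#' @param decoys Character vector among `"ligand"` (a sulfate inside the
#'   sphere: contaminated-site rejection), `"chain"` (a second-chain polymer
#'   atom inside the sphere: multichain rejection) and `"dna"` (a nucleotide
#'   ATOM record inside the sphere: contaminated-site rejection).
#' @param n_copies Number of exact translated copies of the site placed in
#'   the file (homologous copies; the pipeline merges them to one).
#' @param seed Integer seed making the file byte-reproducible.
#' @param resolution,method,protein_name,pdb_id Header metadata.
#' @param ss_probs Probabilities that each coordinating residue is annotated
#'   (via HELIX/SHEET records) as `none`, `helix` or `strand`.
#' @return A validated list of class `site_spec`.
#' @export
site_spec <- function(species = "Cl", cn = 5L,
                      geometry = NULL,
                      distance = 3.2, noise_sigma = 0,
                      partner_residues = NULL,
                      n_waters = 0L, decoys = character(), n_copies = 1L,
                      seed = 1L, resolution = 1.5,
                      method = "X-RAY DIFFRACTION",
                      protein_name = "synthetic halide-binding protein",
                      pdb_id = "SYNT",
                      ss_probs = c(none = 0.5, helix = 0.3, strand = 0.2)) {
  species <- match.arg(species, names(HALIDE_HET))
  cn <- as.integer(cn)
  stopifnot(cn >= 2, cn <= 9)
  if (is.null(geometry)) geometry <- DEFAULT_GEOMETRY_FOR_CN[[as.character(cn)]]
  geometry <- match.arg(geometry, names(GEOMETRY_CN))
  if (GEOMETRY_CN[[geometry]] != cn) {
    stop(sprintf("geometry '%s' has %d vertices but cn = %d",
                 geometry, GEOMETRY_CN[[geometry]], cn), call. = FALSE)
  }
  stopifnot(distance > 0, distance < 5.0, noise_sigma >= 0, n_copies >= 1)
  if (length(decoys) > 0) decoys <- match.arg(decoys, c("ligand", "chain", "dna"),
                                              several.ok = TRUE)
  structure(
    list(species = species, cn = cn, geometry = geometry, distance = distance,
         noise_sigma = noise_sigma, partner_residues = partner_residues,
         n_waters = as.integer(n_waters), decoys = decoys,
         n_copies = as.integer(n_copies), seed = as.integer(seed),
         resolution = resolution, method = method, protein_name = protein_name,
         pdb_id = pdb_id, ss_probs = ss_probs),
    class = "site_spec"
  )
}

format_pdb_atom <- function(serial, name, res_name, chain, res_seq, xyz,
                            element, hetatm = FALSE, occupancy = 1.0, b = 20.0) {
  name_field <- if (nchar(element) == 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetatm) "HETATM" else "ATOM", serial, name_field, " ",
          res_name, chain, res_seq, " ", xyz[1], xyz[2], xyz[3],
          occupancy, b, toupper(element))
}

# random unit vector from the active RNG stream
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic PDB file for one site specification
#'
#' Emits syntactically valid single-model PDB text: header records (HEADER,
#' EXPDTA, REMARK 2 resolution, COMPND molecule name, HELIX/SHEET), the
#' halide HETATM at the site centre, coordinating atoms at the ideal
#' polyhedron vertices scaled to the requested distance (plus seeded noise),
#' each embedded in a minimal dummy residue (the named atom and a CA carbon
#' placed radially outward), optional waters and decoy contaminants.
#' Repeated calls with the same spec are byte-identical.
#'
#' @param spec A [site_spec()].
#' @return Character vector of PDB lines.
#' @export
make_site_structure <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  withr::with_seed(spec$seed, {
    verts <- polyhedron_vertices(spec$geometry)
    partners <- spec$partner_residues
    if (is.null(partners)) {
      partners <- PARTNER_POOL[sample.int(length(PARTNER_POOL), spec$cn, replace = TRUE)]
    } else {
      partners <- rep(partners, length.out = spec$cn)
    }
    ss <- sample(names(spec$ss_probs), spec$cn, replace = TRUE, prob = spec$ss_probs)

    centre0 <- c(10, 10, 10)
    atom_pos <- verts * spec$distance +
      matrix(stats::rnorm(3 * spec$cn, sd = spec$noise_sigma), ncol = 3)

    # waters: random directions at 4.2 A, kept 2.0 A clear of placed atoms
    wdirs <- list()
    occupied <- rbind(c(0, 0, 0), atom_pos)
    for (w in seq_len(spec$n_waters)) {
      for (try in 1:200) {
        cand <- runit() * 4.2
        d <- sqrt(rowSums(sweep(occupied, 2, cand)^2))
        if (all(d > 2.0)) {
          wdirs[[length(wdirs) + 1]] <- cand
          occupied <- rbind(occupied, cand)
          break
        }
      }
    }

    decoy_pos <- list()
    if ("ligand" %in% spec$decoys) decoy_pos$ligand <- runit() * 4.0
    if ("chain" %in% spec$decoys) decoy_pos$chain <- runit() * 3.4
    if ("dna" %in% spec$decoys) decoy_pos$dna <- runit() * 4.5

    lines <- c(
      sprintf("HEADER    %-40s%9s   %4s", "SYNTHETIC HALIDE SITE", "01-JAN-20",
              spec$pdb_id),
      sprintf("COMPND   2 MOLECULE: %s;", toupper(spec$protein_name)),
      sprintf("EXPDTA    %s", spec$method)
    )
    if (!is.na(spec$resolution)) {
      lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                                spec$resolution))
    }

    # one HELIX/SHEET record per annotated dummy residue
    ser_h <- 0L
    ser_s <- 0L
    for (k in seq_len(spec$cn)) {
      rs <- 10L * k
      if (ss[k] == "helix") {
        ser_h <- ser_h + 1L
        lines <- c(lines, sprintf(
          "HELIX  %3d %3s %3s %1s %4d%1s %3s %1s %4d%1s%2d",
          ser_h, sprintf("H%d", ser_h), partners[[k]][1], "A", rs, " ",
          partners[[k]][1], "A", rs, " ", 1L))
      } else if (ss[k] == "strand") {
        ser_s <- ser_s + 1L
        lines <- c(lines, sprintf(
          "SHEET  %3d %3s%2d %3s %1s%4d%1s %3s %1s%4d%1s%2d",
          ser_s, sprintf("S%d", ser_s), 1L, partners[[k]][1], "A", rs, " ",
          partners[[k]][1], "A", rs, " ", 0L))
      }
    }

    het <- HALIDE_HET[[spec$species]]
    serial <- 0L
    nxt <- function() {
      serial <<- serial + 1L
      serial
    }
    for (copy in seq_len(spec$n_copies)) {
      shift <- centre0 + c(40 * (copy - 1), 0, 0)
      res_off <- 1000L * (copy - 1L)
      for (k in seq_len(spec$cn)) {
        p <- partners[[k]]
        u <- verts[k, ]
        apos <- atom_pos[k, ] + shift
        ca <- atom_pos[k, ] + u * 1.53 + shift
        elem <- substr(p[2], 1, 1)  # pool atoms are N/O single-letter elements
        lines <- c(
          lines,
          format_pdb_atom(nxt(), p[2], p[1], "A", 10L * k + res_off, apos, elem),
          format_pdb_atom(nxt(), "CA", p[1], "A", 10L * k + res_off, ca, "C")
        )
      }
      if ("chain" %in% spec$decoys) {
        lines <- c(lines, format_pdb_atom(nxt(), "N", "GLY", "B", 5L + res_off,
                                          decoy_pos$chain + shift, "N"))
      }
      if ("dna" %in% spec$decoys) {
        lines <- c(lines, format_pdb_atom(nxt(), "P", "DA", "C", 1L + res_off,
                                          decoy_pos$dna + shift, "P"))
      }
      lines <- c(lines, format_pdb_atom(nxt(), het$res, het$res, "A",
                                        101L + res_off, shift,
                                        het$element, hetatm = TRUE))
      if ("ligand" %in% spec$decoys) {
        lines <- c(lines, format_pdb_atom(nxt(), "S", "SO4", "A", 201L + res_off,
                                          decoy_pos$ligand + shift, "S",
                                          hetatm = TRUE))
      }
      for (w in seq_along(wdirs)) {
        lines <- c(lines, format_pdb_atom(nxt(), "O", "HOH", "W",
                                          300L + w + res_off,
                                          wdirs[[w]] + shift, "O", hetatm = TRUE))
      }
    }
    c(lines, "END")
  })
}

#' Generate a fixture corpus with a truth table
#'
#' Writes `n_structures` synthetic PDB files plus a plain-text truth TSV and
#' an entry-list TSV into `outdir`. The defaults emulate the census study
#' conditions: species mixed in proportion to the curated dataset
#' (F:Cl:Br:I = 25:3229:206:246), coordination numbers on 2-9 with the mode
#' at 5, per-site distances drawn around the per-species pooled medians
#' (4.09/4.11/4.17/4.28 angstrom), water counts peaked at the per-species
#' modes (I = 2, Cl = Br = 3, F = 4), about 10% of sites contaminated by a
#' second chain, 5% by a ligand, 3% by a nucleotide, and 15% of structures
#' carrying a duplicated homologous site copy.
#'
#' @param n_structures Number of PDB files to generate.
#' @param outdir Output directory (created).
#' @param seed Integer master seed; per-structure seeds are derived from it.
#' @param species_probs Named sampling weights over species.
#' @param cn_probs Named sampling weights over coordination numbers 2-9.
#' @param distance_medians Named per-species centre (angstrom) of the
#'   truncated-normal site-distance draw.
#' @param distance_sd Std. dev. of the distance draw (truncated to
#'   \[3.0, 4.95\] angstrom).
#' @param noise_sigma Per-atom Gaussian noise passed to each site.
#' @param water_modes Named per-species modal water counts.
#' @param decoy_rates Named rates for `ligand`, `chain`, `dna` decoys.
#' @param dup_rate Fraction of (decoy-free) structures written with a second
#'   identical site copy.
#' @return Invisibly, the truth tibble (also written as `truth.tsv`); columns:
#'   `file`, `pdb_id`, `species`, `geometry`, `cn`, `distance`, `n_waters`,
#'   `n_copies`, `decoy`, `expect_kept`, `noise_sigma`.
#' @export
make_corpus <- function(n_structures, outdir, seed = 1L,
                        species_probs = c(F = 25, Cl = 3229, Br = 206, I = 246),
                        cn_probs = c("2" = 0.03, "3" = 0.07, "4" = 0.12,
                                     "5" = 0.40, "6" = 0.18, "7" = 0.10,
                                     "8" = 0.06, "9" = 0.04),
                        distance_medians = c(F = 4.09, Cl = 4.11, Br = 4.17, I = 4.28),
                        distance_sd = 0.35,
                        noise_sigma = 0,
                        water_modes = c(F = 4, Cl = 3, Br = 3, I = 2),
                        decoy_rates = c(ligand = 0.05, chain = 0.10, dna = 0.03),
                        dup_rate = 0.15) {
  stopifnot(n_structures >= 1)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_structures), function(i) {
      sp <- sample(names(species_probs), 1, prob = species_probs)
      cn <- as.integer(sample(names(cn_probs), 1, prob = cn_probs))
      geometry <- if (cn == 5L) {
        sample(c("square-pyramidal", "trigonal-bipyramidal"), 1)
      } else {
        DEFAULT_GEOMETRY_FOR_CN[[as.character(cn)]]
      }
      d <- stats::rnorm(1, distance_medians[[sp]], distance_sd)
      d <- min(max(d, 3.0), 4.95)
      nw <- max(0L, water_modes[[sp]] + sample(c(-1L, 0L, 1L), 1,
                                               prob = c(0.2, 0.6, 0.2)))
      u <- stats::runif(1)
      decoy <- "none"
      cum <- cumsum(decoy_rates)
      if (u < cum[["ligand"]]) decoy <- "ligand"
      else if (u < cum[["chain"]]) decoy <- "chain"
      else if (u < cum[["dna"]]) decoy <- "dna"
      dup <- decoy == "none" && stats::runif(1) < dup_rate
      list(species = sp, cn = cn, geometry = geometry, distance = round(d, 3),
           n_waters = nw, decoy = decoy, n_copies = if (dup) 2L else 1L,
           resolution = round(stats::runif(1, 1.0, 1.9), 2))
    })
  })

  rows <- purrr::imap(draws, function(d, i) {
    id <- sprintf("S%03d", i)
    spec <- site_spec(
      species = d$species, cn = d$cn, geometry = d$geometry,
      distance = d$distance, noise_sigma = noise_sigma,
      n_waters = d$n_waters,
      decoys = if (d$decoy == "none") character() else d$decoy,
      n_copies = d$n_copies, seed = (seed * 1000L + i) %% .Machine$integer.max,
      resolution = d$resolution, pdb_id = id,
      protein_name = sprintf("synthetic protein %s", id)
    )
    file <- file.path(outdir, paste0(id, ".pdb"))
    writeLines(make_site_structure(spec), file)
    tibble::tibble(
      file = basename(file), pdb_id = id, species = d$species,
      geometry = d$geometry, cn = d$cn, distance = d$distance,
      n_waters = d$n_waters, n_copies = d$n_copies, decoy = d$decoy,
      expect_kept = d$decoy == "none", noise_sigma = noise_sigma,
      resolution = d$resolution
    )
  })
  truth <- dplyr::bind_rows(rows)
  readr::write_tsv(truth, file.path(outdir, "truth.tsv"), progress = FALSE)
  write_entry_list(
    tibble::tibble(
      pdb_id = truth$pdb_id, method = "X-RAY DIFFRACTION",
      resolution = truth$resolution,
      protein_name = sprintf("synthetic protein %s", truth$pdb_id)
    ),
    file.path(outdir, "entries.tsv")
  )
  invisible(truth)
}
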