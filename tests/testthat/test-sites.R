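test_that("extraction applies the element and radius rules", {
  txt <- c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 3.0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 2, 3.5, 0, 0),   # carbon: excluded
    pdb_atom_line(3, "O", "SER", "A", 3, 6.0, 0, 0),    # outside sphere
    pdb_atom_line(4, "OG", "SER", "A", 3, 0, 5.0, 0),   # exactly on boundary
    pdb_atom_line(5, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl")
  )
  s <- parse_structure(txt)
  sites <- extract_sites(s)
  expect_equal(nrow(sites), 1)
  expect_equal(sort(sites$coord[[1]]$atom_name), c("N", "OG"))
  expect_equal(sites$cn[1], 2)
  expect_true(all(sites$coord[[1]]$distance <= 5))
  expect_true(all(sites$coord[[1]]$distance > 0))
})

test_that("water handling follows the include_waters mode", {
  txt <- c(
    pdb_atom_line(1, "O", "HOH", "W", 1, 3.0, 0, 0, het = TRUE),
    pdb_atom_line(2, "O", "HOH", "W", 2, 0, 4.5, 0, het = TRUE),
    pdb_atom_line(3, "O", "HOH", "W", 3, 0, 0, 5.2, het = TRUE),  # outside
    pdb_atom_line(4, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl")
  )
  s <- parse_structure(txt)
  dry <- extract_sites(s, census_params(include_waters = FALSE))
  expect_equal(dry$cn[1], 0)
  expect_equal(dry$n_waters[1], 2)
  wet <- extract_sites(s, census_params(include_waters = TRUE))
  expect_equal(wet$cn[1], 2)
  expect_true(all(wet$coord[[1]]$record_class == "water"))
})

test_that("structures without halides give an empty site tibble", {
  s <- parse_structure(pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0))
  sites <- extract_sites(s)
  expect_s3_class(sites, "halide_sites")
  expect_equal(nrow(sites), 0)
})

test_that("contaminated sites are rejected only when the decoy is inside the sphere", {
  mk <- function(lig_dist) {
    c(pdb_atom_line(1, "N", "GLY", "A", 1, 3.0, 0, 0),
      pdb_atom_line(2, "S", "SO4", "A", 301, lig_dist, 0, 0, het = TRUE),
      pdb_atom_line(3, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl"))
  }
  s_in <- parse_structure(mk(4.2))
  expect_equal(nrow(reject_contaminated_sites(extract_sites(s_in), s_in)), 0)
  s_out <- parse_structure(mk(5.5))
  expect_equal(nrow(reject_contaminated_sites(extract_sites(s_out), s_out)), 1)
  # DNA counts as contamination
  dna <- c(pdb_atom_line(1, "N", "GLY", "A", 1, 3.0, 0, 0),
           pdb_atom_line(2, "P", "DA", "C", 1, 0, 4.8, 0),
           pdb_atom_line(3, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl"))
  s_dna <- parse_structure(dna)
  expect_equal(nrow(reject_contaminated_sites(extract_sites(s_dna), s_dna)), 0)
})

test_that("multichain sites are rejected; waters and empty sets do not count", {
  txt <- c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 3.0, 0, 0),
    pdb_atom_line(2, "N", "GLY", "B", 1, 0, 3.0, 0),
    pdb_atom_line(3, "O", "HOH", "W", 1, 0, 0, 3.0, het = TRUE),
    pdb_atom_line(4, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl"),
    pdb_atom_line(5, "BR", "BR", "A", 102, 50, 50, 50, het = TRUE, element = "Br")
  )
  s <- parse_structure(txt)
  sites <- extract_sites(s, census_params(include_waters = TRUE))
  out <- reject_multichain_sites(sites)
  # chloride site spans chains A+B -> dropped; empty bromide site kept
  expect_equal(out$species, "Br")
  one_chain <- parse_structure(txt[-2])
  expect_equal(nrow(reject_multichain_sites(extract_sites(one_chain))), 2)
})

test_that("rejection filters commute", {
  spec <- site_spec(species = "Cl", cn = 5, distance = 3.4,
                    decoys = c("ligand", "chain"), seed = 17)
  s <- select_altlocs(parse_structure(make_site_structure(spec)))
  sites <- extract_sites(s)
  a <- reject_multichain_sites(reject_contaminated_sites(sites, s))
  b <- reject_contaminated_sites(reject_multichain_sites(sites), s)
  expect_identical(a, b)
})

test_that("homologous copies are merged; distinct or distant sites are kept", {
  spec <- site_spec(species = "I", cn = 4, distance = 3.4, n_copies = 3,
                    noise_sigma = 0.03, seed = 13)
  s <- select_altlocs(parse_structure(make_site_structure(spec)))
  sites <- extract_sites(s)
  expect_equal(nrow(sites), 3)
  dd <- dedup_homologous_sites(sites)
  expect_equal(nrow(dd), 1)
  # idempotence
  expect_identical(dedup_homologous_sites(dd), dd)

  # same composition but RMSD above threshold: both survive
  base <- c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 3.0, 0, 0),
    pdb_atom_line(2, "OG", "SER", "A", 2, 0, 3.0, 0),
    pdb_atom_line(3, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl"),
    # second copy: same key, one atom pushed 2 A out of register
    pdb_atom_line(4, "N", "GLY", "A", 11, 43.0, 0, 0),
    pdb_atom_line(5, "OG", "SER", "A", 12, 40, 5.0, 0),
    pdb_atom_line(6, "CL", "CL", "A", 102, 40, 0, 0, het = TRUE, element = "Cl")
  )
  s2 <- parse_structure(base)
  sites2 <- extract_sites(s2)
  expect_equal(nrow(dedup_homologous_sites(sites2)), 2)

  # different composition keys: kept without any RMSD computation
  diff <- c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 3.0, 0, 0),
    pdb_atom_line(2, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl"),
    pdb_atom_line(3, "OG", "SER", "A", 2, 43.0, 0, 0),
    pdb_atom_line(4, "CL", "CL", "A", 102, 40, 0, 0, het = TRUE, element = "Cl")
  )
  s3 <- parse_structure(diff)
  expect_equal(nrow(dedup_homologous_sites(extract_sites(s3))), 2)
})

test_that("extraction matches the brute-force oracle on varied fixtures", {
  for (seed in 1:25) {
    spec <- withr::with_seed(seed, site_spec(
      species = sample(c("F", "Cl", "Br", "I"), 1),
      cn = sample(2:9, 1),
      distance = runif(1, 3.0, 4.8),
      noise_sigma = runif(1, 0, 0.1),
      n_waters = sample(0:4, 1),
      decoys = if (runif(1) < 0.3) sample(c("ligand", "chain", "dna"), 1) else character(),
      n_copies = sample(1:2, 1),
      seed = seed
    ))
    params <- census_params(include_waters = seed %% 2 == 0)
    s <- select_altlocs(parse_structure(make_site_structure(spec)))
    got <- extract_sites(s, params)
    got <- dplyr::arrange(got, .data$chain, .data$res_seq)
    want <- brute_force_sites(s, params)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$cn[i], want[[i]]$cn)
      expect_equal(got$n_waters[i], want[[i]]$n_waters)
      expect_equal(site_coord_keys(got[i, ]), want[[i]]$coord_keys)
    }
  }
})
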