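test_that("atoms are classified by record type and residue code", {
  txt <- c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 3.2),
    pdb_atom_line(2, "CL", "CL", "A", 101, 0, 0, 0, het = TRUE, element = "Cl"),
    pdb_atom_line(3, "O", "HOH", "W", 201, 4, 0, 0, het = TRUE),
    pdb_atom_line(4, "S", "SO4", "A", 301, 8, 0, 0, het = TRUE),
    pdb_atom_line(5, "P", "DA", "C", 1, 9, 0, 0),
    pdb_atom_line(6, "I", "IOD", "A", 102, 12, 0, 0, het = TRUE, element = "I")
  )
  s <- parse_structure(txt)
  expect_equal(s$atoms$record_class,
               c("polymer", "halide", "water", "ligand", "ligand", "halide"))
  # classification is total over HETATM records
  het <- s$atoms$record_class[c(2, 3, 4, 6)]
  expect_true(all(het %in% c("halide", "water", "ligand")))
})

test_that("only the first MODEL is retained", {
  mk <- function(seq0) {
    vapply(1:10, \(k) pdb_atom_line(k, "N", "GLY", "A", seq0 + k, k, 0, 0),
           character(1))
  }
  txt <- c("MODEL        1", mk(0), "ENDMDL", "MODEL        2", mk(100), "ENDMDL")
  s <- parse_structure(txt)
  expect_equal(nrow(s$atoms), 10)
  expect_true(all(s$atoms$res_seq <= 10))
})

test_that("header metadata is read regardless of record order", {
  atoms <- pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0)
  hdr <- c("REMARK   2 RESOLUTION.    1.50 ANGSTROMS.",
           "EXPDTA    X-RAY DIFFRACTION",
           "COMPND   2 MOLECULE: LYSOZYME  C;")
  for (ord in list(1:3, 3:1, c(2, 1, 3))) {
    s <- parse_structure(c(hdr[ord], atoms))
    expect_equal(s$resolution, 1.50)
    expect_equal(s$method, "X-RAY DIFFRACTION")
    expect_equal(s$protein_name, "lysozyme c")
  }
  s <- parse_structure(c("REMARK   2 RESOLUTION. NOT APPLICABLE.", atoms))
  expect_true(is.na(s$resolution))
})

test_that("malformed or empty input raises informative errors", {
  bad <- pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0)
  substr(bad, 31, 38) <- "  xx.yyy"
  expect_error(parse_structure(bad), "line 1")
  expect_error(parse_structure("REMARK   2"), "empty structure")
  noelem <- "ATOM      1  123 GLY A   1       0.000   0.000   0.000  1.00 10.00"
  expect_error(parse_structure(noelem), "infer element")
})

test_that("altloc selection keeps highest occupancy, ties to smallest altloc", {
  txt <- c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, alt = "A", occ = 0.6),
    pdb_atom_line(2, "CA", "SER", "A", 1, 1, 0, 0, alt = "B", occ = 0.4),
    pdb_atom_line(3, "OG", "SER", "A", 1, 0, 1, 0, alt = "B", occ = 0.5),
    pdb_atom_line(4, "OG", "SER", "A", 1, 0, 2, 0, alt = "A", occ = 0.5),
    pdb_atom_line(5, "N", "SER", "A", 1, 0, 3, 0, occ = 0.0)
  )
  s <- select_altlocs(parse_structure(txt))
  expect_equal(nrow(s$atoms), 2)
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  expect_equal(ca$alt_loc, "A")
  og <- s$atoms[s$atoms$atom_name == "OG", ]
  expect_equal(og$alt_loc, "A")  # 0.5/0.5 tie
  expect_false("N" %in% s$atoms$atom_name)  # zero occupancy removed
})

test_that("generator output round-trips through the parser", {
  spec <- site_spec(species = "Br", cn = 5, geometry = "square-pyramidal",
                    distance = 3.3, noise_sigma = 0.05, n_waters = 2, seed = 11)
  txt <- make_site_structure(spec)
  s <- parse_structure(txt)
  written <- s$atoms
  expect_equal(sum(written$record_class == "halide"), 1)
  expect_equal(sum(written$record_class == "water"), 2)
  # coordinates survive to 3 decimals
  reparsed <- parse_structure(txt)$atoms
  expect_equal(written$x, reparsed$x, tolerance = 1e-9)
  expect_equal(written$element, reparsed$element)
})

test_that("site table writing is deterministic and round-trips", {
  spec <- site_spec(species = "Cl", cn = 4, distance = 3.4, n_waters = 1, seed = 5)
  s <- select_altlocs(parse_structure(make_site_structure(spec)))
  sites <- annotate_sites(add_fasa(extract_sites(s), s), s)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_site_table(sites, f1)
  write_site_table(sites, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_site_table(f1)
  expect_equal(as.data.frame(rt), as.data.frame(tab))
  # header-only file for an empty site list
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites[0, ], f3)
  expect_equal(length(readLines(f3)), 1)
  # 2 sites -> 3 lines
  spec2 <- site_spec(species = "Cl", cn = 3, distance = 3.2, n_copies = 2, seed = 6)
  s2 <- select_altlocs(parse_structure(make_site_structure(spec2)))
  sites2 <- annotate_sites(add_fasa(extract_sites(s2), s2), s2)
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites2, f4)
  expect_equal(length(readLines(f4)), 3)
})
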