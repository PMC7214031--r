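cl_atom <- function(x = 0, y = 0, z = 0) {
  tibble::tibble(element = "Cl", atom_name = "CL", res_name = "CL",
                 chain_id = "A", res_seq = 101L, i_code = "",
                 x = x, y = y, z = z, occupancy = 1, b_factor = 0,
                 record_class = "halide")
}

ctx_atom <- function(element, x, y, z, res = "GLY", class = "polymer") {
  tibble::tibble(element = element, atom_name = element, res_name = res,
                 chain_id = "A", res_seq = 1L, i_code = "",
                 x = x, y = y, z = z, occupancy = 1, b_factor = 0,
                 record_class = class)
}

test_that("isolated atom area matches the closed form", {
  p <- census_params()
  r <- 1.67 + 1.4
  expect_equal(atom_asa(cl_atom(), cl_atom()[0, ], p), 4 * pi * r^2,
               tolerance = 1e-9)
})

test_that("a fully enclosed atom has zero area and fASA zero", {
  p <- census_params()
  # shell of large overlapping spheres on octahedral directions
  shell <- dplyr::bind_rows(purrr::map(list(
    c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0), c(0, 0, 3), c(0, 0, -3),
    c(2, 2, 2), c(-2, 2, 2), c(2, -2, 2), c(2, 2, -2),
    c(-2, -2, 2), c(-2, 2, -2), c(2, -2, -2), c(-2, -2, -2)
  ), \(v) ctx_atom("S", v[1], v[2], v[3])))
  expect_equal(atom_asa(cl_atom(), shell, p), 0)
})

test_that("two-atom systems agree with a high-density Monte-Carlo oracle", {
  p <- census_params()
  for (d in c(3.0, 3.5, 4.2, 5.0)) {
    ctx <- ctx_atom("N", d, 0, 0)
    got <- atom_asa(cl_atom(), ctx, p)
    want <- mc_atom_asa(cl_atom(), ctx, p)
    expect_equal(got, want, tolerance = 0.01)
  }
})

test_that("fASA is a fraction, monotone under occlusion, and 1 when isolated", {
  p <- census_params()
  halide_line <- pdb_atom_line(1, "CL", "CL", "A", 101, 0, 0, 0,
                               het = TRUE, element = "Cl")
  s0 <- parse_structure(halide_line)
  expect_equal(fractional_asa(s0$atoms[1, ], s0, p), 1)

  lines <- halide_line
  prev <- 1
  dirs <- list(c(3.2, 0, 0), c(0, 3.2, 0), c(0, 0, 3.2), c(-3.2, 0, 0),
               c(0, -3.2, 0), c(0, 0, -3.2))
  for (k in seq_along(dirs)) {
    lines <- c(lines, pdb_atom_line(k + 1, "N", "GLY", "A", k,
                                    dirs[[k]][1], dirs[[k]][2], dirs[[k]][3]))
    s <- parse_structure(lines)
    h <- s$atoms[s$atoms$record_class == "halide", ]
    f <- fractional_asa(h, s, p)
    expect_gte(f, 0)
    expect_lte(f, prev + 1e-12)  # adding an occluder never increases fASA
    prev <- f
  }
})

test_that("a wall of atoms occludes about half the sphere", {
  p <- census_params()
  # N expanded spheres (1.55 + 1.4 = 2.95 A) centred in the x = 2.95 plane:
  # their occlusion boundary passes through the halide centre, so exactly the
  # +x hemisphere of the probe sphere is buried (up to wall corrugation)
  grid <- expand.grid(y = seq(-12, 12, by = 1.2), z = seq(-12, 12, by = 1.2))
  wall <- dplyr::bind_rows(purrr::map2(grid$y, grid$z,
                                       \(y, z) ctx_atom("N", 2.95, y, z)))
  got <- atom_asa(cl_atom(), wall, p) / (4 * pi * (1.67 + 1.4)^2)
  expect_equal(got, 0.5, tolerance = 0.06)
})

test_that("the sampled area converges with point density and is rotation invariant", {
  ctx <- ctx_atom("O", 3.4, 0.5, -0.2)
  a1 <- atom_asa(cl_atom(), ctx, census_params(sasa_points = 960))
  a2 <- atom_asa(cl_atom(), ctx, census_params(sasa_points = 3840))
  expect_equal(a1, a2, tolerance = 0.01)

  withr::with_seed(71, {
    R <- random_rotation()
    t0 <- c(5, -3, 2)
    h <- as.numeric(R %*% c(0, 0, 0) + t0)
    c2 <- as.numeric(R %*% c(3.4, 0.5, -0.2) + t0)
    a3 <- atom_asa(cl_atom(h[1], h[2], h[3]),
                   ctx_atom("O", c2[1], c2[2], c2[3]),
                   census_params(sasa_points = 960))
  })
  expect_equal(a3, a1, tolerance = 0.5)
})

test_that("a missing element radius raises a configuration error", {
  p <- census_params()
  expect_error(atom_asa(cl_atom(), ctx_atom("Fe", 3, 0, 0), p), "Fe")
})
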