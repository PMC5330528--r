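test_that("unit cells validate their parameters and geometry", {
  expect_error(unit_cell(-1, 5, 5), "positive")
  expect_error(unit_cell(5, 5, 5, 0, 90, 90), "between 0 and 180")
  expect_error(unit_cell(5, 5, 5, 190, 90, 90), "between 0 and 180")
  # near-degenerate angle combination has (essentially) no volume
  expect_error(unit_cell(5, 5, 5, 1, 1, 2), "volume")
  cell <- unit_cell(4, 6, 8, 80, 95, 100)
  expect_equal(cell_volume(cell), abs(det(cell_matrix(cell))), tolerance = 1e-10)
})

test_that("perpendicular widths equal volume over face area", {
  cell <- unit_cell(13, 17, 26)
  expect_equal(cell_perp_widths(cell), c(13, 17, 26), tolerance = 1e-10)
  mono <- unit_cell(10, 10, 10, 90, 120, 90)
  w <- cell_perp_widths(mono)
  # oblique cell: widths shrink below the edge lengths
  expect_true(all(w[c(1, 3)] < 10))
  expect_equal(w[2], 10, tolerance = 1e-10)
})

test_that("fractional/Cartesian conversion round-trips", {
  cell <- unit_cell(9, 7, 11, 85, 95, 103)
  set.seed(1)
  f <- matrix(runif(30), ncol = 3)
  expect_equal(cart_to_frac(frac_to_cart(f, cell), cell), f, tolerance = 1e-12)
})

test_that("a minimal P1 CIF block parses to a 2-site crystal", {
  text <- c(
    "data_tiny",
    "_cell_length_a 10.0", "_cell_length_b 10.0", "_cell_length_c 10.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.2 0.3", "O1 O 0.4 0.5 0.6"
  )
  xs <- read_cif(text = text)
  expect_length(xs, 1)
  x <- xs$tiny
  expect_equal(nrow(x$sites), 2)
  expect_identical(x$symmetry, "x,y,z")
  expect_identical(x$sites$label, c("C1", "O1"))
  expect_equal(x$sites$fz, c(0.3, 0.6))
})

test_that("multi-block CIF yields one crystal per block, named by block", {
  one <- write_cif(random_crystal(1))
  two <- write_cif(random_crystal(2))
  xs <- read_cif(text = c(one, two))
  expect_length(xs, 2)
  expect_identical(names(xs), c("random_1", "random_2"))
})

test_that("CIF write/read round-trips cells and coordinates to 1e-6", {
  for (seed in 1:5) {
    x <- random_crystal(seed)
    y <- read_cif(text = write_cif(x))[[1]]
    expect_equal(as.numeric(y$cell), as.numeric(x$cell), tolerance = 1e-6)
    expect_equal(crystal_frac(y), crystal_frac(x), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(y$sites$label, x$sites$label)
  }
})

test_that("malformed CIF input fails with a block-naming error", {
  expect_error(read_cif(text = c("data_bad", "_cell_length_a 5")),
               "bad.*missing cell|missing cell.*bad")
  nocell <- c("data_x", "_cell_length_a 5", "_cell_length_b 5",
              "_cell_length_c 5", "_cell_angle_alpha 90",
              "_cell_angle_beta 90", "_cell_angle_gamma 90")
  expect_error(read_cif(text = nocell), "atom_site")
  dup <- c(nocell, "loop_", "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
           "C1 C 0 0 0", "C1 C 0.5 0.5 0.5")
  expect_error(read_cif(text = dup), "duplicate")
})

test_that("to_p1 applies operators, merges special positions, is idempotent", {
  cell <- unit_cell(10, 10, 10)
  sites <- data.frame(label = "C1", element = "C", fx = 0.1, fy = 0.1, fz = 0.1)
  x <- crystal(cell, sites, symmetry = c("x,y,z", "-x,-y,-z"))
  p1 <- to_p1(x)
  expect_equal(nrow(p1$sites), 2)
  expect_identical(p1$symmetry, "x,y,z")
  # general position expands; inversion centre merges to a single site
  origin <- crystal(cell, transform(sites, fx = 0, fy = 0, fz = 0),
                    symmetry = c("x,y,z", "-x,-y,-z"))
  expect_equal(nrow(to_p1(origin)$sites), 1)
  # already P1 passes through unchanged
  y <- to_p1(p1)
  expect_equal(crystal_frac(y), crystal_frac(p1), tolerance = 1e-12)
  expect_error(to_p1(crystal(cell, sites, symmetry = "x,q,z")), "q")
})

test_that("to_p1 handles translation operators (2_1 screw)", {
  cell <- unit_cell(10, 10, 10)
  sites <- data.frame(label = "C1", element = "C", fx = 0.1, fy = 0.2, fz = 0.3)
  x <- crystal(cell, sites, symmetry = c("x,y,z", "-x,-y,z+1/2"))
  p1 <- to_p1(x)
  expect_equal(nrow(p1$sites), 2)
  expect_equal(unname(crystal_frac(p1)[2, ]), c(0.9, 0.8, 0.8), tolerance = 1e-12)
})

test_that("expanding an asymmetric unit by a screw yields Z whole molecules", {
  # one molecule in the asymmetric unit + the 2_1 operator reproduce the
  # Z = 2 packing of toy_crystal()
  full <- toy_crystal()
  asym <- full$sites[!grepl("_2$", full$sites$label), ]
  x <- crystal(full$cell, asym, symmetry = c("x,y,z", "-x,-y,z+1/2"),
               z_prime = 1)
  p1 <- to_p1(x)
  expect_equal(nrow(p1$sites), nrow(full$sites))
  topo <- perceive_bonds(p1)
  expect_length(topo$molecules, 2)
  expect_equal(rmscd_crystals(p1, full)$rmscd, 0, tolerance = 1e-9)
})

test_that("supercell replication meets the minimum perpendicular span", {
  cubic50 <- crystal(unit_cell(50, 50, 50),
                     data.frame(label = "C1", element = "C", fx = 0.1, fy = 0.1, fz = 0.1))
  expect_equal(build_supercell(cubic50, 50)$replication, c(1L, 1L, 1L))
  cubic10 <- crystal(unit_cell(10, 10, 10),
                     data.frame(label = "C1", element = "C", fx = 0.1, fy = 0.1, fz = 0.1))
  sc <- build_supercell(cubic10, 50)
  expect_equal(sc$replication, c(5L, 5L, 5L))
  expect_equal(nrow(sc$crystal$sites), 125)
  ortho <- crystal(unit_cell(13, 17, 26),
                   data.frame(label = "C1", element = "C", fx = 0, fy = 0, fz = 0))
  sc2 <- build_supercell(ortho, 50)
  expect_equal(sc2$replication, c(4L, 3L, 2L))
  expect_true(all(cell_perp_widths(sc2$crystal$cell) >= 50))
})

test_that("build_supercell is idempotent once the span is satisfied", {
  x <- toy_crystal()
  sc <- build_supercell(x, 20)
  again <- build_supercell(sc$crystal, 20)
  expect_equal(again$replication, c(1L, 1L, 1L))
  # molecule count multiplies with the replication
  expect_equal(sc$crystal$z_value, x$z_value * prod(sc$replication))
  topo <- perceive_bonds(sc$crystal)
  expect_length(topo$molecules, sc$crystal$z_value)
})

test_that("bond perception uses covalent radii with minimum-image distances", {
  cell <- unit_cell(20, 20, 20)
  two_c <- function(d) {
    crystal(cell, data.frame(label = c("C1", "C2"), element = "C",
                             fx = c(0, d / 20), fy = 0, fz = 0))
  }
  expect_equal(nrow(perceive_bonds(two_c(1.5))$bonds), 1)
  expect_equal(nrow(perceive_bonds(two_c(3.0))$bonds), 0)
  # threshold is r_i + r_j + tolerance = 1.92 exactly
  expect_equal(nrow(perceive_bonds(two_c(1.91))$bonds), 1)
  expect_equal(nrow(perceive_bonds(two_c(1.93))$bonds), 0)
  # bonding across the periodic boundary
  cell15 <- unit_cell(15, 15, 15)
  edge <- crystal(cell15, data.frame(label = c("C1", "C2"), element = "C",
                                     fx = c(0.05, 0.95), fy = 0, fz = 0))
  expect_equal(nrow(perceive_bonds(edge)$bonds), 1)
  expect_error(perceive_bonds(crystal(cell, data.frame(
    label = "X1", element = "Xx", fx = 0, fy = 0, fz = 0))), "Xx")
})

test_that("methyl groups need exactly three H and one heavy neighbour", {
  topo <- perceive_bonds(toy_crystal())
  expect_length(topo$methyl_groups, 4)  # two methyls per molecule, Z = 2
  carbons <- vapply(topo$methyl_groups, function(m) nmrcsp:::base_label(m$carbon), "")
  expect_setequal(unique(carbons), c("C1", "C5"))
  # methane-like: four H, no heavy neighbour -> not a methyl
  cell <- unit_cell(15, 15, 15)
  d <- 1.09 / 15
  methane <- crystal(cell, data.frame(
    label = c("C1", "H1", "H2", "H3", "H4"), element = c("C", rep("H", 4)),
    fx = c(0.5, 0.5 + d, 0.5 - d, 0.5, 0.5),
    fy = c(0.5, 0.5, 0.5, 0.5 + d, 0.5 - d),
    fz = 0.5))
  expect_length(perceive_bonds(methane)$methyl_groups, 0)
})

test_that("bond perception is invariant under rigid fractional translation", {
  x <- toy_crystal()
  topo <- perceive_bonds(x)
  for (shift in list(c(0.3, 0, 0), c(0.17, 0.52, 0.81))) {
    frac <- sweep(crystal_frac(x), 2, shift, "+")
    y <- nmrcsp:::set_frac(x, nmrcsp:::wrap_frac(frac))
    topo2 <- perceive_bonds(y)
    expect_equal(nrow(topo2$bonds), nrow(topo$bonds))
    expect_length(topo2$molecules, length(topo$molecules))
    expect_length(topo2$methyl_groups, length(topo$methyl_groups))
  }
})

test_that("disordered (partial-occupancy) structures are readable but flagged", {
  expect_error(crystal(unit_cell(10, 10, 10),
                       data.frame(label = "C1", element = "C", fx = 0, fy = 0,
                                  fz = 0, occ = 1.2)), "occupanc")
  half <- crystal(unit_cell(10, 10, 10),
                  data.frame(label = "C1", element = "C", fx = 0, fy = 0,
                             fz = 0, occ = 0.5))
  expect_equal(half$sites$occ, 0.5)
})
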