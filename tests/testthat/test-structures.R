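test_that("PDB records are converted to nm and unknown types are reported", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1   X  RES A   1      10.000  20.000 -30.000  1.00  0.00",
    "END"), pdb)
  s <- read_structure(pdb, fix_table())
  expect_equal(nrow(s$atoms), 1)
  expect_equal(unname(unlist(s$atoms[1, c("x", "y", "z")])),
               c(1.0, 2.0, -3.0), tolerance = 1e-9)
  expect_equal(s$atoms$sigma, 0.32)

  writeLines(c(
    "ATOM      1  XX  RES A   1      10.000  20.000 -30.000  1.00  0.00",
    "END"), pdb)
  expect_error(read_structure(pdb, fix_table()), "XX")
})

test_that("text-table serialization round-trips a structure", {
  s <- build_sphere(0.8, 0.25, "XQ", fix_table())
  path <- tempfile()
  write_structure(s, path)
  s2 <- read_structure_table(path)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-9)
  expect_equal(s2$atoms$charge, s$atoms$charge)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
})

test_that("sphere builder matches brute-force lattice enumeration", {
  expect_error(build_sphere(0.2, 0.3, "X", fix_table()))
  radius <- 1.0; spacing <- 0.25
  s <- build_sphere(radius, spacing, "X", fix_table())
  # independent oracle: enumerate all lattice points within the sphere
  rng <- seq(-ceiling(radius / spacing), ceiling(radius / spacing)) * spacing
  grid <- expand.grid(rng, rng, rng)
  n_oracle <- sum(sqrt(rowSums(grid^2)) <= radius + 1e-12)
  expect_equal(nrow(s$atoms), n_oracle)
  pos <- as.matrix(s$atoms[, c("x", "y", "z")])
  expect_true(all(sqrt(rowSums(pos^2)) <= radius + 1e-9))
})

test_that("cylindrical pore builder respects the annulus and its count", {
  expect_error(build_cylindrical_pore(1, -0.1, 2, 0.3, "X", fix_table()))
  s <- build_cylindrical_pore(1.0, 0.6, 2.0, 0.3, "X", fix_table())
  ctr <- s$box[1] / 2
  rad <- sqrt((s$atoms$x - ctr)^2 + (s$atoms$y - ctr)^2)
  expect_true(all(rad >= 1.0 - 1e-9 & rad <= 1.6 + 1e-9))
  # oracle: enumerate annulus lattice points directly
  rng <- seq(-6, 6) * 0.3
  zz <- seq(0, 2.0 - 0.15, by = 0.3)
  grid <- expand.grid(x = rng, y = rng, z = zz)
  rr <- sqrt(grid$x^2 + grid$y^2)
  expect_equal(nrow(s$atoms), sum(rr >= 1.0 - 1e-12 & rr <= 1.6 + 1e-12))
  s2 <- build_cylindrical_pore(2.0, 0.6, 2.0, 0.3, "X", fix_table())
  expect_gt(nrow(s2$atoms), nrow(s$atoms))
})

test_that("armchair nanotube has the rolled-lattice diameter and is cylindrical", {
  expect_error(build_cnt(5, 3, 2), "chirality")
  cnt <- build_cnt(5, 5, 2.0)
  # closed-form rolling oracle: d = (a/pi) sqrt(n^2 + nm + m^2)
  a <- sqrt(3) * 0.142
  d_oracle <- a / pi * sqrt(25 + 25 + 25)
  rad <- sqrt(cnt$atoms$x^2 + cnt$atoms$y^2)
  expect_equal(2 * rad, rep(d_oracle, length(rad)), tolerance = 1e-6)
  expect_lt(diff(range(rad)), 1e-6)
  # doubling the length doubles the atom count up to one ring (2n atoms)
  n1 <- nrow(build_cnt(5, 5, 2.0)$atoms)
  n2 <- nrow(build_cnt(5, 5, 4.0)$atoms)
  expect_lte(abs(n2 - 2 * n1), 2 * 5 * 2)
  # neutral carbons with the combined CNT-water LJ parameters
  expect_true(all(cnt$atoms$charge == 0))
  expect_equal(unique(cnt$atoms$sigma), 0.36)
  expect_equal(unique(cnt$atoms$epsilon), 0.29)
})

test_that("planar slab is a lattice with a +z surface layer", {
  s1 <- build_planar_slab(4, 1, 0.3, "X", fix_table())
  expect_true(all(s1$atoms$z == 0))
  s <- build_planar_slab(4, 3, 0.3, "X", fix_table())
  expect_setequal(unique(s$atoms$z), c(0, -0.3, -0.6))
  top <- s$atoms[s$atoms$is_surface, ]
  expect_true(all(top$z == 0))
  # nearest-neighbour spacing preserved
  pos <- as.matrix(s$atoms[, c("x", "y", "z")])
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  expect_equal(min(d), 0.3, tolerance = 1e-9)
})

test_that("builders are deterministic and validate their outputs", {
  a <- build_sphere(0.9, 0.3, "XQ", fix_table())
  b <- build_sphere(0.9, 0.3, "XQ", fix_table())
  expect_identical(a, b)
  expect_identical(build_cnt(5, 5, 1.5), build_cnt(5, 5, 1.5))
  for (s in list(a, build_cnt(5, 5, 1.5),
                 build_cylindrical_pore(1, 0.6, 1.5, 0.3, "X", fix_table())))
    expect_silent(validate_structure(s))
})

test_that("structure invariants are enforced", {
  expect_error(structure_from(matrix(c(0, 0, NA), 1)), "finite")
  atoms <- data.frame(id = c(1L, 1L), type = "X", x = c(0, 1), y = 0, z = 0,
                      epsilon = 0.65, sigma = 0.32, charge = 0,
                      is_surface = FALSE)
  expect_error(nanoconfine:::new_param_structure(atoms), "unique")
  expect_error(structure_from(matrix(c(5, 0, 0), 1), box = c(2, 2, 2)),
               "inside")
})
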