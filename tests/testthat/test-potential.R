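kBT300 <- nanoconfine:::kBT_kJmol(300)

test_that("Langevin function limits and reference value", {
  expect_equal(langevin(0), 0)
  expect_equal(langevin(1e3), 1 - 1e-3, tolerance = 1e-9)
  # coth(1) - 1 via the exponential form (e^2 + 1)/(e^2 - 1) - 1
  ref <- (exp(2) + 1) / (exp(2) - 1) - 1
  expect_equal(langevin(1), ref, tolerance = 1e-12)
  # the series branch agrees with the direct formula at the switchover
  x <- 9.9e-4
  expect_equal(langevin(x), 1 / tanh(x) - 1 / x, tolerance = 1e-9)
})

test_that("dipole energy has the Langevin weak- and strong-field limits", {
  w <- water_model()
  expect_equal(dipole_energy(0, w, 300), 0)
  kB <- 1.380649e-23; NA_ <- 6.02214076e23
  # weak field: U -> -mu^2 E^2 / (3 kB T)
  E <- 1e-4 * kB * 300 / w$dipole_moment
  expect_equal(dipole_energy(E, w, 300),
               -w$dipole_moment^2 * E^2 / (3 * kB * 300) * NA_ / 1e3,
               tolerance = 1e-3)
  # strong field: U -> -mu E + kB T
  E <- 1e3 * kB * 300 / w$dipole_moment
  expect_equal(dipole_energy(E, w, 300),
               (-w$dipole_moment * E + kB * 300) * NA_ / 1e3,
               tolerance = 1e-6)
})

test_that("LJ profile reproduces the zero crossing, minimum and a hand sum", {
  w <- water_model()
  cfg <- delta_config()
  s <- single_atom(sigma = 0.32, epsilon = 0.65)
  sig_c <- (0.32 + w$lj_sigma_O) / 2
  eps_c <- sqrt(0.65 * w$lj_epsilon_O)
  u <- lj_profile(1, s, w, c(0, 0, 1), c(sig_c, 2^(1 / 6) * sig_c), cfg)
  expect_equal(u[1], 0, tolerance = 1e-10)
  expect_equal(u[2], -eps_c, tolerance = 1e-10)
  # three atoms on a line: term-by-term oracle at 5 grid points
  pos <- rbind(c(0, 0, 0), c(0, 0, -0.3), c(0.3, 0, 0))
  s3 <- structure_from(pos, sigma = 0.32, epsilon = 0.65)
  grid <- c(0.25, 0.3, 0.35, 0.5, 0.8)
  u3 <- lj_profile(1, s3, w, c(0, 0, 1), grid, cfg)
  oracle <- sapply(grid, function(n) {
    p <- c(0, 0, n)
    sum(apply(pos, 1, function(q) {
      r <- sqrt(sum((p - q)^2))
      4 * eps_c * ((sig_c / r)^12 - (sig_c / r)^6)
    }))
  })
  expect_equal(u3, oracle, tolerance = 1e-12)
})

test_that("Coulomb field matches the law of electrostatics", {
  nb0 <- list(x = c(0.2, -0.2), y = c(0, 0), z = c(0, 0), charge = c(0, 0))
  expect_equal(coulomb_field(c(0, 0, 0), nb0), 0)
  # single charge at distance r with eps_r = 1
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  nb1 <- list(x = 0, y = 0, z = 0.5, charge = 0.4)
  expect_equal(coulomb_field(c(0, 0, 0), nb1, eps_r_constant(1)),
               0.4 * e / (4 * pi * eps0 * (0.5e-9)^2), tolerance = 1e-9)
  # two symmetric charges: transverse parts cancel, axial parts add
  nb2 <- list(x = c(0.3, -0.3), y = c(0, 0), z = c(0.4, 0.4),
              charge = c(0.4, 0.4))
  r <- sqrt(0.3^2 + 0.4^2)
  axial <- 2 * 0.4 * e / (4 * pi * eps0 * (r * 1e-9)^2) * (0.4 / r)
  expect_equal(coulomb_field(c(0, 0, 0), nb2, eps_r_constant(1)),
               axial, tolerance = 1e-9)
})

test_that("effective profile reduces to LJ without charges and decays", {
  s <- delta_slab(charge = 0)
  sas <- compute_sas(s)
  i <- surface_atoms(sas)[8]
  p <- effective_profile(i, s, sas, config = delta_config())
  expect_equal(p$U_c, numeric(length(p$n_grid)))
  expect_equal(p$U_eff, p$U_vdw)
  expect_lt(abs(p$U_eff[length(p$U_eff)]), 0.05)
  expect_error(effective_profile(1e6, s, sas), "surface_atoms")
})

test_that("well depth agrees with a 10x finer grid search", {
  s <- delta_slab(charge = 0.2)
  sas <- compute_sas(s)
  i <- surface_atoms(sas)[1]
  cfg <- delta_config(grid_n = 400)
  p <- effective_profile(i, s, sas, config = cfg)
  fine <- effective_profile(i, s, sas, config = delta_config(grid_n = 4000))
  expect_equal(p$well_depth, fine$well_depth, tolerance = 0.01)
})

test_that("local delta matches the parabolic-well closed form", {
  a <- 2.0; b <- 40; c0 <- 0.4; alpha <- 0.25
  fun <- function(n) -a + b * (n - c0)^2
  grid <- seq(0.05, 1, length.out = 2000)
  # exact evaluator route
  p1 <- potential_profile(grid, fun(grid), fun = fun)
  d_exact <- 2 * sqrt((a - alpha * kBT300) / b)
  expect_equal(local_delta(p1, 300, alpha), d_exact, tolerance = 1e-8)
  # spline-interpolated route
  p2 <- potential_profile(grid, fun(grid))
  expect_equal(local_delta(p2, 300, alpha), d_exact, tolerance = 1e-6)
})

test_that("wells shallower than the thermal level give delta = 0", {
  grid <- seq(0.05, 1, length.out = 500)
  shallow <- potential_profile(grid, -0.9 * 0.25 * kBT300 *
                                 exp(-((grid - 0.4) / 0.1)^2))
  expect_equal(local_delta(shallow, 300, 0.25), 0)
})

test_that("delta never grows when the temperature doubles", {
  grid <- seq(0.05, 1, length.out = 1000)
  for (depth in c(0.5, 1, 2, 5)) {
    p <- potential_profile(grid, -depth * exp(-((grid - 0.35) / 0.12)^2))
    expect_lte(local_delta(p, 600), local_delta(p, 300) + 1e-12)
  }
})

test_that("mean delta is the SAS-weighted average of local deltas", {
  s <- delta_slab()
  sas <- compute_sas(s)
  cfg <- delta_config(charges = FALSE)
  res <- mean_delta(s, sas, config = cfg)
  # independent dot-product oracle from the per-atom outputs
  w <- sas$S_loc[names(res$delta_i)]
  expect_equal(res$delta_mean, sum(res$delta_i * w) / sas$S_tot,
               tolerance = 1e-12)
  # symmetric periodic slab: every exposed atom is equivalent up to
  # the sampling orientation of its normal, so all local values agree
  # closely and the weighted mean equals the common value
  expect_true(all(abs(res$delta_i - res$delta_i[1]) < 1e-4))
  expect_equal(res$delta_mean, unname(res$delta_i[1]), tolerance = 1e-4)
  expect_gt(res$delta_mean, 0)
})

test_that("zeroing charges equals the pure-LJ path exactly", {
  s_q <- delta_slab(charge = 0.3)
  sas <- compute_sas(s_q)
  res_off <- mean_delta(s_q, sas, config = delta_config(charges = FALSE))
  s_0 <- s_q
  s_0$atoms$charge <- 0
  res_zero <- mean_delta(s_0, compute_sas(s_0), config = delta_config())
  expect_identical(res_off$delta_i, res_zero$delta_i)
  expect_identical(res_off$delta_mean, res_zero$delta_mean)
})

test_that("delta depends only weakly on the well depth", {
  s <- delta_slab()
  sas <- compute_sas(s)
  d1 <- mean_delta(s, sas, config = delta_config(charges = FALSE))$delta_mean
  s10 <- s
  s10$atoms$epsilon <- s10$atoms$epsilon * 10
  d10 <- mean_delta(s10, sas, config = delta_config(charges = FALSE))$delta_mean
  expect_gt(d10, d1)          # deeper wells widen the trapped layer...
  expect_lt(d10 / d1, 2.5)    # ...but far less than tenfold
})

test_that("delta is stable under grid refinement", {
  s <- delta_slab(charge = 0.2)
  sas <- compute_sas(s)
  d1 <- mean_delta(s, sas, config = delta_config(grid_n = 1000))$delta_mean
  d2 <- mean_delta(s, sas, config = delta_config(grid_n = 2000))$delta_mean
  expect_lt(abs(d2 - d1) / d1, 0.005)
})
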