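test_scene <- function(seed = 1, n_clusters = 8)
  generate_synthetic_edx(shape = c(48, 48), n_clusters = n_clusters,
                         cluster_size = 1.2, seed = seed)

test_that("the synthetic scene generator is deterministic and additive", {
  s0 <- generate_synthetic_edx(n_clusters = 0, seed = 1)
  expect_true(all(s0$image == 0))
  s1 <- test_scene(seed = 5)
  s2 <- test_scene(seed = 5)
  expect_identical(s1$image, s2$image)
  # total intensity = clusters x per-cluster intensity
  expect_equal(sum(s1$image), 8 * 100, tolerance = 1e-9)
})

test_that("pixel density conserves the SPIO count", {
  sc <- test_scene()
  rho <- pixel_density(sc)
  expect_equal(sum(rho) * sc$A_pix, sc$N_SPIO, tolerance = 1e-9)
  # uniform image: uniform density
  su <- sc; su$image <- matrix(3, 10, 10)
  rho_u <- pixel_density(su)
  expect_true(all(abs(rho_u - su$N_SPIO / (100 * su$A_pix)) < 1e-12))
  # single-pixel image puts all mass there
  sp <- sc; sp$image <- matrix(0, 8, 8); sp$image[3, 5] <- 7
  rho_s <- pixel_density(sp)
  expect_equal(rho_s[3, 5] * sp$A_pix, sp$N_SPIO, tolerance = 1e-9)
  expect_equal(sum(rho_s > 0), 1)
})

test_that("local density integrates to one and peaks at cluster centroids", {
  sc <- test_scene()
  rho <- local_density(sc)
  expect_equal(sum(rho) * sc$A_pix, 1, tolerance = 1e-6)
  # two well-separated clusters: maxima within one pixel of centroids
  s2 <- generate_synthetic_edx(shape = c(64, 64), n_clusters = 0, seed = 1)
  img <- matrix(0, 64, 64)
  img[15, 15] <- 1; img[50, 48] <- 1
  s2$image <- img
  rp <- local_density(s2, bandwidth = 2)
  top <- which(rp == max(rp), arr.ind = TRUE)[1, ]
  expect_true(max(abs(top - c(15, 15))) <= 1 ||
              max(abs(top - c(50, 48))) <= 1)
  # both blobs present as separated mass centres
  expect_gt(rp[15, 15], rp[32, 32])
  expect_gt(rp[50, 48], rp[32, 32])
  # tiny bandwidth approximates the indicator of labelled pixels
  rp0 <- local_density(s2, bandwidth = 0.2)
  frac_on <- sum(rp0[img > 0]) / sum(rp0)
  expect_gt(frac_on, 0.99)
})

test_that("pore-scale density is mass-conserving and linear in N_SPIO", {
  sc <- test_scene()
  rp <- local_density(sc)
  rho <- pore_scale_density(sc, rp)
  expect_equal(sum(rho) * sc$A_pix, sc$N_SPIO, tolerance = 1e-9 * sc$N_SPIO)
  sc2 <- sc; sc2$N_SPIO <- 2 * sc$N_SPIO
  expect_equal(pore_scale_density(sc2, rp), 2 * rho, tolerance = 1e-12)
  # uniform rho_point gives the uniform density
  ru <- matrix(1, nrow(sc$image), ncol(sc$image))
  expect_true(all(abs(pore_scale_density(sc, ru) -
    sc$N_SPIO / (length(ru) * sc$A_pix)) < 1e-12))
})

test_that("representative-pore theta follows the shell arithmetic", {
  sc <- test_scene()
  expect_equal(representative_theta(sc, 0), 0)
  # hand computation for 10 SPIOs, r = 2.5 nm, delta = 0.5 nm
  r <- 2.5; d <- 0.5
  V_in <- 10 * 4 * pi / 3 * ((r + d)^3 - r^3)
  V_w <- sc$c_fill * sc$A_p * sc$h - 10 * 4 * pi / 3 * r^3
  expect_equal(representative_theta(sc, 10),
               1 - exp(-V_in / V_w), tolerance = 1e-12)
  # strictly increasing in the count until overfill
  th <- sapply(c(1, 5, 20, 100), function(n) representative_theta(sc, n))
  expect_true(all(diff(th) > 0))
  expect_error(representative_theta(sc, 1e9), "verfilled")
})

test_that("theta map honours the weighted-mean calibration", {
  sc <- test_scene()
  rho <- pore_scale_density(sc, local_density(sc))
  th_bar <- 0.35
  th <- theta_map(sc, rho, th_bar)
  occ <- rho > 0
  # rho-weighted mean of the (unclamped) map equals theta_bar
  expect_equal(sum(th[occ] * rho[occ]) / sum(rho[occ]), th_bar,
               tolerance = 0.02)  # small clamped mass may bite
  # uniform density: constant map at theta_bar
  ru <- matrix(2, 16, 16)
  thu <- theta_map(sc, ru, th_bar)
  expect_true(all(abs(thu - th_bar) < 1e-12))
  # scale invariance: C' absorbs any rescaling of rho
  th_k <- theta_map(sc, 3.7 * rho, th_bar)
  expect_equal(as.vector(th_k), as.vector(th), tolerance = 1e-12)
  expect_true(all(th >= 0 & th <= 1))
})

test_that("relaxivity follows its defining arithmetic", {
  expect_equal(relaxivity(2800, 2800, 1), 0)
  expect_equal(relaxivity(100, 2800, 1), 10 - 1 / 2.8, tolerance = 1e-12)
  expect_gt(relaxivity(50, 2800, 1), relaxivity(100, 2800, 1))
  expect_error(relaxivity(-1, 2800, 1))
})

test_that("enhancement map identities and hand-computed average", {
  law <- scaling_law(D_B = 2.6e-9, D_C = 0)
  # no confinement, reference volume fraction: En = 1 everywhere
  th0 <- matrix(0, 4, 4)
  v0 <- matrix(0.02, 4, 4)
  m0 <- enhancement_map(th0, v0, law, v_bulk = 0.02)
  expect_true(all(m0$En_map == 1))
  expect_equal(m0$En_avg, 1)
  # uniform theta with D_C = 0: En = (v/v_B)/(1 - theta)
  th1 <- matrix(0.4, 4, 4)
  m1 <- enhancement_map(th1, v0, law, v_bulk = 0.01)
  expect_true(all(abs(m1$En_map - 2 / 0.6) < 1e-12))
  # two-region map: weighted-mean oracle
  th2 <- matrix(c(rep(0.2, 8), rep(0.6, 8)), 4, 4)
  v2 <- matrix(c(rep(0.01, 8), rep(0.03, 8)), 4, 4)
  w2 <- matrix(c(rep(1, 8), rep(3, 8)), 4, 4)
  m2 <- enhancement_map(th2, v2, law, v_bulk = 0.01, weights = w2)
  En_a <- (0.01 / (2.6e-9 * 0.8)) / (0.01 / 2.6e-9)
  En_b <- (0.03 / (2.6e-9 * 0.4)) / (0.01 / 2.6e-9)
  oracle <- (En_a * 8 * 1 + En_b * 8 * 3) / (8 * 1 + 8 * 3)
  expect_equal(m2$En_avg, oracle, tolerance = 1e-12)
  # fully confined pixels are flagged and excluded
  th3 <- th2; th3[1, 1] <- 1
  expect_warning(m3 <- enhancement_map(th3, v2, law, v_bulk = 0.01,
                                       weights = w2), "confined")
  expect_equal(m3$n_flagged, 1)
  expect_true(is.na(m3$En_map[1, 1]))
})

test_that("enhancement exceeds one wherever confinement acts", {
  sc <- test_scene()
  out <- cmd_relaxmap(sc)
  En <- out$map$En_map
  v <- spio_volume_fraction(sc, out$rho_spio)
  sel <- !is.na(En) & v >= out$v_bulk & out$map$theta_map > 0
  expect_true(all(En[sel] >= 1))
})

test_that("the full image chain conserves mass and is deterministic", {
  sc <- test_scene(seed = 3)
  out1 <- cmd_relaxmap(sc)
  out2 <- cmd_relaxmap(test_scene(seed = 3))
  expect_identical(out1$map$En_avg, out2$map$En_avg)
  expect_equal(sum(out1$rho_spio) * sc$A_pix, sc$N_SPIO,
               tolerance = 1e-9 * sc$N_SPIO)
})

test_that("raster text I/O round-trips", {
  m <- matrix(runif(30), 5, 6)
  path <- tempfile()
  write_raster(m, path)
  expect_equal(read_raster(path), unname(as.matrix(m)), tolerance = 1e-9,
               ignore_attr = TRUE)
})
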