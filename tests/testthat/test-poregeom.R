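ctx <- thermo_context()

rotate_z <- function(model, theta, shift = c(0, 0, 0)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  m <- model
  m$atoms$x <- xyz[, 1] + shift[1]
  m$atoms$y <- xyz[, 2] + shift[2]
  m$atoms$z <- xyz[, 3] + shift[3]
  m
}

test_that("pore center is the mean of the ten anchor alpha-carbons", {
  pent <- synthetic_pentamer(radius = 10, rise = 1.5, z0 = 0)
  ctr <- pore_center(pent)
  # C5 symmetry about the z axis
  expect_equal(unname(ctr[1:2]), c(0, 0), tolerance = 1e-9)
  # residues 226 and 244 sit at z = 4.5 and 31.5
  expect_equal(unname(ctr[3]), (4.5 + 31.5) / 2, tolerance = 1e-9)
  # translation equivariance
  shifted <- rotate_z(pent, 0, shift = c(3, -2, 7))
  expect_equal(unname(pore_center(shifted)), unname(ctr) + c(3, -2, 7),
               tolerance = 1e-9)
  # hand-computed mean on an explicit two-chain-failure case
  broken <- pent
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "C" &
                                   broken$atoms$resno == 226), ]
  expect_error(pore_center(broken), "chain C residue 226")
})

test_that("pore axis is the oriented principal direction of the anchors", {
  pent <- synthetic_pentamer()
  expect_equal(unname(pore_axis(pent)), c(0, 0, 1), tolerance = 1e-9)
  flipped <- pent
  flipped$atoms$z <- -flipped$atoms$z  # extracellular ring now at low z
  expect_equal(unname(pore_axis(flipped)), c(0, 0, -1), tolerance = 1e-9)
})

test_that("M2 pair distances obey pentagon geometry and locality", {
  R <- 10
  pent <- synthetic_pentamer(radius = R)
  d <- m2_pair_distances(pent)
  expect_length(d, 5L)
  expect_named(d, c("1-3", "1-4", "2-4", "2-5", "3-5"))
  # all non-adjacent distances of a regular pentagon equal 2R sin(2pi/5)
  expect_equal(unname(unclass(d)), rep(2 * R * sin(2 * pi / 5), 5),
               tolerance = 1e-9)
  # moving one subunit inward shrinks exactly the distances involving it
  collapsed <- synthetic_pentamer(radius = R,
                                  perturb = list(chain = "A", dx = -2))
  d2 <- m2_pair_distances(collapsed)
  touched <- c("1-3", "1-4")
  expect_true(all(d2[touched] < d[touched] - 0.1))
  expect_equal(unclass(d2[setdiff(names(d), touched)]),
               unclass(d[setdiff(names(d), touched)]), tolerance = 1e-9)
  # rigid rotation + translation leaves all distances unchanged
  d3 <- m2_pair_distances(rotate_z(pent, 0.7, shift = c(5, 5, -3)))
  expect_equal(unclass(d3), unclass(d), tolerance = 1e-9)
})

test_that("Boltzmann profiles invert Gaussian and uniform distributions", {
  set.seed(52)
  sigma <- 0.5
  s <- rnorm(1e5, 20, sigma)
  prof <- boltzmann_profile(s, bin_width = 0.25, ctx = ctx)
  ok <- !is.na(prof$values) & abs(prof$centers - 20) < 1
  fit <- stats::lm(prof$values[ok] ~ poly(prof$centers[ok], 2, raw = TRUE))
  curv <- 2 * unname(coef(fit)[3])
  expect_equal(curv, ctx$kT / sigma^2, tolerance = 0.1)

  # uniform samples give a flat profile within counting noise
  set.seed(53)
  u <- runif(1e5, 0, 10)
  pu <- boltzmann_profile(u, bin_width = 0.5, ctx = ctx)
  inner <- pu$values[pu$centers > 0.5 & pu$centers < 9.5]
  per_bin <- 1e5 / 20
  noise_sigma <- ctx$kT / sqrt(per_bin)  # delta method on -kT ln(count)
  expect_lt(max(inner) - min(inner), 6 * noise_sigma)

  expect_error(boltzmann_profile(s, bin_width = 0), "positive")
})

test_that("profiles are shift-invariant under sample duplication", {
  set.seed(54)
  s <- rnorm(2e4, 19, 0.8)
  p1 <- boltzmann_profile(s, 0.25, ctx)
  p2 <- boltzmann_profile(c(s, s), 0.25, ctx)
  expect_equal(p2$values, p1$values, tolerance = 1e-9)
})

test_that("bimodal distance distributions yield two separated minima", {
  d <- gen_distance_series(open_center = 20, collapsed_center = 18.5,
                           weights = c(0.7, 0.3), sigmas = c(0.3, 0.25),
                           n = 1e5, seed = 55)
  prof <- boltzmann_profile(d, 0.1, ctx)
  v <- prof$values
  near <- function(x) which.min(abs(prof$centers - x))
  barrier <- min(v[prof$centers > 19 & prof$centers < 19.8], na.rm = TRUE)
  expect_lt(v[near(18.5)], barrier)
  expect_lt(v[near(20)], barrier)
})

test_that("flat-bottom restraints are flat above the wall and smooth at it", {
  spec <- restraint_spec(d0 = 19.5, k = 10)
  above <- restraint_energy(spec, c(19.5, 19.7, 25))
  expect_equal(above$energy, rep(0, 3))
  expect_equal(above$force, rep(0, 3))
  below <- restraint_energy(spec, 18.5)
  expect_equal(below$energy, 0.5 * 10 * 1^2)
  expect_equal(below$force, 10)
  # continuity of U and dU/dd at d0, finite differences at 1e-6 A
  eps <- 1e-6
  u <- restraint_energy(spec, c(19.5 - eps, 19.5 + eps))$energy
  expect_lt(abs(u[2] - u[1]), 1e-10)
  f <- restraint_energy(spec, c(19.5 - eps, 19.5 + eps))$force
  expect_lt(abs(f[2] - f[1]), 1e-4)
})

test_that("restraint design places the wall on the barrier flank", {
  d <- gen_distance_series(n = 1e5, seed = 56)
  prof <- boltzmann_profile(d, 0.1, ctx)
  spec <- design_flat_bottom_restraint(prof, open_basin_center = 20)
  expect_gte(spec$d0, 19.0)
  expect_lte(spec$d0, 19.6)
  expect_equal(spec$k, 10)
  # the wall does not touch the open basin: zero energy at and above d0
  expect_equal(restraint_energy(spec, seq(spec$d0, 21, 0.1))$energy,
               rep(0, length(seq(spec$d0, 21, 0.1))))
  # single-well profiles are rejected
  set.seed(57)
  single <- boltzmann_profile(rnorm(1e5, 20, 0.5), 0.25, ctx)
  expect_error(design_flat_bottom_restraint(single, 20), "barrier")
})

test_that("axial density conserves ligand number through smoothing", {
  # all samples in one interior bin spread over three bins, mass 1
  z <- rep(5.1, 1000)
  prof <- axial_density(z, n_ligands = 1, bin_width = 0.5)
  expect_equal(sum(prof$rho > 0), 3L)
  expect_equal(sum(prof$rho) * prof$bin_width, 1, tolerance = 1e-9)

  # uniform samples, two ligands: flat with integral 2
  set.seed(61)
  zu <- runif(5e4, -10, 10)
  pu <- axial_density(zu, n_ligands = 2, bin_width = 0.5)
  expect_equal(sum(pu$rho) * pu$bin_width, 2, tolerance = 1e-9)
  inner <- pu$rho[pu$centers > -9 & pu$centers < 9]
  expect_lt((max(inner) - min(inner)) / mean(inner), 0.35)

  # conservation holds with and without smoothing
  set.seed(62)
  zg <- rnorm(2e4, 0, 3)
  for (sm in c(TRUE, FALSE)) {
    p <- axial_density(zg, 1, 0.5, smooth = sm)
    expect_equal(sum(p$rho) * p$bin_width, 1, tolerance = 1e-6)
  }
})

test_that("density peaks sit at the toy-pore well centers", {
  model <- pore_toy_model(site_centers = c(0, 7), well_depths = c(3, 2.5),
                          well_widths = c(1, 1), n_frames = 30000,
                          seed = 63)
  z <- gen_pore_trajectory(model, ctx)
  prof <- axial_density(as.numeric(z), 1, 0.5)
  # local maxima of the smoothed density
  r <- prof$rho
  peaks <- prof$centers[which(diff(sign(diff(r))) == -2) + 1]
  expect_true(any(abs(peaks - 0) <= 0.5 + 1e-9))
  expect_true(any(abs(peaks - 7) <= 0.5 + 1e-9))
})

test_that("prime notation maps gate residues to 9' and 16'", {
  expect_identical(prime_index(232), 9L)
  expect_identical(prime_index(239), 16L)
  expect_identical(prime_index(226), 3L)
  expect_identical(prime_index(c(229, 243)), c(6L, 20L))
  expect_error(prime_index(200), "M2 span")
})

test_that("site occupancancies integrate density and conserve ligands", {
  sites <- site_definition(c("secondary_lower", "primary",
                             "secondary_upper"),
                           z_low = c(-8, -1, 6), z_high = c(-1, 6, 15))
  # all density inside the primary site, two ligands
  prof <- axial_density(rnorm(5000, 2, 0.5), 2, 0.5)
  occ <- site_occupancy(prof, sites)
  expect_equal(unname(occ["primary"]), 2, tolerance = 1e-6)
  expect_lt(occ["secondary_lower"] + occ["secondary_upper"], 0.05)
  # occupancies over tiling sites sum to n_ligands (raw-sample route)
  z <- runif(10000, -8, 15)
  occ2 <- site_occupancy(z, sites, n_ligands = 2)
  expect_equal(sum(occ2), 2, tolerance = 1e-9)
  expect_error(site_definition(c("a", "b"), c(0, 1), c(2, 3)), "overlap")
})
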