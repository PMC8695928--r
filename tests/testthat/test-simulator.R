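test_that("conicoid sag matches its closed forms", {
  expect_equal(conicoid_sag(0, 7.8, 0), 0)
  expect_equal(conicoid_sag(0, 6.5, -0.3), 0)
  expect_equal(conicoid_sag(3, 7.8, 0), 7.8 - sqrt(7.8^2 - 9))
  rho <- seq(0, 4, by = 0.5)
  expect_equal(conicoid_sag(rho, 7.8, -1), rho^2 / (2 * 7.8))
  expect_error(conicoid_sag(9, 7.8, 0), "domain")
})

test_that("cone-free, astigmatism-free surfaces are rotationally symmetric", {
  prof <- cornea_profile(astig_D = 0, cone_A = 0)
  z <- build_surface(prof, "anterior")
  # cells at equal rho share a height: compare the four axis directions
  for (k in c(5, 20, 40)) {
    v <- c(z[61 + k, 61], z[61 - k, 61], z[61, 61 + k], z[61, 61 - k])
    expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
  }
  expect_equal(z[61, 61], 0)
  # corners outside the measured zone are missing
  expect_true(is.na(z[1, 1]) && is.na(z[121, 121]))
  expect_false(is.na(z[61, 1]))
})

test_that("the cone bump peaks at its centre with deviation ~ amplitude", {
  base <- cornea_profile(astig_D = 0, cone_A = 0)
  coned <- cornea_profile(astig_D = 0, cone_A = 0.05, cone_x = 0,
                          cone_y = -1, cone_sigma = 1.5)
  dz <- build_surface(base, "anterior") - build_surface(coned, "anterior")
  peak <- which(dz == max(dz, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(51, 61))  # y = -1 mm -> row 51
  expect_equal(max(dz, na.rm = TRUE), 0.05, tolerance = 1e-6)
})

test_that("a mirrored profile builds the column-flipped surface", {
  prof <- cornea_profile(astig_D = 1.5, astig_axis = 35, cone_A = 0.06,
                         cone_x = 0.8, cone_y = -1.1)
  mirr <- cornea_profile(astig_D = 1.5, astig_axis = 145, cone_A = 0.06,
                         cone_x = -0.8, cone_y = -1.1)
  z <- build_surface(prof, "anterior")
  zm <- build_surface(mirr, "anterior")
  expect_equal(zm, z[, 121:1], tolerance = 1e-12)
})

test_that("keratometry of an exact sphere is the closed-form constant", {
  z <- build_surface(cornea_profile(R_ant = 7.8, Q_ant = 0, astig_D = 0,
                                    cone_A = 0), "anterior")
  fk <- axial_power_map(z)
  expect_lt(max(abs(fk - 337.5 / 7.8), na.rm = TRUE), 0.01)
  zp <- build_surface(cornea_profile(R_post = 6.5, Q_post = 0, astig_D = 0,
                                     cone_A = 0), "posterior",
                      zone_radius_mm = 5)
  bk <- axial_power_map(zp, -0.040)
  expect_lt(max(abs(bk - (-40 / 6.5)), na.rm = TRUE), 0.01)
})

test_that("a cone strictly increases the maximum anterior power", {
  base <- cornea_profile(astig_D = 0, cone_A = 0)
  fk0 <- axial_power_map(build_surface(base, "anterior"))
  for (A in c(0.03, 0.06, 0.10)) {
    coned <- cornea_profile(astig_D = 0, cone_A = A)
    fk1 <- axial_power_map(build_surface(coned, "anterior"))
    expect_gt(max(fk1, na.rm = TRUE), max(fk0, na.rm = TRUE))
  }
})

test_that("best-fit sphere recovers an exact sphere with zero residual", {
  z <- build_surface(cornea_profile(R_ant = 7.8, Q_ant = 0, astig_D = 0,
                                    cone_A = 0), "anterior")
  bfs <- best_fit_sphere(z)
  expect_equal(bfs$radius, 7.8, tolerance = 1e-7)
  expect_lt(bfs$rms_residual, 1e-9)
  expect_equal(bfs$apex_offset, 0, tolerance = 1e-7)
})

test_that("best-fit sphere agrees with a brute-force grid search", {
  z0 <- build_surface(cornea_profile(R_ant = 7.7, Q_ant = -0.3, astig_D = 0,
                                     cone_A = 0), "anterior")
  z <- build_surface(cornea_profile(R_ant = 7.7, Q_ant = -0.3, astig_D = 0,
                                    cone_A = 0.03), "anterior")
  bfs0 <- best_fit_sphere(z0)
  bfs <- best_fit_sphere(z)
  co_r <- (seq_len(121) - 61) * 0.1
  rho2 <- outer(co_r, co_r, function(y, x) x^2 + y^2)
  sel <- !is.na(z) & rho2 <= 16
  obj <- function(Rs, zc)
    sum((z[sel] - (zc - sqrt(Rs^2 - rho2[sel])))^2)
  grid <- expand.grid(Rs = seq(bfs$radius - 0.05, bfs$radius + 0.05, 0.005),
                      zc = seq(bfs$z_center - 0.05, bfs$z_center + 0.05, 0.005))
  vals <- mapply(obj, grid$Rs, grid$zc)
  expect_lte(obj(bfs$radius, bfs$z_center), min(vals) + 1e-12)
  # the cone steepens the fit slightly relative to the cone-free surface
  expect_lt(bfs$radius, bfs0$radius)
  expect_gt(bfs$radius, bfs0$radius - 0.2)
})

test_that("elevation of an exact sphere vanishes; a cone gives a positive peak", {
  z_sph <- build_surface(cornea_profile(R_ant = 7.8, Q_ant = 0, astig_D = 0,
                                        cone_A = 0), "anterior")
  elev <- elevation_map(z_sph, best_fit_sphere(z_sph))
  expect_lt(max(abs(elev), na.rm = TRUE), 1e-6)  # um
  z_kc <- build_surface(cornea_profile(astig_D = 0, cone_A = 0.05, cone_x = 0,
                                       cone_y = -1), "anterior")
  bfs <- best_fit_sphere(z_kc)
  elev_kc <- elevation_map(z_kc, bfs)
  # inside the fit zone the peak sits at the cone, tens of um high
  co_r <- (seq_len(121) - 61) * 0.1
  rho2 <- outer(co_r, co_r, function(y, x) x^2 + y^2)
  inzone <- !is.na(elev_kc) & rho2 <= 16
  ez <- elev_kc; ez[!inzone] <- NA
  peak <- which(ez == max(ez, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(sqrt((peak[1, 1] - 51)^2 + (peak[1, 2] - 61)^2), 4)
  expect_gt(max(ez, na.rm = TRUE), 10)
  expect_lt(max(ez, na.rm = TRUE), 100)
  # least-squares orthogonality: residuals average out over the fit zone
  expect_lt(abs(mean(elev_kc[inzone])), 0.5)
})

test_that("pachymetry is CCT for identical surfaces and thins under a cone", {
  z <- build_surface(cornea_profile(astig_D = 0, cone_A = 0), "anterior")
  cp0 <- pachymetry_map(z, z, 545)
  expect_true(all(cp0[!is.na(cp0)] == 545))
  prof <- cornea_profile()  # control defaults
  cp <- pachymetry_map(build_surface(prof, "anterior"),
                       build_surface(prof, "posterior", zone_radius_mm = 5),
                       prof$CCT)
  expect_equal(cp[61, 61], 545, tolerance = 1e-9)
  horiz <- cp[61, 61:111]  # centre outward along +x, within the 5-mm zone
  expect_true(all(diff(horiz) > 0))
  kc <- cornea_profile(cone_A = 0.06, post_cone_scale = 1.5, astig_D = 0)
  cp_kc <- pachymetry_map(build_surface(kc, "anterior"),
                          build_surface(kc, "posterior", zone_radius_mm = 5),
                          kc$CCT)
  mn <- which(cp_kc == min(cp_kc, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(min(cp_kc, na.rm = TRUE), kc$CCT)
  # thinnest point between the vertex and the cone apex, as in keratoconus
  expect_lt(sqrt((mn[1, 1] - 51)^2 + (mn[1, 2] - 67)^2), 12)
  expect_gt(sqrt((mn[1, 1] - 61)^2 + (mn[1, 2] - 61)^2), 2)
  thin <- cornea_profile(CCT = 30, cone_A = 0.1, post_cone_scale = 1.8)
  expect_error(pachymetry_map(build_surface(thin, "anterior"),
                              build_surface(thin, "posterior",
                                            zone_radius_mm = 5),
                              thin$CCT),
               "non-positive thickness")
})

test_that("zero-noise enantiomorphic pairs yield exactly zero parameters", {
  pair <- simulate_pair(zero_asym_profile(5))
  p <- compute_parameters(pair$od, pair$os)
  expect_true(all(p == 0))
})

test_that("asymmetric cones raise front-surface and pachymetry differentials", {
  base <- cornea_profile(cone_A = 0.05)
  pp <- zero_asym_profile(6, base)
  pp$fellow_amp_frac <- 0  # worse eye coned, fellow eye clean
  p <- compute_parameters(simulate_pair(pp)$od, simulate_pair(pp)$os)
  expect_gt(p[["dFEmax"]], 0)
  expect_gt(p[["dFKmax"]], 0)
  expect_true(all(p[c("dCPmax", "dCPmean", "dCPsd")] > 0))
})

test_that("front-surface differentials grow with cone asymmetry", {
  amps <- c(0, 0.02, 0.05, 0.09, 0.14)
  front <- c("dFKmax", "dFKmean", "dFKsd", "dFEmax", "dFEmean", "dFEsd")
  prev <- NULL
  for (A in amps) {
    pp <- zero_asym_profile(8, cornea_profile(cone_A = A))
    pp$fellow_amp_frac <- 0
    pair <- simulate_pair(pp)
    p <- compute_parameters(pair$od, pair$os)
    if (!is.null(prev)) expect_true(all(p[front] >= prev[front]))
    prev <- p
  }
  expect_true(all(prev[front] > 0))
})

test_that("pair simulation is a pure function of its seed", {
  pp <- pair_profile(base = cornea_profile(cone_A = 0.05),
                     fellow_amp_frac = 0.3, seed = 77)
  a <- simulate_pair(pp)
  b <- simulate_pair(pp)
  expect_identical(a$od$maps$FK$values, b$od$maps$FK$values)
  expect_identical(a$os$maps$CP$values, b$os$maps$CP$values)
  expect_identical(a$od$scalars, b$od$scalars)
  pp2 <- pp; pp2$seed <- 78
  expect_false(identical(simulate_pair(pp2)$od$maps$FK$values,
                         a$od$maps$FK$values))
})

test_that("simulated scalar indices respect their orderings", {
  pair <- simulate_pair(pair_profile(base = cornea_profile(cone_A = 0.06),
                                     fellow_amp_frac = 0.2, seed = 12))
  for (exam in list(pair$od, pair$os)) {
    sc <- exam$scalars
    expect_lte(sc[["FK1"]], sc[["FK2"]])
    expect_lte(sc[["FK2"]], sc[["FKmax"]])
    expect_lte(sc[["TCT"]], sc[["CTV"]])
  }
})

test_that("cohort generation writes a reproducible, loadable directory tree", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- cohort_config(n_kc = 2, n_control = 2, seed = 42)
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_length(f1, 4 * 10 + 2)  # 10 grids per subject + manifest + metadata
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  cohort <- load_cohort(d1, file.path(d1, "manifest.csv"))
  expect_length(cohort, 4)
  expect_setequal(vapply(cohort, `[[`, "", "group"),
                  c("KC", "control"))
})
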