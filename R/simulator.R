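## Paired-cornea simulator: conicoid + toric + Gaussian-cone surfaces,
## axial-curvature keratometry, best-fit-sphere elevations, axial pachymetry,
## spatially smoothed measurement noise. Coordinates: column j -> x =
## (j-61)*0.1 mm (nasal-temporal, the mirror axis), row i -> y = (i-61)*0.1 mm.

KERATOMETRIC_INDEX_ANT <- 0.3375   # power = 1000*0.3375 / r_ax(mm)
KERATOMETRIC_INDEX_POST <- -0.040  # posterior surface power is negative

grid_coords <- function(n = GRID_DIM, spacing = GRID_SPACING_MM,
                        center = CENTER_INDEX) {
  ax <- (seq_len(n) - center) * spacing
  list(x = matrix(ax, n, n, byrow = TRUE),   # varies along columns
       y = matrix(ax, n, n, byrow = FALSE))  # varies along rows
}

#' Sagittal height of a conicoid surface
#'
#' Height (sag) of a conic section of revolution at radial distance `rho`
#' from the apex: `z = rho^2 / (R + sqrt(R^2 - (1+Q) rho^2))`, measured from
#' the apex plane toward the eye. `Q = 0` gives a sphere, `Q = -1` the
#' paraboloid `rho^2 / (2R)`, `-1 < Q < 0` the prolate ellipsoids typical of
#' corneas.
#'
#' @param rho radial distance from the apex, mm (vectorised).
#' @param R apical radius of curvature, mm.
#' @param Q asphericity (conic constant).
#' @return Sag in mm, same shape as `rho`.
#' @examples
#' conicoid_sag(3, R = 7.8, Q = 0)   # 7.8 - sqrt(7.8^2 - 9)
#' conicoid_sag(2, R = 7.8, Q = -1)  # 4 / (2 * 7.8)
#' @export
conicoid_sag <- function(rho, R, Q = 0) {
  stopifnot(R > 0)
  disc <- R^2 - (1 + Q) * rho^2
  if (any(disc < 0, na.rm = TRUE))
    stop("rho outside the conicoid domain: (1+Q)*rho^2 must not exceed R^2",
         call. = FALSE)
  rho^2 / (R + sqrt(disc))
}

#' Default simulator cornea
#'
#' Parameters describe one cornea: apical radii and asphericities of the
#' anterior and posterior surfaces, central thickness, corneal astigmatism
#' (power difference between steep and flat meridians, with the steep-axis
#' angle), and an optional keratoconic cone modelled as a Gaussian bump of
#' amplitude `cone_A` (mm of anterior protrusion), width `cone_sigma` (mm)
#' centred at `(cone_x, cone_y)` mm from the vertex. The posterior surface
#' carries the same bump scaled by `post_cone_scale` (> 1 makes the cornea
#' thin under the cone, as in keratoconus).
#'
#' Defaults reproduce an average normal cornea: anterior apical radius
#' 7.85 mm (mean front keratometry about 43 D), posterior 6.50 mm (mean back
#' keratometry about -6.15 D), central thickness 545 um.
#'
#' @param R_ant,R_post apical radii, mm.
#' @param Q_ant,Q_post asphericities.
#' @param CCT central corneal thickness, um.
#' @param astig_D,astig_axis corneal astigmatism, D, and steep axis, degrees
#'   in `[0, 180)`.
#' @param cone_A cone amplitude, mm (0 = no cone).
#' @param cone_x,cone_y cone centre, mm.
#' @param cone_sigma cone Gaussian width, mm.
#' @param post_cone_scale posterior-to-anterior cone amplitude ratio.
#' @return An object of class `cornea_profile`.
#' @export
cornea_profile <- function(R_ant = 7.85, R_post = 6.50,
                           Q_ant = -0.25, Q_post = -0.35,
                           CCT = 545, astig_D = 0.75, astig_axis = 90,
                           cone_A = 0, cone_x = 0.6, cone_y = -1.0,
                           cone_sigma = 1.5, post_cone_scale = 1.4) {
  stopifnot(R_ant > 0, R_post > 0, CCT > 0, cone_A >= 0, cone_sigma > 0,
            post_cone_scale > 0, astig_D >= 0)
  astig_axis <- astig_axis %% 180
  structure(list(R_ant = R_ant, R_post = R_post, Q_ant = Q_ant,
                 Q_post = Q_post, CCT = CCT, astig_D = astig_D,
                 astig_axis = astig_axis, cone_A = cone_A, cone_x = cone_x,
                 cone_y = cone_y, cone_sigma = cone_sigma,
                 post_cone_scale = post_cone_scale),
            class = "cornea_profile")
}

mirror_profile <- function(p) {
  p$cone_x <- -p$cone_x
  p$astig_axis <- (180 - p$astig_axis) %% 180
  p
}

#' Build a corneal surface height grid
#'
#' Sag grid (mm, increasing toward the eye) of the anterior or posterior
#' surface of a [cornea_profile] on the standard 121 x 121 lattice:
#' conicoid base plus a cylindrical (toric) astigmatism term plus the
#' Gaussian cone, which *reduces* the sag locally (the cone protrudes
#' forward), yielding positive elevation against the best-fit sphere and a
#' locally steeper surface. Cells beyond `zone_radius_mm` from the vertex
#' (the unmeasured corners of the square grid) are `NA`.
#'
#' @param profile a [cornea_profile].
#' @param side `"anterior"` or `"posterior"`.
#' @param zone_radius_mm radius of the measured zone, mm.
#' @return 121 x 121 numeric matrix of heights in mm.
#' @export
build_surface <- function(profile, side = c("anterior", "posterior"),
                          zone_radius_mm = 6.0) {
  side <- match.arg(side)
  stopifnot(inherits(profile, "cornea_profile"))
  co <- grid_coords()
  rho <- sqrt(co$x^2 + co$y^2)
  inzone <- rho <= zone_radius_mm + 1e-9
  R <- if (side == "anterior") profile$R_ant else profile$R_post
  Q <- if (side == "anterior") profile$Q_ant else profile$Q_post
  z <- matrix(NA_real_, GRID_DIM, GRID_DIM)
  z[inzone] <- conicoid_sag(rho[inzone], R, Q)
  # cylinder adds curvature dC along the steep meridian; the axis trig is
  # evaluated on the acute angle with an explicit sign so that a mirrored
  # profile (axis -> 180 - axis) yields the bitwise column-flipped surface
  if (profile$astig_D > 0) {
    dC <- profile$astig_D / (1000 * KERATOMETRIC_INDEX_ANT)
    ax <- profile$astig_axis %% 180
    acute <- if (ax <= 90) ax else 180 - ax
    cx <- (if (ax <= 90) 1 else -1) * cospi(acute / 180)
    sy <- sinpi(acute / 180)
    u <- co$x * cx + co$y * sy
    z[inzone] <- z[inzone] + (dC / 2) * u[inzone]^2
  }
  if (profile$cone_A > 0) {
    amp <- profile$cone_A *
      if (side == "posterior") profile$post_cone_scale else 1
    g <- exp(-((co$x - profile$cone_x)^2 + (co$y - profile$cone_y)^2) /
               (2 * profile$cone_sigma^2))
    z[inzone] <- z[inzone] - amp * g[inzone]
  }
  z
}

#' Axial-curvature keratometry map from a height grid
#'
#' Converts a surface sag grid to an axial (sagittal) power map. Away from
#' the axis the axial radius at a cell is `r_ax = rho * sqrt(1 + z'^2) / z'`
#' where `z'` is the radial slope along the local meridian, estimated by
#' central differences; power is `1000 * index_delta / r_ax` diopters.
#' `r_ax` degenerates as `rho -> 0` (and, on keratoconic surfaces whose
#' apex is displaced from the instrument axis, wherever the radial slope
#' crosses zero), so inside `blend_mm` of the vertex the axial curvature is
#' blended linearly with the surface's exact mean curvature, whose apex
#' limit is the analytic one, `1/R`. For a sphere both curvatures equal
#' `1/R` everywhere, making the blend seamless. Cells whose
#' finite-difference stencil leaves the measured zone are `NA`.
#'
#' @param height 121 x 121 sag grid, mm.
#' @param index_delta keratometric refractive-index difference: `0.3375`
#'   for the anterior surface, `-0.040` for the posterior.
#' @param spacing_mm lattice spacing.
#' @param blend_mm radius of the central mean-curvature blend zone.
#' @return 121 x 121 power grid, D.
#' @export
axial_power_map <- function(height, index_delta = KERATOMETRIC_INDEX_ANT,
                            spacing_mm = GRID_SPACING_MM, blend_mm = 1.0) {
  stopifnot(is.matrix(height), nrow(height) == GRID_DIM,
            ncol(height) == GRID_DIM)
  n <- GRID_DIM
  h2 <- 2 * spacing_mm
  gx <- gy <- zxx <- zyy <- zxy <- matrix(NA_real_, n, n)
  mid_c <- 2:(n - 1); mid_r <- 2:(n - 1)
  gx[, mid_c] <- (height[, 3:n] - height[, 1:(n - 2)]) / h2
  gy[mid_r, ] <- (height[3:n, ] - height[1:(n - 2), ]) / h2
  # grouped (A + C) - 2B so the stencil commutes exactly with a column flip
  zxx[, mid_c] <- ((height[, 3:n] + height[, 1:(n - 2)]) -
                     2 * height[, mid_c]) / spacing_mm^2
  zyy[mid_r, ] <- ((height[3:n, ] + height[1:(n - 2), ]) -
                     2 * height[mid_r, ]) / spacing_mm^2
  zxy[mid_r, ] <- (gx[3:n, ] - gx[1:(n - 2), ]) / h2
  co <- grid_coords()
  rho <- sqrt(co$x^2 + co$y^2)
  zr <- (gx * co$x + gy * co$y) / rho        # radial slope; NaN at vertex
  k_ax <- zr / (rho * sqrt(1 + zr^2))        # 1 / axial radius
  # mean curvature (average of principal curvatures); 1/R for a sphere
  k_mean <- ((1 + gy^2) * zxx - 2 * gx * gy * zxy + (1 + gx^2) * zyy) /
    (2 * (1 + gx^2 + gy^2)^1.5)
  w <- pmin(rho / blend_mm, 1)
  k <- ifelse(w >= 1, k_ax, w * k_ax + (1 - w) * k_mean)
  k[rho == 0] <- k_mean[rho == 0]
  1000 * index_delta * k
}

#' Best-fit sphere of a corneal height grid
#'
#' Least-squares sphere over the cells within `zone_diameter_mm / 2` of the
#' vertex, with the centre constrained to the vertex normal (the z axis) and
#' free radius and axial offset — the standard reference surface for
#' corneal elevation maps. An algebraic (linear) sphere fit provides the
#' starting point; the geometric sag residual is then minimised with
#' Nelder-Mead.
#'
#' @param height sag grid, mm.
#' @param zone_diameter_mm fit-zone diameter (default 8 mm).
#' @return An object of class `bfs_fit`: `radius` (mm), `z_center` (mm,
#'   sphere-centre position on the axis), `apex_offset` (mm, BFS apex sag
#'   relative to the surface apex plane), `zone_diameter_mm`, `rms_residual`
#'   (mm).
#' @export
best_fit_sphere <- function(height, zone_diameter_mm = 8.0) {
  co <- grid_coords()
  rho <- sqrt(co$x^2 + co$y^2)
  sel <- !is.na(height) & rho <= zone_diameter_mm / 2 + 1e-9
  if (sum(sel) < 3) stop("fewer than 3 measured cells in the fit zone",
                         call. = FALSE)
  r2 <- rho[sel]^2
  z <- height[sel]
  ord <- order(r2, z)   # canonical order: fit invariant to grid orientation
  r2 <- r2[ord]; z <- z[ord]
  # algebraic fit: rho^2 + z^2 = 2 z zc + (Rs^2 - zc^2), linear in (zc, c2)
  A <- cbind(2 * z, 1)
  sol <- qr.solve(A, r2 + z^2)
  zc0 <- sol[1]
  Rs0 <- sqrt(max(sol[2] + zc0^2, 1e-8))
  sag_resid <- function(par) {
    Rs <- par[1]; zc <- par[2]
    disc <- Rs^2 - r2
    if (any(disc <= 0)) return(1e6)
    sum((z - (zc - sqrt(disc)))^2)
  }
  fit <- stats::optim(c(Rs0, zc0), sag_resid, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  Rs <- fit$par[1]; zc <- fit$par[2]
  structure(list(radius = Rs, z_center = zc, apex_offset = zc - Rs,
                 zone_diameter_mm = zone_diameter_mm,
                 rms_residual = sqrt(fit$value / sum(sel))),
            class = "bfs_fit")
}

#' @export
print.bfs_fit <- function(x, ...) {
  cat(sprintf("bfs_fit: radius %.4f mm, apex offset %+.4f mm, %g-mm zone, RMS %.3g mm\n",
              x$radius, x$apex_offset, x$zone_diameter_mm, x$rms_residual))
  invisible(x)
}

#' Elevation map relative to a best-fit sphere
#'
#' Micrometres of surface elevation above the BFS at each cell:
#' `1000 * (z_bfs - z_surface)`. Because a cone protrudes forward (reduced
#' sag), it produces a positive elevation peak — the convention of clinical
#' elevation displays.
#'
#' @param height sag grid, mm.
#' @param bfs a [best_fit_sphere()] fit of the same grid.
#' @return 121 x 121 elevation grid, um.
#' @export
elevation_map <- function(height, bfs) {
  stopifnot(inherits(bfs, "bfs_fit"))
  co <- grid_coords()
  rho2 <- co$x^2 + co$y^2
  z_bfs <- bfs$z_center - sqrt(pmax(bfs$radius^2 - rho2, 0))
  1000 * (z_bfs - height)
}

#' Axial pachymetry map from the two surfaces
#'
#' Corneal thickness at each cell: `CCT + 1000 * (z_post - z_ant)` um,
#' where both sags are measured from their own apex planes and `CCT`
#' anchors the axial separation at the vertex. A posterior cone scaled
#' above 1 thins the map under the cone.
#'
#' @param z_ant,z_post anterior and posterior sag grids, mm.
#' @param CCT central corneal thickness, um.
#' @return 121 x 121 thickness grid, um.
#' @export
pachymetry_map <- function(z_ant, z_post, CCT) {
  stopifnot(CCT > 0, is.matrix(z_ant), is.matrix(z_post),
            all(dim(z_ant) == dim(z_post)))
  thick <- CCT + 1000 * (z_post - z_ant)
  if (any(thick <= 0, na.rm = TRUE))
    stop("non-positive thickness: unphysical cornea profile", call. = FALSE)
  thick
}

## Spatially correlated measurement noise: white Gaussian field blurred with
## a separable Gaussian kernel, rescaled to unit marginal sd, then scaled.
smoothed_noise <- function(sd, smooth_mm = 0.3, n = GRID_DIM,
                           spacing = GRID_SPACING_MM) {
  if (sd <= 0) return(matrix(0, n, n))
  w <- matrix(stats::rnorm(n * n), n, n)
  s_cells <- smooth_mm / spacing
  half <- max(1L, ceiling(3 * s_cells))
  k <- stats::dnorm(seq(-half, half), sd = s_cells)
  k <- k / sum(k)
  pad_conv <- function(m) {       # replicate-pad rows, convolve columns of m
    top <- m[rep(1L, half), , drop = FALSE]
    bot <- m[rep(nrow(m), half), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (d in seq_along(k))
      out <- out + k[d] * mp[(d - 1) + seq_len(nrow(m)), , drop = FALSE]
    out
  }
  w <- pad_conv(w)
  w <- t(pad_conv(t(w)))
  w / stats::sd(as.vector(w)) * sd
}

#' Paired-eye simulation settings
#'
#' Describes one subject's two eyes: the right eye follows `base`; the left
#' eye is the mirrored profile (cone centre `x -> -x`, astigmatism axis
#' `-> 180 - axis`) with normally jittered biometric parameters and the
#' cone amplitude multiplied by `fellow_amp_frac` (0 gives the
#' forme-fruste pattern: one clinically keratoconic eye, a topographically
#' normal fellow eye). Per-modality measurement-noise sds apply to the
#' final maps after spatial smoothing.
#'
#' Noise defaults are calibrated so that a simulated normal cohort's
#' bilateral differential parameters fall near clinically reported control
#' magnitudes (differential front-keratometry mean about 0.45 D,
#' front-elevation mean about 2.4 um, back-elevation mean about 5.8 um,
#' pachymetry mean about 11.8 um inside the central 1.5-mm zone).
#'
#' @param base a [cornea_profile] for the (worse) right eye.
#' @param fellow_amp_frac fellow-eye cone amplitude as a fraction of
#'   `base$cone_A`, in `[0, 1]`.
#' @param jitter named numeric: between-eye sds for `R_ant`, `R_post`,
#'   `CCT`, `astig_D`, `astig_axis`, `Q`.
#' @param noise_sd named numeric: per-cell measurement noise sd for
#'   modalities `FK` (D), `FE`, `BE`, `CP` (um), applied after smoothing.
#' @param smooth_mm Gaussian smoothing width of the noise field, mm.
#' @param seed integer RNG seed; every map drawn under it.
#' @return An object of class `pair_profile`.
#' @export
pair_profile <- function(base = cornea_profile(),
                         fellow_amp_frac = 1,
                         jitter = c(R_ant = 0.05, R_post = 0.05, CCT = 8,
                                    astig_D = 0.25, astig_axis = 8, Q = 0.03),
                         noise_sd = c(FK = 0.33, FE = 2.3, BE = 5.6, CP = 8.5),
                         smooth_mm = 0.25, seed = 1L) {
  stopifnot(inherits(base, "cornea_profile"),
            fellow_amp_frac >= 0, fellow_amp_frac <= 1,
            all(jitter >= 0), all(noise_sd >= 0), smooth_mm > 0)
  structure(list(base = base, fellow_amp_frac = fellow_amp_frac,
                 jitter = jitter, noise_sd = noise_sd,
                 smooth_mm = smooth_mm, seed = as.integer(seed)),
            class = "pair_profile")
}

jget <- function(j, nm) if (nm %in% names(j)) j[[nm]] else 0

build_eye_exam <- function(profile, laterality, subject_id, noise_sd,
                           smooth_mm) {
  z_ant <- build_surface(profile, "anterior")
  # the device resolves the posterior surface over a smaller zone
  z_post <- build_surface(profile, "posterior", zone_radius_mm = 5.0)
  fk <- axial_power_map(z_ant, KERATOMETRIC_INDEX_ANT)
  bk <- axial_power_map(z_post, KERATOMETRIC_INDEX_POST)
  fe <- elevation_map(z_ant, best_fit_sphere(z_ant))
  be <- elevation_map(z_post, best_fit_sphere(z_post))
  cp <- pachymetry_map(z_ant, z_post, profile$CCT)
  add_noise <- function(m, sd) m + smoothed_noise(sd, smooth_mm) * !is.na(m)
  fk <- add_noise(fk, jget(noise_sd, "FK"))
  bk <- add_noise(bk, jget(noise_sd, "FK"))  # same device noise class as FK
  fe <- add_noise(fe, jget(noise_sd, "FE"))
  be <- add_noise(be, jget(noise_sd, "BE"))
  cp <- add_noise(cp, jget(noise_sd, "CP"))
  maps <- list(
    FK = topography_map(fk, "FK", laterality),
    BK = topography_map(bk, "BK", laterality),
    FE = topography_map(fe, "FE", laterality),
    BE = topography_map(be, "BE", laterality),
    CP = topography_map(cp, "CP", laterality))
  eye_exam(subject_id, laterality, maps,
           scalars = exam_scalars(maps))
}

## FK1/FK2: mean axial power along the flattest/steepest meridian sampled
## over the central 3-mm zone (radius 1.5 mm, both semi-meridians).
meridian_means <- function(power, radius_mm = 1.5, step_deg = 5) {
  angs <- seq(0, 180 - step_deg, by = step_deg)
  rads <- seq(GRID_SPACING_MM, radius_mm, by = GRID_SPACING_MM)
  vapply(angs, function(a) {
    th <- a * pi / 180
    xs <- c(rads * cos(th), -rads * cos(th))
    ys <- c(rads * sin(th), -rads * sin(th))
    mean(bilinear_at(power, xs, ys))
  }, numeric(1)) -> mm
  names(mm) <- angs
  mm
}

bilinear_at <- function(m, x, y, spacing = GRID_SPACING_MM,
                        center = CENTER_INDEX) {
  cj <- x / spacing + center
  ri <- y / spacing + center
  i0 <- floor(ri); j0 <- floor(cj)
  fi <- ri - i0; fj <- cj - j0
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j0 + 1)] * (1 - fi) * fj +
    m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

exam_scalars <- function(maps) {
  fk_m <- meridian_means(maps$FK$values)
  bk_m <- meridian_means(maps$BK$values)
  steep_fk <- which.max(fk_m)
  steep_bk <- which.min(bk_m)  # most negative = steepest posterior
  perp <- function(i, mm) mm[[(i - 1 + length(mm) / 2) %% length(mm) + 1]]
  fk1 <- perp(steep_fk, fk_m); fk2 <- fk_m[[steep_fk]]
  bk2 <- bk_m[[steep_bk]]; bk1 <- perp(steep_bk, bk_m)
  c(FK1 = fk1, FK2 = fk2, FKm = (fk1 + fk2) / 2,
    FKmax = max(maps$FK$values, na.rm = TRUE),
    BK1 = bk1, BK2 = bk2, BKm = (bk1 + bk2) / 2,
    BKmax = min(maps$BK$values, na.rm = TRUE),
    TCT = min(maps$CP$values, na.rm = TRUE),
    CTV = maps$CP$values[CENTER_INDEX, CENTER_INDEX])
}

#' Simulate one subject's paired eyes
#'
#' Builds the right eye from the base profile and the left eye from the
#' mirrored, jittered profile with the fellow cone amplitude, then derives
#' all five modality maps and the scalar indices for each eye. Fully
#' deterministic for a fixed profile (the seed drives jitter and noise).
#'
#' @param pp a [pair_profile].
#' @param subject_id identifier stored in both exams.
#' @return List with elements `od` and `os` ([eye_exam]s) and `profiles`
#'   (the realised per-eye [cornea_profile]s).
#' @examples
#' pair <- simulate_pair(pair_profile(seed = 42))
#' pair$od$scalars[["FKm"]]
#' @export
simulate_pair <- function(pp, subject_id = "sim") {
  stopifnot(inherits(pp, "pair_profile"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(pp$seed)
  j <- pp$jitter
  od_prof <- pp$base
  os_prof <- mirror_profile(pp$base)
  os_prof$R_ant <- os_prof$R_ant + stats::rnorm(1, 0, jget(j, "R_ant"))
  os_prof$R_post <- os_prof$R_post + stats::rnorm(1, 0, jget(j, "R_post"))
  os_prof$CCT <- os_prof$CCT + stats::rnorm(1, 0, jget(j, "CCT"))
  os_prof$astig_D <- max(0, os_prof$astig_D +
                           stats::rnorm(1, 0, jget(j, "astig_D")))
  os_prof$astig_axis <- (os_prof$astig_axis +
                           stats::rnorm(1, 0, jget(j, "astig_axis"))) %% 180
  os_prof$Q_ant <- os_prof$Q_ant + stats::rnorm(1, 0, jget(j, "Q"))
  os_prof$cone_A <- os_prof$cone_A * pp$fellow_amp_frac
  od <- build_eye_exam(od_prof, "OD", subject_id, pp$noise_sd, pp$smooth_mm)
  os <- build_eye_exam(os_prof, "OS", subject_id, pp$noise_sd, pp$smooth_mm)
  list(od = od, os = os, profiles = list(od = od_prof, os = os_prof))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

rtrunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (k in 1:20) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Cohort simulation settings
#'
#' Group sizes default to the clinical reference cohort (161 keratoconus /
#' ectasia subjects, 174 controls). Keratoconic subjects draw a positive
#' cone amplitude with between-eye asymmetry; a `ffk_fraction` of them get a
#' near-zero fellow amplitude (forme fruste pattern). Controls have no cone.
#' All biometric draws are truncated normals.
#'
#' @param n_kc,n_control group sizes.
#' @param seed master seed; every subject's maps derive from it.
#' @param ffk_fraction fraction of keratoconic subjects whose fellow eye is
#'   topographically normal.
#' @param noise_sd,jitter,smooth_mm passed to each subject's
#'   [pair_profile()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_kc = 161, n_control = 174, seed = 1L,
                          ffk_fraction = 0.25,
                          noise_sd = c(FK = 0.33, FE = 2.3, BE = 5.6, CP = 8.5),
                          jitter = c(R_ant = 0.05, R_post = 0.05, CCT = 8,
                                     astig_D = 0.25, astig_axis = 8, Q = 0.03),
                          smooth_mm = 0.25) {
  stopifnot(n_kc >= 0, n_control >= 0, n_kc + n_control >= 1,
            ffk_fraction >= 0, ffk_fraction <= 1)
  structure(list(n_kc = as.integer(n_kc), n_control = as.integer(n_control),
                 seed = as.integer(seed), ffk_fraction = ffk_fraction,
                 noise_sd = noise_sd, jitter = jitter, smooth_mm = smooth_mm),
            class = "cohort_config")
}

draw_profile <- function(group) {
  if (group == "KC") {
    cornea_profile(
      R_ant = rtrunc(1, 7.40, 0.40, 6.40, 8.40),
      R_post = rtrunc(1, 6.15, 0.35, 5.30, 7.00),
      Q_ant = rtrunc(1, -0.40, 0.15, -0.80, -0.05),
      Q_post = rtrunc(1, -0.50, 0.15, -0.90, -0.10),
      CCT = rtrunc(1, 490, 40, 385, 585),
      astig_D = rtrunc(1, 1.8, 1.0, 0, 5),
      astig_axis = stats::runif(1, 0, 180),
      cone_A = rtrunc(1, 0.075, 0.040, 0.020, 0.200),
      cone_x = rtrunc(1, 0.6, 0.4, -0.5, 1.8),
      cone_y = rtrunc(1, -1.0, 0.4, -2.2, 0.2),
      cone_sigma = rtrunc(1, 1.5, 0.3, 0.8, 2.5),
      post_cone_scale = rtrunc(1, 1.5, 0.15, 1.15, 1.85))
  } else {
    cornea_profile(
      R_ant = rtrunc(1, 7.85, 0.25, 7.20, 8.70),
      R_post = rtrunc(1, 6.50, 0.20, 5.95, 7.05),
      Q_ant = rtrunc(1, -0.25, 0.10, -0.55, 0.05),
      Q_post = rtrunc(1, -0.35, 0.10, -0.65, -0.05),
      CCT = rtrunc(1, 545, 33, 460, 645),
      astig_D = rtrunc(1, 0.75, 0.50, 0, 3),
      astig_axis = stats::runif(1, 0, 180),
      cone_A = 0)
  }
}

#' Simulate a keratoconus/control cohort
#'
#' Generates `n_kc + n_control` paired exams, a pure function of the master
#' seed. If `dir` is given, each subject's ten modality grids are written as
#' matrix files plus a `manifest.csv` (the layout [load_cohort()] consumes)
#' and a `metadata.txt` recording the effective seed and group sizes.
#'
#' @param cfg a [cohort_config].
#' @param dir optional output directory (created if needed).
#' @return A `paired_cohort` list (as from [load_cohort()]), invisibly when
#'   `dir` is given.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  groups <- c(rep("KC", cfg$n_kc), rep("control", cfg$n_control))
  ids <- sprintf("%s%03d", ifelse(groups == "KC", "kc", "ct"),
                 c(seq_len(cfg$n_kc), seq_len(cfg$n_control)))
  subj_seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
  ffk <- rep(FALSE, length(groups))
  if (cfg$n_kc > 0)
    ffk[seq_len(cfg$n_kc)] <- stats::runif(cfg$n_kc) < cfg$ffk_fraction
  fellow <- ifelse(ffk, stats::runif(length(groups), 0, 0.05),
                   stats::runif(length(groups), 0.10, 0.60))
  profiles <- lapply(groups, draw_profile)
  worse_od <- stats::runif(length(groups)) < 0.5

  cohort <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    pp <- pair_profile(base = profiles[[i]],
                       fellow_amp_frac = if (groups[i] == "KC") fellow[i] else 1,
                       jitter = cfg$jitter, noise_sd = cfg$noise_sd,
                       smooth_mm = cfg$smooth_mm, seed = subj_seeds[i])
    pair <- simulate_pair(pp, subject_id = ids[i])
    if (!worse_od[i]) {  # worse eye on the left: swap lateralities
      tmp <- pair$od; pair$od <- pair$os; pair$os <- tmp
      pair$od$laterality <- "OD"; pair$os$laterality <- "OS"
      for (m in names(pair$od$maps)) {
        pair$od$maps[[m]] <- mirror_flip(pair$od$maps[[m]])
        pair$od$maps[[m]]$laterality <- "OD"
        pair$od$maps[[m]]$mirrored <- FALSE
        pair$os$maps[[m]] <- mirror_flip(pair$os$maps[[m]])
        pair$os$maps[[m]]$laterality <- "OS"
        pair$os$maps[[m]]$mirrored <- FALSE
      }
    }
    cohort[[i]] <- list(subject_id = ids[i], group = groups[i],
                        od = pair$od, os = pair$os)
  }
  cohort <- structure(cohort, class = "paired_cohort", n_skipped = 0L)
  if (!is.null(dir)) {
    write_cohort_files(cohort, dir, cfg)
    return(invisible(cohort))
  }
  cohort
}

write_cohort_files <- function(cohort, dir, cfg) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mods <- c(fk = "FK", bk = "BK", fe = "FE", be = "BE", cp = "CP")
  rows <- lapply(cohort, function(s) {
    paths <- list(subject_id = s$subject_id, group = s$group)
    for (eye in c("od", "os")) {
      exam <- s[[eye]]
      for (key in names(mods)) {
        fn <- sprintf("%s_%s_%s.csv", s$subject_id, eye, key)
        write_topo_matrix(exam$maps[[mods[key]]], file.path(dir, fn))
        paths[[paste0(eye, "_", key)]] <- fn
      }
    }
    as.data.frame(paths, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("seed: %d", cfg$seed),
               sprintf("n_kc: %d", cfg$n_kc),
               sprintf("n_control: %d", cfg$n_control),
               sprintf("ffk_fraction: %g", cfg$ffk_fraction)),
             file.path(dir, "metadata.txt"))
  invisible(manifest)
}
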