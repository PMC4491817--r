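#' Acquisition specification for simulated tilt series
#'
#' Defaults follow a single-axis cryo-tomography scheme: tilt range -60
#' to +60 degrees in 3 degree increments, nominal underfocus -6
#' micrometre, 300 keV.
#'
#' @param tilt_min,tilt_max,tilt_step tilt range and increment, degrees.
#' @param tilt_axis azimuth of the tilt axis in the image plane,
#'   degrees (0 = y axis; only 0 is currently supported by the
#'   strip-based CTF machinery).
#' @param defocus_nominal mean defocus in micrometre (negative =
#'   underfocus).
#' @param pixel_size pixel size at the specimen level, Angstrom.
#' @param dose_noise_sigma additive Gaussian noise sigma per pixel,
#'   relative to the signal RMS of the clean projections.
#' @param seed integer seed recorded in all outputs.
#' @return an `AcquisitionSpec` list.
#' @export
acquisition_spec <- function(tilt_min = -60, tilt_max = 60, tilt_step = 3,
                             tilt_axis = 0, defocus_nominal = -6,
                             pixel_size = 13.2, dose_noise_sigma = 0,
                             seed = 1L) {
  stopifnot(tilt_min < tilt_max, tilt_step > 0)
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 tilt_step = tilt_step, tilt_axis = tilt_axis,
                 defocus_nominal = defocus_nominal,
                 pixel_size = pixel_size,
                 dose_noise_sigma = dose_noise_sigma,
                 seed = as.integer(seed)),
            class = "AcquisitionSpec")
}

#' Pore phantom specification
#'
#' Geometry of the synthetic eightfold pore: eight soft spheres
#' (diameter 40 nm) on a circle (diameter 90 nm), optionally embedded in
#' a double-membrane patch (shell spacing 35 nm), with an optional
#' per-particle variable sphere and an optional planted asymmetric
#' rigid body for docking tests.
#'
#' @param ring_diameter circle diameter in Angstrom.
#' @param sphere_diameter sphere diameter in Angstrom.
#' @param n_fold rotational symmetry order.
#' @param membrane logical; render the double-membrane patch.
#' @param membrane_spacing luminal height (distance between the two
#'   membrane shells), Angstrom.
#' @param membrane_sigma Gaussian thickness of each shell, Angstrom.
#' @param membrane_amplitude shell density relative to sphere density.
#' @param variable_sphere index (1..n_fold) of a sphere replaced, per
#'   particle, by a randomized lobe arrangement; `NA` disables it.
#' @param planted_body logical; plant an asymmetric three-lobe body at
#'   the first protomer position.
#' @return a `PorePhantom` specification list.
#' @export
pore_phantom_spec <- function(ring_diameter = 900, sphere_diameter = 400,
                              n_fold = 8L, membrane = TRUE,
                              membrane_spacing = 350, membrane_sigma = 25,
                              membrane_amplitude = 0.5,
                              variable_sphere = NA_integer_,
                              planted_body = FALSE) {
  structure(list(ring_diameter = ring_diameter,
                 sphere_diameter = sphere_diameter,
                 n_fold = as.integer(n_fold), membrane = membrane,
                 membrane_spacing = membrane_spacing,
                 membrane_sigma = membrane_sigma,
                 membrane_amplitude = membrane_amplitude,
                 variable_sphere = variable_sphere,
                 planted_body = planted_body),
            class = "PorePhantom")
}

# Add a raised-cosine-edged solid sphere into an array (0-based center,
# voxels), touching only a local bounding box for speed.
add_soft_sphere <- function(a, center, radius, edge = 2, amplitude = 1) {
  d <- dim(a)
  lo <- pmax(floor(center - radius - edge), 0)
  hi <- pmin(ceiling(center + radius + edge), d - 1)
  if (any(lo > hi)) return(a)
  ix <- (lo[1]:hi[1]); iy <- (lo[2]:hi[2]); iz <- (lo[3]:hi[3])
  r <- sqrt(outer(outer((ix - center[1])^2, (iy - center[2])^2, `+`),
                  (iz - center[3])^2, `+`))
  v <- array(0, dim(r))
  v[r <= radius - edge] <- 1
  sel <- r > radius - edge & r < radius
  v[sel] <- 0.5 * (1 + cos(pi * (r[sel] - radius + edge) / edge))
  a[ix + 1, iy + 1, iz + 1] <- a[ix + 1, iy + 1, iz + 1] + amplitude * v
  a
}

# Asymmetric three-lobe "Y-complex-like" rigid body rendered about a
# 0-based center; lobe offsets are in Angstrom in the local (unrotated)
# frame and are rotated by R.
planted_body_lobes <- function() {
  list(offsets = rbind(c(0, 0, 0), c(130, 60, 40), c(60, -110, -50)),
       radii = c(70, 55, 42), amplitudes = c(1.3, 1.2, 1.1))
}

add_planted_body <- function(a, center, R, voxel_size, edge = 2) {
  lob <- planted_body_lobes()
  for (i in seq_along(lob$radii)) {
    off <- as.numeric(R %*% lob$offsets[i, ]) / voxel_size
    a <- add_soft_sphere(a, center + off, lob$radii[i] / voxel_size, edge,
                         lob$amplitudes[i])
  }
  a
}

# Render one pore (plus membrane patch/body) into an array.
# center: 0-based voxel position of the pore center; R: rotation matrix
# (pore axis = R %*% z); rng must already be seeded by the caller when a
# variable sphere is requested.
render_pore <- function(a, spec, center, R, voxel_size, edge = 2,
                        membrane_extent = Inf) {
  d <- dim(a)
  n_fold <- spec$n_fold
  rring <- spec$ring_diameter / 2
  rsph <- spec$sphere_diameter / 2
  for (k in seq_len(n_fold) - 1L) {
    ang <- 2 * pi * k / n_fold
    p <- c(rring * cos(ang), rring * sin(ang), 0)
    ck <- center + as.numeric(R %*% p) / voxel_size
    if (!is.na(spec$variable_sphere) && k == spec$variable_sphere - 1L) {
      # randomized lobes standing in for a structurally variable domain
      n_lobes <- 4L
      for (l in seq_len(n_lobes)) {
        off <- runif(3, -0.55, 0.55) * rsph
        cl <- center + as.numeric(R %*% (p + off)) / voxel_size
        a <- add_soft_sphere(a, cl, runif(1, 0.35, 0.5) * rsph / voxel_size,
                             edge, runif(1, 0.7, 1.4))
      }
    } else {
      a <- add_soft_sphere(a, ck, rsph / voxel_size, edge)
    }
  }
  if (isTRUE(spec$membrane)) {
    # double Gaussian-profile shells, locally planar, with a soft pore
    # opening of the ring diameter
    ctr_rel <- sweep_coords(d, center, R, voxel_size)
    rho <- sqrt(ctr_rel$x^2 + ctr_rel$y^2)
    zz <- ctr_rel$z
    shell <- exp(-(abs(zz) - spec$membrane_spacing / 2)^2 /
                   (2 * spec$membrane_sigma^2))
    hole <- 1 / (1 + exp(-(rho - rring) / 30))
    patch <- if (is.finite(membrane_extent))
      1 / (1 + exp((rho - membrane_extent) / 30)) else 1
    a <- a + spec$membrane_amplitude * shell * hole * patch
  }
  if (isTRUE(spec$planted_body)) {
    cb <- center + as.numeric(R %*% planted_body_position(spec)) / voxel_size
    a <- add_planted_body(a, cb, R, voxel_size, edge)
  }
  a
}

# Planted-body centre in the pore frame (Angstrom): above the ring
# plane, clear of the ring spheres.
planted_body_position <- function(spec) {
  c(spec$ring_diameter / 2, 0, spec$sphere_diameter * 0.95)
}

# Pore-frame coordinates (Angstrom) of every voxel of a grid, given the
# pore center (0-based voxels) and rotation R.
sweep_coords <- function(d, center, R, voxel_size) {
  xs <- (seq_len(d[1]) - 1 - center[1]) * voxel_size
  ys <- (seq_len(d[2]) - 1 - center[2]) * voxel_size
  zs <- (seq_len(d[3]) - 1 - center[3]) * voxel_size
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  Rt <- t(R)
  list(x = Rt[1, 1] * X + Rt[1, 2] * Y + Rt[1, 3] * Z,
       y = Rt[2, 1] * X + Rt[2, 2] * Y + Rt[2, 3] * Z,
       z = Rt[3, 1] * X + Rt[3, 2] * Y + Rt[3, 3] * Z)
}

#' Build a ground-truth phantom tomogram
#'
#' Places `n_copies` eightfold pores on a gently curved oblate-spheroid
#' membrane surface inside a tomogram-sized box, with per-copy in-plane
#' rotation uniform on `[0, 360)` degrees and out-of-plane tilt given by
#' the local membrane normal.  Returns the density together with the
#' exact per-copy poses and membrane normals.
#'
#' @param spec a [pore_phantom_spec()].
#' @param box tomogram dimensions in voxels (length 1 or 3).
#' @param voxel_size Angstrom per voxel.
#' @param n_copies number of pores.
#' @param positions optional n x 2 matrix of lateral (x, y) positions in
#'   voxels (0-based); defaults to a centred lattice.
#' @param spheroid_a,spheroid_c equatorial and polar semi-axes of the
#'   membrane spheroid, Angstrom.
#' @param seed integer seed.
#' @return list with `volume` (`Volume`), `particles` (ground-truth
#'   particle data frame with poses, in voxels/degrees, and membrane
#'   normals) and `membrane_points` (points sampled on the membrane
#'   surface, Angstrom, for spheroid-fitting).
#' @export
build_phantom <- function(spec = pore_phantom_spec(), box = 192,
                          voxel_size = 13.2, n_copies = 2,
                          positions = NULL, spheroid_a = 8000,
                          spheroid_c = 2000, seed = 1L) {
  d <- if (length(box) == 1) rep(box, 3) else box
  set.seed(seed)
  ctr <- floor(d / 2)
  extent_vox <- (spec$ring_diameter + spec$sphere_diameter) / voxel_size
  if (is.null(positions)) {
    step <- extent_vox + 6
    if (n_copies == 1) {
      positions <- cbind(ctr[1], ctr[2])
    } else if (n_copies == 2) {
      # diagonal pair: tighter packing than a lattice
      h <- step / (2 * sqrt(2))
      positions <- cbind(ctr[1] + c(-h, h), ctr[2] + c(-h, h))
    } else {
      ngrid <- ceiling(sqrt(n_copies))
      offs <- (seq_len(ngrid) - (ngrid + 1) / 2) * step
      g <- expand.grid(x = offs, y = offs)[seq_len(n_copies), ,
                                           drop = FALSE]
      positions <- cbind(ctr[1] + g$x, ctr[2] + g$y)
    }
  }
  n_copies <- nrow(positions)
  # collision check (pore footprints on the surface)
  if (n_copies > 1) {
    pd <- as.matrix(dist(positions))
    bad <- which(pd < extent_vox & upper.tri(pd), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("build_phantom: placement error, colliding copies: ",
           paste(apply(bad, 1, paste, collapse = "-"), collapse = ", "))
  }
  # spheroid with its upper pole at the box center
  sph_center <- c(ctr[1], ctr[2], ctr[3] - spheroid_c / voxel_size)
  a <- array(0, d)
  rows <- vector("list", n_copies)
  for (i in seq_len(n_copies)) {
    lx <- (positions[i, 1] - sph_center[1]) * voxel_size
    ly <- (positions[i, 2] - sph_center[2]) * voxel_size
    rad2 <- (lx^2 + ly^2) / spheroid_a^2
    if (rad2 >= 1)
      stop("build_phantom: copy ", i, " falls off the spheroid surface")
    lz <- spheroid_c * sqrt(1 - rad2)
    zpos <- sph_center[3] + lz / voxel_size
    normal <- c(2 * lx / spheroid_a^2, 2 * ly / spheroid_a^2,
                2 * lz / spheroid_c^2)
    normal <- normal / sqrt(sum(normal^2))
    inplane <- runif(1, 0, 360)
    R <- rotation_from_axis(normal) %*% euler_to_matrix(inplane, 0, 0)
    ang <- matrix_to_euler(R)
    center <- c(positions[i, 1], positions[i, 2], zpos)
    if (any(center - extent_vox / 2 < 0) || any(center + extent_vox / 2 > d - 1))
      stop("build_phantom: copy ", i, " does not fit inside the tomogram")
    a <- render_pore(a, spec, center, R, voxel_size,
                     membrane_extent = (extent_vox / 2 + 10) * voxel_size)
    rows[[i]] <- data.frame(particle_id = i, tomo_id = 1L,
                            x = center[1], y = center[2], z = center[3],
                            phi = ang[1], theta = ang[2], psi = ang[3],
                            dx = 0, dy = 0, dz = 0, cc = NA_real_,
                            at_window_limit = FALSE, keep = TRUE,
                            reason = "",
                            norm_x = normal[1], norm_y = normal[2],
                            norm_z = normal[3],
                            stringsAsFactors = FALSE)
  }
  # membrane surface samples for spheroid fitting (Angstrom, volume frame)
  th <- runif(200, 0, 2 * pi)
  rr <- sqrt(runif(200)) * min(d[1], d[2]) * 0.4 * voxel_size
  sx <- rr * cos(th); sy <- rr * sin(th)
  sz <- spheroid_c * sqrt(pmax(0, 1 - (sx^2 + sy^2) / spheroid_a^2))
  pts <- cbind(sx + sph_center[1] * voxel_size,
               sy + sph_center[2] * voxel_size,
               sz + sph_center[3] * voxel_size)
  list(volume = new_volume(a, voxel_size),
       particles = do.call(rbind, rows),
       membrane_points = pts,
       spheroid = list(center = sph_center * voxel_size,
                       a = spheroid_a, c = spheroid_c))
}

# Rotation taking the z axis onto a given unit vector (minimal rotation).
rotation_from_axis <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- c(z[2] * v[3] - z[3] * v[2], z[3] * v[1] - z[1] * v[3],
          z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(ax^2)); ax <- ax / s
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  diag(3) + sin(acos(c_)) * K + (1 - c_) * (K %*% K)
}

#' Simulate wedge-filtered noisy NPC subtomograms
#'
#' Generates `n` cubic subtomograms of an eightfold pore at known random
#' poses, applies the missing wedge of a single-axis tilt geometry in
#' Fourier space, and adds white Gaussian noise at a prescribed SNR
#' (signal variance over noise variance, measured inside the particle
#' envelope, before wedge filtering).  Each particle also carries an
#' initial pose estimate obtained by perturbing the truth, emulating the
#' accuracy of geometry-derived seeds (membrane-normal orientation plus
#' approximate picking coordinates).
#'
#' @param n number of particles.
#' @param box cube edge, voxels.
#' @param voxel_size Angstrom per voxel.
#' @param snr signal-to-noise ratio; `Inf` for noise-free particles.
#' @param noise_stage `"pre_wedge"` (noise enters the imaging chain and
#'   is wedge-filtered with the signal, as in a weighted-backprojection
#'   reconstruction of noisy projections) or `"post_wedge"` (noise
#'   added to the reconstructed subvolume, emulating correction
#'   residuals and crowding contributions that are not confined to the
#'   sampled wedge).
#' @param noise_resolution `Inf` for white noise, or a resolution in
#'   Angstrom to which the noise is band-limited (low-frequency
#'   dominated noise, as in real tomograms).
#' @param snr_reference `"support"` (signal s.d. over the structure's
#'   own voxels, above 10% of the maximum) or `"envelope"` (signal
#'   s.d. over the full spherical particle envelope).
#' @param spec a [pore_phantom_spec()]; the membraneless geometric body
#'   is used when `spec$membrane` is `FALSE`.
#' @param tilt_range missing-wedge tilt range, degrees.
#' @param theta_range true out-of-plane tilt range, degrees.
#' @param shift_max true shift magnitude bound per axis, voxels.
#' @param perturb named list with elements `dphi`, `dtheta`, `dpsi`
#'   (degrees) and `dshift` (voxels): half-widths of the uniform errors
#'   applied to the truth to produce the initial pose estimates.
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @return list with `particles` (list of per-particle lists holding
#'   `volume`, `transform` (initial estimate), `wedge`), `truth`
#'   (data frame of true poses) and `reference` (the clean unrotated
#'   phantom `Volume`).
#' @export
simulate_subtomograms <- function(n, box = 64, voxel_size = 26.4, snr = 0.5,
                                  spec = pore_phantom_spec(),
                                  tilt_range = c(-60, 60),
                                  theta_range = c(5, 15), shift_max = 3,
                                  perturb = list(dphi = 18, dtheta = 6,
                                                 dpsi = 18, dshift = 2),
                                  noise_stage = c("pre_wedge",
                                                  "post_wedge"),
                                  noise_resolution = Inf,
                                  snr_reference = c("support", "envelope"),
                                  seed = 1L) {
  noise_stage <- match.arg(noise_stage)
  snr_reference <- match.arg(snr_reference)
  set.seed(seed)
  d <- rep(box, 3)
  ctr <- floor(d / 2)
  ref <- array(0, d)
  ref <- render_pore(ref, within_spec_novar(spec), ctr, diag(3), voxel_size)
  env <- spherical_mask(box, (spec$ring_diameter + spec$sphere_diameter) /
                          2 / voxel_size + 2)
  wedge <- wedge_mask(box, tilt_range[1], tilt_range[2])
  warr <- wedge_array(wedge)
  noise_filter <- NULL
  if (is.finite(noise_resolution)) {
    cutoff <- box * voxel_size / noise_resolution
    noise_filter <- exp(-(fourier_shells(box) / cutoff)^2)
  }
  particles <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    phi <- runif(1, 0, 360); psi <- runif(1, 0, 360)
    theta <- runif(1, theta_range[1], theta_range[2])
    shift <- runif(3, -shift_max, shift_max)
    R <- euler_to_matrix(phi, theta, psi)
    a <- array(0, d)
    a <- render_pore(a, spec, ctr + shift, R, voxel_size)
    sig_sd <- if (snr_reference == "support")
      sd(a[a > 0.1 * max(a)]) else sd(a[env > 0.5])
    noise <- 0
    if (is.finite(snr)) {
      noise <- array(rnorm(length(a)), d)
      if (!is.null(noise_filter)) {
        noise <- Re(fft(fft(noise) * noise_filter, inverse = TRUE)) /
          length(noise)
        noise <- noise / sd(noise)
      }
      noise <- noise * sig_sd / sqrt(snr)
    }
    obs <- if (noise_stage == "pre_wedge") {
      Re(fft(fft(a + noise) * warr, inverse = TRUE)) / length(a)
    } else {
      Re(fft(fft(a) * warr, inverse = TRUE)) / length(a) + noise
    }
    t0 <- rigid_transform(phi + runif(1, -perturb$dphi, perturb$dphi),
                          theta + runif(1, -perturb$dtheta, perturb$dtheta),
                          psi + runif(1, -perturb$dpsi, perturb$dpsi),
                          shift + runif(3, -perturb$dshift, perturb$dshift))
    particles[[i]] <- list(volume = new_volume(obs, voxel_size),
                           transform = t0, wedge = wedge,
                           particle_id = i, keep = TRUE)
    truth[[i]] <- data.frame(particle_id = i, phi = phi, theta = theta,
                             psi = psi, dx = shift[1], dy = shift[2],
                             dz = shift[3])
  }
  list(particles = particles, truth = do.call(rbind, truth),
       reference = new_volume(ref, voxel_size))
}

# The reference rendering must not contain the per-particle variable
# domain; render the plain sphere there instead.
within_spec_novar <- function(spec) {
  spec$variable_sphere <- NA_integer_
  spec
}

#' Project a volume into a tilt series
#'
#' Line integrals along the beam (z) after rotating the volume about the
#' tilt axis (y) by each tilt angle; one trilinear interpolation per
#' tilt.
#'
#' @param volume a cubic `Volume`.
#' @param acq an [acquisition_spec()].
#' @return a `TiltSeries`: list with `images` (nx x ny x n_tilt array),
#'   `angles`, `tilt_axis`, `pixel_size`, `defocus` (per image,
#'   micrometre), `acq`.
#' @export
project_tilt_series <- function(volume, acq = acquisition_spec()) {
  stopifnot(inherits(volume, "Volume"))
  if (!is_cubic(volume)) stop("project_tilt_series: cubic volume required")
  angles <- seq(acq$tilt_min, acq$tilt_max, by = acq$tilt_step)
  d <- vol_dim(volume)
  imgs <- array(0, c(d[1], d[2], length(angles)))
  for (i in seq_along(angles)) {
    # Ry(alpha) expressed in Z-X-Z Euler angles
    rot <- rigid_transform(90, angles[i], -90)
    rv <- apply_transform(volume, rot, fill = 0)
    imgs[, , i] <- rowSums(rv$data, dims = 2)
  }
  structure(list(images = imgs, angles = angles, tilt_axis = acq$tilt_axis,
                 pixel_size = volume$voxel_size,
                 defocus = rep(acq$defocus_nominal, length(angles)),
                 acq = acq),
            class = "TiltSeries")
}

#' @export
print.TiltSeries <- function(x, ...) {
  cat(sprintf("TiltSeries: %d projections %d x %d, tilts %g..%g, pixel %.2f A\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              min(x$angles), max(x$angles), x$pixel_size))
  invisible(x)
}

#' Corrupt a tilt series with CTF, detector MTF and noise
#'
#' Applies, per image, the strip-wise CTF at the image's defocus
#' gradient (defocus varying with the signed distance from the tilt
#' axis), multiplies by the detector MTF, and adds white Gaussian noise.
#' This is the forward model that the CTF-correction stage inverts.
#'
#' @param tilt_series a `TiltSeries`.
#' @param acq an [acquisition_spec()]; `dose_noise_sigma` is relative to
#'   the clean-series signal RMS.
#' @param ctf a [ctf_model()]; its nominal defocus is taken from `acq`.
#' @param n_strips number of CTF strips per image; `NULL` adapts the
#'   count so strips stay at least 64 pixels wide (the defocus gradient
#'   across narrow fields is negligible, while narrow strips alias the
#'   CTF), capped at 16.
#' @return the corrupted `TiltSeries` (defocus metadata retained).
#' @export
corrupt <- function(tilt_series, acq = tilt_series$acq,
                    ctf = ctf_model(defocus = acq$defocus_nominal),
                    n_strips = NULL) {
  ts <- tilt_series
  set.seed(acq$seed)
  nt <- dim(ts$images)[3]
  if (is.null(n_strips)) n_strips <- default_n_strips(dim(ts$images)[1])
  rms <- sd(as.numeric(ts$images))
  for (i in seq_len(nt)) {
    img <- ts$images[, , i]
    if (abs(acq$defocus_nominal) > 0) {
      dstrip <- defocus_gradient(dim(img)[1], ts$pixel_size, ts$angles[i],
                                 ts$tilt_axis, acq$defocus_nominal,
                                 n_strips)
      img <- apply_ctf_strips(img, dstrip, ctf, ts$pixel_size,
                              mode = "ctf")
    }
    if (ctf$mtf == "sinc2")
      img <- apply_mtf(img, ts$pixel_size, inverse = FALSE)
    if (acq$dose_noise_sigma > 0)
      img <- img + rnorm(length(img), sd = acq$dose_noise_sigma * rms)
    ts$images[, , i] <- img
  }
  ts$defocus <- rep(acq$defocus_nominal, nt)
  ts
}

#' Weighted backprojection reconstruction
#'
#' Ramp-weighted (r*-weighted) backprojection of a single-axis tilt
#' series; the reconstruction is then restricted in Fourier space to the
#' sampled wedge, so amplitudes outside the measured region are zero by
#' construction.
#'
#' @param tilt_series a `TiltSeries` with at least 3 projections.
#' @param size output cube edge in voxels (defaults to the image size).
#' @return the reconstructed `Volume`.
#' @export
weighted_backprojection <- function(tilt_series, size = NULL) {
  imgs <- tilt_series$images
  nt <- dim(imgs)[3]
  if (nt < 3)
    stop("weighted_backprojection: need at least 3 projections")
  nx <- dim(imgs)[1]
  if (is.null(size)) size <- nx
  # discrete ramp (Ram-Lak) weighting along the direction perpendicular
  # to the tilt axis, built from its real-space kernel so the DC term is
  # correct (a plain |k| with a zeroed DC bin produces cupping)
  h <- numeric(nx)
  m <- fft_freq_index(nx)
  h[1] <- 0.25
  odd <- which(m %% 2 != 0)
  h[odd] <- -1 / (pi^2 * m[odd]^2)
  ramp <- Re(fft(h))
  for (i in seq_len(nt)) {
    F <- mvfft(imgs[, , i])
    imgs[, , i] <- Re(mvfft(F * ramp, inverse = TRUE)) / nx
  }
  rec <- cpp_backproject(as.numeric(imgs), as.integer(dim(imgs)),
                         tilt_series$angles * pi / 180,
                         as.integer(rep(size, 3)))
  rec <- array(rec, rep(size, 3))
  w <- wedge_array(wedge_mask(size, min(tilt_series$angles) - 1e-6,
                              max(tilt_series$angles) + 1e-6))
  rec <- Re(fft(fft(rec) * w, inverse = TRUE)) / length(rec)
  # angular weight of the discretized backprojection integral
  dtheta <- pi / 180 * mean(diff(tilt_series$angles))
  new_volume(rec * dtheta, tilt_series$pixel_size)
}

# Largest power-of-two strip count (capped at 16) keeping strips at
# least 64 pixels wide.
default_n_strips <- function(nx) {
  n <- 1L
  while (n < 16L && nx %/% (2L * n) >= 64L) n <- 2L * n
  n
}
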