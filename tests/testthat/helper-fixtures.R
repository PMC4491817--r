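# Shared fixtures: small phantoms and simulation wrappers used across
# the module tests.  Everything is generated in code at test time.

# A smooth asymmetric blob phantom (two soft spheres) for transform and
# reconstruction tests.
blob_phantom <- function(n = 32, voxel_size = 10) {
  a <- array(0, rep(n, 3))
  a <- tomopore:::add_soft_sphere(a, rep(n / 2, 3) + c(4, -2, 0),
                                  n / 6, 2)
  a <- tomopore:::add_soft_sphere(a, rep(n / 2, 3) + c(-5, 3, -2),
                                  n / 8, 2, amplitude = 0.7)
  new_volume(a, voxel_size)
}

# NPC phantom plus fine granular texture inside the particle envelope,
# so the averages carry signal near Nyquist (used by the interpolation
# accounting tests).
textured_pore <- function(box = 32, voxel_size = 52.8, tex_amp = 0.5,
                          seed = 1) {
  set.seed(seed)
  d <- rep(box, 3)
  a <- array(0, d)
  a <- tomopore:::render_pore(a, pore_phantom_spec(), floor(d / 2),
                              diag(3), voxel_size)
  env <- spherical_mask(box, box * 0.4)
  tex <- lowpass(new_volume(array(rnorm(box^3), d), voxel_size),
                 3.2 * voxel_size)$data
  new_volume(a + tex / sd(tex) * tex_amp * env, voxel_size)
}

# Wedge-filtered noisy copies of a base volume at known poses; noise is
# added before the wedge (reconstruction-type noise).
simulate_copies <- function(base, n, snr, seed, theta_range = c(5, 15),
                            shift_max = 3, tilt_range = c(-60, 60)) {
  set.seed(seed)
  box <- dim(base$data)[1]
  wedge <- wedge_mask(box, tilt_range[1], tilt_range[2])
  warr <- wedge_array(wedge)
  env <- spherical_mask(box, box * 0.4)
  parts <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- rigid_transform(runif(1, 0, 360),
                          runif(1, theta_range[1], theta_range[2]),
                          runif(1, 0, 360), runif(3, -shift_max, shift_max))
    a <- apply_transform(base, tr)$data
    sig <- sd(a[env > 0.5])
    nz <- if (is.finite(snr)) rnorm(box^3, sd = sig / sqrt(snr)) else 0
    obs <- Re(fft(fft(a + nz) * warr, inverse = TRUE)) / box^3
    parts[[i]] <- list(volume = new_volume(obs, base$voxel_size),
                       transform = tr, wedge = wedge, particle_id = i,
                       keep = TRUE)
    truth[[i]] <- tr
  }
  list(particles = parts, truth = truth)
}

# Isolated three-lobe asymmetric body (the docking component) in its
# own box.
body_volume <- function(box = 24, voxel_size = 26.4) {
  a <- array(0, rep(box, 3))
  a <- tomopore:::add_planted_body(a, floor(rep(box, 3) / 2), diag(3),
                                   voxel_size)
  new_volume(a, voxel_size)
}

# Desk-scale protomer geometry used throughout the hierarchy tests.
desk_protomer_spec <- function() {
  protomer_spec(protomer_box = 32, radius = 450, subprotomer_box = 16,
                subprotomer_z = c(cpr = 180, npr = -180, sr_ccr = 0))
}
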