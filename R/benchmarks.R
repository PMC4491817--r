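#' Planted-pose recovery benchmark
#'
#' Simulates cubic pore subtomograms at known poses, runs the full
#' global alignment (coarse-to-fine windows, angular scoring at binning
#' 2 with a final unbinned translation stage), extracts and refines the
#' eight protomers for a subset of particles, and reports pose errors
#' against the ground truth (rotations compared modulo the C8 symmetry
#' of the reference).
#'
#' @param n number of subtomograms.
#' @param box cube edge, voxels.
#' @param voxel_size Angstrom per voxel.
#' @param snr simulation signal-to-noise ratio.
#' @param n_protomer_npcs number of pores whose protomers are refined.
#' @param seed integer seed.
#' @return list with `median_angular_error_deg`,
#'   `median_shift_error_voxels`, `protomer_median_angular_error_deg`
#'   and the per-particle errors.
#' @export
benchmark_pose_recovery <- function(n = 32, box = 64, voxel_size = 26.4,
                                    snr = 0.5, n_protomer_npcs = 8,
                                    seed = 1L) {
  sim <- simulate_subtomograms(n, box = box, voxel_size = voxel_size,
                               snr = snr, seed = seed)
  ref <- make_geometric_template(box, voxel_size)
  stages <- list(
    list(window = angular_window(30, 12, 30, 10), shift_bound = 4,
         binning = 2),
    list(window = angular_window(8, 8, 8, 4), shift_bound = 3,
         binning = 2),
    list(window = angular_window(3, 3, 3, 1.5), shift_bound = 2,
         binning = 2),
    list(window = angular_window(0, 0, 0, 1), shift_bound = 2,
         binning = 1))
  out <- align_particles(sim$particles, ref, stages)
  ang <- vapply(seq_len(n), function(i) {
    tru <- sim$truth[i, ]
    sym_rotation_distance(out[[i]]$transform,
                          rigid_transform(tru$phi, tru$theta, tru$psi))
  }, numeric(1))
  shift <- vapply(seq_len(n), function(i) {
    tru <- sim$truth[i, ]
    sqrt(sum((out[[i]]$transform$shift -
                c(tru$dx, tru$dy, tru$dz))^2))
  }, numeric(1))
  # protomer-level refinement for a subset of pores
  pspec <- protomer_spec(protomer_box = box / 2, radius = 450,
                         subprotomer_box = box / 4,
                         subprotomer_z = c(cpr = 180, npr = -180,
                                           sr_ccr = 0))
  spec_mem <- pore_phantom_spec()
  big <- 3 * box / 2
  pref_src <- new_volume(
    render_pore(array(0, rep(big, 3)), spec_mem, floor(rep(big, 3) / 2),
                diag(3), voxel_size), voxel_size)
  pref <- protomer_reference(pref_src, pspec)
  perr <- c()
  for (i in seq_len(min(n_protomer_npcs, n))) {
    prots <- extract_protomers(sim$particles[[i]]$volume,
                               out[[i]]$transform,
                               floor(rep(box, 3) / 2), pspec,
                               wedge = wedge_mask(pspec$protomer_box,
                                                  -60, 60),
                               particle_id = i, on_boundary = "pad")
    prots <- align_particles(prots, pref, list(
      list(window = angular_window(4, 4, 4, 2), shift_bound = 2)))
    tru <- sim$truth[i, ]
    perr <- c(perr, vapply(prots, function(p)
      sym_rotation_distance(p$transform,
                            rigid_transform(tru$phi, tru$theta,
                                            tru$psi)), numeric(1)))
  }
  list(median_angular_error_deg = median(ang),
       median_shift_error_voxels = median(shift),
       protomer_median_angular_error_deg = median(perr),
       angular_errors = ang, shift_errors = shift)
}

#' Wedge-constrained versus wedge-ignorant alignment benchmark
#'
#' Simulates pore subtomograms whose noise is band-limited and not
#' confined to the measured wedge (the regime constrained correlation
#' is designed for: correction residuals and crowding contributions in
#' reconstructed subvolumes are low-frequency dominated and leak into
#' the unsampled region), then aligns each particle twice: once with
#' the missing wedge honoured and once ignoring it.  Recovery means a
#' final rotation within 10 degrees of the truth (modulo C8).
#'
#' @param n number of particles.
#' @param box cube edge, voxels.
#' @param voxel_size Angstrom per voxel.
#' @param snr signal-to-noise ratio (structure-referenced).
#' @param noise_resolution noise band limit, Angstrom.
#' @param seed integer seed.
#' @return list with `constrained_recovery`, `ignorant_recovery`,
#'   `gain_percentage_points` and the per-particle errors.
#' @export
benchmark_wedge_benefit <- function(n = 50, box = 32, voxel_size = 52.8,
                                    snr = 0.25, noise_resolution = 300,
                                    seed = 1L) {
  sim <- simulate_subtomograms(n, box = box, voxel_size = voxel_size,
                               snr = snr, theta_range = c(0, 15),
                               noise_stage = "post_wedge",
                               noise_resolution = noise_resolution,
                               perturb = list(dphi = 15, dtheta = 4,
                                              dpsi = 15, dshift = 1.5),
                               seed = seed)
  ref <- make_geometric_template(box, voxel_size)
  stages <- list(
    list(window = angular_window(30, 12, 30, 10), shift_bound = 3),
    list(window = angular_window(8, 8, 8, 4), shift_bound = 2))
  aware <- align_particles(sim$particles, ref, stages)
  blind_parts <- lapply(sim$particles, function(p) {
    p$wedge <- full_wedge(box)
    p
  })
  blind <- align_particles(blind_parts, ref, stages)
  err <- function(out) vapply(seq_len(n), function(i) {
    tru <- sim$truth[i, ]
    sym_rotation_distance(out[[i]]$transform,
                          rigid_transform(tru$phi, tru$theta, tru$psi))
  }, numeric(1))
  ea <- err(aware)
  eb <- err(blind)
  list(constrained_recovery = mean(ea <= 10),
       ignorant_recovery = mean(eb <= 10),
       gain_percentage_points = 100 * (mean(ea <= 10) - mean(eb <= 10)),
       constrained_errors = ea, ignorant_errors = eb)
}

#' Half-set resolution versus particle count
#'
#' Simulates noisy wedge-filtered pore copies at known poses, averages
#' odd/even halves, and reads the half-set FSC resolution at the 0.5
#' criterion for each particle count; the median over seeds should not
#' worsen as the count doubles.
#'
#' @param counts particle counts.
#' @param n_seeds number of seeds.
#' @param box,voxel_size,snr simulation scale.
#' @param seed base seed.
#' @return list with `median_resolution_A` (per count) and the full
#'   seed-by-count matrix.
#' @export
benchmark_fsc_monotonicity <- function(counts = c(8, 16, 32),
                                       n_seeds = 5, box = 32,
                                       voxel_size = 52.8, snr = 0.5,
                                       seed = 1L) {
  res <- matrix(NA_real_, n_seeds, length(counts))
  for (s in seq_len(n_seeds)) {
    for (j in seq_along(counts)) {
      sim <- simulate_subtomograms(counts[j], box = box,
                                   voxel_size = voxel_size, snr = snr,
                                   perturb = list(dphi = 0, dtheta = 0,
                                                  dpsi = 0, dshift = 0),
                                   seed = seed + 1000L * s + j)
      for (i in seq_along(sim$particles)) {
        tru <- sim$truth[i, ]
        sim$particles[[i]]$transform <-
          rigid_transform(tru$phi, tru$theta, tru$psi,
                          c(tru$dx, tru$dy, tru$dz))
      }
      h <- split_halves(sim$particles)
      res[s, j] <- resolution_at(fsc(wedge_average(h$a),
                                     wedge_average(h$b)),
                                 0.5)$resolution
    }
  }
  list(median_resolution_A = apply(res, 2, median), counts = counts,
       all = res)
}

#' Eightfold consistency of the protomer hierarchy
#'
#' Extracts the eight protomers of a noise-free eightfold phantom,
#' checks their pairwise consistency in the common protomer frame, and
#' reassembles the phantom from its subprotomer crops.
#'
#' @param box phantom cube edge, voxels.
#' @param voxel_size Angstrom per voxel.
#' @return list with `min_pairwise_cc` and `round_trip_cc`.
#' @export
benchmark_c8_consistency <- function(box = 96, voxel_size = 26.4) {
  tpl <- make_geometric_template(box, voxel_size)
  pspec <- protomer_spec(protomer_box = 32, radius = 450,
                         subprotomer_box = 16,
                         subprotomer_z = c(cpr = 180, npr = -180,
                                           sr_ccr = 0))
  prots <- extract_protomers(tpl, rigid_transform(),
                             floor(rep(box, 3) / 2), pspec,
                             particle_id = 1)
  aligned <- lapply(prots, function(p)
    apply_transform(p$volume, invert(p$transform)))
  m <- spherical_mask(32, 13)
  ccs <- c()
  for (i in 1:7) for (j in (i + 1):8)
    ccs <- c(ccs, vol_cc(aligned[[i]]$data * m, aligned[[j]]$data * m))
  pref <- protomer_reference(tpl, pspec)
  avgs <- lapply(stats::setNames(names(pspec$subprotomer_z),
                                 names(pspec$subprotomer_z)),
                 function(r) subprotomer_ref_crop(pref, pspec, r))
  model <- assemble_model(avgs, pspec, box, filter_resolution = NA)
  supp <- array(as.numeric(model$data != 0), dim(model$data))
  list(min_pairwise_cc = min(ccs),
       round_trip_cc = vol_cc(model$data * supp, tpl$data * supp))
}

#' Resolution cost of repeated interpolation
#'
#' Averages identical particle sets through the composed-transform
#' route (one trilinear interpolation from the raw data) and through a
#' stage-wise route that resamples the particles in several passes; on
#' phantoms carrying structure near Nyquist the repeated interpolation
#' measurably degrades the half-set resolution.
#'
#' @param n_seeds number of seeds.
#' @param n particles per seed.
#' @param box,voxel_size,snr simulation scale.
#' @param passes resampling passes of the stage-wise route.
#' @param seed base seed.
#' @return list with `median_single_A`, `median_multipass_A` and the
#'   per-seed values.
#' @export
benchmark_interpolation <- function(n_seeds = 5, n = 16, box = 32,
                                    voxel_size = 52.8, snr = 4,
                                    passes = 2L, seed = 1L) {
  single <- numeric(n_seeds)
  multi <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    base <- textured_pore_volume(box, voxel_size, seed = seed + s)
    sim <- simulate_textured_copies(base, n, snr, seed + 100L * s)
    h <- split_halves(sim)
    single[s] <- resolution_at(fsc(wedge_average(h$a),
                                   wedge_average(h$b)), 0.5)$resolution
    multi[s] <- resolution_at(
      fsc(wedge_average(h$a, resample_passes = passes),
          wedge_average(h$b, resample_passes = passes)),
      0.5)$resolution
  }
  list(median_single_A = median(single),
       median_multipass_A = median(multi),
       # the comparison is paired (identical particles per seed), so
       # the seed-wise median of the paired difference is the stable
       # statistic
       median_paired_difference_A = median(multi - single),
       single = single, multipass = multi)
}

# Pore density plus fine granular texture inside the particle envelope
# (signal near Nyquist makes interpolation losses visible).
textured_pore_volume <- function(box, voxel_size, tex_amp = 0.5,
                                 seed = 1L) {
  set.seed(seed)
  d <- rep(box, 3)
  a <- render_pore(array(0, d), pore_phantom_spec(), floor(d / 2),
                   diag(3), voxel_size)
  env <- spherical_mask(box, box * 0.4)
  tex <- lowpass(new_volume(array(rnorm(box^3), d), voxel_size),
                 3.2 * voxel_size)$data
  new_volume(a + tex / sd(tex) * tex_amp * env, voxel_size)
}

# Noisy wedge-filtered copies of a base volume at known (stored) poses.
simulate_textured_copies <- function(base, n, snr, seed) {
  set.seed(seed)
  box <- dim(base$data)[1]
  wedge <- wedge_mask(box, -60, 60)
  warr <- wedge_array(wedge)
  env <- spherical_mask(box, box * 0.4)
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- rigid_transform(runif(1, 0, 360), runif(1, 5, 15),
                          runif(1, 0, 360), runif(3, -3, 3))
    a <- apply_transform(base, tr)$data
    sig <- sd(a[env > 0.5])
    obs <- Re(fft(fft(a + rnorm(box^3, sd = sig / sqrt(snr))) * warr,
                  inverse = TRUE)) / box^3
    parts[[i]] <- list(volume = new_volume(obs, base$voxel_size),
                       transform = tr, wedge = wedge, particle_id = i,
                       keep = TRUE)
  }
  parts
}

#' Local-resolution contrast from a variable subdomain
#'
#' Simulates pore particles whose first ring sphere is randomized per
#' particle, builds half-set averages at the true poses, measures the
#' local resolution map, and compares the median node resolution inside
#' the variable sphere against a rigid sphere on the opposite side of
#' the ring.
#'
#' @param n_seeds number of seeded runs.
#' @param n particles per run.
#' @param box,voxel_size,snr simulation scale.
#' @param seed base seed.
#' @return list with `fraction_contrast_ok` (runs where the variable
#'   region is worse), the per-run medians, and the leakage check of
#'   the subpart mask.
#' @export
benchmark_localres_contrast <- function(n_seeds = 10, n = 16, box = 64,
                                        voxel_size = 26.4, snr = 1,
                                        seed = 1L) {
  inside <- numeric(n_seeds)
  rigid <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    spec <- pore_phantom_spec(variable_sphere = 1)
    sim <- simulate_subtomograms(n, box = box, voxel_size = voxel_size,
                                 snr = snr, spec = spec,
                                 perturb = list(dphi = 0, dtheta = 0,
                                                dpsi = 0, dshift = 0),
                                 seed = seed + s)
    for (i in seq_along(sim$particles)) {
      tru <- sim$truth[i, ]
      sim$particles[[i]]$transform <-
        rigid_transform(tru$phi, tru$theta, tru$psi,
                        c(tru$dx, tru$dy, tru$dz))
    }
    h <- split_halves(sim$particles)
    lr <- local_resolution(wedge_average(h$a), wedge_average(h$b),
                           grid_spacing = 4, subpart_size = 16)
    ctr <- floor(rep(box, 3) / 2)
    rvox <- 450 / voxel_size
    srad <- 200 / voxel_size
    nodes <- lr$nodes
    dist_to <- function(cx) sqrt((nodes$x - ctr[1] - cx)^2 +
                                   (nodes$y - ctr[2])^2 +
                                   (nodes$z - ctr[3])^2)
    inside[s] <- median(nodes$resolution[dist_to(rvox) <= srad])
    rigid[s] <- median(nodes$resolution[dist_to(-rvox) <= srad])
  }
  leak <- mask_leakage_check(16, spherical_mask(16, 16 * 0.4, 2),
                             n_trials = 60, seed = seed)
  list(fraction_contrast_ok = mean(inside > rigid),
       variable_region_A = inside, rigid_region_A = rigid,
       mask_leakage_pass = leak$pass, mask_leakage_q95 = leak$q95)
}

#' CTF round-trip and defocus-estimation benchmark
#'
#' Simulates a tilt series of a textured phantom at the published
#' acquisition settings (3.3 Angstrom pixels, -6 micrometre nominal
#' underfocus), corrupts it with the strip-wise CTF/MTF model, phase
#' flips it back, and estimates the mean defocus from the corrupted
#' series at working noise.
#'
#' @param noise_sigma working noise level (relative to signal RMS).
#' @param n_seeds noise realizations; the defocus estimate is the
#'   median over seeds.
#' @param seed integer seed.
#' @return list with `restore_cc_min` (phase-flipped projections versus
#'   the amplitude-enveloped clean projections), `defocus_estimate_um`
#'   (median over seeds), `defocus_error_um`, `involution_max_err`.
#' @export
benchmark_ctf_roundtrip <- function(noise_sigma = 0.5, n_seeds = 3,
                                    seed = 2L) {
  set.seed(seed)
  ph <- array(0, rep(128, 3))
  for (i in 1:6)
    ph <- add_soft_sphere(ph, runif(3, 40, 88), runif(1, 5, 12), 2)
  ph <- ph + array(rnorm(128^3, sd = 0.3), rep(128, 3))
  v <- new_volume(ph, 3.3)
  cm <- ctf_model(defocus = -6)
  # zero-noise restoration
  acq0 <- acquisition_spec(pixel_size = 3.3, tilt_step = 20,
                           dose_noise_sigma = 0, seed = seed)
  ts <- project_tilt_series(v, acq0)
  tf <- ctf_correct_series(corrupt(ts, acq0), cm, mean_defocus = -6)
  ns <- default_n_strips(128)
  ccs <- vapply(seq_along(ts$angles), function(i) {
    dg <- defocus_gradient(128, 3.3, ts$angles[i], 0, -6, ns)
    ref <- ctf_amplitude_envelope(ts$images[, , i], dg, cm, 3.3)
    stats::cor(as.numeric(ref), as.numeric(tf$images[, , i]))
  }, numeric(1))
  # involution
  img <- ts$images[, , 1]
  dg <- defocus_gradient(128, 3.3, ts$angles[1], 0, -6, ns)
  inv_err <- max(abs(phase_flip(phase_flip(img, dg, cm, 3.3), dg, cm,
                                3.3) - img))
  # estimation at working noise: median over noise realizations, with
  # the full 41-projection series of the published tilt scheme.  Thon
  # rings are fitted on an amorphous specimen volume (background
  # regions are what defocus is estimated from in practice; strong
  # discrete structures superimpose form-factor oscillations on the
  # rings)
  ests <- vapply(seq_len(n_seeds), function(s) {
    set.seed(seed + 50L + s)
    amorphous <- new_volume(array(rnorm(128^3, sd = 0.5), rep(128, 3)),
                            3.3)
    acqn <- acquisition_spec(pixel_size = 3.3, tilt_step = 3,
                             dose_noise_sigma = noise_sigma,
                             seed = seed + s)
    estimate_mean_defocus(corrupt(project_tilt_series(amorphous, acqn),
                                  acqn), ctf_model())$defocus
  }, numeric(1))
  list(restore_cc_min = min(ccs), involution_max_err = inv_err,
       defocus_estimate_um = median(ests),
       defocus_error_um = abs(median(ests) - (-6)))
}

#' Planted-body docking benchmark
#'
#' For each seed, docks the asymmetric three-lobe body into a 64^3
#' eightfold map with the body planted at a known pose, using random
#' restarts and hill climbing, and checks whether the top-ranked
#' deduplicated solution recovers the pose within 4 degrees and 2
#' voxels.
#'
#' @param n_seeds number of seeds.
#' @param n_starts random starts per seed.
#' @param seed base seed.
#' @return list with `recovery_rate`, per-seed errors, and the
#'   restraint statistics of the truth pose on an exactly planted
#'   anchor set (mean should be 0).
#' @export
benchmark_docking <- function(n_seeds = 6, n_starts = 500, seed = 1L) {
  vs <- 26.4
  spec <- pore_phantom_spec(membrane = FALSE, planted_body = TRUE)
  a <- array(0, rep(64, 3))
  a <- render_pore(a, spec, floor(rep(64, 3) / 2), diag(3), vs)
  map <- new_volume(a, vs)
  b <- array(0, rep(24, 3))
  b <- add_planted_body(b, floor(rep(24, 3) / 2), diag(3), vs)
  body <- new_volume(b, vs)
  truth_pos <- floor(rep(64, 3) / 2) + planted_body_position(spec) / vs
  rot_err <- numeric(n_seeds)
  pos_err <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sols <- dock_global(map, body,
                        list(center = truth_pos + c(1, -1, 1),
                             radius = 6),
                        n_starts = n_starts, seed = seed + s)
    top <- deduplicate(sols)[1, ]
    rot_err[s] <- rotation_distance(
      rigid_transform(top$phi, top$theta, top$psi), rigid_transform())
    pos_err[s] <- sqrt(sum((c(top$x, top$y, top$z) - truth_pos)^2))
  }
  # restraint statistics of exactly planted anchors at the truth pose
  axis <- list(point = floor(rep(64, 3) / 2), dir = c(0, 0, 1))
  cb <- floor(rep(24, 3) / 2)
  set.seed(seed)
  anchors <- data.frame(label = paste0("anchor", 1:6),
                        ax = cb[1] + runif(6, -4, 4),
                        ay = cb[2] + runif(6, -4, 4),
                        az = cb[3] + runif(6, -4, 4))
  anchors$radial_nm <- vapply(1:6, function(i) {
    w <- c(anchors$ax[i], anchors$ay[i], anchors$az[i]) - cb + truth_pos
    sqrt(sum((w[1:2] - axis$point[1:2])^2)) * vs / 10
  }, numeric(1))
  truth_sol <- data.frame(phi = 0, theta = 0, psi = 0, x = truth_pos[1],
                          y = truth_pos[2], z = truth_pos[3])
  rs <- restraint_distances(truth_sol, anchors, axis, vs, rep(24, 3))
  list(recovery_rate = mean(rot_err <= 4 & pos_err <= 2),
       rotation_errors_deg = rot_err, position_errors_voxels = pos_err,
       restraint_mean_nm_at_truth = rs$mean_nm)
}
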