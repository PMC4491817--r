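#' Angular search window
#'
#' @param dphi,dtheta,dpsi half-widths in degrees (0 disables the axis).
#' @param step grid step in degrees (> 0).
#' @return an `AngularWindow` list.
#' @export
angular_window <- function(dphi = 30, dtheta = 12, dpsi = 30, step = 10) {
  stopifnot(step > 0, dphi >= 0, dtheta >= 0, dpsi >= 0)
  structure(list(dphi = dphi, dtheta = dtheta, dpsi = dpsi, step = step),
            class = "AngularWindow")
}

axis_grid <- function(half, step) {
  if (half <= 0) return(0)
  g <- seq(0, half, by = step)
  sort(unique(c(-g, g)))
}

#' Missing-wedge constrained cross-correlation
#'
#' Rotates the reference and its wedge by the candidate transform and
#' computes the normalized cross-correlation over the intersection of
#' the two Fourier supports, excluding the DC component (so means and
#' norms are taken within the common support).
#'
#' @param reference,particle cubic `Volume`s of equal shape.
#' @param wedge_ref,wedge_particle `WedgeMask`s ([full_wedge()] for an
#'   isotropically sampled reference).
#' @param transform candidate `RigidTransform` applied to the reference.
#' @param min_overlap minimum admissible number of Fourier voxels in the
#'   support intersection.
#' @return correlation in `[-1, 1]`.
#' @export
constrained_cc <- function(reference, particle, wedge_ref, wedge_particle,
                           transform = rigid_transform(),
                           min_overlap = 100) {
  stopifnot(all(vol_dim(reference) == vol_dim(particle)),
            is_cubic(reference))
  R <- euler_to_matrix(transform$phi, transform$theta, transform$psi)
  omega <- wedge_array(rotate_wedge(wedge_ref, R)) *
    wedge_array(wedge_particle)
  omega[1] <- 0
  if (sum(omega) < min_overlap)
    stop("constrained_cc: degenerate wedge overlap (",
         sum(omega), " voxels)")
  rv <- apply_transform(reference, transform)
  fa <- fft(rv$data) * omega
  fb <- fft(particle$data) * omega
  denom <- sqrt(sum(Mod(fa)^2) * sum(Mod(fb)^2))
  if (denom == 0) return(0)
  sum(Re(fa * Conj(fb))) / denom
}

#' Align one particle against a reference
#'
#' Exhaustive angular grid search inside an [angular_window()] centred
#' on the particle's current transform; at each orientation the
#' translation is read off the peak of the wedge-constrained
#' cross-correlation map (computed by FFT) with subvoxel parabolic
#' interpolation, restricted to `shift_bound` voxels around the current
#' shift.  The best transform replaces the particle's stored transform
#' (pose bookkeeping by composition; the raw particle is never
#' resampled).  Ties in the correlation are broken by the smallest
#' rotation offset, then the lowest grid index.
#'
#' @param particle list with `volume`, `transform`, `wedge` (as produced
#'   by [simulate_subtomograms()] or [extract_protomers()]).
#' @param reference a `Volume` (same shape as the particle volume).
#' @param window an [angular_window()].
#' @param wedge_ref reference wedge; defaults to full sampling.
#' @param shift_bound translation search bound, voxels.
#' @param mask optional real-space mask multiplied into the reference
#'   before scoring (alignment mask).
#' @return list with `transform` (updated absolute pose), `cc`,
#'   `at_window_limit`.
#' @export
align_particle <- function(particle, reference, window = angular_window(),
                           wedge_ref = NULL, shift_bound = 4, mask = NULL) {
  stopifnot(all(vol_dim(reference) == vol_dim(particle$volume)))
  n <- vol_dim(reference)[1]
  if (is.null(wedge_ref)) wedge_ref <- full_wedge(n)
  t0 <- particle$transform
  wp <- wedge_array(particle$wedge)
  fp <- fft(particle$volume$data)
  full_ref <- wedge_ref$tilt_min <= -90 && wedge_ref$tilt_max >= 90
  if (full_ref) {
    wp[1] <- 0
    fpm <- fp * wp
    np2 <- sum(Mod(fpm)^2)
  }
  offsets <- expand.grid(dphi = axis_grid(window$dphi, window$step),
                         dtheta = axis_grid(window$dtheta, window$step),
                         dpsi = axis_grid(window$dpsi, window$step))
  offsets <- offsets[order(offsets$dphi^2 + offsets$dtheta^2 +
                             offsets$dpsi^2), , drop = FALSE]
  ref_data <- if (is.null(mask)) reference else
    new_volume(reference$data * mask, reference$voxel_size)
  best <- list(cc = -Inf)
  ctr_shift <- round(t0$shift)
  for (i in seq_len(nrow(offsets))) {
    ang <- c(t0$phi + offsets$dphi[i], t0$theta + offsets$dtheta[i],
             t0$psi + offsets$dpsi[i])
    rot <- rigid_transform(ang[1], ang[2], ang[3])
    rv <- apply_transform(ref_data, rot)
    fr <- fft(rv$data)
    if (full_ref) {
      frm <- fr * wp
      om <- wp
    } else {
      R <- euler_to_matrix(ang[1], ang[2], ang[3])
      om <- wedge_array(rotate_wedge(wedge_ref, R)) * wp
      om[1] <- 0
      frm <- fr * om
      fpm <- fp * om
      np2 <- sum(Mod(fpm)^2)
    }
    denom <- sqrt(sum(Mod(frm)^2) * np2)
    if (denom == 0) next
    ccmap <- Re(fft(Conj(frm) * fpm, inverse = TRUE)) / denom
    pk <- cc_peak(ccmap, ctr_shift, shift_bound)
    if (pk$cc > best$cc) {
      best <- list(cc = pk$cc, angles = ang, shift = pk$shift,
                   offset = as.numeric(offsets[i, ]))
    }
  }
  # an angle on the window boundary only counts as "at the limit" when
  # the rotation really moved to the window rim: near theta = 0 the phi
  # and psi axes are degenerate (only phi + psi acts), so offsets like
  # (+w, -w) parameterize a rotation close to the start and must not be
  # flagged
  wins <- c(window$dphi, window$dtheta, window$dpsi)
  railed <- abs(best$offset) >= wins - 1e-9 & wins > 0
  at_limit <- FALSE
  if (any(railed)) {
    moved <- rotation_distance(
      rigid_transform(best$angles[1], best$angles[2], best$angles[3]), t0)
    at_limit <- moved >= 0.9 * min(wins[railed])
  }
  list(transform = rigid_transform(best$angles[1], best$angles[2],
                                   best$angles[3], best$shift),
       cc = best$cc, at_window_limit = at_limit)
}

# Peak of a wrapped CC volume restricted to center +/- bound voxels,
# with per-axis 3-point parabolic subvoxel interpolation.
cc_peak <- function(ccmap, center, bound) {
  n <- dim(ccmap)[1]
  s <- seq(-bound, bound)
  g <- expand.grid(x = center[1] + s, y = center[2] + s, z = center[3] + s)
  idx <- cbind((g$x %% n) + 1, (g$y %% n) + 1, (g$z %% n) + 1)
  vals <- ccmap[idx]
  b <- which.max(vals)
  pk <- as.numeric(g[b, ])
  sub <- numeric(3)
  for (ax in 1:3) {
    p <- pk; m <- pk
    p[ax] <- p[ax] + 1; m[ax] <- m[ax] - 1
    cp <- ccmap[matrix((p %% n) + 1, 1)]
    cm <- ccmap[matrix((m %% n) + 1, 1)]
    c0 <- vals[b]
    den <- cm - 2 * c0 + cp
    if (den < 0) sub[ax] <- max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  list(cc = vals[b], shift = pk + sub)
}

#' Multi-stage alignment of a particle set
#'
#' Runs [align_particle()] over a list of particles for a sequence of
#' stages, each defined by an angular window/step, a shift bound, and a
#' binning factor (coarse angular stages are scored on binned volumes,
#' standard multi-scale practice; the stored poses always refer to the
#' unbinned frame).
#'
#' @param particles list of particle lists (`volume`, `transform`,
#'   `wedge`, `keep`).
#' @param reference a `Volume` at the particles' scale.
#' @param stages list of stages, each a list with `window`
#'   (an [angular_window()]), `shift_bound`, and optional `binning`.
#' @param mask optional alignment mask at the particles' scale.
#' @return the particle list with updated `transform`, `cc`,
#'   `at_window_limit`.
#' @export
align_particles <- function(particles, reference, stages, mask = NULL) {
  for (st in stages) {
    bin <- if (is.null(st$binning)) 1L else as.integer(st$binning)
    ref_b <- bin_volume(reference, bin)
    mask_b <- if (is.null(mask)) NULL else
      bin_volume(new_volume(mask, reference$voxel_size), bin)$data
    for (i in seq_along(particles)) {
      p <- particles[[i]]
      if (!isTRUE(p$keep)) next
      pb <- p
      if (bin > 1L) {
        pb$volume <- bin_volume(p$volume, bin)
        pb$wedge <- wedge_mask(vol_dim(pb$volume)[1], p$wedge$tilt_min,
                               p$wedge$tilt_max, p$wedge$rot)
        pb$transform <- rigid_transform(p$transform$phi, p$transform$theta,
                                        p$transform$psi,
                                        p$transform$shift / bin)
      }
      res <- align_particle(pb, ref_b, st$window,
                            shift_bound = st$shift_bound, mask = mask_b)
      tr <- res$transform
      if (bin > 1L)
        tr <- rigid_transform(tr$phi, tr$theta, tr$psi, tr$shift * bin)
      particles[[i]]$transform <- tr
      particles[[i]]$cc <- res$cc
      particles[[i]]$at_window_limit <- res$at_window_limit
    }
  }
  particles
}

#' Missing-wedge-compensated average of aligned particles
#'
#' Each raw particle is resampled exactly once by the inverse of its
#' composed transform (one trilinear interpolation from the raw data to
#' the reference frame); the Fourier-space sum of the aligned particles,
#' each restricted to its rotated wedge support, is divided by the
#' summed wedge coverage (floored at `eps_frac` of the maximum coverage
#' to avoid amplifying barely-sampled voxels).  The result is normalized
#' to zero mean and unit variance inside the given mask.
#'
#' @param particles list of particle lists (`volume`, `transform`,
#'   `wedge`, `keep`).
#' @param mask normalization mask; defaults to a soft sphere of radius
#'   `n/2 - 2`.
#' @param eps_frac coverage floor as a fraction of the maximum coverage.
#' @param resample_passes number of sequential trilinear resampling
#'   passes used to bring each particle into the reference frame.  The
#'   default 1 is the composed-transform route (transforms accumulated
#'   by composition, the raw data touched by exactly one
#'   interpolation); values above 1 split the inverse transform
#'   geodesically into that many partial resampling steps, emulating a
#'   pipeline that resamples its particles at every refinement stage,
#'   and exist to quantify the resolution cost of repeated
#'   interpolation.
#' @return the average `Volume`.
#' @export
wedge_average <- function(particles, mask = NULL, eps_frac = 1e-3,
                          resample_passes = 1L) {
  keep <- Filter(function(p) isTRUE(p$keep), particles)
  if (length(keep) == 0) stop("wedge_average: empty particle set")
  n <- vol_dim(keep[[1]]$volume)[1]
  num <- array(0 + 0i, rep(n, 3))
  cov <- array(0, rep(n, 3))
  for (p in keep) {
    ti <- invert(p$transform)
    Rt <- euler_to_matrix(ti$phi, ti$theta, ti$psi)
    if (resample_passes <= 1L) {
      aligned <- apply_transform(p$volume, ti)
    } else {
      step <- slice_transform(ti, resample_passes)
      aligned <- p$volume
      for (s in seq_len(resample_passes))
        aligned <- apply_transform(aligned, step)
    }
    wi <- wedge_array(rotate_wedge(p$wedge, Rt))
    num <- num + fft(aligned$data) * wi
    cov <- cov + wi
  }
  eps <- eps_frac * max(cov)
  avg <- Re(fft(num / pmax(cov, eps), inverse = TRUE)) / n^3
  avg[is.na(avg)] <- 0
  if (is.null(mask)) mask <- spherical_mask(n, n / 2 - 2)
  mu <- sum(avg * mask) / sum(mask)
  s <- sqrt(sum(mask * (avg - mu)^2) / sum(mask))
  if (s > 0) avg <- (avg - mu) / s
  new_volume(avg, keep[[1]]$volume$voxel_size)
}

#' Split a particle set into two disjoint halves
#'
#' @param particles list of particle lists with `particle_id` (and
#'   `label` for cross mode).
#' @param mode `"fsc"` (odd/even split by particle id) or `"cross"`
#'   (split by study label, e.g. native versus perturbed condition).
#' @param labels for `"cross"`: character vector of the two labels in
#'   output order; defaults to the sorted unique labels.
#' @return list with `a` and `b`, each a particle list; the two sets are
#'   disjoint and their union is the input.
#' @export
split_halves <- function(particles, mode = c("fsc", "cross"),
                         labels = NULL) {
  mode <- match.arg(mode)
  if (mode == "fsc") {
    ids <- vapply(particles, function(p) p$particle_id, numeric(1))
    list(a = particles[ids %% 2 == 1], b = particles[ids %% 2 == 0])
  } else {
    labs <- vapply(particles, function(p) p$label, character(1))
    if (is.null(labels)) labels <- sort(unique(labs))
    stopifnot(length(labels) == 2)
    list(a = particles[labs == labels[1]], b = particles[labs == labels[2]])
  }
}

#' Exclude particles aligned to the window limits
#'
#' Marks `keep = FALSE` with reason `"angle_at_limit"` for all rows
#' whose alignment landed on the boundary of the angular search range;
#' all other rows are untouched.
#'
#' @param particle_table data frame with at least `at_window_limit`,
#'   `keep`, `reason` columns.
#' @return the updated table.
#' @export
exclude_at_limits <- function(particle_table) {
  sel <- particle_table$at_window_limit & particle_table$keep
  particle_table$keep[sel] <- FALSE
  particle_table$reason[sel] <- "angle_at_limit"
  particle_table
}

# Geodesic n-th root of a rigid transform: a step transform whose
# n-fold composition reproduces the input (axis-angle slicing of the
# rotation; the translation solved from the geometric series).
slice_transform <- function(t, n) {
  R <- euler_to_matrix(t$phi, t$theta, t$psi)
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) {
    Rs <- diag(3)
  } else {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(ang))
    a <- ang / n
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    Rs <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  }
  S <- matrix(0, 3, 3)
  P <- diag(3)
  for (k in seq_len(n)) {
    S <- S + P
    P <- Rs %*% P
  }
  es <- matrix_to_euler(Rs)
  rigid_transform(es[1], es[2], es[3], as.numeric(solve(S, t$shift)))
}
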