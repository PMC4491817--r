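#' Geometric alignment template
#'
#' Eight soft-edged solid spheres (default diameter 40 nm) placed on a
#' circle (default diameter 90 nm) in the central z-plane, with exact
#' C8 symmetry by construction: the starting template for global NPC
#' alignment.
#'
#' @param box cube edge, voxels.
#' @param voxel_size Angstrom per voxel.
#' @param ring_diameter circle diameter, Angstrom.
#' @param sphere_diameter sphere diameter, Angstrom.
#' @param n_fold symmetry order.
#' @param edge raised-cosine edge width, voxels.
#' @return a `Volume`.
#' @export
make_geometric_template <- function(box, voxel_size = 26.4,
                                    ring_diameter = 900,
                                    sphere_diameter = 400, n_fold = 8L,
                                    edge = 2) {
  extent <- (ring_diameter + sphere_diameter) / voxel_size
  if (extent > box)
    stop("make_geometric_template: ring + sphere exceed the box")
  spec <- pore_phantom_spec(ring_diameter = ring_diameter,
                            sphere_diameter = sphere_diameter,
                            n_fold = n_fold, membrane = FALSE)
  a <- array(0, rep(box, 3))
  a <- render_pore(a, spec, floor(rep(box, 3) / 2), diag(3), voxel_size,
                   edge = edge)
  new_volume(a, voxel_size)
}

#' Fit an oblate spheroid to membrane points
#'
#' Least-squares fit of the axis-aligned spheroid
#' `((x-x0)^2 + (y-y0)^2)/a^2 + (z-z0)^2/c^2 = 1` (equatorial semi-axes
#' constrained equal) to points sampled on a nuclear-envelope surface.
#' Spread envelopes are flat in z, so an axis-aligned fit suffices; the
#' oblate relation `a >= c` is flagged, not enforced, since fits on
#' small patches may invert it.
#'
#' @param membrane_points n x 3 matrix of points, Angstrom.
#' @return a `SpheroidModel` list with `center`, `a`, `c`, `oblate`.
#' @export
fit_spheroid <- function(membrane_points) {
  p <- as.matrix(membrane_points)
  if (nrow(p) < 9) stop("fit_spheroid: need at least 9 points")
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  X <- cbind(x^2 + y^2, z^2, x, y, z)
  # column-scaled rank check (columns span many orders of magnitude)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0) || qr(sweep(X, 2, nrm, "/"))$rank < 5)
    stop("fit_spheroid: degenerate (coplanar or rank-deficient) points")
  beta <- qr.coef(qr(X), rep(1, nrow(p)))
  A <- beta[1]; C <- beta[2]
  if (!all(is.finite(beta)) || A <= 0 || C <= 0)
    stop("fit_spheroid: degenerate fit (non-elliptic quadric)")
  x0 <- -beta[3] / (2 * A); y0 <- -beta[4] / (2 * A)
  z0 <- -beta[5] / (2 * C)
  G <- 1 + A * (x0^2 + y0^2) + C * z0^2
  if (G <= 0) stop("fit_spheroid: degenerate fit")
  structure(list(center = c(x0, y0, z0), a = sqrt(G / A), c = sqrt(G / C),
                 oblate = sqrt(G / A) >= sqrt(G / C)),
            class = "SpheroidModel")
}

#' Outward unit normal of a fitted spheroid
#'
#' @param model a `SpheroidModel` from [fit_spheroid()].
#' @param position length-3 position, Angstrom.
#' @return outward unit normal (unit length within 1e-9).
#' @export
normal_at <- function(model, position) {
  d <- position - model$center
  g <- c(2 * d[1] / model$a^2, 2 * d[2] / model$a^2, 2 * d[3] / model$c^2)
  nrm <- sqrt(sum(g^2))
  if (nrm == 0) stop("normal_at: position at the spheroid center")
  g / nrm
}

#' Verify a particle orientation against the membrane normal
#'
#' Compares the particle's aligned pore axis (the rotated z axis,
#' treated as unsigned) with the local membrane surface normal; a
#' mismatch strictly greater than the threshold excludes the particle
#' with reason `"normal_mismatch"`.
#'
#' @param particle_transform the particle's `RigidTransform`.
#' @param spheroid_normal length-3 surface normal (need not be unit).
#' @param threshold_deg exclusion threshold in degrees (default 20).
#' @return list with `keep`, `mismatch_deg`, `reason`.
#' @export
verify_orientation <- function(particle_transform, spheroid_normal,
                               threshold_deg = 20) {
  nrm <- sqrt(sum(spheroid_normal^2))
  if (nrm < 1e-12) stop("verify_orientation: zero-length normal")
  nhat <- spheroid_normal / nrm
  R <- euler_to_matrix(particle_transform$phi, particle_transform$theta,
                       particle_transform$psi)
  axis <- as.numeric(R %*% c(0, 0, 1))
  mismatch <- acos(min(1, abs(sum(axis * nhat)))) * 180 / pi
  keep <- mismatch <= threshold_deg
  list(keep = keep, mismatch_deg = mismatch,
       reason = if (keep) "" else "normal_mismatch")
}

#' Protomer extraction specification
#'
#' @param n_fold symmetry order (8).
#' @param protomer_box protomer cube edge, voxels.
#' @param radius radial position of the protomer centre from the pore
#'   axis, Angstrom (defaults to the ring radius, 450).
#' @param z_offset axial offset of the protomer centre from the pore
#'   midplane, Angstrom.
#' @param subprotomer_box subprotomer cube edge, voxels (80 at binning 1
#'   in the published processing scale).
#' @param subprotomer_z z-offsets of the three subprotomer centres
#'   (cytoplasmic ring, nucleoplasmic ring, spoke + central channel
#'   ring) from the protomer centre, Angstrom.
#' @param subprotomer_r radial offset of the subprotomer centres from
#'   the pore axis, Angstrom (`NA` keeps the protomer radius).
#' @return a `ProtomerSpec` list.
#' @export
protomer_spec <- function(n_fold = 8L, protomer_box = 96L, radius = 450,
                          z_offset = 0, subprotomer_box = 80L,
                          subprotomer_z = c(cpr = 220, npr = -220,
                                            sr_ccr = 0),
                          subprotomer_r = NA) {
  structure(list(n_fold = as.integer(n_fold),
                 protomer_box = as.integer(protomer_box),
                 radius = radius, z_offset = z_offset,
                 subprotomer_box = as.integer(subprotomer_box),
                 subprotomer_z = subprotomer_z,
                 subprotomer_r = subprotomer_r),
            class = "ProtomerSpec")
}

#' Extract the eight asymmetric protomers of an aligned pore
#'
#' Composes the particle's global transform with 45-degree rotations
#' about the pore axis plus the radial offset to the protomer centre,
#' then crops the protomer box around each resulting position.  Each
#' protomer inherits the tomogram's wedge (the crop axes are the
#' tomogram axes) and records its provenance (parent particle, k); the
#' protomer transform maps the common protomer reference frame onto the
#' crop, so averaging the crops with [wedge_average()] still needs only
#' one interpolation from the raw data.
#'
#' @param tomogram the source `Volume`.
#' @param particle_transform global `RigidTransform` of the pore
#'   (rotation part; the pore centre is given separately).
#' @param center pore centre in the tomogram, 0-based voxels.
#' @param spec a [protomer_spec()].
#' @param wedge the tomogram's `WedgeMask` at the protomer box size.
#' @param particle_id parent particle id for provenance.
#' @param on_boundary `"error"` (boundary error listing the failing k),
#'   `"exclude"` (mark `keep = FALSE`, reason `"boundary"`), or `"pad"`
#'   (crop with mean-fill padding at the tomogram rim and keep).
#' @return list of protomer particle lists (`volume`, `transform`,
#'   `wedge`, `parent`, `k`, `keep`, `reason`).
#' @export
extract_protomers <- function(tomogram, particle_transform, center, spec,
                              wedge = NULL, particle_id = NA_integer_,
                              on_boundary = c("error", "exclude", "pad")) {
  on_boundary <- match.arg(on_boundary)
  vs <- tomogram$voxel_size
  if (is.null(wedge)) wedge <- full_wedge(spec$protomer_box)
  Rg <- euler_to_matrix(particle_transform$phi, particle_transform$theta,
                        particle_transform$psi)
  p0 <- c(spec$radius, 0, spec$z_offset) / vs
  out <- vector("list", spec$n_fold)
  failed <- integer(0)
  for (k in seq_len(spec$n_fold) - 1L) {
    Rk <- Rg %*% euler_to_matrix(360 * k / spec$n_fold, 0, 0)
    w <- as.numeric(Rg %*% (euler_to_matrix(360 * k / spec$n_fold, 0, 0)
                            %*% p0)) + center + particle_transform$shift
    wi <- round(w)
    ang <- matrix_to_euler(Rk)
    ok <- TRUE
    vol <- NULL
    cropped <- try(crop_volume(tomogram, wi, spec$protomer_box,
                               pad = on_boundary == "pad"), silent = TRUE)
    if (inherits(cropped, "try-error")) {
      ok <- FALSE
      failed <- c(failed, k)
    } else vol <- cropped
    out[[k + 1]] <- list(volume = vol,
                         transform = rigid_transform(ang[1], ang[2], ang[3],
                                                     w - wi),
                         wedge = wedge, parent = particle_id, k = k,
                         particle_id = spec$n_fold * (particle_id - 1) + k + 1,
                         keep = ok,
                         reason = if (ok) "" else "boundary")
  }
  if (length(failed) > 0 && on_boundary == "error")
    stop("extract_protomers: boundary error for k = ",
         paste(failed, collapse = ", "))
  out
}

#' Balance the angular view distribution of a protomer set
#'
#' Bins protomers by the polar angle of their pore axis and keeps at
#' most `cap` particles per bin (highest correlation first); excess
#' particles are excluded with reason `"view_balance"`.
#'
#' @param protomer_table data frame with `theta`, `cc`, `keep`,
#'   `reason` columns.
#' @param bin_size_deg polar-angle bin width, degrees.
#' @param cap maximum particles per bin.
#' @return the updated table.
#' @export
balance_views <- function(protomer_table, bin_size_deg = 15, cap = 50) {
  t_ <- protomer_table
  bins <- floor((t_$theta %% 180) / bin_size_deg)
  for (b in unique(bins)) {
    sel <- which(bins == b & t_$keep)
    if (length(sel) > cap) {
      drop <- sel[order(t_$cc[sel], decreasing = TRUE)][- seq_len(cap)]
      t_$keep[drop] <- FALSE
      t_$reason[drop] <- "view_balance"
    }
  }
  t_
}

#' Subdivide protomer particles into three subprotomers
#'
#' Crops the three named subprotomer regions (cytoplasmic ring,
#' nucleoplasmic ring, spoke ring + central channel ring) out of each
#' protomer particle and re-centres the transforms so that each
#' subprotomer rotates about its own box centre.
#'
#' @param protomer_particles list of protomer particle lists.
#' @param spec a [protomer_spec()].
#' @param voxel_size protomer voxel size, Angstrom.
#' @return named list (`cpr`, `npr`, `sr_ccr`) of subprotomer particle
#'   lists.
#' @export
subdivide_subprotomers <- function(protomer_particles, spec, voxel_size) {
  regions <- names(spec$subprotomer_z)
  box <- spec$protomer_box
  cbx <- floor(rep(box, 3) / 2)
  out <- stats::setNames(vector("list", length(regions)), regions)
  for (r in seq_along(regions)) {
    off_A <- c(0, 0, spec$subprotomer_z[r])
    if (!is.na(spec$subprotomer_r))
      off_A[1] <- spec$subprotomer_r - spec$radius
    off <- off_A / voxel_size
    subs <- vector("list", length(protomer_particles))
    for (i in seq_along(protomer_particles)) {
      p <- protomer_particles[[i]]
      if (!isTRUE(p$keep)) { subs[[i]] <- p; subs[[i]]$volume <- NULL; next }
      R <- euler_to_matrix(p$transform$phi, p$transform$theta,
                           p$transform$psi)
      w <- as.numeric(R %*% off) + cbx + p$transform$shift
      wi <- round(w)
      vol <- crop_volume(p$volume, wi, spec$subprotomer_box)
      subs[[i]] <- list(volume = vol,
                        transform = rigid_transform(p$transform$phi,
                                                    p$transform$theta,
                                                    p$transform$psi,
                                                    w - wi),
                        wedge = wedge_mask(spec$subprotomer_box,
                                           p$wedge$tilt_min,
                                           p$wedge$tilt_max, p$wedge$rot),
                        parent = p$parent, k = p$k, region = regions[r],
                        particle_id = p$particle_id, keep = TRUE,
                        reason = "")
    }
    out[[r]] <- subs
  }
  out
}

# Crop of the protomer reference frame corresponding to one subprotomer
# region (used by assembly and by round-trip checks).
subprotomer_ref_crop <- function(protomer_ref, spec, region) {
  box <- spec$protomer_box
  cbx <- floor(rep(box, 3) / 2)
  off_A <- c(0, 0, spec$subprotomer_z[[region]])
  if (!is.na(spec$subprotomer_r))
    off_A[1] <- spec$subprotomer_r - spec$radius
  crop_volume(protomer_ref, cbx + off_A / protomer_ref$voxel_size,
              spec$subprotomer_box)
}

#' Alignment masks for protomer/subprotomer refinement
#'
#' Soft masks (raised-cosine edges) that remove the influence of the
#' nuclear envelope and its lumen, and exclude the central channel
#' below a cut-off diameter (17 nm by default) around the pore axis.
#' The masks multiply both reference and particles during scoring.
#'
#' @param box cube edge, voxels.
#' @param voxel_size Angstrom per voxel.
#' @param axis_xy 0-based (x, y) voxel position of the pore axis
#'   (defaults to the box centre; protomer boxes put the axis off-centre).
#' @param channel_diameter central exclusion diameter, Angstrom.
#' @param ne_z_center z of the envelope midplane, voxels (default box
#'   centre); `NA` disables the envelope mask.
#' @param ne_height luminal height, Angstrom.
#' @param pore_radius envelope opening radius, Angstrom.
#' @param edge raised-cosine edge width, voxels.
#' @return list with `channel`, `ne_lumen`, `combined` arrays in
#'   `[0, 1]`.
#' @export
make_masks <- function(box, voxel_size, axis_xy = NULL,
                       channel_diameter = 170, ne_z_center = NULL,
                       ne_height = 350, pore_radius = 450, edge = 2) {
  d <- rep(box, 3)
  ctr <- floor(d / 2)
  if (is.null(axis_xy)) axis_xy <- ctr[1:2]
  if (is.null(ne_z_center)) ne_z_center <- ctr[3]
  rx <- (seq_len(box) - 1 - axis_xy[1]) * voxel_size
  ry <- (seq_len(box) - 1 - axis_xy[2]) * voxel_size
  r2d <- sqrt(outer(rx^2, ry^2, `+`))
  rad <- array(r2d, d)
  rim <- channel_diameter / 2
  ew <- edge * voxel_size
  ch <- array(1, d)
  ch[rad <= rim] <- 0
  sel <- rad > rim & rad < rim + ew
  ch[sel] <- 0.5 * (1 - cos(pi * (rad[sel] - rim) / ew))
  ne <- array(1, d)
  if (!is.na(ne_z_center)) {
    z <- abs((seq_len(box) - 1 - ne_z_center) * voxel_size)
    zslab <- rep(0, box)
    half <- ne_height / 2
    zslab[z >= half + ew] <- 1
    sz <- z > half & z < half + ew
    zslab[sz] <- 0.5 * (1 - cos(pi * (z[sz] - half) / ew))
    slab <- array(rep(zslab, each = box * box), d)
    # only beyond the pore opening does the envelope/lumen exist
    inside_pore <- array(1, d)
    inside_pore[rad >= pore_radius] <- 0
    sp <- rad > pore_radius - ew & rad < pore_radius
    inside_pore[sp] <- 0.5 * (1 + cos(pi * (rad[sp] - pore_radius + ew) / ew))
    ne <- 1 - (1 - slab) * (1 - inside_pore)
  }
  list(channel = ch, ne_lumen = ne, combined = ch * ne)
}

#' Assemble an eightfold model from subprotomer averages
#'
#' Places each subprotomer average back into the protomer frame,
#' blending overlaps with normalized soft-mask weights (weights sum to
#' one wherever any weight is positive), replicates the protomer
#' eightfold about the pore axis with normalized blending, and low-pass
#' filters the assembled map to the target resolution.
#'
#' @param subprotomer_averages named list of `Volume`s (`cpr`, `npr`,
#'   `sr_ccr` or as named in the spec).
#' @param spec a [protomer_spec()].
#' @param out_box output cube edge, voxels.
#' @param filter_resolution final low-pass resolution, Angstrom
#'   (default 20 nm-scale maps use 200; `NA` disables).
#' @return the assembled `Volume`.
#' @export
assemble_model <- function(subprotomer_averages, spec, out_box,
                           filter_resolution = 200) {
  vs <- subprotomer_averages[[1]]$voxel_size
  for (v in subprotomer_averages)
    if (abs(v$voxel_size - vs) > 1e-9)
      stop("assemble_model: inconsistent voxel sizes")
  box <- spec$protomer_box
  cbx <- floor(rep(box, 3) / 2)
  sbox <- spec$subprotomer_box
  wsub <- spherical_mask(sbox, sbox / 2 - 1, 2)
  num <- array(0, rep(box, 3))
  den <- array(0, rep(box, 3))
  for (r in names(subprotomer_averages)) {
    off_A <- c(0, 0, spec$subprotomer_z[[r]])
    if (!is.na(spec$subprotomer_r))
      off_A[1] <- spec$subprotomer_r - spec$radius
    lo <- round(cbx + off_A / vs) - floor(sbox / 2)
    ix <- (lo[1] + 1):(lo[1] + sbox)
    iy <- (lo[2] + 1):(lo[2] + sbox)
    iz <- (lo[3] + 1):(lo[3] + sbox)
    if (min(ix, iy, iz) < 1 || max(ix) > box || max(iy) > box ||
        max(iz) > box)
      stop("assemble_model: subprotomer placement outside the protomer box")
    num[ix, iy, iz] <- num[ix, iy, iz] +
      wsub * subprotomer_averages[[r]]$data
    den[ix, iy, iz] <- den[ix, iy, iz] + wsub
  }
  protomer <- ifelse(den > 1e-6, num / pmax(den, 1e-6), 0)
  wprot <- ifelse(den > 1e-6, 1, 0) * spherical_mask(box, box / 2 - 1, 2)
  # place the protomer into the full box at its radial position
  ctr_out <- floor(rep(out_box, 3) / 2)
  p0 <- c(spec$radius, 0, spec$z_offset) / vs
  v0 <- array(0, rep(out_box, 3))
  w0 <- array(0, rep(out_box, 3))
  lo <- round(ctr_out + p0) - cbx
  ix <- (lo[1] + 1):(lo[1] + box)
  iy <- (lo[2] + 1):(lo[2] + box)
  iz <- (lo[3] + 1):(lo[3] + box)
  if (min(ix, iy, iz) < 1 || max(ix) > out_box || max(iy) > out_box ||
      max(iz) > out_box)
    stop("assemble_model: protomer does not fit in the output box")
  v0[ix, iy, iz] <- protomer * wprot
  w0[ix, iy, iz] <- wprot
  V0 <- new_volume(v0, vs); W0 <- new_volume(w0, vs)
  num8 <- array(0, rep(out_box, 3))
  den8 <- array(0, rep(out_box, 3))
  for (k in seq_len(spec$n_fold) - 1L) {
    rot <- rigid_transform(360 * k / spec$n_fold, 0, 0)
    num8 <- num8 + apply_transform(V0, rot, fill = 0)$data
    den8 <- den8 + apply_transform(W0, rot, fill = 0)$data
  }
  out <- ifelse(den8 > 1e-3, num8 / pmax(den8, 1e-3), 0)
  vol <- new_volume(out, vs)
  if (!is.na(filter_resolution)) vol <- lowpass(vol, filter_resolution)
  vol
}

#' Pore metrics, including the central-channel cylinder volume
#'
#' Computes the cylindrical volume `pi (d/2)^2 h` available to the
#' central-channel phase from the pore diameter and ring height, and,
#' when a map is supplied, measures ring diameters as radial
#' density-peak positions in an annulus over a stated z-range.
#'
#' @param diameter_nm central pore diameter, nm.
#' @param height_nm ring height, nm.
#' @param map optional `Volume` for the radial-peak measurement.
#' @param z_range_nm z-range (relative to the map centre) over which the
#'   radial profile is averaged, nm.
#' @param r_range_nm radial annulus searched for the peak, nm.
#' @return list with `cylinder_volume_nm3` and, when a map is given,
#'   `ring_diameter_nm`, `z_range_nm` and the radial profile.
#' @export
measure_pore_metrics <- function(diameter_nm = 37, height_nm = 26,
                                 map = NULL, z_range_nm = c(-5, 5),
                                 r_range_nm = NULL) {
  stopifnot(diameter_nm > 0, height_nm > 0)
  out <- list(cylinder_volume_nm3 = pi * (diameter_nm / 2)^2 * height_nm,
              diameter_nm = diameter_nm, height_nm = height_nm)
  if (!is.null(map)) {
    d <- vol_dim(map)
    ctr <- floor(d / 2)
    vs_nm <- map$voxel_size / 10
    zs <- round(z_range_nm / vs_nm) + ctr[3]
    zs <- max(1, zs[1] + 1):min(d[3], zs[2] + 1)
    rx <- (seq_len(d[1]) - 1 - ctr[1]) * vs_nm
    ry <- (seq_len(d[2]) - 1 - ctr[2]) * vs_nm
    r2d <- sqrt(outer(rx^2, ry^2, `+`))
    slab <- apply(map$data[, , zs, drop = FALSE], c(1, 2), mean)
    rbin <- round(r2d / vs_nm)
    prof <- tapply(as.numeric(slab), as.numeric(rbin), mean)
    radii <- as.numeric(names(prof)) * vs_nm
    if (!is.null(r_range_nm)) {
      sel <- radii >= r_range_nm[1] & radii <= r_range_nm[2]
      prof <- prof[sel]; radii <- radii[sel]
    }
    pk <- which.max(prof)
    rpk <- radii[pk]
    if (pk > 1 && pk < length(prof)) {
      den <- prof[pk - 1] - 2 * prof[pk] + prof[pk + 1]
      if (den < 0)
        rpk <- rpk + 0.5 * (prof[pk - 1] - prof[pk + 1]) / den *
          (radii[pk + 1] - radii[pk])
    }
    out$ring_diameter_nm <- 2 * rpk
    out$z_range_nm <- z_range_nm
    out$radial_profile <- data.frame(radius_nm = radii,
                                     density = as.numeric(prof))
  }
  out
}

#' Template-matching particle picker
#'
#' Cross-correlates the tomogram with a (smaller) template by FFT and
#' returns the strongest non-overlapping correlation peaks: the
#' automated stand-in for interactive particle picking on synthetic
#' data.
#'
#' @param tomogram a `Volume` (any box shape).
#' @param template a cubic `Volume` at the same voxel size.
#' @param n_peaks number of particles to return.
#' @param min_dist minimum distance between accepted peaks, voxels
#'   (defaults to the template half-width).
#' @return data frame with 0-based `x`, `y`, `z` positions and the
#'   correlation `score`, strongest first.
#' @export
pick_template_match <- function(tomogram, template, n_peaks,
                                min_dist = NULL) {
  d <- vol_dim(tomogram)
  td <- vol_dim(template)
  if (any(td > d)) stop("pick_template_match: template exceeds tomogram")
  if (is.null(min_dist)) min_dist <- td[1] / 2
  # template centred on the (wrapped) origin so the correlation map
  # indexes particle centres directly
  tpl <- template$data - mean(template$data)
  emb <- array(0, d)
  ctr <- floor(td / 2)
  ix <- ((seq_len(td[1]) - 1 - ctr[1]) %% d[1]) + 1
  iy <- ((seq_len(td[2]) - 1 - ctr[2]) %% d[2]) + 1
  iz <- ((seq_len(td[3]) - 1 - ctr[3]) %% d[3]) + 1
  emb[ix, iy, iz] <- tpl
  cc <- Re(fft(fft(tomogram$data) * Conj(fft(emb)), inverse = TRUE)) /
    prod(d)
  ord <- order(cc, decreasing = TRUE)[seq_len(min(length(cc),
                                                  50L * n_peaks))]
  peaks <- matrix(numeric(0), 0, 3)
  scores <- c()
  for (o in ord) {
    pos <- c((o - 1) %% d[1],
             ((o - 1) %/% d[1]) %% d[2],
             (o - 1) %/% (d[1] * d[2]))
    if (nrow(peaks) > 0 &&
        min(sqrt(rowSums(sweep(peaks, 2, pos)^2))) < min_dist) next
    peaks <- rbind(peaks, pos)
    scores <- c(scores, cc[o])
    if (nrow(peaks) == n_peaks) break
  }
  data.frame(x = peaks[, 1], y = peaks[, 2], z = peaks[, 3],
             score = scores)
}
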