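#' Local resolution map
#'
#' Spatially discretized resolution measurement: the two maps are
#' dissected along a regularly spaced grid into cubic subparts, a soft
#' spherical mask is applied to each subpart pair, the Fourier shell
#' correlation is computed, and the resolution at the chosen criterion
#' threshold (0.5 for half-maps, 0.14 for independently processed maps)
#' is entered at the grid node.  Values in between nodes are
#' trilinearly interpolated; nodes whose subpart leaves the map are
#' skipped and hole-filled by nearest-neighbour extrapolation.
#'
#' @param map_a,map_b `Volume`s of identical shape and voxel size.
#' @param grid_spacing node spacing, voxels (default 4).
#' @param subpart_size subpart cube edge, voxels (default 20).
#' @param criterion `"fsc_0.5"` or `"cross_0.14"`.
#' @param mask_radius soft-mask radius, voxels (default 8 for the
#'   default subpart size, scaled otherwise).
#' @return a `LocalResolutionMap`: list with `values` (a `Volume` of
#'   resolution in Angstrom), `criterion`, `grid_spacing`,
#'   `subpart_size`, `nodes` (data frame of node positions, values and
#'   `no_crossing` flags).
#' @export
local_resolution <- function(map_a, map_b, grid_spacing = 4,
                             subpart_size = 20,
                             criterion = c("fsc_0.5", "cross_0.14"),
                             mask_radius = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(all(vol_dim(map_a) == vol_dim(map_b)),
            grid_spacing <= subpart_size)
  if (abs(map_a$voxel_size - map_b$voxel_size) > 1e-6)
    stop("local_resolution: mismatched voxel sizes")
  threshold <- if (criterion == "fsc_0.5") 0.5 else 0.14
  d <- vol_dim(map_a)
  vs <- map_a$voxel_size
  if (is.null(mask_radius)) mask_radius <- subpart_size * 0.4
  smask <- spherical_mask(subpart_size, mask_radius, 2)
  half <- floor(subpart_size / 2)
  nodes_axis <- lapply(d, function(n) seq(0, n - 1, by = grid_spacing))
  grid_dim <- vapply(nodes_axis, length, integer(1))
  vals <- array(NA_real_, grid_dim)
  nocross <- array(FALSE, grid_dim)
  node_rows <- list()
  for (iz in seq_along(nodes_axis[[3]])) {
    for (iy in seq_along(nodes_axis[[2]])) {
      for (ix in seq_along(nodes_axis[[1]])) {
        ctr <- c(nodes_axis[[1]][ix], nodes_axis[[2]][iy],
                 nodes_axis[[3]][iz])
        lo <- ctr - half
        hi <- lo + subpart_size - 1
        if (any(lo < 0) || any(hi > d - 1)) next  # edge node: skipped
        sa <- map_a$data[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                         (lo[3] + 1):(hi[3] + 1)]
        sb <- map_b$data[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                         (lo[3] + 1):(hi[3] + 1)]
        cu <- fsc(new_volume(sa * smask, vs), new_volume(sb * smask, vs))
        res <- resolution_at(cu, threshold)
        vals[ix, iy, iz] <- res$resolution
        nocross[ix, iy, iz] <- res$no_crossing
        node_rows[[length(node_rows) + 1]] <-
          data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                     resolution = res$resolution,
                     no_crossing = res$no_crossing)
      }
    }
  }
  if (all(is.na(vals)))
    stop("local_resolution: no interior node fits (subpart too large)")
  vals <- fill_nearest(vals)
  # trilinear interpolation from the node grid to the full voxel grid
  M <- diag(3) / grid_spacing
  b <- c(0, 0, 0)
  full <- cpp_affine_sample(as.numeric(vals), as.integer(grid_dim), M, b,
                            as.integer(d), NA_real_)
  full <- array(full, d)
  full[is.na(full)] <- max(vals)
  structure(list(values = new_volume(full, vs), criterion = criterion,
                 grid_spacing = grid_spacing, subpart_size = subpart_size,
                 nodes = do.call(rbind, node_rows)),
            class = "LocalResolutionMap")
}

# Nearest-neighbour hole filling of an array with NAs.
fill_nearest <- function(a) {
  d <- dim(a)
  nas <- which(is.na(a), arr.ind = TRUE)
  if (nrow(nas) == 0) return(a)
  ok <- which(!is.na(a), arr.ind = TRUE)
  okv <- a[!is.na(a)]
  for (i in seq_len(nrow(nas))) {
    dd <- (ok[, 1] - nas[i, 1])^2 + (ok[, 2] - nas[i, 2])^2 +
      (ok[, 3] - nas[i, 3])^2
    a[nas[i, 1], nas[i, 2], nas[i, 3]] <- okv[which.min(dd)]
  }
  a
}

#' Check a subpart mask for artificial FSC contribution
#'
#' The soft mask used on subpart volumes must not correlate two
#' independent half-maps by itself.  The check computes the FSC of
#' pairs of independent pure-noise subparts under the mask and passes
#' when the 95th percentile of `|FSC|`, across trials and across the
#' adequately populated shells, stays below 0.2.  Shells with fewer
#' than `min_shell_pop` Fourier voxels carry too much intrinsic FSC
#' variance to assess a mask (their noise FSC exceeds the threshold
#' even unmasked); a subpart so small that no shell qualifies fails
#' outright, which is the failure mode of tiny hard-edged subparts.
#'
#' @param subpart_size subpart cube edge, voxels.
#' @param mask mask array of that size.
#' @param n_trials number of noise pairs.
#' @param min_shell_pop minimum Fourier voxels per assessed shell.
#' @param seed integer seed.
#' @return list with `pass`, `q95`, `shells_used` and the pooled
#'   values.
#' @export
mask_leakage_check <- function(subpart_size, mask, n_trials = 100,
                               min_shell_pop = 150, seed = 1L) {
  set.seed(seed)
  sh <- fourier_shells(subpart_size)
  pops <- table(sh[sh <= subpart_size %/% 2])
  ok_shells <- as.integer(names(pops)[pops >= min_shell_pop])
  ok_shells <- ok_shells[ok_shells > 0]
  if (length(ok_shells) == 0)
    return(list(pass = FALSE, q95 = NA_real_, shells_used = integer(0),
                values = numeric(0),
                reason = "subpart too small for a stable shell FSC"))
  vals <- c()
  for (i in seq_len(n_trials)) {
    a <- array(rnorm(subpart_size^3), rep(subpart_size, 3)) * mask
    b <- array(rnorm(subpart_size^3), rep(subpart_size, 3)) * mask
    cu <- fsc(new_volume(a, 1), new_volume(b, 1))
    vals <- c(vals, abs(cu$fsc[cu$shell %in% ok_shells]))
  }
  q95 <- as.numeric(quantile(vals, 0.95))
  list(pass = q95 < 0.2, q95 = q95, shells_used = ok_shells,
       values = vals)
}

#' Filter a map to its finest measured local resolution
#'
#' Global low-pass at the minimum (finest) local resolution value,
#' rounded up to the next Fourier shell.
#'
#' @param map a `Volume`.
#' @param localres_map a `LocalResolutionMap` (or a numeric resolution
#'   in Angstrom).
#' @return the filtered `Volume`.
#' @export
filter_to_local_best <- function(map, localres_map) {
  best <- if (is.numeric(localres_map)) localres_map else
    min(localres_map$nodes$resolution)
  n <- vol_dim(map)[1]
  # round the cut-off up to the next whole shell (coarser resolution)
  shell <- floor(n * map$voxel_size / best)
  lowpass(map, n * map$voxel_size / shell)
}
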