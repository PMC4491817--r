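#' Global rigid-body docking by cross-correlation from random starts
#'
#' Draws `n_starts` uniformly random placements (uniform random
#' rotation, uniform position within the search region) and refines
#' each by coordinate-wise cross-correlation hill climbing over a
#' coarse-to-fine schedule (angle steps 8, 2, 0.5 degrees; shifts 2, 1,
#' 0.25 voxels) until the gain falls
#' below `tol` or `max_steps` sweeps are exhausted.  Solutions are
#' returned sorted by final correlation; runs are deterministic under a
#' fixed seed.
#'
#' @param map the target `Volume`.
#' @param body the component density `Volume` to place (smaller box).
#' @param search_region list with `center` (0-based voxels in the map)
#'   and `radius` (voxels): positions are drawn uniformly in the ball.
#' @param n_starts number of random starts.
#' @param seed integer seed.
#' @param mask scoring weight over the body box; defaults to the body's
#'   own soft support (density above 10% of its maximum).
#' @param tol convergence tolerance on the correlation gain.
#' @param max_steps maximum hill-climbing sweeps per schedule level.
#' @return a `docking_solutions` data frame with columns `phi`, `theta`,
#'   `psi`, `x`, `y`, `z` (body-centre position, 0-based voxels), `cc`,
#'   `rank`.
#' @export
dock_global <- function(map, body, search_region, n_starts = 2000,
                        seed = 1L, mask = NULL, tol = 1e-4,
                        max_steps = 200) {
  stopifnot(n_starts >= 1)
  if (is.null(search_region$radius) || search_region$radius <= 0)
    stop("dock_global: empty search region")
  bd <- vol_dim(body)
  md <- vol_dim(map)
  if (any(bd > md)) stop("dock_global: body does not fit in the map")
  if (is.null(mask)) mask <- pmax(body$data - 0.1 * max(body$data), 0)
  set.seed(seed)
  fill <- mean(map$data)
  sols <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    R <- random_rotation()
    ang <- matrix_to_euler(R)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    r <- search_region$radius * runif(1)^(1 / 3)
    pos <- search_region$center + u * r
    res <- cpp_dock_refine(as.numeric(map$data), as.integer(md),
                           as.numeric(body$data), as.numeric(mask),
                           as.integer(bd), as.numeric(ang),
                           as.numeric(pos), c(8, 2, 0.5), c(2, 1, 0.25),
                           as.integer(max_steps), tol, fill)
    sols[[i]] <- data.frame(phi = res$phi, theta = res$theta,
                            psi = res$psi, x = res$pos[1], y = res$pos[2],
                            z = res$pos[3], cc = res$cc)
  }
  out <- do.call(rbind, sols)
  out <- out[order(-out$cc), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("docking_solutions", "data.frame")
  out
}

# Uniform random rotation matrix (quaternion method; uses the caller's
# RNG stream).
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3)
}

#' Remove redundant docking solutions
#'
#' Greedy pass in order of descending correlation: a solution within
#' both the rotation and translation tolerance of an already-kept
#' solution is dropped as redundant; ranks are reassigned.
#'
#' @param solutions a `docking_solutions` data frame.
#' @param rot_tol_deg rotation tolerance, degrees.
#' @param trans_tol_voxels translation tolerance, voxels.
#' @return the deduplicated, re-ranked data frame.
#' @export
deduplicate <- function(solutions, rot_tol_deg = 5, trans_tol_voxels = 2) {
  stopifnot(rot_tol_deg > 0, trans_tol_voxels > 0)
  s <- solutions[order(-solutions$cc), , drop = FALSE]
  keep <- logical(nrow(s))
  kept_R <- list()
  kept_p <- list()
  for (i in seq_len(nrow(s))) {
    Ri <- euler_to_matrix(s$phi[i], s$theta[i], s$psi[i])
    pi_ <- c(s$x[i], s$y[i], s$z[i])
    red <- FALSE
    for (j in seq_along(kept_R)) {
      if (rotation_distance(Ri, kept_R[[j]]) <= rot_tol_deg &&
          sqrt(sum((pi_ - kept_p[[j]])^2)) <= trans_tol_voxels) {
        red <- TRUE
        break
      }
    }
    if (!red) {
      keep[i] <- TRUE
      kept_R[[length(kept_R) + 1]] <- Ri
      kept_p[[length(kept_p) + 1]] <- pi_
    }
  }
  out <- s[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("docking_solutions", "data.frame")
  out
}

# Sample the map (or an exclusion mask) in the body frame of a docking
# solution: out(p) = map(R (p - c_body) + pos).
sample_in_body_frame <- function(vol, solution, body_dim, fill = 0) {
  R <- euler_to_matrix(solution$phi, solution$theta, solution$psi)
  cb <- floor(body_dim / 2)
  b <- c(solution$x, solution$y, solution$z) - as.numeric(R %*% cb)
  out <- cpp_affine_sample(as.numeric(vol$data), as.integer(vol_dim(vol)),
                           R, b, as.integer(body_dim), fill)
  array(out, body_dim)
}

#' Plausibility flags for a docking solution
#'
#' `outside_density`: the mass fraction of the body falling where the
#' map is below `density_threshold` exceeds `outside_cap`.
#' `clash`: the body-mass overlap with a user-supplied exclusion mask
#' (e.g. a neighbouring complex or an already-occupied region) exceeds
#' `clash_cap`.
#'
#' @param solution one row of a `docking_solutions` data frame.
#' @param map the target `Volume`.
#' @param body the docked `Volume`.
#' @param density_threshold map density defining "inside the density".
#' @param exclusion_mask optional `Volume` (same grid as `map`) of the
#'   forbidden region.
#' @param outside_cap,clash_cap documented caps (default 10% each).
#' @param body_threshold body density defining body mass.
#' @return list with logical `outside_density`, `clash` and the two
#'   measured fractions.
#' @export
plausibility_flags <- function(solution, map, body, density_threshold,
                               exclusion_mask = NULL, outside_cap = 0.1,
                               clash_cap = 0.1, body_threshold = 0.1) {
  bd <- vol_dim(body)
  w <- pmax(body$data - body_threshold, 0)
  msamp <- sample_in_body_frame(map, solution, bd, fill = 0)
  frac_out <- sum(w * (msamp < density_threshold)) / sum(w)
  frac_clash <- 0
  if (!is.null(exclusion_mask)) {
    es <- sample_in_body_frame(exclusion_mask, solution, bd, fill = 0)
    frac_clash <- sum(w * es) / sum(w)
  }
  list(outside_density = frac_out > outside_cap,
       clash = frac_clash > clash_cap,
       outside_fraction = frac_out, clash_fraction = frac_clash)
}

#' Restraint-distance statistics of a docking solution
#'
#' Transforms each labelled anchor of the docked body by the solution,
#' computes its radial distance from the pore axis (the axial component
#' is projected out, matching the radial nature of super-resolution
#' position measurements), and reports the absolute deviation from the
#' target radial position per label plus mean, sample standard
#' deviation and maximum.
#'
#' @param solution one row of a `docking_solutions` data frame.
#' @param restraints data frame with columns `label`, `ax`, `ay`, `az`
#'   (anchor positions in the body box, 0-based voxels) and `radial_nm`
#'   (target radial position, nm).
#' @param pore_axis list with `point` (0-based voxels on the axis) and
#'   `dir` (axis direction); default: map-centred z axis must be given
#'   explicitly by the caller.
#' @param voxel_size map voxel size, Angstrom.
#' @param body_dim body box dimensions, voxels.
#' @return list with `per_label` data frame (`label`, `radial_nm`,
#'   `target_nm`, `deviation_nm`), `mean_nm`, `sd_nm`, `max_nm`,
#'   `max_label`.
#' @export
restraint_distances <- function(solution, restraints, pore_axis,
                                voxel_size, body_dim) {
  if (nrow(restraints) == 0)
    stop("restraint_distances: empty restraint set")
  if (any(duplicated(restraints$label)))
    stop("restraint_distances: labels must be unique")
  if (any(restraints$radial_nm <= 0))
    stop("restraint_distances: radial targets must be positive")
  R <- euler_to_matrix(solution$phi, solution$theta, solution$psi)
  cb <- floor(body_dim / 2)
  dir <- pore_axis$dir / sqrt(sum(pore_axis$dir^2))
  rows <- lapply(seq_len(nrow(restraints)), function(i) {
    a <- c(restraints$ax[i], restraints$ay[i], restraints$az[i])
    w <- as.numeric(R %*% (a - cb)) + c(solution$x, solution$y, solution$z)
    rel <- w - pore_axis$point
    radial_vox <- sqrt(sum((rel - sum(rel * dir) * dir)^2))
    radial_nm <- radial_vox * voxel_size / 10
    data.frame(label = restraints$label[i], radial_nm = radial_nm,
               target_nm = restraints$radial_nm[i],
               deviation_nm = abs(radial_nm - restraints$radial_nm[i]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  imax <- which.max(per$deviation_nm)
  list(per_label = per, mean_nm = mean(per$deviation_nm),
       sd_nm = if (nrow(per) > 1) sd(per$deviation_nm) else 0,
       max_nm = per$deviation_nm[imax], max_label = per$label[imax])
}

#' Ranked docking report
#'
#' Top-k table of docking solutions with correlation, plausibility
#' flags and restraint statistics; flagged solutions are annotated,
#' never dropped.
#'
#' @param solutions a `docking_solutions` data frame (deduplicated).
#' @param map,body the map and body `Volume`s (for flags).
#' @param restraints optional restraint data frame
#'   (see [restraint_distances()]).
#' @param pore_axis pore axis for restraint evaluation.
#' @param density_threshold map density threshold for the
#'   outside-density flag.
#' @param exclusion_mask optional exclusion `Volume` for the clash flag.
#' @param k number of rows (default 8).
#' @param path optional TSV output path.
#' @return data frame with `rank`, `cc`, `outside_density`, `clash` and,
#'   when restraints are given, `restraint_mean_nm`, `restraint_sd_nm`,
#'   `restraint_max_nm`, `restraint_max_label`.
#' @export
rank_report <- function(solutions, map = NULL, body = NULL,
                        restraints = NULL, pore_axis = NULL,
                        density_threshold = 0.1, exclusion_mask = NULL,
                        k = 8, path = NULL) {
  stopifnot(nrow(solutions) >= 1)
  s <- head(solutions, k)
  rows <- lapply(seq_len(nrow(s)), function(i) {
    row <- data.frame(rank = s$rank[i], cc = s$cc[i], phi = s$phi[i],
                      theta = s$theta[i], psi = s$psi[i], x = s$x[i],
                      y = s$y[i], z = s$z[i])
    if (!is.null(map) && !is.null(body)) {
      fl <- plausibility_flags(s[i, ], map, body, density_threshold,
                               exclusion_mask)
      row$outside_density <- fl$outside_density
      row$clash <- fl$clash
    }
    if (!is.null(restraints)) {
      rs <- restraint_distances(s[i, ], restraints, pore_axis,
                                map$voxel_size, vol_dim(body))
      row$restraint_mean_nm <- rs$mean_nm
      row$restraint_sd_nm <- rs$sd_nm
      row$restraint_max_nm <- rs$max_nm
      row$restraint_max_label <- rs$max_label
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
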