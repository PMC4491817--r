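#' Density volume
#'
#' A 3-D scalar density grid with an isotropic voxel size in Angstrom and
#' an origin in Angstrom.  The universal container for tomograms,
#' subtomograms and averaged maps.
#'
#' @param data 3-D numeric array.
#' @param voxel_size voxel edge length in Angstrom (must be > 0).
#' @param origin numeric length-3 origin in Angstrom.
#' @return an object of class `Volume`.
#' @export
new_volume <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("new_volume: data must be a 3-D array")
  if (any(dim(data) < 1L))
    stop("new_volume: all grid dimensions must be >= 1")
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("new_volume: voxel_size must be a positive finite number")
  if (!all(is.finite(data)))
    stop("new_volume: volume values must be finite")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "Volume")
}

#' @export
print.Volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Volume %d x %d x %d, voxel %.3f A, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

vol_dim <- function(v) dim(v$data)

is_cubic <- function(v) {
  d <- dim(v$data)
  d[1] == d[2] && d[2] == d[3]
}

#' Apply a rigid transform to a volume
#'
#' Resamples the volume under a rigid-body rotation plus translation with
#' a single trilinear interpolation.  The rotation acts about the voxel
#' `floor(N/2)` (0-based) of each dimension; output voxels that map
#' outside the input field of view are set to the volume mean, which
#' keeps cross-correlation normalization stable near the edges.
#'
#' @param volume a `Volume` (must be cubic when the rotation is
#'   non-trivial).
#' @param transform a `RigidTransform`.
#' @param fill out-of-field fill value; defaults to the volume mean.
#' @return the transformed `Volume`.
#' @export
apply_transform <- function(volume, transform, fill = NULL) {
  stopifnot(inherits(volume, "Volume"), inherits(transform, "RigidTransform"))
  if (!all(is.finite(c(transform$phi, transform$theta, transform$psi,
                       transform$shift))))
    stop("apply_transform: non-finite transform parameters")
  d <- vol_dim(volume)
  nontrivial_rot <- any(abs(c(transform$phi, transform$theta,
                              transform$psi)) > 1e-12)
  if (nontrivial_rot && !is_cubic(volume))
    stop("apply_transform: rotations require a cubic volume (pad first)")
  if (is.null(fill)) fill <- mean(volume$data)
  R <- euler_to_matrix(transform$phi, transform$theta, transform$psi)
  ctr <- floor(d / 2)
  # out(y) = vol(t(R) %*% (y - ctr - shift) + ctr)
  M <- t(R)
  b <- as.numeric(ctr - M %*% (ctr + transform$shift))
  out <- cpp_affine_sample(as.numeric(volume$data), as.integer(d), M, b,
                           as.integer(d), fill)
  new_volume(array(out, d), volume$voxel_size, volume$origin)
}

#' Soft spherical mask
#'
#' Values are exactly 1 strictly inside `radius - edge_width`, exactly 0
#' outside `radius`, with a raised-cosine falloff in between.
#'
#' @param n cube edge in voxels (or length-3 dimensions).
#' @param radius mask radius in voxels.
#' @param edge_width raised-cosine edge width in voxels.
#' @param center 0-based centre in voxels; defaults to `floor(dim/2)`.
#' @return 3-D array of mask values in `[0, 1]`.
#' @export
spherical_mask <- function(n, radius, edge_width = 2, center = NULL) {
  d <- if (length(n) == 1) rep(n, 3) else n
  if (is.null(center)) center <- floor(d / 2)
  r <- radial_grid(d, center)
  m <- array(0, d)
  inner <- radius - edge_width
  m[r <= inner] <- 1
  sel <- r > inner & r < radius
  m[sel] <- 0.5 * (1 + cos(pi * (r[sel] - inner) / edge_width))
  m
}

# Euclidean distance of every voxel from a 0-based centre point.
radial_grid <- function(d, center) {
  dx2 <- (seq_len(d[1]) - 1 - center[1])^2
  dy2 <- (seq_len(d[2]) - 1 - center[2])^2
  dz2 <- (seq_len(d[3]) - 1 - center[3])^2
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

#' Normalized cross-correlation of two volumes
#'
#' Pearson correlation over voxels, optionally weighted by a mask.
#'
#' @param a,b `Volume`s or 3-D arrays of equal dimensions.
#' @param mask optional weight array in `[0, 1]`.
#' @return scalar correlation in `[-1, 1]`.
#' @export
vol_cc <- function(a, b, mask = NULL) {
  x <- if (inherits(a, "Volume")) a$data else a
  y <- if (inherits(b, "Volume")) b$data else b
  stopifnot(all(dim(x) == dim(y)))
  if (is.null(mask)) {
    x <- x - mean(x); y <- y - mean(y)
    s <- sqrt(sum(x^2) * sum(y^2))
    if (s == 0) return(0)
    sum(x * y) / s
  } else {
    w <- as.numeric(mask); sw <- sum(w)
    x <- as.numeric(x); y <- as.numeric(y)
    mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    if (vx <= 0 || vy <= 0) return(0)
    sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  }
}

#' Block-average binning of a volume
#'
#' Averages `f x f x f` voxel blocks; the voxel size grows by the factor
#' `f`.  Dimensions must be divisible by `f`.
#'
#' @param volume a `Volume`.
#' @param f integer binning factor.
#' @return the binned `Volume`.
#' @export
bin_volume <- function(volume, f) {
  f <- as.integer(f)
  if (f == 1L) return(volume)
  d <- vol_dim(volume)
  if (any(d %% f != 0))
    stop("bin_volume: dimensions must be divisible by the binning factor")
  nd <- d %/% f
  a <- array(volume$data, c(f, nd[1], f, nd[2], f, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  new_volume(out, volume$voxel_size * f, volume$origin)
}

#' Crop a cubic sub-volume
#'
#' @param volume a `Volume`.
#' @param center 0-based voxel coordinates of the crop centre.
#' @param size crop edge length in voxels.
#' @param pad if `TRUE`, crops reaching outside the volume are filled
#'   with the volume mean instead of raising a boundary error.
#' @return the cropped `Volume`.
#' @export
crop_volume <- function(volume, center, size, pad = FALSE) {
  d <- vol_dim(volume)
  lo <- round(center) - floor(size / 2)   # 0-based inclusive
  hi <- lo + size - 1
  if (any(lo < 0) || any(hi > d - 1)) {
    if (!pad)
      stop(sprintf("crop_volume: crop [%s]..[%s] outside volume",
                   paste(lo, collapse = ","), paste(hi, collapse = ",")))
    out <- array(mean(volume$data), rep(size, 3))
    slo <- pmax(lo, 0)
    shi <- pmin(hi, d - 1)
    if (all(slo <= shi)) {
      out[(slo[1] - lo[1] + 1):(shi[1] - lo[1] + 1),
          (slo[2] - lo[2] + 1):(shi[2] - lo[2] + 1),
          (slo[3] - lo[3] + 1):(shi[3] - lo[3] + 1)] <-
        volume$data[(slo[1] + 1):(shi[1] + 1),
                    (slo[2] + 1):(shi[2] + 1),
                    (slo[3] + 1):(shi[3] + 1)]
    }
    return(new_volume(out, volume$voxel_size,
                      volume$origin + lo * volume$voxel_size))
  }
  new_volume(volume$data[(lo[1] + 1):(hi[1] + 1),
                         (lo[2] + 1):(hi[2] + 1),
                         (lo[3] + 1):(hi[3] + 1), drop = FALSE],
             volume$voxel_size, volume$origin + lo * volume$voxel_size)
}
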