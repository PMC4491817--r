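#' Integer wrapped frequency index along one FFT dimension
#'
#' Returns the signed integer frequency for each FFT bin (0, 1, ...,
#' floor(n/2), -(ceiling(n/2)-1), ..., -1), matching [stats::fft()]
#' ordering.
#'
#' @param n dimension length.
#' @return integer vector of length `n`.
#' @export
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

#' Fourier shell index grid
#'
#' Assigns every Fourier voxel of a cubic grid to an integer shell of
#' width one Fourier voxel; the DC component is shell 0.
#'
#' @param shape cube edge length in voxels (or length-3 dims, all equal).
#' @return 3-D integer array of shell indices.
#' @export
fourier_shells <- function(shape) {
  d <- if (length(shape) == 1) rep(shape, 3) else shape
  if (d[1] != d[2] || d[2] != d[3])
    stop("fourier_shells: cubic shape required")
  n <- d[1]
  f <- fft_freq_index(n)
  r <- sqrt(outer(outer(f^2, f^2, `+`), f^2, `+`))
  array(as.integer(round(r)), c(n, n, n))
}

#' Missing-wedge Fourier support mask
#'
#' Binary support of a single-axis tilt geometry: the tilt axis is y,
#' the beam is z, and a Fourier voxel is sampled when some tilt angle in
#' `[tilt_min, tilt_max]` produces a central section containing it.  The
#' mask is symmetric under Fourier inversion (Friedel symmetry).  An
#' optional rotation matrix re-orients the wedge, as needed when a
#' particle's transform carries its lab-frame wedge into the reference
#' frame.
#'
#' @param tilt_min,tilt_max tilt range in degrees.
#' @param n cube edge in voxels.
#' @param rot optional 3x3 rotation matrix applied to the wedge support:
#'   the support of a particle rotated by `R` is `wedge(t(R) %*% k)`.
#' @return object of class `WedgeMask` with fields `tilt_min`,
#'   `tilt_max`, `n`, `rot`.
#' @export
wedge_mask <- function(n, tilt_min = -60, tilt_max = 60, rot = NULL) {
  stopifnot(tilt_min < tilt_max)
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 n = as.integer(n),
                 rot = if (is.null(rot)) diag(3) else rot),
            class = "WedgeMask")
}

#' Rotate a wedge mask
#'
#' @param wedge a `WedgeMask`.
#' @param R 3x3 rotation matrix (composed onto the existing orientation).
#' @return the rotated `WedgeMask`.
#' @export
rotate_wedge <- function(wedge, R) {
  wedge$rot <- R %*% wedge$rot
  wedge
}

#' Full-support (no missing wedge) mask
#'
#' @param n cube edge in voxels.
#' @return a `WedgeMask` whose support is all of Fourier space.
#' @export
full_wedge <- function(n) wedge_mask(n, -90, 90 + 1e-9)

#' Evaluate a wedge mask on its Fourier grid
#'
#' @param wedge a `WedgeMask`.
#' @return 3-D 0/1 array in FFT bin ordering.
#' @export
wedge_array <- function(wedge) {
  n <- wedge$n
  f <- fft_freq_index(n)
  kx <- array(f, c(n, n, n))
  ky <- array(rep(f, each = n), c(n, n, n))
  kz <- array(rep(f, each = n * n), c(n, n, n))
  # evaluate the unrotated support at t(rot) %*% k
  Rt <- t(wedge$rot)
  kx2 <- Rt[1, 1] * kx + Rt[1, 2] * ky + Rt[1, 3] * kz
  kz2 <- Rt[3, 1] * kx + Rt[3, 2] * ky + Rt[3, 3] * kz
  # a tilt alpha samples the plane -kx*sin(a) + kz*cos(a) = 0,
  # i.e. direction angle atan2(kz, kx) folded to (-90, 90]
  a <- atan2(kz2, kx2) * 180 / pi
  a[a > 90] <- a[a > 90] - 180
  a[a <= -90] <- a[a <= -90] + 180
  m <- (a >= wedge$tilt_min & a <= wedge$tilt_max) |
    (abs(kx2) < 1e-9 & abs(kz2) < 1e-9)
  array(as.numeric(m), c(n, n, n))
}

#' Fourier shell correlation between two volumes
#'
#' @param volume_a,volume_b `Volume`s of identical shape and voxel size.
#' @return an `FscCurve` data frame with columns `shell`, `freq` (1/A)
#'   and `fsc`.
#' @export
fsc <- function(volume_a, volume_b) {
  stopifnot(inherits(volume_a, "Volume"), inherits(volume_b, "Volume"))
  if (!all(vol_dim(volume_a) == vol_dim(volume_b)))
    stop("fsc: mismatched shapes")
  if (abs(volume_a$voxel_size - volume_b$voxel_size) > 1e-6)
    stop("fsc: mismatched voxel sizes")
  n <- vol_dim(volume_a)[1]
  sh <- as.integer(fourier_shells(n))
  fa <- fft(volume_a$data); fb <- fft(volume_b$data)
  nmax <- n %/% 2
  keep <- sh <= nmax
  sh1 <- sh[keep] + 1L
  num <- rowsum(Re(fa[keep] * Conj(fb[keep])), sh1)
  da <- rowsum(Mod(fa[keep])^2, sh1)
  db <- rowsum(Mod(fb[keep])^2, sh1)
  denom <- sqrt(da * db)
  val <- ifelse(denom > 0, num / denom, 0)
  curve <- data.frame(shell = sort(unique(sh1)) - 1L,
                      freq = (sort(unique(sh1)) - 1L) /
                        (n * volume_a$voxel_size),
                      fsc = as.numeric(val))
  class(curve) <- c("FscCurve", "data.frame")
  curve
}

#' Resolution at an FSC threshold
#'
#' Finds the first downward crossing of the threshold, linearly
#' interpolated between shells, and returns the corresponding resolution
#' in Angstrom.  When the curve never drops below the threshold the
#' Nyquist resolution is returned with `no_crossing = TRUE`.
#'
#' @param curve an `FscCurve` from [fsc()].
#' @param threshold correlation threshold (0.5 for half-set FSC, 0.14
#'   for cross-resolution between independently processed maps).
#' @return list with `resolution` (Angstrom) and `no_crossing` flag.
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  v <- curve$fsc
  f <- curve$freq
  for (i in 2:length(v)) {
    if (v[i] < threshold && v[i - 1] >= threshold) {
      fc <- f[i - 1] + (f[i] - f[i - 1]) *
        (v[i - 1] - threshold) / (v[i - 1] - v[i])
      return(list(resolution = 1 / fc, no_crossing = FALSE))
    }
  }
  list(resolution = 1 / f[length(f)], no_crossing = TRUE)
}

#' Low-pass filter a volume to a target resolution
#'
#' Fourier mask with a raised-cosine edge two shells wide, centred on
#' the cut-off shell.
#'
#' @param volume a `Volume`.
#' @param resolution target resolution in Angstrom.
#' @param edge_shells soft edge width in shells.
#' @return the filtered `Volume`.
#' @export
lowpass <- function(volume, resolution, edge_shells = 2) {
  n <- vol_dim(volume)[1]
  stopifnot(is_cubic(volume))
  cutoff <- n * volume$voxel_size / resolution   # shell index of cut-off
  sh <- fourier_shells(n)
  w <- array(0, dim(sh))
  w[sh <= cutoff - edge_shells / 2] <- 1
  sel <- sh > cutoff - edge_shells / 2 & sh < cutoff + edge_shells / 2
  w[sel] <- 0.5 * (1 + cos(pi * (sh[sel] - cutoff + edge_shells / 2) /
                             edge_shells))
  out <- Re(fft(fft(volume$data) * w, inverse = TRUE)) / length(w)
  new_volume(out, volume$voxel_size, volume$origin)
}
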