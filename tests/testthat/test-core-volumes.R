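test_that("rigid transforms satisfy the group laws", {
  set.seed(1)
  for (i in 1:10) {
    t1 <- rigid_transform(runif(1, 0, 360), runif(1, 0, 180),
                          runif(1, 0, 360), runif(3, -5, 5))
    t2 <- rigid_transform(runif(1, 0, 360), runif(1, 0, 180),
                          runif(1, 0, 360), runif(3, -5, 5))
    t3 <- rigid_transform(runif(1, 0, 360), runif(1, 0, 180),
                          runif(1, 0, 360), runif(3, -5, 5))
    Rmat <- function(t) euler_to_matrix(t$phi, t$theta, t$psi)
    # identity and inverse (compared on matrix entries and shifts,
    # which resolve far below the acos-based angle metric)
    idd <- compose(t1, invert(t1))
    expect_lt(max(abs(Rmat(idd) - diag(3))), 1e-9)
    expect_lt(max(abs(idd$shift)), 1e-9)
    ct <- compose(rigid_transform(), t1)
    expect_lt(max(abs(Rmat(ct) - Rmat(t1))), 1e-9)
    expect_lt(max(abs(ct$shift - t1$shift)), 1e-9)
    # associativity
    a <- compose(compose(t1, t2), t3)
    b <- compose(t1, compose(t2, t3))
    expect_lt(max(abs(Rmat(a) - Rmat(b))), 1e-9)
    expect_lt(max(abs(a$shift - b$shift)), 1e-9)
    # Euler round trip
    R <- euler_to_matrix(t1$phi, t1$theta, t1$psi)
    e <- matrix_to_euler(R)
    expect_lt(max(abs(euler_to_matrix(e[1], e[2], e[3]) - R)), 1e-12)
  }
})

test_that("the rotation convention moves an x-offset impulse to +y under phi = 90", {
  n <- 16
  ctr <- floor(n / 2)
  a <- array(0, rep(n, 3))
  a[ctr + 5 + 1, ctr + 1, ctr + 1] <- 1
  r <- apply_transform(new_volume(a, 1), rigid_transform(90, 0, 0),
                       fill = 0)
  hit <- which(r$data > 0.5, arr.ind = TRUE) - 1
  expect_equal(nrow(hit), 1)
  expect_equal(as.numeric(hit), c(ctr, ctr + 5, ctr))
})

test_that("a half-voxel shift splits an impulse by trilinear weights", {
  n <- 16
  ctr <- floor(n / 2)
  a <- array(0, rep(n, 3))
  a[ctr + 1, ctr + 1, ctr + 1] <- 1
  r <- apply_transform(new_volume(a, 1),
                       rigid_transform(shift = c(1.5, 0, 0)), fill = 0)
  expect_equal(r$data[ctr + 2, ctr + 1, ctr + 1], 0.5)
  expect_equal(r$data[ctr + 3, ctr + 1, ctr + 1], 0.5)
  expect_equal(sum(r$data), 1)
})

test_that("composed transforms act like sequential application on a smooth phantom", {
  v <- blob_phantom()
  set.seed(7)
  t1 <- rigid_transform(runif(1, 0, 360), runif(1, 0, 60),
                        runif(1, 0, 360), runif(3, -2, 2))
  t2 <- rigid_transform(runif(1, 0, 360), runif(1, 0, 60),
                        runif(1, 0, 360), runif(3, -2, 2))
  one <- apply_transform(v, compose(t1, t2))
  two <- apply_transform(apply_transform(v, t2), t1)
  expect_gt(vol_cc(one, two), 0.98)
})

test_that("rotations of a band-limited phantom preserve energy within 5%", {
  v <- lowpass(blob_phantom(), 80)
  e0 <- sum((v$data - mean(v$data))^2)
  set.seed(3)
  for (i in 1:5) {
    r <- apply_transform(v, rigid_transform(runif(1, 0, 360),
                                            runif(1, 0, 180),
                                            runif(1, 0, 360)))
    e1 <- sum((r$data - mean(r$data))^2)
    expect_lt(abs(e1 / e0 - 1), 0.05)
  }
})

test_that("transform validation rejects non-finite parameters", {
  expect_error(rigid_transform(NaN, 0, 0), "non-finite")
  v <- blob_phantom(16)
  tr <- rigid_transform()
  tr$shift[1] <- Inf
  expect_error(apply_transform(v, tr), "non-finite")
})

test_that("MRC round trips are lossless for float32 data", {
  dir <- withr::local_tempdir()
  # float32-representable values survive bit-exactly
  v <- new_volume(array(as.numeric(1:(16^3)), rep(16, 3)),
                  voxel_size = 6.6, origin = c(13.2, 0, -6.6))
  path <- file.path(dir, "ramp.mrc")
  write_mrc(v, path)
  v2 <- read_mrc(path)
  expect_identical(v2$data, v$data)
  expect_equal(v2$voxel_size, 6.6, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
  # arbitrary doubles survive to float32 precision
  set.seed(1)
  w <- new_volume(array(rnorm(8^3), rep(8, 3)), 3.3)
  write_mrc(w, file.path(dir, "n.mrc"))
  w2 <- read_mrc(file.path(dir, "n.mrc"))
  expect_lt(max(abs(w2$data - w$data)), 1e-6)
})

test_that("malformed MRC files raise format errors naming the problem", {
  dir <- withr::local_tempdir()
  short <- file.path(dir, "short.mrc")
  writeBin(raw(100), short)
  expect_error(read_mrc(short), "header")
  # plausible header but truncated data section
  v <- new_volume(array(1, rep(8, 3)), 1)
  full <- file.path(dir, "full.mrc")
  write_mrc(v, full)
  bytes <- readBin(full, "raw", n = file.size(full))
  trunc <- file.path(dir, "trunc.mrc")
  writeBin(bytes[1:(1024 + 100)], trunc)
  expect_error(read_mrc(trunc), "truncated")
  expect_error(read_mrc(file.path(dir, "absent.mrc")), "exist")
})

test_that("fourier shells match brute-force radius binning", {
  n <- 8
  sh <- fourier_shells(n)
  f <- fft_freq_index(n)
  brute <- array(0L, rep(n, 3))
  for (k in 1:n) for (j in 1:n) for (i in 1:n)
    brute[i, j, k] <- as.integer(round(sqrt(f[i]^2 + f[j]^2 + f[k]^2)))
  expect_identical(sh, brute)
  expect_equal(sum(sh == 0), 1)           # DC alone in shell 0
  expect_gte(max(sh), n / 2)              # reaches Nyquist
  expect_equal(length(sh), n^3)           # populations sum to the grid
  expect_error(fourier_shells(c(8, 8, 4)), "cubic")
})

test_that("spherical masks are 1 inside, 0 outside, with a raised-cosine edge", {
  m <- spherical_mask(24, 9, 2)
  r <- tomopore:::radial_grid(rep(24, 3), floor(rep(24, 3) / 2))
  expect_true(all(m[r <= 7 - 1e-9] == 1))
  expect_true(all(m[r >= 9] == 0))
  expect_true(all(m >= 0 & m <= 1))
})
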