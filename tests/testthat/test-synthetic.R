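test_that("the pore phantom is eightfold symmetric by construction", {
  vs <- 26.4
  d <- rep(64, 3)
  ctr <- floor(d / 2)
  spec <- pore_phantom_spec(membrane = FALSE)
  a0 <- tomopore:::render_pore(array(0, d), spec, ctr, diag(3), vs)
  a45 <- tomopore:::render_pore(array(0, d), spec, ctr,
                                euler_to_matrix(45, 0, 0), vs)
  # analytic re-render at the symmetry rotation reproduces the density
  expect_gt(vol_cc(a0, a45), 0.999)
  # an interpolated rotation agrees within the supported region
  r45 <- apply_transform(new_volume(a0, vs), rigid_transform(45, 0, 0))
  m <- spherical_mask(64, 28)
  expect_gt(vol_cc(a0 * m, r45$data * m), 0.998)
})

test_that("phantom sphere centres sit on the 90 nm circle", {
  vs <- 26.4
  tpl <- make_geometric_template(64, vs)
  ctr <- floor(rep(64, 3) / 2)
  cents <- sapply(0:7, function(k) {
    ang <- 2 * pi * k / 8
    exp_c <- ctr + c(450 * cos(ang), 450 * sin(ang), 0) / vs
    sel <- spherical_mask(64, 200 / vs, 0.5, center = exp_c)
    w <- tpl$data * sel
    idx <- which(w > 0, arr.ind = TRUE) - 1
    cen <- colSums(idx * w[w > 0]) / sum(w)
    sqrt(sum((cen[1:2] - ctr[1:2])^2)) * vs
  })
  # centroid radius 45 nm within half a voxel
  expect_true(all(abs(cents - 450) < vs / 2))
})

test_that("overlapping pore placements raise a placement error", {
  expect_error(
    build_phantom(box = 192, n_copies = 2,
                  positions = cbind(c(90, 100), c(96, 96)), seed = 1),
    "colliding")
})

test_that("tilt projection count, mass conservation and top-view symmetry", {
  a <- array(0, rep(48, 3))
  a <- tomopore:::add_soft_sphere(a, rep(24, 3), 8, 2)
  v <- new_volume(a, 10)
  acq <- acquisition_spec(pixel_size = 10, defocus_nominal = 0)
  ts <- project_tilt_series(v, acq)
  expect_equal(dim(ts$images)[3], 41)     # -60..60 in 3 degree steps
  masses <- apply(ts$images, 3, sum)
  expect_lt(max(abs(masses / sum(a) - 1)), 0.01)
  # the zero-tilt projection of a centred sphere is circularly symmetric
  p0 <- ts$images[, , which(ts$angles == 0)]
  expect_gt(cor(as.numeric(p0), as.numeric(t(p0))), 0.999)
  # reflection about the sphere centre (1-based row 25)
  expect_gt(cor(as.numeric(p0[2:48, ]), as.numeric(p0[48:2, ])), 0.999)
})

test_that("corruption is the identity without defocus, MTF or noise", {
  a <- array(0, rep(32, 3))
  a <- tomopore:::add_soft_sphere(a, rep(16, 3), 6, 2)
  v <- new_volume(a, 10)
  acq <- acquisition_spec(pixel_size = 10, defocus_nominal = 0,
                          tilt_step = 20, dose_noise_sigma = 0)
  ts <- project_tilt_series(v, acq)
  tc <- corrupt(ts, acq, ctf = ctf_model(defocus = 0, mtf = "none"))
  expect_equal(tc$images, ts$images, tolerance = 1e-12)
})

test_that("corruption with a fixed seed is bit-identical across runs", {
  a <- array(0, rep(32, 3))
  a <- tomopore:::add_soft_sphere(a, rep(16, 3), 6, 2)
  v <- new_volume(a, 3.3)
  acq <- acquisition_spec(pixel_size = 3.3, tilt_step = 30,
                          dose_noise_sigma = 0.5, seed = 42)
  ts <- project_tilt_series(v, acq)
  expect_identical(corrupt(ts, acq)$images, corrupt(ts, acq)$images)
})

test_that("power-spectrum zeros of a corrupted flat-noise image match the CTF zeros", {
  set.seed(1)
  n <- 256
  px <- 3.3
  cm <- ctf_model(defocus = -6)
  img <- matrix(rnorm(n * n), n)
  k1 <- fft_freq_index(n) / (n * px)
  k <- sqrt(outer(k1^2, k1^2, `+`))
  cor_img <- Re(fft(fft(img) * ctf_eval(cm, k, -6), inverse = TRUE)) / n^2
  pw <- Mod(fft(cor_img))^2
  nyq <- 1 / (2 * px)
  nbin <- 128
  bins <- pmin(nbin, 1 + floor(k / nyq * nbin))
  rad <- as.numeric(tapply(as.numeric(pw), as.numeric(bins), mean))
  kc <- (seq_len(nbin) - 0.5) / nbin * nyq
  # analytic zeros of the CTF (including the amplitude-contrast phase)
  kk <- seq(1e-3, nyq, by = 1e-5)
  zer <- kk[which(diff(sign(ctf_eval(cm, kk, -6))) != 0)]
  zer <- zer[zer > 0.02 & zer < 0.06]
  mins <- c()
  for (i in 3:(nbin - 2))
    if (rad[i] < rad[i - 1] && rad[i] < rad[i + 1]) mins <- c(mins, kc[i])
  for (z in zer) {
    expect_lt(min(abs(mins - z)), 1 / (n * px))  # within one Fourier pixel
  }
})

test_that("weighted backprojection reconstructs a dense-coverage sphere", {
  a <- array(0, rep(48, 3))
  a <- tomopore:::add_soft_sphere(a, rep(24, 3), 8, 2)
  v <- new_volume(a, 10)
  acq <- acquisition_spec(tilt_min = -89, tilt_max = 90, tilt_step = 2,
                          pixel_size = 10, defocus_nominal = 0)
  rec <- weighted_backprojection(project_tilt_series(v, acq))
  m <- spherical_mask(48, 13)
  expect_gt(vol_cc(rec$data * m, a * m), 0.95)
})

test_that("the missing wedge of a +-60 reconstruction is empty and WBP is linear", {
  a <- array(0, rep(48, 3))
  a <- tomopore:::add_soft_sphere(a, rep(24, 3), 8, 2)
  v <- new_volume(a, 10)
  acq <- acquisition_spec(pixel_size = 10, defocus_nominal = 0)
  ts <- project_tilt_series(v, acq)
  rec <- weighted_backprojection(ts)
  W <- wedge_array(wedge_mask(48, -60 - 1e-6, 60 + 1e-6))
  F <- fft(rec$data)
  out_rms <- sqrt(mean(Mod(F[W == 0])^2))
  in_rms <- sqrt(mean(Mod(F[W == 1])^2))
  expect_lt(out_rms / in_rms, 1e-6)
  # linearity
  ts3 <- ts
  ts3$images <- 3 * ts$images
  expect_equal(weighted_backprojection(ts3)$data, 3 * rec$data,
               tolerance = 1e-10)
  # wedge-masked phantom agreement
  phw <- Re(fft(fft(a) * W, inverse = TRUE)) / 48^3
  m <- spherical_mask(48, 13)
  expect_gt(vol_cc(rec$data * m, phw * m), 0.9)
  # fewer than 3 projections is refused
  ts2 <- ts
  ts2$images <- ts$images[, , 1:2, drop = FALSE]
  expect_error(weighted_backprojection(ts2), "3 projections")
})

test_that("wedge masks have Friedel symmetry and a partial support", {
  n <- 24
  w <- wedge_array(wedge_mask(n, -60, 60))
  idx <- function(k) (n - k) %% n + 1
  set.seed(2)
  for (t in 1:100) {
    i <- sample(0:(n - 1), 3, replace = TRUE)
    expect_equal(w[i[1] + 1, i[2] + 1, i[3] + 1],
                 w[idx(i[1]), idx(i[2]), idx(i[3])])
  }
  expect_gt(mean(w), 0)
  expect_lt(mean(w), 1)
  expect_equal(mean(wedge_array(full_wedge(n))), 1)
})

test_that("subtomogram simulation is seed-deterministic and honours its SNR", {
  s1 <- simulate_subtomograms(2, box = 32, voxel_size = 52.8, snr = 0.5,
                              seed = 9)
  s2 <- simulate_subtomograms(2, box = 32, voxel_size = 52.8, snr = 0.5,
                              seed = 9)
  expect_identical(s1$particles[[1]]$volume$data,
                   s2$particles[[1]]$volume$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_subtomograms(2, box = 32, voxel_size = 52.8, snr = 0.5,
                              seed = 10)
  expect_false(identical(s1$particles[[1]]$volume$data,
                         s3$particles[[1]]$volume$data))
})
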