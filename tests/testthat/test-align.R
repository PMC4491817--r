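test_that("constrained CC is 1 for identity, -1 for negation, and peaks at the planted pose", {
  v <- blob_phantom(20, 60)
  wf <- full_wedge(20)
  expect_equal(constrained_cc(v, v, wf, wf), 1, tolerance = 1e-6)
  neg <- new_volume(-v$data, v$voxel_size)
  expect_equal(constrained_cc(v, neg, wf, wf), -1, tolerance = 1e-6)
  # brute-force scan on a 20^3 phantom: the planted rotation scores
  # strictly above every candidate at least 10 degrees away
  planted <- rigid_transform(24, 10, -18)
  w <- wedge_mask(20, -60, 60)
  part <- apply_transform(v, planted)
  part <- new_volume(Re(fft(fft(part$data) * wedge_array(w),
                            inverse = TRUE)) / 20^3, v$voxel_size)
  cc_at <- function(tr) constrained_cc(v, part, full_wedge(20), w, tr)
  best <- cc_at(planted)
  grid <- expand.grid(p = seq(-30, 60, by = 15),
                      t = seq(0, 30, by = 15),
                      s = seq(-45, 15, by = 15))
  for (i in seq_len(nrow(grid))) {
    tr <- rigid_transform(grid$p[i], grid$t[i], grid$s[i])
    if (rotation_distance(tr, planted) >= 10)
      expect_lt(cc_at(tr), best)
  }
})

test_that("degenerate wedge overlap raises an error", {
  v <- blob_phantom(16)
  w <- wedge_mask(16, -60, 60)
  expect_error(constrained_cc(v, v, w, w, min_overlap = 1e9),
               "degenerate")
})

test_that("planted poses are recovered at zero noise within 1 degree and half a voxel", {
  sim <- simulate_subtomograms(3, box = 32, voxel_size = 52.8, snr = Inf,
                               seed = 4)
  ref <- make_geometric_template(32, 52.8)
  out <- align_particles(sim$particles, ref, stages = list(
    list(window = angular_window(30, 12, 30, 10), shift_bound = 4),
    list(window = angular_window(8, 8, 8, 4), shift_bound = 3),
    list(window = angular_window(3, 3, 3, 1), shift_bound = 2)))
  for (i in 1:3) {
    tru <- sim$truth[i, ]
    expect_lt(sym_rotation_distance(out[[i]]$transform,
                                    rigid_transform(tru$phi, tru$theta,
                                                    tru$psi)), 1)
    expect_lt(sqrt(sum((out[[i]]$transform$shift -
                          c(tru$dx, tru$dy, tru$dz))^2)), 0.5)
  }
})

test_that("a collapsed window performs translation-only alignment", {
  v <- blob_phantom(24, 40)
  shifted <- apply_transform(v, rigid_transform(shift = c(2, -1, 3)))
  p <- list(volume = shifted, transform = rigid_transform(),
            wedge = full_wedge(24), particle_id = 1, keep = TRUE)
  res <- align_particle(p, v, angular_window(0, 0, 0, 1), shift_bound = 4)
  expect_equal(res$transform$phi, 0)
  expect_equal(res$transform$theta, 0)
  expect_equal(res$transform$psi, 0)
  expect_equal(res$transform$shift, c(2, -1, 3), tolerance = 0.1)
})

test_that("poses planted outside the window raise the at-window-limit flag", {
  v <- blob_phantom(24, 40)
  planted <- rigid_transform(0, 25, 0)   # theta well outside +-8
  part <- list(volume = apply_transform(v, planted),
               transform = rigid_transform(), wedge = full_wedge(24),
               particle_id = 1, keep = TRUE)
  res <- align_particle(part, v, angular_window(0, 8, 0, 4),
                        shift_bound = 2)
  expect_true(res$at_window_limit)
})

test_that("averaging identical noise-free particles reproduces the particle", {
  v <- blob_phantom(24, 40)
  parts <- lapply(1:4, function(i)
    list(volume = v, transform = rigid_transform(),
         wedge = full_wedge(24), particle_id = i, keep = TRUE))
  avg <- wedge_average(parts)
  # output is normalized; compare up to the affine normalization
  expect_gt(vol_cc(avg, v), 0.9999)
  expect_error(wedge_average(list()), "empty")
})

test_that("wedge-compensated averaging fills Fourier space beyond any single particle", {
  base <- textured_pore(32, seed = 2)
  sim <- simulate_copies(base, 6, snr = Inf, seed = 3,
                         theta_range = c(20, 60))
  single_unsampled <- mean(wedge_array(sim$particles[[1]]$wedge) == 0)
  cov <- array(0, rep(32, 3))
  for (p in sim$particles) {
    ti <- invert(p$transform)
    Rt <- euler_to_matrix(ti$phi, ti$theta, ti$psi)
    cov <- cov + wedge_array(rotate_wedge(p$wedge, Rt))
  }
  expect_lt(mean(cov == 0), single_unsampled)
  # determinism of the average
  a1 <- wedge_average(sim$particles)
  a2 <- wedge_average(sim$particles)
  expect_identical(a1$data, a2$data)
})

test_that("half splits are disjoint, exhaustive and label-aware", {
  parts <- lapply(1:10, function(i)
    list(particle_id = i, label = if (i <= 6) "native" else "perturbed"))
  h <- split_halves(parts)
  expect_equal(length(h$a), 5)
  expect_equal(length(h$b), 5)
  ids <- c(sapply(h$a, `[[`, "particle_id"),
           sapply(h$b, `[[`, "particle_id"))
  expect_setequal(ids, 1:10)
  hc <- split_halves(parts, mode = "cross")
  expect_equal(length(hc$a), 6)
  expect_equal(length(hc$b), 4)
  expect_true(all(sapply(hc$a, `[[`, "label") == "native"))
})

test_that("FSC is 1 for identical volumes, -1 for negated, and reads band limits", {
  v <- blob_phantom(32, 10)
  cu <- fsc(v, v)
  expect_true(all(abs(cu$fsc - 1) < 1e-9))
  cn <- fsc(v, new_volume(-v$data, 10))
  expect_true(all(abs(cn$fsc + 1) < 1e-9))
  expect_error(fsc(v, blob_phantom(16, 10)), "shapes")
  # two independent-noise copies of a 30 A-low-passed phantom cross 0.5
  # within one shell of 30 A
  set.seed(8)
  base <- lowpass(new_volume(array(rnorm(32^3), rep(32, 3)), 5), 30)$data
  sg <- sd(base)
  a <- new_volume(base + rnorm(32^3, sd = 1.5 * sg), 5)
  b <- new_volume(base + rnorm(32^3, sd = 1.5 * sg), 5)
  res <- resolution_at(fsc(a, b), 0.5)
  shell_w <- 1 / (32 * 5)
  expect_false(res$no_crossing)
  expect_gt(1 / res$resolution, 1 / 30 - shell_w)
  expect_lt(1 / res$resolution, 1 / 30 + shell_w)
  # no crossing for identical inputs
  expect_true(resolution_at(fsc(v, v), 0.5)$no_crossing)
})

test_that("window-limit exclusions flag exactly the railed rows with a reason code", {
  t_ <- data.frame(particle_id = 1:10,
                   at_window_limit = c(rep(TRUE, 3), rep(FALSE, 7)),
                   keep = TRUE, reason = "", stringsAsFactors = FALSE)
  out <- exclude_at_limits(t_)
  expect_equal(sum(out$keep), 7)
  expect_true(all(out$reason[1:3] == "angle_at_limit"))
  expect_true(all(out$reason[4:10] == ""))
  # untouched when no flags
  t2 <- t_
  t2$at_window_limit <- FALSE
  expect_identical(exclude_at_limits(t2), t2)
})
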