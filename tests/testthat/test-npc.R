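test_that("the geometric template has C8 geometry with 34.4 nm sphere spacing", {
  vs <- 26.4
  tpl <- make_geometric_template(64, vs)
  ctr <- floor(rep(64, 3) / 2)
  cents <- t(sapply(0:7, function(k) {
    ang <- 2 * pi * k / 8
    exp_c <- ctr + c(450 * cos(ang), 450 * sin(ang), 0) / vs
    sel <- spherical_mask(64, 200 / vs, 0.5, center = exp_c)
    w <- tpl$data * sel
    idx <- which(w > 0, arr.ind = TRUE) - 1
    colSums(idx * w[w > 0]) / sum(w)
  }))
  # adjacent sphere spacing: chord 90 sin(22.5 deg) ~ 34.4 nm
  for (k in 1:8) {
    d <- sqrt(sum((cents[k, ] - cents[k %% 8 + 1, ])^2)) * vs / 10
    expect_lt(abs(d - 90 * sin(pi / 8)), 0.5)
  }
  expect_error(make_geometric_template(16, 26.4), "exceed")
})

test_that("spheroid fits recover spheres, oblate surfaces and their normals", {
  set.seed(1)
  th <- runif(300, 0, 2 * pi)
  # sphere special case: a = c = R within 1%
  phs <- runif(300, 0, pi)
  pts <- cbind(5000 * sin(phs) * cos(th), 5000 * sin(phs) * sin(th),
               5000 * cos(phs))
  f <- fit_spheroid(pts)
  expect_lt(abs(f$a / 5000 - 1), 0.01)
  expect_lt(abs(f$c / 5000 - 1), 0.01)
  # oblate a = 2c: pole normal along +-z within 0.5 degrees
  phb <- runif(300, 0, pi / 2.5)
  pts2 <- cbind(6000 * sin(phb) * cos(th), 6000 * sin(phb) * sin(th),
                3000 * cos(phb))
  f2 <- fit_spheroid(pts2)
  expect_true(f2$oblate)
  n2 <- normal_at(f2, c(0, 0, 3000))
  expect_lt(acos(abs(n2[3])) * 180 / pi, 0.5)
  expect_equal(sqrt(sum(n2^2)), 1, tolerance = 1e-9)
  # coplanar points are refused
  expect_error(fit_spheroid(cbind(runif(12, 0, 100), runif(12, 0, 100),
                                  rep(1, 12))), "degenerate")
  expect_error(fit_spheroid(pts[1:5, ]), "9 points")
})

test_that("orientation verification excludes strictly beyond 20 degrees", {
  up <- c(0, 0, 1)
  expect_true(verify_orientation(rigid_transform(0, 0, 0), up)$keep)
  # exactly 20.0 degrees is kept (strict inequality)
  v20 <- verify_orientation(rigid_transform(0, 20, 0), up)
  expect_true(v20$keep)
  expect_equal(v20$mismatch_deg, 20, tolerance = 1e-9)
  v25 <- verify_orientation(rigid_transform(0, 25, 0), up)
  expect_false(v25$keep)
  expect_equal(v25$reason, "normal_mismatch")
  # the axis is unsigned: a flipped pore matches its normal
  expect_true(verify_orientation(rigid_transform(0, 180, 0), up)$keep)
  expect_error(verify_orientation(rigid_transform(), c(0, 0, 0)),
               "zero-length")
})

test_that("protomer extraction yields 8 consistent protomers with tracked wedges", {
  vs <- 26.4
  tpl <- make_geometric_template(96, vs)
  pspec <- desk_protomer_spec()
  prots <- extract_protomers(tpl, rigid_transform(0, 0, 0),
                             floor(rep(96, 3) / 2), pspec,
                             particle_id = 1)
  expect_equal(length(prots), 8)
  expect_equal(sapply(prots, `[[`, "k"), 0:7)
  # all 8 pairwise consistent after mapping to the protomer frame
  aligned <- lapply(prots, function(p)
    apply_transform(p$volume, invert(p$transform)))
  m <- spherical_mask(32, 13)
  for (i in 1:7) for (j in (i + 1):8)
    expect_gt(vol_cc(aligned[[i]]$data * m, aligned[[j]]$data * m), 0.99)
  # pose bookkeeping: protomer k rotation = R_global Rz(45 k)
  R0 <- euler_to_matrix(prots[[1]]$transform$phi,
                        prots[[1]]$transform$theta,
                        prots[[1]]$transform$psi)
  for (k in 0:7) {
    Rk <- euler_to_matrix(prots[[k + 1]]$transform$phi,
                          prots[[k + 1]]$transform$theta,
                          prots[[k + 1]]$transform$psi)
    expect_lt(rotation_distance(Rk, R0 %*% euler_to_matrix(45 * k, 0, 0)),
              1e-9)
  }
  # boundary handling
  expect_error(extract_protomers(tpl, rigid_transform(),
                                 c(2, 2, 2), pspec, particle_id = 1),
               "boundary")
  soft <- extract_protomers(tpl, rigid_transform(), c(2, 2, 2), pspec,
                            particle_id = 1, on_boundary = "exclude")
  expect_true(any(!sapply(soft, `[[`, "keep")))
  expect_true(all(sapply(soft, `[[`, "reason")[!sapply(soft, `[[`, "keep")]
                  == "boundary"))
})

test_that("view balancing caps each polar-angle bin keeping the best correlations", {
  set.seed(3)
  t_ <- data.frame(particle_id = 1:100, theta = rep(5, 100),
                   cc = runif(100), keep = TRUE, reason = "",
                   stringsAsFactors = FALSE)
  out <- balance_views(t_, bin_size_deg = 15, cap = 20)
  expect_equal(sum(out$keep), 20)
  expect_true(all(out$reason[!out$keep] == "view_balance"))
  # kept subset carries the maximal correlations of the bin
  expect_equal(sort(out$cc[out$keep]),
               sort(t_$cc, decreasing = TRUE)[20:1])
  # below the cap nothing changes
  t2 <- t_[1:10, ]
  expect_identical(balance_views(t2, 15, 20), t2)
})

test_that("subprotomer crops re-centre their transforms consistently", {
  vs <- 26.4
  tpl <- make_geometric_template(96, vs)
  pspec <- desk_protomer_spec()
  prots <- extract_protomers(tpl, rigid_transform(0, 0, 0),
                             floor(rep(96, 3) / 2), pspec,
                             particle_id = 1)
  subs <- subdivide_subprotomers(prots, pspec, vs)
  expect_setequal(names(subs), c("cpr", "npr", "sr_ccr"))
  expect_true(all(sapply(subs, length) == 8))
  pref <- tomopore:::protomer_reference(tpl, pspec)
  ms <- spherical_mask(16, 6)
  for (r in names(subs)) {
    sref <- tomopore:::subprotomer_ref_crop(pref, pspec, r)
    for (i in c(1, 4, 7)) {
      back <- apply_transform(subs[[r]][[i]]$volume,
                              invert(subs[[r]][[i]]$transform))
      expect_gt(vol_cc(back$data * ms, sref$data * ms), 0.98)
    }
  }
  # the three crops tile the protomer z-extent around the stated offsets
  offs <- pspec$subprotomer_z / vs
  expect_true(max(offs) + 8 <= pspec$protomer_box - floor(32 / 2) + 16)
})

test_that("alignment masks exclude the 17 nm channel and stay in [0, 1]", {
  vs <- 26.4
  mk <- make_masks(32, vs)
  expect_true(all(mk$channel >= 0 & mk$channel <= 1))
  expect_true(all(mk$combined >= 0 & mk$combined <= 1))
  # zero strictly inside the 17 nm diameter cylinder (any z)
  rx <- (seq_len(32) - 1 - 16) * vs
  r2d <- sqrt(outer(rx^2, rx^2, `+`))
  inside <- array(r2d <= 85, rep(32, 3))
  expect_true(all(mk$channel[inside] == 0))
  # masked CC of volumes differing only inside the excluded cylinder is 1
  v1 <- blob_phantom(32, vs)
  v2 <- v1
  core <- array(r2d < 60, rep(32, 3))
  v2$data[core] <- v2$data[core] + 5
  m <- mk$channel
  expect_equal(vol_cc(v1$data * m, v2$data * m), 1, tolerance = 1e-6)
})

test_that("assembled eightfold models reproduce the phantom they came from", {
  vs <- 26.4
  tpl <- make_geometric_template(96, vs)
  pspec <- desk_protomer_spec()
  pref <- tomopore:::protomer_reference(tpl, pspec)
  avgs <- list(cpr = tomopore:::subprotomer_ref_crop(pref, pspec, "cpr"),
               npr = tomopore:::subprotomer_ref_crop(pref, pspec, "npr"),
               sr_ccr = tomopore:::subprotomer_ref_crop(pref, pspec,
                                                        "sr_ccr"))
  model <- assemble_model(avgs, pspec, 96, filter_resolution = NA)
  msk <- array(as.numeric(model$data != 0), dim(model$data))
  expect_gt(vol_cc(model$data * msk, tpl$data * msk), 0.98)
  # C8 under rotation, within the supported annulus (interpolator-limited)
  r45 <- apply_transform(model, rigid_transform(45, 0, 0), fill = 0)
  ann <- spherical_mask(96, 34)
  expect_gt(vol_cc(model$data * ann, r45$data * ann), 0.98)
  # final low-pass honours its band limit
  filt <- assemble_model(avgs, pspec, 96, filter_resolution = 110)
  cu <- fsc(filt, model)
  res <- resolution_at(cu, 0.5)
  expect_gte(res$resolution, 110 * 0.9)
  # voxel mismatch is refused
  bad <- avgs
  bad$npr$voxel_size <- 13.2
  expect_error(assemble_model(bad, pspec, 96), "voxel sizes")
})

test_that("pore metrics compute the cylinder volume and radial ring peaks", {
  expect_equal(measure_pore_metrics(2, 1)$cylinder_volume_nm3, pi,
               tolerance = 1e-12)
  m <- measure_pore_metrics(37, 26)
  expect_equal(m$cylinder_volume_nm3, pi * 18.5^2 * 26, tolerance = 1e-9)
  expect_equal(round(m$cylinder_volume_nm3), 27955)
  # radial peak machinery on a continuous Gaussian annulus (the
  # azimuthal-mean estimator's intended target; rings of discrete
  # spheres are biased inward by the 1/r shell-area weighting)
  vs <- 26.4
  rx <- (seq_len(64) - 1 - 32) * vs
  r2d <- sqrt(outer(rx^2, rx^2, `+`))
  ring <- exp(-(r2d - 450)^2 / (2 * 40^2))
  b <- array(0, rep(64, 3))
  for (z in 31:35) b[, , z] <- ring
  mm <- measure_pore_metrics(map = new_volume(b, vs),
                             z_range_nm = c(-3, 3), r_range_nm = c(25, 65))
  expect_lt(abs(mm$ring_diameter_nm - 90), vs / 10)
  expect_error(measure_pore_metrics(-1, 5), "diameter_nm > 0")
})

test_that("template matching picks the planted pore positions", {
  ph <- build_phantom(box = 192, voxel_size = 13.2, n_copies = 2,
                      seed = 3)
  tomo <- bin_volume(ph$volume, 2)
  tpl <- make_geometric_template(56, 26.4)
  picks <- pick_template_match(tomo, tpl, n_peaks = 2, min_dist = 20)
  gt <- ph$particles
  for (i in 1:2) {
    d <- sqrt((picks$x - gt$x[i] / 2)^2 + (picks$y - gt$y[i] / 2)^2 +
                (picks$z - gt$z[i] / 2)^2)
    expect_lt(min(d), 3)
  }
  expect_error(pick_template_match(tpl, tomo, 1), "exceeds")
})
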