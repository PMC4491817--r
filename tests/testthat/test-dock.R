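make_docking_scene <- function() {
  vs <- 26.4
  spec <- pore_phantom_spec(membrane = FALSE, planted_body = TRUE)
  a <- array(0, rep(64, 3))
  a <- tomopore:::render_pore(a, spec, floor(rep(64, 3) / 2), diag(3), vs)
  list(map = new_volume(a, vs), body = body_volume(24, vs),
       truth_pos = floor(rep(64, 3) / 2) +
         tomopore:::planted_body_position(spec) / vs,
       vs = vs)
}

test_that("a start at the truth pose converges without leaving it", {
  sc <- make_docking_scene()
  mask <- pmax(sc$body$data - 0.1 * max(sc$body$data), 0)
  res <- tomopore:::cpp_dock_refine(
    as.numeric(sc$map$data), as.integer(rep(64, 3)),
    as.numeric(sc$body$data), as.numeric(mask), as.integer(rep(24, 3)),
    c(0, 0, 0), sc$truth_pos, c(1, 0.25), c(1, 0.25), 200L, 1e-4,
    mean(sc$map$data))
  expect_gt(res$cc, 0.95)
  expect_lt(rotation_distance(rigid_transform(res$phi, res$theta,
                                              res$psi),
                              rigid_transform()), 2)
  expect_lt(sqrt(sum((res$pos - sc$truth_pos)^2)), 1)
})

test_that("global docking is deterministic and recovers the planted pose", {
  sc <- make_docking_scene()
  region <- list(center = sc$truth_pos + c(1, -1, 1), radius = 6)
  s1 <- dock_global(sc$map, sc$body, region, n_starts = 150, seed = 3)
  s2 <- dock_global(sc$map, sc$body, region, n_starts = 150, seed = 3)
  expect_identical(s1, s2)
  top <- deduplicate(s1)[1, ]
  expect_lt(rotation_distance(rigid_transform(top$phi, top$theta,
                                              top$psi),
                              rigid_transform()), 4)
  expect_lt(sqrt(sum((c(top$x, top$y, top$z) - sc$truth_pos)^2)), 2)
  expect_error(dock_global(sc$map, sc$body, list(center = sc$truth_pos,
                                                 radius = 0)), "empty")
})

test_that("deduplication matches a brute-force pairwise clustering", {
  set.seed(5)
  sols <- data.frame(phi = c(0, 1, 30, 30.5, 90),
                     theta = c(0, 0.5, 10, 10, 45),
                     psi = c(0, -1, 5, 5.2, 120),
                     x = c(10, 10.2, 20, 20.1, 30),
                     y = c(10, 10, 20, 20, 30),
                     z = c(10, 10.1, 20, 20, 30),
                     cc = c(0.9, 0.85, 0.8, 0.75, 0.7))
  class(sols) <- c("docking_solutions", "data.frame")
  dd <- deduplicate(sols, rot_tol_deg = 5, trans_tol_voxels = 2)
  expect_equal(nrow(dd), 3)
  expect_equal(dd$rank, 1:3)
  expect_equal(dd$cc, c(0.9, 0.8, 0.7))
  # duplicates of one solution collapse to one
  two <- sols[c(1, 1), ]
  class(two) <- c("docking_solutions", "data.frame")
  expect_equal(nrow(deduplicate(two)), 1)
  # solutions 30 degrees apart at 10 degree tolerance both survive
  far <- sols[c(1, 5), ]
  class(far) <- c("docking_solutions", "data.frame")
  expect_equal(nrow(deduplicate(far, rot_tol_deg = 10)), 2)
  # O(n^2) oracle: every kept pair is separated in rotation or shift
  for (i in seq_len(nrow(dd) - 1)) for (j in (i + 1):nrow(dd)) {
    ri <- euler_to_matrix(dd$phi[i], dd$theta[i], dd$psi[i])
    rj <- euler_to_matrix(dd$phi[j], dd$theta[j], dd$psi[j])
    sep <- rotation_distance(ri, rj) > 5 ||
      sqrt(sum((c(dd$x[i], dd$y[i], dd$z[i]) -
                  c(dd$x[j], dd$y[j], dd$z[j]))^2)) > 2
    expect_true(sep)
  }
})

test_that("plausibility flags match brute-force mass fractions", {
  sc <- make_docking_scene()
  inside <- data.frame(phi = 0, theta = 0, psi = 0,
                       x = sc$truth_pos[1], y = sc$truth_pos[2],
                       z = sc$truth_pos[3])
  fl <- plausibility_flags(inside, sc$map, sc$body,
                           density_threshold = 0.2)
  expect_false(fl$outside_density)
  expect_false(fl$clash)
  # fully outside the density
  outside <- inside
  outside$x <- 6; outside$y <- 6; outside$z <- 6
  fl2 <- plausibility_flags(outside, sc$map, sc$body,
                            density_threshold = 0.2)
  expect_true(fl2$outside_density)
  expect_gt(fl2$outside_fraction, 0.9)
  # brute-force check of the measured fraction
  w <- pmax(sc$body$data - 0.1, 0)
  samp <- tomopore:::sample_in_body_frame(sc$map, inside, rep(24, 3))
  expect_equal(fl$outside_fraction, sum(w * (samp < 0.2)) / sum(w),
               tolerance = 1e-12)
  # clash against an exclusion mask
  excl <- new_volume(array(1, rep(64, 3)), sc$vs)
  fl3 <- plausibility_flags(inside, sc$map, sc$body, 0.2,
                            exclusion_mask = excl)
  expect_true(fl3$clash)
})

test_that("restraint statistics match closed-form geometry", {
  axis <- list(point = c(32, 32, 32), dir = c(0, 0, 1))
  vs <- 26.4
  bd <- rep(24, 3)
  cb <- floor(bd / 2)
  # anchors planted exactly at their target radii: zero everywhere
  sol <- data.frame(phi = 0, theta = 0, psi = 0, x = 32 + 10, y = 32,
                    z = 40)
  r_exact <- data.frame(label = c("a", "b"),
                        ax = cb[1] + c(2, -3), ay = cb[2], az = cb[3],
                        radial_nm = (10 + c(2, -3)) * vs / 10)
  rs <- restraint_distances(sol, r_exact, axis, vs, bd)
  expect_equal(rs$mean_nm, 0, tolerance = 1e-9)
  expect_equal(rs$sd_nm, 0, tolerance = 1e-9)
  # single anchor displaced radially by 3 nm: mean = max = 3
  r_off <- data.frame(label = "a", ax = cb[1] + 2, ay = cb[2],
                      az = cb[3], radial_nm = 12 * vs / 10 + 3)
  rs2 <- restraint_distances(sol, r_off, axis, vs, bd)
  expect_equal(rs2$mean_nm, 3, tolerance = 1e-9)
  expect_equal(rs2$max_nm, 3, tolerance = 1e-9)
  # six anchors under a known pose perturbation: hand-computed radii
  set.seed(11)
  anchors <- data.frame(label = letters[1:6],
                        ax = cb[1] + runif(6, -5, 5),
                        ay = cb[2] + runif(6, -5, 5),
                        az = cb[3] + runif(6, -5, 5))
  sol2 <- data.frame(phi = 25, theta = 10, psi = -40, x = 44, y = 30,
                     z = 36)
  R <- euler_to_matrix(25, 10, -40)
  radial <- sapply(1:6, function(i) {
    w <- R %*% (c(anchors$ax[i], anchors$ay[i], anchors$az[i]) - cb) +
      c(44, 30, 36)
    sqrt(sum((w[1:2] - axis$point[1:2])^2)) * vs / 10
  })
  anchors$radial_nm <- radial + c(1, -2, 0.5, 3, -1, 2)
  rs3 <- restraint_distances(sol2, anchors, axis, vs, bd)
  devs <- abs(c(1, -2, 0.5, 3, -1, 2))
  expect_equal(rs3$per_label$deviation_nm, devs, tolerance = 1e-9)
  expect_equal(rs3$mean_nm, mean(devs), tolerance = 1e-9)
  expect_equal(rs3$sd_nm, sd(devs), tolerance = 1e-9)
  expect_equal(rs3$max_label, "d")
  # radial distances are invariant under rotation about the pore axis
  Rz <- euler_to_matrix(73, 0, 0)
  w0 <- c(sol2$x, sol2$y, sol2$z) - axis$point
  sol_rot <- sol2
  ang <- matrix_to_euler(Rz %*% R)
  sol_rot$phi <- ang[1]; sol_rot$theta <- ang[2]; sol_rot$psi <- ang[3]
  pos_rot <- as.numeric(Rz %*% w0) + axis$point
  sol_rot$x <- pos_rot[1]; sol_rot$y <- pos_rot[2]; sol_rot$z <- pos_rot[3]
  rs4 <- restraint_distances(sol_rot, anchors, axis, vs, bd)
  expect_equal(rs4$mean_nm, rs3$mean_nm, tolerance = 1e-9)
  expect_equal(rs4$sd_nm, rs3$sd_nm, tolerance = 1e-9)
  # validation
  expect_error(restraint_distances(sol, r_exact[0, ], axis, vs, bd),
               "empty")
})

test_that("the rank report annotates flags and discriminates restraint-consistent sites", {
  sc <- make_docking_scene()
  axis <- list(point = floor(rep(64, 3) / 2), dir = c(0, 0, 1))
  # truth site and a decoy: the same body docked 45 degrees around the
  # ring scores similarly but violates the radial restraints of the
  # labelled anchors differently when targets are set from the truth
  truth_sol <- data.frame(phi = 0, theta = 0, psi = 0,
                          x = sc$truth_pos[1], y = sc$truth_pos[2],
                          z = sc$truth_pos[3], cc = 0.98, rank = 1)
  cb <- floor(rep(24, 3) / 2)
  set.seed(2)
  anchors <- data.frame(label = paste0("nup", 1:6),
                        ax = cb[1] + runif(6, -4, 4),
                        ay = cb[2] + runif(6, -4, 4),
                        az = cb[3] + runif(6, -4, 4))
  truth_radial <- sapply(1:6, function(i) {
    w <- c(anchors$ax[i], anchors$ay[i], anchors$az[i]) - cb +
      c(truth_sol$x, truth_sol$y, truth_sol$z)
    sqrt(sum((w[1:2] - axis$point[1:2])^2)) * sc$vs / 10
  })
  anchors$radial_nm <- truth_radial
  decoy <- truth_sol
  decoy$x <- sc$truth_pos[1] + 4
  decoy$z <- sc$truth_pos[3] - 5
  decoy$cc <- 0.80
  decoy$rank <- 2
  sols <- rbind(truth_sol, decoy)
  class(sols) <- c("docking_solutions", "data.frame")
  rep_ <- rank_report(sols, map = sc$map, body = sc$body,
                      restraints = anchors, pore_axis = axis, k = 8,
                      density_threshold = 0.2)
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$rank[1], 1)
  expect_gte(rep_$cc[1], max(rep_$cc))
  expect_true(all(c("outside_density", "clash",
                    "restraint_mean_nm") %in% names(rep_)))
  # the restraint-consistent site has the smaller mean deviation
  expect_lt(rep_$restraint_mean_nm[1], rep_$restraint_mean_nm[2])
})
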