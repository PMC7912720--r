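test_that("branch identification labels the canonical Y and is order/direction invariant", {
  net <- canonical_y()
  branches <- list(ba = net$ba, lva = net$left_va, rva = net$right_va)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (pm in perms) for (flip in 0:7) {
    bl <- unname(branches[pm])
    for (k in 1:3)
      if (bitwAnd(flip, 2^(k - 1)) > 0) bl[[k]] <- reverse_centerline(bl[[k]])
    id <- identify_branches(bl)
    expect_equal(id$basilar_tip, c(0, 0, 24))
    expect_equal(id$confluence, c(0, 0, 0))
    ## labels by free-endpoint position, independent of input arrangement
    expect_equal(id$ba$points[nrow(id$ba$points), ], c(0, 0, 24))
    expect_equal(id$left_va$points[1, ], c(12, 3, -20))
    expect_equal(id$right_va$points[1, ], c(-12, 3, -20))
  }
})

test_that("short spurs are pruned and topology errors are reported", {
  net <- canonical_y()
  t <- seq(0, 1, length.out = 6)
  spur <- centerline(cbind(0.7 * t, 0.2 * t, 12 + 0.3 * t), 0.3)
  with_spur <- list(net$ba, net$left_va, net$right_va, spur)
  id <- identify_branches(with_spur, min_branch_length = 3)
  expect_s3_class(id, "vessel_network")
  expect_equal(nrow(id$ba$points), nrow(net$ba$points))

  ## no junction at all
  expect_error(identify_branches(list(net$ba, spur,
                                      straight_centerline(8, 10, origin = c(50, 0, 0)))),
               class = "topology_error")
  ## left/right tie: mirror-symmetric VAs at equal X
  t2 <- seq(1, 0, length.out = 11)
  va1 <- centerline(cbind(0 * t2, 5 * t2, -20 * t2), 1)
  va2 <- centerline(cbind(0 * t2, -5 * t2, -20 * t2), 1)
  expect_error(identify_branches(list(net$ba, va1, va2)), class = "tie_error")
})

test_that("network construction validates landmark coincidence", {
  net <- canonical_y()
  off <- net$ba
  off$points <- off$points + 0.01
  expect_error(vessel_network(net$left_va, net$right_va, off,
                              net$confluence, net$basilar_tip),
               class = "validation_error")
})

test_that("built networks hit their geometric targets (spot check)", {
  tg <- geometry_targets()   # population-mean morphology
  rt <- roundtrip_errors(tg, seed = 11)
  expect_lt(max(abs(rt$rel)), 0.02)
  expect_lt(rt$bend_abs, 0.05)
  expect_identical(rt$record$ba_lean, "left")
  expect_identical(rt$record$dominance, "equal")

  ## straight, torsion-free basilar artery
  tg0 <- geometry_targets(ba_bend = 0, ba_tortuosity = 0)
  net0 <- build_vessel_network(tg0, seed = 2)
  rec0 <- vessel_morphometry(net0)
  expect_lt(rec0$ba_bend_mm, 1e-9)
  expect_lt(rec0$ba_tortuosity_pct, 1e-6)
  expect_identical(rec0$ba_lean, "none")

  ## infeasible requests fail loudly
  expect_error(geometry_targets(ba_tortuosity = 100), class = "validation_error")
  expect_error(build_vessel_network(geometry_targets(ba_bend = 6, ba_tortuosity = 1),
                                    seed = 1),
               class = "infeasible_geometry_error")
  expect_error(build_vessel_network(
    geometry_targets(left_va_torsion = 40, left_va_curvature = 3,
                     left_va_tortuosity = 60), seed = 1),
    class = "infeasible_geometry_error")
})

test_that("perturbation contract: bitwise no-op, spur injection, landmark preservation", {
  net <- build_vessel_network(geometry_targets(), seed = 3)
  expect_identical(perturb_network(net, 0, 0, 0, seed = 9), net)

  ps <- perturb_network(net, 0.02, 0.01, spur_probability = 1, seed = 9)
  expect_s3_class(ps, "polyline_set")
  expect_length(ps, 4L)
  relabeled <- identify_branches(ps, min_branch_length = 3)
  expect_s3_class(relabeled, "vessel_network")
  expect_equal(relabeled$confluence, net$confluence, tolerance = 1e-9)
  expect_equal(relabeled$basilar_tip, net$basilar_tip, tolerance = 1e-9)

  set.seed(31)
  jit <- perturb_network(net, 0.05, 0, 0, seed = 10)
  expect_s3_class(jit, "vessel_network")
  expect_gt(max(abs(jit$ba$points - net$ba$points)), 0.01)
})

test_that("point noise on a straight tube is flattened by smoothing", {
  straight <- vessel_network(
    left_va = straight_centerline(20, 41, 1.2, dir = c(0.5, 0.1, -1)),
    right_va = straight_centerline(20, 41, 1.2, dir = c(-0.5, 0.1, -1)),
    ba = straight_centerline(24, 49, 1.7),
    confluence = c(0, 0, 0), basilar_tip = c(0, 0, 24))
  jit <- perturb_network(straight, noise_sd_point = 0.1, seed = 5)
  rec <- vessel_morphometry(jit)
  expect_lt(rec$ba_tortuosity_pct, 1)
  expect_lt(rec$left_va_tortuosity_pct, 1)
})

test_that("indices are invariant under translation, rotation, scaling and reversal", {
  tg <- geometry_targets()
  net <- build_vessel_network(tg, seed = 6)
  rec <- vessel_morphometry(net)
  metrics <- setdiff(names(rec), c("ba_lean", "dominance"))
  num <- metrics[vapply(rec[metrics], is.numeric, TRUE)]

  transform_net <- function(net, f) {
    vessel_network(
      left_va = centerline(f(net$left_va$points), net$left_va$radii),
      right_va = centerline(f(net$right_va$points), net$right_va$radii),
      ba = centerline(f(net$ba$points), net$ba$radii),
      confluence = drop(f(matrix(net$confluence, 1))),
      basilar_tip = drop(f(matrix(net$basilar_tip, 1))))
  }

  ## translation: every index identical (bend included)
  shift <- c(5.3, -2.1, 7.7)
  rec_t <- vessel_morphometry(transform_net(net, function(p) sweep(p, 2, -shift)))
  for (m in num) expect_equal(rec_t[[m]], rec[[m]], tolerance = 1e-9)

  ## rigid rotation: all indices except the X-referenced bend and lean
  set.seed(77)
  ax <- rnorm(3); R <- vertebrotwin:::rotation_axis_angle(ax, 0.7)
  rec_r <- vessel_morphometry(transform_net(net, function(p) p %*% t(R)))
  for (m in setdiff(num, "ba_bend_mm"))
    expect_equal(rec_r[[m]], rec[[m]], tolerance = 1e-7)

  ## mirror in X: bend magnitude equal, lean flips, left/right labels swap
  mir <- transform_net(net, function(p) p %*% diag(c(-1, 1, 1)))
  mir2 <- vessel_network(left_va = mir$right_va, right_va = mir$left_va,
                         ba = mir$ba, confluence = mir$confluence,
                         basilar_tip = mir$basilar_tip)
  rec_m <- vessel_morphometry(mir2)
  expect_equal(rec_m$ba_bend_mm, rec$ba_bend_mm, tolerance = 1e-9)
  expect_identical(rec_m$ba_lean, "right")
  expect_equal(rec_m$left_va_equivalent_diameter_mm,
               rec$right_va_equivalent_diameter_mm, tolerance = 1e-9)

  ## scaling by s: lengths/diameters/bend x s, areas x s^2, volumes x s^3,
  ## curvature and torsion x 1/s, tortuosity unchanged
  s <- 1.7
  scl <- vessel_network(
    left_va = centerline(net$left_va$points * s, net$left_va$radii * s),
    right_va = centerline(net$right_va$points * s, net$right_va$radii * s),
    ba = centerline(net$ba$points * s, net$ba$radii * s),
    confluence = net$confluence * s, basilar_tip = net$basilar_tip * s)
  rec_s <- vessel_morphometry(scl, spacing = 0.5 * s)
  expect_equal(rec_s$ba_length_mm, rec$ba_length_mm * s, tolerance = 1e-6)
  expect_equal(rec_s$ba_bend_mm, rec$ba_bend_mm * s, tolerance = 1e-6)
  expect_equal(rec_s$ba_mean_area_mm2, rec$ba_mean_area_mm2 * s^2, tolerance = 1e-6)
  expect_equal(rec_s$ba_volume_mm3, rec$ba_volume_mm3 * s^3, tolerance = 1e-6)
  expect_equal(rec_s$left_va_curvature_index_pct,
               rec$left_va_curvature_index_pct / s, tolerance = 1e-6)
  expect_equal(rec_s$left_va_torsion_index_pct,
               rec$left_va_torsion_index_pct / s, tolerance = 1e-4)
  expect_equal(rec_s$ba_tortuosity_pct, rec$ba_tortuosity_pct, tolerance = 1e-6)

  ## reversal of any centerline changes nothing
  revnet <- vessel_network(left_va = reverse_centerline(net$left_va),
                           right_va = net$right_va,
                           ba = reverse_centerline(net$ba),
                           confluence = net$confluence,
                           basilar_tip = net$basilar_tip)
  rec_rev <- vessel_morphometry(revnet)
  for (m in num) expect_equal(rec_rev[[m]], rec[[m]], tolerance = 1e-9)
})

test_that("build and perturb are reproducible from the seed", {
  tg <- geometry_targets()
  n1 <- build_vessel_network(tg, seed = 123)
  n2 <- build_vessel_network(tg, seed = 123)
  expect_identical(n1, n2)
  p1 <- perturb_network(n1, 0.05, 0.02, 0.5, seed = 9)
  p2 <- perturb_network(n1, 0.05, 0.02, 0.5, seed = 9)
  expect_identical(p1, p2)
  n3 <- build_vessel_network(tg, seed = 124)
  expect_false(identical(n1$left_va$points, n3$left_va$points))
})
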