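test_that("centerline constructor enforces its invariants", {
  p <- cbind(0:4, 0, 0)
  expect_s3_class(centerline(p, 1), "centerline")
  expect_error(centerline(p[1:3, ], 1), class = "validation_error")
  expect_error(centerline(p, c(1, 1, 1, 1, -1)), class = "validation_error")
  expect_error(centerline(rbind(p, p[5, ]), 1), class = "validation_error")
  p_bad <- p; p_bad[2, 1] <- NA
  expect_error(centerline(p_bad, 1), class = "validation_error")
})

test_that("arc-length resampling is uniform, endpoint-exact and idempotent", {
  cl <- straight_centerline(24, 100)
  rs <- resample_arclength(cl, 1)
  expect_equal(nrow(rs$points), 25L)
  seg <- diff(cum_arclength(rs))
  expect_lt(max(abs(seg - 1)), 1e-6)
  expect_equal(rs$points[1, ], cl$points[1, ])
  expect_equal(rs$points[25, ], cl$points[100, ])

  arc <- circle_centerline(R = 10, n = 2000, frac = 0.5)
  rs2 <- resample_arclength(arc, 0.1)
  expect_lt(abs(arc_length(rs2) / (pi * 10) - 1), 1e-3)

  smooth <- helix_centerline(n = 2000)
  once <- resample_arclength(smooth, 0.4)
  twice <- resample_arclength(once, 0.4)
  expect_lt(max(abs(once$points - twice$points)), 1e-6)

  expect_error(resample_arclength(cl, 0), class = "validation_error")
  expect_error(resample_arclength(cl, 50), class = "validation_error")
})

test_that("Taubin smoothing fixes straight lines and out-shrinks plain Laplacian", {
  st <- centerline(cbind(seq(0, 10, length.out = 60),
                         seq(0, 5, length.out = 60),
                         seq(0, 2, length.out = 60)), 1)
  sm <- taubin_smooth(st)
  expect_lt(max(abs(sm$points - st$points)), 1e-12)

  circ <- circle_centerline(R = 10, n = 200, frac = 0.95)
  radius_of <- function(cl) mean(sqrt(rowSums(cl$points[, 1:2]^2)))
  r_taubin <- radius_of(taubin_smooth(circ, 0.5, -0.53, 20))
  r_laplace <- radius_of(laplacian_smooth_oracle(circ, 0.5, 20))
  shrink_taubin <- 1 - r_taubin / 10
  shrink_laplace <- 1 - r_laplace / 10
  expect_lt(abs(shrink_taubin), 0.005)
  expect_gt(shrink_laplace, 5 * max(shrink_taubin, 1e-6))

  expect_error(taubin_smooth(circ, 0.5, -0.53, 0), class = "validation_error")
  expect_error(taubin_smooth(circ, 0.5, -0.4, 5), class = "validation_error")
  expect_error(taubin_smooth(circ, 1.2, -1.3, 5), class = "validation_error")
})

test_that("discrete Frenet estimates match closed forms on circle and helix", {
  circ <- circle_centerline(R = 10, n = 200, frac = 0.9)
  fp <- frenet_profile(circ)
  expect_lt(max(abs(fp$curvature - 0.1)) / 0.1, 0.01)
  expect_lt(max(abs(fp$torsion)), 1e-9)

  hel <- helix_centerline(a = 3, b = 1, turns = 2, n = 500)
  fph <- frenet_profile(hel)
  expect_lt(abs(mean(fph$curvature) - 0.3) / 0.3, 0.01)
  expect_lt(abs(mean(fph$torsion) - 0.1) / 0.1, 0.01)

  ## left-handed helix: torsion flips sign
  lh <- centerline(cbind(3 * cos(seq(0, 4 * pi, length.out = 500)),
                         3 * sin(seq(0, 4 * pi, length.out = 500)),
                         -seq(0, 4 * pi, length.out = 500)), 1)
  expect_lt(mean(frenet_profile(lh)$torsion), -0.09)

  ## straight line: zero curvature, degenerate torsion flagged as 0
  st <- straight_centerline(10, 30)
  fs <- frenet_profile(st)
  expect_equal(fs$curvature, rep(0, nrow(fs)))
  expect_equal(fs$torsion, rep(0, nrow(fs)))
  expect_true(all(fs$degenerate))
})

test_that("Frenet estimates agree with the analytic-derivative oracle and converge", {
  ## generic smooth curve (varying curvature/torsion)
  f  <- function(t) c(cos(t) * (2 + 0.5 * cos(3 * t)),
                      sin(t) * (2 + 0.5 * cos(3 * t)), 0.6 * t)
  df <- function(t) c(-sin(t) * (2 + 0.5 * cos(3 * t)) - 1.5 * cos(t) * sin(3 * t),
                      cos(t) * (2 + 0.5 * cos(3 * t)) - 1.5 * sin(t) * sin(3 * t), 0.6)
  h <- 1e-5
  d2f <- function(t) (df(t + h) - df(t - h)) / (2 * h)
  d3f <- function(t) (df(t + h) - 2 * df(t) + df(t - h)) / h^2
  tg <- seq(0.5, 2 * pi - 0.5, length.out = 2000)
  pts <- t(vapply(tg, f, numeric(3)))
  an <- analytic_frenet(f, df, d2f, d3f, tg)
  ## the discrete profile averages over arc length, so weight the
  ## parameter-grid oracle by the local speed |r'(t)|
  speed <- vapply(tg, function(t) sqrt(sum(df(t)^2)), 1)
  k_true <- sum(an$curvature * speed) / sum(speed)
  t_true <- sum(abs(an$torsion) * speed) / sum(speed)
  cl <- resample_arclength(centerline(pts, 1), 0.04)
  fp <- frenet_profile(cl)
  expect_lt(abs(mean(fp$curvature) / k_true - 1), 0.01)
  expect_lt(abs(mean(abs(fp$torsion)) / t_true - 1), 0.02)

  ## Richardson: halving the spacing must shrink the error by >= first order
  err_at <- function(sp) {
    cl <- resample_arclength(centerline(pts, 1), sp)
    fp <- frenet_profile(cl)
    c(abs(mean(fp$curvature) - k_true), abs(mean(abs(fp$torsion)) - t_true))
  }
  e1 <- err_at(0.32); e2 <- err_at(0.16)
  expect_lt(e2[1], e1[1] / 1.8)
  expect_lt(e2[2], e1[2] / 1.8)
})

test_that("geometry indices reproduce closed forms", {
  cyl <- straight_centerline(24, 200, radius = 1.75)
  gi <- geometry_indices(cyl)
  expect_equal(gi$length_mm, 24, tolerance = 1e-9)
  expect_equal(gi$tortuosity_pct, 0, tolerance = 1e-9)
  expect_equal(gi$mean_area_mm2, pi * 1.75^2, tolerance = 1e-9)
  expect_equal(gi$volume_mm3, pi * 1.75^2 * 24, tolerance = 1e-9)
  expect_equal(gi$equivalent_diameter_mm, 3.5, tolerance = 1e-9)

  semi <- resample_arclength(circle_centerline(R = 10, n = 2001, frac = 0.5), 0.05)
  gs <- geometry_indices(semi)
  expect_equal(gs$tortuosity_pct, (1 - 2 / pi) * 100, tolerance = 1e-3)
  expect_equal(gs$chord_over_arc, 2 / pi, tolerance = 1e-5)
})

test_that("basilar bend matches a dense-sampling oracle on a planar arc", {
  ## circular arc (R = 50) bowed toward +X between two Z-axis landmarks
  R <- 50; half_chord <- 12
  th_max <- asin(half_chord / R)
  th <- seq(-th_max, th_max, length.out = 2001)
  pts <- cbind(R * cos(th) - R * cos(th_max), 0, R * sin(th) + half_chord)
  ba <- centerline(pts, 1.7)
  conf <- c(0, 0, 0); tip <- c(0, 0, 2 * half_chord)
  res <- ba_bend(ba, conf, tip)
  ## brute-force oracle: arc-length-uniform dense sampling of |x offsets|
  dense <- resample_arclength(ba, arc_length(ba) / 1e5)
  oracle <- median(abs(dense$points[, 1]))
  expect_equal(res$bend_mm, oracle, tolerance = 1e-3)
  expect_identical(res$lean, "left")

  mir <- centerline(pts %*% diag(c(-1, 1, 1)), 1.7)
  res_m <- ba_bend(mir, conf, tip)
  expect_equal(res_m$bend_mm, res$bend_mm, tolerance = 1e-12)
  expect_identical(res_m$lean, "right")

  st <- straight_centerline(24, 50)
  r0 <- ba_bend(st, c(0, 0, 0), c(0, 0, 24))
  expect_equal(r0$bend_mm, 0)
  expect_identical(r0$lean, "none")

  expect_error(ba_bend(st, c(5, 0, 0), c(0, 0, 24)), class = "landmark_error")
})

test_that("dominance classification follows the strict 0.3 mm rule", {
  r_left <- classify_dominance(2.8, 2.4)
  expect_equal(r_left$va_difference_mm, 0.4)
  expect_identical(r_left$dominance, "left")
  r <- classify_dominance(2.44, 2.36)
  expect_equal(r$va_difference_mm, 0.08)
  expect_identical(r$dominance, "equal")
  ## boundary difference of exactly 0.3 mm is non-dominant
  expect_identical(classify_dominance(2.4, 2.7)$dominance, "equal")
  expect_identical(classify_dominance(2.71, 2.4)$dominance, "left")
  expect_error(classify_dominance(0, 2), class = "validation_error")
})
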