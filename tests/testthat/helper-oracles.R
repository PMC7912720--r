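# Independent oracles and fixture builders shared across tests.

## -- geometric fixtures -------------------------------------------------------

circle_centerline <- function(R = 10, n = 200, frac = 0.9, radius = 1) {
  th <- seq(0, 2 * pi * frac, length.out = n)
  centerline(cbind(R * cos(th), R * sin(th), 0), radius)
}

helix_centerline <- function(a = 3, b = 1, turns = 2, n = 500, radius = 1) {
  th <- seq(0, 2 * pi * turns, length.out = n)
  centerline(cbind(a * cos(th), a * sin(th), b * th), radius)
}

straight_centerline <- function(L = 24, n = 100, radius = 1.75,
                                dir = c(0, 0, 1), origin = c(0, 0, 0)) {
  t <- seq(0, L, length.out = n)
  centerline(sweep(outer(t, dir / sqrt(sum(dir^2))), 2, origin, `+`), radius)
}

## canonical Y network: BA up +Z, VAs coming from below at +/- X
canonical_y <- function(radius = 1.2) {
  ba <- straight_centerline(24, 49, radius)
  t <- seq(0, 1, length.out = 41)
  lva <- centerline(cbind(12 * t, 3 * t, -20 * t)[rev(seq_along(t)), ], radius)
  rva <- centerline(cbind(-12 * t, 3 * t, -20 * t)[rev(seq_along(t)), ], radius)
  vessel_network(left_va = lva, right_va = rva, ba = ba,
                 confluence = c(0, 0, 0), basilar_tip = c(0, 0, 24))
}

## plain lambda-only Laplacian polyline smoother (comparison oracle for Taubin)
laplacian_smooth_oracle <- function(cl, lambda = 0.5, iterations = 20) {
  p <- cl$points
  n <- nrow(p)
  for (it in seq_len(iterations)) {
    umb <- 0.5 * (p[1:(n - 2), ] + p[3:n, ]) - p[2:(n - 1), ]
    p[2:(n - 1), ] <- p[2:(n - 1), ] + lambda * umb
  }
  centerline(p, cl$radii)
}

## analytic-derivative curvature/torsion on a parametric curve (independent
## of the discrete circumcircle estimator)
analytic_frenet <- function(f, df, d2f, d3f, tgrid) {
  k <- t <- numeric(length(tgrid))
  for (i in seq_along(tgrid)) {
    r1 <- df(tgrid[i]); r2 <- d2f(tgrid[i]); r3 <- d3f(tgrid[i])
    cr <- c(r1[2] * r2[3] - r1[3] * r2[2],
            r1[3] * r2[1] - r1[1] * r2[3],
            r1[1] * r2[2] - r1[2] * r2[1])
    k[i] <- sqrt(sum(cr^2)) / sum(r1^2)^1.5
    t[i] <- sum(cr * r3) / sum(cr^2)
  }
  list(curvature = k, torsion = t)
}

## -- twin-model oracles -------------------------------------------------------

## independent per-pair bivariate-normal log-likelihood with a common mean
## profiled by GLS (explicit loops; no sharing with the package internals)
oracle_pair_loglik <- function(y1, y2, zyg, a2, c2, e2) {
  s2 <- a2 + c2 + e2
  num <- 0; den <- 0
  for (i in seq_along(y1)) {
    cz <- if (zyg[i] == "MZ") a2 + c2 else 0.5 * a2 + c2
    Sinv <- solve(matrix(c(s2, cz, cz, s2), 2))
    one <- c(1, 1)
    num <- num + sum(one %*% Sinv %*% c(y1[i], y2[i]))
    den <- den + sum(one %*% Sinv %*% one)
  }
  mu <- num / den
  ll <- 0
  for (i in seq_along(y1)) {
    cz <- if (zyg[i] == "MZ") a2 + c2 else 0.5 * a2 + c2
    S <- matrix(c(s2, cz, cz, s2), 2)
    r <- c(y1[i], y2[i]) - mu
    ll <- ll - log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
      0.5 * drop(r %*% solve(S) %*% r)
  }
  ll
}

## refining grid search over (a2, c2, e2) down to ~0.001 * var(y) resolution
oracle_grid_search <- function(y1, y2, zyg, rounds = 3, width = NULL) {
  vt <- stats::var(c(y1, y2))
  centre <- rep(vt / 3, 3)
  if (is.null(width)) width <- vt
  best <- list(ll = -Inf, par = centre)
  for (r in seq_len(rounds)) {
    gr <- lapply(1:3, function(j)
      seq(max(0, centre[j] - width), centre[j] + width, length.out = 13))
    for (a2 in gr[[1]]) for (c2 in gr[[2]]) for (e2 in gr[[3]]) {
      if (e2 <= 1e-6 * vt) next
      ll <- oracle_pair_loglik(y1, y2, zyg, a2, c2, e2)
      if (ll > best$ll) best <- list(ll = ll, par = c(a2, c2, e2))
    }
    centre <- best$par
    width <- width / 5
  }
  best
}

## simulate phenotype pairs straight from the ACE covariance structure
sim_ace_pairs <- function(n_mz, n_dz, A, C, E, mu = 0, seed = 1) {
  withr::with_seed(seed, {
    zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
    n <- n_mz + n_dz
    w <- ifelse(zyg == "MZ", 1, sqrt(0.5))
    ash <- rnorm(n); au1 <- rnorm(n); au2 <- rnorm(n)
    a1 <- w * ash + sqrt(1 - w^2) * au1
    a2_ <- w * ash + sqrt(1 - w^2) * au2
    cc <- rnorm(n)
    y1 <- mu + sqrt(A) * a1 + sqrt(C) * cc + sqrt(E) * rnorm(n)
    y2 <- mu + sqrt(A) * a2_ + sqrt(C) * cc + sqrt(E) * rnorm(n)
    data.frame(pair_id = sprintf("P%05d", seq_len(n)), zygosity = zyg,
               y1 = y1, y2 = y2)
  })
}

## long (subject-per-row) format for twin_ace()
pairs_to_long <- function(pairs, extra = NULL) {
  long <- data.frame(
    subject_id = sprintf("%s_%d", rep(pairs$pair_id, each = 2), 1:2),
    pair_id = rep(pairs$pair_id, each = 2),
    zygosity = rep(pairs$zygosity, each = 2),
    y = as.vector(rbind(pairs$y1, pairs$y2)))
  long
}

feasible_random_targets <- function() {
  ## physiological ranges; bend/tortuosity jointly drawn so the pair is
  ## buildable, then projected by the package clamp
  clamp_geometry_targets(geometry_targets(
    ba_length = runif(1, 19, 30),
    ba_mean_diameter = runif(1, 2.6, 4.4),
    ba_bend = runif(1, 0, 3),
    ba_tortuosity = runif(1, 5, 12),
    left_va_diameter = runif(1, 1.7, 3.4),
    right_va_diameter = runif(1, 1.7, 3.4),
    left_va_curvature = runif(1, 5, 11),
    right_va_curvature = runif(1, 5, 11),
    left_va_torsion = runif(1, 7, 17),
    right_va_torsion = runif(1, 7, 17),
    left_va_tortuosity = runif(1, 6, 14),
    right_va_tortuosity = runif(1, 6, 14)))
}

roundtrip_errors <- function(tg, seed) {
  net <- build_vessel_network(tg, seed = seed)
  rec <- vessel_morphometry(net)
  rel <- c(
    ba_length = rec$ba_length_mm / tg$ba_length - 1,
    ba_diameter = rec$ba_equivalent_diameter_mm / tg$ba_mean_diameter - 1,
    ba_tortuosity = rec$ba_tortuosity_pct / tg$ba_tortuosity - 1,
    left_va_diameter = rec$left_va_equivalent_diameter_mm / tg$left_va_diameter - 1,
    right_va_diameter = rec$right_va_equivalent_diameter_mm / tg$right_va_diameter - 1,
    left_va_curvature = rec$left_va_curvature_index_pct / tg$left_va_curvature - 1,
    right_va_curvature = rec$right_va_curvature_index_pct / tg$right_va_curvature - 1,
    left_va_torsion = rec$left_va_torsion_index_pct / tg$left_va_torsion - 1,
    right_va_torsion = rec$right_va_torsion_index_pct / tg$right_va_torsion - 1,
    left_va_tortuosity = rec$left_va_tortuosity_pct / tg$left_va_tortuosity - 1,
    right_va_tortuosity = rec$right_va_tortuosity_pct / tg$right_va_tortuosity - 1)
  list(rel = rel, bend_abs = abs(rec$ba_bend_mm - tg$ba_bend), record = rec)
}
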