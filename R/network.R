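#' Labeled vertebrobasilar network
#'
#' Three labeled centerlines — left and right vertebral artery (V4 segment)
#' and basilar artery — plus the vertebrobasilar confluence and the basilar
#' tip as landmarks. The internal frame is patient-LPS-like: +X is patient
#' left, +Z superior. All three centerlines must terminate (or originate) at
#' the confluence within 1e-6 mm and the far BA endpoint must equal the
#' basilar tip.
#'
#' @param left_va,right_va,ba [centerline()] objects.
#' @param confluence,basilar_tip 3D landmark points (mm).
#' @return object of class `vessel_network`.
#' @export
vessel_network <- function(left_va, right_va, ba, confluence, basilar_tip) {
  for (nm in c("left_va", "right_va", "ba"))
    if (!inherits(get(nm), "centerline"))
      stop_named("validation_error", "'%s' must be a centerline", nm)
  confluence <- as.numeric(confluence); basilar_tip <- as.numeric(basilar_tip)
  if (length(confluence) != 3L || length(basilar_tip) != 3L)
    stop_named("validation_error", "landmarks must be 3D points")
  end_dist <- function(cl) {
    p <- cl$points
    min(vnorm(p[1, ] - confluence), vnorm(p[nrow(p), ] - confluence))
  }
  for (nm in c("left_va", "right_va", "ba"))
    if (end_dist(get(nm)) > 1e-6)
      stop_named("validation_error",
                 "branch '%s' does not reach the confluence (off by %g mm)",
                 nm, end_dist(get(nm)))
  bp <- ba$points
  tip_dist <- min(vnorm(bp[1, ] - basilar_tip), vnorm(bp[nrow(bp), ] - basilar_tip))
  if (tip_dist > 1e-6)
    stop_named("validation_error", "basilar tip is not a BA endpoint (off by %g mm)",
               tip_dist)
  structure(list(left_va = left_va, right_va = right_va, ba = ba,
                 confluence = confluence, basilar_tip = basilar_tip),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network>\n")
  for (nm in c("left_va", "right_va", "ba"))
    cat(sprintf("  %-9s %4d points, %6.2f mm\n", nm,
                nrow(x[[nm]]$points), arc_length(x[[nm]])))
  cat(sprintf("  confluence  (%.2f, %.2f, %.2f) mm\n",
              x$confluence[1], x$confluence[2], x$confluence[3]))
  cat(sprintf("  basilar tip (%.2f, %.2f, %.2f) mm\n",
              x$basilar_tip[1], x$basilar_tip[2], x$basilar_tip[3]))
  invisible(x)
}

#' Label the three arteries of a raw polyline network
#'
#' Branches shorter than `min_branch_length` with a free (unshared) endpoint
#' are pruned as reconstruction spurs. The remaining polylines must form a
#' single Y: exactly one point where three branch endpoints coincide — the
#' vertebrobasilar confluence. The basilar artery is the branch whose free
#' endpoint is most superior (+Z); of the two vertebral arteries, the one
#' whose free endpoint has the greater +X (patient-left) coordinate is the
#' left VA. Labels are invariant to the input ordering and to reversal of
#' any polyline; branches are re-oriented so the VAs end at the confluence
#' and the BA starts there.
#'
#' @param polylines a `polyline_set` or plain list of [centerline()]s.
#' @param min_branch_length pruning threshold (mm), default 3.
#' @param tol endpoint-coincidence tolerance (mm).
#' @return a [vessel_network()].
#' @export
identify_branches <- function(polylines, min_branch_length = 3, tol = 1e-6) {
  if (inherits(polylines, "vessel_network"))
    polylines <- list(polylines$left_va, polylines$right_va, polylines$ba)
  branches <- unname(unclass(polylines))
  if (!all(vapply(branches, inherits, TRUE, "centerline")))
    stop_named("validation_error", "polylines must be centerline objects")
  check_scalar(min_branch_length, "min_branch_length", lower = 0)

  junction_of <- function(branches) {
    ends <- do.call(rbind, lapply(branches, function(b)
      rbind(b$points[1, ], b$points[nrow(b$points), ])))
    ## cluster coincident endpoints
    m <- nrow(ends)
    used <- rep(FALSE, m)
    junctions <- list()
    for (i in seq_len(m)) {
      if (used[i]) next
      d <- rownorms(sweep(ends, 2, ends[i, ]))
      grp <- which(d < tol)
      used[grp] <- TRUE
      if (length(grp) >= 3)
        junctions[[length(junctions) + 1L]] <-
          list(point = ends[i, ], degree = length(grp),
               branch = unique((grp + 1L) %/% 2L))
    }
    junctions
  }

  ## prune short spur branches (free endpoint, short) iteratively
  repeat {
    if (length(branches) < 3L)
      stop_named("topology_error", "fewer than 3 branches after pruning")
    juncs <- junction_of(branches)
    at_junction <- function(pt) any(vapply(juncs, function(j)
      vnorm(j$point - pt) < tol, TRUE))
    spur <- NULL
    for (i in seq_along(branches)) {
      b <- branches[[i]]
      p1 <- b$points[1, ]; p2 <- b$points[nrow(b$points), ]
      n_shared <- sum(vapply(branches[-i], function(o) {
        any(rownorms(sweep(rbind(o$points[1, ], o$points[nrow(o$points), ]), 2, p1)) < tol) ||
        any(rownorms(sweep(rbind(o$points[1, ], o$points[nrow(o$points), ]), 2, p2)) < tol)
      }, TRUE))
      free_end <- !(at_junction(p1) && at_junction(p2))
      if (free_end && arc_length(b) < min_branch_length && length(branches) > 3L) {
        spur <- i; break
      }
    }
    if (is.null(spur)) break
    branches <- branches[-spur]
  }
  juncs <- junction_of(branches)
  deg3 <- Filter(function(j) j$degree == 3L, juncs)
  if (length(deg3) == 0L)
    stop_named("topology_error", "no three-way junction found after pruning")
  if (length(deg3) > 1L)
    stop_named("topology_error", "%d three-way junctions found; expected exactly 1",
               length(deg3))
  confluence <- deg3[[1]]$point
  if (length(branches) != 3L)
    stop_named("topology_error", "%d branches attached after pruning; expected 3",
               length(branches))
  ## orient: free endpoint last for identification
  free_end <- t(vapply(branches, function(b) {
    p1 <- b$points[1, ]; p2 <- b$points[nrow(b$points), ]
    if (vnorm(p1 - confluence) < tol) p2
    else if (vnorm(p2 - confluence) < tol) p1
    else stop_named("topology_error", "branch not attached to the confluence")
  }, numeric(3)))
  ba_i <- which.max(free_end[, 3])
  va_i <- setdiff(1:3, ba_i)
  if (abs(free_end[va_i[1], 1] - free_end[va_i[2], 1]) < 1e-6)
    stop_named("tie_error",
               "vertebral free endpoints have equal X; left/right ambiguous")
  left_i <- va_i[which.max(free_end[va_i, 1])]
  right_i <- setdiff(va_i, left_i)
  orient <- function(b, confluence_last) {
    p <- b$points
    at_start <- vnorm(p[1, ] - confluence) < tol
    if (confluence_last && at_start) reverse_centerline(b)
    else if (!confluence_last && !at_start) reverse_centerline(b)
    else b
  }
  ba <- orient(branches[[ba_i]], confluence_last = FALSE)
  vessel_network(
    left_va = orient(branches[[left_i]], confluence_last = TRUE),
    right_va = orient(branches[[right_i]], confluence_last = TRUE),
    ba = ba,
    confluence = confluence,
    basilar_tip = ba$points[nrow(ba$points), ])
}

#' Target geometry for a synthetic vertebrobasilar network
#'
#' Container of the per-subject geometric indices the parametric builder is
#' asked to reproduce. Lengths and diameters in mm, tortuosity and the
#' curvature/torsion indices in percent (mean 1/mm x 100), bend in mm
#' (median X deviation from the confluence-tip chord).
#'
#' @param ba_length,ba_mean_diameter,ba_bend,ba_tortuosity basilar targets.
#' @param left_va_diameter,right_va_diameter VA equivalent diameters (mm).
#' @param left_va_curvature,right_va_curvature mean curvature x 100.
#' @param left_va_torsion,right_va_torsion mean |torsion| x 100.
#' @param left_va_tortuosity,right_va_tortuosity `(1 - chord/arc) * 100`.
#' @return list of class `geometry_targets`.
#' @export
geometry_targets <- function(ba_length = 24.08, ba_mean_diameter = 3.42,
                             ba_bend = 2.57, ba_tortuosity = 6.37,
                             left_va_diameter = 2.44, right_va_diameter = 2.36,
                             left_va_curvature = 7.79, right_va_curvature = 8.10,
                             left_va_torsion = 12.34, right_va_torsion = 12.62,
                             left_va_tortuosity = 11.77, right_va_tortuosity = 11.57) {
  t <- list(ba_length = ba_length, ba_mean_diameter = ba_mean_diameter,
            ba_bend = ba_bend, ba_tortuosity = ba_tortuosity,
            left_va_diameter = left_va_diameter, right_va_diameter = right_va_diameter,
            left_va_curvature = left_va_curvature, right_va_curvature = right_va_curvature,
            left_va_torsion = left_va_torsion, right_va_torsion = right_va_torsion,
            left_va_tortuosity = left_va_tortuosity,
            right_va_tortuosity = right_va_tortuosity)
  for (nm in c("ba_length", "ba_mean_diameter", "left_va_diameter",
               "right_va_diameter"))
    check_scalar(t[[nm]], nm, lower = 1e-6)
  for (nm in c("ba_tortuosity", "left_va_tortuosity", "right_va_tortuosity"))
    check_scalar(t[[nm]], nm, lower = 0, upper = 100 - 1e-9)
  check_scalar(t$ba_bend, "ba_bend", lower = 0)
  for (nm in c("left_va_curvature", "right_va_curvature",
               "left_va_torsion", "right_va_torsion"))
    check_scalar(t[[nm]], nm, lower = 0)
  structure(t, class = "geometry_targets")
}

## median |x| and arc length of the parametric BA curve, measured the same
## way the morphometry engine does (arc-length-uniform resampling)
ba_curve_points <- function(A, B, chord, n = 801L) {
  t <- seq(0, 1, length.out = n)
  cbind(A * sin(pi * t), B * sin(2 * pi * t), chord * t)
}

## bend and arc length of the parametric BA curve as the measurement pipeline
## will see them (0.5 mm arc-uniform resampling + Taubin smoothing), so the
## solved amplitudes round-trip through vessel_morphometry()
ba_curve_stats <- function(A, B, chord, nseg = NULL, measure_spacing = 0.5) {
  cl <- centerline(ba_curve_points(A, B, chord), 1)
  ## pin the segment count (normally round(target_length / spacing)) so the
  ## probe varies smoothly with A and B; a parity jump in the sample count
  ## shifts the discrete median enough to destabilise the root solves
  sp <- if (is.null(nseg)) measure_spacing else arc_length(cl) / nseg
  cl <- resample_arclength(cl, sp)
  cl <- taubin_smooth(cl)
  list(arc = arc_length(cl), bend = stats::median(abs(cl$points[, 1])))
}

## arc-length excess over the target length of the bend-only BA curve at a
## given tortuosity; > 0 means the (bend, tortuosity) pair is infeasible
ba_arc_excess <- function(tort, ba_length, ba_bend) {
  chord <- ba_length * (1 - tort / 100)
  nseg <- max(6L, as.integer(round(ba_length / 0.5)))
  hi <- max(4 * ba_bend, 1)
  while (ba_curve_stats(hi, 0, chord, nseg)$bend < ba_bend && hi < 100 * ba_length)
    hi <- hi * 2
  A <- stats::uniroot(function(a) ba_curve_stats(a, 0, chord, nseg)$bend - ba_bend,
                      c(0, hi), tol = 1e-8)$root
  ba_curve_stats(A, 0, chord, nseg)$arc - ba_length
}

#' Feasibility of combined bend and tortuosity targets
#'
#' A basilar bend of `ba_bend` mm forces a minimum arc-length excess over the
#' chord, i.e. a minimum tortuosity: `min_ba_tortuosity()` returns the
#' smallest tortuosity (percent) compatible with the requested bend and
#' length. `clamp_geometry_targets()` projects a target vector into the
#' feasible region (raising BA tortuosity to the minimum plus `margin`,
#' capping VA tortuosity below its closed-form helix maximum, flooring
#' strictly positive quantities) so that target vectors simulated as
#' unbounded Gaussian phenotypes can always be built.
#'
#' @param ba_length,ba_bend basilar targets (mm).
#' @return minimum feasible BA tortuosity in percent.
#' @export
min_ba_tortuosity <- function(ba_length, ba_bend) {
  check_scalar(ba_length, "ba_length", lower = 1e-6)
  check_scalar(ba_bend, "ba_bend", lower = 0)
  if (ba_bend == 0) return(0)
  excess <- function(tort) ba_arc_excess(tort, ba_length, ba_bend)
  if (excess(0) <= 0) return(0)
  if (excess(60) > 0) return(60)   # no feasible tortuosity below the cap
  stats::uniroot(excess, c(0, 60), tol = 1e-4)$root
}

#' @rdname min_ba_tortuosity
#' @param targets a [geometry_targets()] (or plain list with its fields).
#' @param margin slack (percentage points of tortuosity) kept above the
#'   feasibility boundary.
#' @export
clamp_geometry_targets <- function(targets, margin = 1) {
  t <- unclass(targets)
  t$ba_length <- max(t$ba_length, 8)
  t$ba_mean_diameter <- max(t$ba_mean_diameter, 0.8)
  t$ba_bend <- max(t$ba_bend, 0)
  t$ba_tortuosity <- min(max(t$ba_tortuosity, 0), 40)
  for (nm in c("left_va_diameter", "right_va_diameter"))
    t[[nm]] <- max(t[[nm]], 0.8)
  for (nm in c("left_va_curvature", "right_va_curvature"))
    t[[nm]] <- max(t[[nm]], 2)
  for (nm in c("left_va_torsion", "right_va_torsion"))
    t[[nm]] <- max(t[[nm]], 0)
  ## BA: bend needs enough arc excess. The drawn tortuosity is kept whenever
  ## it is already feasible; otherwise move just inside the feasible band
  ## (which for deep bends is an interior dip, not a half-line)
  if (t$ba_bend > 0 &&
      ba_arc_excess(t$ba_tortuosity, t$ba_length, t$ba_bend) > -1e-3 * t$ba_length) {
    repeat {
      min_tort <- min_ba_tortuosity(t$ba_length, t$ba_bend)
      cand <- min_tort + margin
      if (ba_arc_excess(cand, t$ba_length, t$ba_bend) > -2e-3 * t$ba_length)
        cand <- stats::optimize(ba_arc_excess, c(max(0, min_tort - 2), min_tort + 10),
                                ba_length = t$ba_length, ba_bend = t$ba_bend)$minimum
      if (ba_arc_excess(cand, t$ba_length, t$ba_bend) <= -2e-3 * t$ba_length) break
      t$ba_bend <- t$ba_bend * 0.9   # bend too deep for any tortuosity: shrink it
      if (t$ba_bend < 1e-3) { t$ba_bend <- 0; cand <- max(t$ba_tortuosity, margin); break }
    }
    t$ba_tortuosity <- cand
  }
  ## VA: helix tortuosity is capped at one full turn. If a drawn torsion is
  ## so large relative to the curvature that no usable tortuosity remains,
  ## shrink the torsion target until one does (mirrors the BA bend fallback).
  for (side in c("left", "right")) {
    kappa <- t[[paste0(side, "_va_curvature")]] / 100
    helix_cap <- function(tors_pct) {
      ## the builder inflates effective torsion a few percent to offset
      ## smoothing attenuation; use a 15% safety factor on the helix cap
      tau <- tors_pct / 100 * 1.15
      (1 - tau / sqrt(kappa^2 + tau^2)) * 100
    }
    tkey <- paste0(side, "_va_torsion")
    while (helix_cap(t[[tkey]]) - margin <= 1 && t[[tkey]] > 1e-3)
      t[[tkey]] <- t[[tkey]] * 0.9
    max_tort <- helix_cap(t[[tkey]])
    t[[paste0(side, "_va_tortuosity")]] <-
      min(max(t[[paste0(side, "_va_tortuosity")]], 1), max_tort - margin)
    if (t[[paste0(side, "_va_tortuosity")]] <= 0)
      stop_named("infeasible_geometry_error",
                 "%s VA torsion/curvature leave no feasible tortuosity", side)
  }
  do.call(geometry_targets, t)
}

#' Build a synthetic vertebrobasilar network from geometric targets
#'
#' Constructs a Y-shaped network whose measured indices (via
#' [vessel_morphometry()]) reproduce the targets: the basilar artery is a
#' smooth curve from the confluence to the basilar tip — an X-direction
#' half-sine bump whose amplitude is solved for the target bend, plus a
#' Y-direction full-sine wiggle solved so the arc length (hence tortuosity)
#' matches; the vertebral arteries are circular-helix arcs with closed-form
#' curvature and torsion, swept until the target tortuosity is reached and
#' rigidly placed (which preserves curvature, torsion and tortuosity) so
#' they terminate at the confluence from below and from the respective side.
#'
#' @param targets a [geometry_targets()].
#' @param seed integer seed controlling the random azimuthal spin of each VA.
#' @param spacing sampling step of the generated centerlines (mm).
#' @return a [vessel_network()].
#' @export
build_vessel_network <- function(targets, seed = 1L, spacing = 0.25) {
  stopifnot(inherits(targets, "geometry_targets"))
  check_scalar(seed, "seed", integer = TRUE)
  ## --- basilar artery -------------------------------------------------------
  L <- targets$ba_length
  chord <- L * (1 - targets$ba_tortuosity / 100)
  A <- 0; B <- 0
  nseg_m <- max(6L, as.integer(round(L / 0.5)))   # measurement discretisation
  if (targets$ba_bend > 0) {
    f_bend <- function(A) ba_curve_stats(A, B, chord, nseg_m)$bend - targets$ba_bend
    hi <- max(4 * targets$ba_bend, 1)
    while (f_bend(hi) < 0 && hi < 100 * L) hi <- hi * 2
    solve_A <- function(B) stats::uniroot(
      function(a) ba_curve_stats(a, B, chord, nseg_m)$bend - targets$ba_bend,
      c(0, hi), tol = 1e-10)$root
    ## nested solve: inner root gives the bend amplitude A for any wiggle B,
    ## outer root picks B so the arc length (hence tortuosity) also matches
    arc_at <- function(B) {
      A <- solve_A(B)
      ba_curve_stats(A, B, chord, nseg_m)$arc
    }
    g0 <- arc_at(0)
    if (g0 > L * 1.02)
      stop_named("infeasible_geometry_error",
                 "BA bend %.2f mm needs arc %.2f mm > target length %.2f mm (tortuosity too small)",
                 targets$ba_bend, g0, L)
    if (g0 < L) {
      bhi <- max(1, L - chord)
      while (arc_at(bhi) < L && bhi < 100 * L) bhi <- bhi * 2
      B <- stats::uniroot(function(b) arc_at(b) - L, c(0, bhi), tol = 1e-8)$root
    }                                      # else: boundary case, bend wins
    A <- solve_A(B)
  } else if (targets$ba_tortuosity > 0) {
    bhi <- max(1, L - chord)
    while (ba_curve_stats(0, bhi, chord, nseg_m)$arc < L && bhi < 100 * L) bhi <- bhi * 2
    B <- stats::uniroot(function(b) ba_curve_stats(0, b, chord, nseg_m)$arc - L,
                        c(0, bhi), tol = 1e-10)$root
  }
  n_ba <- max(9L, as.integer(ceiling(L / spacing)) + 1L)
  ## store the same parametric chain the solver probed, so the measurement
  ## pipeline sees exactly the solved geometry
  ba_pts <- ba_curve_points(A, B, chord)
  ba <- centerline(ba_pts, targets$ba_mean_diameter / 2)
  ba <- resample_arclength(ba, arc_length(ba) / (n_ba - 1L))
  confluence <- c(0, 0, 0)
  basilar_tip <- c(0, 0, chord)
  ## --- vertebral arteries ---------------------------------------------------
  mk_va <- function(curv_pct, tors_pct, tort_pct, diameter, side, spin) {
    kappa <- curv_pct / 100
    tau <- tors_pct / 100
    if (kappa <= 0)
      stop_named("infeasible_geometry_error", "VA curvature must be > 0")
    helix_geom <- function(k_eff, t_eff) {
      a <- k_eff / (k_eff^2 + t_eff^2)
      b <- t_eff / (k_eff^2 + t_eff^2)
      helix_tort <- function(Theta) {
        arc <- Theta * sqrt(a^2 + b^2)
        ch <- sqrt(2 * a^2 * (1 - cos(Theta)) + b^2 * Theta^2)
        (1 - ch / arc) * 100
      }
      max_tort <- helix_tort(2 * pi - 1e-9)
      if (tort_pct >= max_tort)
        stop_named("infeasible_geometry_error",
                   "VA tortuosity %.2f%% infeasible for curvature %.2f%%/torsion %.2f%% (max %.2f%%)",
                   tort_pct, curv_pct, tors_pct, max_tort)
      if (tort_pct <= helix_tort(1e-6))
        stop_named("infeasible_geometry_error",
                   "VA tortuosity %.3f%% too small for a curved vertebral artery",
                   tort_pct)
      Theta <- stats::uniroot(function(th) helix_tort(th) - tort_pct,
                              c(1e-6, 2 * pi - 1e-9), tol = 1e-12)$root
      list(a = a, b = b, Theta = Theta, arc = Theta * sqrt(a^2 + b^2))
    }
    helix_pts <- function(g, n = 1001L) {
      th <- seq(0, g$Theta, length.out = n)
      cbind(g$a * cos(th), g$a * sin(th), g$b * th)
    }
    ## calibrate the underlying helix so the *measured* (resampled + Taubin
    ## smoothed) curvature/torsion indices land on the targets; smoothing
    ## attenuates discrete torsion by a few percent otherwise
    k_eff <- kappa; t_eff <- tau
    for (it in 1:3) {
      g <- helix_geom(k_eff, t_eff)
      probe <- centerline(helix_pts(g, 1001L), 1)
      probe <- taubin_smooth(resample_arclength(probe, 0.5))
      fpm <- frenet_profile(probe)
      k_meas <- mean(fpm$curvature)
      t_meas <- mean(abs(fpm$torsion))
      if (k_meas > 0) k_eff <- k_eff * kappa / k_meas
      if (tau > 0 && t_meas > 0) t_eff <- t_eff * tau / t_meas
    }
    g <- helix_geom(k_eff, t_eff)
    arc <- g$arc
    if (arc < 8 * spacing)
      stop_named("infeasible_geometry_error",
                 "VA arc %.2f mm too short for a %g mm sampling step", arc, spacing)
    n_va <- max(9L, as.integer(ceiling(arc / spacing)) + 1L)
    pts <- helix_pts(g)
    ## rigid placement: helix end (th = Theta) at the confluence, chord
    ## direction pointing down and laterally, with a random spin about the
    ## chord so repeated subjects differ
    pts <- sweep(pts, 2, pts[nrow(pts), ])
    u <- pts[1, ] / vnorm(pts[1, ])          # confluence -> free end
    dirn <- c(side * 0.55, 0.25, -1)
    dirn <- dirn / vnorm(dirn)
    R1 <- rotation_between(u, dirn)
    R2 <- rotation_axis_angle(dirn, spin)
    pts <- t(R2 %*% R1 %*% t(pts))
    cl <- centerline(pts, diameter / 2)
    resample_arclength(cl, arc_length(cl) / (n_va - 1L))
  }
  spins <- with_seed(split_seed(seed, "va_spin"), stats::runif(2, 0, 2 * pi))
  left_va <- mk_va(targets$left_va_curvature, targets$left_va_torsion,
                   targets$left_va_tortuosity, targets$left_va_diameter,
                   side = +1, spin = spins[1])
  right_va <- mk_va(targets$right_va_curvature, targets$right_va_torsion,
                    targets$right_va_tortuosity, targets$right_va_diameter,
                    side = -1, spin = spins[2])
  vessel_network(left_va, right_va, ba, confluence, basilar_tip)
}

#' Perturb a network with measurement-like noise and reconstruction spurs
#'
#' Jitters point coordinates and radii with independent Gaussian noise and,
#' with probability `spur_probability`, attaches one short spurious branch
#' (shorter than the default pruning threshold) at a random interior point,
#' emulating reconstruction artifacts. The confluence and basilar-tip
#' landmark points themselves are left untouched so the network invariants
#' still hold.
#'
#' @param network a [vessel_network()].
#' @param noise_sd_point coordinate jitter SD (mm), >= 0.
#' @param noise_sd_radius radius jitter SD (mm), >= 0.
#' @param spur_probability probability of attaching one spur branch.
#' @param seed integer seed.
#' @return a [vessel_network()] if no spur was added, otherwise an unlabeled
#'   `polyline_set` (4 branches) to be re-labeled by [identify_branches()].
#' @export
perturb_network <- function(network, noise_sd_point = 0, noise_sd_radius = 0,
                            spur_probability = 0, seed = 1L) {
  stopifnot(inherits(network, "vessel_network"))
  check_scalar(noise_sd_point, "noise_sd_point", lower = 0)
  check_scalar(noise_sd_radius, "noise_sd_radius", lower = 0)
  check_fraction(spur_probability, "spur_probability")
  if (noise_sd_point == 0 && noise_sd_radius == 0 && spur_probability == 0)
    return(network)
  with_seed(split_seed(seed, "perturb"), {
    jitter_cl <- function(cl, protect) {
      p <- cl$points; r <- cl$radii
      n <- nrow(p)
      if (noise_sd_point > 0) {
        noise <- matrix(stats::rnorm(3 * n, 0, noise_sd_point), n, 3)
        noise[protect, ] <- 0
        p <- p + noise
      }
      if (noise_sd_radius > 0)
        r <- pmax(r + stats::rnorm(n, 0, noise_sd_radius), 0.05)
      centerline(p, r)
    }
    landmark_ends <- function(cl) {
      n <- nrow(cl$points)
      ends <- c(1L, n)
      is_lm <- vapply(ends, function(i)
        vnorm(cl$points[i, ] - network$confluence) < 1e-6 ||
        vnorm(cl$points[i, ] - network$basilar_tip) < 1e-6, TRUE)
      ends[is_lm]
    }
    lv <- jitter_cl(network$left_va, protect = landmark_ends(network$left_va))
    rv <- jitter_cl(network$right_va, protect = landmark_ends(network$right_va))
    ba <- jitter_cl(network$ba, protect = landmark_ends(network$ba))
    out <- vessel_network(lv, rv, ba, network$confluence, network$basilar_tip)
    if (spur_probability > 0 && stats::runif(1) < spur_probability) {
      host <- sample(c("left_va", "right_va", "ba"), 1)
      hp <- out[[host]]$points
      at <- sample(2:(nrow(hp) - 1L), 1)
      dirn <- stats::rnorm(3); dirn <- dirn / vnorm(dirn)
      len <- stats::runif(1, 0.5, 2.0)   # below the 3 mm pruning default
      t <- seq(0, 1, length.out = 8L)
      spur <- centerline(hp[rep(at, 8L), ] + outer(t * len, dirn),
                         pmax(out[[host]]$radii[at] * (1 - t * 0.5), 0.1))
      return(structure(list(left_va = out$left_va, right_va = out$right_va,
                            ba = out$ba, spur = spur), class = "polyline_set"))
    }
    out
  })
}

#' Full morphometry of a labeled vertebrobasilar network
#'
#' The measurement pipeline applied to each vessel: resample at uniform
#' arc-length `spacing`, Taubin-smooth, then compute all geometric indices
#' ([geometry_indices()]), the basilar bend and lean ([ba_bend()]) and the
#' vertebral dominance ([classify_dominance()] on the VA equivalent
#' diameters). Unlabeled polyline sets are first labeled with
#' [identify_branches()].
#'
#' @param network a [vessel_network()] or unlabeled `polyline_set`.
#' @param spacing resampling step (mm), default 0.5.
#' @param lambda_pass,mu_pass,smooth_iterations Taubin parameters.
#' @param min_branch_length spur-pruning threshold (mm) for unlabeled input.
#' @param dominance_threshold VA dominance threshold (mm), default 0.3.
#' @return one-row data.frame (a morphometry record): per-vessel indices
#'   prefixed `ba_`, `left_va_`, `right_va_`, plus `ba_bend_mm`, `ba_lean`,
#'   `va_difference_mm`, `dominance`.
#' @export
vessel_morphometry <- function(network, spacing = 0.5,
                               lambda_pass = 0.5, mu_pass = -0.53,
                               smooth_iterations = 20L,
                               min_branch_length = 3,
                               dominance_threshold = 0.3) {
  if (!inherits(network, "vessel_network"))
    network <- identify_branches(network, min_branch_length = min_branch_length)
  prep <- function(cl) {
    cl <- resample_arclength(cl, spacing)
    taubin_smooth(cl, lambda_pass, mu_pass, smooth_iterations)
  }
  vessels <- list(ba = prep(network$ba),
                  left_va = prep(network$left_va),
                  right_va = prep(network$right_va))
  rec <- do.call(cbind, lapply(names(vessels), function(nm) {
    gi <- geometry_indices(vessels[[nm]])
    names(gi) <- paste0(nm, "_", names(gi))
    gi
  }))
  bend <- ba_bend(vessels$ba, network$confluence, network$basilar_tip)
  dom <- classify_dominance(rec$left_va_equivalent_diameter_mm,
                            rec$right_va_equivalent_diameter_mm,
                            threshold = dominance_threshold)
  cbind(rec,
        data.frame(ba_bend_mm = bend$bend_mm, ba_lean = bend$lean,
                   va_difference_mm = dom$va_difference_mm,
                   dominance = dom$dominance,
                   stringsAsFactors = FALSE))
}
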