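#' Vessel centerline objects
#'
#' A centerline is an ordered 3D polyline with a per-point
#' maximum-inscribed-sphere radius, the atomic object of vessel morphometry.
#' Coordinates and radii are in millimetres.
#'
#' @param points numeric matrix, n x 3, ordered 3D coordinates (mm).
#' @param radii numeric vector of length n, per-point radius (mm), all > 0.
#' @return An object of class `centerline`: a list with elements `points`
#'   and `radii`.
#' @examples
#' theta <- seq(0, pi, length.out = 100)
#' cl <- centerline(cbind(10 * cos(theta), 10 * sin(theta), 0), rep(1.2, 100))
#' arc_length(cl)
#' @export
centerline <- function(points, radii) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop_named("validation_error", "points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 4L)
    stop_named("validation_error", "a centerline needs at least 4 points, got %d", n)
  if (!all(is.finite(points)))
    stop_named("validation_error", "non-finite coordinates in centerline")
  if (length(radii) == 1L) radii <- rep(as.numeric(radii), n)
  radii <- as.numeric(radii)
  if (length(radii) != n)
    stop_named("validation_error", "radii length (%d) != point count (%d)", length(radii), n)
  if (!all(is.finite(radii)) || any(radii <= 0))
    stop_named("validation_error", "radii must be finite and > 0")
  seg <- rownorms(points[-1, , drop = FALSE] - points[-n, , drop = FALSE])
  if (any(seg == 0))
    stop_named("validation_error", "consecutive duplicate points in centerline")
  structure(list(points = points, radii = radii), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline: %d points, length %.2f mm, mean radius %.3f mm>\n",
              nrow(x$points), arc_length(x), mean(x$radii)))
  invisible(x)
}

#' @export
length.centerline <- function(x) nrow(x$points)

#' Polyline arc length and cumulative arc length
#'
#' @param c a [centerline()].
#' @return `arc_length()`: total length in mm; `cum_arclength()`: vector of
#'   cumulative arc lengths starting at 0.
#' @export
arc_length <- function(c) {
  p <- c$points
  sum(rownorms(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]))
}

#' @rdname arc_length
#' @export
cum_arclength <- function(c) {
  p <- c$points
  c(0, cumsum(rownorms(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])))
}

#' Reverse the point order of a centerline
#' @param c a [centerline()].
#' @export
reverse_centerline <- function(c) {
  centerline(c$points[rev(seq_len(nrow(c$points))), , drop = FALSE], rev(c$radii))
}

#' Resample a centerline at uniform arc-length spacing
#'
#' Points are placed equally spaced in arc length by linear interpolation
#' along the polyline; endpoints are preserved exactly and radii are linearly
#' interpolated in arc length. Uniform spacing is a prerequisite for stable
#' discrete Frenet estimates.
#'
#' @param c a [centerline()].
#' @param spacing target spacing (mm), > 0 and < total length. The realised
#'   spacing is the total length divided by the rounded number of segments, so
#'   endpoints are kept exact.
#' @return a resampled [centerline()].
#' @export
resample_arclength <- function(c, spacing) {
  stopifnot(inherits(c, "centerline"))
  L <- arc_length(c)
  check_scalar(spacing, "spacing", lower = .Machine$double.eps)
  if (spacing >= L)
    stop_named("validation_error", "spacing %g mm >= centerline length %g mm", spacing, L)
  s <- cum_arclength(c)
  nseg <- max(3L, as.integer(round(L / spacing)))
  target <- seq(0, L, length.out = nseg + 1L)
  px <- stats::approx(s, c$points[, 1], xout = target, ties = "ordered")$y
  py <- stats::approx(s, c$points[, 2], xout = target, ties = "ordered")$y
  pz <- stats::approx(s, c$points[, 3], xout = target, ties = "ordered")$y
  r  <- stats::approx(s, c$radii,       xout = target, ties = "ordered")$y
  pts <- cbind(px, py, pz, deparse.level = 0)
  pts[1, ] <- c$points[1, ]
  pts[nrow(pts), ] <- c$points[nrow(c$points), ]
  centerline(pts, r)
}

#' Taubin lambda/mu smoothing of a polyline
#'
#' Two-pass umbrella-weighted Laplacian smoothing: a shrinking step with
#' factor `lambda_pass` followed by an inflating step with negative factor
#' `mu_pass`, which limits the shrinkage of plain Laplacian smoothing.
#' Endpoints are fixed. The umbrella vector at each interior point is
#' projected onto the local normal plane (the tangential component is
#' removed), so points do not slide along the curve and a straight polyline
#' is an exact fixed point.
#'
#' @param c a [centerline()].
#' @param lambda_pass positive smoothing factor in (0, 1).
#' @param mu_pass negative inflation factor, `mu_pass < -lambda_pass`.
#' @param iterations number of lambda+mu double passes, >= 1.
#' @return smoothed [centerline()] with identical point count and radii.
#' @references Taubin, G. (1995) A signal processing approach to fair
#'   surface design.
#' @export
taubin_smooth <- function(c, lambda_pass = 0.5, mu_pass = -0.53, iterations = 20L) {
  stopifnot(inherits(c, "centerline"))
  check_scalar(lambda_pass, "lambda_pass", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(mu_pass, "mu_pass", upper = -lambda_pass)
  check_scalar(iterations, "iterations", lower = 1, integer = TRUE)
  p <- c$points
  n <- nrow(p)
  if (n < 3L) return(c)
  idx <- 2:(n - 1L)
  step <- function(p, w) {
    umb <- 0.5 * (p[idx - 1L, , drop = FALSE] + p[idx + 1L, , drop = FALSE]) -
      p[idx, , drop = FALSE]
    tang <- p[idx + 1L, , drop = FALSE] - p[idx - 1L, , drop = FALSE]
    tl <- rownorms(tang)
    tl[tl == 0] <- 1
    tang <- tang / tl
    umb <- umb - tang * rowSums(umb * tang)
    p[idx, ] <- p[idx, , drop = FALSE] + w * umb
    p
  }
  for (i in seq_len(iterations)) {
    p <- step(p, lambda_pass)
    p <- step(p, mu_pass)
  }
  centerline(p, c$radii)
}

#' Discrete Frenet curvature and torsion profile
#'
#' Curvature at each interior point is the inverse circumradius of the
#' circle through the point and its two neighbours (the local osculating
#' circle). Torsion is the signed dihedral angle between consecutive
#' osculating planes divided by the arc step, positive for a right-handed
#' helix. Boundary points carry no estimate and are excluded; at a collinear
#' triple curvature is 0 and torsion is undefined there (returned as 0 and
#' flagged in the `degenerate` column).
#'
#' @param c a [centerline()], ideally resampled to uniform spacing; >= 5 points.
#' @return a data.frame with one row per interior point (indices
#'   `2:(n-1)` of the input): `index`, `arclength` (mm), `curvature` (1/mm),
#'   `torsion` (1/mm), `degenerate` (logical).
#' @examples
#' th <- seq(0, 4 * pi, length.out = 500)
#' helix <- centerline(cbind(3 * cos(th), 3 * sin(th), th), 1)
#' fp <- frenet_profile(helix)
#' c(mean(fp$curvature), mean(fp$torsion))  # ~ 0.3, 0.1
#' @export
frenet_profile <- function(c) {
  stopifnot(inherits(c, "centerline"))
  p <- c$points
  n <- nrow(p)
  if (n < 5L)
    stop_named("validation_error", "frenet_profile needs >= 5 points, got %d", n)
  a <- p[1:(n - 2), , drop = FALSE]   # p_{i-1}
  b <- p[2:(n - 1), , drop = FALSE]   # p_i
  d <- p[3:n,       , drop = FALSE]   # p_{i+1}
  e1 <- b - a; e2 <- d - b; e3 <- d - a
  l1 <- rownorms(e1); l2 <- rownorms(e2); l3 <- rownorms(e3)
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- rownorms(cr)                       # 2 * triangle area
  kappa <- 2 * area2 / (l1 * l2 * l3)         # 1/R of circumscribed circle
  degen_k <- area2 < 1e-12 * l1 * l2
  kappa[degen_k] <- 0
  ## osculating plane normals (unnormalised = cr); torsion from consecutive planes
  m <- n - 2L                                  # number of interior points
  tau <- rep(0, m)
  degen_t <- rep(FALSE, m)
  if (m >= 2L) {
    n1 <- cr[1:(m - 1), , drop = FALSE]
    n2 <- cr[2:m,       , drop = FALSE]
    ln1 <- rownorms(n1); ln2 <- rownorms(n2)
    ok <- ln1 > 1e-300 & ln2 > 1e-300 & !degen_k[1:(m - 1)] & !degen_k[2:m]
    ## shared edge direction p_{i+1} - p_i orients the sign of the dihedral
    edge <- e2[1:(m - 1), , drop = FALSE]
    le <- rownorms(edge)
    cx <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
                n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
                n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
    sin_t <- rowSums(cx * edge) / (ln1 * ln2 * le)
    cos_t <- rowSums(n1 * n2) / (ln1 * ln2)
    ang <- atan2(sin_t, cos_t)
    tau_mid <- ifelse(ok & le > 0, ang / le, 0)
    ## assign the inter-plane estimate to the first of the two points; the last
    ## interior point inherits its neighbour's value so lengths line up
    tau[1:(m - 1)] <- tau_mid
    tau[m] <- tau[m - 1]
    degen_t[1:(m - 1)] <- !ok
    degen_t[m] <- degen_t[m - 1]
  }
  s <- cum_arclength(c)
  data.frame(index = 2:(n - 1L), arclength = s[2:(n - 1L)],
             curvature = kappa, torsion = tau,
             degenerate = degen_k | degen_t)
}

#' Per-vessel geometric indices
#'
#' Computes the morphological indices of a single vessel from its (smoothed,
#' uniformly resampled) centerline:
#' \describe{
#'   \item{length_mm}{polyline arc length.}
#'   \item{tortuosity_pct}{`(1 - chord/arc) * 100`; the raw chord/arc ratio is
#'     also returned as `chord_over_arc` since the field uses both conventions.}
#'   \item{curvature_index_pct}{mean pointwise curvature (1/mm) times 100.}
#'   \item{torsion_index_pct}{mean absolute pointwise torsion (1/mm) times 100.}
#'   \item{mean_area_mm2}{arc-length-weighted mean of the cross-sectional area
#'     `pi * r^2`.}
#'   \item{equivalent_diameter_mm}{`2 * sqrt(mean_area / pi)`.}
#'   \item{volume_mm3}{trapezoidal integral of the area along arc length.}
#' }
#'
#' @param c a [centerline()].
#' @return one-row data.frame with the fields above.
#' @export
geometry_indices <- function(c) {
  stopifnot(inherits(c, "centerline"))
  p <- c$points
  n <- nrow(p)
  s <- cum_arclength(c)
  L <- s[n]
  chord <- vnorm(p[n, ] - p[1, ])
  fp <- frenet_profile(c)
  area <- pi * c$radii^2
  ds <- diff(s)
  mean_area <- sum((area[-1] + area[-n]) / 2 * ds) / L
  volume <- sum((area[-1] + area[-n]) / 2 * ds)
  data.frame(
    length_mm = L,
    tortuosity_pct = (1 - chord / L) * 100,
    chord_over_arc = chord / L,
    curvature_index_pct = mean(fp$curvature) * 100,
    torsion_index_pct = mean(abs(fp$torsion)) * 100,
    mean_area_mm2 = mean_area,
    equivalent_diameter_mm = 2 * sqrt(mean_area / pi),
    volume_mm3 = volume
  )
}

#' Basilar artery bend relative to the confluence-tip chord
#'
#' The confluence of the two vertebral arteries and the basilar tip are
#' joined by a straight line; each centerline point is projected
#' perpendicularly onto that chord and its signed X offset
#' (`point_x - chord_x` at the foot of the projection) is recorded. The bend
#' is the median absolute offset; the lean is the sign of the median signed
#' offset, with +X read as patient-left.
#'
#' @param ba basilar [centerline()], running between the two landmarks.
#' @param confluence,basilar_tip 3D landmark points (mm).
#' @param tol landmark-match tolerance (mm).
#' @return list with `bend_mm`, `lean` ("left", "right" or "none") and
#'   `median_signed_mm`.
#' @export
ba_bend <- function(ba, confluence, basilar_tip, tol = 1e-6) {
  stopifnot(inherits(ba, "centerline"))
  p <- ba$points
  n <- nrow(p)
  ends_ok <- (vnorm(p[1, ] - confluence) < tol && vnorm(p[n, ] - basilar_tip) < tol) ||
             (vnorm(p[n, ] - confluence) < tol && vnorm(p[1, ] - basilar_tip) < tol)
  if (!ends_ok)
    stop_named("landmark_error",
               "basilar centerline endpoints do not coincide with the landmarks")
  u <- basilar_tip - confluence
  lu <- vnorm(u)
  if (lu < tol) stop_named("landmark_error", "confluence and basilar tip coincide")
  u <- u / lu
  rel <- sweep(p, 2, confluence)
  t_ <- as.numeric(rel %*% u)
  chord_x <- confluence[1] + t_ * u[1]
  offset <- p[, 1] - chord_x
  med_abs <- stats::median(abs(offset))
  med_signed <- stats::median(offset)
  lean <- if (abs(med_signed) <= 1e-9) "none" else if (med_signed > 0) "left" else "right"
  list(bend_mm = med_abs, lean = lean, median_signed_mm = med_signed)
}

#' Vertebral artery dominance from diameters
#'
#' A side is dominant when its diameter exceeds the other side's by strictly
#' more than `threshold` (default 0.3 mm); a difference at or below the
#' threshold is classified "equal".
#'
#' @param d_left,d_right vertebral artery diameters (mm), > 0.
#' @param threshold dominance threshold (mm).
#' @return list with `va_difference_mm` = |d_left - d_right| and
#'   `dominance` in {"left", "right", "equal"}.
#' @examples
#' classify_dominance(2.8, 2.4)   # left dominant
#' classify_dominance(2.44, 2.36) # equal
#' @export
classify_dominance <- function(d_left, d_right, threshold = 0.3) {
  check_scalar(d_left, "d_left", lower = .Machine$double.eps)
  check_scalar(d_right, "d_right", lower = .Machine$double.eps)
  check_scalar(threshold, "threshold", lower = 0)
  diffr <- d_left - d_right
  eps <- 1e-12   # a boundary-exact difference is non-dominant
  dominance <- if (diffr > threshold + eps) "left" else
    if (-diffr > threshold + eps) "right" else "equal"
  list(va_difference_mm = abs(diffr), dominance = dominance)
}
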