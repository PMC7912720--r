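#' Triangulated tube surface around a centerline
#'
#' Sweeps a circle of the local radius along the centerline using
#' parallel-transport (rotation-minimising) frames, producing a watertight
#' triangulated surface with fan-capped ends. Used as an independent
#' geometric oracle for the centerline-integral vessel volume and as mesh
#' export for visualisation.
#'
#' @param c a [centerline()].
#' @param circumferential_segments number of vertices per cross-section ring
#'   (>= 8).
#' @return list of class `tube_mesh` with `vertices` (m x 3) and `faces`
#'   (k x 3 integer, 1-based, outward-oriented).
#' @seealso [mesh_volume()], [write_stl()], [write_obj()]
#' @export
tube_mesh <- function(c, circumferential_segments = 64L) {
  stopifnot(inherits(c, "centerline"))
  ns <- as.integer(check_scalar(circumferential_segments, "circumferential_segments",
                                lower = 8, integer = TRUE))
  p <- c$points
  n <- nrow(p)
  fp <- frenet_profile(c)
  ds <- diff(cum_arclength(c))
  ## self-intersection guard: radius must stay below local curvature radius
  kmax <- max(fp$curvature)
  if (kmax > 0 && max(c$radii) >= 1 / kmax)
    stop_named("self_intersection_error",
               "tube radius %.3f mm >= local curvature radius %.3f mm",
               max(c$radii), 1 / kmax)
  ## parallel transport frames
  tang <- matrix(0, n, 3)
  tang[1, ] <- p[2, ] - p[1, ]
  tang[n, ] <- p[n, ] - p[n - 1, ]
  tang[2:(n - 1), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
  tang <- tang / rownorms(tang)
  normal <- matrix(0, n, 3)
  ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v0 <- ref - sum(ref * tang[1, ]) * tang[1, ]
  normal[1, ] <- v0 / vnorm(v0)
  for (i in 2:n) {
    R <- rotation_between(tang[i - 1, ], tang[i, ])
    normal[i, ] <- as.numeric(R %*% normal[i - 1, ])
    normal[i, ] <- normal[i, ] - sum(normal[i, ] * tang[i, ]) * tang[i, ]
    normal[i, ] <- normal[i, ] / vnorm(normal[i, ])
  }
  binorm <- cbind(tang[, 2] * normal[, 3] - tang[, 3] * normal[, 2],
                  tang[, 3] * normal[, 1] - tang[, 1] * normal[, 3],
                  tang[, 1] * normal[, 2] - tang[, 2] * normal[, 1])
  phi <- 2 * pi * (0:(ns - 1)) / ns
  verts <- matrix(0, n * ns + 2L, 3)
  for (i in 1:n) {
    ring <- p[rep(i, ns), ] +
      c$radii[i] * (outer(cos(phi), normal[i, ]) + outer(sin(phi), binorm[i, ]))
    verts[((i - 1) * ns + 1):(i * ns), ] <- ring
  }
  c1 <- n * ns + 1L  # start cap centre
  c2 <- n * ns + 2L  # end cap centre
  verts[c1, ] <- p[1, ]
  verts[c2, ] <- p[n, ]
  ## side quads -> two triangles, oriented outward
  faces <- vector("list", n - 1L + 2L)
  for (i in 1:(n - 1)) {
    a <- (i - 1) * ns + (1:ns)
    b <- (i - 1) * ns + c(2:ns, 1)
    a2 <- a + ns
    b2 <- b + ns
    faces[[i]] <- rbind(cbind(a, b, a2), cbind(b, b2, a2))
  }
  ring1 <- 1:ns
  faces[[n]] <- cbind(ring1[c(2:ns, 1)], ring1, rep(c1, ns))
  ringN <- (n - 1) * ns + (1:ns)
  faces[[n + 1]] <- cbind(ringN, ringN[c(2:ns, 1)], rep(c2, ns))
  structure(list(vertices = verts, faces = do.call(rbind, faces)),
            class = "tube_mesh")
}

#' Volume enclosed by a watertight triangle mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes
#' `det(v1, v2, v3) / 6` over all outward-oriented faces.
#'
#' @param mesh a `tube_mesh` (or any list with `vertices` and `faces`).
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  cx <- cbind(b[, 2] * d[, 3] - b[, 3] * d[, 2],
              b[, 3] * d[, 1] - b[, 1] * d[, 3],
              b[, 1] * d[, 2] - b[, 2] * d[, 1])
  sum(rowSums(a * cx)) / 6
}

#' Write a triangle mesh to binary STL or Wavefront OBJ
#'
#' @param mesh a `tube_mesh`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- raw(80)
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nf)) {
    tri <- v[mesh$faces[i, ], , drop = FALSE]
    e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    l <- vnorm(nrm); if (l > 0) nrm <- nrm / l
    writeBin(as.numeric(c(nrm, t(tri))), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9f %.9f %.9f",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}
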