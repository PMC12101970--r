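# Closed triangulated primitives. All builders return list(vertices, faces)
# with consistent outward orientation (positive signed volume).

signed_volume_mm3 <- function(vertices, faces) {
  p1 <- vertices[faces[, 1L], , drop = FALSE]
  p2 <- vertices[faces[, 2L], , drop = FALSE]
  p3 <- vertices[faces[, 3L], , drop = FALSE]
  cx <- p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]
  cy <- p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L]
  cz <- p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L]
  sum(p1[, 1L] * cx + p1[, 2L] * cy + p1[, 3L] * cz) / 6
}

orient_outward <- function(mesh) {
  if (signed_volume_mm3(mesh$vertices, mesh$faces) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  }
  mesh
}

#' Axis-aligned cube surface mesh
#'
#' A cube of the given edge length with one corner at the origin,
#' triangulated into 12 outward-oriented faces. Useful as an analytic
#' volume reference: a 10 mm cube encloses exactly 1 ml.
#'
#' @param edge edge length in mm.
#' @return list with `vertices` (8 x 3) and `faces` (12 x 3).
#' @export
cube_mesh <- function(edge = 10) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  # vertex order: 1=(0,0,0) 2=(e,0,0) 3=(0,e,0) 4=(e,e,0) 5..8 top
  f <- rbind(
    c(1, 4, 2), c(1, 3, 4),          # bottom  (-z)
    c(5, 6, 8), c(5, 8, 7),          # top     (+z)
    c(1, 2, 6), c(1, 6, 5),          # front   (-y)
    c(2, 4, 8), c(2, 8, 6),          # right   (+x)
    c(4, 3, 7), c(4, 7, 8),          # back    (+y)
    c(3, 1, 5), c(3, 5, 7)           # left    (-x)
  )
  storage.mode(f) <- "integer"
  dimnames(v) <- NULL
  orient_outward(list(vertices = v, faces = f))
}

#' Icosphere surface mesh
#'
#' A sphere approximation obtained by recursively subdividing an icosahedron
#' and projecting the vertices to the requested radius. Subdivision level
#' `k` yields `20 * 4^k` faces (level 3: 1,280 faces, 642 vertices).
#'
#' @param radius sphere radius in mm.
#' @param subdiv number of subdivision levels (non-negative integer).
#' @return list with `vertices` and `faces` (outward oriented).
#' @export
icosphere <- function(radius = 1, subdiv = 0) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  storage.mode(f) <- "integer"
  for (k in seq_len(subdiv)) {
    mid <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      verts <<- rbind(verts, (verts[i, ] + verts[j, ]) / 2)
      id <- nrow(verts)
      assign(key, id, envir = mid)
      id
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c_ <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca)
      )
    }
    v <- verts
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  orient_outward(list(vertices = v, faces = f))
}

# rows of the ring/apex/cap lattice used by the ellipsoid builders:
# apex at index 1, ring i vertex j at 1 + (i-1)*n_phi + j
bowl_vertices <- function(a, b, c_, n_phi, n_rings) {
  u <- seq_len(n_rings) / n_rings * (pi / 2)
  phi <- (seq_len(n_phi) - 1L) / n_phi * 2 * pi
  ring <- function(ui) {
    cbind(a * sin(ui) * cos(phi), b * sin(ui) * sin(phi), -c_ * cos(ui))
  }
  rbind(c(0, 0, -c_), do.call(rbind, lapply(u, ring)))
}

# faces of the open bowl (apex fan + bands); rim ring edges end up traversed
# j+1 -> j so a cap fan (center, r_j, r_{j+1}) closes it consistently
bowl_faces <- function(n_phi, n_rings) {
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  f <- matrix(0L, 0L, 3L)
  j <- seq_len(n_phi)
  f <- rbind(f, cbind(1L, idx(1L, j + 1L), idx(1L, j)))
  for (i in seq_len(n_rings - 1L)) {
    f <- rbind(
      f,
      cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
      cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j))
    )
  }
  f
}

# closed half-ellipsoid: bowl for z <= 0 plus a flat cap in the z = 0 plane
half_ellipsoid_mesh <- function(a, b, c_, n_phi, n_rings) {
  v <- rbind(bowl_vertices(a, b, c_, n_phi, n_rings), c(0, 0, 0))
  centre <- nrow(v)
  rim <- function(j) 1L + (n_rings - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  j <- seq_len(n_phi)
  f <- rbind(bowl_faces(n_phi, n_rings), cbind(centre, rim(j), rim(j + 1L)))
  storage.mode(f) <- "integer"
  orient_outward(list(vertices = v, faces = f))
}

# closed shell between an inner (endo) and outer (epi) half-ellipsoid,
# joined by an annulus in the z = 0 plane
shell_mesh <- function(a_i, b_i, c_i, a_o, b_o, c_o, n_phi, n_rings) {
  v_o <- bowl_vertices(a_o, b_o, c_o, n_phi, n_rings)
  v_i <- bowl_vertices(a_i, b_i, c_i, n_phi, n_rings)
  off <- nrow(v_o)
  f_o <- bowl_faces(n_phi, n_rings)
  f_i <- bowl_faces(n_phi, n_rings)[, c(1L, 3L, 2L)] + off  # flipped inward
  rim_o <- function(j) 1L + (n_rings - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  rim_i <- function(j) off + rim_o(j)
  j <- seq_len(n_phi)
  annulus <- rbind(
    cbind(rim_o(j), rim_o(j + 1L), rim_i(j + 1L)),
    cbind(rim_o(j), rim_i(j + 1L), rim_i(j))
  )
  f <- rbind(f_o, f_i, annulus)
  storage.mode(f) <- "integer"
  orient_outward(list(vertices = rbind(v_o, v_i), faces = f))
}
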