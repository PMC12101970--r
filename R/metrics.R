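#' Surface distance metrics between point sets
#'
#' Vertex-to-vertex surface distances between two point sets in millimetres.
#' `chamfer_distance()` is the sum of the two directed mean nearest-neighbour
#' distances; `hausdorff_distance()` is the maximum of the two directed
#' Hausdorff distances; `assd()` is the average symmetric surface distance,
#' the sum of all nearest-neighbour distances in both directions divided by
#' the total number of points. All three are symmetric, non-negative and zero
#' exactly when the two sets are equal as sets.
#'
#' @param a,b numeric n x 3 matrices of points (mm). A single point may be
#'   given as a length-3 vector.
#' @return A single non-negative number (mm).
#' @name surface_metrics
NULL

as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty point set")
  x
}

# squared cross-distance matrix |a_i - b_j|^2, clamped at zero
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# directed nearest-neighbour distances from each row of a to the set b:
# the squared cross-distance matrix picks the neighbour index, then the
# distance is recomputed directly (the quadratic expansion cancels
# catastrophically near zero)
nn_dists <- function(a, b) {
  idx <- max.col(-cross_dist2(a, b), "first")
  sqrt(rowSums((a - b[idx, , drop = FALSE])^2))
}

#' @rdname surface_metrics
#' @export
chamfer_distance <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  mean(nn_dists(a, b)) + mean(nn_dists(b, a))
}

#' @rdname surface_metrics
#' @export
hausdorff_distance <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  max(nn_dists(a, b), nn_dists(b, a))
}

#' @rdname surface_metrics
#' @export
assd <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  (sum(nn_dists(a, b)) + sum(nn_dists(b, a))) / (nrow(a) + nrow(b))
}

#' Laplacian smoothness of a vertex set
#'
#' The mean, over vertices, of the Euclidean norm of the mean offset to the
#' neighbouring vertices: `mean_i || mean_{j in N(i)} (v_j - v_i) ||`. Small
#' values indicate a locally smooth surface; the measure is invariant under
#' global translation and scales linearly under uniform scaling.
#'
#' @param vertices numeric V x 3 matrix (mm).
#' @param edges integer E x 2 matrix of undirected edges (e.g. from
#'   [mesh_edges()]), or a [labelled_mesh()] from which edges are taken.
#' @return A single non-negative number (mm).
#' @export
laplacian_smoothness <- function(vertices, edges) {
  if (inherits(edges, "labelled_mesh")) edges <- mesh_edges(edges)
  v <- as.matrix(vertices)
  m <- neighbour_mean_operator(edges, nrow(v))
  d <- as.matrix(m %*% v) - v
  mean(sqrt(rowSums(d^2)))
}

#' Volume enclosed by a closed triangulated surface
#'
#' Signed-tetrahedron (divergence theorem) volume of a closed, consistently
#' oriented triangle surface: the sum over faces of `det[v1 v2 v3]/6`,
#' reported as an absolute volume and converted from cubic millimetres to
#' millilitres.
#'
#' @param vertices numeric V x 3 matrix (mm).
#' @param faces integer F x 3 matrix of 1-based indices forming a closed,
#'   consistently oriented surface.
#' @return Enclosed volume in ml.
#' @export
enclosed_volume <- function(vertices, faces) {
  v <- as.matrix(vertices)
  faces <- as.matrix(faces)
  check_closed_oriented(faces)
  p1 <- v[faces[, 1L], , drop = FALSE]
  p2 <- v[faces[, 2L], , drop = FALSE]
  p3 <- v[faces[, 3L], , drop = FALSE]
  # triple product p1 . (p2 x p3), summed over faces
  cx <- p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]
  cy <- p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L]
  cz <- p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L]
  abs(sum(p1[, 1L] * cx + p1[, 2L] * cy + p1[, 3L] * cz) / 6) / 1000
}

#' Volume of one anatomical part of a mesh
#'
#' @param mesh a [labelled_mesh()].
#' @param part one of `"LV"`, `"MYO"`, `"RV"`. For `"MYO"` the value is the
#'   myocardial wall volume (the volume between the endo- and epicardial
#'   surfaces).
#' @return volume in ml.
#' @export
part_volume <- function(mesh, part) {
  idx <- mesh$part_faces[[part]]
  if (is.null(idx)) stop(sprintf("mesh has no part '%s'", part))
  enclosed_volume(mesh$vertices, mesh$faces[idx, , drop = FALSE])
}
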