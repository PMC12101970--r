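#' Labelled biventricular surface mesh
#'
#' A single time frame of a cardiac surface model: a triangulated surface
#' whose vertices are partitioned into three anatomical parts — the left
#' ventricular blood pool (`"LV"`), the left ventricular myocardium (`"MYO"`)
#' and the right ventricular blood pool (`"RV"`). Each part's faces form a
#' closed, consistently oriented 2-manifold so that enclosed volumes are
#' well defined.
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates in millimetres.
#' @param faces integer F x 3 matrix of 1-based vertex indices,
#'   counter-clockwise when seen from outside (outward normals).
#' @param part character or factor of length V with values in
#'   `c("LV", "MYO", "RV")` assigning each vertex to an anatomical part.
#' @param part_faces named list mapping each part to the integer indices of
#'   the faces that form its closed surface. If `NULL`, faces are assigned to
#'   the part of their first vertex.
#' @param validate if `TRUE` (default) run [validate_mesh()].
#'
#' @return An object of class `labelled_mesh`.
#' @export
labelled_mesh <- function(vertices, faces, part, part_faces = NULL,
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  part <- as.character(part)
  if (is.null(part_faces)) {
    fp <- part[faces[, 1L]]
    part_faces <- split(seq_len(nrow(faces)), fp)
  }
  m <- structure(
    list(vertices = vertices, faces = faces, part = part,
         part_faces = part_faces),
    class = "labelled_mesh"
  )
  if (validate) validate_mesh(m)
  m
}

#' @export
print.labelled_mesh <- function(x, ...) {
  cat(sprintf("<labelled_mesh> %d vertices, %d faces; parts: %s\n",
              nrow(x$vertices), nrow(x$faces),
              paste(sprintf("%s=%d", names(x$part_faces),
                            lengths(x$part_faces)), collapse = ", ")))
  invisible(x)
}

mesh_parts <- function() c("LV", "MYO", "RV")

#' Validate a labelled mesh
#'
#' Checks the structural invariants: all face indices in range, every vertex
#' referenced by at least one face, finite coordinates, and each part's face
#' set a closed consistently oriented 2-manifold (every directed edge used
#' exactly once, so every undirected edge is shared by exactly two faces with
#' opposite winding).
#'
#' @param mesh a [labelled_mesh()].
#' @return `mesh`, invisibly; signals an error on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L) stop("vertices must be a V x 3 matrix")
  if (!is.matrix(f) || ncol(f) != 3L) stop("faces must be an F x 3 matrix")
  if (any(!is.finite(v))) stop("non-finite vertex coordinates")
  nv <- nrow(v)
  if (any(f < 1L) || any(f > nv)) stop("face index out of range")
  if (!all(seq_len(nv) %in% f)) stop("unreferenced vertex present")
  if (length(mesh$part) != nv) stop("part labels must have length V")
  if (!all(mesh$part %in% mesh_parts())) {
    stop("part labels must be in {LV, MYO, RV}")
  }
  for (p in names(mesh$part_faces)) {
    check_closed_oriented(f[mesh$part_faces[[p]], , drop = FALSE], p)
  }
  invisible(mesh)
}

# closed + consistent orientation <=> each directed edge appears exactly once
# and its reverse exactly once
check_closed_oriented <- function(faces, label = "surface") {
  if (nrow(faces) == 0L) stop(sprintf("%s: empty face set", label))
  he <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(he[, 1L], he[, 2L])
  if (anyDuplicated(key)) {
    stop(sprintf("%s: non-manifold surface (repeated directed edge)", label))
  }
  rkey <- paste(he[, 2L], he[, 1L])
  if (!all(rkey %in% key)) {
    stop(sprintf("%s: open or inconsistently oriented surface", label))
  }
  invisible(TRUE)
}

#' Cardiac mesh sequence
#'
#' An ordered sequence of `T` [labelled_mesh()] frames spanning one cardiac
#' cycle, sharing a fixed topology (identical faces and part labels in every
#' frame), together with the subject's clinical conditions.
#'
#' @param frames list of `labelled_mesh` objects (length `T >= 2`).
#' @param condition a [condition()] with the subject's age, sex, weight and
#'   height, or `NULL`.
#' @param subject_id character identifier.
#' @param validate if `TRUE` check the fixed-topology invariant.
#'
#' @return An object of class `mesh_sequence`.
#' @export
mesh_sequence <- function(frames, condition = NULL, subject_id = "subject",
                          validate = TRUE) {
  s <- structure(
    list(frames = frames, condition = condition, subject_id = subject_id),
    class = "mesh_sequence"
  )
  if (validate) validate_sequence(s)
  s
}

#' @export
print.mesh_sequence <- function(x, ...) {
  cat(sprintf("<mesh_sequence> subject %s: T=%d frames, V=%d vertices\n",
              x$subject_id, length(x$frames), nrow(x$frames[[1]]$vertices)))
  invisible(x)
}

#' Validate a mesh sequence
#'
#' @param seq a [mesh_sequence()].
#' @return `seq`, invisibly.
#' @export
validate_sequence <- function(seq) {
  if (length(seq$frames) < 2L) stop("a mesh sequence needs T >= 2 frames")
  f0 <- seq$frames[[1L]]
  validate_mesh(f0)
  for (t in seq_along(seq$frames)[-1L]) {
    ft <- seq$frames[[t]]
    if (nrow(ft$vertices) != nrow(f0$vertices)) {
      stop(sprintf("topology mismatch: frame %d has %d vertices, frame 1 has %d",
                   t, nrow(ft$vertices), nrow(f0$vertices)))
    }
    if (!identical(ft$faces, f0$faces) || !identical(ft$part, f0$part)) {
      stop(sprintf("topology mismatch at frame %d (faces or labels differ)", t))
    }
    if (any(!is.finite(ft$vertices))) {
      stop(sprintf("non-finite coordinates at frame %d", t))
    }
  }
  invisible(seq)
}

#' Number of frames in a sequence
#' @param seq a [mesh_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$frames)

#' Vertex indices of one anatomical part
#' @param mesh a [labelled_mesh()].
#' @param part one of `"LV"`, `"MYO"`, `"RV"`.
#' @return integer vector of vertex indices.
#' @export
part_vertices <- function(mesh, part) which(mesh$part == part)

#' Unique undirected edges of a mesh
#'
#' @param mesh a [labelled_mesh()] (or an F x 3 face matrix).
#' @return integer E x 2 matrix, each row an undirected edge (i < j).
#' @export
mesh_edges <- function(mesh) {
  faces <- if (is.matrix(mesh)) mesh else mesh$faces
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# row-normalized vertex adjacency operator M (V x V sparse): (M v)_i is the
# mean of v over the neighbours of vertex i
neighbour_mean_operator <- function(edges, n_vertices) {
  i <- c(edges[, 1L], edges[, 2L])
  j <- c(edges[, 2L], edges[, 1L])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = rep(n_vertices, 2L))
  deg <- Matrix::rowSums(a)
  if (any(deg == 0)) stop("isolated vertex: every vertex needs a neighbour")
  Matrix::Diagonal(x = 1 / deg) %*% a
}

# symmetric-normalized adjacency with self-loops, D^{-1/2}(A+I)D^{-1/2},
# the propagation operator of the graph-convolution layers
gcn_operator <- function(edges, n_vertices) {
  i <- c(edges[, 1L], edges[, 2L], seq_len(n_vertices))
  j <- c(edges[, 2L], edges[, 1L], seq_len(n_vertices))
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = rep(n_vertices, 2L))
  d <- Matrix::Diagonal(x = 1 / sqrt(Matrix::rowSums(a)))
  d %*% a %*% d
}
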