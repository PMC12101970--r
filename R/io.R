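# PLY (binary little-endian) I/O plus a JSON sidecar manifest describing the
# sequence: conditions, part labels and per-part face ranges. Vertices are
# stored as float64 so write/read round-trips are lossless.

write_ply <- function(vertices, faces, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- c(
    "ply",
    "format binary_little_endian 1.0",
    sprintf("element vertex %d", nrow(vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(faces)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  writeLines(header, con, sep = "\n")
  writeBin(as.double(t(vertices)), con, size = 8L, endian = "little")
  f0 <- t(faces) - 1L   # PLY uses 0-based indices
  for (k in seq_len(ncol(f0))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f0[, k]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  nv <- nf <- NA_integer_
  props <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header: ", path)
    if (grepl("^format ", line) &&
        !grepl("binary_little_endian", line)) {
      stop("unsupported PLY format (expect binary little-endian): ", path)
    }
    if (grepl("^element vertex ", line)) {
      nv <- as.integer(sub("^element vertex ", "", line))
    }
    if (grepl("^element face ", line)) {
      nf <- as.integer(sub("^element face ", "", line))
    }
    if (grepl("^property (double|float) ", line)) {
      props <- c(props, line)
    }
    if (identical(line, "end_header")) break
  }
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  size <- if (any(grepl("float", props))) 4L else 8L
  xyz <- readBin(con, "double", n = 3L * nv, size = size, endian = "little")
  vertices <- matrix(xyz, ncol = 3L, byrow = TRUE)
  faces <- matrix(0L, nrow = nf, ncol = 3L)
  for (k in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", n = 1L))
    if (cnt != 3L) stop("non-triangular face in ", path)
    faces[k, ] <- readBin(con, "integer", n = 3L, size = 4L,
                          endian = "little") + 1L
  }
  list(vertices = vertices, faces = faces)
}

#' Write a mesh sequence to a directory
#'
#' Serializes a [mesh_sequence()] as one binary little-endian PLY file per
#' frame (`frame_000.ply`, `frame_001.ply`, ...) plus a `manifest.json`
#' sidecar holding the subject id, frame count, clinical conditions, per-part
#' vertex labels and per-part face index sets. The pair round-trips exactly
#' through [read_mesh_sequence()].
#'
#' @param seq a [mesh_sequence()].
#' @param path output directory, created if absent.
#' @param overwrite overwrite an existing non-empty directory (default
#'   `FALSE`: error).
#' @return `path`, invisibly.
#' @export
write_mesh_sequence <- function(seq, path, overwrite = FALSE) {
  if (length(seq$frames) == 0L) stop("empty frame list")
  validate_sequence(seq)
  if (dir.exists(path)) {
    if (!overwrite && length(list.files(path)) > 0L) {
      stop("directory exists and is not empty; set overwrite = TRUE: ", path)
    }
  } else if (!dir.create(path, recursive = TRUE)) {
    stop("cannot create directory: ", path)
  }
  for (t in seq_along(seq$frames)) {
    fr <- seq$frames[[t]]
    write_ply(fr$vertices, fr$faces,
              file.path(path, sprintf("frame_%03d.ply", t - 1L)))
  }
  f0 <- seq$frames[[1L]]
  cond <- seq$condition
  manifest <- list(
    subject_id = seq$subject_id,
    T = length(seq$frames),
    condition = if (is.null(cond)) NULL else list(
      age_years = cond$age, sex = cond$sex,
      weight_kg = cond$weight, height_cm = cond$height
    ),
    part_of_vertex = f0$part,
    part_faces = lapply(f0$part_faces, function(ix) as.integer(ix - 1L))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mesh sequence from a directory
#'
#' Reads the `frame_*.ply` files and `manifest.json` written by
#' [write_mesh_sequence()], validating that every frame shares the vertex
#' count, topology and labels declared in the manifest.
#'
#' @param path directory containing the serialized sequence.
#' @return a validated [mesh_sequence()].
#' @export
read_mesh_sequence <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("missing manifest.json in ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  nt <- as.integer(mf$T)
  files <- file.path(path, sprintf("frame_%03d.ply", seq_len(nt) - 1L))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("missing frame file(s): ", paste(basename(files[missing]),
                                          collapse = ", "))
  }
  part <- as.character(mf$part_of_vertex)
  part_faces <- lapply(mf$part_faces, function(ix) as.integer(ix) + 1L)
  frames <- vector("list", nt)
  first <- NULL
  for (t in seq_len(nt)) {
    raw <- read_ply(files[t])
    if (is.null(first)) {
      first <- raw
    } else if (nrow(raw$vertices) != nrow(first$vertices) ||
               !identical(raw$faces, first$faces)) {
      stop("topology mismatch at frame ", t)
    }
    frames[[t]] <- labelled_mesh(raw$vertices, raw$faces, part,
                                 part_faces, validate = (t == 1L))
  }
  cond <- NULL
  if (!is.null(mf$condition)) {
    cond <- condition(age = mf$condition$age_years, sex = mf$condition$sex,
                      weight = mf$condition$weight_kg,
                      height = mf$condition$height_cm)
  }
  mesh_sequence(frames, condition = cond, subject_id = mf$subject_id)
}
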