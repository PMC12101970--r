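#' Cardiac imaging-derived phenotypes of a mesh sequence
#'
#' Computes the standard ventricular structure and function measures from a
#' biventricular mesh sequence: end-diastolic and end-systolic volumes of
#' both ventricles (LVEDV, LVESV, RVEDV, RVESV, in ml), the ejection
#' fractions (LVEF, RVEF, in percent) and the left ventricular myocardial
#' mass (LVM, in g). The end-diastolic frame is the frame with the largest
#' LV cavity volume and the end-systolic frame the one with the smallest
#' (ties broken to the earliest frame). LVM is the myocardial wall volume at
#' the ED frame multiplied by the conventional myocardial tissue density of
#' 1.05 g/ml.
#'
#' @param seq a [mesh_sequence()] whose part surfaces are closed.
#' @param density myocardial tissue density in g/ml (default 1.05).
#' @return A one-row data.frame with columns `LVEDV`, `LVESV`, `LVEF`, `LVM`,
#'   `RVEDV`, `RVESV`, `RVEF`, `ed_frame`, `es_frame` (1-based frame
#'   indices).
#' @export
compute_phenotypes <- function(seq, density = 1.05) {
  vols <- sequence_volumes(seq)
  lv <- vols[, "LV"]
  rv <- vols[, "RV"]
  ed <- which.max(lv)   # earliest frame on ties
  es <- which.min(lv)
  lvedv <- lv[ed]; lvesv <- lv[es]
  if (lvedv <= 0) stop("zero end-diastolic volume")
  rvedv <- rv[ed]; rvesv <- rv[es]
  lvm <- part_volume(seq$frames[[ed]], "MYO") * density
  data.frame(
    LVEDV = lvedv, LVESV = lvesv,
    LVEF = (lvedv - lvesv) / lvedv * 100,
    LVM = lvm,
    RVEDV = rvedv, RVESV = rvesv,
    RVEF = if (rvedv > 0) (rvedv - rvesv) / rvedv * 100 else 0,
    ed_frame = ed, es_frame = es
  )
}

#' Per-frame part volumes of a sequence
#'
#' @param seq a [mesh_sequence()].
#' @return numeric T x 3 matrix with columns `LV`, `MYO`, `RV` (ml); the
#'   `MYO` column holds the wall volume.
#' @export
sequence_volumes <- function(seq) {
  out <- vapply(
    seq$frames,
    function(fr) vapply(mesh_parts(), function(p) part_volume(fr, p), 0),
    numeric(3L)
  )
  t(matrix(out, nrow = 3L, dimnames = list(mesh_parts(), NULL)))
}

phenotype_columns <- function() {
  c("LVEDV", "LVESV", "LVEF", "LVM", "RVEDV", "RVESV", "RVEF")
}
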