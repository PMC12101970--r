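#' Clinical conditions of a subject
#'
#' The four generating factors used to condition the model: age (years),
#' sex (0 = female, 1 = male), weight (kg) and height (cm).
#'
#' @param age age in years, in `[18, 100]`.
#' @param sex 0 (female) or 1 (male).
#' @param weight body weight in kg, in `[30, 200]`.
#' @param height body height in cm, in `[120, 220]`.
#' @return An object of class `condition`.
#' @export
condition <- function(age, sex, weight, height) {
  stopifnot(age >= 18, age <= 100, sex %in% c(0, 1),
            weight >= 30, weight <= 200, height >= 120, height <= 220)
  structure(list(age = as.numeric(age), sex = as.numeric(sex),
                 weight = as.numeric(weight), height = as.numeric(height)),
            class = "condition")
}

#' Body surface area (Mosteller)
#' @param weight kg
#' @param height cm
#' @return BSA in square metres.
#' @export
body_surface_area <- function(weight, height) sqrt(weight * height / 3600)

#' Specification of a synthetic beating-heart population
#'
#' Defines the study conditions emulated by the generator: cohort geometry
#' (frames per cycle, vertices per anatomical part), the timing of
#' end-systole, the linear effect coefficients tying conditions to
#' phenotypes, and the noise levels. Effect defaults give realistic adult
#' ranges (LVEDV roughly 100-180 ml, LVEF roughly 50-70%).
#'
#' @param n_subjects number of subjects.
#' @param T_frames frames per cardiac cycle (default 20; cohort-scale
#'   sequences use 50).
#' @param vertices_per_part approximate vertex count per anatomical part
#'   (default 162).
#' @param es_fraction fraction of the cycle at which end-systole occurs.
#' @param edv_base,edv_bsa,edv_sex,edv_age LVEDV model: `edv_base +
#'   edv_bsa * BSA + edv_sex * sex - edv_age * (age - 60)` (ml).
#' @param ef_base,ef_age LVEF model: `ef_base - ef_age * (age - 60) / 10`
#'   (percent), clipped to `[35, 75]`.
#' @param rv_ratio RV volumes as a multiple of the LV analogues.
#' @param wall_base,wall_sex myocardial wall thickness in mm:
#'   `wall_base + wall_sex * sex`.
#' @param shape_sd standard deviation (mm) of the smooth per-subject shape
#'   perturbation field.
#' @param phenotype_sd standard deviation of the additive phenotype noise:
#'   applied at `phenotype_sd` ml on LVEDV and `phenotype_sd / 4` points on
#'   LVEF.
#' @param seed integer seed for all sampling tied to this spec.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 100, T_frames = 20,
                            vertices_per_part = 162, es_fraction = 0.35,
                            edv_base = 90, edv_bsa = 30, edv_sex = 20,
                            edv_age = 0.3, ef_base = 60, ef_age = 2,
                            rv_ratio = 1.05, wall_base = 8, wall_sex = 1,
                            shape_sd = 2, phenotype_sd = 8, seed = 1L) {
  stopifnot(T_frames >= 2, es_fraction > 0, es_fraction < 1,
            shape_sd >= 0, phenotype_sd >= 0)
  structure(
    list(n_subjects = n_subjects, T_frames = as.integer(T_frames),
         vertices_per_part = as.integer(vertices_per_part),
         es_fraction = es_fraction,
         edv_base = edv_base, edv_bsa = edv_bsa, edv_sex = edv_sex,
         edv_age = edv_age, ef_base = ef_base, ef_age = ef_age,
         rv_ratio = rv_ratio, wall_base = wall_base, wall_sex = wall_sex,
         shape_sd = shape_sd, phenotype_sd = phenotype_sd,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Disease perturbation of a synthetic heart
#'
#' @param kind one of `"dilated"` (LV volumes scaled up by
#'   `1 + 0.4 * severity` at preserved ejection fraction), `"hypertrophic"`
#'   (myocardial wall volume scaled by `1 + 0.6 * severity`) or `"low_ef"`
#'   (stroke volume of both ventricles scaled by `1 - 0.5 * severity`).
#' @param severity in `(0, 1]`.
#' @return An object of class `disease_spec`.
#' @export
disease_spec <- function(kind = c("dilated", "hypertrophic", "low_ef"),
                         severity = 1) {
  kind <- match.arg(kind)
  stopifnot(severity > 0, severity <= 1)
  structure(list(kind = kind, severity = severity), class = "disease_spec")
}

#' Sample clinical conditions for a synthetic cohort
#'
#' Sex is Bernoulli(0.5); age uniform on 45-80 years (the age window of a
#' population imaging cohort); height and weight normal with sex-specific
#' means (females: 162 +- 7 cm, 70 +- 12 kg; males: 176 +- 7 cm,
#' 84 +- 13 kg), truncated to the valid condition ranges.
#'
#' @param spec a [population_spec()] (only used for its seed when `seed` is
#'   `NULL`).
#' @param n number of subjects (`>= 1`).
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list of [condition()] objects, deterministic given the seed.
#' @export
sample_conditions <- function(spec, n = spec$n_subjects, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (is.null(seed)) seed <- spec$seed
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 45, 80)
  height <- stats::rnorm(n, ifelse(sex == 0, 162, 176), 7)
  weight <- stats::rnorm(n, ifelse(sex == 0, 70, 84), ifelse(sex == 0, 12, 13))
  height <- pmin(pmax(height, 120), 220)
  weight <- pmin(pmax(weight, 30), 200)
  lapply(seq_len(n), function(i) {
    condition(age[i], sex[i], weight[i], height[i])
  })
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Ground-truth phenotypes implied by a subject's conditions
#'
#' The generative ground truth of the synthetic population: linear effects
#' of body surface area (Mosteller), sex and age on LVEDV; a linear age
#' effect on LVEF (clipped to 35-75%); RV volumes as a fixed multiple of the
#' LV analogues; and myocardial mass from a wall-thickness model (wall
#' volume of the half-ellipsoid shell at the subject's LV size, times
#' 1.05 g/ml).
#'
#' @param c a [condition()].
#' @param spec a [population_spec()].
#' @param noise if `TRUE`, add seeded Gaussian phenotype noise
#'   (`phenotype_sd` ml on LVEDV, `phenotype_sd / 4` points on LVEF).
#' @param seed integer seed used when `noise = TRUE`.
#' @param disease optional [disease_spec()] perturbation.
#' @return one-row data.frame with the [compute_phenotypes()] phenotype
#'   columns plus the geometric parameters used by the mesh builder.
#' @export
true_phenotypes <- function(c, spec, noise = TRUE, seed = NULL,
                            disease = NULL) {
  bsa <- body_surface_area(c$weight, c$height)
  lvedv <- spec$edv_base + spec$edv_bsa * bsa + spec$edv_sex * c$sex -
    spec$edv_age * (c$age - 60)
  lvef <- spec$ef_base - spec$ef_age * (c$age - 60) / 10
  if (noise && spec$phenotype_sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_exists()
      set.seed(seed)
      on.exit(.restore_seed(old), add = TRUE)
    }
    lvedv <- lvedv + stats::rnorm(1L, 0, spec$phenotype_sd)
    lvef <- lvef + stats::rnorm(1L, 0, spec$phenotype_sd / 4)
  }
  lvef <- min(max(lvef, 35), 75)
  lvedv <- max(lvedv, 40)
  wall <- spec$wall_base + spec$wall_sex * c$sex   # thickness, mm
  wall_mult <- 1                                   # wall-volume multiplier
  if (!is.null(disease)) {
    sev <- disease$severity
    if (disease$kind == "dilated") {
      lvedv <- lvedv * (1 + 0.4 * sev)             # EF preserved
    } else if (disease$kind == "hypertrophic") {
      wall_mult <- 1 + 0.6 * sev
    } else if (disease$kind == "low_ef") {
      lvef <- lvef * (1 - 0.5 * sev)
    }
  }
  lvesv <- lvedv * (1 - lvef / 100)
  rvedv <- spec$rv_ratio * lvedv
  rvesv <- spec$rv_ratio * lvesv
  geom <- lv_geometry(lvedv, wall)
  data.frame(
    LVEDV = lvedv, LVESV = lvesv, LVEF = lvef,
    LVM = geom$wall_volume * wall_mult * 1.05,
    RVEDV = rvedv, RVESV = rvesv, RVEF = lvef,
    wall_thickness = wall, lv_radius = geom$a, lv_depth = geom$c_
  )
}

# analytic LV geometry: cavity = half-ellipsoid with a = b and depth
# c = aspect * a; wall = shell of constant thickness
lv_geometry <- function(lvedv_ml, wall_mm, aspect = 3) {
  a <- (3 * lvedv_ml * 1000 / (2 * pi * aspect))^(1 / 3)
  c_ <- aspect * a
  wall_volume <- (2 / 3) * pi *
    ((a + wall_mm)^2 * (c_ + wall_mm) - a^2 * c_) / 1000
  list(a = a, c_ = c_, wall_volume = wall_volume)
}

# resolve the (n_phi, n_rings) lattice from a requested per-part vertex count
lattice_dims <- function(vertices_per_part) {
  n_phi <- max(6L, as.integer(round(sqrt((vertices_per_part - 2L) / 1.6))))
  n_rings <- max(3L, as.integer(round((vertices_per_part - 2L) / n_phi)))
  # the myocardial shell needs an even ring count split across two surfaces
  if (n_rings %% 2L == 1L) n_rings <- n_rings + 1L
  list(n_phi = n_phi, n_rings = n_rings)
}

# systolic phase s(t): 0 at frame 0 (end-diastole), 1 at the end-systolic
# frame, back towards 0 at the end of the cycle; t is 0-based
systolic_phase <- function(t, T_frames, es_fraction) {
  t_es <- max(1L, round(es_fraction * T_frames))
  ifelse(t <= t_es,
         0.5 * (1 - cos(pi * t / t_es)),
         0.5 * (1 + cos(pi * (t - t_es) / (T_frames - t_es))))
}

# build the three-part template at end-diastole for one subject and scale
# each part so its measured (discretized) volume matches the target exactly
build_heart_template <- function(tp, spec) {
  dims <- lattice_dims(spec$vertices_per_part)
  n_phi <- dims$n_phi; n_r <- dims$n_rings
  a <- tp$lv_radius; c_ <- tp$lv_depth; h <- tp$wall_thickness

  lv <- half_ellipsoid_mesh(a, a, c_, n_phi, n_r)
  lv$vertices <- scale_to_volume(lv, tp$LVEDV)

  myo <- shell_mesh(a, a, c_, a + h, a + h, c_ + h, n_phi, n_r %/% 2L)
  myo$vertices <- scale_to_volume(myo, tp$LVM / 1.05)

  # RV: flattened half-ellipsoid bent into a crescent, placed laterally
  a_r <- (3 * tp$RVEDV * 1000 / (2 * pi * 0.5 * 3))^(1 / 3)
  rv <- half_ellipsoid_mesh(a_r, 0.5 * a_r, c_, n_phi, n_r)
  rv$vertices[, 1L] <- rv$vertices[, 1L] +
    0.006 * rv$vertices[, 2L]^2          # volume-preserving bend
  rv$vertices <- scale_to_volume(rv, tp$RVEDV)
  rv$vertices[, 1L] <- rv$vertices[, 1L] - (a + h + 0.9 * a_r)

  assemble_parts(lv = lv, myo = myo, rv = rv)
}

scale_to_volume <- function(mesh, target_ml) {
  v0 <- enclosed_volume(mesh$vertices, mesh$faces)
  ctr <- colMeans(mesh$vertices)
  s <- (target_ml / v0)^(1 / 3)
  sweep(sweep(mesh$vertices, 2L, ctr) * s, 2L, ctr, "+")
}

assemble_parts <- function(lv, myo, rv) {
  nv <- c(nrow(lv$vertices), nrow(myo$vertices), nrow(rv$vertices))
  off <- cumsum(c(0L, nv))[1:3]
  vertices <- rbind(lv$vertices, myo$vertices, rv$vertices)
  faces <- rbind(lv$faces, myo$faces + off[2L], rv$faces + off[3L])
  part <- rep(c("LV", "MYO", "RV"), nv)
  nf <- c(nrow(lv$faces), nrow(myo$faces), nrow(rv$faces))
  foff <- cumsum(c(0L, nf))
  part_faces <- list(LV = seq_len(nf[1L]),
                     MYO = foff[2L] + seq_len(nf[2L]),
                     RV = foff[3L] + seq_len(nf[3L]))
  labelled_mesh(vertices, faces, part, part_faces)
}

# smooth per-subject shape perturbation: a superposition of low-frequency
# sinusoidal displacement fields with RMS amplitude shape_sd (mm)
shape_noise_field <- function(vertices, shape_sd, n_waves = 6L,
                              wavelength = 30) {
  if (shape_sd <= 0) return(vertices * 0)
  d <- matrix(0, nrow(vertices), 3L)
  for (k in seq_len(n_waves)) {
    w <- stats::rnorm(3L); w <- w / sqrt(sum(w^2)) * (2 * pi / wavelength)
    u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
    ph <- stats::runif(1L, 0, 2 * pi)
    d <- d + outer(sin(vertices %*% w + ph)[, 1L], u)
  }
  d * shape_sd / sqrt(mean(rowSums(d^2)))
}

#' Generate one synthetic cardiac mesh sequence
#'
#' Builds the biventricular template implied by the subject's conditions
#' (LV cavity: capped half-ellipsoid; myocardium: closed shell between the
#' endo- and epicardial half-ellipsoids; RV cavity: crescent-bent flattened
#' half-ellipsoid), calibrates each part so the frame-0 measured volume
#' matches [true_phenotypes()] exactly, applies a smooth seeded per-subject
#' shape perturbation, and animates the cycle by radial scaling about each
#' part's long axis so that the LV cavity volume follows
#' `EDV - (EDV - ESV) * s(t)` with the systolic phase `s` rising from 0 at
#' end-diastole (frame 0) to 1 at `es_fraction * T`.
#'
#' @param c a [condition()].
#' @param spec a [population_spec()].
#' @param seed integer seed (shape noise and phenotype noise).
#' @param disease optional [disease_spec()].
#' @param subject_id character id for the sequence.
#' @return a [mesh_sequence()] with attribute `"true_phenotypes"`.
#' @export
generate_sequence <- function(c, spec, seed = spec$seed, disease = NULL,
                              subject_id = "synthetic") {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  tp <- true_phenotypes(c, spec, noise = spec$phenotype_sd > 0,
                        disease = disease)
  template <- build_heart_template(tp, spec)
  template$vertices <- template$vertices +
    shape_noise_field(template$vertices, spec$shape_sd)

  tt <- seq_len(spec$T_frames) - 1L
  s <- systolic_phase(tt, spec$T_frames, spec$es_fraction)
  g_lv <- sqrt((tp$LVEDV - (tp$LVEDV - tp$LVESV) * s) / tp$LVEDV)
  g_rv <- sqrt((tp$RVEDV - (tp$RVEDV - tp$RVESV) * s) / tp$RVEDV)

  axis_xy <- lapply(mesh_parts(), function(p) {
    colMeans(template$vertices[template$part == p, 1:2, drop = FALSE])
  })
  names(axis_xy) <- mesh_parts()

  frames <- lapply(seq_along(tt), function(i) {
    v <- template$vertices
    for (p in mesh_parts()) {
      gg <- if (p == "RV") g_rv[i] else g_lv[i]   # myocardium follows the LV
      idx <- template$part == p
      v[idx, 1:2] <- sweep(
        sweep(v[idx, 1:2, drop = FALSE], 2L, axis_xy[[p]]) * gg,
        2L, axis_xy[[p]], "+")
    }
    labelled_mesh(v, template$faces, template$part, template$part_faces,
                  validate = FALSE)
  })
  out <- mesh_sequence(frames, condition = c, subject_id = subject_id,
                       validate = FALSE)
  attr(out, "true_phenotypes") <- tp
  out
}

#' Generate and serialize a synthetic dataset
#'
#' Samples conditions, assigns train/val/test splits and disease labels
#' (the training split is healthy-only, matching a normative model trained
#' on asymptomatic hearts), writes every sequence via
#' [write_mesh_sequence()], and writes `dataset.csv` (conditions, labels and
#' true phenotypes) plus `splits.json`.
#'
#' @param spec a [population_spec()].
#' @param path output directory.
#' @param splits named fractions `c(train = , val = , test = )` summing to 1.
#' @param disease_prevalence probability that a val/test subject carries the
#'   disease perturbation.
#' @param disease a [disease_spec()] used for affected subjects.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return invisibly, the dataset table (also written as `dataset.csv`).
#' @export
make_dataset <- function(spec, path, splits = c(train = 0.6, val = 0.2,
                                                test = 0.2),
                         disease_prevalence = 0,
                         disease = disease_spec("low_ef", 0.8),
                         seed = NULL) {
  if (abs(sum(splits) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(seed)) seed <- spec$seed
  n <- spec$n_subjects
  conds <- sample_conditions(spec, n, seed = seed)

  old <- .Random.seed_exists()
  set.seed(seed + 1L)
  on.exit(.restore_seed(old), add = TRUE)
  n_split <- round(n * splits)
  n_split[1L] <- n - sum(n_split[-1L])
  split_of <- rep(names(splits), n_split)
  affected <- split_of != "train" &
    stats::rbinom(n, 1L, disease_prevalence) == 1L

  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%04d", i)
    dis <- if (affected[i]) disease else NULL
    seq_i <- generate_sequence(conds[[i]], spec, seed = seed + 1000L + i,
                               disease = dis, subject_id = sid)
    write_mesh_sequence(seq_i, file.path(path, sid), overwrite = TRUE)
    tp <- attr(seq_i, "true_phenotypes")
    rows[[i]] <- data.frame(
      subject_id = sid, split = split_of[i],
      age = conds[[i]]$age, sex = conds[[i]]$sex,
      weight = conds[[i]]$weight, height = conds[[i]]$height,
      label = if (affected[i]) disease$kind else "healthy",
      true_LVEDV = tp$LVEDV, true_LVESV = tp$LVESV, true_LVEF = tp$LVEF,
      true_LVM = tp$LVM, true_RVEDV = tp$RVEDV, true_RVESV = tp$RVESV,
      true_RVEF = tp$RVEF
    )
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(path, "dataset.csv"), row.names = FALSE)
  jsonlite::write_json(base::split(tab$subject_id, tab$split),
                       file.path(path, "splits.json"))
  invisible(tab)
}

#' Load a dataset written by [make_dataset()]
#'
#' @param path dataset directory.
#' @param split optional split name to filter on.
#' @return list with `table` (the dataset data.frame) and `sequences`
#'   (named list of [mesh_sequence()]).
#' @export
load_dataset <- function(path, split = NULL) {
  tab <- utils::read.csv(file.path(path, "dataset.csv"),
                         stringsAsFactors = FALSE)
  if (!is.null(split)) tab <- tab[tab$split %in% split, , drop = FALSE]
  seqs <- lapply(tab$subject_id, function(sid) {
    read_mesh_sequence(file.path(path, sid))
  })
  names(seqs) <- tab$subject_id
  list(table = tab, sequences = seqs)
}
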