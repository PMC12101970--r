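# Reconstruction/generation evaluation, the latent-delta normative
# deviation score, distribution-similarity metrics and the downstream
# classification / association harnesses.

#' Reconstruction accuracy table
#'
#' Reconstructs every sequence and reports vertex-to-vertex Hausdorff and
#' average symmetric surface distances per anatomical structure (LV, Myo,
#' RV) and averaged across structures, each evaluated as the mean across
#' all time frames as well as at the end-diastolic and end-systolic frames
#' (located on the input sequence via [compute_phenotypes()]). Values are
#' means over subjects, in millimetres.
#'
#' @param state a trained [mesh_model()] state.
#' @param sequences non-empty list of [mesh_sequence()] objects.
#' @param reconstructions optional pre-computed reconstructions aligned with
#'   `sequences` (defaults to running [reconstruct()]).
#' @return data.frame with columns `structure` (`LV`, `MYO`, `RV`, `mean`),
#'   `frames` (`all`, `ED`, `ES`), `HD`, `ASSD`.
#' @export
evaluate_reconstruction <- function(state, sequences,
                                    reconstructions = NULL) {
  if (length(sequences) == 0L) stop("empty evaluation split")
  if (is.null(reconstructions)) {
    reconstructions <- lapply(sequences, reconstruct, state = state)
  }
  parts <- mesh_parts()
  acc <- array(0, dim = c(length(sequences), 3L, 3L, 2L),
               dimnames = list(NULL, parts, c("all", "ED", "ES"),
                               c("HD", "ASSD")))
  for (s in seq_along(sequences)) {
    inp <- sequences[[s]]; rec <- reconstructions[[s]]
    ph <- compute_phenotypes(inp)
    frames_of <- list(all = seq_along(inp$frames), ED = ph$ed_frame,
                      ES = ph$es_frame)
    pidx <- lapply(parts, part_vertices, mesh = inp$frames[[1L]])
    names(pidx) <- parts
    for (p in parts) {
      for (w in names(frames_of)) {
        hd <- assd_v <- numeric(0)
        for (t in frames_of[[w]]) {
          a <- inp$frames[[t]]$vertices[pidx[[p]], , drop = FALSE]
          b <- rec$frames[[t]]$vertices[pidx[[p]], , drop = FALSE]
          hd <- c(hd, hausdorff_distance(a, b))
          assd_v <- c(assd_v, assd(a, b))
        }
        acc[s, p, w, "HD"] <- mean(hd)
        acc[s, p, w, "ASSD"] <- mean(assd_v)
      }
    }
  }
  rows <- expand.grid(structure = c(parts, "mean"),
                      frames = c("all", "ED", "ES"),
                      stringsAsFactors = FALSE)
  rows$HD <- rows$ASSD <- NA_real_
  for (r in seq_len(nrow(rows))) {
    w <- rows$frames[r]
    if (rows$structure[r] == "mean") {
      rows$HD[r] <- mean(acc[, , w, "HD"])
      rows$ASSD[r] <- mean(acc[, , w, "ASSD"])
    } else {
      rows$HD[r] <- mean(acc[, rows$structure[r], w, "HD"])
      rows$ASSD[r] <- mean(acc[, rows$structure[r], w, "ASSD"])
    }
  }
  rows[, c("structure", "frames", "HD", "ASSD")]
}

# ---- distribution similarity --------------------------------------------

# exact 1-D first Wasserstein distance between two samples via the area
# between the empirical CDFs
wasserstein_1d <- function(a, b) {
  x <- sort(unique(c(a, b)))
  if (length(x) == 1L) return(0)
  fa <- stats::ecdf(a)(x); fb <- stats::ecdf(b)(x)
  n <- length(x)
  sum(abs(fa[-n] - fb[-n]) * diff(x))
}

# KL(real || synth) between histograms on shared Freedman-Diaconis bins
# over the pooled sample, with additive smoothing
kl_histogram <- function(real, synth, smoothing = 1e-8) {
  pooled <- c(real, synth)
  if (stats::sd(pooled) == 0) return(0)
  brk <- seq(min(pooled), max(pooled),
             length.out = max(grDevices::nclass.FD(pooled), 2L) + 1L)
  p <- tabulate(findInterval(real, brk, all.inside = TRUE),
                nbins = length(brk) - 1L) + smoothing
  q <- tabulate(findInterval(synth, brk, all.inside = TRUE),
                nbins = length(brk) - 1L) + smoothing
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Similarity between real and synthetic phenotype distributions
#'
#' For each phenotype, compares its distribution in the real and synthetic
#' populations conditioned on a clinical factor: samples are stratified
#' (age by decade bins; sex by level), the KL divergence (real vs synthetic
#' histograms on shared Freedman-Diaconis bins, additive smoothing) and the
#' exact one-dimensional Wasserstein distance are computed per stratum and
#' averaged over strata. Lower is better; identical samples give 0.
#'
#' @param real,synth data.frames holding the phenotype columns plus the
#'   conditioning columns `age` and/or `sex`; at least 20 rows each.
#' @param by conditioning variables (default `c("age", "sex")`).
#' @param phenotypes phenotype columns to compare (defaults to the standard
#'   seven present in both inputs).
#' @param min_stratum smallest per-side stratum kept (smaller strata are
#'   skipped with a warning).
#' @return data.frame with columns `phenotype`, `conditioning`, `KL`, `WD`.
#' @export
phenotype_distribution_similarity <- function(real, synth,
                                              by = c("age", "sex"),
                                              phenotypes = NULL,
                                              min_stratum = 5L) {
  if (nrow(real) < 20L || nrow(synth) < 20L) {
    stop("need at least 20 samples per side")
  }
  if (is.null(phenotypes)) {
    phenotypes <- intersect(phenotype_columns(),
                            intersect(names(real), names(synth)))
  }
  strata_of <- function(df, var) {
    if (var == "age") {
      factor(10 * (df$age %/% 10), levels = seq(0, 110, 10))
    } else {
      factor(df[[var]])
    }
  }
  out <- list()
  for (var in by) {
    sr <- strata_of(real, var); ss <- strata_of(synth, var)
    for (ph in phenotypes) {
      kl <- wd <- numeric(0)
      for (lev in intersect(unique(sr), unique(ss))) {
        a <- real[[ph]][sr == lev]; b <- synth[[ph]][ss == lev]
        if (length(a) < min_stratum || length(b) < min_stratum) {
          warning(sprintf("skipping stratum %s=%s for %s (too few samples)",
                          var, lev, ph))
          next
        }
        kl <- c(kl, kl_histogram(a, b))
        wd <- c(wd, wasserstein_1d(a, b))
      }
      out[[length(out) + 1L]] <- data.frame(
        phenotype = ph, conditioning = var,
        KL = mean(kl), WD = mean(wd))
    }
  }
  do.call(rbind, out)
}

# ---- batched latent machinery -------------------------------------------

# frame latents for a batch of stacked coordinate matrices; coords_big is
# (n_seq * T * V) x 3 (the per-frame graph operator applies blockwise)
batch_frame_latents <- function(state, coords_big) {
  tape <- ad_tape()
  ad_value(fwd_mesh_encode(tape, state$params, coords_big, state$ops))
}

# latent vector from precomputed frame latents (T x 64) and z_c (1 x 32)
latent_from_frames <- function(state, Z, z_c) {
  tape <- ad_tape()
  enc <- fwd_temporal_encode(tape, state$params, Z, z_c, state$config)
  out <- ad_value(enc$enc_out)
  colMeans(out[-(1:2), seq_len(state$config$d_latent), drop = FALSE])
}

#' Latent delta: personalized normative deviation score
#'
#' Encodes the subject's sequence to its latent vector, generates `n`
#' condition-matched synthetic sequences from the standard Gaussian prior
#' using the subject's own clinical conditions, re-encodes each through the
#' mesh and temporal encoders, and returns the Euclidean distance between
#' the subject's latent vector and the mean synthetic latent vector.
#'
#' @param state a trained [mesh_model()] state.
#' @param seq the subject's [mesh_sequence()].
#' @param n number of reference samples (default 100).
#' @param seed integer seed for the prior draws.
#' @param chunk internal batch size for decoding/re-encoding.
#' @return one-row data.frame with `subject_id`, `delta_z`,
#'   `n_reference_samples`, `seed`.
#' @export
latent_delta <- function(state, seq, n = 100L, seed = 1L, chunk = 20L) {
  if (!isTRUE(state$trained)) {
    warning("latent_delta on an untrained model state")
  }
  check_topology(seq, state)
  z_real <- latent_vector(seq, state)
  z_synth <- latent_reference_samples(state, seq$condition, n, seed, chunk)
  dz <- sqrt(sum((z_real - colMeans(z_synth))^2))
  data.frame(subject_id = seq$subject_id, delta_z = dz,
             n_reference_samples = as.integer(n), seed = as.integer(seed))
}

# n latent vectors of prior-sampled synthetic sequences for one condition
latent_reference_samples <- function(state, cond, n, seed, chunk = 20L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  dl <- state$config$d_latent
  zs <- matrix(stats::rnorm(n * dl), n, dl)
  tape <- ad_tape()
  z_c <- fwd_condition(tape, state$params,
                       condition_input(cond, state$norm))
  z_c_val <- ad_value(z_c)
  Tn <- state$T_frames
  out <- matrix(0, n, dl)
  done <- 0L
  while (done < n) {
    b <- min(chunk, n - done)
    FZ <- do.call(rbind, lapply(seq_len(b), function(i) {
      ad_value(fwd_temporal_decode(tape, state$params,
                                   matrix(zs[done + i, ], 1L), z_c,
                                   state$config, state$ops$pe))
    }))
    coords <- ad_value(fwd_mesh_decode(tape, state$params, FZ, z_c_val,
                                       state$config, state$V,
                                       state$base_coords))
    Zb <- batch_frame_latents(state, coords)
    for (i in seq_len(b)) {
      rows <- ((i - 1L) * Tn + 1L):(i * Tn)
      out[done + i, ] <- latent_from_frames(state, Zb[rows, , drop = FALSE],
                                            z_c_val)
    }
    done <- done + b
  }
  out
}

# ---- downstream harnesses ------------------------------------------------

#' Disease classification harness
#'
#' Trains three pluggable classifier kinds — a boosted-trees ensemble
#' (xgboost), linear discriminant analysis (MASS) and a max-margin linear
#' classifier (linear-kernel SVM, e1071) — on a feature table with binary
#' labels, and reports the AUC averaged over seeded random train/test
#' splits (default 5). No per-classifier tuning is performed.
#'
#' @param features numeric data.frame or matrix of features (rows =
#'   subjects).
#' @param labels binary vector (two classes) aligned with `features`.
#' @param classifiers subset of `c("boost", "lda", "svm")`.
#' @param n_splits number of random train/test splits (default 5).
#' @param seed integer seed.
#' @param train_fraction fraction of subjects in each training split.
#' @return data.frame with columns `classifier`, `split`, `auc`.
#' @export
classification_harness <- function(features, labels,
                                   classifiers = c("boost", "lda", "svm"),
                                   n_splits = 5L, seed = 1L,
                                   train_fraction = 0.7) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop("labels must have exactly two classes")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  n <- nrow(x)
  out <- list()
  for (sp in seq_len(n_splits)) {
    idx <- sample.int(n, round(train_fraction * n))
    if (length(unique(y[idx])) < 2L || length(unique(y[-idx])) < 2L) next
    for (cl in classifiers) {
      score <- switch(
        cl,
        boost = {
          dtrain <- xgboost::xgb.DMatrix(x[idx, , drop = FALSE],
                                         label = y[idx], nthread = 1L)
          fit <- xgboost::xgb.train(
            params = list(objective = "binary:logistic", max_depth = 2L,
                          eta = 0.3, nthread = 1L),
            data = dtrain, nrounds = 50L, verbose = 0)
          stats::predict(fit, xgboost::xgb.DMatrix(
            x[-idx, , drop = FALSE], nthread = 1L))
        },
        lda = {
          fit <- MASS::lda(x[idx, , drop = FALSE],
                           grouping = factor(y[idx]))
          stats::predict(fit, x[-idx, , drop = FALSE])$posterior[, "1"]
        },
        svm = {
          fit <- e1071::svm(x[idx, , drop = FALSE], factor(y[idx]),
                            kernel = "linear", scale = TRUE)
          dv <- attr(stats::predict(fit, x[-idx, , drop = FALSE],
                                    decision.values = TRUE),
                     "decision.values")
          # decision values are positive towards the first listed class
          if (startsWith(colnames(dv)[1L], "0/")) -dv[, 1L] else dv[, 1L]
        })
      out[[length(out) + 1L]] <- data.frame(
        classifier = cl, split = sp,
        auc = auc_score(y[-idx], score))
    }
  }
  do.call(rbind, out)
}

# AUC with a fixed direction (score increasing with class 1)
auc_score <- function(y, score) {
  as.numeric(pROC::auc(response = y, predictor = as.numeric(score),
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Association scan of the latent delta against binary outcomes
#'
#' For each outcome column, fits a logistic regression of the outcome on
#' the standardized latent delta and reports the Rao score test p-value,
#' the effect direction, and Bonferroni significance with the family size
#' equal to the number of outcomes actually tested. Constant outcome
#' columns are skipped with a warning.
#'
#' @param deltas data.frame with a `delta_z` column (one row per subject),
#'   e.g. stacked [latent_delta()] rows.
#' @param outcomes data.frame of binary (0/1) outcome columns aligned with
#'   `deltas`.
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame with columns `outcome`, `effect`, `p`, `significant`
#'   (Bonferroni at `alpha`); the family size is in attribute
#'   `"n_outcomes"`.
#' @export
association_scan <- function(deltas, outcomes, alpha = 0.05) {
  z <- as.numeric(scale(deltas$delta_z))
  res <- list()
  for (nm in names(outcomes)) {
    y <- outcomes[[nm]]
    if (length(unique(y)) < 2L) {
      warning("skipping constant outcome column: ", nm)
      next
    }
    fit <- stats::glm(y ~ z, family = stats::binomial())
    sc <- stats::anova(fit, test = "Rao")
    res[[length(res) + 1L]] <- data.frame(
      outcome = nm,
      effect = sign(stats::coef(fit)[["z"]]),
      p = sc[["Pr(>Chi)"]][2L])
  }
  tab <- do.call(rbind, res)
  m <- nrow(tab)
  tab$significant <- tab$p < alpha / m
  attr(tab, "n_outcomes") <- m
  tab
}
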