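ns <- asNamespace("cardiomesh")

test_that("the reconstruction table is zero on perfect reconstructions", {
  s <- tiny_sequence(seed = 25)
  st <- tiny_state(s)
  tab <- evaluate_reconstruction(st, list(s), reconstructions = list(s))
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$HD == 0))
  expect_true(all(tab$ASSD == 0))
})

test_that("a uniform 5 mm shift yields 5 mm everywhere in the table", {
  # three near-point-sized tetrahedral parts, so every vertex-set nearest
  # neighbour distance equals the shift
  tetra <- function(centre, e = 0.01) {
    v <- rbind(c(0, 0, 0), c(e, 0, 0), c(0, e, 0), c(0, 0, e))
    list(vertices = sweep(v, 2, centre, "+"),
         faces = rbind(c(1L, 3L, 2L), c(1L, 2L, 4L),
                       c(1L, 4L, 3L), c(2L, 3L, 4L)))
  }
  parts <- list(tetra(c(0, 0, 0)), tetra(c(30, 0, 0)), tetra(c(0, 30, 0)))
  verts <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  faces <- rbind(parts[[1]]$faces, parts[[2]]$faces + 4L,
                 parts[[3]]$faces + 8L)
  m <- labelled_mesh(verts, faces, rep(c("LV", "MYO", "RV"), each = 4L))
  s <- mesh_sequence(list(m, m), subject_id = "toy")
  st <- tiny_state(tiny_sequence(seed = 26))  # any state: recon is supplied
  m5 <- m
  m5$vertices <- sweep(m$vertices, 2, c(5, 0, 0), "+")
  shifted <- mesh_sequence(list(m5, m5), subject_id = "toy")
  tab <- evaluate_reconstruction(st, list(s),
                                 reconstructions = list(shifted))
  expect_equal(tab$HD, rep(5, 12), tolerance = 0.005)
  expect_equal(tab$ASSD, rep(5, 12), tolerance = 0.005)
  # averaged-structure rows equal the mean over LV/MYO/RV
  for (w in c("all", "ED", "ES")) {
    sub <- tab[tab$frames == w, ]
    expect_equal(sub$HD[sub$structure == "mean"],
                 mean(sub$HD[sub$structure != "mean"]))
  }
})

test_that("Wasserstein and KL distances satisfy their closed forms", {
  expect_equal(ns$wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ns$kl_histogram(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  # point mass at 0 vs point mass at 1 transports mass distance 1
  expect_equal(ns$wasserstein_1d(rep(0, 30), rep(1, 30)), 1)
  # mean-shifted Gaussians: W1 equals the mean difference
  set.seed(2)
  a <- rnorm(1e5, 0, 1); b <- rnorm(1e5, 2.5, 1)
  expect_equal(ns$wasserstein_1d(a, b), 2.5, tolerance = 0.02)
  # non-negativity and a numeric triangle-inequality spot check
  c_ <- rnorm(2000, 5, 2)
  wab <- ns$wasserstein_1d(a, b); wbc <- ns$wasserstein_1d(b, c_)
  wac <- ns$wasserstein_1d(a, c_)
  expect_gte(wab, 0)
  expect_lte(wac, wab + wbc + 1e-9)
  expect_gte(ns$kl_histogram(a, b), 0)
})

test_that("distribution similarity is zero for identical populations", {
  set.seed(3)
  df <- data.frame(LVEDV = rnorm(60, 140, 20), LVEF = rnorm(60, 60, 5),
                   age = runif(60, 45, 80), sex = rbinom(60, 1, 0.5))
  sim <- phenotype_distribution_similarity(df, df, by = c("age", "sex"))
  expect_true(all(sim$KL == 0))
  expect_true(all(sim$WD == 0))
  expect_setequal(unique(sim$conditioning), c("age", "sex"))
  shifted <- df
  shifted$LVEDV <- df$LVEDV + 30
  sim2 <- phenotype_distribution_similarity(df, shifted, by = "sex",
                                            phenotypes = "LVEDV")
  expect_gt(mean(sim2$WD), 10)
  expect_error(phenotype_distribution_similarity(df[1:5, ], df), "20")
})

test_that("latent delta is seeded, non-negative and batch-invariant", {
  s <- tiny_sequence(seed = 27)
  st <- tiny_state(s)
  st$trained <- TRUE
  d1 <- latent_delta(st, s, n = 6, seed = 5)
  d2 <- latent_delta(st, s, n = 6, seed = 5)
  expect_identical(d1$delta_z, d2$delta_z)
  expect_gte(d1$delta_z, 0)
  expect_equal(d1$n_reference_samples, 6L)
  # chunked and unchunked reference sampling agree exactly
  r1 <- ns$latent_reference_samples(st, s$condition, 7, seed = 9, chunk = 3)
  r2 <- ns$latent_reference_samples(st, s$condition, 7, seed = 9,
                                    chunk = 100)
  expect_equal(r1, r2, tolerance = 1e-12)
  # n = 1 reduces to the distance to the single reference latent
  dz1 <- latent_delta(st, s, n = 1, seed = 11)$delta_z
  ref <- ns$latent_reference_samples(st, s$condition, 1, seed = 11)
  expect_equal(dz1, sqrt(sum((latent_vector(s, st) - ref[1, ])^2)))
  st$trained <- NULL
  expect_warning(latent_delta(st, s, n = 2, seed = 1), "untrained")
})

test_that("the classification harness separates and stays honest on nulls", {
  set.seed(8)
  n <- 240
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y_sep <- as.integer(x$a > 0)
  res <- classification_harness(x, y_sep, n_splits = 5, seed = 1)
  expect_setequal(unique(res$classifier), c("boost", "lda", "svm"))
  expect_equal(nrow(res), 15L)
  expect_true(all(res$auc[res$classifier != "boost"] > 0.95))
  expect_gt(mean(res$auc), 0.9)
  y_null <- sample(y_sep)
  res0 <- classification_harness(x, y_null, n_splits = 5, seed = 2)
  expect_lt(abs(mean(res0$auc) - 0.5), 0.1)
  expect_error(classification_harness(x, rep(1, n)), "two classes")
})

test_that("the association scan flags true signals and respects Bonferroni", {
  set.seed(9)
  deltas <- data.frame(delta_z = rexp(300))
  outcomes <- data.frame(hit = as.integer(deltas$delta_z >
                                            stats::median(deltas$delta_z)))
  # the threshold outcome is perfectly separable, so glm warns about
  # fitted probabilities of 0/1; that is inherent to the construction
  res <- suppressWarnings(association_scan(deltas, outcomes))
  expect_true(res$significant[res$outcome == "hit"])
  expect_equal(res$effect[res$outcome == "hit"], 1)
  # single outcome: adjusted threshold equals the raw alpha
  expect_equal(attr(res, "n_outcomes"), 1L)
  outcomes$flat <- 1L
  expect_warning(
    res2 <- withCallingHandlers(
      association_scan(deltas, outcomes),
      warning = function(w) {
        if (grepl("glm|probabilities", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    "constant")
  expect_equal(nrow(res2), 1L)
})
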