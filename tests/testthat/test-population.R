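test_that("condition sampling is seeded and matches the cohort model", {
  spec <- tiny_spec()
  c1 <- sample_conditions(spec, 20, seed = 44)
  c2 <- sample_conditions(spec, 20, seed = 44)
  expect_identical(c1, c2)
  expect_error(sample_conditions(spec, 0), ">= 1")
  big <- sample_conditions(spec, 10000, seed = 45)
  sexes <- vapply(big, function(c) c$sex, 0)
  expect_lt(abs(mean(sexes) - 0.5), 0.02)
  ages <- vapply(big, function(c) c$age, 0)
  expect_true(all(ages >= 45 & ages <= 80))
  hts <- vapply(big, function(c) c$height, 0)
  expect_gt(mean(hts[sexes == 1]), mean(hts[sexes == 0]))
})

test_that("ground-truth phenotypes follow the closed-form effect model", {
  spec <- population_spec(edv_base = 90, edv_bsa = 30, edv_sex = 20,
                          edv_age = 0.3, ef_base = 60, ef_age = 2,
                          phenotype_sd = 0)
  co <- condition(60, 0, 70, 162)
  tp <- true_phenotypes(co, spec, noise = FALSE)
  expect_equal(tp$LVEDV, 90 + 30 * sqrt(70 * 162 / 3600))
  expect_equal(tp$LVEDV, 143.2, tolerance = 1e-3)
  tp70 <- true_phenotypes(condition(70, 0, 70, 162), spec, noise = FALSE)
  expect_equal(tp70$LVEF, 58)
  # identical conditions give identical records when noise is off
  expect_identical(tp, true_phenotypes(condition(60, 0, 70, 162), spec,
                                       noise = FALSE))
  expect_equal(tp$LVESV, tp$LVEDV * (1 - tp$LVEF / 100))
  expect_equal(tp$RVEDV, spec$rv_ratio * tp$LVEDV)
})

test_that("generated sequences recover the specified phenotypes", {
  spec <- tiny_spec(T_frames = 10, vertices_per_part = 162)
  co <- sample_conditions(spec, 1, seed = 3)[[1]]
  s <- generate_sequence(co, spec, seed = 5)
  tp <- true_phenotypes(co, spec, noise = FALSE)
  ph <- compute_phenotypes(s)
  expect_equal(ph$LVEDV, tp$LVEDV, tolerance = 0.03)
  expect_equal(ph$LVEF, tp$LVEF, tolerance = 0.03)
  expect_equal(ph$LVM, tp$LVM, tolerance = 0.03)
  expect_equal(ph$RVEDV, tp$RVEDV, tolerance = 0.03)
  # determinism
  s2 <- generate_sequence(co, spec, seed = 5)
  expect_identical(s$frames[[4]]$vertices, s2$frames[[4]]$vertices)
})

test_that("the volume curve starts at ED and dips at the ES fraction", {
  spec <- tiny_spec(T_frames = 20, vertices_per_part = 162)
  s <- tiny_sequence(seed = 6, spec = spec)
  lv <- sequence_volumes(s)[, "LV"]
  expect_equal(which.max(lv), 1L)
  expect_equal(which.min(lv), round(spec$es_fraction * spec$T_frames) + 1L)
  # unimodal: one sign change of the difference sequence
  expect_equal(sum(diff(sign(diff(lv))) != 0), 1L)
})

test_that("the low-EF perturbation halves the ejection fraction", {
  spec <- tiny_spec(T_frames = 10, vertices_per_part = 162)
  co <- sample_conditions(spec, 1, seed = 8)[[1]]
  healthy <- compute_phenotypes(generate_sequence(co, spec, seed = 9))
  sick <- compute_phenotypes(generate_sequence(
    co, spec, seed = 9, disease = disease_spec("low_ef", 1)))
  expect_equal(sick$LVEF, healthy$LVEF / 2, tolerance = 3 / healthy$LVEF)
  dil <- compute_phenotypes(generate_sequence(
    co, spec, seed = 9, disease = disease_spec("dilated", 1)))
  expect_equal(dil$LVEDV, healthy$LVEDV * 1.4, tolerance = 0.03)
  hyp <- compute_phenotypes(generate_sequence(
    co, spec, seed = 9, disease = disease_spec("hypertrophic", 1)))
  expect_equal(hyp$LVM, healthy$LVM * 1.6, tolerance = 0.05)
})

test_that("all generated subjects share one topology", {
  spec <- tiny_spec()
  cs <- sample_conditions(spec, 3, seed = 10)
  seqs <- lapply(1:3, function(i) generate_sequence(cs[[i]], spec, seed = i))
  f0 <- seqs[[1]]$frames[[1]]
  for (s in seqs) {
    for (fr in s$frames) {
      expect_identical(fr$faces, f0$faces)
      expect_identical(fr$part, f0$part)
    }
  }
})

test_that("datasets split, label and serialize reproducibly", {
  spec <- tiny_spec()
  spec$n_subjects <- 20
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  t1 <- make_dataset(spec, d1, splits = c(train = 0.6, val = 0.2,
                                          test = 0.2),
                     disease_prevalence = 0, seed = 5)
  expect_equal(as.vector(table(t1$split)[c("train", "val", "test")]),
               c(12L, 4L, 4L))
  expect_true(all(t1$label == "healthy"))
  t2 <- make_dataset(spec, d2, splits = c(train = 0.6, val = 0.2,
                                          test = 0.2),
                     disease_prevalence = 0, seed = 5)
  expect_identical(readLines(file.path(d1, "dataset.csv")),
                   readLines(file.path(d2, "dataset.csv")))
  expect_error(make_dataset(spec, d1, splits = c(train = 0.7, test = 0.2)),
               "sum to 1")
  # diseased subjects never land in the training split
  d3 <- withr::local_tempdir()
  t3 <- make_dataset(spec, d3, disease_prevalence = 0.8, seed = 6)
  expect_true(all(t3$label[t3$split == "train"] == "healthy"))
  expect_gt(sum(t3$label != "healthy"), 0)
  ds <- load_dataset(d3, split = "test")
  expect_equal(nrow(ds$table), 4L)
  expect_length(ds$sequences, 4L)
})

test_that("noise-free specified and measured phenotypes correlate tightly", {
  spec <- tiny_spec(T_frames = 6, vertices_per_part = 96)
  spec$n_subjects <- 15
  cs <- sample_conditions(spec, spec$n_subjects, seed = 12)
  tp <- do.call(rbind, lapply(cs, true_phenotypes, spec = spec,
                              noise = FALSE))
  ph <- do.call(rbind, lapply(seq_along(cs), function(i) {
    compute_phenotypes(generate_sequence(cs[[i]], spec, seed = 100 + i))
  }))
  expect_gt(cor(tp$LVEDV, ph$LVEDV), 0.98)
  expect_gt(cor(tp$LVEF, ph$LVEF), 0.98)
})
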