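ns <- asNamespace("cardiomesh")

test_that("positional encoding follows the sinusoidal definition", {
  p0 <- positional_encoding(0, 8)
  expect_equal(p0, rep(c(0, 1), 4))
  p1 <- positional_encoding(1, 64)
  expect_equal(p1[1], sin(1))
  expect_equal(p1[2], cos(1))
  expect_equal(p1[3], sin(1 / 10000^(2 / 64)))
  pm <- positional_encoding(0:500, 32)
  expect_true(all(pm >= -1 & pm <= 1))
  expect_equal(dim(pm), c(501L, 32L))
  expect_error(positional_encoding(0, 7))
})

test_that("encoders produce latents of the configured dimensions", {
  s <- tiny_sequence(seed = 15)
  st <- tiny_state(s)
  z_c <- condition_encode(s$condition, st)
  expect_length(z_c, 32L)
  expect_identical(z_c, condition_encode(s$condition, st))
  z0 <- mesh_encode(s$frames[[1]], st)
  expect_length(z0, 64L)
  expect_identical(z0, mesh_encode(s$frames[[1]], st))
  # identical frames map to identical latents
  expect_identical(mesh_encode(s$frames[[1]], st),
                   mesh_encode(s$frames[[1]], st))
  g <- temporal_encode(matrix(rnorm(6 * 64), 6), z_c, st)
  expect_length(g$mu, 64L)
  expect_length(g$log_sigma, 64L)
})

test_that("the transformer encoder sees T + 2 tokens", {
  s <- tiny_sequence(seed = 16)
  st <- tiny_state(s)
  tape <- ns$ad_tape()
  enc <- ns$encode_sequence(tape, st, s)
  expect_equal(nrow(ns$ad_value(enc$enc_out)), length(s$frames) + 2L)
  expect_equal(ncol(ns$ad_value(enc$enc_out)),
               st$config$d_latent + st$config$d_condition)
})

test_that("mesh encoding is invariant to consistent vertex permutation", {
  s <- tiny_sequence(seed = 17)
  st <- tiny_state(s)
  m <- s$frames[[1]]
  set.seed(31)
  perm <- sample(nrow(m$vertices))
  inv <- order(perm)
  m2 <- m
  m2$vertices <- m$vertices[perm, , drop = FALSE]
  m2$faces <- matrix(inv[m$faces], ncol = 3L)
  m2$part <- m$part[perm]
  expect_equal(mesh_encode(m2, st), mesh_encode(m, st), tolerance = 1e-10)
})

test_that("temporal decoding and mesh decoding respect shape contracts", {
  s <- tiny_sequence(seed = 18)
  st <- tiny_state(s)
  z_c <- condition_encode(s$condition, st)
  z_a <- rnorm(64)
  FZ <- temporal_decode(z_a, z_c, 7, st)
  expect_equal(dim(FZ), c(7L, 64L))
  expect_identical(FZ, temporal_decode(z_a, z_c, 7, st))
  v <- mesh_decode(rnorm(64), st, z_c)
  expect_equal(dim(v), c(st$V, 3L))
  expect_true(all(is.finite(v)))
})

test_that("reconstruction is deterministic and preserves the contract", {
  s <- tiny_sequence(seed = 19)
  st <- tiny_state(s)
  r1 <- reconstruct(s, st)
  r2 <- reconstruct(s, st)
  expect_equal(length(r1$frames), length(s$frames))
  expect_identical(r1$frames[[3]]$vertices, r2$frames[[3]]$vertices)
  expect_identical(r1$frames[[1]]$faces, s$frames[[1]]$faces)
  expect_true(all(is.finite(r1$frames[[1]]$vertices)))
  # a sequence on a different template is rejected
  other <- tiny_sequence(seed = 20, spec = tiny_spec(vertices_per_part = 48))
  expect_error(reconstruct(other, st), "topology")
})

test_that("generation is seeded and shares the template topology", {
  s <- tiny_sequence(seed = 21)
  st <- tiny_state(s)
  g1 <- generate(s$condition, 5, seed = 77, st)
  g2 <- generate(s$condition, 5, seed = 77, st)
  expect_length(g1, 5L)
  expect_identical(g1[[4]]$frames[[2]]$vertices,
                   g2[[4]]$frames[[2]]$vertices)
  expect_false(identical(g1[[1]]$frames[[1]]$vertices,
                         g1[[2]]$frames[[1]]$vertices))
  expect_identical(g1[[1]]$frames[[1]]$faces, s$frames[[1]]$faces)
})

test_that("the latent vector is a deterministic 64-d sequence descriptor", {
  s <- tiny_sequence(seed = 22)
  st <- tiny_state(s)
  z <- latent_vector(s, st)
  expect_length(z, 64L)
  expect_identical(z, latent_vector(s, st))
})

test_that("checkpoints round-trip the model state", {
  s <- tiny_sequence(seed = 23)
  st <- tiny_state(s)
  st$trained <- TRUE
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  st2 <- load_checkpoint(path)
  expect_equal(st2$params, st$params)
  expect_equal(st2$topo_hash, st$topo_hash)
  expect_identical(reconstruct(s, st2)$frames[[1]]$vertices,
                   reconstruct(s, st)$frames[[1]]$vertices)
  # saving the loaded state again is idempotent
  path2 <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st2, path2)
  expect_equal(load_checkpoint(path2)$params, st$params)
})

test_that("parameter count at cohort scale is near the expected magnitude", {
  cnt <- sum(vapply(ns$init_parameters(model_config(), 22043L), length, 0L))
  expect_gt(cnt / 1e6, 65)
  expect_lt(cnt / 1e6, 75)
})
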