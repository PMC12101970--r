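test_that("surface distances match hand-computed values", {
  a2 <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(chamfer_distance(a2, a2), 0)
  expect_equal(chamfer_distance(c(0, 0, 0), c(3, 0, 0)), 6)
  expect_equal(chamfer_distance(rbind(c(0, 0, 0), c(2, 0, 0)),
                                c(1, 0, 0)), 2)
  expect_equal(hausdorff_distance(a2, a2), 0)
  expect_equal(hausdorff_distance(c(0, 0, 0), c(5, 0, 0)), 5)
  expect_equal(hausdorff_distance(rbind(c(0, 0, 0), c(1, 0, 0)),
                                  c(0, 0, 0)), 1)
  expect_equal(assd(a2, a2), 0)
  expect_equal(assd(c(0, 0, 0), c(4, 0, 0)), 4)
  expect_equal(assd(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0)), 1)
})

test_that("surface distances agree with the exhaustive pairwise oracle", {
  set.seed(42)
  for (k in 1:25) {
    a <- matrix(rnorm(3 * sample(2:60, 1), sd = 20), ncol = 3)
    b <- matrix(rnorm(3 * sample(2:60, 1), sd = 20), ncol = 3)
    expect_equal(chamfer_distance(a, b), oracle_chamfer(a, b),
                 tolerance = 1e-12)
    expect_equal(hausdorff_distance(a, b), oracle_hausdorff(a, b),
                 tolerance = 1e-12)
    expect_equal(assd(a, b), oracle_assd(a, b), tolerance = 1e-12)
  }
})

test_that("surface distances are symmetric, non-negative, zero iff equal", {
  set.seed(7)
  for (k in 1:10) {
    a <- matrix(runif(30, -10, 10), ncol = 3)
    b <- matrix(runif(45, -10, 10), ncol = 3)
    for (f in list(chamfer_distance, hausdorff_distance, assd)) {
      expect_equal(f(a, b), f(b, a))
      expect_gte(f(a, b), 0)
      expect_gt(f(a, b), 0)   # disjoint random sets differ a.s.
      expect_equal(f(a, a[sample(nrow(a)), ]), 0)  # equal as sets
    }
  }
  expect_error(chamfer_distance(matrix(0, 0, 3), c(0, 0, 0)), "empty")
})

test_that("laplacian smoothness matches the per-vertex definition", {
  # path graph on collinear points 0, 1, 2: end vertices have offset 1,
  # middle vertex 0, so the mean is 2/3
  v <- cbind(c(0, 1, 2), 0, 0)
  e <- rbind(c(1L, 2L), c(2L, 3L))
  expect_equal(laplacian_smoothness(v, e), 2 / 3)
  expect_equal(laplacian_smoothness(matrix(5, 4, 3),
                                    rbind(c(1L, 2L), c(2L, 3L),
                                          c(3L, 4L), c(4L, 1L))), 0)
})

test_that("laplacian smoothness is translation-invariant and scales linearly", {
  set.seed(9)
  m <- icosphere(10, 1)
  e <- mesh_edges(m$faces)
  v <- m$vertices + matrix(rnorm(length(m$vertices)), ncol = 3)
  s0 <- laplacian_smoothness(v, e)
  expect_equal(laplacian_smoothness(sweep(v, 2, c(5, -3, 11), "+"), e), s0)
  expect_equal(laplacian_smoothness(v * 2.5, e), 2.5 * s0)
  expect_error(laplacian_smoothness(v, rbind(c(1L, 2L))), "isolated")
})

test_that("enclosed volume is exact on the cube and accurate on the sphere", {
  cb <- cube_mesh(10)
  expect_equal(enclosed_volume(cb$vertices, cb$faces), 1)
  ic <- icosphere(10, 3)
  expect_equal(enclosed_volume(ic$vertices, ic$faces), 4 * pi / 3,
               tolerance = 0.02)
  # degenerate flat surface encloses nothing
  flat <- cb
  flat$vertices[, 3] <- 0
  expect_equal(enclosed_volume(flat$vertices, flat$faces), 0)
})

test_that("enclosed volume is rigid-motion invariant and additive", {
  ic <- icosphere(8, 2)
  v0 <- enclosed_volume(ic$vertices, ic$faces)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  vr <- sweep(ic$vertices %*% R, 2, c(12, -4, 7), "+")
  expect_equal(enclosed_volume(vr, ic$faces), v0, tolerance = 1e-9)
  # two disjoint closed surfaces in one face set add their volumes
  cb <- cube_mesh(10)
  verts <- rbind(ic$vertices, cb$vertices + 100)
  faces <- rbind(ic$faces, cb$faces + nrow(ic$vertices))
  expect_equal(enclosed_volume(verts, faces), v0 + 1, tolerance = 1e-9)
  # open surface rejected
  expect_error(enclosed_volume(cb$vertices, cb$faces[-1, ]), "open")
})
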