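# Finite-difference verification of the loss terms and of the network
# gradients (through a smooth readout of the decoded coordinates, so the
# check is not confounded by nearest-neighbour reassignment in the Chamfer
# subgradient).

ns <- asNamespace("cardiomesh")

test_that("chamfer loss gradient matches finite differences", {
  set.seed(1)
  V <- 12L; Tn <- 3L
  target <- matrix(rnorm(Tn * V * 3, sd = 10), ncol = 3)
  pred0 <- target + matrix(rnorm(Tn * V * 3, sd = 2), ncol = 3)
  loss_of <- function(pv) {
    tape <- ns$ad_tape()
    node <- ns$ad_node(tape, pv)
    drop(ns$ad_value(ns$ad_chamfer_frames(tape, node, target, V)))
  }
  tape <- ns$ad_tape()
  node <- ns$ad_node(tape, pred0)
  loss <- ns$ad_chamfer_frames(tape, node, target, V)
  ns$ad_backward(tape, loss)
  h <- 1e-6
  for (ij in sample(length(pred0), 12)) {
    pp <- pred0; pp[ij] <- pp[ij] + h
    pm <- pred0; pm[ij] <- pm[ij] - h
    fd <- (loss_of(pp) - loss_of(pm)) / (2 * h)
    expect_equal(node$grad[ij], fd, tolerance = 1e-3)
  }
})

test_that("laplacian loss gradient matches finite differences", {
  set.seed(2)
  s <- tiny_sequence(seed = 4, spec = tiny_spec(T_frames = 2))
  st <- tiny_state(s)
  coords0 <- ns$stack_frames(s) + matrix(rnorm(2 * st$V * 3), ncol = 3)
  loss_of <- function(pv) {
    tape <- ns$ad_tape()
    node <- ns$ad_node(tape, pv)
    drop(ns$ad_value(ns$ad_laplacian_frames(tape, node, st$ops$Mbig)))
  }
  tape <- ns$ad_tape()
  node <- ns$ad_node(tape, coords0)
  loss <- ns$ad_laplacian_frames(tape, node, st$ops$Mbig)
  ns$ad_backward(tape, loss)
  h <- 1e-6
  for (ij in sample(length(coords0), 10)) {
    pp <- coords0; pp[ij] <- pp[ij] + h
    pm <- coords0; pm[ij] <- pm[ij] - h
    fd <- (loss_of(pp) - loss_of(pm)) / (2 * h)
    expect_equal(node$grad[ij], fd, tolerance = 1e-3)
  }
})

test_that("KL loss gradient matches finite differences and closed form", {
  set.seed(3)
  mu0 <- matrix(rnorm(8), 1); lv0 <- matrix(rnorm(8, sd = 0.3), 1)
  kl_of <- function(mu, lv) {
    tape <- ns$ad_tape()
    drop(ns$ad_value(ns$ad_kl_gaussian(tape, ns$ad_node(tape, mu),
                                       ns$ad_node(tape, lv), 0.01)))
  }
  expect_equal(kl_of(mu0, lv0),
               0.01 * 0.5 * sum(exp(2 * lv0) + mu0^2 - 1 - 2 * lv0))
  tape <- ns$ad_tape()
  nmu <- ns$ad_node(tape, mu0); nlv <- ns$ad_node(tape, lv0)
  loss <- ns$ad_kl_gaussian(tape, nmu, nlv, 0.01)
  ns$ad_backward(tape, loss)
  h <- 1e-7
  for (j in 1:8) {
    mp <- mu0; mp[j] <- mp[j] + h; mm <- mu0; mm[j] <- mm[j] - h
    expect_equal(nmu$grad[j], (kl_of(mp, lv0) - kl_of(mm, lv0)) / (2 * h),
                 tolerance = 1e-3)
    lp <- lv0; lp[j] <- lp[j] + h; lm <- lv0; lm[j] <- lm[j] - h
    expect_equal(nlv$grad[j], (kl_of(mu0, lp) - kl_of(mu0, lm)) / (2 * h),
                 tolerance = 1e-3)
  }
})

test_that("end-to-end network gradients are exact under a smooth readout", {
  set.seed(4)
  s <- tiny_sequence(seed = 9, spec = tiny_spec(T_frames = 4))
  st <- tiny_state(s)
  target <- ns$stack_frames(s)
  cin <- ns$condition_input(s$condition, st$norm)
  Wfix <- matrix(sin(seq_len(length(target))), nrow(target))
  step <- function(params) {
    st2 <- st; st2$params <- params
    tape <- ns$ad_tape(training = TRUE)
    p <- lapply(st2$params, function(w) ns$ad_node(tape, w))
    z_c <- ns$fwd_condition(tape, p, cin)
    Z <- ns$fwd_mesh_encode(tape, p, target, st2$ops)
    enc <- ns$fwd_temporal_encode(tape, p, Z, z_c, st2$config)
    eps <- matrix(seq(-1, 1, length.out = st2$config$d_latent), 1)
    z_a <- ns$ad_add(tape, enc$mu,
                     ns$ad_mul(tape, eps, ns$ad_exp(tape, enc$log_sigma)))
    FZ <- ns$fwd_temporal_decode(tape, p, z_a, z_c, st2$config, st2$ops$pe)
    coords <- ns$fwd_mesh_decode(tape, p, FZ, z_c, st2$config, st2$V,
                                 st2$base_coords)
    cv <- ns$ad_value(coords)
    loss <- ns$ad_node(tape, matrix(sum(cv * Wfix), 1, 1),
                       function(g) ns$ad_acc(coords, Wfix * as.vector(g)))
    kl <- ns$ad_kl_gaussian(tape, enc$mu, enc$log_sigma, 0.01)
    tot <- ns$ad_add(tape, loss, kl)
    ns$ad_backward(tape, tot)
    list(loss = drop(ns$ad_value(tot)),
         grads = lapply(p, function(n) n$grad))
  }
  base <- step(st$params)
  h <- 1e-6
  picks <- c("gcn.W2", "cond.W1", "tok.mu", "tok.sigma", "enc1.sa.Wq",
             "enc2.ff.b2", "head.Wmu", "head.Wsig", "pe.Wp", "dec1.ca.Wk",
             "dec2.ff.b2", "frame.Wf", "mdec.W1", "mdec.W5", "mdec.b5")
  for (nm in picks) {
    w <- st$params[[nm]]
    for (ij in sample(length(w), 2)) {
      pp <- st$params; pp[[nm]] <- w + 0; pp[[nm]][ij] <- w[ij] + h
      pm <- st$params; pm[[nm]] <- w + 0; pm[[nm]][ij] <- w[ij] - h
      fd <- (step(pp)$loss - step(pm)$loss) / (2 * h)
      an <- base$grads[[nm]][ij]
      expect_equal(an, fd, tolerance = 1e-3,
                   label = sprintf("grad of %s[%d]", nm, ij))
    }
  }
})

test_that("reparameterization recovers the Gaussian moments", {
  g <- list(mu = c(0.5, -1, 2), log_sigma = c(log(0.5), 0, log(2)))
  expect_equal(reparameterize(g, epsilon = rep(0, 3))$z_a, g$mu)
  set.seed(10)
  draws <- t(replicate(1e5, reparameterize(g)$z_a))
  expect_equal(colMeans(draws), g$mu, tolerance = 0.02)
  expect_equal(apply(draws, 2, sd), exp(g$log_sigma), tolerance = 0.02)
})
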