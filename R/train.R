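#' Training configuration
#'
#' @param beta weight of the KL term (0.01).
#' @param lambda_s weight of the Laplacian smoothness term (1).
#' @param learning_rate fixed Adam learning rate (1e-4; no schedule, no
#'   weight decay).
#' @param epochs training epochs (desk default 50; cohort-scale 300).
#' @param seed integer seed covering parameter initialization, data order
#'   and the reparameterization noise.
#' @param clip_grad optional global gradient-norm clip (off by default; the
#'   optimizer runs unclipped with a fixed learning rate).
#' @param checkpoint_every write a checkpoint every this many epochs (0 =
#'   only at the end when `checkpoint_dir` is set).
#' @param checkpoint_dir optional directory for checkpoints.
#' @param validate_every compute mean validation ASSD every this many epochs
#'   (0 = never).
#' @return An object of class `train_config`.
#' @export
train_config <- function(beta = 0.01, lambda_s = 1, learning_rate = 1e-4,
                         epochs = 50L, seed = 1L, clip_grad = NULL,
                         checkpoint_every = 0L, checkpoint_dir = NULL,
                         validate_every = 0L) {
  stopifnot(beta >= 0, lambda_s >= 0, learning_rate > 0, epochs >= 0)
  structure(list(beta = beta, lambda_s = lambda_s,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), clip_grad = clip_grad,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir,
                 validate_every = as.integer(validate_every)),
            class = "train_config")
}

#' Loss components
#'
#' `loss_reconstruction()` is the mean over frames of the Chamfer distance
#' between the predicted and target vertex sets; `loss_kl()` the
#' beta-weighted KL divergence of the diagonal latent Gaussian from the
#' standard normal prior; `loss_smooth()` the mean over frames of the
#' Laplacian smoothness of the predicted meshes; `total_loss()` the weighted
#' sum `L_R + L_KL + lambda_s * L_S`.
#'
#' @param pred,target [mesh_sequence()] objects with equal frame counts.
#' @return a single number.
#' @export
loss_reconstruction <- function(pred, target) {
  if (length(pred$frames) != length(target$frames)) {
    stop("frame count mismatch")
  }
  mean(vapply(seq_along(pred$frames), function(t) {
    chamfer_distance(pred$frames[[t]]$vertices, target$frames[[t]]$vertices)
  }, 0))
}

#' @rdname loss_reconstruction
#' @param g list with `mu` and `log_sigma` (scale = `exp(log_sigma)`).
#' @param beta KL weight.
#' @export
loss_kl <- function(g, beta = 0.01) {
  lv <- g$log_sigma
  beta * 0.5 * sum(exp(2 * lv) + g$mu^2 - 1 - 2 * lv)
}

#' @rdname loss_reconstruction
#' @export
loss_smooth <- function(pred) {
  edges <- mesh_edges(pred$frames[[1L]])
  mean(vapply(pred$frames, function(f) {
    laplacian_smoothness(f$vertices, edges)
  }, 0))
}

#' @rdname loss_reconstruction
#' @param L_R,L_KL,L_S loss components.
#' @param cfg a [train_config()] (for `lambda_s`).
#' @export
total_loss <- function(L_R, L_KL, L_S, cfg = train_config()) {
  L_R + L_KL + cfg$lambda_s * L_S
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, opt, lr, clip = NULL) {
  if (!is.null(clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
    if (gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  }
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    adam_update_inplace(params[[nm]], g, opt$m[[nm]], opt$v[[nm]],
                        lr, opt$beta1, opt$beta2, opt$eps, c1, c2)
  }
  list(params = params, opt = opt)
}

# one training step on one sequence; returns losses and parameter grads
training_step <- function(state, target_coords, cin, cfg) {
  tape <- ad_tape(training = TRUE)
  p <- lapply(state$params, function(w) ad_node(tape, w))
  z_c <- fwd_condition(tape, p, cin)
  Z <- fwd_mesh_encode(tape, p, target_coords, state$ops)
  enc <- fwd_temporal_encode(tape, p, Z, z_c, state$config)
  eps <- matrix(stats::rnorm(state$config$d_latent), 1L)
  z_a <- ad_add(tape, enc$mu,
                ad_mul(tape, eps, ad_exp(tape, enc$log_sigma)))
  FZ <- fwd_temporal_decode(tape, p, z_a, z_c, state$config, state$ops$pe)
  coords <- fwd_mesh_decode(tape, p, FZ, z_c, state$config, state$V,
                            state$base_coords)
  L_R <- ad_chamfer_frames(tape, coords, target_coords, state$V)
  L_KL <- ad_kl_gaussian(tape, enc$mu, enc$log_sigma, cfg$beta)
  L_S <- ad_laplacian_frames(tape, coords, state$ops$Mbig)
  total <- ad_add(tape, ad_add(tape, L_R, L_KL),
                  ad_scale(tape, L_S, cfg$lambda_s))
  ad_backward(tape, total)
  grads <- lapply(p, function(n) n$grad)
  list(L_R = drop(ad_value(L_R)), L_KL = drop(ad_value(L_KL)),
       L_S = drop(ad_value(L_S)), L_total = drop(ad_value(total)),
       grads = grads)
}

#' Train the conditional mesh-sequence model
#'
#' Adam with a fixed learning rate and a batch of one mesh sequence per
#' step, on the healthy training split only. Fully seeded: parameter
#' initialization, the shuffling of subjects within each epoch and the
#' reparameterization noise all derive from `train_cfg$seed`, so repeated
#' runs give bitwise-identical loss reports.
#'
#' @param data either a dataset directory created by [make_dataset()] or a
#'   list with elements `sequences` (named list of [mesh_sequence()]) and
#'   `table` (the dataset data.frame).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param val_sequences optional list of held-out sequences used when
#'   `validate_every > 0`.
#' @param quiet suppress progress messages.
#' @return list with `state` (the trained [mesh_model()]) and `report`
#'   (per-step data.frame with columns `step`, `epoch`, `L_R`, `L_KL`,
#'   `L_S`, `L_total`) plus `val` (per-epoch validation ASSD, if computed).
#' @export
train <- function(data, model_cfg = model_config(),
                  train_cfg = train_config(), val_sequences = NULL,
                  quiet = TRUE) {
  if (is.character(data)) data <- load_dataset(data)
  tab <- data$table
  train_ids <- tab$subject_id[tab$split == "train" & tab$label == "healthy"]
  if (length(train_ids) == 0L) stop("empty (healthy) training split")
  seqs <- data$sequences[train_ids]
  conds <- lapply(seqs, function(s) s$condition)
  Tn <- length(seqs[[1L]]$frames)

  state <- model_init(model_cfg, seqs[[1L]]$frames[[1L]], Tn, conds,
                      seed = train_cfg$seed)
  targets <- lapply(seqs, stack_frames)
  cins <- lapply(conds, condition_input, norm = state$norm)

  old <- .Random.seed_exists()
  set.seed(train_cfg$seed + 1L)
  on.exit(.restore_seed(old), add = TRUE)

  if (!is.null(train_cfg$checkpoint_dir) &&
      !dir.exists(train_cfg$checkpoint_dir)) {
    dir.create(train_cfg$checkpoint_dir, recursive = TRUE)
  }
  opt <- adam_init(state$params)
  n <- length(seqs)
  report <- vector("list", train_cfg$epochs * n)
  val_log <- list()
  step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    for (i in sample.int(n)) {
      res <- training_step(state, targets[[i]], cins[[i]], train_cfg)
      if (!is.finite(res$L_total)) {
        stop(sprintf("divergence: non-finite loss at step %d", step + 1L))
      }
      upd <- adam_step(state$params, res$grads, opt,
                       train_cfg$learning_rate, train_cfg$clip_grad)
      state$params <- upd$params
      opt <- upd$opt
      step <- step + 1L
      report[[step]] <- data.frame(step = step, epoch = epoch,
                                   L_R = res$L_R, L_KL = res$L_KL,
                                   L_S = res$L_S, L_total = res$L_total)
    }
    if (train_cfg$validate_every > 0L && !is.null(val_sequences) &&
        epoch %% train_cfg$validate_every == 0L) {
      v <- mean(vapply(val_sequences, function(s) {
        mean_sequence_assd(s, reconstruct(s, state))
      }, 0))
      val_log[[length(val_log) + 1L]] <- data.frame(epoch = epoch,
                                                    val_assd = v)
      if (!quiet) message(sprintf("epoch %d: val ASSD %.3f mm", epoch, v))
    }
    if (!is.null(train_cfg$checkpoint_dir) &&
        train_cfg$checkpoint_every > 0L &&
        epoch %% train_cfg$checkpoint_every == 0L) {
      save_checkpoint(state, file.path(
        train_cfg$checkpoint_dir, sprintf("epoch_%04d.rds", epoch)))
    }
  }
  state$trained <- train_cfg$epochs > 0L
  if (!is.null(train_cfg$checkpoint_dir)) {
    if (!dir.exists(train_cfg$checkpoint_dir)) {
      dir.create(train_cfg$checkpoint_dir, recursive = TRUE)
    }
    save_checkpoint(state, file.path(train_cfg$checkpoint_dir, "final.rds"))
  }
  list(state = state,
       report = if (step > 0L) do.call(rbind, report[seq_len(step)])
                else data.frame(step = integer(), epoch = integer(),
                                L_R = numeric(), L_KL = numeric(),
                                L_S = numeric(), L_total = numeric()),
       val = if (length(val_log)) do.call(rbind, val_log) else NULL)
}

# mean vertex-to-vertex ASSD over frames between two aligned sequences
mean_sequence_assd <- function(a, b) {
  mean(vapply(seq_along(a$frames), function(t) {
    assd(a$frames[[t]]$vertices, b$frames[[t]]$vertices)
  }, 0))
}
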