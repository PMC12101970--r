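#' Model architecture configuration
#'
#' Hyperparameters of the conditional spatio-temporal mesh VAE: a
#' graph-convolutional mesh encoder (three graph-convolution layers and one
#' fully connected layer, mean-pooled over vertices), a temporal transformer
#' encoder with two learnable distribution parameter tokens, a transformer
#' decoder queried by sinusoidal temporal positional encodings, and a
#' five-layer fully connected mesh decoder. Every transformer token is the
#' 64-d frame latent concatenated with the 32-d condition latent, so the
#' attention width is 96.
#'
#' @param d_latent frame/sequence latent dimension (64).
#' @param d_condition condition latent dimension (32).
#' @param gcn_hidden hidden widths of the three graph-convolution layers.
#' @param decoder_hidden hidden widths of the mesh decoder; with the input
#'   and output this gives the five fully connected layers
#'   `96 -> 256 -> 512 -> 1024 -> 1024 -> 3V`.
#' @param n_layers transformer layers in encoder and decoder (2 each).
#' @param n_heads attention heads (4); must divide the attention width.
#' @param d_ff transformer feed-forward size (1024).
#' @param dropout dropout rate applied during training (0.1).
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_latent = 64L, d_condition = 32L,
                         gcn_hidden = c(64L, 64L, 64L),
                         decoder_hidden = c(256L, 512L, 1024L, 1024L),
                         n_layers = 2L, n_heads = 4L, d_ff = 1024L,
                         dropout = 0.1) {
  stopifnot(d_latent > 0, d_condition > 0, length(gcn_hidden) == 3L,
            (d_latent + d_condition) %% n_heads == 0L)
  structure(list(d_latent = as.integer(d_latent),
                 d_condition = as.integer(d_condition),
                 gcn_hidden = as.integer(gcn_hidden),
                 decoder_hidden = as.integer(decoder_hidden),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_ff = as.integer(d_ff), dropout = dropout),
            class = "model_config")
}

#' Sinusoidal temporal positional encoding
#'
#' `p_t[i] = sin(t / 10000^(2k/d))` for even dimension index `i = 2k` and
#' `cos(t / 10000^(2k/d))` for odd `i = 2k + 1` (indices 0-based), so frame
#' 0 encodes as alternating 0 and 1.
#'
#' @param t non-negative frame index (0-based); may be a vector.
#' @param d even encoding dimension.
#' @return a `length(t) x d` matrix (a plain vector if one frame).
#' @export
positional_encoding <- function(t, d) {
  stopifnot(all(t >= 0), d %% 2L == 0L)
  k <- rep(seq_len(d %/% 2L) - 1L, each = 2L)
  freq <- 1 / 10000^(2 * k / d)
  out <- t(vapply(t, function(ti) {
    ang <- ti * freq
    ifelse(seq_len(d) %% 2L == 1L, sin(ang), cos(ang))
  }, numeric(d)))
  if (length(t) == 1L) drop(out) else out
}

# ---- parameter initialization -------------------------------------------

glorot <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -l, l), n_in, n_out)
}

zeros_row <- function(k) matrix(0, 1L, k)
ones_row <- function(k) matrix(1, 1L, k)

attn_params <- function(dm) {
  list(Wq = glorot(dm, dm), bq = zeros_row(dm),
       Wk = glorot(dm, dm), bk = zeros_row(dm),
       Wv = glorot(dm, dm), bv = zeros_row(dm),
       Wo = glorot(dm, dm), bo = zeros_row(dm))
}

block_params <- function(dm, d_ff, cross = FALSE) {
  p <- list(ln1.g = ones_row(dm), ln1.b = zeros_row(dm), sa = attn_params(dm))
  if (cross) {
    p$ln2.g <- ones_row(dm); p$ln2.b <- zeros_row(dm)
    p$ca <- attn_params(dm)
  }
  p$ln3.g <- ones_row(dm); p$ln3.b <- zeros_row(dm)
  p$ff.W1 <- glorot(dm, d_ff); p$ff.b1 <- zeros_row(d_ff)
  p$ff.W2 <- glorot(d_ff, dm); p$ff.b2 <- zeros_row(dm)
  p
}

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_params(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

init_parameters <- function(cfg, V) {
  dl <- cfg$d_latent; dc <- cfg$d_condition; dm <- dl + dc
  gh <- cfg$gcn_hidden
  p <- list(
    cond = list(W1 = glorot(5L, dc), b1 = zeros_row(dc),
                W2 = glorot(dc, dc), b2 = zeros_row(dc)),
    gcn = list(W1 = glorot(3L, gh[1L]), b1 = zeros_row(gh[1L]),
               W2 = glorot(gh[1L], gh[2L]), b2 = zeros_row(gh[2L]),
               W3 = glorot(gh[2L], gh[3L]), b3 = zeros_row(gh[3L]),
               Wfc = glorot(gh[3L], dl), bfc = zeros_row(dl)),
    tok = list(mu = matrix(stats::rnorm(dl, 0, 0.02), 1L),
               sigma = matrix(stats::rnorm(dl, 0, 0.02), 1L)),
    head = list(Wmu = glorot(dm, dl), bmu = zeros_row(dl),
                Wsig = glorot(dm, dl), bsig = zeros_row(dl)),
    pe = list(Wp = glorot(dl, dm), bp = zeros_row(dm)),
    frame = list(Wf = glorot(dm, dl), bf = zeros_row(dl))
  )
  for (l in seq_len(cfg$n_layers)) {
    p[[paste0("enc", l)]] <- block_params(dm, cfg$d_ff, cross = FALSE)
    p[[paste0("dec", l)]] <- block_params(dm, cfg$d_ff, cross = TRUE)
  }
  widths <- c(dm, cfg$decoder_hidden, 3L * V)
  md <- list()
  for (k in seq_len(length(widths) - 1L)) {
    md[[paste0("W", k)]] <- glorot(widths[k], widths[k + 1L])
    md[[paste0("b", k)]] <- zeros_row(widths[k + 1L])
  }
  p$mdec <- md
  flatten_params(p)
}

topology_checksum <- function(faces) {
  f <- as.double(faces)
  sum(f * (seq_along(f) %% 97 + 1)) + nrow(faces) * 1e-3
}

#' Initialize a model state
#'
#' Builds the trainable parameters (Glorot fan-based initialization;
#' distribution tokens drawn from N(0, 0.02^2)) together with the fixed
#' template topology, precomputed graph operators and the condition
#' normalization constants.
#'
#' @param cfg a [model_config()].
#' @param template a [labelled_mesh()] fixing the topology (e.g. the first
#'   training frame).
#' @param T_frames frames per sequence.
#' @param conditions list of [condition()] used to compute the z-scoring
#'   statistics of the continuous conditions (age, weight, height).
#' @param seed integer seed for parameter initialization.
#' @return An object of class `mesh_model`.
#' @export
model_init <- function(cfg, template, T_frames, conditions, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  V <- nrow(template$vertices)
  params <- init_parameters(cfg, V)
  cm <- vapply(conditions, function(cc) {
    c(cc$age, cc$weight, cc$height)
  }, numeric(3L))
  sds <- apply(cm, 1L, stats::sd)
  sds[!is.finite(sds) | sds < 1e-6] <- 1   # degenerate cohorts: no scaling
  norm <- list(mean = rowMeans(cm), sd = sds)
  state <- structure(
    list(params = params, config = cfg,
         T_frames = as.integer(T_frames), V = V,
         base_coords = template$vertices,
         template = list(faces = template$faces, part = template$part,
                         part_faces = template$part_faces),
         norm = norm,
         topo_hash = topology_checksum(template$faces),
         version = "cardiomesh-checkpoint-1"),
    class = "mesh_model"
  )
  state$ops <- model_operators(state)
  state
}

# fixed sparse operators reused by every forward pass
model_operators <- function(state) {
  edges <- mesh_edges(state$template$faces)
  V <- state$V; Tn <- state$T_frames
  A <- gcn_operator(edges, V)
  M <- neighbour_mean_operator(edges, V)
  Mbig <- Matrix::bdiag(rep(list(M), Tn))
  list(A1 = csc_operator(A), Mbig = csc_operator(Mbig),
       pe = positional_encoding(seq_len(Tn) - 1L, state$config$d_latent))
}

#' @export
print.mesh_model <- function(x, ...) {
  cat(sprintf(
    "<mesh_model> V=%d, T=%d, %s parameters%s\n",
    x$V, x$T_frames,
    format(model_parameter_count(x), big.mark = ","),
    if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Total number of trainable parameters
#' @param state a [mesh_model()] state.
#' @return integer count.
#' @export
model_parameter_count <- function(state) {
  sum(vapply(state$params, length, 0L))
}

# ---- forward passes (tape level) ----------------------------------------

# normalized condition input: z-scored age/weight/height + one-hot sex
condition_input <- function(c, norm) {
  z <- (c(c$age, c$weight, c$height) - norm$mean) / norm$sd
  matrix(c(z, 1 - c$sex, c$sex), 1L)
}

fwd_condition <- function(tape, p, cin) {
  h <- ad_linear(tape, cin, p$cond.W1, p$cond.b1, relu = TRUE)
  ad_linear(tape, h, p$cond.W2, p$cond.b2)
}

# X: (T*V) x 3 coordinate matrix (data, not a node) -> T x d_latent frame
# latents; the three graph-convolution layers run as one fused kernel
fwd_mesh_encode <- function(tape, p, X, ops) {
  pooled <- ad_gcn3_pooled(tape, X, p$gcn.W1, p$gcn.b1, p$gcn.W2,
                           p$gcn.b2, p$gcn.W3, p$gcn.b3, ops$A1)
  ad_linear(tape, pooled, p$gcn.Wfc, p$gcn.bfc)
}

fwd_attention <- function(tape, p, pfx, x, kv, n_heads, dropout) {
  g <- function(s) p[[paste(pfx, s, sep = ".")]]
  q <- ad_linear(tape, x, g("Wq"), g("bq"))
  k <- ad_linear(tape, kv, g("Wk"), g("bk"))
  v <- ad_linear(tape, kv, g("Wv"), g("bv"))
  dm <- ncol(ad_value(q)); dh <- dm %/% n_heads
  heads <- vector("list", n_heads)
  for (hh in seq_len(n_heads)) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    qh <- ad_cols(tape, q, idx)
    kh <- ad_cols(tape, k, idx)
    vh <- ad_cols(tape, v, idx)
    s <- ad_scale(tape, ad_mm(tape, qh, ad_transpose(tape, kh)), 1 / sqrt(dh))
    a <- ad_dropout(tape, ad_softmax_rows(tape, s), dropout)
    heads[[hh]] <- ad_mm(tape, a, vh)
  }
  o <- Reduce(function(a, b) ad_cbind2(tape, a, b), heads)
  ad_linear(tape, o, g("Wo"), g("bo"))
}

# pre-norm transformer block: x + MSA(LN(x)) then + FF(LN(.)); when kv is
# given an additional cross-attention sub-block is inserted
fwd_block <- function(tape, p, pfx, x, cfg, kv = NULL) {
  g <- function(s) p[[paste(pfx, s, sep = ".")]]
  h <- ad_layernorm(tape, x, g("ln1.g"), g("ln1.b"))
  x <- ad_add(tape, x, ad_dropout(
    tape, fwd_attention(tape, p, paste(pfx, "sa", sep = "."), h, h,
                        cfg$n_heads, cfg$dropout), cfg$dropout))
  if (!is.null(kv)) {
    h <- ad_layernorm(tape, x, g("ln2.g"), g("ln2.b"))
    # pre-norm applies to the key/value token too: this keeps the decoder
    # input bounded whether z_a comes from the posterior or the prior
    kvn <- ad_layernorm(tape, kv, g("ln2.g"), g("ln2.b"))
    x <- ad_add(tape, x, ad_dropout(
      tape, fwd_attention(tape, p, paste(pfx, "ca", sep = "."), h, kvn,
                          cfg$n_heads, cfg$dropout), cfg$dropout))
  }
  h <- ad_layernorm(tape, x, g("ln3.g"), g("ln3.b"))
  ff <- ad_linear(tape, ad_linear(tape, h, g("ff.W1"), g("ff.b1"),
                                  relu = TRUE), g("ff.W2"), g("ff.b2"))
  ad_add(tape, x, ad_dropout(tape, ff, cfg$dropout))
}

# frame latents + condition latent -> (mu, log_sigma, encoder output)
fwd_temporal_encode <- function(tape, p, Z, z_c, cfg) {
  Tn <- nrow(ad_value(Z))
  toks <- ad_rbind2(tape, ad_rbind2(tape, p$tok.mu, p$tok.sigma), Z)
  x <- ad_cbind2(tape, toks, ad_rowrep(tape, z_c, Tn + 2L))
  for (l in seq_len(cfg$n_layers)) {
    x <- fwd_block(tape, p, paste0("enc", l), x, cfg)
  }
  mu <- ad_linear(tape, ad_rows(tape, x, 1L), p$head.Wmu, p$head.bmu)
  log_sigma <- ad_linear(tape, ad_rows(tape, x, 2L), p$head.Wsig,
                         p$head.bsig)
  list(mu = mu, log_sigma = log_sigma, enc_out = x)
}

# z_a and z_c -> T x d_latent frame latents
fwd_temporal_decode <- function(tape, p, z_a, z_c, cfg, pe) {
  kv <- ad_cbind2(tape, z_a, z_c)
  x <- ad_linear(tape, pe, p$pe.Wp, p$pe.bp)
  for (l in seq_len(cfg$n_layers)) {
    x <- fwd_block(tape, p, paste0("dec", l), x, cfg, kv = kv)
  }
  ad_linear(tape, x, p$frame.Wf, p$frame.bf)
}

# T x d_latent frame latents + z_c -> (T*V) x 3 coordinates. The decoder
# is template-anchored: the FC stack predicts per-vertex displacements from
# the stored template shape, in centimetres (scaled to mm here). Anchoring
# builds the vertex correspondence of the fixed topology into the output
# from the first step — a pure Chamfer objective never enforces it — and
# the centimetre units let the offsets reach anatomical scale within a
# desk-sized step budget at the fixed Adam learning rate.
fwd_mesh_decode <- function(tape, p, FZ, z_c, cfg, V, base) {
  Tn <- nrow(ad_value(FZ))
  x <- ad_cbind2(tape, FZ, ad_rowrep(tape, z_c, Tn))
  n_lin <- length(cfg$decoder_hidden) + 1L
  for (k in seq_len(n_lin)) {
    x <- ad_linear(tape, x, p[[paste0("mdec.W", k)]],
                   p[[paste0("mdec.b", k)]], relu = k < n_lin)
  }
  offsets <- ad_rows_to_coords(tape, ad_scale(tape, x, 10), V)
  ad_shift(tape, offsets, base[rep(seq_len(V), times = Tn), , drop = FALSE])
}

# stack the frames of a sequence into a (T*V) x 3 matrix
stack_frames <- function(seq) {
  do.call(rbind, lapply(seq$frames, function(f) f$vertices))
}

coords_to_sequence <- function(coords, state, condition = NULL,
                               subject_id = "decoded") {
  V <- state$V
  Tn <- nrow(coords) / V
  tpl <- state$template
  frames <- lapply(seq_len(Tn), function(t) {
    labelled_mesh(coords[((t - 1L) * V + 1L):(t * V), , drop = FALSE],
                  tpl$faces, tpl$part, tpl$part_faces, validate = FALSE)
  })
  mesh_sequence(frames, condition = condition, subject_id = subject_id,
                validate = FALSE)
}

check_topology <- function(seq, state) {
  if (abs(topology_checksum(seq$frames[[1L]]$faces) - state$topo_hash) >
      1e-6) {
    stop("topology mismatch: sequence does not match the model template")
  }
}

# ---- public operations ---------------------------------------------------

#' Encode clinical conditions into the condition latent
#'
#' @param c a [condition()].
#' @param state a [mesh_model()] state.
#' @return numeric vector of length `d_condition` (32).
#' @export
condition_encode <- function(c, state) {
  tape <- ad_tape()
  as.vector(ad_value(fwd_condition(tape, state$params,
                                   condition_input(c, state$norm))))
}

#' Encode one mesh frame into its latent representation
#'
#' Three graph-convolution layers over the mesh edge graph
#' (symmetric-normalized adjacency with self-loops) on the vertex
#' coordinates, mean-pooled over vertices, followed by one fully connected
#' layer. Mean pooling makes the embedding invariant to consistent
#' vertex/face permutations.
#'
#' @param mesh a [labelled_mesh()] matching the model topology.
#' @param state a [mesh_model()] state.
#' @return numeric vector of length `d_latent` (64).
#' @export
mesh_encode <- function(mesh, state) {
  if (nrow(mesh$vertices) != state$V) stop("topology mismatch")
  ops <- list(A1 = csc_operator(gcn_operator(mesh_edges(mesh), state$V)))
  tape <- ad_tape()
  as.vector(ad_value(fwd_mesh_encode(tape, state$params, mesh$vertices, ops)))
}

#' Temporal encoding of a sequence of frame latents
#'
#' Appends the two learnable distribution parameter tokens to the frame
#' latents, concatenates every token with the condition latent, runs the
#' pre-norm transformer encoder, and reads the Gaussian parameters off the
#' two distribution-token outputs.
#'
#' @param frame_latents T x 64 matrix of frame latents.
#' @param z_c condition latent (length 32).
#' @param state a [mesh_model()] state.
#' @return list with `mu` and `log_sigma` (length-64 vectors; the scale is
#'   `exp(log_sigma)`).
#' @export
temporal_encode <- function(frame_latents, z_c, state) {
  tape <- ad_tape()
  enc <- fwd_temporal_encode(tape, state$params,
                             as.matrix(frame_latents),
                             matrix(z_c, 1L), state$config)
  list(mu = as.vector(ad_value(enc$mu)),
       log_sigma = as.vector(ad_value(enc$log_sigma)))
}

#' Reparameterization
#'
#' `z_a = mu + epsilon * exp(log_sigma)` with `epsilon ~ N(0, I)`; the
#' stored `log_sigma` is the logarithm of the Gaussian scale.
#'
#' @param g list with `mu` and `log_sigma` (equal-length numeric vectors).
#' @param epsilon optional fixed noise vector (e.g. zeros for evaluation).
#' @param seed integer seed used when `epsilon` is not given.
#' @return list with `z_a` and the `epsilon` used.
#' @export
reparameterize <- function(g, epsilon = NULL, seed = NULL) {
  if (is.null(epsilon)) {
    if (!is.null(seed)) {
      old <- .Random.seed_exists()
      set.seed(seed)
      on.exit(.restore_seed(old), add = TRUE)
    }
    epsilon <- stats::rnorm(length(g$mu))
  }
  list(z_a = g$mu + epsilon * exp(g$log_sigma), epsilon = epsilon)
}

#' Decode the sequence latent into per-frame latents
#'
#' Cross-attention transformer decoder: sinusoidal temporal positional
#' encodings of the frame indices serve as queries; the key/value token is
#' the concatenation of the sequence latent `z_a` and the condition latent.
#'
#' @param z_a sequence latent (length 64).
#' @param z_c condition latent (length 32).
#' @param T_frames number of frames to decode.
#' @param state a [mesh_model()] state.
#' @return T x 64 matrix of frame latents.
#' @export
temporal_decode <- function(z_a, z_c, T_frames, state) {
  tape <- ad_tape()
  pe <- if (T_frames == state$T_frames) state$ops$pe else
    positional_encoding(seq_len(T_frames) - 1L, state$config$d_latent)
  ad_value(fwd_temporal_decode(tape, state$params, matrix(z_a, 1L),
                               matrix(z_c, 1L), state$config,
                               matrix(pe, nrow = T_frames)))
}

#' Decode a frame latent to mesh vertex coordinates
#'
#' Five fully connected layers from the frame latent concatenated with the
#' condition latent to the 3V vertex coordinates; faces come from the fixed
#' template topology.
#'
#' @param z frame latent (length 64) or a T x 64 matrix.
#' @param state a [mesh_model()] state.
#' @param z_c condition latent (length 32); zeros if omitted.
#' @return V x 3 coordinate matrix (or a list of them for matrix input).
#' @export
mesh_decode <- function(z, state, z_c = NULL) {
  if (is.null(z_c)) z_c <- numeric(state$config$d_condition)
  zm <- if (is.null(dim(z))) matrix(z, 1L) else as.matrix(z)
  tape <- ad_tape()
  coords <- ad_value(fwd_mesh_decode(tape, state$params, zm,
                                     matrix(z_c, 1L), state$config,
                                     state$V, state$base_coords))
  if (nrow(zm) == 1L) {
    coords
  } else {
    lapply(seq_len(nrow(zm)), function(t) {
      coords[((t - 1L) * state$V + 1L):(t * state$V), , drop = FALSE]
    })
  }
}

# full encoder stack on a sequence: returns tape-level nodes
encode_sequence <- function(tape, state, seq) {
  p <- state$params
  z_c <- fwd_condition(tape, p, condition_input(seq$condition, state$norm))
  Z <- fwd_mesh_encode(tape, p, stack_frames(seq), state$ops)
  c(fwd_temporal_encode(tape, p, Z, z_c, state$config), list(z_c = z_c))
}

# full decoder stack: z_a (node or 1 x d matrix) + z_c -> coords node
decode_sequence <- function(tape, state, z_a, z_c) {
  FZ <- fwd_temporal_decode(tape, state$params, z_a, z_c, state$config,
                            state$ops$pe)
  fwd_mesh_decode(tape, state$params, FZ, z_c, state$config, state$V,
                  state$base_coords)
}

#' Reconstruct a mesh sequence through the autoencoder
#'
#' Encodes the sequence, takes the posterior mean (`epsilon = 0`; training
#' samples epsilon instead) and decodes it back to a mesh sequence with the
#' template topology.
#'
#' @param seq a [mesh_sequence()] matching the model topology.
#' @param state a [mesh_model()] state.
#' @return the reconstructed [mesh_sequence()].
#' @export
reconstruct <- function(seq, state) {
  check_topology(seq, state)
  tape <- ad_tape()
  enc <- encode_sequence(tape, state, seq)
  coords <- ad_value(decode_sequence(tape, state, enc$mu, enc$z_c))
  coords_to_sequence(coords, state, condition = seq$condition,
                     subject_id = paste0(seq$subject_id, "_recon"))
}

#' Generate synthetic mesh sequences for given conditions
#'
#' Draws `n_samples` sequence latents from the standard Gaussian prior and
#' decodes each with the condition latent of `c` fixed.
#'
#' @param c a [condition()].
#' @param n_samples number of sequences to generate.
#' @param seed integer seed for the prior draws.
#' @param state a [mesh_model()] state.
#' @return list of `n_samples` [mesh_sequence()] objects.
#' @export
generate <- function(c, n_samples, seed, state) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  dl <- state$config$d_latent
  zs <- matrix(stats::rnorm(n_samples * dl), n_samples, dl)
  tape <- ad_tape()
  z_c <- fwd_condition(tape, state$params,
                       condition_input(c, state$norm))
  lapply(seq_len(n_samples), function(i) {
    coords <- ad_value(decode_sequence(tape, state,
                                       matrix(zs[i, ], 1L), z_c))
    coords_to_sequence(coords, state, condition = c,
                       subject_id = sprintf("synth_%03d", i))
  })
}

#' Latent vector of a mesh sequence
#'
#' The 64-d sequence descriptor used for downstream analyses: the mean over
#' the frame-token positions of the transformer encoder output (before the
#' reparameterization step), restricted to the frame-latent subspace of the
#' 96-d token stream; the distribution tokens are excluded from the mean.
#'
#' @param seq a [mesh_sequence()] matching the model topology.
#' @param state a [mesh_model()] state.
#' @return numeric vector of length 64.
#' @export
latent_vector <- function(seq, state) {
  check_topology(seq, state)
  tape <- ad_tape()
  enc <- encode_sequence(tape, state, seq)
  out <- ad_value(enc$enc_out)
  colMeans(out[-(1:2), seq_len(state$config$d_latent), drop = FALSE])
}

# ---- checkpointing -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the parameters, the model
#' configuration, the condition normalization constants and the template
#' topology (with checksum), under a versioned format string.
#'
#' @param state a [mesh_model()] state.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `mesh_model`.
#' @export
save_checkpoint <- function(state, path) {
  keep <- state
  keep$ops <- NULL   # rebuilt on load
  saveRDS(keep, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!identical(state$version, "cardiomesh-checkpoint-1")) {
    stop("unrecognized checkpoint format: ", state$version)
  }
  state$ops <- model_operators(state)
  state
}
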