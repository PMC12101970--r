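# Shared fixtures: tiny meshes, populations and model states, plus naive
# loop-based oracles kept deliberately independent of the vectorized
# implementations they check.

# exhaustive O(|A||B|) pairwise-distance oracles
oracle_directed_min <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(vapply(seq_len(nrow(b)), function(j) {
      sqrt(sum((a[i, ] - b[j, ])^2))
    }, 0))
  }, 0)
}

oracle_chamfer <- function(a, b) {
  mean(oracle_directed_min(a, b)) + mean(oracle_directed_min(b, a))
}

oracle_hausdorff <- function(a, b) {
  max(max(oracle_directed_min(a, b)), max(oracle_directed_min(b, a)))
}

oracle_assd <- function(a, b) {
  (sum(oracle_directed_min(a, b)) + sum(oracle_directed_min(b, a))) /
    (nrow(a) + nrow(b))
}

# small noise-free population spec for fast structural tests
tiny_spec <- function(T_frames = 6, vertices_per_part = 32, ...) {
  population_spec(n_subjects = 4, T_frames = T_frames,
                  vertices_per_part = vertices_per_part,
                  shape_sd = 0, phenotype_sd = 0, seed = 11, ...)
}

tiny_sequence <- function(seed = 21, spec = tiny_spec(), disease = NULL) {
  cc <- sample_conditions(spec, 1, seed = seed)[[1]]
  generate_sequence(cc, spec, seed = seed, disease = disease,
                    subject_id = sprintf("T%03d", seed))
}

tiny_model_config <- function() {
  model_config(gcn_hidden = c(8L, 8L, 8L),
               decoder_hidden = c(16L, 16L, 16L, 16L),
               d_ff = 32L, dropout = 0)
}

tiny_state <- function(seq = tiny_sequence(), seed = 3) {
  model_init(tiny_model_config(), seq$frames[[1]], length(seq$frames),
             list(seq$condition), seed = seed)
}

# in-memory dataset for training smoke tests
tiny_dataset <- function(n = 6, spec = tiny_spec()) {
  conds <- sample_conditions(spec, n, seed = 31)
  seqs <- lapply(seq_len(n), function(i) {
    generate_sequence(conds[[i]], spec, seed = 300 + i,
                      subject_id = sprintf("S%03d", i))
  })
  names(seqs) <- vapply(seqs, function(s) s$subject_id, "")
  tab <- data.frame(
    subject_id = names(seqs), split = "train", label = "healthy",
    age = vapply(conds, function(c) c$age, 0),
    sex = vapply(conds, function(c) c$sex, 0),
    weight = vapply(conds, function(c) c$weight, 0),
    height = vapply(conds, function(c) c$height, 0)
  )
  list(sequences = seqs, table = tab)
}

# ---- desk-scale study fixture (trained once, reused by the acceptance
# tests for training, generation and normative-deviation criteria) --------

.acceptance_env <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.acceptance_env$fx)) return(.acceptance_env$fx)
  root <- file.path(tempdir(), "cardiomesh-acceptance")
  spec_h <- population_spec(n_subjects = 90, T_frames = 20,
                            vertices_per_part = 162, seed = 101)
  tab_h <- make_dataset(spec_h, file.path(root, "healthy"),
                        splits = c(train = 2 / 3, val = 0, test = 1 / 3),
                        disease_prevalence = 0, seed = 101)
  spec_d <- population_spec(n_subjects = 30, T_frames = 20,
                            vertices_per_part = 162, seed = 202)
  tab_d <- make_dataset(spec_d, file.path(root, "disease"),
                        splits = c(train = 0, val = 0, test = 1),
                        disease_prevalence = 1,
                        disease = disease_spec("low_ef", 0.8), seed = 202)
  ds <- load_dataset(file.path(root, "healthy"))
  fit <- train(ds, model_config(), train_config(epochs = 50, seed = 1))
  test_ids <- ds$table$subject_id[ds$table$split == "test"]
  untrained <- model_init(
    model_config(), ds$sequences[[1]]$frames[[1]], 20,
    lapply(ds$sequences[ds$table$split == "train"],
           function(s) s$condition),
    seed = 1)
  .acceptance_env$fx <- list(
    root = root, spec = spec_h,
    table = ds$table, sequences = ds$sequences,
    test_table = ds$table[ds$table$split == "test", ],
    test_sequences = ds$sequences[test_ids],
    disease = load_dataset(file.path(root, "disease")),
    state = fit$state, report = fit$report, untrained = untrained
  )
  .acceptance_env$fx
}
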