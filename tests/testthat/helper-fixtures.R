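# Shared fixtures, built in code and cached for the duration of the test
# run (synthetic corpora and trained models are expensive; every file that
# needs one reuses the same object).

fixture_cache <- new.env(parent = emptyenv())

# A small synthetic corpus: 12 tasks (8 train / 2 val / 2 test).
small_db <- function() {
  if (is.null(fixture_cache$small_db)) {
    fixture_cache$small_db <- generate_database(synth_config(
      n_tasks = 12L, task_split = c(train = 8L, val = 2L, test = 2L),
      molecules_per_task = c(40L, 60L), n_train_pool = 400L,
      latent_dim = 16L, seed = 301L))
  }
  fixture_cache$small_db
}

# A tiny untrained model plus random inputs for contract tests.
tiny_setup <- function(seed, D = 10L, d = 8L, S = 4L, Q = 3L, M = 6L) {
  withr::with_seed(seed, {
    cfg <- model_config(feature_dim = D, hidden_dim = 2L * D, embed_dim = d,
                        context_heads = 2L, cross_heads = 2L, seed = seed)
    model <- init_fewshot_model(cfg)
    model$context <- list(embeddings = matrix(rnorm(M * d), M), frozen = TRUE)
    list(model = model,
         Xs = matrix(rnorm(S * D), S),
         ys = c(rep(1, ceiling(S / 2)), rep(0, floor(S / 2))),
         Xq = matrix(rnorm(Q * D), Q))
  })
}

# Distinct always-valid canonical SMILES (linear alkanes) for benchmark
# plumbing tests that need many molecules but no real chemistry.
alkanes <- function(n, offset = 0L) {
  vapply(seq_len(n) + offset, function(i) strrep("C", i), "")
}

# Long-format records for one toy task group.
toy_group <- function(id, n_act, n_inact, offset = 0L, source_size = n_act + n_inact) {
  data.frame(
    smiles = alkanes(n_act + n_inact, offset),
    group_id = id,
    label = c(rep(1L, n_act), rep(0L, n_inact)),
    source_size = source_size,
    stringsAsFactors = FALSE)
}

# A briefly trained small model shared by training / CLI tests.
make_quick_model <- function(seed = 500L) {
  if (is.null(fixture_cache$quick_model)) {
    db <- small_db()
    ts <- split_tasks(db)
    cfg <- train_config(epochs = 3L, episodes_per_epoch = 15L,
                        context_size = 128L, n_query = 16L)
    mc <- model_config(feature_dim = ncol(db$features), hidden_dim = 64L,
                       embed_dim = 32L)
    fixture_cache$quick_model <- train_fewshot(ts$train, ts$val, db$features,
                                               cfg, mc, seed = seed)
  }
  fixture_cache$quick_model
}

# The reference-scale corpus and trained model used by the acceptance
# criteria (built once; the label-shuffle control reuses the same corpus).
acceptance_db <- function() {
  if (is.null(fixture_cache$acc_db)) {
    fixture_cache$acc_db <- generate_database(synth_config(seed = 2024L))
  }
  fixture_cache$acc_db
}

acceptance_train_config <- function() train_config()

acceptance_model_config <- function(db) {
  model_config(feature_dim = ncol(db$features))
}

acceptance_model <- function() {
  if (is.null(fixture_cache$acc_model)) {
    db <- acceptance_db()
    ts <- split_tasks(db)
    fixture_cache$acc_model <- train_fewshot(
      ts$train, ts$val, db$features, acceptance_train_config(),
      acceptance_model_config(db), seed = 2024L)
  }
  fixture_cache$acc_model
}
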