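# The synthetic bioactivity generator: config validation, determinism,
# split hygiene, ground-truth manifest consistency and label composition.

test_that("degenerate configurations are rejected", {
  expect_error(synth_config(label_noise = 0.5), class = "fewshotmol_config_error")
  expect_error(synth_config(label_noise = -0.1), class = "fewshotmol_config_error")
  expect_error(synth_config(active_fraction = 1.2), class = "fewshotmol_config_error")
  expect_error(synth_config(active_fraction = 0.05, label_noise = 0.1),
               class = "fewshotmol_config_error")
  expect_error(synth_config(n_tasks = 10L, task_split = c(train = 5L, val = 2L, test = 2L)),
               class = "fewshotmol_config_error")
  expect_error(synth_config(fragment_vocab_size = 999L), class = "fewshotmol_config_error")
})

test_that("generation is deterministic under the seed and well-formed", {
  db <- small_db()
  db2 <- generate_database(db$config)
  expect_identical(db$records, db2$records)
  expect_identical(db$features, db2$features)
  expect_setequal(unique(db$records$split), c("train", "val", "test"))
  expect_equal(length(unique(db$records$group_id)), db$config$n_tasks)
  # every molecule is canonical and featurized
  expect_true(all(db$records$smiles %in% rownames(db$features)))
  expect_identical(canonicalize_smiles(rownames(db$features)[1:50]),
                   rownames(db$features)[1:50])
})

test_that("task splits are disjoint and non-training molecules never recur", {
  db <- small_db()
  by_split <- split(db$records$group_id, db$records$split)
  expect_length(intersect(unique(by_split$train), unique(by_split$test)), 0)
  expect_length(intersect(unique(by_split$val), unique(by_split$test)), 0)
  # molecules of val/test tasks are unique to their task and absent from train
  non_train <- db$records[db$records$split != "train", ]
  expect_false(any(duplicated(non_train$smiles)))
  expect_length(intersect(non_train$smiles,
                          db$records$smiles[db$records$split == "train"]), 0)
})

test_that("manifest ground truth reconstructs every clean label exactly", {
  db <- small_db()
  rec <- db$records
  for (tid in names(db$manifest$tasks)[c(1, 5, 11)]) {
    m <- db$manifest$tasks[[tid]]
    rows <- which(rec$group_id == tid)
    observed <- rec$label[rows]
    clean <- observed
    local_flip <- match(m$flipped_rows, rows)
    clean[local_flip] <- 1L - clean[local_flip]
    s <- as.numeric(db$features[rec$smiles[rows], m$dims, drop = FALSE] %*% m$w)
    expect_identical(clean, as.integer(s > m$threshold))
  }
})

test_that("without label noise the latent direction ranks every task perfectly", {
  cfg <- synth_config(n_tasks = 6L, task_split = c(train = 4L, val = 1L, test = 1L),
                      molecules_per_task = c(40L, 50L), n_train_pool = 300L,
                      latent_dim = 16L, label_noise = 0, seed = 302L)
  db <- generate_database(cfg)
  for (tid in names(db$manifest$tasks)) {
    m <- db$manifest$tasks[[tid]]
    d <- db$records[db$records$group_id == tid, ]
    s <- as.numeric(db$features[d$smiles, m$dims, drop = FALSE] %*% m$w)
    expect_equal(metric_auc(s, d$label), 1.0)
  }
})

test_that("observed active fraction tracks the configured rate on large tasks", {
  cfg <- synth_config(n_tasks = 4L, task_split = c(train = 2L, val = 1L, test = 1L),
                      molecules_per_task = c(200L, 260L), n_train_pool = 600L,
                      latent_dim = 16L, seed = 303L)
  db <- generate_database(cfg)
  fr <- tapply(db$records$label, db$records$group_id, mean)
  expect_true(all(abs(fr - cfg$active_fraction) < 0.05))
})

test_that("context sampling stays inside the training split and is reproducible", {
  db <- small_db()
  ctx <- generate_context(db, m = 100L, seed = 4L)
  expect_length(ctx, 100L)
  expect_false(any(duplicated(ctx)))
  test_mols <- db$records$smiles[db$records$split != "train"]
  expect_length(intersect(ctx, test_mols), 0)
  expect_identical(generate_context(db, m = 100L, seed = 4L), ctx)
  expect_false(identical(generate_context(db, m = 100L, seed = 5L), ctx))
  expect_error(generate_context(db, m = 10^6), class = "fewshotmol_too_few_molecules")
})

test_that("a database round-trips through its on-disk form", {
  db <- small_db()
  dir <- withr::local_tempdir()
  write_database(db, dir)
  rec <- utils::read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(rec), nrow(db$records))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_named(man, c("tasks", "families", "clean_fraction", "seed"))
  expect_length(man$tasks, db$config$n_tasks)
})
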