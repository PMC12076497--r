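# Benchmark construction (filters a-d), support draws, the RF baseline,
# paired evaluation and the method comparison report.

test_that("filters keep exactly the groups that survive a-d", {
  # G1: large enough on both classes; G2: too few inactives;
  # G3: inside an oversized HTS source
  rec <- rbind(toy_group("G1", 60L, 60L),
               toy_group("G2", 60L, 10L, offset = 200L),
               toy_group("G3", 60L, 60L, offset = 400L, source_size = 150000L))
  tdb <- build_taskdb(rec, mode = "by_target")
  expect_identical(names(tdb$tasks), "G1")
  expect_equal(unname(tdb$log["hts_cap"]), 120L)
  expect_equal(nrow(tdb$tasks$G1), 120L)
})

test_that("conflicting labels remove the molecule entirely", {
  rec <- toy_group("G1", 60L, 60L)
  conflict <- rec[1, ]
  conflict$label <- 0L
  tdb <- build_taskdb(rbind(rec, conflict), mode = "by_assay",
                      min_active = 30L, min_inactive = 30L)
  expect_equal(nrow(tdb$tasks$G1), 119L)
  expect_false(rec$smiles[1] %in% tdb$tasks$G1$smiles)
  expect_equal(unname(tdb$log["conflicting_labels"]), 2L)
})

test_that("invalid SMILES are removed before class counts (filter order matters)", {
  # 49 valid actives + 1 invalid active + 50 inactives: counting before
  # removing the bad record would keep the group; the a->d order drops it
  rec <- toy_group("G1", 49L, 50L)
  bad <- data.frame(smiles = "not[a(smiles", group_id = "G1", label = 1L,
                    source_size = 100L, stringsAsFactors = FALSE)
  ok <- toy_group("G2", 55L, 55L, offset = 300L)
  tdb <- build_taskdb(rbind(rec, bad, ok), mode = "by_target")
  expect_identical(names(tdb$tasks), "G2")
  expect_equal(unname(tdb$log["invalid_smiles"]), 1L)
})

test_that("by-assay thresholds sit at 30 actives and 30 inactives", {
  keep <- toy_group("A1", 30L, 30L)
  drop <- toy_group("A2", 29L, 30L, offset = 100L)
  tdb <- build_taskdb(rbind(keep, drop), mode = "by_assay")
  expect_identical(names(tdb$tasks), "A1")
  expect_error(build_taskdb(drop, mode = "by_assay"),
               class = "fewshotmol_no_tasks_survive")
})

test_that("support draws have the printed compositions at both sizes", {
  task <- data.frame(smiles = alkanes(120L), label = rep(c(1L, 0L), 60L))
  cases <- list(list(8L, "1:7", c(1L, 7L)), list(8L, "1:3", c(2L, 6L)),
                list(8L, "1:1", c(4L, 4L)), list(16L, "1:7", c(2L, 14L)),
                list(16L, "1:3", c(4L, 12L)), list(16L, "1:1", c(8L, 8L)))
  for (cs in cases) {
    ds <- draw_support(task, cs[[1]], cs[[2]], 0L, seed = 1L, task_id = "T")
    expect_equal(sum(ds$support$labels == 1), cs[[3]][1],
                 label = sprintf("actives at size %d ratio %s", cs[[1]], cs[[2]]))
    expect_equal(sum(ds$support$labels == 0), cs[[3]][2])
    # query set is every remaining molecule
    expect_equal(length(ds$query$smiles), 120L - cs[[1]])
    expect_length(intersect(ds$support$smiles, ds$query$smiles), 0)
  }
})

test_that("a 60/60 task at size 8 ratio 1:1 leaves 56 actives and 56 inactives", {
  task <- data.frame(smiles = alkanes(120L), label = c(rep(1L, 60), rep(0L, 60)))
  ds <- draw_support(task, 8L, "1:1", 1L, seed = 3L, task_id = "T")
  expect_equal(sum(ds$query$labels == 1), 56L)
  expect_equal(sum(ds$query$labels == 0), 56L)
})

test_that("support draws are deterministic per cell and differ across draws", {
  task <- data.frame(smiles = alkanes(60L), label = rep(c(1L, 0L), 30L))
  d1 <- draw_support(task, 8L, "1:1", 0L, seed = 9L, task_id = "T")
  d2 <- draw_support(task, 8L, "1:1", 0L, seed = 9L, task_id = "T")
  expect_identical(d1, d2)
  d3 <- draw_support(task, 8L, "1:1", 1L, seed = 9L, task_id = "T")
  expect_false(identical(sort(d1$support$smiles), sort(d3$support$smiles)))
  expect_error(draw_support(task[1:10, ], 16L, "1:1", 0L, seed = 1L),
               class = "fewshotmol_insufficient_task")
})

test_that("the RF baseline separates well-separated toy data and is seeded", {
  withr::with_seed(21, {
    Xs <- rbind(matrix(rnorm(4 * 10, mean = 5), 4), matrix(rnorm(4 * 10, mean = -5), 4))
    ys <- c(1, 1, 1, 1, 0, 0, 0, 0)
    Xq <- rbind(matrix(rnorm(50 * 10, mean = 5), 50), matrix(rnorm(50 * 10, mean = -5), 50))
    yq <- c(rep(1, 50), rep(0, 50))
  })
  s1 <- rf_baseline(Xs, ys, Xq, seed = 11L)
  expect_equal(metric_auc(s1, yq), 1.0)
  expect_gt(s1[1], 0.5)
  expect_identical(rf_baseline(Xs, ys, Xq, seed = 11L), s1)
  expect_error(rf_baseline(Xs, rep(1, 8), Xq), class = "fewshotmol_one_class_support")
})

make_fake_bench <- function(n_tasks = 5L, n_act = 12L, n_inact = 20L, D = 6L) {
  withr::with_seed(n_tasks + n_act, {
    tasks <- list()
    feats <- list()
    for (t in seq_len(n_tasks)) {
      smis <- alkanes(n_act + n_inact, offset = (t - 1L) * 40L)
      tasks[[sprintf("T%d", t)]] <-
        data.frame(smiles = smis, label = c(rep(1L, n_act), rep(0L, n_inact)))
      feats[[t]] <- matrix(rnorm(length(smis) * D), ncol = D,
                           dimnames = list(smis, NULL))
    }
    tdb <- structure(list(mode = "by_target", tasks = tasks, log = NULL,
                          params = list()), class = "fsm_taskdb")
    list(taskdb = tdb, features = do.call(rbind, feats))
  })
}

test_that("evaluation is a paired full factorial with identical supports per cell", {
  fb <- make_fake_bench()
  seen <- new.env()
  recorder <- function(tag) {
    function(Xs, ys, Xq, seed = 0L) {
      key <- paste(tag, digest_support(Xs, ys), sep = "@")
      seen[[key]] <- TRUE
      rep(0.5, nrow(Xq)) + seq_len(nrow(Xq)) * 1e-3
    }
  }
  digest_support <- function(Xs, ys) paste(c(round(Xs, 6), ys), collapse = ",")
  res <- evaluate_fewshot(fb$taskdb, list(m1 = recorder("m1"), m2 = recorder("m2")),
                          fb$features, sizes = 8L, seed = 31L)
  expect_equal(nrow(res), 5L * 1L * 3L * 3L * 2L)
  keys <- ls(seen)
  h1 <- sort(sub("^m1@", "", keys[startsWith(keys, "m1@")]))
  h2 <- sort(sub("^m2@", "", keys[startsWith(keys, "m2@")]))
  expect_identical(h1, h2)  # byte-identical supports served to both methods
})

test_that("a random-scoring method sits at chance over many cells", {
  fb <- make_fake_bench(n_tasks = 12L, n_act = 15L, n_inact = 25L)
  res <- evaluate_fewshot(fb$taskdb, list(rand = random_method()),
                          fb$features, sizes = c(8L, 16L), seed = 17L)
  expect_gte(nrow(res), 100L)
  expect_lt(abs(median(res$auc) - 0.5), 0.05)
})

test_that("benchmark evaluation is deterministic under the master seed", {
  fb <- make_fake_bench(n_tasks = 3L)
  methods <- list(rf = rf_method(), rand = random_method())
  r1 <- evaluate_fewshot(fb$taskdb, methods, fb$features, sizes = 8L, seed = 23L)
  r2 <- evaluate_fewshot(fb$taskdb, methods, fb$features, sizes = 8L, seed = 23L)
  expect_identical(r1, r2)
})

test_that("method comparison reports medians, exact p-values and stars", {
  fb <- make_fake_bench(n_tasks = 5L, n_act = 10L, n_inact = 14L)
  base <- evaluate_fewshot(fb$taskdb, list(a = random_method()),
                           fb$features, sizes = 8L, seed = 41L)
  shifted <- base
  shifted$method <- "b"
  shifted$auc <- shifted$auc - 0.1
  res <- rbind(base, shifted)
  cmp <- compare_methods(res, "a", "b", metrics = "auc")
  expect_equal(nrow(cmp), 3L)  # one row per ratio at one size
  # constant shift over 15 pairs: the most extreme sign pattern, twice
  expect_equal(cmp$p_value, rep(2 / 2^15, 3), tolerance = 1e-12)
  expect_true(all(cmp$star))
  expect_true(all(cmp$winner == "a"))
  # identical methods: no star, p undefined
  dup <- base
  dup$method <- "b"
  cmp2 <- compare_methods(rbind(base, dup), "a", "b", metrics = "auc")
  expect_true(all(is.na(cmp2$p_value)))
  expect_false(any(cmp2$star))
})
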