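# Few-shot benchmark construction and execution.
#
# A long-format bioactivity table (molecule SMILES, group id, binary label)
# is recast into few-shot tasks through four filters applied in order:
#   a) records from huge HTS sources (> hts_cap data points) are removed,
#   b) molecules with conflicting labels inside a group are removed,
#   c) molecules whose SMILES cannot be parsed are removed (and reported),
#   d) groups with too few actives or inactives are removed
#      (by-target: >= 50 of each; by-assay: >= 30 of each; configurable).
# Evaluation then draws, per task, three support sets at each requested
# size and active:inactive ratio, serves the identical support draws to
# every method (paired design), scores all remaining task molecules, and
# compares methods with a two-sided paired Wilcoxon test.

#' Build a task database from a long-format bioactivity table
#'
#' @param records data.frame with columns `smiles`, `group_id`, `label`
#'   (0/1) and optionally `source_size` (number of records in the source
#'   the group came from; used by filter a).
#' @param mode `"by_target"` (groups are merged per protein target;
#'   minimum 50 actives and 50 inactives) or `"by_assay"` (groups are
#'   individual assays; minimum 30 and 30).
#' @param min_active,min_inactive override the mode's minimum class counts.
#' @param hts_cap filter a threshold on `source_size` (default 100000).
#' @return object of class `fsm_taskdb`: `mode`, `tasks` (named list of
#'   data.frames `smiles` (canonical), `label`), and `log` (records removed
#'   per filter).
#' @section Errors: `fewshotmol_no_tasks_survive` if filtering leaves no
#'   task.
#' @export
build_taskdb <- function(records, mode = c("by_target", "by_assay"),
                         min_active = NULL, min_inactive = NULL,
                         hts_cap = 100000L) {
  mode <- match.arg(mode)
  if (is.null(min_active)) min_active <- if (mode == "by_target") 50L else 30L
  if (is.null(min_inactive)) min_inactive <- if (mode == "by_target") 50L else 30L
  stopifnot(is.data.frame(records),
            all(c("smiles", "group_id", "label") %in% names(records)))
  if (!all(records$label %in% c(0, 1))) {
    fsm_stop("invalid_input", "labels must be 0/1")
  }
  log <- c(hts_cap = 0L, conflicting_labels = 0L, invalid_smiles = 0L,
           conflicting_after_canonicalization = 0L, min_class_counts = 0L)
  df <- records
  # (a) drop records from oversized HTS sources
  if ("source_size" %in% names(df)) {
    drop <- !is.na(df$source_size) & df$source_size > hts_cap
    log["hts_cap"] <- sum(drop)
    df <- df[!drop, , drop = FALSE]
  }
  # (b) conflicting labels within a group: remove all records of the molecule
  if (nrow(df)) {
    key <- paste(df$group_id, df$smiles, sep = "\r")
    nlab <- tapply(df$label, key, function(x) length(unique(x)))
    conflicted <- names(nlab)[nlab > 1L]
    drop <- key %in% conflicted
    log["conflicting_labels"] <- sum(drop)
    df <- df[!drop, , drop = FALSE]
    # collapse exact duplicates to one record
    df <- df[!duplicated(paste(df$group_id, df$smiles, df$label, sep = "\r")), , drop = FALSE]
  }
  # (c) canonicalize; unparsable molecules are reported and removed
  if (nrow(df)) {
    uniq <- unique(df$smiles)
    can <- canonicalize_smiles(uniq)
    names(can) <- uniq
    bad <- is.na(can[df$smiles])
    log["invalid_smiles"] <- sum(bad)
    df <- df[!bad, , drop = FALSE]
    df$smiles <- unname(can[df$smiles])
    # canonicalization may merge distinct inputs: re-resolve conflicts
    if (nrow(df)) {
      df <- df[!duplicated(paste(df$group_id, df$smiles, df$label, sep = "\r")), , drop = FALSE]
      key <- paste(df$group_id, df$smiles, sep = "\r")
      nlab <- tapply(df$label, key, function(x) length(unique(x)))
      conflicted <- names(nlab)[nlab > 1L]
      drop <- key %in% conflicted
      log["conflicting_after_canonicalization"] <- sum(drop)
      df <- df[!drop, , drop = FALSE]
    }
  }
  # (d) minimum class counts per group
  tasks <- list()
  if (nrow(df)) {
    for (g in unique(df$group_id)) {
      d <- df[df$group_id == g, c("smiles", "label"), drop = FALSE]
      if (sum(d$label == 1) >= min_active && sum(d$label == 0) >= min_inactive) {
        rownames(d) <- NULL
        tasks[[g]] <- d
      } else {
        log["min_class_counts"] <- log["min_class_counts"] + nrow(d)
      }
    }
  }
  if (length(tasks) == 0L) {
    fsm_stop("no_tasks_survive", "no group survives the benchmark filters",
             log = log)
  }
  structure(list(mode = mode, tasks = tasks, log = log,
                 params = list(min_active = min_active,
                               min_inactive = min_inactive,
                               hts_cap = hts_cap)),
            class = "fsm_taskdb")
}

#' Parse an active:inactive ratio for a support size
#' @keywords internal
ratio_counts <- function(ratio, support_size) {
  if (is.character(ratio)) {
    ab <- as.integer(strsplit(ratio, ":", fixed = TRUE)[[1]])
  } else {
    ab <- as.integer(ratio)
  }
  if (length(ab) != 2L || any(is.na(ab)) || any(ab <= 0)) {
    fsm_stop("invalid_input", "ratio must be 'a:b' or c(a, b)")
  }
  k <- support_size / sum(ab)
  if (k != round(k)) {
    fsm_stop("invalid_input",
             sprintf("support size %d is not a multiple of ratio %d:%d",
                     support_size, ab[1], ab[2]))
  }
  c(n_active = ab[1] * k, n_inactive = ab[2] * k)
}

#' Draw one support set and its query set from a task
#'
#' The support is drawn without replacement at the exact composition the
#' size and ratio imply (e.g. size 16 at 1:3 gives 4 actives and 12
#' inactives); the query set is all remaining task molecules. The draw is
#' deterministic in `(task_id, support_size, ratio, draw_index, seed)`, and
#' each task's draws are independent of which other tasks exist.
#'
#' @param task data.frame `smiles, label`.
#' @param support_size total support molecules (8 or 16 in the standard
#'   protocol).
#' @param ratio `"a:b"` string or `c(a, b)`.
#' @param draw_index draw replicate index (0, 1, 2 in the standard
#'   protocol).
#' @param seed master benchmark seed.
#' @param task_id task identifier mixed into the draw seed.
#' @return list with `support` (list `smiles`, `labels`) and `query`
#'   (list `smiles`, `labels`).
#' @section Errors: `fewshotmol_insufficient_task` if the task cannot fill
#'   the composition with at least one leftover molecule per class.
#' @export
draw_support <- function(task, support_size, ratio, draw_index = 0L,
                         seed = 1L, task_id = "task") {
  cnt <- ratio_counts(ratio, support_size)
  na <- cnt[["n_active"]]; ni <- cnt[["n_inactive"]]
  act <- which(task$label == 1)
  ina <- which(task$label == 0)
  if (length(act) < na + 1L || length(ina) < ni + 1L) {
    fsm_stop("insufficient_task",
             sprintf("task '%s' has %d/%d actives/inactives; needs %d+1 and %d+1",
                     task_id, length(act), length(ina), na, ni))
  }
  rstr <- if (is.character(ratio)) ratio else paste(ratio, collapse = ":")
  withr::with_seed(derive_seed(seed, "draw", task_id, support_size, rstr, draw_index), {
    sa <- sample(act, na)
    si <- sample(ina, ni)
    rest <- setdiff(seq_len(nrow(task)), c(sa, si))
    list(support = list(smiles = task$smiles[c(sa, si)],
                        labels = c(rep(1, na), rep(0, ni))),
         query = list(smiles = task$smiles[rest], labels = task$label[rest]))
  })
}

# Prediction methods ------------------------------------------------------

#' Random-forest baseline scores for one support/query split
#'
#' Fits a random forest on the support features and labels with the
#' package defaults of the underlying implementation and a fixed seed, and
#' returns the positive-class probability for each query.
#'
#' @param support_features numeric matrix `[S x D]`.
#' @param support_labels binary 0/1 vector.
#' @param query_features numeric matrix `[Q x D]`.
#' @param seed RNG seed for the forest.
#' @return numeric vector of `Q` scores in `[0, 1]`.
#' @section Errors: `fewshotmol_one_class_support` if the support has only
#'   one class.
#' @export
rf_baseline <- function(support_features, support_labels, query_features,
                        seed = 0L) {
  if (length(unique(support_labels)) < 2L) {
    fsm_stop("one_class_support", "support set must contain both classes")
  }
  withr::with_seed(seed, {
    fit <- randomForest::randomForest(x = support_features,
                                      y = factor(support_labels, levels = c(0, 1)))
    unname(stats::predict(fit, query_features, type = "prob")[, "1"])
  })
}

#' Wrap a trained model as a benchmark method
#'
#' @param model a trained `fewshot_model`.
#' @return function `(Xs, ys, Xq, seed)` returning query scores (the model
#'   is deterministic; `seed` is ignored).
#' @export
fewshot_method <- function(model) {
  force(model)
  function(Xs, ys, Xq, seed = 0L) predict_scores(model, Xs, ys, Xq)
}

#' The random-forest baseline as a benchmark method
#' @return function `(Xs, ys, Xq, seed)` returning query scores.
#' @export
rf_method <- function() {
  function(Xs, ys, Xq, seed = 0L) rf_baseline(Xs, ys, Xq, seed)
}

#' A random-score control method
#' @return function `(Xs, ys, Xq, seed)` returning uniform random scores.
#' @export
random_method <- function() {
  function(Xs, ys, Xq, seed = 0L) withr::with_seed(seed, stats::runif(nrow(Xq)))
}

# Evaluation --------------------------------------------------------------

#' Run the few-shot benchmark
#'
#' Full factorial over tasks x support sizes x ratios x three draws x
#' methods. Every method is served the byte-identical support draw of a
#' cell, so the comparison is paired. Tasks too small for a composition are
#' skipped and logged.
#'
#' @param taskdb an `fsm_taskdb`.
#' @param methods named list of method functions (see [fewshot_method()],
#'   [rf_method()]).
#' @param features raw feature matrix covering every task molecule
#'   (rownames = canonical SMILES).
#' @param standardizer a `feature_standardizer` applied to `features`
#'   before scoring (typically the model's own, so all methods see the
#'   features the model was trained with).
#' @param sizes support-set sizes (default `c(8, 16)`).
#' @param ratios active:inactive ratios (default `c("1:7", "1:3", "1:1")`).
#' @param n_draws support draws per cell (default 3).
#' @param seed master benchmark seed.
#' @param alpha,threshold metric parameters (see [metric_vector()]).
#' @return `EvalResult` data.frame: one row per
#'   (task, size, ratio, draw, method) with the five metrics and class
#'   counts; skipped cells in `attr(, "skipped")`.
#' @export
evaluate_fewshot <- function(taskdb, methods, features, standardizer = NULL,
                             sizes = c(8L, 16L),
                             ratios = c("1:7", "1:3", "1:1"),
                             n_draws = 3L, seed = 1L,
                             alpha = 20, threshold = 0.5) {
  stopifnot(inherits(taskdb, "fsm_taskdb"), is.list(methods),
            !is.null(names(methods)))
  X <- if (is.null(standardizer)) features else standardize_features(features, standardizer)
  rows <- list()
  skipped <- list()
  for (tid in names(taskdb$tasks)) {
    task <- taskdb$tasks[[tid]]
    for (size in sizes) {
      for (ratio in ratios) {
        for (draw in seq_len(n_draws) - 1L) {
          ds <- tryCatch(
            draw_support(task, size, ratio, draw, seed, tid),
            fewshotmol_insufficient_task = function(e) e)
          if (inherits(ds, "condition")) {
            skipped[[length(skipped) + 1L]] <-
              data.frame(task_id = tid, support_size = size, ratio = ratio,
                         draw = draw, reason = conditionMessage(ds))
            next
          }
          Xs <- X[ds$support$smiles, , drop = FALSE]
          Xq <- X[ds$query$smiles, , drop = FALSE]
          for (mn in names(methods)) {
            sc <- methods[[mn]](Xs, ds$support$labels, Xq,
                                seed = derive_seed(seed, "method", mn, tid,
                                                   size, ratio, draw))
            mv <- metric_vector(sc, ds$query$labels, alpha, threshold)
            rows[[length(rows) + 1L]] <-
              cbind(data.frame(task_id = tid, draw = draw, method = mn,
                               support_size = size, ratio = ratio,
                               stringsAsFactors = FALSE), mv)
          }
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(res) <- c("fsm_evalresult", class(res))
  res
}

#' Compare two methods over paired benchmark cells
#'
#' For each (support size, ratio, metric): medians of both methods, a
#' two-sided paired Wilcoxon signed-rank test over the paired
#' (task, draw) cells, a significance star at `p < star_alpha`, and the
#' direction of the winner.
#'
#' @param results an `EvalResult` from [evaluate_fewshot()].
#' @param method_a,method_b method names present in `results`.
#' @param metrics metric columns to compare.
#' @param star_alpha significance level for the star flag.
#' @return data.frame with one row per (size, ratio, metric).
#' @export
compare_methods <- function(results, method_a, method_b,
                            metrics = c("auc", "delta_auc_pr", "bedroc",
                                        "bacc", "mcc"),
                            star_alpha = 0.05) {
  stopifnot(all(c(method_a, method_b) %in% results$method))
  key <- c("task_id", "support_size", "ratio", "draw")
  a <- results[results$method == method_a, , drop = FALSE]
  b <- results[results$method == method_b, , drop = FALSE]
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) fsm_stop("too_few_pairs", "no paired cells between methods")
  out <- list()
  for (size in sort(unique(m$support_size))) {
    for (ratio in unique(m$ratio)) {
      sub <- m[m$support_size == size & m$ratio == ratio, , drop = FALSE]
      for (met in metrics) {
        va <- sub[[paste0(met, "_a")]]
        vb <- sub[[paste0(met, "_b")]]
        p <- tryCatch(paired_wilcoxon(va, vb)$p_value,
                      fewshotmol_all_zero_differences = function(e) NA_real_,
                      fewshotmol_too_few_pairs = function(e) NA_real_)
        star <- !is.na(p) && p < star_alpha
        out[[length(out) + 1L]] <- data.frame(
          support_size = size, ratio = ratio, metric = met,
          median_a = stats::median(va), median_b = stats::median(vb),
          n_pairs = nrow(sub), p_value = p, star = star,
          winner = if (!star) NA_character_
                   else if (stats::median(va) >= stats::median(vb)) method_a
                   else method_b,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "methods") <- c(a = method_a, b = method_b)
  res
}
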