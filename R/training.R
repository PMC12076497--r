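# Episodic meta-training: sample a task, draw a small support set at one of
# the evaluation ratios, score held-out queries, and descend the binary
# cross-entropy by Adam. Validation is the median ROC-AUC over held-out
# tasks with a fixed 4:4 support draw; the checkpoint with the best
# validation AUC is returned (early stopping on patience).

#' Training configuration
#'
#' @param epochs maximum training epochs.
#' @param episodes_per_epoch episodes per epoch.
#' @param lr Adam learning rate.
#' @param lr_decay multiplicative decay applied to the learning rate after
#'   each `lr_decay_every` epochs (1 = constant).
#' @param lr_decay_every epochs between decay steps.
#' @param support_size training support-set size.
#' @param ratios list of `c(n_active, n_inactive)` compositions sampled
#'   uniformly per episode (covers all evaluation ratios at size 8).
#' @param n_query queries drawn per training episode.
#' @param patience epochs without validation improvement before stopping.
#' @param context_size molecules in the frozen retrieval context.
#' @param val_support `c(n_active, n_inactive)` support used for validation
#'   draws.
#' @param val_draws number of fixed support draws per validation task; the
#'   validation statistic is the median AUC over all task-draw cells.
#' @param val_every validate every this many epochs (the final epoch is
#'   always validated); unvalidated epochs log `NA`.
#' @param swa_start_frac fraction of the epoch budget after which a running
#'   tail average of the weights is maintained (stochastic weight
#'   averaging); the returned checkpoint is the better, by validation AUC,
#'   of the best single epoch and the tail average. 1 disables averaging.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, episodes_per_epoch = 100L, lr = 1e-3,
                         lr_decay = 0.5, lr_decay_every = 25L,
                         support_size = 8L,
                         ratios = list(c(1L, 7L), c(2L, 6L), c(4L, 4L)),
                         n_query = 64L, patience = epochs,
                         context_size = 1024L,
                         val_support = c(4L, 4L), val_draws = 3L,
                         val_every = 2L, swa_start_frac = 0.6) {
  structure(list(epochs = as.integer(epochs),
                 episodes_per_epoch = as.integer(episodes_per_epoch),
                 lr = lr, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 support_size = as.integer(support_size),
                 ratios = ratios, n_query = as.integer(n_query),
                 patience = as.integer(patience),
                 context_size = as.integer(context_size),
                 val_support = as.integer(val_support),
                 val_draws = as.integer(val_draws),
                 val_every = as.integer(val_every),
                 swa_start_frac = swa_start_frac),
            class = "train_config")
}

#' Sample one training episode from a task collection
#'
#' The support set is drawn without replacement at exactly the requested
#' active:inactive composition; queries come from the remaining molecules
#' of the same task, so support and query sets are disjoint.
#'
#' @param tasks named list of task data.frames (`smiles`, `label`).
#' @param support_ratio `c(n_active, n_inactive)`.
#' @param n_query maximum number of queries to draw.
#' @param seed episode seed.
#' @param task_id optional: fix the task instead of sampling one.
#' @return list with `task_id`, `support` (list `smiles`, `labels`) and
#'   `query` (list `smiles`, `labels`).
#' @section Errors: `fewshotmol_insufficient_task` if the chosen task cannot
#'   provide the composition plus at least one leftover per class;
#'   `fewshotmol_no_valid_tasks` if no task can.
#' @export
sample_episode <- function(tasks, support_ratio, n_query = 32L, seed = 1L,
                           task_id = NULL) {
  na <- support_ratio[1]; ni <- support_ratio[2]
  eligible <- vapply(tasks, function(d) {
    sum(d$label == 1) >= na + 1L && sum(d$label == 0) >= ni + 1L
  }, TRUE)
  if (!is.null(task_id)) {
    if (!task_id %in% names(tasks)) {
      fsm_stop("no_valid_tasks", sprintf("unknown task '%s'", task_id))
    }
    if (!eligible[[task_id]]) {
      fsm_stop("insufficient_task",
               sprintf("task '%s' cannot supply %d actives / %d inactives plus leftovers",
                       task_id, na, ni))
    }
  } else if (!any(eligible)) {
    fsm_stop("no_valid_tasks", "no task can satisfy the requested support composition")
  }
  withr::with_seed(seed, {
    tid <- if (is.null(task_id)) sample(names(tasks)[eligible], 1L) else task_id
    d <- tasks[[tid]]
    act <- which(d$label == 1)
    ina <- which(d$label == 0)
    sa <- sample(act, na)
    si <- sample(ina, ni)
    rest <- setdiff(seq_len(nrow(d)), c(sa, si))
    qi <- if (length(rest) > n_query) sample(rest, n_query) else rest
    list(task_id = tid,
         support = list(smiles = d$smiles[c(sa, si)],
                        labels = c(rep(1, na), rep(0, ni))),
         query = list(smiles = d$smiles[qi], labels = d$label[qi]))
  })
}

#' Mean binary cross-entropy of episode scores
#'
#' @param scores numeric vector of scores in `(0, 1)`.
#' @param labels binary 0/1 labels of the same length.
#' @return non-negative scalar loss.
#' @export
episode_loss <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    fsm_stop("dimension_mismatch", "scores and labels differ in length")
  }
  -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
}

#' Encode with a raw parameter list (training-internal)
#' @keywords internal
encode_params <- function(params, X) {
  H1 <- if (is.null(params$enc_W1)) X else {
    pmax(sweep(X %*% params$enc_W1, 2L, params$enc_b1, "+"), 0)
  }
  ln_fwd(sweep(H1 %*% params$enc_W2, 2L, params$enc_b2, "+"))$y
}

#' Meta-train the few-shot predictor on a task corpus
#'
#' @param tasks_train,tasks_val named lists of task data.frames
#'   (`smiles`, `label`), e.g. from [split_tasks()] or the `tasks` field of
#'   a task database.
#' @param features raw feature matrix covering every molecule in the tasks
#'   and the context (row names = canonical SMILES), from
#'   [featurize_smiles()].
#' @param config a [train_config()].
#' @param model_cfg an [model_config()]; its `feature_dim` must match
#'   `features`.
#' @param seed master seed; all randomness (init, episode sampling, ratio
#'   choice, context sampling, validation draws) flows from it through
#'   named substreams.
#' @param context_smiles molecules forming the retrieval context; defaults
#'   to a uniform sample of `config$context_size` training-task molecules.
#' @param verbose print per-epoch progress.
#' @return a trained `fewshot_model` carrying the feature standardizer, the
#'   frozen context embeddings, and a training log (`attr(model, "log")`:
#'   epoch, mean episode loss, validation median AUC).
#' @export
train_fewshot <- function(tasks_train, tasks_val, features,
                          config = train_config(),
                          model_cfg = model_config(feature_dim = ncol(features)),
                          seed = 1L, context_smiles = NULL, verbose = FALSE) {
  if (length(tasks_train) < 2L) {
    fsm_stop("no_valid_tasks", "need at least 2 training tasks")
  }
  train_mols <- unique(unlist(lapply(tasks_train, `[[`, "smiles"), use.names = FALSE))
  missing <- setdiff(train_mols, rownames(features))
  if (length(missing)) {
    fsm_stop("invalid_input",
             sprintf("%d task molecules missing from the feature matrix", length(missing)))
  }
  std <- fit_standardizer(features[train_mols, , drop = FALSE])
  Xstd <- standardize_features(features, std)
  if (is.null(context_smiles)) {
    context_smiles <- withr::with_seed(derive_seed(seed, "context"), {
      sample(train_mols, min(config$context_size, length(train_mols)))
    })
  }
  Xc <- Xstd[context_smiles, , drop = FALSE]

  model <- init_fewshot_model(model_cfg)
  model$config$seed <- as.integer(seed)
  params <- model$params
  state <- adam_init(params)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), mean_loss = numeric(), val_auc = numeric())
  wait <- 0L
  swa_start <- ceiling(config$swa_start_frac * config$epochs)
  swa <- NULL
  swa_n <- 0L

  val_cells <- expand.grid(tid = names(tasks_val),
                           draw = seq_len(max(1L, config$val_draws)),
                           stringsAsFactors = FALSE)
  val_auc <- function(p) {
    C <- encode_params(p, Xc)
    m <- model; m$params <- p
    aucs <- vapply(seq_len(nrow(val_cells)), function(i) {
      tid <- val_cells$tid[i]
      ep <- tryCatch(
        sample_episode(tasks_val, config$val_support, n_query = Inf,
                       seed = derive_seed(seed, "val", tid, val_cells$draw[i]),
                       task_id = tid),
        fewshotmol_insufficient_task = function(e) NULL)
      if (is.null(ep) || length(unique(ep$query$labels)) < 2L) return(NA_real_)
      sc <- predict_scores(m, Xstd[ep$support$smiles, , drop = FALSE],
                           ep$support$labels,
                           Xstd[ep$query$smiles, , drop = FALSE], context = C)
      metric_auc(sc, ep$query$labels)
    }, 0)
    stats::median(aucs, na.rm = TRUE)
  }

  for (e in seq_len(config$epochs)) {
    lr_e <- config$lr * config$lr_decay^((e - 1L) %/% max(1L, config$lr_decay_every))
    losses <- numeric(config$episodes_per_epoch)
    for (i in seq_len(config$episodes_per_epoch)) {
      rseed <- derive_seed(seed, "ratio", e, i)
      ratio <- config$ratios[[withr::with_seed(rseed, sample.int(length(config$ratios), 1L))]]
      ep <- sample_episode(tasks_train, ratio, config$n_query,
                           seed = derive_seed(seed, "episode", e, i))
      Xs <- Xstd[ep$support$smiles, , drop = FALSE]
      Xq <- Xstd[ep$query$smiles, , drop = FALSE]
      C <- encode_params(params, Xc)
      lg <- fs_loss_grad(params, model$config, Xs, ep$support$labels,
                         Xq, ep$query$labels, C)
      if (!is.finite(lg$loss)) {
        fsm_stop("non_finite_loss",
                 sprintf("non-finite loss at epoch %d episode %d (task %s)",
                         e, i, ep$task_id))
      }
      upd <- adam_step(params, lg$grads, state, lr_e)
      params <- upd$params
      state <- upd$state
      losses[i] <- lg$loss
    }
    if (config$swa_start_frac < 1 && e > swa_start) {
      swa_n <- swa_n + 1L
      swa <- if (is.null(swa)) params else {
        Map(function(a, p) a + (p - a) / swa_n, swa, params)
      }
    }
    do_val <- (e %% max(1L, config$val_every) == 0L) || e == config$epochs
    va <- if (do_val) val_auc(params) else NA_real_
    log <- rbind(log, data.frame(epoch = e, mean_loss = mean(losses), val_auc = va))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  val AUC %s", e, mean(losses),
                      if (do_val) sprintf("%.4f", va) else "-"))
    }
    if (do_val) {
      if (is.finite(va) && va > best$auc + 1e-6) {
        best <- list(auc = va, params = params, epoch = e)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }

  if (!is.null(swa) && swa_n > 1L) {
    va_swa <- val_auc(swa)
    log <- rbind(log, data.frame(epoch = NA_integer_, mean_loss = NA_real_,
                                 val_auc = va_swa))
    if (verbose) message(sprintf("tail-averaged weights  val AUC %.4f", va_swa))
    if (is.finite(va_swa) && va_swa > best$auc) {
      best <- list(auc = va_swa, params = swa, epoch = NA_integer_)
    }
  }
  model$params <- best$params
  model$standardizer <- std
  model$context <- list(smiles = context_smiles,
                        embeddings = encode_params(best$params, Xc),
                        frozen = TRUE)
  attr(model, "log") <- log
  attr(model, "train_config") <- config
  attr(model, "best_epoch") <- best$epoch
  model
}

# Checkpoints ------------------------------------------------------------

#' Save a trained model to a single checkpoint file
#'
#' The checkpoint bundles weights, model configuration, the feature
#' standardizer and the frozen context set under a versioned header.
#'
#' @param model a `fewshot_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fewshot_model"))
  payload <- list(version = model$version,
                  config = model$config,
                  params = model$params,
                  standardizer = model$standardizer,
                  context = model$context,
                  log = attr(model, "log"),
                  train_config = attr(model, "train_config"))
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a `fewshot_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    fsm_stop("invalid_input", sprintf("checkpoint '%s' does not exist", path))
  }
  payload <- readRDS(path)
  if (!identical(payload$version, "fewshotmol-checkpoint-1")) {
    fsm_stop("invalid_input", "unrecognized checkpoint version header")
  }
  model <- structure(list(config = payload$config, params = payload$params,
                          standardizer = payload$standardizer,
                          context = payload$context,
                          version = payload$version),
                     class = "fewshot_model")
  attr(model, "log") <- payload$log
  attr(model, "train_config") <- payload$train_config
  model
}
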