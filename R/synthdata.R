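# Synthetic bioactivity databases with latent task structure.
#
# Molecules are assembled from a small grammar of divalent SMILES fragments
# (each fragment is written so that plain string concatenation extends the
# molecular chain), so every generated string is chemically valid and the
# fingerprint/descriptor pipeline is exercised end to end. Each task carries
# a latent direction in fingerprint space drawn inside one of a few task
# families; a molecule's clean label thresholds its projection onto that
# direction, and observed labels flip a fixed fraction per class. Held-out
# tasks share families with training tasks, which is what a few-shot
# learner can exploit and a from-scratch baseline cannot.

# Chain-extending SMILES fragments: concatenating any sequence of these
# yields a valid molecule (rings close within a fragment, branches are
# balanced, the last atom continues the chain).
FRAGMENT_GRAMMAR <- c(
  "C", "CC", "CCC", "CO", "CCO", "CN", "CCN", "CS",
  "C(C)", "C(C)(C)", "C(F)", "C(F)(F)", "C(Cl)", "C(Br)",
  "C(O)", "C(N)", "C(C#N)", "CC(=O)", "C(=O)O", "C(=O)N",
  "OC(=O)", "NC(=O)", "N(C)", "OCC", "SC", "C=C",
  "S(=O)(=O)", "c1ccc(cc1)", "c1cccc(c1)", "c1ccc(nc1)",
  "c1cc(oc1)", "c1cc(sc1)", "C1CCC(CC1)", "C1CC(CC1)", "C1CCN(CC1)"
)

#' Configuration of the synthetic bioactivity generator
#'
#' Defaults define the package's reference corpus: 270 tasks split
#' 200 train / 20 val / 50 test, 120-300 molecules per task, 5 task
#' families, 30% actives and 10% per-class label noise.
#'
#' @param n_tasks total number of tasks.
#' @param task_split named integer vector `c(train=, val=, test=)` summing
#'   to `n_tasks`.
#' @param molecules_per_task inclusive integer range of task sizes.
#' @param n_task_families number of latent task families.
#' @param latent_dim number of fingerprint dimensions carrying each
#'   family's signal.
#' @param label_noise per-class label flip fraction, in `[0, 0.5)`.
#' @param active_fraction target fraction of observed actives per task.
#' @param fragment_vocab_size number of grammar fragments used (<= 35).
#' @param n_train_pool size of the shared training molecule pool (training
#'   tasks may reuse molecules; validation/test tasks get disjoint ones).
#' @param family_spread standard deviation of a task direction around its
#'   family center.
#' @param seed master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_tasks = 270L,
                         task_split = c(train = 200L, val = 20L, test = 50L),
                         molecules_per_task = c(120L, 300L),
                         n_task_families = 5L,
                         latent_dim = 32L,
                         label_noise = 0.1,
                         active_fraction = 0.3,
                         fragment_vocab_size = 30L,
                         n_train_pool = 6000L,
                         family_spread = 0.25,
                         seed = 1L) {
  task_split <- unlist(task_split)  # tolerate YAML/JSON list form
  molecules_per_task <- unlist(molecules_per_task)
  if (is.null(names(task_split)) && length(task_split) == 3L) {
    names(task_split) <- c("train", "val", "test")  # YAML drops names
  }
  if (!is.numeric(label_noise) || label_noise < 0 || label_noise >= 0.5) {
    fsm_stop("config_error", "label_noise must be in [0, 0.5)")
  }
  if (active_fraction <= 0 || active_fraction >= 1) {
    fsm_stop("config_error", "active_fraction must be in (0, 1)")
  }
  if (active_fraction <= label_noise) {
    fsm_stop("config_error", "active_fraction must exceed label_noise")
  }
  if (any(c(n_tasks, molecules_per_task, n_task_families, latent_dim,
            fragment_vocab_size, n_train_pool) <= 0)) {
    fsm_stop("config_error", "all counts must be positive")
  }
  if (sum(task_split) != n_tasks || !all(c("train", "val", "test") %in% names(task_split))) {
    fsm_stop("config_error", "task_split must be named c(train=,val=,test=) and sum to n_tasks")
  }
  if (fragment_vocab_size > length(FRAGMENT_GRAMMAR)) {
    fsm_stop("config_error",
             sprintf("fragment_vocab_size exceeds grammar size %d", length(FRAGMENT_GRAMMAR)))
  }
  structure(list(n_tasks = as.integer(n_tasks),
                 task_split = vapply(task_split, as.integer, 0L),
                 molecules_per_task = as.integer(molecules_per_task),
                 n_task_families = as.integer(n_task_families),
                 latent_dim = as.integer(latent_dim),
                 label_noise = label_noise,
                 active_fraction = active_fraction,
                 fragment_vocab_size = as.integer(fragment_vocab_size),
                 n_train_pool = as.integer(n_train_pool),
                 family_spread = family_spread,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate unique canonical molecules from the fragment grammar
#' @keywords internal
generate_molecules <- function(n, vocab, seed) {
  out <- character(0)
  round <- 0L
  while (length(out) < n && round < 50L) {
    round <- round + 1L
    raw <- withr::with_seed(derive_seed(seed, "mols", round), {
      k <- sample(2:4, ceiling(1.6 * n), replace = TRUE)
      vapply(k, function(m) paste(sample(vocab, m, replace = TRUE), collapse = ""), "")
    })
    can <- canonicalize_smiles(unique(raw))
    out <- unique(c(out, can[!is.na(can)]))
  }
  if (length(out) < n) {
    fsm_stop("config_error",
             sprintf("fragment grammar yielded only %d unique molecules, need %d",
                     length(out), n))
  }
  out[seq_len(n)]
}

#' Generate a synthetic bioactivity database
#'
#' @param config a [synth_config()].
#' @return object of class `synth_database`: list with
#'   * `records` — data.frame `smiles, group_id, label, source_size, split`
#'     (the long-format benchmark input schema),
#'   * `manifest` — ground truth: per task the family, latent direction,
#'     threshold and flipped record rows; suffices to recompute every clean
#'     label exactly (`clean = label XOR flipped`),
#'   * `features` — raw feature matrix of all unique molecules,
#'   * `config`.
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  vocab <- FRAGMENT_GRAMMAR[seq_len(cfg$fragment_vocab_size)]
  split_of <- rep(c("train", "val", "test"), cfg$task_split)
  n_t <- withr::with_seed(derive_seed(cfg$seed, "sizes"), {
    sample(cfg$molecules_per_task[1]:cfg$molecules_per_task[2],
           cfg$n_tasks, replace = TRUE)
  })
  n_unique <- sum(n_t[split_of != "train"]) + cfg$n_train_pool
  mols <- generate_molecules(n_unique, vocab, cfg$seed)
  X <- featurize_smiles(mols)
  mols <- withr::with_seed(derive_seed(cfg$seed, "shuffle"), sample(mols))

  # families: latent directions live on fingerprint bits that actually vary
  fp_mean <- colMeans(X[, seq_len(FP_BITS), drop = FALSE])
  informative <- which(fp_mean > 0.02 & fp_mean < 0.98)
  if (length(informative) < cfg$latent_dim) {
    fsm_stop("config_error", "too few informative fingerprint bits for latent_dim")
  }
  fam <- withr::with_seed(derive_seed(cfg$seed, "families"), {
    lapply(seq_len(cfg$n_task_families), function(f) {
      list(dims = sample(informative, cfg$latent_dim),
           center = stats::rnorm(cfg$latent_dim))
    })
  })
  family_of <- (seq_len(cfg$n_tasks) - 1L) %% cfg$n_task_families + 1L

  clean_frac <- (cfg$active_fraction - cfg$label_noise) / (1 - 2 * cfg$label_noise)
  cursor <- 0L
  rec_list <- vector("list", cfg$n_tasks)
  man_tasks <- vector("list", cfg$n_tasks)
  row_offset <- 0L
  for (t in seq_len(cfg$n_tasks)) {
    tid <- sprintf("T%03d", t)
    n <- n_t[t]
    if (split_of[t] == "train") {
      task_mols <- withr::with_seed(derive_seed(cfg$seed, "taskmols", t), {
        sample(mols[seq_len(cfg$n_train_pool)], n)
      })
    } else {
      task_mols <- mols[cfg$n_train_pool + cursor + seq_len(n)]
      cursor <- cursor + n
    }
    f <- fam[[family_of[t]]]
    w <- withr::with_seed(derive_seed(cfg$seed, "w", t), {
      v <- f$center + cfg$family_spread * stats::rnorm(cfg$latent_dim)
      v / sqrt(sum(v^2))
    })
    s <- as.numeric(X[task_mols, f$dims, drop = FALSE] %*% w)
    # threshold at the distinct-value boundary nearest the target count, so
    # the clean label is exactly 1{s > threshold} even when molecules tie
    k0 <- max(1L, min(n - 1L, round(clean_frac * n)))
    ss <- sort(s, decreasing = TRUE)
    boundaries <- which(ss[-n] > ss[-1])
    if (length(boundaries) == 0L) {
      fsm_stop("config_error",
               sprintf("task %s is degenerate: all molecules share one latent score", tid))
    }
    k <- boundaries[which.min(abs(boundaries - k0))]
    thr <- (ss[k] + ss[k + 1L]) / 2
    clean <- as.integer(s > thr)
    flip <- withr::with_seed(derive_seed(cfg$seed, "flip", t), {
      fa <- sample(which(clean == 1L), round(cfg$label_noise * k))
      fi <- sample(which(clean == 0L), round(cfg$label_noise * (n - k)))
      c(fa, fi)
    })
    label <- clean
    label[flip] <- 1L - label[flip]
    rec_list[[t]] <- data.frame(smiles = task_mols, group_id = tid,
                                label = label, source_size = n,
                                split = split_of[t], stringsAsFactors = FALSE)
    man_tasks[[t]] <- list(task_id = tid, split = split_of[t],
                           family = family_of[t], n = n,
                           w = w, dims = unname(f$dims), threshold = thr,
                           flipped_rows = row_offset + sort(flip))
    row_offset <- row_offset + n
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  names(man_tasks) <- vapply(man_tasks, `[[`, "", "task_id")
  structure(list(records = records,
                 manifest = list(tasks = man_tasks,
                                 families = fam,
                                 clean_fraction = clean_frac,
                                 seed = cfg$seed),
                 features = X,
                 config = cfg),
            class = "synth_database")
}

#' Sample a context set from the training split of a database
#'
#' Uniform sample without replacement from molecules that appear in
#' training tasks only — never from validation or test tasks, so the frozen
#' retrieval memory cannot leak evaluation molecules.
#'
#' @param db a `synth_database`.
#' @param m context size (default 512).
#' @param seed sampling seed.
#' @return character vector of `m` distinct canonical SMILES.
#' @export
generate_context <- function(db, m = 512L, seed = 1L) {
  stopifnot(inherits(db, "synth_database"))
  train_mols <- unique(db$records$smiles[db$records$split == "train"])
  if (m > length(train_mols)) {
    fsm_stop("too_few_molecules",
             sprintf("requested %d context molecules but the training split has %d",
                     m, length(train_mols)))
  }
  withr::with_seed(derive_seed(seed, "context"), sample(train_mols, m))
}

#' Task tables of a synthetic database, split into train/val/test
#'
#' @param db a `synth_database`.
#' @return list of three named lists (`train`, `val`, `test`); each element
#'   maps a task id to a data.frame `smiles, label`.
#' @export
split_tasks <- function(db) {
  stopifnot(inherits(db, "synth_database"))
  out <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    rec <- db$records[db$records$split == sp, , drop = FALSE]
    lapply(split(rec[, c("smiles", "label")], rec$group_id), function(d) {
      rownames(d) <- NULL
      d
    })
  })
  out
}

#' Write a synthetic database to disk
#'
#' Emits `records.csv` (long-format benchmark schema) and `manifest.json`
#' (ground truth).
#'
#' @param db a `synth_database`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "synth_database"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(db$records, file.path(dir, "records.csv"), row.names = FALSE)
  jsonlite::write_json(db$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
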