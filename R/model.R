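# The few-shot predictor.
#
# Three stages operate on molecule embeddings:
#   1. context module  — each embedding is enriched by one step of
#      Hopfield-style (scaled dot-product) attention over a large frozen
#      context set, with residual connection and layer normalization; rows
#      are updated independently of one another.
#   2. cross-attention — for each query separately, joint self-attention
#      over the set {query} + support shares information between the query
#      and its support molecules. Labels are not visible at this stage.
#   3. similarity      — the query score is a sigmoid of the scaled mean
#      cosine similarity to the support embeddings, signed by the support
#      labels (+1 active, -1 inactive).
#
# Because labels enter only in stage 3, flipping every support label maps a
# score p to exactly 1 - p.

#' Model configuration
#'
#' @param feature_dim input feature dimension `D` (default [feature_dim()]).
#' @param hidden_dim width of the encoder's hidden ReLU layer; 0 gives a
#'   purely linear encoder.
#' @param embed_dim embedding width `d`; must be divisible by both head
#'   counts.
#' @param context_heads attention heads in the context module.
#' @param cross_heads attention heads in the cross-attention module.
#' @param retrieval_beta inverse-temperature multiplier of the context
#'   retrieval; the effective logit scale is `retrieval_beta / sqrt(d_head)`.
#' @param similarity_scale_init initial value of the learnable positive
#'   similarity scale (softplus-parameterized).
#' @param seed seed for weight initialization.
#' @return object of class `fsm_config`.
#' @export
model_config <- function(feature_dim = fewshotmol::feature_dim(),
                         hidden_dim = 0L,
                         embed_dim = 64L,
                         context_heads = 4L,
                         cross_heads = 4L,
                         retrieval_beta = 2,
                         similarity_scale_init = 5,
                         seed = 1L) {
  stopifnot(feature_dim >= 1, hidden_dim >= 0, embed_dim >= 1,
            embed_dim %% context_heads == 0, embed_dim %% cross_heads == 0,
            retrieval_beta > 0, similarity_scale_init > 0)
  structure(list(feature_dim = as.integer(feature_dim),
                 hidden_dim = as.integer(hidden_dim),
                 embed_dim = as.integer(embed_dim),
                 context_heads = as.integer(context_heads),
                 cross_heads = as.integer(cross_heads),
                 retrieval_beta = retrieval_beta,
                 similarity_scale_init = similarity_scale_init,
                 seed = as.integer(seed)),
            class = "fsm_config")
}

#' Initialize model parameters
#'
#' @param config an `fsm_config`.
#' @return object of class `fewshot_model`: list with `config`, `params`,
#'   and empty slots for `standardizer` and `context` (filled by training /
#'   checkpoint loading).
#' @export
init_fewshot_model <- function(config) {
  stopifnot(inherits(config, "fsm_config"))
  D <- config$feature_dim
  h <- config$hidden_dim
  d <- config$embed_dim
  params <- withr::with_seed(derive_seed(config$seed, "init"), {
    rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
    enc <- if (h > 0) {
      list(enc_W1 = rmat(D, h), enc_b1 = numeric(h),
           enc_W2 = rmat(h, d), enc_b2 = numeric(d))
    } else {
      list(enc_W2 = rmat(D, d), enc_b2 = numeric(d))
    }
    c(enc, list(
      ctx_Wq = rmat(d, d), ctx_Wk = rmat(d, d), ctx_Wv = rmat(d, d),
      crs_Wq = rmat(d, d), crs_Wk = rmat(d, d), crs_Wv = rmat(d, d),
      rho = log(expm1(config$similarity_scale_init))
    ))
  })
  structure(list(config = config, params = params,
                 standardizer = NULL, context = NULL,
                 version = "fewshotmol-checkpoint-1"),
            class = "fewshot_model")
}

#' Learnable similarity scale of a model (softplus of the raw parameter)
#' @keywords internal
similarity_scale <- function(params) log1p(exp(params$rho))

# Numerical building blocks ----------------------------------------------

#' Row-wise layer normalization (no affine parameters)
#' @keywords internal
ln_fwd <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  list(y = xc * inv, inv = inv)
}

#' Backward pass of row-wise layer normalization
#' @keywords internal
ln_bwd <- function(dY, y, inv) {
  (dY - rowMeans(dY) - y * rowMeans(dY * y)) * inv
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Multi-head scaled dot-product attention readout (forward)
#'
#' Queries come from rows of `E`, keys and values from rows of `C`.
#' @keywords internal
attn_fwd <- function(E, C, Wq, Wk, Wv, heads, beta, keep = FALSE) {
  d <- ncol(Wq)
  dh <- d %/% heads
  Qm <- E %*% Wq
  K <- C %*% Wk
  V <- C %*% Wv
  R <- matrix(0, nrow(E), d)
  A <- if (keep) vector("list", heads) else NULL
  for (h in seq_len(heads)) {
    j <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- softmax_rows(beta * Qm[, j, drop = FALSE] %*% t(K[, j, drop = FALSE]))
    R[, j] <- Ah %*% V[, j, drop = FALSE]
    if (keep) A[[h]] <- Ah
  }
  if (keep) list(R = R, A = A, Qm = Qm, K = K, V = V) else list(R = R)
}

#' Backward pass of multi-head attention
#'
#' Returns gradients for the weight matrices, for the query-side input `E`,
#' and for the memory input `C` (via the key/value paths). The context
#' module discards the memory gradient (its context set is frozen); the
#' cross-attention module adds it back because queries and memory are the
#' same token matrix there.
#' @keywords internal
attn_bwd <- function(dR, cache, E, C, Wq, Wk, Wv, heads, beta) {
  d <- ncol(Wq)
  dh <- d %/% heads
  dQm <- matrix(0, nrow(E), d)
  dK <- matrix(0, nrow(C), d)
  dV <- matrix(0, nrow(C), d)
  for (h in seq_len(heads)) {
    j <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- cache$A[[h]]
    dRh <- dR[, j, drop = FALSE]
    dA <- dRh %*% t(cache$V[, j, drop = FALSE])
    dV[, j] <- t(Ah) %*% dRh
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQm[, j] <- beta * dS %*% cache$K[, j, drop = FALSE]
    dK[, j] <- beta * t(dS) %*% cache$Qm[, j, drop = FALSE]
  }
  list(dWq = t(E) %*% dQm, dWk = t(C) %*% dK, dWv = t(C) %*% dV,
       dE = dQm %*% t(Wq), dC = dK %*% t(Wk) + dV %*% t(Wv))
}

# Stage forwards (user-facing) -------------------------------------------

#' Encode feature vectors into embeddings
#'
#' A row-wise map: a one-hidden-layer perceptron (ReLU) followed by layer
#' normalization, so a molecule's embedding depends only on its own feature
#' row.
#'
#' @param model a `fewshot_model`.
#' @param X numeric matrix `[N x D]` of (standardized) features.
#' @return numeric matrix `[N x d]`.
#' @export
encode <- function(model, X) {
  if (ncol(X) != model$config$feature_dim) {
    fsm_stop("dimension_mismatch",
             sprintf("features have %d columns, model expects %d",
                     ncol(X), model$config$feature_dim))
  }
  encode_params(model$params, X)
}

#' Enrich embeddings by attention over a frozen context set
#'
#' One Hopfield-style retrieval step per row: residual + attention readout
#' over the context embeddings, then layer normalization. Rows are updated
#' independently; permuting the context rows leaves the output unchanged.
#'
#' @param model a `fewshot_model`.
#' @param E embedding matrix `[N x d]`.
#' @param context context embedding matrix `[M x d]` (defaults to the
#'   model's stored frozen context).
#' @return enriched embedding matrix `[N x d]`.
#' @export
context_enrich <- function(model, E, context = NULL) {
  p <- model$params
  cfg <- model$config
  C <- if (is.null(context)) model$context$embeddings else context
  if (is.null(C) || nrow(C) == 0L) {
    fsm_stop("empty_context", "context set is empty")
  }
  if (ncol(E) != cfg$embed_dim || ncol(C) != cfg$embed_dim) {
    fsm_stop("dimension_mismatch", "embedding width does not match model config")
  }
  beta <- cfg$retrieval_beta / sqrt(cfg$embed_dim / cfg$context_heads)
  R <- attn_fwd(E, C, p$ctx_Wq, p$ctx_Wk, p$ctx_Wv, cfg$context_heads, beta)$R
  ln_fwd(E + R)$y
}

#' Share information between one query and its support set
#'
#' Joint multi-head self-attention over the token set {query} + support,
#' residual + layer normalization. Each query is processed on its own, so
#' its output never depends on other queries in a batch; support labels are
#' not an input.
#'
#' @param model a `fewshot_model`.
#' @param query_emb numeric vector of length `d`.
#' @param support_emb numeric matrix `[S x d]`, `S >= 2`.
#' @return list with `query` (vector `[d]`) and `support` (matrix `[S x d]`).
#' @export
cross_attend <- function(model, query_emb, support_emb) {
  p <- model$params
  cfg <- model$config
  if (length(query_emb) != cfg$embed_dim || ncol(support_emb) != cfg$embed_dim) {
    fsm_stop("dimension_mismatch", "embedding width does not match model config")
  }
  Tm <- rbind(matrix(query_emb, 1L), support_emb)
  beta <- 1 / sqrt(cfg$embed_dim / cfg$cross_heads)
  R <- attn_fwd(Tm, Tm, p$crs_Wq, p$crs_Wk, p$crs_Wv, cfg$cross_heads, beta)$R
  U <- ln_fwd(Tm + R)$y
  list(query = U[1L, ], support = U[-1L, , drop = FALSE])
}

#' Similarity-weighted label aggregation
#'
#' `score = sigmoid( scale/S * sum_s cos(query, support_s) * (2*label_s - 1) )`.
#' The mean over the support keeps the logit scale stable across support
#' sizes.
#'
#' @param query_emb query embedding vector.
#' @param support_emb support embedding matrix `[S x d]`.
#' @param labels binary 0/1 support labels, length `S`.
#' @param scale positive scalar weight on the mean signed similarity.
#' @return score in `(0, 1)`.
#' @section Errors: `fewshotmol_zero_vector` if any embedding has zero norm
#'   (cosine undefined).
#' @export
similarity_predict <- function(query_emb, support_emb, labels, scale) {
  stopifnot(length(labels) == nrow(support_emb), scale > 0)
  nq <- sqrt(sum(query_emb^2))
  ns <- sqrt(rowSums(support_emb^2))
  if (nq < 1e-12 || any(ns < 1e-12)) {
    fsm_stop("zero_vector", "zero-norm embedding: cosine similarity undefined")
  }
  cs <- as.numeric(support_emb %*% query_emb) / (nq * ns)
  stats::plogis(scale * mean(cs * (2 * labels - 1)))
}

# End-to-end scoring ------------------------------------------------------

#' Score query molecules from standardized feature matrices
#'
#' Internal composition used by training, prediction and benchmarking:
#' encode -> context enrichment (queries and support independently) ->
#' per-query cross-attention -> similarity scoring.
#'
#' @param model a `fewshot_model` with a context set.
#' @param Xs support feature matrix `[S x D]` (standardized).
#' @param ys binary support labels.
#' @param Xq query feature matrix `[Q x D]` (standardized).
#' @param context optional context embedding override `[M x d]`.
#' @return numeric vector of `Q` scores in `(0, 1)`.
#' @export
predict_scores <- function(model, Xs, ys, Xq, context = NULL) {
  C <- if (is.null(context)) model$context$embeddings else context
  if (is.null(C) || nrow(C) == 0L) fsm_stop("empty_context", "model has no context set")
  if (ncol(Xs) != model$config$feature_dim || ncol(Xq) != model$config$feature_dim) {
    fsm_stop("dimension_mismatch", "feature width does not match model config")
  }
  fs_forward(model$params, model$config, Xs, ys, Xq, C)$scores
}

#' Predict activities for query molecules from SMILES
#'
#' The user-facing prediction entry point: canonicalizes and featurizes the
#' three molecule lists with the model's frozen feature standardizer, then
#' scores each query against the labeled support set. Scores are invariant
#' to support ordering and to which other queries are in the batch.
#'
#' @param model a trained `fewshot_model` (see [load_checkpoint()]).
#' @param actives character vector of known-active SMILES (>= 1).
#' @param inactives character vector of known-inactive SMILES (>= 1).
#' @param queries character vector of query SMILES (>= 1).
#' @return data.frame (`PredictionTable`) with columns `smiles` (input
#'   query SMILES) and `prediction` in `(0, 1)`, in input order. Attribute
#'   `"rejected"` lists any SMILES that failed to parse.
#' @section Errors: `fewshotmol_empty_support_class` if no valid active or
#'   no valid inactive molecule remains.
#' @export
predict_fewshot <- function(model, actives, inactives, queries) {
  stopifnot(inherits(model, "fewshot_model"))
  if (is.null(model$standardizer)) {
    fsm_stop("invalid_input", "model carries no feature standardizer; load a trained checkpoint")
  }
  parse_group <- function(smis, group) {
    can <- canonicalize_smiles(smis)
    bad <- which(is.na(can))
    list(can = can, rejected = if (length(bad))
      data.frame(group = group, smiles = smis[bad], stringsAsFactors = FALSE)
      else NULL)
  }
  ga <- parse_group(actives, "active")
  gi <- parse_group(inactives, "inactive")
  gq <- parse_group(queries, "query")
  rejected <- do.call(rbind, Filter(Negate(is.null), list(ga$rejected, gi$rejected, gq$rejected)))
  a <- ga$can[!is.na(ga$can)]
  i <- gi$can[!is.na(gi$can)]
  qk <- which(!is.na(gq$can))
  if (length(a) == 0L || length(i) == 0L) {
    fsm_stop("empty_support_class",
             "need at least one valid active and one valid inactive molecule")
  }
  if (length(qk) == 0L) {
    fsm_stop("invalid_input", "no valid query molecule")
  }
  uniq <- unique(c(a, i, gq$can[qk]))
  X <- standardize_features(featurize_smiles(uniq), model$standardizer)
  scores <- predict_scores(model,
                           Xs = X[c(a, i), , drop = FALSE],
                           ys = c(rep(1, length(a)), rep(0, length(i))),
                           Xq = X[gq$can[qk], , drop = FALSE])
  out <- data.frame(smiles = queries[qk], prediction = scores,
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- rejected
  out
}
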