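# Episode forward pass and hand-written reverse-mode gradients.
#
# The cross-attention stage runs once per query over the token set
# {query} + support. Looping over queries in R is the training bottleneck,
# so both directions are written as batched block-matrix operations over
# all queries at once: the (S+1)x(S+1) attention of query i decomposes
# into a shared support-support block and query-specific border terms.
# The batched forward is the single code path used by training and
# prediction; the public cross_attend() operation (one query at a time) is
# asserted equal to it in the unit tests, and the backward is validated
# against central finite differences.

#' Batched episode forward pass
#'
#' @param params model parameter list.
#' @param cfg an `fsm_config`.
#' @param Xs,ys support features `[S x D]` and binary labels.
#' @param Xq query features `[Q x D]`.
#' @param C context embeddings `[M x d]` (frozen memory).
#' @param keep cache intermediates for the backward pass.
#' @return list with `scores` and (if `keep`) `cache`.
#' @keywords internal
fs_forward <- function(params, cfg, Xs, ys, Xq, C, keep = FALSE) {
  S <- nrow(Xs); Q <- nrow(Xq); d <- cfg$embed_dim
  X <- rbind(Xs, Xq)
  has_hidden <- !is.null(params$enc_W1)
  H1 <- if (has_hidden) {
    pmax(sweep(X %*% params$enc_W1, 2L, params$enc_b1, "+"), 0)
  } else X
  H <- sweep(H1 %*% params$enc_W2, 2L, params$enc_b2, "+")
  l1 <- ln_fwd(H); E <- l1$y
  b1 <- cfg$retrieval_beta / sqrt(d / cfg$context_heads)
  a1 <- attn_fwd(E, C, params$ctx_Wq, params$ctx_Wk, params$ctx_Wv,
                 cfg$context_heads, b1, keep = keep)
  l2 <- ln_fwd(E + a1$R); Z <- l2$y
  Zs <- Z[seq_len(S), , drop = FALSE]
  Zq <- Z[S + seq_len(Q), , drop = FALSE]
  b2 <- 1 / sqrt(d / cfg$cross_heads)

  # ---- batched cross-attention over all queries ----
  Qq <- Zq %*% params$crs_Wq; Kq <- Zq %*% params$crs_Wk; Vq <- Zq %*% params$crs_Wv
  Qs <- Zs %*% params$crs_Wq; Ks <- Zs %*% params$crs_Wk; Vs <- Zs %*% params$crs_Wv
  dh <- d %/% cfg$cross_heads
  iq <- rep(seq_len(Q), each = S)    # query index of each (query, support) row
  is <- rep(seq_len(S), Q)           # support index of each row
  Rtop <- matrix(0, Q, d)
  Rsup <- matrix(0, Q * S, d)
  Atop <- Asup <- vector("list", cfg$cross_heads)
  for (h in seq_len(cfg$cross_heads)) {
    j <- ((h - 1L) * dh + 1L):(h * dh)
    Qqj <- Qq[, j, drop = FALSE]; Kqj <- Kq[, j, drop = FALSE]; Vqj <- Vq[, j, drop = FALSE]
    Qsj <- Qs[, j, drop = FALSE]; Ksj <- Ks[, j, drop = FALSE]; Vsj <- Vs[, j, drop = FALSE]
    # query-token rows: logits [self | supports]
    At <- softmax_rows(b2 * cbind(rowSums(Qqj * Kqj), Qqj %*% t(Ksj)))
    Rtop[, j] <- At[, 1L] * Vqj + At[, -1L, drop = FALSE] %*% Vsj
    # support-token rows, stacked query-major: logits [query | supports]
    M1 <- Qsj %*% t(Kqj)                       # S x Q (column i = query i)
    As <- softmax_rows(b2 * cbind(as.vector(M1), Qsj[is, , drop = FALSE] %*% t(Ksj)))
    Rsup[, j] <- As[, 1L] * Vqj[iq, , drop = FALSE] +
      As[, -1L, drop = FALSE] %*% Vsj
    if (keep) { Atop[[h]] <- At; Asup[[h]] <- As }
  }
  lq <- ln_fwd(Zq + Rtop)
  ls <- ln_fwd(Zs[is, , drop = FALSE] + Rsup)
  Uq <- lq$y                                   # Q x d refined queries
  Us <- ls$y                                   # (Q*S) x d refined supports
  nq <- sqrt(rowSums(Uq^2))
  ns <- sqrt(rowSums(Us^2))
  if (any(nq < 1e-12) || any(ns < 1e-12)) {
    fsm_stop("zero_vector", "zero-norm embedding in similarity stage")
  }
  cs <- rowSums(Us * Uq[iq, , drop = FALSE]) / (nq[iq] * ns)
  tsgn <- 2 * ys - 1
  scale <- log1p(exp(params$rho))
  logits <- scale * as.numeric(rowsum(cs * tsgn[is], iq)) / S
  scores <- stats::plogis(logits)
  if (!keep) return(list(scores = scores))
  list(scores = scores,
       cache = list(S = S, Q = Q, d = d, dh = dh, iq = iq, is = is,
                    X = X, H1 = H1, l1 = l1, E = E, a1 = a1, l2 = l2,
                    Z = Z, Zs = Zs, Zq = Zq, b1 = b1, b2 = b2,
                    Qq = Qq, Kq = Kq, Vq = Vq, Qs = Qs, Ks = Ks, Vs = Vs,
                    Atop = Atop, Asup = Asup, lq = lq, ls = ls,
                    Uq = Uq, Us = Us, nq = nq, ns = ns, cs = cs,
                    tsgn = tsgn, scale = scale, has_hidden = has_hidden))
}

#' Episode loss and parameter gradients
#'
#' Mean binary cross-entropy of the query scores for one episode, plus
#' gradients for every model parameter. The context embedding matrix `C`
#' is a frozen constant (gradients still reach the context module's key
#' and value projections, which multiply `C`).
#'
#' @inheritParams fs_forward
#' @param yq binary query labels.
#' @return list with `loss`, `scores`, and `grads`.
#' @keywords internal
fs_loss_grad <- function(params, cfg, Xs, ys, Xq, yq, C) {
  fw <- fs_forward(params, cfg, Xs, ys, Xq, C, keep = TRUE)
  cc <- fw$cache
  S <- cc$S; Q <- cc$Q; d <- cc$d; dh <- cc$dh
  iq <- cc$iq; is <- cc$is
  scores <- fw$scores
  eps <- 1e-12
  loss <- -mean(yq * log(scores + eps) + (1 - yq) * log(1 - scores + eps))

  dlogit <- (scores - yq) / Q
  # similarity stage
  dcs <- (dlogit[iq] * cc$scale / S) * cc$tsgn[is]
  dscale <- sum(dlogit * as.numeric(rowsum(cc$cs * cc$tsgn[is], iq)) / S)
  nq_i <- cc$nq[iq]
  dUs <- (dcs / (nq_i * cc$ns)) * cc$Uq[iq, , drop = FALSE] -
    (dcs * cc$cs / cc$ns^2) * cc$Us
  dUq_rows <- (dcs / (nq_i * cc$ns)) * cc$Us -
    (dcs * cc$cs / nq_i^2) * cc$Uq[iq, , drop = FALSE]
  dUq <- rowsum(dUq_rows, iq)
  # cross-attention layer norms
  dPq <- ln_bwd(dUq, cc$Uq, cc$lq$inv)        # Q x d
  dPs <- ln_bwd(dUs, cc$Us, cc$ls$inv)        # (Q*S) x d
  dZq <- dPq                                   # residual paths
  dZs <- rowsum(dPs, is)
  dRtop <- dPq
  dRsup <- dPs
  # batched cross-attention backward
  dQq <- matrix(0, Q, d); dKq <- matrix(0, Q, d); dVq <- matrix(0, Q, d)
  dQs <- matrix(0, S, d); dKs <- matrix(0, S, d); dVs <- matrix(0, S, d)
  b2 <- cc$b2
  for (h in seq_len(cfg$cross_heads)) {
    j <- ((h - 1L) * dh + 1L):(h * dh)
    Qqj <- cc$Qq[, j, drop = FALSE]; Kqj <- cc$Kq[, j, drop = FALSE]
    Vqj <- cc$Vq[, j, drop = FALSE]
    Qsj <- cc$Qs[, j, drop = FALSE]; Ksj <- cc$Ks[, j, drop = FALSE]
    Vsj <- cc$Vs[, j, drop = FALSE]
    At <- cc$Atop[[h]]; As <- cc$Asup[[h]]
    dRt <- dRtop[, j, drop = FALSE]; dRs <- dRsup[, j, drop = FALSE]
    # readout backward (query rows)
    dAt <- cbind(rowSums(dRt * Vqj), dRt %*% t(Vsj))
    dVq[, j] <- dVq[, j] + At[, 1L] * dRt
    dVs[, j] <- dVs[, j] + t(At[, -1L, drop = FALSE]) %*% dRt
    # readout backward (support rows)
    dAs <- cbind(rowSums(dRs * Vqj[iq, , drop = FALSE]), dRs %*% t(Vsj))
    dVq[, j] <- dVq[, j] + rowsum(As[, 1L] * dRs, iq)
    dVs[, j] <- dVs[, j] + t(As[, -1L, drop = FALSE]) %*% dRs
    # softmax backward
    dLt <- At * (dAt - rowSums(dAt * At))
    dLs <- As * (dAs - rowSums(dAs * As))
    # logit backward, query rows: L[i, ] = b2 * [Qq_i.Kq_i | Qq_i Ks^T]
    dQq[, j] <- dQq[, j] + b2 * (dLt[, 1L] * Kqj + dLt[, -1L, drop = FALSE] %*% Ksj)
    dKq[, j] <- dKq[, j] + b2 * (dLt[, 1L] * Qqj)
    dKs[, j] <- dKs[, j] + b2 * (t(dLt[, -1L, drop = FALSE]) %*% Qqj)
    # logit backward, support rows: L[(i,s), ] = b2 * [Qs_s.Kq_i | Qs_s Ks^T]
    Qs_rep <- Qsj[is, , drop = FALSE]
    dQs[, j] <- dQs[, j] +
      b2 * rowsum(dLs[, 1L] * Kqj[iq, , drop = FALSE] +
                    dLs[, -1L, drop = FALSE] %*% Ksj, is)
    dKq[, j] <- dKq[, j] + b2 * rowsum(dLs[, 1L] * Qs_rep, iq)
    dKs[, j] <- dKs[, j] + b2 * (t(dLs[, -1L, drop = FALSE]) %*% Qs_rep)
  }
  g <- list()
  g$crs_Wq <- t(cc$Zq) %*% dQq + t(cc$Zs) %*% dQs
  g$crs_Wk <- t(cc$Zq) %*% dKq + t(cc$Zs) %*% dKs
  g$crs_Wv <- t(cc$Zq) %*% dVq + t(cc$Zs) %*% dVs
  dZq <- dZq + dQq %*% t(params$crs_Wq) + dKq %*% t(params$crs_Wk) +
    dVq %*% t(params$crs_Wv)
  dZs <- dZs + dQs %*% t(params$crs_Wq) + dKs %*% t(params$crs_Wk) +
    dVs %*% t(params$crs_Wv)
  dZ <- rbind(dZs, dZq)
  # context stage backward
  dP2 <- ln_bwd(dZ, cc$Z, cc$l2$inv)
  bw1 <- attn_bwd(dP2, cc$a1, cc$E, C,
                  params$ctx_Wq, params$ctx_Wk, params$ctx_Wv,
                  cfg$context_heads, cc$b1)
  g$ctx_Wq <- bw1$dWq; g$ctx_Wk <- bw1$dWk; g$ctx_Wv <- bw1$dWv
  dE <- dP2 + bw1$dE                 # context memory C is frozen: no dC path
  # encoder backward
  dH <- ln_bwd(dE, cc$E, cc$l1$inv)
  g$enc_W2 <- t(cc$H1) %*% dH
  g$enc_b2 <- colSums(dH)
  if (cc$has_hidden) {
    dH1 <- (dH %*% t(params$enc_W2)) * (cc$H1 > 0)
    g$enc_W1 <- t(cc$X) %*% dH1
    g$enc_b1 <- colSums(dH1)
  }
  g$rho <- dscale * stats::plogis(params$rho)
  list(loss = loss, scores = scores, grads = g)
}

#' Adam update step
#' @keywords internal
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(t = 0L, m = zero, v = zero)
}
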