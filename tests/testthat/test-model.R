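# Architectural contracts of the predictor: row-wise encoding, independent
# context enrichment, per-query cross-attention, label-flip antisymmetry,
# and the analytic gradients that train it.

test_that("encoding is a row-wise map", {
  ts <- tiny_setup(101)
  X <- ts$Xs
  E <- encode(ts$model, X)
  expect_identical(dim(E), c(nrow(X), ts$model$config$embed_dim))
  # duplicated rows encode identically
  E2 <- encode(ts$model, X[c(1, 1, 2), ])
  expect_equal(E2[1, ], E2[2, ], tolerance = 1e-12)
  # permuting rows permutes embeddings
  p <- c(3, 1, 4, 2)
  expect_equal(encode(ts$model, X[p, ]), E[p, ], tolerance = 1e-12)
  expect_error(encode(ts$model, X[, 1:3]), class = "fewshotmol_dimension_mismatch")
})

test_that("context enrichment updates rows independently and ignores context order", {
  ts <- tiny_setup(102)
  E <- encode(ts$model, rbind(ts$Xs, ts$Xq))
  C <- ts$model$context$embeddings
  Z <- context_enrich(ts$model, E, C)
  # row independence: enriching a single row equals its slice of the batch
  for (i in seq_len(nrow(E))) {
    zi <- context_enrich(ts$model, E[i, , drop = FALSE], C)
    expect_equal(as.numeric(zi), Z[i, ], tolerance = 1e-6)
  }
  # permutation invariance over the memory
  perm <- withr::with_seed(1, sample(nrow(C)))
  expect_equal(context_enrich(ts$model, E, C[perm, ]), Z, tolerance = 1e-6)
  expect_error(context_enrich(ts$model, E, C[0, , drop = FALSE]),
               class = "fewshotmol_empty_context")
})

test_that("a single-molecule context yields the same enrichment for any retrieval beta", {
  # softmax over one memory slot is 1 regardless of temperature, so the
  # readout is that slot's value row and beta cannot matter
  ts1 <- tiny_setup(103)
  C1 <- ts1$model$context$embeddings[1, , drop = FALSE]
  E <- encode(ts1$model, ts1$Xs)
  m_hot <- ts1$model
  m_hot$config$retrieval_beta <- 50
  expect_equal(context_enrich(ts1$model, E, C1),
               context_enrich(m_hot, E, C1), tolerance = 1e-9)
})

test_that("cross-attention treats queries separately and support order equivariantly", {
  ts <- tiny_setup(104)
  E <- encode(ts$model, rbind(ts$Xs, ts$Xq))
  S <- nrow(ts$Xs)
  Zs <- E[seq_len(S), ]
  q1 <- E[S + 1, ]
  q2 <- E[S + 2, ]
  ca1 <- cross_attend(ts$model, q1, Zs)
  ca2 <- cross_attend(ts$model, q2, Zs)
  expect_length(ca1$query, ts$model$config$embed_dim)
  expect_identical(dim(ca1$support), dim(Zs))
  # repeating with another query around does not change the first's output
  expect_equal(cross_attend(ts$model, q1, Zs)$query, ca1$query, tolerance = 1e-12)
  # support permutation permutes support outputs and fixes the query output
  perm <- c(3, 1, 4, 2)
  cap <- cross_attend(ts$model, q1, Zs[perm, ])
  expect_equal(cap$query, ca1$query, tolerance = 1e-6)
  expect_equal(cap$support, ca1$support[perm, ], tolerance = 1e-6)
  expect_false(isTRUE(all.equal(ca1$query, ca2$query)))
})

test_that("similarity scoring obeys its closed forms", {
  q <- c(1, 2, -1, 0.5)
  # support = {q with label 1, -q with label 0} gives sigmoid(scale)
  Smat <- rbind(q, -q)
  for (scale in c(0.5, 2, 5)) {
    expect_equal(similarity_predict(q, Smat, c(1, 0), scale),
                 plogis(scale), tolerance = 1e-12)
  }
  # orthogonal support with balanced labels scores exactly 0.5
  o1 <- c(2, -1, 0, 0)
  o2 <- c(0, 0, 1, 2)
  expect_equal(similarity_predict(q, rbind(o1, o2), c(1, 0), 3), 0.5, tolerance = 1e-12)
  # flipping all labels complements the score exactly
  withr::with_seed(9, {
    Sm <- matrix(rnorm(20), 5)
    y <- c(1, 0, 1, 1, 0)
    s1 <- similarity_predict(q[1:4], Sm, y, 4)
    s2 <- similarity_predict(q[1:4], Sm, 1 - y, 4)
    expect_equal(s1 + s2, 1, tolerance = 1e-12)
  })
  expect_error(similarity_predict(c(0, 0, 0, 0), Smat, c(1, 0), 1),
               class = "fewshotmol_zero_vector")
})

test_that("end-to-end scores are in (0,1), support-order invariant and label-flip antisymmetric", {
  ts <- tiny_setup(105)
  sc <- predict_scores(ts$model, ts$Xs, ts$ys, ts$Xq)
  expect_true(all(sc > 0 & sc < 1))
  perm <- withr::with_seed(2, sample(nrow(ts$Xs)))
  sc_perm <- predict_scores(ts$model, ts$Xs[perm, ], ts$ys[perm], ts$Xq)
  expect_equal(sc_perm, sc, tolerance = 1e-6)
  sc_flip <- predict_scores(ts$model, ts$Xs, 1 - ts$ys, ts$Xq)
  expect_equal(sc + sc_flip, rep(1, length(sc)), tolerance = 1e-6)
  # singleton batches match the full batch
  for (i in seq_len(nrow(ts$Xq))) {
    expect_equal(predict_scores(ts$model, ts$Xs, ts$ys, ts$Xq[i, , drop = FALSE]),
                 sc[i], tolerance = 1e-6)
  }
})

test_that("training forward pass reproduces the prediction path exactly", {
  ts <- tiny_setup(106)
  yq <- c(1, 0, 1)
  lg <- fewshotmol:::fs_loss_grad(ts$model$params, ts$model$config, ts$Xs, ts$ys,
                                  ts$Xq, yq, ts$model$context$embeddings)
  expect_equal(lg$scores, predict_scores(ts$model, ts$Xs, ts$ys, ts$Xq),
               tolerance = 1e-14)
  expect_equal(lg$loss, episode_loss(lg$scores, yq), tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  ts <- tiny_setup(107, D = 7L, d = 4L, S = 3L, Q = 2L, M = 5L)
  p <- ts$model$params
  cfg <- ts$model$config
  C <- ts$model$context$embeddings
  yq <- c(0, 1)
  lg <- fewshotmol:::fs_loss_grad(p, cfg, ts$Xs, ts$ys, ts$Xq, yq, C)
  h <- 1e-6
  for (nm in names(p)) {
    n <- length(p[[nm]])
    idx <- withr::with_seed(1, if (n > 6) sample(n, 6) else seq_len(n))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (fewshotmol:::fs_loss_grad(pp, cfg, ts$Xs, ts$ys, ts$Xq, yq, C)$loss -
             fewshotmol:::fs_loss_grad(pm, cfg, ts$Xs, ts$ys, ts$Xq, yq, C)$loss) / (2 * h)
      expect_equal(lg$grads[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d]", nm, i))
    }
  }
})
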