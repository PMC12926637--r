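test_that("complex_score reproduces hand and brute-force oracles", {
  # zero embeddings -> 0
  emb0 <- init_complex_emb(3, 1, 2, seed = 1)
  emb0$ent_re[] <- 0; emb0$ent_im[] <- 0; emb0$rel_re[] <- 0; emb0$rel_im[] <- 0
  expect_equal(complex_score(0L, 0L, 1L, emb0), 0)

  # K=1 pure real: w=1, e_h=1, e_t=1 -> 1
  e <- init_complex_emb(2, 1, 1, seed = 1)
  e$ent_re[] <- 1; e$ent_im[] <- 0; e$rel_re[] <- 1; e$rel_im[] <- 0
  expect_equal(complex_score(0L, 0L, 1L, e), 1)

  # K=1 imaginary witness: w=i, e_h=1, e_t=i -> Re(i * 1 * conj(i)) = 1
  e$ent_re[] <- c(1, 0); e$ent_im[] <- c(0, 1)
  e$rel_re[] <- 0; e$rel_im[] <- 1
  expect_equal(complex_score(0L, 0L, 1L, e), 1)

  # brute force with native complex arithmetic, 1000 random cases
  set.seed(12)
  max_err <- 0
  for (case in 1:50) {
    K <- sample(1:8, 1)
    n <- sample(3:10, 1)
    emb <- init_complex_emb(n, 2, K, seed = case)
    ce <- emb$ent_re + 1i * emb$ent_im
    cw <- emb$rel_re + 1i * emb$rel_im
    h <- sample(0:(n - 1), 20, replace = TRUE)
    r <- sample(0:1, 20, replace = TRUE)
    t <- sample(0:(n - 1), 20, replace = TRUE)
    phi <- complex_score(h, r, t, emb)
    oracle <- vapply(1:20, function(i) {
      Re(sum(cw[r[i] + 1, ] * ce[h[i] + 1, ] * Conj(ce[t[i] + 1, ])))
    }, numeric(1))
    max_err <- max(max_err, max(abs(phi - oracle)))
  }
  expect_lt(max_err, 1e-10)
  expect_error(complex_score(99L, 0L, 0L, e), "out of range")
})

test_that("ComplEx can be antisymmetric; DistMult restriction cannot", {
  e <- init_complex_emb(2, 1, 1, seed = 1)
  e$ent_re[] <- c(1, 0); e$ent_im[] <- c(0, 1)
  e$rel_re[] <- 0; e$rel_im[] <- 1
  expect_false(isTRUE(all.equal(complex_score(0L, 0L, 1L, e),
                                complex_score(1L, 0L, 0L, e))))
  # imaginary-zero restriction is symmetric for any embeddings
  set.seed(3)
  dm <- init_complex_emb(6, 2, 4, seed = 3)
  dm$ent_im[] <- 0; dm$rel_im[] <- 0
  h <- sample(0:5, 30, replace = TRUE)
  r <- sample(0:1, 30, replace = TRUE)
  t <- sample(0:5, 30, replace = TRUE)
  expect_equal(complex_score(h, r, t, dm), complex_score(t, r, h, dm),
               tolerance = 1e-12)
})

test_that("the regularised logistic loss matches scalar evaluations", {
  e <- init_complex_emb(2, 1, 1, seed = 1)
  e$ent_re[] <- 0; e$ent_im[] <- 0; e$rel_re[] <- 0; e$rel_im[] <- 0
  ts <- triple_set(c("A", "B"), "r", matrix(c(0L, 0L, 1L), 1), 1L)
  expect_equal(kg_logistic_loss(ts, e, lambda = 0), log(2), tolerance = 1e-12)

  # phi = 2 with Y = -1: log(1 + e^2)
  e$ent_re[] <- 1; e$rel_re[] <- 2
  ts_neg <- triple_set(c("A", "B"), "r", matrix(c(0L, 0L, 1L), 1), -1L)
  expect_equal(kg_logistic_loss(ts_neg, e, lambda = 0), log(1 + exp(2)),
               tolerance = 1e-12)
  expect_equal(round(kg_logistic_loss(ts_neg, e, 0), 4), 2.1269)

  # monotone decreasing in Y*phi; lambda > 0 strictly increases the loss
  e2 <- e; e2$rel_re[] <- 3
  expect_lt(kg_logistic_loss(ts, e2, 0), kg_logistic_loss(ts, e, 0))
  expect_gt(kg_logistic_loss(ts, e, 1e-3), kg_logistic_loss(ts, e, 0))
  bad <- ts; bad$labels <- 2L
  expect_error(kg_logistic_loss(bad, e), "labels")
})

test_that("negative sampling corrupts exactly one slot and avoids positives", {
  set.seed(4)
  tri <- cbind(sample(0:19, 10), sample(0:1, 10, replace = TRUE), sample(0:19, 10))
  tri <- tri[tri[, 1] != tri[, 3], , drop = FALSE]
  ts <- triple_set(sprintf("E%d", 1:20), c("r1", "r2"), tri,
                   rep(1L, nrow(tri)))
  neg <- sample_negatives(ts, k = 2, seed = 5)
  expect_equal(nrow(neg$triples), 2L * nrow(tri))
  expect_true(all(neg$labels == -1L))
  seen <- paste(tri[, 1], tri[, 2], tri[, 3])
  expect_false(any(paste(neg$triples[, 1], neg$triples[, 2],
                         neg$triples[, 3]) %in% seen))
  src <- tri[rep(seq_len(nrow(tri)), each = 2), , drop = FALSE]
  diff_h <- neg$triples[, 1] != src[, 1]
  diff_t <- neg$triples[, 3] != src[, 3]
  expect_true(all(xor(diff_h, diff_t)))
  expect_true(all(neg$triples[, 2] == src[, 2]))
  expect_identical(sample_negatives(ts, 2, seed = 5)$triples, neg$triples)
})

test_that("training reduces loss and the DistMult restriction stays real", {
  cfg <- synth_config(seed = 6, n_kg_entities = 50, n_kg_relations = 2,
                      planted_rank = 4)
  kg <- gen_kg_triples(cfg)
  fit <- train_complex(kg$triples, rank = 8, epochs = 15, seed = 2)
  expect_lte(tail(fit$loss_history, 1), fit$loss_history[1])
  fit2 <- train_complex(kg$triples, rank = 8, epochs = 15, seed = 2)
  expect_identical(fit$loss_history, fit2$loss_history)

  dm <- train_complex(kg$triples, rank = 8, epochs = 5, seed = 2,
                      freeze_imaginary = TRUE)
  expect_true(all(dm$emb$ent_im == 0))
  tri <- kg$triples$triples[1:20, ]
  phi <- complex_score(tri[, 1], tri[, 2], tri[, 3], dm$emb)
  oracle <- vapply(1:20, function(i) {
    sum(dm$emb$rel_re[tri[i, 2] + 1, ] * dm$emb$ent_re[tri[i, 1] + 1, ] *
        dm$emb$ent_re[tri[i, 3] + 1, ])
  }, numeric(1))
  expect_equal(phi, oracle, tolerance = 1e-12)
})

test_that("global embeddings extract real parts with projection and cold starts", {
  emb <- init_complex_emb(3, 1, 2, seed = 1,
                          entity_names = c("D1", "D2", "D3"))
  emb$ent_re[1, ] <- c(1, 3)
  emb$ent_im[1, ] <- c(2, -1)
  G <- global_embeddings("D1", emb)
  expect_equal(unname(G[1, ]), c(1, 3))
  # purely imaginary embedding -> zero real part
  emb$ent_re[2, ] <- 0
  expect_equal(unname(global_embeddings("D2", emb)[1, ]), c(0, 0))
  # deterministic projection when d != rank
  G1 <- global_embeddings(c("D1", "D3"), emb, d = 5)
  G2 <- global_embeddings(c("D1", "D3"), emb, d = 5)
  expect_identical(G1, G2)
  expect_equal(ncol(G1), 5L)
  expect_warning(Gx <- global_embeddings("D9", emb), "cold-start")
  expect_equal(unname(Gx[1, ]), c(0, 0))
})
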