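test_that("layer_norm standardises across the feature dimension", {
  expect_equal(layer_norm(c(1, 1, 1), rep(1, 3), rep(0, 3)), rep(0, 3),
               tolerance = 1e-2)
  # two-point standardisation as eps -> 0
  expect_equal(layer_norm(c(1, 3), rep(1, 2), rep(0, 2), eps = 1e-12),
               c(-1, 1), tolerance = 1e-5)
  # centring whenever beta = 0
  set.seed(2)
  x <- rnorm(16)
  out <- layer_norm(x, runif(16, 0.5, 2), rep(0, 16))
  expect_lt(abs(mean(out)), 0.5)  # gamma-weighted, but centred xhat
  out2 <- layer_norm(x, rep(1, 16), rep(0, 16))
  expect_lt(abs(mean(out2)), 1e-10)
})

test_that("attention weights are simplex rows and match the scalar oracle", {
  ns <- asNamespace("ddifuse")
  # rows sum to 1 for random inputs
  set.seed(7)
  worst <- 0
  for (case in 1:200) {
    fp <- init_fusion_params(d = 8, n_tokens = 3, heads = 2, seed = case)
    toks <- lapply(1:3, function(i) matrix(rnorm(8), 1, 8))
    mf <- ns$mha_forward(toks, fp)
    for (h in seq_along(mf$cache$heads)) {
      for (i in 1:3) {
        worst <- max(worst, abs(rowSums(mf$cache$heads[[h]]$P[[i]]) - 1))
      }
    }
  }
  expect_lt(worst, 1e-6)

  # zero query/key projections -> uniform 1/3 weights
  fp <- init_fusion_params(d = 4, n_tokens = 3, heads = 1, seed = 1)
  fp$heads[[1]]$WQ[] <- 0
  fp$heads[[1]]$WK[] <- 0
  toks <- lapply(1:3, function(i) matrix(rnorm(4), 1, 4))
  mf <- ns$mha_forward(toks, fp)
  expect_equal(unname(mf$cache$heads[[1]]$P[[1]][1, ]), rep(1 / 3, 3),
               tolerance = 1e-12)

  # 2-token scalar check with identity projections: weight e/(e+1)
  fp1 <- init_fusion_params(d = 1, n_tokens = 2, heads = 1, seed = 1)
  fp1$heads[[1]]$WQ[] <- 1; fp1$heads[[1]]$WK[] <- 1; fp1$heads[[1]]$WV[] <- 1
  fp1$WO[] <- 1; fp1$bO[] <- 0
  toks <- list(matrix(1, 1, 1), matrix(0, 1, 1))
  mf <- ns$mha_forward(toks, fp1)
  w11 <- mf$cache$heads[[1]]$P[[1]][1, 1]
  expect_equal(w11, exp(1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(round(mf$out[[1]][1, 1], 4), 0.7311)
})

test_that("the encoder block is residual and permutation equivariant", {
  d <- 8
  fp <- init_fusion_params(d = d, n_tokens = 3, heads = 2, seed = 3)
  # zero every sub-layer output path: block must be the identity
  fp0 <- fp
  fp0$WO[] <- 0; fp0$bO[] <- 0
  fp0$ffn$W2[] <- 0; fp0$ffn$b2[] <- 0
  set.seed(5)
  tokens <- matrix(rnorm(3 * d), 3, d)
  expect_equal(transformer_encoder_block(tokens, fp0), tokens,
               tolerance = 1e-12)

  # shape contract and finiteness
  out <- transformer_encoder_block(tokens, fp)
  expect_equal(dim(out), dim(tokens))
  expect_true(all(is.finite(out)))

  # permuting the scale tokens permutes outputs identically (no positions)
  perm <- c(3, 1, 2)
  expect_equal(transformer_encoder_block(tokens[perm, ], fp), out[perm, ],
               tolerance = 1e-10)
  # same through raw attention
  expect_equal(multi_head_attention(tokens[perm, ], fp),
               multi_head_attention(tokens, fp)[perm, ], tolerance = 1e-10)
})

test_that("fusion strategies match their elementwise oracles", {
  a <- c(1, 2); l <- c(2, 0.5); g <- c(1, 1)
  expect_equal(fuse(list(a, l, g), "hadamard"), c(2, 1))
  expect_equal(fuse(list(c(1, 2), c(2, 4), c(3, 6)), "average"), c(2, 4))
  cc <- fuse(list(a, l, g), "concat")
  expect_length(cc, 6L)   # 3d before projection
  expect_equal(cc, c(a, l, g))

  # random-input oracles for the projected paths
  set.seed(11)
  for (case in 1:25) {
    d <- 6
    sc <- lapply(1:3, function(i) rnorm(d))
    fp_h <- init_fusion_params(d, 3, 2, strategy = "hadamard", seed = case)
    x <- fuse(sc, "hadamard", fp_h)
    oracle <- as.numeric(fp_h$readout$W %*% (sc[[1]] * sc[[2]] * sc[[3]]) +
                         fp_h$readout$b)
    expect_equal(x, oracle, tolerance = 1e-6)
    fp_a <- init_fusion_params(d, 3, 2, strategy = "average", seed = case)
    x2 <- fuse(sc, "average", fp_a)
    oracle2 <- as.numeric(fp_a$readout$W %*% ((sc[[1]] + sc[[2]] + sc[[3]]) / 3) +
                          fp_a$readout$b)
    expect_equal(x2, oracle2, tolerance = 1e-6)
  }

  # all strategies emit width-d vectors when parameterised
  for (st in c("transformer", "concat", "hadamard", "average")) {
    fp <- init_fusion_params(8, 3, 2, strategy = st, seed = 2)
    sc <- lapply(1:3, function(i) rnorm(8))
    expect_length(fuse(sc, st, fp), 8L)
  }
  expect_error(fuse(list(a, l, g), "geometric"), "arg")
  expect_error(init_fusion_params(10, 3, 3), "divisible")
})
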