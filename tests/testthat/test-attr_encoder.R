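test_that("mask counts follow the round-half-up, minimum-one rule", {
  # exhaustive rule check over |V| in 1..1000 against the stated formula
  sizes <- 1:1000
  expected <- pmax(1L, as.integer(floor(0.15 * sizes + 0.5)))
  # spot-check through mask_nodes itself on a spread of real graphs
  for (n in c(1L, 7L, 10L, 100L, 333L)) {
    g <- smiles_to_graph(chain_smiles(n))
    mk <- mask_nodes(g, rate = 0.15, seed = 2)
    expect_length(mk$masked, expected[n])
    expect_true(all(mk$masked <= n))
    expect_equal(mk$targets, match(g$atom[mk$masked], ddifuse:::ATOM_TYPES))
  }
  # |V|=100 at the default rate: exactly 15 masked nodes
  expect_length(mask_nodes(smiles_to_graph(chain_smiles(100)))$masked, 15L)
  # formula sweep (the rule itself, all sizes)
  expect_equal(pmax(1L, as.integer(floor(0.15 * 7 + 0.5))), 1L)
  expect_true(all(expected >= 1L))
  expect_error(mask_nodes(smiles_to_graph("C"), rate = 1.5), "rate")
})

test_that("the message-passing layer matches a per-node loop oracle", {
  set.seed(31)
  d <- 6
  for (case in 1:20) {
    n <- sample(2:10, 1)
    g <- random_molgraph(n)
    h <- matrix(rnorm(n * d), n, d)
    e <- matrix(rnorm(nrow(g$edges) * d), nrow(g$edges), d)
    layer <- list(W1 = matrix(rnorm(d * d), d, d), b1 = rnorm(d),
                  W2 = matrix(rnorm(d * d), d, d), b2 = rnorm(d))
    out <- gnn_layer(g, h, e, layer)
    # brute force: per node, sum neighbours + self + incident edge rows,
    # then the two-affine MLP with rectifiers
    for (v in sample(n, min(n, 3))) {
      s <- h[v, ]
      for (k in seq_len(nrow(g$edges))) {
        i <- g$edges[k, 1]; j <- g$edges[k, 2]
        if (i == v) { s <- s + h[j, ] + e[k, ] }
        if (j == v) { s <- s + h[i, ] + e[k, ] }
      }
      z1 <- pmax(layer$W1 %*% s + layer$b1, 0)
      z2 <- pmax(layer$W2 %*% z1 + layer$b2, 0)
      expect_equal(out[v, ], as.numeric(z2), tolerance = 1e-6)
    }
  }
})

test_that("layer algebra degenerate cases behave as stated", {
  d <- 2
  idmlp <- list(W1 = diag(d), b1 = rep(0, d), W2 = diag(d), b2 = rep(0, d))
  # isolated node, identity MLP -> ReLU(h_v)
  g1 <- smiles_to_graph("C")
  h <- matrix(c(-1, 2), 1, 2)
  expect_equal(gnn_layer(g1, h, matrix(0, 0, 2), idmlp),
               matrix(c(0, 2), 1, 2))
  # two connected nodes with an edge embedding, identity MLP
  g2 <- smiles_to_graph("CC")
  h <- rbind(c(1, 0), c(0, 1))
  e <- matrix(c(1, 1), 1, 2)
  out <- gnn_layer(g2, h, e, idmlp)
  expect_equal(out[1, ], c(2, 2))
  expect_equal(out[2, ], c(2, 2))
})

test_that("encoding is permutation invariant and pooling is the mean", {
  params <- init_attr_params(d = 8, K = 2, seed = 5)
  g <- smiles_to_graph("CC(N)C(=O)O")
  a <- encode_molecule(g, params)
  expect_length(a, 8L)
  # relabel nodes: reverse order
  perm <- rev(seq_len(g$n))
  g2 <- g
  g2$atom <- g$atom[perm]
  inv <- order(perm)
  g2$edges <- matrix(cbind(inv[g$edges[, 1]], inv[g$edges[, 2]]), ncol = 2)
  g2$charge <- g$charge[perm]
  expect_equal(encode_molecule(g2, params), a, tolerance = 1e-12)

  # mean pooling of known node embeddings
  ns <- asNamespace("ddifuse")
  H <- ns$attr_encode_nodes(g, params)
  expect_equal(a, colMeans(H))
})

test_that("masking pretraining learns and is seed-deterministic", {
  mols <- lapply(gen_molecules(40, seed = 17)$smiles, smiles_to_graph)
  fit1 <- pretrain_masking(mols, epochs = 15, d = 16, K = 2, seed = 4)
  fit2 <- pretrain_masking(mols, epochs = 15, d = 16, K = 2, seed = 4)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_true(all(is.finite(fit1$loss_history)))
  expect_lte(tail(fit1$loss_history, 1), fit1$loss_history[1])
  # untrained accuracy is near chance for the four types present
  expect_lt(fit1$init_acc, 1 / 4 + 0.1 + 0.05)
  # trained reconstruction beats the untrained model
  acc0 <- masked_accuracy(mols, init_attr_params(16, 2, 4), seed = 77)
  acc1 <- masked_accuracy(mols, fit1$params, seed = 77)
  expect_gt(acc1, acc0)
})

test_that("single-atom-type corpora trigger the degenerate-target warning", {
  mols <- lapply(c("CCC", "CC"), smiles_to_graph)
  expect_warning(pretrain_masking(mols, epochs = 2, d = 8, K = 1, seed = 1),
                 "single atom type")
})
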