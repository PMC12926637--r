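test_that("relation_update matches the stated hand example", {
  # v with neighbours u1, u2 under one relation; W selects the neighbour
  # half of the concatenation, so output = sigmoid(mean(u1, u2))
  assoc <- data.frame(drug_id = c("D1", "D1"), relation = "protein",
                      entity_id = c("P1", "P2"))
  g <- hetero_graph(assoc, "D1")
  d <- 2
  E <- rbind(c(0, 0), c(1, 1), c(3, 3))   # D1, P1, P2
  W <- cbind(matrix(0, d, d), diag(d))    # selector of the neighbour mean
  out <- relation_update(g, "D1", "protein", E, W)
  expect_equal(out, rep(plogis(2), 2), tolerance = 1e-4)
  expect_equal(round(out[1], 4), 0.8808)

  # empty neighbourhood aggregates to zero -> sigmoid(0) = 0.5
  assoc2 <- data.frame(drug_id = "D2", relation = "disease", entity_id = "X")
  g2 <- hetero_graph(assoc2, c("D1", "D2"))
  expect_equal(relation_update(g2, "D1", "disease", matrix(0, 3, d), W),
               rep(0.5, d))
  expect_error(relation_update(g, "D1", "pathway", E, W), "unknown relation")
})

test_that("layer_forward sums relation updates and stays bounded", {
  assoc <- tiny_assoc()
  g <- hetero_graph(assoc, c("D1", "D2", "D3"))
  d <- 4
  set.seed(2)
  E <- matrix(rnorm(length(g$nodes) * d), ncol = d)
  W_layer <- lapply(g$relations, function(r) matrix(rnorm(d * 2 * d, sd = 0.5), d, 2 * d))
  names(W_layer) <- g$relations
  out <- layer_forward(g, E, W_layer)
  # bounded elementwise by the number of relations
  expect_true(all(out > 0 & out < length(g$relations)))
  # matches per-node relation_update sum
  for (v in c("D1", "D3", "P1")) {
    ref <- Reduce(`+`, lapply(g$relations, function(r) {
      relation_update(g, v, r, E, W_layer[[r]])
    }))
    expect_equal(out[match(v, g$nodes), ], ref, tolerance = 1e-6)
  }
})

test_that("single-relation graphs make layer_forward equal relation_update", {
  assoc <- data.frame(drug_id = c("D1", "D2"), relation = "protein",
                      entity_id = c("P1", "P1"))
  g <- hetero_graph(assoc, c("D1", "D2"))
  d <- 3
  set.seed(3)
  E <- matrix(rnorm(length(g$nodes) * d), ncol = d)
  W <- list(protein = matrix(rnorm(d * 2 * d), d, 2 * d))
  out <- layer_forward(g, E, W)
  expect_equal(out[1, ], relation_update(g, "D1", "protein", E, W$protein),
               tolerance = 1e-8)
})

test_that("encode_local is invariant to entity relabeling and warns on cold starts", {
  assoc <- tiny_assoc()
  g <- hetero_graph(assoc, c("D1", "D2", "D3"))
  p <- init_local_params(g, d = 8, K = 1, seed = 6)
  L <- encode_local(g, p)
  expect_equal(rownames(L), c("D1", "D2", "D3"))
  # renaming entities (same structure) leaves drug embeddings unchanged
  assoc2 <- assoc
  assoc2$entity_id <- paste0("X", assoc$entity_id)
  g2 <- hetero_graph(assoc2, c("D1", "D2", "D3"))
  p2 <- p  # same parameter tables; node order is identical by construction
  expect_equal(encode_local(g2, p2), L)

  # a drug absent from the association table is a cold start
  g3 <- hetero_graph(assoc, c("D1", "D2", "D3", "D4"))
  p3 <- init_local_params(g3, d = 8, K = 1, seed = 6)
  expect_warning(encode_local(g3, p3), "cold-start.*D4")
})

test_that("link-reconstruction pretraining reduces loss deterministically", {
  cfg <- synth_config(seed = 21, n_drugs = 40, n_entities_per_relation = 12,
                      n_communities = 2)
  het <- gen_hetero_associations(cfg)
  g <- hetero_graph(het$associations, sprintf("D%03d", 1:40))
  f1 <- pretrain_local(g, epochs = 20, d = 12, K = 1, seed = 9)
  f2 <- pretrain_local(g, epochs = 20, d = 12, K = 1, seed = 9)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_lte(tail(f1$loss_history, 1), f1$loss_history[1])

  # held-out style check: observed edges outscore sampled non-edges
  L <- suppressWarnings(encode_local(g, f1$params))
  E_all <- f1$params$E0
  for (k in seq_len(f1$params$K)) E_all <- layer_forward(g, E_all, f1$params$W[[k]])
  idx <- stats::setNames(seq_along(g$nodes), g$nodes)
  pos <- het$associations[1:50, ]
  s_pos <- rowSums(E_all[idx[pos$drug_id], ] * E_all[idx[pos$entity_id], ])
  set.seed(1)
  rnd_d <- sample(g$drug_ids, 50, replace = TRUE)
  rnd_e <- sample(setdiff(g$nodes, g$drug_ids), 50, replace = TRUE)
  s_neg <- rowSums(E_all[idx[rnd_d], ] * E_all[idx[rnd_e], ])
  expect_gt(mean(s_pos), mean(s_neg))
})
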