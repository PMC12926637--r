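test_that("generators are pure functions of their seeds", {
  expect_identical(gen_molecules(5, seed = 1), gen_molecules(5, seed = 1))
  cfg <- synth_config(seed = 4, n_drugs = 30, n_entities_per_relation = 10)
  expect_identical(gen_hetero_associations(cfg)$associations,
                   gen_hetero_associations(cfg)$associations)
  cfg2 <- synth_config(seed = 4, n_drugs = 10, n_kg_entities = 40,
                       planted_rank = 4)
  expect_identical(gen_kg_triples(cfg2)$triples$triples,
                   gen_kg_triples(cfg2)$triples$triples)
  U <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(sprintf("D%03d", 1:30), NULL))
  expect_identical(gen_pairs(U, "binary", cfg), gen_pairs(U, "binary", cfg))
})

test_that("generated molecules parse and vary in size", {
  mols <- gen_molecules(200, seed = 3)
  graphs <- lapply(mols$smiles, smiles_to_graph)   # must not error
  sizes <- vapply(graphs, function(g) g$n, integer(1))
  expect_equal(length(mols$smiles), 200L)
  expect_gte(length(unique(sizes)), 2L)
  expect_true(all(unlist(lapply(graphs, `[[`, "atom")) %in%
                  c("C", "N", "O", "S")))
})

test_that("association block structure matches p_in / p_out expectations", {
  # Monte-Carlo mean degree over seeds vs p_in*block + p_out*rest, 3 SE
  cfg0 <- synth_config(n_drugs = 40, n_entities_per_relation = 20,
                       n_communities = 2)
  block <- 10; rest <- 10
  exp_deg <- 0.3 * block + 0.02 * rest
  degs <- vapply(1:50, function(s) {
    cfg <- synth_config(seed = s, n_drugs = 40,
                        n_entities_per_relation = 20, n_communities = 2)
    het <- gen_hetero_associations(cfg)
    nrow(het$associations) / (40 * 3)   # mean degree per drug per relation
  }, numeric(1))
  se <- sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - exp_deg), 3 * se + 1e-9)

  # drugs in different communities have disjoint high-probability blocks
  het <- gen_hetero_associations(synth_config(seed = 2, n_drugs = 40,
                                              n_entities_per_relation = 20,
                                              n_communities = 2))
  blocks <- het$entity_block[["protein"]]
  expect_true(all(table(blocks) == 10))
})

test_that("planted KG triples follow the top-quantile rule", {
  cfg <- synth_config(seed = 11, n_kg_entities = 200, n_kg_relations = 3,
                      planted_rank = 8)
  kg <- gen_kg_triples(cfg)
  n_pos <- floor(0.05 * 200 * 200)
  expect_equal(nrow(kg$triples$triples), 3L * n_pos)
  expect_equal(nrow(kg$heldout_negatives$triples), 3L * n_pos)
  expect_true(all(kg$triples$labels == 1L))
  expect_true(all(kg$heldout_negatives$labels == -1L))

  # strict quantile labelling: per relation, min planted positive score
  # exceeds max planted negative score
  pl <- kg$planted
  score_of <- function(tri) {
    emb <- init_complex_emb(200, 3, 8, seed = 1)
    emb$ent_re <- pl$ent_re; emb$ent_im <- pl$ent_im
    emb$rel_re <- pl$rel_re; emb$rel_im <- pl$rel_im
    complex_score(tri[, 1], tri[, 2], tri[, 3], emb)
  }
  for (r in 0:2) {
    ps <- score_of(kg$triples$triples[kg$triples$triples[, 2] == r, , drop = FALSE])
    ns <- score_of(kg$heldout_negatives$triples[
      kg$heldout_negatives$triples[, 2] == r, , drop = FALSE])
    expect_gt(min(ps), max(ns))
  }
})

test_that("zero-imaginary planted embeddings reduce to the real trilinear product", {
  set.seed(8)
  n <- 12; K <- 4
  er <- matrix(rnorm(n * K), n, K)
  wr <- rnorm(K)
  ns <- asNamespace("ddifuse")
  S <- ns$complex_score_matrix(er, matrix(0, n, K), wr, rep(0, K))
  oracle <- matrix(0, n, n)
  for (h in 1:n) for (t in 1:n) oracle[h, t] <- sum(wr * er[h, ] * er[t, ])
  expect_equal(S, oracle, tolerance = 1e-12)
})

test_that("pair labels carry planted signal with calibrated positives", {
  cfg <- synth_config(seed = 5, n_drugs = 300)
  community <- rep_len(1:4, 300)
  U <- gen_drug_latents(cfg, community)
  pairs <- gen_pairs(U, "binary", cfg)
  frac <- mean(pairs$label)
  expect_gte(frac, 0.40)
  expect_lte(frac, 0.60)

  # the generating probability ranks the drawn labels far above chance,
  # and permuting labels destroys the association
  p_truth <- attr(pairs, "truth")
  expect_gt(rank_metrics(pairs$label, p_truth)$auroc, 0.9)
  set.seed(1)
  perm <- sample(pairs$label)
  expect_lt(abs(rank_metrics(perm, p_truth)$auroc - 0.5), 0.05)
})

test_that("event classes are long-tailed and Zipf-prior ordered", {
  cfg <- synth_config(seed = 9, n_drugs = 150, event_classes = 20,
                      zipf_exponent = 1.5)
  community <- rep_len(1:4, 150)
  U <- gen_drug_latents(cfg, community)
  pairs <- gen_pairs(U, "event", cfg)
  freq <- sort(table(pairs$label), decreasing = TRUE)
  expect_true(all(diff(as.integer(freq)) <= 0))
  expect_gt(max(freq) / min(freq), 3)   # a genuine tail
  expect_length(attr(pairs, "class_vocab"), length(unique(pairs$label)))
})

test_that("simulate_dataset writes a coherent, re-readable bundle", {
  dir <- tempfile()
  cfg <- synth_config(seed = 3, n_drugs = 25, n_entities_per_relation = 10,
                      n_kg_entities = 40, n_pairs = 60)
  sim <- simulate_dataset(cfg, dir)
  drugs <- read_drug_table(file.path(dir, "drugs.tsv"))
  expect_equal(nrow(drugs), 25L)
  assoc <- read_association_table(file.path(dir, "associations.tsv"))
  expect_true(all(assoc$drug_id %in% drugs$drug_id))
  ts <- read_triples(file.path(dir, "triples.tsv"))
  # drugs without any positive triple drop out of the file vocabulary and
  # take the documented cold-start path downstream
  expect_gt(mean(drugs$drug_id %in% names(ts$entity_vocab)), 0.8)
  pairs <- read_pair_table(file.path(dir, "pairs.tsv"), "binary")
  expect_true(all(c(pairs$drug_a, pairs$drug_b) %in% drugs$drug_id))
  truth <- utils::read.delim(file.path(dir, "truth", "communities.tsv"))
  expect_equal(nrow(truth), 25L)
})
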