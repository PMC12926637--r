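# Shared fixtures, built in code at load time.

write_tmp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

tiny_drug_file <- function() {
  write_tmp_tsv(c("drug_id\tsmiles", "D1\tCCO", "D2\tCC"))
}

# A small deterministic association table over two relations.
tiny_assoc <- function() {
  data.frame(
    drug_id = c("D1", "D1", "D2", "D2", "D3"),
    relation = c("protein", "disease", "protein", "side_effect", "protein"),
    entity_id = c("P1", "DI1", "P1", "S1", "P2")
  )
}

# A linear carbon chain of n atoms as SMILES.
chain_smiles <- function(n) paste(rep("C", n), collapse = "")

# Random mol_graph-compatible structure for oracle tests: a random simple
# graph on n nodes with ~p edge density, atoms drawn from C/N/O/S.
random_molgraph <- function(n, p = 0.4) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  structure(list(
    n = n,
    atom = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    edges = matrix(as.integer(edges), ncol = 2L),
    bond_order = rep(1L, nrow(edges)),
    charge = integer(n),
    smiles = NA_character_
  ), class = "mol_graph")
}

# Ridge linear probe accuracy: binary labels from embeddings, 70/30 split.
ridge_probe_accuracy <- function(E, y, seed = 1) {
  set.seed(seed)
  n <- nrow(E)
  tr <- sample(n, round(0.7 * n))
  fit <- glmnet::glmnet(E[tr, ], y[tr], family = "binomial",
                        alpha = 0, lambda = 0.05)
  p <- predict(fit, E[-tr, ], type = "response")[, 1]
  mean((p > 0.5) == (y[-tr] == 1))
}
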