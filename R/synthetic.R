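# Seeded synthetic-data generators. These emulate the statistical structure
# the model assumes — valid small-molecule SMILES whose atom types are a
# near-deterministic function of topological role, relation-typed bipartite
# association graphs with planted drug communities, knowledge-graph triples
# from a planted low-rank complex factorisation, and pair labels from a
# plantable bilinear interaction rule — without imitating real chemistry or
# ontology semantics. Every generator is a pure function of (config, seed).

#' Synthetic-world configuration
#'
#' Defaults are the stated world of the package's test surface: 4 drug
#' communities with latent noise `tau = 0.15` and pair-logit scale 6 make the
#' planted interaction rule informative but not trivial; `p_in = 0.3` /
#' `p_out = 0.02` give recoverable community structure at desk scale;
#' the top-5\% quantile rule and Zipf exponent 1.5 govern the planted
#' knowledge graph and the long-tailed event classes.
#'
#' @param seed master integer seed; each generator derives its own stream
#'   via [sub_seed()].
#' @param n_drugs number of drugs.
#' @param n_entities_per_relation entities per association relation
#'   (side_effect / protein / disease).
#' @param n_kg_entities total knowledge-graph entities (must be >=
#'   `n_drugs` when drugs are embedded in the KG).
#' @param n_kg_relations number of KG relation types.
#' @param planted_rank rank of the planted complex factorisation.
#' @param n_communities number of latent drug communities.
#' @param event_classes number of DDI event classes (event mode).
#' @param zipf_exponent exponent of the Zipf class prior (> 0).
#' @param p_in,p_out within/between-block association edge probabilities.
#' @param kg_quantile fraction of candidate triples labelled positive per
#'   relation.
#' @param latent_dim dimension of the planted per-drug latent vectors.
#' @param tau community noise: u_i = centre(community) + tau * eps.
#' @param pair_logit_scale standard deviation of the centred pair logits.
#' @param dominant_atom_prob probability that an atom takes the type its
#'   topological role dictates.
#' @param n_pairs number of drug pairs to generate; `NULL` (default) takes
#'   12\% of all unordered pairs, the approximate density of curated DDI
#'   corpora.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_drugs = 100L,
                         n_entities_per_relation = 30L,
                         n_kg_entities = 150L, n_kg_relations = 3L,
                         planted_rank = 8L, n_communities = 4L,
                         event_classes = 10L, zipf_exponent = 1.5,
                         p_in = 0.3, p_out = 0.02, kg_quantile = 0.05,
                         latent_dim = 8L, tau = 0.15, pair_logit_scale = 10,
                         dominant_atom_prob = 0.9, n_pairs = NULL) {
  cfg <- list(seed = as.integer(seed), n_drugs = as.integer(n_drugs),
              n_entities_per_relation = as.integer(n_entities_per_relation),
              n_kg_entities = as.integer(n_kg_entities),
              n_kg_relations = as.integer(n_kg_relations),
              planted_rank = as.integer(planted_rank),
              n_communities = as.integer(n_communities),
              event_classes = as.integer(event_classes),
              zipf_exponent = zipf_exponent, p_in = p_in, p_out = p_out,
              kg_quantile = kg_quantile, latent_dim = as.integer(latent_dim),
              tau = tau, pair_logit_scale = pair_logit_scale,
              dominant_atom_prob = dominant_atom_prob,
              n_pairs = if (is.null(n_pairs)) NULL else as.integer(n_pairs))
  counts <- cfg[c("n_drugs", "n_entities_per_relation", "n_kg_entities",
                  "n_kg_relations", "planted_rank", "n_communities",
                  "event_classes", "latent_dim")]
  if (!is.null(cfg$n_pairs) && cfg$n_pairs < 1L) stop("n_pairs must be >= 1")
  if (any(unlist(counts) < 1L)) stop("all synth_config counts must be >= 1")
  if (cfg$zipf_exponent <= 0) stop("zipf_exponent must be > 0")
  class(cfg) <- "synth_config"
  cfg
}

# ---- molecules --------------------------------------------------------------

# Random heavy-atom skeleton: a degree-capped random tree plus at most one
# ring edge, serialised to SMILES by depth-first traversal (the single
# non-tree edge becomes ring-closure digit 1).
random_skeleton <- function(n_atoms, ring_prob = 0.5) {
  parent <- integer(n_atoms)
  deg <- integer(n_atoms)
  for (i in seq_len(n_atoms)[-1]) {
    cand <- which(deg[seq_len(i - 1L)] < 4L)
    p <- cand[sample.int(length(cand), 1L)]
    parent[i] <- p
    deg[p] <- deg[p] + 1L
    deg[i] <- deg[i] + 1L
  }
  ring <- NULL
  if (n_atoms >= 3L && stats::runif(1) < ring_prob) {
    # candidate back edges: (i, ancestor at distance 2..5), degree cap 4
    anc <- function(i, k) { while (k > 0L && i > 0L) { i <- parent[i]; k <- k - 1L }; i }
    cand <- list()
    for (i in seq_len(n_atoms)[-1]) {
      for (dist in 2:5) {
        a <- anc(i, dist)
        if (a > 0L && deg[i] < 4L && deg[a] < 4L) cand[[length(cand) + 1L]] <- c(i, a)
      }
    }
    if (length(cand)) {
      ring <- cand[[sample.int(length(cand), 1L)]]
      deg[ring] <- deg[ring] + 1L
    }
  }
  list(parent = parent, ring = ring, deg = deg)
}

# Atom types by topological role, each with probability p_dom, else uniform
# over the remaining three of {C, N, O, S}.
assign_atoms <- function(sk, p_dom) {
  n <- length(sk$parent)
  on_ring <- logical(n)
  if (!is.null(sk$ring)) {
    i <- sk$ring[1L]; a <- sk$ring[2L]
    path <- i
    while (i != a) { i <- sk$parent[i]; path <- c(path, i) }
    on_ring[path] <- TRUE
  }
  role_type <- ifelse(sk$deg == 1L, "O",
               ifelse(sk$deg >= 3L, "N",
               ifelse(on_ring, "S", "C")))
  pool <- c("C", "N", "O", "S")
  flip <- stats::runif(n) >= p_dom
  out <- role_type
  if (any(flip)) {
    out[flip] <- vapply(role_type[flip], function(t) {
      sample(setdiff(pool, t), 1L)
    }, character(1))
  }
  out
}

skeleton_to_smiles <- function(sk, atoms) {
  n <- length(atoms)
  children <- split(seq_len(n)[-1][sk$parent[-1] > 0L], sk$parent[-1])
  ring <- sk$ring
  emit <- function(v) {
    s <- atoms[v]
    if (!is.null(ring) && v %in% ring) s <- paste0(s, "1")
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return(s)
    parts <- vapply(kids, emit, character(1))
    # last child continues the chain; earlier ones become branches
    k <- length(parts)
    if (k > 1L) {
      s <- paste0(s, paste0("(", parts[-k], ")", collapse = ""), parts[k])
    } else {
      s <- paste0(s, parts)
    }
    s
  }
  emit(1L)
}

#' Generate synthetic small-molecule SMILES
#'
#' Molecules are degree-capped random trees (8–20 heavy atoms) with at most
#' one ring, over atoms C/N/O/S and single bonds. Atom type follows the
#' atom's topological role (chain end -> O, branch point -> N, ring -> S,
#' chain interior -> C) with probability `p_dom`, so masked-attribute
#' reconstruction has learnable context signal while type frequencies stay
#' roughly balanced.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed.
#' @param p_dom dominant-role probability (default 0.9).
#' @return data.frame with `drug_id` (D001, ...) and `smiles`; every string
#'   parses with [smiles_to_graph()].
#' @export
gen_molecules <- function(n, seed, p_dom = 0.9) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    smiles <- vapply(seq_len(n), function(i) {
      n_atoms <- sample(8:20, 1L)
      sk <- random_skeleton(n_atoms)
      skeleton_to_smiles(sk, assign_atoms(sk, p_dom))
    }, character(1))
    data.frame(drug_id = sprintf("D%03d", seq_len(n)), smiles = smiles)
  })
}

# ---- association graph ------------------------------------------------------

#' Generate a relation-typed drug-entity association table
#'
#' Drugs are assigned to `n_communities` latent communities; each relation's
#' entity set is split into matching blocks. A drug-entity edge appears with
#' probability `p_in` inside the matched block and `p_out` elsewhere
#' (bipartite stochastic block model, independent across relations).
#'
#' @param cfg a [synth_config()].
#' @param drug_ids optional drug id tokens (default D001, ...).
#' @return list with `associations` (data.frame drug_id/relation/entity_id),
#'   `community` (integer vector of hidden labels, 1-based) and
#'   `entity_block` (named list per relation).
#' @export
gen_hetero_associations <- function(cfg, drug_ids = NULL) {
  n <- cfg$n_drugs
  if (is.null(drug_ids)) drug_ids <- sprintf("D%03d", seq_len(n))
  stopifnot(length(drug_ids) == n)
  with_seed(sub_seed(cfg$seed, STAGE_OFFSETS[["associations"]]), {
    community <- sample(rep_len(seq_len(cfg$n_communities), n))
    m <- cfg$n_entities_per_relation
    rows <- list()
    entity_block <- list()
    for (rel in RELATION_SET) {
      block <- rep_len(seq_len(cfg$n_communities), m)
      ents <- sprintf("%s_%03d", toupper(substr(rel, 1L, 2L)), seq_len(m))
      entity_block[[rel]] <- stats::setNames(block, ents)
      pmat <- matrix(cfg$p_out, n, m)
      pmat[outer(community, block, "==")] <- cfg$p_in
      hit <- matrix(stats::runif(n * m), n, m) < pmat
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx)) {
        rows[[rel]] <- data.frame(drug_id = drug_ids[idx[, 1L]],
                                  relation = rel,
                                  entity_id = ents[idx[, 2L]])
      }
    }
    assoc <- do.call(rbind, rows)
    rownames(assoc) <- NULL
    list(associations = assoc, community = community,
         entity_block = entity_block)
  })
}

# ---- knowledge graph --------------------------------------------------------

#' Generate knowledge-graph triples from a planted complex factorisation
#'
#' Entity and relation embeddings of rank `planted_rank` are drawn with
#' independent standard-normal real and imaginary parts; every candidate
#' (head, tail) pair is scored with the ComplEx scoring function and, per
#' relation, the top `kg_quantile` fraction becomes positive triples
#' (Y = +1). An equal count of non-positive candidates is sampled per
#' relation as held-out negatives.
#'
#' @param cfg a [synth_config()].
#' @param entity_names optional entity tokens (length `n_kg_entities`).
#' @return list with `triples` (positive `triple_set`), `heldout_negatives`
#'   (`triple_set` with Y = -1, sharing the same vocabularies) and `planted`
#'   (the planted embedding tables).
#' @export
gen_kg_triples <- function(cfg, entity_names = NULL) {
  n <- cfg$n_kg_entities
  K <- cfg$planted_rank
  stopifnot(K >= 1L)
  if (is.null(entity_names)) entity_names <- sprintf("E%04d", seq_len(n))
  stopifnot(length(entity_names) == n)
  rel_names <- sprintf("rel_%d", seq_len(cfg$n_kg_relations))
  n_pos_per_rel <- floor(cfg$kg_quantile * n * n)
  if (n_pos_per_rel < 1L) stop("candidate space too small for kg_quantile")
  if (2L * n_pos_per_rel > n * n) {
    stop("candidate space smaller than requested positive+negative sample")
  }
  with_seed(sub_seed(cfg$seed, STAGE_OFFSETS[["kg"]]), {
    planted <- list(
      ent_re = matrix(stats::rnorm(n * K), n, K),
      ent_im = matrix(stats::rnorm(n * K), n, K),
      rel_re = matrix(stats::rnorm(cfg$n_kg_relations * K), cfg$n_kg_relations, K),
      rel_im = matrix(stats::rnorm(cfg$n_kg_relations * K), cfg$n_kg_relations, K)
    )
    pos <- list(); neg <- list()
    for (r in seq_len(cfg$n_kg_relations)) {
      sc <- complex_score_matrix(planted$ent_re, planted$ent_im,
                                 planted$rel_re[r, ], planted$rel_im[r, ])
      ord <- order(sc, decreasing = TRUE)       # column-major linear indices
      top <- ord[seq_len(n_pos_per_rel)]
      rest <- ord[-seq_len(n_pos_per_rel)]
      samp <- rest[sample.int(length(rest), n_pos_per_rel)]
      lin2hr <- function(lin) cbind(((lin - 1L) %% n), r - 1L, ((lin - 1L) %/% n))
      pos[[r]] <- lin2hr(top)
      neg[[r]] <- lin2hr(samp)
    }
    pos <- do.call(rbind, pos)
    neg <- do.call(rbind, neg)
    list(
      triples = triple_set(entity_names, rel_names, pos, rep(1L, nrow(pos))),
      heldout_negatives = triple_set(entity_names, rel_names, neg,
                                     rep(-1L, nrow(neg))),
      planted = planted
    )
  })
}

# Full n x n ComplEx score matrix for one relation: S[h, t].
complex_score_matrix <- function(ent_re, ent_im, w_re, w_im) {
  (ent_re * rep(w_re, each = nrow(ent_re))) %*% t(ent_re) +
  (ent_im * rep(w_re, each = nrow(ent_re))) %*% t(ent_im) +
  (ent_re * rep(w_im, each = nrow(ent_re))) %*% t(ent_im) -
  (ent_im * rep(w_im, each = nrow(ent_im))) %*% t(ent_re)
}

# ---- pair labels ------------------------------------------------------------

zipf_weights <- function(k, s) {
  w <- seq_len(k)^(-s)
  w / sum(w)
}

#' Generate DDI pair labels from planted drug latents
#'
#' Binary mode: for sampled unordered pairs, the interaction logit is the
#' symmetric bilinear form u_i' M u_j with a seeded random symmetric M,
#' centred at its median (so positives come out near 50\%) and rescaled to
#' standard deviation `pair_logit_scale`; labels are Bernoulli draws of the
#' logistic probability. Event mode: the class is drawn from a multinomial
#' whose logits are a Zipf prior plus a pair-feature term, giving a learnable
#' long-tailed class distribution.
#'
#' @param drug_features numeric matrix (n_drugs x latent_dim) of planted
#'   per-drug latent vectors, rownames = drug ids.
#' @param mode "binary" or "event".
#' @param cfg a [synth_config()].
#' @return a pair table (see [pair_table()]) with attribute `truth` holding
#'   the generating probabilities.
#' @export
gen_pairs <- function(drug_features, mode = c("binary", "event"), cfg) {
  mode <- match.arg(mode)
  U <- as.matrix(drug_features)
  n <- nrow(U)
  ids <- rownames(U)
  if (is.null(ids)) ids <- sprintf("D%03d", seq_len(n))
  with_seed(sub_seed(cfg$seed, STAGE_OFFSETS[["pairs"]]), {
    n_all <- n * (n - 1L) / 2
    n_want <- if (is.null(cfg$n_pairs)) max(1, round(0.12 * n_all)) else cfg$n_pairs
    n_take <- min(n_want, n_all)
    lin <- sample.int(n_all, n_take)
    # unrank linear index -> (i < j)
    j <- ceiling((1 + sqrt(1 + 8 * lin)) / 2)
    i <- lin - (j - 1) * (j - 2) / 2
    i <- as.integer(i); j <- as.integer(j)
    p_dim <- ncol(U)
    M <- matrix(stats::rnorm(p_dim * p_dim), p_dim)
    M <- (M + t(M)) / 2
    raw <- rowSums((U[i, , drop = FALSE] %*% M) * U[j, , drop = FALSE])
    logits <- (raw - stats::median(raw)) / stats::sd(raw) * cfg$pair_logit_scale
    if (mode == "binary") {
      p <- sigmoid(logits)
      y <- as.integer(stats::runif(n_take) < p)
      out <- pair_table(ids[i], ids[j], y, "binary")
      attr(out, "truth") <- p
    } else {
      k <- cfg$event_classes
      prior <- log(zipf_weights(k, cfg$zipf_exponent))
      R <- matrix(stats::rnorm(p_dim * k), p_dim, k)
      V <- U[i, , drop = FALSE] + U[j, , drop = FALSE]
      class_logits <- sweep(1.5 * (V %*% R), 2L, prior, "+")
      P <- softmax_rows(class_logits)
      cls <- apply(P, 1L, function(p) sample.int(k, 1L, prob = p))
      out <- pair_table(ids[i], ids[j], sprintf("event_%02d", cls), "event")
      attr(out, "truth") <- P
    }
    out
  })
}

#' Planted per-drug latent vectors (multimodal)
#'
#' The pair-label rule acts on latents that are, by construction,
#' recoverable functions of the observable data, with every modality
#' contributing a block: the first `latent_dim - 4` dimensions are the
#' drug's community centre (the association graph exposes the community),
#' two dimensions are the drug's knowledge-graph degree profile (head- and
#' tail-degree over the positive triples, which trained entity embeddings
#' encode), and two are z-scored molecular-composition descriptors (which
#' mean-pooled atom embeddings encode). Keeping the latents deterministic
#' given the observables keeps the planted rule learnable end to end; the
#' only irreducible noise is the Bernoulli draw in [gen_pairs()]. When
#' `kg_feats` or `mol_desc` is missing, its block falls back to community
#' centres plus `tau` jitter.
#'
#' @param cfg a [synth_config()] with `latent_dim >= 5`.
#' @param community integer community labels (1-based), length `n_drugs`.
#' @param kg_feats optional n_drugs x 2 matrix of KG structural features.
#' @param mol_desc optional n_drugs x 2 matrix of molecular descriptors.
#' @param drug_ids drug id tokens.
#' @return numeric matrix n_drugs x latent_dim with drug ids as rownames.
#' @export
gen_drug_latents <- function(cfg, community, kg_feats = NULL, mol_desc = NULL,
                             drug_ids = NULL) {
  n <- cfg$n_drugs
  stopifnot(cfg$latent_dim >= 5L)
  if (is.null(drug_ids)) drug_ids <- sprintf("D%03d", seq_len(n))
  zscore <- function(M) {
    s <- apply(M, 2L, stats::sd)
    s[!is.finite(s) | s < 1e-12] <- 1
    sweep(sweep(M, 2L, colMeans(M)), 2L, s, "/")
  }
  comm_dims <- cfg$latent_dim - 4L
  with_seed(sub_seed(cfg$seed, STAGE_OFFSETS[["pairs"]]) + 1L, {
    centres <- matrix(stats::rnorm(cfg$n_communities * comm_dims),
                      cfg$n_communities, comm_dims)
    comm_block <- centres[community, , drop = FALSE]
    fallback <- function() {
      ctr <- matrix(stats::rnorm(cfg$n_communities * 2L), cfg$n_communities, 2L)
      ctr[community, , drop = FALSE] +
        cfg$tau * matrix(stats::rnorm(n * 2L), n, 2L)
    }
    kg_block <- if (is.null(kg_feats)) fallback() else {
      zscore(kg_feats[seq_len(n), 1:2, drop = FALSE])
    }
    chem_block <- if (is.null(mol_desc)) fallback() else {
      zscore(mol_desc[seq_len(n), 1:2, drop = FALSE])
    }
    U <- cbind(comm_block, kg_block, chem_block)
    rownames(U) <- drug_ids
    U
  })
}

#' Knowledge-graph degree profile of the first n entities
#'
#' Head- and tail-degree of each entity over the positive triples; a
#' gauge-invariant structural summary that trained entity embeddings encode.
#'
#' @param ts a `triple_set`.
#' @param n number of leading entities (the drugs).
#' @return n x 2 matrix (head_degree, tail_degree).
#' @export
kg_degree_features <- function(ts, n) {
  pos <- ts$triples[ts$labels == 1L, , drop = FALSE]
  cbind(head_degree = tabulate(pos[, 1L] + 1L, n),
        tail_degree = tabulate(pos[, 3L] + 1L, n))
}

#' Molecular-composition descriptors of a drug table
#'
#' Two per-drug summaries that the mean-pooled attribute embedding encodes:
#' the oxygen fraction and the nitrogen fraction of heavy atoms.
#'
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @return n x 2 matrix (frac_O, frac_N) with drug ids as rownames.
#' @export
mol_descriptors <- function(drugs) {
  D <- t(vapply(drugs$smiles, function(s) {
    g <- smiles_to_graph(s)
    c(mean(g$atom == "O"), mean(g$atom == "N"))
  }, numeric(2)))
  dimnames(D) <- list(drugs$drug_id, c("frac_O", "frac_N"))
  D
}

# ---- full dataset -----------------------------------------------------------

#' Simulate a complete synthetic dataset on disk
#'
#' Writes the four TSV inputs (drugs, associations, triples, pairs) plus a
#' `truth/` subdirectory with the hidden community labels and planted
#' latents/embeddings that probe tests use. Drugs are embedded as the first
#' `n_drugs` knowledge-graph entities.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param mode pair-label mode, "binary" or "event".
#' @return (invisibly) a list with all in-memory pieces.
#' @export
simulate_dataset <- function(cfg, out_dir, mode = c("binary", "event")) {
  mode <- match.arg(mode)
  if (cfg$n_kg_entities < cfg$n_drugs) {
    stop("n_kg_entities must be >= n_drugs (drugs are KG entities)")
  }
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  drugs <- gen_molecules(cfg$n_drugs, sub_seed(cfg$seed, STAGE_OFFSETS[["molecules"]]),
                         cfg$dominant_atom_prob)
  het <- gen_hetero_associations(cfg, drugs$drug_id)
  ents <- c(drugs$drug_id,
            sprintf("E%04d", seq_len(cfg$n_kg_entities - cfg$n_drugs)))
  kg <- gen_kg_triples(cfg, ents)
  U <- gen_drug_latents(cfg, het$community,
                        kg_feats = kg_degree_features(kg$triples, cfg$n_drugs),
                        mol_desc = mol_descriptors(drugs),
                        drug_ids = drugs$drug_id)
  pairs <- gen_pairs(U, mode, cfg)

  write_drug_table(drugs, file.path(out_dir, "drugs.tsv"))
  write_association_table(het$associations, file.path(out_dir, "associations.tsv"))
  write_triples(kg$triples, file.path(out_dir, "triples.tsv"))
  write_triples(kg$heldout_negatives, file.path(out_dir, "triples_heldout_neg.tsv"))
  write_pair_table(pairs, file.path(out_dir, "pairs.tsv"))
  write_tsv_strict(data.frame(drug_id = drugs$drug_id,
                              community = het$community),
                   file.path(out_dir, "truth", "communities.tsv"))
  latents <- data.frame(drug_id = rownames(U), U, check.names = FALSE)
  names(latents)[-1] <- sprintf("u%d", seq_len(ncol(U)))
  write_tsv_strict(latents, file.path(out_dir, "truth", "drug_latents.tsv"))
  invisible(list(cfg = cfg, drugs = drugs, hetero = het, kg = kg,
                 latents = U, pairs = pairs))
}
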