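# Global semantic embeddings by ComplEx factorisation of the knowledge
# graph. The score of a triple (h, r, t) is
#   phi = Re( sum_k w_rk * e_hk * conj(e_tk) )
#       = <Re w, Re h, Re t> + <Re w, Im h, Im t>
#       + <Im w, Re h, Im t> - <Im w, Im h, Re t>
# and parameters minimise the regularised logistic loss
#   L = sum_i log(1 + exp(-Y_i phi_i)) + lambda * ||Theta||^2.
# DistMult is the all-imaginary-zero restriction and exists here only as a
# degenerate test case. A drug's global embedding g_i is Re(e_drug),
# projected by a fixed linear map when the rank differs from the common d.

#' Initialise ComplEx embeddings
#'
#' @param n_entities,n_relations vocabulary sizes.
#' @param rank complex rank K.
#' @param seed integer seed.
#' @param entity_names,relation_names optional token vectors.
#' @return object of class `complex_emb` with matrices `ent_re`, `ent_im`
#'   (n_entities x rank), `rel_re`, `rel_im` (n_relations x rank).
#' @export
init_complex_emb <- function(n_entities, n_relations, rank, seed = 1L,
                             entity_names = NULL, relation_names = NULL) {
  with_seed(seed, {
    e <- list(ent_re = init_mat(n_entities, rank, 0.1),
              ent_im = init_mat(n_entities, rank, 0.1),
              rel_re = init_mat(n_relations, rank, 0.1),
              rel_im = init_mat(n_relations, rank, 0.1))
    e$rank <- as.integer(rank)
    if (!is.null(entity_names)) rownames(e$ent_re) <- rownames(e$ent_im) <- entity_names
    if (!is.null(relation_names)) rownames(e$rel_re) <- rownames(e$rel_im) <- relation_names
    class(e) <- "complex_emb"
    e
  })
}

#' ComplEx score of triples
#'
#' @param h,r,t 0-based head / relation / tail index vectors (equal length).
#' @param emb a `complex_emb`.
#' @return numeric vector of scores phi.
#' @export
complex_score <- function(h, r, t, emb) {
  n_e <- nrow(emb$ent_re); n_r <- nrow(emb$rel_re)
  if (any(h < 0L | h >= n_e) || any(t < 0L | t >= n_e)) {
    stop("entity index out of range")
  }
  if (any(r < 0L | r >= n_r)) stop("relation index out of range")
  hre <- emb$ent_re[h + 1L, , drop = FALSE]
  him <- emb$ent_im[h + 1L, , drop = FALSE]
  tre <- emb$ent_re[t + 1L, , drop = FALSE]
  tim <- emb$ent_im[t + 1L, , drop = FALSE]
  wre <- emb$rel_re[r + 1L, , drop = FALSE]
  wim <- emb$rel_im[r + 1L, , drop = FALSE]
  unname(rowSums(wre * (hre * tre + him * tim) + wim * (hre * tim - him * tre)))
}

#' Regularised logistic loss of a labelled triple set
#'
#' @param ts a `triple_set` with labels in \{-1, +1\}.
#' @param emb a `complex_emb`.
#' @param lambda L2 weight on all embedding tables.
#' @return scalar loss (sum over triples plus the full L2 term).
#' @export
kg_logistic_loss <- function(ts, emb, lambda = 0) {
  if (!all(ts$labels %in% c(-1L, 1L))) stop("labels must be -1 or 1")
  phi <- complex_score(ts$triples[, 1L], ts$triples[, 2L], ts$triples[, 3L], emb)
  # softplus(-y*phi), computed stably
  z <- -ts$labels * phi
  data_term <- sum(ifelse(z > 30, z, log1p(exp(z))))
  reg <- lambda * (sum(emb$ent_re^2) + sum(emb$ent_im^2) +
                   sum(emb$rel_re^2) + sum(emb$rel_im^2))
  data_term + reg
}

#' Sample corrupted negative triples
#'
#' For each positive, `k` corruptions replace the head or the tail (fair
#' coin) with a uniformly drawn entity; corruptions colliding with an
#' observed positive are rejected and resampled (up to 100 attempts each).
#'
#' @param ts a `triple_set` (its positive rows are corrupted).
#' @param k negatives per positive.
#' @param seed integer seed.
#' @return a `triple_set` with Y = -1 rows over the same vocabularies.
#' @export
sample_negatives <- function(ts, k = 10L, seed = 1L) {
  stopifnot(k >= 1L)
  pos <- ts$triples[ts$labels == 1L, , drop = FALSE]
  n_ent <- length(ts$entity_vocab)
  seen <- paste(pos[, 1L], pos[, 2L], pos[, 3L])
  with_seed(seed, {
    base <- pos[rep(seq_len(nrow(pos)), each = k), , drop = FALSE]
    corrupt_head <- stats::runif(nrow(base)) < 0.5
    repl <- sample.int(n_ent, nrow(base), replace = TRUE) - 1L
    cand <- base
    cand[corrupt_head, 1L] <- repl[corrupt_head]
    cand[!corrupt_head, 3L] <- repl[!corrupt_head]
    # avoid "corruption equals the source" and collisions with positives
    for (attempt in seq_len(100L)) {
      bad <- which(paste(cand[, 1L], cand[, 2L], cand[, 3L]) %in% seen |
                   (cand[, 1L] == base[, 1L] & cand[, 3L] == base[, 3L]))
      if (!length(bad)) break
      if (attempt == 100L) stop("negative sampling saturated: graph too dense")
      repl <- sample.int(n_ent, length(bad), replace = TRUE) - 1L
      ch <- corrupt_head[bad]
      cand[bad[ch], 1L] <- repl[ch]
      cand[bad[!ch], 3L] <- repl[!ch]
    }
    triple_set(names(ts$entity_vocab), names(ts$relation_vocab),
               cand, rep(-1L, nrow(cand)))
  })
}

#' Train ComplEx embeddings
#'
#' Full-batch Adam on the regularised logistic loss over the positive triples
#' plus freshly sampled corruptions each epoch. Any Y = -1 rows already in
#' the input are kept as fixed negatives.
#'
#' @param ts a `triple_set` with at least one positive.
#' @param rank complex rank K.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param lambda L2 regularisation weight.
#' @param negatives corruptions per positive per epoch.
#' @param seed integer seed.
#' @param freeze_imaginary if TRUE, imaginary parts stay at zero (the
#'   DistMult restriction, for tests).
#' @return list with `emb` (`complex_emb`) and `loss_history` (per-epoch
#'   mean loss per triple).
#' @export
train_complex <- function(ts, rank = 32L, epochs = 60L, lr = 0.05,
                          lambda = 1e-3, negatives = 10L, seed = 1L,
                          freeze_imaginary = FALSE) {
  if (!any(ts$labels == 1L)) stop("need at least one positive triple")
  n_ent <- length(ts$entity_vocab)
  n_rel <- length(ts$relation_vocab)
  emb <- init_complex_emb(n_ent, n_rel, rank, seed,
                          names(ts$entity_vocab), names(ts$relation_vocab))
  if (freeze_imaginary) {
    emb$ent_im[] <- 0
    emb$rel_im[] <- 0
  }
  tk <- c("ent_re", "ent_im", "rel_re", "rel_im")
  opt <- adam_init(emb[tk])
  fixed_neg <- ts$triples[ts$labels == -1L, , drop = FALSE]
  pos <- ts$triples[ts$labels == 1L, , drop = FALSE]
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    neg <- sample_negatives(
      triple_set(names(ts$entity_vocab), names(ts$relation_vocab),
                 pos, rep(1L, nrow(pos))),
      k = negatives, seed = sub_seed(seed, 300L + ep))
    tri <- rbind(pos, neg$triples, fixed_neg)
    y <- c(rep(1, nrow(pos)), rep(-1, nrow(neg$triples)),
           rep(-1, nrow(fixed_neg)))
    N <- length(y)
    hre <- emb$ent_re[tri[, 1L] + 1L, , drop = FALSE]
    him <- emb$ent_im[tri[, 1L] + 1L, , drop = FALSE]
    tre <- emb$ent_re[tri[, 3L] + 1L, , drop = FALSE]
    tim <- emb$ent_im[tri[, 3L] + 1L, , drop = FALSE]
    wre <- emb$rel_re[tri[, 2L] + 1L, , drop = FALSE]
    wim <- emb$rel_im[tri[, 2L] + 1L, , drop = FALSE]
    phi <- rowSums(wre * (hre * tre + him * tim) + wim * (hre * tim - him * tre))
    z <- -y * phi
    loss <- (sum(ifelse(z > 30, z, log1p(exp(z)))) +
             lambda * (sum(emb$ent_re^2) + sum(emb$ent_im^2) +
                       sum(emb$rel_re^2) + sum(emb$rel_im^2))) / N
    if (!is.finite(loss)) stop("divergence: try a smaller learning rate")
    loss_hist[ep] <- loss
    dphi <- (-y * sigmoid(z)) / N
    g <- list(
      ent_re = (agg_rows(dphi * (wre * tre + wim * tim), tri[, 1L] + 1L, n_ent) +
                agg_rows(dphi * (wre * hre - wim * him), tri[, 3L] + 1L, n_ent) +
                2 * lambda * emb$ent_re / N),
      ent_im = (agg_rows(dphi * (wre * tim - wim * tre), tri[, 1L] + 1L, n_ent) +
                agg_rows(dphi * (wre * him + wim * hre), tri[, 3L] + 1L, n_ent) +
                2 * lambda * emb$ent_im / N),
      rel_re = (agg_rows(dphi * (hre * tre + him * tim), tri[, 2L] + 1L, n_rel) +
                2 * lambda * emb$rel_re / N),
      rel_im = (agg_rows(dphi * (hre * tim - him * tre), tri[, 2L] + 1L, n_rel) +
                2 * lambda * emb$rel_im / N)
    )
    if (freeze_imaginary) {
      g$ent_im[] <- 0
      g$rel_im[] <- 0
    }
    st <- adam_step(emb[tk], g, opt, lr)
    rn_e <- rownames(emb$ent_re); rn_r <- rownames(emb$rel_re)
    emb[tk] <- st$params
    rownames(emb$ent_re) <- rownames(emb$ent_im) <- rn_e
    rownames(emb$rel_re) <- rownames(emb$rel_im) <- rn_r
    opt <- st$opt
  }
  list(emb = emb, loss_history = loss_hist)
}

#' Global semantic embedding of drugs
#'
#' g_i is the real part of the learned entity embedding; when the complex
#' rank differs from the requested width `d`, a fixed seeded linear map
#' (deterministic in rank and d) projects it.
#'
#' @param drug_ids character vector of entity tokens.
#' @param emb a `complex_emb` with entity rownames.
#' @param d output width (default: the rank, no projection).
#' @return matrix length(drug_ids) x d, drug ids as rownames; unknown drugs
#'   get a zero row with a warning.
#' @export
global_embeddings <- function(drug_ids, emb, d = emb$rank) {
  pos <- match(drug_ids, rownames(emb$ent_re))
  if (anyNA(pos)) {
    warning("cold-start zero embedding for unknown drug(s): ",
            paste(utils::head(drug_ids[is.na(pos)], 3L), collapse = ", "))
  }
  G <- matrix(0, length(drug_ids), emb$rank)
  ok <- !is.na(pos)
  G[ok, ] <- emb$ent_re[pos[ok], , drop = FALSE]
  if (d != emb$rank) {
    P <- with_seed(sub_seed(emb$rank * 131L + d, 17L),
                   init_mat(emb$rank, d, 1 / sqrt(emb$rank)))
    G <- G %*% P
  }
  rownames(G) <- drug_ids
  G
}
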