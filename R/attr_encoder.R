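# Atomic-scale encoder: message passing over the heavy-atom graph with
# attribute-masking pretraining. Node features are categorical codes (atom
# type, degree, formal charge) summed as embedding-table lookups; masked
# nodes take a dedicated mask row in the atom-type table with degree/charge
# contributions zeroed. The layer update is
#   h_v^(k) = ReLU( MLP^(k)( sum_{u in N(v) + v} h_u^(k-1) + sum_{e=(v,u)} h_e ) )
# with MLP^(k) two affine maps and a rectifier between, and the molecule
# embedding a_i is the mean of the final node embeddings.

N_DEGREE_BINS <- 6L   # degrees 0..4, then 5+
N_CHARGE_BINS <- 3L   # -1, 0, +1

#' Initialise attribute-encoder parameters
#'
#' @param d embedding width.
#' @param K number of message-passing layers.
#' @param seed integer seed for the Gaussian initialisation.
#' @return list of embedding tables, per-layer MLP weights and the linear
#'   atom-type reconstruction head; class `attr_params`.
#' @export
init_attr_params <- function(d = 32L, K = 2L, seed = 1L) {
  stopifnot(K >= 1L, d >= 1L)
  nt <- length(ATOM_TYPES)
  with_seed(seed, {
    p <- list(
      atom_emb = init_mat(nt + 1L, d, 0.3),   # last row = mask token
      deg_emb = init_mat(N_DEGREE_BINS, d, 0.3),
      charge_emb = init_mat(N_CHARGE_BINS, d, 0.3),
      bond_emb = init_mat(3L, d, 0.3),
      layers = lapply(seq_len(K), function(k) {
        list(W1 = init_mat(d, d), b1 = rep(0, d),
             W2 = init_mat(d, d), b2 = rep(0, d))
      }),
      head = list(W = init_mat(nt, d), b = rep(0, nt))
    )
    p$d <- d
    p$K <- K
    class(p) <- "attr_params"
    p
  })
}

#' Select nodes for attribute masking
#'
#' Exactly `max(1, floor(rate * |V| + 0.5))` nodes (round half up, minimum
#' one) are drawn uniformly without replacement.
#'
#' @param g a `mol_graph`.
#' @param rate masking fraction in (0, 1); default 0.15.
#' @param seed integer seed.
#' @return list with `graph` (input graph carrying a `masked` field),
#'   `masked` (node indices) and `targets` (original atom-type codes,
#'   1-based into `ATOM_TYPES`).
#' @export
mask_nodes <- function(g, rate = 0.15, seed = 1L) {
  stopifnot(inherits(g, "mol_graph"))
  if (g$n < 1L) stop("cannot mask an empty graph")
  if (rate <= 0 || rate >= 1) stop("rate must lie in (0, 1)")
  n_mask <- max(1L, as.integer(floor(rate * g$n + 0.5)))
  idx <- with_seed(seed, sort(sample.int(g$n, n_mask)))
  g$masked <- idx
  list(graph = g, masked = idx,
       targets = match(g$atom[idx], ATOM_TYPES))
}

# Categorical feature codes for a mol_graph.
mol_feature_codes <- function(g) {
  list(type = match(g$atom, ATOM_TYPES),
       deg = pmin(mol_degree(g), N_DEGREE_BINS - 1L) + 1L,
       charge = pmax(pmin(g$charge, 1L), -1L) + 2L,
       bond = pmin(g$bond_order, 3L))
}

# Initial node embeddings; masked nodes take the mask row with degree and
# charge contributions zeroed.
attr_input_embeddings <- function(g, params, masked = integer(0)) {
  f <- mol_feature_codes(g)
  H <- params$atom_emb[f$type, , drop = FALSE] +
    params$deg_emb[f$deg, , drop = FALSE] +
    params$charge_emb[f$charge, , drop = FALSE]
  if (length(masked)) {
    H[masked, ] <- params$atom_emb[rep(nrow(params$atom_emb), length(masked)), ,
                                   drop = FALSE]
  }
  H
}

# Scatter-add rows of X into an n-row accumulator by index.
agg_rows <- function(X, idx, n) {
  out <- matrix(0, n, ncol(X))
  if (length(idx)) {
    r <- rowsum(X, idx)
    out[as.integer(rownames(r)), ] <- r
  }
  out
}

#' One message-passing layer of the attribute encoder
#'
#' @param g a `mol_graph`.
#' @param h_prev n x d matrix of node embeddings.
#' @param e_prev m x d matrix of edge embeddings (one row per bond).
#' @param layer list with `W1`, `b1`, `W2`, `b2` (the layer MLP).
#' @return n x d matrix of updated node embeddings.
#' @export
gnn_layer <- function(g, h_prev, e_prev, layer) {
  if (ncol(h_prev) != ncol(layer$W1)) {
    stop("embedding width ", ncol(h_prev), " does not match layer width ",
         ncol(layer$W1))
  }
  gnn_layer_forward(g, h_prev, e_prev, layer)$H
}

gnn_layer_forward <- function(g, h_prev, e_prev, layer) {
  n <- g$n
  m <- nrow(g$edges)
  src <- c(g$edges[, 1L], g$edges[, 2L])
  dst <- c(g$edges[, 2L], g$edges[, 1L])
  S <- h_prev + agg_rows(h_prev[src, , drop = FALSE], dst, n)
  if (m) S <- S + agg_rows(e_prev[rep(seq_len(m), 2L), , drop = FALSE], dst, n)
  Z1 <- sweep(S %*% t(layer$W1), 2L, layer$b1, "+")
  H1 <- relu(Z1)
  Z2 <- sweep(H1 %*% t(layer$W2), 2L, layer$b2, "+")
  list(H = relu(Z2), S = S, Z1 = Z1, H1 = H1, Z2 = Z2, src = src, dst = dst)
}

# Backward pass of one layer; returns grads for W1/b1/W2/b2, dh_prev, de_prev.
gnn_layer_backward <- function(g, cache, layer, dH) {
  dZ2 <- dH * (cache$Z2 > 0)
  gW2 <- t(dZ2) %*% cache$H1
  gb2 <- colSums(dZ2)
  dH1 <- dZ2 %*% layer$W2
  dZ1 <- dH1 * (cache$Z1 > 0)
  gW1 <- t(dZ1) %*% cache$S
  gb1 <- colSums(dZ1)
  dS <- dZ1 %*% layer$W1
  n <- g$n
  m <- nrow(g$edges)
  dh_prev <- dS + agg_rows(dS[cache$dst, , drop = FALSE], cache$src, n)
  de_prev <- if (m) {
    dS[g$edges[, 1L], , drop = FALSE] + dS[g$edges[, 2L], , drop = FALSE]
  } else matrix(0, 0L, ncol(dS))
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       dh_prev = dh_prev, de_prev = de_prev)
}

#' Encode one molecule to its attribute embedding a_i
#'
#' Runs K message-passing layers from the categorical input embeddings and
#' mean-pools the final node embeddings (permutation invariant).
#'
#' @param g a `mol_graph`.
#' @param params an `attr_params`.
#' @param masked optional node indices treated as masked.
#' @return numeric vector of length `params$d`.
#' @export
encode_molecule <- function(g, params, masked = integer(0)) {
  if (g$n < 1L) stop("cannot encode an empty graph")
  H <- attr_encode_nodes(g, params, masked)
  colMeans(H)
}

# Final-layer node embeddings (n x d).
attr_encode_nodes <- function(g, params, masked = integer(0)) {
  f <- mol_feature_codes(g)
  H <- attr_input_embeddings(g, params, masked)
  E <- params$bond_emb[f$bond, , drop = FALSE]
  if (nrow(g$edges) == 0L) E <- matrix(0, 0L, params$d)
  for (k in seq_len(params$K)) {
    H <- gnn_layer_forward(g, H, E, params$layers[[k]])$H
  }
  H
}

# ---- batched pretraining over a disjoint union of all molecules ------------

# Pack a list of mol_graphs into one disjoint-union graph.
pack_molecules <- function(graphs) {
  ns <- vapply(graphs, function(g) g$n, integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  edges <- do.call(rbind, Map(function(g, o) {
    if (nrow(g$edges)) g$edges + o else g$edges
  }, graphs, offs))
  structure(list(
    n = sum(ns),
    atom = unlist(lapply(graphs, `[[`, "atom")),
    edges = edges,
    bond_order = unlist(lapply(graphs, `[[`, "bond_order")),
    charge = unlist(lapply(graphs, `[[`, "charge")),
    smiles = NA_character_,
    graph_id = rep(seq_along(graphs), ns),
    offsets = offs
  ), class = "mol_graph")
}

# Forward through K layers on a packed graph with caches.
attr_forward_cached <- function(g, params, masked) {
  f <- mol_feature_codes(g)
  H0 <- attr_input_embeddings(g, params, masked)
  E <- params$bond_emb[f$bond, , drop = FALSE]
  if (nrow(g$edges) == 0L) E <- matrix(0, 0L, params$d)
  caches <- vector("list", params$K)
  H <- H0
  for (k in seq_len(params$K)) {
    caches[[k]] <- gnn_layer_forward(g, H, E, params$layers[[k]])
    caches[[k]]$H_in <- H
    H <- caches[[k]]$H
  }
  list(H = H, H0 = H0, E = E, caches = caches, codes = f)
}

# Cross-entropy of the reconstruction head at masked nodes, plus gradients
# for every parameter. Returns list(loss, acc, grads).
attr_masked_loss <- function(g, params, masked, targets, want_grads = TRUE) {
  fw <- attr_forward_cached(g, params, masked)
  Hm <- fw$H[masked, , drop = FALSE]
  logits <- sweep(Hm %*% t(params$head$W), 2L, params$head$b, "+")
  P <- softmax_rows(logits)
  nm <- length(masked)
  ll <- -log(clip01(P[cbind(seq_len(nm), targets)]))
  acc <- mean(max.col(P, ties.method = "first") == targets)
  loss <- mean(ll)
  if (!want_grads) return(list(loss = loss, acc = acc))

  dlogits <- P
  dlogits[cbind(seq_len(nm), targets)] <-
    dlogits[cbind(seq_len(nm), targets)] - 1
  dlogits <- dlogits / nm
  gHeadW <- t(dlogits) %*% Hm
  gHeadb <- colSums(dlogits)
  dH <- matrix(0, g$n, params$d)
  dH[masked, ] <- dlogits %*% params$head$W

  glayers <- vector("list", params$K)
  dE <- matrix(0, nrow(fw$E), params$d)
  for (k in rev(seq_len(params$K))) {
    bk <- gnn_layer_backward(g, fw$caches[[k]], params$layers[[k]], dH)
    glayers[[k]] <- bk$grads
    dH <- bk$dh_prev
    if (nrow(dE)) dE <- dE + bk$de_prev
  }
  # input-embedding table grads
  f <- fw$codes
  g_atom <- matrix(0, nrow(params$atom_emb), params$d)
  g_deg <- matrix(0, N_DEGREE_BINS, params$d)
  g_charge <- matrix(0, N_CHARGE_BINS, params$d)
  unmasked <- setdiff(seq_len(g$n), masked)
  if (length(unmasked)) {
    g_atom <- g_atom + agg_rows(dH[unmasked, , drop = FALSE],
                                f$type[unmasked], nrow(params$atom_emb))
    g_deg <- g_deg + agg_rows(dH[unmasked, , drop = FALSE],
                              f$deg[unmasked], N_DEGREE_BINS)
    g_charge <- g_charge + agg_rows(dH[unmasked, , drop = FALSE],
                                    f$charge[unmasked], N_CHARGE_BINS)
  }
  if (length(masked)) {
    g_atom[nrow(g_atom), ] <- g_atom[nrow(g_atom), ] +
      colSums(dH[masked, , drop = FALSE])
  }
  g_bond <- if (nrow(dE)) agg_rows(dE, f$bond, 3L) else matrix(0, 3L, params$d)
  grads <- list(atom_emb = g_atom, deg_emb = g_deg, charge_emb = g_charge,
                bond_emb = g_bond, layers = glayers,
                head = list(W = gHeadW, b = gHeadb))
  list(loss = loss, acc = acc, grads = grads)
}

#' Pretrain the attribute encoder by attribute masking
#'
#' Each epoch re-masks every molecule (default 15\% of nodes, minimum one),
#' runs the encoder over the disjoint union of all graphs, applies the linear
#' reconstruction head at masked positions and takes an Adam step on the
#' cross-entropy over atom-type classes.
#'
#' @param molecules list of `mol_graph` objects (>= 2).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param rate masking rate (default 0.15).
#' @param d,K encoder width and depth.
#' @param seed integer seed (initialisation and per-epoch masks).
#' @return list with `params` (`attr_params`), `loss_history`,
#'   `acc_history` and the initial masked accuracy `init_acc`.
#' @export
pretrain_masking <- function(molecules, epochs = 30L, lr = 0.01,
                             rate = 0.15, d = 32L, K = 2L, seed = 1L) {
  stopifnot(length(molecules) >= 2L)
  if (length(unique(unlist(lapply(molecules, `[[`, "atom")))) < 2L) {
    warning("corpus has a single atom type; masking targets are degenerate")
  }
  packed <- pack_molecules(molecules)
  params <- init_attr_params(d, K, seed)
  tk <- c("atom_emb", "deg_emb", "charge_emb", "bond_emb", "layers", "head")
  opt <- adam_init(params[tk])
  loss_hist <- acc_hist <- numeric(epochs)
  init_acc <- NA_real_
  for (ep in seq_len(epochs)) {
    mk <- with_seed(sub_seed(seed, 100L + ep), {
      lapply(molecules, function(g) {
        n_mask <- max(1L, as.integer(floor(rate * g$n + 0.5)))
        sample.int(g$n, n_mask)
      })
    })
    masked <- unlist(Map(function(ix, o) ix + o, mk, packed$offsets))
    targets <- match(packed$atom[masked], ATOM_TYPES)
    res <- attr_masked_loss(packed, params, masked, targets)
    if (ep == 1L) init_acc <- res$acc
    if (!is.finite(res$loss)) stop("divergence: non-finite masking loss")
    st <- adam_step(params[tk], res$grads[tk], opt, lr)
    params[tk] <- st$params
    opt <- st$opt
    loss_hist[ep] <- res$loss
    acc_hist[ep] <- res$acc
  }
  list(params = params, loss_history = loss_hist, acc_history = acc_hist,
       init_acc = init_acc)
}

#' Masked atom-type reconstruction accuracy under a fixed mask
#'
#' @param molecules list of `mol_graph`.
#' @param params an `attr_params`.
#' @param rate masking rate.
#' @param seed seed for the evaluation masks.
#' @return fraction of masked atoms whose type the head recovers.
#' @export
masked_accuracy <- function(molecules, params, rate = 0.15, seed = 99L) {
  packed <- pack_molecules(molecules)
  mk <- with_seed(seed, {
    lapply(molecules, function(g) {
      n_mask <- max(1L, as.integer(floor(rate * g$n + 0.5)))
      sample.int(g$n, n_mask)
    })
  })
  masked <- unlist(Map(function(ix, o) ix + o, mk, packed$offsets))
  targets <- match(packed$atom[masked], ATOM_TYPES)
  attr_masked_loss(packed, params, masked, targets, want_grads = FALSE)$acc
}

#' Attribute embeddings for a drug table
#'
#' The encoder is pretrained at its own (typically wider) width; at export
#' a fixed seeded linear map projects the mean-pooled embedding to the
#' common fusion width `d_out`, preserving more molecular information than
#' pretraining at the narrow width directly.
#'
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @param params an `attr_params`.
#' @param d_out output width; default the encoder width (no projection).
#' @return matrix n_drugs x d_out with drug ids as rownames.
#' @export
attr_embeddings <- function(drugs, params, d_out = params$d) {
  A <- t(vapply(drugs$smiles,
                function(s) encode_molecule(smiles_to_graph(s), params),
                numeric(params$d)))
  if (d_out != params$d) {
    P <- with_seed(sub_seed(params$d * 157L + d_out, 19L),
                   init_mat(params$d, d_out, 1 / sqrt(params$d)))
    A <- A %*% P
  }
  rownames(A) <- drugs$drug_id
  A
}
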