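# Local-interaction encoder over the relation-typed drug-entity graph.
# Per relation r and layer k:
#   E_N^(k,r)(v) = mean of neighbour embeddings under r (zero if none)
#   E_v^(k,r)    = sigmoid( W^(k,r) %*% concat(E_v^(k-1), E_N^(k,r)(v)) )
# and layers integrate relations by summation: E_v^(k) = sum_r E_v^(k,r).
# Initial embeddings are a learned per-node lookup table. The pretraining
# objective (the propagation rule's own stage loss is not prescribed by the
# architecture) is per-relation link reconstruction with 1:1 uniform
# negative sampling: score(v, u) = sigmoid(E_v . E_u + b). The trainable
# scalar bias b (initialised at minus the median initial dot product) is
# needed because sigmoid-activated embeddings make every dot product
# non-negative; without it the score saturates at 1 for all pairs and
# training collapses to the zero embedding.

#' Build a heterogeneous drug-entity graph
#'
#' Nodes are the supplied drugs plus every entity appearing in the
#' association table; adjacency is kept per relation and is symmetric
#' (associations are undirected). Drugs without any association are retained
#' as isolated nodes (cold start: empty neighbourhoods).
#'
#' @param assoc association data.frame (`drug_id`, `relation`, `entity_id`).
#' @param drug_ids character vector of all drug ids (supersets the table's).
#' @return object of class `hetero_graph`: node names/types, per-relation
#'   directed edge lists (both directions) and neighbour counts.
#' @export
hetero_graph <- function(assoc, drug_ids) {
  drug_ids <- unique(as.character(drug_ids))
  extra <- setdiff(unique(assoc$drug_id), drug_ids)
  if (length(extra)) {
    stop("association table names unknown drug(s): ",
         paste(utils::head(extra, 3L), collapse = ", "))
  }
  rels <- sort(unique(assoc$relation))
  bad <- setdiff(rels, RELATION_SET)
  if (length(bad)) stop("unknown relation(s): ", paste(bad, collapse = ", "))
  ent_ids <- unique(assoc$entity_id)
  nodes <- c(drug_ids, ent_ids)
  node_type <- c(rep("drug", length(drug_ids)),
                 assoc$relation[match(ent_ids, assoc$entity_id)])
  idx <- stats::setNames(seq_along(nodes), nodes)
  rel_edges <- lapply(rels, function(r) {
    sub <- assoc[assoc$relation == r, ]
    u <- idx[sub$drug_id]
    v <- idx[sub$entity_id]
    src <- c(u, v)          # message source
    dst <- c(v, u)          # message destination
    deg <- tabulate(dst, length(nodes))
    list(src = unname(src), dst = unname(dst), deg = deg)
  })
  names(rel_edges) <- rels
  structure(list(nodes = nodes, node_type = node_type,
                 drug_ids = drug_ids, relations = rels,
                 rel_edges = rel_edges),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("<hetero_graph> ", length(x$nodes), " nodes (",
      length(x$drug_ids), " drugs), relations: ",
      paste(x$relations, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Initialise local-encoder parameters
#'
#' @param graph a `hetero_graph`.
#' @param d embedding width.
#' @param K number of layers.
#' @param seed integer seed.
#' @return list with the initial-embedding table `E0` (n_nodes x d) and
#'   per-layer, per-relation weight matrices `W[[k]][[r]]` (d x 2d);
#'   class `local_params`.
#' @export
init_local_params <- function(graph, d = 32L, K = 1L, seed = 1L) {
  stopifnot(K >= 1L)
  with_seed(seed, {
    p <- list(
      E0 = init_mat(length(graph$nodes), d, 0.5),
      W = lapply(seq_len(K), function(k) {
        w <- lapply(graph$relations, function(r) init_mat(d, 2L * d))
        names(w) <- graph$relations
        w
      })
    )
    p$d <- d
    p$K <- K
    class(p) <- "local_params"
    p
  })
}

# Mean-aggregate neighbour embeddings for one relation: n x d matrix.
rel_neighbor_mean <- function(graph, r, E_prev) {
  re <- graph$rel_edges[[r]]
  if (is.null(re)) stop("unknown relation '", r, "'")
  M <- agg_rows(E_prev[re$src, , drop = FALSE], re$dst, nrow(E_prev))
  nz <- re$deg > 0L
  M[nz, ] <- M[nz, , drop = FALSE] / re$deg[nz]
  M
}

#' Single-node, single-relation update (reference form)
#'
#' @param graph a `hetero_graph`.
#' @param v node index (1-based) or node name.
#' @param r relation name.
#' @param E_prev n x d embedding matrix.
#' @param W relation-specific weight matrix (d x 2d).
#' @return the updated embedding for `v` under `r` (values in (0, 1)).
#' @export
relation_update <- function(graph, v, r, E_prev, W) {
  if (is.character(v)) v <- match(v, graph$nodes)
  if (!r %in% graph$relations) stop("unknown relation '", r, "'")
  re <- graph$rel_edges[[r]]
  nb <- re$src[re$dst == v]
  m <- if (length(nb)) colMeans(E_prev[nb, , drop = FALSE]) else numeric(ncol(E_prev))
  as.numeric(sigmoid(W %*% c(E_prev[v, ], m)))
}

#' One full propagation layer
#'
#' @param graph a `hetero_graph`.
#' @param E_prev n x d embedding matrix.
#' @param W_layer named list of relation weight matrices for this layer.
#' @return n x d matrix: the relation-wise updates summed over relations.
#' @export
layer_forward <- function(graph, E_prev, W_layer) {
  local_layer_forward(graph, E_prev, W_layer)$E
}

local_layer_forward <- function(graph, E_prev, W_layer) {
  E_new <- matrix(0, nrow(E_prev), ncol(E_prev))
  per_rel <- list()
  for (r in graph$relations) {
    M <- rel_neighbor_mean(graph, r, E_prev)
    Z <- cbind(E_prev, M) %*% t(W_layer[[r]])
    out <- sigmoid(Z)
    per_rel[[r]] <- list(M = M, out = out)
    E_new <- E_new + out
  }
  list(E = E_new, per_rel = per_rel)
}

# Backward through one layer. dE_new: gradient at the layer output.
# Returns dE_prev and per-relation weight grads.
local_layer_backward <- function(graph, E_prev, W_layer, cache, dE_new) {
  d <- ncol(E_prev)
  dE_prev <- matrix(0, nrow(E_prev), d)
  gW <- list()
  for (r in graph$relations) {
    pr <- cache$per_rel[[r]]
    dZ <- dE_new * pr$out * (1 - pr$out)
    gW[[r]] <- t(dZ) %*% cbind(E_prev, pr$M)
    dCat <- dZ %*% W_layer[[r]]
    dE_prev <- dE_prev + dCat[, seq_len(d), drop = FALSE]
    dM <- dCat[, d + seq_len(d), drop = FALSE]
    re <- graph$rel_edges[[r]]
    nz <- re$deg > 0L
    dM[nz, ] <- dM[nz, , drop = FALSE] / re$deg[nz]
    dE_prev <- dE_prev + agg_rows(dM[re$dst, , drop = FALSE], re$src,
                                  nrow(E_prev))
  }
  list(dE_prev = dE_prev, gW = gW)
}

#' Local-interaction embeddings for all drugs
#'
#' Applies K propagation layers from the learned initial table and returns
#' the drug rows. Drugs with no associations pass through with all-empty
#' neighbourhoods (cold start) and trigger a warning.
#'
#' @param graph a `hetero_graph`.
#' @param params a `local_params`.
#' @return matrix n_drugs x d, drug ids as rownames.
#' @export
encode_local <- function(graph, params) {
  E <- params$E0
  for (k in seq_len(params$K)) {
    E <- layer_forward(graph, E, params$W[[k]])
  }
  di <- seq_along(graph$drug_ids)
  deg_any <- Reduce(`+`, lapply(graph$rel_edges, function(re) re$deg[di]))
  if (any(deg_any == 0L)) {
    warning("cold-start drugs without associations: ",
            paste(utils::head(graph$drug_ids[deg_any == 0L], 3L), collapse = ", "))
  }
  L <- E[di, , drop = FALSE]
  rownames(L) <- graph$drug_ids
  L
}

#' Pretrain the local encoder by link reconstruction
#'
#' Observed drug-entity edges are positives; an equal number of uniformly
#' sampled unobserved (drug, entity) pairs per relation are negatives. The
#' score of a pair is sigmoid of the dot product of the final embeddings
#' plus a trainable scalar bias (initialised so scores start centred), and
#' the loss is binary cross-entropy, minimised by Adam over the initial
#' embedding table, all relation weight matrices and the bias.
#'
#' @param graph a `hetero_graph` with at least one edge in some relation.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param d,K width and depth.
#' @param seed integer seed.
#' @return list with `params` (`local_params`) and `loss_history`.
#' @export
pretrain_local <- function(graph, epochs = 40L, lr = 0.05,
                           d = 32L, K = 1L, seed = 1L) {
  params <- init_local_params(graph, d, K, seed)
  n <- length(graph$nodes)
  idx <- stats::setNames(seq_along(graph$nodes), graph$nodes)
  pos <- list()
  for (r in graph$relations) {
    re <- graph$rel_edges[[r]]
    m <- length(re$src) / 2L
    if (m == 0L) { warning("relation ", r, " has no edges; skipped"); next }
    pos[[r]] <- cbind(re$src[seq_len(m)], re$dst[seq_len(m)])  # drug, entity
  }
  if (!length(pos)) stop("graph has no edges in any relation")
  # centre the initial link scores (see module header)
  E_init <- params$E0
  for (k in seq_len(K)) E_init <- layer_forward(graph, E_init, params$W[[k]])
  all_pos <- do.call(rbind, pos)
  params$b <- -stats::median(rowSums(E_init[all_pos[, 1L], , drop = FALSE] *
                                     E_init[all_pos[, 2L], , drop = FALSE]))
  tk <- c("E0", "W", "b")
  opt <- adam_init(params[tk])
  loss_hist <- numeric(epochs)
  rel_nodes <- lapply(graph$relations, function(r) {
    which(graph$node_type == r)
  })
  names(rel_nodes) <- graph$relations
  drugs <- which(graph$node_type == "drug")
  for (ep in seq_len(epochs)) {
    neg <- with_seed(sub_seed(seed, 200L + ep), {
      lapply(names(pos), function(r) {
        np <- nrow(pos[[r]])
        seen <- paste(pos[[r]][, 1L], pos[[r]][, 2L])
        du <- sample(drugs, np, replace = TRUE)
        ev <- sample(rel_nodes[[r]], np, replace = TRUE)
        keep <- !(paste(du, ev) %in% seen)
        cbind(du[keep], ev[keep])
      })
    })
    samp <- rbind(do.call(rbind, pos), do.call(rbind, neg))
    y <- c(rep(1, sum(vapply(pos, nrow, integer(1)))),
           rep(0, sum(vapply(neg, nrow, integer(1)))))
    # forward with caches
    E <- params$E0
    caches <- vector("list", K)
    Es <- vector("list", K + 1L); Es[[1L]] <- E
    for (k in seq_len(K)) {
      caches[[k]] <- local_layer_forward(graph, E, params$W[[k]])
      E <- caches[[k]]$E
      Es[[k + 1L]] <- E
    }
    s <- rowSums(E[samp[, 1L], , drop = FALSE] * E[samp[, 2L], , drop = FALSE]) +
      params$b
    p <- clip01(sigmoid(s))
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    if (!is.finite(loss)) stop("divergence: non-finite link loss")
    loss_hist[ep] <- loss
    ds <- (p - y) / length(y)
    dE <- agg_rows(ds * E[samp[, 2L], , drop = FALSE], samp[, 1L], n) +
          agg_rows(ds * E[samp[, 1L], , drop = FALSE], samp[, 2L], n)
    gW <- vector("list", K)
    for (k in rev(seq_len(K))) {
      bk <- local_layer_backward(graph, Es[[k]], params$W[[k]], caches[[k]], dE)
      gW[[k]] <- bk$gW
      dE <- bk$dE_prev
    }
    grads <- list(E0 = dE, W = gW, b = sum(ds))
    st <- adam_step(params[tk], grads, opt, lr)
    params[tk] <- st$params
    opt <- st$opt
  }
  list(params = params, loss_history = loss_hist)
}
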