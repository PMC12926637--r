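# Pair scoring and training. A drug pair is scored by an MLP on
# Concat(x_i, x_j) — two hidden ReLU layers, then a sigmoid unit (binary
# DDI) or a softmax over event classes. Because concatenation is
# order-sensitive while DDI is undirected, training uses both orderings of
# every pair and inference reports the mean of score(i, j) and score(j, i).
# Event training follows the phased schedule: cross-entropy for t < T/2,
# focal loss (gamma = 2) for t >= T/2.

#' Initialise a prediction head
#'
#' @param d fused embedding width (head input is 2d).
#' @param n_classes 1 for binary mode, otherwise the event-class count.
#' @param hidden widths of the two hidden layers.
#' @param seed integer seed.
#' @return list of class `pred_head`.
#' @export
init_pred_head <- function(d, n_classes = 1L, hidden = c(256L, 128L),
                           seed = 1L) {
  with_seed(seed, {
    p <- list(W1 = init_mat(hidden[1L], 2L * d), b1 = rep(0, hidden[1L]),
              W2 = init_mat(hidden[2L], hidden[1L]), b2 = rep(0, hidden[2L]),
              W3 = init_mat(n_classes, hidden[2L], 0.1), b3 = rep(0, n_classes))
    p$d <- as.integer(d); p$n_classes <- as.integer(n_classes)
    class(p) <- "pred_head"
    p
  })
}

head_forward <- function(X, head, mode) {
  Z1 <- sweep(X %*% t(head$W1), 2L, head$b1, "+"); H1 <- relu(Z1)
  Z2 <- sweep(H1 %*% t(head$W2), 2L, head$b2, "+"); H2 <- relu(Z2)
  Z3 <- sweep(H2 %*% t(head$W3), 2L, head$b3, "+")
  P <- if (mode == "binary") sigmoid(Z3) else softmax_rows(Z3)
  list(P = P, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, Z3 = Z3, X = X)
}

# dZ3: gradient at the pre-activation output. Returns grads + dX.
head_backward <- function(cache, head, dZ3) {
  gW3 <- t(dZ3) %*% cache$H2; gb3 <- colSums(dZ3)
  dH2 <- dZ3 %*% head$W3
  dZ2 <- dH2 * (cache$Z2 > 0)
  gW2 <- t(dZ2) %*% cache$H1; gb2 <- colSums(dZ2)
  dH1 <- dZ2 %*% head$W2
  dZ1 <- dH1 * (cache$Z1 > 0)
  gW1 <- t(dZ1) %*% cache$X; gb1 <- colSums(dZ1)
  dX <- dZ1 %*% head$W1
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3), dX = dX)
}

#' Score one drug pair
#'
#' @param x_i,x_j fused drug vectors.
#' @param head a `pred_head`.
#' @param mode "binary" or "event".
#' @return interaction probability (binary) or class distribution (event);
#'   the mean of the two concatenation orders.
#' @export
pair_score <- function(x_i, x_j, head, mode = c("binary", "event")) {
  mode <- match.arg(mode)
  if (length(x_i) != head$d || length(x_j) != head$d) {
    stop("fused width does not match head input")
  }
  X <- rbind(c(x_i, x_j), c(x_j, x_i))
  P <- head_forward(X, head, mode)$P
  colMeans(P)
}

#' Binary cross-entropy of one prediction
#'
#' @param y true label, 0 or 1.
#' @param yhat predicted probability (clipped to [1e-7, 1 - 1e-7]).
#' @return scalar loss.
#' @export
bce_loss <- function(y, yhat) {
  if (!all(y %in% c(0, 1))) stop("binary labels must be 0 or 1")
  yhat <- clip01(yhat)
  mean(-(y * log(yhat) + (1 - y) * log(1 - yhat)))
}

#' Event-classification loss (cross-entropy or focal)
#'
#' CE: -sum_i y_i log y'_i. FL: -sum_i (1 - y'_i)^gamma y_i log y'_i, which
#' reduces to CE exactly at gamma = 0 and is pointwise <= CE for gamma >= 0.
#'
#' @param y one-hot vector over the classes.
#' @param yprime predicted distribution (same length).
#' @param phase "CE" or "FL".
#' @param gamma_f focusing exponent (default 2, the FL-phase setting).
#' @return scalar loss.
#' @export
event_loss <- function(y, yprime, phase = c("CE", "FL"), gamma_f = 2) {
  phase <- match.arg(phase)
  if (length(y) != length(yprime) || !all(y %in% c(0, 1)) || sum(y) != 1) {
    stop("y must be a one-hot vector matching yprime")
  }
  p <- clip01(yprime)
  w <- if (phase == "FL") (1 - p)^gamma_f else 1
  -sum(w * y * log(p))
}

#' Phase of the CE -> FL schedule at an epoch
#'
#' @param t 0-based epoch index.
#' @param T_total total number of epochs.
#' @return "CE" when t < T/2, "FL" when t >= T/2.
#' @export
phase_of_epoch <- function(t, T_total) {
  if (t < 0 || t >= T_total) stop("epoch index out of range [0, ", T_total, ")")
  if (t < T_total / 2) "CE" else "FL"
}

#' Remove rare event classes
#'
#' Classes with strictly fewer than `min_count` pairs are dropped entirely
#' and the class vocabulary is rebuilt; surviving rows keep their order.
#'
#' @param pairs an event-mode pair table.
#' @param min_count threshold (default 10; a class with exactly `min_count`
#'   instances is retained).
#' @return filtered pair table.
#' @export
filter_rare_events <- function(pairs, min_count = 10L) {
  if (!identical(attr(pairs, "mode"), "event")) {
    stop("filter_rare_events applies to event-mode pair tables")
  }
  cnt <- table(pairs$label)
  keep_classes <- names(cnt)[cnt >= min_count]
  if (!length(keep_classes)) {
    stop("all event classes fall below min_count = ", min_count)
  }
  out <- pairs[pairs$label %in% keep_classes, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_vocab") <- build_vocab(out$label)
  attr(out, "mode") <- "event"
  out
}

#' Stratified K-fold partition of a pair table
#'
#' Within each class, rows are shuffled by the seed and dealt round-robin to
#' folds, so per-fold class counts deviate from exact proportionality by at
#' most one. Folds are disjoint and exhaustive.
#'
#' @param pairs a pair table (binary labels or event classes).
#' @param K number of folds (>= 2).
#' @param seed integer seed.
#' @return list of K elements, each `list(train = idx, test = idx)`.
#' @export
stratified_kfold <- function(pairs, K = 5L, seed = 1L) {
  stopifnot(K >= 2L)
  lab <- as.character(pairs$label)
  cnt <- table(lab)
  if (any(cnt < K)) {
    warning("class(es) with fewer than K instances: ",
            paste(names(cnt)[cnt < K], collapse = ", "),
            " (some folds will lack them)")
  }
  fold <- integer(nrow(pairs))
  with_seed(seed, {
    for (cl in names(cnt)) {
      idx <- which(lab == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  lapply(seq_len(K), function(k) {
    list(train = which(fold != k), test = which(fold == k))
  })
}

# ---- training ---------------------------------------------------------------

#' Training plan
#'
#' @param mode "binary" or "event".
#' @param epochs total epochs T.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @param focal_gamma focusing exponent of the FL phase.
#' @param fine_tune_encoders if TRUE, the exported per-drug scale-embedding
#'   matrices are updated along with fusion and head (representation-level
#'   fine-tuning); encoders are frozen otherwise.
#' @param folds fold count for cross-validation helpers.
#' @param hidden hidden widths of the pair head.
#' @param heads attention head count of the transformer fusion.
#' @param strategy fusion strategy.
#' @return list of class `train_plan`.
#' @export
train_plan <- function(mode = c("binary", "event"), epochs = 100L, lr = 0.01,
                       seed = 1L, focal_gamma = 2, fine_tune_encoders = FALSE,
                       folds = 5L, hidden = c(256L, 128L), heads = 4L,
                       strategy = c("transformer", "concat", "hadamard",
                                    "average")) {
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  stopifnot(epochs >= 1L, focal_gamma >= 0)
  structure(list(mode = mode, epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed), focal_gamma = focal_gamma,
                 fine_tune_encoders = isTRUE(fine_tune_encoders),
                 folds = as.integer(folds), hidden = as.integer(hidden),
                 heads = as.integer(heads), strategy = strategy),
            class = "train_plan")
}

# Column-standardise a scale matrix; returns matrix + stats for reuse.
standardize_scale <- function(M, stats_in = NULL) {
  if (is.null(stats_in)) {
    mu <- colMeans(M)
    sd <- apply(M, 2L, stats::sd)
    sd[!is.finite(sd) | sd < 1e-8] <- 1
    stats_in <- list(mu = mu, sd = sd)
  }
  list(M = sweep(sweep(M, 2L, stats_in$mu), 2L, stats_in$sd, "/"),
       stats = stats_in)
}

#' Train the fusion + pair-head model
#'
#' Stage-wise regime: the supplied per-drug scale embeddings stay frozen
#' (unless `plan$fine_tune_encoders`), and Adam updates the fusion
#' parameters and the MLP head. Binary mode minimises binary cross-entropy;
#' event mode follows the phased CE -> FL schedule with the switch at the
#' first epoch t >= T/2.
#'
#' @param pairs pair table (mode must match the plan).
#' @param scales named list of per-drug embedding matrices (any non-empty
#'   subset of a/l/g; equal widths; rownames = drug ids). Each is
#'   column-standardised before fusion.
#' @param plan a [train_plan()].
#' @param val_pairs optional held-out pair table for per-epoch metrics.
#' @return object of class `ddi_model`: fusion + head parameters,
#'   standardisation stats, training history (loss, phase, optional
#'   validation AUROC/accuracy).
#' @export
train_model <- function(pairs, scales, plan, val_pairs = NULL) {
  mode <- plan$mode
  if (!identical(attr(pairs, "mode"), mode)) {
    stop("pair table mode does not match plan mode '", mode, "'")
  }
  ids <- rownames(scales[[1L]])
  for (s in scales) stopifnot(identical(rownames(s), ids))
  missing <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), ids)
  if (length(missing)) {
    stop("pairs reference drug(s) without embeddings: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  d <- ncol(scales[[1L]])
  std <- lapply(scales, standardize_scale)
  S_mats <- lapply(std, `[[`, "M")
  n_tokens <- length(S_mats)

  if (mode == "event") {
    cvoc <- attr(pairs, "class_vocab")
    n_classes <- length(cvoc)
    y_cls <- cvoc[pairs$label] + 1L
  } else {
    n_classes <- 1L
    y <- pairs$label
  }
  fparams <- init_fusion_params(d, n_tokens, plan$heads, plan$strategy,
                                seed = sub_seed(plan$seed, STAGE_OFFSETS[["fusion_train"]]))
  head <- init_pred_head(d, n_classes, plan$hidden,
                         seed = sub_seed(plan$seed, STAGE_OFFSETS[["fusion_train"]]) + 1L)
  fkeys <- if (plan$strategy == "transformer") {
    c("heads", "WO", "bO", "ln1", "ln2", "ffn", "readout")
  } else "readout"
  hkeys <- c("W1", "b1", "W2", "b2", "W3", "b3")
  params <- list(fusion = fparams[fkeys], head = head[hkeys])
  if (plan$fine_tune_encoders) params$scales <- S_mats
  opt <- adam_init(params)

  ia <- match(pairs$drug_a, ids)
  ib <- match(pairs$drug_b, ids)
  # both orderings of every pair
  ord1 <- c(ia, ib)
  ord2 <- c(ib, ia)
  ylab <- if (mode == "binary") c(y, y) else c(y_cls, y_cls)
  N <- length(ord1)
  n_drugs <- length(ids)

  history <- data.frame(epoch = seq_len(plan$epochs) - 1L,
                        loss = NA_real_, phase = NA_character_,
                        val_metric = NA_real_)
  for (ep in seq_len(plan$epochs)) {
    t0 <- ep - 1L
    phase <- if (mode == "event") phase_of_epoch(t0, plan$epochs) else "CE"
    fparams[fkeys] <- params$fusion
    head[hkeys] <- params$head
    if (plan$fine_tune_encoders) S_mats <- params$scales
    ff <- fuse_forward(S_mats, fparams)
    X <- ff$X
    Xp <- cbind(X[ord1, , drop = FALSE], X[ord2, , drop = FALSE])
    hf <- head_forward(Xp, head, mode)
    if (mode == "binary") {
      p <- clip01(hf$P[, 1L])
      loss <- -mean(ylab * log(p) + (1 - ylab) * log(1 - p))
      dZ3 <- matrix((hf$P[, 1L] - ylab) / N, ncol = 1L)
    } else {
      P <- hf$P
      pt <- clip01(P[cbind(seq_len(N), ylab)])
      if (phase == "CE") {
        loss <- mean(-log(pt))
        dZ3 <- P
        dZ3[cbind(seq_len(N), ylab)] <- dZ3[cbind(seq_len(N), ylab)] - 1
        dZ3 <- dZ3 / N
      } else {
        g <- plan$focal_gamma
        loss <- mean(-(1 - pt)^g * log(pt))
        # dL/dp_t, then through softmax (only the true-class row of y)
        dLdpt <- g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt
        a <- dLdpt * pt / N
        dZ3 <- -a * P
        dZ3[cbind(seq_len(N), ylab)] <- dZ3[cbind(seq_len(N), ylab)] + a
      }
    }
    if (!is.finite(loss)) stop("divergence: non-finite training loss")
    hb <- head_backward(hf, head, dZ3)
    dX <- agg_rows(hb$dX[, seq_len(d), drop = FALSE], ord1, n_drugs) +
          agg_rows(hb$dX[, d + seq_len(d), drop = FALSE], ord2, n_drugs)
    fb <- fuse_backward(ff$cache, dX, fparams)
    grads <- list(fusion = fb$grads[fkeys], head = hb$grads)
    if (plan$fine_tune_encoders) grads$scales <- fb$dscales
    st <- adam_step(params, grads, opt, plan$lr)
    params <- st$params
    opt <- st$opt
    history$loss[ep] <- loss
    history$phase[ep] <- phase
    if (!is.null(val_pairs)) {
      va <- match(val_pairs$drug_a, ids)
      vb <- match(val_pairs$drug_b, ids)
      Pv <- (head_forward(cbind(X[va, , drop = FALSE], X[vb, , drop = FALSE]),
                          head, mode)$P +
             head_forward(cbind(X[vb, , drop = FALSE], X[va, , drop = FALSE]),
                          head, mode)$P) / 2
      history$val_metric[ep] <- if (mode == "binary") {
        rank_metrics(val_pairs$label, as.numeric(Pv))$auroc
      } else {
        mean(max.col(Pv) == cvoc[val_pairs$label] + 1L)
      }
    }
  }
  model <- finalize_model(params, fparams, head, fkeys, hkeys, std, ids, plan,
                          n_classes, if (mode == "event") cvoc else NULL,
                          history = history)
  model$X_cache <- {
    S_final <- if (plan$fine_tune_encoders) params$scales else S_mats
    Xf <- fuse_forward(S_final, model$fusion)$X
    rownames(Xf) <- ids
    Xf
  }
  model
}

finalize_model <- function(params, fparams, head, fkeys, hkeys, std, ids,
                           plan, n_classes, class_vocab, history = NULL) {
  fparams[fkeys] <- params$fusion
  head[hkeys] <- params$head
  structure(list(
    fusion = fparams, head = head,
    scale_stats = lapply(std, `[[`, "stats"),
    scale_names = names(std),
    fine_tuned_scales = params$scales,
    drug_ids = ids, mode = plan$mode, d = fparams$d,
    n_classes = n_classes, class_vocab = class_vocab,
    plan = plan, history = history
  ), class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("<ddi_model> mode=", x$mode, " strategy=", x$fusion$strategy,
      " d=", x$d, " drugs=", length(x$drug_ids), "\n", sep = "")
  invisible(x)
}

#' Fused representations of the model's drugs
#'
#' @param model a `ddi_model`.
#' @param scales the same named list of raw scale matrices used in training
#'   (standardised with the stored statistics). Ignored when the model was
#'   fine-tuned at the representation level.
#' @return matrix n_drugs x d of fused vectors.
#' @export
fused_embeddings <- function(model, scales) {
  S_mats <- if (!is.null(model$fine_tuned_scales)) {
    model$fine_tuned_scales
  } else {
    Map(function(nm, st) standardize_scale(scales[[nm]], st)$M,
        model$scale_names, model$scale_stats)
  }
  X <- fuse_forward(S_mats, model$fusion)$X
  rownames(X) <- model$drug_ids
  X
}

#' Score drug pairs with a trained model
#'
#' Inference averages the two concatenation orders of each pair.
#'
#' @param model a `ddi_model`.
#' @param pairs pair table (labels, if present, are ignored).
#' @param scales raw scale matrices; defaults to those frozen in the model
#'   when it was trained without fine-tuning and cached, otherwise required.
#' @return numeric vector of probabilities (binary) or a matrix with one
#'   column per event class (columns named by class token).
#' @export
predict_pairs <- function(model, pairs, scales = NULL) {
  X <- if (!is.null(model$X_cache)) model$X_cache else {
    if (is.null(scales) && is.null(model$fine_tuned_scales)) {
      stop("supply the scale matrices used at training time")
    }
    fused_embeddings(model, scales)
  }
  ia <- match(pairs$drug_a, model$drug_ids)
  ib <- match(pairs$drug_b, model$drug_ids)
  if (anyNA(ia) || anyNA(ib)) stop("pairs reference drugs unknown to the model")
  P1 <- head_forward(cbind(X[ia, , drop = FALSE], X[ib, , drop = FALSE]),
                     model$head, model$mode)$P
  P2 <- head_forward(cbind(X[ib, , drop = FALSE], X[ia, , drop = FALSE]),
                     model$head, model$mode)$P
  P <- (P1 + P2) / 2
  if (model$mode == "binary") as.numeric(P) else {
    colnames(P) <- names(model$class_vocab)
    P
  }
}
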