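test_that("pair scoring is order-averaged and normalised", {
  head <- init_pred_head(d = 4, n_classes = 1, hidden = c(8, 6), seed = 2)
  x <- rnorm(4); y <- rnorm(4)
  s_xy <- pair_score(x, y, head)
  s_yx <- pair_score(y, x, head)
  expect_equal(s_xy, s_yx)                   # averaging makes it symmetric
  expect_equal(pair_score(x, x, head), pair_score(x, x, head))

  # zero weights -> sigmoid(0) = 0.5
  h0 <- head
  for (k in c("W1", "b1", "W2", "b2", "W3", "b3")) h0[[k]][] <- 0
  expect_equal(unname(pair_score(x, y, h0)), 0.5)

  # event mode sums to one
  he <- init_pred_head(d = 4, n_classes = 5, hidden = c(8, 6), seed = 2)
  expect_equal(sum(pair_score(x, y, he, mode = "event")), 1, tolerance = 1e-6)
  expect_error(pair_score(rnorm(3), y, head), "width")
})

test_that("losses match their scalar oracles and identities", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(round(bce_loss(1, 0.9), 4), 0.1054)
  expect_lt(bce_loss(0, 1e-9), 1e-6)
  expect_error(bce_loss(2, 0.5), "0 or 1")

  y <- c(0, 1, 0)
  expect_equal(event_loss(y, c(0, 1, 0), "CE"), 0, tolerance = 1e-6)
  expect_equal(event_loss(y, c(0.3, 0.5, 0.2), "FL", gamma_f = 2),
               0.25 * log(2), tolerance = 1e-9)
  expect_equal(round(event_loss(y, c(0.3, 0.5, 0.2), "FL", 2), 4), 0.1733)
  expect_error(event_loss(c(1, 1, 0), c(0.5, 0.3, 0.2), "CE"), "one-hot")

  # FL with gamma 0 equals CE on 1000 random distributions; FL <= CE
  set.seed(13)
  worst <- 0
  for (case in 1:1000) {
    k <- sample(2:10, 1)
    p <- runif(k); p <- p / sum(p)
    yy <- integer(k); yy[sample(k, 1)] <- 1L
    ce <- event_loss(yy, p, "CE")
    fl0 <- event_loss(yy, p, "FL", gamma_f = 0)
    fl2 <- event_loss(yy, p, "FL", gamma_f = 2)
    worst <- max(worst, abs(ce - fl0))
    expect_lte(fl2, ce)
  }
  expect_lt(worst, 1e-9)
})

test_that("the CE to FL switch happens exactly at t >= T/2", {
  expect_equal(vapply(0:9, phase_of_epoch, "", T_total = 10),
               rep(c("CE", "FL"), each = 5))
  expect_equal(phase_of_epoch(0, 1), "CE")
  expect_equal(vapply(0:6, phase_of_epoch, "", T_total = 7),
               c(rep("CE", 4), rep("FL", 3)))
  expect_error(phase_of_epoch(10, 10), "out of range")
  expect_error(phase_of_epoch(-1, 10), "out of range")
})

test_that("rare-event filtering is strict and rebuilds the vocabulary", {
  lab <- c(rep("A", 9), rep("B", 10), rep("C", 3))
  n <- length(lab)
  pt <- pair_table(sprintf("D%02d", 1:n), sprintf("E%02d", 1:n), lab, "event")
  kept <- filter_rare_events(pt, min_count = 10)
  expect_equal(unique(kept$label), "B")       # A (9) and C (3) dropped
  expect_equal(nrow(kept), 10L)               # exactly-10 class retained
  expect_length(attr(kept, "class_vocab"), 1L)
  # vacuous threshold is the identity
  expect_equal(nrow(filter_rare_events(pt, 1)), n)
  expect_error(filter_rare_events(pt, 100), "below min_count")
  expect_error(filter_rare_events(pair_table("a", "b", 1, "binary")), "event")
})

test_that("stratified folds deal classes round-robin within one of parity", {
  lab <- c(rep("x", 50), rep("y", 50))
  pt <- pair_table(sprintf("D%03d", 1:100), sprintf("E%03d", 1:100), lab, "event")
  folds <- stratified_kfold(pt, K = 5, seed = 3)
  for (f in folds) {
    expect_equal(sum(pt$label[f$test] == "x"), 10L)
    expect_equal(sum(pt$label[f$test] == "y"), 10L)
  }
  # uneven classes: {A:7, B:13}, K=5 -> per-fold A in {1,2}, B in {2,3}
  lab2 <- c(rep("A", 7), rep("B", 13))
  pt2 <- pair_table(sprintf("D%02d", 1:20), sprintf("E%02d", 1:20), lab2, "event")
  folds2 <- stratified_kfold(pt2, 5, seed = 1)
  cnts <- t(vapply(folds2, function(f) {
    c(sum(pt2$label[f$test] == "A"), sum(pt2$label[f$test] == "B"))
  }, integer(2)))
  expect_true(all(cnts[, 1] %in% 1:2))
  expect_true(all(cnts[, 2] %in% 2:3))
  expect_equal(sum(cnts), 20L)
  # partition property
  all_test <- sort(unlist(lapply(folds2, `[[`, "test")))
  expect_equal(all_test, 1:20)
  expect_warning(stratified_kfold(pt2[1:8, ], K = 5, seed = 1), "fewer than K")
})

test_that("training reduces loss, is deterministic and logs the phase switch", {
  set.seed(42)
  n_drugs <- 30
  ids <- sprintf("D%03d", 1:n_drugs)
  U <- matrix(rnorm(n_drugs * 6), n_drugs, 6, dimnames = list(ids, NULL))
  cfg <- synth_config(seed = 8, n_drugs = n_drugs, n_pairs = 120,
                      pair_logit_scale = 8)
  pairs <- gen_pairs(U, "binary", cfg)
  scales <- list(u = U %*% matrix(rnorm(6 * 12), 6, 12))
  rownames(scales$u) <- ids
  plan <- train_plan("binary", epochs = 30, seed = 3, hidden = c(16, 8),
                     strategy = "concat")
  m1 <- train_model(pairs, scales, plan)
  m2 <- train_model(pairs, scales, plan)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_lte(tail(m1$history$loss, 1), m1$history$loss[1])
  expect_true(all(m1$history$phase == "CE"))   # binary mode never switches

  # event mode records the CE -> FL switch at ceil(T/2)
  pe <- gen_pairs(U, "event", cfg)
  plan_e <- train_plan("event", epochs = 10, seed = 3, hidden = c(16, 8),
                       strategy = "concat")
  me <- train_model(pe, scales, plan_e)
  expect_equal(me$history$phase, rep(c("CE", "FL"), each = 5))

  # scoring covers both orders and aligns with write_predictions
  sc <- predict_pairs(m1, pairs)
  expect_length(sc, nrow(pairs))
  expect_true(all(sc >= 0 & sc <= 1))
  Pe <- predict_pairs(me, pe)
  expect_true(is.matrix(Pe))
  expect_equal(unname(rowSums(Pe)), rep(1, nrow(pe)), tolerance = 1e-6)
})
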