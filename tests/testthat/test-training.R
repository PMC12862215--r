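test_that("stratified batches keep per-batch composition near the global mix", {
  biotype <- c(rep("coding", 80), rep("noncoding", 20))
  ord <- stratified_batches(biotype, 4L, seed = 1)
  expect_setequal(ord, 1:100)
  for (b in seq(1, 100, by = 4)) {
    n_cod <- sum(biotype[ord[b:(b + 3)]] == "coding")
    expect_true(abs(n_cod / 4 - 0.8) <= 1 / 4)
  }
  expect_identical(ord, stratified_batches(biotype, 4L, seed = 1))
  expect_false(identical(ord, stratified_batches(biotype, 4L, seed = 2)))

  all_cod <- stratified_batches(rep("coding", 10), 4L, seed = 1)
  expect_setequal(all_cod, 1:10)
  expect_error(stratified_batches(character(0), 4L), "no samples")
})

test_that("proportionality bound holds across random mixes", {
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(20:200, 1)
      bs <- sample(2:8, 1)
      biotype <- sample(c("coding", "noncoding"), n, replace = TRUE)
      ord <- stratified_batches(biotype, bs, seed = i)
      expect_setequal(ord, seq_len(n))
      frac <- mean(biotype == "coding")
      for (b in seq(1, n, by = bs)) {
        idx <- ord[b:min(n, b + bs - 1)]
        # a batch of k samples has composition granularity 1/k (the final
        # batch may be smaller than bs)
        expect_true(abs(mean(biotype[idx] == "coding") - frac) <=
                      1 / length(idx) + 1e-9,
                    label = sprintf("batch composition (n=%d bs=%d)", n, bs))
      }
    }
  })
})

test_that("masked cross-entropy matches closed forms and ignores padding", {
  # uniform logits: loss is ln 3 per position
  lg <- array(0, dim = c(10, 3, 1))
  lab <- matrix(rep(1L, 10), ncol = 1)
  expect_equal(masked_cross_entropy(lg, lab, 10L), log(3))

  # confident correct logits drive the loss toward 0
  lg2 <- array(rep(c(50, 0, 0), each = 1), dim = c(1, 3, 1))
  lg2[1, , 1] <- c(50, 0, 0)
  expect_lt(masked_cross_entropy(lg2, matrix(1L), 1L), 1e-10)

  # altering logits at padded positions changes nothing
  withr::with_seed(9, {
    lg3 <- array(rnorm(60), dim = c(10, 3, 2))
    lab3 <- matrix(sample(1:3, 20, TRUE), 10, 2)
    base <- masked_cross_entropy(lg3, lab3, c(6L, 8L))
    lg4 <- lg3
    lg4[7:10, , 1] <- 99
    lg4[9:10, , 2] <- -99
    expect_identical(masked_cross_entropy(lg4, lab3, c(6L, 8L)), base)
  })
})

test_that("engine loss equals the reference masked cross-entropy", {
  m <- build_model(tiny_model_config(30L), seed = 10)
  withr::with_seed(10, {
    tok <- matrix(sample(0:4, 90, replace = TRUE), nrow = 30)
    lab_r <- matrix(sample(1:3, 90, replace = TRUE), nrow = 30)
  })
  vl <- c(30L, 22L, 15L)
  lab_engine <- lab_r - 1L
  for (b in 1:3) if (vl[b] < 30) lab_engine[(vl[b] + 1):30, b] <- -1L
  engine <- orfcall:::.nn_eval_loss(m$ptr, tok, lab_engine, 2L)
  reference <- masked_cross_entropy(model_forward(m, tok), lab_r, vl)
  expect_equal(engine, reference, tolerance = 1e-5)
})

test_that("plateau schedule halves the rate and early stopping keeps the best epoch", {
  # plateau after 3 flat epochs: lr halved once, applied from epoch 5
  s <- orfcall:::plateau_schedule(c(1.0, 0.9, 0.9, 0.9, 0.9), lr0 = 1e-3,
                                  factor = 0.5, plateau_patience = 3,
                                  early_stop_patience = 5)
  expect_equal(s$lrs, c(1e-3, 1e-3, 1e-3, 1e-3, 1e-3))
  expect_equal(s$next_lr, 5e-4)
  expect_equal(s$best_epoch, 2)

  # five non-improving epochs stop training; best precedes the streak
  s2 <- orfcall:::plateau_schedule(c(1.0, 0.8, 0.85, 0.85, 0.85, 0.85, 0.85, 0.9),
                                   lr0 = 1e-3, factor = 0.5,
                                   plateau_patience = 3, early_stop_patience = 5)
  expect_equal(s2$stopped_epoch, 7)
  expect_equal(s2$best_epoch, 2)

  s3 <- orfcall:::plateau_schedule(0.5, 1e-3, 0.5, 3, 5)
  expect_equal(s3$best_epoch, 1)
  expect_equal(s3$stopped_epoch, 1)
})

test_that("training runs reproduce exactly under a fixed seed and keep the best weights", {
  withr::with_seed(12, {
    recs <- generate_transcriptome(small_synth_config(16, 16, seed = 5))
    enc <- encode_transcripts(recs, 120L)
  })
  idx_val <- seq(1, 32, by = 4)
  tr <- list(tokens = enc$tokens[, -idx_val], labels = enc$labels[, -idx_val],
             records = enc$records[-idx_val, ])
  va <- list(tokens = enc$tokens[, idx_val], labels = enc$labels[, idx_val],
             records = enc$records[idx_val, ])
  cfgs <- train_config(max_epochs = 3, seed = 2)
  f1 <- train_model(build_model(tiny_model_config(120L), seed = 3), tr, va,
                    cfgs, verbose = FALSE)
  f2 <- train_model(build_model(tiny_model_config(120L), seed = 3), tr, va,
                    cfgs, verbose = FALSE)
  expect_equal(f1$history, f2$history)
  expect_equal(f1$best_val_loss, min(f1$history$val_loss))
  expect_equal(f1$history$val_loss[f1$best_epoch], f1$best_val_loss)
})

test_that("a few epochs reliably decrease the training loss on learnable data", {
  # 200-sample synthetic set; training loss after 5 epochs must drop from
  # epoch 1 in at least 4 of 5 seeds
  withr::with_seed(13, {
    recs <- generate_transcriptome(small_synth_config(100, 100, seed = 6))
    enc <- encode_transcripts(recs, 200L)
  })
  idx_val <- seq(1, 200, by = 10)
  tr <- list(tokens = enc$tokens[, -idx_val], labels = enc$labels[, -idx_val],
             records = enc$records[-idx_val, ])
  va <- list(tokens = enc$tokens[, idx_val], labels = enc$labels[, idx_val],
             records = enc$records[idx_val, ])
  wins <- 0
  for (seed in 1:5) {
    fit <- train_model(build_model(small_model_config(200L), seed = seed),
                       tr, va, train_config(max_epochs = 5, seed = seed),
                       verbose = FALSE)
    if (tail(fit$history$train_loss, 1) < fit$history$train_loss[1])
      wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("max_epochs of one trains exactly one epoch", {
  withr::with_seed(14, {
    recs <- generate_transcriptome(small_synth_config(8, 8, seed = 7))
    enc <- encode_transcripts(recs, 100L)
  })
  half <- 1:8
  tr <- list(tokens = enc$tokens[, half], labels = enc$labels[, half],
             records = enc$records[half, ])
  fit <- train_model(build_model(tiny_model_config(100L), seed = 1), tr, tr,
                     train_config(max_epochs = 1, seed = 1), verbose = FALSE)
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$best_epoch, 1)
})
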