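test_that("the head has the exact published parameter count", {
  expect_equal(head_param_count(head_config()),
               (1025 * 1024 + 1024) + 2 * (1024 * 1024 + 1024) +
                 (1024 * 512 + 512) + (512 * 6 + 6))
  expect_equal(head_param_count(head_config()), 3677702)
})

test_that("participant splitting follows the 60/20/20 rounding rule", {
  ids <- sprintf("p%02d", 1:78)
  sp <- split_participants(ids, seed = 4)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 47L, val = 16L, test = 15L))
  # partition properties
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  # seeded determinism
  expect_identical(sp, split_participants(ids, seed = 4))
  expect_error(split_participants(c("a", "b")), "at least 3")
})

test_that("per-epoch balancing undersamples the majority class afresh", {
  set.seed(8)
  y <- matrix(0L, 400, 6)
  pos_rows <- 1:100
  y[pos_rows, 3] <- 1L
  idx1 <- balance_epoch(y, seed = 2, epoch = 1)
  expect_length(idx1, 200L)
  expect_equal(sum(idx1 %in% pos_rows), 100L)
  # all positives kept, majority subset varies across epochs
  idx2 <- balance_epoch(y, seed = 2, epoch = 2)
  expect_false(setequal(setdiff(idx1, pos_rows), setdiff(idx2, pos_rows)))
  expect_identical(sort(balance_epoch(y, seed = 2, epoch = 1)), sort(idx1))

  # already balanced input: everything kept, order permuted
  yb <- rbind(y[1:100, ], y[1:100, ] * 0L)
  idxb <- balance_epoch(yb, seed = 2, epoch = 1)
  expect_setequal(idxb, 1:200)

  expect_error(balance_epoch(matrix(0L, 10, 6)), "both classes")
})

test_that("early stopping keeps the best epoch under a scripted schedule", {
  # validation loss strictly increases from epoch 2 on; patience 5
  sched <- c(0.30, 0.25, 0.26, 0.27, 0.28, 0.29, 0.31, 0.32, 0.33)
  tr <- early_stop_trace(sched, patience = 5)
  expect_equal(tr$best_epoch, 2L)
  expect_equal(tr$stop_epoch, 7L)
  # monotone improvement never stops early
  tr2 <- early_stop_trace(seq(1, 0.1, length.out = 9), patience = 5)
  expect_equal(tr2$best_epoch, 9L)
  expect_equal(tr2$stop_epoch, 9L)
})

make_toy <- function(n = 24, seed = 1) {
  # two well-separated feature clusters with opposite subframe targets
  set.seed(seed)
  cls <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * 1025, sd = 0.3), n, 1025) + 2 * cls
  y <- matrix(0L, n, 6); y[cls == 1, ] <- 1L
  list(x = x, y = y)
}

test_that("training descends on a separable toy and respects max_epochs", {
  toy <- make_toy()
  cfg <- head_config(hidden_units = c(16L, 16L, 16L, 8L), l2_layers = 1:3,
                     max_epochs = 30L, batch_size = 8L, seed = 2L)
  fit <- train_head(cfg, toy$x, toy$y, toy$x, toy$y)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_lte(fit$epochs_run, 30L)
  p <- predict(fit, toy$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[toy$y == 1]), mean(p[toy$y == 0]))

  one <- train_head(head_config(hidden_units = c(8L, 8L, 8L, 4L),
                                max_epochs = 1L, batch_size = 8L),
                    toy$x, toy$y, toy$x, toy$y)
  expect_equal(nrow(one$history), 1L)
})

test_that("the training loop's stopping record matches the reference trace", {
  toy <- make_toy(seed = 3)
  val <- make_toy(n = 16, seed = 4)
  cfg <- head_config(hidden_units = c(8L, 8L, 8L, 4L), max_epochs = 25L,
                     batch_size = 8L, patience = 3L, seed = 7L)
  fit <- train_head(cfg, toy$x, toy$y, val$x, val$y)
  ref <- early_stop_trace(fit$history$val_loss, patience = 3)
  expect_equal(fit$best_epoch, ref$best_epoch)
  expect_equal(fit$epochs_run, ref$stop_epoch)
  # restored weights reproduce the best validation loss
  pv <- predict(fit, val$x)
  expect_equal(mean((pv - val$y)^2), min(fit$history$val_loss),
               tolerance = 1e-10)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
})

test_that("training is bitwise reproducible from its seeds", {
  toy <- make_toy(seed = 9)
  cfg <- head_config(hidden_units = c(8L, 8L, 8L, 4L), max_epochs = 5L,
                     batch_size = 8L, seed = 11L)
  f1 <- train_head(cfg, toy$x, toy$y, toy$x, toy$y)
  f2 <- train_head(cfg, toy$x, toy$y, toy$x, toy$y)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("shape errors are raised before any epoch runs", {
  toy <- make_toy()
  cfg <- head_config(hidden_units = c(8L, 8L, 8L, 4L), max_epochs = 2L)
  expect_error(train_head(cfg, toy$x[, 1:100], toy$y, toy$x, toy$y),
               "input_dim")
  expect_error(train_head(cfg, toy$x, toy$y[, 1:3], toy$x, toy$y), "6")
})

test_that("a zero-weight head outputs sigmoid(0) = 0.5 everywhere", {
  cfg <- head_config(hidden_units = c(8L, 8L, 8L, 4L))
  init <- init_head(cfg)
  zero <- lapply(init$W, function(w) w * 0)
  h <- structure(list(weights = list(W = zero, b = init$b), scaling = NULL,
                      config = cfg), class = "trained_head")
  expect_equal(as.vector(predict(h, rnorm(1025))), rep(0.5, 6))
  expect_identical(predict(h, matrix(1, 2, 1025)),
                   predict(h, matrix(1, 2, 1025)))
})

test_that("checkpoints round-trip with their JSON sidecar", {
  toy <- make_toy()
  cfg <- head_config(hidden_units = c(8L, 8L, 8L, 4L), max_epochs = 2L,
                     batch_size = 8L)
  fit <- train_head(cfg, toy$x, toy$y, toy$x, toy$y)
  p <- withr::local_tempfile(fileext = ".rds")
  save_head(fit, p, extra = list(backend = "projection"))
  back <- load_head(p)
  expect_identical(back$weights, fit$weights)
  expect_equal(back$sidecar$param_count, head_param_count(cfg))
  expect_equal(back$sidecar$backend, "projection")
  expect_error(load_head(file.path(tempdir(), "nope.rds")), "not found")
})
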