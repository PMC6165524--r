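test_that("zero-weight cell reduces to the sigmoid/tanh fixed point", {
  w <- lstm_cell_weights(2, 3, seed = NULL)   # all zeros
  st <- lstm_cell_step(c(1, -2), h_prev = numeric(3), c_prev = numeric(3), w)
  expect_equal(st$h, numeric(3))
  expect_equal(st$c, numeric(3))
  # with nonzero previous cell: every gate is sigma(0) = 0.5
  st2 <- lstm_cell_step(c(1, -2), numeric(3), c_prev = c(1, -1, 2), w,
                        peephole = FALSE)
  expect_equal(st2$c, 0.5 * c(1, -1, 2))
  expect_equal(st2$h, 0.5 * tanh(0.5 * c(1, -1, 2)))
})

test_that("scalar cell matches a hand walk-through of the gate equations", {
  w <- list(Wxi = matrix(0.5), Whi = matrix(0.3), Wxf = matrix(-0.2),
            Whf = matrix(0.4), Wcf = matrix(0.1), Wxc = matrix(0.7),
            Whc = matrix(-0.5), Wxo = matrix(0.6), Who = matrix(0.2),
            Wco = matrix(-0.3), bi = 0.1, bf = -0.1, bc = 0.2, bo = 0.05)
  x <- 1.2; h0 <- 0.4; c0 <- -0.6
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(0.5 * 1.2 + 0.3 * (-0.6) + 0.1)
  f <- sig(-0.2 * 1.2 + 0.4 * 0.4 + 0.1 * (-0.6) - 0.1)
  g <- tanh(0.7 * 1.2 - 0.5 * 0.4 + 0.2)
  cc <- f * c0 + i * g
  o <- sig(0.6 * 1.2 + 0.2 * 0.4 - 0.3 * cc + 0.05)
  st <- lstm_cell_step(x, h0, c0, w)
  expect_equal(st$c, cc, tolerance = 1e-14)
  expect_equal(st$h, o * tanh(cc), tolerance = 1e-14)
})

test_that("vectorised cell equals the element-wise oracle to 1e-10", {
  set.seed(21)
  for (rep in 1:10) {
    D <- sample(1:6, 1); H <- sample(1:6, 1)
    w <- lstm_cell_weights(D, H, seed = rep)
    x <- rnorm(D); h0 <- rnorm(H) * 0.5; c0 <- rnorm(H)
    for (peep in c(TRUE, FALSE)) {
      got <- lstm_cell_step(x, h0, c0, w, peephole = peep)
      want <- lstm_cell_bruteforce(x, h0, c0, w, peephole = peep)
      expect_lt(max(abs(got$h - want$h)), 1e-10)
      expect_lt(max(abs(got$c - want$c)), 1e-10)
    }
  }
})

test_that("hidden outputs always lie strictly inside (-1, 1)", {
  set.seed(4)
  w <- lstm_cell_weights(3, 4, seed = 2)
  st <- lstm_cell_step(rnorm(3, sd = 50), rnorm(4), rnorm(4, sd = 10), w)
  expect_true(all(abs(st$h) < 1))
  expect_error(lstm_cell_step(rnorm(5), rnorm(4), rnorm(4), w), "mismatch")
})

test_that("analytic gradients match central finite differences", {
  cfg <- lstm_config(hidden_units = 3, stacked_layers = 2, steps = 2,
                     dense_units = 3, seed = 2)
  set.seed(1)
  n <- 4; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  Y <- diag(3)[sample(1:3, n, TRUE), ]
  params <- harspect:::init_params(cfg, p %/% cfg$steps, 3)
  bp <- harspect:::backward_pass(params, X, Y, cfg)

  gv <- function(p, path) { for (k in path) p <- p[[k]]; p }
  sv <- function(p, path, v) {
    if (length(path) == 1) { p[[path[[1]]]] <- v; return(p) }
    p[[path[[1]]]] <- sv(p[[path[[1]]]], path[-1], v)
    p
  }
  eps <- 1e-6
  for (path in list(list("layers", 1L, "Wxi"), list("layers", 1L, "Whi"),
                    list("layers", 1L, "Wcf"), list("layers", 2L, "Wco"),
                    list("layers", 2L, "Whf"), list("layers", 1L, "bc"),
                    list("dense", "W"), list("out", "W"))) {
    ana <- gv(bp$grads, path)
    p0 <- gv(params, path)
    num <- p0 * 0
    for (k in seq_along(p0)) {
      v <- p0; v[k] <- v[k] + eps
      lp <- harspect:::backward_pass(sv(params, path, v), X, Y, cfg)$loss
      v[k] <- v[k] - 2 * eps
      lm <- harspect:::backward_pass(sv(params, path, v), X, Y, cfg)$loss
      num[k] <- (lp - lm) / (2 * eps)
    }
    expect_lt(max(abs(ana - num)), 1e-6)
  }
})

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(hidden_units = 6, stacked_layers = 2, steps = 4,
         learning_rate = 0.01, max_epochs = 150,
         feature_transform = "none", seed = 1),
    list(...))
  do.call(lstm_config, args)
}

test_that("a linearly separable two-class problem is fit perfectly", {
  fs <- separable_feature_set()
  model <- train_lstm(fs, small_cfg())
  expect_equal(tail(model$history$accuracy, 1), 1)
  expect_identical(as.character(predict(model, fs)),
                   as.character(fs$labels))
})

test_that("training is seed-deterministic and honours max_epochs = 0", {
  fs <- separable_feature_set()
  m1 <- train_lstm(fs, small_cfg(max_epochs = 30))
  m2 <- train_lstm(fs, small_cfg(max_epochs = 30))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  m0 <- train_lstm(fs, small_cfg(max_epochs = 0))
  expect_equal(nrow(m0$history), 0)
})

test_that("degenerate inputs are rejected", {
  fs <- separable_feature_set()
  one_class <- feature_set(fs$features, rep("ST", nrow(fs$features)))
  expect_error(train_lstm(one_class, small_cfg()), "2 classes")
  expect_error(train_lstm(fs, small_cfg(steps = 3)), "divide")
  expect_error(lstm_config(learning_rate = 1.5), "between 0 and 1")
})

test_that("softmax rows normalise and predictions are deterministic", {
  fs <- separable_feature_set()
  model <- train_lstm(fs, small_cfg(max_epochs = 40))
  pr <- predict(model, fs, type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  dup <- feature_set(fs$features[c(1, 1), ], c("ST", "ST"))
  pd <- predict(model, dup)
  expect_identical(pd[1], pd[2])
  expect_error(predict(model, matrix(0, 2, 5)), "width")
})

test_that("stronger L2 regularisation never lowers the final loss", {
  fs <- separable_feature_set()
  base <- train_lstm(fs, small_cfg(max_epochs = 80, l2_lambda = 1e-4))
  strong <- train_lstm(fs, small_cfg(max_epochs = 80, l2_lambda = 1e-3))
  expect_gte(tail(strong$history$loss, 1), tail(base$history$loss, 1))
})

test_that("a checkpoint round-trips through JSON with identical predictions", {
  fs <- separable_feature_set()
  model <- train_lstm(fs, small_cfg(max_epochs = 30))
  path <- withr::local_tempfile(fileext = ".json")
  save_lstm(model, path)
  reloaded <- load_lstm(path)
  expect_equal(predict(reloaded, fs, type = "prob"),
               predict(model, fs, type = "prob"), tolerance = 1e-12)
})
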