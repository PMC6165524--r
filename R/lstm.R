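#' Training configuration for the stacked LSTM classifier
#'
#' Defaults follow the study configuration: 5 stacked LSTM layers of 15
#' hidden units, Adam optimisation of softmax cross-entropy with an L2
#' penalty, mini-batch size 8000 (capped at the dataset size), a loss target
#' of 0.001, and gate equations carrying the peephole-style cell terms
#' (`W_hi c_{t-1}`, `W_cf c_{t-1}`, `W_co c_t`). Static feature vectors are
#' presented to the recurrent stack as a short sequence: by default 4 time
#' steps, one per feature block (SA, LeA, SG, LG).
#'
#' @param hidden_units Hidden state width of every LSTM layer (default 15).
#' @param stacked_layers Number of stacked LSTM layers (default 5).
#' @param learning_rate Adam step size, in (0, 1) (default 0.003).
#' @param mini_batch_size Mini-batch size; the effective batch is
#'   `min(mini_batch_size, n)` (default 8000).
#' @param l2_lambda L2 regularisation strength on all weight matrices
#'   (default 1e-4).
#' @param loss_target Stop training once the epoch loss drops to this value
#'   (default 0.001).
#' @param max_epochs Maximum training epochs (default 300).
#' @param steps Number of time steps the feature vector is reshaped into;
#'   must divide the feature length (default 4).
#' @param peephole Use the cell-state gate terms as printed (default TRUE);
#'   FALSE gives a standard LSTM cell where the input gate sees `h_{t-1}`
#'   and the extra cell-state terms are dropped.
#' @param standardize Z-score features with training-set statistics before
#'   the recurrent stack (default TRUE).
#' @param feature_transform `"log10"` (default) maps each spectral density
#'   x to `log10(max(x, 0) + 1e-12)` before standardisation — power
#'   densities span many orders of magnitude, and the log representation
#'   keeps the quieter classes from being squashed by the loudest one —
#'   or `"none"` for raw values.
#' @param dense_units Width of the ReLU dense stage between the last hidden
#'   state and the softmax layer (default = `hidden_units`).
#' @param init_gain Multiplier on the fan-in-scaled uniform weight
#'   initialisation (default 3). With only a few time steps and several
#'   stacked layers, unit-gain initialisation attenuates the forward signal
#'   to near-constant hidden states; a modest gain keeps the stack trainable.
#' @param seed Integer seed for weight initialisation and batch order.
#' @return Object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 15, stacked_layers = 5,
                        learning_rate = 0.003, mini_batch_size = 8000,
                        l2_lambda = 1e-4, loss_target = 0.001,
                        max_epochs = 300, steps = 4, peephole = TRUE,
                        standardize = TRUE,
                        feature_transform = c("log10", "none"),
                        dense_units = hidden_units, init_gain = 3,
                        seed = 1L) {
  feature_transform <- match.arg(feature_transform)
  if (learning_rate <= 0 || learning_rate >= 1) {
    stop_bad_arg("learning_rate must lie strictly between 0 and 1")
  }
  if (hidden_units < 1 || stacked_layers < 1 || steps < 1) {
    stop_bad_arg("hidden_units, stacked_layers and steps must be >= 1")
  }
  structure(
    list(hidden_units = as.integer(hidden_units),
         stacked_layers = as.integer(stacked_layers),
         learning_rate = learning_rate,
         mini_batch_size = as.integer(mini_batch_size),
         l2_lambda = l2_lambda, loss_target = loss_target,
         max_epochs = as.integer(max_epochs), steps = as.integer(steps),
         peephole = isTRUE(peephole), standardize = isTRUE(standardize),
         feature_transform = feature_transform,
         dense_units = as.integer(dense_units), init_gain = init_gain,
         seed = as.integer(seed)),
    class = "lstm_config"
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Log-power representation of non-negative spectral features; negatives
# (possible only in user-supplied matrices) are clipped to zero.
transform_features <- function(X, transform) {
  switch(transform, none = X, log10 = log10(pmax(X, 0) + 1e-12))
}

#' Random LSTM cell weights
#'
#' Uniform initialisation scaled by fan-in (`1/sqrt(fan_in)`), seeded. The
#' returned list carries the full gate weight set `W_xi, W_hi, W_xf, W_hf,
#' W_cf, W_xc, W_hc, W_xo, W_ho, W_co` and biases `b_i, b_f, b_c, b_o`
#' (`W_cf`/`W_co` are retained but unused when `peephole = FALSE`).
#'
#' @param input_size Width of the cell input vector.
#' @param hidden_units Hidden state width.
#' @param seed Integer seed, or `NULL` for all-zero weights.
#' @return Named list of weight matrices and bias vectors.
#' @export
lstm_cell_weights <- function(input_size, hidden_units, seed = 1L) {
  H <- hidden_units; D <- input_size
  mk <- function(r, c, scale) {
    if (is.null(seed)) matrix(0, r, c)
    else matrix(runif(r * c, -scale, scale), r, c)
  }
  build <- function() {
    sx <- 1 / sqrt(D); sh <- 1 / sqrt(H)
    list(Wxi = mk(H, D, sx), Whi = mk(H, H, sh),
         Wxf = mk(H, D, sx), Whf = mk(H, H, sh), Wcf = mk(H, H, sh),
         Wxc = mk(H, D, sx), Whc = mk(H, H, sh),
         Wxo = mk(H, D, sx), Who = mk(H, H, sh), Wco = mk(H, H, sh),
         bi = numeric(H), bf = numeric(H), bc = numeric(H), bo = numeric(H))
  }
  if (is.null(seed)) build() else with_local_seed(seed, build())
}

#' Single LSTM cell step
#'
#' Applies the gate equations to one input vector:
#' \deqn{i_t = \sigma(W_{xi} x_t + W_{hi} c_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf} x_t + W_{hf} h_{t-1} + W_{cf} c_{t-1} + b_f)}
#' \deqn{c_t = f_t \otimes c_{t-1} + i_t \otimes \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + W_{co} c_t + b_o)}
#' \deqn{h_t = o_t \otimes \tanh(c_t)}
#' With `peephole = FALSE` the `W_{hi}` term multiplies \eqn{h_{t-1}} instead
#' of \eqn{c_{t-1}} and the \eqn{W_{cf}}, \eqn{W_{co}} terms are dropped.
#'
#' @param x_t Input vector.
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @param w Weight list as from [lstm_cell_weights()].
#' @param peephole Use the cell-state gate terms (default TRUE).
#' @return List with components `h` and `c`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, w, peephole = TRUE) {
  H <- length(h_prev)
  if (length(c_prev) != H || nrow(w$Wxi) != H || ncol(w$Wxi) != length(x_t)) {
    stop_bad_arg("shape mismatch between inputs and cell weights")
  }
  st <- cell_forward(matrix(x_t, nrow = 1), matrix(h_prev, nrow = 1),
                     matrix(c_prev, nrow = 1), w, peephole)
  list(h = as.numeric(st$h), c = as.numeric(st$c))
}

# Batched cell forward: X (n x D), Hprev/Cprev (n x H). Returns the gate
# activations needed for backpropagation alongside h and c.
cell_forward <- function(X, Hprev, Cprev, w, peephole) {
  bias <- function(b) matrix(b, nrow = nrow(X), ncol = length(b), byrow = TRUE)
  Pi <- if (peephole) Cprev else Hprev
  i <- sigmoid(X %*% t(w$Wxi) + Pi %*% t(w$Whi) + bias(w$bi))
  af <- X %*% t(w$Wxf) + Hprev %*% t(w$Whf) + bias(w$bf)
  if (peephole) af <- af + Cprev %*% t(w$Wcf)
  f <- sigmoid(af)
  g <- tanh(X %*% t(w$Wxc) + Hprev %*% t(w$Whc) + bias(w$bc))
  c <- f * Cprev + i * g
  ao <- X %*% t(w$Wxo) + Hprev %*% t(w$Who) + bias(w$bo)
  if (peephole) ao <- ao + c %*% t(w$Wco)
  o <- sigmoid(ao)
  tc <- tanh(c)
  list(h = o * tc, c = c, i = i, f = f, g = g, o = o, tc = tc,
       X = X, Hprev = Hprev, Cprev = Cprev)
}

# Backward pass through one cell step. dh/dc are gradients w.r.t. h_t, c_t.
# Returns gradients for the weights plus dX, dHprev, dCprev.
cell_backward <- function(st, w, dh, dc_next, peephole) {
  do <- dh * st$tc
  dao <- do * st$o * (1 - st$o)
  dc <- dh * st$o * (1 - st$tc^2) + dc_next
  if (peephole) dc <- dc + dao %*% w$Wco
  di <- dc * st$g
  dg <- dc * st$i
  df <- dc * st$Cprev
  dai <- di * st$i * (1 - st$i)
  daf <- df * st$f * (1 - st$f)
  dag <- dg * (1 - st$g^2)

  dCprev <- dc * st$f
  if (peephole) dCprev <- dCprev + daf %*% w$Wcf + dai %*% w$Whi
  dHprev <- daf %*% w$Whf + dag %*% w$Whc + dao %*% w$Who
  if (!peephole) dHprev <- dHprev + dai %*% w$Whi
  dX <- dai %*% w$Wxi + daf %*% w$Wxf + dag %*% w$Wxc + dao %*% w$Wxo

  Pi <- if (peephole) st$Cprev else st$Hprev
  gr <- list(Wxi = t(dai) %*% st$X, Whi = t(dai) %*% Pi,
             Wxf = t(daf) %*% st$X, Whf = t(daf) %*% st$Hprev,
             Wxc = t(dag) %*% st$X, Whc = t(dag) %*% st$Hprev,
             Wxo = t(dao) %*% st$X, Who = t(dao) %*% st$Hprev,
             bi = colSums(dai), bf = colSums(daf),
             bc = colSums(dag), bo = colSums(dao))
  if (peephole) {
    gr$Wcf <- t(daf) %*% st$Cprev
    gr$Wco <- t(dao) %*% st$c
  } else {
    gr$Wcf <- w$Wcf * 0
    gr$Wco <- w$Wco * 0
  }
  list(grads = gr, dX = dX, dHprev = dHprev, dCprev = dCprev)
}

# Initialise the full parameter set: one cell per stacked layer, plus the
# ReLU dense stage and the softmax output layer.
init_params <- function(cfg, features_per_step, n_classes) {
  with_local_seed(cfg$seed, {
    g <- cfg$init_gain
    layers <- lapply(seq_len(cfg$stacked_layers), function(l) {
      D <- if (l == 1) features_per_step else cfg$hidden_units
      H <- cfg$hidden_units
      sx <- g / sqrt(D); sh <- g / sqrt(H)
      # open input/output gates (bias 1) and forget bias 1: with few time
      # steps and a deep stack, near-closed gates at init attenuate the
      # signal to numerical silence before it reaches the softmax head.
      list(Wxi = matrix(runif(H * D, -sx, sx), H, D),
           Whi = matrix(runif(H * H, -sh, sh), H, H),
           Wxf = matrix(runif(H * D, -sx, sx), H, D),
           Whf = matrix(runif(H * H, -sh, sh), H, H),
           Wcf = matrix(runif(H * H, -sh, sh), H, H),
           Wxc = matrix(runif(H * D, -sx, sx), H, D),
           Whc = matrix(runif(H * H, -sh, sh), H, H),
           Wxo = matrix(runif(H * D, -sx, sx), H, D),
           Who = matrix(runif(H * H, -sh, sh), H, H),
           Wco = matrix(runif(H * H, -sh, sh), H, H),
           bi = rep(1, H), bf = rep(1, H),
           bc = numeric(H), bo = rep(1, H))
    })
    H <- cfg$hidden_units; Du <- cfg$dense_units
    list(layers = layers,
         dense = list(W = matrix(runif(Du * H, -1 / sqrt(H), 1 / sqrt(H)), Du, H),
                      b = numeric(Du)),
         out = list(W = matrix(runif(n_classes * Du, -1 / sqrt(Du), 1 / sqrt(Du)),
                               n_classes, Du),
                    b = numeric(n_classes)))
  })
}

# Full forward pass: X is n x p; reshaped to `steps` inputs of width
# p/steps. Returns class probabilities and (optionally) all caches.
forward_pass <- function(params, X, cfg, keep_cache = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  fps <- p %/% cfg$steps
  H <- cfg$hidden_units
  inputs <- lapply(seq_len(cfg$steps), function(t) {
    X[, ((t - 1) * fps + 1):(t * fps), drop = FALSE]
  })
  caches <- vector("list", cfg$stacked_layers)
  for (l in seq_len(cfg$stacked_layers)) {
    h <- matrix(0, n, H); c <- matrix(0, n, H)
    layer_cache <- vector("list", cfg$steps)
    outs <- vector("list", cfg$steps)
    for (t in seq_len(cfg$steps)) {
      st <- cell_forward(inputs[[t]], h, c, params$layers[[l]], cfg$peephole)
      h <- st$h; c <- st$c
      layer_cache[[t]] <- st
      outs[[t]] <- h
    }
    caches[[l]] <- layer_cache
    inputs <- outs
  }
  hT <- inputs[[cfg$steps]]
  ad <- hT %*% t(params$dense$W) +
    matrix(params$dense$b, n, cfg$dense_units, byrow = TRUE)
  z <- pmax(ad, 0)
  logits <- z %*% t(params$out$W) +
    matrix(params$out$b, n, nrow(params$out$W), byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  out <- list(probs = probs)
  if (keep_cache) {
    out$caches <- caches; out$hT <- hT; out$ad <- ad; out$z <- z
  }
  out
}

# Forward + backward over one batch. Y is the n x K one-hot matrix.
# Returns loss (cross-entropy + L2) and gradients in the params layout.
backward_pass <- function(params, X, Y, cfg) {
  fw <- forward_pass(params, X, cfg, keep_cache = TRUE)
  n <- nrow(X)
  eps <- 1e-12
  ce <- -mean(rowSums(Y * log(fw$probs + eps)))
  l2 <- 0
  for (w in params$layers) {
    for (nm in names(w)) if (startsWith(nm, "W")) l2 <- l2 + sum(w[[nm]]^2)
  }
  l2 <- l2 + sum(params$dense$W^2) + sum(params$out$W^2)
  loss <- ce + cfg$l2_lambda * l2

  dlogits <- (fw$probs - Y) / n
  g_out <- list(W = t(dlogits) %*% fw$z + 2 * cfg$l2_lambda * params$out$W,
                b = colSums(dlogits))
  dz <- dlogits %*% params$out$W
  dad <- dz * (fw$ad > 0)
  g_dense <- list(W = t(dad) %*% fw$hT + 2 * cfg$l2_lambda * params$dense$W,
                  b = colSums(dad))
  dhT <- dad %*% params$dense$W

  H <- cfg$hidden_units
  g_layers <- vector("list", cfg$stacked_layers)
  # dOut[[t]]: gradient flowing into layer l's hidden output at step t
  dOut <- rep(list(matrix(0, n, H)), cfg$steps)
  dOut[[cfg$steps]] <- dhT
  for (l in rev(seq_len(cfg$stacked_layers))) {
    w <- params$layers[[l]]
    acc <- lapply(w, function(m) m * 0)
    dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
    dX_steps <- vector("list", cfg$steps)
    for (t in rev(seq_len(cfg$steps))) {
      dh <- dOut[[t]] + dh_next
      bk <- cell_backward(fw$caches[[l]][[t]], w, dh, dc_next, cfg$peephole)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bk$grads[[nm]]
      dh_next <- bk$dHprev; dc_next <- bk$dCprev
      dX_steps[[t]] <- bk$dX
    }
    for (nm in names(acc)) {
      if (startsWith(nm, "W")) acc[[nm]] <- acc[[nm]] + 2 * cfg$l2_lambda * w[[nm]]
    }
    g_layers[[l]] <- acc
    dOut <- dX_steps
  }
  list(loss = loss, ce = ce,
       grads = list(layers = g_layers, dense = g_dense, out = g_out))
}

# One Adam update over the nested parameter list.
adam_update <- function(params, grads, state, lr, t,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd(p, g, m, v)
    }
  }
  walk(params, grads, state$m, state$v)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

#' Train the stacked LSTM classifier
#'
#' Minimises softmax cross-entropy plus an L2 penalty with Adam, by full
#' backpropagation through time over the stacked cells. Training stops when
#' the epoch loss reaches `cfg$loss_target` or after `cfg$max_epochs`.
#' Deterministic given `cfg$seed` on a fixed platform.
#'
#' @param features A [feature_set()] with at least two classes.
#' @param cfg An [lstm_config()]; `cfg$steps` must divide the feature width.
#' @return Object of class `har_lstm`: parameters, config, class levels,
#'   standardisation statistics and a `history` data.frame (epoch, loss,
#'   accuracy).
#' @export
train_lstm <- function(features, cfg = lstm_config()) {
  stopifnot(inherits(features, "feature_set"), inherits(cfg, "lstm_config"))
  n <- nrow(features$features)
  if (n == 0) stop_bad_arg("empty feature set")
  classes <- levels(droplevels(features$labels))
  if (length(classes) < 2) {
    stop_bad_arg("training requires at least 2 classes, got ", length(classes))
  }
  p <- ncol(features$features)
  if (p %% cfg$steps != 0) {
    stop_bad_arg("steps (", cfg$steps, ") must divide feature length (", p, ")")
  }
  X <- transform_features(features$features, cfg$feature_transform)
  scaling <- NULL
  if (cfg$standardize) {
    mu <- colMeans(X)
    s <- apply(X, 2, sd)
    s[s == 0 | !is.finite(s)] <- 1
    X <- sweep(sweep(X, 2, mu), 2, s, "/")
    scaling <- list(mu = mu, sd = s)
  }
  y <- factor(as.character(features$labels), levels = classes)
  Y <- matrix(0, n, length(classes))
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  params <- init_params(cfg, p %/% cfg$steps, length(classes))
  model <- structure(
    list(params = params, cfg = cfg, classes = classes, scaling = scaling,
         history = data.frame(epoch = integer(0), loss = numeric(0),
                              accuracy = numeric(0))),
    class = "har_lstm"
  )
  if (cfg$max_epochs == 0) return(model)

  batch <- min(cfg$mini_batch_size, n)
  state <- list(m = zero_like(params), v = zero_like(params))
  step <- 0
  history <- vector("list", cfg$max_epochs)
  order_seed <- derive_seed(cfg$seed, 7919L)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- if (batch < n) {
      with_local_seed(derive_seed(order_seed, epoch), sample.int(n))
    } else seq_len(n)
    losses <- c(); accs <- c(); ws <- c()
    for (b0 in seq.int(1L, n, by = batch)) {
      rows <- idx[b0:min(b0 + batch - 1L, n)]
      bp <- backward_pass(params, X[rows, , drop = FALSE],
                          Y[rows, , drop = FALSE], cfg)
      step <- step + 1
      r <- adam_update(params, bp$grads, state, cfg$learning_rate, step)
      params <- r$p; state <- list(m = r$m, v = r$v)
      losses <- c(losses, bp$loss); ws <- c(ws, length(rows))
    }
    fw <- forward_pass(params, X, cfg)
    acc <- mean(max.col(fw$probs, ties.method = "first") == as.integer(y))
    epoch_loss <- sum(losses * ws) / sum(ws)
    history[[epoch]] <- data.frame(epoch = epoch, loss = epoch_loss,
                                   accuracy = acc)
    if (epoch_loss <= cfg$loss_target) break
  }
  model$params <- params
  model$history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  model
}

#' Predict activity labels or class probabilities
#'
#' @param object A `har_lstm` model from [train_lstm()].
#' @param newdata A [feature_set()] or numeric matrix with the training
#'   feature width.
#' @param type `"class"` (default) for labels (argmax of the softmax,
#'   ties broken towards the lowest class index) or `"prob"` for the
#'   probability matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or an n x K probability matrix.
#' @export
predict.har_lstm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_set")) newdata$features else
    as.matrix(newdata)
  p_train <- ncol(object$params$layers[[1]]$Wxi) * object$cfg$steps
  if (ncol(X) != p_train) {
    stop_bad_arg("feature width ", ncol(X), " does not match the model (",
                 p_train, ")")
  }
  X <- transform_features(X, object$cfg$feature_transform)
  if (!is.null(object$scaling)) {
    X <- sweep(sweep(X, 2, object$scaling$mu), 2, object$scaling$sd, "/")
  }
  fw <- forward_pass(object$params, X, object$cfg)
  colnames(fw$probs) <- object$classes
  if (type == "prob") return(fw$probs)
  factor(object$classes[max.col(fw$probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.har_lstm <- function(x, ...) {
  tr <- if (nrow(x$history)) {
    sprintf("trained %d epochs, final loss %.4g, train acc %.1f%%",
            max(x$history$epoch), tail(x$history$loss, 1),
            100 * tail(x$history$accuracy, 1))
  } else "untrained"
  cat(sprintf("<har_lstm> %d x %d-unit layers (%s cells), classes %s; %s\n",
              x$cfg$stacked_layers, x$cfg$hidden_units,
              if (x$cfg$peephole) "peephole" else "standard",
              paste(x$classes, collapse = "/"), tr))
  invisible(x)
}

#' Save / load a trained model as a JSON checkpoint
#'
#' The checkpoint is a single text file echoing the full configuration,
#' class levels, scaling statistics and all weights at full precision.
#'
#' @param model A `har_lstm`.
#' @param path Output file path.
#' @return `save_lstm` returns `path` invisibly; `load_lstm` the model.
#' @export
save_lstm <- function(model, path) {
  stopifnot(inherits(model, "har_lstm"))
  jsonlite::write_json(
    list(cfg = unclass(model$cfg), classes = model$classes,
         scaling = model$scaling, params = model$params,
         history = model$history),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname save_lstm
#' @export
load_lstm <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- do.call(lstm_config,
                 raw$cfg[names(raw$cfg) %in% names(formals(lstm_config))])
  params <- raw$params
  params$layers <- lapply(params$layers, function(w) {
    for (nm in names(w)) {
      w[[nm]] <- if (startsWith(nm, "W")) as.matrix(w[[nm]])
                 else as.numeric(w[[nm]])
    }
    w
  })
  params$dense <- list(W = as.matrix(params$dense$W),
                       b = as.numeric(params$dense$b))
  params$out <- list(W = as.matrix(params$out$W),
                     b = as.numeric(params$out$b))
  scaling <- if (is.null(raw$scaling)) NULL else
    list(mu = as.numeric(raw$scaling$mu), sd = as.numeric(raw$scaling$sd))
  structure(list(params = params, cfg = cfg, classes = raw$classes,
                 scaling = scaling,
                 history = as.data.frame(raw$history)),
            class = "har_lstm")
}
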