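# Stacked auto-encoder: greedy layerwise pretraining of single-hidden-layer
# auto-encoders; the narrowest (bottleneck) layer output is the embedding.

activation_registry <- list(
  sigmoid = list(
    fn = function(a) 1 / (1 + exp(-a)),
    grad = function(a, y) y * (1 - y)   # derivative in terms of the output
  ),
  linear = list(
    fn = function(a) a,
    grad = function(a, y) 1
  ),
  relu = list(
    fn = function(a) pmax(a, 0),
    grad = function(a, y) (a > 0) * 1
  )
)

get_activation <- function(name) {
  act <- activation_registry[[name]]
  if (is.null(act)) {
    stop_ctx("unknown activation '%s'; available: %s", name,
             paste(names(activation_registry), collapse = ", "))
  }
  act
}

#' Construct a single auto-encoder layer
#'
#' An auto-encoder layer encodes with y = f(W x + b) and decodes with
#' z = g(W~ y + b~), where f and g are elementwise activations.
#'
#' @param W encoder weights, hidden x input matrix.
#' @param b encoder bias, length hidden.
#' @param W_tilde decoder weights, input x hidden matrix.
#' @param b_tilde decoder bias, length input.
#' @param f,g encoder/decoder activation names: `"sigmoid"`, `"linear"` or
#'   `"relu"`.
#' @return An object of class `ae_layer`.
#' @export
ae_layer <- function(W, b, W_tilde, b_tilde, f = "sigmoid", g = "linear") {
  W <- as.matrix(W); W_tilde <- as.matrix(W_tilde)
  b <- as.numeric(b); b_tilde <- as.numeric(b_tilde)
  if (nrow(W) != length(b)) stop_ctx("ae_layer: W (%d rows) and b (%d) disagree", nrow(W), length(b))
  if (nrow(W_tilde) != ncol(W) || ncol(W_tilde) != nrow(W)) {
    stop_ctx("ae_layer: decoder shape (%d x %d) is not the transpose shape of encoder (%d x %d)",
             nrow(W_tilde), ncol(W_tilde), nrow(W), ncol(W))
  }
  if (nrow(W_tilde) != length(b_tilde)) {
    stop_ctx("ae_layer: W_tilde (%d rows) and b_tilde (%d) disagree", nrow(W_tilde), length(b_tilde))
  }
  get_activation(f); get_activation(g)
  structure(list(W = W, b = b, W_tilde = W_tilde, b_tilde = b_tilde, f = f, g = g),
            class = "ae_layer")
}

#' Encode through one auto-encoder layer
#'
#' Computes y = f(W x + b). Accepts a single vector or a matrix with one
#' sample per row.
#'
#' @param x numeric vector of length d, or an n x d matrix.
#' @param layer an [ae_layer()].
#' @return The hidden representation (vector, or n x h matrix).
#' @export
encode <- function(x, layer) {
  stopifnot(inherits(layer, "ae_layer"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != ncol(layer$W)) {
    stop_ctx("encode: input dimension %d does not match layer input %d",
             ncol(X), ncol(layer$W))
  }
  A <- sweep(X %*% t(layer$W), 2, layer$b, "+")
  Y <- get_activation(layer$f)$fn(A)
  if (vec) drop(Y) else Y
}

#' Decode through one auto-encoder layer
#'
#' Computes z = g(W~ y + b~), the mirror of [encode()].
#'
#' @param y numeric vector of length h, or an n x h matrix.
#' @param layer an [ae_layer()].
#' @return The reconstruction (vector, or n x d matrix).
#' @export
decode <- function(y, layer) {
  stopifnot(inherits(layer, "ae_layer"))
  vec <- is.null(dim(y))
  Y <- if (vec) matrix(y, nrow = 1) else as.matrix(y)
  if (ncol(Y) != ncol(layer$W_tilde)) {
    stop_ctx("decode: input dimension %d does not match layer hidden size %d",
             ncol(Y), ncol(layer$W_tilde))
  }
  A <- sweep(Y %*% t(layer$W_tilde), 2, layer$b_tilde, "+")
  Z <- get_activation(layer$g)$fn(A)
  if (vec) drop(Z) else Z
}

#' Reconstruction losses
#'
#' `mse_loss` is the squared Euclidean norm ||x - z||^2 used with real-valued
#' inputs; `xent_loss` is the summed binary cross-entropy used when the input
#' is a bit vector, with the reconstruction clipped into (0, 1).
#'
#' @param x input vector (binary for `xent_loss`).
#' @param z reconstruction vector.
#' @param eps clipping bound keeping the logarithms finite.
#' @return A single non-negative number.
#' @export
mse_loss <- function(x, z) {
  if (length(x) != length(z)) stop_ctx("mse_loss: length mismatch (%d vs %d)", length(x), length(z))
  sum((x - z)^2)
}

#' @rdname mse_loss
#' @export
xent_loss <- function(x, z, eps = 1e-7) {
  if (length(x) != length(z)) stop_ctx("xent_loss: length mismatch (%d vs %d)", length(x), length(z))
  if (any(x != 0 & x != 1)) stop_ctx("xent_loss: x must be a 0/1 vector")
  z <- pmin(pmax(z, eps), 1 - eps)
  -sum(x * log(z) + (1 - x) * log(1 - z))
}

#' Training settings for the stacked auto-encoder
#'
#' Defaults follow the training protocol of the framework: 100 epochs,
#' minibatches of 100, the adadelta optimizer with mean-square reconstruction
#' loss, and a 70/30 train/validation row split used only for early stopping.
#' Training halts early once the validation reconstruction error has failed
#' to improve on its running minimum by at least `min_delta` for `patience`
#' consecutive epochs.
#'
#' @param nb_epoch maximum number of epochs (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param optimizer `"adadelta"` (decay `rho`, stabilizer `epsilon`),
#'   `"sgd"` (learning rate `lr`) or `"adam"` (`lr`, `beta1`, `beta2`,
#'   `epsilon`).
#' @param loss `"mean_square"` or `"cross_entropy"` (the latter requires 0/1
#'   inputs and a sigmoid decoder).
#' @param training_ratio,validation_ratio row fractions for the early-stopping
#'   split; must sum to 1.
#' @param patience,min_delta early-stopping tolerance (epochs, loss units).
#' @param lr,rho,epsilon,beta1,beta2 optimizer hyperparameters (canonical
#'   defaults).
#' @param seed integer seed making training deterministic.
#' @return A list of class `sae_control`.
#' @export
sae_control <- function(nb_epoch = 100, batch_size = 100,
                        optimizer = c("adadelta", "sgd", "adam"),
                        loss = c("mean_square", "cross_entropy"),
                        training_ratio = 0.7, validation_ratio = 0.3,
                        patience = 5, min_delta = 1e-4,
                        lr = 1.0, rho = 0.95, epsilon = 1e-6,
                        beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  if (nb_epoch < 1 || batch_size < 1) stop_ctx("sae_control: nb_epoch and batch_size must be >= 1")
  if (abs(training_ratio + validation_ratio - 1) > 1e-12) {
    stop_ctx("sae_control: training_ratio + validation_ratio must equal 1")
  }
  structure(list(nb_epoch = as.integer(nb_epoch), batch_size = as.integer(batch_size),
                 optimizer = optimizer, loss = loss,
                 training_ratio = training_ratio, validation_ratio = validation_ratio,
                 patience = as.integer(patience), min_delta = min_delta,
                 lr = lr, rho = rho, epsilon = epsilon,
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed)),
            class = "sae_control")
}

# one optimizer step for a list of parameter gradients; state is mutated copy
make_optimizer <- function(control, shapes) {
  zeros <- lapply(shapes, function(s) array(0, dim = s))
  if (control$optimizer == "sgd") {
    state <- list()
    step <- function(params, grads, state) {
      for (k in names(params)) params[[k]] <- params[[k]] - control$lr * grads[[k]]
      list(params = params, state = state)
    }
  } else if (control$optimizer == "adadelta") {
    state <- list(Eg = zeros, Ex = zeros)
    step <- function(params, grads, state) {
      for (k in names(params)) {
        g <- grads[[k]]
        state$Eg[[k]] <- control$rho * state$Eg[[k]] + (1 - control$rho) * g^2
        dx <- -sqrt(state$Ex[[k]] + control$epsilon) /
          sqrt(state$Eg[[k]] + control$epsilon) * g
        state$Ex[[k]] <- control$rho * state$Ex[[k]] + (1 - control$rho) * dx^2
        params[[k]] <- params[[k]] + control$lr * dx
      }
      list(params = params, state = state)
    }
  } else { # adam
    state <- list(m = zeros, v = zeros, t = 0)
    step <- function(params, grads, state) {
      state$t <- state$t + 1
      for (k in names(params)) {
        g <- grads[[k]]
        state$m[[k]] <- control$beta1 * state$m[[k]] + (1 - control$beta1) * g
        state$v[[k]] <- control$beta2 * state$v[[k]] + (1 - control$beta2) * g^2
        mhat <- state$m[[k]] / (1 - control$beta1^state$t)
        vhat <- state$v[[k]] / (1 - control$beta2^state$t)
        params[[k]] <- params[[k]] - control$lr * mhat / (sqrt(vhat) + control$epsilon)
      }
      list(params = params, state = state)
    }
  }
  list(step = step, state = state)
}

glorot_init <- function(n_out, n_in) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -limit, limit), nrow = n_out)
}

# mean per-row reconstruction loss of a single AE parameter set
ae_recon_error <- function(X, params, f, g, loss, eps = 1e-7) {
  Y <- get_activation(f)$fn(sweep(X %*% t(params$W), 2, params$b, "+"))
  Z <- get_activation(g)$fn(sweep(Y %*% t(params$W_tilde), 2, params$b_tilde, "+"))
  if (loss == "mean_square") {
    sum((X - Z)^2) / nrow(X)
  } else {
    Z <- pmin(pmax(Z, eps), 1 - eps)
    -sum(X * log(Z) + (1 - X) * log(1 - Z)) / nrow(X)
  }
}

# Train one auto-encoder (input X, hidden size h) by minibatch gradient
# descent; returns layer parameters and the per-epoch error log.
train_single_ae <- function(X, hidden, control, f, g) {
  n <- nrow(X); d <- ncol(X)
  params <- list(
    W = glorot_init(hidden, d), b = numeric(hidden),
    W_tilde = glorot_init(d, hidden), b_tilde = numeric(d)
  )
  opt <- make_optimizer(control, lapply(params, function(p) dim(p) %||% length(p)))
  state <- opt$state
  n_train <- max(1L, round_half_up(control$training_ratio * n))
  perm <- sample.int(n)
  tr <- perm[seq_len(n_train)]
  va <- if (n_train < n) perm[(n_train + 1L):n] else tr
  Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]
  fa <- get_activation(f); ga <- get_activation(g)

  log <- data.frame(epoch = integer(0), train_error = numeric(0),
                    val_error = numeric(0))
  best_val <- Inf; stall <- 0L
  for (epoch in seq_len(control$nb_epoch)) {
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1L, nrow(Xtr), by = control$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + control$batch_size - 1L, nrow(Xtr))]
      B <- Xtr[idx, , drop = FALSE]
      m <- nrow(B)
      A1 <- sweep(B %*% t(params$W), 2, params$b, "+")
      Y <- fa$fn(A1)
      A2 <- sweep(Y %*% t(params$W_tilde), 2, params$b_tilde, "+")
      Z <- ga$fn(A2)
      if (control$loss == "mean_square") {
        dZ <- 2 * (Z - B) / m
      } else {
        Zc <- pmin(pmax(Z, 1e-7), 1 - 1e-7)
        dZ <- (Zc - B) / (Zc * (1 - Zc)) / m
      }
      dA2 <- dZ * ga$grad(A2, Z)
      gW_tilde <- t(dA2) %*% Y
      gb_tilde <- colSums(dA2)
      dY <- dA2 %*% params$W_tilde
      dA1 <- dY * fa$grad(A1, Y)
      gW <- t(dA1) %*% B
      gb <- colSums(dA1)
      upd <- opt$step(params,
                      list(W = gW, b = gb, W_tilde = gW_tilde, b_tilde = gb_tilde),
                      state)
      params <- upd$params; state <- upd$state
    }
    tr_err <- ae_recon_error(Xtr, params, f, g, control$loss)
    va_err <- ae_recon_error(Xva, params, f, g, control$loss)
    log <- rbind(log, data.frame(epoch = epoch, train_error = tr_err,
                                 val_error = va_err))
    if (!is.finite(tr_err) || !is.finite(va_err)) {
      warning("auto-encoder training diverged (non-finite reconstruction error); ",
              "stopping — consider a smaller learning rate", call. = FALSE)
      break
    }
    if (va_err < best_val - control$min_delta) {
      best_val <- va_err
      stall <- 0L
    } else {
      best_val <- min(best_val, va_err)
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }
  list(params = params, log = log)
}

#' Train a stacked auto-encoder
#'
#' Auto-encoders are trained greedily layer by layer: the hidden output of
#' each trained auto-encoder becomes the input of the next, down to the
#' bottleneck in the middle of the (palindromic) size list. The bottleneck
#' output is the embedded representation used downstream; see
#' [predict.sae()]. The default architecture for the protein problem is
#' `c(d, 140, 10, 140, d)`, giving a 10-dimensional embedding.
#'
#' An optional joint fine-tuning pass (full encoder/decoder stack trained
#' end-to-end on the reconstruction loss) is available but off by default:
#' the embedding is taken directly from the greedily trained stack.
#'
#' @param x a [feature_matrix()] or a plain numeric matrix (rows = samples).
#' @param sizes integer vector of layer widths; must be palindromic and start
#'   at `ncol(x)`. Default `c(d, 140, 10, 140, d)`.
#' @param control a [sae_control()].
#' @param hidden_activation,output_activation activations for hidden layers
#'   and for the final reconstruction layer. The defaults (sigmoid hidden,
#'   linear output) suit z-scored inputs, which can be negative.
#' @param fine_tune if `TRUE`, run a joint end-to-end fine-tuning pass after
#'   greedy pretraining.
#' @return An object of class `sae` with elements `layers` (list of
#'   [ae_layer()]), `layer_sizes`, `bottleneck_index`, `training_log` and
#'   `control`.
#' @seealso [predict.sae()], [write_sae()]
#' @export
sae <- function(x, sizes = NULL, control = sae_control(),
                hidden_activation = "sigmoid", output_activation = "linear",
                fine_tune = FALSE) {
  X <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (nrow(X) == 0) stop_ctx("sae: empty input")
  d <- ncol(X)
  if (is.null(sizes)) sizes <- c(d, 140L, 10L, 140L, d)
  sizes <- as.integer(sizes)
  k <- length(sizes)
  if (k < 3 || k %% 2 == 0) stop_ctx("sae: sizes must have odd length >= 3")
  if (!identical(sizes, rev(sizes))) stop_ctx("sae: sizes must be palindromic around the bottleneck")
  if (sizes[1] != d) stop_ctx("sae: sizes[1] (%d) must equal the feature dimension (%d)", sizes[1], d)
  n_ae <- (k - 1L) %/% 2L
  bottleneck <- n_ae + 1L

  layers <- vector("list", n_ae)
  logs <- vector("list", n_ae)
  with_seed(control$seed, {
    input <- X
    for (i in seq_len(n_ae)) {
      g_i <- if (i == 1L) output_activation else hidden_activation
      fit <- train_single_ae(input, sizes[i + 1L], control,
                             f = hidden_activation, g = g_i)
      layers[[i]] <- ae_layer(fit$params$W, fit$params$b,
                              fit$params$W_tilde, fit$params$b_tilde,
                              f = hidden_activation, g = g_i)
      logs[[i]] <- cbind(ae = i, fit$log)
      input <- encode(input, layers[[i]])
    }
    if (fine_tune) {
      ft <- fine_tune_stack(X, layers, control)
      layers <- ft$layers
      logs[[length(logs) + 1L]] <- cbind(ae = NA_integer_, ft$log)
    }
  })

  structure(list(layers = layers, layer_sizes = sizes,
                 bottleneck_index = bottleneck,
                 training_log = do.call(rbind, logs),
                 control = control,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 fine_tuned = fine_tune),
            class = "sae")
}

# Joint end-to-end fine-tuning of the stacked encoder/decoder on the
# reconstruction loss (mean-square), full stack backprop.
fine_tune_stack <- function(X, layers, control) {
  n_ae <- length(layers)
  # parameter list: encoder 1..n_ae then decoders n_ae..1
  n <- nrow(X)
  n_train <- max(1L, round_half_up(control$training_ratio * n))
  perm <- sample.int(n)
  tr <- perm[seq_len(n_train)]
  va <- if (n_train < n) perm[(n_train + 1L):n] else tr
  Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]

  shapes <- list()
  params <- list()
  for (i in seq_len(n_ae)) {
    params[[paste0("W", i)]] <- layers[[i]]$W
    params[[paste0("b", i)]] <- layers[[i]]$b
    params[[paste0("Wt", i)]] <- layers[[i]]$W_tilde
    params[[paste0("bt", i)]] <- layers[[i]]$b_tilde
  }
  opt <- make_optimizer(control, lapply(params, function(p) dim(p) %||% length(p)))
  state <- opt$state

  forward <- function(B, params) {
    acts <- list(list(Y = B))
    # encoder chain
    for (i in seq_len(n_ae)) {
      f <- get_activation(layers[[i]]$f)
      A <- sweep(acts[[length(acts)]]$Y %*% t(params[[paste0("W", i)]]), 2,
                 params[[paste0("b", i)]], "+")
      acts[[length(acts) + 1L]] <- list(A = A, Y = f$fn(A), act = layers[[i]]$f)
    }
    # decoder chain, innermost first
    for (i in rev(seq_len(n_ae))) {
      g <- get_activation(layers[[i]]$g)
      A <- sweep(acts[[length(acts)]]$Y %*% t(params[[paste0("Wt", i)]]), 2,
                 params[[paste0("bt", i)]], "+")
      acts[[length(acts) + 1L]] <- list(A = A, Y = g$fn(A), act = layers[[i]]$g)
    }
    acts
  }
  recon_err <- function(Xs, params) {
    acts <- forward(Xs, params)
    sum((Xs - acts[[length(acts)]]$Y)^2) / nrow(Xs)
  }

  log <- data.frame(epoch = integer(0), train_error = numeric(0),
                    val_error = numeric(0))
  best_val <- Inf; stall <- 0L
  for (epoch in seq_len(control$nb_epoch)) {
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1L, nrow(Xtr), by = control$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + control$batch_size - 1L, nrow(Xtr))]
      B <- Xtr[idx, , drop = FALSE]
      m <- nrow(B)
      acts <- forward(B, params)
      grads <- params; for (k in names(grads)) grads[[k]][] <- 0
      # backprop through decoder chain then encoder chain
      delta <- 2 * (acts[[length(acts)]]$Y - B) / m
      pos <- length(acts)
      # decoders were applied innermost-first (n_ae..1), so walking the
      # computation graph backwards visits decoder 1 first
      for (i in seq_len(n_ae)) {
        lay <- acts[[pos]]
        g <- get_activation(lay$act)
        dA <- delta * g$grad(lay$A, lay$Y)
        below <- acts[[pos - 1L]]$Y
        key <- paste0("Wt", i)
        grads[[key]] <- grads[[key]] + t(dA) %*% below
        kb <- paste0("bt", i)
        grads[[kb]] <- grads[[kb]] + colSums(dA)
        delta <- dA %*% params[[key]]
        pos <- pos - 1L
      }
      for (i in rev(seq_len(n_ae))) {
        lay <- acts[[pos]]
        f <- get_activation(lay$act)
        dA <- delta * f$grad(lay$A, lay$Y)
        below <- acts[[pos - 1L]]$Y
        key <- paste0("W", i)
        grads[[key]] <- grads[[key]] + t(dA) %*% below
        kb <- paste0("b", i)
        grads[[kb]] <- grads[[kb]] + colSums(dA)
        delta <- dA %*% params[[key]]
        pos <- pos - 1L
      }
      upd <- opt$step(params, grads, state)
      params <- upd$params; state <- upd$state
    }
    tr_err <- recon_err(Xtr, params)
    va_err <- recon_err(Xva, params)
    log <- rbind(log, data.frame(epoch = epoch, train_error = tr_err,
                                 val_error = va_err))
    if (!is.finite(tr_err) || !is.finite(va_err)) break
    if (va_err < best_val - control$min_delta) {
      best_val <- va_err; stall <- 0L
    } else {
      best_val <- min(best_val, va_err)
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }
  for (i in seq_len(n_ae)) {
    layers[[i]] <- ae_layer(params[[paste0("W", i)]], params[[paste0("b", i)]],
                            params[[paste0("Wt", i)]], params[[paste0("bt", i)]],
                            f = layers[[i]]$f, g = layers[[i]]$g)
  }
  list(layers = layers, log = log)
}

#' @export
print.sae <- function(x, ...) {
  cat(sprintf("Stacked auto-encoder: layers %s (bottleneck %d units)\n",
              paste(x$layer_sizes, collapse = "-"),
              x$layer_sizes[x$bottleneck_index]))
  cat(sprintf("  %d auto-encoder(s), activations %s/%s, %strained for %d logged epochs\n",
              length(x$layers), x$hidden_activation, x$output_activation,
              if (x$fine_tuned) "fine-tuned, " else "",
              nrow(x$training_log)))
  invisible(x)
}

#' @export
summary.sae <- function(object, ...) {
  log <- object$training_log
  per_ae <- do.call(rbind, lapply(split(log, log$ae), function(d) {
    data.frame(ae = d$ae[1], epochs = nrow(d),
               final_train_error = d$train_error[nrow(d)],
               final_val_error = d$val_error[nrow(d)])
  }))
  structure(list(layer_sizes = object$layer_sizes, per_ae = per_ae),
            class = "summary.sae")
}

#' @export
print.summary.sae <- function(x, ...) {
  cat(sprintf("SAE %s\n", paste(x$layer_sizes, collapse = "-")))
  print(x$per_ae, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sae <- function(x, ...) {
  log <- x$training_log
  graphics::plot(log$epoch, log$train_error, type = "n",
                 xlab = "epoch", ylab = "reconstruction error",
                 main = "SAE training curves", ...)
  for (a in unique(log$ae)) {
    d <- log[log$ae %in% a, ]
    graphics::lines(d$epoch, d$train_error, lty = 1, col = a)
    graphics::lines(d$epoch, d$val_error, lty = 2, col = a)
  }
  graphics::legend("topright", legend = c("train", "validation"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' Embed data through the bottleneck of a trained stacked auto-encoder
#'
#' Rows are mapped through the encoder half of the stack up to the bottleneck
#' layer; the result is the low-dimensional embedded representation
#' (10-dimensional under the default architecture).
#'
#' @param object a fitted [sae()].
#' @param x a [feature_matrix()] or numeric matrix with `ncol` equal to the
#'   model's input width.
#' @param ... unused.
#' @return If `x` is a `feature_matrix`, a `feature_matrix` of embedded
#'   values with ids and labels carried through; otherwise a plain matrix.
#' @export
predict.sae <- function(object, x, ...) {
  fm <- inherits(x, "feature_matrix")
  X <- if (fm) x$values else as.matrix(x)
  if (ncol(X) != object$layer_sizes[1]) {
    stop_ctx("predict.sae: input has %d columns; model expects %d",
             ncol(X), object$layer_sizes[1])
  }
  for (layer in object$layers) X <- encode(X, layer)
  colnames(X) <- paste0("sae_dim_", seq_len(ncol(X)))
  if (!fm) return(X)
  feature_matrix(X,
                 data.frame(property = "sae_embedding",
                            component = colnames(X), stringsAsFactors = FALSE),
                 x$row_ids, x$row_labels)
}

#' Serialize a stacked auto-encoder to JSON
#'
#' Stores layer sizes, activations, all weight arrays and the training log in
#' a documented plain-text structure; [read_sae()] restores it bit-exactly
#' within double-precision printing limits (`digits = NA` keeps full
#' precision).
#'
#' @param model a fitted [sae()].
#' @param path output path.
#' @return `path` (write) or an `sae` object (read).
#' @export
write_sae <- function(model, path) {
  stopifnot(inherits(model, "sae"))
  payload <- list(
    layer_sizes = model$layer_sizes,
    bottleneck_index = model$bottleneck_index,
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    fine_tuned = model$fine_tuned,
    layers = lapply(model$layers, function(l) {
      list(W = l$W, b = l$b, W_tilde = l$W_tilde, b_tilde = l$b_tilde,
           f = l$f, g = l$g)
    }),
    training_log = model$training_log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sae
#' @export
read_sae <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(length(p$layers$f)), function(i) {
    ae_layer(p$layers$W[[i]], p$layers$b[[i]],
             p$layers$W_tilde[[i]], p$layers$b_tilde[[i]],
             f = p$layers$f[i], g = p$layers$g[i])
  })
  structure(list(layers = layers, layer_sizes = as.integer(p$layer_sizes),
                 bottleneck_index = as.integer(p$bottleneck_index),
                 training_log = as.data.frame(p$training_log),
                 control = NULL,
                 hidden_activation = p$hidden_activation,
                 output_activation = p$output_activation,
                 fine_tuned = isTRUE(p$fine_tuned)),
            class = "sae")
}
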