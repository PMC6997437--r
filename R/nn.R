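# Internal dense-network primitives shared by the multimodal autoencoder and
# the pair classifier: layer init, forward/backward passes, inverted dropout,
# and the momentum SGD update. Everything is plain matrix algebra so that
# training is deterministic given a seed and gradients are checkable against
# finite differences.

sigmoid <- function(z) 1 / (1 + exp(-z))
relu <- function(z) pmax(z, 0)

act_fun <- function(name) switch(name, sigmoid = sigmoid, relu = relu,
                                 stop("unknown activation: ", name))

# derivative of the activation expressed via its OUTPUT a
act_grad <- function(name, a) {
  switch(name,
         sigmoid = a * (1 - a),
         relu = (a > 0) * 1,
         stop("unknown activation: ", name))
}

# Uniform fan-scaled init (Glorot-style); caller controls the RNG seed.
dense_init <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out),
       b = rep(0, n_out))
}

# affine transform for a batch X (rows = samples)
dense_forward <- function(layer, x) {
  sweep(x %*% layer$W, 2, layer$b, `+`)
}

# Forward pass through a chain of layers. acts: activation name per layer.
# dropout_p > 0 applies inverted dropout to every layer output except the
# last (training mode only). Returns activations (incl. input) and masks.
mlp_forward <- function(layers, acts, x, dropout_p = 0, training = FALSE) {
  n <- length(layers)
  a <- vector("list", n + 1L)
  masks <- vector("list", n)
  a[[1L]] <- x
  for (l in seq_len(n)) {
    h <- act_fun(acts[l])(dense_forward(layers[[l]], a[[l]]))
    if (training && dropout_p > 0 && l < n) {
      keep <- 1 - dropout_p
      mask <- matrix(stats::runif(length(h)) < keep, nrow(h), ncol(h)) / keep
      h <- h * mask
      masks[[l]] <- mask
    }
    a[[l + 1L]] <- h
  }
  list(a = a, masks = masks)
}

# Backward pass given delta at the LAST layer's pre-activation (dL/dz_n).
# Returns per-layer gradients and (optionally) delta wrt the chain input.
mlp_backward <- function(layers, acts, fwd, delta_z, input_grad = FALSE) {
  n <- length(layers)
  grads <- vector("list", n)
  for (l in rev(seq_len(n))) {
    grads[[l]] <- list(W = crossprod(fwd$a[[l]], delta_z),
                       b = colSums(delta_z))
    if (l > 1L || input_grad) {
      delta_a <- delta_z %*% t(layers[[l]]$W)
      if (l > 1L) {
        if (!is.null(fwd$masks[[l - 1L]])) delta_a <- delta_a * fwd$masks[[l - 1L]]
        delta_z <- delta_a * act_grad(acts[l - 1L], fwd$a[[l]])
      } else {
        return(list(grads = grads, delta_input = delta_a))
      }
    }
  }
  list(grads = grads, delta_input = NULL)
}

# velocity-accumulating momentum SGD: v <- momentum*v - lr*g; w <- w + v
sgd_update <- function(layers, grads, state, lr, momentum) {
  if (is.null(state)) {
    state <- lapply(layers, function(l)
      list(W = matrix(0, nrow(l$W), ncol(l$W)), b = rep(0, length(l$b))))
  }
  for (l in seq_along(layers)) {
    state[[l]]$W <- momentum * state[[l]]$W - lr * grads[[l]]$W
    state[[l]]$b <- momentum * state[[l]]$b - lr * grads[[l]]$b
    layers[[l]]$W <- layers[[l]]$W + state[[l]]$W
    layers[[l]]$b <- layers[[l]]$b + state[[l]]$b
  }
  list(layers = layers, state = state)
}

# element-mean binary cross-entropy, clipped away from log(0)
bce_loss <- function(y, a) {
  eps <- 1e-12
  a <- pmin(pmax(a, eps), 1 - eps)
  -mean(y * log(a) + (1 - y) * log(1 - a))
}

minibatches <- function(n, batch_size, shuffle_order) {
  split(shuffle_order, ceiling(seq_along(shuffle_order) / batch_size))
}
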