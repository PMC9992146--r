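# Minimal dense-network machinery (He init, ReLU, Adam) shared by the
# reference quantifier. Inputs are row-major matrices (samples x features).

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    layers <- vector("list", length(sizes) - 1)
    for (i in seq_along(layers)) {
      fan_in <- sizes[i]
      layers[[i]] <- list(
        W = matrix(rnorm(fan_in * sizes[i + 1], 0, sqrt(2 / fan_in)),
                   fan_in, sizes[i + 1]),
        b = rep(0, sizes[i + 1]))
    }
    layers
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (i in seq_along(layers)) {
    z <- acts[[i]] %*% layers[[i]]$W
    z <- sweep(z, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else z
  }
  acts
}

mlp_predict <- function(layers, X) {
  mlp_forward(layers, X)[[length(layers) + 1]]
}

# MSE loss gradient backprop; returns list of dW, db per layer
mlp_backward <- function(layers, acts) {
  n <- nrow(acts[[1]])
  grads <- vector("list", length(layers))
  delta <- NULL
  for (i in rev(seq_along(layers))) {
    if (i == length(layers)) {
      delta <- acts$delta_out
    } else {
      delta <- (delta %*% t(layers[[i + 1]]$W)) * (acts[[i + 1]] > 0)
    }
    grads[[i]] <- list(dW = crossprod(acts[[i]], delta) / n,
                       db = colSums(delta) / n)
  }
  grads
}

adam_state <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      gnm <- paste0("d", nm)
      r <- walk(params[[i]][[nm]], grads[[i]][[gnm]],
                state$m[[i]][[nm]], state$v[[i]][[nm]])
      params[[i]][[nm]] <- r$p
      state$m[[i]][[nm]] <- r$m
      state$v[[i]][[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

mlp_adam_state <- function(layers) {
  zero <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  list(m = zero, v = zero)
}
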