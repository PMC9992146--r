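# Convolutional layer machinery for the conditional GAN: thin R wrappers
# over the GEMM-based C++ conv primitives, plus activations, nearest
# upsampling and Adam over lists of kernels. One image at a time, batch
# accumulation in the training loop.

conv_layer <- function(in_ch, out_ch, k = 3, stride = 1, act = "relu") {
  fan_in <- k * k * in_ch
  list(W = matrix(rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)), fan_in,
                  out_ch),
       b = rep(0, out_ch), k = k, stride = stride, pad = (k - 1) %/% 2,
       act = act, in_ch = in_ch, out_ch = out_ch)
}

act_fw <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         lrelu = pmax(z, 0) + 0.2 * pmin(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

act_bw <- function(dz_post, z, a, act) {
  switch(act,
         relu = dz_post * (z > 0),
         lrelu = dz_post * (0.2 + 0.8 * (z > 0)),
         sigmoid = dz_post * a * (1 - a),
         linear = dz_post)
}

conv_fw <- function(x, ly) {
  z <- .conv2d_fw_cpp(x, ly$W, ly$b, ly$k, ly$k, ly$stride, ly$pad)
  list(x = x, z = z, a = act_fw(z, ly$act))
}

conv_bw <- function(cache, ly, da, need_dx = TRUE) {
  dz <- act_bw(da, cache$z, cache$a, ly$act)
  g <- .conv2d_bw_cpp(cache$x, ly$W, dz, ly$k, ly$k, ly$stride, ly$pad,
                      need_dx)
  list(dx = g$dx, dW = g$dw, db = as.numeric(g$db))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  h <- d[1] / 2; w <- d[2] / 2
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2)
  dy[o1, o2, , drop = FALSE] + dy[o1 + 1, o2, , drop = FALSE] +
    dy[o1, o2 + 1, , drop = FALSE] + dy[o1 + 1, o2 + 1, , drop = FALSE]
}

concat_ch <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

split_ch <- function(d, n_first) {
  list(first = d[, , seq_len(n_first), drop = FALSE],
       second = d[, , -seq_len(n_first), drop = FALSE])
}

# Adam over a list of conv layers
conv_adam_state <- function(net) {
  zero <- lapply(net, function(l) list(W = l$W * 0, b = l$b * 0))
  list(m = zero, v = zero, t = 0)
}

conv_adam_update <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                             eps = 1e-8) {
  st$t <- st$t + 1
  for (i in seq_along(net)) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[paste0("d", nm)]]
      st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g
      st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- st$m[[i]][[nm]] / (1 - beta1^st$t)
      vhat <- st$v[[i]][[nm]] / (1 - beta2^st$t)
      net[[i]][[nm]] <- net[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, st = st)
}

zero_like_grads <- function(net) {
  lapply(net, function(l) list(dW = l$W * 0, db = l$b * 0))
}

add_grads <- function(acc, g, scale = 1) {
  for (i in seq_along(acc)) {
    acc[[i]]$dW <- acc[[i]]$dW + scale * g[[i]]$dW
    acc[[i]]$db <- acc[[i]]$db + scale * g[[i]]$db
  }
  acc
}
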