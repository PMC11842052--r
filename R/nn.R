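# Minimal feed-forward network engine: dense and block-diagonal layers,
# reverse-mode gradients, inverted dropout and ADAM. Written in-package
# because the autoencoders and the Pi-model classifier are the method
# itself; everything runs on plain BLAS matrix products at desk scale.

nn_act <- function(z, act, slope = 0.01) {
  switch(act,
    linear = z,
    relu = pmax(z, 0),
    lrelu = ifelse(z > 0, z, slope * z),
    sigmoid = 1 / (1 + exp(-z)),
    vq_abort(sprintf("unknown activation '%s'", act), "vqtarget_nn_error")
  )
}

nn_act_grad <- function(z, a, act, slope = 0.01) {
  switch(act,
    linear = matrix(1, nrow(z), ncol(z)),
    relu = (z > 0) * 1,
    lrelu = ifelse(z > 0, 1, slope),
    sigmoid = a * (1 - a),
    vq_abort(sprintf("unknown activation '%s'", act), "vqtarget_nn_error")
  )
}

# He-style initialization; draws from the ambient RNG stream so callers
# control determinism with one seed.
nn_dense <- function(n_in, n_out, act = "lrelu", slope = 0.01, dropout = 0) {
  list(type = "dense",
       W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out),
       act = act, slope = slope, dropout = dropout)
}

# One independent dense map per block of input columns; output is the
# column-concatenation of the per-block outputs. Used for the
# cell-independent first (and mirrored last) layer of the multimodal model.
nn_block <- function(in_sizes, out_sizes, act = "lrelu", slope = 0.01) {
  stopifnot(length(in_sizes) == length(out_sizes))
  Ws <- Map(function(ni, no) {
    matrix(rnorm(ni * no, sd = sqrt(2 / ni)), ni, no)
  }, in_sizes, out_sizes)
  bs <- lapply(out_sizes, numeric)
  list(type = "block", Ws = Ws, bs = bs,
       in_sizes = as.integer(in_sizes), out_sizes = as.integer(out_sizes),
       act = act, slope = slope, dropout = 0)
}

nn_layer_forward <- function(layer, x, train = FALSE) {
  if (layer$type == "dense") {
    z <- x %*% layer$W + matrix(layer$b, nrow(x), length(layer$b),
                                byrow = TRUE)
  } else {
    in_ends <- cumsum(layer$in_sizes)
    in_starts <- in_ends - layer$in_sizes + 1L
    parts <- vector("list", length(layer$Ws))
    for (k in seq_along(layer$Ws)) {
      xk <- x[, in_starts[k]:in_ends[k], drop = FALSE]
      parts[[k]] <- xk %*% layer$Ws[[k]] +
        matrix(layer$bs[[k]], nrow(x), layer$out_sizes[k], byrow = TRUE)
    }
    z <- do.call(cbind, parts)
  }
  a <- nn_act(z, layer$act, layer$slope)
  mask <- NULL
  if (train && layer$dropout > 0) {
    mask <- matrix(
      (runif(length(a)) >= layer$dropout) / (1 - layer$dropout),
      nrow(a), ncol(a)
    )
    a <- a * mask
  }
  list(a = a, cache = list(x = x, z = z, a = a, mask = mask))
}

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- nn_layer_forward(layers[[i]], x, train = train)
    caches[[i]] <- step$cache
    x <- step$a
  }
  list(out = x, caches = caches)
}

nn_layer_backward <- function(layer, cache, d_a) {
  if (!is.null(cache$mask)) {
    d_a <- d_a * cache$mask
  }
  d_z <- d_a * nn_act_grad(cache$z, cache$a, layer$act, layer$slope)
  if (layer$type == "dense") {
    list(grads = list(W = crossprod(cache$x, d_z), b = colSums(d_z)),
         d_x = tcrossprod(d_z, layer$W))
  } else {
    in_ends <- cumsum(layer$in_sizes)
    in_starts <- in_ends - layer$in_sizes + 1L
    out_ends <- cumsum(layer$out_sizes)
    out_starts <- out_ends - layer$out_sizes + 1L
    gW <- vector("list", length(layer$Ws))
    gb <- vector("list", length(layer$Ws))
    d_x <- matrix(0, nrow(d_z), sum(layer$in_sizes))
    for (k in seq_along(layer$Ws)) {
      dzk <- d_z[, out_starts[k]:out_ends[k], drop = FALSE]
      xk <- cache$x[, in_starts[k]:in_ends[k], drop = FALSE]
      gW[[k]] <- crossprod(xk, dzk)
      gb[[k]] <- colSums(dzk)
      d_x[, in_starts[k]:in_ends[k]] <- tcrossprod(dzk, layer$Ws[[k]])
    }
    list(grads = list(Ws = gW, bs = gb), d_x = d_x)
  }
}

nn_backward <- function(layers, caches, d_out) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    step <- nn_layer_backward(layers[[i]], caches[[i]], d_out)
    grads[[i]] <- step$grads
    d_out <- step$d_x
  }
  list(grads = grads, d_x = d_out)
}

nn_layer_params <- function(layer) {
  if (layer$type == "dense") layer[c("W", "b")] else layer[c("Ws", "bs")]
}

nn_set_layer_params <- function(layer, params) {
  for (nm in names(params)) layer[[nm]] <- params[[nm]]
  layer
}

nn_params <- function(layers) lapply(layers, nn_layer_params)

nn_set_params <- function(layers, params) {
  Map(nn_set_layer_params, layers, params)
}

nn_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, nn_zeros_like) else p * 0
}

nn_n_parameters <- function(layers) {
  sum(rapply(nn_params(layers), length, how = "unlist"))
}

# ---- ADAM ---------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_walk <- function(p, g, m, v, f) {
  if (is.list(p)) {
    pm <- p
    mm <- m
    vm <- v
    for (i in seq_along(p)) {
      r <- adam_walk(p[[i]], g[[i]], m[[i]], v[[i]], f)
      pm[[i]] <- r$p
      mm[[i]] <- r$m
      vm[[i]] <- r$v
    }
    list(p = pm, m = mm, v = vm)
  } else {
    f(p, g, m, v)
  }
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  f <- function(p, g, m, v) {
    m <- state$beta1 * m + (1 - state$beta1) * g
    v <- state$beta2 * v + (1 - state$beta2) * g^2
    p <- p - state$lr * (m / c1) / (sqrt(v / c2) + state$eps)
    list(p = p, m = m, v = v)
  }
  r <- adam_walk(params, grads, state$m, state$v, f)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# ---- per-column standardization ----------------------------------------

# Zero mean / unit variance per column, with the transform kept so held-out
# inputs are mapped identically. Constant columns get scale 1.
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}
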