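# Neural layer primitives with explicit forward/backward passes.
#
# Tensor layout conventions (column-major R arrays):
#   conv2d activations: (H, W, C, N)      [N = batch]
#   conv1d activations: (L, C, N)
#   dense activations:  (D, N)
# Every backward pass is validated against finite differences in the test
# suite; gradients here are the analytic forms.

uniform_init <- function(n_out, n_in, fan_in, rng_sd = NULL) {
  lim <- sqrt(1 / fan_in)
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# ---- conv2d ----------------------------------------------------------------

# "same" padding, stride 1. Patch-gather (im2col) indices and the transposed
# scatter operator are precomputed from the static input shape.
layer_conv2d <- function(h, w, in_c, kh, kw, out_c) {
  hp <- h + kh - 1L; wp <- w + kw - 1L
  patch_off <- as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * hp, "+"))
  out_base <- as.vector(outer(1:h, (1:w - 1L) * hp, "+"))
  idx1 <- outer(patch_off, out_base, "+")               # one channel
  idx <- do.call(rbind, lapply(seq_len(in_c), function(c) {
    idx1 + (c - 1L) * hp * wp
  }))                                                   # (kh*kw*C, H*W)
  k <- kh * kw * in_c
  scatter <- Matrix::sparseMatrix(
    i = as.vector(idx),
    j = seq_len(length(idx)),
    x = 1, dims = c(hp * wp * in_c, k * h * w)
  )
  list(type = "conv2d", h = h, w = w, in_c = in_c, kh = kh, kw = kw,
       out_c = out_c, hp = hp, wp = wp, k = k, idx = idx, scatter = scatter,
       pt = (kh - 1L) %/% 2L, pl = (kw - 1L) %/% 2L,
       params = list(W = uniform_init(out_c, k, k), b = numeric(out_c)),
       frozen = FALSE)
}

conv2d_cols <- function(layer, x) {
  n <- dim(x)[4]
  xpad <- array(0, c(layer$hp, layer$wp, layer$in_c, n))
  xpad[layer$pt + seq_len(layer$h), layer$pl + seq_len(layer$w), , ] <- x
  stride <- layer$hp * layer$wp * layer$in_c
  # gather indices are static per batch size; cache the expanded form
  full <- layer$idx_cache[[as.character(n)]]
  if (is.null(full)) {
    full <- as.integer(outer(as.vector(layer$idx),
                             (0:(n - 1L)) * stride, "+"))
  }
  list(p = matrix(xpad[full], nrow = layer$k), full = full)  # (K, H*W*N)
}

conv2d_forward <- function(layer, x) {
  n <- dim(x)[4]
  cols <- conv2d_cols(layer, x)
  if (is.null(layer$idx_cache[[as.character(n)]])) {
    layer$idx_cache[[as.character(n)]] <- cols$full
  }
  out <- layer$params$W %*% cols$p + layer$params$b
  y <- aperm(array(out, c(layer$out_c, layer$h, layer$w, n)), c(2, 3, 1, 4))
  list(out = y, cache = list(p = cols$p, n = n), layer = layer)
}

conv2d_backward <- function(layer, dout, cache) {
  n <- cache$n
  dy <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = layer$out_c)
  grads <- list(W = dy %*% t(cache$p), b = rowSums(dy))
  dp <- t(layer$params$W) %*% dy                        # (K, H*W*N)
  dpm <- matrix(dp, nrow = layer$k * layer$h * layer$w, ncol = n)
  dxpad <- as.matrix(layer$scatter %*% dpm)
  dx <- array(dxpad, c(layer$hp, layer$wp, layer$in_c, n))[
    layer$pt + seq_len(layer$h), layer$pl + seq_len(layer$w), , ,
    drop = FALSE]
  list(dx = dx, grads = grads)
}

# ---- max pooling -----------------------------------------------------------

layer_maxpool2d <- function(pool = 3L) {
  list(type = "maxpool2d", pool = as.integer(pool), params = list(),
       frozen = FALSE)
}

maxpool2d_forward <- function(layer, x) {
  p <- layer$pool
  d <- dim(x)
  ho <- d[1] %/% p; wo <- d[2] %/% p
  best <- array(-Inf, c(ho, wo, d[3], d[4]))
  arg <- array(1L, c(ho, wo, d[3], d[4]))
  for (di in 0:(p - 1L)) for (dj in 0:(p - 1L)) {
    s <- x[seq(di + 1L, by = p, length.out = ho),
           seq(dj + 1L, by = p, length.out = wo), , , drop = FALSE]
    hit <- s > best
    best[hit] <- s[hit]
    arg[hit] <- di * p + dj + 1L
  }
  list(out = best, cache = list(arg = arg, dim = d, ho = ho, wo = wo))
}

maxpool2d_backward <- function(layer, dout, cache) {
  p <- layer$pool
  d <- cache$dim
  ho <- cache$ho; wo <- cache$wo
  m <- ho * wo * d[3] * d[4]
  # recover source coordinates of each argmax and scatter in one pass
  oi <- rep.int(seq_len(ho), m %/% ho)
  oj <- rep(rep(seq_len(wo), each = ho), m %/% (ho * wo))
  cn <- rep(seq_len(d[3] * d[4]), each = ho * wo)
  a <- as.vector(cache$arg) - 1L
  src_i <- (oi - 1L) * p + (a %/% p) + 1L
  src_j <- (oj - 1L) * p + (a %% p) + 1L
  lin <- src_i + (src_j - 1L) * d[1] + (cn - 1L) * (d[1] * d[2])
  dx <- numeric(prod(d))
  dx[lin] <- as.vector(dout)
  dim(dx) <- d
  list(dx = dx, grads = list())
}

# ---- batch normalisation (per channel, dim 3 of a 4-d array) ---------------

layer_batchnorm <- function(n_c, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", n_c = n_c, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n_c), beta = rep(0, n_c)),
       buffers = list(run_mean = rep(0, n_c), run_var = rep(1, n_c),
                      initialised = FALSE),
       frozen = FALSE)
}

channel_mat <- function(x) {
  # (H, W, C, N) -> matrix with one column per channel
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

channel_unmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

batchnorm_forward <- function(layer, x, train) {
  d <- dim(x)
  xm <- channel_mat(x)
  use_batch <- train && !layer$frozen
  if (use_batch) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    if (!layer$buffers$initialised) {
      layer$buffers$run_mean <- mu
      layer$buffers$run_var <- v
      layer$buffers$initialised <- TRUE
    } else {
      mom <- layer$momentum
      layer$buffers$run_mean <- mom * layer$buffers$run_mean + (1 - mom) * mu
      layer$buffers$run_var <- mom * layer$buffers$run_var + (1 - mom) * v
    }
  } else {
    mu <- layer$buffers$run_mean
    v <- layer$buffers$run_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  m <- nrow(xm)
  xhat <- (xm - rep(mu, each = m)) * rep(invstd, each = m)
  ym <- xhat * rep(layer$params$gamma, each = m) +
    rep(layer$params$beta, each = m)
  list(out = channel_unmat(ym, d), layer = layer,
       cache = list(xhat = xhat, invstd = invstd, d = d,
                    batch_stats = use_batch))
}

batchnorm_backward <- function(layer, dout, cache) {
  d <- cache$d
  dym <- channel_mat(dout)
  m <- nrow(dym)
  grads <- list(gamma = colSums(dym * cache$xhat), beta = colSums(dym))
  if (cache$batch_stats) {
    scale <- layer$params$gamma * cache$invstd / m
    dxm <- (m * dym - rep(grads$beta, each = m) -
              cache$xhat * rep(grads$gamma, each = m)) *
      rep(scale, each = m)
  } else {
    dxm <- dym * rep(layer$params$gamma * cache$invstd, each = m)
  }
  list(dx = channel_unmat(dxm, d), grads = grads)
}

# ---- relu / dropout / flatten ----------------------------------------------

layer_relu <- function() list(type = "relu", params = list(), frozen = FALSE)

relu_forward <- function(layer, x) {
  mask <- x > 0
  list(out = x * mask, cache = list(mask = mask))
}

relu_backward <- function(layer, dout, cache) {
  list(dx = dout * cache$mask, grads = list())
}

layer_dropout <- function(rate) {
  list(type = "dropout", rate = rate, params = list(), frozen = FALSE)
}

dropout_forward <- function(layer, x, train) {
  if (!train || layer$rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$rate
  mask <- array(stats::rbinom(length(x), 1, keep) / keep, dim(x) %||% length(x))
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, dout, cache) {
  if (is.null(cache$mask)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache$mask, grads = list())
}

layer_flatten <- function() list(type = "flatten", params = list(),
                                 frozen = FALSE)

flatten_forward <- function(layer, x) {
  d <- dim(x)
  n <- d[length(d)]
  list(out = matrix(x, ncol = n), cache = list(d = d))
}

flatten_backward <- function(layer, dout, cache) {
  list(dx = array(dout, cache$d), grads = list())
}

# ---- dense -----------------------------------------------------------------

layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = uniform_init(n_out, n_in, n_in),
                     b = numeric(n_out)),
       frozen = FALSE)
}

dense_forward <- function(layer, x) {
  list(out = layer$params$W %*% x + layer$params$b, cache = list(x = x))
}

dense_backward <- function(layer, dout, cache) {
  list(dx = t(layer$params$W) %*% dout,
       grads = list(W = dout %*% t(cache$x), b = rowSums(dout)))
}

# ---- conv1d (as conv2d with unit width) ------------------------------------

layer_conv1d <- function(l, in_c, k, out_c) {
  inner <- layer_conv2d(l, 1L, in_c, k, 1L, out_c)
  inner$type <- "conv1d"
  inner
}

conv1d_forward <- function(layer, x) {
  # x: (L, C, N) -> lift to (L, 1, C, N)
  d <- dim(x)
  r <- conv2d_forward(layer, array(x, c(d[1], 1L, d[2], d[3])))
  r$out <- array(r$out, c(d[1], layer$out_c, d[3]))
  r
}

conv1d_backward <- function(layer, dout, cache) {
  d <- dim(dout)
  r <- conv2d_backward(layer, array(dout, c(d[1], 1L, d[2], d[3])), cache)
  r$dx <- array(r$dx, c(layer$h, layer$in_c, d[3]))
  r
}

layer_maxpool1d <- function(pool = 6L) {
  list(type = "maxpool1d", pool = as.integer(pool), params = list(),
       frozen = FALSE)
}

maxpool1d_forward <- function(layer, x) {
  p <- layer$pool
  d <- dim(x)                                  # (L, C, N)
  lo <- d[1] %/% p
  best <- array(-Inf, c(lo, d[2], d[3]))
  arg <- array(1L, c(lo, d[2], d[3]))
  for (di in 0:(p - 1L)) {
    s <- x[seq(di + 1L, by = p, length.out = lo), , , drop = FALSE]
    hit <- s > best
    best[hit] <- s[hit]
    arg[hit] <- di + 1L
  }
  list(out = best, cache = list(arg = arg, dim = d, lo = lo))
}

maxpool1d_backward <- function(layer, dout, cache) {
  p <- layer$pool
  dx <- array(0, cache$dim)
  for (di in 0:(p - 1L)) {
    mask <- cache$arg == (di + 1L)
    ii <- seq(di + 1L, by = p, length.out = cache$lo)
    cur <- dx[ii, , , drop = FALSE]
    cur[mask] <- cur[mask] + dout[mask]
    dx[ii, , ] <- cur
  }
  list(dx = dx, grads = list())
}

# ---- batchnorm for (L, C, N) activations -----------------------------------

batchnorm1d_forward <- function(layer, x, train) {
  d <- dim(x)
  r <- batchnorm_forward(layer, array(x, c(d[1], 1L, d[2], d[3])), train)
  r$out <- array(r$out, d)
  r
}

batchnorm1d_backward <- function(layer, dout, cache) {
  d <- dim(dout)
  r <- batchnorm_backward(layer, array(dout, c(d[1], 1L, d[2], d[3])), cache)
  r$dx <- array(r$dx, d)
  r
}

# ---- attention pooling over time (1D-CNN head-end) -------------------------
# Input (L, C, N), C even: first C/2 filters are values, second C/2 carry a
# per-filter softmax over time that weights the values; output (C/2, N).

layer_attention_pool <- function() {
  list(type = "attention_pool", params = list(), frozen = FALSE)
}

attention_pool_forward <- function(layer, x) {
  d <- dim(x)
  stop_if_not(d[2] %% 2L == 0L,
              "attention pooling needs an even filter count, got ", d[2])
  half <- d[2] %/% 2L
  a <- x[, seq_len(half), , drop = FALSE]
  b <- x[, half + seq_len(half), , drop = FALSE]
  bmax <- apply(b, c(2, 3), max)
  e <- exp(sweep(b, c(2, 3), bmax, "-"))
  w <- sweep(e, c(2, 3), apply(e, c(2, 3), sum), "/")
  out <- apply(a * w, c(2, 3), sum)                     # (half, N)
  if (is.null(dim(out))) out <- matrix(out, nrow = half)
  list(out = out, cache = list(a = a, w = w, d = d, half = half))
}

attention_pool_backward <- function(layer, dout, cache) {
  # dout: (half, N); broadcast over time
  dvec <- aperm(array(dout, c(cache$half, dim(dout)[2], cache$d[1])),
                c(3, 1, 2))
  da <- cache$w * dvec
  ds <- cache$a * dvec                                  # d(score contribution)
  wsum <- apply(cache$w * ds, c(2, 3), sum)
  db <- cache$w * sweep(ds, c(2, 3), wsum, "-")
  dx <- array(0, cache$d)
  dx[, seq_len(cache$half), ] <- da
  dx[, cache$half + seq_len(cache$half), ] <- db
  list(dx = dx, grads = list())
}

# ---- generic network runner ------------------------------------------------

net_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv2d = conv2d_forward(ly, x),
      conv1d = conv1d_forward(ly, x),
      maxpool2d = maxpool2d_forward(ly, x),
      maxpool1d = maxpool1d_forward(ly, x),
      batchnorm = batchnorm_forward(ly, x, train),
      batchnorm1d = batchnorm1d_forward(ly, x, train),
      relu = relu_forward(ly, x),
      dropout = dropout_forward(ly, x, train),
      flatten = flatten_forward(ly, x),
      dense = dense_forward(ly, x),
      attention_pool = attention_pool_forward(ly, x),
      stop("unknown layer type: ", ly$type)
    )
    if (!is.null(r$layer)) layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv2d = conv2d_backward(ly, dout, caches[[i]]),
      conv1d = conv1d_backward(ly, dout, caches[[i]]),
      maxpool2d = maxpool2d_backward(ly, dout, caches[[i]]),
      maxpool1d = maxpool1d_backward(ly, dout, caches[[i]]),
      batchnorm = batchnorm_backward(ly, dout, caches[[i]]),
      batchnorm1d = batchnorm1d_backward(ly, dout, caches[[i]]),
      relu = relu_backward(ly, dout, caches[[i]]),
      dropout = dropout_backward(ly, dout, caches[[i]]),
      flatten = flatten_backward(ly, dout, caches[[i]]),
      dense = dense_backward(ly, dout, caches[[i]]),
      attention_pool = attention_pool_backward(ly, dout, caches[[i]]),
      stop("unknown layer type: ", ly$type)
    )
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

sgd_update_layers <- function(layers, grads, lr, momentum = 0) {
  for (i in seq_along(layers)) {
    if (isTRUE(layers[[i]]$frozen) || length(layers[[i]]$params) == 0) next
    for (p in names(layers[[i]]$params)) {
      g <- grads[[i]][[p]]
      if (is.null(g)) next
      if (momentum > 0) {
        v <- layers[[i]]$vel[[p]]
        if (is.null(v)) v <- g * 0
        v <- momentum * v - lr * g
        layers[[i]]$vel[[p]] <- v
        layers[[i]]$params[[p]] <- layers[[i]]$params[[p]] + v
      } else {
        layers[[i]]$params[[p]] <- layers[[i]]$params[[p]] - lr * g
      }
    }
  }
  layers
}

net_param_vector <- function(layers) {
  unlist(lapply(layers, function(ly) unlist(ly$params)), use.names = FALSE)
}

net_param_count <- function(layers) length(net_param_vector(layers))

# ---- LSTM (single direction, with step masking) ----------------------------

layer_lstm <- function(n_in, n_units) {
  k <- 4L * n_units
  list(type = "lstm", n_in = n_in, n_units = n_units,
       params = list(
         Wx = uniform_init(k, n_in, n_in),
         Wh = uniform_init(k, n_units, n_units),
         # forget-gate bias 1 (standard initialisation)
         b = rep(c(0, 1, 0, 0), each = n_units)
       ),
       frozen = FALSE)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# xs: list over time of (D, N); mask: T x N matrix of 0/1 (1 = real slot).
# Masked steps carry h and c through unchanged. Returns the final hidden
# state (n_units, N) and per-step caches.
lstm_forward <- function(layer, xs, mask) {
  nu <- layer$n_units
  n <- ncol(xs[[1]])
  h <- matrix(0, nu, n)
  cst <- matrix(0, nu, n)
  caches <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    z <- layer$params$Wx %*% xs[[t]] + layer$params$Wh %*% h + layer$params$b
    i <- sigmoid(z[seq_len(nu), , drop = FALSE])
    f <- sigmoid(z[nu + seq_len(nu), , drop = FALSE])
    g <- tanh(z[2 * nu + seq_len(nu), , drop = FALSE])
    o <- sigmoid(z[3 * nu + seq_len(nu), , drop = FALSE])
    c_new <- f * cst + i * g
    h_new <- o * tanh(c_new)
    m <- matrix(mask[t, ], nu, n, byrow = TRUE)
    caches[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cst, i = i, f = f,
                        g = g, o = o, c_new = c_new, m = m)
    h <- m * h_new + (1 - m) * h
    cst <- m * c_new + (1 - m) * cst
  }
  list(h = h, caches = caches)
}

# dh_final: gradient w.r.t. the final hidden state.
lstm_backward <- function(layer, caches, dh_final) {
  nu <- layer$n_units
  n <- ncol(dh_final)
  dh <- dh_final
  dc <- matrix(0, nu, n)
  gWx <- layer$params$Wx * 0
  gWh <- layer$params$Wh * 0
  gb <- layer$params$b * 0
  dxs <- vector("list", length(caches))
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    m <- cc$m
    dh_step <- m * dh          # gradient into this step's h_new
    dc_step <- m * dc
    tc <- tanh(cc$c_new)
    do <- dh_step * tc
    dc_new <- dc_step + dh_step * cc$o * (1 - tc^2)
    di <- dc_new * cc$g
    df <- dc_new * cc$c_prev
    dg <- dc_new * cc$i
    dz <- rbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    gWx <- gWx + dz %*% t(cc$x)
    gWh <- gWh + dz %*% t(cc$h_prev)
    gb <- gb + rowSums(dz)
    dxs[[t]] <- t(layer$params$Wx) %*% dz
    dh_prev_rec <- t(layer$params$Wh) %*% dz
    dh <- (1 - m) * dh + dh_prev_rec
    dc <- (1 - m) * dc + dc_new * cc$f
  }
  list(dxs = dxs, grads = list(Wx = gWx, Wh = gWh, b = gb))
}
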