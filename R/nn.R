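# Minimal neural-network core used by the model harness: 1-D convolutions
# (im2col matrix products), max-pooling, inverted dropout, dense layers,
# gated attention pooling, and Adam. Batches are stored as [n, L, C] arrays;
# flattening is column-major throughout (sample index varies fastest), so
# reshape and matrix products stay consistent. Gradients are checked against
# numeric differentiation in the test suite.

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

nn_conv1d <- function(filters, kernel, c_in) {
  list(kind = "conv1d", k = kernel, c_in = c_in, c_out = filters,
       W = .he_init(kernel * c_in, filters, kernel * c_in),
       b = matrix(0, 1, filters))
}
nn_relu <- function() list(kind = "relu")
nn_maxpool1d <- function(size = 2L) list(kind = "maxpool", size = size)
nn_dropout <- function(rate = 0.2) list(kind = "dropout", rate = rate)
nn_flatten <- function() list(kind = "flatten")
nn_dense <- function(units, d_in) {
  list(kind = "dense", d_in = d_in, d_out = units,
       W = .he_init(d_in, units, d_in), b = matrix(0, 1, units))
}

.im2col <- function(X, k) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L - k + 1L
  out <- matrix(0, n * Lout, k * C)
  for (o in seq_len(k)) {
    sl <- X[, o:(o + Lout - 1L), , drop = FALSE]
    out[, ((o - 1L) * C + 1L):(o * C)] <- matrix(sl, n * Lout, C)
  }
  out
}

.col2im <- function(dXc, dimX, k) {
  n <- dimX[1]; L <- dimX[2]; C <- dimX[3]
  Lout <- L - k + 1L
  dX <- array(0, dimX)
  for (o in seq_len(k)) {
    piece <- array(dXc[, ((o - 1L) * C + 1L):(o * C)], c(n, Lout, C))
    dX[, o:(o + Lout - 1L), ] <- dX[, o:(o + Lout - 1L), , drop = FALSE] + piece
  }
  dX
}

layer_forward <- function(layer, X, train = FALSE) {
  switch(layer$kind,
    conv1d = {
      d <- dim(X)
      Xc <- .im2col(X, layer$k)
      Y <- sweep(Xc %*% layer$W, 2L, layer$b, "+")
      list(out = array(Y, c(d[1], d[2] - layer$k + 1L, layer$c_out)),
           cache = list(Xc = Xc, dimX = d))
    },
    relu = {
      mask <- X > 0
      list(out = X * mask, cache = list(mask = mask))
    },
    maxpool = {
      d <- dim(X); s <- layer$size
      Lout <- d[2] %/% s
      n <- d[1]; C <- d[3]
      idx_base <- (seq_len(Lout) - 1L) * s
      Y <- array(-Inf, c(n, Lout, C))
      arg <- array(1L, c(n, Lout, C))
      for (o in seq_len(s)) {
        sl <- X[, idx_base + o, , drop = FALSE]
        upd <- sl > Y
        Y[upd] <- sl[upd]
        arg[upd] <- o
      }
      list(out = Y, cache = list(arg = arg, dimX = d, Lout = Lout))
    },
    dropout = {
      if (!train || layer$rate <= 0) return(list(out = X, cache = list(mask = NULL)))
      mask <- array(stats::rbinom(length(X), 1L, 1 - layer$rate), dim(X)) /
        (1 - layer$rate)
      list(out = X * mask, cache = list(mask = mask))
    },
    flatten = {
      d <- dim(X)
      list(out = matrix(X, d[1], prod(d[-1])), cache = list(dimX = d))
    },
    dense = {
      list(out = sweep(X %*% layer$W, 2L, layer$b, "+"), cache = list(X = X))
    },
    stop("unknown layer kind ", layer$kind))
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$kind,
    conv1d = {
      d2 <- dim(dY)
      dYc <- matrix(dY, d2[1] * d2[2], d2[3])
      list(dX = .col2im(dYc %*% t(layer$W), cache$dimX, layer$k),
           grads = list(W = crossprod(cache$Xc, dYc),
                        b = matrix(colSums(dYc), 1)))
    },
    relu = list(dX = dY * cache$mask, grads = NULL),
    maxpool = {
      d <- cache$dimX; s <- layer$size; Lout <- cache$Lout
      dX <- array(0, d)
      idx_base <- (seq_len(Lout) - 1L) * s
      for (o in seq_len(s)) {
        sel <- cache$arg == o
        contrib <- dY * sel
        dX[, idx_base + o, ] <- dX[, idx_base + o, , drop = FALSE] + contrib
      }
      list(dX = dX, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    flatten = list(dX = array(dY, cache$dimX), grads = NULL),
    dense = list(dX = dY %*% t(layer$W),
                 grads = list(W = crossprod(cache$X, dY),
                              b = matrix(colSums(dY), 1))),
    stop("unknown layer kind ", layer$kind))
}

seq_forward <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], X, train)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

seq_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dY)
    dY <- bw$dX
    grads[i] <- list(bw$grads)
  }
  list(dX = dY, grads = grads)
}

# gated attention parameters: V, U [d x a], w [a x 1]
attn_params <- function(d, a) {
  list(V = .he_init(d, a, d), U = .he_init(d, a, d),
       w = matrix(stats::rnorm(a, sd = sqrt(1 / a)), a, 1))
}

attn_forward <- function(p, H) {
  Zv <- H %*% p$V
  Zu <- H %*% p$U
  Tn <- tanh(Zv)
  S <- 1 / (1 + exp(-Zu))
  A <- Tn * S
  s <- drop(A %*% p$w)
  s <- s - max(s)
  e <- exp(s)
  alpha <- e / sum(e)
  pooled <- drop(crossprod(H, alpha))
  list(pooled = pooled, weights = alpha,
       cache = list(H = H, Tn = Tn, S = S, A = A, alpha = alpha))
}

attn_backward <- function(p, cache, dpooled) {
  H <- cache$H; alpha <- cache$alpha
  dalpha <- drop(H %*% dpooled)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  dA <- ds %*% t(p$w)
  dw <- crossprod(cache$A, ds)
  dT <- dA * cache$S
  dS <- dA * cache$Tn
  dZv <- dT * (1 - cache$Tn^2)
  dZu <- dS * cache$S * (1 - cache$S)
  dH <- dZv %*% t(p$V) + dZu %*% t(p$U) + outer(alpha, dpooled)
  list(dH = dH, grads = list(V = crossprod(H, dZv), U = crossprod(H, dZu),
                             w = matrix(dw, ncol = 1)))
}

# ---- parameter trees ---------------------------------------------------

.is_param <- function(x) is.numeric(x) && !is.null(dim(x))

tree_map2 <- function(f, a, b) {
  if (.is_param(a)) return(f(a, b))
  if (is.null(a)) return(NULL)
  out <- a
  keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
          else seq_along(a)
  for (nm in keys) out[nm] <- list(tree_map2(f, a[[nm]], b[[nm]]))
  out
}

tree_zero <- function(a) {
  if (.is_param(a)) return(a * 0)
  if (is.null(a)) return(NULL)
  lapply(a, tree_zero)
}

tree_scale_add <- function(acc, g, scale = 1) {
  tree_map2(function(x, y) x + scale * y, acc, g)
}

# Adam with bias correction; state created lazily to mirror the tree
adam_new <- function() list(t = 0L, m = NULL, v = NULL)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- tree_zero(params)
    state$v <- tree_zero(params)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- tree_map2(function(m, .) m / bc1, state$m, state$m)
  vh <- tree_map2(function(v, .) v / bc2, state$v, state$v)
  upd <- tree_map2(function(m, v) m / (sqrt(v) + eps), mh, vh)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# layer lists carry params inline; extract/assign them as a tree so the
# optimizer can treat a whole model uniformly
layers_params <- function(layers) {
  lapply(layers, function(l)
    if (!is.null(l$W)) list(W = l$W, b = l$b) else NULL)
}

layers_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (!is.null(params[[i]])) {
      layers[[i]]$W <- params[[i]]$W
      layers[[i]]$b <- params[[i]]$b
    }
  }
  layers
}

# binary cross-entropy on logits: loss and d(loss)/d(logit), summed over n
bce_with_logits <- function(z, y) {
  p <- 1 / (1 + exp(-z))
  loss <- sum(ifelse(z > 0, z - z * y + log1p(exp(-z)),
                     -z * y + log1p(exp(z))))
  list(loss = loss, dz = p - y, p = p)
}
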