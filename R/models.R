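# Model harness: architecture construction, training (Adam on binary
# cross-entropy), prediction, and stratified cross-validation for the five
# model kinds:
#   geo_cnn    two-layer CNN on a geographic matrix alone
#   seq_cnn    conv-block CNN on the one-hot sequence window alone
#   gepse      fused geography + sequence network
#   i_gepse    isoform-attention MIL over per-isoform geography
#   ti_gepse   nested MIL: sequence instances, then isoforms
#   read_gepse read-level geography scored per read, Noisy-OR to site level

#' Model configuration
#'
#' Defaults follow the reference architecture: the geographic branch uses
#' two convolutional layers with 64 and 32 filters, kernel sizes 5 and 3,
#' one max-pooling and one dropout layer in between; training uses Adam on
#' binary cross-entropy with mini-batches of 128 for 20 epochs (fixed-shape
#' models) or 1 epoch (variable-shape bag models). Attention layers default
#' to a 128-dimensional member feature (two 64-unit projections) and a
#' 64-dimensional attention hidden layer; all are overridable.
#'
#' @param kind One of `"geo_cnn"`, `"seq_cnn"`, `"gepse"`, `"i_gepse"`,
#'   `"ti_gepse"`, `"read_gepse"`.
#' @param geo_shape `c(rows, cols)` of the geographic matrix (default 35 x 7).
#' @param seq_shape `c(window, 4)` of the one-hot sequence input.
#' @param geo_filters,geo_kernels Filter counts and kernel sizes of the two
#'   geographic conv layers.
#' @param seq_filters,seq_kernels Same for the sequence branch.
#' @param dropout Dropout rate.
#' @param proj_dim Per-branch projection width feeding the attention layer.
#' @param attn_dim Attention hidden size.
#' @param head_dim Hidden width of the output head.
#' @param inst_len,inst_stride Instance window length/stride for `ti_gepse`.
#' @param lr,batch_size,epochs Optimizer settings; `epochs = NULL` resolves
#'   to 20 for fixed-shape kinds and 1 for bag kinds.
#' @param seed One seed controlling initialization, shuffling and dropout.
#' @return A config list.
#' @export
model_config <- function(kind, geo_shape = c(35L, 7L), seq_shape = c(101L, 4L),
                         geo_filters = c(64L, 32L), geo_kernels = c(5L, 3L),
                         seq_filters = c(32L, 64L), seq_kernels = c(5L, 3L),
                         dropout = 0.2, proj_dim = 64L, attn_dim = 64L,
                         head_dim = 64L, inst_len = 50L, inst_stride = 10L,
                         lr = 1e-3, batch_size = 128L, epochs = NULL,
                         seed = 1L) {
  kind <- match.arg(kind, c("geo_cnn", "seq_cnn", "gepse", "i_gepse",
                            "ti_gepse", "read_gepse"))
  if (is.null(epochs))
    epochs <- if (kind %in% c("geo_cnn", "seq_cnn", "gepse")) 20L else 1L
  as.list(environment())
}

.conv_branch <- function(shape, filters, kernels, dropout) {
  L <- shape[1]; C <- shape[2]
  l1 <- L - kernels[1] + 1L
  l2 <- l1 %/% 2L
  l3 <- l2 - kernels[2] + 1L
  if (l3 < 1L) stop("input of length ", L, " too short for the conv stack")
  list(layers = list(nn_conv1d(filters[1], kernels[1], C), nn_relu(),
                     nn_maxpool1d(2L), nn_dropout(dropout),
                     nn_conv1d(filters[2], kernels[2], filters[1]), nn_relu(),
                     nn_flatten()),
       dim = l3 * filters[2])
}

.seq_branch <- function(shape, filters, kernels, dropout) {
  W <- shape[1]; C <- shape[2]
  l1 <- W - kernels[1] + 1L
  l2 <- l1 %/% 2L
  l3 <- l2 - kernels[2] + 1L
  l4 <- l3 %/% 2L
  if (l4 < 1L) stop("sequence window ", W, " too short for the conv stack")
  list(layers = list(nn_conv1d(filters[1], kernels[1], C), nn_relu(),
                     nn_maxpool1d(2L), nn_dropout(dropout),
                     nn_conv1d(filters[2], kernels[2], filters[1]), nn_relu(),
                     nn_maxpool1d(2L), nn_flatten()),
       dim = l4 * filters[2])
}

.proj <- function(d_in, d_out) list(layers = list(nn_dense(d_out, d_in), nn_relu()),
                                    dim = d_out)
.head <- function(d_in, hid) list(nn_dense(hid, d_in), nn_relu(),
                                  nn_dense(1L, hid))

#' Build an untrained model handle
#'
#' @param kind Model kind (see [model_config()]); ignored if `config` is
#'   given.
#' @param config A [model_config()] list.
#' @return An object of class `geotx_model` exposing [train_model()] and
#'   [predict.geotx_model()].
#' @export
build_model <- function(kind, config = model_config(kind)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  kind <- config$kind
  mod <- list()
  dims <- list()
  if (kind %in% c("geo_cnn", "gepse", "i_gepse", "ti_gepse", "read_gepse")) {
    g <- .conv_branch(config$geo_shape, config$geo_filters, config$geo_kernels,
                      config$dropout)
    mod$geo <- g$layers
    dims$geo <- g$dim
  }
  if (kind %in% c("seq_cnn", "gepse", "i_gepse")) {
    s <- .seq_branch(config$seq_shape, config$seq_filters, config$seq_kernels,
                     config$dropout)
    mod$seq <- s$layers
    dims$seq <- s$dim
  }
  if (kind == "ti_gepse") {
    it <- .conv_branch(c(config$inst_len, 4L), config$seq_filters,
                       config$seq_kernels, config$dropout)
    mod$inst <- it$layers
    mod$inst_proj <- .proj(it$dim, config$proj_dim)$layers
    mod$inst_attn <- attn_params(config$proj_dim, config$attn_dim)
  }
  head_in <- switch(kind,
    geo_cnn = dims$geo,
    seq_cnn = dims$seq,
    gepse = dims$geo + dims$seq,
    read_gepse = dims$geo,
    i_gepse = , ti_gepse = 2L * config$proj_dim)
  if (kind %in% c("i_gepse", "ti_gepse")) {
    mod$geo_proj <- .proj(dims$geo, config$proj_dim)$layers
    if (kind == "i_gepse")
      mod$seq_proj <- .proj(dims$seq, config$proj_dim)$layers
    mod$attn <- attn_params(2L * config$proj_dim, config$attn_dim)
  }
  mod$head <- .head(head_in, config$head_dim)
  structure(list(kind = kind, config = config, mod = mod, dims = dims,
                 trained = FALSE, history = NULL),
            class = "geotx_model")
}

#' @export
print.geotx_model <- function(x, ...) {
  cat(sprintf("<geotx_model> kind=%s, %strained\n", x$kind,
              if (x$trained) "" else "un"))
  invisible(x)
}

.get_params <- function(model) {
  lapply(model$mod, function(m)
    if (!is.null(m$V)) m else layers_params(m))
}

.set_params <- function(model, params) {
  for (nm in names(params)) {
    if (!is.null(model$mod[[nm]]$V)) model$mod[[nm]] <- params[[nm]]
    else model$mod[[nm]] <- layers_set_params(model$mod[[nm]], params[[nm]])
  }
  model
}

# ---- flat kinds --------------------------------------------------------

.flat_inputs <- function(kind) switch(kind,
  geo_cnn = "x_geo", seq_cnn = "x_seq", gepse = c("x_geo", "x_seq"))

.flat_forward <- function(model, data, idx, train) {
  mod <- model$mod
  caches <- list()
  feats <- list()
  dims <- integer(0)
  if (!is.null(mod$geo) && model$kind != "seq_cnn") {
    fw <- seq_forward(mod$geo, data$x_geo[idx, , , drop = FALSE], train)
    caches$geo <- fw$caches
    feats <- c(feats, list(fw$out))
    dims <- c(dims, geo = ncol(fw$out))
  }
  if (!is.null(mod$seq)) {
    fw <- seq_forward(mod$seq, data$x_seq[idx, , , drop = FALSE], train)
    caches$seq <- fw$caches
    feats <- c(feats, list(fw$out))
    dims <- c(dims, seq = ncol(fw$out))
  }
  X <- do.call(cbind, feats)
  hf <- seq_forward(mod$head, X, train)
  caches$head <- hf$caches
  list(z = drop(hf$out), caches = caches, dims = dims)
}

.flat_backward <- function(model, fw, dz) {
  mod <- model$mod
  hb <- seq_backward(mod$head, fw$caches$head, matrix(dz, ncol = 1))
  grads <- list(head = hb$grads)
  dX <- hb$dX
  off <- 0L
  for (nm in names(fw$dims)) {
    cols <- (off + 1L):(off + fw$dims[[nm]])
    off <- off + fw$dims[[nm]]
    bb <- seq_backward(mod[[nm]], fw$caches[[nm]], dX[, cols, drop = FALSE])
    grads[[nm]] <- bb$grads
  }
  grads
}

# ---- bag kinds ---------------------------------------------------------

.bag_forward_igepse <- function(model, bag, train) {
  mod <- model$mod
  m <- dim(bag$geo)[1]
  p <- model$config$proj_dim
  gf <- seq_forward(mod$geo, bag$geo, train)
  gp <- seq_forward(mod$geo_proj, gf$out, train)
  if (model$kind == "i_gepse") {
    sf <- seq_forward(mod$seq, array(bag$seq, c(1L, dim(bag$seq))), train)
    sp <- seq_forward(mod$seq_proj, sf$out, train)
    seq_feat <- sp$out
    seq_cache <- list(sf = sf, sp = sp)
  } else { # ti_gepse: instance-level MIL over sequence windows
    instf <- seq_forward(mod$inst, bag$inst, train)
    instp <- seq_forward(mod$inst_proj, instf$out, train)
    ia <- attn_forward(mod$inst_attn, instp$out)
    seq_feat <- matrix(ia$pooled, 1L)
    seq_cache <- list(instf = instf, instp = instp, ia = ia)
  }
  H <- cbind(gp$out, matrix(seq_feat, m, p, byrow = TRUE))
  af <- attn_forward(mod$attn, H)
  hf <- seq_forward(mod$head, matrix(af$pooled, 1L), train)
  list(z = drop(hf$out), weights = af$weights,
       cache = list(gf = gf, gp = gp, seq_cache = seq_cache, af = af,
                    hf = hf, m = m, p = p))
}

.bag_backward_igepse <- function(model, fw, dz) {
  mod <- model$mod
  cc <- fw$cache
  hb <- seq_backward(mod$head, cc$hf$caches, matrix(dz, 1L, 1L))
  ab <- attn_backward(mod$attn, cc$af$cache, drop(hb$dX))
  p <- cc$p
  dG <- ab$dH[, 1:p, drop = FALSE]
  dSeq <- matrix(colSums(ab$dH[, (p + 1L):(2L * p), drop = FALSE]), 1L)
  gpb <- seq_backward(mod$geo_proj, cc$gp$caches, dG)
  gb <- seq_backward(mod$geo, cc$gf$caches, gpb$dX)
  grads <- list(head = hb$grads, attn = ab$grads,
                geo_proj = gpb$grads, geo = gb$grads)
  if (model$kind == "i_gepse") {
    spb <- seq_backward(mod$seq_proj, cc$seq_cache$sp$caches, dSeq)
    sb <- seq_backward(mod$seq, cc$seq_cache$sf$caches, spb$dX)
    grads$seq_proj <- spb$grads
    grads$seq <- sb$grads
  } else {
    iab <- attn_backward(mod$inst_attn, cc$seq_cache$ia$cache, drop(dSeq))
    ipb <- seq_backward(mod$inst_proj, cc$seq_cache$instp$caches, iab$dH)
    ib <- seq_backward(mod$inst, cc$seq_cache$instf$caches, ipb$dX)
    grads$inst_attn <- iab$grads
    grads$inst_proj <- ipb$grads
    grads$inst <- ib$grads
  }
  grads
}

.bag_forward_read <- function(model, bag, train) {
  mod <- model$mod
  gf <- seq_forward(mod$geo, bag$geo, train)
  hf <- seq_forward(mod$head, gf$out, train)
  z <- drop(hf$out)
  pr <- 1 / (1 + exp(-z))
  real <- if (is.null(bag$real)) rep(TRUE, length(pr)) else bag$real
  P <- 1 - prod(1 - pr[real])
  P <- min(max(P, 1e-7), 1 - 1e-7)
  list(z = z, read_probs = pr, site_prob = P, real = real,
       cache = list(gf = gf, hf = hf))
}

.bag_backward_read <- function(model, fw, y) {
  # d(site BCE)/dz_r = (P - y) * p_r / P for covered reads, 0 for padding
  pr <- fw$read_probs
  dz <- (fw$site_prob - y) * pr / fw$site_prob
  dz[!fw$real] <- 0
  hb <- seq_backward(model$mod$head, fw$cache$hf$caches, matrix(dz, ncol = 1))
  gb <- seq_backward(model$mod$geo, fw$cache$gf$caches, hb$dX)
  list(head = hb$grads, geo = gb$grads)
}

# ---- training ----------------------------------------------------------

.is_bag_kind <- function(kind) kind %in% c("i_gepse", "ti_gepse", "read_gepse")

#' Train a model
#'
#' Seeded end to end: initialization, shuffling and dropout all derive from
#' `config$seed`, so the same configuration and data give an identical loss
#' history.
#'
#' @param model An untrained (or previously trained) `geotx_model`.
#' @param data For fixed-shape kinds: `list(x_geo = [n, L, 7] array,
#'   x_seq = [n, W, 4] array, y = 0/1)` with only the arrays the kind needs.
#'   For bag kinds: `list(bags = list, y = 0/1)`; each bag is
#'   `list(geo = [m, L, 7] array, seq = [W, 4] matrix | inst = [k, 50, 4]
#'   array | real = logical)`.
#' @param epochs,batch_size,lr Optional overrides of the config values.
#' @param verbose Print the per-epoch loss.
#' @return The trained model; `$history` holds the mean per-sample loss per
#'   epoch.
#' @export
train_model <- function(model, data, epochs = NULL, batch_size = NULL,
                        lr = NULL, verbose = FALSE) {
  cfg <- model$config
  epochs <- if (is.null(epochs)) cfg$epochs else epochs
  batch_size <- if (is.null(batch_size)) cfg$batch_size else batch_size
  lr <- if (is.null(lr)) cfg$lr else lr
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 1L)
  params <- .get_params(model)
  state <- adam_new()
  history <- numeric(epochs)
  n <- length(data$y)
  y <- as.numeric(data$y)
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    total <- 0
    for (bstart in seq.int(1L, n, by = batch_size)) {
      idx <- perm[bstart:min(bstart + batch_size - 1L, n)]
      nb <- length(idx)
      if (!.is_bag_kind(model$kind)) {
        fw <- .flat_forward(model, data, idx, train = TRUE)
        l <- bce_with_logits(fw$z, y[idx])
        grads <- .flat_backward(model, fw, l$dz / nb)
        total <- total + l$loss
      } else {
        grads <- NULL
        for (i in idx) {
          if (model$kind == "read_gepse") {
            fw <- .bag_forward_read(model, data$bags[[i]], train = TRUE)
            P <- fw$site_prob
            total <- total - (y[i] * log(P) + (1 - y[i]) * log(1 - P))
            g <- .bag_backward_read(model, fw, y[i])
          } else {
            fw <- .bag_forward_igepse(model, data$bags[[i]], train = TRUE)
            l <- bce_with_logits(fw$z, y[i])
            total <- total + l$loss
            g <- .bag_backward_igepse(model, fw, l$dz)
          }
          grads <- if (is.null(grads)) tree_map2(function(a, .) a / nb, g, g)
                   else tree_scale_add(grads, g, 1 / nb)
        }
      }
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
      model <- .set_params(model, params)
    }
    history[ep] <- total / n
    if (verbose) message(sprintf("epoch %d/%d loss %.4f", ep, epochs, history[ep]))
  }
  model$trained <- TRUE
  model$history <- c(model$history, history)
  model
}

#' Predict site-level probabilities
#'
#' @param object A `geotx_model`.
#' @param data Dataset in the same layout used for training.
#' @param attention If `TRUE` (MIL kinds), also return per-bag attention
#'   weights (or read probabilities for `read_gepse`).
#' @param ... Unused.
#' @return Numeric probabilities, or a list with `prob` and `weights` when
#'   `attention = TRUE`.
#' @export
predict.geotx_model <- function(object, data, attention = FALSE, ...) {
  if (!.is_bag_kind(object$kind)) {
    n <- dim(data[[.flat_inputs(object$kind)[1]]])[1]
    probs <- numeric(n)
    for (bstart in seq.int(1L, n, by = 1024L)) {
      idx <- bstart:min(bstart + 1023L, n)
      fw <- .flat_forward(object, data, idx, train = FALSE)
      probs[idx] <- 1 / (1 + exp(-fw$z))
    }
    return(probs)
  }
  n <- length(data$bags)
  probs <- numeric(n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    if (object$kind == "read_gepse") {
      fw <- .bag_forward_read(object, data$bags[[i]], train = FALSE)
      probs[i] <- fw$site_prob
      wts[[i]] <- fw$read_probs
    } else {
      fw <- .bag_forward_igepse(object, data$bags[[i]], train = FALSE)
      probs[i] <- 1 / (1 + exp(-fw$z))
      wts[[i]] <- fw$weights
    }
  }
  if (attention) list(prob = probs, weights = wts) else probs
}

.subset_data <- function(data, idx) {
  out <- data
  for (nm in c("x_geo", "x_seq"))
    if (!is.null(data[[nm]])) out[[nm]] <- data[[nm]][idx, , , drop = FALSE]
  if (!is.null(data$bags)) out$bags <- data$bags[idx]
  out$y <- data$y[idx]
  out
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label; one model is trained per fold (fold f uses
#' `config$seed + f`) and evaluated on the held-out fold. Predictions for an
#' optional independent dataset are the average over all fold models.
#'
#' @param kind Model kind.
#' @param data Training dataset (see [train_model()]).
#' @param config A [model_config()]; its `kind` must match.
#' @param folds Number of folds (10 for base-resolution site data, 5 for
#'   smaller peak-level datasets).
#' @param independent Optional independent dataset to score.
#' @param ... Passed to [train_model()] (e.g. `epochs`).
#' @return List with `per_fold` (metric data.frame), `mean`, `sd`,
#'   and `independent` (scores + `metric_report`) when requested.
#' @export
cross_validate <- function(kind, data, config = model_config(kind), folds = 10L,
                           independent = NULL, ...) {
  y <- data$y
  n <- length(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  fold_id <- integer(n)
  for (cl in unique(y)) {
    w <- which(y == cl)
    fold_id[w] <- sample(rep_len(seq_len(folds), length(w)))
  }
  per_fold <- NULL
  ind_acc <- NULL
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
      stop("fold ", f, " is single-class; reduce the number of folds")
    cfg <- config
    cfg$seed <- config$seed + f
    model <- build_model(kind, cfg)
    model <- train_model(model, .subset_data(data, tr), ...)
    sc <- predict(model, .subset_data(data, te))
    m <- evaluate(sc, y[te])
    per_fold <- rbind(per_fold, as.data.frame(unclass(m)))
    if (!is.null(independent)) {
      p <- predict(model, independent)
      ind_acc <- if (is.null(ind_acc)) p else ind_acc + p
    }
  }
  out <- list(per_fold = per_fold,
              mean = colMeans(per_fold),
              sd = apply(per_fold, 2, stats::sd))
  if (!is.null(independent)) {
    sc <- ind_acc / folds
    out$independent <- list(scores = sc, metrics = evaluate(sc, independent$y))
  }
  out
}
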