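# 3D DenseNet feature extractor, implemented directly on dense arrays.
# Activations are 5-D arrays (D, H, W, C, N); convolutions go through a
# vol2col expansion so every layer reduces to matrix algebra. Backward
# passes are hand-derived and verified against finite differences in the
# test suite.

#' DenseNet configuration
#'
#' Architecture and training protocol of the volumetric feature extractor.
#' Defaults reproduce the reference design: a 3x3x3 stem convolution,
#' three dense blocks of three units each (bottleneck 1x1x1 with 48
#' channels, then 3x3x3 with growth-rate 12 channels), transition layers
#' with compression 0.5 and stride-2 average pooling between blocks, and a
#' head of two fully connected layers (512 and 256 units). Training uses
#' Adam at learning rate 1e-4, batch size 64, at most 200 epochs, early
#' stopping after 30 epochs without validation-loss improvement, and class
#' weights inversely proportional to training-class frequency. Reduced
#' settings (small `input_shape`, fewer blocks/channels) give a network
#' that trains in seconds for tests.
#'
#' @param input_shape 3 positive integers (default `c(64, 64, 64)`).
#' @param n_blocks Number of dense blocks.
#' @param units_per_block Dense units per block.
#' @param growth_rate Channels added by each dense unit.
#' @param bottleneck_channels Channels of the 1x1x1 bottleneck convolution.
#' @param compression Transition-layer channel compression in (0, 1].
#' @param stem_channels Channels of the initial convolution (2x growth by
#'   convention).
#' @param stem_bn Apply batch-norm + ReLU right after the stem convolution
#'   (the reference design leaves normalization to the pre-activation
#'   units; both variants are available).
#' @param stem_pool Stride-2 average pooling after the stem.
#' @param fc_sizes Widths of the two fully connected layers; the first is
#'   the embedding dimension.
#' @param learning_rate,batch_size,max_epochs,patience Training protocol.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A `densenet_config` list.
#' @export
densenet_config <- function(input_shape = c(64, 64, 64), n_blocks = 3,
                            units_per_block = 3, growth_rate = 12,
                            bottleneck_channels = 48, compression = 0.5,
                            stem_channels = 2 * growth_rate,
                            stem_bn = FALSE, stem_pool = FALSE,
                            fc_sizes = c(512, 256), learning_rate = 1e-4,
                            batch_size = 64, max_epochs = 200, patience = 30,
                            seed = 1) {
  if (compression <= 0 || compression > 1) abort("`compression` must be in (0, 1].")
  if (growth_rate < 1) abort("`growth_rate` must be at least 1.")
  if (length(fc_sizes) != 2) abort("`fc_sizes` must give two widths.")
  if (length(input_shape) != 3 || any(input_shape < 1)) {
    abort("`input_shape` must be 3 positive integers.")
  }
  structure(list(input_shape = as.integer(input_shape),
                 n_blocks = as.integer(n_blocks),
                 units_per_block = as.integer(units_per_block),
                 growth_rate = as.integer(growth_rate),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 compression = compression,
                 stem_channels = as.integer(stem_channels),
                 stem_bn = stem_bn, stem_pool = stem_pool,
                 fc_sizes = as.integer(fc_sizes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "densenet_config")
}

# ---- array <-> matrix views ------------------------------------------------

# (D,H,W,C,N) -> (D*H*W*N, C): channels as columns, spatial-then-sample rows.
as_channel_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 3, 5, 4)), prod(d[c(1, 2, 3, 5)]), d[4])
}

from_channel_matrix <- function(m, dims) {
  aperm(array(m, dims[c(1, 2, 3, 5, 4)]), c(1, 2, 3, 5, 4))
}

# ---- convolution -----------------------------------------------------------

# Expand x (D,H,W,C,N) into a (D*H*W*N, k^3*C) patch matrix, same padding.
# Column order matches a weight array of dim (k,k,k,Cin,Cout) flattened to
# (k^3*Cin, Cout): kernel offsets fastest, input channel slowest.
vol2col <- function(x, k) {
  d <- dim(x); D <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]; N <- d[5]
  if (k == 1) return(as_channel_matrix(x))
  p <- (k - 1) %/% 2
  xp <- array(0, c(D + 2 * p, H + 2 * p, W + 2 * p, C, N))
  xp[p + seq_len(D), p + seq_len(H), p + seq_len(W), , ] <- x
  cols <- matrix(0, D * H * W * N, k^3 * C)
  col <- 0L
  for (cc in seq_len(C)) for (l in seq_len(k)) for (j in seq_len(k)) for (i in seq_len(k)) {
    col <- col + 1L
    cols[, col] <- xp[i + seq_len(D) - 1L, j + seq_len(H) - 1L,
                      l + seq_len(W) - 1L, cc, ]
  }
  cols
}

# Scatter-add the patch-matrix gradient back onto the input array.
col2vol <- function(dcols, dims, k) {
  D <- dims[1]; H <- dims[2]; W <- dims[3]; C <- dims[4]; N <- dims[5]
  if (k == 1) return(from_channel_matrix(dcols, dims))
  p <- (k - 1) %/% 2
  dxp <- array(0, c(D + 2 * p, H + 2 * p, W + 2 * p, C, N))
  col <- 0L
  for (cc in seq_len(C)) for (l in seq_len(k)) for (j in seq_len(k)) for (i in seq_len(k)) {
    col <- col + 1L
    di <- i + seq_len(D) - 1L; dj <- j + seq_len(H) - 1L; dl <- l + seq_len(W) - 1L
    dxp[di, dj, dl, cc, ] <- dxp[di, dj, dl, cc, ] +
      array(dcols[, col], c(D, H, W, N))
  }
  dxp[p + seq_len(D), p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

conv_forward <- function(x, layer) {
  d <- dim(x)
  k <- conv_k(layer)
  cols <- vol2col(x, k)
  out_mat <- cols %*% layer$W
  out_mat <- sweep(out_mat, 2, layer$b, "+")
  out <- aperm(array(out_mat, c(d[1:3], d[5], ncol(layer$W))), c(1, 2, 3, 5, 4))
  list(out = out, cache = list(cols = cols, in_dims = d, k = k))
}

conv_backward <- function(dout, layer, cache) {
  d <- dim(dout)
  dout_mat <- matrix(aperm(dout, c(1, 2, 3, 5, 4)), prod(d[c(1, 2, 3, 5)]), d[4])
  dW <- crossprod(cache$cols, dout_mat)
  db <- colSums(dout_mat)
  dcols <- dout_mat %*% t(layer$W)
  dx <- col2vol(dcols, cache$in_dims, cache$k)
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- batch normalization ---------------------------------------------------

bn_forward <- function(x, layer, buffers, training, eps = 1e-5, momentum = 0.9) {
  dims <- dim(x)
  xm <- as_channel_matrix(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    buffers$mean <- momentum * buffers$mean + (1 - momentum) * mu
    buffers$var <- momentum * buffers$var + (1 - momentum) * v
  } else {
    mu <- buffers$mean
    v <- buffers$var
    xc <- sweep(xm, 2, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(out = from_channel_matrix(ym, dims), buffers = buffers,
       cache = list(xhat = xhat, istd = istd, dims = dims))
}

bn_backward <- function(dout, layer, cache) {
  dym <- as_channel_matrix(dout)
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, layer$gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2, cache$istd, "*")
  list(dx = from_channel_matrix(dxm, cache$dims),
       grads = list(gamma = dgamma, beta = dbeta))
}

# ---- pooling ---------------------------------------------------------------

pool_forward <- function(x) {
  d <- dim(x)
  if (any(d[1:3] %% 2 != 0)) {
    abort("Spatial dimensions must be even at each pooling step; input shape is too small or odd for the pooling schedule.")
  }
  s <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    s <- s + x[seq(1 + a, d[1], 2), seq(1 + b, d[2], 2),
               seq(1 + cc, d[3], 2), , , drop = FALSE]
  }
  list(out = s / 8, cache = list(in_dims = d))
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dims
  dx <- array(0, d)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    dx[seq(1 + a, d[1], 2), seq(1 + b, d[2], 2),
       seq(1 + cc, d[3], 2), , ] <- dout / 8
  }
  dx
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

flatten_forward <- function(x) {
  d <- dim(x)
  list(out = t(matrix(x, prod(d[1:4]), d[5])), cache = d)
}
flatten_backward <- function(dout, cache) array(t(dout), cache)

fc_forward <- function(x, layer) {
  list(out = sweep(x %*% layer$W, 2, layer$b, "+"), cache = x)
}
fc_backward <- function(dout, layer, cache) {
  list(dx = dout %*% t(layer$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

# ---- architecture ----------------------------------------------------------

#' Build the DenseNet model specification
#'
#' Resolves the configuration into an explicit layer plan and a
#' hand-checkable shape table: the stem convolution, `n_blocks` dense
#' blocks (each unit concatenating `growth_rate` new channels onto the
#' running feature stack) separated by compressing transition layers, a
#' final batch-norm + ReLU, and the fully connected head. Validates that
#' the pooling schedule fits the input shape.
#'
#' @param config A [densenet_config()].
#' @return A `densenet_spec`: `config`, `shape_table` (tibble: `stage`,
#'   `d`, `h`, `w`, `channels`, `n_params`), `n_classes_slot` filled at
#'   training time.
#' @export
build_extractor <- function(config) {
  stopifnot(inherits(config, "densenet_config"))
  shp <- config$input_shape
  ch <- config$stem_channels
  rows <- list(tibble(stage = "input", d = shp[1], h = shp[2], w = shp[3],
                      channels = 1, n_params = 0))
  conv_params <- function(k, cin, cout) k^3 * cin * cout + cout
  add_row <- function(stage, ch, np) {
    rows[[length(rows) + 1]] <<- tibble(stage = stage, d = shp[1], h = shp[2],
                                        w = shp[3], channels = ch, n_params = np)
  }
  add_row("stem_conv", ch, conv_params(3, 1, ch))
  if (config$stem_bn) add_row("stem_bn", ch, 2 * ch)
  if (config$stem_pool) {
    if (any(shp %% 2 != 0)) abort("`input_shape` incompatible with stem pooling.")
    shp <- shp %/% 2
    add_row("stem_pool", ch, 0)
  }
  for (b in seq_len(config$n_blocks)) {
    np <- 0
    for (u in seq_len(config$units_per_block)) {
      np <- np + 2 * ch + conv_params(1, ch, config$bottleneck_channels) +
        2 * config$bottleneck_channels +
        conv_params(3, config$bottleneck_channels, config$growth_rate)
      ch <- ch + config$growth_rate
    }
    add_row(paste0("dense_block_", b), ch, np)
    if (b < config$n_blocks) {
      cout <- floor(ch * config$compression)
      np <- 2 * ch + conv_params(1, ch, cout)
      if (any(shp %% 2 != 0) || any(shp < 2)) {
        abort("`input_shape` too small for the pooling schedule.")
      }
      ch <- cout
      shp <- shp %/% 2
      add_row(paste0("transition_", b), ch, np)
    }
  }
  add_row("final_bn", ch, 2 * ch)
  flat <- prod(shp) * ch
  rows[[length(rows) + 1]] <- tibble(stage = "flatten", d = 1, h = 1, w = 1,
                                     channels = flat, n_params = 0)
  rows[[length(rows) + 1]] <- tibble(stage = "fc1", d = 1, h = 1, w = 1,
                                     channels = config$fc_sizes[1],
                                     n_params = flat * config$fc_sizes[1] + config$fc_sizes[1])
  rows[[length(rows) + 1]] <- tibble(stage = "fc2", d = 1, h = 1, w = 1,
                                     channels = config$fc_sizes[2],
                                     n_params = prod(config$fc_sizes) + config$fc_sizes[2])
  structure(list(config = config, shape_table = bind_rows(rows)),
            class = "densenet_spec")
}

#' @export
print.densenet_spec <- function(x, ...) {
  cat("densenet_spec (", sum(x$shape_table$n_params),
      " parameters before the output head)\n", sep = "")
  print(x$shape_table, n = Inf)
  invisible(x)
}

he_conv <- function(k, cin, cout) {
  matrix(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))), k^3 * cin, cout)
}

# Kernel size rides along as an attribute so the parameter tree flattens
# to weights only.
new_conv <- function(k, cin, cout) {
  structure(list(W = he_conv(k, cin, cout), b = rep(0, cout)), k = k)
}
conv_k <- function(layer) attr(layer, "k")
new_bn <- function(ch) list(gamma = rep(1, ch), beta = rep(0, ch))
new_bn_buffers <- function(ch) list(mean = rep(0, ch), var = rep(1, ch))
new_fc <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))
  list(W = matrix(runif(din * dout, -lim, lim), din, dout), b = rep(0, dout))
}

# Allocate parameters and batch-norm buffers for a spec. Called inside
# with_seed() by train_extractor().
densenet_init <- function(spec, n_classes) {
  cfg <- spec$config
  ch <- cfg$stem_channels
  params <- list(stem = new_conv(3, 1, ch))
  buffers <- list()
  if (cfg$stem_bn) {
    params$stem_bn <- new_bn(ch)
    buffers$stem_bn <- new_bn_buffers(ch)
  }
  params$blocks <- list()
  buffers$blocks <- list()
  for (b in seq_len(cfg$n_blocks)) {
    units <- list(); ubuf <- list()
    for (u in seq_len(cfg$units_per_block)) {
      units[[u]] <- list(bn1 = new_bn(ch),
                         conv1 = new_conv(1, ch, cfg$bottleneck_channels),
                         bn2 = new_bn(cfg$bottleneck_channels),
                         conv3 = new_conv(3, cfg$bottleneck_channels, cfg$growth_rate))
      ubuf[[u]] <- list(bn1 = new_bn_buffers(ch),
                        bn2 = new_bn_buffers(cfg$bottleneck_channels))
      ch <- ch + cfg$growth_rate
    }
    params$blocks[[b]] <- units
    buffers$blocks[[b]] <- ubuf
    if (b < cfg$n_blocks) {
      cout <- floor(ch * cfg$compression)
      params$trans[[b]] <- list(bn = new_bn(ch), conv = new_conv(1, ch, cout))
      buffers$trans[[b]] <- list(bn = new_bn_buffers(ch))
      ch <- cout
    }
  }
  params$final_bn <- new_bn(ch)
  buffers$final_bn <- new_bn_buffers(ch)
  flat <- spec$shape_table$channels[spec$shape_table$stage == "flatten"]
  params$fc1 <- new_fc(flat, cfg$fc_sizes[1])
  params$fc2 <- new_fc(cfg$fc_sizes[1], cfg$fc_sizes[2])
  params$out <- new_fc(cfg$fc_sizes[2], n_classes)
  list(params = params, buffers = buffers)
}

concat_channels <- function(x, y) {
  d <- dim(x); g <- dim(y)[4]
  out <- array(0, c(d[1:3], d[4] + g, d[5]))
  out[, , , seq_len(d[4]), ] <- x
  out[, , , d[4] + seq_len(g), ] <- y
  out
}

dense_unit_forward <- function(x, p, buf, training) {
  c1 <- bn_forward(x, p$bn1, buf$bn1, training); buf$bn1 <- c1$buffers
  r1 <- relu_forward(c1$out)
  c2 <- conv_forward(r1$out, p$conv1)
  c3 <- bn_forward(c2$out, p$bn2, buf$bn2, training); buf$bn2 <- c3$buffers
  r2 <- relu_forward(c3$out)
  c4 <- conv_forward(r2$out, p$conv3)
  list(out = concat_channels(x, c4$out), buffers = buf,
       cache = list(bn1 = c1$cache, r1 = r1$cache, conv1 = c2$cache,
                    bn2 = c3$cache, r2 = r2$cache, conv3 = c4$cache,
                    cin = dim(x)[4]))
}

dense_unit_backward <- function(dout, p, cache) {
  cin <- cache$cin
  dx_skip <- dout[, , , seq_len(cin), , drop = FALSE]
  dnew <- dout[, , , -seq_len(cin), , drop = FALSE]
  b4 <- conv_backward(dnew, p$conv3, cache$conv3)
  dr2 <- relu_backward(b4$dx, cache$r2)
  b3 <- bn_backward(dr2, p$bn2, cache$bn2)
  b2 <- conv_backward(b3$dx, p$conv1, cache$conv1)
  dr1 <- relu_backward(b2$dx, cache$r1)
  b1 <- bn_backward(dr1, p$bn1, cache$bn1)
  list(dx = dx_skip + b1$dx,
       grads = list(bn1 = b1$grads, conv1 = b2$grads,
                    bn2 = b3$grads, conv3 = b4$grads))
}

transition_forward <- function(x, p, buf, training) {
  c1 <- bn_forward(x, p$bn, buf$bn, training); buf$bn <- c1$buffers
  r1 <- relu_forward(c1$out)
  c2 <- conv_forward(r1$out, p$conv)
  pl <- pool_forward(c2$out)
  list(out = pl$out, buffers = buf,
       cache = list(bn = c1$cache, r = r1$cache, conv = c2$cache, pool = pl$cache))
}

transition_backward <- function(dout, p, cache) {
  dp <- pool_backward(dout, cache$pool)
  b2 <- conv_backward(dp, p$conv, cache$conv)
  dr <- relu_backward(b2$dx, cache$r)
  b1 <- bn_backward(dr, p$bn, cache$bn)
  list(dx = b1$dx, grads = list(bn = b1$grads, conv = b2$grads))
}

# Full forward pass. x: (D,H,W,1,N). Returns logits, the post-ReLU first
# fully connected activations (the subject embedding), caches for
# backprop, and (in training mode) updated batch-norm buffers.
densenet_forward <- function(net, x, training = FALSE) {
  p <- net$params; buf <- net$buffers; cfg <- net$config
  caches <- list()
  st <- conv_forward(x, p$stem); caches$stem <- st$cache
  h <- st$out
  if (cfg$stem_bn) {
    sb <- bn_forward(h, p$stem_bn, buf$stem_bn, training)
    buf$stem_bn <- sb$buffers
    sr <- relu_forward(sb$out)
    caches$stem_bn <- sb$cache; caches$stem_relu <- sr$cache
    h <- sr$out
  }
  if (cfg$stem_pool) {
    sp <- pool_forward(h); caches$stem_pool <- sp$cache; h <- sp$out
  }
  caches$blocks <- list(); caches$trans <- list()
  for (b in seq_along(p$blocks)) {
    caches$blocks[[b]] <- list()
    for (u in seq_along(p$blocks[[b]])) {
      r <- dense_unit_forward(h, p$blocks[[b]][[u]], buf$blocks[[b]][[u]], training)
      buf$blocks[[b]][[u]] <- r$buffers
      caches$blocks[[b]][[u]] <- r$cache
      h <- r$out
    }
    if (b < length(p$blocks)) {
      r <- transition_forward(h, p$trans[[b]], buf$trans[[b]], training)
      buf$trans[[b]] <- r$buffers
      caches$trans[[b]] <- r$cache
      h <- r$out
    }
  }
  fb <- bn_forward(h, p$final_bn, buf$final_bn, training)
  buf$final_bn <- fb$buffers
  fr <- relu_forward(fb$out)
  caches$final_bn <- fb$cache; caches$final_relu <- fr$cache
  fl <- flatten_forward(fr$out); caches$flatten <- fl$cache
  f1 <- fc_forward(fl$out, p$fc1); caches$fc1 <- f1$cache
  a1 <- relu_forward(f1$out); caches$a1 <- a1$cache
  f2 <- fc_forward(a1$out, p$fc2); caches$fc2 <- f2$cache
  a2 <- relu_forward(f2$out); caches$a2 <- a2$cache
  fo <- fc_forward(a2$out, p$out); caches$out <- fo$cache
  list(logits = fo$out, embedding = a1$out, caches = caches, buffers = buf)
}

densenet_backward <- function(net, caches, dlogits) {
  p <- net$params
  grads <- list()
  bo <- fc_backward(dlogits, p$out, caches$out); grads$out <- bo$grads
  da2 <- relu_backward(bo$dx, caches$a2)
  b2 <- fc_backward(da2, p$fc2, caches$fc2); grads$fc2 <- b2$grads
  da1 <- relu_backward(b2$dx, caches$a1)
  b1 <- fc_backward(da1, p$fc1, caches$fc1); grads$fc1 <- b1$grads
  dh <- flatten_backward(b1$dx, caches$flatten)
  dh <- relu_backward(dh, caches$final_relu)
  bfb <- bn_backward(dh, p$final_bn, caches$final_bn); grads$final_bn <- bfb$grads
  dh <- bfb$dx
  grads$blocks <- vector("list", length(p$blocks))
  grads$trans <- vector("list", length(p$trans))
  for (b in rev(seq_along(p$blocks))) {
    if (b < length(p$blocks)) {
      tb <- transition_backward(dh, p$trans[[b]], caches$trans[[b]])
      grads$trans[[b]] <- tb$grads
      dh <- tb$dx
    }
    grads$blocks[[b]] <- vector("list", length(p$blocks[[b]]))
    for (u in rev(seq_along(p$blocks[[b]]))) {
      ub <- dense_unit_backward(dh, p$blocks[[b]][[u]], caches$blocks[[b]][[u]])
      grads$blocks[[b]][[u]] <- ub$grads
      dh <- ub$dx
    }
  }
  if (net$config$stem_pool) dh <- pool_backward(dh, caches$stem_pool)
  if (net$config$stem_bn) {
    dh <- relu_backward(dh, caches$stem_relu)
    bsb <- bn_backward(dh, p$stem_bn, caches$stem_bn)
    grads$stem_bn <- bsb$grads
    dh <- bsb$dx
  }
  bst <- conv_backward(dh, p$stem, caches$stem)
  grads$stem <- bst$grads
  grads
}

# Class-weighted softmax cross-entropy. `class_weights` is a per-class
# vector; the loss is sum_i w[y_i] * ce_i / sum_i w[y_i].
weighted_ce <- function(logits, y_idx, class_weights) {
  probs <- row_softmax(logits)
  n <- nrow(logits)
  w <- class_weights[y_idx]
  p <- probs[cbind(seq_len(n), y_idx)]
  loss <- sum(w * -log(pmax(p, 1e-12))) / sum(w)
  y_onehot <- matrix(0, n, ncol(logits))
  y_onehot[cbind(seq_len(n), y_idx)] <- 1
  dlogits <- (probs - y_onehot) * w / sum(w)
  list(loss = loss, dlogits = dlogits, probs = probs)
}

volumes_to_batch <- function(vols, ids) {
  shape <- dim(vols$volumes[[ids[1]]])
  x <- array(0, c(shape, 1, length(ids)))
  for (i in seq_along(ids)) x[, , , 1, i] <- vols$volumes[[ids[i]]]
  x
}

#' Class weights inversely proportional to training frequency
#'
#' `w_c = n / (k * n_c)` for `k` classes, so weight ratios are the inverse
#' of the class-count ratios and the mean weight over the training rows'
#' classes is balanced.
#'
#' @param labels Training labels (character/factor).
#' @param class_order Class order for the returned vector.
#' @return Named numeric vector of per-class weights.
#' @examples
#' balanced_class_weights(rep(c("A", "B"), c(10, 40)), c("A", "B"))
#' @export
balanced_class_weights <- function(labels, class_order) {
  counts <- table(factor(labels, levels = class_order))
  if (any(counts == 0)) {
    abort(paste0("Class absent from the training labels: ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  w <- sum(counts) / (length(counts) * as.numeric(counts))
  setNames(w, class_order)
}

#' Train the DenseNet feature extractor
#'
#' Minimizes class-weighted softmax cross-entropy with Adam on the
#' training split, evaluates loss on the validation split after each
#' epoch, stops at `max_epochs` or after `patience` epochs without
#' validation-loss improvement, and restores the best-validation weights.
#' Pass `init` (a previous fit) to transfer-initialize a harder task from
#' an easier one. Deterministic given `config$seed`.
#'
#' @param volumes A `volume_set`.
#' @param labels Named vector id -> class.
#' @param split Named vector id -> `{train, val, test}`.
#' @param config A [densenet_config()].
#' @param init Optional `densenet_model` whose weights warm-start
#'   training (architecture and class count must match).
#' @param class_order Class order of the output units; default sorted
#'   training classes.
#' @return A `densenet_model`: `params`, `buffers`, `config`, `classes`,
#'   `history` (tibble: epoch, train_loss, train_acc, val_loss, val_acc),
#'   `best_epoch`.
#' @export
train_extractor <- function(volumes, labels, split, config, init = NULL,
                            class_order = NULL) {
  stopifnot(inherits(volumes, "volume_set"), inherits(config, "densenet_config"))
  if (!all(dim(volumes$volumes[[1]]) == config$input_shape)) {
    abort("Volume shape does not match `config$input_shape`.")
  }
  ids_train <- volumes$ids[split[volumes$ids] == "train"]
  ids_val <- volumes$ids[split[volumes$ids] == "val"]
  y_train <- as.character(labels[ids_train])
  if (is.null(class_order)) class_order <- sort(unique(y_train))
  cw <- balanced_class_weights(y_train, class_order)
  spec <- build_extractor(config)
  net <- with_seed(config$seed, {
    st <- densenet_init(spec, length(class_order))
    if (!is.null(init)) {
      if (!identical(dim(init$params$out$W), dim(st$params$out$W))) {
        abort("Transfer weights have a different architecture or class count.")
      }
      st$params <- init$params
      st$buffers <- init$buffers
    }
    list(params = st$params, buffers = st$buffers, config = config)
  })
  y_idx_of <- function(ids) match(as.character(labels[ids]), class_order)
  batch_loss <- function(net, ids) {
    # inference-mode loss/accuracy over ids, in batches
    tot <- 0; correct <- 0
    for (chunk in split(ids, ceiling(seq_along(ids) / config$batch_size))) {
      x <- volumes_to_batch(volumes, chunk)
      fwd <- densenet_forward(net, x, training = FALSE)
      wc <- weighted_ce(fwd$logits, y_idx_of(chunk), cw)
      tot <- tot + wc$loss * length(chunk)
      correct <- correct + sum(max.col(wc$probs, ties.method = "first") ==
                                 y_idx_of(chunk))
    }
    list(loss = tot / length(ids), acc = correct / length(ids))
  }
  history <- list()
  with_seed(derive_seed(config$seed, 11L), {
    pvec <- tree_flatten(net$params)
    mvec <- pvec * 0; vvec <- pvec * 0; tstep <- 0
    best <- list(loss = Inf, params = net$params, buffers = net$buffers, epoch = 0L)
    since <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      order_ids <- sample(ids_train)
      ep_loss <- 0
      for (chunk in split(order_ids, ceiling(seq_along(order_ids) / config$batch_size))) {
        x <- volumes_to_batch(volumes, chunk)
        fwd <- densenet_forward(net, x, training = TRUE)
        net$buffers <- fwd$buffers
        wc <- weighted_ce(fwd$logits, y_idx_of(chunk), cw)
        ep_loss <- ep_loss + wc$loss * length(chunk)
        grads <- densenet_backward(net, fwd$caches, wc$dlogits)
        gvec <- tree_flatten(grads[names(net$params)])
        pvec <- tree_flatten(net$params)
        tstep <- tstep + 1
        mvec <- 0.9 * mvec + 0.1 * gvec
        vvec <- 0.999 * vvec + 0.001 * gvec^2
        pvec <- pvec - config$learning_rate *
          (mvec / (1 - 0.9^tstep)) / (sqrt(vvec / (1 - 0.999^tstep)) + 1e-8)
        net$params <- tree_unflatten(pvec, net$params)
      }
      tr <- batch_loss(net, ids_train)
      va <- if (length(ids_val) > 0) batch_loss(net, ids_val) else tr
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = tr$loss, train_acc = tr$acc,
                                 val_loss = va$loss, val_acc = va$acc)
      if (va$loss < best$loss - 1e-12) {
        best <- list(loss = va$loss, params = net$params,
                     buffers = net$buffers, epoch = epoch)
        since <- 0L
      } else {
        since <- since + 1L
        if (since >= max(config$patience, 1L)) break
      }
    }
  })
  structure(list(params = best$params, buffers = best$buffers, config = config,
                 classes = class_order, history = bind_rows(history),
                 best_epoch = best$epoch, spec = spec),
            class = "densenet_model")
}

#' @export
print.densenet_model <- function(x, ...) {
  cat("densenet_model: classes ", paste(x$classes, collapse = "/"),
      ", ", length(unlist(x$params)), " parameters, trained ",
      nrow(x$history), " epochs (best at ", x$best_epoch, ")\n", sep = "")
  invisible(x)
}

#' Extract per-subject embeddings
#'
#' Runs the trained network in inference mode and returns the post-ReLU
#' activations of the first fully connected layer — the subject embedding
#' used as population-graph node features. Pure: repeated calls on the
#' same inputs are bit-identical.
#'
#' @param model A `densenet_model`.
#' @param volumes A `volume_set` with the model's input shape.
#' @param batch_size Subjects per forward batch.
#' @return Matrix, subjects x `fc_sizes[1]`, rownames = subject ids.
#' @export
extract_features <- function(model, volumes, batch_size = 16) {
  stopifnot(inherits(model, "densenet_model"), inherits(volumes, "volume_set"))
  if (!all(dim(volumes$volumes[[1]]) == model$config$input_shape)) {
    abort("Volume shape does not match the model's input shape.")
  }
  net <- list(params = model$params, buffers = model$buffers,
              config = model$config)
  out <- matrix(0, length(volumes$ids), model$config$fc_sizes[1])
  rownames(out) <- volumes$ids
  for (chunk in split(volumes$ids, ceiling(seq_along(volumes$ids) / batch_size))) {
    x <- volumes_to_batch(volumes, chunk)
    fwd <- densenet_forward(net, x, training = FALSE)
    if (any(!is.finite(fwd$embedding))) abort("Non-finite embedding values.")
    out[chunk, ] <- fwd$embedding
  }
  colnames(out) <- sprintf("f%03d", seq_len(ncol(out)))
  out
}

#' Serialize / load a trained DenseNet
#'
#' Writes a single JSON checkpoint embedding the configuration, class
#' order, flattened weights and batch-norm buffers, and the training
#' history as CSV next to it.
#'
#' @param model A `densenet_model`.
#' @param path Checkpoint file path (`.json`).
#' @export
write_extractor <- function(model, path) {
  obj <- list(config = unclass(model$config), classes = model$classes,
              params = tree_flatten(model$params),
              buffers = tree_flatten(model$buffers),
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  readr::write_csv(model$history, sub("\\.json$", "_history.csv", path))
  invisible(path)
}

#' @rdname write_extractor
#' @export
read_extractor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(densenet_config, obj$config[setdiff(names(obj$config), character())])
  spec <- build_extractor(cfg)
  skel <- with_seed(1L, densenet_init(spec, length(obj$classes)))
  params <- tree_unflatten(as.numeric(obj$params), skel$params)
  buffers <- tree_unflatten(as.numeric(obj$buffers), skel$buffers)
  hist_path <- sub("\\.json$", "_history.csv", path)
  history <- if (file.exists(hist_path)) {
    readr::read_csv(hist_path, show_col_types = FALSE)
  } else tibble()
  structure(list(params = params, buffers = buffers, config = cfg,
                 classes = obj$classes, history = history,
                 best_epoch = obj$best_epoch, spec = spec),
            class = "densenet_model")
}
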