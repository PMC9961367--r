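#' GCN hyper-parameters
#'
#' Defaults follow the reference protocol: 32 hidden units, dropout 0.5 on
#' both layer inputs, Adam, at most 500 epochs with early stopping once
#' validation accuracy has not improved for 20 epochs (best-validation
#' weights are restored).
#'
#' @param hidden_units First-layer width.
#' @param dropout Dropout fraction in `[0, 1)`, applied to the input
#'   features and the hidden activations during training only.
#' @param learning_rate Adam step size (reference values: 1e-3 for the
#'   demographic-edge experiment, 1e-4 for the neuropsychological-edge
#'   and three-class experiments).
#' @param max_epochs,patience Stopping controls.
#' @param n_classes 2 or 3.
#' @param seed Integer seed covering initialization and dropout.
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(hidden_units = 32, dropout = 0.5,
                       learning_rate = 1e-3, max_epochs = 500,
                       patience = 20, n_classes = 2, seed = 1) {
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  if (!n_classes %in% c(2, 3)) abort("`n_classes` must be 2 or 3.")
  structure(list(hidden_units = as.integer(hidden_units), dropout = dropout,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "gcn_config")
}

#' Symmetric renormalized propagation operator
#'
#' Adds a self-loop to every node and symmetrically normalizes by the
#' resulting degrees: `S = Dhat^(-1/2) (A + I) Dhat^(-1/2)` with
#' `Dhat = diag(rowSums(A + I))`. The self-loop guarantees strictly
#' positive degrees, so `S` is always finite, symmetric, with spectral
#' radius at most 1.
#'
#' @param A Symmetric nonnegative adjacency with zero diagonal (matrix or
#'   `population_graph`).
#' @return The n x n propagation matrix `S`.
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2)) # all entries 0.5
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "population_graph")) A <- A$A
  if (!isSymmetric(unname(A), tol = 1e-8)) abort("`A` must be symmetric.")
  if (any(A < 0)) abort("`A` must be nonnegative.")
  if (any(diag(A) != 0)) abort("`A` must have a zero diagonal.")
  ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(ahat))
  s <- ahat * tcrossprod(dinv)
  if (any(!is.finite(s))) abort("Non-finite propagation operator.")
  s
}

# Glorot-uniform weight initialization.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

gcn_init_weights <- function(d, config) {
  list(W0 = glorot(d, config$hidden_units),
       b0 = rep(0, config$hidden_units),
       W1 = glorot(config$hidden_units, config$n_classes),
       b1 = rep(0, config$n_classes))
}

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the two-layer GCN
#'
#' `H1 = ReLU(S X W0 + b0)`; output `= softmax(S H1 W1 + b1)` row-wise.
#' Dropout (inverted, on `X` and `H1`) is applied only when
#' `training = TRUE`; at inference the pass is deterministic.
#'
#' @param weights List `W0`, `b0`, `W1`, `b1`.
#' @param S Propagation operator from [normalize_adjacency()].
#' @param X Node feature matrix.
#' @param training Apply dropout?
#' @param dropout Dropout fraction used when `training`.
#' @return List: `probs` (n x k, rows sum to 1) plus the intermediates
#'   needed for backprop (`Z1`, `H1d`, `Xd`, dropout masks).
#' @export
gcn_forward <- function(weights, S, X, training = FALSE, dropout = 0) {
  keep <- 1 - dropout
  if (training && dropout > 0) {
    mask_x <- matrix(runif(length(X)) < keep, nrow(X), ncol(X)) / keep
    xd <- X * mask_x
  } else {
    mask_x <- NULL
    xd <- X
  }
  z1 <- S %*% (xd %*% weights$W0)
  z1 <- sweep(z1, 2, weights$b0, "+")
  h1 <- pmax(z1, 0)
  if (training && dropout > 0) {
    mask_h <- matrix(runif(length(h1)) < keep, nrow(h1), ncol(h1)) / keep
    h1d <- h1 * mask_h
  } else {
    mask_h <- NULL
    h1d <- h1
  }
  z2 <- S %*% (h1d %*% weights$W1)
  z2 <- sweep(z2, 2, weights$b1, "+")
  if (any(!is.finite(z2))) abort("Non-finite GCN activations (exploding weights?).")
  list(probs = row_softmax(z2), Z1 = z1, H1d = h1d, Xd = xd,
       mask_x = mask_x, mask_h = mask_h)
}

# Gradient of the train-node cross-entropy w.r.t. all weights.
# `y_onehot` has zero rows outside the train mask.
gcn_backward <- function(weights, S, fwd, y_onehot, train_mask) {
  n_train <- sum(train_mask)
  dz2 <- (fwd$probs - y_onehot)
  dz2[!train_mask, ] <- 0
  dz2 <- dz2 / n_train
  sh1 <- S %*% fwd$H1d
  dW1 <- crossprod(sh1, dz2)
  db1 <- colSums(dz2)
  dh1d <- (S %*% dz2) %*% t(weights$W1)
  dh1 <- if (is.null(fwd$mask_h)) dh1d else dh1d * fwd$mask_h
  dz1 <- dh1 * (fwd$Z1 > 0)
  sx <- S %*% fwd$Xd
  dW0 <- crossprod(sx, dz1)
  db0 <- colSums(dz1)
  list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1)
}

gcn_loss <- function(probs, y_idx, mask) {
  idx <- which(mask)
  p <- probs[cbind(idx, y_idx[idx])]
  -mean(log(pmax(p, 1e-12)))
}

# One Adam update over a flat list of parameter arrays.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

#' Train the GCN transductively on a population graph
#'
#' The whole graph — labeled training and validation nodes plus unlabeled
#' test nodes — enters every forward pass; the cross-entropy loss is
#' restricted to training nodes. Full-batch Adam; early stopping monitors
#' validation accuracy with the configured patience and restores the
#' best-validation weights. Deterministic given `config$seed`.
#'
#' @param graph A `population_graph` from [build_graph()].
#' @param labels Named vector (id -> class label) covering at least the
#'   train and val nodes; defaults to the graph's stored diagnoses.
#' @param config A [gcn_config()].
#' @param class_order Class label order defining output units; default
#'   sorted unique labels of the training nodes.
#' @return A `gcn_fit`: weights, config, `classes`, `history` tibble
#'   (epoch, loss, val_acc), `best_epoch`.
#' @export
train_gcn <- function(graph, labels = NULL, config = gcn_config(),
                      class_order = NULL) {
  stopifnot(inherits(graph, "population_graph"))
  if (is.null(labels)) labels <- setNames(graph$diagnosis, graph$ids)
  y <- as.character(labels[graph$ids])
  train_mask <- graph$masks$train
  val_mask <- graph$masks$val
  if (!any(train_mask)) abort("Empty training mask.")
  if (anyNA(y[train_mask | val_mask])) {
    abort("Labels must cover all train and val nodes.")
  }
  if (is.null(class_order)) class_order <- sort(unique(y[train_mask]))
  if (length(class_order) != config$n_classes) {
    abort(sprintf("Config expects %d classes but training labels have %d.",
                  config$n_classes, length(class_order)))
  }
  missing_cl <- setdiff(class_order, y[train_mask])
  if (length(missing_cl) > 0) {
    abort(paste0("Class absent from the training split: ",
                 paste(missing_cl, collapse = ", ")))
  }
  s <- normalize_adjacency(graph$A)
  x <- graph$X
  y_idx <- match(y, class_order)
  y_onehot <- matrix(0, length(y), length(class_order))
  ok <- !is.na(y_idx)
  y_onehot[cbind(which(ok), y_idx[ok])] <- 1

  with_seed(config$seed, {
    weights <- gcn_init_weights(ncol(x), config)
    state <- adam_init(weights)
    best <- list(acc = -Inf, weights = weights, epoch = 0L)
    since_improve <- 0L
    history <- vector("list", config$max_epochs)
    n_epochs <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      fwd <- gcn_forward(weights, s, x, training = TRUE,
                         dropout = config$dropout)
      loss <- gcn_loss(fwd$probs, y_idx, train_mask)
      grads <- gcn_backward(weights, s, fwd, y_onehot, train_mask)
      upd <- adam_step(weights, grads, state, config$learning_rate)
      weights <- upd$params
      state <- upd$state
      eval_fwd <- gcn_forward(weights, s, x, training = FALSE)
      pred <- max.col(eval_fwd$probs, ties.method = "first")
      val_acc <- if (any(val_mask)) {
        mean(pred[val_mask] == y_idx[val_mask])
      } else NA_real_
      history[[epoch]] <- tibble(epoch = epoch, loss = loss, val_acc = val_acc)
      n_epochs <- epoch
      track <- if (is.na(val_acc)) -loss else val_acc
      if (track > best$acc + 1e-12) {
        best <- list(acc = track, weights = weights, epoch = epoch)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= max(config$patience, 1L)) break
      }
    }
  })
  structure(list(weights = best$weights, config = config,
                 classes = class_order,
                 history = bind_rows(history[seq_len(n_epochs)]),
                 best_epoch = best$epoch),
            class = "gcn_fit")
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat("gcn_fit: ", ncol(x$weights$W0), " hidden units, classes ",
      paste(x$classes, collapse = "/"), "; ", nrow(x$history),
      " epochs (best at ", x$best_epoch, ")\n", sep = "")
  invisible(x)
}

#' Predict node labels on a population graph
#'
#' Forward pass with dropout off; the hard label is the arg-max class,
#' with exact ties broken toward the lower class index.
#'
#' @param object A `gcn_fit`.
#' @param graph A `population_graph` with matching feature dimension.
#' @param ... Unused.
#' @return Tibble: `id`, `split`, one `.prob_<class>` column per class,
#'   and `.pred` (predicted label).
#' @export
predict.gcn_fit <- function(object, graph, ...) {
  s <- normalize_adjacency(graph$A)
  fwd <- gcn_forward(object$weights, s, graph$X, training = FALSE)
  probs <- fwd$probs
  colnames(probs) <- paste0(".prob_", object$classes)
  pred_idx <- max.col(probs, ties.method = "first")
  split <- rep(NA_character_, length(graph$ids))
  for (nm in names(graph$masks)) split[graph$masks[[nm]]] <- nm
  bind_cols(tibble(id = graph$ids, split = split),
            as_tibble(probs),
            tibble(.pred = object$classes[pred_idx]))
}

#' Evaluate a fitted GCN on one split of the graph
#'
#' @param fit A `gcn_fit`.
#' @param graph The `population_graph` to score.
#' @param split Which nodes to evaluate (default `"test"`).
#' @param labels Named truth labels; default the graph's diagnoses.
#' @return List: `metrics` ([binary_metrics()] tibble or
#'   [multiclass_metrics()] list) and `confusion`.
#' @export
evaluate_gcn <- function(fit, graph, split = "test", labels = NULL) {
  if (is.null(labels)) labels <- setNames(graph$diagnosis, graph$ids)
  preds <- predict(fit, graph)
  keep <- preds$split == split
  y_true <- as.character(labels[preds$id[keep]])
  y_pred <- preds$.pred[keep]
  cm <- confusion(y_true, y_pred, class_order = fit$classes)
  metrics <- if (length(fit$classes) == 2) binary_metrics(cm) else multiclass_metrics(cm)
  list(metrics = metrics, confusion = cm)
}

#' @export
#' @method glance gcn_fit
#' @rdname train_gcn
#' @param x,... For the broom methods: a `gcn_fit` and unused arguments.
glance.gcn_fit <- function(x, ...) {
  tibble(n_epochs = nrow(x$history),
         best_epoch = x$best_epoch,
         best_val_acc = if (x$best_epoch > 0) {
           100 * x$history$val_acc[x$best_epoch]
         } else NA_real_,
         final_loss = x$history$loss[nrow(x$history)],
         hidden_units = x$config$hidden_units,
         n_classes = x$config$n_classes)
}

#' @export
#' @method tidy gcn_fit
#' @rdname train_gcn
tidy.gcn_fit <- function(x, ...) {
  tibble(layer = c("gc1", "gc1", "gc2", "gc2"),
         term = c("W0", "b0", "W1", "b1"),
         n_parameters = c(length(x$weights$W0), length(x$weights$b0),
                          length(x$weights$W1), length(x$weights$b1)),
         frobenius_norm = c(sqrt(sum(x$weights$W0^2)), sqrt(sum(x$weights$b0^2)),
                            sqrt(sum(x$weights$W1^2)), sqrt(sum(x$weights$b1^2))))
}
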