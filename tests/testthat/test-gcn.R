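test_that("propagation operator matches hand arithmetic and the entrywise oracle", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    a <- matrix(runif(n * n), n); a <- (a + t(a)) / 2; diag(a) <- 0
    s <- normalize_adjacency(a)
    ahat <- a + diag(n)
    dhat <- rowSums(ahat)
    oracle <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) oracle[i, j] <- ahat[i, j] / sqrt(dhat[i] * dhat[j])
    expect_lt(max(abs(s - oracle)), 1e-10)
    expect_equal(s, t(s), tolerance = 1e-12)
    expect_lte(max(abs(eigen(s, symmetric = TRUE, only.values = TRUE)$values)), 1 + 1e-10)
  }
  expect_error(normalize_adjacency(matrix(c(1, 0, 0, 0), 2)), "diagonal")
  expect_error(normalize_adjacency(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
})

test_that("stronger edges increase the off-diagonal propagation weight", {
  s_of <- function(w) normalize_adjacency(matrix(c(0, w, w, 0), 2))[1, 2]
  w <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(sapply(w, s_of)) > 0))
})

test_that("the forward pass degenerates to a per-node network when S = I", {
  set.seed(2)
  x <- matrix(rnorm(12), 4, 3)
  w <- list(W0 = diag(3), b0 = rep(0, 3), W1 = matrix(rnorm(6), 3, 2), b1 = c(0, 0))
  fwd <- gcn_forward(w, diag(4), x)
  expect_equal(fwd$Z1, x, ignore_attr = TRUE)          # Z1 = X when S = I, W0 = I
  expect_equal(pmax(fwd$Z1, 0), pmax(x, 0), ignore_attr = TRUE) # H1 = ReLU(X)
  expect_equal(rowSums(fwd$probs), rep(1, 4), tolerance = 1e-6)
})

test_that("a 2-node forward pass equals scalar arithmetic", {
  # S for an edge weight of 1 is the constant 1/2 matrix
  s <- matrix(0.5, 2, 2)
  x <- rbind(c(2, 0), c(0, 4))
  w <- list(W0 = diag(2), b0 = c(0, 0),
            W1 = rbind(c(1, -1), c(0, 1)), b1 = c(0.5, 0))
  # hand computation: SX = [[1,2],[1,2]]; H1 = ReLU(SX) = same
  # S H1 = [[1,2],[1,2]]; Z2 = [[1*1+2*0+0.5, -1*1+1*2]] = [[1.5, 1]] both rows
  p <- exp(c(1.5, 1)) / sum(exp(c(1.5, 1)))
  fwd <- gcn_forward(w, s, x)
  expect_equal(fwd$probs[1, ], p, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fwd$probs[2, ], p, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  n <- 7; d <- 5; k <- 3
  a <- matrix(runif(n * n), n); a <- (a + t(a)) / 2; diag(a) <- 0
  s <- normalize_adjacency(a)
  x <- matrix(rnorm(n * d), n)
  y_idx <- sample(1:k, n, replace = TRUE)
  mask <- c(rep(TRUE, 4), rep(FALSE, 3))
  y1 <- matrix(0, n, k); y1[cbind(1:n, y_idx)] <- 1; y1[!mask, ] <- 0
  w <- popgraphstager:::gcn_init_weights(d, gcn_config(hidden_units = 4, n_classes = 3))
  lossfun <- function(w) {
    popgraphstager:::gcn_loss(gcn_forward(w, s, x)$probs, y_idx, mask)
  }
  gr <- popgraphstager:::gcn_backward(w, s, gcn_forward(w, s, x), y1, mask)
  eps <- 1e-6
  for (nm in names(w)) {
    num <- w[[nm]] * 0
    for (i in seq_along(num)) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num[i] <- (lossfun(wp) - lossfun(wm)) / (2 * eps)
    }
    expect_lt(max(abs(num - gr[[nm]])), 1e-7)
  }
})

clique_graph <- function(n_per = 10, seed = 3) {
  # two fully connected same-class cliques, no inter-clique edges,
  # strongly separated features
  set.seed(seed)
  n <- 2 * n_per
  ids <- sprintf("c%02d", 1:n)
  cls <- rep(c("CN", "AD"), each = n_per)
  x <- matrix(rnorm(n * 4, sd = 0.1), n)
  x[cls == "AD", 1] <- x[cls == "AD", 1] + 5
  x[cls == "CN", 2] <- x[cls == "CN", 2] + 5
  rownames(x) <- ids
  a <- matrix(0, n, n)
  a[cls == "CN", cls == "CN"] <- 1
  a[cls == "AD", cls == "AD"] <- 1
  diag(a) <- 0
  split <- rep(c("train", "train", "train", "val", "test"), length.out = n_per)
  masks <- lapply(c(train = "train", val = "val", test = "test"),
                  function(s) rep(split, 2) == s)
  structure(list(ids = ids, A = a, X = x, masks = masks, diagnosis = cls,
                 edge_spec = edge_spec("baseline")),
            class = "population_graph")
}

test_that("separable cliques are classified perfectly", {
  g <- clique_graph()
  # nearest-centroid separability oracle before asking the GCN
  cent <- rbind(colMeans(g$X[g$diagnosis == "CN", ]),
                colMeans(g$X[g$diagnosis == "AD", ]))
  d2 <- cbind(rowSums(sweep(g$X, 2, cent[1, ])^2),
              rowSums(sweep(g$X, 2, cent[2, ])^2))
  expect_equal(mean(c("CN", "AD")[max.col(-d2)] == g$diagnosis), 1)
  fit <- train_gcn(g, config = gcn_config(seed = 1, learning_rate = 1e-2,
                                          n_classes = 2))
  ev <- evaluate_gcn(fit, g)
  expect_equal(ev$metrics$acc, 100)
})

test_that("training is deterministic and respects stopping contracts", {
  g <- clique_graph(n_per = 8, seed = 5)
  cfg <- gcn_config(seed = 12, learning_rate = 1e-2, max_epochs = 40)
  f1 <- train_gcn(g, config = cfg)
  f2 <- train_gcn(g, config = cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
  expect_lte(nrow(f1$history), 40)

  f0 <- train_gcn(g, config = gcn_config(seed = 12, patience = 0, max_epochs = 100))
  # patience 0: the run ends at the first epoch that fails to improve
  first_flat <- which(diff(c(-Inf, cummax(f0$history$val_acc))) == 0)[1]
  expect_equal(nrow(f0$history), first_flat)

  expect_error(train_gcn(g, config = gcn_config(n_classes = 3)), "3 classes")
  g_bad <- g
  g_bad$diagnosis[g_bad$masks$train] <- "CN"
  expect_error(train_gcn(g_bad, config = gcn_config(n_classes = 2),
                         class_order = c("CN", "AD")), "AD")
})

test_that("prediction is consistent with the forward pass and breaks ties low", {
  g <- clique_graph(n_per = 6, seed = 9)
  fit <- train_gcn(g, config = gcn_config(seed = 2, learning_rate = 1e-2,
                                          max_epochs = 30))
  preds <- predict(fit, g)
  s <- normalize_adjacency(g$A)
  fwd <- gcn_forward(fit$weights, s, g$X)
  expect_equal(preds$.pred,
               fit$classes[max.col(fwd$probs, ties.method = "first")])
  probs <- as.matrix(preds[, paste0(".prob_", fit$classes)])
  expect_equal(unname(probs), unname(fwd$probs), tolerance = 1e-12)
  # documented tie contract: equal probabilities go to the lower class index
  expect_equal(max.col(matrix(0.5, 1, 2), ties.method = "first"), 1)
})

test_that("relabeling nodes permutes predictions identically", {
  g <- clique_graph(n_per = 6, seed = 21)
  fit <- train_gcn(g, config = gcn_config(seed = 4, learning_rate = 1e-2,
                                          max_epochs = 25))
  perm <- sample(length(g$ids))
  g2 <- g
  g2$ids <- g$ids[perm]; g2$A <- g$A[perm, perm]; g2$X <- g$X[perm, , drop = FALSE]
  g2$diagnosis <- g$diagnosis[perm]
  g2$masks <- lapply(g$masks, function(m) m[perm])
  p1 <- predict(fit, g)
  p2 <- predict(fit, g2)
  expect_equal(p2$.pred, p1$.pred[perm])
})

test_that("broom methods summarize the fit", {
  g <- clique_graph(n_per = 5, seed = 33)
  fit <- train_gcn(g, config = gcn_config(seed = 1, learning_rate = 1e-2,
                                          max_epochs = 15, patience = 15))
  gl <- glance(fit)
  expect_equal(gl$n_classes, 2L)
  expect_equal(gl$n_epochs, nrow(fit$history))
  td <- tidy(fit)
  expect_equal(td$n_parameters,
               c(length(fit$weights$W0), length(fit$weights$b0),
                 length(fit$weights$W1), length(fit$weights$b1)))
})
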