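test_that("the default architecture matches hand-computed shape arithmetic", {
  spec <- build_extractor(densenet_config())
  tab <- spec$shape_table
  ch <- function(stage) tab$channels[tab$stage == stage]
  # stem: 2 x growth = 24 channels; each dense block adds 3 x 12 = 36
  expect_equal(ch("stem_conv"), 24)
  expect_equal(ch("dense_block_1"), 24 + 36)
  expect_equal(ch("transition_1"), floor(60 * 0.5))
  expect_equal(ch("dense_block_2"), 30 + 36)
  expect_equal(ch("transition_2"), floor(66 * 0.5))
  expect_equal(ch("dense_block_3"), 33 + 36)
  # two stride-2 poolings: 64 -> 32 -> 16
  expect_equal(tab$d[tab$stage == "transition_2"], 16)
  expect_equal(ch("flatten"), 16^3 * 69)
  # the embedding layer is the 512-unit first fully connected layer
  expect_equal(ch("fc1"), 512)
  expect_equal(ch("fc2"), 256)
})

test_that("dense-block channel growth holds for arbitrary configs", {
  cfg <- densenet_config(input_shape = c(16, 16, 16), n_blocks = 2,
                         units_per_block = 4, growth_rate = 6,
                         stem_channels = 10, compression = 0.4,
                         fc_sizes = c(20, 10))
  tab <- build_extractor(cfg)$shape_table
  expect_equal(tab$channels[tab$stage == "dense_block_1"], 10 + 4 * 6)
  expect_equal(tab$channels[tab$stage == "transition_1"], floor(34 * 0.4))
  # parameter count of one dense unit: 2 BN params per input channel,
  # bottleneck 1x1x1 conv, 2 BN per bottleneck channel, 3x3x3 growth conv
  c_in <- 10; bott <- cfg$bottleneck_channels; g <- 6
  unit1 <- 2 * c_in + (c_in * bott + bott) + 2 * bott + (27 * bott * g + g)
  c_in2 <- 16
  unit2 <- 2 * c_in2 + (c_in2 * bott + bott) + 2 * bott + (27 * bott * g + g)
  c_in3 <- 22
  unit3 <- 2 * c_in3 + (c_in3 * bott + bott) + 2 * bott + (27 * bott * g + g)
  c_in4 <- 28
  unit4 <- 2 * c_in4 + (c_in4 * bott + bott) + 2 * bott + (27 * bott * g + g)
  expect_equal(tab$n_params[tab$stage == "dense_block_1"],
               unit1 + unit2 + unit3 + unit4)
})

test_that("an input too small for the pooling schedule is rejected", {
  expect_error(build_extractor(densenet_config(input_shape = c(2, 2, 2))),
               "pooling schedule")
  expect_error(build_extractor(densenet_config(input_shape = c(7, 7, 7))),
               "pooling schedule")
  expect_error(densenet_config(compression = 0), "compression")
  expect_error(densenet_config(growth_rate = 0), "growth")
})

test_that("allocated parameters match the shape-table count", {
  cfg <- densenet_config(input_shape = c(8, 8, 8), n_blocks = 2,
                         units_per_block = 2, growth_rate = 4,
                         bottleneck_channels = 8, stem_channels = 8,
                         fc_sizes = c(32, 16))
  spec <- build_extractor(cfg)
  st <- popgraphstager:::with_seed(1, popgraphstager:::densenet_init(spec, 2))
  n_head <- 16 * 2 + 2 # output layer is task-dependent, not in the table
  expect_equal(length(popgraphstager:::tree_flatten(st$params)),
               sum(spec$shape_table$n_params) + n_head)
})

test_that("backpropagation matches finite differences through every layer type", {
  cfg <- densenet_config(input_shape = c(4, 4, 4), n_blocks = 2,
                         units_per_block = 1, growth_rate = 2,
                         bottleneck_channels = 3, stem_channels = 2,
                         stem_bn = TRUE, fc_sizes = c(5, 4), seed = 9)
  spec <- build_extractor(cfg)
  st <- popgraphstager:::with_seed(3, popgraphstager:::densenet_init(spec, 2))
  net <- list(params = st$params, buffers = st$buffers, config = cfg)
  set.seed(14)
  x <- array(rnorm(4 * 4 * 4 * 1 * 3), c(4, 4, 4, 1, 3))
  y <- c(1, 2, 1); cw <- c(1, 1.5)
  lossfun <- function(params) {
    net2 <- net; net2$params <- params
    f <- popgraphstager:::densenet_forward(net2, x, training = TRUE)
    popgraphstager:::weighted_ce(f$logits, y, cw)$loss
  }
  f <- popgraphstager:::densenet_forward(net, x, training = TRUE)
  wc <- popgraphstager:::weighted_ce(f$logits, y, cw)
  gr <- popgraphstager:::densenet_backward(net, f$caches, wc$dlogits)
  gvec <- popgraphstager:::tree_flatten(gr[names(net$params)])
  pvec <- popgraphstager:::tree_flatten(net$params)
  idx <- sort(sample(length(pvec), 80))
  eps <- 1e-5
  num <- sapply(idx, function(i) {
    pp <- pvec; pp[i] <- pp[i] + eps
    pm <- pvec; pm[i] <- pm[i] - eps
    (lossfun(popgraphstager:::tree_unflatten(pp, net$params)) -
       lossfun(popgraphstager:::tree_unflatten(pm, net$params))) / (2 * eps)
  })
  expect_lt(max(abs(num - gvec[idx])), 1e-7)
})

test_that("class weights are inversely proportional to frequency", {
  w <- balanced_class_weights(rep(c("A", "B"), c(10, 40)), c("A", "B"))
  expect_equal(unname(w["A"] / w["B"]), 4)
  expect_error(balanced_class_weights(rep("A", 5), c("A", "B")), "B")
})

test_that("the extractor learns separable toy volumes to perfect training accuracy", {
  fx <- small_cohort(counts = c(CN = 20, MCI = 0, AD = 20), seed = 5)
  vols <- generate_volumes(fx$cohort, shape = c(8, 8, 8), atrophy_amplitude = 1,
                           noise_sd = 0.02, seed = 5)
  # voxel-mean threshold oracle confirms separability before training
  mask <- volume_atrophy_mask(c(8, 8, 8))
  m <- sapply(vols$volumes, function(v) mean(v[mask]))
  cls <- as.character(fx$cohort$diagnosis[match(names(m), fx$cohort$id)])
  thr <- mean(tapply(m, cls, mean))
  expect_equal(mean(ifelse(m < thr, "AD", "CN") == cls), 1)

  labels <- setNames(as.character(fx$cohort$diagnosis), fx$cohort$id)
  split <- setNames(fx$cohort$split, fx$cohort$id)
  model <- train_extractor(vols, labels, split, toy_densenet_config())
  expect_lte(nrow(model$history), toy_densenet_config()$max_epochs)
  expect_equal(max(model$history$train_acc), 1)
  # loss decreases from the first epoch to the best epoch
  expect_lt(model$history$train_loss[model$best_epoch],
            model$history$train_loss[1])

  feats <- extract_features(model, vols)
  expect_equal(dim(feats), c(40, 32))
  expect_identical(feats, extract_features(model, vols))
  expect_true(all(is.finite(feats)))

  # identical inputs give identical rows; an all-zero volume stays finite
  vols2 <- vols
  vols2$volumes[[2]] <- vols2$volumes[[1]]
  vols2$volumes[[3]] <- array(0, c(8, 8, 8))
  f2 <- extract_features(model, vols2)
  expect_equal(unname(f2[1, ]), unname(f2[2, ]))
  expect_true(all(is.finite(f2[3, ])))

  # checkpoint round trip reproduces the embeddings exactly
  ckpt <- withr::local_tempfile(fileext = ".json")
  write_extractor(model, ckpt)
  back <- read_extractor(ckpt)
  expect_equal(extract_features(back, vols), feats, tolerance = 1e-12)

  # transfer initialization: warm-start a second task from these weights
  model2 <- train_extractor(vols, labels, split,
                            toy_densenet_config(max_epochs = 2), init = model)
  expect_equal(dim(model2$params$out$W), dim(model$params$out$W))
  bad_init <- model
  bad_init$params$out$W <- matrix(0, 16, 3)
  expect_error(train_extractor(vols, labels, split,
                               toy_densenet_config(max_epochs = 2),
                               init = bad_init), "architecture")
})

test_that("training stops when a class is missing and respects max epochs", {
  fx <- small_cohort(counts = c(CN = 6, MCI = 0, AD = 6), seed = 2)
  vols <- generate_volumes(fx$cohort, shape = c(8, 8, 8), seed = 2)
  labels <- setNames(rep("CN", 12), fx$cohort$id)
  split <- setNames(fx$cohort$split, fx$cohort$id)
  expect_error(train_extractor(vols, labels, split,
                               toy_densenet_config(max_epochs = 1),
                               class_order = c("CN", "AD")), "AD")
})
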