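# Shared fixtures, generated in code at test time.

small_cohort <- function(counts = c(CN = 20, MCI = 24, AD = 20), seed = 42,
                         feature_dim = 16, class_separation = 3, noise_sd = 1) {
  config <- cohort_config(class_counts = counts, feature_dim = feature_dim,
                          class_separation = class_separation,
                          noise_sd = noise_sd, seed = seed)
  cohort <- generate_cohort(config)
  list(config = config,
       cohort = cohort,
       features = generate_features(cohort, config))
}

# Tiny reduced DenseNet settings that train in seconds on 8^3 phantoms.
toy_densenet_config <- function(...) {
  defaults <- list(input_shape = c(8, 8, 8), n_blocks = 2, units_per_block = 2,
                   growth_rate = 4, bottleneck_channels = 8, stem_channels = 8,
                   fc_sizes = c(32, 16), learning_rate = 3e-3, batch_size = 10,
                   max_epochs = 40, patience = 10, seed = 7)
  do.call(densenet_config, utils::modifyList(defaults, list(...)))
}

# Brute-force scalar-loop adjacency oracle: applies the scalar similarity
# functions pair by pair, independent of the vectorized build_graph path.
brute_force_adjacency <- function(features, phenotypes, spec) {
  n <- nrow(phenotypes)
  a <- matrix(0, n, n)
  x <- features[phenotypes$id, , drop = FALSE]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    simg <- max(imaging_similarity(x[i, ], x[j, ]), 0)
    snimg <- vapply(spec$features, function(f) {
      vi <- phenotypes[[f$name]][i]; vj <- phenotypes[[f$name]][j]
      if (f$kind == "categorical") as.numeric(categorical_similarity(vi, vj))
      else as.numeric(quantitative_similarity(vi, vj, f$beta))
    }, numeric(1))
    a[i, j] <- switch(spec$mode,
                      baseline = simg,
                      nonimaging = sum(snimg),
                      combined = simg * sum(snimg))
  }
  a
}
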