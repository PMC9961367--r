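#' Configuration for the synthetic cohort simulator
#'
#' Bundles everything [generate_cohort()], [generate_features()] and
#' [generate_volumes()] need: class counts, per-class covariate
#' distributions, the embedding dimension and class-separation of the
#' synthetic anatomical features, and the train/validation/test fractions.
#' Defaults emulate the ADNI-1 baseline cohort (187 AD, 382 MCI, 229 CN;
#' covariates per [adni1_covariate_params()]; 70/10/20 split).
#'
#' @param class_counts Named vector of subjects per diagnosis
#'   (`CN`, `MCI`, `AD`); zero counts allowed.
#' @param covariate_params Per-class covariate distributions in the format
#'   of [adni1_covariate_params()].
#' @param feature_dim Dimension of the synthetic anatomical embedding
#'   (default 512, the width of the CNN's first fully connected layer).
#' @param class_separation Euclidean distance between feature centroids of
#'   adjacent severity classes (CN-MCI and MCI-AD); 0 means no imaging
#'   signal.
#' @param noise_sd Per-coordinate SD of feature noise around the centroid.
#' @param split_fractions Named fractions for `train`, `val`, `test`;
#'   must sum to 1.
#' @param seed Integer seed; every simulator draw is derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(class_counts = adni1_class_counts(),
                          covariate_params = adni1_covariate_params(),
                          feature_dim = 512,
                          class_separation = 3,
                          noise_sd = 1,
                          split_fractions = c(train = 0.7, val = 0.1, test = 0.2),
                          seed = 1) {
  if (any(class_counts < 0)) abort("`class_counts` must be nonnegative.")
  if (!all(c("CN", "MCI", "AD") %in% names(class_counts))) {
    abort("`class_counts` must name CN, MCI and AD.")
  }
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    abort("`split_fractions` must sum to 1.")
  }
  if (!all(c("train", "val", "test") %in% names(split_fractions))) {
    abort("`split_fractions` must name train, val and test.")
  }
  if (feature_dim <= 0) abort("`feature_dim` must be positive.")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (class_separation < 0) abort("`class_separation` must be nonnegative.")
  structure(list(class_counts = class_counts,
                 covariate_params = covariate_params,
                 feature_dim = as.integer(feature_dim),
                 class_separation = class_separation,
                 noise_sd = noise_sd,
                 split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Stratified split: within each diagnosis, assign floor(n * frac) subjects
# per partition and distribute remainders by largest fractional part, so
# realised fractions are within one subject of the request.
stratified_split <- function(diagnosis, fractions) {
  split <- character(length(diagnosis))
  parts <- names(fractions)
  for (cl in unique(diagnosis)) {
    idx <- which(diagnosis == cl)
    n <- length(idx)
    target <- n * fractions
    base <- floor(target)
    rem <- n - sum(base)
    if (rem > 0) {
      order_rem <- order(target - base, decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
    }
    assignment <- rep(parts, times = base)
    split[idx] <- sample(assignment)
  }
  split
}

#' Generate a synthetic cohort
#'
#' Draws a phenotype table with the statistical structure of the ADNI-1
#' baseline cohort: per-diagnosis normal draws for the quantitative
#' covariates (clipped to physiological ranges), categorical draws for
#' gender and ApoE4 allele count, and a stratified
#' train/validation/test split. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: `id`, `diagnosis` (factor
#'   CN < MCI < AD), `age`, `gender`, `apoe4`, the nine scores named by
#'   [score_names()], and `split`.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   class_counts = c(CN = 30, MCI = 40, AD = 30), seed = 7))
#' dplyr::count(cohort, diagnosis, split)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  counts <- config$class_counts[c("CN", "MCI", "AD")]
  n <- sum(counts)
  diagnosis <- rep(names(counts), times = counts)
  out <- tibble(
    id = sprintf("S%04d", seq_len(n)),
    diagnosis = factor(diagnosis, levels = c("CN", "MCI", "AD"))
  )
  if (n == 0) {
    out$age <- numeric(); out$gender <- character(); out$apoe4 <- integer()
    for (s in score_names()) out[[s]] <- numeric()
    out$split <- character()
    return(out)
  }
  qp <- config$covariate_params$quantitative
  cp <- config$covariate_params$categorical
  with_seed(derive_seed(config$seed, 1L), {
    for (v in unique(qp$variable)) {
      vals <- numeric(n)
      for (cl in names(counts)) {
        row <- qp[qp$variable == v & qp$diagnosis == cl, ]
        idx <- which(diagnosis == cl)
        draw <- rnorm(length(idx), row$mean, row$sd)
        vals[idx] <- pmin(pmax(draw, row$lower), row$upper)
      }
      out[[v]] <- vals
    }
    for (v in unique(cp$variable)) {
      vals <- character(n)
      for (cl in names(counts)) {
        sub <- cp[cp$variable == v & cp$diagnosis == cl, ]
        idx <- which(diagnosis == cl)
        vals[idx] <- sample(sub$level, length(idx), replace = TRUE, prob = sub$prob)
      }
      out[[v]] <- vals
    }
    out$split <- stratified_split(diagnosis, config$split_fractions)
  })
  out$apoe4 <- as.integer(out$apoe4)
  score_cols <- intersect(score_names(), names(out))
  out[, c("id", "diagnosis", "age", "gender", "apoe4", score_cols, "split")]
}

#' Generate synthetic anatomical feature vectors
#'
#' Emulates the CNN embedding: each subject's feature vector is drawn from
#' a normal centred on a diagnosis-specific centroid and rectified at zero
#' (post-ReLU activations are nonnegative, which keeps cosine similarities
#' nonnegative downstream). Centroids sit on a severity line: CN at the
#' base point, MCI one step and AD two steps of length
#' `config$class_separation` along a random unit direction.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param config The same [cohort_config()].
#' @return Numeric matrix, subjects x `feature_dim`, rownames = subject ids.
#' @export
generate_features <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(cohort) == 0) abort("`cohort` is empty.")
  d <- config$feature_dim
  if (d <= 0) abort("`feature_dim` must be positive.")
  severity <- c(CN = 0, MCI = 1, AD = 2)[as.character(cohort$diagnosis)]
  with_seed(derive_seed(config$seed, 2L), {
    base <- abs(rnorm(d, mean = 1, sd = 0.25))
    dir <- rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    centroids <- outer(severity, dir * config$class_separation) +
      matrix(base, nrow(cohort), d, byrow = TRUE)
    x <- centroids + matrix(rnorm(nrow(cohort) * d, sd = config$noise_sd),
                            nrow(cohort), d)
  })
  x <- pmax(x, 0)
  rownames(x) <- cohort$id
  colnames(x) <- sprintf("f%03d", seq_len(d))
  x
}

#' Write / read a phenotype table
#'
#' CSV with header `id,diagnosis,age,gender,apoe4,MMSE,CDR_SB,ADAS11,
#' ADAS13,FAQ,ADNI_MEM,ADNI_EF,ADNI_LAN,ADNI_VS,split`.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `write_phenotypes()` returns `path` invisibly;
#'   `read_phenotypes()` returns the cohort tibble with `diagnosis`
#'   restored as an ordered factor.
#' @export
write_phenotypes <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           diagnosis = readr::col_character(),
                           gender = readr::col_character(),
                           apoe4 = readr::col_integer(),
                           split = readr::col_character(),
                           .default = readr::col_double()))
  out$diagnosis <- factor(out$diagnosis, levels = c("CN", "MCI", "AD"))
  out
}

#' Write / read a cohort configuration as YAML
#'
#' The seed is mandatory in the file so a stored configuration always
#' reproduces the same cohort.
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  obj <- unclass(config)
  # named atomic vectors serialize as YAML sequences (names lost); store maps
  obj$class_counts <- as.list(obj$class_counts)
  obj$split_fractions <- as.list(obj$split_fractions)
  obj$covariate_params <- list(
    quantitative = as.data.frame(obj$covariate_params$quantitative),
    categorical = as.data.frame(obj$covariate_params$categorical))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$seed)) abort("Cohort configuration file must record a seed.")
  cp <- list(quantitative = as_tibble(as.data.frame(obj$covariate_params$quantitative)),
             categorical = as_tibble(as.data.frame(obj$covariate_params$categorical)))
  cp$quantitative$lower[is.na(cp$quantitative$lower)] <- -Inf
  cp$quantitative$upper[is.na(cp$quantitative$upper)] <- Inf
  cohort_config(class_counts = unlist(obj$class_counts),
                covariate_params = cp,
                feature_dim = obj$feature_dim,
                class_separation = obj$class_separation,
                noise_sd = obj$noise_sd,
                split_fractions = unlist(obj$split_fractions),
                seed = obj$seed)
}
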