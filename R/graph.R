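#' Specify an edge-assigning function
#'
#' Three graph families are supported, mirroring the edge taxonomy of the
#' framework: `baseline` (cosine similarity of imaging features only),
#' `nonimaging` (sum of phenotype indicator similarities), and `combined`
#' (their product). Non-imaging features are declared with
#' [edge_feature()].
#'
#' @param mode One of `"baseline"`, `"nonimaging"`, `"combined"`.
#' @param features List of [edge_feature()]s; must be empty for `baseline`
#'   and nonempty otherwise.
#' @return An `edge_spec` object.
#' @examples
#' edge_spec("combined", list(edge_feature("age", "quantitative", beta = 2),
#'                            edge_feature("gender", "categorical"),
#'                            edge_feature("apoe4", "categorical")))
#' @export
edge_spec <- function(mode = c("baseline", "nonimaging", "combined"),
                      features = list()) {
  mode <- match.arg(mode)
  if (mode == "baseline" && length(features) > 0) {
    abort("Baseline graphs take no non-imaging features.")
  }
  if (mode != "baseline" && length(features) == 0) {
    abort(paste0("Mode '", mode, "' needs at least one non-imaging feature."))
  }
  ok <- vapply(features, function(f) inherits(f, "edge_feature"), logical(1))
  if (!all(ok)) abort("`features` must be a list of edge_feature() objects.")
  structure(list(mode = mode, features = features), class = "edge_spec")
}

#' @rdname edge_spec
#' @param name Phenotype column name in the cohort table.
#' @param kind `"categorical"` (Kronecker delta) or `"quantitative"`
#'   (unit step with threshold `beta`).
#' @param beta Positive threshold, required for quantitative features.
#' @export
edge_feature <- function(name, kind = c("categorical", "quantitative"),
                         beta = NULL) {
  kind <- match.arg(kind)
  if (kind == "quantitative") {
    if (is.null(beta) || beta <= 0) {
      abort(paste0("Quantitative feature '", name, "' needs beta > 0."))
    }
  }
  structure(list(name = name, kind = kind, beta = beta), class = "edge_feature")
}

#' @export
print.edge_spec <- function(x, ...) {
  cat("edge_spec: ", x$mode, "\n", sep = "")
  for (f in x$features) {
    cat("  - ", f$name, " (", f$kind,
        if (f$kind == "quantitative") paste0(", beta = ", f$beta) else "",
        ")\n", sep = "")
  }
  invisible(x)
}

#' Short display label for an edge specification
#' @param spec An [edge_spec()].
#' @return Character scalar like `"Scom(age+gender)"`.
#' @export
edge_label <- function(spec) {
  prefix <- switch(spec$mode, baseline = "Simg", nonimaging = "Snimg",
                   combined = "Scom")
  if (spec$mode == "baseline") return(prefix)
  paste0(prefix, "(", paste(vapply(spec$features, `[[`, "", "name"),
                            collapse = "+"), ")")
}

# Sum of indicator similarities over the spec's non-imaging features,
# as a dense n x n matrix.
nonimaging_similarity_matrix <- function(phenotypes, features) {
  n <- nrow(phenotypes)
  s <- matrix(0, n, n)
  for (f in features) {
    if (!f$name %in% names(phenotypes)) {
      abort(paste0("Phenotype column '", f$name, "' not found."))
    }
    v <- phenotypes[[f$name]]
    if (f$kind == "categorical") {
      m <- outer(v, v, function(a, b) as.numeric(!is.na(a) & !is.na(b) & a == b))
    } else {
      vv <- as.numeric(v)
      m <- outer(vv, vv, function(a, b) {
        as.numeric(is.finite(a) & is.finite(b) & abs(a - b) < f$beta)
      })
    }
    s <- s + m
  }
  s
}

#' Build a population graph
#'
#' Assembles the symmetric weighted adjacency over subjects from the
#' chosen edge-assigning function, together with the node feature matrix
#' and split masks. Edge weights per mode (i != j):
#' * `baseline`: `max(Simg_ij, 0)` — negative cosines are clamped so the
#'   propagation normalization stays well defined (with rectified CNN
#'   features the clamp is a no-op);
#' * `nonimaging`: `sum_p Snimg_p(i, j)`;
#' * `combined`: `max(Simg_ij, 0) * sum_p Snimg_p(i, j)`.
#' The diagonal is zero; the self-loop is added later by
#' [normalize_adjacency()].
#'
#' @param features Numeric matrix, subjects x d, rownames = subject ids.
#' @param phenotypes Cohort tibble (needs `id`, `split`, and any phenotype
#'   columns the spec references), same subjects as `features`.
#' @param spec An [edge_spec()].
#' @return A `population_graph`: list with `ids`, `A` (n x n), `X`,
#'   `masks` (logical `train`/`val`/`test`), `diagnosis`, `edge_spec`.
#' @export
build_graph <- function(features, phenotypes, spec) {
  stopifnot(inherits(spec, "edge_spec"))
  ids <- phenotypes$id
  if (is.null(rownames(features))) abort("`features` must carry subject ids as rownames.")
  missing <- setdiff(ids, rownames(features))
  extra <- setdiff(rownames(features), ids)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0("Feature/phenotype id mismatch. Missing features: ",
                 paste(head(missing, 5), collapse = ", "),
                 "; unmatched feature rows: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  x <- features[ids, , drop = FALSE]
  n <- length(ids)
  a <- switch(spec$mode,
    baseline = pmax(cosine_similarity_matrix(x), 0),
    nonimaging = nonimaging_similarity_matrix(phenotypes, spec$features),
    combined = pmax(cosine_similarity_matrix(x), 0) *
      nonimaging_similarity_matrix(phenotypes, spec$features)
  )
  diag(a) <- 0
  masks <- lapply(c(train = "train", val = "val", test = "test"),
                  function(s) phenotypes$split == s)
  structure(list(ids = ids, A = a, X = x, masks = masks,
                 diagnosis = as.character(phenotypes$diagnosis),
                 edge_spec = spec),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  n <- length(x$ids)
  cat("population_graph: ", n, " nodes, ",
      sum(x$A > 0) / 2, " weighted edges, features ", ncol(x$X),
      "-d, edge function ", edge_label(x$edge_spec), "\n", sep = "")
  cat("  split: ", sum(x$masks$train), " train / ", sum(x$masks$val),
      " val / ", sum(x$masks$test), " test\n", sep = "")
  invisible(x)
}

#' Validation-driven threshold search
#'
#' Exhaustively evaluates every candidate threshold with a user-supplied
#' callback (typically: build the graph at that threshold, train the GCN,
#' return validation accuracy) and returns the maximizer. Ties break
#' toward the smaller threshold — the sparser graph — to limit
#' over-smoothing.
#'
#' @param candidates Nonempty numeric vector of thresholds.
#' @param evaluate Function `beta -> validation accuracy`.
#' @return List: `beta` (the winner) and `trace`, a tibble of every
#'   `(beta, accuracy)` pair evaluated.
#' @export
grid_search_threshold <- function(candidates, evaluate) {
  if (length(candidates) == 0) abort("`candidates` must be nonempty.")
  candidates <- sort(candidates)
  acc <- vapply(candidates, function(b) as.numeric(evaluate(b)), numeric(1))
  best <- candidates[which.max(acc)]  # which.max takes the first = smallest beta
  list(beta = best, trace = tibble(beta = candidates, accuracy = acc))
}

#' Serialize / load a population graph
#'
#' The adjacency goes to `adjacency.mtx` (Matrix Market coordinate
#' format), node features to `features.csv`, and ids, diagnosis and split
#' to `nodes.csv`, all under `dir`.
#'
#' @param graph A `population_graph`.
#' @param dir Directory (created if needed).
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "population_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(graph$A, sparse = TRUE),
                  file.path(dir, "adjacency.mtx"))
  split <- rep(NA_character_, length(graph$ids))
  for (s in names(graph$masks)) split[graph$masks[[s]]] <- s
  readr::write_csv(tibble(id = graph$ids, diagnosis = graph$diagnosis,
                          split = split),
                   file.path(dir, "nodes.csv"))
  feat <- as_tibble(graph$X, .name_repair = "minimal")
  feat <- bind_cols(tibble(id = graph$ids), feat)
  readr::write_csv(feat, file.path(dir, "features.csv"))
  yaml::write_yaml(list(mode = graph$edge_spec$mode,
                        features = lapply(graph$edge_spec$features, unclass)),
                   file.path(dir, "edge_spec.yaml"))
  invisible(dir)
}

#' @rdname write_graph
#' @export
read_graph <- function(dir) {
  a <- as.matrix(Matrix::readMM(file.path(dir, "adjacency.mtx")))
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"), show_col_types = FALSE)
  feat <- readr::read_csv(file.path(dir, "features.csv"), show_col_types = FALSE)
  x <- as.matrix(feat[, setdiff(names(feat), "id")])
  rownames(x) <- feat$id
  masks <- lapply(c(train = "train", val = "val", test = "test"),
                  function(s) nodes$split == s)
  spec_path <- file.path(dir, "edge_spec.yaml")
  spec <- if (file.exists(spec_path)) {
    obj <- yaml::read_yaml(spec_path)
    edge_spec(obj$mode, lapply(obj$features, function(f) {
      edge_feature(f$name, f$kind, beta = f$beta)
    }))
  } else {
    edge_spec("baseline")
  }
  structure(list(ids = nodes$id, A = a, X = x[nodes$id, , drop = FALSE],
                 masks = masks, diagnosis = nodes$diagnosis,
                 edge_spec = spec),
            class = "population_graph")
}
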