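test_that("edge specs validate their mode/feature combinations", {
  expect_error(edge_spec("baseline", list(edge_feature("age", "quantitative", 2))),
               "no non-imaging")
  expect_error(edge_spec("combined"), "at least one")
  expect_error(edge_feature("age", "quantitative"), "beta")
  expect_equal(edge_label(edge_spec("baseline")), "Simg")
  expect_equal(edge_label(edge_spec("combined",
                                    list(edge_feature("age", "quantitative", 2),
                                         edge_feature("gender", "categorical")))),
               "Scom(age+gender)")
})

test_that("baseline graph gives unit weight to identical feature vectors", {
  pheno <- tibble::tibble(id = c("a", "b"), diagnosis = factor(c("CN", "AD")),
                          split = c("train", "test"))
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  g <- build_graph(x, pheno, edge_spec("baseline"))
  expect_equal(g$A[1, 2], 1)
  expect_equal(unname(diag(g$A)), c(0, 0))
})

test_that("a 4-node combined graph equals its hand-evaluated adjacency", {
  pheno <- tibble::tibble(
    id = c("s1", "s2", "s3", "s4"),
    diagnosis = factor(c("CN", "CN", "AD", "AD"), levels = c("CN", "MCI", "AD")),
    gender = c("M", "M", "F", "M"),
    split = c("train", "train", "val", "test"))
  x <- rbind(s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 1), s4 = c(1, 0))
  spec <- edge_spec("combined", list(edge_feature("gender", "categorical")))
  g <- build_graph(x, pheno, spec)
  r2 <- 1 / sqrt(2)
  expected <- rbind(c(0, r2, 0, 1),   # s1: same gender as s2, s4
                    c(r2, 0, 0, r2),  # s2: cos with s3 = r2 but genders differ -> 0
                    c(0, 0, 0, 0),    # s3: only female
                    c(1, r2, 0, 0))
  expect_equal(unname(g$A), expected, tolerance = 1e-12)
})

test_that("a sub-gap threshold produces an empty non-imaging graph", {
  pheno <- tibble::tibble(id = c("a", "b", "c"),
                          diagnosis = factor(c("CN", "CN", "AD")),
                          age = c(60, 70, 80), split = c("train", "val", "test"))
  x <- matrix(rnorm(6), 3, dimnames = list(c("a", "b", "c"), NULL))
  g <- build_graph(x, pheno,
                   edge_spec("nonimaging", list(edge_feature("age", "quantitative", 5))))
  expect_equal(g$A, matrix(0, 3, 3))
})

test_that("vectorized construction equals the brute-force pairwise oracle", {
  set.seed(17)
  for (rep in 1:3) {
    n <- sample(5:20, 1)
    pheno <- tibble::tibble(
      id = sprintf("x%02d", 1:n),
      diagnosis = factor(sample(c("CN", "MCI", "AD"), n, replace = TRUE),
                         levels = c("CN", "MCI", "AD")),
      age = runif(n, 60, 90),
      gender = sample(c("M", "F"), n, replace = TRUE),
      MMSE = runif(n, 20, 30),
      split = sample(c("train", "val", "test"), n, replace = TRUE))
    x <- matrix(rnorm(n * 6), n, dimnames = list(pheno$id, NULL))
    specs <- list(
      edge_spec("baseline"),
      edge_spec("nonimaging", list(edge_feature("age", "quantitative", 3),
                                   edge_feature("gender", "categorical"))),
      edge_spec("combined", list(edge_feature("MMSE", "quantitative", 2),
                                 edge_feature("gender", "categorical"))))
    for (spec in specs) {
      g <- build_graph(x, pheno, spec)
      oracle <- brute_force_adjacency(x, pheno, spec)
      expect_lt(max(abs(g$A - oracle)), 1e-10)
      expect_equal(g$A, t(g$A))
      expect_true(all(g$A >= 0))
    }
  }
})

test_that("edge count grows monotonically with the quantitative threshold", {
  set.seed(5)
  pheno <- tibble::tibble(id = sprintf("n%02d", 1:15),
                          diagnosis = factor(rep("CN", 15)),
                          age = rnorm(15, 75, 6),
                          split = rep("train", 15))
  x <- matrix(abs(rnorm(15 * 4)), 15, dimnames = list(pheno$id, NULL))
  counts <- sapply(c(0.5, 1, 2, 4, 8, 16), function(b) {
    g <- build_graph(x, pheno,
                     edge_spec("nonimaging", list(edge_feature("age", "quantitative", b))))
    sum(g$A > 0)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("relabeling subjects permutes the adjacency consistently", {
  set.seed(23)
  n <- 10
  pheno <- tibble::tibble(id = sprintf("p%02d", 1:n),
                          diagnosis = factor(sample(c("CN", "AD"), n, TRUE)),
                          gender = sample(c("M", "F"), n, TRUE),
                          split = sample(c("train", "test"), n, TRUE))
  x <- matrix(abs(rnorm(n * 4)), n, dimnames = list(pheno$id, NULL))
  spec <- edge_spec("combined", list(edge_feature("gender", "categorical")))
  g <- build_graph(x, pheno, spec)
  perm <- sample(n)
  g2 <- build_graph(x, pheno[perm, ], spec)
  expect_equal(g2$A, g$A[perm, perm], tolerance = 1e-12)
})

test_that("id mismatches are reported with the offending ids", {
  pheno <- tibble::tibble(id = c("a", "b"), diagnosis = factor(c("CN", "AD")),
                          split = c("train", "test"))
  x <- matrix(1:4, 2, dimnames = list(c("a", "zz"), NULL))
  expect_error(build_graph(x, pheno, edge_spec("baseline")), "zz")
  expect_error(build_graph(unname(x), pheno, edge_spec("baseline")), "rownames")
})

test_that("threshold grid search maximizes validation accuracy, ties to sparser", {
  expect_equal(grid_search_threshold(3, function(b) 0.5)$beta, 3)
  res <- grid_search_threshold(c(3, 1, 2), function(b) c(`1` = 0.2, `2` = 0.9, `3` = 0.4)[[as.character(b)]])
  expect_equal(res$beta, 2)
  expect_equal(res$trace$beta, c(1, 2, 3))
  tie <- grid_search_threshold(c(1, 2, 3), function(b) if (b >= 2) 0.8 else 0.1)
  expect_equal(tie$beta, 2)
  expect_error(grid_search_threshold(numeric(0), identity), "nonempty")
})

test_that("graph serialization round-trips through Matrix Market + CSV", {
  fx <- small_cohort(counts = c(CN = 6, MCI = 5, AD = 5), seed = 13)
  spec <- edge_spec("combined", list(edge_feature("apoe4", "categorical")))
  g <- build_graph(fx$features, fx$cohort, spec)
  dir <- withr::local_tempdir()
  write_graph(g, dir)
  expect_true(file.exists(file.path(dir, "adjacency.mtx")))
  back <- read_graph(dir)
  expect_equal(back$ids, g$ids)
  expect_equal(back$A, g$A, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(back$X), unname(g$X), tolerance = 1e-10)
  expect_equal(back$masks, g$masks)
  expect_equal(edge_label(back$edge_spec), "Scom(apoe4)")
})
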