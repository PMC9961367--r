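# Edge-assigning similarity functions: cosine similarity of imaging
# feature vectors, Kronecker-delta similarity for categorical phenotypes,
# unit-step similarity for quantitative phenotypes, and their product
# combination.

#' Cosine similarity of two imaging feature vectors
#'
#' `x . y / (||x|| ||y||)`, in `[-1, 1]` and symmetric in its arguments.
#' A zero-norm vector yields similarity 0 (with a message) rather than an
#' error, so an all-zero embedding cannot crash graph construction.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @return Scalar cosine similarity.
#' @examples
#' imaging_similarity(c(1, 1), c(1, 0)) # 1/sqrt(2)
#' @export
imaging_similarity <- function(xi, xj) {
  stopifnot(length(xi) == length(xj))
  ni <- sqrt(sum(xi^2)); nj <- sqrt(sum(xj^2))
  if (ni == 0 || nj == 0) {
    inform("Zero-norm feature vector: imaging similarity defined as 0.")
    return(0)
  }
  sum(xi * xj) / (ni * nj)
}

#' Kronecker-delta similarity for categorical phenotypes
#'
#' 1 when the two category values are equal, else 0. Missing values never
#' match (reported with a message).
#'
#' @param ni,nj Category values (vectors recycle).
#' @return Integer 0/1 vector.
#' @export
categorical_similarity <- function(ni, nj) {
  if (anyNA(ni) || anyNA(nj)) {
    inform("Missing categorical value treated as unequal.")
  }
  out <- as.integer(!is.na(ni) & !is.na(nj) & ni == nj)
  out
}

#' Unit-step similarity for quantitative phenotypes
#'
#' 1 when `|ni - nj| < beta` (strictly), else 0; symmetric in `ni`, `nj`.
#' Non-finite inputs give 0 with a warning.
#'
#' @param ni,nj Numeric values (vectors recycle).
#' @param beta Positive threshold.
#' @return Integer 0/1 vector.
#' @examples
#' quantitative_similarity(74, 75, beta = 2) # 1
#' quantitative_similarity(70, 75, beta = 2) # 0
#' @export
quantitative_similarity <- function(ni, nj, beta) {
  if (beta <= 0) abort("`beta` must be positive.")
  bad <- !is.finite(ni) | !is.finite(nj)
  if (any(bad)) warn("Non-finite quantitative value: similarity set to 0.")
  out <- as.integer(!bad & abs(ni - nj) < beta)
  out
}

#' Combined imaging / non-imaging similarity
#'
#' The product form `Simg * sum(Snimg_p)` over the P non-imaging features:
#' the imaging similarity is scaled up by however many phenotype features
#' agree, and annihilated when none do. Weights may exceed 1.
#'
#' @param simg Imaging (cosine) similarity.
#' @param snimg_values Vector of 0/1 non-imaging similarities (P >= 1).
#' @return Scalar combined weight.
#' @examples
#' combined_similarity(0.8, c(1, 0)) # 0.8
#' combined_similarity(0.5, c(1, 1, 1)) # 1.5
#' @export
combined_similarity <- function(simg, snimg_values) {
  if (length(snimg_values) < 1) {
    abort("`snimg_values` must contain at least one non-imaging similarity; use a baseline graph when there are none.")
  }
  simg * sum(snimg_values)
}

#' Pairwise cosine similarity matrix
#'
#' Row-normalizes `X` and returns `X X^T`; rows with zero norm get
#' similarity 0 against everything.
#'
#' @param x Numeric matrix, subjects x features.
#' @return Symmetric n x n matrix of cosine similarities, unit diagonal
#'   (zero for zero-norm rows).
#' @export
cosine_similarity_matrix <- function(x) {
  norms <- sqrt(rowSums(x^2))
  zero <- norms == 0
  if (any(zero)) inform(sprintf("%d zero-norm feature rows: similarities set to 0.", sum(zero)))
  norms[zero] <- 1
  xn <- x / norms
  s <- tcrossprod(xn)
  s[zero, ] <- 0
  s[, zero] <- 0
  s
}
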