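#' Pearson correlation matrix between two feature sets
#'
#' Correlates every column of `X` with every column of `Y` across samples
#' (rows).  Constant columns yield `NA` (undefined, not zero).
#'
#' @param X,Y Numeric matrices with matching sample rows; `Y` defaults to
#'   `X`.
#' @return Matrix of Pearson correlations, `ncol(X)` by `ncol(Y)`.
#' @export
pearson_matrix <- function(X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same sample rows")
  if (nrow(X) < 3L) stop("need at least 3 samples")
  suppressWarnings(stats::cor(X, Y, method = "pearson"))
}

#' Euclidean distance between samples
#'
#' Distances over (by default z-scored) variables; zero-variance columns are
#' excluded with a warning, since they carry no information and break
#' standardization.
#'
#' @param M Numeric matrix or data frame, samples as rows.
#' @param standardize Z-score each column first (default; environmental
#'   variables usually mix units).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_distance <- function(M, standardize = TRUE) {
  M <- as.matrix(M)
  if (standardize) {
    v <- apply(M, 2, stats::var)
    if (any(v == 0)) {
      warning("excluding zero-variance column(s): ",
              paste(colnames(M)[v == 0], collapse = ", "))
      M <- M[, v > 0, drop = FALSE]
    }
    M <- scale(M)
  }
  as.matrix(stats::dist(M))
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower-triangle entries;
#' the null distribution is generated by jointly permuting the rows and
#' columns of `D2`, and the one-sided p-value is
#' `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`.  Reproducible given `seed`.
#'
#' @param D1,D2 Square symmetric distance matrices over the same samples in
#'   the same order.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List with `r` (statistic), `p_value` and `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999L, seed = NULL) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in size")
  n <- nrow(D1)
  lt <- lower.tri(D1)
  r_obs <- stats::cor(D1[lt], D2[lt])
  count <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      if (stats::cor(D1[lt], D2[perm, perm][lt]) >= r_obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(r = r_obs, p_value = (1 + count) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition, via
#' [stats::cmdscale()].  Coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues; each axis's sign is fixed by making
#' its largest-magnitude loading positive.  Negative eigenvalues are
#' reported but excluded from the proportion-explained denominator.
#'
#' @param D Distance matrix.
#' @param k Number of axes (must be below the number of samples).
#' @return List with `coordinates` (samples x k), `eigenvalues` (all n) and
#'   `proportion_explained` (per retained axis, relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of samples")
  sc <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  coords <- sc$points
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  pos <- sc$eig[sc$eig > 0]
  list(coordinates = coords, eigenvalues = sc$eig,
       proportion_explained = sc$eig[seq_len(ncol(coords))] / sum(pos))
}
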