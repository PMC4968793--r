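# Gaussian-assumption information estimators.
#
# Under multivariate normality, entropy, mutual information (MI) and
# conditional mutual information (CMI) reduce to log-ratios of covariance
# determinants:
#   H(X)        = 1/2 log( (2*pi*e)^d |C(X)| )
#   MI(X;Y)     = 1/2 log( |C(X)| |C(Y)| / |C(X,Y)| )
#   CMI(X;Y|Z)  = 1/2 log( |C(X,Z)| |C(Y,Z)| / (|C(Z)| |C(X,Y,Z)|) )
# All values are in nats (natural log); thresholds elsewhere in the package
# are interpreted on the same scale.

# Relative determinant floor below which a covariance matrix is treated as
# numerically singular instead of yielding +/-Inf information values.
.DET_GUARD <- 1e-12

#' Estimate a covariance matrix for a gene subset
#'
#' Computes the covariance matrix of the selected genes across samples.
#' `mode = "auto"` uses the unbiased empirical estimator when there are more
#' samples than genes in the subset, and otherwise shrinks the off-diagonal
#' entries toward zero with an analytically chosen intensity
#' (variance-of-entries criterion), falling back to a fixed `1e-6` ridge if
#' the shrunk matrix is still not positive definite.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @param genes character vector of gene identifiers (subset of rownames).
#' @param mode one of `"auto"`, `"empirical"`, `"shrinkage"`.
#' @return an object of class `"covariance_matrix"`: a list with elements
#'   `genes`, `C` (symmetric matrix; positive definite after regularization in
#'   shrinkage mode — exact collinearity in empirical mode is caught by the
#'   determinant guard where MI/CMI consume the matrix) and `mode` (the mode
#'   actually used).
#' @examples
#' x <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("G", 1:4), NULL))
#' estimate_covariance(x, c("G1", "G2"))
#' @export
estimate_covariance <- function(expr, genes, mode = c("auto", "empirical", "shrinkage")) {
  expr <- validate_expr(expr)
  mode <- match.arg(mode)
  check_genes(expr, genes)
  if (anyDuplicated(genes))
    stop_lbn("argument", "duplicated gene in covariance subset")
  N <- ncol(expr)
  X <- expr[genes, , drop = FALSE]
  v <- apply(X, 1L, stats::var)
  if (any(v <= 0))
    stop_lbn("degenerate_data", "constant expression (zero variance) for gene(s): %s",
             paste(genes[v <= 0], collapse = ", "))
  if (mode == "auto") mode <- if (N > length(genes)) "empirical" else "shrinkage"
  S <- stats::cov(t(X))                       # unbiased, N-1 denominator
  if (mode == "shrinkage") {
    C <- .shrink_cov(X, S)
    eig <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(eig) <= 0)
      stop_lbn("degenerate_data",
               "covariance matrix for {%s} is not positive definite after regularization",
               paste(genes, collapse = ", "))
  } else {
    # the raw empirical estimate; exact collinearity is caught where its
    # determinant is consumed (MI/CMI), via the relative determinant guard
    C <- S
  }
  structure(list(genes = genes, C = C, mode = mode), class = "covariance_matrix")
}

# Shrink S toward its diagonal; lambda estimated from the sampling variance of
# the off-diagonal entries (Schafer-Strimmer style), clamped to [0, 1].
.shrink_cov <- function(X, S) {
  d <- nrow(S); N <- ncol(X)
  if (d == 1L) return(S)
  Xc <- X - rowMeans(X)
  num <- 0; den <- 0
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      w <- Xc[i, ] * Xc[j, ]
      num <- num + N / (N - 1)^3 * sum((w - mean(w))^2)
      den <- den + S[i, j]^2
    }
  }
  lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  C <- (1 - lambda) * S
  diag(C) <- diag(S)
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(eig) <= 0) C <- C + diag(1e-6, d)
  C
}

# Determinant of a covariance matrix; explicit formulas for d <= 2 keep the
# 2x2 case exact (so MI is bit-symmetric in its arguments and exactly 0 at
# sample correlation 0).
.cov_det <- function(x) {
  C <- if (inherits(x, "covariance_matrix")) x$C else x
  d <- nrow(C)
  if (d == 1L) C[1L, 1L]
  else if (d == 2L) C[1L, 1L] * C[2L, 2L] - C[1L, 2L] * C[2L, 1L]
  else det(C)
}

# Determinant with the collinearity guard: |C| below 1e-12 relative to the
# product of the diagonal (its value for a diagonal covariance) signals
# numerically collinear expression rather than returning +/-Inf information.
.det_guarded <- function(cv) {
  dt <- .cov_det(cv)
  if (dt < .DET_GUARD * prod(diag(cv$C)))
    stop_lbn("degenerate_data",
             "covariance of {%s} is numerically singular (collinear expression)",
             paste(cv$genes, collapse = ", "))
  dt
}

#' Differential entropy of a Gaussian with covariance C
#'
#' Returns `0.5 * log((2*pi*e)^d * |C|)` in nats, where `d` is the dimension
#' of `C`.
#'
#' @param C a `"covariance_matrix"` object (from [estimate_covariance()]) or a
#'   positive-definite numeric matrix.
#' @return entropy in nats.
#' @examples
#' gaussian_entropy(matrix(1))       # 0.5 * log(2 * pi * e)
#' @export
gaussian_entropy <- function(C) {
  M <- if (inherits(C, "covariance_matrix")) C$C else C
  if (!is.matrix(M)) M <- as.matrix(M)
  d <- nrow(M)
  dt <- det(M)
  if (!is.finite(dt) || dt <= 0)
    stop_lbn("degenerate_data", "covariance determinant is not positive (|C| = %g)", dt)
  0.5 * (d * log(2 * pi * exp(1)) + log(dt))
}

#' Mutual information between two genes (Gaussian estimator)
#'
#' `MI(i, j) = 0.5 * log(|C(i)| * |C(j)| / |C(i, j)|)` in nats, computed from
#' [estimate_covariance()] on the marginal and joint subsets. For the
#' empirical covariance this is algebraically `-0.5 * log(1 - r^2)` with `r`
#' the sample Pearson correlation. Raw values that fall below zero through
#' round-off are clamped to 0.
#'
#' @inheritParams estimate_covariance
#' @param gene_i,gene_j distinct gene identifiers.
#' @return nonnegative MI estimate in nats.
#' @export
mutual_information <- function(expr, gene_i, gene_j, mode = "auto") {
  if (identical(gene_i, gene_j))
    stop_lbn("argument", "mutual information requires two distinct genes")
  di <- .det_guarded(estimate_covariance(expr, gene_i, mode))
  dj <- .det_guarded(estimate_covariance(expr, gene_j, mode))
  dij <- .det_guarded(estimate_covariance(expr, c(gene_i, gene_j), mode))
  max(0, 0.5 * log(di * dj / dij))
}

#' Conditional mutual information given up to two genes
#'
#' `CMI(i, j | Z) = 0.5 * log(|C(i,Z)| * |C(j,Z)| / (|C(Z)| * |C(i,j,Z)|))` in
#' nats. With an empty conditioning set this reduces exactly to
#' [mutual_information()]; with two conditioning genes it is the second-order
#' CMI. Values are clamped at 0.
#'
#' @inheritParams mutual_information
#' @param cond character vector of 0, 1 or 2 conditioning gene identifiers,
#'   disjoint from `gene_i` and `gene_j`.
#' @return nonnegative CMI estimate in nats.
#' @export
conditional_mutual_information <- function(expr, gene_i, gene_j,
                                           cond = character(), mode = "auto") {
  cond <- as.character(cond)
  if (identical(gene_i, gene_j))
    stop_lbn("argument", "conditional MI requires two distinct genes")
  if (length(cond) > 2L)
    stop_lbn("argument", "at most 2 conditioning genes supported, got %d", length(cond))
  if (anyDuplicated(cond))
    stop_lbn("argument", "duplicated conditioning gene")
  if (any(c(gene_i, gene_j) %in% cond))
    stop_lbn("argument", "conditioning set overlaps the gene pair")
  if (length(cond) == 0L)
    return(mutual_information(expr, gene_i, gene_j, mode))
  diz  <- .det_guarded(estimate_covariance(expr, c(gene_i, cond), mode))
  djz  <- .det_guarded(estimate_covariance(expr, c(gene_j, cond), mode))
  dz   <- .det_guarded(estimate_covariance(expr, cond, mode))
  dijz <- .det_guarded(estimate_covariance(expr, c(gene_i, gene_j, cond), mode))
  max(0, 0.5 * log(diz * djz / (dz * dijz)))
}

#' All pairwise mutual informations
#'
#' Vectorised MI over every gene pair (the screening step of network
#' construction); entry `(i, j)` equals `mutual_information(expr, i, j)` with
#' the empirical covariance. `O(n^2)` pairs are evaluated.
#'
#' @inheritParams estimate_covariance
#' @return symmetric `n x n` numeric matrix in nats with zero diagonal and
#'   gene identifiers as dimnames.
#' @export
pairwise_mi_matrix <- function(expr) {
  expr <- validate_expr(expr)
  v <- apply(expr, 1L, stats::var)
  if (any(v <= 0))
    stop_lbn("degenerate_data", "constant expression (zero variance) for gene(s): %s",
             paste(rownames(expr)[v <= 0], collapse = ", "))
  r <- stats::cor(t(expr))
  r2 <- r^2
  diag(r2) <- 0
  bad <- which(1 - r2 < .DET_GUARD, arr.ind = TRUE)
  if (nrow(bad))
    stop_lbn("degenerate_data", "perfectly collinear gene pair: %s / %s",
             rownames(expr)[bad[1L, 1L]], rownames(expr)[bad[1L, 2L]])
  mi <- -0.5 * log1p(-r2)
  mi <- pmax(mi, 0)
  mi <- (mi + t(mi)) / 2            # enforce exact symmetry
  diag(mi) <- 0
  dimnames(mi) <- list(rownames(expr), rownames(expr))
  mi
}
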