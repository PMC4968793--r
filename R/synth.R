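# Linear-Gaussian synthetic benchmarks: random gold-standard DAGs and
# expression data simulated from them by a structural equation model. Because
# the data are exactly multivariate Gaussian, every population MI/CMI value is
# available in closed form from the SEM covariance
# Sigma = (I - B')^{-1} D (I - B')^{-T}, which makes the estimators testable
# against analytic ground truth.

#' Specification of a synthetic benchmark
#'
#' @param n_genes number of genes.
#' @param n_edges number of directed edges; must not exceed
#'   `n_genes * (n_genes - 1) / 2` (a DAG under some ordering).
#' @param N_samples number of independent samples.
#' @param coeff_range positive `(low, high)` range of absolute regulatory
#'   coefficients; signs (activation/repression) are drawn at random. The
#'   default 0.5-1.0 keeps edges bounded away from undetectable strength.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; the whole module is deterministic given it.
#' @return object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_genes, n_edges, N_samples, coeff_range = c(0.5, 1),
                       noise_sd = 0.5, seed = 1L) {
  n_genes <- as.integer(n_genes); n_edges <- as.integer(n_edges)
  N_samples <- as.integer(N_samples)
  if (is.na(n_genes) || n_genes < 2L) stop_lbn("argument", "need n_genes >= 2")
  if (is.na(n_edges) || n_edges < 0L ||
      n_edges > n_genes * (n_genes - 1L) / 2L)
    stop_lbn("argument", "n_edges must be between 0 and n_genes*(n_genes-1)/2")
  if (is.na(N_samples) || N_samples < 3L)
    stop_lbn("argument", "need N_samples >= 3")
  if (length(coeff_range) != 2L || any(coeff_range <= 0) ||
      coeff_range[1L] > coeff_range[2L])
    stop_lbn("argument", "coeff_range must be 0 < low <= high")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_lbn("argument", "noise_sd must be positive")
  structure(list(n_genes = n_genes, n_edges = n_edges, N_samples = N_samples,
                 coeff_range = as.numeric(coeff_range),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "synth_spec")
}

#' Sample a random gold-standard DAG
#'
#' Draws a uniform topological order over `G1..Gn`, then `n_edges` distinct
#' forward edges uniformly at random; acyclic by construction and
#' deterministic given the seed.
#'
#' @param spec a [synth_spec()].
#' @return directed `"gene_network"` with stage `"gold"`.
#' @export
generate_random_dag <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop_lbn("argument", "spec must be a synth_spec")
  ids <- sprintf("G%d", seq_len(spec$n_genes))
  with_seed(spec$seed, {
    ord <- sample(ids)
    pairs <- utils::combn(seq_along(ord), 2L)
    pick <- sample.int(ncol(pairs), spec$n_edges)
    edges <- data.frame(from = ord[pairs[1L, pick]], to = ord[pairs[2L, pick]],
                        weight = rep(1, length(pick)), stringsAsFactors = FALSE)
    gene_network(ids, edges, directed = TRUE, stage = "gold")
  })
}

# Deterministic topological order (smallest canonical index among current
# sources first).
.topo_order <- function(net) {
  ids <- net$gene_ids
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) adj[cbind(net$edges$from, net$edges$to)] <- TRUE
  out <- character(0)
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  while (any(alive)) {
    indeg <- colSums(adj[alive, alive, drop = FALSE])
    src <- names(indeg)[indeg == 0]
    if (!length(src)) stop_lbn("argument", "network contains a directed cycle")
    nxt <- ids[ids %in% src][1L]
    out <- c(out, nxt)
    alive[nxt] <- FALSE
  }
  out
}

#' Simulate expression data from a DAG by a linear-Gaussian SEM
#'
#' Each gene is the signed-coefficient linear combination of its parents plus
#' independent Gaussian noise, evaluated in topological order; samples are
#' i.i.d. Coefficient magnitudes are drawn uniformly from `coeff_range` with
#' random signs. The drawn coefficient matrix `B` (entry `[u, v]` = effect of
#' `u` on `v`) and `noise_sd` are attached as attributes, so the population
#' covariance `(I - B)'^{-1} D (I - B)^{-1}` is available in closed form.
#'
#' @param dag an acyclic directed `"gene_network"` (e.g. from
#'   [generate_random_dag()]).
#' @param spec a [synth_spec()].
#' @return numeric expression matrix (genes x samples) with attributes
#'   `coefficients` and `noise_sd`.
#' @export
simulate_expression <- function(dag, spec) {
  if (!inherits(spec, "synth_spec")) stop_lbn("argument", "spec must be a synth_spec")
  if (!dag$directed) stop_lbn("argument", "dag must be a directed network")
  ord <- .topo_order(dag)  # errors on cyclic input
  ids <- dag$gene_ids
  N <- spec$N_samples
  with_seed(spec$seed + 1L, {
    B <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(dag$edges)) {
      mag <- stats::runif(nrow(dag$edges), spec$coeff_range[1L], spec$coeff_range[2L])
      sgn <- sample(c(-1, 1), nrow(dag$edges), replace = TRUE)
      B[cbind(dag$edges$from, dag$edges$to)] <- mag * sgn
    }
    X <- matrix(0, length(ids), N, dimnames = list(ids, NULL))
    for (g in ord) {
      pa <- ids[B[, g] != 0]
      X[g, ] <- stats::rnorm(N, 0, spec$noise_sd) +
        if (length(pa)) as.numeric(B[pa, g] %*% X[pa, , drop = FALSE]) else 0
    }
    attr(X, "coefficients") <- B
    attr(X, "noise_sd") <- spec$noise_sd
    X
  })
}

#' Named benchmark fixtures
#'
#' Seeded gold-network/data bundles with documented shapes:
#' \describe{
#'   \item{`tiny_chain`}{3 genes, chain `G1 -> G2 -> G3`.}
#'   \item{`vstructure`}{3 genes, collider `G1 -> G3 <- G2`.}
#'   \item{`sos_like`}{9 genes, 24 random DAG edges (the size of the
#'     experimentally verified SOS DNA-repair network).}
#'   \item{`dream10_like`}{10 genes, 10 random DAG edges (the size of the
#'     smallest DREAM3 benchmark).}
#' }
#'
#' @param name fixture name.
#' @param N_samples number of samples (default 200).
#' @param seed integer seed.
#' @return list with `network` (gold `"gene_network"`), `expr` (expression
#'   matrix) and `spec` (the [synth_spec()] used).
#' @export
make_fixture <- function(name = c("tiny_chain", "vstructure", "sos_like",
                                  "dream10_like"),
                         N_samples = 200L, seed = 1L) {
  name <- match.arg(name)
  fixed3 <- function(edges) {
    spec <- synth_spec(3L, 2L, N_samples, seed = seed)
    net <- gene_network(sprintf("G%d", 1:3), edges, directed = TRUE, stage = "gold")
    list(network = net, expr = simulate_expression(net, spec), spec = spec)
  }
  switch(name,
    tiny_chain = fixed3(data.frame(from = c("G1", "G2"), to = c("G2", "G3"))),
    vstructure = fixed3(data.frame(from = c("G1", "G2"), to = c("G3", "G3"))),
    sos_like = {
      spec <- synth_spec(9L, 24L, N_samples, seed = seed)
      net <- generate_random_dag(spec)
      list(network = net, expr = simulate_expression(net, spec), spec = spec)
    },
    dream10_like = {
      spec <- synth_spec(10L, 10L, N_samples, seed = seed)
      net <- generate_random_dag(spec)
      list(network = net, expr = simulate_expression(net, spec), spec = spec)
    })
}
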