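# Bayesian-network structure scoring and exact search over small gene sets.
#
# The joint density of a DAG model factorises into per-node families
# P(X_1,...,X_n) = prod_i P(X_i | Pa(X_i)), so a decomposable score (here the
# Gaussian BIC) turns structure search into choosing one parent set per node
# subject to global acyclicity. Subnetworks small enough for exact search are
# solved optimally; larger ones fall back to exhaustive parent-set selection
# for the centre gene only (the O(2^m) search).

#' Search configuration for local Bayesian networks
#'
#' @param max_parents maximum in-degree `m` allowed for any node (default 3).
#' @param exhaustive_node_limit subnetwork size above which full-DAG search is
#'   replaced by centre-parent-set search (default 5).
#' @param score score family; only `"bic_gaussian"` is implemented.
#' @return an object of class `"search_config"`.
#' @export
search_config <- function(max_parents = 3L, exhaustive_node_limit = 5L,
                          score = "bic_gaussian") {
  score <- match.arg(score, "bic_gaussian")
  max_parents <- as.integer(max_parents)
  exhaustive_node_limit <- as.integer(exhaustive_node_limit)
  if (is.na(max_parents) || max_parents < 0L)
    stop_lbn("argument", "max_parents must be >= 0")
  if (is.na(exhaustive_node_limit) || exhaustive_node_limit < 2L)
    stop_lbn("argument", "exhaustive_node_limit must be >= 2")
  structure(list(max_parents = max_parents,
                 exhaustive_node_limit = exhaustive_node_limit, score = score),
            class = "search_config")
}

#' Gaussian BIC family score
#'
#' Scores one node-given-parents family: the maximised log-likelihood of the
#' linear Gaussian regression of `child` on `parents` (intercept included,
#' MLE residual variance `RSS / N`) minus the BIC penalty
#' `0.5 * (|parents| + 2) * log(N)` for the regression coefficients, the
#' intercept and the residual variance. Higher is better; the score is
#' decomposable, so a structure score is the sum of its family scores.
#'
#' @inheritParams estimate_covariance
#' @param child gene identifier of the node being scored.
#' @param parents character vector of parent gene identifiers (may be empty).
#' @return the family score (log scale).
#' @export
family_score <- function(expr, child, parents = character()) {
  expr <- validate_expr(expr)
  check_genes(expr, child, "child")
  parents <- as.character(parents)
  if (length(parents)) check_genes(expr, parents, "parent")
  if (child %in% parents)
    stop_lbn("argument", "child '%s' cannot be its own parent", child)
  if (anyDuplicated(parents))
    stop_lbn("argument", "duplicated parent gene")
  .family_score_raw(expr, child, parents)
}

# Unvalidated fast path used by the search loops.
.family_score_raw <- function(expr, child, parents) {
  y <- expr[child, ]
  N <- length(y)
  X <- cbind(rep(1, N), if (length(parents)) t(expr[parents, , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_lbn("degenerate_data", "collinear parent block for child '%s' ({%s})",
             child, paste(parents, collapse = ", "))
  rss <- sum(qr.resid(qx, y)^2)
  sigma2 <- rss / N
  vy <- mean((y - mean(y))^2)
  if (sigma2 <= 1e-12 * max(vy, .Machine$double.eps))
    stop_lbn("degenerate_data",
             "residual variance ~ 0 for child '%s' given {%s}",
             child, paste(parents, collapse = ", "))
  ll <- -N / 2 * (log(2 * pi * sigma2) + 1)
  ll - 0.5 * (length(parents) + 2) * log(N)
}

# -- local DAG container ------------------------------------------------------

#' Construct a local DAG
#'
#' @param genes ordered gene subset.
#' @param parent_sets named list mapping each gene to its (possibly empty)
#'   character vector of parents; must define an acyclic graph.
#' @param family_scores named numeric vector of per-gene family scores.
#' @param edge_weights optional numeric vector named `"u\rv"` giving the
#'   score improvement supporting each edge (defaults to `NA`).
#' @return an object of class `"local_dag"` with fields `genes`,
#'   `parent_sets`, `family_scores`, `total_score` and an `edges` data frame.
#' @export
local_dag <- function(genes, parent_sets, family_scores, edge_weights = NULL) {
  genes <- as.character(genes)
  if (!setequal(names(parent_sets), genes) || !setequal(names(family_scores), genes))
    stop_lbn("argument", "parent_sets and family_scores must be named by the DAG genes")
  parent_sets <- parent_sets[genes]
  family_scores <- unlist(family_scores)[genes]
  adj <- .parent_sets_adj(genes, parent_sets)
  if (!.is_acyclic(adj))
    stop_lbn("argument", "parent sets define a cyclic graph")
  from <- character(); to <- character()
  for (g in genes) {
    ps <- parent_sets[[g]]
    if (length(ps)) { from <- c(from, ps); to <- c(to, rep(g, length(ps))) }
  }
  wkey <- paste(from, to, sep = "\r")
  weight <- if (is.null(edge_weights)) rep(NA_real_, length(from))
            else as.numeric(edge_weights[wkey])
  edges <- data.frame(from = from, to = to, weight = weight,
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, genes), match(edges$to, genes)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genes = genes, parent_sets = parent_sets,
                 family_scores = family_scores,
                 total_score = sum(family_scores), edges = edges),
            class = "local_dag")
}

#' @export
print.local_dag <- function(x, ...) {
  cat(sprintf("<local_dag: %d genes, %d edges, score %.4f>\n",
              length(x$genes), nrow(x$edges), x$total_score))
  invisible(x)
}

.parent_sets_adj <- function(genes, parent_sets) {
  d <- length(genes)
  adj <- matrix(FALSE, d, d, dimnames = list(genes, genes))
  for (g in genes) {
    ps <- parent_sets[[g]]
    if (length(ps)) adj[ps, g] <- TRUE
  }
  adj
}

# Kahn's algorithm on a logical adjacency matrix (adj[u, v] == u -> v).
.is_acyclic <- function(adj) {
  d <- nrow(adj)
  if (d == 0L) return(TRUE)
  alive <- rep(TRUE, d)
  repeat {
    if (!any(alive)) return(TRUE)
    indeg <- colSums(adj[alive, alive, drop = FALSE])
    src <- which(indeg == 0)
    if (!length(src)) return(FALSE)
    alive[which(alive)[src]] <- FALSE
  }
}

#' Total score of a DAG structure
#'
#' Sums the Gaussian BIC family score over every gene of the DAG
#' (decomposability of the structure score).
#'
#' @inheritParams family_score
#' @param dag a `"local_dag"`.
#' @return total structure score.
#' @export
structure_score <- function(expr, dag) {
  expr <- validate_expr(expr)
  sum(vapply(dag$genes,
             function(g) family_score(expr, g, dag$parent_sets[[g]]),
             numeric(1)))
}

#' Enumerate every labelled DAG over a small gene set
#'
#' Generates each directed acyclic graph over `genes` whose in-degrees are all
#' `<= max_parents`, exactly once, by assigning a parent set per node with
#' incremental acyclicity pruning. Intended as the exhaustive candidate space
#' for tiny subnetworks (and as a brute-force oracle); refuses gene sets
#' larger than `node_limit`.
#'
#' @param genes character vector of gene identifiers.
#' @param max_parents maximum in-degree.
#' @param node_limit maximum gene-set size accepted.
#' @return list of named parent-set lists (one entry per DAG).
#' @export
enumerate_dags <- function(genes, max_parents = 3L, node_limit = 5L) {
  genes <- as.character(genes)
  d <- length(genes)
  if (d > node_limit)
    stop_lbn("size", "gene set of size %d exceeds the exhaustive limit %d",
             d, node_limit)
  if (d == 0L) return(list())
  cand <- lapply(seq_len(d), function(i)
    .parent_subsets(genes[-i], min(max_parents, d - 1L)))
  out <- list(); n_out <- 0L
  adj <- matrix(FALSE, d, d, dimnames = list(genes, genes))
  assign_node <- function(i, adj, acc) {
    if (i > d) {
      n_out <<- n_out + 1L
      out[[n_out]] <<- acc
      return(invisible())
    }
    for (ps in cand[[i]]) {
      a2 <- adj
      if (length(ps)) a2[ps, i] <- TRUE
      if (.is_acyclic(a2)) {
        acc[[genes[i]]] <- ps
        assign_node(i + 1L, a2, acc)
      }
    }
  }
  assign_node(1L, adj, stats::setNames(vector("list", d), genes))
  out[seq_len(n_out)]
}

# All subsets of `pool` with size 0..m, ordered by size then lexicographically.
.parent_subsets <- function(pool, m) {
  pool <- sort(pool)
  subsets <- list(character())
  for (s in seq_len(min(m, length(pool)))) {
    cmb <- utils::combn(pool, s, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  subsets
}

#' Learn the best-scoring local Bayesian network of a subnetwork
#'
#' For subnetworks with at most `cfg$exhaustive_node_limit` members, finds the
#' globally optimal DAG over the members under the Gaussian BIC score (an
#' exact dynamic program over sink orderings, equivalent to scoring every DAG
#' from [enumerate_dags()]); ties are resolved toward fewer edges, then by a
#' fixed deterministic search order. For larger subnetworks, exhaustively
#' scores all parent sets of the centre gene drawn from the other members
#' (size `<= max_parents`) and returns a DAG whose edges all point into the
#' centre; sibling-sibling edges are left to the subnetworks centred at those
#' siblings.
#'
#' @inheritParams family_score
#' @param sub a `"local_subnetwork"` from [decompose_network()].
#' @param cfg a [search_config()].
#' @return a `"local_dag"`; edge weights hold each edge's family-score
#'   improvement (score with the edge minus score without it).
#' @export
learn_local_bn <- function(expr, sub, cfg = search_config()) {
  expr <- validate_expr(expr)
  members <- sub$members
  check_genes(expr, members)
  m <- cfg$max_parents
  cache <- new.env(parent = emptyenv())
  fs <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- .family_score_raw(expr, child, parents)
    cache[[key]]
  }
  if (length(members) <= cfg$exhaustive_node_limit) {
    parent_sets <- .best_dag_exact(members, m, fs)
  } else {
    center <- sub$center
    others <- setdiff(members, center)
    best <- NULL; best_score <- -Inf
    for (ps in .parent_subsets(others, m)) {
      s <- fs(center, ps)
      if (s > best_score + 1e-9) { best <- ps; best_score <- s }
    }
    parent_sets <- stats::setNames(vector("list", length(members)), members)
    for (g in members) parent_sets[[g]] <- character()
    parent_sets[[center]] <- best
  }
  family_scores <- vapply(members, function(g) fs(g, parent_sets[[g]]), numeric(1))
  ew <- numeric(); ek <- character()
  for (g in members) {
    ps <- parent_sets[[g]]
    for (u in ps) {
      ek <- c(ek, paste(u, g, sep = "\r"))
      ew <- c(ew, fs(g, ps) - fs(g, setdiff(ps, u)))
    }
  }
  local_dag(members, parent_sets, family_scores,
            edge_weights = stats::setNames(ew, ek))
}

# Exact optimum over all DAGs with in-degree <= m, by dynamic programming on
# node subsets: best(S) = max over sinks v in S of best(S \ v) + the best
# admissible parent set of v inside S \ v. Tie-break: higher score (1e-9
# tolerance), then fewer total edges, then first-found in the fixed
# enumeration order.
.best_dag_exact <- function(members, m, fs) {
  d <- length(members)
  full <- bitwShiftL(1L, d) - 1L
  # per node: candidate parent sets as bitmasks with precomputed scores
  ps_mask <- vector("list", d); ps_score <- vector("list", d)
  for (i in seq_len(d)) {
    subs <- .parent_subsets(members[-i], min(m, d - 1L))
    ps_mask[[i]] <- vapply(subs, function(s) .mask_of(s, members), integer(1))
    ps_score[[i]] <- vapply(subs, function(s) fs(members[i], s), numeric(1))
  }
  # bestfam[[i]][A + 1]: best parent-set score/size/index for node i with
  # parents restricted to the node set encoded by mask A.
  bf_score <- matrix(-Inf, d, full + 1L)
  bf_size <- matrix(0L, d, full + 1L)
  bf_idx <- matrix(1L, d, full + 1L)
  for (i in seq_len(d)) {
    pm <- ps_mask[[i]]; sc <- ps_score[[i]]
    sz <- vapply(pm, .popcount, integer(1))
    for (A in 0:full) {
      ok <- which(bitwAnd(pm, bitwNot(A)) == 0L)
      # candidates are ordered by size then lex; pick best score with that
      # preference on ties
      best <- ok[1L]; bs <- sc[ok[1L]]
      for (j in ok[-1L]) {
        if (sc[j] > bs + 1e-9) { best <- j; bs <- sc[j] }
      }
      bf_score[i, A + 1L] <- bs
      bf_size[i, A + 1L] <- sz[best]
      bf_idx[i, A + 1L] <- best
    }
  }
  best <- rep(-Inf, full + 1L); best[1L] <- 0
  cnt <- rep(0L, full + 1L)
  sink <- rep(NA_integer_, full + 1L)
  ord <- order(vapply(0:full, .popcount, integer(1)))
  for (S in (0:full)[ord]) {
    if (S == 0L) next
    for (v in seq_len(d)) {
      b <- bitwShiftL(1L, v - 1L)
      if (bitwAnd(S, b) == 0L) next
      R <- bitwAnd(S, bitwNot(b))
      s <- best[R + 1L] + bf_score[v, R + 1L]
      e <- cnt[R + 1L] + bf_size[v, R + 1L]
      better <- s > best[S + 1L] + 1e-9 ||
        (s > best[S + 1L] - 1e-9 && e < cnt[S + 1L])
      if (is.na(sink[S + 1L]) || better) {
        best[S + 1L] <- s; cnt[S + 1L] <- e; sink[S + 1L] <- v
      }
    }
  }
  parent_sets <- stats::setNames(vector("list", d), members)
  S <- full
  while (S != 0L) {
    v <- sink[S + 1L]
    R <- bitwAnd(S, bitwNot(bitwShiftL(1L, v - 1L)))
    pm <- ps_mask[[v]][bf_idx[v, R + 1L]]
    parent_sets[[members[v]]] <- members[.mask_bits(pm, d)]
    S <- R
  }
  parent_sets
}

.mask_of <- function(genes, members) {
  idx <- match(genes, members)
  if (!length(idx)) return(0L)
  as.integer(sum(bitwShiftL(1L, idx - 1L)))
}

.mask_bits <- function(mask, d) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)
}

.popcount <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}
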