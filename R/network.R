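# Gene networks and structural operations: thresholded initial network,
# shortest-path-k neighbourhoods, per-gene decomposition into local
# subnetworks, and integration of local DAGs into a global directed network.

.NET_STAGES <- c("G_MI", "G_B", "G_C", "G_F", "gold")

#' Construct a gene network
#'
#' A light-weight container for a (possibly directed) weighted graph over a
#' fixed gene universe. Undirected networks store each edge once in canonical
#' gene order (the row order of the expression matrix); isolated genes remain
#' in the node set so that evaluation over all ordered pairs is well defined.
#'
#' @param gene_ids character vector of unique gene identifiers (canonical
#'   order).
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (defaults to 1), or `NULL` for an edgeless network.
#' @param directed logical.
#' @param stage stage label, one of `"G_MI"`, `"G_B"`, `"G_C"`, `"G_F"`,
#'   `"gold"`.
#' @return an object of class `"gene_network"`.
#' @export
gene_network <- function(gene_ids, edges = NULL, directed = FALSE, stage = "G_MI") {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids) || anyDuplicated(gene_ids) || any(!nzchar(gene_ids)))
    stop_lbn("identifier", "gene_ids must be unique non-empty identifiers")
  stage <- match.arg(stage, .NET_STAGES)
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- data.frame(from = character(), to = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      stop_lbn("argument", "edges need 'from' and 'to' columns")
    if (is.null(edges$weight)) edges$weight <- 1
    edges <- edges[, c("from", "to", "weight")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    unknown <- setdiff(c(edges$from, edges$to), gene_ids)
    if (length(unknown))
      stop_lbn("identifier", "edge endpoint(s) not in gene universe: %s",
               paste(unique(unknown), collapse = ", "))
    if (any(edges$from == edges$to))
      stop_lbn("argument", "self-loop edges are not allowed")
    if (!directed) {
      i <- match(edges$from, gene_ids); j <- match(edges$to, gene_ids)
      swap <- i > j
      tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    }
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key))
      stop_lbn("argument", "duplicate edge(s): %s",
               paste(unique(gsub("\r", "->", key[duplicated(key)])), collapse = ", "))
    edges <- edges[order(match(edges$from, gene_ids), match(edges$to, gene_ids)), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(gene_ids = gene_ids, edges = edges, directed = directed,
                 stage = stage),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network %s: %d genes, %d %s edges>\n",
              x$stage, length(x$gene_ids), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character())
  paste(net$edges$from, net$edges$to, sep = "\r")
}

# igraph view used for shortest-path distances; direction is ignored so that
# neighbourhood queries on directed stage networks see the skeleton.
.net_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = net$gene_ids))
}

#' Build the initial network by thresholding pairwise MI
#'
#' Keeps an undirected edge `(i, j)` iff `mi[i, j] >= alpha`; all genes remain
#' as nodes even when isolated. This is the screening stage (`G_MI`) of the
#' inference pipeline.
#'
#' @param mi symmetric MI matrix with zero diagonal and gene ids as dimnames
#'   (see [pairwise_mi_matrix()]).
#' @param alpha nonnegative threshold in nats.
#' @return undirected `"gene_network"` with stage `"G_MI"`; edge weights are
#'   the MI values.
#' @export
build_initial_network <- function(mi, alpha) {
  if (!is.matrix(mi) || nrow(mi) != ncol(mi) || is.null(rownames(mi)))
    stop_lbn("argument", "mi must be a square matrix with gene ids as dimnames")
  if (!isSymmetric(unname(mi), tol = 1e-8))
    stop_lbn("argument", "mi matrix is not symmetric")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop_lbn("argument", "alpha must be a single nonnegative number")
  ids <- rownames(mi)
  sel <- which(upper.tri(mi) & mi >= alpha, arr.ind = TRUE)
  edges <- data.frame(from = ids[sel[, 1L]], to = ids[sel[, 2L]],
                      weight = mi[sel], stringsAsFactors = FALSE)
  gene_network(ids, edges, directed = FALSE, stage = "G_MI")
}

#' Genes within shortest-path distance k
#'
#' Returns all genes at unweighted shortest-path distance between 1 and `k`
#' (inclusive) of `gene`, excluding `gene` itself. Distances ignore edge
#' direction and weights. The cumulative (distance <= k) convention is used:
#' the `k = 2` neighbourhood contains the `k = 1` neighbourhood, which is what
#' makes it approximately cover a node's Markov blanket.
#'
#' @param net a `"gene_network"`.
#' @param gene gene identifier present in `net`.
#' @param k positive integer.
#' @return character vector of gene identifiers in canonical order.
#' @export
k_neighborhood <- function(net, gene, k) {
  if (!gene %in% net$gene_ids)
    stop_lbn("identifier", "unknown gene: %s", gene)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop_lbn("argument", "k must be a positive integer")
  d <- igraph::distances(.net_igraph(net), v = gene, mode = "all")[1L, ]
  nb <- names(d)[d >= 1 & d <= k]
  net$gene_ids[net$gene_ids %in% nb]
}

#' Decompose a network into per-gene local subnetworks
#'
#' Produces one local subnetwork per gene (in canonical order): the centre
#' gene plus its distance-`<= k` neighbourhood, with the induced edges of
#' `net`. An isolated centre yields a singleton subnetwork.
#'
#' @inheritParams k_neighborhood
#' @param k neighbourhood radius, typically 1 or 2.
#' @return list of `"local_subnetwork"` objects (fields `center`, `members`,
#'   `edges`, `k`), one per gene.
#' @export
decompose_network <- function(net, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop_lbn("argument", "k must be a positive integer")
  D <- igraph::distances(.net_igraph(net), mode = "all")
  D <- D[net$gene_ids, net$gene_ids, drop = FALSE]
  lapply(net$gene_ids, function(g) {
    nb <- net$gene_ids[D[g, ] >= 1 & D[g, ] <= k]
    members <- net$gene_ids[net$gene_ids %in% c(g, nb)]
    keep <- net$edges$from %in% members & net$edges$to %in% members
    structure(list(center = g, members = members,
                   edges = net$edges[keep, , drop = FALSE], k = k),
              class = "local_subnetwork")
  })
}

#' @export
print.local_subnetwork <- function(x, ...) {
  cat(sprintf("<local_subnetwork center=%s: %d members, %d edges, k=%d>\n",
              x$center, length(x$members), nrow(x$edges), x$k))
  invisible(x)
}

#' Integrate local DAGs into a candidate directed network
#'
#' Takes the union of all directed edges proposed by the local Bayesian
#' networks. When the same edge is proposed more than once its largest
#' supporting score improvement is kept; when both orientations `i -> j` and
#' `j -> i` are proposed, the orientation with the larger family-score
#' improvement wins, with ties (within `1e-9`) broken toward the
#' lexicographically smaller source gene, so the result never contains a
#' 2-cycle. The integrated network need not be globally acyclic; directed
#' cycles are left in place (and can be detected downstream) — only
#' antiparallel pairs are resolved.
#'
#' @param dags list of `"local_dag"` objects (see [learn_local_bn()]).
#' @param gene_ids gene universe of the result; defaults to the union of the
#'   DAGs' genes.
#' @param policy conflict policy for antiparallel edges; only
#'   `"score"` (described above) is implemented.
#' @return directed `"gene_network"` with stage `"G_B"`; edge weights are the
#'   best supporting family-score improvements.
#' @export
integrate_local_dags <- function(dags, gene_ids = NULL, policy = "score") {
  policy <- match.arg(policy, "score")
  if (is.null(gene_ids)) {
    gene_ids <- unique(unlist(lapply(dags, `[[`, "genes")))
    if (is.null(gene_ids)) gene_ids <- character()
  }
  all_edges <- do.call(rbind, lapply(dags, `[[`, "edges"))
  if (is.null(all_edges) || !nrow(all_edges))
    return(gene_network(gene_ids, NULL, directed = TRUE, stage = "G_B"))
  key <- paste(all_edges$from, all_edges$to, sep = "\r")
  w <- tapply(all_edges$weight, key, max)
  uk <- names(w)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  rev_key <- paste(to, from, sep = "\r")
  drop <- logical(length(uk))
  for (e in seq_along(uk)) {
    r <- match(rev_key[e], uk)
    if (is.na(r) || drop[r]) next
    dw <- w[[e]] - w[[r]]
    keep_e <- if (dw > 1e-9) TRUE else if (dw < -1e-9) FALSE else from[e] < from[r]
    drop[if (keep_e) r else e] <- TRUE
  }
  edges <- data.frame(from = from[!drop], to = to[!drop],
                      weight = as.numeric(w[!drop]), stringsAsFactors = FALSE)
  gene_network(gene_ids, edges, directed = TRUE, stage = "G_B")
}
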