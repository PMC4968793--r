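# Test helpers: fixtures built in code and independent brute-force oracles.
# The oracles deliberately avoid the package's own code paths.

# Random expression matrix with gene rownames.
rand_expr <- function(n, N, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * N), n, N, dimnames = list(sprintf("g%02d", seq_len(n)), NULL))
}

# Simulate a linear chain x -> z -> y (unit coefficients, unit noise).
chain_data <- function(N, seed = 1) {
  set.seed(seed)
  x <- rnorm(N); z <- x + rnorm(N); y <- z + rnorm(N)
  rbind(x = x, z = z, y = y)
}

# Brute force: all labelled digraphs over d nodes as edge subsets, keeping the
# acyclic ones (acyclicity checked by searching for a topological order over
# all permutations). Returns a sorted character vector of canonical DAG
# signatures "u>v|u>v|...".
oracle_all_dags <- function(genes, max_indegree = Inf) {
  d <- length(genes)
  pairs <- which(diag(d) == 0, arr.ind = TRUE)   # all ordered pairs
  n_e <- nrow(pairs)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  all_orders <- perms(seq_len(d))
  sigs <- character()
  for (mask in 0:(2^n_e - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_e) - 1L)) != 0L)
    from <- pairs[sel, 1L]; to <- pairs[sel, 2L]
    if (length(sel) && max(tabulate(to, d)) > max_indegree) next
    ok <- any(vapply(all_orders, function(ord) {
      pos <- order(ord)
      all(pos[from] < pos[to])
    }, logical(1)))
    if (!ok) next
    sig <- paste(sort(paste(genes[from], genes[to], sep = ">")), collapse = "|")
    sigs <- c(sigs, sig)
  }
  sort(sigs)
}

dag_signature <- function(parent_sets) {
  e <- character()
  for (g in names(parent_sets))
    for (p in parent_sets[[g]]) e <- c(e, paste(p, g, sep = ">"))
  paste(sort(e), collapse = "|")
}

# Breadth-first search truncated at depth k, on an undirected edge data frame.
oracle_bfs <- function(gene_ids, edges, start, k) {
  nb <- lapply(setNames(gene_ids, gene_ids), function(g)
    unique(c(edges$to[edges$from == g], edges$from[edges$to == g])))
  dist <- setNames(rep(Inf, length(gene_ids)), gene_ids)
  dist[start] <- 0
  frontier <- start
  depth <- 0
  while (length(frontier) && depth < k) {
    depth <- depth + 1
    nxt <- unique(unlist(nb[frontier]))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- depth
    frontier <- nxt
  }
  names(dist)[dist >= 1 & dist <= k]
}

# Sample a random undirected network over gene ids.
rand_network <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  gene_network(ids, data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                               weight = runif(sum(keep))),
               directed = FALSE)
}
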