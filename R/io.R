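# Text I/O: tab-separated expression matrices (DREAM dialect: header row of
# sample labels, gene identifiers in the first column), DREAM gold-standard
# edge lists (`regulator<TAB>target<TAB>{0,1}`), and weighted edge lists.

#' Read a tab-separated expression matrix
#'
#' @param path file path.
#' @param dialect `"genes_by_samples"` (rows are genes; first column holds
#'   gene ids, header row holds sample labels) or `"samples_by_genes"` (the
#'   transpose: header row holds gene ids, first column holds sample labels).
#' @return validated numeric matrix, genes in rows.
#' @export
read_expression <- function(path, dialect = c("genes_by_samples", "samples_by_genes")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_lbn("format", "expression file '%s' is empty", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncells <- lengths(cells)
  if (any(ncells != ncells[1L]))
    stop_lbn("format", "ragged rows in '%s' (line %d)", path,
             which(ncells != ncells[1L])[1L])
  body <- cells[-1L]
  row_ids <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_real_, length(body), ncells[1L] - 1L)
  for (r in seq_along(body)) {
    x <- suppressWarnings(as.numeric(body[[r]][-1L]))
    bad <- which(is.na(x))
    if (length(bad))
      stop_lbn("parse", "non-numeric cell at row %d ('%s'), column %d of '%s'",
               r, row_ids[r], bad[1L] + 1L, path)
    vals[r, ] <- x
  }
  if (dialect == "genes_by_samples") {
    ids <- row_ids
    m <- vals
  } else {
    ids <- cells[[1L]][-1L]
    m <- t(vals)
  }
  if (anyDuplicated(ids))
    stop_lbn("identifier", "duplicate gene identifier(s) in '%s': %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(m) <- ids
  validate_expr(m)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces them exactly.
#'
#' @param expr numeric expression matrix with gene rownames.
#' @param path output file.
#' @param sample_ids optional sample labels for the header row.
#' @export
write_expression <- function(expr, path, sample_ids = NULL) {
  expr <- validate_expr(expr)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(expr)))
  header <- paste(c("gene", sample_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(expr)), function(r)
    paste(c(rownames(expr)[r],
            formatC(expr[r, ], digits = 17, format = "g")), collapse = "\t"),
    "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a DREAM-format gold standard
#'
#' Lines of `regulator<TAB>target<TAB>label` with label in `{0, 1}` (a
#' missing third column means 1). Positives are the label-1 lines; label-0
#' lines contribute their genes to the universe only. Duplicate positive
#' lines are deduplicated with a warning.
#'
#' @param path file path.
#' @param genes optional additional gene identifiers to include in the
#'   universe.
#' @return directed `"gene_network"` with stage `"gold"` whose `gene_ids` is
#'   the full universe.
#' @export
read_gold <- function(path, genes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  from <- character(); to <- character(); lab <- integer()
  for (i in seq_along(cells)) {
    f <- cells[[i]]
    if (!length(f) %in% 2:3)
      stop_lbn("format", "line %d of '%s': expected 2 or 3 tab-separated fields", i, path)
    l <- if (length(f) == 3L) f[3L] else "1"
    if (!l %in% c("0", "1"))
      stop_lbn("format", "line %d of '%s': malformed label '%s'", i, path, l)
    if (f[1L] == f[2L])
      stop_lbn("format", "line %d of '%s': self-loop %s -> %s", i, path, f[1L], f[2L])
    from[i] <- f[1L]; to[i] <- f[2L]; lab[i] <- as.integer(l)
  }
  universe <- unique(c(genes, from, to))
  pos <- lab == 1L
  key <- paste(from[pos], to[pos], sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("deduplicated %d duplicate positive line(s) in '%s'",
                    sum(duplicated(key)), path))
    keep <- !duplicated(key)
  } else keep <- rep(TRUE, sum(pos))
  edges <- data.frame(from = from[pos][keep], to = to[pos][keep], weight = 1,
                      stringsAsFactors = FALSE)
  gene_network(universe, edges, directed = TRUE, stage = "gold")
}

#' Write a network as a weighted edge list
#'
#' One `source<TAB>target<TAB>weight` line per edge. Directed networks are
#' sorted by descending weight then lexicographically (stable for diffing);
#' undirected networks emit each edge once in canonical orientation.
#'
#' @param net a `"gene_network"`.
#' @param path output file.
#' @param gold logical; if `TRUE`, write DREAM gold format (`weight` column
#'   replaced by the constant label 1).
#' @export
write_edge_list <- function(net, path, gold = FALSE) {
  e <- net$edges
  if (net$directed && nrow(e))
    e <- e[order(-e$weight, e$from, e$to), , drop = FALSE]
  w <- if (gold) rep("1", nrow(e)) else formatC(e$weight, digits = 17, format = "g")
  writeLines(if (nrow(e)) paste(e$from, e$to, w, sep = "\t") else character(), path)
  invisible(path)
}

#' Read a weighted edge list as a network
#'
#' @param path file of `source<TAB>target<TAB>weight` lines.
#' @param gene_ids gene universe; defaults to the genes mentioned in the file.
#' @param directed logical.
#' @param stage stage label for the resulting network.
#' @return a `"gene_network"`.
#' @export
read_edge_list <- function(path, gene_ids = NULL, directed = TRUE, stage = "G_F") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    if (is.null(gene_ids))
      stop_lbn("format", "empty edge list '%s' and no gene universe given", path)
    return(gene_network(gene_ids, NULL, directed = directed, stage = stage))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 3L))
    stop_lbn("format", "line %d of '%s': expected 3 tab-separated fields",
             which(lengths(cells) != 3L)[1L], path)
  from <- vapply(cells, `[[`, "", 1L)
  to <- vapply(cells, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(cells, `[[`, "", 3L)))
  if (any(is.na(w)))
    stop_lbn("parse", "line %d of '%s': non-numeric weight", which(is.na(w))[1L], path)
  if (is.null(gene_ids)) gene_ids <- unique(c(from, to))
  gene_network(gene_ids, data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE),
               directed = directed, stage = stage)
}
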