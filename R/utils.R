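# Shared internal helpers: condition classes, RNG scoping, input validation.

# All package errors carry a subclass so callers (and the CLI) can react to the
# failure mode rather than parse messages:
#   lbn_identifier_error, lbn_argument_error, lbn_insufficient_samples_error,
#   lbn_degenerate_data_error, lbn_size_error, lbn_format_error,
#   lbn_parse_error, lbn_undefined_auc_error
stop_lbn <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(paste0("lbn_", class, "_error"), "lbn_error")))
}

# Run `code` under a fixed seed, restoring the caller's RNG state afterwards so
# that seeded subroutines never perturb user-level random streams.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# An expression matrix is a plain numeric matrix, one row per gene, one column
# per sample, with unique non-empty rownames (the canonical gene order).
validate_expr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_lbn("argument", "expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || any(!nzchar(rownames(expr))))
    stop_lbn("identifier", "expression matrix must carry gene identifiers as rownames")
  dup <- rownames(expr)[duplicated(rownames(expr))]
  if (length(dup))
    stop_lbn("identifier", "duplicate gene identifiers: %s",
             paste(unique(dup), collapse = ", "))
  if (nrow(expr) < 2L)
    stop_lbn("argument", "need at least 2 genes, got %d", nrow(expr))
  if (ncol(expr) < 3L)
    stop_lbn("insufficient_samples", "need at least 3 samples, got %d", ncol(expr))
  if (any(!is.finite(expr)))
    stop_lbn("argument", "expression matrix contains missing or non-finite values")
  expr
}

check_genes <- function(expr, genes, what = "gene") {
  if (!length(genes)) stop_lbn("argument", "empty %s set", what)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop_lbn("identifier", "unknown %s identifier(s): %s", what,
             paste(missing, collapse = ", "))
  invisible(genes)
}
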