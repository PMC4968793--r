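# Evaluation against gold-standard networks: confusion counts over ordered
# gene pairs, the standard metric panel, ROC/AUC threshold sweeps, per-gene
# AUC summaries, and a permutation-based MI significance threshold.

#' Confusion counts between predicted and gold networks
#'
#' Evaluates over the full pair universe of the shared gene set: all ordered
#' pairs `(i, j)`, `i != j` (`n * (n - 1)` pairs) in directed mode, or all
#' unordered pairs in undirected mode. Self-pairs are excluded.
#'
#' @param pred,gold `"gene_network"` objects over identical gene universes.
#'   In directed mode both must be directed.
#' @param mode `"directed"` or `"undirected"`.
#' @return object of class `"confusion_counts"`: list with integer fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, gold, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  if (!setequal(pred$gene_ids, gold$gene_ids))
    stop_lbn("identifier", "predicted and gold networks have different gene universes")
  n <- length(gold$gene_ids)
  pair_set <- function(net) {
    if (!nrow(net$edges)) return(character())
    f <- net$edges$from; t <- net$edges$to
    if (mode == "undirected") {
      swap <- f > t
      tmp <- f[swap]; f[swap] <- t[swap]; t[swap] <- tmp
      unique(paste(f, t, sep = "\r"))
    } else {
      if (!net$directed)
        stop_lbn("argument", "directed evaluation requires directed networks")
      paste(f, t, sep = "\r")
    }
  }
  p <- pair_set(pred); g <- pair_set(gold)
  universe <- if (mode == "directed") n * (n - 1L) else n * (n - 1L) / 2L
  TP <- length(intersect(p, g))
  FP <- length(setdiff(p, g))
  FN <- length(setdiff(g, p))
  TN <- universe - TP - FP - FN
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Metric panel from confusion counts
#'
#' Computes TPR, FPR, FDR, PPV, ACC, F and MCC:
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`, `FDR = FP/(TP+FP)`,
#' `PPV = TP/(TP+FP)`, `ACC = (TP+TN)/(TP+FP+TN+FN)`,
#' `F = 2*PPV*TPR/(PPV+TPR)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Zero denominators yield defined sentinels (0) so that threshold sweeps are
#' total functions.
#'
#' @param counts a `"confusion_counts"` object, or a list with fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @return named numeric vector with elements TPR, FPR, FDR, PPV, ACC, F, MCC.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  tot <- TP + FP + TN + FN
  if (tot <= 0) stop_lbn("argument", "no evaluated pairs")
  sdiv <- function(num, den) if (den > 0) num / den else 0
  TPR <- sdiv(TP, TP + FN)
  FPR <- sdiv(FP, FP + TN)
  FDR <- sdiv(FP, TP + FP)
  PPV <- sdiv(TP, TP + FP)
  ACC <- (TP + TN) / tot
  Fm <- sdiv(2 * PPV * TPR, PPV + TPR)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else 0
  c(TPR = TPR, FPR = FPR, FDR = FDR, PPV = PPV, ACC = ACC, F = Fm, MCC = MCC)
}

# Shared AUC core: scores and binary labels over a pair universe. Sweeps the
# threshold across distinct score values from large to small; tied scores are
# a single step; trapezoidal integration (equals the Mann-Whitney
# normalisation with ties counted 1/2).
.roc_core <- function(scores, labels) {
  P <- sum(labels); Ng <- sum(!labels)
  if (P == 0L || Ng == 0L)
    stop_lbn("undefined_auc", "AUC undefined: gold standard has %d positives and %d negatives",
             P, Ng)
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l, grp, sum)
  fp <- tapply(!l, grp, sum)
  thr <- s[!duplicated(s)]
  TPR <- c(0, cumsum(tp) / P)
  FPR <- c(0, cumsum(fp) / Ng)
  auc <- sum(diff(FPR) * (utils::head(TPR, -1L) + utils::tail(TPR, -1L)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), FPR = FPR, TPR = TPR),
       auc = auc)
}

# Confidence vector over the ordered-pair universe of `gold`, defaulting to 0
# for pairs absent from `ranked`.
.pair_scores <- function(ranked, gold) {
  ranked <- as.data.frame(ranked, stringsAsFactors = FALSE)
  cn <- names(ranked)
  conf_col <- if ("confidence" %in% cn) "confidence" else cn[3L]
  from <- as.character(ranked[[1L]]); to <- as.character(ranked[[2L]])
  unknown <- setdiff(c(from, to), gold$gene_ids)
  if (length(unknown))
    stop_lbn("identifier", "ranked pairs mention gene(s) outside the gold universe: %s",
             paste(unique(unknown), collapse = ", "))
  conf <- as.numeric(ranked[[conf_col]])
  if (any(!is.finite(conf)))
    stop_lbn("argument", "confidences must be finite")
  ids <- gold$gene_ids
  grid <- expand.grid(to = ids, from = ids, stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[grid$from != grid$to, ]
  key <- paste(grid$from, grid$to, sep = "\r")
  scores <- stats::setNames(rep(0, length(key)), key)
  rk <- paste(from, to, sep = "\r")
  if (anyDuplicated(rk)) {
    agg <- tapply(conf, rk, max)
    scores[names(agg)] <- agg
  } else {
    scores[rk] <- conf
  }
  labels <- key %in% paste(gold$edges$from, gold$edges$to, sep = "\r")
  list(key = key, scores = scores, labels = labels,
       from = grid$from, to = grid$to)
}

#' ROC curve and AUC for a ranked edge list
#'
#' Sweeps a confidence threshold from large to small over all ordered gene
#' pairs of the gold universe; pairs absent from `ranked` get confidence 0.
#'
#' @param ranked data frame whose first two columns are the ordered pair
#'   (regulator, target) and which carries a `confidence` column (or the
#'   third column), e.g. the output of [coef.lbn()].
#' @param gold a directed `"gene_network"` of true edges.
#' @return list with `points` (data frame `threshold`, `FPR`, `TPR`, starting
#'   at (0, 0) and ending at (1, 1)) and `auc` (trapezoidal area).
#' @export
roc_auc <- function(ranked, gold) {
  if (!gold$directed) stop_lbn("argument", "gold network must be directed")
  ps <- .pair_scores(ranked, gold)
  .roc_core(ps$scores, ps$labels)
}

#' Per-regulator or per-target AUC summary
#'
#' Restricts the ordered-pair universe to pairs with each gene in the stated
#' role, computes the AUC per gene, and summarises: mean AUC and the number /
#' proportion of evaluated genes with AUC above 0.7 and 0.8. Genes with no
#' gold positives (or no negatives) in-role are skipped and listed.
#'
#' @inheritParams roc_auc
#' @param role `"regulator"` (pairs `(g, *)`) or `"target"` (pairs `(*, g)`).
#' @return list with `auc` (named vector), `mean_auc`, `n_above` /
#'   `prop_above` (named by cutoff), and `skipped`.
#' @export
per_gene_auc <- function(ranked, gold, role = c("regulator", "target")) {
  role <- match.arg(role)
  if (!gold$directed) stop_lbn("argument", "gold network must be directed")
  ps <- .pair_scores(ranked, gold)
  anchor <- if (role == "regulator") ps$from else ps$to
  aucs <- numeric(0)
  skipped <- character(0)
  for (g in gold$gene_ids) {
    sel <- anchor == g
    lab <- ps$labels[sel]
    if (!sum(lab) || !sum(!lab)) { skipped <- c(skipped, g); next }
    aucs[g] <- .roc_core(ps$scores[sel], lab)$auc
  }
  cutoffs <- c(`0.7` = 0.7, `0.8` = 0.8)
  n_above <- vapply(cutoffs, function(ct) sum(aucs > ct), numeric(1))
  list(auc = aucs, mean_auc = if (length(aucs)) mean(aucs) else NA_real_,
       n_above = n_above,
       prop_above = if (length(aucs)) n_above / length(aucs) else n_above * NA,
       skipped = skipped)
}

#' Permutation null threshold for MI
#'
#' Builds an empirical null distribution of the Gaussian MI estimator by `B`
#' random sample-order permutations (each permutation shuffles one gene's
#' samples against another randomly chosen gene's) and returns the
#' `1 - significance` quantile, for use as a data-driven `alpha`/`beta`. This
#' is a permutation substitute for parametric significance tests of MI.
#'
#' @param expr expression matrix.
#' @param significance significance level in (0, 1), e.g. 0.05.
#' @param B number of permutations (>= 100).
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return threshold in nats.
#' @export
permutation_threshold <- function(expr, significance = 0.05, B = 1000L, seed = 1L) {
  expr <- validate_expr(expr)
  if (!is.numeric(significance) || length(significance) != 1L ||
      is.na(significance) || significance <= 0 || significance >= 1)
    stop_lbn("argument", "significance must lie strictly between 0 and 1")
  B <- as.integer(B)
  if (is.na(B) || B < 100L)
    stop_lbn("argument", "B must be at least 100 permutations")
  n <- nrow(expr); N <- ncol(expr)
  with_seed(seed, {
    null_mi <- vapply(seq_len(B), function(b) {
      ij <- sample.int(n, 2L)
      r <- stats::cor(expr[ij[1L], ], expr[ij[2L], sample.int(N)])
      max(0, -0.5 * log1p(-min(r^2, 1 - 1e-15)))
    }, numeric(1))
    stats::quantile(null_mi, 1 - significance, names = FALSE)
  })
}
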