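# Confusion counts, metric panel, ROC/AUC and the permutation threshold.

test_that("confusion counts match an exhaustive pair-by-pair oracle", {
  set.seed(61)
  ids <- letters[1:6]
  rand_net <- function(p) {
    grid <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    grid <- grid[grid$from != grid$to, ]
    keep <- runif(nrow(grid)) < p
    gene_network(ids, grid[keep, ], directed = TRUE, stage = "gold")
  }
  for (rep in 1:5) {
    pred <- rand_net(0.25); gold <- rand_net(0.2)
    cc <- confusion_counts(pred, gold, "directed")
    pk <- paste(pred$edges$from, pred$edges$to)
    gk <- paste(gold$edges$from, gold$edges$to)
    tp <- fp <- tn <- fn <- 0L
    for (i in ids) for (j in ids) {
      if (i == j) next
      p <- paste(i, j) %in% pk; g <- paste(i, j) %in% gk
      if (p && g) tp <- tp + 1L else if (p) fp <- fp + 1L
      else if (g) fn <- fn + 1L else tn <- tn + 1L
    }
    expect_identical(unclass(cc)[c("TP", "FP", "TN", "FN")],
                     list(TP = tp, FP = fp, TN = tn, FN = fn))
  }
  # perfect prediction
  g <- rand_net(0.3)
  cc <- confusion_counts(g, g, "directed")
  expect_identical(c(cc$FP, cc$FN), c(0L, 0L))
  # empty prediction vs 10-gene/10-edge gold: TP=0 FN=10 TN=80 FP=0
  fx <- make_fixture("dream10_like", N_samples = 50, seed = 62)
  none <- gene_network(fx$network$gene_ids, NULL, directed = TRUE, stage = "G_F")
  cc0 <- confusion_counts(none, fx$network, "directed")
  expect_identical(unclass(cc0)[c("TP", "FP", "TN", "FN")],
                   list(TP = 0L, FP = 0L, TN = 80L, FN = 10L))
  bad <- gene_network(c(ids, "zz"), NULL, directed = TRUE)
  expect_error(confusion_counts(bad, g, "directed"), class = "lbn_identifier_error")
})

test_that("the metric panel reproduces the published worked examples", {
  # 9-gene network, 24 gold edges, 15 true + 10 false predicted links
  m <- compute_metrics(list(TP = 15, FP = 10, TN = 38, FN = 9))
  published <- c(TPR = 0.625, FPR = 0.208, FDR = 0.400, PPV = 0.600,
                 ACC = 0.736, F = 0.612, MCC = 0.412)
  for (k in names(published))
    expect_lt(abs(m[[k]] - published[[k]]), 1e-3)
  # 10-gene benchmark: TPR 0.9, FPR 0.05 with 10 positives over 90 pairs
  m2 <- compute_metrics(list(TP = 9, FP = 4, TN = 76, FN = 1))
  published2 <- c(TPR = 0.900, FPR = 0.050, ACC = 0.944, PPV = 0.692)
  for (k in names(published2))
    expect_lt(abs(m2[[k]] - published2[[k]]), 1e-3)
})

test_that("metric identities and zero-denominator sentinels hold", {
  set.seed(63)
  for (rep in 1:20) {
    c4 <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                           c("TP", "FP", "TN", "FN")))
    if (sum(unlist(c4)) == 0) next
    m <- compute_metrics(c4)
    if (c4$TP + c4$FP > 0) expect_equal(m[["PPV"]], 1 - m[["FDR"]], tolerance = 1e-12)
    if (c4$TP + c4$FN > 0)
      expect_equal(m[["TPR"]] + c4$FN / (c4$TP + c4$FN), 1, tolerance = 1e-12)
    expect_true(all(m[c("TPR", "FPR", "FDR", "PPV", "ACC", "F")] >= 0 &
                    m[c("TPR", "FPR", "FDR", "PPV", "ACC", "F")] <= 1))
    expect_gte(m[["MCC"]], -1); expect_lte(m[["MCC"]], 1)
  }
  # perfect classifier
  mp <- compute_metrics(list(TP = 5, FP = 0, TN = 10, FN = 0))
  expect_equal(unname(mp[c("TPR", "FPR", "PPV", "ACC", "F", "MCC")]),
               c(1, 0, 1, 1, 1, 1))
  # all-sentinel case: nothing predicted, nothing positive except FN
  ms <- compute_metrics(list(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_equal(unname(ms[c("PPV", "FDR", "F", "MCC")]), c(0, 0, 0, 0))
})

test_that("ROC sweep matches the rank-sum AUC and is a proper curve", {
  fx <- make_fixture("dream10_like", N_samples = 50, seed = 64)
  gold <- fx$network
  ids <- gold$gene_ids
  set.seed(65)
  grid <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  sub <- grid[sample(nrow(grid), 20), ]
  ranked <- data.frame(sub, confidence = round(runif(20), 1))  # ties likely
  r <- roc_auc(ranked, gold)
  # oracle: Mann-Whitney with ties counted 1/2 over the full pair universe
  key <- paste(grid$from, grid$to)
  conf <- setNames(rep(0, nrow(grid)), key)
  conf[paste(sub$from, sub$to)] <- ranked$confidence
  lab <- key %in% paste(gold$edges$from, gold$edges$to)
  pos <- conf[lab]; neg <- conf[!lab]
  u <- sum(vapply(pos, function(p) sum(p > neg) + 0.5 * sum(p == neg), 0))
  expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-9)
  # curve shape
  expect_true(all(diff(r$points$FPR) >= 0))
  expect_true(all(diff(r$points$TPR) >= 0))
  expect_equal(unlist(r$points[1, c("FPR", "TPR")]), c(FPR = 0, TPR = 0))
  expect_equal(unlist(r$points[nrow(r$points), c("FPR", "TPR")]),
               c(FPR = 1, TPR = 1))
  # perfect separation and the all-tied diagonal
  perfect <- data.frame(gold$edges[, c("from", "to")], confidence = 1)
  expect_equal(roc_auc(perfect, gold)$auc, 1)
  flat <- data.frame(grid, confidence = 0.5)
  expect_equal(roc_auc(flat, gold)$auc, 0.5)
  # degenerate gold
  empty_gold <- gene_network(ids, NULL, directed = TRUE, stage = "gold")
  expect_error(roc_auc(ranked, empty_gold), class = "lbn_undefined_auc_error")
})

test_that("per-gene AUCs equal restricted-universe sweeps", {
  fx <- make_fixture("dream10_like", N_samples = 50, seed = 66)
  gold <- fx$network
  set.seed(67)
  ranked <- data.frame(gold$edges[, c("from", "to")],
                       confidence = runif(nrow(gold$edges)))
  res <- per_gene_auc(ranked, gold, role = "regulator")
  regs <- unique(gold$edges$from)
  expect_setequal(names(res$auc), setdiff(gold$gene_ids, res$skipped))
  for (g in names(res$auc)) {
    # oracle: restrict the universe to pairs (g, *) and rerun the sweep
    others <- setdiff(gold$gene_ids, g)
    sub_gold <- gene_network(gold$gene_ids,
                             gold$edges[gold$edges$from == g, ],
                             directed = TRUE, stage = "gold")
    key_pos <- paste(sub_gold$edges$from, sub_gold$edges$to)
    conf <- setNames(rep(0, length(others)), paste(g, others))
    rsel <- ranked[ranked$from == g, ]
    conf[paste(rsel$from, rsel$to)] <- rsel$confidence
    lab <- names(conf) %in% key_pos
    pos <- conf[lab]; neg <- conf[!lab]
    u <- sum(vapply(pos, function(p) sum(p > neg) + 0.5 * sum(p == neg), 0))
    expect_equal(res$auc[[g]], u / (length(pos) * length(neg)), tolerance = 1e-9)
  }
  # genes with no in-role gold positives are skipped
  expect_true(all(!res$skipped %in% gold$edges$from))
  # a perfectly ranked single regulator scores AUC 1
  expect_true(all(per_gene_auc(data.frame(gold$edges[, c("from", "to")],
                                          confidence = 1),
                               gold, "regulator")$auc == 1))
  expect_equal(unname(res$n_above), unname(vapply(c(0.7, 0.8),
                                                  function(ct) sum(res$auc > ct), 0)))
})

test_that("the permutation threshold is deterministic and matches the null law", {
  expr <- rand_expr(10, 100, seed = 68)
  t1 <- permutation_threshold(expr, 0.05, B = 2000, seed = 7)
  t2 <- permutation_threshold(expr, 0.05, B = 2000, seed = 7)
  expect_identical(t1, t2)
  # closed-form null: r^2 ~ Beta(1/2, (N-2)/2) for independent Gaussians,
  # so the threshold should be near -0.5*log(1 - qbeta(0.95, ...))
  expected <- -0.5 * log(1 - qbeta(0.95, 0.5, (100 - 2) / 2))
  expect_equal(t1, expected, tolerance = 0.15)
  # significance = 0.5 sits near the null median
  t50 <- permutation_threshold(expr, 0.5, B = 2000, seed = 7)
  med <- -0.5 * log(1 - qbeta(0.5, 0.5, (100 - 2) / 2))
  expect_equal(t50, med, tolerance = 0.2)
  expect_error(permutation_threshold(expr, 1.0), class = "lbn_argument_error")
  expect_error(permutation_threshold(expr, 0.05, B = 50), class = "lbn_argument_error")
})
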