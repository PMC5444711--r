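test_that("packaged panels are well-formed", {
  expect_length(cin70_panel()$genes, 70)
  expect_false(anyDuplicated(cin70_panel()$genes) > 0)
  expect_true("PIGN" %in% gpi_panel()$genes)
  expect_error(gene_panel("bad", c("A", "A")), "Duplicate")
  expect_error(gene_panel("empty", character()), "at least one")
})

test_that("row z-scoring uses the population convention and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 6))
  colnames(m) <- c("s1", "s2", "s3")
  coh <- expression_cohort(m, c("RA", "RA", "RARS"))
  expect_warning(z <- zscore_rows(coh), "zero-variance")
  expect_equal(unname(z$expr["a", ]),
               c(-1.224744871, 0, 1.224744871), tolerance = 1e-8)
  expect_false("b" %in% rownames(z$expr))
  z2 <- zscore_rows(z)
  expect_equal(z$expr, z2$expr, tolerance = 1e-12)
  one_col <- expression_cohort(m[, 1, drop = FALSE], "RA")
  expect_error(zscore_rows(one_col), "at least 2 samples")
})

test_that("panel_pc1 matches a dense eigendecomposition oracle", {
  set.seed(99)
  for (rep in 1:100) {
    p <- sample(2:10, 1); n <- sample(3:10, 1)
    m <- matrix(rnorm(p * n), nrow = p,
                dimnames = list(sprintf("g%d", 1:p), sprintf("s%d", 1:n)))
    coh <- expression_cohort(m, rep("RA", n))
    ps <- panel_pc1(coh, gene_panel("all", rownames(m)))
    # oracle: explicit z-score, eigen of the sample covariance of t(z)
    mu <- rowMeans(m); s <- sqrt(rowMeans((m - mu)^2))
    z <- (m - mu) / s
    x <- t(z)
    ev <- eigen(crossprod(x) / (n - 1), symmetric = TRUE)
    oracle <- as.vector(x %*% ev$vectors[, 1])
    flip <- sign(sum(oracle * ps$scores$score))
    expect_equal(ps$scores$score, flip * oracle, tolerance = 1e-8)
    expect_equal(ps$explained_variance_fraction,
                 ev$values[1] / sum(ev$values), tolerance = 1e-8)
  }
})

test_that("panel_pc1 on a rank-1 panel tracks the gene and explains all variance", {
  base <- c(1, 4, 2, 6)
  m <- rbind(g1 = base, g2 = base)
  colnames(m) <- sprintf("s%d", 1:4)
  coh <- expression_cohort(m, rep("RA", 4))
  ps <- panel_pc1(coh, gene_panel("dup", c("g1", "g2")))
  expect_equal(ps$explained_variance_fraction, 1, tolerance = 1e-12)
  z <- (base - mean(base)) / sqrt(mean((base - mean(base))^2))
  expect_equal(cor(ps$scores$score, z), 1, tolerance = 1e-12)
})

test_that("panel_pc1 orientation makes scores track the mean panel z-score", {
  coh <- simulate_expression_cohort(mds_cohort_preset(),
                                    list(gpi_panel(), cin70_panel()), seed = 5)
  for (p in list(gpi_panel(), cin70_panel())) {
    ps <- panel_pc1(coh, p)
    sub <- zscore_rows(panel_submatrix_for_test(coh, p))
    expect_gte(cor(ps$scores$score, colMeans(sub$expr)), 0)
  }
})

test_that("missing panel genes are skipped with a warning, few genes error", {
  m <- matrix(rnorm(12), nrow = 3,
              dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:4)))
  coh <- expression_cohort(m, rep("RA", 4))
  expect_warning(ps <- panel_pc1(coh, gene_panel("p", c("A", "B", "ZZZ"))),
                 "ZZZ")
  expect_equal(ps$n_genes, 2)
  expect_error(suppressWarnings(panel_pc1(coh, gene_panel("p", c("A", "X", "Y")))),
               "fewer than 2")
})

test_that("panel_correlation matches hand-computed values and is symmetric", {
  mk <- function(v, name) {
    structure(list(scores = tibble::tibble(sample = sprintf("s%d", seq_along(v)),
                                           score = v),
                   panel = name, n_genes = 2,
                   explained_variance_fraction = 0.5, orientation = 1),
              class = "panel_score")
  }
  a <- mk(c(1, 2, 3, 4), "a"); b <- mk(c(2, 1, 4, 3), "b")
  expect_equal(panel_correlation(a, b)$r, 0.6, tolerance = 1e-12)
  expect_equal(panel_correlation(a, b)$r, panel_correlation(b, a)$r)
  expect_equal(panel_correlation(a, a)$r, 1)
  expect_equal(panel_correlation(a, mk(-c(1, 2, 3, 4), "c"))$r, -1)
  # affine invariance with positive slope
  expect_equal(panel_correlation(mk(3 + 2 * c(1, 2, 3, 4), "d"), b)$r, 0.6,
               tolerance = 1e-12)
  # p from the t distribution on n - 2 df
  r <- 0.6; n <- 4
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(panel_correlation(a, b)$p, 2 * pt(-abs(tstat), n - 2),
               tolerance = 1e-12)
  expect_error(panel_correlation(a, mk(c(1, 1, 1, 1), "e")), "Zero-variance")
})

test_that("heatmap groups columns by subtype and clusters correlated rows", {
  set.seed(1)
  x <- rnorm(8); y <- rnorm(8)
  m <- rbind(a1 = x, a2 = x + rnorm(8, 0, 1e-3), b1 = -x, b2 = -x + rnorm(8, 0, 1e-3))
  colnames(m) <- sprintf("s%d", 1:8)
  subtype <- c("RAEB1", "RA", "RAEB1", "RA", "Control", "RA", "Control", "RAEB1")
  coh <- expression_cohort(m, subtype)
  hm <- heatmap_matrix(coh, gene_panel("p", rownames(m)))
  # columns grouped by subtype order, stable within subtype
  expect_equal(hm$col_order, c("s5", "s7", "s2", "s4", "s6", "s1", "s3", "s8"))
  # anticorrelated pairs form the two top-level clusters
  top_split <- stats::cutree(hm$hclust, k = 2)
  expect_equal(top_split[["a1"]], top_split[["a2"]])
  expect_equal(top_split[["b1"]], top_split[["b2"]])
  expect_false(top_split[["a1"]] == top_split[["b1"]])
  # identical rows sit adjacent
  m2 <- rbind(m, a3 = x)
  hm2 <- heatmap_matrix(expression_cohort(m2, subtype),
                        gene_panel("p", rownames(m2)))
  pos <- match(c("a1", "a3"), hm2$row_order)
  expect_lte(abs(diff(pos)), 2)  # a1/a2/a3 cluster together
})

test_that("random forest importance ranks a perfectly separating gene first", {
  coh <- toy_cohort(n_low = 30, n_high = 30, n_signal = 1, n_noise = 9,
                    effect = 10, seed = 1)
  for (s in 1:5) {
    imp <- tidy(rf_risk_importance(coh, gene_panel("p", rownames(coh$expr)),
                                   n_trees = 500, seed = s))
    expect_equal(imp$symbol[imp$rank == 1], "SIG1")
  }
})

test_that("importance is a permutation, deterministic under seed", {
  coh <- toy_cohort(seed = 2)
  p <- gene_panel("p", rownames(coh$expr))
  i1 <- tidy(rf_risk_importance(coh, p, seed = 10))
  i2 <- tidy(rf_risk_importance(coh, p, seed = 10))
  i3 <- tidy(rf_risk_importance(coh, p, seed = 11))
  expect_identical(i1, i2)
  expect_false(identical(i1$mda, i3$mda))
  expect_setequal(i1$rank, seq_len(nrow(i1)))
})

test_that("permuted labels give importances centred at zero", {
  coh <- toy_cohort(n_low = 30, n_high = 30, effect = 8, seed = 3)
  p <- gene_panel("p", rownames(coh$expr))
  # a fresh label permutation per repeat: no gene-label association remains
  mdas <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    perm <- coh
    perm$samples$risk <- perm$samples$risk[sample(nrow(perm$samples))]
    tidy(rf_risk_importance(perm, p, n_trees = 300, seed = s)) %>%
      dplyr::arrange(symbol) %>% dplyr::pull(mda)
  })
  m <- rowMeans(mdas)
  s <- apply(mdas, 1, sd)
  expect_true(all(abs(m) <= 3 * s + 1e-8))
})

test_that("a class with fewer than 2 samples is rejected", {
  coh <- toy_cohort(n_low = 10, n_high = 6, seed = 4)
  r <- as.character(coh$samples$risk)
  r[which(r == "high")[-1]] <- "low"   # leave exactly one 'high'
  coh$samples$risk <- factor(r, levels = c("low", "high"))
  expect_error(rf_risk_importance(coh, gene_panel("p", rownames(coh$expr)),
                                  seed = 1), "fewer than 2 samples")
})
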