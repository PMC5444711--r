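#' @noRd
panel_submatrix <- function(cohort, panel, min_genes = 2L) {
  stopifnot(inherits(cohort, "expression_cohort"), inherits(panel, "gene_panel"))
  present <- panel$genes[panel$genes %in% rownames(cohort$expr)]
  missing <- setdiff(panel$genes, present)
  if (length(present) < min_genes) {
    abort(paste0("Panel '", panel$name, "' has fewer than ", min_genes,
                 " genes in the matrix; missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(missing) > 0L) {
    warn(paste0("Panel '", panel$name, "': skipping ", length(missing),
                " absent gene(s): ", paste(head(missing, 5L), collapse = ", "),
                if (length(missing) > 5L) ", ..." else ""))
  }
  cohort$expr <- cohort$expr[present, , drop = FALSE]
  cohort
}

#' Per-sample panel score (first principal component)
#'
#' Scores each sample by its projection on the first principal component of
#' the row-z-scored panel submatrix, with samples as observations. The sign
#' of a principal component is arbitrary; it is fixed here so that the score
#' correlates non-negatively with the per-sample mean of the panel z-scores,
#' making the sign of downstream correlations reproducible.
#'
#' @param cohort An [expression_cohort()].
#' @param panel A [gene_panel()]; at least 2 panel genes must be present in
#'   the matrix (absent genes are skipped with a warning).
#' @return An object of class `panel_score`: tibble of per-sample scores plus
#'   the explained-variance fraction and the applied orientation.
#' @seealso [panel_correlation()]
#' @export
panel_pc1 <- function(cohort, panel) {
  sub <- panel_submatrix(cohort, panel)
  sub <- zscore_rows(sub)
  z <- sub$expr
  x <- t(z)                         # samples x genes, columns mean 0
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  evf <- pc$sdev[1]^2 / sum(pc$sdev^2)
  orientation <- 1
  msc <- colMeans(z)                # per-sample mean panel z-score
  if (sd(msc) > 0 && sd(scores) > 0 && cor(scores, msc) < 0) orientation <- -1
  scores <- orientation * scores
  structure(list(
    scores = tibble(sample = colnames(z), score = unname(scores)) %>%
      left_join(cohort$samples, by = "sample"),
    panel = panel$name,
    n_genes = nrow(z),
    explained_variance_fraction = unname(evf),
    orientation = orientation
  ), class = "panel_score")
}

#' @export
print.panel_score <- function(x, ...) {
  cat("<panel_score> ", x$panel, ": ", nrow(x$scores), " samples, ",
      x$n_genes, " genes, PC1 explains ",
      sprintf("%.1f%%", 100 * x$explained_variance_fraction), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.panel_score <- function(x, ...) x$scores

#' @export
glance.panel_score <- function(x, ...) {
  tibble(panel = x$panel, n_genes = x$n_genes,
         explained_variance_fraction = x$explained_variance_fraction,
         orientation = x$orientation)
}

#' @export
autoplot.panel_score <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$subtype, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7,
                         ggplot2::aes(colour = .data$risk)) +
    ggplot2::labs(y = paste0(object$panel, " PC1 score"), x = NULL)
}

#' Correlate two panel scores across samples
#'
#' Pearson product-moment correlation between the per-sample scores of two
#' panels, with a two-sided p-value from the t distribution on n - 2 degrees
#' of freedom.
#'
#' @param a,b `panel_score` objects over the same samples in the same order.
#' @return One-row tibble: `panel_a`, `panel_b`, `r`, `p`, `n`.
#' @export
panel_correlation <- function(a, b) {
  stopifnot(inherits(a, "panel_score"), inherits(b, "panel_score"))
  if (nrow(a$scores) != nrow(b$scores) ||
      !identical(a$scores$sample, b$scores$sample)) {
    abort("Panel scores must cover the same samples in the same order.")
  }
  x <- a$scores$score
  y <- b$scores$score
  if (length(x) < 3L) abort("Correlation needs at least 3 samples.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance panel scores.")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(panel_a = a$panel, panel_b = b$panel,
         r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Heat-map-ready panel matrix
#'
#' Row-z-scores the panel submatrix, groups columns by subtype (in subtype
#' order, preserving within-subtype input order) and orders rows by
#' average-linkage hierarchical clustering on 1 - Pearson correlation
#' distance.
#'
#' @inheritParams panel_pc1
#' @return An object of class `panel_heatmap` with the reordered matrix and
#'   the row/column orders.
#' @export
heatmap_matrix <- function(cohort, panel) {
  sub <- panel_submatrix(cohort, panel)
  sub <- zscore_rows(sub)
  z <- sub$expr
  col_order <- order(as.integer(sub$samples$subtype))  # stable sort
  if (nrow(z) > 1L) {
    d <- stats::as.dist(1 - cor(t(z)))
    hc <- stats::hclust(d, method = "average")
    row_order <- hc$order
  } else {
    hc <- NULL
    row_order <- 1L
  }
  structure(list(
    matrix = z[row_order, col_order, drop = FALSE],
    row_order = rownames(z)[row_order],
    col_order = colnames(z)[col_order],
    samples = sub$samples[col_order, ],
    hclust = hc,
    panel = panel$name
  ), class = "panel_heatmap")
}

#' @export
print.panel_heatmap <- function(x, ...) {
  cat("<panel_heatmap> ", x$panel, ": ", nrow(x$matrix), " genes x ",
      ncol(x$matrix), " samples\n", sep = "")
  invisible(x)
}

#' @export
tidy.panel_heatmap <- function(x, ...) {
  as_tibble(x$matrix, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "z") %>%
    mutate(gene = factor(.data$gene, levels = rev(x$row_order)),
           sample = factor(.data$sample, levels = x$col_order)) %>%
    left_join(x$samples, by = "sample")
}

#' @export
autoplot.panel_heatmap <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample, y = .data$gene,
                               fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_grid(. ~ subtype, scales = "free_x", space = "free_x") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z")
}

#' Random-forest permutation importance of panel genes for risk prediction
#'
#' Fits a random-forest classifier of the per-sample risk stratum (or the
#' full subtype) on the panel submatrix and ranks genes by unscaled
#' out-of-bag permutation importance (mean decrease in accuracy): for each
#' tree, out-of-bag accuracy minus accuracy after permuting the gene's
#' out-of-bag values, averaged over trees. Forest settings mirror the
#' classic defaults: `floor(sqrt(p))` variables per split, unlimited depth,
#' bootstrap sampling with replacement.
#'
#' @inheritParams panel_pc1
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; the ranking is fully reproducible under it.
#' @param classes `"risk"` for the binary low/high stratum (default) or
#'   `"subtype"` for the 5-class labels.
#' @return An object of class `importance_ranking`; `tidy()` returns a
#'   tibble (`symbol`, `mda`, `rank`) with rank 1 = largest mean decrease in
#'   accuracy, ties broken by panel order.
#' @export
rf_risk_importance <- function(cohort, panel, n_trees = 500, seed,
                               classes = c("risk", "subtype")) {
  classes <- match.arg(classes)
  sub <- panel_submatrix(cohort, panel)
  y <- droplevels(sub$samples[[classes]])
  if (nlevels(y) < 2L) abort("Need at least 2 classes present.")
  tab <- table(y)
  if (any(tab < 2L)) {
    abort(paste0("Class '", names(tab)[which(tab < 2L)[1]],
                 "' has fewer than 2 samples."))
  }
  x <- t(sub$expr)
  rf <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, importance = TRUE
  ))
  mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-mda, seq_along(mda))   # ties broken by panel order
  rank <- integer(length(mda))
  rank[ord] <- seq_along(mda)
  structure(list(
    importance = tibble(symbol = colnames(x), mda = unname(mda),
                        rank = rank) %>% arrange(rank),
    settings = list(n_trees = n_trees, seed = seed, classes = classes),
    oob_error = unname(rf$err.rate[n_trees, "OOB"]),
    panel = panel$name
  ), class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("<importance_ranking> ", x$panel, " panel, ",
      nrow(x$importance), " genes, ", x$settings$n_trees, " trees (",
      x$settings$classes, " classes), OOB error ",
      sprintf("%.3f", x$oob_error), "\n", sep = "")
  print(head(x$importance, 5))
  invisible(x)
}

#' @export
tidy.importance_ranking <- function(x, ...) x$importance

#' @export
glance.importance_ranking <- function(x, ...) {
  tibble(panel = x$panel, n_genes = nrow(x$importance),
         n_trees = x$settings$n_trees, classes = x$settings$classes,
         oob_error = x$oob_error)
}

#' @export
autoplot.importance_ranking <- function(object, ...) {
  d <- object$importance %>%
    mutate(symbol = factor(.data$symbol, levels = rev(.data$symbol)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mda, y = .data$symbol)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean decrease in accuracy", y = NULL)
}
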