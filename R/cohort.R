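#' Construct an expression cohort
#'
#' Bundles a gene-by-sample log2 expression matrix with per-sample subtype
#' annotations and the derived risk stratum. Subtypes follow the WHO myeloid
#' classification used for MDS risk stratification: `Control`, `RA`, `RARS`
#' (lower risk) and `RAEB1`, `RAEB2` (higher risk).
#'
#' @param expr Numeric matrix, rows = gene symbols (unique), columns = sample
#'   identifiers; log2 scale; all values finite.
#' @param subtype Character/factor vector of length `ncol(expr)` giving each
#'   sample's subtype.
#' @param subtype_levels Ordered subtype labels (defines column grouping order
#'   and the risk mapping).
#' @return An object of class `expression_cohort` with elements `expr`
#'   (matrix) and `samples` (tibble: `sample`, `subtype`, `risk`).
#' @seealso [risk_from_subtype()], [zscore_rows()], [panel_pc1()]
#' @export
expression_cohort <- function(expr, subtype,
                              subtype_levels = c("Control", "RA", "RARS",
                                                 "RAEB1", "RAEB2")) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("`expr` must carry gene symbols as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(expr))) {
    abort(paste0("Duplicate gene symbols in expression matrix: ",
                 paste(unique(rownames(expr)[duplicated(rownames(expr))]),
                       collapse = ", ")))
  }
  if (!all(is.finite(expr))) abort("Expression matrix must be finite.")
  subtype <- as.character(subtype)
  if (length(subtype) != ncol(expr)) {
    abort("`subtype` must have one label per sample (column).")
  }
  if (anyNA(subtype)) abort("Missing sample subtype labels are not allowed.")
  unknown <- setdiff(unique(subtype), subtype_levels)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown subtype label(s): ", paste(unknown, collapse = ", ")))
  }
  samples <- tibble(
    sample = colnames(expr),
    subtype = factor(subtype, levels = subtype_levels),
    risk = risk_from_subtype(subtype, subtype_levels = subtype_levels)
  )
  structure(list(expr = expr, samples = samples,
                 subtype_levels = subtype_levels),
            class = "expression_cohort")
}

#' Map disease subtype to risk stratum
#'
#' `Control`, `RA` and `RARS` map to `low`; the excess-blast subtypes `RAEB1`
#' and `RAEB2` map to `high`, mirroring the contrast between low-risk
#' subtypes/controls and high-risk disease.
#'
#' @param subtype Character vector of subtype labels.
#' @param high Labels mapped to the high-risk stratum.
#' @param subtype_levels Allowed labels.
#' @return Factor with levels `low`, `high`.
#' @export
risk_from_subtype <- function(subtype, high = c("RAEB1", "RAEB2"),
                              subtype_levels = c("Control", "RA", "RARS",
                                                 "RAEB1", "RAEB2")) {
  subtype <- as.character(subtype)
  unknown <- setdiff(unique(subtype), subtype_levels)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown subtype label(s): ", paste(unknown, collapse = ", ")))
  }
  factor(ifelse(subtype %in% high, "high", "low"), levels = c("low", "high"))
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", nrow(x$expr), " genes x ", ncol(x$expr),
      " samples\n", sep = "")
  print(dplyr::count(x$samples, .data$subtype, .data$risk))
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$expr)

#' Tidy an expression cohort into long form
#'
#' @param x An `expression_cohort`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `sample`, `subtype`, `risk`, `value`.
#' @export
tidy.expression_cohort <- function(x, ...) {
  as_tibble(x$expr, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") %>%
    left_join(x$samples, by = "sample")
}

#' Z-score the rows of an expression cohort
#'
#' Centers and scales every gene row to mean 0, standard deviation 1 using
#' the population convention (divisor n). Rows with zero variance carry no
#' between-sample information and are dropped with a warning rather than
#' imputed.
#'
#' @param cohort An [expression_cohort()] with at least 2 samples.
#' @return The cohort with z-scored rows (zero-variance rows removed).
#' @export
zscore_rows <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  m <- cohort$expr
  if (ncol(m) < 2L) abort("Row z-scoring needs at least 2 samples.")
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))  # population sd, divisor n
  zero <- s == 0
  if (any(zero)) {
    warn(paste0("Dropping ", sum(zero), " zero-variance row(s): ",
                paste(head(rownames(m)[zero], 5L), collapse = ", "),
                if (sum(zero) > 5L) ", ..." else ""))
    m <- m[!zero, , drop = FALSE]
    mu <- mu[!zero]
    s <- s[!zero]
  }
  cohort$expr <- (m - mu) / s
  cohort
}

#' Write / read an expression cohort as flat files
#'
#' The matrix is written as a tab-separated genes-by-samples table with a
#' one-line header (first column `gene`); sample annotations as CSV with
#' columns `sample`, `subtype`.
#'
#' @param cohort An [expression_cohort()].
#' @param expr_path,annot_path Output (or input) file paths.
#' @return `write_cohort()` returns `cohort` invisibly; `read_cohort()`
#'   returns an `expression_cohort`.
#' @export
write_cohort <- function(cohort, expr_path, annot_path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  readr::write_tsv(as_tibble(cohort$expr, rownames = "gene"), expr_path)
  readr::write_csv(cohort$samples[, c("sample", "subtype")], annot_path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @param subtype_levels Ordered subtype labels for [expression_cohort()].
#' @export
read_cohort <- function(expr_path, annot_path,
                        subtype_levels = c("Control", "RA", "RARS",
                                           "RAEB1", "RAEB2")) {
  tab <- readr::read_tsv(expr_path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  ann <- readr::read_csv(annot_path, show_col_types = FALSE)
  if (!all(c("sample", "subtype") %in% names(ann))) {
    abort("Annotation CSV must have columns `sample` and `subtype`.")
  }
  idx <- match(colnames(m), ann$sample)
  if (anyNA(idx)) abort("Annotation CSV is missing labels for some samples.")
  expression_cohort(m, ann$subtype[idx], subtype_levels = subtype_levels)
}
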