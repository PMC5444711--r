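#' Specify a synthetic colony-forming-cell (CFC) assay
#'
#' Parameters for [simulate_cfc_counts()], emulating proaerolysin-selection
#' CFC assays: GPI-anchored-protein-deficient clones resist the toxin, so
#' colony counts under selection estimate the deficiency frequency relative
#' to the control plating efficiency.
#'
#' @param true_frequency True GPI-AP deficiency frequency, in \[0, 1\].
#' @param cells_plated_selective Cells plated per selective replicate.
#' @param cells_plated_control Cells plated per non-selective replicate.
#' @param control_plating_efficiency Clonogenic plating efficiency in (0, 1\].
#' @param replicates Number of replicates (>= 1).
#' @return An object of class `cfc_spec`.
#' @export
cfc_spec <- function(true_frequency, cells_plated_selective = 1e6,
                     cells_plated_control = 2000,
                     control_plating_efficiency = 0.1, replicates = 3) {
  if (true_frequency < 0 || true_frequency > 1) {
    abort("`true_frequency` must be in [0, 1].")
  }
  if (control_plating_efficiency <= 0 || control_plating_efficiency > 1) {
    abort("`control_plating_efficiency` must be in (0, 1].")
  }
  if (cells_plated_selective < 1 || cells_plated_control < 1 || replicates < 1) {
    abort("Cell counts and replicates must be >= 1.")
  }
  structure(list(true_frequency = true_frequency,
                 cells_plated_selective = as.integer(cells_plated_selective),
                 cells_plated_control = as.integer(cells_plated_control),
                 control_plating_efficiency = control_plating_efficiency,
                 replicates = as.integer(replicates)),
            class = "cfc_spec")
}

#' Simulate CFC colony counts
#'
#' Per replicate, selective colonies ~ Binomial(cells plated selective,
#' true_frequency x plating efficiency) and control colonies ~
#' Binomial(cells plated control, plating efficiency).
#'
#' @param spec A [cfc_spec()].
#' @param seed Integer seed.
#' @param population Population label carried on the rows.
#' @return Tibble with one row per replicate: `population`, `replicate`,
#'   `cells_selective`, `colonies_selective`, `cells_control`,
#'   `colonies_control`.
#' @export
simulate_cfc_counts <- function(spec, seed, population = "sample") {
  stopifnot(inherits(spec, "cfc_spec"))
  with_seed(seed, {
    tibble(
      population = population,
      replicate = seq_len(spec$replicates),
      cells_selective = spec$cells_plated_selective,
      colonies_selective = rbinom(
        spec$replicates, spec$cells_plated_selective,
        spec$true_frequency * spec$control_plating_efficiency),
      cells_control = spec$cells_plated_control,
      colonies_control = rbinom(spec$replicates, spec$cells_plated_control,
                                spec$control_plating_efficiency)
    )
  })
}

#' Per-replicate GPI-AP deficiency frequency
#'
#' The mutant-frequency estimator for selective CFC assays: the selective
#' plating rate divided by the control plating efficiency,
#' `f = (colonies_selective / cells_selective) /
#' (colonies_control / cells_control)`. Sampling noise at high frequencies
#' can push the ratio above 1; such values are clipped to 1 with a warning.
#'
#' @param counts Tibble of replicate counts with columns `cells_selective`,
#'   `colonies_selective`, `cells_control`, `colonies_control` (as written
#'   by [simulate_cfc_counts()] or read from a replicate CSV).
#' @return The tibble with a `frequency` column added.
#' @export
#' @examples
#' deficiency_frequency(tibble::tibble(
#'   cells_selective = 1e6, colonies_selective = 12,
#'   cells_control = 2000, colonies_control = 200))$frequency  # 1.2e-4
deficiency_frequency <- function(counts) {
  counts <- as_tibble(counts)
  req <- c("cells_selective", "colonies_selective",
           "cells_control", "colonies_control")
  if (!all(req %in% names(counts))) {
    abort(paste0("`counts` must have columns: ", paste(req, collapse = ", ")))
  }
  if (any(counts$colonies_control <= 0)) {
    abort("Zero control colonies: plating efficiency undefined.")
  }
  if (any(counts$cells_selective <= 0) || any(counts$cells_control <= 0)) {
    abort("Cells plated must be > 0.")
  }
  if (any(counts$colonies_selective > counts$cells_selective) ||
      any(counts$colonies_control > counts$cells_control)) {
    abort("Colony counts cannot exceed cells plated.")
  }
  f <- (counts$colonies_selective / counts$cells_selective) /
    (counts$colonies_control / counts$cells_control)
  if (any(f > 1)) {
    warn(paste0(sum(f > 1), " frequency value(s) > 1 clipped to 1."))
    f <- pmin(f, 1)
  }
  mutate(counts, frequency = f)
}

#' Summarize deficiency frequencies across replicates
#'
#' Median (middle order statistic; mean of the middle two for even n) and
#' min-max range of the per-replicate frequencies, per population.
#'
#' @param counts Replicate tibble; the `frequency` column is computed with
#'   [deficiency_frequency()] if absent. A `population` column, if present,
#'   groups the summary.
#' @return Tibble: `population` (if present), `median`, `min`, `max`,
#'   `n_replicates`.
#' @export
summarize_deficiency <- function(counts) {
  counts <- as_tibble(counts)
  if (!"frequency" %in% names(counts)) counts <- deficiency_frequency(counts)
  if (nrow(counts) == 0L) abort("No valid replicate.")
  grp <- if ("population" %in% names(counts)) "population" else character()
  counts %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(median = median(.data$frequency),
              min = min(.data$frequency),
              max = max(.data$frequency),
              n_replicates = dplyr::n(), .groups = "drop")
}

#' Fold difference between two deficiency estimates
#'
#' Ratio of median frequencies, `a / b`.
#'
#' @param a,b One-row summaries from [summarize_deficiency()], or bare
#'   medians (numeric scalars).
#' @return The fold ratio (numeric scalar).
#' @export
#' @examples
#' fold_over(0.0120, 0.00009)  # 133.3
fold_over <- function(a, b) {
  med <- function(x) if (is.data.frame(x)) x$median else as.numeric(x)
  ma <- med(a); mb <- med(b)
  if (length(ma) != 1L || length(mb) != 1L) {
    abort("`a` and `b` must each carry a single median.")
  }
  if (mb <= 0) abort("Zero (or negative) denominator median.")
  ma / mb
}

# GPI-AP deficiency frequency of a normal population, as a proportion
NORMAL_GPI_DEFICIENCY_BACKGROUND <- 2e-5  # i.e. 0.002%

#' Fold over the normal-population background frequency
#'
#' @param a Summary (or median) as in [fold_over()].
#' @param background Background deficiency frequency as a proportion;
#'   default `2e-5` (0.002%), the approximate GPI-AP deficiency frequency of
#'   a normal population.
#' @return The fold ratio.
#' @export
fold_over_background <- function(a, background = NORMAL_GPI_DEFICIENCY_BACKGROUND) {
  fold_over(a, background)
}
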