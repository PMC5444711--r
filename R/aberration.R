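#' Relative expression fold change (delta-delta-Ct)
#'
#' Relative qPCR quantification at 100% amplification efficiency:
#' `fold = 2^-((Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator)`.
#'
#' @param measurements Tibble with columns `ct_target`, `ct_reference`,
#'   `ct_target_calibrator`, `ct_reference_calibrator` (all finite, > 0).
#' @return The tibble with `ddct` and `fold` columns added.
#' @export
#' @examples
#' fold_change_ddct(tibble::tibble(ct_target = 20, ct_reference = 18,
#'                                 ct_target_calibrator = 24,
#'                                 ct_reference_calibrator = 20))$fold  # 4
fold_change_ddct <- function(measurements) {
  m <- as_tibble(measurements)
  req <- c("ct_target", "ct_reference", "ct_target_calibrator",
           "ct_reference_calibrator")
  if (!all(req %in% names(m))) {
    abort(paste0("Need columns: ", paste(req, collapse = ", ")))
  }
  vals <- as.matrix(m[, req])
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("All Ct values must be finite and > 0.")
  }
  m %>%
    mutate(ddct = (.data$ct_target - .data$ct_reference) -
             (.data$ct_target_calibrator - .data$ct_reference_calibrator),
           fold = 2^(-.data$ddct))
}

#' Read the packaged patient expression-status table
#'
#' A 48-patient cohort fixture transcribed verbatim from the published
#' table: per patient, TP53 deletion status, PIGN protein expression status
#' (western blot; `N.D` = not determined), PIGN gene fold expression
#' (RT-qPCR relative to normal controls) and karyotype class.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Tibble: `id`, `age`, `sex`, `tp53_deletion`, `protein_status`
#'   (`present`/`absent`/`not_determined`), `fold_expression` (NA when not
#'   determined), `karyotype`.
#' @export
pign_patient_table <- function(path = system.file("extdata",
                                                  "pign_patient_status.csv",
                                                  package = "gpinstab")) {
  readr::read_csv(path, show_col_types = FALSE, na = "N.D",
                  col_types = readr::cols(
                    id = readr::col_character(),
                    age = readr::col_integer(),
                    sex = readr::col_character(),
                    tp53_deletion = readr::col_character(),
                    protein_status = readr::col_character(),
                    fold_expression = readr::col_double(),
                    karyotype = readr::col_character())) %>%
    mutate(protein_status = dplyr::coalesce(.data$protein_status,
                                            "not_determined"))
}

#' Classify transcript/protein expression aberration
#'
#' The aberrant expression pattern is elevated transcript with diminished
#' to absent protein. Operationally the call keys on protein absence:
#' `aberrant` when protein is absent, `concordant` when protein is present,
#' `indeterminate` when protein status (or, in strict mode, fold) is not
#' determined. The `basis` column records whether the fold also exceeds the
#' up-regulation threshold; `strict = TRUE` additionally requires
#' `fold >= fold_up_threshold` for an aberrant call, surfacing the tension
#' between the verbal definition and the protein-absent headline count.
#'
#' @param patients Patient tibble as from [pign_patient_table()] (columns
#'   `protein_status`, `fold_expression`).
#' @param fold_up_threshold Fold threshold counting as elevated transcript
#'   (default 2).
#' @param strict Require elevated fold as well as absent protein?
#' @return The tibble with `call` and `basis` columns added.
#' @export
classify_aberration <- function(patients, fold_up_threshold = 2.0,
                                strict = FALSE) {
  p <- as_tibble(patients)
  if (!all(c("protein_status", "fold_expression") %in% names(p))) {
    abort("Need columns `protein_status` and `fold_expression`.")
  }
  bad <- setdiff(unique(p$protein_status),
                 c("present", "absent", "not_determined"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown protein_status value(s): ", paste(bad, collapse = ", ")))
  }
  fold_up <- !is.na(p$fold_expression) & p$fold_expression >= fold_up_threshold
  call <- dplyr::case_when(
    p$protein_status == "not_determined" ~ "indeterminate",
    p$protein_status == "present" ~ "concordant",
    strict & is.na(p$fold_expression) ~ "indeterminate",
    strict & !fold_up ~ "concordant",
    TRUE ~ "aberrant"
  )
  basis <- dplyr::case_when(
    call == "indeterminate" ~ "protein or fold not determined",
    p$protein_status == "present" ~ "protein present",
    fold_up ~ sprintf("protein absent, fold >= %.1f", fold_up_threshold),
    TRUE ~ sprintf("protein absent, fold < %.1f", fold_up_threshold)
  )
  mutate(p, call = call, basis = basis)
}

#' Summarize aberration calls over a cohort
#'
#' @inheritParams classify_aberration
#' @return One-row tibble: `total`, `determined` (protein status
#'   determined), `aberrant`, `protein_absent`, `complex_karyotype`,
#'   `tp53_deleted`.
#' @export
cohort_summary <- function(patients, fold_up_threshold = 2.0, strict = FALSE) {
  p <- classify_aberration(patients, fold_up_threshold = fold_up_threshold,
                           strict = strict)
  if (nrow(p) == 0L) abort("Empty patient table.")
  tibble(
    total = nrow(p),
    determined = sum(p$protein_status != "not_determined"),
    aberrant = sum(p$call == "aberrant"),
    protein_absent = sum(p$protein_status == "absent"),
    complex_karyotype = if ("karyotype" %in% names(p)) {
      sum(p$karyotype == "Complex", na.rm = TRUE)
    } else NA_integer_,
    tp53_deleted = if ("tp53_deletion" %in% names(p)) {
      sum(p$tp53_deletion == "+", na.rm = TRUE)
    } else NA_integer_
  )
}
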