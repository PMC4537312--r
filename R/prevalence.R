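#' Aggregate mentions to patient-level ADE flags
#'
#' A patient is flagged positive for an ADE when at least one of their
#' mentions of it, in any document, ended with positive status (`candidate`
#' or `retained`); a patient whose every mention was removed is flagged
#' negative. One flag per (patient, ADE) pair.
#'
#' @param mentions A mention tibble carrying `patient_id`
#'   ([annotate_corpus()]).
#' @param ade_id Optional single ADE to restrict to; default all ADEs
#'   present.
#' @return A tibble `patient_id`, `ade_id`, `positive` (logical).
#' @export
patient_level_flags <- function(mentions, ade_id = NULL) {
  if (!"patient_id" %in% names(mentions) || anyNA(mentions$patient_id)) {
    ade_abort("every mention needs a patient_id to compute patient-level flags")
  }
  if (!is.null(ade_id)) mentions <- mentions[mentions$ade_id %in% ade_id, , drop = FALSE]
  mentions |>
    dplyr::mutate(pos = .data$status %in% c("candidate", "retained")) |>
    dplyr::group_by(.data$patient_id, .data$ade_id) |>
    dplyr::summarise(positive = any(.data$pos), .groups = "drop")
}

#' Build a stratified prevalence table
#'
#' Splits a patient cohort by one attribute and reports, per stratum, the
#' cohort size, the number of patients flagged positive for the ADE, and the
#' prevalence as a percentage, plus a totals row. Patients missing the
#' stratifier are collected in an explicit `"unknown"` stratum.
#'
#' @param flags Patient-level flags ([patient_level_flags()]), or any tibble
#'   with `patient_id`, `ade_id`, `positive`.
#' @param patients Patient attribute table: `patient_id` plus attribute
#'   columns (e.g. `age_band`, `gender`, `ethnicity`, `diagnosis`). Defines
#'   the cohort: every row is a cohort member whether or not mentioned.
#' @param stratifier Name of the attribute column to stratify by.
#' @param ade_id The ADE to tabulate.
#' @return A `stratified_table` tibble: `stratum`, `cohort_size`,
#'   `positive_count`, `prevalence` (percent), with a final `"total"` row.
#' @export
build_stratified_table <- function(flags, patients, stratifier, ade_id) {
  if (!stratifier %in% names(patients)) {
    ade_abort(sprintf("patients table has no column '%s'", stratifier))
  }
  strat <- as.character(patients[[stratifier]])
  strat[is.na(strat) | !nzchar(strat)] <- "unknown"
  fl <- flags[flags$ade_id == ade_id & flags$positive, , drop = FALSE]
  pos <- patients$patient_id %in% fl$patient_id
  tab <- tibble::tibble(stratum = strat, pos = pos) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      cohort_size = dplyr::n(),
      positive_count = sum(.data$pos),
      .groups = "drop"
    )
  tab <- dplyr::bind_rows(tab, tibble::tibble(
    stratum = "total",
    cohort_size = nrow(patients),
    positive_count = sum(pos)
  ))
  tab$prevalence <- 100 * tab$positive_count / tab$cohort_size
  structure(tab, class = c("stratified_table", class(tab)))
}

#' Pearson chi-square test of heterogeneity
#'
#' Pearson's X² on a strata-by-outcome count table,
#' \eqn{X^2 = \sum (O - E)^2 / E} with expectations from the row/column
#' margins, df = (rows − 1)(cols − 1), and **no** continuity correction
#' (Yates-corrected values do not reproduce the reference statistics this
#' package's tests pin down). The p-value comes from the chi-square survival
#' function.
#'
#' @param x A matrix or data frame of non-negative counts, typically strata
#'   in rows and `positive` / `negative` in columns.
#' @return A `chisq_result` list: `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi_square <- function(x) {
  m <- as.matrix(x)
  if (any(m < 0) || anyNA(m)) ade_abort("counts must be non-negative and complete")
  if (nrow(m) < 2 || ncol(m) < 2) ade_abort("need at least a 2 x 2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    ade_abort("zero row/column margin: expected counts are undefined")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = unname(ht$p.value),
      expected = ht$expected
    ),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Chi-square heterogeneity across the strata of a prevalence table
#'
#' Convenience wrapper: drops the totals row of a [build_stratified_table()]
#' result, forms the strata × (positive, negative) count matrix and runs
#' [pearson_chi_square()].
#'
#' @param table A `stratified_table`.
#' @return A `chisq_result`.
#' @export
prevalence_chi_square <- function(table) {
  tab <- table[table$stratum != "total", , drop = FALSE]
  m <- cbind(
    positive = tab$positive_count,
    negative = tab$cohort_size - tab$positive_count
  )
  rownames(m) <- tab$stratum
  pearson_chi_square(m)
}

#' Reconstruct an integer count from a printed prevalence
#'
#' Published prevalence tables often print per-stratum prevalences as
#' percentages (two decimals) without the underlying counts. The count is
#' recovered as `prevalence/100 * cohort`, rounded half-up. Vectorised.
#'
#' @param prevalence_percent Prevalence in percent, `0..100`.
#' @param cohort_size Stratum cohort size (non-negative).
#' @return Integer count(s).
#' @export
reconstruct_counts <- function(prevalence_percent, cohort_size) {
  if (any(prevalence_percent < 0 | prevalence_percent > 100, na.rm = TRUE)) {
    ade_abort("prevalence_percent must lie in [0, 100]")
  }
  if (any(cohort_size < 0, na.rm = TRUE)) ade_abort("cohort_size must be non-negative")
  as.integer(floor(prevalence_percent / 100 * cohort_size + 0.5))
}
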