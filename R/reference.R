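#' Published EPSE prevalence reference table
#'
#' The package ships the published stratified prevalence table for the four
#' extrapyramidal side effects (EPSEs) in a cohort of 12,879 patients with
#' serious mental illness: per-stratum cohort sizes and prevalences (percent,
#' two decimals) under four partitions of the same cohort — eight age bands,
#' gender, four ethnic groups and three SMI diagnoses — plus the per-EPSE
#' totals (390, 750, 440, 324 patients). Per-stratum counts were not
#' published; [epse_reference_counts()] reconstructs them with
#' [reconstruct_counts()].
#'
#' @return `epse_prevalence_reference()`: tibble `partition`, `stratum`,
#'   `cohort_size`, and one prevalence column per EPSE.
#'   `epse_totals_reference()`: tibble `ade_id`, `total_patients`.
#' @export
epse_prevalence_reference <- function() {
  path <- system.file("extdata", "epse_smi_prevalence.csv", package = "ademiner")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname epse_prevalence_reference
#' @export
epse_totals_reference <- function() {
  path <- system.file("extdata", "epse_smi_totals.csv", package = "ademiner")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Reconstructed per-stratum EPSE counts
#'
#' Recovers the integer positive count for each stratum of one partition of
#' the reference cohort as round-half-up(prevalence/100 × cohort). Summed
#' over the strata of any partition these reproduce the published per-EPSE
#' totals, which is the consistency check that validates the half-up
#' rounding convention.
#'
#' @param partition One of `"age"`, `"gender"`, `"ethnicity"`,
#'   `"diagnosis"`.
#' @param ade_id One of `"dystonia"`, `"akathisia"`, `"parkinsonism"`,
#'   `"tardive_dyskinesia"`; `NULL` returns all four count columns.
#' @return A tibble `stratum`, `cohort_size`, plus count column(s).
#' @export
epse_reference_counts <- function(partition = c("age", "gender", "ethnicity", "diagnosis"),
                                  ade_id = NULL) {
  partition <- match.arg(partition)
  ref <- epse_prevalence_reference()
  ref <- ref[ref$partition == partition, , drop = FALSE]
  ades <- c("dystonia", "akathisia", "parkinsonism", "tardive_dyskinesia")
  if (!is.null(ade_id)) {
    ades <- match.arg(ade_id, ades)
  }
  out <- tibble::tibble(stratum = ref$stratum, cohort_size = ref$cohort_size)
  for (a in ades) out[[a]] <- reconstruct_counts(ref[[a]], ref$cohort_size)
  out
}

#' Worked examples of the rule cascade
#'
#' A curated set of short note texts, one rule family each: seven in which a
#' removal stage should demote the dystonia mention, four in which a
#' possessive retain cue confirms it, and one in which a retain override
#' rescues a negated mention. Useful as a smoke test of a gazetteer/config
#' combination and used by the package's own acceptance checks.
#'
#' @return A tibble `text`, `ade_id`, `expected` (`"removed"` /
#'   `"positive"`), `family`.
#' @export
worked_examples <- function() {
  path <- system.file("extdata", "worked_examples.csv", package = "ademiner")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
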