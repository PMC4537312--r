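#' Default context mix for the synthetic corpus generator
#'
#' Proportions of the eleven context families embedded in generated notes.
#' The defaults put most mass on plain affirmative mentions and negated
#' mentions — the two commonest contexts around ADE terms in clinical
#' narrative — with the remaining removal families (monitoring, warnings,
#' other-person, organisations, hypotheticals, homonyms, punctuation cues,
#' drug-effect listings) sharing the tail.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_context_mix <- function() {
  c(
    plain = 0.30, retain = 0.10, negation = 0.15, monitoring = 0.08,
    warning = 0.10, other_person = 0.07, organisation = 0.04,
    hypothetical = 0.07, diagnosis_homonym = 0.02, symbol = 0.03,
    drug_listing = 0.04
  )
}

# One template per row: sentence with a {T} slot, the gold label, and the
# single removal stage (or retain clause) expected to decide it. Templates
# are crafted so exactly one rule family fires — the degradation property
# of the generator depends on that.
context_templates <- function() {
  tpl <- function(family, text, label, stage) {
    tibble::tibble(family = family, template = text, label = label, stage = stage)
  }
  dplyr::bind_rows(
    tpl("plain", "Patient experienced {T} overnight.", "positive", NA),
    tpl("plain", "On examination {T} was evident.", "positive", NA),
    tpl("plain", "Marked {T} noted at clinic today.", "positive", NA),
    tpl("plain", "Ongoing {T} affecting daily activities.", "positive", NA),
    tpl("retain", "Her {T} had become worse.", "positive", "S12.retain_possessive"),
    tpl("retain", "His {T} remains a problem.", "positive", "S12.retain_possessive"),
    tpl("retain", "The {T} was severe last night.", "positive", "S12.retain_possessive"),
    tpl("retain", "Patient was diagnosed with {T} in January.", "positive", "S12.retain_diagnostic"),
    tpl("retain", "The patient does not think the {T} was painful.", "positive", "S12.retain_possessive"),
    tpl("negation", "She denied any {T}.", "negative", "S1.negation_before"),
    tpl("negation", "There was no {T} at assessment.", "negative", "S1.negation_before"),
    tpl("negation", "Patient did not have {T}.", "negative", "S1.negation_before"),
    tpl("negation", "{T} was ruled out.", "negative", "S2.negation_after"),
    tpl("negation", "{T} seems unlikely at this stage.", "negative", "S2.negation_after"),
    tpl("monitoring", "Check for any {T}.", "negative", "S6.monitor"),
    tpl("monitoring", "We will monitor for {T} at next review.", "negative", "S6.monitor"),
    tpl("monitoring", "Continue to watch for {T}.", "negative", "S6.monitor"),
    tpl("warning", "Discussed possibility of {T} with ZZZZZ.", "negative", "S7.negative_effects"),
    tpl("warning", "Warned about {T} before starting treatment.", "negative", "S7.negative_effects"),
    tpl("warning", "Explained risk of {T} on admission.", "negative", "S7.negative_effects"),
    tpl("other_person", "Mother had developed {T} many years ago.", "negative", "S5.other_person"),
    tpl("other_person", "Her sister has {T}.", "negative", "S5.other_person"),
    tpl("other_person", "Father experienced {T} in his youth.", "negative", "S5.other_person"),
    tpl("organisation", "{T} Society have always been a useful resource for carers.", "negative", "S3.organisation"),
    tpl("organisation", "Leaflet from {T} Association was provided.", "negative", "S3.organisation"),
    tpl("hypothetical", "If {T} develops seek urgent review.", "negative", "S11.hypothetical"),
    tpl("hypothetical", "If {T} occurs stop the current dose.", "negative", "S11.hypothetical"),
    tpl("diagnosis_homonym", "Ego {T} was explored in the session.", "negative", "S9.diagnosis_homonym"),
    tpl("diagnosis_homonym", "Themes of ego {T} arose in therapy.", "negative", "S9.diagnosis_homonym"),
    tpl("symbol", "Query {T}?", "negative", "S4.symbol_punct"),
    tpl("symbol", "Seen in {T} / movement clinic.", "negative", "S4.symbol_punct"),
    tpl("drug_listing", "Noted {T} secondary to antipsychotic medication.", "negative", "S10.drug_effects"),
    tpl("drug_listing", "{T} likely induced by clozapine.", "negative", "S10.drug_effects")
  )
}

filler_sentences <- function() {
  c(
    "Slept well overnight.",
    "Appetite remains good.",
    "Attended ward round this morning.",
    "Engaged well with activities.",
    "Community team to follow up next week.",
    "Mental state settled on review.",
    "Plans for weekend leave discussed.",
    "Remains on the same ward."
  )
}

# spelling variants offered per starter ADE (beyond the canonical surface)
ade_variants <- function() {
  list(
    dystonia = c("dystonic reactions", "acute dystonia"),
    akathisia = c("akithisia", "acathisia", "akathesia"),
    parkinsonism = c("parkinsonian", "pseudoparkinsonism"),
    tardive_dyskinesia = c("orofacial dyskinesia")
  )
}

#' Generate a synthetic clinical-note corpus with gold labels
#'
#' Builds a fully labelled corpus that emulates the *contextual* structure
#' the rule cascade targets — ADE terms embedded in plain affirmative,
#' retain-cue, negated, monitoring, warning, other-person, organisation,
#' hypothetical, diagnosis-homonym, symbol-adjacent and drug-listing
#' sentences — without any claim to wider clinical realism. Each document is
#' 1–6 sentences: 1–2 templated mention sentences plus neutral filler.
#' Casing jitter and a configurable misspelling rate (spelling-variant
#' surfaces drawn from the starter lexicons) keep matches from being
#' positional artefacts; filler and jitter never introduce cue terms. Every
#' embedded term gets exactly one gold label (positive for plain/retain
#' families, negative otherwise), and per-patient truth flags plus a patient
#' attribute table (age band, gender, ethnicity, SMI diagnosis, sampled from
#' the reference cohort's category frequencies) are bookkept alongside.
#'
#' The `diagnosis_homonym` family exists only for dystonia (the shipped
#' homonym dictionary covers "ego dystonia"); giving it positive weight
#' without dystonia among `ades` is a validation error.
#'
#' @param n_patients Number of patients.
#' @param docs_per_patient Length-2 integer range; documents per patient are
#'   drawn uniformly from it.
#' @param ades Character vector of starter-ADE ids to embed.
#' @param context_mix Named proportions over the eleven context families;
#'   must sum to 1.
#' @param misspelling_rate Probability that a mention uses a spelling-variant
#'   surface instead of the canonical term.
#' @param seed Integer seed; the seed fully determines the corpus.
#' @return A `generated_corpus` list: `documents`, `gold` (with bookkeeping
#'   columns `family`, `stage`), `patients`, `truth`, `spec`.
#' @export
generate_corpus <- function(n_patients = 40,
                            docs_per_patient = c(1, 3),
                            ades = c("dystonia", "akathisia", "parkinsonism",
                                     "tardive_dyskinesia"),
                            context_mix = default_context_mix(),
                            misspelling_rate = 0.1,
                            seed = 1L) {
  families <- names(default_context_mix())
  if (is.null(names(context_mix)) || !setequal(names(context_mix), families)) {
    ade_abort(sprintf("context_mix must be named over: %s",
                      paste(families, collapse = ", ")))
  }
  context_mix <- context_mix[families]
  if (any(context_mix < 0) || abs(sum(context_mix) - 1) > 1e-8) {
    ade_abort("context_mix proportions must be non-negative and sum to 1")
  }
  if (context_mix[["diagnosis_homonym"]] > 0 && !"dystonia" %in% ades) {
    ade_abort("diagnosis_homonym contexts require dystonia among the embedded ADEs")
  }
  if (misspelling_rate < 0 || misspelling_rate > 1) {
    ade_abort("misspelling_rate must be in [0, 1]")
  }
  stopifnot(length(docs_per_patient) == 2, docs_per_patient[1] >= 1,
            docs_per_patient[2] >= docs_per_patient[1])

  templates <- context_templates()
  variants <- ade_variants()
  fillers <- filler_sentences()
  attrs <- reference_attribute_distributions()

  withr::with_seed(seed, {
    patients <- tibble::tibble(
      patient_id = sprintf("p%04d", seq_len(n_patients)),
      age_band = sample(attrs$age$stratum, n_patients, TRUE, attrs$age$p),
      gender = sample(attrs$gender$stratum, n_patients, TRUE, attrs$gender$p),
      ethnicity = sample(attrs$ethnicity$stratum, n_patients, TRUE, attrs$ethnicity$p),
      diagnosis = sample(attrs$diagnosis$stratum, n_patients, TRUE, attrs$diagnosis$p)
    )

    docs <- list(); golds <- list()
    doc_no <- 0L
    for (p in seq_len(n_patients)) {
      n_docs <- sample(seq(docs_per_patient[1], docs_per_patient[2]), 1)
      for (d in seq_len(n_docs)) {
        doc_no <- doc_no + 1L
        doc_id <- sprintf("d%05d", doc_no)
        n_mentions <- sample(1:2, 1)
        n_filler <- sample(0:4, 1)
        pieces <- list()
        for (m in seq_len(n_mentions)) {
          fam <- sample(families, 1, prob = context_mix)
          rows <- which(templates$family == fam)
          row <- templates[rows[sample(length(rows), 1)], ]
          if (fam == "diagnosis_homonym") {
            ade <- "dystonia"; term <- "dystonia"
          } else {
            ade <- if (length(ades) == 1) ades else sample(ades, 1)
            term <- stringi::stri_replace_all_fixed(ade, "_", " ")
            vs <- variants[[ade]]
            if (!is.null(vs) && stats::runif(1) < misspelling_rate) {
              term <- vs[sample(length(vs), 1)]
            }
          }
          r <- stats::runif(1)  # casing jitter
          if (r < 0.15) term <- stringi::stri_trans_totitle(term)
          else if (r < 0.18) term <- stringi::stri_trans_toupper(term)
          parts <- stringi::stri_split_fixed(row$template, "{T}")[[1]]
          pieces[[length(pieces) + 1L]] <- list(
            kind = "mention",
            sentence = paste0(parts[1], term, if (length(parts) > 1) parts[2] else ""),
            prefix_len = nchar(parts[1]), term_len = nchar(term),
            ade = ade, label = row$label, family = fam, stage = row$stage
          )
        }
        for (f in seq_len(n_filler)) {
          pieces[[length(pieces) + 1L]] <- list(
            kind = "filler",
            sentence = fillers[sample(length(fillers), 1)]
          )
        }
        pieces <- pieces[sample(length(pieces))]
        offset <- 0L
        sent_texts <- character(length(pieces))
        for (i in seq_along(pieces)) {
          pc <- pieces[[i]]
          sent_texts[i] <- pc$sentence
          if (pc$kind == "mention") {
            start <- offset + pc$prefix_len
            golds[[length(golds) + 1L]] <- tibble::tibble(
              doc_id = doc_id, ade_id = pc$ade,
              start = as.integer(start), end = as.integer(start + pc$term_len),
              label = pc$label, family = pc$family, stage = pc$stage,
              patient_id = patients$patient_id[p]
            )
          }
          offset <- offset + nchar(pc$sentence) + 1L  # sentences joined by " "
        }
        docs[[doc_no]] <- tibble::tibble(
          doc_id = doc_id, patient_id = patients$patient_id[p],
          text = paste(sent_texts, collapse = " ")
        )
      }
    }

    documents <- dplyr::bind_rows(docs)
    documents$meta <- rep(list(character(0)), nrow(documents))
    gold <- dplyr::bind_rows(golds)
    truth <- gold |>
      dplyr::group_by(.data$patient_id, .data$ade_id) |>
      dplyr::summarise(positive = any(.data$label == "positive"), .groups = "drop")

    structure(
      list(
        documents = documents,
        gold = gold,
        patients = patients,
        truth = truth,
        spec = list(
          n_patients = n_patients, docs_per_patient = docs_per_patient,
          ades = ades, context_mix = context_mix,
          misspelling_rate = misspelling_rate, seed = seed
        )
      ),
      class = "generated_corpus"
    )
  })
}

#' @export
print.generated_corpus <- function(x, ...) {
  cat(sprintf(
    "<generated_corpus: %d documents, %d gold mentions, %d patients (seed %d)>\n",
    nrow(x$documents), nrow(x$gold), nrow(x$patients), x$spec$seed
  ))
  invisible(x)
}

# Category frequencies of the reference cohort, used to sample patient
# attributes so prevalence tables run end-to-end on generated data.
reference_attribute_distributions <- function() {
  ref <- epse_prevalence_reference()
  one <- function(part) {
    r <- ref[ref$partition == part, ]
    list(stratum = r$stratum, p = r$cohort_size / sum(r$cohort_size))
  }
  list(age = one("age"), gender = one("gender"),
       ethnicity = one("ethnicity"), diagnosis = one("diagnosis"))
}
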