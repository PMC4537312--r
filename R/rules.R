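#' Rule-cascade configuration
#'
#' Controls which removal stages run, whether retain overrides are enabled,
#' and the size of the context windows. All rule scopes are confined to the
#' mention's sentence; within the sentence, most stages look only at a window
#' of non-space tokens on each side of the mention.
#'
#' @param stages Ordered subset of `1:11` — the removal stages to apply.
#'   Stage order is fixed; supplying stages out of order is a validation
#'   error.
#' @param retain Apply the retain overrides (stage 12)?
#' @param window_before,window_after Number of non-space tokens either side
#'   of the mention that a context cue may occupy (default 5 — the smallest
#'   window consistent with the worked examples of every cue family).
#' @param patient_refs Word tokens accepted as a reference to the patient for
#'   the patient+indication retain clause. Real patient names cannot occur in
#'   de-identified text, so generic references stand in; configurable.
#' @return A `rule_config` object (list).
#' @export
rule_config <- function(stages = 1:11, retain = TRUE,
                        window_before = 5, window_after = 5,
                        patient_refs = c("patient", "pt", "he", "she")) {
  stages <- as.integer(stages)
  if (length(stages) && (anyNA(stages) || any(!stages %in% 1:11))) {
    ade_abort("unknown removal stage id; stages must be within 1..11")
  }
  if (is.unsorted(stages, strictly = TRUE) && length(stages) > 1) {
    ade_abort("removal stages must be given in their fixed cascade order")
  }
  if (window_before < 1 || window_after < 1) {
    ade_abort("context windows must be at least 1 token")
  }
  structure(
    list(
      stages = stages, retain = isTRUE(retain),
      window_before = as.integer(window_before),
      window_after = as.integer(window_after),
      patient_refs = stringi::stri_trans_tolower(patient_refs)
    ),
    class = "rule_config"
  )
}

stage_ids <- c(
  "S1.negation_before", "S2.negation_after", "S3.organisation",
  "S4.symbol_punct", "S5.other_person", "S6.monitor",
  "S7.negative_effects", "S8.single_word", "S9.diagnosis_homonym",
  "S10.drug_effects", "S11.hypothetical"
)

stage_gazetteer <- c(
  "negationbefore", "negationafter", "organisation", NA, "people", "monitor",
  "negseffect", NA, "diagnost", "druglink", "adrin"
)

get_gazetteer <- function(gazetteers, name) {
  gz <- gazetteers[[name]]
  if (is.null(gz)) ade_abort(sprintf("gazetteer '%s' is required but not supplied", name))
  gz
}

# All occurrences of any entry of `gz` within the sentence rows, dropping
# occurrences that overlap the mention span itself.
sentence_hits <- function(gz, low, srows, first, last) {
  hits <- list()
  for (k in seq_along(gz$entry_tokens)) {
    occ <- phrase_occurrences(low, srows, gz$entry_tokens[[k]])
    for (h in occ) {
      if (h[2] >= first && h[1] <= last) next  # overlaps the mention
      hits[[length(hits) + 1L]] <- list(s = h[1], e = h[2], term = gz$entries[[k]])
    }
  }
  hits
}

# like sentence_hits but keeps mention-overlapping occurrences (needed by
# the diagnosis-homonym containment test)
sentence_hits_all <- function(gz, low, srows) {
  hits <- list()
  for (k in seq_along(gz$entry_tokens)) {
    occ <- phrase_occurrences(low, srows, gz$entry_tokens[[k]])
    for (h in occ) {
      hits[[length(hits) + 1L]] <- list(s = h[1], e = h[2], term = gz$entries[[k]])
    }
  }
  hits
}

hit_before <- function(hits, first, window) {
  Filter(function(h) h$e < first && first - h$e <= window, hits)
}
hit_after <- function(hits, last, window) {
  Filter(function(h) h$s > last && h$s - last <= window, hits)
}
hit_in_window <- function(hits, first, last, cfg) {
  c(hit_before(hits, first, cfg$window_before), hit_after(hits, last, cfg$window_after))
}
first_trigger <- function(hits) if (length(hits)) hits[[1]]$term else NA_character_

# Locate the mention's filtered-token range; mention spans are token aligned
# by construction.
mention_tok_range <- function(ctx, mention) {
  first <- which(ctx$ftok$start == mention$start)
  last <- which(ctx$ftok$end == mention$end)
  if (length(first) != 1 || length(last) != 1 || last < first) {
    ade_abort(sprintf(
      "mention span [%d,%d) is not token-aligned with the document text",
      mention$start, mention$end
    ))
  }
  c(first, last)
}

#' Apply the removal stages to one candidate mention
#'
#' Evaluates every enabled removal stage against the mention's sentence
#' context and returns one decision row per stage, in cascade order, whether
#' or not it fired (`action` is `"remove"` or `"none"`). All stages are
#' always evaluated — there is no short-circuit after the first removal — so
#' the decision list doubles as an audit trail and supports cumulative-stage
#' ablation. The eleven stages:
#'
#' 1. *negation before*: a `negationbefore` cue within the window before the
#'    mention ("did **not** have dystonia").
#' 2. *negation after*: a `negationafter` cue within the window after
#'    ("dystonia was **ruled out**").
#' 3. *organisation*: an `organisation` term immediately adjacent
#'    ("Dystonia **Society**").
#' 4. *symbols/punctuation*: `?`, `/` or `@` immediately before or after,
#'    space tokens ignored ("dystonia**?**").
#' 5. *other person*: a `people` term anywhere in the sentence
#'    ("**mother** had developed dystonia").
#' 6. *monitor*: a `monitor` cue in the window ("**check for** any dystonic
#'    reaction").
#' 7. *negative effects*: a `negseffect` warning/advice cue in the window
#'    ("**possibility of** dystonia").
#' 8. *single word*: a `singlewordbefore` word immediately before, or a
#'    `singlewordafter` word immediately after.
#' 9. *diagnosis homonym*: the mention lies strictly inside a `diagnost`
#'    phrase ("**ego dystonia**"); containment is tested on the whole
#'    sentence regardless of windows.
#' 10. *drug effects*: a `druglink` cue in the window ("dystonia
#'    **secondary to** antipsychotics").
#' 11. *hypothetical*: an "if" token in the before-window together with an
#'    `adrin` indication term in either window ("**If** dystonia
#'    **develops** ...").
#'
#' @param mention One mention row (list or one-row tibble) with `start`,
#'   `end`.
#' @param document One-row document tibble/list with `text`.
#' @param gazetteers Named list of `gazetteer` objects (see
#'   [starter_gazetteers()]).
#' @param config A [rule_config()].
#' @return A tibble of decisions: `stage_id`, `action`, `trigger_term`.
#' @export
apply_removal_stages <- function(mention, document, gazetteers, config = rule_config()) {
  ctx <- prep_document(document$text[[1]])
  removal_decisions(mention, ctx, gazetteers, config)
}

removal_decisions <- function(mention, ctx, gazetteers, cfg) {
  rng <- mention_tok_range(ctx, mention)
  first <- rng[1]; last <- rng[2]
  ftok <- ctx$ftok
  low <- ftok$low
  srows <- which(ftok$sent == ftok$sent[first])
  wb <- cfg$window_before; wa <- cfg$window_after

  n_st <- length(cfg$stages)
  v_stage <- character(n_st); v_action <- character(n_st); v_trig <- character(n_st)

  decide <- function(stage) {
    gz_name <- stage_gazetteer[[stage]]
    gz <- if (!is.na(gz_name)) get_gazetteer(gazetteers, gz_name)
    trig <- NA_character_
    fired <- FALSE
    if (stage == 1) {
      h <- hit_before(sentence_hits(gz, low, srows, first, last), first, wb)
      fired <- length(h) > 0; trig <- first_trigger(h)
    } else if (stage == 2) {
      h <- hit_after(sentence_hits(gz, low, srows, first, last), last, wa)
      fired <- length(h) > 0; trig <- first_trigger(h)
    } else if (stage == 3) {
      h <- Filter(function(x) x$e == first - 1 || x$s == last + 1,
                  sentence_hits(gz, low, srows, first, last))
      fired <- length(h) > 0; trig <- first_trigger(h)
    } else if (stage == 4) {
      syms <- c("?", "/", "@")
      prev_ok <- (first - 1) %in% srows && low[first - 1] %in% syms
      next_ok <- (last + 1) %in% srows && low[last + 1] %in% syms
      fired <- prev_ok || next_ok
      if (fired) trig <- if (prev_ok) low[first - 1] else low[last + 1]
    } else if (stage == 5) {
      h <- sentence_hits(gz, low, srows, first, last)
      fired <- length(h) > 0; trig <- first_trigger(h)
    } else if (stage %in% c(6, 7, 10)) {
      h <- hit_in_window(sentence_hits(gz, low, srows, first, last), first, last, cfg)
      fired <- length(h) > 0; trig <- first_trigger(h)
    } else if (stage == 8) {
      before <- get_gazetteer(gazetteers, "singlewordbefore")
      after <- get_gazetteer(gazetteers, "singlewordafter")
      prev_ok <- (first - 1) %in% srows && low[first - 1] %in% before$entries
      next_ok <- (last + 1) %in% srows && low[last + 1] %in% after$entries
      fired <- prev_ok || next_ok
      if (fired) trig <- if (prev_ok) low[first - 1] else low[last + 1]
    } else if (stage == 9) {
      h <- Filter(function(x) {
        x$s <= first && x$e >= last && (x$e - x$s) > (last - first)
      }, sentence_hits_all(gz, low, srows))
      fired <- length(h) > 0; trig <- first_trigger(h)
    } else if (stage == 11) {
      if_before <- any(low[srows] == "if" &
                         srows < first & first - srows <= wb)
      h <- hit_in_window(sentence_hits(gz, low, srows, first, last), first, last, cfg)
      fired <- if_before && length(h) > 0
      if (fired) trig <- paste("if +", h[[1]]$term)
    }
    list(fired = fired, trig = trig)
  }

  for (i in seq_len(n_st)) {
    st <- cfg$stages[[i]]
    d <- decide(st)
    v_stage[[i]] <- stage_ids[[st]]
    v_action[[i]] <- if (d$fired) "remove" else "none"
    v_trig[[i]] <- d$trig
  }
  tibble::tibble(stage_id = v_stage, action = v_action, trigger_term = v_trig)
}

#' Apply the retain overrides to one mention
#'
#' Retain rules rescue mentions that context makes clearly real despite a
#' removal cue, and confirm unremoved candidates. Three clauses, each
#' emitting its own decision:
#'
#' * `S12.retain_possessive` — the definite article or a possessive pronoun
#'   (`the, his, her, their, my, your, its`) is the word token immediately
#'   before the mention ("**her** dystonia had become worse").
#' * `S12.retain_diagnostic` — a diagnostic phrase from the `retaindiag`
#'   dictionary in the context window ("**diagnosed with** akathisia").
#' * `S12.retain_patient_adrin` — a patient-reference token and an `adrin`
#'   indication term both within the window.
#'
#' Retain precedence is absolute: a removed mention with at least one retain
#' decision becomes `retained` (counted positive); a candidate with a retain
#' decision stays `candidate` and is simply confirmed.
#'
#' @inheritParams apply_removal_stages
#' @return A tibble of fired decisions: `stage_id`, `action` (`"retain"`),
#'   `trigger_term`; zero rows when no clause fires.
#' @export
apply_retain_rules <- function(mention, document, gazetteers, config = rule_config()) {
  ctx <- prep_document(document$text[[1]])
  retain_decisions(mention, ctx, gazetteers, config)
}

retain_decisions <- function(mention, ctx, gazetteers, cfg) {
  rng <- mention_tok_range(ctx, mention)
  first <- rng[1]; last <- rng[2]
  ftok <- ctx$ftok
  low <- ftok$low
  srows <- which(ftok$sent == ftok$sent[first])
  ids <- character(0); trigs <- character(0)

  possessives <- c("the", "his", "her", "their", "my", "your", "its")
  if ((first - 1) %in% srows && ftok$kind[first - 1] == "word" &&
        low[first - 1] %in% possessives) {
    ids <- c(ids, "S12.retain_possessive")
    trigs <- c(trigs, low[first - 1])
  }

  rd <- get_gazetteer(gazetteers, "retaindiag")
  h <- hit_in_window(sentence_hits(rd, low, srows, first, last), first, last, cfg)
  if (length(h)) {
    ids <- c(ids, "S12.retain_diagnostic")
    trigs <- c(trigs, first_trigger(h))
  }

  adrin <- get_gazetteer(gazetteers, "adrin")
  pref_rows <- srows[low[srows] %in% cfg$patient_refs & ftok$kind[srows] == "word"]
  pref_near <- any((pref_rows < first & first - pref_rows <= cfg$window_before) |
                     (pref_rows > last & pref_rows - last <= cfg$window_after))
  ha <- hit_in_window(sentence_hits(adrin, low, srows, first, last), first, last, cfg)
  if (pref_near && length(ha)) {
    ids <- c(ids, "S12.retain_patient_adrin")
    trigs <- c(trigs, first_trigger(ha))
  }

  tibble::tibble(stage_id = ids, action = rep("retain", length(ids)),
                 trigger_term = trigs)
}

#' Annotate one document with the full rule cascade
#'
#' Runs the complete decision flow on a document: locate candidate mentions
#' of every lexicon term, apply the enabled removal stages, then apply the
#' retain overrides. A mention's final status is `removed` if at least one
#' removal stage fired and no retain clause did, `retained` if a retain
#' clause overrode a removal, and `candidate` otherwise. Positive mentions
#' are those with status `candidate` or `retained`. Rules never alter
#' mention spans, only status; the `fired_rules` column lists every decision
#' that matched, in cascade order.
#'
#' @inheritParams find_candidate_mentions
#' @param gazetteers Named list of context gazetteers
#'   ([starter_gazetteers()]).
#' @param config A [rule_config()].
#' @return A mention tibble with final `status` and `fired_rules`.
#' @export
annotate_document <- function(document, lexicons, gazetteers, config = rule_config()) {
  annotate_with_table(document, lexicon_term_table(lexicons), gazetteers, config)
}

annotate_with_table <- function(document, term_table, gazetteers, config) {
  ctx <- prep_document(document$text[[1]])
  mentions <- mentions_from_ctx(document$doc_id[[1]], ctx, term_table)
  if (nrow(mentions) == 0) return(mentions)
  for (i in seq_len(nrow(mentions))) {
    m <- list(start = mentions$start[[i]], end = mentions$end[[i]])
    dec <- removal_decisions(m, ctx, gazetteers, config)
    fired <- dec$stage_id[dec$action == "remove"]
    status <- if (length(fired)) "removed" else "candidate"
    if (config$retain) {
      rt <- retain_decisions(m, ctx, gazetteers, config)
      if (nrow(rt)) {
        fired <- c(fired, rt$stage_id)
        if (status == "removed") status <- "retained"
      }
    }
    mentions$status[[i]] <- status
    mentions$fired_rules[[i]] <- fired
  }
  mentions
}

#' Annotate a whole corpus
#'
#' Applies [annotate_document()] to every row of a document table and binds
#' the results, attaching each document's `patient_id` to its mentions.
#'
#' @param documents A document tibble from [read_documents()].
#' @inheritParams annotate_document
#' @return A mention tibble with a `patient_id` column.
#' @export
annotate_corpus <- function(documents, lexicons, gazetteers, config = rule_config()) {
  tab <- lexicon_term_table(lexicons)
  res <- lapply(seq_len(nrow(documents)), function(i) {
    m <- annotate_with_table(documents[i, ], tab, gazetteers, config)
    m$patient_id <- rep(documents$patient_id[[i]], nrow(m))
    m
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      doc_id = character(0), ade_id = character(0), start = integer(0),
      end = integer(0), matched_term = character(0), sentence_index = integer(0),
      status = character(0), fired_rules = list(), patient_id = character(0)
    )
  }
  out
}

#' Positive mentions of an annotated set
#'
#' @param mentions A mention tibble.
#' @return The rows whose status is `candidate` or `retained`.
#' @export
positive_mentions <- function(mentions) {
  mentions[mentions$status %in% c("candidate", "retained"), , drop = FALSE]
}
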