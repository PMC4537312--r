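#' Load a gazetteer term list
#'
#' Gazetteer files are UTF-8 text, one phrase per line; `#` starts a comment
#' and blank lines are ignored (the GATE `.lst` convention). Entries are
#' case-folded and de-duplicated on load. Matching is case-insensitive and
#' token-boundary aligned; hyphens count as boundaries, so the entry
#' `"ego dystonia"` also matches `"ego-dystonia"`.
#'
#' @param path Path to the term list.
#' @param name Gazetteer name (the rule stage it feeds, e.g.
#'   `"negationbefore"`, `"monitor"`).
#' @return A `gazetteer` object: list with `name`, `entries` (case-folded
#'   phrases) and `entry_tokens` (each phrase as a word-token sequence).
#' @export
load_gazetteer <- function(path, name = sub("\\.lst$", "", basename(path))) {
  if (!file.exists(path)) ade_io_abort(sprintf("cannot read gazetteer file '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  new_gazetteer(name, lines, source = path)
}

#' Construct a gazetteer from an in-memory phrase vector
#'
#' @param name Gazetteer name.
#' @param entries Character vector of phrases.
#' @param source Optional provenance string.
#' @return A `gazetteer` object.
#' @export
new_gazetteer <- function(name, entries, source = NULL) {
  entries <- unique(stringi::stri_trans_tolower(trimws(entries)))
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0) {
    ade_abort(sprintf("gazetteer '%s' has no entries after comment/blank removal", name))
  }
  structure(
    list(
      name = name,
      entries = entries,
      entry_tokens = lapply(entries, phrase_tokens),
      source = source
    ),
    class = "gazetteer"
  )
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer '%s': %d entries>\n", x$name, length(x$entries)))
  invisible(x)
}

# Lower-cased word/number tokens of a phrase, hyphens and spaces dropped.
phrase_tokens <- function(phrase) {
  tk <- tokenize(stringi::stri_trans_tolower(phrase))
  tk$surface[tk$kind != "space" & tk$surface != "-"]
}

#' Load the starter gazetteers shipped with the package
#'
#' Returns the named list of context gazetteers that drive the rule stages:
#' `negationbefore`, `negationafter`, `organisation`, `people`, `monitor`,
#' `negseffect`, `singlewordbefore`, `singlewordafter`, `diagnost`,
#' `druglink`, `adrin`, `retaindiag`. These are deliberately small seed
#' lists reconstructed from published examples of each context family;
#' production use on real records needs richer, locally curated lists.
#'
#' @param dir Directory of `.lst` files; defaults to the lists installed with
#'   the package.
#' @return Named list of `gazetteer` objects.
#' @export
starter_gazetteers <- function(dir = system.file("extdata", "gazetteers", package = "ademiner")) {
  files <- sort(list.files(dir, pattern = "\\.lst$", full.names = TRUE))
  gaz <- lapply(files, load_gazetteer)
  setNames(gaz, vapply(gaz, `[[`, "", "name"))
}

#' Load an ADE lexicon
#'
#' An ADE lexicon maps one canonical adverse-event name to the set of surface
#' phrases (synonyms, spelling variants) used for it in clinical text. The
#' canonical name is always included as a term.
#'
#' @param path Term-list file, one phrase per line, `#` comments.
#' @param ade_id Canonical ADE name; defaults to the file name.
#' @return An `ade_lexicon` object: list with `ade_id`, `terms`.
#' @export
load_lexicon <- function(path, ade_id = sub("\\.lst$", "", basename(path))) {
  gz <- load_gazetteer(path, name = ade_id)
  new_lexicon(ade_id, gz$entries)
}

#' @rdname load_lexicon
#' @param terms Character vector of surface phrases for `new_lexicon()`.
#' @export
new_lexicon <- function(ade_id, terms) {
  terms <- unique(stringi::stri_trans_tolower(c(
    stringi::stri_replace_all_fixed(ade_id, "_", " "), trimws(terms)
  )))
  terms <- terms[nzchar(terms)]
  structure(list(ade_id = ade_id, terms = terms), class = "ade_lexicon")
}

#' @export
print.ade_lexicon <- function(x, ...) {
  cat(sprintf("<ade_lexicon '%s': %d terms>\n", x$ade_id, length(x$terms)))
  invisible(x)
}

#' Load the starter ADE lexicons shipped with the package
#'
#' Twelve starter lexicons ship: the four extrapyramidal side effects of
#' antipsychotic treatment (`dystonia`, `akathisia`, `parkinsonism`,
#' `tardive_dyskinesia`, each with curated spelling variants) and eight
#' unrelated ADEs (`alopecia`, `convulsions`, `hypersalivation`,
#' `myocarditis`, `nausea`, `pneumonia`, `stevens_johnson_syndrome`,
#' `tachycardia`). The rule cascade itself is ADE-agnostic: any user lexicon
#' can be supplied.
#'
#' @param ades Optional character vector restricting which lexicons to load.
#' @param dir Directory of `.lst` files; defaults to the installed lists.
#' @return Named list of `ade_lexicon` objects.
#' @export
starter_lexicons <- function(ades = NULL,
                             dir = system.file("extdata", "lexicons", package = "ademiner")) {
  files <- sort(list.files(dir, pattern = "\\.lst$", full.names = TRUE))
  lex <- lapply(files, load_lexicon)
  lex <- setNames(lex, vapply(lex, `[[`, "", "ade_id"))
  if (!is.null(ades)) {
    missing <- setdiff(ades, names(lex))
    if (length(missing)) {
      ade_abort(sprintf("no starter lexicon for: %s", paste(missing, collapse = ", ")))
    }
    lex <- lex[ades]
  }
  lex
}

# Normalise the lexicon argument (list of ade_lexicon, or named list of
# character vectors) into a term table, checking cross-lexicon ambiguity.
lexicon_term_table <- function(lexicons) {
  if (inherits(lexicons, "ade_lexicon")) lexicons <- list(lexicons)
  if (length(lexicons) == 0) ade_abort("at least one ADE lexicon is required")
  lex <- lapply(seq_along(lexicons), function(i) {
    x <- lexicons[[i]]
    if (inherits(x, "ade_lexicon")) return(x)
    new_lexicon(names(lexicons)[[i]], x)
  })
  tab <- dplyr::bind_rows(lapply(lex, function(l) {
    tibble::tibble(ade_id = l$ade_id, term = l$terms)
  }))
  tab$tokens <- lapply(tab$term, phrase_tokens)
  tab$key <- vapply(tab$tokens, paste, "", collapse = " ")
  tab <- tab[nzchar(tab$key), , drop = FALSE]
  dup <- tab$key[duplicated(tab$key)]
  clash <- tab[tab$key %in% dup, , drop = FALSE]
  if (nrow(clash)) {
    amb <- vapply(split(clash$ade_id, clash$key), function(a) length(unique(a)) > 1, TRUE)
    if (any(amb)) {
      ade_abort(sprintf(
        "term(s) shared by different ADE lexicons (ambiguous): %s",
        paste(names(amb)[amb], collapse = ", ")
      ))
    }
    tab <- tab[!duplicated(tab$key), , drop = FALSE]
  }
  tab$len <- lengths(tab$tokens)
  tab[order(-tab$len), , drop = FALSE]
}

# Occurrences of a token phrase within a surface vector restricted to rows
# `rows` (global indices into the filtered token stream). Returns a list of
# c(first, last) global index pairs.
phrase_occurrences <- function(low, rows, ptoks) {
  L <- length(ptoks)
  if (L == 0 || length(rows) < L) return(list())
  hits <- list()
  nr <- length(rows)
  starts <- which(low[rows] == ptoks[[1]])
  for (s in starts) {
    if (s + L - 1 > nr) next
    seg <- rows[s:(s + L - 1)]
    # require consecutive filtered tokens (no intervening punctuation rows
    # are skipped because `rows` is contiguous within a sentence)
    if (all(low[seg] == ptoks)) hits[[length(hits) + 1L]] <- c(seg[1], seg[L])
  }
  hits
}

#' Find candidate ADE mentions in a document
#'
#' Scans the document for all lexicon terms using case-insensitive,
#' token-boundary-aligned, longest-match lookup: when both
#' `"dystonic reaction"` and `"dystonic reactions"` are terms, the plural
#' span wins and no nested sub-span is also reported. Matches never cross
#' sentence boundaries. Every hit is returned as a `candidate` mention; the
#' rule cascade ([annotate_document()]) then decides its final status.
#'
#' @param document A one-row document tibble (or list) with `doc_id` and
#'   `text`.
#' @param lexicons A list of [new_lexicon()] / [load_lexicon()] objects, or a
#'   named list of character vectors.
#' @return A mention tibble: `doc_id`, `ade_id`, `start`, `end`,
#'   `matched_term`, `sentence_index`, `status` (all `"candidate"`),
#'   `fired_rules` (empty list-column).
#' @export
find_candidate_mentions <- function(document, lexicons) {
  tab <- lexicon_term_table(lexicons)
  ctx <- prep_document(document$text[[1]])
  mentions_from_ctx(document$doc_id[[1]], ctx, tab)
}

mentions_from_ctx <- function(doc_id, ctx, term_table) {
  ftok <- ctx$ftok
  out <- list()
  if (nrow(ftok)) {
    low <- ftok$low
    by_first <- split(seq_len(nrow(term_table)),
                      vapply(term_table$tokens, `[[`, "", 1))
    for (srows in split(seq_len(nrow(ftok)), ftok$sent)) {
      i <- 1L
      n <- length(srows)
      while (i <= n) {
        first_tok <- low[srows[i]]
        cand <- by_first[[first_tok]]
        matched <- FALSE
        if (!is.null(cand)) {
          for (j in cand) {  # term_table is sorted longest-first
            L <- term_table$len[[j]]
            if (i + L - 1 > n) next
            seg <- srows[i:(i + L - 1)]
            if (all(low[seg] == term_table$tokens[[j]])) {
              # ambiguity across lexicons at the same span was rejected in
              # lexicon_term_table(); first (longest) hit wins here
              out[[length(out) + 1L]] <- list(
                ade_id = term_table$ade_id[[j]],
                start = ftok$start[seg[1]],
                end = ftok$end[seg[L]],
                term = term_table$term[[j]],
                sent = ftok$sent[seg[1]]
              )
              i <- i + L
              matched <- TRUE
              break
            }
          }
        }
        if (!matched) i <- i + 1L
      }
    }
  }
  tibble::tibble(
    doc_id = rep(doc_id, length(out)),
    ade_id = vapply(out, `[[`, "", "ade_id"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    matched_term = vapply(out, function(m) {
      stringi::stri_sub(ctx$text, m$start + 1, m$end)
    }, ""),
    sentence_index = vapply(out, `[[`, 0L, "sent"),
    status = rep("candidate", length(out)),
    fired_rules = rep(list(character(0)), length(out))
  )
}
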