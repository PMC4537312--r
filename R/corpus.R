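#' Read a corpus of clinical documents
#'
#' Loads free-text clinical notes into a document table. Three on-disk layouts
#' are supported:
#'
#' * `"text-dir"`: a directory of `*.txt` files, one document per file; the
#'   file name (without extension) is the `doc_id`. An optional sidecar
#'   `metadata.csv` (columns `doc_id`, `patient_id`, ...) supplies patient
#'   identifiers.
#' * `"jsonl"`: one JSON object per line with fields `doc_id`, `patient_id`
#'   (optional), `text`, and an optional `meta` object.
#' * `"xml"`: a minimal dialect
#'   `<corpus><doc id="..." patient="..."><text>...</text></doc></corpus>`.
#'
#' Text is returned exactly as stored — no whitespace normalisation — so that
#' all downstream character offsets refer to the original content.
#'
#' @param path File (jsonl, xml) or directory (text-dir) to read.
#' @param format One of `"text-dir"`, `"jsonl"`, `"xml"`.
#' @return A tibble with columns `doc_id`, `patient_id`, `text`, `meta`
#'   (list-column of named character vectors).
#' @seealso [write_documents()], [read_annotations()]
#' @export
read_documents <- function(path, format = c("jsonl", "text-dir", "xml")) {
  format <- match.arg(format)
  switch(format,
    "jsonl" = read_documents_jsonl(path),
    "text-dir" = read_documents_dir(path),
    "xml" = read_documents_xml(path)
  )
}

new_document_table <- function(doc_id, patient_id, text, meta = NULL) {
  if (anyDuplicated(doc_id)) {
    ade_abort(sprintf(
      "duplicate doc_id in corpus: %s",
      paste(unique(doc_id[duplicated(doc_id)]), collapse = ", ")
    ))
  }
  if (is.null(meta)) meta <- rep(list(character(0)), length(doc_id))
  tibble::tibble(
    doc_id = as.character(doc_id),
    patient_id = as.character(patient_id),
    text = as.character(text),
    meta = meta
  )
}

read_documents_jsonl <- function(path) {
  if (!file.exists(path)) ade_io_abort(sprintf("cannot read jsonl file '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(new_document_table(character(0), character(0), character(0)))
  recs <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    if (is.null(rec$doc_id)) {
      ade_abort(sprintf("record %d in '%s' is missing doc_id", i, path))
    }
    list(
      doc_id = as.character(rec$doc_id),
      patient_id = if (is.null(rec$patient_id)) NA_character_ else as.character(rec$patient_id),
      text = if (is.null(rec$text)) "" else as.character(rec$text),
      meta = if (is.null(rec$meta)) character(0) else unlist(rec$meta)
    )
  })
  new_document_table(
    vapply(recs, `[[`, "", "doc_id"),
    vapply(recs, `[[`, "", "patient_id"),
    vapply(recs, `[[`, "", "text"),
    lapply(recs, `[[`, "meta")
  )
}

read_documents_dir <- function(path) {
  if (!dir.exists(path)) ade_io_abort(sprintf("cannot read directory '%s'", path))
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  ids <- sub("\\.txt$", "", basename(files))
  texts <- vapply(files, function(f) {
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, "")
  patient <- rep(NA_character_, length(ids))
  sidecar <- file.path(path, "metadata.csv")
  if (file.exists(sidecar)) {
    md <- read.csv(sidecar, stringsAsFactors = FALSE, colClasses = "character")
    if ("patient_id" %in% names(md)) {
      patient <- md$patient_id[match(ids, md$doc_id)]
    }
  }
  new_document_table(ids, patient, unname(texts))
}

read_documents_xml <- function(path) {
  if (!file.exists(path)) ade_io_abort(sprintf("cannot read xml file '%s'", path))
  root <- xml2::read_xml(path)
  docs <- xml2::xml_find_all(root, ".//doc")
  ids <- xml2::xml_attr(docs, "id")
  if (any(is.na(ids))) {
    ade_abort(sprintf(
      "xml record(s) %s missing 'id' attribute in '%s'",
      paste(which(is.na(ids)), collapse = ", "), path
    ))
  }
  patient <- xml2::xml_attr(docs, "patient")
  texts <- vapply(docs, function(d) {
    node <- xml2::xml_find_first(d, "./text")
    if (inherits(node, "xml_missing")) "" else xml2::xml_text(node)
  }, "")
  new_document_table(ids, patient, texts)
}

#' Write a corpus of documents
#'
#' Serialises a document table to JSON-lines or to the package's XML dialect.
#' `read_documents(write_documents(x))` preserves `doc_id`, `patient_id` and
#' `text` byte-for-byte.
#'
#' @param documents A document tibble as returned by [read_documents()].
#' @param path Output file.
#' @param format `"jsonl"` or `"xml"`.
#' @return `path`, invisibly.
#' @export
write_documents <- function(documents, path, format = c("jsonl", "xml")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(documents)), function(i) {
      rec <- list(
        doc_id = documents$doc_id[[i]],
        patient_id = documents$patient_id[[i]],
        text = documents$text[[i]]
      )
      meta <- documents$meta[[i]]
      if (length(meta)) rec$meta <- as.list(meta)
      jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    root <- xml2::xml_new_root("corpus")
    for (i in seq_len(nrow(documents))) {
      doc <- xml2::xml_add_child(root, "doc", id = documents$doc_id[[i]])
      if (!is.na(documents$patient_id[[i]])) {
        xml2::xml_set_attr(doc, "patient", documents$patient_id[[i]])
      }
      xml2::xml_add_child(doc, "text", documents$text[[i]])
    }
    xml2::write_xml(root, path)
  }
  invisible(path)
}

#' Tokenize text into offset-anchored tokens
#'
#' Splits text into maximal letter runs (`word`), digit runs (`number`),
#' whitespace runs (`space`) and single-character `punctuation` / `symbol`
#' tokens. Offsets are 0-based, half-open, so
#' `substr(text, start + 1, end) == surface` for every token. Punctuation is
#' never merged: `"?"`, `"/"`, `"@"` and `";"` always come out as
#' single-character tokens, which the context rules rely on.
#'
#' @param text A single character string.
#' @return A tibble with columns `start`, `end`, `surface`, `kind`.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- tibble::tibble(
    start = integer(0), end = integer(0),
    surface = character(0), kind = character(0)
  )
  if (is.na(text) || !nzchar(text)) return(empty)
  loc <- stringi::stri_locate_all_regex(
    text, "\\p{L}+|\\p{N}+|\\s+|[^\\p{L}\\p{N}\\s]"
  )[[1]]
  if (anyNA(loc[, 1])) return(empty)
  surface <- stringi::stri_sub(text, loc[, 1], loc[, 2])
  kind <- ifelse(
    stringi::stri_detect_regex(surface, "^\\p{L}+$"), "word",
    ifelse(
      stringi::stri_detect_regex(surface, "^\\p{N}+$"), "number",
      ifelse(
        stringi::stri_detect_regex(surface, "^\\s+$"), "space",
        ifelse(stringi::stri_detect_regex(surface, "^\\p{S}$"), "symbol", "punctuation")
      )
    )
  )
  tibble::tibble(
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2]),
    surface = surface,
    kind = kind
  )
}

#' Segment tokenized text into sentences
#'
#' Sentences are closed by a terminator token: `"."`, `"!"`, `"?"`, or a
#' whitespace run containing a newline. Each token belongs to exactly one
#' sentence; the terminator belongs to the sentence it closes. Context rules
#' never look across a sentence boundary, so this segmentation bounds the
#' scope of every removal and retain stage.
#'
#' @param text The text the tokens were produced from.
#' @param tokens The token table from [tokenize()].
#' @return A tibble with columns `start`, `end` (0-based, half-open).
#' @export
split_sentences <- function(text, tokens) {
  groups <- sentence_groups(tokens)
  if (length(groups) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  idx <- split(seq_len(nrow(tokens)), groups)
  tibble::tibble(
    start = vapply(idx, function(i) min(tokens$start[i]), 0L),
    end = vapply(idx, function(i) max(tokens$end[i]), 0L)
  )
}

# Sentence group id per token (integer vector, consecutive from 1).
sentence_groups <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0) return(integer(0))
  terminator <- (tokens$kind %in% c("punctuation", "symbol") &
    tokens$surface %in% c(".", "!", "?")) |
    (tokens$kind == "space" & stringi::stri_detect_fixed(tokens$surface, "\n"))
  # a terminator closes the current sentence; the next token opens a new one
  cumsum(c(1L, utils::head(as.integer(terminator), -1)))
}

#' Read or write mention annotations as JSON-lines
#'
#' Each line is one mention:
#' `{"doc_id":..., "ade_id":..., "start":..., "end":..., "matched_term":...,
#' "status":..., "fired_rules":[...]}`. Spans use the package-wide 0-based,
#' half-open convention.
#'
#' @param mentions A mention tibble (see [annotate_document()]).
#' @param path File to read or write.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns a mention tibble.
#' @export
write_annotations <- function(mentions, path) {
  lines <- vapply(seq_len(nrow(mentions)), function(i) {
    rec <- list(
      doc_id = mentions$doc_id[[i]],
      ade_id = mentions$ade_id[[i]],
      start = mentions$start[[i]],
      end = mentions$end[[i]],
      matched_term = mentions$matched_term[[i]],
      status = mentions$status[[i]],
      fired_rules = as.list(mentions$fired_rules[[i]])
    )
    if ("patient_id" %in% names(mentions)) rec$patient_id <- mentions$patient_id[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) ade_io_abort(sprintf("cannot read annotations file '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tibble::tibble(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
    patient_id = vapply(recs, function(r) {
      if (is.null(r$patient_id)) NA_character_ else as.character(r$patient_id)
    }, ""),
    ade_id = vapply(recs, function(r) as.character(r$ade_id), ""),
    start = vapply(recs, function(r) as.integer(r$start), 0L),
    end = vapply(recs, function(r) as.integer(r$end), 0L),
    matched_term = vapply(recs, function(r) as.character(r$matched_term), ""),
    status = vapply(recs, function(r) as.character(r$status), ""),
    fired_rules = lapply(recs, function(r) as.character(unlist(r$fired_rules)))
  )
}

#' Read or write gold mention labels
#'
#' Gold labels are JSON-lines records
#' `{"doc_id":..., "ade_id":..., "start":..., "end":..., "label":...}` with
#' `label` either `"positive"` or `"negative"`, in the same span convention
#' as the annotations.
#'
#' @param gold A gold-label tibble with columns `doc_id`, `ade_id`, `start`,
#'   `end`, `label`.
#' @param path File to read or write.
#' @return `write_gold()` returns `path` invisibly; `read_gold()` a tibble.
#' @export
write_gold <- function(gold, path) {
  lines <- vapply(seq_len(nrow(gold)), function(i) {
    jsonlite::toJSON(list(
      doc_id = gold$doc_id[[i]], ade_id = gold$ade_id[[i]],
      start = gold$start[[i]], end = gold$end[[i]], label = gold$label[[i]]
    ), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gold
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) ade_io_abort(sprintf("cannot read gold file '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  bad <- vapply(recs, function(r) !(r$label %in% c("positive", "negative")), TRUE)
  if (any(bad)) {
    ade_abort(sprintf("gold labels must be positive/negative (records %s)",
                      paste(which(bad), collapse = ", ")))
  }
  tibble::tibble(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
    ade_id = vapply(recs, function(r) as.character(r$ade_id), ""),
    start = vapply(recs, function(r) as.integer(r$start), 0L),
    end = vapply(recs, function(r) as.integer(r$end), 0L),
    label = vapply(recs, function(r) as.character(r$label), "")
  )
}

# ---- internal prepared-document representation --------------------------

# Tokenise once, segment once, and build the filtered token stream the
# matcher and rules operate on: non-space tokens with hyphens dropped, so a
# hyphen acts as a word boundary ("ego-dystonic" ~ the two-token phrase) and
# "with or without any space tokens" adjacency comes for free.
prep_document <- function(text) {
  tokens <- tokenize(text)
  groups <- sentence_groups(tokens)
  sentences <- split_sentences(text, tokens)
  keep <- tokens$kind != "space" & tokens$surface != "-"
  ftok <- tokens[keep, , drop = FALSE]
  ftok$sent <- if (nrow(tokens)) groups[keep] else integer(0)
  ftok$low <- stringi::stri_trans_tolower(ftok$surface)
  list(text = text, tokens = tokens, sentences = sentences, ftok = ftok)
}
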