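# Shared fixtures: starter resources are loaded once per test run.

.fixtures <- new.env(parent = emptyenv())

test_gazetteers <- function() {
  if (is.null(.fixtures$gaz)) .fixtures$gaz <- starter_gazetteers()
  .fixtures$gaz
}

test_lexicons <- function(ades = NULL) {
  if (is.null(.fixtures$lex)) .fixtures$lex <- starter_lexicons()
  if (is.null(ades)) .fixtures$lex else .fixtures$lex[ades]
}

make_doc <- function(text, doc_id = "d1", patient_id = "p1") {
  tibble::tibble(doc_id = doc_id, patient_id = patient_id, text = text,
                 meta = list(character(0)))
}

# final status of the single mention expected in `text`
annotate_one <- function(text, ade = "dystonia", config = rule_config()) {
  ann <- annotate_document(make_doc(text), test_lexicons(ade),
                           test_gazetteers(), config)
  expect_equal(nrow(ann), 1)
  ann
}

random_text <- function(n_chars, seed_chars) {
  paste(sample(seed_chars, n_chars, replace = TRUE), collapse = "")
}
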