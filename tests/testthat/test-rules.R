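stage_cases <- list(
  list(text = "Patient did not have dystonia", stage = "S1.negation_before"),
  list(text = "Dystonia was ruled out at assessment", stage = "S2.negation_after"),
  list(text = "Dystonia Society have always been a useful resource for patients",
       stage = "S3.organisation"),
  list(text = "query dystonia?", stage = "S4.symbol_punct"),
  list(text = "seen in dystonia / movement clinic", stage = "S4.symbol_punct"),
  list(text = "review @ dystonia clinic", stage = "S4.symbol_punct"),
  list(text = "mother had developed dystonia many years ago", stage = "S5.other_person"),
  list(text = "Check for any dystonic reaction", stage = "S6.monitor"),
  list(text = "possibility of dystonia with ZZZZZ", stage = "S7.negative_effects"),
  list(text = "symptoms like dystonia were discussed", stage = "S8.single_word"),
  list(text = "for dystonia consider referral", stage = "S8.single_word"),
  list(text = "ego dystonia was explored in therapy", stage = "S9.diagnosis_homonym"),
  list(text = "noted dystonia secondary to antipsychotics", stage = "S10.drug_effects"),
  list(text = "If Dystonia develops give procyclidine dose", stage = "S11.hypothetical")
)

test_that("each removal stage fires on its own cue family and only then", {
  gaz <- test_gazetteers()
  lex <- test_lexicons("dystonia")
  for (case in stage_cases) {
    doc <- make_doc(case$text)
    m <- find_candidate_mentions(doc, lex)
    expect_equal(nrow(m), 1, label = case$text)
    dec <- apply_removal_stages(m[1, ], doc, gaz)
    fired <- dec$stage_id[dec$action == "remove"]
    expect_equal(fired, case$stage, label = case$text)
    expect_false(is.na(dec$trigger_term[dec$stage_id == case$stage]))
  }
})

test_that("a cue-free sentence leaves the candidate untouched", {
  ann <- annotate_one("patient developed dystonia overnight")
  expect_equal(ann$status, "candidate")
  expect_length(ann$fired_rules[[1]], 0)
})

test_that("retain clauses fire on possessives, diagnostic phrases and patient+indication", {
  gaz <- test_gazetteers()
  doc <- make_doc("her dystonia had become worse")
  m <- find_candidate_mentions(doc, test_lexicons("dystonia"))
  rt <- apply_retain_rules(m[1, ], doc, gaz)
  expect_equal(rt$stage_id, "S12.retain_possessive")
  expect_equal(rt$trigger_term, "her")

  doc2 <- make_doc("She was diagnosed with dystonia")
  m2 <- find_candidate_mentions(doc2, test_lexicons("dystonia"))
  rt2 <- apply_retain_rules(m2[1, ], doc2, gaz)
  expect_true("S12.retain_diagnostic" %in% rt2$stage_id)

  doc3 <- make_doc("Pt had a reaction with dystonia evident")
  m3 <- find_candidate_mentions(doc3, test_lexicons("dystonia"))
  rt3 <- apply_retain_rules(m3[1, ], doc3, gaz)
  expect_true("S12.retain_patient_adrin" %in% rt3$stage_id)

  doc4 <- make_doc("examination showed dystonia in clinic")
  m4 <- find_candidate_mentions(doc4, test_lexicons("dystonia"))
  expect_equal(nrow(apply_retain_rules(m4[1, ], doc4, gaz)), 0)
})

test_that("retain overrides removal with absolute precedence", {
  ann <- annotate_one("The patient does not think the dystonia was painful")
  expect_equal(ann$status, "retained")
  expect_true("S1.negation_before" %in% ann$fired_rules[[1]])
  expect_true("S12.retain_possessive" %in% ann$fired_rules[[1]])

  # diagnostic phrase also overrides a negation
  ann2 <- annotate_one("Not obvious but diagnosed with dystonia in 2010")
  expect_equal(ann2$status, "retained")

  # with retain disabled the same mention stays removed
  ann3 <- annotate_one("The patient does not think the dystonia was painful",
                       config = rule_config(retain = FALSE))
  expect_equal(ann3$status, "removed")
})

test_that("cues never act across a sentence boundary", {
  ann <- annotate_one("Mother visited today. Dystonia was evident.")
  expect_equal(ann$status, "candidate")
  ann2 <- annotate_one("She denied low mood. Dystonia was evident.")
  expect_equal(ann2$status, "candidate")
  # same cues inside the mention's sentence do remove
  ann3 <- annotate_one("Mother visited today and mentioned her dystonia history.")
  expect_true("S5.other_person" %in% ann3$fired_rules[[1]])
})

test_that("window limits bound cue reach and are configurable", {
  text <- "No improvement in sleep and patient still has ongoing dystonia"
  ann <- annotate_one(text)  # 'no' is 8 tokens away: outside the window
  expect_equal(ann$status, "candidate")
  wide <- annotate_one(text, config = rule_config(window_before = 10, window_after = 10))
  expect_equal(wide$status, "removed")
})

test_that("rules change status but never spans", {
  cc <- generate_corpus(n_patients = 10, seed = 21)
  lex <- test_lexicons(); gaz <- test_gazetteers()
  for (i in seq_len(min(nrow(cc$documents), 8))) {
    doc <- cc$documents[i, ]
    cand <- find_candidate_mentions(doc, lex)
    ann <- annotate_document(doc, lex, gaz)
    expect_identical(ann$start, cand$start)
    expect_identical(ann$end, cand$end)
    expect_identical(ann$matched_term, cand$matched_term)
  }
})

test_that("enabling more removal stages never increases positives; retain never decreases", {
  cc <- generate_corpus(n_patients = 25, seed = 13)
  lex <- test_lexicons(); gaz <- test_gazetteers()
  counts <- vapply(0:11, function(k) {
    cfg <- rule_config(stages = seq_len(k), retain = FALSE)
    nrow(positive_mentions(annotate_corpus(cc$documents, lex, gaz, cfg)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  with_retain <- nrow(positive_mentions(
    annotate_corpus(cc$documents, lex, gaz, rule_config(retain = TRUE))
  ))
  expect_gte(with_retain, counts[[12]])
})

test_that("invalid configurations are rejected", {
  expect_error(rule_config(stages = c(1, 13)), "unknown removal stage")
  expect_error(rule_config(stages = c(5, 2)), "cascade order")
  expect_error(rule_config(window_before = 0), "at least 1")
})
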