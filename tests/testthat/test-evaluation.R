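fake_mentions <- function(doc_id, start, status = "candidate", ade = "dystonia") {
  tibble::tibble(
    doc_id = doc_id, ade_id = ade, start = start, end = start + 8L,
    matched_term = "dystonia", sentence_index = 1L, status = status,
    fired_rules = rep(list(character(0)), length(doc_id))
  )
}

test_that("precision and recall follow the confusion counts", {
  # 4 predicted positives: 3 true, 1 matching a gold negative; 2 gold positives missed
  pred <- fake_mentions(paste0("d", 1:4), rep(0L, 4))
  gold <- tibble::tibble(
    doc_id = paste0("d", 1:6), ade_id = "dystonia",
    start = 0L, end = 8L,
    label = c("positive", "positive", "positive", "negative", "positive", "positive")
  )
  sc <- score_annotations(pred, gold)
  expect_equal(sc$tp, 3L)
  expect_equal(sc$fp, 1L)
  expect_equal(sc$fn, 2L)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$recall, 0.6)
})

test_that("predictions identical to the gold positives score perfectly", {
  cc <- generate_corpus(n_patients = 8, seed = 2)
  ann <- annotate_corpus(cc$documents, test_lexicons(), test_gazetteers())
  sc <- score_annotations(ann, cc$gold)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
})

test_that("undefined ratios are NA with a warning, never zero", {
  pred <- fake_mentions("d1", 0L, status = "removed")
  gold <- tibble::tibble(doc_id = "d1", ade_id = "dystonia",
                         start = 0L, end = 8L, label = "positive")
  expect_warning(sc <- score_annotations(pred, gold), "precision undefined")
  expect_true(is.na(sc$precision))
  expect_equal(sc$fn, 1L)
})

test_that("gold spans outside the document text are rejected", {
  docs <- make_doc("short text")
  gold <- tibble::tibble(doc_id = "d1", ade_id = "dystonia",
                         start = 5L, end = 99L, label = "positive")
  expect_error(score_annotations(fake_mentions("d1", 0L), gold, documents = docs),
               "gold span", class = "ademiner_validation_error")
})

test_that("scoring equals the brute-force counting oracle on generated corpora", {
  for (seed in c(31, 32)) {
    cc <- generate_corpus(n_patients = 30, seed = seed)
    # disable some stages so the confusion is non-trivial (FPs and FNs exist)
    cfg <- rule_config(stages = c(1, 3, 5, 7, 9), retain = FALSE)
    ann <- annotate_corpus(cc$documents, test_lexicons(), test_gazetteers(), cfg)
    sc <- suppressWarnings(score_annotations(ann, cc$gold))
    oracle <- brute_force_confusion(ann, cc$gold)
    expect_equal(sc$tp, oracle$tp)
    expect_equal(sc$fp, oracle$fp)
    expect_equal(sc$fn, oracle$fn)
  }
})

test_that("document order does not change any metric", {
  cc <- generate_corpus(n_patients = 12, seed = 17)
  ann <- annotate_corpus(cc$documents, test_lexicons(), test_gazetteers())
  sc1 <- score_annotations(ann, cc$gold)
  perm <- withr::with_seed(1, sample(nrow(ann)))
  gperm <- withr::with_seed(2, sample(nrow(cc$gold)))
  sc2 <- score_annotations(ann[perm, ], cc$gold[gperm, ])
  expect_equal(sc1$precision, sc2$precision)
  expect_equal(sc1$recall, sc2$recall)
})

test_that("cumulative ablation shows the removal/retain shape", {
  mix <- c(plain = 0.5, retain = 0, negation = 0, monitoring = 0, warning = 0,
           other_person = 0.5, organisation = 0, hypothetical = 0,
           diagnosis_homonym = 0, symbol = 0, drug_listing = 0)
  cc <- generate_corpus(n_patients = 30, seed = 8, context_mix = mix)
  rpt <- cumulative_stage_report(cc$documents, cc$gold, test_lexicons(),
                                 test_gazetteers())
  expect_equal(rpt$stage_label[c(1, 2, 13)], c("keyword", "through S1", "retain"))
  # positives monotone: non-increasing through S11, non-decreasing at retain
  n_pos <- rpt$n_positive
  expect_true(all(diff(n_pos[1:12]) <= 0))
  expect_gte(n_pos[13], n_pos[12])
  # all negatives are other-person contexts: precision flat until S5, 1 after
  expect_true(all(rpt$precision[1:5] == rpt$precision[1]))
  expect_lt(rpt$precision[1], 1)
  expect_equal(rpt$precision[6], 1)
  # recall can only drop as stages are added
  expect_true(all(diff(rpt$recall[1:12]) <= 0))
  expect_gte(rpt$recall[13], rpt$recall[12])
})

test_that("keyword-only precision is 1 when no negative contexts exist", {
  mix <- c(plain = 0.7, retain = 0.3, negation = 0, monitoring = 0, warning = 0,
           other_person = 0, organisation = 0, hypothetical = 0,
           diagnosis_homonym = 0, symbol = 0, drug_listing = 0)
  cc <- generate_corpus(n_patients = 10, seed = 4, context_mix = mix)
  cfg <- rule_config(stages = integer(0), retain = FALSE)
  ann <- annotate_corpus(cc$documents, test_lexicons(), test_gazetteers(), cfg)
  expect_equal(score_annotations(ann, cc$gold)$precision, 1)
})

test_that("kappa matches its definition and a planted-table oracle", {
  ident <- rep(c("positive", "negative"), 10)
  ag <- inter_annotator_agreement(ident, ident)
  expect_equal(ag$percent_agreement, 100)
  expect_equal(ag$kappa, 1)

  # A all-positive, B half positive: observed = chance, kappa exactly 0
  a <- rep("positive", 50)
  b <- rep(c("positive", "negative"), 25)
  expect_equal(inter_annotator_agreement(a, b)$kappa, 0)

  # planted 2x2 agreement tables vs direct computation from the cells
  withr::with_seed(55, {
    for (rep_i in 1:10) {
      cells <- as.vector(stats::rmultinom(1, 50, runif(4, 0.05, 1)))
      aa <- c(rep("positive", cells[1] + cells[2]), rep("negative", cells[3] + cells[4]))
      bb <- c(rep("positive", cells[1]), rep("negative", cells[2]),
              rep("positive", cells[3]), rep("negative", cells[4]))
      n <- sum(cells)
      p_o <- (cells[1] + cells[4]) / n
      p_e <- ((cells[1] + cells[2]) * (cells[1] + cells[3]) +
                (cells[3] + cells[4]) * (cells[2] + cells[4])) / n^2
      expected <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
      ag <- inter_annotator_agreement(aa, bb)
      expect_equal(ag$kappa, expected, tolerance = 1e-12)
      expect_equal(ag$p_o, p_o)
    }
  })
})

test_that("agreement is symmetric and item sets must align", {
  withr::with_seed(9, {
    a <- sample(c("positive", "negative"), 40, TRUE)
    b <- sample(c("positive", "negative"), 40, TRUE)
  })
  expect_equal(inter_annotator_agreement(a, b)$kappa,
               inter_annotator_agreement(b, a)$kappa)
  names(a) <- paste0("m", 1:40)
  b2 <- setNames(b, paste0("m", c(1:39, 99)))
  expect_error(inter_annotator_agreement(a, b2), "different item sets",
               class = "ademiner_validation_error")
  expect_error(inter_annotator_agreement(a[1:5], b[1:9]), "different numbers")
})
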