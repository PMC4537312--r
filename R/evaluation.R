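#' Score predicted mentions against gold labels
#'
#' Mention-level confusion: a predicted-positive mention (status `candidate`
#' or `retained`) is a true positive when it matches a gold-positive label
#' for the same document and ADE, a false positive when it matches a
#' gold-negative label or nothing; a gold-positive label with no matching
#' predicted positive is a false negative. The default matching policy is
#' `overlap` (any span intersection counts), reflecting an annotation
#' protocol in which annotators classified pre-located term occurrences
#' rather than drawing free spans; `exact` requires identical spans.
#'
#' Undefined ratios (e.g. precision when nothing was predicted positive) are
#' reported as `NA` with a warning, never silently as 0.
#'
#' @param predictions A mention tibble ([annotate_corpus()]).
#' @param gold A gold-label tibble (`doc_id`, `ade_id`, `start`, `end`,
#'   `label`).
#' @param policy `"overlap"` or `"exact"`.
#' @param documents Optional document tibble; when supplied, every gold span
#'   is validated to lie inside its document's text.
#' @return An `eval_result`: one-row tibble with `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
score_annotations <- function(predictions, gold, policy = c("overlap", "exact"),
                              documents = NULL) {
  policy <- match.arg(policy)
  if (!is.null(documents)) {
    len <- nchar(documents$text)[match(gold$doc_id, documents$doc_id)]
    bad <- is.na(len) | gold$start < 0 | gold$end > len | gold$start >= gold$end
    if (any(bad)) {
      ade_abort(sprintf(
        "gold span(s) not found in document text: record(s) %s",
        paste(which(bad), collapse = ", ")
      ))
    }
  }
  pos <- positive_mentions(predictions)
  matches <- function(p_doc, p_ade, p_start, p_end, g) {
    same <- g$doc_id == p_doc & g$ade_id == p_ade
    if (policy == "exact") {
      same & g$start == p_start & g$end == p_end
    } else {
      same & g$start < p_end & g$end > p_start
    }
  }
  tp <- 0L; fp <- 0L
  gold_hit <- rep(FALSE, nrow(gold))
  for (i in seq_len(nrow(pos))) {
    m <- matches(pos$doc_id[[i]], pos$ade_id[[i]], pos$start[[i]], pos$end[[i]], gold)
    hit <- which(m)
    if (length(hit) && any(gold$label[hit] == "positive")) {
      tp <- tp + 1L
      gold_hit[hit[gold$label[hit] == "positive"]] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  fn <- sum(gold$label == "positive" & !gold_hit)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined (no predicted positives); reported as NA")
    NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("recall undefined (no gold positives); reported as NA")
    NA_real_
  }
  structure(
    tibble::tibble(tp = tp, fp = fp, fn = as.integer(fn),
                   precision = precision, recall = recall),
    class = c("eval_result", class(tibble::tibble()))
  )
}

#' Cumulative-stage ablation report
#'
#' Re-annotates the corpus under a ladder of configurations — keyword lookup
#' only, then removal stages 1..k for k = 1..11, then the full cascade with
#' retain overrides — and scores each row against the same gold labels. By
#' construction the positive-mention count is non-increasing down the
#' removal rows and non-decreasing at the retain row.
#'
#' @param documents Document tibble.
#' @param gold Gold-label tibble.
#' @inheritParams annotate_corpus
#' @param policy Span-matching policy passed to [score_annotations()].
#' @return A tibble with one row per configuration: `stage_label`,
#'   `n_positive`, `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
cumulative_stage_report <- function(documents, gold, lexicons, gazetteers,
                                    config = rule_config(),
                                    policy = c("overlap", "exact")) {
  policy <- match.arg(policy)
  ladder <- c(list(list(label = "keyword", stages = integer(0), retain = FALSE)),
              lapply(config$stages, function(k) {
                list(label = sprintf("through S%d", k),
                     stages = config$stages[config$stages <= k], retain = FALSE)
              }),
              list(list(label = "retain", stages = config$stages, retain = TRUE)))
  rows <- lapply(ladder, function(step) {
    cfg <- rule_config(
      stages = step$stages, retain = step$retain,
      window_before = config$window_before, window_after = config$window_after,
      patient_refs = config$patient_refs
    )
    ann <- annotate_corpus(documents, lexicons, gazetteers, cfg)
    sc <- suppressWarnings(score_annotations(ann, gold, policy))
    tibble::tibble(
      stage_label = step$label,
      n_positive = nrow(positive_mentions(ann)),
      tp = sc$tp, fp = sc$fp, fn = sc$fn,
      precision = sc$precision, recall = sc$recall
    )
  })
  dplyr::bind_rows(rows)
}

#' Inter-annotator agreement (two raters, binary labels)
#'
#' Percent agreement and Cohen's kappa for two annotators who labelled the
#' identical mention set. Kappa is the two-rater, two-category form
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed agreement \eqn{p_o}
#' and chance agreement \eqn{p_e} from the product of the marginal label
#' proportions; no weighting.
#'
#' @param labels_a,labels_b Character/factor vectors of `"positive"` /
#'   `"negative"` labels, aligned item-for-item. If both are named, the name
#'   sets must be identical (items are aligned by name).
#' @return An `agreement_result` list: `n_items`, `percent_agreement`,
#'   `p_o`, `p_e`, `kappa`.
#' @export
inter_annotator_agreement <- function(labels_a, labels_b) {
  a <- as.character(labels_a); b <- as.character(labels_b)
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    extra_a <- setdiff(names(labels_a), names(labels_b))
    extra_b <- setdiff(names(labels_b), names(labels_a))
    if (length(extra_a) || length(extra_b)) {
      ade_abort(sprintf(
        "annotators labelled different item sets (only A: %s; only B: %s)",
        paste(extra_a, collapse = ","), paste(extra_b, collapse = ",")
      ))
    }
    b <- b[match(names(labels_a), names(labels_b))]
  }
  if (length(a) != length(b)) {
    ade_abort(sprintf("annotators labelled different numbers of items (%d vs %d)",
                      length(a), length(b)))
  }
  n <- length(a)
  if (n == 0) ade_abort("no items to compare")
  p_o <- mean(a == b)
  cats <- union(a, b)
  p_e <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k), 0))
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(
    list(n_items = n, percent_agreement = 100 * p_o,
         p_o = p_o, p_e = p_e, kappa = kappa),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Inter-annotator agreement over %d items\n", x$n_items))
  cat(sprintf("  percent agreement: %.1f%%\n", x$percent_agreement))
  cat(sprintf("  Cohen's kappa:     %.3f (p_o = %.3f, p_e = %.3f)\n",
              x$kappa, x$p_o, x$p_e))
  invisible(x)
}
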