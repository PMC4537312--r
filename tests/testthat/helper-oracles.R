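# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# hand-rolled confusion-matrix counter (overlap policy)
brute_force_confusion <- function(predictions, gold) {
  pos <- predictions[predictions$status %in% c("candidate", "retained"), ]
  tp <- 0; fp <- 0
  hit <- rep(FALSE, nrow(gold))
  for (i in seq_len(nrow(pos))) {
    found <- FALSE
    for (j in seq_len(nrow(gold))) {
      if (pos$doc_id[i] == gold$doc_id[j] && pos$ade_id[i] == gold$ade_id[j] &&
            pos$start[i] < gold$end[j] && pos$end[i] > gold$start[j]) {
        if (gold$label[j] == "positive") {
          found <- TRUE
          hit[j] <- TRUE
        }
      }
    }
    if (found) tp <- tp + 1 else fp <- fp + 1
  }
  fn <- sum(gold$label == "positive" & !hit)
  list(tp = tp, fp = fp, fn = fn)
}

# textbook direct-summation Pearson chi-square
direct_chisq <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  sum((m - e)^2 / e)
}
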