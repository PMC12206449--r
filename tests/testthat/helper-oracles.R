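# Independent from-the-definitions metrics oracle: explicit one-vs-rest 2x2
# tables computed by scalar loops, sharing nothing with compute_metrics().
oracle_metrics <- function(cm) {
  classes <- rownames(cm)
  total <- sum(cm)
  res <- list()
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in rownames(cm)) {
      for (j in colnames(cm)) {
        n <- cm[i, j]
        if (i == cl && j == cl) tp <- tp + n
        if (i == cl && j != cl) fn <- fn + n
        if (i != cl && j == cl) fp <- fp + n
      }
    }
    tn <- total - tp - fp - fn
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    res[[cl]] <- c(
      support = tp + fn,
      mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
      f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
      precision = if (tp + fp == 0) 0 else tp / (tp + fp),
      recall = if (tp + fn == 0) 0 else tp / (tp + fn)
    )
  }
  m <- do.call(rbind, res)
  w <- m[, "support"] / sum(m[, "support"])
  list(weighted_mcc = sum(w * m[, "mcc"]), weighted_f1 = sum(w * m[, "f1"]),
       precision = sum(w * m[, "precision"]), recall = sum(w * m[, "recall"]))
}
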