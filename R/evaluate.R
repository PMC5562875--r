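## Sequence-identity stratification and performance evaluation.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise sequence identity and coverage
#'
#' Aligns two amino-acid sequences globally (Needleman-Wunsch via
#' `Biostrings::pairwiseAlignment`, BLOSUM62, gap opening 10, gap extension
#' 0.5). Identity is the fraction of identical aligned positions over the
#' alignment length excluding terminal gaps; coverage is the aligned span
#' (alignment length after trimming terminal gaps) divided by the length of
#' the longer sequence.
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @return Named numeric vector `c(identity = ..., coverage = ...)`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) >= 1, nchar(b) >= 1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  inner <- which(!gap)
  if (length(inner) == 0) return(c(identity = 0, coverage = 0))
  span <- min(tail(inner, 1)) - inner[[1]] + 1L
  keep <- inner[[1]]:tail(inner, 1)
  ident <- sum(pa[keep] == sa[keep] & pa[keep] != "-")
  c(identity = ident / span,
    coverage = span / max(nchar(a), nchar(b)))
}

#' Cluster sequences by identity for leakage-safe cross-validation
#'
#' Single-linkage clustering over the graph whose edges join pairs with
#' identity strictly above `si_cutoff` and coverage at least `cov_cutoff`
#' (the stratification used to keep homologous sequences out of opposite
#' cross-validation folds). Cluster indices are deterministic: clusters are
#' numbered by their first member in dataset order.
#'
#' @param proteins A dataset tibble.
#' @param si_cutoff Sequence-identity cutoff (default 0.25).
#' @param cov_cutoff Coverage cutoff (default 0.90).
#' @return A tibble with columns `protein_id` and `cluster`.
#' @export
cluster_sequences <- function(proteins, si_cutoff = 0.25, cov_cutoff = 0.90) {
  validate_dataset(proteins)
  n <- nrow(proteins)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pid <- pairwise_identity(proteins$sequence[[i]], proteins$sequence[[j]])
        if (pid[["identity"]] > si_cutoff && pid[["coverage"]] >= cov_cutoff) {
          parent[[find(j)]] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster <- match(roots, unique(roots))
  tibble(protein_id = proteins$id, cluster = cluster)
}

#' Confusion counts of binary calls against labels
#'
#' @param calls,labels 0/1 vectors of equal length.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(calls, labels) {
  if (length(calls) != length(labels)) abort("calls and labels differ in length")
  calls <- as.integer(calls); labels <- as.integer(labels)
  tibble(
    tp = sum(calls == 1L & labels == 1L),
    fp = sum(calls == 1L & labels == 0L),
    tn = sum(calls == 0L & labels == 0L),
    fn = sum(calls == 0L & labels == 1L)
  )
}

#' Confusion-derived classification metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, balanced
#' accuracy `(sen+spe)/2`, precision `tp/(tp+fp)` and the Matthews
#' correlation coefficient. Any metric with a zero denominator is returned
#' as 0, with a warning, so that fold averages stay computable.
#'
#' @param counts A one-row tibble from [confusion()].
#' @return A one-row tibble with columns `sen`, `spe`, `acc`, `bac`, `pre`,
#'   `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) abort("empty confusion table")
  degenerate <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      degenerate <<- c(degenerate, what)
      0
    } else num / den
  }
  sen <- safe_div(tp, tp + fn, "sensitivity")
  spe <- safe_div(tn, tn + fp, "specificity")
  pre <- safe_div(tp, tp + fp, "precision")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "MCC")
    0
  } else (tp * tn - fp * fn) / mcc_den
  if (length(degenerate) > 0) {
    warn(paste0("zero denominator for ", paste(degenerate, collapse = ", "),
                "; returning 0"))
  }
  tibble(sen = sen, spe = spe, acc = (tp + tn) / n,
         bac = (sen + spe) / 2, pre = pre, mcc = mcc)
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the probability that a random positive outranks a random
#' negative, with ties counted 0.5 (the Mann-Whitney statistic), so the
#' value is invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) abort("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Threshold maximizing Youden's J
#'
#' Sweeps the ROC vertices (the distinct observed scores, with an inclusive
#' `>=` call rule) and returns the threshold maximizing
#' `J = sensitivity + specificity - 1`; ties are broken toward the larger
#' threshold.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
best_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes required")
  cand <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  best_t <- cand[[1]]; best_j <- -Inf
  for (t in cand) {
    calls <- scores >= t
    j <- sum(calls & labels == 1L) / np + sum(!calls & labels == 0L) / nn - 1
    if (j > best_j) {   # strict: first (largest) threshold wins ties
      best_j <- j; best_t <- t
    }
  }
  best_t
}

#' Precision among the top-scoring fraction of residues
#'
#' Selects the `ceiling(fraction * n)` highest scores; ties at the selection
#' boundary are resolved by including every tied score.
#'
#' @inheritParams roc_auc
#' @param fraction Fraction of residues to keep (0 < fraction <= 1).
#' @return Precision over the selected subset.
#' @export
top_fraction_ppv <- function(scores, labels, fraction) {
  stopifnot(fraction > 0, fraction <= 1, length(scores) >= 1)
  labels <- as.integer(labels)
  k <- ceiling(fraction * length(scores))
  boundary <- sort(scores, decreasing = TRUE)[[k]]
  sel <- scores >= boundary
  mean(labels[sel] == 1L)
}

#' A full evaluation report for one score/label set
#'
#' @inheritParams roc_auc
#' @param tau Threshold applied to the scores (inclusive).
#' @return One-row tibble: `sen, spe, acc, bac, pre, mcc, auc, ppv_top10,
#'   ppv_top5, tau` (AUC is `NA` when a single class is present).
#' @export
metrics_report <- function(scores, labels, tau) {
  m <- classification_metrics(confusion(classify_scores(scores, tau), labels))
  one_class <- length(unique(as.integer(labels))) < 2
  m$auc <- if (one_class) NA_real_ else roc_auc(scores, labels)
  m$ppv_top10 <- top_fraction_ppv(scores, labels, 0.10)
  m$ppv_top5 <- top_fraction_ppv(scores, labels, 0.05)
  m$tau <- tau
  m
}

# like classify() but without the [0,1] restriction, so it also applies to
# raw decision values
classify_scores <- function(scores, tau) as.integer(scores >= tau)

#' Leave-one-cluster-out stratified cross-validation
#'
#' Clusters the proteins at the identity/coverage cutoffs, then evaluates
#' one fold per cluster: the SVM, the Platt calibration and the decision
#' threshold are all fitted without the held-out cluster, and the fold is
#' scored on the held-out residues only. By default the calibration (and
#' threshold) are fitted on decision values from an internal
#' cluster-respecting split of the training data, which avoids the
#' optimistic calibration of reusing training scores; `calibration =
#' "train"` uses the training decision values directly. Folds whose test set
#' contains a single class have their class-dependent metrics flagged
#' undefined (NA) and excluded from the average, with a warning.
#'
#' @param proteins A labelled dataset tibble.
#' @param profiles A wide profile tibble aligned to `proteins`.
#' @param C,gamma,class_weights SVM hyperparameters (see [efold_train()]).
#' @param si_cutoff,cov_cutoff Stratification cutoffs (see
#'   [cluster_sequences()]).
#' @param calibration `"inner_cv"` (default) or `"train"`.
#' @param threshold `"fit"` (Youden-optimal on the calibration scores,
#'   default) or `"fixed"` (use `tau`).
#' @param tau Threshold used when `threshold = "fixed"` (default 0.163).
#' @param inner_k Number of internal calibration splits (default 3).
#' @param average `"folds"` (unweighted mean of per-fold metrics, default)
#'   or `"pooled"` (metrics of all held-out predictions pooled into one
#'   set).
#' @param normalize_all Passed to [featurize_dataset()].
#' @return An object of class `efold_cv`: per-fold metrics (`$folds`), the
#'   averaged report (`$average`), the cluster assignment (`$clusters`) and
#'   the pooled held-out predictions (`$predictions`).
#' @export
crossvalidate <- function(proteins, profiles, C = 100, gamma = 0.04,
                          class_weights = "balanced",
                          si_cutoff = 0.25, cov_cutoff = 0.90,
                          calibration = c("inner_cv", "train"),
                          threshold = c("fit", "fixed"), tau = 0.163,
                          inner_k = 3, average = c("folds", "pooled"),
                          normalize_all = FALSE) {
  calibration <- match.arg(calibration)
  threshold <- match.arg(threshold)
  average <- match.arg(average)
  validate_dataset(proteins)
  if (!"labels" %in% names(proteins)) abort("cross-validation needs a labelled dataset")
  clusters <- cluster_sequences(proteins, si_cutoff, cov_cutoff)
  if (max(clusters$cluster) < 2) abort("need at least 2 clusters to cross-validate")
  feats <- featurize_dataset(proteins, profiles, normalize_all = normalize_all)
  feats$cluster <- clusters$cluster[match(feats$protein_id, clusters$protein_id)]
  X <- feature_matrix(feats)
  y <- feats$label

  fold_rows <- list()
  pooled <- list()
  for (k in sort(unique(clusters$cluster))) {
    test <- feats$cluster == k
    if (length(unique(y[!test])) < 2) {
      warn(paste0("fold ", k, ": training residues single-class; fold skipped"))
      next
    }
    model <- efold_train(X[!test, , drop = FALSE], y[!test], C = C,
                         gamma = gamma, class_weights = class_weights,
                         calibrate = FALSE)
    cal <- calibration_scores(X[!test, , drop = FALSE], y[!test],
                              feats$cluster[!test], model, calibration,
                              inner_k, C, gamma, class_weights)
    model$platt <- platt_calibrate(cal$scores, cal$labels)
    cal_prob <- platt_prob(cal$scores, model$platt)
    tau_k <- if (threshold == "fit") best_threshold(cal_prob, cal$labels) else tau
    prob <- platt_prob(decision_values(model, X[test, , drop = FALSE]), model$platt)
    if (length(unique(y[test])) < 2) {
      warn(paste0("fold ", k, ": held-out residues single-class; ",
                  "class-dependent metrics undefined"))
      rep_k <- tibble(sen = NA_real_, spe = NA_real_,
                      acc = mean(classify_scores(prob, tau_k) == y[test]),
                      bac = NA_real_, pre = NA_real_, mcc = NA_real_,
                      auc = NA_real_, ppv_top10 = NA_real_,
                      ppv_top5 = NA_real_, tau = tau_k)
    } else {
      rep_k <- metrics_report(prob, y[test], tau_k)
    }
    rep_k$fold <- k
    rep_k$n_test <- sum(test)
    rep_k$n_test_pos <- sum(y[test] == 1L)
    fold_rows[[length(fold_rows) + 1]] <- rep_k
    pooled[[length(pooled) + 1]] <- tibble(
      protein_id = feats$protein_id[test],
      residue_number = feats$residue_number[test],
      fold = k, probability = prob, label = y[test],
      call = classify_scores(prob, tau_k)
    )
  }
  folds <- bind_rows(fold_rows)
  predictions <- bind_rows(pooled)
  metric_cols <- c("sen", "spe", "acc", "bac", "pre", "mcc", "auc",
                   "ppv_top10", "ppv_top5")
  avg <- if (average == "folds") {
    if (anyNA(folds[metric_cols])) {
      warn("undefined fold metrics excluded from the average")
    }
    as_tibble(lapply(folds[metric_cols], mean, na.rm = TRUE))
  } else {
    m <- classification_metrics(confusion(predictions$call, predictions$label))
    m$auc <- roc_auc(predictions$probability, predictions$label)
    m$ppv_top10 <- top_fraction_ppv(predictions$probability, predictions$label, 0.10)
    m$ppv_top5 <- top_fraction_ppv(predictions$probability, predictions$label, 0.05)
    m
  }
  structure(
    list(folds = folds, average = avg, clusters = clusters,
         predictions = predictions,
         settings = list(C = C, gamma = gamma, class_weights = class_weights,
                         si_cutoff = si_cutoff, cov_cutoff = cov_cutoff,
                         calibration = calibration, threshold = threshold,
                         tau = tau, average = average)),
    class = "efold_cv"
  )
}

# decision values used to fit the Platt sigmoid for one outer fold
calibration_scores <- function(X, y, cluster, model, calibration, inner_k,
                               C, gamma, class_weights) {
  if (calibration == "train") {
    return(list(scores = decision_values(model, X), labels = y))
  }
  ids <- unique(cluster)
  k <- min(inner_k, length(ids))
  if (k < 2) {
    return(list(scores = decision_values(model, X), labels = y))
  }
  grp <- rep_len(seq_len(k), length(ids))[match(cluster, ids)]
  sc <- numeric(0); lb <- integer(0)
  for (g in seq_len(k)) {
    hold <- grp == g
    if (length(unique(y[!hold])) < 2) next
    m <- efold_train(X[!hold, , drop = FALSE], y[!hold], C = C, gamma = gamma,
                     class_weights = class_weights, calibrate = FALSE)
    sc <- c(sc, decision_values(m, X[hold, , drop = FALSE]))
    lb <- c(lb, y[hold])
  }
  if (length(unique(lb)) < 2) {
    return(list(scores = decision_values(model, X), labels = y))
  }
  list(scores = sc, labels = lb)
}

#' @export
print.efold_cv <- function(x, ...) {
  cat("<efold_cv>", nrow(x$folds), "folds over", max(x$clusters$cluster),
      "sequence-identity clusters\n")
  cat("average:\n")
  print(as.data.frame(round(x$average, 3)), row.names = FALSE)
  invisible(x)
}

#' Tidy / summarise a cross-validation result
#'
#' `tidy()` returns the per-fold metric rows; `glance()` returns the
#' averaged one-row report.
#'
#' @param x An `efold_cv` object.
#' @param ... Unused.
#' @method tidy efold_cv
#' @export
tidy.efold_cv <- function(x, ...) x$folds

#' @rdname tidy.efold_cv
#' @method glance efold_cv
#' @export
glance.efold_cv <- function(x, ...) x$average

#' Write a cross-validation report as TSV
#'
#' Per-fold rows followed by an `average` row.
#'
#' @param cv An `efold_cv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  metric_cols <- c("sen", "spe", "acc", "bac", "pre", "mcc", "auc",
                   "ppv_top10", "ppv_top5")
  folds <- cv$folds[, c("fold", "n_test", "n_test_pos", metric_cols, "tau")]
  avg <- cv$average[, metric_cols]
  avg$fold <- "average"; avg$n_test <- sum(folds$n_test)
  avg$n_test_pos <- sum(folds$n_test_pos); avg$tau <- NA_real_
  out <- bind_rows(mutate(folds, fold = as.character(.data$fold)), avg)
  utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
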