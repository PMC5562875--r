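# brute-force oracles, kept deliberately naive and independent of the
# package's implementations
oracle_metrics <- function(calls, labels) {
  tp <- sum(calls == 1 & labels == 1); fp <- sum(calls == 1 & labels == 0)
  tn <- sum(calls == 0 & labels == 0); fn <- sum(calls == 0 & labels == 1)
  z <- function(num, den) if (den == 0) 0 else num / den
  sen <- z(tp, tp + fn); spe <- z(tn, tn + fp)
  mden <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(sen = sen, spe = spe, acc = (tp + tn) / length(calls),
    bac = (sen + spe) / 2, pre = z(tp, tp + fp),
    mcc = if (mden == 0) 0 else (tp * tn - fp * fn) / mden)
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("pairwise identity and coverage behave at the reference points", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEV"
  expect_equal(pairwise_identity(s, s), c(identity = 1, coverage = 1))
  expect_equal(pairwise_identity("AAAA", "CCCC")[["identity"]], 0)
  half <- substr(s, 1, nchar(s) / 2)
  pid <- pairwise_identity(s, half)
  expect_equal(pid[["coverage"]], 0.5)
  expect_equal(pid[["identity"]], 1)
  # symmetric
  expect_equal(pairwise_identity(half, s), pid)
})

test_that("single-linkage clustering merges transitively and only above cutoffs", {
  set.seed(41)
  s1 <- random_sequence(30); s2 <- random_sequence(30)
  s3 <- random_sequence(30); s4 <- random_sequence(30)
  a <- paste0(s1, s2)  # A ~ B share s1
  b <- paste0(s1, s3)  # B ~ C share s3
  c_ <- paste0(s4, s3)
  d <- efold_dataset(c("A", "B", "C"), c(a, b, c_))
  # sanity: A and C are below the identity cutoff directly
  expect_lt(pairwise_identity(a, c_)[["identity"]], 0.25)
  cl <- cluster_sequences(d)
  expect_equal(cl$cluster, c(1L, 1L, 1L))

  # identical pair plus one unrelated: 2 clusters
  d2 <- efold_dataset(c("x", "y", "z"), c(a, a, c_))
  expect_equal(cluster_sequences(d2)$cluster, c(1L, 1L, 2L))

  # all dissimilar: singletons
  d3 <- efold_dataset(c("u", "v", "w"),
                      c(random_sequence(40), random_sequence(40), random_sequence(40)))
  expect_equal(cluster_sequences(d3)$cluster, c(1L, 2L, 3L))
})

test_that("coverage gates the clustering edge regardless of identity", {
  set.seed(42)
  long <- random_sequence(80)
  half <- substr(long, 1, 40)  # identity 1 but coverage 0.5
  d <- efold_dataset(c("L", "H"), c(long, half))
  expect_equal(cluster_sequences(d)$cluster, c(1L, 2L))
})

test_that("confusion counts are standard and conserve n", {
  expect_equal(confusion(c(1, 0), c(1, 0)),
               tibble::tibble(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  expect_equal(confusion(c(0, 0, 0), c(1, 1, 0)),
               tibble::tibble(tp = 0L, fp = 0L, tn = 1L, fn = 2L))
  set.seed(1)
  calls <- rbinom(50, 1, 0.4); labels <- rbinom(50, 1, 0.3)
  cc <- confusion(calls, labels)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 50)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metrics match hand computation and the zero-denominator convention", {
  perfect <- classification_metrics(confusion(c(1, 0), c(1, 0)))
  expect_equal(unlist(perfect), c(sen = 1, spe = 1, acc = 1, bac = 1, pre = 1, mcc = 1))

  m <- classification_metrics(tibble::tibble(tp = 3L, fp = 2L, tn = 6L, fn = 1L))
  expect_equal(m$sen, 0.75)
  expect_equal(m$spe, 0.75)
  expect_equal(m$pre, 0.6)
  expect_equal(m$acc, 0.75)
  expect_equal(m$bac, 0.75)
  expect_equal(m$mcc, 16 / sqrt(1120))

  expect_warning(m0 <- classification_metrics(confusion(c(0, 0, 0), c(1, 1, 0))),
                 "zero denominator")
  expect_equal(m0$pre, 0)
  expect_equal(m0$sen, 0)
})

test_that("metrics agree with a brute-force oracle on random instances", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    calls <- rbinom(n, 1, runif(1, 0.2, 0.8))
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    got <- suppressWarnings(classification_metrics(confusion(calls, labels)))
    expect_equal(unlist(got), oracle_metrics(calls, labels))
  }
})

test_that("AUC equals the pairwise rank statistic and is transform-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    scores <- round(rnorm(n), 1)  # rounded to force some ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    a <- roc_auc(scores, labels)
    expect_equal(a, oracle_auc(scores, labels))
    expect_equal(roc_auc(exp(2 * scores), labels), a)
  }
})

test_that("best_threshold maximizes Youden's J with ties toward larger tau", {
  # perfectly separated: threshold sits at the smallest positive score
  tau <- best_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(tau, 0.8)
  set.seed(4)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    scores <- round(runif(n), 2)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    tau <- best_threshold(scores, labels)
    j_at <- function(t) {
      calls <- as.integer(scores >= t)
      sum(calls & labels) / sum(labels) + sum(!calls & !labels) / sum(!labels) - 1
    }
    js <- vapply(sort(unique(scores)), j_at, numeric(1))
    expect_equal(j_at(tau), max(js))
    # tie-break: no larger candidate achieves the same J
    larger <- sort(unique(scores))[sort(unique(scores)) > tau]
    if (length(larger) > 0) expect_true(all(vapply(larger, j_at, numeric(1)) < j_at(tau)))
  }
})

test_that("top-fraction precision uses ceil and inclusive boundary ties", {
  # n = 10, single positive at the top
  expect_equal(top_fraction_ppv(c(0.99, runif(9, 0, 0.5)),
                                c(1, rep(0, 9)), 0.10), 1)
  expect_equal(top_fraction_ppv(runif(20), rep(1, 20), 0.05), 1)
  # crafted boundary tie: k = 2 but three scores tie at the boundary
  scores <- c(0.9, 0.5, 0.5, 0.5, rep(0.1, 16))
  labels <- c(1, 1, 0, 0, rep(0, 16))
  # selected set is {0.9, 0.5, 0.5, 0.5}: precision 2/4
  expect_equal(top_fraction_ppv(scores, labels, 0.10), 0.5)
  # brute force at several fractions
  set.seed(5)
  scores <- round(runif(30), 1); labels <- rbinom(30, 1, 0.3)
  for (f in c(0.05, 0.1, 0.25, 1)) {
    k <- ceiling(f * 30)
    cut <- sort(scores, decreasing = TRUE)[k]
    expect_equal(top_fraction_ppv(scores, labels, f),
                 mean(labels[scores >= cut]))
  }
})

test_that("cross-validation respects the cluster partition", {
  set.seed(44)
  ds <- generate_dataset(synthetic_config(n_proteins = 8, seed = 44))
  # plant an exact duplicate of the first protein
  dup <- ds$proteins[1, ]
  dup$id <- "dup001"
  proteins <- dplyr::bind_rows(ds$proteins, dup)
  prof_dup <- ds$profiles[ds$profiles$protein_id == ds$proteins$id[[1]], ]
  prof_dup$protein_id <- "dup001"
  profiles <- dplyr::bind_rows(ds$profiles, prof_dup)

  cl <- cluster_sequences(proteins)
  expect_equal(cl$cluster[cl$protein_id == "dup001"],
               cl$cluster[cl$protein_id == ds$proteins$id[[1]]])

  cv <- suppressWarnings(crossvalidate(proteins, profiles))
  # one fold per cluster
  expect_equal(sort(unique(cv$folds$fold)), sort(unique(cl$cluster)))
  # held-out proteins never share > 25% identity at >= 90% coverage with training
  for (k in unique(cl$cluster)) {
    test_ids <- cl$protein_id[cl$cluster == k]
    train_ids <- cl$protein_id[cl$cluster != k]
    for (ti in test_ids) for (tr in train_ids) {
      pid <- pairwise_identity(proteins$sequence[proteins$id == ti],
                               proteins$sequence[proteins$id == tr])
      expect_false(pid[["identity"]] > 0.25 && pid[["coverage"]] >= 0.90)
    }
  }
  # every test residue comes from the held-out cluster only
  pred_cl <- cl$cluster[match(cv$predictions$protein_id, cl$protein_id)]
  expect_equal(pred_cl, cv$predictions$fold)
})

test_that("fold averages are unweighted means and reports are written", {
  set.seed(45)
  ds <- generate_dataset(synthetic_config(n_proteins = 6, seed = 45))
  cv <- suppressWarnings(crossvalidate(ds$proteins, ds$profiles,
                                       calibration = "train"))
  for (m in c("sen", "spe", "acc", "auc")) {
    expect_equal(cv$average[[m]], mean(cv$folds[[m]], na.rm = TRUE))
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(cv, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(cv$folds) + 1)
  expect_equal(tab$fold[nrow(tab)], "average")
  # tidy/glance accessors
  expect_equal(generics::tidy(cv), cv$folds)
  expect_equal(generics::glance(cv), cv$average)
})

test_that("pooled averaging scores the concatenated held-out predictions", {
  set.seed(46)
  ds <- generate_dataset(synthetic_config(n_proteins = 6, seed = 46))
  cv <- suppressWarnings(crossvalidate(ds$proteins, ds$profiles,
                                       calibration = "train", average = "pooled"))
  expect_equal(cv$average$auc,
               roc_auc(cv$predictions$probability, cv$predictions$label))
})
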