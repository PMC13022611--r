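test_that("patient splits have the study shape and partition the cohort", {
  ids <- sprintf("P%02d", 1:25)
  sp <- make_cv_splits(ids, n_folds = 5, n_val = 3, seed = 9)
  expect_length(sp, 5)
  for (f in sp) {
    expect_length(f$test_patients, 5)
    expect_length(f$val_patients, 3)
    expect_length(f$train_patients, 17)
    expect_equal(anyDuplicated(c(f$train_patients, f$val_patients,
                                 f$test_patients)), 0L)
  }
  tests <- unlist(lapply(sp, `[[`, "test_patients"))
  expect_setequal(tests, ids)
  expect_equal(anyDuplicated(tests), 0L)

  expect_identical(make_cv_splits(ids, seed = 9), make_cv_splits(ids, seed = 9))
  expect_false(identical(make_cv_splits(ids, seed = 9),
                         make_cv_splits(ids, seed = 10)))
  expect_error(make_cv_splits(ids[1:4], n_folds = 5, n_val = 3), "at least")
  expect_error(make_cv_splits(ids[1:5], n_folds = 5, n_val = 4), "too few")
})

test_that("confusion counts are exact and symmetric", {
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  expect_equal(unlist(confusion_counts(y, y)),
               c(tp = 4L, fp = 0L, tn = 4L, fn = 0L))
  allpos <- confusion_counts(y, rep(1, 8))
  expect_equal(allpos$fp, 4L)
  a <- confusion_counts(y, c(1, 0, 1, 1, 0, 0, 1, 0))
  b <- confusion_counts(1 - y, 1 - c(1, 0, 1, 1, 0, 0, 1, 0))
  expect_equal(c(a$tp, a$tn, a$fp, a$fn), c(b$tn, b$tp, b$fn, b$fp))
  expect_error(confusion_counts(y, y[-1]), "mismatch")
})

test_that("metric formulas agree with closed forms and a perfect classifier", {
  perfect <- compute_metrics(tibble::tibble(tp = 10, fp = 0, tn = 14, fn = 0),
                             scores = c(rep(1, 10), rep(0, 14)),
                             y_true = rep(c(1, 0), c(10, 14)))
  expect_true(all(unlist(perfect) == 1))

  m <- compute_metrics(tibble::tibble(tp = 6, fp = 1, tn = 9, fn = 4))
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 6 / 7)
  expect_equal(m$balanced_accuracy, 0.75)
  expect_equal(m$f1, 2 * (6 / 7) * 0.6 / (6 / 7 + 0.6))
})

test_that("MCC equals the Pearson correlation of indicator vectors", {
  set.seed(92)
  for (i in 1:1000) {
    cnt <- as.list(rmultinom(1, sample(8:60, 1), runif(4, 0.05, 1))[, 1])
    names(cnt) <- c("tp", "fp", "tn", "fn")
    y <- rep(c(1, 1, 0, 0), unlist(cnt)[c("tp", "fn", "tn", "fp")])
    p <- rep(c(1, 0, 0, 1), unlist(cnt)[c("tp", "fn", "tn", "fp")])
    m <- compute_metrics(tibble::as_tibble(cnt))
    if (stats::sd(y) == 0 || stats::sd(p) == 0) {
      expect_true(is.na(m$mcc))
    } else {
      expect_equal(m$mcc, stats::cor(y, p), tolerance = 1e-12)
    }
    # identities
    if (!is.na(m$balanced_accuracy))
      expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    if (!is.na(m$f1))
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity))
  }
})

test_that("rank AUC matches pairwise counting, is tie-aware and monotone-invariant", {
  pair_auc <- function(s, y) { # brute-force oracle
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(93)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties likely
    expect_equal(auc_rank(s, y), pair_auc(s, y))
    expect_equal(auc_rank(exp(3 * s) - 0.2, y), auc_rank(s, y)) # monotone map
  }
  expect_true(is.na(auc_rank(runif(5), rep(1, 5))))
})

test_that("random scores on balanced truth give AUC near one half", {
  set.seed(94)
  n <- 2000
  y <- rep(c(0, 1), n / 2)
  a <- auc_rank(runif(n), y)
  se <- sqrt((n / 2 + 1) / (12 * (n / 2)^2)) # Mann-Whitney null SE
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("Cohen's kappa matches hand arithmetic and its null behavior", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))$kappa, 1)

  # 2x2 agreement table: both-yes 20, both-no 60, discordant 10 + 10
  a <- rep(c(1, 1, 0, 0), c(20, 10, 10, 60))
  b <- rep(c(1, 0, 1, 0), c(20, 10, 10, 60))
  kr <- cohens_kappa(a, b)
  po <- 0.8; pe <- 0.3 * 0.3 + 0.7 * 0.7
  expect_equal(kr$po, po, tolerance = 1e-12)
  expect_equal(kr$pe, pe, tolerance = 1e-12)
  expect_equal(kr$kappa, (po - pe) / (1 - pe), tolerance = 1e-9)
  expect_true(kr$ci[1] <= kr$kappa && kr$kappa <= kr$ci[2])

  set.seed(95)
  n <- 4000
  ka <- cohens_kappa(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  expect_lt(abs(ka$kappa), 3 / sqrt(n)) # independent raters: kappa ~ 0

  expect_error(cohens_kappa(1:3, 1:2), "equal-length")
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5))$kappa, 1) # degenerate po=1
  d <- tidy(ka)
  expect_equal(d$estimate, ka$kappa)
})

test_that("degenerate folds flag metrics as undefined rather than zero", {
  one_class <- compute_metrics(tibble::tibble(tp = 5, fp = 0, tn = 0, fn = 3),
                               scores = runif(8), y_true = rep(1, 8))
  expect_true(is.na(one_class$specificity))
  expect_true(is.na(one_class$mcc))
  expect_true(is.na(one_class$auc))
  expect_false(is.na(one_class$accuracy))
})
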