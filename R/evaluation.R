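#' Patient-level cross-validation splits
#'
#' Patients are shuffled under `seed` and divided into `n_folds` test groups
#' that partition the cohort; within each fold, `n_val` validation patients
#' are drawn from the non-test pool and the rest train. All scans of a
#' patient follow the patient, so no patient appears in two cohorts of one
#' fold. With 25 patients and the defaults each fold has 5 test, 3
#' validation and 17 training patients.
#'
#' @param patient_ids Character or integer vector of distinct patient ids.
#' @param n_folds Number of folds.
#' @param n_val Validation patients per fold.
#' @param seed Integer seed.
#' @return List of `n_folds` lists with `fold`, `train_patients`,
#'   `val_patients`, `test_patients`.
#' @export
make_cv_splits <- function(patient_ids, n_folds = 5, n_val = 3, seed = 1L) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  assert_that(n >= n_folds, "need at least n_folds patients")
  max_test <- ceiling(n / n_folds)
  assert_that(n_val >= 1 && n - max_test - n_val >= 1,
              "too few patients for the requested validation size")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample(patient_ids)
  groups <- split(perm, sort(rep_len(seq_len(n_folds), n)))
  lapply(seq_len(n_folds), function(i) {
    test <- groups[[i]]
    pool <- setdiff(perm, test)
    val <- sample(pool, n_val)
    list(fold = i, train_patients = setdiff(pool, val),
         val_patients = val, test_patients = test)
  })
}

#' Confusion counts for binary vectors
#'
#' @param y_true,y_pred Equal-length binary (0/1 or logical) vectors.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred), "length mismatch")
  t <- as.integer(y_true); p <- as.integer(y_pred)
  tibble::tibble(tp = sum(t == 1 & p == 1), fp = sum(t == 0 & p == 1),
                 tn = sum(t == 0 & p == 0), fn = sum(t == 1 & p == 0))
}

#' Rank-based AUC with midrank tie handling
#'
#' Mann-Whitney formulation: the probability a random positive outscores a
#' random negative, ties counting one half. Invariant under strictly
#' monotone score transformations; `NA` when either class is absent.
#'
#' @param scores Numeric section scores.
#' @param y_true Binary truth.
#' @return AUC in `[0, 1]`, or `NA` for one-class truth.
#' @export
auc_rank <- function(scores, y_true) {
  y <- as.integer(y_true)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores) # midranks for ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metric suite for one fold
#'
#' Computes accuracy, balanced accuracy, precision, sensitivity,
#' specificity, F1, Matthews correlation coefficient and rank-based AUC from
#' confusion counts and (optionally) continuous section scores. Metrics
#' whose denominator is degenerate (e.g. MCC or AUC with one-class truth)
#' are reported as `NA`, never silently zeroed.
#'
#' @param conf One-row tibble from [confusion_counts()] (or a list with
#'   `tp`, `fp`, `tn`, `fn`).
#' @param scores Optional section scores for AUC.
#' @param y_true Truth vector matching `scores`.
#' @return One-row tibble of metrics.
#' @export
compute_metrics <- function(conf, scores = NULL, y_true = NULL) {
  tp <- conf$tp; fp <- conf$fp; tn <- conf$tn; fn <- conf$fn
  n <- tp + fp + tn + fn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
         else NA_real_
  auc <- if (!is.null(scores)) auc_rank(scores, y_true) else NA_real_
  tibble::tibble(
    accuracy = div(tp + tn, n),
    balanced_accuracy = if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_,
    precision = prec, sensitivity = sens, specificity = spec,
    f1 = f1, mcc = mcc, auc = auc
  )
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement between two raters:
#' `kappa = (po - pe) / (1 - pe)` with expected agreement `pe` from the
#' marginal products. The 95% CI uses the standard large-sample variance
#' `po (1 - po) / (n (1 - pe)^2)` with normal quantiles, clipped to
#' `[-1, 1]`. Degenerate marginals (`pe = 1`) give kappa 1 when agreement is
#' perfect and `NA` otherwise.
#'
#' @param a,b Equal-length categorical vectors (two raters).
#' @param conf_level Confidence level.
#' @return A `kappa_result`: `kappa`, `ci` (length 2), `n_items`, `po`, `pe`.
#' @examples
#' cohens_kappa(rep(c(1, 0), c(30, 70)), rep(c(1, 0, 1, 0), c(20, 10, 10, 60)))
#' @export
cohens_kappa <- function(a, b, conf_level = 0.95) {
  assert_that(length(a) == length(b) && length(a) > 0,
              "raters must be equal-length, non-empty")
  n <- length(a)
  lev <- union(unique(a), unique(b))
  ta <- table(factor(a, lev), factor(b, lev))
  po <- sum(diag(ta)) / n
  pe <- sum(rowSums(ta) * colSums(ta)) / n^2
  if (1 - pe < 1e-12) {
    k <- if (abs(po - 1) < 1e-12) 1 else NA_real_
    ci <- c(k, k)
  } else {
    k <- (po - pe) / (1 - pe)
    se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- pmin(pmax(k + c(-1, 1) * z * se, -1), 1)
  }
  structure(list(kappa = k, ci = ci, n_items = n, po = po, pe = pe,
                 conf_level = conf_level),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f  (%.0f%% CI %.4f to %.4f), n = %d\n",
              x$kappa, 100 * x$conf_level, x$ci[1], x$ci[2], x$n_items))
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(estimate = x$kappa, conf.low = x$ci[1], conf.high = x$ci[2],
                 n = x$n_items, p.agree = x$po, p.chance = x$pe)
}

# population SD (divisor n), the convention used for across-fold spreads
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Patient-level cross-validated training and evaluation
#'
#' The full experiment: for each fold and task, weak-labeled training and
#' validation patch sets are assembled from the fold's patients, a fresh
#' patch classifier is trained, every retained test patch is scored, patch
#' probabilities are aggregated into section calls, and the metric suite is
#' computed per fold. Means and population SDs across folds summarize each
#' task. Every test section is scored exactly once across the experiment
#' (the test groups partition patients). Folds whose test truth is
#' one-class get `NA` for the affected metrics and the run continues.
#'
#' @param patches QC'd patch tibble (pixels retained at least for
#'   `qc_status == "retained"` rows).
#' @param manifest Cohort manifest.
#' @param tasks Character vector of tasks to model.
#' @param model_config A [cnn_config()] applied to every task (the per-task
#'   seed is derived from it).
#' @param agg_config An [aggregation_config()].
#' @param n_folds,n_val,seed Split parameters, see [make_cv_splits()].
#' @param max_train_patches,max_val_patches Per-fold caps; balanced seeded
#'   subsamples keep desk-scale runs fast while every *test* patch is
#'   always scored.
#' @param verbose Print fold progress.
#' @return A `cv_report`: `folds` (per-task per-fold metrics + confusion),
#'   `summary` (mean and population SD per metric), `predictions`
#'   (section-level calls vs truth), `splits`.
#' @export
cross_validate <- function(patches, manifest,
                           tasks = c("abnormal", "active_inflammation",
                                     "chronic_changes"),
                           model_config = cnn_config(),
                           agg_config = aggregation_config(),
                           n_folds = 5, n_val = 3, seed = 1L,
                           max_train_patches = 800, max_val_patches = 240,
                           verbose = FALSE) {
  splits <- make_cv_splits(unique(manifest$patient_id), n_folds, n_val, seed)
  fold_rows <- list()
  pred_rows <- list()
  for (task in tasks) {
    bags <- build_bags(manifest, patches, task)
    for (sp in splits) {
      res <- run_fold(patches, bags, sp, task, model_config, agg_config,
                      seed, max_train_patches, max_val_patches)
      fold_rows[[length(fold_rows) + 1]] <-
        tibble::tibble(task = task, fold = sp$fold, res$conf, res$metrics,
                       n_test_sections = res$n_test_sections,
                       n_nocall = res$n_nocall)
      pred_rows[[length(pred_rows) + 1]] <- res$predictions
      if (verbose)
        message(sprintf("[%s] fold %d: acc %.3f  auc %s", task, sp$fold,
                        res$metrics$accuracy,
                        ifelse(is.na(res$metrics$auc), "NA",
                               sprintf("%.3f", res$metrics$auc))))
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("accuracy", "balanced_accuracy", "precision", "sensitivity",
                   "specificity", "f1", "mcc", "auc")
  summary <- folds |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$task, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = pop_sd(.data$value),
                     n_folds_defined = sum(!is.na(.data$value)),
                     .groups = "drop")
  structure(list(folds = folds, summary = summary,
                 predictions = dplyr::bind_rows(pred_rows), splits = splits,
                 tasks = tasks, seed = seed),
            class = "cv_report")
}

# Train/evaluate one (task, fold). Balanced seeded subsampling caps the
# train/val patch pools; all retained test patches are scored.
run_fold <- function(patches, bags, sp, task, model_config, agg_config,
                     seed, max_train, max_val) {
  pick_instances <- function(pats, cap) {
    b <- bags[bags$patient_id %in% pats & bags$usable, ]
    ix <- unlist(b$instances, use.names = FALSE)
    lab <- rep(b$weak_label, b$n_instances)
    if (length(ix) > cap) {
      # balanced subsample: up to cap/2 per class, seeded
      keep <- unlist(lapply(c(0, 1), function(cl) {
        cl_ix <- which(lab == cl)
        if (length(cl_ix) > cap / 2) sample(cl_ix, cap / 2) else cl_ix
      }))
      keep <- sort(keep)
      ix <- ix[keep]; lab <- lab[keep]
    }
    list(ix = ix, lab = lab)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, task, sp$fold))
  tr <- pick_instances(sp$train_patients, max_train)
  va <- pick_instances(sp$val_patients, max_val)
  assert_that(length(unique(tr$lab)) == 2,
              sprintf("fold %d (%s): training labels are one-class", sp$fold, task))
  if (length(va$ix) == 0) va <- tr # degenerate val pool: fall back to train

  cfg <- model_config
  cfg$seed <- derive_seed(model_config$seed, task, sp$fold)
  model <- build_model(cfg)
  model <- fit_patch_cnn(model, patches$pixels[tr$ix], tr$lab,
                         patches$pixels[va$ix], va$lab, task = task)

  test_bags <- bags[bags$patient_id %in% sp$test_patients, ]
  preds <- lapply(seq_len(nrow(test_bags)), function(i) {
    ix <- test_bags$instances[[i]]
    if (length(ix %||% integer()) == 0) {
      return(tibble::tibble(task = task, fold = sp$fold,
                            scan_id = test_bags$scan_id[i],
                            patient_id = test_bags$patient_id[i],
                            n_patches = 0L, positive_fraction = NA_real_,
                            score = NA_real_, call = NA,
                            true_label = test_bags$weak_label[i]))
    }
    probs <- predict_patches(model, patches$pixels[ix])
    agg <- aggregate_section(probs, agg_config)
    tibble::tibble(task = task, fold = sp$fold,
                   scan_id = test_bags$scan_id[i],
                   patient_id = test_bags$patient_id[i], agg,
                   true_label = test_bags$weak_label[i])
  })
  preds <- dplyr::bind_rows(preds)
  scored <- preds[!is.na(preds$call), ]
  conf <- confusion_counts(scored$true_label, scored$call)
  metrics <- compute_metrics(conf, scores = scored$score,
                             y_true = scored$true_label)
  list(conf = conf, metrics = metrics, predictions = preds,
       n_test_sections = nrow(preds), n_nocall = sum(is.na(preds$call)))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds x %d tasks, %d test sections\n",
              length(x$splits), length(x$tasks), nrow(x$predictions)))
  s <- x$summary |>
    dplyr::filter(.data$metric %in% c("accuracy", "mcc", "auc")) |>
    dplyr::mutate(txt = sprintf("%s %.3f (%.3f)", .data$metric, .data$mean, .data$sd))
  for (tk in unique(s$task))
    cat(" ", tk, ": ", paste(s$txt[s$task == tk], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn cross_validate Per-fold metrics in long form.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) {
  x$folds |>
    tidyr::pivot_longer(c("accuracy", "balanced_accuracy", "precision",
                          "sensitivity", "specificity", "f1", "mcc", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("task", "fold", "metric", "value")
}

#' @describeIn cross_validate One row per task: mean (SD) of each metric.
#' @export
glance.cv_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(id_cols = "task", names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}
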