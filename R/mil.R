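#' Aggregation rule configuration
#'
#' Section-level calls follow a two-threshold majority rule: a patch is
#' "positive" when its probability strictly exceeds `patch_threshold`
#' (default P > .5), and the section is called positive when the fraction of
#' positive patches strictly exceeds `bag_threshold` (default more than
#' 50%). Ties at either threshold therefore go negative. The continuous
#' section score used for ROC curves is the positive fraction by default
#' (so the binary call is exactly a threshold on the score), with mean
#' patch probability as an alternative.
#'
#' @param patch_threshold Patch-level probability threshold (strict `>`).
#' @param bag_threshold Fraction-of-positive-patches threshold (strict `>`).
#' @param score_mode `"positive_fraction"` or `"mean_probability"`.
#' @return An `aggregation_config` object.
#' @export
aggregation_config <- function(patch_threshold = 0.5, bag_threshold = 0.5,
                               score_mode = c("positive_fraction",
                                              "mean_probability")) {
  assert_that(patch_threshold >= 0 && patch_threshold <= 1 &&
                bag_threshold >= 0 && bag_threshold <= 1,
              "thresholds must be in [0, 1]")
  structure(list(patch_threshold = patch_threshold,
                 bag_threshold = bag_threshold,
                 score_mode = match.arg(score_mode)),
            class = "aggregation_config")
}

#' Aggregate patch probabilities into a section prediction
#'
#' @param probs Numeric vector of per-patch probabilities (>= 1).
#' @param config An [aggregation_config()].
#' @return One-row tibble: `n_patches`, `positive_fraction`, `score`,
#'   `call` (logical section-level abnormality call).
#' @examples
#' aggregate_section(c(0.9, 0.8, 0.2, 0.7, 0.6, 0.9, 0.1, 0.3, 0.8, 0.95))
#' @export
aggregate_section <- function(probs, config = aggregation_config()) {
  assert_that(length(probs) >= 1, "cannot aggregate an empty probability list")
  assert_that(all(is.finite(probs) & probs >= 0 & probs <= 1),
              "probabilities must lie in [0, 1]")
  pf <- mean(probs > config$patch_threshold)
  tibble::tibble(
    n_patches = length(probs),
    positive_fraction = pf,
    score = section_score(probs, config),
    call = pf > config$bag_threshold
  )
}

#' Continuous section score
#'
#' @inheritParams aggregate_section
#' @return Score in `[0, 1]` per `config$score_mode`.
#' @export
section_score <- function(probs, config = aggregation_config()) {
  assert_that(length(probs) >= 1, "cannot score an empty probability list")
  switch(config$score_mode,
         positive_fraction = mean(probs > config$patch_threshold),
         mean_probability = mean(probs))
}

#' Build MIL bags for one task
#'
#' One bag per scan: the scan's QC-retained patches, each inheriting the
#' section's pathologist label for the task (weak supervision - instance
#' labels are unknown and noisy by design). Bags with zero retained patches
#' are kept in the output flagged `usable = FALSE`; they are excluded from
#' training and reported as "no-call" in evaluation rather than forced
#' negative.
#'
#' @param manifest Cohort manifest with `scan_id`, `patient_id` and label
#'   columns.
#' @param patches Patch tibble covering the manifest's scans.
#' @param task One of `"abnormal"`, `"active_inflammation"`,
#'   `"chronic_changes"`.
#' @return Nested tibble: `scan_id`, `patient_id`, `weak_label` (0/1),
#'   `n_instances`, `usable`, and list-column `instances` (row indices into
#'   `patches`).
#' @export
build_bags <- function(manifest, patches, task = c("abnormal",
                                                   "active_inflammation",
                                                   "chronic_changes")) {
  task <- match.arg(task)
  unknown <- setdiff(unique(patches$scan_id), manifest$scan_id)
  assert_that(length(unknown) == 0,
              paste("patches reference scans missing from the manifest:",
                    paste(head(unknown, 3), collapse = ", ")))
  ret <- which(patches$qc_status == "retained")
  by_scan <- split(ret, patches$scan_id[ret])
  bags <- manifest |>
    dplyr::transmute(
      scan_id = .data$scan_id,
      patient_id = .data$patient_id,
      weak_label = as.integer(.data[[task]]),
      instances = unname(by_scan[.data$scan_id]),
      n_instances = vapply(.data$instances, function(ix) length(ix %||% integer()), 0L),
      usable = .data$n_instances > 0
    )
  attr(bags, "task") <- task
  bags
}
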