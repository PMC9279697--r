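# Cohort construction: HAM-D severity banding, binary-task screening,
# dataset assembly and train/test splitting.

#' Severity band levels
#'
#' Ordered severity bands derived from HDRS-24 totals: `NONE` < `PROBABLE` <
#' `MEDIUM` < `SEVERE`.
#'
#' @return Character vector of the four band names, in increasing severity.
#' @export
severity_bands <- function() c("NONE", "PROBABLE", "MEDIUM", "SEVERE")

#' Band an HDRS-24 total into a severity level
#'
#' Interval rules: `NONE` for scores in \[0, 8\], `PROBABLE` for (8, 20\],
#' `MEDIUM` for (20, 35\], `SEVERE` above 35. The printed clinical bands
#' overlap at their boundaries ("0-8" and "8-20" both contain 8); the
#' left-open convention adopted here is the only one consistent with the
#' usual screening cutpoint "> 8", so a score of exactly 8 is `NONE`.
#'
#' @param hamd Non-negative HDRS-24 total score(s).
#' @return Ordered factor over [severity_bands()], same length as `hamd`.
#' @export
#' @examples
#' band_score(c(0, 8, 8.5, 20, 26.8, 39.6))
band_score <- function(hamd) {
  if (any(!is.finite(hamd)) || any(hamd < 0)) {
    abort("band_score: scores must be finite and non-negative")
  }
  idx <- 1L + (hamd > 8) + (hamd > 20) + (hamd > 35)
  factor(severity_bands()[idx], levels = severity_bands(), ordered = TRUE)
}

#' Screen a cohort for the binary task
#'
#' Removes the contradictory records before binary labeling: patients whose
#' HDRS-24 total is below 8 (typically recovered under treatment) and
#' normal controls scoring above 8. Both filters are strict, so a score of
#' exactly 8 is always kept. Idempotent.
#'
#' @param records Tibble of subject records with columns `subject_id`,
#'   `group` (`PATIENT`/`NORMAL`) and `hamd_score`.
#' @param exclusions Optional tibble (`subject_id`, `reason`) of additional
#'   manual removals (e.g. psychiatrist advice).
#' @return List with `kept` (tibble) and `removed` (tibble with a `reason`
#'   column).
#' @export
screen_binary <- function(records, exclusions = NULL) {
  records <- tibble::as_tibble(records)
  reason <- rep(NA_character_, nrow(records))
  reason[records$group == "PATIENT" & records$hamd_score < 8] <-
    "patient_score_below_8"
  reason[records$group == "NORMAL" & records$hamd_score > 8] <-
    "normal_score_above_8"
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    hit <- match(records$subject_id, exclusions$subject_id)
    manual <- !is.na(hit) & is.na(reason)
    reason[manual] <- paste0("manual:", exclusions$reason[hit[manual]])
  }
  removed <- records[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = records[is.na(reason), , drop = FALSE], removed = removed)
}

#' Assemble a labeled dataset
#'
#' Links subject records to their feature tensors and attaches task labels.
#' For the binary task the positive class is depression: label 1 iff
#' `group == "PATIENT"` (apply [screen_binary()] first). For the multi-class
#' task the label is the severity band of the HDRS-24 total and every record
#' is used, unscreened.
#'
#' @param records Tibble of subject records (see [read_subjects()]).
#' @param tensors Named list of [feature_tensor()] objects keyed by
#'   `subject_id`.
#' @param task `"binary"` or `"multi"`.
#' @return A `labeled_dataset`: list with `task`, `items` (tibble
#'   `subject_id`, `label`, `class_name`), `tensors`, `class_names`.
#' @export
build_dataset <- function(records, tensors, task = c("binary", "multi")) {
  task <- match.arg(task)
  records <- tibble::as_tibble(records)
  missing_t <- setdiff(records$subject_id, names(tensors))
  if (length(missing_t) > 0) {
    abort(paste0("build_dataset: no tensor for subject(s): ",
                 paste(head(missing_t, 5), collapse = ", ")))
  }
  if (nrow(records) == 0) abort("build_dataset: no records")
  if (task == "binary") {
    class_names <- c("NON_DEPRESSION", "DEPRESSION")
    label <- as.integer(records$group == "PATIENT")
  } else {
    class_names <- severity_bands()
    band <- band_score(records$hamd_score)
    label <- as.integer(band) - 1L
  }
  items <- tibble::tibble(
    subject_id = records$subject_id,
    label = label,
    class_name = class_names[label + 1L]
  )
  structure(
    list(task = task, items = items,
         tensors = tensors[records$subject_id], class_names = class_names),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  counts <- table(factor(x$items$class_name, levels = x$class_names))
  cat(sprintf("<labeled_dataset> task %s, %d items (%s)\n", x$task,
              nrow(x$items),
              paste(names(counts), counts, sep = "=", collapse = ", ")))
  invisible(x)
}

dataset_subset <- function(ds, idx) {
  structure(
    list(task = ds$task, items = ds$items[idx, , drop = FALSE],
         tensors = ds$tensors[idx], class_names = ds$class_names),
    class = "labeled_dataset"
  )
}

#' Split a labeled dataset into train and test sets
#'
#' Disjoint and exhaustive. The train size is `floor((1 - test_fraction) *
#' N)`. Under stratified splitting, per-class train counts start at the floor
#' of the class share and the remainder is assigned by largest fractional
#' part, so class proportions are preserved within one item per class; a
#' class with fewer than 2 items degrades to non-stratified handling with a
#' warning. Reproducible under a fixed seed (the global RNG state is left
#' untouched).
#'
#' @param ds A `labeled_dataset` from [build_dataset()].
#' @param test_fraction In (0, 1); e.g. 0.30 or 0.20.
#' @param seed Integer seed for the split.
#' @param stratified Preserve class proportions (default `TRUE` for the
#'   multi-class task, `FALSE` for binary).
#' @return List with `train` and `test` datasets and a `manifest` tibble
#'   (`subject_id`, `partition`).
#' @export
split_dataset <- function(ds, test_fraction, seed = 1,
                          stratified = identical(ds$task, "multi")) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("split_dataset: test_fraction must be in (0, 1)")
  }
  n <- nrow(ds$items)
  n_train <- floor((1 - test_fraction) * n)
  train_idx <- withr::with_seed(seed, {
    if (!stratified) {
      sample(n, n_train)
    } else {
      labels <- ds$items$label
      tab <- table(labels)
      if (any(tab < 2)) {
        warn("split_dataset: class with < 2 items; falling back to a non-stratified split")
        sample(n, n_train)
      } else {
        share <- as.numeric(tab) / n * n_train
        base <- floor(share)
        rem <- n_train - sum(base)
        if (rem > 0) {
          extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
          base[extra] <- base[extra] + 1
        }
        idx <- integer(0)
        classes <- as.integer(names(tab))
        for (k in seq_along(classes)) {
          members <- which(labels == classes[k])
          idx <- c(idx, sample(members, base[k]))
        }
        idx
      }
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  manifest <- tibble::tibble(
    subject_id = ds$items$subject_id,
    partition = ifelse(seq_len(n) %in% train_idx, "train", "test")
  )
  list(train = dataset_subset(ds, train_idx),
       test = dataset_subset(ds, test_idx),
       manifest = manifest)
}
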