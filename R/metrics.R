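#' Binary confusion matrix
#'
#' Standard TP/FP/TN/FN counts with a declared positive label. The
#' default positive label is the lexicographically (numerically) larger
#' one, matching the usual 0/1 UCI encodings.
#'
#' @param truth,estimate Equal-length label vectors (two classes).
#' @param positive The positive class label; `NULL` picks the larger of
#'   the two observed labels.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`,
#'   `positive`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion <- function(truth, estimate, positive = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have equal length.", call. = FALSE)
  }
  classes <- sort(unique(c(truth, estimate)))
  if (length(classes) > 2L) {
    stop("More than 2 classes; use metric_report(averaging = \"macro\").",
         call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- classes[length(classes)]
  }
  positive <- as.character(positive)
  tibble::tibble(
    tp = sum(truth == positive & estimate == positive),
    fp = sum(truth != positive & estimate == positive),
    tn = sum(truth != positive & estimate != positive),
    fn = sum(truth == positive & estimate != positive),
    positive = positive
  )
}

#' Accuracy from a confusion matrix, in percent
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)` at full precision (rounding is
#' left to the reporting layer).
#'
#' @param cm A one-row data frame with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion()]), or a numeric vector of the four counts in that order.
#' @return Accuracy on the 0-100 scale.
#' @export
#' @examples
#' accuracy_from_confusion(c(tp = 35, fp = 28, tn = 90, fn = 39)) # 65.104...
accuracy_from_confusion <- function(cm) {
  if (is.data.frame(cm)) {
    counts <- c(cm$tp, cm$fp, cm$tn, cm$fn)
  } else {
    counts <- unname(cm[c(1, 2, 3, 4)])
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("Confusion matrix has no scored instances.", call. = FALSE)
  }
  100 * (counts[1] + counts[3]) / total
}

# Mann-Whitney AUC with midrank tie handling.
rank_auc <- function(truth01, scores) {
  n_pos <- sum(truth01 == 1)
  n_neg <- sum(truth01 == 0)
  if (n_pos == 0 || n_neg == 0) {
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth01 == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as 0.",
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metric report
#'
#' Accuracy, precision, recall, F1 (reported on the 0-100 percent scale)
#' and AUC (0-1) for one set of predictions. Binary metrics use the
#' declared positive class; `averaging = "macro"` averages one-vs-rest
#' precision/recall/F1/AUC over classes (required for more than two
#' classes). AUC is the Mann-Whitney rank statistic on the provided
#' scores, with midranks for ties. Undefined precision/recall (zero
#' denominator) is reported as 0 with a warning so reports stay total.
#'
#' @param truth True labels.
#' @param estimate Predicted labels.
#' @param scores Per-instance positive-class scores (binary) or a matrix
#'   with one named column per class. `NULL` gives `NA` AUC.
#' @param positive Positive class (binary mode); `NULL` picks the larger
#'   observed label.
#' @param averaging `"positive_class"` (default, binary) or `"macro"`.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`, `averaging`.
#' @export
metric_report <- function(truth, estimate, scores = NULL, positive = NULL,
                          averaging = c("positive_class", "macro")) {
  averaging <- match.arg(averaging)
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate))
  classes <- sort(unique(truth))
  if (length(classes) > 2L && averaging == "positive_class") {
    stop("More than 2 classes requires averaging = \"macro\".", call. = FALSE)
  }
  accuracy <- 100 * mean(truth == estimate)

  one_vs_rest <- function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    precision <- safe_ratio(tp, tp + fp, paste0("precision(", cl, ")"))
    recall <- safe_ratio(tp, tp + fn, paste0("recall(", cl, ")"))
    f1 <- if (precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    auc <- NA_real_
    if (!is.null(scores)) {
      s <- if (is.matrix(scores)) scores[, cl] else scores
      auc <- rank_auc(as.numeric(truth == cl), s)
    }
    c(precision = precision, recall = recall, f1 = f1, auc = auc)
  }

  if (averaging == "positive_class") {
    pos <- if (is.null(positive)) classes[length(classes)] else as.character(positive)
    vals <- one_vs_rest(pos)
  } else {
    per_class <- vapply(classes, one_vs_rest, numeric(4))
    vals <- rowMeans(per_class)
  }
  tibble::tibble(
    accuracy = accuracy,
    precision = 100 * vals[["precision"]],
    recall = 100 * vals[["recall"]],
    f1 = 100 * vals[["f1"]],
    auc = vals[["auc"]],
    averaging = averaging
  )
}

# Largest-remainder allocation of test counts per class.
largest_remainder_counts <- function(class_sizes, test_fraction) {
  exact <- class_sizes * test_fraction
  base <- floor(exact)
  total <- round(sum(class_sizes) * test_fraction)
  shortfall <- total - sum(base)
  if (shortfall > 0) {
    order_by_rem <- order(exact - base, decreasing = TRUE)
    base[order_by_rem[seq_len(shortfall)]] <- base[order_by_rem[seq_len(shortfall)]] + 1
  } else if (shortfall < 0) {
    order_by_rem <- order(exact - base)
    take <- order_by_rem[seq_len(-shortfall)]
    base[take] <- base[take] - 1
  }
  base
}

#' Stratified hold-out split
#'
#' Per-class shuffled allocation into a training and a test part, with
#' largest-remainder rounding of the per-class test counts so every class
#' is represented in proportion (within one instance). Deterministic per
#' seed.
#'
#' @param data Data frame with a label column.
#' @param fraction Training fraction, default 0.7.
#' @param seed RNG seed for the shuffle.
#' @param label_col Name of the label column.
#' @return A list of class `split_plan`: `train_indices`, `test_indices`,
#'   `seed`, `fraction`.
#' @export
stratified_holdout <- function(data, fraction = 0.7, seed = 0,
                               label_col = "label") {
  stopifnot(fraction > 0, fraction < 1)
  labels <- as.character(data[[label_col]])
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("Every class needs at least 2 members for a stratified split.",
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  test_counts <- largest_remainder_counts(as.numeric(tab), 1 - fraction)
  names(test_counts) <- names(tab)
  test_idx <- integer(0)
  for (cl in names(tab)) {
    members <- sample(which(labels == cl))
    test_idx <- c(test_idx, members[seq_len(test_counts[[cl]])])
  }
  test_idx <- sort(test_idx)
  structure(
    list(
      train_indices = setdiff(seq_along(labels), test_idx),
      test_indices = test_idx,
      seed = seed,
      fraction = fraction
    ),
    class = "split_plan"
  )
}

#' Repeated stratified k-fold plan
#'
#' For each repetition r, a stratified k-fold assignment is generated from
#' `seeds[r]`: within every class, shuffled members are dealt round-robin
#' into folds, so per-class fold sizes differ by at most one and the test
#' folds partition the data.
#'
#' @param data Data frame with a label column.
#' @param k Number of folds, default 5.
#' @param repetitions Number of independent rounds, default 30.
#' @param seeds One seed per repetition, default `1:repetitions`.
#' @param label_col Name of the label column.
#' @return A list of class `kfold_plan`: `folds` (list of length
#'   `repetitions`, each an integer fold-assignment vector in `1..k`),
#'   `k`, `repetitions`, `seeds`.
#' @export
repeated_stratified_kfold <- function(data, k = 5, repetitions = 30,
                                      seeds = seq_len(repetitions),
                                      label_col = "label") {
  stopifnot(k >= 2, repetitions >= 1, length(seeds) == repetitions)
  labels <- as.character(data[[label_col]])
  tab <- table(labels)
  if (any(tab < k)) {
    stop("Every class needs at least k = ", k, " members.", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  folds <- lapply(seeds, function(s) {
    set.seed(s)
    assignment <- integer(length(labels))
    for (cl in names(tab)) {
      members <- sample(which(labels == cl))
      assignment[members] <- rep_len(seq_len(k), length(members))
    }
    assignment
  })
  structure(
    list(folds = folds, k = k, repetitions = repetitions, seeds = seeds),
    class = "kfold_plan"
  )
}
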