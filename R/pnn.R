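#' @importFrom generics tidy glance augment
#' @importFrom rlang .data
NULL

#' Split a labeled data frame into features and labels
#'
#' Datasets are plain data frames: numeric feature columns plus one label
#' column (default `"label"`). Used by every estimator in the package.
#'
#' @param data A data frame.
#' @param label_col Name of the label column.
#' @return A list with `features` (numeric matrix), `labels` (character),
#'   `classes` (ordered distinct classes), `feature_names`.
#' @keywords internal
split_features_labels <- function(data, label_col = "label") {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame.", call. = FALSE)
  }
  if (!label_col %in% names(data)) {
    stop("`data` has no `", label_col, "` column.", call. = FALSE)
  }
  labels <- as.character(data[[label_col]])
  feats <- data[setdiff(names(data), label_col)]
  if (ncol(feats) < 1L) {
    stop("`data` has no feature columns.", call. = FALSE)
  }
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    stop("All feature columns must be numeric.", call. = FALSE)
  }
  features <- as.matrix(feats)
  if (anyNA(features) || anyNA(labels)) {
    stop("Missing values are not supported.", call. = FALSE)
  }
  classes <- if (is.factor(data[[label_col]])) {
    levels(droplevels(data[[label_col]]))
  } else {
    sort(unique(labels))
  }
  list(features = features, labels = labels, classes = classes,
       feature_names = colnames(features))
}

#' Fit a probabilistic neural network
#'
#' Single-pass fit of a Parzen-window PNN: the pattern layer stores every
#' training row as a Gaussian kernel center; the summation layer averages
#' kernel activations per class (optionally cost-weighted and biased); the
#' output layer takes the argmax. There is no iterative training — all
#' adaptivity comes from the pattern weights `alpha` and class biases `b`
#' that [train_mpa_pnn()] tunes.
#'
#' @param data Data frame of numeric features plus a label column.
#' @param sigma Gaussian kernel bandwidth (smoothing parameter), shared by
#'   all pattern units; default 0.1, appropriate for features scaled to
#'   `[0, 1]`.
#' @param label_col Name of the label column, default `"label"`.
#' @param lambda_b Scale of the additive class-bias term, default 1.
#' @return An object of class `pnn` with fields `centers`, `sigma`,
#'   `pattern_weights` (alpha, all 1), `class_biases` (all 0),
#'   `class_costs` (all 1), `class_counts`, `classes`, `feature_names`,
#'   `lambda_b`, `center_labels`.
#' @export
#' @examples
#' d <- synth_dataset(dataset_spec("toy", n = 40, d = 2, seed = 1))
#' model <- pnn(d)
#' head(predict(model, d))
pnn <- function(data, sigma = 0.1, label_col = "label", lambda_b = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  parts <- split_features_labels(data, label_col)
  if (nrow(parts$features) < 2L) {
    stop("Training data needs at least 2 rows.", call. = FALSE)
  }
  if (length(parts$classes) < 2L) {
    stop("Degenerate class structure: training data has a single class.",
         call. = FALSE)
  }
  counts <- vapply(parts$classes, function(cl) sum(parts$labels == cl),
                   numeric(1))
  structure(
    list(
      centers = parts$features,
      center_labels = parts$labels,
      sigma = sigma,
      pattern_weights = rep(1, nrow(parts$features)),
      class_biases = stats::setNames(rep(0, length(parts$classes)), parts$classes),
      class_costs = stats::setNames(rep(1, length(parts$classes)), parts$classes),
      class_counts = counts,
      classes = parts$classes,
      feature_names = parts$feature_names,
      lambda_b = lambda_b
    ),
    class = "pnn"
  )
}

#' @export
print.pnn <- function(x, ...) {
  cat("<pnn> ", nrow(x$centers), " centers, ", length(x$classes),
      " classes, sigma = ", x$sigma, "\n", sep = "")
  invisible(x)
}

# Squared Euclidean distances between rows of a and rows of b.
squared_distances <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Pattern-layer kernel activations
#'
#' `phi_i(x) = exp(-||x - w_i||^2 / (2 sigma^2))` for every stored center
#' `w_i`; each activation lies in (0, 1], equal to 1 exactly at a center.
#'
#' @param model A fitted [pnn()].
#' @param x A single feature vector (length d) or an m x d matrix.
#' @return A length-`n_tr` vector (single x) or an m x `n_tr` matrix.
#' @export
kernel_activations <- function(model, x) {
  stopifnot(inherits(model, "pnn"))
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(xm) != ncol(model$centers)) {
    stop("`x` must have ", ncol(model$centers), " features.", call. = FALSE)
  }
  phi <- exp(-squared_distances(xm, model$centers) / (2 * model$sigma^2))
  if (is.matrix(x)) phi else drop(phi)
}

# Summation-layer scores for an activation matrix (m x n_tr).
scores_from_activations <- function(model, phi, loo_index = NULL) {
  classes <- model$classes
  weighted <- sweep(phi, 2, model$pattern_weights, `*`)
  if (!is.null(loo_index)) {
    # zero the self-kernel when scoring training rows against themselves
    weighted[cbind(seq_len(nrow(weighted)), loo_index)] <- 0
  }
  scores <- vapply(classes, function(cl) {
    idx <- model$center_labels == cl
    model$class_costs[[cl]] *
      rowSums(weighted[, idx, drop = FALSE]) / model$class_counts[[cl]]
  }, numeric(nrow(phi)))
  scores <- matrix(scores, nrow = nrow(phi),
                   dimnames = list(NULL, classes))
  sweep(scores, 2, model$lambda_b * model$class_biases, `+`)
}

#' Summation-layer class scores
#'
#' `f_c(x) = C_c * (1/n_c) * sum_{i in c} alpha_i phi_i(x) + lambda_b b_c`.
#' With the fitted defaults (`alpha = 1`, `b = 0`, `C_c = 1`) this is the
#' plain class-conditional Parzen density estimate.
#'
#' @inheritParams kernel_activations
#' @return A named length-C vector (single x) or an m x C matrix.
#' @export
class_scores <- function(model, x) {
  phi <- kernel_activations(model, if (is.matrix(x)) x else matrix(x, nrow = 1))
  phi <- if (is.matrix(phi)) phi else matrix(phi, nrow = 1)
  scores <- scores_from_activations(model, phi)
  if (is.matrix(x)) scores else drop(scores)
}

argmax_classes <- function(scores, classes) {
  # ties break toward the earliest class in the declared class order
  classes[apply(scores, 1, which.max)]
}

#' Predict classes with a fitted PNN
#'
#' The output layer takes the class with the highest summation-layer
#' score; exact ties break toward the earliest class in the declared
#' class order (deterministic and independent of training-row order).
#' With `loo = TRUE`, row i of `newdata` is assumed to be training row i
#' and its own kernel is excluded — the leave-one-out mode that backs the
#' hybrid trainer's fitness.
#'
#' @param object A fitted [pnn()].
#' @param newdata Data frame of features (a label column, if present, is
#'   ignored) or a numeric matrix.
#' @param type `"class"` (default) for a tibble of predictions plus
#'   scores, or `"score"` for the raw score matrix.
#' @param loo Leave-one-out scoring of the training matrix itself.
#' @param ... Unused.
#' @return For `type = "class"`, a tibble with `.pred_class` and one
#'   `.score_<class>` column per class; for `"score"`, the m x C matrix.
#' @export
predict.pnn <- function(object, newdata, type = c("class", "score"),
                        loo = FALSE, ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) {
    newdata
  } else {
    feats <- newdata[setdiff(names(newdata), "label")]
    as.matrix(feats)
  }
  if (ncol(x) != ncol(object$centers)) {
    stop("`newdata` must have ", ncol(object$centers), " feature columns.",
         call. = FALSE)
  }
  d2 <- squared_distances(x, object$centers)
  phi <- exp(-d2 / (2 * object$sigma^2))
  loo_index <- NULL
  if (loo) {
    if (nrow(x) != nrow(object$centers)) {
      stop("`loo = TRUE` requires `newdata` to be the training matrix.",
           call. = FALSE)
    }
    loo_index <- seq_len(nrow(x))
  }
  scores <- scores_from_activations(object, phi, loo_index)
  if (type == "score") {
    return(scores)
  }
  pred <- argmax_classes(scores, object$classes)
  # Rows whose scores are exactly tied have usually underflowed (every
  # kernel rounded to 0 at tiny sigma / large distances). In exact
  # arithmetic the nearest centers still dominate, so re-decide those rows
  # with a distance-shifted exponent: a common positive factor per row that
  # leaves the argmax of the kernel term unchanged.
  tied <- which(apply(scores, 1, function(s) max(s) == min(s)))
  if (length(tied) > 0) {
    d2t <- d2[tied, , drop = FALSE]
    if (!is.null(loo_index)) {
      d2t[cbind(seq_along(tied), tied)] <- Inf
    }
    shifted <- exp(-(d2t - apply(d2t, 1, min)) / (2 * object$sigma^2))
    model0 <- object
    model0$class_biases[] <- 0
    s2 <- scores_from_activations(model0, shifted)
    pred[tied] <- argmax_classes(s2, object$classes)
  }
  out <- tibble::tibble(.pred_class = pred)
  score_cols <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(score_cols) <- paste0(".score_", object$classes)
  dplyr::bind_cols(out, score_cols)
}

#' Serialize a PNN model to JSON
#'
#' Round-trip exact for inference: centers, bandwidth, pattern weights,
#' class biases, costs, counts and the class order are all stored.
#'
#' @param model A fitted [pnn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pnn_json <- function(model, path) {
  payload <- list(
    centers = unname(model$centers),
    center_labels = model$center_labels,
    sigma = model$sigma,
    pattern_weights = model$pattern_weights,
    class_biases = unname(model$class_biases),
    class_costs = unname(model$class_costs),
    class_counts = unname(model$class_counts),
    classes = model$classes,
    feature_names = model$feature_names,
    lambda_b = model$lambda_b
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PNN model from JSON
#'
#' @param path Path written by [write_pnn_json()].
#' @return A `pnn` object.
#' @export
read_pnn_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- matrix(as.numeric(p$centers), nrow = length(p$center_labels))
  colnames(centers) <- p$feature_names
  structure(
    list(
      centers = centers,
      center_labels = as.character(p$center_labels),
      sigma = p$sigma,
      pattern_weights = as.numeric(p$pattern_weights),
      class_biases = stats::setNames(as.numeric(p$class_biases), p$classes),
      class_costs = stats::setNames(as.numeric(p$class_costs), p$classes),
      class_counts = stats::setNames(as.numeric(p$class_counts), p$classes),
      classes = as.character(p$classes),
      feature_names = as.character(p$feature_names),
      lambda_b = p$lambda_b
    ),
    class = "pnn"
  )
}
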