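#' Stratified cross-validation folds shared across layers
#'
#' Assigns each exemplar to one of `n_folds` folds, stratified by category,
#' deterministically per seed. Using one assignment for every layer makes
#' per-layer accuracies directly comparable.
#'
#' @param labels Per-exemplar category labels.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold id per exemplar.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 1) {
  folds <- integer(length(labels))
  with_seed(derive_seed(seed, 29), {
    for (cc in unique(labels)) {
      idx <- which(labels == cc)
      if (length(idx) < n_folds) {
        abort(sprintf("category %s has %d exemplars (< %d folds).",
                      cc, length(idx), n_folds),
              class = "strsa_bad_arg")
      }
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

#' Cross-validated linear SVM decoding of one feature layer
#'
#' Trains a linear multi-class support vector machine (libsvm) on
#' exemplar-level activations with stratified n-fold cross-validation.
#' Features are standardized per dimension using training-fold statistics
#' only. The 95% confidence interval comes from the dispersion of fold
#' accuracies.
#'
#' @param bank A `feature_bank` (>= `n_folds` exemplars per category).
#' @param n_folds Folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param folds Optional precomputed fold vector (see [make_folds()]).
#' @param cost SVM regularization constant.
#' @return A `decoding_result` tibble row: `layer`, `accuracy`,
#'   `ci_lower`, `ci_upper`, `n_classes`, `chance`, plus a
#'   `fold_accuracies` list-column.
#' @export
decode_layer <- function(bank, n_folds = 5, seed = 1, folds = NULL, cost = 1) {
  stopifnot(inherits(bank, "feature_bank"))
  y <- factor(bank$labels, levels = bank$categories)
  folds <- folds %||% make_folds(bank$labels, n_folds, seed)
  acc <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    mu <- colMeans(bank$activations[tr, , drop = FALSE])
    s <- apply(bank$activations[tr, , drop = FALSE], 2, stats::sd)
    s[s < 1e-12] <- 1
    Xtr <- sweep(sweep(bank$activations[tr, , drop = FALSE], 2, mu), 2, s, "/")
    Xte <- sweep(sweep(bank$activations[!tr, , drop = FALSE], 2, mu), 2, s, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost, scale = FALSE)
    mean(stats::predict(fit, Xte) == y[!tr])
  }, numeric(1))
  m <- mean(acc)
  half <- qt(0.975, n_folds - 1) * stats::sd(acc) / sqrt(n_folds)
  out <- tibble(
    layer = bank$layer_id, accuracy = m,
    ci_lower = max(0, m - half), ci_upper = min(1, m + half),
    n_classes = length(bank$categories), chance = 1 / length(bank$categories),
    fold_accuracies = list(acc)
  )
  structure(out, class = c("decoding_result", class(tibble())))
}

#' Decode every layer with a shared fold assignment
#'
#' @param banks List of `feature_bank` objects sharing exemplar labels.
#' @param n_folds,seed,cost As in [decode_layer()].
#' @return A `decoding_result` tibble, one row per layer.
#' @export
decode_all_layers <- function(banks, n_folds = 5, seed = 1, cost = 1) {
  lab0 <- banks[[1]]$labels
  for (b in banks) {
    if (!identical(b$labels, lab0)) {
      abort("banks do not share exemplar labels.", class = "strsa_bad_arg")
    }
  }
  folds <- make_folds(lab0, n_folds, seed)
  out <- bind_rows(lapply(banks, decode_layer, n_folds = n_folds, seed = seed,
                          folds = folds, cost = cost))
  structure(out, class = c("decoding_result", class(tibble())), folds = folds)
}

#' @export
glance.decoding_result <- function(x, ...) {
  tibble(n_layers = nrow(x), min_accuracy = min(x$accuracy),
         max_accuracy = max(x$accuracy), chance = x$chance[1])
}

#' @export
tidy.decoding_result <- function(x, ...) {
  tidyr::unnest_longer(as_tibble(x), "fold_accuracies", values_to = "fold_accuracy") |>
    group_by(.data$layer) |>
    mutate(fold = dplyr::row_number()) |>
    ungroup() |>
    select("layer", "fold", "fold_accuracy", "accuracy", "n_classes", "chance")
}

#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- as_tibble(object)
  df$layer <- factor(df$layer, levels = unique(df$layer))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                           width = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$chance), linetype = 2) +
    ggplot2::labs(y = "decoding accuracy", x = NULL,
                  title = "Category decoding per layer") +
    ggplot2::theme_minimal()
}
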