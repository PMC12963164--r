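#' Train the before/after-draping classifier
#'
#' Fits a support vector machine with a radial-basis (RBF) kernel on the four
#' entry-normalized color features (`dR`, `dG`, `dB`, `dCyan`), with default
#' regularization `cost = 1` and the variance-adaptive kernel width
#' `gamma = 1 / (n_features * Var(X))` (the "scale" rule, the default of the
#' scikit-learn SVC the original system was configured with; `e1071`'s own
#' default `1/n_features` is not variance-adaptive and degenerates on
#' unscaled color deltas). Defaults drift across library releases, so the
#' library version and effective parameters are recorded in the model
#' metadata. No feature scaling is applied beyond the entry normalization
#' unless `standardize = TRUE`.
#'
#' @param features Data frame or matrix with columns `dR`, `dG`, `dB`,
#'   `dCyan` (a `label` column is used when `labels` is missing).
#' @param labels Vector of `"before"` / `"after"` labels, one per row.
#' @param standardize Standardize features inside the SVM (default `FALSE`).
#' @param ... Passed on to [e1071::svm()] (e.g. `cost`, `gamma`).
#' @return A `drape_classifier` object with elements `svm`, `feature_names`
#'   and `metadata`.
#' @export
train_drape_classifier <- function(features, labels = NULL,
                                   standardize = FALSE, ...) {
  if (is.null(labels)) {
    if (is.null(features$label)) stop_input("labels are required")
    labels <- features$label
  }
  x <- as.matrix(as.data.frame(features)[, c("dR", "dG", "dB", "dCyan")])
  if (nrow(x) != length(labels)) stop_input("features and labels differ in length")
  if (any(!is.finite(x))) stop_input("features contain non-finite values")
  y <- factor(labels, levels = c("before", "after"))
  if (any(is.na(y))) stop_input("labels must be 'before' or 'after'")
  if (nlevels(droplevels(y)) < 2) {
    stop(errorCondition("training data must contain both classes",
                        class = c("drape_training_error", "error", "condition")))
  }
  dots <- list(...)
  if (is.null(dots$gamma)) {
    # scikit-learn's 'scale' default: 1 / (n_features * population variance)
    v <- mean((x - mean(x))^2)
    dots$gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  fit <- do.call(e1071::svm,
                 c(list(x = x, y = y, kernel = "radial", scale = standardize),
                   dots))
  structure(list(
    svm = fit,
    feature_names = colnames(x),
    metadata = list(
      library = "e1071",
      library_version = as.character(utils::packageVersion("e1071")),
      kernel = "radial",
      cost = fit$cost,
      gamma = fit$gamma,
      gamma_rule = if (is.null(list(...)$gamma)) "scale" else "user",
      standardize = standardize,
      n_before = sum(y == "before"),
      n_after = sum(y == "after")
    )
  ), class = "drape_classifier")
}

#' Classify samples as before or after draping
#'
#' Per-sample, order-preserving prediction. `model` is normally a
#' [train_drape_classifier()] fit; a plain function
#' `features -> labels` is also accepted, which makes it easy to plug in
#' oracle or threshold classifiers.
#'
#' @param model A `drape_classifier` or a function.
#' @param features Data frame with columns `dR`, `dG`, `dB`, `dCyan`.
#' @return Factor of `"before"` / `"after"`, one per row.
#' @export
classify_samples <- function(model, features) {
  UseMethod("classify_samples")
}

#' @export
classify_samples.drape_classifier <- function(model, features) {
  if (nrow(features) == 0) {
    return(factor(character(0), levels = c("before", "after")))
  }
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) {
    stop_input(paste("features lack columns:", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(features)[, model$feature_names])
  if (any(!is.finite(x))) stop_input("features contain non-finite values")
  factor(as.character(stats::predict(model$svm, x)),
         levels = c("before", "after"))
}

#' @export
classify_samples.function <- function(model, features) {
  factor(as.character(model(features)), levels = c("before", "after"))
}

#' @export
predict.drape_classifier <- function(object, newdata, ...) {
  classify_samples(object, newdata)
}

#' @export
print.drape_classifier <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<drape_classifier: RBF SVM (%s %s), cost=%g gamma=%g, trained on %d before / %d after>\n",
    md$library, md$library_version, md$cost, md$gamma, md$n_before, md$n_after))
  invisible(x)
}

#' Persist and restore a trained classifier
#'
#' The model is written as a single RDS archive with a JSON metadata sidecar
#' (`<path>.json`) describing the training configuration. Reloading restores
#' bit-identical predictions.
#'
#' @param model A `drape_classifier`.
#' @param path Destination file.
#' @return `load_drape_classifier()` returns the model;
#'   `save_drape_classifier()` returns `path` invisibly.
#' @export
save_drape_classifier <- function(model, path) {
  if (!inherits(model, "drape_classifier")) stop_input("not a drape_classifier")
  saveRDS(model, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(model$metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_drape_classifier
#' @export
load_drape_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "drape_classifier")) stop_input("not a drape_classifier archive")
  model
}

#' Assemble a labeled training set from annotated cases
#'
#' Labels the normalized feature samples of each case by its annotated
#' draping onset: samples earlier than `onset - margin` become `"before"`,
#' samples later than `onset + margin` become `"after"`, and samples inside
#' the ambiguous transition margin are excluded. Because most of a case
#' precedes draping, the majority class is optionally downsampled per case to
#' balance the classes.
#'
#' @param feature_list List of normalized-feature data frames (one per case,
#'   columns `t`, `dR`, `dG`, `dB`, `dCyan`; `t` in seconds since entry).
#' @param onsets Annotated draping onsets, seconds since entry, one per case.
#' @param margin Ambiguity margin around the onset, seconds (default 10).
#' @param balance Downsample the majority class within each case.
#' @param seed Seed for the downsampling draw.
#' @return Data frame of labeled features with a `label` column.
#' @export
assemble_training_set <- function(feature_list, onsets, margin = 10,
                                  balance = TRUE, seed = 1L) {
  if (length(feature_list) != length(onsets)) {
    stop_input("one onset per feature table is required")
  }
  with_seed(seed, {
    parts <- lapply(seq_along(feature_list), function(i) {
      f <- feature_list[[i]]
      lab <- ifelse(f$t < onsets[[i]] - margin, "before",
                    ifelse(f$t > onsets[[i]] + margin, "after", NA))
      f <- f[!is.na(lab), , drop = FALSE]
      f$label <- lab[!is.na(lab)]
      if (balance && nrow(f) > 0) {
        n_min <- min(table(factor(f$label, levels = c("before", "after"))))
        if (n_min > 0) {
          keep <- unlist(lapply(c("before", "after"), function(cl) {
            idx <- which(f$label == cl)
            if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
          }))
          f <- f[sort(keep), , drop = FALSE]
        }
      }
      f
    })
    do.call(rbind, parts)
  })
}
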