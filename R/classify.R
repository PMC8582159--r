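#' Specify a classifier for AD-vs-CN evaluation
#'
#' @param model_family `"svm"` or `"logistic"`.
#' @param kernel SVM kernel: `"quadratic"` (degree-2 polynomial, the
#'   default), `"linear"`, or `"coarse_gaussian"` (RBF with a wide scale).
#' @param feature_set which feature columns to use; see [feature_columns()].
#' @param n_folds cross-validation folds (default 20).
#' @param seed fold-assignment seed.
#' @param standardise standardise features to zero mean / unit SD on each
#'   training split (voxel counts and SUVr live on very different scales).
#' @param regularisation SVM cost parameter C.
#' @param gaussian_scale kernel scale for `"coarse_gaussian"`.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(model_family = c("svm", "logistic"),
                            kernel = c("quadratic", "linear", "coarse_gaussian"),
                            feature_set = "six_features",
                            n_folds = 20L, seed = 1L, standardise = TRUE,
                            regularisation = 1.0, gaussian_scale = 4.0) {
  model_family <- match.arg(model_family)
  kernel <- match.arg(kernel)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (regularisation <= 0) stop("regularisation must be > 0")
  structure(list(model_family = model_family, kernel = kernel,
                 feature_set = match.arg(feature_set,
                                         c("six_features", "clusters_1_4",
                                           "composite_suvr", "gm_two")),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 standardise = isTRUE(standardise),
                 regularisation = regularisation,
                 gaussian_scale = gaussian_scale),
            class = "classifier_spec")
}

# Stratified fold assignment: each class's shuffled subjects are dealt
# round-robin, so every training fold keeps both classes.
make_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Fit on training rows, return decision scores for test rows
# (positive score <=> AD).
fit_and_score <- function(x_train, y_train, x_test, spec) {
  if (spec$standardise) {
    mu <- colMeans(x_train)
    sd <- apply(x_train, 2L, stats::sd)
    sd[sd == 0] <- 1
    x_train <- sweep(sweep(x_train, 2L, mu), 2L, sd, "/")
    x_test <- sweep(sweep(x_test, 2L, mu), 2L, sd, "/")
  }
  if (spec$model_family == "logistic") {
    df_train <- as.data.frame(x_train)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = cbind(df_train, y = as.integer(y_train == "AD")),
                 family = stats::binomial()))
    scores <- as.numeric(
      suppressWarnings(stats::predict(fit, newdata = as.data.frame(x_test),
                                      type = "link")))
  } else {
    kern <- switch(spec$kernel,
                   quadratic = list(kernel = "polynomial", degree = 2,
                                    coef0 = 1, gamma = 1 / ncol(x_train)),
                   linear = list(kernel = "linear"),
                   coarse_gaussian = list(kernel = "radial",
                                          gamma = 1 / (spec$gaussian_scale^2 *
                                                         ncol(x_train))))
    fit <- do.call(e1071::svm,
                   c(list(x = x_train, y = factor(y_train, c("CN", "AD")),
                          cost = spec$regularisation, scale = FALSE,
                          probability = FALSE), kern))
    pred <- stats::predict(fit, x_test, decision.values = TRUE)
    scores <- as.numeric(attr(pred, "decision.values"))
    # libsvm orients the decision value towards its first training label
    if (colnames(attr(pred, "decision.values"))[1L] == "CN/AD") scores <- -scores
  }
  scores
}

#' Area under the ROC curve
#'
#' AUC = (concordant pairs + 0.5 x tied pairs) / (n_pos x n_neg), computed
#' via midranks (equivalent to the Mann-Whitney statistic).
#'
#' @param scores numeric decision values (higher = more AD-like).
#' @param labels binary labels: logical/0-1, or a vector in which `"AD"`
#'   marks positives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) labels == "AD"
  else as.logical(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the observed scores and reports one
#' (FPR, TPR) point per distinct threshold.
#'
#' @inheritParams roc_auc
#' @return Data frame `threshold`, `fpr`, `tpr`, from (1, 1) to (0, 0).
#' @export
roc_points <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) labels == "AD"
  else as.logical(labels)
  th <- c(-Inf, sort(unique(scores)))
  data.frame(threshold = th,
             fpr = vapply(th, function(t) mean(scores[!pos] > t), 0),
             tpr = vapply(th, function(t) mean(scores[pos] > t), 0))
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return List `sensitivity` = TP/(TP+FN), `specificity` = TN/(TN+FP),
#'   `accuracy` = (TP+TN)/n, `error_rate` = 1 - accuracy. Cells with a zero
#'   denominator are `NA` (undefined), never 0.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("all confusion counts are zero")
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / n,
       error_rate = 1 - (tp + tn) / n)
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified seeded k-fold cross-validation on the AD and CN rows of a
#' feature table: per fold, features are standardised on the training split
#' only, the specified model is fitted, and held-out subjects are scored.
#' Pooled out-of-fold scores drive the AUC; the confusion matrix is taken at
#' the model's native decision boundary (SVM score 0 / logistic probability
#' 0.5).
#'
#' @param features feature table from [build_feature_table()] (rows with
#'   groups other than AD/CN are dropped).
#' @param spec a [classifier_spec()].
#' @return A `cv_report` list: `confusion` (tp/fp/tn/fn), the four
#'   [confusion_metrics()], `auc`, `n`, `scores`, `labels`, `folds`, `spec`.
#' @export
cross_validate <- function(features, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  dat <- features[features$group %in% c("AD", "CN"), , drop = FALSE]
  if (length(unique(dat$group)) < 2L)
    stop("need both AD and CN subjects; found only ", paste(unique(dat$group)))
  if (min(table(dat$group)) < 2L) stop("need at least 2 subjects per class")
  x <- as.matrix(dat[, feature_columns(spec$feature_set), drop = FALSE])
  y <- dat$group
  n_folds <- spec$n_folds
  if (n_folds > nrow(dat)) {
    warning("reducing folds to the number of subjects")
    n_folds <- nrow(dat)
  }
  folds <- make_folds(y, n_folds, spec$seed)
  scores <- numeric(nrow(dat))
  for (f in sort(unique(folds))) {
    test <- folds == f
    if (length(unique(y[!test])) < 2L)
      stop("a training fold lost one class; reduce n_folds")
    scores[test] <- fit_and_score(x[!test, , drop = FALSE], y[!test],
                                  x[test, , drop = FALSE], spec)
  }
  pred_ad <- scores > 0
  is_ad <- y == "AD"
  tp <- sum(pred_ad & is_ad); fp <- sum(pred_ad & !is_ad)
  tn <- sum(!pred_ad & !is_ad); fn <- sum(!pred_ad & is_ad)
  structure(c(list(confusion = list(tp = tp, fp = fp, tn = tn, fn = fn)),
              confusion_metrics(tp, fp, tn, fn),
              list(auc = roc_auc(scores, is_ad), n = nrow(dat),
                   scores = scores, labels = y, folds = folds, spec = spec)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %s/%s on %s: n = %d, accuracy %.3f, ",
                     "sens %.3f, spec %.3f, AUC %.3f, error %.3f\n"),
              x$spec$model_family,
              if (x$spec$model_family == "svm") x$spec$kernel else "-",
              x$spec$feature_set, x$n, x$accuracy, x$sensitivity,
              x$specificity, x$auc))
  invisible(x)
}

#' Default comparison: the four evaluated methods
#'
#' Quadratic SVM on all six features; quadratic SVM on the four cluster
#' counts; logistic regression on composite SUVr alone; logistic regression
#' on the two grey-matter features.
#'
#' @param n_folds,seed shared cross-validation settings.
#' @return Named list of [classifier_spec()] objects.
#' @export
default_method_specs <- function(n_folds = 20L, seed = 1L) {
  list(
    six_features = classifier_spec("svm", "quadratic", "six_features",
                                   n_folds = n_folds, seed = seed),
    clusters_1_4 = classifier_spec("svm", "quadratic", "clusters_1_4",
                                   n_folds = n_folds, seed = seed),
    composite_suvr = classifier_spec("logistic", feature_set = "composite_suvr",
                                     n_folds = n_folds, seed = seed),
    gm_two = classifier_spec("logistic", feature_set = "gm_two",
                             n_folds = n_folds, seed = seed))
}

#' Compare classifiers over shared cross-validation folds
#'
#' Evaluates each specification with [cross_validate()] under one shared
#' seed (identical fold assignment, enabling paired comparison), and
#' tabulates metrics, percentage changes relative to the first
#' (six-feature) method, and ROC curve points.
#'
#' @param features feature table restricted internally to AD/CN rows.
#' @param specs named list of [classifier_spec()]s; default
#'   [default_method_specs()].
#' @param seed shared fold seed (overrides each spec's seed).
#' @return List: `reports` (per method `cv_report`), `metrics` (data
#'   frame), `pct_change` (sensitivity/specificity/AUC change in percent
#'   versus the reference method), `roc` (per-method curve points).
#' @export
compare_feature_sets <- function(features, specs = default_method_specs(),
                                 seed = 1L) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs)) || any(names(specs) == ""))
    stop("specs must be a named list")
  reports <- lapply(specs, function(sp) {
    sp$seed <- as.integer(seed)
    cross_validate(features, sp)
  })
  metrics <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm, features = length(feature_columns(r$spec$feature_set)),
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy, auc = r$auc, error_rate = r$error_rate,
               stringsAsFactors = FALSE)
  }))
  ref <- reports[[1L]]
  pct <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm,
               sensitivity = 100 * (r$sensitivity - ref$sensitivity) / ref$sensitivity,
               specificity = 100 * (r$specificity - ref$specificity) / ref$specificity,
               auc = 100 * (r$auc - ref$auc) / ref$auc,
               stringsAsFactors = FALSE)
  }))
  roc <- lapply(reports, function(r) roc_points(r$scores, r$labels))
  list(reports = reports, metrics = metrics, pct_change = pct, roc = roc)
}
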