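# Canonical class order for a 3-class imagery problem: (vi_low, rest,
# vi_high); anything else falls back to sorted unique labels.
.class_order <- function(labels) {
  u <- unique(labels)
  vi <- grepl("^vi_", u)
  if ("rest" %in% u && sum(vi) == length(u) - 1L) {
    f <- sort(as.numeric(sub("^vi_", "", u[vi])))
    c(paste0("vi_", f[1]), "rest", paste0("vi_", if (length(f) > 1) f[2] else f[1]))
  } else sort(u)
}

#' Fit the 3-class linear SVM decoder
#'
#' Features are standardized per column (z-score with mean and scale
#' estimated from the training rows only; zero-variance columns get
#' scale 1), then one linear-kernel support vector machine with C = 1 is
#' fitted per class one-vs-rest; prediction takes the class with the
#' largest decision value, ties resolving to the earlier class in the
#' fixed order (low frequency, rest, high frequency).
#'
#' @param features A `feature_matrix`.
#' @param rows Optional integer/logical subset of training rows.
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `vi_svm` with the per-class machines,
#'   standardization parameters, class order and training recording ids.
#' @export
vi_svm <- function(features, rows = NULL, cost = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(rows)) rows <- seq_len(nrow(features$x))
  x <- features$x[rows, , drop = FALSE]
  y <- features$labels[rows]
  if (length(unique(y)) < 2L) stop("training set holds a single class")
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  xs <- scale(x, center = mu, scale = sigma)
  classes <- .class_order(y)
  machines <- lapply(classes, function(k) {
    yk <- factor(ifelse(y == k, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(xs, yk, kernel = "linear", cost = cost,
                      scale = FALSE, fitted = FALSE)
    dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
               "decision.values")[, 1]
    # libsvm's decision-value sign depends on label encounter order;
    # normalize so positive means "this class".
    flip <- mean(dv[y == k]) < mean(dv[y != k])
    list(fit = fit, flip = flip)
  })
  structure(list(machines = machines, classes = classes, mu = mu,
                 sigma = sigma, cost = cost,
                 training_recordings = unique(features$recording_id[rows])),
            class = "vi_svm")
}

#' @export
print.vi_svm <- function(x, ...) {
  cat(sprintf("<vi_svm> linear SVM, C = %g, one-vs-rest over (%s)\n",
              x$cost, paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d features; trained on recordings: %s\n", length(x$mu),
              paste(x$training_recordings, collapse = ", ")))
  invisible(x)
}

# Decision-value matrix (trials x classes) on new data.
.decision_values <- function(model, x) {
  xs <- scale(x, center = model$mu, scale = model$sigma)
  dv <- vapply(model$machines, function(m) {
    d <- attr(stats::predict(m$fit, xs, decision.values = TRUE),
              "decision.values")[, 1]
    if (m$flip) -d else d
  }, numeric(nrow(xs)))
  matrix(dv, nrow = nrow(xs), dimnames = list(NULL, model$classes))
}

#' @export
predict.vi_svm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  if (ncol(x) != length(object$mu)) stop("feature columns do not match the model")
  dv <- .decision_values(object, x)
  object$classes[apply(dv, 1, which.max)]
}

#' Evaluate a decoder on a feature matrix
#'
#' @param model A fitted [vi_svm()].
#' @param features A `feature_matrix` with matching columns.
#' @return List with `accuracy` (percent correct) and `confusion`
#'   (square matrix, rows = true class, columns = predicted, in the
#'   model's class order).
#' @export
evaluate <- function(model, features) {
  stopifnot(inherits(model, "vi_svm"), inherits(features, "feature_matrix"))
  pred <- predict(model, features)
  truth <- factor(features$labels, levels = model$classes)
  if (anyNA(truth)) stop("labels outside the model's classes")
  pred <- factor(pred, levels = model$classes)
  conf <- table(truth, pred, dnn = c("true", "predicted"))
  conf <- unclass(conf)
  list(accuracy = 100 * sum(diag(conf)) / sum(conf), confusion = conf)
}

#' Temporal 5-fold cross-validation over ten recordings
#'
#' The ten chronologically ordered offline recordings are grouped into
#' five consecutive pairs; in fold i the i-th pair is the test set and
#' the remaining eight recordings train the decoder, so every recording
#' is tested exactly once and folds respect recording chronology.
#'
#' @param blocks List of exactly 10 `feature_matrix` objects in
#'   chronological order, one per recording.
#' @param cost SVM regularization constant passed to [vi_svm()].
#' @return An object of class `vi_cv`: per-fold test recording ids,
#'   accuracies (%), confusion matrices and fitted models; plus
#'   `mean_accuracy`, `sd_accuracy` (population SD over folds) and
#'   `best_fold` (highest accuracy, earliest on ties).
#' @export
temporal_cv <- function(blocks, cost = 1) {
  if (length(blocks) != 10L)
    stop("temporal cross-validation expects exactly 10 recordings")
  folds <- lapply(1:5, function(i) c(2L * i - 1L, 2L * i))
  fold_res <- lapply(seq_along(folds), function(i) {
    test_i <- folds[[i]]
    train <- .rbind_features(blocks[-test_i])
    test <- .rbind_features(blocks[test_i])
    model <- vi_svm(train, cost = cost)
    ev <- evaluate(model, test)
    list(test_recordings = unique(test$recording_id),
         accuracy = ev$accuracy, confusion = ev$confusion, model = model)
  })
  acc <- vapply(fold_res, `[[`, numeric(1), "accuracy")
  structure(list(folds = fold_res, accuracy = acc,
                 mean_accuracy = mean(acc),
                 sd_accuracy = sqrt(mean((acc - mean(acc))^2)),
                 best_fold = which.max(acc)),
            class = "vi_cv")
}

#' @export
print.vi_cv <- function(x, ...) {
  cat(sprintf("<vi_cv> 5-fold temporal CV: mean %.2f%% (sd %.2f), best fold %d\n",
              x$mean_accuracy, x$sd_accuracy, x$best_fold))
  cat("  fold accuracies (%):", paste(sprintf("%.2f", x$accuracy),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.vi_cv <- function(object, ...) {
  df <- data.frame(fold = seq_along(object$accuracy),
                   accuracy = object$accuracy,
                   test = vapply(object$folds, function(f)
                     paste(f$test_recordings, collapse = "+"), character(1)))
  cat(sprintf("5-fold temporal cross-validation: mean accuracy %.2f%% (population SD %.2f)\n",
              object$mean_accuracy, object$sd_accuracy))
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
plot.vi_cv <- function(x, ...) {
  graphics::barplot(x$accuracy, names.arg = seq_along(x$accuracy),
                    xlab = "fold", ylab = "accuracy (%)", ylim = c(0, 100),
                    ...)
  graphics::abline(h = 100 / 3, lty = 2)
  invisible(x)
}

#' Pick the decoder deployed online
#'
#' Returns the model of the cross-validation fold with the highest
#' accuracy (earliest fold on ties), the rule used to choose the
#' classifier replayed against the online session.
#'
#' @param cv A [temporal_cv()] result.
#' @return The selected `vi_svm` model.
#' @export
select_online_model <- function(cv) {
  stopifnot(inherits(cv, "vi_cv"))
  cv$folds[[cv$best_fold]]$model
}
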