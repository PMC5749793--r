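#' Labeled per-subject feature sets for supervised sleep staging
#'
#' @param features list of epochs x channels feature matrices, one per
#'   subject; all with identical channel order.
#' @param stages list of per-epoch stage label vectors (W, N1, N2, N3, R),
#'   aligned to the feature rows.
#' @param subjects subject identifiers.
#' @return An object of class `labeled_feature_set`.
#' @export
labeled_feature_set <- function(features, stages, subjects = NULL) {
  assert_that(length(features) == length(stages),
              "one stage vector per feature matrix is required")
  subjects <- subjects %||% sprintf("S%02d", seq_along(features))
  channels <- colnames(features[[1]])
  for (i in seq_along(features)) {
    assert_that(identical(colnames(features[[i]]), channels),
                "all subjects must share one channel order")
    assert_that(nrow(features[[i]]) == length(stages[[i]]),
                "labels must align to epochs for subject ", subjects[i])
    bad <- setdiff(unique(stages[[i]]), STAGE_LEVELS)
    assert_that(length(bad) == 0, "unknown stage label(s): ",
                paste(bad, collapse = ", "))
  }
  structure(list(features = features, stages = stages, subjects = subjects,
                 channels = channels),
            class = "labeled_feature_set")
}

pool_epochs <- function(data, exclude = NULL) {
  keep <- setdiff(seq_along(data$subjects), exclude)
  x <- do.call(rbind, data$features[keep])
  y <- factor(unlist(data$stages[keep]), levels = STAGE_LEVELS)
  list(x = x, y = droplevels(y))
}

#' Weighted and per-class F1 from labels
#'
#' Per-class F1 combines precision (true positives over all epochs predicted
#' as the class) and recall (true positives over all epochs of the class);
#' the weighted average uses class support as weights, which is the
#' appropriate summary for the imbalanced stage distribution of real sleep.
#'
#' @param truth,pred vectors of labels.
#' @param levels label space (default union of both).
#' @return List with `weighted`, `per_class`, `support` and the `confusion`
#'   matrix (truth in rows).
#' @export
weighted_f1 <- function(truth, pred, levels = NULL) {
  levels <- levels %||% sort(union(unique(truth), unique(pred)))
  cm <- table(factor(truth, levels), factor(pred, levels))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm) / sum(cm)
  list(weighted = sum(support * f1), per_class = stats::setNames(f1, levels),
       support = support, confusion = cm)
}

default_grid <- function(kind) {
  switch(kind,
         random_forest = data.frame(mtry = c(2, 4, 8)),
         feedforward_net = expand.grid(size = c(16, 32), decay = c(0, 0.1)))
}

fit_one <- function(kind, x, y, hp, seed, ntree) {
  with_preserved_seed(seed, {
    if (kind == "random_forest") {
      randomForest::randomForest(x = x, y = y,
                                 mtry = min(hp$mtry, ncol(x)), ntree = ntree)
    } else {
      nnet::nnet(x = x, y = nnet::class.ind(y), size = hp$size,
                 decay = hp$decay, softmax = TRUE, maxit = 200,
                 MaxNWts = 10000, trace = FALSE)
    }
  })
}

predict_one <- function(kind, model, x, levels) {
  if (kind == "random_forest") {
    as.character(predict(model, x))
  } else {
    pr <- predict(model, x)
    colnames(pr)[max.col(pr, ties.method = "first")]
  }
}

#' Train a five-class sleep-stage classifier with inner grid search
#'
#' Hyperparameters are chosen by 10-fold cross-validation on the training
#' epochs, optimizing weighted F1 (one grid point skips the search); the
#' winning point is refit on all training data. Deterministic given `seed`.
#'
#' @param data a `labeled_feature_set` (or list(x =, y =) of pooled epochs).
#' @param kind "random_forest" or "feedforward_net".
#' @param grid data frame of candidate hyperparameters (default:
#'   `mtry` in \{2,4,8\} for the forest; width \{16,32\} x decay \{0,0.1\}
#'   for the single-hidden-layer net).
#' @param seed integer seed.
#' @param ntree number of trees (forest; fixed, not searched).
#' @param inner_folds folds for the inner search (default 10).
#' @return A `stage_classifier` carrying the fitted model, chosen
#'   hyperparameters, fixed channel order and seed.
#' @export
train_stage_classifier <- function(data, kind = c("random_forest", "feedforward_net"),
                                   grid = NULL, seed = 1L, ntree = 500,
                                   inner_folds = 10) {
  kind <- match.arg(kind)
  pooled <- if (inherits(data, "labeled_feature_set")) pool_epochs(data) else data
  x <- pooled$x; y <- droplevels(factor(pooled$y, levels = STAGE_LEVELS))
  assert_that(nlevels(y) >= 2, "training data must contain at least two classes")
  grid <- grid %||% default_grid(kind)
  assert_that(is.data.frame(grid) && nrow(grid) >= 1, "empty hyperparameter grid")
  cv_scores <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    folds <- with_preserved_seed(derive_seed(seed, 101L),
                                 sample(rep(seq_len(inner_folds), length.out = nrow(x))))
    for (g in seq_len(nrow(grid))) {
      pred <- character(nrow(x))
      for (f in seq_len(inner_folds)) {
        tr <- folds != f
        fit <- fit_one(kind, x[tr, , drop = FALSE], droplevels(y[tr]),
                       grid[g, , drop = FALSE], derive_seed(seed, 200L + f), ntree)
        pred[!tr] <- predict_one(kind, fit, x[!tr, , drop = FALSE], levels(y))
      }
      cv_scores[g] <- weighted_f1(as.character(y), pred, levels(y))$weighted
    }
  }
  best <- if (nrow(grid) == 1) 1L else which.max(cv_scores)
  model <- fit_one(kind, x, y, grid[best, , drop = FALSE],
                   derive_seed(seed, 999L), ntree)
  structure(list(kind = kind, model = model,
                 hyperparameters = as.list(grid[best, , drop = FALSE]),
                 cv_scores = cv_scores, grid = grid,
                 channels = colnames(x), levels = levels(y),
                 ntree = if (kind == "random_forest") ntree else NULL,
                 seed = as.integer(seed)),
            class = "stage_classifier")
}

#' @export
print.stage_classifier <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("<stage_classifier> %s (%s); channels: %s\n", x$kind, hp,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Leave-one-subject-out evaluation of the stage classifier
#'
#' Each subject is scored once by a model trained (with its own inner grid
#' search) on the remaining subjects only, so its epochs never enter model
#' fitting or hyperparameter selection. The cohort summary uses median and
#' MAD (median absolute deviation, unscaled) across subjects.
#'
#' @inheritParams train_stage_classifier
#' @param cohort a `labeled_feature_set` with at least two subjects.
#' @param chance_reps Monte-Carlo repetitions for the per-fold dummy chance
#'   estimate.
#' @return A `cv_result`: per-subject weighted F1, per-class F1, chance
#'   level, winning hyperparameters, pooled channel importances (forest) and
#'   the median/MAD summary.
#' @export
loso_evaluate <- function(cohort, kind = c("random_forest", "feedforward_net"),
                          grid = NULL, seed = 1L, ntree = 500,
                          inner_folds = 10, chance_reps = 50) {
  kind <- match.arg(kind)
  ns <- length(cohort$subjects)
  assert_that(ns >= 2, "leave-one-subject-out needs at least two subjects")
  res <- vector("list", ns)
  for (i in seq_len(ns)) {
    train <- cohort
    train$features <- cohort$features[-i]
    train$stages <- cohort$stages[-i]
    train$subjects <- cohort$subjects[-i]
    clf <- train_stage_classifier(train, kind, grid, seed = derive_seed(seed, i),
                                  ntree = ntree, inner_folds = inner_folds)
    pred <- predict_hypnogram(clf, cohort$features[[i]])
    truth <- cohort$stages[[i]]
    sc <- weighted_f1(truth, pred, STAGE_LEVELS)
    ch <- chance_level(unlist(train$stages), truth,
                       seed = derive_seed(seed, 5000L + i), n_rep = chance_reps)
    res[[i]] <- list(subject = cohort$subjects[i], weighted_f1 = sc$weighted,
                     per_class_f1 = sc$per_class, chance_f1 = ch$mean,
                     chance_se = ch$se,
                     hyperparameters = clf$hyperparameters,
                     importance = if (kind == "random_forest")
                       feature_importance(clf) else NULL)
  }
  f1s <- vapply(res, `[[`, numeric(1), "weighted_f1")
  structure(list(folds = res, subjects = cohort$subjects, weighted_f1 = f1s,
                 median_f1 = stats::median(f1s),
                 mad_f1 = stats::mad(f1s, constant = 1),
                 chance_f1 = mean(vapply(res, `[[`, numeric(1), "chance_f1")),
                 kind = kind),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d subjects: median weighted F1 %.3f (MAD %.3f), chance %.3f\n",
              x$kind, length(x$subjects), x$median_f1, x$mad_f1, x$chance_f1))
  invisible(x)
}

#' Chance-level weighted F1 of a class-distribution dummy
#'
#' The dummy draws predictions from the training class proportions,
#' independent of the inputs; its expected per-class F1 equals the class
#' proportion, so the expected weighted F1 is the sum of squared proportions.
#' Estimated by Monte Carlo.
#'
#' @param train_stages training labels providing the class distribution.
#' @param test_stages labels to score against (default: the training labels).
#' @param seed integer seed.
#' @param n_rep repetitions.
#' @return List with `mean`, `sd`, `se` and the repetition values.
#' @export
chance_level <- function(train_stages, test_stages = train_stages, seed = 1L,
                         n_rep = 200) {
  p <- table(train_stages) / length(train_stages)
  lv <- names(p)
  vals <- with_preserved_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      pred <- sample(lv, length(test_stages), replace = TRUE, prob = p)
      weighted_f1(test_stages, pred, union(lv, unique(test_stages)))$weighted
    }, numeric(1))
  })
  list(mean = mean(vals), sd = stats::sd(vals),
       se = stats::sd(vals) / sqrt(n_rep), values = vals)
}

#' Per-channel importance of a fitted random forest stage classifier
#'
#' Mean decrease in Gini impurity per channel, normalized to sum to 1.
#'
#' @param model a `stage_classifier` of kind "random_forest".
#' @return Named non-negative vector over the model's channels, summing to 1.
#' @export
feature_importance <- function(model) {
  assert_that(inherits(model, "stage_classifier"),
              "model must be a stage_classifier")
  assert_that(model$kind == "random_forest",
              "feature importance is only defined for the random forest")
  imp <- model$model$importance[, "MeanDecreaseGini"]
  stats::setNames(as.numeric(imp / sum(imp)), model$channels)
}

#' Epoch-by-epoch stage prediction (hypnogram)
#'
#' One of the five stage labels per epoch, in temporal order, with no
#' temporal smoothing. The feature channel order must match the model's.
#'
#' @param model a `stage_classifier`.
#' @param features epochs x channels feature matrix.
#' @return Character vector of predicted stages, one per epoch.
#' @export
predict_hypnogram <- function(model, features) {
  assert_that(identical(colnames(features), model$channels),
              "channel order mismatch between features and model")
  predict_one(model$kind, model$model, features, model$levels)
}

#' Persist / restore a cv_result as JSON
#' @param cv a `cv_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cv_result <- function(cv, file) {
  jsonlite::write_json(
    list(kind = cv$kind, subjects = cv$subjects,
         weighted_f1 = cv$weighted_f1, median_f1 = cv$median_f1,
         mad_f1 = cv$mad_f1, chance_f1 = cv$chance_f1),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
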