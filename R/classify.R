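#' Stratified split of a labeled table into learning and test sets
#'
#' Splits a classified feature table into a learning set (default two-thirds
#' of the cells) and a test set from the remainder, stratified by class and
#' reproducible under the seed.
#'
#' @param labeled_table `data.frame` with a `class` column.
#' @param fraction learning-set fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `learn`, `test` (row subsets) and `assignment`
#'   (character vector "learn"/"test" per row).
#' @export
split_training <- function(labeled_table, fraction = 2 / 3, seed = 1L) {
  .assert("class" %in% names(labeled_table), "table must have a class column")
  .assert(fraction > 0 && fraction < 1, "fraction must be in (0, 1): both sets must be non-empty")
  cls <- as.character(labeled_table$class)
  tab <- table(cls)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    stop(
      "class(es) with fewer than 2 cells cannot be split: ",
      paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  assignment <- local_seed(seed, {
    a <- character(nrow(labeled_table))
    for (cl in names(tab)) {
      rows <- which(cls == cl)
      n_learn <- round(length(rows) * fraction)
      n_learn <- min(max(n_learn, 1L), length(rows) - 1L)
      learn <- sample(rows, n_learn)
      a[learn] <- "learn"
      a[setdiff(rows, learn)] <- "test"
    }
    a
  })
  list(
    learn = labeled_table[assignment == "learn", , drop = FALSE],
    test = labeled_table[assignment == "test", , drop = FALSE],
    assignment = assignment
  )
}

# z-score parameters fitted on a training block; zero-variance features get
# sd NA and are flagged
.fit_scaling <- function(data, features) {
  mu <- vapply(features, function(f) mean(data[[f]]), numeric(1))
  sd_ <- vapply(features, function(f) stats::sd(data[[f]]), numeric(1))
  sd_[!is.finite(sd_) | sd_ == 0] <- NA_real_
  list(mean = mu, sd = sd_)
}

.apply_scaling <- function(data, features, scaling) {
  out <- lapply(features, function(f) (data[[f]] - scaling$mean[[f]]) / scaling$sd[[f]])
  names(out) <- features
  as.data.frame(out)
}

#' V-fold (permuted reiteration) cross-validated SVM accuracy
#'
#' Performance assessment by `V` randomly permuted reiterations of
#' training/test splits: each fold draws a fresh stratified split, fits an
#' RBF-kernel C-classification SVM on the training portion (features
#' z-scored with parameters from that portion only) and scores accuracy on
#' the held-out portion. Features with zero variance in a fold's training
#' portion are dropped with a warning.
#'
#' @param data `data.frame` with a `class` column and feature columns.
#' @param features character vector of feature columns to use.
#' @param C SVM cost.
#' @param gamma RBF kernel width; default `1/length(features)`.
#' @param V number of reiterations.
#' @param fraction training fraction per fold.
#' @param seed integer seed.
#' @return list with `mean_acc`, `sd_acc`, `per_fold` (length `V`).
#' @export
crossval_svm <- function(data, features, C = 10, gamma = NULL, V = 5L,
                         fraction = 2 / 3, seed = 1L) {
  .assert(V >= 2, "V must be >= 2")
  .assert(
    all(features %in% names(data)),
    "all features must be columns of the data"
  )
  if (is.null(gamma)) gamma <- 1 / length(features)
  accs <- local_seed(seed, {
    vapply(seq_len(V), function(v) {
      sp <- split_training(data, fraction, seed = sample.int(.Machine$integer.max, 1))
      .svm_fold_accuracy(sp$learn, sp$test, features, C, gamma)
    }, numeric(1))
  })
  list(mean_acc = mean(accs), sd_acc = stats::sd(accs), per_fold = accs)
}

.svm_fold_accuracy <- function(learn, test, features, C, gamma) {
  scaling <- .fit_scaling(learn, features)
  ok <- features[!is.na(scaling$sd[features])]
  if (length(ok) < length(features)) {
    warning(
      "dropping zero-variance feature(s) in fold: ",
      paste(setdiff(features, ok), collapse = ", ")
    )
  }
  if (!length(ok)) {
    return(0)
  }
  xl <- .apply_scaling(learn, ok, scaling)
  xt <- .apply_scaling(test, ok, scaling)
  fit <- e1071::svm(
    x = as.matrix(xl), y = factor(learn$class),
    type = "C-classification", kernel = "radial",
    cost = C, gamma = gamma, scale = FALSE
  )
  mean(as.character(stats::predict(fit, as.matrix(xt))) == as.character(test$class))
}

#' Greedy forward feature selection by cross-validated SVM accuracy
#'
#' Starting from the empty set, each step adds the descriptor that maximizes
#' the V-fold cross-validated mean accuracy given the features already
#' chosen, producing the full selection path. The recommended set is chosen
#' lexicographically: among sets within `tol` of the best mean accuracy, the
#' smallest; ties broken by the lowest accuracy standard deviation, then by
#' path order.
#'
#' @param data `data.frame` with `class` and feature columns.
#' @param features candidate features (default the 16 descriptors).
#' @param max_k maximum subset size to explore.
#' @param C,gamma,V,fraction,seed as in [crossval_svm()] (`gamma` defaults
#'   to `1/k` for a k-feature subset).
#' @param tol accuracy tolerance for the minimal-size recommendation
#'   (default half a percentage point).
#' @return list with `path` (data.frame: `k`, `feature_added`, `mean_acc`,
#'   `sd_acc`), `feature_sets` (list of the k-subsets along the path) and
#'   `selected` (recommended feature set).
#' @export
greedy_feature_selection <- function(data, features = descriptor_names(),
                                     max_k = length(features), C = 10,
                                     gamma = NULL, V = 5L, fraction = 2 / 3,
                                     seed = 1L, tol = 0.005) {
  .assert(length(unique(data$class)) >= 2, "need at least 2 classes")
  features <- intersect(features, names(data))
  .assert(length(features) > 0, "no candidate features present in the data")
  max_k <- min(max_k, length(features))
  chosen <- character(0)
  path <- data.frame(
    k = integer(0), feature_added = character(0),
    mean_acc = numeric(0), sd_acc = numeric(0)
  )
  sets <- list()
  for (k in seq_len(max_k)) {
    cand <- setdiff(features, chosen)
    best <- NULL
    for (f in cand) { # fixed feature order makes ties deterministic
      cv <- suppressWarnings(crossval_svm(
        data, c(chosen, f),
        C = C,
        gamma = if (is.null(gamma)) 1 / k else gamma,
        V = V, fraction = fraction, seed = seed
      ))
      if (is.null(best) || cv$mean_acc > best$cv$mean_acc) {
        best <- list(f = f, cv = cv)
      }
    }
    chosen <- c(chosen, best$f)
    sets[[k]] <- chosen
    path <- rbind(path, data.frame(
      k = k, feature_added = best$f,
      mean_acc = best$cv$mean_acc, sd_acc = best$cv$sd_acc
    ))
  }
  ok <- which(path$mean_acc >= max(path$mean_acc) - tol)
  sel <- ok[order(path$k[ok], path$sd_acc[ok])][1]
  list(path = path, feature_sets = sets, selected = sets[[sel]])
}

#' Train an RBF-SVM cell-type classifier
#'
#' Tunes `(C, gamma)` on a small logarithmic grid by V-fold permuted
#' cross-validation, then fits the final C-classification SVM on all
#' training rows with features z-scored on the full training data. One
#' classifier is intended per genotype and time point.
#'
#' @param data `data.frame` with `class` and feature columns.
#' @param features feature subset to use (e.g. from
#'   [greedy_feature_selection()]).
#' @param C_grid,gamma_grid hyperparameter grids; `gamma_grid` defaults to
#'   `1/d * c(0.1, 1, 10)` for `d` features.
#' @param V,fraction,seed as in [crossval_svm()].
#' @param genotype,timepoint optional registry key metadata.
#' @return object of class `qh_classifier`: fitted model, `features`,
#'   `scaling`, `C`, `gamma`, `cv_record`, `classes`, key metadata.
#' @export
train_classifier <- function(data, features, C_grid = c(1, 10, 100),
                             gamma_grid = NULL, V = 5L, fraction = 2 / 3,
                             seed = 1L, genotype = NA_character_,
                             timepoint = NA_real_) {
  .assert(
    all(features %in% names(data)),
    "all features must be columns of the data"
  )
  if (is.null(gamma_grid)) gamma_grid <- c(0.1, 1, 10) / length(features)
  best <- NULL
  for (C in C_grid) {
    for (g in gamma_grid) {
      cv <- suppressWarnings(
        crossval_svm(data, features, C = C, gamma = g, V = V, fraction = fraction, seed = seed)
      )
      if (is.null(best) || cv$mean_acc > best$cv$mean_acc) {
        best <- list(C = C, gamma = g, cv = cv)
      }
    }
  }
  scaling <- .fit_scaling(data, features)
  .assert(!anyNA(scaling$sd[features]), "zero-variance feature in training data")
  x <- .apply_scaling(data, features, scaling)
  fit <- e1071::svm(
    x = as.matrix(x), y = factor(data$class),
    type = "C-classification", kernel = "radial",
    cost = best$C, gamma = best$gamma, scale = FALSE
  )
  structure(
    list(
      model = fit, features = features, scaling = scaling,
      C = best$C, gamma = best$gamma, cv_record = best$cv,
      classes = levels(factor(data$class)),
      genotype = genotype, timepoint = timepoint
    ),
    class = "qh_classifier"
  )
}

#' @export
print.qh_classifier <- function(x, ...) {
  cat(
    "qh_classifier:", length(x$features), "features, C =", x$C,
    ", gamma =", signif(x$gamma, 3),
    sprintf(
      ", CV accuracy %.3f +/- %.3f\n",
      x$cv_record$mean_acc, x$cv_record$sd_acc
    )
  )
  invisible(x)
}

#' Predict cell classes for a feature table
#'
#' Applies the classifier's stored normalization and SVM decision model and
#' appends a `class` column.
#'
#' @param classifier a `qh_classifier`.
#' @param table `feature_table` / `data.frame` holding the classifier's
#'   selected features.
#' @return the table with a `class` character column.
#' @export
predict_classes <- function(classifier, table) {
  .assert(inherits(classifier, "qh_classifier"), "not a qh_classifier")
  missing <- setdiff(classifier$features, names(table))
  if (length(missing)) {
    stop(
      "table lacks feature column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(table) == 0L) {
    table$class <- character(0)
    return(table)
  }
  x <- .apply_scaling(table, classifier$features, classifier$scaling)
  table$class <- as.character(stats::predict(classifier$model, as.matrix(x)))
  table
}

#' Per-class accuracy report and confusion matrix
#'
#' @param pred predicted classes (character/factor), aligned with `truth`.
#' @param truth true classes.
#' @return list with `confusion` (rows = truth), `per_class` (recall per
#'   true class), `overall` (fraction correct), `mean_acc`, `median_acc`
#'   (mean/median of per-class recalls), and `unseen_pred` (classes
#'   predicted but absent from the truth, flagged).
#' @export
accuracy_report <- function(pred, truth) {
  .assert(length(pred) == length(truth), "pred and truth must align")
  pred <- as.character(pred)
  truth <- as.character(truth)
  lev <- sort(unique(c(pred, truth)))
  conf <- table(
    truth = factor(truth, levels = lev),
    pred = factor(pred, levels = lev)
  )
  present <- rowSums(conf) > 0
  per_class <- diag(as.matrix(conf))[present] / rowSums(conf)[present]
  list(
    confusion = conf,
    per_class = per_class,
    overall = mean(pred == truth),
    mean_acc = mean(per_class),
    median_acc = stats::median(per_class),
    unseen_pred = setdiff(unique(pred), unique(truth))
  )
}

#' Persist / restore a trained classifier
#'
#' The classifier directory holds a human-readable `params.json` (features,
#' hyperparameters, normalization, class set, CV record, registry key) and
#' the fitted SVM model blob.
#'
#' @param classifier a `qh_classifier`.
#' @param dir directory to create/use.
#' @return `load_classifier` returns the `qh_classifier`.
#' @export
save_classifier <- function(classifier, dir) {
  .assert(inherits(classifier, "qh_classifier"), "not a qh_classifier")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- classifier[c(
    "features", "C", "gamma", "classes", "genotype",
    "timepoint"
  )]
  params$scaling <- lapply(classifier$scaling, as.list)
  params$cv_record <- classifier$cv_record
  jsonlite::write_json(params, file.path(dir, "params.json"),
    auto_unbox = TRUE, digits = NA
  )
  saveRDS(classifier$model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  p <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  structure(
    list(
      model = readRDS(file.path(dir, "model.rds")),
      features = p$features,
      scaling = list(
        mean = unlist(p$scaling$mean),
        sd = unlist(p$scaling$sd)
      ),
      C = p$C, gamma = p$gamma,
      cv_record = list(
        mean_acc = p$cv_record$mean_acc,
        sd_acc = p$cv_record$sd_acc,
        per_fold = p$cv_record$per_fold
      ),
      classes = p$classes, genotype = p$genotype, timepoint = p$timepoint
    ),
    class = "qh_classifier"
  )
}
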