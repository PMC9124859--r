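#' Stratified subject-level train/test split
#'
#' Randomly splits one subject's trials into train and test sets, stratified
#' by class: for each class, `round((1 - fraction) * n_class)` trials (at
#' least one) go to the test set. With the default 84 balanced trials and
#' `fraction = 0.9` this yields 76 train / 8 test (19/2 per class).
#'
#' @param labels per-trial class labels.
#' @param fraction training fraction (default 0.9); must leave a non-empty
#'   test set.
#' @param seed RNG seed; identical seeds give identical assignments.
#' @return object of class `split_plan`: list with `scheme`, `train`, `test`
#'   (integer trial indices), `seed`.
#' @export
subject_split <- function(labels, fraction = 0.9, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 10) stop("need at least 10 trials to split")
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1): an empty train or test set is not usable")
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2)
      stop(sprintf("class %s has fewer than 2 trials; cannot stratify", cl))
    n_test <- max(1L, round((1 - fraction) * length(idx)))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  structure(list(scheme = "subject", train = setdiff(seq_len(n), test),
                 test = test, seed = as.integer(seed)), class = "split_plan")
}

#' Group-level split: per-subject near-equal parts
#'
#' Within each subject, trials are shuffled and partitioned into `folds`
#' near-equal parts (sizes differing by at most one); one randomly chosen
#' part per subject forms that subject's test share. The pooled train and
#' test sets are then shuffled. With 84 trials and 10 folds the part sizes
#' are four 9s and six 8s.
#'
#' @param subject per-trial subject index.
#' @param folds number of parts (default 10).
#' @param seed RNG seed.
#' @return a `split_plan` (scheme `"group"`).
#' @export
group_split <- function(subject, folds = 10L, seed = 1L) {
  if (folds < 2) stop("folds must be at least 2")
  subject <- as.integer(as.factor(subject))
  set.seed(seed)
  train <- integer(0); test <- integer(0)
  for (s in unique(subject)) {
    idx <- which(subject == s)
    if (length(idx) < folds)
      stop(sprintf("subject %d has %d trials, fewer than folds = %d",
                   s, length(idx), folds))
    idx <- sample(idx)
    sizes <- rep(length(idx) %/% folds, folds) +
      (seq_len(folds) <= length(idx) %% folds)
    part <- rep(seq_len(folds), times = sizes)
    hold <- sample(folds, 1)
    test <- c(test, idx[part == hold])
    train <- c(train, idx[part != hold])
  }
  structure(list(scheme = "group", train = sample(train), test = sample(test),
                 seed = as.integer(seed)), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d train / %d test (seed %d)\n",
              x$scheme, length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Train and evaluate the four ablation variants
#'
#' Trains the full model and the three reduced variants (no spatial dropout,
#' no batch normalization, neither) on identical inputs, splits and seeds,
#' and reports the evaluation metrics for each.
#'
#' @param train_x,train_y,test_x,test_y assembled inputs and labels.
#' @param arch base [dualcnn_architecture] (the "full" variant; the others
#'   differ only in the dropout/batch-norm flags).
#' @param tcfg a [dualcnn_training].
#' @param classes class label set.
#' @return named list of four `metrics_report`s (`full`, `no_dropout`,
#'   `no_batchnorm`, `neither`), with the fitted models in
#'   `attr(, "models")`.
#' @export
run_ablation <- function(train_x, train_y, test_x, test_y,
                         arch = dualcnn_architecture(),
                         tcfg = dualcnn_training(), classes = mi_classes()) {
  if (length(unique(as.character(train_y))) < length(classes))
    stop("training set must contain every class")
  variants <- list(
    full = c(dropout = TRUE, bn = TRUE),
    no_dropout = c(dropout = FALSE, bn = TRUE),
    no_batchnorm = c(dropout = TRUE, bn = FALSE),
    neither = c(dropout = FALSE, bn = FALSE))
  reports <- list(); models <- list()
  for (nm in names(variants)) {
    a <- arch
    a$use_spatial_dropout <- variants[[nm]][["dropout"]]
    a$use_batchnorm <- variants[[nm]][["bn"]]
    model <- dualcnn_init(a, seed = tcfg$seed, classes = classes)
    model <- dualcnn_train(model, train_x, train_y, test_x, test_y, tcfg)
    reports[[nm]] <- compute_metrics(predict(model, test_x),
                                     test_y, classes)
    models[[nm]] <- model
  }
  attr(reports, "models") <- models
  reports
}
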