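#' Predict from a dual-CNN model
#'
#' Runs the evaluation-mode forward pass (running batch-norm statistics, no
#' dropout).
#'
#' @param object a `dualcnn`.
#' @param newdata an `mi_assembled`, a trials x 1280 x 9 array, or a single
#'   1280 x 9 matrix.
#' @param type `"prob"` for the class-probability matrix (trials x classes),
#'   `"class"` for predicted labels, `"features"` for the hemispheric
#'   difference feature matrix (trials x 800 for the default architecture).
#' @param batch forward-pass chunk size.
#' @param ... unused.
#' @return matrix of probabilities or features, or a character vector of
#'   labels.
#' @export
predict.dualcnn <- function(object, newdata, type = c("prob", "class", "features"),
                            batch = 256L, ...) {
  type <- match.arg(type)
  bm <- prepare_branch_matrices(newdata, object$arch)
  bm$XL <- (bm$XL - object$input_center) / object$input_scale
  bm$XR <- (bm$XR - object$input_center) / object$input_scale
  geom <- build_geometry(object$arch)
  probs <- matrix(0, bm$n, object$arch$n_classes,
                  dimnames = list(NULL, object$classes))
  feats <- NULL
  if (type == "features")
    feats <- matrix(0, bm$n, branch_flat_dim(object$arch))
  for (a in seq(1, bm$n, by = batch)) {
    b <- min(bm$n, a + batch - 1L)
    fw <- dualcnn_batch_forward(object, bm$XL[, a:b, drop = FALSE],
                                bm$XR[, a:b, drop = FALSE], geom,
                                training = FALSE)
    probs[a:b, ] <- t(fw$probs)
    if (type == "features") feats[a:b, ] <- t(fw$diff)
  }
  switch(type,
         prob = probs,
         class = object$classes[max.col(probs, ties.method = "first")],
         features = feats)
}

#' @export
print.dualcnn <- function(x, ...) {
  cat(sprintf("<dualcnn> %s-branch hemispheric-difference CNN (%s)\n",
              x$arch$weight_sharing,
              if (is.null(x$history)) "untrained" else
                sprintf("trained, %d iterations", nrow(x$history))))
  cat(sprintf("  branches: %s maps, kernels %s, pools %s; FC %d -> softmax %d (%s)\n",
              paste(x$arch$maps, collapse = "/"),
              paste(x$arch$kernel_t, collapse = "/"),
              paste(x$arch$pool_t, collapse = "/"),
              x$arch$fc_units, x$arch$n_classes,
              paste(x$classes, collapse = ",")))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train acc %.3f%s\n", last$train_acc,
                if (!is.na(last$test_acc))
                  sprintf(", test acc %.3f", last$test_acc) else ""))
  }
  invisible(x)
}

#' @export
summary.dualcnn <- function(object, ...) {
  cat("Hemispheric-difference dual-CNN\n\n")
  print(shape_propagate(object$arch), row.names = FALSE)
  npar <- sum(vapply(object$params, length, 0L))
  cat(sprintf("\nParameters: %d (%s branches, dropout %.2f%s, batchnorm %s)\n",
              npar, object$arch$weight_sharing, object$arch$dropout_rate,
              if (object$arch$use_spatial_dropout) " spatial" else "",
              if (object$arch$use_batchnorm) "on" else "off"))
  if (!is.null(object$history)) {
    last <- object$history[nrow(object$history), ]
    cat(sprintf("Training: %d iterations, final batch loss %.4f, train acc %.3f\n",
                nrow(object$history), last$train_loss, last$train_acc))
    if (!is.na(last$test_acc))
      cat(sprintf("Held-out: loss %.4f, accuracy %.3f\n",
                  last$test_loss, last$test_acc))
  }
  invisible(object)
}

#' @export
coef.dualcnn <- function(object, ...) object$params

#' Plot dual-CNN learning curves
#'
#' Train-batch and held-out loss and accuracy against the training iteration.
#'
#' @param x a trained `dualcnn`.
#' @param ... passed to [graphics::matplot].
#' @export
plot.dualcnn <- function(x, ...) {
  if (is.null(x$history)) stop("model is untrained: nothing to plot")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$iteration, cbind(h$train_loss, h$test_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "iteration", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train (batch)", "test"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::matplot(h$iteration, cbind(h$train_acc, h$test_acc), type = "l",
                    lty = 1, col = c("grey40", "firebrick"), ylim = c(0, 1),
                    xlab = "iteration", ylab = "accuracy", ...)
  invisible(x)
}

#' Simulate labels from a fitted dual-CNN
#'
#' Draws class labels from the model's predictive distribution for the given
#' inputs, one column per replicate.
#'
#' @param object a trained `dualcnn`.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param newdata inputs to predict on (required).
#' @param ... unused.
#' @return a data frame with `nsim` columns of sampled labels.
#' @export
simulate.dualcnn <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (is.null(newdata)) stop("newdata is required")
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata, type = "prob")
  out <- replicate(nsim, apply(p, 1, function(pr)
    sample(object$classes, 1, prob = pr)))
  as.data.frame(matrix(out, nrow(p), nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))),
                stringsAsFactors = FALSE)
}

#' Export training history as CSV
#'
#' @param model a trained `dualcnn`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(model, path) {
  if (is.null(model$history)) stop("model is untrained")
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
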