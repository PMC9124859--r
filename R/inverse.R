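#' Estimate the sensor noise covariance from baseline data
#'
#' Sample covariance of the concatenated, per-segment demeaned baseline
#' segments, stabilized by diagonal loading:
#' `C <- (1 - loading) * C + loading * mean(diag(C)) * I`.
#'
#' @param segments list of channels x samples matrices (e.g. from
#'   [baseline_segments]), or a single matrix.
#' @param loading diagonal-loading fraction in \[0, 1\] (default 0.1).
#' @return object of class `noise_covariance`: list with `matrix` (V^2),
#'   `loading`, `n_samples`.
#' @export
estimate_noise_covariance <- function(segments, loading = 0.1) {
  if (is.matrix(segments)) segments <- list(segments)
  if (!length(segments)) stop("empty baseline segment list")
  stopifnot(loading >= 0, loading <= 1)
  demeaned <- lapply(segments, function(s) s - rowMeans(s))
  X <- do.call(cbind, demeaned)
  n <- ncol(X)
  if (n < nrow(X)) {
    warning(sprintf(
      "only %d baseline samples for %d channels; covariance is rank deficient - consider heavier loading",
      n, nrow(X)))
  }
  C <- tcrossprod(X) / max(1L, n - 1L)
  C <- (C + t(C)) / 2
  C <- (1 - loading) * C + loading * mean(diag(C)) * diag(nrow(C))
  structure(list(matrix = C, loading = loading, n_samples = n),
            class = "noise_covariance")
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat(sprintf("<noise_covariance> %d x %d, loading %.2f, %d baseline samples\n",
              nrow(x$matrix), ncol(x$matrix), x$loading, x$n_samples))
  invisible(x)
}

#' Depth weights for the weighted minimum-norm inverse
#'
#' Standard leadfield-norm depth weighting: `weight_i = ||L[, i]||^gamma`.
#' Deep sources have smaller gain columns, hence smaller weights and larger
#' entries of the source prior `R_w = diag(weights)^-2`, compensating the
#' depth bias of the unweighted minimum-norm solution. `gamma = 0` recovers
#' plain MNE.
#'
#' @param L a [leadfield].
#' @param gamma depth-weighting exponent, >= 0 (default 0.5).
#' @return object of class `source_weighting`: list with `weights`, `gamma`.
#' @export
depth_weights <- function(L, gamma = 0.5) {
  stopifnot(gamma >= 0)
  cn <- sqrt(colSums(L$gain^2))
  if (any(cn == 0))
    stop(sprintf("leadfield column %d has zero norm; cannot weight source %d",
                 which(cn == 0)[1], which(cn == 0)[1]))
  structure(list(weights = cn^gamma, gamma = gamma), class = "source_weighting")
}

#' Build the weighted minimum-norm (WMNE) inverse operator
#'
#' Realizes the standard weighted minimum-norm estimator
#' \deqn{K = R_w L^T (L R_w L^T + \lambda C)^{-1}, \quad R_w = diag(w)^{-2},}
#' the solution of `min ||y - L x||^2_{C^-1} + lambda ||diag(w) x||^2`.
#' Whitening by the noise covariance is implicit in the `(... + lambda C)^-1`
#' form.
#'
#' @param L a [leadfield].
#' @param C a `noise_covariance` (or `NULL` for the identity).
#' @param W a `source_weighting` (or `NULL` for unit weights).
#' @param lambda regularization scalar >= 0; `NULL` selects
#'   `trace(L R_w L^T) / (trace(C) * snr_power)`.
#' @param snr_power assumed signal-to-noise power ratio for the automatic
#'   lambda rule (default 9, i.e. amplitude SNR 3).
#' @return object of class `inverse_operator`: list with `kernel`
#'   (sources x sensors), `lambda`, `gamma`, `provenance`.
#' @export
build_wmne_operator <- function(L, C = NULL, W = NULL, lambda = NULL,
                                snr_power = 9) {
  G <- L$gain
  nE <- nrow(G); nS <- ncol(G)
  if (is.null(C)) C <- structure(list(matrix = diag(nE), loading = 0),
                                 class = "noise_covariance")
  if (is.null(W)) W <- structure(list(weights = rep(1, nS), gamma = 0),
                                 class = "source_weighting")
  if (nrow(C$matrix) != nE) stop("covariance size does not match sensor count")
  if (length(W$weights) != nS) stop("weight count does not match source count")
  rw <- 1 / W$weights^2                       # diagonal of R_w
  GRW <- sweep(G, 2, rw, `*`)                 # L R_w
  Gram <- tcrossprod(GRW, G)                  # L R_w L^T
  Gram <- (Gram + t(Gram)) / 2
  if (is.null(lambda))
    lambda <- sum(diag(Gram)) / (sum(diag(C$matrix)) * snr_power)
  if (lambda < 0) stop("lambda must be >= 0")
  A <- Gram + lambda * C$matrix
  kernel <- tryCatch(t(solve(A, GRW)),
                     error = function(e) stop(
                       "(L R_w L^T + lambda C) is singular; use lambda > 0 ",
                       "(leadfield appears rank deficient)", call. = FALSE))
  structure(list(kernel = kernel, lambda = lambda, gamma = W$gamma,
                 provenance = list(leadfield = L$model,
                                   cov_loading = C$loading)),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d sources x %d sensors, lambda %.4g, gamma %.2f\n",
              nrow(x$kernel), ncol(x$kernel), x$lambda, x$gamma))
  invisible(x)
}

#' Apply an inverse operator to scalp epochs
#'
#' Per-trial matrix product mapping sensor epochs to source epochs; labels,
#' sampling rate and trial count are carried through unchanged.
#'
#' @param K an `inverse_operator`.
#' @param epochs an [epoch_set] of scalp data whose channel count matches the
#'   kernel's sensor count.
#' @return an [epoch_set] of source time courses (montage `NULL`).
#' @export
apply_inverse <- function(K, epochs) {
  stopifnot(inherits(K, "inverse_operator"), inherits(epochs, "mi_epochs"))
  d <- dim(epochs$epochs)
  if (d[2] != ncol(K$kernel))
    stop(sprintf("montage mismatch: epochs have %d channels, kernel expects %d",
                 d[2], ncol(K$kernel)))
  out <- array(0, c(d[1], nrow(K$kernel), d[3]))
  for (tr in seq_len(d[1]))
    out[tr, , ] <- K$kernel %*% matrix(epochs$epochs[tr, , ], d[2], d[3])
  epoch_set(out, epochs$labels, epochs$fs, montage = NULL,
            subject = epochs$subject)
}

#' Export/import an inverse kernel with a JSON sidecar
#'
#' @param K an `inverse_operator`.
#' @param path base path; writes `<path>.txt` (delimited matrix) and
#'   `<path>.json` (lambda, gamma, provenance).
#' @return base path, invisibly.
#' @export
write_inverse_operator <- function(K, path) {
  utils::write.table(K$kernel, paste0(path, ".txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(lambda = K$lambda, gamma = K$gamma,
                            provenance = K$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_inverse_operator
#' @export
read_inverse_operator <- function(path) {
  kernel <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(kernel) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(kernel = kernel, lambda = meta$lambda, gamma = meta$gamma,
                 provenance = meta$provenance), class = "inverse_operator")
}
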