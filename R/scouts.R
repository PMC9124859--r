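#' Define the 18 motor-cortex scouts
#'
#' For each of the nine left-hemisphere electrodes (FC5, FC3, FC1, C5, C3, C1,
#' CP5, CP3, CP1) and their nine right-hemisphere mirrors, the scalp position
#' is projected radially onto the cortical shell and the 20 nearest source
#' vertices (Euclidean distance) form the scout. Scouts are kept disjoint by
#' assigning vertices greedily in the fixed pair order (left then right within
#' each pair).
#'
#' @param source_space a `source_space` with at least 360 sources.
#' @param montage a [sensor_array] containing the 18 electrode names.
#' @return object of class `mi_scouts`: list of 18 scout entries
#'   (`name`, `hemisphere`, `vertex_indices`) plus `pairing`, a 9 x 2 matrix
#'   of (left, right) names in the fixed order.
#' @export
define_motor_scouts <- function(source_space, montage) {
  sc <- motor_scout_names()
  if (nrow(source_space$positions) < 360)
    stop("source space must contain at least 360 sources (18 scouts x 20 vertices)")
  missing <- setdiff(c(sc$left, sc$right), montage$names)
  if (length(missing))
    stop("montage lacks electrodes: ", paste(missing, collapse = ", "))
  radius <- if (!is.null(source_space$radius) && is.finite(source_space$radius))
    source_space$radius else mean(sqrt(rowSums(source_space$positions^2)))
  taken <- rep(FALSE, nrow(source_space$positions))
  scouts <- list()
  # greedy pair order: (FC5, FC6), (FC3, FC4), ...
  ordered <- as.vector(rbind(sc$left, sc$right))
  for (nm in ordered) {
    e <- montage$positions[match(nm, montage$names), ]
    target <- e / sqrt(sum(e^2)) * radius          # radial cortical projection
    d2 <- colSums((t(source_space$positions) - target)^2)
    d2[taken] <- Inf
    idx <- order(d2)[1:20]
    taken[idx] <- TRUE
    scouts[[nm]] <- list(name = nm,
                         hemisphere = if (nm %in% sc$left) "left" else "right",
                         vertex_indices = as.integer(idx))
  }
  structure(list(scouts = scouts[c(sc$left, sc$right)],
                 pairing = cbind(left = sc$left, right = sc$right)),
            class = "mi_scouts")
}

#' @export
print.mi_scouts <- function(x, ...) {
  cat("<mi_scouts> 18 motor-cortex scouts (20 vertices each), pairs:\n  ")
  cat(paste(x$pairing[, 1], x$pairing[, 2], sep = "-", collapse = " "), "\n")
  invisible(x)
}

# named list scout -> vertex indices
scout_vertex_map <- function(scouts) {
  stats::setNames(lapply(scouts$scouts, `[[`, "vertex_indices"),
                  names(scouts$scouts))
}

# sign-aligned mean of a vertices x time matrix: each vertex series is
# flipped, if needed, to correlate non-negatively with the scout's first
# principal component; the global sign is fixed to agree with the first vertex
sign_aligned_mean <- function(X) {
  E <- eigen(tcrossprod(X), symmetric = TRUE)
  u1 <- E$vectors[, 1]
  pc <- as.vector(crossprod(u1, X))       # first principal time course
  s <- sign(as.vector(X %*% pc))
  s[s == 0] <- 1
  if (s[1] < 0) s <- -s
  colMeans(X * s)
}

#' Extract scout time series from source epochs
#'
#' Aggregates each scout's 20 vertex series into one virtual-electrode series
#' per trial by a sign-aligned mean (vertex signs are chosen so every series
#' correlates non-negatively with the scout's first principal direction,
#' preventing cancellation of opposed dipole orientations; the overall sign
#' follows the scout's first vertex). `method = "pca"` returns the first
#' principal component instead, scaled to the mean vertex amplitude.
#'
#' @param source_epochs an [epoch_set] of source time courses (from
#'   [apply_inverse] or simulation ground truth).
#' @param scouts an `mi_scouts`.
#' @param method `"mean"` (sign-aligned mean, default) or `"pca"`.
#' @return object of class `scout_series`: list with `series`
#'   (trials x 18 x samples array, scout names on dim 2), `labels`, `fs`,
#'   `pairing`.
#' @export
extract_scout_series <- function(source_epochs, scouts,
                                 method = c("mean", "pca")) {
  method <- match.arg(method)
  stopifnot(inherits(source_epochs, "mi_epochs"), inherits(scouts, "mi_scouts"))
  d <- dim(source_epochs$epochs)
  vmap <- scout_vertex_map(scouts)
  if (max(unlist(vmap)) > d[2])
    stop(sprintf("scout vertex index %d out of range (%d sources)",
                 max(unlist(vmap)), d[2]))
  nms <- names(vmap)
  out <- array(0, c(d[1], length(nms), d[3]), dimnames = list(NULL, nms, NULL))
  for (tr in seq_len(d[1])) {
    for (j in seq_along(nms)) {
      X <- matrix(source_epochs$epochs[tr, vmap[[j]], ], 20, d[3])
      out[tr, j, ] <- if (method == "mean") sign_aligned_mean(X) else {
        E <- eigen(tcrossprod(X), symmetric = TRUE)
        u1 <- E$vectors[, 1]
        pc <- as.vector(crossprod(u1, X))
        if (sum(u1) < 0) pc <- -pc
        pc * mean(abs(u1))
      }
    }
  }
  structure(list(series = out, labels = source_epochs$labels,
                 fs = source_epochs$fs, pairing = scouts$pairing,
                 subject = source_epochs$subject),
            class = "scout_series")
}

#' Assemble the dual-branch network input
#'
#' Builds the per-trial 1280 x 9 input matrix: column j stacks the 640-sample
#' left-hemisphere series of pair j on top of its right-hemisphere mirror
#' (left series rows 1-640, right series rows 641-1280). [split_branches] is
#' its exact inverse.
#'
#' @param scout_series a `scout_series` (18 scouts) or a trials x 18 x samples
#'   array whose second dimension is named with the scout names.
#' @param pairing 9 x 2 matrix of (left, right) scout names; defaults to the
#'   fixed motor pairing.
#' @return object of class `mi_assembled`: list with `x` (trials x 1280 x 9
#'   array), `labels`, `pairing`, `fs`, `subject`.
#' @export
assemble_input <- function(scout_series, pairing = NULL) {
  if (inherits(scout_series, "scout_series")) {
    arr <- scout_series$series
    if (is.null(pairing)) pairing <- scout_series$pairing
    labels <- scout_series$labels; fs <- scout_series$fs
    subject <- scout_series$subject
  } else {
    arr <- scout_series; labels <- NULL; fs <- NULL; subject <- NULL
  }
  if (is.null(pairing)) {
    sc <- motor_scout_names()
    pairing <- cbind(left = sc$left, right = sc$right)
  }
  d <- dim(arr)
  nms <- dimnames(arr)[[2]]
  li <- match(pairing[, 1], nms); ri <- match(pairing[, 2], nms)
  if (anyNA(li) || anyNA(ri))
    stop("pairing names not found in the scout series")
  x <- array(0, c(d[1], 2 * d[3], nrow(pairing)))
  for (j in seq_len(nrow(pairing))) {
    x[, 1:d[3], j] <- arr[, li[j], ]
    x[, (d[3] + 1):(2 * d[3]), j] <- arr[, ri[j], ]
  }
  structure(list(x = x, labels = labels, pairing = pairing, fs = fs,
                 subject = subject), class = "mi_assembled")
}

#' Split an assembled input into its two hemisphere branches
#'
#' Exact inverse of [assemble_input]: rows 1-640 of each column form the left
#' branch, rows 641-1280 the right branch.
#'
#' @param x a 1280 x 9 matrix (one trial) or trials x 1280 x 9 array, or an
#'   `mi_assembled`.
#' @return list with `left` and `right` (matching 640 x 9 shapes).
#' @export
split_branches <- function(x) {
  if (inherits(x, "mi_assembled")) x <- x$x
  d <- dim(x)
  tdim <- d[length(d) - 1]
  if (tdim %% 2 != 0) stop("assembled input time dimension must be even")
  h <- tdim / 2
  if (length(d) == 2) {
    list(left = x[1:h, , drop = FALSE], right = x[(h + 1):tdim, , drop = FALSE])
  } else {
    list(left = x[, 1:h, , drop = FALSE], right = x[, (h + 1):tdim, , drop = FALSE])
  }
}

#' Serialize scout definitions to JSON
#'
#' @param scouts an `mi_scouts`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_scouts_json <- function(scouts, path) {
  jsonlite::write_json(
    list(pairing = apply(scouts$pairing, 1, paste, collapse = "-"),
         scouts = lapply(scouts$scouts, function(s)
           list(name = s$name, hemisphere = s$hemisphere,
                vertex_indices = s$vertex_indices))),
    path, auto_unbox = TRUE)
  invisible(path)
}
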