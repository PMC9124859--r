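#' Cortical source space on a sphere
#'
#' Places `n` current-dipole sources quasi-uniformly on a spherical cortical
#' shell strictly inside the inner (brain) compartment, with fixed radial
#' orientations (the spherical-model stand-in for dipoles perpendicular to the
#' cortex). The default uses a Fibonacci lattice; with `symmetric = TRUE` the
#' lattice is built on the right hemisphere and mirrored through the
#' mid-sagittal plane, so the source grid is exactly left/right symmetric
#' (which scout symmetry checks rely on).
#'
#' @param n number of sources (even when `symmetric`).
#' @param radius shell radius in meters; must be below the inner-sphere radius
#'   of the head model it is used with (default 0.076, inside 0.080).
#' @param symmetric mirror the grid through the x = 0 plane.
#' @return an object of class `source_space`: list with `positions` (n x 3,
#'   meters), `orientations` (n x 3 unit radial vectors) and `radius`.
#' @export
cortical_source_space <- function(n = 1200, radius = 0.076, symmetric = TRUE) {
  stopifnot(n >= 2, radius > 0)
  if (symmetric) {
    m <- ceiling(n / 2)
    # Fibonacci lattice restricted to x > 0 by construction: generate on a
    # half-sphere via azimuth in (-pi/2, pi/2)
    i <- seq_len(m) - 0.5
    z <- 1 - 2 * i / m
    phi <- pi * (sqrt(5) - 1) * i          # golden-angle spiral
    rho <- sqrt(pmax(0, 1 - z^2))
    x <- abs(rho * cos(phi)) + 1e-9        # keep strictly off the midline
    y <- rho * sin(phi)
    u <- cbind(x, y, z)
    u <- u / sqrt(rowSums(u^2))
    u <- rbind(u, u * matrix(c(-1, 1, 1), m, 3, byrow = TRUE))
  } else {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    phi <- 2 * pi * (sqrt(5) - 1) / 2 * i
    rho <- sqrt(pmax(0, 1 - z^2))
    u <- cbind(rho * cos(phi), rho * sin(phi), z)
  }
  structure(list(positions = u * radius, orientations = u, radius = radius),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d radial dipoles on a %.1f mm cortical shell\n",
              nrow(x$positions), 1000 * x$radius))
  invisible(x)
}

#' Leadfield constructor / validator
#'
#' @param gain sensors x sources numeric matrix in volts per ampere-meter.
#' @param sensors the [sensor_array] the rows refer to.
#' @param model free-form metadata string (radii/conductivities or "imported").
#' @return object of class `leadfield`.
#' @export
leadfield <- function(gain, sensors = NULL, model = "imported") {
  gain <- as.matrix(gain)
  dimnames(gain) <- NULL
  if (!all(is.finite(gain))) stop("leadfield entries must all be finite")
  if (!is.null(sensors) && nrow(gain) != length(sensors$names))
    stop(sprintf("leadfield has %d rows but the sensor array has %d electrodes",
                 nrow(gain), length(sensors$names)))
  structure(list(gain = gain, sensors = sensors, model = model),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources (%s)\n",
              nrow(x$gain), ncol(x$gain), x$model))
  invisible(x)
}

# Solve the degree-n radial boundary-value problem for three concentric
# shells.  Returns the surface-potential transfer value for a unit primary
# coefficient scaled as (r/r1)^-(n+1); all matrix entries are O(1) so the
# 5x5 solves stay well conditioned for large n.
three_shell_transfer <- function(n, radii, cond) {
  r1 <- radii[1]; r2 <- radii[2]; r3 <- radii[3]
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  t12 <- (r1 / r2)^n; u12 <- (r1 / r2)^(n + 1)
  t23 <- (r2 / r3)^n; u23 <- (r2 / r3)^(n + 1)
  # unknowns: a1, b2, g2, b3, g3  (region bases scaled to be <= 1 in-region)
  A <- matrix(0, 5, 5)
  b <- numeric(5)
  # potential continuity at r1:  1 + a1 = b2*t12 + g2
  A[1, ] <- c(1, -t12, -1, 0, 0);              b[1] <- -1
  # current continuity at r1: s1*(-(n+1) + a1*n) = s2*(b2*n*t12 - g2*(n+1))
  A[2, ] <- c(s1 * n, -s2 * n * t12, s2 * (n + 1), 0, 0); b[2] <- s1 * (n + 1)
  # potential continuity at r2: b2 + g2*u12 = b3*t23 + g3
  A[3, ] <- c(0, 1, u12, -t23, -1);            b[3] <- 0
  # current continuity at r2
  A[4, ] <- c(0, s2 * n, -s2 * (n + 1) * u12, -s3 * n * t23, s3 * (n + 1)); b[4] <- 0
  # insulating outer boundary at r3: b3*n - g3*(n+1)*u23 = 0
  A[5, ] <- c(0, 0, 0, n, -(n + 1) * u23);     b[5] <- 0
  x <- solve(A, b)
  x[4] + x[5] * u23                      # V(r3) for the scaled primary
}

#' Analytic three-shell spherical EEG leadfield
#'
#' Computes the gain matrix of the EEG forward model (scalp potential per unit
#' current-dipole moment) for three concentric spheres (brain, skull, scalp)
#' via the Legendre-series solution: per spherical-harmonic degree the radial
#' boundary-value problem is solved exactly, and the series over degrees is
#' summed up to `n_terms`. An average reference is applied by default, after
#' which every column sums to zero.
#'
#' @param sensors a [sensor_array]; electrodes are taken to lie on the outer
#'   sphere (their positions are rescaled to `radii[3]` if the sensor-array
#'   head radius differs).
#' @param sources a `source_space` (positions strictly inside `radii[1]`).
#' @param radii increasing brain/skull/scalp radii in meters.
#' @param conductivities compartment conductivities in S/m.
#' @param n_terms series truncation degree (>= 20). If the largest relative
#'   magnitude of the final term exceeds 1e-10 a warning reports the achieved
#'   tolerance.
#' @param reference `"average"` (default) or `"none"`.
#' @return a [leadfield] (sensors x sources, V / (A m)).
#' @export
three_sphere_leadfield <- function(sensors, sources,
                                   radii = c(0.080, 0.085, 0.092),
                                   conductivities = c(0.33, 0.0042, 0.33),
                                   n_terms = 60,
                                   reference = c("average", "none")) {
  reference <- match.arg(reference)
  stopifnot(length(radii) == 3, length(conductivities) == 3)
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  if (n_terms < 20) stop("n_terms must be at least 20")
  pos <- sources$positions
  b <- sqrt(rowSums(pos^2))
  if (any(b >= radii[1]))
    stop("all sources must lie strictly inside the inner (brain) sphere")
  ori <- sources$orientations
  if (any(abs(sqrt(rowSums(ori^2)) - 1) > 1e-8))
    stop("source orientations must be unit vectors")

  E <- sensors$positions / sqrt(rowSums(sensors$positions^2))  # unit electrode dirs
  S <- pos / b                                                 # unit source dirs
  u <- E %*% t(S)                          # cos(angle electrode-source), nE x nS
  u <- pmin(pmax(u, -1), 1)
  m_r <- rowSums(ori * S)                  # radial moment component per source
  ME <- E %*% t(ori)                       # (orientation . electrode dir)
  # tangential angular factor: m.e_hat - u * m_r
  tang <- ME - sweep(u, 2, m_r, `*`)

  nE <- nrow(E); nS <- nrow(S)
  V <- matrix(0, nE, nS)
  Pnm1 <- matrix(1, nE, nS)   # P_0
  Pn   <- u                   # P_1
  dPnm1 <- matrix(0, nE, nS)  # P_0'
  dPn   <- matrix(1, nE, nS)  # P_1'
  ratio <- matrix(1, nE, nS)               # (b/r1)^(n-1), equals 1 at n = 1
  bfac <- b / radii[1]
  last_rel <- 0
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      Pn1 <- ((2 * n - 1) * u * Pn - (n - 1) * Pnm1) / n
      dPn1 <- dPnm1 + (2 * n - 1) * Pn
      Pnm1 <- Pn; Pn <- Pn1
      dPnm1 <- dPn; dPn <- dPn1
      ratio <- sweep(ratio, 2, bfac, `*`)
    }
    f <- three_shell_transfer(n, radii, conductivities)
    term <- f / radii[1]^2 * ratio *
      (n * sweep(Pn, 2, m_r, `*`) + tang * dPn)
    V <- V + term
    if (n == n_terms)
      last_rel <- max(abs(term)) / max(abs(V))
  }
  V <- V / (4 * pi * conductivities[1])
  if (last_rel > 1e-10)
    warning(sprintf(
      "leadfield series not fully converged at n_terms = %d (relative final term %.2e); increase n_terms",
      n_terms, last_rel))
  if (reference == "average")
    V <- sweep(V, 2, colMeans(V))
  leadfield(V, sensors,
            model = sprintf("3-sphere r=%s cond=%s nterms=%d",
                            paste(radii, collapse = "/"),
                            paste(conductivities, collapse = "/"), n_terms))
}

#' Import an externally computed leadfield
#'
#' Reads a delimited numeric matrix (e.g. exported from a BEM tool) and
#' validates its shape against the sensor array and expected source count.
#'
#' @param path path to a whitespace- or comma-delimited numeric matrix file.
#' @param sensors the [sensor_array] the rows must match.
#' @param n_sources expected number of columns.
#' @param transpose set `TRUE` if the file stores sources x sensors.
#' @param average_ref re-reference columns to the sensor average.
#' @return a [leadfield].
#' @export
load_leadfield <- function(path, sensors, n_sources, transpose = FALSE,
                           average_ref = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl(",", lines[1])) "," else ""
  rows <- strsplit(trimws(lines), if (sep == ",") "\\s*,\\s*" else "\\s+")
  nc <- length(rows[[1]])
  if (any(lengths(rows) != nc))
    stop(sprintf("ragged matrix in '%s': rows have differing column counts", path))
  vals <- suppressWarnings(lapply(rows, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]) & !(rows[[i]] %in% c("NA", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column %d of '%s': '%s'",
                   i, bad[1], path, rows[[i]][bad[1]]))
  }
  M <- do.call(rbind, vals)
  if (transpose) M <- t(M)
  nE <- length(sensors$names)
  if (nrow(M) != nE || ncol(M) != n_sources)
    stop(sprintf("leadfield shape mismatch: expected %d x %d, found %d x %d",
                 nE, n_sources, nrow(M), ncol(M)))
  if (average_ref) M <- sweep(M, 2, colMeans(M))
  leadfield(M, sensors, model = "imported")
}

#' Write a leadfield as a delimited text matrix
#'
#' @param lf a [leadfield].
#' @param path output file.
#' @export
write_leadfield <- function(lf, path) {
  utils::write.table(lf$gain, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
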