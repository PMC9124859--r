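#' Simulation configuration for synthetic motor-imagery EEG
#'
#' Defines the generative conditions for the built-in four-class MI-EEG
#' simulator. Defaults emulate the structure of the public 64-channel
#' motor-movement/imagery recordings: 160 Hz sampling, 4 s trials, 21 trials
#' per class (84 per subject), classes T1 (left fist), T2 (right fist),
#' T3 (both fists), T4 (both feet).
#'
#' Each of the 18 motor-cortex regions carries a baseline process of
#' amplitude-modulated mu (10-12 Hz) and beta (18-25 Hz) sinusoids with random
#' frequencies/phases plus a 1/f pink background. Event-related
#' desynchronization is modelled by multiplying the oscillation amplitude in a
#' class's active regions by `1 - erd_depth`; T1 suppresses the
#' right-hemisphere set, T2 the left, T3 both, and T4 both but in the beta
#' band only (a distinct spectral signature, since the region set itself is
#' fixed).
#'
#' @param n_subjects number of simulated subjects.
#' @param trials_per_class trials per class per subject (default 21).
#' @param fs sampling frequency in Hz (default 160).
#' @param epoch_s trial length in seconds (default 4); `fs * epoch_s` must be
#'   a whole number of samples.
#' @param n_channels scalp channel count (default 64; must match the montage).
#' @param mu_band,beta_band oscillation bands in Hz.
#' @param erd_depth fractional oscillation-amplitude reduction in active
#'   regions, in \[0, 1\].
#' @param sensor_snr_db sensor signal-to-noise ratio in dB, defined as the
#'   ratio of mean 8-30 Hz signal band power across channels to white-noise
#'   power in the same band.
#' @param seed integer RNG seed; identical seed and config give a
#'   bit-identical dataset.
#' @param mu_amp,beta_amp,pink_amp source-level component amplitudes
#'   (arbitrary units; scaled by `source_amp` at projection).
#' @param source_amp dipole moment per source vertex in ampere-meters
#'   (default 1e-8, i.e. 10 nA m, giving microvolt-scale scalp signals).
#' @param noise_floor_var absolute sensor noise variance (V^2) used when the
#'   projected signal is exactly zero (default (1 uV)^2).
#' @param baseline_s length of the resting-state segment generated per
#'   subject for noise-covariance estimation.
#' @param class_templates named list mapping each class to
#'   `list(rois = <scout names>, bands = <"mu"/"beta">)`; `NULL` for the
#'   defaults described above.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1L, trials_per_class = 21L, fs = 160,
                       epoch_s = 4, n_channels = 64L,
                       mu_band = c(10, 12), beta_band = c(18, 25),
                       erd_depth = 0.8, sensor_snr_db = 10, seed = 1L,
                       mu_amp = 1, beta_amp = 0.6, pink_amp = 0.3,
                       source_amp = 1e-8, noise_floor_var = 1e-12,
                       baseline_s = 20, class_templates = NULL) {
  n_samp <- fs * epoch_s
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("fs * epoch_s must be an integer sample count")
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must be in [0, 1]")
  if (trials_per_class < 1) stop("trials_per_class must be >= 1")
  if (is.null(class_templates)) class_templates <- default_class_templates()
  stopifnot(setequal(names(class_templates), mi_classes()))
  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_class = as.integer(trials_per_class),
    fs = fs, epoch_s = epoch_s, n_samples = as.integer(round(n_samp)),
    n_channels = as.integer(n_channels),
    mu_band = mu_band, beta_band = beta_band,
    erd_depth = erd_depth, sensor_snr_db = sensor_snr_db,
    seed = as.integer(seed),
    mu_amp = mu_amp, beta_amp = beta_amp, pink_amp = pink_amp,
    source_amp = source_amp, noise_floor_var = noise_floor_var,
    baseline_s = baseline_s,
    class_templates = class_templates), class = "sim_config")
}

#' The four motor-imagery class labels
#' @return `c("T1","T2","T3","T4")` (left fist, right fist, both fists, both feet).
#' @export
mi_classes <- function() c("T1", "T2", "T3", "T4")

#' Names of the nine left- and right-hemisphere motor scouts
#' @return list with `left` and `right` character vectors of 9 names, in the
#'   fixed pairing order (FC row, C row, CP row; lateral to medial).
#' @export
motor_scout_names <- function() {
  list(left  = c("FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1"),
       right = c("FC6", "FC4", "FC2", "C6", "C4", "C2", "CP6", "CP4", "CP2"))
}

default_class_templates <- function() {
  sc <- motor_scout_names()
  list(T1 = list(rois = sc$right, bands = c("mu", "beta")),
       T2 = list(rois = sc$left,  bands = c("mu", "beta")),
       T3 = list(rois = c(sc$left, sc$right), bands = c("mu", "beta")),
       T4 = list(rois = c(sc$left, sc$right), bands = "beta"))
}

# pink (1/f power) noise via spectral shaping, unit-free amplitude `sd`
pink_noise <- function(n, sd) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  k <- c(1, seq_len(n - 1))                     # avoid the DC bin
  shape <- 1 / sqrt(pmin(k, n - k + 1))         # symmetric 1/sqrt(f) amplitude
  shape[1] <- 0
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# amplitude-modulated band-limited oscillation: K sinusoids with random
# frequencies in `band`, random phases, and a slow sinusoidal envelope
band_oscillation <- function(tt, band, amp, K = 3) {
  x <- numeric(length(tt))
  for (k in seq_len(K)) {
    f <- stats::runif(1, band[1], band[2])
    x <- x + sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  }
  fe <- stats::runif(1, 0.1, 0.5)
  env <- 1 + 0.5 * sin(2 * pi * fe * tt + stats::runif(1, 0, 2 * pi))
  amp / sqrt(K) * env * x
}

#' Generate ground-truth cortical activity for one trial
#'
#' Draws the 18 motor-scout source time series for a single trial of the given
#' class. Uses the current RNG state; seed it (or use [generate_dataset]) for
#' reproducibility.
#'
#' @param class_label one of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @param config a [sim_config].
#' @return object of class `ground_truth`: list with `activity` (18 x samples
#'   matrix, rownames the scout names), `class`, `active_rois`, and
#'   `active_bands`.
#' @export
generate_source_activity <- function(class_label, config) {
  if (!(is.character(class_label) && length(class_label) == 1 &&
        class_label %in% mi_classes()))
    stop(sprintf("unknown motor-imagery class '%s': must be one of %s",
                 paste(class_label, collapse = ","),
                 paste(mi_classes(), collapse = ", ")))
  tpl <- config$class_templates[[class_label]]
  sc <- motor_scout_names()
  rois <- c(sc$left, sc$right)
  tt <- (seq_len(config$n_samples) - 1) / config$fs
  act <- matrix(0, length(rois), config$n_samples, dimnames = list(rois, NULL))
  for (r in rois) {
    g_mu <- if (r %in% tpl$rois && "mu" %in% tpl$bands) 1 - config$erd_depth else 1
    g_beta <- if (r %in% tpl$rois && "beta" %in% tpl$bands) 1 - config$erd_depth else 1
    act[r, ] <- pink_noise(config$n_samples, config$pink_amp) +
      g_mu * band_oscillation(tt, config$mu_band, config$mu_amp) +
      g_beta * band_oscillation(tt, config$beta_band, config$beta_amp)
  }
  structure(list(activity = act, class = class_label,
                 active_rois = tpl$rois, active_bands = tpl$bands),
            class = "ground_truth")
}

# mean band power (V^2) of a multichannel signal in [lo, hi] Hz via the
# periodogram, averaged over channels
band_power <- function(x, fs, lo, hi) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- ncol(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  X <- stats::mvfft(t(x))
  mean(colMeans(abs(X[keep, , drop = FALSE])^2)) * 2 / n^2
}

#' Project ground-truth cortical activity to the scalp
#'
#' Assigns each region's time series to its 20 source vertices (each carrying
#' `source_amp` ampere-meters per unit activity), multiplies through the
#' leadfield, and adds spatially white Gaussian sensor noise at
#' `sensor_snr_db` (mean 8-30 Hz signal band power across channels over noise
#' band power). A zero signal receives noise at the configured absolute floor
#' variance instead.
#'
#' @param truth a `ground_truth` from [generate_source_activity].
#' @param lf a [leadfield].
#' @param vertex_map named list: scout name -> integer vertex (column) indices.
#' @param config a [sim_config].
#' @return channels x samples matrix in volts.
#' @export
project_to_scalp <- function(truth, lf, vertex_map, config) {
  rois <- rownames(truth$activity)
  if (!all(rois %in% names(vertex_map)))
    stop("vertex_map is missing entries for: ",
         paste(setdiff(rois, names(vertex_map)), collapse = ", "))
  idx <- unlist(vertex_map[rois], use.names = FALSE)
  if (max(idx) > ncol(lf$gain))
    stop(sprintf("vertex index %d exceeds leadfield source count %d",
                 max(idx), ncol(lf$gain)))
  reps <- lengths(vertex_map[rois])
  S <- truth$activity[rep(seq_along(rois), reps), , drop = FALSE] * config$source_amp
  y <- lf$gain[, idx, drop = FALSE] %*% S
  p_sig <- band_power(y, config$fs, 8, 30)
  if (p_sig > 0) {
    band_frac <- (30 - 8) / (config$fs / 2)
    nvar <- p_sig / 10^(config$sensor_snr_db / 10) / band_frac
  } else {
    nvar <- config$noise_floor_var
  }
  y + matrix(stats::rnorm(length(y), sd = sqrt(nvar)), nrow(y))
}

#' Generate a complete labelled synthetic MI-EEG dataset
#'
#' Produces `trials_per_class` trials per class per subject (default 21 x 4 =
#' 84 per subject), shuffled with the order recorded, plus a resting-state
#' baseline segment per subject (background activity without ERD, used for
#' noise-covariance estimation). Deterministic given `config$seed`.
#'
#' @param config a [sim_config].
#' @param forward optional forward model from [mi_forward_model]; built with
#'   defaults when `NULL`.
#' @return object of class `mi_dataset`: list with `epochs` (an [epoch_set]),
#'   `ground_truth` (per-trial list), `baseline` (per-subject list of
#'   channels x samples matrices), `trial_order`, `forward`, `config`.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_dataset(sim_config(trials_per_class = 2, seed = 7))
#' dim(ds$epochs$epochs)  # 8 trials x 64 channels x 640 samples
#' }
generate_dataset <- function(config, forward = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(forward)) forward <- mi_forward_model()
  if (length(forward$montage$names) != config$n_channels)
    stop("forward model channel count does not match config$n_channels")
  set.seed(config$seed)
  vmap <- scout_vertex_map(forward$scouts)
  n_tr <- config$trials_per_class * 4L
  all_epochs <- array(0, c(n_tr * config$n_subjects, config$n_channels,
                           config$n_samples))
  labels <- character(n_tr * config$n_subjects)
  subject <- integer(n_tr * config$n_subjects)
  gt <- vector("list", n_tr * config$n_subjects)
  baseline <- vector("list", config$n_subjects)
  order_rec <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    cls <- rep(mi_classes(), each = config$trials_per_class)
    ord <- sample(n_tr)
    cls <- cls[ord]
    order_rec[[s]] <- ord
    for (i in seq_len(n_tr)) {
      tr <- generate_source_activity(cls[i], config)
      row <- (s - 1L) * n_tr + i
      all_epochs[row, , ] <- project_to_scalp(tr, forward$leadfield, vmap, config)
      labels[row] <- cls[i]
      gt[[row]] <- tr
      subject[row] <- s
    }
    baseline[[s]] <- generate_baseline_segment(config, forward, vmap)
  }
  ep <- epoch_set(all_epochs, labels, config$fs, forward$montage$names,
                  subject = subject)
  structure(list(epochs = ep, ground_truth = gt, baseline = baseline,
                 trial_order = order_rec, forward = forward, config = config),
            class = "mi_dataset")
}

# resting background: all regions at baseline amplitude (no ERD), projected
# and noised exactly like a trial
generate_baseline_segment <- function(config, forward, vmap) {
  rest_cfg <- config
  rest_cfg$erd_depth <- 0
  rest_cfg$n_samples <- as.integer(round(config$baseline_s * config$fs))
  tr <- generate_source_activity("T1", rest_cfg)  # erd 0: class is irrelevant
  project_to_scalp(tr, forward$leadfield, vmap, rest_cfg)
}

#' @export
print.mi_dataset <- function(x, ...) {
  cat(sprintf(
    "<mi_dataset> %d subjects x %d trials (%d per class), %d ch @ %g Hz, %g s epochs\n",
    x$config$n_subjects, x$config$trials_per_class * 4L,
    x$config$trials_per_class, x$config$n_channels, x$config$fs,
    x$config$epoch_s))
  cat(sprintf("  erd_depth %.2f, sensor SNR %g dB, seed %d\n",
              x$config$erd_depth, x$config$sensor_snr_db, x$config$seed))
  invisible(x)
}
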