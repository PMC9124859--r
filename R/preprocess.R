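#' Epoch-set container
#'
#' Labelled trials as a trials x channels x samples array with sampling rate
#' and montage. Channels may be scalp electrodes or (after applying an inverse
#' operator) cortical sources, in which case `montage` is `NULL`.
#'
#' @param epochs numeric array, trials x channels x samples.
#' @param labels character/factor of class labels, one per trial
#'   (levels T1-T4 for task epochs).
#' @param fs sampling frequency in Hz.
#' @param montage channel names, or `NULL` for source epochs.
#' @param subject optional integer subject index per trial.
#' @return object of class `mi_epochs`.
#' @export
epoch_set <- function(epochs, labels, fs, montage = NULL, subject = NULL) {
  stopifnot(length(dim(epochs)) == 3, fs > 0)
  if (dim(epochs)[1] != length(labels))
    stop("labels length must equal the trial count")
  if (!is.null(montage) && dim(epochs)[2] != length(montage))
    stop("montage length must equal the channel count")
  labels <- factor(as.character(labels), levels = union(mi_classes(),
                                                        unique(as.character(labels))))
  structure(list(epochs = epochs, labels = labels, fs = fs, montage = montage,
                 subject = subject), class = "mi_epochs")
}

#' @export
print.mi_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<mi_epochs> %d trials x %d %s x %d samples @ %g Hz\n",
              d[1], d[2], if (is.null(x$montage)) "sources" else "channels",
              d[3], x$fs))
  print(table(droplevels(x$labels)))
  invisible(x)
}

#' Raw continuous recording
#'
#' @param samples channels x time numeric matrix in volts.
#' @param fs sampling frequency in Hz.
#' @param channel_names unique channel labels.
#' @param annotations data frame with columns `onset` (s), `duration` (s),
#'   `code` (character), possibly empty.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, channel_names,
                          annotations = empty_annotations()) {
  samples <- as.matrix(samples)
  if (fs <= 0) stop("fs must be positive")
  if (nrow(samples) != length(channel_names))
    stop("channel_names length must equal the channel count")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  stopifnot(all(c("onset", "duration", "code") %in% names(annotations)))
  structure(list(samples = samples, fs = fs,
                 channel_names = as.character(channel_names),
                 annotations = annotations), class = "raw_recording")
}

empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0), code = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %.1f s @ %g Hz, %d annotations\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Band-pass filter specification
#'
#' @param low,high band edges in Hz (defaults 8 and 30, the mu+beta range).
#' @param order per-pass Butterworth order (default 4).
#' @param zero_phase apply forward-backward (zero-phase) filtering.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low = 8, high = 30, order = 4, zero_phase = TRUE) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  structure(list(low = low, high = high, order = order,
                 kind = "butterworth", zero_phase = zero_phase),
            class = "filter_spec")
}

#' Cut fixed-length task epochs from a continuous recording
#'
#' One epoch per task cue, starting at the cue onset and lasting exactly
#' `round(window_s * fs)` samples; the label is assigned through
#' `run_task_map`. Cues too close to the end of the recording are dropped
#' with a message reporting the count. Epoch extraction is pure slicing and
#' never changes sample values.
#'
#' @param raw a [raw_recording] with annotations.
#' @param run_task_map named character vector mapping annotation codes to
#'   class labels, e.g. `c(T1 = "T1", T2 = "T2", ...)`; codes absent from the
#'   map (rest markers etc.) are ignored.
#' @param window_s epoch length in seconds (default 4).
#' @return an [epoch_set]; empty (0 trials) if no mapped cues exist.
#' @export
extract_epochs <- function(raw, run_task_map = stats::setNames(mi_classes(), mi_classes()),
                           window_s = 4) {
  stopifnot(inherits(raw, "raw_recording"))
  n_win <- round(window_s * raw$fs)
  ann <- raw$annotations
  ann <- ann[ann$code %in% names(run_task_map), , drop = FALSE]
  starts <- round(ann$onset * raw$fs) + 1L
  keep <- starts + n_win - 1L <= ncol(raw$samples)
  if (any(!keep))
    message(sprintf("extract_epochs: dropped %d cue(s) too close to the recording end",
                    sum(!keep)))
  ann <- ann[keep, , drop = FALSE]; starts <- starts[keep]
  ep <- array(0, c(nrow(ann), nrow(raw$samples), n_win))
  for (i in seq_len(nrow(ann)))
    ep[i, , ] <- raw$samples[, starts[i]:(starts[i] + n_win - 1L)]
  epoch_set(ep, unname(run_task_map[ann$code]), raw$fs, raw$channel_names)
}

butter_sos <- function(spec, fs) {
  ny <- fs / 2
  if (!(spec$low > 0 && spec$high < ny))
    stop(sprintf("band [%g, %g] Hz must lie inside (0, Nyquist = %g) Hz",
                 spec$low, spec$high, ny))
  signal::butter(spec$order, c(spec$low, spec$high) / ny, type = "pass")
}

filter_matrix <- function(x, flt, zero_phase) {
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- if (zero_phase) signal::filtfilt(flt, x[i, ])
                else signal::filter(flt, x[i, ])
  }
  out
}

#' Band-pass filter epochs or a continuous segment
#'
#' Zero-phase (forward-backward) Butterworth band-pass by default; filtering
#' is linear, applied per channel, and leaves shapes and labels unchanged.
#'
#' @param x an [epoch_set] or a channels x samples matrix.
#' @param spec a [filter_spec].
#' @param fs sampling rate, required when `x` is a bare matrix.
#' @return object of the same shape/class as `x`.
#' @export
bandpass <- function(x, spec = filter_spec(), fs = NULL) {
  UseMethod("bandpass")
}

#' @export
bandpass.mi_epochs <- function(x, spec = filter_spec(), fs = NULL) {
  flt <- butter_sos(spec, x$fs)
  d <- dim(x$epochs)
  for (tr in seq_len(d[1]))
    x$epochs[tr, , ] <- filter_matrix(matrix(x$epochs[tr, , ], d[2], d[3]),
                                      flt, spec$zero_phase)
  x
}

#' @export
bandpass.matrix <- function(x, spec = filter_spec(), fs = NULL) {
  if (is.null(fs)) stop("fs is required when filtering a bare matrix")
  filter_matrix(x, butter_sos(spec, fs), spec$zero_phase)
}

#' Collect baseline (resting) segments for noise-covariance estimation
#'
#' Under the default `"rest"` policy, returns the stretches annotated with one
#' of `rest_codes`. Under `"pre-cue"`, returns the gaps between the end of one
#' task annotation and the onset of the next (up to `max_pre_s` seconds before
#' each cue); back-to-back trials leave no usable gap and raise an error.
#'
#' @param raw a [raw_recording].
#' @param policy `"rest"` or `"pre-cue"`.
#' @param rest_codes annotation codes treated as rest (default `"rest"`, `"T0"`).
#' @param min_s minimum usable segment length in seconds.
#' @param max_pre_s cap on the pre-cue gap length used.
#' @return list of channels x samples matrices.
#' @export
baseline_segments <- function(raw, policy = c("rest", "pre-cue"),
                              rest_codes = c("rest", "T0"), min_s = 0.5,
                              max_pre_s = 2) {
  policy <- match.arg(policy)
  ann <- raw$annotations
  segs <- list()
  if (policy == "rest") {
    rest <- ann[ann$code %in% rest_codes, , drop = FALSE]
    for (i in seq_len(nrow(rest))) {
      a <- round(rest$onset[i] * raw$fs) + 1L
      b <- min(ncol(raw$samples), round((rest$onset[i] + rest$duration[i]) * raw$fs))
      if ((b - a + 1L) / raw$fs >= min_s)
        segs[[length(segs) + 1L]] <- raw$samples[, a:b, drop = FALSE]
    }
  } else {
    # gaps before task cues; rest blocks are not cues but still occupy time
    so <- ann[order(ann$onset), , drop = FALSE]
    if (nrow(so)) {
      ends <- c(0, (so$onset + so$duration)[-nrow(so)])
      for (i in seq_len(nrow(so))) {
        if (so$code[i] %in% rest_codes) next
        lo <- max(ends[i], so$onset[i] - max_pre_s)
        if (so$onset[i] - lo >= min_s) {
          a <- round(lo * raw$fs) + 1L
          b <- round(so$onset[i] * raw$fs)
          segs[[length(segs) + 1L]] <- raw$samples[, a:b, drop = FALSE]
        }
      }
    }
  }
  if (!length(segs))
    stop("no qualifying baseline segments under policy '", policy,
         "'; supply a noise covariance explicitly")
  segs
}
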