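# Minimal EDF+C reader/writer.
# Layout: 256-byte fixed header, 256 bytes per signal header, then data
# records of 16-bit little-endian integers; annotations travel in an
# "EDF Annotations" signal as time-stamped annotation lists (TALs).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF header field '%s' exceeds %d chars", x, width))
  formatC(x, width = -width, flag = "-")
}

num_field <- function(v, width = 8) {
  s <- formatC(v, format = "g", digits = 6, width = -1)
  if (nchar(s) > width) s <- formatC(v, format = "g", digits = 3, width = -1)
  pad_field(s, width)
}

#' Write a continuous recording as an EDF+C file
#'
#' Samples are scaled per channel to the 16-bit digital range with physical
#' units of microvolts; annotations are stored in an `EDF Annotations` signal,
#' one data record per second. Recordings whose length is not a whole number
#' of seconds are zero-padded to the next record boundary.
#'
#' @param raw a [raw_recording] (samples in volts).
#' @param path output file path.
#' @param patient,recording free-text EDF identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path, patient = "X X X X", recording = "Startdate X X X X") {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf supports integer sampling rates only")
  fs <- as.integer(round(fs))
  nch <- nrow(raw$samples)
  n_rec <- as.integer(ceiling(ncol(raw$samples) / fs))
  x <- raw$samples * 1e6                      # volts -> uV
  if (ncol(x) < n_rec * fs)
    x <- cbind(x, matrix(0, nch, n_rec * fs - ncol(x)))

  pm <- apply(abs(x), 1, max)
  pm <- ifelse(pm == 0, 1, pm * 1.001)
  pm <- vapply(pm, function(v) as.numeric(trimws(num_field(v))), 0)
  dig <- round(sweep(x, 1, pm / 32767, `/`))
  dig[dig > 32767] <- 32767L; dig[dig < -32768] <- -32768L

  # annotation TAL byte stream per record
  ann <- raw$annotations
  tal_recs <- lapply(seq_len(n_rec) - 1L, function(t0) {
    out <- c(charToRaw(sprintf("+%d", t0)), as.raw(c(0x14, 0x14, 0x00)))
    sel <- which(ann$onset >= t0 & ann$onset < t0 + 1)
    for (i in sel) {
      ev <- c(charToRaw(sprintf("+%.4f", ann$onset[i])), as.raw(0x15),
              charToRaw(sprintf("%.4f", ann$duration[i])), as.raw(0x14),
              charToRaw(ann$code[i]), as.raw(c(0x14, 0x00)))
      out <- c(out, ev)
    }
    out
  })
  ann_bytes <- max(60L, max(lengths(tal_recs)))
  ann_bytes <- ann_bytes + ann_bytes %% 2L
  ann_ns <- ann_bytes %/% 2L

  ns <- nch + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_field("0", 8)); wr(pad_field(patient, 80)); wr(pad_field(recording, 80))
  wr(pad_field("01.01.00", 8)); wr(pad_field("00.00.00", 8))
  wr(pad_field(256 * (ns + 1L), 8)); wr(pad_field("EDF+C", 44))
  wr(pad_field(n_rec, 8)); wr(pad_field("1", 8)); wr(pad_field(ns, 4))

  labs <- c(raw$channel_names, "EDF Annotations")
  for (l in labs) wr(pad_field(l, 16))
  for (l in labs) wr(pad_field("", 80))                           # transducer
  for (i in seq_len(nch)) wr(pad_field("uV", 8)); wr(pad_field("", 8))
  for (i in seq_len(nch)) wr(num_field(-pm[i])); wr(num_field(-1))  # phys min
  for (i in seq_len(nch)) wr(num_field(pm[i]));  wr(num_field(1))   # phys max
  for (i in seq_len(ns)) wr(pad_field(-32768, 8))
  for (i in seq_len(ns)) wr(pad_field(32767, 8))
  for (i in seq_len(ns)) wr(pad_field("", 80))                    # prefiltering
  for (i in seq_len(nch)) wr(pad_field(fs, 8)); wr(pad_field(ann_ns, 8))
  for (i in seq_len(ns)) wr(pad_field("", 32))

  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nch))
      writeBin(as.integer(dig[i, cols]), con, size = 2, endian = "little")
    tal <- tal_recs[[r]]
    writeBin(c(tal, raw(ann_bytes - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, converts samples to volts (microvolt channels are
#' rescaled; channels in other physical dimensions are returned as stored),
#' and decodes `EDF Annotations` TALs into an annotation table. Files without
#' an annotation signal are returned with an empty annotation list and a
#' warning.
#'
#' @param path path to an EDF/EDF+ file.
#' @return a [raw_recording].
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop(sprintf("'%s' is not a valid EDF file (too short)", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    trimws(s)
  }
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)           # ids, date, time
  rd(8)                                  # header bytes
  rd(44)                                 # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1)
    stop(sprintf("malformed EDF header in '%s': no signals", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  data_idx <- which(!is_ann)
  if (!length(data_idx))
    stop(sprintf("malformed EDF file '%s': zero data channels", path))
  if (anyNA(c(pmin_[data_idx], pmax_[data_idx], dmin_[data_idx], dmax_[data_idx], nsamp)))
    stop(sprintf("malformed EDF header in '%s'", path))

  sig <- lapply(seq_len(ns), function(i) vector("list", n_rec))
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * nsamp[i]))
      } else {
        sig[[i]][[r]] <- readBin(con, "integer", nsamp[i], size = 2,
                                 signed = TRUE, endian = "little")
      }
    }
  }
  fs <- nsamp[data_idx[1]] / rec_dur
  samples <- matrix(0, length(data_idx), n_rec * nsamp[data_idx[1]])
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    d <- unlist(sig[[i]])
    scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    phys <- pmin_[i] + (d - dmin_[i]) * scale
    if (dims[i] == "uV") phys <- phys * 1e-6
    samples[k, ] <- phys
  }
  annotations <- if (any(is_ann)) parse_tals(ann_raw) else {
    warning(sprintf("'%s' has no annotation signal; returning empty annotations", path))
    empty_annotations()
  }
  raw_recording(samples, fs, labels[data_idx], annotations)
}

# decode a TAL byte stream into an annotation data frame, dropping the
# record-keeping timestamps (TALs with no label)
parse_tals <- function(bytes) {
  out <- empty_annotations()
  # TALs are nul-separated; each is onset[\x15duration]\x14label\x14
  nul <- which(bytes == as.raw(0))
  bounds <- cbind(c(1L, nul + 1L), c(nul - 1L, length(bytes)))
  pieces <- apply(bounds, 1, function(b) {
    if (b[1] > b[2]) "" else rawToChar(bytes[b[1]:b[2]])
  })
  for (p in pieces) {
    if (!nzchar(p)) next
    fields <- strsplit(p, "\x14", fixed = TRUE)[[1]]
    if (length(fields) < 2 || !nzchar(fields[2])) next    # timestamp TAL
    od <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(od[1])
    duration <- if (length(od) > 1) as.numeric(od[2]) else 0
    for (lab in fields[-1])
      if (nzchar(lab))
        out <- rbind(out, data.frame(onset = onset, duration = duration,
                                     code = lab, stringsAsFactors = FALSE))
  }
  out
}

#' Render a simulated subject as a continuous annotated recording
#'
#' Concatenates the subject's baseline segment (annotated `rest`) and task
#' epochs back-to-back, with one annotation per trial, reproducing the layout
#' [extract_epochs] and [baseline_segments] expect.
#'
#' @param ds an `mi_dataset` from [generate_dataset].
#' @param subject subject index.
#' @return a [raw_recording].
#' @export
dataset_recording <- function(ds, subject = 1L) {
  stopifnot(inherits(ds, "mi_dataset"))
  sel <- which(ds$epochs$subject == subject)
  if (!length(sel)) stop("no such subject in the dataset")
  base <- ds$baseline[[subject]]
  rest_s <- ncol(base) / ds$config$fs
  ep <- ds$epochs$epochs
  n_samp <- dim(ep)[3]
  tr_mats <- lapply(sel, function(i) matrix(ep[i, , ], dim(ep)[2], n_samp))
  samples <- cbind(base, do.call(cbind, tr_mats))
  onsets <- rest_s + (seq_along(sel) - 1) * (n_samp / ds$config$fs)
  ann <- rbind(
    data.frame(onset = 0, duration = rest_s, code = "rest",
               stringsAsFactors = FALSE),
    data.frame(onset = onsets, duration = n_samp / ds$config$fs,
               code = as.character(ds$epochs$labels[sel]),
               stringsAsFactors = FALSE))
  raw_recording(samples, ds$config$fs, ds$epochs$montage, ann)
}

#' Write a simulated dataset as one EDF file per subject
#'
#' @param ds an `mi_dataset`.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_mi_edf <- function(ds, dir) {
  stopifnot(inherits(ds, "mi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ds$config$n_subjects)
  for (s in seq_len(ds$config$n_subjects)) {
    paths[s] <- file.path(dir, sprintf("subject-%02d.edf", s))
    write_edf(dataset_recording(ds, s), paths[s],
              recording = sprintf("Startdate X simulated-subject-%02d X X", s))
  }
  invisible(paths)
}
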