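make_annotated_recording <- function(n_cue_per_class = 3, fs = 160,
                                     rest_s = 6, trial_s = 4) {
  classes <- rep(mi_classes(), n_cue_per_class)
  total_s <- rest_s + length(classes) * trial_s
  n <- total_s * fs
  x <- matrix(rnorm(4 * n, sd = 1e-5), 4, n)
  ann <- rbind(
    data.frame(onset = 0, duration = rest_s, code = "rest",
               stringsAsFactors = FALSE),
    data.frame(onset = rest_s + (seq_along(classes) - 1) * trial_s,
               duration = trial_s, code = classes, stringsAsFactors = FALSE))
  raw_recording(x, fs, paste0("ch", 1:4), ann)
}

test_that("epoch extraction is pure slicing with the documented sample count", {
  rec <- make_annotated_recording()
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$epochs), c(12L, 4L, 640L))
  expect_equal(unname(table(as.character(ep$labels))), rep(3L, 4),
               ignore_attr = TRUE)
  # values are untouched copies of the raw samples
  i <- 5
  a <- round(rec$annotations$onset[i + 1] * rec$fs) + 1
  expect_identical(ep$epochs[i, , ], rec$samples[, a:(a + 639)])
  # no mapped cues -> empty epoch set
  none <- rec; none$annotations <- none$annotations[1, , drop = FALSE]
  ep0 <- extract_epochs(none)
  expect_equal(dim(ep0$epochs)[1], 0L)
  # a cue too close to the end is dropped with a message
  short <- rec
  short$samples <- short$samples[, 1:(ncol(short$samples) - 200)]
  expect_message(eps <- extract_epochs(short), "dropped 1")
  expect_equal(dim(eps$epochs)[1], 11L)
})

test_that("a full synthetic subject yields 84 four-second epochs", {
  fs <- 160
  classes <- rep(mi_classes(), each = 21)
  n <- (4 * length(classes) + 2) * fs
  x <- matrix(0, 2, n)
  ann <- data.frame(onset = 2 + (seq_along(classes) - 1) * 4, duration = 4,
                    code = sample(classes), stringsAsFactors = FALSE)
  ep <- extract_epochs(raw_recording(x, fs, c("a", "b"), ann))
  expect_equal(dim(ep$epochs), c(84L, 2L, 640L))
  expect_equal(unname(table(as.character(ep$labels))), rep(21L, 4),
               ignore_attr = TRUE)
})

test_that("band-pass keeps in-band sinusoids and attenuates out-of-band ones", {
  fs <- 160
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  amp_of <- function(v, f) {
    # least-squares sinusoid fit at frequency f on the central samples
    mid <- v[(length(v) / 4):(3 * length(v) / 4)]
    tm <- tt[(length(v) / 4):(3 * length(v) / 4)]
    b <- coef(lm(mid ~ sin(2 * pi * f * tm) + cos(2 * pi * f * tm) - 1))
    sqrt(sum(b^2))
  }
  x20 <- matrix(sin(2 * pi * 20 * tt), 1)
  y20 <- bandpass(x20, filter_spec(), fs = fs)
  expect_equal(amp_of(y20[1, ], 20), 1, tolerance = 0.05)
  x2 <- matrix(sin(2 * pi * 2 * tt), 1)
  y2 <- bandpass(x2, filter_spec(), fs = fs)
  expect_lt(20 * log10(amp_of(y2[1, ], 2)), -20)
  # all-zero input stays exactly zero
  expect_equal(bandpass(matrix(0, 2, 400), filter_spec(), fs = fs),
               matrix(0, 2, 400))
})

test_that("filtering is linear and preserves labels and shapes", {
  fs <- 160
  set.seed(8)
  a <- matrix(rnorm(2 * 640), 2); b <- matrix(rnorm(2 * 640), 2)
  fa <- bandpass(a, fs = fs); fb <- bandpass(b, fs = fs)
  fab <- bandpass(2 * a + 3 * b, fs = fs)
  expect_equal(fab, 2 * fa + 3 * fb, tolerance = 1e-9)
  ep <- epoch_set(array(rnorm(3 * 2 * 640), c(3, 2, 640)),
                  c("T1", "T3", "T2"), fs, c("x", "y"))
  epf <- bandpass(ep)
  expect_identical(epf$labels, ep$labels)
  expect_equal(dim(epf$epochs), dim(ep$epochs))
  expect_error(bandpass(ep, filter_spec(low = 8, high = 90)), "Nyquist")
})

test_that("baseline segments follow the rest and pre-cue policies", {
  rec <- make_annotated_recording(rest_s = 6)
  segs <- baseline_segments(rec, "rest")
  expect_length(segs, 1)
  expect_equal(ncol(segs[[1]]), 6 * 160)
  expect_identical(segs[[1]], rec$samples[, 1:(6 * 160)])
  # conservation: total duration equals the sum of selected segments
  expect_equal(sum(vapply(segs, ncol, 0L)) / rec$fs, 6)
  # a recording whose rest block ends before the first cue leaves one
  # usable pre-cue gap; back-to-back trials leave none after that
  gap_rec <- rec
  gap_rec$annotations$duration[1] <- 4   # rest [0, 4], first cue at 6
  gap <- baseline_segments(gap_rec, "pre-cue")
  expect_length(gap, 1)
  expect_equal(ncol(gap[[1]]), 2 * 160)
  # rest covers right up to the first cue and trials are back-to-back: error
  expect_error(baseline_segments(rec, "pre-cue"), "no qualifying")
  norest <- rec
  norest$annotations <- norest$annotations[-1, , drop = FALSE]
  expect_error(baseline_segments(norest, "rest"), "supply a noise covariance")
})
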