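#' Build the default forward model bundle
#'
#' Montage, cortical source space, three-shell spherical leadfield and the 18
#' motor scouts, packaged for reuse by the simulator and the inverse stage.
#'
#' @param montage a [sensor_array] (default [default_montage]).
#' @param n_sources source count for the cortical shell (default 1200).
#' @param source_radius cortical shell radius in meters.
#' @param radii,conductivities three-shell head-model parameters.
#' @param n_terms series truncation for the leadfield (default 150, enough
#'   for full convergence at the default geometry).
#' @return object of class `mi_forward`: list with `montage`, `sources`,
#'   `leadfield`, `scouts`.
#' @export
mi_forward_model <- function(montage = default_montage(), n_sources = 1200L,
                             source_radius = 0.076,
                             radii = c(0.080, 0.085, 0.092),
                             conductivities = c(0.33, 0.0042, 0.33),
                             n_terms = 150L) {
  sources <- cortical_source_space(n_sources, source_radius, symmetric = TRUE)
  lf <- three_sphere_leadfield(montage, sources, radii, conductivities, n_terms)
  scouts <- define_motor_scouts(sources, montage)
  structure(list(montage = montage, sources = sources, leadfield = lf,
                 scouts = scouts), class = "mi_forward")
}

#' @export
print.mi_forward <- function(x, ...) {
  cat("<mi_forward> forward-model bundle\n")
  print(x$montage); print(x$sources); print(x$leadfield); print(x$scouts)
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every stage's settings for the end-to-end runs. The master `seed`
#' is propagated to each stochastic stage (simulation, splitting, training)
#' through fixed offsets, so a run is a pure function of its configuration.
#'
#' @param source `"simulate"` or `"edf"`.
#' @param edf_dir directory of per-subject EDF files (for `source = "edf"`).
#' @param sim a [sim_config] (for `source = "simulate"`).
#' @param filter a [filter_spec].
#' @param forward an `mi_forward` or `NULL` to build the default lazily.
#' @param lambda WMNE regularization (`NULL` = automatic SNR rule).
#' @param gamma depth-weighting exponent.
#' @param loading covariance diagonal-loading fraction.
#' @param arch a [dualcnn_architecture].
#' @param training a [dualcnn_training].
#' @param split_fraction subject-level training fraction.
#' @param folds group-level fold count.
#' @param scout_method scout aggregation, `"mean"` or `"pca"`.
#' @param out_dir output directory for artifacts, or `NULL` to skip writing.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = c("simulate", "edf"), edf_dir = NULL,
                            sim = sim_config(), filter = filter_spec(),
                            forward = NULL, lambda = NULL, gamma = 0.5,
                            loading = 0.1, arch = dualcnn_architecture(),
                            training = dualcnn_training(),
                            split_fraction = 0.9, folds = 10L,
                            scout_method = "mean", out_dir = NULL, seed = 1L) {
  source <- match.arg(source)
  if (source == "edf" && (is.null(edf_dir) || !dir.exists(edf_dir)))
    stop("source = 'edf' requires an existing edf_dir")
  structure(list(source = source, edf_dir = edf_dir, sim = sim,
                 filter = filter, forward = forward, lambda = lambda,
                 gamma = gamma, loading = loading, arch = arch,
                 training = training, split_fraction = split_fraction,
                 folds = as.integer(folds), scout_method = scout_method,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# load per-subject recordings: simulate or read an EDF directory; returns a
# list of (epochs, baseline_segments) per subject plus the forward model
pipeline_ingest <- function(cfg) {
  if (is.null(cfg$forward)) cfg$forward <- mi_forward_model()
  subjects <- list()
  if (cfg$source == "simulate") {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    ds <- generate_dataset(sim, cfg$forward)
    for (s in seq_len(sim$n_subjects)) {
      sel <- which(ds$epochs$subject == s)
      ep <- epoch_set(ds$epochs$epochs[sel, , , drop = FALSE],
                      ds$epochs$labels[sel], ds$epochs$fs, ds$epochs$montage)
      subjects[[s]] <- list(epochs = ep, baseline = list(ds$baseline[[s]]))
    }
  } else {
    paths <- sort(list.files(cfg$edf_dir, "\\.edf$", full.names = TRUE))
    if (!length(paths)) stop("no EDF files in ", cfg$edf_dir)
    for (s in seq_along(paths)) {
      raw <- read_edf(paths[s])
      subjects[[s]] <- list(
        epochs = extract_epochs(raw),
        baseline = baseline_segments(raw, policy = "rest"))
    }
  }
  list(subjects = subjects, forward = cfg$forward)
}

# scalp epochs + baseline -> assembled dual-branch inputs for one subject
pipeline_features <- function(epochs, baseline, forward, cfg) {
  ep_f <- bandpass(epochs, cfg$filter)
  base_f <- lapply(baseline, bandpass, spec = cfg$filter, fs = epochs$fs)
  C <- estimate_noise_covariance(base_f, loading = cfg$loading)
  W <- depth_weights(forward$leadfield, gamma = cfg$gamma)
  K <- build_wmne_operator(forward$leadfield, C, W, lambda = cfg$lambda)
  # restrict the kernel to the scout vertices: only they feed the classifier
  vmap <- scout_vertex_map(forward$scouts)
  vert <- sort(unique(unlist(vmap)))
  Ksub <- K
  Ksub$kernel <- K$kernel[vert, , drop = FALSE]
  remap <- match(unlist(vmap), vert)
  scouts_sub <- forward$scouts
  i0 <- 0
  for (nm in names(scouts_sub$scouts)) {
    scouts_sub$scouts[[nm]]$vertex_indices <- remap[i0 + 1:20]
    i0 <- i0 + 20
  }
  src <- apply_inverse(Ksub, ep_f)
  sc <- extract_scout_series(src, scouts_sub, method = cfg$scout_method)
  assemble_input(sc)
}

write_provenance <- function(cfg, dir, extra = list()) {
  jsonlite::write_json(
    c(list(seed = cfg$seed, source = cfg$source,
           filter = unclass(cfg$filter),
           gamma = cfg$gamma, loading = cfg$loading,
           lambda = if (is.null(cfg$lambda)) "auto" else cfg$lambda,
           arch = unclass(cfg$arch), training = unclass(cfg$training),
           package_version = as.character(utils::packageVersion("hemidiff"))),
      extra),
    file.path(dir, "provenance.json"), auto_unbox = TRUE)
}

#' Run the subject-level experiment
#'
#' Full chain per subject: simulate (or read EDF), band-pass 8-30 Hz, noise
#' covariance from baseline, WMNE inverse, scout extraction, 1280 x 9
#' assembly, stratified 90/10 split, dual-CNN training, evaluation metrics.
#' When `cfg$out_dir` is set, per-subject metrics JSON, learning-curve CSV
#' and a provenance log are written.
#'
#' @param cfg a [pipeline_config].
#' @return list of per-subject results (`metrics`, `model`, `split`), with
#'   class `subject_level_result`.
#' @export
run_subject_level <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ing <- pipeline_ingest(cfg)
  out <- list()
  for (s in seq_along(ing$subjects)) {
    sub <- ing$subjects[[s]]
    assembled <- pipeline_features(sub$epochs, sub$baseline, ing$forward, cfg)
    labels <- as.character(assembled$labels)
    split <- subject_split(labels, cfg$split_fraction, seed = cfg$seed + 17L * s)
    tr_x <- assembled$x[split$train, , , drop = FALSE]
    te_x <- assembled$x[split$test, , , drop = FALSE]
    tcfg <- cfg$training
    tcfg$seed <- cfg$seed + 1000L + s
    model <- dualcnn(tr_x, labels[split$train], arch = cfg$arch, tcfg = tcfg,
                     test_x = te_x, test_y = labels[split$test])
    rep <- compute_metrics(predict(model, te_x), labels[split$test],
                           model$classes)
    if (!is.null(cfg$out_dir)) {
      d <- file.path(cfg$out_dir, sprintf("subject-%02d", s))
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      write_metrics_json(rep, file.path(d, "metrics.json"),
                         file.path(d, "confusion.csv"))
      write_history_csv(model, file.path(d, "history.csv"))
      write_provenance(cfg, d, list(subject = s))
    }
    out[[s]] <- list(metrics = rep, model = model, split = split)
  }
  structure(out, class = "subject_level_result")
}

#' Run the group-level experiment
#'
#' Pools all subjects, splits each subject's trials into `cfg$folds`
#' near-equal parts (one random part per subject to the test pool), trains a
#' single model on the pooled training set and reports one metrics report.
#' With `ablation = TRUE` the four dropout/batch-norm variants are trained on
#' the identical split instead.
#'
#' @param cfg a [pipeline_config] (needs at least 2 subjects).
#' @param ablation run the four-variant ablation grid.
#' @return list with `metrics` (one report, or the four ablation reports),
#'   `model`(s), `split`.
#' @export
run_group_level <- function(cfg, ablation = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ing <- pipeline_ingest(cfg)
  if (length(ing$subjects) < 2)
    stop("group-level experiment needs at least 2 subjects")
  xs <- list(); labels <- character(0); subject <- integer(0)
  for (s in seq_along(ing$subjects)) {
    sub <- ing$subjects[[s]]
    a <- pipeline_features(sub$epochs, sub$baseline, ing$forward, cfg)
    xs[[s]] <- a$x
    labels <- c(labels, as.character(a$labels))
    subject <- c(subject, rep(s, dim(a$x)[1]))
  }
  x <- do.call(function(...) {
    arrs <- list(...)
    tot <- sum(vapply(arrs, function(z) dim(z)[1], 0L))
    out <- array(0, c(tot, dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
    at <- 0L
    for (z in arrs) { out[at + seq_len(dim(z)[1]), , ] <- z; at <- at + dim(z)[1] }
    out
  }, xs)
  split <- group_split(subject, folds = cfg$folds, seed = cfg$seed + 29L)
  tr_x <- x[split$train, , , drop = FALSE]
  te_x <- x[split$test, , , drop = FALSE]
  tcfg <- cfg$training
  tcfg$seed <- cfg$seed + 2000L
  if (ablation) {
    reports <- run_ablation(tr_x, labels[split$train], te_x, labels[split$test],
                            arch = cfg$arch, tcfg = tcfg)
    models <- attr(reports, "models")
  } else {
    model <- dualcnn(tr_x, labels[split$train], arch = cfg$arch, tcfg = tcfg,
                     test_x = te_x, test_y = labels[split$test])
    reports <- compute_metrics(predict(model, te_x), labels[split$test],
                               model$classes)
    models <- model
  }
  if (!is.null(cfg$out_dir)) {
    d <- file.path(cfg$out_dir, "group")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    if (ablation) {
      for (nm in names(reports))
        write_metrics_json(reports[[nm]], file.path(d, paste0(nm, ".json")))
    } else {
      write_metrics_json(reports, file.path(d, "metrics.json"),
                         file.path(d, "confusion.csv"))
      write_history_csv(models, file.path(d, "history.csv"))
    }
    write_provenance(cfg, d, list(subjects = length(ing$subjects)))
  }
  list(metrics = reports, model = models, split = split)
}
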