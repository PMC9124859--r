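#' Dual-CNN architecture configuration
#'
#' The default configuration is the fixed reference architecture: per
#' hemisphere branch four unpadded stride-1 convolutions (25/50/100/200
#' feature maps, time kernel 11; the first kernel spans all 9 scout columns,
#' collapsing the channel axis) each followed by max pooling (time extents
#' 3/3/3/2, floor division), a flatten to 800 features per branch, an
#' element-wise difference of the two branch feature vectors, one fully
#' connected layer of 128 rectified units and a 4-way softmax read-out.
#'
#' @param input_time samples per branch (default 640 = 4 s at 160 Hz).
#' @param input_ch scout columns per branch (default 9).
#' @param maps feature maps per convolution block.
#' @param kernel_t convolution kernel time extents.
#' @param pool_t max-pooling time extents.
#' @param fc_units width of the fully connected layer.
#' @param n_classes softmax width.
#' @param weight_sharing `"independent"` (each branch has its own parameters,
#'   initialized identically) or `"shared"` (both branches are literally the
#'   same parameter set).
#' @param dropout_rate spatial-dropout rate in \[0, 1).
#' @param use_spatial_dropout drop whole feature maps after each pooling
#'   layer during training.
#' @param use_batchnorm batch-normalize after each convolution, before the
#'   rectifier.
#' @return object of class `dualcnn_architecture`.
#' @export
dualcnn_architecture <- function(input_time = 640L, input_ch = 9L,
                                 maps = c(25L, 50L, 100L, 200L),
                                 kernel_t = c(11L, 11L, 11L, 11L),
                                 pool_t = c(3L, 3L, 3L, 2L),
                                 fc_units = 128L, n_classes = 4L,
                                 weight_sharing = c("independent", "shared"),
                                 dropout_rate = 0.5,
                                 use_spatial_dropout = TRUE,
                                 use_batchnorm = TRUE) {
  weight_sharing <- match.arg(weight_sharing)
  stopifnot(length(maps) == length(kernel_t),
            length(maps) == length(pool_t),
            all(kernel_t > 0), all(pool_t > 0), fc_units > 0, n_classes >= 2)
  if (!(dropout_rate >= 0 && dropout_rate < 1))
    stop("dropout_rate must be in [0, 1)")
  if (kernel_t[1] > input_time)
    stop("first kernel time extent exceeds the branch input length")
  structure(list(input_time = as.integer(input_time),
                 input_ch = as.integer(input_ch),
                 maps = as.integer(maps), kernel_t = as.integer(kernel_t),
                 pool_t = as.integer(pool_t), fc_units = as.integer(fc_units),
                 n_classes = as.integer(n_classes),
                 weight_sharing = weight_sharing,
                 dropout_rate = dropout_rate,
                 use_spatial_dropout = use_spatial_dropout,
                 use_batchnorm = use_batchnorm),
            class = "dualcnn_architecture")
}

#' Training configuration
#'
#' @param iterations number of mini-batch updates (default 600).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size mini-batch size (default 32).
#' @param seed RNG seed controlling initialization order, shuffling and
#'   dropout.
#' @return object of class `dualcnn_training`.
#' @export
dualcnn_training <- function(iterations = 600L, learning_rate = 1e-3,
                             batch_size = 32L, seed = 1L) {
  stopifnot(iterations >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = "categorical cross-entropy", optimizer = "adam"),
            class = "dualcnn_training")
}

#' Propagate output shapes through the architecture
#'
#' Pure arithmetic: unpadded convolution `out = in - kernel + 1`, max pooling
#' `out = floor(in / pool)`, flatten multiplies dimensions, the difference
#' layer preserves width, and the fully connected and softmax layers set their
#' widths. The default architecture yields the chain
#' 640x9 -> 630/210/200/66/56/18/8/4 -> 800 -> 800 -> 128 -> 4.
#'
#' @param arch a [dualcnn_architecture].
#' @return data frame with columns `layer` (L1..L13 for the default depth),
#'   `name` and `output` (shape string), one row per layer.
#' @export
shape_propagate <- function(arch = dualcnn_architecture()) {
  stopifnot(inherits(arch, "dualcnn_architecture"))
  tdim <- arch$input_time; nL <- length(arch$maps)
  rows <- data.frame(layer = "L1", name = "Input",
                     output = sprintf("%dx%d,%dx%d", tdim, arch$input_ch,
                                      tdim, arch$input_ch),
                     stringsAsFactors = FALSE)
  li <- 2L
  for (l in seq_len(nL)) {
    tconv <- tdim - arch$kernel_t[l] + 1L
    if (tconv < 1)
      stop(sprintf("layer Conv_%d: kernel %d exceeds input length %d",
                   l, arch$kernel_t[l], tdim))
    rows <- rbind(rows, data.frame(
      layer = sprintf("L%d", li), name = sprintf("Conv_L%d,Conv_R%d", l, l),
      output = sprintf("%dx1x%d", tconv, arch$maps[l])))
    li <- li + 1L
    tpool <- tconv %/% arch$pool_t[l]
    if (tpool < 1)
      stop(sprintf("layer Pool_%d: pool %d exceeds input length %d",
                   l, arch$pool_t[l], tconv))
    rows <- rbind(rows, data.frame(
      layer = sprintf("L%d", li), name = sprintf("Pool_L%d, Pool_R%d", l, l),
      output = sprintf("%dx1x%d", tpool, arch$maps[l])))
    li <- li + 1L
    tdim <- tpool
  }
  flat <- tdim * arch$maps[nL]
  rows <- rbind(rows,
    data.frame(layer = sprintf("L%d", li), name = "Flatten_L,Flatten_R",
               output = sprintf("%d", flat)),
    data.frame(layer = sprintf("L%d", li + 1L), name = "Flatten_L-Flatten_R",
               output = sprintf("%d", flat)),
    data.frame(layer = sprintf("L%d", li + 2L), name = "FC",
               output = sprintf("%d", arch$fc_units)),
    data.frame(layer = sprintf("L%d", li + 3L), name = "Softmax",
               output = sprintf("%d", arch$n_classes)))
  rows
}

# geometry cache: per conv block the im2col index matrix and output sizes
build_geometry <- function(arch) {
  tdim <- arch$input_time; cin <- arch$input_ch
  geom <- list()
  for (l in seq_along(arch$maps)) {
    k <- arch$kernel_t[l]
    t_out <- tdim - k + 1L
    if (t_out < 1) stop(sprintf("non-positive conv output at layer %d", l))
    kc <- k * cin
    offsets <- as.vector(outer(seq_len(k), (seq_len(cin) - 1L) * tdim, `+`))
    idx <- outer(0:(t_out - 1L), rep(1L, kc)) +
      matrix(offsets, t_out, kc, byrow = TRUE)
    p <- arch$pool_t[l]
    t_pool <- t_out %/% p
    if (t_pool < 1) stop(sprintf("non-positive pool output at layer %d", l))
    geom[[l]] <- list(t_in = tdim, c_in = cin, k = k, kc = kc, t_out = t_out,
                      idxvec = as.vector(idx), idx = idx, pool = p,
                      t_pool = t_pool, maps = arch$maps[l])
    tdim <- t_pool; cin <- arch$maps[l]
  }
  attr(geom, "mat") <- do.call(rbind, lapply(geom, function(g)
    c(g$t_in, g$c_in, g$k, g$t_out, g$pool, g$t_pool, g$maps)))
  geom
}

branch_flat_dim <- function(arch) {
  g <- build_geometry(arch)
  last <- g[[length(g)]]
  last$t_pool * last$maps
}

# ---- parameter handling (flat named list) ----------------------------------

init_branch_params <- function(arch, prefix) {
  g <- build_geometry(arch)
  par <- list()
  for (l in seq_along(g)) {
    fan_in <- g[[l]]$kc
    par[[sprintf("%s.conv%d.W", prefix, l)]] <-
      matrix(stats::rnorm(fan_in * g[[l]]$maps, sd = sqrt(2 / fan_in)),
             fan_in, g[[l]]$maps)
    par[[sprintf("%s.conv%d.b", prefix, l)]] <- numeric(g[[l]]$maps)
    if (arch$use_batchnorm) {
      par[[sprintf("%s.bn%d.gamma", prefix, l)]] <- rep(1, g[[l]]$maps)
      par[[sprintf("%s.bn%d.beta", prefix, l)]] <- numeric(g[[l]]$maps)
    }
  }
  par
}

init_bn_state <- function(arch, prefix) {
  st <- list()
  if (!arch$use_batchnorm) return(st)
  for (l in seq_along(arch$maps)) {
    st[[sprintf("%s.bn%d.mean", prefix, l)]] <- numeric(arch$maps[l])
    st[[sprintf("%s.bn%d.var", prefix, l)]] <- rep(1, arch$maps[l])
  }
  st
}

#' Initialize an untrained dual-CNN model
#'
#' Builds the two convolutional branches (shared or independent parameters
#' per the architecture; independent branches are initialized identically
#' from the seed and then updated independently) and the difference/FC/softmax
#' head. The softmax head weights start near zero, so an untrained model
#' predicts the uniform distribution and its initial cross-entropy is close
#' to `log(n_classes)`.
#'
#' @param arch a [dualcnn_architecture].
#' @param seed integer seed for deterministic initialization.
#' @param classes class labels for the softmax outputs.
#' @return object of class `dualcnn` (untrained: `$history` is `NULL`).
#' @export
dualcnn_init <- function(arch = dualcnn_architecture(), seed = 1L,
                         classes = mi_classes()) {
  stopifnot(inherits(arch, "dualcnn_architecture"))
  if (length(classes) != arch$n_classes)
    stop(sprintf("arch expects %d classes but %d class labels were given",
                 arch$n_classes, length(classes)))
  set.seed(seed)
  flat <- branch_flat_dim(arch)
  br <- init_branch_params(arch, "B")
  if (arch$weight_sharing == "shared") {
    par <- stats::setNames(br, sub("^B\\.", "S.", names(br)))
    bn_state <- init_bn_state(arch, "S")
  } else {
    par <- c(stats::setNames(br, sub("^B\\.", "L.", names(br))),
             stats::setNames(br, sub("^B\\.", "R.", names(br))))
    bn_state <- c(init_bn_state(arch, "L"), init_bn_state(arch, "R"))
  }
  par[["head.W1"]] <- matrix(stats::rnorm(flat * arch$fc_units,
                                          sd = sqrt(2 / flat)),
                             flat, arch$fc_units)
  par[["head.b1"]] <- numeric(arch$fc_units)
  par[["head.W2"]] <- matrix(stats::rnorm(arch$fc_units * arch$n_classes,
                                          sd = 1e-2),
                             arch$fc_units, arch$n_classes)
  par[["head.b2"]] <- numeric(arch$n_classes)
  structure(list(arch = arch, params = par, bn_state = bn_state,
                 classes = as.character(classes), seed = as.integer(seed),
                 input_center = 0, input_scale = 1,
                 history = NULL, training = NULL),
            class = "dualcnn")
}


# ---- compiled-kernel glue ---------------------------------------------------

# gather one branch's parameters into the list layout the C++ step expects
pack_branch_params <- function(par, prefix, nL, use_bn) {
  list(W = lapply(seq_len(nL), function(l) par[[sprintf("%s.conv%d.W", prefix, l)]]),
       b = lapply(seq_len(nL), function(l) par[[sprintf("%s.conv%d.b", prefix, l)]]),
       gamma = if (use_bn)
         lapply(seq_len(nL), function(l) par[[sprintf("%s.bn%d.gamma", prefix, l)]])
       else rep(list(numeric(0)), nL),
       beta = if (use_bn)
         lapply(seq_len(nL), function(l) par[[sprintf("%s.bn%d.beta", prefix, l)]])
       else rep(list(numeric(0)), nL))
}

# rename a C++ branch-gradient list into the flat parameter names
map_branch_grads <- function(g, prefix, use_bn) {
  out <- list()
  for (l in seq_along(g$dW)) {
    out[[sprintf("%s.conv%d.W", prefix, l)]] <- g$dW[[l]]
    out[[sprintf("%s.conv%d.b", prefix, l)]] <- as.numeric(g$db[[l]])
    if (use_bn) {
      out[[sprintf("%s.bn%d.gamma", prefix, l)]] <- as.numeric(g$dgamma[[l]])
      out[[sprintf("%s.bn%d.beta", prefix, l)]] <- as.numeric(g$dbeta[[l]])
    }
  }
  out
}

# forward through one branch (evaluation or BN-recalibration pass)
branch_forward <- function(model, prefix, A, geom, training, dropout = training) {
  arch <- model$arch
  nL <- length(geom)
  pp <- pack_branch_params(model$params, prefix, nL, arch$use_batchnorm)
  if (arch$use_batchnorm) {
    run_mu <- lapply(seq_len(nL), function(l)
      model$bn_state[[sprintf("%s.bn%d.mean", prefix, l)]])
    run_var <- lapply(seq_len(nL), function(l)
      model$bn_state[[sprintf("%s.bn%d.var", prefix, l)]])
  } else {
    run_mu <- run_var <- rep(list(numeric(0)), nL)
  }
  branch_forward_cpp(A, pp$W, pp$b, pp$gamma, pp$beta, run_mu, run_var,
                     attr(geom, "mat"), training, arch$use_batchnorm,
                     dropout && arch$use_spatial_dropout && arch$dropout_rate > 0,
                     arch$dropout_rate)
}

# full eval-style forward for a batch; XL/XR: (t*c) x B matrices
dualcnn_batch_forward <- function(model, XL, XR, geom, training = FALSE,
                                  dropout = training) {
  pre <- if (model$arch$weight_sharing == "shared") c("S", "S") else c("L", "R")
  fl <- branch_forward(model, pre[1], XL, geom, training, dropout)
  fr <- branch_forward(model, pre[2], XR, geom, training, dropout)
  D <- fl$flat - fr$flat
  par <- model$params
  H1 <- crossprod(par[["head.W1"]], D) + par[["head.b1"]]
  H <- H1 * (H1 > 0)
  logits <- crossprod(par[["head.W2"]], H) + par[["head.b2"]]
  el <- exp(sweep(logits, 2, apply(logits, 2, max)))
  probs <- sweep(el, 2, colSums(el), `/`)
  list(probs = probs, diff = D,
       muL = fl$mu, vvL = fl$vv, muR = fr$mu, vvR = fr$vv)
}

softmax_xent <- function(probs, y_idx) {
  p <- probs[cbind(y_idx, seq_along(y_idx))]
  -mean(log(pmax(p, 1e-12)))
}

# fold a training step's batch statistics into the running BN statistics;
# in shared mode one statistic set serves both branches
update_bn_state <- function(model, muL, vvL, muR, vvR, momentum = 0.9) {
  if (!model$arch$use_batchnorm) return(model)
  shared <- model$arch$weight_sharing == "shared"
  for (l in seq_along(model$arch$maps)) {
    mL <- as.numeric(muL[[l]]); vL <- as.numeric(vvL[[l]])
    mR <- as.numeric(muR[[l]]); vR <- as.numeric(vvR[[l]])
    if (shared) {
      mk <- sprintf("S.bn%d.mean", l); vk <- sprintf("S.bn%d.var", l)
      model$bn_state[[mk]] <- momentum * model$bn_state[[mk]] +
        (1 - momentum) * (mL + mR) / 2
      model$bn_state[[vk]] <- momentum * model$bn_state[[vk]] +
        (1 - momentum) * (vL + vR) / 2
    } else {
      for (s in c("L", "R")) {
        m <- if (s == "L") mL else mR
        v <- if (s == "L") vL else vR
        mk <- sprintf("%s.bn%d.mean", s, l); vk <- sprintf("%s.bn%d.var", s, l)
        model$bn_state[[mk]] <- momentum * model$bn_state[[mk]] + (1 - momentum) * m
        model$bn_state[[vk]] <- momentum * model$bn_state[[vk]] + (1 - momentum) * v
      }
    }
  }
  model
}

# convert inputs (mi_assembled or trials x 1280 x 9 array) into the two
# branch matrices ((640*9) x trials each)
prepare_branch_matrices <- function(x, arch) {
  if (inherits(x, "mi_assembled")) x <- x$x
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  d <- dim(x)
  if (length(d) != 3 || d[2] != 2 * arch$input_time || d[3] != arch$input_ch)
    stop(sprintf("expected trials x %d x %d assembled input, got %s",
                 2 * arch$input_time, arch$input_ch,
                 paste(d, collapse = " x ")))
  n <- d[1]; tt <- arch$input_time; cc <- arch$input_ch
  XL <- matrix(0, tt * cc, n); XR <- matrix(0, tt * cc, n)
  for (i in seq_len(n)) {
    XL[, i] <- as.vector(x[i, 1:tt, ])
    XR[, i] <- as.vector(x[i, (tt + 1):(2 * tt), ])
  }
  list(XL = XL, XR = XR, n = n)
}

# Replace the BN running statistics with population statistics of the
# dropout-free training-set activations.  Statistics accumulated during
# training reflect the inverted-dropout distribution (inflated variance);
# evaluation runs without dropout, so normalizing with them mis-scales the
# features (the known dropout/batch-norm variance-shift disharmony).  One
# dropout-free pass over the training set fixes the mismatch.
recalibrate_bn <- function(model, bm, geom, chunk = 256L) {
  if (!model$arch$use_batchnorm) return(model)
  shared <- model$arch$weight_sharing == "shared"
  nL <- length(model$arch$maps)
  acc <- list(); wt <- 0
  for (a in seq(1, bm$n, by = chunk)) {
    b <- min(bm$n, a + chunk - 1L)
    fw <- dualcnn_batch_forward(model, bm$XL[, a:b, drop = FALSE],
                                bm$XR[, a:b, drop = FALSE], geom,
                                training = TRUE, dropout = FALSE)
    w <- b - a + 1L
    for (l in seq_len(nL)) {
      for (side in c("L", "R")) {
        mu_l <- as.numeric(fw[[paste0("mu", side)]][[l]])
        vv_l <- as.numeric(fw[[paste0("vv", side)]][[l]])
        mk <- sprintf("%s.mu%d", side, l); vk <- sprintf("%s.m2%d", side, l)
        acc[[mk]] <- (if (is.null(acc[[mk]])) 0 else acc[[mk]]) + w * mu_l
        acc[[vk]] <- (if (is.null(acc[[vk]])) 0 else acc[[vk]]) +
          w * (vv_l + mu_l^2)
      }
    }
    wt <- wt + w
  }
  for (l in seq_len(nL)) {
    muL <- acc[[sprintf("L.mu%d", l)]] / wt
    muR <- acc[[sprintf("R.mu%d", l)]] / wt
    vvL <- acc[[sprintf("L.m2%d", l)]] / wt - muL^2
    vvR <- acc[[sprintf("R.m2%d", l)]] / wt - muR^2
    if (shared) {
      model$bn_state[[sprintf("S.bn%d.mean", l)]] <- (muL + muR) / 2
      model$bn_state[[sprintf("S.bn%d.var", l)]] <- (vvL + vvR) / 2
    } else {
      model$bn_state[[sprintf("L.bn%d.mean", l)]] <- muL
      model$bn_state[[sprintf("L.bn%d.var", l)]] <- vvL
      model$bn_state[[sprintf("R.bn%d.mean", l)]] <- muR
      model$bn_state[[sprintf("R.bn%d.var", l)]] <- vvR
    }
  }
  model
}

#' Train a dual-CNN model
#'
#' Minimizes the categorical cross-entropy with Adam over mini-batches drawn
#' from reshuffled epochs. Per iteration the history records the training
#' batch loss/accuracy and, when a test set is given, the eval-mode loss and
#' accuracy on the full test set. After the final iteration the batch-norm
#' running statistics are recalibrated with one dropout-free pass over the
#' training set. Deterministic given the training seed.
#'
#' @param model an untrained (or previously trained) `dualcnn` from
#'   [dualcnn_init].
#' @param x training inputs: an `mi_assembled` or trials x 1280 x 9 array.
#' @param y training labels (character/factor over the model's classes);
#'   taken from `x$labels` when `NULL`.
#' @param test_x,test_y optional held-out set evaluated every iteration.
#' @param tcfg a [dualcnn_training].
#' @return the trained `dualcnn` (history filled in).
#' @export
dualcnn_train <- function(model, x, y = NULL, test_x = NULL, test_y = NULL,
                          tcfg = dualcnn_training()) {
  stopifnot(inherits(model, "dualcnn"), inherits(tcfg, "dualcnn_training"))
  if (is.null(y) && inherits(x, "mi_assembled")) y <- x$labels
  if (is.null(y)) stop("training labels are required")
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("training set must contain at least 2 classes")
  if (!all(y %in% model$classes))
    stop("labels outside the model's classes: ",
         paste(setdiff(unique(y), model$classes), collapse = ", "))
  bm <- prepare_branch_matrices(x, model$arch)
  if (bm$n == 0) stop("empty training set")
  # standardize inputs (EEG-derived series can be on a nanovolt scale, far
  # below the batch-norm epsilon); the affine is stored with the model so
  # prediction applies the identical transform
  model$input_center <- mean(c(bm$XL, bm$XR))
  sc <- stats::sd(c(bm$XL, bm$XR))
  model$input_scale <- if (is.finite(sc) && sc > 0) sc else 1
  bm$XL <- (bm$XL - model$input_center) / model$input_scale
  bm$XR <- (bm$XR - model$input_center) / model$input_scale
  y_idx <- match(y, model$classes)
  has_test <- !is.null(test_x)
  if (has_test) {
    if (is.null(test_y) && inherits(test_x, "mi_assembled")) test_y <- test_x$labels
    tb <- prepare_branch_matrices(test_x, model$arch)
    tb$XL <- (tb$XL - model$input_center) / model$input_scale
    tb$XR <- (tb$XR - model$input_center) / model$input_scale
    ty_idx <- match(as.character(test_y), model$classes)
  }
  arch <- model$arch
  geom <- build_geometry(arch)
  gm <- attr(geom, "mat")
  nL <- length(arch$maps)
  use_bn <- arch$use_batchnorm
  shared <- arch$weight_sharing == "shared"
  pre <- if (shared) c("S", "S") else c("L", "R")
  drop_on <- arch$use_spatial_dropout && arch$dropout_rate > 0
  set.seed(tcfg$seed)
  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- lapply(model$params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- matrix(NA_real_, tcfg$iterations, 4,
                 dimnames = list(NULL, c("train_loss", "train_acc",
                                         "test_loss", "test_acc")))
  pool <- sample(bm$n)
  pos <- 1L
  for (it in seq_len(tcfg$iterations)) {
    take <- min(tcfg$batch_size, bm$n)
    if (pos + take - 1L > length(pool)) { pool <- sample(bm$n); pos <- 1L }
    bi <- pool[pos:(pos + take - 1L)]
    pos <- pos + take
    step <- dualcnn_step_cpp(
      bm$XL[, bi, drop = FALSE], bm$XR[, bi, drop = FALSE],
      pack_branch_params(model$params, pre[1], nL, use_bn),
      pack_branch_params(model$params, pre[2], nL, use_bn),
      model$params[["head.W1"]], model$params[["head.b1"]],
      model$params[["head.W2"]], model$params[["head.b2"]],
      gm, use_bn, shared, drop_on, arch$dropout_rate,
      y_idx[bi], arch$n_classes)
    hist[it, "train_loss"] <- step$loss
    hist[it, "train_acc"] <- step$acc
    grads <- c(list(head.W1 = step$dW1, head.b1 = as.numeric(step$db1),
                    head.W2 = step$dW2, head.b2 = as.numeric(step$db2)),
               map_branch_grads(step$gradL, pre[1], use_bn),
               if (!shared) map_branch_grads(step$gradR, "R", use_bn))
    model <- update_bn_state(model, step$muL, step$vvL, step$muR, step$vvR)
    corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
    for (nm in names(grads)) {
      adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
      adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
      model$params[[nm]] <- model$params[[nm]] -
        tcfg$learning_rate * (adam_m[[nm]] / corr1) /
        (sqrt(adam_v[[nm]] / corr2) + eps)
    }
    if (has_test) {
      tf <- dualcnn_batch_forward(model, tb$XL, tb$XR, geom, training = FALSE)
      hist[it, "test_loss"] <- softmax_xent(tf$probs, ty_idx)
      hist[it, "test_acc"] <- mean(max.col(t(tf$probs)) == ty_idx)
    }
  }
  model <- recalibrate_bn(model, bm, geom)
  model$history <- data.frame(iteration = seq_len(tcfg$iterations), hist)
  model$training <- tcfg
  model
}

#' Fit a dual-CNN motor-imagery classifier
#'
#' Convenience wrapper: initializes a model with [dualcnn_init] and trains it
#' with [dualcnn_train].
#'
#' @param x training inputs (an `mi_assembled` or trials x 1280 x 9 array).
#' @param y training labels; taken from `x$labels` when `NULL`.
#' @param arch a [dualcnn_architecture].
#' @param tcfg a [dualcnn_training].
#' @param test_x,test_y optional held-out set tracked in the history.
#' @param classes class labels (defaults to the four MI classes, or the
#'   sorted unique labels when they differ).
#' @return a trained object of class `dualcnn`.
#' @export
#' @examples
#' \donttest{
#' # two linearly separable pseudo-classes
#' set.seed(1)
#' x <- array(rnorm(40 * 1280 * 9), c(40, 1280, 9))
#' x[1:20, 1:640, ] <- x[1:20, 1:640, ] + 1
#' y <- rep(c("T1", "T2"), each = 20)
#' fit <- dualcnn(x, y, arch = dualcnn_architecture(n_classes = 2),
#'                tcfg = dualcnn_training(iterations = 50),
#'                classes = c("T1", "T2"))
#' }
dualcnn <- function(x, y = NULL, arch = dualcnn_architecture(),
                    tcfg = dualcnn_training(), test_x = NULL, test_y = NULL,
                    classes = NULL) {
  if (is.null(y) && inherits(x, "mi_assembled")) y <- x$labels
  if (is.null(classes)) {
    uy <- unique(as.character(y))
    classes <- if (all(uy %in% mi_classes()) && arch$n_classes == 4)
      mi_classes() else sort(uy)
  }
  model <- dualcnn_init(arch, seed = tcfg$seed, classes = classes)
  dualcnn_train(model, x, y, test_x, test_y, tcfg)
}
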