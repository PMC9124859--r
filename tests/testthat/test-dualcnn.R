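tiny_arch <- function(...) {
  dualcnn_architecture(input_time = 16L, input_ch = 2L, maps = c(3L, 4L),
                       kernel_t = c(3L, 3L), pool_t = c(2L, 2L),
                       fc_units = 5L, n_classes = 3L, dropout_rate = 0,
                       use_spatial_dropout = FALSE, ...)
}

test_that("shape propagation handles boundaries and rejects impossible configs", {
  sp <- shape_propagate(dualcnn_architecture(input_time = 11L, input_ch = 9L,
                                             maps = 4L, kernel_t = 11L,
                                             pool_t = 1L))
  expect_equal(sp$output[sp$name == "Conv_L1,Conv_R1"], "1x1x4")
  expect_error(shape_propagate(dualcnn_architecture(input_time = 32L,
                                                    maps = c(4L, 4L),
                                                    kernel_t = c(11L, 30L),
                                                    pool_t = c(1L, 1L))),
               "Conv_2")
  expect_error(dualcnn_architecture(dropout_rate = 1), "dropout_rate")
})

test_that("initialization is deterministic with identically initialized branches", {
  m1 <- dualcnn_init(seed = 42)
  m2 <- dualcnn_init(seed = 42)
  expect_identical(m1$params, m2$params)
  # independent branches start as exact copies of one another
  expect_identical(m1$params[["L.conv1.W"]], m1$params[["R.conv1.W"]])
  expect_identical(m1$params[["L.bn3.gamma"]], m1$params[["R.bn3.gamma"]])
  # shared mode holds a single branch parameter set used by both branches
  ms <- dualcnn_init(dualcnn_architecture(weight_sharing = "shared"), seed = 1)
  expect_true(any(grepl("^S\\.", names(ms$params))))
  expect_false(any(grepl("^[LR]\\.", names(ms$params))))
  # FC width between difference layer and FC is 800 x 128
  expect_equal(dim(m1$params[["head.W1"]]), c(800L, 128L))
})

test_that("forward output lies on the probability simplex and the zeroed head is uniform", {
  m <- dualcnn_init(seed = 7)
  set.seed(1)
  x <- array(rnorm(3 * 1280 * 9), c(3, 1280, 9))
  p <- predict(m, x)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  expect_true(all(p >= 0))
  m$params[["head.W2"]][] <- 0
  m$params[["head.b2"]][] <- 0
  expect_equal(unname(predict(m, x)), matrix(0.25, 3, 4), tolerance = 1e-12)
})

test_that("shared-weight evaluation is antisymmetric under branch swap", {
  m <- dualcnn_init(dualcnn_architecture(weight_sharing = "shared"), seed = 5)
  set.seed(2)
  x <- array(rnorm(2 * 1280 * 9), c(2, 1280, 9))
  xs <- x
  xs[, 1:640, ] <- x[, 641:1280, ]
  xs[, 641:1280, ] <- x[, 1:640, ]
  f <- predict(m, x, type = "features")
  fs <- predict(m, xs, type = "features")
  expect_lt(max(abs(f + fs)), 1e-5)
  # identical branch inputs give exactly zero difference features
  xi <- x
  xi[, 641:1280, ] <- x[, 1:640, ]
  expect_equal(max(abs(predict(m, xi, type = "features"))), 0)
})

test_that("analytic gradients match numerical differentiation on a tiny network", {
  arch <- tiny_arch()
  m <- dualcnn_init(arch, seed = 3, classes = c("a", "b", "c"))
  geom <- hemidiff:::build_geometry(arch)
  set.seed(4)
  B <- 5
  XL <- matrix(rnorm(32 * B), 32)
  XR <- matrix(rnorm(32 * B), 32)
  y_idx <- c(1L, 2L, 3L, 1L, 2L)
  loss_at <- function(par) {
    mm <- m; mm$params <- par
    pp <- function(pfx) hemidiff:::pack_branch_params(par, pfx, 2, TRUE)
    st <- hemidiff:::dualcnn_step_cpp(XL, XR, pp("L"), pp("R"),
                                      par[["head.W1"]], par[["head.b1"]],
                                      par[["head.W2"]], par[["head.b2"]],
                                      attr(geom, "mat"), TRUE, FALSE,
                                      FALSE, 0, y_idx, 3L)
    st$loss
  }
  pp <- function(pfx) hemidiff:::pack_branch_params(m$params, pfx, 2, TRUE)
  st <- hemidiff:::dualcnn_step_cpp(XL, XR, pp("L"), pp("R"),
                                    m$params[["head.W1"]], m$params[["head.b1"]],
                                    m$params[["head.W2"]], m$params[["head.b2"]],
                                    attr(geom, "mat"), TRUE, FALSE,
                                    FALSE, 0, y_idx, 3L)
  grads <- c(list(head.W1 = st$dW1, head.b1 = as.numeric(st$db1),
                  head.W2 = st$dW2, head.b2 = as.numeric(st$db2)),
             hemidiff:::map_branch_grads(st$gradL, "L", TRUE),
             hemidiff:::map_branch_grads(st$gradR, "R", TRUE))
  eps <- 1e-6
  set.seed(9)
  for (nm in c("L.conv1.W", "R.conv2.W", "L.bn1.gamma", "R.bn2.beta",
               "head.W1", "head.W2", "head.b2", "L.conv1.b")) {
    g <- grads[[nm]]
    for (probe in sample(length(g), min(4, length(g)))) {
      pu <- m$params; pu[[nm]][probe] <- pu[[nm]][probe] + eps
      pd <- m$params; pd[[nm]][probe] <- pd[[nm]][probe] - eps
      num <- (loss_at(pu) - loss_at(pd)) / (2 * eps)
      expect_lt(abs(g[probe] - num), 1e-6 + 1e-4 * abs(num),
                label = sprintf("analytic-numeric gap for %s[%d]", nm, probe))
    }
  }
})

test_that("training reaches separability, starts at chance loss, and records history", {
  set.seed(2)
  n <- 40
  x <- array(rnorm(n * 1280 * 9), c(n, 1280, 9))
  y <- rep(c("T1", "T2"), each = n / 2)
  x[y == "T1", 1:640, ] <- x[y == "T1", 1:640, ] * 3
  fit <- dualcnn(x, y, arch = dualcnn_architecture(n_classes = 2),
                 tcfg = dualcnn_training(iterations = 150, seed = 4),
                 classes = c("T1", "T2"))
  expect_equal(nrow(fit$history), 150)
  expect_equal(fit$history$train_loss[1], log(2), tolerance = 0.15)
  expect_gte(max(fit$history$train_acc), 1)
  expect_equal(mean(predict(fit, x, type = "class") == y), 1)
  # 4-class chance-level initial loss
  m4 <- dualcnn_init(seed = 1)
  set.seed(3)
  xx <- array(rnorm(32 * 1280 * 9), c(32, 1280, 9))
  p <- predict(m4, xx)
  expect_equal(-mean(log(p[cbind(1:32, sample(4, 32, TRUE))])), log(4),
               tolerance = 0.15)
})

test_that("training is deterministic under a fixed seed and validates inputs", {
  set.seed(1)
  x <- array(rnorm(12 * 1280 * 9), c(12, 1280, 9))
  y <- rep(mi_classes(), 3)
  t1 <- dualcnn(x, y, tcfg = dualcnn_training(iterations = 5, seed = 77))
  t2 <- dualcnn(x, y, tcfg = dualcnn_training(iterations = 5, seed = 77))
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
  m <- dualcnn_init()
  expect_error(dualcnn_train(m, x, rep("T1", 12)), "at least 2 classes")
  expect_error(dualcnn_train(m, x[0, , , drop = FALSE], character(0)),
               "at least 2 classes|empty")
  expect_error(predict(m, array(0, c(1, 100, 9))), "expected trials")
})

test_that("model methods print, summarize, plot, and simulate", {
  set.seed(6)
  x <- array(rnorm(12 * 1280 * 9), c(12, 1280, 9))
  y <- rep(mi_classes(), 3)
  fit <- dualcnn(x, y, tcfg = dualcnn_training(iterations = 3, seed = 1))
  expect_output(print(fit), "trained, 3 iterations")
  expect_output(summary(fit), "Softmax")
  expect_named(coef(fit)["head.W1"], "head.W1")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  sims <- simulate(fit, nsim = 2, seed = 1, newdata = x)
  expect_equal(dim(sims), c(12L, 2L))
  expect_true(all(unlist(sims) %in% mi_classes()))
  h <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(fit, h)
  expect_equal(nrow(utils::read.csv(h)), 3)
})
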