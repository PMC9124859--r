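test_that("motor scouts have 20 disjoint vertices near their electrode projections", {
  fw <- small_forward()
  sc <- fw$scouts
  expect_length(sc$scouts, 18)
  sizes <- vapply(sc$scouts, function(s) length(s$vertex_indices), 0L)
  expect_true(all(sizes == 20))
  all_idx <- unlist(lapply(sc$scouts, `[[`, "vertex_indices"))
  expect_false(any(duplicated(all_idx)))      # disjoint by construction
  expect_identical(sc$pairing[, "left"], motor_scout_names()$left)
  expect_identical(sc$pairing[, "right"], motor_scout_names()$right)
  # geometric oracle, on a grid dense enough that greedy disjointness does
  # not displace the scouts: each centroid is close to the electrode's
  # radial cortical projection (within 1.5x the local grid spacing)
  montage <- default_montage()
  src <- cortical_source_space(3000, radius = 0.076)
  dense <- define_motor_scouts(src, montage)
  spacing <- sqrt(4 * pi * src$radius^2 / nrow(src$positions))
  for (nm in c("C3", "C4", "FC5", "CP2")) {
    e <- montage$positions[match(nm, montage$names), ]
    target <- e / sqrt(sum(e^2)) * src$radius
    centroid <- colMeans(src$positions[dense$scouts[[nm]]$vertex_indices, ])
    expect_lt(sqrt(sum((centroid - target)^2)), 1.5 * spacing)
  }
})

test_that("C3 and C4 scouts are mirror images on a symmetric grid", {
  src <- cortical_source_space(3000, radius = 0.076)
  scouts <- define_motor_scouts(src, default_montage())
  p3 <- src$positions[scouts$scouts[["C3"]]$vertex_indices, ]
  p4 <- src$positions[scouts$scouts[["C4"]]$vertex_indices, ]
  mirrored <- p3 %*% diag(c(-1, 1, 1))
  reorder <- apply(mirrored, 1, function(v)
    which.min(colSums((t(p4) - v)^2)))
  expect_equal(p4[reorder, ], mirrored, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("scout definition requires enough sources and known electrodes", {
  small_src <- cortical_source_space(100, radius = 0.07)
  expect_error(define_motor_scouts(small_src, default_montage()),
               "at least 360")
})

test_that("sign-aligned mean matches its direct oracle and the flip cases", {
  set.seed(5)
  s <- sin(seq(0, 8 * pi, length.out = 100))
  # 20 identical copies -> the series itself
  X <- matrix(rep(s, each = 20), 20)
  expect_equal(hemidiff:::sign_aligned_mean(X), s, tolerance = 1e-12)
  # 10 copies of s, 10 of -s -> s, not zero
  X2 <- rbind(matrix(rep(s, each = 10), 10), matrix(rep(-s, each = 10), 10))
  expect_equal(hemidiff:::sign_aligned_mean(X2), s, tolerance = 1e-12)
  # random series: equals an independently computed sign-aligned mean
  X3 <- matrix(rnorm(20 * 100), 20)
  oracle <- {
    sv <- svd(X3)
    pc <- sv$v[, 1] * sv$d[1]
    sg <- sign(X3 %*% pc)
    sg[sg == 0] <- 1
    if (sg[1] < 0) sg <- -sg
    colMeans(X3 * as.vector(sg))
  }
  expect_lt(max(abs(hemidiff:::sign_aligned_mean(X3) - oracle)), 1e-12)
})

test_that("scout extraction is shape-correct and index-checked", {
  fw <- small_forward()
  src_ep <- epoch_set(array(rnorm(2 * 500 * 64), c(2, 500, 64)),
                      c("T1", "T2"), 160, montage = NULL)
  sc <- extract_scout_series(src_ep, fw$scouts)
  expect_equal(dim(sc$series), c(2L, 18L, 64L))
  expect_identical(dimnames(sc$series)[[2]],
                   c(motor_scout_names()$left, motor_scout_names()$right))
  short <- epoch_set(array(0, c(1, 100, 10)), "T1", 160, montage = NULL)
  expect_error(extract_scout_series(short, fw$scouts), "out of range")
})

test_that("assemble and split are exact mutual inverses with the documented layout", {
  set.seed(9)
  arr <- array(rnorm(3 * 18 * 640), c(3, 18, 640),
               dimnames = list(NULL, c(motor_scout_names()$left,
                                       motor_scout_names()$right), NULL))
  asm <- assemble_input(arr)
  expect_equal(dim(asm$x), c(3L, 1280L, 9L))
  br <- split_branches(asm$x[2, , ])
  expect_equal(dim(br$left), c(640L, 9L))
  expect_equal(dim(br$right), c(640L, 9L))
  # round trip is bit-exact
  for (j in 1:9) {
    expect_identical(br$left[, j], arr[2, j, ])
    expect_identical(br$right[, j], arr[2, 9 + j, ])
  }
  # constant fill: left rows all ones, right rows all twos
  cst <- array(0, c(1, 18, 640), dimnames = dimnames(arr))
  cst[, 1:9, ] <- 1; cst[, 10:18, ] <- 2
  xc <- assemble_input(cst)$x[1, , ]
  expect_true(all(xc[1:640, ] == 1) && all(xc[641:1280, ] == 2))
  # swapping pair columns before assembly swaps both branches identically
  perm <- c(2, 1, 3:9)
  arrp <- arr[, c(perm, 9 + perm), , drop = FALSE]
  dimnames(arrp)[[2]] <- dimnames(arr)[[2]]
  brp <- split_branches(assemble_input(arrp)$x[1, , ])
  br1 <- split_branches(asm$x[1, , ])
  expect_identical(brp$left, br1$left[, perm])
  expect_identical(brp$right, br1$right[, perm])
  expect_error(split_branches(matrix(0, 1281, 9)), "even")
})

test_that("scout definitions serialize to JSON", {
  fw <- small_forward()
  f <- withr::local_tempfile(fileext = ".json")
  write_scouts_json(fw$scouts, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_length(js$scouts, 18)
  expect_equal(length(js$scouts$C3$vertex_indices), 20)
})
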