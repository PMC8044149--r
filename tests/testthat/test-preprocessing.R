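test_that("band-pass keeps in-band sinusoids and rejects out-of-band power", {
  inband <- bandpass_filter(sine_signal(0.055))
  # compare amplitudes away from the filter edges
  core <- 300:1700
  expect_gt(sd(inband$data[1, core]) / sd(sine_signal(0.055)$data[1, core]),
            0.95)
  expect_lt(sd(inband$data[1, core]) / sd(sine_signal(0.055)$data[1, core]),
            1.05)

  outband <- bandpass_filter(sine_signal(0.25))
  expect_lt(sd(outband$data[1, core]) / sd(sine_signal(0.25)$data[1, core]),
            0.05)

  flat <- graph_signal(matrix(5, 2, 400), 0.72)
  filtered <- bandpass_filter(flat)
  expect_lt(max(abs(filtered$data)), 1e-6)
  expect_lt(max(abs(rowMeans(filtered$data))), 1e-12)

  expect_error(bandpass_filter(flat, 0.04, 0.8), "Nyquist")
})

test_that("global signal regression removes the shared component", {
  # identical rows collapse to ~0
  same <- graph_signal(matrix(rep(sin(1:200 / 7), each = 3), 3, 200), 0.72)
  expect_lt(max(abs(global_signal_regression(same)$data)), 1e-10)

  # residuals are orthogonal to the global signal (normal equations)
  withr::with_seed(2, x <- graph_signal(matrix(rnorm(8 * 300), 8, 300), 0.72))
  res <- global_signal_regression(x)
  gl <- colMeans(x$data)
  expect_true(all(abs(res$data %*% gl) < 1e-8))
  expect_true(all(abs(res$data %*% rep(1, 300)) < 1e-8))

  expect_error(global_signal_regression(
    graph_signal(matrix(1, 3, 50), 0.72)), "constant")
})

test_that("bandpass + GSR commute with region permutation", {
  withr::with_seed(6, x <- graph_signal(matrix(rnorm(6 * 400), 6, 400), 0.72))
  pipe <- function(s) global_signal_regression(bandpass_filter(s))
  perm <- c(4, 1, 6, 2, 5, 3)
  direct <- pipe(graph_signal(x$data[perm, ], 0.72))
  permuted <- pipe(x)$data[perm, ]
  expect_equal(direct$data, permuted, tolerance = 1e-10)
})

test_that("session scaling maps to the target range and inverts exactly", {
  withr::with_seed(4, x <- graph_signal(matrix(runif(5 * 100, -2, 2), 5, 100),
                                        0.72))
  x$data[1, 1] <- -2; x$data[5, 100] <- 2
  mm <- scale_session(x, "minmax01")
  expect_equal(min(mm$data), 0)
  expect_equal(max(mm$data), 1)
  expect_equal(unscale_session(mm)$data, x$data, tolerance = 1e-10)

  zs <- scale_session(x, "zscore")
  expect_lt(abs(mean(zs$data)), 1e-10)
  expect_lt(abs(sd(as.vector(zs$data)) - 1), 1e-10)
  expect_equal(unscale_session(zs)$data, x$data, tolerance = 1e-10)

  expect_error(scale_session(graph_signal(matrix(3, 2, 10), 0.72)), "constant")
})

test_that("windowing yields T - t_p - t_f + 1 samples with contiguous pairs", {
  mk <- function(t_n) graph_signal(matrix(seq_len(2 * t_n), 2, t_n), 0.72)
  expect_equal(nrow(windowize(mk(1200), 30, 30)$index), 1141)
  expect_equal(nrow(windowize(mk(60), 30, 30)$index), 1)
  expect_equal(nrow(windowize(mk(600), 30, 30)$index), 541)
  expect_error(windowize(mk(50), 30, 30), "t_p \\+ t_f")

  ds <- windowize(mk(100), 10, 5)
  s <- get_sample(ds, 37)
  expect_equal(dim(s$input), c(2, 10))
  expect_equal(dim(s$target), c(2, 5))
  # input ends immediately before the target starts
  expect_equal(s$input[, 10] + 2, s$target[, 1])
})

test_that("chronological split reproduces the reference sample counts", {
  mk <- function(t_n) graph_signal(matrix(rnorm(2 * t_n), 2, t_n), 0.72)
  withr::with_seed(1, {
    ds <- split_samples(windowize(mk(1200), 30, 30))
  })
  counts <- table(ds$index$split)
  expect_equal(unname(counts[["train"]]), 912)
  expect_equal(unname(counts[["val"]]), 114)
  expect_equal(unname(counts[["test"]]), 114)

  withr::with_seed(2, {
    ds10 <- split_samples(windowize(replicate(10, mk(600), simplify = FALSE),
                                    30, 30))
  })
  expect_equal(sum(ds10$index$split == "test"), 540)

  ds_small <- split_samples(windowize(mk(19), 5, 5))  # 10 samples
  expect_equal(as.integer(table(ds_small$index$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
})

test_that("split preserves temporal order and partitions samples", {
  x <- graph_signal(matrix(rnorm(2 * 119), 2, 119), 0.72)  # 100 samples
  ds <- split_samples(windowize(x, 10, 10))
  idx <- ds$index
  expect_equal(as.integer(table(idx$split)[c("train", "val", "test")]),
               c(80L, 10L, 10L))
  # concatenating train|val|test in order recovers all samples exactly once
  expect_equal(c(idx$sample[idx$split == "train"],
                 idx$sample[idx$split == "val"],
                 idx$sample[idx$split == "test"]),
               seq_len(100))
  # temporal order: every train start precedes every test start
  expect_lt(max(idx$start[idx$split == "train"]),
            min(idx$start[idx$split == "test"]))
})

test_that("gapped split makes evaluation windows disjoint from training targets", {
  x <- graph_signal(matrix(rnorm(2 * 619), 2, 619), 0.72)  # 600 samples
  ds <- split_samples(windowize(x, 10, 10), gap = TRUE)
  idx <- ds$index
  expect_equal(sum(idx$split == "train"), 480)
  expect_equal(sum(idx$split == "val"), 40)
  expect_equal(sum(idx$split == "test"), 40)
  # no val/test input timepoint overlaps any training target timepoint
  expect_gte(min(idx$start[idx$split == "val"]),
             max(idx$start[idx$split == "train"]) + 10 + 10 + 1)
  # a gap larger than a partition is refused
  short <- windowize(graph_signal(matrix(rnorm(2 * 219), 2, 219), 0.72),
                     10, 10)
  expect_error(split_samples(short, gap = TRUE), "empty")
})
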