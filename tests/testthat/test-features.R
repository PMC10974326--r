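test_that("window counting reproduces the study arithmetic", {
  expect_identical(count_windows(250 * 180 * 4 * 10, 125), 14400L)
  expect_identical(count_windows(124, 125), 0L)
  expect_identical(count_windows(45000, 125), 360L)
  expect_error(count_windows(100, 0), "window_len")
})

test_that("constant and zero windows give closed-form features", {
  z <- rep(0, 125)
  expect_equal(unname(extract_features(z, z, z)), rep(0, 12))

  c5 <- rep(5, 125)
  f <- extract_features(c5, z, z, rectify_acc = TRUE)
  expect_equal(unname(f[c("Xsum", "Xstd", "Xmax")]), c(625, 0, 5))
  expect_equal(unname(f[c("dXsum", "dXstd", "dXmax")]), c(0, 0, 0))
})

test_that("features match an independent loop-based oracle", {
  loop_stats <- function(v) {
    s <- 0; for (x in v) s <- s + x
    m <- s / length(v)
    ss <- 0; for (x in v) ss <- ss + (x - m)^2
    mx <- v[1]; for (x in v) if (x > mx) mx <- x
    c(s, sqrt(ss / length(v)), mx)
  }
  set.seed(23)
  for (i in 1:25) {
    wx <- rnorm(125); wy <- rnorm(125); wz <- rnorm(125)
    f <- extract_features(wx, wy, wz, rectify_acc = TRUE)
    dx <- numeric(124)
    for (j in 1:124) dx[j] <- abs(wx[j + 1] - wx[j])
    oracle <- c(loop_stats(abs(wx)), loop_stats(dx),
                loop_stats(abs(wy)), loop_stats(abs(wz)))
    expect_equal(unname(f), oracle)
  }
})

test_that("features are scale-covariant", {
  set.seed(29)
  wx <- rnorm(125); wy <- rnorm(125); wz <- rnorm(125)
  f1 <- extract_features(wx, wy, wz)
  f3 <- extract_features(3 * wx, 3 * wy, 3 * wz)
  expect_equal(unname(f3), 3 * unname(f1))
})

test_that("the vectorized matrix path reproduces per-window extraction", {
  feats <- tiny_features()
  rec <- tiny_dataset()[[1]]$recording
  fx <- bandpass(rec$x, 250); fy <- bandpass(rec$y, 250)
  fz <- bandpass(rec$z, 250)
  for (w in c(1, 7, 40)) {
    idx <- ((w - 1) * 125 + 1):(w * 125)
    row <- feats[feats$participant == rec$participant_id &
                   feats$position == rec$position &
                   feats$window_index == w, feature_names()]
    expect_equal(unlist(row, use.names = FALSE),
                 unname(extract_features(fx[idx], fy[idx], fz[idx])))
  }
})

test_that("feature matrix dimensions, alignment and ordering invariants hold", {
  ds <- tiny_dataset()
  feats <- tiny_features()
  expect_identical(nrow(feats), 4L * count_windows(20 * 250, 125))
  expect_identical(names(feats)[1:12], feature_names())
  expect_true(all(feats$label %in% 0:1))
  expect_identical(nrow(feats), length(feats$label))

  # shuffling recording order preserves the multiset of (row, label) pairs
  feats_rev <- build_feature_matrix(rev(lapply(ds, `[[`, "recording")))
  key <- function(d) {
    k <- apply(round(as.matrix(d[, c(feature_names(), "label")]), 9), 1,
               paste, collapse = ",")
    sort(k)
  }
  expect_identical(key(feats), key(feats_rev))
})

test_that("mixed sample rates are rejected", {
  r1 <- tiny_dataset()[[1]]$recording
  r2 <- r1
  r2$sample_rate <- 100
  expect_error(build_feature_matrix(list(r1, r2)), "mixed sample rates")
})

test_that("feature CSV export round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tiny_features(), path)
  back <- read.csv(path)
  expect_identical(names(back)[1:12], feature_names())
  expect_equal(back$Xsum, tiny_features()$Xsum, tolerance = 1e-9)
})
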