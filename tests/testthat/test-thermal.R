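test_that("ambient estimation is the robust median", {
  expect_equal(estimate_ambient(radiometric_frame(matrix(25, 32, 32))), 25)
  px <- matrix(25, 100, 100)
  px[1:10, 1:10] <- 29                      # 1% contamination
  expect_equal(estimate_ambient(radiometric_frame(px)), 25)
  cb <- matrix(24, 32, 32); cb[, 17:32] <- 26
  expect_equal(estimate_ambient(radiometric_frame(cb)), 25)
})

# independent oracle: exhaustive pixel scan of the thresholded region
oracle_centroid <- function(px, threshold_excess) {
  amb <- median(px)
  acc_u <- 0; acc_v <- 0; acc_w <- 0
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      w <- px[i, j] - amb - threshold_excess
      if (w > 0) {
        acc_u <- acc_u + w * (j - 1)
        acc_v <- acc_v + w * (i - 1)
        acc_w <- acc_w + w
      }
    }
  }
  c(acc_u, acc_v) / acc_w
}

gauss_frame <- function(h, w, cu, cv, sigma, peak, ambient = 25) {
  U <- matrix(rep(0:(w - 1), each = h), h, w)
  V <- matrix(rep(0:(h - 1), w), h, w)
  radiometric_frame(
    ambient + peak * exp(-((U - cu)^2 + (V - cv)^2) / (2 * sigma^2)))
}

test_that("a single Gaussian hot spot is found at its weighted centroid", {
  fr <- gauss_frame(64, 128, cu = 64, cv = 32, sigma = 3, peak = 4)
  b <- detect_blobs(fr, threshold_excess = 1)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$u - 64), 0.1)
  expect_lt(abs(b$v - 32), 0.1)
  oc <- oracle_centroid(fr$pixels, 1)
  expect_equal(c(b$u, b$v), oc, tolerance = 1e-9)
  expect_gt(b$peak_excess, 3.5)
})

test_that("uniform frames yield no detections", {
  expect_equal(nrow(detect_blobs(radiometric_frame(matrix(25, 64, 64)))), 0)
})

test_that("two separated spots give two blobs at oracle centroids", {
  fr <- gauss_frame(64, 128, cu = 40, cv = 32, sigma = 3, peak = 4)
  U <- matrix(rep(0:127, each = 64), 64, 128)
  V <- matrix(rep(0:63, 128), 64, 128)
  px <- fr$pixels + 3 * exp(-((U - 80)^2 + (V - 32)^2) / (2 * 9))
  fr2 <- radiometric_frame(px)
  b <- detect_blobs(fr2, threshold_excess = 1)
  expect_equal(nrow(b), 2)
  # sorted by descending peak excess: the +4 spot first
  expect_lt(abs(b$u[1] - 40), 0.2)
  expect_lt(abs(b$u[2] - 80), 0.2)
})

test_that("detection count is invariant to constant pixel offsets", {
  fr <- gauss_frame(64, 128, cu = 64, cv = 32, sigma = 3, peak = 4)
  for (off in c(-10, 5, 40)) {
    b <- detect_blobs(radiometric_frame(fr$pixels + off))
    expect_equal(nrow(b), 1)
    expect_lt(abs(b$u - 64), 0.1)
  }
})

test_that("centers stay within 0.5 px under sensor noise", {
  set.seed(99)
  errs <- replicate(100, {
    fr <- gauss_frame(48, 48, cu = 24, cv = 20, sigma = 3, peak = 4)
    fr <- radiometric_frame(fr$pixels + rnorm(48 * 48, 0, 0.1))
    b <- detect_blobs(fr, threshold_excess = 1)
    if (nrow(b) == 1) sqrt((b$u - 24)^2 + (b$v - 20)^2) else Inf
  })
  expect_lt(max(errs), 0.5)
})

test_that("blob radius grows with spot size", {
  rs <- vapply(c(2, 3, 4, 6), function(s) {
    b <- detect_blobs(gauss_frame(96, 96, 48, 48, s, 4))
    b$r
  }, 0)
  expect_true(all(diff(rs) > 0))
})
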