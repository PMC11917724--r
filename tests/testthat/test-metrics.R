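test_that("SSIM satisfies its identities, symmetry, and closed forms", {
  set.seed(1)
  x <- array(runif(18^3, 0, 255), rep(18, 3))
  y <- array(runif(18^3, 0, 255), rep(18, 3))
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_gte(ssim(x, y), -1); expect_lte(ssim(x, y), 1)
  # constant images: all variances vanish -> luminance term only
  cfg <- metric_config()
  a <- array(100, rep(12, 3)); b <- array(200, rep(12, 3))
  expect_equal(ssim(a, b, cfg), (2 * 100 * 200 + cfg$c1) / (100^2 + 200^2 + cfg$c1))
  expect_error(ssim(x, array(0, rep(17, 3))), "shape")
  expect_error(ssim(array(0, rep(8, 3)), array(0, rep(8, 3))), "kernel")
})

test_that("SSIM local moments match a brute-force sliding-window oracle", {
  set.seed(2)
  x <- array(runif(16^3, 0, 255), rep(16, 3))
  kern <- neuroinpaint:::gaussian_kernel1d(11, 1.5)
  K3 <- outer(outer(kern, kern), kern)
  mu <- neuroinpaint:::separable_filter_valid(x, kern)
  xx <- neuroinpaint:::separable_filter_valid(x * x, kern)
  for (rep_i in 1:5) {
    p <- sample(1:6, 3, replace = TRUE)
    win <- x[p[1]:(p[1] + 10), p[2]:(p[2] + 10), p[3]:(p[3] + 10)]
    expect_equal(mu[p[1], p[2], p[3]], sum(K3 * win), tolerance = 1e-6)
    expect_equal(xx[p[1], p[2], p[3]], sum(K3 * win^2), tolerance = 1e-6)
  }
})

test_that("PSNR follows its conventions and handles the zero-error case", {
  cfg <- metric_config()
  x <- array(runif(1000, 0, 255), c(10, 10, 10))
  expect_identical(psnr(x, x, cfg), Inf)
  # MSE = M^2 -> 0 dB; MSE = M^2 / 10 -> 10 dB (squared peak)
  y0 <- array(x + 255 * (2 * (seq_len(1000) %% 2) - 1), dim(x))
  expect_equal(psnr(x, y0, cfg), 0)
  mse_target <- 255^2 / 10
  y10 <- array(x + sqrt(mse_target) * (2 * (seq_len(1000) %% 2) - 1), dim(x))
  expect_equal(psnr(x, y10, cfg), 10)
  # printed linear-peak convention is selectable and differs
  cfg_lin <- metric_config(psnr_convention = "linear_peak")
  expect_equal(psnr(x, y0, cfg_lin), 10 * log10(255 / 255^2))
})

test_that("Dice matches direct set counting", {
  X <- array(0, rep(16, 3)); X[4:6, 4:6, 4:6] <- 1
  expect_equal(dice(X, X), 1)
  Y <- array(0, rep(16, 3)); Y[10:12, 10:12, 10:12] <- 1
  expect_equal(dice(X, Y), 0)
  # |X| = |Y| = 8, |intersection| = 4 -> 0.5
  A <- array(0, rep(16, 3)); A[1:8, 1, 1] <- 1
  B <- array(0, rep(16, 3)); B[5:12, 1, 1] <- 1
  expect_equal(dice(A, B), 0.5)
  expect_equal(dice(A, B), dice(B, A))
  expect_error(dice(array(0, rep(16, 3)), array(0, rep(16, 3))), "empty")
  expect_error(dice(X, Y * 2), "binary")
})

test_that("HD95 matches the all-pairs brute-force oracle", {
  S <- array(0, rep(10, 3)); S[3:6, 3:6, 3:6] <- 1
  expect_equal(hd95(S, S, 1.0), 0)
  A <- array(0, rep(16, 3)); A[5, 5, 5] <- 1
  B <- array(0, rep(16, 3)); B[5, 8, 5] <- 1
  expect_equal(hd95(A, B, 1.0), 3.0)
  expect_equal(hd95(A, B, 0.7), 2.1)
  set.seed(3)
  for (i in 1:12) {
    M1 <- random_small_mask(c(12, 12, 12), sample(20:200, 1))
    M2 <- random_small_mask(c(12, 12, 12), sample(20:200, 1))
    bx <- neuroinpaint:::boundary_voxels(M1)
    by <- neuroinpaint:::boundary_voxels(M2)
    dA <- apply(bx, 1, function(p) min(sqrt(colSums((t(by) - p)^2))))
    dB <- apply(by, 1, function(p) min(sqrt(colSums((t(bx) - p)^2))))
    oracle <- max(quantile(dA, 0.95, type = 7), quantile(dB, 0.95, type = 7))
    expect_equal(hd95(M1, M2, 1.0), unname(oracle), tolerance = 1e-9)
    expect_equal(hd95(M1, M2, 1.0), hd95(M2, M1, 1.0))
  }
  expect_error(hd95(A, array(0, rep(16, 3))), "empty")
})

test_that("translating a mask away never decreases HD95", {
  X <- array(0, rep(20, 3)); X[8:12, 8:12, 8:12] <- 1
  prev <- -1
  for (shift in 0:6) {
    Y <- array(0, rep(20, 3)); Y[(8:12) + shift, 8:12, 8:12] <- 1
    h <- hd95(X, Y, 1.0)
    expect_gte(h, prev)
    prev <- h
  }
})

test_that("absolute-agreement ICC is calibrated on identical, offset, and null pairs", {
  v <- c(2.1, 5.0, 3.3, 9.4, 1.7)
  expect_equal(icc_a1(cbind(v, v)), 1)
  # offset lowers absolute agreement below 1 (consistency ICC would stay 1)
  expect_lt(icc_a1(cbind(v, v + 50)), 1)
  # hand-computed mean squares on the 5-subject offset example
  pairs <- cbind(v, v + 50)
  n <- 5; k <- 2
  grand <- mean(pairs)
  msr <- k * sum((rowMeans(pairs) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(pairs) - grand)^2) / (k - 1)
  mse <- (sum((pairs - grand)^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  expect_equal(icc_a1(pairs),
               (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
  # independent cross-check: base R anova mean squares give the same value
  pairs2 <- cbind(v, v + 50 + c(0.4, -0.2, 0.1, -0.3, 0.2))
  df <- data.frame(y = c(pairs2), subj = factor(rep(1:5, 2)),
                   meas = factor(rep(1:2, each = 5)))
  ms <- anova(stats::aov(y ~ subj + meas, df))$`Mean Sq`
  expect_equal(icc_a1(pairs2),
               (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3])))
  set.seed(4)
  z <- matrix(rnorm(20000), ncol = 2)
  expect_lt(abs(icc_a1(z)), 0.05)
  expect_error(icc_a1(cbind(1:2, 1:2)), "n >= 3")
  expect_error(icc_a1(cbind(rep(1, 5), rep(1, 5))), "zero total variance")
})

test_that("the evaluation report assembles image and label metrics", {
  p <- fixture_phantom(seed = 9, grid = 36)
  mask <- array(0, dim(p$intensity)); mask[14:22, 14:22, 14:22] <- 1
  rep1 <- evaluate_inpainting(p$intensity, p$intensity, mask,
                              p$labels, p$labels)
  expect_equal(rep1$ssim, 1)
  expect_identical(rep1$psnr, Inf)
  expect_true(all(rep1$dice == 1))
  expect_true(all(rep1$hd95 == 0, na.rm = TRUE))
  # a label missing from the test segmentation: dice 0, hd95 missing, no crash
  test_lab <- p$labels
  in_mask_labs <- sort(unique(p$labels[mask > 0]))
  drop_lab <- in_mask_labs[1]
  other <- setdiff(in_mask_labs, drop_lab)[1]
  test_lab[test_lab == drop_lab & mask > 0] <- other
  rep2 <- evaluate_inpainting(p$intensity, p$intensity, mask, p$labels, test_lab)
  expect_equal(unname(rep2$dice[as.character(drop_lab)]), 0)
  expect_true(is.na(rep2$hd95[as.character(drop_lab)]))
  lines <- write_eval_report(rep2)
  expect_true(any(grepl("^psnr_db\t", lines)))
  expect_true(any(grepl("^hd95_mm\tmean\t", lines)))
  expect_error(evaluate_inpainting(p$intensity, p$intensity,
                                   array(0, dim(p$intensity))), "empty")
})
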