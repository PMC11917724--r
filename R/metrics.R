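# Evaluation metrics: SSIM, PSNR, Dice, 95th-percentile Hausdorff distance,
# absolute-agreement ICC, and the report assembler tying them together.

#' Metric configuration
#'
#' @param L Dynamic range of the intensity scale (default 255).
#' @param M Maximum representable value for PSNR (default 255).
#' @param kernel_size SSIM Gaussian window size (odd, default 11).
#' @param kernel_sd SSIM Gaussian standard deviation (default 1.5).
#' @param psnr_convention "squared_peak" (`20 log10(M) - 10 log10(MSE)`, the
#'   convention of standard image-quality frameworks; default) or
#'   "linear_peak" (`10 log10(M / MSE)`). The stability constants `c1 =
#'   (0.01 L)^2` and `c2 = (0.03 L)^2` are derived, never set directly.
#' @return A `metric_config` list.
#' @export
metric_config <- function(L = 255, M = 255, kernel_size = 11, kernel_sd = 1.5,
                          psnr_convention = c("squared_peak", "linear_peak")) {
  psnr_convention <- match.arg(psnr_convention)
  stopifnot_scalar(L, "L", positive = TRUE)
  stopifnot_scalar(M, "M", positive = TRUE)
  stopifnot_scalar(kernel_size, "kernel_size", positive = TRUE, integerish = TRUE)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd", call. = FALSE)
  structure(list(L = L, M = M, kernel_size = as.integer(kernel_size),
                 kernel_sd = kernel_sd, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2,
                 psnr_convention = psnr_convention),
            class = "metric_config")
}

gaussian_kernel1d <- function(size, sd) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

# separable valid-mode filtering along every axis of a 2D/3D array
separable_filter_valid <- function(a, kern) {
  d <- dim(a)
  ks <- length(kern)
  for (ax in seq_along(d)) {
    n <- d[ax]
    nv <- n - ks + 1
    Fm <- matrix(0, nv, n)
    for (i in seq_len(nv)) Fm[i, i:(i + ks - 1)] <- kern
    a <- if (length(d) == 2) {
      if (ax == 1) Fm %*% a else a %*% t(Fm)
    } else {
      m <- apply(a, setdiff(1:3, ax), function(v) Fm %*% v)
      dim(m) <- c(nv, d[setdiff(1:3, ax)])
      aperm(m, order(c(ax, setdiff(1:3, ax))))
    }
    d <- dim(a)
  }
  a
}

#' Structural similarity index (SSIM)
#'
#' Mean over all (valid) window positions of
#' `(2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' with Gaussian-weighted local moments (window 11, sd 1.5 by default).
#' Symmetric in its arguments; 1 for identical images.
#'
#' @param x,y 2D or 3D arrays of identical shape on the 0-255 scale.
#' @param config A [metric_config()].
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(x, y, config = metric_config()) {
  if (!identical(dim(x), dim(y))) stop("x and y must have the same shape", call. = FALSE)
  if (any(dim(x) < config$kernel_size)) {
    stop("image smaller than the SSIM kernel", call. = FALSE)
  }
  kern <- gaussian_kernel1d(config$kernel_size, config$kernel_sd)
  mu_x <- separable_filter_valid(x, kern)
  mu_y <- separable_filter_valid(y, kern)
  xx <- separable_filter_valid(x * x, kern)
  yy <- separable_filter_valid(y * y, kern)
  xy <- separable_filter_valid(x * y, kern)
  sx <- xx - mu_x^2
  sy <- yy - mu_y^2
  sxy <- xy - mu_x * mu_y
  num <- (2 * mu_x * mu_y + config$c1) * (2 * sxy + config$c2)
  den <- (mu_x^2 + mu_y^2 + config$c1) * (sx + sy + config$c2)
  mean(num / den)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' @inheritParams ssim
#' @return PSNR in dB; `Inf` when the images are identical (MSE = 0). Under
#'   the default squared-peak convention `20 log10(M) - 10 log10(MSE)`; the
#'   linear-peak convention computes `10 log10(M / MSE)`.
#' @export
psnr <- function(x, y, config = metric_config()) {
  if (!identical(dim(x), dim(y))) stop("x and y must have the same shape", call. = FALSE)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  if (config$psnr_convention == "squared_peak") {
    20 * log10(config$M) - 10 * log10(mse)
  } else {
    10 * log10(config$M / mse)
  }
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC(X, Y) = 2 |X intersect Y| / (|X| + |Y|)`.
#'
#' @param X,Y Binary arrays of identical shape.
#' @return Value in \[0, 1\]; errors when both masks are empty (undefined).
#' @export
dice <- function(X, Y) {
  if (!identical(dim(X), dim(Y))) stop("masks must share the same grid", call. = FALSE)
  if (!all(X %in% c(0, 1)) || !all(Y %in% c(0, 1))) {
    stop("masks must be binary", call. = FALSE)
  }
  nx <- sum(X); ny <- sum(Y)
  if (nx + ny == 0) stop("Dice undefined: both masks are empty", call. = FALSE)
  2 * sum(X * Y) / (nx + ny)
}

# boundary voxels: positive with at least one face-adjacent zero (the grid
# edge counts as zero, so masks touching the border have a boundary there)
boundary_voxels <- function(X) {
  inner <- array(TRUE, dim(X))
  for (r in seq_len(nrow(neighbor_offsets(6)))) {
    o <- neighbor_offsets(6)[r, ]
    inner <- inner & shift_array(X, o[1], o[2], o[3], fill = 0) > 0
  }
  which(X > 0 & !inner, arr.ind = TRUE)
}

directed_percentile_distance <- function(A, B, voxel_size, prob) {
  # A, B: n x 3 integer coordinate matrices
  nA <- nrow(A)
  dmin <- numeric(nA)
  chunk <- 512L
  Bt <- t(B) * voxel_size
  bb <- colSums(Bt^2)
  for (i0 in seq(1, nA, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nA)
    Ac <- A[i0:i1, , drop = FALSE] * voxel_size
    d2 <- outer(rowSums(Ac^2), bb, "+") - 2 * Ac %*% Bt
    dmin[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  as.numeric(stats::quantile(dmin, prob, type = 7))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Extracts face-adjacency boundary voxels of both masks, computes directed
#' Euclidean nearest-boundary distances in each direction, takes the 95th
#' percentile (linear interpolation) of each, and returns the maximum of the
#' two. 0 for identical masks.
#'
#' @param X,Y Nonempty binary arrays on the same grid.
#' @param voxel_size Isotropic voxel size in mm.
#' @param prob Percentile (default 0.95).
#' @return Distance in mm.
#' @export
hd95 <- function(X, Y, voxel_size = 1.0, prob = 0.95) {
  if (!identical(dim(X), dim(Y))) stop("masks must share the same grid", call. = FALSE)
  if (sum(X) == 0 || sum(Y) == 0) {
    stop("Hausdorff distance undefined for an empty mask", call. = FALSE)
  }
  bx <- boundary_voxels(X)
  by <- boundary_voxels(Y)
  max(directed_percentile_distance(bx, by, voxel_size, prob),
      directed_percentile_distance(by, bx, voxel_size, prob))
}

#' Two-way random-effects absolute-agreement single-measurement ICC
#'
#' ICC(A,1): with row (subject) mean square MS_R, column (measurement) mean
#' square MS_C, error mean square MS_E and k measurements,
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`. Unlike the
#' consistency ICC, a constant offset between the two measurements lowers the
#' value; identical non-constant measurements give exactly 1. May be negative.
#'
#' @param pairs n x 2 numeric matrix (n >= 3 subjects, 2 paired measurements).
#' @return ICC value.
#' @export
icc_a1 <- function(pairs) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  k <- ncol(pairs)
  if (n < 3 || k != 2) stop("pairs must be an n x 2 matrix with n >= 3", call. = FALSE)
  if (!all(is.finite(pairs))) stop("pairs must be finite", call. = FALSE)
  grand <- mean(pairs)
  sst <- sum((pairs - grand)^2)
  if (sst == 0) stop("ICC undefined: zero total variance", call. = FALSE)
  ssr <- k * sum((rowMeans(pairs) - grand)^2)
  ssc <- n * sum((colMeans(pairs) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

mask_bounding_box <- function(mask, pad = 0) {
  d <- dim(mask)
  ind <- which(mask > 0, arr.ind = TRUE)
  lo <- pmax(apply(ind, 2, min) - pad, 1)
  hi <- pmin(apply(ind, 2, max) + pad, d)
  list(lo = lo, hi = hi)
}

#' Evaluate inpainting quality against the pre-lesion reference
#'
#' Image metrics (SSIM, PSNR) are computed over the lesion bounding box
#' dilated by half the SSIM kernel (the only region where methods can differ,
#' given that the exterior is conserved). Segmentation metrics (Dice, HD95)
#' are computed per label between `test_labels` and `ref_labels` restricted
#' to the mask, plus unweighted means. A label present in the reference but
#' missing from the test segmentation scores Dice 0 and a missing HD95.
#'
#' @param original Pre-lesion intensity volume (0-255).
#' @param inpainted Inpainted intensity volume.
#' @param mask Binary lesion mask.
#' @param ref_labels,test_labels Integer label volumes (reference truth and
#'   segmentation of the inpainted image); NULL to skip label metrics.
#' @param config A [metric_config()].
#' @param voxel_size Voxel size in mm for HD95.
#' @return An `eval_report` list with `psnr`, `ssim`, `dice` / `hd95` per
#'   label and their means, `region`, and the PSNR convention used.
#' @export
evaluate_inpainting <- function(original, inpainted, mask, ref_labels = NULL,
                                test_labels = NULL, config = metric_config(),
                                voxel_size = 1.0) {
  if (!identical(dim(original), dim(inpainted)) ||
      !identical(dim(original), dim(mask))) {
    stop("original, inpainted and mask must share the same grid", call. = FALSE)
  }
  if (!any(mask > 0)) stop("mask is empty: nothing was inpainted", call. = FALSE)
  pad <- config$kernel_size %/% 2
  bb <- mask_bounding_box(mask, pad = pad)
  # grow the box to hold at least one SSIM window
  for (ax in 1:3) {
    need <- config$kernel_size - (bb$hi[ax] - bb$lo[ax] + 1)
    if (need > 0) {
      bb$lo[ax] <- max(1, bb$lo[ax] - ceiling(need / 2))
      bb$hi[ax] <- min(dim(mask)[ax], bb$lo[ax] + config$kernel_size - 1)
      bb$lo[ax] <- bb$hi[ax] - config$kernel_size + 1
    }
  }
  sub <- function(a) a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
  rep_ssim <- ssim(sub(original), sub(inpainted), config)
  rep_psnr <- psnr(sub(original), sub(inpainted), config)

  dice_tab <- hd_tab <- NULL
  if (!is.null(ref_labels) && !is.null(test_labels)) {
    labs <- sort(unique(ref_labels[mask > 0]))
    dice_tab <- stats::setNames(numeric(length(labs)), labs)
    hd_tab <- stats::setNames(rep(NA_real_, length(labs)), labs)
    for (i in seq_along(labs)) {
      Xr <- array(as.numeric(ref_labels == labs[i] & mask > 0), dim(mask))
      Xt <- array(as.numeric(test_labels == labs[i] & mask > 0), dim(mask))
      if (sum(Xt) == 0) {
        dice_tab[i] <- 0          # label absent from the test segmentation
      } else {
        dice_tab[i] <- dice(Xr, Xt)
        hd_tab[i] <- hd95(Xr, Xt, voxel_size)
      }
    }
  }
  structure(list(
    psnr = rep_psnr, ssim = rep_ssim,
    dice = dice_tab, dice_mean = if (is.null(dice_tab)) NA_real_ else mean(dice_tab),
    hd95 = hd_tab,
    hd95_mean = if (is.null(hd_tab) || all(is.na(hd_tab))) NA_real_
                else mean(hd_tab, na.rm = TRUE),
    region = sprintf("lesion bounding box + %d voxels", pad),
    psnr_convention = config$psnr_convention,
    voxel_size = voxel_size
  ), class = "eval_report")
}

#' Serialize an evaluation report as delimited text
#'
#' @param report An `eval_report`.
#' @param path Output file; NULL returns the lines invisibly.
#' @return The TSV lines, invisibly.
#' @export
write_eval_report <- function(report, path = NULL) {
  lines <- c(
    "metric\tlabel\tvalue",
    sprintf("psnr_db\t-\t%.6g", report$psnr),
    sprintf("ssim\t-\t%.6g", report$ssim),
    sprintf("psnr_convention\t-\t%s", report$psnr_convention),
    sprintf("region\t-\t%s", report$region)
  )
  if (!is.null(report$dice)) {
    lines <- c(lines,
               sprintf("dice\t%s\t%.6g", names(report$dice), report$dice),
               sprintf("dice\tmean\t%.6g", report$dice_mean),
               sprintf("hd95_mm\t%s\t%.6g", names(report$hd95), report$hd95),
               sprintf("hd95_mm\tmean\t%.6g", report$hd95_mean))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
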