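# The 2D slab denoiser: a U-Net-style noise predictor whose outermost
# down/up-sampling pair is a voxel-size-adaptive (VINN) bilinear resampling
# that normalizes feature-map spacing to a fixed internal resolution, so a
# single set of weights serves 0.7-1.0 mm inputs. Implemented directly on
# BLAS matrix primitives: im2col convolution, matrix-form pooling/resampling,
# and a hand-written Adam optimizer.

#' Configure the slab denoiser
#'
#' @param slab_thickness Slices per input slab (odd, >= 1; default 7). The
#'   slab enters the 2D network as channels, and noise is predicted for all
#'   of its slices.
#' @param internal_voxel_size Normalized internal resolution rho in mm
#'   (default 1.0): feature maps are resampled so their spacing matches rho.
#' @param base_channels Feature channels at the first scale.
#' @param depth Number of scales (>= 2); the first transition is the VINN
#'   resampling, deeper transitions are fixed factor-2 pooling/unpooling.
#' @param time_embedding_dim Sinusoidal timestep embedding size (even).
#' @return A `vinn_config` list.
#' @export
vinn_config <- function(slab_thickness = 7, internal_voxel_size = 1.0,
                        base_channels = 8, depth = 2, time_embedding_dim = 16) {
  stopifnot_scalar(slab_thickness, "slab_thickness", positive = TRUE, integerish = TRUE)
  if (slab_thickness %% 2 == 0) stop("slab_thickness must be odd", call. = FALSE)
  stopifnot_scalar(internal_voxel_size, "internal_voxel_size", positive = TRUE)
  stopifnot_scalar(depth, "depth", positive = TRUE, integerish = TRUE)
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  if (time_embedding_dim %% 2 != 0) stop("time_embedding_dim must be even", call. = FALSE)
  structure(list(slab_thickness = as.integer(slab_thickness),
                 internal_voxel_size = internal_voxel_size,
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 time_embedding_dim = as.integer(time_embedding_dim)),
            class = "vinn_config")
}

#' Voxel-size scale factor for VINN resampling
#'
#' @param voxel_size Input voxel size in mm (> 0).
#' @param rho_norm Internal normalized voxel size in mm (> 0).
#' @return `voxel_size / rho_norm`; a 0.7 mm input yields 0.7, shrinking its
#'   feature grid to match 1.0 mm spacing.
#' @export
vinn_scale_factor <- function(voxel_size, rho_norm = 1.0) {
  stopifnot_scalar(voxel_size, "voxel_size", positive = TRUE)
  stopifnot_scalar(rho_norm, "rho_norm", positive = TRUE)
  voxel_size / rho_norm
}

# corner-aligned linear interpolation matrix (n_out x n_in)
bilinear_axis_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  if (n_out == 1 || n_in == 1) {
    M[] <- 1 / n_in
    return(M)
  }
  pos <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(pos), n_in - 2)
  w <- pos - i0
  for (i in seq_len(n_out)) {
    M[i, i0[i] + 1] <- 1 - w[i]
    M[i, i0[i] + 2] <- w[i]
  }
  M
}

pool_axis_matrix <- function(n_in) {
  n_out <- ceiling(n_in / 2)
  M <- matrix(0, n_out, n_in)
  for (r in seq_len(n_out)) {
    cols <- (2 * r - 1):min(2 * r, n_in)
    M[r, cols] <- 1 / length(cols)
  }
  M
}

unpool_axis_matrix <- function(n_fine, n_coarse) {
  M <- matrix(0, n_fine, n_coarse)
  M[cbind(seq_len(n_fine), pmin(ceiling(seq_len(n_fine) / 2), n_coarse))] <- 1
  M
}

# out = A %*% channel %*% t(B) for every channel of X ((H*W) x C)
spatial_apply <- function(X, H, W, A, B) {
  C <- ncol(X)
  Ho <- nrow(A); Wo <- nrow(B)
  out <- matrix(0, Ho * Wo, C)
  for (c in seq_len(C)) {
    out[, c] <- as.vector(A %*% matrix(X[, c], H, W) %*% t(B))
  }
  out
}

#' Resample a feature map by a voxel-size factor
#'
#' Bilinear, corner-aligned interpolation of each channel to the rescaled
#' spatial shape (`round half up`, minimum 4 per axis). `direction = "inward"`
#' applies the factor, `"outward"` applies its reciprocal; supplying
#' `target_shape` (as the network does with the cached pre-VINN shape)
#' restores the original shape exactly.
#'
#' @param feature_map H x W matrix or H x W x C array.
#' @param factor Positive scale factor (see [vinn_scale_factor()]).
#' @param direction "inward" or "outward".
#' @param target_shape Optional explicit c(H, W) output shape.
#' @return Resampled map of the same type.
#' @export
vinn_resample <- function(feature_map, factor, direction = c("inward", "outward"),
                          target_shape = NULL) {
  direction <- match.arg(direction)
  stopifnot_scalar(factor, "factor", positive = TRUE)
  was_matrix <- is.matrix(feature_map)
  if (was_matrix) dim(feature_map) <- c(dim(feature_map), 1L)
  d <- dim(feature_map)
  f <- if (direction == "inward") factor else 1 / factor
  new_shape <- if (!is.null(target_shape)) as.integer(target_shape[1:2])
  else as.integer(round_half_up(d[1:2] * f))
  if (any(new_shape < 4)) {
    stop("resampled spatial shape would fall below 4 voxels", call. = FALSE)
  }
  A <- bilinear_axis_matrix(new_shape[1], d[1])
  B <- bilinear_axis_matrix(new_shape[2], d[2])
  X <- matrix(feature_map, d[1] * d[2], d[3])
  out <- array(spatial_apply(X, d[1], d[2], A, B), c(new_shape, d[3]))
  if (was_matrix) dim(out) <- new_shape
  out
}

# --- parameter initialization ---------------------------------------------

level_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1)

#' Build a slab denoiser
#'
#' Network layout: 3x3 input convolution, VINN inward resampling to the
#' internal resolution, `depth` residual conv blocks connected by factor-2
#' average pooling, a mirrored decoder with nearest-neighbor unpooling and
#' skip connections, VINN outward resampling back to the input grid, and a
#' zero-initialized 3x3 output convolution. The timestep enters through a
#' sinusoidal embedding (with the voxel size appended as a scalar conditioning
#' term) projected to a per-channel bias in every block. The parameter count
#' is independent of input grid size and voxel size.
#'
#' @param config A [vinn_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `vinn_denoiser` model object (config + parameter environment).
#' @export
build_denoiser <- function(config = vinn_config(), seed = 1) {
  stopifnot(inherits(config, "vinn_config"))
  Cin <- config$slab_thickness
  ch <- level_channels(config)
  E <- config$time_embedding_dim + 1L  # + voxel-size term
  params <- with_seed(seed, {
    p <- list()
    rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
    conv_init <- function(cin, cout) rn(9 * cin, cout, sqrt(2 / (9 * cin)))
    p$conv_in_W <- conv_init(Cin, ch[1]); p$conv_in_b <- numeric(ch[1])
    block_init <- function(prefix, cin, cout) {
      p[[paste0(prefix, "_c1_W")]] <<- conv_init(cin, cout)
      p[[paste0(prefix, "_c1_b")]] <<- numeric(cout)
      p[[paste0(prefix, "_c2_W")]] <<- conv_init(cout, cout)
      p[[paste0(prefix, "_c2_b")]] <<- numeric(cout)
      p[[paste0(prefix, "_emb_W")]] <<- rn(E, cout, 1 / sqrt(E))
      if (cin != cout) p[[paste0(prefix, "_sc_W")]] <<- rn(cin, cout, sqrt(1 / cin))
    }
    block_init("enc1", ch[1], ch[1])
    for (l in 2:config$depth) block_init(paste0("enc", l), ch[l - 1], ch[l])
    for (l in (config$depth - 1):1) {
      block_init(paste0("dec", l), ch[l + 1] + ch[l], ch[l])
    }
    p$conv_out_W <- matrix(0, 9 * ch[1], Cin)
    p$conv_out_b <- numeric(Cin)
    p
  })
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$adam_m <- lapply(params, function(x) x * 0)
  env$adam_v <- lapply(params, function(x) x * 0)
  env$last_latent_shape <- NULL
  structure(list(config = config, env = env, seed = as.integer(seed)),
            class = "vinn_denoiser")
}

# --- convolution primitives ------------------------------------------------

im2col_indices <- function(H, W) {
  idx <- vector("list", 9)
  k <- 1
  for (dj in 0:2) for (di in 0:2) {
    rows <- rep(di + seq_len(H), times = W)
    cols <- rep(dj + seq_len(W), each = H)
    idx[[k]] <- rows + (cols - 1) * (H + 2)
    k <- k + 1
  }
  interior <- rep(1 + seq_len(H), times = W) + (rep(seq_len(W), each = H)) * (H + 2)
  list(offsets = idx, interior = interior, H = H, W = W)
}

conv3_forward <- function(X, H, W, Wmat, b, idx) {
  C <- ncol(X)
  Xp <- matrix(0, (H + 2) * (W + 2), C)
  Xp[idx$interior, ] <- X
  cols <- matrix(0, H * W, 9 * C)
  for (k in 1:9) cols[, ((k - 1) * C + 1):(k * C)] <- Xp[idx$offsets[[k]], ]
  out <- cols %*% Wmat
  out <- sweep(out, 2, b, "+")
  list(out = out, cols = cols)
}

conv3_backward <- function(dOut, cols, Wmat, H, W, C, idx) {
  dW <- crossprod(cols, dOut)
  db <- colSums(dOut)
  dCols <- dOut %*% t(Wmat)
  dXp <- matrix(0, (H + 2) * (W + 2), C)
  for (k in 1:9) {
    dXp[idx$offsets[[k]], ] <- dXp[idx$offsets[[k]], ] +
      dCols[, ((k - 1) * C + 1):(k * C)]
  }
  list(dX = dXp[idx$interior, , drop = FALSE], dW = dW, db = db)
}

silu <- function(x) {
  s <- 1 / (1 + exp(-x))
  x * s
}

silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

time_embedding <- function(t, voxel_size, dim) {
  half <- dim / 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  c(sin(t * freqs), cos(t * freqs), voxel_size - 1)
}

# --- forward / backward ----------------------------------------------------

block_forward <- function(p, prefix, X, H, W, emb, idx) {
  c1 <- conv3_forward(X, H, W, p[[paste0(prefix, "_c1_W")]],
                      p[[paste0(prefix, "_c1_b")]], idx)
  ebias <- as.vector(emb %*% p[[paste0(prefix, "_emb_W")]])
  pre <- sweep(c1$out, 2, ebias, "+")
  h <- silu(pre)
  c2 <- conv3_forward(h, H, W, p[[paste0(prefix, "_c2_W")]],
                      p[[paste0(prefix, "_c2_b")]], idx)
  scW <- p[[paste0(prefix, "_sc_W")]]
  sc <- if (is.null(scW)) X else X %*% scW
  pre2 <- c2$out + sc
  out <- silu(pre2)
  list(out = out, X = X, pre = pre, h = h, pre2 = pre2,
       cols1 = c1$cols, cols2 = c2$cols)
}

block_backward <- function(p, prefix, cache, dOut, H, W, emb, idx, grads) {
  dPre2 <- dOut * silu_grad(cache$pre2)
  Ch <- ncol(cache$h)
  Cx <- ncol(cache$X)
  bw2 <- conv3_backward(dPre2, cache$cols2, p[[paste0(prefix, "_c2_W")]],
                        H, W, Ch, idx)
  grads[[paste0(prefix, "_c2_W")]] <- bw2$dW
  grads[[paste0(prefix, "_c2_b")]] <- bw2$db
  scW <- p[[paste0(prefix, "_sc_W")]]
  if (is.null(scW)) {
    dX_sc <- dPre2
  } else {
    grads[[paste0(prefix, "_sc_W")]] <- crossprod(cache$X, dPre2)
    dX_sc <- dPre2 %*% t(scW)
  }
  dPre <- bw2$dX * silu_grad(cache$pre)
  grads[[paste0(prefix, "_emb_W")]] <- outer(emb, colSums(dPre))
  bw1 <- conv3_backward(dPre, cache$cols1, p[[paste0(prefix, "_c1_W")]],
                        H, W, Cx, idx)
  grads[[paste0(prefix, "_c1_W")]] <- bw1$dW
  grads[[paste0(prefix, "_c1_b")]] <- bw1$db
  list(dX = bw1$dX + dX_sc, grads = grads)
}

denoiser_forward <- function(model, slab, t, voxel_size, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$env$params
  d <- dim(slab)
  if (length(d) != 3L || d[3] != cfg$slab_thickness) {
    stop("slab must be H x W x slab_thickness with the configured thickness",
         call. = FALSE)
  }
  if (d[1] < 16 || d[2] < 16) stop("slab spatial extent must be >= 16", call. = FALSE)
  H <- d[1]; W <- d[2]
  emb <- time_embedding(t, voxel_size, cfg$time_embedding_dim)
  factor <- vinn_scale_factor(voxel_size, cfg$internal_voxel_size)
  cache <- list(H = H, W = W, emb = emb, factor = factor)

  idx0 <- im2col_indices(H, W)
  X <- matrix(slab, H * W, cfg$slab_thickness)
  cin <- conv3_forward(X, H, W, p$conv_in_W, p$conv_in_b, idx0)
  cache$cols_in <- cin$cols

  # VINN inward: normalize spacing to the internal resolution
  Hv <- max(4L, as.integer(round_half_up(H * factor)))
  Wv <- max(4L, as.integer(round_half_up(W * factor)))
  Ain <- bilinear_axis_matrix(Hv, H); Bin <- bilinear_axis_matrix(Wv, W)
  h <- spatial_apply(cin$out, H, W, Ain, Bin)
  model$env$last_latent_shape <- c(Hv, Wv)
  cache$Ain <- Ain; cache$Bin <- Bin; cache$Hv <- Hv; cache$Wv <- Wv

  shapes <- list(c(Hv, Wv))
  idxs <- list(im2col_indices(Hv, Wv))
  enc <- vector("list", cfg$depth)
  enc[[1]] <- block_forward(p, "enc1", h, Hv, Wv, emb, idxs[[1]])
  pools <- vector("list", cfg$depth)
  cur <- enc[[1]]$out
  for (l in 2:cfg$depth) {
    sh <- shapes[[l - 1]]
    A <- pool_axis_matrix(sh[1]); B <- pool_axis_matrix(sh[2])
    pooled <- spatial_apply(cur, sh[1], sh[2], A, B)
    shapes[[l]] <- c(nrow(A), nrow(B))
    idxs[[l]] <- im2col_indices(shapes[[l]][1], shapes[[l]][2])
    pools[[l]] <- list(A = A, B = B)
    enc[[l]] <- block_forward(p, paste0("enc", l), pooled,
                              shapes[[l]][1], shapes[[l]][2], emb, idxs[[l]])
    cur <- enc[[l]]$out
  }
  dec <- vector("list", cfg$depth)
  ups <- vector("list", cfg$depth)
  for (l in (cfg$depth - 1):1) {
    shc <- shapes[[l + 1]]; shf <- shapes[[l]]
    U <- unpool_axis_matrix(shf[1], shc[1]); V <- unpool_axis_matrix(shf[2], shc[2])
    up <- spatial_apply(cur, shc[1], shc[2], U, V)
    ups[[l]] <- list(U = U, V = V)
    cat_in <- cbind(up, enc[[l]]$out)
    dec[[l]] <- block_forward(p, paste0("dec", l), cat_in, shf[1], shf[2],
                              emb, idxs[[l]])
    cur <- dec[[l]]$out
  }

  # VINN outward: restore the exact input shape
  Aout <- bilinear_axis_matrix(H, Hv); Bout <- bilinear_axis_matrix(W, Wv)
  hv <- spatial_apply(cur, Hv, Wv, Aout, Bout)
  cache$Aout <- Aout; cache$Bout <- Bout
  cout <- conv3_forward(hv, H, W, p$conv_out_W, p$conv_out_b, idx0)
  out <- array(cout$out, d)

  if (!keep_cache) return(list(out = out))
  cache$idx0 <- idx0; cache$idxs <- idxs; cache$shapes <- shapes
  cache$enc <- enc; cache$dec <- dec; cache$pools <- pools; cache$ups <- ups
  cache$cols_out <- cout$cols
  cache$hv_in <- cur
  list(out = out, cache = cache)
}

denoiser_backward <- function(model, fw, dOut) {
  cfg <- model$config
  p <- model$env$params
  ca <- fw$cache
  H <- ca$H; W <- ca$W; emb <- ca$emb
  grads <- list()
  dOut <- matrix(dOut, H * W, cfg$slab_thickness)

  ch1 <- cfg$base_channels
  bwo <- conv3_backward(dOut, ca$cols_out, p$conv_out_W, H, W, ch1, ca$idx0)
  grads$conv_out_W <- bwo$dW; grads$conv_out_b <- bwo$db
  # through VINN outward
  dCur <- spatial_apply(bwo$dX, H, W, t(ca$Aout), t(ca$Bout))

  dEnc <- vector("list", cfg$depth)
  for (l in 1:(cfg$depth - 1)) {
    shf <- ca$shapes[[l]]
    bb <- block_backward(p, paste0("dec", l), ca$dec[[l]], dCur,
                         shf[1], shf[2], emb, ca$idxs[[l]], grads)
    grads <- bb$grads
    # concat layout was cbind(upsampled, skip)
    c_up <- ncol(ca$enc[[l + 1]]$out)
    dUp <- bb$dX[, seq_len(c_up), drop = FALSE]
    dEnc[[l]] <- bb$dX[, (c_up + 1):ncol(bb$dX), drop = FALSE]
    dCoarse <- spatial_apply(dUp, shf[1], shf[2],
                             t(ca$ups[[l]]$U), t(ca$ups[[l]]$V))
    if (l == cfg$depth - 1) {
      dEnc[[cfg$depth]] <- dCoarse          # feeds the bottleneck block
    } else {
      dCur <- dCoarse                       # gradient w.r.t. dec[[l+1]] output
    }
  }

  # encoder backward, deepest first
  dX_enc <- dEnc[[cfg$depth]]
  for (l in cfg$depth:2) {
    sh <- ca$shapes[[l]]
    bb <- block_backward(p, paste0("enc", l), ca$enc[[l]], dX_enc,
                         sh[1], sh[2], emb, ca$idxs[[l]], grads)
    grads <- bb$grads
    shf <- ca$shapes[[l - 1]]
    dPooled <- spatial_apply(bb$dX, sh[1], sh[2],
                             t(ca$pools[[l]]$A), t(ca$pools[[l]]$B))
    dX_enc <- dPooled + dEnc[[l - 1]]
  }
  bb <- block_backward(p, "enc1", ca$enc[[1]], dX_enc,
                       ca$Hv, ca$Wv, emb, ca$idxs[[1]], grads)
  grads <- bb$grads

  # through VINN inward
  dConvIn <- spatial_apply(bb$dX, ca$Hv, ca$Wv, t(ca$Ain), t(ca$Bin))
  bwi <- conv3_backward(dConvIn, ca$cols_in, p$conv_in_W, H, W,
                        cfg$slab_thickness, ca$idx0)
  grads$conv_in_W <- bwi$dW; grads$conv_in_b <- bwi$db
  grads
}

adam_update <- function(model, grads, lr, step, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  if (lr == 0) return(invisible(model))
  env <- model$env
  for (nm in names(grads)) {
    g <- grads[[nm]]
    env$adam_m[[nm]] <- beta1 * env$adam_m[[nm]] + (1 - beta1) * g
    env$adam_v[[nm]] <- beta2 * env$adam_v[[nm]] + (1 - beta2) * g^2
    mhat <- env$adam_m[[nm]] / (1 - beta1^step)
    vhat <- env$adam_v[[nm]] / (1 - beta2^step)
    env$params[[nm]] <- env$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(model)
}

#' Predict the noise content of a slab
#'
#' @param denoiser A `vinn_denoiser` from [build_denoiser()] or
#'   [train_denoiser()].
#' @param slab H x W x slab_thickness array (diffusion scale, \[-1, 1\]-ish).
#' @param t Timestep.
#' @param voxel_size Voxel size of the slab's volume in mm.
#' @return Noise estimate of identical shape; deterministic given parameters
#'   and inputs.
#' @export
predict_noise <- function(denoiser, slab, t, voxel_size) {
  stopifnot(inherits(denoiser, "vinn_denoiser"))
  out <- denoiser_forward(denoiser, slab, t, voxel_size, keep_cache = FALSE)$out
  if (!all(is.finite(out))) stop("denoiser produced non-finite output", call. = FALSE)
  out
}

#' Spatial shape of the most recent post-VINN feature grid
#'
#' @param denoiser A `vinn_denoiser` that has run at least one forward pass.
#' @return Integer c(H, W) of the latent grid, or NULL.
#' @export
latent_shape <- function(denoiser) denoiser$env$last_latent_shape

#' Total trainable parameter count
#'
#' @param denoiser A `vinn_denoiser`.
#' @return Integer number of scalar parameters.
#' @export
n_parameters <- function(denoiser) {
  sum(vapply(denoiser$env$params, length, integer(1)))
}

# --- slab plumbing shared with the inference scheduler ---------------------

VIEW_AXES <- c(sagittal = 1L, coronal = 2L, axial = 3L)

view_axis <- function(view) {
  if (is.numeric(view)) return(as.integer(view))
  ax <- VIEW_AXES[[match.arg(view, names(VIEW_AXES))]]
  ax
}

#' Extract a slab of adjacent slices from a volume
#'
#' @param volume 3D array.
#' @param view "axial", "coronal", or "sagittal" (slices cut orthogonal to
#'   this axis).
#' @param start First slice index (1-based).
#' @param thickness Number of slices.
#' @return H x W x thickness array (in-plane dims in axis order).
#' @export
get_slab <- function(volume, view, start, thickness) {
  ax <- view_axis(view)
  d <- dim(volume)
  sl <- start:(start + thickness - 1)
  if (start < 1 || max(sl) > d[ax]) stop("slab out of volume bounds", call. = FALSE)
  if (ax == 1L) aperm(volume[sl, , , drop = FALSE], c(2, 3, 1))
  else if (ax == 2L) aperm(volume[, sl, , drop = FALSE], c(1, 3, 2))
  else volume[, , sl, drop = FALSE]
}

#' Write a slab back into a volume
#'
#' @inheritParams get_slab
#' @param slab Array as returned by [get_slab()].
#' @return The updated volume.
#' @export
set_slab <- function(volume, slab, view, start, thickness) {
  ax <- view_axis(view)
  sl <- start:(start + thickness - 1)
  if (ax == 1L) volume[sl, , ] <- aperm(slab, c(3, 1, 2))
  else if (ax == 2L) volume[, sl, ] <- aperm(slab, c(1, 3, 2))
  else volume[, , sl] <- slab
  volume
}

#' Slab sampler over a set of lesion-free phantoms
#'
#' Returns a closure drawing random (phantom, view, position) slabs with
#' intensities mapped to the diffusion scale \[-1, 1\]. The closure uses the
#' calling RNG stream, so sampling is deterministic under the training seed.
#'
#' @param phantoms List of `labeled_phantom` objects (no lesions).
#' @param slab_thickness Slices per slab.
#' @param views Views to sample from.
#' @return Function () -> list(data, voxel_size).
#' @export
phantom_slab_source <- function(phantoms, slab_thickness = 7,
                                views = c("axial", "coronal", "sagittal")) {
  scaled <- lapply(phantoms, function(p) list(x = 2 * p$intensity / 255 - 1,
                                              vs = p$voxel_size))
  axes <- vapply(views, view_axis, integer(1))
  function() {
    p <- scaled[[sample.int(length(scaled), 1)]]
    ax <- axes[sample.int(length(axes), 1)]
    n <- dim(p$x)[ax]
    start <- sample.int(n - slab_thickness + 1, 1)
    list(data = get_slab(p$x, ax, start, slab_thickness), voxel_size = p$vs)
  }
}
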