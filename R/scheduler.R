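# 2.5D inference: rotate among axial/coronal/sagittal views across reverse
# steps, cut shifted slabs, denoise only lesion-intersecting slabs, composite
# the known region each step, and reassemble the 3D volume.

#' Configure mask-constrained inference
#'
#' @param T_infer Reverse-diffusion steps (defaults to the schedule's T at
#'   run time when NULL).
#' @param slab_thickness Slices per slab; must match the trained denoisers.
#' @param view_cycle Ordered axes to rotate through (one view per step).
#' @param offset_policy "cyclic" (offset = t mod slab_thickness) or "random".
#' @param resample Extra re-noising loops per step (RePaint-style jump-backs;
#'   0 disables).
#' @param seed Integer seed for all inference randomness.
#' @return An `inpaint_config` list.
#' @export
inpaint_config <- function(T_infer = NULL, slab_thickness = 7,
                           view_cycle = c("axial", "coronal", "sagittal"),
                           offset_policy = c("cyclic", "random"),
                           resample = 0, seed = 1) {
  offset_policy <- match.arg(offset_policy)
  view_cycle <- match.arg(view_cycle, c("axial", "coronal", "sagittal"),
                          several.ok = TRUE)
  if (length(view_cycle) < 1) stop("view_cycle must be nonempty", call. = FALSE)
  if (!is.null(T_infer)) {
    stopifnot_scalar(T_infer, "T_infer", positive = TRUE, integerish = TRUE)
  }
  stopifnot_scalar(resample, "resample", integerish = TRUE)
  structure(list(T_infer = if (is.null(T_infer)) NULL else as.integer(T_infer),
                 slab_thickness = as.integer(slab_thickness),
                 view_cycle = view_cycle, offset_policy = offset_policy,
                 resample = as.integer(resample), seed = as.integer(seed)),
            class = "inpaint_config")
}

#' View used at a given reverse step
#'
#' Steps run t = T_infer, ..., 1; the cycle index is `(T_infer - t) mod k`,
#' so all views are visited with equal frequency over a full run.
#'
#' @param t Reverse step (>= 1).
#' @param config An [inpaint_config()] with `T_infer` set.
#' @return View name.
#' @export
next_view <- function(t, config) {
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  k <- length(config$view_cycle)
  config$view_cycle[((config$T_infer - t) %% k) + 1]
}

#' Plan the lesion-intersecting slabs for one step
#'
#' Tiles the axis with non-overlapping slabs of `slab_thickness` slices
#' starting at `offset - slab_thickness` (1-based start `offset -
#' slab_thickness + 1`), clamps boundary slabs inward (never padding), and
#' keeps only slabs whose slice range intersects a mask-positive slice.
#'
#' @param mask 3D binary array.
#' @param view View name or axis index.
#' @param slab_thickness Slices per slab.
#' @param offset Integer in \[0, slab_thickness).
#' @return List with `view`, `offset`, `slab_starts` (ascending 1-based first
#'   slice indices).
#' @export
plan_slabs <- function(mask, view, slab_thickness, offset) {
  ax <- view_axis(view)
  n <- dim(mask)[ax]
  th <- as.integer(slab_thickness)
  if (n < th) stop("mask grid smaller than slab thickness along this axis", call. = FALSE)
  if (offset < 0 || offset >= th) {
    stop("offset must lie in [0, slab_thickness)", call. = FALSE)
  }
  pos <- which(apply(mask > 0, ax, any))
  if (length(pos) == 0) {
    return(list(view = view, offset = as.integer(offset), slab_starts = integer(0)))
  }
  starts <- seq.int(from = offset - th + 1L, to = n, by = th)
  keep <- integer(0)
  for (s in starts) {
    e <- s + th - 1L
    if (e < 1L || s > n) next              # fully outside the grid
    s2 <- min(max(s, 1L), n - th + 1L)     # clamp inward, never pad
    keep <- c(keep, s2)
  }
  keep <- sort(unique(keep))
  sel <- vapply(keep, function(s) any(pos >= s & pos <= s + th - 1L), logical(1))
  list(view = view, offset = as.integer(offset),
       slab_starts = as.integer(keep[sel]))
}

#' Inpaint the masked region of a volume by reverse diffusion
#'
#' Initializes the mask interior with standard normal noise (the exterior
#' with the matching forward-noise level of the input), then for t = T_infer
#' down to 1 picks the step's view and slab offset, denoises every
#' lesion-intersecting slab with the view's model, and composites the known
#' region once per step. The returned volume is on the original 0-255 scale
#' with every voxel outside the mask bit-identical to the input.
#'
#' @param volume 3D array on the 0-255 scale (or a volume record from
#'   [load_volume()]).
#' @param mask 3D binary array on the same grid.
#' @param models Named list of `vinn_denoiser` objects keyed by view; a
#'   single model is accepted and used for every view (shared weights).
#' @param schedule A [build_schedule()] result.
#' @param config An [inpaint_config()].
#' @param voxel_size Voxel size in mm (taken from `volume` if it is a record).
#' @return Inpainted 3D array; attribute `denoiser_calls` counts network
#'   evaluations (proportional to the number of mask-intersecting slabs).
#' @export
inpaint_volume <- function(volume, mask, models, schedule, config = inpaint_config(),
                           voxel_size = NULL) {
  if (is.list(volume) && !is.null(volume$data)) {
    if (is.null(voxel_size)) voxel_size <- volume$voxel_size
    volume <- volume$data
  }
  if (is.null(voxel_size)) voxel_size <- 1.0
  if (!identical(dim(volume), dim(mask))) {
    stop("volume and mask must share the same grid", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)", call. = FALSE)
  if (inherits(models, "vinn_denoiser")) {
    models <- stats::setNames(rep(list(models), length(config$view_cycle)),
                              config$view_cycle)
  }
  missing_views <- setdiff(config$view_cycle, names(models))
  if (length(missing_views) > 0) {
    stop("no trained model for view(s): ", paste(missing_views, collapse = ", "),
         call. = FALSE)
  }
  th <- config$slab_thickness
  for (m in models[config$view_cycle]) {
    if (m$config$slab_thickness != th) {
      stop("model slab thickness does not match inpaint configuration", call. = FALSE)
    }
  }
  T_infer <- if (is.null(config$T_infer)) schedule$T else config$T_infer
  if (T_infer > schedule$T) stop("T_infer exceeds the schedule's T", call. = FALSE)
  cfg <- config
  cfg$T_infer <- T_infer

  out <- volume
  calls <- 0L
  if (any(mask > 0)) {
    x0 <- 2 * volume / 255 - 1
    if (max(abs(x0)) > 1 + 1e-8) {
      stop("volume intensities must lie in [0, 255]", call. = FALSE)
    }
    x <- with_seed(cfg$seed, {
      x <- forward_noise(x0, T_infer, array(stats::rnorm(length(x0)), dim(x0)),
                         schedule)
      x[mask > 0] <- stats::rnorm(sum(mask > 0))
      for (t in T_infer:1) {
        n_loops <- if (t > 1) cfg$resample + 1L else 1L
        for (loop in seq_len(n_loops)) {
          if (loop > 1) {
            # RePaint jump-back: re-noise x_{t-1} to level t and redo the step
            x <- sqrt(schedule$alpha[t]) * x +
              sqrt(schedule$beta[t]) * array(stats::rnorm(length(x)), dim(x))
          }
          vw <- next_view(t, cfg)
          offset <- if (cfg$offset_policy == "cyclic") t %% th
                    else sample.int(th, 1) - 1L
          plan <- plan_slabs(mask, vw, th, offset)
          for (s in plan$slab_starts) {
            slab <- get_slab(x, vw, s, th)
            eps_hat <- predict_noise(models[[vw]], slab, t, voxel_size)
            z <- if (t > 1) array(stats::rnorm(length(slab)), dim(slab)) else NULL
            slab_prev <- reverse_step(slab, t, eps_hat, schedule, z)
            x <- set_slab(x, slab_prev, vw, s, th)
            calls <- calls + 1L
          }
          x <- composite_known(x, x0, mask, t, schedule,
                               eps = stats::rnorm(length(x0)))
        }
      }
      x
    })
    out <- finalize((x + 1) * 255 / 2, volume, mask)
  }
  attr(out, "denoiser_calls") <- calls
  out
}

#' Restore the known region and valid intensity range
#'
#' The output equals `original` outside the mask (bit-exact copy, including
#' all attributes/metadata of `original`) and the candidate clamped to
#' \[0, 255\] inside it.
#'
#' @param candidate Inpainted 3D array on the 0-255 scale.
#' @param original Input 3D array.
#' @param mask 3D binary array.
#' @return Finalized 3D array.
#' @export
finalize <- function(candidate, original, mask) {
  if (!identical(dim(candidate), dim(original)) ||
      !identical(dim(original), dim(mask))) {
    stop("candidate, original and mask must share the same grid", call. = FALSE)
  }
  out <- original
  inside <- mask > 0
  out[inside] <- pmin(pmax(candidate[inside], 0), 255)
  out
}

#' Mean-intensity fill baseline
#'
#' Fills the mask with the mean intensity of a surrounding two-voxel ring, the
#' classic neighborhood-fill baseline that diffusion inpainting is compared
#' against.
#'
#' @param volume 3D array on the 0-255 scale.
#' @param mask 3D binary array.
#' @param ring Dilation iterations defining the sampling ring.
#' @return Filled 3D array.
#' @export
mean_fill_inpaint <- function(volume, mask, ring = 2) {
  if (!identical(dim(volume), dim(mask))) {
    stop("volume and mask must share the same grid", call. = FALSE)
  }
  if (!any(mask > 0)) return(volume)
  ringmask <- dilate_mask(mask, iterations = ring, connectivity = 26) - mask
  fill <- mean(volume[ringmask > 0])
  out <- volume
  out[mask > 0] <- fill
  out
}
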