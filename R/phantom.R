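# Synthetic labeled brain phantoms: a seeded stand-in for a no-lesion MRI
# corpus with reliable segmentations. Geometry is defined in world millimetres
# so the same seed renders consistently at any isotropic voxel size.

PHANTOM_LABELS <- c(
  background = 0L, skull = 1L, csf = 2L, cortical_gm = 3L, white_matter = 4L,
  ventricle = 5L, thalamus = 6L, putamen = 7L
)

#' Default tissue-class mean intensities (0-255 scale)
#'
#' Chosen to mimic the class ordering of a T1-weighted scan (CSF dark, gray
#' matter intermediate, white matter bright) with gaps wide enough for
#' nearest-mean classification at moderate noise.
#'
#' @return Named numeric vector keyed by label id (as character).
#' @export
default_class_means <- function() {
  stats::setNames(
    c(5, 95, 45, 110, 190, 30, 150, 135),
    as.character(PHANTOM_LABELS)
  )
}

#' Specify a synthetic brain phantom
#'
#' @param grid_shape Integer triple, voxels per axis (each >= 32).
#' @param voxel_size Isotropic voxel edge length in mm (> 0; the training
#'   corpus emulated here spans 0.7-1.0 mm).
#' @param class_means Named numeric vector mapping label id (character) to the
#'   mean intensity on the 0-255 scale; must cover every emitted label.
#' @param noise_sd Additive Gaussian intensity noise, >= 0.
#' @param bias_amplitude Strength of the smooth multiplicative bias field
#'   (0 disables it).
#' @param fold_frequency Angular cycles of the cortical-ribbon undulation.
#' @param seed Integer seed; phantoms are pure functions of (spec, seed).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), voxel_size = 1.0,
                         class_means = default_class_means(),
                         noise_sd = 4, bias_amplitude = 0.05,
                         fold_frequency = 6, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L)) {
    stop("grid_shape must be an integer triple with every axis >= 32 ",
         "(smaller grids cannot host all tissue structures)", call. = FALSE)
  }
  stopifnot_scalar(voxel_size, "voxel_size", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  need <- as.character(PHANTOM_LABELS)
  if (!all(need %in% names(class_means))) {
    stop("class_means must provide a mean for every emitted label: ",
         paste(setdiff(need, names(class_means)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    class_means = class_means, noise_sd = noise_sd,
    bias_amplitude = bias_amplitude, fold_frequency = fold_frequency,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Generate a labeled brain-like phantom
#'
#' Renders an ellipsoidal head with skull shell, CSF layer, a folded cortical
#' gray-matter ribbon (2-4 voxels thick at 1 mm), white-matter interior,
#' paired ventricles, and two subcortical nuclei. Intensity is the class mean
#' modulated by a smooth multiplicative bias field plus Gaussian noise.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return A `labeled_phantom`: list with `intensity` (3D array, 0-255),
#'   `labels` (3D integer array), `voxel_size` (mm), `affine` (4x4
#'   voxel-index-to-world transform, 0-based indices).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size
  w <- voxel_world_coords(d, vs)
  X <- array(rep(w[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(w[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(w[[3]], each = d[1] * d[2]), d)

  # head ellipsoid semi-axes (mm), leaving a background margin
  ext <- d * vs
  a <- 0.46 * ext
  r <- sqrt((X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2)
  # world mm per unit of normalized radius along each voxel's direction
  rad_mm <- sqrt(X^2 + Y^2 + Z^2)
  scale_mm <- ifelse(r > 0, rad_mm / pmax(r, 1e-12), mean(a))

  theta <- atan2(Y, X)
  phi <- acos(pmin(pmax(ifelse(rad_mm > 0, Z / pmax(rad_mm, 1e-12), 0), -1), 1))
  fold <- 0.035 * sin(spec$fold_frequency * theta) * cos(spec$fold_frequency * phi)

  r_skull_out <- 1.0
  r_skull_in <- 0.93
  r_brain <- 0.84 + fold              # folded pial boundary (normalized)
  gm_mm <- 2.8                        # cortical thickness target, mm
  r_wm <- r_brain - gm_mm / pmax(scale_mm, 1e-6)

  lab <- array(PHANTOM_LABELS[["background"]], d)
  lab[r <= r_skull_out] <- PHANTOM_LABELS[["skull"]]
  lab[r <= r_skull_in] <- PHANTOM_LABELS[["csf"]]
  lab[r <= r_brain] <- PHANTOM_LABELS[["cortical_gm"]]
  lab[r <= r_wm] <- PHANTOM_LABELS[["white_matter"]]

  inside_wm <- lab == PHANTOM_LABELS[["white_matter"]]
  # paired ventricles: ellipsoids flanking the midline
  for (sgn in c(-1, 1)) {
    cv <- c(sgn * 0.16 * a[1], -0.05 * a[2], 0.05 * a[3])
    sv <- c(0.12 * a[1], 0.26 * a[2], 0.13 * a[3])
    rv <- sqrt(((X - cv[1]) / sv[1])^2 + ((Y - cv[2]) / sv[2])^2 +
                 ((Z - cv[3]) / sv[3])^2)
    lab[rv <= 1 & inside_wm] <- PHANTOM_LABELS[["ventricle"]]
  }
  # subcortical nuclei: thalamus-like and putamen-like spheres per hemisphere
  rmin <- 0.18 * min(a)
  for (sgn in c(-1, 1)) {
    ct <- c(sgn * 0.28 * a[1], 0.16 * a[2], -0.02 * a[3])
    rt <- sqrt((X - ct[1])^2 + (Y - ct[2])^2 + (Z - ct[3])^2)
    lab[rt <= rmin & inside_wm] <- PHANTOM_LABELS[["thalamus"]]
    cp <- c(sgn * 0.40 * a[1], -0.22 * a[2], -0.05 * a[3])
    rp <- sqrt((X - cp[1])^2 + (Y - cp[2])^2 + (Z - cp[3])^2)
    lab[rp <= 0.88 * rmin & inside_wm] <- PHANTOM_LABELS[["putamen"]]
  }

  if (!all(as.character(PHANTOM_LABELS) %in% as.character(unique(as.vector(lab))))) {
    stop("grid too small to host all structures at this voxel size; ",
         "increase grid_shape", call. = FALSE)
  }
  emitted <- as.character(sort(unique(as.vector(lab))))
  if (!all(emitted %in% names(spec$class_means))) {
    stop("class_means does not cover emitted label(s): ",
         paste(setdiff(emitted, names(spec$class_means)), collapse = ", "),
         call. = FALSE)
  }

  means <- spec$class_means[as.character(as.vector(lab))]
  intensity <- array(as.numeric(means), d)
  if (spec$bias_amplitude != 0 || spec$noise_sd > 0) {
    ph <- with_seed(spec$seed, list(phase = stats::runif(3, 0, 2 * pi),
                                    noise = if (spec$noise_sd > 0)
                                      stats::rnorm(prod(d)) else numeric(0)))
    if (spec$bias_amplitude != 0) {
      bias <- cos(2 * pi * X / ext[1] + ph$phase[1]) *
        cos(2 * pi * Y / ext[2] + ph$phase[2]) *
        cos(2 * pi * Z / ext[3] + ph$phase[3])
      intensity <- intensity * (1 + spec$bias_amplitude * bias)
    }
    if (spec$noise_sd > 0) {
      intensity <- intensity + spec$noise_sd * array(ph$noise, d)
    }
    intensity <- pmin(pmax(intensity, 0), 255)
  }

  structure(list(
    intensity = intensity, labels = lab, voxel_size = vs,
    affine = default_affine(d, vs), spec = spec
  ), class = "labeled_phantom")
}

#' Backward-warp a volume by a displacement field
#'
#' `output(x) = input(x - u(x))`: the displacement (mm) is subtracted from each
#' voxel's position and the input is sampled there, so a field pointing away
#' from a center pushes structures outward.
#'
#' @param volume 3D array.
#' @param field A `deformation_field` (list with `displacement`, an
#'   `[dim, 3]` array in mm, and `voxel_size`).
#' @param interpolation "linear" (intensities) or "nearest" (labels).
#' @param background Value used for samples falling outside the grid.
#' @return Warped 3D array of the same shape.
#' @export
apply_deformation <- function(volume, field, interpolation = c("linear", "nearest"),
                              background = 0) {
  interpolation <- match.arg(interpolation)
  d <- dim(volume)
  if (!identical(d, dim(field$displacement)[1:3])) {
    stop("volume and deformation field must share the same grid", call. = FALSE)
  }
  vs <- field$voxel_size
  idx <- list(
    array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
    array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
    array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  )
  # sample positions in (1-based) voxel coordinates
  sx <- idx[[1]] - field$displacement[, , , 1] / vs
  sy <- idx[[2]] - field$displacement[, , , 2] / vs
  sz <- idx[[3]] - field$displacement[, , , 3] / vs

  if (interpolation == "nearest") {
    ix <- round_half_up(sx); iy <- round_half_up(sy); iz <- round_half_up(sz)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    out <- array(background, d)
    lin <- (ix[ok] - 1) + (iy[ok] - 1) * d[1] + (iz[ok] - 1) * d[1] * d[2] + 1
    out[ok] <- volume[lin]
    if (is.integer(volume)) storage.mode(out) <- "integer"
    return(out)
  }
  # trilinear
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  out <- array(0, d)
  wsum <- array(0, d)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    wgt <- (ifelse(dx == 1, fx, 1 - fx)) * (ifelse(dy == 1, fy, 1 - fy)) *
      (ifelse(dz == 1, fz, 1 - fz))
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    lin <- (pmin(pmax(ix, 1), d[1]) - 1) + (pmin(pmax(iy, 1), d[2]) - 1) * d[1] +
      (pmin(pmax(iz, 1), d[3]) - 1) * d[1] * d[2] + 1
    contrib <- wgt * ifelse(ok, volume[lin], background)
    out <- out + contrib
    wsum <- wsum + wgt
  }
  out
}

# Discrete Jacobian determinant of x + u(x) via central differences (mm/mm).
jacobian_determinant <- function(displacement, voxel_size) {
  d <- dim(displacement)[1:3]
  grad <- function(comp, axis) {
    u <- displacement[, , , comp]
    sh <- c(0, 0, 0)
    sh[axis] <- 1
    fwd <- shift_array(u, -sh[1], -sh[2], -sh[3], fill = NA)
    bwd <- shift_array(u, sh[1], sh[2], sh[3], fill = NA)
    g <- (fwd - bwd) / (2 * voxel_size)
    # one-sided at the boundary
    g[is.na(g)] <- 0
    fe <- (fwd - u) / voxel_size
    be <- (u - bwd) / voxel_size
    g[is.na(bwd) & !is.na(fwd)] <- fe[is.na(bwd) & !is.na(fwd)]
    g[is.na(fwd) & !is.na(bwd)] <- be[is.na(fwd) & !is.na(bwd)]
    g
  }
  J <- vector("list", 9)
  k <- 1
  for (ci in 1:3) for (ax in 1:3) {
    J[[k]] <- grad(ci, ax) + as.numeric(ci == ax)
    k <- k + 1
  }
  # det of 3x3 with rows (J1.,J2.,J3.)
  J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
}

# Build the radial Gaussian mass-effect field u(d) = A (d/sigma) exp(-d^2/2sigma^2)
# pointing away from `center` (world mm), with A reduced until the discrete
# Jacobian determinant stays positive.
make_mass_effect_field <- function(phantom, center, amplitude, sigma) {
  d <- dim(phantom$labels)
  vs <- phantom$voxel_size
  w <- voxel_world_coords(d, vs)
  X <- array(rep(w[[1]], times = d[2] * d[3]), d) - center[1]
  Y <- array(rep(rep(w[[2]], each = d[1]), times = d[3]), d) - center[2]
  Z <- array(rep(w[[3]], each = d[1] * d[2]), d) - center[3]
  dist <- sqrt(X^2 + Y^2 + Z^2)
  A <- amplitude
  repeat {
    mag <- A * (dist / sigma) * exp(-dist^2 / (2 * sigma^2))
    unit <- 1 / pmax(dist, 1e-9)
    disp <- array(0, c(d, 3))
    disp[, , , 1] <- mag * X * unit
    disp[, , , 2] <- mag * Y * unit
    disp[, , , 3] <- mag * Z * unit
    if (A == 0 || min(jacobian_determinant(disp, vs)) > 0.05) break
    A <- A * 0.8
  }
  structure(list(displacement = disp, voxel_size = vs, amplitude = A),
            class = "deformation_field")
}

brain_label_ids <- function() {
  unname(PHANTOM_LABELS[c("cortical_gm", "white_matter", "ventricle",
                          "thalamus", "putamen")])
}

#' Insert a tumor-like lesion with mass effect
#'
#' Applies a radial Gaussian mass-effect deformation jointly to intensity
#' (linear interpolation) and labels (nearest), so the warped labels remain a
#' valid reference segmentation of the warped image. The lesion mask is a
#' spheroid (optionally perturbed by seeded smooth angular noise) warped by
#' the same field; intensity inside the mask is replaced by a tumor-like fill
#' so the lesion is visibly abnormal. Labels are NOT altered inside the mask:
#' they encode the tissue truth the inpainting should restore.
#'
#' @param phantom A `labeled_phantom`.
#' @param center World-mm triple, or NULL to sample randomly within the brain
#'   (retried up to `max_retries` times; implausible placements are rejected).
#' @param radius Lesion radius in mm (> 0).
#' @param displacement_amplitude Peak mass-effect displacement in mm (>= 0;
#'   automatically capped so the deformation does not fold).
#' @param seed Integer seed.
#' @param tumor_intensity Fill value on the 0-255 scale (default hyperintense).
#' @param shape_noise Relative radius perturbation amplitude (0 = exact sphere).
#' @param max_retries Attempts at sampling a plausible random center.
#' @return List with `phantom` (deformed + lesioned), `mask` (binary array,
#'   kind "tumor"), `field` (the `deformation_field`).
#' @export
insert_tumor_lesion <- function(phantom, center = NULL, radius = 6,
                                displacement_amplitude = 2, seed = 1,
                                tumor_intensity = 230, shape_noise = 0.15,
                                max_retries = 10) {
  stopifnot(inherits(phantom, "labeled_phantom"))
  stopifnot_scalar(radius, "radius", positive = TRUE)
  if (displacement_amplitude < 0) stop("displacement_amplitude must be >= 0", call. = FALSE)
  d <- dim(phantom$labels)
  vs <- phantom$voxel_size
  w <- voxel_world_coords(d, vs)
  brain <- phantom$labels %in% brain_label_ids()
  dim(brain) <- d

  res <- with_seed(seed, {
    ctr <- center
    if (is.null(ctr)) {
      cand <- which(brain)
      ok <- FALSE
      for (i in seq_len(max_retries)) {
        v <- cand[sample.int(length(cand), 1)]
        ijk <- arrayInd(v, d)
        ctr_try <- c(w[[1]][ijk[1]], w[[2]][ijk[2]], w[[3]][ijk[3]])
        if (sphere_brain_fraction(phantom, ctr_try, radius, brain) >= 0.5) {
          ctr <- ctr_try
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("no plausible tumor location found after ", max_retries,
             " attempts; case rejected", call. = FALSE)
      }
    } else {
      ijk <- world_to_index(phantom$affine, ctr)
      if (any(ijk < 1) || any(ijk > d) || !brain[ijk[1], ijk[2], ijk[3]]) {
        stop("center must lie inside the brain", call. = FALSE)
      }
    }
    field <- make_mass_effect_field(phantom, ctr, displacement_amplitude,
                                    sigma = radius)
    intensity <- apply_deformation(phantom$intensity, field, "linear",
                                   background = phantom$spec$class_means[["0"]])
    labels <- apply_deformation(phantom$labels, field, "nearest",
                                background = PHANTOM_LABELS[["background"]])
    # spheroid mask with smooth angular radius perturbation, warped by the field
    X <- array(rep(w[[1]], times = d[2] * d[3]), d) - ctr[1]
    Y <- array(rep(rep(w[[2]], each = d[1]), times = d[3]), d) - ctr[2]
    Z <- array(rep(w[[3]], each = d[1] * d[2]), d) - ctr[3]
    dist <- sqrt(X^2 + Y^2 + Z^2)
    rmod <- radius
    if (shape_noise > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      th <- atan2(Y, X)
      pz <- acos(pmin(pmax(ifelse(dist > 0, Z / pmax(dist, 1e-9), 0), -1), 1))
      rmod <- radius * (1 + shape_noise * sin(3 * th + ph[1]) * cos(2 * pz + ph[2]))
    }
    mask0 <- array(as.numeric(dist <= rmod), d)
    mask <- apply_deformation(mask0, field, "nearest", background = 0)
    fill_noise <- stats::rnorm(sum(mask > 0), 0, 0.03 * tumor_intensity)
    intensity[mask > 0] <- pmin(pmax(tumor_intensity + fill_noise, 0), 255)
    list(intensity = intensity, labels = labels, mask = mask, field = field)
  })

  out <- phantom
  out$intensity <- res$intensity
  out$labels <- res$labels
  mask <- structure(res$mask, kind = "tumor")
  list(phantom = out, mask = mask, field = res$field)
}

sphere_brain_fraction <- function(phantom, center, radius, brain) {
  d <- dim(phantom$labels)
  w <- voxel_world_coords(d, phantom$voxel_size)
  X <- array(rep(w[[1]], times = d[2] * d[3]), d) - center[1]
  Y <- array(rep(rep(w[[2]], each = d[1]), times = d[3]), d) - center[2]
  Z <- array(rep(w[[3]], each = d[1] * d[2]), d) - center[3]
  inside <- (X^2 + Y^2 + Z^2) <= radius^2
  if (!any(inside)) return(0)
  sum(brain[inside]) / sum(inside)
}

world_to_index <- function(affine, world) {
  v <- solve(affine) %*% c(world, 1)
  round_half_up(v[1:3]) + 1L  # 0-based index convention -> R's 1-based
}

#' Insert multifocal MS-like white-matter lesions
#'
#' Places `n_lesions` spheroids centered in white matter, alters the intensity
#' inside them to a lesion-like value, and leaves labels and geometry
#' untouched (the mass effect of such lesions is negligible). The default
#' fill is hypointense, matching the T1-weighted presentation of
#' demyelinating lesions ("black holes") that the phantom's contrast
#' emulates; on this scale a hyperintense fill would be indistinguishable
#' from white matter to an intensity-based segmenter.
#'
#' @param phantom A `labeled_phantom`.
#' @param n_lesions Number of lesions (>= 1).
#' @param radius_range Length-2 mm interval within [1, 8].
#' @param seed Integer seed.
#' @param lesion_intensity Fill value on the 0-255 scale.
#' @param max_retries Placement attempts per lesion before failing.
#' @return List with `phantom` (lesioned intensity, identical labels) and
#'   `mask` (binary array, kind "ms").
#' @export
insert_ms_lesions <- function(phantom, n_lesions = 5, radius_range = c(1.5, 4),
                              seed = 1, lesion_intensity = 60,
                              max_retries = 50) {
  stopifnot(inherits(phantom, "labeled_phantom"))
  stopifnot_scalar(n_lesions, "n_lesions", positive = TRUE, integerish = TRUE)
  if (length(radius_range) != 2 || radius_range[1] < 1 || radius_range[2] > 8 ||
      radius_range[1] > radius_range[2]) {
    stop("radius_range must be an increasing interval within [1, 8] mm", call. = FALSE)
  }
  d <- dim(phantom$labels)
  vs <- phantom$voxel_size
  w <- voxel_world_coords(d, vs)
  wm <- phantom$labels == PHANTOM_LABELS[["white_matter"]]
  dim(wm) <- d
  wm_idx <- which(wm)
  if (length(wm_idx) < n_lesions * 10) {
    stop("white matter too small to place the requested lesions", call. = FALSE)
  }
  X <- array(rep(w[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(w[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(w[[3]], each = d[1] * d[2]), d)

  res <- with_seed(seed, {
    mask <- array(0, d)
    placed <- 0
    for (i in seq_len(n_lesions)) {
      done <- FALSE
      for (try in seq_len(max_retries)) {
        v <- wm_idx[sample.int(length(wm_idx), 1)]
        ijk <- arrayInd(v, d)
        ctr <- c(w[[1]][ijk[1]], w[[2]][ijk[2]], w[[3]][ijk[3]])
        rad <- stats::runif(1, radius_range[1], radius_range[2])
        inside <- ((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2) <= rad^2
        if (any(inside) && mean(wm[inside]) >= 0.9) {
          mask[inside] <- 1
          placed <- placed + 1
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop("could not place lesion ", i, " inside white matter after ",
             max_retries, " attempts", call. = FALSE)
      }
    }
    fill_noise <- stats::rnorm(sum(mask > 0), 0, 0.02 * lesion_intensity)
    list(mask = mask, fill = fill_noise)
  })

  out <- phantom
  out$intensity[res$mask > 0] <-
    pmin(pmax(lesion_intensity + res$fill, 0), 255)
  mask <- structure(res$mask, kind = "ms")
  list(phantom = out, mask = mask)
}

#' Nearest-class-mean reference segmenter
#'
#' A deterministic stand-in segmenter: median-smooths the intensity with a 3^3
#' window (edge-replicated borders) and assigns each voxel the label whose
#' class mean is nearest; ties go to the lowest label id. Together with the
#' phantom generator's reference labels this enables Dice/Hausdorff evaluation
#' of inpainting without any external segmentation tool.
#'
#' @param intensity 3D array on the 0-255 scale.
#' @param class_means Named numeric vector, label id (character) -> mean.
#' @return 3D integer label array.
#' @export
reference_segment <- function(intensity, class_means = default_class_means()) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L || length(intensity) == 0) {
    stop("intensity must be a non-empty 3D array", call. = FALSE)
  }
  if (length(class_means) == 0) stop("class_means must be nonempty", call. = FALSE)
  sm <- median_filter3(intensity)
  ids <- as.integer(names(class_means))
  o <- order(ids)
  ids <- ids[o]
  mu <- as.numeric(class_means)[o]
  # nearest mean; which.min takes the first (lowest label id) on ties
  dist <- abs(outer(as.vector(sm), mu, "-"))
  lab <- ids[max.col(-dist, ties.method = "first")]
  array(as.integer(lab), dim(intensity))
}

# 3^3 median filter with edge replication; order()-based rowwise median.
median_filter3 <- function(a) {
  d <- dim(a)
  n <- prod(d)
  vals <- matrix(0, n, 27)
  col <- 1
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    ii <- pmin(pmax(seq_len(d[1]) + di, 1), d[1])
    jj <- pmin(pmax(seq_len(d[2]) + dj, 1), d[2])
    kk <- pmin(pmax(seq_len(d[3]) + dk, 1), d[3])
    vals[, col] <- as.vector(a[ii, jj, kk])
    col <- col + 1
  }
  ridx <- rep(seq_len(n), times = 27)
  o <- order(ridx, as.vector(vals))
  med <- as.vector(vals)[o[(seq_len(n) - 1) * 27 + 14]]
  array(med, d)
}
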