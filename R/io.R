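# File I/O for the standard formats touched: NIfTI volumes, ASCII PLY
# meshes, per-vertex scalar files, plain-text affines, key-value run
# configuration, and model checkpoints.

#' Load a 3D isotropic NIfTI volume
#'
#' @param path Path to a .nii or .nii.gz file.
#' @return A `volume_record`: list with `data` (3D numeric array),
#'   `voxel_size` (mm), `affine` (4 x 4 voxel-index-to-world, 0-based
#'   indices), `dtype`, `provenance`.
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("unsupported input: expected a 3D volume, got ", length(d),
         " dimensions", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-3) {
    stop("unsupported input: anisotropic voxels (",
         paste(signif(pd, 4), collapse = " x "),
         " mm); this method is defined for isotropic volumes", call. = FALSE)
  }
  vs <- mean(pd)
  if (vs < 0.5 - 1e-9 || vs > 2.0 + 1e-9) {
    stop("voxel size ", signif(vs, 4), " mm outside the accepted [0.5, 2.0] mm",
         call. = FALSE)
  }
  aff <- structure(RNifti::xform(img), class = NULL)
  structure(list(
    data = array(as.numeric(img), d), voxel_size = vs,
    affine = unclass(aff)[1:4, 1:4],
    dtype = RNifti::niftiHeader(img)$datatype,
    provenance = list(source = normalizePath(path), log = character(0))
  ), class = "volume_record")
}

#' Save a volume record (or array) as NIfTI
#'
#' @param record A `volume_record`, `labeled_phantom` field, or plain 3D
#'   array (then `voxel_size`/`affine` must be given or default).
#' @param path Output .nii or .nii.gz path.
#' @param voxel_size,affine Used when `record` is a plain array.
#' @param datatype NIfTI datatype: "double" round-trips intensities
#'   bit-exactly; "uint8" for labels and masks.
#' @return The path, invisibly.
#' @export
save_volume <- function(record, path, voxel_size = 1.0, affine = NULL,
                        datatype = "double") {
  if (is.list(record) && !is.null(record$data)) {
    data <- record$data
    voxel_size <- record$voxel_size
    affine <- record$affine
  } else {
    data <- record
    if (is.null(affine)) affine <- default_affine(dim(data), voxel_size)
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write an ASCII PLY triangle mesh
#'
#' Minimal ASCII PLY support: `vertex` elements with x/y/z properties and
#' `face` elements with a vertex-index list. Faces are 0-based in the file
#' (PLY convention) and 1-based in R.
#'
#' @param path PLY file path.
#' @param affine Optional 4 x 4 companion volume affine to attach.
#' @return A `surface_mesh`: list with `vertices` (n x 3), `faces` (m x 3),
#'   `affine`.
#' @export
read_ply <- function(path, affine = diag(4)) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file", call. = FALSE)
  end_hdr <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(end_hdr)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (any(grepl("^format (binary)", hdr))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  vtx_lines <- lines[(end_hdr + 1):(end_hdr + nv)]
  vertices <- matrix(as.numeric(unlist(strsplit(trimws(vtx_lines), "\\s+"))),
                     nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  faces <- NULL
  if (nf > 0) {
    f_lines <- lines[(end_hdr + nv + 1):(end_hdr + nv + nf)]
    fl <- strsplit(trimws(f_lines), "\\s+")
    faces <- t(vapply(fl, function(v) as.integer(v[2:4]) + 1L, integer(3)))
  }
  structure(list(vertices = vertices, faces = faces, affine = affine),
            class = "surface_mesh")
}

#' @rdname read_ply
#' @param mesh A `surface_mesh`.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- if (is.null(mesh$faces)) 0L else nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vl <- apply(mesh$vertices, 1, function(v) paste(format(v, trim = TRUE), collapse = " "))
  fl <- if (nf > 0) {
    apply(mesh$faces - 1L, 1, function(f) paste(c(3L, f), collapse = " "))
  } else character(0)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read / write per-vertex scalars as plain text (one value per line)
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_vertex_scalars <- function(path) as.numeric(readLines(path))

#' @rdname read_vertex_scalars
#' @param values Numeric vector indexed by vertex.
#' @export
write_vertex_scalars <- function(values, path) {
  writeLines(format(values, trim = TRUE, digits = 17), path)
  invisible(path)
}

#' Read / write a 4x4 affine as a plain-text matrix
#'
#' @param path File path.
#' @return 4 x 4 numeric matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(4L, 4L))) stop("affine file must be 4x4", call. = FALSE)
  m
}

#' @rdname read_affine
#' @param affine 4 x 4 numeric matrix.
#' @export
write_affine <- function(affine, path) {
  utils::write.table(format(affine, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- run configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(
    schedule_T = 200L, beta_start = 1e-4, beta_end = 0.02, schedule_kind = "linear",
    slab_thickness = 7L, internal_voxel_size = 1.0, base_channels = 8L,
    depth = 2L, time_embedding_dim = 16L,
    views = "axial,coronal,sagittal", offset_policy = "cyclic", resample = 0L,
    train_steps = 400L, train_batch = 2L, train_lr = 2e-3,
    metric_L = 255, metric_M = 255, ssim_kernel_size = 11L, ssim_kernel_sd = 1.5,
    psnr_convention = "squared_peak",
    seed = 1L
  )
}

#' Read a key=value run configuration
#'
#' Plain-text `key = value` lines ('#' comments allowed) covering every
#' tunable default; unknown keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' @param path Config file, or NULL for pure defaults.
#' @param overrides Named list applied after the file.
#' @return Named list with the fully resolved configuration.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
      cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    cfg[[key]] <- overrides[[key]]
  }
  cfg
}

# --- checkpoints -----------------------------------------------------------

#' Save / load trained denoiser models
#'
#' A checkpoint is a single-file archive holding the network configuration,
#' per-view parameters, noise schedule, and training seed.
#'
#' @param models Named list of `vinn_denoiser` (by view) or a single model.
#' @param schedule The [build_schedule()] used in training.
#' @param path Checkpoint file path.
#' @return `save_checkpoint`: the path, invisibly; `load_checkpoint`: list
#'   with `models` and `schedule`.
#' @export
save_checkpoint <- function(models, schedule, path) {
  if (inherits(models, "vinn_denoiser")) models <- list(shared = models)
  payload <- list(
    schedule = unclass(schedule),
    models = lapply(models, function(m) list(config = unclass(m$config),
                                             params = m$env$params,
                                             seed = m$seed))
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  schedule <- structure(payload$schedule, class = "noise_schedule")
  models <- lapply(payload$models, function(m) {
    cfg <- structure(m$config, class = "vinn_config")
    mod <- build_denoiser(cfg, seed = m$seed)
    mod$env$params <- m$params
    mod
  })
  list(models = models, schedule = schedule)
}
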