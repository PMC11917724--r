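# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# round-half-up (deterministic, unlike round()'s round-half-even)
round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

is_binary_array <- function(x) {
  is.array(x) && all(x %in% c(0, 1))
}

# Shift a 3D array by integer offsets, padding with `fill`.
shift_array <- function(a, di, dj, dk, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src_i <- max(1, 1 - di):min(d[1], d[1] - di)
  src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
  src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
  if (length(src_i) < 1 || length(src_j) < 1 || length(src_k) < 1) return(out)
  out[src_i + di, src_j + dj, src_k + dk] <- a[src_i, src_j, src_k]
  out
}

neighbor_offsets <- function(connectivity = 6) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
}

#' Label connected components of a binary volume
#'
#' Iterative minimum-label propagation over the chosen neighborhood; adequate
#' for the small, compact components produced by the lesion generators.
#'
#' @param mask 3D binary array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of the same shape; 0 for background, components
#'   numbered 1..k.
#' @export
connected_components <- function(mask, connectivity = 6) {
  if (!is_binary_array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a 3D binary array", call. = FALSE)
  }
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask > 0] <- seq_len(sum(mask > 0))
  offs <- neighbor_offsets(connectivity)
  repeat {
    prev <- lab
    for (r in seq_len(nrow(offs))) {
      nb <- shift_array(lab, offs[r, 1], offs[r, 2], offs[r, 3], fill = 0)
      take <- mask > 0 & nb > 0 & nb < lab
      lab[take] <- nb[take]
    }
    if (identical(prev, lab)) break
  }
  ids <- sort(unique(lab[lab > 0]))
  relab <- array(0L, d)
  for (i in seq_along(ids)) relab[lab == ids[i]] <- i
  relab
}

# World-mm coordinates of every voxel center (0-based indices, centered grid).
voxel_world_coords <- function(grid_shape, voxel_size) {
  lapply(seq_len(3), function(ax) {
    (seq_len(grid_shape[ax]) - 1 - (grid_shape[ax] - 1) / 2) * voxel_size
  })
}

# Default affine: centered grid, world = voxel_size * (index0 - (n-1)/2).
default_affine <- function(grid_shape, voxel_size) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  a
}
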