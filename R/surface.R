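# Lesion-to-surface post-processing: relabel segmentations inside the
# inpainted area, project the lesion mask onto mesh vertices
# (dilate -> mark -> mode-filter), exclude marked vertices from group
# statistics, and compute vertex-wise ICC maps.

#' Relabel a segmentation inside the lesion mask
#'
#' @param seg Integer label volume.
#' @param mask Binary lesion mask on the same grid.
#' @param lesion_label Integer label to assign inside the mask; must not
#'   collide with an anatomical label already present in `seg`.
#' @return Relabeled volume; voxels outside the mask are unchanged.
#' @export
relabel_segmentation <- function(seg, mask, lesion_label = 99L) {
  if (!identical(dim(seg), dim(mask))) {
    stop("segmentation and mask must share the same grid", call. = FALSE)
  }
  if (lesion_label %in% unique(as.vector(seg))) {
    stop("lesion_label collides with an existing label (", lesion_label, ")",
         call. = FALSE)
  }
  out <- seg
  out[mask > 0] <- as.integer(lesion_label)
  out
}

#' Binary dilation of a lesion mask
#'
#' @param mask Binary 3D array.
#' @param iterations Number of dilation passes (>= 0; 0 is the identity).
#' @param connectivity 6 (faces) or 26 (full 3x3x3 neighborhood).
#' @return Dilated binary array; the input is always a subset of the output.
#' @export
dilate_mask <- function(mask, iterations = 1, connectivity = 26) {
  stopifnot_scalar(iterations, "iterations", integerish = TRUE)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  offs <- neighbor_offsets(connectivity)
  out <- mask
  for (i in seq_len(iterations)) {
    acc <- out
    for (r in seq_len(nrow(offs))) {
      acc <- pmax(acc, shift_array(out, offs[r, 1], offs[r, 2], offs[r, 3], fill = 0))
    }
    out <- acc
  }
  out
}

#' Mark mesh vertices intersecting a volumetric mask
#'
#' Each vertex is mapped from world mm to voxel indices through the inverse
#' of the mesh's companion affine (0-based voxel centers at integer indices),
#' rounded to the nearest voxel, and marked when that voxel is inside the
#' grid and mask-positive. Out-of-grid vertices are left unmarked.
#'
#' @param mesh A `surface_mesh` (list with `vertices` n x 3 world mm, `faces`
#'   m x 3 vertex indices, `affine` 4 x 4).
#' @param mask Binary 3D array.
#' @return Integer vector of per-vertex labels (1 = lesion).
#' @export
mark_vertices <- function(mesh, mask) {
  inv <- solve(mesh$affine)
  v <- cbind(mesh$vertices, 1) %*% t(inv)
  idx <- round_half_up(v[, 1:3, drop = FALSE]) + 1  # 0-based indices -> R's 1-based
  d <- dim(mask)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- integer(nrow(idx))
  lin <- (idx[ok, 1] - 1) + (idx[ok, 2] - 1) * d[1] + (idx[ok, 3] - 1) * d[1] * d[2] + 1
  out[ok] <- as.integer(mask[lin] > 0)
  out
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- rbind(e, e[, 2:1])
  unique(e)
}

#' Mode-filter per-vertex labels on a mesh
#'
#' Every vertex takes the majority label of itself and its 1-ring neighbors;
#' ties keep the current label; isolated vertices keep theirs. Iterated a
#' fixed number of times (default 3), stopping early at a fixed point. Used
#' to smooth the lesion border and fill holes after [mark_vertices()].
#'
#' @param mesh A `surface_mesh`.
#' @param labels Integer 0/1 per-vertex labels.
#' @param iterations Maximum filter passes (>= 1).
#' @return Filtered label vector.
#' @export
mode_filter <- function(mesh, labels, iterations = 3) {
  stopifnot_scalar(iterations, "iterations", positive = TRUE, integerish = TRUE)
  nv <- nrow(mesh$vertices)
  if (length(labels) != nv) stop("labels length must equal vertex count", call. = FALSE)
  edges <- mesh_edges(mesh$faces)
  deg <- numeric(nv)
  tab <- table(factor(edges[, 1], levels = seq_len(nv)))
  deg <- as.numeric(tab)
  cur <- as.integer(labels)
  for (i in seq_len(iterations)) {
    pos <- numeric(nv)
    agg <- rowsum(as.numeric(cur[edges[, 2]]), edges[, 1])
    pos[as.integer(rownames(agg))] <- agg
    pos_total <- pos + cur
    total <- deg + 1
    newlab <- ifelse(2 * pos_total > total, 1L,
                     ifelse(2 * pos_total < total, 0L, cur))
    if (identical(newlab, cur)) break
    cur <- as.integer(newlab)
  }
  cur
}

#' Per-vertex group statistics excluding lesion-marked vertices
#'
#' @param thickness_maps Numeric matrix, vertices x subjects (e.g., cortical
#'   thickness in mm on a common template indexing).
#' @param vertex_masks Binary matrix of the same shape; 1 = lesion-marked,
#'   excluded for that subject at that vertex.
#' @return Data frame with per-vertex `n` (contributing subjects), `mean`,
#'   `sd`, and `missing` (TRUE when no subject contributes).
#' @export
exclude_and_summarize <- function(thickness_maps, vertex_masks) {
  thickness_maps <- as.matrix(thickness_maps)
  vertex_masks <- as.matrix(vertex_masks)
  if (!identical(dim(thickness_maps), dim(vertex_masks))) {
    stop("thickness maps and vertex masks must have matching dimensions", call. = FALSE)
  }
  keep <- vertex_masks == 0
  n <- rowSums(keep)
  sum1 <- rowSums(thickness_maps * keep)
  mean_v <- ifelse(n > 0, sum1 / n, NA_real_)
  sum2 <- rowSums(thickness_maps^2 * keep)
  var_v <- ifelse(n > 1, (sum2 - n * mean_v^2) / (n - 1), NA_real_)
  var_v <- pmax(var_v, 0)
  data.frame(n = n, mean = mean_v, sd = sqrt(var_v), missing = n == 0)
}

#' Vertex-wise absolute-agreement ICC of paired thickness maps
#'
#' For every vertex with at least `min_n` subjects unmasked in both sessions,
#' computes [icc_a1()] over the paired pre/post measurements; other vertices
#' are flagged missing.
#'
#' @param pre_maps,post_maps Numeric matrices, vertices x subjects.
#' @param vertex_masks Binary matrix (1 = excluded) applied to both sessions.
#' @param min_n Minimum unmasked subjects per vertex (>= 3).
#' @return Data frame with `icc`, `n`, `missing`.
#' @export
vertex_icc_map <- function(pre_maps, post_maps, vertex_masks = NULL, min_n = 3) {
  pre_maps <- as.matrix(pre_maps)
  post_maps <- as.matrix(post_maps)
  if (!identical(dim(pre_maps), dim(post_maps))) {
    stop("pre and post maps must have matching dimensions", call. = FALSE)
  }
  if (is.null(vertex_masks)) vertex_masks <- matrix(0, nrow(pre_maps), ncol(pre_maps))
  if (min_n < 3) stop("min_n must be >= 3 (ICC needs >= 3 subjects)", call. = FALSE)
  nv <- nrow(pre_maps)
  icc <- rep(NA_real_, nv)
  n <- integer(nv)
  for (v in seq_len(nv)) {
    ok <- vertex_masks[v, ] == 0
    n[v] <- sum(ok)
    if (n[v] >= min_n) {
      icc[v] <- tryCatch(icc_a1(cbind(pre_maps[v, ok], post_maps[v, ok])),
                         error = function(e) NA_real_)
    }
  }
  data.frame(icc = icc, n = n, missing = is.na(icc))
}
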