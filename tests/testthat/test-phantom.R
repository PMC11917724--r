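test_that("phantom generation is deterministic and honors the noise-free limit", {
  sp <- phantom_spec(grid_shape = rep(36, 3), seed = 5)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$intensity, p2$intensity)
  expect_identical(p1$labels, p2$labels)

  sp0 <- phantom_spec(grid_shape = rep(36, 3), noise_sd = 0, bias_amplitude = 0)
  p0 <- generate_phantom(sp0)
  means <- default_class_means()
  expect_true(all(p0$intensity == means[as.character(p0$labels)]))
  # all declared tissue classes present
  expect_setequal(unique(as.vector(p0$labels)), 0:7)
})

test_that("phantom spec validation rejects unusable inputs", {
  expect_error(phantom_spec(grid_shape = c(20, 48, 48)), ">= 32")
  expect_error(phantom_spec(voxel_size = 0), "positive")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
  cm <- default_class_means()
  expect_error(generate_phantom(
    structure(list(grid_shape = rep(36L, 3), voxel_size = 1,
                   class_means = cm[1:3], noise_sd = 0, bias_amplitude = 0,
                   fold_frequency = 6, seed = 1), class = "phantom_spec")))
})

test_that("cortical ribbon is 2-4 voxels thick at 1 mm", {
  p <- fixture_phantom(seed = 3)
  # thickness along the x axis through the midline: runs of GM label
  d <- dim(p$labels)
  runs <- c()
  for (k in seq(12, d[3] - 12, by = 6)) {
    line <- p$labels[, d[2] %/% 2, k]
    r <- rle(line)
    runs <- c(runs, r$lengths[r$values == 3])
  }
  expect_true(length(runs) > 0)
  expect_true(median(runs) >= 2 && median(runs) <= 4)
})

test_that("per-class world volumes are consistent across voxel sizes", {
  # identical world extents: 48 mm at 1.0 vs 0.8 mm, 49 mm at 1.0 vs 0.7 mm
  p1 <- fixture_phantom(seed = 2, grid = 48, voxel_size = 1.0)
  p08 <- fixture_phantom(seed = 2, grid = 60, voxel_size = 0.8)
  p149 <- generate_phantom(phantom_spec(rep(49, 3), 1.0, seed = 2))
  p07 <- generate_phantom(phantom_spec(rep(70, 3), 0.7, seed = 2))
  expect_equal(dim(p07$labels)[1] / dim(p149$labels)[1], 1.0 / 0.7,
               tolerance = 0.05)
  for (pair in list(list(a = p1, b = p08, vs = 0.8),
                    list(a = p149, b = p07, vs = 0.7))) {
    for (l in 0:7) {
      v1 <- sum(pair$a$labels == l) * 1.0^3
      v2 <- sum(pair$b$labels == l) * pair$vs^3
      expect_lt(abs(v1 - v2) / max(v1, v2), 0.05)
    }
  }
})

test_that("tumor insertion deforms image and labels jointly without folding", {
  p <- fixture_phantom(seed = 3)
  les <- insert_tumor_lesion(p, radius = 6, displacement_amplitude = 2, seed = 9)
  expect_s3_class(les$field, "deformation_field")
  expect_equal(attr(les$mask, "kind"), "tumor")
  # discrete Jacobian determinant positive everywhere
  jd <- neuroinpaint:::jacobian_determinant(les$field$displacement, p$voxel_size)
  expect_gt(min(jd), 0)
  # mask is a single connected component
  expect_equal(max(connected_components(array(les$mask, dim(les$mask)), 26)), 1)
  # determinism
  les2 <- insert_tumor_lesion(p, radius = 6, displacement_amplitude = 2, seed = 9)
  expect_identical(les$phantom$intensity, les2$phantom$intensity)
})

test_that("zero-amplitude tumor leaves labels unchanged and mask spherical", {
  p <- fixture_phantom(seed = 3)
  les <- insert_tumor_lesion(p, center = c(0, 0, 0), radius = 5,
                             displacement_amplitude = 0, seed = 1,
                             shape_noise = 0)
  expect_identical(les$phantom$labels, p$labels)
  vol <- sum(les$mask)
  expect_lt(abs(vol - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.10)
})

test_that("MS lesions alter intensity but never labels or geometry", {
  p <- fixture_phantom(seed = 4)
  ms1 <- insert_ms_lesions(p, n_lesions = 1, radius_range = c(1.5, 1.5), seed = 2)
  expect_equal(max(connected_components(array(ms1$mask, dim(ms1$mask)), 26)), 1)
  ms <- insert_ms_lesions(p, n_lesions = 12, radius_range = c(1.5, 3), seed = 2)
  ncomp <- max(connected_components(array(ms$mask, dim(ms$mask)), 26))
  expect_lte(ncomp, 12)
  expect_gte(ncomp, 1)
  expect_identical(ms$phantom$labels, p$labels)
  expect_false(identical(ms$phantom$intensity, p$intensity))
  # intensity outside the mask untouched
  out <- ms$mask == 0
  expect_identical(ms$phantom$intensity[out], p$intensity[out])
  expect_error(insert_ms_lesions(p, n_lesions = 2, radius_range = c(1, 10)),
               "radius_range")
})

test_that("apply_deformation implements backward warping", {
  p <- fixture_phantom(seed = 3, grid = 48)
  d <- dim(p$labels)
  zero <- structure(list(displacement = array(0, c(d, 3)), voxel_size = 1),
                    class = "deformation_field")
  expect_identical(apply_deformation(p$labels, zero, "nearest"), p$labels)
  # constant integer shift: output(x) = input(x - u) == shift by +u voxels
  shift <- structure(list(displacement = array(rep(c(2, 0, 0), each = prod(d)),
                                               c(d, 3)), voxel_size = 1),
                     class = "deformation_field")
  warped <- apply_deformation(p$labels, shift, "nearest", background = 0)
  expect_identical(warped[3:d[1], , ], p$labels[1:(d[1] - 2), , ])
  expect_true(all(warped[1:2, , ] == 0))
  # nearest interpolation cannot invent labels
  expect_true(all(unique(as.vector(warped)) %in% c(0, unique(as.vector(p$labels)))))
  bad <- structure(list(displacement = array(0, c(8, 8, 8, 3)), voxel_size = 1),
                   class = "deformation_field")
  expect_error(apply_deformation(p$labels, bad), "grid")
})

test_that("reference segmenter recovers noise-free labels away from boundaries", {
  p0 <- generate_phantom(phantom_spec(rep(36, 3), noise_sd = 0, bias_amplitude = 0))
  seg <- reference_segment(p0$intensity)
  # voxels with a uniform 26-neighborhood must be classified exactly
  interior <- array(TRUE, dim(p0$labels))
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    s <- neuroinpaint:::shift_array(p0$labels, di, dj, dk, fill = -1)
    interior <- interior & (s == p0$labels | s == -1)
  }
  expect_true(all(seg[interior] == p0$labels[interior]))

  const <- array(default_class_means()[["4"]], c(8, 8, 8))
  expect_true(all(reference_segment(const) == 4))
  # tie between two class means resolves to the lowest label id
  tied <- array(100, c(6, 6, 6))
  expect_true(all(reference_segment(tied, c(`2` = 90, `5` = 110)) == 2))
  expect_error(reference_segment(array(1, c(0, 3, 3))), "non-empty")
})
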