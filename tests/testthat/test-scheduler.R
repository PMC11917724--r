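test_that("view rotation visits all views with equal frequency", {
  cfg <- inpaint_config(T_infer = 300)
  views <- vapply(300:1, next_view, character(1), config = cfg)
  expect_equal(unname(table(views)["axial"]), 100, ignore_attr = TRUE)
  expect_equal(unname(table(views)["coronal"]), 100, ignore_attr = TRUE)
  expect_equal(unname(table(views)["sagittal"]), 100, ignore_attr = TRUE)
  expect_equal(views[1:4], c("axial", "coronal", "sagittal", "axial"))
  cfg1 <- inpaint_config(T_infer = 10, view_cycle = "coronal")
  expect_true(all(vapply(10:1, next_view, character(1), config = cfg1) == "coronal"))
})

test_that("slab planning tiles the axis and keeps only lesion-intersecting slabs", {
  d <- c(64, 64, 64)
  empty <- array(0, d)
  expect_length(plan_slabs(empty, "axial", 7, 0)$slab_starts, 0)

  # mask confined to slices 11-13 (1-based), thickness 7, offset 0:
  # tiling starts 1, 8, 15, ... -> the single slab [8, 14] covers it
  m <- array(0, d); m[, , 11:13] <- 1
  plan <- plan_slabs(m, "axial", 7, 0)
  expect_equal(plan$slab_starts, 8L)

  # full-volume mask: ceiling(64 / 7) = 10 slabs, every slice covered
  full <- array(1, d)
  plan <- plan_slabs(full, "axial", 7, 0)
  expect_length(plan$slab_starts, 10)
  covered <- unique(unlist(lapply(plan$slab_starts, function(s) s:(s + 6))))
  expect_setequal(covered, 1:64)
  # interior slabs never overlap: starts advance by the slab thickness
  expect_true(all(diff(plan$slab_starts[-length(plan$slab_starts)]) == 7))

  expect_error(plan_slabs(array(0, c(4, 64, 64)), "sagittal", 7, 0), "smaller")
  expect_error(plan_slabs(m, "axial", 7, 7), "offset")
})

test_that("cyclic offsets cover every value across consecutive steps", {
  th <- 7
  offsets <- (20:1) %% th
  for (w in 1:(20 - th + 1)) {
    expect_setequal(offsets[w:(w + th - 1)], 0:(th - 1))
  }
})

test_that("inpainting with an empty mask returns the input bitwise with zero calls", {
  p <- fixture_phantom(seed = 6, grid = 36)
  sched <- fixture_schedule(20)
  out <- inpaint_volume(p$intensity, array(0, dim(p$intensity)),
                        fixture_tiny_model(), sched,
                        inpaint_config(T_infer = 20, seed = 1))
  expect_equal(attr(out, "denoiser_calls"), 0L)
  attr(out, "denoiser_calls") <- NULL
  expect_identical(out, p$intensity)
})

test_that("voxels outside the mask are bit-identical after inpainting", {
  p <- fixture_phantom(seed = 6, grid = 36)
  sched <- fixture_schedule(20)
  les <- insert_tumor_lesion(p, radius = 4, displacement_amplitude = 1, seed = 3)
  mask <- array(as.numeric(les$mask), dim(les$mask))
  out <- inpaint_volume(les$phantom$intensity, mask, fixture_tiny_model(), sched,
                        inpaint_config(T_infer = 20, seed = 5))
  expect_gt(attr(out, "denoiser_calls"), 0)
  expect_identical(out[mask == 0], les$phantom$intensity[mask == 0])
  # all inpainted values remain on the valid intensity scale
  expect_true(all(out[mask == 1] >= 0 & out[mask == 1] <= 255))
})

test_that("inpainting is seed-deterministic and varies only inside the mask", {
  p <- fixture_phantom(seed = 8, grid = 36)
  sched <- fixture_schedule(20)
  ms <- insert_ms_lesions(p, n_lesions = 2, radius_range = c(2, 3), seed = 4)
  mask <- array(as.numeric(ms$mask), dim(ms$mask))
  m <- fixture_tiny_model()
  a <- inpaint_volume(ms$phantom$intensity, mask, m, sched,
                      inpaint_config(T_infer = 20, seed = 9))
  b <- inpaint_volume(ms$phantom$intensity, mask, m, sched,
                      inpaint_config(T_infer = 20, seed = 9))
  expect_identical(a, b)
  c_ <- inpaint_volume(ms$phantom$intensity, mask, m, sched,
                       inpaint_config(T_infer = 20, seed = 10))
  expect_identical(a[mask == 0], c_[mask == 0])
  expect_false(identical(a[mask == 1], c_[mask == 1]))
})

test_that("denoiser-call count scales with the mask's slab footprint", {
  p <- fixture_phantom(seed = 6, grid = 36)
  sched <- fixture_schedule(20)
  m <- fixture_tiny_model()
  big <- array(0, dim(p$intensity)); big[8:28, 8:28, 8:28] <- 1
  small <- array(0, dim(p$intensity)); small[8:18, 8:18, 8:18] <- 1
  out_b <- inpaint_volume(p$intensity, big, m, sched, inpaint_config(T_infer = 10, seed = 1))
  out_s <- inpaint_volume(p$intensity, small, m, sched, inpaint_config(T_infer = 10, seed = 1))
  expect_lte(attr(out_s, "denoiser_calls"), attr(out_b, "denoiser_calls"))
})

test_that("finalize restores the exterior, clamps the interior, and keeps metadata", {
  orig <- array(runif(27, 0, 255), c(3, 3, 3))
  attr(orig, "voxel_size") <- 0.8
  cand <- array(runif(27, -50, 300), c(3, 3, 3))
  m0 <- array(0, c(3, 3, 3))
  expect_identical(finalize(cand, orig, m0), orig)
  m1 <- array(1, c(3, 3, 3))
  full <- finalize(cand, orig, m1)
  expect_equal(as.vector(full), pmin(pmax(as.vector(cand), 0), 255))
  expect_identical(attr(full, "voxel_size"), 0.8)
  mm <- m0; mm[1, , ] <- 1
  fin <- finalize(cand, orig, mm)
  expect_identical(fin[mm == 0], orig[mm == 0])
})

test_that("inpainting rejects invalid inputs", {
  p <- fixture_phantom(seed = 6, grid = 36)
  sched <- fixture_schedule(20)
  m <- fixture_tiny_model()
  expect_error(inpaint_volume(p$intensity, array(0, c(8, 8, 8)), m, sched),
               "grid")
  badmask <- array(0, dim(p$intensity)); badmask[1] <- 0.5
  expect_error(inpaint_volume(p$intensity, badmask, m, sched), "binary")
  mask <- array(0, dim(p$intensity)); mask[18, 18, 18] <- 1
  expect_error(inpaint_volume(p$intensity, mask, list(axial = m), sched,
                              inpaint_config(T_infer = 5, seed = 1)),
               "no trained model")
})

test_that("mean-fill baseline fills the mask with the surrounding ring mean", {
  vol <- array(100, c(16, 16, 16))
  vol[4:8, 4:8, 4:8] <- 200
  mask <- array(0, c(16, 16, 16)); mask[5:7, 5:7, 5:7] <- 1
  mf <- mean_fill_inpaint(vol, mask)
  expect_identical(mf[mask == 0], vol[mask == 0])
  expect_true(all(mf[mask == 1] == mf[which(mask == 1)[1]]))
  expect_identical(mean_fill_inpaint(vol, array(0, dim(vol))), vol)
})
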