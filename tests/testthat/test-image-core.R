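test_that("NIfTI write/read round-trip preserves data and geometry", {
  dir <- withr::local_tempdir()
  img <- random_image(spacing = c(0.78, 0.78, 5), origin = c(1.5, -2, 3),
                      direction = rotation_about_z(0.3), seed = 7)
  f <- file.path(dir, "img.nii.gz")
  write_image(img, f)
  r <- read_image(f)
  expect_lt(max(abs(r$data - img$data)), 1e-6)
  expect_lt(max(abs(r$spacing - img$spacing)), 1e-6)
  expect_lt(max(abs(r$origin - img$origin)), 1e-6)
  expect_lt(max(abs(r$direction - img$direction)), 1e-6)
})

test_that("read_image recovers a diagonal affine from spacing", {
  dir <- withr::local_tempdir()
  img <- random_image(spacing = c(0.78, 0.78, 5))
  f <- file.path(dir, "diag.nii")
  write_image(img, f)
  aff <- RNifti::xform(RNifti::readNifti(f))
  expect_equal(diag(aff[1:3, 1:3]), c(0.78, 0.78, 5), tolerance = 1e-6)
})

test_that("read_image rejects missing files and non-3D payloads", {
  expect_error(read_image(file.path(tempdir(), "nope.nii")), "not found")
  dir <- withr::local_tempdir()
  f <- file.path(dir, "flat.nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(runif(16), 4, 4)), f)
  expect_error(read_image(f), "3D")
})

test_that("image3d validates geometry invariants", {
  expect_error(image3d(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image3d(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(image3d(array(0, c(2, 2, 2)), direction = diag(3) * 2),
               "orthonormal")
  expect_error(image3d(array(0, c(2, 2, 2)), mask = array(1, c(3, 2, 2))),
               "mask")
})

test_that("voxel/world maps follow the affine and invert each other", {
  img <- random_image(spacing = c(1, 2, 3), origin = c(0, 0, 0))
  expect_equal(voxel_to_world(img, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(voxel_to_world(img, c(1, 1, 1)), c(1, 2, 3))
  img2 <- random_image(spacing = c(0.7, 1.1, 2.3), origin = c(5, -3, 2),
                       direction = rotation_about_z(0.9))
  set.seed(3)
  p <- matrix(runif(30, -10, 10), ncol = 3)
  expect_lt(max(abs(world_to_voxel(img2, voxel_to_world(img2, p)) - p)),
            1e-9)
})

test_that("rigid transforms compose, invert and stay rigid", {
  tr <- rigid_euler(c(10, -5, 20), c(1, 2, 3), center = c(4, 5, 6))
  expect_lt(max(abs(crossprod(tr$R) - diag(3))), 1e-12)
  expect_equal(det(tr$R), 1, tolerance = 1e-12)
  id <- compose_rigid(tr, invert_rigid(tr))
  expect_lt(max(abs(id$R - diag(3))), 1e-6)
  expect_lt(max(abs(id$t)), 1e-6)
  # composition acts right-to-left on points
  a <- rigid_euler(c(0, 0, 30)); b <- rigid_euler(c(15, 0, 0), c(1, 0, 0))
  p <- c(1, 2, 3)
  expect_equal(apply_rigid(compose_rigid(a, b), p),
               apply_rigid(a, apply_rigid(b, p)), tolerance = 1e-12)
  expect_equal(rotation_angle(rigid_euler(c(0, 0, 7))), 7, tolerance = 1e-9)
})

test_that("split_stack produces consistently posed slices and is invertible", {
  img <- random_image(dims = c(32, 32, 20), spacing = c(1, 1, 2.5),
                      origin = c(-3, 4, 1), direction = rotation_about_z(0.4),
                      seed = 11)
  st <- split_stack(img, stack_id = "s1")
  expect_length(st$slices, 20)
  expect_identical(vapply(st$slices, function(s) s$slice_index, integer(1)),
                   0:19)
  for (k in c(1, 7, 20)) {
    f <- slice_transform(st$slices[[k]])
    expect_equal(f$t, voxel_to_world(img, c(0, 0, k - 1)), tolerance = 1e-9)
  }
  back <- stack_to_image(st)
  expect_identical(back$data, img$data)
  expect_equal(back$spacing, img$spacing, tolerance = 1e-12)
  # mask dimensions are checked
  expect_error(split_stack(img, mask = random_image(c(8, 8, 8))), "mask")
})

test_that("propagate_mask is nearest-neighbour through world space", {
  set.seed(2)
  m <- image3d(array(rbinom(8 * 8 * 8, 1, 0.4), c(8, 8, 8)),
               spacing = c(1, 1, 1))
  same <- propagate_mask(m, m)
  expect_identical(same$data, m$data * 1)
  # target shifted by exactly one voxel along axis 0: brute-force oracle
  tgt <- image3d(array(0, c(8, 8, 8)), spacing = c(1, 1, 1),
                 origin = c(1, 0, 0))
  out <- propagate_mask(m, tgt)
  oracle <- array(0, c(8, 8, 8))
  oracle[1:7, , ] <- m$data[2:8, , ]
  expect_identical(out$data, oracle * 1)
  expect_true(all(out$data %in% c(0, 1)))
  expect_warning(propagate_mask(image3d(array(0, c(4, 4, 4))), tgt), "empty")
})

test_that("propagate_mask is idempotent on a shared lattice", {
  set.seed(9)
  m <- image3d(array(rbinom(6^3, 1, 0.5), c(6, 6, 6)))
  once <- propagate_mask(m, m)
  twice <- propagate_mask(once, m)
  expect_identical(once$data, twice$data)
})

test_that("polynomial bias-field correction flattens a smooth shading", {
  ph <- make_phantom(dims = 20, spacing = 1, seed = 33)
  d <- dim(ph$data)
  co <- sweep(arrayInd(seq_len(prod(d)), d) - 1, 2, d - 1, "/") - 0.5
  field <- array(exp(0.6 * co[, 1] + 0.4 * co[, 3]), d)
  flat <- ph
  flat$data <- (ph$mask != 0) * 0.5          # homogeneous tissue
  shaded <- flat
  shaded$data <- flat$data * field
  fixed <- polyfield_correction(shaded, mask = flat, order = 1)
  fg <- ph$mask != 0
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(shaded$data[fg]), 0.1)        # shading is material
  expect_lt(cv(fixed$data[fg]), 0.01)        # and removed
})

test_that("linear intensity correction recovers affine intensity maps", {
  ts <- fixture("tiny_sim_clean", function() tiny_sim())
  # a stack whose pixels ARE the reference samples at the pixel positions
  st <- ts$stacks[[1]]
  for (k in seq_along(st$slices)) {
    sl <- st$slices[[k]]
    w <- srrecon:::slice_pixel_world(sl)
    st$slices[[k]]$pixels <- matrix(sample_volume(ts$phantom, w),
                                    nrow(sl$pixels), ncol(sl$pixels))
  }
  fixed <- linear_intensity_correction(st, ts$phantom)
  expect_equal(attr(fixed, "intensity_map"), c(1, 0), tolerance = 1e-9)
  # y = 2 * ref + 5 is mapped back (closed-form simple regression oracle)
  st2 <- st
  for (k in seq_along(st2$slices))
    st2$slices[[k]]$pixels <- 2 * st2$slices[[k]]$pixels + 5
  corr <- linear_intensity_correction(st2, ts$phantom)
  expect_equal(attr(corr, "intensity_map"), c(0.5, -2.5), tolerance = 1e-9)
  for (k in seq_along(corr$slices))
    expect_lt(max(abs(corr$slices[[k]]$pixels - st$slices[[k]]$pixels)),
              1e-9)
  # degenerate: constant stack
  st3 <- st
  for (k in seq_along(st3$slices)) st3$slices[[k]]$pixels[] <- 1
  expect_warning(out <- linear_intensity_correction(st3, ts$phantom),
                 "degenerate")
  expect_equal(attr(out, "intensity_map"), c(1, 0))
})
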