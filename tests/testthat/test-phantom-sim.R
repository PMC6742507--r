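test_that("phantom generation is deterministic and well-bounded", {
  p1 <- make_phantom(dims = 24, seed = 9)
  p2 <- make_phantom(dims = 24, seed = 9)
  expect_identical(p1$data, p2$data)
  p3 <- make_phantom(dims = 24, seed = 10)
  expect_false(identical(p1$data, p3$data))
  expect_gte(min(p1$data), 0)
  expect_lte(max(p1$data), 1)
  expect_true(all(p1$data[p1$mask == 0] == 0))
  # tubes are brighter than the 90th percentile of the other foreground
  tube <- attr(p1, "tube")
  fg_other <- p1$mask != 0 & !tube
  expect_gt(min(p1$data[tube]), quantile(p1$data[fg_other], 0.9))
})

test_that("acquisition plans have the stated series counts and geometry", {
  counts <- c("a+c" = 2, "a+c+s" = 3, "2a+2c+2s" = 6, "a+c+s+3obl" = 6,
              "a+c+s+4obl" = 7, "2a+2c+2s+4obl" = 10)
  for (cfg in names(counts))
    expect_length(build_plan(cfg), counts[[cfg]])
  expect_error(build_plan("a+c+42obl"), "unknown configuration")
  plan <- build_plan("2a+2c+2s+4obl")
  for (g in plan) {
    expect_equal(sqrt(sum(g$normal^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(g$e1^2)), 1, tolerance = 1e-9)
    # right-handed orthonormal slice frame
    R <- cbind(g$e1, g$e2, g$normal)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
  # oblique normals point to the four lower cube corners: pairwise angles
  # arccos(1/3) or arccos(-1/3)
  obl <- plan[7:10]
  expect_true(all(vapply(obl, function(g) g$normal[3] < 0, logical(1))))
  for (a in 1:3) for (b in (a + 1):4) {
    d <- sum(obl[[a]]$normal * obl[[b]]$normal)
    expect_true(min(abs(d - 1 / 3), abs(d + 1 / 3)) < 1e-9)
  }
})

test_that("simulated slices follow the forward model exactly", {
  ph <- make_phantom(dims = 16, spacing = 1, seed = 11)
  plan <- build_plan("a+c", in_plane = 1, thickness = 3)
  sim <- simulate_stack(ph, plan[[1]], seed = 12)
  for (sl in sim$stack$slices) {
    proj <- srrecon:::project_slice(ph, sl)
    expect_lt(max(abs(sl$pixels - proj)), 1e-12)
  }
  # motions recorded per slice, identity when amplitudes are zero
  expect_length(sim$motions, length(sim$stack$slices))
  for (m in sim$motions) expect_lt(max(abs(m$R - diag(3))) + max(abs(m$t)), 1e-12)
})

test_that("noise amplitude is calibrated and motion draws respect bounds", {
  ph <- make_phantom(dims = 24, spacing = 1, seed = 11)
  plan <- build_plan("a+c", in_plane = 0.5, thickness = 3)
  clean <- simulate_stack(ph, plan[[1]], noise_sd = 0, seed = 13)
  noisy <- simulate_stack(ph, plan[[1]], noise_sd = 0.01, seed = 13)
  resid <- unlist(lapply(seq_along(clean$stack$slices), function(k)
    noisy$stack$slices[[k]]$pixels - clean$stack$slices[[k]]$pixels))
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.01) / 0.01, 0.10)
  moved <- simulate_stack(ph, plan[[1]], motion_t = 3, motion_r = 3,
                          seed = 14)
  for (m in moved$motions) {
    expect_lte(rotation_angle(m), 3 + 1e-9)
    disp <- apply_rigid(m, moved$center) - moved$center
    expect_lte(sqrt(sum(disp^2)), 3 + 1e-9)
  }
})

test_that("half-shifted stacks interleave the unshifted slice centres", {
  ph <- make_phantom(dims = 24, spacing = 1, seed = 11)
  plan <- build_plan("2a+2c+2s", in_plane = 1, thickness = 4)
  ax <- simulate_stack(ph, plan[[1]], seed = 15)$stack
  axs <- simulate_stack(ph, plan[[4]], seed = 15)$stack
  z <- vapply(ax$slices, function(sl)
    sum(slice_transform(sl)$t * c(0, 0, 1)), numeric(1))
  zs <- vapply(axs$slices, function(sl)
    sum(slice_transform(sl)$t * c(0, 0, 1)), numeric(1))
  off <- outer(zs, z, "-")
  # every shifted centre sits half a thickness from an unshifted one
  expect_lt(max(abs(apply(abs(off - 2), 1, min))), 1e-9)
})

test_that("slice corruption is booked correctly and severe enough", {
  ph <- make_phantom(dims = 24, spacing = 0.9, seed = 16)
  plan <- build_plan("a+c", in_plane = 0.9, thickness = 4)
  sim <- simulate_stack(ph, plan[[1]], noise_sd = 0.01, seed = 17)
  st <- sim$stack
  expect_identical(corrupt_slices(st, 0)$slices, st$slices)
  bad <- corrupt_slices(st, 2, mode = "mispose", seed = 18)
  idx <- attr(bad, "corrupted")
  expect_length(idx, 2)
  for (k in seq_along(st$slices)) {
    same_pose <- max(abs(bad$slices[[k]]$pose$R - st$slices[[k]]$pose$R)) +
      max(abs(bad$slices[[k]]$pose$t - st$slices[[k]]$pose$t)) < 1e-12
    expect_identical(bad$slices[[k]]$pixels, st$slices[[k]]$pixels)
    expect_equal(!same_pose, (k - 1) %in% idx)
  }
  noisy <- corrupt_slices(st, 2, mode = "noise", seed = 19)
  for (k in attr(noisy, "corrupted") + 1) {
    expect_false(identical(noisy$slices[[k]]$pixels, st$slices[[k]]$pixels))
    # histogram preserved, structure destroyed
    expect_equal(sort(as.numeric(noisy$slices[[k]]$pixels)),
                 sort(as.numeric(st$slices[[k]]$pixels)))
  }
  # corrupted slices disagree with their original projections below the
  # first rejection threshold
  for (k in attr(noisy, "corrupted") + 1) {
    proj <- srrecon:::project_slice(ph, st$slices[[k]])
    keep <- st$slices[[k]]$mask != 0
    expect_lt(ncc(noisy$slices[[k]]$pixels[keep], proj[keep]), 0.6)
  }
  expect_error(corrupt_slices(st, length(st$slices)), "smaller")
})

test_that("protocol geometry reproduces the through-plane sampling ratio", {
  plan <- build_plan("a+c")
  ratio <- plan[[1]]$thickness / plan[[1]]$in_plane
  expect_equal(ratio, 5 / 0.78, tolerance = 1e-12)
  expect_equal(round(ratio), 6)
})
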