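# Registration and pipeline behaviour on small phantoms.  The full
# motion-recovery study at protocol scale lives in test-acceptance.R.

reg_fixture <- function() {
  fixture("reg_phantom", function() {
    ph <- make_phantom(dims = 28, spacing = 1, seed = 21)
    sim <- simulate_protocol(ph, "a+c+s", seed = 21, in_plane = 1,
                             thickness = 4)
    list(phantom = ph, stacks = sim$stacks, grid = roi_grid(ph))
  })
}

test_that("self-registration is a fixed point", {
  fx <- reg_fixture()
  set <- registration_settings(truncation = 3)   # matches the simulation PSF
  sl <- fx$stacks[[1]]$slices[[3]]
  corr <- register_slice_rigid(sl, fx$phantom, settings = set)
  expect_false(attr(corr, "failed"))
  expect_lt(sqrt(sum(corr$t^2)), 0.1)
  expect_lt(rotation_angle(corr), 0.1)
})

test_that("known in-plane translation and rotation are recovered", {
  fx <- reg_fixture()
  set <- registration_settings()
  sl <- fx$stacks[[1]]$slices[[3]]
  cen <- srrecon:::slice_center_world(sl)
  # 2 mm in-plane translation
  truth_t <- rigid_transform(diag(3), c(2, 0, 0))
  moved <- sl
  moved$pixels <- srrecon:::project_slice(fx$phantom, sl, correction = truth_t)
  corr <- register_slice_rigid(moved, fx$phantom, settings = set)
  E <- compose_rigid(invert_rigid(corr), truth_t)
  expect_lt(sqrt(sum((apply_rigid(E, cen) - cen)^2)), 0.5)
  # 3 degree rotation about the slice normal (axis 3 for an axial slice)
  truth_r <- rigid_euler(c(0, 0, 3), center = cen)
  moved$pixels <- srrecon:::project_slice(fx$phantom, sl, correction = truth_r)
  corr <- register_slice_rigid(moved, fx$phantom, settings = set)
  E <- compose_rigid(invert_rigid(corr), truth_r)
  expect_lt(rotation_angle(E), 1)
})

test_that("registration returns init with a flag on empty overlap", {
  fx <- reg_fixture()
  sl <- fx$stacks[[1]]$slices[[3]]
  sl$pose <- rigid_transform(diag(3), c(0, 0, 500))
  sl$mask <- NULL
  out <- register_slice_rigid(sl, fx$phantom)
  expect_true(attr(out, "failed"))
  expect_equal(out$R, diag(3))
})

test_that("stack alignment is near-identity for aligned stacks and recovers
           a known stack offset", {
  fx <- reg_fixture()
  set <- registration_settings()
  al <- align_stacks(fx$stacks, settings = set, grid = fx$grid)
  expect_length(al$transforms, length(fx$stacks))
  for (tr in al$transforms) {
    expect_lt(sqrt(sum((apply_rigid(tr, c(0, 0, 0)) - c(0, 0, 0))^2)), 0.5)
    expect_lt(rotation_angle(tr), 1)
  }
  # displace one stack by 3 mm and ask for it back
  moved <- fx$stacks
  off <- rigid_transform(diag(3), c(3, 0, 0))
  for (j in seq_along(moved[[2]]$slices)) {
    sl <- moved[[2]]$slices[[j]]
    moved[[2]]$slices[[j]]$pixels <-
      srrecon:::project_slice(fx$phantom, sl, correction = off)
  }
  al2 <- align_stacks(moved, settings = set, grid = fx$grid)
  rec <- al2$transforms[[2]]
  expect_lt(sqrt(sum((rec$t - off$t)^2)), 0.5)
})

test_that("inlier selection respects thresholds, masks and nesting", {
  fx <- reg_fixture()
  set <- registration_settings(truncation = 3)
  x <- solve_srr(fx$stacks, fx$grid, alpha = 0.01, max_outer = 4)
  # sigma = -1 retains everything (NCC >= -1 always)
  sel_all <- select_inliers(fx$stacks, x, -1, settings = set)
  expect_identical(vapply(sel_all$inliers, length, integer(1)),
                   vapply(fx$stacks, function(s) length(s$slices),
                          integer(1)))
  # noiseless self-consistent slices all survive the tightest threshold:
  # re-simulate the slices from the reconstruction itself
  self_stacks <- fx$stacks
  for (si in seq_along(self_stacks))
    for (j in seq_along(self_stacks[[si]]$slices)) {
      sl <- self_stacks[[si]]$slices[[j]]
      self_stacks[[si]]$slices[[j]]$pixels <-
        srrecon:::project_slice(x, sl)
    }
  sel_self <- select_inliers(self_stacks, x, 0.7, settings = set)
  expect_identical(vapply(sel_self$inliers, length, integer(1)),
                   vapply(self_stacks, function(s) length(s$slices),
                          integer(1)))
  expect_true(all(unlist(sel_self$scores) > 0.99))
  # one shuffled slice is rejected at 0.6, clean ones retained
  bad <- self_stacks
  set.seed(22)
  bad[[1]]$slices[[2]]$pixels <-
    matrix(sample(as.numeric(bad[[1]]$slices[[2]]$pixels)),
           nrow(bad[[1]]$slices[[2]]$pixels))
  sel_bad <- select_inliers(bad, x, 0.6, settings = set)
  expect_false(1L %in% sel_bad$inliers[[1]])
  expect_equal(sum(lengths(sel_self$inliers)) - sum(lengths(sel_bad$inliers)),
               1)
  # threshold nesting
  lo <- select_inliers(bad, x, 0.6, settings = set)
  hi <- select_inliers(bad, x, 0.7, settings = set)
  for (si in seq_along(lo$inliers))
    expect_true(all(hi$inliers[[si]] %in% lo$inliers[[si]]))
})

test_that("static reconstruction is the sigma = -1, no-registration
           reduction of the robust pipeline", {
  fx <- reg_fixture()
  sta <- reconstruct_static(fx$stacks, fx$grid, alpha = 0.01, max_outer = 3)
  rob <- suppressWarnings(reconstruct_outlier_robust(
    fx$stacks, fx$grid, alpha = 0.01, iterations = 1, sigma = -1,
    align = FALSE, register = FALSE, max_outer = 3))
  expect_identical(sta$volume$data, rob$volume$data)
  expect_identical(sta$inlier_history, rob$inlier_history)
  # bookkeeping contract: one all-slices inlier set, nothing rejected
  expect_length(sta$inlier_history, 1)
  expect_equal(sta$rejected_count, 0)
  expect_identical(vapply(sta$inlier_history[[1]], length, integer(1)),
                   vapply(fx$stacks, function(s) length(s$slices),
                          integer(1)))
  expect_gte(min(sta$volume$data), 0)
})

test_that("in-plane deformation is a fixed point on identical sections and
           recovers a synthetic warp", {
  fx <- reg_fixture()
  sl <- fx$stacks[[1]]$slices[[3]]
  # identical reference: displacement stays essentially zero
  out <- deform_slice_inplane(sl, sl$pixels, max_iter = 10)
  expect_false(attr(out, "failed"))
  u <- attr(out, "displacement")
  if (!is.null(u)) expect_lt(max(abs(c(u$ux, u$uy))), 0.3)
  # a smooth 2-pixel bump: warping back improves LNCC
  d <- dim(sl$pixels)
  gx <- outer(seq_len(d[1]), rep(1, d[2]))
  bump_u <- 2 * exp(-((gx - d[1] / 2)^2) / 18)
  warped <- srrecon:::cpp_warp_bilinear(sl$pixels, bump_u, bump_u * 0)
  wsl <- sl
  wsl$pixels <- warped
  before <- lncc(warped, sl$pixels, mask = sl$mask, radius = 3)
  rec <- deform_slice_inplane(wsl, sl$pixels, max_iter = 25)
  expect_gte(attr(rec, "lncc"), before)
  if (!attr(rec, "failed")) {
    after <- lncc(rec$pixels, sl$pixels, mask = sl$mask, radius = 3)
    expect_gt(after, before)
  }
})

test_that("reference-guided reconstruction reduces to the static solution
           for a perfect reference without motion", {
  fx <- reg_fixture()
  set <- registration_settings(truncation = 3)   # PSF matches the simulation
  rg <- reconstruct_reference_guided(fx$stacks, fx$phantom, grid = fx$grid,
                                     alpha = 0.01, settings = set,
                                     max_outer = 3)
  sta <- reconstruct_static(fx$stacks, fx$grid, alpha = 0.01, max_outer = 3)
  # identity corrections score 1 against the generating volume, so
  # registration is a fixed point and the solves coincide
  expect_false(any(unlist(rg$flags)))
  expect_identical(rg$volume$data, sta$volume$data)
  expect_equal(rg$method, "rg")
})

test_that("a contrast-free reference raises per-slice failure flags", {
  fx <- reg_fixture()
  flat <- fx$phantom
  flat$data[] <- 0
  rg <- reconstruct_reference_guided(fx$stacks, flat, grid = fx$grid,
                                     alpha = 0.01, max_outer = 2)
  expect_true(all(unlist(rg$flags)))
})

test_that("motion_errors reports one row per slice with sane zeros", {
  fx <- reg_fixture()
  sta <- reconstruct_static(fx$stacks, fx$grid, alpha = 0.01, max_outer = 2)
  motions <- lapply(fx$stacks, function(st)
    lapply(st$slices, function(sl) rigid_transform()))
  me <- motion_errors(sta, motions)
  expect_equal(nrow(me), sum(vapply(fx$stacks, function(s)
    length(s$slices), integer(1))))
  expect_lt(max(me$trans_mm), 1e-9)
  expect_lt(max(me$rot_deg), 1e-9)
})
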