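test_that("spatial gradient and its adjoint are exact duals", {
  expect_true(all(unlist(spatial_gradient(array(3, c(5, 6, 4)))) == 0))
  ramp <- array(rep(0:4, 5 * 4), c(5, 5, 4))
  g <- spatial_gradient(ramp)
  expect_true(all(g$gx[1:4, , ] == 1))
  expect_true(all(g$gx[5, , ] == 0))
  set.seed(13)
  x <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  gr <- list(gx = array(rnorm(210), c(5, 6, 7)),
             gy = array(rnorm(210), c(5, 6, 7)),
             gz = array(rnorm(210), c(5, 6, 7)))
  gx <- spatial_gradient(x)
  lhs <- sum(gx$gx * gr$gx) + sum(gx$gy * gr$gy) + sum(gx$gz * gr$gz)
  rhs <- sum(x * gradient_adjoint(gr))
  expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
})

test_that("sparse gradient matrix agrees with the array operator", {
  set.seed(14)
  dims <- c(4, 5, 3)
  x <- array(rnorm(prod(dims)), dims)
  D <- srrecon:::gradient_matrix(dims)
  g <- spatial_gradient(x)
  expect_lt(max(abs(as.numeric(D %*% as.numeric(x)) -
                    c(g$gx, g$gy, g$gz))), 1e-12)
})

test_that("scattered init matches a brute-force Nadaraya-Watson oracle", {
  ph <- make_phantom(dims = 12, spacing = 1, seed = 3)
  sim <- simulate_protocol(ph, "a+c", seed = 3, in_plane = 1, thickness = 2)
  grid <- recon_grid(c(12, 12, 12), 1, origin = ph$origin)
  nw <- scattered_init(sim$stacks, grid, use_mask = FALSE)
  # independent oracle: accumulate unnormalized Gaussian weights per voxel
  num <- array(0, grid$dims); den <- array(0, grid$dims)
  vox <- as.matrix(expand.grid(i = 0:11, j = 0:11, k = 0:11))
  vox_w <- sweep(vox, 2, grid$origin, "+")
  for (st in sim$stacks) for (sl in st$slices) {
    tr <- compose_rigid(sl$correction, sl$pose)
    s <- c(sl$in_plane_spacing, sl$thickness)
    cov <- tr$R %*% diag(c((1.2 * s[1])^2, (1.2 * s[2])^2, s[3]^2) /
                           (8 * log(2))) %*% t(tr$R)
    covinv <- solve(cov)
    d <- dim(sl$pixels)
    for (jj in seq_len(d[2])) for (ii in seq_len(d[1])) {
      cen <- tr$t + (ii - 1) * tr$R[, 1] * s[1] + (jj - 1) * tr$R[, 2] * s[2]
      df <- sweep(vox_w, 2, cen, "-")
      m <- rowSums((df %*% covinv) * df)
      w <- ifelse(m <= 9, exp(-m / 2), 0)
      num <- num + array(w, grid$dims) * sl$pixels[ii, jj]
      den <- den + array(w, grid$dims)
    }
  }
  oracle <- ifelse(den > 1e-12, num / pmax(den, 1e-12), 0)
  expect_lt(max(abs(nw$data - oracle)), 1e-8)
  # constant stacks give a constant volume inside the joint support
  stc <- sim$stacks
  for (si in seq_along(stc)) for (j in seq_along(stc[[si]]$slices))
    stc[[si]]$slices[[j]]$pixels[] <- 4.2
  nwc <- scattered_init(stc, grid, use_mask = FALSE)
  def <- !attr(nwc, "undefined")
  expect_lt(max(abs(nwc$data[def] - 4.2)), 1e-9)
  expect_true(all(nwc$data[attr(nwc, "undefined")] == 0))
})

test_that("solver matches the dense normal-equations oracle", {
  ph <- make_phantom(dims = 6, spacing = 1, seed = 4)
  ph$data <- ph$data + 0.2            # keep the solution interior (x > 0)
  ph$mask <- array(1, dim(ph$data))   # plan slices over the full cube
  sim <- simulate_protocol(ph, "a+c+s", seed = 4, in_plane = 1,
                           thickness = 1.5, min_mask_pixels = 4)
  for (si in seq_along(sim$stacks))
    for (j in seq_along(sim$stacks[[si]]$slices))
      sim$stacks[[si]]$slices[[j]]$mask <- NULL   # dense oracle uses all pixels
  grid <- recon_grid(c(6, 6, 6), 1, origin = ph$origin)
  alpha <- 0.01
  x <- solve_srr(sim$stacks, grid, alpha = alpha, max_outer = 30,
                 max_inner = 40, tol = 1e-12)
  slices <- srrecon:::selected_slices(sim$stacks)
  A <- do.call(rbind, lapply(slices, function(sl)
    as.matrix(slice_operator(sl, grid)$A)))
  yv <- unlist(lapply(slices, function(sl) as.numeric(sl$pixels)))
  D <- as.matrix(srrecon:::gradient_matrix(grid$dims))
  xd <- solve(crossprod(A) + alpha * crossprod(D), crossprod(A, yv))
  expect_true(min(xd) > 0)            # interior: constraint inactive
  obj <- function(v) 0.5 * sum((A %*% v - yv)^2) + alpha / 2 * sum((D %*% v)^2)
  expect_lte(obj(as.numeric(x$data)), obj(xd) + 1e-6)
  # exact-data recovery with verified full column rank
  expect_equal(qr(A)$rank, ncol(A))
  x0 <- solve_srr(sim$stacks, grid, alpha = 0, max_outer = 30,
                  max_inner = 40, tol = 1e-12)
  truth <- ph$data
  expect_lt(sqrt(sum((x0$data - truth)^2)) / sqrt(sum(truth^2)), 0.05)
})

test_that("full inlier subset reproduces the unrestricted solution exactly", {
  ts <- fixture("tiny_sim_clean", function() tiny_sim())
  all_idx <- lapply(ts$stacks, function(st)
    vapply(st$slices, function(sl) sl$slice_index, integer(1)))
  x_all <- solve_srr(ts$stacks, ts$grid, alpha = 0.01, max_outer = 3)
  x_sub <- solve_srr(ts$stacks, ts$grid, alpha = 0.01, inliers = all_idx,
                     max_outer = 3)
  expect_identical(x_all$data, x_sub$data)
  expect_error(solve_srr(ts$stacks, ts$grid,
                         inliers = lapply(all_idx, function(i) i + 99L)),
               "missing slice")
})

test_that("solver output is non-negative and regularization dominates", {
  ts <- fixture("tiny_sim_clean", function() tiny_sim())
  noisy <- ts$stacks
  set.seed(15)
  for (si in seq_along(noisy)) for (j in seq_along(noisy[[si]]$slices))
    noisy[[si]]$slices[[j]]$pixels <-
      noisy[[si]]$slices[[j]]$pixels + rnorm(400, 0, 0.3)
  x <- solve_srr(noisy, ts$grid, alpha = 0.01, max_outer = 4)
  expect_gte(min(x$data), 0)
  xl <- solve_srr(ts$stacks, ts$grid, alpha = 1e6, max_outer = 4)
  expect_lt(max(xl$data) - min(xl$data), 0.01 * max(mean(xl$data), 1e-9))
  # objective trace is non-increasing
  expect_true(all(diff(attr(x, "trace")) <= 1e-9))
})

test_that("two initializations reach the same objective (convexity)", {
  ph <- make_phantom(dims = 8, spacing = 1, seed = 6)
  sim <- simulate_protocol(ph, "a+c", seed = 6, in_plane = 1, thickness = 2,
                           min_mask_pixels = 8)
  grid <- recon_grid(c(8, 8, 8), 1, origin = ph$origin)
  obj_of <- function(x0) {
    x <- solve_srr(sim$stacks, grid, alpha = 0.05, x0 = x0, max_outer = 40,
                   max_inner = 30, tol = 1e-10)
    tail(attr(x, "trace"), 1)
  }
  set.seed(16)
  f1 <- obj_of(array(0, grid$dims))
  f2 <- obj_of(array(runif(prod(grid$dims)), grid$dims))
  expect_lt(abs(f1 - f2) / max(abs(f1), 1e-12), 1e-6)
})

test_that("l_curve reports the residual/seminorm trade-off", {
  ts <- fixture("tiny_sim_clean", function() tiny_sim())
  lc <- l_curve(ts$stacks, ts$grid, alphas = c(1e-3, 1e-1, 10),
                max_outer = 2, max_inner = 10)
  expect_equal(nrow(lc), 3)
  expect_gt(lc$residual[3], lc$residual[1])  # residual grows with alpha
  expect_lt(lc$seminorm[3], lc$seminorm[1])  # smoothness penalty shrinks
})
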