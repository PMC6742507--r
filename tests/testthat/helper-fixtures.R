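# Shared fixtures.  Heavy simulation studies are computed once per test run
# and cached here so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

random_image <- function(dims = c(4, 4, 4), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), direction = diag(3),
                         seed = 1) {
  set.seed(seed)
  image3d(array(runif(prod(dims)), dims), spacing = spacing,
          origin = origin, direction = direction)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# independent brute-force construction of the dense PSF operator matrix:
# same model (truncated oriented Gaussian, voxel-centre evaluation, row
# normalization) but written directly against the definitions, without the
# package's C++ kernels
dense_psf_matrix <- function(slice, grid, truncation = 3) {
  tr <- compose_rigid(slice$correction, slice$pose)
  s <- c(slice$in_plane_spacing, slice$thickness)
  cov <- tr$R %*% diag(c((1.2 * s[1])^2, (1.2 * s[2])^2, s[3]^2) /
                         (8 * log(2))) %*% t(tr$R)
  covinv <- solve(cov)
  dims <- if (inherits(grid, "srr_grid")) grid$dims else dim(grid$data)
  vox <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  G <- grid$direction %*% diag(grid$spacing)
  vox_w <- sweep(vox %*% t(G), 2, grid$origin, "+")
  d <- dim(slice$pixels)
  A <- matrix(0, prod(d), prod(dims))
  for (jj in seq_len(d[2])) for (ii in seq_len(d[1])) {
    cen <- tr$t + (ii - 1) * tr$R[, 1] * s[1] + (jj - 1) * tr$R[, 2] * s[2]
    df <- sweep(vox_w, 2, cen, "-")
    m <- rowSums((df %*% covinv) * df)
    w <- ifelse(m <= truncation^2, exp(-m / 2), 0)
    if (sum(w) > 0) w <- w / sum(w)
    A[ii + (jj - 1) * d[1], ] <- w
  }
  A
}

# a small phantom + single-config simulation reused by several cheap tests
tiny_sim <- function(dims = 20, config = "a+c+s", seed = 5, motion_t = 0,
                     motion_r = 0, noise_sd = 0, thickness = 4) {
  ph <- make_phantom(dims = dims, spacing = 1, seed = seed)
  sim <- simulate_protocol(ph, config, motion_t = motion_t,
                           motion_r = motion_r, noise_sd = noise_sd,
                           seed = seed, in_plane = 1, thickness = thickness)
  list(phantom = ph, stacks = sim$stacks, motions = sim$motions,
       grid = roi_grid(ph))
}
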