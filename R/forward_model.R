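# Oriented-Gaussian PSF slice acquisition operator and its adjoint.
#
# The acquisition of slice pixel j from the high-resolution volume x is
# modelled as y(j) = A(j, x) + noise, with A a PSF-defined intensity
# interpolator: a 3D Gaussian aligned with the slice, truncated at a fixed
# Mahalanobis radius and renormalized to unit row sum so constants are
# reproduced.

#' Gaussian PSF covariance of a 2D multi-slice acquisition
#'
#' The slice profile is approximated by a 3D Gaussian whose variances in the
#' slice coordinate frame are
#' `diag((1.2 s1)^2, (1.2 s2)^2, s3^2) / (8 ln 2)`,
#' i.e. in-plane FWHM of 1.2 times the pixel spacing and through-plane FWHM
#' equal to the slice thickness.
#'
#' @param s1,s2 in-plane pixel spacings in mm (> 0).
#' @param s3 slice thickness in mm (> 0).
#' @return 3x3 diagonal covariance matrix in mm^2 (class `srr_psf`).
#' @export
psf_covariance <- function(s1, s2, s3) {
  if (any(c(s1, s2, s3) <= 0))
    stop("psf_covariance: spacings must be strictly positive")
  v <- c((1.2 * s1)^2, (1.2 * s2)^2, s3^2) / (8 * log(2))
  structure(diag(v), class = "srr_psf")
}

#' Rotate a PSF covariance into the world frame
#'
#' @param cov 3x3 covariance matrix (slice frame).
#' @param rotation 3x3 orthonormal world rotation of the posed slice.
#' @return `R %*% cov %*% t(R)`.
#' @export
orient_covariance <- function(cov, rotation) {
  rotation <- as.matrix(rotation)
  if (!is_orthonormal(rotation))
    stop("orient_covariance: rotation must be orthonormal")
  structure(rotation %*% unclass(cov) %*% t(rotation), class = "srr_psf")
}

# geometry bundle consumed by the C++ kernels
operator_geometry <- function(slice, grid, truncation = 3) {
  f <- slice_frame(slice)
  cov <- orient_covariance(
    psf_covariance(slice$in_plane_spacing[1], slice$in_plane_spacing[2],
                   slice$thickness), f$R)
  G <- direction_of(grid) %*% diag(spacing_of(grid))
  Ginv <- solve(G)
  # index-space half-widths of the truncation ellipsoid bounding box
  hw <- truncation * sqrt(pmax(diag(Ginv %*% unclass(cov) %*% t(Ginv)), 0))
  list(gdim = as.integer(dim_of(grid)), G = G, Ginv = Ginv,
       o = origin_of(grid), p0 = f$p0, e1 = f$e1, e2 = f$e2,
       n1 = nrow(slice$pixels), n2 = ncol(slice$pixels),
       covinv = solve(unclass(cov)), r2 = truncation^2, hw = hw)
}

#' Build the slice acquisition operator for a posed slice on a grid
#'
#' Assembles the (sparse) linear operator mapping a high-resolution volume on
#' `grid` to the pixels of `slice` at its current corrected pose
#' (`correction o pose`).  Weights are an oriented Gaussian evaluated at
#' voxel centres, truncated at `truncation` standard deviations and
#' renormalized per pixel.
#'
#' @param slice `srr_slice`.
#' @param grid `srr_image` or `srr_grid` defining the target lattice.
#' @param truncation PSF cutoff in Mahalanobis standard deviations.
#' @return Object of class `srr_operator` with the sparse matrix `A`
#'   (`n_pixels x n_voxels`), the unnormalized row sums `wsum`, and the
#'   out-of-support pixel flags `outside`.
#' @export
slice_operator <- function(slice, grid, truncation = 3) {
  g <- operator_geometry(slice, grid, truncation)
  if (any(g$gdim <= 0)) stop("slice_operator: degenerate zero-extent grid")
  tr <- cpp_operator_triplets(g$gdim, g$G, g$Ginv, g$o, g$p0, g$e1, g$e2,
                              g$n1, g$n2, g$covinv, g$r2, g$hw, TRUE)
  A <- Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$w,
                            dims = c(g$n1 * g$n2, prod(g$gdim)))
  structure(list(A = A, wsum = tr$wsum, outside = tr$wsum == 0,
                 n1 = g$n1, n2 = g$n2, grid_dim = g$gdim,
                 truncation = truncation),
            class = "srr_operator")
}

#' Apply the forward slice operator
#'
#' Simulates the acquisition of one 2D slice from a high-resolution volume.
#' Pixels whose PSF support lies entirely outside the grid are zero and
#' flagged in the `"outside"` attribute.
#'
#' @param x `srr_image` or numeric array on the operator's grid.
#' @param op `srr_operator` from [slice_operator()].
#' @return n1 x n2 matrix of simulated pixel intensities.
#' @export
apply_forward <- function(x, op) {
  xv <- if (inherits(x, "srr_image")) as.numeric(x$data) else as.numeric(x)
  if (length(xv) != ncol(op$A))
    stop("apply_forward: volume size does not match operator grid")
  y <- matrix(as.numeric(op$A %*% xv), op$n1, op$n2)
  attr(y, "outside") <- matrix(op$outside, op$n1, op$n2)
  y
}

#' Apply the adjoint slice operator
#'
#' Scatters slice pixel values back into the high-resolution grid with the
#' transposed forward weights, satisfying `<A x, y> == <x, A^T y>`.
#'
#' @param y n1 x n2 numeric matrix (a slice residual or data term).
#' @param op `srr_operator`.
#' @return numeric 3D array on the operator grid.
#' @export
apply_adjoint <- function(y, op) {
  y <- as.matrix(y)
  if (nrow(y) != op$n1 || ncol(y) != op$n2)
    stop("apply_adjoint: slice shape mismatch")
  array(as.numeric(Matrix::crossprod(op$A, as.numeric(y))), dim = op$grid_dim)
}

# Direct (assembly-free) forward projection used inside registration loops,
# numerically identical to apply_forward(x, slice_operator(...)).  `stride`
# subsamples the pixel lattice for coarse resolution levels.
project_slice <- function(volume, slice, correction = NULL, truncation = 3,
                          stride = 1L) {
  if (!is.null(correction)) slice$correction <- correction
  g <- operator_geometry(slice, volume, truncation)
  if (stride > 1L) {
    d <- dim(slice$pixels)
    i1 <- seq(1, d[1], by = stride)
    i2 <- seq(1, d[2], by = stride)
    slice$pixels <- slice$pixels[i1, i2, drop = FALSE]
    if (!is.null(slice$mask)) slice$mask <- slice$mask[i1, i2, drop = FALSE]
    # subsample the pixel lattice; the physical PSF is unchanged
    g$e1 <- g$e1 * stride
    g$e2 <- g$e2 * stride
    g$n1 <- length(i1)
    g$n2 <- length(i2)
  }
  pr <- cpp_forward_project(as.numeric(volume$data), g$gdim, g$G, g$Ginv, g$o,
                            g$p0, g$e1, g$e2, g$n1, g$n2, g$covinv, g$r2,
                            g$hw, TRUE)
  y <- matrix(pr$y, g$n1, g$n2)
  attr(y, "outside") <- matrix(pr$wsum == 0, g$n1, g$n2)
  attr(y, "pixels") <- slice$pixels
  attr(y, "mask") <- slice$mask
  y
}
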