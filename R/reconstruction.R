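# Super-resolution reconstruction: non-negative first-order-Tikhonov
# least squares over all slice acquisition operators,
#   x* = argmin_{x >= 0}  sum_{s,i} 1/2 ||y_si - A_si x||^2 + alpha/2 ||D x||^2
# solved by conjugate-gradient least squares with non-negativity enforced by
# projection (with backtracking) between restarts.

#' Define an isotropic reconstruction grid
#'
#' @param dims integer length-3 voxel counts.
#' @param spacing isotropic voxel size in mm (scalar).
#' @param origin world mm of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix.
#' @return An object of class `srr_grid`.
#' @export
recon_grid <- function(dims, spacing, origin = c(0, 0, 0),
                       direction = diag(3)) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (max(spacing) - min(spacing) > 1e-9)
    stop("recon_grid: spacing must be isotropic")
  if (any(spacing <= 0)) stop("recon_grid: spacing must be positive")
  structure(list(dims = as.integer(dims), spacing = spacing,
                 origin = as.numeric(origin), direction = as.matrix(direction)),
            class = "srr_grid")
}

#' @export
print.srr_grid <- function(x, ...) {
  cat("<srr_grid> ", paste(x$dims, collapse = " x "), " voxels at ",
      signif(x$spacing[1], 4), " mm isotropic\n", sep = "")
  invisible(x)
}

empty_volume <- function(grid, fill = 0)
  image3d(array(fill, dim = grid$dims), spacing = grid$spacing,
          origin = grid$origin, direction = grid$direction)

#' Default reconstruction grid from the input stacks
#'
#' World-axis-aligned isotropic lattice at the in-plane spacing of the first
#' stack (unless overridden), covering the union of the motion-corrected
#' stack footprints dilated by `margin` voxels.
#'
#' @param stacks list of `srr_stack`.
#' @param spacing isotropic spacing in mm; default in-plane spacing of the
#'   first stack.
#' @param margin dilation of the field of view in voxels.
#' @export
default_recon_grid <- function(stacks, spacing = NULL, margin = 1) {
  if (is.null(spacing)) spacing <- stacks[[1]]$slices[[1]]$in_plane_spacing[1]
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (st in stacks) for (sl in st$slices) {
    f <- slice_frame(sl)
    d <- dim(sl$pixels)
    n3 <- slice_transform(sl)$R[, 3] * sl$thickness / 2
    corners <- rbind(f$p0, f$p0 + (d[1] - 1) * f$e1, f$p0 + (d[2] - 1) * f$e2,
                     f$p0 + (d[1] - 1) * f$e1 + (d[2] - 1) * f$e2)
    corners <- rbind(sweep(corners, 2, n3, "+"), sweep(corners, 2, n3, "-"))
    lo <- pmin(lo, apply(corners, 2, min))
    hi <- pmax(hi, apply(corners, 2, max))
  }
  origin <- lo - margin * spacing
  dims <- ceiling((hi - origin) / spacing) + margin + 1
  recon_grid(dims, spacing, origin)
}

#' Reconstruction grid covering an image's field of view
#'
#' Isotropic lattice aligned with the image axes and covering its extent
#' (typically the masked region of interest), dilated by `margin` voxels.
#' Reconstruction restricted to the imaged ROI is much cheaper than the
#' union-of-footprints default when oblique stacks are present.
#'
#' @param img `srr_image` (e.g. a phantom or a mask image).
#' @param spacing isotropic spacing in mm; default the in-plane spacing of
#'   the image.
#' @param margin dilation in voxels.
#' @export
roi_grid <- function(img, spacing = NULL, margin = 2) {
  if (is.null(spacing)) spacing <- img$spacing[1]
  lo <- voxel_to_world(img, c(0, 0, 0))
  hi <- voxel_to_world(img, dim(img$data) - 1)
  lo2 <- pmin(lo, hi); hi2 <- pmax(lo, hi)
  origin <- lo2 - margin * spacing
  dims <- ceiling((hi2 - origin) / spacing) + margin + 1
  recon_grid(dims, spacing, origin, direction = diag(3))
}

#' Resample an image onto a grid
#'
#' @param img `srr_image`.
#' @param grid `srr_grid` or `srr_image` giving the target lattice.
#' @param interpolation `"linear"` or `"nearest"`.
#' @export
resample_to_grid <- function(img, grid, interpolation = "linear") {
  d <- dim_of(grid)
  out <- empty_volume(if (inherits(grid, "srr_grid")) grid else
    recon_grid(d, spacing_of(grid)[1], origin_of(grid), direction_of(grid)))
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  w <- voxel_to_world(out, idx)
  out$data <- array(sample_volume(img, w, interpolation = interpolation),
                    dim = d)
  out
}

# ---- first-order difference operator ----------------------------------------

#' Spatial gradient by forward finite differences
#'
#' Forward differences per axis in voxel units, zero at the far boundary
#' (Neumann).  The adjoint is [gradient_adjoint()] (negative divergence with
#' matching boundary handling).
#'
#' @param x 3D numeric array or `srr_image`.
#' @return list of three arrays `gx`, `gy`, `gz`.
#' @export
spatial_gradient <- function(x) {
  if (inherits(x, "srr_image")) x <- x$data
  d <- dim(x)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  if (d[1] > 1) gx[-d[1], , ] <- x[-1, , ] - x[-d[1], , ]
  if (d[2] > 1) gy[, -d[2], ] <- x[, -1, ] - x[, -d[2], ]
  if (d[3] > 1) gz[, , -d[3]] <- x[, , -1] - x[, , -d[3]]
  list(gx = gx, gy = gy, gz = gz)
}

#' Adjoint of the spatial gradient
#'
#' Satisfies `sum(g * spatial_gradient(x)) == sum(x * gradient_adjoint(g))`
#' for all `x`, `g`.
#'
#' @param g list of three arrays as returned by [spatial_gradient()].
#' @return 3D numeric array.
#' @export
gradient_adjoint <- function(g) {
  d <- dim(g$gx)
  out <- array(0, d)
  if (d[1] > 1) {
    out[-1, , ] <- out[-1, , ] + g$gx[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] - g$gx[-d[1], , ]
  }
  if (d[2] > 1) {
    out[, -1, ] <- out[, -1, ] + g$gy[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] - g$gy[, -d[2], ]
  }
  if (d[3] > 1) {
    out[, , -1] <- out[, , -1] + g$gz[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] - g$gz[, , -d[3]]
  }
  out
}

# sparse matrix form of the same operator (rows: 3N stacked axis blocks)
gradient_matrix <- function(dims) {
  N <- prod(dims)
  lin <- function(i, j, k) i + dims[1] * (j + dims[2] * k) + 1
  idx <- expand.grid(i = seq_len(dims[1]) - 1, j = seq_len(dims[2]) - 1,
                     k = seq_len(dims[3]) - 1)
  blocks <- list()
  for (ax in 1:3) {
    ok <- idx[[ax]] < dims[ax] - 1
    self <- which(ok)
    step <- c(1, dims[1], dims[1] * dims[2])[ax]
    blocks[[ax]] <- Matrix::sparseMatrix(
      i = c(self, self), j = c(self + step, self),
      x = c(rep(1, length(self)), rep(-1, length(self))), dims = c(N, N))
  }
  do.call(rbind, blocks)
}

# ---- scattered-data initialization -------------------------------------------

#' Nadaraya-Watson scattered-data approximation on a grid
#'
#' Builds an initial high-resolution volume from the (volumetrically aligned)
#' stacks: every voxel is the PSF-weighted mean of all slice pixel intensities
#' whose oriented, truncated Gaussian weight at that voxel is positive.
#' Voxels with no support are zero and flagged.
#'
#' @param stacks list of `srr_stack` (current corrections are honoured).
#' @param grid `srr_grid`.
#' @param truncation PSF cutoff in standard deviations.
#' @param use_mask restrict contributions to masked slice pixels.  Off by
#'   default: outside-mask pixels are genuine acquisition data whose
#'   (near-empty) signal constrains the reconstruction; enable for data whose
#'   field of view contains structures outside the region of interest.
#' @return `srr_image` with attribute `"undefined"` (logical array).
#' @export
scattered_init <- function(stacks, grid, truncation = 3, use_mask = FALSE) {
  num <- numeric(prod(grid$dims))
  den <- numeric(prod(grid$dims))
  for (st in stacks) for (sl in st$slices) {
    g <- operator_geometry(sl, grid, truncation)
    m <- if (use_mask && !is.null(sl$mask)) as.numeric(sl$mask != 0)
         else rep(1, g$n1 * g$n2)
    num <- num + cpp_adjoint_project(as.numeric(sl$pixels) * m, g$gdim, g$G,
                                     g$Ginv, g$o, g$p0, g$e1, g$e2, g$n1,
                                     g$n2, g$covinv, g$r2, g$hw, FALSE)
    den <- den + cpp_adjoint_project(m, g$gdim, g$G, g$Ginv,
                                     g$o, g$p0, g$e1, g$e2, g$n1, g$n2,
                                     g$covinv, g$r2, g$hw, FALSE)
  }
  undef <- den <= 1e-12
  vals <- ifelse(undef, 0, num / pmax(den, 1e-12))
  out <- empty_volume(grid)
  out$data <- array(vals, dim = grid$dims)
  attr(out, "undefined") <- array(undef, dim = grid$dims)
  out
}

# ---- solver ------------------------------------------------------------------

# select slices: inliers is NULL (all) or a list (per stack) of 0-based
# retained slice indices
selected_slices <- function(stacks, inliers = NULL) {
  out <- list()
  for (si in seq_along(stacks)) {
    keep <- if (is.null(inliers)) vapply(stacks[[si]]$slices,
                                         function(s) s$slice_index, integer(1))
            else inliers[[si]]
    all_idx <- vapply(stacks[[si]]$slices, function(s) s$slice_index,
                      integer(1))
    if (!all(keep %in% all_idx))
      stop("solve_srr: inlier index refers to a missing slice")
    for (sl in stacks[[si]]$slices)
      if (sl$slice_index %in% keep)
        out[[length(out) + 1L]] <- sl
  }
  out
}

#' Solve the regularized super-resolution problem
#'
#' Minimizes `sum_si 1/2 ||y_si - A_si x||^2 + alpha/2 ||D x||^2` over
#' `x >= 0` with conjugate-gradient least squares (CGLS) restarts and
#' projection onto the non-negative orthant between restarts; a backtracking
#' safeguard keeps the objective non-increasing across outer iterations.
#'
#' @param stacks list of `srr_stack`.
#' @param grid `srr_grid` (default [default_recon_grid()]).
#' @param alpha regularization weight (>= 0); the gradient is taken in voxel
#'   units.
#' @param inliers optional list (one per stack) of 0-based retained slice
#'   indices; `NULL` keeps every slice.
#' @param x0 optional initial volume (`srr_image` or array); default
#'   [scattered_init()].
#' @param max_outer,max_inner outer restarts and CGLS iterations per restart.
#' @param tol relative normal-equation residual for convergence.
#' @param nonneg enforce `x >= 0` (default `TRUE`).
#' @param truncation PSF cutoff in standard deviations.
#' @param use_mask restrict the data term to masked slice pixels (see
#'   [scattered_init()]; off by default).
#' @param trace_file optional CSV path for the objective-per-iteration log.
#' @return `srr_image` with attribute `"trace"` (objective per outer
#'   iteration) and `"converged"`.
#' @export
solve_srr <- function(stacks, grid = NULL, alpha = 0.01, inliers = NULL,
                      x0 = NULL, max_outer = 10, max_inner = 20, tol = 1e-6,
                      nonneg = TRUE, truncation = 3, use_mask = FALSE,
                      trace_file = NULL) {
  if (alpha < 0) stop("solve_srr: alpha must be >= 0")
  if (is.null(grid)) grid <- default_recon_grid(stacks)
  slices <- selected_slices(stacks, inliers)
  if (length(slices) == 0) stop("solve_srr: no inlier slices to reconstruct from")
  rows_of <- function(sl) {
    if (use_mask && !is.null(sl$mask)) which(as.vector(sl$mask) != 0)
    else seq_along(sl$pixels)
  }
  ops <- lapply(slices, function(sl) {
    op <- slice_operator(sl, grid, truncation = truncation)
    op$A[rows_of(sl), , drop = FALSE]
  })
  Afull <- do.call(rbind, ops)
  if (nrow(Afull) == 0)
    stop("solve_srr: no masked pixels to reconstruct from")
  yv <- unlist(lapply(slices, function(s) as.numeric(s$pixels)[rows_of(s)]))
  D <- gradient_matrix(grid$dims)
  B <- if (alpha > 0) rbind(Afull, sqrt(alpha) * D) else Afull
  cvec <- c(yv, numeric(if (alpha > 0) nrow(D) else 0))

  obj <- function(x) {
    r <- as.numeric(Afull %*% x) - yv
    reg <- if (alpha > 0) alpha * sum(as.numeric(D %*% x)^2) else 0
    0.5 * sum(r^2) + 0.5 * reg
  }

  x <- if (is.null(x0)) as.numeric(scattered_init(stacks, grid, truncation,
                                                  use_mask = use_mask)$data)
       else if (inherits(x0, "srr_image")) as.numeric(x0$data)
       else as.numeric(x0)
  if (nonneg) x <- pmax(x, 0)

  cgls <- function(x, iters) {
    r <- cvec - as.numeric(B %*% x)
    s <- as.numeric(Matrix::crossprod(B, r))
    p <- s
    gam <- sum(s^2)
    for (it in seq_len(iters)) {
      if (gam == 0) break
      q <- as.numeric(B %*% p)
      qq <- sum(q^2)
      if (qq == 0) break
      al <- gam / qq
      x <- x + al * p
      r <- r - al * q
      s <- as.numeric(Matrix::crossprod(B, r))
      gam_new <- sum(s^2)
      p <- s + (gam_new / gam) * p
      gam <- gam_new
    }
    x
  }

  s0 <- sqrt(sum(as.numeric(Matrix::crossprod(B, cvec))^2))
  f <- obj(x)
  trace <- f
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    xr <- cgls(x, max_inner)
    d <- xr - x
    t_step <- 1
    repeat {
      x_try <- x + t_step * d
      if (nonneg) x_try <- pmax(x_try, 0)
      f_try <- obj(x_try)
      if (f_try <= f || t_step < 1 / 1024) break
      t_step <- t_step / 2
    }
    if (f_try > f) { converged <- TRUE; break }  # no feasible descent left
    rel_change <- sqrt(sum((x_try - x)^2)) / max(sqrt(sum(x^2)), 1e-12)
    x <- x_try; f <- f_try
    trace <- c(trace, f)
    gnorm <- sqrt(sum(as.numeric(Matrix::crossprod(B, cvec -
                                                   as.numeric(B %*% x)))^2))
    if (gnorm <= tol * max(s0, 1e-12) || rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("solve_srr: not converged within max_outer restarts; ",
            "returning best iterate")
  if (!is.null(trace_file))
    write.csv(data.frame(iteration = seq_along(trace) - 1,
                         objective = trace),
              trace_file, row.names = FALSE)
  out <- empty_volume(grid)
  out$data <- array(x, dim = grid$dims)
  attr(out, "trace") <- trace
  attr(out, "converged") <- converged
  out
}

#' L-curve sweep for the regularization weight
#'
#' Solves the reconstruction for each candidate `alpha` and reports the data
#' residual norm, the gradient seminorm and the discrete log-log curvature of
#' the resulting L-curve.  A diagnostic aid; no automatic selection is made.
#'
#' @inheritParams solve_srr
#' @param alphas numeric vector of candidate regularization weights (> 0).
#' @return data.frame with columns `alpha`, `residual`, `seminorm`,
#'   `curvature`.
#' @export
l_curve <- function(stacks, grid = NULL, alphas = 10^seq(-4, 0, by = 0.5),
                    max_outer = 5, max_inner = 20, ...) {
  if (is.null(grid)) grid <- default_recon_grid(stacks)
  res <- sem <- numeric(length(alphas))
  x0 <- scattered_init(stacks, grid)
  for (k in seq_along(alphas)) {
    x <- solve_srr(stacks, grid, alpha = alphas[k], x0 = x0,
                   max_outer = max_outer, max_inner = max_inner, ...)
    slices <- selected_slices(stacks)
    r2 <- 0
    for (sl in slices) {
      op <- slice_operator(sl, grid)
      res2 <- (apply_forward(x, op) - sl$pixels)^2
      if (!is.null(sl$mask)) res2 <- res2[sl$mask != 0]
      r2 <- r2 + sum(res2)
    }
    res[k] <- sqrt(r2)
    g <- spatial_gradient(x)
    sem[k] <- sqrt(sum(g$gx^2) + sum(g$gy^2) + sum(g$gz^2))
  }
  lr <- log(res); ls <- log(sem)
  curv <- rep(NA_real_, length(alphas))
  if (length(alphas) >= 3) {
    for (k in 2:(length(alphas) - 1)) {
      d1r <- (lr[k + 1] - lr[k - 1]) / 2; d1s <- (ls[k + 1] - ls[k - 1]) / 2
      d2r <- lr[k + 1] - 2 * lr[k] + lr[k - 1]
      d2s <- ls[k + 1] - 2 * ls[k] + ls[k - 1]
      curv[k] <- (d1r * d2s - d1s * d2r) / (d1r^2 + d1s^2)^1.5
    }
  }
  data.frame(alpha = alphas, residual = res, seminorm = sem, curvature = curv)
}
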