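# Rigid slice-to-volume registration, the iterative outlier-robust
# registration-reconstruction pipeline, the reference-guided (optionally
# in-plane deformable) pipeline, and the static baseline.

#' Registration settings
#'
#' @param metric similarity metric name (from the similarity module
#'   vocabulary; `"ncc"` by default).
#' @param rot_scale,trans_scale optimizer parameter scales in degrees / mm.
#' @param max_eval Nelder-Mead iteration budget per resolution level
#'   (coarse, fine).
#' @param strides pixel subsampling per resolution level.
#' @param mask_restrict evaluate the metric inside the slice mask only.
#' @param n_starts number of multi-start jitter initializations (>= 1).
#' @param jitter_t,jitter_r multi-start jitter amplitudes (mm, degrees).
#' @param min_pixels minimum overlapping pixels for a valid metric.
#' @param min_overlap minimum fraction of the (masked) slice pixels whose PSF
#'   support intersects the volume for a score to count; slices mostly
#'   outside the field of view are unscorable and treated as failures.
#' @param truncation PSF cutoff used for the simulated slices.
#' @param psf_aware simulate candidate slices through the PSF forward model
#'   (default); `FALSE` falls back to trilinear sampling of the volume at the
#'   pixel centres.
#' @export
registration_settings <- function(metric = "ncc", rot_scale = 2,
                                  trans_scale = 2,
                                  max_eval = c(200, 80, 80),
                                  strides = c(2L, 1L, 1L),
                                  scale_decay = c(1, 0.4, 0.1),
                                  mask_restrict = TRUE,
                                  n_starts = 1, jitter_t = 1, jitter_r = 1,
                                  min_pixels = 8, min_overlap = 0.5,
                                  truncation = 2.5, psf_aware = TRUE) {
  structure(list(metric = metric, rot_scale = rot_scale,
                 trans_scale = trans_scale, max_eval = max_eval,
                 strides = as.integer(strides), scale_decay = scale_decay,
                 mask_restrict = isTRUE(mask_restrict),
                 n_starts = n_starts, jitter_t = jitter_t,
                 jitter_r = jitter_r, min_pixels = min_pixels,
                 min_overlap = min_overlap,
                 truncation = truncation, psf_aware = isTRUE(psf_aware)),
            class = "srr_regset")
}

# Precompiled scorer: similarity between the slice pixels and the volume
# simulated at a candidate correction.  Geometry and pixel selections are
# prepared once so repeated evaluations inside optimizer loops stay cheap.
make_slice_scorer <- function(volume, slice, settings, stride = 1L) {
  d <- dim(slice$pixels)
  i1 <- seq(1, d[1], by = stride)
  i2 <- seq(1, d[2], by = stride)
  keep <- matrix(TRUE, length(i1), length(i2))
  if (settings$mask_restrict && !is.null(slice$mask))
    keep <- slice$mask[i1, i2, drop = FALSE] != 0
  pix <- slice$pixels[i1, i2, drop = FALSE][keep]
  min_px <- settings$min_pixels
  metric <- settings$metric
  score_vals <- function(a, b) {
    # a constant simulated counterpart carries no pose information: treat as
    # a registration failure, not a zero score
    if (sd(b) == 0) return(-1)
    if (metric == "ncc") return(ncc(a, b, on_constant = "zero"))
    sc <- try(evaluate_similarity(a, b, metric = metric)$value,
              silent = TRUE)
    if (inherits(sc, "try-error") || !is.finite(sc)) -1 else sc
  }
  if (length(pix) < min_px || sd(pix) == 0)
    return(function(correction) -1)
  s1 <- slice$in_plane_spacing[1]
  s2 <- slice$in_plane_spacing[2]
  if (settings$psf_aware) {
    xv <- as.numeric(volume$data)
    gdim <- as.integer(dim_of(volume))
    G <- direction_of(volume) %*% diag(spacing_of(volume))
    Ginv <- solve(G)
    o <- origin_of(volume)
    cov0 <- unclass(psf_covariance(s1, s2, slice$thickness))
    trunc <- settings$truncation
    pixsel <- as.integer(outer(i1 - 1L, (i2 - 1L) * d[1], "+"))[keep]
    pose <- slice$pose
    function(correction) {
      tr <- compose_rigid(correction, pose)
      covw <- tr$R %*% cov0 %*% t(tr$R)
      hw <- trunc * sqrt(pmax(diag(Ginv %*% covw %*% t(Ginv)), 0))
      pr <- cpp_forward_project_subset(xv, gdim, G, Ginv, o, tr$t,
                                       tr$R[, 1] * s1, tr$R[, 2] * s2,
                                       d[1], pixsel, solve(covw), trunc^2, hw)
      valid <- pr$wsum > 0
      if (sum(valid) < min_px ||
          mean(valid) < settings$min_overlap) return(-1)
      score_vals(pix[valid], pr$y[valid])
    }
  } else {
    idx <- cbind(rep(i1 - 1, length(i2)), rep(i2 - 1, each = length(i1)))
    idx <- idx[as.vector(keep), , drop = FALSE]
    pose <- slice$pose
    function(correction) {
      tr <- compose_rigid(correction, pose)
      w <- sweep(idx[, 1, drop = FALSE] %*% t(tr$R[, 1] * s1) +
                 idx[, 2, drop = FALSE] %*% t(tr$R[, 2] * s2), 2, tr$t, "+")
      v <- sample_volume(volume, w, outside = NA)
      valid <- !is.na(v)
      if (sum(valid) < min_px ||
          mean(valid) < settings$min_overlap) return(-1)
      score_vals(pix[valid], v[valid])
    }
  }
}

# one-shot convenience wrapper around make_slice_scorer
slice_score <- function(volume, slice, correction, settings, stride = 1L)
  make_slice_scorer(volume, slice, settings, stride)(correction)

slice_center_world <- function(slice) {
  f <- slice_frame(slice)
  d <- dim(slice$pixels)
  f$p0 + (d[1] - 1) / 2 * f$e1 + (d[2] - 1) / 2 * f$e2
}

#' Rigid slice-to-volume registration
#'
#' Finds the 6-parameter rigid correction (3 Euler angles, 3 translations,
#' pivoting about the slice centre) that maximizes the similarity between the
#' slice pixels and the volume simulated through the PSF forward model at the
#' candidate pose.  Derivative-free Nelder-Mead over two resolution levels
#' (subsampled then full pixel lattice), warm-started at `init`; the returned
#' transform never scores below `init`.
#'
#' @param slice `srr_slice`.
#' @param volume `srr_image` target (a reconstruction iterate or a reference
#'   volume).
#' @param init initial correction (`srr_rigid`), default the slice's current
#'   correction.
#' @param settings [registration_settings()].
#' @param seed optional seed for multi-start jitter.
#' @param dof degrees of freedom: 6 (full rigid) or 3 (in-plane/world
#'   translations only, rotations frozen — used to bootstrap motion
#'   correction against blurry early reconstruction iterates).
#' @return `srr_rigid` correction with attributes `"score"` and `"failed"`.
#' @export
register_slice_rigid <- function(slice, volume, init = NULL,
                                 settings = registration_settings(),
                                 seed = NULL, dof = 6) {
  if (is.null(init)) init <- slice$correction
  if (!dof %in% c(3, 6)) stop("register_slice_rigid: dof must be 3 or 6")
  center <- {
    s <- slice; s$correction <- init
    slice_center_world(s)
  }
  par_to_corr <- if (dof == 6)
    function(par) compose_rigid(rigid_euler(par[1:3], par[4:6],
                                            center = center), init)
  else
    function(par) compose_rigid(rigid_euler(c(0, 0, 0), par,
                                            center = center), init)

  fine_scorer <- make_slice_scorer(volume, slice, settings, stride = 1L)
  init_score <- fine_scorer(init)
  if (init_score <= -1) {
    attr(init, "score") <- init_score
    attr(init, "failed") <- TRUE
    return(init)
  }

  starts <- list(rep(0, dof))
  if (settings$n_starts > 1) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    for (s in seq_len(settings$n_starts - 1))
      starts[[s + 1]] <- if (dof == 6)
        c(runif(3, -settings$jitter_r, settings$jitter_r),
          runif(3, -settings$jitter_t, settings$jitter_t))
      else runif(3, -settings$jitter_t, settings$jitter_t)
  }

  n_levels <- length(settings$strides)
  scorers <- lapply(seq_len(n_levels), function(lv) {
    stride <- settings$strides[lv]
    if (stride > 1 && min(dim(slice$pixels)) / stride < 8) fine_scorer
    else if (stride == 1) fine_scorer
    else make_slice_scorer(volume, slice, settings, stride = stride)
  })
  best_par <- rep(0, dof)
  best_val <- Inf
  scales <- if (dof == 6)
    c(rep(settings$rot_scale, 3), rep(settings$trans_scale, 3))
  else rep(settings$trans_scale, 3)
  for (st in starts) {
    par <- st
    for (lv in seq_len(n_levels)) {
      scorer <- scorers[[lv]]
      fn <- function(p) -scorer(par_to_corr(p))
      opt <- optim(par, fn, method = "Nelder-Mead",
                   control = list(maxit = settings$max_eval[min(lv,
                                    length(settings$max_eval))],
                                  parscale = scales *
                                    settings$scale_decay[min(lv,
                                      length(settings$scale_decay))],
                                  reltol = 1e-7,
                                  warn.1d.NelderMead = FALSE))
      par <- opt$par
    }
    val <- -fine_scorer(par_to_corr(par))
    if (val < best_val) { best_val <- val; best_par <- par }
  }

  if (-best_val > init_score) {
    out <- par_to_corr(best_par)
    attr(out, "score") <- -best_val
    attr(out, "failed") <- FALSE
    out
  } else {
    attr(init, "score") <- init_score
    attr(init, "failed") <- FALSE
    init
  }
}

#' Volumetric stack-to-target alignment
#'
#' Estimates one rigid transform per stack maximizing the mean slice
#' similarity against a target volume.  When `target` is `NULL`, each stack
#' is aligned to a scattered-data approximation built from the *other*
#' stacks (leave-self-out), so a displaced stack cannot anchor itself; a
#' single stack is returned with the identity.  The estimate is applied as
#' the initial correction of every slice in the stack.
#'
#' @param stacks list of `srr_stack`.
#' @param target optional `srr_image`.
#' @param settings [registration_settings()].
#' @param grid optional `srr_grid` for the internal scattered-data targets.
#' @return list with `transforms` (per-stack `srr_rigid`) and `stacks` (the
#'   stacks with initial corrections applied).
#' @export
align_stacks <- function(stacks, target = NULL,
                         settings = registration_settings(), grid = NULL) {
  loso <- is.null(target)
  if (loso && is.null(grid)) grid <- default_recon_grid(stacks)
  transforms <- vector("list", length(stacks))
  for (si in seq_along(stacks)) {
    if (loso && length(stacks) == 1L) {
      transforms[[si]] <- rigid_transform()
      next
    }
    tgt <- if (loso) scattered_init(stacks[-si], grid,
                                    truncation = settings$truncation)
           else target
    st <- stacks[[si]]
    mid <- st$slices[[ceiling(length(st$slices) / 2)]]
    center <- slice_center_world(mid)
    scorers <- lapply(st$slices, function(sl)
      make_slice_scorer(tgt, sl, settings,
                        stride = max(settings$strides)))
    base_corrs <- lapply(st$slices, function(sl) sl$correction)
    score_of <- function(par) {
      tr <- rigid_euler(par[1:3], par[4:6], center = center)
      mean(vapply(seq_along(scorers), function(k)
        scorers[[k]](compose_rigid(tr, base_corrs[[k]])), numeric(1)))
    }
    base_score <- score_of(rep(0, 6))
    opt <- try(optim(rep(0, 6), function(p) -score_of(p),
                     method = "Nelder-Mead",
                     control = list(maxit = settings$max_eval[1],
                                    parscale = c(rep(settings$rot_scale, 3),
                                                 rep(settings$trans_scale, 3)))),
               silent = TRUE)
    if (inherits(opt, "try-error") || -opt$value <= -1 + 1e-12 ||
        -opt$value < base_score) {
      if (inherits(opt, "try-error") || -opt$value <= -1 + 1e-12)
        warning("align_stacks: registration failed for stack ", st$stack_id,
                "; identity used")
      transforms[[si]] <- rigid_transform()
    } else {
      transforms[[si]] <- rigid_euler(opt$par[1:3], opt$par[4:6],
                                      center = center)
    }
  }
  for (si in seq_along(stacks))
    for (k in seq_along(stacks[[si]]$slices))
      stacks[[si]]$slices[[k]]$correction <-
        compose_rigid(transforms[[si]], stacks[[si]]$slices[[k]]$correction)
  list(transforms = transforms, stacks = stacks)
}

#' Select inlier slices against the current reconstruction
#'
#' A slice is retained when the similarity between its pixels and its
#' simulated counterpart projected from the current reconstruction is at
#' least `sigma` (ties retained), evaluated inside the slice mask.
#'
#' @param stacks list of `srr_stack` (current corrections honoured).
#' @param recon `srr_image` current reconstruction iterate.
#' @param sigma similarity threshold.
#' @param settings [registration_settings()] (metric and masking).
#' @return list with `inliers` (per-stack 0-based retained indices) and
#'   `scores` (per-stack numeric score vectors).
#' @export
select_inliers <- function(stacks, recon, sigma,
                           settings = registration_settings()) {
  inliers <- vector("list", length(stacks))
  scores <- vector("list", length(stacks))
  for (si in seq_along(stacks)) {
    sc <- vapply(stacks[[si]]$slices, function(sl)
      slice_score(recon, sl, sl$correction, settings, stride = 1L),
      numeric(1))
    idx <- vapply(stacks[[si]]$slices, function(sl) sl$slice_index,
                  integer(1))
    scores[[si]] <- sc
    inliers[[si]] <- idx[sc >= sigma]
  }
  list(inliers = inliers, scores = scores)
}

new_srr_result <- function(volume, stacks, inlier_history, scores, params,
                           method, flags = NULL) {
  corrections <- lapply(stacks, function(st)
    lapply(st$slices, function(sl) sl$correction))
  rejected <- vapply(inlier_history, function(h) {
    total <- sum(vapply(stacks, function(st) length(st$slices), integer(1)))
    total - sum(vapply(h, length, integer(1)))
  }, numeric(1))
  structure(list(volume = volume, corrections = corrections,
                 inlier_history = inlier_history, scores = scores,
                 rejected_count = rejected, params = params, method = method,
                 flags = flags, stacks = stacks),
            class = "srr_result")
}

#' @export
print.srr_result <- function(x, ...) {
  cat("<srr_result> method '", x$method, "': volume ",
      paste(dim(x$volume$data), collapse = " x "), " at ",
      signif(x$volume$spacing[1], 4), " mm, ",
      length(x$inlier_history), " iteration(s), rejected per iteration: ",
      paste(x$rejected_count, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Outlier-robust iterative rigid motion correction and reconstruction
#'
#' The full two-step iterative pipeline: optional volumetric stack alignment,
#' scattered-data initialization, then `iterations` rounds of (i) rigid
#' slice-to-volume registration of every slice to the previous reconstruction
#' iterate and (ii) regularized reconstruction restricted to the slices whose
#' similarity to their simulated counterparts reaches the iteration's
#' threshold `sigma[k]` (defaults 0.6, 0.65, 0.7 over three iterations).
#'
#' Registration is bootstrapped conservatively: in the first round only
#' translations are optimized (`bootstrap_translation`), because the initial
#' scattered-data target is too blurred to constrain slice rotations
#' reliably; subsequent rounds search the full six parameters afresh from the
#' scanner-reported pose and keep the new estimate only when it scores at
#' least as well as the current one.  In the final round each stack can be
#' registered against a reconstruction computed from the other stacks only
#' (`loso_final`), which removes the bias of a slice registering to its own
#' contribution.
#'
#' @param stacks list of `srr_stack` (at least three orientations
#'   recommended; fewer triggers a warning).
#' @param grid `srr_grid`, default [default_recon_grid()].
#' @param alpha regularization weight.
#' @param iterations number of registration-reconstruction rounds.
#' @param sigma similarity threshold schedule (recycled to `iterations`).
#' @param settings [registration_settings()].
#' @param align run the volumetric stack alignment step first (useful when
#'   whole stacks may be displaced, e.g. between breath-holds).
#' @param register run the per-slice registration step.
#' @param bootstrap_translation restrict the first round to translations.
#' @param loso_final leave-one-stack-out registration targets in the final
#'   round.
#' @param max_outer,max_inner,tol solver controls, see [solve_srr()].
#' @param seed seed for any multi-start jitter (reproducible pipelines).
#' @param truncation PSF cutoff in standard deviations.
#' @return An `srr_result`.
#' @export
reconstruct_outlier_robust <- function(stacks, grid = NULL, alpha = 0.01,
                                       iterations = 3,
                                       sigma = c(0.6, 0.65, 0.7),
                                       settings = registration_settings(),
                                       align = FALSE, register = TRUE,
                                       bootstrap_translation = TRUE,
                                       loso_final = TRUE,
                                       max_outer = 10, max_inner = 20,
                                       tol = 1e-6, seed = NULL,
                                       truncation = 3) {
  if (length(stacks) < 3)
    warning("reconstruct_outlier_robust: fewer than three stack ",
            "orientations; reconstruction quality may be poor")
  sigma <- rep(sigma, length.out = max(iterations, 1))
  if (is.null(grid)) grid <- default_recon_grid(stacks)
  if (align) stacks <- align_stacks(stacks, settings = settings,
                                    grid = grid)$stacks
  x <- scattered_init(stacks, grid, truncation = truncation)

  inlier_history <- list()
  score_history <- list()
  all_idx <- lapply(stacks, function(st)
    vapply(st$slices, function(sl) sl$slice_index, integer(1)))
  sel_settings <- settings
  sel_settings$truncation <- truncation  # score with the solver's PSF
  sel <- NULL

  if (iterations == 0) {
    x <- solve_srr(stacks, grid, alpha = alpha, x0 = x, max_outer = max_outer,
                   max_inner = max_inner, tol = tol, truncation = truncation)
    inlier_history <- list(all_idx)
  } else {
    for (k in seq_len(iterations)) {
      if (register) {
        dof <- if (bootstrap_translation && k == 1L) 3 else 6
        use_loso <- loso_final && k == iterations && k > 1L &&
          length(stacks) > 1L
        for (si in seq_along(stacks)) {
          target <- if (use_loso)
            solve_srr(stacks[-si], grid, alpha = alpha,
                      inliers = if (!is.null(sel)) sel$inliers[-si],
                      x0 = x, max_outer = max(2, floor(max_outer / 3)),
                      max_inner = max_inner, tol = tol,
                      truncation = truncation)
          else x
          for (j in seq_along(stacks[[si]]$slices)) {
            sl <- stacks[[si]]$slices[[j]]
            cand <- register_slice_rigid(sl, target,
                                         init = rigid_transform(),
                                         settings = settings, dof = dof,
                                         seed = if (!is.null(seed))
                                           as.integer(seed) + 1000L * k +
                                           100L * si + j)
            cur <- make_slice_scorer(target, sl, settings)(sl$correction)
            if (attr(cand, "score") >= cur)
              stacks[[si]]$slices[[j]]$correction <- cand
          }
        }
      }
      sel <- select_inliers(stacks, x, sigma[k], settings = sel_settings)
      if (sum(vapply(sel$inliers, length, integer(1))) == 0) {
        diag <- paste(unlist(lapply(seq_along(sel$scores), function(si)
          sprintf("%s/%d: %.3f", stacks[[si]]$stack_id,
                  all_idx[[si]], sel$scores[[si]]))), collapse = "; ")
        stop("reconstruct_outlier_robust: all slices rejected at iteration ",
             k, " (sigma = ", sigma[k], "). Per-slice scores: ", diag)
      }
      for (si in seq_along(stacks))
        for (j in seq_along(stacks[[si]]$slices))
          stacks[[si]]$slices[[j]]$inlier <-
            stacks[[si]]$slices[[j]]$slice_index %in% sel$inliers[[si]]
      inlier_history[[k]] <- sel$inliers
      score_history[[k]] <- sel$scores
      x <- solve_srr(stacks, grid, alpha = alpha, inliers = sel$inliers,
                     x0 = x, max_outer = max_outer, max_inner = max_inner,
                     tol = tol, truncation = truncation)
    }
  }
  new_srr_result(x, stacks, inlier_history, score_history,
                 params = list(alpha = alpha, sigma = sigma,
                               iterations = iterations,
                               metric = settings$metric),
                 method = "robust")
}

#' Static reconstruction baseline (no motion correction)
#'
#' Solves the regularized reconstruction on all slices at their
#' scanner-reported poses with identity corrections: the reduction of the
#' outlier-robust pipeline with threshold -1 and no registration.
#'
#' @inheritParams reconstruct_outlier_robust
#' @return An `srr_result` with a single all-slices inlier set.
#' @export
reconstruct_static <- function(stacks, grid = NULL, alpha = 0.01,
                               settings = registration_settings(),
                               max_outer = 10, max_inner = 20, tol = 1e-6,
                               truncation = 3) {
  res <- suppressWarnings(reconstruct_outlier_robust(
    stacks, grid = grid, alpha = alpha, iterations = 1, sigma = -1,
    settings = settings, align = FALSE, register = FALSE,
    max_outer = max_outer, max_inner = max_inner, tol = tol,
    truncation = truncation))
  res$method <- "static"
  res
}

#' In-plane free-form deformation of a slice toward a reference section
#'
#' Estimates a 2D cubic B-spline displacement field (control-point spacing
#' `grid_spacing` pixels, bending-energy weight `bending`) maximizing the
#' localized normalized cross-correlation between the deformed slice and the
#' reference section; the displacement is confined to the slice plane.
#'
#' @param slice `srr_slice`.
#' @param reference_section 2D matrix: the reference volume resampled on the
#'   (rigidly registered) slice plane.
#' @param grid_spacing control point spacing in pixels.
#' @param bending bending-energy penalty weight.
#' @param radius LNCC window half-width in pixels.
#' @param max_iter optimizer iteration budget.
#' @return The slice with deformed pixels; attributes `"displacement"`
#'   (list `ux`, `uy`), `"failed"` and `"lncc"` record the outcome.
#' @export
deform_slice_inplane <- function(slice, reference_section, grid_spacing = 5,
                                 bending = 0.01, radius = 3, max_iter = 20) {
  n1 <- nrow(slice$pixels); n2 <- ncol(slice$pixels)
  m1 <- floor((n1 - 1) / grid_spacing) + 4
  m2 <- floor((n2 - 1) / grid_spacing) + 4
  msk <- slice$mask
  score <- function(img) {
    sc <- try(lncc(img, reference_section, mask = msk, radius = radius),
              silent = TRUE)
    if (inherits(sc, "try-error")) -1 else sc
  }
  bend_energy <- function(cx, cy) {
    sum_d2 <- function(m) {
      s <- 0
      if (nrow(m) > 2) s <- s + sum((m[-c(1, 2), ] - 2 * m[-c(1, nrow(m)), ]
                                     + m[-c(nrow(m) - 1, nrow(m)), ])^2)
      if (ncol(m) > 2) s <- s + sum((m[, -c(1, 2)] - 2 * m[, -c(1, ncol(m))]
                                     + m[, -c(ncol(m) - 1, ncol(m))])^2)
      s
    }
    sum_d2(cx) + sum_d2(cy)
  }
  obj <- function(par) {
    cx <- matrix(par[seq_len(m1 * m2)], m1, m2)
    cy <- matrix(par[m1 * m2 + seq_len(m1 * m2)], m1, m2)
    f <- cpp_ffd_field(cx, cy, grid_spacing, n1, n2)
    warped <- cpp_warp_bilinear(slice$pixels, f$ux, f$uy)
    -score(warped) + bending * bend_energy(cx, cy)
  }
  base_score <- score(slice$pixels)
  opt <- try(optim(rep(0, 2 * m1 * m2), obj, method = "L-BFGS-B",
                   lower = -2 * grid_spacing, upper = 2 * grid_spacing,
                   control = list(maxit = max_iter)), silent = TRUE)
  if (inherits(opt, "try-error")) {
    attr(slice, "failed") <- TRUE
    attr(slice, "lncc") <- base_score
    return(slice)
  }
  cx <- matrix(opt$par[seq_len(m1 * m2)], m1, m2)
  cy <- matrix(opt$par[m1 * m2 + seq_len(m1 * m2)], m1, m2)
  f <- cpp_ffd_field(cx, cy, grid_spacing, n1, n2)
  warped <- cpp_warp_bilinear(slice$pixels, f$ux, f$uy)
  new_score <- score(warped)
  if (new_score < base_score) {
    attr(slice, "failed") <- TRUE
    attr(slice, "lncc") <- base_score
    return(slice)
  }
  slice$pixels <- warped
  attr(slice, "displacement") <- list(ux = f$ux, uy = f$uy)
  attr(slice, "failed") <- FALSE
  attr(slice, "lncc") <- new_score
  slice
}

#' Reference-guided reconstruction
#'
#' Non-iterative three-step pipeline: (i) rigid slice-to-volume registration
#' of every slice to a separately acquired high-resolution reference volume;
#' (ii) optionally, in-plane free-form deformation of each slice toward the
#' reference resampled on its registered plane; (iii) regularized
#' reconstruction using all slices with the estimated transforms (no outlier
#' rejection).
#'
#' @inheritParams reconstruct_outlier_robust
#' @param reference `srr_image` reference volume covering the region of
#'   interest (possibly of a different contrast).
#' @param deformable run the in-plane deformation step.
#' @param deform_spacing control-point spacing (pixels) for the deformation.
#' @return An `srr_result`; per-slice registration failure flags are in
#'   `$flags`.
#' @export
reconstruct_reference_guided <- function(stacks, reference,
                                         deformable = FALSE, grid = NULL,
                                         alpha = 0.01,
                                         settings = registration_settings(),
                                         deform_spacing = 5, max_outer = 10,
                                         max_inner = 20, tol = 1e-6,
                                         truncation = 3, seed = NULL) {
  flags <- lapply(stacks, function(st) logical(length(st$slices)))
  for (si in seq_along(stacks)) {
    for (j in seq_along(stacks[[si]]$slices)) {
      sl <- stacks[[si]]$slices[[j]]
      corr <- register_slice_rigid(sl, reference, init = sl$correction,
                                   settings = settings,
                                   seed = if (!is.null(seed))
                                     as.integer(seed) + 100L * si + j)
      flags[[si]][j] <- isTRUE(attr(corr, "failed"))
      stacks[[si]]$slices[[j]]$correction <- corr
      if (deformable && !flags[[si]][j]) {
        sl <- stacks[[si]]$slices[[j]]
        w <- slice_pixel_world(sl)
        section <- matrix(sample_volume(reference, w), nrow(sl$pixels),
                          ncol(sl$pixels))
        stacks[[si]]$slices[[j]] <-
          deform_slice_inplane(sl, section, grid_spacing = deform_spacing)
      }
    }
  }
  if (is.null(grid)) grid <- default_recon_grid(stacks)
  x <- solve_srr(stacks, grid, alpha = alpha,
                 x0 = scattered_init(stacks, grid, truncation = truncation),
                 max_outer = max_outer, max_inner = max_inner, tol = tol,
                 truncation = truncation)
  all_idx <- lapply(stacks, function(st)
    vapply(st$slices, function(sl) sl$slice_index, integer(1)))
  new_srr_result(x, stacks, list(all_idx), list(),
                 params = list(alpha = alpha, deformable = deformable),
                 method = if (deformable) "rg_deformable" else "rg",
                 flags = flags)
}

#' Motion recovery errors against simulated ground truth
#'
#' Compares estimated per-slice corrections with the true simulated motions:
#' for each slice the discrepancy transform `inv(estimate) o truth` is
#' summarized by its displacement of the slice centre (mm) and its rotation
#' angle (degrees).
#'
#' @param result `srr_result`.
#' @param motions list (per stack) of lists of true `srr_rigid` motions, as
#'   returned by [simulate_protocol()].
#' @return data.frame with columns `stack`, `slice`, `trans_mm`, `rot_deg`.
#' @export
motion_errors <- function(result, motions) {
  rows <- list()
  for (si in seq_along(result$corrections)) {
    for (j in seq_along(result$corrections[[si]])) {
      est <- result$corrections[[si]][[j]]
      tru <- motions[[si]][[j]]
      E <- compose_rigid(invert_rigid(est), tru)
      cen <- slice_center_world(result$stacks[[si]]$slices[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        stack = si, slice = j - 1L,
        trans_mm = sqrt(sum((apply_rigid(E, cen) - cen)^2)),
        rot_deg = rotation_angle(E))
    }
  }
  do.call(rbind, rows)
}
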