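# Digital phantom and acquisition simulator.  Emulates a multi-orientation
# thick-slice 2D acquisition protocol: stacks in axial/coronal/sagittal
# planes, half-slice-shifted duplicates, and four oblique orientations whose
# slice-select directions point toward the lower corners of the cube
# [-1, 1]^3, with per-slice rigid motion and additive Gaussian noise.

# separable Gaussian smoothing with edge replication
gauss_smooth <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    out <- apply(out, setdiff(1:3, ax), conv1)
    out <- aperm(array(out, c(d[ax], d[-ax])), order(c(ax, setdiff(1:3, ax))))
  }
  out
}

#' Generate a deterministic digital phantom
#'
#' A piecewise-smooth non-negative volume centred at the world origin:
#' nested ellipsoids of distinct intensity, thin bright curvilinear tubes
#' (1-2 voxels in diameter, emulating ducts/vessels whose depiction suffers
#' most from thick-slice partial voluming) and fine smooth texture.
#' Intensities lie in `[0, 1]`; the background is exactly 0.  The foreground
#' ellipsoid is attached as the image mask.
#'
#' @param dims integer length-3 (or scalar) voxel counts, >= 16 recommended.
#' @param spacing isotropic voxel size in mm.
#' @param seed integer seed; identical seeds give identical volumes.
#' @return `srr_image` with `mask` set to the foreground region.
#' @export
make_phantom <- function(dims = c(40, 40, 40), spacing = 0.78, seed = 1) {
  if (length(dims) == 1) dims <- rep(dims, 3)
  dims <- as.integer(dims)
  set.seed(as.integer(seed))
  origin <- -(dims - 1) / 2 * spacing
  ext <- (dims - 1) * spacing
  idx <- expand.grid(i = seq_len(dims[1]) - 1, j = seq_len(dims[2]) - 1,
                     k = seq_len(dims[3]) - 1)
  w <- sweep(as.matrix(idx) * spacing, 2, origin, "+")

  ell <- function(center, semi) {
    array(((w[, 1] - center[1]) / semi[1])^2 +
          ((w[, 2] - center[2]) / semi[2])^2 +
          ((w[, 3] - center[3]) / semi[3])^2 <= 1, dims)
  }
  fg <- ell(c(0, 0, 0), ext * c(0.42, 0.40, 0.44))
  inner_hi <- ell(ext * c(-0.12, 0.08, 0.05), ext * c(0.17, 0.14, 0.16))
  inner_lo <- ell(ext * c(0.15, -0.12, -0.08), ext * c(0.12, 0.15, 0.13))

  vol <- array(0, dims)
  vol[fg] <- 0.35
  vol[inner_hi] <- 0.60
  vol[inner_lo] <- 0.15

  # smooth random texture confined to the foreground
  tex <- gauss_smooth(array(rnorm(prod(dims)), dims), sigma = 1.2)
  tex <- tex / max(abs(tex)) * 0.10
  vol[fg] <- vol[fg] + tex[fg]

  # thin bright tubes: a helix and a bent duct across the foreground
  mark_tube <- function(vol, pts_world, value = 1) {
    v <- sweep(pts_world, 2, origin, "-") / spacing
    for (r in seq_len(nrow(v))) {
      c0 <- round(v[r, ])
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        p <- c0 + c(dx, dy, dz)
        if (all(p >= 0) && all(p <= dims - 1) &&
            sum((p - v[r, ])^2) <= 1.0)
          vol[p[1] + 1, p[2] + 1, p[3] + 1] <- value
      }
    }
    vol
  }
  t1 <- seq(0, 2 * pi, length.out = 200)
  helix <- cbind(0.22 * ext[1] * cos(t1), 0.22 * ext[2] * sin(t1),
                 ext[3] * (0.30 * t1 / (2 * pi) - 0.15))
  t2 <- seq(-1, 1, length.out = 150)
  duct <- cbind(0.30 * ext[1] * t2, 0.20 * ext[2] * sin(1.5 * pi * t2),
                0.25 * ext[3] * t2)
  vol <- mark_tube(vol, helix, 1)
  vol <- mark_tube(vol, duct, 0.95)

  vol[!fg] <- 0
  vol <- pmin(pmax(vol, 0), 1)
  ph <- image3d(vol, spacing = rep(spacing, 3), origin = origin,
                mask = fg * 1)
  attr(ph, "tube") <- (vol >= 0.95) & fg
  ph
}

#' Build an acquisition plan for a named source-data configuration
#'
#' Supported configurations and their series counts:
#' `"a+c"` (2), `"a+c+s"` (3), `"2a+2c+2s"` (6), `"a+c+s+3obl"` (6),
#' `"a+c+s+4obl"` (7), `"2a+2c+2s+4obl"` (10).  The oblique slice-select
#' directions are the four unit vectors toward the lower corners of the cube
#' `[-1, 1]^3`, ordered `(+,+,-)`, `(-,+,-)`, `(+,-,-)`, `(-,-,-)` (an
#' arbitrary but fixed labelling); shifted stacks are offset by half the
#' slice thickness along the slice-select direction.
#'
#' @param config configuration name (see above).
#' @param in_plane in-plane pixel spacing in mm.
#' @param thickness slice thickness (= slice spacing) in mm.
#' @return Object of class `srr_plan`: list of stack geometries with fields
#'   `plane_label`, `normal`, `e1`, `e2`, `in_plane`, `thickness`, `shifted`.
#' @export
build_plan <- function(config, in_plane = 0.78, thickness = 5) {
  frame_for <- function(normal) {
    n <- normal / sqrt(sum(normal^2))
    e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n
    if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * n) * n
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    list(e1 = e1, e2 = e2, n = n)
  }
  geom <- function(label, e1, e2, n, shifted = FALSE)
    list(plane_label = label, normal = n, e1 = e1, e2 = e2,
         in_plane = in_plane, thickness = thickness, shifted = shifted)
  axial <- geom("axial", c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  coronal <- geom("coronal", c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  sagittal <- geom("sagittal", c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  shift_of <- function(g) {
    g$shifted <- TRUE
    g$plane_label <- paste0(g$plane_label, "_shifted")
    g
  }
  corners <- rbind(c(1, 1, -1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, -1))
  obl <- lapply(1:4, function(k) {
    f <- frame_for(corners[k, ])
    geom(paste0("oblique_", k), f$e1, f$e2, f$n)
  })
  plan <- switch(config,
    "a+c" = list(axial, coronal),
    "a+c+s" = list(axial, coronal, sagittal),
    "2a+2c+2s" = list(axial, coronal, sagittal, shift_of(axial),
                      shift_of(coronal), shift_of(sagittal)),
    "a+c+s+3obl" = c(list(axial, coronal, sagittal), obl[1:3]),
    "a+c+s+4obl" = c(list(axial, coronal, sagittal), obl),
    "2a+2c+2s+4obl" = c(list(axial, coronal, sagittal, shift_of(axial),
                             shift_of(coronal), shift_of(sagittal)), obl),
    stop("build_plan: unknown configuration '", config, "'")
  )
  structure(plan, class = "srr_plan", config = config)
}

# a random rigid motion with bounded total magnitude: rotation by a uniform
# angle in [-amp_r, amp_r] degrees about a uniformly random axis through
# `center`, plus a translation of uniform length [0, amp_t] mm in a uniformly
# random direction
draw_rigid_motion <- function(amp_t, amp_r, center) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -amp_r, amp_r) * pi / 180
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  mag <- runif(1, 0, amp_t)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  rigid_transform(R, as.numeric(center - R %*% center) + dir * mag)
}

#' Simulate one thick-slice stack from a phantom
#'
#' Each slice is the oriented-PSF forward projection of the phantom at its
#' nominally planned pose composed with a random per-slice rigid motion
#' (rotation angle and translation magnitude bounded by the amplitudes,
#' pivoting about the phantom centre), plus additive Gaussian noise.  Slices
#' are planned over the phantom's foreground mask; planned slices whose
#' nominal intersection with the mask is below `min_mask_pixels` are not
#' acquired.  The stack records the nominal (scanner-reported) poses with
#' identity corrections; the true motions are returned alongside so recovery
#' can be scored.
#'
#' @param phantom `srr_image` ground-truth volume.
#' @param geometry one element of an [build_plan()] plan.
#' @param motion_t,motion_r motion amplitude bounds: maximum translation
#'   magnitude (mm) and maximum rotation angle (degrees) per slice.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units); set `rician = TRUE` for Rician-distributed magnitude noise.
#' @param seed integer seed.
#' @param stack_id identifier.
#' @param margin extra in-plane pixels around the projected phantom extent.
#' @param truncation PSF cutoff in standard deviations.
#' @param rician use Rician instead of additive Gaussian noise.
#' @param min_mask_pixels planned slices with fewer nominal foreground pixels
#'   are skipped (set 0 to keep every slice of the planned slab).
#' @return list with `stack` (`srr_stack`), `motions` (list of true
#'   `srr_rigid` per slice) and `center` (rotation pivot).
#' @export
simulate_stack <- function(phantom, geometry, motion_t = 0, motion_r = 0,
                           noise_sd = 0, seed = 1, stack_id = NULL,
                           margin = 2, truncation = 3, rician = FALSE,
                           min_mask_pixels = 30) {
  set.seed(as.integer(seed))
  if (is.null(stack_id)) stack_id <- geometry$plane_label
  d <- dim(phantom$data)
  # plan the stack over the imaged region of interest (foreground mask when
  # available), as a protocol would, rather than the full array box
  if (!is.null(phantom$mask) && any(phantom$mask != 0)) {
    fg <- which(phantom$mask != 0)
    if (length(fg) > 20000) fg <- fg[seq(1, length(fg), length.out = 20000)]
    wc <- voxel_to_world(phantom, arrayInd(fg, d) - 1)
  } else {
    corners <- as.matrix(expand.grid(i = c(0, d[1] - 1), j = c(0, d[2] - 1),
                                     k = c(0, d[3] - 1)))
    wc <- voxel_to_world(phantom, corners)
  }
  pr1 <- wc %*% geometry$e1
  pr2 <- wc %*% geometry$e2
  pr3 <- wc %*% geometry$normal
  s12 <- geometry$in_plane
  lo1 <- min(pr1) - margin * s12; hi1 <- max(pr1) + margin * s12
  lo2 <- min(pr2) - margin * s12; hi2 <- max(pr2) + margin * s12
  n1 <- ceiling((hi1 - lo1) / s12) + 1
  n2 <- ceiling((hi2 - lo2) / s12) + 1
  K <- max(1, ceiling((max(pr3) - min(pr3)) / geometry$thickness))
  zc <- (max(pr3) + min(pr3)) / 2 +
    if (isTRUE(geometry$shifted)) geometry$thickness / 2 else 0
  z <- zc + (seq_len(K) - (K + 1) / 2) * geometry$thickness
  R <- cbind(geometry$e1, geometry$e2, geometry$normal)
  center <- voxel_to_world(phantom, (d - 1) / 2)

  mask_vol <- phantom
  mask_vol$data <- array(as.numeric(phantom$mask != 0), d)

  slices <- list()
  motions <- list()
  for (k in seq_len(K)) {
    p0 <- lo1 * geometry$e1 + lo2 * geometry$e2 + z[k] * geometry$normal
    pose <- rigid_transform(R, p0)
    sl <- slice2d(matrix(0, n1, n2), in_plane_spacing = c(s12, s12),
                  thickness = geometry$thickness, pose = pose,
                  stack_id = stack_id, slice_index = 0L)
    # plan on the nominal pose: skip slices that barely touch the ROI
    m_plan <- project_slice(mask_vol, sl, truncation = truncation)
    if (sum(m_plan > 0.5) < min_mask_pixels) next
    motion <- if (motion_t > 0 || motion_r > 0)
      draw_rigid_motion(motion_t, motion_r, center)
    else rigid_transform()
    y <- project_slice(phantom, sl, correction = motion,
                       truncation = truncation)
    m <- project_slice(mask_vol, sl, correction = motion,
                       truncation = truncation)
    if (noise_sd > 0) {
      if (rician) {
        y[] <- sqrt((y + rnorm(length(y), 0, noise_sd))^2 +
                    rnorm(length(y), 0, noise_sd)^2)
      } else {
        y[] <- y + rnorm(length(y), 0, noise_sd)
      }
    }
    sl$slice_index <- length(slices)
    sl$pixels <- matrix(as.numeric(y), n1, n2)
    sl$mask <- (matrix(as.numeric(m), n1, n2) > 0.5) * 1
    slices[[length(slices) + 1L]] <- sl
    motions[[length(motions) + 1L]] <- motion
  }
  if (length(slices) == 0)
    stop("simulate_stack: no planned slice intersects the phantom mask")
  list(stack = new_stack(slices, plane_label = geometry$plane_label,
                         stack_id = stack_id),
       motions = motions, center = center)
}

#' Simulate a full multi-stack acquisition protocol
#'
#' Runs [simulate_stack()] for every geometry of a plan (or named
#' configuration), with per-stack seeds derived from `seed`.
#'
#' @inheritParams simulate_stack
#' @param plan an `srr_plan` or a configuration name for [build_plan()].
#' @param in_plane,thickness geometry passed to [build_plan()] when `plan`
#'   is a name.
#' @return list with `stacks` (list of `srr_stack`), `motions` (list of
#'   per-stack true-motion lists) and `center`.
#' @export
simulate_protocol <- function(phantom, plan = "a+c+s+3obl", motion_t = 0,
                              motion_r = 0, noise_sd = 0, seed = 1,
                              in_plane = 0.78, thickness = 5,
                              truncation = 3, min_mask_pixels = 30) {
  if (is.character(plan)) plan <- build_plan(plan, in_plane, thickness)
  stacks <- list(); motions <- list(); center <- NULL
  for (g in seq_along(plan)) {
    sim <- simulate_stack(phantom, plan[[g]], motion_t = motion_t,
                          motion_r = motion_r, noise_sd = noise_sd,
                          seed = as.integer(seed) * 131L + g,
                          truncation = truncation,
                          min_mask_pixels = min_mask_pixels)
    stacks[[g]] <- sim$stack
    motions[[g]] <- sim$motions
    center <- sim$center
  }
  list(stacks = stacks, motions = motions, center = center,
       config = attr(plan, "config"))
}

#' Corrupt slices of a stack for outlier-rejection studies
#'
#' Either gives `k` randomly chosen slices a gross pose error (`"mispose"`:
#' a translation of at least `amplitude` mm plus a rotation of the same
#' magnitude in degrees, leaving pixels untouched) or replaces their pixels
#' by a random permutation (`"noise"`), destroying spatial structure while
#' preserving the histogram.
#'
#' @param stack `srr_stack`.
#' @param k number of slices to corrupt (`k < number of slices`).
#' @param mode `"mispose"` or `"noise"`.
#' @param seed integer seed.
#' @param amplitude gross pose error magnitude (mm and degrees).
#' @return The corrupted stack, with 0-based corrupted slice indices in
#'   attribute `"corrupted"`.
#' @export
corrupt_slices <- function(stack, k, mode = c("mispose", "noise"), seed = 1,
                           amplitude = 15) {
  mode <- match.arg(mode)
  n <- length(stack$slices)
  if (k >= n) stop("corrupt_slices: k must be smaller than the slice count")
  set.seed(as.integer(seed))
  if (k == 0) {
    attr(stack, "corrupted") <- integer(0)
    return(stack)
  }
  pick <- sample(n, k)
  for (p in pick) {
    sl <- stack$slices[[p]]
    if (mode == "mispose") {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ang <- rnorm(3); ang <- ang / sqrt(sum(ang^2)) * amplitude
      err <- rigid_euler(ang, dir * amplitude, center = slice_frame(sl)$p0)
      sl$pose <- compose_rigid(err, sl$pose)
    } else {
      sl$pixels <- matrix(sample(as.numeric(sl$pixels)), nrow(sl$pixels),
                          ncol(sl$pixels))
    }
    stack$slices[[p]] <- sl
  }
  attr(stack, "corrupted") <- sort(vapply(pick, function(p)
    stack$slices[[p]]$slice_index, integer(1)))
  stack
}
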