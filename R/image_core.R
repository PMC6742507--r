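#' @useDynLib srrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif sd cor quantile median lm coef predict
#' @importFrom utils write.csv
NULL

# ---- 3D image container ----------------------------------------------------

#' Create a 3D image with world geometry
#'
#' An `srr_image` is a scalar 3D lattice together with its world geometry:
#' voxel spacing (mm), world origin (mm) and a 3x3 orthonormal direction
#' matrix.  Voxel indices are 0-based and the continuous index of a voxel
#' centre is integral, so the world position of voxel `v` is
#' `origin + direction %*% diag(spacing) %*% v` (NIfTI affine semantics).
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix mapping index axes to world axes.
#' @param mask optional binary array with the same dimensions as `data`.
#' @return An object of class `srr_image`.
#' @export
image3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    direction = diag(3), mask = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image3d: 'data' must be a 3D array, got ", length(dim(data)),
         " dimension(s)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image3d: spacing must be 3 strictly positive numbers")
  if (length(origin) != 3L) stop("image3d: origin must have length 3")
  direction <- as.matrix(direction)
  if (!is_orthonormal(direction))
    stop("image3d: direction matrix is not orthonormal")
  if (!is.null(mask)) {
    mask <- as.array(mask)
    if (!identical(dim(mask), dim(data)))
      stop("image3d: mask dimensions differ from data dimensions")
    mask <- (mask != 0) * 1
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction, mask = mask),
            class = "srr_image")
}

is_orthonormal <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol
}

#' @export
print.srr_image <- function(x, ...) {
  cat("<srr_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm", if (!is.null(x$mask)) ", with mask", "\n", sep = "")
  invisible(x)
}

# index->world matrix: direction %*% diag(spacing)
index_matrix <- function(img) img$direction %*% diag(img$spacing)

affine_of <- function(img) {
  aff <- diag(4)
  aff[1:3, 1:3] <- index_matrix(img)
  aff[1:3, 4] <- img$origin
  aff
}

#' Map continuous voxel indices to world coordinates
#'
#' @param img an `srr_image` (or recon grid).
#' @param index numeric length-3 vector or n x 3 matrix of 0-based
#'   (possibly fractional, possibly out-of-bounds) voxel indices.
#' @return world coordinates in mm, same shape as `index`.
#' @export
voxel_to_world <- function(img, index) {
  M <- index_matrix(img)
  if (is.matrix(index))
    sweep(index %*% t(M), 2, img$origin, "+")
  else
    as.numeric(M %*% as.numeric(index) + img$origin)
}

#' Map world coordinates to continuous voxel indices
#'
#' Inverse of [voxel_to_world()].
#' @inheritParams voxel_to_world
#' @param points numeric length-3 vector or n x 3 matrix of world mm.
#' @export
world_to_voxel <- function(img, points) {
  Minv <- solve(index_matrix(img))
  if (is.matrix(points))
    sweep(points, 2, img$origin, "-") %*% t(Minv)
  else
    as.numeric(Minv %*% (as.numeric(points) - img$origin))
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a 3D NIfTI image
#'
#' Loads a NIfTI-1 file and populates geometry (spacing, origin, direction)
#' from the stored affine.  Intensities are returned unmodified.
#'
#' @param path path to a `.nii` or `.nii.gz` file with a 3D payload.
#' @return An `srr_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("read_image: expected a 3D payload, got ",
         paste(dim(arr), collapse = "x"))
  aff <- RNifti::xform(nii)
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0) || abs(det(M)) < 1e-12)
    stop("read_image: non-invertible affine in ", path)
  direction <- M %*% diag(1 / spacing)
  # NIfTI qform/sform are RAS and may be left-handed; re-orthonormalize the
  # direction columns against float rounding.
  s <- svd(direction)
  direction <- s$u %*% t(s$v)
  image3d(array(as.numeric(arr), dim = dim(arr)), spacing = spacing,
          origin = aff[1:3, 4], direction = direction)
}

#' Write a 3D image as NIfTI
#'
#' Intensities are stored as 32-bit float; the full affine is stored in the
#' sform (code 2).
#'
#' @param img an `srr_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  nii <- RNifti::asNifti(img$data, datatype = "float")
  nii <- RNifti::`sform<-`(nii, structure(affine_of(img), code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# ---- rigid transforms ------------------------------------------------------

#' Create a rigid transform (rotation + translation, world mm)
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation numeric length-3, mm.
#' @return An object of class `srr_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!is_orthonormal(rotation) || det(rotation) < 0)
    stop("rigid_transform: rotation must be orthonormal with det +1")
  structure(list(R = rotation, t = translation), class = "srr_rigid")
}

#' Rigid transform from Euler angles
#'
#' Rotation is composed as `Rz(c) %*% Ry(b) %*% Rx(a)` (degrees) about
#' `center`, followed by a translation.
#'
#' @param angles numeric length-3, rotations about x, y, z in degrees.
#' @param translation numeric length-3, mm.
#' @param center world point (mm) the rotation pivots about.
#' @export
rigid_euler <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                        center = c(0, 0, 0)) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  center <- as.numeric(center)
  rigid_transform(R, as.numeric(center - R %*% center) + translation)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `srr_rigid` transforms.
#' @return `srr_rigid` equal to `a o b`.
#' @export
compose_rigid <- function(a, b)
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)

#' Invert a rigid transform
#' @param tr an `srr_rigid`.
#' @export
invert_rigid <- function(tr)
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))

#' Apply a rigid transform to world points
#' @param tr an `srr_rigid`.
#' @param points length-3 vector or n x 3 matrix of world mm.
#' @export
apply_rigid <- function(tr, points) {
  if (is.matrix(points)) sweep(points %*% t(tr$R), 2, tr$t, "+")
  else as.numeric(tr$R %*% as.numeric(points) + tr$t)
}

#' Rotation angle (degrees) of a rigid transform
#' @param tr an `srr_rigid`.
#' @export
rotation_angle <- function(tr) {
  ctheta <- (sum(diag(tr$R)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

rigid_identity <- function() rigid_transform()

# ---- slices and stacks -----------------------------------------------------

#' Create a 2D slice acquisition
#'
#' A slice carries its pixel array, in-plane spacing and through-plane
#' thickness, a rigid `pose` mapping 0-based pixel indices `(i, j, 0)` scaled
#' by `(s1, s2, thickness)` to world mm, and a rigid `correction` (the motion
#' estimate, identity by default) applied on top of the pose in world space.
#'
#' @param pixels 2D numeric matrix.
#' @param in_plane_spacing numeric length-2 `(s1, s2)` in mm.
#' @param thickness slice thickness `s3` in mm.
#' @param pose `srr_rigid` scanner-reported slice pose.
#' @param correction `srr_rigid` motion correction estimate.
#' @param stack_id identifier of the parent stack.
#' @param slice_index 0-based index within the stack.
#' @param inlier logical inlier flag.
#' @param mask optional 2D binary matrix, same dimensions as `pixels`.
#' @return An object of class `srr_slice`.
#' @export
slice2d <- function(pixels, in_plane_spacing, thickness, pose,
                    correction = rigid_transform(), stack_id = "stack",
                    slice_index = 0L, inlier = TRUE, mask = NULL) {
  pixels <- as.matrix(pixels)
  in_plane_spacing <- as.numeric(in_plane_spacing)
  if (length(in_plane_spacing) != 2 || any(in_plane_spacing <= 0))
    stop("slice2d: in-plane spacings must be two positive numbers")
  if (thickness <= 0) stop("slice2d: thickness must be positive")
  if (!inherits(pose, "srr_rigid")) stop("slice2d: pose must be srr_rigid")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(pixels)))
      stop("slice2d: mask dimensions differ from pixel dimensions")
    mask <- (mask != 0) * 1
  }
  structure(list(pixels = pixels, in_plane_spacing = in_plane_spacing,
                 thickness = thickness, pose = pose, correction = correction,
                 stack_id = stack_id, slice_index = as.integer(slice_index),
                 inlier = isTRUE(inlier), mask = mask),
            class = "srr_slice")
}

#' Composed world transform of a slice (`correction o pose`)
#' @param slice an `srr_slice`.
#' @export
slice_transform <- function(slice) compose_rigid(slice$correction, slice$pose)

# world positions: p0 = centre of pixel (0,0); e1/e2 = world steps per pixel
slice_frame <- function(slice) {
  tr <- slice_transform(slice)
  list(p0 = tr$t,
       e1 = tr$R[, 1] * slice$in_plane_spacing[1],
       e2 = tr$R[, 2] * slice$in_plane_spacing[2],
       R = tr$R)
}

# world centre of every pixel, n1*n2 x 3 (column-major pixel order)
slice_pixel_world <- function(slice) {
  f <- slice_frame(slice)
  d <- dim(slice$pixels)
  idx <- cbind(rep(seq_len(d[1]) - 1, d[2]),
               rep(seq_len(d[2]) - 1, each = d[1]))
  sweep(idx[, 1, drop = FALSE] %*% t(f$e1) +
        idx[, 2, drop = FALSE] %*% t(f$e2), 2, f$p0, "+")
}

#' Create a stack of slices
#'
#' @param slices list of `srr_slice` sharing in-plane spacing and thickness,
#'   with unique contiguous `slice_index` values starting at 0.
#' @param plane_label one of `"axial"`, `"coronal"`, `"sagittal"`, their
#'   `"_shifted"` variants, or `"oblique_1"` .. `"oblique_4"`.
#' @param stack_id identifier.
#' @return An object of class `srr_stack`.
#' @export
new_stack <- function(slices, plane_label = "axial", stack_id = "stack") {
  stopifnot(length(slices) >= 1)
  sp <- slices[[1]]$in_plane_spacing
  th <- slices[[1]]$thickness
  for (s in slices) {
    if (max(abs(s$in_plane_spacing - sp)) > 1e-9 || abs(s$thickness - th) > 1e-9)
      stop("new_stack: slices must share in-plane spacing and thickness")
  }
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  if (!identical(sort(idx), seq_along(slices) - 1L))
    stop("new_stack: slice_index values must be unique and contiguous from 0")
  structure(list(slices = slices[order(idx)], plane_label = plane_label,
                 stack_id = stack_id),
            class = "srr_stack")
}

#' @export
print.srr_stack <- function(x, ...) {
  cat("<srr_stack> '", x$stack_id, "' (", x$plane_label, "): ",
      length(x$slices), " slices of ",
      paste(dim(x$slices[[1]]$pixels), collapse = " x "), " pixels\n", sep = "")
  invisible(x)
}

#' Split a loaded multi-slice image into a stack of posed 2D slices
#'
#' Each k-index of the volume becomes one slice whose pose maps pixel
#' `(i, j, 0)` to the world position of voxel `(i, j, k)`; the through-plane
#' spacing of the volume becomes the slice thickness.
#'
#' @param img `srr_image` holding the acquired stack.
#' @param mask optional `srr_image` mask on the same lattice.
#' @param plane_label,stack_id stack labelling.
#' @return An `srr_stack`.
#' @export
split_stack <- function(img, mask = NULL, plane_label = "axial",
                        stack_id = "stack") {
  if (!is.null(mask) && !identical(dim(mask$data), dim(img$data)))
    stop("split_stack: mask dimensions differ from image dimensions")
  d <- dim(img$data)
  slices <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    p0 <- voxel_to_world(img, c(0, 0, k - 1))
    pose <- rigid_transform(img$direction, p0)
    slices[[k]] <- slice2d(img$data[, , k],
                           in_plane_spacing = img$spacing[1:2],
                           thickness = img$spacing[3], pose = pose,
                           stack_id = stack_id, slice_index = k - 1L,
                           mask = if (!is.null(mask)) mask$data[, , k])
  }
  new_stack(slices, plane_label = plane_label, stack_id = stack_id)
}

#' Reassemble a stack into a 3D image on its acquisition lattice
#'
#' Inverse of [split_stack()] for stacks whose slices still share the original
#' lattice (poses are not consulted beyond slice 0).
#' @param stack an `srr_stack`.
#' @export
stack_to_image <- function(stack) {
  s1 <- stack$slices[[1]]
  d <- c(dim(s1$pixels), length(stack$slices))
  arr <- array(0, dim = d)
  for (k in seq_along(stack$slices)) arr[, , k] <- stack$slices[[k]]$pixels
  f <- slice_frame(s1)
  image3d(arr, spacing = c(s1$in_plane_spacing, s1$thickness),
          origin = f$p0, direction = slice_transform(s1)$R)
}

# all slices of a list of stacks, with (stack, index) bookkeeping
flatten_slices <- function(stacks) {
  out <- list()
  for (si in seq_along(stacks))
    for (sl in stacks[[si]]$slices)
      out[[length(out) + 1L]] <- list(stack = si, index = sl$slice_index,
                                      slice = sl)
  out
}

# ---- resampling helpers ----------------------------------------------------

#' Sample a volume at world points
#'
#' @param img `srr_image`.
#' @param points n x 3 matrix of world mm.
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @param outside value assigned outside the volume.
#' @return numeric vector of length `nrow(points)`.
#' @export
sample_volume <- function(img, points,
                          interpolation = c("linear", "nearest"),
                          outside = 0) {
  interpolation <- match.arg(interpolation)
  v <- world_to_voxel(img, points)
  d <- dim(img$data)
  if (interpolation == "nearest") {
    iv <- round(v)
    ok <- iv[, 1] >= 0 & iv[, 1] <= d[1] - 1 &
          iv[, 2] >= 0 & iv[, 2] <= d[2] - 1 &
          iv[, 3] >= 0 & iv[, 3] <= d[3] - 1
    out <- rep(outside, nrow(v))
    if (any(ok))
      out[ok] <- img$data[cbind(iv[ok, 1] + 1, iv[ok, 2] + 1, iv[ok, 3] + 1)]
    return(out)
  }
  ok <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
        v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
        v[, 3] >= 0 & v[, 3] <= d[3] - 1
  out <- rep(outside, nrow(v))
  if (!any(ok)) return(out)
  vv <- v[ok, , drop = FALSE]
  f0 <- pmin(floor(vv), matrix(rep(d - 2, each = nrow(vv)), ncol = 3))
  f0 <- pmax(f0, 0)
  fr <- vv - f0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * img$data[cbind(f0[, 1] + dx + 1, f0[, 2] + dy + 1,
                                    f0[, 3] + dz + 1)]
  }
  out[ok] <- acc
  out
}

#' Propagate a binary mask onto another image lattice
#'
#' World-space nearest-neighbour resampling; voxels mapping outside the mask
#' field of view are 0.
#'
#' @param mask_img `srr_image` with binary intensities.
#' @param target `srr_image` (or recon grid) defining the output lattice.
#' @return `srr_image` with binary data on the target lattice.
#' @export
propagate_mask <- function(mask_img, target) {
  if (all(mask_img$data == 0))
    warning("propagate_mask: input mask is empty")
  d <- dim_of(target)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  w <- voxel_to_world(target, idx)
  vals <- sample_volume(mask_img, w, interpolation = "nearest", outside = 0)
  image3d(array((vals != 0) * 1, dim = d), spacing = spacing_of(target),
          origin = origin_of(target), direction = direction_of(target))
}

# accessors that work for both srr_image and srr_grid
dim_of <- function(x) if (inherits(x, "srr_grid")) x$dims else dim(x$data)
spacing_of <- function(x) x$spacing
origin_of <- function(x) x$origin
direction_of <- function(x) x$direction

# ---- intensity harmonization -----------------------------------------------

#' Per-stack linear intensity correction against a reference volume
#'
#' Fits one affine intensity map `a * y + b` per stack by least squares
#' between masked slice intensities and the reference volume sampled at the
#' corresponding world positions, then applies it to all pixels of the stack.
#'
#' @param stack `srr_stack`.
#' @param reference `srr_image` providing target intensities.
#' @param mask optional `srr_image` region of interest; slice masks are used
#'   when present, otherwise all pixels with reference support contribute.
#' @return The corrected `srr_stack`, with the fitted `c(a, b)` attached as
#'   attribute `"intensity_map"`.
#' @export
linear_intensity_correction <- function(stack, reference, mask = NULL) {
  ys <- c(); rs <- c()
  for (sl in stack$slices) {
    w <- slice_pixel_world(sl)
    ref <- sample_volume(reference, w, outside = NA)
    keep <- !is.na(ref)
    if (!is.null(sl$mask)) keep <- keep & (as.vector(sl$mask) != 0)
    if (!is.null(mask)) {
      mv <- sample_volume(mask, w, interpolation = "nearest", outside = 0)
      keep <- keep & (mv != 0)
    }
    ys <- c(ys, as.vector(sl$pixels)[keep])
    rs <- c(rs, ref[keep])
  }
  ab <- c(1, 0)
  if (length(ys) < 2 || sd(ys) == 0) {
    warning("linear_intensity_correction: degenerate fit, identity map used")
  } else {
    fit <- lm(rs ~ ys)
    ab <- c(coef(fit)[2], coef(fit)[1])
  }
  for (k in seq_along(stack$slices))
    stack$slices[[k]]$pixels <- ab[1] * stack$slices[[k]]$pixels + ab[2]
  attr(stack, "intensity_map") <- unname(ab)
  stack
}

#' Low-order polynomial multiplicative bias-field correction
#'
#' Fits a polynomial field (in normalized voxel coordinates) to the log
#' intensities inside the mask and divides it out.  A lightweight smooth
#' shading correction for preprocessing; off by default in the phantom
#' pipelines.
#'
#' @param img `srr_image` with positive intensities inside the mask.
#' @param mask optional `srr_image` mask (defaults to `img$mask`, else all).
#' @param order polynomial order (1 or 2).
#' @return Corrected `srr_image`.
#' @export
polyfield_correction <- function(img, mask = NULL, order = 2) {
  d <- dim(img$data)
  m <- if (!is.null(mask)) mask$data != 0
       else if (!is.null(img$mask)) img$mask != 0
       else array(TRUE, d)
  idx <- which(m & img$data > 0)
  if (length(idx) < 20) return(img)
  co <- arrayInd(idx, d)
  X <- sweep(co - 1, 2, pmax(d - 1, 1), "/") - 0.5
  df <- data.frame(x = X[, 1], y = X[, 2], z = X[, 3],
                   l = log(img$data[idx]))
  form <- if (order >= 2)
    l ~ x + y + z + I(x^2) + I(y^2) + I(z^2) + x:y + x:z + y:z
  else l ~ x + y + z
  fit <- lm(form, data = df)
  allco <- arrayInd(seq_len(prod(d)), d)
  Xa <- sweep(allco - 1, 2, pmax(d - 1, 1), "/") - 0.5
  nd <- data.frame(x = Xa[, 1], y = Xa[, 2], z = Xa[, 3])
  field <- exp(predict(fit, newdata = nd) - mean(df$l))
  img$data <- img$data / array(field, d)
  img
}
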