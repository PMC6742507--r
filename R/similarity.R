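# Similarity measures used for registration, outlier rejection,
# self-consistency and ground-truth evaluation.  All metrics operate on plain
# numeric arrays of matching shape, restricted to an optional binary mask;
# voxels outside the mask never influence the score.

mask_values <- function(a, b, mask) {
  if (!identical(dim(a), dim(b)) && !(is.null(dim(a)) && is.null(dim(b)) &&
                                      length(a) == length(b)))
    stop("similarity: arrays must have identical shape")
  if (is.null(mask)) {
    list(a = as.numeric(a), b = as.numeric(b))
  } else {
    keep <- as.vector(mask != 0)
    list(a = as.numeric(a)[keep], b = as.numeric(b)[keep])
  }
}

#' Normalized cross-correlation
#'
#' Pearson correlation of the (masked) intensities of two arrays; symmetric
#' in its arguments and invariant to affine intensity changes.
#'
#' @param a,b numeric arrays of identical shape.
#' @param mask optional binary array of the same shape.
#' @param on_constant what to do when either input has zero variance:
#'   `"error"` (default) or `"zero"` (return 0, used for registration
#'   robustness).
#' @return scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b, mask = NULL, on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  v <- mask_values(a, b, mask)
  if (length(v$a) < 2) {
    if (on_constant == "zero") return(0)
    stop("ncc: fewer than 2 compared voxels")
  }
  if (sd(v$a) == 0 || sd(v$b) == 0) {
    if (on_constant == "zero") return(0)
    stop("ncc: zero variance in compared intensities")
  }
  cor(v$a, v$b)
}

# local box sums over each dimension via running sums; x an array
box_sum <- function(x, radius) {
  run_sum <- function(v) {
    cs <- cumsum(c(0, v))
    m <- length(v)
    lo <- pmax(seq_len(m) - radius, 1)
    hi <- pmin(seq_len(m) + radius, m)
    cs[hi + 1] - cs[lo]
  }
  d <- dim(x)
  if (is.null(d) || length(d) == 1L) return(run_sum(as.numeric(x)))
  out <- x
  n <- length(d)
  for (ax in seq_len(n)) {
    out <- apply(out, setdiff(seq_len(n), ax), run_sum)
    # apply puts the worked dimension first; rotate back
    out <- aperm(array(out, c(d[ax], d[-ax])),
                 order(c(ax, setdiff(seq_len(n), ax))))
  }
  out
}

#' Localized normalized cross-correlation
#'
#' Mean over masked voxels of the Pearson correlation computed in cubic
#' windows of half-width `radius` centred at each voxel (windows are clipped
#' at array borders).  Windows where either image is locally constant are
#' skipped.
#'
#' @inheritParams ncc
#' @param radius window half-width in voxels (>= 1).
#' @export
lncc <- function(a, b, mask = NULL, radius = 3) {
  if (radius < 1) stop("lncc: radius must be >= 1")
  a <- as.array(a); b <- as.array(b)
  if (!identical(dim(a), dim(b)))
    stop("lncc: arrays must have identical shape")
  m <- if (is.null(mask)) array(1, dim(a)) else array((mask != 0) * 1, dim(a))
  # window statistics over masked voxels only: the mask confines the metric
  a0 <- a * m; b0 <- b * m
  n <- box_sum(m, radius)
  sa <- box_sum(a0, radius); sb <- box_sum(b0, radius)
  saa <- box_sum(a0 * a0, radius); sbb <- box_sum(b0 * b0, radius)
  sab <- box_sum(a0 * b0, radius)
  va <- saa - sa^2 / pmax(n, 1)
  vb <- sbb - sb^2 / pmax(n, 1)
  cab <- sab - sa * sb / pmax(n, 1)
  eps <- 1e-12 * max(1, max(abs(a0)), max(abs(b0)))^2
  ok <- (m != 0) & n >= 2 & va > eps & vb > eps
  if (!any(ok)) stop("lncc: no windows with local variance inside the mask")
  mean(cab[ok] / sqrt(va[ok] * vb[ok]))
}

#' Structural similarity index
#'
#' SSIM with a uniform window (default 7 voxels wide), constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, computed on intensities linearly
#' rescaled to `[0, 1]` over the mask (`L = 1`); the mean SSIM over masked
#' voxels is returned.
#'
#' @inheritParams ncc
#' @param window odd window width in voxels.
#' @export
ssim_index <- function(a, b, mask = NULL, window = 7) {
  a <- as.array(a); b <- as.array(b)
  if (!identical(dim(a), dim(b)))
    stop("ssim: arrays must have identical shape")
  keep <- if (is.null(mask)) array(TRUE, dim(a)) else mask != 0
  rng <- range(c(a[keep], b[keep]))
  if (diff(rng) > 0) {
    a <- (a - rng[1]) / diff(rng)
    b <- (b - rng[1]) / diff(rng)
  }
  radius <- (window - 1) / 2
  m <- keep * 1
  a <- a * m; b <- b * m   # window statistics confined to the mask
  n <- pmax(box_sum(m, radius), 1)
  mu_a <- box_sum(a, radius) / n
  mu_b <- box_sum(b, radius) / n
  va <- box_sum(a * a, radius) / n - mu_a^2
  vb <- box_sum(b * b, radius) / n - mu_b^2
  cab <- box_sum(a * b, radius) / n - mu_a * mu_b
  C1 <- 0.01^2; C2 <- 0.03^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s[keep])
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` with the peak taken as the maximum intensity of
#' the reference (`b`) inside the mask.  Identical inputs give `Inf`.
#'
#' @param a test array.
#' @param b reference array.
#' @inheritParams ncc
#' @export
psnr <- function(a, b, mask = NULL) {
  v <- mask_values(a, b, mask)
  mse <- mean((v$a - v$b)^2)
  if (mse == 0) return(Inf)
  peak <- max(abs(v$b))
  10 * log10(peak^2 / mse)
}

joint_hist <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  ia <- if (diff(ra) > 0)
    pmin(floor((a - ra[1]) / diff(ra) * bins) + 1, bins) else rep(1L, length(a))
  ib <- if (diff(rb) > 0)
    pmin(floor((b - rb[1]) / diff(rb) * bins) + 1, bins) else rep(1L, length(b))
  h <- matrix(0, bins, bins)
  t <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  h[] <- as.numeric(t)
  h / length(a)
}

entropy_of <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information (nats)
#'
#' Joint-histogram mutual information `H(a) + H(b) - H(a, b)` with equal-width
#' bins over the masked intensity ranges.
#'
#' @inheritParams ncc
#' @param bins histogram bin count per image.
#' @export
mutual_information <- function(a, b, mask = NULL, bins = 32) {
  v <- mask_values(a, b, mask)
  h <- joint_hist(v$a, v$b, bins)
  entropy_of(rowSums(h)) + entropy_of(colSums(h)) - entropy_of(h)
}

#' Normalized mutual information
#'
#' `(H(a) + H(b)) / H(a, b)`; equals 2 for identical images with spread
#' histograms and tends to 1 for independent ones.
#'
#' @inheritParams mutual_information
#' @export
nmi <- function(a, b, mask = NULL, bins = 32) {
  v <- mask_values(a, b, mask)
  h <- joint_hist(v$a, v$b, bins)
  hj <- entropy_of(h)
  if (hj == 0) return(Inf)
  (entropy_of(rowSums(h)) + entropy_of(colSums(h))) / hj
}

#' Evaluate a named similarity metric
#'
#' Dispatch to one of the implemented measures and return a structured score.
#'
#' @inheritParams ncc
#' @param metric one of `"ncc"`, `"lncc"`, `"ssim"`, `"psnr"`, `"nmi"`,
#'   `"mi"` (case-insensitive).
#' @param ... passed to the underlying metric (e.g. `radius`, `bins`).
#' @return An object of class `srr_score` with fields `metric`, `value`,
#'   `n_voxels`, and `identical` flag (PSNR of identical inputs).
#' @export
evaluate_similarity <- function(a, b, mask = NULL, metric = "ncc", ...) {
  m <- tolower(metric)
  value <- switch(m,
    ncc = ncc(a, b, mask, ...),
    lncc = lncc(a, b, mask, ...),
    ssim = ssim_index(a, b, mask, ...),
    psnr = psnr(a, b, mask, ...),
    nmi = nmi(a, b, mask, ...),
    mi = mutual_information(a, b, mask, ...),
    stop("evaluate_similarity: unknown metric '", metric, "'")
  )
  n <- if (is.null(mask)) length(a) else sum(mask != 0)
  structure(list(metric = m, value = value, n_voxels = n,
                 identical = (m == "psnr" && is.infinite(value))),
            class = "srr_score")
}

#' @export
print.srr_score <- function(x, ...) {
  cat("<srr_score> ", toupper(x$metric), " = ",
      if (x$identical) "Inf (identical images)" else signif(x$value, 6),
      " over ", x$n_voxels, " voxels\n", sep = "")
  invisible(x)
}
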