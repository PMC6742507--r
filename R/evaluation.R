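# Self-consistency and ground-truth evaluation, and the experiment-grid
# harness replicating acquisition-protocol optimization studies on phantoms.

#' Self-consistency of a reconstruction
#'
#' For every slice (inlier or not), the similarity between its pixels and its
#' simulated counterpart projected from the reconstructed volume, evaluated
#' inside the slice mask.
#'
#' @param result `srr_result`.
#' @param stacks optional list of `srr_stack`; defaults to the
#'   motion-corrected stacks recorded in `result`.
#' @param metric similarity metric name.
#' @param truncation PSF cutoff in standard deviations.
#' @return list with `scores` (data.frame: stack, slice, score) and `summary`
#'   (per-stack and overall mean/sd/median).
#' @export
self_consistency <- function(result, stacks = NULL, metric = "ncc",
                             truncation = 3) {
  if (is.null(stacks)) stacks <- result$stacks
  settings <- registration_settings(metric = metric, truncation = truncation)
  rows <- list()
  for (si in seq_along(stacks)) {
    for (sl in stacks[[si]]$slices) {
      sc <- slice_score(result$volume, sl, sl$correction, settings)
      rows[[length(rows) + 1L]] <- data.frame(
        stack = stacks[[si]]$stack_id, slice = sl$slice_index, score = sc)
    }
  }
  scores <- do.call(rbind, rows)
  per_stack <- do.call(rbind, lapply(split(scores$score, scores$stack),
    function(v) data.frame(mean = mean(v), sd = sd(v), median = median(v))))
  per_stack$stack <- rownames(per_stack)
  overall <- data.frame(mean = mean(scores$score), sd = sd(scores$score),
                        median = median(scores$score))
  list(scores = scores, summary = list(per_stack = per_stack,
                                       overall = overall))
}

#' Ground-truth similarity of a reconstruction
#'
#' Compares the reconstructed volume with a ground-truth volume under the
#' requested metrics, inside a mask.  The truth is resampled onto the
#' reconstruction grid when the lattices differ and `resample = TRUE`.
#'
#' @param result `srr_result` (or `srr_image`).
#' @param truth `srr_image` ground-truth volume.
#' @param mask optional `srr_image` mask; defaults to the truth's own mask
#'   propagated to the reconstruction grid, else all voxels.
#' @param metrics character vector of metric names.
#' @param resample allow resampling of the truth onto the recon grid.
#' @return named list of `srr_score` objects.
#' @export
ground_truth_similarity <- function(result, truth, mask = NULL,
                                    metrics = "ncc", resample = TRUE) {
  vol <- if (inherits(result, "srr_result")) result$volume else result
  same_grid <- identical(dim(vol$data), dim(truth$data)) &&
    max(abs(vol$spacing - truth$spacing)) < 1e-9 &&
    max(abs(vol$origin - truth$origin)) < 1e-9 &&
    max(abs(vol$direction - truth$direction)) < 1e-9
  if (!same_grid) {
    if (!resample)
      stop("ground_truth_similarity: grids differ and resample = FALSE")
    if (is.null(mask) && !is.null(truth$mask)) {
      mimg <- truth
      mimg$data <- array(as.numeric(truth$mask != 0), dim(truth$data))
      mask <- propagate_mask(mimg, vol)
    }
    truth <- resample_to_grid(truth, vol)
  }
  m <- if (!is.null(mask)) {
    md <- if (inherits(mask, "srr_image")) mask$data else mask
    if (!identical(dim(md), dim(vol$data)))
      stop("ground_truth_similarity: mask grid mismatch")
    md
  } else if (!is.null(truth$mask) && same_grid) truth$mask
  else NULL
  out <- lapply(metrics, function(mm)
    evaluate_similarity(vol$data, truth$data, mask = m, metric = mm))
  names(out) <- metrics
  out
}

#' Define an experiment grid
#'
#' @param configs character vector of source-data configuration names (see
#'   [build_plan()]).
#' @param methods character vector of method names among `"static"`, `"rg"`,
#'   `"rg_deformable"`, `"robust"`, and the reference-flavoured `"rg_hrt2w"`,
#'   `"rg_ht2w"`, `"rg_bffe"`.
#' @param seeds integer vector of simulation seeds.
#' @param metrics character vector of evaluation metric names.
#' @return Object of class `srr_grid_spec`.
#' @export
experiment_grid <- function(configs, methods, seeds = 1L, metrics = "ncc") {
  structure(list(configs = configs, methods = methods,
                 seeds = as.integer(seeds), metrics = metrics),
            class = "srr_grid_spec")
}

#' Enumerate the cells of an experiment grid
#'
#' One row per reconstruction: every (config, method) pair for every seed.
#' @param grid `srr_grid_spec`.
#' @export
grid_cells <- function(grid) {
  expand.grid(config = grid$configs, method = grid$methods,
              seed = grid$seeds, stringsAsFactors = FALSE)
}

#' Brain-style optimization grid
#'
#' Six source-data configurations crossed with five motion-correction
#' strategies (static, three reference-guided flavours, outlier-robust):
#' 30 reconstructions per seed.
#' @param seeds integer vector of seeds.
#' @export
brain_style_grid <- function(seeds = 1L)
  experiment_grid(configs = c("a+c", "a+c+s", "2a+2c+2s", "a+c+s+3obl",
                              "a+c+s+4obl", "2a+2c+2s+4obl"),
                  methods = c("static", "rg_ht2w", "rg_bffe", "rg_hrt2w",
                              "robust"),
                  seeds = seeds)

#' Abdomen-style optimization grid
#'
#' Three source-data configurations crossed with four strategies (no
#' high-resolution same-contrast reference available): 12 reconstructions
#' per seed.
#' @param seeds integer vector of seeds.
#' @export
abdomen_style_grid <- function(seeds = 1L)
  experiment_grid(configs = c("a+c", "a+c+s", "a+c+s+3obl"),
                  methods = c("static", "rg_ht2w", "rg_bffe", "robust"),
                  seeds = seeds)

# synthetic reference volumes emulating the contrast/quality of the
# candidate registration references
make_reference <- function(phantom, flavour) {
  switch(flavour,
    hrt2w = phantom,
    # heavily T2-weighted: duct/fluid signal strongly amplified, soft tissue
    # compressed (high contrast only at the bright tubes)
    ht2w = { p <- phantom; p$data <- pmin(phantom$data^2.5 * 2, 1); p },
    # balanced gradient echo: different (partly inverted) soft-tissue
    # contrast with smooth shading
    bffe = {
      p <- phantom
      d <- dim(p$data)
      shade <- array(rep(seq(0.9, 1.1, length.out = d[3]), each = d[1] * d[2]),
                     d)
      p$data <- pmax(0, (0.8 - phantom$data) * (phantom$data > 0)) * shade
      p
    },
    stop("make_reference: unknown flavour '", flavour, "'"))
}

run_one_cell <- function(phantom, config, method, seed, metrics, motion_t,
                         motion_r, noise_sd, alpha, settings, solver) {
  sim <- simulate_protocol(phantom, config, motion_t = motion_t,
                           motion_r = motion_r, noise_sd = noise_sd,
                           seed = seed,
                           in_plane = phantom$spacing[1],
                           thickness = solver$thickness)
  grid <- roi_grid(phantom)
  res <- switch(method,
    static = reconstruct_static(sim$stacks, grid = grid, alpha = alpha,
                                max_outer = solver$max_outer,
                                max_inner = solver$max_inner),
    robust = suppressWarnings(reconstruct_outlier_robust(
      sim$stacks, grid = grid, alpha = alpha,
      iterations = solver$iterations,
      sigma = solver$sigma, settings = settings, seed = seed,
      max_outer = solver$max_outer, max_inner = solver$max_inner)),
    rg = ,
    rg_hrt2w = ,
    rg_ht2w = ,
    rg_bffe = ,
    rg_deformable = {
      flavour <- switch(method, rg = , rg_deformable = , rg_hrt2w = "hrt2w",
                        rg_ht2w = "ht2w", rg_bffe = "bffe")
      reconstruct_reference_guided(
        sim$stacks, make_reference(phantom, flavour),
        deformable = identical(method, "rg_deformable"), grid = grid,
        alpha = alpha,
        settings = settings, seed = seed, max_outer = solver$max_outer,
        max_inner = solver$max_inner)
    },
    stop("run_experiment_grid: unknown method '", method, "'"))
  gt <- ground_truth_similarity(res, phantom, metrics = metrics)
  data.frame(config = config, method = method, seed = seed,
             metric = metrics,
             value = vapply(gt, function(s) s$value, numeric(1)),
             rejected = sum(res$rejected_count[length(res$rejected_count)]),
             row.names = NULL)
}

#' Run an experiment grid on a simulated phantom
#'
#' For every (config, method, seed) cell: simulate the protocol, reconstruct
#' with the requested method, and evaluate ground-truth similarity.  Failures
#' of individual cells are recorded and the grid continues.
#'
#' @param grid `srr_grid_spec`.
#' @param phantom `srr_image`; default a fresh [make_phantom()].
#' @param motion_t,motion_r,noise_sd simulation parameters (see
#'   [simulate_stack()]).
#' @param alpha regularization weight.
#' @param settings [registration_settings()].
#' @param iterations,sigma outlier-robust schedule.
#' @param thickness slice thickness in mm.
#' @param max_outer,max_inner solver budget per reconstruction.
#' @return data.frame (config, method, seed, metric, value, rejected); failed
#'   cells carry `NA` values and the condition message in the `"failures"`
#'   attribute.
#' @export
run_experiment_grid <- function(grid, phantom = NULL, motion_t = 3,
                                motion_r = 3, noise_sd = 0.01, alpha = 0.01,
                                settings = registration_settings(),
                                iterations = 3, sigma = c(0.6, 0.65, 0.7),
                                thickness = 5, max_outer = 10,
                                max_inner = 20) {
  if (is.null(phantom)) phantom <- make_phantom()
  cells <- grid_cells(grid)
  solver <- list(iterations = iterations, sigma = sigma,
                 thickness = thickness, max_outer = max_outer,
                 max_inner = max_inner)
  out <- list(); failures <- list()
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    res <- try(run_one_cell(phantom, cell$config, cell$method, cell$seed,
                            grid$metrics, motion_t, motion_r, noise_sd,
                            alpha, settings, solver), silent = TRUE)
    if (inherits(res, "try-error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(config = cell$config, method = cell$method,
                   seed = cell$seed, message = as.character(res))
      res <- data.frame(config = cell$config, method = cell$method,
                        seed = cell$seed, metric = grid$metrics,
                        value = NA_real_, rejected = NA_real_)
    }
    out[[r]] <- res
  }
  tab <- do.call(rbind, out)
  attr(tab, "failures") <- if (length(failures)) do.call(rbind, failures)
                           else NULL
  tab
}
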