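#' Refinement configuration
#'
#' Bundles the knobs of the iterative refinement loop.
#'
#' @param crop_size side of the training volumes cropped from rotated cubes.
#' @param noise_mode one of "none", "ramp", "hamming": reconstruction filter
#'   of the simulated noise (use the one matching how the tomograms were
#'   reconstructed); "off" disables noise injection entirely.
#' @param noise_warmup iterations trained without noise (default 10).
#' @param noise_step denoise-level increment (default 0.05).
#' @param noise_step_every iterations per increment (default 5).
#' @param noise_max denoise-level cap (default 0.2).
#' @param keep_iterations how many iterations of corrected cubes/checkpoints
#'   to retain on disk (default 2); 0 disables persistence.
#' @param output_dir directory for checkpoints and corrected cubes
#'   (default: a session temporary directory).
#' @return A list of class `refine_config`.
#' @export
refine_config <- function(crop_size = 64,
                          noise_mode = c("off", "none", "ramp", "hamming"),
                          noise_warmup = 10, noise_step = 0.05,
                          noise_step_every = 5, noise_max = 0.2,
                          keep_iterations = 2, output_dir = NULL) {
  noise_mode <- match.arg(noise_mode)
  structure(list(crop_size = crop_size, noise_mode = noise_mode,
                 noise_warmup = noise_warmup, noise_step = noise_step,
                 noise_step_every = noise_step_every, noise_max = noise_max,
                 keep_iterations = keep_iterations, output_dir = output_dir),
            class = "refine_config")
}

new_refine_state <- function(cubes, model, master_seed) {
  structure(list(iteration = 0L,
                 original = cubes,
                 corrected = cubes,
                 model = model,
                 denoise_level = 0,
                 loss_history = list(),
                 mse_history = numeric(),
                 master_seed = master_seed),
            class = "refine_state")
}

#' One refinement iteration
#'
#' Performs the four per-iteration stages: (1) training pairs are generated
#' from the corrected cubes of the previous iteration via the 20 wedge-moving
#' rotations; (2) reconstruction-consistent noise is added to the inputs at
#' the scheduled denoise level; (3) the network is trained; (4) the network
#' predicts on the ORIGINAL cubes (never on its own previous predictions)
#' and the predictions' missing-wedge Fourier content is merged into the
#' originals to form the next corrected cubes.  Because of the merge, the
#' sampled Fourier region of every corrected cube equals the original's at
#' every iteration, so errors cannot accumulate across iterations.
#'
#' @param state a `refine_state`.
#' @param w a [wedge_spec].
#' @param cfg a [refine_config].
#' @param train_cfg a [train_config] (its `rng_seed` is ignored; per-
#'   iteration seeds are derived from the state's master seed).
#' @return The advanced `refine_state`.
#' @export
refine_iteration <- function(state, w = wedge_spec(), cfg = refine_config(),
                             train_cfg = train_config()) {
  stopifnot(inherits(state, "refine_state"))
  it <- state$iteration + 1L
  pairs <- build_epoch_dataset(state$corrected, w, cfg$crop_size,
                               rng_seed = derive_seed(state$master_seed, it, 1))
  level <- if (cfg$noise_mode == "off") 0 else
    denoise_schedule(it, cfg$noise_warmup, cfg$noise_step,
                     cfg$noise_step_every, cfg$noise_max)
  if (level > 0) {
    ncfg <- noise_config(cfg$noise_mode)
    for (i in seq_along(pairs)) {
      nv <- backproject_noise(dim(pairs[[i]]$input)[1], ncfg,
                              rng_seed = derive_seed(state$master_seed, it, 2, i))
      pairs[[i]]$noisy_input <- add_noise(pairs[[i]]$input, nv, level)
    }
  }
  tc <- train_cfg
  tc$rng_seed <- derive_seed(state$master_seed, it, 3)
  state$model$adam <- NULL   # fresh optimizer each iteration; weights carry over
  trained <- train_network(state$model, pairs, tc)
  state$model <- trained$model
  state$loss_history[[it]] <- trained$loss
  prev <- state$corrected
  state$corrected$cubes <- lapply(seq_along(state$original$cubes), function(i) {
    pred <- predict_cube(state$model, state$original$cubes[[i]])
    as_volume(fourier_merge(state$original$cubes[[i]], pred, w))
  })
  state$mse_history[it] <- mean(vapply(seq_along(prev$cubes), function(i)
    mean((state$corrected$cubes[[i]] - prev$cubes[[i]])^2), 0))
  state$denoise_level <- level
  state$iteration <- it
  persist_state(state, cfg)
  state
}

persist_state <- function(state, cfg) {
  if (cfg$keep_iterations <= 0) return(invisible(NULL))
  dir <- cfg$output_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(state, file.path(dir, sprintf("state_iter%02d.rds", state$iteration)))
  cube_dir <- file.path(dir, sprintf("corrected_iter%02d", state$iteration))
  dir.create(cube_dir, showWarnings = FALSE)
  for (i in seq_along(state$corrected$cubes))
    write_mrc(state$corrected$cubes[[i]],
              file.path(cube_dir, sprintf("cube_%03d.mrc", i)),
              pixel_size = state$corrected$pixel_size)
  old <- state$iteration - cfg$keep_iterations
  if (old >= 1) {
    unlink(file.path(dir, sprintf("state_iter%02d.rds", old)))
    unlink(file.path(dir, sprintf("corrected_iter%02d", old)), recursive = TRUE)
  }
  invisible(NULL)
}

#' Iterative missing-wedge refinement
#'
#' Runs [refine_iteration] `iterations` times starting from fresh cubes, a
#' resumed state, or pretrained weights.  All randomness (pair shuffling,
#' noise, dropout) derives from `master_seed`, so a resumed run reproduces an
#' uninterrupted one exactly.
#'
#' @param cubes a `subtomo_set` (ignored when `continue_from` is given).
#' @param iterations total number of iterations to reach.
#' @param w a [wedge_spec].
#' @param cfg a [refine_config].
#' @param train_cfg a [train_config].
#' @param model_cfg a [unet_config] for the fresh model.
#' @param master_seed master RNG seed.
#' @param continue_from a `refine_state` (or path to a saved one) to resume.
#' @param pretrained_model a `unet_model` to warm-start from.
#' @return The final `refine_state`.
#' @export
refine <- function(cubes, iterations, w = wedge_spec(),
                   cfg = refine_config(), train_cfg = train_config(),
                   model_cfg = unet_config(), master_seed = 1,
                   continue_from = NULL, pretrained_model = NULL) {
  if (!is.null(continue_from)) {
    state <- if (is.character(continue_from)) readRDS(continue_from)
             else continue_from
    stopifnot(inherits(state, "refine_state"))
    if (state$original$cube_size %% 2^state$model$cfg$depth != 0)
      stop("resume state has incompatible cube size for its model")
  } else {
    stopifnot(inherits(cubes, "subtomo_set"), length(cubes$cubes) >= 1)
    model <- if (!is.null(pretrained_model)) pretrained_model
             else build_model(model_cfg, rng_seed = derive_seed(master_seed, 0, 0))
    state <- new_refine_state(cubes, model, master_seed)
  }
  while (state$iteration < iterations)
    state <- refine_iteration(state, w, cfg, train_cfg)
  state
}

#' Run the split-halves refinement
#'
#' Trains two networks independently on the two halves of a split
#' `subtomo_set` (see [extract_subtomograms] with `split = TRUE`), the
#' gold-standard protocol that enables unbiased FSC between the two
#' resulting reconstructions.
#'
#' @inheritParams refine
#' @return List of two `refine_state` objects, one per half.
#' @export
refine_halves <- function(cubes, iterations, w = wedge_spec(),
                          cfg = refine_config(), train_cfg = train_config(),
                          model_cfg = unet_config(), master_seed = 1) {
  stopifnot(inherits(cubes, "subtomo_set"), !all(is.na(cubes$half_id)))
  lapply(1:2, function(h) {
    sel <- which(cubes$half_id == h)
    half <- cubes
    half$cubes <- cubes$cubes[sel]
    half$half_id <- cubes$half_id[sel]
    if (!is.null(half$seeds)) half$seeds <- cubes$seeds[sel, , drop = FALSE]
    if (!is.null(half$norm)) half$norm <- cubes$norm[sel]
    hcfg <- cfg
    if (!is.null(cfg$output_dir))
      hcfg$output_dir <- file.path(cfg$output_dir, sprintf("half%d", h))
    refine(half, iterations, w, hcfg, train_cfg, model_cfg,
           master_seed = derive_seed(master_seed, h))
  })
}
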