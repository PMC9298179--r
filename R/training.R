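#' Training configuration
#'
#' Orchestrates the three-phase schedule: (1) the generator alone is
#' trained on the non-adversarial terms until it produces primary-quality
#' images; (2) the discriminator alone is trained to separate real images
#' from frozen-generator fakes; (3) the adversarial game runs with both
#' networks updating under the full objectives. Canonical full-scale
#' regimes pair input size and batch size as (128, 32), (256, 20),
#' (512, 4), with 256/20 the default.
#'
#' @param input_size Training crop side in px.
#' @param batch_size Images per step; defaults to the canonical pairing for
#'   `input_size` (20 at 256 px), 8 otherwise.
#' @param steps_phase1_g,steps_phase2_d,steps_phase3_game Steps per phase.
#' @param lr,beta1,beta2 Adam hyper-parameters (DCGAN-standard defaults).
#' @param lr_game Learning rate for the adversarial game (phase 3);
#'   defaults to `lr`. The warm-up phases tolerate a larger step size than
#'   the game, so scaled-down configs warm up fast and play the game at
#'   the conservative rate.
#' @param loss_weights A [loss_weights()].
#' @param gen_config A [generator_config()].
#' @param disc_config A [discriminator_config()].
#' @param extractor A [feature_extractor()] (or NULL for the default).
#' @param d_steps_per_g Discriminator updates per generator update in
#'   phase 3.
#' @param seed Master seed; a run is bit-reproducible given the seed.
#' @param checkpoint_every Emit a checkpoint every this many steps (also at
#'   the end); 0 disables intermediate checkpoints.
#' @return Object of class `training_config`.
#' @export
training_config <- function(input_size = 256L, batch_size = NULL,
                            steps_phase1_g = 1000L, steps_phase2_d = 1000L,
                            steps_phase3_game = 10000L,
                            lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                            lr_game = NULL,
                            loss_weights = cellsharp::loss_weights(),
                            gen_config = generator_config(),
                            disc_config = discriminator_config(),
                            extractor = NULL,
                            d_steps_per_g = 1L,
                            seed = 1L, checkpoint_every = 0L) {
  if (is.null(batch_size)) {
    batch_size <- switch(as.character(input_size),
                         "128" = 32L, "256" = 20L, "512" = 4L, 8L)
  }
  if (is.null(extractor)) extractor <- feature_extractor("random", seed = 17L)
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 steps_phase1_g = as.integer(steps_phase1_g),
                 steps_phase2_d = as.integer(steps_phase2_d),
                 steps_phase3_game = as.integer(steps_phase3_game),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 lr_game = if (is.null(lr_game)) lr else lr_game,
                 loss_weights = loss_weights,
                 gen_config = gen_config, disc_config = disc_config,
                 extractor = extractor,
                 d_steps_per_g = as.integer(d_steps_per_g),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "training_config")
}

phase_of_step <- function(step, config) {
  if (step <= config$steps_phase1_g) 1L
  else if (step <= config$steps_phase1_g + config$steps_phase2_d) 2L
  else 3L
}

total_steps <- function(config) {
  config$steps_phase1_g + config$steps_phase2_d + config$steps_phase3_game
}

dataset_batch <- function(dataset, idx) {
  inputs <- to_batch(lapply(dataset$pairs[idx], `[[`, "input"))
  targets <- to_batch(lapply(dataset$pairs[idx], `[[`, "target"))
  list(inputs = inputs, targets = targets)
}

new_history <- function() {
  data.frame(step = integer(), phase = integer(),
             l_rec = numeric(), l_feat = numeric(), l_style = numeric(),
             l_tv = numeric(), l_adv_g = numeric(), l_adv_d = numeric(),
             l_g_total = numeric())
}

# One generator update on (inputs, targets); adversarial term included when
# `disc` is non-NULL. Returns updated gen/adam state plus the loss report.
g_update <- function(gen, disc, extractor, inputs, targets, lw, adam_g, config,
                     lr = config$lr) {
  x_hat <- generate(inputs, gen, keep_cache = TRUE)
  x_hat_plain <- x_hat
  attributes(x_hat_plain)$cache <- NULL
  attributes(x_hat_plain)$residual_mask <- NULL

  gout <- lw$lambda_rec * grad_reconstruction(targets, x_hat_plain)
  if (lw$lambda_tv > 0) gout <- gout + lw$lambda_tv * grad_tv(x_hat_plain)
  if (lw$lambda_feat > 0 || lw$lambda_style > 0)
    gout <- gout + grad_perceptual(targets, x_hat_plain, extractor,
                                   lw$lambda_feat, lw$lambda_style)
  l_adv_g <- NA_real_
  d_fake <- NULL
  if (!is.null(disc)) {
    d_fake <- discriminate(x_hat_plain, disc, keep_cache = TRUE)
    gout <- gout + lw$lambda_adv_g *
      grad_adversarial_g(d_fake, disc, dim(x_hat_plain))
    l_adv_g <- adversarial_losses(1, as.numeric(d_fake))$l_adv_g
  }
  bw <- generator_backward(gen, x_hat, gout)
  upd <- adam_step(gen$weights, bw$gw, adam_g, lr = lr,
                   beta1 = config$beta1, beta2 = config$beta2)
  gen$weights <- upd$weights
  report <- generator_total_loss(targets, x_hat_plain,
                                 if (is.null(d_fake)) NULL else as.numeric(d_fake),
                                 extractor, lw)
  list(gen = gen, adam_g = upd$state, report = report)
}

# One discriminator update against frozen-generator fakes.
d_update <- function(gen, disc, inputs, targets, adam_d, config,
                     lr = config$lr) {
  x_hat <- generate(inputs, gen, keep_cache = FALSE)
  d_real <- discriminate(targets, disc, keep_cache = TRUE)
  cache_r <- attr(d_real, "cache")
  d_fake <- discriminate(x_hat, disc, keep_cache = TRUE)
  cache_f <- attr(d_fake, "cache")
  pr <- pmin(pmax(as.numeric(d_real), .eps_prob), 1 - .eps_prob)
  pf <- pmin(pmax(as.numeric(d_fake), .eps_prob), 1 - .eps_prob)
  B <- length(pr)
  # L_D = -mean(log pr + log(1 - pf))
  gp_real <- array(-1 / (B * pr), dim = c(1, 1, 1, B))
  gp_fake <- array(1 / (B * (1 - pf)), dim = c(1, 1, 1, B))
  bw_r <- net_backward(disc$net, disc$weights, cache_r, gp_real)
  bw_f <- net_backward(disc$net, disc$weights, cache_f, gp_fake)
  gsum <- bw_r$gw
  for (i in seq_along(gsum))
    for (nm in names(gsum[[i]]))
      gsum[[i]][[nm]] <- gsum[[i]][[nm]] + bw_f$gw[[i]][[nm]]
  upd <- adam_step(disc$weights, gsum, adam_d, lr = lr,
                   beta1 = config$beta1, beta2 = config$beta2)
  disc$weights <- upd$weights
  l_adv_d <- adversarial_losses(pr, pf)$l_adv_d
  list(disc = disc, adam_d = upd$state, l_adv_d = l_adv_d)
}

check_finite_losses <- function(report, step) {
  for (nm in names(report)) {
    v <- report[[nm]]
    if (!is.na(v) && !is.finite(v))
      stop(sprintf("non-finite loss term '%s' at step %d", nm, step))
  }
}

#' Train the enhancement GAN
#'
#' Runs the three-phase schedule on a paired dataset. Phase 1 updates the
#' generator only, with the non-adversarial terms; phase 2 updates the
#' discriminator only; phase 3 alternates discriminator and generator
#' updates under the full objectives. The CIEGANP variant is not a
#' different trainer — it is this function applied to a dataset built with
#' `target_mode = "EGT"`.
#'
#' @param dataset A `paired_dataset` (see [build_dataset()]).
#' @param config A [training_config()].
#' @param out_dir Optional directory for intermediate checkpoints and the
#'   history CSV.
#' @return List with `checkpoint` (see [save_checkpoint()]) and `history`
#'   (one row per step with every loss term and the phase label).
#' @export
train <- function(dataset, config, out_dir = NULL) {
  stopifnot(inherits(dataset, "paired_dataset"), length(dataset$pairs) >= 1)
  d0 <- dim(dataset$pairs[[1]]$input$pixels)
  gen <- init_generator(config$gen_config, seed = config$seed)
  disc <- init_discriminator(config$disc_config, seed = config$seed + 1L)
  state <- list(gen = gen, disc = disc,
                adam_g = adam_init(gen$weights),
                adam_d = adam_init(disc$weights),
                step = 0L, history = new_history())
  with_seed(config$seed + 2L,
            run_training_loop(state, dataset, config, out_dir))
}

run_training_loop <- function(state, dataset, config, out_dir = NULL) {
  n <- length(dataset$pairs)
  bs <- config$batch_size
  lw <- config$loss_weights
  extractor <- config$extractor
  nsteps <- total_steps(config)
  hist_rows <- vector("list", nsteps - state$step)
  ri <- 0L
  while (state$step < nsteps) {
    step <- state$step + 1L
    phase <- phase_of_step(step, config)
    idx <- if (bs <= n) sample.int(n, bs) else sample.int(n, bs, replace = TRUE)
    b <- dataset_batch(dataset, idx)
    row <- data.frame(step = step, phase = phase, l_rec = NA_real_,
                      l_feat = NA_real_, l_style = NA_real_, l_tv = NA_real_,
                      l_adv_g = NA_real_, l_adv_d = NA_real_,
                      l_g_total = NA_real_)
    if (phase == 1L) {
      up <- g_update(state$gen, NULL, extractor, b$inputs, b$targets, lw,
                     state$adam_g, config)
      state$gen <- up$gen; state$adam_g <- up$adam_g
      check_finite_losses(up$report, step)
      row[c("l_rec", "l_feat", "l_style", "l_tv", "l_g_total")] <-
        up$report[c("l_rec", "l_feat", "l_style", "l_tv", "l_g_total")]
    } else if (phase == 2L) {
      up <- d_update(state$gen, state$disc, b$inputs, b$targets,
                     state$adam_d, config)
      state$disc <- up$disc; state$adam_d <- up$adam_d
      if (!is.finite(up$l_adv_d))
        stop(sprintf("non-finite loss term 'l_adv_d' at step %d", step))
      row$l_adv_d <- up$l_adv_d
    } else {
      for (k in seq_len(config$d_steps_per_g)) {
        up_d <- d_update(state$gen, state$disc, b$inputs, b$targets,
                         state$adam_d, config, lr = config$lr_game)
        state$disc <- up_d$disc; state$adam_d <- up_d$adam_d
      }
      up <- g_update(state$gen, state$disc, extractor, b$inputs, b$targets,
                     lw, state$adam_g, config, lr = config$lr_game)
      state$gen <- up$gen; state$adam_g <- up$adam_g
      check_finite_losses(up$report, step)
      row[c("l_rec", "l_feat", "l_style", "l_tv", "l_adv_g", "l_g_total")] <-
        up$report[c("l_rec", "l_feat", "l_style", "l_tv", "l_adv_g", "l_g_total")]
      row$l_adv_d <- up_d$l_adv_d
    }
    state$step <- step
    ri <- ri + 1L
    hist_rows[[ri]] <- row
    if (!is.null(out_dir) && config$checkpoint_every > 0L &&
        step %% config$checkpoint_every == 0L) {
      snap <- state
      snap$history <- rbind(state$history,
                            do.call(rbind, hist_rows[seq_len(ri)]))
      save_checkpoint(make_checkpoint(snap, config),
                      file.path(out_dir, sprintf("step%06d.ckpt", step)))
    }
  }
  state$history <- rbind(state$history,
                         do.call(rbind, hist_rows[seq_len(ri)]))
  ckpt <- make_checkpoint(state, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(ckpt, file.path(out_dir, "final.ckpt"))
    write.csv(state$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
  }
  list(checkpoint = ckpt, history = state$history)
}

make_checkpoint <- function(state, config) {
  structure(list(version = 1L,
                 config = config,
                 gen = state$gen, disc = state$disc,
                 adam_g = state$adam_g, adam_d = state$adam_d,
                 step = state$step,
                 history = state$history,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "ciegan_checkpoint")
}

#' Save / load a training checkpoint
#'
#' Checkpoints carry the full training state: both networks' configs and
#' weights, optimiser moments, the step counter, the loss history and the
#' RNG state, so a resumed run is bit-identical to an uninterrupted one.
#'
#' @param checkpoint A `ciegan_checkpoint`.
#' @param path File path (`.ckpt`).
#' @return `path` (or the checkpoint for [load_checkpoint()]).
#' @export
save_checkpoint <- function(checkpoint, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "ciegan_checkpoint")) stop("corrupt or foreign checkpoint")
  ckpt
}

config_compatible <- function(a, b) {
  fields <- c("input_size", "batch_size", "steps_phase1_g", "steps_phase2_d",
              "lr", "lr_game", "beta1", "beta2", "d_steps_per_g", "seed")
  bad <- fields[vapply(fields, function(f) !identical(a[[f]], b[[f]]), logical(1))]
  arch <- c("gen_config", "disc_config")
  bad <- c(bad, arch[vapply(arch, function(f) !identical(unclass(a[[f]]), unclass(b[[f]])), logical(1))])
  bad
}

#' Resume training from a checkpoint
#'
#' Continues to the (possibly extended) step total in `config`. All
#' architecture and optimiser fields must match the checkpointed config;
#' `steps_phase3_game` may be increased.
#'
#' @param checkpoint A `ciegan_checkpoint` (or path to one).
#' @param dataset The training `paired_dataset`.
#' @param config A [training_config()] compatible with the checkpoint.
#' @return As [train()].
#' @export
resume <- function(checkpoint, dataset, config = NULL) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (is.null(config)) config <- checkpoint$config
  bad <- config_compatible(checkpoint$config, config)
  if (length(bad))
    stop(sprintf("resume config incompatible with checkpoint; differing fields: %s",
                 paste(bad, collapse = ", ")))
  state <- list(gen = checkpoint$gen, disc = checkpoint$disc,
                adam_g = checkpoint$adam_g, adam_d = checkpoint$adam_d,
                step = checkpoint$step, history = checkpoint$history)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", checkpoint$rng_state, envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  run_training_loop(state, dataset, config)
}
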