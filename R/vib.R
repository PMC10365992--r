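#' Training configuration for the capacity-constrained network
#'
#' The network minimizes `E[reward loss] + beta * I`, where `I` is the KL
#' information cost of the stochastic encoder and the reward loss is the
#' expected misclassification (accuracy context) or the misclassification
#' weighted by the diagonality difference at stake (reward context).
#'
#' @param context `"accuracy"` or `"reward"`.
#' @param beta Information regularization weight, nonnegative.
#' @param steps Number of minibatch steps.
#' @param batch Minibatch size (pairs).
#' @param lr Adam step size.
#' @param seed Integer seed.
#' @param n_pool Number of pre-rendered training pairs.
#' @return A list of class `fm_vib_config`.
#' @export
vib_config <- function(context = c("accuracy", "reward"), beta = 0.003,
                       steps = 3000L, batch = 512L, lr = 1e-3, seed = 1L,
                       n_pool = 4096L) {
  context <- match.arg(context)
  if (beta < 0) stop_fitmax("`beta` must be nonnegative.", "fitmax_range_error")
  structure(list(context = context, beta = beta, steps = as.integer(steps),
                 batch = as.integer(batch), lr = lr, seed = as.integer(seed),
                 n_pool = as.integer(n_pool)),
            class = "fm_vib_config")
}

# conv geometry: 4x4 kernels, stride 2
conv_geometry <- function(size) {
  pos <- seq(1L, size - 3L, by = 2L)
  n_out <- length(pos)
  idx <- matrix(0L, 16L, n_out^2)
  p <- 0L
  for (cj in pos) for (ci in pos) {
    p <- p + 1L
    cell <- 0L
    for (kj in 0:3) for (ki in 0:3) {
      cell <- cell + 1L
      idx[cell, p] <- (cj + kj - 1L) * size + (ci + ki)
    }
  }
  list(idx = idx, n_patch = n_out^2)
}

init_vib_model <- function(spec = gabor_spec(), latent_k = 4L, width = 20L,
                           n_filters = 4L, seed = 1L) {
  set.seed(derive_seed(seed, "vib/init"))
  geo <- conv_geometry(spec$size)
  enc_in <- geo$n_patch * n_filters
  g <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  model <- list(
    Wc = g(16L, n_filters), bc = rep(0, n_filters),
    Wm = g(enc_in, latent_k) * 0.3, bm = rep(0, latent_k),
    Wv = matrix(0, enc_in, latent_k), bv = rep(-1, latent_k),
    W1 = g(2L * latent_k, width), b1 = rep(0, width),
    W2 = g(width, 1L), b2 = 0
  )
  structure(list(params = model, spec = spec, geo = geo, latent_k = latent_k,
                 width = width, n_filters = n_filters),
            class = "fm_vib_model")
}

# extract conv patches for a batch of images: 16 x (n_patch * B)
image_patches <- function(model, images) {
  geo <- model$geo
  b <- ncol(images)
  matrix(images[rep(geo$idx, b) +
                  rep((seq_len(b) - 1L) * nrow(images), each = 16L * geo$n_patch)],
         16L)
}

# forward pass through conv + encoder heads; takes images or a precomputed
# patch matrix (the training loop precomputes patches for its whole pool)
encoder_forward <- function(model, images = NULL, pm = NULL, b = NULL) {
  geo <- model$geo
  if (is.null(pm)) {
    b <- ncol(images)
    pm <- image_patches(model, images)
  }
  np <- geo$n_patch
  nf <- model$n_filters
  kk <- model$latent_k
  conv <- crossprod(pm, model$params$Wc)
  conv <- conv + rep(model$params$bc, each = nrow(conv))
  conv_r <- pmax(conv, 0)
  # encoder heads without materializing the B x (np*nf) layout: per-filter
  # blocks of Wm / Wv act on the np x B view of each filter map
  mu <- matrix(model$params$bm, b, kk, byrow = TRUE)
  lv <- matrix(model$params$bv, b, kk, byrow = TRUE)
  hblocks <- vector("list", nf)
  for (f in seq_len(nf)) {
    hb <- matrix(conv_r[, f], np, b)
    hblocks[[f]] <- hb
    rows <- ((f - 1L) * np + 1L):(f * np)
    mu <- mu + crossprod(hb, model$params$Wm[rows, , drop = FALSE])
    lv <- lv + crossprod(hb, model$params$Wv[rows, , drop = FALSE])
  }
  lv <- pmin(pmax(lv, -8), 4)
  list(hblocks = hblocks, mu = mu, lv = lv, conv_mask = conv > 0, pm = pm)
}

# KL(N(mu, diag exp(lv)) || N(0, I)) per row
kl_terms <- function(mu, lv) {
  0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)
}

#' Loss terms of the information-bottleneck objective on a batch
#'
#' Returns the expected reward-loss term, the information (KL) term and their
#' `beta`-weighted total for a batch of stimulus pairs, using a single
#' reparameterized latent sample per input.
#'
#' @param model An `fm_vib_model`.
#' @param x1,x2 Image batches (`size^2 x B` matrices).
#' @param d1,d2 Diagonality values (degrees) of the two stimuli.
#' @param config A [vib_config()].
#' @param eps1,eps2 Optional pre-drawn standard normal noise (`B x K`).
#' @param pm1,pm2 Optional precomputed patch matrices (with `b`), used by the
#'   training loop in place of raw images.
#' @param b Batch size when patch matrices are supplied.
#' @return A list with `reward_loss`, `information`, `total` and the forward
#'   state (for the internal training loop).
#' @export
vib_losses <- function(model, x1, x2, d1, d2, config, eps1 = NULL,
                       eps2 = NULL, pm1 = NULL, pm2 = NULL, b = NULL) {
  b <- b %||% ncol(x1)
  kk <- model$latent_k
  f1 <- encoder_forward(model, x1, pm = pm1, b = b)
  f2 <- encoder_forward(model, x2, pm = pm2, b = b)
  if (is.null(eps1)) eps1 <- matrix(rnorm(b * kk), b, kk)
  if (is.null(eps2)) eps2 <- matrix(rnorm(b * kk), b, kk)
  z1 <- f1$mu + exp(f1$lv / 2) * eps1
  z2 <- f2$mu + exp(f2$lv / 2) * eps2
  a <- cbind(z1, z2)
  h1 <- pmax(a %*% model$params$W1 +
               matrix(model$params$b1, b, model$width, byrow = TRUE), 0)
  logit <- h1 %*% model$params$W2 + model$params$b2
  p <- 1 / (1 + exp(-logit))
  y <- as.numeric(d1 > d2)
  wscale <- config$wt_scale %||% 1
  wt <- if (config$context == "reward") abs(d1 - d2) / 45 * wscale else rep(1, b)
  err <- y * (1 - p) + (1 - y) * p
  reward_loss <- mean(wt * err)
  info <- mean(kl_terms(f1$mu, f1$lv) + kl_terms(f2$mu, f2$lv))
  list(reward_loss = reward_loss, information = info,
       total = reward_loss + config$beta * info,
       state = list(f1 = f1, f2 = f2, z1 = z1, z2 = z2, a = a, h1 = h1,
                    p = p, y = y, wt = wt, eps1 = eps1, eps2 = eps2))
}

# gradients of the vib objective; returns list matching params
vib_backward <- function(model, x1, x2, st, config) {
  b <- length(st$y)
  kk <- model$latent_k
  prm <- model$params
  dlogit <- st$wt * (1 - 2 * st$y) * st$p * (1 - st$p) / b
  gW2 <- crossprod(st$h1, dlogit)
  gb2 <- sum(dlogit)
  dh1 <- tcrossprod(dlogit, prm$W2) * (st$h1 > 0)
  gW1 <- crossprod(st$a, dh1)
  gb1 <- colSums(dh1)
  da <- tcrossprod(dh1, prm$W1)
  gWm <- matrix(0, nrow(prm$Wm), kk); gbm <- rep(0, kk)
  gWv <- matrix(0, nrow(prm$Wv), kk); gbv <- rep(0, kk)
  gWc <- matrix(0, 16L, model$n_filters); gbc <- rep(0, model$n_filters)
  for (side in 1:2) {
    f <- if (side == 1) st$f1 else st$f2
    eps <- if (side == 1) st$eps1 else st$eps2
    dz <- da[, ((side - 1) * kk + 1):(side * kk), drop = FALSE]
    dmu <- dz + config$beta * f$mu / b
    dlv <- dz * eps * 0.5 * exp(f$lv / 2) +
      config$beta * 0.5 * (exp(f$lv) - 1) / b
    gbm <- gbm + colSums(dmu)
    gbv <- gbv + colSums(dlv)
    np <- model$geo$n_patch
    nf <- model$n_filters
    dconv <- matrix(0, np * b, nf)
    for (ff in seq_len(nf)) {
      rows <- ((ff - 1L) * np + 1L):(ff * np)
      gWm[rows, ] <- gWm[rows, ] + f$hblocks[[ff]] %*% dmu
      gWv[rows, ] <- gWv[rows, ] + f$hblocks[[ff]] %*% dlv
      # gradient into this filter map: np x B
      dhb <- prm$Wm[rows, , drop = FALSE] %*% t(dmu) +
        prm$Wv[rows, , drop = FALSE] %*% t(dlv)
      dconv[, ff] <- dhb
    }
    dconv <- dconv * f$conv_mask
    gWc <- gWc + f$pm %*% dconv
    gbc <- gbc + colSums(dconv)
  }
  list(Wc = gWc, bc = gbc, Wm = gWm, bm = gbm, Wv = gWv, bv = gbv,
       W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, frozen = character(0),
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    if (nm %in% frozen) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# draw task pairs. "iid": both orientations drawn independently from the
# prior (the product pair density of the normative objectives; dense regions
# yield close pairs, rare regions distant ones - the interaction that
# separates the two reward contexts). "staircase": reference from the prior,
# comparison offset in diagonality, mirroring the adaptive behavioural task.
draw_task_pairs <- function(n, prior, mode = c("iid", "staircase"),
                            sep_sd = 8, sep_min = 1) {
  mode <- match.arg(mode)
  if (mode == "iid") {
    s1 <- sample_stimuli(prior, n)
    s2 <- sample_stimuli(prior, n)
    return(list(s1 = s1, s2 = s2, d1 = diagonality(s1), d2 = diagonality(s2)))
  }
  ref <- sample_stimuli(prior, n)
  d_ref <- diagonality(ref)
  sep <- pmin(pmax(abs(rnorm(n, 0, sep_sd)), sep_min), 44)
  dir <- sample(c(-1, 1), n, replace = TRUE)
  d_cmp <- d_ref + dir * sep
  flip <- d_cmp > 45 | d_cmp < 0
  d_cmp[flip] <- d_ref[flip] - dir[flip] * sep[flip]
  d_cmp <- pmin(pmax(d_cmp, 0), 45)
  cmp <- orientation_from_diagonality(d_cmp, ref)
  swap <- runif(n) < 0.5
  s1 <- ifelse(swap, cmp, ref)
  s2 <- ifelse(swap, ref, cmp)
  list(s1 = s1, s2 = s2, d1 = diagonality(s1), d2 = diagonality(s2))
}

#' Train the capacity-constrained network
#'
#' Minibatch Adam training of the stochastic-encoder network on orientation
#' pairs whose statistics mirror the behavioural task (references drawn from
#' the natural-orientation prior). Training aborts if the smoothed loss
#' exceeds ten times its starting level.
#'
#' @param config A [vib_config()].
#' @param prior Orientation prior used to draw training stimuli.
#' @param spec A [gabor_spec()].
#' @param model Optional warm-start model (default: fresh initialization).
#' @param frozen Character vector of parameter names excluded from updates
#'   (e.g. the encoder parameters in the transfer experiment).
#' @param stop_at_accuracy Optional `c(lo, hi)` band: training stops once
#'   held-out accuracy (checked every 100 steps after the first 300) enters
#'   the band; used to calibrate models to matched discrimination accuracy
#'   before comparing their loss metrics.
#' @return The trained `fm_vib_model` with a `trace` tibble (step, loss,
#'   reward loss, information) and `holdout` (accuracy and reward loss on a
#'   held-out pair stream) attached.
#' @export
train_vib <- function(config, prior = orientation_prior(),
                      spec = gabor_spec(), model = NULL,
                      frozen = character(0), stop_at_accuracy = NULL) {
  # the training stream (pool, minibatches, encoder noise) depends only on
  # the seed, not the context: paired context comparisons then isolate the
  # objective as the only difference
  set.seed(derive_seed(config$seed, "vib/train"))
  if (is.null(model)) model <- init_vib_model(spec, seed = config$seed)
  pool <- draw_task_pairs(config$n_pool, prior)
  # normalize the reward weight to unit mean over the pool so the two
  # contexts face comparable loss scales (beta is defined up to this scale)
  config$wt_scale <- 1 / mean(abs(pool$d1 - pool$d2) / 45)
  pm1 <- image_patches(model, render_gabor(spec, pool$s1))
  pm2 <- image_patches(model, render_gabor(spec, pool$s2))
  np <- model$geo$n_patch
  ho <- draw_task_pairs(2048L, prior)
  hx1 <- render_gabor(spec, ho$s1)
  hx2 <- render_gabor(spec, ho$s2)
  ad <- adam_init(model$params)
  trace <- list()
  ema <- NA_real_
  ema0 <- NA_real_
  for (step in seq_len(config$steps)) {
    ix <- sample.int(config$n_pool, config$batch, replace = FALSE)
    cols <- rep((ix - 1L) * np, each = np) + seq_len(np)
    vl <- vib_losses(model, NULL, NULL, pool$d1[ix], pool$d2[ix], config,
                     pm1 = pm1[, cols, drop = FALSE],
                     pm2 = pm2[, cols, drop = FALSE], b = config$batch)
    g <- vib_backward(model, NULL, NULL, vl$state, config)
    upd <- adam_step(model$params, g, ad, config$lr, frozen = frozen)
    model$params <- upd$params
    ad <- upd$state
    ema <- if (is.na(ema)) vl$total else 0.98 * ema + 0.02 * vl$total
    if (is.na(ema0) && step >= 20L) ema0 <- ema
    if (!is.na(ema0) && ema > 10 * ema0) {
      stop_fitmax(sprintf("Training diverged at step %d (loss %.3g).", step, ema),
                  "fitmax_divergence")
    }
    if (step %% 100L == 0L) {
      trace[[length(trace) + 1L]] <-
        tibble::tibble(step = step, loss = ema, reward_loss = vl$reward_loss,
                       information = vl$information)
    }
    if (!is.null(stop_at_accuracy) && step >= 300L && step %% 100L == 0L) {
      acc <- vib_holdout(model, hx1, hx2, ho, config)$accuracy
      if (acc >= stop_at_accuracy[1] && acc <= stop_at_accuracy[2]) break
    }
  }
  model$trace <- dplyr::bind_rows(trace)
  model$holdout <- vib_holdout(model, hx1, hx2, ho, config)
  model$config <- config
  model
}

# held-out evaluation: decision accuracy and the reward-weighted error metric
vib_holdout <- function(model, hx1, hx2, ho, config) {
  f1 <- encoder_forward(model, hx1)
  f2 <- encoder_forward(model, hx2)
  b <- ncol(hx1)
  kk <- model$latent_k
  z1 <- f1$mu + exp(f1$lv / 2) * matrix(rnorm(b * kk), b, kk)
  z2 <- f2$mu + exp(f2$lv / 2) * matrix(rnorm(b * kk), b, kk)
  a <- cbind(z1, z2)
  h1 <- pmax(a %*% model$params$W1 +
               matrix(model$params$b1, b, model$width, byrow = TRUE), 0)
  p <- 1 / (1 + exp(-(h1 %*% model$params$W2 + model$params$b2)))
  y <- as.numeric(ho$d1 > ho$d2)
  acc <- mean((p > 0.5) == (y == 1))
  err <- y * (1 - p) + (1 - y) * p
  list(accuracy = acc,
       reward_loss = mean(abs(ho$d1 - ho$d2) / 45 * err),
       accuracy_loss = mean(err))
}

#' Fisher information of the trained encoder over diagonality
#'
#' Renders many stimuli per angle on the 0-45 degree grid (0.5-degree steps),
#' computes the mean latent response \eqn{\bar z(s)} and the per-dimension
#' noise (encoder variance plus render-to-render variability), rescales each
#' latent dimension to unit noise variance, and returns
#' \eqn{J(s) = \lVert d\bar z / ds \rVert^2} using central finite differences
#' smoothed by a 5-point moving average.
#'
#' @param model A trained `fm_vib_model`.
#' @param samples_per_angle Renders per angle (default 500).
#' @param angles Angle grid in degrees (default 0 to 45 by 0.5).
#' @param seed Integer seed for render phases and encoder noise.
#' @return A tibble of class `fm_fisher_curve` with columns `angle` and `J`.
#' @export
fisher_curve <- function(model, samples_per_angle = 500L,
                         angles = seq(0, 45, by = 0.5), seed = 1L) {
  set.seed(derive_seed(seed, "vib/fisher"))
  kk <- model$latent_k
  zbar <- matrix(0, length(angles), kk)
  noise <- matrix(0, length(angles), kk)
  for (i in seq_along(angles)) {
    imgs <- render_gabor(model$spec, rep(angles[i], samples_per_angle))
    f <- encoder_forward(model, imgs)
    zbar[i, ] <- colMeans(f$mu)
    noise[i, ] <- colMeans(exp(f$lv)) + apply(f$mu, 2, var)
  }
  sdn <- sqrt(pmax(colMeans(noise), 1e-10))
  floored <- colMeans(noise) <= 1e-10
  if (any(floored)) {
    warn(sprintf("Zero noise variance in latent dimension(s) %s; flooring.",
                 paste(which(floored), collapse = ", ")),
         class = "fitmax_zero_noise")
  }
  zr <- sweep(zbar, 2, sdn, "/")
  h <- diff(angles[1:2])
  dz <- apply(zr, 2, function(col) {
    d <- c(col[2] - col[1],
           (col[-(1:2)] - col[seq_len(length(col) - 2L)]) / 2,
           col[length(col)] - col[length(col) - 1L]) / h
    stats::filter(d, rep(1 / 5, 5), sides = 2) |> as.numeric()
  })
  jj <- rowSums(dz^2)
  # moving-average endpoints are NA; carry the nearest smoothed value
  jj[1:2] <- jj[3]
  jj[(length(jj) - 1):length(jj)] <- jj[length(jj) - 2]
  out <- tibble::tibble(angle = angles, J = jj)
  attr(out, "samples_per_angle") <- samples_per_angle
  class(out) <- c("fm_fisher_curve", class(out))
  out
}

#' Encoder freeze-and-retrain transfer experiment
#'
#' Trains a network in the accuracy context, then (i) freezes everything up
#' to the stochastic encoder and retrains only the downstream layers in the
#' reward context, (ii) retrains the whole network in the reward context, and
#' (iii) trains a reward-context network from scratch. All three are
#' compared on the held-out reward-loss metric; discrimination accuracies are
#' reported so comparisons can be gated on matched accuracy.
#'
#' @param config_acc,config_rew [vib_config()]s for the two contexts.
#' @param prior Orientation prior.
#' @param spec A [gabor_spec()].
#' @param width Downstream width for the retrained heads (default the
#'   model's own width; widen it to probe whether downstream complexity can
#'   rescue a frozen encoder).
#' @param accuracy_band Optional `c(lo, hi)` accuracy band passed to every
#'   training so all variants are compared at matched discrimination
#'   accuracy.
#' @return A tibble with one row per variant (`frozen`, `unfrozen`,
#'   `scratch`) and columns `accuracy` and `reward_loss`, plus the trained
#'   models in the `models` attribute.
#' @export
freeze_encoder_retrain <- function(config_acc, config_rew,
                                   prior = orientation_prior(),
                                   spec = gabor_spec(), width = NULL,
                                   accuracy_band = NULL) {
  base <- train_vib(config_acc, prior, spec, stop_at_accuracy = accuracy_band)
  enc_names <- c("Wc", "bc", "Wm", "bm", "Wv", "bv")
  reinit_head <- function(model, seed) {
    set.seed(derive_seed(seed, "vib/head"))
    w <- width %||% model$width
    kk <- model$latent_k
    model$params$W1 <- matrix(rnorm(2 * kk * w, 0, sqrt(2 / (2 * kk))), 2 * kk, w)
    model$params$b1 <- rep(0, w)
    model$params$W2 <- matrix(rnorm(w, 0, sqrt(2 / w)), w, 1)
    model$params$b2 <- 0
    model$width <- w
    model
  }
  frozen <- train_vib(config_rew, prior, spec,
                      model = reinit_head(base, config_rew$seed + 1L),
                      frozen = enc_names, stop_at_accuracy = accuracy_band)
  unfrozen <- train_vib(config_rew, prior, spec,
                        model = reinit_head(base, config_rew$seed + 2L),
                        stop_at_accuracy = accuracy_band)
  scratch <- train_vib(config_rew, prior, spec,
                       stop_at_accuracy = accuracy_band)
  out <- tibble::tibble(
    variant = c("frozen", "unfrozen", "scratch"),
    accuracy = c(frozen$holdout$accuracy, unfrozen$holdout$accuracy,
                 scratch$holdout$accuracy),
    reward_loss = c(frozen$holdout$reward_loss, unfrozen$holdout$reward_loss,
                    scratch$holdout$reward_loss),
    accuracy_loss = c(frozen$holdout$accuracy_loss,
                      unfrozen$holdout$accuracy_loss,
                      scratch$holdout$accuracy_loss)
  )
  # reward at stake per unit of error: an accuracy-robust signature of where
  # the encoder lets errors happen (high- vs low-stake pairs)
  out$stake_per_error <- out$reward_loss / out$accuracy_loss
  attr(out, "models") <- list(base = base, frozen = frozen,
                              unfrozen = unfrozen, scratch = scratch)
  out
}
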