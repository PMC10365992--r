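#' MCMC schedule for the hierarchical fit
#'
#' The default schedule mirrors the long production schedule (3 chains,
#' 20,000 burn-in draws, 5,000 retained draws thinned by 5, i.e. 3,000 final
#' samples); fits used in tests run a much shorter schedule, which recovery
#' checks show is sufficient for the scientific contract.
#'
#' @param chains Number of chains (at least 2).
#' @param burnin Burn-in iterations per chain.
#' @param draws Post-burn-in iterations per chain.
#' @param thin Thinning factor.
#' @param seed Integer seed.
#' @return A list of class `fm_fit_config`.
#' @export
fit_config <- function(chains = 3L, burnin = 20000L, draws = 5000L,
                       thin = 5L, seed = 1L) {
  if (chains < 2L) stop_fitmax("At least 2 chains are required.", "fitmax_range_error")
  if (thin < 1L) stop_fitmax("`thin` must be at least 1.", "fitmax_range_error")
  structure(
    list(chains = as.integer(chains), burnin = as.integer(burnin),
         draws = as.integer(draws), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "fm_fit_config"
  )
}

#' Split a trial table into early and late training phases
#'
#' Early = trials 1-200, late = trials beyond 200, within each subject and
#' context. Sessions with no late trials are flagged.
#'
#' @param trials A decision trial tibble with a `trial` index column.
#' @return A list with elements `early`, `late` (tibbles) and
#'   `short_sessions` (subjects without late trials).
#' @export
split_phases <- function(trials) {
  early <- dplyr::filter(trials, .data$trial <= 200L)
  late <- dplyr::filter(trials, .data$trial > 200L)
  counts <- trials |>
    dplyr::group_by(.data$subject, .data$context) |>
    dplyr::summarise(n = max(.data$trial), .groups = "drop")
  short <- counts$subject[counts$n <= 200L]
  if (length(short) > 0) {
    warn(sprintf("No late-phase trials for: %s", paste(short, collapse = ", ")),
         class = "fitmax_short_session")
  }
  list(early = early, late = late, short_sessions = short)
}

# per-subject precomputation for the choice likelihood on the diagonality axis
prep_subject_data <- function(d1, d2, choice, a, omega) {
  th1 <- 4 * d1 * pi / 180
  th2 <- 4 * d2 * pi / 180
  list(
    L1 = log((a - cos(th1)) / omega), L2 = log((a - cos(th2)) / omega),
    sin1 = sin(th1), sin2 = sin(th2),
    c1 = a - cos(th1), c2 = a - cos(th2),
    chose1 = choice == 1L, omega = omega, n = length(d1), d1 = d1, d2 = d2
  )
}

# log-likelihood of one subject's choices under (q, k, lambda, beta0);
# bias and variance follow the closed-form power-law observer with the
# radian-normalized density (L = log of inverse density; moments converted
# to degrees)
subject_loglik <- function(dat, q, k, lambda, beta0) {
  if (q <= 0 || k <= 0 || lambda < 0 || lambda > 1) return(-Inf)
  deg <- 180 / pi
  v1 <- deg^2 * exp(q * dat$L1) / k
  v2 <- deg^2 * exp(q * dat$L2) / k
  b1 <- deg * (1 - 1 / q) * 4 * q * dat$sin1 * exp((q - 1) * dat$L1) /
    (k * dat$omega)
  b2 <- deg * (1 - 1 / q) * 4 * q * dat$sin2 * exp((q - 1) * dat$L2) /
    (k * dat$omega)
  arg <- ((dat$d1 + b1) - (dat$d2 + b2)) / sqrt(v1 + v2)
  p1 <- lambda / 2 + (1 - lambda) * pnorm(arg + beta0)
  p <- ifelse(dat$chose1, p1, 1 - p1)
  sum(log(pmin(pmax(p, 1e-12), 1 - 1e-12)))
}

# natural-scale parameters from the transformed vector
theta_natural <- function(th) {
  c(q = exp(th[1]), k = exp(th[2]), lambda = stats::plogis(th[3]),
    beta0 = th[4])
}

subject_loglik_t <- function(dat, th) {
  p <- theta_natural(th)
  subject_loglik(dat, p[1], p[2], p[3], p[4])
}

#' Hierarchical Bayesian fit of the power-law observer to choice data
#'
#' Fits subject-level parameters (q, k, lambda, beta0) with group-level
#' Gaussian pooling on transformed scales (log q, log k, logit lambda,
#' identity beta0) and effectively flat hyperpriors. Each trial's choice
#' likelihood is the lapse-and-bias probit rule with closed-form bias and
#' variance of the power-law observer on the diagonality axis. Sampling is by
#' adaptive Metropolis-within-Gibbs: random-walk block updates of each
#' subject's transformed parameter vector (proposal scales adapted during
#' burn-in only) and conjugate draws of the group means and variances.
#'
#' @param trials Decision trial tibble (columns `subject`, `d1`, `d2`,
#'   `choice`).
#' @param prior Orientation prior carrying the steepness `a` (the diagonality
#'   fold is applied internally).
#' @param config A [fit_config()].
#' @return An `fm_fit` object: list with `draws` (long tibble: parameter,
#'   level, chain, iteration, value on the natural scale), `rhat` (per
#'   latent), `n_retained`, `config`, and warnings about convergence or
#'   degenerate data.
#' @export
fit_hierarchical <- function(trials, prior, config = fit_config()) {
  subjects <- unique(trials$subject)
  if (length(subjects) < 2L) {
    stop_fitmax("At least 2 subjects are required for the hierarchical model.",
                "fitmax_range_error")
  }
  a <- attr(prior, "a")
  if (!is.finite(a)) stop_fitmax("Prior must be the parametric orientation prior.",
                                 "fitmax_prior_error")
  pd <- orientation_prior(a, stimulus_domain(0, 45))
  omega <- attr(pd, "omega") * 180 / pi # per-radian normalizer
  dat <- lapply(subjects, function(sj) {
    tt <- trials[trials$subject == sj, ]
    if (length(unique(tt$choice)) < 2L) {
      warn(sprintf("All choices identical for subject %s; parameters weakly identified.", sj),
           class = "fitmax_degenerate_data")
    }
    prep_subject_data(tt$d1, tt$d2, tt$choice, a, omega)
  })
  ns <- length(dat)
  npar <- 4L
  # crude pooled initialization: 1-D profile over log k at q = 1.5
  pool <- list(
    L1 = unlist(lapply(dat, `[[`, "L1")), L2 = unlist(lapply(dat, `[[`, "L2")),
    sin1 = unlist(lapply(dat, `[[`, "sin1")), sin2 = unlist(lapply(dat, `[[`, "sin2")),
    c1 = unlist(lapply(dat, `[[`, "c1")), c2 = unlist(lapply(dat, `[[`, "c2")),
    chose1 = unlist(lapply(dat, `[[`, "chose1")), omega = omega,
    d1 = unlist(lapply(dat, `[[`, "d1")), d2 = unlist(lapply(dat, `[[`, "d2"))
  )
  lks <- seq(log(1), log(5000), length.out = 40)
  prof <- vapply(lks, function(lk) subject_loglik(pool, 1.5, exp(lk), 0.02, 0),
                 numeric(1))
  lk0 <- lks[which.max(prof)]
  # stacked trial matrices (rows = trials, columns = subjects; ragged
  # sessions are padded and masked) so every proposal is scored with one
  # vectorized likelihood evaluation across the cohort
  nmax <- max(vapply(dat, `[[`, integer(1), "n"))
  stack <- function(field, fill = 0) {
    vapply(dat, function(d) c(d[[field]], rep(fill, nmax - d$n)),
           numeric(nmax))
  }
  M <- list(
    L1 = stack("L1"), L2 = stack("L2"), sin1 = stack("sin1"),
    sin2 = stack("sin2"), dd = stack("d1") - stack("d2"),
    chose1 = stack("chose1"),
    mask = vapply(dat, function(d) c(rep(1, d$n), rep(0, nmax - d$n)),
                  numeric(nmax))
  )
  nr <- nmax
  # cohort log-likelihood for per-subject parameter columns (transformed
  # scale); returns one value per subject
  ll_all <- function(th) {
    q <- exp(th[, 1]); k <- exp(th[, 2])
    lambda <- stats::plogis(th[, 3]); beta0 <- th[, 4]
    deg <- 180 / pi
    qr <- rep(q, each = nr); kr <- rep(k, each = nr)
    e1 <- exp(M$L1 * qr); e2 <- exp(M$L2 * qr)
    vsum <- deg^2 * (e1 + e2) / kr
    bfac <- rep(deg * (1 - 1 / q) * 4 * q / omega / k, each = nr)
    b1 <- bfac * M$sin1 * e1 / exp(M$L1)
    b2 <- bfac * M$sin2 * e2 / exp(M$L2)
    arg <- (M$dd + b1 - b2) / sqrt(vsum)
    p1 <- rep(lambda / 2, each = nr) +
      rep(1 - lambda, each = nr) * pnorm(arg + rep(beta0, each = nr))
    p <- ifelse(M$chose1 > 0.5, p1, 1 - p1)
    colSums(M$mask * log(pmin(pmax(p, 1e-12), 1 - 1e-12)))
  }
  # flat-on-a-box priors on the transformed scales: the lapse and bias
  # directions are likelihood-flat in their tails, and unbounded flat priors
  # would let chains drift without limit there
  box_lo <- c(-3, -5, -7, -3)
  box_hi <- c(3, 12, 2, 3)
  in_box <- function(th) {
    (th[, 1] >= box_lo[1] & th[, 1] <= box_hi[1]) &
      (th[, 2] >= box_lo[2] & th[, 2] <= box_hi[2]) &
      (th[, 3] >= box_lo[3] & th[, 3] <= box_hi[3]) &
      (th[, 4] >= box_lo[4] & th[, 4] <= box_hi[4])
  }
  ridge_slope <- 1.5 * mean(unlist(lapply(dat, function(d) c(d$L1, d$L2))))
  total_iter <- config$burnin + config$draws
  keep_iter <- seq(config$burnin + config$thin, total_iter, by = config$thin)
  all_draws <- list()
  par_names <- c("q", "k", "lambda", "beta0")
  for (chain in seq_len(config$chains)) {
    set.seed(derive_seed(config$seed, paste0("fit/chain", chain)))
    theta <- matrix(rep(c(log(1.5), lk0, stats::qlogis(0.02), 0), each = ns),
                    nrow = ns) + matrix(rnorm(ns * npar, 0, 0.15), ns)
    mu <- colMeans(theta)
    sg <- rep(0.5, npar)
    prop_sd <- matrix(0.1, ns, npar)
    am_scale <- rep(2.38^2 / npar, ns)
    cov_n <- 0
    cov_mean <- matrix(0, ns, npar)
    cov_m2 <- array(0, c(ns, npar, npar))
    glob_sd <- rep(0.05, npar + 1L)
    cur_ll <- ll_all(theta)
    kept <- array(NA_real_, dim = c(length(keep_iter), ns, npar))
    kept_mu <- matrix(NA_real_, length(keep_iter), npar)
    kept_sg <- matrix(NA_real_, length(keep_iter), npar)
    ki <- 0L
    for (it in seq_len(total_iter)) {
      adapt <- it <= config$burnin
      step <- min(0.1, 10 / sqrt(it + 10))
      # componentwise Metropolis, all subjects in parallel
      for (p in seq_len(npar)) {
        prop <- theta
        prop[, p] <- prop[, p] + rnorm(ns, 0, prop_sd[, p])
        ll_new <- ll_all(prop)
        lr <- (ll_new + dnorm(prop[, p], mu[p], sg[p], log = TRUE)) -
          (cur_ll + dnorm(theta[, p], mu[p], sg[p], log = TRUE))
        ok <- in_box(prop) & is.finite(lr) & log(runif(ns)) < lr
        theta[ok, ] <- prop[ok, , drop = FALSE]
        cur_ll[ok] <- ll_new[ok]
        if (adapt) {
          prop_sd[, p] <- pmin(pmax(prop_sd[, p] * exp(step * (ok - 0.44)),
                                    1e-3), 3)
        }
      }
      # adaptive-Metropolis block move with learned subject covariances
      # (handles the strong log q - log k likelihood ridge)
      cov_n <- cov_n + 1
      dlt <- theta - cov_mean
      cov_mean <- cov_mean + dlt / cov_n
      for (j in seq_len(ns)) {
        cov_m2[j, , ] <- cov_m2[j, , ] + outer(dlt[j, ], theta[j, ] - cov_mean[j, ])
      }
      if (cov_n > 50) {
        prop <- theta
        for (j in seq_len(ns)) {
          sig <- cov_m2[j, , ] / (cov_n - 1) + diag(1e-8, npar)
          chol_u <- tryCatch(chol(am_scale[j] * sig), error = function(e) NULL)
          if (!is.null(chol_u)) {
            prop[j, ] <- theta[j, ] + drop(rnorm(npar) %*% chol_u)
          }
        }
        ll_new <- ll_all(prop)
        lr <- (ll_new + rowSums(dnorm(prop, rep(mu, each = ns),
                                      rep(sg, each = ns), log = TRUE))) -
          (cur_ll + rowSums(dnorm(theta, rep(mu, each = ns),
                                  rep(sg, each = ns), log = TRUE)))
        ok <- in_box(prop) & is.finite(lr) & log(runif(ns)) < lr
        theta[ok, ] <- prop[ok, , drop = FALSE]
        cur_ll[ok] <- ll_new[ok]
        if (adapt) {
          am_scale <- pmin(pmax(am_scale * exp(step * (ok - 0.25)), 1e-4), 25)
        }
      }
      # collective moves: rigid translation of every subject and the group
      # mean along one coordinate, or a coupled (log q, log k) ridge shift;
      # the pooling terms cancel so only the likelihood decides. These
      # unstick cohort-level modes that individual updates cannot reach when
      # the group prior is tight.
      gm <- 1L + (it %% (npar + 1L))
      delta <- rnorm(1, 0, glob_sd[gm])
      prop <- theta
      if (gm <= npar) {
        prop[, gm] <- prop[, gm] + delta
      } else {
        prop[, 1] <- prop[, 1] + delta
        prop[, 2] <- prop[, 2] + delta * ridge_slope
      }
      if (all(in_box(prop))) {
        ll_new <- ll_all(prop)
        lr <- sum(ll_new) - sum(cur_ll)
        accepted <- is.finite(lr) && log(runif(1)) < lr
        if (accepted) {
          theta <- prop
          cur_ll <- ll_new
          if (gm <= npar) {
            mu[gm] <- mu[gm] + delta
          } else {
            mu[1] <- mu[1] + delta
            mu[2] <- mu[2] + delta * ridge_slope
          }
        }
        if (adapt) {
          glob_sd[gm] <- min(max(glob_sd[gm] * exp(step * (accepted - 0.3)),
                                 1e-4), 2)
        }
      }
      # conjugate group updates under flat hyperpriors
      mu <- rnorm(npar, colMeans(theta), sg / sqrt(ns))
      ssq <- colSums((theta - matrix(mu, ns, npar, byrow = TRUE))^2)
      sg <- sqrt(1 / rgamma(npar, shape = ns / 2, rate = ssq / 2))
      sg <- pmin(pmax(sg, 1e-3), 10)
      if (it %in% keep_iter) {
        ki <- ki + 1L
        kept[ki, , ] <- theta
        kept_mu[ki, ] <- mu
        kept_sg[ki, ] <- sg
      }
    }
    all_draws[[chain]] <- list(subj = kept, mu = kept_mu, sg = kept_sg)
  }
  n_keep <- length(keep_iter)
  to_nat <- function(m, p) switch(p, q = exp(m), k = exp(m),
                                  lambda = stats::plogis(m), beta0 = m)
  rows <- list()
  for (cid in seq_len(config$chains)) {
    dr <- all_draws[[cid]]
    for (p in seq_len(npar)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = par_names[p], level = "group_mean", chain = cid,
        iteration = seq_len(n_keep),
        value = to_nat(dr$mu[, p], par_names[p]),
        transformed = dr$mu[, p]
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = par_names[p], level = "group_sd", chain = cid,
        iteration = seq_len(n_keep), value = dr$sg[, p],
        transformed = log(dr$sg[, p])
      )
      for (j in seq_len(ns)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          parameter = par_names[p], level = subjects[j], chain = cid,
          iteration = seq_len(n_keep),
          value = to_nat(dr$subj[, j, p], par_names[p]),
          transformed = dr$subj[, j, p]
        )
      }
    }
  }
  draws <- dplyr::bind_rows(rows)
  rhat <- draws |>
    dplyr::group_by(.data$parameter, .data$level) |>
    dplyr::group_modify(function(d, key) {
      m <- matrix(d$transformed, ncol = config$chains)
      tibble::tibble(rhat = gelman_rubin(m))
    }) |>
    dplyr::ungroup()
  conv_warn <- any(rhat$rhat >= 1.05, na.rm = TRUE)
  if (conv_warn) {
    warn(sprintf("Gelman-Rubin diagnostic at or above 1.05 for %d latent(s).",
                 sum(rhat$rhat >= 1.05, na.rm = TRUE)),
         class = "fitmax_convergence")
  }
  structure(
    list(draws = draws, rhat = rhat, n_retained = n_keep * config$chains,
         config = config, subjects = subjects, converged = !conv_warn),
    class = "fm_fit"
  )
}

#' @export
print.fm_fit <- function(x, ...) {
  cat(sprintf(
    "<hierarchical fit: %d subjects, %d retained draws, max Rhat = %.3f>\n",
    length(x$subjects), x$n_retained, max(x$rhat$rhat, na.rm = TRUE)
  ))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic (non-split, non-rank-normalized) PSRF:
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}} with `W` the mean
#' within-chain variance and `B` the between-chain variance of the chain
#' means. Chains with zero between-chain variance (e.g. identical sequences)
#' give \eqn{\hat R = 1}.
#'
#' @param draws Matrix of draws, iterations in rows, chains in columns (at
#'   least 2 chains).
#' @return The scalar \eqn{\hat R}.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) {
    stop_fitmax("At least 2 chains are required.", "fitmax_range_error")
  }
  nn <- nrow(draws)
  means <- colMeans(draws)
  w <- mean(apply(draws, 2, var))
  b <- nn * var(means)
  if (b == 0) return(1)
  if (w == 0) return(Inf)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Two-sided posterior probability of a contrast
#'
#' One minus the posterior probability that the contrast is greater (or less)
#' than zero — the MCMC analogue of a two-sided p-value.
#'
#' @param draws Numeric vector of posterior draws of a scalar contrast.
#' @return \eqn{1 - \max(P(>0), P(<0))}.
#' @export
posterior_prob <- function(draws) {
  1 - max(mean(draws > 0), mean(draws < 0))
}

#' Exhaustive grid point estimates (sampler oracle)
#'
#' Evaluates the choice log-likelihood on a full factorial grid over
#' (q, k, lambda, beta0) and returns the per-subject and pooled argmax. Used
#' as a brute-force check of the MCMC fitter on dense data.
#'
#' @inheritParams fit_hierarchical
#' @param q_grid,k_grid,lambda_grid,beta0_grid Numeric grids.
#' @return A list with `by_subject` (tibble of argmax rows) and `pooled`.
#' @export
map_grid_fit <- function(trials, prior, q_grid, k_grid, lambda_grid = 0,
                         beta0_grid = 0) {
  a <- attr(prior, "a")
  pd <- orientation_prior(a, stimulus_domain(0, 45))
  omega <- attr(pd, "omega") * 180 / pi
  grid <- expand.grid(q = q_grid, k = k_grid, lambda = lambda_grid,
                      beta0 = beta0_grid)
  subjects <- unique(trials$subject)
  ll_mat <- matrix(NA_real_, nrow(grid), length(subjects))
  for (j in seq_along(subjects)) {
    tt <- trials[trials$subject == subjects[j], ]
    dd <- prep_subject_data(tt$d1, tt$d2, tt$choice, a, omega)
    ll_mat[, j] <- vapply(seq_len(nrow(grid)), function(i) {
      subject_loglik(dd, grid$q[i], grid$k[i], grid$lambda[i], grid$beta0[i])
    }, numeric(1))
  }
  by_subject <- dplyr::bind_rows(lapply(seq_along(subjects), function(j) {
    i <- which.max(ll_mat[, j])
    tibble::tibble(subject = subjects[j], q = grid$q[i], k = grid$k[i],
                   lambda = grid$lambda[i], beta0 = grid$beta0[i],
                   loglik = ll_mat[i, j])
  }))
  ip <- which.max(rowSums(ll_mat))
  list(
    by_subject = by_subject,
    pooled = tibble::tibble(q = grid$q[ip], k = grid$k[ip],
                            lambda = grid$lambda[ip], beta0 = grid$beta0[ip],
                            loglik = sum(ll_mat[ip, ]))
  )
}

#' Posterior draws of a group-level parameter
#'
#' @param fit An `fm_fit`.
#' @param parameter One of `"q"`, `"k"`, `"lambda"`, `"beta0"`.
#' @param level Level name (default `"group_mean"`).
#' @return Numeric vector of draws on the natural scale.
#' @export
group_draws <- function(fit, parameter, level = "group_mean") {
  d <- fit$draws
  d$value[d$parameter == parameter & d$level == level]
}
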