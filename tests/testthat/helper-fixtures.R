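# shared fixtures, built in code at load time

unit_dom <- function(n = 513L) stimulus_domain(0, 1, n_grid = n)

uniform_prior <- function(n = 513L) {
  prior_from_density(unit_dom(n), function(s) rep(1, length(s)))
}

# density 1.6 on [0, 0.5], 0.4 on [0.5, 1]
piecewise_prior <- function(n = 1025L) {
  prior_from_density(unit_dom(n), function(s) ifelse(s <= 0.5, 1.6, 0.4))
}

orient_prior <- function(n = 512L) {
  orientation_prior(domain = stimulus_domain(0, 180, circular = TRUE, n_grid = n))
}

diag_prior <- function(n = 512L) {
  orientation_prior(domain = stimulus_domain(0, 45, n_grid = n))
}

linear_reward <- function(domain) {
  reward_map(domain, "linear", intercept = 0, slope = 1)
}

# Monte-Carlo loss of a quantized code: pairs drawn from the prior, fair-coin
# tie-break within a level (independent oracle for the loss quadratures)
mc_code_loss <- function(prior, code, n_pairs, reward = NULL, seed = 42) {
  set.seed(seed)
  s1 <- sample_stimuli(prior, n_pairs)
  s2 <- sample_stimuli(prior, n_pairs)
  edges <- c(-Inf, code$boundaries, Inf)
  l1 <- findInterval(s1, edges)
  l2 <- findInterval(s2, edges)
  same <- l1 == l2
  if (is.null(reward)) {
    x <- same * 0.5
  } else {
    x <- same * 0.5 * abs(reward_at(reward, s1) - reward_at(reward, s2))
  }
  list(mean = mean(x), se = sd(x) / sqrt(n_pairs))
}

trapz_ <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
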