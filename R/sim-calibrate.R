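# Calibration of the latent affect slope against the observed 0..K scale.
#
# The generator injects a *standardized* within-person effect b: the slope of
# the daily-mean ordinal affect outcome on person-centered log exposure, in SD
# units of both, after round-and-clip discretization. Discretization attenuates
# a latent linear slope, so the latent slope is root-found such that the
# induced observed-scale standardized slope equals the target. All moments are
# closed-form normal-bin sums integrated over stratified normal quadrature; no
# simulation is involved, so calibration is deterministic.

# E[X] and E[X^2] for X = round(clip(u, 0, K)), u ~ N(mu, sig_e); vectorized
# over mu. Uses P(X >= k) = P(u >= k - 1/2): E[X] = sum_k P(X >= k),
# E[X^2] = sum_k (2k - 1) P(X >= k).
clip_round_moments <- function(mu, sig_e, K) {
  s <- max(sig_e, 1e-9)
  g <- 0; h <- 0
  for (k in seq_len(K)) {
    p <- pnorm((mu - (k - 0.5)) / s)
    g <- g + p
    h <- h + (2 * k - 1) * p
  }
  list(mean = g, second = h)
}

# Population moments of the daily-mean outcome y under the generator's model:
# y = mean over n_prompts of round(clip(a + beta*z + e)), a ~ N(mu_a, sig_a^2),
# z ~ N(0, sd_z^2) person-centered exposure, e ~ N(0, sig_e^2) per prompt.
observed_scale_moments <- function(beta, mu_a, sig_a, sig_e, sd_z, K,
                                   n_prompts, nq = 161L) {
  u <- (seq_len(nq) - 0.5) / nq
  q <- qnorm(u)
  A <- rep(q, times = nq)
  Z <- rep(q, each = nq)
  zval <- sd_z * Z
  m <- mu_a + sig_a * A + beta * zval
  mom <- clip_round_moments(m, sig_e, K)
  Ey <- mean(mom$mean)
  cov_yz <- mean(mom$mean * zval)        # E[z] = 0
  var_g <- mean(mom$mean^2) - Ey^2
  prompt_noise <- mean(mom$second - mom$mean^2) / n_prompts
  vy <- max(var_g + prompt_noise, 1e-12)
  slope <- if (sd_z > 0) cov_yz / sd_z^2 else 0
  list(slope = slope, sd_y = sqrt(vy), mean_y = Ey)
}

# Root-find the latent slope achieving standardized observed slope b_target.
calibrate_within_slope <- function(b_target, mu_a, sig_a, sig_e, sd_z, K,
                                   n_prompts) {
  std_of <- function(beta) {
    mom <- observed_scale_moments(beta, mu_a, sig_a, sig_e, sd_z, K, n_prompts)
    list(std = mom$slope * sd_z / mom$sd_y, mom = mom)
  }
  if (b_target == 0 || sd_z <= 0) {
    mom <- observed_scale_moments(0, mu_a, sig_a, sig_e, sd_z, K, n_prompts)
    return(list(beta_latent = 0, beta_observed = 0, b_target = b_target,
                sd_y = mom$sd_y, sd_z = sd_z))
  }
  f <- function(beta) std_of(beta)$std - b_target
  hi <- sign(b_target) * max(1, abs(b_target)) / sd_z
  it <- 0
  while (f(hi) * f(0) > 0) {
    hi <- hi * 2; it <- it + 1
    if (it > 40) stop("cannot achieve requested standardized effect")
  }
  root <- uniroot(f, sort(c(0, hi)), tol = 1e-8)$root
  res <- std_of(root)
  list(beta_latent = root, beta_observed = res$mom$slope, b_target = b_target,
       sd_y = res$mom$sd_y, sd_z = sd_z)
}

# Memoized per-config calibration (keyed on all inputs) so repeated cohort
# simulation at one configuration calibrates once.
.calib_cache <- new.env(parent = emptyenv())

calibrate_cached <- function(b_target, mu_a, sig_a, sig_e, sd_z, K, n_prompts) {
  key <- paste(format(c(b_target, mu_a, sig_a, sig_e, sd_z, K, n_prompts),
                      digits = 12), collapse = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- calibrate_within_slope(b_target, mu_a, sig_a, sig_e, sd_z, K, n_prompts)
  .calib_cache[[key]] <- out
  out
}

# One ordinal response per row of the latent-location vector m.
sample_responses <- function(m, sig_e, K) {
  u <- m + rnorm(length(m), 0, sig_e)
  as.integer(round(pmin(K, pmax(0, u))))
}
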