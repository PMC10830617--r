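# Shared fixtures and independent oracles, all built in code at test time.

# two-component log-time sample with configurable separation (in SD units)
two_component_sample <- function(n, d, sd = 0.3, prop_low = 0.5, seed = 1) {
  set.seed(seed)
  z <- stats::rbinom(n, 1, prop_low)
  x <- stats::rnorm(n, mean = ifelse(z == 1, 0, d * sd), sd = sd)
  list(x = x, z = z)
}

# independent dense grid search over (mu, sigma, pi) maximizing the weighted
# Gaussian-mixture log-likelihood; used as an oracle for C = 1, 2 on tiny n
grid_gmm_loglik <- function(x, w = rep(1, length(x)), n_components,
                            n_mu = 40, n_sd = 15, n_pi = 19) {
  mus <- seq(min(x), max(x), length.out = n_mu)
  sds <- seq(max(stats::sd(x) / 20, 0.01), stats::sd(x) * 1.5,
             length.out = n_sd)
  pars <- expand.grid(mu = mus, sd = sds)
  D <- sapply(seq_len(nrow(pars)),
              function(i) stats::dnorm(x, pars$mu[i], pars$sd[i]))
  if (n_components == 1) {
    return(max(colSums(w * log(pmax(D, 1e-300)))))
  }
  stopifnot(n_components == 2)
  pis <- seq(0.05, 0.95, length.out = n_pi)
  best <- -Inf
  for (i in seq_len(nrow(pars))) {
    for (p in pis) {
      mix <- p * D[, i] + (1 - p) * D
      ll <- colSums(w * log(pmax(mix, 1e-300)))
      m <- max(ll)
      if (m > best) best <- m
    }
  }
  best
}

# simulate responses from a known GPCM (generating side of recovery tests)
simulate_gpcm_responses <- function(items, group, group_means, group_sds,
                                    seed = 1) {
  set.seed(seed)
  N <- length(group)
  theta <- stats::rnorm(N, group_means[group], group_sds[group])
  Y <- sapply(seq_along(items), function(j) {
    pr <- gpcm_category_probs(items[[j]]$discrimination,
                              items[[j]]$step_difficulties, theta)
    max.col(stats::runif(N) < t(apply(pr, 1, cumsum)), "first") - 1L
  })
  Y
}

random_gpcm_items <- function(J, K, seed = 1) {
  set.seed(seed)
  lapply(seq_len(J), function(j) {
    list(discrimination = exp(stats::rnorm(1, 0, 0.2)),
         step_difficulties = sort(stats::rnorm(K, 0, 0.8)))
  })
}

# small screen-record data.frame for IO tests
tiny_screen_records <- function() {
  data.frame(
    respondent_id = c("r1", "r2", "r3"),
    group_id = "G01",
    scale_id = "S01",
    time_seconds = c(16, 60, 8),
    n_items = 4L,
    sampling_weight = 1,
    stringsAsFactors = FALSE
  )
}
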