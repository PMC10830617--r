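# Hierarchical Beta regression: link prediction, Beta log-density, the two
# estimation routes, and the split-Rhat diagnostic.

test_that("mean prediction is the inverse-logit of the linear predictor", {
  expect_equal(predict_cier_mean(0, numeric(0), numeric(0)), 0.5)
  expect_equal(predict_cier_mean(1, c(2, -1), c(0.5, 1)), plogis(1))
  # strictly increasing in a covariate with positive slope
  slope <- c(0.021, 0.016)
  vals <- vapply(seq(10, 90, by = 10), function(p)
    predict_cier_mean(-4.2, slope, c(p, 10)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(predict_cier_mean(0, c(1, 2), 1),
               class = "attweights_error_input")
  expect_error(predict_cier_mean(Inf, 1, 1),
               class = "attweights_error_input")
})

test_that("Beta log-density matches closed forms and integrates to 1", {
  # mu = 1/2, phi = 2 is Beta(1,1): log density 0 everywhere
  expect_equal(beta_loglik(0.5, 2, c(0.1, 0.5, 0.93)), rep(0, 3))
  # mu = 1/2, phi = 4 is Beta(2,2): density 6 y (1-y)
  expect_equal(beta_loglik(0.5, 4, 0.5), log(1.5))
  ys <- c(0.2, 0.8)
  expect_equal(beta_loglik(0.5, 4, ys), log(6 * ys * (1 - ys)))
  # matches an independent numeric evaluation of the Beta density on a grid
  grid <- seq(0.05, 0.95, by = 0.05)
  mu <- 0.3; phi <- 11
  manual <- (mu * phi - 1) * log(grid) +
    ((1 - mu) * phi - 1) * log(1 - grid) - lbeta(mu * phi, (1 - mu) * phi)
  expect_equal(beta_loglik(mu, phi, grid), manual, tolerance = 1e-10)
  expect_equal(
    integrate(function(y) exp(beta_loglik(0.37, 9, y)), 0, 1)$value, 1,
    tolerance = 1e-6)
  expect_error(beta_loglik(0.5, 2, 0), class = "attweights_error_input")
  expect_error(beta_loglik(0.5, 2, 1), class = "attweights_error_input")
  expect_error(beta_loglik(1.2, 2, 0.5), class = "attweights_error_input")
})

test_that("boundary proportions are pulled inside the open interval", {
  y <- c(0, 0.2, 1)
  adj <- adjust_proportions(y)
  expect_true(all(adj > 0 & adj < 1))
  expect_equal(adjust_proportions(0.5, 101), 0.5)
})

test_that("split-Rhat diagnoses convergence", {
  set.seed(6)
  draws <- rnorm(500)
  expect_lt(psrf(list(draws, draws)), 1.01)             # identical chains
  expect_gt(psrf(list(rnorm(500), rnorm(500, 5))), 2)   # disjoint chains
  # one stationary chain split in half
  long <- rnorm(1000)
  expect_lt(psrf(list(long[1:500], long[501:1000])), 1.05)
  # matrix input, one column per chain
  expect_lt(psrf(cbind(rnorm(400), rnorm(400))), 1.05)
  r <- psrf(list(rep(1, 100), rep(1, 100)))
  expect_true(is.na(r))
  expect_error(psrf(list(rnorm(100))), class = "attweights_error_input")
})

make_beta_fixture <- function(G = 30, S = 40, sigma = 0.4, seed = 1) {
  set.seed(seed)
  pos <- rep(seq(21, 80, length.out = S), times = G)
  grp <- rep(seq_len(G), each = S)
  b_g <- rnorm(G, 0, sigma)
  eta <- -3 + 0.02 * pos + b_g[grp]
  mu <- plogis(eta)
  list(y = rbeta(G * S, mu * 25, (1 - mu) * 25), grp = grp,
       X = matrix(pos, ncol = 1, dimnames = list(NULL, "position")),
       b_g = b_g)
}

test_that("ML route recovers the generating parameters", {
  fx <- make_beta_fixture(seed = 101)
  ml <- suppressWarnings(
    fit_hierarchical_beta(fx$y, fx$grp, fx$X, method = "ml"))
  expect_true(ml$converged)
  expect_lt(abs(ml$coefficients["intercept"] + 3) / 3, 0.25)
  expect_lt(abs(ml$coefficients["position"] - 0.02) / 0.02, 0.25)
  expect_lt(abs(ml$precision - 25) / 25, 0.25)
  expect_lt(abs(ml$random_intercept_sd - 0.4) / 0.4, 0.5)
  # the SD estimate tracks the realized spread of the drawn intercepts
  expect_lt(abs(ml$random_intercept_sd - sd(fx$b_g)) / sd(fx$b_g), 0.25)
})

test_that("Bayesian route converges and agrees with ML within uncertainty", {
  fx <- make_beta_fixture(seed = 101)
  bay <- fit_hierarchical_beta(fx$y, fx$grp, fx$X, method = "bayes",
                               seed = 7)
  expect_true(bay$convergence_ok)
  expect_true(all(bay$psrf < 1.05, na.rm = TRUE))
  post_sd <- apply(bay$draws, 2, sd)
  ml <- suppressWarnings(
    fit_hierarchical_beta(fx$y, fx$grp, fx$X, method = "ml"))
  # EAPs recover the truth up to the data's own sampling error: they sit no
  # farther from the generating values than the same data's MLE, plus
  # posterior slack (the realized dataset, not the sampler, sets the floor)
  expect_lt(abs(bay$coefficients["intercept"] + 3),
            abs(ml$coefficients["intercept"] + 3) + 2 * post_sd["mu_b0"])
  expect_lt(abs(bay$coefficients["position"] - 0.02),
            abs(ml$coefficients["position"] - 0.02) + 2 * post_sd["position"])
  expect_lt(abs(bay$coefficients["intercept"] - ml$coefficients["intercept"]),
            2 * (post_sd["mu_b0"] + ml$se["intercept"]))
  expect_lt(abs(bay$coefficients["position"] - ml$coefficients["position"]),
            2 * (post_sd["position"] + ml$se["position"]))
})

test_that("a degenerate hierarchy collapses to the non-hierarchical fit", {
  # sigma generated as 0; wider per-group design chosen so the noise floor
  # of the SD estimate sits well below the 0.05 check
  fx <- make_beta_fixture(S = 120, sigma = 0, seed = 202)
  ml <- suppressWarnings(
    fit_hierarchical_beta(fx$y, fx$grp, fx$X, method = "ml"))
  expect_lte(ml$random_intercept_sd, 0.05)
  # independent non-hierarchical Beta regression on the pooled data
  negll <- function(par) {
    mu <- plogis(par[1] + par[2] * fx$X[, 1])
    -sum(dbeta(fx$y, mu * exp(par[3]), (1 - mu) * exp(par[3]), log = TRUE))
  }
  flat <- optim(c(qlogis(mean(fx$y)), 0, log(10)), negll, method = "BFGS",
                control = list(reltol = 1e-12))
  expect_lt(abs(ml$coefficients["intercept"] - flat$par[1]), 0.02)
  expect_lt(abs(ml$coefficients["position"] - flat$par[2]), 0.02)
})

test_that("input validation rejects malformed regression data", {
  expect_error(fit_hierarchical_beta(c(0.1, 0.2), c(1, 1),
                                     matrix(1:2, 2, 1)),
               class = "attweights_error_input")
  expect_error(fit_hierarchical_beta(runif(6), rep(1:2, 3),
                                     matrix(1, 5, 1)),
               class = "attweights_error_input")
})
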