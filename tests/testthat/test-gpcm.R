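# Weighted multi-group GPCM: category probabilities, pseudo-likelihood
# objective, MML-EM estimation, and the adjusted/unadjusted comparison.

test_that("category probabilities match hand-evaluated cases and sum to 1", {
  expect_equal(drop(gpcm_category_probs(1, 0, 0)), c(0.5, 0.5))
  expect_equal(drop(gpcm_category_probs(0, c(0.3, -0.7), 1.2)),
               rep(1 / 3, 3))
  # a=1, b=(-1,1), theta=0: cumulative numerators exp(0), exp(1(0-(-1))),
  # exp(1(0-(-1)) + 1(0-1)) = exp(0), exp(1), exp(0)
  p <- drop(gpcm_category_probs(1, c(-1, 1), 0))
  expect_equal(p, c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.2119, 0.5761, 0.2119))
  # extreme theta: log-space evaluation stays finite and normalized
  grid <- seq(-6, 6, length.out = 61)
  P <- gpcm_category_probs(2.5, c(-1, 0, 1), c(grid, -50, 50))
  expect_true(all(is.finite(P)))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
})

test_that("weighted marginal log-likelihood reduces to known values", {
  items <- list(list(discrimination = 0, step_difficulties = 0))
  groups <- data.frame(mean = 0, sd = 1)
  y <- matrix(1L, 1, 1)
  # a = 0, K = 1: both categories probability 0.5 at any theta
  expect_equal(weighted_marginal_loglik(items, groups, y, 1L), log(0.5))

  items <- random_gpcm_items(3, 2, seed = 2)
  Y <- simulate_gpcm_responses(items, rep(1L, 60), 0, 1, seed = 3)
  groups <- data.frame(mean = 0, sd = 1)
  g <- rep(1L, 60)
  ll1 <- weighted_marginal_loglik(items, groups, Y, g)
  # all weights 1 equals the unweighted objective; doubling one respondent's
  # weight equals duplicating that respondent
  ll_dup <- weighted_marginal_loglik(items, groups, Y[c(1:60, 7), ],
                                     c(g, 1L))
  w <- rep(1, 60); w[7] <- 2
  expect_equal(weighted_marginal_loglik(items, groups, Y, g, w), ll_dup)
  # missing responses are skipped in the product
  Y2 <- Y; Y2[5, ] <- NA
  ll_m <- weighted_marginal_loglik(items, groups, Y2, g)
  expect_equal(ll_m, ll1 - (ll1 - weighted_marginal_loglik(
    items, groups, Y[-5, , drop = FALSE], g[-5])) , tolerance = 1e-10)
  expect_error(weighted_marginal_loglik(items, groups, Y, g, rep(0, 60)),
               class = "attweights_error_input")
  expect_error(weighted_marginal_loglik(items, groups, Y, g,
                                        n_quadrature = 11),
               class = "attweights_error_input")
})

test_that("multi-group parameters are recovered from simulated data", {
  items <- random_gpcm_items(6, 3, seed = 42)
  N <- 3000
  group <- rep(1:2, each = N / 2)
  Y <- simulate_gpcm_responses(items, group, c(0, 0.5), c(1, 1.2), seed = 42)
  fit <- fit_multigroup_gpcm(Y, group)
  expect_true(fit$converged)
  a_err <- vapply(1:6, function(j)
    fit$items[[j]]$discrimination - items[[j]]$discrimination, numeric(1))
  b_err <- unlist(lapply(1:6, function(j)
    fit$items[[j]]$step_difficulties - items[[j]]$step_difficulties))
  expect_lt(sqrt(mean(a_err^2)), 0.15)
  expect_lt(sqrt(mean(b_err^2)), 0.15)
  expect_lt(abs(fit$groups$mean[2] - 0.5), 0.08)
  expect_equal(fit$groups$mean[1], 0)
  expect_equal(fit$groups$sd[1], 1)
  # EM monotonicity with numerical slack
  expect_true(all(diff(fit$loglik_trace) >= -1e-9 * abs(fit$loglik)))
})

test_that("EM solution matches a direct optimization of the weighted objective", {
  # identified binary instance: 4 items, 1 step each, one group
  items <- random_gpcm_items(4, 1, seed = 9)
  N <- 200
  group <- rep(1L, N)
  Y <- simulate_gpcm_responses(items, group, 0, 1, seed = 10)
  set.seed(11)
  w <- runif(N, 0.5, 1.5)
  fit <- fit_multigroup_gpcm(Y, group, weights = w, tol = 1e-8)

  # independent route: generic quasi-Newton on the same pseudo-likelihood
  negll <- function(par) {
    its <- lapply(1:4, function(j) list(discrimination = par[j],
                                        step_difficulties = par[4 + j]))
    -weighted_marginal_loglik(its, data.frame(mean = 0, sd = 1), Y, group, w)
  }
  opt <- optim(c(rep(1, 4), rep(0, 4)), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  a_hat <- vapply(fit$items, `[[`, numeric(1), "discrimination")
  b_hat <- vapply(fit$items, function(i) i$step_difficulties, numeric(1))
  expect_equal(unname(c(a_hat, b_hat)), unname(opt$par), tolerance = 1e-3)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("weighting invariances hold", {
  items <- random_gpcm_items(4, 2, seed = 14)
  N <- 400
  group <- rep(1:2, each = N / 2)
  Y <- simulate_gpcm_responses(items, group, c(0, 0.3), c(1, 1.1), seed = 15)
  set.seed(16)
  w <- runif(N, 0.2, 2)
  f1 <- fit_multigroup_gpcm(Y, group, weights = w)
  f2 <- fit_multigroup_gpcm(Y, group, weights = 3.7 * w)
  expect_equal(f1$groups, f2$groups, tolerance = 1e-6)
  expect_equal(f1$items, f2$items, tolerance = 1e-6)
  expect_equal(f2$loglik, 3.7 * f1$loglik, tolerance = 1e-8)

  # zero weights exclude rows exactly
  w0 <- rep(1, N); w0[1:80] <- 0
  f_w0 <- fit_multigroup_gpcm(Y, group, weights = w0)
  f_sub <- fit_multigroup_gpcm(Y[-(1:80), ], group[-(1:80)])
  expect_equal(f_w0$groups, f_sub$groups, tolerance = 1e-4)
  expect_equal(vapply(f_w0$items, `[[`, numeric(1), "discrimination"),
               vapply(f_sub$items, `[[`, numeric(1), "discrimination"),
               tolerance = 1e-4)
})

test_that("degenerate inputs are handled: empty groups, all-missing rows, unseen categories", {
  items <- random_gpcm_items(3, 2, seed = 20)
  Y <- simulate_gpcm_responses(items, rep(1L, 120), 0, 1, seed = 20)
  expect_error(fit_multigroup_gpcm(Y, rep(2L, 120)),
               class = "attweights_error_input")
  Y2 <- Y; Y2[3, ] <- NA
  fit <- fit_multigroup_gpcm(Y2, rep(1L, 120))
  expect_equal(fit$dropped_rows, 3L)
  # collapse an unobserved middle category
  Y3 <- Y; Y3[Y3 == 1L] <- 2L
  expect_message(fit3 <- fit_multigroup_gpcm(Y3, rep(1L, 120)), "collapsed")
  expect_true(all(vapply(fit3$items, function(i)
    length(i$step_difficulties), integer(1)) == 1L))
})

test_that("attentiveness weighting reduces contamination bias in group means", {
  # 20% uniform-random responders in group 2 drag its estimated mean toward
  # the scale centre; near-zero attentiveness weights on those rows must
  # shrink the error. The design (N, J, group-2 mean) is sized so the
  # contamination bias is ~4 sampling SDs — see the methods vignette.
  items <- random_gpcm_items(6, 2, seed = 30)
  N <- 1200
  group <- rep(1:2, each = N / 2)
  true_mu2 <- 1.8
  wins <- vapply(1:6, function(r) {
    Y <- simulate_gpcm_responses(items, group, c(0, true_mu2), c(1, 1),
                                 seed = 300 + r)
    set.seed(600 + r)
    bad <- which(group == 2)[runif(N / 2) < 0.2]
    Y[bad, ] <- matrix(sample(0:2, length(bad) * 6, TRUE), length(bad), 6)
    w_att <- rep(1, N); w_att[bad] <- 1e-3
    f_un <- fit_multigroup_gpcm(Y, group)
    f_ad <- fit_multigroup_gpcm(Y, group, weights = w_att)
    abs(f_ad$groups$mean[2] - true_mu2) < abs(f_un$groups$mean[2] - true_mu2)
  }, logical(1))
  expect_gte(sum(wins), 5)
})

test_that("fit comparison reports per-group differences and their median", {
  items <- random_gpcm_items(3, 2, seed = 40)
  group <- rep(1:3, each = 100)
  Y <- simulate_gpcm_responses(items, group, c(0, 0.4, -0.3), c(1, 1, 1.2),
                               seed = 41)
  f1 <- fit_multigroup_gpcm(Y, group)
  cmp_same <- compare_fits(f1, f1)
  expect_equal(cmp_same$table$diff_mean, rep(0, 3))
  expect_equal(cmp_same$median_abs_diff_mean, 0)
  expect_equal(cmp_same$median_abs_diff_var, 0)

  set.seed(42)
  f2 <- fit_multigroup_gpcm(Y, group, weights = runif(300, 0.2, 1))
  cmp <- compare_fits(f2, f1)
  expect_equal(cmp$table$diff_mean, f2$groups$mean - f1$groups$mean)
  expect_equal(cmp$median_abs_diff_mean,
               median(abs(f2$groups$mean - f1$groups$mean)))
  expect_error(compare_fits(f1, list(items = f1$items[1:2],
                                     groups = f1$groups)),
               class = "attweights_error_input")
})
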