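# Hierarchical random-intercept Beta regression of group x scale C/IER
# proportions on scale characteristics. The mean is modelled on the logit
# scale with a group-specific random intercept,
#   y_sg ~ Beta(mu_sg * phi, (1 - mu_sg) * phi),
#   logit(mu_sg) = mu_b0 + b_g + sum_p beta_p x_ps,  b_g ~ N(0, sigma_b0^2).
# Two estimation routes: random-walk Metropolis-within-Gibbs with the
# diffuse priors used for this model class (N(0,10) on fixed effects,
# half-Cauchy(0,5) on sigma_b0 and phi), and a fast maximum-likelihood
# route marginalizing the random intercepts by adaptive Gauss-Hermite
# quadrature.

#' Expected C/IER proportion from fixed effects
#'
#' Inverse-logit of the fixed-effects linear predictor,
#' \eqn{\mu = \exp(\eta)/(1+\exp(\eta))} with
#' \eqn{\eta = \beta_0 + \sum_p \beta_p x_p}.
#'
#' @param intercept fixed intercept (e.g., the posterior mean of
#'   \eqn{\mu_{\beta_0}}).
#' @param slopes numeric vector of regression weights.
#' @param covariates numeric vector of covariate values aligned with
#'   \code{slopes}.
#' @return expected proportion in (0, 1).
#' @examples
#' predict_cier_mean(0, numeric(0), numeric(0))  # 0.5
#' @export
predict_cier_mean <- function(intercept, slopes, covariates) {
  if (length(slopes) != length(covariates)) {
    aw_stop("slopes and covariates must align", "attweights_error_input")
  }
  if (!all(is.finite(c(intercept, slopes, covariates)))) {
    aw_stop("inputs must be finite", "attweights_error_input")
  }
  stats::plogis(intercept + sum(slopes * covariates))
}

#' Beta log-density in mean/precision parameterization
#'
#' Log density of \eqn{\mathrm{Beta}(\mu\phi, (1-\mu)\phi)} at \eqn{y}.
#'
#' @param mu mean in (0, 1).
#' @param phi precision > 0.
#' @param y observed proportion strictly inside (0, 1); boundary values are
#'   an error — adjust them first (see \code{\link{adjust_proportions}}).
#' @return log density (vectorized over any argument).
#' @export
beta_loglik <- function(mu, phi, y) {
  if (any(y <= 0 | y >= 1)) {
    aw_stop("y must lie strictly inside (0, 1); adjust boundary proportions first",
            "attweights_error_input")
  }
  if (any(mu <= 0 | mu >= 1) || any(phi <= 0)) {
    aw_stop("mu must be in (0, 1) and phi > 0", "attweights_error_input")
  }
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

#' Pull boundary proportions into the open interval
#'
#' Standard Beta-regression adjustment \eqn{(y(n-1)+1/2)/n} applied to all
#' values, harmless for interior proportions at large \eqn{n} and required
#' for exact 0/1 from the mixture step.
#'
#' @param y proportions in \eqn{[0, 1]}.
#' @param n sample size behind the proportions (default \code{length(y)}).
#' @return proportions strictly inside (0, 1).
#' @export
adjust_proportions <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

# log prior pieces
lp_normal <- function(x, sd = 10) sum(stats::dnorm(x, 0, sd, log = TRUE))
lp_half_cauchy <- function(x, scale = 5) {
  # density 2/(pi*scale*(1+(x/scale)^2)) on x > 0
  sum(log(2) - log(pi * scale) - log1p((x / scale)^2))
}

#' Fit the hierarchical Beta regression
#'
#' @param proportions C/IER proportions per group x scale cell; values at 0
#'   or 1 are moved inside (0,1) by \code{\link{adjust_proportions}}.
#' @param group integer group index per observation.
#' @param covariates numeric matrix (observations x P) of scale
#'   characteristics; column names label the slopes.
#' @param method \code{"bayes"} (Metropolis-within-Gibbs, the default) or
#'   \code{"ml"} (marginal ML by adaptive Gauss-Hermite quadrature).
#' @param n_chains,n_iter MCMC chains and iterations per chain; the first
#'   half of each chain is warm-up (and is where proposal scales adapt).
#' @param n_nodes Gauss-Hermite nodes for the ML route.
#' @param seed integer seed.
#' @return an object of class \code{beta_regression_fit} with elements
#'   \code{coefficients} (named: intercept then slopes),
#'   \code{random_intercept_sd}, \code{precision}, \code{group_intercepts},
#'   \code{method}; for \code{"bayes"} additionally \code{draws} (pooled
#'   post-warm-up matrix), \code{psrf} per parameter and
#'   \code{convergence_ok} (all PSRF < 1.05); for \code{"ml"} additionally
#'   \code{se} (from the numeric Hessian) and \code{loglik}.
#' @export
fit_hierarchical_beta <- function(proportions, group, covariates,
                                  method = c("bayes", "ml"),
                                  n_chains = 2L, n_iter = 3000L,
                                  n_nodes = 21L, seed = 1L) {
  method <- match.arg(method)
  covariates <- as.matrix(covariates)
  n <- length(proportions)
  if (length(group) != n || nrow(covariates) != n) {
    aw_stop("proportions, group and covariates must align",
            "attweights_error_input")
  }
  group <- as.integer(factor(group))
  G <- max(group)
  if (G < 2L || nrow(unique(as.data.frame(covariates))) < 2L) {
    aw_stop("need at least 2 groups and 2 distinct scales",
            "attweights_error_input")
  }
  y <- proportions
  if (any(y <= 0 | y >= 1)) {
    y <- adjust_proportions(y, n)
  }
  P <- ncol(covariates)
  cn <- colnames(covariates) %||% paste0("x", seq_len(P))

  if (method == "ml") {
    fit <- beta_ml_fit(y, group, covariates, n_nodes, cn)
  } else {
    fit <- beta_mcmc_fit(y, group, covariates, n_chains, n_iter, seed, cn)
  }
  structure(fit, class = "beta_regression_fit")
}

# ---- maximum likelihood via adaptive Gauss-Hermite ----

beta_ml_fit <- function(y, group, X, n_nodes, cn) {
  gh <- pracma::gaussHermite(n_nodes)
  G <- max(group)
  P <- ncol(X)
  rows_g <- lapply(seq_len(G), function(g) which(group == g))

  # marginal loglik for one group given eta0 (linear predictor w/o b)
  group_ll <- function(eta0_g, y_g, sigma, phi) {
    h <- function(b) {
      mu <- stats::plogis(eta0_g + b)
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      sum(stats::dbeta(y_g, mu * phi, (1 - mu) * phi, log = TRUE)) +
        stats::dnorm(b, 0, sigma, log = TRUE)
    }
    if (sigma < 1e-6) {
      mu <- stats::plogis(eta0_g)
      return(sum(stats::dbeta(y_g, mu * phi, (1 - mu) * phi, log = TRUE)))
    }
    opt <- stats::optimize(h, interval = c(-6 * sigma - 1, 6 * sigma + 1),
                           maximum = TRUE)
    bhat <- opt$maximum
    eps <- 1e-4
    d2 <- (h(bhat + eps) - 2 * h(bhat) + h(bhat - eps)) / eps^2
    shat <- 1 / sqrt(max(-d2, 1 / (10 * sigma)^2))
    bq <- bhat + sqrt(2) * shat * gh$x
    lv <- vapply(bq, h, numeric(1)) + gh$x^2 + log(gh$w)
    mx <- max(lv)
    mx + log(sum(exp(lv - mx))) + 0.5 * log(2) + log(shat)
  }

  negll <- function(par) {
    beta0 <- par[1L]
    beta <- par[1L + seq_len(P)]
    sigma <- exp(par[P + 2L])
    phi <- exp(par[P + 3L])
    if (!all(is.finite(c(sigma, phi))) || phi > 1e8) return(1e10)
    eta0 <- beta0 + drop(X %*% beta)
    ll <- sum(vapply(seq_len(G), function(g) {
      group_ll(eta0[rows_g[[g]]], y[rows_g[[g]]], sigma, phi)
    }, numeric(1)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start <- c(stats::qlogis(mean(y)), rep(0, P), log(0.3), log(10))
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10),
                      hessian = TRUE)
  par <- opt$par
  se <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e) rep(NA_real_, length(par)))
  beta0 <- par[1L]
  beta <- par[1L + seq_len(P)]
  sigma <- exp(par[P + 2L])
  phi <- exp(par[P + 3L])
  # empirical Bayes modes for the group intercepts
  eta0 <- beta0 + drop(X %*% beta)
  b_g <- vapply(seq_len(G), function(g) {
    if (sigma < 1e-6) return(0)
    stats::optimize(function(b) {
      mu <- stats::plogis(eta0[rows_g[[g]]] + b)
      sum(stats::dbeta(y[rows_g[[g]]], mu * phi, (1 - mu) * phi, log = TRUE)) +
        stats::dnorm(b, 0, sigma, log = TRUE)
    }, interval = c(-6 * sigma - 1, 6 * sigma + 1), maximum = TRUE)$maximum
  }, numeric(1))
  list(
    method = "ml",
    coefficients = stats::setNames(c(beta0, beta), c("intercept", cn)),
    random_intercept_sd = sigma,
    precision = phi,
    group_intercepts = b_g,
    se = stats::setNames(se, c("intercept", cn, "log_sigma_b0", "log_phi")),
    loglik = -opt$value,
    converged = opt$convergence == 0L
  )
}

# ---- Bayesian route: adaptive random-walk Metropolis within Gibbs ----

beta_mcmc_fit <- function(y, group, X, n_chains, n_iter, seed, cn) {
  G <- max(group)
  P <- ncol(X)
  rows_g <- lapply(seq_len(G), function(g) which(group == g))
  warmup <- floor(n_iter / 2)

  data_ll_by_group <- function(beta0, beta, b, phi) {
    eta <- beta0 + drop(X %*% beta) + b[group]
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
    vapply(rows_g, function(r) sum(ll[r]), numeric(1))
  }

  par_names <- c("mu_b0", cn, paste0("b[", seq_len(G), "]"),
                 "sigma_b0", "phi")
  chains <- vector("list", n_chains)

  for (ch in seq_len(n_chains)) {
    with_seed(derive_seed(seed, paste0("betareg-chain", ch)), {
      beta0 <- stats::qlogis(mean(y)) + stats::rnorm(1, 0, 0.5)
      beta <- stats::rnorm(P, 0, 0.05)
      b <- stats::rnorm(G, 0, 0.2)
      lsig <- log(0.3) + stats::rnorm(1, 0, 0.2)
      lphi <- log(10) + stats::rnorm(1, 0, 0.2)

      # proposal scales, adapted during warm-up toward 0.3-0.45 acceptance
      sc_fix <- rep(0.05, P + 1L)
      sc_b <- rep(0.2, G)
      sc_sig <- 0.3
      sc_phi <- 0.2
      acc <- list(fix = numeric(P + 1L), b = numeric(G), sig = 0, phi = 0)
      win <- 50L

      ll_g <- data_ll_by_group(beta0, beta, b, exp(lphi))
      draws <- matrix(NA_real_, n_iter, length(par_names))
      for (it in seq_len(n_iter)) {
        phi <- exp(lphi)
        sigma <- exp(lsig)
        ## fixed effects, single-site random walk
        for (p in 0:P) {
          prop_b0 <- beta0
          prop_be <- beta
          if (p == 0L) prop_b0 <- beta0 + stats::rnorm(1, 0, sc_fix[1L])
          else prop_be[p] <- beta[p] + stats::rnorm(1, 0, sc_fix[p + 1L])
          ll_new <- data_ll_by_group(prop_b0, prop_be, b, phi)
          lacc <- sum(ll_new) - sum(ll_g) +
            lp_normal(c(prop_b0, prop_be)) - lp_normal(c(beta0, beta))
          if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
            beta0 <- prop_b0
            beta <- prop_be
            ll_g <- ll_new
            acc$fix[p + 1L] <- acc$fix[p + 1L] + 1
          }
        }
        ## random intercepts, single-site (only the group's data enter)
        eta_base <- beta0 + drop(X %*% beta)
        for (g in seq_len(G)) {
          bp <- b[g] + stats::rnorm(1, 0, sc_b[g])
          r <- rows_g[[g]]
          mu_new <- stats::plogis(eta_base[r] + bp)
          mu_new <- pmin(pmax(mu_new, 1e-12), 1 - 1e-12)
          ll_new <- sum(stats::dbeta(y[r], mu_new * phi,
                                     (1 - mu_new) * phi, log = TRUE))
          lacc <- ll_new - ll_g[g] +
            stats::dnorm(bp, 0, sigma, log = TRUE) -
            stats::dnorm(b[g], 0, sigma, log = TRUE)
          if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
            b[g] <- bp
            ll_g[g] <- ll_new
            acc$b[g] <- acc$b[g] + 1
          }
        }
        ## translation along the intercept/random-intercept ridge: shifting
        ## beta0 by delta and all b_g by -delta leaves the data likelihood
        ## unchanged, so only the priors enter; this decorrelates beta0 from
        ## the mean of the random intercepts
        delta <- stats::rnorm(1, 0, sigma / sqrt(G))
        lacc <- lp_normal(beta0 + delta) - lp_normal(beta0) +
          sum(stats::dnorm(b - delta, 0, sigma, log = TRUE)) -
          sum(stats::dnorm(b, 0, sigma, log = TRUE))
        if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
          beta0 <- beta0 + delta
          b <- b - delta
        }
        ## log sigma_b0 (half-Cauchy prior, Jacobian exp(lsig))
        lsig_p <- lsig + stats::rnorm(1, 0, sc_sig)
        lacc <- sum(stats::dnorm(b, 0, exp(lsig_p), log = TRUE)) -
          sum(stats::dnorm(b, 0, exp(lsig), log = TRUE)) +
          lp_half_cauchy(exp(lsig_p)) - lp_half_cauchy(exp(lsig)) +
          lsig_p - lsig
        if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
          lsig <- lsig_p
          acc$sig <- acc$sig + 1
        }
        ## log phi (half-Cauchy prior, Jacobian)
        lphi_p <- lphi + stats::rnorm(1, 0, sc_phi)
        ll_new <- data_ll_by_group(beta0, beta, b, exp(lphi_p))
        lacc <- sum(ll_new) - sum(ll_g) +
          lp_half_cauchy(exp(lphi_p)) - lp_half_cauchy(exp(lphi)) +
          lphi_p - lphi
        if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
          lphi <- lphi_p
          ll_g <- ll_new
          acc$phi <- acc$phi + 1
        }

        ## adapt proposal scales during warm-up
        if (it <= warmup && it %% win == 0L) {
          tune <- function(scale, rate) {
            if (rate < 0.30) scale * 0.8 else if (rate > 0.45) scale * 1.25 else scale
          }
          sc_fix <- mapply(tune, sc_fix, acc$fix / win)
          sc_b <- mapply(tune, sc_b, acc$b / win)
          sc_sig <- tune(sc_sig, acc$sig / win)
          sc_phi <- tune(sc_phi, acc$phi / win)
          acc <- list(fix = numeric(P + 1L), b = numeric(G), sig = 0, phi = 0)
        }
        draws[it, ] <- c(beta0, beta, b, exp(lsig), exp(lphi))
      }
      chains[[ch]] <- draws[(warmup + 1L):n_iter, , drop = FALSE]
    })
  }

  rhat <- vapply(seq_along(par_names), function(k) {
    psrf(lapply(chains, function(m) m[, k]))
  }, numeric(1))
  names(rhat) <- par_names
  pooled <- do.call(rbind, chains)
  colnames(pooled) <- par_names
  eap <- colMeans(pooled)
  if (any(rhat > 1.05, na.rm = TRUE)) {
    warning(sprintf(
      "PSRF above 1.05 for: %s — chains may not have converged",
      paste(par_names[which(rhat > 1.05)], collapse = ", ")
    ), call. = FALSE)
  }
  list(
    method = "bayes",
    coefficients = stats::setNames(eap[seq_len(ncol(X) + 1L)],
                                   c("intercept", cn)),
    random_intercept_sd = unname(eap["sigma_b0"]),
    precision = unname(eap["phi"]),
    group_intercepts = unname(eap[ncol(X) + 1L + seq_len(G)]),
    draws = pooled,
    psrf = rhat,
    convergence_ok = all(rhat <= 1.05, na.rm = TRUE)
  )
}

#' @export
print.beta_regression_fit <- function(x, ...) {
  cat(sprintf("Hierarchical Beta regression (%s)\n",
              if (x$method == "bayes") "Bayesian, Metropolis-within-Gibbs"
              else "marginal ML, adaptive Gauss-Hermite"))
  print(round(x$coefficients, 4))
  cat(sprintf("random intercept SD = %.4f, precision phi = %.3f\n",
              x$random_intercept_sd, x$precision))
  if (x$method == "bayes") {
    cat(sprintf("max PSRF = %.4f (%s)\n", max(x$psrf, na.rm = TRUE),
                if (isTRUE(x$convergence_ok)) "ok" else "above 1.05"))
  }
  invisible(x)
}

#' Potential scale reduction factor (split-Rhat)
#'
#' Gelman-Rubin convergence diagnostic: each chain is split in half and the
#' between/within variance ratio of the resulting half-chains is
#' square-rooted.
#'
#' @param chains list of numeric vectors (one per chain) or a matrix with
#'   one column per chain, post-warm-up draws of a single parameter.
#' @return the PSRF; \code{NA} with attribute \code{reason} if all
#'   half-chains are degenerate (zero variance).
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) {
    chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  }
  if (length(chains) < 2L || any(lengths(chains) < 10L)) {
    aw_stop("need >= 2 chains with >= 10 draws each",
            "attweights_error_input")
  }
  halves <- unlist(lapply(chains, function(v) {
    m <- floor(length(v) / 2)
    list(v[seq_len(m)], v[m + seq_len(m)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) {
    if (B <= 0) return(structure(NA_real_, reason = "zero-variance chains"))
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}
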