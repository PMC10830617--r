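# Step 2 of the weighting procedure: weighted marginal maximum likelihood
# estimation of a multi-group generalized partial credit model (GPCM), with
# each respondent's log-likelihood contribution multiplied by
# attentiveness x sampling weight (pseudo-likelihood weighting), and the
# adjusted-vs-unadjusted comparison of group distributions.
#
# Identification follows operational large-scale-assessment practice: item
# parameters are common to all groups, group 1 is fixed at N(0, 1), and the
# remaining group means and SDs are free.

#' GPCM category probabilities
#'
#' Category probabilities of the generalized partial credit model,
#' \deqn{p_k(\theta) = \frac{\exp \sum_{l=0}^{k} a(\theta - b_l)}
#'                          {\sum_{r=0}^{K} \exp \sum_{l=0}^{r} a(\theta - b_l)}}
#' with the empty sum for \eqn{k = 0} defined as zero. Computed with
#' max-subtraction in log space.
#'
#' @param discrimination item slope \eqn{a}.
#' @param step_difficulties numeric vector \eqn{b_1, \dots, b_K}.
#' @param theta numeric vector of trait values.
#' @return a \code{length(theta) x (K+1)} matrix of probabilities; each row
#'   sums to 1.
#' @export
gpcm_category_probs <- function(discrimination, step_difficulties, theta) {
  if (!all(is.finite(c(discrimination, step_difficulties, theta)))) {
    aw_stop("all GPCM inputs must be finite", "attweights_error_input")
  }
  K <- length(step_difficulties)
  # cumulative numerator exponents: s_k(theta) = sum_{l<=k} a (theta - b_l)
  s <- cbind(0, outer(theta, seq_len(K)) * discrimination -
               rep(discrimination * cumsum(step_difficulties),
                   each = length(theta)))
  mx <- apply(s, 1L, max)
  e <- exp(s - mx)
  e / rowSums(e)
}

# log category probabilities at a theta grid in the internal
# (a, c_1..c_K) parameterization, c_k = -a * cumsum(b)[k]
gpcm_logprobs_ac <- function(a, cvec, theta) {
  K <- length(cvec)
  s <- cbind(0, outer(theta, seq_len(K)) * a +
               rep(cvec, each = length(theta)))
  s - row_logsumexp(s)
}

#' Weighted marginal GPCM log-likelihood
#'
#' Pseudo-likelihood objective of the weighted multi-group GPCM:
#' \eqn{\sum_i w_i \log \int \prod_j p(y_{ij} \mid \theta)\, dF_{\gamma_g}(\theta)},
#' with the integral taken by fixed rectangle quadrature over the
#' group-specific normal trait distribution and missing responses skipped in
#' the product. With all weights 1 this is the ordinary MML log-likelihood.
#'
#' @param items list of item parameter lists, each with
#'   \code{discrimination} and \code{step_difficulties}.
#' @param groups data.frame with columns \code{mean} and \code{sd}, one row
#'   per group.
#' @param responses integer matrix (respondents x items), categories
#'   \code{0..K_j}, \code{NA} for omitted.
#' @param group integer group index per respondent.
#' @param weights total case weight per respondent (attentiveness x
#'   sampling); default all 1.
#' @param n_quadrature number of rectangle nodes (>= 21) on
#'   \code{theta_range} in the group-standardized metric.
#' @param theta_range quadrature interval, default \code{c(-6, 6)}.
#' @return the weighted marginal log-likelihood (scalar).
#' @export
weighted_marginal_loglik <- function(items, groups, responses, group,
                                     weights = NULL, n_quadrature = 61L,
                                     theta_range = c(-6, 6)) {
  if (n_quadrature < 21L) {
    aw_stop("n_quadrature must be >= 21", "attweights_error_input")
  }
  n <- nrow(responses)
  if (is.null(weights)) weights <- rep(1, n)
  if (all(weights == 0)) {
    aw_stop("no effective sample: all case weights are zero",
            "attweights_error_input")
  }
  z <- seq(theta_range[1], theta_range[2], length.out = n_quadrature)
  pz <- stats::dnorm(z)
  pz <- pz / sum(pz)
  ll <- 0
  for (g in seq_len(nrow(groups))) {
    rows <- which(group == g & weights > 0)
    if (!length(rows)) next
    theta_g <- groups$mean[g] + groups$sd[g] * z
    L <- matrix(rep(log(pz), each = length(rows)), nrow = length(rows))
    for (j in seq_along(items)) {
      y <- responses[rows, j]
      obs <- !is.na(y)
      if (!any(obs)) next
      lp <- log(gpcm_category_probs(items[[j]]$discrimination,
                                    items[[j]]$step_difficulties, theta_g))
      L[obs, ] <- L[obs, , drop = FALSE] + t(lp)[y[obs] + 1L, , drop = FALSE]
    }
    ll <- ll + sum(weights[rows] * row_logsumexp(L))
  }
  ll
}

#' Fit a weighted multi-group GPCM by MML-EM
#'
#' EM estimation of the weighted marginal likelihood: the E-step computes
#' weighted posterior distributions over the quadrature nodes, the M-step
#' updates item parameters by Newton steps (with step-halving) in a
#' category-intercept parameterization and the free group means/SDs by
#' closed-form weighted posterior moments. Group 1 is fixed at N(0, 1);
#' item parameters are shared across groups.
#'
#' Rows with every response missing are dropped from estimation (reported in
#' \code{dropped_rows}); categories never observed with positive weight are
#' collapsed onto the adjacent lower category, with the remapping recorded
#' in \code{category_maps}.
#'
#' @inheritParams weighted_marginal_loglik
#' @param responses integer matrix (respondents x items) with categories
#'   \code{0..K_j} and \code{NA} for omissions.
#' @param group integer group index per respondent (1-based, group 1 is the
#'   reference).
#' @param weights non-negative case weights (attentiveness x sampling).
#' @param max_cycles,tol EM cycle cap and convergence threshold on the
#'   maximum absolute parameter change.
#' @return an object of class \code{gpcm_fit}: \code{items} (list of
#'   \code{discrimination}, \code{step_difficulties}), \code{groups}
#'   (data.frame \code{mean}, \code{sd}), \code{loglik}, \code{converged},
#'   \code{n_cycles}, \code{n_quadrature}, \code{loglik_trace},
#'   \code{category_maps}, \code{dropped_rows}.
#' @export
fit_multigroup_gpcm <- function(responses, group, weights = NULL,
                                n_quadrature = 61L, theta_range = c(-6, 6),
                                max_cycles = 1000L, tol = 1e-5) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  J <- ncol(responses)
  group <- as.integer(group)
  if (length(group) != n) {
    aw_stop("group must align with responses", "attweights_error_input")
  }
  G <- max(group)
  if (any(tabulate(group, G) == 0L)) {
    aw_stop("empty group: every group index 1..G must occur",
            "attweights_error_input")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || any(!is.finite(weights))) {
    aw_stop("weights must be finite and >= 0", "attweights_error_input")
  }
  if (all(weights == 0)) {
    aw_stop("no effective sample: all case weights are zero",
            "attweights_error_input")
  }

  # drop all-missing rows and zero-weight rows from estimation
  all_missing <- rowSums(!is.na(responses)) == 0L
  keep <- !all_missing & weights > 0
  dropped <- which(all_missing)
  est_y <- responses[keep, , drop = FALSE]
  est_g <- group[keep]
  est_w <- weights[keep]
  if (any(tabulate(est_g, G) == 0L)) {
    aw_stop("a group has no usable rows after dropping all-missing/zero-weight cases",
            "attweights_error_input")
  }

  # collapse unobserved categories (positive-weight occurrences only)
  category_maps <- vector("list", J)
  for (j in seq_len(J)) {
    y <- est_y[, j]
    obs_cats <- sort(unique(y[!is.na(y)]))
    if (length(obs_cats) < 2L) {
      aw_stop(sprintf("item %d has fewer than 2 observed categories", j),
              "attweights_error_input")
    }
    K_j <- max(obs_cats)
    full <- 0:K_j
    if (!all(full %in% obs_cats)) {
      remap <- cumsum(full %in% obs_cats) - 1L
      message(sprintf(
        "item %d: unobserved categories collapsed (map %s -> %s)",
        j, paste(full, collapse = ","), paste(remap, collapse = ",")
      ))
      est_y[, j] <- remap[y + 1L]
      category_maps[[j]] <- stats::setNames(remap, full)
    } else {
      category_maps[[j]] <- stats::setNames(full, full)
    }
  }
  K <- vapply(seq_len(J), function(j) max(est_y[, j], na.rm = TRUE), integer(1))

  # quadrature in the group-standardized metric
  Q <- as.integer(n_quadrature)
  z <- seq(theta_range[1], theta_range[2], length.out = Q)
  log_pz <- stats::dnorm(z, log = TRUE)
  log_pz <- log_pz - log(sum(exp(log_pz)))

  # starting values: a = 1, equally spaced steps; groups at N(0,1)
  a <- rep(1, J)
  cmat <- lapply(seq_len(J), function(j) {
    b0 <- seq(-1, 1, length.out = K[j])
    -cumsum(b0)            # c_k with a = 1
  })
  mu <- rep(0, G)
  sg <- rep(1, G)

  grp_rows <- lapply(seq_len(G), function(g) which(est_g == g))
  converged <- FALSE
  trace <- numeric(0)
  params_old <- c(a, unlist(cmat), mu[-1], sg[-1])

  for (cycle in seq_len(max_cycles)) {
    ## E-step: per group posteriors over nodes
    node_theta <- matrix(0, G, Q)     # theta value of node q in group g
    # expected counts for items: list over j of (G*Q) x (K_j+1)
    cnt <- lapply(seq_len(J), function(j) matrix(0, G * Q, K[j] + 1L))
    ll <- 0
    post_m1 <- numeric(G)
    post_m2 <- numeric(G)
    sw_g <- numeric(G)
    for (g in seq_len(G)) {
      rows <- grp_rows[[g]]
      theta_g <- mu[g] + sg[g] * z
      node_theta[g, ] <- theta_g
      lp_items <- lapply(seq_len(J), function(j) {
        gpcm_logprobs_ac(a[j], cmat[[j]], theta_g)   # Q x (K+1)
      })
      L <- matrix(rep(log_pz, each = length(rows)), nrow = length(rows))
      for (j in seq_len(J)) {
        y <- est_y[rows, j]
        obs <- !is.na(y)
        if (!any(obs)) next
        L[obs, ] <- L[obs, , drop = FALSE] +
          t(lp_items[[j]])[y[obs] + 1L, , drop = FALSE]
      }
      lse <- row_logsumexp(L)
      ll <- ll + sum(est_w[rows] * lse)
      f <- exp(L - lse) * est_w[rows]          # weighted posteriors, n_g x Q
      # group moment accumulators (posterior mean/variance of theta)
      fq <- colSums(f)
      sw_g[g] <- sum(est_w[rows])
      post_m1[g] <- sum(fq * theta_g)
      post_m2[g] <- sum(fq * theta_g^2)
      # item expected counts at this group's nodes
      idx <- (g - 1L) * Q + seq_len(Q)
      for (j in seq_len(J)) {
        y <- est_y[rows, j]
        obs <- which(!is.na(y))
        if (!length(obs)) next
        for (k in 0:K[j]) {
          sel <- obs[y[obs] == k]
          if (length(sel)) {
            cnt[[j]][idx, k + 1L] <- cnt[[j]][idx, k + 1L] +
              colSums(f[sel, , drop = FALSE])
          }
        }
      }
    }
    trace <- c(trace, ll)

    ## M-step: group distributions (closed-form weighted moments)
    for (g in seq_len(G)) {
      if (g == 1L) next                       # identification: N(0,1)
      m1 <- post_m1[g] / sw_g[g]
      v <- post_m2[g] / sw_g[g] - m1^2
      mu[g] <- m1
      sg[g] <- sqrt(max(v, 1e-4))
    }

    ## M-step: items, one Newton step each with step-halving
    th <- as.vector(t(node_theta))            # stacked node thetas (G*Q)
    for (j in seq_len(J)) {
      upd <- gpcm_newton_step(a[j], cmat[[j]], th, cnt[[j]])
      a[j] <- upd$a
      cmat[[j]] <- upd$cvec
    }

    params <- c(a, unlist(cmat), mu[-1], sg[-1])
    if (max(abs(params - params_old)) < tol) {
      converged <- TRUE
      params_old <- params
      break
    }
    params_old <- params
  }

  items <- lapply(seq_len(J), function(j) {
    b <- -diff(c(0, cmat[[j]])) / a[j]        # b_l = (c_{l-1} - c_l) / a
    list(discrimination = a[j], step_difficulties = b)
  })
  groups <- data.frame(mean = mu, sd = sg)
  ll_final <- weighted_marginal_loglik(items, groups, est_y, est_g, est_w,
                                       n_quadrature = Q,
                                       theta_range = theta_range)
  structure(list(
    items = items, groups = groups, loglik = ll_final,
    converged = converged, n_cycles = length(trace),
    n_quadrature = Q, theta_range = theta_range,
    loglik_trace = trace, category_maps = category_maps,
    dropped_rows = dropped
  ), class = "gpcm_fit")
}

# one damped Newton step on the expected complete-data log-likelihood of one
# item in the (a, c_1..c_K) parameterization; counts is (T x K+1)
gpcm_newton_step <- function(a, cvec, theta, counts, max_halving = 10L) {
  K <- length(cvec)
  kk <- 0:K
  Nt <- rowSums(counts)
  use <- Nt > 0
  theta <- theta[use]
  counts <- counts[use, , drop = FALSE]
  Nt <- Nt[use]

  qfun <- function(a, cvec) {
    lp <- gpcm_logprobs_ac(a, cvec, theta)
    sum(counts * lp)
  }
  lp <- gpcm_logprobs_ac(a, cvec, theta)
  p <- exp(lp)
  q0 <- sum(counts * lp)

  m1 <- drop(p %*% kk)                        # E[k | node]
  m2 <- drop(p %*% kk^2)
  # gradient
  resid <- counts - p * Nt
  g_a <- sum(theta * drop(resid %*% kk))
  g_c <- colSums(resid)[-1L]
  grad <- c(g_a, g_c)
  # Hessian of Q (negative definite)
  H <- matrix(0, K + 1L, K + 1L)
  H[1L, 1L] <- -sum(Nt * theta^2 * (m2 - m1^2))
  for (m in seq_len(K)) {
    ham <- -sum(Nt * theta * p[, m + 1L] * (m - m1))
    H[1L, m + 1L] <- ham
    H[m + 1L, 1L] <- ham
    for (m2i in seq_len(K)) {
      H[m + 1L, m2i + 1L] <- -sum(Nt * (p[, m + 1L] * (m == m2i) -
                                          p[, m + 1L] * p[, m2i + 1L]))
    }
  }
  step <- tryCatch(
    solve(H + diag(-1e-10, K + 1L), grad),
    error = function(e) grad / max(abs(diag(H)), 1)
  )
  step <- -step                               # ascent direction: -H^{-1} g
  # cap wild steps
  if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
  lambda <- 1
  for (h in seq_len(max_halving)) {
    a_new <- a + lambda * step[1L]
    c_new <- cvec + lambda * step[-1L]
    if (a_new > 1e-3 && qfun(a_new, c_new) >= q0 - 1e-12) {
      return(list(a = a_new, cvec = c_new))
    }
    lambda <- lambda / 2
  }
  list(a = a, cvec = cvec)
}

#' @export
print.gpcm_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted multi-group GPCM: %d items, %d groups, loglik = %.3f (%s, %d cycles)\n",
    length(x$items), nrow(x$groups), x$loglik,
    if (x$converged) "converged" else "NOT converged", x$n_cycles
  ))
  it <- data.frame(
    a = vapply(x$items, `[[`, numeric(1), "discrimination"),
    t(vapply(x$items, function(i) {
      b <- i$step_difficulties
      length(b) <- max(vapply(x$items, function(z) length(z$step_difficulties),
                              integer(1)))
      b
    }, numeric(max(vapply(x$items, function(z) length(z$step_difficulties),
                          integer(1))))))
  )
  names(it)[-1L] <- paste0("b", seq_len(ncol(it) - 1L))
  print(round(it, 3))
  cat("Group trait distributions:\n")
  print(round(x$groups, 3))
  invisible(x)
}

#' Compare adjusted and unadjusted GPCM fits
#'
#' Contrasts group trait means and variances of two fits of the same scale
#' (typically with and without attentiveness weighting). Means are compared
#' in the common group-1 N(0,1) metric ("standardized" differences); a
#' per-group-SD-scaled variant (each mean divided by its own group SD) is
#' reported alongside.
#'
#' @param adjusted,unadjusted \code{gpcm_fit} objects on the same items and
#'   groups.
#' @return an object of class \code{gpcm_comparison}: per-group table of
#'   means/variances and their differences, plus the median absolute
#'   difference and middle-50\% range across groups for means and variances.
#' @export
compare_fits <- function(adjusted, unadjusted) {
  if (length(adjusted$items) != length(unadjusted$items) ||
      nrow(adjusted$groups) != nrow(unadjusted$groups)) {
    aw_stop("fits have mismatched items or groups", "attweights_error_input")
  }
  tab <- data.frame(
    group = seq_len(nrow(adjusted$groups)),
    mean_unadjusted = unadjusted$groups$mean,
    mean_adjusted = adjusted$groups$mean,
    var_unadjusted = unadjusted$groups$sd^2,
    var_adjusted = adjusted$groups$sd^2
  )
  tab$diff_mean <- tab$mean_adjusted - tab$mean_unadjusted
  tab$diff_var <- tab$var_adjusted - tab$var_unadjusted
  tab$diff_mean_scaled <- tab$mean_adjusted / adjusted$groups$sd -
    tab$mean_unadjusted / unadjusted$groups$sd
  mid50 <- function(v) unname(stats::quantile(v, c(0.25, 0.75)))
  structure(list(
    table = tab,
    median_abs_diff_mean = stats::median(abs(tab$diff_mean)),
    mid50_abs_diff_mean = mid50(abs(tab$diff_mean)),
    median_abs_diff_var = stats::median(abs(tab$diff_var)),
    mid50_abs_diff_var = mid50(abs(tab$diff_var)),
    median_abs_diff_mean_scaled = stats::median(abs(tab$diff_mean_scaled))
  ), class = "gpcm_comparison")
}

#' @export
print.gpcm_comparison <- function(x, ...) {
  cat(sprintf(
    "Adjusted vs unadjusted GPCM: median |diff mean| = %.4f [%.4f; %.4f], median |diff var| = %.4f [%.4f; %.4f]\n",
    x$median_abs_diff_mean, x$mid50_abs_diff_mean[1], x$mid50_abs_diff_mean[2],
    x$median_abs_diff_var, x$mid50_abs_diff_var[1], x$mid50_abs_diff_var[2]
  ))
  print(round(x$table, 4))
  invisible(x)
}
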