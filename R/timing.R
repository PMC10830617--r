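# Step 1 of the weighting procedure: transform screen times, decompose the
# log-time distribution of each group x scale cell into Gaussian mixture
# components, label the lowest-mean component as careless/insufficient-effort
# responding (C/IER), and turn posterior class probabilities into
# attentiveness weights.

#' Log geometric mean screen time per item
#'
#' Transforms a total screen time \eqn{t} (seconds) spent on a screen showing
#' \eqn{J} items into the natural log of the per-item geometric mean time,
#' \eqn{\ln(t^{1/J}) = \ln(t)/J}. With \code{n_items = 1} this is the plain
#' log screen time.
#'
#' @param time_seconds positive numeric vector of screen times in seconds.
#' @param n_items positive integer vector (recycled) of items per screen.
#' @return numeric vector of log per-item geometric mean times.
#' @examples
#' log_geometric_time(16, 4)  # log(2)
#' @export
log_geometric_time <- function(time_seconds, n_items) {
  if (any(!is.finite(time_seconds)) || any(time_seconds <= 0)) {
    aw_stop("time_seconds must be finite and > 0", "attweights_error_input")
  }
  if (any(!is.finite(n_items)) || any(n_items < 1) ||
      any(n_items != round(n_items))) {
    aw_stop("n_items must be integers >= 1", "attweights_error_input")
  }
  log(time_seconds) / n_items
}

# minimum observations needed to fit a C-component mixture
min_obs_for_components <- function(n_components) {
  if (n_components <= 1L) 2L else max(10L * n_components, 50L)
}

#' Fit a weighted univariate Gaussian mixture by EM
#'
#' Maximizes the weight-multiplied (pseudo-)log-likelihood
#' \eqn{\sum_i w_i \log \sum_c \pi_c \phi(x_i; \mu_c, \sigma_c)} by EM with
#' case weights entering every sufficient statistic, so that an integer
#' weight is exactly equivalent to replicating the observation. Components
#' have unequal variances. Weights are normalized to mean 1 before fitting.
#'
#' Initialization uses weighted (type-1) quantile seeds refined by a weighted
#' Lloyd k-means pass; \code{n_starts} restarts jitter the seeds and the best
#' final log-likelihood is kept. All randomness is governed by \code{seed}.
#'
#' @param x numeric vector of (log) times.
#' @param weights positive case weights aligned with \code{x}; default all 1.
#' @param n_components number of mixture components \eqn{C \ge 1}.
#' @param seed integer seed controlling restarts.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param var_floor lower bound for component variances, guarding against
#'   degenerate spikes on duplicated values.
#' @param n_starts number of jittered initializations.
#' @return an object of class \code{mixture_fit}: list with
#'   \code{n_components}, \code{means}, \code{sds}, \code{proportions},
#'   \code{loglik}, \code{bic}, \code{converged}, \code{n_obs}, \code{seed},
#'   and the per-iteration \code{loglik_trace} of the winning start.
#' @export
fit_weighted_gmm <- function(x, weights = NULL, n_components = 2L,
                             seed = 1L, max_iter = 500L, tol = 1e-8,
                             var_floor = 1e-4, n_starts = 5L) {
  n_components <- as.integer(n_components)
  if (n_components < 1L) {
    aw_stop("n_components must be >= 1", "attweights_error_input")
  }
  keep <- is.finite(x)
  if (!all(keep)) aw_stop("x must be finite", "attweights_error_input")
  n <- length(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0)) {
    aw_stop("weights must be positive, finite and aligned with x",
            "attweights_error_input")
  }
  if (n < min_obs_for_components(n_components)) {
    aw_stop(sprintf(
      "need >= %d observations for %d components, got %d",
      min_obs_for_components(n_components), n_components, n
    ), "attweights_error_insufficient_data")
  }
  w <- weights / mean(weights)

  if (n_components == 1L) {
    mom <- weighted_moments(x, w)
    sd1 <- sqrt(max(mom["var"], var_floor))
    ll <- sum(w * stats::dnorm(x, mom["mean"], sd1, log = TRUE))
    return(new_mixture_fit(
      means = unname(mom["mean"]), sds = unname(sd1), proportions = 1,
      loglik = ll, n_obs = n, converged = TRUE, seed = seed,
      loglik_trace = ll
    ))
  }

  C <- n_components
  best <- NULL
  with_seed(seed, {
    # short-run restarts: each start gets a 50-iteration preliminary EM,
    # only the best-by-loglik candidate is polished to full convergence
    for (s in seq_len(n_starts)) {
      init <- gmm_init(x, w, C, jitter = (s > 1L))
      fit <- gmm_em(x, w, init, max_iter = min(50L, max_iter), tol = tol,
                    var_floor = var_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (!best$converged) {
      short_trace <- best$trace
      best <- gmm_em(x, w, list(means = best$means, sds = best$sds,
                                proportions = best$proportions),
                     max_iter = max_iter, tol = tol, var_floor = var_floor)
      best$trace <- c(short_trace, best$trace)
    }
  })
  new_mixture_fit(
    means = best$means, sds = best$sds, proportions = best$proportions,
    loglik = best$loglik, n_obs = n, converged = best$converged,
    seed = seed, loglik_trace = best$trace
  )
}

# quantile-spread seeds + short weighted Lloyd pass -> initial parameters
gmm_init <- function(x, w, C, jitter = FALSE, kmeans_iter = 20L) {
  probs <- (seq_len(C) - 0.5) / C
  centers <- weighted_quantile(x, w, probs)
  if (jitter) {
    centers <- centers + stats::rnorm(C, 0, max(stats::sd(x), 1e-3) / 4)
  }
  for (it in seq_len(kmeans_iter)) {
    d <- abs(outer(x, centers, "-"))
    assign <- max.col(-d, ties.method = "first")
    newc <- centers
    for (c in seq_len(C)) {
      idx <- assign == c
      if (any(idx)) newc[c] <- sum(w[idx] * x[idx]) / sum(w[idx])
    }
    if (max(abs(newc - centers)) < 1e-10) {
      centers <- newc
      break
    }
    centers <- newc
  }
  d <- abs(outer(x, centers, "-"))
  assign <- max.col(-d, ties.method = "first")
  means <- centers
  sds <- numeric(C)
  props <- numeric(C)
  overall_sd <- max(sqrt(weighted_moments(x, w)["var"]), 1e-2)
  for (c in seq_len(C)) {
    idx <- assign == c
    props[c] <- sum(w[idx]) / sum(w)
    sds[c] <- if (sum(idx) > 1L) {
      max(sqrt(weighted_moments(x[idx], w[idx])["var"]), overall_sd / 20)
    } else {
      overall_sd
    }
  }
  props <- pmax(props, 1e-6)
  props <- props / sum(props)
  list(means = means, sds = sds, proportions = props)
}

# weighted EM core (compiled inner loop); returns parameters, loglik,
# trace, convergence flag
gmm_em <- function(x, w, init, max_iter, tol, var_floor) {
  overall_sd <- max(sqrt(weighted_moments(x, w)["var"]), 1e-2)
  gmm_em_cpp(x, w, init$means, init$sds, init$proportions,
             as.integer(max_iter), tol, var_floor, overall_sd)
}

# pure-R reference version of the EM loop, kept for cross-checking the
# compiled path in the test suite
gmm_em_r <- function(x, w, init, max_iter, tol, var_floor) {
  means <- init$means
  sds <- init$sds
  props <- init$proportions
  C <- length(means)
  sw <- sum(w)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  overall_sd <- max(sqrt(weighted_moments(x, w)["var"]), 1e-2)
  n <- length(x)
  for (it in seq_len(max_iter)) {
    # log(pi_c) + log phi(x; mu_c, sigma_c), built without dnorm overhead
    u <- (matrix(x, n, C) - rep(means, each = n)) / rep(sds, each = n)
    ld <- -0.5 * u * u +
      rep(log(props) - log(sds) - 0.9189385332046727, each = n)
    dim(ld) <- c(n, C)
    ll_i <- row_logsumexp(ld)
    ll <- sum(w * ll_i)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- exp(ld - ll_i)            # responsibilities, rows sum to 1
    wr <- r * w
    n_c <- colSums(wr)
    dead <- n_c < 1e-8
    if (any(dead)) {
      # re-seed collapsed components at a random observation
      for (c in which(dead)) {
        means[c] <- x[sample.int(length(x), 1L)]
        sds[c] <- overall_sd
        props[c] <- 1 / C
      }
      props <- props / sum(props)
      ll_old <- -Inf
      next
    }
    props <- n_c / sw
    means <- colSums(wr * x) / n_c
    sds <- sqrt(pmax(
      colSums(wr * (outer(x, means, "-")^2)) / n_c, var_floor
    ))
  }
  list(means = means, sds = sds, proportions = props, loglik = ll,
       trace = trace, converged = converged)
}

new_mixture_fit <- function(means, sds, proportions, loglik, n_obs,
                            converged, seed, loglik_trace) {
  C <- length(means)
  stopifnot(length(sds) == C, length(proportions) == C)
  structure(list(
    n_components = C,
    means = means,
    sds = sds,
    proportions = proportions,
    loglik = loglik,
    bic = -2 * loglik + (3 * C - 1) * log(n_obs),
    converged = converged,
    n_obs = n_obs,
    seed = as.integer(seed),
    loglik_trace = loglik_trace
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted Gaussian mixture: C = %d, n = %d, loglik = %.3f, BIC = %.3f%s\n",
    x$n_components, x$n_obs, x$loglik, x$bic,
    if (x$converged) "" else " (not converged)"
  ))
  print(round(data.frame(
    mean = x$means, sd = x$sds, proportion = x$proportions
  ), 4))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits mixtures with \eqn{C = 1, \dots,} \code{max_components} components to
#' the same data and returns the fit minimizing
#' \eqn{\mathrm{BIC} = -2\ell + (3C-1)\ln n}. Candidate counts whose data
#' requirement (\eqn{n \ge \max(10C, 50)}) is not met are skipped with a
#' warning; ties in BIC go to the smaller \eqn{C}.
#'
#' @inheritParams fit_weighted_gmm
#' @param max_components largest component count considered (default 9).
#' @return the minimum-BIC \code{mixture_fit}, with attribute
#'   \code{bic_path}: a data.frame of \code{n_components}, \code{loglik},
#'   \code{bic}, \code{converged} over all fitted counts.
#' @export
select_components <- function(x, weights = NULL, max_components = 9L,
                              seed = 1L, ...) {
  max_components <- as.integer(max_components)
  if (max_components < 1L) {
    aw_stop("max_components must be >= 1", "attweights_error_input")
  }
  n <- length(x)
  if (n < 2L) {
    aw_stop("need at least 2 observations", "attweights_error_insufficient_data")
  }
  cand <- seq_len(max_components)
  ok <- vapply(cand, function(C) n >= min_obs_for_components(C), logical(1))
  if (!all(ok)) {
    warning(sprintf(
      "skipping C in {%s}: fewer than max(10C, 50) observations (n = %d)",
      paste(cand[!ok], collapse = ", "), n
    ), call. = FALSE)
    cand <- cand[ok]
  }
  fits <- lapply(cand, function(C) {
    fit_weighted_gmm(x, weights, n_components = C,
                     seed = derive_seed(seed, paste0("gmm-C", C)), ...)
  })
  path <- data.frame(
    n_components = cand,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  best <- fits[[which.min(path$bic)]]   # which.min takes the first (lowest C)
  attr(best, "bic_path") <- path
  best
}

#' Posterior C/IER class probability for a log time
#'
#' Bayes posterior that an observation belongs to a designated component,
#' \eqn{\pi_c \phi(x;\mu_c,\sigma_c) / \sum_k \pi_k \phi(x;\mu_k,\sigma_k)},
#' evaluated in log space so extreme values underflow to exact 0/1 rather
#' than NaN.
#'
#' @param fit a \code{mixture_fit}.
#' @param cier_component integer component index in \code{1..C}.
#' @param x_value numeric vector of log times.
#' @return posterior probabilities in \eqn{[0, 1]}.
#' @export
posterior_cier <- function(fit, cier_component, x_value) {
  C <- fit$n_components
  cier_component <- as.integer(cier_component)
  if (cier_component < 1L || cier_component > C) {
    aw_stop("cier_component out of range", "attweights_error_input")
  }
  ld <- vapply(seq_len(C), function(c) {
    stats::dnorm(x_value, fit$means[c], fit$sds[c], log = TRUE) +
      log(fit$proportions[c])
  }, numeric(length(x_value)))
  ld <- matrix(ld, nrow = length(x_value))
  exp(ld[, cier_component] - row_logsumexp(ld))
}

#' Attentiveness weights from posterior C/IER probabilities
#'
#' @param posteriors numeric vector of probabilities in \eqn{[0, 1]}.
#' @return \code{1 - posteriors}.
#' @export
attentiveness_weights <- function(posteriors) {
  if (any(!is.finite(posteriors)) || any(posteriors < 0) ||
      any(posteriors > 1)) {
    aw_stop("posteriors must lie in [0, 1]", "attweights_error_input")
  }
  1 - posteriors
}

#' Label the C/IER component and compute attentiveness weights
#'
#' Applies the labelling rule of the screen-time decomposition: with at least
#' two components, the component with the lowest mean log time is taken to
#' collect C/IER sessions and its mixture proportion is the group-level
#' C/IER proportion; a one-component solution is read as "no C/IER detected"
#' and every respondent keeps weight 1. Ties in the minimum mean go to the
#' lowest component index with a warning.
#'
#' @param fit a \code{mixture_fit}.
#' @param x the log times the fit was obtained on (posteriors are computed
#'   for these values).
#' @param weights optional positive case weights used for the reported
#'   weighted mean posterior.
#' @return an object of class \code{cier_decomposition}: list with
#'   \code{fit}, \code{cier_component} (\code{NA} for \eqn{C=1}),
#'   \code{cier_proportion} (the mixture proportion \eqn{\pi^{CIER}}),
#'   \code{posterior_mean_cier} (weighted mean posterior, the secondary
#'   prevalence measure), \code{posteriors}, \code{attentiveness_weights},
#'   and \code{mean_cier_time_per_item} (\eqn{e^{\mu_{CIER}}} seconds).
#' @export
label_cier <- function(fit, x, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  if (fit$n_components == 1L) {
    out <- list(
      fit = fit, cier_component = NA_integer_, cier_proportion = 0,
      posterior_mean_cier = 0,
      posteriors = rep(0, length(x)),
      attentiveness_weights = rep(1, length(x)),
      mean_cier_time_per_item = NA_real_
    )
    return(structure(out, class = "cier_decomposition"))
  }
  if (sum(fit$means == min(fit$means)) > 1L) {
    warning("tie in component means; labelling the lowest index as C/IER",
            call. = FALSE)
  }
  comp <- which.min(fit$means)    # first minimum = lowest index
  post <- posterior_cier(fit, comp, x)
  structure(list(
    fit = fit,
    cier_component = comp,
    cier_proportion = fit$proportions[comp],
    posterior_mean_cier = sum(weights * post) / sum(weights),
    posteriors = post,
    attentiveness_weights = attentiveness_weights(post),
    mean_cier_time_per_item = exp(fit$means[comp])
  ), class = "cier_decomposition")
}

#' @export
print.cier_decomposition <- function(x, ...) {
  if (is.na(x$cier_component)) {
    cat("One-component solution: no C/IER detected; all weights 1.\n")
  } else {
    cat(sprintf(
      paste0("C/IER component %d of %d: proportion %.3f, ",
             "mean time/item %.2f s, weighted mean posterior %.3f\n"),
      x$cier_component, x$fit$n_components, x$cier_proportion,
      x$mean_cier_time_per_item, x$posterior_mean_cier
    ))
  }
  invisible(x)
}
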