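# Synthetic survey sessions with known ground truth: grouped respondents,
# lognormal attentive / C/IER screen-time components, GPCM-consistent
# attentive responses, C/IER response styles (uniform random, straight-line,
# full omission), omissions, and sampling weights. Every other module is
# testable against the truth labels this generator echoes.

#' Simulation configuration
#'
#' Builds and validates the configuration for
#' \code{\link{simulate_cier_dataset}}. Defaults emulate the timing
#' structure of a large-scale background questionnaire: attentive per-item
#' geometric mean times around 2.08 s and C/IER times around 1.13 s (log
#' scale SDs 0.3, a standardized separation of about 2), a C/IER proportion
#' of 0.06, four-category Likert items, and mildly dispersed lognormal
#' sampling weights normalized to mean 1 per group.
#'
#' @param n_groups number of (country-by-language analog) groups.
#' @param n_per_group respondents per group.
#' @param n_scales number of scales (one screen each).
#' @param items_per_scale items J per screen (scalar or length
#'   \code{n_scales}).
#' @param n_categories response categories per item (K + 1).
#' @param cier_proportion probability of a C/IER session per respondent x
#'   scale; scalar, or a \code{n_groups x n_scales} matrix.
#' @param attentive_log_mean,attentive_log_sd mean(s) and SD(s) of the
#'   attentive log per-item time component(s); vectors of length 1 or 2.
#' @param attentive_mix mixing proportions of the attentive components
#'   (same length as \code{attentive_log_mean}).
#' @param cier_log_mean,cier_log_sd single C/IER log per-item time
#'   component; its mean must lie below every attentive mean.
#' @param style_probs probabilities of the C/IER response styles
#'   \code{uniform}, \code{straightline}, \code{omit}; must sum to 1.
#' @param omission_rate_attentive,omission_rate_cier per-item omission
#'   probability for attentive sessions and for (non-fully-omitted) C/IER
#'   sessions.
#' @param group_trait_means,group_trait_sds trait distribution per group;
#'   group 1 is pinned at N(0, 1). \code{NULL} draws the free groups'
#'   means from N(0, 0.3) and SDs from U(0.85, 1.2).
#' @param gpcm_params optional list per scale of item parameter lists
#'   (\code{discrimination}, \code{step_difficulties}); \code{NULL} draws
#'   discriminations from logN(0, 0.2) and ordered steps around 0.
#' @param weight_log_sd log-scale SD of the lognormal sampling weights.
#' @param seed integer root seed; all randomness in the generator descends
#'   from it.
#' @return validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_groups = 2L, n_per_group = 1000L,
                              n_scales = 4L, items_per_scale = 4L,
                              n_categories = 4L, cier_proportion = 0.06,
                              attentive_log_mean = log(2.08),
                              attentive_log_sd = 0.3,
                              attentive_mix = 1,
                              cier_log_mean = log(1.13),
                              cier_log_sd = 0.3,
                              style_probs = c(uniform = 0.4,
                                              straightline = 0.3,
                                              omit = 0.3),
                              omission_rate_attentive = 0.02,
                              omission_rate_cier = 0.10,
                              group_trait_means = NULL,
                              group_trait_sds = NULL,
                              gpcm_params = NULL,
                              weight_log_sd = 0.25,
                              seed = 1L) {
  chk <- function(ok, field) {
    if (!ok) aw_stop(paste0("invalid config field: ", field),
                     "attweights_error_config")
  }
  chk(n_groups >= 1 && n_per_group >= 1 && n_scales >= 1, "n_groups/n_per_group/n_scales")
  items_per_scale <- rep_len(as.integer(items_per_scale), n_scales)
  chk(all(items_per_scale >= 1), "items_per_scale")
  chk(n_categories >= 2, "n_categories")
  if (is.matrix(cier_proportion)) {
    chk(all(dim(cier_proportion) == c(n_groups, n_scales)), "cier_proportion")
  } else {
    cier_proportion <- matrix(cier_proportion, n_groups, n_scales)
  }
  chk(all(cier_proportion >= 0 & cier_proportion <= 1), "cier_proportion")
  chk(length(attentive_log_mean) %in% 1:2 &&
        length(attentive_log_sd) == length(attentive_log_mean), "attentive_log_mean")
  attentive_mix <- rep_len(attentive_mix, length(attentive_log_mean))
  attentive_mix <- attentive_mix / sum(attentive_mix)
  chk(all(attentive_log_sd > 0) && cier_log_sd > 0, "log_sd")
  chk(cier_log_mean < min(attentive_log_mean), "cier_log_mean (must be below attentive means)")
  chk(length(style_probs) == 3L && abs(sum(style_probs) - 1) < 1e-8 &&
        all(style_probs >= 0), "style_probs")
  chk(omission_rate_attentive >= 0 && omission_rate_attentive <= 1 &&
        omission_rate_cier >= 0 && omission_rate_cier <= 1, "omission_rate")
  chk(weight_log_sd >= 0, "weight_log_sd")
  structure(list(
    n_groups = as.integer(n_groups), n_per_group = as.integer(n_per_group),
    n_scales = as.integer(n_scales), items_per_scale = items_per_scale,
    n_categories = as.integer(n_categories),
    cier_proportion = cier_proportion,
    attentive_log_mean = attentive_log_mean,
    attentive_log_sd = attentive_log_sd, attentive_mix = attentive_mix,
    cier_log_mean = cier_log_mean, cier_log_sd = cier_log_sd,
    style_probs = style_probs,
    omission_rate_attentive = omission_rate_attentive,
    omission_rate_cier = omission_rate_cier,
    group_trait_means = group_trait_means,
    group_trait_sds = group_trait_sds,
    gpcm_params = gpcm_params,
    weight_log_sd = weight_log_sd,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a survey dataset with known C/IER ground truth
#'
#' Per respondent x scale: a latent C/IER label is drawn with the configured
#' proportion; the log per-item screen time comes from the label's normal
#' component (total time \eqn{t = e^{xJ}}); attentive responses are drawn
#' from the GPCM at a group-distributed trait value; C/IER responses follow
#' the configured style mix (independent uniform categories, one repeated
#' straight-line category, or full omission); omissions are added at the
#' label-conditional rates. Byte-identical output for equal seeds.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list of class \code{simulated_dataset}:
#'   \code{screen_records} (long data.frame:
#'   \code{respondent_id, group_id, scale_id, time_seconds, n_items,
#'   sampling_weight}), \code{responses} (per scale: \code{responses}
#'   matrix with \code{NA} omissions and \code{group} vector),
#'   \code{truth} (long data.frame with \code{is_cier} and \code{style}),
#'   \code{params} (drawn GPCM parameters, group trait distributions, and
#'   the config).
#' @export
simulate_cier_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    aw_stop("config must be a simulation_config", "attweights_error_config")
  }
  cf <- config
  G <- cf$n_groups
  S <- cf$n_scales
  Npg <- cf$n_per_group
  N <- G * Npg
  K <- cf$n_categories - 1L

  with_seed(cf$seed, {
    # group trait distributions (group 1 pinned at N(0,1))
    mu_t <- cf$group_trait_means %||% c(0, stats::rnorm(G - 1, 0, 0.3))
    sd_t <- cf$group_trait_sds %||% c(1, stats::runif(max(G - 1, 0), 0.85, 1.2))
    mu_t[1] <- 0
    sd_t[1] <- 1

    # GPCM item parameters per scale
    gpcm <- cf$gpcm_params %||% lapply(seq_len(S), function(s) {
      J <- cf$items_per_scale[s]
      lapply(seq_len(J), function(j) {
        list(
          discrimination = exp(stats::rnorm(1, 0, 0.2)),
          step_difficulties = sort(stats::rnorm(K, 0, 0.8))
        )
      })
    })

    respondent_id <- sprintf("R%06d", seq_len(N))
    group <- rep(seq_len(G), each = Npg)
    # sampling weights, lognormal, normalized to mean 1 within group
    v <- exp(stats::rnorm(N, 0, cf$weight_log_sd))
    for (g in seq_len(G)) {
      idx <- group == g
      v[idx] <- v[idx] / mean(v[idx])
    }

    records <- vector("list", S)
    truth <- vector("list", S)
    resp <- vector("list", S)
    styles <- c("uniform", "straightline", "omit")

    for (s in seq_len(S)) {
      J <- cf$items_per_scale[s]
      p_cier <- cf$cier_proportion[cbind(group, s)]
      is_cier <- stats::rbinom(N, 1L, p_cier)
      style <- rep(NA_character_, N)
      style[is_cier == 1L] <- sample(styles, sum(is_cier), replace = TRUE,
                                     prob = cf$style_probs)

      # log per-item time from the label's component
      x <- numeric(N)
      att <- which(is_cier == 0L)
      if (length(att)) {
        comp <- sample.int(length(cf$attentive_mix), length(att),
                           replace = TRUE, prob = cf$attentive_mix)
        x[att] <- stats::rnorm(length(att), cf$attentive_log_mean[comp],
                               cf$attentive_log_sd[comp])
      }
      ci <- which(is_cier == 1L)
      if (length(ci)) {
        x[ci] <- stats::rnorm(length(ci), cf$cier_log_mean, cf$cier_log_sd)
      }

      # responses
      theta <- stats::rnorm(N, mu_t[group], sd_t[group])
      Y <- matrix(NA_integer_, N, J)
      for (j in seq_len(J)) {
        pr <- gpcm_category_probs(gpcm[[s]][[j]]$discrimination,
                                  gpcm[[s]][[j]]$step_difficulties, theta)
        u <- stats::runif(N)
        Y[, j] <- max.col(u < t(apply(pr, 1L, cumsum)),
                          ties.method = "first") - 1L
      }
      if (length(ci)) {
        uni <- ci[style[ci] == "uniform"]
        if (length(uni)) {
          Y[uni, ] <- matrix(sample.int(K + 1L, length(uni) * J,
                                        replace = TRUE) - 1L,
                             length(uni), J)
        }
        str <- ci[style[ci] == "straightline"]
        if (length(str)) {
          Y[str, ] <- matrix(rep(sample.int(K + 1L, length(str),
                                            replace = TRUE) - 1L, J),
                             length(str), J)
        }
        omi <- ci[style[ci] == "omit"]
        if (length(omi)) Y[omi, ] <- NA_integer_
      }
      # item-level omissions at label-conditional rates
      om_rate <- ifelse(is_cier == 1L, cf$omission_rate_cier,
                        cf$omission_rate_attentive)
      om_rate[!is.na(style) & style == "omit"] <- 0   # already fully omitted
      om <- matrix(stats::runif(N * J) < om_rate, N, J)
      Y[om] <- NA_integer_

      records[[s]] <- data.frame(
        respondent_id = respondent_id,
        group_id = sprintf("G%02d", group),
        scale_id = sprintf("S%02d", s),
        time_seconds = exp(x * J),
        n_items = J,
        sampling_weight = v,
        stringsAsFactors = FALSE
      )
      truth[[s]] <- data.frame(
        respondent_id = respondent_id,
        group_id = sprintf("G%02d", group),
        scale_id = sprintf("S%02d", s),
        is_cier = is_cier,
        style = ifelse(is.na(style), "attentive", style),
        stringsAsFactors = FALSE
      )
      rownames(Y) <- respondent_id
      resp[[s]] <- list(responses = Y, group = group)
    }

    structure(list(
      screen_records = do.call(rbind, records),
      responses = stats::setNames(resp, sprintf("S%02d", seq_len(S))),
      truth = do.call(rbind, truth),
      params = list(gpcm = gpcm,
                    group_trait_means = mu_t, group_trait_sds = sd_t,
                    config = cf)
    ), class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cf <- x$params$config
  cat(sprintf(
    "Simulated survey: %d groups x %d respondents, %d scales, %d categories; %.1f%% C/IER sessions\n",
    cf$n_groups, cf$n_per_group, cf$n_scales, cf$n_categories,
    100 * mean(x$truth$is_cier)
  ))
  invisible(x)
}

#' Minimum sample size for mixture decomposition
#'
#' Rule-of-thumb sample size \eqn{8/d^4} for trustworthy univariate Gaussian
#' mixture decomposition, where \eqn{d} is the smallest standardized mean
#' difference between any two components.
#'
#' @param separation_d positive standardized separation.
#' @return required sample size \eqn{8/d^4}.
#' @examples
#' minimum_sample_size(0.5)  # 128
#' @export
minimum_sample_size <- function(separation_d) {
  if (any(!is.finite(separation_d)) || any(separation_d <= 0)) {
    aw_stop("separation_d must be > 0", "attweights_error_input")
  }
  8 / separation_d^4
}
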