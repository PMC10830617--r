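# Threshold-based timing indicators and agreement/consistency statistics
# used to gather validity evidence for the screen-time decomposition:
# fixed-threshold and normative-threshold (NT30) flags, weighted
# correlations with omission counts, point-biserial agreement with
# posterior C/IER probabilities, and lagged rank-order consistency.

#' Fixed-threshold C/IER indicator
#'
#' Flags a respondent-by-scale interaction as inattentive iff the per-item
#' geometric mean time \eqn{t^{1/J}} is strictly below a threshold in
#' seconds (customarily 2 s, or the more conservative 1 s).
#'
#' @param time_seconds positive screen times (seconds).
#' @param n_items items per screen (recycled).
#' @param threshold_seconds positive threshold on the per-item time.
#' @return integer vector of 0/1 flags.
#' @export
fixed_threshold_indicator <- function(time_seconds, n_items,
                                      threshold_seconds) {
  if (length(threshold_seconds) != 1L || !is.finite(threshold_seconds) ||
      threshold_seconds <= 0) {
    aw_stop("threshold_seconds must be a single positive number",
            "attweights_error_input")
  }
  if (any(!is.finite(time_seconds)) || any(time_seconds <= 0)) {
    aw_stop("time_seconds must be finite and > 0", "attweights_error_input")
  }
  per_item <- time_seconds^(1 / n_items)
  as.integer(per_item < threshold_seconds)
}

#' Normative-threshold (NT30) C/IER indicator
#'
#' Flags a respondent iff the per-item geometric mean time is strictly below
#' a fraction (default 30\%) of the unweighted mean per-item time of the
#' respondent's group on that scale. Sampling weights are deliberately not
#' used in the group mean.
#'
#' @param time_seconds positive screen times.
#' @param n_items items per screen (recycled).
#' @param group_ids group membership per observation.
#' @param fraction normative fraction of the group mean (default 0.30).
#' @return integer vector of 0/1 flags aligned with the input.
#' @export
nt30_indicator <- function(time_seconds, n_items, group_ids,
                           fraction = 0.30) {
  if (any(!is.finite(time_seconds)) || any(time_seconds <= 0)) {
    aw_stop("time_seconds must be finite and > 0", "attweights_error_input")
  }
  if (!length(group_ids) || length(group_ids) != length(time_seconds)) {
    aw_stop("group_ids must align with time_seconds",
            "attweights_error_input")
  }
  per_item <- time_seconds^(1 / n_items)
  gmean <- stats::ave(per_item, group_ids, FUN = mean)
  as.integer(per_item < fraction * gmean)
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with case weights, computed on pairwise-complete
#' observations. A result is "undefined" (returned as \code{NA} with
#' attribute \code{reason}) when fewer than 3 complete pairs remain or when
#' either variable has zero weighted variance; undefined values are flagged,
#' not silently propagated NaNs.
#'
#' @param x,y numeric vectors.
#' @param weights positive case weights; default all 1.
#' @return the weighted correlation, or flagged \code{NA}.
#' @export
weighted_correlation <- function(x, y, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  ok <- is.finite(x) & is.finite(y) & is.finite(weights) & weights > 0
  x <- x[ok]; y <- y[ok]; w <- weights[ok]
  if (length(x) < 3L) {
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  }
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a binary 0/1 indicator and a continuous
#' vector (e.g., posterior C/IER probabilities). A constant indicator yields
#' a flagged undefined value.
#'
#' @param binary_indicator vector of 0/1 flags.
#' @param continuous numeric vector (e.g., posteriors).
#' @param weights optional positive case weights.
#' @return the correlation, or flagged \code{NA}.
#' @export
point_biserial <- function(binary_indicator, continuous, weights = NULL) {
  if (any(!binary_indicator %in% c(0, 1, NA))) {
    aw_stop("binary_indicator must contain only 0/1", "attweights_error_input")
  }
  weighted_correlation(as.numeric(binary_indicator), continuous, weights)
}

#' Item omissions per respondent
#'
#' @param responses integer matrix (respondents x items) with \code{NA}
#'   marking omitted items.
#' @return integer vector of omission counts per respondent.
#' @export
omission_counts <- function(responses) {
  responses <- as.matrix(responses)
  rowSums(is.na(responses))
}

#' Lagged rank-order consistency of C/IER behavior
#'
#' For scales ordered by screen position, computes for each lag
#' \eqn{\ell = 1, \dots,} \code{max_lag} the mean over position pairs
#' \eqn{(s, s+\ell)} of the correlation between respondents' posterior C/IER
#' probabilities on the two scales. Pairs whose correlation is undefined
#' (insufficient overlap or zero variance) are excluded from the mean and
#' counted.
#'
#' @param posterior_matrix numeric matrix, respondents x ordered scale
#'   positions, of posterior C/IER probabilities (\code{NA} where a
#'   respondent did not see a scale).
#' @param max_lag largest lag considered (default 15).
#' @param weights optional case weights for the pairwise correlations.
#' @return data.frame with \code{lag}, \code{mean_correlation},
#'   \code{n_pairs} (pairs averaged), \code{n_undefined}.
#' @export
lagged_consistency <- function(posterior_matrix, max_lag = 15L,
                               weights = NULL) {
  posterior_matrix <- as.matrix(posterior_matrix)
  S <- ncol(posterior_matrix)
  if (S < 2L) {
    aw_stop("need at least 2 scale positions", "attweights_error_input")
  }
  max_lag <- min(as.integer(max_lag), S - 1L)
  out <- lapply(seq_len(max_lag), function(l) {
    rs <- vapply(seq_len(S - l), function(s) {
      weighted_correlation(posterior_matrix[, s], posterior_matrix[, s + l],
                           weights)
    }, numeric(1))
    data.frame(
      lag = l,
      mean_correlation = if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE),
      n_pairs = sum(!is.na(rs)),
      n_undefined = sum(is.na(rs))
    )
  })
  do.call(rbind, out)
}
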