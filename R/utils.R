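# internal helpers shared across modules

#' Stop with a classed condition
#' @noRd
aw_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "attweights_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a root seed and a string label, below 2^31
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' log(sum(exp(x))) without overflow, rowwise over a matrix
#' (column loop with pmax: much faster than apply(m, 1, max))
#' @noRd
row_logsumexp <- function(m) {
  nc <- ncol(m)
  mx <- m[, 1L]
  if (nc > 1L) for (j in 2:nc) mx <- pmax(mx, m[, j])
  s <- exp(m[, 1L] - mx)
  if (nc > 1L) for (j in 2:nc) s <- s + exp(m[, j] - mx)
  mx + log(s)
}

#' Type-1 (left-continuous inverse cdf) weighted quantile.
#' For integer weights this equals the unweighted type-1 quantile of the
#' replicated sample, which the replication-equivalence property relies on.
#' @noRd
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Weighted mean and ML (divide-by-sum-of-weights) standard deviation
#' @noRd
weighted_moments <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  c(mean = m, var = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
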