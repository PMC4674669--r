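#' Per-fragment interactability profile
#'
#' Interactability measures a baited fragment's generic propensity to form
#' ligation products, estimated from its trans-chromosomal di-tag total under
#' the assumption that trans contacts are random background and therefore
#' proportional to that propensity. Counts are normalised by the mean trans
#' count over retained fragments, so interactability is 1 for an average
#' retained fragment; the scale cancels into the regression intercept
#' downstream.
#'
#' @param fragments tibble with `fragment_id` and `trans_count` (from
#'   [aggregate_counts()]).
#' @param threshold noise threshold: fragments with `trans_count` below it
#'   are flagged as not retained (see [noise_threshold()]).
#' @return tibble with `fragment_id`, `trans_count`, `interactability`,
#'   `retained`.
#' @export
interactability_profile <- function(fragments, threshold = 0) {
  stopifnot(all(c("fragment_id", "trans_count") %in% names(fragments)))
  if (all(fragments$trans_count == 0)) {
    abort("degenerate library: all trans counts are zero")
  }
  retained <- fragments$trans_count >= threshold
  if (!any(retained)) abort("no fragments pass the noise threshold")
  mean_ret <- mean(fragments$trans_count[retained])
  tibble(
    fragment_id = fragments$fragment_id,
    trans_count = fragments$trans_count,
    interactability = fragments$trans_count / mean_ret,
    retained = retained
  )
}

#' Fit a left-truncated negative binomial to trans counts
#'
#' The distribution of per-fragment trans counts is bimodal: a low-count mode
#' of stochastic noise and a high-count mode of genuinely interacting
#' fragments. The signal mode is modelled by fitting a negative binomial by
#' maximum likelihood to the counts at or above `truncation` (default 3,000),
#' with the likelihood renormalised by the upper-tail mass so that the
#' returned `mean` and `size` describe the underlying non-truncated
#' distribution. Optimisation is over log-transformed parameters.
#'
#' @param counts integer vector of per-fragment trans totals.
#' @param truncation left truncation point; counts below it are excluded from
#'   the fit. `0` gives the ordinary untruncated ML fit.
#' @param min_counts minimum number of counts at/above the truncation.
#' @return object of class `chic_tnb` with elements `mean`, `size`,
#'   `truncation`, `loglik`, `convergence`, `n_used`. Supports [tidy()],
#'   [glance()] and `print()`.
#' @examples
#' set.seed(1)
#' fit_truncated_nb(rnbinom(2000, mu = 5000, size = 2), truncation = 3000)
#' @export
fit_truncated_nb <- function(counts, truncation = 3000, min_counts = 25) {
  stopifnot(is.numeric(counts), all(counts >= 0), truncation >= 0)
  y <- counts[counts >= truncation]
  if (length(y) < min_counts) {
    abort(paste0("only ", length(y), " counts at or above the truncation point ",
                 truncation, " (need at least ", min_counts, ")"))
  }
  nll <- function(par) {
    mu <- exp(par[1])
    size <- exp(par[2])
    ll <- dnbinom(y, mu = mu, size = size, log = TRUE)
    if (truncation > 0) {
      ll <- ll - pnbinom(truncation - 1, mu = mu, size = size,
                         lower.tail = FALSE, log.p = TRUE)
    }
    v <- -sum(ll)
    if (!is.finite(v)) return(1e12)
    v
  }
  m <- mean(y)
  v <- var(y)
  start <- c(log(m), log(max(m^2 / max(v - m, m / 10), 1e-2)))
  opt <- suppressWarnings(optim(start, nll, method = "BFGS"))
  if (opt$convergence != 0) {
    abort(paste0("truncated NB fit did not converge (optim code ",
                 opt$convergence, ")"))
  }
  structure(
    list(
      mean = exp(opt$par[1]),
      size = exp(opt$par[2]),
      truncation = truncation,
      loglik = -opt$value,
      convergence = opt$convergence,
      n_used = length(y)
    ),
    class = "chic_tnb"
  )
}

#' @export
print.chic_tnb <- function(x, ...) {
  cat(sprintf(
    "Left-truncated negative binomial fit (truncation %s, n = %d)\n  mean %.1f  size %.3f  logLik %.1f\n",
    format(x$truncation, big.mark = ","), x$n_used, x$mean, x$size, x$loglik
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chic_tnb <- function(x, ...) {
  tibble(term = c("mean", "size"), estimate = c(x$mean, x$size))
}

#' @exportS3Method generics::glance
glance.chic_tnb <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n_used, truncation = x$truncation,
         converged = x$convergence == 0)
}

#' Noise threshold from a truncated-NB fit
#'
#' The threshold separating stochastic-noise fragments from genuinely
#' interacting ones: the smallest integer count whose cumulative probability
#' under the *non-truncated* fitted negative binomial reaches `quantile`
#' (default 5%).
#'
#' @param fit a `chic_tnb` fit from [fit_truncated_nb()].
#' @param quantile lower-tail probability in (0, 1).
#' @return integer threshold count.
#' @export
noise_threshold <- function(fit, quantile = 0.05) {
  stopifnot(inherits(fit, "chic_tnb"))
  if (quantile <= 0 || quantile >= 1) abort("quantile must be in (0, 1)")
  as.integer(qnbinom(quantile, mu = fit$mean, size = fit$size))
}

#' Remove low-signal fragments
#'
#' Drops fragments whose trans count falls below the noise threshold
#' ("fewer than" is strict: a fragment exactly at the threshold is kept).
#' The removal tally is attached as the `filter_tally` attribute.
#'
#' @param profile interactability profile from [interactability_profile()].
#' @param threshold count threshold; defaults to the profile's own `retained`
#'   flag when `NULL`.
#' @return The retained rows of `profile`.
#' @export
filter_low_signal <- function(profile, threshold = NULL) {
  keep <- if (is.null(threshold)) profile$retained else
    profile$trans_count >= threshold
  out <- profile[keep, , drop = FALSE]
  attr(out, "filter_tally") <- tibble(
    n_fragments = nrow(profile), n_retained = sum(keep),
    n_removed = sum(!keep)
  )
  out
}

#' Fit the trans-count background for one experiment
#'
#' Convenience wrapper chaining [fit_truncated_nb()], [noise_threshold()]
#' and [interactability_profile()] on the per-fragment totals of one capture
#' experiment.
#'
#' @param fragments per-fragment totals from [aggregate_counts()].
#' @param truncation signal-mode truncation point.
#' @param quantile noise quantile.
#' @return list of class `chic_background` with `fit`, `threshold`,
#'   `profile`.
#' @export
fit_background <- function(fragments, truncation = 3000, quantile = 0.05) {
  fit <- fit_truncated_nb(fragments$trans_count, truncation = truncation)
  thr <- noise_threshold(fit, quantile = quantile)
  profile <- interactability_profile(fragments, threshold = thr)
  structure(list(fit = fit, threshold = thr, profile = profile),
            class = "chic_background")
}

#' @export
print.chic_background <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  noise threshold %d; %d / %d fragments retained\n",
              x$threshold, sum(x$profile$retained), nrow(x$profile)))
  invisible(x)
}
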