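## Dispersion of context-resolved mutation rates: entropy and KL divergence
## from the uniform-rate expectation, with a small-count bias correction.

#' Entropy of a count vector (bits)
#'
#' Plug-in entropy or the Grassberger small-count bias-corrected estimator
#' `H = ln N - (1/N) sum n_i [psi(n_i) + (-1)^{n_i} / (n_i (n_i + 1))]`
#' (converted to bits), which reduces to the plug-in estimate as the total
#' count grows.
#'
#' @param counts Non-negative integer vector with positive total.
#' @param method `"grassberger"` (default) or `"plugin"`.
#' @return Entropy estimate in bits.
#' @export
entropy_estimate <- function(counts, method = c("grassberger", "plugin")) {
  method <- match.arg(method)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive")
  if (method == "plugin") {
    p <- counts[counts > 0] / n
    return(-sum(p * log2(p)))
  }
  ni <- counts[counts > 0]
  h_nat <- log(n) - sum(ni * (digamma(ni) + (-1)^ni / (ni * (ni + 1)))) / n
  h_nat / log(2)
}

#' KL divergence of observed counts from the uniform-rate expectation
#'
#' Divergence (bits) between the distribution underlying the observed
#' per-context counts and the expectation under a uniform mutation rate,
#' where each context's expected share is proportional to its opportunity
#' count: `q[i] = T[i] / sum(T)`. Computed as the cross-entropy of the
#' empirical distribution with `q` minus the (optionally bias-corrected)
#' entropy estimate, so small-count bias in the entropy term is reduced.
#'
#' @param counts Mutation counts per context.
#' @param opportunities Positive opportunity counts `T[i]` (same length).
#' @param method Entropy estimator, see [entropy_estimate()].
#' @param n_boot Optional number of multinomial bootstrap resamples for a
#'   standard error and percentile interval.
#' @return Object of class `dispersion_result`: `kl` and `entropy` (bits),
#'   `method`, `n_total`, and bootstrap `se`/`ci` when requested.
#' @export
kl_from_uniform <- function(counts, opportunities,
                            method = c("grassberger", "plugin"),
                            n_boot = 0L) {
  method <- match.arg(method)
  stopifnot(length(counts) == length(opportunities))
  if (any(opportunities <= 0)) stop("opportunities must be positive")
  n <- sum(counts)
  q <- opportunities / sum(opportunities)
  p_hat <- counts / n
  cross <- -sum(p_hat * log2(q))          # q is known, no estimation bias
  h <- entropy_estimate(counts, method)
  kl <- cross - h
  res <- structure(list(kl = kl, entropy = h, method = method, n_total = n),
                   class = "dispersion_result")
  if (n_boot > 0L) {
    boots <- replicate(n_boot, {
      cb <- stats::rmultinom(1L, n, p_hat)[, 1L]
      -sum(cb / n * log2(q)) - entropy_estimate(cb, method)
    })
    res$se <- stats::sd(boots)
    res$ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  }
  res
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("KL from uniform: %.4f bits (entropy %.4f bits, %s estimator, n = %d)\n",
              x$kl, x$entropy, x$method, x$n_total))
  if (!is.null(x$se))
    cat(sprintf("  bootstrap se %.4f, 95%% CI [%.4f, %.4f]\n",
                x$se, x$ci[1], x$ci[2]))
  invisible(x)
}
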