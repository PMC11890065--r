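## Luria-Delbruck fluctuation-assay estimation of the mutation rate to a
## selectable phenotype (e.g. rifampicin resistance) from per-culture mutant
## counts.

#' Luria-Delbruck mutant-count distribution (MSS recursion)
#'
#' Probability mass of observing `0..n_max` mutant colonies in a culture in
#' which mutations arise during exponential growth with expected number `m`
#' per culture, via the Ma-Sandri-Sarkar recursion:
#' `p_0 = exp(-m)`; `p_n = (m/n) * sum_{k=0}^{n-1} p_k / (n - k + 1)`.
#'
#' @param m Expected mutations per culture (>= 0).
#' @param n_max Largest count computed; tail mass beyond it is not
#'   distributed (the vector sums to < 1).
#' @return Numeric vector of probabilities for counts `0..n_max`.
#' @export
ld_pmf <- function(m, n_max) {
  if (m < 0) stop("m must be non-negative")
  n_max <- as.integer(n_max)
  p <- numeric(n_max + 1L)
  p[1L] <- exp(-m)
  if (n_max >= 1L) {
    for (n in seq_len(n_max)) {
      k <- 0:(n - 1L)
      p[n + 1L] <- (m / n) * sum(p[k + 1L] / (n - k + 1L))
    }
  }
  p
}

## log-likelihood with per-culture exposure weights; counts beyond n_cap are
## treated as right-censored (tail mass), which bounds the O(n^2) recursion
## while leaving the MLE essentially unchanged (the tail shape is nearly
## flat in m)
ld_loglik <- function(m, cfu, weights, n_cap = 500L) {
  if (m <= 0) return(if (all(cfu == 0)) 0 else -Inf)
  ll <- 0
  for (w in unique(weights)) {
    sel <- weights == w
    x <- cfu[sel]
    top <- min(max(x), n_cap)
    pm <- ld_pmf(m * w, top)
    cens <- x > n_cap
    pr <- pm[pmin(x, n_cap) + 1L]
    if (any(cens)) pr[cens] <- max(1 - sum(pm), 1e-300)  # P(N > n_cap)
    if (any(pr <= 0)) return(-Inf)
    ll <- ll + sum(log(pr))
  }
  ll
}

#' Maximum-likelihood fit of a fluctuation assay
#'
#' Estimates the expected number of mutations per culture `m` under the
#' Luria-Delbruck (MSS) model by Newton iteration on the log-likelihood,
#' with a 95% interval from likelihood-ratio inversion, and converts it to
#' a per-generation mutation rate `mu = m / Nt`. Variation in the final
#' number of cells is handled by per-culture exposure scaling: each
#' culture's expected mutations are `m * Nt_j / median(Nt)`.
#'
#' @param cfu Integer mutant counts, one per culture.
#' @param Nt Final cell number: a scalar, or one value per culture.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `ld_fit` with `m_hat`, `ci`, `mu`, `mu_ci`,
#'   `Nt`, `loglik`.
#' @export
fit_ld <- function(cfu, Nt = NA, conf_level = 0.95) {
  if (length(cfu) < 2L) stop("need at least two cultures")
  if (any(cfu < 0 | cfu != round(cfu))) stop("cfu must be non-negative integers")
  w <- if (length(Nt) == length(cfu) && all(is.finite(Nt)))
    Nt / stats::median(Nt) else rep(1, length(cfu))
  Nt_ref <- if (length(Nt) == length(cfu) && all(is.finite(Nt)))
    stats::median(Nt) else Nt[1L]
  qcut <- stats::qchisq(conf_level, 1L) / 2

  if (all(cfu == 0)) {
    ## p0 estimator limit: likelihood exp(-m * sum(w)), one-sided interval
    upper <- qcut / sum(w)
    fit <- list(m_hat = 0, ci = c(0, upper), loglik = 0)
  } else {
    ## coarse log-grid pre-search, then Newton on log m
    f <- function(lm) ld_loglik(exp(lm), cfu, w)
    grid <- seq(log(0.02), log(max(cfu) + 1), length.out = 25L)
    lm <- grid[which.max(vapply(grid, f, 1))]
    for (it in 1:50) {
      h <- 1e-4
      f0 <- f(lm); f1 <- f(lm + h); f2 <- f(lm - h)
      g <- (f1 - f2) / (2 * h); H <- (f1 - 2 * f0 + f2) / h^2
      stepn <- if (is.finite(H) && H < 0) -g / H else sign(g) * 0.5
      stepn <- max(min(stepn, 1), -1)
      lm_new <- lm + stepn
      if (!is.finite(f(lm_new))) lm_new <- lm + stepn / 4
      if (abs(lm_new - lm) < 1e-8) { lm <- lm_new; break }
      lm <- lm_new
    }
    m_hat <- exp(lm)
    ll_max <- f(lm)
    ## likelihood-ratio interval
    lo <- tryCatch(stats::uniroot(function(x) f(log(x)) - (ll_max - qcut),
                                  c(m_hat * 1e-4, m_hat))$root,
                   error = function(e) 0)
    hi <- tryCatch(stats::uniroot(function(x) f(log(x)) - (ll_max - qcut),
                                  c(m_hat, m_hat * 100))$root,
                   error = function(e) NA_real_)
    fit <- list(m_hat = m_hat, ci = c(lo, hi), loglik = ll_max)
  }
  mu <- if (is.finite(Nt_ref)) fit$m_hat / Nt_ref else NA_real_
  mu_ci <- if (is.finite(Nt_ref)) fit$ci / Nt_ref else c(NA_real_, NA_real_)
  structure(list(m_hat = fit$m_hat, ci = fit$ci, mu = mu, mu_ci = mu_ci,
                 Nt = Nt_ref, level = conf_level, loglik = fit$loglik,
                 n_cultures = length(cfu)),
            class = "ld_fit")
}

#' @export
print.ld_fit <- function(x, ...) {
  cat(sprintf("<ld_fit> %d cultures: m = %.3g [%.3g, %.3g]\n",
              x$n_cultures, x$m_hat, x$ci[1], x$ci[2]))
  if (is.finite(x$mu))
    cat(sprintf("  mutation rate mu = m/Nt = %.3g [%.3g, %.3g] per generation\n",
                x$mu, x$mu_ci[1], x$mu_ci[2]))
  invisible(x)
}

#' @export
coef.ld_fit <- function(object, ...) {
  c(m_hat = object$m_hat, ci_low = object$ci[1], ci_high = object$ci[2],
    mu = object$mu)
}

#' Read / write fluctuation assay tables
#'
#' TSV with columns `culture_id`, `cfu`, `Nt`.
#'
#' @param path TSV path.
#' @export
read_assay <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_assay
#' @param assay data.frame with `culture_id`, `cfu`, `Nt`.
#' @export
write_assay <- function(assay, path) {
  utils::write.table(assay, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
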