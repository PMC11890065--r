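## Mathematical models of the interaction between proofreading and MMR.

#' Predicted mutation rate under MMR saturation
#'
#' In the saturation mixture model, a proportion `theta` of the errors made
#' by the proofreading-deficient polymerase arise while MMR is saturated
#' (and escape it entirely); the rest are corrected with the per-context
#' escape probability `q_MMR`. The predicted rate in the
#' proofreading-deficient MMR-proficient strain is
#' `mu_C[i] = gamma[i] * (theta + (1 - theta) * q_MMR[i])`,
#' where `gamma[i]` is the pre-repair error rate (the rate observed when
#' both systems are inactive).
#'
#' @param gamma Pre-repair error rate(s).
#' @param q_mmr MMR escape probability(ies) in (0, 1].
#' @param theta Saturation mixture proportion in \[0, 1\].
#' @return Predicted rate(s), elementwise.
#' @export
saturation_mu <- function(gamma, q_mmr, theta) {
  if (length(theta) != 1L || theta < 0 || theta > 1)
    stop("theta must be a single value in [0, 1]")
  if (any(gamma < 0)) stop("gamma must be non-negative")
  if (any(q_mmr <= 0 | q_mmr > 1)) stop("q_mmr must be in (0, 1]")
  gamma * (theta + (1 - theta) * q_mmr)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Fit the MMR-saturation mixture model to four genotypes
#'
#' Joint Bayesian fit of the saturation model to the Poisson counts of the
#' four repair genotypes: the fully deficient strain (rate `gamma[i]`), the
#' MMR-deficient proofreading-proficient strain (rate `beta[i]`), the
#' wild-type (rate `beta[i] * q[i]`, which identifies the MMR escape
#' probability `q[i]` with the ratio mu_R/mu_MMR-), and the
#' proofreading-deficient strain (rate
#' `gamma[i] * (theta + (1 - theta) * q[i])`). `theta` has a Uniform(0, 1)
#' prior; `log10 gamma`, `log10 beta` and `logit q` have hierarchical
#' normal priors, so uncertainty in the per-context rates propagates into
#' `theta` instead of being plugged in as fixed ratios. Sampling is adaptive
#' random-walk Metropolis within Gibbs.
#'
#' @param tab_R,tab_MMR,tab_C,tab_LC [count_table()]s for the wild-type,
#'   MMR-deficient, proofreading-deficient, and double-deficient genotypes,
#'   over the same contexts.
#' @param chains,iter,warmup,seed MCMC settings as in
#'   [fit_hierarchical_rates()].
#' @return Object of class `theta_fit`: `theta` (draws), `gamma`, `beta`,
#'   `q` (draw matrices, rate/probability scale), `prop_saturated` (per-draw
#'   implied proportion of proofreading-deficient-strain mutations arising
#'   from the saturated fraction), `rhat`, and the data.
#' @export
fit_theta <- function(tab_R, tab_MMR, tab_C, tab_LC, chains = 2L,
                      iter = 4000L, warmup = 2000L, seed = 1L) {
  tabs <- list(R = tab_R, MMR = tab_MMR, C = tab_C, LC = tab_LC)
  ctx <- names(tab_R$m)
  for (tb in tabs) if (!identical(names(tb$m), ctx))
    stop("the four genotype tables must share contexts")
  k <- length(ctx)
  m <- sapply(tabs, `[[`, "m")                     # k x 4
  E <- sapply(tabs, function(tb) tb$T * tb$G)      # exposures, k x 4
  res <- lapply(seq_len(chains), function(ch) {
    set.seed(seed + 1000L * (ch - 1L))
    theta_chain(m, E, iter, warmup)
  })
  theta <- unlist(lapply(res, `[[`, "theta"))
  lg <- do.call(rbind, lapply(res, `[[`, "lg"))
  lb <- do.call(rbind, lapply(res, `[[`, "lb"))
  q <- do.call(rbind, lapply(res, `[[`, "q"))
  colnames(lg) <- colnames(lb) <- colnames(q) <- ctx
  ## implied proportion of C* mutations from the saturated fraction
  gam <- 10^lg
  Tc <- matrix(tab_C$T, nrow(gam), k, byrow = TRUE)
  prop_sat <- rowSums(gam * theta * Tc) /
    rowSums(gam * (theta + (1 - theta) * q) * Tc)
  rhat <- theta_rhat(res, iter)
  structure(list(theta = theta, gamma = gam, beta = 10^lb, q = q,
                 prop_saturated = prop_sat, rhat = rhat,
                 contexts = ctx, m = m, E = E,
                 chains = chains, iter = iter),
            class = "theta_fit")
}

theta_chain <- function(m, E, iter, warmup) {
  k <- nrow(m)
  ## initial values from (regularised) ML rates
  lg <- log10((m[, "LC"] + 0.5) / E[, "LC"])
  lb <- log10((m[, "MMR"] + 0.5) / E[, "MMR"])
  q0 <- ((m[, "R"] + 0.5) / E[, "R"]) / ((m[, "MMR"] + 0.5) / E[, "MMR"])
  z <- logit(pmin(pmax(q0, 1e-4), 0.999))
  zt <- 0
  Mg <- mean(lg); Sg <- max(stats::sd(lg), 0.1)
  Mb <- mean(lb); Sb <- max(stats::sd(lb), 0.1)
  Mq <- mean(z); Sq <- max(stats::sd(z), 0.1)
  step <- list(lg = rep(0.4, k), lb = rep(0.4, k), z = rep(0.6, k), zt = 0.6,
               Sg = 0.4, Sb = 0.4, Sq = 0.4)
  acc <- list(lg = numeric(k), lb = numeric(k), z = numeric(k), zt = 0,
              Sg = 0, Sb = 0, Sq = 0)
  batch <- 50L
  total <- warmup + iter
  out <- list(theta = numeric(iter),
              lg = matrix(NA_real_, iter, k), lb = matrix(NA_real_, iter, k),
              q = matrix(NA_real_, iter, k))

  pois_ll <- function(mm, mu, ee) mm * log(mu * ee) - mu * ee

  for (t in seq_len(total)) {
    theta <- inv_logit(zt); q <- inv_logit(z)
    gam <- 10^lg; bet <- 10^lb

    ## gamma: LC and C likelihood terms
    lgp <- lg + stats::rnorm(k, 0, step$lg)
    gp <- 10^lgp
    d <- pois_ll(m[, "LC"], gp, E[, "LC"]) - pois_ll(m[, "LC"], gam, E[, "LC"]) +
      pois_ll(m[, "C"], gp * (theta + (1 - theta) * q), E[, "C"]) -
      pois_ll(m[, "C"], gam * (theta + (1 - theta) * q), E[, "C"]) +
      stats::dnorm(lgp, Mg, Sg, log = TRUE) - stats::dnorm(lg, Mg, Sg, log = TRUE)
    a <- log(stats::runif(k)) < d
    lg[a] <- lgp[a]; gam <- 10^lg; acc$lg <- acc$lg + a

    ## beta: MMR and R terms
    lbp <- lb + stats::rnorm(k, 0, step$lb)
    bp <- 10^lbp
    d <- pois_ll(m[, "MMR"], bp, E[, "MMR"]) - pois_ll(m[, "MMR"], bet, E[, "MMR"]) +
      pois_ll(m[, "R"], bp * q, E[, "R"]) - pois_ll(m[, "R"], bet * q, E[, "R"]) +
      stats::dnorm(lbp, Mb, Sb, log = TRUE) - stats::dnorm(lb, Mb, Sb, log = TRUE)
    a <- log(stats::runif(k)) < d
    lb[a] <- lbp[a]; bet <- 10^lb; acc$lb <- acc$lb + a

    ## q (logit scale): R and C terms
    zp <- z + stats::rnorm(k, 0, step$z)
    qp <- inv_logit(zp)
    d <- pois_ll(m[, "R"], bet * qp, E[, "R"]) - pois_ll(m[, "R"], bet * q, E[, "R"]) +
      pois_ll(m[, "C"], gam * (theta + (1 - theta) * qp), E[, "C"]) -
      pois_ll(m[, "C"], gam * (theta + (1 - theta) * q), E[, "C"]) +
      stats::dnorm(zp, Mq, Sq, log = TRUE) - stats::dnorm(z, Mq, Sq, log = TRUE)
    a <- log(stats::runif(k)) < d
    z[a] <- zp[a]; q <- inv_logit(z); acc$z <- acc$z + a

    ## theta (logit scale; Uniform(0,1) prior -> log-Jacobian theta(1-theta))
    ztp <- zt + stats::rnorm(1L, 0, step$zt)
    thp <- inv_logit(ztp)
    d <- sum(pois_ll(m[, "C"], gam * (thp + (1 - thp) * q), E[, "C"]) -
               pois_ll(m[, "C"], gam * (theta + (1 - theta) * q), E[, "C"])) +
      log(thp * (1 - thp)) - log(theta * (1 - theta))
    if (log(stats::runif(1L)) < d) { zt <- ztp; theta <- thp; acc$zt <- acc$zt + 1 }

    ## hyper-means: conjugate Gibbs (prior N(-9,3^2) for rates, N(0,2^2) for logit q)
    Mg <- hyper_mean_draw(lg, Sg, -9, 3)
    Mb <- hyper_mean_draw(lb, Sb, -9, 3)
    Mq <- hyper_mean_draw(z, Sq, 0, 2)
    ## hyper-sds: MH on log scale, half-Normal(0,2) prior
    up <- hyper_sd_update(lg, Mg, Sg, step$Sg); Sg <- up$S; acc$Sg <- acc$Sg + up$acc
    up <- hyper_sd_update(lb, Mb, Sb, step$Sb); Sb <- up$S; acc$Sb <- acc$Sb + up$acc
    up <- hyper_sd_update(z, Mq, Sq, step$Sq); Sq <- up$S; acc$Sq <- acc$Sq + up$acc

    if (t <= warmup && t %% batch == 0L) {
      for (nm in names(step))
        step[[nm]] <- step[[nm]] * exp((acc[[nm]] / batch - 0.44) / 2)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] * 0
    }
    if (t > warmup) {
      i <- t - warmup
      out$theta[i] <- theta
      out$lg[i, ] <- lg; out$lb[i, ] <- lb; out$q[i, ] <- q
    }
  }
  out
}

hyper_mean_draw <- function(x, S, m0, s0) {
  prec <- length(x) / S^2 + 1 / s0^2
  stats::rnorm(1L, (sum(x) / S^2 + m0 / s0^2) / prec, sqrt(1 / prec))
}

hyper_sd_update <- function(x, M, S, step) {
  sp <- S * exp(stats::rnorm(1L, 0, step))
  d <- sum(stats::dnorm(x, M, sp, log = TRUE) -
             stats::dnorm(x, M, S, log = TRUE)) +
    (-sp^2 + S^2) / 8 + log(sp) - log(S)
  if (log(stats::runif(1L)) < d) list(S = sp, acc = 1) else list(S = S, acc = 0)
}

theta_rhat <- function(res, iter) {
  half <- iter %/% 2L
  if (half < 2L || length(res) < 1L) return(1)
  splits <- unlist(lapply(res, function(r)
    list(r$theta[seq_len(half)], r$theta[(half + 1L):(2L * half)])),
    recursive = FALSE)
  means <- vapply(splits, mean, 1); vars <- vapply(splits, stats::var, 1)
  W <- mean(vars); B <- half * stats::var(means)
  sqrt(((half - 1) / half * W + B / half) / max(W, 1e-300))
}

#' @export
print.theta_fit <- function(x, ...) {
  qs <- stats::quantile(x$theta, c(0.025, 0.5, 0.975), names = FALSE)
  ps <- stats::quantile(x$prop_saturated, c(0.025, 0.5, 0.975), names = FALSE)
  cat(sprintf("<theta_fit> %d contexts, %d draws, R-hat(theta) %.3f\n",
              length(x$contexts), length(x$theta), x$rhat))
  cat(sprintf("  theta: %.3f [95%% CrI %.3f, %.3f]\n", qs[2], qs[1], qs[3]))
  cat(sprintf("  saturated fraction of observed mutations: %.2f [%.2f, %.2f]\n",
              ps[2], ps[1], ps[3]))
  invisible(x)
}

#' @export
summary.theta_fit <- function(object, ...) {
  list(theta = stats::quantile(object$theta, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       prop_saturated = stats::quantile(object$prop_saturated,
                                        c(0.025, 0.5, 0.975)),
       rhat = object$rhat)
}

#' Posterior-predictive counts for a saturation-model fit
#'
#' Draws replicate counts for each genotype from the fitted posterior and
#' returns central predictive intervals next to the observed counts.
#'
#' @param fit A `theta_fit`.
#' @param level Central predictive level (default 0.95).
#' @param ndraw Posterior draws used (default all, capped at 4000).
#' @return data.frame with `context`, `genotype`, `observed`, `pred_low`,
#'   `pred_high`, `inside`.
#' @export
posterior_predictive_counts <- function(fit, level = 0.95, ndraw = 4000L) {
  n <- min(length(fit$theta), ndraw)
  idx <- seq_len(n)
  th <- fit$theta[idx]
  mu <- list(R = fit$beta[idx, , drop = FALSE] * fit$q[idx, , drop = FALSE],
             MMR = fit$beta[idx, , drop = FALSE],
             C = fit$gamma[idx, , drop = FALSE] *
               (th + (1 - th) * fit$q[idx, , drop = FALSE]),
             LC = fit$gamma[idx, , drop = FALSE])
  out <- NULL
  a <- (1 - level) / 2
  for (g in names(mu)) {
    lam <- sweep(mu[[g]], 2L, fit$E[, g], `*`)
    rep_counts <- matrix(stats::rpois(length(lam), lam), nrow = n)
    lo <- apply(rep_counts, 2L, stats::quantile, probs = a, names = FALSE)
    hi <- apply(rep_counts, 2L, stats::quantile, probs = 1 - a, names = FALSE)
    out <- rbind(out, data.frame(
      context = fit$contexts, genotype = g, observed = fit$m[, g],
      pred_low = lo, pred_high = hi,
      inside = fit$m[, g] >= lo & fit$m[, g] <= hi,
      stringsAsFactors = FALSE))
  }
  out
}

#' Saturation proportion of a capacity-k MMR under Poisson errors
#'
#' In a simplified replication model, pre-MMR errors per generation are
#' `N ~ Poisson(lambda)` and MMR corrects (with its usual per-error escape
#' probability) only the first `k` errors; errors beyond capacity escape as
#' if MMR were saturated. The fraction of errors arising under saturation is
#' `theta(k, lambda) = E[(N - k)+] / E[N]`.
#'
#' @param k Non-negative integer capacity (vectorized).
#' @param lambda Mean pre-MMR errors per generation.
#' @return `theta(k, lambda)`.
#' @export
theta_of_capacity <- function(k, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  if (any(k < 0 | k != round(k))) stop("k must be non-negative integers")
  ## E[(N-k)+] = lambda P(N >= k) - k P(N >= k+1)
  (lambda * stats::ppois(k - 1, lambda, lower.tail = FALSE) -
     k * stats::ppois(k, lambda, lower.tail = FALSE)) / lambda
}

#' Invert the capacity relation: from theta to MMR capacity k
#'
#' Returns the smallest integer capacity `k` whose saturation proportion
#' `theta(k, lambda)` is at most the estimated `theta_hat`, plus the
#' continuous (linear) interpolation between the bracketing integers.
#'
#' @param lambda Mean pre-MMR errors per generation (e.g. the genome-wide
#'   pre-repair error rate times genome size).
#' @param theta_hat Estimated saturation proportion in (0, 1\].
#' @return List with `k` (integer), `k_interp` (continuous) and the curve
#'   values `theta_k` used.
#' @export
theta_to_capacity <- function(lambda, theta_hat) {
  if (theta_hat >= 1) return(list(k = 0L, k_interp = 0,
                                  theta_k = theta_of_capacity(0L, lambda)))
  if (theta_hat <= 0) stop("theta_hat must be in (0, 1]")
  k <- 0L
  repeat {
    if (theta_of_capacity(k, lambda) <= theta_hat) break
    k <- k + 1L
    if (k > 10000L) stop("capacity search did not terminate")
  }
  th <- theta_of_capacity(seq(0L, k), lambda)
  interp <- if (k == 0L) 0 else {
    (k - 1L) + (th[k] - theta_hat) / (th[k] - th[k + 1L])
  }
  list(k = k, k_interp = interp, theta_k = th)
}

#' Two-step proofreading error transform
#'
#' Proofreading detects and removes a misincorporated nucleotide with
#' probability `d`, after which a nucleotide is reincorporated with the
#' polymerase's initial error probability `gamma` (the cycle can repeat).
#' The post-proofreading error probability is
#' `e = gamma * (1 - d) / (1 - gamma * d)`.
#'
#' @param gamma Initial error probability(ies) in (0, 1).
#' @param d Detection/removal probability(ies) in \[0, 1\].
#' @return Post-proofreading error probability `e`.
#' @export
proofread_transform <- function(gamma, d) {
  if (any(d < 0 | d > 1)) stop("d must be in [0, 1]")
  if (any(gamma <= 0 | gamma >= 1)) stop("gamma must be in (0, 1)")
  gamma * (1 - d) / (1 - gamma * d)
}

#' @rdname proofread_transform
#' @param e Observed post-proofreading error probability(ies).
#' @return For the inverse, the detection probability
#'   `d = (gamma - e) / (gamma * (1 - e))`, clipped to \[0, 1\]; `NA` (with a
#'   warning) where `e > gamma`, which the model cannot produce.
#' @export
proofread_detection <- function(gamma, e) {
  bad <- e > gamma
  if (any(bad)) warning("e > gamma: detection probability undefined")
  d <- (gamma - e) / (gamma * (1 - e))
  d <- pmin(pmax(d, 0), 1)
  d[bad] <- NA_real_
  d
}

#' Log-log amplification slope of proofreading
#'
#' Least-squares slope of `log10(e)` on `log10(gamma)` across contexts. A
#' slope of 1 means proofreading reduces all error rates proportionally; a
#' slope of 2 means the biases are squared, which arises when the
#' non-detection probability `1 - d[i]` is proportional to `gamma[i]` (the
#' most common errors are also the least likely to be caught).
#'
#' @param gamma,e Positive vectors (length >= 3) of pre- and
#'   post-proofreading error rates.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
amplification_slope <- function(gamma, e) {
  stopifnot(length(gamma) == length(e))
  keep <- gamma > 0 & e > 0
  if (any(!keep)) warning("zero entries excluded from slope fit")
  if (sum(keep) < 3L) stop("need at least 3 positive pairs")
  fit <- stats::lm(log10(e[keep]) ~ log10(gamma[keep]))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Two-subclass aggregation model
#'
#' Counts aggregate two subclasses of errors with subclass-specific
#' pre-correction rates and repair escape probabilities. The model predicts
#' the four genotype rates and the sign of the apparent epistasis
#' `log((mu_R * mu_LC) / (mu_MMR * mu_C))`: positive (super-multiplicative)
#' when proofreading and MMR preferentially repair the same subclass,
#' negative (sub-multiplicative) for opposite specificities, and zero when
#' either system treats both subclasses equally.
#'
#' @param gamma Length-2 pre-correction rates per subclass.
#' @param p_prf Length-2 proofreading escape probabilities in (0, 1].
#' @param p_mmr Length-2 MMR escape probabilities in (0, 1].
#' @return List with the four predicted rates (`mu_LC`, `mu_MMR`, `mu_C`,
#'   `mu_R`), `epistasis` (the log ratio) and `sign`.
#' @export
two_subclass_analyze <- function(gamma, p_prf, p_mmr) {
  stopifnot(length(gamma) == 2L, length(p_prf) == 2L, length(p_mmr) == 2L)
  if (any(gamma <= 0)) stop("gamma must be positive")
  if (any(p_prf <= 0 | p_prf > 1) || any(p_mmr <= 0 | p_mmr > 1))
    stop("escape probabilities must be in (0, 1]")
  mu_LC <- sum(gamma)
  mu_MMR <- sum(gamma * p_prf)
  mu_C <- sum(gamma * p_mmr)
  mu_R <- sum(gamma * p_prf * p_mmr)
  eps <- log((mu_R * mu_LC) / (mu_MMR * mu_C))
  list(mu_LC = mu_LC, mu_MMR = mu_MMR, mu_C = mu_C, mu_R = mu_R,
       epistasis = eps, sign = sign(round(eps, 12)))
}
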