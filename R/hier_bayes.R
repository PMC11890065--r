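## Hierarchical Bayesian estimation of per-context mutation rates.
##
## Model: m[i] ~ Poisson(mu[i] * T[i] * G), log10 mu[i] ~ Normal(M, S^2),
## with weakly informative hyperpriors M ~ Normal(-9, 3^2) and
## S ~ half-Normal(0, 2^2) on the log10 scale. Sampled by random-walk
## Metropolis within Gibbs: componentwise vectorized MH for the log-rates
## (conditionally independent given M, S), a conjugate Gibbs draw for M,
## and MH on log(S); proposal steps adapt during warmup toward ~44%
## acceptance and are then frozen.

LOG10 <- log(10)

#' Fit hierarchical per-context mutation rates
#'
#' Estimates the 64 stranded-triplet rates (or the 6 substitution-type
#' rates, or any other context partition) of one genotype, borrowing
#' strength across contexts through strain-level hyperparameters: the mean
#' `M` and standard deviation `S` of the log10 rates. Contexts with few or
#' zero counts shrink toward `M`, which yields finite estimates even for
#' contexts without observed mutations.
#'
#' @param table A [count_table()].
#' @param chains Number of chains (default 4).
#' @param iter Post-warmup draws per chain (default 10000).
#' @param warmup Adaptation iterations per chain, discarded (default 2000).
#' @param seed Integer RNG seed.
#' @param prior List with `M_mean`, `M_sd`, `S_sd` overriding the
#'   hyperpriors.
#' @param max_tries Additional doubled-warmup attempts when convergence
#'   (max split R-hat < 1.05) fails.
#' @return Object of class `hier_rates`: `draws` (matrix, post-warmup
#'   samples x contexts, log10 rates), `hyper` (columns `M`, `S`),
#'   `rhat`, `genotype`, `contexts`, plus the data.
#' @export
fit_hierarchical_rates <- function(table, chains = 4L, iter = 10000L,
                                   warmup = 2000L, seed = 1L,
                                   prior = list(M_mean = -9, M_sd = 3,
                                                S_sd = 2),
                                   max_tries = 2L) {
  keep <- table$T > 0
  m <- table$m[keep]; T_opp <- table$T[keep]; G <- table$G
  k <- length(m)
  if (!k) stop("no contexts with positive opportunities")
  expo <- T_opp * G

  for (attempt in seq_len(max_tries)) {
    res <- lapply(seq_len(chains), function(ch) {
      set.seed(seed + 1000L * (ch - 1L) + 7L * (attempt - 1L))
      hb_chain(m, expo, iter, warmup, prior)
    })
    draws <- do.call(rbind, lapply(res, `[[`, "l"))
    hyper <- do.call(rbind, lapply(res, `[[`, "hyper"))
    rhat <- hb_rhat(res, iter)
    if (rhat < 1.05) break
    warmup <- warmup * 2L
  }
  if (rhat >= 1.05)
    warning(sprintf("convergence not reached: max split R-hat = %.3f", rhat))
  colnames(draws) <- names(m)
  structure(list(draws = draws, hyper = hyper, rhat = rhat,
                 genotype = table$genotype, contexts = names(m),
                 m = m, T = T_opp, G = G,
                 chains = chains, iter = iter),
            class = "hier_rates")
}

## one chain; returns post-warmup log10-rate draws and hyper draws
hb_chain <- function(m, expo, iter, warmup, prior) {
  k <- length(m)
  ## init at (regularised) ML
  l <- log10((m + 0.5) / expo)
  M <- mean(l)
  S <- if (length(l) > 1L) max(stats::sd(l), 0.1) else 0.5
  step_l <- rep(0.5, k); step_s <- 0.5
  acc_l <- numeric(k); acc_s <- 0; batch <- 50L
  total <- warmup + iter
  out_l <- matrix(NA_real_, iter, k)
  out_h <- matrix(NA_real_, iter, 2L, dimnames = list(NULL, c("M", "S")))
  pm <- prior$M_mean; pv <- prior$M_sd^2; ps <- prior$S_sd

  for (t in seq_len(total)) {
    ## log10 rates: vectorized componentwise MH
    lp <- l + stats::rnorm(k, 0, step_l)
    dlp <- m * LOG10 * (lp - l) - expo * (10^lp - 10^l) +
      stats::dnorm(lp, M, S, log = TRUE) - stats::dnorm(l, M, S, log = TRUE)
    acc <- log(stats::runif(k)) < dlp
    l[acc] <- lp[acc]
    acc_l <- acc_l + acc

    ## M: conjugate normal draw
    prec <- k / S^2 + 1 / pv
    M <- stats::rnorm(1L, (sum(l) / S^2 + pm / pv) / prec, sqrt(1 / prec))

    ## S: MH on log scale, half-normal prior + Jacobian
    sp <- S * exp(stats::rnorm(1L, 0, step_s))
    dsp <- sum(stats::dnorm(l, M, sp, log = TRUE)) -
      sum(stats::dnorm(l, M, S, log = TRUE)) +
      (-sp^2 + S^2) / (2 * ps^2) + log(sp) - log(S)
    if (log(stats::runif(1L)) < dsp) { S <- sp; acc_s <- acc_s + 1 }

    ## warmup adaptation in batches
    if (t <= warmup && t %% batch == 0L) {
      step_l <- step_l * exp((acc_l / batch - 0.44) / 2)
      step_s <- step_s * exp((acc_s / batch - 0.44) / 2)
      acc_l[] <- 0; acc_s <- 0
    }
    if (t > warmup) {
      out_l[t - warmup, ] <- l
      out_h[t - warmup, ] <- c(M, S)
    }
  }
  list(l = out_l, hyper = out_h)
}

## max split R-hat over hyperparameters and log-rates
hb_rhat <- function(res, iter) {
  half <- iter %/% 2L
  if (half < 2L) return(1)
  mats <- lapply(res, function(r) cbind(r$l, r$hyper))
  splits <- unlist(lapply(mats, function(mm)
    list(mm[seq_len(half), , drop = FALSE],
         mm[(half + 1L):(2L * half), , drop = FALSE])), recursive = FALSE)
  nchain <- length(splits)
  means <- sapply(splits, colMeans)                    # params x chains
  vars <- sapply(splits, function(mm) apply(mm, 2L, stats::var))
  W <- rowMeans(vars)
  B <- half * apply(means, 1L, stats::var)
  vhat <- (half - 1) / half * W + B / half
  max(sqrt(vhat / pmax(W, 1e-300)), na.rm = TRUE)
}

#' @export
print.hier_rates <- function(x, ...) {
  cat(sprintf(
    "<hier_rates> %s: %d contexts, %d x %d post-warmup draws, max R-hat %.3f\n",
    x$genotype, length(x$contexts), x$chains, x$iter, x$rhat))
  h <- colMeans(x$hyper)
  cat(sprintf("  hyper: M = %.2f, S = %.2f (log10 rate scale)\n",
              h["M"], h["S"]))
  invisible(x)
}

#' @export
coef.hier_rates <- function(object, ...) {
  10^apply(object$draws, 2L, stats::median)
}

#' Posterior summaries per context
#'
#' Point estimate (posterior median) and central 50% and 95% credibility
#' intervals per context, on the rate scale.
#'
#' @param post A `hier_rates` fit (or any matrix of log10-rate draws with
#'   context columns).
#' @return data.frame with `context`, `median`, `q2.5`, `q25`, `q75`,
#'   `q97.5` (rates) and `log10_median`.
#' @export
summarize_posterior <- function(post) {
  draws <- if (inherits(post, "hier_rates")) post$draws else as.matrix(post)
  if (nrow(draws) < 1000L)
    warning("fewer than 1000 draws; quantiles will be noisy")
  qs <- apply(draws, 2L, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  data.frame(context = colnames(draws),
             median = 10^qs[3L, ], q2.5 = 10^qs[1L, ], q25 = 10^qs[2L, ],
             q75 = 10^qs[4L, ], q97.5 = 10^qs[5L, ],
             log10_median = qs[3L, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
summary.hier_rates <- function(object, ...) summarize_posterior(object)

## draw-aligned matrix pairs: subsample all to a common size
align_draws <- function(posts, n = NULL) {
  mats <- lapply(posts, function(p)
    if (inherits(p, "hier_rates")) p$draws else as.matrix(p))
  ctx <- colnames(mats[[1L]])
  for (mm in mats[-1L])
    if (!identical(colnames(mm), ctx)) stop("mismatched contexts")
  nmin <- min(vapply(mats, nrow, 1L))
  if (is.null(n)) n <- nmin
  idx <- lapply(mats, function(mm) sample.int(nrow(mm), n, replace = n > nrow(mm)))
  Map(function(mm, ii) mm[ii, , drop = FALSE], mats, idx)
}

#' Posterior probabilities for rate-ratio comparisons
#'
#' Monte-Carlo comparison of two rate ratios from four independent
#' posteriors: per context, `P(mu_A/mu_B > mu_C/mu_D)` from paired draws.
#' When `postC`/`postD` are omitted the ratio A/B is compared against 1.
#' Also returns credibility intervals of the log10 ratio A/B — e.g. the
#' apparent repair escape probabilities mu_MMR-/mu_LC* (proofreading) and
#' mu_R/mu_MMR- (MMR).
#'
#' @param postA,postB,postC,postD `hier_rates` fits (or log10-draw
#'   matrices) over the same contexts.
#' @param seed Seed for the draw pairing.
#' @return data.frame with `context`, `prob` and quantiles of
#'   `log10(mu_A/mu_B)`.
#' @export
posterior_ratio_prob <- function(postA, postB, postC = NULL, postD = NULL,
                                 seed = 1L) {
  set.seed(seed)
  posts <- list(postA, postB)
  have_cd <- !is.null(postC) && !is.null(postD)
  if (have_cd) posts <- c(posts, list(postC, postD))
  al <- align_draws(posts)
  lr_ab <- al[[1L]] - al[[2L]]
  rhs <- if (have_cd) al[[3L]] - al[[4L]] else 0
  prob <- colMeans(lr_ab > rhs)
  qs <- apply(lr_ab, 2L, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  data.frame(context = colnames(lr_ab), prob = prob,
             lr_median = qs[3L, ], lr_q2.5 = qs[1L, ], lr_q25 = qs[2L, ],
             lr_q75 = qs[4L, ], lr_q97.5 = qs[5L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation between log-rate profiles
#'
#' @param log_ratesA,log_ratesB Equal-length numeric vectors of log10 point
#'   estimates.
#' @return Pearson r; NA with a warning if either vector has zero variance.
#' @export
profile_correlation <- function(log_ratesA, log_ratesB) {
  stopifnot(length(log_ratesA) == length(log_ratesB))
  if (any(!is.finite(log_ratesA)) || any(!is.finite(log_ratesB)))
    stop("profiles must be finite")
  if (stats::sd(log_ratesA) == 0 || stats::sd(log_ratesB) == 0) {
    warning("zero variance profile; correlation undefined")
    return(NA_real_)
  }
  stats::cor(log_ratesA, log_ratesB)
}
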