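#' Per-context mutation count table
#'
#' The unit of all rate estimation: per genotype, mutation counts `m[i]` and
#' site opportunities `T[i]` per context, with the summed number of
#' generations `G` across MA lines.
#'
#' @param genotype Genotype label.
#' @param m Named integer vector of mutation counts per context.
#' @param T_opp Named numeric vector of opportunities (bp) per context;
#'   names must cover those of `m`.
#' @param G Total generations (lines summed).
#' @return An object of class `count_table`.
#' @export
count_table <- function(genotype, m, T_opp, G) {
  if (is.null(names(m)) && length(m) == 1L) names(m) <- "all"
  if (is.null(names(T_opp)) && length(T_opp) == 1L) names(T_opp) <- "all"
  if (!all(names(m) %in% names(T_opp)))
    stop("contexts of m must be a subset of contexts of T")
  if (any(m < 0) || any(m != round(m))) stop("m must be non-negative integers")
  if (any(T_opp <= 0)) stop("opportunities must be positive")
  if (G <= 0) stop("G must be positive")
  structure(list(genotype = genotype, m = m,
                 T = T_opp[names(m)], G = G),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s: %d contexts, %d mutations, G = %s generations\n",
              x$genotype, length(x$m), sum(x$m), format(x$G)))
  invisible(x)
}

#' @rdname count_table
#' @param path TSV path with columns genotype, context, m, T, G.
#' @export
read_count_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  count_table(x$genotype[1L], stats::setNames(x$m, x$context),
              stats::setNames(x$T, x$context), x$G[1L])
}

#' @rdname count_table
#' @param table A `count_table`.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(
    data.frame(genotype = table$genotype, context = names(table$m),
               m = table$m, T = table$T, G = table$G),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregated substitution counts of the B. subtilis hypermutator MA study
#'
#' The strain-level substitution counts from the mutation-accumulation
#' experiments analysed by this package: wild-type backgrounds (R168, R3610,
#' RPY79), MMR-deficient strains (dS, dL, Lstar and their aggregates), the
#' proofreading-deficient strain Cstar and the double-deficient LCstar.
#' `generations` and counts refer to intervals retained after excluding
#' intervals with a detected rate decrease; the `*_discarded` columns hold
#' the excluded generations/substitutions. All counts refer to the reference
#' subset of `3,794,734` well-covered positions.
#'
#' @return data.frame with one row per strain: `strain`, `lines`,
#'   `generations`, `substitutions`, `transitions`, `transversions`,
#'   `gens_discarded`, `subs_discarded`, `gens_per_step`, `T_ref`.
#' @export
strain_count_table <- function() {
  df <- data.frame(
    strain = c("R168", "R3610", "RPY79", "dS", "dL", "Lstar",
               "MMR-168", "MMR-3610", "MMR-PY79", "Cstar", "LCstar"),
    lines = c(4L, 50L, 75L, 4L, 4L, 4L, 12L, 19L, 118L, 4L, 4L),
    generations = c(3790, 251000, 272700, 2151, 2151, 2151,
                    6454, 38000, 105020, 1895, 230),
    substitutions = c(1L, 319L, 222L, 157L, 149L, 113L,
                      419L, 4844L, 5538L, 395L, 502L),
    transitions = c(1L, 238L, 178L, 155L, 147L, 111L,
                    413L, 4711L, 5432L, 348L, 484L),
    transversions = c(0L, 81L, 44L, 2L, 2L, 2L,
                      6L, 133L, 106L, 47L, 18L),
    gens_discarded = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 256, 896),
    subs_discarded = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 19L, 627L),
    gens_per_step = c(25.61, 27.53, 25.61, 25.61, 25.61, 25.61,
                      25.61, 27.53, 25.61, 25.61, 25.61),
    stringsAsFactors = FALSE)
  df$T_ref <- 3794734
  df
}

#' @rdname strain_count_table
#' @param strain Strain label, a row of `strain_count_table()`.
#' @export
strain_counts <- function(strain) {
  tab <- strain_count_table()
  row <- tab[tab$strain == strain, ]
  if (!nrow(row)) stop("unknown strain: ", strain)
  count_table(strain, c(all = row$substitutions),
              c(all = row$T_ref), row$generations)
}

#' Maximum-likelihood mutation rate with exact Poisson interval
#'
#' Point estimate `mu = m / (T * G)` with an exact Poisson confidence
#' interval for the count `m`, scaled by the exposure `T * G`.
#'
#' @param m Observed mutation count (integer).
#' @param T_opp Opportunities (bp).
#' @param G Generations.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `rate_estimate` with `point`, `ci_low`,
#'   `ci_high` in per-bp per-generation units.
#' @examples
#' ml_rate(157, 3794734, 2151)  # 1.9e-08 [1.6e-08, 2.2e-08]
#' @export
ml_rate <- function(m, T_opp, G, conf_level = 0.95) {
  if (length(m) != 1L || m < 0 || m != round(m))
    stop("m must be a single non-negative integer")
  if (T_opp <= 0 || G <= 0) stop("T and G must be positive")
  exposure <- T_opp * G
  ci <- stats::poisson.test(m, conf.level = conf_level)$conf.int / exposure
  structure(list(point = m / exposure, ci_low = ci[1L], ci_high = ci[2L],
                 level = conf_level, m = m, exposure = exposure,
                 kind = "rate"),
            class = "rate_estimate")
}

#' Exact binomial proportion (Clopper-Pearson)
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `rate_estimate` (unitless proportion).
#' @examples
#' binomial_proportion(81, 319)  # 0.25 [0.21, 0.31]
#' @export
binomial_proportion <- function(x, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (x < 0 || x > n) stop("x must be in [0, n]")
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  structure(list(point = x / n, ci_low = ci[1L], ci_high = ci[2L],
                 level = conf_level, m = x, exposure = n,
                 kind = "proportion"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 3, ...) {
  unit <- if (x$kind == "rate") " bp^-1.gen^-1" else ""
  cat(sprintf("%s [%s%% CI %s, %s]%s\n",
              signif(x$point, digits), format(100 * x$level),
              signif(x$ci_low, digits), signif(x$ci_high, digits), unit))
  invisible(x)
}

#' @export
coef.rate_estimate <- function(object, ...) {
  c(point = object$point, ci_low = object$ci_low, ci_high = object$ci_high)
}

#' Poisson regression test for a categorical rate factor
#'
#' Fits log-link Poisson GLMs for the counts with and without the factor
#' (with log-exposure offsets) and compares them by analysis of deviance
#' (likelihood-ratio chi-square).
#'
#' @param counts Integer counts per category.
#' @param exposures Exposures (T * G) per category.
#' @param factor_labels Factor of the same length assigning categories to
#'   levels of the factor under test.
#' @return List with `p_value`, `deviance` (LR statistic), `df`.
#' @export
poisson_glm_lrt <- function(counts, exposures, factor_labels) {
  f <- factor(factor_labels)
  if (nlevels(f) < 2L) stop("need at least two factor levels")
  if (all(counts == 0)) return(list(p_value = 1, deviance = 0,
                                    df = nlevels(f) - 1L))
  off <- log(exposures)
  full <- stats::glm(counts ~ f + offset(off), family = stats::poisson())
  null <- stats::glm(counts ~ 1 + offset(off), family = stats::poisson())
  an <- stats::anova(null, full, test = "Chisq")
  p <- an[["Pr(>Chi)"]][2L]
  if (is.na(p)) p <- 1    # zero deviance difference
  list(p_value = p, deviance = an$Deviance[2L], df = an$Df[2L])
}

#' Detect mutation-rate decreases along an MA line
#'
#' Sequencing intervals are tested in time order: each interval's count is
#' compared one-sided against the rate pooled over the preceding non-flagged
#' intervals, with an exact conditional binomial test (given the total count
#' of the interval and the pooled reference, the interval count is binomial
#' with success probability equal to its share of the exposure). Flagged
#' intervals (and their mutations) are excluded from the pooled reference
#' for the next tests and from downstream rate estimates.
#'
#' @param m Integer vector of new mutations per interval, in time order.
#' @param G Generations per interval.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with `interval`, `m`, `G`, `p_value`, `flagged`.
#' @export
detect_rate_decrease <- function(m, G, alpha = 0.05) {
  stopifnot(length(m) == length(G), length(m) >= 1L)
  n <- length(m)
  p <- rep(NA_real_, n); flag <- rep(FALSE, n)
  for (j in seq_len(n)[-1L]) {
    keep <- which(seq_len(j - 1L) > 0 & !flag[seq_len(j - 1L)])
    m0 <- sum(m[keep]); G0 <- sum(G[keep])
    if (G0 <= 0 || m0 + m[j] == 0) next
    pr <- G[j] / (G[j] + G0)
    p[j] <- stats::binom.test(m[j], m[j] + m0, p = pr,
                              alternative = "less")$p.value
    flag[j] <- p[j] < alpha
  }
  data.frame(interval = seq_len(n), m = m, G = G, p_value = p,
             flagged = flag)
}

#' Fold change between two genotypes' mutation rates
#'
#' Ratio of the maximum-likelihood rates of two count tables (summed over
#' contexts); a shared opportunity denominator cancels.
#'
#' @param numerator,denominator [count_table()] objects.
#' @return The rate ratio (numeric scalar).
#' @examples
#' fold_change(strain_counts("Cstar"), strain_counts("R3610"))  # ~164
#' @export
fold_change <- function(numerator, denominator) {
  rn <- sum(numerator$m) / (sum(numerator$T) * numerator$G)
  rd <- sum(denominator$m) / (sum(denominator$T) * denominator$G)
  if (rd == 0) {
    warning("denominator rate is zero; fold change undefined")
    return(NaN)
  }
  rn / rd
}
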