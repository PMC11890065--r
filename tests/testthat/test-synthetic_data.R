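test_that("simulated genomes honor GC content, landmarks and the seed", {
  g <- make_genome(10000, gc = 0.435, seed = 1)
  gc <- mean(g$bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.435), 0.02)
  g2 <- make_genome(10000, gc = 0.435, seed = 1)
  expect_identical(g$sequence, g2$sequence)
  g3 <- make_genome(10000, gc = 0.435, seed = 2)
  expect_false(identical(g$sequence, g3$sequence))
  expect_error(make_genome(10000, gc = 1.0), "gc")
  expect_error(make_genome(50), "length")
})

test_that("MA simulation matches the Poisson mean and supports decreases", {
  g <- make_genome(3000, seed = 3)
  ctx <- triplet_contexts()
  rates <- setNames(rep(0, 64), ctx)
  target <- names(which.max(count_opportunities(g)))
  rates[target] <- 2e-5
  # expected total r * T * G over lines
  T_ctx <- count_opportunities(g)[[target]]
  totals <- vapply(1:50, function(s)
    nrow(simulate_ma_experiment(g, rates, lines = 2, steps = 5,
                                gens_per_step = 25, seed = s)$mutations), 1)
  expected <- 2e-5 * T_ctx * 25 * 5 * 2
  se <- sqrt(expected / 50)
  expect_lt(abs(mean(totals) - expected), 3 * se)
  # zero rates give an empty table
  empty <- simulate_ma_experiment(g, setNames(rep(0, 64), ctx), seed = 1)
  expect_equal(nrow(empty$mutations), 0)
  # mutations land only on sites of their context
  sim <- simulate_ma_experiment(g, rates, lines = 2, steps = 5, seed = 4)
  expect_true(all(sim$mutations$context == target))
  sites <- context_sites(g)[[target]]
  expect_true(all(sim$mutations$position %in% sites))
  # no position reused within a line
  expect_false(any(duplicated(
    sim$mutations[c("line_id", "position")])))
})

test_that("an injected rate decrease lowers downstream interval rates", {
  g <- make_genome(4000, seed = 6)
  rates <- setNames(rep(1e-5, 64), triplet_contexts())
  pre <- 0; post <- 0
  for (s in 1:15) {
    sim <- simulate_ma_experiment(g, rates, lines = 1, steps = 10,
                                  gens_per_step = 25,
                                  decrease = list(line = 1, step = 6,
                                                  factor = 0.1),
                                  seed = s)
    pre <- pre + sum(sim$mutations$step < 6)
    post <- post + sum(sim$mutations$step >= 6)
  }
  expect_lt(abs(post / pre - 0.1), 0.05)
})

test_that("pileups render planted mutations and pooled frequencies", {
  g <- make_genome(2000, seed = 9)
  rates <- setNames(rep(2e-5, 64), triplet_contexts())
  sim <- simulate_ma_experiment(g, rates, lines = 4, steps = 8,
                                gens_per_step = 25, seed = 11)
  expect_gt(nrow(sim$mutations), 10)
  pus <- simulate_pileups(g, sim$mutations, depth = 300, error_rate = 0,
                          pool_steps = 8, seed = 12)
  # endpoint: alt frequency 1 at planted sites (no noise)
  ln <- sim$mutations$line_id[1]
  mm <- sim$mutations[sim$mutations$line_id == ln, ]
  pu <- pus$endpoint[[ln]]
  for (i in seq_len(nrow(mm))) {
    alt <- mm$alt[i]; p <- mm$position[i]
    altn <- pu[[paste0(alt, "f")]][p] + pu[[paste0(alt, "r")]][p]
    expect_equal(altn, unname(mutacc:::dpeff(pu[p, ])))
  }
  # pool at the final step: frequency ~ (lines carrying)/4
  pool <- pus$pools$step8
  singletons <- names(which(table(sim$mutations$position) == 1))
  p1 <- as.integer(singletons[1])
  altb <- sim$mutations$alt[sim$mutations$position == p1]
  altn <- pool[[paste0(altb, "f")]][p1] + pool[[paste0(altb, "r")]][p1]
  dp <- mutacc:::dpeff(pool[p1, ])
  expect_gt(altn / dp, qbinom(0.0005, 300, 0.25) / 300)
  expect_lt(altn / dp, qbinom(0.9995, 300, 0.25) / 300)
})

test_that("low sequencing noise produces no false calls at the 75% rule", {
  g <- make_genome(10000, seed = 13)
  pus <- simulate_pileups(g, data.frame(line_id = character(),
                                        step = integer(), position = integer(),
                                        ref = character(), alt = character(),
                                        class = character(),
                                        context = character()),
                          depth = 300, error_rate = 0.001, seed = 14)
  rec <- call_endpoint_mutations(pus$endpoint[[1]], g)
  expect_equal(nrow(rec), 0)
})

test_that("four-genotype tables follow the saturation-model expectations", {
  gamma <- setNames(c(3e-7, 1e-7), c("C>T", "T>C"))
  tabs <- simulate_four_genotypes(gamma, q = 0.01, theta = 0, r_prf = 0.03,
                                  T_opp = 1e6,
                                  G = c(R = 5e4, MMR = 5e3, C = 2e3, LC = 200),
                                  seed = 3)
  tr <- tabs$truth
  # multiplicative structure at theta = 0: mu_C = gamma q, mu_R = mu_MMR q
  expect_equal(tr$mu$C, tr$gamma * tr$q, ignore_attr = TRUE)
  expect_equal(tr$mu$R, tr$mu$MMR * tr$q, ignore_attr = TRUE)
  expect_equal(names(tabs$LC$m), names(gamma))
  # determinism
  tabs2 <- simulate_four_genotypes(gamma, 0.01, 0, 0.03, 1e6,
                                   c(R = 5e4, MMR = 5e3, C = 2e3, LC = 200),
                                   seed = 3)
  expect_identical(tabs$C$m, tabs2$C$m)
  # counts are Poisson around mu * T * G
  expect_lt(abs(sum(tabs$LC$m) -
                  sum(tr$mu$LC * 1e6 * 200)) /
              sqrt(sum(tr$mu$LC * 1e6 * 200)), 4)
})

test_that("fluctuation draws match the MSS distribution", {
  assay0 <- simulate_fluctuation(0, 1e8, 50, seed = 1)
  expect_true(all(assay0$cfu == 0))
  big <- simulate_fluctuation(1, 1e8, 10000, seed = 2)
  p0_hat <- mean(big$cfu == 0)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 10000)
  expect_lt(abs(p0_hat - exp(-1)), 3 * se)
  # binomial thinning reduces counts ~4-fold on the same base draws
  full <- simulate_fluctuation(2, 1e8, 4000, seed = 7)
  thin <- simulate_fluctuation(2, 1e8, 4000, plating_fraction = 0.25,
                               seed = 7)
  expect_equal(mean(thin$cfu) / mean(full$cfu), 0.25, tolerance = 0.05)
})

test_that("the YAML-driven study generator writes every artifact with truth", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 5,
              genome = list(length = 1500, gc = 0.435, ter = 750),
              ma = list(rate = 1e-5, lines = 2, steps = 4,
                        gens_per_step = 25.61),
              sequencing = list(depth = 120, pool_steps = 4),
              four_genotypes = list(gamma = c(3e-7, 1e-7), q = c(0.01, 0.02),
                                    theta = 0.08, r_prf = 0.03,
                                    T = c(1e6, 1e6), G_R = 5e4, G_MMR = 5e3,
                                    G_C = 2e3, G_LC = 200),
              fluctuation = list(m = 1, Nt = 1e8, cultures = 20))
  yml <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, yml)
  out <- simulate_study(yml, file.path(dir, "out"))
  files <- list.files(file.path(dir, "out"))
  expect_true(all(c("genome.fasta", "mutations.tsv", "counts_R.tsv",
                    "assay.tsv", "truth.json") %in% files))
  expect_true(any(grepl("^pileup_L1", files)))
  expect_true(any(grepl("^pileup_pool", files)))
  truth <- jsonlite::read_json(file.path(dir, "out", "truth.json"))
  expect_equal(truth$four_genotypes$theta, 0.08)
  # regenerating with the same config is bit-identical
  out2 <- simulate_study(yml, file.path(dir, "out2"))
  expect_identical(readLines(file.path(dir, "out", "mutations.tsv")),
                   readLines(file.path(dir, "out2", "mutations.tsv")))
})

test_that("simulate -> call -> count -> estimate recovers the planted rates", {
  g <- make_genome(12000, seed = 21)
  ctx <- triplet_contexts()
  set.seed(22)
  rates <- setNames(10^runif(64, -5.6, -5.0), ctx)
  sim <- simulate_ma_experiment(g, rates, lines = 4, steps = 21,
                                gens_per_step = 25.61, seed = 23)
  pus <- simulate_pileups(g, sim$mutations, depth = 300, error_rate = 0,
                          seed = 24)
  called <- do.call(rbind, lapply(names(pus$endpoint), function(ln) {
    rec <- call_endpoint_mutations(pus$endpoint[[ln]], g)
    rec$line_id <- rep(ln, nrow(rec))
    rec
  }))
  called <- to_pyrimidine_class(called, g)
  # precision and recall of the calling stage are exact without noise
  key <- function(df) paste(df$line_id, df$position)
  expect_setequal(key(called), key(sim$mutations))
  # per-context rates: truth inside the exact CI for >= 90% of contexts
  opp <- count_opportunities(g)
  G_tot <- 4 * 21 * 25.61
  m_ctx <- table(factor(called$context, levels = ctx))
  cover <- vapply(ctx, function(cc) {
    if (opp[[cc]] == 0) return(NA)
    r <- ml_rate(as.integer(m_ctx[[cc]]), opp[[cc]], G_tot)
    r$ci_low <= rates[[cc]] && rates[[cc]] <= r$ci_high
  }, TRUE)
  expect_gte(mean(cover, na.rm = TRUE), 0.90)
})
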