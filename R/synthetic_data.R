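## Generators for every input the pipeline consumes, with the statistical
## structure the analysis assumes: a random genome, per-context Poisson
## mutation accumulation along bottlenecked lines, endpoint and pooled
## pileups with binomial sequencing noise, four-genotype count tables under
## the saturation model, and Luria-Delbruck assay counts. All generators are
## deterministic under a fixed seed. Mutation defaults mirror the MA design
## emulated throughout the package: 4 parallel lines, 21 MA-steps of 25.61
## generations, mean sequencing depth 300.

#' Simulate a random genome
#'
#' I.i.d. bases at a requested GC content (default 0.435, the B. subtilis
#' chromosome value), with replication origin and terminus recorded.
#'
#' @param length Genome length in bp (>= 100).
#' @param gc GC fraction in (0, 1).
#' @param ori,ter Origin/terminus positions (defaults: 1 and length/2,
#'   i.e. symmetric replichores).
#' @param seed Integer RNG seed.
#' @param id Sequence identifier.
#' @return A [ref_genome()] with a full mask.
#' @export
make_genome <- function(length, gc = 0.435, ori = 1L, ter = NULL,
                        seed = 1L, id = "sim_chr") {
  if (length < 100) stop("length must be >= 100")
  if (gc <= 0 || gc >= 1) stop("gc must be inside (0, 1)")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  ref_genome(paste(bases, collapse = ""), id = id, ori = ori, ter = ter)
}

#' Simulate a mutation-accumulation experiment
#'
#' For each line and MA-step, draws per-context new-mutation counts
#' `Poisson(rate * T[i] * gens_per_step)` and places them uniformly (without
#' replacement within a line) on the sites of that context. An optional rate
#' decrease multiplies the rates of one line from a given step onward.
#' Substitution alleles are the transition partner of the focal pyrimidine.
#'
#' @param genome A [ref_genome()].
#' @param true_rates Named rates per stranded-triplet context (names from
#'   [triplet_contexts()]; missing contexts get rate 0), per bp per
#'   generation.
#' @param lines Number of MA lines (default 4).
#' @param steps MA-steps per line (default 21).
#' @param gens_per_step Generations per step (default 25.61).
#' @param decrease Optional `list(line =, step =, factor =)` applying a
#'   rate multiplier from `step` onward in `line`.
#' @param seed Integer RNG seed.
#' @return List with `mutations` (data.frame: `line_id`, `step`,
#'   `position`, `ref`, `alt`, `class`, `context`) and `truth` (the
#'   arguments and per-context expected counts).
#' @export
simulate_ma_experiment <- function(genome, true_rates, lines = 4L,
                                   steps = 21L, gens_per_step = 25.61,
                                   decrease = NULL, seed = 1L) {
  if (any(true_rates < 0)) stop("rates must be non-negative")
  set.seed(seed)
  sites <- context_sites(genome)
  ctx <- intersect(names(true_rates)[true_rates > 0], names(sites))
  out <- list()
  for (ln in seq_len(lines)) {
    used <- integer()
    for (st in seq_len(steps)) {
      fac <- if (!is.null(decrease) && ln == decrease$line &&
                 st >= decrease$step) decrease$factor else 1
      for (cc in ctx) {
        avail <- setdiff(sites[[cc]], used)
        lam <- true_rates[[cc]] * length(sites[[cc]]) * gens_per_step * fac
        n <- stats::rpois(1L, lam)
        if (n > length(avail)) {
          warning("requested mutations exceed available sites; truncating")
          n <- length(avail)
        }
        if (n == 0L) next
        pos <- if (length(avail) == 1L) avail else sample(avail, n)
        used <- c(used, pos)
        ref <- genome$bases[pos]
        alt <- unname(c(A = "G", G = "A", C = "T", T = "C")[ref])
        out[[length(out) + 1L]] <- data.frame(
          line_id = paste0("L", ln), step = st, position = pos,
          ref = ref, alt = alt, class = "substitution", context = cc,
          stringsAsFactors = FALSE)
      }
    }
  }
  muts <- if (length(out)) do.call(rbind, out) else
    data.frame(line_id = character(), step = integer(), position = integer(),
               ref = character(), alt = character(), class = character(),
               context = character(), stringsAsFactors = FALSE)
  muts <- muts[order(muts$line_id, muts$step, muts$position), ]
  rownames(muts) <- NULL
  opp <- vapply(sites, length, 1L)
  list(mutations = muts,
       truth = list(true_rates = true_rates, lines = lines, steps = steps,
                    gens_per_step = gens_per_step, decrease = decrease,
                    opportunities = opp,
                    expected_counts = true_rates[names(opp)] * opp *
                      gens_per_step * steps * lines))
}

empty_pileup <- function(genome) {
  L <- genome$length
  data.frame(pos = seq_len(L), ref = genome$bases,
             Af = 0L, Cf = 0L, Gf = 0L, Tf = 0L,
             Ar = 0L, Cr = 0L, Gr = 0L, Tr = 0L,
             ins = 0L, del = 0L, stringsAsFactors = FALSE)
}

## fill one sample's pileup given per-position alt allele frequencies
fill_pileup <- function(genome, alt_freq, alt_base, depth, error_rate) {
  pu <- empty_pileup(genome)
  L <- genome$length
  dp <- stats::rpois(L, depth)
  alt_n <- stats::rbinom(L, dp, alt_freq)
  ref_n <- dp - alt_n
  ## sequencing errors scatter a fraction of ref reads to the 3 other bases
  err_n <- stats::rbinom(L, ref_n, error_rate)
  ref_n <- ref_n - err_n
  bases <- c("A", "C", "G", "T")
  for (b in bases) {
    n_b <- integer(L)
    sel <- genome$bases == b
    n_b[sel] <- n_b[sel] + ref_n[sel]
    selA <- !is.na(alt_base) & alt_base == b
    n_b[selA] <- n_b[selA] + alt_n[selA]
    ## errors split over the three non-ref bases
    selE <- genome$bases != b
    n_b[selE] <- n_b[selE] + stats::rbinom(sum(selE), err_n[selE], 1 / 3)
    fwd <- stats::rbinom(L, n_b, 0.5)
    pu[[paste0(b, "f")]] <- fwd
    pu[[paste0(b, "r")]] <- n_b - fwd
  }
  pu
}

#' Simulate endpoint and pooled pileups from planted mutations
#'
#' Endpoint samples carry each line's mutations at frequency ~1 (with
#' Poisson depth and binomial strand split and sequencing noise); pooled
#' samples at a given MA-step carry a mutation at frequency (lines carrying
#' it by that step) / lines.
#'
#' @param genome A [ref_genome()].
#' @param mutations Mutation data.frame from [simulate_ma_experiment()]
#'   (substitutions are rendered; indels are not emitted by the generator).
#' @param depth Mean sequencing depth (default 300).
#' @param error_rate Per-read probability of a miscalled base (default 0).
#' @param pool_steps MA-steps at which pooled samples are taken.
#' @param seed Integer RNG seed.
#' @return List with `endpoint` (named list of pileups per line) and
#'   `pools` (named list of pileups per pooled step).
#' @export
simulate_pileups <- function(genome, mutations, depth = 300,
                             error_rate = 0, pool_steps = integer(),
                             seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  lines <- sort(unique(mutations$line_id))
  if (!length(lines)) lines <- "L1"
  L <- genome$length
  endpoint <- list()
  for (ln in lines) {
    mm <- mutations[mutations$line_id == ln, ]
    af <- numeric(L); ab <- rep(NA_character_, L)
    af[mm$position] <- 1; ab[mm$position] <- mm$alt
    endpoint[[ln]] <- fill_pileup(genome, af, ab, depth, error_rate)
  }
  pools <- list()
  for (st in pool_steps) {
    af <- numeric(L); ab <- rep(NA_character_, L)
    mm <- mutations[mutations$step <= st, ]
    if (nrow(mm)) {
      byp <- tapply(mm$line_id, mm$position, function(x) length(unique(x)))
      pos <- as.integer(names(byp))
      af[pos] <- as.numeric(byp) / length(lines)
      ab[pos] <- mm$alt[match(pos, mm$position)]
    }
    pools[[paste0("step", st)]] <- fill_pileup(genome, af, ab, depth,
                                               error_rate)
  }
  list(endpoint = endpoint, pools = pools)
}

#' Simulate four-genotype count tables under the saturation model
#'
#' Counts are Poisson with rates `mu_LC = gamma`, `mu_MMR = gamma * r_prf`,
#' `mu_R = mu_MMR * q`, and
#' `mu_C = gamma * (theta + (1 - theta) * q)` per context.
#'
#' @param gamma Named pre-repair rates per context.
#' @param q MMR escape probabilities per context (recycled).
#' @param theta Saturation mixture proportion.
#' @param r_prf Proofreading escape probability (mu_MMR / gamma; recycled).
#' @param T_opp Opportunities per context (recycled).
#' @param G Named numeric: generations for genotypes `R`, `MMR`, `C`, `LC`.
#' @param seed Integer RNG seed.
#' @return Named list of four [count_table()]s (`R`, `MMR`, `C`, `LC`) plus
#'   a `truth` element with the generating rates.
#' @export
simulate_four_genotypes <- function(gamma, q, theta, r_prf, T_opp, G,
                                    seed = 1L) {
  stopifnot(all(c("R", "MMR", "C", "LC") %in% names(G)))
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  k <- length(gamma)
  if (is.null(names(gamma))) names(gamma) <- paste0("ctx", seq_len(k))
  q <- rep_len(q, k); r_prf <- rep_len(r_prf, k); T_opp <- rep_len(T_opp, k)
  names(T_opp) <- names(gamma)
  mu <- list(R = gamma * r_prf * q, MMR = gamma * r_prf,
             C = gamma * (theta + (1 - theta) * q), LC = gamma)
  set.seed(seed)
  tabs <- lapply(c("R", "MMR", "C", "LC"), function(g) {
    m <- stats::rpois(k, mu[[g]] * T_opp * G[[g]])
    names(m) <- names(gamma)
    count_table(g, m, T_opp, G[[g]])
  })
  names(tabs) <- c("R", "MMR", "C", "LC")
  tabs$truth <- list(gamma = gamma, q = q, theta = theta, r_prf = r_prf,
                     mu = mu, T_opp = T_opp, G = G)
  tabs
}

#' Simulate a fluctuation assay
#'
#' Per-culture mutant counts drawn from the Luria-Delbruck (MSS)
#' distribution, with per-culture exposure scaling by the final cell number
#' and optional binomial thinning for plating a fraction of each culture.
#'
#' @param m Expected mutations per culture at the reference (median) final
#'   cell number.
#' @param Nt Final cell number: scalar or one per culture.
#' @param cultures Number of cultures.
#' @param plating_fraction Fraction of each culture plated (default 1).
#' @param n_max Truncation point of the sampled distribution; tail draws
#'   are assigned `n_max` (default 10000).
#' @param seed Integer RNG seed.
#' @return data.frame with `culture_id`, `cfu`, `Nt`.
#' @export
simulate_fluctuation <- function(m, Nt, cultures, plating_fraction = 1,
                                 n_max = 10000L, seed = 1L) {
  if (m < 0) stop("m must be non-negative")
  set.seed(seed)
  Ntv <- rep_len(Nt, cultures)
  w <- Ntv / stats::median(Ntv)
  cfu <- integer(cultures)
  for (ww in unique(w)) {
    sel <- which(w == ww)
    pm <- ld_pmf(m * ww, n_max)
    cdf <- cumsum(pm)
    u <- stats::runif(length(sel))
    cfu[sel] <- findInterval(u, cdf)      # tail mass -> n_max + 1
    cfu[sel] <- pmin(cfu[sel], n_max)
  }
  if (plating_fraction < 1)
    cfu <- stats::rbinom(cultures, cfu, plating_fraction)
  data.frame(culture_id = paste0("c", seq_len(cultures)), cfu = cfu,
             Nt = Ntv, stringsAsFactors = FALSE)
}

#' Run every generator from a YAML configuration
#'
#' Reads a simulation configuration (seed, genome, rates, MA design,
#' sequencing, four-genotype and fluctuation parameters), runs the
#' generators, and writes FASTA, pileup/mutation/count-table/assay TSVs and
#' a machine-readable truth JSON into `dir`.
#'
#' @param config Path to a YAML file or an equivalent named list. Keys:
#'   `seed`, `genome` (length, gc, ori, ter), `ma` (rate, contexts, lines,
#'   steps, gens_per_step), `sequencing` (depth, error_rate, pool_steps),
#'   `four_genotypes` (gamma, q, theta, r_prf, T, G_R, G_MMR, G_C, G_LC),
#'   `fluctuation` (m, Nt, cultures, plating_fraction). Sections are
#'   optional; only requested outputs are produced.
#' @param dir Output directory (created).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(config, dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  out <- list()
  truth <- list(seed = seed)

  if (!is.null(cfg$genome)) {
    gc <- cfg$genome
    genome <- make_genome(gc$length, gc = gc$gc %||% 0.435,
                          ori = gc$ori %||% 1L, ter = gc$ter,
                          seed = seed)
    write_genome_fasta(genome, file.path(dir, "genome.fasta"))
    out$genome <- genome

    if (!is.null(cfg$ma)) {
      ma <- cfg$ma
      rates <- stats::setNames(rep(ma$rate, length(triplet_contexts())),
                               triplet_contexts())
      sim <- simulate_ma_experiment(genome, rates,
                                    lines = ma$lines %||% 4L,
                                    steps = ma$steps %||% 21L,
                                    gens_per_step = ma$gens_per_step %||% 25.61,
                                    seed = seed + 1L)
      write_mutations_tsv(sim$mutations, file.path(dir, "mutations.tsv"))
      out$ma <- sim
      truth$ma <- sim$truth[c("lines", "steps", "gens_per_step")]
      truth$ma$n_mutations <- nrow(sim$mutations)

      sq <- cfg$sequencing
      if (!is.null(sq)) {
        pus <- simulate_pileups(genome, sim$mutations,
                                depth = sq$depth %||% 300,
                                error_rate = sq$error_rate %||% 0,
                                pool_steps = sq$pool_steps %||% integer(),
                                seed = seed + 2L)
        for (nm in names(pus$endpoint))
          write_pileup(pus$endpoint[[nm]],
                       file.path(dir, paste0("pileup_", nm, ".tsv")))
        for (nm in names(pus$pools))
          write_pileup(pus$pools[[nm]],
                       file.path(dir, paste0("pileup_pool_", nm, ".tsv")))
        out$pileups <- pus
      }
    }
  }

  if (!is.null(cfg$four_genotypes)) {
    fg <- cfg$four_genotypes
    tabs <- simulate_four_genotypes(
      gamma = unlist(fg$gamma), q = unlist(fg$q), theta = fg$theta,
      r_prf = unlist(fg$r_prf), T_opp = unlist(fg$T),
      G = c(R = fg$G_R, MMR = fg$G_MMR, C = fg$G_C, LC = fg$G_LC),
      seed = seed + 3L)
    for (g in c("R", "MMR", "C", "LC"))
      write_count_table(tabs[[g]], file.path(dir, paste0("counts_", g, ".tsv")))
    out$four_genotypes <- tabs
    truth$four_genotypes <- tabs$truth[c("theta", "q", "r_prf")]
  }

  if (!is.null(cfg$fluctuation)) {
    fl <- cfg$fluctuation
    assay <- simulate_fluctuation(fl$m, fl$Nt, fl$cultures,
                                  plating_fraction = fl$plating_fraction %||% 1,
                                  seed = seed + 4L)
    write_assay(assay, file.path(dir, "assay.tsv"))
    out$fluctuation <- assay
    truth$fluctuation <- fl
  }

  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
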