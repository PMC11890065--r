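# shared fixtures and slow-but-simple oracles used across test files

# independent per-position triplet classifier (string ops only), used as the
# brute-force oracle for classify_site / count_opportunities
oracle_classify <- function(seq, ori, ter, pos) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(seq, "")[[1]]
  ctr <- b[pos]
  trip <- paste0(b[pos - 1], ctr, b[pos + 1])
  if (!ctr %in% c("C", "T")) {
    trip <- paste(rev(unname(comp[strsplit(trip, "")[[1]]])), collapse = "")
  }
  in_r1 <- if (ori < ter) pos > ori && pos <= ter else (pos > ori || pos <= ter)
  plus_pyr <- ctr %in% c("C", "T")
  lead <- (plus_pyr && in_r1) || (!plus_pyr && !in_r1)
  paste0(trip, ":", if (lead) "leading" else "lagging")
}

# a small pileup data.frame builder: one row per position
pileup_row <- function(pos, ref, counts) {
  df <- data.frame(pos = pos, ref = ref,
                   Af = 0L, Cf = 0L, Gf = 0L, Tf = 0L,
                   Ar = 0L, Cr = 0L, Gr = 0L, Tr = 0L,
                   ins = 0L, del = 0L, stringsAsFactors = FALSE)
  for (nm in names(counts)) df[[nm]] <- counts[[nm]]
  df
}

# clean homogeneous pileup for a genome: every position covered at `depth`
# by the reference base, split evenly over strands
flat_pileup <- function(genome, depth = 200L) {
  pu <- mutacc:::empty_pileup(genome)
  half <- depth %/% 2L
  for (b in c("A", "C", "G", "T")) {
    sel <- genome$bases == b
    pu[[paste0(b, "f")]][sel] <- half
    pu[[paste0(b, "r")]][sel] <- depth - half
  }
  pu
}

# exact Poisson expectation oracles for the capacity model
oracle_excess_mean <- function(k, lambda, nmax = 200) {
  n <- 0:nmax
  sum(pmax(n - k, 0) * dpois(n, lambda))
}
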