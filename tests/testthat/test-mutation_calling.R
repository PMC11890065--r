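test_that("reference subset applies the depth and strand rules in all samples", {
  g <- make_genome(1000, seed = 5)
  good <- flat_pileup(g, 150L)        # 75:75 per strand everywhere
  # sample 2: a planted low-coverage block and one strand-biased position
  bad <- flat_pileup(g, 150L)
  block <- 401:450
  for (b in c("A", "C", "G", "T")) {
    f <- paste0(b, "f"); r <- paste0(b, "r")
    bad[[f]][block] <- pmin(bad[[f]][block], 49L)
    bad[[r]][block] <- pmin(bad[[r]][block], 50L)  # DPeff 99 at best
  }
  strand_pos <- 700L
  bb <- g$bases[strand_pos]
  bad[[paste0(bb, "f")]][strand_pos] <- 190L
  bad[[paste0(bb, "r")]][strand_pos] <- 10L        # 5% minor strand
  mask <- build_reference_subset(list(good, bad))
  expect_false(any(block %in% mask))
  expect_false(strand_pos %in% mask)
  expect_setequal(setdiff(seq_len(1000), mask), c(block, strand_pos))

  # boundary: DPeff exactly 100 with 10% minor strand passes
  edge <- pileup_row(1L, "A", list(Af = 90L, Ar = 10L))
  g1 <- ref_genome("A")
  expect_equal(build_reference_subset(list(edge)), 1L)
  edge99 <- pileup_row(1L, "A", list(Af = 89L, Ar = 10L))
  expect_length(build_reference_subset(list(edge99)), 0)

  # exclusion intervals removed
  mask2 <- build_reference_subset(list(good),
                                  exclusions = data.frame(start = 1, end = 10))
  expect_false(any(1:10 %in% mask2))
})

test_that("endpoint calling applies the 75% / 10% minor-strand rules", {
  g <- ref_genome("AAAAA", ori = 1, ter = 3)
  # DPeff 200, alt 160 (80%) with strand split 140:20 -> called
  pu <- pileup_row(3L, "A", list(Af = 20L, Ar = 20L, Gf = 140L, Gr = 20L))
  rec <- call_endpoint_mutations(pu, g)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$alt, "G")
  expect_equal(rec$freq, 0.8)
  # 50% frequency -> not called
  pu2 <- pileup_row(3L, "A", list(Af = 50L, Ar = 50L, Gf = 60L, Gr = 40L))
  expect_equal(nrow(call_endpoint_mutations(pu2, g)), 0)
  # alt strand split 95:5 (5% minor) -> rejected even at high frequency
  pu3 <- pileup_row(3L, "A", list(Af = 10L, Ar = 10L, Gf = 171L, Gr = 9L))
  expect_equal(nrow(call_endpoint_mutations(pu3, g)), 0)
  # the configurable threshold admits a 60% variant when lowered
  pu4 <- pileup_row(3L, "A", list(Af = 40L, Ar = 40L, Gf = 60L, Gr = 60L))
  expect_equal(nrow(call_endpoint_mutations(pu4, g)), 0)
  expect_equal(nrow(call_endpoint_mutations(pu4, g, freq_min = 0.60)), 1)
  expect_error(call_endpoint_mutations(
    pileup_row(3L, "A", list(Af = -1L)), g), "negative")
})

test_that("calling on a planted fixture equals direct rule application", {
  set.seed(42)
  g <- make_genome(100, seed = 42)
  pu <- flat_pileup(g, 200L)
  truth <- sort(sample(2:99, 12))
  for (p in truth) {
    ref <- g$bases[p]
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    pu[[paste0(ref, "f")]][p] <- 15L; pu[[paste0(ref, "r")]][p] <- 15L
    pu[[paste0(alt, "f")]][p] <- 85L; pu[[paste0(alt, "r")]][p] <- 85L
  }
  rec <- call_endpoint_mutations(pu, g)
  expect_identical(rec$position, truth)
  # idempotent and order-independent
  rec2 <- call_endpoint_mutations(pu[sample(nrow(pu)), ], g)
  expect_identical(sort(rec2$position), truth)
})

test_that("back-tracing finds the first pool at or above threshold", {
  tb <- trace_back(c(0.00, 0.01, 0.12, 0.40))
  expect_equal(tb$first_detected, 3)
  expect_equal(tb$interval, c(2, 3))
  expect_equal(trace_back(c(0.6, 0.7))$first_detected, 1)
  # absent from all pools: assigned to the final interval
  expect_equal(trace_back(c(0, 0, 0))$first_detected, 4)
  # configurable threshold
  expect_equal(trace_back(c(0.03, 0.1), pool_freq_min = 0.02)$first_detected, 1)
  # random trajectories agree with a first-passage scan
  set.seed(1)
  for (i in 1:50) {
    fr <- runif(8, 0, 0.2)
    want <- which(fr >= 0.05)
    want <- if (length(want)) want[1] else 9L
    expect_equal(trace_back(fr)$first_detected, want)
  }
})

test_that("pre-existing mutations are discarded by the all-samples/all-lines rule", {
  strains <- list(X = c("X1", "X2", "X3", "X4"), Y = c("Y1", "Y2"))
  rec <- data.frame(
    position = c(rep(10L, 4), rep(20L, 3), rep(30L, 6), 40L),
    alt = "T",
    line_id = c("X1", "X2", "X3", "X4",   # all 4 lines of X -> drop
                "X1", "X2", "X3",          # 3 of 4 -> keep
                "X1", "X2", "X3", "X4", "Y1", "Y2",  # all samples -> drop
                "Y1"))
  out <- discard_preexisting(rec, strains)
  expect_setequal(unique(out$position), c(20L, 40L))

  # randomized membership agrees with a set-algebra oracle
  set.seed(9)
  for (i in 1:20) {
    n <- 30
    rec <- data.frame(position = sample(1:8, n, TRUE), alt = "T",
                      line_id = sample(unlist(strains), n, TRUE))
    rec <- unique(rec)
    out <- discard_preexisting(rec, strains)
    keys <- split(rec$line_id, rec$position)
    bad <- names(keys)[vapply(keys, function(l)
      all(strains$X %in% l) || all(strains$Y %in% l), TRUE)]
    expect_setequal(unique(out$position), setdiff(names(keys), bad))
  }
})

test_that("coordinate transfer requires a unique exact 41-mer match", {
  src <- make_genome(300, seed = 13)
  pos <- c(60L, 150L)
  # insertion upstream shifts coordinates by its length
  tgt_seq <- paste0(substr(src$sequence, 1, 30), strrep("ACGTT", 2),
                    substr(src$sequence, 31, 300))
  tgt <- ref_genome(tgt_seq)
  tr <- transfer_coordinates(src, tgt, pos)
  expect_true(all(tr$mapped))
  expect_equal(tr$target_position, pos + 10L)
  expect_equal(tr$strand, c("+", "+"))
  # reverse-complemented target: strand flip and mirrored coordinate
  rc <- ref_genome(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(src$sequence))))
  tr <- transfer_coordinates(src, rc, pos)
  expect_true(all(tr$mapped))
  expect_equal(tr$target_position, src$length + 1L - pos)
  expect_equal(tr$strand, c("-", "-"))
  # duplicated 41-mer -> unmapped, not an error
  dup <- ref_genome(paste0(src$sequence, substr(src$sequence, 40, 80)))
  tr <- transfer_coordinates(src, dup, 60L)
  expect_false(tr$mapped)
  expect_true(is.na(tr$target_position))
  expect_error(transfer_coordinates(src, tgt, 10L), "flank")
})

test_that("pyrimidine classification complements purine references", {
  # position 2 of GGA has minus-strand context TCC; G>A becomes C>T
  g <- ref_genome("GGACTAG", ori = 1, ter = 4)
  rec <- data.frame(position = 2L, ref = "G", alt = "A",
                    class = "substitution")
  out <- to_pyrimidine_class(rec, g)
  expect_equal(out$pyr_class, "C>T")
  expect_equal(out$ts_tv, "transition")
  expect_equal(out$triplet, "TCC")
  # C>T stays C>T
  rec <- data.frame(position = 4L, ref = "C", alt = "T",
                    class = "substitution")
  expect_equal(to_pyrimidine_class(rec, g)$pyr_class, "C>T")

  # all 12 ref->alt pairs map onto 6 classes, exactly 2 transitions
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  g2 <- make_genome(200, seed = 2)
  classes <- character(0)
  for (ref in c("A", "C", "G", "T")) for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
    p <- which(g2$bases == ref & seq_along(g2$bases) > 1 &
                 seq_along(g2$bases) < 200)[1]
    out <- to_pyrimidine_class(
      data.frame(position = p, ref = ref, alt = alt, class = "substitution"), g2)
    want <- if (ref %in% c("C", "T")) paste0(ref, ">", alt) else
      paste0(comp[ref], ">", comp[alt])
    expect_equal(out$pyr_class, unname(want))
    classes <- c(classes, out$pyr_class)
  }
  expect_length(unique(classes), 6)
  ts <- unique(classes[classes %in% c("C>T", "T>C")])
  expect_length(ts, 2)
  # indels get homopolymer context and no pyrimidine class
  g3 <- ref_genome("GCAAAAT")
  out <- to_pyrimidine_class(
    data.frame(position = 4L, ref = "A", alt = "del", class = "deletion"), g3)
  expect_true(is.na(out$pyr_class))
  expect_equal(out$homopolymer_len, 4L)
})

test_that("pileup and mutation tables round-trip through disk formats", {
  g <- make_genome(120, seed = 8)
  pu <- flat_pileup(g, 100L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(pu, path)
  expect_equal(readLines(path, n = 1),
               "pos\tref\tA+\tC+\tG+\tT+\tA-\tC-\tG-\tT-\tins\tdel")
  expect_equal(read_pileup(path), pu)

  rec <- data.frame(position = c(5L, 9L), ref = c("A", "C"),
                    alt = c("G", "del"),
                    class = c("substitution", "deletion"),
                    line_id = c("L1", "L2"), interval = c("0-3", "3-7"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_mutations_vcf(rec, vcf, genome = g)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  expect_match(body[1], "LINE=L1;INTERVAL=0-3")
  expect_match(body[2], "<DEL>")
})
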