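#' Reference genome with replication landmarks
#'
#' Builds the genome object used throughout the package: a single circular
#' chromosome sequence, the positions of the replication origin and terminus
#' (which define the two replichores), and a mask of analyzable positions
#' (the "reference subset" of well-covered sites on which all opportunity
#' and mutation counting is performed).
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive),
#'   1-based positions.
#' @param id Sequence identifier.
#' @param ori,ter 1-based positions of the replication origin and terminus.
#' @param mask Integer vector of analyzable positions, or `NULL` for all
#'   positions. Positions whose base is N are always dropped from the mask.
#' @return An object of class `ref_genome`.
#' @examples
#' g <- ref_genome("GGACTAG", ori = 1, ter = 4)
#' classify_site(g, 4)
#' @export
ref_genome <- function(sequence, id = "chr", ori = 1L, ter = NULL,
                       mask = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence may only contain A, C, G, T, N")
  len <- nchar(sequence)
  if (is.null(ter)) ter <- as.integer(max(1L, len %/% 2L))
  ori <- as.integer(ori); ter <- as.integer(ter)
  if (ori < 1L || ori > len || ter < 1L || ter > len)
    stop("ori and ter must lie in [1, length]")
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (is.null(mask)) mask <- seq_len(len)
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1L || max(mask) > len))
    stop("mask positions outside [1, length]")
  mask <- mask[bases[mask] != "N"]
  structure(list(id = id, sequence = sequence, bases = bases,
                 length = len, ori = ori, ter = ter, mask = mask),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %d bp (circular), ori=%d, ter=%d, %d masked positions\n",
              x$id, x$length, x$ori, x$ter, length(x$mask)))
  invisible(x)
}

#' @export
length.ref_genome <- function(x) x$length

#' Read / write a single-record FASTA genome
#'
#' @param path FASTA file with exactly one record.
#' @param ori,ter,mask Passed to [ref_genome()].
#' @return A `ref_genome`.
#' @export
read_genome_fasta <- function(path, ori = 1L, ter = NULL, mask = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single FASTA record")
  ref_genome(as.character(ss[[1L]]), id = names(ss)[1L],
             ori = ori, ter = ter, mask = mask)
}

#' @rdname read_genome_fasta
#' @param genome A `ref_genome`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' The 64 stranded-triplet context labels
#'
#' Pyrimidine-centric triplets read 5'->3' on the strand carrying the focal
#' pyrimidine (central base C or T), annotated with the replication strand of
#' that pyrimidine-bearing strand: 32 triplets x {leading, lagging}.
#' Labels have the form `"ACT:leading"`.
#'
#' @return Character vector of length 64 in canonical order.
#' @export
triplet_contexts <- function() {
  b <- c("A", "C", "G", "T")
  trip <- as.vector(t(outer(c("C", "T"), as.vector(outer(b, b, paste0)),
                            function(ctr, fl) paste0(substr(fl, 1, 1), ctr,
                                                     substr(fl, 2, 2)))))
  as.vector(outer(sort(trip), c("leading", "lagging"),
                  function(t, s) paste0(t, ":", s)))
}

## replichore 1 = positions in (ori, ter] walking in increasing coordinates
## (wrapping if ter < ori); the plus strand is leading on replichore 1.
replichore_of <- function(genome, position) {
  p <- as.integer(position)
  if (genome$ori < genome$ter) {
    ifelse(p > genome$ori & p <= genome$ter, 1L, 2L)
  } else if (genome$ori > genome$ter) {
    ifelse(p > genome$ori | p <= genome$ter, 1L, 2L)
  } else {
    rep(1L, length(p))
  }
}

#' Classify a genomic site into its stranded-triplet context
#'
#' The focal base of a site is the pyrimidine of the Watson-Crick pair: when
#' the plus-strand base is a purine, the triplet is read on the minus strand
#' (reverse complement). The replication strand is that of the
#' pyrimidine-bearing strand, under the convention that the plus strand is
#' leading on replichore 1 (origin to terminus in increasing coordinates).
#'
#' @param genome A [ref_genome()].
#' @param position Integer vector of 1-based positions in `[2, length-1]`.
#' @return A data.frame with columns `position`, `triplet`,
#'   `replication_strand`, `context` (triplet:strand label),
#'   `pyrimidine_strand` (`"+"` or `"-"`), and `homopolymer_len`
#'   (maximal plus-strand run containing the position). Sites with an N base
#'   or N neighbor get `NA` context.
#' @export
classify_site <- function(genome, position) {
  p <- as.integer(position)
  if (any(p < 2L | p > genome$length - 1L))
    stop("position must be in [2, length-1] (contig ends have no neighbor)")
  b <- genome$bases
  left <- b[p - 1L]; ctr <- b[p]; right <- b[p + 1L]
  ok <- left != "N" & ctr != "N" & right != "N"
  pyr_plus <- ctr %in% c("C", "T")
  trip <- ifelse(pyr_plus,
                 paste0(left, ctr, right),
                 paste0(COMPLEMENT[right], COMPLEMENT[ctr], COMPLEMENT[left]))
  repl <- replichore_of(genome, p)
  ## plus strand leading on replichore 1; pyrimidine strand inherits
  lead <- (pyr_plus & repl == 1L) | (!pyr_plus & repl == 2L)
  strand <- ifelse(lead, "leading", "lagging")
  trip[!ok] <- NA_character_; strand[!ok] <- NA_character_
  runs <- homopolymer_lengths(genome)
  data.frame(position = p, triplet = trip, replication_strand = strand,
             context = ifelse(ok, paste0(trip, ":", strand), NA_character_),
             pyrimidine_strand = ifelse(pyr_plus, "+", "-"),
             homopolymer_len = runs[p], stringsAsFactors = FALSE)
}

## per-position length of the maximal plus-strand homopolymer run
homopolymer_lengths <- function(genome) {
  r <- rle(genome$bases)
  rep(r$lengths, r$lengths)
}

#' Count per-context opportunities
#'
#' Tallies, for each of the 64 stranded-triplet contexts, the number of masked
#' positions whose Watson-Crick pyrimidine falls in that context (the T\[i\]
#' denominators of all rate estimates). Positions at contig ends or with an N
#' neighbor are excluded, so the counts sum to the number of masked positions
#' with both neighbors available.
#'
#' @param genome A [ref_genome()].
#' @return Named integer vector over [triplet_contexts()].
#' @export
count_opportunities <- function(genome) {
  if (!length(genome$mask)) stop("genome has an empty mask")
  p <- genome$mask
  p <- p[p >= 2L & p <= genome$length - 1L]
  cls <- classify_site(genome, p)
  ctx <- cls$context[!is.na(cls$context)]
  tab <- table(factor(ctx, levels = triplet_contexts()))
  out <- as.integer(tab)
  names(out) <- triplet_contexts()
  out
}

#' Positions of each stranded-triplet context
#'
#' @param genome A [ref_genome()].
#' @return Named list mapping context label to the masked positions in it.
#' @export
context_sites <- function(genome) {
  p <- genome$mask
  p <- p[p >= 2L & p <= genome$length - 1L]
  cls <- classify_site(genome, p)
  keep <- !is.na(cls$context)
  split(cls$position[keep], factor(cls$context[keep],
                                   levels = triplet_contexts()))
}

#' Replication partition of a position
#'
#' Assigns each position to a replichore (1: origin to terminus in increasing
#' coordinates, terminus included) and to the replication-timing halves: the
#' "first half" is the circular window centred on the origin (2 Mbp on the
#' real chromosome; by default half the genome length).
#'
#' @param genome A [ref_genome()].
#' @param position Integer vector of positions.
#' @param first_half_size Width (bp) of the origin-centred window.
#' @return data.frame with columns `position`, `replichore`, `half`.
#' @export
partition_replication <- function(genome, position,
                                  first_half_size = genome$length %/% 2L) {
  p <- as.integer(position)
  if (any(p < 1L | p > genome$length)) stop("position outside genome")
  L <- genome$length
  d <- abs(p - genome$ori)
  circ <- pmin(d, L - d)
  half <- ifelse(circ <= first_half_size / 2, "first", "second")
  data.frame(position = p, replichore = replichore_of(genome, p),
             half = half, stringsAsFactors = FALSE)
}

#' Label transcription regions as high or low expression
#'
#' Implements the region classification used to test a transcription effect
#' on mutation rate: candidate regions overlapping any other region (both
#' strands transcribed) and regions shorter than 100 bp are removed; a region
#' is "high" if its expression is in the top 30% in at least one sample
#' (ties at the 70th percentile included), otherwise "low".
#'
#' @param regions data.frame with columns `region_id`, `start`, `end`,
#'   `strand` (1-based closed intervals).
#' @param expression Numeric matrix or data.frame, one row per region (rows
#'   matched by `region_id` rownames or by order), one column per sample.
#' @param top_fraction Fraction defining "high" (default 0.30).
#' @param min_length Minimum region length kept (default 100 bp).
#' @return The retained regions with an added `label` column (`high`/`low`).
#' @export
classify_transcription_regions <- function(regions, expression,
                                           top_fraction = 0.30,
                                           min_length = 100L) {
  stopifnot(all(c("region_id", "start", "end") %in% names(regions)))
  expression <- as.matrix(expression)
  if (any(expression < 0)) stop("expression values must be non-negative")
  if (!is.null(rownames(expression)))
    expression <- expression[match(regions$region_id, rownames(expression)), ,
                             drop = FALSE]
  if (nrow(expression) != nrow(regions))
    stop("expression must have one row per region")

  len_ok <- (regions$end - regions$start + 1L) >= min_length
  ir <- IRanges::IRanges(start = regions$start, end = regions$end)
  ov <- IRanges::countOverlaps(ir, ir) > 1L   # overlaps anything but itself
  keep <- len_ok & !ov
  regions <- regions[keep, , drop = FALSE]
  expression <- expression[keep, , drop = FALSE]

  high <- rep(FALSE, nrow(regions))
  for (j in seq_len(ncol(expression))) {
    thr <- stats::quantile(expression[, j], probs = 1 - top_fraction,
                           names = FALSE)
    high <- high | expression[, j] >= thr
  }
  regions$label <- ifelse(high, "high", "low")
  regions
}

#' Read / write BED interval files
#'
#' Intervals are 0-based half-open on disk (BED convention) and 1-based
#' closed in memory; conversion happens at this boundary.
#'
#' @param path BED file path.
#' @return data.frame with `start`, `end` (1-based closed), optional `name`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    df <- data.frame(start = gr$start, end = gr$end,
                     strand = as.character(gr$strand),
                     stringsAsFactors = FALSE)
    if (!is.null(gr$name)) df$name <- gr$name
    return(df)
  }
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  df <- data.frame(start = x[[2L]] + 1L, end = x[[3L]],
                   stringsAsFactors = FALSE)
  if (ncol(x) >= 4L) df$name <- x[[4L]]
  if (ncol(x) >= 6L) df$strand <- x[[6L]]
  df
}

#' @rdname read_bed
#' @param intervals data.frame with 1-based closed `start`, `end`, optional
#'   `name` and `strand` columns.
#' @param chrom Chromosome name written in column 1.
#' @export
write_bed <- function(intervals, path, chrom = "chr") {
  name <- if (!is.null(intervals$name)) intervals$name else "."
  strand <- if (!is.null(intervals$strand)) intervals$strand else "."
  out <- data.frame(chrom = chrom, start = intervals$start - 1L,
                    end = intervals$end, name = name, score = 0L,
                    strand = strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Positions-to-mask conversion for BED round trips
#'
#' Collapses a set of positions into maximal runs (1-based closed intervals)
#' and expands intervals back into positions.
#'
#' @param positions Sorted integer vector.
#' @return data.frame of intervals, or integer vector for the inverse.
#' @export
positions_to_intervals <- function(positions) {
  p <- sort(unique(as.integer(positions)))
  if (!length(p)) return(data.frame(start = integer(), end = integer()))
  brk <- c(0L, which(diff(p) > 1L), length(p))
  data.frame(start = p[brk[-length(brk)] + 1L], end = p[brk[-1L]])
}

#' @rdname positions_to_intervals
#' @param intervals data.frame with `start`, `end` (1-based closed).
#' @export
intervals_to_positions <- function(intervals) {
  if (!nrow(intervals)) return(integer())
  sort(unique(unlist(Map(seq.int, intervals$start, intervals$end))))
}
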