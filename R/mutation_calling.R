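## Variant identification from per-position stranded count tables.
## Upstream read processing (trimming, alignment, realignment, base/mapping
## quality filters) is assumed already applied to the counts.

PILEUP_COLS <- c("pos", "ref", "A+", "C+", "G+", "T+",
                 "A-", "C-", "G-", "T-", "ins", "del")
PILEUP_NAMES <- c("pos", "ref", "Af", "Cf", "Gf", "Tf",
                  "Ar", "Cr", "Gr", "Tr", "ins", "del")

#' Read / write pileup count tables
#'
#' The pileup TSV holds, per reference position, the number of observations
#' of each nucleotide on the plus and minus strands plus insertion and
#' deletion observations (columns
#' `pos ref A+ C+ G+ T+ A- C- G- T- ins del`, header line included).
#' In memory, strand columns are named `Af..Tr` (f = forward/plus,
#' r = reverse/minus).
#'
#' @param path TSV file path.
#' @return data.frame of per-position counts.
#' @export
read_pileup <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(PILEUP_COLS %in% names(x)))
    stop("pileup TSV must have columns: ", paste(PILEUP_COLS, collapse = " "))
  x <- x[PILEUP_COLS]
  names(x) <- PILEUP_NAMES
  x
}

#' @rdname read_pileup
#' @param pileup data.frame as returned by [read_pileup()] or the simulator.
#' @export
write_pileup <- function(pileup, path) {
  stopifnot(all(PILEUP_NAMES %in% names(pileup)))
  out <- pileup[PILEUP_NAMES]
  names(out) <- PILEUP_COLS
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## effective depth: all informative observations at the position
dpeff <- function(pileup) {
  rowSums(pileup[, c("Af", "Cf", "Gf", "Tf", "Ar", "Cr", "Gr", "Tr",
                     "ins", "del")])
}

#' Build the reference subset of analyzable positions
#'
#' Positions well covered on both strands in every sample: effective depth
#' `DPeff >= min_depth` and at least `min_strand_frac` of the stranded reads
#' on the less represented strand, in all samples; positions inside
#' `exclusions` (over-covered regions such as duplicated repair-gene loci)
#' are removed.
#'
#' @param pileups List of pileup data.frames (one per sample), covering the
#'   same positions.
#' @param exclusions Optional data.frame of 1-based closed intervals
#'   (`start`, `end`), e.g. from [read_bed()].
#' @param min_depth Minimum DPeff (default 100).
#' @param min_strand_frac Minimum fraction of stranded reads on the minor
#'   strand (default 0.10).
#' @return Sorted integer vector of retained positions (the mask).
#' @export
build_reference_subset <- function(pileups, exclusions = NULL,
                                   min_depth = 100, min_strand_frac = 0.10) {
  if (!length(pileups)) stop("at least one sample required")
  if (is.data.frame(pileups)) pileups <- list(pileups)
  ok <- NULL
  pos <- pileups[[1L]]$pos
  for (pu in pileups) {
    if (!identical(pu$pos, pos)) stop("samples must cover identical positions")
    fwd <- rowSums(pu[, c("Af", "Cf", "Gf", "Tf")])
    rev <- rowSums(pu[, c("Ar", "Cr", "Gr", "Tr")])
    tot <- fwd + rev
    minor <- ifelse(tot > 0, pmin(fwd, rev) / tot, 0)
    this <- dpeff(pu) >= min_depth & minor >= min_strand_frac
    ok <- if (is.null(ok)) this else ok & this
  }
  keep <- pos[ok]
  if (!is.null(exclusions) && nrow(exclusions)) {
    excl <- intervals_to_positions(exclusions)
    keep <- setdiff(keep, excl)
  }
  sort(keep)
}

#' Call mutations at the endpoint of an MA line
#'
#' A mutation is identified where a non-reference variant accounts for at
#' least `freq_min` of the effective depth, with at least `minor_strand_min`
#' of the non-reference reads on the less represented strand. When several
#' alternative alleles are present, only the most frequent is tested.
#' Insertion/deletion observations carry no strand in the count table, so
#' the strand rule applies to substitutions only.
#'
#' @param pileup Pileup data.frame for one sample.
#' @param genome A [ref_genome()]; reference bases are checked against it.
#' @param freq_min Minimum variant fraction of DPeff (default 0.75; lowered
#'   to 0.60 for one contaminated line in the study design).
#' @param minor_strand_min Minimum minor-strand fraction among non-reference
#'   reads (default 0.10).
#' @param mask Optional positions to restrict calling to.
#' @return data.frame of mutation records: `position`, `ref`, `alt`,
#'   `class` (`substitution`/`insertion`/`deletion`), `freq`, `dpeff`.
#' @export
call_endpoint_mutations <- function(pileup, genome, freq_min = 0.75,
                                    minor_strand_min = 0.10, mask = NULL) {
  if (any(pileup[PILEUP_NAMES[-(1:2)]] < 0)) stop("negative counts in pileup")
  pu <- pileup
  if (!is.null(mask)) pu <- pu[pu$pos %in% mask, , drop = FALSE]
  dp <- dpeff(pu)
  bases <- c("A", "C", "G", "T")
  cnt <- sapply(bases, function(b) pu[[paste0(b, "f")]] + pu[[paste0(b, "r")]])
  cnt <- matrix(cnt, nrow = nrow(pu),
                dimnames = list(NULL, bases))
  ref <- genome$bases[pu$pos]
  if (any(pu$ref != ref))
    stop("pileup ref column disagrees with genome sequence")
  ## candidate alleles: non-reference bases, insertion, deletion
  allele_counts <- cbind(cnt, ins = pu$ins, del = pu$del)
  for (b in bases) allele_counts[ref == b, b] <- 0L
  best <- max.col(allele_counts, ties.method = "first")
  alleles <- colnames(allele_counts)
  alt <- alleles[best]
  alt_n <- allele_counts[cbind(seq_len(nrow(pu)), best)]
  freq <- ifelse(dp > 0, alt_n / dp, 0)
  is_sub <- alt %in% bases
  ## minor-strand fraction of the alt-allele reads (substitutions only)
  fwdmat <- as.matrix(pu[, c("Af", "Cf", "Gf", "Tf")])
  alt_idx <- match(alt, bases)
  altf <- rep(NA_real_, nrow(pu))
  altf[is_sub] <- fwdmat[cbind(which(is_sub), alt_idx[is_sub])]
  altr <- alt_n - altf
  minor <- ifelse(is_sub & alt_n > 0, pmin(altf, altr) / alt_n, 1)
  pass <- freq >= freq_min & minor >= minor_strand_min & alt_n > 0
  data.frame(position = pu$pos[pass], ref = ref[pass], alt = alt[pass],
             class = ifelse(alt[pass] == "ins", "insertion",
                            ifelse(alt[pass] == "del", "deletion",
                                   "substitution")),
             freq = freq[pass], dpeff = dp[pass],
             stringsAsFactors = FALSE)
}

#' Trace a mutation back through pooled intermediate samples
#'
#' Given the variant's frequency in time-ordered pooled samples, returns the
#' MA-step interval in which it first appeared: the first pool where its
#' frequency reaches `pool_freq_min` closes the interval. A mutation below
#' threshold in every pool is assigned to the final interval (after the last
#' pool).
#'
#' @param pool_freqs Numeric vector of variant frequencies in time order.
#' @param pool_freq_min Detection threshold (default 0.05; lowered to 0.02
#'   for one strain in the study design).
#' @return List with `first_detected` (pool index, `length(pool_freqs)+1`
#'   if never detected) and `interval = c(lower, upper)` pool indices
#'   (half-open: detected after pool `lower`, by pool `upper`).
#' @export
trace_back <- function(pool_freqs, pool_freq_min = 0.05) {
  stopifnot(is.numeric(pool_freqs), length(pool_freqs) >= 1L)
  hit <- which(pool_freqs >= pool_freq_min)
  k <- if (length(hit)) hit[1L] else length(pool_freqs) + 1L
  list(first_detected = k, interval = c(k - 1L, k))
}

#' Discard mutations fixed before the MA experiment
#'
#' Variants found in every sample, or in all MA lines of one strain, were
#' present in the ancestor and are removed before rate calculation.
#'
#' @param records data.frame with at least `position`, `alt`, `line_id`.
#' @param lines_per_strain Named list mapping strain label to the character
#'   vector of its `line_id`s.
#' @return The filtered records.
#' @export
discard_preexisting <- function(records, lines_per_strain) {
  if (!nrow(records)) return(records)
  key <- paste(records$position, records$alt, sep = ":")
  all_lines <- unique(unlist(lines_per_strain))
  lines_of <- split(records$line_id, key)
  drop_keys <- names(lines_of)[vapply(lines_of, function(l)
    all(all_lines %in% l), logical(1L))]
  for (strain in names(lines_per_strain)) {
    sl <- lines_per_strain[[strain]]
    drop_keys <- union(drop_keys,
                       names(lines_of)[vapply(lines_of, function(l)
                         all(sl %in% l), logical(1L))])
  }
  records[!key %in% drop_keys, , drop = FALSE]
}

#' Transfer positions between genomes by unique flanking-sequence match
#'
#' Maps each position by locating the (2*flank+1)-mer centred on it in the
#' target genome; a position transfers only if the k-mer (or its reverse
#' complement) occurs exactly once in the target.
#'
#' @param source,target [ref_genome()] objects.
#' @param positions Integer positions on `source` with at least `flank` bp on
#'   each side.
#' @param flank Flank length (default 20, i.e. 41-mers).
#' @return data.frame with `position`, `target_position`, `strand`
#'   (`+`/`-`), `mapped` (FALSE when zero or multiple matches; then
#'   `target_position` is NA).
#' @export
transfer_coordinates <- function(source, target, positions, flank = 20L) {
  p <- as.integer(positions)
  if (any(p - flank < 1L | p + flank > source$length))
    stop("position lacks ", flank, " bp of flank")
  tgt <- Biostrings::DNAString(target$sequence)
  out <- data.frame(position = p, target_position = NA_integer_,
                    strand = NA_character_, mapped = FALSE)
  for (i in seq_along(p)) {
    kmer <- substr(source$sequence, p[i] - flank, p[i] + flank)
    if (grepl("N", kmer, fixed = TRUE)) next
    fwd <- Biostrings::matchPattern(kmer, tgt)
    rev <- Biostrings::matchPattern(revcomp(kmer), tgt)
    nf <- length(fwd); nr <- length(rev)
    if (nf + nr != 1L) next
    out$mapped[i] <- TRUE
    if (nf == 1L) {
      out$target_position[i] <- IRanges::start(fwd)[1L] + flank
      out$strand[i] <- "+"
    } else {
      out$target_position[i] <- IRanges::start(rev)[1L] + flank
      out$strand[i] <- "-"
    }
  }
  out
}

#' Pyrimidine-centric classification of substitutions
#'
#' Records each substitution with the pyrimidine (C or T) of the Watson-Crick
#' pair as the reference base: purine references are complemented together
#' with their alternative allele. Returns the six pyrimidine classes
#' (C>T, C>A, C>G, T>C, T>A, T>G; C>T and T>C are transitions) along with the
#' stranded-triplet context from [classify_site()]. Indels get a homopolymer
#' context instead of a pyrimidine class.
#'
#' @param records data.frame with `position`, `ref`, `alt`, `class`.
#' @param genome A [ref_genome()].
#' @return `records` with added `pyr_class`, `ts_tv`, `triplet`,
#'   `replication_strand`, `context`, `homopolymer_len` columns.
#' @export
to_pyrimidine_class <- function(records, genome) {
  if (!nrow(records)) {
    for (cc in c("pyr_class", "ts_tv", "triplet", "replication_strand",
                 "context")) records[[cc]] <- character()
    records$homopolymer_len <- integer()
    return(records)
  }
  cls <- classify_site(genome, records$position)
  is_sub <- records$class == "substitution"
  ref <- records$ref; alt <- records$alt
  purine <- ref %in% c("A", "G")
  ref2 <- ifelse(purine, COMPLEMENT[ref], ref)
  alt2 <- ifelse(purine & is_sub, COMPLEMENT[alt], alt)
  pyr <- ifelse(is_sub, paste0(ref2, ">", alt2), NA_character_)
  ts <- ifelse(is_sub, ifelse(pyr %in% c("C>T", "T>C"),
                              "transition", "transversion"), NA_character_)
  records$pyr_class <- pyr
  records$ts_tv <- ts
  records$triplet <- cls$triplet
  records$replication_strand <- cls$replication_strand
  records$context <- cls$context
  records$homopolymer_len <- cls$homopolymer_len
  records
}

#' Write mutation records
#'
#' Plain TSV plus a minimal VCF 4.2 writer
#' (CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO with `LINE` and `INTERVAL` keys).
#'
#' @param records Mutation record data.frame.
#' @param path Output file.
#' @export
write_mutations_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutations_tsv
#' @param genome A [ref_genome()] (for the VCF contig header).
#' @export
write_mutations_vcf <- function(records, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=LINE,Number=1,Type=String,Description=\"MA line\">",
               "##INFO=<ID=INTERVAL,Number=1,Type=String,Description=\"MA-step interval of first detection\">",
               if (!is.null(genome))
                 sprintf("##contig=<ID=%s,length=%d>", genome$id, genome$length),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records)) {
    chrom <- if (is.null(genome)) "chr" else genome$id
    line <- if (!is.null(records$line_id)) records$line_id else "."
    itv <- if (!is.null(records$interval)) records$interval else "."
    alt <- ifelse(records$class == "substitution", records$alt,
                  ifelse(records$class == "insertion", "<INS>", "<DEL>"))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tLINE=%s;INTERVAL=%s",
                       chrom, records$position, records$ref, alt, line, itv),
               con)
  }
  invisible(path)
}
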