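# Per-library pileups over a target space.
#
# Internally all coordinates are 1-based closed (GRanges convention); BED
# input is consumed as standard 0-based half-open and converted on import,
# and pileup/VCF output is written 1-based.

#' Construct a target space
#'
#' @param x One of: a `GRanges`; a data.frame with columns `chrom`, `start`,
#'   `end` in 0-based half-open coordinates (BED convention); or the path to
#'   a BED file.
#' @return A sorted, reduced (non-overlapping) `GRanges`.
#' @export
target_space <- function(x) {
  if (methods::is(x, "GRanges")) {
    gr <- x
  } else if (is.character(x) && length(x) == 1L) {
    gr <- rtracklayer::import(x, format = "BED")
  } else if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (any(x$end <= x$start)) stop("target intervals must satisfy end > start")
    gr <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
  } else {
    stop("cannot interpret target space input")
  }
  GenomicRanges::sort(GenomicRanges::reduce(gr))
}

#' Number of reference positions covered by a target space
#'
#' @param target A `GRanges` target space.
#' @return Integer count of positions.
#' @export
n_target_positions <- function(target) {
  sum(GenomicRanges::width(target))
}

# reference accessor: accepts a named character vector (chrom -> sequence)
# or a DNAStringSet; returns named character vector
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else if (is.character(reference) && !is.null(names(reference))) {
    reference
  } else {
    stop("reference must be a named character vector or DNAStringSet")
  }
}

ref_base_at <- function(reference, chrom, pos) {
  reference <- as_reference(reference)
  substring(reference[chrom], pos, pos)
}

#' Build a pileup from aligned consensus records
#'
#' Tallies every aligned, non-`N` consensus base falling inside the target
#' space into per-position A/C/G/T counts. Records are ungapped stretches of
#' reference-aligned bases (fixed-primer amplicon contract); records on
#' contigs absent from the target are skipped and counted, not an error.
#'
#' @param aligned data.frame with columns `chrom`, `start` (1-based leftmost
#'   reference position) and `seq` (aligned bases, `N` allowed).
#' @param reference Named character vector (chrom -> sequence) or
#'   `DNAStringSet` supplying reference bases.
#' @param target `GRanges` target space.
#' @param library_id Library identifier stored in the result.
#' @return data.frame with columns `library_id`, `chrom`, `pos` (1-based),
#'   `ref`, `A`, `C`, `G`, `T`, `depth`, ordered by position; only covered
#'   in-target positions are present. Attribute `n_skipped_contig` counts
#'   skipped records.
#' @export
build_pileup <- function(aligned, reference, target, library_id = "lib1") {
  reference <- as_reference(reference)
  empty <- data.frame(library_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(aligned) || nrow(aligned) == 0L) {
    attr(empty, "n_skipped_contig") <- 0L
    return(empty)
  }
  tgt_chroms <- as.character(GenomicRanges::seqnames(target))
  on_contig <- aligned$chrom %in% tgt_chroms
  n_skipped <- sum(!on_contig)
  aligned <- aligned[on_contig, , drop = FALSE]
  if (nrow(aligned) == 0L) {
    attr(empty, "n_skipped_contig") <- n_skipped
    return(empty)
  }
  # identical aligned records (typical for amplicon consensus data) are
  # collapsed and counted by weight before per-base expansion
  rkey <- paste0(aligned$chrom, "\r", aligned$start, "\r", aligned$seq)
  uf <- factor(rkey)
  w <- tabulate(uf, nbins = nlevels(uf))
  aligned <- aligned[match(levels(uf), rkey), , drop = FALSE]

  uchroms <- unique(tgt_chroms)
  L <- nchar(aligned$seq)
  pos <- rep(aligned$start, L) + sequence(L) - 1L
  cidx <- rep(match(aligned$chrom, uchroms), L)
  wexp <- rep(w, L)
  code <- utf8ToInt(paste(aligned$seq, collapse = ""))

  # in-target membership via interval search per contig
  keep <- code != .N_CODE
  tdf <- data.frame(chrom = tgt_chroms,
                    start = GenomicRanges::start(target),
                    end = GenomicRanges::end(target))
  for (ci in seq_along(uchroms)) {
    sel <- cidx == ci
    iv <- tdf[tdf$chrom == uchroms[ci], , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    j <- findInterval(pos[sel], iv$start)
    keep[sel] <- keep[sel] & j >= 1L & pos[sel] <= iv$end[pmax(j, 1L)]
  }
  if (!any(keep)) {
    attr(empty, "n_skipped_contig") <- n_skipped
    return(empty)
  }
  cidx <- cidx[keep]; pos <- pos[keep]; code <- code[keep]; wexp <- wexp[keep]
  big <- max(pos) + 1
  key <- (cidx - 1) * big + pos
  f <- sort(unique(key))
  idx <- match(key, f)
  nk <- length(f)
  counts <- vapply(.BASE_CODES, function(cc) {
    cs <- rep(0, nk)
    sel <- code == cc
    if (any(sel)) {
      got <- rowsum(wexp[sel], group = idx[sel], reorder = TRUE)
      cs[sort(unique(idx[sel]))] <- as.numeric(got)
    }
    as.integer(cs)
  }, integer(nk))
  counts <- matrix(counts, nrow = nk,
                   dimnames = list(NULL, names(.BASE_CODES)))
  out_chrom <- uchroms[f %/% big + 1]
  out_pos <- as.integer(f %% big)
  out <- data.frame(
    library_id = library_id,
    chrom = out_chrom,
    pos = out_pos,
    ref = ref_base_at(reference, out_chrom, out_pos),
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_contig") <- n_skipped
  out
}

#' Build a pileup from aligned consensus sequences in SAM format
#'
#' Reads a SAM file of aligned error-corrected consensus sequences and
#' tallies base counts over the target space (no base-quality or
#' mapping-quality thresholds, matching an uncapped mpileup run). `N` bases
#' and positions outside the target are excluded.
#'
#' @param sam_path Path to a SAM file (with header).
#' @inheritParams build_pileup
#' @return As [build_pileup()].
#' @export
pileup_from_sam <- function(sam_path, reference, target, library_id = "lib1") {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = 0L, min_mapq = 0L,
    min_nucleotide_depth = 1L, distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  sbp <- Rsamtools::ScanBamParam(which = target)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  empty <- build_pileup(NULL, reference, target, library_id)
  if (nrow(p) == 0L) return(empty)
  p <- p[p$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (nrow(p) == 0L) return(empty)
  key <- paste0(p$seqnames, ":", p$pos)
  f <- factor(key)
  nk <- nlevels(f)
  counts <- matrix(0L, nrow = nk, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T")) {
    sel <- p$nucleotide == b
    if (any(sel)) {
      cs <- rowsum(p$count[sel], group = as.integer(f)[sel], reorder = TRUE)
      counts[sort(unique(as.integer(f)[sel])), b] <- as.integer(cs)
    }
  }
  first <- match(levels(f), key)
  chrom <- as.character(p$seqnames)[first]
  pos <- p$pos[first]
  out <- data.frame(
    library_id = library_id, chrom = chrom, pos = pos,
    ref = ref_base_at(reference, chrom, pos),
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_contig") <- 0L
  out
}

#' Place paired consensus sequences on the reference (amplicon layout)
#'
#' For fixed-primer amplicon data the aligned position of each consensus
#' mate is fully determined by the amplicon coordinates: mate 1 covers the
#' bases immediately after the clipped forward primer and mate 2 (sequenced
#' in reverse-complement orientation) covers the tail of the amplicon. This
#' helper emits one aligned record per mate, reverse-complementing mate 2.
#' It replaces an external aligner only for this fixed-layout case.
#'
#' @param consensus data.frame from [call_consensus()] / [filter_consensus()].
#' @param chrom Contig name of the amplicon.
#' @param amplicon_start 1-based reference position of the amplicon's first
#'   base (including primer).
#' @param read_len Raw read length per mate before clipping.
#' @param clip_len Primer bases clipped from each mate.
#' @return data.frame with columns `chrom`, `start`, `seq` suitable for
#'   [build_pileup()].
#' @export
place_consensus <- function(consensus, chrom, amplicon_start = 1L,
                            read_len = 144L, clip_len = 30L) {
  if (nrow(consensus) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  r1_start <- amplicon_start + clip_len
  # mate 2 covers amplicon positions read_len+1 .. 2*read_len - clip_len
  r2_start <- amplicon_start + read_len
  data.frame(
    chrom = chrom,
    start = c(rep(r1_start, nrow(consensus)), rep(r2_start, nrow(consensus))),
    seq = c(consensus$consensus1, revcomp(consensus$consensus2)),
    stringsAsFactors = FALSE)
}

#' Reverse-complement nucleotide strings (IUPAC ACGTN)
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
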