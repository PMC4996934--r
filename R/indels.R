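# Post-filters for externally generated candidate indels.
#
# Candidate indels arrive as VCF (anchor-base convention: one of REF/ALT is
# a prefix of the other). Detection itself (e.g. VarScan-style calling from
# pileups) is out of scope; its published thresholds are enforced here on
# whatever candidate source is supplied, so results are reproducible.

#' Read candidate indels from a VCF file
#'
#' Expects a single-sample VCF with FORMAT fields `DP` (consensus depth),
#' `AD` (variant-supporting consensus sequences) and `FREQ` (VAF as a
#' percentage string, e.g. `"0.50%"`). Non-indel records are dropped.
#'
#' @param path Path to the VCF file.
#' @param library_id Library id recorded for every candidate.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `library_id`, `depth`, `support`, `vaf`.
#' @export
read_indel_vcf <- function(path, library_id = "lib1") {
  vcf <- VariantAnnotation::readVcf(path)
  alt_l <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt_l) != 1L)) {
    stop("multi-allelic VCF records are not supported: ", path)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  freq <- as.numeric(sub("%", "", geno$FREQ[, 1L], fixed = TRUE)) / 100
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt_l)),
    library_id = library_id,
    depth = as.integer(geno$DP[, 1L]),
    support = as.integer(geno$AD[, 1L]),
    vaf = freq,
    stringsAsFactors = FALSE)
  is_indel <- nchar(out$ref) != nchar(out$alt)
  out <- out[is_indel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Accept candidate indels by coverage, support and VAF thresholds
#'
#' A candidate is retained when depth >= `min_coverage`, support >=
#' `min_support` and VAF >= `min_vaf` (all inclusive, matching the
#' minimum-threshold semantics of the upstream caller's parameters).
#'
#' @param candidates Indel candidate data.frame (see [read_indel_vcf()]).
#' @param min_coverage Minimum consensus depth (default 1000).
#' @param min_support Minimum supporting consensus sequences (default 5).
#' @param min_vaf Minimum VAF (default 0.001).
#' @return The retained candidates.
#' @export
accept_indel_candidates <- function(candidates, min_coverage = 1000L,
                                    min_support = 5L, min_vaf = 0.001) {
  keep <- candidates$depth >= min_coverage &
    candidates$support >= min_support &
    candidates$vaf >= min_vaf
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# left-align one indel (VCF anchor convention) against the reference;
# returns list(pos, ref, alt)
left_align_one <- function(chrom, pos, ref, alt, reference) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substring(ref, nr, nr) == substring(alt, na, na)) {
      ref <- substring(ref, 1L, nr - 1L)
      alt <- substring(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (pos <= 1L) {
        # cannot extend left of the contig; restore anchor and stop
        b <- ref_base_at(reference, chrom, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        break
      }
      pos <- pos - 1L
      b <- ref_base_at(reference, chrom, pos)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
    } else {
      break
    }
  }
  # trim shared leading bases beyond the single anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-align (normalize) indel candidates
#'
#' Shifts each indel to its leftmost equivalent representation against the
#' reference (VCF anchor-base convention). Idempotent on already-normalized
#' records.
#'
#' @param candidates Indel candidate data.frame.
#' @param reference Named character vector (chrom -> sequence) or
#'   `DNAStringSet`.
#' @return The candidates with normalized `pos`, `ref`, `alt`.
#' @export
left_align_indels <- function(candidates, reference) {
  reference <- as_reference(reference)
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    la <- left_align_one(candidates$chrom[i], candidates$pos[i],
                         candidates$ref[i], candidates$alt[i], reference)
    candidates$pos[i] <- la$pos
    candidates$ref[i] <- la$ref
    candidates$alt[i] <- la$alt
  }
  candidates
}

# length of the run of base `b` in `refseq` starting at position `from`
run_length_at <- function(refseq, from, b) {
  n <- nchar(refseq)
  run <- 0L
  while (from + run <= n && substring(refseq, from + run, from + run) == b) {
    run <- run + 1L
  }
  run
}

#' Remove single-base indels inside homopolymer runs
#'
#' A 1-bp insertion or deletion is removed when the reference run of bases
#' identical to the inserted/deleted base, immediately adjacent (to the
#' right) of the left-aligned anchor position, is at least `min_run` long —
#' the classic polymerase-slippage artefact. Longer indels are untouched.
#'
#' @param candidates Left-aligned indel candidates.
#' @param reference Named character vector or `DNAStringSet`.
#' @param min_run Minimum homopolymer run length for removal (default 4).
#' @return list with `retained` and `removed` candidate sets.
#' @export
homopolymer_filter <- function(candidates, reference, min_run = 4L) {
  reference <- as_reference(reference)
  if (nrow(candidates) == 0L) {
    return(list(retained = candidates, removed = candidates))
  }
  removed <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    lr <- nchar(candidates$ref[i]); la <- nchar(candidates$alt[i])
    if (abs(lr - la) != 1L) next
    longer <- if (lr > la) candidates$ref[i] else candidates$alt[i]
    b <- substring(longer, 2L, 2L)
    refseq <- reference[candidates$chrom[i]]
    if (is.na(refseq)) stop("reference contig unavailable: ", candidates$chrom[i])
    run <- run_length_at(refseq, candidates$pos[i] + 1L, b)
    removed[i] <- run >= min_run
  }
  list(retained = candidates[!removed, , drop = FALSE],
       removed = candidates[removed, , drop = FALSE])
}

#' Remove indels recurring across individuals
#'
#' An identical normalized indel observed in two or more distinct
#' individuals is treated as a technical artefact and removed everywhere.
#' Recurrence within one individual (replicates, time points) is preserved —
#' replicate concordance is itself required downstream. Set
#' `by = "library"` to remove at library level instead.
#'
#' @param candidates Normalized indel candidates across all libraries.
#' @param manifest Sample manifest.
#' @param by `"individual"` (default) or `"library"`.
#' @return list with `retained` and `removed` candidate sets.
#' @export
multi_sample_filter <- function(candidates, manifest,
                                by = c("individual", "library")) {
  by <- match.arg(by)
  if (nrow(candidates) == 0L) {
    return(list(retained = candidates, removed = candidates))
  }
  mrow <- match(candidates$library_id, manifest$library_id)
  if (anyNA(mrow)) {
    stop("library absent from manifest: ",
         paste(unique(candidates$library_id[is.na(mrow)]), collapse = ", "))
  }
  unit <- if (by == "individual") manifest$individual_id[mrow] else candidates$library_id
  vkey <- paste(candidates$chrom, candidates$pos, candidates$ref, candidates$alt)
  n_units <- tapply(unit, vkey, function(x) length(unique(x)))
  recurrent <- vkey %in% names(n_units)[n_units >= 2L]
  list(retained = candidates[!recurrent, , drop = FALSE],
       removed = candidates[recurrent, , drop = FALSE])
}

#' Report clonal indels with replicate concordance
#'
#' Applies the same replicate-concordance and clonal-ceiling semantics as
#' the SNV path (shared code): an indel is reported when present in at
#' least `min_replicates` replicates within one time point, and reported as
#' clonal only below `max_vaf` at every supported time point.
#'
#' @param candidates Filtered indel candidates across libraries (with
#'   `library_id`, `depth`, `support`).
#' @param manifest Sample manifest.
#' @param min_replicates Replicates required within one time point (default 2).
#' @param max_vaf Exclusive clonal VAF ceiling (default 0.2).
#' @return list with `clonal`, `non_clonal` and `calls` (all reported,
#'   classified by time point).
#' @export
report_clonal_indels <- function(candidates, manifest, min_replicates = 2L,
                                 max_vaf = 0.2) {
  pseudo <- data.frame(
    library_id = candidates$library_id,
    chrom = candidates$chrom, pos = candidates$pos,
    ref = candidates$ref, alt = candidates$alt,
    k = candidates$support, depth = candidates$depth,
    pass = TRUE, stringsAsFactors = FALSE)
  calls <- merge_replicates(pseudo, manifest, min_replicates = min_replicates)
  calls <- classify_timepoints(calls)
  streams <- report_clonal(calls, max_vaf = max_vaf)
  list(clonal = streams$clonal, non_clonal = streams$non_clonal, calls = calls)
}
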