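# UMI read-family consensus calling.
#
# Reads are handled as a plain data.frame ("reads frame") with columns
#   umi  : 16-nt unique molecular identifier
#   r1   : read-1 sequence (A/C/G/T/N)
#   r2   : read-2 sequence
# plus optional q1/q2 qualities and sample_index. This mirrors the FASTQ
# trio interface (R1, R2, UMI index read) used on disk.

.BASE_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L)
.N_CODE <- 78L

# Hamming distance between each string in `x` and a single string `ref`.
# All strings must have equal length.
hamming_dist <- function(x, ref) {
  rb <- utf8ToInt(ref)
  vapply(x, function(s) sum(utf8ToInt(s) != rb), integer(1), USE.NAMES = FALSE)
}

#' Assign sample indices to libraries by Hamming distance
#'
#' Each observed index is assigned to the unique library whose sample index
#' lies within `max_mismatch` mismatches. Indices matching no library, or
#' more than one, are labelled `"unassigned"`.
#'
#' @param indices Character vector of observed sample-index sequences.
#' @param index_map Named character vector mapping library id to its sample
#'   index (all indices the same length), or a data.frame with columns
#'   `library_id` and `index`.
#' @param max_mismatch Maximum Hamming distance for a match (default 1).
#' @return Character vector of library ids (or `"unassigned"`), parallel to
#'   `indices`.
#' @export
assign_sample_index <- function(indices, index_map, max_mismatch = 1L) {
  if (is.data.frame(index_map)) {
    index_map <- stats::setNames(as.character(index_map$index),
                                 as.character(index_map$library_id))
  }
  if (anyDuplicated(index_map)) {
    stop("index_map contains duplicate sample indices")
  }
  if (length(unique(nchar(index_map))) != 1L) {
    stop("all sample indices in index_map must have equal length")
  }
  if (length(indices) == 0L) return(character(0))
  uniq <- unique(indices)
  dmat <- vapply(index_map, function(ix) hamming_dist(uniq, ix),
                 integer(length(uniq)))
  dmat <- matrix(dmat, nrow = length(uniq))
  hits <- dmat <= max_mismatch
  nhit <- rowSums(hits)
  lab <- rep("unassigned", length(uniq))
  one <- nhit == 1L
  lab[one] <- names(index_map)[max.col(hits[one, , drop = FALSE])]
  lab[match(indices, uniq)]
}

#' Demultiplex a reads frame by sample index
#'
#' @param reads Reads frame with a `sample_index` column.
#' @inheritParams assign_sample_index
#' @return Named list of reads frames, one per library plus `"unassigned"`
#'   (present even when empty).
#' @export
demultiplex_reads <- function(reads, index_map, max_mismatch = 1L) {
  if (is.data.frame(index_map)) {
    libs <- as.character(index_map$library_id)
  } else {
    libs <- names(index_map)
  }
  lab <- assign_sample_index(reads$sample_index, index_map, max_mismatch)
  out <- lapply(c(libs, "unassigned"), function(l) reads[lab == l, , drop = FALSE])
  names(out) <- c(libs, "unassigned")
  out
}

#' Hard-clip primer bases from both mates
#'
#' Removes the first `clip_len` bases (and qualities, when present) from each
#' mate; read pairs in which either mate is not longer than `clip_len` are
#' dropped and counted in the `"n_dropped_short"` attribute.
#'
#' @param reads Reads frame with columns `r1` and `r2`.
#' @param clip_len Number of leading bases to remove per mate (default 30).
#' @return The clipped reads frame, with attribute `n_dropped_short`.
#' @export
clip_primers <- function(reads, clip_len = 30L) {
  clip_len <- as.integer(clip_len)
  stopifnot(clip_len >= 0L)
  keep <- nchar(reads$r1) > clip_len & nchar(reads$r2) > clip_len
  out <- reads[keep, , drop = FALSE]
  out$r1 <- substring(out$r1, clip_len + 1L)
  out$r2 <- substring(out$r2, clip_len + 1L)
  if (!is.null(out$q1)) out$q1 <- substring(out$q1, clip_len + 1L)
  if (!is.null(out$q2)) out$q2 <- substring(out$q2, clip_len + 1L)
  attr(out, "n_dropped_short") <- sum(!keep)
  out
}

# Per-position consensus over one mate for all kept families at once.
# seqs: equal-length sequences; fam: integer family index (1..nfam);
# nfam: number of families; sizes: family sizes (length nfam).
# Returns list(seq = consensus strings, n = per-family N counts).
consensus_bases <- function(seqs, fam, nfam, sizes, agreement) {
  L <- nchar(seqs[1L])
  # identical reads within a family are collapsed and counted once, which
  # keeps the tally linear in the number of distinct reads, not raw reads
  ukey <- paste0(fam, "\r", seqs)
  uf <- factor(ukey)
  w <- tabulate(uf, nbins = nlevels(uf))
  first <- match(levels(uf), ukey)
  seqs_u <- seqs[first]
  fam_u <- fam[first]
  m <- matrix(utf8ToInt(paste(seqs_u, collapse = "")), ncol = L, byrow = TRUE)
  cnt <- lapply(.BASE_CODES, function(cc) {
    rowsum(w * (m == cc), group = fam_u, reorder = TRUE)
  })
  modal <- pmax(cnt$A, cnt$C, cnt$G, cnt$T)
  nties <- (cnt$A == modal) + (cnt$C == modal) + (cnt$G == modal) + (cnt$T == modal)
  # agreement is on modal count / family size; N bases count in the
  # denominator but can never be the modal base
  ok <- (modal / sizes) >= agreement & nties == 1L & modal > 0L
  code <- matrix(.N_CODE, nrow = nfam, ncol = L)
  for (b in names(.BASE_CODES)) {
    sel <- ok & (cnt[[b]] == modal)
    code[sel] <- .BASE_CODES[[b]]
  }
  flat <- as.vector(t(code))
  s <- intToUtf8(flat)
  starts <- seq(1L, by = L, length.out = nfam)
  list(seq = substring(s, starts, starts + L - 1L),
       n = as.integer(rowSums(code == .N_CODE)))
}

#' Collapse UMI read families into error-corrected consensus sequences
#'
#' Read pairs are grouped by exact UMI identity. Families with at least
#' `min_family_size` members are collapsed position by position: the modal
#' base is emitted when its frequency among family members reaches
#' `agreement`, otherwise `N`. Ties for the modal base yield `N`. Member `N`
#' bases count toward family size but never toward the modal base. Pairs
#' whose UMI contains `N` are excluded up front and counted.
#'
#' All mates within a family must have equal length (fixed-primer amplicon
#' chemistry); a deviating family raises an error naming its UMI.
#'
#' @param reads Clipped reads frame with columns `umi`, `r1`, `r2`.
#' @param min_family_size Minimum reads per family (default 5).
#' @param agreement Minimum modal-base fraction for a base call, inclusive
#'   (default 0.90).
#' @param umi_len Expected UMI length (default 16).
#' @return data.frame with columns `umi`, `consensus1`, `consensus2`,
#'   `family_size`, `n_count`, `total_len`, one row per family meeting the
#'   size threshold. Attributes: `reads_in`, `n_umi_excluded`,
#'   `families_total`, `families_small`.
#' @export
call_consensus <- function(reads, min_family_size = 5L, agreement = 0.90,
                           umi_len = 16L) {
  stopifnot(agreement > 0, agreement <= 1, min_family_size >= 1L)
  empty <- data.frame(umi = character(0), consensus1 = character(0),
                      consensus2 = character(0), family_size = integer(0),
                      n_count = integer(0), total_len = integer(0),
                      stringsAsFactors = FALSE)
  reads_in <- nrow(reads)
  if (reads_in == 0L) {
    attr(empty, "reads_in") <- 0L
    attr(empty, "n_umi_excluded") <- 0L
    attr(empty, "families_total") <- 0L
    attr(empty, "families_small") <- 0L
    return(empty)
  }
  if (any(nchar(reads$umi) != umi_len)) {
    stop("all UMIs must be exactly ", umi_len, " nt")
  }
  has_n <- grepl("N", reads$umi, fixed = TRUE)
  n_umi_excluded <- sum(has_n)
  reads <- reads[!has_n, , drop = FALSE]

  fam_f <- factor(reads$umi)
  families_total <- nlevels(fam_f)
  sizes_all <- tabulate(fam_f, nbins = families_total)
  keep_lvl <- sizes_all >= min_family_size
  families_small <- sum(!keep_lvl)

  out <- empty
  if (any(keep_lvl)) {
    sel <- keep_lvl[as.integer(fam_f)]
    sub <- reads[sel, , drop = FALSE]
    fam_f2 <- droplevels(fam_f[sel])
    fam <- as.integer(fam_f2)
    nfam <- nlevels(fam_f2)
    sizes <- tabulate(fam, nbins = nfam)

    for (mate in c("r1", "r2")) {
      lens <- nchar(sub[[mate]])
      if (length(unique(lens)) > 1L) {
        rng <- tapply(lens, fam, function(x) length(unique(x)))
        bad <- which(rng > 1L)
        if (length(bad)) {
          stop("unequal ", mate, " lengths within read family ",
               levels(fam_f2)[bad[1L]])
        }
      }
    }
    # families may differ in length between one another; process per length class
    key <- paste(nchar(sub$r1), nchar(sub$r2))
    res <- vector("list", 0L)
    for (kk in unique(key)) {
      ksel <- key == kk
      ksub <- sub[ksel, , drop = FALSE]
      kfam_f <- droplevels(fam_f2[ksel])
      kfam <- as.integer(kfam_f)
      knfam <- nlevels(kfam_f)
      ksizes <- tabulate(kfam, nbins = knfam)
      c1 <- consensus_bases(ksub$r1, kfam, knfam, ksizes, agreement)
      c2 <- consensus_bases(ksub$r2, kfam, knfam, ksizes, agreement)
      res[[length(res) + 1L]] <- data.frame(
        umi = levels(kfam_f),
        consensus1 = c1$seq, consensus2 = c2$seq,
        family_size = ksizes,
        n_count = c1$n + c2$n,
        total_len = nchar(c1$seq[1L]) + nchar(c2$seq[1L]),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    out <- out[order(out$umi), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "reads_in") <- reads_in
  attr(out, "n_umi_excluded") <- n_umi_excluded
  attr(out, "families_total") <- families_total
  attr(out, "families_small") <- families_small
  out
}

#' N-fraction retention filter for consensus sequences
#'
#' A consensus pair is discarded when its `N` fraction strictly exceeds
#' `max_n_frac` of the paired consensus length (e.g. more than 10% of the
#' 228 nt paired read at the defaults).
#'
#' @param n_count Integer vector of `N` counts across both mates.
#' @param total_len Integer vector of paired consensus lengths.
#' @param max_n_frac Maximum tolerated N fraction, inclusive (default 0.10).
#' @return Logical vector: `TRUE` when the record is retained.
#' @export
filter_n_fraction <- function(n_count, total_len, max_n_frac = 0.10) {
  if (any(total_len <= 0L)) stop("total_len must be positive")
  stopifnot(all(n_count >= 0L), all(n_count <= total_len))
  !(n_count / total_len > max_n_frac)
}

#' Split consensus records into retained and discarded sets
#'
#' @param consensus data.frame from [call_consensus()].
#' @inheritParams filter_n_fraction
#' @return list with elements `retained` and `discarded`.
#' @export
filter_consensus <- function(consensus, max_n_frac = 0.10) {
  if (nrow(consensus) == 0L) {
    return(list(retained = consensus, discarded = consensus))
  }
  keep <- filter_n_fraction(consensus$n_count, consensus$total_len, max_n_frac)
  list(retained = consensus[keep, , drop = FALSE],
       discarded = consensus[!keep, , drop = FALSE])
}

#' Run the full read-to-consensus stage for one library
#'
#' Primer clipping, UMI grouping, family consensus and the N-fraction filter,
#' with per-stage accounting.
#'
#' @param reads Raw reads frame (columns `umi`, `r1`, `r2`).
#' @inheritParams clip_primers
#' @inheritParams call_consensus
#' @inheritParams filter_n_fraction
#' @return list with `consensus` (retained records), `discarded`, and
#'   `report` (named counts: reads_in, dropped_short, umi_excluded,
#'   families_total, families_pass_size, eccs_retained, eccs_discarded).
#' @export
consensus_pipeline <- function(reads, clip_len = 30L, min_family_size = 5L,
                               agreement = 0.90, max_n_frac = 0.10,
                               umi_len = 16L) {
  reads_in <- nrow(reads)
  clipped <- clip_primers(reads, clip_len)
  cons <- call_consensus(clipped, min_family_size = min_family_size,
                         agreement = agreement, umi_len = umi_len)
  flt <- filter_consensus(cons, max_n_frac)
  report <- c(
    reads_in = reads_in,
    dropped_short = attr(clipped, "n_dropped_short"),
    umi_excluded = attr(cons, "n_umi_excluded"),
    families_total = attr(cons, "families_total"),
    families_pass_size = nrow(cons),
    eccs_retained = nrow(flt$retained),
    eccs_discarded = nrow(flt$discarded))
  list(consensus = flt$retained, discarded = flt$discarded, report = report)
}
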