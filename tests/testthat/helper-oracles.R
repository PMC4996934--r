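# Independent oracles and small fixture builders used across tests.

# brute-force per-position consensus over one family: plain loops, no
# shared code with the package implementation
oracle_consensus <- function(seqs, agreement = 0.90) {
  L <- nchar(seqs[1])
  n <- length(seqs)
  out <- character(L)
  for (i in seq_len(L)) {
    col <- substring(seqs, i, i)
    tab <- table(col[col != "N"])
    if (length(tab) == 0) {
      out[i] <- "N"
      next
    }
    mx <- max(tab)
    winners <- names(tab)[tab == mx]
    if (length(winners) == 1 && mx / n >= agreement) {
      out[i] <- winners
    } else {
      out[i] <- "N"
    }
  }
  paste(out, collapse = "")
}

# exact binomial upper tail by direct summation of the mass function
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# random read family as a character vector of sequences
random_family <- function(size, len, bases = c("A", "C", "G", "T", "N"),
                         probs = c(0.3, 0.25, 0.2, 0.2, 0.05)) {
  vapply(seq_len(size), function(i)
    paste(sample(bases, len, replace = TRUE, prob = probs), collapse = ""),
    "")
}

# reads frame holding a single family
family_frame <- function(r1, r2 = r1, umi = strrep("A", 16)) {
  data.frame(umi = umi, r1 = r1, r2 = r2, stringsAsFactors = FALSE)
}

# single-row pileup data.frame
pileup_row <- function(chrom = "chr1", pos = 100L, ref = "A",
                       counts = c(A = 0L, C = 0L, G = 0L, T = 0L),
                       library_id = "lib1") {
  data.frame(library_id = library_id, chrom = chrom, pos = pos, ref = ref,
             A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
             T = counts[["T"]], depth = sum(counts),
             stringsAsFactors = FALSE)
}

# pileup with a given alt count k at one position, ref-only elsewhere
toy_pileup <- function(k, depth, pos = 100L, ref = "A", alt = "T",
                       library_id = "lib1", chrom = "chr1") {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  counts[ref] <- depth - k
  counts[alt] <- counts[alt] + k
  pileup_row(chrom, pos, ref, counts, library_id)
}

toy_target <- function(chrom = "chr1", start0 = 0L, end0 = 1000L) {
  target_space(data.frame(chrom = chrom, start = start0, end = end0))
}

# four-library manifest: one individual, two time points x two replicates
toy_manifest <- function() sim_manifest(1L, 2L, 2L)

# write a minimal single-sample VCF of indel candidates
write_test_vcf <- function(path, records, sample = "S1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Variant reads\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"VAF percent\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD:FREQ\t0/1:%d:%d:%s%%",
                 records$chrom, records$pos, records$ref, records$alt,
                 records$depth, records$support,
                 format(records$vaf * 100, scientific = FALSE))
  writeLines(c(hdr, rec), path)
  path
}

# write a minimal SAM file of ungapped aligned consensus records
write_test_sam <- function(path, chrom, chrom_len, starts, seqs) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  rec <- sprintf("r%03d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                 seq_along(seqs), chrom, starts, nchar(seqs), seqs,
                 strrep("I", nchar(seqs)))
  writeLines(c(hdr, rec), path)
  path
}

# uniform profile over a pileup's sites
uniform_profile_for <- function(pileups, rate) {
  uniform_error_profile(unique(pileups[, c("chrom", "pos", "ref")]), rate)
}

# uniform profile over a read-set simulation's covered region
sim_read_profile <- function(sim, rate = 1e-5) {
  pos <- GenomicRanges::start(sim$target):GenomicRanges::end(sim$target)
  uniform_error_profile(
    data.frame(chrom = sim$layout$chrom, pos = pos,
               ref = strsplit(sim$reference[[1]], "")[[1]][pos]),
    rate)
}
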