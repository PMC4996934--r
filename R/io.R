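# Readers and writers for the plain-text interface files: FASTQ trios,
# manifest / germline / pileup / profile / droplet TSVs and a minimal
# variant VCF writer.

#' Read a FASTQ trio (R1, R2, UMI index read) into a reads frame
#'
#' Files may be plain or gzipped. The UMI read supplies the `umi` column;
#' an optional fourth file supplies `sample_index`.
#'
#' @param r1,r2,umi Paths to the three FASTQ files.
#' @param sample_index Optional path to the sample-index FASTQ.
#' @return Reads frame with columns `umi`, `r1`, `r2` (and `sample_index`).
#' @export
read_fastq_trio <- function(r1, r2, umi, sample_index = NULL) {
  rd <- function(p) as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  u <- unname(rd(umi)); s1 <- unname(rd(r1)); s2 <- unname(rd(r2))
  if (length(unique(c(length(u), length(s1), length(s2)))) != 1L) {
    stop("FASTQ trio files differ in record count")
  }
  out <- data.frame(umi = u, r1 = s1, r2 = s2, stringsAsFactors = FALSE)
  if (!is.null(sample_index)) out$sample_index <- unname(rd(sample_index))
  out
}

#' Write consensus sequences as a FASTQ pair
#'
#' Family size and N count are recorded in the record description as
#' space-separated `key=value` pairs. Consensus base qualities are a fixed
#' maximum placeholder (qualities are not used in consensus calling).
#'
#' @param consensus data.frame from [call_consensus()].
#' @param r1_path,r2_path Output FASTQ paths (`.gz` for gzip).
#' @export
write_consensus_fastq <- function(consensus, r1_path, r2_path) {
  ids <- sprintf("%s family_size=%d n_count=%d", consensus$umi,
                 consensus$family_size, consensus$n_count)
  wr <- function(seqs, path) {
    x <- Biostrings::BStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(L)
      strrep("I", L), ""))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  }
  wr(consensus$consensus1, r1_path)
  wr(consensus$consensus2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a sample manifest TSV
#'
#' Columns: `library_id`, `individual_id`, `timepoint`, `replicate`.
#'
#' @param path Path to the TSV.
#' @return Validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("library_id", "individual_id", "timepoint", "replicate")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$library_id)) stop("manifest library ids must be unique")
  reps <- tapply(m$replicate, paste(m$individual_id, m$timepoint),
                 function(x) length(unique(x)))
  if (any(reps > 2L)) {
    stop("at most two replicates per (individual, time point)")
  }
  m$timepoint <- as.integer(m$timepoint)
  m
}

#' Read a germline site table TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `maf` (population minor allele
#' fraction in `[0, 0.5]`).
#'
#' @param path Path to the TSV.
#' @return Validated germline data.frame.
#' @export
read_germline_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(g))) {
    stop("germline table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(g$maf < 0 | g$maf > 0.5)) stop("germline MAF must lie in [0, 0.5]")
  if (anyDuplicated(g[, c("chrom", "pos", "ref", "alt")])) {
    stop("duplicate germline sites")
  }
  g
}

#' Write / read a pileup TSV (1-based positions)
#'
#' @param pileup Pileup data.frame.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(T = "integer"))
}

#' Write an error profile TSV
#'
#' @param profile Error profile data.frame.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read droplet counts TSV
#'
#' Columns: `sample`, `well`, `n_total`, `n_empty`, `n_mut_only`,
#' `n_ref_pos`, `dilution`.
#'
#' @param path Path to the TSV.
#' @return data.frame of droplet counts.
#' @export
read_droplet_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write reported calls as a minimal VCF
#'
#' One record per reported variant with per-time-point VAF/depth, replicate
#' patterns and time-point class in INFO; the FILTER column is `PASS` for
#' the clonal stream and `nonclonal` otherwise.
#'
#' @param calls Classified calls (from [classify_timepoints()]).
#' @param path Output path.
#' @param clonal_max_vaf Ceiling used for the FILTER annotation.
#' @export
write_calls_vcf <- function(calls, path, clonal_max_vaf = 0.2) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ecscall_%s", as.character(utils::packageVersion("ecscall"))),
    "##INFO=<ID=IND,Number=1,Type=String,Description=\"Individual id\">",
    "##INFO=<ID=TP1VAF,Number=1,Type=Float,Description=\"Time point 1 pooled VAF\">",
    "##INFO=<ID=TP1DP,Number=1,Type=Integer,Description=\"Time point 1 pooled depth\">",
    "##INFO=<ID=TP2VAF,Number=1,Type=Float,Description=\"Time point 2 pooled VAF\">",
    "##INFO=<ID=TP2DP,Number=1,Type=Integer,Description=\"Time point 2 pooled depth\">",
    "##INFO=<ID=REPS,Number=1,Type=String,Description=\"Passing replicate pattern TP1/TP2\">",
    "##INFO=<ID=TPCLASS,Number=1,Type=String,Description=\"Time point class\">",
    sprintf("##FILTER=<ID=nonclonal,Description=\"Pooled VAF not below %s at a supported time point\">",
            format(clonal_max_vaf)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  over <- (calls$pass_tp1 & !(calls$tp1_vaf < clonal_max_vaf)) |
    (calls$pass_tp2 & !(calls$tp2_vaf < clonal_max_vaf))
  info <- sprintf(
    "IND=%s;TP1VAF=%s;TP1DP=%d;TP2VAF=%s;TP2DP=%d;REPS=%s/%s;TPCLASS=%s",
    calls$individual_id,
    format(calls$tp1_vaf, digits = 6, trim = TRUE),
    as.integer(calls$tp1_depth),
    format(calls$tp2_vaf, digits = 6, trim = TRUE),
    as.integer(calls$tp2_depth),
    ifelse(calls$tp1_pattern == "", ".", calls$tp1_pattern),
    ifelse(calls$tp2_pattern == "", ".", calls$tp2_pattern),
    calls$timepoint_class)
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                 calls$chrom, calls$pos, calls$ref, calls$alt,
                 ifelse(over, "nonclonal", "PASS"), info)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write simulated reads as gzipped FASTQ trios
#'
#' @param sim Result of [simulate_read_set()].
#' @param dir Output directory (created if needed).
#' @return Named list of per-library file-path triples.
#' @export
write_read_fastqs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (lib in names(sim$libraries)) {
    rf <- sim$libraries[[lib]]
    paths <- file.path(dir, sprintf("%s_%s.fastq.gz", lib, c("R1", "R2", "UMI")))
    ids <- sprintf("%s:%07d", lib, seq_len(nrow(rf)))
    for (j in 1:3) {
      seqs <- rf[[c("r1", "r2", "umi")[j]]]
      x <- Biostrings::BStringSet(seqs)
      names(x) <- ids
      q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
      Biostrings::writeXStringSet(x, paths[j], format = "fastq",
                                  qualities = q, compress = TRUE)
    }
    out[[lib]] <- stats::setNames(paths, c("r1", "r2", "umi"))
  }
  out
}
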