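# End-to-end orchestration with logged, reproducible runs.

#' Pipeline parameters with validation
#'
#' One configuration surface housing every numeric threshold of the
#' pipeline. Defaults are the published operating point of the method:
#' 30 nt primer clip, family size >= 5, 90% consensus agreement, <= 10% N
#' fraction, 1000x depth floor, Bonferroni-corrected binomial alpha 0.05,
#' >= 5 supporting consensus sequences, VAF > 1e-4, >= 2 passing replicates
#' within one time point, clonal ceiling 0.2 VAF, germline MAF exclusion
#' above 0.01, indel candidate thresholds 1000/5/0.001 and homopolymer run
#' >= 4.
#'
#' @param ... Named overrides of any default.
#' @return Validated parameter list of class `ecs_params`.
#' @export
ecs_params <- function(...) {
  p <- list(
    clip_len = 30L, min_family_size = 5L, agreement = 0.90,
    max_n_frac = 0.10, umi_len = 16L, max_mismatch = 1L,
    min_depth = 1000L, alpha = 0.05, bonferroni_m = NULL,
    min_support = 5L, min_vaf = 1e-4, min_replicates = 2L,
    clonal_max_vaf = 0.2, germline_max_maf = 0.01,
    indel_min_coverage = 1000L, indel_min_support = 5L,
    indel_min_vaf = 0.001, homopolymer_min_run = 4L,
    profile_mode = "per_allele")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(ov)] <- ov
  validate_params(p)
  p
}

validate_params <- function(p) {
  frac01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!frac01(p$agreement) || p$agreement <= 0) {
    stop("validation error: agreement must lie in (0, 1]")
  }
  for (nm in c("max_n_frac", "min_vaf", "clonal_max_vaf",
               "germline_max_maf", "indel_min_vaf")) {
    if (!frac01(p[[nm]])) stop("validation error: ", nm, " must lie in [0, 1]")
  }
  if (!(p$alpha > 0 && p$alpha < 1)) {
    stop("validation error: alpha must lie in (0, 1)")
  }
  for (nm in c("clip_len", "min_family_size", "min_depth", "min_support",
               "min_replicates", "indel_min_coverage", "indel_min_support",
               "homopolymer_min_run", "umi_len", "max_mismatch")) {
    if (!(is.numeric(p[[nm]]) && p[[nm]] >= 0)) {
      stop("validation error: ", nm, " must be a non-negative number")
    }
  }
  if (!p$profile_mode %in% c("per_allele", "per_position")) {
    stop("validation error: profile_mode must be per_allele or per_position")
  }
  invisible(p)
}

#' Run the complete consensus-to-calls pipeline
#'
#' Composes the stages consensus -> placement -> pileup -> error profile ->
#' candidate calling -> replicate merging -> classification -> clonal
#' reporting for a set of libraries, with per-stage accounting. Parameters
#' are validated before any work.
#'
#' @param reads_by_library Named list of raw reads frames (columns `umi`,
#'   `r1`, `r2`), one per library; names must match the manifest.
#' @param manifest Sample manifest.
#' @param layout Amplicon layout: list with `chrom`, `amplicon_start`,
#'   `read_len`, `clip_len` (see [place_consensus()]).
#' @param reference Named character vector or `DNAStringSet`.
#' @param target `GRanges` target space.
#' @param germline Optional germline site table.
#' @param profile Optional externally supplied error profile (otherwise
#'   leave-one-individual-out profiles are built).
#' @param params Parameter list from [ecs_params()].
#' @param out_dir Optional directory: pileup/calls TSVs, calls VCF and a
#'   JSON run report are written there.
#' @param seed Optional seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return list of class `ecs_run`: `clonal`, `non_clonal`, `calls`,
#'   `candidates`, `pileups`, `consensus_reports`, `threshold`, `params`,
#'   `report`.
#' @export
run_pipeline <- function(reads_by_library, manifest, layout, reference,
                         target, germline = NULL, profile = NULL,
                         params = ecs_params(), out_dir = NULL, seed = NULL) {
  validate_params(params)
  if (!setequal(names(reads_by_library), manifest$library_id)) {
    stop("validation error: library names must match the manifest")
  }
  consensus_reports <- list()
  pileups <- list()
  for (lib in manifest$library_id) {
    cp <- consensus_pipeline(reads_by_library[[lib]],
                             clip_len = params$clip_len,
                             min_family_size = params$min_family_size,
                             agreement = params$agreement,
                             max_n_frac = params$max_n_frac,
                             umi_len = params$umi_len)
    consensus_reports[[lib]] <- cp$report
    placed <- place_consensus(cp$consensus, chrom = layout$chrom,
                              amplicon_start = layout$amplicon_start,
                              read_len = layout$read_len,
                              clip_len = layout$clip_len)
    pileups[[lib]] <- build_pileup(placed, reference, target,
                                   library_id = lib)
  }
  pileups_df <- do.call(rbind, pileups)
  rownames(pileups_df) <- NULL
  res <- call_snvs(pileups_df, manifest, target, germline = germline,
                   profile = profile, alpha = params$alpha,
                   bonferroni_m = params$bonferroni_m,
                   min_depth = params$min_depth,
                   max_maf = params$germline_max_maf,
                   min_support = params$min_support,
                   min_vaf = params$min_vaf,
                   min_replicates = params$min_replicates,
                   clonal_max_vaf = params$clonal_max_vaf,
                   profile_mode = params$profile_mode)
  report <- list(
    package_version = as.character(utils::packageVersion("ecscall")),
    seed = seed,
    params = params[!vapply(params, is.null, TRUE)],
    consensus = consensus_reports,
    calling = as.list(res$counters),
    threshold = as.numeric(res$threshold),
    bonferroni_m = attr(res$threshold, "m"))
  out <- list(clonal = res$clonal, non_clonal = res$non_clonal,
              calls = res$calls, candidates = res$candidates,
              pileups = pileups_df, consensus_reports = consensus_reports,
              threshold = res$threshold, params = params, report = report)
  class(out) <- "ecs_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pileup_tsv(pileups_df, file.path(out_dir, "pileups.tsv"))
    utils::write.table(res$calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_calls_vcf(res$calls, file.path(out_dir, "calls.vcf"),
                    clonal_max_vaf = params$clonal_max_vaf)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.ecs_run <- function(x, ...) {
  cat("ecscall pipeline run\n")
  cat("  libraries:          ", length(x$consensus_reports), "\n")
  cat("  candidates evaluated:", x$report$calling$candidates_evaluated, "\n")
  cat("  reported variants:  ", nrow(x$calls), "\n")
  cat("  clonal (<",
      format(x$params$clonal_max_vaf), "VAF):",
      nrow(x$clonal), "\n")
  invisible(x)
}
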