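# Rare-SNV filter chain: site masks, binomial calling criteria, replicate
# concordance, longitudinal classification and clonal reporting.

#' Apply depth, target-space and germline site filters
#'
#' Expands a pileup into one row per (position, alternate allele) and flags
#' each against the site masks: depth at least `min_depth`, position inside
#' the target space, and population minor allele fraction not above
#' `max_maf` (exclusion is strictly "above": a site listed at exactly
#' `max_maf` stays eligible).
#'
#' @param pileup Pileup data.frame for one library.
#' @param target `GRanges` target space.
#' @param germline Optional data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `maf` (population minor allele fraction).
#' @param min_depth Minimum consensus depth for evaluation (default 1000).
#' @param max_maf Largest population MAF still eligible (default 0.01).
#' @return data.frame with columns `library_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `k`, `depth` and logical flags `depth_ok`, `in_target`,
#'   `germline_ok`, `eligible`.
#' @export
apply_site_filters <- function(pileup, target, germline = NULL,
                               min_depth = 1000L, max_maf = 0.01) {
  sites <- expand_alt_alleles(pileup)
  if (is.null(sites) || nrow(sites) == 0L) {
    return(data.frame(library_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      k = integer(0), depth = integer(0),
                      depth_ok = logical(0), in_target = logical(0),
                      germline_ok = logical(0), eligible = logical(0),
                      stringsAsFactors = FALSE))
  }
  sites$depth_ok <- sites$depth >= min_depth
  gp <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  sites$in_target <- IRanges::overlapsAny(gp, target)
  sites$germline_ok <- TRUE
  if (!is.null(germline) && nrow(germline) > 0L) {
    gk <- paste(germline$chrom, germline$pos, germline$ref, germline$alt)
    sk <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
    maf <- germline$maf[match(sk, gk)]
    sites$germline_ok <- is.na(maf) | !(maf > max_maf)
  }
  sites$eligible <- sites$depth_ok & sites$in_target & sites$germline_ok
  sites <- sites[, c("library_id", "chrom", "pos", "ref", "alt", "k", "depth",
                     "depth_ok", "in_target", "germline_ok", "eligible")]
  rownames(sites) <- NULL
  sites
}

#' Call candidate variants with the binomial criteria
#'
#' For each eligible (position, alternate allele) the observed count is
#' tested against the background error rate from the profile. A candidate
#' passes when all three criteria hold: the exact binomial upper-tail
#' p-value is below `threshold` (Bonferroni-corrected significance), the
#' variant is supported by at least `min_support` consensus sequences, and
#' its VAF strictly exceeds `min_vaf`. All flags are recorded for failing
#' candidates too. Sites missing from the profile are skipped and counted.
#'
#' @param sites Site table from [apply_site_filters()] (only `eligible`
#'   rows are evaluated).
#' @param profile Error profile data.frame (`chrom`, `pos`, `alt`, `p_hat`).
#' @param threshold Per-test significance threshold (see
#'   [bonferroni_threshold()]).
#' @param min_support Minimum supporting consensus sequences (default 5).
#' @param min_vaf Exclusive VAF floor (default 1e-4).
#' @return data.frame of candidates with `vaf`, `p_hat`, `p_value` and
#'   logical flags `pass_sig`, `pass_support`, `pass_vaf`, `pass`.
#'   Attribute `n_skipped_profile` counts eligible sites without a profile
#'   entry.
#' @export
call_candidates <- function(sites, profile, threshold, min_support = 5L,
                            min_vaf = 1e-4) {
  cand <- sites[sites$eligible, , drop = FALSE]
  pk <- paste(profile$chrom, profile$pos, profile$alt)
  ck <- paste(cand$chrom, cand$pos, cand$alt)
  hit <- match(ck, pk)
  n_skipped <- sum(is.na(hit))
  cand <- cand[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  cand$p_hat <- profile$p_hat[hit]
  if (nrow(cand)) {
    cand$vaf <- cand$k / cand$depth
    cand$p_value <- binom_pvalue(cand$k, cand$depth, cand$p_hat)
    cand$pass_sig <- cand$p_value < threshold
    cand$pass_support <- cand$k >= min_support
    cand$pass_vaf <- cand$vaf > min_vaf
    cand$pass <- cand$pass_sig & cand$pass_support & cand$pass_vaf
  } else {
    cand$vaf <- numeric(0); cand$p_value <- numeric(0)
    cand$pass_sig <- logical(0); cand$pass_support <- logical(0)
    cand$pass_vaf <- logical(0); cand$pass <- logical(0)
  }
  rownames(cand) <- NULL
  attr(cand, "n_skipped_profile") <- n_skipped
  cand
}

#' Merge candidate calls across replicates and time points
#'
#' A variant is reported for an individual when it passes the per-library
#' criteria in at least `min_replicates` replicates **within a single time
#' point** (one passing replicate in each of two time points does not
#' qualify). Per-time-point VAF is depth weighted: pooled alternate counts
#' divided by pooled depth across that time point's replicate libraries.
#'
#' @param candidates data.frame of per-library candidates (rbind across
#'   libraries) from [call_candidates()].
#' @param manifest Sample manifest (`library_id`, `individual_id`,
#'   `timepoint`, `replicate`).
#' @param min_replicates Passing replicates required within one time point
#'   (default 2).
#' @param require_single_timepoint When `FALSE`, passing once in each of two
#'   time points also qualifies (strictness switch; default `TRUE`).
#' @return data.frame of reported calls: one row per (individual, variant)
#'   with `tp1_k`, `tp1_depth`, `tp1_vaf`, `tp1_nrep_pass`, `tp1_pattern`
#'   (and `tp2_*`), `pass_tp1`, `pass_tp2`.
#' @export
merge_replicates <- function(candidates, manifest, min_replicates = 2L,
                             require_single_timepoint = TRUE) {
  empty <- data.frame(individual_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      tp1_k = numeric(0), tp1_depth = numeric(0),
                      tp1_vaf = numeric(0), tp1_nrep_pass = integer(0),
                      tp1_pattern = character(0),
                      tp2_k = numeric(0), tp2_depth = numeric(0),
                      tp2_vaf = numeric(0), tp2_nrep_pass = integer(0),
                      tp2_pattern = character(0),
                      pass_tp1 = logical(0), pass_tp2 = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  mrow <- match(candidates$library_id, manifest$library_id)
  if (anyNA(mrow)) {
    stop("library absent from manifest: ",
         paste(unique(candidates$library_id[is.na(mrow)]), collapse = ", "))
  }
  candidates$individual_id <- manifest$individual_id[mrow]
  candidates$timepoint <- manifest$timepoint[mrow]
  candidates$replicate <- manifest$replicate[mrow]

  vkey <- paste(candidates$individual_id, candidates$chrom, candidates$pos,
                candidates$ref, candidates$alt, sep = "\r")
  f <- factor(vkey)
  idx <- as.integer(f)
  nk <- nlevels(f)
  first <- match(levels(f), vkey)

  out <- data.frame(
    individual_id = candidates$individual_id[first],
    chrom = candidates$chrom[first],
    pos = candidates$pos[first],
    ref = candidates$ref[first],
    alt = candidates$alt[first],
    stringsAsFactors = FALSE)
  for (tp in c(1L, 2L)) {
    sel <- candidates$timepoint == tp
    k <- depth <- rep(0, nk)
    npass <- rep(0L, nk)
    pattern <- rep("", nk)
    if (any(sel)) {
      ks <- rowsum(candidates$k[sel], idx[sel], reorder = TRUE)
      ds <- rowsum(candidates$depth[sel], idx[sel], reorder = TRUE)
      got <- sort(unique(idx[sel]))
      k[got] <- as.numeric(ks)
      depth[got] <- as.numeric(ds)
      ps <- sel & candidates$pass
      if (any(ps)) {
        np <- rowsum(rep(1L, sum(ps)), idx[ps], reorder = TRUE)
        npass[sort(unique(idx[ps]))] <- as.integer(np)
        pat <- tapply(as.character(candidates$replicate[ps]), idx[ps],
                      function(x) paste(sort(x), collapse = ""))
        pattern[as.integer(names(pat))] <- as.character(pat)
      }
    }
    out[[paste0("tp", tp, "_k")]] <- k
    out[[paste0("tp", tp, "_depth")]] <- depth
    out[[paste0("tp", tp, "_vaf")]] <- ifelse(depth > 0, k / depth, NA_real_)
    out[[paste0("tp", tp, "_nrep_pass")]] <- npass
    out[[paste0("tp", tp, "_pattern")]] <- pattern
  }
  out$pass_tp1 <- out$tp1_nrep_pass >= min_replicates
  out$pass_tp2 <- out$tp2_nrep_pass >= min_replicates
  reported <- out$pass_tp1 | out$pass_tp2
  if (!require_single_timepoint) {
    reported <- reported | (out$tp1_nrep_pass >= 1L & out$tp2_nrep_pass >= 1L)
  }
  out <- out[reported, , drop = FALSE]
  out <- out[order(out$individual_id, out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify reported calls by time point of detection
#'
#' @param calls Reported calls from [merge_replicates()].
#' @return `calls` with a `timepoint_class` column
#'   (`"both"`, `"first_only"`, `"second_only"`); attribute `summary` holds
#'   the per-class counts.
#' @export
classify_timepoints <- function(calls) {
  if (nrow(calls) > 0L && any(!calls$pass_tp1 & !calls$pass_tp2)) {
    stop("internal consistency error: reported call passing in neither time point")
  }
  cls <- ifelse(calls$pass_tp1 & calls$pass_tp2, "both",
                ifelse(calls$pass_tp1, "first_only", "second_only"))
  calls$timepoint_class <- cls
  attr(calls, "summary") <- c(both = sum(cls == "both"),
                              first_only = sum(cls == "first_only"),
                              second_only = sum(cls == "second_only"))
  calls
}

#' Split reported calls into clonal and non-clonal streams
#'
#' A call is reported as (likely) clonal only when the VAF at every
#' replicate-supported time point is strictly below `max_vaf`; calls at or
#' above the ceiling are diverted to the non-clonal / likely-germline
#' stream, never silently dropped.
#'
#' @param calls Reported calls from [merge_replicates()].
#' @param max_vaf Exclusive clonal VAF ceiling (default 0.2).
#' @return list with elements `clonal` and `non_clonal`.
#' @export
report_clonal <- function(calls, max_vaf = 0.2) {
  if (nrow(calls) == 0L) return(list(clonal = calls, non_clonal = calls))
  over1 <- calls$pass_tp1 & !(calls$tp1_vaf < max_vaf)
  over2 <- calls$pass_tp2 & !(calls$tp2_vaf < max_vaf)
  clonal <- !(over1 | over2)
  list(clonal = calls[clonal, , drop = FALSE],
       non_clonal = calls[!clonal, , drop = FALSE])
}

#' Tabulate per-compartment VAFs for reported variants
#'
#' Produces a long-format concordance table of one row per (variant, time
#' point, compartment) over the four sorted blood compartments; compartments
#' without a measurement are present with `present = FALSE` and `vaf = NA`,
#' never imputed.
#'
#' @param calls Reported calls (must carry `individual_id`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param compartment_vafs data.frame with columns `individual_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `timepoint`, `compartment` (one of `B`, `T`,
#'   `myeloid`, `bulk`) and `vaf` (e.g. from droplet digital PCR).
#' @param compartments Allowed compartment labels.
#' @return Long-format data.frame with `present` flag and `vaf`.
#' @export
tabulate_compartments <- function(calls, compartment_vafs,
                                  compartments = c("B", "T", "myeloid", "bulk")) {
  bad <- setdiff(unique(compartment_vafs$compartment), compartments)
  if (length(bad)) {
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(calls) == 0L) {
    return(data.frame(individual_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      timepoint = integer(0), compartment = character(0),
                      present = logical(0), vaf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  grid <- merge(
    calls[, c("individual_id", "chrom", "pos", "ref", "alt")],
    expand.grid(timepoint = c(1L, 2L), compartment = compartments,
                stringsAsFactors = FALSE))
  key <- function(d) paste(d$individual_id, d$chrom, d$pos, d$ref, d$alt,
                           d$timepoint, d$compartment)
  hit <- match(key(grid), key(compartment_vafs))
  grid$present <- !is.na(hit)
  grid$vaf <- compartment_vafs$vaf[hit]
  grid <- grid[order(grid$individual_id, grid$chrom, grid$pos, grid$alt,
                     grid$timepoint, grid$compartment), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Run the full SNV calling chain over a set of libraries
#'
#' Convenience wrapper composing site filters, binomial candidate calling,
#' replicate merging, time-point classification and clonal reporting for
#' every individual in the manifest. Unless an explicit `profile` is given,
#' a leave-one-individual-out error profile is built per individual from
#' all other individuals' libraries.
#'
#' @param pileups data.frame of pileups for all libraries (with
#'   `library_id`), or a list of per-library pileups.
#' @param manifest Sample manifest.
#' @param target `GRanges` target space.
#' @param germline Optional germline site table (see [apply_site_filters()]).
#' @param profile Optional error profile applied to every individual
#'   (otherwise built leave-one-individual-out).
#' @param alpha Family-wise significance level (default 0.05).
#' @param bonferroni_m Optional explicit Bonferroni test count.
#' @param min_depth,max_maf,min_support,min_vaf,min_replicates,clonal_max_vaf
#'   Filter-chain thresholds; defaults 1000, 0.01, 5, 1e-4, 2, 0.2.
#' @param profile_mode `"per_allele"` or `"per_position"`.
#' @return list with `clonal`, `non_clonal`, `calls` (all reported,
#'   classified), `candidates` (every evaluated site with flags),
#'   `threshold`, and `counters`.
#' @export
call_snvs <- function(pileups, manifest, target, germline = NULL,
                      profile = NULL, alpha = 0.05, bonferroni_m = NULL,
                      min_depth = 1000L, max_maf = 0.01, min_support = 5L,
                      min_vaf = 1e-4, min_replicates = 2L,
                      clonal_max_vaf = 0.2, profile_mode = "per_allele") {
  if (is.list(pileups) && !is.data.frame(pileups)) {
    pileups <- do.call(rbind, pileups)
  }
  threshold <- bonferroni_threshold(alpha, target, m = bonferroni_m)
  all_cand <- list()
  all_calls <- list()
  n_skipped_profile <- 0L
  for (ind in unique(manifest$individual_id)) {
    prof <- if (is.null(profile)) {
      build_error_profile(pileups, manifest, ind, mode = profile_mode)
    } else {
      profile
    }
    libs <- manifest$library_id[manifest$individual_id == ind]
    cand_ind <- list()
    for (lib in libs) {
      pl <- pileups[pileups$library_id == lib, , drop = FALSE]
      sites <- apply_site_filters(pl, target, germline,
                                  min_depth = min_depth, max_maf = max_maf)
      cand <- call_candidates(sites, prof, threshold,
                              min_support = min_support, min_vaf = min_vaf)
      n_skipped_profile <- n_skipped_profile + attr(cand, "n_skipped_profile")
      cand_ind[[lib]] <- cand
    }
    cand_ind <- do.call(rbind, cand_ind)
    all_cand[[ind]] <- cand_ind
    all_calls[[ind]] <- merge_replicates(cand_ind, manifest,
                                         min_replicates = min_replicates)
  }
  candidates <- do.call(rbind, all_cand)
  rownames(candidates) <- NULL
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  calls <- classify_timepoints(calls)
  streams <- report_clonal(calls, max_vaf = clonal_max_vaf)
  list(clonal = streams$clonal, non_clonal = streams$non_clonal,
       calls = calls, candidates = candidates, threshold = threshold,
       counters = c(candidates_evaluated = nrow(candidates),
                    candidates_pass = sum(candidates$pass),
                    reported = nrow(calls),
                    clonal = nrow(streams$clonal),
                    non_clonal = nrow(streams$non_clonal),
                    skipped_no_profile = n_skipped_profile))
}
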