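# Cross-individual position-specific binomial error model.

#' Exact upper-tail binomial p-value
#'
#' Returns `P(X >= k)` for `X ~ Binomial(n, p)` (inclusive survival
#' function), the test statistic of the position-specific error model.
#' Vectorised over its arguments.
#'
#' @param k Observed alternate-allele count(s), `0 <= k <= n`.
#' @param n Depth(s).
#' @param p Background error rate(s), `0 < p <= 1`.
#' @return Numeric vector of upper-tail probabilities.
#' @export
binom_pvalue <- function(k, n, p) {
  if (any(p <= 0) || any(p > 1)) stop("error rate p must satisfy 0 < p <= 1")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' The family-wise significance level `alpha` is divided by the number of
#' tests `m`. By default `m = alts_per_position * n_target_positions(target)`
#' (three alternate alleles per reference position); `m` can be overridden
#' directly.
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param target `GRanges` target space (used when `m` is `NULL`).
#' @param m Optional explicit number of tests.
#' @param alts_per_position Alternate alleles tested per position (default 3).
#' @return The per-test threshold `alpha / m`, with attribute `m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, target = NULL, m = NULL,
                                 alts_per_position = 3L) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(m)) {
    if (is.null(target)) stop("supply either a target space or m")
    npos <- n_target_positions(target)
    if (npos == 0L) stop("target space is empty")
    m <- alts_per_position * npos
  }
  stopifnot(m >= 1)
  structure(alpha / m, m = m)
}

# expand a pileup (or pooled counts) into one row per (position, alt allele)
expand_alt_alleles <- function(pileup) {
  bases <- c("A", "C", "G", "T")
  rows <- lapply(bases, function(b) {
    sub <- pileup[pileup$ref != b, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(chrom = sub$chrom, pos = sub$pos, ref = sub$ref, alt = b,
               k = sub[[b]], depth = sub$depth,
               library_id = if ("library_id" %in% names(sub)) sub$library_id else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      k = integer(0), depth = integer(0),
                      library_id = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a position-specific error profile from other individuals' libraries
#'
#' Pools pileup counts across every library that does **not** belong to the
#' focal individual and converts them to per-position background error
#' rates with a one-count pseudocount:
#' `p_hat = (pooled alt count + 1) / (pooled depth + 1)`,
#' guaranteeing `p_hat > 0` at error-free positions. In `"per_allele"` mode
#' (default) each alternate allele gets its own rate; in `"per_position"`
#' mode the summed non-reference count is used for all three alternates.
#'
#' @param pileups A single data.frame of pileups carrying `library_id`
#'   (rbind of per-library pileups), or a list of such data.frames.
#' @param manifest Sample manifest (columns `library_id`, `individual_id`,
#'   `timepoint`, `replicate`).
#' @param focal_individual Individual whose libraries are excluded.
#' @param mode `"per_allele"` or `"per_position"`.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `p_hat`,
#'   `pooled_depth`.
#' @export
build_error_profile <- function(pileups, manifest, focal_individual,
                                mode = c("per_allele", "per_position")) {
  mode <- match.arg(mode)
  if (is.list(pileups) && !is.data.frame(pileups)) {
    pileups <- do.call(rbind, pileups)
  }
  nonfocal <- manifest$library_id[manifest$individual_id != focal_individual]
  if (length(nonfocal) == 0L) {
    stop("no libraries from other individuals available for individual ",
         focal_individual)
  }
  sub <- pileups[pileups$library_id %in% nonfocal, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      p_hat = numeric(0), pooled_depth = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste0(sub$chrom, ":", sub$pos)
  f <- factor(key)
  idx <- as.integer(f)
  pooled <- data.frame(
    chrom = tapply(sub$chrom, idx, `[`, 1L),
    pos = as.integer(tapply(sub$pos, idx, `[`, 1L)),
    ref = tapply(sub$ref, idx, `[`, 1L),
    A = as.integer(rowsum(sub$A, idx)), C = as.integer(rowsum(sub$C, idx)),
    G = as.integer(rowsum(sub$G, idx)), T = as.integer(rowsum(sub$T, idx)),
    stringsAsFactors = FALSE)
  pooled$depth <- pooled$A + pooled$C + pooled$G + pooled$T
  alts <- expand_alt_alleles(pooled)
  if (mode == "per_position") {
    tot <- tapply(alts$k, paste0(alts$chrom, ":", alts$pos), sum)
    alts$k <- as.numeric(tot[paste0(alts$chrom, ":", alts$pos)])
  }
  data.frame(chrom = alts$chrom, pos = alts$pos, ref = alts$ref,
             alt = alts$alt,
             p_hat = (alts$k + 1) / (alts$depth + 1),
             pooled_depth = alts$depth, stringsAsFactors = FALSE)
}

#' Uniform error profile at a fixed background rate
#'
#' Builds a profile assigning the same background error rate to every
#' alternate allele at every supplied site; used when the background rate is
#' known (simulations) or supplied externally.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`.
#' @param rate Background error rate, `0 < rate <= 1`.
#' @return data.frame in the same shape as [build_error_profile()].
#' @export
uniform_error_profile <- function(sites, rate) {
  stopifnot(rate > 0, rate <= 1)
  sites <- unique(sites[, c("chrom", "pos", "ref")])
  bases <- c("A", "C", "G", "T")
  out <- do.call(rbind, lapply(bases, function(b) {
    sub <- sites[sites$ref != b, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(chrom = sub$chrom, pos = sub$pos, ref = sub$ref, alt = b,
               p_hat = rate, pooled_depth = NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
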