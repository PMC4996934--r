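# Poisson quantification of droplet digital PCR.
#
# Template molecules partition into droplets approximately Poisson; the
# fraction of empty (all-negative) droplets identifies the mean occupancy
# lambda, and the expected number of singleton droplets (exactly one
# molecule) is n_total * lambda * exp(-lambda). Rare-variant VAF is the
# count of mutant-only droplets (positive for the mutant assay, negative
# for the reference allele) over the expected singleton count.

#' Estimate mean molecules per droplet from empty droplets
#'
#' `lambda = -log(n_empty / n_total)` under the Poisson partitioning model.
#'
#' @param n_total Total droplets counted (> 0).
#' @param n_empty Droplets negative for all assays (0 < n_empty <= n_total).
#' @return Mean occupancy `lambda` (0 when all droplets are empty).
#' @export
estimate_lambda <- function(n_total, n_empty) {
  stopifnot(n_total > 0, n_empty >= 0, n_empty <= n_total)
  if (any(n_empty == 0)) {
    stop("saturated ddPCR well: no empty droplets, lambda is unbounded")
  }
  -log(n_empty / n_total)
}

#' Expected number of singleton droplets
#'
#' @inheritParams estimate_lambda
#' @param lambda Mean occupancy (estimated from `n_empty` when omitted).
#' @return Expected count of droplets containing exactly one molecule.
#' @export
expected_singletons <- function(n_total, n_empty, lambda = NULL) {
  if (is.null(lambda)) lambda <- estimate_lambda(n_total, n_empty)
  n_total * lambda * exp(-lambda)
}

#' Poisson singleton-based VAF estimate from droplet counts
#'
#' The VAF is estimated as the number of droplets lacking the reference
#' allele (mutant-only droplets) over the Poisson-expected number of
#' singleton droplets. Valid in the dilute regime where multi-molecule
#' droplets are rare; the estimate carries a delta-method standard error
#' when `se = TRUE` (treating the mutant-only count as Poisson).
#'
#' @param counts A data.frame or list with fields `n_total`, `n_empty`,
#'   `n_mut_only` (droplets positive for mutant and negative for reference).
#' @param se Also return a standard error (default `FALSE`).
#' @return A list with `vaf`, `lambda`, `singletons` (and `se_vaf` when
#'   requested). `vaf` is 0 when no mutant-only droplets are observed.
#' @export
poisson_vaf <- function(counts, se = FALSE) {
  n_total <- counts$n_total; n_empty <- counts$n_empty
  n_mut <- counts$n_mut_only
  stopifnot(n_mut >= 0)
  if (n_mut == 0 && n_empty == n_total) {
    out <- list(vaf = 0, lambda = 0, singletons = 0)
    if (se) out$se_vaf <- 0
    return(out)
  }
  lambda <- estimate_lambda(n_total, n_empty)
  s <- expected_singletons(n_total, lambda = lambda)
  out <- list(vaf = if (n_mut == 0) 0 else n_mut / s,
              lambda = lambda, singletons = s)
  if (se) out$se_vaf <- sqrt(n_mut) / s
  out
}

#' Poisson estimate of assayed molecules from positive droplets
#'
#' `molecules = n_total * (-log(1 - n_positive / n_total)) * dilution`,
#' correcting droplet counts for multi-molecule occupancy; used to load a
#' fixed number of uniquely tagged molecules into library amplification.
#'
#' @param n_total Total droplets counted.
#' @param n_positive Droplets positive for the assay (< n_total).
#' @param dilution Fold-dilution of the assayed aliquot (default 1).
#' @return Estimated molecules in the undiluted input.
#' @export
quantify_molecules <- function(n_total, n_positive, dilution = 1) {
  stopifnot(n_total > 0, n_positive >= 0, dilution > 0)
  if (any(n_positive >= n_total)) {
    stop("saturated ddPCR well: all droplets positive, count is unbounded")
  }
  n_total * (-log(1 - n_positive / n_total)) * dilution
}

#' Summarise droplet-count wells into per-sample estimates
#'
#' Sums droplet categories across the wells of each sample and applies the
#' Poisson VAF estimator to the pooled counts.
#'
#' @param wells data.frame with columns `sample`, `n_total`, `n_empty`,
#'   `n_mut_only` (and optionally `n_ref_pos`, `dilution`).
#' @return data.frame with one row per sample: pooled counts, `lambda`,
#'   `singletons`, `vaf`, `se_vaf`.
#' @export
ddpcr_estimates <- function(wells) {
  out <- lapply(split(wells, wells$sample), function(w) {
    cnt <- list(n_total = sum(w$n_total), n_empty = sum(w$n_empty),
                n_mut_only = sum(w$n_mut_only))
    est <- poisson_vaf(cnt, se = TRUE)
    data.frame(sample = w$sample[1L], n_total = cnt$n_total,
               n_empty = cnt$n_empty, n_mut_only = cnt$n_mut_only,
               lambda = est$lambda, singletons = est$singletons,
               vaf = est$vaf, se_vaf = est$se_vaf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
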