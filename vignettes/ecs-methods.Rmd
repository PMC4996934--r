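---
title: "Error-corrected sequencing: consensus calling and the binomial error model"
author: "ecscall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-corrected sequencing: consensus calling and the binomial error model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecscall)
```

## The problem

Standard short-read sequencing mis-calls roughly 1 base in 100–1000, so a
somatic variant present in fewer than ~2% of alleles (variant allele
fraction, VAF < 0.02) is indistinguishable from noise. Error-corrected
sequencing (ECS) breaks that floor in two stages:

1. **Molecular consensus.** Every template molecule is tagged with a random
   16-nt unique molecular identifier (UMI) before amplification. All read
   pairs carrying the same UMI derive from one molecule; a base call that
   is not shared by (nearly) all members of such a *read family* is an
   amplification or sequencing artefact and is suppressed when the family
   is collapsed to an error-corrected consensus sequence (ECCS).
2. **Statistical calling.** Residual consensus-level errors are
   position- and substitution-specific (cytosine deamination, for example,
   inflates C→T). For each individual, a background error rate
   $\hat p_{j,b}$ is estimated at every position $j$ and alternate allele
   $b$ from the libraries of *all other individuals*, and an observed
   count $k$ among $n$ ECCSs is tested against
   $X \sim \mathrm{Binomial}(n, \hat p_{j,b})$ with the exact upper tail
   $P(X \ge k)$, Bonferroni-corrected over all tests.

At the published operating point this chain detects clones down to
0.0003 VAF — roughly one mutant cell in 10,000 — which is what makes
clonal haematopoiesis measurable in essentially all middle-aged adults
rather than the few percent visible to conventional sequencing.

## The consensus stage

`consensus_pipeline()` applies, in order:

| step | rule | default |
|------|------|---------|
| primer clip | remove the first `clip_len` bases of each mate | 30 nt |
| family grouping | exact UMI string identity | 16-nt UMIs |
| family size | families with fewer members yield nothing | ≥ 5 read pairs |
| base agreement | modal base emitted iff modal count / family size ≥ `agreement`, else `N` | 0.90 |
| N filter | discard the ECCS iff N fraction **strictly** exceeds `max_n_frac` of the paired length | 0.10 of 228 nt |

Design choices a user should know about:

* **Exact-match UMI grouping.** No UMI error correction or network
  clustering is attempted: two UMIs differing at one position are two
  families. This matches the fixed published procedure; directional
  clustering would recover a few percent more families at the cost of a
  different (and harder to audit) error model.
* **Positional stacking.** All mates of a family are assumed to start at
  the same amplicon coordinate (fixed-primer amplicon chemistry), so
  "alignment" within a family is positional. Families whose members differ
  in length are rejected with an error naming the UMI.
* **Qualities are ignored.** The consensus compares nucleotides only;
  emitted consensus qualities are a fixed placeholder.
* **Ties and member Ns.** An exact tie for the modal base yields `N`
  (this includes the open case of exactly 90% agreement with three
  distinct bases: the non-modal remainder cannot reach 90%, so only true
  ties matter, and they resolve to `N`). Member `N` bases count toward
  the family-size denominator but can never be the modal base — missing
  evidence argues against a call, never for one.
* The agreement comparison is done as `modal/size >= agreement`, i.e. in
  the same floating-point rounding as the stated decimal threshold, so a
  family of 20 with modal count 18 sits exactly on the 0.90 boundary and
  is called.

## Pileups and coordinates

`build_pileup()` tallies every aligned non-`N` consensus base inside the
target space into per-position A/C/G/T counts; depth is their sum, so
consensus `N`s contribute no evidence anywhere. Internally the package
uses 1-based closed coordinates (the Bioconductor `GRanges` convention;
targets are `GRanges`), BED input is consumed as standard 0-based
half-open and converted on import, and all TSV/VCF output is 1-based.
Read alignment itself is out of scope: the pipeline consumes aligned
consensus records (SAM via `pileup_from_sam()`, or the fixed-layout
amplicon placement of `place_consensus()` for synthetic data).

## The error model

`build_error_profile()` pools counts across every library *not* from the
focal individual and sets

$$\hat p_{j,b} = \frac{k_{j,b} + 1}{n_j + 1}$$

with a one-count pseudocount. The pseudocount guarantees a usable
(non-zero) null rate at positions where the pooled libraries show no
errors at all; it is slightly conservative (it can only raise
$\hat p$). Rates are kept **per alternate allele** by default, which
captures substitution-type asymmetry such as the C→T deamination excess;
`mode = "per_position"` pools the three alternates, for users who prefer
a coarser but better-sampled null.

The Bonferroni divisor is $m = 3 \times$ (target positions) — three
alternate alleles per reference position is the natural count of tests
performed — and is reported with the threshold and overridable via
`bonferroni_m` for users who count tests differently.

## The SNV filter chain

A site is *eligible* when depth ≥ 1000 ECCS, the position is inside the
target space, and any annotated population minor allele fraction is not
above 0.01 (exclusion is strictly "above": a site at exactly 0.01 stays
eligible). An eligible candidate is called when all of

* (a) exact binomial $P(X \ge k) <$ the Bonferroni-corrected threshold
  (0.05 family-wise),
* (b) $k \ge 5$ supporting ECCSs,
* (c) VAF $> 10^{-4}$ (strict), and
* (d) criteria a–c hold in at least two replicate libraries **within a
  single time point**

hold. For (d) we read "two replicates from one of the two time points"
literally: one passing replicate in each of two time points does not
qualify. Because that reading is not the only possible one, it is exposed
as `require_single_timepoint = FALSE` in `merge_replicates()`.

The per-time-point VAF of a reported variant is depth-weighted — pooled
alternate counts over pooled depth across that time point's replicates —
rather than a mean of replicate VAFs; with unequal replicate depths the
pooled ratio is the maximum-likelihood single-number summary. Reported
calls are classified `both` / `first_only` / `second_only` by which time
points pass (d), and the clonal report keeps calls whose VAF at **every
supported time point** is strictly below 0.2; the rest are diverted to a
non-clonal (likely germline) stream rather than dropped.

## Indel post-filters

Indel detection itself is delegated to an external caller consumed as
VCF; the package enforces the published candidate thresholds (depth
≥ 1000, support ≥ 5, VAF ≥ 0.001 — inclusive, these are the upstream
caller's minimums) and then removes the two classic artefact classes:

* **Homopolymer slippage**: 1-bp indels whose base matches a reference
  run of ≥ 4 identical bases immediately right of the left-aligned
  anchor. Candidates are left-normalized first (`left_align_indels()`,
  idempotent), so the anchoring convention is deterministic.
* **Cross-sample recurrence**: an identical normalized indel seen in two
  or more *individuals* is removed everywhere. "Sample" here must mean
  individual, not library: replicate concordance is *required* by filter
  (d), so removing replicate-recurrent indels would contradict the
  pipeline's own reporting rule. A `by = "library"` switch exists for
  the stricter reading.

Replicate concordance and the <0.2 clonal ceiling are then applied by the
same code path as SNVs.

## ddPCR quantification

Droplet digital PCR partitions template into droplets with Poisson
occupancy $\lambda$, estimated from the all-negative fraction:
$\lambda = -\ln(n_{\text{empty}}/n_{\text{total}})$. The expected number
of singleton droplets is $S = n_{\text{total}}\,\lambda e^{-\lambda}$ and
the VAF estimate is $n_{\text{mut-only}}/S$, where mutant-only droplets
are positive for the mutant assay and negative for the reference allele.
$\lambda$ is estimated from double-negative droplets so that the
mutant-only count is commensurate with the singleton denominator. This is
the standard Poisson singleton estimator; it is slightly biased upward in
concentrated wells (a multi-molecule all-mutant droplet counts as one
singleton), which is negligible at the dilute $\lambda \lesssim 0.1$ used
for validation wells. A delta-method standard error (treating the
mutant-only count as Poisson) is available; saturation (no empty
droplets, or all droplets positive) is an error, not a number.
`quantify_molecules()` applies the same occupancy correction, times the
dilution factor, for library loading. Volume constants are deliberately
not baked in: outputs are molecules per assayed aliquot.

## The synthetic data generator

Three seeded levels, each with a ground-truth ledger that can be recounted
exactly from the emitted artifacts:

* `simulate_read_set()` emulates the sequencing input contract: one
  amplicon per run, each library receiving `molecules` uniquely tagged
  templates, clones converting molecules with probability VAF, family
  sizes drawn from a zero-truncated negative binomial (over-dispersed
  amplicon duplication; `family_dispersion = Inf` recovers Poisson), and
  independent per-base substitution errors. UMI collisions occur
  naturally among random 16-mers and are flagged in the ledger so
  consensus tests can exclude them.
* `simulate_pileups()` is the count-level shortcut for caller testing:
  per-alternate-allele background counts are
  $\mathrm{Binomial}(\text{depth}, e)$ — the *post-consensus residual*
  error, a separate knob from the read-level rate — plus
  $\mathrm{Binomial}(\text{depth}, \mathrm{VAF})$ clone counts, with
  replicates independent.
* `simulate_droplets()` draws Poisson occupancies and Bernoulli mutant
  molecules and tallies droplet categories.

The default manifest mirrors the study design: individuals × two time
points × two technical replicates. What the generator deliberately does
**not** model: PCR jackpotting and chimeras, quality-score structure,
PhiX spike-ins, mapping error, and indel generation at read level. Tests
passing on this generator therefore demonstrate the *statistical* and
*algorithmic* correctness of the chain — error suppression, threshold
boundaries, false-positive control, parameter recovery — not robustness
to every artefact of real libraries.

## Validation conditions and problem sizes

The packaged validation (test suite and `scripts/acceptance.R`) uses
desk-scale versions of the study conditions, chosen once:

* Detection-floor sweep: 1000 target positions, one individual, two
  replicates per time point at 60,000× ECCS depth, uniform
  per-alternate-allele background $10^{-5}$ supplied as the profile,
  probed VAFs {0.001, 0.0005, 0.0003}, 100 seeded repeats per VAF. At
  0.0003 VAF a clone contributes ~18 mutant ECCSs per replicate against a
  background of ~0.6, comfortably clearing the k ≥ 7 implied by the
  significance and VAF criteria, so the measured floor is 0.0003.
* False-positive control: identical conditions without a clone, 100
  repeats; mean reported SNVs below 0.05.
* VAF recovery: spikes at {0.001, 0.01, 0.1} with two replicates at
  100,000×, pooled estimates within $3\sqrt{v(1-v)/200{,}000}$ of truth.
* End-to-end: read-level runs at 13,000 molecules per library
  (family mean 7, dispersion 50), sized so the retained ECCS depth stays
  above 10,000 across the seeded runs; a 0.01-VAF clone must be recovered
  in 100 of 100 runs.

## Known limitations

* No UMI error correction (exact-match grouping slightly fragments
  families and deflates family sizes).
* The binomial null under-calls true hotspots recurring across
  individuals — a variant present in many pooled libraries inflates its
  own background rate; this mirrors the method's published behaviour and
  is not corrected here.
* Indels are filtered, never detected, and complex/multi-nucleotide
  variants are out of scope.
* The ddPCR estimator assumes dilute wells; concentrated wells should be
  summed across more dilute replicates instead.
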