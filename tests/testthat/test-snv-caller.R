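# The rare-SNV filter chain.

test_that("site filters enforce depth, target membership and germline exclusion", {
  tgt <- toy_target("chr1", 0L, 1000L)
  germ <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                     ref = "A", alt = "T", maf = c(0.02, 0.01, 0.005),
                     stringsAsFactors = FALSE)
  pl <- rbind(toy_pileup(5L, 10000L, pos = 100L),   # germline MAF 0.02
              toy_pileup(5L, 10000L, pos = 200L),   # exactly 0.01: eligible
              toy_pileup(5L, 10000L, pos = 300L),   # 0.005: eligible
              toy_pileup(5L, 999L, pos = 400L),     # below depth floor
              toy_pileup(5L, 1000L, pos = 500L),    # at depth floor: eligible
              toy_pileup(5L, 10000L, pos = 2000L))  # outside target
  sites <- apply_site_filters(pl, tgt, germ)
  at <- function(p, a) sites[sites$pos == p & sites$alt == a, ]
  expect_false(at(100L, "T")$eligible)
  expect_false(at(100L, "T")$germline_ok)
  expect_true(at(100L, "C")$eligible)   # other alleles untouched by germline
  expect_true(at(200L, "T")$eligible)   # strictly "above" excludes
  expect_true(at(300L, "T")$eligible)
  expect_false(at(400L, "T")$depth_ok)
  expect_true(at(500L, "T")$eligible)
  expect_false(at(2000L, "T")$in_target)
  expect_false(at(2000L, "T")$eligible)
})

test_that("candidate calling applies criteria a-c with recorded flags", {
  tgt <- toy_target("chr1", 0L, 1000L)
  th <- bonferroni_threshold(0.05, tgt)  # 0.05/3000
  cases <- list(
    # (k, depth, p_hat, expect_pass, failing flag)
    list(k = 4L, n = 10000L, p = 1e-6, pass = FALSE, flag = "pass_support"),
    list(k = 10L, n = 100000L, p = 1e-6, pass = FALSE, flag = "pass_vaf"),
    list(k = 25L, n = 10000L, p = 1e-4, pass = TRUE, flag = NULL),
    list(k = 11L, n = 100000L, p = 1e-6, pass = TRUE, flag = NULL))
  for (cs in cases) {
    pl <- toy_pileup(cs$k, cs$n)
    sites <- apply_site_filters(pl, tgt, min_depth = 1000L)
    prof <- uniform_profile_for(pl, cs$p)
    cand <- call_candidates(sites, prof, th)
    row <- cand[cand$alt == "T", ]
    expect_equal(row$pass, cs$pass, info = cs$k)
    if (!is.null(cs$flag)) expect_false(row[[cs$flag]], info = cs$k)
    # significance flag always agrees with the exact oracle
    expect_equal(row$pass_sig,
                 oracle_binom_tail(cs$k, cs$n, cs$p) < as.numeric(th))
  }
})

test_that("VAF floor is exclusive: k/n equal to 1e-4 fails, above passes", {
  tgt <- toy_target("chr1", 0L, 1000L)
  th <- bonferroni_threshold(0.05, tgt)
  pl10 <- toy_pileup(10L, 100000L)
  pl11 <- toy_pileup(11L, 100000L)
  prof <- uniform_profile_for(pl10, 1e-6)
  c10 <- call_candidates(apply_site_filters(pl10, tgt), prof, th)
  c11 <- call_candidates(apply_site_filters(pl11, tgt), prof, th)
  expect_false(c10[c10$alt == "T", "pass_vaf"])
  expect_true(c11[c11$alt == "T", "pass_vaf"])
})

test_that("passing is monotone in the supporting count at fixed depth", {
  tgt <- toy_target("chr1", 0L, 1000L)
  th <- bonferroni_threshold(0.05, tgt)
  depth <- 50000L
  passed <- vapply(1:40, function(k) {
    pl <- toy_pileup(k, depth)
    cand <- call_candidates(apply_site_filters(pl, tgt),
                            uniform_profile_for(pl, 1e-5), th)
    cand[cand$alt == "T", "pass"]
  }, TRUE)
  # once k passes, every larger k passes
  first <- which(passed)[1]
  expect_false(is.na(first))
  expect_true(all(passed[first:40]))
})

test_that("candidates missing from the profile are skipped and counted", {
  tgt <- toy_target("chr1", 0L, 1000L)
  pl <- rbind(toy_pileup(5L, 10000L, pos = 100L),
              toy_pileup(5L, 10000L, pos = 101L))
  prof <- uniform_profile_for(toy_pileup(5L, 10000L, pos = 100L), 1e-5)
  cand <- call_candidates(apply_site_filters(pl, tgt), prof, 1e-5)
  expect_equal(attr(cand, "n_skipped_profile"), 3L)  # 3 alts at pos 101
  expect_true(all(cand$pos == 100L))
})

test_that("every eligible (site, allele) appears exactly once with complete flags", {
  sim <- simulate_pileups(seed = 61, manifest = sim_manifest(1, 1, 1),
                          n_positions = 50L, depth = 5000L, error_rate = 1e-4)
  tgt <- sim$target
  sites <- apply_site_filters(sim$pileups, tgt, min_depth = 1000L)
  cand <- call_candidates(sites, uniform_profile_for(sim$pileups, 1e-4),
                          bonferroni_threshold(0.05, tgt))
  expect_equal(nrow(cand), 3L * 50L)
  expect_false(anyDuplicated(cand[, c("chrom", "pos", "alt")]) > 0)
  expect_false(any(is.na(cand$pass_sig | cand$pass_support | cand$pass_vaf)))
})

test_that("replicate merging requires two passing replicates within one time point", {
  manifest <- toy_manifest()
  mk <- function(lib, pass) {
    data.frame(library_id = lib, chrom = "chr1", pos = 100L, ref = "A",
               alt = "T", k = 10L, depth = 10000L, pass = pass,
               stringsAsFactors = FALSE)
  }
  # both replicates of TP1 pass -> reported
  cand <- rbind(mk("I01_T1_A", TRUE), mk("I01_T1_B", TRUE),
                mk("I01_T2_A", FALSE), mk("I01_T2_B", FALSE))
  out <- merge_replicates(cand, manifest)
  expect_equal(nrow(out), 1L)
  expect_true(out$pass_tp1); expect_false(out$pass_tp2)
  expect_equal(out$tp1_pattern, "AB")
  # single passing replicate -> not reported
  cand <- rbind(mk("I01_T1_A", TRUE), mk("I01_T1_B", FALSE))
  expect_equal(nrow(merge_replicates(cand, manifest)), 0L)
  # one passing replicate in each time point -> not reported (strict), but
  # reported under the relaxed strictness switch
  cand <- rbind(mk("I01_T1_A", TRUE), mk("I01_T1_B", FALSE),
                mk("I01_T2_A", TRUE), mk("I01_T2_B", FALSE))
  expect_equal(nrow(merge_replicates(cand, manifest)), 0L)
  expect_equal(nrow(merge_replicates(cand, manifest,
                                     require_single_timepoint = FALSE)), 1L)
})

test_that("per-time-point VAF is pooled counts over pooled depth", {
  manifest <- toy_manifest()
  cand <- data.frame(
    library_id = c("I01_T1_A", "I01_T1_B"),
    chrom = "chr1", pos = 100L, ref = "A", alt = "T",
    k = c(10L, 30L), depth = c(10000L, 30000L), pass = TRUE,
    stringsAsFactors = FALSE)
  out <- merge_replicates(cand, manifest)
  expect_equal(out$tp1_k, 40)
  expect_equal(out$tp1_depth, 40000)
  expect_equal(out$tp1_vaf, 40 / 40000)  # not mean(0.001, 0.001) in general
  expect_equal(out$tp1_nrep_pass, 2L)
})

test_that("a library absent from the manifest is a configuration error", {
  cand <- data.frame(library_id = "ghost", chrom = "chr1", pos = 1L,
                     ref = "A", alt = "T", k = 5L, depth = 5000L, pass = TRUE,
                     stringsAsFactors = FALSE)
  expect_error(merge_replicates(cand, toy_manifest()), "ghost")
})

test_that("time-point classification tallies both/first/second", {
  calls <- data.frame(
    individual_id = "I01", chrom = "chr1", pos = 1:10, ref = "A", alt = "T",
    tp1_vaf = 0.001, tp2_vaf = 0.001,
    pass_tp1 = c(rep(TRUE, 4), TRUE, TRUE, rep(FALSE, 4)),
    pass_tp2 = c(rep(TRUE, 4), FALSE, FALSE, rep(TRUE, 4)),
    stringsAsFactors = FALSE)
  out <- classify_timepoints(calls)
  expect_equal(unname(attr(out, "summary")), c(4L, 2L, 4L))
  expect_equal(out$timepoint_class[5], "first_only")
  expect_equal(out$timepoint_class[10], "second_only")
  bad <- calls; bad$pass_tp1[1] <- bad$pass_tp2[1] <- FALSE
  expect_error(classify_timepoints(bad), "consistency")
})

test_that("clonal ceiling is exclusive and diverts, never drops", {
  mkcall <- function(vaf) {
    data.frame(individual_id = "I01", chrom = "chr1", pos = 1L, ref = "A",
               alt = "T", tp1_vaf = vaf, tp2_vaf = NA_real_,
               pass_tp1 = TRUE, pass_tp2 = FALSE, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, lapply(c(0.0005, 0.05, 0.19, 0.2, 0.25), mkcall))
  out <- report_clonal(calls)
  expect_equal(out$clonal$tp1_vaf, c(0.0005, 0.05, 0.19))
  expect_equal(out$non_clonal$tp1_vaf, c(0.2, 0.25))
  expect_equal(nrow(out$clonal) + nrow(out$non_clonal), nrow(calls))
})

test_that("the ceiling applies only at replicate-supported time points", {
  call <- data.frame(individual_id = "I01", chrom = "chr1", pos = 1L,
                     ref = "A", alt = "T", tp1_vaf = 0.001, tp2_vaf = 0.5,
                     pass_tp1 = TRUE, pass_tp2 = FALSE,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(report_clonal(call)$clonal), 1L)
  call$pass_tp2 <- TRUE
  expect_equal(nrow(report_clonal(call)$clonal), 0L)
})

test_that("compartment tabulation emits a complete labelled grid", {
  calls <- data.frame(individual_id = "I01", chrom = "chr1", pos = 100L,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  cv <- data.frame(individual_id = "I01", chrom = "chr1", pos = 100L,
                   ref = "A", alt = "T",
                   timepoint = 1L,
                   compartment = c("bulk", "B", "myeloid"),
                   vaf = c(0.002, 0.0021, 0.0019), stringsAsFactors = FALSE)
  tab <- tabulate_compartments(calls, cv)
  expect_equal(nrow(tab), 8L)  # 2 time points x 4 compartments
  tcell <- tab[tab$timepoint == 1L & tab$compartment == "T", ]
  expect_false(tcell$present)
  expect_true(is.na(tcell$vaf))
  expect_equal(sum(tab$present), 3L)
  bad <- cv; bad$compartment[1] <- "plasma"
  expect_error(tabulate_compartments(calls, bad), "plasma")
})

test_that("the caller is deterministic on identical inputs", {
  sim <- simulate_pileups(seed = 77, manifest = toy_manifest(),
                          n_positions = 100L, depth = 20000L,
                          error_rate = 1e-5,
                          clones = data.frame(pos = 10L, alt = NA, vaf = 0.01,
                                              individual_id = "I01"))
  prof <- uniform_profile_for(sim$pileups, 1e-5)
  r1 <- call_snvs(sim$pileups, sim$manifest, sim$target, profile = prof)
  r2 <- call_snvs(sim$pileups, sim$manifest, sim$target, profile = prof)
  expect_identical(r1$calls, r2$calls)
  expect_identical(r1$candidates, r2$candidates)
  # and the serialized report is byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  utils::write.table(r1$calls, f1); utils::write.table(r2$calls, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reported calls are a subset of evaluated candidates", {
  sim <- simulate_pileups(seed = 78, manifest = toy_manifest(),
                          n_positions = 100L, depth = 20000L,
                          error_rate = 1e-5,
                          clones = data.frame(pos = 10L, alt = NA, vaf = 0.01,
                                              individual_id = "I01"))
  res <- call_snvs(sim$pileups, sim$manifest, sim$target,
                   profile = uniform_profile_for(sim$pileups, 1e-5))
  ck <- paste(res$calls$chrom, res$calls$pos, res$calls$alt)
  ak <- paste(res$candidates$chrom, res$candidates$pos, res$candidates$alt)
  expect_true(all(ck %in% ak))
})

test_that("spiked clone VAFs are recovered within binomial error", {
  # pooled over two replicates at depth 100000 each, tolerance
  # 3 * sqrt(v(1-v)/200000); run over a seeded set of repeats
  for (v in c(0.001, 0.01, 0.1)) {
    ok <- 0L
    for (r in 1:20) {
      sim <- simulate_pileups(seed = 9000 + r, manifest = sim_manifest(1, 1, 2),
                              n_positions = 20L, depth = 100000L,
                              error_rate = 1e-5,
                              clones = data.frame(pos = 5L, alt = NA, vaf = v,
                                                  individual_id = "I01",
                                                  timepoints = "1"))
      res <- call_snvs(sim$pileups, sim$manifest, sim$target,
                       profile = uniform_profile_for(sim$pileups, 1e-5))
      stopifnot(nrow(res$calls) >= 1L)
      got <- res$calls$tp1_vaf[res$calls$pos == 5L]
      if (abs(got - v) <= 3 * sqrt(v * (1 - v) / 200000)) ok <- ok + 1L
    }
    expect_gte(ok, 19L)
  }
})
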