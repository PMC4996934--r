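# Read demultiplexing, primer clipping, UMI grouping and family consensus.

test_that("sample-index demultiplexing resolves unique matches within one mismatch", {
  map <- c(libA = "AAAAAAAA", libB = "CCCCCCCC")
  expect_equal(assign_sample_index("AAAAAAAA", map), "libA")      # exact
  expect_equal(assign_sample_index("AAAAAAAT", map), "libA")      # distance 1
  expect_equal(assign_sample_index("AAAACCCC", map), "unassigned") # distance 4 from both
  # equidistant (distance 1 from two libraries) is ambiguous
  map2 <- c(libA = "AAAAAAAA", libB = "AAAAAAGG")
  expect_equal(assign_sample_index("AAAAAAAG", map2), "unassigned")
  # zero-mismatch mode rejects distance-1 indices
  expect_equal(assign_sample_index("AAAAAAAT", map, max_mismatch = 0L),
               "unassigned")
})

test_that("demultiplexing rejects duplicate or unequal-length index maps", {
  expect_error(assign_sample_index("AAAA", c(a = "AAAA", b = "AAAA")),
               "duplicate")
  expect_error(assign_sample_index("AAAA", c(a = "AAAA", b = "CCCCC")),
               "equal length")
})

test_that("demultiplex_reads partitions every record exactly once", {
  set.seed(11)
  map <- c(libA = "AAAAAAAA", libB = "CCCCCCCC", libC = "GGGGGGGG")
  idx <- c(sample(map, 50, replace = TRUE), rep("TTTTTTTT", 5),
           "AAAAAAAC", "CCCCCCCA")
  reads <- data.frame(umi = strrep("A", 16), r1 = "ACGT", r2 = "ACGT",
                      sample_index = idx, stringsAsFactors = FALSE)
  out <- demultiplex_reads(reads, map)
  expect_setequal(names(out), c("libA", "libB", "libC", "unassigned"))
  expect_equal(sum(vapply(out, nrow, 0L)), nrow(reads))
  expect_equal(nrow(out$unassigned), 5L)
})

test_that("primer clipping removes exactly clip_len leading bases and drops short reads", {
  reads <- data.frame(
    umi = strrep("A", 16),
    r1 = c(strrep("G", 144), strrep("G", 30), strrep("G", 144)),
    r2 = c(strrep("C", 144), strrep("C", 144), strrep("C", 100)),
    stringsAsFactors = FALSE)
  out <- clip_primers(reads, clip_len = 30L)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_dropped_short"), 1L)
  expect_equal(nchar(out$r1), c(114L, 114L))
  expect_equal(nchar(out$r2), c(114L, 70L))
  # a full paired record covers 228 nt after clipping 144-nt mates
  expect_equal(nchar(out$r1[1]) + nchar(out$r2[1]), 228L)
})

test_that("UMI grouping is by exact string identity", {
  u1 <- paste(rep("A", 16), collapse = "")
  u2 <- sub("A$", "C", u1)  # one mismatch: distinct family
  reads <- data.frame(umi = c(rep(u1, 10), u2),
                      r1 = "ACGT", r2 = "ACGT", stringsAsFactors = FALSE)
  cons <- call_consensus(reads, min_family_size = 1L)
  expect_equal(nrow(cons), 2L)
  expect_equal(sort(cons$family_size), c(1L, 10L))
})

test_that("grouping conserves read counts across families and exclusions", {
  set.seed(7)
  umis <- random_family(7, 16, bases = c("A", "C", "G", "T"),
                        probs = rep(0.25, 4))
  reads <- data.frame(umi = sample(umis, 100, replace = TRUE),
                      r1 = "ACGT", r2 = "ACGT", stringsAsFactors = FALSE)
  reads$umi[1:3] <- sub("^A", "N", strrep("N", 16))  # N-containing UMIs
  cons <- call_consensus(reads, min_family_size = 1L)
  expect_equal(attr(cons, "n_umi_excluded"), 3L)
  expect_lte(attr(cons, "families_total"), 7L)
  expect_equal(sum(cons$family_size) + attr(cons, "n_umi_excluded"),
               nrow(reads))
})

test_that("consensus agreement boundary: >=90% emits the modal base, <90% emits N", {
  # 9 of 10 agree -> 0.90 exactly -> base emitted
  reads <- family_frame(c(rep("ACGT", 9), "CCGT"))
  cons <- call_consensus(reads)
  expect_equal(cons$consensus1, "ACGT")
  expect_equal(cons$n_count, 0L)
  # 17 of 20 agree -> 0.85 -> N
  reads <- family_frame(c(rep("ACGT", 17), rep("CCGT", 3)), r2 = "GGGG")
  cons <- call_consensus(reads)
  expect_equal(cons$consensus1, "NCGT")
  expect_equal(cons$n_count, 1L)
  # unanimity reproduces the read exactly
  reads <- family_frame(rep("ACGTACGT", 5))
  cons <- call_consensus(reads)
  expect_equal(cons$consensus1, "ACGTACGT")
  expect_equal(cons$n_count, 0L)
  expect_equal(cons$total_len, 16L)
})

test_that("families below the minimum size yield no consensus", {
  for (size in 3:7) {
    reads <- family_frame(rep("ACGT", size))
    cons <- call_consensus(reads, min_family_size = 5L)
    expect_equal(nrow(cons), as.integer(size >= 5L), info = size)
  }
})

test_that("modal-base ties resolve to N and member Ns never win", {
  # 10 A + 10 C at position 1 of a size-20 family: tie at 50%, low agreement -> N
  reads <- family_frame(c(rep("AGGG", 10), rep("CGGG", 10)))
  cons <- call_consensus(reads, agreement = 0.5)
  expect_equal(substring(cons$consensus1, 1, 1), "N")
  # Ns dominate a column but cannot be called: 4 N + 1 A of 5 -> A is modal
  # with 1/5 = 0.2 agreement -> N at default agreement
  reads <- family_frame(c(rep("NGGG", 4), "AGGG"))
  cons <- call_consensus(reads)
  expect_equal(substring(cons$consensus1, 1, 1), "N")
  # but Ns still count in the denominator: 9 A + 1 N = 0.9 -> A
  reads <- family_frame(c(rep("AGGG", 9), "NGGG"))
  cons <- call_consensus(reads)
  expect_equal(substring(cons$consensus1, 1, 1), "A")
})

test_that("consensus matches a brute-force per-position oracle on random families", {
  set.seed(42)
  for (rep_i in 1:25) {
    size <- sample(1:50, 1)
    len <- sample(5:30, 1)
    r1 <- random_family(size, len)
    r2 <- random_family(size, len)
    reads <- family_frame(r1, r2)
    cons <- call_consensus(reads, min_family_size = 1L)
    expect_equal(cons$consensus1, oracle_consensus(r1), info = rep_i)
    expect_equal(cons$consensus2, oracle_consensus(r2), info = rep_i)
    expect_equal(cons$n_count,
                 sum(strsplit(paste0(oracle_consensus(r1), oracle_consensus(r2)),
                              "")[[1]] == "N"))
  }
})

test_that("consensus is invariant under permutation of family members", {
  set.seed(43)
  r1 <- random_family(20, 12)
  r2 <- random_family(20, 12)
  reads <- family_frame(r1, r2)
  perm <- sample(nrow(reads))
  expect_equal(call_consensus(reads)[, -1],
               call_consensus(reads[perm, ])[, -1])
})

test_that("unequal member lengths raise an error naming the family UMI", {
  umi <- strrep("G", 16)
  reads <- data.frame(umi = umi, r1 = c("ACGT", "ACGTT", rep("ACGT", 3)),
                      r2 = "ACGT", stringsAsFactors = FALSE)
  expect_error(call_consensus(reads), umi)
})

test_that("N-fraction filter discards strictly above the threshold", {
  # 23/228 = 10.09% -> discarded; 22/228 = 9.65% -> retained
  expect_false(filter_n_fraction(23L, 228L))
  expect_true(filter_n_fraction(22L, 228L))
  expect_true(filter_n_fraction(0L, 228L))
  # exactly at the threshold is retained (strictly greater discards)
  expect_true(filter_n_fraction(22L, 220L))
  expect_error(filter_n_fraction(0L, 0L), "positive")
})

test_that("consensus error rate is quadratically suppressed for families of five", {
  # with per-base error eps and >=5-read families, the consensus mis-call
  # rate must fall below eps^2 (an error must recur in >=90% of members)
  set.seed(99)
  eps <- 0.01
  n_fam <- 400L
  len <- 50L
  truth <- strrep("A", len)
  bad <- 0L; called <- 0L
  for (i in seq_len(n_fam)) {
    m <- matrix("A", nrow = 5, ncol = len)
    err <- which(matrix(runif(5 * len) < eps, nrow = 5))
    m[err] <- sample(c("C", "G", "T"), length(err), replace = TRUE)
    seqs <- apply(m, 1, paste, collapse = "")
    cons <- call_consensus(family_frame(seqs, truth))
    cc <- strsplit(cons$consensus1, "")[[1]]
    bad <- bad + sum(cc != "A" & cc != "N")
    called <- called + sum(cc != "N")
  }
  expect_lt(bad / called, eps^2)
})

test_that("consensus pipeline accounting is conserved", {
  set.seed(5)
  sim <- simulate_read_set(seed = 5, manifest = sim_manifest(1, 1, 1),
                           molecules = 200L, family_mean = 6,
                           read_len = 40L, clip_len = 10L)
  reads <- sim$libraries[[1]]
  out <- consensus_pipeline(reads, clip_len = 10L)
  rep_ <- out$report
  expect_equal(rep_[["eccs_retained"]] + rep_[["eccs_discarded"]],
               rep_[["families_pass_size"]])
  expect_equal(rep_[["reads_in"]], nrow(reads))
  expect_lte(rep_[["families_pass_size"]], rep_[["families_total"]])
  # reads in retained + discarded families plus reads in small families,
  # dropped-short pairs and N-UMI pairs account for every input pair
  clipped <- clip_primers(reads, 10L)
  all_fam <- call_consensus(clipped, min_family_size = 1L)
  small <- sum(all_fam$family_size[all_fam$family_size < 5L])
  expect_equal(sum(out$consensus$family_size) + sum(out$discarded$family_size) +
                 small + rep_[["dropped_short"]] + rep_[["umi_excluded"]],
               rep_[["reads_in"]])
})
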