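# Seeded synthetic-data generation at three levels: UMI-tagged reads,
# count-level pileups, and droplet counts, each with a ground-truth ledger
# that can be recounted from the emitted data.

#' Build a sample manifest for simulation
#'
#' The default layout mirrors a longitudinal technical-replicate design:
#' each individual sampled at two time points, each sample prepared as two
#' replicate libraries.
#'
#' @param n_individuals Number of individuals (default 2).
#' @param n_timepoints Time points per individual (default 2).
#' @param n_replicates Replicate libraries per (individual, time point)
#'   (default 2).
#' @return Manifest data.frame with columns `library_id`, `individual_id`,
#'   `timepoint`, `replicate`.
#' @export
sim_manifest <- function(n_individuals = 2L, n_timepoints = 2L,
                         n_replicates = 2L) {
  g <- expand.grid(replicate = LETTERS[seq_len(n_replicates)],
                   timepoint = seq_len(n_timepoints),
                   individual_id = sprintf("I%02d", seq_len(n_individuals)),
                   stringsAsFactors = FALSE)
  data.frame(
    library_id = sprintf("%s_T%d_%s", g$individual_id, g$timepoint, g$replicate),
    individual_id = g$individual_id,
    timepoint = as.integer(g$timepoint),
    replicate = g$replicate,
    stringsAsFactors = FALSE)
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random UMIs as strings, via one intToUtf8 round trip
random_umis <- function(n, umi_len = 16L) {
  codes <- sample(.BASE_CODES, n * umi_len, replace = TRUE)
  s <- intToUtf8(codes)
  starts <- seq(1L, by = umi_len, length.out = n)
  substring(s, starts, starts + umi_len - 1L)
}

check_clones <- function(clones, manifest) {
  if (is.null(clones) || nrow(clones) == 0L) {
    return(data.frame(pos = integer(0), alt = character(0), vaf = numeric(0),
                      individual_id = character(0), timepoints = character(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("pos", "alt", "vaf", "individual_id") %in% names(clones)))
  if (is.null(clones$timepoints)) clones$timepoints <- "1,2"
  stopifnot(all(clones$vaf >= 0), all(clones$vaf < 0.5))
  if (!all(clones$individual_id %in% manifest$individual_id)) {
    stop("clone individual absent from manifest")
  }
  clones
}

# resolve clone alt alleles: NA picks the first non-reference base, and an
# explicit alt equal to the reference base is a configuration error
fill_clone_alts <- function(clones, refv) {
  if (!nrow(clones)) return(clones)
  na <- is.na(clones$alt)
  if (any(na)) {
    clones$alt[na] <- vapply(clones$pos[na], function(p)
      setdiff(c("A", "C", "G", "T"), refv[p])[1L], "")
  }
  if (any(clones$alt == refv[clones$pos])) {
    stop("clone alt allele equals the reference base")
  }
  clones
}

clone_active <- function(clone, manifest_row) {
  tps <- as.integer(strsplit(as.character(clone$timepoints), ",")[[1L]])
  manifest_row$individual_id == clone$individual_id &&
    manifest_row$timepoint %in% tps
}

#' Simulate count-level pileups with spiked clones
#'
#' A fast shortcut for testing the calling chain: per library, background
#' alternate-allele counts are drawn as `Binomial(depth, error_rate)`
#' independently for each of the three alternate alleles at every position
#' (the post-consensus residual error), and each clone adds
#' `Binomial(depth, VAF)` mutant consensus counts on its allele in the
#' libraries of its individual at its time points. Replicates are drawn
#' independently. Fully deterministic for a fixed seed.
#'
#' @param seed Mandatory RNG seed.
#' @param manifest Manifest from [sim_manifest()].
#' @param n_positions Target positions (default 1000).
#' @param depth Consensus depth per position per library (default 60000).
#' @param error_rate Per-alternate-allele background rate (default 1e-5).
#' @param clones Optional data.frame with columns `pos` (1-based index into
#'   the simulated contig), `alt`, `vaf`, `individual_id` and optionally
#'   `timepoints` (comma-separated, default `"1,2"`).
#' @param chrom Contig name (default `"sim1"`).
#' @param reference Optional reference sequence of length `n_positions`
#'   (random otherwise).
#' @return list with `pileups` (one data.frame over all libraries),
#'   `ledger` (list of `background` and `clones` realized-count tables),
#'   `reference` (named character), `target` (`GRanges`), `manifest`.
#' @export
simulate_pileups <- function(seed, manifest = sim_manifest(),
                             n_positions = 1000L, depth = 60000L,
                             error_rate = 1e-5, clones = NULL,
                             chrom = "sim1", reference = NULL) {
  stopifnot(!missing(seed), error_rate >= 0, error_rate <= 1)
  set.seed(seed)
  if (is.null(reference)) reference <- random_sequence(n_positions)
  stopifnot(nchar(reference) == n_positions)
  refv <- strsplit(reference, "", fixed = TRUE)[[1L]]
  clones <- check_clones(clones, manifest)
  if (nrow(clones) && any(clones$pos < 1L | clones$pos > n_positions)) {
    stop("clone position outside the simulated target")
  }
  clones <- fill_clone_alts(clones, refv)
  bases <- c("A", "C", "G", "T")
  alt_of <- lapply(bases, function(b) setdiff(bases, b))
  names(alt_of) <- bases

  pileups <- vector("list", nrow(manifest))
  bg_ledger <- vector("list", nrow(manifest))
  clone_ledger <- vector("list", 0L)
  for (li in seq_len(nrow(manifest))) {
    lib <- manifest$library_id[li]
    counts <- matrix(0L, nrow = n_positions, ncol = 4L,
                     dimnames = list(NULL, bases))
    bg <- matrix(stats::rbinom(3L * n_positions, depth, error_rate),
                 nrow = n_positions, ncol = 3L)
    # map the 3 background columns onto the non-reference bases per position
    for (b in bases) {
      prow <- refv == b
      if (!any(prow)) next
      alts <- alt_of[[b]]
      for (j in 1:3) counts[prow, alts[j]] <- bg[prow, j]
    }
    if (nrow(clones)) {
      for (ci in seq_len(nrow(clones))) {
        if (clone_active(clones[ci, ], manifest[li, ])) {
          ck <- stats::rbinom(1L, depth, clones$vaf[ci])
          counts[clones$pos[ci], clones$alt[ci]] <-
            counts[clones$pos[ci], clones$alt[ci]] + ck
          clone_ledger[[length(clone_ledger) + 1L]] <- data.frame(
            library_id = lib, chrom = chrom, pos = clones$pos[ci],
            ref = refv[clones$pos[ci]], alt = clones$alt[ci],
            true_vaf = clones$vaf[ci], clone_count = ck,
            stringsAsFactors = FALSE)
        }
      }
    }
    ref_idx <- match(refv, bases)
    alt_sum <- rowSums(counts)
    if (any(alt_sum > depth)) stop("simulated alt counts exceed depth")
    counts[cbind(seq_len(n_positions), ref_idx)] <- depth - alt_sum
    pileups[[li]] <- data.frame(
      library_id = lib, chrom = chrom, pos = seq_len(n_positions),
      ref = refv,
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
      T = counts[, "T"], depth = depth, stringsAsFactors = FALSE)
    bg_long <- data.frame(
      library_id = lib, chrom = chrom,
      pos = rep(seq_len(n_positions), 3L),
      alt = c(vapply(seq_len(n_positions), function(i) alt_of[[refv[i]]][1L], ""),
              vapply(seq_len(n_positions), function(i) alt_of[[refv[i]]][2L], ""),
              vapply(seq_len(n_positions), function(i) alt_of[[refv[i]]][3L], "")),
      bg_count = c(bg[, 1L], bg[, 2L], bg[, 3L]),
      stringsAsFactors = FALSE)
    bg_ledger[[li]] <- bg_long
  }
  list(pileups = do.call(rbind, pileups),
       ledger = list(background = do.call(rbind, bg_ledger),
                     clones = if (length(clone_ledger))
                       do.call(rbind, clone_ledger)
                     else NULL),
       reference = stats::setNames(reference, chrom),
       target = target_space(data.frame(chrom = chrom, start = 0L,
                                        end = n_positions)),
       manifest = manifest)
}

# zero-truncated negative binomial family sizes
rfamily_sizes <- function(n, mean, dispersion) {
  s <- stats::rnbinom(n, mu = mean, size = dispersion)
  while (any(s == 0L)) {
    z <- s == 0L
    s[z] <- stats::rnbinom(sum(z), mu = mean, size = dispersion)
  }
  s
}

# apply independent per-base substitution errors to a vector of read
# strings; the error count is binomial over all bases and positions are
# sampled without replacement, equivalent to independent per-base trials
apply_read_errors <- function(x, read_len, rate) {
  if (rate <= 0 || length(x) == 0L) return(x)
  total <- length(x) * read_len
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(x)
  cell <- sample.int(total, n_err)
  rd <- (cell - 1L) %% length(x) + 1L
  posn <- (cell - 1L) %/% length(x) + 1L
  cur <- match(substring(x[rd], posn, posn), names(.BASE_CODES))
  shift <- sample.int(3L, n_err, replace = TRUE)
  newb <- names(.BASE_CODES)[(cur + shift - 1L) %% 4L + 1L]
  for (i in seq_len(n_err)) {
    substr(x[rd[i]], posn[i], posn[i]) <- newb[i]
  }
  x
}

int_matrix_to_strings <- function(m) {
  L <- ncol(m)
  s <- intToUtf8(as.vector(t(m)))
  starts <- seq(1L, by = L, length.out = nrow(m))
  substring(s, starts, starts + L - 1L)
}

#' Simulate UMI-tagged paired-end amplicon reads
#'
#' Emulates the sequencing input contract: each library receives `molecules`
#' uniquely tagged template molecules on a single amplicon; clones convert a
#' `Binomial(molecules, VAF)`-distributed subset of molecules to the mutant
#' allele; every molecule is amplified into a zero-truncated negative
#' binomial number of read pairs; independent per-base substitution errors
#' are applied to every read. Read 1 covers the amplicon head in forward
#' orientation and read 2 the amplicon tail in reverse complement, each
#' starting with `clip_len` primer bases, so the clipped pair spans
#' `2 * (read_len - clip_len)` reference positions. UMI collisions occur
#' naturally and are flagged in the ledger.
#'
#' @param seed Mandatory RNG seed.
#' @param manifest Manifest (default a single individual's two replicates at
#'   one time point: `sim_manifest(1, 1, 2)`).
#' @param molecules Template molecules per library (default 2000).
#' @param family_mean,family_dispersion Mean and negative binomial
#'   dispersion of read-pairs per molecule (defaults 8 and 10; dispersion
#'   `Inf` gives Poisson).
#' @param read_error Per-base substitution error rate (default 1e-3).
#' @param read_len,clip_len Raw read and primer lengths (defaults 144, 30).
#' @param amplicon Optional amplicon sequence of length `2 * read_len`
#'   (random otherwise).
#' @param chrom Contig name (default `"amp1"`).
#' @param amplicon_start 1-based reference start of the amplicon (default 1).
#' @param clones Optional clone table as in [simulate_pileups()]; positions
#'   are 1-based within the amplicon and must lie in the clipped, covered
#'   region.
#' @return list with `libraries` (named list of reads frames `umi`/`r1`/`r2`),
#'   `ledger` (per-molecule table: library, umi, family size, per-clone
#'   mutant flags, UMI-collision flag), `reference`, `target` (covered
#'   region), `layout` (chrom/amplicon_start/read_len/clip_len) and
#'   `manifest`.
#' @export
simulate_read_set <- function(seed, manifest = sim_manifest(1L, 1L, 2L),
                              molecules = 2000L, family_mean = 8,
                              family_dispersion = 10, read_error = 1e-3,
                              read_len = 144L, clip_len = 30L,
                              amplicon = NULL, chrom = "amp1",
                              amplicon_start = 1L, clones = NULL) {
  stopifnot(!missing(seed), read_len > clip_len, read_error >= 0,
            read_error <= 1)
  set.seed(seed)
  amp_len <- 2L * read_len
  if (is.null(amplicon)) amplicon <- random_sequence(amp_len)
  stopifnot(nchar(amplicon) == amp_len)
  amp_codes <- utf8ToInt(amplicon)
  covered <- c(start = clip_len + 1L, end = amp_len - clip_len)
  clones <- check_clones(clones, manifest)
  if (nrow(clones)) {
    refv <- strsplit(amplicon, "", fixed = TRUE)[[1L]]
    if (any(clones$pos < covered["start"] | clones$pos > covered["end"])) {
      stop("clone position outside the covered amplicon region")
    }
    clones <- fill_clone_alts(clones, refv)
  }
  comp <- integer(128)
  comp[.BASE_CODES] <- .BASE_CODES[c("T", "G", "C", "A")]
  comp[.N_CODE] <- .N_CODE

  libraries <- vector("list", nrow(manifest))
  names(libraries) <- manifest$library_id
  ledgers <- vector("list", nrow(manifest))
  for (li in seq_len(nrow(manifest))) {
    lib <- manifest$library_id[li]
    umi <- random_umis(molecules)
    fs <- rfamily_sizes(molecules, family_mean, family_dispersion)
    mut <- matrix(FALSE, nrow = molecules,
                  ncol = max(1L, nrow(clones)))
    led <- data.frame(library_id = lib, umi = umi, family_size = fs,
                      umi_collision = duplicated(umi) | duplicated(umi, fromLast = TRUE),
                      stringsAsFactors = FALSE)
    if (nrow(clones)) {
      for (ci in seq_len(nrow(clones))) {
        if (clone_active(clones[ci, ], manifest[li, ])) {
          mut[, ci] <- stats::runif(molecules) < clones$vaf[ci]
        }
        led[[paste0("clone", ci, "_mutant")]] <- mut[, ci]
      }
    }
    nreads <- sum(fs)
    mol_of_read <- rep.int(seq_len(molecules), fs)
    # build per-molecule template strings, then replicate into reads
    m1 <- matrix(rep(amp_codes[1:read_len], each = molecules),
                 nrow = molecules, ncol = read_len)
    tail_codes <- rev(comp[amp_codes[(read_len + 1L):amp_len]])
    m2 <- matrix(rep(tail_codes, each = molecules),
                 nrow = molecules, ncol = read_len)
    if (nrow(clones)) {
      for (ci in seq_len(nrow(clones))) {
        rows <- mut[, ci]
        p <- clones$pos[ci]
        ac <- utf8ToInt(clones$alt[ci])
        if (p <= read_len) {
          m1[rows, p] <- ac
        } else {
          m2[rows, amp_len - p + 1L] <- comp[ac]
        }
      }
    }
    s1 <- int_matrix_to_strings(m1)[mol_of_read]
    s2 <- int_matrix_to_strings(m2)[mol_of_read]
    libraries[[lib]] <- data.frame(
      umi = umi[mol_of_read],
      r1 = apply_read_errors(s1, read_len, read_error),
      r2 = apply_read_errors(s2, read_len, read_error),
      stringsAsFactors = FALSE)
    ledgers[[li]] <- led
  }
  list(libraries = libraries,
       ledger = do.call(rbind, ledgers),
       clones = clones,
       reference = stats::setNames(amplicon, chrom),
       target = target_space(data.frame(
         chrom = chrom,
         start = amplicon_start + covered["start"] - 2L,
         end = amplicon_start + covered["end"] - 1L)),
       layout = list(chrom = chrom, amplicon_start = amplicon_start,
                     read_len = read_len, clip_len = clip_len),
       manifest = manifest)
}

#' Simulate droplet digital PCR counts
#'
#' Molecules per droplet are Poisson(`lambda`); each molecule is mutant
#' independently with probability `vaf`. Droplets are tallied into empty,
#' mutant-only (no reference molecule) and reference-positive categories.
#'
#' @param seed Mandatory RNG seed.
#' @param n_total Number of droplets (default 10000).
#' @param lambda Mean molecules per droplet (default 0.1).
#' @param vaf True variant allele fraction (default 0).
#' @param dilution Fold-dilution recorded with the counts (default 1).
#' @return list with `counts` (`n_total`, `n_empty`, `n_mut_only`,
#'   `n_ref_pos`, `dilution`) and `truth` (`molecules`, `mutant_molecules`).
#' @export
simulate_droplets <- function(seed, n_total = 10000L, lambda = 0.1,
                              vaf = 0, dilution = 1) {
  stopifnot(!missing(seed), lambda > 0, n_total > 0, vaf >= 0, vaf <= 1)
  set.seed(seed)
  m <- stats::rpois(n_total, lambda)
  mut <- stats::rbinom(n_total, m, vaf)
  counts <- list(
    n_total = n_total,
    n_empty = sum(m == 0L),
    n_mut_only = sum(m > 0L & mut == m),
    n_ref_pos = sum(m > mut),
    dilution = dilution)
  list(counts = counts,
       truth = list(molecules = sum(m), mutant_molecules = sum(mut)))
}
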