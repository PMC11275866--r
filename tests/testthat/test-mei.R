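# Insertion-caller evidence channels and genotyping.

mei_fixture <- function(seed = 1, genotype = "hom_alt", tiled = FALSE,
                        sample_id = "s1") {
  cfg <- sim_config(seed = seed)
  ref <- simulate_reference(cfg)
  aln <- simulate_reads(
    cfg, ref,
    sample_genotypes = tibble::tibble(sample_id = sample_id,
                                      insertion_genotype = genotype),
    tiled = tiled
  )
  list(cfg = cfg, ref = ref, aln = aln, tr = ref$truth,
       region = tibble::tibble(chrom = ref$truth$insertion_contig,
                               start = ref$truth$bp_left - 2000L,
                               end = ref$truth$bp_right + 2000L))
}

test_that("a homozygous carrier shows exactly one elevated interval: the TSD", {
  f <- mei_fixture(seed = 2, genotype = "hom_alt", tiled = TRUE)
  prof <- depth_profile(f$aln, f$region)
  elev <- attr(prof, "elevated")
  expect_equal(nrow(elev), 1)
  expect_lte(abs(elev$start - f$tr$bp_left), 1)
  expect_lte(abs(elev$end - f$tr$bp_right), 1)
})

test_that("a reference-homozygous sample has no elevated interval and no clips", {
  f <- mei_fixture(seed = 2, genotype = "hom_ref", tiled = TRUE)
  expect_equal(nrow(attr(depth_profile(f$aln, f$region), "elevated")), 0)
  expect_equal(nrow(cluster_soft_clips(f$aln, f$region)), 0)
})

test_that("depth counts aligned bases of a single read", {
  aln <- tibble::tibble(
    qname = "r1", flag = 0L, rname = "c", pos = 100L, mapq = 60L,
    cigar = "10M5S", rnext = "=", pnext = 0L, tlen = 0L,
    seq = strrep("A", 15), qual = "*", sample_id = "s"
  )
  prof <- depth_profile(aln, tibble::tibble(chrom = "c", start = 95L, end = 120L))
  expect_equal(prof$depth[prof$pos %in% 100:109], rep(1L, 10))
  expect_equal(sum(prof$depth), 10)
})

test_that("the TSD gains depth over equal-length flanks in a homozygous carrier", {
  f <- mei_fixture(seed = 3, genotype = "hom_alt")
  prof <- depth_profile(f$aln, f$region)
  tsd <- mean(prof$depth[prof$pos >= f$tr$bp_left & prof$pos <= f$tr$bp_right])
  w <- f$tr$bp_right - f$tr$bp_left + 1L
  left <- mean(prof$depth[prof$pos >= f$tr$bp_left - 300 - w & prof$pos < f$tr$bp_left - 300])
  right <- mean(prof$depth[prof$pos > f$tr$bp_right + 300 & prof$pos <= f$tr$bp_right + 300 + w])
  expect_gt(tsd, left)
  expect_gt(tsd, right)
})

test_that("clip clusters sit on the two breakpoints with element consensus", {
  f <- mei_fixture(seed = 4, genotype = "hom_alt")
  cl <- cluster_soft_clips(f$aln, f$region)
  expect_equal(nrow(cl), 2)
  left <- cl[cl$side == "clip_left_of", ]
  right <- cl[cl$side == "clip_right_of", ]
  expect_equal(left$breakpoint, f$tr$bp_left)
  expect_equal(right$breakpoint, f$tr$bp_right)
  el <- f$tr$inserted_sequence
  expect_equal(right$consensus, substr(el, 1, nchar(right$consensus)))
  expect_equal(left$consensus,
               substr(el, nchar(el) - nchar(left$consensus) + 1, nchar(el)))
})

test_that("short clips are ignored and identical clips give their shared consensus", {
  base <- tibble::tibble(
    qname = c("r1", "r2"), flag = 1L, rname = "c", pos = 100L, mapq = 60L,
    cigar = "30M25S", rnext = "=", pnext = 0L, tlen = 0L,
    seq = paste0(strrep("G", 30), strrep("ACGTA", 5)), qual = "*", sample_id = "s"
  )
  region <- tibble::tibble(chrom = "c", start = 50L, end = 200L)
  cl <- cluster_soft_clips(base, region, mei_params(min_support = 2))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$consensus, strrep("ACGTA", 5))
  short <- dplyr::mutate(base, cigar = "50M5S", seq = paste0(strrep("G", 50), "ACGTA"))
  expect_equal(nrow(cluster_soft_clips(short, region, mei_params(min_support = 2))), 0)
})

test_that("poly-A detection handles tails, heads and absence", {
  expect_equal(detect_polyA(paste0("GC", strrep("A", 12)))$polyA_length, 12)
  expect_equal(detect_polyA(paste0("GC", strrep("A", 12)))$orientation, "forward")
  rev_case <- detect_polyA(paste0(strrep("T", 10), "GCGCGCGCGC"))
  expect_equal(rev_case$polyA_length, 10)
  expect_equal(rev_case$orientation, "reverse")
  expect_equal(detect_polyA(strrep("G", 40))$polyA_length, 0)
  # purity: 8 A's broken by 2 G's within a 10-window still passes at 0.8
  expect_gte(detect_polyA(paste0("CCCC", "AAAAGAAAAG"), purity = 0.8)$polyA_length, 10)
})

test_that("discordant counting follows the mate rules", {
  aln <- tibble::tibble(
    qname = c("p1", "p2", "p3", "p4"),
    flag = c(1L, 1L, 9L, 0L), # p3 mate-unmapped, p4 unpaired
    rname = "c", pos = c(100L, 200L, 300L, 400L), mapq = 60L,
    cigar = "50M", rnext = c("=", "other", "=", "="),
    pnext = c(130L, 5000L, 0L, 0L), tlen = 0L,
    seq = strrep("A", 50), qual = "*", sample_id = "s"
  )
  region <- tibble::tibble(chrom = "c", start = 1L, end = 1000L)
  expect_equal(count_discordant(aln, region), 2L) # p2 other contig + p3 unmapped
  proper <- dplyr::mutate(aln[1, ], rnext = "=", pnext = 130L)
  expect_equal(count_discordant(proper, region), 0L)
  expect_warning(n <- count_discordant(aln[4, ], region), "no paired")
  expect_equal(n, 0L)
})

test_that("discordant counts track the generative model within binomial bounds", {
  f <- mei_fixture(seed = 5, genotype = "hom_alt")
  stats <- attr(f$aln, "read_stats")
  whole <- tibble::tibble(chrom = f$tr$insertion_contig, start = 1L,
                          end = nchar(f$ref$contigs$seq[1]))
  got <- count_discordant(f$aln, whole)
  p <- f$cfg$discordant_frac
  lo <- stats$n_forced + qbinom(0.005, stats$n_coin_eligible, p)
  hi <- stats$n_forced + qbinom(0.995, stats$n_coin_eligible, p)
  expect_gte(got, lo)
  expect_lte(got, hi)
})

test_that("a noiseless homozygous sample yields the exact call", {
  f <- mei_fixture(seed = 6, genotype = "hom_alt")
  calls <- call_mei(f$aln, f$ref$contigs$seq[1], f$region)
  calls <- calls[!calls$one_sided, ]
  expect_equal(nrow(calls), 1)
  expect_equal(calls$bp_left, f$tr$bp_left)
  expect_equal(calls$bp_right, f$tr$bp_right)
  expect_equal(calls$tsd_sequence, f$tr$tsd_sequence)
  expect_equal(nchar(calls$tsd_sequence), 15L)
  expect_gt(calls$polyA_length, 0)
  gt <- calls$genotypes[[1]]
  expect_equal(gt$genotype[gt$sample_id == "s1"], "hom_alt")
  # 150 bp reads cannot span a 210 bp element: any reported length must come
  # from an overlap-merge of the two clip consensuses, never invention
  if (!is.na(calls$insert_length_estimate)) {
    expect_equal(calls$insert_length_estimate, nchar(f$tr$inserted_sequence))
    expect_equal(calls$insert_consensus, f$tr$inserted_sequence)
  }
})

test_that("a reference-homozygous sample genotypes hom_ref at the locus", {
  f <- mei_fixture(seed = 6, genotype = "hom_alt")
  ref_aln <- simulate_reads(
    f$cfg, f$ref,
    sample_genotypes = tibble::tibble(sample_id = "r1", insertion_genotype = "hom_ref")
  )
  both <- dplyr::bind_rows(f$aln, ref_aln)
  calls <- call_mei(both, f$ref$contigs$seq[1], f$region)
  gt <- calls$genotypes[[1]]
  expect_equal(gt$genotype[gt$sample_id == "r1"], "hom_ref")
  expect_equal(gt$genotype[gt$sample_id == "s1"], "hom_alt")
})

test_that("mixed 50:50 reads genotype het across seeds", {
  for (seed in 1:20) {
    f <- mei_fixture(seed = seed, genotype = "het")
    calls <- call_mei(f$aln, f$ref$contigs$seq[1], f$region)
    calls <- calls[!calls$one_sided, ]
    expect_equal(nrow(calls), 1, info = sprintf("seed %d", seed))
    gt <- calls$genotypes[[1]]
    expect_equal(gt$genotype[gt$sample_id == "s1"], "het",
                 info = sprintf("seed %d", seed))
  }
})

test_that("breakpoints are within 1 bp of truth on noiseless runs", {
  for (seed in c(11, 12, 13, 14, 15)) {
    f <- mei_fixture(seed = seed, genotype = "hom_alt")
    calls <- call_mei(f$aln, f$ref$contigs$seq[1], f$region)
    calls <- calls[!calls$one_sided, ]
    expect_lte(abs(calls$bp_left - f$tr$bp_left), 1)
    expect_lte(abs(calls$bp_right - f$tr$bp_right), 1)
    # TSD consistency: reported sequence is the reference substring
    expect_equal(calls$tsd_sequence,
                 substr(f$ref$contigs$seq[1], calls$bp_left, calls$bp_right))
  }
})

test_that("raising min_support never increases the number of calls", {
  f <- mei_fixture(seed = 8, genotype = "het")
  n <- vapply(c(3, 10, 30, 80), function(ms) {
    nrow(call_mei(f$aln, f$ref$contigs$seq[1], f$region, mei_params(min_support = ms)))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("one-sided evidence is flagged, not promoted to a confident call", {
  f <- mei_fixture(seed = 9, genotype = "hom_alt")
  # keep only right-extending clips by truncating the region at the left bp
  region <- tibble::tibble(chrom = f$region$chrom,
                           start = f$tr$bp_left + 3L, end = f$region$end)
  calls <- call_mei(f$aln, f$ref$contigs$seq[1], region)
  expect_true(all(calls$one_sided))
  expect_true(all(is.na(calls$tsd_sequence)))
})
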