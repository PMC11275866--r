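# QC filtering, sliding-window ROH detection, critical-region logic.

test_that("markers below the MAF threshold are removed", {
  # 20 samples, one marker het in exactly 1 (MAF 0.025 < 0.05), another common
  geno <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:20), function(s) {
    single_sample_geno(
      pos = c(100, 200), call = c("hom_ref", "het"),
      sample_id = s, phenotype = "control"
    )
  }))
  geno$call[geno$pos == 100 & geno$sample_id == "s01"] <- "het"
  out <- qc_filter(geno)
  expect_equal(unique(out$pos), 200L)
  expect_equal(qc_report(out)$markers_removed_maf, 1)
})

test_that("disabled thresholds make QC the identity", {
  cfg <- sim_config(seed = 4, markers_per_chromosome = 50)
  ref <- simulate_reference(cfg)
  geno <- simulate_genotype_cohort(cfg, ref)
  out <- qc_filter(geno, maf_min = 0, missing_max = 1)
  expect_equal(nrow(out), nrow(geno))
})

test_that("a marker missing in 3 of 26 samples exceeds the 10% bound", {
  geno <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:26), function(s) {
    single_sample_geno(
      pos = c(100, 200), call = c("het", "het"),
      sample_id = s, phenotype = "control"
    )
  }))
  geno$call[geno$pos == 100 & geno$sample_id %in% c("s01", "s02", "s03")] <- "missing"
  out <- qc_filter(geno) # 3/26 = 11.5% > 10%
  expect_equal(unique(out$pos), 200L)
  expect_equal(qc_report(out)$markers_removed_missing, 1)
})

test_that("QC that removes everything raises with both counts", {
  geno <- dplyr::bind_rows(
    single_sample_geno(100, "het", "s1"),
    single_sample_geno(100, "missing", "s2")
  )
  expect_error(qc_filter(geno, maf_min = 0.9), "no markers left")
})

test_that("an all-heterozygous sample has no runs", {
  p <- roh_params(window_snps = 5, min_markers = 5, min_length_bp = 10)
  geno <- single_sample_geno(seq(1000, 100000, by = 1000), "het")
  expect_equal(nrow(detect_roh(geno, p)), 0)
})

test_that("chromosomes with fewer markers than the window are skipped with a warning", {
  geno <- single_sample_geno(c(100, 200, 300), rep("hom_ref", 3))
  expect_warning(out <- detect_roh(geno, roh_params(window_snps = 50)), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("the planted case ROH is recovered as a single segment near truth", {
  cfg <- sim_config(seed = 31)
  ref <- simulate_reference(cfg)
  geno <- simulate_genotype_cohort(cfg, ref)
  tr <- attr(geno, "truth")
  segs <- detect_roh(qc_filter(geno), samples = "case_01") |>
    dplyr::filter(chrom == tr$roh_interval$chrom)
  hit <- segs |>
    dplyr::filter(start <= tr$insertion_site_genomic, end >= tr$insertion_site_genomic)
  expect_equal(nrow(hit), 1)
  # with hit_threshold 0.05 over 50-marker windows, eligibility needs >= 3
  # homozygous covering windows, so the detected run may sit two markers
  # inside the planted boundary; chance homozygosity can extend it outward
  spacing <- 3 * 25000
  expect_lte(hit$start, tr$roh_interval$start + spacing)
  expect_gte(hit$end, tr$roh_interval$end - spacing)
})

test_that("the scanner matches the brute-force enumerator on random instances", {
  set.seed(501)
  for (i in 1:30) {
    n <- sample(60:200, 1)
    params <- roh_params(
      window_snps = sample(c(5, 10, 20), 1),
      het_allow = sample(0:2, 1),
      missing_allow = sample(c(1, 5), 1),
      hit_threshold = sample(c(0.05, 0.5, 1), 1),
      min_markers = sample(c(5, 10, 20), 1),
      min_length_bp = sample(c(1, 5000, 50000), 1),
      gap_max_bp = sample(c(20000, 1e6), 1),
      density_max_kb = sample(c(20, 1e6), 1)
    )
    pos <- sort(sample.int(2e6, n))
    call <- sample(c("hom_ref", "hom_alt", "het", "missing"), n,
                   replace = TRUE, prob = c(0.55, 0.25, 0.12, 0.08))
    got <- detect_roh(single_sample_geno(pos, call), params) |>
      dplyr::select(start, end, n_markers, n_het) |>
      as.data.frame()
    want <- as.data.frame(oracle_roh(pos, call, params))
    expect_equal(got, want, info = sprintf("instance %d", i), ignore_attr = TRUE)
  }
})

test_that("raising het_allow never shrinks a reported segment", {
  # tested in the regime where density can never bind tighter than the gap
  # rule, which is where run growth is provably monotone
  set.seed(502)
  for (i in 1:10) {
    n <- 150
    pos <- sort(sample.int(2e6, n))
    call <- sample(c("hom_ref", "het", "missing"), n, replace = TRUE,
                   prob = c(0.8, 0.15, 0.05))
    geno <- single_sample_geno(pos, call)
    base <- roh_params(window_snps = 10, min_markers = 10, min_length_bp = 1,
                       gap_max_bp = 1e6, density_max_kb = 1000)
    lo <- detect_roh(geno, modifyList(base, list(het_allow = 1)))
    hi <- detect_roh(geno, modifyList(base, list(het_allow = 3)))
    for (j in seq_len(nrow(lo))) {
      covered <- any(hi$start <= lo$start[j] & hi$end >= lo$end[j])
      expect_true(covered, info = sprintf("instance %d segment %d", i, j))
    }
  }
})

test_that("raising maf_min never increases the marker count", {
  cfg <- sim_config(seed = 6, markers_per_chromosome = 100)
  geno <- simulate_genotype_cohort(cfg, simulate_reference(cfg))
  n <- vapply(c(0, 0.05, 0.2), function(m) {
    length(unique(qc_filter(geno, maf_min = m)$marker_id))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("the shared critical region contains the insertion and excludes controls", {
  cfg <- sim_config(seed = 41)
  ref <- simulate_reference(cfg)
  geno <- simulate_genotype_cohort(cfg, ref)
  tr <- attr(geno, "truth")
  genoqc <- qc_filter(geno)
  segs <- detect_roh(genoqc, samples = paste0("case_0", 1:4))
  regions <- shared_critical_region(segs, genoqc)
  expect_equal(nrow(regions), 1)
  expect_true(regions$start[1] <= tr$insertion_site_genomic &&
                regions$end[1] >= tr$insertion_site_genomic)
})

test_that("a case without segments empties the intersection", {
  cfg <- sim_config(seed = 41)
  geno <- simulate_genotype_cohort(cfg, simulate_reference(cfg))
  genoqc <- qc_filter(geno)
  segs <- detect_roh(genoqc, samples = paste0("case_0", 1:4)) |>
    dplyr::filter(sample_id != "case_01") # case_01 contributes nothing
  expect_equal(nrow(shared_critical_region(segs, genoqc)), 0)
})

test_that("an interval where a control is fully homozygous is excluded", {
  # two cases sharing a run; one control homozygous across it
  pos <- seq(1000, 40000, by = 1000)
  geno <- dplyr::bind_rows(
    single_sample_geno(pos, rep("hom_alt", 40), "c1", "case"),
    single_sample_geno(pos, rep("hom_alt", 40), "c2", "case"),
    single_sample_geno(pos, rep("hom_ref", 40), "k1", "control")
  )
  p <- roh_params(window_snps = 5, min_markers = 10, min_length_bp = 10000,
                  gap_max_bp = 1e6, density_max_kb = 1e6)
  segs <- detect_roh(geno, p, samples = c("c1", "c2"))
  expect_gt(nrow(segs), 0)
  expect_equal(nrow(shared_critical_region(segs, geno)), 0)
  # give the control one het inside and the region survives
  geno$call[geno$sample_id == "k1" & geno$pos == 20000] <- "het"
  out <- shared_critical_region(segs, geno)
  expect_equal(nrow(out), 1)
})

test_that("flanking case het calls trim the region to the markers between them", {
  pos <- seq(1000, 20000, by = 1000)
  call <- rep("hom_ref", 20)
  call[c(2, 19)] <- "het"
  geno <- dplyr::bind_rows(
    single_sample_geno(pos, call, "c1", "case"),
    single_sample_geno(pos, rep("hom_ref", 20), "k1", "control")
  )
  region <- tibble::tibble(chrom = "chr1", start = 1000L, end = 20000L)
  refined <- refine_by_het_calls(region, geno)
  expect_equal(refined$start, 3000L)
  expect_equal(refined$end, 18000L)
})

test_that("refinement without het calls is the identity", {
  pos <- seq(1000, 10000, by = 1000)
  geno <- single_sample_geno(pos, rep("hom_alt", 10), "c1", "case")
  region <- tibble::tibble(chrom = "chr1", start = 1000L, end = 10000L)
  expect_identical(refine_by_het_calls(region, geno), region)
})

test_that("an interior het splits the region and the longest piece wins", {
  pos <- seq(1000, 30000, by = 1000)
  call <- rep("hom_ref", 30)
  call[10] <- "het" # split: markers 1-9 (1000-9000) vs 11-30 (11000-30000)
  geno <- single_sample_geno(pos, call, "c1", "case")
  region <- tibble::tibble(chrom = "chr1", start = 1000L, end = 30000L)
  expect_message(refined <- refine_by_het_calls(region, geno), "2 candidates")
  expect_equal(refined$start, 11000L)
  expect_equal(refined$end, 30000L)
  alt <- attr(refined, "alternates")
  expect_equal(alt$start, 1000L)
  expect_equal(alt$end, 9000L)
})

test_that("the shared+refined region recovers the insertion site across seeds", {
  for (seed in 1:8) {
    cfg <- sim_config(seed = seed)
    ref <- simulate_reference(cfg)
    geno <- simulate_genotype_cohort(cfg, ref)
    tr <- attr(geno, "truth")
    genoqc <- qc_filter(geno)
    segs <- detect_roh(genoqc, samples = unique(geno$sample_id[geno$phenotype == "case"]))
    regions <- shared_critical_region(segs, genoqc)
    expect_gte(nrow(regions), 1)
    refined <- suppressMessages(refine_by_het_calls(regions[1, ], genoqc))
    expect_true(
      refined$start <= tr$insertion_site_genomic &&
        refined$end >= tr$insertion_site_genomic,
      info = sprintf("seed %d", seed)
    )
  }
})
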